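# Independent oracle implementations used to cross-check the package.
# These are written naively (explicit loops, no shared code paths with the
# package internals) so that agreement is evidence, not tautology.

# --- brute-force spindle-pole detector -------------------------------------
# Direct evaluation of the spot-detection definition on a full patch:
# Gaussian smoothing by explicit kernel sums with edge-clamped indexing,
# exhaustive neighbour checks for 8-connected maxima, plateau collapse to
# the smallest column-major index, contrast filtering, and the ordered
# path-minimum merge.
oracle_poles <- function(tubulin, mask, params) {
  nx <- nrow(tubulin); ny <- ncol(tubulin)
  sig <- params$smoothing_sigma
  r <- ceiling(3 * sig)
  w <- exp(-((-r:r)^2) / (2 * sig^2)); w <- w / sum(w)
  w2 <- outer(w, w)                       # full 2-D kernel
  cl <- function(v, n) pmin(pmax(v, 1), n)
  sm <- matrix(0, nx, ny)
  for (x in 1:nx) for (y in 1:ny)
    sm[x, y] <- sum(w2 * tubulin[cl((x - r):(x + r), nx),
                                 cl((y - r):(y + r), ny)])
  # 8-connected in-mask local maxima
  cand <- matrix(0, 0, 3)  # x, y, value
  for (x in 1:nx) for (y in 1:ny) {
    if (!mask[x, y]) next
    v <- sm[x, y]; ok <- TRUE
    for (i in -1:1) for (j in -1:1) {
      if (i == 0 && j == 0) next
      xx <- x + i; yy <- y + j
      if (xx < 1 || xx > nx || yy < 1 || yy > ny) next
      if (mask[xx, yy] && sm[xx, yy] > v) ok <- FALSE
    }
    if (ok) cand <- rbind(cand, c(x, y, v))
  }
  if (nrow(cand) == 0) return(integer(0))
  # collapse equal-valued 8-connected plateaus (smallest linear index wins):
  # within each group of exactly tied candidates, find connected components
  # by breadth-first search over Chebyshev-adjacent members
  lin <- (cand[, 2] - 1) * nx + cand[, 1]
  if (anyDuplicated(cand[, 3])) {
    keep <- rep(TRUE, nrow(cand))
    for (v in unique(cand[cand[, 3] %in% cand[duplicated(cand[, 3]), 3], 3])) {
      grp <- which(cand[, 3] == v)
      if (length(grp) < 2) next
      pos <- cand[grp, 1:2, drop = FALSE]
      unvisited <- rep(TRUE, length(grp))
      while (any(unvisited)) {
        comp <- which(unvisited)[1]
        unvisited[comp] <- FALSE
        frontier <- comp
        while (length(frontier)) {
          nxt <- integer(0)
          for (f in frontier) for (g in which(unvisited))
            if (max(abs(pos[g, ] - pos[f, ])) <= 1) {
              unvisited[g] <- FALSE
              nxt <- c(nxt, g)
            }
          comp <- c(comp, nxt)
          frontier <- nxt
        }
        # drop all but the smallest linear index in this plateau component
        drop <- grp[comp][lin[grp[comp]] != min(lin[grp[comp]])]
        keep[drop] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    lin <- lin[keep]
  }
  bg <- median(sm[mask]); mx <- max(sm[mask])
  if (mx <= bg) return(integer(0))
  rel <- (cand[, 3] - bg) / (mx - bg)
  sel <- rel > params$rel_spot_intensity_min
  cand <- cand[sel, , drop = FALSE]; lin <- lin[sel]
  if (nrow(cand) <= 1) return(cand[, 1:2, drop = FALSE])
  ord <- order(-cand[, 3], lin)
  cand <- cand[ord, , drop = FALSE]
  kept <- 1L
  for (j in 2:nrow(cand)) {
    absorbed <- FALSE
    for (k in kept) {
      x1 <- cand[k, 1]; y1 <- cand[k, 2]
      x2 <- cand[j, 1]; y2 <- cand[j, 2]
      nstep <- max(abs(x2 - x1), abs(y2 - y1))
      vmin <- Inf
      for (s in 0:nstep) {
        t <- if (nstep == 0) 0 else s / nstep
        vmin <- min(vmin, sm[round(x1 + (x2 - x1) * t),
                             round(y1 + (y2 - y1) * t)])
      }
      if (vmin > params$splitting_coefficient * cand[j, 3]) {
        absorbed <- TRUE; break
      }
    }
    if (!absorbed) kept <- c(kept, j)
  }
  cand[kept, 1:2, drop = FALSE]
}

# --- exhaustive complete-linkage agglomeration -----------------------------
# Recomputes every inter-cluster distance from the original matrix at each
# step (no Lance-Williams update), with the same lowest-index tie rule.
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      key <- c(min(unlist(clusters[c(a, b)])),
               max(min(clusters[[a]]), min(clusters[[b]])))
      if (is.null(best) || h < best$h - 1e-15 ||
          (abs(h - best$h) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(a = a, b = b, h = h, key = key)
    }
    heights <- c(heights, best$h)
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    clusters <- clusters[-c(best$a, best$b)]
    clusters[[length(clusters) + 1]] <- merged
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition induced by cutting at distance h: clusters whose merges all
# happened at height <= h (recomputed exhaustively)
oracle_cut <- function(d, h) {
  d <- as.matrix(d)
  n <- nrow(d)
  res <- oracle_complete_linkage(d)
  groups <- lapply(seq_len(n), identity)
  steps <- which(res$heights <= h)
  if (length(steps)) groups <- res$partitions[[max(steps)]]
  # normalize: sort members, order by first member
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, numeric(1), 1))]
}

partition_from_assignments <- function(ids) {
  groups <- split(seq_along(ids), ids)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, numeric(1), 1))])
}

# --- Spearman rho by the rank formula with average ranks --------------------
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(rx)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# --- small synthetic patch builders ----------------------------------------
# A flat patch with isotropic Gaussian foci; no noise unless asked for.
make_foci_patch <- function(size, centers, amp = 100, sigma = 2,
                            background = 10, noise_sd = 0, seed = NULL) {
  m <- matrix(background, size, size)
  g <- 0:(size - 1)
  for (k in seq_len(nrow(centers)))
    m <- m + amp * outer(exp(-((g - centers[k, 1])^2) / (2 * sigma^2)),
                         exp(-((g - centers[k, 2])^2) / (2 * sigma^2)))
  if (noise_sd > 0)
    m <- m + spindlescreen:::with_seed(seed,
      matrix(rnorm(size^2, 0, noise_sd), size, size))
  m
}
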