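# Spindle-pole spot detection and the mitotic quality-control filters.
#
# The spot detector is the package's own concrete definition of
# local-maxima pole counting: background-and-maximum-normalized peak
# contrast (the "relative spot intensity") plus a path-minimum merge rule
# (the "splitting coefficient"), with the screen's published numeric
# operating point (0.095, 0.56) as defaults. Both rules are intensity-scale
# invariant: the contrast is a ratio, and the valley test compares two
# intensities that scale together.

#' Apply the mitotic-cell quality-control filters
#'
#' Sets `exclusion_reason` on each mitotic cell, checking in order:
#' \enumerate{
#'   \item `edge` — the cytoplasm mask touches the image border
#'     (incomplete segmentation);
#'   \item `roundness` — isoperimetric roundness `4*pi*A/P^2` of the
#'     cytoplasm mask is below `roundness_min` (poor segmentation);
#'   \item `low_tubulin` — mean tubulin over the mask is below
#'     `tubulin_mean_min` (poles cannot be distinguished).
#' }
#' All inequalities are strict ("below" the threshold excludes; equality
#' keeps). Every mitotic cell receives exactly one reason (`none` if kept).
#'
#' @param cells data frame from [segment_mitotic_cells()] (`$cells`).
#' @param cyto_labels cytoplasm label matrix from the same call.
#' @param tubulin tubulin channel matrix.
#' @param params a [pipeline_params()].
#' @return `cells` with added `roundness`, `tubulin_mean`,
#'   `exclusion_reason` (factor: none, edge, roundness, low_tubulin).
#' @export
qc_filter <- function(cells, cyto_labels, tubulin,
                      params = pipeline_params()) {
  if (nrow(cells) == 0L) {
    cells$roundness <- numeric(0)
    cells$tubulin_mean <- numeric(0)
    cells$exclusion_reason <- factor(character(0),
                                     levels = EXCLUSION_LEVELS)
    return(cells)
  }
  shp <- EBImage::computeFeatures.shape(cyto_labels)
  lab <- as.integer(rownames(shp))
  area <- shp[match(cells$label, lab), "s.area"]
  perim <- shp[match(cells$label, lab), "s.perimeter"]
  cells$roundness <- ifelse(perim > 0, 4 * pi * area / perim^2, 1)
  means <- tapply(tubulin[cyto_labels > 0L],
                  cyto_labels[cyto_labels > 0L], mean)
  cells$tubulin_mean <- as.numeric(means[as.character(cells$label)])
  reason <- rep("none", nrow(cells))
  reason[cells$tubulin_mean < params$tubulin_mean_min] <- "low_tubulin"
  reason[cells$roundness < params$roundness_min] <- "roundness"
  reason[cells$touches_edge] <- "edge"
  cells$exclusion_reason <- factor(reason, levels = EXCLUSION_LEVELS)
  cells
}

EXCLUSION_LEVELS <- c("none", "edge", "roundness", "low_tubulin")

#' Detect spindle poles as merged local intensity maxima
#'
#' The pole count of one QC-passed mitotic cell, computed from the tubulin
#' channel restricted to its cytoplasm mask:
#' \enumerate{
#'   \item smooth the tubulin patch with a Gaussian of SD
#'     `smoothing_sigma` (separable, replicate-padded);
#'   \item find 8-connected local maxima inside the mask (a pixel whose
#'     smoothed value is >= all in-mask neighbours; equal-valued connected
#'     plateaus are represented by their lowest linear index);
#'   \item keep maxima whose relative spot intensity
#'     `r = (peak - bg) / (max_cell - bg)` exceeds
#'     `rel_spot_intensity_min`, where `bg` is the median smoothed
#'     intensity over the mask and `max_cell` its maximum;
#'   \item merge: processing candidates from brightest to dimmest, a
#'     candidate is absorbed by an already-kept brighter peak when the
#'     minimum smoothed intensity along the straight pixel path between
#'     them exceeds `splitting_coefficient` times the candidate's own peak
#'     (the valley is too shallow to split them).
#' }
#'
#' @param tubulin tubulin channel matrix.
#' @param mask logical matrix, the cell's cytoplasm mask.
#' @param params a [pipeline_params()].
#' @return data frame of accepted poles: 0-based `x`, `y`, smoothed `peak`
#'   intensity, `rel_intensity`. Zero rows for a uniform cell; an error for
#'   an empty mask; a warning and zero rows when the mask is smaller than
#'   the smoothing kernel.
#' @examples
#' tub <- matrix(0, 64, 64)
#' for (p in list(c(20, 32), c(44, 32)))
#'   tub <- tub + 100 * exp(-outer((0:63 - p[1])^2, (0:63 - p[2])^2, "+") / 8)
#' mask <- matrix(TRUE, 64, 64)
#' nrow(detect_spindle_poles(tub, mask, pipeline_params(smoothing_sigma = 1)))
#' @export
detect_spindle_poles <- function(tubulin, mask, params = pipeline_params()) {
  stopifnot(is.matrix(tubulin), is.logical(mask),
            all(dim(tubulin) == dim(mask)))
  if (!any(mask)) stopf("empty cytoplasm mask")
  ksize <- 2L * as.integer(ceiling(3 * params$smoothing_sigma)) + 1L
  idx <- which(mask, arr.ind = TRUE)
  bb <- c(range(idx[, 1]), range(idx[, 2]))
  if ((bb[2] - bb[1] + 1L) < ksize && (bb[4] - bb[3] + 1L) < ksize) {
    warnf("mask (%dx%d px) smaller than the smoothing kernel (%d px); 0 poles",
          bb[2] - bb[1] + 1L, bb[4] - bb[3] + 1L, ksize)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
                      rel_intensity = numeric(0)))
  }
  # crop with a kernel-sized pad so smoothing sees local context and the
  # result is exactly translation-covariant
  pad <- as.integer(ceiling(3 * params$smoothing_sigma))
  x0 <- max(1L, bb[1] - pad); x1 <- min(nrow(tubulin), bb[2] + pad)
  y0 <- max(1L, bb[3] - pad); y1 <- min(ncol(tubulin), bb[4] + pad)
  patch <- tubulin[x0:x1, y0:y1, drop = FALSE]
  pmask <- mask[x0:x1, y0:y1, drop = FALSE]
  sm <- smooth_gaussian(patch, params$smoothing_sigma)
  cand <- local_maxima(sm, pmask)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
                      rel_intensity = numeric(0)))
  bg <- median(sm[pmask])
  mx <- max(sm[pmask])
  if (mx <= bg)
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
                      rel_intensity = numeric(0)))
  cand$rel_intensity <- (cand$peak - bg) / (mx - bg)
  cand <- cand[cand$rel_intensity > params$rel_spot_intensity_min, ,
               drop = FALSE]
  if (nrow(cand) > 1L) {
    ord <- order(-cand$peak, cand$i)
    cand <- cand[ord, , drop = FALSE]
    kept <- 1L
    for (j in seq_len(nrow(cand))[-1]) {
      absorbed <- FALSE
      for (k in kept) {
        valley <- path_min(sm, cand$px[k], cand$py[k], cand$px[j],
                           cand$py[j])
        if (valley > params$splitting_coefficient * cand$peak[j]) {
          absorbed <- TRUE
          break
        }
      }
      if (!absorbed) kept <- c(kept, j)
    }
    cand <- cand[kept, , drop = FALSE]
  }
  out <- data.frame(x = cand$px - 1L + (x0 - 1L),
                    y = cand$py - 1L + (y0 - 1L),
                    peak = cand$peak, rel_intensity = cand$rel_intensity)
  rownames(out) <- NULL
  out
}

# 8-connected in-mask local maxima of a smoothed patch; plateaus collapse
# to the member with the smallest column-major linear index.
local_maxima <- function(sm, pmask) {
  nx <- nrow(sm); ny <- ncol(sm)
  idx <- which(pmask)
  is_cand <- logical(length(sm))
  for (ii in idx) {
    x <- (ii - 1L) %% nx + 1L
    y <- (ii - 1L) %/% nx + 1L
    v <- sm[ii]
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      xx <- x + dx; yy <- y + dy
      if (xx < 1L || xx > nx || yy < 1L || yy > ny) next
      jj <- xx + (yy - 1L) * nx
      if (pmask[jj] && sm[jj] > v) { ok <- FALSE; break }
    }
    if (!ok) next
    is_cand[ii] <- TRUE
  }
  ci <- which(is_cand)
  if (length(ci) == 0L)
    return(data.frame(i = integer(0), px = integer(0), py = integer(0),
                      peak = numeric(0)))
  # collapse equal-valued 8-connected plateaus of candidates
  keep <- logical(length(ci))
  visited <- logical(length(sm))
  for (a in seq_along(ci)) {
    ii <- ci[a]
    if (visited[ii]) next
    # flood fill over candidate pixels with the same value
    visited[ii] <- TRUE
    comp <- frontier <- ii
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        x <- (f - 1L) %% nx + 1L; y <- (f - 1L) %/% nx + 1L
        for (dx in -1:1) for (dy in -1:1) {
          xx <- x + dx; yy <- y + dy
          if (xx < 1L || xx > nx || yy < 1L || yy > ny) next
          jj <- xx + (yy - 1L) * nx
          if (is_cand[jj] && !visited[jj] && sm[jj] == sm[ii]) {
            visited[jj] <- TRUE
            nxt <- c(nxt, jj)
          }
        }
      }
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    keep[match(min(comp), ci)] <- TRUE
  }
  ci <- ci[keep]
  data.frame(i = ci, px = (ci - 1L) %% nx + 1L, py = (ci - 1L) %/% nx + 1L,
             peak = sm[ci])
}

# Minimum intensity along the straight pixel path between two points:
# max(|dx|, |dy|) + 1 evenly spaced samples, rounded to the nearest pixel.
path_min <- function(sm, x1, y1, x2, y2) {
  n <- max(abs(x2 - x1), abs(y2 - y1))
  if (n == 0L) return(sm[x1, y1])
  t <- seq(0, 1, length.out = n + 1L)
  xs <- round(x1 + (x2 - x1) * t)
  ys <- round(y1 + (y2 - y1) * t)
  min(sm[cbind(xs, ys)])
}

#' Classify a cell as multipolar from its pole count
#'
#' A mitotic cell is multipolar iff it has strictly more than two spindle
#' poles (`n_poles >= multipolar_pole_count_min`, default 3). Cells with
#' zero detected poles are retained as non-multipolar and contribute 0 to
#' the mean pole count.
#'
#' @param n_poles integer vector of pole counts.
#' @param params a [pipeline_params()].
#' @return logical vector.
#' @export
classify_multipolar <- function(n_poles, params = pipeline_params()) {
  n_poles >= params$multipolar_pole_count_min
}
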