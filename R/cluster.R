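# Phenotypic clustering of differential-Z profiles: gene inclusion filter,
# uncentred-Pearson / city-block distances, complete-linkage agglomeration
# with deterministic tie-breaking, the similarity cut, and Cluster-3.0
# (CDT/GTR) plus Newick export.

DZ_FEATURES <- c("pct_multipolar", "mean_poles", "n_cells",
                 "mitotic_index", "pct_multinucleate")

#' Filter genes for clustering and build the dZ matrix
#'
#' Keeps genes whose sensitized-background Z score exceeds 1 in magnitude
#' (strictly) for the percentage of multipolar spindles OR the mean pole
#' count, and assembles their differential-Z values across all five
#' features into the clustering matrix.
#'
#' @param scores a `gene_scores` data frame from [compute_zscores()].
#' @param z_min magnitude threshold on `z_chtog` (default 1, strict).
#' @return numeric matrix (genes x 5 features) of dZ values, feature order
#'   fixed and recorded in `colnames`; errors when no gene passes or a
#'   passing gene has incomplete features.
#' @export
filter_genes <- function(scores, z_min = 1) {
  sel <- scores[scores$feature %in% c("pct_multipolar", "mean_poles") &
                  abs(scores$z_chtog) > z_min, , drop = FALSE]
  genes <- unique(sel$gene)
  if (length(genes) == 0L)
    stopf("no gene passes the |Z_chTOG| > %g filter", z_min)
  m <- matrix(NA_real_, length(genes), length(DZ_FEATURES),
              dimnames = list(genes, DZ_FEATURES))
  for (f in DZ_FEATURES) {
    sf <- scores[scores$feature == f, , drop = FALSE]
    m[, f] <- sf$dz[match(genes, sf$gene)]
  }
  if (anyNA(m))
    stopf("incomplete dZ rows for gene(s): %s",
          paste(rownames(m)[!complete.cases(m)], collapse = ", "))
  m
}

#' Pairwise distances between gene dZ profiles
#'
#' Two metrics: `uncentred_pearson` distance
#' `1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` (the uncentred correlation
#' treats the zero profile as the origin, so two genes agreeing in sign and
#' shape of their dZ profile are close even if their means differ), and
#' `cityblock` (`sum(|x - y|)`).
#'
#' @param m genes x features matrix, e.g. from [filter_genes()].
#' @param metric distance metric.
#' @return symmetric distance matrix with zero diagonal and a `metric`
#'   attribute; an all-zero row under `uncentred_pearson` is an error (its
#'   similarity is undefined).
#' @export
pairwise_distance <- function(m, metric = c("uncentred_pearson",
                                            "cityblock")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2L) stopf("need >= 2 genes")
  if (metric == "uncentred_pearson") {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0))
      stopf("all-zero dZ row(s): %s (uncentred similarity undefined)",
            paste(rownames(m)[nrm == 0], collapse = ", "))
    s <- (m %*% t(m)) / outer(nrm, nrm)
    d <- 1 - s
    d[d < 0] <- 0
  } else {
    d <- as.matrix(dist(m, method = "manhattan"))
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- metric
  d
}

#' Complete-linkage hierarchical clustering with deterministic ties
#'
#' Agglomerates from singletons, at each step merging the pair of clusters
#' with the smallest complete-linkage (maximum pairwise) distance. Ties are
#' broken deterministically by the lowest gene index contained in the
#' candidate pairs, so the tree is reproducible across platforms.
#'
#' @param d distance matrix from [pairwise_distance()].
#' @return object of class `spindle_tree` with hclust-compatible `merge`,
#'   `height`, `order`, `labels`, plus `method` and `dist.method`. Coerce
#'   with [as.hclust()] for plotting or cutting with standard tools.
#' @export
cluster_complete <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stopf("need >= 2 genes")
  labels <- rownames(d) %||% as.character(seq_len(n))
  # active cluster bookkeeping: members (original indices) and hclust id
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  cd <- d                      # complete-linkage distances between clusters
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- cd[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    hmin <- min(sub)
    cand <- which(sub <= hmin + 1e-15, arr.ind = TRUE)
    # tie-break by the lowest original gene index in the candidate pair,
    # then by the other cluster's lowest index
    mm <- vapply(members[active], min, numeric(1))
    k1 <- pmin(mm[cand[, 1]], mm[cand[, 2]])
    k2 <- pmax(mm[cand[, 1]], mm[cand[, 2]])
    pick <- order(k1, k2)[1]
    a <- active[cand[pick, 1]]; b <- active[cand[pick, 2]]
    merge[step, ] <- sort(c(ids[a], ids[b]),
                          decreasing = FALSE)  # negatives (leaves) first
    height[step] <- cd[a, b]
    # merged cluster replaces a; complete linkage = max of the two rows
    newd <- pmax(cd[a, ], cd[b, ])
    cd[a, ] <- newd; cd[, a] <- newd; cd[a, a] <- 0
    members[[a]] <- c(members[[a]], members[[b]])
    ids[a] <- step
    active <- setdiff(active, b)
  }
  order <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "complete",
                 dist.method = attr(d, "metric") %||% "unknown"),
            class = "spindle_tree")
}

tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
as.hclust.spindle_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method, call = match.call()),
            class = "hclust")
}

#' @export
print.spindle_tree <- function(x, ...) {
  cat(sprintf("<spindle_tree> %d genes, %s linkage on %s distance\n",
              length(x$labels), x$method, x$dist.method))
  invisible(x)
}

#' @export
plot.spindle_tree <- function(x, ...) {
  plot(as.hclust(x), ...)
}

#' Cut a gene tree into phenotypic clusters
#'
#' Clusters are the maximal subtrees all of whose merge heights are at or
#' below the cut. For trees built on uncentred-Pearson distances the cut is
#' given on the similarity scale (genes group when they cluster together
#' above similarity `cut`, i.e. at distance `<= 1 - cut`); for city-block
#' distances the cut is a free distance parameter.
#'
#' @param tree a `spindle_tree`.
#' @param cut similarity cut in `[0, 1]` (`mode = "similarity"`) or a
#'   distance (`mode = "distance"`).
#' @param mode cut scale; defaults to similarity for uncentred-Pearson
#'   trees and distance otherwise.
#' @return list of class `cluster_result`: `assignments` (named integer
#'   vector; ids contiguous from 1, numbered by first gene occurrence),
#'   `n_clusters`, `cut`, `mode`, `height_cut`, `tree`.
#' @examples
#' m <- rbind(a = c(1, 1, 0, 0, 0), b = c(2, 2, 0, 0, 0),
#'            c = c(-1, 0, 1, 0, 0))
#' tr <- cluster_complete(pairwise_distance(m))
#' cut_clusters(tr, 0.7)$assignments
#' @export
cut_clusters <- function(tree, cut = 0.7, mode = NULL) {
  stopifnot(inherits(tree, "spindle_tree"))
  mode <- mode %||%
    (if (tree$dist.method == "uncentred_pearson") "similarity" else
       "distance")
  mode <- match.arg(mode, c("similarity", "distance"))
  if (mode == "similarity") {
    if (cut < 0 || cut > 1)
      stopf("similarity cut must lie in [0, 1] (got %g)", cut)
    h <- 1 - cut
  } else h <- cut
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_rep <- integer(n - 1L)   # representative leaf of each merge node
  for (s in seq_len(n - 1L)) {
    ch <- tree$merge[s, ]
    reps <- ifelse(ch < 0L, -ch, node_rep[pmax(ch, 1L)])
    node_rep[s] <- reps[1]
    if (tree$height[s] <= h) {
      ra <- find(reps[1]); rb <- find(reps[2])
      parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  names(ids) <- tree$labels
  structure(list(assignments = ids, n_clusters = max(ids), cut = cut,
                 mode = mode, height_cut = h, tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters of %d genes (%s cut %.2f)\n",
              x$n_clusters, length(x$assignments), x$mode, x$cut))
  invisible(x)
}

#' Export a gene tree in Cluster-3.0 / TreeView and Newick formats
#'
#' Writes `<name>.cdt` (the clustered data table, rows in leaf order),
#' `<name>.gtr` (the gene-tree node list, with similarity `1 - height`)
#' and `<name>.nwk` (a Newick string of the gene tree). The CDT round
#' trips: [read_cdt()] reproduces the matrix.
#'
#' @param tree a `spindle_tree`.
#' @param m the matrix that was clustered (genes x features).
#' @param dir output directory (created if needed).
#' @param name file basename.
#' @return invisibly, the named vector of file paths.
#' @export
export_tree <- function(tree, m, dir, name = "screen") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory: %s", dir)
  paths <- c(cdt = file.path(dir, paste0(name, ".cdt")),
             gtr = file.path(dir, paste0(name, ".gtr")),
             nwk = file.path(dir, paste0(name, ".nwk")))
  n <- length(tree$labels)
  stopifnot(nrow(m) == n)
  gid <- function(i) sprintf("GENE%dX", i)
  nid <- function(i) sprintf("NODE%dX", i)
  node_name <- function(v) ifelse(v < 0L, gid(-v), nid(v))
  gtr <- sprintf("%s\t%s\t%s\t%s", nid(seq_len(n - 1L)),
                 node_name(tree$merge[, 1]), node_name(tree$merge[, 2]),
                 format(1 - tree$height, digits = 15, trim = TRUE))
  ok <- tryCatch({
    writeLines(gtr, paths["gtr"])
    hdr <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)),
                 collapse = "\t")
    ew <- paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                collapse = "\t")
    rows <- vapply(tree$order, function(i)
      paste(c(gid(i), tree$labels[i], tree$labels[i], "1",
              format(m[i, ], digits = 15, trim = TRUE)), collapse = "\t"),
      character(1))
    writeLines(c(hdr, ew, rows), paths["cdt"])
    ph <- ape::as.phylo(as.hclust(tree))
    ape::write.tree(ph, file = paths["nwk"])
    TRUE
  }, error = function(e)
    stopf("tree export to %s failed: %s", dir, conditionMessage(e)))
  invisible(paths)
}

#' Read back a Cluster-3.0 CDT file
#'
#' @param path a CDT written by [export_tree()].
#' @return numeric matrix with gene rownames and feature colnames (rows in
#'   the file's leaf order).
#' @export
read_cdt <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1], "\t", fixed = TRUE)[[1]]
  feats <- hdr[-(1:4)]
  body <- ln[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.numeric(p[-(1:4)]),
                numeric(length(feats))))
  rownames(m) <- vapply(parts, `[[`, character(1), 2L)
  colnames(m) <- feats
  m
}
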