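# Nucleus and cytoplasm segmentation built on EBImage primitives
# (Otsu thresholding, connected components, distance-map watershed,
# geodesic Voronoi propagation).

#' Segment nuclei from the DNA channel
#'
#' Detects and segments all nuclei: Otsu threshold on the normalized DNA
#' image, removal of sub-`nucleus_min_area` specks, and a distance-map
#' watershed to split touching nuclei. The number of segmented nuclei is
#' the well's total cell number.
#'
#' @param dna `[x, y]` intensity matrix.
#' @param params a [pipeline_params()].
#' @return list with `labels` (integer label matrix, 0 = background) and
#'   `nuclei`, a data frame per nucleus: `label`, 0-based centroid `x`,
#'   `y`, `area`, `dna_mean`. A blank (constant) image yields zero nuclei.
#' @export
segment_nuclei <- function(dna, params = pipeline_params()) {
  stopifnot(is.matrix(dna), length(dna) > 0)
  rng <- range(dna)
  empty <- list(labels = matrix(0L, nrow(dna), ncol(dna)),
                nuclei = data.frame(label = integer(0), x = numeric(0),
                                    y = numeric(0), area = integer(0),
                                    dna_mean = numeric(0)))
  if (rng[2] <= rng[1]) return(empty)
  norm <- (dna - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  # drop specks below the minimum nucleus area
  areas <- tabulate(labels[labels > 0L])
  drop <- which(areas < params$nucleus_min_area)
  if (length(drop)) {
    mask[labels %in% drop] <- FALSE
    if (!any(mask)) return(empty)
  }
  # split touching nuclei at the distance-map saddle
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  labels <- matrix(as.integer(labels), nrow(dna), ncol(dna))
  cen <- label_centroids(labels)
  cen$dna_mean <- label_means(dna, labels)
  list(labels = labels, nuclei = cen)
}

#' Gate mitotic nuclei on PHH3 intensity
#'
#' A nucleus is mitotic iff its mean PHH3 intensity exceeds the threshold
#' (strict inequality). With `phh3_threshold = "auto"` the threshold is
#' estimated as mean + 3 SD of the lower (interphase) mode of the
#' per-nucleus PHH3 means, the modes being split by 2-means; at least 10
#' nuclei are required for the estimate.
#'
#' @param nucleus_seg output of [segment_nuclei()].
#' @param phh3 PHH3 channel matrix.
#' @param params a [pipeline_params()].
#' @return the nucleus data frame with added `phh3_mean` and `is_mitotic`;
#'   the attribute `mitotic_index` holds mitotic / total nuclei.
#' @export
classify_mitotic <- function(nucleus_seg, phh3, params = pipeline_params()) {
  nuc <- nucleus_seg$nuclei
  nuc$phh3_mean <- label_means(phh3, nucleus_seg$labels)
  thr <- params$phh3_threshold
  if (identical(thr, "auto")) {
    if (nrow(nuc) < 10L)
      stopf("auto PHH3 threshold needs >= 10 nuclei (have %d)", nrow(nuc))
    thr <- auto_bimodal_threshold(nuc$phh3_mean)
  }
  nuc$is_mitotic <- nuc$phh3_mean > thr
  attr(nuc, "phh3_threshold") <- thr
  attr(nuc, "mitotic_index") <-
    if (nrow(nuc) > 0) mean(nuc$is_mitotic) else NA_real_
  nuc
}

# mean + 3 SD of the lower of two 2-means modes; collapses to a
# conservative high threshold when the values are unimodal.
auto_bimodal_threshold <- function(v) {
  if (diff(range(v)) == 0) return(v[1] + abs(v[1]) + 1)  # nothing above
  km <- kmeans(v, centers = matrix(range(v), 2, 1))
  lower <- v[km$cluster == which.min(km$centers)]
  s <- if (length(lower) > 1L) sd(lower) else 0
  mean(lower) + 3 * s
}

#' Segment mitotic cytoplasm from the RFP channel
#'
#' Grows one cytoplasm mask per mitotic nucleus over RFP-positive pixels
#' (Otsu threshold on RFP) by geodesic Voronoi propagation from the nucleus
#' seeds; masks are disjoint by construction. Cells whose mask meets the
#' image border are flagged `touches_edge`; a nucleus with no surrounding
#' RFP signal keeps its nucleus mask and is flagged `rfp_weak`.
#'
#' @param rfp RFP channel matrix.
#' @param nucleus_seg output of [segment_nuclei()].
#' @param nuclei nucleus data frame from [classify_mitotic()] (needs
#'   `is_mitotic`).
#' @return list with `labels` (cytoplasm label matrix; labels match the
#'   `label` column) and `cells`, one row per mitotic nucleus: `label`,
#'   centroid, `cyto_area`, `touches_edge`, `rfp_weak`.
#' @export
segment_mitotic_cells <- function(rfp, nucleus_seg, nuclei) {
  mit <- nuclei[nuclei$is_mitotic, , drop = FALSE]
  out_empty <- list(labels = matrix(0L, nrow(rfp), ncol(rfp)),
                    cells = data.frame(label = integer(0), x = numeric(0),
                                       y = numeric(0), cyto_area = integer(0),
                                       touches_edge = logical(0),
                                       rfp_weak = logical(0)))
  if (nrow(mit) == 0L) return(out_empty)
  seeds <- nucleus_seg$labels
  seeds[!seeds %in% mit$label] <- 0L
  rng <- range(rfp)
  rfp_mask <- if (rng[2] > rng[1]) {
    norm <- (rfp - rng[1]) / (rng[2] - rng[1])
    norm > EBImage::otsu(EBImage::Image(norm))
  } else matrix(FALSE, nrow(rfp), ncol(rfp))
  mask <- rfp_mask | seeds > 0L
  cyto <- EBImage::propagate(rfp, seeds, mask = mask)
  cyto <- matrix(as.integer(cyto), nrow(rfp), ncol(rfp))
  cells <- mit[, c("label", "x", "y")]
  border <- rbind(cbind(seq_len(nrow(rfp)), 1L),
                  cbind(seq_len(nrow(rfp)), ncol(rfp)),
                  cbind(1L, seq_len(ncol(rfp))),
                  cbind(nrow(rfp), seq_len(ncol(rfp))))
  border_labs <- unique(cyto[border])
  cells$cyto_area <- vapply(cells$label, function(l) sum(cyto == l),
                            integer(1))
  seed_area <- vapply(cells$label, function(l) sum(seeds == l), integer(1))
  cells$touches_edge <- cells$label %in% border_labs
  cells$rfp_weak <- cells$cyto_area <= seed_area
  rownames(cells) <- NULL
  list(labels = cyto, cells = cells)
}

#' Count nuclei per interphase cell and flag multinucleates
#'
#' Mitotic nuclei are excluded first; interphase cell bodies are then
#' segmented from the RFP channel (Otsu threshold, connected components)
#' and every body containing at least one interphase nucleus and no mitotic
#' nucleus is scored by the number of interphase nuclei it contains. Bodies
#' touching the image border are excluded from the denominator, mirroring
#' the edge rule for mitotic cells.
#'
#' @param rfp RFP channel matrix.
#' @param nucleus_seg output of [segment_nuclei()].
#' @param nuclei nucleus data frame from [classify_mitotic()].
#' @return data frame, one row per scored interphase cell body: `body`,
#'   centroid `x`, `y`, `n_nuclei`, `is_multinucleate` (`n_nuclei >= 2`),
#'   `touches_edge`. The attribute `pct_multinucleate` summarizes non-edge
#'   bodies.
#' @export
detect_multinucleate <- function(rfp, nucleus_seg, nuclei) {
  int_nuc <- nuclei[!nuclei$is_mitotic, , drop = FALSE]
  empty <- data.frame(body = integer(0), x = numeric(0), y = numeric(0),
                      n_nuclei = integer(0), is_multinucleate = logical(0),
                      touches_edge = logical(0))
  if (nrow(int_nuc) == 0L) {
    attr(empty, "pct_multinucleate") <- NA_real_
    return(empty)
  }
  rng <- range(rfp)
  if (rng[2] <= rng[1]) {
    attr(empty, "pct_multinucleate") <- NA_real_
    return(empty)
  }
  norm <- (rfp - rng[1]) / (rng[2] - rng[1])
  mask <- norm > EBImage::otsu(EBImage::Image(norm))
  bodies <- EBImage::bwlabel(mask)
  bodies <- matrix(as.integer(bodies), nrow(rfp), ncol(rfp))
  # body label under each nucleus centroid (centroids are 0-based)
  nuc_body <- bodies[cbind(clamp(round(nuclei$x) + 1L, 1L, nrow(rfp)),
                           clamp(round(nuclei$y) + 1L, 1L, ncol(rfp)))]
  mit_bodies <- unique(nuc_body[nuclei$is_mitotic & nuc_body > 0L])
  int_body <- nuc_body[!nuclei$is_mitotic]
  keep <- int_body > 0L & !int_body %in% mit_bodies
  if (!any(keep)) {
    attr(empty, "pct_multinucleate") <- NA_real_
    return(empty)
  }
  counts <- table(int_body[keep])
  cen <- label_centroids(bodies)
  border_labs <- unique(c(bodies[1, ], bodies[nrow(bodies), ],
                          bodies[, 1], bodies[, ncol(bodies)]))
  out <- data.frame(body = as.integer(names(counts)),
                    n_nuclei = as.integer(counts))
  out$x <- cen$x[match(out$body, cen$label)]
  out$y <- cen$y[match(out$body, cen$label)]
  out$is_multinucleate <- out$n_nuclei >= 2L
  out$touches_edge <- out$body %in% border_labs
  out <- out[, c("body", "x", "y", "n_nuclei", "is_multinucleate",
                 "touches_edge")]
  scored <- out[!out$touches_edge, , drop = FALSE]
  attr(out, "pct_multinucleate") <-
    if (nrow(scored) > 0) 100 * mean(scored$is_multinucleate) else NA_real_
  out
}

#' Measure a spindle marker's intensity in mitotic cells
#'
#' Identifies mitotic nuclei by a DNA-intensity threshold (condensed
#' mitotic chromatin is brighter than interphase nuclei), segments the
#' spindle by thresholding the marker channel, and measures the marker
#' within the spindle region nearest each mitotic nucleus.
#'
#' @param marker spindle-marker channel matrix (e.g. an HSET immunostain).
#' @param dna DNA channel matrix.
#' @param params a [pipeline_params()]; `dna_threshold` gates mitotic
#'   nuclei (`"auto"` splits per-nucleus DNA means by 2-means and takes the
#'   upper mode's lower edge), `spindle_search_radius` limits how far from
#'   the nucleus a marker region may sit.
#' @return data frame per mitotic nucleus: `label`, centroid, `mean_marker`
#'   and `integrated_marker` over the matched spindle region (both `NA`
#'   when no marker signal above threshold lies within reach — missing,
#'   not zero).
#' @export
measure_spindle_intensity <- function(marker, dna,
                                      params = pipeline_params()) {
  seg <- segment_nuclei(dna, params)
  nuc <- seg$nuclei
  if (nrow(nuc) == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      mean_marker = numeric(0),
                      integrated_marker = numeric(0)))
  thr <- params$dna_threshold
  if (identical(thr, "auto")) {
    km <- kmeans(nuc$dna_mean, centers = matrix(range(nuc$dna_mean), 2, 1))
    hi <- which.max(km$centers)
    thr <- min(nuc$dna_mean[km$cluster == hi]) - 1e-9
  }
  mit <- nuc[nuc$dna_mean > thr, , drop = FALSE]
  rng <- range(marker)
  spots <- if (rng[2] > rng[1]) {
    norm <- (marker - rng[1]) / (rng[2] - rng[1])
    m <- norm > EBImage::otsu(EBImage::Image(norm))
    matrix(as.integer(EBImage::bwlabel(m)), nrow(marker), ncol(marker))
  } else matrix(0L, nrow(marker), ncol(marker))
  cen <- label_centroids(spots)
  out <- mit[, c("label", "x", "y")]
  out$mean_marker <- NA_real_
  out$integrated_marker <- NA_real_
  if (nrow(cen) > 0L) for (i in seq_len(nrow(out))) {
    d <- sqrt((cen$x - out$x[i])^2 + (cen$y - out$y[i])^2)
    near <- cen$label[d <= params$spindle_search_radius]
    if (length(near)) {
      px <- marker[spots %in% near]
      out$mean_marker[i] <- mean(px)
      out$integrated_marker[i] <- sum(px)
    }
  }
  rownames(out) <- NULL
  out
}
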