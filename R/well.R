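#' Run the full per-cell analysis on one field
#'
#' Composes the per-field stages: nucleus segmentation, PHH3 mitotic
#' gating, RFP cytoplasm segmentation of mitotic cells, quality-control
#' filters, spindle-pole detection with multipolar classification, and
#' multinucleate scoring of interphase cells.
#'
#' @param field a `field_image` from [simulate_field()] /
#'   [read_field_tiff()], or a named list of channel matrices (`dna`,
#'   `phh3`, `rfp`, `tubulin`).
#' @param params a [pipeline_params()].
#' @param field_id identifier recorded in the output rows.
#' @return list of class `field_analysis`:
#'   \describe{
#'     \item{nuclei}{per-nucleus records with `phh3_mean`, `is_mitotic`.}
#'     \item{mitotic}{per-mitotic-cell records: QC columns, `n_poles`,
#'       `is_multipolar` (poles are only counted for QC-passed cells;
#'       excluded cells carry `NA`).}
#'     \item{interphase}{per-interphase-body records with `n_nuclei`,
#'       `is_multinucleate`.}
#'     \item{poles}{accepted poles of every kept mitotic cell.}
#'   }
#' @export
analyze_field <- function(field, params = pipeline_params(),
                          field_id = 1L) {
  ch <- if (inherits(field, "field_image")) field$channels else field
  stopifnot(all(c("dna", "phh3", "rfp", "tubulin") %in% names(ch)))
  seg <- segment_nuclei(ch$dna, params)
  nuclei <- classify_mitotic(seg, ch$phh3, params)
  cyt <- segment_mitotic_cells(ch$rfp, seg, nuclei)
  mit <- qc_filter(cyt$cells, cyt$labels, ch$tubulin, params)
  mit$n_poles <- NA_integer_
  mit$is_multipolar <- NA
  poles <- list()
  for (i in seq_len(nrow(mit))) {
    if (mit$exclusion_reason[i] != "none") next
    pol <- detect_spindle_poles(ch$tubulin, cyt$labels == mit$label[i],
                                params)
    mit$n_poles[i] <- nrow(pol)
    if (nrow(pol)) poles[[length(poles) + 1L]] <-
      cbind(cell_label = mit$label[i], pol)
  }
  kept <- !is.na(mit$n_poles)
  mit$is_multipolar[kept] <- classify_multipolar(mit$n_poles[kept], params)
  interphase <- detect_multinucleate(ch$rfp, seg, nuclei)
  add_id <- function(d) if (nrow(d)) cbind(field = field_id, d) else
    cbind(d[0, , drop = FALSE], field = integer(0))[, c("field",
                                                        names(d)), drop = FALSE]
  structure(list(
    nuclei = add_id(nuclei),
    mitotic = add_id(mit),
    interphase = add_id(interphase),
    poles = if (length(poles)) add_id(do.call(rbind, poles)) else NULL,
    phh3_threshold = attr(nuclei, "phh3_threshold")),
    class = "field_analysis")
}

#' Summarize one well's cell records into the five screen features
#'
#' @param analyses a single `field_analysis` or a list of them (all fields
#'   of one well).
#' @param well,gene,background,replicate metadata carried into the row.
#' @return one-row data frame (a WellSummary): `n_cells` (total segmented
#'   nuclei), `mitotic_index` (mitotic / total nuclei), `pct_multipolar`
#'   (percent of QC-passed mitotic cells with > 2 poles), `mean_poles`
#'   (mean pole count over QC-passed mitotic cells), `pct_multinucleate`
#'   (percent of scored interphase bodies with >= 2 nuclei). With zero kept
#'   mitotic cells the two mitotic features are `NA` (missing, not zero);
#'   excluded cells never enter them.
#' @examples
#' f <- simulate_field(random_field_config(6, 3, seed = 1))
#' summarize_well(analyze_field(f), well = "A01")
#' @export
summarize_well <- function(analyses, well = NA_character_,
                           gene = NA_character_,
                           background = NA_character_,
                           replicate = NA_integer_) {
  if (inherits(analyses, "field_analysis")) analyses <- list(analyses)
  nuclei <- do.call(rbind, lapply(analyses, `[[`, "nuclei"))
  mit <- do.call(rbind, lapply(analyses, `[[`, "mitotic"))
  inter <- do.call(rbind, lapply(analyses, `[[`, "interphase"))
  n_cells <- if (is.null(nuclei)) 0L else nrow(nuclei)
  n_mit_nuc <- if (is.null(nuclei)) 0L else sum(nuclei$is_mitotic)
  kept <- if (is.null(mit) || nrow(mit) == 0L)
    mit[0, , drop = FALSE] else mit[mit$exclusion_reason == "none", ,
                                    drop = FALSE]
  n_kept <- if (is.null(kept)) 0L else nrow(kept)
  scored_int <- if (is.null(inter) || nrow(inter) == 0L) NULL else
    inter[!inter$touches_edge, , drop = FALSE]
  data.frame(
    well = well, gene = gene, background = background,
    replicate = replicate,
    n_cells = n_cells,
    mitotic_index = if (n_cells > 0) n_mit_nuc / n_cells else NA_real_,
    pct_multipolar = if (n_kept > 0) 100 * mean(kept$is_multipolar)
                     else NA_real_,
    mean_poles = if (n_kept > 0) mean(kept$n_poles) else NA_real_,
    pct_multinucleate = if (!is.null(scored_int) && nrow(scored_int) > 0)
      100 * mean(scored_int$is_multinucleate) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-cell pole-count accuracy against simulator ground truth
#'
#' Matches every simulated mitotic cell to the nearest analysed mitotic
#' record of the same field (within the cell radius) and scores exact
#' pole-count agreement. Cells that were lost, excluded by QC, or received
#' a different count all count as disagreements, so this is a conservative
#' whole-pipeline recovery rate.
#'
#' @param analyses list of `field_analysis` objects (one per field).
#' @param truth pooled per-cell truth with a `field` column (as returned in
#'   `truth` by [simulate_and_analyze_well()]).
#' @return list with `accuracy` (fraction of simulated mitotic cells whose
#'   detected pole count equals the truth), `n_mitotic`, and `matched`
#'   (a data frame pairing true and detected counts).
#' @export
pole_count_accuracy <- function(analyses, truth) {
  mt <- truth[truth$kind == "mitotic", , drop = FALSE]
  rows <- vector("list", nrow(mt))
  for (i in seq_len(nrow(mt))) {
    fa <- analyses[[mt$field[i]]]
    det <- fa$mitotic
    found <- NA_integer_
    if (!is.null(det) && nrow(det)) {
      d <- sqrt((det$x - mt$x[i])^2 + (det$y - mt$y[i])^2)
      j <- which.min(d)
      if (d[j] <= mt$cell_radius[i]) found <- det$n_poles[j]
    }
    rows[[i]] <- data.frame(field = mt$field[i], true_poles = mt$n_poles[i],
                            detected_poles = found)
  }
  matched <- do.call(rbind, rows)
  acc <- if (nrow(mt) > 0)
    mean(!is.na(matched$detected_poles) &
           matched$detected_poles == matched$true_poles) else NA_real_
  list(accuracy = acc, n_mitotic = nrow(mt), matched = matched)
}

#' Simulate and analyse one well's worth of fields
#'
#' Convenience wrapper used for benchmarking the image pipeline against
#' ground truth: simulates `n_fields` random fields under one condition,
#' runs [analyze_field()] on each, and returns the well summary together
#' with the pooled ground truth and per-field analyses.
#'
#' @param n_fields number of fields.
#' @param n_interphase,n_mitotic cells per field.
#' @param penetrance true multipolar penetrance.
#' @param params a [pipeline_params()].
#' @param seed RNG seed (fields get consecutive derived seeds).
#' @param ... further arguments to [random_field_config()].
#' @return list with `summary` (the WellSummary row), `truth` (pooled
#'   per-cell truth), `truth_summary` (five features recomputed from
#'   truth), and `analyses`.
#' @export
simulate_and_analyze_well <- function(n_fields = 5L, n_interphase = 10L,
                                      n_mitotic = 4L, penetrance = 0.2,
                                      params = pipeline_params(),
                                      seed = NULL, ...) {
  seeds <- with_seed(seed, sample.int(2^31 - 1, n_fields))
  analyses <- vector("list", n_fields)
  truths <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    fld <- simulate_field(random_field_config(
      n_interphase = n_interphase, n_mitotic = n_mitotic,
      penetrance = penetrance, seed = seeds[f], ...))
    analyses[[f]] <- analyze_field(fld, params, field_id = f)
    truths[[f]] <- cbind(field = f, fld$truth)
  }
  truth <- do.call(rbind, truths)
  list(summary = summarize_well(analyses),
       truth = truth,
       truth_summary = truth_features(truth),
       analyses = analyses)
}
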