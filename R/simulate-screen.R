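#' Per-gene, per-background phenotype effect model
#'
#' Builds the table of true per-gene effects driving
#' [simulate_screen_tables()]. Defaults emulate the screen's biology: in the
#' unsensitized `NS` background few cells are mitotic (index ~0.03, giving
#' roughly 36 mitotic cells from ~1200 cells per well) and multipolar
#' spindles are rare (penetrance 0.05); in the sensitizing `chTOG`
#' background cells arrest in mitosis (index 0.30, ~270 mitotic cells from
#' ~900 cells) and ~40 percent of spindles are multipolar. `well_noise_sd`
#' is an additive Gaussian perturbation of the per-well penetrance (on the
#' 0-1 fraction scale) emulating reagent and handling variability.
#'
#' @param layout a `plate_layout` (or a character vector of genes); every
#'   non-empty gene gets one row per background.
#' @param ns,chtog named lists overriding the per-background defaults
#'   (`multipolar_penetrance`, `mean_pole_count`, `mitotic_fraction`,
#'   `multinucleate_fraction`, `cell_count_mean`, `well_noise_sd`).
#' @return a data frame of class `gene_effect_model`, one row per
#'   gene-background pair.
#' @seealso [set_gene_effect()] to designate enhancers or suppressors.
#' @export
gene_effect_model <- function(layout, ns = list(), chtog = list()) {
  genes <- if (is.data.frame(layout))
    unique(layout$gene[!is.na(layout$gene)]) else unique(as.character(layout))
  defaults <- list(
    NS = list(multipolar_penetrance = 0.05, mean_pole_count = 3.5,
              mitotic_fraction = 0.03, multinucleate_fraction = 0.05,
              cell_count_mean = 1200, well_noise_sd = 0.02),
    chTOG = list(multipolar_penetrance = 0.40, mean_pole_count = 3.5,
                 mitotic_fraction = 0.30, multinucleate_fraction = 0.08,
                 cell_count_mean = 900, well_noise_sd = 0.02))
  defaults$NS[names(ns)] <- ns
  defaults$chTOG[names(chtog)] <- chtog
  out <- do.call(rbind, lapply(names(defaults), function(bg) {
    d <- defaults[[bg]]
    check_effect_values(d)
    data.frame(gene = genes, background = bg,
               multipolar_penetrance = d$multipolar_penetrance,
               mean_pole_count = d$mean_pole_count,
               mitotic_fraction = d$mitotic_fraction,
               multinucleate_fraction = d$multinucleate_fraction,
               cell_count_mean = d$cell_count_mean,
               well_noise_sd = d$well_noise_sd, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("gene_effect_model", "data.frame"))
}

check_effect_values <- function(d) {
  if (d$multipolar_penetrance < 0 || d$multipolar_penetrance > 1 ||
      d$mitotic_fraction < 0 || d$mitotic_fraction > 1 ||
      d$multinucleate_fraction < 0 || d$multinucleate_fraction > 1)
    stopf("fractions must lie in [0, 1]")
  if (d$mean_pole_count < 3)
    stopf("mean_pole_count must be >= 3 (multipolar means more than 2 poles)")
  if (d$cell_count_mean <= 0) stopf("cell_count_mean must be > 0")
  if (d$well_noise_sd < 0) stopf("well_noise_sd must be >= 0")
}

#' Designate gene effects in an effect model
#'
#' Overrides effect-model fields for selected genes in one background,
#' e.g. to plant enhancers (raised penetrance) or suppressors (lowered
#' penetrance) with known identity.
#'
#' @param model a [gene_effect_model()].
#' @param genes genes to modify.
#' @param background `"NS"` or `"chTOG"`.
#' @param ... named fields to set (e.g. `multipolar_penetrance = 0.55`).
#' @return the modified model.
#' @export
set_gene_effect <- function(model, genes, background, ...) {
  vals <- list(...)
  idx <- model$gene %in% genes & model$background == background
  if (sum(idx) != length(unique(genes)))
    stopf("model has no row for gene(s): %s in background %s",
          paste(setdiff(genes, model$gene[model$background == background]),
                collapse = ", "), background)
  for (nm in names(vals)) {
    if (!nm %in% names(model)) stopf("unknown effect field: %s", nm)
    model[idx, nm] <- vals[[nm]]
  }
  for (i in which(idx)) check_effect_values(as.list(model[i, ]))
  model
}

#' Simulate well-level screen tables with known ground truth
#'
#' Tabular stand-in for a full imaging screen: for every non-empty well of
#' the layout it draws a cell count from Poisson(`cell_count_mean`), splits
#' cells into mitotic and interphase by Binomial(`mitotic_fraction`), draws
#' multipolar mitotic cells by Binomial of the per-well penetrance, pole
#' counts of multipolar cells as `3 + Poisson(mean_pole_count - 3)` (bipolar
#' cells have exactly 2), and multinucleate interphase cells by
#' Binomial(`multinucleate_fraction`). The per-well penetrance is the
#' gene-background penetrance plus a per-plate batch shift
#' (`Normal(0, plate_effect_sd)`, shared by every well of a plate — the
#' staining/imaging batch structure of a real screen) plus per-well noise
#' (`Normal(0, well_noise_sd)`), truncated to `[0, 1]`.
#'
#' Emitted well features are computed exactly from the drawn counts, so
#' recomputing them from per-cell truth rows (`per_cell = TRUE`) reproduces
#' them identically.
#'
#' @param layout a `plate_layout`.
#' @param model a [gene_effect_model()] covering every non-empty layout gene.
#' @param cells_per_well fallback mean cell count used where the model has
#'   no `cell_count_mean` column.
#' @param seed RNG seed; identical seeds give byte-identical tables.
#' @param plate_effect_sd SD of the per-plate additive penetrance shift.
#' @param per_cell also emit one truth row per simulated cell (memory-heavy
#'   for full-size screens; intended for small verification runs).
#' @return list with `wells` (WellSummary rows: layout columns plus the five
#'   features), `truth` (per-well true penetrance and counts) and, when
#'   requested, `cells` (per-cell truth rows).
#' @examples
#' lay <- make_layout(paste0("G", 1:8), n_controls = 4)
#' mod <- gene_effect_model(lay)
#' sim <- simulate_screen_tables(lay, mod, seed = 1)
#' head(sim$wells)
#' @export
simulate_screen_tables <- function(layout, model, cells_per_well = NULL,
                                   seed = NULL, plate_effect_sd = 0.035,
                                   per_cell = FALSE) {
  validate_layout(layout)
  live <- layout[layout$role != "empty", , drop = FALSE]
  key_m <- paste(model$gene, model$background)
  key_w <- paste(live$gene, live$background)
  miss <- setdiff(unique(key_w), key_m)
  if (length(miss))
    stopf("effect model is missing gene/background pairs: %s",
          paste(miss, collapse = "; "))
  mrow <- match(key_w, key_m)
  if (!"cell_count_mean" %in% names(model)) {
    if (is.null(cells_per_well))
      stopf("model lacks cell_count_mean and no cells_per_well given")
    model$cell_count_mean <- cells_per_well
  }
  plates <- unique(live[, c("background", "replicate")])
  with_seed(seed, {
    plate_shift <- rnorm(nrow(plates), 0, plate_effect_sd)
    names(plate_shift) <- paste(plates$background, plates$replicate)
    n_w <- nrow(live)
    wells <- live
    tf <- matrix(NA_real_, n_w, 5,
                 dimnames = list(NULL, WELL_FEATURES))
    truth <- cbind(live,
                   data.frame(true_penetrance = NA_real_, n_mitotic = 0L,
                              n_interphase = 0L, n_multipolar = 0L,
                              n_multinucleate = 0L, sum_poles = 0L))
    cell_rows <- if (per_cell) vector("list", n_w) else NULL
    for (i in seq_len(n_w)) {
      m <- model[mrow[i], ]
      shift <- plate_shift[paste(live$background[i], live$replicate[i])]
      p <- clamp(m$multipolar_penetrance + shift +
                   rnorm(1, 0, m$well_noise_sd), 0, 1)
      n <- rpois(1, m$cell_count_mean)
      n_mit <- rbinom(1, n, m$mitotic_fraction)
      n_int <- n - n_mit
      k <- rbinom(1, n_mit, p)
      poles <- if (k > 0) 3L + rpois(k, m$mean_pole_count - 3) else integer(0)
      mn <- rbinom(1, n_int, m$multinucleate_fraction)
      tf[i, ] <- c(
        n,
        if (n > 0) n_mit / n else NA_real_,
        if (n_mit > 0) 100 * k / n_mit else NA_real_,
        if (n_mit > 0) (2 * (n_mit - k) + sum(poles)) / n_mit else NA_real_,
        if (n_int > 0) 100 * mn / n_int else NA_real_)
      truth$true_penetrance[i] <- p
      truth$n_mitotic[i] <- n_mit
      truth$n_interphase[i] <- n_int
      truth$n_multipolar[i] <- k
      truth$n_multinucleate[i] <- mn
      truth$sum_poles[i] <- sum(poles) + 2L * (n_mit - k)
      if (per_cell && n > 0) {
        kind <- rep(c("mitotic", "interphase"), c(n_mit, n_int))
        np <- c(poles, rep(2L, n_mit - k), rep(NA_integer_, n_int))
        nn <- c(rep(1L, n_mit), rep(2L, mn), rep(1L, n_int - mn))
        cell_rows[[i]] <- data.frame(
          well = live$well[i], background = live$background[i],
          replicate = live$replicate[i], gene = live$gene[i],
          cell = seq_len(n), kind = kind, n_nuclei = nn, n_poles = np,
          is_multipolar = ifelse(kind == "mitotic", np > 2L, NA),
          stringsAsFactors = FALSE)
      }
    }
    wells <- cbind(wells, as.data.frame(tf))
    rownames(wells) <- rownames(truth) <- NULL
    out <- list(wells = wells, truth = truth)
    if (per_cell)
      out$cells <- do.call(rbind, cell_rows) %||%
        data.frame(well = character(0))
    out
  })
}
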