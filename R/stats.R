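# Gene-level screen statistics: replicate agreement, plate-normalized Z
# and differential-Z scores, hit calling against control-well dispersion,
# and multiplicative genetic-interaction scoring.

#' Spearman correlation between replica plates
#'
#' Rank correlation of one well feature between the two replicate plates of
#' a background, with average-rank tie handling. The p value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`; for small
#' plates a permutation p value is available.
#'
#' @param plate_a,plate_b well-summary data frames sharing the same
#'   well-to-gene map (matched on `well`).
#' @param feature feature column to correlate.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutation null.
#' @return list of class `correlation_result`: `feature`, `rho`, `p`, `n`,
#'   `method`.
#' @export
replicate_correlation <- function(plate_a, plate_b, feature,
                                  method = c("t", "permutation"),
                                  n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(feature %in% names(plate_a), feature %in% names(plate_b))
  common <- intersect(plate_a$well, plate_b$well)
  a <- plate_a[match(common, plate_a$well), ]
  b <- plate_b[match(common, plate_b$well), ]
  if ("gene" %in% names(a) && "gene" %in% names(b) &&
      !identical(as.character(a$gene), as.character(b$gene)))
    stopf("plates disagree on the well-to-gene map")
  x <- a[[feature]]; y <- b[[feature]]
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need >= 3 paired wells (have %d)", n)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  p <- if (is.na(rho)) NA_real_   # a constant plate has no rank order
  else if (method == "t") {
    if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
  } else with_seed(seed, {
    null <- replicate(n_perm, cor(x, sample(y), method = "spearman"))
    (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
  })
  structure(list(feature = feature, rho = rho, p = p, n = n,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (%s): rho = %.3f, p = %.3g, n = %d\n",
              x$feature, x$rho, x$p, x$n))
  invisible(x)
}

#' Plate-normalized Z and differential-Z scores per gene
#'
#' Per plate (one background-replicate combination) and per feature, well
#' values are standardized as `Z = (x - mu) / sigma` with `mu`, `sigma`
#' taken over that plate's library sample wells (or median/MAD with
#' `robust = TRUE`). Final per-gene Z scores average the replicate Z
#' values; the differential Z is `dZ = Z_NS - Z_chTOG`.
#'
#' @param wells well-summary data frame (columns `well`, `background`,
#'   `replicate`, `gene` and the feature columns).
#' @param layout a `plate_layout`; supplies well roles. If `wells` already
#'   carries a `role` column the layout may be omitted.
#' @param features feature columns to score.
#' @param robust use median/MAD instead of mean/SD for the plate reference.
#' @return data frame of class `gene_scores`: `gene`, `feature`, `z_ns`,
#'   `z_chtog`, `dz`. Genes missing a feature value in any contributing
#'   well are dropped from that feature with a warning.
#' @export
compute_zscores <- function(wells, layout = NULL,
                            features = WELL_FEATURES, robust = FALSE) {
  wells <- join_roles(wells, layout)
  smp <- wells[wells$role == "sample", , drop = FALSE]
  if (nrow(smp) == 0L) stopf("no sample wells to normalize")
  smp$plate <- paste(smp$background, smp$replicate, sep = "_")
  for (f in features) {
    zs <- rep(NA_real_, nrow(smp))
    for (pl in unique(smp$plate)) {
      i <- smp$plate == pl
      v <- smp[[f]][i]
      mu <- if (robust) median(v, na.rm = TRUE) else mean(v, na.rm = TRUE)
      sig <- if (robust) mad(v, na.rm = TRUE) else sd(v, na.rm = TRUE)
      if (!is.finite(sig) || sig == 0)
        stopf("feature '%s' is degenerate (zero spread) on plate %s", f, pl)
      zs[i] <- (v - mu) / sig
    }
    smp[[paste0("z_", f)]] <- zs
  }
  out <- list()
  for (f in features) {
    zcol <- paste0("z_", f)
    bad <- is.na(smp[[zcol]])
    drop_genes <- unique(smp$gene[bad])
    if (length(drop_genes))
      warnf("feature '%s': dropping gene(s) with missing values: %s", f,
            paste(drop_genes, collapse = ", "))
    ok <- smp[!smp$gene %in% drop_genes, , drop = FALSE]
    ag <- stats::aggregate(ok[[zcol]],
                           by = list(gene = ok$gene,
                                     background = ok$background), FUN = mean)
    wide <- merge(ag[ag$background == "NS", c("gene", "x")],
                  ag[ag$background == "chTOG", c("gene", "x")],
                  by = "gene", suffixes = c("_ns", "_chtog"))
    if (nrow(wide) == 0L) next
    out[[f]] <- data.frame(gene = wide$gene, feature = f,
                           z_ns = wide$x_ns, z_chtog = wide$x_chtog,
                           dz = wide$x_ns - wide$x_chtog,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("gene_scores", "data.frame"))
}

join_roles <- function(wells, layout) {
  if (!"role" %in% names(wells)) {
    if (is.null(layout)) stopf("need a layout (or a role column in wells)")
    key_w <- paste(wells$well, wells$background, wells$replicate)
    key_l <- paste(layout$well, layout$background, layout$replicate)
    wells$role <- layout$role[match(key_w, key_l)]
    if (anyNA(wells$role))
      stopf("layout does not cover all wells (first missing: %s)",
            wells$well[which(is.na(wells$role))[1]])
  }
  wells
}

#' Call suppressor and enhancer hits against control-well dispersion
#'
#' Per gene and background, the percentage of multipolar mitotic cells is
#' averaged across replicates and compared with the non-targeting control
#' wells of the same background: a gene is an `enhancer` when its mean lies
#' strictly above `mu_ctrl + k * sd_ctrl`, a `suppressor` strictly below
#' `mu_ctrl - k * sd_ctrl`, otherwise `none`. Hit calling operates on the
#' raw feature (not Z scores).
#'
#' @param wells well-summary data frame.
#' @param layout a `plate_layout` (optional if `wells` has roles).
#' @param k SD multiplier (default 1.5).
#' @param feature feature to call hits on.
#' @return data frame of class `hit_calls`: `gene`, `background`,
#'   `mean_value`, `class`; attributes `control_mean` and `control_sd`
#'   (named by background) record the thresholds' ingredients.
#' @export
call_hits <- function(wells, layout = NULL, k = 1.5,
                      feature = "pct_multipolar") {
  wells <- join_roles(wells, layout)
  out <- list()
  ctrl_mu <- ctrl_sd <- c()
  for (bg in unique(wells$background)) {
    wb <- wells[wells$background == bg, , drop = FALSE]
    ctrl <- wb[wb$role == "control", , drop = FALSE]
    if (nrow(ctrl) < 2L)
      stopf("background %s: need >= 2 control wells (have %d)", bg,
            nrow(ctrl))
    mu <- mean(ctrl[[feature]], na.rm = TRUE)
    sig <- sd(ctrl[[feature]], na.rm = TRUE)
    ctrl_mu[bg] <- mu; ctrl_sd[bg] <- sig
    smp <- wb[wb$role == "sample", , drop = FALSE]
    ag <- stats::aggregate(smp[[feature]], by = list(gene = smp$gene),
                           FUN = function(v) mean(v, na.rm = TRUE))
    cls <- rep("none", nrow(ag))
    cls[which(ag$x > mu + k * sig)] <- "enhancer"
    cls[which(ag$x < mu - k * sig)] <- "suppressor"
    out[[bg]] <- data.frame(gene = ag$gene, background = bg,
                            mean_value = ag$x, class = cls,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("hit_calls", "data.frame"),
            control_mean = ctrl_mu, control_sd = ctrl_sd, k = k,
            feature = feature)
}

#' Summarize hit counts into per-background hit rates
#'
#' `pct_hits = 100 * (n_suppressors + n_enhancers) / library_size`,
#' reported to one decimal place — the screen's headline summary (e.g. 8
#' enhancers of 240 genes is a 3.3 percent hit rate).
#'
#' @param hits either a `hit_calls` data frame (summarized per background)
#'   or a numeric vector/list with elements `n_suppressors` and
#'   `n_enhancers`.
#' @param library_size number of genes screened.
#' @return data frame with `background` (where known), `n_suppressors`,
#'   `n_enhancers`, `pct_hits`.
#' @examples
#' summarize_hits(c(n_suppressors = 0, n_enhancers = 8), 240)   # 3.3
#' summarize_hits(c(n_suppressors = 13, n_enhancers = 15), 240) # 11.7
#' @export
summarize_hits <- function(hits, library_size) {
  if (library_size <= 0) stopf("library_size must be > 0")
  if (is.data.frame(hits)) {
    out <- do.call(rbind, lapply(unique(hits$background), function(bg) {
      h <- hits[hits$background == bg, ]
      data.frame(background = bg,
                 n_suppressors = sum(h$class == "suppressor"),
                 n_enhancers = sum(h$class == "enhancer"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    hits <- as.list(hits)
    out <- data.frame(background = NA_character_,
                      n_suppressors = as.numeric(hits$n_suppressors),
                      n_enhancers = as.numeric(hits$n_enhancers))
  }
  out$pct_hits <- round(100 * (out$n_suppressors + out$n_enhancers) /
                          library_size, 1)
  out
}

#' Percentage summary of a count proportion
#'
#' `100 * numerator / denominator`, rounded to `digits` decimals (default
#' whole percent, matching manual live-imaging summaries such as 11 of 25
#' cells = 44 percent).
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @param digits decimals in the reported percentage.
#' @return numeric percentage.
#' @examples
#' proportion(11, 25)  # 44
#' @export
proportion <- function(numerator, denominator, digits = 0) {
  if (length(denominator) != 1L || denominator <= 0)
    stopf("denominator must be a single positive count")
  round(100 * numerator / denominator, digits)
}

#' Multiplicative genetic-interaction score
#'
#' Normalizes each phenotype to the reference condition
#' (`w_X = p_X / p_ref`, so the unperturbed control is 1), forms the
#' multiplicative expectation for the double perturbation
#' `expected = w_A * w_B`, and scores the deviation
#' `epsilon = w_AB - expected`. Under the default `"severity"` convention
#' (severity = percentage of multipolar spindles) a double phenotype less
#' severe than expected (`epsilon < -threshold`) is an alleviating
#' interaction and one more severe (`epsilon > threshold`) aggravating;
#' `"rescue"` flips the labels for phenotypes where larger values mean
#' rescue. The score is invariant to rescaling all four phenotypes by a
#' common factor.
#'
#' @param p_ref reference (e.g. control-treated) phenotype, in percent;
#'   must be positive.
#' @param p_a,p_b single-perturbation phenotypes, in percent.
#' @param p_ab double-perturbation phenotype, in percent.
#' @param threshold minimum `|epsilon|` to call an interaction.
#' @param convention `"severity"` or `"rescue"` (see above).
#' @return list of class `interaction_result`: `w_a`, `w_b`, `w_ab`,
#'   `expected`, `epsilon`, `classification`.
#' @examples
#' interaction_score(20, 10, 8, 2)   # epsilon = 0.1 - 0.2 = -0.1
#' @export
interaction_score <- function(p_ref, p_a, p_b, p_ab, threshold = 0.25,
                              convention = c("severity", "rescue")) {
  convention <- match.arg(convention)
  if (p_ref <= 0) stopf("reference phenotype must be > 0")
  vals <- c(p_ref = p_ref, p_a = p_a, p_b = p_b, p_ab = p_ab)
  if (any(vals < 0 | vals > 100))
    stopf("phenotypes must lie in [0, 100] (percent)")
  w_a <- p_a / p_ref; w_b <- p_b / p_ref; w_ab <- p_ab / p_ref
  expected <- w_a * w_b
  eps <- w_ab - expected
  cls <- if (abs(eps) <= threshold) "none"
         else if (eps < 0) "alleviating" else "aggravating"
  if (convention == "rescue" && cls != "none")
    cls <- if (cls == "alleviating") "aggravating" else "alleviating"
  structure(list(w_a = w_a, w_b = w_b, w_ab = w_ab, expected = expected,
                 epsilon = eps, classification = cls,
                 threshold = threshold, convention = convention),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(paste0("Multiplicative interaction: w_A = %.3f, w_B = %.3f, ",
                     "w_AB = %.3f\n  expected = %.3f, epsilon = %+.3f -> %s\n"),
              x$w_a, x$w_b, x$w_ab, x$expected, x$epsilon,
              x$classification))
  invisible(x)
}
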