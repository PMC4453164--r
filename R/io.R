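# File formats and the end-to-end runner. Images travel as multi-page
# TIFF (one page per channel, channel names in the page description);
# tables as CSV carrying the run-manifest hash in a leading comment line;
# the manifest itself as JSON.

CHANNEL_ORDER <- c("dna", "phh3", "rfp", "tubulin")
TIFF_SCALE <- 65535

#' Write a field image as a multi-page TIFF
#'
#' One 16-bit page per channel in the order dna, phh3, rfp, tubulin (or as
#' given by `channels`); the channel list is recorded in a JSON metadata
#' sidecar (`<path>.meta.json`). Intensities are stored as `value / 65535`.
#'
#' @param field a `field_image` or named list of channel matrices.
#' @param path output file.
#' @param channels channel order to write.
#' @return invisibly, `path`.
#' @export
write_field_tiff <- function(field, path, channels = CHANNEL_ORDER) {
  ch <- if (inherits(field, "field_image")) field$channels else field
  stopifnot(all(channels %in% names(ch)))
  pages <- lapply(channels, function(nm) {
    m <- t(ch[[nm]]) / TIFF_SCALE     # TIFF rows are image y
    clamp(m, 0, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(channels = channels, scale = TIFF_SCALE),
                       paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a multi-page field TIFF back into channel matrices
#'
#' @param path TIFF written by [write_field_tiff()] (or any multi-page
#'   TIFF whose page order matches `channels`).
#' @param channels channel names to assign, used when the file has no
#'   `<path>.meta.json` sidecar.
#' @return a `field_image` (with empty truth).
#' @export
read_field_tiff <- function(path, channels = CHANNEL_ORDER) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    channels <- unlist(jsonlite::read_json(meta_path)$channels)
  if (length(pages) != length(channels))
    stopf("%s has %d pages but %d channel names", path, length(pages),
          length(channels))
  ch <- lapply(pages, function(p) t(p) * TIFF_SCALE)
  names(ch) <- channels
  structure(list(channels = ch, truth = NULL, config = NULL),
            class = "field_image")
}

#' Build and write the run manifest
#'
#' The manifest records every parameter and threshold of a run (no silent
#' defaults) and is hashed (MD5 of its JSON serialization); output tables
#' carry the hash so each table can be traced to its exact configuration.
#' The manifest contains no timestamps, so identical configurations yield
#' identical manifests and byte-identical outputs.
#'
#' @param params a [pipeline_params()].
#' @param ... further named configuration entries (seeds, cuts, k, ...).
#' @param path optional path to write `manifest.json`.
#' @return list with `manifest` and its `hash`.
#' @export
run_manifest <- function(params = pipeline_params(), ..., path = NULL) {
  manifest <- list(package = "spindlescreen",
                   version = as.character(utils::packageVersion(
                     "spindlescreen")),
                   params = unclass(params), ...)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp))
  if (!is.null(path)) file.copy(tmp, path, overwrite = TRUE)
  unlink(tmp)
  list(manifest = manifest, hash = hash)
}

write_screen_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# manifest_md5: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [run_screen()]
#'
#' Skips the leading manifest-hash comment line and returns it as the
#' `manifest_md5` attribute.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_screen_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (grepl("^# manifest_md5:", first))
    attr(df, "manifest_md5") <- sub("^# manifest_md5:\\s*", "", first)
  df
}

#' Run the whole screen analysis end to end
#'
#' Composes the pipeline on either imaging data or precomputed well tables:
#' per-field segmentation and per-cell analysis (imaging mode), well
#' summaries, replicate Spearman correlations, plate-normalized Z and dZ
#' scores, hit calling, hit-rate summary, the clustering gene filter, the
#' complete-linkage tree and the similarity cut. Either mode fed the same
#' well table produces identical downstream statistics.
#'
#' @param layout a `plate_layout`.
#' @param wells precomputed well-summary table (tables mode), or `NULL`.
#' @param images imaging mode: named list mapping
#'   `"<well>_<background>_<replicate>"` to a list of `field_image`
#'   objects (or of TIFF paths).
#' @param params a [pipeline_params()].
#' @param k hit-calling SD multiplier.
#' @param cut clustering similarity cut.
#' @param metric clustering distance metric.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param out optional output directory; when given, writes `wells.csv`,
#'   `cells.csv` (imaging mode), `gene_scores.csv`, `hits.csv`,
#'   `hit_summary.csv`, `correlations.csv`, `clusters.csv`, the CDT/GTR/
#'   Newick tree files and `manifest.json`, all tables stamped with the
#'   manifest hash.
#' @return list of class `screen_result` with elements `wells`, `scores`,
#'   `hits`, `hit_summary`, `correlations`, `clusters`, `tree`,
#'   `dz_matrix`, `manifest`, and in imaging mode `cells`.
#' @export
run_screen <- function(layout, wells = NULL, images = NULL,
                       params = pipeline_params(), k = 1.5, cut = 0.7,
                       metric = "uncentred_pearson", seed = NULL,
                       out = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  validate_layout(layout)
  cells <- NULL
  if (is.null(wells)) {
    if (is.null(images)) stopf("provide either wells or images")
    res <- stage("segment", analyze_image_wells(layout, images, params))
    wells <- res$wells
    cells <- res$cells
  }
  wells <- stage("summarize", join_roles(wells, layout))
  correlations <- stage("correlate", {
    do.call(rbind, lapply(unique(wells$background), function(bg) {
      reps <- sort(unique(wells$replicate[wells$background == bg]))
      if (length(reps) < 2L) return(NULL)
      do.call(rbind, lapply(WELL_FEATURES, function(f) {
        r <- replicate_correlation(
          wells[wells$background == bg & wells$replicate == reps[1], ],
          wells[wells$background == bg & wells$replicate == reps[2], ], f)
        data.frame(background = bg, feature = f, rho = r$rho, p = r$p,
                   n = r$n, stringsAsFactors = FALSE)
      }))
    }))
  })
  scores <- stage("score", compute_zscores(wells, layout))
  hits <- stage("call_hits", call_hits(wells, layout, k = k))
  library_size <- length(unique(layout$gene[layout$role == "sample"]))
  hit_summary <- stage("summarize_hits", summarize_hits(hits, library_size))
  dzm <- stage("filter_genes", filter_genes(scores))
  tree <- stage("cluster", cluster_complete(pairwise_distance(dzm, metric)))
  clusters <- stage("cut", cut_clusters(tree, cut))
  mf <- run_manifest(params, k = k, cut = cut, metric = metric,
                     seed = seed, library_size = library_size,
                     mode = if (is.null(cells)) "tables" else "images")
  result <- structure(list(wells = wells, cells = cells,
                           correlations = correlations, scores = scores,
                           hits = hits, hit_summary = hit_summary,
                           dz_matrix = dzm, tree = tree,
                           clusters = clusters, manifest = mf),
                      class = "screen_result")
  if (!is.null(out)) stage("write", write_screen_result(result, out))
  result
}

analyze_image_wells <- function(layout, images, params) {
  keys <- paste(layout$well, layout$background, layout$replicate,
                sep = "_")
  miss <- setdiff(names(images), keys)
  if (length(miss))
    stopf("images for unknown wells: %s", paste(miss, collapse = ", "))
  rows <- list(); cell_rows <- list()
  for (nm in names(images)) {
    i <- match(nm, keys)
    flds <- images[[nm]]
    analyses <- lapply(seq_along(flds), function(f) {
      fld <- flds[[f]]
      if (is.character(fld)) fld <- read_field_tiff(fld)
      analyze_field(fld, params, field_id = f)
    })
    rows[[nm]] <- summarize_well(analyses, well = layout$well[i],
                                 gene = layout$gene[i],
                                 background = layout$background[i],
                                 replicate = layout$replicate[i])
    mit <- do.call(rbind, lapply(analyses, `[[`, "mitotic"))
    if (!is.null(mit) && nrow(mit))
      cell_rows[[nm]] <- cbind(well = layout$well[i],
                               background = layout$background[i],
                               replicate = layout$replicate[i], mit)
  }
  list(wells = do.call(rbind, rows),
       cells = if (length(cell_rows)) do.call(rbind, cell_rows) else NULL)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("<screen_result> %d wells | %d scored genes | ",
                     "%d clusters at cut %.2f\n"),
              nrow(x$wells), length(unique(x$scores$gene)),
              x$clusters$n_clusters, x$clusters$cut))
  print(x$hit_summary)
  invisible(x)
}

write_screen_result <- function(result, out) {
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stopf("cannot create output directory: %s", out)
  h <- result$manifest$hash
  jsonlite::write_json(result$manifest$manifest,
                       file.path(out, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_screen_csv(result$wells, file.path(out, "wells.csv"), h)
  if (!is.null(result$cells))
    write_screen_csv(result$cells, file.path(out, "cells.csv"), h)
  write_screen_csv(result$correlations,
                   file.path(out, "correlations.csv"), h)
  write_screen_csv(as.data.frame(result$scores),
                   file.path(out, "gene_scores.csv"), h)
  write_screen_csv(as.data.frame(result$hits),
                   file.path(out, "hits.csv"), h)
  write_screen_csv(result$hit_summary,
                   file.path(out, "hit_summary.csv"), h)
  write_screen_csv(data.frame(gene = names(result$clusters$assignments),
                              cluster = unname(result$clusters$assignments)),
                   file.path(out, "clusters.csv"), h)
  export_tree(result$tree, result$dz_matrix, out, "screen")
  invisible(out)
}
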