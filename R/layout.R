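VALID_BACKGROUNDS <- c("NS", "chTOG")
VALID_ROLES <- c("sample", "control", "positive_control", "empty")
WELL_FEATURES <- c("n_cells", "mitotic_index", "pct_multipolar",
                   "mean_poles", "pct_multinucleate")

well_id_ok <- function(w) grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", w)

validate_layout <- function(layout) {
  req <- c("well", "gene", "sirna_id", "background", "replicate", "role")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stopf("layout is missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(!well_id_ok(layout$well))
  if (length(bad))
    stopf("malformed well ids (expect A01-P24) in rows: %s",
          paste(head(bad, 10), collapse = ", "))
  bad <- which(!layout$background %in% VALID_BACKGROUNDS)
  if (length(bad))
    stopf("unknown background token in rows %s (expect NS or chTOG)",
          paste(head(bad, 10), collapse = ", "))
  bad <- which(!layout$role %in% VALID_ROLES)
  if (length(bad))
    stopf("unknown role in rows: %s", paste(head(bad, 10), collapse = ", "))
  key <- paste(layout$well, layout$background, layout$replicate)
  if (anyDuplicated(key))
    stopf("duplicated well id(s) within a plate: %s",
          paste(unique(layout$well[duplicated(key)]), collapse = ", "))
  # every sample gene should appear in both replicates of each background
  smp <- layout[layout$role == "sample", ]
  for (bg in intersect(VALID_BACKGROUNDS, smp$background)) {
    reps <- sort(unique(layout$replicate))
    if (length(reps) < 2L) next
    tab <- table(unique(smp[smp$background == bg, c("gene", "replicate")]))
    lonely <- rownames(tab)[rowSums(tab > 0) < length(reps)]
    if (length(lonely))
      warnf("background %s: gene(s) present in only one replicate: %s",
            bg, paste(lonely, collapse = ", "))
  }
  layout
}

#' Read and validate a plate-layout CSV
#'
#' The layout maps wells to genes and screen structure. Required columns:
#' `well` (A01-P24), `gene`, `sirna_id`, `background` (`NS` or `chTOG`),
#' `replicate`, `role` (`sample`, `control`, `positive_control`, `empty`).
#' Well ids must be unique within each plate (a plate is one
#' background-replicate combination). Sample genes present in only one
#' replicate trigger a validation warning naming the gene.
#'
#' @param path path to a CSV file; lines starting with `#` are skipped.
#' @return a validated data frame of class `plate_layout`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  layout <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  structure(validate_layout(layout), class = c("plate_layout", "data.frame"))
}

#' Build a duplicate two-background 384-well layout
#'
#' Generates the screen's plate design in code: each background (`NS`,
#' `chTOG`) is screened in duplicate, with every library gene in one well
#' per plate, `n_controls` non-targeting control wells, and positive-control
#' wells; remaining wells are `empty`.
#'
#' @param genes character vector of library gene symbols (<= 366 with the
#'   default control counts).
#' @param n_controls number of non-targeting control wells per plate.
#' @param positive_controls character vector of positive-control genes.
#' @param backgrounds,replicates screen structure.
#' @return a `plate_layout` data frame covering all plates.
#' @examples
#' lay <- make_layout(paste0("GENE", 1:24), n_controls = 4)
#' table(lay$role) / 4  # per plate
#' @export
make_layout <- function(genes, n_controls = 16L,
                        positive_controls = c("MCAK", "RACGAP1"),
                        backgrounds = c("NS", "chTOG"), replicates = 1:2) {
  genes <- as.character(genes)
  n <- length(genes) + n_controls + length(positive_controls)
  if (n > 384L) stopf("layout needs %d wells; a 384-well plate has 384", n)
  wells <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
  plate <- data.frame(
    well = wells[seq_len(n)],
    gene = c(genes, rep("CTRL_NT", n_controls), positive_controls),
    sirna_id = c(paste0("siOTP_", genes), sprintf("siCTRL_%02d",
                                                  seq_len(n_controls)),
                 if (length(positive_controls))
                   paste0("siOTP_", positive_controls) else character(0)),
    role = c(rep("sample", length(genes)), rep("control", n_controls),
             rep("positive_control", length(positive_controls))),
    stringsAsFactors = FALSE)
  if (n < 384L) {
    extra <- data.frame(well = wells[(n + 1L):384L], gene = NA_character_,
                        sirna_id = NA_character_, role = "empty",
                        stringsAsFactors = FALSE)
    plate <- rbind(plate, extra)
  }
  out <- do.call(rbind, lapply(backgrounds, function(bg)
    do.call(rbind, lapply(replicates, function(rp)
      cbind(plate, background = bg, replicate = rp,
            stringsAsFactors = FALSE)))))
  rownames(out) <- NULL
  out <- out[, c("well", "gene", "sirna_id", "background", "replicate",
                 "role")]
  structure(validate_layout(out), class = c("plate_layout", "data.frame"))
}
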