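#' Specify one synthetic cell
#'
#' Describes a single cell to be rendered by [simulate_field()]: an
#' interphase cell with one or more nuclei inside an RFP-filled body, or a
#' mitotic cell with condensed PHH3-positive chromatin and `n_poles` tubulin
#' pole foci.
#'
#' @param center numeric length-2, cell centre in 0-based pixel coordinates.
#' @param kind `"interphase"` or `"mitotic"`.
#' @param n_nuclei number of nuclei (interphase cells only; mitotic cells
#'   always have one condensed chromatin mass).
#' @param n_poles number of spindle-pole foci (mitotic cells only).
#' @param pole_positions optional matrix (n_poles x 2) of 0-based pole
#'   positions; defaults to poles placed evenly on a circle of radius
#'   `0.45 * cell_radius` around the centre (a bipolar cell gets two opposed
#'   poles).
#' @param pole_amplitude peak intensity of each pole focus above background.
#' @param cell_radius radius of the circular cell body in pixels.
#' @param phh3_level peak PHH3 intensity over mitotic chromatin (ignored for
#'   interphase cells).
#' @return an object of class `cell_spec`.
#' @examples
#' cell_spec(c(60, 60), "mitotic", n_poles = 3)
#' @export
cell_spec <- function(center, kind = c("interphase", "mitotic"),
                      n_nuclei = 1L, n_poles = 2L, pole_positions = NULL,
                      pole_amplitude = 3000, cell_radius = 18,
                      phh3_level = 2500) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2L, cell_radius > 0, pole_amplitude >= 0,
            phh3_level >= 0)
  if (kind == "mitotic") {
    n_nuclei <- 1L
    n_poles <- as.integer(n_poles)
    if (n_poles < 0L) stopf("n_poles must be >= 0")
    if (is.null(pole_positions)) {
      if (n_poles > 0L) {
        ang <- 2 * pi * (seq_len(n_poles) - 1L) / n_poles
        r <- 0.45 * cell_radius
        pole_positions <- cbind(center[1] + r * cos(ang),
                                center[2] + r * sin(ang))
      } else pole_positions <- matrix(numeric(0), 0, 2)
    } else {
      pole_positions <- matrix(as.numeric(pole_positions), ncol = 2)
      if (nrow(pole_positions) != n_poles)
        stopf("pole_positions must have n_poles = %d rows", n_poles)
    }
    if (n_poles > 0L) {
      d <- sqrt((pole_positions[, 1] - center[1])^2 +
                (pole_positions[, 2] - center[2])^2)
      if (any(d > cell_radius))
        stopf("pole positions must lie inside the cell radius")
    }
  } else {
    n_poles <- 0L
    n_nuclei <- as.integer(n_nuclei)
    if (n_nuclei < 1L) stopf("interphase cells need n_nuclei >= 1")
    pole_positions <- matrix(numeric(0), 0, 2)
  }
  structure(list(center = as.numeric(center), kind = kind,
                 n_nuclei = n_nuclei, n_poles = n_poles,
                 pole_positions = pole_positions,
                 pole_amplitude = pole_amplitude, cell_radius = cell_radius,
                 phh3_level = phh3_level),
            class = "cell_spec")
}

#' Configure a synthetic field
#'
#' Collects everything [simulate_field()] needs: the field geometry, the
#' cells to render, per-channel background levels, the noise model and the
#' optical blur.
#'
#' Intensities are generated on a 16-bit-like continuous scale;
#' `eight_bit = TRUE` rescales all channels by 255/65535 so that the
#' low-tubulin quality-control threshold (a mean of 30) is exercised on its
#' native 8-bit scale.
#'
#' @param field_size integer length 1 or 2, field dimensions in pixels.
#' @param cells list of [cell_spec()] objects.
#' @param background named per-channel background level (channels `dna`,
#'   `phh3`, `rfp`, `tubulin`).
#' @param noise list with `poisson_scale` (photon/intensity conversion;
#'   larger = less shot noise; 0 disables the Poisson component) and
#'   `gaussian_sd` (additive read noise SD; 0 disables).
#' @param psf_sigma Gaussian blur SD in pixels applied to every channel
#'   (a crude in-focus point-spread stand-in; 0 disables).
#' @param eight_bit logical; rescale output channels to the 0-255 range.
#' @param overlap_tol allowed fractional overlap of cell bodies: two cells
#'   whose centre distance is below `(r1 + r2) * (1 - overlap_tol)` make
#'   segmentation ground truth ill-defined and are rejected.
#' @param seed RNG seed for the noise draws (NULL = use current stream).
#' @return an object of class `field_config`.
#' @export
field_config <- function(field_size = 256L, cells = list(),
                         background = c(dna = 300, phh3 = 250, rfp = 300,
                                        tubulin = 300),
                         noise = list(poisson_scale = 0.1, gaussian_sd = 30),
                         psf_sigma = 1, eight_bit = FALSE,
                         overlap_tol = 0.1, seed = NULL) {
  field_size <- as.integer(rep(field_size, length.out = 2L))
  if (any(field_size <= 0L)) stopf("field_size must be positive")
  if (any(background < 0)) stopf("background levels must be >= 0")
  if (noise$poisson_scale < 0 || noise$gaussian_sd < 0)
    stopf("noise parameters must be >= 0")
  stopifnot(all(vapply(cells, inherits, logical(1), "cell_spec")))
  structure(list(field_size = field_size, cells = cells,
                 background = background, noise = noise,
                 psf_sigma = psf_sigma, eight_bit = eight_bit,
                 overlap_tol = overlap_tol, seed = seed),
            class = "field_config")
}

# Additive isotropic Gaussian blob at 0-based centre (cx, cy).
add_gaussian <- function(m, cx, cy, sigma, amp) {
  nx <- nrow(m); ny <- ncol(m)
  gx <- 0:(nx - 1L); gy <- 0:(ny - 1L)
  m + amp * outer(exp(-((gx - cx)^2) / (2 * sigma^2)),
                  exp(-((gy - cy)^2) / (2 * sigma^2)))
}

disc_mask <- function(nx, ny, cx, cy, r) {
  gx <- 0:(nx - 1L); gy <- 0:(ny - 1L)
  outer((gx - cx)^2, (gy - cy)^2, `+`) <= r^2
}

#' Render a synthetic multichannel field with per-cell ground truth
#'
#' Renders the four screen channels from a [field_config()]:
#' \describe{
#'   \item{dna}{Gaussian-blob nuclei; mitotic chromatin is brighter and more
#'     condensed than interphase nuclei.}
#'   \item{phh3}{high only over mitotic chromatin.}
#'   \item{rfp}{filled circular cell bodies.}
#'   \item{tubulin}{isotropic Gaussian foci at the pole positions on a
#'     diffuse low-amplitude spindle haze; interphase cells carry a faint
#'     cytoplasmic level.}
#' }
#' Optics and noise are then applied per the config: Gaussian blur, Poisson
#' shot noise on the signal, additive Gaussian read noise.
#'
#' @param config a [field_config()].
#' @return list with class `field_image` holding `channels` (named list of
#'   `[x, y]` matrices) and `truth`, a data frame with one row per cell
#'   (`cell`, `x`, `y`, `kind`, `n_nuclei`, `n_poles`, `is_multipolar`,
#'   `cell_radius`).
#' @examples
#' fc <- field_config(96, list(cell_spec(c(48, 48), "mitotic", n_poles = 3)),
#'                    noise = list(poisson_scale = 0, gaussian_sd = 0))
#' f <- simulate_field(fc)
#' f$truth$n_poles
#' @export
simulate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  nx <- config$field_size[1]; ny <- config$field_size[2]
  cells <- config$cells
  # reject overlapping bodies: downstream segmentation truth is ill-defined
  if (length(cells) > 1L) {
    ctr <- t(vapply(cells, `[[`, numeric(2), "center"))
    rad <- vapply(cells, `[[`, numeric(1), "cell_radius")
    for (i in seq_len(length(cells) - 1L)) for (j in (i + 1L):length(cells)) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d < (rad[i] + rad[j]) * (1 - config$overlap_tol))
        stopf("cells %d and %d overlap beyond tolerance (centre distance %.1f px)",
              i, j, d)
    }
  }
  ch <- list(dna = matrix(0, nx, ny), phh3 = matrix(0, nx, ny),
             rfp = matrix(0, nx, ny), tubulin = matrix(0, nx, ny))
  dna_amp <- 2000; rfp_amp <- 1500; haze_frac <- 0.08
  pole_sigma <- 2
  truth <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    cx <- cl$center[1]; cy <- cl$center[2]; r <- cl$cell_radius
    body <- disc_mask(nx, ny, cx, cy, r)
    ch$rfp[body] <- ch$rfp[body] + rfp_amp
    if (cl$kind == "mitotic") {
      ns <- r / 4.5
      ch$dna <- add_gaussian(ch$dna, cx, cy, ns, 1.6 * dna_amp)
      ch$phh3 <- add_gaussian(ch$phh3, cx, cy, ns, cl$phh3_level)
      if (cl$n_poles > 0L) {
        pc <- colMeans(cl$pole_positions)
        ch$tubulin <- add_gaussian(ch$tubulin, pc[1], pc[2], r / 2,
                                   haze_frac * cl$pole_amplitude)
        for (p in seq_len(cl$n_poles))
          ch$tubulin <- add_gaussian(ch$tubulin, cl$pole_positions[p, 1],
                                     cl$pole_positions[p, 2], pole_sigma,
                                     cl$pole_amplitude)
      }
    } else {
      ns <- r / 3.2
      if (cl$n_nuclei == 1L) {
        ch$dna <- add_gaussian(ch$dna, cx, cy, ns, dna_amp)
      } else {
        ang0 <- 2 * pi * (i %% 7) / 7   # deterministic orientation
        ang <- ang0 + 2 * pi * (seq_len(cl$n_nuclei) - 1L) / cl$n_nuclei
        rr <- 0.45 * r
        for (k in seq_len(cl$n_nuclei))
          ch$dna <- add_gaussian(ch$dna, cx + rr * cos(ang[k]),
                                 cy + rr * sin(ang[k]), ns * 0.85, dna_amp)
      }
      ch$tubulin[body] <- ch$tubulin[body] + 0.03 * cl$pole_amplitude
    }
    truth[[i]] <- data.frame(
      cell = i, x = cx, y = cy, kind = cl$kind, n_nuclei = cl$n_nuclei,
      n_poles = if (cl$kind == "mitotic") cl$n_poles else NA_integer_,
      is_multipolar = if (cl$kind == "mitotic") cl$n_poles > 2L else NA,
      cell_radius = r, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
               kind = character(0), n_nuclei = integer(0),
               n_poles = integer(0), is_multipolar = logical(0),
               cell_radius = numeric(0))
  with_seed(config$seed, {
    for (nm in names(ch)) {
      m <- ch[[nm]] + config$background[[nm]]
      if (config$psf_sigma > 0) m <- smooth_gaussian(m, config$psf_sigma)
      s <- config$noise$poisson_scale
      if (s > 0) m <- matrix(rpois(length(m), m * s) / s, nrow(m), ncol(m))
      if (config$noise$gaussian_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, config$noise$gaussian_sd),
                        nrow(m), ncol(m))
      m <- pmax(m, 0)
      if (config$eight_bit) m <- m * (255 / 65535)
      ch[[nm]] <- m
    }
  })
  structure(list(channels = ch, truth = truth, config = config),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, channels: %s, %d cells\n",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              paste(names(x$channels), collapse = "/"), nrow(x$truth)))
  invisible(x)
}

#' Randomly populate a field configuration
#'
#' Places `n_interphase + n_mitotic` non-overlapping cells uniformly at
#' random (with an edge margin so no body touches the border), assigning
#' pole counts to mitotic cells and extra nuclei to interphase cells from
#' the given probabilities.
#'
#' @param n_interphase,n_mitotic cell counts.
#' @param penetrance probability that a mitotic cell is multipolar.
#' @param pole_count_mean mean pole count of multipolar cells (poles are
#'   drawn as `3 + Poisson(pole_count_mean - 3)`); bipolar cells have 2.
#' @param multinucleate_fraction probability an interphase cell is
#'   binucleate.
#' @param cell_radius body radius in pixels.
#' @param margin minimum distance of a cell centre from the field border;
#'   defaults to `cell_radius + 6`.
#' @param seed RNG seed for placement and phenotype draws.
#' @param ... passed to [field_config()] (e.g. `field_size`, `noise`).
#' @return a [field_config()].
#' @export
random_field_config <- function(n_interphase = 10L, n_mitotic = 4L,
                                penetrance = 0.2, pole_count_mean = 3.5,
                                multinucleate_fraction = 0.05,
                                cell_radius = 18, margin = NULL,
                                seed = NULL, ...) {
  args <- list(...)
  field_size <- as.integer(rep(args$field_size %||% 256L, length.out = 2L))
  margin <- margin %||% (cell_radius + 6)
  n <- n_interphase + n_mitotic
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    restarts <- 0L
    tries <- 0L
    while (nrow(centers) < n) {
      if ((tries <- tries + 1L) > 400L) {
        # dart throwing wedged itself; restart the whole placement
        if ((restarts <- restarts + 1L) > 100L)
          stopf("could not place %d non-overlapping cells in a %dx%d field",
                n, field_size[1], field_size[2])
        centers <- centers[0, , drop = FALSE]
        tries <- 0L
      }
      p <- c(runif(1, margin, field_size[1] - 1 - margin),
             runif(1, margin, field_size[2] - 1 - margin))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                             byrow = TRUE))^2)) >
              2.35 * cell_radius))
        centers <- rbind(centers, p)
    }
    kind <- sample(rep(c("mitotic", "interphase"),
                       c(n_mitotic, n_interphase)))
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      if (kind[i] == "mitotic") {
        np <- if (runif(1) < penetrance) 3L + rpois(1, pole_count_mean - 3)
              else 2L
        cells[[i]] <- cell_spec(centers[i, ], "mitotic", n_poles = np,
                                cell_radius = cell_radius)
      } else {
        nn <- if (runif(1) < multinucleate_fraction) 2L else 1L
        cells[[i]] <- cell_spec(centers[i, ], "interphase", n_nuclei = nn,
                                cell_radius = cell_radius)
      }
    }
    # derive a noise seed so simulate_field() is reproducible end to end
    args$seed <- args$seed %||% sample.int(2^31 - 1, 1)
    args$field_size <- NULL
    do.call(field_config,
            c(list(field_size = field_size, cells = cells), args))
  })
}

#' Recompute the five per-well screen features from per-cell truth rows
#'
#' The five features of the screen, computed exactly from ground-truth cell
#' rows (as emitted by [simulate_field()] or
#' [simulate_screen_tables()] with `per_cell = TRUE`): total cells, mitotic
#' index, percentage multipolar, mean poles per mitotic cell, percentage
#' multinucleate. Useful for conservation checks against emitted well
#' summaries.
#'
#' @param truth per-cell truth data frame with columns `kind`, `n_nuclei`,
#'   `n_poles`.
#' @param count `"nuclei"` counts every nucleus as one object (matching
#'   image-based counting, where total cell number is the number of
#'   segmented nuclei, so a binucleate cell contributes 2); `"cells"` counts
#'   cell bodies (matching the tabular simulator's draws, where mitotic +
#'   interphase cells equal the total).
#' @return one-row data frame with `n_cells`, `mitotic_index`,
#'   `pct_multipolar`, `mean_poles`, `pct_multinucleate`. Mitotic features
#'   are `NA` when the well has no mitotic cell.
#' @export
truth_features <- function(truth, count = c("nuclei", "cells")) {
  count <- match.arg(count)
  mit <- truth$kind == "mitotic"
  n_nuc <- if (count == "nuclei") sum(truth$n_nuclei[!mit]) + sum(mit)
           else nrow(truth)
  n_mit <- sum(mit)
  data.frame(
    n_cells = n_nuc,
    mitotic_index = if (n_nuc > 0) n_mit / n_nuc else NA_real_,
    pct_multipolar = if (n_mit > 0)
      100 * sum(truth$n_poles[mit] > 2L) / n_mit else NA_real_,
    mean_poles = if (n_mit > 0) mean(truth$n_poles[mit]) else NA_real_,
    pct_multinucleate = if (sum(!mit) > 0)
      100 * mean(truth$n_nuclei[!mit] >= 2L) else NA_real_
  )
}
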