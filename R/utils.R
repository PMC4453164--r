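# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Separable Gaussian smoothing with replicate (edge-clamped) padding.
# Kernel radius = ceiling(3 * sigma); sigma = 0 returns the input.
# Used by the spot detector; kept free of FFT so that a naive direct
# convolution reproduces it exactly.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) clamp(seq_len(n + 2L * r) - r, 1L, n)
  # smooth along x (rows of the [x, y] matrix)
  mx <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mx[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
  my <- out[, pad_idx(ncol(m)), drop = FALSE]
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k))
    out2 <- out2 + k[j] * my[, seq_len(ncol(m)) + (j - 1L), drop = FALSE]
  out2
}

# Mean of image values over a labelled region.
label_means <- function(img, labels) {
  idx <- labels > 0L
  if (!any(idx)) return(numeric(0))
  as.numeric(tapply(img[idx], labels[idx], mean))
}

# 0-based centroids and areas of a label matrix ([x, y] convention).
label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  lab <- labels[idx]
  xs <- (idx - 1L) %% nrow(labels)         # 0-based x
  ys <- (idx - 1L) %/% nrow(labels)        # 0-based y
  data.frame(
    label = as.integer(names(tapply(xs, lab, mean))),
    x = as.numeric(tapply(xs, lab, mean)),
    y = as.numeric(tapply(ys, lab, mean)),
    area = as.integer(tapply(xs, lab, length))
  )
}
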