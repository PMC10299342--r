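# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Expand one user seed into deterministic, well-separated substream seeds
#'
#' Streams: 1 placement, 2 phases/frequencies, 3 noise, 4 texture.
#' Values stay below 2^31 so they are valid R integer seeds.
#' @noRd
substream_seed <- function(seed, stream) {
  ((as.double(seed) %% 1000003) * 1009 + 97 * stream) %% 2147483647
}

#' Clamp numeric values into [lo, hi]
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear sampling of a matrix at fractional (row, col) coordinates
#'
#' Coordinates are 1-based; points outside the matrix are clamped to the
#' border (replicate padding).
#' @noRd
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  rows <- clamp(rows, 1, h); cols <- clamp(cols, 1, w)
  r0 <- floor(rows); c0 <- floor(cols)
  r0 <- pmin(r0, h - 1L); c0 <- pmin(c0, w - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- r0 + (c0 - 1) * h
  v00 <- img[i00];     v10 <- img[i00 + 1]
  v01 <- img[i00 + h]; v11 <- img[i00 + h + 1]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Trailing (causal) moving average of width k
#' @noRd
moving_average <- function(x, k = 3L) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  cs <- cumsum(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - k + 1L)
    out[i] <- (cs[i] - if (j > 1L) cs[j - 1L] else 0) / (i - j + 1L)
  }
  out
}

#' Round half away from zero (base round() rounds half to even)
#' @noRd
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Stop with a consistent input-error message
#' @noRd
fail_input <- function(...) stop(sprintf(...), call. = FALSE)
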