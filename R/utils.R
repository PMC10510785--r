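# Internal raster helpers shared across modules. Images are numeric matrices
# (grayscale) or height x width x 3 arrays (RGB) with values on [0, 1] as
# read/written by the png package.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_rgb <- function(image) is.array(image) && length(dim(image)) == 3L

#' Convert an image to luminance
#'
#' RGB arrays are reduced with Rec.601 weights (0.299, 0.587, 0.114);
#' grayscale matrices pass through unchanged. Alpha channels are dropped.
#'
#' @param image Numeric matrix or h x w x 3(4) array.
#' @return Numeric matrix.
#' @export
to_luminance <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is_rgb(image)) stop("image must be a matrix or an h x w x channels array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Apply a matrix-valued function to every channel of an image.
per_channel <- function(image, f) {
  if (is.matrix(image)) return(f(image))
  out <- lapply(seq_len(dim(image)[3]), function(ch) f(image[, , ch]))
  array(unlist(out, use.names = FALSE), dim = c(dim(out[[1]]), length(out)))
}

transpose_image <- function(image) per_channel(image, t)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Replicate-pad a matrix by `n` pixels on every side.
pad_replicate <- function(m, n = 1L) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, n), seq_len(h), rep(h, n)), c(rep(1L, n), seq_len(w), rep(w, n)),
    drop = FALSE]
}

# 2-D FFT convolution with an isotropic Gaussian (periodic boundary).
# sigma in pixels; sigma = 0 is the identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  fy <- fft_freq(h); fx <- fft_freq(w)
  g <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, rep(1, w))) *
    exp(-2 * pi^2 * sigma^2 * outer(rep(1, h), fx^2))
  Re(stats::fft(stats::fft(m) * g, inverse = TRUE)) / (h * w)
}

# Frequencies (cycles/pixel) of an n-point DFT, numpy-fftfreq layout.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
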