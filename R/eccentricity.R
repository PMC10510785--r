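#' Contrast-sensitivity parameters for the eccentricity filter
#'
#' The foveation filter removes, per spatial-frequency band, the local
#' image content whose band-limited contrast falls below the
#' eccentricity-dependent detection threshold
#' `CT(f, e) = CT0(f) * 10^(ecc_factor * f * e)`,
#' with `f` the band center frequency in cycles/degree and `e` the retinal
#' eccentricity in degrees. The foveal threshold `CT0(f)` is a log-parabola
#' with minimum `ct0_min` at `f_peak` cycles/degree — the standard CSF
#' shape. A single eccentricity factor (deg^-1 cpd^-1) governs the
#' threshold growth; thresholds above 1 mean nothing in that band is
#' visible at that location.
#'
#' @param K Number of octave-spaced bandpass levels.
#' @param ct0_min Minimum foveal threshold contrast (default 0.005).
#' @param f_peak Frequency of peak foveal sensitivity in cpd (default 4).
#' @param logpar_width Width parameter of the log-parabola (default 0.5).
#' @param ecc_factor Threshold growth constant k in `10^(k * f * e)`
#'   (default 0.05 deg^-1 cpd^-1).
#' @param eps Luminance floor for the contrast ratio, as a fraction of full
#'   range (default 0.01).
#' @return Object of class `csf_params`.
#' @export
csf_params <- function(K = 5L, ct0_min = 0.005, f_peak = 4, logpar_width = 0.5,
                       ecc_factor = 0.05, eps = 0.01) {
  if (K < 1) stopf("csf_params: K must be >= 1")
  if (ct0_min <= 0 || ecc_factor <= 0 || f_peak <= 0 || eps <= 0)
    stopf("csf_params: ct0_min, f_peak, ecc_factor and eps must be positive")
  structure(list(K = as.integer(K), ct0_min = ct0_min, f_peak = f_peak,
                 logpar_width = logpar_width, ecc_factor = ecc_factor,
                 eps = eps),
            class = "csf_params")
}

#' Eccentricity-dependent contrast-detection threshold
#'
#' @param f Spatial frequency in cycles/degree (scalar).
#' @param e Eccentricity in degrees (scalar, vector or matrix).
#' @param params A [csf_params()].
#' @return Threshold contrast, same shape as `e`; monotone increasing in
#'   the product `f * e`.
#' @export
eccentricity_threshold <- function(f, e, params = csf_params()) {
  if (f <= 0) stopf("eccentricity_threshold: f must be positive")
  if (any(e < 0)) stopf("eccentricity_threshold: e must be non-negative")
  ct0 <- params$ct0_min * 10^(params$logpar_width * (log10(f / params$f_peak))^2)
  ct0 * 10^(params$ecc_factor * f * e)
}

# Cosine-log radial filters: K one-octave-wide bandpass filters with
# centers at 2^-(k+1) cycles/pixel (band 1 additionally passes everything
# above its center) plus the complementary lowpass residual. The filters
# form an exact partition of unity, so the bands plus the residual
# reconstruct the input to floating point.
cosine_log_filters <- function(h, w, K) {
  if (2^(-(K + 2)) < 1 / min(h, w))
    stopf("build_pyramid: K = %d is too large for a %d x %d image", K, h, w)
  fy <- fft_freq(h); fx <- fft_freq(w)
  r <- sqrt(outer(fy^2, rep(1, w)) + outer(rep(1, h), fx^2))
  lr <- suppressWarnings(log2(r))
  lr[!is.finite(lr)] <- -1000  # DC: below every band edge, lands in the lowpass
  bands <- vector("list", K)
  for (k in seq_len(K)) {
    ctr <- -(k + 1)
    g <- 0.5 * (1 + cos(pi * (lr - ctr)))
    g[abs(lr - ctr) > 1] <- 0
    if (k == 1) g[lr >= ctr] <- 1
    bands[[k]] <- g
  }
  low <- 1 - Reduce(`+`, bands)
  low[low < 0] <- 0
  list(bands = bands, lowpass = low)
}

apply_radial_filter <- function(m, g) {
  Re(stats::fft(stats::fft(m) * g, inverse = TRUE)) / length(m)
}

#' Build a band-limited contrast pyramid
#'
#' Decomposes a luminance raster into `K` octave-spaced bandpass levels at
#' full resolution (frequency-domain cosine-log filters) plus a residual
#' lowpass. Band `k` has center frequency `ppd / 2^(k+1)` cycles/degree.
#' The levels plus the residual sum exactly back to the input.
#'
#' @param image 2-D luminance matrix.
#' @param K Number of bandpass levels.
#' @param display A [make_display()] model supplying ppd (used only to
#'   label band frequencies in cpd); when `NULL`, frequencies are reported
#'   in cycles/pixel (`ppd = 1`).
#' @return Object of class `contrast_pyramid`: `bands` (list of K
#'   matrices), `lowpass`, `K`, `f_centers_cpd`, `ppd`.
#' @export
build_pyramid <- function(image, K, display = NULL) {
  if (!is.matrix(image)) stopf("build_pyramid: image must be a 2-D luminance raster")
  if (K < 1) stopf("build_pyramid: K must be >= 1")
  flt <- cosine_log_filters(nrow(image), ncol(image), K)
  Fm <- stats::fft(image)
  inv <- function(g) Re(stats::fft(Fm * g, inverse = TRUE)) / length(image)
  ppd <- if (is.null(display)) 1 else display$ppd
  structure(list(bands = lapply(flt$bands, inv), lowpass = inv(flt$lowpass),
                 K = as.integer(K),
                 f_centers_cpd = ppd / 2^(seq_len(K) + 1), ppd = ppd),
            class = "contrast_pyramid")
}

#' Local band-limited contrast of one pyramid level
#'
#' `c_k(x) = b_k(x) / max(l_k(x), eps)`, where `l_k` is the local
#' luminance: the lowpass content below band `k` (all lower-frequency
#' bands plus the residual). Dimensionless; invariant under global
#' luminance scaling (up to the floor `eps`).
#'
#' @param pyramid A [build_pyramid()] result.
#' @param k Band index, 1 (highest frequency) to `K`.
#' @param eps Luminance floor (fraction of full range).
#' @return Contrast raster, same size as the image.
#' @export
local_band_contrast <- function(pyramid, k, eps = 0.01) {
  if (k < 1 || k > pyramid$K) stopf("local_band_contrast: k out of range")
  lk <- pyramid$lowpass
  if (k < pyramid$K)
    lk <- lk + Reduce(`+`, pyramid$bands[(k + 1):pyramid$K])
  pyramid$bands[[k]] / pmax(lk, eps)
}

#' Simulate the decline of contrast sensitivity with eccentricity
#'
#' Builds the contrast pyramid, computes each pixel's retinal eccentricity
#' from the fixation (via the display's ppd), and zeroes every bandpass
#' coefficient whose local band-limited contrast is below the band's
#' eccentricity-dependent detection threshold; the image is then
#' reconstructed from the surviving coefficients plus the untouched
#' residual lowpass. Content is eliminated, not blurred: subthreshold
#' structure is removed outright, matching detection-threshold semantics.
#' When combined with carving, the pipeline order is foveate-then-carve.
#'
#' For RGB images the keep/zero decision is made on the luminance pyramid
#' and applied to each channel's pyramid.
#'
#' @param image Grayscale matrix or RGB array, values on [0, 1].
#' @param display A [make_display()] model.
#' @param fixation Fixation `c(x, y)` in pixels, inside the frame.
#' @param params A [csf_params()].
#' @return Filtered image, same shape as the input.
#' @export
foveate <- function(image, display, fixation, params = csf_params()) {
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (fixation[[1]] < 1 || fixation[[1]] > dims[2] ||
      fixation[[2]] < 1 || fixation[[2]] > dims[1])
    stopf("foveate: fixation must lie inside the frame")
  lum <- to_luminance(image)
  pyr <- build_pyramid(lum, params$K, display)
  ecc <- sqrt(outer((seq_len(dims[1]) - fixation[[2]])^2, rep(1, dims[2])) +
              outer(rep(1, dims[1]), (seq_len(dims[2]) - fixation[[1]])^2)) /
    display$ppd
  keep <- lapply(seq_len(params$K), function(k) {
    ct <- eccentricity_threshold(pyr$f_centers_cpd[k], ecc, params)
    abs(local_band_contrast(pyr, k, params$eps)) >= ct
  })
  rebuild <- function(p) {
    kept <- Map(function(b, kp) b * kp, p$bands, keep)
    Reduce(`+`, kept) + p$lowpass
  }
  if (is.matrix(image)) return(rebuild(pyr))
  per_channel(image, function(ch) rebuild(build_pyramid(ch, params$K, display)))
}
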