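test_that("pyramid levels plus residual reconstruct the input exactly", {
  set.seed(21)
  x <- matrix(runif(128 * 128), 128, 128)
  p <- build_pyramid(x, 5)
  rec <- Reduce(`+`, p$bands) + p$lowpass
  expect_lt(max(abs(rec - x)), 1e-6)
  # constant image: all bandpass levels identically zero
  pc <- build_pyramid(matrix(0.7, 64, 64), 4)
  expect_lt(max(abs(unlist(pc$bands))), 1e-12)
  expect_error(build_pyramid(matrix(0, 16, 16), 6), "too large")
})

test_that("band center frequencies follow ppd / 2^(k+1)", {
  d <- make_display(128, 128, 8)  # ppd = 16
  p <- build_pyramid(matrix(0.5, 128, 128), 4, d)
  expect_equal(p$f_centers_cpd, 16 / 2^(2:5))
})

test_that("a pure grating concentrates its energy in its own band", {
  # grating at band-2 center frequency (2^-3 cycles/pixel)
  g <- 0.5 + 0.2 * sin(2 * pi * 0.125 * outer(rep(1, 128), 1:128))
  p <- build_pyramid(g, 4)
  en <- vapply(p$bands, function(b) sum(b^2), numeric(1))
  expect_gt(en[2] / sum(en), 0.8)
})

test_that("local band contrast is Michelson-like and luminance invariant", {
  g <- 0.5 + 0.5 * 0.3 * sin(2 * pi * 0.125 * outer(rep(1, 128), 1:128))
  p <- build_pyramid(g, 4)
  c2 <- local_band_contrast(p, 2)
  expect_equal(max(abs(c2)), 0.3, tolerance = 0.1)  # Michelson m = 0.3
  # zero band -> zero contrast
  expect_equal(max(abs(local_band_contrast(build_pyramid(matrix(0.4, 64, 64), 3), 1))), 0)
  # doubling overall luminance leaves contrast unchanged
  p2 <- build_pyramid(2 * g, 4)
  expect_equal(local_band_contrast(p2, 2), c2, tolerance = 1e-9)
})

test_that("detection thresholds grow with frequency-eccentricity product", {
  prm <- csf_params(ct0_min = 0.01, f_peak = 8, logpar_width = 0, ecc_factor = 0.05)
  # foveal identity
  expect_equal(eccentricity_threshold(8, 0, prm), 0.01)
  # stated growth law: CT0 * 10^(k f e)
  expect_equal(eccentricity_threshold(8, 10, prm), 0.01 * 10^4)
  expect_gte(eccentricity_threshold(8, 10, prm), 1)  # band fully removed there
  # monotone in eccentricity for every band
  for (f in c(1, 4, 16)) {
    e <- seq(0, 30, by = 5)
    th <- eccentricity_threshold(f, e, csf_params())
    expect_true(all(diff(th) > 0))
  }
  expect_error(eccentricity_threshold(-1, 0), "positive")
})

test_that("foveation leaves uniform and foveal high-contrast content unchanged", {
  d <- make_display(128, 128, 16)
  fix <- fixation_point(64, 64)
  expect_equal(foveate(matrix(0.5, 128, 128), d, fix), matrix(0.5, 128, 128))
  # high-contrast content within 1 deg of fixation survives
  img <- generate_fixture("random_texture", c(128, 128), seed = 4)$image
  img <- 0.5 + (img - 0.5)  # full contrast
  out <- foveate(img, d, fix, csf_params(K = 4))
  ctr <- 61:67  # within ~0.5 deg at ppd 8
  expect_equal(out[ctr, ctr], img[ctr, ctr], tolerance = 0.05)
  expect_error(foveate(img, d, fixation_point(500, 64)), "inside")
})

test_that("band retention is non-increasing across eccentricity annuli", {
  d <- make_display(128, 128, 32)  # ppd = 4
  fix <- fixation_point(64, 64)
  img <- generate_fixture("random_texture", c(128, 128), seed = 6)$image
  prm <- csf_params(K = 4, ecc_factor = 0.2)
  pyr <- build_pyramid(img, prm$K, d)
  ecc <- sqrt(outer((1:128 - 64)^2, rep(1, 128)) +
              outer(rep(1, 128), (1:128 - 64)^2)) / d$ppd
  # fraction of suprathreshold (surviving) coefficients per annulus,
  # fovea outward: must not increase with eccentricity
  edges <- c(0, 4, 8, 12, 16)
  for (k in 1:2) {
    ck <- abs(local_band_contrast(pyr, k, prm$eps))
    ct <- eccentricity_threshold(pyr$f_centers_cpd[k], ecc, prm)
    keep <- ck >= ct
    frac <- vapply(seq_len(length(edges) - 1), function(a) {
      ann <- ecc >= edges[a] & ecc < edges[a + 1]
      mean(keep[ann])
    }, numeric(1))
    expect_true(all(diff(frac) <= 0.02),
                info = sprintf("band %d retention: %s", k,
                               paste(round(frac, 3), collapse = " ")))
  }
})

test_that("foveation preserves mean luminance and commutes with luminance scaling", {
  d <- make_display(128, 128, 32)
  fix <- fixation_point(64, 64)
  img <- generate_fixture("random_texture", c(128, 128), seed = 8)$image
  prm <- csf_params(K = 4, ecc_factor = 0.15)
  out <- foveate(img, d, fix, prm)
  expect_lt(abs(mean(out) - mean(img)) / mean(img), 0.01)
  # contrast is a ratio: scaling luminance scales the output
  out2 <- foveate(0.5 * img, d, fix, prm)
  expect_equal(out2, 0.5 * out, tolerance = 1e-6)
})

test_that("thresholds forced to (near) zero give perfect reconstruction", {
  d <- make_display(128, 128, 16)
  img <- generate_fixture("random_texture", c(128, 128), seed = 14)$image
  prm <- csf_params(K = 4, ct0_min = 1e-12, ecc_factor = 1e-12)
  out <- foveate(img, d, fixation_point(64, 64), prm)
  expect_lt(max(abs(out - img)), 1e-6)
})

test_that("low-contrast high-frequency content survives near fixation but not far", {
  d <- make_display(256, 256, 64)  # ppd = 4
  fix <- fixation_point(128, 128)
  freq <- 0.125  # c/px -> 0.5 cpd... band scales from ppd
  patches <- list(
    list(center = c(136, 128), radius_px = 10, freq_cpp = freq, contrast = 0.12),
    list(center = c(208, 128), radius_px = 10, freq_cpp = freq, contrast = 0.12))
  img <- generate_fixture("grating_patchwork", c(256, 256), seed = 1,
                          patches = patches)$image
  out <- foveate(img, d, fix, csf_params(K = 4, ecc_factor = 0.3))
  dev <- abs(out - 0.5)
  near <- dev[118:138, 126:146]   # patch at ~2 deg
  far <- dev[118:138, 198:218]    # patch at ~20 deg
  expect_gt(sum(near^2), sum(far^2))
})
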