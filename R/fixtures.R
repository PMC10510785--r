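#' Deterministic synthetic test fixtures
#'
#' Generates the synthetic stimuli used throughout the test suite and the
#' demonstrations, each with machine-readable ground truth so carving
#' effects (line shortening, grid-line continuity, object occlusion by a
#' scotoma) can be measured as exact pixel counts. The same seed always
#' yields a bit-identical raster.
#'
#' Kinds and their parameters (`...`):
#' \describe{
#'   \item{line_scene}{Uniform-noise background with one dark horizontal
#'     line; `line_row`, `line_cols` (range), `line_value` (default 0).}
#'   \item{amsler_grid}{White grid on black; `pitch` (px). Grid lines at
#'     1, 1+pitch, ... plus both borders.}
#'   \item{random_texture}{Smoothed uniform noise (Gaussian `sigma`,
#'     default 1.5) rescaled to [0, 1]; generic nonzero energy everywhere.}
#'   \item{carpenter_grid}{Rectilinear "carpenter's world": dark window
#'     grid on a light facade; `pitch`, `bar`.}
#'   \item{shoulder_silhouette}{Dark head-and-shoulders silhouette on a
#'     light background; ground truth: shoulder line row and width.}
#'   \item{panorama}{Wide smoothed-noise scene with vertical landmark
#'     bars; `span_deg` (default 109), `ppd`, `height_px`.}
#'   \item{grating_patchwork}{Mid-gray field with sinusoidal grating
#'     patches; `patches` = list of lists with `center` (x, y px),
#'     `radius_px`, `freq_cpp` (cycles/pixel), `contrast`.}
#'   \item{moving_square_video}{Frame list: textured background with a
#'     dark square translating along a linear trajectory; `n_frames_video`,
#'     `square_size`, `start_xy`, `step_xy`.}
#' }
#'
#' @param kind Fixture kind (see Details).
#' @param size Length-2 `(rows, cols)` raster size.
#' @param seed Integer seed; fully determines the output.
#' @param ... Kind-specific parameters.
#' @return List with `image` (or `frames` for video kinds) and
#'   `ground_truth` (a named list).
#' @export
generate_fixture <- function(kind, size = c(64, 64), seed = 1L, ...) {
  args <- list(...)
  h <- size[1]; w <- size[2]
  with_seed(seed, switch(kind,
    line_scene = {
      row <- args$line_row %||% round(h / 2)
      cols <- args$line_cols %||% c(max(1, round(w * 0.125)), round(w * 0.85))
      val <- args$line_value %||% 0
      img <- matrix(stats::runif(h * w, 0.3, 0.7), h, w)
      img[row, cols[1]:cols[2]] <- val
      list(image = img,
           ground_truth = list(line_row = row, line_cols = cols,
                               line_value = val,
                               line_length = cols[2] - cols[1] + 1L))
    },
    amsler_grid = {
      pitch <- args$pitch %||% 20L
      img <- matrix(0, h, w)
      vls <- unique(c(seq(1L, w, by = pitch), w))
      hls <- unique(c(seq(1L, h, by = pitch), h))
      img[, vls] <- 1; img[hls, ] <- 1
      list(image = img,
           ground_truth = list(pitch = pitch, v_lines = vls, h_lines = hls,
                               n_v_lines = length(vls), n_h_lines = length(hls)))
    },
    random_texture = {
      sigma <- args$sigma %||% 1.5
      img <- gaussian_blur(matrix(stats::runif(h * w), h, w), sigma)
      img <- (img - min(img)) / (max(img) - min(img))
      list(image = img, ground_truth = list(sigma = sigma))
    },
    carpenter_grid = {
      pitch <- args$pitch %||% 12L
      bar <- args$bar %||% 3L
      img <- matrix(0.8, h, w)
      for (r in seq(1L, h, by = pitch)) img[r:min(h, r + bar - 1L), ] <- 0.15
      for (cc in seq(1L, w, by = pitch)) img[, cc:min(w, cc + bar - 1L)] <- 0.15
      list(image = img, ground_truth = list(pitch = pitch, bar = bar))
    },
    shoulder_silhouette = {
      img <- matrix(0.85, h, w)
      cx <- w / 2; head_r <- h / 8; head_cy <- h * 0.3
      shoulder_row <- round(h * 0.55)
      half_width <- round(w * 0.35)
      dd <- outer((seq_len(h) - head_cy)^2, rep(1, w)) +
        outer(rep(1, h), (seq_len(w) - cx)^2)
      img[dd <= head_r^2] <- 0.1
      for (r in shoulder_row:h) {
        hw <- min(half_width, round(half_width * (r - shoulder_row + 6) / 6))
        img[r, max(1, round(cx - hw)):min(w, round(cx + hw))] <- 0.1
      }
      list(image = img,
           ground_truth = list(shoulder_row = shoulder_row,
                               shoulder_width = 2L * half_width + 1L,
                               dark_value = 0.1))
    },
    panorama = {
      span <- args$span_deg %||% 109
      ppd <- args$ppd %||% 4
      hh <- args$height_px %||% h
      ww <- as.integer(round(span * ppd))
      img <- gaussian_blur(matrix(stats::runif(hh * ww), hh, ww), 2)
      img <- 0.25 + 0.5 * (img - min(img)) / (max(img) - min(img))
      bars <- round(seq(ww * 0.08, ww * 0.92, length.out = 12))
      for (b in bars) img[round(hh * 0.25):round(hh * 0.9),
                          max(1, b - 1):min(ww, b + 1)] <- 0.05
      list(image = img,
           ground_truth = list(span_deg = span, ppd = ppd, width_px = ww,
                               height_px = hh, bar_cols = bars))
    },
    grating_patchwork = {
      patches <- args$patches %||% list()
      img <- matrix(0.5, h, w)
      for (p in patches) {
        gx <- outer(rep(1, h), seq_len(w))
        g <- 0.5 + 0.5 * p$contrast * sin(2 * pi * p$freq_cpp * gx)
        dd <- outer((seq_len(h) - p$center[2])^2, rep(1, w)) +
          outer(rep(1, h), (seq_len(w) - p$center[1])^2)
        inside <- dd <= p$radius_px^2
        img[inside] <- g[inside]
      }
      list(image = img, ground_truth = list(patches = patches))
    },
    moving_square_video = {
      n <- args$n_frames_video %||% 10L
      sz <- args$square_size %||% 6L
      start <- args$start_xy %||% c(5, round(h / 2))
      step <- args$step_xy %||% c(3, 0)
      bg <- gaussian_blur(matrix(stats::runif(h * w, 0.35, 0.65), h, w), 1)
      frames <- vector("list", n)
      pos <- matrix(0, n, 2)
      for (i in seq_len(n)) {
        x <- round(start[1] + (i - 1) * step[1])
        y <- round(start[2] + (i - 1) * step[2])
        pos[i, ] <- c(x, y)
        fr <- bg
        rr <- max(1, y):min(h, y + sz - 1L)
        cc <- max(1, x):min(w, x + sz - 1L)
        fr[rr, cc] <- 0
        frames[[i]] <- fr
      }
      list(frames = frames,
           ground_truth = list(square_size = sz, positions = pos,
                               square_value = 0))
    },
    stopf("generate_fixture: unknown fixture kind '%s'", kind)))
}
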