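#' Fixation sequence
#'
#' An ordered set of fixation locations with a per-fixation dwell time,
#' representing an observer scanning a scene with saccades (typical dwell
#' 2 seconds per fixation in the demonstrations).
#'
#' @param points n x 2 matrix (or length-2 vector) of fixation (x, y)
#'   positions in pixels of the target (panorama) image.
#' @param dwell_s Dwell per fixation in seconds (recycled to n).
#' @return Object of class `fixation_sequence`.
#' @export
fixation_sequence <- function(points, dwell_s = 2.0) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2, byrow = TRUE)
  if (nrow(points) == 0) stopf("fixation_sequence: at least one fixation required")
  if (any(dwell_s <= 0)) stopf("fixation_sequence: dwell must be positive")
  structure(list(points = points, dwell_s = rep_len(dwell_s, nrow(points))),
            class = "fixation_sequence")
}

#' Video timing specification
#'
#' @param fps Frames per second (default 25, so the 200 ms saccadic delay
#'   and 2 s dwell are whole frame counts).
#' @param saccade_delay_ms Delay between fixation-marker shift and image
#'   switch in guided-gaze videos (default 200 ms, an average saccadic
#'   latency).
#' @param blur_ms Duration of the inserted saccadic-blur/blank transition
#'   (default 40 ms = one frame at 25 fps).
#' @param blur_mode `"blurred"` (Gaussian-blurred mean of the two frames)
#'   or `"blank"` (uniform mid-gray).
#' @param blur_sigma_px Gaussian sigma of the blurred transition frame.
#' @return Object of class `video_spec`.
#' @export
video_spec <- function(fps = 25, saccade_delay_ms = 200, blur_ms = 40,
                       blur_mode = c("blurred", "blank"), blur_sigma_px = 10) {
  blur_mode <- match.arg(blur_mode)
  if (fps <= 0) stopf("video_spec: fps must be positive")
  if (saccade_delay_ms < 0 || blur_ms < 0)
    stopf("video_spec: durations must be >= 0")
  structure(list(fps = fps, saccade_delay_ms = saccade_delay_ms,
                 blur_ms = blur_ms, blur_mode = blur_mode,
                 blur_sigma_px = blur_sigma_px),
            class = "video_spec")
}

n_frames <- function(ms, fps) as.integer(round(ms * fps / 1000))

blur_transition_frame <- function(a, b, spec) {
  if (spec$blur_mode == "blank") {
    return(per_channel(a, function(m) matrix(0.5, nrow(m), ncol(m))))
  }
  mean_img <- if (is.matrix(a)) (a + b) / 2 else (a + b) / 2
  per_channel(mean_img, function(m) gaussian_blur(m, spec$blur_sigma_px))
}

#' Abrupt-flip saccade video
#'
#' The simplest saccade representation: switch quickly between two views
#' of the scene (e.g. the same scene carved for two different fixations).
#' Optionally a saccadic-suppression transition — a blurred or blank frame
#' lasting `blur_ms` — is inserted at every switch, which largely masks
#' the apparent motion of the periscotomatous distortions.
#'
#' @param frameA,frameB Same-shape images.
#' @param spec A [video_spec()].
#' @param with_blur Insert transition frames at each switch.
#' @param dwell_s Duration of each segment in seconds.
#' @param n_cycles Number of A,B pairs (default 2: A,B,A,B).
#' @return List: `frames` (list of images) and `meta` (frame accounting).
#' @export
make_flip_video <- function(frameA, frameB, spec = video_spec(),
                            with_blur = FALSE, dwell_s = 2, n_cycles = 2) {
  da <- if (is.matrix(frameA)) dim(frameA) else dim(frameA)
  db <- if (is.matrix(frameB)) dim(frameB) else dim(frameB)
  if (!identical(da, db)) stopf("make_flip_video: frames must have the same shape")
  dwell_f <- n_frames(dwell_s * 1000, spec$fps)
  blur_f <- if (with_blur) n_frames(spec$blur_ms, spec$fps) else 0L
  segs <- rep(list(frameA, frameB), n_cycles)
  frames <- list()
  for (i in seq_along(segs)) {
    if (i > 1 && blur_f > 0)
      frames <- c(frames, rep(list(blur_transition_frame(segs[[i - 1]], segs[[i]], spec)),
                              blur_f))
    frames <- c(frames, rep(list(segs[[i]]), dwell_f))
  }
  list(frames = frames,
       meta = list(segments = length(segs), dwell_frames = dwell_f,
                   blur_frames_per_switch = blur_f,
                   switches = length(segs) - 1L,
                   total_frames = length(segs) * dwell_f +
                     (length(segs) - 1L) * blur_f))
}

# Draw a fixation marker (black cross with white border) into an image.
draw_fixation_marker <- function(image, fix, half = 6L) {
  stamp <- function(m, r, cset, v) {
    r <- r[r >= 1 & r <= nrow(m)]; cset <- cset[cset >= 1 & cset <= ncol(m)]
    m[r, cset] <- v
    m
  }
  x <- round(fix[[1]]); y <- round(fix[[2]])
  per_channel(image, function(m) {
    m <- stamp(m, (y - 1):(y + 1), (x - half):(x + half), 1)
    m <- stamp(m, (y - half):(y + half), (x - 1):(x + 1), 1)
    m <- stamp(m, y, (x - half):(x + half), 0)
    stamp(m, (y - half):(y + half), x, 0)
  })
}

#' Guided-gaze saccade video
#'
#' Approximates a gaze-contingent display: the fixation marker jumps from
#' `fixA` to `fixB`, and the scene switches from `frameA` to `frameB`
#' `saccade_delay_ms` later (an average saccadic latency), optionally with
#' saccadic-blur transition frames at the switch. An observer following
#' the marker saccades as the image switches, so the switch transient is
#' masked by their own saccade.
#'
#' @param frameA,frameB Same-shape images.
#' @param fixA,fixB Fixation marker positions `c(x, y)` in pixels.
#' @param spec A [video_spec()].
#' @param dwell_s Pre- and post-switch dwell in seconds.
#' @param with_blur Insert blur frames at the scene switch.
#' @param markers Draw fixation markers (`FALSE` gives bare frames).
#' @return List: `frames` plus `meta` with `marker_shift_frame` and
#'   `switch_frame` (1-based indices).
#' @export
make_guided_gaze <- function(frameA, fixA, frameB, fixB, spec = video_spec(),
                             dwell_s = 2, with_blur = FALSE, markers = TRUE) {
  dwell_f <- n_frames(dwell_s * 1000, spec$fps)
  delay_f <- n_frames(spec$saccade_delay_ms, spec$fps)
  blur_f <- if (with_blur) n_frames(spec$blur_ms, spec$fps) else 0L
  deco <- function(fr, fx) if (markers) draw_fixation_marker(fr, fx) else fr
  frames <- rep(list(deco(frameA, fixA)), dwell_f)           # steady fixation on A
  t0 <- length(frames) + 1L                                  # marker shifts here
  frames <- c(frames, rep(list(deco(frameA, fixB)), delay_f))  # marker moved, scene old
  if (blur_f > 0)
    frames <- c(frames, rep(list(blur_transition_frame(frameA, frameB, spec)), blur_f))
  switch_frame <- length(frames) + 1L
  frames <- c(frames, rep(list(deco(frameB, fixB)), dwell_f))
  list(frames = frames,
       meta = list(marker_shift_frame = t0, switch_frame = switch_frame,
                   delay_frames = delay_f, blur_frames = blur_f,
                   total_frames = length(frames)))
}

#' Flipbook of carved fixations across a panorama
#'
#' Simulates saccadic scanning of a scene wider than the display: for each
#' fixation in the sequence, the panorama is (optionally) foveated and
#' carved with the scotomas positioned relative to that fixation, then
#' cropped to the display span (45 degrees wide by default) with the
#' fixation at the center, and held for the dwell duration. No blur frames
#' are inserted between fixations: the whole retinal image updates at each
#' saccade, which itself masks the transition.
#'
#' @param panorama Image wider than the display crop.
#' @param fixations A [fixation_sequence()] in panorama pixel coordinates.
#' @param display A [make_display()] model; the crop is
#'   `round(span_deg * ppd)` pixels wide and `height_px` tall.
#' @param specs List of `scotoma_spec`s (may be empty).
#' @param ecc_params Optional [csf_params()]; when supplied each view is
#'   foveated before carving.
#' @param spec A [video_spec()].
#' @param policy A [carve_policy()].
#' @param markers Draw the central fixation marker in each frame.
#' @return List: `frames`, and `meta` with `crop_width_px`,
#'   `frames_per_fixation`, `total_frames`, and per-fixation seam counts.
#' @export
make_flipbook <- function(panorama, fixations, display, specs = list(),
                          ecc_params = NULL, spec = video_spec(),
                          policy = carve_policy(), markers = FALSE) {
  dims <- if (is.matrix(panorama)) dim(panorama) else dim(panorama)[1:2]
  cw <- as.integer(round(display$span_deg * display$ppd))
  chh <- min(display$height_px, dims[1])
  dwell_f <- vapply(fixations$dwell_s, function(d) n_frames(d * 1000, spec$fps),
                    integer(1))
  frames <- list(); seam_counts <- integer(nrow(fixations$points))
  for (i in seq_len(nrow(fixations$points))) {
    fix <- fixations$points[i, ]
    half <- cw %/% 2L
    if (fix[1] - half < 1 || fix[1] - half + cw - 1L > dims[2])
      stopf("make_flipbook: crop window for fixation %d (x = %g) exceeds the panorama",
            i, fix[1])
    view <- panorama
    if (!is.null(ecc_params)) view <- foveate(view, display, fix, ecc_params)
    res <- carve_scotoma(view, specs, display, fix, policy)
    seam_counts[i] <- length(res$seams)
    fx <- res$fixation[["x"]]; fy <- res$fixation[["y"]]
    carved <- res$image
    cdims <- if (is.matrix(carved)) dim(carved) else dim(carved)[1:2]
    if (cdims[1] < chh) {
      # horizontal seams shrank the view below the crop height; restore it
      # with edge-replicated rows so every frame shares one size
      pad_top <- (chh - cdims[1]) %/% 2L
      ridx <- c(rep(1L, pad_top), seq_len(cdims[1]),
                rep(cdims[1], chh - cdims[1] - pad_top))
      carved <- per_channel(carved, function(m) m[ridx, , drop = FALSE])
      fy <- fy + pad_top
      cdims[1] <- chh
    }
    c0 <- round(fx) - half
    if (c0 < 1 || c0 + cw - 1L > cdims[2])
      stopf("make_flipbook: post-carve crop for fixation %d exceeds the carved image", i)
    r0 <- max(1L, min(round(fy) - chh %/% 2L, cdims[1] - chh + 1L))
    fr <- per_channel(carved, function(m)
      m[r0:(r0 + chh - 1L), c0:(c0 + cw - 1L), drop = FALSE])
    if (markers)
      fr <- draw_fixation_marker(fr, c(round(fx) - c0 + 1L, round(fy) - r0 + 1L))
    frames <- c(frames, rep(list(fr), dwell_f[i]))
  }
  list(frames = frames,
       meta = list(crop_width_px = cw, crop_height_px = chh,
                   frames_per_fixation = dwell_f, seam_counts = seam_counts,
                   total_frames = sum(dwell_f)))
}

# Embed an image into an H x W frame with edge-replicated padding.
embed_frame <- function(image, H, W, align = c("center", "left")) {
  align <- match.arg(align)
  per_channel(image, function(m) {
    h <- nrow(m); w <- ncol(m)
    if (h > H || w > W) stopf("embed_frame: image larger than target frame")
    r0 <- if (align == "center") (H - h) %/% 2L else 0L
    c0 <- if (align == "center") (W - w) %/% 2L else 0L
    ridx <- c(rep(1L, r0), seq_len(h), rep(h, H - h - r0))
    cidx <- c(rep(1L, c0), seq_len(w), rep(w, W - w - c0))
    m[ridx, cidx, drop = FALSE]
  })
}

#' Per-frame scotoma carving of a video with a fixation track
#'
#' Each frame is independently (optionally) foveated and carved with the
#' scotomas placed relative to that frame's fixation, then center-embedded
#' into the original frame size with edge-replicated padding so all output
#' frames share one size. This reproduces the optic-flow situation: static
#' objects sweeping peripherally disappear into and reemerge out of the
#' scotomas as the scene flows past.
#'
#' @param frames List of same-size images.
#' @param fixation_track n x 2 matrix of (x, y) fixations, one per frame.
#' @param specs List of `scotoma_spec`s.
#' @param display A [make_display()] model.
#' @param policy A [carve_policy()].
#' @param ecc_params Optional [csf_params()] for pre-carve foveation.
#' @return List of carved, embedded frames (same size as the input).
#' @export
carve_video <- function(frames, fixation_track, specs, display,
                        policy = carve_policy(), ecc_params = NULL) {
  if (!is.matrix(fixation_track)) fixation_track <- matrix(fixation_track, ncol = 2)
  if (nrow(fixation_track) != length(frames))
    stopf("carve_video: fixation track length %d != frame count %d",
          nrow(fixation_track), length(frames))
  dims <- if (is.matrix(frames[[1]])) dim(frames[[1]]) else dim(frames[[1]])[1:2]
  lapply(seq_along(frames), function(i) {
    fix <- fixation_track[i, ]
    fr <- frames[[i]]
    if (!is.null(ecc_params)) fr <- foveate(fr, display, fix, ecc_params)
    res <- carve_scotoma(fr, specs, display, fix, policy)
    embed_frame(res$image, dims[1], dims[2], align = "center")
  })
}
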