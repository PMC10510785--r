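#' Display model: pixel / visual-degree geometry
#'
#' A display model fixes the angular calibration of the simulation: how many
#' pixels subtend one degree of visual angle for an observer fixating the
#' screen. The default mapping is linear (constant pixels-per-degree,
#' `ppd = width_px / span_deg`), appropriate for the moderate spans used in
#' the demonstrations; a tangent (flat-screen) mapping is available in
#' [deg_to_px()] and [rasterize_scotoma()] via `mapping = "tangent"`.
#'
#' @param width_px,height_px Display size in pixels (positive integers).
#' @param span_deg Horizontal angular span of the display in degrees.
#' @return An object of class `display_model` with fields `width_px`,
#'   `height_px`, `span_deg` and the derived `ppd` (pixels per degree).
#' @examples
#' d <- make_display(1920, 1080, 45)
#' d$ppd  # 42.67 px/deg
#' @export
make_display <- function(width_px, height_px, span_deg) {
  if (width_px <= 0 || height_px <= 0 || span_deg <= 0)
    stopf("make_display: width_px, height_px and span_deg must all be positive")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         span_deg = span_deg, ppd = width_px / span_deg),
    class = "display_model")
}

#' @export
print.display_model <- function(x, ...) {
  cat(sprintf("<display_model> %d x %d px, %.4g deg span, %.4g px/deg\n",
              x$width_px, x$height_px, x$span_deg, x$ppd))
  invisible(x)
}

#' Fixation point in pixel coordinates
#'
#' Pixel coordinates are 1-based with the origin at the top-left pixel
#' center; `x` increases rightward (image columns) and `y` downward (image
#' rows), so positive `y` offsets in degrees lie in the inferior visual
#' field.
#'
#' @param x_px,y_px Pixel coordinates of fixation.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
fixation_point <- function(x_px, y_px) c(x = as.numeric(x_px), y = as.numeric(y_px))

#' Convert visual-degree offsets to pixel coordinates
#'
#' @param display A [make_display()] model.
#' @param fixation Fixation point (`c(x, y)` in pixels).
#' @param point_deg Length-2 vector or n x 2 matrix of (x, y) offsets from
#'   fixation in degrees; positive y is downward (inferior field).
#' @param mapping `"linear"` (constant ppd, default) or `"tangent"`
#'   (flat-screen: `px = f * tan(theta)` with focal length `f = ppd * 180/pi`,
#'   matching the linear mapping at small angles).
#' @param round Round the result to the nearest pixel (default `TRUE`).
#' @return Pixel coordinates in the same shape as `point_deg`. The result
#'   may fall outside the frame; callers clip.
#' @export
deg_to_px <- function(display, fixation, point_deg,
                      mapping = c("linear", "tangent"), round = TRUE) {
  mapping <- match.arg(mapping)
  pd <- if (is.matrix(point_deg)) point_deg else matrix(point_deg, ncol = 2)
  off <- switch(mapping,
    linear  = pd * display$ppd,
    tangent = tan(pd * pi / 180) * display$ppd * 180 / pi)
  out <- cbind(x = fixation[[1]] + off[, 1], y = fixation[[2]] + off[, 2])
  if (round) out <- round(out)
  if (is.matrix(point_deg)) out else stats::setNames(as.numeric(out), c("x", "y"))
}

#' Convert pixel coordinates to visual-degree offsets from fixation
#'
#' Inverse of [deg_to_px()] (before rounding).
#' @inheritParams deg_to_px
#' @param point_px Length-2 vector or n x 2 matrix of pixel coordinates.
#' @return Degree offsets, positive y downward.
#' @export
px_to_deg <- function(display, fixation, point_px,
                      mapping = c("linear", "tangent")) {
  mapping <- match.arg(mapping)
  pp <- if (is.matrix(point_px)) point_px else matrix(point_px, ncol = 2)
  off <- cbind(pp[, 1] - fixation[[1]], pp[, 2] - fixation[[2]])
  out <- switch(mapping,
    linear  = off / display$ppd,
    tangent = atan(off / (display$ppd * 180 / pi)) * 180 / pi)
  colnames(out) <- c("x", "y")
  if (is.matrix(point_px)) out else stats::setNames(as.numeric(out), c("x", "y"))
}

#' Parametric scotoma specifications
#'
#' Scotomas are defined in visual degrees relative to the current fixation,
#' so the same specification travels with the eye across fixations. Shapes:
#' a circular disc (e.g. a 6 deg central disciform scotoma), an axis-aligned
#' or rotated ellipse (e.g. a 5 x 8 deg paracentral scotoma), an arcuate
#' annulus sector (the glaucomatous arcuate defect), or an explicit binary
#' mask raster loaded from an 8-bit PNG (nonzero = scotoma).
#'
#' Angles for the arcuate shape are measured from the positive x axis
#' (rightward), increasing clockwise in image coordinates, i.e. 90 degrees
#' points down into the inferior field.
#'
#' @param diameter_deg Circle diameter in degrees.
#' @param center_deg Length-2 (x, y) offset of the shape center from
#'   fixation, in degrees (positive y = inferior).
#' @param label Free-text label used in logs and error messages.
#' @return An object of class `scotoma_spec`.
#' @export
scotoma_circle <- function(diameter_deg, center_deg = c(0, 0), label = "circle") {
  if (diameter_deg <= 0) stopf("scotoma_circle: diameter_deg must be positive")
  new_scotoma_spec("circle", center_deg, label, diameter_deg = diameter_deg)
}

#' @rdname scotoma_circle
#' @param width_deg,height_deg Ellipse axis lengths in degrees.
#' @param rotation_deg Clockwise rotation of the ellipse in degrees.
#' @export
scotoma_ellipse <- function(width_deg, height_deg, rotation_deg = 0,
                            center_deg = c(0, 0), label = "ellipse") {
  if (width_deg <= 0 || height_deg <= 0)
    stopf("scotoma_ellipse: width_deg and height_deg must be positive")
  new_scotoma_spec("ellipse", center_deg, label, width_deg = width_deg,
                   height_deg = height_deg, rotation_deg = rotation_deg)
}

#' @rdname scotoma_circle
#' @param mean_radius_deg Mean radius (eccentricity of the arc midline) in
#'   degrees.
#' @param angular_start_deg,angular_extent_deg Start angle and angular
#'   extent of the sector in degrees; extent must lie in (0, 360].
#' @param thickness_deg Radial thickness of the annulus in degrees.
#' @export
scotoma_arcuate <- function(mean_radius_deg, angular_start_deg,
                            angular_extent_deg, thickness_deg,
                            center_deg = c(0, 0), label = "arcuate") {
  if (mean_radius_deg <= 0 || thickness_deg <= 0)
    stopf("scotoma_arcuate: mean_radius_deg and thickness_deg must be positive")
  if (angular_extent_deg <= 0 || angular_extent_deg > 360)
    stopf("scotoma_arcuate: angular_extent_deg must lie in (0, 360]")
  new_scotoma_spec("arcuate", center_deg, label,
                   mean_radius_deg = mean_radius_deg,
                   angular_start_deg = angular_start_deg,
                   angular_extent_deg = angular_extent_deg,
                   thickness_deg = thickness_deg)
}

#' @rdname scotoma_circle
#' @param path Path to an 8-bit single-channel PNG mask whose size must
#'   equal the target image exactly (masks are never resampled).
#' @export
scotoma_maskfile <- function(path, label = "maskfile") {
  new_scotoma_spec("maskfile", c(0, 0), label, path = path)
}

new_scotoma_spec <- function(shape, center_deg, label, ...) {
  structure(list(shape = shape, center_deg = as.numeric(center_deg),
                 label = label, ...),
            class = "scotoma_spec")
}

#' @export
print.scotoma_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("shape", "center_deg", "label"))]
  cat(sprintf("<scotoma_spec> %s '%s' at (%.3g, %.3g) deg; %s\n",
              x$shape, x$label, x$center_deg[1], x$center_deg[2],
              paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Rasterize a scotoma specification into a boolean mask
#'
#' A pixel belongs to the mask when its center falls inside the analytic
#' boundary of the shape, with pixel centers at integer coordinates and
#' degree coordinates obtained from the display mapping relative to the
#' given fixation. Mask files are loaded as nonzero = scotoma and must
#' match `image_shape` exactly.
#'
#' @inheritParams deg_to_px
#' @param spec A `scotoma_spec`.
#' @param image_shape Length-2 integer `(rows, cols)` of the target image.
#' @return Logical matrix of dimension `image_shape` with class
#'   `scotoma_mask`; attribute `empty` flags a shape that fell entirely
#'   outside the frame (also raised as a warning).
#' @export
rasterize_scotoma <- function(spec, display, fixation, image_shape,
                              mapping = c("linear", "tangent")) {
  mapping <- match.arg(mapping)
  if (!inherits(spec, "scotoma_spec")) stopf("spec must be a scotoma_spec")
  rows <- image_shape[1]; cols <- image_shape[2]

  if (spec$shape == "maskfile") {
    raw <- png::readPNG(spec$path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    if (!all(dim(raw) == c(rows, cols)))
      stopf("mask file '%s' is %d x %d but the image is %d x %d (masks are never resampled)",
            spec$path, nrow(raw), ncol(raw), rows, cols)
    m <- raw > 0
  } else {
    # degree coordinates of every pixel center relative to fixation
    xd <- px_to_deg(display, fixation, cbind(seq_len(cols), fixation[[2]]),
                    mapping = mapping)[, 1]
    yd <- px_to_deg(display, fixation, cbind(fixation[[1]], seq_len(rows)),
                    mapping = mapping)[, 2]
    dx <- outer(rep(1, rows), xd) - spec$center_deg[1]
    dy <- outer(yd, rep(1, cols)) - spec$center_deg[2]
    m <- switch(spec$shape,
      circle = dx^2 + dy^2 <= (spec$diameter_deg / 2)^2,
      ellipse = {
        th <- spec$rotation_deg * pi / 180
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        (u / (spec$width_deg / 2))^2 + (v / (spec$height_deg / 2))^2 <= 1
      },
      arcuate = {
        r <- sqrt(dx^2 + dy^2)
        ang <- (atan2(dy, dx) * 180 / pi) %% 360
        rel <- (ang - spec$angular_start_deg) %% 360
        abs(r - spec$mean_radius_deg) <= spec$thickness_deg / 2 &
          rel <= spec$angular_extent_deg
      },
      stopf("unknown scotoma shape '%s'", spec$shape))
  }
  empty <- !any(m)
  if (empty)
    warning(sprintf("scotoma '%s' rasterized to an empty mask (fully outside the frame)",
                    spec$label), call. = FALSE)
  structure(m, class = c("scotoma_mask", class(m)),
            spec = spec, fixation = fixation, empty = empty)
}

# Centroid (x, y) in pixels of a logical/0-1 mask.
mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}
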