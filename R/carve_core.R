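#' Prewitt gradient-magnitude energy
#'
#' The per-pixel saliency used by the seam carver: the Euclidean magnitude
#' `sqrt(Gx^2 + Gy^2)` of the 3 x 3 Prewitt horizontal and vertical
#' responses (unnormalized kernels with unit weights). RGB inputs are first
#' reduced to Rec.601 luminance; image borders are handled by edge
#' replication, so a constant image has zero energy everywhere.
#'
#' @param image Grayscale matrix or RGB array (any numeric scale).
#' @return Numeric matrix of gradient magnitudes, same size as the image.
#' @export
prewitt_energy <- function(image) {
  m <- to_luminance(image)
  if (!is.matrix(m)) stopf("prewitt_energy: input must reduce to a 2-D raster")
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, 1L)
  s <- function(dr, dc) p[seq_len(h) + 1L + dr, seq_len(w) + 1L + dc, drop = FALSE]
  gx <- (s(-1L, 1L) + s(0L, 1L) + s(1L, 1L)) - (s(-1L, -1L) + s(0L, -1L) + s(1L, -1L))
  gy <- (s(1L, -1L) + s(1L, 0L) + s(1L, 1L)) - (s(-1L, -1L) + s(-1L, 0L) + s(-1L, 1L))
  sqrt(gx^2 + gy^2)
}

#' Cumulative minimum-energy cost of monotone seams
#'
#' Dynamic program over monotone 8-connected paths: the first row of the
#' cost equals the energy's first row, and every other cell adds its energy
#' to the minimum of its (up to) three predecessors in the previous row.
#' Backpointers record the argmin column offset in \{-1, 0, +1\}, with ties
#' broken in the order -1, 0, +1. Horizontal seams are computed on the
#' transposed energy.
#'
#' @param energy Finite numeric matrix (see [prewitt_energy()]).
#' @param direction `"vertical"` (top-to-bottom seams, default) or
#'   `"horizontal"`.
#' @return List of class `cumulative_cost` with `cost` and `back` matrices
#'   (in carving orientation, i.e. transposed for horizontal) and
#'   `direction`.
#' @export
cumulative_cost <- function(energy, direction = c("vertical", "horizontal")) {
  direction <- match.arg(direction)
  if (length(energy) == 0) stopf("cumulative_cost: empty energy map")
  if (any(!is.finite(energy))) stopf("cumulative_cost: energy must be finite")
  e <- if (direction == "horizontal") t(energy) else energy
  h <- nrow(e); w <- ncol(e)
  cost <- matrix(0, h, w)
  back <- matrix(0L, h, w)
  cost[1, ] <- e[1, ]
  if (h > 1) for (i in 2:h) {
    prev <- cost[i - 1, ]
    cands <- cbind(c(Inf, prev[-w]), prev, c(prev[-1], Inf))
    pick <- max.col(-cands, ties.method = "first")
    back[i, ] <- pick - 2L
    cost[i, ] <- e[i, ] + cands[cbind(seq_len(w), pick)]
  }
  structure(list(cost = cost, back = back, direction = direction),
            class = "cumulative_cost")
}

#' Extract the minimum-energy seam
#'
#' Starts at the minimal final-row cost (ties broken toward the smallest
#' index) and follows the backpointers upward. The seam's `total_energy`
#' equals that minimal final cost.
#'
#' @param cc A [cumulative_cost()] result.
#' @return An object of class `seam`: `direction`; `positions`, one column
#'   index per row for a vertical seam (one row index per column for a
#'   horizontal one); `total_energy`.
#' @export
extract_min_seam <- function(cc) {
  cost <- cc$cost; back <- cc$back
  h <- nrow(cost)
  pos <- integer(h)
  j <- which.min(cost[h, ])
  total <- cost[h, j]
  pos[h] <- j
  if (h > 1) for (i in (h - 1):1) {
    j <- j + back[i + 1, j]
    pos[i] <- j
  }
  structure(list(direction = cc$direction, positions = pos, total_energy = total),
            class = "seam")
}

#' @export
print.seam <- function(x, ...) {
  cat(sprintf("<seam> %s, length %d, total energy %.6g\n",
              x$direction, length(x$positions), x$total_energy))
  invisible(x)
}

#' Remove a seam from an image and aligned auxiliary rasters
#'
#' For a vertical seam each row drops its seam pixel and the pixels to its
#' right shift left by one, reducing the width by exactly one; the same
#' deletion is applied to every auxiliary raster (scotoma masks, coordinate
#' maps, eccentricity maps) so they stay aligned with the image. Horizontal
#' seams are handled by transposition.
#'
#' @param image Matrix or RGB array.
#' @param seam A [extract_min_seam()] seam valid for the current shape.
#' @param aux Named list of matrices with the image's 2-D shape.
#' @return List with the carved `image` and `aux` list.
#' @export
remove_seam <- function(image, seam, aux = list()) {
  if (seam$direction == "horizontal") {
    out <- remove_seam(transpose_image(image),
                       structure(list(direction = "vertical",
                                      positions = seam$positions,
                                      total_energy = seam$total_energy),
                                 class = "seam"),
                       lapply(aux, t))
    return(list(image = transpose_image(out$image), aux = lapply(out$aux, t)))
  }
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  h <- dims[1]; w <- dims[2]
  if (length(seam$positions) != h)
    stopf("remove_seam: seam length %d does not match image height %d",
          length(seam$positions), h)
  if (any(seam$positions < 1 | seam$positions > w))
    stopf("remove_seam: seam positions out of range")
  keep <- matrix(TRUE, h, w)
  keep[cbind(seq_len(h), seam$positions)] <- FALSE
  drop_col <- function(m) {
    if (!is.matrix(m) || !all(dim(m) == c(h, w)))
      stopf("remove_seam: auxiliary raster shape does not match the image")
    matrix(t(m)[t(keep)], nrow = h, byrow = TRUE)
  }
  list(image = per_channel(image, drop_col), aux = lapply(aux, drop_col))
}
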