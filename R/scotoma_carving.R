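#' Carving policy
#'
#' Controls how the constrained carver chooses seam directions and orders
#' multiple scotomas.
#'
#' Direction rules follow the clinically motivated conventions: seams are
#' carved orthogonally to the fovea-to-scotoma axis (vertical seams for
#' lateral scotomas, horizontal for vertical ones) or along the longer mask
#' dimension (fewer seams); a scotoma containing the fixation pixel is
#' treated as central and carved with strictly alternating
#' vertical/horizontal seams, starting vertical.
#'
#' @param direction_rule One of `"orthogonal_to_fovea_axis"` (default),
#'   `"elongation"`, `"alternating"`, `"fixed_vertical"`,
#'   `"fixed_horizontal"`.
#' @param mask_energy Energy value assigned to active-mask pixels. The
#'   default `NULL` auto-computes `-(L * (Emax + P) + 1)` per carved frame,
#'   where `L` is the seam path length, `Emax` the current maximum natural
#'   energy and `P` the other-mask penalty; this guarantees every optimal
#'   seam passes through the scotoma.
#' @param multi_scotoma_order `"by_decreasing_eccentricity"` (default) or
#'   `"as_listed"`.
#' @param max_iterations Guard on the total number of seams removed.
#' @return An object of class `carve_policy`.
#' @export
carve_policy <- function(direction_rule = c("orthogonal_to_fovea_axis",
                                            "elongation", "alternating",
                                            "fixed_vertical", "fixed_horizontal"),
                         mask_energy = NULL,
                         multi_scotoma_order = c("by_decreasing_eccentricity",
                                                 "as_listed"),
                         max_iterations = 20000L) {
  direction_rule <- match.arg(direction_rule)
  multi_scotoma_order <- match.arg(multi_scotoma_order)
  if (!is.null(mask_energy) && mask_energy >= 0)
    stopf("carve_policy: mask_energy must be negative")
  if (max_iterations <= 0) stopf("carve_policy: max_iterations must be positive")
  structure(list(direction_rule = direction_rule, mask_energy = mask_energy,
                 multi_scotoma_order = multi_scotoma_order,
                 max_iterations = as.integer(max_iterations)),
            class = "carve_policy")
}

#' Seam direction for one scotoma
#'
#' A mask containing the fixation pixel is central and carved alternating.
#' Otherwise, under the fovea-axis rule, vertical seams are used when the
#' mask centroid's horizontal offset from fixation is at least its vertical
#' offset (ties go vertical); under the elongation rule seams run along the
#' longer mask dimension so that fewer seams are needed.
#'
#' @param mask Logical or 0/1 mask matrix (nonempty).
#' @param fixation Fixation `c(x, y)` in pixels of the mask's frame.
#' @param policy A [carve_policy()].
#' @return `"vertical"`, `"horizontal"` or `"alternating"`.
#' @export
direction_for_scotoma <- function(mask, fixation, policy = carve_policy()) {
  if (!any(mask > 0)) stopf("direction_for_scotoma: empty mask")
  switch(policy$direction_rule,
         fixed_vertical = return("vertical"),
         fixed_horizontal = return("horizontal"),
         alternating = return("alternating"))
  fx <- round(fixation[[1]]); fy <- round(fixation[[2]])
  if (fy >= 1 && fy <= nrow(mask) && fx >= 1 && fx <= ncol(mask) &&
      mask[fy, fx] > 0)
    return("alternating")
  if (policy$direction_rule == "orthogonal_to_fovea_axis") {
    cen <- mask_centroid(mask)
    if (abs(cen[["x"]] - fixation[[1]]) >= abs(cen[["y"]] - fixation[[2]]))
      "vertical" else "horizontal"
  } else {  # elongation
    idx <- which(mask > 0, arr.ind = TRUE)
    width_ext <- diff(range(idx[, 2])) + 1
    height_ext <- diff(range(idx[, 1])) + 1
    if (width_ext > height_ext) "horizontal" else "vertical"
  }
}

#' Force seams through the active scotoma
#'
#' Active-mask pixels are set to a large negative energy so that every
#' globally optimal seam enters the scotoma; pixels of other not-yet-carved
#' scotomas receive a positive penalty `P` exceeding any natural seam
#' energy, so one scotoma's seams never consume another's pixels. All other
#' pixels are unchanged.
#'
#' @param energy Natural energy map.
#' @param active_mask Mask being carved (logical or 0/1 matrix).
#' @param other_masks List of other scotomas' masks (may be empty).
#' @param policy A [carve_policy()]; `policy$mask_energy` overrides the
#'   auto-computed negative constant.
#' @return Modified energy map.
#' @export
apply_mask_energy <- function(energy, active_mask, other_masks = list(),
                              policy = carve_policy()) {
  act <- active_mask > 0
  if (!any(act)) return(energy)
  L <- max(dim(energy))
  emax <- max(energy, 0)
  P <- L * emax + 1
  M <- policy$mask_energy %||% (-(L * (emax + P) + 1))
  for (om in other_masks) {
    o <- om > 0
    if (any(o & act))
      stopf("apply_mask_energy: active mask overlaps another scotoma's mask")
    energy[o] <- P
  }
  energy[act] <- M
  energy
}

#' Carve out scotomas from an image
#'
#' The core constrained-carving loop. Each scotoma is rasterized relative
#' to the fixation and carved in turn (by decreasing eccentricity by
#' default): the natural Prewitt energy of the current image is computed,
#' the active mask is forced negative (other masks penalized positive), the
#' globally minimal monotone seam is extracted and removed from the image
#' together with every mask and the coordinate map, until no active-mask
#' pixel remains. The surrounding content thereby closes into apposition
#' over the scotoma and the image shrinks by the size of the scotoma.
#'
#' @param image Grayscale matrix or RGB array.
#' @param specs A `scotoma_spec`, a list of them, and/or pre-rasterized
#'   logical mask matrices of the image's shape. An empty list returns the
#'   image unchanged.
#' @param display A [make_display()] model (may be `NULL` if all specs are
#'   pre-rasterized masks).
#' @param fixation Fixation `c(x, y)` in pixels.
#' @param policy A [carve_policy()].
#' @param mapping Degree-to-pixel mapping for rasterization.
#' @return Object of class `carve_result`: `image` (carved), `seams` (list
#'   of removed seams, each with `iteration` and `scotoma` label),
#'   `coord_rows`/`coord_cols` (per-output-pixel original coordinates),
#'   `residual` (leftover combined mask, all zero on success), per-direction
#'   counts `n_vertical`/`n_horizontal`, `dim_original`, and the tracked
#'   `fixation` in carved coordinates.
#' @export
carve_scotoma <- function(image, specs, display = NULL, fixation,
                          policy = carve_policy(),
                          mapping = c("linear", "tangent")) {
  mapping <- match.arg(mapping)
  if (inherits(specs, "scotoma_spec") || is.matrix(specs)) specs <- list(specs)
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]

  masks <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (inherits(s, "scotoma_spec")) {
      if (is.null(display)) stopf("carve_scotoma: display required to rasterize spec %d", i)
      m <- rasterize_scotoma(s, display, fixation, dims, mapping = mapping)
    } else if (is.matrix(s)) {
      if (!all(dim(s) == dims))
        stopf("carve_scotoma: mask %d shape does not match the image", i)
      m <- s
    } else stopf("carve_scotoma: specs must be scotoma_spec objects or mask matrices")
    mm <- matrix(as.numeric(m > 0), dims[1], dims[2])
    attr(mm, "label") <- if (inherits(s, "scotoma_spec")) s$label else sprintf("mask_%d", i)
    mm
  })
  masks <- Filter(function(m) any(m > 0), masks)

  coord_rows <- matrix(as.numeric(row(matrix(0, dims[1], dims[2]))), dims[1])
  coord_cols <- matrix(as.numeric(col(matrix(0, dims[1], dims[2]))), dims[1])
  fx <- fixation[[1]]; fy <- fixation[[2]]
  seams <- list(); n_v <- 0L; n_h <- 0L; iter <- 0L

  if (length(masks) > 0 && policy$multi_scotoma_order == "by_decreasing_eccentricity") {
    ecc <- vapply(masks, function(m) {
      cen <- mask_centroid(m)
      sqrt((cen[["x"]] - fx)^2 + (cen[["y"]] - fy)^2)
    }, numeric(1))
    masks <- masks[order(ecc, decreasing = TRUE)]
  }

  for (si in seq_along(masks)) {
    label <- attr(masks[[si]], "label")
    dir0 <- direction_for_scotoma(masks[[si]], c(fx, fy), policy)
    alt_k <- 0L
    while (sum(masks[[si]]) > 0) {
      iter <- iter + 1L
      if (iter > policy$max_iterations)
        stopf("carve_scotoma: max_iterations exceeded while carving scotoma '%s'", label)
      dir <- if (dir0 == "alternating") {
        alt_k <- alt_k + 1L
        if (alt_k %% 2L == 1L) "vertical" else "horizontal"
      } else dir0
      energy <- prewitt_energy(image)
      others <- masks[-si][vapply(masks[-si], function(m) any(m > 0), logical(1))]
      energy <- apply_mask_energy(energy, masks[[si]], others, policy)
      seam <- extract_min_seam(cumulative_cost(energy, dir))
      aux <- c(masks, list(.cr = coord_rows, .cc = coord_cols))
      out <- remove_seam(image, seam, aux)
      image <- out$image
      labels <- lapply(masks, attr, "label")
      masks <- out$aux[seq_along(masks)]
      for (k in seq_along(masks)) attr(masks[[k]], "label") <- labels[[k]]
      coord_rows <- out$aux$.cr; coord_cols <- out$aux$.cc
      if (dir == "vertical") {
        n_v <- n_v + 1L
        s <- seam$positions[min(max(round(fy), 1), length(seam$positions))]
        if (s < fx) fx <- fx - 1
        fx <- min(fx, ncol(coord_cols))
      } else {
        n_h <- n_h + 1L
        s <- seam$positions[min(max(round(fx), 1), length(seam$positions))]
        if (s < fy) fy <- fy - 1
        fy <- min(fy, nrow(coord_rows))
      }
      seam$iteration <- iter
      seam$scotoma <- label
      seams[[length(seams) + 1L]] <- seam
    }
  }

  residual <- if (length(masks) > 0) Reduce(`+`, masks) else
    matrix(0, nrow(coord_rows), ncol(coord_cols))
  structure(list(image = image, seams = seams, coord_rows = coord_rows,
                 coord_cols = coord_cols, residual = residual,
                 n_vertical = n_v, n_horizontal = n_h,
                 dim_original = dims, fixation = c(x = fx, y = fy)),
            class = "carve_result")
}

#' @export
print.carve_result <- function(x, ...) {
  d <- if (is.matrix(x$image)) dim(x$image) else dim(x$image)[1:2]
  cat(sprintf("<carve_result> %d x %d -> %d x %d px; %d vertical + %d horizontal seams; residual mask pixels: %d\n",
              x$dim_original[1], x$dim_original[2], d[1], d[2],
              x$n_vertical, x$n_horizontal, sum(x$residual > 0)))
  invisible(x)
}

#' Displacement and distortion field of a carve
#'
#' Quantifies how the carving pulls the surrounding content toward the
#' scotoma: per output pixel, the displacement is its original coordinate
#' minus its embedded output coordinate (the carved image being embedded in
#' the original frame left-aligned or center-aligned). The scalar
#' distortion map is the finite-difference gradient magnitude of the
#' displacement field, large where neighboring pixels were pulled by
#' different amounts (i.e. near the carved scotoma where seams converge).
#'
#' @param result A [carve_scotoma()] result.
#' @param embedding `"center_align"` (default) or `"left_align"`.
#' @return List with matrices `dx`, `dy` (pixels), `distortion`, and the
#'   embedding `offset` (x, y).
#' @export
displacement_field <- function(result, embedding = c("center_align", "left_align")) {
  embedding <- match.arg(embedding)
  h <- nrow(result$coord_rows); w <- ncol(result$coord_cols)
  off <- switch(embedding,
    left_align = c(x = 0, y = 0),
    center_align = c(x = floor((result$dim_original[2] - w) / 2),
                     y = floor((result$dim_original[1] - h) / 2)))
  out_r <- row(result$coord_rows); out_c <- col(result$coord_cols)
  dy <- result$coord_rows - (out_r + off[["y"]])
  dx <- result$coord_cols - (out_c + off[["x"]])
  grad_mag2 <- function(m) {
    gx <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE]) - m
    gy <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE]) - m
    gx^2 + gy^2
  }
  list(dx = dx, dy = dy, distortion = sqrt(grad_mag2(dx) + grad_mag2(dy)),
       offset = off)
}
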