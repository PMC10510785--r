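test_that("direction selection follows the fovea-axis, elongation and central rules", {
  mk <- function(rows, cols, h = 100, w = 100) {
    m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE; m
  }
  fix <- c(50, 50)
  # lateral scotoma (centroid left of fixation, no vertical offset) -> vertical
  expect_equal(direction_for_scotoma(mk(48:52, 10:14), fix), "vertical")
  # superior scotoma -> horizontal
  expect_equal(direction_for_scotoma(mk(10:14, 48:52), fix), "horizontal")
  # mask containing fixation -> alternating (central)
  expect_equal(direction_for_scotoma(mk(45:55, 45:55), fix), "alternating")
  # exact diagonal |dx| = |dy| -> vertical by the >= tie rule
  expect_equal(direction_for_scotoma(mk(69:71, 69:71), fix), "vertical")
  # elongation rule: seams run along the longer dimension
  pol <- carve_policy("elongation")
  expect_equal(direction_for_scotoma(mk(40:42, 10:30), fix, pol), "horizontal")
  expect_equal(direction_for_scotoma(mk(10:30, 40:42), fix, pol), "vertical")
  expect_equal(direction_for_scotoma(mk(10:20, 30:40), fix, pol), "vertical")
  # forced directions and errors
  expect_equal(direction_for_scotoma(mk(1:2, 1:2), fix,
                                     carve_policy("fixed_horizontal")),
               "horizontal")
  expect_error(direction_for_scotoma(matrix(FALSE, 5, 5), fix), "empty")
})

test_that("mask energy forces seams through the scotoma and out of other masks", {
  e <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)
  act <- matrix(FALSE, 3, 3); act[2, 2] <- TRUE
  oth <- matrix(FALSE, 3, 3); oth[1, 3] <- TRUE
  out <- apply_mask_energy(e, act, list(oth))
  expect_lt(out[2, 2], 0)
  # any seam with one mask pixel beats every mask-avoiding seam
  expect_lt(out[2, 2] + 2 * max(e), 0)
  # other-mask pixels exceed any natural seam energy
  expect_gt(out[1, 3], 3 * max(e))
  untouched <- !(act | oth)
  expect_equal(out[untouched], e[untouched])
  # empty active mask: identity
  expect_equal(apply_mask_energy(e, matrix(FALSE, 3, 3)), e)
  # overlap is an error
  expect_error(apply_mask_energy(e, act, list(act)), "overlap")
  # explicit policy value is respected
  pol <- carve_policy(mask_energy = -999)
  expect_equal(apply_mask_energy(e, act, policy = pol)[2, 2], -999)
})

test_that("a rectangular mask is eliminated by exactly its width in vertical seams", {
  fx <- rect_mask_fixture()
  res <- carve_scotoma(fx$image, fx$mask, fixation = c(2, 20),
                       policy = carve_policy("fixed_vertical"))
  expect_equal(res$n_vertical, 4)  # mask is 4 px wide
  expect_equal(dim(res$image), c(40, 36))
  expect_equal(sum(res$residual), 0)
  # seam confinement: at mask rows every seam lies within mask columns
  for (s in res$seams) {
    expect_equal(s$direction, "vertical")
    expect_true(all(s$positions[15:25] >= 18 & s$positions[15:25] <= 21))
  }
})

test_that("a line through the scotoma is shortened by the scotoma's width", {
  fx <- rect_mask_fixture()
  expect_equal(sum(fx$image == 0), 30)  # 30 px line before carving
  res <- carve_scotoma(fx$image, fx$mask, fixation = c(2, 20),
                       policy = carve_policy("fixed_vertical"))
  expect_equal(sum(res$image == 0), 26)  # 30 - 4 after carving
})

test_that("empty spec list returns the image unchanged with zero seams", {
  img <- matrix(runif(100), 10, 10)
  res <- carve_scotoma(img, list(), fixation = c(5, 5))
  expect_equal(res$image, img)
  expect_equal(length(res$seams), 0)
  expect_equal(sum(res$residual), 0)
})

test_that("every fixture shape is fully eliminated and sizes account for seams", {
  d <- make_display(120, 120, 24)  # ppd = 5
  fix <- fixation_point(60, 60)
  img <- generate_fixture("random_texture", c(120, 120), seed = 9)$image
  shapes <- list(
    rect_offcenter = scotoma_ellipse(3, 2, center_deg = c(6, 1)),
    ellipse = scotoma_ellipse(4, 2.5, rotation_deg = 30, center_deg = c(-5, 2)),
    arcuate = scotoma_arcuate(8, 300, 120, 1.6),
    central = scotoma_circle(3))
  for (nm in names(shapes)) {
    res <- carve_scotoma(img, shapes[[nm]], d, fix)
    expect_equal(sum(res$residual), 0, info = nm)
    dims <- dim(res$image)
    expect_equal(dims[2], 120 - res$n_vertical, info = nm)
    expect_equal(dims[1], 120 - res$n_horizontal, info = nm)
  }
  # multiple scotomas at once
  res2 <- carve_scotoma(img, list(shapes$rect_offcenter, shapes$ellipse), d, fix)
  expect_equal(sum(res2$residual), 0)
  expect_equal(dim(res2$image),
               c(120 - res2$n_horizontal, 120 - res2$n_vertical))
})

test_that("coordinate map stays injective and preserves pixel provenance", {
  fx <- rect_mask_fixture()
  res <- carve_scotoma(fx$image, fx$mask, fixation = c(2, 20),
                       policy = carve_policy("fixed_vertical"))
  keys <- res$coord_rows * 1000 + res$coord_cols
  expect_equal(anyDuplicated(as.vector(keys)), 0)
  expect_equal(res$image,
               matrix(fx$image[cbind(as.vector(res$coord_rows),
                                     as.vector(res$coord_cols))],
                      nrow(res$image)))
  # no source pixel under the mask survives
  mask_keys <- which(fx$mask) # linear indices
  src_lin <- (as.vector(res$coord_cols) - 1) * 40 + as.vector(res$coord_rows)
  expect_equal(length(intersect(src_lin, mask_keys)), 0)
})

test_that("a full-height strip mask carves to plain column deletion", {
  set.seed(31)
  img <- matrix(runif(30 * 30), 30, 30)
  strip <- matrix(FALSE, 30, 30); strip[, 12:15] <- TRUE
  res <- carve_scotoma(img, strip, fixation = c(2, 15),
                       policy = carve_policy("fixed_vertical"))
  expect_equal(res$n_vertical, 4)
  expect_equal(res$image, img[, -(12:15)])
})

test_that("a central disc empties under alternating carving within the size bound", {
  d <- make_display(100, 100, 20)  # ppd = 5
  img <- generate_fixture("random_texture", c(100, 100), seed = 12)$image
  res <- carve_scotoma(img, scotoma_circle(4), d, fixation_point(50, 50))
  expect_equal(sum(res$residual), 0)
  dirs <- vapply(res$seams, `[[`, character(1), "direction")
  expect_true(all(c("vertical", "horizontal") %in% dirs))
  # strict alternation starting vertical
  expect_equal(dirs[1:4], c("vertical", "horizontal", "vertical", "horizontal"))
  # termination within d*ppd + margin iterations per direction
  expect_lte(res$n_vertical, 4 * 5 + 5)
  expect_lte(res$n_horizontal, 4 * 5 + 5)
})

test_that("displacement field reflects deletion semantics and concentrates distortion near the mask", {
  # zero seams -> zero displacement
  img <- matrix(runif(64), 8, 8)
  res0 <- carve_scotoma(img, list(), fixation = c(4, 4))
  df0 <- displacement_field(res0, "left_align")
  expect_equal(max(abs(df0$dx)), 0)
  expect_equal(max(abs(df0$dy)), 0)
  # single straight vertical seam, left-aligned: +1 horizontal pull right of it
  img2 <- matrix(0.5, 10, 10)
  j <- 6
  strip <- matrix(FALSE, 10, 10); strip[, j] <- TRUE
  res1 <- carve_scotoma(img2, strip, fixation = c(2, 5),
                        policy = carve_policy("fixed_vertical"))
  df1 <- displacement_field(res1, "left_align")
  expect_true(all(df1$dx[, j:9] == 1))
  expect_true(all(df1$dx[, 1:(j - 1)] == 0))
  expect_true(all(df1$dy == 0))
  # distortion near the carved scotoma exceeds distortion far away
  big <- generate_fixture("random_texture", c(200, 200), seed = 77)$image
  mask <- matrix(FALSE, 200, 200); mask[95:105, 98:102] <- TRUE
  res2 <- carve_scotoma(big, mask, fixation = c(10, 100),
                        policy = carve_policy("fixed_vertical"))
  df2 <- displacement_field(res2, "left_align")
  src_d <- sqrt((res2$coord_rows - 100)^2 + (res2$coord_cols - 100)^2)
  near <- src_d <= 15 & src_d >= 3
  far <- src_d >= 50 & src_d <= 100
  expect_gt(mean(df2$distortion[near]), mean(df2$distortion[far]))
})

test_that("carving an RGB image removes the same seams from every channel", {
  set.seed(13)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  mask <- matrix(FALSE, 40, 40); mask[18:22, 19:20] <- TRUE
  res <- carve_scotoma(img, mask, fixation = c(5, 20),
                       policy = carve_policy("fixed_vertical"))
  expect_equal(dim(res$image), c(40, 38, 3))
  for (ch in 1:3)
    expect_equal(res$image[, , ch],
                 matrix(img[, , ch][cbind(as.vector(res$coord_rows),
                                          as.vector(res$coord_cols))], 40))
})

test_that("unreachable iteration guards error with the scotoma's name", {
  img <- matrix(runif(400), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  expect_error(
    carve_scotoma(img, mask, fixation = c(2, 10),
                  policy = carve_policy("fixed_vertical", max_iterations = 2)),
    "max_iterations.*mask_1")
})
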