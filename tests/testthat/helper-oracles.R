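# Independent oracles used to check the package's fast implementations.

# Minimum-energy monotone vertical seam by exhaustive enumeration of all
# start columns x all step sequences in {-1, 0, +1}^(h-1). Independent of
# the DP implementation; feasible up to ~8x8.
brute_force_min_seam <- function(energy) {
  h <- nrow(energy); w <- ncol(energy)
  if (h == 1) {
    j <- which.min(energy[1, ])
    return(list(positions = j, total = energy[1, j]))
  }
  offs <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), h - 1)))
  cums <- offs
  if (ncol(offs) > 1)
    for (j in 2:ncol(offs)) cums[, j] <- cums[, j - 1] + offs[, j]
  best <- Inf; best_pos <- NULL
  for (s in seq_len(w)) {
    pos <- cbind(s, s + cums)
    ok <- rowSums(pos < 1 | pos > w) == 0
    if (!any(ok)) next
    pos <- pos[ok, , drop = FALSE]
    tot <- rowSums(matrix(vapply(seq_len(h),
                                 function(i) energy[i, pos[, i]],
                                 numeric(nrow(pos))),
                          nrow = nrow(pos)))
    if (min(tot) < best) {
      best <- min(tot)
      best_pos <- pos[which.min(tot), ]
    }
  }
  list(positions = as.integer(best_pos), total = best)
}

# Direct (slow, double-loop) 3x3 Prewitt gradient magnitude with edge
# replication; reference for prewitt_energy().
reference_prewitt <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cl <- function(i, n) min(max(i, 1L), n)
  out <- matrix(0, h, w)
  kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, byrow = TRUE)
  ky <- t(kx)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- m[cl(i + di, h), cl(j + dj, w)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# The rectangular-mask fixture used across the carving tests: a 40 x 40
# uniform-noise scene with a dark 30 px line through a 4 px-wide mask.
rect_mask_fixture <- function(seed = 42) {
  fx <- generate_fixture("line_scene", c(40, 40), seed = seed,
                         line_row = 20, line_cols = c(5, 34), line_value = 0)
  mask <- matrix(FALSE, 40, 40)
  mask[15:25, 18:21] <- TRUE
  list(image = fx$image, mask = mask, ground_truth = fx$ground_truth)
}

expect_images_equal <- function(a, b, tol = 0) {
  expect_equal(dim(a), dim(b))
  expect_true(max(abs(a - b)) <= tol)
}
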