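# Shared fixture builders for the test suite.

# uniform RGB image (h x w x 3, 0-255)
uniform_image <- function(rgb, h = 8, w = 8) {
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

# random 0/1 mask of given size under the current RNG
random_mask <- function(h, w) {
  pixel_mask(matrix(rbinom(h * w, 1L, 0.4), h, w))
}

# sum-of-Euclidean-distances objective of the geometric median
gm_objective <- function(y, points) {
  sum(sqrt(rowSums(sweep(points, 2L, y)^2)))
}

# representative purple: LCh (60, 30, 315) as sRGB
purple_rgb <- function() as.numeric(lab_to_srgb(lch_to_lab(c(60, 30, 315))))

# two well-separated trivariate blobs; returns list(lab, membership)
two_blobs <- function(n_each = 40, sep = 30) {
  lab <- rbind(
    matrix(rnorm(n_each * 3, 0, 1), ncol = 3),
    matrix(rnorm(n_each * 3, 0, 1), ncol = 3) +
      matrix(c(sep, 0, 0), n_each, 3, byrow = TRUE))
  # first blob has lower first component (darker) -> canonical label 1
  list(lab = lab, membership = rep(c(1L, 0L), each = n_each))
}
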