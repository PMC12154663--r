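# sRGB <-> CIELAB <-> LCh conversions, D65/2 degree observer throughout.
#
# All functions are vectorized over n x 3 matrices; a bare length-3 vector is
# treated as a single color. Internal math is double precision; 8-bit
# quantization happens only at the sRGB boundary.

# sRGB (linear) -> XYZ matrix and D65 reference white. The white point is the
# row sums of the matrix, so (255,255,255) maps exactly to L=100, a=b=0.
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.xyz_to_srgb <- solve(.srgb_to_xyz)
.d65_white <- rowSums(.srgb_to_xyz)

.as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(what, " must have 3 components", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop(what, " must be an n x 3 matrix", call. = FALSE)
    storage.mode(x) <- "double"
  }
  x
}

#' Convert 8-bit sRGB colors to CIELAB
#'
#' Applies the IEC 61966-2-1 sRGB transfer function, the sRGB primaries
#' (D65 white, 2 degree observer), and the CIE 1976 L*a*b* formulae with the
#' standard 6/29 cusp.
#'
#' @param rgb an n x 3 matrix (or length-3 vector) of integer channel values
#'   in 0--255, columns r, g, b.
#' @return an n x 3 matrix with columns `L`, `a`, `b`. `L` lies in
#'   \[0, 100\] for any valid sRGB input.
#' @examples
#' srgb_to_lab(c(255, 255, 255))  # L = 100, a = b = 0
#' srgb_to_lab(rbind(c(128, 0, 128), c(0, 0, 0)))
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_color_matrix(rgb, "rgb")
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("rgb channels must be finite values in [0, 255]", call. = FALSE)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz)
  t_ <- sweep(xyz, 2L, .d65_white, "/")
  cusp <- (6 / 29)^3
  f <- ifelse(t_ > cusp, t_^(1 / 3), t_ / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * f[, 2L] - 16,
               a = 500 * (f[, 1L] - f[, 2L]),
               b = 200 * (f[, 2L] - f[, 3L]))
  lab
}

#' Convert CIELAB colors to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colors are clipped channel-wise in
#' linear light before 8-bit rounding, so every input yields a valid sRGB
#' triple; the clip is intended for display (hex) use only. Round trips from
#' valid sRGB recover each channel within +/- 1.
#'
#' @param lab an n x 3 matrix (or length-3 vector) with columns L, a, b.
#' @return an n x 3 integer matrix with columns `r`, `g`, `b` in 0--255.
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_color_matrix(lab, "lab")
  if (any(!is.finite(lab))) stop("lab components must be finite", call. = FALSE)
  fy <- (lab[, 1L] + 16) / 116
  fx <- fy + lab[, 2L] / 500
  fz <- fy - lab[, 3L] / 200
  f <- cbind(fx, fy, fz)
  finv <- ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- sweep(finv, 2L, .d65_white, "*")
  lin <- xyz %*% t(.xyz_to_srgb)
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- round(pmin(pmax(v, 0), 1) * 255)
  storage.mode(out) <- "integer"
  colnames(out) <- c("r", "g", "b")
  out
}

#' Convert CIELAB to LCh (cylindrical CIELAB)
#'
#' C = sqrt(a^2 + b^2); h = atan2(b, a) in degrees mapped to \[0, 360).
#' Achromatic colors (C below `achromatic_tol`) take h = 0 by convention, so
#' grays have a deterministic hue.
#'
#' @param lab an n x 3 matrix (or length-3 vector) with columns L, a, b.
#' @param achromatic_tol chroma below which hue is defined as 0.
#' @return an n x 3 matrix with columns `L`, `C`, `h`.
#' @export
lab_to_lch <- function(lab, achromatic_tol = 1e-8) {
  lab <- .as_color_matrix(lab, "lab")
  if (any(!is.finite(lab))) stop("lab components must be finite", call. = FALSE)
  C <- sqrt(lab[, 2L]^2 + lab[, 3L]^2)
  h <- (atan2(lab[, 3L], lab[, 2L]) * 180 / pi) %% 360
  h[C < achromatic_tol] <- 0
  cbind(L = lab[, 1L], C = C, h = h)
}

#' Convert LCh back to CIELAB
#'
#' Exact inverse of [lab_to_lch()]: a = C cos(h), b = C sin(h).
#'
#' @param lch an n x 3 matrix (or length-3 vector) with columns L, C, h
#'   (h in degrees).
#' @return an n x 3 matrix with columns `L`, `a`, `b`.
#' @export
lch_to_lab <- function(lch) {
  lch <- .as_color_matrix(lch, "lch")
  if (any(!is.finite(lch))) stop("lch components must be finite", call. = FALSE)
  if (any(lch[, 2L] < 0)) stop("chroma must be non-negative", call. = FALSE)
  hr <- lch[, 3L] * pi / 180
  cbind(L = lch[, 1L], a = lch[, 2L] * cos(hr), b = lch[, 2L] * sin(hr))
}

#' Hex display color of a CIELAB value
#'
#' @param lab an n x 3 matrix (or length-3 vector) with columns L, a, b.
#' @return character vector of `"#RRGGBB"` strings (uppercase), via
#'   [lab_to_srgb()] with its gamut clip.
#' @export
lab_to_hex <- function(lab) {
  rgb <- lab_to_srgb(lab)
  sprintf("#%02X%02X%02X", rgb[, 1L], rgb[, 2L], rgb[, 3L])
}

#' Parse "#RRGGBB" hex strings to 8-bit sRGB
#'
#' @param hex character vector of 6-digit hex color strings, leading `#`.
#' @return an n x 3 integer matrix with columns `r`, `g`, `b`.
#' @export
hex_to_srgb <- function(hex) {
  if (!is.character(hex) || any(!grepl("^#[0-9a-fA-F]{6}$", hex)))
    stop("hex colors must match \"#RRGGBB\"", call. = FALSE)
  out <- cbind(r = strtoi(substr(hex, 2L, 3L), 16L),
               g = strtoi(substr(hex, 4L, 5L), 16L),
               b = strtoi(substr(hex, 6L, 7L), 16L))
  storage.mode(out) <- "integer"
  out
}
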