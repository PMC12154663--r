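# Binary flower masks: construction, RLE-JSON persistence, IoU evaluation,
# and a transparent LCh-threshold segmenter.

#' Construct a pixel mask
#'
#' A pixel mask holds per-pixel binary flower labels for one image:
#' 1 = "flower", 0 = "not a flower".
#'
#' @param labels an integer matrix (height x width) of 0/1 labels.
#' @return an object of class `pixel_mask` with fields `width`, `height`,
#'   `labels`.
#' @export
pixel_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (length(labels) == 0L) stop("mask must be non-empty", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("mask labels must be 0 or 1", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(width = ncol(labels), height = nrow(labels), labels = labels),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask %d x %d, %d flower pixels (%.1f%%)>\n",
              x$width, x$height, sum(x$labels),
              100 * mean(x$labels)))
  invisible(x)
}

.check_image <- function(image) {
  if (is.null(dim(image)) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  if (any(dim(image)[1:2] == 0L)) stop("image must be non-empty", call. = FALSE)
  invisible(image)
}

#' Segmenter configuration
#'
#' Thresholds for [threshold_segment()], a deterministic LCh-window
#' classifier. The default hue windows are the purple/violet ranges
#' (0--50 and 250--360 degrees) that bound wild-type *Monarda* corolla
#' colors; chroma and lightness bounds exclude desaturated and
#' near-black/near-white background pixels.
#'
#' @param chroma_min minimum LCh chroma for a flower pixel.
#' @param hue_windows list of `c(lo, hi)` closed hue intervals in degrees
#'   within \[0, 360\]; an upper bound of 360 also admits h = 0.
#' @param lightness_range `c(L_min, L_max)` closed lightness interval.
#' @return a `segmenter_config` list.
#' @export
segmenter_config <- function(chroma_min = 12,
                             hue_windows = list(c(0, 50), c(250, 360)),
                             lightness_range = c(15, 97)) {
  if (!is.numeric(chroma_min) || chroma_min < 0)
    stop("chroma_min must be a non-negative number", call. = FALSE)
  if (!is.list(hue_windows) || !length(hue_windows))
    stop("hue_windows must be a non-empty list of intervals", call. = FALSE)
  for (w in hue_windows) {
    if (length(w) != 2L || any(w < 0) || any(w > 360) || w[1L] > w[2L])
      stop("each hue window must be an ordered interval within [0, 360]",
           call. = FALSE)
  }
  if (length(lightness_range) != 2L || any(lightness_range < 0) ||
      any(lightness_range > 100) || lightness_range[1L] > lightness_range[2L])
    stop("lightness_range must be an ordered interval within [0, 100]",
         call. = FALSE)
  structure(list(chroma_min = chroma_min, hue_windows = hue_windows,
                 lightness_range = lightness_range),
            class = "segmenter_config")
}

#' Threshold-based flower segmentation
#'
#' Labels a pixel "flower" iff its LCh chroma is at least `chroma_min`, its
#' hue falls in any configured window (closed intervals; 360 treated as 0),
#' and its lightness lies in `lightness_range`. This is a transparent,
#' deterministic classifier: all thresholds are configuration, not learned.
#'
#' @param image a height x width x 3 array of 8-bit sRGB values (0--255).
#' @param cfg a [segmenter_config()].
#' @return a [pixel_mask()] of the same dimensions.
#' @export
threshold_segment <- function(image, cfg = segmenter_config()) {
  .check_image(image)
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  lch <- lab_to_lch(srgb_to_lab(rgb))
  ok_c <- lch[, 2L] >= cfg$chroma_min
  ok_l <- lch[, 1L] >= cfg$lightness_range[1L] &
    lch[, 1L] <= cfg$lightness_range[2L]
  h <- lch[, 3L]
  ok_h <- rep(FALSE, length(h))
  for (w in cfg$hue_windows)
    ok_h <- ok_h | (h >= w[1L] & h <= w[2L]) | (w[2L] >= 360 & h == 0)
  pixel_mask(matrix(as.integer(ok_c & ok_l & ok_h), d[1L], d[2L]))
}

#' Serialize a mask to its JSON document
#'
#' The persisted dialect stores run lengths of the row-major label sequence,
#' alternating 0-runs and 1-runs and always starting with a 0-run (possibly
#' of length zero). The round trip through [json_to_mask()] is lossless.
#'
#' @param mask a [pixel_mask()].
#' @return a JSON string with fields `width`, `height`, `rle`.
#' @export
mask_to_json <- function(mask) {
  if (!inherits(mask, "pixel_mask")) stop("not a pixel_mask", call. = FALSE)
  v <- as.integer(t(mask$labels))  # row-major
  r <- rle(v)
  lens <- r$lengths
  if (r$values[1L] == 1L) lens <- c(0L, lens)
  jsonlite::toJSON(list(width = mask$width, height = mask$height,
                        rle = as.integer(lens)),
                   auto_unbox = TRUE)
}

#' Parse a mask JSON document
#'
#' Accepts only the dialect written by [mask_to_json()] and fails loudly,
#' naming the offending field, on anything else.
#'
#' @param doc a JSON string or parsed list with fields `width`, `height`,
#'   `rle`.
#' @return a [pixel_mask()].
#' @export
json_to_mask <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::fromJSON(doc)
  for (f in c("width", "height", "rle"))
    if (is.null(doc[[f]])) stop("mask document missing field: ", f,
                                call. = FALSE)
  w <- doc$width; h <- doc$height; lens <- doc$rle
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w))
    stop("invalid field: width", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || h < 1 || h != round(h))
    stop("invalid field: height", call. = FALSE)
  if (!is.numeric(lens) || any(lens < 0) || any(lens != round(lens)))
    stop("invalid field: rle (runs must be non-negative integers)",
         call. = FALSE)
  if (sum(lens) != w * h)
    stop("invalid field: rle (run lengths sum to ", sum(lens),
         ", expected width*height = ", w * h, ")", call. = FALSE)
  vals <- rep(rep_len(c(0L, 1L), length(lens)), as.integer(lens))
  pixel_mask(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}

#' Write / read one mask file
#'
#' One JSON file per image; by convention the filename is the image id plus
#' `".json"`.
#'
#' @param mask a [pixel_mask()].
#' @param path file path.
#' @return `read_mask` returns a [pixel_mask()]; `write_mask` returns `path`
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  writeLines(mask_to_json(mask), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  json_to_mask(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Mean intersection-over-union of two masks
#'
#' Mean over the two classes (flower, not-flower) of
#' |intersection| / |union|. A class absent from both masks contributes an
#' IoU of 1, so single-class toy images score sensibly.
#'
#' @param predicted,truth [pixel_mask()] objects with equal dimensions.
#' @return a fraction in \[0, 1\]; 1 iff the masks are identical.
#' @export
mean_iou <- function(predicted, truth) {
  if (!inherits(predicted, "pixel_mask") || !inherits(truth, "pixel_mask"))
    stop("arguments must be pixel_mask objects", call. = FALSE)
  if (predicted$width != truth$width || predicted$height != truth$height)
    stop("mask dimensions differ", call. = FALSE)
  p <- predicted$labels; t_ <- truth$labels
  iou <- vapply(c(0L, 1L), function(cls) {
    inter <- sum(p == cls & t_ == cls)
    uni <- sum(p == cls | t_ == cls)
    if (uni == 0L) 1 else inter / uni
  }, numeric(1L))
  mean(iou)
}

#' Extract CIELAB values of flower pixels
#'
#' Converts every pixel where the mask is 1 to CIELAB, in row-major order.
#' An all-zero mask yields a zero-row matrix; the caller decides whether that
#' constitutes a failure (see [phenotype_image()]).
#'
#' @param image a height x width x 3 array of 8-bit sRGB values.
#' @param mask a [pixel_mask()] with matching dimensions.
#' @return an n x 3 matrix of L, a, b rows (possibly n = 0).
#' @export
extract_flower_pixels <- function(image, mask) {
  .check_image(image)
  d <- dim(image)
  if (mask$height != d[1L] || mask$width != d[2L])
    stop("mask dimensions do not match image", call. = FALSE)
  sel <- t(mask$labels) == 1L
  rgb <- cbind(as.vector(t(image[, , 1L]))[sel],
               as.vector(t(image[, , 2L]))[sel],
               as.vector(t(image[, , 3L]))[sel])
  if (nrow(rgb) == 0L)
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("L", "a", "b"))))
  srgb_to_lab(rgb)
}
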