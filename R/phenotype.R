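# Reduce flower pixels to one robust color per image, and observations to one
# image each, producing the analysis-ready phenotype table.

#' Geometric median of a point set
#'
#' The point minimizing the sum of Euclidean distances to the input points: a
#' robust (50% breakdown) alternative to the mean, used here to summarize a
#' cloud of flower-pixel CIELAB values contaminated by mislabeled background
#' pixels. Computed by Weiszfeld's iteratively reweighted averaging, started
#' at the coordinate-wise mean. When an iterate coincides with a data point
#' the plain update would divide by zero; the Vardi-Zhang correction step is
#' applied instead, so anchor points are handled exactly.
#'
#' Averaging is always done in Cartesian CIELAB coordinates, never in LCh:
#' hue is circular and polar averaging is invalid.
#'
#' @param points an n x d numeric matrix (rows are points), n >= 1.
#' @param tol convergence threshold on the movement of successive iterates
#'   (same units as the coordinates).
#' @param max_iter iteration cap.
#' @return a length-d numeric vector.
#' @references Weiszfeld (1937); Vardi & Zhang (2000, PNAS 97:1423-1426).
#' @export
geometric_median <- function(points, tol = 1e-7, max_iter = 1000L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) == 0L)
    stop("no flower pixels: geometric median of an empty set", call. = FALSE)
  if (any(!is.finite(points)))
    stop("points must have finite coordinates", call. = FALSE)
  if (nrow(points) == 1L) return(drop(points[1L, ]))

  y <- colMeans(points)
  for (iter in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(points, 2L, y)^2))
    at_point <- d < 1e-12
    if (any(at_point)) {
      # Vardi-Zhang: y sits on data point(s) with total multiplicity eta.
      eta <- sum(at_point)
      others <- points[!at_point, , drop = FALSE]
      if (nrow(others) == 0L) return(y)  # all points coincide with y
      dd <- d[!at_point]
      w <- 1 / dd
      r_vec <- colSums(sweep(others, 2L, y) * w)
      r <- sqrt(sum(r_vec^2))
      if (r <= eta) return(y)  # y is the median despite being a data point
      t_tilde <- colSums(others * w) / sum(w)
      y_new <- (1 - eta / r) * t_tilde + (eta / r) * y
    } else {
      w <- 1 / d
      y_new <- colSums(points * w) / sum(w)
    }
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

#' Phenotype one image
#'
#' Composes pixel extraction, the geometric median in CIELAB, and the LCh /
#' hex conversions into a single phenotype record for one image.
#'
#' @param image a height x width x 3 array of 8-bit sRGB values.
#' @param mask a [pixel_mask()]; must contain at least one flower pixel.
#' @param observation_id,image_id identifiers carried into the record.
#' @param tol,max_iter passed to [geometric_median()].
#' @return a one-row data.frame with columns `observation_id`, `image_id`,
#'   `L`, `a`, `b`, `C`, `h`, `hex`, `n_pixels`.
#' @seealso [phenotype_table()] for the batch version that tolerates and
#'   logs failed images.
#' @export
phenotype_image <- function(image, mask, observation_id = NA_character_,
                            image_id = NA_character_, tol = 1e-7,
                            max_iter = 1000L) {
  px <- extract_flower_pixels(image, mask)
  if (nrow(px) == 0L)
    stop(structure(class = c("floracline_no_flower_pixels", "error",
                             "condition"),
                   list(message = paste0("no flower pixels in image ",
                                         image_id),
                        call = NULL)))
  lab <- geometric_median(px, tol = tol, max_iter = max_iter)
  lch <- lab_to_lch(lab)
  data.frame(observation_id = observation_id, image_id = image_id,
             L = lab[1L], a = lab[2L], b = lab[3L],
             C = lch[1L, "C"], h = lch[1L, "h"],
             hex = lab_to_hex(lab), n_pixels = nrow(px),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phenotype a directory of images against their masks
#'
#' Iterates the observation table (one row per image), reading
#' `<image_id>.png` from `images_dir` and `<image_id>.json` from `masks_dir`.
#' Images whose mask has no flower pixels, or whose files are missing or
#' unreadable, are tolerated: they are excluded from the phenotype table and
#' logged in a failures table instead of raising.
#'
#' @param observations data.frame with columns `observation_id`, `image_id`
#'   (one row per image); other columns are ignored here.
#' @param images_dir directory of 8-bit RGB PNG images.
#' @param masks_dir directory of mask JSON files.
#' @param tol,max_iter passed to [geometric_median()].
#' @return a list with `phenotypes` (data.frame as in [phenotype_image()])
#'   and `failures` (data.frame `observation_id`, `image_id`, `reason`).
#' @export
phenotype_table <- function(observations, images_dir, masks_dir,
                            tol = 1e-7, max_iter = 1000L) {
  stopifnot(is.data.frame(observations),
            all(c("observation_id", "image_id") %in% names(observations)))
  rows <- vector("list", nrow(observations))
  fails <- list()
  for (i in seq_len(nrow(observations))) {
    oid <- observations$observation_id[i]
    iid <- observations$image_id[i]
    rec <- tryCatch({
      img <- read_image_png(file.path(images_dir, paste0(iid, ".png")))
      mask <- read_mask(file.path(masks_dir, paste0(iid, ".json")))
      phenotype_image(img, mask, observation_id = oid, image_id = iid,
                      tol = tol, max_iter = max_iter)
    }, error = function(e) {
      fails[[length(fails) + 1L]] <<- data.frame(
        observation_id = oid, image_id = iid,
        reason = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
    rows[[i]] <- rec
  }
  phen <- do.call(rbind, rows)
  if (is.null(phen))
    phen <- data.frame(observation_id = character(), image_id = character(),
                       L = numeric(), a = numeric(), b = numeric(),
                       C = numeric(), h = numeric(), hex = character(),
                       n_pixels = integer(), stringsAsFactors = FALSE)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(observation_id = character(), image_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(phenotypes = phen, failures = failures)
}

#' Read an 8-bit RGB PNG as a 0--255 array
#'
#' @param path PNG file path.
#' @return a height x width x 3 integer array in 0--255 (alpha dropped).
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  arr <- arr[, , 1:3, drop = FALSE]
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a 0--255 RGB array as PNG
#'
#' @param image a height x width x 3 array in 0--255.
#' @param path output file path.
#' @export
write_image_png <- function(image, path) {
  .check_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Sample one image per observation
#'
#' Observations with multiple phenotyped images contribute one image to the
#' spatial analysis, chosen uniformly at random under a caller-supplied seed
#' (required: reproducibility of the sampling step is part of the analysis
#' contract). Observations whose images all failed phenotyping are simply
#' absent from the input and hence dropped.
#'
#' @param phenotypes phenotype data.frame with at least `observation_id`.
#' @param seed integer seed for the selection; no default.
#' @return the subset of `phenotypes` with exactly one row per observation,
#'   ordered by `observation_id`.
#' @export
sample_one_image_per_observation <- function(phenotypes, seed) {
  stopifnot(is.data.frame(phenotypes),
            "observation_id" %in% names(phenotypes))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (nrow(phenotypes) == 0L) return(phenotypes)
  ord <- order(phenotypes$observation_id, phenotypes$image_id)
  phenotypes <- phenotypes[ord, , drop = FALSE]
  idx <- with_seed(seed, {
    vapply(split(seq_len(nrow(phenotypes)), phenotypes$observation_id),
           function(ix) if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
           integer(1L))
  })
  out <- phenotypes[sort(unname(idx)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
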