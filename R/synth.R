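# Synthetic cohorts with planted ground truth: georeferenced observations
# with two regional color regimes, rendered flower images with exact masks,
# and two-rater lighting annotations. Every downstream stage can be verified
# against the planted truth.

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a continent-scale community-science
#' flower dataset: longitudes spanning -135.3 to -61.4 degrees, a regional
#' color divide at -100 degrees with the west darker (lower L) and more
#' chromatic (higher C) but matching the east in hue (315 degrees, violet);
#' a small fraction of white-flowered outliers; multiple images for some
#' observations; and a full-sun exposure artifact that lightens the observed
#' (not the true) color.
#'
#' @param seed integer seed governing all generation (required).
#' @param n_observations number of observations.
#' @param longitude_range,latitude_range uniform sampling ranges in degrees.
#' @param divide_longitude planted west/east color divide.
#' @param west_color_lch,east_color_lch regional mean colors as `c(L, C, h)`;
#'   stored internally as CIELAB means.
#' @param color_sd per-component (L, a, b) SD of the trivariate normal color
#'   noise around the regional mean.
#' @param p_multi_image probability an observation has 2 images (else 1).
#' @param p_white_morph probability of a white-flowered outlier.
#' @param white_L_mean,white_L_sd,white_chroma_range,white_hue_range
#'   distribution of white-morph colors: high lightness, near-zero chroma,
#'   unstable greenish/yellowish hue.
#' @param lighting_probs named probabilities over shade/partial/full.
#' @param full_sun_L_shift additive shift on observed L under full sun.
#' @param rater_noise per-item probability a simulated rater mislabels the
#'   lighting category.
#' @param p_rater_nan per-item probability a rater answers "NAN".
#' @param image_size rendered images are `image_size` x `image_size` pixels.
#' @param pixel_jitter SD of per-pixel 8-bit RGB jitter on flower pixels.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_observations = 1000L,
                         longitude_range = c(-135.3, -61.4),
                         latitude_range = c(25, 55),
                         divide_longitude = -100,
                         west_color_lch = c(L = 55, C = 38, h = 315),
                         east_color_lch = c(L = 68, C = 26, h = 315),
                         color_sd = c(6, 4, 4),
                         p_multi_image = 0.25,
                         p_white_morph = 0.007,
                         white_L_mean = 92, white_L_sd = 2,
                         white_chroma_range = c(1, 6),
                         white_hue_range = c(60, 240),
                         lighting_probs = c(shade = 0.3, partial = 0.4,
                                            full = 0.3),
                         full_sun_L_shift = 10,
                         rater_noise = 0.15,
                         p_rater_nan = 0.02,
                         image_size = 32L,
                         pixel_jitter = 2) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  chk_range <- function(x, nm) if (length(x) != 2L || x[1L] > x[2L])
    stop("invalid field: ", nm, " (must be an ordered range)", call. = FALSE)
  chk_prob <- function(x, nm) if (any(x < 0) || any(x > 1))
    stop("invalid field: ", nm, " (must be in [0, 1])", call. = FALSE)
  if (!is.numeric(n_observations) || n_observations < 0)
    stop("invalid field: n_observations", call. = FALSE)
  chk_range(longitude_range, "longitude_range")
  chk_range(latitude_range, "latitude_range")
  chk_range(white_chroma_range, "white_chroma_range")
  chk_range(white_hue_range, "white_hue_range")
  chk_prob(p_multi_image, "p_multi_image")
  chk_prob(p_white_morph, "p_white_morph")
  chk_prob(rater_noise, "rater_noise")
  chk_prob(p_rater_nan, "p_rater_nan")
  chk_prob(lighting_probs, "lighting_probs")
  if (abs(sum(lighting_probs) - 1) > 1e-8)
    stop("invalid field: lighting_probs (must sum to 1)", call. = FALSE)
  if (!setequal(names(lighting_probs), c("shade", "partial", "full")))
    stop("invalid field: lighting_probs (names must be shade/partial/full)",
         call. = FALSE)
  if (any(color_sd <= 0) || length(color_sd) != 3L)
    stop("invalid field: color_sd", call. = FALSE)
  if (image_size < 8L) stop("invalid field: image_size (>= 8)", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_observations = as.integer(n_observations),
    longitude_range = longitude_range, latitude_range = latitude_range,
    divide_longitude = divide_longitude,
    west_color_lab = drop(lch_to_lab(west_color_lch)),
    east_color_lab = drop(lch_to_lab(east_color_lch)),
    color_sd = color_sd, p_multi_image = p_multi_image,
    p_white_morph = p_white_morph, white_L_mean = white_L_mean,
    white_L_sd = white_L_sd, white_chroma_range = white_chroma_range,
    white_hue_range = white_hue_range,
    lighting_probs = lighting_probs[c("shade", "partial", "full")],
    full_sun_L_shift = full_sun_L_shift, rater_noise = rater_noise,
    p_rater_nan = p_rater_nan, image_size = as.integer(image_size),
    pixel_jitter = pixel_jitter), class = "synth_config")
}

#' Generate synthetic observations with ground truth
#'
#' Draws longitudes/latitudes uniformly, assigns each observation a true
#' CIELAB phenotype from its regional mean plus trivariate normal noise
#' (white morphs overwrite with a high-L, near-achromatic color), samples a
#' lighting category, and derives the *observed* color by adding the
#' full-sun lightening to L where applicable. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `observations` (data.frame, one row per image:
#'   `observation_id`, `latitude`, `longitude`, `date`, `image_id`) and
#'   `truth` (data.frame, one row per observation: ids, coordinates, region,
#'   `lighting`, `is_white_morph`, true pre-lighting color `L_true`,
#'   `a_true`, `b_true`, observed color `L`, `a`, `b`, `C`, `h`).
#' @export
generate_observations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, .generate_observations_impl(cfg))
}

.generate_observations_impl <- function(cfg) {
  n <- cfg$n_observations
  empty_obs <- data.frame(observation_id = character(),
                          latitude = numeric(), longitude = numeric(),
                          date = character(), image_id = character(),
                          stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(observations = empty_obs,
                truth = data.frame(observation_id = character())))
  oid <- sprintf("obs%06d", seq_len(n))
  lon <- stats::runif(n, cfg$longitude_range[1L], cfg$longitude_range[2L])
  lat <- stats::runif(n, cfg$latitude_range[1L], cfg$latitude_range[2L])
  date <- format(as.Date("2019-06-01") +
                   sample.int(1200L, n, replace = TRUE) - 1L, "%Y-%m-%d")
  region <- ifelse(lon < cfg$divide_longitude, "west", "east")

  mu <- rbind(west = cfg$west_color_lab, east = cfg$east_color_lab)[region, ,
                                                                    drop = FALSE]
  lab_true <- mu + cbind(stats::rnorm(n, 0, cfg$color_sd[1L]),
                         stats::rnorm(n, 0, cfg$color_sd[2L]),
                         stats::rnorm(n, 0, cfg$color_sd[3L]))
  is_white <- stats::runif(n) < cfg$p_white_morph
  if (any(is_white)) {
    nw <- sum(is_white)
    wl <- pmin(99, pmax(80, stats::rnorm(nw, cfg$white_L_mean, cfg$white_L_sd)))
    wc <- stats::runif(nw, cfg$white_chroma_range[1L],
                       cfg$white_chroma_range[2L])
    wh <- stats::runif(nw, cfg$white_hue_range[1L], cfg$white_hue_range[2L])
    lab_true[is_white, ] <- lch_to_lab(cbind(wl, wc, wh))
  }
  lighting <- sample(names(cfg$lighting_probs), n, replace = TRUE,
                     prob = cfg$lighting_probs)
  lab_obs <- lab_true
  lab_obs[, 1L] <- pmin(100, lab_obs[, 1L] +
                          ifelse(lighting == "full", cfg$full_sun_L_shift, 0))
  lch_obs <- lab_to_lch(lab_obs)

  n_img <- 1L + stats::rbinom(n, 1L, cfg$p_multi_image)
  rows <- rep(seq_len(n), n_img)
  img_no <- sequence(n_img)
  observations <- data.frame(
    observation_id = oid[rows], latitude = lat[rows], longitude = lon[rows],
    date = date[rows],
    image_id = sprintf("%s_img%d", oid[rows], img_no),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    observation_id = oid, latitude = lat, longitude = lon, date = date,
    region = region, lighting = lighting, is_white_morph = is_white,
    n_images = n_img,
    L_true = lab_true[, 1L], a_true = lab_true[, 2L], b_true = lab_true[, 3L],
    L = lab_obs[, 1L], a = lab_obs[, 2L], b = lab_obs[, 3L],
    C = lch_obs[, 2L], h = lch_obs[, 3L],
    stringsAsFactors = FALSE)
  list(observations = observations, truth = truth)
}

# background palette: hues stay in (50, 250) even under +/-15 channel noise,
# so background pixels never enter the purple segmentation windows
.bg_green <- c(75, 105, 55)
.bg_olive <- c(90, 90, 45)

#' Render a synthetic flower image and its true mask
#'
#' Draws disc-shaped "flowers" of the observed color (with optional
#' per-pixel 8-bit jitter) on a green/olive textured background. The mask
#' marks exactly the flower pixels; discs are added until flower pixels
#' cover at least 5% of the image.
#'
#' @param lab_color length-3 observed CIELAB color of the flowers.
#' @param cfg a [synth_config()] (uses `image_size`, `pixel_jitter`).
#' @param seed optional seed; `NULL` uses the current RNG state (as when
#'   called inside [generate_cohort()]).
#' @return list with `image` (size x size x 3 array, 0--255) and `mask`
#'   (the ground-truth [pixel_mask()]).
#' @export
render_image <- function(lab_color, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, .render_image_impl(lab_color, cfg))
}

.render_image_impl <- function(lab_color, cfg) {
  s <- cfg$image_size
  npx <- s * s
  # textured background: mix of green and olive with uniform channel noise
  pick <- stats::runif(npx) < 0.65
  base <- matrix(0, npx, 3L)
  base[pick, ] <- matrix(.bg_green, sum(pick), 3L, byrow = TRUE)
  base[!pick, ] <- matrix(.bg_olive, sum(!pick), 3L, byrow = TRUE)
  bg <- base + matrix(stats::runif(npx * 3L, -15, 15), npx, 3L)

  # flower discs until coverage >= 5%
  mask <- matrix(0L, s, s)
  cx_grid <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  cy_grid <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  n_discs <- sample(1:3, 1L)
  repeat {
    for (i in seq_len(n_discs)) {
      r <- stats::runif(1L, 0.12, 0.2) * s
      cx <- stats::runif(1L, r, s - r); cy <- stats::runif(1L, r, s - r)
      mask[(cx_grid - cx)^2 + (cy_grid - cy)^2 <= r^2] <- 1L
    }
    if (sum(mask) >= 0.05 * npx) break
    n_discs <- 1L
  }

  flower_rgb <- as.numeric(lab_to_srgb(lab_color))
  px <- bg
  sel <- as.vector(mask) == 1L
  nf <- sum(sel)
  jit <- if (cfg$pixel_jitter > 0)
    matrix(stats::rnorm(nf * 3L, 0, cfg$pixel_jitter), nf, 3L) else 0
  px[sel, ] <- matrix(flower_rgb, nf, 3L, byrow = TRUE) + jit
  px <- round(pmin(pmax(px, 0), 255))
  img <- array(0L, c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(as.integer(px[, ch]), s, s)
  list(image = img, mask = pixel_mask(mask))
}

#' Simulate two-rater lighting annotations
#'
#' Each of two simulated raters reports an image's true lighting category,
#' independently flipping to one of the other two categories with
#' probability `rater_noise` and answering `"NAN"` with probability
#' `p_rater_nan`.
#'
#' @param truth the truth data.frame from [generate_observations()].
#' @param observations the per-image observation table (image ids inherit
#'   their observation's lighting).
#' @param cfg a [synth_config()] (uses `rater_noise`, `p_rater_nan`).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `image_id`, `rater_id`, `category`.
#' @export
generate_rater_annotations <- function(truth, observations, cfg,
                                       seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, {
    true_cat <- truth$lighting[match(observations$observation_id,
                                     truth$observation_id)]
    cats <- c("shade", "partial", "full")
    one_rater <- function(rater) {
      m <- length(true_cat)
      rep_cat <- true_cat
      flip <- stats::runif(m) < cfg$rater_noise
      if (any(flip))
        rep_cat[flip] <- vapply(true_cat[flip], function(tc)
          sample(setdiff(cats, tc), 1L), character(1L))
      rep_cat[stats::runif(m) < cfg$p_rater_nan] <- "NAN"
      data.frame(image_id = observations$image_id, rater_id = rater,
                 category = rep_cat, stringsAsFactors = FALSE)
    }
    out <- rbind(one_rater("rater1"), one_rater("rater2"))
    rownames(out) <- NULL
    out
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Emits everything the pipeline consumes: PNG images, ground-truth mask
#' JSONs, the observation table, two-rater lighting annotations, and the
#' ground-truth table. All files are produced under one seeded RNG stream,
#' so identical configurations yield byte-identical cohorts.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed). Writes
#'   `images/<image_id>.png`, `truth_masks/<image_id>.json`,
#'   `observations.csv`, `annotations.csv`, `ground_truth.csv`.
#' @return invisibly, the list from [generate_observations()] plus
#'   `annotations`.
#' @export
generate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth_masks"), recursive = TRUE,
             showWarnings = FALSE)
  out <- with_seed(cfg$seed, {
    gen <- .generate_observations_impl(cfg)
    obs <- gen$observations; truth <- gen$truth
    lab_obs <- as.matrix(truth[, c("L", "a", "b")])
    for (i in seq_len(nrow(obs))) {
      row <- match(obs$observation_id[i], truth$observation_id)
      ri <- .render_image_impl(lab_obs[row, ], cfg)
      write_image_png(ri$image,
                      file.path(dir, "images", paste0(obs$image_id[i], ".png")))
      write_mask(ri$mask,
                 file.path(dir, "truth_masks", paste0(obs$image_id[i], ".json")))
    }
    ann <- generate_rater_annotations(truth, obs, cfg, seed = NULL)
    list(observations = obs, truth = truth, annotations = ann)
  })
  utils::write.csv(out$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(out$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(out$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(out)
}
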