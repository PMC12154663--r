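# End-to-end orchestration: segment -> phenotype -> sample -> aggregate ->
# analyze, with a run manifest reconciling counts at every stage boundary.
# All outputs are deterministic given the configuration and seeds (no
# timestamps), so repeated runs are byte-identical.

.stage_stop <- function(stage, ...) {
  stop("stage ", stage, ": ", ..., call. = FALSE)
}

#' Run the full color-cline analysis pipeline
#'
#' Executes, in order: threshold segmentation of every image, per-image
#' phenotype extraction (geometric median in CIELAB), sampling of one image
#' per observation, km-grid aggregation, and the analysis battery (fixed
#' west/east Hotelling test, sliding breakpoint scan, k-means cluster
#' profile, hue-outlier screen, and — when annotations are present — the
#' lighting-bias validation). A run manifest with seeds, configuration, and
#' per-stage counts is written last; counts reconcile (images in =
#' phenotyped + failed).
#'
#' @param input_dir cohort directory containing `images/` and
#'   `observations.csv` (and optionally `annotations.csv`), e.g. as written
#'   by [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the per-observation image sampling and the
#'   k-means initialization.
#' @param segmenter a [segmenter_config()].
#' @param masks_dir optional directory of precomputed mask JSONs; when
#'   supplied the segmentation stage is skipped and these masks are used.
#' @param cell_km grid-cell side for spatial aggregation (km).
#' @param split_longitude fixed regional split for the west/east test.
#' @param scan_points,min_group breakpoint-scan resolution and minimum group
#'   size.
#' @param kmeans_restarts random restarts for [kmeans_two()].
#' @return invisibly, a list with the manifest and all in-memory stage
#'   results. Files written under `out_dir`: `masks/`, `phenotypes.csv`,
#'   `failures.csv`, `phenotypes_sampled.csv`, `grid.csv`, `scan.csv`,
#'   `profile.csv`, `analysis.json`, `config.json`, `manifest.json`.
#' @export
run_pipeline <- function(input_dir, out_dir, seed,
                         segmenter = segmenter_config(),
                         masks_dir = NULL,
                         cell_km = 200, split_longitude = -100,
                         scan_points = 1000L, min_group = 100L,
                         kmeans_restarts = 10L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  images_dir <- file.path(input_dir, "images")
  obs_file <- file.path(input_dir, "observations.csv")
  if (!dir.exists(images_dir))
    .stage_stop("segment", "missing input directory 'images': ", images_dir)
  if (!file.exists(obs_file))
    .stage_stop("segment", "missing input file 'observations': ", obs_file)
  observations <- utils::read.csv(obs_file, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  config <- list(seed = as.integer(seed), segmenter = unclass(segmenter),
                 cell_km = cell_km, split_longitude = split_longitude,
                 scan_points = scan_points, min_group = min_group,
                 kmeans_restarts = kmeans_restarts,
                 external_masks = !is.null(masks_dir))
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # -- segment ---------------------------------------------------------------
  if (is.null(masks_dir)) {
    masks_dir <- file.path(out_dir, "masks")
    dir.create(masks_dir, showWarnings = FALSE)
    for (iid in observations$image_id) {
      img_path <- file.path(images_dir, paste0(iid, ".png"))
      if (!file.exists(img_path))
        .stage_stop("segment", "missing image for id ", iid)
      mask <- threshold_segment(read_image_png(img_path), segmenter)
      write_mask(mask, file.path(masks_dir, paste0(iid, ".json")))
    }
  } else if (!dir.exists(masks_dir)) {
    .stage_stop("phenotype", "missing input directory 'masks': ", masks_dir)
  }

  # -- phenotype -------------------------------------------------------------
  ph <- phenotype_table(observations, images_dir, masks_dir)
  phen <- merge(ph$phenotypes,
                unique(observations[, c("image_id", "latitude", "longitude",
                                        "date")]),
                by = "image_id", sort = TRUE)
  phen <- phen[order(phen$observation_id, phen$image_id), ]
  rownames(phen) <- NULL
  utils::write.csv(phen, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(ph$failures, file.path(out_dir, "failures.csv"),
                   row.names = FALSE)

  # -- sample one image per observation --------------------------------------
  sampled <- sample_one_image_per_observation(phen, seed = seed)
  utils::write.csv(sampled, file.path(out_dir, "phenotypes_sampled.csv"),
                   row.names = FALSE)
  if (nrow(sampled) == 0L) .stage_stop("sample", "no phenotypes to analyze")

  # -- aggregate -------------------------------------------------------------
  grid <- bin_to_grid(sampled, cell_km = cell_km)
  utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)

  # -- analyze ---------------------------------------------------------------
  lab <- as.matrix(sampled[, c("L", "a", "b")])
  region <- assign_region(sampled$longitude, split = split_longitude)
  regional <- hotelling_t2(lab[region == "west", , drop = FALSE],
                           lab[region == "east", , drop = FALSE])
  scan <- sliding_breakpoint_scan(lab, sampled$longitude,
                                  n_points = scan_points,
                                  min_group = min_group)
  labels <- kmeans_two(lab, seed = seed, n_restarts = kmeans_restarts)
  profile <- cluster_profile(labels, sampled$longitude,
                             n_points = scan_points)
  outliers <- classify_hue_outliers(sampled)
  utils::write.csv(data.frame(longitude = scan$longitudes, t2 = scan$t2),
                   file.path(out_dir, "scan.csv"), row.names = FALSE)
  utils::write.csv(data.frame(longitude = profile$window_centers,
                              mean_assignment = profile$mean_assignment),
                   file.path(out_dir, "profile.csv"), row.names = FALSE)

  ann_file <- file.path(input_dir, "annotations.csv")
  lighting <- NULL
  if (file.exists(ann_file)) {
    annotations <- utils::read.csv(ann_file, stringsAsFactors = FALSE)
    lighting <- lighting_analysis(phen, annotations, split = split_longitude)
  }

  analysis <- list(
    regional = list(split_longitude = split_longitude,
                    t2 = regional$t2, f = regional$f, df1 = regional$df1,
                    df2 = regional$df2, p_value = regional$p_value,
                    partial_eta2 = regional$partial_eta2,
                    n_west = regional$n1, n_east = regional$n2),
    scan = list(peak_longitude = scan$peak_longitude,
                peak_t2 = scan$peak$t2,
                peak_partial_eta2 = scan$peak$partial_eta2,
                n_points = scan$n_points, min_group = scan$min_group,
                multiple_testing = "uncorrected exploratory localization"),
    cluster = list(crossing_longitude = profile$crossing_longitude,
                   n_cluster1 = sum(labels)),
    hue_outliers = list(n_flagged = outliers$n_flagged,
                        fraction = outliers$fraction,
                        window = outliers$window))
  if (!is.null(lighting)) {
    fullL <- lighting$factorial$coefficients
    fullL <- fullL[fullL$component == "L" & fullL$term == "lightingfull", ]
    analysis$lighting <- list(
      kappa = lighting$kappa$kappa,
      kappa_ci = c(lighting$kappa$ci_low, lighting$kappa$ci_high),
      percent_agreement = lighting$kappa$percent_agreement,
      chi_square = lighting$chi_square$statistic,
      chi_square_p = lighting$chi_square$p_value,
      full_sun_L_beta = fullL$estimate,
      manova = lighting$factorial$manova,
      n_rated = lighting$n_rated, n_consensus = lighting$n_consensus)
  }
  jsonlite::write_json(analysis, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("floracline")),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = as.integer(seed),
    counts = list(images_in = nrow(observations),
                  phenotyped = nrow(phen),
                  failed = nrow(ph$failures),
                  observations_sampled = nrow(sampled),
                  grid_cells = nrow(grid)),
    outputs = sort(c("config.json", "phenotypes.csv", "failures.csv",
                     "phenotypes_sampled.csv", "grid.csv", "scan.csv",
                     "profile.csv", "analysis.json")))
  stopifnot(manifest$counts$images_in ==
              manifest$counts$phenotyped + manifest$counts$failed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, phenotypes = phen,
                 failures = ph$failures, sampled = sampled, grid = grid,
                 regional = regional, scan = scan, profile = profile,
                 outliers = outliers, lighting = lighting))
}
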