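test_that("config validation names the offending field", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(seed = 1, n_observations = -5), "n_observations")
  expect_error(synth_config(seed = 1, p_white_morph = 2), "p_white_morph")
  expect_error(synth_config(seed = 1, longitude_range = c(-61, -135)),
               "longitude_range")
  expect_error(synth_config(seed = 1,
                            lighting_probs = c(shade = 0.5, partial = 0.4,
                                               full = 0.4)),
               "lighting_probs")
})

test_that("an empty cohort is an empty table", {
  g <- generate_observations(synth_config(seed = 4, n_observations = 0))
  expect_equal(nrow(g$observations), 0)
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(seed = 123, n_observations = 200)
  g1 <- generate_observations(cfg)
  g2 <- generate_observations(cfg)
  expect_identical(g1, g2)
  g3 <- generate_observations(synth_config(seed = 124, n_observations = 200))
  expect_false(identical(g1$truth$L, g3$truth$L))
})

test_that("planted regional means are recovered at large n", {
  g <- generate_observations(synth_config(seed = 55, n_observations = 10000))
  t_ <- g$truth[!g$truth$is_white_morph, ]
  dL <- mean(t_$L_true[t_$region == "west"]) -
    mean(t_$L_true[t_$region == "east"])
  expect_lt(abs(dL - (-13)), 0.5)
  # hue similar between regions, lightness starkly different (LCh contrast)
  lch <- lab_to_lch(cbind(t_$L_true, t_$a_true, t_$b_true))
  hw <- mean(lch[t_$region == "west", "h"])
  he <- mean(lch[t_$region == "east", "h"])
  expect_lt(abs(hw - he), 3)
  expect_gt(abs(dL), 10)
})

test_that("white morphs appear at the configured rate", {
  g <- generate_observations(synth_config(seed = 77, n_observations = 10000))
  frac <- mean(g$truth$is_white_morph)
  se <- sqrt(0.007 * 0.993 / 10000)
  expect_lt(abs(frac - 0.007), 1.96 * se)
  whites <- g$truth[g$truth$is_white_morph, ]
  expect_true(all(whites$L_true > 75))
  expect_true(all(whites$h > 50 & whites$h < 250))
})

test_that("full sun lightens the observed color but not the true phenotype", {
  g <- generate_observations(synth_config(seed = 60, n_observations = 4000))
  t_ <- g$truth[!g$truth$is_white_morph, ]
  shift <- t_$L - t_$L_true
  expect_true(all(shift[t_$lighting == "full"] > 0))
  expect_true(all(shift[t_$lighting != "full"] == 0))
  east_full <- t_$region == "east" & t_$lighting == "full"
  east_shade <- t_$region == "east" & t_$lighting == "shade"
  expect_equal(mean(t_$L[east_full]) - mean(t_$L[east_shade]), 10,
               tolerance = 0.1)
})

test_that("rendered images carry their exact mask and color", {
  cfg0 <- synth_config(seed = 5, pixel_jitter = 0)
  truth_lab <- c(58, 25, -25)
  ri <- render_image(truth_lab, cfg0, seed = 9)
  expect_s3_class(ri$mask, "pixel_mask")
  expect_gte(mean(ri$mask$labels), 0.05)
  px <- extract_flower_pixels(ri$image, ri$mask)
  # zero jitter: all flower pixels identical, median exact up to 8-bit rounding
  expect_equal(nrow(unique(px)), 1)
  expect_lt(sqrt(sum((geometric_median(px) - truth_lab)^2)), 0.5)
  # default jitter: phenotype still recovered closely
  cfg2 <- synth_config(seed = 5)
  err <- vapply(1:25, function(s) {
    r <- render_image(truth_lab, cfg2, seed = s)
    ph <- phenotype_image(r$image, r$mask)
    sqrt(sum((c(ph$L, ph$a, ph$b) - truth_lab)^2))
  }, numeric(1))
  expect_lt(max(err), 1.5)
})

test_that("noise-free raters agree perfectly and NAN rows drop cleanly", {
  cfg <- synth_config(seed = 31, n_observations = 300, rater_noise = 0,
                      p_rater_nan = 0.02)
  g <- generate_observations(cfg)
  ann <- generate_rater_annotations(g$truth, g$observations, cfg, seed = 2)
  r1 <- ann[ann$rater_id == "rater1", ]
  r2 <- ann[ann$rater_id == "rater2", ]
  r2 <- r2[match(r1$image_id, r2$image_id), ]
  k <- cohens_kappa(r1$category, r2$category)
  expect_equal(k$kappa, 1)
  expect_lt(k$n_items, nrow(r1))  # some NAN items were excluded
})

test_that("noisy raters degrade agreement toward chance", {
  cfg <- synth_config(seed = 32, n_observations = 2000, rater_noise = 2 / 3,
                      p_rater_nan = 0)
  g <- generate_observations(cfg)
  ann <- generate_rater_annotations(g$truth, g$observations, cfg, seed = 3)
  r1 <- ann[ann$rater_id == "rater1", ]
  r2 <- ann[ann$rater_id == "rater2", ]
  r2 <- r2[match(r1$image_id, r2$image_id), ]
  k <- cohens_kappa(r1$category, r2$category)
  expect_lt(abs(k$kappa), 0.08)
})

test_that("a cohort on disk is reproducible byte for byte", {
  cfg <- synth_config(seed = 21, n_observations = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  # files cover every image id
  obs <- read.csv(file.path(d1, "observations.csv"))
  expect_setequal(list.files(file.path(d1, "images")),
                  paste0(obs$image_id, ".png"))
  expect_setequal(list.files(file.path(d1, "truth_masks")),
                  paste0(obs$image_id, ".json"))
})
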