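# Fixture shared with an independent implementation: the expected T2/F/p
# below were computed for these exact matrices with pingouin's two-sample
# multivariate t-test and frozen here.
.hot_A <- matrix(c(
  60.5, 17.7, -18.5, 57.5, 21.6, -20.4, 61, 19.6, -11.9, 54.7, 25.2, -10.9,
  49.4, 18.9, -20.5, 57.5, 18.9, -30.6, 45.2, 25.3, -21.2, 47.9, 19.3, -15.1,
  62.6, 18.3, -21, 47.9, 21.8, -22.6), ncol = 3, byrow = TRUE)
.hot_B <- matrix(c(
  61.8, 17.8, -10.9, 57.6, 17, -21.9, 56.9, 11.6, -24.7, 60.1, 15.8, -16.4,
  63, 12.1, -20.5, 61.7, 11.8, -9.2, 58.3, 17.6, -13.7, 56.9, 21.3, -12.4,
  60.4, 16.1, -12.3, 60.4, 3, -13.9, 58.5, 15.7, -12.7, 65.6, 12.1, -9.8),
  ncol = 3, byrow = TRUE)

test_that("Hotelling's T2 matches a cross-implementation oracle", {
  h <- hotelling_t2(.hot_A, .hot_B)
  expect_equal(h$t2, 21.69104374181447, tolerance = 1e-10)
  expect_equal(h$f, 6.507313122544342, tolerance = 1e-10)
  expect_equal(h$p_value, 0.0035717646236132776, tolerance = 1e-8)
  expect_equal(h$df1, 3); expect_equal(h$df2, 18)
  expect_equal(h$partial_eta2, h$t2 / (h$t2 + 20))
})

test_that("identical groups give T2 = 0 and p = 1", {
  h <- hotelling_t2(.hot_A, .hot_A)
  expect_equal(h$t2, 0, tolerance = 1e-9)
  expect_equal(h$p_value, 1)
})

test_that("the univariate reduction equals the squared pooled t statistic", {
  set.seed(8)
  for (i in 1:100) {
    x <- matrix(rnorm(sample(5:30, 1), mean = runif(1, -1, 1)), ncol = 1)
    y <- matrix(rnorm(sample(5:30, 1)), ncol = 1)
    h <- hotelling_t2(x, y)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(h$t2, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(h$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("T2 is invariant under a common invertible affine transform", {
  set.seed(12)
  M <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, -0.4, 0.1, 3), 3)
  v <- c(5, -2, 7)
  h1 <- hotelling_t2(.hot_A, .hot_B)
  tf <- function(X) sweep(X %*% t(M), 2, v, "+")
  h2 <- hotelling_t2(tf(.hot_A), tf(.hot_B))
  expect_equal(h2$t2, h1$t2, tolerance = 1e-6)
})

test_that("degenerate Hotelling inputs are rejected", {
  expect_error(hotelling_t2(.hot_A[1:3, ], .hot_B), "observations")
  sing <- cbind(.hot_A[, 1], .hot_A[, 1], .hot_A[, 2])
  expect_error(hotelling_t2(sing, sing + 1), "singular")
})

test_that("Pillai's trace for a 2-level factor agrees with T2", {
  set.seed(23)
  Y <- rbind(matrix(rnorm(60, 0), ncol = 3),
             matrix(rnorm(75, 0.8), ncol = 3))
  grp <- factor(rep(c("w", "e"), c(20, 25)))
  h <- hotelling_t2(Y[grp == "w", ], Y[grp == "e", ])
  V <- summary(stats::manova(Y ~ grp))$stats["grp", "Pillai"]
  expect_equal(V, h$t2 / (h$t2 + nrow(Y) - 2), tolerance = 1e-10)
})

test_that("the breakpoint scan recovers a planted divide", {
  g <- generate_observations(synth_config(seed = 88, n_observations = 5000))
  lab <- as.matrix(g$truth[, c("L", "a", "b")])
  sc <- sliding_breakpoint_scan(lab, g$truth$longitude)
  expect_length(sc$longitudes, 1000)
  expect_equal(range(sc$longitudes), range(g$truth$longitude))
  expect_lt(abs(sc$peak_longitude - (-100)), 1)
  # statistic undefined wherever a side has fewer than min_group observations
  k <- findInterval(sc$longitudes, sort(g$truth$longitude), left.open = TRUE)
  expect_true(all(is.na(sc$t2[k < 100 | (5000 - k) < 100])))
  expect_true(all(!is.na(sc$t2[k >= 100 & (5000 - k) >= 100])))
})

test_that("null data yield scan peaks consistent with permutation", {
  set.seed(17)
  n <- 600
  lon <- runif(n, -135, -61)
  lab <- matrix(rnorm(3 * n, 60, 5), ncol = 3)
  sc <- sliding_breakpoint_scan(lab, lon, min_group = 50)
  # permutation reference for the maximum scan statistic
  perm_max <- replicate(30, {
    max(sliding_breakpoint_scan(lab, sample(lon), min_group = 50)$t2,
        na.rm = TRUE)
  })
  expect_lt(max(sc$t2, na.rm = TRUE), max(perm_max) * 1.5)
})

test_that("scans without a feasible split are errors", {
  lab <- matrix(rnorm(450), ncol = 3)
  expect_error(sliding_breakpoint_scan(lab, rep(-120, 150)), "min_group")
  expect_error(sliding_breakpoint_scan(lab[1:50, ], runif(50, -120, -60)),
               "min_group")
})

test_that("k-means recovers well-separated blobs with canonical labels", {
  set.seed(9)
  tb <- two_blobs()
  for (s in c(1, 2, 3)) {
    lbl <- kmeans_two(tb$lab, seed = s)
    expect_identical(lbl, tb$membership)  # darker blob always labeled 1
  }
  expect_error(kmeans_two(matrix(1, 10, 3), seed = 1), "distinct")
})

test_that("k-means solution beats random label assignments", {
  sse <- function(X, lbl) {
    sum(vapply(unique(lbl), function(g) {
      sub <- X[lbl == g, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  set.seed(33)
  for (i in 1:20) {
    X <- matrix(rnorm(3 * 30, sd = 3), ncol = 3)
    lbl <- kmeans_two(X, seed = i)
    best <- sse(X, lbl)
    rand <- vapply(1:200, function(j) {
      rl <- rbinom(30, 1, 0.5)
      if (length(unique(rl)) < 2) return(Inf)
      sse(X, rl)
    }, numeric(1))
    expect_lte(best, min(rand))
  }
})

test_that("cluster profiles trace a step in the labels", {
  lon <- seq(-130, -65, length.out = 2000)
  all_one <- cluster_profile(rep(1L, 2000), lon, n_points = 200)
  expect_true(all(all_one$mean_assignment == 1, na.rm = TRUE))
  step <- as.integer(lon < -100)
  pr <- cluster_profile(step, lon, window_halfwidth = 1, n_points = 500)
  expect_lt(abs(pr$crossing_longitude - (-100)), 1)
  # monotone non-increasing for a monotone cline (up to float noise)
  expect_true(all(diff(pr$mean_assignment) <= 1e-12, na.rm = TRUE))
})

test_that("hue outlier rule flags the strict interior of [50, 250]", {
  out <- classify_hue_outliers(c(300, 136, 50, 250, 49.9, 250.1, 0))
  expect_identical(out$flagged,
                   c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$n_flagged, 1)
  df <- data.frame(h = c(100, 300))
  expect_equal(classify_hue_outliers(df)$fraction, 0.5)
})

test_that("Cohen's kappa matches hand-computed fixtures", {
  a <- c(rep("shade", 25), rep("full", 25))
  b <- c(rep("shade", 20), rep("full", 5), rep("shade", 10), rep("full", 15))
  # confusion [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa, 0.4)
  expect_equal(k$percent_agreement, 70)
  expect_equal(k$n_items, 50)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)

  ident <- cohens_kappa(rep(c("shade", "partial", "full"), 20),
                        rep(c("shade", "partial", "full"), 20))
  expect_equal(ident$kappa, 1)
})

test_that("independent random ratings give kappa near zero", {
  set.seed(15)
  cats <- c("shade", "partial", "full")
  a <- sample(cats, 3000, replace = TRUE)
  b <- sample(cats, 3000, replace = TRUE)
  k <- cohens_kappa(a, b)
  expect_true(k$ci_low < 0 && 0 < k$ci_high)
  expect_lt(abs(k$kappa), 0.08)
})

test_that("kappa excludes NAN items and rejects degenerate inputs", {
  a <- c("shade", "NAN", "full", "partial", NA, "shade")
  b <- c("shade", "full", "NAN", "partial", "shade", "full")
  k <- cohens_kappa(a, b)
  expect_equal(k$n_items, 3)
  expect_error(cohens_kappa(rep("shade", 5), rep("shade", 5)), "2 observed")
  expect_error(cohens_kappa(rep("NAN", 3), rep("shade", 3)), "no items")
  expect_error(cohens_kappa(c("shade", "sun"), c("shade", "shade")),
               "unknown categories")
})

test_that("chi-square independence matches textbook computations", {
  even <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  same_rows <- chi_square_independence(rbind(c(12, 30, 18), c(12, 30, 18)))
  expect_equal(same_rows$statistic, 0)
  expect_equal(same_rows$df, 2)
  hand <- chi_square_independence(matrix(c(30, 10, 10, 30), 2))
  expect_equal(hand$statistic, 20)  # expected counts all 20
  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 4))), "margins")
})

test_that("factorial analysis is Type II with treatment coding", {
  set.seed(26)
  # balanced design: Type II and Type III sums of squares coincide
  region <- rep(c("west", "east"), each = 30)
  lighting <- rep(rep(c("shade", "partial", "full"), each = 10), 2)
  Y <- matrix(rnorm(180, 60, 5), ncol = 3)
  Y[, 1] <- Y[, 1] + ifelse(lighting == "full", 10, 0)
  fa <- factorial_analysis(Y, region, lighting)
  d <- data.frame(y = Y[, 1],
                  region = relevel(factor(region), "east"),
                  lighting = relevel(factor(lighting), "shade"))
  a3 <- car::Anova(lm(y ~ region * lighting, data = d,
                      contrasts = list(region = "contr.sum",
                                       lighting = "contr.sum")),
                   type = "III")
  ours <- fa$anova[fa$anova$component == "L", ]
  expect_equal(ours$sum_sq,
               a3[["Sum Sq"]][match(c("region", "lighting", "region:lighting"),
                                    rownames(a3))],
               tolerance = 1e-8)
  # treatment-coded coefficient: full-sun effect on L relative to shade
  cf <- fa$coefficients
  beta <- cf[cf$component == "L" & cf$term == "lightingfull", ]
  expect_lt(abs(beta$estimate - 10), 3 * beta$se)
  # MANOVA table covers the three effects with Pillai in range
  expect_setequal(fa$manova$term, c("region", "lighting", "region:lighting"))
  expect_true(all(fa$manova$pillai >= 0))
  expect_true(all(fa$manova$partial_eta2 >= 0 & fa$manova$partial_eta2 < 1))
})

test_that("factorial analysis rejects empty cells by name", {
  region <- c(rep("west", 10), rep("east", 10))
  lighting <- c(rep("shade", 10), rep(c("partial", "full"), 5))
  Y <- matrix(rnorm(60), ncol = 3)
  expect_error(factorial_analysis(Y, region, lighting),
               "empty design cell: west x partial|empty design cell: east x shade")
  expect_error(factorial_analysis(Y, rep("west", 20), lighting),
               "factors must vary")
})

test_that("MANOVA Pillai F approximation reproduces published df structure", {
  # 2-level and 3-level factors with n = 371 consensus items give the
  # classical (3, 363) and (6, 728) df pairs
  set.seed(41)
  n <- 371
  region <- sample(c("west", "east"), n, replace = TRUE)
  lighting <- sample(c("shade", "partial", "full"), n, replace = TRUE)
  Y <- matrix(rnorm(3 * n), ncol = 3)
  fa <- factorial_analysis(Y, region, lighting)
  expect_equal(fa$manova$df1[fa$manova$term == "region"], 3)
  expect_equal(fa$manova$df2[fa$manova$term == "region"], 363)
  expect_equal(fa$manova$df1[fa$manova$term == "lighting"], 6)
  expect_equal(fa$manova$df2[fa$manova$term == "lighting"], 728)
})
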