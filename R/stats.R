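# Inferential battery: Hotelling's T-squared with effect size, the sliding
# longitudinal breakpoint scan, k-means transition profiling, hue-window
# outlier screening, and the lighting-bias validation tests (Cohen's kappa,
# chi-square, factorial ANOVA/MANOVA).

#' Two-sample Hotelling's T-squared test
#'
#' Multivariate extension of the pooled two-sample t-test, comparing mean
#' vectors of two groups under a common covariance:
#' \deqn{T^2 = \frac{n m}{n + m} d' S^{-1} d}
#' with d the mean difference and S the pooled covariance. The F reference is
#' \eqn{F = T^2 (n + m - p - 1) / (p (n + m - 2))} on (p, n + m - p - 1)
#' degrees of freedom. Effect size is the multivariate partial eta-squared
#' \eqn{T^2 / (T^2 + n + m - 2)}.
#'
#' @param group_a,group_b numeric matrices (n x p and m x p) with matching
#'   columns; for color analyses, rows are observations and columns L, a, b.
#' @return an object of class `hotelling_test`: list with `t2`, `f`, `df1`,
#'   `df2`, `p_value`, `partial_eta2`, `n1`, `n2`, `p` (number of variables),
#'   `mean_diff`.
#' @export
hotelling_t2 <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  if (ncol(A) != ncol(B)) stop("groups must have the same variables",
                               call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("groups must contain finite values", call. = FALSE)
  p <- ncol(A); n <- nrow(A); m <- nrow(B)
  if (n < p + 1 || m < p + 1)
    stop("each group needs at least p + 1 = ", p + 1, " observations",
         call. = FALSE)
  d <- colMeans(A) - colMeans(B)
  S <- ((n - 1) * stats::cov(A) + (m - 1) * stats::cov(B)) / (n + m - 2)
  sol <- tryCatch(solve(S, d), error = function(e)
    stop("pooled covariance is singular; remove collinear variables",
         call. = FALSE))
  t2 <- (n * m / (n + m)) * drop(crossprod(d, sol))
  .hotelling_result(t2, n, m, p, d)
}

.hotelling_result <- function(t2, n, m, p, mean_diff = NULL) {
  df1 <- p; df2 <- n + m - p - 1
  f <- t2 * df2 / (p * (n + m - 2))
  structure(list(t2 = t2, f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 partial_eta2 = t2 / (t2 + n + m - 2),
                 n1 = n, n2 = m, p = p, mean_diff = mean_diff),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Hotelling's T2 = %.2f, F(%d, %d) = %.2f, p = %.3g, partial eta2 = %.1f%% (n = %d vs %d)\n",
    x$t2, x$df1, x$df2, x$f, x$p_value, 100 * x$partial_eta2, x$n1, x$n2))
  invisible(x)
}

# T2 from first and second cumulative moments of the two sides of a split;
# returns NA if the pooled covariance is numerically singular.
.t2_from_moments <- function(n, m, sum_w, sum_e, cp_w, cp_e) {
  mw <- sum_w / n; me <- sum_e / m
  Sw <- (cp_w - n * tcrossprod(mw)) / (n - 1)
  Se <- (cp_e - m * tcrossprod(me)) / (m - 1)
  S <- ((n - 1) * Sw + (m - 1) * Se) / (n + m - 2)
  d <- mw - me
  sol <- tryCatch(solve(S, d), error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  (n * m / (n + m)) * drop(crossprod(d, sol))
}

#' Sliding Hotelling's T-squared breakpoint scan
#'
#' Scans candidate split longitudes, evenly spaced (inclusive endpoints)
#' between the observed minimum and maximum longitude, splitting the data at
#' each (west = strictly less) and computing the two-sample Hotelling T2 on
#' the color components wherever both sides hold at least `min_group`
#' observations. The breakpoint estimate is the arg-max longitude; ties are
#' broken toward the westmost candidate. No multiplicity correction is
#' applied across scan positions: the scan is exploratory localization, not
#' simultaneous testing.
#'
#' @param lab an n x p matrix of color components (typically CIELAB).
#' @param longitude length-n numeric vector of decimal degrees.
#' @param n_points number of evenly spaced candidate splits (default 1000).
#' @param min_group minimum observations required on each side (default 100).
#' @return an object of class `breakpoint_scan`: list with `longitudes`
#'   (the scan grid), `t2` (statistic or NA per position), `peak_longitude`,
#'   `peak` (the full `hotelling_test` at the peak), `n_points`, `min_group`,
#'   `n`.
#' @export
sliding_breakpoint_scan <- function(lab, longitude, n_points = 1000L,
                                    min_group = 100L) {
  X <- as.matrix(lab); storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(longitude) != n)
    stop("longitude must align with the color matrix", call. = FALSE)
  if (n < 2L * min_group)
    stop("need at least 2 * min_group observations", call. = FALSE)
  ord <- order(longitude)
  lon_s <- longitude[ord]
  X <- X[ord, , drop = FALSE]

  # cumulative first and second moments along the longitude order
  cs <- apply(X, 2L, cumsum)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cp <- apply(X[, pairs[, 1L], drop = FALSE] * X[, pairs[, 2L], drop = FALSE],
              2L, cumsum)
  tot_s <- cs[n, ]; tot_cp <- cp[n, ]
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pairs[, 1L], pairs[, 2L])] <- v
    M[cbind(pairs[, 2L], pairs[, 1L])] <- v
    M
  }

  grid <- seq(lon_s[1L], lon_s[n], length.out = n_points)
  # number of observations strictly west of each candidate split
  k <- findInterval(grid, lon_s, left.open = TRUE)
  t2 <- rep(NA_real_, n_points)
  for (i in seq_len(n_points)) {
    nw <- k[i]; ne <- n - nw
    if (nw < min_group || ne < min_group) next
    t2[i] <- .t2_from_moments(nw, ne, cs[nw, ], tot_s - cs[nw, ],
                              unpack(cp[nw, ]), unpack(tot_cp - cp[nw, ]))
  }
  if (all(is.na(t2)))
    stop("no candidate split leaves at least min_group = ", min_group,
         " observations on each side", call. = FALSE)
  peak_i <- which.max(t2)  # first maximum = westmost tie
  nw <- k[peak_i]
  structure(list(longitudes = grid, t2 = t2,
                 peak_longitude = grid[peak_i],
                 peak = .hotelling_result(t2[peak_i], nw, n - nw, p),
                 n_points = n_points, min_group = min_group, n = n),
            class = "breakpoint_scan")
}

#' @export
print.breakpoint_scan <- function(x, ...) {
  cat(sprintf(
    "Breakpoint scan over %d longitudes [%.2f, %.2f], n = %d (min_group = %d)\n",
    x$n_points, min(x$longitudes), max(x$longitudes), x$n, x$min_group))
  cat(sprintf("  peak T2 = %.2f at longitude %.3f\n",
              x$peak$t2, x$peak_longitude))
  invisible(x)
}

#' Two-cluster k-means on color components
#'
#' Lloyd's algorithm with k = 2, best of `n_restarts` seeded random
#' initializations by within-cluster sum of squares. Labels are
#' canonicalized so that cluster 1 is the darker cluster (lower mean L,
#' assumed to be the first column): raw k-means labels are arbitrary, and a
#' fixed convention keeps profiles reproducible across seeds.
#'
#' @param labs an n x 3 matrix of CIELAB values (column 1 = L).
#' @param seed integer seed.
#' @param n_restarts number of random initializations (default 10).
#' @return integer vector of labels in {0, 1}; 1 = darker cluster.
#' @export
kmeans_two <- function(labs, seed, n_restarts = 10L) {
  X <- as.matrix(labs); storage.mode(X) <- "double"
  if (nrow(unique(X)) < 2L)
    stop("k-means needs at least 2 distinct points", call. = FALSE)
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(X, centers = 2L, nstart = n_restarts,
                  algorithm = "Lloyd", iter.max = 100L)))
  dark <- which.min(km$centers[, 1L])
  as.integer(km$cluster == dark)
}

#' Sliding-window cluster-assignment profile
#'
#' Averages binary cluster labels over all observations within
#' `window_halfwidth` degrees of each scan longitude, tracing how the
#' proportion assigned to the darker cluster shifts along the gradient.
#'
#' @param labels integer vector of 0/1 cluster labels.
#' @param longitudes aligned numeric vector of decimal degrees.
#' @param window_halfwidth half-width of each window in degrees (default 1).
#' @param n_points number of window centers, evenly spaced over the observed
#'   longitude range (default 1000).
#' @return an object of class `cluster_profile`: list with `window_centers`,
#'   `mean_assignment` (NA for empty windows), `crossing_longitude` (first
#'   center at which the profile drops below 0.5, NA if it never does),
#'   `window_halfwidth`.
#' @export
cluster_profile <- function(labels, longitudes, window_halfwidth = 1,
                            n_points = 1000L) {
  if (length(labels) != length(longitudes))
    stop("labels and longitudes must align", call. = FALSE)
  centers <- seq(min(longitudes), max(longitudes), length.out = n_points)
  prof <- vapply(centers, function(cc) {
    sel <- abs(longitudes - cc) <= window_halfwidth
    if (!any(sel)) NA_real_ else mean(labels[sel])
  }, numeric(1L))
  below <- which(!is.na(prof) & prof < 0.5)
  structure(list(window_centers = centers, mean_assignment = prof,
                 crossing_longitude = if (length(below)) centers[below[1L]]
                                      else NA_real_,
                 window_halfwidth = window_halfwidth),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf(
    "Cluster profile over %d windows (halfwidth %.1f deg); crosses 0.5 at %.3f\n",
    length(x$window_centers), x$window_halfwidth, x$crossing_longitude))
  invisible(x)
}

#' Flag hue-window outliers
#'
#' Wild-type corollas are shades of purple, with LCh hue in 0--50 or
#' 250--360 degrees. Phenotypes whose hue falls strictly inside the
#' complementary window (default \[50, 250\]) are flagged as outliers:
#' typically white-flowered individuals or segmentation failures, whose
#' near-achromatic colors have unstable hue.
#'
#' @param phenotypes a data.frame with column `h`, or a numeric vector of
#'   hue angles in degrees.
#' @param window `c(lo, hi)` hue interval whose strict interior is flagged.
#' @return list with `flagged` (logical vector), `n_flagged`, `fraction`,
#'   `window`.
#' @export
classify_hue_outliers <- function(phenotypes, window = c(50, 250)) {
  h <- if (is.data.frame(phenotypes)) phenotypes$h else phenotypes
  if (is.null(h) || !is.numeric(h))
    stop("phenotypes must supply numeric hue values in column h",
         call. = FALSE)
  flagged <- h > window[1L] & h < window[2L]
  list(flagged = flagged, n_flagged = sum(flagged),
       fraction = mean(flagged), window = window)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement on categorical labels from the k x k confusion
#' matrix: kappa = (p_o - p_e) / (1 - p_e). Items where either rater gave
#' `NA` or the `"NAN"` sentinel are excluded first. The 95% confidence
#' interval uses the asymptotic (Fleiss-Cohen-Everitt) standard error with
#' the normal 1.96 quantile.
#'
#' @param ratings_a,ratings_b aligned character/factor vectors.
#' @param categories the admissible categories, in display order.
#' @return an object of class `kappa_result`: list with `kappa`, `ci_low`,
#'   `ci_high`, `se`, `percent_agreement`, `n_items`, `confusion`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b,
                         categories = c("shade", "partial", "full")) {
  a <- as.character(ratings_a); b <- as.character(ratings_b)
  if (length(a) != length(b)) stop("rating vectors must align", call. = FALSE)
  keep <- !is.na(a) & !is.na(b) & a != "NAN" & b != "NAN"
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no items remain after NAN exclusion", call. = FALSE)
  bad <- setdiff(unique(c(a, b)), categories)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(unique(c(a, b))) < 2L)
    stop("need at least 2 observed categories", call. = FALSE)
  tab <- table(factor(a, categories), factor(b, categories))
  n <- sum(tab)
  pr <- tab / n
  po <- sum(diag(pr))
  prow <- rowSums(pr); pcol <- colSums(pr)
  pe <- sum(prow * pcol)
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance
  k <- nrow(pr)
  termA <- sum(diag(pr) * (1 - (prow + pcol) * (1 - kappa))^2)
  off <- !diag(TRUE, k)
  sums <- outer(pcol, prow, "+")  # [i,j] = p_.i + p_j. for rating pair (i,j)
  termB <- (1 - kappa)^2 * sum(pr[off] * sums[off])
  termC <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, termA + termB - termC) / (n * (1 - pe)^2))
  structure(list(kappa = kappa,
                 ci_low = max(-1, kappa - 1.96 * se),
                 ci_high = min(1, kappa + 1.96 * se),
                 se = se, percent_agreement = 100 * po, n_items = n,
                 confusion = tab),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %.3f (95%% CI %.3f-%.3f), agreement = %.1f%%, n = %d\n",
    x$kappa, x$ci_low, x$ci_high, x$percent_agreement, x$n_items))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' For a region x lighting contingency table of counts (no continuity
#' correction), testing whether lighting composition differs between
#' regions.
#'
#' @param counts a matrix of non-negative counts with positive margins
#'   (typically 2 regions x 3 lighting categories).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative and finite", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all row and column margins must be positive", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Two-way factorial ANOVA and MANOVA on color components
#'
#' Fits `component ~ region * lighting` for each CIELAB component
#' (univariate two-way ANOVAs with interaction) and jointly for all three
#' (MANOVA with Pillai's trace), using Type II sums of squares and treatment
#' coding with stated reference levels. A non-significant interaction
#' indicates the regional color difference is consistent across lighting
#' conditions. Univariate partial eta-squared is SS_effect /
#' (SS_effect + SS_residual); for the MANOVA it is Pillai's V divided by s =
#' min(p, df_effect).
#'
#' @param lab an n x 3 matrix of CIELAB components (columns L, a, b).
#' @param region length-n factor/character with 2 levels.
#' @param lighting length-n factor/character with up to 3 levels
#'   (shade/partial/full).
#' @param ref_region,ref_lighting reference levels for treatment coding
#'   (defaults: east, shade), so e.g. the `lightingfull` coefficient on L is
#'   the full-sun lightening effect relative to shade.
#' @return an object of class `factorial_analysis`: list with `anova`
#'   (long data.frame: component, term, df, sum_sq, f, p_value,
#'   partial_eta2), `coefficients` (data.frame: component, term, estimate,
#'   se, ci_low, ci_high, p_value), `manova` (data.frame: term, pillai, df,
#'   df1, df2, f, p_value, partial_eta2), `cell_counts`, `n`.
#' @export
factorial_analysis <- function(lab, region, lighting,
                               ref_region = "east", ref_lighting = "shade") {
  Y <- as.matrix(lab); storage.mode(Y) <- "double"
  if (ncol(Y) != 3L) stop("lab must have 3 columns", call. = FALSE)
  colnames(Y) <- c("L", "a", "b")
  region <- factor(region); lighting <- factor(lighting)
  if (nlevels(region) < 2L || nlevels(lighting) < 2L)
    stop("both factors must vary", call. = FALSE)
  region <- stats::relevel(region, ref = ref_region)
  lighting <- stats::relevel(lighting, ref = ref_lighting)
  tab <- table(region, lighting)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: ", rownames(tab)[empty[1L]], " x ",
         colnames(tab)[empty[2L]], call. = FALSE)
  }
  d <- data.frame(region = region, lighting = lighting)

  # univariate two-way ANOVAs, Type II
  anova_rows <- list(); coef_rows <- list()
  for (comp in colnames(Y)) {
    d$y <- Y[, comp]
    fit <- stats::lm(y ~ region * lighting, data = d)
    a2 <- car::Anova(fit, type = "II")
    ss_res <- a2[["Sum Sq"]][rownames(a2) == "Residuals"]
    for (term in c("region", "lighting", "region:lighting")) {
      i <- which(rownames(a2) == term)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        component = comp, term = term, df = a2$Df[i],
        sum_sq = a2[["Sum Sq"]][i], f = a2[["F value"]][i],
        p_value = a2[["Pr(>F)"]][i],
        partial_eta2 = a2[["Sum Sq"]][i] / (a2[["Sum Sq"]][i] + ss_res),
        stringsAsFactors = FALSE)
    }
    cs <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    coef_rows[[length(coef_rows) + 1L]] <- data.frame(
      component = comp, term = rownames(cs), estimate = cs[, 1L],
      se = cs[, 2L], ci_low = ci[, 1L], ci_high = ci[, 2L],
      p_value = cs[, 4L], stringsAsFactors = FALSE, row.names = NULL)
  }

  # joint MANOVA, Type II, Pillai's trace with the standard F approximation
  mfit <- stats::lm(Y ~ region * lighting, data = d)
  A <- car::Anova(mfit, type = "II")
  E <- A$SSPE; p <- ncol(Y); err_df <- A$error.df
  man_rows <- lapply(names(A$SSP), function(term) {
    H <- A$SSP[[term]]; q <- A$df[[term]]
    V <- sum(diag(H %*% solve(H + E)))
    s <- min(p, q)
    m1 <- (abs(p - q) - 1) / 2
    n1 <- (err_df - p - 1) / 2
    df1 <- s * (2 * m1 + s + 1); df2 <- s * (2 * n1 + s + 1)
    f <- (df2 / df1) * (V / (s - V))
    data.frame(term = term, pillai = V, df = q, df1 = df1, df2 = df2,
               f = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
               partial_eta2 = V / s, stringsAsFactors = FALSE)
  })

  structure(list(anova = do.call(rbind, anova_rows),
                 coefficients = do.call(rbind, coef_rows),
                 manova = do.call(rbind, man_rows),
                 cell_counts = tab, n = nrow(Y)),
            class = "factorial_analysis")
}

#' @export
print.factorial_analysis <- function(x, ...) {
  cat(sprintf("Two-way factorial analysis (n = %d)\nMANOVA (Pillai):\n", x$n))
  print(x$manova, digits = 4)
  invisible(x)
}

#' Full lighting-bias validation analysis
#'
#' Combines the three lighting checks on a rated image subset: inter-rater
#' agreement (Cohen's kappa) on lighting categories, a chi-square test that
#' lighting composition does not differ between west and east, and the
#' factorial ANOVA/MANOVA of color on region x lighting. The chi-square and
#' factorial tests use the consensus subset: images where both raters chose
#' the same non-NAN category.
#'
#' @param phenotypes data.frame with columns `image_id`, `longitude`, `L`,
#'   `a`, `b` (one row per rated image present in the data).
#' @param annotations data.frame with columns `image_id`, `rater_id`,
#'   `category` (two raters, categories shade/partial/full/NAN).
#' @param split regional split longitude (default -100).
#' @return list with `kappa` ([cohens_kappa()]), `chi_square`
#'   ([chi_square_independence()]), `factorial` ([factorial_analysis()]),
#'   `n_rated`, `n_consensus`.
#' @export
lighting_analysis <- function(phenotypes, annotations, split = -100) {
  stopifnot(all(c("image_id", "rater_id", "category") %in% names(annotations)),
            all(c("image_id", "longitude", "L", "a", "b") %in%
                  names(phenotypes)))
  raters <- sort(unique(annotations$rater_id))
  if (length(raters) != 2L)
    stop("expected exactly two raters, found ", length(raters), call. = FALSE)
  ids <- sort(intersect(phenotypes$image_id, annotations$image_id))
  get_ratings <- function(r) {
    sub <- annotations[annotations$rater_id == r, ]
    sub$category[match(ids, sub$image_id)]
  }
  ra <- get_ratings(raters[1L]); rb <- get_ratings(raters[2L])
  kap <- cohens_kappa(ra, rb)

  cons <- !is.na(ra) & !is.na(rb) & ra != "NAN" & rb != "NAN" & ra == rb
  cons_ids <- ids[cons]; cons_cat <- ra[cons]
  ph <- phenotypes[match(cons_ids, phenotypes$image_id), , drop = FALSE]
  region <- assign_region(ph$longitude, split = split)
  chi <- chi_square_independence(table(region, cons_cat))
  fact <- factorial_analysis(cbind(ph$L, ph$a, ph$b), region, cons_cat)
  list(kappa = kap, chi_square = chi, factorial = fact,
       n_rated = length(ids), n_consensus = length(cons_ids))
}
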