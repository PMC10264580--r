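test_that("the omnibus normality statistic matches an independent oracle", {
  # expected values computed with an independent implementation of the
  # K2 = Z(skew)^2 + Z(kurt)^2 omnibus (scipy.stats.normaltest), frozen
  x <- sin(1:30) * 3 + (0:29) * 0.1
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 3.917933101308, tolerance = 1e-10)
  expect_equal(r$p, 0.141004066210, tolerance = 1e-9)

  y <- c(1:15, 40, 60)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 23.175661829271, tolerance = 1e-10)
  expect_equal(r2$p, 9.278312e-06, tolerance = 1e-6)
})

test_that("the normality screen accepts Gaussian and rejects heavy tails", {
  set.seed(88)
  null_p <- replicate(100, dagostino_pearson(rnorm(500))$p)
  expect_gte(mean(null_p > 0.05), 0.90)
  heavy_p <- replicate(100, dagostino_pearson(rt(500, df = 2))$p)
  expect_gte(mean(heavy_p < 0.05), 0.90)
})

test_that("degenerate normality inputs are refused", {
  expect_error(dagostino_pearson(rnorm(7)), "insufficient n")
  expect_error(dagostino_pearson(rep(1, 20)), "constant")
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  # H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1) on {1,2,3},{4,5,6},{7,8,9}:
  # Rbar = 2, 5, 8; H = 12/90 * (3*4 + 3*25 + 3*64) - 30 = 7.2, no ties
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-10)

  same <- kruskal_wallis(rep(1:3, 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  expect_error(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), each = 3)),
               "identical")
})

test_that("Dunn z matches hand-computed tie-corrected rank algebra", {
  # no ties: se = sqrt(N(N+1)/12 * (1/3+1/3)) = sqrt(5); z = dRbar/sqrt(5)
  d <- dunn_posthoc(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(d$z, c(-3, -6, -3) / sqrt(5), tolerance = 1e-10)

  # tied data, cross-checked against an independent rank computation
  v <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6, 7, 7)
  g <- rep(c("a", "b", "c"), each = 4)
  dt <- dunn_posthoc(v, g)
  expect_equal(dt$z, c(-1.439568209855, -3.028057269005, -1.588489059150),
               tolerance = 1e-10)
  kwt <- kruskal_wallis(v, g)
  expect_equal(kwt$statistic, 9.176523297491, tolerance = 1e-10)

  # Bonferroni over the requested family only
  fam <- dunn_posthoc(1:9, rep(c("a", "b", "c"), each = 3),
                      comparisons = list(c("a", "c")))
  expect_equal(fam$p_adj, fam$p)
  expect_error(dunn_posthoc(1:9, rep(c("a", "b", "c"), each = 3),
                            comparisons = list(c("a", "zzz"))),
               "unknown group")
})

test_that("adjusted p values never fall below raw p values", {
  set.seed(13)
  d <- dunn_posthoc(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_true(all(d$p_adj >= d$p))
  expect_true(all(d$p_adj <= 1))
})

test_that("paired t handles direction, degeneracy and identity", {
  idn <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$statistic, 0)
  expect_equal(idn$p, 1)

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")

  set.seed(5)
  a <- rnorm(30); b <- a - 1 + rnorm(30, 0, 0.01)
  r <- paired_t(a, b)
  expect_lt(r$p, 1e-10)
  expect_gt(r$mean_diff, 0)
})

test_that("significance stars follow the figure-caption convention", {
  expect_identical(signif_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("the battery flags constructed treatment effects and not null arms", {
  set.seed(91)
  eyes <- eye_frame(Healthy = 16, Sham = 20, Anodal = 18, Cathodal = 16)
  latf <- function(g, d, e) {
    p2 <- 90
    if (d > 0 && g == "Sham") p2 <- 90 * 1.15
    c(P1 = 25 + (d > 0) * rnorm(1, 0, 0.3),
      N1 = 50 + (d > 0) * rnorm(1, 0, 0.4),
      P2 = p2 + (d > 0) * rnorm(1, 0, 0.5))
  }
  cohort <- build_cohort_table(make_marks_df(eyes, c(0, 8), latf))
  res <- run_endpoint_battery(cohort, grouping = "design", timepoints = 8,
                              measures = "P2")
  row_of <- function(g1, g2) res[(res$group1 == g1 & res$group2 == g2) |
                                 (res$group1 == g2 & res$group2 == g1), ]
  expect_lt(row_of("Sham", "Anodal")$p_adj, 0.05)
  expect_lt(row_of("Sham", "Cathodal")$p_adj, 0.05)
  expect_gt(row_of("Healthy", "Anodal")$p_adj, 0.05)
  expect_gt(row_of("Healthy", "Cathodal")$p_adj, 0.05)
  expect_identical(unique(res$branch), "kruskal-wallis+dunn")
})

test_that("a null cohort produces no stars beyond alpha-level false positives", {
  set.seed(17)
  eyes <- eye_frame(Healthy = 16, A = 16, B = 16)
  latf <- function(g, d, e) c(P1 = 25, N1 = 50 + (d > 0) * rnorm(1, 0, 0.5),
                              P2 = 90 + (d > 0) * rnorm(1, 0, 0.5))
  cohort <- build_cohort_table(make_marks_df(eyes, c(0, 7, 11), latf))
  res <- run_endpoint_battery(cohort, grouping = "design",
                              measures = c("N1", "P2"))
  expect_lte(mean(res$p_adj < 0.05), 0.10)
})

test_that("the paired N1-versus-P2 contrast detects a larger P2 delay", {
  set.seed(23)
  eyes <- eye_frame(Healthy = 16, EAE = 40)
  latf <- function(g, d, e) {
    scale_n1 <- if (g == "EAE" && d > 0) 1.05 else 1
    scale_p2 <- if (g == "EAE" && d > 0) 1.12 else 1
    c(P1 = 25, N1 = 50 * scale_n1 + (d > 0) * rnorm(1, 0, 0.4),
      P2 = 90 * scale_p2 + (d > 0) * rnorm(1, 0, 0.6))
  }
  cohort <- pool_eae(build_cohort_table(make_marks_df(eyes, c(0, 7), latf)))
  r <- n1_p2_contrast(cohort, day = 7, group = "EAE")
  expect_lt(r$p, 0.001)
  expect_gt(r$mean_diff, 0)
  expect_equal(r$n, 40)
})
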