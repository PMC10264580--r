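#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p Numeric p values.
#' @return Character vector of star strings (`"ns"` when p >= 0.05).
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the
#' omnibus statistic K2 = Z(skewness)^2 + Z(kurtosis)^2, referred to a
#' chi-square distribution with 2 degrees of freedom. The skewness is
#' normalized with D'Agostino's transformation and the kurtosis with the
#' Anscombe-Glynn transformation.
#'
#' @param x Numeric sample, n >= 8.
#' @return A `vep_test` list: `statistic` (K2), `p`, `n`, `method`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("insufficient n for omnibus test (need n >= 8)")
  if (stats::sd(x) == 0) stop("sample is constant; normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness branch (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis branch (Anscombe & Glynn 1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  structure(list(method = "D'Agostino-Pearson omnibus", statistic = k2,
                 p = stats::pchisq(k2, df = 2, lower.tail = FALSE), n = n),
            class = "vep_test")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference, via
#' [stats::kruskal.test()].
#'
#' @param values Numeric endpoint values.
#' @param groups Group labels (factor or character), same length.
#' @return A `vep_test` list: `statistic` (H), `df`, `p`, `n` per group.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1) {
    stop("all observations identical; H undefined")
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value,
                 n = table(groups)),
            class = "vep_test")
}

#' Dunn's post-hoc test on pooled ranks
#'
#' Pairwise z statistics on pooled mid-ranks with the tie-corrected
#' variance,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' p values are multiplicity-adjusted over the requested comparison
#' family (Bonferroni by default, capped at 1).
#'
#' @param values Numeric endpoint values.
#' @param groups Group labels, same length.
#' @param comparisons List of length-2 character vectors naming the
#'   comparisons of interest; `NULL` = all pairs.
#' @param p_adjust Adjustment method (see [stats::p.adjust()]); the
#'   Bonferroni default multiplies by the family size.
#' @return Data frame: `group1`, `group2`, `z`, `p`, `p_adj`, `stars`,
#'   `n1`, `n2`.
#' @export
dunn_posthoc <- function(values, groups, comparisons = NULL,
                         p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  nn <- table(groups)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))

  if (is.null(comparisons)) {
    comparisons <- utils::combn(levels(groups), 2, simplify = FALSE)
  }
  out <- do.call(rbind, lapply(comparisons, function(cmp) {
    g1 <- cmp[1]; g2 <- cmp[2]
    if (!all(cmp %in% levels(groups))) {
      stop("unknown group in comparison: ", paste(cmp, collapse = " vs "))
    }
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / nn[g1] + 1 / nn[g2]))
    z <- (rb[g1] - rb[g2]) / se
    data.frame(group1 = g1, group2 = g2, z = unname(z),
               p = 2 * stats::pnorm(-abs(unname(z))),
               n1 = unname(nn[g1]), n2 = unname(nn[g2]),
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- signif_stars(out$p_adj)
  rownames(out) <- NULL
  out[c("group1", "group2", "z", "p", "p_adj", "stars", "n1", "n2")]
}

#' Paired t test between two endpoint series
#'
#' Standard two-sided paired Student t on per-eye differences (e.g. P2
#' percent change minus N1 percent change in pooled EAE eyes). Pairs with
#' a missing member are dropped. If every difference is exactly zero the
#' degenerate no-effect result (t = 0, p = 1) is returned; a nonzero
#' constant difference has no finite t and raises an error.
#'
#' @param a,b Paired numeric vectors (same eyes, same order).
#' @return A `vep_test` list: `statistic` (t), `df`, `p`, `n`,
#'   `mean_diff`.
#' @export
paired_t <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  if (length(d) < 2) stop("need at least two complete pairs")
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(method = "paired t", statistic = 0,
                            df = length(d) - 1, p = 1, n = length(d),
                            mean_diff = 0),
                       class = "vep_test"))
    }
    stop("zero variance of differences; t undefined")
  }
  tt <- stats::t.test(a[keep], b[keep], paired = TRUE)
  structure(list(method = "paired t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = length(d),
                 mean_diff = unname(tt$estimate)),
            class = "vep_test")
}

#' @export
print.vep_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Run the endpoint comparison battery over a cohort
#'
#' For each requested measure x timepoint, screens each group's endpoint
#' distribution with the D'Agostino-Pearson test (recorded, groups with
#' n < 8 are screened as `NA`), then runs the nonparametric branch:
#' Kruskal-Wallis across groups followed by Dunn's post-hoc test over the
#' requested comparison family with Bonferroni adjustment. Groups with no
#' eyes at a timepoint drop that comparison with a warning.
#'
#' @param cohort A `vep_cohort`.
#' @param grouping Which label column to compare: `"stratified"` or
#'   `"design"`.
#' @param timepoints Days to analyze (baseline excluded by default since
#'   every percent change is 0 there).
#' @param measures Measures to analyze (default all six).
#' @param comparisons Comparison family for Dunn's test (`NULL` = all
#'   pairs).
#' @param exclude_groups Labels dropped before testing (e.g.
#'   `"unclassifiable"`).
#' @return Data frame, one row per measure x day x comparison:
#'   Kruskal-Wallis H and p, Dunn z, raw/adjusted p, stars, group sizes,
#'   and the recorded normality screen (minimum per-group p).
#' @export
run_endpoint_battery <- function(cohort,
                                 grouping = c("stratified", "design"),
                                 timepoints = setdiff(unique(cohort$day), 0),
                                 measures = vep_measures,
                                 comparisons = NULL,
                                 exclude_groups = "unclassifiable") {
  grouping <- match.arg(grouping)
  gcol <- if (grouping == "stratified") "group_stratified" else "group_design"
  rows <- list()
  for (m in measures) {
    for (d in timepoints) {
      sub <- cohort[cohort$measure == m & cohort$day == d &
                      !(cohort[[gcol]] %in% exclude_groups), ]
      sub <- sub[!is.na(sub$pct_change), ]
      if (nrow(sub) == 0) next
      tab <- table(sub[[gcol]])
      if (any(tab == 0) || length(tab) < 2) {
        warning("skipping ", m, " at day ", d, ": empty group")
        next
      }
      norm_p <- vapply(names(tab), function(g) {
        v <- sub$pct_change[sub[[gcol]] == g]
        if (length(v) >= 8 && stats::sd(v) > 0) dagostino_pearson(v)$p
        else NA_real_
      }, numeric(1))
      kw <- tryCatch(kruskal_wallis(sub$pct_change, sub[[gcol]]),
                     error = function(e) NULL)
      if (is.null(kw)) next
      dn <- dunn_posthoc(sub$pct_change, sub[[gcol]], comparisons)
      dn$measure <- m; dn$day <- d
      dn$kw_H <- kw$statistic; dn$kw_p <- kw$p
      dn$normality_min_p <- suppressWarnings(min(norm_p, na.rm = TRUE))
      dn$branch <- "kruskal-wallis+dunn"
      rows[[length(rows) + 1L]] <- dn
    }
  }
  if (length(rows) == 0) stop("no testable measure x timepoint cells")
  out <- do.call(rbind, rows)
  out[c("measure", "day", "group1", "group2", "kw_H", "kw_p", "z", "p",
        "p_adj", "stars", "n1", "n2", "normality_min_p", "branch")]
}

#' Paired N1-versus-P2 delay contrast
#'
#' Tests, within one group of eyes at one timepoint, whether the P2
#' percent latency change differs from the N1 percent latency change,
#' pairing by eye.
#'
#' @param cohort A `vep_cohort`.
#' @param day Timepoint to test.
#' @param group Group label (on `group_stratified`), e.g. a pooled
#'   `"EAE"` group from [pool_eae()].
#' @return A `vep_test` from [paired_t()]; positive `mean_diff` means P2
#'   is delayed more than N1.
#' @export
n1_p2_contrast <- function(cohort, day, group = "EAE") {
  sub <- cohort[cohort$day == day & cohort$group_stratified == group &
                  cohort$measure %in% c("N1", "P2"), ]
  wide <- stats::reshape(sub[c("eye_id", "measure", "pct_change")],
                         idvar = "eye_id", timevar = "measure",
                         direction = "wide")
  paired_t(wide$pct_change.P2, wide$pct_change.N1)
}
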