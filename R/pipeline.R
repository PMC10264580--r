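#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> average -> filter -> mark -> endpoints for
#' every session of a cohort design: each session's sweeps are averaged
#' per block, filtered zero-phase, marked on the grand average (block
#' averages feed the cross-block reproducibility check), converted to
#' implicit times, and assembled into the long endpoint table with
#' percent change from baseline. Optionally the EAE eyes are stratified
#' by the early-latency-delay rule. Sessions are realized one at a time
#' from per-session seeds, so memory stays flat and reruns with the same
#' design are bit-identical.
#'
#' @param design A [cohort_design()].
#' @param base_truth Baseline components, list of [component_spec()]s.
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()].
#' @param filt A [filter_spec()] (or `NULL` to skip filtering).
#' @param windows A [search_windows()].
#' @param rule A [stratification_rule()], or `NULL` to skip
#'   stratification.
#' @param use_grand Mark on the grand average (default) or on the first
#'   block average.
#' @param out_dir Optional directory; when given, `marks.csv` and
#'   `endpoints.csv` are written there.
#' @return List with `marks` (one row per session, detected marks plus
#'   ground truth), `cohort` (the `vep_cohort` endpoint table) and
#'   `sim` (the `vep_cohort_sim`).
#' @export
vep_pipeline <- function(design, base_truth = default_components(),
                         noise = noise_spec(), acq = acquisition_spec(),
                         filt = filter_spec(), windows = search_windows(),
                         rule = stratification_rule(), use_grand = TRUE,
                         out_dir = NULL) {
  sim <- simulate_cohort(design, base_truth, noise, acq)
  man <- sim$manifest
  mark_rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sess <- cohort_session(sim, i)
    pp <- preprocess_session(sess, filt)
    trace <- if (use_grand) pp$grand else pp$blocks[[1]]
    marks <- detect_components(trace, windows)
    mark_rows[[i]] <- cbind(man[i, c("eye_id", "mouse_id", "group", "day",
                                     "true_p1", "true_n1", "true_p2")],
                            as.data.frame(marks))
  }
  marks_df <- do.call(rbind, mark_rows)
  rownames(marks_df) <- NULL
  cohort <- build_cohort_table(marks_df)
  if (!is.null(rule)) {
    cohort <- tryCatch(stratify_eyes(cohort, rule), error = function(e) cohort)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(marks_df, file.path(out_dir, "marks.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "endpoints.csv"),
                     row.names = FALSE)
  }
  list(marks = marks_df, cohort = cohort, sim = sim)
}

#' Plot group latency-change trajectories
#'
#' One panel per measure: group mean percent latency change from
#' baseline over days, with SEM error bars.
#'
#' @param cohort A `vep_cohort`.
#' @param measures Measures to plot (default all six, in a 2 x 3 layout).
#' @param grouping `"stratified"` or `"design"` labels.
#' @param file Optional PDF path; when given the figure is written there.
#' @return Invisibly, the summary table (group x day x measure means and
#'   SEMs) underlying the figure.
#' @export
plot_group_trajectories <- function(cohort, measures = vep_measures,
                                    grouping = c("stratified", "design"),
                                    file = NULL) {
  grouping <- match.arg(grouping)
  gcol <- if (grouping == "stratified") "group_stratified" else "group_design"
  sub <- cohort[cohort$measure %in% measures & !is.na(cohort$pct_change) &
                  cohort[[gcol]] != "unclassifiable", ]
  agg <- stats::aggregate(pct_change ~ measure + day + sub[[gcol]],
                          data = sub, FUN = function(v) {
                            c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                              n = length(v))
                          })
  names(agg)[3] <- "group"
  agg <- cbind(agg[c("measure", "day", "group")],
               as.data.frame(agg$pct_change))

  if (!is.null(file)) {
    grDevices::pdf(file, width = 10, height = 6)
    on.exit(grDevices::dev.off())
  }
  groups <- sort(unique(agg$group))
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")[seq_along(groups)]
  old <- graphics::par(mfrow = c(2, ceiling(length(measures) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (m in measures) {
    a <- agg[agg$measure == m, ]
    if (nrow(a) == 0) next
    ylim <- range(a$mean - a$sem, a$mean + a$sem, 0)
    graphics::plot(NA, xlim = range(a$day), ylim = ylim,
                   xlab = "days post-immunization",
                   ylab = "latency change (%)", main = m)
    graphics::abline(h = 0, col = "grey70", lty = 3)
    for (gi in seq_along(groups)) {
      g <- a[a$group == groups[gi], ]
      g <- g[order(g$day), ]
      if (nrow(g) == 0) next
      graphics::lines(g$day, g$mean, col = cols[gi], type = "b", pch = 19)
      has_sem <- is.finite(g$sem) & g$sem > 0
      if (any(has_sem)) {
        graphics::arrows(g$day[has_sem], g$mean[has_sem] - g$sem[has_sem],
                         g$day[has_sem], g$mean[has_sem] + g$sem[has_sem],
                         angle = 90, code = 3, length = 0.03, col = cols[gi])
      }
    }
    if (m == measures[1]) {
      graphics::legend("topleft", legend = groups, col = cols, lty = 1,
                       pch = 19, bty = "n", cex = 0.8)
    }
  }
  invisible(agg)
}
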