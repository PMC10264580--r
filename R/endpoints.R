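vep_measures <- c("P1", "N1", "P2", "P1-N1", "N1-P2", "P1-P2")

measure_columns <- c("P1" = "p1_latency", "N1" = "n1_latency",
                     "P2" = "p2_latency", "P1-N1" = "p1_n1_time",
                     "N1-P2" = "n1_p2_time", "P1-P2" = "p1_p2_time")

#' Percent change from baseline
#'
#' `100 * (value - baseline) / baseline`. Missing operands propagate as
#' `NA` (an eye without a baseline measurement contributes no endpoint
#' for that measure).
#'
#' @param value Measure at the follow-up timepoint (ms).
#' @param baseline Measure at the same eye's baseline session (ms, > 0).
#' @return Percent change (vectorized).
#' @export
percent_change <- function(value, baseline) {
  out <- 100 * (value - baseline) / baseline
  out[!is.na(baseline) & baseline <= 0] <- NA_real_
  out
}

#' Build the long-format cohort endpoint table
#'
#' Converts a per-session marks table (one row per eye x day, columns as
#' in [as.data.frame.vep_marks()] plus `eye_id`, `mouse_id`, `group`,
#' `day`) into a tidy long table with one row per eye x day x measure,
#' carrying the raw value in ms and its percent change from that eye's
#' baseline (day 0). The percent change at baseline is exactly 0 for
#' every measure present at baseline; eyes without a baseline value for
#' a measure get `NA` percent change at every day.
#'
#' @param marks_df Data frame of per-session marks.
#' @param baseline_day Day treated as baseline (default 0).
#' @return An object of classes `vep_cohort` and `data.frame` with
#'   columns `eye_id`, `mouse_id`, `group_design`, `group_stratified`,
#'   `day`, `measure`, `value_ms`, `pct_change`.
#' @export
build_cohort_table <- function(marks_df, baseline_day = 0) {
  if (is.null(marks_df) || nrow(marks_df) == 0) stop("no session records")
  req <- c("eye_id", "group", "day")
  if (!all(req %in% names(marks_df))) {
    stop("marks table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(marks_df[c("eye_id", "day")])) {
    stop("duplicate (eye_id, day) keys in session records")
  }
  if (!"mouse_id" %in% names(marks_df)) marks_df$mouse_id <- marks_df$eye_id

  long <- do.call(rbind, lapply(vep_measures, function(m) {
    data.frame(eye_id = marks_df$eye_id, mouse_id = marks_df$mouse_id,
               group_design = marks_df$group,
               group_stratified = marks_df$group,
               day = marks_df$day, measure = m,
               value_ms = marks_df[[measure_columns[m]]],
               stringsAsFactors = FALSE)
  }))

  base <- long[long$day == baseline_day, c("eye_id", "measure", "value_ms")]
  names(base)[3] <- "baseline_ms"
  long <- merge(long, base, by = c("eye_id", "measure"), all.x = TRUE,
                sort = FALSE)
  long$pct_change <- percent_change(long$value_ms, long$baseline_ms)
  long$baseline_ms <- NULL
  long <- long[order(long$eye_id, long$day, match(long$measure, vep_measures)), ]
  rownames(long) <- NULL
  class(long) <- c("vep_cohort", "data.frame")
  long
}

#' Stratify EAE eyes by early latency delay
#'
#' Labels each non-Healthy eye "EAE W LD" (with latency delay) when its
#' percent change of the rule's reference measure at the rule's timepoint
#' exceeds the threshold, and "EAE W/O LD" otherwise. When the rule's
#' threshold is `NULL` it is derived as Healthy mean + `n_sd` x SD of the
#' same endpoint among the cohort's Healthy eyes. Healthy eyes are never
#' relabeled; eyes lacking a session at the rule timepoint are labeled
#' `"unclassifiable"`. Deterministic given (cohort, rule).
#'
#' @param cohort A `vep_cohort` from [build_cohort_table()].
#' @param rule A [stratification_rule()].
#' @return The cohort with `group_stratified` filled in; the applied
#'   threshold is attached as attribute `"threshold"`.
#' @export
stratify_eyes <- function(cohort, rule = stratification_rule()) {
  sub <- cohort[cohort$measure == rule$measure & cohort$day == rule$day, ]
  thr <- rule$threshold
  if (is.null(thr)) {
    healthy <- sub$pct_change[sub$group_design == rule$healthy_label]
    healthy <- healthy[!is.na(healthy)]
    if (length(healthy) < 2) {
      stop("stratification needs Healthy reference eyes or an absolute threshold")
    }
    thr <- mean(healthy) + rule$n_sd * stats::sd(healthy)
  }
  lab <- stats::setNames(rep("unclassifiable", length(unique(cohort$eye_id))),
                         unique(cohort$eye_id))
  ok <- !is.na(sub$pct_change)
  lab[sub$eye_id[ok]] <- ifelse(sub$pct_change[ok] > thr, "EAE W LD", "EAE W/O LD")
  eae <- cohort$group_design != rule$healthy_label
  cohort$group_stratified[eae] <- lab[cohort$eye_id[eae]]
  cohort$group_stratified[!eae] <- cohort$group_design[!eae]
  attr(cohort, "threshold") <- thr
  cohort
}

#' Pool all non-Healthy groups into one EAE group
#'
#' Used for pooled-EAE contrasts (e.g. the paired N1-versus-P2 delay
#' comparison at early timepoints).
#'
#' @param cohort A `vep_cohort`.
#' @param healthy_label Label of the Healthy group.
#' @param pooled_label Label given to all pooled eyes.
#' @return The cohort with `group_stratified` collapsed.
#' @export
pool_eae <- function(cohort, healthy_label = "Healthy", pooled_label = "EAE") {
  eae <- cohort$group_design != healthy_label
  cohort$group_stratified[eae] <- pooled_label
  cohort$group_stratified[!eae] <- cohort$group_design[!eae]
  cohort
}
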