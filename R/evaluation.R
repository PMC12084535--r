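#' Clinical response policy
#'
#' Evaluation conventions for alarm streams: alarms fired in the closed
#' window \[onset - `true_alarm_window`, onset\] count toward true positives
#' on septic encounters; on non-septic encounters an uncertainty-zone alarm
#' counts as a false positive only when severe sepsis is the top-1
#' differential, while a direct-fire alarm counts unconditionally. Alarms
#' matching neither rule are ignored (neither true nor false) -- this
#' asymmetric top-5/top-1 policy is reproduced as stated, not reinterpreted.
#'
#' @param true_alarm_window Hours before onset in which an alarm is true
#'   (default 48).
#' @param top5_tp_rule,top1_fp_rule Flags enabling the asymmetric rules
#'   (defaults `TRUE`).
#' @return Object of class `response_policy`.
#' @export
response_policy <- function(true_alarm_window = 48, top5_tp_rule = TRUE,
                            top1_fp_rule = TRUE) {
  if (true_alarm_window <= 0) stop("true_alarm_window must be > 0")
  structure(
    list(true_alarm_window = true_alarm_window,
         top5_tp_rule = top5_tp_rule, top1_fp_rule = top1_fp_rule),
    class = "response_policy"
  )
}

#' Classify fired alarms of one encounter
#'
#' @param alarms List of alarm records for one encounter (time-sorted).
#' @param truth Truth record: `septic` flag and `onset_hour` when septic.
#' @param policy A [response_policy()].
#' @return Character vector per alarm: `"true"`, `"false"`, or `"ignored"`.
#' @export
classify_alarms <- function(alarms, truth, policy = response_policy()) {
  if (isTRUE(truth$septic) && is.null(truth$onset_hour)) {
    stop("septic truth requires an onset hour")
  }
  vapply(alarms, function(a) {
    if (!isTRUE(a$fired)) return("ignored")
    has_topk <- !is.null(a$ddx_topk) && length(a$ddx_topk)
    if (isTRUE(truth$septic)) {
      inwin <- a$hour >= truth$onset_hour - policy$true_alarm_window &&
        a$hour <= truth$onset_hour
      if (!inwin) return("ignored")
      ok <- a$zone == "direct" || !has_topk ||
        (!policy$top5_tp_rule) ||
        ("Severe Sepsis" %in% utils::head(a$ddx_topk, 5))
      if (ok) "true" else "ignored"
    } else {
      if (a$zone == "direct" || !has_topk || !policy$top1_fp_rule) {
        return("false")
      }
      if (identical(a$ddx_topk[[1]], "Severe Sepsis")) "false" else "ignored"
    }
  }, character(1))
}

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' F1 as the harmonic mean of sensitivity and PPV
#'
#' @param sensitivity,ppv Percentages.
#' @return F1 in percent (`NA` when both inputs are zero or missing).
#' @export
#' @examples
#' f1_harmonic(72.1, 52.9) # 61.0 to one decimal
f1_harmonic <- function(sensitivity, ppv) {
  if (is.na(sensitivity) || is.na(ppv) || sensitivity + ppv == 0) {
    return(NA_real_)
  }
  2 * sensitivity * ppv / (sensitivity + ppv)
}

#' Encounter-level alarm metrics
#'
#' TP = septic encounters with at least one true alarm; FN = septic with
#' none; FP = non-septic with at least one false alarm. Sensitivity =
#' TP/(TP+FN), PPV = TP/(TP+FP), F1 their harmonic mean, all in percent;
#' undefined denominators yield `NA`, never 0. FAPH is the total count of
#' false alarms divided by the total hourly prediction time points.
#'
#' @param alarms Flat list of alarm records (from [run_cohort()]).
#' @param truths Named list of truth records, names = encounter ids; every
#'   encounter must be labeled.
#' @param policy A [response_policy()].
#' @param patient_hours Total hourly prediction time points (FAPH
#'   denominator).
#' @param subgroup Optional tag recorded in the report.
#' @return Object of class `metrics_report`.
#' @export
encounter_metrics <- function(alarms, truths, policy = response_policy(),
                              patient_hours = NA_real_, subgroup = NULL) {
  ids <- names(truths)
  by_enc <- split(alarms, vapply(alarms, `[[`, character(1), "encounter_id"))
  tp <- fp <- fn <- 0L
  false_alarms <- 0L
  for (id in ids) {
    tr <- truths[[id]]
    cls <- classify_alarms(by_enc[[id]] %||% list(), tr, policy)
    false_alarms <- false_alarms + sum(cls == "false")
    if (isTRUE(tr$septic)) {
      if (any(cls == "true")) tp <- tp + 1L else fn <- fn + 1L
    } else if (any(cls == "false")) {
      fp <- fp + 1L
    }
  }
  sens <- pct(tp, tp + fn)
  ppv <- pct(tp, tp + fp)
  structure(
    list(sensitivity = sens, ppv = ppv, f1 = f1_harmonic(sens, ppv),
         faph = faph(false_alarms, patient_hours),
         tp = tp, fp = fp, fn = fn, false_alarm_count = false_alarms,
         total_patient_hours = patient_hours, subgroup = subgroup),
    class = "metrics_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report%s> sensitivity %.1f%%  PPV %.1f%%  F1 %.1f%%  FAPH %s\n",
    if (is.null(x$subgroup)) "" else paste0(" [", x$subgroup, "]"),
    x$sensitivity, x$ppv, x$f1,
    if (is.na(x$faph)) "NA" else format(round(x$faph, 4))))
  cat(sprintf("  TP %d  FP %d  FN %d  false alarms %d  patient-hours %s\n",
              x$tp, x$fp, x$fn, x$false_alarm_count,
              format(x$total_patient_hours)))
  invisible(x)
}

#' False alarms per patient-hour
#'
#' @param false_alarm_count Total false alarms.
#' @param patient_hours Sum of hourly prediction time points across all
#'   encounters.
#' @return Rate (`NA` when patient_hours is 0 or missing).
#' @export
faph <- function(false_alarm_count, patient_hours) {
  if (is.na(patient_hours) || patient_hours == 0) return(NA_real_)
  false_alarm_count / patient_hours
}

#' Expected false alarms in a care unit
#'
#' Converts a FAPH rate into the expected number of false alarms over
#' `hours` hours in a unit of `beds` beds: `faph * beds * hours`.
#'
#' @param faph_rate False alarms per patient-hour.
#' @param beds Number of beds.
#' @param hours Time span in hours.
#' @return Expected alarm count.
#' @export
#' @examples
#' expected_unit_alarms(0.037, 20, 2) # 1.48
expected_unit_alarms <- function(faph_rate, beds, hours) {
  stopifnot(faph_rate >= 0, beds >= 0, hours >= 0)
  faph_rate * beds * hours
}

#' A proportion as a percentage
#'
#' @param x Count.
#' @param n Total.
#' @return `100 * x / n`.
#' @export
proportion_percent <- function(x, n) {
  if (n <= 0) stop("total must be positive")
  100 * x / n
}

#' Suspected-infection subgroup filter
#'
#' Keeps encounters where a blood-culture draw and an antibiotic start both
#' fall inside the closed `window`-hour interval centered on the encounter's
#' prediction time, emulating a condition-for-use restricted to patients
#' with a clinical suspicion of infection at prediction time.
#'
#' @param cohort An `ed_cohort`.
#' @param prediction_hours Named numeric vector (names = encounter ids) of
#'   per-encounter prediction times, e.g. the first fired-alarm hour or
#'   first eligible hour.
#' @param window Window width in hours (default 6, closed at both ends).
#' @return Character vector of included encounter ids.
#' @export
suspected_infection_subgroup <- function(cohort, prediction_hours,
                                         window = 6) {
  keep <- character(0)
  for (e in cohort) {
    p <- prediction_hours[[e$encounter_id]]
    if (is.null(p) || is.na(p)) next
    lo <- p - window / 2
    hi <- p + window / 2
    df <- order_df(e$orders)
    has_cult <- any(df$kind == "blood_culture" & df$hour >= lo & df$hour <= hi)
    has_abx <- any(df$kind == "iv_antibiotic_start" & df$hour >= lo &
                     df$hour <= hi)
    if (has_cult && has_abx) keep <- c(keep, e$encounter_id)
  }
  keep
}

#' Truth records of a cohort, keyed by encounter id
#'
#' @param cohort An `ed_cohort` with generator-planted truth, or a label data
#'   frame from [label_cohort()].
#' @return Named list of truth records (`septic`, `onset_hour`).
#' @export
cohort_truths <- function(cohort) {
  if (is.data.frame(cohort)) {
    out <- lapply(seq_len(nrow(cohort)), function(i) {
      list(septic = cohort$septic[i],
           onset_hour = if (is.na(cohort$onset_hour[i])) NULL
                        else cohort$onset_hour[i])
    })
    names(out) <- cohort$encounter_id
    return(out)
  }
  out <- lapply(cohort, `[[`, "truth")
  names(out) <- vapply(cohort, `[[`, character(1), "encounter_id")
  out
}
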