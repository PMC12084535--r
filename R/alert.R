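#' Alerting configuration
#'
#' Decision thresholds and policies of the hourly alert loop. Scores at or
#' above `theta1` fire directly; scores in `[theta2, theta1)` fall in the
#' high-uncertainty zone where the note-based differential adjudicates;
#' anything below `theta2` takes no action. After any fired alarm the
#' encounter is silenced (no further firing, scoring continues) for
#' `silencing_hours`.
#'
#' @param theta1 Primary decision threshold (default 0.75).
#' @param theta2 Secondary threshold opening the uncertainty zone
#'   (default 0.5); must satisfy `0 <= theta2 < theta1 <= 1`.
#' @param alpha Sepsis-likelihood threshold for the `slt` variant (strict
#'   exceedance); calibrated on a development split, `NA` until set.
#' @param silencing_hours Alarm silencing period (default 6).
#' @param truth_window_hours Evaluation true-alarm window before onset
#'   (default 48).
#' @param prediction_start First prediction hour after triage (default 2).
#' @param required_note_types At least one note of one of these types must
#'   exist for an hour to be eligible.
#' @param variant One of `"ddx"`, `"slt"`, `"baseline"`, `"composer_only"`.
#' @param composer_only_threshold Single threshold used by the
#'   `composer_only` variant (default 0.6).
#' @return Object of class `alert_config`.
#' @export
alert_config <- function(theta1 = 0.75, theta2 = 0.5, alpha = NA_real_,
                         silencing_hours = 6, truth_window_hours = 48,
                         prediction_start = 2,
                         required_note_types = c(
                           "ED provider note", "History and Physical note",
                           "Diagnostic image report", "Progress note"),
                         variant = c("ddx", "slt", "baseline",
                                     "composer_only"),
                         composer_only_threshold = 0.6) {
  variant <- match.arg(variant)
  if (!(theta2 >= 0 && theta2 < theta1 && theta1 <= 1)) {
    stop("thresholds must satisfy 0 <= theta2 < theta1 <= 1")
  }
  if (silencing_hours < 0 || truth_window_hours <= 0) {
    stop("silencing and truth windows must be positive")
  }
  structure(
    list(theta1 = theta1, theta2 = theta2, alpha = alpha,
         silencing_hours = silencing_hours,
         truth_window_hours = truth_window_hours,
         prediction_start = prediction_start,
         required_note_types = required_note_types,
         variant = variant,
         composer_only_threshold = composer_only_threshold),
    class = "alert_config"
  )
}

#' Hourly prediction eligibility
#'
#' A prediction is made at `hour` iff there is at least one vital and one lab
#' measurement in the half-open 24-h lookback `(hour - 24, hour]`, no
#' antibiotics have been started at or before `hour`, and at least one note
#' of a required type exists at or before `hour` (incomplete notes still
#' qualify; contextual information in a partial note remains usable).
#'
#' @param encounter An `ed_encounter`.
#' @param hour Prediction hour (>= `prediction_start`).
#' @param config An [alert_config()].
#' @return Logical flag.
#' @export
eligible <- function(encounter, hour, config = alert_config()) {
  vit <- any(encounter$vitals_times > hour - 24 & encounter$vitals_times <= hour)
  lab <- any(encounter$labs_times > hour - 24 & encounter$labs_times <= hour)
  if (!vit || !lab) return(FALSE)
  for (o in encounter$orders) {
    if (o$kind == "iv_antibiotic_start" && o$hour <= hour) return(FALSE)
  }
  for (nt in encounter$notes) {
    if (nt$note_type %in% config$required_note_types && nt$hour <= hour) {
      return(TRUE)
    }
  }
  FALSE
}

#' Gate a risk score into an action zone
#'
#' @param score Risk score in \[0, 1\].
#' @param config An [alert_config()].
#' @return `"direct_fire"` (score >= theta1), `"llm_zone"`
#'   (theta2 <= score < theta1), or `"no_action"`.
#' @export
gate <- function(score, config = alert_config()) {
  if (!is.numeric(score) || is.na(score) || score < 0 || score > 1) {
    stop("score must be in [0, 1]")
  }
  if (score >= config$theta1) "direct_fire"
  else if (score >= config$theta2) "llm_zone"
  else "no_action"
}

#' Differential-diagnosis alert decision
#'
#' Fire iff `"Severe Sepsis"` appears within the top-5 sorted differentials
#' and a suspicion of bacterial infection was extracted.
#'
#' @param topk Character vector from [ddx_top_k()] with `k = 5`.
#' @param bacterial_suspicion Flag: was `"suspicion of bacterial infection"`
#'   among the extracted present signs?
#' @return Logical flag.
#' @export
ddx_decision <- function(topk, bacterial_suspicion) {
  ("Severe Sepsis" %in% topk) && isTRUE(bacterial_suspicion)
}

#' Sepsis-likelihood-tool alert decision
#'
#' Fire iff the posterior sepsis likelihood strictly exceeds `alpha` and a
#' suspicion of bacterial infection was extracted.
#'
#' @param likelihood Posterior probability of severe sepsis.
#' @param bacterial_suspicion Flag as in [ddx_decision()].
#' @param config An [alert_config()] with `alpha` set.
#' @return Logical flag.
#' @export
slt_decision <- function(likelihood, bacterial_suspicion,
                         config = alert_config()) {
  if (is.na(config$alpha)) stop("alpha is not set in the alert config")
  (likelihood > config$alpha) && isTRUE(bacterial_suspicion)
}

#' Note-only sepsis alert decision
#'
#' Queries the backend with the direct sepsis prompt over the retrieved
#' context of all notes up to the prediction hour; fires iff the majority of
#' parsed "Sepsis" answers is yes. Parse failures fail safe to "no".
#'
#' @param notes Note events at or before the prediction hour.
#' @param backend Backend function, e.g. [mock_sepsis_backend()].
#' @param rconfig A [retrieval_config()].
#' @param encounter_id For per-run seed derivation.
#' @return Logical flag.
#' @export
baseline_decision <- function(notes, backend = mock_sepsis_backend(),
                              rconfig = retrieval_config(),
                              encounter_id = "enc") {
  chunks <- chunk_notes(notes, rconfig)
  query <- "severe sepsis bacterial infection organ dysfunction"
  ctx <- retrieve_chunks(query, chunks, rconfig)
  context <- paste(vapply(ctx, `[[`, character(1), "text"), collapse = "\n")
  prompt <- fill_template(prompt_templates()$sepsis, context = context)
  votes <- logical(rconfig$n_votes)
  for (r in seq_len(rconfig$n_votes)) {
    seed <- derive_seed(encounter_id, "Sepsis", r)
    ans <- parse_extraction_json(
      backend(prompt, context, rconfig$temperature, seed), "Sepsis")
    if (is.null(ans)) {
      ans <- parse_extraction_json(
        backend(prompt, context, rconfig$temperature, seed + 1L), "Sepsis")
    }
    votes[r] <- !is.null(ans) && ans$yes
  }
  sum(votes) > rconfig$n_votes / 2
}

#' Run the hourly alert loop over one encounter
#'
#' Loops over integer hours in the closed-open monitoring interval from
#' `prediction_start` up to (excluding) the end of monitoring -- the earlier
#' of sepsis onset, when known, and discharge. At each eligible
#' hour the risk score is gated; a `direct_fire` zone fires immediately, an
#' `llm_zone` hour triggers extraction and the variant's decision rule. After
#' any fired alarm, firing (not scoring) is suppressed for `silencing_hours`.
#' The `composer_only` variant ignores the uncertainty zone and fires
#' whenever the score reaches `composer_only_threshold`.
#'
#' @param encounter An `ed_encounter`.
#' @param scorer Function `(encounter, hour) -> score`
#'   (default [surrogate_risk_score()]).
#' @param extractor Extractor function from [make_rag_extractor()] or
#'   [make_oracle_extractor()].
#' @param config An [alert_config()].
#' @param table A [likelihood_table()] for the ddx/slt decisions.
#' @param baseline_backend Backend for the `baseline` variant.
#' @param rconfig Retrieval config for the `baseline` variant.
#' @return Data-frame-like list of alarm records (one per evaluated hour with
#'   zone != no_action): `encounter_id`, `hour`, `zone`, `fired`,
#'   `bacterial_suspicion`, `ddx_topk` (list column), plus attribute
#'   `eligible_hours` (count of hourly prediction time points).
#' @export
run_encounter <- function(encounter, scorer = surrogate_risk_score,
                          extractor = make_oracle_extractor(),
                          config = alert_config(),
                          table = likelihood_table(),
                          baseline_backend = mock_sepsis_backend(),
                          rconfig = retrieval_config()) {
  onset <- encounter$truth$onset_hour
  horizon <- encounter$discharge_hour
  if (!is.null(onset)) horizon <- min(horizon, onset)
  # closed-open monitoring interval [prediction_start, horizon)
  last_hour <- floor(horizon - 1e-9)
  hours <- if (last_hour < config$prediction_start) numeric(0) else
    seq(config$prediction_start, last_hour)
  records <- list()
  n_eligible <- 0L
  last_fire <- -Inf
  for (h in hours) {
    if (!eligible(encounter, h, config)) next
    n_eligible <- n_eligible + 1L
    score <- scorer(encounter, h)
    silenced <- (h - last_fire) < config$silencing_hours

    if (config$variant == "composer_only") {
      if (score < config$composer_only_threshold) next
      zone <- "direct"
      fired <- !silenced
      topk <- NULL
      susp <- NA
    } else {
      z <- gate(score, config)
      if (z == "no_action") next
      if (z == "direct_fire") {
        zone <- "direct"
        fired <- !silenced
        topk <- NULL
        susp <- NA
      } else {
        zone <- "llm_gated"
        if (config$variant == "baseline") {
          hrs <- vapply(encounter$notes, `[[`, numeric(1), "hour")
          fire_wanted <- baseline_decision(encounter$notes[hrs <= h],
                                           baseline_backend, rconfig,
                                           encounter$encounter_id)
          topk <- NULL
          susp <- NA
        } else {
          ex <- extractor(encounter, h)
          susp <- "suspicion of bacterial infection" %in% ex$present
          res <- ddx_posterior(ex$present, table)
          topk <- ddx_top_k(res, 5)
          fire_wanted <- if (config$variant == "ddx") {
            ddx_decision(topk, susp)
          } else {
            slt_decision(sepsis_likelihood(ex$present, table), susp, config)
          }
        }
        fired <- fire_wanted && !silenced
      }
    }
    if (fired) last_fire <- h
    records[[length(records) + 1]] <- list(
      encounter_id = encounter$encounter_id, hour = h, zone = zone,
      fired = fired, bacterial_suspicion = susp, ddx_topk = topk
    )
  }
  structure(records, eligible_hours = n_eligible)
}

#' Run the alert loop over a cohort
#'
#' @param cohort An `ed_cohort`.
#' @inheritParams run_encounter
#' @return List with `alarms` (flat list of alarm records) and
#'   `patient_hours` (total hourly prediction time points across the
#'   cohort, the FAPH denominator).
#' @export
run_cohort <- function(cohort, scorer = surrogate_risk_score,
                       extractor = make_oracle_extractor(),
                       config = alert_config(),
                       table = likelihood_table(),
                       baseline_backend = mock_sepsis_backend(),
                       rconfig = retrieval_config()) {
  alarms <- list()
  ph <- 0L
  for (e in cohort) {
    rec <- run_encounter(e, scorer, extractor, config, table,
                         baseline_backend, rconfig)
    ph <- ph + attr(rec, "eligible_hours")
    alarms <- c(alarms, rec)
  }
  list(alarms = alarms, patient_hours = ph)
}

#' Calibrate the SLT likelihood threshold on a development split
#'
#' Grid search over candidate alpha values maximizing the encounter-level F1
#' of the `slt` variant on the development cohort; ties take the smallest
#' alpha (favoring sensitivity).
#'
#' @param dev_cohort Labeled development `ed_cohort`.
#' @param config Base [alert_config()] (variant forced to `"slt"`).
#' @param table A [likelihood_table()].
#' @param extractor Extractor function.
#' @param grid Candidate thresholds.
#' @param scorer Risk scorer.
#' @return The selected alpha.
#' @export
calibrate_alpha <- function(dev_cohort, config = alert_config(),
                            table = likelihood_table(),
                            extractor = make_oracle_extractor(),
                            grid = seq(0.05, 0.95, by = 0.05),
                            scorer = surrogate_risk_score) {
  cfg <- config
  cfg$variant <- "slt"
  truths <- cohort_truths(dev_cohort)
  best_alpha <- grid[1]
  best_f1 <- -1
  for (a in grid) {
    cfg$alpha <- a
    run <- run_cohort(dev_cohort, scorer, extractor, cfg, table)
    rep <- encounter_metrics(run$alarms, truths,
                             patient_hours = run$patient_hours)
    f1 <- if (is.na(rep$f1)) 0 else rep$f1
    if (f1 > best_f1 + 1e-9) {
      best_f1 <- f1
      best_alpha <- a
    }
  }
  best_alpha
}
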