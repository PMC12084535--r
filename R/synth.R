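#' Synthetic cohort specification
#'
#' Parameters of the synthetic emergency-department cohort generator. The
#' defaults emulate the reported structure of the alerting cohort: septic
#' prevalence around 16.6%, sepsis onset a few hours after triage (median
#' 3.2 h), ED length of stay with median near 12 h (non-septic) and 22 h
#' (septic), and notes that carry the canonical phrases of the truly present
#' clinical signs.
#'
#' @param n_encounters Number of encounters (>= 1).
#' @param septic_fraction Probability an encounter is septic (default 0.166).
#' @param onset_delay_median_hr Median triage-to-onset delay in hours
#'   (default 3.2); delays are log-normal, truncated below at 2.5 h because
#'   encounters already septic before the hour-2 prediction start are
#'   excluded from alerting cohorts by design.
#' @param note_symptom_noise Probability that a note omits a truly present
#'   symptom phrase, and independently that any absent catalog symptom
#'   appears as a decoy phrase (default 0.02, mild documentation noise).
#' @param mimic_fraction Probability a non-septic encounter carries a
#'   sepsis-mimic diagnosis (sampled uniformly over the 18 mimics) with its
#'   symptom signature planted; the rest are benign with no planted signs
#'   (default 0.7: the cohort emulated is pre-filtered to clinically
#'   concerning presentations).
#' @param seed Integer seed; a fixed seed gives byte-identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_encounters, septic_fraction = 0.166,
                        onset_delay_median_hr = 3.2,
                        note_symptom_noise = 0.02,
                        mimic_fraction = 0.7, seed = 1) {
  if (!is.numeric(n_encounters) || n_encounters < 1) {
    stop("n_encounters must be >= 1")
  }
  for (p in c(septic_fraction, note_symptom_noise, mimic_fraction)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  structure(
    list(n_encounters = as.integer(n_encounters),
         septic_fraction = septic_fraction,
         onset_delay_median_hr = onset_delay_median_hr,
         note_symptom_noise = note_symptom_noise,
         mimic_fraction = mimic_fraction,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

filler_sentences <- c(
  "Patient arrived by private vehicle and was triaged promptly.",
  "Past medical history reviewed in the chart.",
  "Home medications were reconciled on arrival.",
  "Plan discussed with the patient who verbalized understanding.",
  "Will continue to monitor clinical trajectory closely.",
  "Labs and imaging ordered as clinically indicated."
)

#' Plant canonical symptom phrases into note text
#'
#' Builds free text containing the canonical phrase of each truly present
#' symptom with probability `1 - noise`, and the phrase of each absent
#' catalog symptom (a decoy) with probability `noise`, interleaved with
#' neutral filler sentences. Deterministic given `seed`.
#'
#' @param truth_symptoms Character vector of catalog symptom names.
#' @param noise Probability in \[0, 1\] of omitting a true phrase /
#'   introducing each decoy phrase.
#' @param seed Integer seed.
#' @param lexicon Named phrase lexicon, see [symptom_lexicon()].
#' @return A single character string of note text.
#' @export
plant_symptom_phrases <- function(truth_symptoms, noise = 0, seed = 1,
                                  lexicon = symptom_lexicon()) {
  bad <- setdiff(truth_symptoms, names(lexicon))
  if (length(bad)) stop("unknown symptom(s): ", paste(bad, collapse = ", "))
  if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  rng <- local_rng(seed)
  on.exit(rng())
  keep <- names(lexicon) %in% truth_symptoms
  u <- stats::runif(length(lexicon))
  use <- ifelse(keep, u >= noise, u < noise)
  phrases <- unname(lexicon[use])
  fill <- sample(filler_sentences, 2 + length(phrases) %/% 3, replace = TRUE)
  body <- character(0)
  for (i in seq_along(phrases)) {
    # keep the phrase byte-verbatim so fixed-string detection is exact
    body <- c(body, paste0("Noted: ", phrases[i], "."))
    if (i %% 3 == 0) body <- c(body, fill[1 + (i %/% 3) %% length(fill)])
  }
  paste(c(fill[1], body, fill[length(fill)]), collapse = " ")
}

# Save/restore the global RNG state around seeded draws, so helpers are
# reproducible without clobbering the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, .GlobalEnv)
    }
  }
}

rlnorm_med <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

generate_encounter <- function(i, spec, table, lexicon) {
  id <- sprintf("enc%05d", i)
  septic <- stats::runif(1) < spec$septic_fraction

  if (septic) {
    dx <- "Severe Sepsis"
    # truncated log-normal onset delay; resample below the prediction start
    onset <- rlnorm_med(1, spec$onset_delay_median_hr, 1.1)
    while (onset < 2.5 || onset > 40) {
      onset <- rlnorm_med(1, spec$onset_delay_median_hr, 1.1)
    }
    discharge <- max(onset + 4, min(96, rlnorm_med(1, 22, 0.7)))
    severity <- stats::rbeta(1, 5, 2)
  } else {
    onset <- NULL
    dx <- if (stats::runif(1) < spec$mimic_fraction) {
      sample(setdiff(disease_set(), "Severe Sepsis"), 1)
    } else {
      NA_character_
    }
    discharge <- min(96, max(4, rlnorm_med(1, 12, 0.7)))
    severity <- if (is.na(dx)) stats::rbeta(1, 1.5, 8) else stats::rbeta(1, 2.5, 4)
  }

  # truly present signs: Bernoulli draws from the planted likelihood table
  symptoms <- character(0)
  if (!is.na(dx)) {
    p <- table$lik[[dx]]
    symptoms <- names(p)[stats::runif(length(p)) < p]
  }

  # orders
  orders <- list()
  if (septic) {
    culture_first <- stats::runif(1) < 0.8
    if (culture_first) {
      culture <- onset + stats::runif(1, 0, 2)
      abx <- culture + stats::runif(1, 0, 48)
    } else {
      abx <- onset + stats::runif(1, 0, 2)
      culture <- abx + stats::runif(1, 0, 20)
    }
    orders <- list(
      list(kind = "blood_culture", hour = culture),
      list(kind = "iv_antibiotic_start", hour = abx, prophylactic = FALSE),
      list(kind = "iv_antibiotic_end", hour = abx + 96 + stats::runif(1, 2, 72),
           prophylactic = FALSE)
    )
  } else if (stats::runif(1) < 0.3) {
    culture <- stats::runif(1, 1, 8)
    orders <- list(list(kind = "blood_culture", hour = culture))
    if (stats::runif(1) < 0.5) {
      abx <- culture + stats::runif(1, 0, 4)
      proph <- stats::runif(1) < 0.3
      dur <- if (proph) 120 else stats::runif(1, 12, 72) # short or prophylactic
      orders <- c(orders, list(
        list(kind = "iv_antibiotic_start", hour = abx, prophylactic = proph),
        list(kind = "iv_antibiotic_end", hour = abx + dur, prophylactic = proph)
      ))
    }
  }
  # order events (notably antibiotic ends) may post-date ED discharge:
  # a 4-day IV course continues on the inpatient side

  # hourly SOFA with a planted jump of +3 exactly at onset for septic cases
  hrs <- 0:ceiling(discharge)
  base <- sample(0:1, 1)
  sofa <- base + sample(c(0, 0, 0, 1), length(hrs), replace = TRUE)
  if (septic) {
    sofa[hrs > onset] <- base + 3 + sample(0:1, sum(hrs > onset), replace = TRUE)
    sofa_hour <- sort(c(hrs, onset))
    sofa_val <- c(sofa[hrs <= onset], base + 3, sofa[hrs > onset])
    ord <- order(sofa_hour)
    sofa_series <- data.frame(hour = sofa_hour[ord], sofa = sofa_val[ord])
  } else {
    sofa_series <- data.frame(hour = hrs, sofa = sofa)
  }

  vitals <- seq(0.25, discharge, by = 1)
  labs <- seq(0.5, discharge, by = 4)

  note_seed <- spec$seed * 10000L + i
  ed_text <- plant_symptom_phrases(symptoms, spec$note_symptom_noise,
                                   seed = note_seed, lexicon = lexicon)
  notes <- list(
    list(note_type = "ED provider note", hour = stats::runif(1, 0.3, 1.2),
         text = ed_text, complete = stats::runif(1) > 0.1),
    list(note_type = "History and Physical note",
         hour = stats::runif(1, 1.0, 1.9),
         text = paste(sample(filler_sentences, 3, replace = TRUE),
                      collapse = " "),
         complete = TRUE)
  )
  if (discharge > 14) {
    notes <- c(notes, list(list(
      note_type = "Progress note", hour = 12,
      text = paste(sample(filler_sentences, 2), collapse = " "),
      complete = TRUE
    )))
  }

  jitter <- stats::rnorm(length(hrs), 0, 0.6)

  structure(
    list(
      encounter_id = id, triage_time = 0,
      vitals_times = vitals, labs_times = labs,
      sofa_series = sofa_series, orders = orders, notes = notes,
      discharge_hour = discharge,
      risk_features = list(severity = severity, jitter = jitter,
                           jitter_hours = hrs),
      truth = list(septic = septic, onset_hour = onset,
                   diagnosis = dx, symptoms = symptoms)
    ),
    class = "ed_encounter"
  )
}

#' Generate a synthetic ED cohort
#'
#' Produces encounters with the temporal and statistical structure the
#' alerting pipeline assumes: hourly vitals, 4-hourly labs, an ED provider
#' note and an H&P note within the first two hours, SOFA scores with a
#' planted acute rise at onset for septic encounters, order events that
#' satisfy (septic) or fail (non-septic) the suspicion-of-infection timing
#' windows, truly present signs drawn Bernoulli from `table`'s likelihood
#' values for the true diagnosis, and their canonical phrases planted in the
#' ED note. Each encounter also carries planted severity features consumed by
#' [surrogate_risk_score()].
#'
#' @param spec A [cohort_spec()].
#' @param table Likelihood table used as generative ground truth (defaults to
#'   [likelihood_table()]).
#' @return List of `ed_encounter` objects (class `ed_cohort`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(5, seed = 42))
#' sapply(coh, function(e) e$truth$septic)
generate_cohort <- function(spec, table = likelihood_table()) {
  stopifnot(inherits(spec, "cohort_spec"))
  lexicon <- symptom_lexicon()
  rng <- local_rng(spec$seed)
  on.exit(rng())
  out <- lapply(seq_len(spec$n_encounters), generate_encounter,
                spec = spec, table = table, lexicon = lexicon)
  class(out) <- c("ed_cohort", "list")
  out
}

#' Surrogate hourly sepsis risk score
#'
#' A deterministic logistic stand-in for an upstream structured-data risk
#' model: `plogis(6 * (severity - 0.45) + jitter[hour])`, using the severity
#' and per-hour jitter planted by [generate_cohort()]. Neutral severity
#' (0.45) maps to score 0.5 and maximal severity saturates above 0.9; the
#' spread is calibrated so that synthetic scores straddle the 0.5/0.75
#' decision thresholds.
#'
#' @param encounter An `ed_encounter` with `risk_features`.
#' @param hour Integer prediction hour.
#' @return Risk score in \[0, 1\].
#' @export
surrogate_risk_score <- function(encounter, hour) {
  rf <- encounter$risk_features
  if (is.null(rf)) stop("encounter has no planted risk features")
  i <- match(floor(hour), rf$jitter_hours)
  if (is.na(i)) stop("no risk features for hour ", hour)
  stats::plogis(6 * (rf$severity - 0.45) + rf$jitter[i])
}

#' Serialize / read a cohort as JSONL
#'
#' One encounter per line, schema-versioned. All fields round-trip except
#' numeric precision (kept at full digits).
#'
#' @param cohort An `ed_cohort`.
#' @param path Output file path.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in cohort) {
    rec <- unclass(e)
    rec$schema_version <- 1L
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @return `read_cohort_jsonl()` returns an `ed_cohort`.
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
    e$schema_version <- NULL
    e$notes <- apply_rows(e$notes)
    e$orders <- apply_rows(e$orders)
    e$truth$symptoms <- as.character(e$truth$symptoms)
    if (is.null(e$truth$onset_hour)) e$truth$onset_hour <- NULL
    class(e) <- "ed_encounter"
    e
  })
  class(out) <- c("ed_cohort", "list")
  out
}

apply_rows <- function(df) {
  if (is.null(df) || !length(df)) return(list())
  if (is.data.frame(df)) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    df
  }
}

#' Flatten cohort event streams to a table
#'
#' @param cohort An `ed_cohort`.
#' @return Data frame with one row per event (vital, lab, SOFA, order, note).
#' @export
cohort_event_table <- function(cohort) {
  rows <- lapply(cohort, function(e) {
    rbind(
      data.frame(encounter_id = e$encounter_id, event = "vital",
                 hour = e$vitals_times, detail = NA_character_),
      data.frame(encounter_id = e$encounter_id, event = "lab",
                 hour = e$labs_times, detail = NA_character_),
      data.frame(encounter_id = e$encounter_id, event = "sofa",
                 hour = e$sofa_series$hour,
                 detail = as.character(e$sofa_series$sofa)),
      if (length(e$orders)) {
        data.frame(encounter_id = e$encounter_id, event = "order",
                   hour = vapply(e$orders, `[[`, numeric(1), "hour"),
                   detail = vapply(e$orders, `[[`, character(1), "kind"))
      },
      data.frame(encounter_id = e$encounter_id, event = "note",
                 hour = vapply(e$notes, `[[`, numeric(1), "hour"),
                 detail = vapply(e$notes, `[[`, character(1), "note_type"))
    )
  })
  do.call(rbind, rows)
}
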