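# Small fixtures shared across test files. Everything is built in code so
# the suite needs no data files.

# two-disease toy table over a one-symptom universe (the spec-style toy);
# present-only semantics unless use_absence is requested
toy_table2 <- function(pa = 0.9, pb = 0.1, use_absence = FALSE) {
  likelihood_table(
    lik = list(A = c(s1 = pa), B = c(s1 = pb)),
    map = list(A = "s1", B = "s1"),
    catalog = "s1",
    use_absence = use_absence
  )
}

# small multi-symptom table where every disease maps the whole universe
toy_table_full <- function(liks, use_absence = FALSE) {
  catalog <- colnames(liks)
  map <- stats::setNames(rep(list(catalog), nrow(liks)), rownames(liks))
  lik <- stats::setNames(
    lapply(seq_len(nrow(liks)), function(i) {
      stats::setNames(as.numeric(liks[i, ]), catalog)
    }),
    rownames(liks)
  )
  likelihood_table(lik = lik, map = map, catalog = catalog,
                   use_absence = use_absence)
}

# minimal well-formed encounter for alert-loop tests: eligible from hour 2,
# notes at hour 1, no orders unless supplied
stub_encounter <- function(id = "stub1", discharge = 14, orders = list(),
                           truth = list(septic = FALSE, onset_hour = NULL,
                                        diagnosis = NA_character_,
                                        symptoms = character(0)),
                           note_text = "routine visit no acute findings") {
  hrs <- 0:ceiling(discharge)
  structure(
    list(
      encounter_id = id, triage_time = 0,
      vitals_times = seq(0.25, discharge, by = 1),
      labs_times = seq(0.5, discharge, by = 4),
      sofa_series = data.frame(hour = hrs, sofa = rep(1L, length(hrs))),
      orders = orders,
      notes = list(list(note_type = "ED provider note", hour = 1,
                        text = note_text, complete = TRUE)),
      discharge_hour = discharge,
      risk_features = list(severity = 0.45, jitter = rep(0, length(hrs)),
                           jitter_hours = hrs),
      truth = truth
    ),
    class = "ed_encounter"
  )
}

const_scorer <- function(value) function(encounter, hour) value

abx_order <- function(start, end, prophylactic = FALSE) {
  list(
    list(kind = "iv_antibiotic_start", hour = start,
         prophylactic = prophylactic),
    list(kind = "iv_antibiotic_end", hour = end, prophylactic = prophylactic)
  )
}

culture_order <- function(hour) list(list(kind = "blood_culture", hour = hour))
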