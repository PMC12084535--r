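test_that("alert config enforces threshold ordering", {
  expect_error(alert_config(theta1 = 0.4, theta2 = 0.5), "theta2 < theta1")
  expect_error(alert_config(theta1 = 1.2), "theta2 < theta1")
})

test_that("eligibility requires recent vitals/labs, no antibiotics, a note", {
  e <- stub_encounter()
  expect_true(eligible(e, 2))
  # antibiotics started before the prediction hour
  e2 <- stub_encounter(orders = abx_order(3, 120))
  expect_true(eligible(e2, 2))
  expect_false(eligible(e2, 4))
  # half-open 24-h lookback (hour-24, hour]: a lab exactly 24 h old is out
  e3 <- stub_encounter(discharge = 40)
  e3$labs_times <- 2
  expect_true(eligible(e3, 25))
  e3$labs_times <- 1        # exactly hour - 24
  expect_false(eligible(e3, 25))
  e3$labs_times <- 0.5      # the hour-25 lab of the boundary example
  expect_false(eligible(e3, 25))
  # no qualifying note type
  e4 <- stub_encounter()
  e4$notes[[1]]$note_type <- "Nursing flowsheet"
  expect_false(eligible(e4, 2, alert_config()))
})

test_that("gating respects the closed boundary convention", {
  cfg <- alert_config()
  expect_equal(gate(0.80, cfg), "direct_fire")
  expect_equal(gate(0.75, cfg), "direct_fire")
  expect_equal(gate(0.60, cfg), "llm_zone")
  expect_equal(gate(0.50, cfg), "llm_zone")
  expect_equal(gate(0.49, cfg), "no_action")
  expect_error(gate(1.2, cfg), "score")
  expect_error(gate(NA_real_, cfg), "score")
})

test_that("ddx and slt decisions are strict conjunctions", {
  top <- c("cardiogenic shock", "pulmonary embolism", "Severe Sepsis",
           "hypovolemia", "influenza")
  expect_true(ddx_decision(top, TRUE))
  expect_false(ddx_decision(top, FALSE))
  expect_false(ddx_decision(setdiff(disease_set(), "Severe Sepsis")[1:5],
                            TRUE))
  cfg <- alert_config(alpha = 0.5)
  expect_true(slt_decision(0.9, TRUE, cfg))
  expect_false(slt_decision(0.5, TRUE, cfg))  # strict exceedance
  expect_false(slt_decision(0.9, FALSE, cfg))
  expect_error(slt_decision(0.9, TRUE, alert_config()), "alpha")
})

test_that("baseline decision fires on a planted sepsis signature only", {
  lex <- symptom_lexicon()
  sep_txt <- paste(lex[c("suspicion of bacterial infection", "fever",
                         "elevated lactate")], collapse = ". ")
  notes_yes <- list(list(note_type = "ED provider note", hour = 1,
                         text = sep_txt, complete = TRUE))
  notes_no <- list(list(note_type = "ED provider note", hour = 1,
                        text = "well appearing no complaints",
                        complete = TRUE))
  expect_true(baseline_decision(notes_yes))
  expect_false(baseline_decision(notes_no))
  # majority yes,no,no -> no fire
  flip <- local({
    n <- 0
    function(prompt, context, temperature, seed) {
      n <<- n + 1
      jsonlite::toJSON(list(Sepsis = c(if (n == 1) "Yes" else "No", "j")),
                       auto_unbox = FALSE)
    }
  })
  expect_false(baseline_decision(notes_yes, backend = flip))
})

test_that("silencing arithmetic: constant 0.9 scorer on a 14-h stay fires at 2 and 8", {
  e <- stub_encounter(discharge = 14)
  rec <- run_encounter(e, scorer = const_scorer(0.9))
  fired <- Filter(function(a) a$fired, rec)
  expect_equal(vapply(fired, `[[`, numeric(1), "hour"), c(2, 8))
  # all hours were still evaluated
  expect_equal(length(rec), 12)
  expect_equal(attr(rec, "eligible_hours"), 12L)
})

test_that("scores below theta2 never alarm", {
  e <- stub_encounter()
  expect_length(run_encounter(e, scorer = const_scorer(0.3)), 0)
})

test_that("llm-zone fire composes gate, ddx decision and silencing", {
  coh <- generate_cohort(cohort_spec(3, septic_fraction = 1,
                                     note_symptom_noise = 0, seed = 41))
  e <- Filter(function(x) "suspicion of bacterial infection" %in%
                x$truth$symptoms, coh)[[1]]
  e$truth$onset_hour <- NULL # keep monitoring open the whole stay
  e$orders <- list()
  e$discharge_hour <- 14
  rec <- run_encounter(e, scorer = const_scorer(0.6),
                       extractor = make_oracle_extractor(),
                       config = alert_config(variant = "ddx"))
  fired <- Filter(function(a) a$fired, rec)
  expect_equal(fired[[1]]$hour, 2)
  expect_equal(fired[[1]]$zone, "llm_gated")
  expect_true(all(diff(vapply(fired, `[[`, numeric(1), "hour")) >= 6))
  expect_true("Severe Sepsis" %in% fired[[1]]$ddx_topk)
})

test_that("monitoring stops at sepsis onset", {
  e <- stub_encounter(discharge = 30)
  e$truth <- list(septic = TRUE, onset_hour = 6.5, diagnosis = "Severe Sepsis",
                  symptoms = character(0))
  rec <- run_encounter(e, scorer = const_scorer(0.9))
  expect_true(all(vapply(rec, `[[`, numeric(1), "hour") < 6.5))
})

test_that("no two fired alarms are closer than the silencing period (property)", {
  coh <- generate_cohort(cohort_spec(60, seed = 17))
  for (variant in c("ddx", "composer_only")) {
    run <- run_cohort(coh, config = alert_config(variant = variant))
    fired <- Filter(function(a) a$fired, run$alarms)
    by_enc <- split(vapply(fired, `[[`, numeric(1), "hour"),
                    vapply(fired, `[[`, character(1), "encounter_id"))
    for (hrs in by_enc) {
      if (length(hrs) > 1) expect_true(all(diff(sort(hrs)) >= 6))
    }
  }
})

test_that("composer_only at 0.6 fires a superset of theta1=0.75 direct fires", {
  coh <- generate_cohort(cohort_spec(40, seed = 29))
  # silencing off isolates the pure threshold comparison
  cfg_low <- alert_config(variant = "composer_only",
                          composer_only_threshold = 0.6, silencing_hours = 0)
  cfg_ddx <- alert_config(variant = "ddx", silencing_hours = 0)
  key <- function(a) paste(a$encounter_id, a$hour)
  low <- run_cohort(coh, config = cfg_low)$alarms
  ddx <- run_cohort(coh, config = cfg_ddx)$alarms
  low_fired <- vapply(Filter(function(a) a$fired, low), key, character(1))
  direct_fired <- vapply(
    Filter(function(a) a$fired && a$zone == "direct", ddx), key, character(1))
  expect_true(all(direct_fired %in% low_fired))
})

test_that("ddx-variant alarms only occur where the gate is open", {
  coh <- generate_cohort(cohort_spec(30, seed = 37))
  run <- run_cohort(coh, config = alert_config(variant = "ddx"))
  for (a in run$alarms) {
    e <- Filter(function(x) x$encounter_id == a$encounter_id, coh)[[1]]
    expect_gte(surrogate_risk_score(e, a$hour), 0.5)
  }
})

test_that("alpha calibration returns a grid value and is deterministic", {
  dev <- generate_cohort(cohort_spec(80, note_symptom_noise = 0, seed = 53))
  a1 <- calibrate_alpha(dev, grid = c(0.2, 0.5, 0.8))
  a2 <- calibrate_alpha(dev, grid = c(0.2, 0.5, 0.8))
  expect_identical(a1, a2)
  expect_true(a1 %in% c(0.2, 0.5, 0.8))
})
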