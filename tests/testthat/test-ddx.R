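test_that("catalog and disease set match their stated cardinalities", {
  expect_length(symptom_catalog(), 51)
  expect_true("suspicion of bacterial infection" %in% symptom_catalog())
  expect_length(disease_set(), 19)
  expect_true("Severe Sepsis" %in% disease_set())
  expect_setequal(names(disease_symptom_map()), disease_set())
  expect_true(all(unlist(disease_symptom_map()) %in% symptom_catalog()))
})

test_that("likelihood table validates its invariants", {
  tab <- likelihood_table()
  expect_equal(sum(tab$prior), 1)
  expect_true(all(unlist(tab$lik) > 0 & unlist(tab$lik) < 1))
  expect_error(likelihood_table(prior = stats::setNames(
    rep(0.1, 19), disease_set())), "sum to 1")
  bad <- lapply(disease_symptom_map(), function(s) {
    stats::setNames(rep(1.0, length(s)), s)
  })
  expect_error(likelihood_table(lik = bad), "strictly in")
})

test_that("joint likelihood is the log-product over present mapped signs", {
  tab <- toy_table_full(rbind(A = c(s1 = 0.9, s2 = 0.8, s3 = 0.1)))
  expect_equal(joint_likelihood(character(0), "A", tab), 0)
  expect_equal(joint_likelihood("s1", "A", tab), log(0.9))
  expect_equal(joint_likelihood(c("s1", "s2", "s3"), "A", tab), log(0.072))
  # signs outside the disease map contribute nothing
  tab2 <- likelihood_table()
  expect_equal(joint_likelihood("ketonuria", "Severe Sepsis", tab2), 0)
  expect_error(joint_likelihood("nope", "A", tab), "unknown symptom")
  expect_error(joint_likelihood("s1", "nope", tab), "unknown disease")
})

test_that("posterior reproduces the two-disease toy and the prior limit", {
  tab <- toy_table2(0.9, 0.1)
  res <- ddx_posterior("s1", tab)
  expect_equal(unname(res$posterior[c("A", "B")]), c(0.9, 0.1))
  expect_equal(res$ranked, c("A", "B"))
  # empty set: present-only semantics fall back to the prior
  expect_equal(unname(ddx_posterior(character(0), tab)$posterior),
               c(0.5, 0.5))
  # identical rows: uniform posterior, table-order ranking
  same <- toy_table_full(rbind(A = c(s1 = 0.4), B = c(s1 = 0.4)))
  res2 <- ddx_posterior("s1", same)
  expect_equal(unname(res2$posterior), c(0.5, 0.5))
  expect_equal(res2$ranked, c("A", "B"))
})

test_that("posteriors normalize to 1 for arbitrary inputs (property)", {
  tab <- likelihood_table()
  set.seed(99)
  for (i in 1:40) {
    present <- sample(symptom_catalog(), sample(0:12, 1))
    res <- ddx_posterior(present, tab)
    expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
    expect_setequal(res$ranked, disease_set())
  }
})

test_that("log-space posterior matches direct-product computation to 1e-12", {
  liks <- rbind(A = c(s1 = 0.9, s2 = 0.2, s3 = 0.5),
                B = c(s1 = 0.3, s2 = 0.7, s3 = 0.6),
                C = c(s1 = 0.5, s2 = 0.5, s3 = 0.5))
  for (use_absence in c(TRUE, FALSE)) {
    tab <- toy_table_full(liks, use_absence = use_absence)
    for (present in list(character(0), "s1", c("s1", "s3"),
                         c("s1", "s2", "s3"))) {
      direct <- vapply(rownames(liks), function(d) {
        p <- liks[d, ]
        hit <- colnames(liks) %in% present
        num <- prod(p[hit])
        if (use_absence) num <- num * prod(1 - p[!hit])
        num / 3
      }, numeric(1))
      direct <- direct / sum(direct)
      got <- ddx_posterior(present, tab)$posterior
      expect_equal(unname(got[names(direct)]), unname(direct),
                   tolerance = 1e-12)
    }
  }
})

test_that("posterior is invariant to symptom order and duplicates", {
  tab <- likelihood_table()
  s <- c("fever", "hypotension", "elevated lactate")
  a <- ddx_posterior(s, tab)$posterior
  b <- ddx_posterior(rev(s), tab)$posterior
  d <- ddx_posterior(c(s, s), tab)$posterior
  expect_equal(a, b)
  expect_equal(a, d)
})

test_that("adding a sign most likely under D never lowers D's rank", {
  set.seed(7)
  syms <- paste0("s", 1:6)
  for (i in 1:20) {
    liks <- matrix(runif(18, 0.05, 0.95), nrow = 3,
                   dimnames = list(c("A", "B", "C"), syms))
    tab <- toy_table_full(liks, use_absence = TRUE)
    present <- sample(syms, 2)
    extra <- sample(setdiff(syms, present), 1)
    liks[, extra] <- c(0.9, runif(2, 0.05, 0.5)) # A clearly favored
    tab2 <- toy_table_full(liks, use_absence = TRUE)
    rank_of <- function(res) match("A", res$ranked)
    before <- rank_of(ddx_posterior(present, tab2))
    after <- rank_of(ddx_posterior(c(present, extra), tab2))
    expect_lte(after, before)
  }
})

test_that("top_k slices the ranking and validates k", {
  tab <- likelihood_table()
  res <- ddx_posterior("fever", tab)
  expect_length(ddx_top_k(res, 19), 19)
  expect_equal(ddx_top_k(res, 1), res$ranked[1])
  expect_error(ddx_top_k(res, 0), "k must be")
  expect_error(ddx_top_k(res, 20), "k must be")
})

test_that("sepsis likelihood reads the Severe Sepsis coordinate", {
  tab <- likelihood_table()
  present <- c("suspicion of bacterial infection", "fever",
               "elevated lactate")
  expect_equal(sepsis_likelihood(present, tab),
               unname(ddx_posterior(present, tab)$posterior["Severe Sepsis"]))
  expect_gt(sepsis_likelihood(present, tab), 0.5)
})

test_that("degenerate inputs raise errors", {
  tab <- toy_table2()
  expect_error(ddx_posterior("unknown sign", tab), "unknown symptom")
})

test_that("calibration: budget 0 returns the initial table; non-regression holds", {
  sets <- list(
    list(symptoms = c("suspicion of bacterial infection", "fever"),
         septic = TRUE, diagnosis = "Severe Sepsis"),
    list(symptoms = "chest pain", septic = FALSE,
         diagnosis = "myocardial infarction")
  )
  init <- likelihood_table()
  expect_identical(calibrate_likelihoods(sets, init, budget = 0), init)
  expect_error(calibrate_likelihoods(sets[1], init, budget = 5),
               "septic and non-septic")

  coh <- generate_cohort(cohort_spec(150, septic_fraction = 0.3,
                                     mimic_fraction = 1,
                                     note_symptom_noise = 0, seed = 8))
  dev <- lapply(coh, function(e) {
    list(symptoms = e$truth$symptoms, septic = e$truth$septic,
         diagnosis = e$truth$diagnosis)
  })
  septic <- vapply(dev, `[[`, logical(1), "septic")
  dx <- vapply(dev, `[[`, character(1), "diagnosis")
  obj_init <- edsepsis:::ddx_alert_objective(init, lapply(dev, `[[`, "symptoms"),
                                             septic, dx)
  for (seed in c(1, 2)) {
    out <- calibrate_likelihoods(dev, init, budget = 6, seed = seed)
    obj <- edsepsis:::ddx_alert_objective(out, lapply(dev, `[[`, "symptoms"),
                                          septic, dx)
    expect_gte(obj$f1, obj_init$f1)
  }
  # determinism given seed
  a <- calibrate_likelihoods(dev, init, budget = 4, seed = 3)
  b <- calibrate_likelihoods(dev, init, budget = 4, seed = 3)
  expect_identical(a, b)
})
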