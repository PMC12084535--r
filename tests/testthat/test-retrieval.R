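note <- function(text, hour = 1, type = "ED provider note") {
  list(note_type = type, hour = hour, text = text, complete = TRUE)
}

words <- function(n, w = "tok") paste(paste0(w, seq_len(n)), collapse = " ")

test_that("retrieval config enforces its invariants", {
  expect_error(retrieval_config(chunk_size = 100, chunk_overlap = 100),
               "overlap")
  expect_error(retrieval_config(n_votes = 2), "odd")
  expect_error(retrieval_config(top_k = 0), "top_k")
})

test_that("chunker window arithmetic matches the stride rule", {
  cfg <- retrieval_config()
  expect_length(chunk_notes(list(note(words(1000))), cfg), 1)
  two <- chunk_notes(list(note(words(1700))), cfg)
  expect_length(two, 2)
  expect_equal(vapply(two, `[[`, numeric(1), "start_token"), c(0, 700))
  expect_length(chunk_notes(list(), cfg), 0)
})

test_that("chunk coverage is exact: every token in >= 1 chunk, overlap exact", {
  cfg <- retrieval_config(chunk_size = 10, chunk_overlap = 3)
  token_idx <- function(ch) {
    ch$start_token + seq_along(strsplit(ch$text, " ")[[1]])
  }
  for (n in c(1, 9, 10, 11, 17, 18, 25, 40)) {
    chunks <- chunk_notes(list(note(words(n))), cfg)
    expect_setequal(unlist(lapply(chunks, token_idx)), seq_len(n))
    if (length(chunks) > 1) {
      for (i in seq_len(length(chunks) - 1)) {
        ov <- length(intersect(token_idx(chunks[[i]]),
                               token_idx(chunks[[i + 1]])))
        expect_equal(ov, 3)
      }
    }
  }
})

test_that("chunks are ordered by note hour then start token", {
  cfg <- retrieval_config(chunk_size = 5, chunk_overlap = 1)
  chunks <- chunk_notes(list(note(words(12), hour = 3),
                             note(words(7, "x"), hour = 1)), cfg)
  ids <- vapply(chunks, `[[`, character(1), "source_note_id")
  expect_true(all(diff(as.integer(sub(":.*", "", sub("note", "", ids)))) >= 0))
  expect_true(grepl("^x1", chunks[[1]]$text)) # hour-1 note chunks first
})

test_that("retrieval ranks by cosine similarity with stable ties", {
  cfg <- retrieval_config(top_k = 5)
  emb <- bow_embedder()
  # distinct hash buckets are a precondition of the hand computation
  buckets <- vapply(c("fever", "chills", "cough"),
                    function(w) which(emb(w) > 0), integer(1))
  expect_equal(anyDuplicated(buckets), 0L)
  chunks <- list(list(text = "fever fever fever", source_note_id = "a",
                      start_token = 0),
                 list(text = "fever chills", source_note_id = "b",
                      start_token = 0),
                 list(text = "cough", source_note_id = "c", start_token = 0))
  got <- retrieve_chunks("fever", chunks, cfg, emb)
  expect_equal(vapply(got, `[[`, character(1), "source_note_id"),
               c("a", "b", "c"))
  # hand-computed cosines on token counts
  expect_equal(cosine_sim(emb("fever"), emb("fever fever fever")), 1)
  expect_equal(cosine_sim(emb("fever"), emb("fever chills")), 1 / sqrt(2))
  expect_equal(cosine_sim(emb("fever"), emb("cough")), 0)

  # K exceeding the pool returns everything; duplicates are retained in order
  expect_length(retrieve_chunks("fever", chunks[1:2],
                                retrieval_config(top_k = 5)), 2)
  dup <- retrieve_chunks("fever", chunks[c(1, 1)], cfg, emb)
  expect_equal(vapply(dup, `[[`, character(1), "text"),
               rep("fever fever fever", 2))
})

test_that("zero-norm embeddings get similarity 0", {
  expect_equal(cosine_sim(numeric(4), c(1, 0, 0, 0)), 0)
  got <- retrieve_chunks("fever", list(list(text = "cough",
                                            source_note_id = "a",
                                            start_token = 0)))
  expect_length(got, 1) # still returned, just at similarity 0
})

test_that("mock extraction keys on planted phrases with unanimous votes", {
  lex <- symptom_lexicon()
  notes <- list(note(paste("exam notable for", lex[["fever"]], "today")))
  res <- extract_symptom("fever", notes)
  expect_true(res$present)
  expect_equal(res$votes, rep(TRUE, 3))
  expect_false(any(res$parse_failures))
  expect_match(res$justification, "note states")

  none <- extract_symptom("hypotension", notes)
  expect_false(none$present)
})

test_that("majority voting and fail-safe parsing behave as specified", {
  notes <- list(note("plain text"))
  # backend voting yes, yes, no -> present
  flaky <- local({
    calls <- 0
    function(prompt, context, temperature, seed) {
      calls <<- calls + 1
      ans <- if (calls <= 2) "Yes" else "No"
      jsonlite::toJSON(list(fever = c(ans, "j")), auto_unbox = FALSE)
    }
  })
  res <- extract_symptom("fever", notes, backend = flaky)
  expect_true(res$present)
  expect_equal(res$votes, c(TRUE, TRUE, FALSE))

  # malformed output on every run: retried, then counted "no" and logged
  broken <- function(prompt, context, temperature, seed) "not json at all"
  res2 <- extract_symptom("fever", notes, backend = broken)
  expect_false(res2$present)
  expect_true(all(res2$parse_failures))
})

test_that("flipping a strict minority of votes never changes the outcome", {
  for (votes in list(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                     c(TRUE, TRUE, TRUE))) {
    maj <- sum(votes) > length(votes) / 2
    for (i in which(votes != maj)) {
      flipped <- votes
      flipped[i] <- maj
      expect_equal(sum(flipped) > length(flipped) / 2, maj)
    }
  }
})

test_that("extract_all round-trips the planted truth at noise 0", {
  coh <- generate_cohort(cohort_spec(30, note_symptom_noise = 0, seed = 13))
  for (e in coh) {
    got <- extract_all(symptom_catalog(), e$notes,
                       encounter_id = e$encounter_id)
    expect_setequal(got$present, e$truth$symptoms)
  }
  expect_length(extract_all(character(0), list())$present, 0)
})

test_that("per-symptom backend errors do not abort the batch", {
  angry <- function(prompt, context, temperature, seed) stop("backend down")
  got <- extract_all(c("fever", "hypotension"), list(note("text")),
                     backend = angry)
  expect_length(got$present, 0)
  expect_true(all(vapply(got$results, function(r) all(r$parse_failures),
                         logical(1))))
})

test_that("full-catalog extraction over an encounter is fast enough to test with", {
  e <- generate_cohort(cohort_spec(1, septic_fraction = 1, seed = 2))[[1]]
  t0 <- Sys.time()
  got <- extract_all(symptom_catalog(), e$notes, encounter_id = "speed")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_length(got$results, 51)
})
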