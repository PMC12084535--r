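#' Retrieval and extraction configuration
#'
#' Parameters of the retrieval-augmented extraction pipeline: notes are
#' segmented into overlapping chunks of `chunk_size` tokens (whitespace
#' tokenization; the production tokenizer is model-internal, so a
#' deterministic, model-free token definition is used for chunking), the
#' `top_k` chunks most cosine-similar to the query embedding form the
#' context, and the extractor backend is run `n_votes` times at
#' `temperature`, taking the majority of parsed yes/no answers.
#'
#' @param chunk_size Tokens per chunk (default 1000).
#' @param chunk_overlap Token overlap between consecutive chunks (default
#'   300); must satisfy `0 <= chunk_overlap < chunk_size`.
#' @param top_k Number of chunks retrieved (default 5).
#' @param temperature Sampling temperature passed to the backend (default
#'   0.3; ignored by deterministic backends).
#' @param n_votes Odd number of extraction runs (default 3).
#' @return Object of class `retrieval_config`.
#' @export
retrieval_config <- function(chunk_size = 1000, chunk_overlap = 300,
                             top_k = 5, temperature = 0.3, n_votes = 3) {
  if (chunk_overlap < 0 || chunk_overlap >= chunk_size) {
    stop("chunk_overlap must satisfy 0 <= overlap < chunk_size")
  }
  if (top_k < 1) stop("top_k must be >= 1")
  if (n_votes %% 2 != 1) stop("n_votes must be odd")
  structure(
    list(chunk_size = chunk_size, chunk_overlap = chunk_overlap,
         top_k = top_k, temperature = temperature, n_votes = n_votes),
    class = "retrieval_config"
  )
}

#' Extraction prompt templates
#'
#' The two prompt contracts of the extraction pipeline: one querying a single
#' clinical sign or symptom, one asking directly whether sepsis is present
#' (the note-only baseline). `{symptom}` and `{context}` are substituted at
#' call time; both demand a JSON answer of the form
#' `{<name>: ["Yes or No", "Concise justification?"]}`.
#'
#' @return Named list with elements `symptom` and `sepsis`.
#' @export
prompt_templates <- function() {
  list(
    symptom = paste0(
      "You are an ED doctor. Your task is to identify the following ",
      "abnormal clinical signs and symptoms: {symptom}. Think step-by-step ",
      "and provide your response in the following JSON format: ",
      "{\"{symptom}\": [\"Yes or No\", \"Concise justification?\"]} ",
      "Medical note: {context}."
    ),
    sepsis = paste0(
      "You are an ED doctor. Your task is to identify if sepsis is present ",
      "in the current admission. Think step-by-step and provide your ",
      "response in the following JSON format: ",
      "{\"Sepsis\": [\"Yes or No\", \"Concise justification?\"]}. ",
      "Note that \"Sepsis\" is defined as suspicion or documentation of ",
      "infection with evidence of organ dysfunction. ",
      "Medical note: {context}."
    )
  )
}

tokenize_ws <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Chunk clinical notes into token windows
#'
#' Each note (already filtered to hours at or before the prediction time) is
#' split into windows of `chunk_size` whitespace tokens with stride
#' `chunk_size - chunk_overlap`; the final partial window is kept, and no
#' window is emitted beyond the one that reaches the last token. Chunks are
#' ordered by (note hour, start token).
#'
#' @param notes List of note events (`note_type`, `hour`, `text`).
#' @param config A [retrieval_config()].
#' @return List of chunks: `text`, `source_note_id` (index + type), and
#'   `start_token` (0-based).
#' @export
chunk_notes <- function(notes, config = retrieval_config()) {
  stopifnot(inherits(config, "retrieval_config"))
  if (!length(notes)) return(list())
  hours <- vapply(notes, `[[`, numeric(1), "hour")
  notes <- notes[order(hours)]
  stride <- config$chunk_size - config$chunk_overlap
  out <- list()
  for (ni in seq_along(notes)) {
    toks <- tokenize_ws(notes[[ni]]$text)
    n <- length(toks)
    if (!n) next
    starts <- 0
    s <- 0
    while (s + config$chunk_size < n) {
      s <- s + stride
      starts <- c(starts, s)
    }
    for (st in starts) {
      idx <- (st + 1):min(st + config$chunk_size, n)
      out[[length(out) + 1]] <- list(
        text = paste(toks[idx], collapse = " "),
        source_note_id = paste0("note", ni, ":", notes[[ni]]$note_type),
        start_token = st
      )
    }
  }
  out
}

#' Hashed bag-of-words embedder
#'
#' Deterministic test embedder: each lowercased token is hashed into one of
#' `dim` buckets (a small polynomial rolling hash) and counted. Stands in
#' for a neural sentence embedder behind the same text -> vector interface.
#'
#' @param dim Embedding dimension (default 64).
#' @return Function mapping a character string to a numeric vector.
#' @export
bow_embedder <- function(dim = 64) {
  force(dim)
  function(text) {
    v <- numeric(dim)
    for (tok in tokenize_ws(tolower(text))) {
      codes <- utf8ToInt(tok)
      h <- 0
      for (cc in codes) h <- (h * 31 + cc) %% 1000003
      v[(h %% dim) + 1] <- v[(h %% dim) + 1] + 1
    }
    v
  }
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Retrieve the chunks most similar to a query
#'
#' Top `top_k` chunks by cosine similarity between the query embedding and
#' each chunk embedding, descending; ties keep the input chunk ordering.
#' Duplicated chunks are retained.
#'
#' @param query Query text.
#' @param chunks Chunk list from [chunk_notes()].
#' @param config A [retrieval_config()].
#' @param embedder Deterministic text -> vector function
#'   (default [bow_embedder()]).
#' @return List of at most `top_k` chunks.
#' @export
retrieve_chunks <- function(query, chunks, config = retrieval_config(),
                            embedder = bow_embedder()) {
  if (!length(chunks)) return(list())
  q <- embedder(query)
  sims <- vapply(chunks, function(ch) cosine_sim(q, embedder(ch$text)),
                 numeric(1))
  ord <- order(-sims) # stable: ties resolved by chunk ordering
  chunks[ord[seq_len(min(config$top_k, length(chunks)))]]
}

fill_template <- function(template, symptom = NULL, context = "") {
  if (!is.null(symptom)) {
    template <- gsub("{symptom}", symptom, template, fixed = TRUE)
  }
  gsub("{context}", context, template, fixed = TRUE)
}

# 32-bit-safe deterministic seed from strings/ints, for per-run backend seeds
derive_seed <- function(...) {
  parts <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(parts)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

parse_extraction_json <- function(raw, key) {
  parsed <- tryCatch(jsonlite::fromJSON(raw), error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed[[key]]) || !length(parsed[[key]])) {
    return(NULL)
  }
  ans <- parsed[[key]]
  list(yes = identical(tolower(ans[[1]]), "yes"),
       justification = if (length(ans) > 1) as.character(ans[[2]]) else "")
}

#' Extract one clinical sign from notes
#'
#' Builds the symptom prompt, retrieves the `top_k` most query-similar
#' chunks of all notes up to the prediction hour, and queries the backend
#' `n_votes` times. Each raw output is parsed as JSON mapping the symptom to
#' `[yes/no, justification]`; an unparseable run is retried once and then
#' counted as "no" (fail-safe toward not alerting). `present` is the strict
#' majority of votes.
#'
#' @param symptom Catalog symptom name.
#' @param notes Note events with `hour` at or before the prediction hour.
#' @param config A [retrieval_config()].
#' @param backend Function `(prompt, context, temperature, seed) -> raw text`.
#' @param encounter_id Used (with the symptom and run index) to derive
#'   per-run seeds so stochastic backends are reproducible.
#' @param embedder Retrieval embedder.
#' @param lexicon Phrase lexicon; the canonical phrase enriches the
#'   retrieval query.
#' @return List (`extraction_result`): `symptom`, `present`, `votes`
#'   (logical of length `n_votes`), `justification`, `parse_failures`,
#'   `chunk_ids`.
#' @export
extract_symptom <- function(symptom, notes, config = retrieval_config(),
                            backend = mock_backend(),
                            encounter_id = "enc", embedder = bow_embedder(),
                            lexicon = symptom_lexicon()) {
  check_symptoms(symptom, names(lexicon))
  chunks <- chunk_notes(notes, config)
  query <- paste(symptom, lexicon[[symptom]])
  ctx_chunks <- retrieve_chunks(query, chunks, config, embedder)
  context <- paste(vapply(ctx_chunks, `[[`, character(1), "text"),
                   collapse = "\n")
  prompt <- fill_template(prompt_templates()$symptom, symptom, context)
  votes <- logical(config$n_votes)
  fails <- logical(config$n_votes)
  just <- ""
  for (r in seq_len(config$n_votes)) {
    seed <- derive_seed(encounter_id, symptom, r)
    ans <- parse_extraction_json(
      backend(prompt, context, config$temperature, seed), symptom)
    if (is.null(ans)) { # one retry, then fail-safe "no"
      ans <- parse_extraction_json(
        backend(prompt, context, config$temperature, seed + 1L), symptom)
    }
    if (is.null(ans)) {
      votes[r] <- FALSE
      fails[r] <- TRUE
    } else {
      votes[r] <- ans$yes
      if (ans$yes && !nzchar(just)) just <- ans$justification
    }
  }
  structure(
    list(symptom = symptom, present = sum(votes) > config$n_votes / 2,
         votes = votes, justification = just, parse_failures = fails,
         chunk_ids = vapply(ctx_chunks, `[[`, character(1),
                            "source_note_id")),
    class = "extraction_result"
  )
}

#' Extract a set of clinical signs
#'
#' Runs [extract_symptom()] for each queried symptom; per-symptom backend
#' errors are caught and recorded as absent with a parse failure rather than
#' aborting the batch.
#'
#' @param symptoms Character vector of catalog symptom names (non-empty use
#'   is typical; an empty vector returns an empty result).
#' @inheritParams extract_symptom
#' @return List with `present` (character vector of symptoms judged
#'   present), `results` (per-symptom `extraction_result`s).
#' @export
extract_all <- function(symptoms, notes, config = retrieval_config(),
                        backend = mock_backend(), encounter_id = "enc",
                        embedder = bow_embedder(),
                        lexicon = symptom_lexicon()) {
  results <- lapply(symptoms, function(s) {
    tryCatch(
      extract_symptom(s, notes, config, backend, encounter_id, embedder,
                      lexicon),
      error = function(e) {
        structure(list(symptom = s, present = FALSE,
                       votes = rep(FALSE, config$n_votes), justification = "",
                       parse_failures = rep(TRUE, config$n_votes),
                       chunk_ids = character(0)),
                  class = "extraction_result")
      }
    )
  })
  present <- vapply(results, `[[`, logical(1), "present")
  list(present = symptoms[present], results = results)
}

#' Deterministic mock extraction backend
#'
#' Emulates an instruction-following extractor by exact phrase matching: the
#' queried symptom is read back out of the prompt, and the answer is "Yes"
#' iff the symptom's canonical lexicon phrase occurs (fixed-string,
#' case-insensitive) in the retrieved context. Always returns well-formed
#' JSON; deterministic across runs, so the three votes are unanimous.
#'
#' @param lexicon Named phrase lexicon.
#' @return Backend function `(prompt, context, temperature, seed) -> text`.
#' @export
mock_backend <- function(lexicon = symptom_lexicon()) {
  force(lexicon)
  function(prompt, context, temperature, seed) {
    m <- regmatches(prompt,
                    regexpr("signs and symptoms: (.*?)\\. Think", prompt))
    symptom <- sub("signs and symptoms: (.*?)\\. Think", "\\1", m)
    if (!length(symptom) || !symptom %in% names(lexicon)) {
      return("{}")
    }
    hit <- grepl(tolower(lexicon[[symptom]]), tolower(context), fixed = TRUE)
    ans <- if (hit) "Yes" else "No"
    why <- if (hit) paste0("note states: ", lexicon[[symptom]]) else
      "no supporting documentation found"
    jsonlite::toJSON(stats::setNames(list(c(ans, why)), symptom),
                     auto_unbox = FALSE)
  }
}

#' Mock backend for the direct sepsis question
#'
#' Answers "Yes" to the note-only sepsis prompt iff the context contains the
#' bacterial-infection phrase and at least two further severe-sepsis phrases.
#'
#' @param lexicon Named phrase lexicon.
#' @return Backend function with the same signature as [mock_backend()].
#' @export
mock_sepsis_backend <- function(lexicon = symptom_lexicon()) {
  sepsis_syms <- disease_symptom_map()[["Severe Sepsis"]]
  function(prompt, context, temperature, seed) {
    low <- tolower(context)
    hits <- vapply(sepsis_syms, function(s) {
      grepl(tolower(lexicon[[s]]), low, fixed = TRUE)
    }, logical(1))
    yes <- hits[["suspicion of bacterial infection"]] && sum(hits) >= 3
    ans <- if (yes) "Yes" else "No"
    jsonlite::toJSON(list(Sepsis = c(ans, "phrase-pattern mock")),
                     auto_unbox = FALSE)
  }
}

#' Extractor adapters for the alert loop
#'
#' [run_encounter()] consumes an extractor: a function
#' `(encounter, hour) -> list(present = <character>, results = <list|NULL>)`.
#' `make_rag_extractor()` wraps the full chunk/retrieve/vote pipeline over
#' the notes available at the prediction hour. `make_oracle_extractor()`
#' reads the generator-planted truth symptom set directly -- the noise-free
#' upper bound used for mechanism checks and large simulations.
#'
#' @param symptoms Symptoms to query (default: the full catalog).
#' @param config A [retrieval_config()].
#' @param backend Extraction backend.
#' @return An extractor function.
#' @export
make_rag_extractor <- function(symptoms = symptom_catalog(),
                               config = retrieval_config(),
                               backend = mock_backend()) {
  function(encounter, hour) {
    hrs <- vapply(encounter$notes, `[[`, numeric(1), "hour")
    notes <- encounter$notes[hrs <= hour]
    extract_all(symptoms, notes, config, backend,
                encounter_id = encounter$encounter_id)
  }
}

#' @rdname make_rag_extractor
#' @export
make_oracle_extractor <- function() {
  function(encounter, hour) {
    list(present = encounter$truth$symptoms, results = NULL)
  }
}
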