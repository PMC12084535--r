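#' Sepsis-3 phenotyping configuration
#'
#' Windows and thresholds of the electronic Sepsis-3 operationalization:
#' suspicion of infection is a blood-culture draw paired with a sustained
#' course of non-prophylactic IV antibiotics (culture first: antibiotics must
#' start within `abx_after_culture_window` hours; antibiotics first: culture
#' must be drawn within `culture_after_abx_window` hours), and organ
#' dysfunction is an acute rise of `sofa_delta` or more SOFA points in the
#' window from `dysfunction_window_before` hours before to
#' `dysfunction_window_after` hours after the suspicion time. All windows are
#' closed at both ends ("within" read as inclusive).
#'
#' @param abx_after_culture_window Hours (default 72).
#' @param culture_after_abx_window Hours (default 24).
#' @param min_abx_days Minimum antibiotic course, days (default 4, i.e. a
#'   continuous span of at least 96 h from start).
#' @param sofa_delta Minimum SOFA increase (default 2).
#' @param dysfunction_window_before,dysfunction_window_after Hours (48, 24).
#' @return An object of class `phenotype_config`.
#' @export
phenotype_config <- function(abx_after_culture_window = 72,
                             culture_after_abx_window = 24,
                             min_abx_days = 4,
                             sofa_delta = 2,
                             dysfunction_window_before = 48,
                             dysfunction_window_after = 24) {
  cfg <- list(
    abx_after_culture_window = abx_after_culture_window,
    culture_after_abx_window = culture_after_abx_window,
    min_abx_days = min_abx_days,
    sofa_delta = sofa_delta,
    dysfunction_window_before = dysfunction_window_before,
    dysfunction_window_after = dysfunction_window_after
  )
  if (any(unlist(cfg[c(1, 2, 3, 5, 6)]) <= 0)) stop("all windows must be > 0")
  if (sofa_delta < 1) stop("sofa_delta must be >= 1")
  structure(cfg, class = "phenotype_config")
}

# order events are plain lists: list(kind=, hour=, prophylactic=)
order_df <- function(orders) {
  if (!length(orders)) {
    return(data.frame(kind = character(), hour = numeric(),
                      prophylactic = logical()))
  }
  data.frame(
    kind = vapply(orders, `[[`, character(1), "kind"),
    hour = vapply(orders, `[[`, numeric(1), "hour"),
    prophylactic = vapply(orders, function(o) {
      isTRUE(o$prophylactic)
    }, logical(1))
  )
}

# pair iv_antibiotic_start rows with the first subsequent end of the episode
abx_episodes <- function(df) {
  starts <- df[df$kind == "iv_antibiotic_start", , drop = FALSE]
  ends <- df[df$kind == "iv_antibiotic_end", , drop = FALSE]
  if (!nrow(starts)) {
    return(data.frame(start = numeric(), end = numeric(),
                      prophylactic = logical()))
  }
  starts <- starts[order(starts$hour), , drop = FALSE]
  ends <- ends[order(ends$hour), , drop = FALSE]
  used <- rep(FALSE, nrow(ends))
  out <- lapply(seq_len(nrow(starts)), function(i) {
    j <- which(!used & ends$hour > starts$hour[i])
    if (!length(j)) return(NULL)
    used[j[1]] <<- TRUE
    data.frame(start = starts$hour[i], end = ends$hour[j[1]],
               prophylactic = starts$prophylactic[i])
  })
  do.call(rbind, c(out, list(data.frame(start = numeric(), end = numeric(),
                                        prophylactic = logical()))))
}

#' Find suspicion-of-infection events
#'
#' Every (blood culture, qualifying antibiotic episode) pair satisfying the
#' Sepsis-3 order-timing windows. A qualifying episode is non-prophylactic
#' and lasts at least `min_abx_days` days. The suspicion time is the earlier
#' of the culture draw and the antibiotic start.
#'
#' @param orders List of order events, each a list with `kind` (one of
#'   `"blood_culture"`, `"iv_antibiotic_start"`, `"iv_antibiotic_end"`),
#'   `hour`, and for antibiotics an optional `prophylactic` flag.
#' @param config A [phenotype_config()].
#' @return Data frame with columns `suspicion_hour`, `culture_hour`,
#'   `abx_start_hour`, sorted by `suspicion_hour`; zero rows when no pair
#'   qualifies.
#' @export
find_suspicion_events <- function(orders, config = phenotype_config()) {
  stopifnot(inherits(config, "phenotype_config"))
  df <- order_df(orders)
  cultures <- sort(df$hour[df$kind == "blood_culture"])
  ep <- abx_episodes(df)
  ep <- ep[!ep$prophylactic &
             (ep$end - ep$start) >= config$min_abx_days * 24, , drop = FALSE]
  out <- data.frame(suspicion_hour = numeric(), culture_hour = numeric(),
                    abx_start_hour = numeric())
  for (ch in cultures) {
    for (ah in ep$start) {
      ok <- if (ch <= ah) {
        ah - ch <= config$abx_after_culture_window
      } else {
        ch - ah <= config$culture_after_abx_window
      }
      if (ok) {
        out <- rbind(out, data.frame(suspicion_hour = min(ch, ah),
                                     culture_hour = ch, abx_start_hour = ah))
      }
    }
  }
  out[order(out$suspicion_hour), , drop = FALSE]
}

#' Assign sepsis onset relative to a suspicion event
#'
#' Scans the SOFA series over the closed dysfunction window
#' \[suspicion - 48 h, suspicion + 24 h\] and returns the first hour t at
#' which SOFA(t) minus the running minimum SOFA (from the window start up to
#' t) is at least `sofa_delta`. The running-minimum baseline is the common
#' operationalization of "an acute rise of >= 2 points" and is monotone in
#' the window width.
#'
#' @param sofa_series Data frame or list with `hour` (strictly increasing)
#'   and `sofa` (integer scores).
#' @param suspicion_hour Suspicion-of-infection time in hours.
#' @param config A [phenotype_config()].
#' @return Onset hour, or `NULL` if no qualifying rise occurs in the window.
#' @export
assign_onset <- function(sofa_series, suspicion_hour,
                         config = phenotype_config()) {
  stopifnot(inherits(config, "phenotype_config"))
  hour <- sofa_series$hour
  sofa <- sofa_series$sofa
  if (!length(hour)) stop("sofa_series must be non-empty")
  if (is.unsorted(hour, strictly = TRUE)) {
    stop("sofa_series hours must be strictly increasing")
  }
  lo <- suspicion_hour - config$dysfunction_window_before
  hi <- suspicion_hour + config$dysfunction_window_after
  inw <- which(hour >= lo & hour <= hi)
  runmin <- Inf
  for (i in inw) {
    runmin <- min(runmin, sofa[i])
    if (sofa[i] - runmin >= config$sofa_delta) return(hour[i])
  }
  NULL
}

#' Label one encounter under Sepsis-3
#'
#' An encounter is septic iff some suspicion-of-infection event has a
#' qualifying SOFA rise in its dysfunction window; the onset is the earliest
#' qualifying dysfunction hour across suspicion events.
#'
#' @param encounter An `ed_encounter` (see [generate_cohort()]) or any list
#'   with `orders` and `sofa_series`.
#' @param config A [phenotype_config()].
#' @return List with `septic` (flag), `onset_hour` (or `NULL`), and
#'   `suspicion` (the qualifying suspicion event row, or `NULL`).
#' @export
label_encounter <- function(encounter, config = phenotype_config()) {
  ev <- find_suspicion_events(encounter$orders, config)
  best <- NULL
  best_susp <- NULL
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      on <- assign_onset(encounter$sofa_series, ev$suspicion_hour[i], config)
      if (!is.null(on) && (is.null(best) || on < best)) {
        best <- on
        best_susp <- ev[i, , drop = FALSE]
      }
    }
  }
  list(septic = !is.null(best), onset_hour = best, suspicion = best_susp)
}

#' Label a whole cohort
#'
#' @param cohort List of encounters.
#' @param config A [phenotype_config()].
#' @return Data frame with `encounter_id`, `septic`, `onset_hour` (NA when
#'   non-septic).
#' @export
label_cohort <- function(cohort, config = phenotype_config()) {
  rows <- lapply(cohort, function(e) {
    lab <- label_encounter(e, config)
    data.frame(encounter_id = e$encounter_id, septic = lab$septic,
               onset_hour = if (is.null(lab$onset_hour)) NA_real_
                            else lab$onset_hour)
  })
  do.call(rbind, rows)
}
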