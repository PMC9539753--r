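# Trial-level and session-level behavioral statistics: outcome
# classification from event logs, session summaries, the conditional
# omission metrics (OAC / OAIO / extended OAIO) that separate attentional
# omissions from reward-eating confounds, and the perseveration rank-transfer
# analysis.

OUTCOMES <- c("correct", "incorrect", "omission", "premature")

normalize_outcomes <- function(x) {
  x <- tolower(as.character(x))
  map <- c(c = "correct", i = "incorrect", o = "omission", p = "premature")
  short <- x %in% names(map)
  x[short] <- map[x[short]]
  bad <- !x %in% OUTCOMES
  if (any(bad)) {
    stop("unknown outcome symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Summarise a session
#'
#' Outcome counts and fractions, latency means and duration for one session.
#' Accuracy is correct / (correct + incorrect); with no responded trials it
#' is `NA` and flagged undefined rather than forced to 0 or 1, and such
#' sessions are excluded from group means downstream.
#'
#' @param session an `fc_session`, or any list with a `trials` data.frame
#'   (and optionally `meta`).
#' @return one-row data.frame with counts (`n_trials`, `n_correct`,
#'   `n_incorrect`, `n_omission`, `n_premature`), `accuracy`,
#'   `accuracy_defined`, `omission_fraction`, `premature_fraction`, latency
#'   and eating means, and `duration_min`.
#' @export
session_summary <- function(session) {
  tr <- session$trials
  out <- tr$outcome
  n <- nrow(tr)
  nc <- sum(out == "correct")
  ni <- sum(out == "incorrect")
  no <- sum(out == "omission")
  np <- sum(out == "premature")
  stopifnot(nc + ni + no + np == n)
  acc_def <- (nc + ni) > 0
  lat <- tr$response_latency_s
  poke_t <- tr$stimulus_onset_s + lat
  if (all(is.na(poke_t)) && !all(is.na(tr$reward_retrieval_s))) {
    # magazine sessions: no stimulus; reward latency is undefined
    poke_t <- rep(NA_real_, n)
  }
  reward_lat <- tr$reward_retrieval_s - poke_t
  meta <- session$meta
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE)
                            else NA_real_
  data.frame(
    stage = if (!is.null(meta$stage)) meta$stage else NA_character_,
    sd_s = if (!is.null(meta$sd_s)) meta$sd_s else NA_real_,
    iti_s = if (!is.null(meta$iti_s)) meta$iti_s else NA_real_,
    n_trials = n, n_correct = nc, n_incorrect = ni, n_omission = no,
    n_premature = np,
    accuracy = if (acc_def) nc / (nc + ni) else NA_real_,
    accuracy_defined = acc_def,
    omission_fraction = if (n > 0) no / n else NA_real_,
    premature_fraction = if (n > 0) np / n else NA_real_,
    mean_correct_latency_s = mean_or_na(lat[out == "correct"]),
    mean_incorrect_latency_s = mean_or_na(lat[out == "incorrect"]),
    mean_reward_latency_s = mean_or_na(reward_lat[out == "correct"]),
    mean_eating_s = mean_or_na(tr$eating_duration_s[out == "correct"]),
    duration_min = if (!is.null(meta$duration_s)) meta$duration_s / 60
                   else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Conditional omission fractions (OAC / OAIO / extended OAIO)
#'
#' Fraction of trials that are omissions, conditioned on the outcome of the
#' immediately preceding trial:
#' \describe{
#'   \item{OAC}{predecessor correct -- reward from the previous trial may
#'     still be occupying the animal, so this measure is confounded by
#'     eating delays.}
#'   \item{OAIO}{predecessor incorrect or omission -- no reward precedes the
#'     trial, so eating cannot explain an omission here.}
#'   \item{OAIO_EXT}{OAIO after additionally dropping trials whose
#'     predecessor is an omission that itself immediately follows a correct
#'     trial (a very long eating bout can outlast one full trial).}
#' }
#' The first trial (no predecessor) and trials whose predecessor is a
#' premature response belong to no denominator; setting
#' `include_premature_predecessor = TRUE` adopts the broader
#' "after any non-correct trial" reading of OAIO.
#'
#' @param outcomes character vector of per-trial outcomes in session order
#'   (`"correct"`, `"incorrect"`, `"omission"`, `"premature"`, or the
#'   initials `C`/`I`/`O`/`P`).
#' @param mode which conditional metric to compute.
#' @param include_premature_predecessor include premature predecessors in the
#'   OAIO/OAIO_EXT denominator.
#' @return list with `fraction` (`NA` when the denominator is empty), `num`,
#'   `den` and `defined`.
#' @examples
#' conditional_omissions(c("C", "O", "I", "O", "O", "C", "O"), "OAC")
#' @export
conditional_omissions <- function(outcomes,
                                  mode = c("OAC", "OAIO", "OAIO_EXT"),
                                  include_premature_predecessor = FALSE) {
  mode <- match.arg(mode)
  o <- normalize_outcomes(outcomes)
  n <- length(o)
  if (n < 1) stop("outcomes must contain at least one trial")
  if (n == 1) return(list(fraction = NA_real_, num = 0L, den = 0L,
                          defined = FALSE))
  pred <- o[seq_len(n - 1)]
  cur <- o[2:n]
  if (mode == "OAC") {
    elig <- pred == "correct"
  } else {
    targets <- c("incorrect", "omission")
    if (include_premature_predecessor) targets <- c(targets, "premature")
    elig <- pred %in% targets
    if (mode == "OAIO_EXT") {
      # predecessor is an omission that itself follows a correct trial
      pred2 <- c(NA_character_, o[seq_len(n - 2)])
      contaminated <- pred == "omission" & !is.na(pred2) & pred2 == "correct"
      elig <- elig & !contaminated
    }
  }
  num <- sum(elig & cur == "omission")
  den <- sum(elig)
  list(fraction = if (den > 0) num / den else NA_real_,
       num = num, den = den, defined = den > 0)
}

#' Classify a single cued trial from its events
#'
#' Applies the outcome rules to the time-ordered events of one trial window:
#' an aperture poke before stimulus onset is premature; a poke in the cued
#' aperture within stimulus duration + limited hold of onset is correct; a
#' poke in a dark aperture within the window is incorrect; no poke by the end
#' of the window is an omission.
#'
#' @param trial_events data.frame with columns `time_s`, `event`, `arg`
#'   covering one trial, times relative to any origin, ordered.
#' @param sd_s,limited_hold_s,iti_s trial timing constants; `iti_s` is
#'   accepted for interface completeness (prematurity is determined by poke
#'   time relative to stimulus onset).
#' @return list with `outcome`, `cued_aperture`, `responded_aperture`,
#'   `response_latency_s`.
#' @export
classify_trial <- function(trial_events, sd_s, limited_hold_s, iti_s = NA) {
  ev <- trial_events
  if (is.unsorted(ev$time_s)) stop("trial events are out of time order")
  pokes <- ev[ev$event == "POKE_APERTURE", , drop = FALSE]
  if (nrow(pokes) > 0 &&
      any(is.na(pokes$arg) | pokes$arg < 1 | pokes$arg > 5)) {
    stop("POKE_APERTURE with undefined aperture id")
  }
  on_row <- which(ev$event == "STIM_ON")
  if (length(on_row) == 0) {
    if (nrow(pokes) > 0) {
      return(list(outcome = "premature", cued_aperture = NA_integer_,
                  responded_aperture = as.integer(pokes$arg[1]),
                  response_latency_s = NA_real_))
    }
    return(list(outcome = "omission", cued_aperture = NA_integer_,
                responded_aperture = NA_integer_,
                response_latency_s = NA_real_))
  }
  onset <- ev$time_s[on_row[1]]
  cued <- as.integer(ev$arg[on_row[1]])
  early <- pokes[pokes$time_s < onset, , drop = FALSE]
  if (nrow(early) > 0) {
    return(list(outcome = "premature", cued_aperture = cued,
                responded_aperture = as.integer(early$arg[1]),
                response_latency_s = NA_real_))
  }
  wend <- onset + sd_s + limited_hold_s + 2e-3  # ms-rounding slack
  inwin <- pokes[pokes$time_s >= onset & pokes$time_s <= wend, , drop = FALSE]
  if (nrow(inwin) == 0) {
    return(list(outcome = "omission", cued_aperture = cued,
                responded_aperture = NA_integer_,
                response_latency_s = NA_real_))
  }
  ap <- as.integer(inwin$arg[1])
  list(outcome = if (ap == cued) "correct" else "incorrect",
       cued_aperture = cued, responded_aperture = ap,
       response_latency_s = inwin$time_s[1] - onset)
}

#' Eating time from the events of one correct trial
#'
#' Seconds from the retrieval head entry (`POKE_MAGAZINE`) to the annotated
#' `EAT_END`. A missing eat-end annotation yields `NA`, never zero.
#'
#' @param trial_events data.frame with columns `time_s`, `event`.
#' @return seconds (>= 0) or `NA_real_`.
#' @export
eating_time <- function(trial_events) {
  entry <- trial_events$time_s[trial_events$event == "POKE_MAGAZINE"]
  eend <- trial_events$time_s[trial_events$event == "EAT_END"]
  if (length(entry) == 0 || length(eend) == 0) return(NA_real_)
  d <- eend[1] - entry[1]
  if (d < 0) stop("EAT_END precedes magazine head entry")
  d
}

#' Rank apertures by acquisition preference
#'
#' Counts responses into each of the five apertures across a mouse's operant
#' acquisition sessions and rank-orders the apertures from most to least
#' preferred. Ties are broken by ascending aperture id.
#'
#' @param acquisition_sessions an `fc_session` or list of them (their
#'   `trials` need `responded_aperture`).
#' @return list with `ranking` (aperture ids, rank 1 first),
#'   `counts_by_rank` and `counts_by_aperture`.
#' @export
aperture_rank_profile <- function(acquisition_sessions) {
  if (inherits(acquisition_sessions, "fc_session")) {
    acquisition_sessions <- list(acquisition_sessions)
  }
  aps <- unlist(lapply(acquisition_sessions,
                       function(s) s$trials$responded_aperture))
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0) stop("no aperture responses: ranking undefined")
  counts <- tabulate(aps, nbins = 5)
  ranking <- order(-counts, seq_len(5))
  list(ranking = ranking, counts_by_rank = counts[ranking],
       counts_by_aperture = counts)
}

#' Tally discrimination errors into acquisition preference ranks
#'
#' Carries a mouse's acquisition aperture ranking forward and counts how many
#' incorrect discrimination responses fell into the aperture of each rank.
#' The tally over ranks equals the total number of incorrect responses.
#'
#' @param ranking aperture ids in rank order (a permutation of 1..5, e.g.
#'   `aperture_rank_profile()$ranking`).
#' @param discrimination_sessions an `fc_session` or list of them.
#' @return integer vector of length 5: errors at rank 1..5.
#' @export
rank_transfer_errors <- function(ranking, discrimination_sessions) {
  if (!setequal(ranking, 1:5) || length(ranking) != 5) {
    stop("ranking must be a permutation of aperture ids 1..5")
  }
  if (inherits(discrimination_sessions, "fc_session")) {
    discrimination_sessions <- list(discrimination_sessions)
  }
  errs <- unlist(lapply(discrimination_sessions, function(s) {
    tr <- s$trials
    tr$responded_aperture[tr$outcome == "incorrect"]
  }))
  rank_of <- integer(5)
  rank_of[ranking] <- seq_len(5)
  out <- integer(5)
  if (length(errs) > 0) {
    tab <- tabulate(rank_of[errs], nbins = 5)
    out <- tab
  }
  out
}

#' Recover the lapse curve from simulated OAIO
#'
#' OAIO conditions on trials with no preceding reward, so (up to a small
#' contribution from slow-latency misses and from eating bouts that outlast a
#' whole trial) it estimates the attentional lapse probability directly.
#' This utility simulates training sessions at every staircase SD until the
#' requested trial count and compares the pooled OAIO against the generative
#' [lapse_probability()] curve.
#'
#' @param params `fc_agent_params`.
#' @param config protocol configuration.
#' @param n_trials_per_sd minimum simulated trials at each SD.
#' @param seed optional seed.
#' @return data.frame with `sd_s`, `truth`, `estimate`, `abs_error`.
#' @export
lapse_recovery <- function(params, config = default_protocol(),
                           n_trials_per_sd = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(config$train_sd_sequence_s, function(sd) {
    num <- 0L
    den <- 0L
    tot <- 0L
    while (tot < n_trials_per_sd) {
      s <- simulate_session(params, "training", config, sd_s = sd,
                            emit_events = FALSE)
      co <- conditional_omissions(s$trials$outcome, "OAIO")
      num <- num + co$num
      den <- den + co$den
      tot <- tot + nrow(s$trials)
    }
    est <- num / den
    truth <- lapse_probability(params, sd)
    data.frame(sd_s = sd, truth = truth, estimate = est,
               abs_error = abs(est - truth))
  })
  do.call(rbind, rows)
}

# tidy tables ---------------------------------------------------------------

#' Per-session metric table for a cohort or mouse
#'
#' One row per mouse x session: identity, stage, outcome counts and
#' fractions, latency and eating means, and the conditional omission metrics
#' computed within-session.
#'
#' @param x an `fc_cohort` or `fc_mouse`.
#' @return data.frame.
#' @export
session_metrics <- function(x) {
  mice <- if (inherits(x, "fc_cohort")) x$mice else list(x)
  rows <- lapply(mice, function(m) {
    if (length(m$sessions) == 0) return(NULL)
    per <- lapply(seq_along(m$sessions), function(i) {
      s <- m$sessions[[i]]
      sm <- s$summary
      oac <- conditional_omissions(s$trials$outcome, "OAC")
      oaio <- conditional_omissions(s$trials$outcome, "OAIO")
      ext <- conditional_omissions(s$trials$outcome, "OAIO_EXT")
      cbind(
        data.frame(mouse_id = m$meta$mouse_id %||% NA_character_,
                   group = m$meta$group %||% NA_character_,
                   age_days = m$meta$age_days %||% NA_real_,
                   activity = m$activity_score %||% NA_real_,
                   session = i, stringsAsFactors = FALSE),
        sm,
        data.frame(oac = oac$fraction, oac_num = oac$num, oac_den = oac$den,
                   oaio = oaio$fraction, oaio_num = oaio$num,
                   oaio_den = oaio$den,
                   oaio_ext = ext$fraction, oaio_ext_num = ext$num,
                   oaio_ext_den = ext$den)
      )
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-mouse stimulus-duration profile
#'
#' Aggregates training sessions per mouse and SD level: the mouse is the
#' unit of analysis, so session-level fractions and latency means are
#' averaged across sessions at the same SD (undefined session values are
#' skipped). The result feeds the repeated-measures ANOVA directly.
#'
#' @param cohort an `fc_cohort` (full tracks or [cohort_sd_sweep()] output).
#' @return data.frame: one row per mouse x SD with `accuracy`,
#'   `omission_fraction`, `premature_fraction`, `oac`, `oaio`, `oaio_ext`,
#'   latency and eating means, plus mouse identity, age and activity.
#' @export
sd_profile <- function(cohort) {
  sm <- session_metrics(cohort)
  sm <- sm[sm$stage == "training" & !is.na(sm$sd_s), , drop = FALSE]
  if (nrow(sm) == 0) stop("cohort contains no training sessions")
  key <- interaction(sm$mouse_id, sm$sd_s, drop = TRUE)
  agg <- function(v) tapply(v, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  first <- function(v) tapply(v, key, function(x) x[1])
  out <- data.frame(
    mouse_id = as.vector(first(sm$mouse_id)),
    group = as.vector(first(sm$group)),
    age_days = as.vector(first(sm$age_days)),
    activity = as.vector(first(sm$activity)),
    sd_s = as.vector(first(sm$sd_s)),
    n_trials = as.vector(agg(sm$n_trials)),
    accuracy = as.vector(agg(sm$accuracy)),
    omission_fraction = as.vector(agg(sm$omission_fraction)),
    premature_fraction = as.vector(agg(sm$premature_fraction)),
    oac = as.vector(agg(sm$oac)),
    oaio = as.vector(agg(sm$oaio)),
    oaio_ext = as.vector(agg(sm$oaio_ext)),
    mean_correct_latency_s = as.vector(agg(sm$mean_correct_latency_s)),
    mean_eating_s = as.vector(agg(sm$mean_eating_s)),
    stringsAsFactors = FALSE
  )
  out[order(out$group, out$mouse_id, -out$sd_s), , drop = FALSE]
}
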