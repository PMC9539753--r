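#' Default 5CSRTT protocol configuration
#'
#' Returns the staged protocol constants used throughout the package: the
#' magazine-training schedule, operant-acquisition and visuospatial-
#' discrimination session caps and advancement criteria, the 5CSRTT training
#' stimulus-duration (SD) staircase with its per-session criteria, and the
#' two test-day manipulations (variable SD, variable ITI).
#'
#' All durations are in seconds, session caps in minutes, criteria as counts
#' or fractions. Criterion comparisons are strict (`>` / `<`); ties fail.
#'
#' @return A list of class `fc_protocol`. Key fields:
#' \describe{
#'   \item{magazine_itis}{pseudorandom inter-delivery intervals, s}
#'   \item{magazine_max_rewards, magazine_max_min}{magazine session caps}
#'   \item{acq_session_max_trials, acq_session_max_min}{acquisition caps}
#'   \item{acq_criterion_trials, acq_criterion_consecutive}{advance when
#'     trials exceed this count on this many consecutive sessions}
#'   \item{vd_criterion_accuracy, vd_iti_s}{discrimination accuracy
#'     criterion and intertrial interval}
#'   \item{train_sd_sequence_s}{staircase of stimulus durations, s}
#'   \item{train_iti_s, train_limited_hold_s, train_timeout_s}{trial timing}
#'   \item{train_criteria}{list(max_omission_fraction, min_accuracy_fraction,
#'     min_trials) -- all three must hold in a single session to advance}
#'   \item{train_max_sessions_per_sd}{forced advance after this many sessions}
#'   \item{test_vsd_sds_s, test_viti_itis_s}{test-day manipulations}
#' }
#' @examples
#' cfg <- default_protocol()
#' cfg$train_sd_sequence_s
#' @export
default_protocol <- function() {
  cfg <- list(
    magazine_itis = c(4, 8, 16, 32),
    magazine_max_rewards = 50,
    magazine_max_min = 25,
    acq_session_max_trials = 60,
    acq_session_max_min = 25,
    acq_criterion_trials = 25,
    acq_criterion_consecutive = 2,
    vd_criterion_accuracy = 0.5,
    vd_iti_s = 5,
    vd_session_max_trials = 60,
    vd_session_max_min = 25,
    train_sd_sequence_s = c(16, 8, 4, 2, 1.5, 1),
    train_iti_s = 5,
    train_limited_hold_s = 4,
    train_timeout_s = 5,
    train_session_max_trials = 100,
    train_session_max_min = 30,
    train_criteria = list(
      max_omission_fraction = 0.30,
      min_accuracy_fraction = 0.60,
      min_trials = 50
    ),
    train_max_sessions_per_sd = 10,
    test_vsd_sds_s = c(1, 0.5, 0.2),
    test_vsd_iti_s = 5,
    test_viti_itis_s = c(5, 7.5, 12.5),
    test_viti_sd_s = 1,
    test_session_max_trials = 100,
    test_day1_max_min = 30,
    test_day2_max_min = 45
  )
  class(cfg) <- "fc_protocol"
  validate_protocol(cfg)
  cfg
}

#' Validate a protocol configuration
#'
#' Checks the structural invariants: all durations positive, the training SD
#' sequence strictly decreasing, criterion fractions inside (0, 1).
#'
#' @param config a protocol list as returned by [default_protocol()].
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_protocol <- function(config) {
  req <- c(
    "magazine_itis", "magazine_max_rewards", "magazine_max_min",
    "acq_session_max_trials", "acq_session_max_min", "acq_criterion_trials",
    "acq_criterion_consecutive", "vd_criterion_accuracy", "vd_iti_s",
    "vd_session_max_trials", "vd_session_max_min",
    "train_sd_sequence_s", "train_iti_s", "train_limited_hold_s",
    "train_timeout_s", "train_session_max_trials", "train_session_max_min",
    "train_criteria", "train_max_sessions_per_sd",
    "test_vsd_sds_s", "test_vsd_iti_s", "test_viti_itis_s", "test_viti_sd_s",
    "test_session_max_trials", "test_day1_max_min", "test_day2_max_min"
  )
  missing <- setdiff(req, names(config))
  if (length(missing) > 0) {
    stop("protocol config is missing fields: ", paste(missing, collapse = ", "))
  }
  durations <- c(
    config$magazine_itis, config$vd_iti_s, config$train_sd_sequence_s,
    config$train_iti_s, config$train_limited_hold_s, config$train_timeout_s,
    config$test_vsd_sds_s, config$test_vsd_iti_s, config$test_viti_itis_s,
    config$test_viti_sd_s, config$magazine_max_min, config$acq_session_max_min,
    config$vd_session_max_min, config$train_session_max_min,
    config$test_day1_max_min, config$test_day2_max_min
  )
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all protocol durations must be positive and finite")
  }
  sds <- config$train_sd_sequence_s
  if (length(sds) < 1 || any(diff(sds) >= 0)) {
    stop("train_sd_sequence_s must be strictly decreasing")
  }
  crit <- config$train_criteria
  fracs <- c(crit$max_omission_fraction, crit$min_accuracy_fraction,
             config$vd_criterion_accuracy)
  if (any(fracs <= 0) || any(fracs >= 1)) {
    stop("criterion fractions must lie strictly inside (0, 1)")
  }
  invisible(config)
}

#' Stage state for protocol progression
#'
#' A small record tracking where a subject sits inside a protocol stage:
#' the current training stimulus duration, how many sessions have been run at
#' that level, and whether the stage is complete.
#'
#' @param stage one of `"habituation"`, `"magazine"`, `"acquisition"`,
#'   `"discrimination"`, `"training"`, `"test_vsd"`, `"test_viti"`.
#' @param sd_s current stimulus duration (training stage only); defaults to
#'   the first element of the config staircase for training.
#' @param config protocol configuration, used to seed `sd_s`.
#' @return list of class `fc_stage_state` with fields `stage`, `sd_s`,
#'   `sessions_at_sd`, `complete`.
#' @export
stage_state <- function(stage, sd_s = NULL, config = default_protocol()) {
  stages <- c("habituation", "magazine", "acquisition", "discrimination",
              "training", "test_vsd", "test_viti")
  stage <- match.arg(stage, stages)
  if (stage == "training") {
    if (is.null(sd_s)) sd_s <- config$train_sd_sequence_s[1]
    if (!sd_s %in% config$train_sd_sequence_s) {
      stop("sd_s must be a member of train_sd_sequence_s")
    }
  } else {
    sd_s <- NA_real_
  }
  structure(
    list(stage = stage, sd_s = sd_s, sessions_at_sd = 0L, complete = FALSE),
    class = "fc_stage_state"
  )
}

#' Has a stage's advancement criterion been met?
#'
#' Evaluates the consecutive-session criteria for operant acquisition
#' (trials strictly greater than the criterion count on each of the last two
#' sessions) and visuospatial discrimination (the same trial criterion plus
#' accuracy strictly greater than 50% on each of the last two sessions).
#' Fewer sessions than the window requires is `FALSE`, not an error.
#'
#' @param stage_id `"acquisition"` or `"discrimination"`.
#' @param summaries data.frame of session summaries ordered oldest to newest,
#'   with at least columns `n_trials` and (for discrimination) `accuracy`.
#' @param config protocol configuration.
#' @return logical scalar.
#' @examples
#' s <- data.frame(n_trials = c(26, 26), accuracy = c(0.6, 0.6))
#' stage_criterion_met("acquisition", s)
#' @export
stage_criterion_met <- function(stage_id, summaries,
                                config = default_protocol()) {
  if (!stage_id %in% c("acquisition", "discrimination")) {
    stop("no advancement criterion defined for stage '", stage_id, "'")
  }
  need <- config$acq_criterion_consecutive
  n <- nrow(summaries)
  if (is.null(n) || n < need) return(FALSE)
  last <- summaries[(n - need + 1):n, , drop = FALSE]
  trials_ok <- all(last$n_trials > config$acq_criterion_trials)
  if (stage_id == "acquisition") return(trials_ok)
  acc <- last$accuracy
  acc_ok <- all(!is.na(acc) & acc > config$vd_criterion_accuracy)
  trials_ok && acc_ok
}

#' Advance the training stimulus-duration staircase by one session
#'
#' After each training session the subject advances to the next (shorter)
#' stimulus duration if the session met all three criteria (omission fraction
#' below 30%, accuracy above 60%, more than 50 trials), or, failing that,
#' after 10 sessions at the same SD. The session-counter includes the session
#' just evaluated and resets on every advance. Advancing past the final SD
#' marks training complete. The staircase never skips a level and never moves
#' backward.
#'
#' @param state an `fc_stage_state` with `stage == "training"`.
#' @param last_session a session summary (list or one-row data.frame) with
#'   fields `omission_fraction`, `accuracy`, `n_trials`.
#' @param config protocol configuration.
#' @return the updated `fc_stage_state`.
#' @export
staircase_step <- function(state, last_session, config = default_protocol()) {
  if (!identical(state$stage, "training")) {
    stop("staircase_step applies to the training stage only")
  }
  crit <- config$train_criteria
  acc <- last_session$accuracy
  met <- isTRUE(last_session$omission_fraction < crit$max_omission_fraction) &&
    isTRUE(!is.na(acc) && acc > crit$min_accuracy_fraction) &&
    isTRUE(last_session$n_trials > crit$min_trials)
  counter <- state$sessions_at_sd + 1L
  seq_sd <- config$train_sd_sequence_s
  i <- match(state$sd_s, seq_sd)
  if (is.na(i)) stop("state$sd_s is not a member of train_sd_sequence_s")
  if (met || counter >= config$train_max_sessions_per_sd) {
    if (i == length(seq_sd)) {
      state$complete <- TRUE
    } else {
      state$sd_s <- seq_sd[i + 1]
    }
    state$sessions_at_sd <- 0L
  } else {
    state$sessions_at_sd <- counter
  }
  state
}
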