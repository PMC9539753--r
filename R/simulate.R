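# Session-, mouse- and cohort-level simulation over the per-trial agent
# mechanism. Every stage of the staged protocol (magazine, acquisition,
# discrimination, training staircase, variable-SD and variable-ITI test
# days) is playable, so the whole analysis surface can be exercised without
# real operant data.

new_trials_acc <- function(cap = 128L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  for (f in c("outcome")) assign(f, character(cap), envir = e)
  for (f in c("cued_aperture", "responded_aperture")) {
    assign(f, integer(cap), envir = e)
  }
  for (f in c("response_latency_s", "stimulus_onset_s", "reward_retrieval_s",
              "eating_duration_s", "sd_s", "iti_s")) {
    assign(f, numeric(cap), envir = e)
  }
  e
}

trials_add <- function(e, tr, sd_s, iti_s) {
  n <- e$n + 1L
  if (n > length(e$outcome)) {
    for (f in c("outcome", "cued_aperture", "responded_aperture",
                "response_latency_s", "stimulus_onset_s",
                "reward_retrieval_s", "eating_duration_s", "sd_s", "iti_s")) {
      v <- get(f, envir = e)
      assign(f, c(v, v[0][seq_along(v)]), envir = e)  # double capacity
    }
  }
  e$outcome[n] <- tr$outcome
  e$cued_aperture[n] <- tr$cued_aperture
  e$responded_aperture[n] <- tr$responded_aperture
  e$response_latency_s[n] <- tr$response_latency_s
  e$stimulus_onset_s[n] <- tr$stimulus_onset_s
  e$reward_retrieval_s[n] <- tr$reward_retrieval_s
  e$eating_duration_s[n] <- tr$eating_duration_s
  e$sd_s[n] <- sd_s
  e$iti_s[n] <- iti_s
  e$n <- n
  invisible(e)
}

trials_collect <- function(e) {
  idx <- seq_len(e$n)
  data.frame(
    index = idx - 1L,
    outcome = e$outcome[idx],
    cued_aperture = e$cued_aperture[idx],
    responded_aperture = e$responded_aperture[idx],
    response_latency_s = e$response_latency_s[idx],
    stimulus_onset_s = e$stimulus_onset_s[idx],
    reward_retrieval_s = e$reward_retrieval_s[idx],
    eating_duration_s = e$eating_duration_s[idx],
    sd_s = e$sd_s[idx],
    iti_s = e$iti_s[idx],
    stringsAsFactors = FALSE
  )
}

fc_session <- function(meta, trials, events, config) {
  s <- list(meta = meta, trials = trials, events = events)
  class(s) <- "fc_session"
  s$summary <- session_summary(s)
  s
}

#' Simulate one session of any protocol stage
#'
#' Plays the agent through a single session. Training and test sessions use
#' the full cued-trial mechanism of [simulate_trial()]; magazine sessions
#' deliver pellets on the pseudorandom interval schedule; acquisition
#' sessions are free responding into five lit apertures; discrimination
#' sessions present one lit aperture with no response deadline. A session
#' terminates at its stage's trial cap or time cap, whichever binds first.
#'
#' @param params `fc_agent_params`.
#' @param stage one of `"magazine"`, `"acquisition"`, `"discrimination"`,
#'   `"training"`, `"test_vsd"`, `"test_viti"`.
#' @param config protocol configuration.
#' @param sd_s stimulus duration for training sessions (ignored elsewhere).
#' @param emit_events if `TRUE`, build the timestamped event log alongside the
#'   trial ledger. RNG consumption is identical either way, so metrics are
#'   unchanged by this flag.
#' @param meta named list merged into the session header (mouse id, group,
#'   age, date, ...).
#' @param seed optional integer seed set before the session.
#' @return an `fc_session`: list with `meta`, `trials` (one row per trial,
#'   ground-truth ledger), `events` (time-ordered data.frame or `NULL`) and
#'   `summary` (see [session_summary()]).
#' @export
simulate_session <- function(params, stage, config = default_protocol(),
                             sd_s = NULL, emit_events = TRUE, meta = list(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage <- match.arg(stage, c("magazine", "acquisition", "discrimination",
                              "training", "test_vsd", "test_viti"))
  ev <- if (emit_events) ev_new() else NULL
  acc <- new_trials_acc()
  t_end <- switch(stage,
    magazine = sim_magazine(params, config, acc, ev),
    acquisition = sim_acquisition(params, config, acc, ev),
    discrimination = sim_discrimination(params, config, acc, ev),
    training = sim_cued(params, config, acc, ev, stage, sd_s),
    test_vsd = sim_cued(params, config, acc, ev, stage, NULL),
    test_viti = sim_cued(params, config, acc, ev, stage, NULL)
  )
  trials <- trials_collect(acc)
  events <- NULL
  if (emit_events) {
    end_t <- t_end
    if (ev$n > 0) end_t <- max(end_t, max(ev$time[seq_len(ev$n)]))
    ev_add(ev, end_t, "SESSION_END")
    events <- ev_collect(ev)
  }
  m <- list(stage = stage,
            sd_s = if (stage == "training") sd_s
                   else if (stage == "test_viti") config$test_viti_sd_s
                   else NA_real_,
            iti_s = switch(stage,
                           training = config$train_iti_s,
                           test_vsd = config$test_vsd_iti_s,
                           discrimination = config$vd_iti_s,
                           NA_real_),
            duration_s = t_end,
            protocol_hash = protocol_hash(config))
  m[names(meta)] <- meta
  fc_session(m, trials, events, config)
}

sim_magazine <- function(params, config, acc, ev) {
  cap_t <- config$magazine_max_min * 60
  t <- 0
  while (acc$n < config$magazine_max_rewards && t < cap_t) {
    iti <- sample(config$magazine_itis, 1L)
    t_del <- t + iti
    retr <- t_del + stats::rgamma(1, shape = 2,
                                  rate = 2 / params$magazine_latency_mean)
    eat <- stats::rgamma(1, shape = params$eating_shape,
                         rate = params$eating_shape / params$eating_mean)
    if (!is.null(ev)) {
      ev_add(ev, t_del, "PELLET_DELIVERED")
      ev_add(ev, retr, "POKE_MAGAZINE")
      ev_add(ev, retr, "PELLET_RETRIEVED")
      ev_add(ev, retr + eat, "EAT_END")
    }
    trials_add(acc, list(outcome = "correct", cued_aperture = NA_integer_,
                         responded_aperture = NA_integer_,
                         response_latency_s = NA_real_,
                         stimulus_onset_s = NA_real_,
                         reward_retrieval_s = retr, eating_duration_s = eat),
               NA_real_, NA_real_)
    t <- retr
  }
  t
}

sim_acquisition <- function(params, config, acc, ev) {
  cap_t <- config$acq_session_max_min * 60
  t <- 0
  if (!is.null(ev)) ev_add(ev, 0, "HOUSELIGHT_ON")
  while (acc$n < config$acq_session_max_trials && t < cap_t) {
    lat <- stats::rlnorm(1, params$latency_mu, params$latency_sigma)
    ap <- sample.int(5L, 1L, prob = params$aperture_bias)
    poke <- t + lat
    retr <- poke + stats::rgamma(1, shape = 2,
                                 rate = 2 / params$magazine_latency_mean)
    eat <- stats::rgamma(1, shape = params$eating_shape,
                         rate = params$eating_shape / params$eating_mean)
    if (!is.null(ev)) {
      ev_add(ev, poke, "POKE_APERTURE", ap)
      ev_add(ev, poke, "PELLET_DELIVERED")
      ev_add(ev, retr, "POKE_MAGAZINE")
      ev_add(ev, retr, "PELLET_RETRIEVED")
      ev_add(ev, retr + eat, "EAT_END")
    }
    trials_add(acc, list(outcome = "correct", cued_aperture = NA_integer_,
                         responded_aperture = ap, response_latency_s = lat,
                         stimulus_onset_s = t, reward_retrieval_s = retr,
                         eating_duration_s = eat),
               NA_real_, NA_real_)
    t <- retr
  }
  t
}

sim_discrimination <- function(params, config, acc, ev) {
  cap_t <- config$vd_session_max_min * 60
  iti <- config$vd_iti_s
  t <- 0
  while (acc$n < config$vd_session_max_trials && t < cap_t) {
    t_on <- t + iti
    cued <- sample.int(5L, 1L)
    lat <- stats::rlnorm(1, params$latency_mu, params$latency_sigma)
    poke <- t_on + lat
    if (!is.null(ev)) ev_add(ev, t_on, "STIM_ON", cued)
    if (stats::runif(1) < params$accuracy_given_response) {
      retr <- poke + stats::rgamma(1, shape = 2,
                                   rate = 2 / params$magazine_latency_mean)
      eat <- stats::rgamma(1, shape = params$eating_shape,
                           rate = params$eating_shape / params$eating_mean)
      if (!is.null(ev)) {
        ev_add(ev, poke, "STIM_OFF", cued)
        ev_add(ev, poke, "POKE_APERTURE", cued)
        ev_add(ev, poke, "PELLET_DELIVERED")
        ev_add(ev, retr, "POKE_MAGAZINE")
        ev_add(ev, retr, "PELLET_RETRIEVED")
        ev_add(ev, retr + eat, "EAT_END")
      }
      trials_add(acc, list(outcome = "correct", cued_aperture = cued,
                           responded_aperture = cued,
                           response_latency_s = lat, stimulus_onset_s = t_on,
                           reward_retrieval_s = retr,
                           eating_duration_s = eat),
                 NA_real_, iti)
      t <- retr
    } else {
      w <- params$aperture_bias
      w[cued] <- 0
      if (sum(w) <= 0) w <- replace(rep(1, 5), cued, 0)
      ap <- sample.int(5L, 1L, prob = w)
      if (!is.null(ev)) {
        ev_add(ev, poke, "STIM_OFF", cued)
        ev_add(ev, poke, "POKE_APERTURE", ap)
      }
      trials_add(acc, list(outcome = "incorrect", cued_aperture = cued,
                           responded_aperture = ap,
                           response_latency_s = lat, stimulus_onset_s = t_on,
                           reward_retrieval_s = NA_real_,
                           eating_duration_s = NA_real_),
                 NA_real_, iti)
      t <- poke
    }
  }
  t
}

sim_cued <- function(params, config, acc, ev, stage, sd_s) {
  if (stage == "training") {
    if (is.null(sd_s) || !sd_s %in% config$train_sd_sequence_s) {
      stop("training sessions need sd_s from train_sd_sequence_s")
    }
    cap_t <- config$train_session_max_min * 60
    cap_n <- config$train_session_max_trials
  } else if (stage == "test_vsd") {
    cap_t <- config$test_day1_max_min * 60
    cap_n <- config$test_session_max_trials
  } else {
    cap_t <- config$test_day2_max_min * 60
    cap_n <- config$test_session_max_trials
  }
  state <- agent_state()
  while (acc$n < cap_n && state$t < cap_t) {
    sd_trial <- switch(stage,
                       training = sd_s,
                       test_vsd = sample(config$test_vsd_sds_s, 1L),
                       test_viti = config$test_viti_sd_s)
    iti_trial <- switch(stage,
                        training = config$train_iti_s,
                        test_vsd = config$test_vsd_iti_s,
                        test_viti = sample(config$test_viti_itis_s, 1L))
    res <- simulate_trial(state, params, sd_trial, iti_trial, config,
                          events = ev)
    state <- res$state
    trials_add(acc, res$trial, sd_trial, iti_trial)
  }
  state$t
}

#' Simulate a mouse through the staged protocol
#'
#' Runs habituation (emits an activity score only), two magazine sessions,
#' operant acquisition until criterion, visuospatial discrimination until
#' criterion, the 5CSRTT training staircase from 16 s down to 1 s, and the
#' two test days. Returns every session plus a stage-transition ledger.
#'
#' @param params `fc_agent_params`.
#' @param config protocol configuration.
#' @param seed optional integer seed (all within-mouse randomness).
#' @param stages character vector of stages to run, in protocol order.
#' @param max_stage_sessions guard on acquisition/discrimination looping when
#'   an agent cannot reach criterion.
#' @param emit_events build event logs for every session (slower).
#' @param meta named list merged into each session header.
#' @return an `fc_mouse`: list with `meta`, `activity_score`, `sessions`
#'   (list of `fc_session`) and `transitions` (data.frame: stage, sessions
#'   run, advanced flag).
#' @export
simulate_mouse <- function(params, config = default_protocol(), seed = NULL,
                           stages = c("habituation", "magazine",
                                      "acquisition", "discrimination",
                                      "training", "test_vsd", "test_viti"),
                           max_stage_sessions = 30, emit_events = FALSE,
                           meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  sessions <- list()
  trans <- list()
  activity <- NA_real_

  run_until <- function(stage) {
    summ <- data.frame(n_trials = integer(0), accuracy = numeric(0))
    k <- 0L
    advanced <- FALSE
    repeat {
      s <- simulate_session(params, stage, config,
                            emit_events = emit_events, meta = meta)
      sessions[[length(sessions) + 1L]] <<- s
      k <- k + 1L
      summ <- rbind(summ, data.frame(n_trials = s$summary$n_trials,
                                     accuracy = s$summary$accuracy))
      if (stage_criterion_met(stage, summ, config)) {
        advanced <- TRUE
        break
      }
      if (k >= max_stage_sessions) break
    }
    c(k, advanced)
  }

  for (stage in stages) {
    if (stage == "habituation") {
      activity <- max(0, stats::rnorm(1, params$activity,
                                      0.1 * params$activity))
      trans[[length(trans) + 1L]] <- data.frame(stage = stage, sessions = 0L,
                                                advanced = TRUE)
    } else if (stage == "magazine") {
      for (i in 1:2) {
        sessions[[length(sessions) + 1L]] <-
          simulate_session(params, "magazine", config,
                           emit_events = emit_events, meta = meta)
      }
      trans[[length(trans) + 1L]] <- data.frame(stage = stage, sessions = 2L,
                                                advanced = TRUE)
    } else if (stage %in% c("acquisition", "discrimination")) {
      res <- run_until(stage)
      trans[[length(trans) + 1L]] <- data.frame(stage = stage,
                                                sessions = res[1],
                                                advanced = as.logical(res[2]))
    } else if (stage == "training") {
      st <- stage_state("training", config = config)
      k <- 0L
      while (!st$complete) {
        s <- simulate_session(params, "training", config, sd_s = st$sd_s,
                              emit_events = emit_events, meta = meta)
        sessions[[length(sessions) + 1L]] <- s
        k <- k + 1L
        st <- staircase_step(st, s$summary, config)
      }
      trans[[length(trans) + 1L]] <- data.frame(stage = stage, sessions = k,
                                                advanced = TRUE)
    } else {
      sessions[[length(sessions) + 1L]] <-
        simulate_session(params, stage, config, emit_events = emit_events,
                         meta = meta)
      trans[[length(trans) + 1L]] <- data.frame(stage = stage, sessions = 1L,
                                                advanced = TRUE)
    }
  }
  structure(
    list(meta = meta, params = params, activity_score = activity,
         sessions = sessions, transitions = do.call(rbind, trans)),
    class = "fc_mouse"
  )
}

#' One training session at every stimulus duration
#'
#' Runs a single 5CSRTT training session at each level of the staircase
#' (16, 8, 4, 2, 1.5, 1 s by default) regardless of criteria. This is the
#' sampling design behind stimulus-duration profiles of omissions, OAC and
#' OAIO: one session per SD per mouse, mirroring final-session-per-SD
#' analyses.
#'
#' @inheritParams simulate_mouse
#' @return list of `fc_session`, one per SD, in staircase order.
#' @export
simulate_sd_sweep <- function(params, config = default_protocol(),
                              seed = NULL, emit_events = FALSE,
                              meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  lapply(config$train_sd_sequence_s, function(sd) {
    simulate_session(params, "training", config, sd_s = sd,
                     emit_events = emit_events, meta = meta)
  })
}
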