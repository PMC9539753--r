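# Generative agent model. A simulated mouse is a small set of stationary
# parameters; all trial-to-trial variability comes from the RNG. The one
# deliberately mechanistic piece is reward-eating occupancy: the ITI clock
# starts at reward retrieval while eating continues, so eating can spill into
# the next stimulus window and force an omission -- the motor confound the
# conditional-omission metrics are designed to dissociate.

#' Construct and validate agent parameters
#'
#' @param lapse_base probability of an attentional lapse at the reference
#'   stimulus duration (16 s).
#' @param lapse_sd_slope increase in lapse probability per halving of the
#'   stimulus duration: `lapse(SD) = clamp(lapse_base +
#'   lapse_sd_slope * log2(16 / SD), 0, 1)`.
#' @param accuracy_given_response probability the cued aperture is chosen when
#'   the agent responds.
#' @param latency_mu,latency_sigma log-scale mean and sd of the log-normal
#'   response latency (s).
#' @param premature_hazard constant hazard (events/s) of a premature poke
#'   during the intertrial interval.
#' @param magazine_latency_mean mean seconds from reward delivery to magazine
#'   head entry (Gamma with shape 2).
#' @param eating_mean,eating_shape mean (s) and shape of the Gamma-distributed
#'   pellet-eating duration.
#' @param activity arbitrary locomotion score emitted during habituation.
#' @param aperture_bias five non-negative weights governing aperture choice
#'   for acquisition responses, incorrect responses and premature pokes;
#'   normalised to sum to 1.
#' @return validated list of class `fc_agent_params`.
#' @examples
#' p <- agent_params(eating_mean = 15.6)
#' lapse_probability(p, sd_s = 1)
#' @export
agent_params <- function(lapse_base = 0.05,
                         lapse_sd_slope = 0.05,
                         accuracy_given_response = 0.85,
                         latency_mu = log(1.0),
                         latency_sigma = 0.35,
                         premature_hazard = 0.01,
                         magazine_latency_mean = 2,
                         eating_mean = 10.4,
                         eating_shape = 10,
                         activity = 50,
                         aperture_bias = rep(0.2, 5)) {
  p <- list(
    lapse_base = lapse_base, lapse_sd_slope = lapse_sd_slope,
    accuracy_given_response = accuracy_given_response,
    latency_mu = latency_mu, latency_sigma = latency_sigma,
    premature_hazard = premature_hazard,
    magazine_latency_mean = magazine_latency_mean,
    eating_mean = eating_mean, eating_shape = eating_shape,
    activity = activity, aperture_bias = aperture_bias
  )
  probs <- c(p$lapse_base, p$accuracy_given_response)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("lapse_base and accuracy_given_response must lie in [0, 1]")
  }
  if (!is.finite(p$lapse_sd_slope) || p$lapse_sd_slope < 0) {
    stop("lapse_sd_slope must be non-negative")
  }
  pos <- c(p$magazine_latency_mean, p$eating_mean, p$eating_shape,
           p$latency_sigma, p$activity)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("means, shapes, sigma and activity must be positive")
  }
  if (!is.finite(p$premature_hazard) || p$premature_hazard < 0) {
    stop("premature_hazard must be non-negative")
  }
  if (length(p$aperture_bias) != 5 || any(p$aperture_bias < 0) ||
      sum(p$aperture_bias) <= 0) {
    stop("aperture_bias must be 5 non-negative weights with positive sum")
  }
  p$aperture_bias <- p$aperture_bias / sum(p$aperture_bias)
  class(p) <- "fc_agent_params"
  p
}

#' Attentional lapse probability at a given stimulus duration
#'
#' The lapse probability rises as the stimulus shortens, on a log2 link
#' anchored at a 16 s reference duration and clamped to \[0, 1\]:
#' `lapse(SD) = clamp(lapse_base + lapse_sd_slope * log2(sd_ref / SD), 0, 1)`.
#'
#' @param params `fc_agent_params`.
#' @param sd_s stimulus duration, s (vectorised).
#' @param sd_ref reference duration, s.
#' @return lapse probabilities in \[0, 1\].
#' @export
lapse_probability <- function(params, sd_s, sd_ref = 16) {
  pmin(1, pmax(0, params$lapse_base +
                 params$lapse_sd_slope * log2(sd_ref / sd_s)))
}

#' Fresh agent state for the start of a session
#'
#' @return list with wall-clock time `t` (s from session start) and
#'   `residual_eating_s`, the eating time left over from the previous reward
#'   as of time `t`.
#' @export
agent_state <- function() {
  list(t = 0, residual_eating_s = 0)
}

# growable event accumulator ------------------------------------------------

ev_new <- function(cap = 512L) {
  e <- new.env(parent = emptyenv())
  e$time <- numeric(cap)
  e$event <- character(cap)
  e$arg <- integer(cap)
  e$n <- 0L
  e
}

ev_add <- function(e, time, event, arg = NA_integer_) {
  n <- e$n + 1L
  if (n > length(e$time)) {
    e$time <- c(e$time, numeric(length(e$time)))
    e$event <- c(e$event, character(length(e$event)))
    e$arg <- c(e$arg, integer(length(e$arg)))
  }
  # ms precision throughout: the on-disk dialect prints milliseconds, and
  # keeping the in-memory stream identical makes write/read lossless
  e$time[n] <- round(time, 3)
  e$event[n] <- event
  e$arg[n] <- arg
  e$n <- n
  invisible(e)
}

ev_collect <- function(e) {
  idx <- seq_len(e$n)
  df <- data.frame(
    time_s = e$time[idx], event = e$event[idx], arg = e$arg[idx],
    stringsAsFactors = FALSE
  )
  df[order(df$time_s), , drop = FALSE]
}

#' Simulate one cued 5CSRTT trial
#'
#' Generates a single training/test-style trial by the ordered mechanism:
#' (1) during the ITI a premature poke occurs with probability
#' `1 - exp(-premature_hazard * iti_s)`; (2) at stimulus onset, if the agent
#' is still eating the previous pellet past the whole response window
#' (residual eating greater than SD + limited hold) the trial is an omission
#' regardless of attention -- the occupancy confound; (3) otherwise the agent
#' lapses with probability [lapse_probability()]; (4) otherwise a log-normal
#' response latency is drawn, becoming an omission if it outruns the window,
#' else a correct or incorrect poke; (5) a correct poke delivers a pellet,
#' the magazine is entered after the magazine latency, a Gamma eating
#' duration is drawn, and the next ITI starts at retrieval so eating time in
#' excess of the ITI carries into the next trial.
#'
#' @param state agent state from [agent_state()] or a previous trial.
#' @param params `fc_agent_params`.
#' @param sd_s stimulus duration for this trial, s.
#' @param iti_s intertrial interval preceding the stimulus, s.
#' @param config protocol configuration (limited hold and timeout).
#' @param cued cued aperture 1..5; drawn uniformly when `NULL`.
#' @param events internal event accumulator or `NULL` to skip event emission.
#'   RNG consumption is identical either way.
#' @return list with `trial` (named list: `outcome`, `cued_aperture`,
#'   `responded_aperture`, `response_latency_s`, `stimulus_onset_s`,
#'   `reward_retrieval_s`, `eating_duration_s`) and the updated `state`.
#' @export
simulate_trial <- function(state, params, sd_s, iti_s,
                           config = default_protocol(), cued = NULL,
                           events = NULL) {
  if (!inherits(params, "fc_agent_params")) {
    stop("params must be built with agent_params()")
  }
  lh <- config$train_limited_hold_s
  timeout <- config$train_timeout_s
  t0 <- state$t
  res <- state$residual_eating_s
  if (is.null(cued)) cued <- sample.int(5L, 1L)
  emit <- !is.null(events)

  trial <- list(
    outcome = NA_character_, cued_aperture = cued,
    responded_aperture = NA_integer_, response_latency_s = NA_real_,
    stimulus_onset_s = NA_real_, reward_retrieval_s = NA_real_,
    eating_duration_s = NA_real_
  )

  h <- params$premature_hazard
  p_prem <- if (h > 0) 1 - exp(-h * iti_s) else 0
  if (p_prem > 0 && stats::runif(1) < p_prem) {
    # premature poke at a truncated-exponential time inside the ITI
    tp <- -log(1 - stats::runif(1) * p_prem) / h
    ap <- sample.int(5L, 1L, prob = params$aperture_bias)
    poke_t <- t0 + tp
    if (emit) {
      ev_add(events, poke_t, "POKE_APERTURE", ap)
      ev_add(events, poke_t, "TIMEOUT_START")
      ev_add(events, poke_t + timeout, "TIMEOUT_END")
    }
    t_end <- poke_t + timeout
    trial$outcome <- "premature"
    trial$responded_aperture <- ap
    state$residual_eating_s <- max(0, res - (t_end - t0))
    state$t <- t_end
    return(list(trial = trial, state = state))
  }

  t_on <- t0 + iti_s
  trial$stimulus_onset_s <- t_on
  if (emit) ev_add(events, t_on, "STIM_ON", cued)
  window <- sd_s + lh
  res_on <- max(0, res - iti_s)  # eating left at stimulus onset

  omit <- FALSE
  lat <- NA_real_
  if (res_on > window) {
    omit <- TRUE                               # occupied: still eating
  } else if (stats::runif(1) < lapse_probability(params, sd_s)) {
    omit <- TRUE                               # attentional lapse
  } else {
    lat <- stats::rlnorm(1, params$latency_mu, params$latency_sigma)
    if (lat > window) {
      omit <- TRUE                             # too slow for the window
      lat <- NA_real_
    }
  }

  if (omit) {
    if (emit) {
      ev_add(events, t_on + sd_s, "STIM_OFF", cued)
      ev_add(events, t_on + window, "TIMEOUT_START")
      ev_add(events, t_on + window + timeout, "TIMEOUT_END")
    }
    t_end <- t_on + window + timeout
    trial$outcome <- "omission"
    state$residual_eating_s <- max(0, res - (t_end - t0))
    state$t <- t_end
    return(list(trial = trial, state = state))
  }

  poke_t <- t_on + lat
  off_t <- t_on + min(lat, sd_s)  # light off at response or at SD expiry
  trial$response_latency_s <- lat
  if (stats::runif(1) < params$accuracy_given_response) {
    retr <- poke_t + stats::rgamma(1, shape = 2,
                                   rate = 2 / params$magazine_latency_mean)
    eat <- stats::rgamma(1, shape = params$eating_shape,
                         rate = params$eating_shape / params$eating_mean)
    if (emit) {
      ev_add(events, off_t, "STIM_OFF", cued)
      ev_add(events, poke_t, "POKE_APERTURE", cued)
      ev_add(events, poke_t, "PELLET_DELIVERED")
      ev_add(events, retr, "POKE_MAGAZINE")
      ev_add(events, retr, "PELLET_RETRIEVED")
      ev_add(events, retr + eat, "EAT_END")
    }
    trial$outcome <- "correct"
    trial$responded_aperture <- cued
    trial$reward_retrieval_s <- retr
    trial$eating_duration_s <- eat
    state$residual_eating_s <- eat  # next ITI starts now; eating continues
    state$t <- retr
  } else {
    w <- params$aperture_bias
    w[cued] <- 0
    if (sum(w) <= 0) w <- replace(rep(1, 5), cued, 0)
    ap <- sample.int(5L, 1L, prob = w)
    if (emit) {
      ev_add(events, off_t, "STIM_OFF", cued)
      ev_add(events, poke_t, "POKE_APERTURE", ap)
      ev_add(events, poke_t, "TIMEOUT_START")
      ev_add(events, poke_t + timeout, "TIMEOUT_END")
    }
    t_end <- poke_t + timeout
    trial$outcome <- "incorrect"
    trial$responded_aperture <- ap
    state$residual_eating_s <- max(0, res - (t_end - t0))
    state$t <- t_end
  }
  list(trial = trial, state = state)
}
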