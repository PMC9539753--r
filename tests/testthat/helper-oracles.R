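# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# conditional omission metrics by literal per-index enumeration
oracle_conditional <- function(o, mode) {
  num <- 0L
  den <- 0L
  for (i in seq_along(o)) {
    if (i == 1) next
    pred <- o[i - 1]
    elig <- switch(mode,
      OAC = pred == "correct",
      OAIO = pred %in% c("incorrect", "omission"),
      OAIO_EXT = {
        base <- pred %in% c("incorrect", "omission")
        excl <- pred == "omission" && i >= 3 && o[i - 2] == "correct"
        base && !excl
      }
    )
    if (elig) {
      den <- den + 1L
      if (o[i] == "omission") num <- num + 1L
    }
  }
  list(num = num, den = den,
       fraction = if (den > 0) num / den else NA_real_)
}

long_outcomes <- function(o) {
  map <- c(C = "correct", I = "incorrect", O = "omission", P = "premature")
  unname(map[o])
}

random_outcomes <- function(n) {
  sample(c("correct", "incorrect", "omission", "premature"), n,
         replace = TRUE, prob = c(0.4, 0.15, 0.3, 0.15))
}

# split-plot sums of squares from first principles (balanced designs only)
oracle_split_plot <- function(d) {
  d$g <- as.character(d$g)
  d$w <- as.character(d$w)
  d$s <- as.character(d$s)
  grand <- mean(d$y)
  k <- length(unique(d$w))
  subj_mean <- tapply(d$y, d$s, mean)
  g_of_s <- tapply(d$g, d$s, function(x) x[1])
  n_g <- table(g_of_s)
  N <- sum(n_g)
  grp_mean <- tapply(d$y, d$g, mean)
  lev_mean <- tapply(d$y, d$w, mean)
  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- k * sum(n_g[names(grp_mean)] * (grp_mean - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_level <- N * sum((lev_mean - grand)^2)
  ss_inter <- 0
  for (g in names(grp_mean)) {
    for (w in unique(d$w)) {
      cell <- mean(d$y[d$g == g & d$w == w])
      ss_inter <- ss_inter + n_g[[g]] *
        (cell - grp_mean[[g]] - lev_mean[[w]] + grand)^2
    }
  }
  ss_total <- sum((d$y - grand)^2)
  ss_ww_err <- ss_total - ss_between_subj - ss_level - ss_inter
  ng <- length(grp_mean)
  df_g <- ng - 1
  df_se <- N - ng
  df_w <- k - 1
  df_i <- df_g * df_w
  df_we <- df_se * df_w
  list(
    F_between = (ss_group / df_g) / (ss_subj_err / df_se),
    F_within = (ss_level / df_w) / (ss_ww_err / df_we),
    F_interaction = (ss_inter / df_i) / (ss_ww_err / df_we)
  )
}

# agents used across tests
perfect_agent <- function() {
  agent_params(lapse_base = 0, lapse_sd_slope = 0,
               accuracy_given_response = 1, latency_mu = log(0.3),
               latency_sigma = 0.1, premature_hazard = 0,
               eating_mean = 2, eating_shape = 20)
}

always_lapsing_agent <- function() {
  agent_params(lapse_base = 1, lapse_sd_slope = 0, premature_hazard = 0)
}

# build a cued-trial event table for classify_trial
trial_events_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(time_s = r[[1]], event = r[[2]],
               arg = if (length(r) >= 3) as.integer(r[[3]]) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

fake_session <- function(outcomes, latencies = NULL, eating = NULL) {
  n <- length(outcomes)
  trials <- data.frame(
    index = seq_len(n) - 1L,
    outcome = outcomes,
    cued_aperture = rep(NA_integer_, n),
    responded_aperture = rep(NA_integer_, n),
    response_latency_s = if (is.null(latencies)) rep(NA_real_, n)
                         else latencies,
    stimulus_onset_s = rep(NA_real_, n),
    reward_retrieval_s = rep(NA_real_, n),
    eating_duration_s = if (is.null(eating)) rep(NA_real_, n) else eating,
    sd_s = rep(NA_real_, n), iti_s = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  structure(list(meta = list(stage = "training", duration_s = NA_real_),
                 trials = trials, events = NULL),
            class = "fc_session")
}
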