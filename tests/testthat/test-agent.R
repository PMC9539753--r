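test_that("agent parameter validation catches out-of-range values", {
  expect_error(agent_params(lapse_base = 1.2), "\\[0, 1\\]")
  expect_error(agent_params(accuracy_given_response = -0.1), "\\[0, 1\\]")
  expect_error(agent_params(eating_mean = 0), "positive")
  expect_error(agent_params(premature_hazard = -1), "non-negative")
  expect_error(agent_params(aperture_bias = c(1, 1, 1, 1)), "5")
  p <- agent_params(aperture_bias = c(2, 1, 1, 1, 1))
  expect_equal(sum(p$aperture_bias), 1)
})

test_that("lapse probability follows the log2 link and is clamped", {
  p <- agent_params(lapse_base = 0.05, lapse_sd_slope = 0.05)
  expect_equal(lapse_probability(p, 16), 0.05)
  expect_equal(lapse_probability(p, 1), 0.05 + 0.05 * 4)
  expect_equal(lapse_probability(p, 8), 0.10)
  steep <- agent_params(lapse_base = 0.9, lapse_sd_slope = 0.5)
  expect_equal(lapse_probability(steep, 1), 1)   # clamped
  # monotone: shorter stimulus, higher lapse
  sds <- c(16, 8, 4, 2, 1.5, 1)
  expect_true(all(diff(lapse_probability(p, sds)) >= 0))
})

test_that("a degenerate deterministic agent is always correct", {
  set.seed(1)
  st <- agent_state()
  for (i in 1:20) {
    r <- simulate_trial(st, perfect_agent(), sd_s = 4, iti_s = 5)
    expect_equal(r$trial$outcome, "correct")
    expect_lt(r$trial$response_latency_s, 4)
    st <- r$state
  }
})

test_that("residual eating beyond the response window forces an omission", {
  set.seed(2)
  st <- agent_state()
  st$residual_eating_s <- 30
  # even a perfect, never-lapsing agent omits while occupied
  r <- simulate_trial(st, perfect_agent(), sd_s = 1, iti_s = 5)
  expect_equal(r$trial$outcome, "omission")
  # residual is drawn down by the elapsed trial time
  expect_lt(r$state$residual_eating_s, 30)
})

test_that("premature rate matches the closed-form ITI hazard", {
  p <- agent_params(premature_hazard = log(2) / 5, lapse_base = 0,
                    lapse_sd_slope = 0, accuracy_given_response = 1,
                    latency_mu = log(0.3), latency_sigma = 0.1,
                    eating_mean = 2, eating_shape = 20)
  set.seed(31)
  st <- agent_state()
  n <- 10000
  prem <- 0L
  for (i in seq_len(n)) {
    r <- simulate_trial(st, p, sd_s = 4, iti_s = 5)
    if (r$trial$outcome == "premature") prem <- prem + 1L
    st <- r$state
  }
  expect_equal(prem / n, 0.5, tolerance = 0.04)  # 1 - exp(-h*iti) = 1/2
})

test_that("outcome counts always sum to the trial count", {
  set.seed(41)
  for (i in 1:25) {
    p <- agent_params(
      lapse_base = runif(1, 0, 0.5), lapse_sd_slope = runif(1, 0, 0.2),
      accuracy_given_response = runif(1, 0.3, 1),
      latency_mu = log(runif(1, 0.3, 3)), latency_sigma = runif(1, 0.1, 0.8),
      premature_hazard = runif(1, 0, 0.1),
      eating_mean = runif(1, 2, 20), eating_shape = runif(1, 2, 20)
    )
    stage <- sample(c("training", "test_vsd", "test_viti"), 1)
    s <- simulate_session(p, stage, sd_s = sample(c(16, 2, 1), 1),
                          emit_events = FALSE)
    sm <- s$summary
    expect_equal(sm$n_correct + sm$n_incorrect + sm$n_omission +
                   sm$n_premature, sm$n_trials)
    expect_equal(sm$n_trials, nrow(s$trials))
  }
})

test_that("every correct trial has one delivery and one retrieval event", {
  set.seed(43)
  s <- simulate_session(agent_params(), "training", sd_s = 2)
  nc <- sum(s$trials$outcome == "correct")
  expect_equal(sum(s$events$event == "PELLET_DELIVERED"), nc)
  expect_equal(sum(s$events$event == "PELLET_RETRIEVED"), nc)
})

test_that("session caps bind: trial cap for fast agents, time cap for slow", {
  fast <- simulate_session(perfect_agent(), "training", sd_s = 16,
                           seed = 51, emit_events = FALSE)
  expect_equal(fast$summary$n_trials, 100)
  expect_lt(fast$summary$duration_min, 30)
  slow <- agent_params(latency_mu = log(60), latency_sigma = 0.3)
  acq <- simulate_session(slow, "acquisition", seed = 52,
                          emit_events = FALSE)
  expect_lt(acq$summary$n_trials, 30)
  expect_gte(acq$summary$duration_min, 25)
})

test_that("expected omission fraction rises as the stimulus shortens", {
  p <- agent_params(premature_hazard = 0)
  om <- vapply(c(16, 4, 1), function(sd) {
    set.seed(61)
    tot <- 0L
    n <- 0L
    for (k in 1:10) {
      s <- simulate_session(p, "training", sd_s = sd, emit_events = FALSE)
      tot <- tot + s$summary$n_omission
      n <- n + s$summary$n_trials
    }
    tot / n
  }, 0)
  expect_true(all(diff(om) > 0))  # 16 -> 4 -> 1 s: more omissions
})

test_that("fixed seeds give identical sessions and logs", {
  s1 <- simulate_session(agent_params(), "training", sd_s = 2, seed = 71)
  s2 <- simulate_session(agent_params(), "training", sd_s = 2, seed = 71)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$events, s2$events)
})

test_that("cohort bookkeeping preserves sizes, labels and ages", {
  spec <- cohort_spec(list(a = agent_params(), b = agent_params()),
                      n_per_group = 3, seed = 9,
                      stages = c("habituation", "magazine"))
  co <- simulate_cohort(spec)
  expect_length(co$mice, 6)
  groups <- vapply(co$mice, function(m) m$meta$group, "")
  expect_equal(sort(unique(groups)), c("a", "b"))
  expect_equal(sum(groups == "a"), 3)
  ages <- vapply(co$mice, function(m) m$meta$age_days, 0)
  expect_true(all(ages >= 70 & ages <= 160))
  expect_error(cohort_spec(list(a = agent_params()), n_per_group = 0),
               "at least 1")
})

test_that("group eating-time parameters are recovered in cohort means", {
  spec <- cohort_preset("angelman_like", seed = 12)
  co <- cohort_sd_sweep(spec)
  prof <- sd_profile(co)
  eat <- tapply(prof$mean_eating_s, prof$group,
                function(x) mean(x, na.rm = TRUE))
  expect_gt(eat[["mutant"]], eat[["control"]])
  expect_equal(eat[["control"]], 10.4, tolerance = 0.15)
  expect_equal(eat[["mutant"]], 15.6, tolerance = 0.15)
})

test_that("identical groups rarely produce spurious group differences", {
  # null calibration: same parameters in both groups
  reps <- 40
  ps <- vapply(seq_len(reps), function(r) {
    spec <- cohort_spec(
      list(control = agent_params(), mutant = agent_params()),
      n_per_group = 6, seed = 5000 + r
    )
    co <- cohort_sd_sweep(spec)
    v <- vapply(co$mice, function(m) {
      m$sessions[[6]]$summary$omission_fraction  # SD 1 s session
    }, 0)
    g <- vapply(co$mice, function(m) m$meta$group, "")
    two_sample_t(v[g == "control"], v[g == "mutant"])$p
  }, 0)
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("per-mouse substreams are stable when cohort size changes", {
  g <- list(control = agent_params(), mutant = agent_params())
  small <- simulate_cohort(cohort_spec(g, n_per_group = 2, seed = 4,
                                       stages = "magazine"))
  large <- simulate_cohort(cohort_spec(g, n_per_group = 3, seed = 4,
                                       stages = "magazine"))
  s_ids <- vapply(small$mice, function(m) m$meta$mouse_id, "")
  l_ids <- vapply(large$mice, function(m) m$meta$mouse_id, "")
  for (id in s_ids) {
    a <- small$mice[[match(id, s_ids)]]
    b <- large$mice[[match(id, l_ids)]]
    expect_identical(a$sessions[[1]]$trials, b$sessions[[1]]$trials)
  }
})
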