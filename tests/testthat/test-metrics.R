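test_that("classify_trial applies the window rules", {
  # poke in the cued aperture while the light is on
  ev <- trial_events_df(list(0, "STIM_ON", 3), list(2.0, "POKE_APERTURE", 3))
  r <- classify_trial(ev, sd_s = 4, limited_hold_s = 4, iti_s = 5)
  expect_equal(r$outcome, "correct")
  expect_equal(r$response_latency_s, 2.0)

  # poke during the limited hold still counts
  ev <- trial_events_df(list(0, "STIM_ON", 3), list(4, "STIM_OFF", 3),
                        list(7.5, "POKE_APERTURE", 3))
  r <- classify_trial(ev, 4, 4)
  expect_equal(r$outcome, "correct")
  expect_equal(r$response_latency_s, 7.5)

  # dark aperture inside the window
  ev <- trial_events_df(list(0, "STIM_ON", 3), list(1.2, "POKE_APERTURE", 5))
  expect_equal(classify_trial(ev, 4, 4)$outcome, "incorrect")

  # no poke by SD + limited hold
  ev <- trial_events_df(list(0, "STIM_ON", 2), list(1, "STIM_OFF", 2),
                        list(5, "TIMEOUT_START"))
  expect_equal(classify_trial(ev, 1, 4)$outcome, "omission")

  # poke before the stimulus is premature
  ev <- trial_events_df(list(2, "POKE_APERTURE", 1), list(5, "STIM_ON", 3))
  expect_equal(classify_trial(ev, 4, 4)$outcome, "premature")

  # poke after the window expires does not rescue the trial
  ev <- trial_events_df(list(0, "STIM_ON", 3), list(9.5, "POKE_APERTURE", 3))
  expect_equal(classify_trial(ev, 4, 4)$outcome, "omission")

  expect_error(classify_trial(
    trial_events_df(list(3, "STIM_ON", 1), list(1, "POKE_APERTURE", 1)),
    4, 4), "out of")
  expect_error(classify_trial(
    trial_events_df(list(0, "STIM_ON", 1), list(1, "POKE_APERTURE", 9)),
    4, 4), "aperture")
})

test_that("conditional omission metrics match hand enumeration", {
  o <- c("C", "O", "I", "O", "O", "C", "O")
  oac <- conditional_omissions(o, "OAC")
  expect_equal(oac$num, 2L)
  expect_equal(oac$den, 2L)
  expect_equal(oac$fraction, 1.0)
  oaio <- conditional_omissions(o, "OAIO")
  expect_equal(oaio$num, 2L)
  expect_equal(oaio$den, 4L)
  expect_equal(oaio$fraction, 0.5)
  # extended: the trial after a (correct, omission) pair leaves the
  # denominator -- index 2's predecessor omission follows a correct trial
  ext <- conditional_omissions(o, "OAIO_EXT")
  expect_equal(ext$den, 3L)
  expect_equal(ext$num, oracle_conditional(long_outcomes(o), "OAIO_EXT")$num)
  expect_equal(ext$fraction,
               oracle_conditional(long_outcomes(o), "OAIO_EXT")$fraction)
})

test_that("first trials and premature predecessors are excluded", {
  expect_equal(conditional_omissions(c("O"), "OAC")$den, 0L)
  expect_false(conditional_omissions(c("O"), "OAC")$defined)
  r <- conditional_omissions(c("P", "O", "P", "O"), "OAIO")
  expect_equal(r$den, 1L)  # only the trial following the omission counts
  broad <- conditional_omissions(c("P", "O", "P", "O"), "OAIO",
                                 include_premature_predecessor = TRUE)
  expect_equal(broad$den, 3L)
  expect_error(conditional_omissions(c("C", "X")), "unknown outcome")
})

test_that("metrics equal the brute-force enumerator on random sequences", {
  set.seed(91)
  for (i in 1:300) {
    o <- random_outcomes(sample(1:200, 1))
    for (mode in c("OAC", "OAIO", "OAIO_EXT")) {
      got <- conditional_omissions(o, mode)
      want <- oracle_conditional(o, mode)
      expect_identical(got$num, want$num)
      expect_identical(got$den, want$den)
      expect_equal(got$fraction, want$fraction)
    }
    # partition: every omission follows exactly one predecessor class
    oac <- conditional_omissions(o, "OAC")
    oaio <- conditional_omissions(o, "OAIO")
    after_prem <- sum(o[-1] == "omission" & o[-length(o)] == "premature")
    first_om <- as.integer(o[1] == "omission")
    expect_identical(oac$num + oaio$num + after_prem + first_om,
                     sum(o == "omission"))
    # extended denominator is nested in the OAIO denominator
    ext <- conditional_omissions(o, "OAIO_EXT")
    expect_lte(ext$den, oaio$den)
    no_o_after_c <- !any(o[-1] == "omission" & o[-length(o)] == "correct")
    if (no_o_after_c) expect_identical(ext, oaio)
  }
})

test_that("session summaries implement the accuracy and fraction formulas", {
  s <- fake_session(rep(c("correct", "incorrect", "omission"),
                        c(6, 4, 10)))
  sm <- session_summary(s)
  expect_equal(sm$accuracy, 0.60)
  expect_equal(sm$omission_fraction, 0.50)
  expect_equal(sm$n_trials, 20)

  all_om <- session_summary(fake_session(rep("omission", 8)))
  expect_true(is.na(all_om$accuracy))
  expect_false(all_om$accuracy_defined)
  expect_equal(all_om$omission_fraction, 1.0)
})

test_that("session summary equals a brute-force recount on random sessions", {
  set.seed(95)
  for (i in 1:20) {
    s <- simulate_session(agent_params(premature_hazard = 0.03), "training",
                          sd_s = sample(c(8, 2, 1), 1), emit_events = FALSE)
    sm <- s$summary
    out <- s$trials$outcome
    expect_equal(sm$n_correct, sum(out == "correct"))
    expect_equal(sm$n_incorrect, sum(out == "incorrect"))
    expect_equal(sm$n_omission, sum(out == "omission"))
    expect_equal(sm$n_premature, sum(out == "premature"))
    expect_equal(sm$accuracy,
                 sum(out == "correct") /
                   (sum(out == "correct") + sum(out == "incorrect")))
    lat <- s$trials$response_latency_s
    expect_equal(sm$mean_correct_latency_s, mean(lat[out == "correct"]))
  }
})

test_that("eating time is the head-entry to eat-end interval", {
  ev <- trial_events_df(list(10.0, "POKE_MAGAZINE"), list(22.0, "EAT_END"))
  expect_equal(eating_time(ev), 12.0)
  ev0 <- trial_events_df(list(10.0, "POKE_MAGAZINE"), list(10.0, "EAT_END"))
  expect_equal(eating_time(ev0), 0)
  miss <- trial_events_df(list(10.0, "POKE_MAGAZINE"))
  expect_true(is.na(eating_time(miss)))  # absent, never zero
})

test_that("event-derived eating times recover the simulator's Gamma draws", {
  # eating bouts may interleave with later trials, so the event stream pins
  # down the multiset of bout boundaries; the per-session mean and total are
  # exact against the ledger of generative draws
  set.seed(97)
  s <- simulate_session(agent_params(eating_mean = 15, eating_shape = 10),
                        "training", sd_s = 16)
  cls <- classify_events(s$events, s$meta)
  ok <- !is.na(s$trials$eating_duration_s)
  expect_identical(sum(!is.na(cls$eating_duration_s)), sum(ok))
  expect_equal(sum(cls$eating_duration_s[ok]),
               sum(s$trials$eating_duration_s[ok]), tolerance = 1e-3)
  expect_equal(mean(cls$eating_duration_s[ok]),
               mean(s$trials$eating_duration_s[ok]), tolerance = 1e-3)
  expect_true(all(cls$eating_duration_s[ok] >= 0))
})

test_that("aperture ranking sorts by count with ascending-id tie-break", {
  mk <- function(counts) {
    fake <- fake_session(rep("correct", sum(counts)))
    fake$trials$responded_aperture <- rep(1:5, counts)
    fake
  }
  r <- aperture_rank_profile(mk(c(5, 3, 8, 2, 2)))
  expect_equal(r$ranking, c(3, 1, 2, 4, 5))
  expect_equal(r$counts_by_rank, c(8, 5, 3, 2, 2))
  u <- aperture_rank_profile(mk(c(4, 4, 4, 4, 4)))
  expect_equal(u$ranking, 1:5)
  set.seed(99)
  counts <- sample(0:20, 5, replace = TRUE)
  rr <- aperture_rank_profile(mk(counts))
  expect_equal(sort(rr$counts_by_rank), sort(counts))  # permutation
  empty <- fake_session(character(0))
  expect_error(aperture_rank_profile(empty), "undefined")
})

test_that("rank transfer tallies discrimination errors by acquisition rank", {
  ranking <- c(3, 1, 2, 4, 5)
  mk_disc <- function(err_aps) {
    s <- fake_session(rep("incorrect", length(err_aps)))
    s$trials$responded_aperture <- err_aps
    s
  }
  conc <- rank_transfer_errors(ranking, mk_disc(rep(3, 7)))
  expect_equal(conc, c(7, 0, 0, 0, 0))
  flat <- rank_transfer_errors(ranking, mk_disc(1:5))
  expect_equal(flat, rep(1L, 5))
  set.seed(101)
  errs <- sample(1:5, 40, replace = TRUE)
  got <- rank_transfer_errors(ranking, mk_disc(errs))
  want <- vapply(1:5, function(rk) sum(errs == ranking[rk]), 0L)
  expect_equal(got, want)
  expect_equal(sum(got), 40)
  expect_error(rank_transfer_errors(c(1, 1, 2, 3, 4), mk_disc(1)),
               "permutation")
})

test_that("classification reproduces the simulator's own labels everywhere", {
  set.seed(103)
  stages <- c("magazine", "acquisition", "discrimination", "training",
              "test_vsd", "test_viti")
  for (stage in stages) {
    s <- simulate_session(agent_params(premature_hazard = 0.02), stage,
                          sd_s = 2)
    cls <- classify_events(s$events, s$meta)
    expect_identical(cls$outcome, s$trials$outcome)
    expect_equal(nrow(cls), nrow(s$trials))
    lat_ok <- !is.na(s$trials$response_latency_s)
    if (any(lat_ok)) {
      expect_equal(cls$response_latency_s[lat_ok],
                   s$trials$response_latency_s[lat_ok], tolerance = 0.005)
    }
  }
})

test_that("sd_profile aggregates one row per mouse and SD", {
  spec <- cohort_preset("eating_only", n_per_group = 3, seed = 17)
  prof <- sd_profile(cohort_sd_sweep(spec))
  expect_equal(nrow(prof), 6 * 6)  # 6 mice x 6 SDs
  expect_setequal(unique(prof$sd_s), c(16, 8, 4, 2, 1.5, 1))
  expect_true(all(table(prof$mouse_id) == 6))
  expect_true(all(!is.na(prof$omission_fraction)))
})
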