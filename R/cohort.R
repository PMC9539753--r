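# Cohorts of simulated mice. Group-level agent parameters define the study
# conditions; each mouse gets its own reproducible RNG substream plus mild
# multiplicative between-mouse parameter jitter, so regressions across
# individuals (eating time vs OAC, activity vs omissions) have real spread.

#' Specify a simulated cohort
#'
#' @param groups named list of [agent_params()] objects, one per group.
#' @param n_per_group scalar or named vector of mice per group (names must
#'   match `groups`).
#' @param age_range_days admissible age range at study start, days.
#' @param age_mean_days,age_sd_days optional named vectors of per-group
#'   normal age parameters; ages are clipped to `age_range_days`. When
#'   `NULL`, ages are drawn uniformly over the range.
#' @param seed master seed; per-mouse substreams are derived from it so that
#'   changing the cohort size does not reshuffle individual mice.
#' @param between_mouse_cv coefficient of variation of the log-normal
#'   between-mouse jitter applied to eating time, latency scale, lapse rate
#'   and activity. Zero disables jitter.
#' @param stages protocol stages each mouse runs (see [simulate_mouse()]).
#' @return list of class `fc_cohort_spec`.
#' @export
cohort_spec <- function(groups, n_per_group = 16,
                        age_range_days = c(70, 160),
                        age_mean_days = NULL, age_sd_days = NULL,
                        seed = 1, between_mouse_cv = 0.15,
                        stages = c("habituation", "magazine", "acquisition",
                                   "discrimination", "training",
                                   "test_vsd", "test_viti")) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list of agent_params()")
  }
  for (g in groups) {
    if (!inherits(g, "fc_agent_params")) {
      stop("every group must be built with agent_params()")
    }
  }
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)),
                                   names(groups))
  }
  n_per_group <- n_per_group[names(groups)]
  if (any(is.na(n_per_group)) || any(n_per_group < 1)) {
    stop("n_per_group must give at least 1 mouse for every group")
  }
  structure(
    list(groups = groups, n_per_group = n_per_group,
         age_range_days = age_range_days, age_mean_days = age_mean_days,
         age_sd_days = age_sd_days, seed = as.integer(seed),
         between_mouse_cv = between_mouse_cv, stages = stages),
    class = "fc_cohort_spec"
  )
}

mouse_substream_seed <- function(master, group_index, mouse_index) {
  # deterministic, stable under changes to per-group n (indices are within
  # group); kept below 2^31 - 1
  (abs(as.numeric(master)) * 1009 +
     (group_index * 10000 + mouse_index) * 7919) %% 2147483647
}

jitter_params <- function(params, cv) {
  if (cv <= 0) return(params)
  j <- function(x) x * stats::rlnorm(1, -cv^2 / 2, cv)
  params$eating_mean <- j(params$eating_mean)
  params$latency_mu <- params$latency_mu + stats::rnorm(1, 0, cv)
  params$lapse_base <- min(1, j(params$lapse_base))
  params$activity <- j(params$activity)
  params
}

draw_age <- function(spec, group) {
  rng <- spec$age_range_days
  if (is.null(spec$age_mean_days)) {
    return(round(stats::runif(1, rng[1], rng[2])))
  }
  a <- stats::rnorm(1, spec$age_mean_days[[group]], spec$age_sd_days[[group]])
  round(min(rng[2], max(rng[1], a)))
}

#' Simulate a full cohort
#'
#' Runs [simulate_mouse()] for every mouse in the cohort spec, on per-mouse RNG
#' substreams of the master seed.
#'
#' @param spec an `fc_cohort_spec`.
#' @param emit_events build event logs for every session (slower; off by
#'   default for cohort-scale work).
#' @param stages optional override of the cohort spec's stage list.
#' @return list of class `fc_cohort` with elements `spec` and `mice` (list of
#'   `fc_mouse`; each `meta` carries `mouse_id`, `group`, `age_days`).
#' @export
simulate_cohort <- function(spec, emit_events = FALSE, stages = NULL) {
  stopifnot(inherits(spec, "fc_cohort_spec"))
  if (is.null(stages)) stages <- spec$stages
  mice <- list()
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    for (mi in seq_len(spec$n_per_group[[gname]])) {
      set.seed(mouse_substream_seed(spec$seed, gi, mi))
      age <- draw_age(spec, gname)
      p <- jitter_params(spec$groups[[gname]], spec$between_mouse_cv)
      meta <- list(mouse_id = sprintf("%s_%02d", gname, mi),
                   group = gname, age_days = age)
      mice[[length(mice) + 1L]] <-
        simulate_mouse(p, seed = NULL, stages = stages,
                       emit_events = emit_events, meta = meta)
    }
  }
  structure(list(spec = spec, mice = mice), class = "fc_cohort")
}

#' Stimulus-duration sweep for a whole cohort
#'
#' Each mouse runs one training session at every staircase SD (see
#' [simulate_sd_sweep()]). This is the cohort design used for
#' stimulus-duration profiles of omissions, OAC and OAIO, and is far cheaper
#' than full protocol tracks.
#'
#' @inheritParams simulate_cohort
#' @return `fc_cohort` whose mice contain only the six training sessions.
#' @export
cohort_sd_sweep <- function(spec, emit_events = FALSE) {
  stopifnot(inherits(spec, "fc_cohort_spec"))
  mice <- list()
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    for (mi in seq_len(spec$n_per_group[[gname]])) {
      set.seed(mouse_substream_seed(spec$seed, gi, mi))
      age <- draw_age(spec, gname)
      p <- jitter_params(spec$groups[[gname]], spec$between_mouse_cv)
      meta <- list(mouse_id = sprintf("%s_%02d", gname, mi),
                   group = gname, age_days = age)
      activity <- max(0, stats::rnorm(1, p$activity, 0.1 * p$activity))
      sess <- simulate_sd_sweep(p, emit_events = emit_events, meta = meta)
      mice[[length(mice) + 1L]] <- structure(
        list(meta = meta, params = p, activity_score = activity,
             sessions = sess,
             transitions = data.frame(stage = "training",
                                      sessions = length(sess),
                                      advanced = TRUE)),
        class = "fc_mouse"
      )
    }
  }
  structure(list(spec = spec, mice = mice), class = "fc_cohort")
}

#' Cohort presets
#'
#' `"angelman_like"` mirrors the wild-type vs Angelman-model (Ube3a maternal
#' deletion) contrast structure: the mutant-like group eats rewards more
#' slowly (15.6 s vs 10.4 s on average), is hypoactive during habituation,
#' has a steeper attentional-lapse slope as the stimulus shortens, and is
#' slightly more accurate when it does respond. `"eating_only"` isolates the
#' motor confound: the two groups differ only in mean eating time (15 s vs
#' 10 s), with identical lapse parameters -- the manipulation under which OAC
#' should separate groups while OAIO should not. `"null"` gives both groups
#' identical parameters.
#'
#' @param name preset name.
#' @param n_per_group override of group sizes (default: 14 control / 16
#'   mutant for `"angelman_like"`, 16/16 otherwise).
#' @param seed master seed stored in the cohort spec.
#' @return `fc_cohort_spec`.
#' @export
cohort_preset <- function(name = c("angelman_like", "eating_only", "null"),
                          n_per_group = NULL, seed = 1) {
  name <- match.arg(name)
  if (name == "angelman_like") {
    groups <- list(
      control = agent_params(eating_mean = 10.4, activity = 50,
                             lapse_base = 0.05, lapse_sd_slope = 0.05,
                             accuracy_given_response = 0.85),
      mutant = agent_params(eating_mean = 15.6, activity = 30,
                            lapse_base = 0.05, lapse_sd_slope = 0.12,
                            accuracy_given_response = 0.92)
    )
    if (is.null(n_per_group)) n_per_group <- c(control = 14, mutant = 16)
    return(cohort_spec(groups, n_per_group = n_per_group,
                       age_mean_days = c(control = 136, mutant = 109),
                       age_sd_days = c(control = 22, mutant = 30),
                       seed = seed))
  }
  if (name == "eating_only") {
    base <- list(lapse_base = 0.05, lapse_sd_slope = 0.05,
                 accuracy_given_response = 0.85)
    groups <- list(
      control = do.call(agent_params, c(base, list(eating_mean = 10))),
      mutant = do.call(agent_params, c(base, list(eating_mean = 15)))
    )
  } else {
    groups <- list(control = agent_params(), mutant = agent_params())
  }
  if (is.null(n_per_group)) n_per_group <- 16
  cohort_spec(groups, n_per_group = n_per_group, seed = seed)
}
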