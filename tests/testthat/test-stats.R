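test_that("two-sample t handles textbook and degenerate cases", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  tt <- two_sample_t(c(1, 2), c(3, 4), "student")
  expect_equal(tt$t, -2 * sqrt(2), tolerance = 1e-10)
  expect_equal(tt$df, 2)

  # translation invariance
  a <- c(2.1, 3.7, 1.4, 5.0)
  b <- c(4.2, 6.1, 3.3)
  base <- two_sample_t(a, b)
  shift <- two_sample_t(a + 7, b + 7)
  expect_equal(base[c("t", "df", "p")], shift[c("t", "df", "p")])

  # constant groups with different means: degenerate, p -> 0
  deg <- two_sample_t(c(1, 1), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("welch variant differs from student under unequal variances", {
  a <- c(1, 2, 3, 4, 50)
  b <- c(2.0, 2.1, 1.9, 2.05)
  st <- two_sample_t(a, b, "student")
  we <- two_sample_t(a, b, "welch")
  expect_false(isTRUE(all.equal(st$df, we$df)))
})

rm_design <- function(seed, n_per_group = 3, k = 3, effect = 0) {
  set.seed(seed)
  g <- rep(c("wt", "mut"), each = n_per_group * k)
  s <- rep(sprintf("m%02d", 1:(2 * n_per_group)), each = k)
  w <- rep(paste0("L", 1:k), times = 2 * n_per_group)
  subj_eff <- rep(rnorm(2 * n_per_group), each = k)
  y <- rnorm(length(g)) + subj_eff + effect * (g == "mut")
  data.frame(mouse = s, group = g, level = w, value = y)
}

test_that("mixed ANOVA matches a brute-force sums-of-squares oracle", {
  for (seed in c(1, 2, 3, 4, 5)) {
    d <- rm_design(seed)
    got <- mixed_anova(d)
    want <- oracle_split_plot(data.frame(y = d$value, g = d$group,
                                         w = d$level, s = d$mouse))
    expect_equal(got$F[got$effect == "between"], want$F_between,
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "within"], want$F_within,
                 tolerance = 1e-8)
    expect_equal(got$F[got$effect == "interaction"], want$F_interaction,
                 tolerance = 1e-8)
  }
})

test_that("mixed ANOVA degrees of freedom follow the split-plot convention", {
  d <- rm_design(7, n_per_group = 5, k = 6)
  got <- mixed_anova(d)
  expect_equal(got$df1, c(1, 5, 5))
  expect_equal(got$df2, c(8, 40, 40))
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  d <- rm_design(8)
  d$value <- 1  # no variance anywhere
  flat <- mixed_anova(d)
  expect_equal(flat$F, c(0, 0, 0))
  expect_equal(flat$p, c(1, 1, 1))

  # pure main effect: group B = group A + constant at every level
  d2 <- rm_design(9)
  d2$value <- rep(rnorm(3), times = 6) + 2 * (d2$group == "mut")
  pure <- mixed_anova(d2)
  expect_equal(pure$F[pure$effect == "interaction"], 0, tolerance = 1e-8)
  expect_gt(pure$F[pure$effect == "between"], 0)
})

test_that("one within level reduces the ANOVA to the squared t", {
  set.seed(10)
  d <- data.frame(mouse = sprintf("m%02d", 1:10),
                  group = rep(c("a", "b"), each = 5),
                  level = "only", value = rnorm(10))
  an <- mixed_anova(d)
  tt <- two_sample_t(d$value[d$group == "a"], d$value[d$group == "b"])
  expect_equal(an$F[1], tt$t^2, tolerance = 1e-8)
  expect_equal(an$p[1], tt$p, tolerance = 1e-8)
  expect_true(all(is.na(an$F[2:3])))
})

test_that("unbalanced or incomplete designs are refused, never imputed", {
  d <- rm_design(11)
  expect_error(mixed_anova(d[-1, ]), "unbalanced")
  d2 <- d
  d2$value[3] <- NA
  expect_error(mixed_anova(d2), "complete")
})

test_that("statistics are invariant to row order", {
  d <- rm_design(12)
  set.seed(13)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(mixed_anova(d), mixed_anova(shuffled))
})

test_that("bonferroni adjustment multiplies and clips", {
  set.seed(14)
  d <- rm_design(14, n_per_group = 6, k = 6, effect = 1.5)
  ph <- bonferroni_posthoc(d)
  expect_equal(nrow(ph), 6)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 6))
  expect_true(all(ph$p_adj >= ph$p_raw))
})

test_that("linear regression recovers exact and degenerate fits", {
  pf <- linear_regression(c(0, 1, 2), c(0, 1, 2))
  expect_equal(pf$slope, 1)
  expect_equal(pf$r_squared, 1)

  flat <- linear_regression(c(0, 1, 2), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(linear_regression(c(1, 1, 1), c(1, 2, 3)), "constant")

  set.seed(15)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30)
  base <- linear_regression(x, y)
  resc <- linear_regression(3 * x - 1, -0.5 * y + 4)
  expect_equal(base$r_squared, resc$r_squared, tolerance = 1e-12)
  expect_equal(base$p, resc$p, tolerance = 1e-10)
})

test_that("age adjustment changes little when age is orthogonal", {
  set.seed(16)
  n <- 200
  group <- rep(c("wt", "mut"), each = n / 2)
  age <- rnorm(n, 120, 20)             # independent of group and outcome
  y <- rnorm(n) + 0.3 * (group == "mut")
  r <- covariate_adjusted_group_effect(y, group, age)
  expect_true(r$adjusted)
  expect_lt(abs(r$p - r$p_unadjusted), 0.05)
})

test_that("age adjustment absorbs an age-driven pseudo-effect", {
  set.seed(17)
  n <- 40
  group <- rep(c("wt", "mut"), each = n / 2)
  age <- c(rnorm(n / 2, 140, 5), rnorm(n / 2, 100, 5))  # confounded
  y <- 0.1 * age + rnorm(n, sd = 0.5)   # outcome is pure age
  r <- covariate_adjusted_group_effect(y, group, age)
  un <- two_sample_t(y[group == "wt"], y[group == "mut"])
  expect_lt(un$p, 0.001)   # naive comparison is fooled
  expect_gt(r$p, 0.05)     # adjusted model is not
})

test_that("constant age falls back to the unadjusted comparison", {
  set.seed(18)
  y <- rnorm(12)
  group <- rep(c("a", "b"), 6)
  r <- covariate_adjusted_group_effect(y, group, rep(100, 12))
  expect_false(r$adjusted)
  expect_match(r$warning, "constant")
  expect_equal(r$p, r$p_unadjusted)
  # translating age only moves the intercept
  age <- rnorm(12, 100, 10)
  r1 <- covariate_adjusted_group_effect(y, group, age)
  r2 <- covariate_adjusted_group_effect(y, group, age + 50)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("stats_report covers the ANOVA, t and regression surface", {
  spec <- cohort_preset("angelman_like", n_per_group = c(control = 8,
                                                      mutant = 8), seed = 19)
  prof <- sd_profile(cohort_sd_sweep(spec))
  rep_ <- stats_report(prof)
  expect_true(all(c("rm_anova", "t_test") %in% rep_$test))
  oac_rows <- rep_[rep_$measure == "oac" & rep_$test == "rm_anova", ]
  expect_equal(oac_rows$effect, c("between", "within", "interaction"))
  expect_true(all(rep_$p <= 1, na.rm = TRUE))
  expect_true("mean_eating_s" %in% rep_$measure)
})
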