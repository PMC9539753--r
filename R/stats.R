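# Group-level statistics battery: Student/Welch t, two-way repeated-measures
# ANOVA (subject nested in group) with Bonferroni post-hoc contrasts, OLS
# regression, and fixed-covariate age adjustment. Model fitting is delegated
# to stats::aov / stats::lm; this module owns the interface, the balance
# checks and the degenerate-case conventions.

#' Two-sample t test
#'
#' Student (pooled variance, the default -- matching degrees-of-freedom
#' reporting like df = 28 for group sizes 14 + 16) or Welch. Degenerate
#' inputs follow fixed conventions: both groups constant with equal means
#' gives t = 0, p = 1; constant with unequal means gives p = 0, flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided), `mean_diff`, `degenerate`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0,
                mean_diff = mean(a) - mean(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "student")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(a) - mean(b), degenerate = FALSE)
}

check_rm_design <- function(data, dv, between, within, subject) {
  for (col in c(dv, between, within, subject)) {
    if (!col %in% names(data)) stop("column '", col, "' not found")
  }
  if (any(is.na(data[[dv]]))) {
    stop("missing values in '", dv, "': the repeated-measures design must ",
         "be complete (imputation is out of scope)")
  }
  tab <- table(data[[subject]], data[[within]])
  if (any(tab != 1)) {
    stop("unbalanced design: every subject must contribute exactly one ",
         "value at every within-factor level")
  }
  gps <- tapply(data[[between]], data[[subject]],
                function(g) length(unique(g)))
  if (any(gps != 1)) stop("each subject must belong to exactly one group")
  invisible(TRUE)
}

#' Two-way repeated-measures ANOVA (split-plot)
#'
#' Between-subjects factor (e.g. genotype) crossed with a within-subjects
#' factor (e.g. stimulus duration), subject nested in group. Degrees of
#' freedom follow the standard convention: the between effect is tested
#' against subject-within-group error (df = N - groups), the within effect
#' and the interaction against the subject x within error
#' (df = (N - groups) x (levels - 1)). The design must be complete and
#' balanced within subjects; missing cells are an error, never imputed.
#' With a single within level the model reduces to a one-way
#' between-subjects ANOVA (F equals the squared Student t for two groups).
#' Effects with zero sum of squares report F = 0, p = 1. No sphericity
#' correction is applied (uncorrected df, matching the conventional
#' reporting); Greenhouse-Geisser adjustment is deliberately not provided.
#'
#' @param data data.frame in long format.
#' @param dv,between,within,subject column names.
#' @return data.frame with one row per effect (`between`, `within`,
#'   `interaction`): `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data, dv = "value", between = "group",
                        within = "level", subject = "mouse") {
  check_rm_design(data, dv, between, within, subject)
  d <- data.frame(
    y = data[[dv]],
    g = factor(data[[between]]),
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  # F computed from the stratum sums of squares with explicit degenerate
  # rules: a zero-SS effect is F = 0, p = 1 (no variance to explain); a
  # positive effect over a zero error term is F = Inf, p = 0
  total_ss <- sum((d$y - mean(d$y))^2)
  zero_data <- total_ss < 1e-12 * (1 + sum(d$y^2))
  tol <- 1e-10 * max(total_ss, .Machine$double.xmin)
  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    if (zero_data || ss_eff <= tol) return(list(F = 0, p = 1))
    if (ss_err <= tol) return(list(F = Inf, p = 0))
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    list(F = F, p = stats::pf(F, df_eff, df_err, lower.tail = FALSE))
  }
  if (nlevels(d$w) <= 1) {
    fit <- stats::aov(y ~ g, data = d)
    sm <- summary(fit)[[1]]
    eff <- f_of(sm[["Sum Sq"]][1], sm$Df[1], sm[["Sum Sq"]][2], sm$Df[2])
    return(data.frame(
      effect = c("between", "within", "interaction"),
      F = c(eff$F, NA, NA), df1 = c(sm$Df[1], NA, NA),
      df2 = c(sm$Df[2], NA, NA), p = c(eff$p, NA, NA),
      stringsAsFactors = FALSE
    ))
  }
  fit <- stats::aov(y ~ g * w + Error(s), data = d)
  sm <- summary(fit)
  up <- sm[["Error: s"]][[1]]        # between stratum
  lo <- sm[["Error: Within"]][[1]]   # within stratum
  rn_up <- trimws(rownames(up))
  rn_lo <- trimws(rownames(lo))
  bi <- match("g", rn_up)
  ri <- match("Residuals", rn_up)
  wi <- match("w", rn_lo)
  ii <- match("g:w", rn_lo)
  li <- match("Residuals", rn_lo)
  be <- f_of(up[["Sum Sq"]][bi], up$Df[bi], up[["Sum Sq"]][ri], up$Df[ri])
  wn <- f_of(lo[["Sum Sq"]][wi], lo$Df[wi], lo[["Sum Sq"]][li], lo$Df[li])
  ia <- f_of(lo[["Sum Sq"]][ii], lo$Df[ii], lo[["Sum Sq"]][li], lo$Df[li])
  data.frame(
    effect = c("between", "within", "interaction"),
    F = c(be$F, wn$F, ia$F),
    df1 = c(up$Df[bi], lo$Df[wi], lo$Df[ii]),
    df2 = c(up$Df[ri], lo$Df[li], lo$Df[li]),
    p = c(be$p, wn$p, ia$p),
    stringsAsFactors = FALSE
  )
}

#' Bonferroni post-hoc group contrasts per within level
#'
#' Two-sample comparison of the between-groups contrast at every level of
#' the within factor, with p multiplied by the number of levels and clipped
#' at 1. Intended after [mixed_anova()] reports a between main effect or an
#' interaction.
#'
#' @inheritParams mixed_anova
#' @param variant t-test variant, see [two_sample_t()].
#' @return data.frame: one row per within level with `t`, `df`, `p_raw`,
#'   `p_adj`, `mean_diff`.
#' @export
bonferroni_posthoc <- function(data, dv = "value", between = "group",
                               within = "level", variant = "student") {
  g <- factor(data[[between]])
  if (nlevels(g) != 2) stop("post-hoc contrast requires exactly two groups")
  lv <- unique(data[[within]])
  k <- length(lv)
  rows <- lapply(lv, function(l) {
    sel <- data[[within]] == l
    a <- data[[dv]][sel & g == levels(g)[1]]
    b <- data[[dv]][sel & g == levels(g)[2]]
    tt <- two_sample_t(a, b, variant)
    data.frame(level = l, t = tt$t, df = tt$df, p_raw = tt$p,
               p_adj = min(1, tt$p * k), mean_diff = tt$mean_diff)
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and two-sided `p` from the slope t test. A constant `y`
#'   gives slope 0, R-squared 0 and `p = NA`.
#' @export
linear_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate inputs; summary.lm warns about them
  co <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = stats::cor(x, y)^2,
       p = unname(co["x", "Pr(>|t|)"]))
}

#' Group effect with age-covariate adjustment
#'
#' Fits `value ~ group + age` and reports the group coefficient and its
#' two-sided p, alongside the unadjusted comparison. A constant age falls
#' back to the unadjusted model with a warning record (not an error).
#'
#' @param values numeric outcome per subject.
#' @param group two-level factor (or coercible).
#' @param age_days numeric covariate.
#' @return list with `estimate` (group coefficient), `t`, `df`, `p`,
#'   `p_unadjusted`, `adjusted` (logical), `warning` (character or NA).
#' @export
covariate_adjusted_group_effect <- function(values, group, age_days) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (length(values) < nlevels(g) + 2) stop("too few observations")
  un <- stats::lm(values ~ g)
  co_un <- summary(un)$coefficients
  p_un <- co_un[2, "Pr(>|t|)"]
  if (length(unique(age_days)) <= 1) {
    return(list(estimate = unname(co_un[2, "Estimate"]),
                t = unname(co_un[2, "t value"]),
                df = un$df.residual, p = p_un, p_unadjusted = p_un,
                adjusted = FALSE,
                warning = "age is constant: reporting unadjusted comparison"))
  }
  fit <- stats::lm(values ~ g + age_days)
  co <- summary(fit)$coefficients
  list(estimate = unname(co[2, "Estimate"]), t = unname(co[2, "t value"]),
       df = fit$df.residual, p = unname(co[2, "Pr(>|t|)"]),
       p_unadjusted = p_un, adjusted = TRUE, warning = NA_character_)
}

#' Full group-statistics report for a stimulus-duration profile
#'
#' Runs the analysis surface over a per-mouse x SD metric table (see
#' [sd_profile()]): repeated-measures ANOVA (group x SD) for omissions, OAC
#' and OAIO with Bonferroni post-hoc contrasts when warranted, the
#' between-group eating-time t test at the longest SD, and the
#' eating-time/OAC and eating-time/OAIO regressions.
#'
#' @param profile data.frame from [sd_profile()].
#' @param alpha significance level gating post-hoc tests.
#' @return data.frame, one row per test: `measure`, `test`, `effect`,
#'   `statistic`, `df1`, `df2`, `p`, `p_adj`.
#' @export
stats_report <- function(profile, alpha = 0.05) {
  rows <- list()
  add <- function(measure, test, effect, statistic, df1, df2, p,
                  p_adj = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, test = test, effect = effect,
      statistic = statistic, df1 = df1, df2 = df2, p = p, p_adj = p_adj,
      stringsAsFactors = FALSE)
  }
  for (meas in c("omission_fraction", "oac", "oaio", "oaio_ext",
                 "accuracy")) {
    d <- profile[!is.na(profile[[meas]]),
                 c("mouse_id", "group", "sd_s", meas)]
    names(d)[4] <- "value"
    complete <- stats::ave(d$value, d$mouse_id, FUN = length)
    keep <- complete == length(unique(d$sd_s))
    d <- d[keep, , drop = FALSE]
    if (length(unique(d$mouse_id)) < 4) next
    an <- mixed_anova(d, dv = "value", between = "group", within = "sd_s",
                      subject = "mouse_id")
    for (j in seq_len(nrow(an))) {
      add(meas, "rm_anova", an$effect[j], an$F[j], an$df1[j], an$df2[j],
          an$p[j])
    }
    if (!is.na(an$p[1]) && (an$p[1] < alpha ||
                            (!is.na(an$p[3]) && an$p[3] < alpha))) {
      ph <- bonferroni_posthoc(d, dv = "value", between = "group",
                               within = "sd_s")
      for (j in seq_len(nrow(ph))) {
        add(meas, "bonferroni_t", paste0("sd_", ph$level[j]), ph$t[j],
            ph$df[j], NA, ph$p_raw[j], ph$p_adj[j])
      }
    }
  }
  sd_top <- max(profile$sd_s)
  top <- profile[profile$sd_s == sd_top & !is.na(profile$mean_eating_s), ]
  if (nrow(top) >= 4) {
    gl <- unique(top$group)
    tt <- two_sample_t(top$mean_eating_s[top$group == gl[1]],
                       top$mean_eating_s[top$group == gl[2]])
    add("mean_eating_s", "t_test", "group", tt$t, tt$df, NA, tt$p)
  }
  per_mouse <- function(col) {
    tapply(profile[[col]], profile$mouse_id,
           function(x) mean(x, na.rm = TRUE))
  }
  eat <- tapply(profile$mean_eating_s, profile$mouse_id,
                function(x) mean(x, na.rm = TRUE))
  for (meas in c("oac", "oaio")) {
    v <- per_mouse(meas)
    common <- intersect(names(eat)[!is.na(eat)], names(v)[!is.na(v)])
    if (length(common) >= 3 && stats::sd(eat[common]) > 0) {
      lr <- linear_regression(eat[common], v[common])
      add(meas, "regression_on_eating", "slope", lr$slope, NA, NA, lr$p)
      add(meas, "regression_on_eating", "r_squared", lr$r_squared, NA, NA,
          NA)
    }
  }
  do.call(rbind, rows)
}
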