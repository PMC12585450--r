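# Inferential layer: 2x2 (group x time) mixed ANOVA with partial eta-squared
# and noncentral-F confidence intervals, effect-size labels, and the
# independent t-tests used for demographics.

#' Mixed 2x2 (group x time) ANOVA
#'
#' One between-subjects factor (group, 2 levels) crossed with one
#' within-subjects factor (time, 2 levels). Sums of squares follow the
#' classical split-plot decomposition: the group effect is tested against
#' subjects-within-groups, and the time and interaction effects against the
#' time-by-subjects-within-groups residual. With a two-level within factor
#' sphericity holds trivially and no correction is applied. Subjects missing
#' either time point are excluded listwise (and recorded in the result);
#' the within-stratum error degrees of freedom therefore drop by one per
#' excluded subject. Partial eta-squared is `SS_effect / (SS_effect +
#' SS_error_for_that_effect)`, with a noncentral-F confidence interval from
#' [eta_p2_ci()].
#'
#' @param data A data frame with one row per subject x time.
#' @param value,subject,group,time Column names (strings) of the outcome,
#'   subject identifier, between factor and within factor.
#' @param ci_level Confidence level for the eta-squared interval
#'   (default 0.95).
#' @param ci_conversion Passed to [eta_p2_ci()].
#' @param ci Compute the eta-squared confidence intervals (default `TRUE`);
#'   set `FALSE` to skip them, e.g. in large simulation loops.
#' @return An object of class `coord_anova`; see [tidy.coord_anova()] for the
#'   three-effect results table.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:8),
#'                         time = c("pre", "post"))
#' d$group <- rep(c("A", "B"), each = 8)
#' set.seed(1); d$value <- rnorm(16)
#' tidy(mixed_anova_2x2(d))
mixed_anova_2x2 <- function(data, value = "value", subject = "subject",
                            group = "group", time = "time",
                            ci_level = 0.95, ci_conversion = "sample",
                            ci = TRUE) {
  df <- tibble::tibble(
    subject = as.character(data[[subject]]),
    group = as.character(data[[group]]),
    time = as.character(data[[time]]),
    value = as.numeric(data[[value]])
  )
  groups <- sort(unique(df$group))
  times <- unique(df$time)
  if (length(groups) != 2L) {
    stop("mixed_anova_2x2(): group must have exactly 2 levels", call. = FALSE)
  }
  if (length(times) != 2L) {
    stop("mixed_anova_2x2(): time must have exactly 2 levels", call. = FALSE)
  }
  wide <- df |>
    dplyr::filter(!is.na(.data$value)) |>
    tidyr::pivot_wider(id_cols = c("subject", "group"),
                       names_from = "time", values_from = "value")
  complete <- stats::complete.cases(wide[times])
  excluded <- wide$subject[!complete]
  wide <- wide[complete, ]
  n_g <- table(factor(wide$group, levels = groups))
  if (any(n_g < 2)) {
    stop("mixed_anova_2x2(): need at least 2 complete subjects per group",
         call. = FALSE)
  }
  y <- as.matrix(wide[times])                 # subjects x 2 times
  g <- factor(wide$group, levels = groups)
  N <- nrow(y)

  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, g, mean)
  time_mean <- colMeans(y)
  cell_mean <- rbind(tapply(y[, 1], g, mean), tapply(y[, 2], g, mean))

  ss_total <- sum((y - grand)^2)
  ss_between <- 2 * sum((subj_mean - grand)^2)
  ss_group <- 2 * sum(n_g * (grp_mean - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- N * sum((time_mean - grand)^2)
  int_dev <- sweep(sweep(cell_mean, 2, as.numeric(grp_mean)), 1, time_mean) +
    grand
  ss_int <- sum(rep(as.numeric(n_g), each = 2) * int_dev^2)
  ss_within <- ss_total - ss_between
  ss_err_w <- ss_within - ss_time - ss_int

  df_err_b <- N - 2
  df_err_w <- N - 2
  ms <- function(ss, d) ss / d
  eff <- tibble::tibble(
    effect = c("group", "time", "interaction"),
    sum_sq = c(ss_group, ss_time, ss_int),
    error_sum_sq = c(ss_subj, ss_err_w, ss_err_w),
    df1 = c(1, 1, 1),
    df2 = c(df_err_b, df_err_w, df_err_w)
  )
  f <- ms(eff$sum_sq, eff$df1) / ms(eff$error_sum_sq, eff$df2)
  eff$statistic <- ifelse(eff$sum_sq == 0, 0, f)  # 0/0 when all cells equal
  eff$p.value <- pf(eff$statistic, eff$df1, eff$df2, lower.tail = FALSE)
  eta <- eff$sum_sq / (eff$sum_sq + eff$error_sum_sq)
  eff$eta_p2 <- ifelse(eff$sum_sq == 0, 0, eta)
  bounds <- if (ci) {
    purrr::map2_dfr(eff$statistic, eff$df2, function(f, d2) {
      if (!is.finite(f)) return(tibble::tibble(ci_lo = NA_real_,
                                               ci_hi = NA_real_))
      b <- eta_p2_ci(f, 1, d2, level = ci_level, conversion = ci_conversion)
      tibble::tibble(ci_lo = b[1], ci_hi = b[2])
    })
  } else {
    tibble::tibble(ci_lo = rep(NA_real_, 3), ci_hi = rep(NA_real_, 3))
  }
  eff <- dplyr::bind_cols(eff, bounds)
  eff$size_label <- label_effect_size(eff$eta_p2)

  structure(
    list(
      table = eff,
      ss = tibble::tibble(
        component = c("group", "subjects_within_groups", "time",
                      "interaction", "time_x_subjects", "total"),
        sum_sq = c(ss_group, ss_subj, ss_time, ss_int, ss_err_w, ss_total)
      ),
      excluded = excluded,
      n_per_group = stats::setNames(as.integer(n_g), groups),
      groups = groups,
      times = times,
      ci_level = ci_level
    ),
    class = "coord_anova"
  )
}

#' @export
print.coord_anova <- function(x, ...) {
  cat("Mixed 2x2 (group x time) ANOVA: n =",
      paste(x$n_per_group, collapse = " + "),
      if (length(x$excluded)) paste0("(", length(x$excluded),
                                     " excluded listwise)") else "", "\n")
  print(x$table)
  invisible(x)
}

#' Tidy a mixed 2x2 ANOVA
#'
#' @param x A `coord_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect (`group`, `time`, `interaction`):
#'   `effect`, `sum_sq`, `error_sum_sq`, `df1`, `df2`, `statistic` (F),
#'   `p.value`, `eta_p2`, `ci_lo`, `ci_hi`, `size_label`.
#' @method tidy coord_anova
#' @export
tidy.coord_anova <- function(x, ...) {
  x$table
}

#' One-row model summary of a mixed 2x2 ANOVA
#'
#' @param x A `coord_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, exclusions and error dfs.
#' @method glance coord_anova
#' @export
glance.coord_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = sum(x$n_per_group),
    n_excluded = length(x$excluded),
    df_between_error = x$table$df2[x$table$effect == "group"],
    df_within_error = x$table$df2[x$table$effect == "interaction"],
    ci_level = x$ci_level
  )
}

#' Noncentral-F confidence interval for partial eta-squared
#'
#' Inverts the noncentral F distribution: the noncentrality bounds
#' `lambda_lo`, `lambda_hi` solve `CDF(F; df1, df2, lambda) = 1 - alpha/2`
#' and `alpha/2` (clamped at zero where no positive solution exists), then
#' each bound is converted to the eta-squared scale. The default conversion
#' (`"sample"`) plugs the bound into the sample statistic's form,
#' `eta = lambda / (lambda + df2)` — the convention used by the SPSS
#' noncentral-F routine whose output this package mirrors. The
#' `"smithson"` conversion `eta = lambda / (lambda + df1 + df2 + 1)` is the
#' common textbook alternative; the two differ in the second decimal for
#' small samples.
#'
#' @param f Observed F ratio (>= 0, finite).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param level Confidence level (default 0.95).
#' @param conversion `"sample"` (default) or `"smithson"`.
#' @return Numeric vector `c(lo, hi)` with `0 <= lo <= hi < 1`.
#' @export
#' @examples
#' eta_p2_ci(1.693, 1, 21) # upper bound ~ 0.339
eta_p2_ci <- function(f, df1, df2, level = 0.95,
                      conversion = c("sample", "smithson")) {
  conversion <- match.arg(conversion)
  if (!is.finite(f) || f < 0) {
    stop("eta_p2_ci(): F must be finite and non-negative", call. = FALSE)
  }
  alpha <- 1 - level
  solve_lambda <- function(target) {
    # find lambda with pf(f, df1, df2, ncp = lambda) == target;
    # pf is decreasing in lambda
    if (pf(f, df1, df2, ncp = 0) <= target) return(0)
    hi <- max(4 * (f * df1 + df2), 10)
    while (pf(f, df1, df2, ncp = hi) > target && hi < 1e8) hi <- hi * 2
    stats::uniroot(function(l) pf(f, df1, df2, ncp = l) - target,
                   lower = 0, upper = hi, tol = 1e-10)$root
  }
  l_lo <- solve_lambda(1 - alpha / 2)
  l_hi <- solve_lambda(alpha / 2)
  conv <- switch(conversion,
                 sample = function(l) l / (l + df2),
                 smithson = function(l) l / (l + df1 + df2 + 1))
  c(conv(l_lo), conv(l_hi))
}

#' Label a partial eta-squared effect size
#'
#' Thresholds 0.01, 0.06 and 0.14 for small, medium and large; values below
#' 0.01 are labelled negligible.
#'
#' @param eta_p2 Numeric vector of partial eta-squared values in `[0, 1]`.
#' @return A factor with levels `negligible`, `small`, `medium`, `large`.
#' @export
#' @examples
#' label_effect_size(c(0.009, 0.012, 0.075, 0.2))
label_effect_size <- function(eta_p2) {
  if (any(eta_p2 < 0 | eta_p2 > 1, na.rm = TRUE)) {
    stop("eta_p2 must lie in [0, 1]", call. = FALSE)
  }
  cut(eta_p2, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large"))
}

#' Independent two-sample t-test (pooled variance)
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = TRUE`, used for
#' group demographics. The degenerate case of zero variance in both groups
#' with equal means returns `t = 0, p = 1` rather than an error.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A one-row tibble: `statistic` (t), `df`, `p.value`, `mean_a`,
#'   `mean_b`.
#' @export
#' @examples
#' independent_t_test(c(1, 2, 3), c(4, 5, 6))
independent_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("independent_t_test(): each group needs at least 2 values",
         call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(tibble::tibble(statistic = 0, df = length(a) + length(b) - 2,
                          p.value = 1, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
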