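# Mixed 2x2 ANOVA, partial eta-squared confidence intervals, effect-size
# labels and demographic t-tests.

test_that("all-equal cell values give F = 0 and eta = 0 everywhere", {
  d <- make_design(6)
  d$value <- 7
  fit <- tidy(mixed_anova_2x2(d))
  expect_equal(fit$statistic, rep(0, 3))
  expect_equal(fit$eta_p2, rep(0, 3))
  expect_equal(fit$p.value, rep(1, 3))
})

test_that("F and eta match the brute-force sums-of-squares oracle", {
  set.seed(21)
  for (i in 1:20) {
    d <- make_design(12, effect_int = runif(1, 0, 2))
    fit <- tidy(mixed_anova_2x2(d))
    wide <- tidyr::pivot_wider(d, id_cols = c("subject", "group"),
                               names_from = "time", values_from = "value")
    y <- as.matrix(wide[c("pre", "post")])
    want <- oracle_mixed_ss(y, factor(wide$group))
    expect_equal(fit$statistic[fit$effect == "group"], want$f_group,
                 tolerance = 1e-8)
    expect_equal(fit$statistic[fit$effect == "time"], want$f_time,
                 tolerance = 1e-8)
    expect_equal(fit$statistic[fit$effect == "interaction"], want$f_int,
                 tolerance = 1e-8)
    expect_equal(fit$eta_p2[fit$effect == "interaction"],
                 want$int / (want$int + want$err_w), tolerance = 1e-8)
  }
})

test_that("results agree with stats::aov as an independent cross-check", {
  set.seed(22)
  d <- make_design(12, effect_int = 1)
  fit <- tidy(mixed_anova_2x2(d))
  a <- summary(stats::aov(
    value ~ group * time + Error(subject),
    data = transform(d, subject = factor(subject), group = factor(group),
                     time = factor(time))))
  between <- a[["Error: subject"]][[1]]
  within <- a[["Error: Within"]][[1]]
  expect_equal(fit$statistic[fit$effect == "group"],
               between["group", "F value"], tolerance = 1e-10)
  expect_equal(fit$statistic[fit$effect == "time"],
               within["time", "F value"], tolerance = 1e-10)
  expect_equal(fit$statistic[fit$effect == "interaction"],
               within["group:time", "F value"], tolerance = 1e-10)
})

test_that("sums of squares decompose the total on every input", {
  set.seed(23)
  for (i in 1:10) {
    d <- make_design(sample(4:15, 1), effect_int = rnorm(1))
    fit <- mixed_anova_2x2(d)
    ss <- fit$ss
    total <- ss$sum_sq[ss$component == "total"]
    parts <- sum(ss$sum_sq[ss$component != "total"])
    expect_equal(parts, total, tolerance = 1e-8)
  }
})

test_that("listwise exclusion drops the within-error df from 22 to 21", {
  set.seed(24)
  d <- make_design(12)
  full <- glance(mixed_anova_2x2(d))
  expect_equal(full$df_within_error, 22)
  expect_equal(full$n_excluded, 0)
  d2 <- d[!(d$subject == "S03" & d$time == "post"), ]
  fit2 <- mixed_anova_2x2(d2)
  expect_equal(glance(fit2)$df_within_error, 21)
  expect_equal(fit2$excluded, "S03")
  # a group reduced below 2 complete subjects is an error
  d3 <- d[!(d$subject %in% sprintf("S%02d", 13:23) & d$time == "post"), ]
  expect_error(mixed_anova_2x2(d3), "2 complete subjects")
})

test_that("interaction type-I error is nominal over null simulations", {
  set.seed(25)
  reject <- vapply(1:400, function(i) {
    d <- make_design(12)
    tab <- tidy(mixed_anova_2x2(d, ci = FALSE))
    tab$p.value[tab$effect == "interaction"] < 0.05
  }, logical(1))
  # 400 nulls: 5% +/- binomial noise; 3-sigma band ~ [0.017, 0.083]
  expect_gte(mean(reject), 0.017)
  expect_lte(mean(reject), 0.083)
})

test_that("eta CI: zero F pins the lower bound at zero and the printed
           benchmark is reproduced", {
  ci0 <- eta_p2_ci(0, 1, 22)
  expect_equal(ci0[1], 0)
  ci <- eta_p2_ci(1.693, 1, 21)
  expect_equal(ci[1], 0)
  expect_lt(abs(ci[2] - 0.339), 0.01)
  expect_error(eta_p2_ci(NaN, 1, 21), "finite")
})

test_that("eta and its CI behave monotonically", {
  f <- c(0.5, 1, 2, 4, 8)
  eta <- f / (f + 22)
  expect_true(all(diff(eta) > 0))
  his <- vapply(f, function(x) eta_p2_ci(x, 1, 22)[2], numeric(1))
  expect_true(all(diff(his) > 0))
  # CI width shrinks as df2 grows for fixed F
  widths <- vapply(c(10, 20, 40, 80), function(d2) {
    ci <- eta_p2_ci(3, 1, d2)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("CI coverage under the null is ~97.5% (one-sided clamping)", {
  set.seed(26)
  contains0 <- vapply(1:400, function(i) {
    d <- make_design(12)
    tab <- tidy(mixed_anova_2x2(d))
    tab$ci_lo[tab$effect == "interaction"] == 0
  }, logical(1))
  expect_gt(mean(contains0), 0.94)
})

test_that("effect-size labels follow the 0.01/0.06/0.14 thresholds", {
  expect_equal(as.character(label_effect_size(0.075)), "medium")
  expect_equal(as.character(label_effect_size(0.093)), "medium")
  expect_equal(as.character(label_effect_size(0.121)), "medium")
  expect_equal(as.character(label_effect_size(0.009)), "negligible")
  expect_equal(as.character(label_effect_size(c(0.01, 0.06, 0.14))),
               c("small", "medium", "large"))
  expect_error(label_effect_size(1.2), "0, 1")
})

test_that("pooled t-test matches the closed form and handles degenerate
           input", {
  res <- independent_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$statistic), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  same <- independent_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(independent_t_test(1, c(1, 2)), "at least 2")
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(27)
  p <- vapply(1:1000, function(i) {
    independent_t_test(rnorm(12), rnorm(12))$p.value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("interaction F is distribution-invariant under group relabelling
           on null data", {
  set.seed(28)
  base <- make_design(8)
  f_int <- function(d) tidy(mixed_anova_2x2(d, ci = FALSE))$statistic[3]
  subj <- unique(base$subject)
  perm <- replicate(300, {
    g <- sample(rep(c("A", "B"), each = 8))
    d <- base
    d$group <- g[match(d$subject, subj)]
    f_int(d)
  })
  sims <- replicate(300, f_int(make_design(8)))
  ks <- suppressWarnings(stats::ks.test(perm, sims))
  expect_gt(ks$p.value, 0.01)
})
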