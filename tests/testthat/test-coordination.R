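# Modified vector coding: coupling angles, circular statistics, pattern
# classification, subphase aggregation and variability.

test_that("ensemble mean is pointwise arithmetic", {
  one <- tibble::tibble(stride = 1, pct = 0:100,
                        hip_deg = sin(0:100 / 16) * 20)
  expect_equal(ensemble_mean_cycle(one)$hip_deg, one$hip_deg)
  two <- dplyr::bind_rows(one,
                          dplyr::mutate(one, stride = 2,
                                        hip_deg = hip_deg + 2))
  expect_equal(ensemble_mean_cycle(two)$hip_deg, one$hip_deg + 1)
  expect_error(ensemble_mean_cycle(one[0, ]), "no cycles")
})

test_that("ensemble mean of noisy cycles converges at the standard-error
           rate", {
  set.seed(8)
  base <- 25 * sin(2 * pi * (0:100) / 100)
  cycles <- purrr::map_dfr(1:20, function(s) {
    tibble::tibble(stride = s, pct = 0:100,
                   hip_deg = base + rnorm(101, sd = 1))
  })
  m <- ensemble_mean_cycle(cycles)$hip_deg
  # pointwise SE is 1/sqrt(20); the max over 101 points concentrates near
  # SE * sqrt(2 log 101) ~ 3 SE, so bound the max at 4.5 SE
  expect_lt(max(abs(m - base)), 4.5 / sqrt(20))
  expect_lt(mean(abs(m - base)), 2 / sqrt(20))
})

test_that("coupling angles realize the quadrant-preserving arctangent", {
  mk <- function(dp, dd) {
    list(prox = cumsum(c(0, rep(dp, 100))), dist = cumsum(c(0, rep(dd, 100))))
  }
  ca <- function(dp, dd) {
    v <- mk(dp, dd)
    coupling_angles(v$prox, v$dist)$theta_deg[1]
  }
  expect_equal(ca(1, 0), 90)    # proximal moving, distal stationary
  expect_equal(ca(0, 1), 0)
  expect_equal(ca(1, 1), 45)
  expect_equal(ca(-1, -1), 225)
  expect_equal(ca(-1, 1), 315)
  expect_equal(ca(0, -1), 180)
  # both joints stationary: direction undefined
  v <- mk(1, 1)
  v$prox[51] <- v$prox[50]
  v$dist[51] <- v$dist[50]
  th <- coupling_angles(v$prox, v$dist)$theta_deg
  expect_true(is.na(th[50]))
  expect_false(anyNA(th[-50]))
})

test_that("coupling_angles validates its input", {
  expect_error(coupling_angles(1:100, 1:101), "101")
  expect_error(coupling_angles(c(1:100, NA), 1:101), "finite")
})

test_that("circular mean matches the worked two-angle cases", {
  cm <- circular_mean(c(45, 45, 45))
  expect_equal(cm$mean_deg, 45)
  expect_equal(cm$R, 1)
  expect_equal(cm$sd_deg, 0)
  cm2 <- circular_mean(c(0, 90))
  expect_equal(cm2$mean_deg, 45, tolerance = 1e-10)
  expect_equal(cm2$R, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cm2$sd_deg, sqrt(-2 * log(sqrt(2) / 2)) * 180 / pi,
               tolerance = 1e-10)
  # antipodal cancellation: undefined mean, infinite spread
  cm3 <- circular_mean(c(0, 180))
  expect_equal(cm3$R, 0)
  expect_true(is.na(cm3$mean_deg))
  expect_true(is.infinite(cm3$sd_deg))
  expect_error(circular_mean(c(NA_real_, NA_real_)), "non-missing")
})

test_that("circular mean agrees with a complex-sum oracle on random sets", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(2:50, 1)
    a <- runif(n, 0, 360)
    got <- circular_mean(a)
    want <- oracle_circular(a)
    expect_lt(abs(got$R - want$R), 1e-9)
    expect_lt(abs(pre_post_delta(want$mean_deg, got$mean_deg)), 1e-7)
  }
})

test_that("circular mean is rotation-equivariant", {
  set.seed(12)
  for (i in 1:50) {
    a <- runif(sample(3:30, 1), 0, 360)
    phi <- runif(1, -720, 720)
    base <- circular_mean(a)
    rot <- circular_mean((a + phi) %% 360)
    expect_lt(abs(pre_post_delta((base$mean_deg + phi) %% 360,
                                 rot$mean_deg)), 1e-9)
    expect_lt(abs(base$R - rot$R), 1e-9)
    expect_lt(abs(base$sd_deg - rot$sd_deg), 1e-9)
  }
})

test_that("pattern classification matches the narrated worked examples", {
  expect_equal(as.character(classify_pattern(212.7)), "in_phase_proximal")
  expect_equal(as.character(classify_pattern(235.5)), "in_phase_distal")
  expect_equal(as.character(classify_pattern(97.0)), "anti_phase_distal")
  expect_equal(as.character(classify_pattern(85.5)), "in_phase_distal")
})

test_that("the four classes partition the circle with left-closed bins", {
  a <- seq(0, 359.9, by = 0.1)
  cls <- classify_pattern(a)
  expect_false(anyNA(cls))
  expect_equal(length(cls), length(a))
  # boundary handling: left-closed, right-open
  expect_equal(as.character(classify_pattern(45)), "in_phase_distal")
  expect_equal(as.character(classify_pattern(315)), "anti_phase_proximal")
  expect_equal(as.character(classify_pattern(0)), "in_phase_proximal")
  # each bin maps to its documented class over both half-turns
  expect_equal(as.character(classify_pattern(c(20, 200))),
               rep("in_phase_proximal", 2))
  expect_equal(as.character(classify_pattern(c(70, 250))),
               rep("in_phase_distal", 2))
  expect_equal(as.character(classify_pattern(c(110, 290))),
               rep("anti_phase_distal", 2))
  expect_equal(as.character(classify_pattern(c(160, 340))),
               rep("anti_phase_proximal", 2))
})

test_that("dominance semantics: distal-X geometry puts |dprox| >= |ddist|
           exactly in 45-135 and 225-315", {
  set.seed(13)
  dp <- runif(500, -2, 2)
  dd <- runif(500, -2, 2)
  th <- (atan2(dp, dd) * 180 / pi) %% 360
  in_band <- (th >= 45 & th <= 135) | (th >= 225 & th <= 315)
  expect_equal(in_band, abs(dp) >= abs(dd))
})

test_that("subphase coordination aggregates piecewise-constant series
           correctly", {
  th <- rep(45, 100)
  sc <- subphase_coordination(tibble::tibble(step = 0:99, theta_deg = th))
  expect_equal(sc$mean_deg, rep(45, 4))
  expect_equal(sc$sd_deg, rep(0, 4))
  th2 <- rep(NA_real_, 100)
  th2[1:21] <- 10   # steps 0..20
  th2[22:41] <- 300 # steps 21..40
  th2[42:100] <- 90
  sc2 <- subphase_coordination(tibble::tibble(step = 0:99, theta_deg = th2))
  expect_equal(sc2$mean_deg[1], 10, tolerance = 1e-10)
  expect_equal(sc2$mean_deg[2], 300, tolerance = 1e-10)
  expect_equal(as.character(sc2$pattern[1]), "in_phase_proximal")
  # a fully-missing subphase is an error naming the subphase
  th3 <- rep(45, 100)
  th3[72:100] <- NA
  expect_error(
    subphase_coordination(tibble::tibble(step = 0:99, theta_deg = th3)),
    "second_half_swing")
})

test_that("subphase means recover a von Mises centre", {
  set.seed(14)
  th <- (200 + rvm_test(100, 50)) %% 360
  sc <- subphase_coordination(tibble::tibble(step = 0:99, theta_deg = th))
  # each window mean has SE ~ sd/sqrt(n_steps); bound at 3 SE per window
  w <- subphase_windows()
  n_steps <- pmin(w$end, 99) - w$start + 1
  bound <- 3 * vm_circ_sd_deg(50) / sqrt(n_steps)
  expect_true(all(abs(pre_post_delta(200, sc$mean_deg)) < bound))
})

test_that("coordination variability: identical strides give zero, two
           opposite-ish strides give the closed form", {
  same <- purrr::map_dfr(1:8, function(s) {
    tibble::tibble(stride = s, step = 0:99, theta_deg = rep(120, 100))
  })
  v <- coordination_variability(same)
  expect_lt(max(v$variability_deg), 1e-5)
  two <- purrr::map_dfr(1:2, function(s) {
    tibble::tibble(stride = s, step = 0:99,
                   theta_deg = rep(if (s == 1) 0 else 90, 100))
  })
  v2 <- coordination_variability(two)
  expect_equal(v2$variability_deg,
               rep(sqrt(-2 * log(sqrt(2) / 2)) * 180 / pi, 4),
               tolerance = 1e-8)
  # noise-free coupled pairs have zero variability
  cyc <- generate_coupled_pair(rep(75, 100), kappa = Inf, n_strides = 8,
                               seed = 1)
  v3 <- coordination_variability(stride_couplings(cyc, "prox", "dist"))
  expect_lt(max(v3$variability_deg), 1e-5)
})

test_that("stride_mean variability convention reduces to the circular SD of
           per-stride means", {
  set.seed(15)
  offs <- runif(6, -30, 30)
  coup <- purrr::map_dfr(seq_along(offs), function(s) {
    tibble::tibble(stride = s, step = 0:99,
                   theta_deg = (150 + offs[s]) %% 360)
  })
  v <- coordination_variability(coup, method = "stride_mean")
  want <- oracle_circular((150 + offs) %% 360)$sd_deg
  expect_equal(v$variability_deg, rep(want, 4), tolerance = 1e-8)
})

test_that("pre/post deltas are minimal signed circular differences", {
  expect_equal(pre_post_delta(188.6, 184.2), -4.4, tolerance = 1e-10)
  expect_equal(pre_post_delta(10, 10), 0)
  expect_equal(pre_post_delta(350, 10), 20)
  # brute-force minimal wrap over {d, d +/- 360}
  set.seed(16)
  for (i in 1:200) {
    pre <- runif(1, 0, 360)
    post <- runif(1, 0, 360)
    d <- post - pre
    cand <- c(d, d + 360, d - 360)
    want <- cand[which.min(abs(cand))]
    expect_equal(pre_post_delta(pre, post), want, tolerance = 1e-10)
  }
})

test_that("parameter recovery through the full coupling pathway", {
  # 20 strides of von Mises (kappa = 10) noise around a varying profile:
  # subphase means within 2 degrees of the profile's window means, and
  # variability within 15% of the analytic von Mises circular SD
  prof <- 150 + 60 * sin(2 * pi * (1:100) / 100)
  cyc <- generate_coupled_pair(prof, kappa = 10, n_strides = 20, seed = 11)
  m <- ensemble_mean_cycle(cyc, channels = c("prox_deg", "dist_deg"))
  sc <- subphase_coordination(coupling_angles(m$prox_deg, m$dist_deg))
  w <- subphase_windows()
  target <- vapply(seq_len(4), function(i) {
    oracle_circular(prof[(w$start[i]:min(w$end[i], 99)) + 1])$mean_deg
  }, numeric(1))
  expect_true(all(abs(pre_post_delta(target, sc$mean_deg)) < 2))
  v <- coordination_variability(stride_couplings(cyc, "prox", "dist"))
  expect_true(all(abs(v$variability_deg - vm_circ_sd_deg(10)) /
                    vm_circ_sd_deg(10) < 0.15))
})
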