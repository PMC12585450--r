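# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: circular statistics by direct complex sums,
# ANOVA sums of squares by explicit mean decompositions, and the von Mises
# circular SD in closed form.

oracle_circular <- function(angles_deg) {
  z <- mean(exp(1i * angles_deg * pi / 180))
  R <- Mod(z)
  list(
    mean_deg = (Arg(z) * 180 / pi) %% 360,
    R = R,
    sd_deg = if (R > 0) sqrt(-2 * log(R)) * 180 / pi else Inf
  )
}

# approximate von Mises deviates (degrees, centred on 0) for large kappa,
# where the distribution is close to a wrapped normal with sd 1/sqrt(kappa)
rvm_test <- function(n, kappa) {
  rnorm(n, 0, (1 / sqrt(kappa)) * 180 / pi)
}

# analytic circular SD of a von Mises distribution with concentration kappa
vm_circ_sd_deg <- function(kappa) {
  R <- besselI(kappa, 1) / besselI(kappa, 0)
  sqrt(-2 * log(R)) * 180 / pi
}

# brute-force sums-of-squares oracle for the 2x2 mixed design.
# y: n x 2 matrix (pre, post); g: factor with 2 levels.
oracle_mixed_ss <- function(y, g) {
  N <- nrow(y)
  grand <- mean(y)
  subj <- rowMeans(y)
  gm <- tapply(subj, g, mean)
  tm <- colMeans(y)
  n_g <- as.numeric(table(g))
  cell <- sapply(1:2, function(t) tapply(y[, t], g, mean)) # group x time
  ss_total <- sum((y - grand)^2)
  ss_between <- 2 * sum((subj - grand)^2)
  ss_group <- 2 * sum(n_g * (gm - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- N * sum((tm - grand)^2)
  ss_int <- 0
  for (gi in 1:2) {
    for (ti in 1:2) {
      ss_int <- ss_int +
        n_g[gi] * (cell[gi, ti] - gm[gi] - tm[ti] + grand)^2
    }
  }
  ss_err_w <- ss_total - ss_between - ss_time - ss_int
  out <- list(group = ss_group, subj = ss_subj, time = ss_time, int = ss_int,
              err_w = ss_err_w, total = ss_total,
              f_group = (ss_group / 1) / (ss_subj / (N - 2)),
              f_time = (ss_time / 1) / (ss_err_w / (N - 2)),
              f_int = (ss_int / 1) / (ss_err_w / (N - 2)))
  lapply(out, unname)
}

# random balanced 2x2 design table, n subjects per group
make_design <- function(n_per_group, effect_int = 0, sd = 1) {
  d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:(2 * n_per_group)),
                          time = c("pre", "post"))
  idx <- as.integer(sub("S", "", d$subject))
  d$group <- ifelse(idx <= n_per_group, "A", "B")
  d$value <- rnorm(nrow(d), sd = sd) +
    ifelse(d$group == "A" & d$time == "post", effect_int, 0)
  d
}
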