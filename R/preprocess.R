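# Preprocessing: zero-phase low-pass filtering, quintic gap filling, gait
# event detection from vertical GRF, stride segmentation and 101-point time
# normalization, and the four subphase windows of the running gait cycle.

# single-pass IIR filter (direct form, zero initial conditions) using the
# compiled recursions in stats::filter
iir_pass <- function(x, b, a) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter of the stated order forward and
#' backward (zero phase; events are not shifted in time). The effective
#' magnitude response is therefore the squared single-pass response. Edge
#' transients are suppressed by odd-reflection padding whose length is chosen
#' from the filter's pole radii, so constants and linear trends pass through
#' essentially unchanged over the full output.
#'
#' @param x Numeric time series (no missing values; fill gaps first).
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist rate.
#' @param order Filter order per pass (default 3).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 5, by = 1 / 120)
#' x <- sin(2 * pi * 0.5 * t) + 0.2 * sin(2 * pi * 40 * t)
#' y <- lowpass_filter(x, rate = 120, cutoff = 10)
lowpass_filter <- function(x, rate, cutoff, order = 3) {
  if (anyNA(x)) {
    stop("lowpass_filter(): input contains missing values (unfilled gap); ",
         "run fill_gaps() first", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("cutoff must lie in (0, rate/2)", call. = FALSE)
  }
  if (length(x) <= 3 * order) {
    stop("signal too short for order-", order, " filtering", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  # pad long enough that a zero-IC start-up transient decays below ~1e-13
  pr <- max(Mod(polyroot(rev(a))))
  pad <- ceiling(log(1e-13) / log(max(min(pr, 0.999), 1e-6)))
  pad <- min(max(pad, 3 * (order + 1)), length(x) - 1)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  xp <- c(front, x, back)
  y <- iir_pass(xp, b, a)
  y <- rev(iir_pass(rev(y), b, a))
  y[(pad + 1):(pad + length(x))]
}

#' Fill short interior gaps by quintic interpolation
#'
#' Replaces runs of missing values with quintic (degree-5) polynomial
#' interpolation through the three nearest valid samples on each side of the
#' gap; degree-5 trajectories are therefore recovered exactly. Gaps longer
#' than `max_gap` samples are refused rather than filled, and gaps touching
#' either end of the record cannot be interpolated and are an error.
#'
#' @param x Numeric vector with `NA` runs in its interior.
#' @param max_gap Longest fillable gap, in samples (default 10).
#' @return `x` with all gaps filled; samples that were present are unchanged.
#' @export
#' @examples
#' x <- sin(seq(0, 2, length.out = 50))
#' x[20:22] <- NA
#' fill_gaps(x)
fill_gaps <- function(x, max_gap = 10) {
  if (!anyNA(x)) return(x)
  miss <- is.na(x)
  if (miss[1] || miss[length(x)]) {
    stop("fill_gaps(): gap at the ", if (miss[1]) "start" else "end",
         " of the record cannot be interpolated", call. = FALSE)
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx_all <- which(!miss)
  out <- x
  for (k in which(r$values)) {
    gs <- starts[k]; ge <- ends[k]; glen <- ge - gs + 1
    if (glen > max_gap) {
      stop("fill_gaps(): gap of ", glen, " samples starting at index ", gs,
           " exceeds max_gap = ", max_gap, call. = FALSE)
    }
    left <- utils::tail(idx_all[idx_all < gs], 3)
    right <- utils::head(idx_all[idx_all > ge], 3)
    pts <- c(left, right)
    xc <- pts - mean(pts)                      # centre for conditioning
    deg <- min(5, length(pts) - 1)
    V <- outer(xc, 0:deg, `^`)
    coef <- solve(V, x[pts])
    xq <- (gs:ge) - mean(pts)
    out[gs:ge] <- drop(outer(xq, 0:deg, `^`) %*% coef)
  }
  out
}

#' Detect gait events from the vertical ground reaction force
#'
#' Initial contact is the first sample of each maximal run with GRF above the
#' threshold lasting at least `min_phase_s`; toe-off is the first sample after
#' such a run. Runs above or below threshold shorter than `min_phase_s` are
#' treated as noise and merged into their neighbours. A run that is already in
#' progress at the first sample has no observable contact and is discarded, as
#' is a final toe-off that falls beyond the recording.
#'
#' @param grf Numeric vertical GRF series, newtons; must be finite.
#' @param rate GRF sampling rate, Hz.
#' @param threshold Contact threshold in newtons (default 20).
#' @param min_phase_s Shortest accepted stance or swing duration, seconds
#'   (default 0.05); a debounce well below any plausible sprint stance.
#' @return A tibble with integer columns `contact` and `toe_off` (sample
#'   indices on the GRF grid), one row per detected stance.
#' @export
#' @examples
#' grf <- rep(c(rep(0, 300), rep(1000, 200)), 4)
#' detect_gait_events(grf, rate = 1000)
detect_gait_events <- function(grf, rate, threshold = 20,
                               min_phase_s = 0.05) {
  if (anyNA(grf) || any(!is.finite(grf))) {
    stop("detect_gait_events(): GRF must be finite", call. = FALSE)
  }
  min_n <- max(1L, ceiling(min_phase_s * rate))
  above <- grf > threshold

  # merge interior below-threshold blips shorter than the debounce
  r <- rle(above)
  if (length(r$lengths) > 2) {
    interior <- seq(2, length(r$lengths) - 1)
    short_gap <- interior[!r$values[interior] & r$lengths[interior] < min_n]
    if (length(short_gap)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in short_gap) above[starts[k]:ends[k]] <- TRUE
    }
  }
  # drop above-threshold spikes shorter than the debounce
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  short_run <- which(r$values & r$lengths < min_n)
  for (k in short_run) above[starts[k]:ends[k]] <- FALSE

  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  contacts <- starts[runs]
  toe_offs <- ends[runs] + 1L
  keep <- contacts > 1L & toe_offs <= length(grf)
  contacts <- contacts[keep]; toe_offs <- toe_offs[keep]
  if (length(contacts) < 2) {
    stop("insufficient strides: fewer than 2 contacts detected",
         call. = FALSE)
  }
  tibble::tibble(contact = as.integer(contacts),
                 toe_off = as.integer(toe_offs))
}

#' Subphase windows of the normalized running gait cycle
#'
#' The four analysis windows over the 101-point (0-100%) cycle: first half
#' stance 0-20%, second half stance 21-40%, first half swing 41-70%, second
#' half swing 71-100%. The windows are disjoint closed integer ranges whose
#' union covers the whole cycle.
#'
#' @return A tibble with columns `subphase` (factor), `start`, `end`.
#' @export
subphase_windows <- function() {
  tibble::tibble(
    subphase = factor(
      c("first_half_stance", "second_half_stance",
        "first_half_swing", "second_half_swing"),
      levels = c("first_half_stance", "second_half_stance",
                 "first_half_swing", "second_half_swing")
    ),
    start = c(0L, 21L, 41L, 71L),
    end = c(20L, 40L, 70L, 100L)
  )
}

#' Segment strides and time-normalize to 101 points
#'
#' Cuts the joint-angle record into contact-to-ipsilateral-contact strides
#' using GRF-grid events, snaps each event to the nearest kinematic sample,
#' and resamples every angle channel to 101 points (0-100% of the gait cycle)
#' by natural cubic spline interpolation. Strides whose toe-off does not fall
#' at 40 +/- 5% of the cycle are flagged, not dropped.
#'
#' @param angles Tibble with a `time_s` column and one or more `*_deg` angle
#'   channels on the kinematic grid.
#' @param kinematic_rate Kinematic sampling rate, Hz.
#' @param events Event tibble from [detect_gait_events()].
#' @param grf_rate GRF sampling rate, Hz (to convert event indices to times).
#' @param flag_band Acceptable toe-off position, percent of cycle
#'   (default `c(35, 45)`).
#' @return A tibble with columns `stride`, `pct` (0..100), the angle
#'   channels, `toe_off_pct` and `flagged` (both constant within a stride).
#' @export
segment_and_normalize <- function(angles, kinematic_rate, events, grf_rate,
                                  flag_band = c(35, 45)) {
  if (!"time_s" %in% names(angles)) {
    stop("angles must contain a time_s column", call. = FALSE)
  }
  chans <- setdiff(names(angles), "time_s")
  t_kin <- angles$time_s
  contact_t <- (events$contact - 1) / grf_rate
  toe_t <- (events$toe_off - 1) / grf_rate
  # nearest kinematic sample: sub-frame alignment is below kinematic
  # resolution
  snap <- function(tt) round(tt * kinematic_rate) / kinematic_rate
  contact_t <- snap(contact_t)
  tol <- 0.5 / kinematic_rate
  if (any(contact_t < min(t_kin) - tol) || any(contact_t > max(t_kin) + tol)) {
    stop("events fall outside the kinematic time span", call. = FALSE)
  }
  contact_t <- pmin(pmax(contact_t, min(t_kin)), max(t_kin))
  if (length(contact_t) < 2) {
    stop("insufficient strides: need at least 2 contacts", call. = FALSE)
  }
  funs <- lapply(chans, function(ch) {
    stats::splinefun(t_kin, angles[[ch]], method = "natural")
  })
  names(funs) <- chans
  purrr::map_dfr(seq_len(length(contact_t) - 1), function(i) {
    t0 <- contact_t[i]; t1 <- contact_t[i + 1]
    grid <- seq(t0, t1, length.out = 101)
    to_pct <- if (i <= length(toe_t)) (toe_t[i] - t0) / (t1 - t0) * 100
              else NA_real_
    out <- tibble::tibble(stride = i, pct = 0:100)
    for (ch in chans) out[[ch]] <- funs[[ch]](grid)
    out$toe_off_pct <- to_pct
    out$flagged <- is.na(to_pct) | to_pct < flag_band[1] | to_pct > flag_band[2]
    out
  })
}

#' Enforce the minimum stride count for variability estimates
#'
#' Coordination variability needs at least eight strides to stabilise; this
#' gate refuses shorter recordings.
#'
#' @param cycles Normalized-cycle tibble from [segment_and_normalize()].
#' @param minimum Minimum number of strides (default 8).
#' @return `cycles`, unchanged, if the stride count is sufficient.
#' @export
require_min_strides <- function(cycles, minimum = 8) {
  n <- dplyr::n_distinct(cycles$stride)
  if (n < minimum) {
    stop("fewer than ", minimum, " strides available (got ", n, ")",
         call. = FALSE)
  }
  cycles
}
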