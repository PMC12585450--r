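# End-to-end orchestration: preprocess -> coordination -> group statistics
# for a cohort of trials, with tidy outputs shaped like the usual reporting
# tables (group x time mean +/- SD per outcome, pair and subphase).

#' Pipeline parameters with study defaults
#'
#' All tunable preprocessing/coordination parameters with their conventional
#' defaults: 10 Hz kinematic and 50 Hz GRF low-pass cutoffs (third order,
#' zero-phase), 20 N contact threshold with a 50 ms debounce, 101-point
#' normalization, a minimum of 8 strides, and the pointwise variability
#' convention.
#'
#' @param kinematic_cutoff_hz Low-pass cutoff for angle channels, Hz.
#' @param grf_cutoff_hz Low-pass cutoff for the GRF channel, Hz.
#' @param filter_order Butterworth order per pass.
#' @param event_threshold_n Contact threshold, newtons.
#' @param min_phase_s Event debounce, seconds.
#' @param min_strides Minimum strides per trial.
#' @param max_gap Longest fillable gap, samples.
#' @param variability_method `"pointwise"` or `"stride_mean"`.
#' @param wrap_warn_deg Warn when a cell mean angle lies within this many
#'   degrees of the 0/360 wrap (the ANOVA treats angles as linear values).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(kinematic_cutoff_hz = 10,
                            grf_cutoff_hz = 50,
                            filter_order = 3,
                            event_threshold_n = 20,
                            min_phase_s = 0.05,
                            min_strides = 8,
                            max_gap = 10,
                            variability_method = "pointwise",
                            wrap_warn_deg = 20) {
  as.list(environment())
}

# preprocess one trial into normalized cycles
trial_to_cycles <- function(trial, params) {
  kin_rate <- trial$meta$config$kinematic_rate %||%
    trial$meta$kinematic_rate %||% (1 / stats::median(diff(trial$angles$time_s)))
  grf_rate <- trial$meta$config$grf_rate %||% trial$meta$grf_rate %||%
    (1 / stats::median(diff(trial$grf$time_s)))
  angles <- trial$angles
  for (ch in setdiff(names(angles), "time_s")) {
    filled <- fill_gaps(angles[[ch]], max_gap = params$max_gap)
    angles[[ch]] <- lowpass_filter(filled, rate = kin_rate,
                                   cutoff = params$kinematic_cutoff_hz,
                                   order = params$filter_order)
  }
  grf_f <- lowpass_filter(trial$grf$grf_N, rate = grf_rate,
                          cutoff = params$grf_cutoff_hz,
                          order = params$filter_order)
  events <- detect_gait_events(pmax(grf_f, 0), rate = grf_rate,
                               threshold = params$event_threshold_n,
                               min_phase_s = params$min_phase_s)
  cycles <- segment_and_normalize(angles, kin_rate, events, grf_rate)
  require_min_strides(cycles, minimum = params$min_strides)
}

#' Run the full coordination study pipeline on a cohort
#'
#' For every subject x time recording: gap-fill and low-pass the angle
#' channels, filter the GRF, detect gait events, segment and time-normalize
#' strides, then compute subphase coordination angles (from ensemble-mean
#' trajectories) and coordination variability (across per-stride coupling
#' series) for each joint pair. Each outcome x pair x subphase then enters a
#' mixed 2x2 (group x time) ANOVA. Failures are collected per subject and the
#' pipeline stops at the end if any recording could not be processed.
#'
#' @param trials A tibble with columns `subject`, `group`, `time` and a
#'   list-column `trial` of `gait_trial` objects (or directory paths readable
#'   by [read_trial()]).
#' @param pairs List of `c(prox, dist)` joint pairs (default hip-ankle and
#'   knee-ankle).
#' @param params Parameter list from [pipeline_params()].
#' @return A `coordgait_report`: list with tibbles `results` (per subject x
#'   pair x subphase), `anova` (three effects per outcome x pair x subphase),
#'   `summary` (group x time mean +/- SD tables) and a `log` list recording
#'   flagged strides, exclusions and wrap-proximity warnings.
#' @export
run_pipeline <- function(trials,
                         pairs = list(c("hip", "ankle"), c("knee", "ankle")),
                         params = pipeline_params()) {
  stopifnot(all(c("subject", "group", "time", "trial") %in% names(trials)))
  failures <- list()
  flagged <- list()
  results <- purrr::pmap_dfr(
    trials[c("subject", "group", "time", "trial")],
    function(subject, group, time, trial) {
      res <- tryCatch({
        if (is.character(trial)) trial <- read_trial(trial)
        cycles <- trial_to_cycles(trial, params)
        nflag <- cycles |>
          dplyr::distinct(.data$stride, .data$flagged) |>
          dplyr::summarise(n = sum(.data$flagged)) |>
          dplyr::pull(n)
        if (nflag > 0) {
          flagged[[length(flagged) + 1]] <<- list(
            subject = subject, time = time, n_flagged_strides = nflag)
        }
        coordination_summary(cycles, pairs = pairs,
                             variability_method = params$variability_method) |>
          dplyr::mutate(subject = subject, group = group, time = time,
                        .before = 1)
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- list(
          subject = subject, time = time, stage = "preprocess/coordination",
          message = conditionMessage(e))
        NULL
      })
      res
    })

  if (length(failures)) {
    stop("run_pipeline(): ", length(failures), " recording(s) failed: ",
         paste(vapply(failures, function(f)
           paste0(f$subject, "/", f$time, " (", f$message, ")"),
           character(1)), collapse = "; "),
         call. = FALSE)
  }

  long <- results |>
    tidyr::pivot_longer(cols = c("coord_angle_deg", "variability_deg"),
                        names_to = "outcome", values_to = "value") |>
    dplyr::mutate(outcome = dplyr::recode(.data$outcome,
                                          coord_angle_deg = "coord_angle",
                                          variability_deg = "variability"))

  wrap_warnings <- list()
  anova_tab <- long |>
    dplyr::group_by(.data$outcome, .data$pair, .data$subphase) |>
    dplyr::group_modify(function(df, key) {
      fit <- mixed_anova_2x2(df)
      if (key$outcome == "coord_angle") {
        cells <- df |>
          dplyr::group_by(.data$group, .data$time) |>
          dplyr::summarise(m = circular_mean(.data$value)$mean_deg,
                           .groups = "drop")
        near <- pmin(cells$m, 360 - cells$m) < params$wrap_warn_deg
        if (any(near, na.rm = TRUE)) {
          wrap_warnings[[length(wrap_warnings) + 1]] <<- list(
            outcome = key$outcome, pair = key$pair,
            subphase = as.character(key$subphase),
            cell_means_deg = cells$m)
        }
      }
      tidy(fit) |>
        dplyr::mutate(n_excluded = length(fit$excluded))
    }) |>
    dplyr::ungroup()

  grp_vars <- c("outcome", "pair", "subphase", "group", "time")
  summary_tab <- dplyr::bind_rows(
    long |>
      dplyr::filter(.data$outcome == "coord_angle") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
      dplyr::summarise(
        mean = circular_mean(.data$value)$mean_deg,
        # arithmetic SD of the angles after unwrapping about the circular
        # mean (matches the usual mean +/- SD presentation of angular data)
        sd = {
          ctr <- circular_mean(.data$value)$mean_deg
          sd(ctr + pre_post_delta(ctr, .data$value))
        },
        n = dplyr::n(), .groups = "drop"
      ),
    long |>
      dplyr::filter(.data$outcome == "variability") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n = dplyr::n(), .groups = "drop")
  ) |>
    dplyr::arrange(.data$outcome, .data$pair, .data$subphase, .data$group,
                   .data$time)

  if (length(wrap_warnings)) {
    warning("some coordination-angle cell means lie within ",
            params$wrap_warn_deg,
            " degrees of the 0/360 wrap; the linear ANOVA on angles may be ",
            "distorted there", call. = FALSE)
  }

  structure(
    list(results = results, anova = anova_tab, summary = summary_tab,
         log = list(params = params,
                    n_recordings = nrow(trials),
                    flagged_strides = flagged,
                    wrap_proximity = wrap_warnings,
                    failures = failures)),
    class = "coordgait_report"
  )
}

#' @export
print.coordgait_report <- function(x, ...) {
  cat("<coordgait_report> ", x$log$n_recordings, " recordings; ",
      nrow(x$results), " result rows; ", nrow(x$anova), " ANOVA rows\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Synthetic study cohort

# build hip/ankle 101-point templates whose step directions follow a
# per-window coupling profile. Increments are lightly smoothed so the
# waveforms are band-limited like real kinematics, and step magnitudes are
# minimally reweighted (directions untouched) so each template closes its
# loop: joint angles are periodic over a stride, and a non-periodic template
# would put a discontinuity at every contact that filtering smears into the
# adjacent subphases.
profile_to_templates <- function(window_centers_deg, smooth = 11,
                                 step_deg = 1) {
  w <- subphase_windows()
  prof <- numeric(100)
  for (i in seq_len(nrow(w))) {
    steps <- (w$start[i]:min(w$end[i], 99)) + 1
    prof[steps] <- window_centers_deg[i]
  }
  th <- deg2rad(prof)
  dp <- step_deg * sin(th)
  dd <- step_deg * cos(th)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    pad <- (smooth - 1) / 2
    sm <- function(v) {
      vp <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
      as.numeric(stats::filter(vp, k, sides = 2))[(pad + 1):(pad + length(v))]
    }
    dp <- sm(dp); dd <- sm(dd)
  }
  # minimal-norm positive reweighting m with sum(m * (dp, dd)) = (0, 0)
  m <- rep(1, 100)
  free <- rep(TRUE, 100)
  for (it in 1:20) {
    resid <- c(sum(m * dp), sum(m * dd))
    if (max(abs(resid)) < 1e-12) break
    Vf <- rbind(dp[free], dd[free])
    delta <- -drop(t(Vf) %*% solve(Vf %*% t(Vf), resid))
    m[free] <- m[free] + delta
    low <- m < 0.3          # keep every step's magnitude well away from zero:
    m[low] <- 0.3           # tiny steps have ill-conditioned directions
    free <- !low
  }
  dp <- dp * m
  dd <- dd * m
  list(prox = cumsum(c(0, dp)), dist = cumsum(c(0, dd)),
       true_theta_deg = wrap360(rad2deg(atan2(dp, dd))))
}

#' Simulate a two-group, pre/post running-study cohort
#'
#' Builds one synthetic trial per subject x time in a 2 (group) x 2 (time)
#' design in which the hip-ankle coupling follows prescribed per-subphase
#' directions, and only the treatment group changes — in a single subphase —
#' from pre to post. Subject-specific direction offsets (drawn once per
#' subject and centred within each group, so group-level means stay on the
#' prescription) provide between-subject variance; stride-level von Mises
#' noise provides within-trial variability. The knee follows the default
#' waveform. Ground-truth per-window coupling means for every subject x time
#' are returned alongside the trials.
#'
#' @param n_per_group Subjects per group (default 12).
#' @param n_strides Strides per trial (default 10).
#' @param kappa Stride-level von Mises concentration (default 8).
#' @param subject_sd_deg SD of the per-subject direction offset, degrees
#'   (default 8).
#' @param day_sd_deg SD of the per-recording (test-retest) direction offset,
#'   degrees (default 3); applied to all subphases of a recording at once,
#'   emulating day-to-day marker placement and calibration shifts.
#' @param centers_pre Per-subphase hip-ankle coupling directions, degrees,
#'   shared by both groups at pre.
#' @param shift_deg Pre-to-post change applied to the treatment group in
#'   `shift_subphase` (default +22.8).
#' @param shift_subphase Which subphase shifts (default second half stance).
#' @param control_centers Optional per-subphase directions for the control
#'   group (default: `centers_pre` with second half stance at 268.7).
#' @param seed Integer seed.
#' @return A list with `trials` (tibble: `subject`, `group`, `time`,
#'   list-column `trial`) and `truth` (tibble: per subject x time x subphase
#'   true hip-ankle coupling mean, degrees).
#' @export
simulate_cohort <- function(n_per_group = 12,
                            n_strides = 10,
                            kappa = 8,
                            subject_sd_deg = 8,
                            day_sd_deg = 3,
                            centers_pre = c(153.9, 212.7, 16.9, 184.1),
                            shift_deg = 22.8,
                            shift_subphase = "second_half_stance",
                            control_centers = NULL,
                            seed = 1L) {
  w <- subphase_windows()
  stopifnot(shift_subphase %in% as.character(w$subphase))
  shift_idx <- match(shift_subphase, as.character(w$subphase))
  if (is.null(control_centers)) {
    control_centers <- centers_pre
    control_centers[2] <- 268.7
  }
  withr::with_seed(as.integer(seed), {
    design <- tidyr::expand_grid(
      group = c("treatment", "control"),
      idx = seq_len(n_per_group)
    ) |>
      dplyr::mutate(subject = sprintf("%s%02d", substr(.data$group, 1, 1),
                                      .data$idx))
    offsets <- lapply(c("treatment", "control"), function(g) {
      o <- rnorm(n_per_group, 0, subject_sd_deg)
      o - mean(o)                      # centre so group means stay on target
    })
    names(offsets) <- c("treatment", "control")
    subject_seed <- sample.int(1e6, nrow(design) * 2)

    rows <- list()
    truth <- list()
    r <- 0L
    for (i in seq_len(nrow(design))) {
      g <- design$group[i]
      off <- offsets[[g]][design$idx[i]]
      for (tm in c("pre", "post")) {
        r <- r + 1L
        centers <- if (g == "treatment") centers_pre else control_centers
        if (g == "treatment" && tm == "post") {
          centers[shift_idx] <- centers[shift_idx] + shift_deg
        }
        day <- rnorm(1, 0, day_sd_deg)
        tpl <- profile_to_templates(wrap360(centers + off + day))
        wf <- default_joint_waveforms()
        wf$hip <- list(template = 20 + tpl$prox)
        wf$ankle <- list(template = tpl$dist)
        cfg <- gait_sim_config(
          n_strides = n_strides,
          joint_waveforms = wf,
          coupling_noise_kappa = kappa,
          seed = subject_seed[r]
        )
        trial <- generate_trial(cfg)
        rows[[r]] <- tibble::tibble(subject = design$subject[i], group = g,
                                    time = tm, trial = list(trial))
        truth[[r]] <- tibble::tibble(
          subject = design$subject[i], group = g, time = tm,
          subphase = w$subphase,
          true_theta_deg = vapply(seq_len(nrow(w)), function(k) {
            steps <- (w$start[k]:min(w$end[k], 99)) + 1
            circular_mean(tpl$true_theta_deg[steps])$mean_deg
          }, numeric(1))
        )
      }
    }
    list(trials = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}
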