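# Modified vector coding: coupling angles between a proximal and a distal
# joint, circular summary statistics, subphase aggregation, coordination
# pattern classification and coordination variability.

#' Ensemble mean trajectory across normalized strides
#'
#' Pointwise arithmetic mean of each angle channel across strides at each of
#' the 101 cycle points. Joint angles are treated as linear quantities here
#' (their excursions are far below 360 degrees), matching standard practice
#' for ensemble-averaged gait curves.
#'
#' @param cycles Normalized-cycle tibble from [segment_and_normalize()] (or
#'   any tibble with `stride`, `pct` and angle columns).
#' @param channels Optional character vector of channel columns to average;
#'   defaults to every `*_deg` column except bookkeeping columns.
#' @return A tibble with `pct` (0..100) and the averaged channels.
#' @export
ensemble_mean_cycle <- function(cycles, channels = NULL) {
  if (nrow(cycles) == 0L) {
    stop("ensemble_mean_cycle(): no cycles supplied", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- setdiff(grep("_deg$", names(cycles), value = TRUE),
                        c("toe_off_pct"))
  }
  cycles |>
    dplyr::group_by(.data$pct) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(channels), mean),
                     .groups = "drop")
}

#' Coupling angles of a joint pair by modified vector coding
#'
#' For each inter-point step of a 101-point cycle, the coupling angle is the
#' orientation, relative to the right horizontal of the angle-angle plot
#' (distal joint on X, proximal joint on Y), of the vector joining two
#' consecutive points: the two-argument arctangent of
#' (delta proximal, delta distal), wrapped to `[0, 360)`. The two-argument
#' form is the quadrant-preserving realization of the one-argument
#' arctangent-plus-modulo formula usually printed for this method, which by
#' itself cannot reach all four quadrants. Steps where neither joint moves
#' have no defined direction and are returned as missing.
#'
#' @param prox,dist Numeric vectors of 101 angle values (degrees) for the
#'   proximal (hip or knee) and distal (ankle) joint.
#' @return A tibble with `step` (0..99) and `theta_deg` on `[0, 360)`
#'   (`NA` where both increments are zero).
#' @export
#' @examples
#' coupling_angles(seq(0, 100, length.out = 101),
#'                 seq(0, 100, length.out = 101))$theta_deg[1] # 45
coupling_angles <- function(prox, dist) {
  if (length(prox) != 101L || length(dist) != 101L) {
    stop("coupling_angles(): trajectories must have exactly 101 points",
         call. = FALSE)
  }
  if (anyNA(prox) || anyNA(dist) || any(!is.finite(c(prox, dist)))) {
    stop("coupling_angles(): trajectories must be finite", call. = FALSE)
  }
  dp <- diff(prox)
  dd <- diff(dist)
  theta <- wrap360(rad2deg(atan2(dp, dd)))
  theta[dp == 0 & dd == 0] <- NA_real_
  tibble::tibble(step = 0:99, theta_deg = theta)
}

#' Per-stride coupling angle series for a joint pair
#'
#' Convenience wrapper applying [coupling_angles()] to every stride of a
#' normalized-cycle tibble.
#'
#' @param cycles Normalized-cycle tibble (`stride`, `pct`, angle columns).
#' @param prox,dist Column names (or joint names; `"hip"` resolves to
#'   `"hip_deg"`) of the proximal and distal channel.
#' @return A tibble with `stride`, `step` (0..99) and `theta_deg`.
#' @export
stride_couplings <- function(cycles, prox, dist) {
  resolve <- function(nm) {
    if (nm %in% names(cycles)) nm
    else if (paste0(nm, "_deg") %in% names(cycles)) paste0(nm, "_deg")
    else stop("channel '", nm, "' not found in cycles", call. = FALSE)
  }
  pcol <- resolve(prox); dcol <- resolve(dist)
  cycles |>
    dplyr::arrange(.data$stride, .data$pct) |>
    dplyr::group_by(.data$stride) |>
    dplyr::group_modify(function(df, key) {
      coupling_angles(df[[pcol]], df[[dcol]])
    }) |>
    dplyr::ungroup()
}

#' Classify a coupling angle into a coordination pattern
#'
#' Maps angles to the four coordination patterns of the standard polar
#' classification for a proximal-distal joint pair: in-phase proximal
#' dominancy (0-45 or 180-225), in-phase distal (ankle) dominancy (45-90 or
#' 225-270), anti-phase distal dominancy (90-135 or 270-315) and anti-phase
#' proximal dominancy (135-180 or 315-360). Bins are left-closed and
#' right-open; input is wrapped to `[0, 360)` first.
#'
#' @param angle_deg Numeric vector of coupling angles in degrees.
#' @return A factor with levels `in_phase_proximal`, `in_phase_distal`,
#'   `anti_phase_distal`, `anti_phase_proximal`.
#' @export
#' @examples
#' classify_pattern(c(212.7, 235.5, 97.0, 85.5))
classify_pattern <- function(angle_deg) {
  lv <- c("in_phase_proximal", "in_phase_distal",
          "anti_phase_distal", "anti_phase_proximal")
  idx <- floor(wrap360(angle_deg) / 45) %% 4
  factor(lv[idx + 1], levels = lv)
}

#' Circular summaries of the coupling series per subphase
#'
#' Computes the circular mean, mean resultant length and circular SD of the
#' coupling angles whose step index falls inside each subphase window (step
#' `t`, joining cycle points `t` and `t + 1`, is assigned to the window
#' containing point `t`), plus the coordination-pattern class of the subphase
#' mean. Missing steps are excluded; a subphase with no defined steps is an
#' error.
#'
#' @param coupling Coupling tibble from [coupling_angles()] (columns `step`,
#'   `theta_deg`), typically computed from the ensemble-mean trajectories.
#' @param windows Subphase windows (default [subphase_windows()]).
#' @return A tibble with one row per subphase: `subphase`, `mean_deg`, `R`,
#'   `sd_deg`, `n`, `pattern`.
#' @export
subphase_coordination <- function(coupling, windows = subphase_windows()) {
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    th <- coupling$theta_deg[coupling$step >= windows$start[i] &
                               coupling$step <= windows$end[i]]
    if (all(is.na(th))) {
      stop("all coupling angles missing in subphase '",
           as.character(windows$subphase[i]), "'", call. = FALSE)
    }
    cm <- circular_mean(th)
    dplyr::bind_cols(tibble::tibble(subphase = windows$subphase[i]), cm) |>
      dplyr::mutate(pattern = classify_pattern(.data$mean_deg))
  })
}

#' Stride-to-stride coordination variability per subphase
#'
#' The default (`"pointwise"`) convention computes, at every cycle step, the
#' circular standard deviation of the coupling angle across strides (via the
#' mean resultant length over strides), and reports each subphase's
#' variability as the arithmetic mean of those per-step SDs inside the
#' window. The alternative (`"stride_mean"`) convention first takes each
#' stride's circular mean over the window and then the circular SD of those
#' per-stride means across strides. Steps missing in some strides use the
#' remaining strides; steps missing in all strides are skipped, and a window
#' with no usable step is an error.
#'
#' @param couplings Per-stride coupling tibble from [stride_couplings()]
#'   (columns `stride`, `step`, `theta_deg`).
#' @param windows Subphase windows (default [subphase_windows()]).
#' @param method `"pointwise"` (default) or `"stride_mean"`; see Details.
#' @return A tibble with `subphase`, `variability_deg` and `n_strides`.
#' @export
coordination_variability <- function(couplings,
                                     windows = subphase_windows(),
                                     method = c("pointwise", "stride_mean")) {
  method <- match.arg(method)
  n_strides <- dplyr::n_distinct(couplings$stride)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    win <- couplings[couplings$step >= windows$start[i] &
                       couplings$step <= windows$end[i], ]
    if (all(is.na(win$theta_deg))) {
      stop("no usable coupling angles in subphase '",
           as.character(windows$subphase[i]), "'", call. = FALSE)
    }
    v <- if (method == "pointwise") {
      per_step <- win |>
        dplyr::group_by(.data$step) |>
        dplyr::summarise(
          n_ok = sum(!is.na(.data$theta_deg)),
          sd_deg = if (sum(!is.na(.data$theta_deg)) > 0)
            circ_sd_deg(.data$theta_deg) else NA_real_,
          .groups = "drop"
        ) |>
        dplyr::filter(.data$n_ok > 0)
      mean(per_step$sd_deg)
    } else {
      means <- win |>
        dplyr::group_by(.data$stride) |>
        dplyr::summarise(m = circular_mean(.data$theta_deg)$mean_deg,
                         .groups = "drop")
      circ_sd_deg(means$m)
    }
    tibble::tibble(subphase = windows$subphase[i], variability_deg = v,
                   n_strides = n_strides)
  })
}

#' Per-trial coordination summary for one or more joint pairs
#'
#' The full coordination stage for one recording: subphase coordination
#' angles come from the coupling series of the ensemble-mean joint
#' trajectories, while coordination variability comes from the per-stride
#' coupling series — two separate pathways, as is conventional for modified
#' vector coding.
#'
#' @param cycles Normalized-cycle tibble from [segment_and_normalize()].
#' @param pairs List of `c(prox, dist)` joint-name pairs (default hip-ankle
#'   and knee-ankle).
#' @param windows Subphase windows (default [subphase_windows()]).
#' @param variability_method Passed to [coordination_variability()].
#' @return Tidy tibble with one row per pair x subphase: `pair`, `subphase`,
#'   `coord_angle_deg`, `R`, `variability_deg`, `pattern`, `n_strides`.
#' @export
coordination_summary <- function(cycles,
                                 pairs = list(c("hip", "ankle"),
                                              c("knee", "ankle")),
                                 windows = subphase_windows(),
                                 variability_method = "pointwise") {
  purrr::map_dfr(pairs, function(pr) {
    mean_cycle <- ensemble_mean_cycle(cycles)
    resolve <- function(nm) if (nm %in% names(mean_cycle)) nm
                            else paste0(nm, "_deg")
    coup_mean <- coupling_angles(mean_cycle[[resolve(pr[1])]],
                                 mean_cycle[[resolve(pr[2])]])
    coord <- subphase_coordination(coup_mean, windows)
    vari <- coordination_variability(stride_couplings(cycles, pr[1], pr[2]),
                                     windows, method = variability_method)
    dplyr::left_join(coord, vari, by = "subphase") |>
      dplyr::transmute(
        pair = paste0(pr[1], "-", pr[2]),
        subphase = .data$subphase,
        coord_angle_deg = .data$mean_deg,
        R = .data$R,
        variability_deg = .data$variability_deg,
        pattern = .data$pattern,
        n_strides = .data$n_strides
      )
  })
}
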