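# ggplot2 figures: angle-angle plots (distal on X, proximal on Y, with
# contact and toe-off markers), the polar classification plot, and autoplot
# methods for fitted objects.

#' Angle-angle plot for a joint pair
#'
#' Plots the ensemble-mean trajectory of the proximal joint (Y) against the
#' distal joint (X) over the normalized gait cycle, optionally overlaying a
#' second (e.g. post-training) condition. Initial contact (0% of the cycle)
#' is marked with a filled circle and nominal toe-off (40%) with a filled
#' square.
#'
#' @param cycles Normalized-cycle tibble (one condition).
#' @param prox,dist Joint/channel names (e.g. `"hip"`, `"ankle"`).
#' @param cycles2 Optional second condition to overlay.
#' @param labels Length-2 labels for the conditions (default `"pre"`,
#'   `"post"`).
#' @return A ggplot object.
#' @export
plot_angle_angle <- function(cycles, prox, dist, cycles2 = NULL,
                             labels = c("pre", "post")) {
  resolve <- function(df, nm) if (nm %in% names(df)) nm else paste0(nm, "_deg")
  one <- function(cy, lab) {
    m <- ensemble_mean_cycle(cy)
    tibble::tibble(pct = m$pct,
                   dist = m[[resolve(m, dist)]],
                   prox = m[[resolve(m, prox)]],
                   condition = lab)
  }
  df <- one(cycles, labels[1])
  if (!is.null(cycles2)) df <- dplyr::bind_rows(df, one(cycles2, labels[2]))
  df$condition <- factor(df$condition, levels = labels)
  marks <- df[df$pct %in% c(0, 40), ]
  marks$event <- ifelse(marks$pct == 0, "initial contact", "toe-off")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist, y = .data$prox,
                                   colour = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(shape = .data$event), size = 3) +
    ggplot2::scale_shape_manual(values = c("initial contact" = 16,
                                           "toe-off" = 15)) +
    ggplot2::labs(x = paste(dist, "angle (deg)"),
                  y = paste(prox, "angle (deg)"),
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Polar plot of subphase coordination against the pattern bins
#'
#' Draws the four coordination-pattern bins (each appearing in two opposite
#' 45-degree sectors) on a polar axis and overlays the subphase mean coupling
#' angles with segment length equal to the mean resultant length R.
#'
#' @param subphase_summary Output of [subphase_coordination()] (columns
#'   `subphase`, `mean_deg`, `R`).
#' @return A ggplot object.
#' @export
plot_coupling_polar <- function(subphase_summary) {
  lv <- c("in_phase_proximal", "in_phase_distal",
          "anti_phase_distal", "anti_phase_proximal")
  bins <- tibble::tibble(
    start = seq(0, 315, by = 45),
    end = seq(45, 360, by = 45),
    pattern = factor(lv[(0:7 %% 4) + 1], levels = lv)
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bins,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
                   fill = .data$pattern),
      alpha = 0.25
    ) +
    ggplot2::geom_segment(
      data = subphase_summary,
      ggplot2::aes(x = .data$mean_deg, xend = .data$mean_deg, y = 0,
                   yend = .data$R, colour = .data$subphase),
      linewidth = 1
    ) +
    ggplot2::coord_polar(theta = "x", direction = -1, start = pi / 2) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "coupling angle (deg)", y = "mean resultant length R",
                  fill = "pattern", colour = "subphase") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_angle_angle autoplot method for a single trial: joint
#'   angles and GRF over time.
#' @param object A `gait_trial`.
#' @param ... Unused.
#' @method autoplot gait_trial
#' @export
autoplot.gait_trial <- function(object, ...) {
  ang <- object$angles |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  grf <- object$grf |>
    dplyr::mutate(channel = "grf_N") |>
    dplyr::rename(value = "grf_N")
  df <- dplyr::bind_rows(ang, grf[c("time_s", "channel", "value")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.coord_anova autoplot method: partial eta-squared per
#'   effect with its confidence interval; dashed lines mark the small,
#'   medium and large thresholds.
#' @param object A `coord_anova` object.
#' @param ... Unused.
#' @method autoplot coord_anova
#' @export
autoplot.coord_anova <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$eta_p2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::geom_hline(yintercept = c(0.01, 0.06, 0.14),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "partial eta-squared") +
    ggplot2::theme_minimal()
}
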