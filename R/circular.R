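# Circular statistics for coupling angles. Angles are degrees on [0, 360)
# everywhere in the user-facing API; radians appear only inside these helpers.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the interval [0, 360)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector with every finite value wrapped to `[0, 360)`.
#' @export
#' @examples
#' wrap360(c(-90, 370, 360))
wrap360 <- function(x) {
  out <- x %% 360
  # guard against 360 - eps rounding back up to exactly 360
  out[out == 360] <- 0
  out
}

#' Circular mean, mean resultant length and circular standard deviation
#'
#' Summarises a set of angles by the direction and modulus of their mean unit
#' vector. The mean resultant length R is 1 for perfectly concentrated angles
#' and 0 for uniformly dispersed (or antipodally cancelling) ones. The
#' circular standard deviation is `sqrt(-2 log R)` converted to degrees; it is
#' the coordination-variability measure used throughout this package.
#'
#' When R is numerically zero (antipodal cancellation) the mean direction is
#' undefined: `mean_deg` is `NA` and `sd_deg` is `Inf`.
#'
#' @param angles_deg Numeric vector of angles in degrees; `NA`s are dropped.
#' @return A one-row tibble with columns `mean_deg` (circular mean on
#'   `[0, 360)`), `R` (mean resultant length in `[0, 1]`), `sd_deg`
#'   (circular standard deviation, degrees) and `n` (number of angles used).
#' @export
#' @examples
#' circular_mean(c(0, 90)) # mean 45, R = sqrt(2)/2, sd ~ 47.7 deg
circular_mean <- function(angles_deg) {
  a <- angles_deg[!is.na(angles_deg)]
  if (length(a) == 0L) {
    stop("circular_mean(): no non-missing angles", call. = FALSE)
  }
  th <- deg2rad(a)
  C <- mean(cos(th))
  S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    return(tibble::tibble(mean_deg = NA_real_, R = 0, sd_deg = Inf,
                          n = length(a)))
  }
  R <- min(R, 1)
  tibble::tibble(
    mean_deg = wrap360(rad2deg(atan2(S, C))),
    R = R,
    sd_deg = sqrt(-2 * log(R)) * 180 / pi,
    n = length(a)
  )
}

# circular SD alone (degrees) from a vector of angles; NA-dropping as above
circ_sd_deg <- function(angles_deg) circular_mean(angles_deg)$sd_deg

#' Signed minimal circular difference between two angles
#'
#' Computes the pre-to-post change `post - pre` as the minimal signed circular
#' difference in `(-180, 180]` degrees. For changes well inside one revolution
#' this coincides with plain subtraction; across the 0/360 wrap it takes the
#' short way around.
#'
#' @param pre_deg,post_deg Numeric vectors of angles in degrees on `[0, 360)`.
#' @return Numeric vector of signed changes in degrees, in `(-180, 180]`.
#' @export
#' @examples
#' pre_post_delta(188.6, 184.2) # -4.4: a 4.4 degree decrease
#' pre_post_delta(350, 10)      # +20 across the wrap
pre_post_delta <- function(pre_deg, post_deg) {
  d <- (post_deg - pre_deg) %% 360
  ifelse(d > 180, d - 360, d)
}
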