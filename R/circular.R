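# Circular summary statistics. A phase p in [0, 24) maps to the angle
# theta = p * 2*pi / 24; summaries are computed on the unit-vector resultant.

#' Circular mean phase
#'
#' Angle of the mean resultant vector of the phase angles, mapped back to
#' hours on `[0, period_hours)`. When the resultant length is numerically zero
#' (perfectly balanced phases) the mean direction is undefined and `NA` is
#' returned with a warning.
#'
#' @param phases Peak times in hours on `[0, period_hours)`; at least one.
#' @param period_hours Period of the circle (default 24).
#' @return Mean phase in hours, or `NA` if undefined.
#' @examples
#' circular_mean_phase(c(23, 1)) # 0
#' circular_mean_phase(c(0, 6)) # 3
#' @export
circular_mean_phase <- function(phases, period_hours = 24) {
  check_phases(phases, period_hours, n_min = 1)
  theta <- phases * 2 * pi / period_hours
  C <- mean(cos(theta))
  S <- mean(sin(theta))
  if (sqrt(C^2 + S^2) < 1e-8) {
    warning("mean resultant length ~ 0: circular mean undefined",
            call. = FALSE)
    return(NA_real_)
  }
  m <- (atan2(S, C) %% (2 * pi)) * period_hours / (2 * pi)
  if (period_hours - m < 1e-9) m <- 0 # keep the result inside [0, period)
  m
}

#' Rayleigh test of phase coherency
#'
#' Tests the null of uniformly distributed phase angles against a unimodal
#' concentration, using the mean resultant length. The p-value uses the
#' standard series approximation of the Rayleigh statistic's null tail,
#' clamped into `(0, 1]`.
#'
#' @inheritParams circular_mean_phase
#' @return A one-row tibble: `n`, `r_bar` (mean resultant length),
#'   `statistic` (`n * r_bar^2`) and `p_value`.
#' @examples
#' rayleigh_test(rep(3, 10))$p_value # ~ exp(-10)
#' rayleigh_test(c(0, 12))$p_value # 1: antipodal, no coherency
#' @export
rayleigh_test <- function(phases, period_hours = 24) {
  check_phases(phases, period_hours, n_min = 2)
  n <- length(phases)
  theta <- phases * 2 * pi / period_hours
  r_bar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  Z <- n * r_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  tibble::tibble(n = n, r_bar = r_bar, statistic = Z, p_value = p)
}

check_phases <- function(phases, period_hours, n_min) {
  if (length(phases) < n_min) {
    stop("need at least ", n_min, " phase(s)", call. = FALSE)
  }
  if (!all(is.finite(phases))) {
    stop("phases must be finite", call. = FALSE)
  }
  if (any(phases < 0 | phases >= period_hours)) {
    stop("phases must lie in [0, ", period_hours, ")", call. = FALSE)
  }
  invisible(phases)
}
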