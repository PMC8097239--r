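# Stationary renewal theory linking closed and open birth intervals.
#
# In a stationary renewal process with inter-event (closed-interval)
# survivor function S and mean mu, the backward recurrence time -- the open
# interval observed at a random inspection time -- has density
# f_B(t) = S(t)/mu. The inverse reads the closed interval off an observed
# open-interval density: mu = 1/f_B(0) and S(t) = mu * f_B(t).
#
# Distributions live on a uniform monthly grid t = 0, dt, ..., T with
# T <= 360 months (the data's CMC resolution); integrals use the trapezoid
# rule, for which the grid-point density convention is exact to O(dt^2).

.trapz <- function(y, dt) dt * (sum(y) - (y[1] + y[length(y)]) / 2)

.cumtrapz <- function(y, dt) {
  c(0, cumsum(dt * (y[-length(y)] + y[-1]) / 2))
}

#' Construct a duration distribution on a monthly grid
#'
#' Represents a closed- or open-interval distribution by its density and
#' survivor function on a uniform grid of time points `0, dt, .., t_max`
#' months. Supply either `pdf` (grid-point density values, renormalised to
#' integrate to 1) or `survivor` (from which the density is obtained by
#' central differencing -- this form also accommodates distributions with
#' jumps, such as a degenerate interval). The mean is the trapezoid integral
#' of the survivor function.
#'
#' @param grid numeric vector of equally spaced time points starting at 0,
#'   in months; maximum 360.
#' @param pdf density values at the grid points (>= 0).
#' @param survivor survivor-function values at the grid points (S(0) = 1,
#'   non-increasing).
#' @return a `duration_distribution`: list with `grid`, `pdf`, `survivor`,
#'   `mean_months`, `dt`.
#' @export
duration_distribution <- function(grid, pdf = NULL, survivor = NULL) {
  stopifnot(is.numeric(grid), length(grid) >= 3)
  dt <- grid[2] - grid[1]
  if (grid[1] != 0 || any(abs(diff(grid) - dt) > 1e-9)) {
    stop("grid must be uniform and start at 0")
  }
  if (max(grid) > 360) stop("grid capped at 360 months")
  if (is.null(pdf) == is.null(survivor)) {
    stop("supply exactly one of pdf or survivor")
  }
  if (is.null(pdf)) {
    s <- survivor
    if (length(s) != length(grid) || abs(s[1] - 1) > 1e-9 ||
        any(diff(s) > 1e-9) || any(s < -1e-9)) {
      stop("survivor must start at 1 and be non-increasing")
    }
    s <- pmax(s, 0)
    # density by central differences of -S; one-sided at the ends
    n <- length(s)
    pdf <- numeric(n)
    pdf[1] <- (s[1] - s[2]) / dt
    pdf[n] <- (s[n - 1] - s[n]) / dt
    pdf[2:(n - 1)] <- (s[1:(n - 2)] - s[3:n]) / (2 * dt)
    pdf <- pmax(pdf, 0)
  } else {
    if (length(pdf) != length(grid) || any(!is.finite(pdf)) || any(pdf < 0)) {
      stop("pdf must be non-negative and finite on the grid")
    }
    total <- .trapz(pdf, dt)
    if (total <= 0) stop("pdf integrates to zero")
    pdf <- pdf / total
    s <- pmax(0, pmin(1, 1 - .cumtrapz(pdf, dt)))
  }
  mu <- .trapz(s, dt)
  if (mu <= 0) stop("domain error: mean duration must be positive")
  structure(list(grid = grid, pdf = pdf, survivor = s,
                 mean_months = mu, dt = dt),
            class = "duration_distribution")
}

#' @export
print.duration_distribution <- function(x, ...) {
  cat("Duration distribution on [0,", max(x$grid), "] months (dt =", x$dt,
      ")\n  mean:", signif(x$mean_months, 5), "months\n")
  invisible(x)
}

# convenience constructors for the standard analytic test distributions
#' Analytic duration distributions on the monthly grid
#'
#' Convenience constructors for exponential, uniform, degenerate, and gamma
#' closed-interval distributions, evaluated on a uniform grid.
#'
#' @param mean_months mean duration in months.
#' @param max_months upper end of a uniform duration; `at_months` the
#'   location of a degenerate one; `shape` the gamma shape.
#' @param t_max grid end (months, <= 360); `dt` grid step.
#' @return a `duration_distribution`.
#' @name analytic_durations
NULL

#' @rdname analytic_durations
#' @export
ddist_exponential <- function(mean_months, t_max = 360, dt = 1) {
  grid <- seq(0, t_max, by = dt)
  duration_distribution(grid, pdf = stats::dexp(grid, rate = 1 / mean_months))
}

#' @rdname analytic_durations
#' @export
ddist_uniform <- function(max_months, t_max = 360, dt = 1) {
  grid <- seq(0, t_max, by = dt)
  duration_distribution(grid,
                        survivor = pmax(0, pmin(1, 1 - grid / max_months)))
}

#' @rdname analytic_durations
#' @export
ddist_degenerate <- function(at_months, t_max = 360, dt = 1) {
  grid <- seq(0, t_max, by = dt)
  duration_distribution(grid, survivor = as.numeric(grid < at_months))
}

#' @rdname analytic_durations
#' @export
ddist_gamma <- function(shape, mean_months, t_max = 360, dt = 1) {
  grid <- seq(0, t_max, by = dt)
  duration_distribution(grid,
                        pdf = stats::dgamma(grid, shape = shape,
                                            rate = shape / mean_months))
}

#' Backward recurrence (open-interval) distribution from a closed one
#'
#' Applies the stationary identity `f_B(t) = S(t)/mu`: the open-interval
#' density at duration t is the closed-interval survivor function there,
#' scaled by the mean closed interval. At t = 0 this gives `f_B(0) = 1/mu`,
#' and the mean of the backward recurrence time is `E[X^2]/(2 mu)`.
#'
#' @param closed a `duration_distribution` for the closed interval.
#' @return a `duration_distribution` for the backward recurrence time, on
#'   the same grid.
#' @export
backward_recurrence_from_closed <- function(closed) {
  stopifnot(inherits(closed, "duration_distribution"))
  if (closed$mean_months <= 0) stop("domain error: mean must be positive")
  duration_distribution(closed$grid,
                        pdf = closed$survivor / closed$mean_months)
}

#' Closed-interval distribution estimated from an open one
#'
#' Inverts the stationary identity: the mean closed interval is estimated as
#' `1/f_B(0)` and the closed survivor function as `mu * f_B(t)`, with the
#' density recovered by central differencing. Valid only under the
#' stationarity assumption; an increasing open-interval density contradicts
#' it and raises an error. A round trip through
#' [backward_recurrence_from_closed()] recovers the input within grid
#' tolerance.
#'
#' @param open_pdf a `duration_distribution` for the open interval (backward
#'   recurrence time); its density must be positive at 0 and non-increasing.
#' @return a `duration_distribution` for the closed interval.
#' @export
closed_from_open <- function(open_pdf) {
  stopifnot(inherits(open_pdf, "duration_distribution"))
  f0 <- open_pdf$pdf[1]
  if (f0 <= 0) stop("domain error: open-interval density at 0 must be > 0")
  if (any(diff(open_pdf$pdf) > 1e-9 * max(open_pdf$pdf))) {
    stop("open-interval density is increasing, which violates the ",
         "stationarity assumption; no closed-interval estimate is possible")
  }
  mu_hat <- 1 / f0
  s_hat <- pmin(1, mu_hat * open_pdf$pdf)
  s_hat <- cummin(s_hat) # enforce monotonicity against rounding
  duration_distribution(open_pdf$grid, survivor = s_hat)
}

# Kolmogorov-Smirnov distance between a sample and a piecewise-linear CDF
# given on a grid.
.ks_distance <- function(sample, grid, cdf) {
  f <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
  s <- sort(sample)
  n <- length(s)
  fs <- f(s)
  max(abs(seq_len(n) / n - fs), abs((seq_len(n) - 1) / n - fs))
}

#' Check the renewal identity against the event-driven simulator
#'
#' Draws backward recurrence times from [sample_stationary_renewal()] and
#' compares their empirical distribution with the analytic prediction
#' `f_B(t) = S(t)/mu` by the Kolmogorov-Smirnov distance. If no analytic
#' closed-interval distribution is supplied, one is estimated from a large
#' pilot sample of the same sampler (binned to the monthly grid).
#'
#' @param closed_sampler function of `n` returning closed-interval draws in
#'   months.
#' @param n number of simulated backward recurrence times.
#' @param seed integer seed.
#' @param closed optional analytic `duration_distribution` of the closed
#'   interval; estimated from a pilot sample when `NULL`.
#' @param burn_in_events renewal burn-in (see [sample_stationary_renewal()]).
#' @param t_max,dt grid used when estimating the closed distribution.
#' @return a `renewal_validation` list: `n`, `ks_distance`, `mean_backward`
#'   (simulated), `predicted_mean` (from the identity `E[X^2]/(2 mu)` via
#'   the predicted density), and `mu_closed`.
#' @export
validate_against_simulation <- function(closed_sampler, n, seed = 1L,
                                        closed = NULL,
                                        burn_in_events = 200L,
                                        t_max = 360, dt = 1) {
  if (is.null(closed)) {
    set.seed(seed + 1L)
    pilot <- closed_sampler(100000L)
    if (any(!is.finite(pilot)) || any(pilot <= 0)) {
      stop("domain error: sampler must return positive finite durations")
    }
    grid <- seq(0, t_max, by = dt)
    dens <- stats::density(pilot, from = 0, to = t_max, n = length(grid))
    closed <- duration_distribution(grid, pdf = pmax(dens$y, 0))
  }
  pred <- backward_recurrence_from_closed(closed)
  sim <- sample_stationary_renewal(closed_sampler, n = n,
                                   burn_in_events = burn_in_events,
                                   seed = seed)
  cdf <- .cumtrapz(pred$pdf, pred$dt)
  ks <- .ks_distance(sim$backward, pred$grid, pmin(cdf, 1))
  structure(list(n = n,
                 ks_distance = ks,
                 mean_backward = mean(sim$backward),
                 predicted_mean = pred$mean_months,
                 mu_closed = closed$mean_months),
            class = "renewal_validation")
}

#' @export
print.renewal_validation <- function(x, ...) {
  cat("Renewal identity check: n =", x$n,
      "\n  KS distance (simulated vs S(t)/mu):", signif(x$ks_distance, 3),
      "\n  mean backward recurrence: simulated", signif(x$mean_backward, 4),
      "vs predicted", signif(x$predicted_mean, 4), "months\n")
  invisible(x)
}

#' Cast a binned open-interval distribution to a monthly duration density
#'
#' Interprets the 20 yearly percentages of an
#' [tabulate_distribution()] result as a piecewise-constant density on a
#' monthly grid over 0..240 months. This is only meaningful if the surveyed
#' population is stationary, which real populations generally are not, so
#' the cast must be requested explicitly.
#'
#' @param dist an `open_interval_distribution`.
#' @param assume_stationary must be set to `TRUE` to acknowledge the
#'   stationarity assumption.
#' @return a `duration_distribution` on 0..240 months.
#' @export
as_duration_distribution <- function(dist, assume_stationary = FALSE) {
  stopifnot(inherits(dist, "open_interval_distribution"))
  if (!isTRUE(assume_stationary)) {
    stop("casting an observed open-interval distribution to a duration ",
         "density is only valid for a stationary population; set ",
         "assume_stationary = TRUE to proceed")
  }
  grid <- seq(0, 240, by = 1)
  # yearly mass spread uniformly over the 12 months of its interval year
  monthly <- rep(dist$percentages / 100 / 12, each = 12)
  pdf <- c(monthly, 0)[seq_along(grid)]
  duration_distribution(grid, pdf = pdf)
}
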