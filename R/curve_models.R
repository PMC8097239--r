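# Fitting the two-parameter power curve y = a * x^(-b) and three comparator
# families to a 20-bin open-interval distribution. Parameters follow the
# spreadsheet-trendline convention: transformable families (power,
# exponential) are fitted by ordinary least squares in log space, the others
# by OLS on the original scale. Fit quality is reported both in the fitting
# space (r2_transformed) and, comparably across families, as
# 1 - SS_res/SS_tot on the proportion scale (r2_original).

.as_proportions <- function(dist) {
  if (inherits(dist, "open_interval_distribution")) {
    dist$percentages / 100
  } else if (is.numeric(dist) && length(dist) == 20) {
    if (any(dist < 0) || !all(is.finite(dist))) {
      stop("distribution values must be finite and non-negative")
    }
    # numeric input is taken on its own scale: the slope is scale-invariant
    # and the level scales with y (a_percent = 100 * a_proportion)
    dist
  } else {
    stop("expected an open_interval_distribution or 20 numeric values")
  }
}

# log-space OLS helper; perfect fits are expected on noiseless inputs, so
# summary.lm's reliability warning is suppressed
.lm_r2 <- function(fit) suppressWarnings(summary(fit)$r.squared)

.r2_original <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

new_curve_fit <- function(family, params, fitted, y, r2_transformed = NA_real_,
                          n_dropped = 0L) {
  structure(list(family = family,
                 params = params,
                 fitted = fitted,
                 r2_original = .r2_original(y, fitted),
                 r2_transformed = r2_transformed,
                 n_dropped_zero_bins = as.integer(n_dropped)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("Curve fit:", x$family, "\n  params:",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      "\n  R2 (original scale):", signif(x$r2_original, 4), "\n")
  invisible(x)
}

#' Fit the power curve to an open-interval distribution
#'
#' Fits `y = a * x^(-b)` over interval years `x = 1..20` by ordinary least
#' squares on `(ln x, ln y)`, the log-log trendline convention: `a` is the
#' exponential of the intercept and `b` the negated slope, stored as a
#' positive magnitude. The level `a` is in proportion units (multiply by 100
#' for the percentage scale; `b` is scale-invariant). Zero bins are dropped
#' from the log fit and counted in `n_dropped_zero_bins`; fitted values and
#' `r2_original` are evaluated over all 20 bins on the proportion scale.
#'
#' @param dist an `open_interval_distribution` (fitted on the proportion
#'   scale), or a numeric vector of 20 bin values taken on their own scale.
#' @return a `curve_fit` with `params["a"]` and `params["b"]`.
#' @export
fit_power <- function(dist) {
  y <- .as_proportions(dist)
  x <- 1:20
  pos <- y > 0
  if (sum(pos) < 3) {
    stop("insufficient-data error: need >= 3 positive bins for a power fit")
  }
  fit <- stats::lm(log(y[pos]) ~ log(x[pos]))
  a <- exp(unname(stats::coef(fit)[1]))
  b <- -unname(stats::coef(fit)[2])
  new_curve_fit("power", c(a = a, b = b), fitted = a * x^(-b), y = y,
                r2_transformed = .lm_r2(fit),
                n_dropped = sum(!pos))
}

#' Fit the exponential comparator
#'
#' Fits `y = a * exp(c x)` by OLS on `(x, ln y)`; zero bins are dropped from
#' the log fit as in [fit_power()].
#'
#' @inheritParams fit_power
#' @return a `curve_fit` with `params["a"]` and `params["c"]`.
#' @export
fit_exponential <- function(dist) {
  y <- .as_proportions(dist)
  x <- 1:20
  pos <- y > 0
  if (sum(pos) < 3) {
    stop("insufficient-data error: need >= 3 positive bins")
  }
  fit <- stats::lm(log(y[pos]) ~ x[pos])
  a <- exp(unname(stats::coef(fit)[1]))
  cc <- unname(stats::coef(fit)[2])
  new_curve_fit("exponential", c(a = a, c = cc), fitted = a * exp(cc * x),
                y = y, r2_transformed = .lm_r2(fit),
                n_dropped = sum(!pos))
}

#' Fit the logarithmic comparator
#'
#' Fits `y = c + d ln x` by OLS on the original scale.
#'
#' @inheritParams fit_power
#' @return a `curve_fit` with `params["c"]` and `params["d"]`.
#' @export
fit_logarithmic <- function(dist) {
  y <- .as_proportions(dist)
  x <- 1:20
  fit <- stats::lm(y ~ log(x))
  cf <- unname(stats::coef(fit))
  new_curve_fit("logarithmic", c(c = cf[1], d = cf[2]),
                fitted = cf[1] + cf[2] * log(x), y = y,
                r2_transformed = .lm_r2(fit))
}

#' Fit the quadratic polynomial comparator
#'
#' Fits `y = c0 + c1 x + c2 x^2` by OLS -- the minimal nonlinear polynomial
#' and the spreadsheet default.
#'
#' @inheritParams fit_power
#' @return a `curve_fit` with `params["c0"]`, `params["c1"]`, `params["c2"]`.
#' @export
fit_polynomial <- function(dist) {
  y <- .as_proportions(dist)
  if (sum(y > 0) < 4) {
    stop("insufficient-data error: need >= 4 positive bins")
  }
  x <- 1:20
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  new_curve_fit("polynomial", c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
                fitted = cf[1] + cf[2] * x + cf[3] * x^2, y = y,
                r2_transformed = .lm_r2(fit))
}

#' Compare the four model families on one distribution
#'
#' Fits power, exponential, logarithmic, and quadratic-polynomial curves to
#' the same distribution and ranks them by `r2_original` (computed on the
#' proportion scale for every family, so the ranking is comparable); ties
#' are broken in favour of fewer parameters. A family whose fit fails (for
#' example from too few positive bins) is reported with `NA` and ranked
#' last; the remaining families are unaffected.
#'
#' @inheritParams fit_power
#' @return a `model_comparison` data frame with columns `family`,
#'   `r2_original`, `r2_transformed`, `n_params`, `rank`, ordered by rank.
#'   The full `curve_fit` objects are in `attr(x, "fits")`.
#' @export
compare_models <- function(dist) {
  fitters <- list(power = fit_power, exponential = fit_exponential,
                  logarithmic = fit_logarithmic, polynomial = fit_polynomial)
  n_params <- c(power = 2L, exponential = 2L, logarithmic = 2L,
                polynomial = 3L)
  fits <- lapply(fitters, function(f) {
    tryCatch(f(dist), error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all model fits failed")
  r2o <- vapply(names(fits), function(f) {
    if (ok[f]) fits[[f]]$r2_original else NA_real_
  }, numeric(1))
  r2t <- vapply(names(fits), function(f) {
    if (ok[f]) fits[[f]]$r2_transformed else NA_real_
  }, numeric(1))
  out <- data.frame(family = names(fits),
                    r2_original = r2o,
                    r2_transformed = r2t,
                    n_params = n_params[names(fits)],
                    stringsAsFactors = FALSE)
  # rank: best r2 first, ties to the more parsimonious family, failures last
  ord <- order(ifelse(is.na(out$r2_original), Inf, -out$r2_original),
               out$n_params)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ok]
  class(out) <- c("model_comparison", "data.frame")
  out
}
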