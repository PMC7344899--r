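## Melting-temperature extraction from a melting curve.
##
## The default estimator is the midpoint Tm of a least-squares 4-parameter
## logistic  gci(T) = b + (a - b) / (1 + exp((T - Tm) / s)); a half-range
## crossing estimator is available as a robust fallback for noisy curves.

.logistic4 <- function(T, a, b, tm, s) b + (a - b) / (1 + exp((T - tm) / s))

## Linear-interpolation crossing of the half-range level.
.midpoint_crossing <- function(temps, gci) {
  level <- (max(gci) + min(gci)) / 2
  below <- which(gci <= level)
  above <- which(gci >= level)
  ## first index where the (decreasing) curve crosses the level
  i <- which(diff(gci >= level) == -1)
  if (length(i) == 0) {
    ## monotone up to noise; bracket by the closest pair
    i <- which.min(abs(gci - level))
    return(temps[i])
  }
  i <- i[1]
  t1 <- temps[i]; t2 <- temps[i + 1]
  g1 <- gci[i]; g2 <- gci[i + 1]
  if (g1 == g2) return((t1 + t2) / 2)
  t1 + (level - g1) * (t2 - t1) / (g2 - g1)
}

#' Fit the melting temperature of a melting curve
#'
#' Estimates the temperature at which membrane occupancy falls to the
#' midpoint of its transition. The `"logistic"` method least-squares fits
#' `gci(T) = b + (a - b)/(1 + exp((T - Tm)/s))` (Levenberg-Marquardt) and
#' reports the fitted midpoint `Tm` with a standard-error-based confidence
#' half-width; the `"midpoint"` method returns the linear-interpolated
#' crossing of the half-range level and is used as an automatic fallback when
#' the logistic fit fails to converge.
#'
#' @param curve A [melting_curve()] tibble (columns `temperature`, `gci`).
#' @param method `"logistic"` (default) or `"midpoint"`.
#' @param min_drop Minimum required decrease in `gci` across the curve
#'   (default 0.2); flatter curves raise a no-transition error.
#' @return Object of class `melt_fit` with elements `tm`, `tm_se`,
#'   `steepness`, `upper`, `lower`, `method`, `fit` (the `nls` object or
#'   `NULL`) and `curve`.
#' @export
fit_melting_temperature <- function(curve, method = c("logistic", "midpoint"),
                                    min_drop = 0.2) {
  method <- match.arg(method)
  stopifnot(all(c("temperature", "gci") %in% names(curve)))
  temps <- curve$temperature
  gci <- curve$gci
  if (length(temps) < 4) abort("At least 4 temperatures are required to fit.")
  drop <- max(gci) - min(gci)
  if (drop < min_drop) {
    abort(sprintf(
      "No melting transition: curve decreases by %.3f (< %.2f required).",
      drop, min_drop), class = "cgmelt_no_transition")
  }
  tm0 <- .midpoint_crossing(temps, gci)
  if (method == "midpoint") {
    return(structure(list(tm = tm0, tm_se = NA_real_, steepness = NA_real_,
                          upper = max(gci), lower = min(gci),
                          method = "midpoint", fit = NULL, curve = curve),
                     class = "melt_fit"))
  }
  span <- diff(range(temps))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      gci ~ b + (a - b) / (1 + exp((temperature - tm) / s)),
      data = curve,
      start = list(a = max(gci), b = min(gci), tm = tm0, s = span / 10),
      lower = c(a = 0, b = 0, tm = min(temps) - span, s = 1e-3),
      upper = c(a = 1.5, b = 1.5, tm = max(temps) + span, s = 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("Logistic fit did not converge; falling back to the midpoint estimator.")
    return(fit_melting_temperature(curve, method = "midpoint", min_drop = min_drop))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tm", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(tm = unname(cf["tm"]), tm_se = unname(se),
                 steepness = unname(cf["s"]),
                 upper = unname(cf["a"]), lower = unname(cf["b"]),
                 method = "logistic", fit = fit, curve = curve),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f K (%s%s)\n", x$tm, x$method,
              if (is.na(x$tm_se)) "" else sprintf(", se %.2f K", x$tm_se)))
  if (!is.na(x$steepness)) {
    cat(sprintf("  plateau %.3f -> %.3f, steepness %.2f K\n",
                x$upper, x$lower, x$steepness))
  }
  invisible(x)
}

#' Tidy a melting-temperature fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @method tidy melt_fit
#' @export
tidy.melt_fit <- function(x, ...) {
  if (x$method == "logistic") {
    s <- summary(x$fit)$coefficients
    tibble(term = rownames(s), estimate = s[, "Estimate"],
           std.error = s[, "Std. Error"])
  } else {
    tibble(term = c("tm", "a", "b"),
           estimate = c(x$tm, x$upper, x$lower),
           std.error = NA_real_)
  }
}

#' One-row summary of a melting-temperature fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return Tibble with `tm`, `tm_se`, `steepness`, `upper`, `lower`,
#'   `method`, `rmse`, `n_temperatures`.
#' @method glance melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  pred <- if (x$method == "logistic") {
    .logistic4(x$curve$temperature, x$upper, x$lower, x$tm, x$steepness)
  } else {
    NA_real_
  }
  tibble(tm = x$tm, tm_se = x$tm_se, steepness = x$steepness,
         upper = x$upper, lower = x$lower, method = x$method,
         rmse = if (x$method == "logistic") sqrt(mean((x$curve$gci - pred)^2)) else NA_real_,
         n_temperatures = nrow(x$curve))
}
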