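#' Fit an oxidation rate to a kinetic trace
#'
#' Ordinary least-squares slope of concentration versus time over a time
#' window. On a two-point window the OLS slope reduces exactly to the
#' difference quotient (c2 - c1)/(t2 - t1), the classical way an
#' uninhibited oxidation rate is read off the first 25 minutes of a run.
#'
#' @param trace A [kinetic_trace()] (or data frame with `time_min`,
#'   `concentration_M`).
#' @param window Length-2 numeric, time window in minutes (inclusive).
#'   Default `c(0, 25)`, the conventional uninhibited-rate window after
#'   initiator addition.
#' @return An object of class `rate_estimate` with elements
#'   `rate_M_min`, `intercept_M`, `window`, `rms_M` (RMS fit residual)
#'   and `n_points`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' tr <- kinetic_trace(c(0, 25), c(0, 8.25e-6))
#' fit_oxidation_rate(tr)$rate_M_min  # 3.3e-7 M/min
fit_oxidation_rate <- function(trace, window = c(0, 25)) {
  df <- as_tibble(trace)
  if (!all(c("time_min", "concentration_M") %in% names(df))) {
    abort("`trace` needs columns `time_min` and `concentration_M`.",
          class = "clperox_validation_error")
  }
  if (length(window) != 2 || !all(is.finite(window))) {
    abort("`window` must be a finite length-2 numeric.",
          class = "clperox_domain_error")
  }
  window <- sort(window)
  df <- df[df$time_min >= window[1] & df$time_min <= window[2], ]
  if (nrow(df) < 2) {
    abort(sprintf("Need >= 2 points in window [%g, %g] min (found %d).",
                  window[1], window[2], nrow(df)),
          class = "clperox_insufficient_data")
  }
  fit <- lm(concentration_M ~ time_min, data = df)
  structure(
    list(
      rate_M_min = unname(coef(fit)[["time_min"]]),
      intercept_M = unname(coef(fit)[["(Intercept)"]]),
      window = window,
      rms_M = sqrt(mean(fit$residuals^2)),
      n_points = nrow(df)
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3g M/min (%.3g nM/min) over [%g, %g] min, %d points, RMS %.2g M\n",
              x$rate_M_min, x$rate_M_min * 1e9, x$window[1], x$window[2],
              x$n_points, x$rms_M))
  invisible(x)
}

#' @rdname fit_oxidation_rate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(term = c("intercept_M", "rate_M_min"),
         estimate = c(x$intercept_M, x$rate_M_min))
}

#' @rdname fit_oxidation_rate
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble(rate_M_min = x$rate_M_min, rate_nM_min = x$rate_M_min * 1e9,
         window_start_min = x$window[1], window_end_min = x$window[2],
         rms_M = x$rms_M, n_points = x$n_points)
}

#' Replicate mean and sample standard deviation
#'
#' Aggregates replicate measurements the way kinetic assay tables report
#' them: arithmetic mean plus the sample (n - 1) standard deviation.
#' Single-replicate groups get sd 0 and are flagged as low-n, as are
#' two-run groups.
#'
#' @param values Numeric vector of replicate values (>= 1).
#' @return A one-row tibble: `mean`, `sd`, `n`, `low_n` (logical flag for
#'   n < 3).
#' @export
#' @examples
#' replicate_stats(c(2, 4, 6))  # mean 4, sd 2
replicate_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("No replicate values supplied.", class = "clperox_insufficient_data")
  }
  tibble(
    mean = mean(values),
    sd = if (length(values) == 1) 0 else sd(values),
    n = length(values),
    low_n = length(values) < 3
  )
}
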