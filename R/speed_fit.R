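# Speed-versus-gait-metric regressions: three-parameter exponential decay for
# stance and stride times, straight lines (with 95% prediction intervals) for
# stride distance and frequency.

#' Fit a speed-metric relationship
#'
#' Least-squares fit of a gait metric against per-stride speed. Two model
#' families are supported: `"expdecay"`, `y = a * exp(-b * v) + c`, the form
#' taken by stance and stride times which decay towards a floor at high
#' speed; and `"linear"`, `y = intercept + slope * v`, appropriate for stride
#' distance and stride frequency. The exponential fit uses multi-start
#' Levenberg-Marquardt with decay-rate starts `{0.005, 0.02, 0.08}` scaled to
#' the observed speed range. For the linear family, per-point 95% prediction
#' interval half-widths from the standard regression formula are included.
#'
#' @param data A data frame of points.
#' @param response Column holding the metric (tidy-eval).
#' @param speed Column holding speed in cm/s (tidy-eval, default `speed`).
#' @param kind `"expdecay"` or `"linear"`.
#' @return An object of class `gait_speed_fit` with `kind`, `coefficients`,
#'   `r.squared`, `n`, and a `points` tibble (speed, observed, fitted, and for
#'   linear fits `pi_half_width`). Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' d <- tibble::tibble(speed = seq(20, 100, length.out = 20),
#'                     stance = 0.3 * exp(-0.02 * speed) + 0.05)
#' fit_speed_relationship(d, stance, kind = "expdecay")
#' @export
fit_speed_relationship <- function(data, response, speed = speed,
                                   kind = c("expdecay", "linear")) {
  kind <- match.arg(kind)
  y <- dplyr::pull(data, {{ response }})
  v <- dplyr::pull(data, {{ speed }})
  keep <- is.finite(y) & is.finite(v)
  y <- y[keep]
  v <- v[keep]
  n <- length(y)
  n_par <- if (kind == "expdecay") 3L else 2L
  if (n < n_par + 1) abort("too few points for the requested model family")
  if (any(v <= 0)) abort("speeds must be positive")
  if (diff(range(v)) == 0) abort("degenerate design: all speeds are equal")

  sstot <- sum((y - mean(y))^2)
  if (kind == "linear") {
    fit <- lm(y ~ v)
    pred <- suppressWarnings(
      predict(fit, interval = "prediction", level = 0.95))
    cf <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
    fitted <- unname(pred[, "fit"])
    pi_half <- unname((pred[, "upr"] - pred[, "lwr"]) / 2)
  } else {
    span <- diff(range(v))
    b_starts <- c(0.005, 0.02, 0.08) * 50 / span
    best <- NULL
    for (b0 in b_starts) {
      a0 <- max(max(y) - min(y), .Machine$double.eps)
      c0 <- min(y)
      fit_try <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-b * v) + cc,
                          start = list(a = a0, b = b0, cc = c0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit_try)) {
        ss <- sum(stats::resid(fit_try)^2)
        if (is.null(best) || ss < best$ss) best <- list(fit = fit_try, ss = ss)
      }
    }
    if (is.null(best)) {
      abort("exponential decay fit failed to converge from any start")
    }
    fit <- best$fit
    cf <- setNames(coef(fit), c("a", "b", "c"))
    fitted <- stats::fitted(fit)
    pi_half <- rep(NA_real_, n)
  }
  ssres <- sum((y - fitted)^2)
  r2 <- 1 - ssres / sstot
  structure(
    list(kind = kind, coefficients = cf, r.squared = r2, n = n,
         points = tibble(speed = v, observed = y, fitted = as.numeric(fitted),
                         pi_half_width = pi_half),
         fit = fit),
    class = "gait_speed_fit"
  )
}

#' @export
print.gait_speed_fit <- function(x, ...) {
  eqn <- if (x$kind == "expdecay") {
    sprintf("y = %.4g * exp(-%.4g v) + %.4g",
            x$coefficients["a"], x$coefficients["b"], x$coefficients["c"])
  } else {
    sprintf("y = %.4g + %.4g v",
            x$coefficients["intercept"], x$coefficients["slope"])
  }
  cat(sprintf("Speed relationship (%s): %s\n", x$kind, eqn))
  cat(sprintf("  R^2 = %.4f over %d points\n", x$r.squared, x$n))
  invisible(x)
}

#' @export
tidy.gait_speed_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.gait_speed_fit <- function(x, ...) {
  tibble(kind = x$kind, r.squared = x$r.squared, n = x$n)
}

#' Plot a fitted speed relationship
#'
#' Scatter of the observed points with the fitted curve; linear fits also show
#' the 95% prediction band.
#'
#' @param object A `gait_speed_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_speed_fit <- function(object, ...) {
  pts <- arrange(object$points, .data$speed)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$speed, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::labs(x = "speed (cm/s)", y = "metric",
                  subtitle = sprintf("%s fit, R² = %.3f",
                                     object$kind, object$r.squared)) +
    ggplot2::theme_minimal()
  if (object$kind == "linear" && all(is.finite(pts$pi_half_width))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$fitted - .data$pi_half_width,
                   ymax = .data$fitted + .data$pi_half_width),
      alpha = 0.15, fill = "#b2182b")
  }
  p
}
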