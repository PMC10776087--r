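# Bespoke statistical layer: two-proportion z tests (pooled / unpooled),
# circular descriptives on phases measured in cycles, Watson's two-sample U2
# with Monte-Carlo calibration of its null quantile.

#' Two-proportion z test (binomial proportion test)
#'
#' Tests the difference between two independent proportions `x1/n1` and
#' `x2/n2` with a normal approximation. Both classical variance estimates are
#' available: `"pooled"` uses the common proportion `(x1 + x2)/(n1 + n2)` under
#' the null, `"unpooled"` uses the two sample proportions separately. The
#' statistic is signed as `p2 - p1`, so swapping the samples flips the sign.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @param variant Variance estimate, `"pooled"` (default) or `"unpooled"`.
#' @param correction Apply a continuity correction of `(1/n1 + 1/n2)/2` to the
#'   absolute difference. Off by default.
#' @return An object of class `gait_prop_test` with elements `x1`, `n1`, `x2`,
#'   `n2`, `estimate` (p2 - p1), `variant`, `statistic` (z) and `p.value`
#'   (two-tailed). Has [tidy()] and [glance()] methods.
#' @examples
#' two_proportion_z(3, 238, 12, 218, variant = "unpooled")
#' @export
two_proportion_z <- function(x1, n1, x2, n2,
                             variant = c("pooled", "unpooled"),
                             correction = FALSE) {
  variant <- match.arg(variant)
  counts <- c(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
  if (any(!is.finite(counts))) abort("counts must be finite numbers")
  if (n1 < 1 || n2 < 1) abort("both sample sizes must be at least 1")
  if (x1 < 0 || x2 < 0) abort("counts cannot be negative")
  if (x1 > n1 || x2 > n2) abort("successes cannot exceed trials")

  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- switch(variant,
    pooled = {
      p <- (x1 + x2) / (n1 + n2)
      sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    },
    unpooled = sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  )
  if (se == 0) {
    abort(paste0("zero variance under the ", variant,
                 " variant: cannot standardise the difference"))
  }
  diff <- p2 - p1
  if (correction) {
    cc <- (1 / n1 + 1 / n2) / 2
    diff <- sign(diff) * max(abs(diff) - cc, 0)
  }
  z <- diff / se
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
         estimate = p2 - p1, variant = variant, correction = correction,
         statistic = z, p.value = 2 * pnorm(-abs(z))),
    class = "gait_prop_test"
  )
}

#' @export
print.gait_prop_test <- function(x, ...) {
  cat(sprintf("Two-proportion z test (%s variance)\n", x$variant))
  cat(sprintf("  p1 = %d/%d = %.4f, p2 = %d/%d = %.4f\n",
              x$x1, x$n1, x$x1 / x$n1, x$x2, x$n2, x$x2 / x$n2))
  cat(sprintf("  z = %.3f, two-tailed p = %.4g\n", x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.gait_prop_test <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$statistic, p.value = x$p.value,
    x1 = x$x1, n1 = x$n1, x2 = x$x2, n2 = x$n2, variant = x$variant
  )
}

#' @export
glance.gait_prop_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, variant = x$variant)
}

#' Circular summary of phase values
#'
#' Descriptive circular statistics for phases measured in cycles on `[0, 1)`.
#' Phases are mapped to angles on the unit circle; the mean direction is the
#' angle of the resultant vector, `R` its mean length, and the circular SD is
#' `sqrt(-2 log R) / (2 pi)` cycles.
#'
#' @param phases Numeric vector of phases in cycles. Values are wrapped mod 1.
#' @return A one-row tibble with `n`, `mean_direction` (cycles), `R`,
#'   `circular_sd` (cycles) and `mean_defined` (`FALSE` when `R` is zero, in
#'   which case the mean direction and SD are `NA`).
#' @examples
#' circular_summary(c(0.4, 0.6))
#' @export
circular_summary <- function(phases) {
  if (length(phases) < 1) abort("need at least one phase value")
  if (any(!is.finite(phases))) abort("phases must be finite")
  theta <- 2 * pi * (phases %% 1)
  cbar <- mean(cos(theta))
  sbar <- mean(sin(theta))
  R <- sqrt(cbar^2 + sbar^2)
  if (R < .Machine$double.eps^0.5) {
    return(tibble(n = length(phases), mean_direction = NA_real_, R = R,
                  circular_sd = NA_real_, mean_defined = FALSE))
  }
  mu <- (atan2(sbar, cbar) / (2 * pi)) %% 1
  tibble(n = length(phases), mean_direction = mu, R = R,
         circular_sd = sqrt(-2 * log(R)) / (2 * pi), mean_defined = TRUE)
}

#' Watson's two-sample U2 test for a common circular distribution
#'
#' Nonparametric test that two circular samples come from populations with the
#' same direction. Both samples (phases in cycles) are pooled and ordered; at
#' each of the `N = n1 + n2` points the difference `d_k` of the two empirical
#' cumulative fractions is taken, and
#' `U2 = (n1 n2 / N^2) * (sum(d_k^2) - (sum d_k)^2 / N)`.
#' Cross-sample ties are handled by replacing every `d` within a tie group by
#' the group mean, processed in sorted order, which makes the statistic
#' deterministic and symmetric in the two samples. The statistic is invariant
#' to a common rotation of both samples.
#'
#' @param sample1,sample2 Numeric vectors of phases in cycles.
#' @param critical_value Asymptotic 5% critical value used for the
#'   significance flag; the classical tabulated value is 0.1869.
#' @return An object of class `gait_watson_u2` with `u2`, `n1`, `n2`,
#'   `critical_value` and `significant`. Has [tidy()] and [glance()] methods.
#' @examples
#' watson_u2(c(0.1, 0.2, 0.3, 0.4), c(0.6, 0.7, 0.8, 0.9))
#' @export
watson_u2 <- function(sample1, sample2, critical_value = 0.1869) {
  n1 <- length(sample1)
  n2 <- length(sample2)
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty")
  if (any(!is.finite(c(sample1, sample2)))) abort("phases must be finite")
  if (n1 < 4 || n2 < 4) {
    warn("Watson's U2 with fewer than 4 observations per sample is unreliable")
  } else if (n1 < 8 || n2 < 8) {
    warn("Watson's U2 with fewer than 8 observations per sample is approximate")
  }
  s1 <- sample1 %% 1
  s2 <- sample2 %% 1
  N <- n1 + n2
  x <- c(s1, s2)
  from1 <- c(rep(TRUE, n1), rep(FALSE, n2))
  ord <- order(x)
  x <- x[ord]
  from1 <- from1[ord]
  d <- cumsum(from1) / n1 - cumsum(!from1) / n2
  # average d within cross-sample tie groups so the statistic does not depend
  # on the within-tie ordering
  grp <- cumsum(c(TRUE, diff(x) != 0))
  d <- stats::ave(d, grp)
  u2 <- (n1 * n2 / N^2) * (sum(d^2) - sum(d)^2 / N)
  structure(
    list(u2 = u2, n1 = n1, n2 = n2, critical_value = critical_value,
         significant = u2 > critical_value),
    class = "gait_watson_u2"
  )
}

#' @export
print.gait_watson_u2 <- function(x, ...) {
  cat("Watson's two-sample U2 test\n")
  cat(sprintf("  U2 = %.4f (n1 = %d, n2 = %d)\n", x$u2, x$n1, x$n2))
  cat(sprintf("  %ssignificant at the %.4f asymptotic 5%% critical value\n",
              if (x$significant) "" else "not ", x$critical_value))
  invisible(x)
}

#' @export
tidy.gait_watson_u2 <- function(x, ...) {
  tibble(statistic = x$u2, n1 = x$n1, n2 = x$n2,
         critical_value = x$critical_value, significant = x$significant)
}

#' @export
glance.gait_watson_u2 <- function(x, ...) tidy(x)

#' Monte-Carlo null quantile of Watson's U2
#'
#' Draws both samples from a common uniform circular distribution, computes
#' `U2` for each replicate, and returns an empirical quantile of the null
#' distribution together with a bootstrap standard error. With moderate sample
#' sizes the 95th percentile approaches the asymptotic critical value 0.1869.
#'
#' @param n1,n2 Sample sizes per replicate.
#' @param n_replicates Number of Monte-Carlo replicates (at least 100;
#'   5000 or more recommended).
#' @param seed Integer seed for reproducibility.
#' @param level Quantile level (default 0.95).
#' @param n_boot Bootstrap resamples for the standard error.
#' @return A one-row tibble with `level`, `quantile`, `se_boot`,
#'   `n_replicates`, `n1`, `n2`.
#' @export
u2_null_quantile <- function(n1, n2, n_replicates = 5000, seed = 1L,
                             level = 0.95, n_boot = 200L) {
  if (n_replicates < 100) abort("n_replicates must be at least 100")
  if (n_replicates < 1000) {
    warn("fewer than 1000 replicates gives a noisy quantile estimate")
  }
  u2s <- with_preserved_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      watson_u2_stat(runif(n1), runif(n2))
    }, numeric(1))
  })
  q <- unname(quantile(u2s, level, type = 7))
  se <- with_preserved_seed(seed + 1L, {
    stats::sd(vapply(seq_len(n_boot), function(i) {
      unname(quantile(sample(u2s, replace = TRUE), level, type = 7))
    }, numeric(1)))
  })
  tibble(level = level, quantile = q, se_boot = se,
         n_replicates = n_replicates, n1 = n1, n2 = n2)
}

# statistic-only path used in tight Monte-Carlo loops (skips validation,
# warnings and object construction)
watson_u2_stat <- function(s1, s2) {
  n1 <- length(s1)
  n2 <- length(s2)
  N <- n1 + n2
  x <- c(s1 %% 1, s2 %% 1)
  from1 <- c(rep(TRUE, n1), rep(FALSE, n2))
  ord <- order(x)
  x <- x[ord]
  from1 <- from1[ord]
  d <- cumsum(from1) / n1 - cumsum(!from1) / n2
  if (anyDuplicated(x)) {
    grp <- cumsum(c(TRUE, diff(x) != 0))
    d <- stats::ave(d, grp)
  }
  (n1 * n2 / N^2) * (sum(d^2) - sum(d)^2 / N)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
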