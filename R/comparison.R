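#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)}
#' over \eqn{i < j}. Pairs with identical points (0/0) are undefined and
#' excluded, slopes exactly equal to -1 are excluded, and x-ties with
#' unequal y contribute signed infinite slopes counted at the extremes.
#' The median rank is shifted by K, the number of slopes below -1, which
#' makes the estimate invariant under swapping the roles of x and y.
#' Confidence bounds come from the rank statistic
#' \eqn{w = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}}; intercept bounds are the
#' medians of \eqn{y - b x} evaluated at the slope bounds.
#'
#' @param x Reference-method values (here Harboe fHb, mg/L).
#' @param y Comparator values (here index-estimated fHb, mg/L).
#' @param ci_level Two-sided confidence level (default 0.95). Confidence
#'   bounds are reported only for n >= 10; below that they are `NA`.
#' @return A list with `slope`, `slope_ci`, `intercept`, `intercept_ci`,
#'   `n`, and `ci_level`.
#' @examples
#' passing_bablok(c(1, 2, 3, 4, 5), c(3, 5, 7, 9, 11))  # slope 2, intercept 1
#' @export
passing_bablok <- function(x, y, ci_level = 0.95) {
  check_paired(x, y, min_n = 3)
  if (length(unique(x)) == 1) {
    abort("all `x` values identical: slope undefined", class = "freehb_estimation_error")
  }
  n <- length(x)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- y[ij[, 2]] - y[ij[, 1]]
  s <- dy / dx                      # 0/0 -> NaN; ties in x only -> +-Inf
  s <- s[!is.nan(s) & s != -1]
  n_slopes <- length(s)
  if (n_slopes == 0) {
    abort("all pairwise slopes excluded: cannot estimate",
          class = "freehb_estimation_error")
  }
  s <- sort(s)                      # NaN already dropped; +-Inf sort to ends
  k_off <- sum(s < -1)
  at <- function(r) s[min(max(r, 1L), n_slopes)]
  b <- if (n_slopes %% 2 == 1) {
    at(k_off + (n_slopes + 1L) / 2L)
  } else {
    mean(c(at(k_off + n_slopes / 2L), at(k_off + n_slopes / 2L + 1L)))
  }
  if (!is.finite(b)) {
    abort("degenerate data: slope estimate not finite",
          class = "freehb_estimation_error")
  }
  a <- median(y - b * x)

  if (n >= 10) {
    w <- qnorm(1 - (1 - ci_level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
    m1 <- round((n_slopes - w) / 2)
    m2 <- n_slopes - m1 + 1L
    b_lo <- at(m1 + k_off)
    b_hi <- at(m2 + k_off)
    a_lo <- median(y - b_hi * x)
    a_hi <- median(y - b_lo * x)
    slope_ci <- c(b_lo, b_hi)
    intercept_ci <- c(a_lo, a_hi)
  } else {
    slope_ci <- c(NA_real_, NA_real_)
    intercept_ci <- c(NA_real_, NA_real_)
  }
  list(slope = b, slope_ci = slope_ci,
       intercept = a, intercept_ci = intercept_ci,
       n = n, ci_level = ci_level)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `x - y` (reference minus comparator) so a
#' comparator that underestimates yields a positive bias. Limits of
#' agreement are `bias +/- loa_multiplier * sd(d)` with the sample standard
#' deviation; the bias confidence interval uses the t distribution with
#' n - 1 degrees of freedom.
#'
#' @inheritParams passing_bablok
#' @param loa_multiplier Multiplier on the SD of differences (default 1.96,
#'   the ~95% normal coverage convention).
#' @param ci_level Confidence level for the bias CI.
#' @return A list with `bias`, `bias_ci`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`, and `difference_direction`.
#' @examples
#' bland_altman(c(2, 3, 4), c(1, 1, 1))
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96, ci_level = 0.95) {
  check_paired(x, y, min_n = 2)
  d <- x - y
  n <- length(d)
  bias <- mean(d)
  sdd <- sd(d)
  half <- qt(1 - (1 - ci_level) / 2, df = n - 1) * sdd / sqrt(n)
  list(bias = bias,
       bias_ci = c(bias - half, bias + half),
       loa_low = bias - loa_multiplier * sdd,
       loa_high = bias + loa_multiplier * sdd,
       sd_diff = sdd, n = n,
       difference_direction = "x - y (reference minus comparator)")
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties); the
#' confidence interval uses the Fisher z transform with standard error
#' \eqn{1/\sqrt{n-3}}, and the p-value the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @inheritParams passing_bablok
#' @return A list with `rho`, `rho_ci`, `p_value`, and `n`.
#' @examples
#' spearman_rank(1:10, (1:10)^2)  # rho = 1 on any monotone pairing
#' @export
spearman_rank <- function(x, y, ci_level = 0.95) {
  check_paired(x, y, min_n = 3)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("zero rank variance: rho undefined", class = "freehb_estimation_error")
  }
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sd(rx) * sd(ry))
  rho <- min(1, max(-1, rho))
  if (n > 3 && abs(rho) < 1) {
    zr <- atanh(rho)
    zw <- qnorm(1 - (1 - ci_level) / 2) / sqrt(n - 3)
    rho_ci <- tanh(c(zr - zw, zr + zw))
  } else {
    rho_ci <- c(NA_real_, NA_real_)
  }
  p <- if (abs(rho) == 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, rho_ci = rho_ci, p_value = p, n = n)
}

#' Compare two fHb measurement routes on a paired-sample table
#'
#' Runs the full method-comparison panel — Passing-Bablok regression,
#' Bland-Altman agreement, and Spearman rank correlation — on two columns
#' of a per-sample table, treating the first as the reference method.
#'
#' @param data A data frame of paired measurements.
#' @param x,y Unquoted column names: reference method and comparator
#'   (default `fhb` and `efhb`).
#' @param ci_level Two-sided confidence level (default 0.95).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `fhb_comparison`; see [tidy.fhb_comparison()]
#'   and [glance.fhb_comparison()] for tabular views and
#'   [autoplot.fhb_comparison()] for plots.
#' @examples
#' cohort <- simulate_cohort(n = 61, seed = 1)
#' compare_methods(cohort, fhb, efhb)
#' @export
compare_methods <- function(data, x = fhb, y = efhb, ci_level = 0.95,
                            loa_multiplier = 1.96) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  out <- list(
    pb = passing_bablok(xv, yv, ci_level = ci_level),
    ba = bland_altman(xv, yv, loa_multiplier = loa_multiplier,
                      ci_level = ci_level),
    sp = spearman_rank(xv, yv, ci_level = ci_level),
    n = length(xv),
    ci_level = ci_level,
    data = tibble::tibble(x = xv, y = yv)
  )
  structure(out, class = "fhb_comparison")
}

#' @export
print.fhb_comparison <- function(x, ...) {
  cat("<fhb_comparison>  n =", x$n, "\n")
  cat(sprintf("  Passing-Bablok: slope %.3f [%.3f, %.3f], intercept %.2f [%.2f, %.2f]\n",
              x$pb$slope, x$pb$slope_ci[1], x$pb$slope_ci[2],
              x$pb$intercept, x$pb$intercept_ci[1], x$pb$intercept_ci[2]))
  cat(sprintf("  Bland-Altman:   bias %.2f [%.2f, %.2f], LoA [%.2f, %.2f]\n",
              x$ba$bias, x$ba$bias_ci[1], x$ba$bias_ci[2],
              x$ba$loa_low, x$ba$loa_high))
  cat(sprintf("  Spearman:       rho %.3f [%.3f, %.3f], p %.3g\n",
              x$sp$rho, x$sp$rho_ci[1], x$sp$rho_ci[2], x$sp$p_value))
  invisible(x)
}

#' Tidy a method-comparison result
#'
#' @param x An `fhb_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`pb_intercept`, `pb_slope`,
#'   `spearman_rho`, `ba_bias`, `ba_loa_low`, `ba_loa_high`) and columns
#'   `estimate`, `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.fhb_comparison <- function(x, ...) {
  tibble::tibble(
    term = c("pb_intercept", "pb_slope", "spearman_rho", "ba_bias",
             "ba_loa_low", "ba_loa_high"),
    estimate = c(x$pb$intercept, x$pb$slope, x$sp$rho, x$ba$bias,
                 x$ba$loa_low, x$ba$loa_high),
    conf.low = c(x$pb$intercept_ci[1], x$pb$slope_ci[1], x$sp$rho_ci[1],
                 x$ba$bias_ci[1], NA, NA),
    conf.high = c(x$pb$intercept_ci[2], x$pb$slope_ci[2], x$sp$rho_ci[2],
                  x$ba$bias_ci[2], NA, NA),
    p.value = c(NA, NA, x$sp$p_value, NA, NA, NA)
  )
}

#' One-row summary of a method-comparison result
#'
#' @param x An `fhb_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.fhb_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    pb_slope = x$pb$slope, pb_intercept = x$pb$intercept,
    spearman_rho = x$sp$rho, spearman_p = x$sp$p_value,
    ba_bias = x$ba$bias, ba_loa_low = x$ba$loa_low,
    ba_loa_high = x$ba$loa_high
  )
}

#' Plot a method-comparison result
#'
#' @param object An `fhb_comparison`.
#' @param type `"regression"` for the Passing-Bablok scatter with identity
#'   and fitted lines, `"bland_altman"` for the difference plot with bias
#'   and limits of agreement.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fhb_comparison
#' @export
autoplot.fhb_comparison <- function(object, type = c("regression", "bland_altman"),
                                    ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "regression") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::geom_abline(slope = object$pb$slope,
                           intercept = object$pb$intercept,
                           colour = "#2166AC") +
      ggplot2::labs(x = "Reference method (fHb, mg/L)",
                    y = "Comparator (efHb, mg/L)",
                    title = "Passing-Bablok regression") +
      ggplot2::theme_minimal()
  } else {
    pd <- dplyr::mutate(d, m = (.data$x + .data$y) / 2, diff = .data$x - .data$y)
    ggplot2::ggplot(pd, ggplot2::aes(x = .data$m, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = object$ba$bias, colour = "#2166AC") +
      ggplot2::geom_hline(yintercept = c(object$ba$loa_low, object$ba$loa_high),
                          linetype = "dashed", colour = "#B2182B") +
      ggplot2::labs(x = "Mean of methods (mg/L)",
                    y = "Difference fHb - efHb (mg/L)",
                    title = "Bland-Altman agreement") +
      ggplot2::theme_minimal()
  }
}

check_paired <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort("`x` and `y` must be numeric", class = "freehb_input_error")
  }
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "freehb_input_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite and free of NA", class = "freehb_input_error")
  }
  if (length(x) < min_n) {
    abort(paste0("need at least ", min_n, " paired values"),
          class = "freehb_estimation_error")
  }
  invisible(TRUE)
}
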