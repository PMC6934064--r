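#' Bin response rates into 10%-wide classes
#'
#' The unit of the normative fitting procedure: response rates on the percent
#' scale are tallied into ten classes of width 10. Classes are half-open at
#' the low edge, `(low, high]`, with the top class closed at 100; a rate of
#' exactly 0 is assigned to the first class. Relative frequencies and their
#' running total (the measured cumulative distribution) are computed.
#'
#' @param rates numeric vector of rates in \[0, 100\].
#' @return Object of class `binned_distribution` with fields `class_edges`
#'   (0, 10, ..., 100), `counts` (10 integers), `rel_freq`, `cum_freq`, `n`.
#' @export
bin_rates <- function(rates) {
  if (!is.numeric(rates) || !length(rates)) stop("rates must be a nonempty numeric vector")
  if (anyNA(rates)) stop("rates contain NA")
  if (any(rates < 0 | rates > 100)) {
    stop("rates outside [0, 100]: ", paste(utils::head(rates[rates < 0 | rates > 100], 3), collapse = ", "))
  }
  idx <- pmax(1L, as.integer(ceiling(rates / 10)))
  counts <- tabulate(idx, nbins = 10L)
  binned_distribution(counts)
}

#' Construct a binned distribution from class counts
#'
#' @param counts 10 nonnegative class counts (classes `(0,10], ..., (90,100]`,
#'   the first class also holding exact zeros).
#' @return Object of class `binned_distribution`.
#' @export
binned_distribution <- function(counts) {
  if (length(counts) != 10L || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be 10 nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("binned distribution must contain at least one observation")
  rel <- counts / n
  structure(list(class_edges = seq(0, 100, by = 10),
                 counts = as.integer(counts),
                 rel_freq = rel,
                 cum_freq = cumsum(rel),
                 n = as.integer(n)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat("Binned response-rate distribution (n =", x$n, ")\n")
  lab <- sprintf("(%d,%d]", x$class_edges[-11L], x$class_edges[-1L])
  print(data.frame(class = lab, count = x$counts,
                   rel_freq = round(x$rel_freq, 4),
                   cum_freq = round(x$cum_freq, 4)),
        row.names = FALSE)
  invisible(x)
}

upper_edges <- function(binned) binned$class_edges[-1L]

fit_result <- function(model, params, model_cum, binned, classes = NULL) {
  if (is.null(classes)) classes <- rep(TRUE, 10L)
  residuals <- (binned$cum_freq - model_cum)^2
  residuals[!classes] <- 0
  structure(list(model = model, params = params,
                 model_cum = model_cum,
                 residuals = residuals,
                 ssr = sum(residuals),
                 classes = classes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit:", x$model, " SSR =", format(x$ssr, digits = 4), "\n")
  cat("  params:", paste(names(x$params), "=",
                         vapply(x$params, format, "", digits = 5), collapse = ", "), "\n")
  invisible(x)
}

# Grid search over candidate exponents followed by golden-section refinement
# around the best grid point; ties on the grid go to the smallest z.
optimize_z <- function(ssr_fun, z_grid) {
  vals <- vapply(z_grid, ssr_fun, numeric(1L))
  i <- which.min(vals)  # which.min returns the first (smallest-z) minimum
  z0 <- z_grid[i]
  lo <- if (i > 1L) z_grid[i - 1L] else z0
  hi <- if (i < length(z_grid)) z_grid[i + 1L] else z0
  if (hi > lo) {
    opt <- stats::optimize(ssr_fun, interval = c(lo, hi), tol = 1e-3)
    if (opt$objective < vals[i]) return(list(z = opt$minimum, ssr = opt$objective))
  }
  list(z = z0, ssr = vals[i])
}

default_z_grid <- function() seq(0.1, 30, by = 0.1)

#' Normal-distribution fit on the cumulative scale
#'
#' The model cumulative value of class `c` is the normal CDF evaluated at the
#' class's upper edge; it is not renormalized (the CDF at 100 may fall short
#' of 1, and that shortfall is a genuine residual against the measured
#' cumulative frequency, which always ends at 1). The mean and SD default to
#' nothing here: pass the cohort's sample mean and SD of the raw (unbinned)
#' rates, as [select_model()] does.
#'
#' @param binned a `binned_distribution`.
#' @param mean,sd normal parameters on the percent scale; `sd > 0`.
#' @return A `fit_result` with `params = list(mean, sd)`.
#' @export
fit_normal <- function(binned, mean, sd) {
  stopifnot(inherits(binned, "binned_distribution"))
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive")
  model_cum <- stats::pnorm(upper_edges(binned), mean = mean, sd = sd)
  fit_result("normal", list(mean = mean, sd = sd), model_cum, binned)
}

#' Poisson fit on the cumulative scale
#'
#' A Poisson distribution on the percent scale: the model cumulative value of
#' class `c` is the Poisson CDF at the class upper edge, with rate `lambda`
#' equal to the cohort's mean response rate in percent. Like the normal fit
#' it is not renormalized. When `lambda` is not supplied it is estimated from
#' the binned data as the count-weighted mean of class midpoints.
#'
#' @param binned a `binned_distribution`.
#' @param lambda Poisson rate on the percent scale (typically the cohort mean
#'   rate); estimated from the bins when `NULL`.
#' @return A `fit_result` with `params = list(lambda)`.
#' @export
fit_poisson <- function(binned, lambda = NULL) {
  stopifnot(inherits(binned, "binned_distribution"))
  if (is.null(lambda)) {
    mid <- binned$class_edges[-11L] + 5
    lambda <- sum(binned$counts * mid) / binned$n
  }
  if (lambda < 0) stop("lambda must be nonnegative")
  model_cum <- stats::ppois(upper_edges(binned), lambda = lambda)
  fit_result("poisson", list(lambda = lambda), model_cum, binned)
}

#' Exponential fit on the cumulative scale
#'
#' Raw class values are `exp(i * z / 100)` with `i` the class upper edge in
#' percent; their running total is normalized by its final value so the model
#' cumulative is comparable to the measured one. `z` is chosen to minimize
#' the sum of squared residuals by grid search with local refinement. At
#' `i = 0` the raw value is 1 for any `z`: the exponential model admits
#' nonzero mass at zero performance.
#'
#' @param binned a `binned_distribution`.
#' @param z_grid candidate exponents searched before refinement.
#' @return A `fit_result` with `params = list(z)`.
#' @export
fit_exponential <- function(binned, z_grid = default_z_grid()) {
  stopifnot(inherits(binned, "binned_distribution"))
  up <- upper_edges(binned)
  cum <- binned$cum_freq
  model_cum_at <- function(z) {
    y <- exp(up * z / 100)
    cumsum(y) / sum(y)
  }
  best <- optimize_z(function(z) sum((model_cum_at(z) - cum)^2), z_grid)
  fit_result("exponential", list(z = best$z), model_cum_at(best$z), binned)
}

#' Power-law fit on the cumulative scale
#'
#' The model is `y = k * x^z` with `x` the class upper edge rescaled to
#' \[0, 1\]. `k` is fixed at the maximum of the measured relative-frequency
#' distribution; raw class values are cumulated and normalized by the final
#' cumulative value, and `z` minimizes the sum of squared residuals against
#' the measured cumulative frequencies (grid search plus local refinement,
#' ties to the smallest `z`). At `x = 0` the power law is 0: the model
#' assigns zero probability to zero-performance individuals.
#'
#' @param binned a `binned_distribution` with at least one nonzero count.
#' @param z_grid candidate exponents searched before refinement.
#' @return A `fit_result` with `params = list(k, z)`.
#' @export
fit_power_law <- function(binned, z_grid = default_z_grid()) {
  stopifnot(inherits(binned, "binned_distribution"))
  k <- max(binned$rel_freq)
  if (k <= 0) stop("degenerate binned input: all counts zero")
  x <- upper_edges(binned) / 100
  cum <- binned$cum_freq
  model_cum_at <- function(z) {
    y <- k * x^z
    cumsum(y) / sum(y)
  }
  best <- optimize_z(function(z) sum((model_cum_at(z) - cum)^2), z_grid)
  fit_result("power_law", list(k = k, z = best$z), model_cum_at(best$z), binned)
}

#' Select the best-fitting candidate model by SSR
#'
#' Fits all four candidates (normal, Poisson, exponential, power law) to the
#' binned distribution and keeps the one with the smallest sum of squared
#' residuals on the cumulative scale. The normal fit uses the cohort's sample
#' mean and SD of the raw rates; the Poisson rate is the same sample mean.
#' Exact SSR ties (measure-zero in practice) are broken by the fixed order
#' normal, power law, exponential, Poisson.
#'
#' @param binned a `binned_distribution`.
#' @param normal_params numeric `c(mean, sd)` of the cohort's raw rates.
#' @param z_grid candidate exponents for the exponential and power-law fits.
#' @return Object of class `model_selection`: list with the four `fit_result`s
#'   (`$fits`), their SSRs (`$ssr`), and the winner (`$best`, `$best_model`).
#' @export
select_model <- function(binned, normal_params, z_grid = default_z_grid()) {
  stopifnot(inherits(binned, "binned_distribution"),
            is.numeric(normal_params), length(normal_params) == 2L)
  fits <- list(
    normal      = fit_normal(binned, normal_params[1L], normal_params[2L]),
    power_law   = fit_power_law(binned, z_grid),
    exponential = fit_exponential(binned, z_grid),
    poisson     = fit_poisson(binned, lambda = normal_params[1L])
  )
  ssr <- vapply(fits, function(f) f$ssr, numeric(1L))
  best <- names(ssr)[which.min(ssr)]  # first minimum = documented tie order
  structure(list(fits = fits, ssr = ssr, best_model = best, best = fits[[best]]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (SSR on the cumulative scale):\n")
  for (m in names(x$ssr)) {
    cat(sprintf("  %-12s %s%s\n", m, format(x$ssr[[m]], digits = 4),
                if (m == x$best_model) "  <- best" else ""))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal distribution with the
#' sample mean and SD. Used as the gate between mean-based and rank-based
#' group tests and for reporting; the p-value is approximate (parameters are
#' estimated from the same sample) and is treated as a heuristic gate, not a
#' calibrated test.
#'
#' @param rates numeric vector, `n >= 5`, not all equal.
#' @return List with `statistic` and `p_like` (the approximate p-value).
#' @export
ks_normality <- function(rates) {
  if (!is.numeric(rates) || length(rates) < 5L) stop("need at least 5 observations")
  s <- stats::sd(rates)
  if (!is.finite(s) || s == 0) stop("constant input: normality check undefined")
  kt <- suppressWarnings(stats::ks.test(rates, "pnorm", mean = mean(rates), sd = s))
  list(statistic = unname(kt$statistic), p_like = unname(kt$p.value))
}

#' Refit the low-end tail of a binned distribution
#'
#' The worst-performing portion of a cohort often follows a power law even
#' when the body of the distribution does not. The tail is the set of classes
#' whose measured cumulative frequency is at most `cutoff` (default 0.10,
#' i.e. the bottom ~10% of the cohort). The refit compares tail shapes: both
#' the measured cumulative frequencies and the candidate model's cumulative
#' values are renormalized to end at 1 over the tail classes, and the
#' power-law and exponential exponents are refit to minimize the restricted
#' SSR (`k` remains the maximum relative frequency of the full distribution;
#' it cancels in the renormalization and is reported for reference). With
#' `cutoff = 1` the renormalization spans all ten classes and the result
#' coincides with the full [fit_power_law()] / [fit_exponential()].
#'
#' @param binned a `binned_distribution`.
#' @param cutoff cumulative measured frequency bounding the tail (default 0.10).
#' @param z_grid candidate exponents.
#' @return List of class `tail_fit`: `$power_law` and `$exponential`
#'   (`fit_result`s whose `ssr` is the tail-restricted SSR and whose
#'   `model_cum`/`residuals` are `NA`/0 outside the tail), `$cutoff`,
#'   `$classes` (logical mask of the tail classes) and `$measured_cum`
#'   (the renormalized measured tail curve).
#' @export
fit_low_end_tail <- function(binned, cutoff = 0.10, z_grid = default_z_grid()) {
  stopifnot(inherits(binned, "binned_distribution"))
  classes <- binned$cum_freq <= cutoff
  if (sum(classes) < 2L) {
    stop("fewer than 2 classes with cumulative frequency <= ", cutoff)
  }
  if (sum(binned$counts[classes]) == 0) {
    stop("no observed mass below cutoff ", cutoff, ": tail refit is degenerate")
  }
  k <- max(binned$rel_freq)
  x <- (upper_edges(binned) / 100)[classes]
  up <- upper_edges(binned)[classes]
  m_tail <- binned$cum_freq[classes]
  m_tail <- m_tail / m_tail[length(m_tail)]
  pow_cum <- function(z) { y <- x^z; cumsum(y) / sum(y) }
  exp_cum <- function(z) { y <- exp(up * z / 100); cumsum(y) / sum(y) }
  rssr <- function(model_cum) sum((model_cum - m_tail)^2)
  bp <- optimize_z(function(z) rssr(pow_cum(z)), z_grid)
  be <- optimize_z(function(z) rssr(exp_cum(z)), z_grid)
  as_fit <- function(model, params, tail_cum, ssr) {
    model_cum <- rep(NA_real_, 10L)
    model_cum[classes] <- tail_cum
    residuals <- rep(0, 10L)
    residuals[classes] <- (tail_cum - m_tail)^2
    structure(list(model = model, params = params, model_cum = model_cum,
                   residuals = residuals, ssr = ssr, classes = classes),
              class = "fit_result")
  }
  structure(list(
    power_law = as_fit("power_law", list(k = k, z = bp$z), pow_cum(bp$z), bp$ssr),
    exponential = as_fit("exponential", list(z = be$z), exp_cum(be$z), be$ssr),
    cutoff = cutoff, classes = classes, measured_cum = m_tail
  ), class = "tail_fit")
}
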