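#' Build a normative reference from a control cohort
#'
#' Scores every control session, then for each battery domain: bins the
#' response rates, runs the four-model selection (normal parameters = sample
#' mean/SD of the raw rates), fits a normal to the per-respondent mean
#' response times, and records the KS normality gate. Cohort-level summary
#' means of the per-respondent summary rate and summary time define the cut
#' lines of the quadrant classifier, and the cumulative performance curve of
#' summary rates is stored for overlay plots.
#'
#' @param control_sessions list of at least 2 [respondent_session()]s.
#' @param battery the `battery_config`.
#' @param z_grid candidate exponents for the exponential/power-law fits.
#' @return Object of class `normative_reference`: per-domain entries
#'   (`$domains[[d]]`: `rates`, `binned`, `selection`, `rate_mean`, `rate_sd`,
#'   `rate_ks`, `rt_mean`, `rt_sd`), cohort cut lines (`$mean_rate_pct`,
#'   `$mean_rt_s`), the control score table (`$scores`) and the cumulative
#'   performance curve (`$performance_curve`).
#' @export
build_reference <- function(control_sessions, battery = default_battery(),
                            z_grid = default_z_grid()) {
  if (length(control_sessions) < 2L) {
    stop("need at least 2 control sessions to build a reference")
  }
  scores <- score_cohort(control_sessions, battery)
  domains <- list()
  for (d in battery$domains$domain) {
    rates <- scores[[paste0("rate_", d)]]
    rts <- scores[[paste0("rt_", d)]]
    ok <- !is.na(rates)
    rates <- rates[ok]; rts <- rts[!is.na(rts)]
    if (length(rates) < 2L) {
      stop("domain `", d, "` has fewer than 2 observations in the control cohort")
    }
    binned <- bin_rates(rates)
    rate_mean <- mean(rates); rate_sd <- stats::sd(rates)
    sel <- select_model(binned, c(rate_mean, max(rate_sd, 1e-8)), z_grid)
    ks <- tryCatch(ks_normality(rates), error = function(e) NULL)
    domains[[d]] <- list(rates = rates, binned = binned, selection = sel,
                         rate_mean = rate_mean, rate_sd = rate_sd,
                         rate_ks = ks,
                         rt_mean = mean(rts), rt_sd = stats::sd(rts))
  }
  structure(list(
    battery = battery,
    domains = domains,
    mean_rate_pct = mean(scores$summary_rate_pct),
    mean_rt_s = mean(scores$summary_rt_s),
    scores = scores,
    performance_curve = cumulative_performance_curve_from_rates(scores$summary_rate_pct)
  ), class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("Normative reference:", nrow(x$scores), "controls\n")
  cat(sprintf("  cut lines: rate %.2f%%, time %.2f s\n", x$mean_rate_pct, x$mean_rt_s))
  for (d in names(x$domains)) {
    e <- x$domains[[d]]
    cat(sprintf("  %-18s best: %-11s (rate %.2f +- %.2f %%, time %.2f +- %.2f s)\n",
                d, e$selection$best_model, e$rate_mean, e$rate_sd, e$rt_mean, e$rt_sd))
  }
  invisible(x)
}

#' Classify a respondent on the rate-by-time plane
#'
#' The plane of summary response rate against summary response time is cut
#' into four fields by the control-cohort means: A (at least the control mean
#' rate, no slower than the control mean time), B (high rate, slower),
#' C (lower rate, fast), D (lower rate, slower). A point exactly on a cut
#' line is assigned to the better side (A-ward).
#'
#' @param summary_rate_pct respondent's summary response rate (percent).
#' @param summary_rt_s respondent's summary response time (seconds).
#' @param ref a [build_reference()] result (or any list with `mean_rate_pct`
#'   and `mean_rt_s`).
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
classify_quadrant <- function(summary_rate_pct, summary_rt_s, ref) {
  stopifnot(is.finite(summary_rate_pct), is.finite(summary_rt_s))
  high <- summary_rate_pct >= ref$mean_rate_pct
  fast <- summary_rt_s <= ref$mean_rt_s
  if (high) { if (fast) "A" else "B" } else { if (fast) "C" else "D" }
}

# Evaluate a fitted model's cumulative curve at an arbitrary rate in [0,100].
# Normal and Poisson fits have a genuine CDF; the normalized exponential /
# power-law cumulative values are defined at class upper edges only, so they
# are interpolated linearly through (0, 0), (10, c1), ..., (100, c10).
model_cdf_at <- function(fit, rate) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$model == "normal") {
    return(stats::pnorm(rate, fit$params$mean, fit$params$sd))
  }
  if (fit$model == "poisson") {
    return(stats::ppois(rate, fit$params$lambda))
  }
  stats::approx(x = seq(0, 100, 10), y = c(0, fit$model_cum),
                xout = rate, rule = 2)$y
}

#' Profile a respondent against the normative reference
#'
#' Produces the three profiling outputs: (1) a plain-text report with
#' demographics, per-domain rates and times and the overall field label;
#' (2) scatter-plot data - every control point plus the respondent's marked
#' point on the summary rate-by-time plane; (3) per-domain placements: the
#' respondent's rate located on the domain's best-fit cumulative model
#' (percentile, 0-100) and the response time as a z-score under the control
#' time distribution. The report is deterministic: identical inputs give
#' byte-identical text.
#'
#' @param session a [respondent_session()].
#' @param ref a [build_reference()] result covering the session's domains.
#' @param battery the `battery_config`.
#' @param rate_percentile_from `"model"` (default; smooth, small-cohort-robust
#'   best-fit cumulative curve) or `"empirical"` (control-cohort empirical CDF).
#' @return Object of class `quadrant_profile`: `field`, `summary_rate_pct`,
#'   `summary_rt_s`, `placements` (data.frame with `domain`, `rate_pct`,
#'   `rt_s`, `rate_percentile`, `rt_zscore`), `report` (character vector of
#'   lines) and `scatter` (data.frame of plot points).
#' @export
profile_respondent <- function(session, ref, battery = default_battery(),
                               rate_percentile_from = c("model", "empirical")) {
  rate_percentile_from <- match.arg(rate_percentile_from)
  stopifnot(inherits(ref, "normative_reference"))
  sc <- score_session(session, battery)
  missing_doms <- setdiff(sc$domains$domain, names(ref$domains))
  if (length(missing_doms)) {
    stop("domain(s) absent from reference: ", paste(missing_doms, collapse = ", "))
  }
  field <- classify_quadrant(sc$summary_rate_pct, sc$summary_rt_s, ref)

  placements <- do.call(rbind, lapply(seq_len(nrow(sc$domains)), function(i) {
    d <- sc$domains$domain[i]
    e <- ref$domains[[d]]
    rate <- sc$domains$response_rate_pct[i]
    rt <- sc$domains$mean_rt_s[i]
    pct <- if (rate_percentile_from == "model") {
      100 * model_cdf_at(e$selection$best, rate)
    } else {
      100 * mean(e$rates <= rate)
    }
    data.frame(domain = d, rate_pct = rate, rt_s = rt,
               rate_percentile = pct,
               rt_zscore = (rt - e$rt_mean) / e$rt_sd)
  }))

  scatter <- rbind(
    data.frame(respondent_id = ref$scores$respondent_id,
               summary_rate_pct = ref$scores$summary_rate_pct,
               summary_rt_s = ref$scores$summary_rt_s,
               role = "control"),
    data.frame(respondent_id = session$respondent_id,
               summary_rate_pct = sc$summary_rate_pct,
               summary_rt_s = sc$summary_rt_s,
               role = "respondent")
  )

  report <- c(
    sprintf("Respondent: %s", session$respondent_id),
    sprintf("Age: %s   Education: %s", format(session$age_years),
            format(session$education)),
    sprintf("Mouse handling time: %s",
            if (is.na(sc$mouse_time_s)) "not calibrated"
            else sprintf("%.2f s", sc$mouse_time_s)),
    "",
    sprintf("%-18s %10s %10s %12s %8s", "Domain", "rate (%)", "time (s)",
            "percentile", "time z"),
    vapply(seq_len(nrow(placements)), function(i) {
      sprintf("%-18s %10.2f %10.2f %12.1f %8.2f",
              placements$domain[i], placements$rate_pct[i], placements$rt_s[i],
              placements$rate_percentile[i], placements$rt_zscore[i])
    }, character(1L)),
    "",
    sprintf("Summary response rate: %.2f %%  (control mean %.2f %%)",
            sc$summary_rate_pct, ref$mean_rate_pct),
    sprintf("Summary response time: %.2f s  (control mean %.2f s)",
            sc$summary_rt_s, ref$mean_rt_s),
    sprintf("Field: %s", field)
  )

  structure(list(field = field,
                 summary_rate_pct = sc$summary_rate_pct,
                 summary_rt_s = sc$summary_rt_s,
                 placements = placements,
                 report = report,
                 scatter = scatter),
            class = "quadrant_profile")
}

#' @export
print.quadrant_profile <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

cumulative_performance_curve_from_rates <- function(rates, thresholds = 0:100) {
  n <- length(rates)
  data.frame(rate_threshold = thresholds,
             fraction_at_or_above = vapply(thresholds,
                                           function(t) sum(rates >= t) / n,
                                           numeric(1L)))
}

#' Cumulative performance curve of a cohort
#'
#' For each rate threshold t = 0, 1, ..., 100, the fraction of the cohort
#' whose summary response rate is at least t - a nonincreasing step curve
#' showing what share of the cohort achieved a given performance level.
#'
#' @param sessions list of at least 1 [respondent_session()].
#' @param battery the `battery_config`.
#' @return data.frame with `rate_threshold` and `fraction_at_or_above`.
#' @export
cumulative_performance_curve <- function(sessions, battery = default_battery()) {
  stopifnot(length(sessions) >= 1L)
  scores <- score_cohort(sessions, battery)
  cumulative_performance_curve_from_rates(scores$summary_rate_pct)
}
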