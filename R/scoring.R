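#' Score a session into per-domain and summary measures
#'
#' For each battery domain with at least one answered task: the response rate
#' (percent of answered tasks that were correct), the mean response time in
#' seconds, and the number answered. Absent tasks enter neither numerator nor
#' denominator. The summary score is the unweighted mean over the domains
#' present - averaging over domains, not over tasks, so a 26-task domain does
#' not outweigh a 5-task one.
#'
#' @param session a [respondent_session()].
#' @param battery the `battery_config` the session was recorded under.
#' @return A list of class `session_score` with elements
#'   \describe{
#'     \item{domains}{data.frame: `domain`, `response_rate_pct`, `mean_rt_s`,
#'       `n_answered`, `n_correct` - one row per domain with answers.}
#'     \item{summary_rate_pct}{unweighted mean of the domain rates.}
#'     \item{summary_rt_s}{unweighted mean of the domain mean times.}
#'     \item{mouse_time_s}{mean of the 9 calibration times, or `NA` when
#'       calibration was not run.}
#'     \item{skipped_domains}{battery domains with zero answered tasks.}
#'   }
#' @examples
#' b <- default_battery()
#' s <- respondent_session("r1", "control", 30, 12,
#'   data.frame(domain = "irony", task_id = as.character(1:5),
#'              correct = c(TRUE, TRUE, TRUE, TRUE, FALSE),
#'              response_time_s = rep(2, 5)),
#'   battery = b)
#' score_session(s, b)$domains$response_rate_pct  # 80
#' @export
score_session <- function(session, battery = default_battery()) {
  stopifnot(inherits(session, "respondent_session"),
            inherits(battery, "battery_config"))
  resp <- session$responses
  doms <- battery$domains$domain
  rows <- lapply(doms, function(d) {
    r <- resp[resp$domain == d, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(domain = d,
               response_rate_pct = 100 * sum(r$correct) / nrow(r),
               mean_rt_s = mean(r$response_time_s),
               n_answered = nrow(r),
               n_correct = sum(r$correct))
  })
  present <- !vapply(rows, is.null, logical(1L))
  if (!any(present)) {
    stop("session `", session$respondent_id, "` has no answered tasks in any domain")
  }
  skipped <- doms[!present]
  if (length(skipped)) {
    warning("session `", session$respondent_id, "` has no answers in domain(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  domains <- do.call(rbind, rows[present])
  rownames(domains) <- NULL
  structure(list(
    respondent_id = session$respondent_id,
    group = session$group,
    domains = domains,
    summary_rate_pct = mean(domains$response_rate_pct),
    summary_rt_s = mean(domains$mean_rt_s),
    mouse_time_s = if (is.null(session$mouse_times_s)) NA_real_ else mean(session$mouse_times_s),
    skipped_domains = skipped
  ), class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat("Session score:", x$respondent_id, "(", x$group, ")\n")
  print(x$domains, row.names = FALSE, digits = 4)
  cat(sprintf("  summary rate %.2f%%  summary time %.2f s  mouse %.2f s\n",
              x$summary_rate_pct, x$summary_rt_s, x$mouse_time_s))
  invisible(x)
}

#' Mouse-handling calibration time
#'
#' The arithmetic mean of the 9 calibration trials, used to rule out motor
#' slowing as an explanation of long task response times.
#'
#' @param session a [respondent_session()].
#' @return Mean calibration time in seconds.
#' @export
mouse_calibration <- function(session) {
  stopifnot(inherits(session, "respondent_session"))
  if (is.null(session$mouse_times_s)) {
    stop("session `", session$respondent_id,
         "` has no mouse calibration block")
  }
  mean(session$mouse_times_s)
}

#' Tabulate scores for a cohort
#'
#' Scores every session and assembles one row per respondent: demographics,
#' per-domain response rates (`rate_<domain>`) and mean response times
#' (`rt_<domain>`), the summary rate/time and the mouse calibration time.
#' Domains a respondent never answered are `NA` in their row.
#'
#' @param sessions list of [respondent_session()] objects.
#' @param battery the `battery_config`.
#' @return data.frame with one row per respondent.
#' @export
score_cohort <- function(sessions, battery = default_battery()) {
  stopifnot(length(sessions) >= 1L)
  doms <- battery$domains$domain
  rows <- lapply(sessions, function(s) {
    sc <- score_session(s, battery)
    row <- data.frame(respondent_id = sc$respondent_id, group = sc$group,
                      age_years = s$age_years, education = s$education)
    for (d in doms) {
      i <- match(d, sc$domains$domain)
      row[[paste0("rate_", d)]] <- if (is.na(i)) NA_real_ else sc$domains$response_rate_pct[i]
      row[[paste0("rt_", d)]]   <- if (is.na(i)) NA_real_ else sc$domains$mean_rt_s[i]
    }
    row$summary_rate_pct <- sc$summary_rate_pct
    row$summary_rt_s <- sc$summary_rt_s
    row$mouse_time_s <- sc$mouse_time_s
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
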