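#' Social-cognition domains
#'
#' The five domains of the default battery. All domain fields throughout the
#' package are validated against this set (or against the domains a custom
#' battery declares).
#'
#' @return Character vector of the five canonical domain names.
#' @export
domain_names <- function() {
  c("ToM", "metaphor", "irony", "social_perception", "emotional_prosody")
}

#' Battery configuration
#'
#' A battery declares which domains a test session contains, how many tasks
#' each domain has, and how many response choices each task offers.
#'
#' @param domains data.frame with columns `domain` (character, unique, drawn
#'   from [domain_names()]), `n_tasks` (positive integer) and `n_choices`
#'   (integer >= 2).
#' @return An object of class `battery_config`.
#' @seealso [default_battery()]
#' @export
battery_config <- function(domains) {
  stopifnot(is.data.frame(domains))
  req <- c("domain", "n_tasks", "n_choices")
  if (!all(req %in% names(domains))) {
    stop("battery `domains` must have columns: ", paste(req, collapse = ", "))
  }
  domains$domain <- as.character(domains$domain)
  if (anyDuplicated(domains$domain)) {
    stop("duplicate domain names in battery: ",
         paste(unique(domains$domain[duplicated(domains$domain)]), collapse = ", "))
  }
  unknown <- setdiff(domains$domain, domain_names())
  if (length(unknown)) {
    stop("unknown domain(s) in battery: ", paste(unknown, collapse = ", "))
  }
  if (any(domains$n_tasks < 1) || any(domains$n_tasks != round(domains$n_tasks))) {
    stop("n_tasks must be positive integers")
  }
  if (any(domains$n_choices < 2) || any(domains$n_choices != round(domains$n_choices))) {
    stop("n_choices must be integers >= 2")
  }
  domains$n_tasks <- as.integer(domains$n_tasks)
  domains$n_choices <- as.integer(domains$n_choices)
  structure(list(domains = domains, n_total = sum(domains$n_tasks)),
            class = "battery_config")
}

#' Default test battery
#'
#' The standard battery: 26 theory-of-mind tasks (two-choice eyes-expression
#' test), 24 emotional-prosody tasks (two-choice emotion identification from
#' spoken sentences), 9 social-perception tasks (three-choice judgments of
#' brief interpersonal scenes), and 5 irony and 5 metaphor scenarios
#' (two questions per scenario, scored as one unit each) - 69 tasks in all.
#'
#' @return A `battery_config` totalling 69 tasks.
#' @examples
#' b <- default_battery()
#' b$n_total  # 69
#' @export
default_battery <- function() {
  battery_config(data.frame(
    domain    = c("ToM", "emotional_prosody", "social_perception", "irony", "metaphor"),
    n_tasks   = c(26L, 24L, 9L, 5L, 5L),
    n_choices = c(2L, 2L, 3L, 2L, 2L)
  ))
}

#' @export
print.battery_config <- function(x, ...) {
  cat("Battery configuration:", nrow(x$domains), "domains,", x$n_total, "tasks\n")
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' Respondent session
#'
#' One person's demographics, optional mouse-handling calibration times and
#' task-level responses. Sessions are validated on construction: response
#' times must be positive, every response's domain must be declared in the
#' battery, each (domain, task_id) pair may occur at most once, and a
#' calibration block - when present - must contain exactly 9 times.
#'
#' @param respondent_id character scalar.
#' @param group one of `"control"`, `"patient"`, `"unknown"`.
#' @param age_years positive number.
#' @param education nonnegative number; unit-agnostic (years or a score),
#'   as long as a cohort uses one scale consistently.
#' @param responses data.frame with columns `domain`, `task_id`, `correct`
#'   (logical), `response_time_s` (positive seconds). May have zero rows.
#' @param mouse_times_s numeric vector of exactly 9 positive calibration
#'   times, or `NULL` when calibration was not run.
#' @param battery `battery_config` to validate against (default battery if
#'   omitted).
#' @return An object of class `respondent_session`.
#' @export
respondent_session <- function(respondent_id, group = "unknown", age_years,
                               education, responses, mouse_times_s = NULL,
                               battery = default_battery()) {
  stopifnot(is.character(respondent_id), length(respondent_id) == 1L,
            nzchar(respondent_id))
  group <- match.arg(group, c("control", "patient", "unknown"))
  if (!is.numeric(age_years) || length(age_years) != 1L || age_years <= 0) {
    stop("age_years must be a positive number")
  }
  if (!is.numeric(education) || length(education) != 1L || education < 0) {
    stop("education must be a nonnegative number")
  }
  if (!is.null(mouse_times_s)) {
    if (!is.numeric(mouse_times_s) || length(mouse_times_s) != 9L) {
      stop("mouse_times_s must contain exactly 9 calibration times (got ",
           length(mouse_times_s), ")")
    }
    if (any(mouse_times_s <= 0)) stop("mouse calibration times must be positive")
  }
  responses <- validate_responses(responses, battery)
  structure(list(respondent_id = respondent_id, group = group,
                 age_years = as.numeric(age_years),
                 education = as.numeric(education),
                 mouse_times_s = if (is.null(mouse_times_s)) NULL else as.numeric(mouse_times_s),
                 responses = responses),
            class = "respondent_session")
}

validate_responses <- function(responses, battery) {
  stopifnot(is.data.frame(responses))
  req <- c("domain", "task_id", "correct", "response_time_s")
  if (!all(req %in% names(responses))) {
    stop("responses must have columns: ", paste(req, collapse = ", "))
  }
  responses <- responses[req]
  responses$domain <- as.character(responses$domain)
  responses$task_id <- as.character(responses$task_id)
  responses$correct <- as.logical(responses$correct)
  responses$response_time_s <- as.numeric(responses$response_time_s)
  if (nrow(responses)) {
    unknown <- setdiff(responses$domain, battery$domains$domain)
    if (length(unknown)) {
      stop("response domain(s) not declared in battery: ",
           paste(unknown, collapse = ", "))
    }
    key <- paste(responses$domain, responses$task_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- responses[duplicated(key), c("domain", "task_id")][1L, ]
      stop("duplicate response for (", dup$domain, ", ", dup$task_id, ")")
    }
    if (anyNA(responses$correct)) stop("responses$correct must be TRUE/FALSE")
    if (anyNA(responses$response_time_s) || any(responses$response_time_s <= 0)) {
      stop("response_time_s must be positive")
    }
    # missing tasks are permitted (recorded as absent, not incorrect);
    # completeness is reported by read_session, not enforced here
    if (nrow(responses) > battery$n_total) {
      stop("session has more responses (", nrow(responses),
           ") than battery tasks (", battery$n_total, ")")
    }
  }
  rownames(responses) <- NULL
  responses
}

#' @export
print.respondent_session <- function(x, ...) {
  cat("Respondent session:", x$respondent_id, "(", x$group, ")\n")
  cat("  age:", x$age_years, " education:", x$education, "\n")
  cat("  responses:", nrow(x$responses), " mouse calibration:",
      if (is.null(x$mouse_times_s)) "absent" else "9 trials", "\n")
  invisible(x)
}
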