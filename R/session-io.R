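#' Read a respondent session from its result folder
#'
#' Sessions live in one folder per respondent: `demographics.json` (id, group,
#' age, education), `responses.csv` (header
#' `domain,task_id,correct,response_time_s`) and, when mouse calibration was
#' run, `mouse.csv` with 9 rows of `time_s`. The layout is deliberately
#' spreadsheet-friendly.
#'
#' Missing battery tasks are permitted: they are recorded as absent (not as
#' incorrect) and reported through a completeness warning.
#'
#' @param path folder of one respondent.
#' @param battery `battery_config` to validate against.
#' @return A validated [respondent_session()].
#' @seealso [write_session()]
#' @export
read_session <- function(path, battery = default_battery()) {
  if (!dir.exists(path)) stop("no such session folder: ", path)
  demo_file <- file.path(path, "demographics.json")
  resp_file <- file.path(path, "responses.csv")
  mouse_file <- file.path(path, "mouse.csv")
  if (!file.exists(demo_file)) stop("missing file: ", demo_file)
  if (!file.exists(resp_file)) stop("missing file: ", resp_file)

  demo <- tryCatch(jsonlite::read_json(demo_file, simplifyVector = TRUE),
                   error = function(e) {
                     stop("parse error in ", demo_file, ": ", conditionMessage(e))
                   })
  for (f in c("respondent_id", "age_years", "education")) {
    if (is.null(demo[[f]])) stop("demographics.json lacks field `", f, "` in ", demo_file)
  }

  responses <- read_responses_csv(resp_file)

  mouse <- NULL
  if (file.exists(mouse_file)) {
    mt <- tryCatch(utils::read.csv(mouse_file, strip.white = TRUE),
                   error = function(e) {
                     stop("parse error in ", mouse_file, ": ", conditionMessage(e))
                   })
    if (!"time_s" %in% names(mt)) stop(mouse_file, " must have a `time_s` column")
    mouse <- as.numeric(mt$time_s)
  }

  session <- respondent_session(
    respondent_id = as.character(demo$respondent_id),
    group = if (is.null(demo$group)) "unknown" else as.character(demo$group),
    age_years = as.numeric(demo$age_years),
    education = as.numeric(demo$education),
    responses = responses,
    mouse_times_s = mouse,
    battery = battery
  )
  if (nrow(session$responses) < battery$n_total) {
    warning("session `", session$respondent_id, "` is incomplete: ",
            nrow(session$responses), " of ", battery$n_total,
            " battery tasks answered", call. = FALSE)
  }
  session
}

read_responses_csv <- function(file) {
  raw <- tryCatch(
    utils::read.csv(file, strip.white = TRUE, colClasses = "character"),
    error = function(e) stop("parse error in ", file, ": ", conditionMessage(e))
  )
  req <- c("domain", "task_id", "correct", "response_time_s")
  if (!all(req %in% names(raw))) {
    stop(file, " must have header: ", paste(req, collapse = ","))
  }
  correct <- as.logical(raw$correct)
  rt <- suppressWarnings(as.numeric(raw$response_time_s))
  bad <- which(is.na(correct) | is.na(rt))
  if (length(bad)) {
    # +1 for the header row, so the number matches the file line
    stop("parse error in ", file, ", line ", bad[1L] + 1L,
         ": missing or malformed value")
  }
  raw$correct <- correct
  raw$response_time_s <- rt
  raw
}

#' Write a respondent session to a result folder
#'
#' Inverse of [read_session()]: creates `<parent>/<respondent_id>/` containing
#' `demographics.json`, `responses.csv` and (when calibration is present)
#' `mouse.csv`. A session without calibration omits `mouse.csv` entirely.
#'
#' @param session a [respondent_session()].
#' @param parent directory under which the respondent folder is created.
#' @param overwrite overwrite an existing folder for the same respondent?
#'   Defaults to `FALSE`, in which case a collision is an error.
#' @return Invisibly, the path of the written folder.
#' @export
write_session <- function(session, parent, overwrite = FALSE) {
  stopifnot(inherits(session, "respondent_session"))
  if (!dir.exists(parent)) {
    dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  }
  dest <- file.path(parent, session$respondent_id)
  if (dir.exists(dest)) {
    if (!overwrite) {
      stop("session folder already exists: ", dest,
           " (use overwrite = TRUE to replace it)")
    }
    unlink(dest, recursive = TRUE)
  }
  dir.create(dest)
  # %.17g: shortest decimal form that reconstructs the double exactly,
  # so write_session / read_session round-trips field-for-field
  num17 <- function(x) sub("^(-?\\d+)$", "\\1", sprintf("%.17g", x))
  writeLines(c(
    "{",
    sprintf('  "respondent_id": %s,', jsonlite::toJSON(session$respondent_id, auto_unbox = TRUE)),
    sprintf('  "group": "%s",', session$group),
    sprintf('  "age_years": %s,', num17(session$age_years)),
    sprintf('  "education": %s', num17(session$education)),
    "}"
  ), file.path(dest, "demographics.json"))
  resp_out <- session$responses
  resp_out$response_time_s <- num17(resp_out$response_time_s)
  utils::write.csv(resp_out, file.path(dest, "responses.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(session$mouse_times_s)) {
    utils::write.csv(data.frame(time_s = num17(session$mouse_times_s)),
                     file.path(dest, "mouse.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(dest)
}

#' Read every session folder under a directory
#'
#' @param parent directory whose sub-folders each hold one respondent.
#' @param battery `battery_config` to validate against.
#' @return List of [respondent_session()] objects, in folder-name order.
#' @export
read_cohort <- function(parent, battery = default_battery()) {
  dirs <- list.dirs(parent, recursive = FALSE)
  if (!length(dirs)) stop("no session folders under ", parent)
  lapply(sort(dirs), read_session, battery = battery)
}

#' Write a list of sessions as folder-per-respondent layout
#'
#' @param sessions list of [respondent_session()] objects.
#' @param parent directory under which the folders are created.
#' @param overwrite passed to [write_session()].
#' @return Invisibly, the written folder paths.
#' @export
write_cohort <- function(sessions, parent, overwrite = FALSE) {
  invisible(vapply(sessions, write_session, character(1L),
                   parent = parent, overwrite = overwrite))
}
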