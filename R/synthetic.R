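#' Rate models for the synthetic generator
#'
#' A domain's response-rate distribution on the percent scale, in one of the
#' three shapes the normative fitting distinguishes: `power_law_model(k, z)`
#' (mass concentrated near 100, zero mass at 0), `exponential_model(z)`
#' (steep but with nonzero mass at zero performance) and
#' `normal_model(mean, sd)` (symmetric around a central tendency).
#'
#' @param k power-law constant (maximum relative frequency, in (0, 1]).
#' @param z positive exponent.
#' @param mean,sd normal parameters on the percent scale.
#' @return A `rate_model` object.
#' @name rate_models
NULL

#' @rdname rate_models
#' @export
power_law_model <- function(k, z) {
  stopifnot(k > 0, k <= 1, z > 0)
  structure(list(kind = "power_law", k = k, z = z), class = "rate_model")
}

#' @rdname rate_models
#' @export
exponential_model <- function(z) {
  stopifnot(z > 0)
  structure(list(kind = "exponential", z = z), class = "rate_model")
}

#' @rdname rate_models
#' @export
normal_model <- function(mean, sd) {
  stopifnot(is.finite(mean), sd > 0)
  structure(list(kind = "normal", mean = mean, sd = sd), class = "rate_model")
}

# Normalized probability mass of the ten 10%-classes under a rate model,
# evaluated the same way the fitting side evaluates its candidates (power law
# and exponential at class upper edges; normal as CDF mass within the class).
rate_class_masses <- function(model) {
  up <- seq(10, 100, by = 10)
  y <- switch(model$kind,
    power_law   = model$k * (up / 100)^model$z,
    exponential = exp(up * model$z / 100),
    normal      = stats::pnorm(up, model$mean, model$sd) -
                  stats::pnorm(up - 10, model$mean, model$sd)
  )
  y / sum(y)
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: the cohort size, one rate
#' model and one response-time model (normal, truncated at 0.2 s) per battery
#' domain, a mouse-calibration time model, demographic ranges and the group
#' label. Use [control_cohort_spec()] / [patient_cohort_spec()] for the
#' presets that mirror the published control and patient cohorts.
#'
#' @param n cohort size.
#' @param rate_models named list (one per battery domain) of `rate_model`s.
#' @param time_models named list (one per battery domain) of `list(mean, sd)`
#'   response-time parameters in seconds; `sd` may be 0 (degenerate).
#' @param mouse_model `list(mean, sd)` for the 9 calibration times.
#' @param age_range,education_range length-2 numeric ranges; demographics are
#'   drawn uniformly within them.
#' @param group `"control"` or `"patient"`.
#' @param seed integer seed making the cohort reproducible.
#' @param battery the `battery_config` the cohort completes.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, rate_models, time_models, mouse_model,
                        age_range, education_range,
                        group = c("control", "patient"), seed = 1L,
                        battery = default_battery()) {
  group <- match.arg(group)
  stopifnot(n >= 1, n == round(n))
  doms <- battery$domains$domain
  if (!setequal(names(rate_models), doms)) {
    stop("rate_models must be named by the battery domains: ",
         paste(doms, collapse = ", "))
  }
  if (!setequal(names(time_models), doms)) {
    stop("time_models must be named by the battery domains")
  }
  for (m in rate_models) stopifnot(inherits(m, "rate_model"))
  for (tm in time_models) {
    if (!is.numeric(tm$mean) || tm$mean <= 0 || !is.numeric(tm$sd) || tm$sd < 0) {
      stop("time models need mean > 0 and sd >= 0")
    }
  }
  if (mouse_model$mean <= 0 || mouse_model$sd < 0) stop("invalid mouse_model")
  stopifnot(length(age_range) == 2L, age_range[1] > 0, diff(age_range) >= 0,
            length(education_range) == 2L, education_range[1] >= 0,
            diff(education_range) >= 0)
  structure(list(n = as.integer(n), rate_models = rate_models[doms],
                 time_models = time_models[doms], mouse_model = mouse_model,
                 age_range = as.numeric(age_range),
                 education_range = as.numeric(education_range),
                 group = group, seed = as.integer(seed), battery = battery),
            class = "cohort_spec")
}

#' Preset cohort specifications
#'
#' Ready-made `cohort_spec`s mirroring the published cohorts. The control
#' preset (n = 101) uses the fitted normative rate models - theory of mind
#' normal(85.68, 8.70); metaphor power-law(0.75, 12); irony exponential(12.7);
#' social perception power-law(0.71, 9); emotional prosody
#' power-law(0.69, 11) - and the control response-time means/SDs. The patient
#' preset (n = 86) uses normal rate models for theory of mind (74.88, 12.88),
#' metaphor (69.99, 25.35) and irony (58.74, 18.31) and power laws for social
#' perception (0.39, 2.3) and emotional prosody (0.36, 3.3), with the patient
#' time parameters. Demographic ranges give the control cohort wider age and
#' education spreads than the patients, so threshold trimming has work to do.
#'
#' @param n cohort size (defaults: 101 controls, 86 patients).
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @name cohort_presets
NULL

#' @rdname cohort_presets
#' @export
control_cohort_spec <- function(n = 101L, seed = 1L) {
  cohort_spec(
    n = n,
    rate_models = list(
      ToM               = normal_model(85.68, 8.70),
      metaphor          = power_law_model(0.75, 12),
      irony             = exponential_model(12.7),
      social_perception = power_law_model(0.71, 9),
      emotional_prosody = power_law_model(0.69, 11)
    ),
    time_models = list(
      ToM               = list(mean = 7.30, sd = 2.44),
      metaphor          = list(mean = 6.31, sd = 2.22),
      irony             = list(mean = 3.54, sd = 1.30),
      social_perception = list(mean = 9.02, sd = 2.54),
      emotional_prosody = list(mean = 3.76, sd = 1.24)
    ),
    mouse_model = list(mean = 3.11, sd = 2.05),
    age_range = c(20, 60),
    education_range = c(9, 30),
    group = "control",
    seed = seed
  )
}

#' @rdname cohort_presets
#' @export
patient_cohort_spec <- function(n = 86L, seed = 2L) {
  cohort_spec(
    n = n,
    rate_models = list(
      ToM               = normal_model(74.88, 12.88),
      metaphor          = normal_model(69.99, 25.35),
      irony             = normal_model(58.74, 18.31),
      social_perception = power_law_model(0.39, 2.3),
      emotional_prosody = power_law_model(0.36, 3.3)
    ),
    time_models = list(
      ToM               = list(mean = 9.49, sd = 7.36),
      metaphor          = list(mean = 9.34, sd = 5.24),
      irony             = list(mean = 6.84, sd = 4.71),
      social_perception = list(mean = 15.01, sd = 6.04),
      emotional_prosody = list(mean = 5.51, sd = 2.55)
    ),
    mouse_model = list(mean = 3.66, sd = 1.57),
    age_range = c(23, 49),
    education_range = c(8, 15),
    group = "patient",
    seed = seed
  )
}

# Normal draws truncated below at `floor` by rejection (vectorized resampling).
rtruncnorm_floor <- function(n, mean, sd, floor = 0.2) {
  if (sd == 0) return(rep(max(mean, floor), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Simulate a cohort of respondent sessions
#'
#' For every respondent and domain, a target response rate is drawn from the
#' domain's rate model (a 10%-class is sampled from the model's normalized
#' class masses, then a rate uniformly within that class). The target is
#' realized over the domain's tasks by marking `round(n_tasks * rate / 100)`
#' randomly chosen tasks correct, so the realized rate equals the target up
#' to the achievable `1/n_tasks` grid and the cohort's observed rate
#' distribution follows the specified model. Response times are drawn per
#' task from the domain's normal time model truncated at 0.2 s, mouse
#' calibration times (9 trials) from the mouse model, and demographics
#' uniformly within the specified ranges. Rate and time are drawn
#' independently. Fully reproducible given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return List of `spec$n` [respondent_session()] objects.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  battery <- spec$battery
  doms <- battery$domains$domain
  n_tasks <- stats::setNames(battery$domains$n_tasks, doms)
  masses <- lapply(spec$rate_models, rate_class_masses)
  prefix <- if (spec$group == "control") "ctrl" else "pat"

  lapply(seq_len(spec$n), function(i) {
    resp <- do.call(rbind, lapply(doms, function(d) {
      nt <- n_tasks[[d]]
      cl <- sample.int(10L, 1L, prob = masses[[d]])
      rate <- stats::runif(1L, (cl - 1L) * 10, cl * 10)
      n_correct <- round(nt * rate / 100)
      correct <- rep(FALSE, nt)
      if (n_correct > 0) correct[sample.int(nt, n_correct)] <- TRUE
      tm <- spec$time_models[[d]]
      data.frame(domain = d,
                 task_id = sprintf("%s_%02d", d, seq_len(nt)),
                 correct = correct,
                 response_time_s = rtruncnorm_floor(nt, tm$mean, tm$sd))
    }))
    respondent_session(
      respondent_id = sprintf("%s%03d", prefix, i),
      group = spec$group,
      age_years = stats::runif(1L, spec$age_range[1], spec$age_range[2]),
      education = stats::runif(1L, spec$education_range[1], spec$education_range[2]),
      responses = resp,
      mouse_times_s = rtruncnorm_floor(9L, spec$mouse_model$mean, spec$mouse_model$sd),
      battery = battery
    )
  })
}

#' The published worked-example binned distribution
#'
#' The exact printed control-cohort emotional-prosody class counts used as
#' the worked example of the SSR procedure: 5 respondents in (70, 80],
#' 26 in (80, 90] and 70 in (90, 100], n = 101.
#'
#' @return A `binned_distribution` with counts (0, ..., 0, 5, 26, 70).
#' @export
table2_fixture <- function() {
  binned_distribution(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 5L, 26L, 70L))
}
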