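# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# A full-battery session with a given number of correct answers and a constant
# response time per domain.
make_session <- function(id = "r1", group = "control",
                         n_correct = c(ToM = 26, emotional_prosody = 24,
                                       social_perception = 9, irony = 5, metaphor = 5),
                         rt = c(ToM = 2, emotional_prosody = 2,
                                social_perception = 2, irony = 2, metaphor = 2),
                         age = 30, education = 12, mouse = rep(3, 9),
                         battery = default_battery()) {
  resp <- do.call(rbind, lapply(battery$domains$domain, function(d) {
    nt <- battery$domains$n_tasks[battery$domains$domain == d]
    nc <- n_correct[[d]]
    data.frame(domain = d,
               task_id = sprintf("%s_%02d", d, seq_len(nt)),
               correct = seq_len(nt) <= nc,
               response_time_s = rep(rt[[d]], nt))
  }))
  respondent_session(id, group, age, education, resp,
                     mouse_times_s = mouse, battery = battery)
}

# A session with randomized correctness/times under the current RNG state.
random_session <- function(id, group = "control", battery = default_battery(),
                           mouse = TRUE) {
  resp <- do.call(rbind, lapply(battery$domains$domain, function(d) {
    nt <- battery$domains$n_tasks[battery$domains$domain == d]
    data.frame(domain = d,
               task_id = sprintf("%s_%02d", d, seq_len(nt)),
               correct = runif(nt) < runif(1),
               response_time_s = runif(nt, 0.5, 12))
  }))
  respondent_session(id, group,
                     age_years = runif(1, 18, 70),
                     education = runif(1, 0, 25),
                     responses = resp,
                     mouse_times_s = if (mouse) runif(9, 0.5, 8) else NULL,
                     battery = battery)
}

# Independent SSR oracle: recompute the sum of squared residuals directly
# from a fit's cumulative curve and the measured cumulative frequencies.
oracle_ssr <- function(fit, binned, classes = NULL) {
  if (is.null(classes)) classes <- rep(TRUE, 10)
  sum(((binned$cum_freq - fit$model_cum)^2)[classes])
}

# Independent exhaustive grid-search oracle for the exponent fits.
oracle_argmin_z <- function(binned, kind, grid = seq(0.1, 30, by = 0.1),
                            classes = rep(TRUE, 10)) {
  up <- binned$class_edges[-1]
  cum <- binned$cum_freq
  k <- max(binned$rel_freq)
  ssr <- vapply(grid, function(z) {
    y <- if (kind == "power_law") k * (up / 100)^z else exp(up * z / 100)
    mc <- cumsum(y) / sum(y)
    sum(((mc - cum)^2)[classes])
  }, numeric(1))
  list(z = grid[which.min(ssr)], ssr = min(ssr))
}

random_binned <- function() {
  binned_distribution(c(rmultinom(1, sample(20:400, 1), prob = runif(10))))
}
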