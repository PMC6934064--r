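#' Compare two cohorts variable by variable
#'
#' For each shared numeric score column, a normality gate (KS statistic of
#' each group against a normal with its sample moments) chooses the test:
#' when both groups pass (p > 0.05) an independent two-sample t test compares
#' means; otherwise a rank-based test (Kruskal-Wallis, which for two groups
#' is the Mann-Whitney test up to statistic convention) compares the groups.
#' The Bonferroni flag marks p-values below `alpha / m`, with `m` the number
#' of variables compared (5 domain rates at `alpha = 0.05` gives the
#' conventional 0.01 threshold).
#'
#' @param cg_scores,sg_scores data.frames of per-respondent scores (e.g. from
#'   [score_cohort()]); every shared numeric column except identifiers is
#'   compared.
#' @param alpha family significance level (default 0.05).
#' @param variables optional character vector naming the columns to compare;
#'   defaults to all shared numeric columns.
#' @return data.frame of class `group_comparison`: one row per variable with
#'   `variable`, `test` ("t" or "rank"), `statistic`, `p_value`,
#'   `mean_cg`, `mean_sg`, `significant_after_bonferroni`; the Bonferroni
#'   threshold is attached as attribute `bonferroni_threshold`.
#' @export
compare_groups <- function(cg_scores, sg_scores, alpha = 0.05, variables = NULL) {
  stopifnot(is.data.frame(cg_scores), is.data.frame(sg_scores))
  if (nrow(cg_scores) < 2L || nrow(sg_scores) < 2L) {
    stop("both groups need at least 2 members")
  }
  if (is.null(variables)) {
    shared <- intersect(names(cg_scores), names(sg_scores))
    variables <- shared[vapply(shared, function(v) {
      is.numeric(cg_scores[[v]]) && is.numeric(sg_scores[[v]])
    }, logical(1L))]
    variables <- setdiff(variables, c("respondent_id"))
  }
  if (!length(variables)) stop("no shared numeric variables to compare")
  thr <- alpha / length(variables)

  rows <- lapply(variables, function(v) {
    x <- cg_scores[[v]]; y <- sg_scores[[v]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      stop("variable `", v, "` has fewer than 2 observations in a group")
    }
    gate <- function(u) {
      ks <- tryCatch(ks_normality(u), error = function(e) NULL)
      !is.null(ks) && ks$p_like > 0.05
    }
    if (gate(x) && gate(y)) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      g <- factor(rep(c("cg", "sg"), c(length(x), length(y))))
      kw <- stats::kruskal.test(c(x, y), g)
      test <- "rank"; statistic <- unname(kw$statistic); p <- kw$p.value
    }
    data.frame(variable = v, test = test, statistic = statistic,
               p_value = p, mean_cg = mean(x), mean_sg = mean(y),
               significant_after_bonferroni = p < thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Bonferroni threshold p <",
      format(attr(x, "bonferroni_threshold"), digits = 3), ")\n")
  y <- as.data.frame(x)
  y$p_value <- round(y$p_value, 3)
  y$statistic <- round(y$statistic, 3)
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}

extract_demographics <- function(x, what) {
  if (is.data.frame(x)) {
    col <- switch(what, age = "age_years", education = "education")
    if (!col %in% names(x)) stop("data.frame lacks column `", col, "`")
    return(x[[col]])
  }
  vapply(x, function(s) {
    stopifnot(inherits(s, "respondent_session"))
    if (what == "age") s$age_years else s$education
  }, numeric(1L))
}

subset_cohort <- function(x, keep) {
  if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
}

#' Create matched subgroups by threshold trimming
#'
#' Two-stage trimming that equates cohorts on education and age. Stage 1:
#' the highest education in the patient group and the lowest in the control
#' group become the upper and lower thresholds, and members of either group
#' strictly outside `[low, high]` are removed (boundary members are
#' retained). Stage 2 applies the same rule to age on the stage-1 survivors.
#' Because removing a member can tighten the data-driven thresholds, the
#' education-then-age pass is repeated until no further member is removed;
#' the returned subgroups are therefore a fixed point, and reapplying the
#' procedure to its own output changes nothing. Cohorts already inside both
#' bands pass through unchanged.
#'
#' @param cg,sg control and patient cohorts: either lists of
#'   [respondent_session()]s or data.frames with `age_years` and `education`
#'   columns.
#' @return List of class `matched_subgroups`: trimmed `cg` and `sg` (same
#'   type as the input), `thresholds` (named numeric, from the final pass:
#'   `edu_low`, `edu_high`, `age_low`, `age_high`) and the retained index
#'   vectors `cg_kept`, `sg_kept` (into the original cohorts).
#' @export
match_subgroups <- function(cg, sg) {
  n_cg <- if (is.data.frame(cg)) nrow(cg) else length(cg)
  n_sg <- if (is.data.frame(sg)) nrow(sg) else length(sg)
  if (n_cg < 1L || n_sg < 1L) stop("both cohorts must be nonempty")

  edu_cg_all <- extract_demographics(cg, "education")
  edu_sg_all <- extract_demographics(sg, "education")
  age_cg_all <- extract_demographics(cg, "age")
  age_sg_all <- extract_demographics(sg, "age")

  cg_kept <- seq_len(n_cg)
  sg_kept <- seq_len(n_sg)
  thresholds <- NULL
  repeat {
    edu_high <- max(edu_sg_all[sg_kept])
    edu_low <- min(edu_cg_all[cg_kept])
    k1_cg <- cg_kept[edu_cg_all[cg_kept] >= edu_low & edu_cg_all[cg_kept] <= edu_high]
    k1_sg <- sg_kept[edu_sg_all[sg_kept] >= edu_low & edu_sg_all[sg_kept] <= edu_high]
    if (!length(k1_cg) || !length(k1_sg)) {
      stop("education trimming (stage 1) emptied the ",
           if (!length(k1_cg)) "control" else "patient", " group")
    }
    age_high <- max(age_sg_all[k1_sg])
    age_low <- min(age_cg_all[k1_cg])
    k2_cg <- k1_cg[age_cg_all[k1_cg] >= age_low & age_cg_all[k1_cg] <= age_high]
    k2_sg <- k1_sg[age_sg_all[k1_sg] >= age_low & age_sg_all[k1_sg] <= age_high]
    if (!length(k2_cg) || !length(k2_sg)) {
      stop("age trimming (stage 2) emptied the ",
           if (!length(k2_cg)) "control" else "patient", " group")
    }
    thresholds <- c(edu_low = edu_low, edu_high = edu_high,
                    age_low = age_low, age_high = age_high)
    converged <- length(k2_cg) == length(cg_kept) && length(k2_sg) == length(sg_kept)
    cg_kept <- k2_cg
    sg_kept <- k2_sg
    if (converged) break
  }

  structure(list(
    cg = subset_cohort(cg, cg_kept),
    sg = subset_cohort(sg, sg_kept),
    thresholds = thresholds,
    cg_kept = cg_kept, sg_kept = sg_kept
  ), class = "matched_subgroups")
}

#' @export
print.matched_subgroups <- function(x, ...) {
  t <- x$thresholds
  cat("Matched subgroups\n")
  cat(sprintf("  education band [%g, %g], age band [%g, %g]\n",
              t["edu_low"], t["edu_high"], t["age_low"], t["age_high"]))
  n <- function(g) if (is.data.frame(g)) nrow(g) else length(g)
  cat(sprintf("  retained: %d controls, %d patients\n", n(x$cg), n(x$sg)))
  invisible(x)
}
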