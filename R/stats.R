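# Endpoint comparison engines for the trial's analysis plan. Test
# selection mirrors common clinical practice: a Shapiro-Wilk gate at
# alpha = 0.05 on every relevant vector chooses between the parametric
# test and its rank-based counterpart, and descriptives switch between
# mean +/- SD and median (Q1-Q3) accordingly. All tests are two-sided at
# alpha = 0.05 unless overridden.

shapiro_ok <- function(x, alpha = 0.05) {
  # constant vectors cannot be normal; Shapiro needs 3 <= n <= 5000 --
  # below that we cannot certify normality and fall back to ranks
  if (length(x) < 3 || length(x) > 5000) return(FALSE)
  if (sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value > alpha
}

describe_group <- function(x, group, parametric) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    group = group, n = length(x),
    mean = mean(x), sd = sd(x),
    median = q[2], q1 = q[1], q3 = q[3],
    summary = if (parametric) {
      sprintf("%.2f ± %.2f", mean(x), sd(x))
    } else {
      sprintf("%.2f (%.2f–%.2f)", q[2], q[1], q[3])
    }
  )
}

new_comparison <- function(design, test_used, statistic, p_value,
                           descriptives, parametric, alpha = 0.05,
                           notes = character(), extra = list()) {
  structure(
    c(list(design = design, test_used = test_used,
           statistic = unname(statistic), p_value = unname(p_value),
           descriptives = descriptives, parametric = parametric,
           alpha = alpha, two_tailed = TRUE, notes = notes),
      extra),
    class = "fbn_comparison"
  )
}

#' @export
print.fbn_comparison <- function(x, ...) {
  cat("<fbn_comparison> ", x$design, " design: ", x$test_used, "\n", sep = "")
  for (i in seq_len(nrow(x$descriptives))) {
    cat("  ", x$descriptives$group[i], " (n=", x$descriptives$n[i], "): ",
        x$descriptives$summary[i], "\n", sep = "")
  }
  cat(sprintf("  statistic = %.4g, p = %.4g (two-tailed, alpha = %g)\n",
              x$statistic, x$p_value, x$alpha))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Tidy a comparison result
#'
#' @param x An `fbn_comparison` as returned by [compare_independent()],
#'   [compare_paired()], [compare_longitudinal()] or
#'   [compare_categorical()].
#' @param ... Unused.
#' @return A one-row tibble: `design`, `test_used`, `statistic`,
#'   `p_value`, `parametric`, `n`, `significant`.
#' @export
tidy.fbn_comparison <- function(x, ...) {
  tibble::tibble(
    design = x$design,
    test_used = x$test_used,
    statistic = x$statistic,
    p_value = x$p_value,
    parametric = x$parametric,
    n = sum(x$descriptives$n),
    significant = x$p_value < x$alpha
  )
}

#' @rdname tidy.fbn_comparison
#' @export
glance.fbn_comparison <- function(x, ...) tidy.fbn_comparison(x, ...)

#' Between-group comparison of a continuous endpoint
#'
#' Independent two-sample contrast with a normality gate: Student's t test
#' (pooled variance, two-sided) when both groups pass Shapiro-Wilk at
#' alpha = 0.05, otherwise the Mann-Whitney U test. Descriptives are
#' mean +/- SD or median (Q1-Q3) accordingly.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param labels Group names for reporting.
#' @param alpha Significance level (default 0.05, two-tailed).
#' @return An `fbn_comparison`.
#' @export
compare_independent <- function(values_a, values_b,
                                labels = c("treatment", "control"),
                                alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs n >= 2.", class = "sleepfbn_insufficient_data")
  }
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    abort("degenerate data: both groups constant with equal means.",
          class = "sleepfbn_degenerate_data")
  }
  parametric <- shapiro_ok(a, alpha) && shapiro_ok(b, alpha)
  if (parametric) {
    res <- t.test(a, b, var.equal = TRUE)
    test_used <- "Student's t (pooled variance)"
    stat <- res$statistic
  } else {
    res <- suppressWarnings(wilcox.test(a, b))
    test_used <- "Mann–Whitney U"
    stat <- res$statistic
  }
  new_comparison(
    "independent", test_used, stat, res$p.value,
    dplyr::bind_rows(describe_group(a, labels[1], parametric),
                     describe_group(b, labels[2], parametric)),
    parametric, alpha
  )
}

#' Paired baseline-vs-follow-up comparison
#'
#' Paired contrast on the within-subject differences with a normality
#' gate: paired Student's t when the differences pass Shapiro-Wilk at
#' alpha = 0.05, otherwise the Wilcoxon signed-rank test.
#'
#' @param before,after Equal-length paired numeric vectors, n >= 2.
#' @param labels Names of the two conditions for reporting.
#' @inheritParams compare_independent
#' @return An `fbn_comparison`.
#' @export
compare_paired <- function(before, after,
                           labels = c("baseline", "follow-up"),
                           alpha = 0.05) {
  x <- as.numeric(before); y <- as.numeric(after)
  if (length(x) != length(y)) {
    abort("`before` and `after` must be paired (equal length).",
          class = "sleepfbn_pairing")
  }
  if (length(x) < 2) {
    abort("need n >= 2 pairs.", class = "sleepfbn_insufficient_data")
  }
  d <- y - x
  if (all(d == 0)) {
    abort("degenerate data: all paired differences are zero.",
          class = "sleepfbn_degenerate_data")
  }
  if (sd(d) == 0) {
    abort("degenerate data: paired differences have zero variance (undefined t).",
          class = "sleepfbn_degenerate_data")
  }
  parametric <- shapiro_ok(d, alpha)
  if (parametric) {
    res <- t.test(y, x, paired = TRUE)
    test_used <- "paired Student's t"
  } else {
    res <- suppressWarnings(wilcox.test(y, x, paired = TRUE))
    test_used <- "Wilcoxon signed-rank"
  }
  new_comparison(
    "paired", test_used, res$statistic, res$p.value,
    dplyr::bind_rows(describe_group(x, labels[1], parametric),
                     describe_group(y, labels[2], parametric)),
    parametric, alpha,
    extra = list(mean_difference = mean(d))
  )
}

# Greenhouse-Geisser epsilon from the double-centered covariance of the
# subject x timepoint matrix, and its Huynh-Feldt modification (capped at 1).
sphericity_epsilon <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  S <- cov(Y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  gg <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  hf <- min(1, (n * (k - 1) * gg - 2) / ((k - 1) * ((n - 1) - (k - 1) * gg)))
  list(gg = gg, hf = max(hf, gg))
}

#' Longitudinal comparison across timepoints
#'
#' One-way repeated-measures ANOVA on one measure across the ordered
#' timepoints of a long-format score table, on subjects with complete
#' data. Sphericity is handled by adjusting the F degrees of freedom with
#' the Huynh-Feldt epsilon by default; Greenhouse-Geisser and no
#' correction are available. With two timepoints the result reduces
#' exactly to the paired t test (F = t^2).
#'
#' @param data Long-format data frame with one row per subject x
#'   timepoint (x measure).
#' @param measure Measure name to analyze (ignored with a message if
#'   `data` has no `measure` column).
#' @param subject,timepoint,value Column names (tidy-eval) holding the
#'   subject id, the timepoint label, and the score.
#' @param sphericity `"huynh-feldt"` (default), `"greenhouse-geisser"`, or
#'   `"none"`.
#' @inheritParams compare_independent
#' @return An `fbn_comparison` with the F statistic, epsilon-adjusted
#'   degrees of freedom and p-value.
#' @export
compare_longitudinal <- function(data, measure = NULL,
                                 subject = "subject_id",
                                 timepoint = "timepoint",
                                 value = "value",
                                 sphericity = c("huynh-feldt",
                                                "greenhouse-geisser", "none"),
                                 alpha = 0.05) {
  sphericity <- match.arg(sphericity)
  df <- as.data.frame(data)
  if (!is.null(measure) && "measure" %in% names(df)) {
    df <- df[df$measure == measure, , drop = FALSE]
    if (nrow(df) == 0) {
      abort(sprintf("measure '%s' not found in `data`.", measure),
            class = "sleepfbn_invalid_input")
    }
  }
  tp <- df[[timepoint]]
  levels_tp <- if (is.factor(tp)) levels(tp)[levels(tp) %in% tp] else unique(tp)
  Y <- tidyr::pivot_wider(
    tibble::tibble(.s = df[[subject]], .t = factor(tp, levels = levels_tp),
                   .v = df[[value]]),
    names_from = ".t", values_from = ".v"
  )
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  mat <- as.matrix(Y[, -1, drop = FALSE])
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2) {
    abort("need at least two timepoints.", class = "sleepfbn_insufficient_data")
  }
  if (n < 3) {
    abort(sprintf("insufficient data: %d subject(s) with complete data, need >= 3.", n),
          class = "sleepfbn_insufficient_data")
  }
  subj_m <- rowMeans(mat); time_m <- colMeans(mat); g <- mean(mat)
  ss_time <- n * sum((time_m - g)^2)
  ss_err <- sum((mat - outer(subj_m, rep(1, k)) -
                   outer(rep(1, n), time_m) + g)^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (ss_err == 0) {
    abort("degenerate data: zero within-subject error variance.",
          class = "sleepfbn_degenerate_data")
  }
  Fv <- (ss_time / df1) / (ss_err / df2)
  eps <- switch(sphericity,
                "none" = 1,
                "greenhouse-geisser" = sphericity_epsilon(mat)$gg,
                "huynh-feldt" = sphericity_epsilon(mat)$hf)
  if (k == 2) eps <- 1  # single contrast: sphericity holds trivially
  p <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  desc <- purrr::map_dfr(seq_len(k), function(j) {
    describe_group(mat[, j], colnames(mat)[j], TRUE)
  })
  corr_lab <- switch(sphericity, "none" = "uncorrected",
                     "greenhouse-geisser" = "Greenhouse–Geisser",
                     "huynh-feldt" = "Huynh–Feldt")
  new_comparison(
    "longitudinal",
    paste0("one-way repeated-measures ANOVA (", corr_lab, ")"),
    Fv, p, desc, TRUE, alpha,
    notes = sprintf("epsilon = %.3f, df = (%.2f, %.2f), %d complete subjects",
                    eps, df1 * eps, df2 * eps, n),
    extra = list(epsilon = eps, df1 = df1 * eps, df2 = df2 * eps,
                 n_subjects = n)
  )
}

#' Categorical between-group comparison
#'
#' Pearson's chi-squared test without continuity correction on a groups x
#' categories count table (the statistic is the classical
#' sum of (O-E)^2/E). When any expected cell count falls below 5 the
#' result carries a note; Fisher's exact test can be requested instead of
#' or conditional on that event.
#'
#' @param counts Matrix of non-negative integer counts, groups in rows.
#' @param exact `"never"` (default: always Pearson), `"auto"` (Fisher when
#'   any expected count < 5), or `"always"`.
#' @inheritParams compare_independent
#' @return An `fbn_comparison`.
#' @export
compare_categorical <- function(counts, exact = c("never", "auto", "always"),
                                alpha = 0.05) {
  exact <- match.arg(exact)
  counts <- as.matrix(counts)
  if (length(counts) == 0 || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    abort("`counts` must be a non-empty matrix of non-negative integers.",
          class = "sleepfbn_invalid_input")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("`counts` has an empty row or column.",
          class = "sleepfbn_invalid_input")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low_expected <- any(expected < 5)
  notes <- character()
  use_fisher <- exact == "always" || (exact == "auto" && low_expected)
  if (use_fisher) {
    res <- fisher.test(counts)
    test_used <- "Fisher's exact"
    stat <- NA_real_
    if (exact == "auto") {
      notes <- "Fisher's exact substituted: expected cell count < 5"
    }
  } else {
    res <- suppressWarnings(chisq.test(counts, correct = FALSE))
    test_used <- "Pearson chi-squared"
    stat <- res$statistic
    if (low_expected) notes <- "expected cell count < 5; interpret with care"
  }
  desc <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    tibble::tibble(group = rownames(counts)[i] %||% paste0("group", i),
                   n = sum(counts[i, ]), mean = NA_real_, sd = NA_real_,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   summary = paste(counts[i, ], collapse = "/"))
  })
  new_comparison("categorical", test_used, stat, res$p.value, desc,
                 FALSE, alpha, notes = notes)
}

#' Percent change between two means
#'
#' `100 * (followup - baseline) / baseline`, the convention used for
#' reporting volumetric change between baseline and follow-up group means.
#'
#' @param baseline_mean Baseline mean (> 0).
#' @param followup_mean Follow-up mean.
#' @param digits Decimal places for the returned value; `NULL` for the
#'   exact value. Reports use 2.
#' @return Percent change (a plain number; 1.51 means +1.51%).
#' @export
#' @examples
#' percent_change(614239.25, 623498.50)  # +1.51%
percent_change <- function(baseline_mean, followup_mean, digits = 2) {
  if (!is.numeric(baseline_mean) || any(baseline_mean <= 0)) {
    abort("`baseline_mean` must be > 0.", class = "sleepfbn_invalid_input")
  }
  pc <- 100 * (followup_mean - baseline_mean) / baseline_mean
  if (is.null(digits)) pc else round(pc, digits)
}
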