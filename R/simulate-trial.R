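# Synthetic trial tables. Defaults emulate the study conditions of a
# two-arm cerebral-palsy trial: 15 treated vs 10 control subjects, scale
# endpoints at baseline/1M/3M/6M/24M, and paired regional gray-matter
# volumes at baseline/6M for nine analyzable subjects. Baseline locations
# and spreads are seeded from the trial's printed endpoint tables.

TRIAL_TIMEPOINTS <- c("baseline", "1M", "3M", "6M", "24M")

#' Default clinical-scale measures
#'
#' Baseline means and valid score ranges for the scale endpoints the
#' generator emulates: adapted developmental scales (fine motor,
#' sociability, life adaptability, expressive ability), the GMFM-88 gross
#' motor total, activities of daily living, and the children's sleep
#' disturbance scale.
#'
#' @return A tibble with columns `measure`, `baseline_mean`, `lower`,
#'   `upper`.
#' @export
default_scale_measures <- function() {
  tibble::tibble(
    measure = c("FMFS", "SS", "LAS", "EAS", "GMFM-88-TOTAL", "ADL", "SDSC"),
    baseline_mean = c(24.0, 26.7, 29.4, 29.3, 52.4, 34.5, 49.4),
    lower = c(0, 0, 0, 0, 0, 0, 26),
    upper = c(100, 100, 100, 100, 100, 100, 130)
  )
}

#' Two-arm longitudinal trial design
#'
#' Ground-truth description of a simulated scale-endpoint table: arm
#' sizes, ordered timepoints, standardized effect sizes per
#' (measure, timepoint, arm), and the between-/within-subject variance
#' components of the underlying random-intercept model. Baseline effects
#' are zero by construction in both arms.
#'
#' @param n_treatment,n_control Subjects per arm (each >= 2).
#' @param timepoints Ordered unique timepoint labels.
#' @param measures Measure table as in [default_scale_measures()] (columns
#'   `measure`, `baseline_mean`, `lower`, `upper`).
#' @param effect_sizes `NULL` (no effects) or a data frame with columns
#'   `measure`, `timepoint`, `arm`, `effect`: the mean shift at that cell
#'   in units of `between_subject_sd`. Timepoints must belong to
#'   `timepoints` and may not include a nonzero baseline effect.
#' @param between_subject_sd,within_subject_sd Score-unit SDs of the
#'   subject random intercept and the residual noise (both > 0).
#' @param seed Integer seed.
#' @return An object of class `trial_design`.
#' @seealso [simulate_scales()]
#' @export
trial_design <- function(n_treatment = 15, n_control = 10,
                         timepoints = TRIAL_TIMEPOINTS,
                         measures = default_scale_measures(),
                         effect_sizes = NULL,
                         between_subject_sd = 15, within_subject_sd = 5,
                         seed = 1) {
  if (n_treatment < 2 || n_control < 2) {
    abort("need n >= 2 per arm.", class = "sleepfbn_invalid_design")
  }
  timepoints <- as.character(timepoints)
  if (anyDuplicated(timepoints) || length(timepoints) < 1) {
    abort("`timepoints` must be unique labels.", class = "sleepfbn_invalid_design")
  }
  if (between_subject_sd <= 0 || within_subject_sd <= 0) {
    abort("all SDs must be > 0.", class = "sleepfbn_invalid_design")
  }
  measures <- tibble::as_tibble(measures)
  stopifnot(all(c("measure", "baseline_mean", "lower", "upper") %in% names(measures)))
  if (!is.null(effect_sizes)) {
    effect_sizes <- tibble::as_tibble(effect_sizes)
    stopifnot(all(c("measure", "timepoint", "arm", "effect") %in% names(effect_sizes)))
    bad_tp <- setdiff(effect_sizes$timepoint, timepoints)
    if (length(bad_tp) > 0) {
      abort(paste0("unknown timepoint label(s) in effect_sizes: ",
                   paste(bad_tp, collapse = ", ")),
            class = "sleepfbn_invalid_design")
    }
    if (any(effect_sizes$timepoint == timepoints[1] & effect_sizes$effect != 0)) {
      abort("baseline effects must be zero by construction.",
            class = "sleepfbn_invalid_design")
    }
    bad_m <- setdiff(effect_sizes$measure, measures$measure)
    if (length(bad_m) > 0) {
      abort(paste0("unknown measure(s) in effect_sizes: ",
                   paste(bad_m, collapse = ", ")),
            class = "sleepfbn_invalid_design")
    }
    if (!all(effect_sizes$arm %in% c("treatment", "control"))) {
      abort("effect_sizes$arm must be 'treatment' or 'control'.",
            class = "sleepfbn_invalid_design")
    }
  }
  structure(
    list(n_treatment = n_treatment, n_control = n_control,
         timepoints = timepoints, measures = measures,
         effect_sizes = effect_sizes,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd, seed = as.integer(seed)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", x$n_treatment, " treatment vs ", x$n_control,
      " control; timepoints: ", paste(x$timepoints, collapse = ", "),
      "; ", nrow(x$measures), " measures; ",
      if (is.null(x$effect_sizes)) "no planted effects"
      else paste0(nrow(x$effect_sizes), " planted effect cells"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a long-format clinical-scale table
#'
#' Draws scores from a linear random-intercept model: for subject `i`,
#' measure `m`, timepoint `t`,
#' `score = baseline_mean_m + b_i + delta(m, t, arm) * sigma_b + e_it`,
#' with `b_i ~ N(0, sigma_b^2)`, `e ~ N(0, sigma_w^2)`, and `delta` the
#' standardized effect from the design (zero at baseline). Scores are
#' truncated to each measure's valid range.
#'
#' @param design A [trial_design()].
#' @return A tibble with one row per subject x timepoint x measure:
#'   `subject_id`, `arm`, `timepoint` (ordered factor), `measure`,
#'   `value`.
#' @export
simulate_scales <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  subs <- tibble::tibble(
    subject_id = c(sprintf("T%02d", seq_len(design$n_treatment)),
                   sprintf("C%02d", seq_len(design$n_control))),
    arm = rep(c("treatment", "control"),
              c(design$n_treatment, design$n_control))
  )
  grid <- tidyr::expand_grid(subs,
                             timepoint = design$timepoints,
                             measure = design$measures$measure)
  grid <- dplyr::left_join(grid, design$measures, by = "measure")
  if (!is.null(design$effect_sizes)) {
    grid <- dplyr::left_join(
      grid,
      dplyr::rename(design$effect_sizes, .effect = "effect"),
      by = c("measure", "timepoint", "arm")
    )
    grid$.effect[is.na(grid$.effect)] <- 0
  } else {
    grid$.effect <- 0
  }
  with_seed_if(design$seed, {
    b <- setNames(rnorm(nrow(subs), 0, design$between_subject_sd),
                  subs$subject_id)
    grid$value <- grid$baseline_mean + b[grid$subject_id] +
      grid$.effect * design$between_subject_sd +
      rnorm(nrow(grid), 0, design$within_subject_sd)
  })
  grid$value <- pmin(pmax(grid$value, grid$lower), grid$upper)
  grid$timepoint <- factor(grid$timepoint, levels = design$timepoints,
                           ordered = TRUE)
  grid[, c("subject_id", "arm", "timepoint", "measure", "value")]
}

#' Default regional gray-matter volume table
#'
#' The nine AAL atlas regions the volumetric analysis tracks (occipital,
#' fusiform, parietal, angular and temporal-pole regions), with baseline
#' mean volumes and between-subject SDs in cubic millimetres, plus the
#' remainder of total gray matter outside these regions so that regional
#' and total analyses are mutually consistent.
#'
#' @return A tibble with columns `region_index`, `region`, `mean`, `sd`.
#' @export
default_aal_regions <- function() {
  tibble::tibble(
    region_index = c(49L, 52L, 53L, 54L, 56L, 60L, 62L, 66L, 87L),
    region = c("SOG.L", "MOG.R", "IOG.L", "IOG.R", "FFG.R",
               "SPG.R", "IPL.R", "ANG.R", "TPOmid.L"),
    mean = c(4924.49, 8141.31, 4474.26, 4239.01, 11843.16,
             5877.22, 5238.69, 6505.39, 2390.20),
    sd = c(685.36, 1263.95, 485.94, 797.49, 1078.77,
           960.71, 587.67, 727.61, 654.50)
  )
}

#' Simulate a paired regional-volume table
#'
#' Generates baseline and 6-month gray-matter volumes per subject and AAL
#' region. Baselines are Gaussian around each region's mean; the follow-up
#' applies the planted fractional change plus multiplicative measurement
#' noise. A `TOTAL` pseudo-region is the sum of the regional volumes plus
#' a per-subject remainder (gray matter outside the tracked regions) that
#' is left unchanged between timepoints, so the planted regional effects
#' are recoverable both regionally and in the total.
#'
#' @param n_subjects Number of paired subjects (default 9).
#' @param regions Region table as [default_aal_regions()].
#' @param effect Named numeric vector of fractional changes (> -1), names
#'   matching `regions$region`; e.g. `c(SOG.L = 0.05)` plants +5% in the
#'   left superior occipital gyrus. `NULL` for no change.
#' @param noise_sd Multiplicative measurement noise SD at follow-up, as a
#'   fraction of the regional mean (default 0.02).
#' @param remainder_mean,remainder_sd Mean and between-subject SD of the
#'   untracked remainder volume entering the total.
#' @param include_total Add the `TOTAL` pseudo-region rows.
#' @param seed Integer seed.
#' @return A tibble with one row per subject x region x timepoint:
#'   `subject_id`, `region_index` (`NA` for `TOTAL`), `region`,
#'   `timepoint` (`"baseline"`/`"6M"`), `volume` (mm^3).
#' @export
simulate_volumes <- function(n_subjects = 9, regions = default_aal_regions(),
                             effect = NULL, noise_sd = 0.02,
                             remainder_mean = 560605, remainder_sd = 39000,
                             include_total = TRUE, seed = 1) {
  regions <- tibble::as_tibble(regions)
  if (!is.null(effect)) {
    bad <- setdiff(names(effect), regions$region)
    if (length(bad) > 0) {
      abort(paste0("unknown region label(s) in `effect`: ",
                   paste(bad, collapse = ", ")),
            class = "sleepfbn_invalid_region")
    }
    if (any(effect <= -1)) {
      abort("fractional effects must be > -1.", class = "sleepfbn_invalid_region")
    }
  }
  eff <- setNames(rep(0, nrow(regions)), regions$region)
  if (!is.null(effect)) eff[names(effect)] <- effect
  subs <- sprintf("V%02d", seq_len(n_subjects))
  with_seed_if(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
      base <- pmax(rnorm(n_subjects, regions$mean[r], regions$sd[r]),
                   0.1 * regions$mean[r])
      fu <- base * (1 + eff[regions$region[r]]) +
        regions$mean[r] * noise_sd * rnorm(n_subjects)
      tibble::tibble(
        subject_id = rep(subs, 2),
        region_index = regions$region_index[r],
        region = regions$region[r],
        timepoint = rep(c("baseline", "6M"), each = n_subjects),
        volume = c(base, fu)
      )
    })
    if (include_total) {
      remainder <- pmax(rnorm(n_subjects, remainder_mean, remainder_sd),
                        0.1 * remainder_mean)
      tot <- rows |>
        dplyr::group_by(.data$subject_id, .data$timepoint) |>
        dplyr::summarise(volume = sum(.data$volume), .groups = "drop") |>
        dplyr::mutate(volume = .data$volume + remainder[match(.data$subject_id, subs)],
                      region_index = NA_integer_, region = "TOTAL")
      rows <- dplyr::bind_rows(rows, tot[, names(rows)])
    }
    rows
  })
}
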