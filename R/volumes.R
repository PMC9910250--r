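#' Regional gray-matter volume analysis
#'
#' For every region (including the `TOTAL` pseudo-region) in a paired
#' long-format volume table: a paired baseline-vs-follow-up comparison
#' ([compare_paired()], normality-gated) plus the percent change of the
#' group means, rounded to two decimals. Every subject must contribute
#' both timepoints in every region.
#'
#' @param data Long-format data frame with columns `subject_id`, `region`,
#'   `timepoint`, `volume` (as produced by [simulate_volumes()]).
#' @param baseline,followup The two timepoint labels (defaults `"baseline"`
#'   and `"6M"`).
#' @param alpha Significance level passed to the paired engine.
#' @return A tibble with one row per region: `region`, `n`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`,
#'   `pct_change`, `test_used`, `statistic`, `p_value`, `significant`.
#' @export
volume_region_analysis <- function(data, baseline = "baseline",
                                   followup = "6M", alpha = 0.05) {
  df <- tibble::as_tibble(data)
  need <- c("subject_id", "region", "timepoint", "volume")
  if (!all(need %in% names(df))) {
    abort(paste0("`data` must have columns ", paste(need, collapse = ", "), "."),
          class = "sleepfbn_invalid_input")
  }
  if (any(df$volume <= 0)) {
    abort("volumes must be > 0.", class = "sleepfbn_invalid_input")
  }
  df <- df[df$timepoint %in% c(baseline, followup), ]
  regions <- unique(df$region)
  purrr::map_dfr(regions, function(r) {
    sub <- df[df$region == r, ]
    wide <- tidyr::pivot_wider(sub[, c("subject_id", "timepoint", "volume")],
                               names_from = "timepoint",
                               values_from = "volume")
    unpaired <- wide$subject_id[!stats::complete.cases(wide)]
    if (length(unpaired) > 0) {
      abort(paste0("unpaired subject(s) in region ", r, ": ",
                   paste(unpaired, collapse = ", ")),
            class = "sleepfbn_pairing")
    }
    bl <- wide[[baseline]]; fu <- wide[[followup]]
    cmp <- compare_paired(bl, fu, labels = c(baseline, followup),
                          alpha = alpha)
    tibble::tibble(
      region = r, n = length(bl),
      baseline_mean = mean(bl), baseline_sd = sd(bl),
      followup_mean = mean(fu), followup_sd = sd(fu),
      pct_change = percent_change(mean(bl), mean(fu), digits = 2),
      test_used = cmp$test_used,
      statistic = cmp$statistic,
      p_value = cmp$p_value,
      significant = cmp$p_value < alpha
    )
  })
}
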