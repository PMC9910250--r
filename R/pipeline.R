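#' Default planted coupling structure
#'
#' A three-edge coupling over the canonical montage: homologous
#' sensorimotor (C3--C4, weight 0.8), parietal (P3--P4, 0.6) and occipital
#' (O1--O2, 0.4) pairs -- the kind of strong interhemispheric coupling
#' sleep EEG exhibits -- with all other pairs independent.
#'
#' @return An 8 x 8 symmetric coupling matrix with [fbn_channels()]
#'   dimnames.
#' @export
default_coupling <- function() {
  w <- matrix(0, 8, 8, dimnames = list(FBN_CHANNELS, FBN_CHANNELS))
  w["C3", "C4"] <- w["C4", "C3"] <- 0.8
  w["P3", "P4"] <- w["P4", "P3"] <- 0.6
  w["O1", "O2"] <- w["O2", "O1"] <- 0.4
  w
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis -- cohort sizes, EEG
#' generation, filtering band, segment policy, network options, and the
#' statistics plan -- into one serializable list. The effective
#' configuration (plus its hash and seed) is embedded in every output so a
#' run can be reproduced exactly.
#'
#' @param n_treatment,n_control Subjects per arm.
#' @param timepoints EEG assessment timepoints (default baseline/6M/24M).
#' @param fs Sampling rate, Hz.
#' @param duration Recording length per subject x timepoint, seconds
#'   (>= `n_segments * segment_dur`).
#' @param n_segments,segment_dur Segment policy (default ten 15-s
#'   windows).
#' @param segment_strategy `"sequential"` or `"random"`.
#' @param low,high,filter_order Band-pass settings (default 0.30--30 Hz,
#'   4th-order sections).
#' @param coupling Baseline coupling matrix (default [default_coupling()]).
#' @param coupling_scale `NULL`, or a data frame with columns `arm`,
#'   `timepoint`, `scale` multiplying the coupling matrix for that cell --
#'   the hook for planting longitudinal connectivity change.
#' @param noise_sd Sensor noise SD relative to unit signal SD.
#' @param threshold,binarize Network sensitivity options (off by
#'   default).
#' @param aggregate `"mean-network"` (average the per-segment adjacency
#'   matrices, then compute metrics once -- the default) or
#'   `"metrics-per-segment"` (compute metrics per segment and average
#'   those).
#' @param paired_followup Timepoint compared against baseline in the
#'   paired within-arm contrast (default: the last timepoint).
#' @param seed Integer master seed; every recording's seed derives from
#'   it.
#' @return A list of class `fbn_config`.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(n_treatment = 15, n_control = 10,
                            timepoints = c("baseline", "6M", "24M"),
                            fs = 128, duration = 160,
                            n_segments = 10, segment_dur = 15,
                            segment_strategy = "sequential",
                            low = 0.30, high = 30, filter_order = 4,
                            coupling = default_coupling(),
                            coupling_scale = NULL,
                            noise_sd = 1,
                            threshold = 0, binarize = FALSE,
                            aggregate = c("mean-network",
                                          "metrics-per-segment"),
                            paired_followup = NULL,
                            seed = 1) {
  aggregate <- match.arg(aggregate)
  if (duration < n_segments * segment_dur) {
    abort("`duration` must cover n_segments x segment_dur.",
          class = "sleepfbn_invalid_argument")
  }
  cfg <- list(
    n_treatment = n_treatment, n_control = n_control,
    timepoints = as.character(timepoints), fs = fs, duration = duration,
    n_segments = n_segments, segment_dur = segment_dur,
    segment_strategy = segment_strategy,
    low = low, high = high, filter_order = filter_order,
    coupling = as.matrix(coupling),
    coupling_scale = if (is.null(coupling_scale)) NULL
                     else as.data.frame(coupling_scale),
    noise_sd = noise_sd, threshold = threshold, binarize = binarize,
    aggregate = aggregate,
    paired_followup = paired_followup %||% tail2(as.character(timepoints)),
    seed = as.integer(seed)
  )
  class(cfg) <- "fbn_config"
  cfg
}

tail2 <- function(x) x[length(x)]

coupling_scale_for <- function(cfg, arm, tp) {
  cs <- cfg$coupling_scale
  if (is.null(cs)) return(1)
  hit <- cs$arm == arm & cs$timepoint == tp
  if (any(hit)) cs$scale[which(hit)[1]] else 1
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s, subject %s] %s", stage, subject_id,
                  conditionMessage(e)),
          class = c("sleepfbn_stage_error", class(e)[1]), parent = e)
  })
}

metrics_for_recording <- function(rec, cfg) {
  rec <- bandpass_filter(rec, cfg$low, cfg$high, cfg$filter_order)
  segs <- extract_segments(rec, n = cfg$n_segments, dur = cfg$segment_dur,
                           strategy = cfg$segment_strategy,
                           seed = if (cfg$segment_strategy == "random")
                             cfg$seed else NULL)
  if (cfg$aggregate == "mean-network") {
    net <- build_fbn(segs, threshold = cfg$threshold,
                     binarize = cfg$binarize)
    list(metrics = network_metrics(net), net = net)
  } else {
    nets <- segment_networks(segs)
    if (cfg$threshold > 0) nets <- lapply(nets, fbn_threshold, tau = cfg$threshold)
    if (cfg$binarize) nets <- lapply(nets, fbn_binarize)
    per <- purrr::map_dfr(nets, network_metrics)
    m <- per |>
      dplyr::summarise(dplyr::across(c("D", "C", "L", "E", "BNE",
                                       "unreachable_pair_fraction"),
                                     ~ mean(.x, na.rm = TRUE)))
    m <- dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id,
                                         timepoint = rec$timepoint), m)
    list(metrics = m, net = aggregate_networks(nets))
  }
}

#' Run the end-to-end functional-brain-network pipeline
#'
#' Simulates (or reads) one recording per subject and timepoint, filters
#' it, extracts the analysis segments, builds the aggregated
#' Pearson-correlation network, computes the five graph metrics, and runs
#' the trial's comparison plan on the resulting metric table:
#' between-group contrasts at every post-baseline timepoint, the paired
#' baseline-vs-follow-up contrast within the treatment arm, and (with
#' three or more timepoints) the longitudinal repeated-measures contrast
#' in the treatment arm. Deterministic given `config$seed`.
#'
#' @param config An [pipeline_config()].
#' @param edf_paths `NULL` to simulate the cohort, or a data frame with
#'   columns `subject_id`, `arm`, `timepoint`, `path` pointing at EDF
#'   recordings to analyze instead.
#' @param output_dir If non-`NULL`, `metrics.csv`, `comparisons.csv` and
#'   `config.yaml` (with seed and config hash) are written there.
#' @return A list of class `fbn_pipeline_result`: `metrics` (tibble, one
#'   row per subject x timepoint), `comparisons` (tibble, one row per
#'   contrast), `networks` (named list of [fbn()]), `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), edf_paths = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "fbn_config"))
  plan <- if (is.null(edf_paths)) {
    tidyr::expand_grid(
      tibble::tibble(
        subject_id = c(sprintf("T%02d", seq_len(config$n_treatment)),
                       sprintf("C%02d", seq_len(config$n_control))),
        arm = rep(c("treatment", "control"),
                  c(config$n_treatment, config$n_control))
      ),
      timepoint = config$timepoints
    )
  } else {
    tibble::as_tibble(edf_paths)
  }
  rec_seeds <- with_seed_if(config$seed,
                            sample.int(.Machine$integer.max - 1, nrow(plan)))
  results <- purrr::map(seq_len(nrow(plan)), function(i) {
    sid <- plan$subject_id[i]; tp <- plan$timepoint[i]
    rec <- if (is.null(edf_paths)) {
      with_stage("simulate", sid, {
        scale <- coupling_scale_for(config, plan$arm[i], tp)
        model <- coupling_model(config$coupling * scale,
                                noise_sd = config$noise_sd,
                                seed = rec_seeds[i])
        simulate_eeg(model, duration = config$duration, fs = config$fs,
                     subject_id = sid, timepoint = tp)
      })
    } else {
      with_stage("read_edf", sid, {
        if (!file.exists(plan$path[i])) {
          abort(sprintf("input file not found: %s", plan$path[i]),
                class = "sleepfbn_file_not_found")
        }
        read_edf(plan$path[i], subject_id = sid, timepoint = tp)
      })
    }
    with_stage("network", sid, metrics_for_recording(rec, config))
  })
  metrics <- purrr::map_dfr(results, "metrics")
  metrics <- dplyr::bind_cols(plan[, c("subject_id", "arm", "timepoint")],
                              metrics[, setdiff(names(metrics),
                                                c("subject_id", "timepoint"))])
  networks <- setNames(purrr::map(results, "net"),
                       paste(plan$subject_id, plan$timepoint, sep = "/"))
  comparisons <- pipeline_comparisons(metrics, config)
  out <- structure(
    list(metrics = metrics, comparisons = comparisons, networks = networks,
         config = config, config_hash = rlang::hash(config)),
    class = "fbn_pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

pipeline_comparisons <- function(metrics, config) {
  metric_cols <- c("D", "C", "L", "E", "BNE")
  tps <- config$timepoints
  rows <- list()
  for (m in metric_cols) {
    for (tp in setdiff(tps, tps[1])) {
      a <- metrics[[m]][metrics$arm == "treatment" & metrics$timepoint == tp]
      b <- metrics[[m]][metrics$arm == "control" & metrics$timepoint == tp]
      cmp <- tryCatch(compare_independent(a, b),
                      sleepfbn_insufficient_data = function(e) NULL,
                      sleepfbn_degenerate_data = function(e) NULL)
      if (!is.null(cmp)) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(measure = m, contrast = "between-group",
                         timepoint = tp), tidy(cmp))
      }
    }
    tr <- metrics[metrics$arm == "treatment", ]
    fu <- config$paired_followup
    wide <- tidyr::pivot_wider(tr[, c("subject_id", "timepoint", m)],
                               names_from = "timepoint",
                               values_from = dplyr::all_of(m))
    if (all(c(tps[1], fu) %in% names(wide))) {
      ok <- stats::complete.cases(wide[, c(tps[1], fu)])
      cmp <- tryCatch(compare_paired(wide[[tps[1]]][ok], wide[[fu]][ok],
                                     labels = c(tps[1], fu)),
                      sleepfbn_insufficient_data = function(e) NULL,
                      sleepfbn_degenerate_data = function(e) NULL)
      if (!is.null(cmp)) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(measure = m, contrast = "paired-vs-baseline",
                         timepoint = fu), tidy(cmp))
      }
    }
    if (length(tps) >= 3) {
      long <- tr[, c("subject_id", "timepoint", m)]
      names(long)[3] <- "value"
      cmp <- tryCatch(compare_longitudinal(long),
                      sleepfbn_insufficient_data = function(e) NULL,
                      sleepfbn_degenerate_data = function(e) NULL)
      if (!is.null(cmp)) {
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(measure = m, contrast = "longitudinal",
                         timepoint = paste(tps, collapse = "|")), tidy(cmp))
      }
    }
  }
  dplyr::bind_rows(rows)
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$metrics, file.path(output_dir, "metrics.csv"))
  readr::write_csv(result$comparisons, file.path(output_dir, "comparisons.csv"))
  cfg <- result$config
  cfg$coupling <- apply(cfg$coupling, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(c(list(config_hash = result$config_hash),
                     unclass(cfg)),
                   file.path(output_dir, "config.yaml"))
  invisible(output_dir)
}

#' @export
print.fbn_pipeline_result <- function(x, ...) {
  cat("<fbn_pipeline_result> ", nrow(x$metrics), " subject-timepoints, ",
      nrow(x$comparisons), " contrasts, seed ", x$config$seed,
      ", config hash ", substr(x$config_hash, 1, 8), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fbn_pipeline_result <- function(x, ...) x$comparisons

#' @export
glance.fbn_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$metrics$subject_id)),
    n_timepoints = length(unique(x$metrics$timepoint)),
    n_contrasts = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant),
    seed = x$config$seed,
    config_hash = x$config_hash
  )
}
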