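#' Configuration of an end-to-end synthetic study run
#'
#' Bundles the task configuration, signal specification, response
#' parameters and analysis settings of a full study. Two profiles are
#' provided: `"full"` mirrors the study design (43 participants x 128
#' blocks, 10,000 permutations) and `"ci"` is a scaled-down profile for
#' routine checks (8 participants x 16 blocks, 1,000 permutations,
#' decoding restricted to the peak window).
#'
#' @param profile `"ci"` (default) or `"full"`.
#' @param n_participants number of simulated participants.
#' @param task a [task_config()].
#' @param signal a [signal_spec()].
#' @param response_params per-condition [psych_params()] list.
#' @param tfr_freqs TFR frequencies (Hz).
#' @param tfr_step TFR time step (s).
#' @param decode_timepoints decoding timepoints (s re cue onset).
#' @param decode_window window over which per-trial decoding scores are
#'   averaged for the power-decoding analyses (default `c(1.0, 1.2)`, the
#'   post-probe decoding peak).
#' @param n_perm cluster-permutation count.
#' @param threshold_p cluster-forming threshold (two-sided).
#' @param use_csd apply the surface Laplacian before the TFR.
#' @param n_bins bins for the power-decoding bin analysis.
#' @param export_data also export each participant's trials and epochs.
#' @return an object of class `wm_run_config`.
#' @export
run_config <- function(profile = c("ci", "full"),
                       n_participants = NULL,
                       task = NULL,
                       signal = signal_spec(),
                       response_params = default_response_params(),
                       tfr_freqs = 2:40,
                       tfr_step = 0.04,
                       decode_timepoints = NULL,
                       decode_window = c(1.0, 1.2),
                       n_perm = NULL,
                       threshold_p = 0.05,
                       use_csd = TRUE,
                       n_bins = 8,
                       export_data = FALSE) {
  profile <- match.arg(profile)
  if (is.null(n_participants)) {
    n_participants <- if (profile == "full") 43 else 8
  }
  if (is.null(task)) {
    task <- if (profile == "full") {
      task_config()
    } else {
      # short sessions need balanced orientation coverage for the decoder
      task_config(n_blocks = 16, balance_orientations = TRUE)
    }
  }
  if (is.null(n_perm)) n_perm <- if (profile == "full") 10000 else 1000
  if (is.null(decode_timepoints)) {
    decode_timepoints <- if (profile == "full") {
      seq(0.8, 1.4, by = 0.05)
    } else {
      seq(1.0, 1.2, by = 0.05)
    }
  }
  cfg <- structure(
    list(
      profile = profile,
      n_participants = n_participants,
      task = task,
      signal = signal,
      response_params = response_params,
      tfr_freqs = tfr_freqs,
      tfr_step = tfr_step,
      decode_timepoints = decode_timepoints,
      decode_window = decode_window,
      n_perm = n_perm,
      threshold_p = threshold_p,
      use_csd = use_csd,
      n_bins = n_bins,
      export_data = export_data
    ),
    class = "wm_run_config"
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

# per-participant seeds derived from the master seed by one draw each
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1, n)
}

# analysis channels needed for the TFR stage
tfr_channels <- function() {
  unique(c(channel_set("central9"), channel_set("frontal6")))
}

# analyze one participant's dataset; returns per-trial measures, TFR
# contrast maps and psychometric fits
analyze_dataset <- function(trials, epochs, config, participant_id) {
  # --- spectral stage -------------------------------------------------
  ep_tfr <- subset_epochs(epochs, channels = intersect(tfr_channels(),
                                                       epochs$channels))
  if (config$use_csd) {
    # CSD needs the full montage; compute on all channels, then subset
    ep_tfr <- subset_epochs(surface_laplacian(epochs),
                            channels = intersect(tfr_channels(),
                                                 epochs$channels))
  }
  tfr <- tfr_hanning(ep_tfr, freqs = config$tfr_freqs,
                     t_step = config$tfr_step)
  tfr <- baseline_db(tfr)

  beta <- band_power(tfr, preset = "beta")
  theta <- band_power(tfr, preset = "theta")

  # condition-mean time-frequency maps averaged over each channel set
  is_sw <- trials$condition == "switch"
  is_rep <- trials$condition %in% c("repeat1", "repeat2plus")
  set_map <- function(chs, rows) {
    sel <- match(chs, tfr$channels)
    apply(tfr$power[rows, sel, , , drop = FALSE], c(3, 4), mean)
  }
  central_diff <- set_map(channel_set("central9"), which(is_sw)) -
    set_map(channel_set("central9"), which(is_rep))
  frontal_diff <- set_map(channel_set("frontal6"), which(is_sw)) -
    set_map(channel_set("frontal6"), which(is_rep))

  # --- decoding stage (raw epochs, not CSD) ---------------------------
  dec <- purrr::map(c("cued", "uncued", "cross"), function(tg) {
    crossval_decode(epochs, trials, target = tg,
                    timepoints = config$decode_timepoints)
  })
  score_in_window <- function(res) {
    res |>
      dplyr::filter(.data$time >= config$decode_window[1],
                    .data$time <= config$decode_window[2]) |>
      dplyr::group_by(.data$trial) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
  }
  scores <- purrr::map(dec, score_in_window)

  measures <- trials |>
    dplyr::mutate(
      participant = participant_id,
      trial = dplyr::row_number(),
      beta_power = beta$power,
      theta_power = theta$power,
      score_cued = scores[[1]]$score,
      score_uncued = scores[[2]]$score,
      score_cross = scores[[3]]$score
    )

  # --- behavior stage -------------------------------------------------
  fits <- purrr::map_dfr(
    list(
      c(condition = "switch", swap = FALSE),
      c(condition = "repeat", swap = FALSE),
      c(condition = "switch", swap = TRUE),
      c(condition = "repeat", swap = TRUE)
    ),
    function(row) {
      filt <- if (row[["condition"]] == "switch") "switch" else
        c("repeat1", "repeat2plus")
      fit <- fit_psychometric(trials, include_swap = as.logical(row[["swap"]]),
                              condition_filter = filt)
      tidy(fit) |>
        dplyr::mutate(
          participant = participant_id,
          condition = row[["condition"]],
          include_swap = as.logical(row[["swap"]]),
          neg_log_lik = fit$neg_log_lik,
          .before = 1
        )
    }
  )

  list(
    measures = measures,
    central_diff = central_diff,
    frontal_diff = frontal_diff,
    tfr_freqs = tfr$freqs,
    tfr_times = tfr$times,
    psychfits = fits,
    decoding = dplyr::bind_rows(dec) |>
      dplyr::mutate(participant = participant_id, .before = 1)
  )
}

# stack per-participant maps into a participants x cells matrix restricted
# to the grid cells finite for every participant, keeping a rectangle
stack_maps <- function(maps, freqs, times) {
  ok <- Reduce(`&`, purrr::map(maps, is.finite))
  f_keep <- which(apply(ok, 1, any))
  t_keep <- which(apply(ok[f_keep, , drop = FALSE], 2, all))
  f_keep <- f_keep[apply(ok[f_keep, t_keep, drop = FALSE], 1, all)]
  m <- do.call(rbind, purrr::map(maps, function(x) {
    as.vector(x[f_keep, t_keep, drop = FALSE])
  }))
  list(data = m, freqs = freqs[f_keep], times = times[t_keep],
       grid_dim = c(length(f_keep), length(t_keep)))
}

# group-level analysis over stacked per-participant results
group_analysis <- function(parts, config) {
  measures <- dplyr::bind_rows(purrr::map(parts, "measures"))
  psychfits <- dplyr::bind_rows(purrr::map(parts, "psychfits"))

  behavior <- switch_cost_summary(measures)
  dist_acc <- distance_effect(measures, "accuracy")
  dist_rt <- distance_effect(measures, "rt")

  # Fig. 2 analog: switch-vs-repeat cluster tests on the set-mean maps
  central <- stack_maps(purrr::map(parts, "central_diff"),
                        parts[[1]]$tfr_freqs, parts[[1]]$tfr_times)
  frontal <- stack_maps(purrr::map(parts, "frontal_diff"),
                        parts[[1]]$tfr_freqs, parts[[1]]$tfr_times)
  cl_central <- cluster_permutation(central$data, central$grid_dim,
                                    n_perm = config$n_perm,
                                    threshold_p = config$threshold_p)
  cl_frontal <- cluster_permutation(frontal$data, frontal$grid_dim,
                                    n_perm = config$n_perm,
                                    threshold_p = config$threshold_p)

  trialdat <- measures |>
    dplyr::filter(.data$condition != "block_start") |>
    dplyr::mutate(cond2 = ifelse(.data$condition == "switch",
                                 "switch", "repeat"))

  # Fig. 3 analog: band power ~ item distance, per condition
  dist_coef <- purrr::map_dfr(c("beta_power", "theta_power"), function(bp) {
    ztrial_regress(trialdat, y = bp, predictors = "item_distance",
                   by_condition = "cond2") |>
      dplyr::mutate(band = sub("_power", "", bp), .before = 1)
  })
  dist_tests <- dist_coef |>
    dplyr::group_by(.data$band, .data$cond2) |>
    dplyr::group_modify(~ group_ttest(.x$estimate)) |>
    dplyr::ungroup()

  # distance-level ANOVA on switch-trial beta power (levels present for all)
  sw_lvl <- trialdat |>
    dplyr::filter(.data$cond2 == "switch") |>
    dplyr::group_by(.data$participant, .data$item_distance) |>
    dplyr::summarise(beta_power = mean(.data$beta_power), .groups = "drop")
  lvl_counts <- sw_lvl |>
    dplyr::count(.data$item_distance) |>
    dplyr::filter(.data$n == length(parts))
  anova_beta <- NULL
  if (nrow(lvl_counts) >= 3) {
    anova_beta <- rm_anova_1way(
      dplyr::semi_join(sw_lvl, lvl_counts, by = "item_distance"),
      value = "beta_power", level = "item_distance"
    )
  }

  # Figs. 4-5 analog: power -> decoding regressions per target and band
  pd_coef <- purrr::map_dfr(c("cued", "uncued", "cross"), function(tg) {
    purrr::map_dfr(c("beta_power", "theta_power"), function(bp) {
      ztrial_regress(trialdat, y = paste0("score_", tg), predictors = bp,
                     by_condition = "cond2") |>
        dplyr::mutate(target = tg, band = sub("_power", "", bp), .before = 1)
    })
  })
  pd_tests <- pd_coef |>
    dplyr::group_by(.data$target, .data$band, .data$cond2) |>
    dplyr::group_modify(~ group_ttest(.x$estimate)) |>
    dplyr::ungroup()

  # multiple regression with item distance and its interaction (cued, beta)
  multi_coef <- ztrial_regress(
    trialdat, y = "score_cued",
    predictors = c("beta_power", "item_distance"),
    interactions = list(c("beta_power", "item_distance")),
    by_condition = "cond2"
  )
  multi_tests <- multi_coef |>
    dplyr::group_by(.data$cond2, .data$term) |>
    dplyr::group_modify(~ group_ttest(.x$estimate)) |>
    dplyr::ungroup()

  # 8-bin analysis of cued decoding by beta power
  bins <- bin_analysis(trialdat, power = "beta_power", score = "score_cued",
                       n_bins = config$n_bins, condition = "cond2")

  list(
    behavior = behavior,
    psychfits = psychfits,
    distance_accuracy = dist_acc,
    distance_rt = dist_rt,
    cluster_central = cl_central,
    cluster_frontal = cl_frontal,
    map_axes = list(central = central[c("freqs", "times")],
                    frontal = frontal[c("freqs", "times")]),
    distance_power_coef = dist_coef,
    distance_power_tests = dist_tests,
    anova_beta_distance = anova_beta,
    power_decoding_coef = pd_coef,
    power_decoding_tests = pd_tests,
    multi_regression_coef = multi_coef,
    multi_regression_tests = multi_tests,
    bin_analysis = bins,
    trial_measures = measures
  )
}

#' Run a complete synthetic study
#'
#' Simulates `n_participants` independent datasets (task structure,
#' behavioral responses and epochs), runs the full analysis chain on each
#' (psychometric fits, switch-cost and item-distance behavior analyses,
#' baselined time-frequency contrasts, per-trial band power, cross-validated
#' decoding of the cued/uncued items plus cross-decoding), and performs the
#' group-level statistics (cluster-corrected switch-vs-repeat power maps,
#' distance regressions and ANOVA, power-decoding regressions and the
#' binned analysis). With `out_dir` all tables are written as TSV/JSON plus
#' a run log; a rerun with the same seed and config reproduces the bundle
#' byte for byte.
#'
#' @param config a [run_config()].
#' @param seed master seed; per-participant seeds are derived from it.
#' @param out_dir optional output directory for the report bundle.
#' @return (invisibly) the report bundle: a list of all group-level results
#'   plus `trial_measures` and per-participant psychometric fits.
#' @export
run_synthetic_study <- function(config = run_config(), seed = 1,
                                out_dir = NULL) {
  stopifnot(inherits(config, "wm_run_config"))
  seeds <- derive_seeds(seed, config$n_participants)
  log_lines <- character(0)
  log_add <- function(stage, msg) {
    log_lines <<- c(log_lines, jsonlite::toJSON(
      list(stage = stage, message = msg, config_hash = config$hash),
      auto_unbox = TRUE
    ))
  }

  parts <- purrr::map(seq_len(config$n_participants), function(i) {
    set.seed(seeds[i])
    trials <- generate_task(config$task)
    trials <- simulate_responses(trials, config$response_params)
    epochs <- generate_epochs(trials, config$signal)
    if (config$export_data && !is.null(out_dir)) {
      export_dataset(trials, epochs, file.path(out_dir, "data"), i)
    }
    res <- analyze_dataset(trials, epochs, config, i)
    log_add("participant", sprintf("participant %d analyzed (seed %d)",
                                   i, seeds[i]))
    res
  })

  set.seed(seeds[1] + 1L)   # group-stage RNG (permutations)
  group <- group_analysis(parts, config)
  log_add("group", "group-level analysis complete")

  bundle <- c(group, list(config = config, seed = seed,
                          participant_seeds = seeds))
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, log_lines)
  }
  invisible(bundle)
}

#' Run the analysis chain on imported datasets
#'
#' Identical to [run_synthetic_study()] but skips the generator: reads
#' per-participant trial tables and epoch containers previously written by
#' [export_dataset()] (or conforming to the same schema) and runs the
#' analysis and group stages.
#'
#' @param data_dir directory holding `trials_<id>.tsv` and
#'   `epochs_<id>.dat/.json` files.
#' @param ids integer participant ids to import.
#' @param config a [run_config()]; generator settings are ignored.
#' @param seed seed for the group-stage permutations.
#' @param out_dir optional output directory.
#' @return (invisibly) the report bundle.
#' @export
run_import_study <- function(data_dir, ids, config = run_config(), seed = 1,
                             out_dir = NULL) {
  stopifnot(inherits(config, "wm_run_config"))
  log_lines <- character(0)
  parts <- purrr::map(seq_along(ids), function(k) {
    ds <- import_dataset(data_dir, ids[k])
    analyze_dataset(ds$trials, ds$epochs, config, k)
  })
  seeds <- derive_seeds(seed, max(config$n_participants, 1))
  set.seed(seeds[1] + 1L)
  group <- group_analysis(parts, config)
  bundle <- c(group, list(config = config, seed = seed,
                          participant_seeds = seeds))
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, log_lines)
  }
  invisible(bundle)
}

# write the report bundle as TSV tables + JSON summaries + JSONL log
write_bundle <- function(bundle, out_dir, log_lines = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))

  wt(bundle$behavior$summary, "behavior_summary.tsv")
  if (!is.null(bundle$behavior$contrasts)) {
    wt(bundle$behavior$contrasts, "behavior_contrasts.tsv")
  }
  wt(bundle$psychfits, "psychometric_fits.tsv")
  wt(bundle$distance_accuracy$slopes, "distance_slopes_accuracy.tsv")
  wt(bundle$distance_rt$slopes, "distance_slopes_rt.tsv")
  wt(bundle$distance_power_coef, "distance_power_coefficients.tsv")
  wt(bundle$power_decoding_coef, "power_decoding_coefficients.tsv")
  wt(bundle$multi_regression_coef, "multi_regression_coefficients.tsv")
  wt(bundle$bin_analysis$bins, "bin_means.tsv")
  wt(bundle$bin_analysis$slopes, "bin_slopes.tsv")
  wt(bundle$trial_measures, "trial_measures.tsv")

  tests <- list(
    config_hash = bundle$config$hash,
    seed = bundle$seed,
    behavior_contrasts = bundle$behavior$contrasts,
    distance_accuracy_tests = bundle$distance_accuracy$tests,
    distance_rt_tests = bundle$distance_rt$tests,
    distance_power_tests = bundle$distance_power_tests,
    power_decoding_tests = bundle$power_decoding_tests,
    multi_regression_tests = bundle$multi_regression_tests,
    bin_tests = bundle$bin_analysis$tests,
    anova_beta_distance = if (!is.null(bundle$anova_beta_distance)) {
      tidy(bundle$anova_beta_distance)
    },
    cluster_central = tidy(bundle$cluster_central),
    cluster_frontal = tidy(bundle$cluster_frontal)
  )
  jsonlite::write_json(tests, file.path(out_dir, "group_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  cfg <- bundle$config
  cfg$signal$montage <- NULL   # bulky; the montage is code-defined
  jsonlite::write_json(
    purrr::map(unclass(cfg), function(x) {
      if (inherits(x, "wm_task_config") || inherits(x, "wm_psych_params") ||
          inherits(x, "wm_signal_spec")) unclass(x) else x
    }),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  invisible(out_dir)
}
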