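# shared fixtures, all generated in code

# trial table with responses under identical parameters in every condition
uniform_param_trials <- function(n_blocks, lambda, sigma, p_swap, seed,
                                 balance = FALSE) {
  par <- psych_params(lambda = lambda, sigma = sigma, p_swap = p_swap)
  tt <- generate_task(task_config(n_blocks = n_blocks,
                                  balance_orientations = balance),
                      seed = seed)
  simulate_responses(
    tt,
    params_by_condition = list(block_start = par, switch = par,
                               repeat1 = par, repeat2plus = par)
  )
}

# hand-built epoch container for spectral unit tests
toy_epochs <- function(data, fs = 250, t0 = 0, channels = NULL,
                       positions = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(positions)) {
    ang <- 2 * pi * seq_len(d[2]) / d[2]
    positions <- cbind(x = cos(ang) * 0.5, y = sin(ang) * 0.5,
                       z = sqrt(1 - 0.25))
    rownames(positions) <- channels
  }
  structure(
    list(
      data = data,
      times = t0 + (seq_len(d[3]) - 1) / fs,
      sampling_rate = fs,
      channels = channels,
      positions = positions,
      csd_applied = FALSE
    ),
    class = "wm_epochs"
  )
}

# reduced montages so generator-based tests avoid simulating 61 channels
montage_subset <- function(sets) {
  keep <- unique(unlist(lapply(sets, channel_set)))
  m <- default_montage()
  m[m$channel %in% keep, ]
}

# signal spec for band-power tests: central + frontal channels only
band_test_spec <- function(...) {
  m <- montage_subset(c("central9", "frontal6"))
  signal_spec(montage = m, tuning_channels = intersect(
    channel_set("posterior17"), m$channel
  ), ...)
}

# signal spec for decoding tests: posterior + frontal + central channels
decode_test_spec <- function(...) {
  m <- montage_subset(c("posterior17", "central9", "frontal6"))
  signal_spec(montage = m, ...)
}

# mean switch-minus-repeat difference of a per-trial measure
switch_repeat_diff <- function(values, trials) {
  sw <- trials$condition == "switch"
  rp <- trials$condition %in% c("repeat1", "repeat2plus")
  mean(values[sw]) - mean(values[rp])
}

# beta band power restricted to a fast freq/time slice
quick_beta_power <- function(epochs, trials) {
  tfr <- tfr_hanning(epochs, freqs = 15:25,
                     channels = channel_set("central9"))
  tfr <- baseline_db(tfr)
  band_power(tfr, band = c(15, 25), channels = channel_set("central9"),
             time_window = c(0.4, 0.8))
}
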