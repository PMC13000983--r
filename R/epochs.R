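#' Idealized 61-channel 10-20 montage on the unit sphere
#'
#' Standard extended 10-20 labels with spherical positions built
#' geometrically: the outer ring (Fp1/Fpz/Fp2, F7/8, FT7/8, T7/8, TP7/8,
#' P7/8, PO7/8, O1/Oz/O2) sits at 90 degrees from the vertex in 18-degree
#' azimuth steps, midline electrodes step down the sagittal arc in 22.5
#' degree increments, and intermediate electrodes are great-circle
#' interpolations between the midline electrode of their row and the ring
#' electrode that terminates it. Coordinates are unit vectors with +x right,
#' +y anterior, +z superior.
#'
#' @return tibble with columns `channel`, `x`, `y`, `z`.
#' @export
default_montage <- function() {
  sph <- function(polar, azim) {
    # polar from vertex, azimuth from anterior midline (positive = right)
    p <- deg2rad(polar); a <- deg2rad(azim)
    c(sin(p) * sin(a), sin(p) * cos(a), cos(p))
  }
  slerp <- function(a, b, f) {
    om <- acos(pmin(pmax(sum(a * b), -1), 1))
    v <- (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
    v / sqrt(sum(v^2))
  }
  pts <- list()
  add <- function(name, v) pts[[name]] <<- v

  ring <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
            TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
            O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
            FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18)
  mid <- c(AFz = 0, Fz = 0, FCz = 0, Cz = 0, CPz = 180, Pz = 180, POz = 180)
  mid_pol <- c(AFz = 67.5, Fz = 45, FCz = 22.5, Cz = 0,
               CPz = 22.5, Pz = 45, POz = 67.5)
  for (nm in names(ring)) add(nm, sph(90, ring[[nm]]))
  for (nm in names(mid)) add(nm, sph(mid_pol[[nm]], mid[[nm]]))

  # rows: midline anchor, ring terminus, electrode names at fractions 1/4..3/4
  row_def <- list(
    list("Fz",  "F7",  c(F1 = 1, F3 = 2, F5 = 3),  "F8",  c(F2 = 1, F4 = 2, F6 = 3)),
    list("FCz", "FT7", c(FC1 = 1, FC3 = 2, FC5 = 3), "FT8", c(FC2 = 1, FC4 = 2, FC6 = 3)),
    list("Cz",  "T7",  c(C1 = 1, C3 = 2, C5 = 3),  "T8",  c(C2 = 1, C4 = 2, C6 = 3)),
    list("CPz", "TP7", c(CP1 = 1, CP3 = 2, CP5 = 3), "TP8", c(CP2 = 1, CP4 = 2, CP6 = 3)),
    list("Pz",  "P7",  c(P1 = 1, P3 = 2, P5 = 3),  "P8",  c(P2 = 1, P4 = 2, P6 = 3)),
    list("POz", "PO7", c(PO3 = 2, PO5 = 3),        "PO8", c(PO4 = 2, PO6 = 3)),
    list("AFz", "AF7", c(AF3 = 2),                 "AF8", c(AF4 = 2))
  )
  for (rw in row_def) {
    for (side in c(2, 4)) {
      anchor <- pts[[rw[[1]]]]
      terminus <- pts[[rw[[side]]]]
      fr <- rw[[side + 1]]
      for (nm in names(fr)) add(nm, slerp(anchor, terminus, fr[[nm]] / 4))
    }
  }
  # AF7/AF8 only served as interpolation termini; drop to keep 61 channels
  pts[["AF7"]] <- NULL
  pts[["AF8"]] <- NULL
  tibble::tibble(
    channel = names(pts),
    x = purrr::map_dbl(pts, 1),
    y = purrr::map_dbl(pts, 2),
    z = purrr::map_dbl(pts, 3)
  )
}

#' Named channel sets used by the analyses
#'
#' `posterior17` is the decoding sensor set, `central9` the beta-band set,
#' `frontal6` the theta-band set and `posterior_alpha8` the alpha-band set.
#'
#' @param set one of `"posterior17"`, `"central9"`, `"frontal6"`,
#'   `"posterior_alpha8"`.
#' @return character vector of channel labels.
#' @export
channel_set <- function(set = c("posterior17", "central9", "frontal6",
                                "posterior_alpha8")) {
  set <- match.arg(set)
  switch(set,
    posterior17 = c("P7", "P5", "P3", "P1", "P2", "P4", "P6", "P8",
                    "PO7", "PO5", "PO3", "POz", "PO4", "PO8",
                    "O1", "Oz", "O2"),
    central9 = c("C1", "Cz", "C2", "CP1", "CPz", "CP2", "P1", "Pz", "P2"),
    frontal6 = c("AF3", "AFz", "AF4", "F1", "Fz", "F2"),
    posterior_alpha8 = c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8")
  )
}

#' Signal specification for the synthetic EEG generator
#'
#' Controls the statistical structure of generated epochs: a 1/f background
#' mixed through a random spatial matrix plus white sensor noise; an
#' orientation-tuned evoked pattern on posterior channels (weight
#' `cos(2 * (theta_cued - phi_c))` with fixed random preferred angles,
#' gated by a post-probe temporal envelope), plus a weaker uncued-item
#' pattern; a frontal theta oscillation whose amplitude increases on switch
#' trials; and a central beta oscillation whose amplitude decreases on
#' switch trials, additionally scaled down with item distance and jittered
#' lognormally per trial. On switch trials the cued evoked amplitude is
#' coupled to the beta amplitude jitter so that their correlation
#' approximates `beta_decoding_coupling` (negative by default: weaker beta,
#' stronger decoding).
#'
#' @param sampling_rate Hz (default 250).
#' @param epoch_window seconds relative to cue onset, default `c(-0.75, 2.5)`.
#' @param montage tibble of channel positions, see [default_montage()].
#' @param evoked_snr amplitude of the cued orientation-tuned pattern
#'   (arbitrary units against a unit-variance noise background).
#' @param uncued_snr_ratio uncued pattern amplitude as a fraction of cued.
#' @param uncued_shares_weights if `TRUE` the uncued pattern reuses the cued
#'   preferred angles (makes cross-decoding positive); default `FALSE`.
#' @param tuning_channels channels carrying the evoked patterns.
#' @param theta_freq,beta_freq oscillation frequencies in Hz.
#' @param amp_theta,amp_beta baseline oscillation amplitudes.
#' @param theta_switch_gain fractional theta amplitude increase on switches.
#' @param beta_switch_gain fractional beta amplitude decrease on switches.
#' @param beta_distance_slope additional fractional beta decrease per degree
#'   of item distance on switch trials.
#' @param beta_decoding_coupling target correlation between trial beta
#'   amplitude and evoked amplitude on switch trials.
#' @param beta_jitter_sdlog sdlog of the lognormal trial-level beta jitter.
#' @param noise_alpha spectral exponent of the background (power ~ 1/f^alpha).
#' @param n_noise_sources number of mixed background sources.
#' @param sensor_noise_sd white sensor-noise standard deviation.
#' @param envelope_center,envelope_sd seconds; Gaussian envelope of the
#'   evoked patterns (post-probe).
#' @return an object of class `wm_signal_spec`.
#' @export
signal_spec <- function(sampling_rate = 250,
                        epoch_window = c(-0.75, 2.5),
                        montage = default_montage(),
                        evoked_snr = 0.7,
                        uncued_snr_ratio = 0.5,
                        uncued_shares_weights = FALSE,
                        tuning_channels = channel_set("posterior17"),
                        theta_freq = 6,
                        beta_freq = 20,
                        amp_theta = 0.7,
                        amp_beta = 0.7,
                        theta_switch_gain = 0.25,
                        beta_switch_gain = 0.12,
                        beta_distance_slope = 0.002,
                        beta_decoding_coupling = -0.3,
                        beta_jitter_sdlog = 0.3,
                        noise_alpha = 1,
                        n_noise_sources = 24,
                        sensor_noise_sd = 0.5,
                        envelope_center = 1.1,
                        envelope_sd = 0.15) {
  stopifnot(
    sampling_rate > 0, epoch_window[1] < epoch_window[2],
    evoked_snr >= 0, amp_theta >= 0, amp_beta >= 0,
    theta_switch_gain >= -1,
    abs(beta_decoding_coupling) <= 1,
    all(tuning_channels %in% montage$channel)
  )
  # beta gains must never drive the amplitude negative at the largest distance
  if (beta_switch_gain + beta_distance_slope * 78.75 > 1) {
    stop("beta_switch_gain + beta_distance_slope * 78.75 must be <= 1")
  }
  structure(
    as.list(environment()),
    class = "wm_signal_spec"
  )
}

raised_cos_gate <- function(t, t0, t1, ramp = 0.1) {
  g <- numeric(length(t))
  g[t >= t0 + ramp & t <= t1 - ramp] <- 1
  up <- t >= t0 & t < t0 + ramp
  g[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  dn <- t > t1 - ramp & t <= t1
  g[dn] <- 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  g
}

# unit-variance 1/f^alpha noise, one column per source
pink_noise <- function(n, n_src, fs, alpha) {
  white <- matrix(rnorm(n * n_src), n, n_src)
  spec <- mvfft(white)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)        # mirror to two-sided frequencies
  amp <- c(0, f[-1]^(-alpha / 2))
  x <- Re(mvfft(spec * amp, inverse = TRUE)) / n
  scale(x, center = TRUE, scale = apply(x, 2, sd))
}

#' Generate synthetic multichannel epochs for a trial table
#'
#' Simulates one epoch per trial according to a [signal_spec()]: background
#' noise plus orientation-tuned evoked patterns and condition-dependent
#' theta/beta oscillations (see [signal_spec()] for the signal model).
#' Oscillations are confined to the post-cue period so the pre-cue baseline
#' carries no condition information.
#'
#' @param trials trial table from [generate_task()].
#' @param spec a [signal_spec()].
#' @param seed optional integer seed.
#' @return an object of class `wm_epochs`: list with `data` (trials x
#'   channels x samples array), `times`, `sampling_rate`, `channels`,
#'   `positions` (channels x 3 matrix), `csd_applied`.
#' @export
generate_epochs <- function(trials, spec = signal_spec(), seed = NULL) {
  stopifnot(inherits(spec, "wm_signal_spec"), nrow(trials) > 0)
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$sampling_rate
  # time axis anchored so that cue onset (t = 0) falls on a sample
  times <- seq(ceiling(spec$epoch_window[1] * fs),
               floor(spec$epoch_window[2] * fs)) / fs
  n_samp <- length(times)
  channels <- spec$montage$channel
  n_ch <- length(channels)
  n_tr <- nrow(trials)

  tune_idx <- match(spec$tuning_channels, channels)
  frontal_idx <- match(intersect(channel_set("frontal6"), channels), channels)
  central_idx <- match(intersect(channel_set("central9"), channels), channels)
  if (length(frontal_idx) == 0 || length(central_idx) == 0) {
    stop("montage must include the frontal and central channel sets")
  }

  # dataset-level fixed draws
  phi_cued <- runif(length(tune_idx), 0, pi)
  phi_uncued <- if (spec$uncued_shares_weights) phi_cued else runif(length(tune_idx), 0, pi)
  mix <- matrix(rnorm(n_ch * spec$n_noise_sources), n_ch) /
    sqrt(spec$n_noise_sources)

  # per-trial amplitude machinery
  is_switch <- as.numeric(trials$condition == "switch")
  u <- rnorm(n_tr)                              # standardized beta log-jitter
  g_beta <- exp(spec$beta_jitter_sdlog * u)
  beta_mod <- 1 - is_switch *
    (spec$beta_switch_gain + spec$beta_distance_slope * trials$item_distance)
  beta_amp <- spec$amp_beta * pmax(beta_mod, 0) * g_beta
  cc <- spec$beta_decoding_coupling
  v <- cc * u + sqrt(1 - cc^2) * rnorm(n_tr)
  snr_tr <- spec$evoked_snr *
    ifelse(is_switch == 1, pmax(1 + 0.5 * v, 0.05), 1)
  theta_amp <- spec$amp_theta * (1 + spec$theta_switch_gain * is_switch)
  phase_theta <- runif(n_tr, 0, 2 * pi)
  phase_beta <- runif(n_tr, 0, 2 * pi)

  gate_theta <- raised_cos_gate(times, 0, min(2.3, max(times)))
  gate_beta <- raised_cos_gate(times, 0.1, 1.1)
  env <- exp(-(times - spec$envelope_center)^2 / (2 * spec$envelope_sd^2))

  w_cued <- outer(deg2rad(trials$theta_cued), phi_cued,
                  function(th, ph) cos(2 * th - 2 * ph))
  w_uncued <- outer(deg2rad(trials$theta_uncued), phi_uncued,
                    function(th, ph) cos(2 * th - 2 * ph))

  dat <- array(0, dim = c(n_tr, n_ch, n_samp))
  for (i in seq_len(n_tr)) {
    src <- pink_noise(n_samp, spec$n_noise_sources, fs, spec$noise_alpha)
    ep <- mix %*% t(src) +
      matrix(rnorm(n_ch * n_samp, sd = spec$sensor_noise_sd), n_ch)
    ep[frontal_idx, ] <- ep[frontal_idx, ] + rep(1, length(frontal_idx)) %o%
      (theta_amp[i] * sin(2 * pi * spec$theta_freq * times + phase_theta[i]) *
         gate_theta)
    ep[central_idx, ] <- ep[central_idx, ] + rep(1, length(central_idx)) %o%
      (beta_amp[i] * sin(2 * pi * spec$beta_freq * times + phase_beta[i]) *
         gate_beta)
    ep[tune_idx, ] <- ep[tune_idx, ] +
      (snr_tr[i] * w_cued[i, ]) %o% env +
      (snr_tr[i] * spec$uncued_snr_ratio * w_uncued[i, ]) %o% env
    dat[i, , ] <- ep
  }

  structure(
    list(
      data = dat,
      times = times,
      sampling_rate = fs,
      channels = channels,
      positions = as.matrix(spec$montage[, c("x", "y", "z")]) |>
        `rownames<-`(channels),
      csd_applied = FALSE
    ),
    class = "wm_epochs"
  )
}

#' Subset an epoch set by channels and/or trials
#'
#' @param epochs a `wm_epochs` object.
#' @param channels character vector of channel labels to keep.
#' @param trials integer vector of trial indices to keep.
#' @return a `wm_epochs` object.
#' @export
subset_epochs <- function(epochs, channels = NULL, trials = NULL) {
  stopifnot(inherits(epochs, "wm_epochs"))
  ch_idx <- seq_along(epochs$channels)
  if (!is.null(channels)) {
    ch_idx <- match(channels, epochs$channels)
    if (anyNA(ch_idx)) {
      stop("channels not in montage: ",
           paste(channels[is.na(ch_idx)], collapse = ", "))
    }
  }
  tr_idx <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else trials
  epochs$data <- epochs$data[tr_idx, ch_idx, , drop = FALSE]
  epochs$channels <- epochs$channels[ch_idx]
  epochs$positions <- epochs$positions[ch_idx, , drop = FALSE]
  epochs
}

#' @export
print.wm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<wm_epochs> %d trials x %d channels x %d samples (%.2f..%.2f s @ %g Hz)%s\n",
    d[1], d[2], d[3], min(x$times), max(x$times), x$sampling_rate,
    if (isTRUE(x$csd_applied)) " [CSD]" else ""
  ))
  invisible(x)
}
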