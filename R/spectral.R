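#' Spherical-spline surface Laplacian (current source density)
#'
#' Re-expresses scalp potentials as an estimate of the radial current
#' source density using spherical splines: the potential is interpolated
#' with spline basis functions g(cos angle) built from Legendre polynomials
#' (stiffness order m = 4, series truncated at `degree` terms), with
#' Tikhonov regularization `lambda` on the fitted coefficients, and the
#' surface Laplacian is evaluated through the companion h-function. The
#' result is reference-free (invariant to adding a constant across
#' channels) and sharpens focal topographies into center-surround patterns.
#'
#' @param epochs a `wm_epochs` object with valid channel positions.
#' @param degree truncation of the Legendre series (default 10).
#' @param lambda regularization added to the diagonal of the g-matrix
#'   (default 1e-5).
#' @param conductivity scalp conductivity in S/m (default 0.33).
#' @param head_radius head radius in meters (default 0.085) used to scale
#'   the CSD to physical units.
#' @param stiffness spline stiffness order m (default 4).
#' @return the epoch set with `data` replaced by CSD values and
#'   `csd_applied = TRUE`.
#' @export
surface_laplacian <- function(epochs, degree = 10, lambda = 1e-5,
                              conductivity = 0.33, head_radius = 0.085,
                              stiffness = 4) {
  stopifnot(inherits(epochs, "wm_epochs"))
  if (isTRUE(epochs$csd_applied)) stop("CSD already applied to these epochs")
  pos <- epochs$positions
  if (is.null(pos) || anyNA(pos)) stop("channel positions missing")
  n_ch <- nrow(pos)
  if (n_ch < 32) stop("need at least 32 channels for a stable CSD estimate")
  pos <- pos / sqrt(rowSums(pos^2))
  cosang <- tcrossprod(pos)
  cosang <- pmin(pmax(cosang, -1), 1)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-12)) {
    stop("duplicate channel positions")
  }

  # Legendre series for the spline kernel and its Laplacian companion
  gh_kernels <- function(x, degree, m) {
    pm2 <- rep(1, length(x)); pm1 <- x
    g <- h <- numeric(length(x))
    for (n in seq_len(degree)) {
      pn <- if (n == 1) pm1 else ((2 * n - 1) * x * pm1 - (n - 1) * pm2) / n
      if (n >= 2) { pm2 <- pm1; pm1 <- pn }
      fac <- (2 * n + 1) / (n * (n + 1))^m
      g <- g + fac * pn
      h <- h + fac * (n * (n + 1)) * pn
    }
    list(g = g / (4 * pi), h = h / (4 * pi))
  }
  kk <- gh_kernels(as.vector(cosang), degree, stiffness)
  G <- matrix(kk$g, n_ch, n_ch)
  H <- matrix(kk$h, n_ch, n_ch)

  # spline fit with a constant term: [0 1'; 1 G+lambda*I] [c0; c] = [0; V]
  A <- rbind(
    c(0, rep(1, n_ch)),
    cbind(rep(1, n_ch), G + diag(lambda, n_ch))
  )
  Ainv <- solve(A)

  d <- dim(epochs$data)
  V <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])  # ch x (tr*samp)
  cc <- Ainv %*% rbind(0, V)       # first row c0, rest spline coefficients
  csd <- (H %*% cc[-1, , drop = FALSE]) / (conductivity * head_radius^2)
  epochs$data <- aperm(array(csd, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  epochs$csd_applied <- TRUE
  epochs
}

#' Sliding-window Hanning-taper time-frequency decomposition
#'
#' Power at each frequency is estimated with a Hann-tapered complex dot
#' product over a window spanning five cycles of that frequency, centered on
#' each output timepoint, then converted to dB (10 log10). The taper is
#' normalized so that a pure sinusoid of amplitude A yields linear power
#' A^2 / 2. Timepoints whose five-cycle window extends beyond the epoch are
#' returned as `NA` rather than zero-padded, so edge artifacts cannot leak
#' into the pre-cue baseline.
#'
#' @param epochs a `wm_epochs` object.
#' @param freqs frequencies in Hz (default 2:40).
#' @param t_step output time step in seconds (default 0.04).
#' @param times optional explicit output timepoints (seconds); overrides
#'   `t_step`.
#' @param channels optional channel subset.
#' @param n_cycles taper length in cycles (default 5).
#' @return an object of class `wm_tfr`: list with `power` (trials x
#'   channels x freqs x times array, dB), `freqs`, `times`, `channels`,
#'   `baseline_corrected`, `baseline_window`.
#' @export
tfr_hanning <- function(epochs, freqs = 2:40, t_step = 0.04, times = NULL,
                        channels = NULL, n_cycles = 5) {
  stopifnot(inherits(epochs, "wm_epochs"))
  if (!is.null(channels)) epochs <- subset_epochs(epochs, channels = channels)
  fs <- epochs$sampling_rate
  if (any(freqs <= 0) || any(freqs > fs / 2)) {
    stop("frequencies must lie in (0, Nyquist]")
  }
  t_axis <- epochs$times
  if (is.null(times)) {
    # multiples of t_step inside the epoch, so standard analysis windows
    # (e.g. 0.4-0.8 s) fall exactly on output timepoints
    times <- seq(ceiling(min(t_axis) / t_step - 1e-9),
                 floor(max(t_axis) / t_step + 1e-9)) * t_step
  }
  d <- dim(epochs$data)
  X <- matrix(epochs$data, nrow = d[1] * d[2])   # (tr*ch) x samples
  n_t <- length(times); n_f <- length(freqs)
  pow <- array(NA_real_, dim = c(d[1], d[2], n_f, n_t))

  t0 <- t_axis[1]
  for (fi in seq_len(n_f)) {
    f <- freqs[fi]
    half <- floor(n_cycles / f * fs / 2)
    len <- 2 * half + 1
    if (len > d[3]) next
    hann <- 0.5 * (1 - cos(2 * pi * seq(0, len - 1) / (len - 1)))
    twin <- (seq_len(len) - 1 - half) / fs
    kern <- hann * exp(-2i * pi * f * twin) / (sum(hann) / 2)
    # requested timepoints snap to the nearest sample (< half-sample error)
    centers <- round((times - t0) * fs) + 1
    ok <- centers - half >= 1 & centers + half <= d[3]
    if (!any(ok)) next
    cols <- which(ok)
    Kr <- matrix(0, d[3], length(cols))
    Ki <- matrix(0, d[3], length(cols))
    for (j in seq_along(cols)) {
      idx <- (centers[cols[j]] - half):(centers[cols[j]] + half)
      Kr[idx, j] <- Re(kern)
      Ki[idx, j] <- Im(kern)
    }
    p_lin <- ((X %*% Kr)^2 + (X %*% Ki)^2) / 2
    pow[, , fi, cols] <- array(10 * log10(pmax(p_lin, 1e-300)),
                               dim = c(d[1], d[2], length(cols)))
  }

  structure(
    list(
      power = pow, freqs = freqs, times = times,
      channels = epochs$channels,
      baseline_corrected = FALSE, baseline_window = NULL
    ),
    class = "wm_tfr"
  )
}

#' Baseline-correct a time-frequency representation (dB)
#'
#' Subtracts the mean pre-cue dB power in the baseline window from every
#' timepoint. By default the baseline is the average across trials per
#' channel and frequency (condition-independent); `per_trial = TRUE`
#' subtracts each trial's own baseline instead. Frequencies whose five-cycle
#' windows do not fit anywhere inside the baseline window inherit `NA`.
#'
#' @param tfr a `wm_tfr` object (in dB, not yet baselined).
#' @param window baseline window in seconds, default `c(-0.75, -0.25)`.
#' @param per_trial use trial-wise baselines (default `FALSE`).
#' @return the baselined `wm_tfr` with `baseline_corrected = TRUE`.
#' @export
baseline_db <- function(tfr, window = c(-0.75, -0.25), per_trial = FALSE) {
  stopifnot(inherits(tfr, "wm_tfr"))
  if (isTRUE(tfr$baseline_corrected)) stop("TFR is already baseline-corrected")
  sel <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(sel)) stop("baseline window lies outside the TFR time axis")
  base <- apply(tfr$power[, , , sel, drop = FALSE], c(1, 2, 3), mean,
                na.rm = TRUE)                     # trials x ch x freqs
  base[is.nan(base)] <- NA_real_
  if (!per_trial) {
    base <- array(
      rep(colMeans(base, na.rm = TRUE), each = dim(base)[1]),
      dim = dim(base)
    )
  }
  tfr$power <- tfr$power - as.vector(base)   # recycles over the time dim
  tfr$baseline_corrected <- TRUE
  tfr$baseline_window <- window
  tfr
}

#' Band/channel/time-window presets
#'
#' Standard selections used throughout the analyses: beta 15-25 Hz at
#' central channels, theta 4-8 Hz at frontal channels, alpha 8-14 Hz at
#' posterior channels, each with the 0.4-0.8 s post-cue window.
#'
#' @param name `"beta"`, `"theta"` or `"alpha"`.
#' @return list with `band` (Hz), `channels`, `window` (s).
#' @export
band_preset <- function(name = c("beta", "theta", "alpha")) {
  name <- match.arg(name)
  switch(name,
    beta = list(band = c(15, 25), channels = channel_set("central9"),
                window = c(0.4, 0.8)),
    theta = list(band = c(4, 8), channels = channel_set("frontal6"),
                 window = c(0.4, 0.8)),
    alpha = list(band = c(8, 14), channels = channel_set("posterior_alpha8"),
                 window = c(0.4, 0.8))
  )
}

#' Per-trial mean band power
#'
#' Averages TFR power over a frequency band, channel set and time window,
#' returning one value per trial. `NA` cells (edge timepoints without a
#' full taper window) are dropped from the average.
#'
#' @param tfr a `wm_tfr` object.
#' @param band frequency range in Hz, `c(lo, hi)` inclusive.
#' @param channels channel labels to average.
#' @param time_window time range in seconds, `c(lo, hi)` inclusive.
#' @param preset optional preset name (see [band_preset()]); overrides the
#'   other selection arguments.
#' @return tibble with columns `trial` and `power` (dB).
#' @export
band_power <- function(tfr, band = NULL, channels = NULL, time_window = NULL,
                       preset = NULL) {
  stopifnot(inherits(tfr, "wm_tfr"))
  if (!is.null(preset)) {
    ps <- band_preset(preset)
    band <- ps$band; channels <- ps$channels; time_window <- ps$window
  }
  f_sel <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  c_sel <- match(channels, tfr$channels)
  if (anyNA(c_sel)) {
    stop("channels not in TFR: ",
         paste(channels[is.na(c_sel)], collapse = ", "))
  }
  t_sel <- which(tfr$times >= time_window[1] & tfr$times <= time_window[2])
  if (length(f_sel) == 0 || length(c_sel) == 0 || length(t_sel) == 0) {
    stop("empty band/channel/time selection")
  }
  sub <- tfr$power[, c_sel, f_sel, t_sel, drop = FALSE]
  tibble::tibble(
    trial = seq_len(dim(sub)[1]),
    power = apply(sub, 1, mean, na.rm = TRUE)
  )
}
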