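test_that("a pure sinusoid yields calibrated, time-stable band power", {
  fs <- 250
  t <- (0:1499) / fs
  a1 <- 2
  x <- array(0, dim = c(1, 2, length(t)))
  x[1, 1, ] <- a1 * sin(2 * pi * 20 * t)
  x[1, 2, ] <- 2 * a1 * sin(2 * pi * 20 * t)
  ep <- toy_epochs(x, fs = fs)
  tfr <- tfr_hanning(ep, freqs = c(10, 20, 30), t_step = 0.1)
  mid <- which(tfr$times > 1 & tfr$times < 5)
  p20 <- tfr$power[1, 1, 2, mid]
  # linear power A^2/2, i.e. 10*log10(2) dB for amplitude 2
  expect_equal(mean(p20), 10 * log10(a1^2 / 2), tolerance = 0.01)
  expect_lt(sd(p20), 0.01)                      # constant over time
  # doubling the amplitude adds 6.02 dB
  p20b <- tfr$power[1, 2, 2, mid]
  expect_equal(mean(p20b - p20), 20 * log10(2), tolerance = 0.01)
  # off-peak frequencies carry far less power
  expect_lt(mean(tfr$power[1, 1, 1, mid]), mean(p20) - 30)
  # frequencies outside (0, Nyquist] are rejected
  expect_error(tfr_hanning(ep, freqs = c(0, 10)), "Nyquist")
  expect_error(tfr_hanning(ep, freqs = 200), "Nyquist")
})

test_that("white-noise power is flat over time and matches the taper factor", {
  set.seed(21)
  fs <- 250
  n <- 2000
  sd_noise <- 1.5
  x <- array(rnorm(60 * n, sd = sd_noise), dim = c(60, 1, n))
  ep <- toy_epochs(x, fs = fs)
  tfr <- tfr_hanning(ep, freqs = 20, t_step = 0.2)
  mid <- which(tfr$times > 1 & tfr$times < 7)
  lin <- 10^(tfr$power[, 1, 1, mid] / 10)
  # independent expectation: E|sum(w x e)|^2 = sigma^2 sum(w^2), kernel is
  # normalized by sum(w)/2 and power halves the squared magnitude
  len <- 2 * floor(5 / 20 * fs / 2) + 1
  w <- 0.5 * (1 - cos(2 * pi * seq(0, len - 1) / (len - 1)))
  expected <- sd_noise^2 * sum(w^2) / (sum(w) / 2)^2 / 2
  expect_equal(mean(lin), expected, tolerance = 0.05)
  # stationarity: time-resolved means stay within sampling error
  tm <- colMeans(lin)
  expect_lt(max(abs(tm - mean(lin))) / mean(lin), 0.35)
})

test_that("an amplitude-modulated burst is tracked within taper smearing", {
  fs <- 250
  t <- (0:1999) / fs
  env <- exp(-(t - 4)^2 / (2 * 0.5^2))
  x <- array(env * sin(2 * pi * 20 * t), dim = c(1, 1, length(t)))
  ep <- toy_epochs(x, fs = fs)
  tfr <- tfr_hanning(ep, freqs = 20, t_step = 0.05)
  p <- tfr$power[1, 1, 1, ]
  ok <- is.finite(p)
  # peak time within half a taper width of the envelope peak
  expect_lt(abs(tfr$times[ok][which.max(p[ok])] - 4), 0.125)
  # peak power matches the envelope maximum (amplitude 1 -> -3.01 dB)
  expect_equal(max(p[ok]), 10 * log10(0.5), tolerance = 0.2)
  # power tracks the squared envelope where the envelope is substantial
  sel <- ok & tfr$times > 2.5 & tfr$times < 5.5
  expect_gt(cor(p[sel], 20 * log10(env[match(round(tfr$times[sel] * fs),
                                             round(t * fs))])), 0.99)
})

test_that("edge timepoints without a full five-cycle window are missing", {
  fs <- 250
  x <- array(rnorm(2 * 500), dim = c(2, 1, 500))   # 2 s epoch
  ep <- toy_epochs(x, fs = fs, t0 = -0.75)
  tfr <- tfr_hanning(ep, freqs = c(4, 20), t_step = 0.04)
  # 4 Hz needs +-0.625 s around each timepoint
  t4 <- tfr$power[1, 1, 1, ]
  expect_true(any(is.na(t4)))
  expect_gte(min(tfr$times[is.finite(t4)]), -0.75 + 0.625 - 0.02)
  expect_lte(max(tfr$times[is.finite(t4)]), max(ep$times) - 0.625 + 0.02)
  # 20 Hz has valid baseline points
  t20 <- tfr$power[1, 1, 2, ]
  expect_true(any(is.finite(t20[tfr$times <= -0.25])))
})

test_that("dB baselining subtracts the pre-cue level", {
  fs <- 250
  t_axis <- seq(-188, 375) / fs
  n <- length(t_axis)
  # constant-amplitude oscillation: baselined power is 0 dB everywhere
  x <- array(0, dim = c(3, 2, n))
  for (tr in 1:3) for (ch in 1:2) x[tr, ch, ] <- sin(2 * pi * 20 * t_axis)
  ep <- toy_epochs(x, fs = fs, t0 = t_axis[1])
  tfr <- baseline_db(tfr_hanning(ep, freqs = 20, t_step = 0.04),
                     window = c(-0.6, -0.3))
  expect_true(tfr$baseline_corrected)
  vals <- tfr$power[, , 1, ][is.finite(tfr$power[, , 1, ])]
  expect_lt(max(abs(vals)), 0.01)     # dB; residual taper leakage only
  expect_error(baseline_db(tfr), "already")

  # amplitude step of sqrt(2) after t=0: baselined level is +3.01 dB
  x2 <- x
  gain <- ifelse(t_axis > 0, sqrt(2), 1)
  for (tr in 1:3) for (ch in 1:2) x2[tr, ch, ] <- gain * x[tr, ch, ]
  ep2 <- toy_epochs(x2, fs = fs, t0 = t_axis[1])
  tfr2 <- baseline_db(tfr_hanning(ep2, freqs = 20, t_step = 0.04),
                      window = c(-0.6, -0.3))
  late <- tfr2$times > 0.3 & tfr2$times < 1.2
  expect_equal(mean(tfr2$power[1, 1, 1, late], na.rm = TRUE),
               10 * log10(2), tolerance = 0.02)
})

test_that("condition contrasts are invariant to condition-independent baselining", {
  set.seed(51)
  fs <- 250
  t_axis <- seq(-188, 375) / fs
  n <- length(t_axis)
  x <- array(rnorm(20 * 2 * n), dim = c(20, 2, n))
  # post-cue oscillation stronger for the first 10 trials ("condition A")
  gate <- as.numeric(t_axis > 0.1 & t_axis < 1.2)
  for (tr in 1:20) {
    amp <- if (tr <= 10) 1.5 else 1.0
    x[tr, 1, ] <- x[tr, 1, ] + amp * gate * sin(2 * pi * 20 * t_axis)
  }
  ep <- toy_epochs(x, fs = fs, t0 = t_axis[1])
  raw <- tfr_hanning(ep, freqs = 15:25, t_step = 0.04)
  bl <- baseline_db(raw, window = c(-0.6, -0.3))
  bp_raw <- band_power(raw, band = c(15, 25), channels = "ch1",
                       time_window = c(0.4, 0.8))
  bp_bl <- band_power(bl, band = c(15, 25), channels = "ch1",
                      time_window = c(0.4, 0.8))
  d_raw <- mean(bp_raw$power[1:10]) - mean(bp_raw$power[11:20])
  d_bl <- mean(bp_bl$power[1:10]) - mean(bp_bl$power[11:20])
  # trial-average baseline is a common constant: the contrast is unchanged
  expect_equal(d_raw, d_bl, tolerance = 1e-10)
  expect_gt(d_raw, 0)
})

test_that("band power averaging is selection-exact and order-invariant", {
  pow <- array(rnorm(4 * 3 * 5 * 6), dim = c(4, 3, 5, 6))
  tfr <- structure(
    list(power = pow, freqs = 10:14, times = seq(0, 1, by = 0.2),
         channels = c("a", "b", "c"),
         baseline_corrected = TRUE, baseline_window = c(-0.5, -0.25)),
    class = "wm_tfr"
  )
  one <- band_power(tfr, band = c(11, 11), channels = "b",
                    time_window = c(0.4, 0.4))
  expect_equal(one$power, pow[, 2, 2, 3])
  # channels-then-freqs vs freqs-then-channels averaging
  sel <- band_power(tfr, band = c(11, 13), channels = c("a", "c"),
                    time_window = c(0.2, 0.8))
  manual <- apply(pow[, c(1, 3), 2:4, 2:5], 1, mean)
  expect_equal(sel$power, manual)
  expect_error(band_power(tfr, band = c(50, 60), channels = "a",
                          time_window = c(0, 1)), "empty")
  expect_error(band_power(tfr, band = c(11, 13), channels = "zz",
                          time_window = c(0, 1)), "not in TFR")
})

test_that("the surface Laplacian is reference-free and sharpens focal maps", {
  set.seed(61)
  montage <- default_montage()
  n_ch <- nrow(montage)
  n_samp <- 50
  base <- array(rnorm(2 * n_ch * n_samp), dim = c(2, n_ch, n_samp))
  pos <- as.matrix(montage[, c("x", "y", "z")])
  rownames(pos) <- montage$channel
  mk <- function(a) toy_epochs(a, channels = montage$channel, positions = pos)

  # spatially uniform potential: CSD vanishes
  flat <- array(rep(rnorm(n_samp), each = 2 * n_ch), dim = c(2, n_ch, n_samp))
  csd_flat <- surface_laplacian(mk(flat))
  expect_lt(max(abs(csd_flat$data)) / max(abs(flat)), 1e-6)

  # invariance to a common offset across channels
  csd1 <- surface_laplacian(mk(base))
  shifted <- base + array(rep(rnorm(n_samp) * 50, each = 2 * n_ch),
                          dim = dim(base))
  csd2 <- surface_laplacian(mk(shifted))
  expect_equal(csd1$data, csd2$data, tolerance = 1e-6)
  expect_true(csd1$csd_applied)
  expect_error(surface_laplacian(csd1), "already")

  # focal Gaussian topography: center-surround sign structure
  cz <- which(montage$channel == "Cz")
  angdist <- acos(pmin(pmax(pos %*% pos[cz, ], -1), 1))
  topo <- exp(-(angdist / 0.6)^2)
  foc <- array(rep(topo, each = 1), dim = c(1, n_ch, 1))
  csd_f <- surface_laplacian(mk(foc))
  v <- csd_f$data[1, , 1]
  expect_gt(v[cz], 0)                         # positive peak at the center
  ring <- which(angdist > 0.7 & angdist < 1.6)
  expect_lt(min(v[ring]), 0)                  # negative surround
  expect_equal(montage$channel[which.max(v)], "Cz")
})
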