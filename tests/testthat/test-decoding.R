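test_that("pooled features have the documented bookkeeping", {
  set.seed(71)
  spec <- decode_test_spec(evoked_snr = 0, amp_theta = 0, amp_beta = 0)
  tt <- generate_task(task_config(n_blocks = 2), seed = 71)
  ep <- generate_epochs(tt, spec)
  fm <- build_features(ep, t = 1.0)
  expect_equal(ncol(fm$x), 629)                    # 37 x 17
  expect_equal(length(fm$sensors), 17)
  expect_equal(length(fm$time_offsets), 37)
  # backward-looking window: samples strictly inside (t - 0.45, t]
  expect_equal(max(fm$time_offsets), 0)
  expect_gt(min(fm$time_offsets), -0.45)
  expect_equal(diff(fm$time_offsets)[1], 0.012, tolerance = 1e-9)
  expect_error(build_features(ep, t = -0.5), "out of epoch range")
})

test_that("feature values equal a direct re-implementation on a toy epoch", {
  fs <- 250
  n <- 500
  set.seed(72)
  dat <- array(rnorm(2 * 3 * n), dim = c(2, 3, n))
  # constant-in-time channel demeans to exactly zero
  dat[1, 2, ] <- 7
  ep <- toy_epochs(dat, fs = fs, t0 = 0)
  fm <- build_features(ep, t = 1.0, sensors = c("ch1", "ch2", "ch3"))
  expect_equal(ncol(fm$x), 3 * 37)
  expect_equal(unname(fm$x[1, 38:74]), rep(0, 37))
  # independent computation: decimated window samples minus the sensor mean
  i_t <- round(1.0 * fs) + 1
  idx <- i_t - 3 * (36:0)
  for (ch in 1:3) {
    raw <- dat[2, ch, idx]
    expect_equal(unname(fm$x[2, (ch - 1) * 37 + 1:37]), raw - mean(raw))
  }
  # without demeaning the raw decimated values are returned
  fm_raw <- build_features(ep, t = 1.0, sensors = c("ch1", "ch2", "ch3"),
                           demean = FALSE)
  expect_equal(unname(fm_raw$x[2, 1:37]), dat[2, 1, idx])
})

test_that("shrinkage covariance is well-conditioned and consistent", {
  set.seed(73)
  # identity-generated data, large n: estimate approaches identity
  x <- matrix(rnorm(4000 * 8), 4000, 8)
  est <- shrinkage_covariance(x)
  expect_lt(max(abs(est$sigma - diag(8))), 0.12)
  # n < p: estimate is still positive definite
  x2 <- matrix(rnorm(20 * 50), 20, 50)
  est2 <- shrinkage_covariance(x2)
  expect_gt(est2$shrinkage, 0)
  expect_no_error(chol(est2$sigma))
  ev <- eigen(est2$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(ev) / min(ev), 1e6)
  # zero-variance feature flagged but handled
  x3 <- cbind(matrix(rnorm(30 * 3), 30, 3), 0)
  expect_warning(est3 <- shrinkage_covariance(x3), "zero-variance")
  expect_no_error(chol(est3$sigma))
  expect_error(shrinkage_covariance(x2[1, , drop = FALSE]), "at least 2")
})

test_that("shrinkage intensity matches the analytic formula computed longhand", {
  set.seed(74)
  x <- matrix(rnorm(40 * 6), 40, 6)
  est <- shrinkage_covariance(x)
  # independent longhand computation
  xc <- scale(x, center = TRUE, scale = FALSE)
  n <- nrow(xc); p <- ncol(xc)
  s <- t(xc) %*% xc / n
  mu <- mean(diag(s))
  d2 <- sum((s - mu * diag(p))^2)
  b2bar <- 0
  for (k in seq_len(n)) {
    b2bar <- b2bar + sum((tcrossprod(xc[k, ]) - s)^2)
  }
  b2bar <- b2bar / n^2
  rho <- min(b2bar, d2) / d2
  expect_equal(est$shrinkage, rho, tolerance = 1e-10)
  expect_equal(est$sigma, rho * mu * diag(p) + (1 - rho) * s,
               tolerance = 1e-10)
})

test_that("tuning curves center on the test orientation and invert distances", {
  set.seed(75)
  grid <- 2.8125 + 11.25 * (0:15)
  train_x <- matrix(rnorm(160 * 5), 160, 5)
  train_ori <- rep(grid, each = 10)
  # test row equal to a class mean attains maximal similarity at offset 0
  m9 <- colMeans(train_x[train_ori == grid[9], ])
  curve <- mahalanobis_tuning(train_x, train_ori, m9, grid[9], diag(5))
  expect_equal(curve$offsets, 11.25 * (1:16) - 90)
  expect_equal(which.max(curve$similarity), curve$center_index)
  expect_equal(curve$similarity[curve$center_index], 0)
  # identity covariance reduces to Euclidean distance
  x0 <- rnorm(5)
  curve2 <- mahalanobis_tuning(train_x, train_ori, x0, grid[1], diag(5))
  m1 <- colMeans(train_x[train_ori == grid[1], ])
  expect_equal(curve2$similarity[curve2$center_index],
               -sqrt(sum((x0 - m1)^2)))
  # missing training class is an error without a fallback
  expect_error(
    mahalanobis_tuning(train_x[train_ori != grid[3], ],
                       train_ori[train_ori != grid[3]],
                       x0, grid[1], diag(5)),
    "absent"
  )
})

test_that("the cosine vector mean scores flat, tuned and inverted curves", {
  offs <- 11.25 * (1:16) - 90
  flat <- structure(list(similarity = rep(3.7, 16), offsets = offs,
                         center_index = 8), class = "wm_tuning")
  expect_equal(decoding_score(flat), 0, tolerance = 1e-12)
  cosine <- cos(2 * offs * pi / 180)
  expect_equal(decoding_score(cosine), 8, tolerance = 1e-12)
  expect_equal(decoding_score(-cosine), -8, tolerance = 1e-12)
  # offset invariance: cosine weights sum to zero
  expect_equal(decoding_score(cosine + 123.4), 8, tolerance = 1e-9)
})

test_that("fold construction uses contiguous blocks with the stated sizes", {
  f128 <- wmswitch:::fold_blocks(1:128)
  expect_equal(as.vector(table(f128)), c(rep(10, 12), 8))
  expect_equal(length(unique(f128)), 13)
  # folds are contiguous in block order
  expect_true(all(diff(f128) >= 0))
  f16 <- wmswitch:::fold_blocks(1:16)
  expect_equal(length(unique(f16)), 13)
  expect_equal(sum(table(f16)), 16)
  expect_error(wmswitch:::fold_blocks(1:10), "at least 13")
})

test_that("decoding pure noise gives scores centered on zero", {
  set.seed(76)
  spec <- decode_test_spec(evoked_snr = 0, amp_theta = 0, amp_beta = 0,
                           theta_switch_gain = 0, beta_switch_gain = 0,
                           beta_distance_slope = 0,
                           beta_decoding_coupling = 0)
  tt <- generate_task(task_config(n_blocks = 13,
                                  balance_orientations = TRUE), seed = 76)
  tt <- simulate_responses(tt)
  ep <- generate_epochs(tt, spec)
  dec <- suppressWarnings(
    crossval_decode(ep, tt, target = "cued", timepoints = 1.1)
  )
  z <- mean(dec$score) / (sd(dec$score) / sqrt(nrow(dec)))
  expect_lt(abs(z), 3.5)
})

test_that("planted tuning is recovered and grows with signal strength", {
  set.seed(77)
  tt <- generate_task(task_config(n_blocks = 13,
                                  balance_orientations = TRUE), seed = 77)
  tt <- simulate_responses(tt)
  scores <- purrr::map_dbl(c(0.35, 0.7), function(snr) {
    ep <- generate_epochs(tt, decode_test_spec(evoked_snr = snr), seed = 770)
    dec <- suppressWarnings(
      crossval_decode(ep, tt, target = "cued", timepoints = 1.1)
    )
    mean(dec$score)
  })
  expect_gt(scores[1], 0)
  expect_gt(scores[2], scores[1])
})

test_that("cross-decoding tracks whether the uncued item shares channel weights", {
  set.seed(78)
  tt <- generate_task(task_config(n_blocks = 26,
                                  balance_orientations = TRUE), seed = 78)
  tt <- simulate_responses(tt)
  ep_shared <- generate_epochs(
    tt, decode_test_spec(uncued_shares_weights = TRUE), seed = 781
  )
  dec_shared <- suppressWarnings(
    crossval_decode(ep_shared, tt, target = "cross", timepoints = 1.1)
  )
  ep_indep <- generate_epochs(
    tt, decode_test_spec(uncued_shares_weights = FALSE), seed = 781
  )
  dec_indep <- suppressWarnings(
    crossval_decode(ep_indep, tt, target = "cross", timepoints = 1.1)
  )
  # shared weights make the cued-trained decoder transfer to uncued items
  expect_gt(mean(dec_shared$score), 0)
  expect_gt(mean(dec_shared$score), mean(dec_indep$score) + 0.5)
})
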