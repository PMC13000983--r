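#' Build pooled spatiotemporal decoding features
#'
#' For a decoding timepoint `t`, pools the signal of the posterior sensors
#' over a 450 ms backward-looking window: the 250 Hz signal is decimated to
#' one sample every 12 ms (every third sample), the 37 window samples
#' strictly inside `(t - 0.45, t]` are taken per sensor, each sensor's
#' samples are demeaned across the window, and sensors are concatenated -
#' 37 x 17 = 629 features with the default sensor set.
#'
#' @param epochs a `wm_epochs` object at 250 Hz.
#' @param t decoding timepoint in seconds relative to cue onset.
#' @param sensors sensor labels (default the 17-channel posterior set).
#' @param window_s backward window length in seconds (default 0.45).
#' @param decim decimation factor (default 3, i.e. 83.3 Hz).
#' @param demean demean across window timepoints within each sensor
#'   (default `TRUE`).
#' @return an object of class `wm_features`: list with `x` (trials x
#'   features matrix), `sensors`, `time_offsets` (seconds re `t`), `t`.
#' @export
build_features <- function(epochs, t,
                           sensors = channel_set("posterior17"),
                           window_s = 0.45, decim = 3, demean = TRUE) {
  stopifnot(inherits(epochs, "wm_epochs"))
  ep <- subset_epochs(epochs, channels = sensors)
  fs <- ep$sampling_rate
  step <- decim / fs
  n_win <- floor(window_s / step)          # samples strictly inside (t-w, t]
  i_t <- which.min(abs(ep$times - t))
  if (abs(ep$times[i_t] - t) > 1 / fs) {
    stop("timepoint t lies outside the epoch time axis")
  }
  idx <- i_t - decim * ((n_win - 1):0)
  if (min(idx) < 1) stop("window [t - ", window_s, ", t] out of epoch range")
  d <- dim(ep$data)
  sub <- ep$data[, , idx, drop = FALSE]          # tr x sensors x n_win
  if (demean) {
    mu <- apply(sub, c(1, 2), mean)
    sub <- sub - as.vector(mu)        # recycles over the window dimension
  }
  # feature order: sensor-major (all window samples of sensor 1, then 2, ...)
  x <- matrix(aperm(sub, c(1, 3, 2)), nrow = d[1])
  structure(
    list(
      x = x,
      sensors = ep$channels,
      time_offsets = (idx - i_t) / fs,
      t = t
    ),
    class = "wm_features"
  )
}

#' Ledoit-Wolf analytic shrinkage covariance
#'
#' Sample covariance of the rows of `x` shrunk toward a scaled identity
#' with the analytic (data-derived) shrinkage intensity. The estimate is
#' symmetric positive definite even when features outnumber observations,
#' which is what makes Mahalanobis distances computable on 629 features
#' from a couple of hundred trials.
#'
#' @param x numeric matrix, observations in rows. Rows are expected to be
#'   residuals (class means already removed); the estimator centers them
#'   once more for safety.
#' @return list with `sigma` (p x p covariance), `shrinkage` (intensity in
#'   `[0, 1]`), `mu` (identity scale).
#' @export
shrinkage_covariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 residual rows")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (any(apply(x, 2, function(v) all(abs(v) < 1e-12)))) {
    warning("zero-variance features present; shrinkage handles the rank deficiency")
  }
  s <- crossprod(x) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2)
  # b2bar = (1/n^2) sum_k || x_k x_k' - S ||_F^2  =  (1/n^2) sum ||x_k||^4 - tr(S^2)/n
  norm4 <- sum(rowSums(x^2)^2)
  b2bar <- norm4 / n^2 - sum(s^2) / n
  b2 <- min(max(b2bar, 0), d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  sigma <- rho * diag(mu, p) + (1 - rho) * s
  list(sigma = sigma, shrinkage = rho, mu = mu)
}

#' Mahalanobis tuning curve for one test trial
#'
#' Computes the Mahalanobis distances between a test-trial feature vector
#' and the 16 orientation class means of the training data, circularly
#' shifts the 16-vector so the test trial's own orientation sits at offset
#' 0, and sign-flips the distances so larger values mean greater pattern
#' similarity.
#'
#' @param train_x training feature matrix (trials x features).
#' @param train_ori training orientations (degrees, on the 16-point grid).
#' @param test_x test feature vector (or 1 x p matrix).
#' @param test_ori orientation of the test trial.
#' @param sigma noise covariance (from [shrinkage_covariance()]).
#' @param grid the 16-point orientation grid.
#' @param squared use squared Mahalanobis distances (default `FALSE`).
#' @return an object of class `wm_tuning`: list with `similarity` (16
#'   values, sign-flipped distances), `offsets` (degrees, -78.75..90) and
#'   `center_index`.
#' @export
mahalanobis_tuning <- function(train_x, train_ori, test_x, test_ori, sigma,
                               grid = 2.8125 + 11.25 * (0:15),
                               squared = FALSE) {
  m <- class_means(train_x, train_ori, grid)
  ch <- chol(sigma)
  diffs <- sweep(m, 2, as.numeric(test_x))
  w <- backsolve(ch, t(diffs), transpose = TRUE)   # solves t(ch) %*% w = t(diffs)
  d2 <- colSums(w^2)
  d <- if (squared) d2 else sqrt(d2)
  shift_tuning(-d, grid, test_ori)
}

# class means per orientation; when a class is absent from `x` (a fold's
# training portion) the mean is pooled from `fallback_x` (all available
# trials); a class absent everywhere is an error
class_means <- function(x, ori, grid, fallback_x = NULL, fallback_ori = NULL) {
  key <- match(round(ori, 6), round(grid, 6))
  if (anyNA(key)) stop("orientations off the 16-point grid")
  missing <- setdiff(seq_along(grid), unique(key))
  if (length(missing) > 0 && is.null(fallback_x)) {
    stop("orientation(s) absent from training data: ",
         paste(grid[missing], collapse = ", "))
  }
  m <- matrix(0, length(grid), ncol(x))
  for (j in seq_along(grid)) {
    if (j %in% missing) {
      fkey <- match(round(fallback_ori, 6), round(grid, 6))
      rows <- fallback_x[fkey == j, , drop = FALSE]
      if (nrow(rows) == 0) {
        stop("orientation ", grid[j], " absent from the entire session")
      }
      warning("orientation ", grid[j],
              " missing from a training fold; pooled over all trials")
      m[j, ] <- colMeans(rows)
    } else {
      m[j, ] <- colMeans(x[key == j, , drop = FALSE])
    }
  }
  m
}

# circularly shift a per-class vector so the test orientation sits at offset 0
shift_tuning <- function(values, grid, test_ori) {
  n <- length(grid)
  offsets <- 11.25 * (1:n) - 90          # -78.75 .. +90
  j0 <- match(round(test_ori, 6), round(grid, 6))
  if (is.na(j0)) stop("test orientation off the grid")
  center_index <- which(offsets == 0)
  # value at offset o belongs to the class at orientation test_ori + o (mod 180)
  src <- ((j0 - 1 + (offsets / 11.25)) %% n) + 1
  structure(
    list(similarity = values[src], offsets = offsets,
         center_index = center_index),
    class = "wm_tuning"
  )
}

#' Cosine-vector-mean decoding score of a tuning curve
#'
#' Sum of the tuning curve weighted by the cosine of the doubled orientation
#' offsets: `sum_j cos(2 theta_j) D_j`. The doubled-angle cosine weights sum
#' to zero over the 16-point grid, so a flat curve scores exactly 0, a curve
#' peaking at offset 0 scores positive, and an inverted curve negative. The
#' score is invariant to adding a constant to all curve values.
#'
#' @param curve a `wm_tuning` object, or a bare numeric vector of 16
#'   similarity values on the standard offset grid.
#' @return numeric decoding score (arbitrary units).
#' @export
decoding_score <- function(curve) {
  if (inherits(curve, "wm_tuning")) {
    v <- curve$similarity
    offs <- curve$offsets
  } else {
    v <- as.numeric(curve)
    offs <- 11.25 * seq_along(v) - 90
  }
  sum(cos(2 * deg2rad(offs)) * v)
}

# contiguous-block fold assignment: sizes as equal as possible while
# matching the convention that early folds take ceiling(n/k) blocks
fold_blocks <- function(block_ids, k = 13) {
  blocks <- sort(unique(block_ids))
  n <- length(blocks)
  if (n < k) stop("need at least ", k, " blocks for ", k, "-fold CV")
  sizes <- integer(k)
  remaining <- n
  for (i in seq_len(k)) {
    sizes[i] <- min(ceiling(n / k), remaining - (k - i))
    remaining <- remaining - sizes[i]
  }
  fold_of_block <- rep(seq_len(k), times = sizes)
  fold_of_block[match(block_ids, blocks)]
}

#' Cross-validated Mahalanobis decoding of memorized orientations
#'
#' Runs the full decoding pipeline: 13 folds of contiguous blocks; per fold
#' and decoding timepoint, orientation class means and a shrinkage noise
#' covariance (on residuals after removing class means) are estimated from
#' the training folds, and every test trial's tuning curve is summarized by
#' the cosine-vector-mean score. Targets: `"cued"`/`"uncued"` train and
#' test on that item's orientation; `"cross"` trains on the cued and tests
#' on the uncued orientation.
#'
#' @param epochs a `wm_epochs` object.
#' @param trials the matching trial table (for block ids and orientations).
#' @param target `"cued"`, `"uncued"` or `"cross"`.
#' @param timepoints decoding timepoints in seconds (default
#'   `seq(0.8, 1.4, by = 0.05)`).
#' @param n_folds number of cross-validation folds (default 13).
#' @param sensors,window_s,decim,demean passed to [build_features()].
#' @param squared passed to [mahalanobis_tuning()].
#' @param grid the 16-point orientation grid.
#' @return tibble with columns `trial`, `time`, `target`, `score`, `fold`.
#' @export
crossval_decode <- function(epochs, trials,
                            target = c("cued", "uncued", "cross"),
                            timepoints = seq(0.8, 1.4, by = 0.05),
                            n_folds = 13,
                            sensors = channel_set("posterior17"),
                            window_s = 0.45, decim = 3, demean = TRUE,
                            squared = FALSE,
                            grid = 2.8125 + 11.25 * (0:15)) {
  target <- match.arg(target)
  stopifnot(nrow(trials) == dim(epochs$data)[1])
  fold <- fold_blocks(trials$block_id, n_folds)
  train_ori <- if (target == "uncued") trials$theta_uncued else trials$theta_cued
  test_ori <- if (target == "cued") trials$theta_cued else trials$theta_uncued

  out <- vector("list", length(timepoints))
  for (ti in seq_along(timepoints)) {
    fm <- build_features(epochs, timepoints[ti], sensors = sensors,
                         window_s = window_s, decim = decim, demean = demean)
    x <- fm$x
    scores <- numeric(nrow(x))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      te <- which(fold == f)
      m <- class_means(x[tr, , drop = FALSE], train_ori[tr], grid,
                       fallback_x = x, fallback_ori = train_ori)
      key <- match(round(train_ori[tr], 6), round(grid, 6))
      residuals <- x[tr, , drop = FALSE] - m[key, , drop = FALSE]
      sc <- shrinkage_covariance(residuals)
      ch <- chol(sc$sigma)
      # all test trials at once: d2_ij = ||u_i||^2 + ||v_j||^2 - 2 u_i . v_j
      u <- t(backsolve(ch, t(x[te, , drop = FALSE]), transpose = TRUE))
      v <- t(backsolve(ch, t(m), transpose = TRUE))
      d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * tcrossprod(u, v)
      d2 <- pmax(d2, 0)
      dmat <- if (squared) d2 else sqrt(d2)
      cosw <- cos(2 * deg2rad(11.25 * seq_along(grid) - 90))
      for (i in seq_along(te)) {
        curve <- shift_tuning(-dmat[i, ], grid, test_ori[te[i]])
        scores[te[i]] <- sum(cosw * curve$similarity)
      }
    }
    out[[ti]] <- tibble::tibble(
      trial = seq_len(nrow(x)), time = timepoints[ti],
      target = target, score = scores, fold = fold
    )
  }
  dplyr::bind_rows(out)
}
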