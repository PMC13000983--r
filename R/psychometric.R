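#' Psychometric parameters for the clockwise/counterclockwise judgment
#'
#' Container for the parameters of the psychometric response model. In the
#' basic model the probability of a clockwise response given the signed
#' probe-minus-target offset theta is
#' `P(cw | theta) = (1 - lambda) * Phi(theta; mu, sigma) + lambda`,
#' where `Phi` is the normal CDF, `lambda` the lapse rate, `mu` the response
#' bias (fixed to 0) and `sigma` the inverse of memory precision in degrees.
#' The swap-extended model adds erroneous comparisons to the uncued item:
#' `P(cw) = (1 - p_swap - lambda) * Phi(theta_cued) +
#'  p_swap * Phi(theta_uncued) + lambda`.
#'
#' As printed, this form is asymmetric: it asymptotes at `lambda` for
#' theta -> -Inf and at 1 for theta -> +Inf, i.e. all guesses land on
#' "clockwise". The standard symmetric lapse form
#' `(1 - 2 lambda) * Phi + lambda` is available via `form = "symmetric"`
#' in [psychometric_predict()] and [fit_psychometric()]; the literal form is
#' the default.
#'
#' @param lambda lapse rate in `[0, 1]`.
#' @param sigma inverse precision in degrees, > 0.
#' @param p_swap swap rate in `[0, 1]`; `lambda + p_swap <= 1`.
#' @param mu response bias in degrees (fixed at 0 by the fitting routines).
#' @param rt_shift shift of the shifted-lognormal RT model, seconds.
#' @param rt_median median RT (seconds) at item distance 0 for this
#'   condition; RT plumbing for the generator, not part of the fitted model.
#' @param rt_sdlog lognormal sdlog of the RT model.
#' @param rt_distance_slope additional seconds of median RT per degree of
#'   item distance.
#' @return an object of class `wm_psych_params`.
#' @export
psych_params <- function(lambda = 0.07, sigma = 17.6, p_swap = 0,
                         mu = 0,
                         rt_shift = 0.2, rt_median = 0.61,
                         rt_sdlog = 0.35, rt_distance_slope = 0) {
  stopifnot(
    lambda >= 0, lambda <= 1,
    p_swap >= 0, p_swap <= 1,
    lambda + p_swap <= 1,
    sigma > 0,
    rt_median > rt_shift
  )
  structure(
    list(
      lambda = lambda, sigma = sigma, p_swap = p_swap, mu = mu,
      rt_shift = rt_shift, rt_median = rt_median, rt_sdlog = rt_sdlog,
      rt_distance_slope = rt_distance_slope
    ),
    class = "wm_psych_params"
  )
}

#' Default per-condition response parameters for the generator
#'
#' One [psych_params()] per condition. Defaults follow the behavioral
#' regime typical of this task: slightly higher lapse and swap rates and
#' about 80 ms slower responses on switch trials, comparable precision
#' across conditions, and a stronger RT cost of item distance on switches
#' (about 22 ms vs 6 ms per 10 degrees).
#'
#' @return named list with entries `block_start`, `switch`, `repeat1`,
#'   `repeat2plus`.
#' @export
default_response_params <- function() {
  rep_par <- psych_params(
    lambda = 0.07, sigma = 17.6, p_swap = 0.02,
    rt_median = 0.61, rt_distance_slope = 0.0006
  )
  list(
    block_start = rep_par,
    switch = psych_params(
      lambda = 0.092, sigma = 18.2, p_swap = 0.05,
      rt_median = 0.69, rt_distance_slope = 0.00225
    ),
    repeat1 = rep_par,
    repeat2plus = psych_params(
      lambda = 0.07, sigma = 17.6, p_swap = 0.02,
      rt_median = 0.60, rt_distance_slope = 0.0006
    )
  )
}

#' Clockwise-response probability under the psychometric model
#'
#' Evaluates the psychometric response function at signed probe offsets.
#' With `p_swap = 0` (or `theta_uncued = NULL`) this is the basic
#' lapse-plus-normal-CDF model; otherwise the swap-extended model. Offsets
#' must already be folded to `(-90, 90]` (see [fold_offset180()]).
#'
#' @param theta_cued signed probe-minus-cued offset(s), degrees in
#'   `(-90, 90]`.
#' @param theta_uncued signed probe-minus-uncued offset(s) or `NULL`.
#' @param params a [psych_params()].
#' @param form `"literal"` (default) uses the asymmetric
#'   `(1 - lambda) Phi + lambda` form; `"symmetric"` uses
#'   `(1 - 2 lambda) Phi + lambda`.
#' @return probability/ies of a clockwise response.
#' @examples
#' psychometric_predict(0, params = psych_params(lambda = 0))  # 0.5
#' @export
psychometric_predict <- function(theta_cued, theta_uncued = NULL,
                                 params = psych_params(),
                                 form = c("literal", "symmetric")) {
  form <- match.arg(form)
  check_fold <- function(x, nm) {
    if (any(x <= -90 - 1e-9 | x > 90 + 1e-9, na.rm = TRUE)) {
      stop(nm, " offsets must be folded to (-90, 90]")
    }
  }
  check_fold(theta_cued, "theta_cued")
  lam <- params$lambda
  sw <- params$p_swap
  phi_c <- pnorm(theta_cued, mean = params$mu, sd = params$sigma)
  # literal printed form: (1 - lam) Phi + lam ; symmetric: (1 - 2 lam) Phi + lam
  scale_lam <- if (form == "literal") 1 - lam else 1 - 2 * lam
  if (sw == 0) {
    p <- scale_lam * phi_c + lam
  } else {
    if (is.null(theta_uncued)) stop("p_swap > 0 requires theta_uncued offsets")
    check_fold(theta_uncued, "theta_uncued")
    phi_u <- pnorm(theta_uncued, mean = params$mu, sd = params$sigma)
    p <- (scale_lam - sw) * phi_c + sw * phi_u + lam
  }
  pmin(pmax(p, 0), 1)
}

#' Simulate behavioral responses on a trial table
#'
#' Draws clockwise/counterclockwise responses from the psychometric model
#' evaluated at each trial's probe offsets, with per-condition parameters,
#' and reaction times from a shifted lognormal whose median may depend on
#' condition and item distance. `correct` compares the response against the
#' true sign of the probe-minus-cued offset.
#'
#' @param trials a trial table from [generate_task()].
#' @param params_by_condition named list of [psych_params()], one entry per
#'   condition present in `trials` (see [default_response_params()]).
#' @param seed optional integer seed.
#' @param form psychometric form passed to [psychometric_predict()].
#' @return `trials` with `response`, `correct` and `rt_ms` filled in.
#' @export
simulate_responses <- function(trials,
                               params_by_condition = default_response_params(),
                               seed = NULL,
                               form = c("literal", "symmetric")) {
  form <- match.arg(form)
  if (!is.null(seed)) set.seed(seed)
  conds <- unique(trials$condition)
  missing_conds <- setdiff(conds, names(params_by_condition))
  if (length(missing_conds) > 0) {
    stop("no parameters supplied for condition(s): ",
         paste(missing_conds, collapse = ", "))
  }
  n <- nrow(trials)
  p_cw <- numeric(n)
  rt <- numeric(n)
  for (cond in conds) {
    idx <- which(trials$condition == cond)
    par <- params_by_condition[[cond]]
    stopifnot(inherits(par, "wm_psych_params"))
    p_cw[idx] <- psychometric_predict(
      trials$probe_offset_cued[idx],
      theta_uncued = trials$probe_offset_uncued[idx],
      params = par, form = form
    )
    med <- par$rt_median - par$rt_shift +
      par$rt_distance_slope * trials$item_distance[idx]
    rt[idx] <- par$rt_shift +
      rlnorm(length(idx), meanlog = log(med), sdlog = par$rt_sdlog)
  }
  cw <- rbinom(n, 1, p_cw) == 1
  trials$response <- ifelse(cw, "cw", "ccw")
  trials$correct <- cw == (trials$probe_offset_cued > 0)
  trials$rt_ms <- rt * 1000
  trials
}

#' Fit the psychometric model by maximum likelihood
#'
#' Maximizes the Bernoulli likelihood of the observed cw/ccw responses over
#' lapse rate, inverse precision and (optionally) swap rate, with the bias
#' mu fixed at 0. Optimization uses bounded L-BFGS-B from multiple random
#' starting points; bounds are lambda, p_swap in `[0, 0.5]` and sigma in
#' `[1, 90]` degrees.
#'
#' @param trials trial table with `response`, `probe_offset_cued` and (for
#'   the swap model) `probe_offset_uncued` columns.
#' @param include_swap fit the swap-extended model (default `FALSE`).
#' @param condition_filter optional character vector of conditions to keep
#'   before fitting (e.g. `"switch"` or `c("repeat1", "repeat2plus")`).
#' @param form psychometric form, as in [psychometric_predict()].
#' @param n_restarts number of random restarts (default 10).
#' @param min_trials minimum number of responded trials required (50).
#' @return an object of class `wm_psychfit` with elements `lambda`, `sigma`,
#'   `p_swap`, `mu`, `neg_log_lik`, `n_trials`, `convergence`,
#'   `boundary_flag`, `include_swap`, `form`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_psychometric <- function(trials, include_swap = FALSE,
                             condition_filter = NULL,
                             form = c("literal", "symmetric"),
                             n_restarts = 10,
                             min_trials = 50) {
  form <- match.arg(form)
  if (!is.null(condition_filter)) {
    trials <- dplyr::filter(trials, .data$condition %in% condition_filter)
  }
  trials <- dplyr::filter(trials, .data$response %in% c("cw", "ccw"))
  if (nrow(trials) < min_trials) {
    stop("need at least ", min_trials, " responded trials; got ", nrow(trials))
  }
  y <- as.numeric(trials$response == "cw")
  thc <- trials$probe_offset_cued
  thu <- trials$probe_offset_uncued

  nll <- function(par) {
    lam <- par[1]; sig <- par[2]
    sw <- if (include_swap) par[3] else 0
    if (lam + sw > 1) return(1e10)
    pp <- psych_params(lambda = lam, sigma = sig, p_swap = sw)
    p <- psychometric_predict(thc, theta_uncued = if (sw > 0) thu else NULL,
                              params = pp, form = form)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }

  lower <- c(0, 1); upper <- c(0.5, 90)
  if (include_swap) { lower <- c(lower, 0); upper <- c(upper, 0.5) }

  best <- NULL
  # deterministic low-discrepancy restarts (independent of the global RNG,
  # so fits are reproducible wherever they run in a pipeline)
  k <- seq_len(n_restarts)
  frac <- function(mult) (k * mult) %% 1
  starts <- cbind(
    lower[1] + frac(0.618034) * (upper[1] - lower[1]),
    lower[2] + frac(0.414214) * (upper[2] - lower[2])
  )
  if (include_swap) {
    starts <- cbind(starts, lower[3] + frac(0.259921) * (upper[3] - lower[3]))
  }
  starts[1, ] <- if (include_swap) c(0.05, 15, 0.02) else c(0.05, 15)
  for (k in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(starts[k, ], nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("psychometric fit failed to converge from any restart")
  }
  on_boundary <- any(abs(best$par - lower) < 1e-6) ||
    any(abs(best$par - upper) < 1e-6)
  structure(
    list(
      lambda = best$par[1],
      sigma = best$par[2],
      p_swap = if (include_swap) best$par[3] else 0,
      mu = 0,
      neg_log_lik = best$value,
      n_trials = length(y),
      convergence = best$convergence,
      boundary_flag = on_boundary,
      include_swap = include_swap,
      form = form
    ),
    class = "wm_psychfit"
  )
}

#' @export
print.wm_psychfit <- function(x, ...) {
  cat("Psychometric fit (", x$form, " form",
      if (x$include_swap) ", swap-extended" else "", ")\n", sep = "")
  cat(sprintf("  lambda = %.4f  sigma = %.2f deg  p_swap = %.4f\n",
              x$lambda, x$sigma, x$p_swap))
  cat(sprintf("  -logLik = %.2f on %d trials%s\n", x$neg_log_lik, x$n_trials,
              if (x$boundary_flag) "  [boundary]" else ""))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x a `wm_psychfit` object.
#' @param ... unused.
#' @export
tidy.wm_psychfit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "sigma", "p_swap", "mu"),
    estimate = c(x$lambda, x$sigma, x$p_swap, x$mu)
  )
}

#' @rdname fit_psychometric
#' @export
glance.wm_psychfit <- function(x, ...) {
  tibble::tibble(
    neg_log_lik = x$neg_log_lik,
    n_trials = x$n_trials,
    convergence = x$convergence,
    boundary_flag = x$boundary_flag,
    include_swap = x$include_swap,
    form = x$form
  )
}
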