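#' Z-scored within-participant trial regression
#'
#' Regresses a trial-level outcome on one or more trial-level predictors
#' separately within each participant (and, when requested, each
#' condition). The outcome and every predictor are z-scored within the
#' participant(-condition) cell before fitting; interaction columns are
#' formed as products of z-scored mains and then z-scored themselves.
#' Returned coefficients are therefore standardized and comparable across
#' participants; group inference is a one-sample t-test on each term (see
#' [group_ttest()]).
#'
#' @param data trial-level data frame.
#' @param y outcome column name.
#' @param predictors character vector of predictor column names.
#' @param interactions list of character pairs to include as interactions,
#'   e.g. `list(c("power", "item_distance"))`.
#' @param participant grouping column name (default `"participant"`).
#' @param by_condition optionally a condition column name: fits are run
#'   separately per condition.
#' @param min_trials minimum trials per cell (default 10).
#' @return tibble with columns `participant`, (`condition`,) `term`,
#'   `estimate`.
#' @export
ztrial_regress <- function(data, y, predictors,
                           interactions = NULL,
                           participant = "participant",
                           by_condition = NULL,
                           min_trials = 10) {
  stopifnot(y %in% names(data), all(predictors %in% names(data)))
  if (!participant %in% names(data)) data[[participant]] <- 1L
  groups <- c(participant, by_condition)
  zs <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("constant variable in regression cell")
    (v - mean(v)) / s
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      d <- d[complete.cases(d[, c(y, predictors)]), , drop = FALSE]
      if (nrow(d) < min_trials) {
        stop("fewer than ", min_trials, " trials in a regression cell")
      }
      yy <- zs(d[[y]])
      X <- purrr::map(predictors, ~ zs(d[[.x]]))
      names(X) <- predictors
      if (!is.null(interactions)) {
        for (pr in interactions) {
          X[[paste(pr, collapse = ":")]] <- zs(X[[pr[1]]] * X[[pr[2]]])
        }
      }
      Xm <- cbind(`(Intercept)` = 1, do.call(cbind, X))
      qrx <- qr(Xm)
      if (qrx$rank < ncol(Xm)) stop("singular design in regression cell")
      beta <- qr.coef(qrx, yy)
      tibble::tibble(term = names(X), estimate = unname(beta[-1]))
    }) |>
    dplyr::ungroup()
}

#' One-sample and paired group-level t-test with Cohen's d
#'
#' Standard one-sample t-test of per-participant values against zero, with
#' Cohen's d = mean / SD. For a paired contrast pass the per-participant
#' differences.
#'
#' @param values numeric vector, one value per participant.
#' @param mu null value (default 0).
#' @return one-row tibble: `estimate`, `t`, `df`, `p`, `d`, `n`.
#' @export
group_ttest <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 participants")
  if (sd(values) == 0) {
    stop("zero variance across participants; t statistic undefined")
  }
  tt <- t.test(values, mu = mu)
  tibble::tibble(
    estimate = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    d = (mean(values) - mu) / sd(values),
    n = n
  )
}

#' Cluster-based sign-flip permutation test
#'
#' Group-level test of per-participant effect maps against zero with
#' cluster-based correction for multiple comparisons. Cells whose
#' one-sample |t| exceeds the two-sided cluster-forming threshold are
#' grouped into same-sign connected clusters (4-neighborhood on the grid);
#' each cluster's mass (sum of t) is compared against the permutation null
#' distribution of the maximum |mass| under random per-participant sign
#' flips. Corrected p-values use the +1 correction, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param maps matrix of per-participant effects: participants x cells. For
#'   a time-frequency grid, cells must be column-major over a
#'   `grid_dim[1] x grid_dim[2]` grid.
#' @param grid_dim integer vector `c(n_rows, n_cols)`; defaults to a 1-D
#'   grid over all cells.
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param threshold_p two-sided cluster-forming p threshold (default 0.05).
#' @return an object of class `wm_cluster`: list with `t_obs` (matrix),
#'   `labels` (cluster index per cell), `clusters` (tibble: `cluster`,
#'   `mass`, `sign`, `n_cells`, `p`), `null_max_mass`, `n_perm`,
#'   `t_crit`. Supports [tidy()].
#' @export
cluster_permutation <- function(maps, grid_dim = NULL, n_perm = 10000,
                                threshold_p = 0.05) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 participants")
  ncell <- ncol(maps)
  if (is.null(grid_dim)) grid_dim <- c(1L, ncell)
  stopifnot(prod(grid_dim) == ncell)
  t_crit <- qt(1 - threshold_p / 2, df = n - 1)

  mean_obs <- colMeans(maps)
  sd_obs <- apply(maps, 2, sd)
  t_obs <- ifelse(sd_obs > 0, mean_obs / (sd_obs / sqrt(n)), 0)
  obs <- cluster_label_cpp(matrix(t_obs, grid_dim[1], grid_dim[2]), t_crit)

  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  null_max <- perm_max_mass_cpp(maps, signs, t_crit,
                                as.integer(grid_dim[1]),
                                as.integer(grid_dim[2]))

  mass <- obs$mass
  clusters <- tibble::tibble(
    cluster = seq_along(mass),
    mass = mass,
    sign = sign(mass),
    n_cells = as.integer(tabulate(obs$labels[obs$labels > 0],
                                  nbins = length(mass))),
    p = purrr::map_dbl(mass, ~ (1 + sum(null_max >= abs(.x))) / (1 + n_perm))
  )
  structure(
    list(
      t_obs = matrix(t_obs, grid_dim[1], grid_dim[2]),
      labels = obs$labels,
      clusters = clusters,
      null_max_mass = null_max,
      n_perm = n_perm,
      t_crit = t_crit,
      grid_dim = grid_dim
    ),
    class = "wm_cluster"
  )
}

#' @export
print.wm_cluster <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d x %d grid, %d permutations, |t| > %.2f\n",
              x$grid_dim[1], x$grid_dim[2], x$n_perm, x$t_crit))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @rdname cluster_permutation
#' @param x a `wm_cluster` object.
#' @param ... unused.
#' @export
tidy.wm_cluster <- function(x, ...) {
  x$clusters
}

#' Binned power-decoding analysis
#'
#' Within each participant (and condition), trials are ranked by band power
#' and split into `n_bins` equal-count bins (remainder trials spread across
#' the lowest bins); the mean decoding score per bin is regressed on bin
#' index. Group inference is a one-sample t-test on the per-participant
#' slopes per condition, plus a paired test between the first two
#' conditions when both are present.
#'
#' @param data data frame with one row per trial.
#' @param power,score column names of the binned variable and the outcome.
#' @param n_bins number of bins (default 8).
#' @param participant,condition grouping column names (`condition` optional).
#' @return list with `bins` (participant x condition x bin means), `slopes`
#'   (per participant/condition), `tests` (group t-tests; `NULL` if < 3
#'   participants).
#' @export
bin_analysis <- function(data, power, score, n_bins = 8,
                         participant = "participant",
                         condition = NULL) {
  stopifnot(power %in% names(data), score %in% names(data))
  if (!participant %in% names(data)) data[[participant]] <- 1L
  groups <- c(participant, condition)
  bins <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < n_bins) stop("fewer trials than bins in a cell")
      sizes <- rep(n %/% n_bins, n_bins)
      extra <- n %% n_bins
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      ord <- order(d[[power]])
      bin_of_trial <- integer(n)
      bin_of_trial[ord] <- rep(seq_len(n_bins), times = sizes)
      ms <- vapply(seq_len(n_bins),
                   function(b) mean(d[[score]][bin_of_trial == b]),
                   numeric(1))
      mp <- vapply(seq_len(n_bins),
                   function(b) mean(d[[power]][bin_of_trial == b]),
                   numeric(1))
      tibble::tibble(bin = seq_len(n_bins), mean_score = ms, mean_power = mp)
    }) |>
    dplyr::ungroup()

  slopes <- bins |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      slope = coef(lm(mean_score ~ bin))[["bin"]],
      .groups = "drop"
    )

  tests <- NULL
  if (dplyr::n_distinct(slopes[[participant]]) >= 3) {
    if (is.null(condition)) {
      tests <- group_ttest(slopes$slope)
    } else {
      conds <- sort(unique(slopes[[condition]]))
      tests <- purrr::map_dfr(conds, function(cn) {
        group_ttest(slopes$slope[slopes[[condition]] == cn]) |>
          dplyr::mutate(condition = cn, .before = 1)
      })
      if (length(conds) >= 2) {
        wide <- tidyr::pivot_wider(slopes, id_cols = dplyr::all_of(participant),
                                   names_from = dplyr::all_of(condition),
                                   values_from = "slope")
        tests <- dplyr::bind_rows(
          tests,
          group_ttest(wide[[conds[1]]] - wide[[conds[2]]]) |>
            dplyr::mutate(condition = paste(conds[1], "-", conds[2]),
                          .before = 1)
        )
      }
    }
  }
  list(bins = bins, slopes = slopes, tests = tests)
}

#' One-way repeated-measures ANOVA
#'
#' F-test of a within-participant factor with partial eta squared and
#' optional Greenhouse-Geisser correction of the degrees of freedom. Sums
#' of squares come from `stats::aov` with an `Error(participant)` stratum;
#' the Greenhouse-Geisser epsilon is computed from the double-centered
#' covariance of the participant x level table.
#'
#' @param data data frame in long format.
#' @param value,level,participant column names. The participant x level
#'   table must be complete.
#' @param gg apply Greenhouse-Geisser correction (default `TRUE`).
#' @return an object of class `wm_rm_anova`: list with `F`, `df1`, `df2`,
#'   `p`, `partial_eta2`, `epsilon`, `n_participants`, `n_levels`.
#'   Supports [tidy()].
#' @export
rm_anova_1way <- function(data, value, level, participant = "participant",
                          gg = TRUE) {
  stopifnot(all(c(value, level, participant) %in% names(data)))
  d <- data.frame(
    y = data[[value]],
    lv = factor(data[[level]]),
    id = factor(data[[participant]])
  )
  tab <- table(d$id, d$lv)
  if (any(tab != 1)) stop("participant x level table must be complete (one value per cell)")
  fit <- aov(y ~ lv + Error(id), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  ss_eff <- s["lv", "Sum Sq"]
  ss_err <- s["Residuals", "Sum Sq"]
  df1 <- s["lv", "Df"]
  df2 <- s["Residuals", "Df"]
  f_val <- (ss_eff / df1) / (ss_err / df2)

  eps <- 1
  if (gg) {
    wide <- tidyr::pivot_wider(
      tibble::tibble(id = d$id, lv = d$lv, y = d$y),
      names_from = "lv", values_from = "y"
    )
    m <- as.matrix(wide[, -1])
    v <- cov(m)
    k <- ncol(m)
    cent <- v - outer(rowMeans(v), rep(1, k)) -
      outer(rep(1, k), colMeans(v)) + mean(v)
    eps <- sum(diag(cent))^2 / ((k - 1) * sum(cent^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
  }
  structure(
    list(
      F = f_val,
      df1 = df1 * eps,
      df2 = df2 * eps,
      p = pf(f_val, df1 * eps, df2 * eps, lower.tail = FALSE),
      partial_eta2 = ss_eff / (ss_eff + ss_err),
      epsilon = eps,
      n_participants = nlevels(d$id),
      n_levels = nlevels(d$lv)
    ),
    class = "wm_rm_anova"
  )
}

#' @export
print.wm_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.4f%s\n",
    x$df1, x$df2, x$F, x$p, x$partial_eta2,
    if (x$epsilon < 1) sprintf(" (GG epsilon = %.3f)", x$epsilon) else ""
  ))
  invisible(x)
}

#' @rdname rm_anova_1way
#' @param x a `wm_rm_anova` object.
#' @param ... unused.
#' @export
tidy.wm_rm_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df1 = x$df1, df2 = x$df2, p.value = x$p,
    partial_eta2 = x$partial_eta2, epsilon = x$epsilon
  )
}

#' @importFrom stats cov
NULL
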