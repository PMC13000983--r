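#' Plot a psychometric fit over binned response data
#'
#' Draws the fitted clockwise-response curve and, when a trial table is
#' supplied, the observed proportion of clockwise responses in probe-offset
#' bins.
#'
#' @param object a `wm_psychfit`.
#' @param trials optional trial table the fit came from (same filtering).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_psychfit <- function(object, trials = NULL, ...) {
  pars <- psych_params(lambda = object$lambda, sigma = object$sigma,
                       p_swap = 0)
  grid <- tibble::tibble(
    offset = seq(-90, 90, by = 1),
    p_cw = psychometric_predict(seq(-90, 90, by = 1), params = pars,
                                form = object$form)
  )
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$offset, y = .data$p_cw)) +
    ggplot2::geom_line(linewidth = 0.8, color = "#2166ac") +
    ggplot2::labs(x = "probe - target offset (deg)",
                  y = "P(clockwise response)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    obs <- trials |>
      dplyr::filter(.data$response %in% c("cw", "ccw")) |>
      dplyr::mutate(bin = 11.25 * round(.data$probe_offset_cued / 11.25)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(p_cw = mean(.data$response == "cw"), .groups = "drop")
    gg <- gg + ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$bin, y = .data$p_cw),
      inherit.aes = FALSE, size = 2
    )
  }
  gg
}

#' Plot a tuning curve
#'
#' @param object a `wm_tuning`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_tuning <- function(object, ...) {
  df <- tibble::tibble(offset = object$offsets,
                       similarity = object$similarity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$similarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, alpha = 0.4) +
    ggplot2::labs(x = "orientation offset (deg)",
                  y = "pattern similarity (-distance)") +
    ggplot2::theme_minimal()
}

#' Plot a cluster-permutation result as a time-frequency map
#'
#' Cells belonging to significant clusters (corrected p below `alpha`) are
#' drawn saturated; other cells are dimmed.
#'
#' @param object a `wm_cluster`.
#' @param freqs,times optional axes for the grid (defaults to indices).
#' @param alpha significance level for highlighting (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wm_cluster <- function(object, freqs = NULL, times = NULL,
                                alpha = 0.05, ...) {
  gd <- object$grid_dim
  if (is.null(freqs)) freqs <- seq_len(gd[1])
  if (is.null(times)) times <- seq_len(gd[2])
  sig_ids <- object$clusters$cluster[object$clusters$p < alpha]
  df <- tibble::tibble(
    freq = rep(freqs, times = gd[2]),
    time = rep(times, each = gd[1]),
    t = as.vector(object$t_obs),
    significant = as.vector(matrix(object$labels, gd[1], gd[2])) %in% sig_ids
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t,
                                      alpha = .data$significant)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "t") +
    ggplot2::theme_minimal()
}

#' Plot the binned power-decoding relationship
#'
#' Group-mean decoding score per power bin with a linear fit, by condition.
#'
#' @param bins the `bins` tibble from [bin_analysis()].
#' @param condition optional condition column name.
#' @return a ggplot object.
#' @export
plot_bin_analysis <- function(bins, condition = "cond2") {
  has_cond <- condition %in% names(bins)
  groups <- c("bin", if (has_cond) condition)
  df <- bins |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      mean_score = mean(.data$mean_score),
      se = sd(.data$mean_score) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  aes <- if (has_cond) {
    ggplot2::aes(x = .data$bin, y = .data$mean_score,
                 color = .data[[condition]])
  } else {
    ggplot2::aes(x = .data$bin, y = .data$mean_score)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::labs(x = "band-power bin (low to high)",
                  y = "mean decoding score (a.u.)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
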