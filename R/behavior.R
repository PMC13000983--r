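#' Switch-cost summary of accuracy and reaction time
#'
#' Per participant and condition (`switch`, `repeat1`, `repeat2plus`;
#' block-start trials are excluded) computes mean accuracy and the median RT
#' of correct trials, then compares conditions with paired t-tests and
#' Cohen's d across participants. With a single participant only the
#' summary table is returned.
#'
#' @param trials trial table with filled `correct`/`rt_ms`; may contain a
#'   `participant` column (added by the pipeline) - if absent, a single
#'   participant is assumed.
#' @return list with `summary` (participant x condition accuracy / median
#'   RT) and `contrasts` (paired t-tests between conditions; `NULL` for a
#'   single participant).
#' @export
switch_cost_summary <- function(trials) {
  trials <- ensure_participant(trials)
  trials <- dplyr::filter(trials, .data$condition != "block_start")
  conds <- unique(trials$condition)
  if (length(conds) < 2) {
    stop("need at least two conditions to summarize switch costs")
  }
  summ <- trials |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      median_rt_ms = median(.data$rt_ms[.data$correct]),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  contrasts <- NULL
  if (dplyr::n_distinct(summ$participant) >= 3) {
    pairs <- utils::combn(sort(conds), 2, simplify = FALSE)
    contrasts <- purrr::map_dfr(pairs, function(pr) {
      wide <- summ |>
        dplyr::filter(.data$condition %in% pr) |>
        tidyr::pivot_wider(
          id_cols = "participant", names_from = "condition",
          values_from = c("accuracy", "median_rt_ms")
        )
      purrr::map_dfr(c("accuracy", "median_rt_ms"), function(m) {
        a <- wide[[paste0(m, "_", pr[1])]]
        b <- wide[[paste0(m, "_", pr[2])]]
        group_ttest(a - b) |>
          dplyr::mutate(measure = m, contrast = paste(pr[1], "-", pr[2]),
                        .before = 1)
      })
    })
  }
  list(summary = summ, contrasts = contrasts)
}

#' Item-distance effect on accuracy or reaction time
#'
#' Fits, per participant and condition, a least-squares line of the outcome
#' (trial accuracy in percent, or RT of correct trials in ms) on item
#' distance, and tests the slopes across participants against zero and
#' between switch and repeat conditions. Slopes are reported per 10 degrees
#' of item distance.
#'
#' @param trials trial table (optionally with `participant` column).
#' @param outcome `"accuracy"` or `"rt"`.
#' @param conditions named list mapping the two analysis conditions to the
#'   trial-table condition labels they pool; default keeps `switch` and
#'   pools `repeat1`/`repeat2plus` as `repeat`.
#' @return list with `slopes` (participant x condition slope per 10 deg) and
#'   `tests` (one-sample t on each condition's slopes and a paired t on
#'   their difference; `NULL` with fewer than 3 participants).
#' @export
distance_effect <- function(trials, outcome = c("accuracy", "rt"),
                            conditions = list(
                              switch = "switch",
                              repeat_ = c("repeat1", "repeat2plus")
                            )) {
  outcome <- match.arg(outcome)
  trials <- ensure_participant(trials)
  trials <- dplyr::filter(trials, .data$condition != "block_start")

  slopes <- purrr::imap_dfr(conditions, function(labels, cname) {
    sub <- dplyr::filter(trials, .data$condition %in% labels)
    if (outcome == "rt") sub <- dplyr::filter(sub, .data$correct)
    sub |>
      dplyr::group_by(.data$participant) |>
      dplyr::group_modify(function(d, key) {
        if (dplyr::n_distinct(d$item_distance) < 2) {
          stop("item distance is constant for a participant/condition cell")
        }
        y <- if (outcome == "accuracy") 100 * d$correct else d$rt_ms
        fit <- lm(y ~ item_distance, data = dplyr::mutate(d, y = y))
        tibble::tibble(slope_per_10deg = 10 * coef(fit)[["item_distance"]])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(condition = cname)
  })

  tests <- NULL
  if (dplyr::n_distinct(slopes$participant) >= 3) {
    wide <- tidyr::pivot_wider(slopes, id_cols = "participant",
                               names_from = "condition",
                               values_from = "slope_per_10deg")
    cn <- names(conditions)
    tests <- dplyr::bind_rows(
      group_ttest(wide[[cn[1]]]) |> dplyr::mutate(effect = cn[1], .before = 1),
      group_ttest(wide[[cn[2]]]) |> dplyr::mutate(effect = cn[2], .before = 1),
      group_ttest(wide[[cn[1]]] - wide[[cn[2]]]) |>
        dplyr::mutate(effect = paste(cn[1], "-", cn[2]), .before = 1)
    )
  }
  list(slopes = slopes, tests = tests)
}

#' Residualize a trial-level variable on a covariate, per participant
#'
#' Ordinary least-squares residuals of `y` on `x` (with intercept), computed
#' separately within each participant. Used to remove the item-distance
#' component from switch-cost contrasts.
#'
#' @param data data frame holding the variables.
#' @param y,x column names (strings) of outcome and covariate.
#' @param participant column name of the grouping variable; if absent from
#'   `data`, one group is assumed.
#' @return `data` with an added column `<y>_resid`.
#' @export
residualize <- function(data, y, x, participant = "participant") {
  if (!participant %in% names(data)) data[[participant]] <- 1L
  stopifnot(y %in% names(data), x %in% names(data))
  out_col <- paste0(y, "_resid")
  data |>
    dplyr::group_by(.data[[participant]]) |>
    dplyr::group_modify(function(d, key) {
      xv <- d[[x]]
      if (dplyr::n_distinct(xv) < 2) stop("singular design: constant covariate")
      d[[out_col]] <- unname(resid(lm(d[[y]] ~ xv)))
      d
    }) |>
    dplyr::ungroup()
}

ensure_participant <- function(trials) {
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  trials
}
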