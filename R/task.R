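#' Task configuration for the two-item priority-switch experiment
#'
#' Describes the block/trial structure of a two-item orientation
#' working-memory task with frequent retro-cue priority switches. Each block
#' starts with two memorized orientations drawn from a 16-point grid (11.25
#' degree spacing) under the constraint that they are neither identical nor
#' exactly orthogonal, so the circular distance between the items ("item
#' distance") takes one of the seven values 11.25, 22.5, ..., 78.75 degrees.
#' Within a block, the cue either repeats the previously cued item or
#' switches to the other one; after every switch the number of subsequent
#' cue repeats is drawn from a distribution supported on 1..7.
#'
#' @param n_blocks number of task blocks (default 128).
#' @param trials_per_block trials per block (default 16).
#' @param orientation_grid memory-item orientations, degrees in `[0, 180)`.
#' @param probe_grid probe orientations, degrees in `[0, 180)`; the default
#'   grid is offset from `orientation_grid` by 5.625 degrees so the probe
#'   never coincides with or is orthogonal to a memory item.
#' @param repeat_run_distribution probability vector over run lengths 1..7:
#'   the number of cue repeats following each switch (and following the
#'   first trial of a block). The default is a truncated geometric
#'   distribution (success probability 0.38) renormalized on 1..7, giving a
#'   mean run length of about 2.4 and a switch : repeat1 : repeat2+ trial
#'   mix close to the roughly 1 : 1.2 : 1.4 ratio typical of this design.
#' @param cue_soa seconds from cue onset to probe onset (default 0.8).
#' @param iti_range intertrial interval bounds in seconds; ITIs are drawn
#'   from a truncated exponential with mean `iti_mean`.
#' @param iti_mean mean of the truncated-exponential ITI in seconds.
#' @param exclusion apply the identical/orthogonal exclusion when sampling
#'   the two memory items (default `TRUE`; disable only for null checks).
#' @param balance_orientations if `TRUE`, block orientations are sampled
#'   with a low-count preference so that all 16 orientations occur even in
#'   short sessions (needed by the decoder's 16 class means); the default
#'   `FALSE` draws pairs uniformly, which is safe at the full 128-block
#'   session length.
#' @return an object of class `wm_task_config` (a named list).
#' @seealso [generate_task()]
#' @export
task_config <- function(n_blocks = 128,
                        trials_per_block = 16,
                        orientation_grid = 2.8125 + 11.25 * (0:15),
                        probe_grid = 8.4375 + 11.25 * (0:15),
                        repeat_run_distribution = trunc_geom_runs(0.38),
                        cue_soa = 0.8,
                        iti_range = c(0.4, 0.9),
                        iti_mean = 0.55,
                        exclusion = TRUE,
                        balance_orientations = FALSE) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  grid_ok <- function(g) {
    length(unique(g)) == length(g) && all(g >= 0) && all(g < 180)
  }
  if (!grid_ok(orientation_grid)) {
    stop("orientation_grid must hold distinct values in [0, 180)")
  }
  if (!grid_ok(probe_grid)) {
    stop("probe_grid must hold distinct values in [0, 180)")
  }
  if (length(repeat_run_distribution) != 7 ||
      any(repeat_run_distribution < 0) ||
      abs(sum(repeat_run_distribution) - 1) > 1e-8) {
    stop("repeat_run_distribution must be a probability vector on runs 1..7")
  }
  if (exclusion && length(admissible_pairs(orientation_grid)) == 0) {
    stop("orientation_grid admits no item pair under the exclusion constraint")
  }
  structure(
    list(
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      orientation_grid = orientation_grid,
      probe_grid = probe_grid,
      repeat_run_distribution = repeat_run_distribution,
      cue_soa = cue_soa,
      iti_range = iti_range,
      iti_mean = iti_mean,
      exclusion = exclusion,
      balance_orientations = balance_orientations
    ),
    class = "wm_task_config"
  )
}

#' Truncated geometric distribution over cue-repeat run lengths
#'
#' Geometric probabilities `q * (1 - q)^(r - 1)` renormalized on the support
#' 1..7, used as the default distribution of the number of cue repeats after
#' each priority switch.
#'
#' @param q geometric success probability in (0, 1).
#' @return numeric vector of length 7 summing to 1.
#' @export
trunc_geom_runs <- function(q = 0.38) {
  stopifnot(q > 0, q < 1)
  p <- q * (1 - q)^(0:6)
  p / sum(p)
}

# all index pairs (i < j) on the grid passing the exclusion constraint
admissible_pairs <- function(grid) {
  n <- length(grid)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- circ_dist180(grid[i], grid[j])
      if (d > 1e-9 && abs(d - 90) > 1e-9) out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

#' Generate the trial table of a priority-switch session
#'
#' Builds one participant-session of the two-item task: samples the two
#' memory orientations of every block (excluding identical and orthogonal
#' pairs unless disabled), constructs the cue sequence from run lengths
#' drawn from `repeat_run_distribution`, samples probe orientations
#' uniformly from the probe grid, and labels every trial as `block_start`,
#' `switch`, `repeat1` (first repeat after a switch or block start) or
#' `repeat2plus`.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; if supplied the table is reproducible.
#' @return a tibble with one row per trial: `block_id`, `trial_in_block`,
#'   `cued_item` ("A"/"B"), `condition`, `theta_cued`, `theta_uncued`,
#'   `item_distance`, `probe`, `probe_offset_cued` and
#'   `probe_offset_uncued` (signed probe-minus-item differences folded to
#'   `(-90, 90]`), `iti_s`, and empty `response`, `correct`, `rt_ms`
#'   columns to be filled by [simulate_responses()].
#' @examples
#' tt <- generate_task(task_config(n_blocks = 4), seed = 1)
#' dplyr::count(tt, condition)
#' @export
generate_task <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "wm_task_config"))
  if (!is.null(seed)) set.seed(seed)
  grid <- config$orientation_grid
  run_p <- config$repeat_run_distribution

  ori_counts <- integer(length(grid))
  blocks <- purrr::map(seq_len(config$n_blocks), function(b) {
    # memory items for the block
    if (config$balance_orientations) {
      admissible <- function(i, j) {
        d <- circ_dist180(grid[i], grid[j])
        !config$exclusion || (d > 1e-9 && abs(d - 90) > 1e-9)
      }
      low <- which(ori_counts == min(ori_counts))
      i <- if (length(low) == 1) low else sample(low, 1)
      partners <- which(purrr::map_lgl(seq_along(grid),
                                       ~ .x != i && admissible(i, .x)))
      pc <- ori_counts[partners]
      lowp <- partners[pc == min(pc)]
      j <- if (length(lowp) == 1) lowp else sample(lowp, 1)
      ij <- c(i, j)
      ori_counts[ij] <<- ori_counts[ij] + 1L
    } else {
      repeat {
        ij <- sample(length(grid), 2)
        d <- circ_dist180(grid[ij[1]], grid[ij[2]])
        if (!config$exclusion || (d > 1e-9 && abs(d - 90) > 1e-9)) break
      }
    }
    ori <- c(A = grid[ij[1]], B = grid[ij[2]])

    # cue sequence: segments of (entry trial + r repeats), r ~ run_p on 1..7
    n_tr <- config$trials_per_block
    cue <- character(0)
    current <- sample(c("A", "B"), 1)
    while (length(cue) < n_tr) {
      r <- sample.int(7, 1, prob = run_p)
      cue <- c(cue, rep(current, 1 + r))
      current <- setdiff(c("A", "B"), current)
    }
    cue <- cue[seq_len(n_tr)]

    condition <- character(n_tr)
    condition[1] <- "block_start"
    for (t in 2:n_tr) {
      if (cue[t] != cue[t - 1]) {
        condition[t] <- "switch"
      } else if (condition[t - 1] %in% c("switch", "block_start")) {
        condition[t] <- "repeat1"
      } else {
        condition[t] <- "repeat2plus"
      }
    }

    probe <- sample(config$probe_grid, n_tr, replace = TRUE)
    # truncated exponential ITI via inverse-cdf on the truncated range
    rate <- 1 / (config$iti_mean - config$iti_range[1])
    span <- diff(config$iti_range)
    u <- runif(n_tr)
    iti <- config$iti_range[1] -
      log(1 - u * (1 - exp(-rate * span))) / rate

    th_cued <- unname(ori[cue])
    th_uncued <- unname(ori[ifelse(cue == "A", "B", "A")])
    tibble::tibble(
      block_id = b,
      trial_in_block = seq_len(n_tr),
      cued_item = cue,
      condition = condition,
      theta_cued = th_cued,
      theta_uncued = th_uncued,
      item_distance = circ_dist180(th_cued, th_uncued),
      probe = probe,
      probe_offset_cued = fold_offset180(probe - th_cued),
      probe_offset_uncued = fold_offset180(probe - th_uncued),
      iti_s = iti
    )
  })

  out <- dplyr::bind_rows(blocks)
  out$response <- NA_character_
  out$correct <- NA
  out$rt_ms <- NA_real_
  out
}

#' Admissible item distances on an orientation grid
#'
#' Enumerates all unordered pairs on the grid and returns the distinct
#' circular distances that survive the identical/orthogonal exclusion.
#'
#' @param grid orientation grid in degrees.
#' @return sorted numeric vector of admissible distances.
#' @export
admissible_distances <- function(grid = 2.8125 + 11.25 * (0:15)) {
  d <- purrr::map_dbl(admissible_pairs(grid), ~ circ_dist180(grid[.x[1]], grid[.x[2]]))
  sort(unique(round(d, 6)))
}
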