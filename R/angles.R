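#' Circular angle utilities for 180-degree-periodic orientation space
#'
#' Oriented bars repeat every 180 degrees, so all angular arithmetic in the
#' package lives on the half-circle. `circ_dist180()` returns the unsigned
#' circular distance between two orientations (always in `[0, 90]`);
#' `fold_offset180()` folds a signed angular difference into `(-90, 90]`,
#' the canonical range for probe-minus-target offsets.
#'
#' @param a,b orientations in degrees.
#' @param x signed angular difference in degrees.
#' @return degrees; `circ_dist180()` in `[0, 90]`, `fold_offset180()` in
#'   `(-90, 90]`.
#' @examples
#' circ_dist180(170, 10) # 20, wrapping through 180
#' fold_offset180(135)   # -45
#' @export
circ_dist180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' @rdname circ_dist180
#' @export
fold_offset180 <- function(x) {
  f <- x %% 180
  ifelse(f > 90, f - 180, f)
}

deg2rad <- function(x) x * pi / 180
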