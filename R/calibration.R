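#' Stretch-induced birefringence calibration
#'
#' A calibration is an anchor table mapping (curing ratio, length ratio) to
#' induced birefringence, evaluated by piecewise-linear interpolation within
#' the anchored range for each curing ratio. Every curing ratio must anchor
#' the relaxed state at `(length_ratio = 1, delta_n = 0)` and be nondecreasing
#' in length ratio (induced birefringence grows with stretch). No
#' extrapolation is performed: clamps slip at a curing-ratio-dependent maximum
#' elongation, so values beyond the anchored range are not defined.
#'
#' @param anchors A data frame with columns `curing_ratio`, `length_ratio`,
#'   `delta_n` and optionally `source` (free text; `"synthetic"` marks values
#'   that are plausible placeholders rather than measured data).
#' @return A `psoct_calibration` tibble.
#' @seealso [default_stretch_calibration()], [evaluate_stretch_calibration()]
#' @export
stretch_calibration <- function(anchors) {
  anchors <- as_tibble(anchors)
  req <- c("curing_ratio", "length_ratio", "delta_n")
  if (!all(req %in% names(anchors))) {
    abort("`anchors` needs columns curing_ratio, length_ratio, delta_n.")
  }
  if (!"source" %in% names(anchors)) anchors$source <- "user"
  if (any(anchors$length_ratio < 1)) {
    abort("Anchor length ratios must be >= 1.")
  }
  anchors <- dplyr::arrange(anchors, .data$curing_ratio, .data$length_ratio)
  for (cr in unique(anchors$curing_ratio)) {
    a <- anchors[anchors$curing_ratio == cr, ]
    if (nrow(a) < 2L) {
      abort(sprintf("Curing ratio %g:1 needs >= 2 anchor points.", cr))
    }
    if (anyDuplicated(a$length_ratio)) {
      abort(sprintf("Curing ratio %g:1 has duplicated length-ratio anchors.", cr))
    }
    if (a$length_ratio[1] != 1 || a$delta_n[1] != 0) {
      abort(sprintf(
        "Curing ratio %g:1 must anchor the relaxed state (1, 0).", cr
      ))
    }
    if (is.unsorted(a$delta_n)) {
      abort(sprintf(
        "Curing ratio %g:1 anchors must be nondecreasing in delta_n.", cr
      ))
    }
  }
  class(anchors) <- c("psoct_calibration", class(anchors))
  anchors
}

#' Default stretch calibration anchors
#'
#' Shipped anchor table for Sylgard-184 PDMS at curing ratios 10:1, 15:1,
#' 20:1 and 25:1. Two anchor families are measured facts: the relaxed state
#' `(1, 0)` for every ratio, and the 20:1 maximum of delta-n = 2.1e-4 at a
#' length ratio of 5. All other anchors are marked `source = "synthetic"`:
#' they follow the qualitative trends (lower curing ratios respond faster but
#' slip earlier; 20:1 and 25:1 stretch past five times their length) and are
#' meant to be replaced by a user-measured table for quantitative work.
#'
#' @return A `psoct_calibration` tibble.
#' @export
#' @examples
#' evaluate_stretch_calibration(default_stretch_calibration(), 20, 5)
default_stretch_calibration <- function() {
  anchors <- tibble(
    curing_ratio = c(
      10, 10, 10,
      15, 15, 15, 15, 15,
      20, 20, 20, 20, 20,
      25, 25, 25, 25, 25
    ),
    length_ratio = c(
      1, 1.5, 2,
      1, 1.5, 2, 2.5, 3,
      1, 2, 3, 4, 5,
      1, 2, 3, 4, 5
    ),
    delta_n = c(
      0, 0.60e-4, 1.20e-4,
      0, 0.40e-4, 0.80e-4, 1.20e-4, 1.50e-4,
      0, 0.50e-4, 1.00e-4, 1.55e-4, 2.10e-4,
      0, 0.40e-4, 0.80e-4, 1.20e-4, 1.60e-4
    ),
    source = "synthetic"
  )
  anchors$source[anchors$length_ratio == 1] <- "relaxed"
  anchors$source[anchors$curing_ratio == 20 & anchors$length_ratio == 5] <-
    "measured-max"
  stretch_calibration(anchors)
}

#' Evaluate a stretch calibration
#'
#' Piecewise-linear interpolation of induced birefringence between the anchor
#' points for one curing ratio. Exact at anchors; refuses to extrapolate
#' beyond the anchored length-ratio range.
#'
#' @param calibration A [stretch_calibration()].
#' @param curing_ratio Curing ratio to look up (must be anchored).
#' @param length_ratio Stretch to evaluate at; must lie within the anchored
#'   range for this curing ratio.
#' @return Induced birefringence delta-n (dimensionless scalar).
#' @export
evaluate_stretch_calibration <- function(calibration, curing_ratio, length_ratio) {
  if (!inherits(calibration, "psoct_calibration")) {
    calibration <- stretch_calibration(calibration)
  }
  a <- calibration[calibration$curing_ratio == curing_ratio, ]
  if (nrow(a) < 2L) {
    abort(sprintf(
      "No calibration anchors for curing ratio %g:1.", curing_ratio
    ))
  }
  if (length_ratio < min(a$length_ratio) || length_ratio > max(a$length_ratio)) {
    abort(sprintf(
      paste0(
        "length_ratio %g outside the anchored range [%g, %g] for curing ",
        "ratio %g:1; no extrapolation (clamps slip beyond the measured range)."
      ),
      length_ratio, min(a$length_ratio), max(a$length_ratio), curing_ratio
    ))
  }
  stats::approx(a$length_ratio, a$delta_n, xout = length_ratio,
                method = "linear", ties = "ordered")$y
}
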