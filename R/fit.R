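#' Layer analysis windows
#'
#' Named depth windows below the detected surface, in physical micrometres,
#' over which per-layer birefringence is fitted. Windows must be non-empty,
#' non-overlapping and ordered by depth.
#'
#' @param layer Character vector of window names.
#' @param zmin_um,zmax_um Window bounds, um below the surface; each window is
#'   the half-open interval `[zmin, zmax)`.
#' @return A `psoct_windows` tibble.
#' @export
#' @examples
#' layer_windows(c("urothelium", "LP"), c(0, 50), c(50, 250))
layer_windows <- function(layer, zmin_um, zmax_um) {
  stopifnot(length(layer) == length(zmin_um), length(layer) == length(zmax_um))
  w <- tibble(layer = as.character(layer),
              zmin_um = as.numeric(zmin_um),
              zmax_um = as.numeric(zmax_um))
  if (any(w$zmax_um <= w$zmin_um)) abort("Windows must be non-empty.")
  if (is.unsorted(w$zmin_um, strictly = TRUE)) {
    abort("Windows must be ordered by depth.")
  }
  if (any(w$zmin_um[-1] < w$zmax_um[-nrow(w)])) {
    abort("Windows must not overlap.")
  }
  class(w) <- c("psoct_windows", class(w))
  w
}

#' Laterally averaged retardation profile
#'
#' Averages the flattened retardation over a lateral region at each depth,
#' using valid columns and in-sample pixels only, and converts the depth axis
#' to physical micrometres below the surface (optical path divided by the
#' refractive index). The lateral region defaults to 2 mm centred on the
#' B-scan.
#'
#' @param flat A [flatten()] result.
#' @param columns Optional integer vector of column indices to average. When
#'   `NULL`, a region of `width_um` centred on `center_column` is used.
#' @param center_column Centre of the averaging region (default: image
#'   centre).
#' @param width_um Width of the averaging region in micrometres (default
#'   2000, i.e. 2 mm; the number of columns is `round(width_um /
#'   lateral_pixel_spacing_um)`).
#' @param refractive_index Index used for the optical-to-physical depth
#'   conversion (default 1.4).
#' @return A `psoct_profile` tibble: `depth_um` (strictly increasing),
#'   `retardation_deg` (mean over valid columns), `n_valid` (columns
#'   contributing at that depth). Attributes record `n_columns` (valid
#'   columns in the region) and `column_range_um` (lateral extent).
#' @export
lateral_average <- function(flat, columns = NULL, center_column = NULL,
                            width_um = 2000, refractive_index = NULL) {
  stopifnot(inherits(flat, "psoct_flat"))
  W <- ncol(flat$retardation)
  if (is.null(columns)) {
    ncols <- max(1L, as.integer(round(
      width_um / flat$config$lateral_pixel_spacing_um
    )))
    if (is.null(center_column)) center_column <- (W + 1L) %/% 2L
    half_lo <- (ncols - 1L) %/% 2L
    columns <- (center_column - half_lo):(center_column - half_lo + ncols - 1L)
  }
  columns <- columns[columns >= 1L & columns <= W]
  columns <- columns[flat$valid[columns]]
  if (!length(columns)) abort("No valid columns in the averaging region.")
  if (is.null(refractive_index)) refractive_index <- 1.4

  sub <- flat$retardation[, columns, drop = FALSE]
  n_valid <- rowSums(!is.na(sub))
  keep <- which(n_valid > 0)
  mean_ret <- rowMeans(sub, na.rm = TRUE)[keep]
  depth_um <- pixels_to_physical_thickness(keep - 1L, flat$config,
                                           refractive_index)
  out <- tibble(
    depth_um = depth_um,
    retardation_deg = mean_ret,
    n_valid = n_valid[keep]
  )
  structure(out,
    class = c("psoct_profile", class(out)),
    n_columns = length(columns),
    column_range_um = length(columns) * flat$config$lateral_pixel_spacing_um,
    refractive_index = refractive_index
  )
}

#' Estimate the retardation noise floor of a B-scan
#'
#' Above the detected surface the retardation channel contains folded phase
#' noise only; for Gaussian phase noise of standard deviation `sigma` (small
#' against the 90-degree fold) the folded values have mean
#' `sigma * sqrt(2/pi)`. Inverting that relation on the above-surface pixels
#' yields a data-driven estimate of `sigma`, used to exclude
#' below-noise-floor depths from retardation-slope fits (folding at zero
#' biases the mean retardation upward wherever the true phase is comparable
#' to the noise).
#'
#' @param pair A `psoct_bscan`.
#' @param seg Its [detect_surfaces()] segmentation.
#' @param margin_px Rows immediately above the surface to skip.
#' @return Estimated phase-noise sd in degrees (0 when no above-surface
#'   pixels exist).
#' @export
estimate_retardation_noise <- function(pair, seg, margin_px = 2L) {
  stopifnot(inherits(pair, "psoct_bscan"), inherits(seg, "psoct_segmentation"))
  vals <- numeric(0)
  for (j in seq_len(nrow(seg))) {
    if (!seg$valid[j]) next
    top <- seg$top[j] - margin_px
    if (top >= 2L) vals <- c(vals, pair$retardation[seq_len(top - 1L), j])
  }
  if (!length(vals)) return(0)
  mean(vals) / sqrt(2 / pi)
}

#' Fit birefringence from a retardation-depth profile
#'
#' Ordinary least-squares line through mean retardation versus physical depth
#' inside a fit window; the cumulative retardation of a uniformly
#' birefringent region grows as `delta = 2 pi * dn * z / lambda`, so the
#' fitted slope converts to birefringence as `dn = slope_rad_per_m * lambda /
#' (2 pi)`. Negative slopes yield negative delta-n (reported, not clipped:
#' thin or non-birefringent layers legitimately fit slightly negative).
#'
#' Two guards restrict the fitted points to the physically linear region:
#' points after the profile's maximum are dropped when that maximum comes
#' within 5 degrees of the 90-degree fold (the fold reverses the slope), and
#' points whose mean retardation lies below `min_retardation_deg` (typically
#' twice the estimated noise floor) are dropped because folding at zero
#' biases them upward. Either guard is skipped if it would leave fewer than
#' three points.
#'
#' @param profile A [lateral_average()] result (or any tibble with
#'   `depth_um` and `retardation_deg`).
#' @param config The [imaging_config()] (supplies the wavelength).
#' @param fit_window Numeric `c(zmin, zmax)` in um below the surface; the fit
#'   uses depths in `[zmin, zmax)`. `NULL` uses the full profile from 10 um
#'   below the surface (skipping specular surface pixels).
#' @param min_retardation_deg Noise-floor exclusion level in degrees
#'   (default 0: no exclusion).
#' @return A `biref_estimate`: list with `delta_n`, `slope_deg_per_um`,
#'   `intercept_deg`, `r_squared`, `n_points`, `fit_window_um`, `n_columns`,
#'   `note`.
#' @export
fit_birefringence <- function(profile, config, fit_window = NULL,
                              min_retardation_deg = 0) {
  stopifnot(inherits(config, "psoct_config"))
  if (is.null(fit_window)) fit_window <- c(10, Inf)
  if (length(fit_window) != 2L || fit_window[2] <= fit_window[1]) {
    abort("`fit_window` must be c(zmin, zmax) with zmax > zmin.")
  }
  d <- profile$depth_um
  r <- profile$retardation_deg
  sel <- which(d >= fit_window[1] & d < fit_window[2] & !is.na(r))
  if (length(sel) < 3L) {
    abort("Fewer than 3 profile points inside the fit window.")
  }
  note <- character(0)

  # stay on the pre-fold branch: drop the peak and everything past it when
  # the profile approaches the 90-degree fold (the peak pixel itself may
  # already sit past the crossing, folded back just under 90)
  rmax_i <- which.max(r[sel])
  if (r[sel][rmax_i] >= 85 && rmax_i >= 4L) {
    sel <- sel[seq_len(rmax_i - 1L)]
    note <- c(note, "truncated at retardation fold")
  }

  if (min_retardation_deg > 0) {
    above <- r[sel] >= min_retardation_deg
    if (sum(above) >= 3L) {
      if (!all(above)) note <- c(note, "noise-floor points excluded")
      sel <- sel[above]
    } else {
      note <- c(note, "entire window below noise floor")
    }
  }

  dd <- d[sel]; rr <- r[sel]
  if (max(dd) == min(dd)) abort("Zero depth spread in the fit window.")
  fit <- lm(rr ~ dd)
  slope <- unname(coef(fit)[2])                  # degrees per um
  lambda_um <- config$wavelength_nm / 1000
  delta_n <- slope * lambda_um / 360             # = slope_rad_per_m * lambda_m / (2 pi)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((rr - mean(rr))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(
      delta_n = delta_n,
      slope_deg_per_um = slope,
      intercept_deg = unname(coef(fit)[1]),
      r_squared = max(0, min(1, r2)),
      n_points = length(sel),
      fit_window_um = c(min(dd), max(dd)),
      n_columns = attr(profile, "n_columns") %||% NA_integer_,
      note = if (length(note)) paste(note, collapse = "; ") else NA_character_
    ),
    class = "biref_estimate"
  )
}

#' @export
print.biref_estimate <- function(x, ...) {
  cat(sprintf(
    "<biref_estimate> delta-n = %.4g (slope %.4g deg/um, R^2 %.3f, %d pts, window %.0f-%.0f um)\n",
    x$delta_n, x$slope_deg_per_um, x$r_squared, x$n_points,
    x$fit_window_um[1], x$fit_window_um[2]
  ))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
tidy.biref_estimate <- function(x, ...) {
  tibble(
    delta_n = x$delta_n,
    slope_deg_per_um = x$slope_deg_per_um,
    intercept_deg = x$intercept_deg,
    r_squared = x$r_squared,
    n_points = x$n_points,
    window_min_um = x$fit_window_um[1],
    window_max_um = x$fit_window_um[2],
    n_columns = x$n_columns,
    note = x$note
  )
}

#' @export
glance.biref_estimate <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_points = x$n_points,
         n_columns = x$n_columns)
}

#' Per-layer birefringence estimates
#'
#' Fits one birefringence estimate per layer window over a laterally averaged
#' retardation profile. Windows whose start lies at or beyond the deepest
#' averaged point (e.g. beyond the maximum detection depth) are reported as
#' absent (`delta_n = NA`) rather than fitted.
#'
#' @param flat A [flatten()] result.
#' @param windows A [layer_windows()] table.
#' @param config The [imaging_config()].
#' @param min_retardation_deg Noise-floor exclusion passed to
#'   [fit_birefringence()].
#' @param ... Lateral-region arguments passed to [lateral_average()].
#' @return A tibble with one row per window: `layer`, `delta_n`,
#'   `slope_deg_per_um`, `r_squared`, `n_points`, window bounds, `note`.
#' @export
layer_birefringence <- function(flat, windows, config,
                                min_retardation_deg = 0, ...) {
  stopifnot(inherits(windows, "psoct_windows"))
  profile <- lateral_average(flat, ...)
  max_depth <- max(profile$depth_um)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    if (w$zmin_um >= max_depth) {
      return(tibble(
        layer = w$layer, delta_n = NA_real_, slope_deg_per_um = NA_real_,
        r_squared = NA_real_, n_points = 0L,
        window_min_um = w$zmin_um, window_max_um = w$zmax_um,
        n_columns = attr(profile, "n_columns"),
        note = "beyond max detection depth"
      ))
    }
    est <- fit_birefringence(profile, config,
                             fit_window = c(w$zmin_um, w$zmax_um),
                             min_retardation_deg = min_retardation_deg)
    tibble(
      layer = w$layer, delta_n = est$delta_n,
      slope_deg_per_um = est$slope_deg_per_um,
      r_squared = est$r_squared, n_points = est$n_points,
      window_min_um = w$zmin_um, window_max_um = w$zmax_um,
      n_columns = est$n_columns, note = est$note
    )
  })
}

#' Signed percent change between two birefringence values
#'
#' @param delta_n_test Test value.
#' @param delta_n_reference Reference value (non-zero).
#' @return `100 * (test - reference) / reference`, signed.
#' @export
#' @examples
#' percent_change(1.40e-4, 1.01e-4)  # 38.6 (to 3 s.f.)
percent_change <- function(delta_n_test, delta_n_reference) {
  if (any(delta_n_reference == 0)) abort("Reference delta-n must be non-zero.")
  100 * (delta_n_test - delta_n_reference) / delta_n_reference
}

`%||%` <- function(a, b) if (is.null(a)) b else a
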