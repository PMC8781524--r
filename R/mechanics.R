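#' Engineering stress of a clamped stretch experiment
#'
#' `sigma = P / A` with `A = L1 * L2_0`, the cross-sectional area of the
#' sample in its relaxed state (clamp-contact width times relaxed thickness).
#' The width is held fixed by the clamps throughout the experiment.
#'
#' @param force_P_N Stretching force, newtons, `>= 0`.
#' @param width_L1_mm Clamp-contact width, mm, `> 0`.
#' @param initial_thickness_L2_0_mm Relaxed sample thickness, mm, `> 0`.
#' @return Stress in pascals.
#' @export
#' @examples
#' compute_stress(1, 10, 1.5)  # 1 / 1.5e-5 m^2 ~ 66667 Pa
compute_stress <- function(force_P_N, width_L1_mm, initial_thickness_L2_0_mm) {
  if (any(force_P_N < 0)) abort("`force_P_N` must be >= 0.")
  if (any(width_L1_mm <= 0) || any(initial_thickness_L2_0_mm <= 0)) {
    abort("Clamp geometry must be > 0.")
  }
  area_m2 <- width_L1_mm * initial_thickness_L2_0_mm * 1e-6  # mm^2 -> m^2
  force_P_N / area_m2
}

#' Run a simulated stretch-characterization campaign
#'
#' Reproduces the slab-phantom characterization experiment in silico: for
#' each requested length ratio and replicate, the relaxed sample is stretched
#' ([apply_stretch()]), imaged ([simulate_bscan()], fresh seed per
#' replicate), segmented, flattened, laterally averaged and fitted
#' ([fit_birefringence()]). The stretching force is synthesized from a linear
#' toy stress-stretch law `sigma = stress_slope_Pa * (ratio - 1)` (the law is
#' a plotting aid, not a constitutive model; configure `stress_slope_Pa` to
#' taste).
#'
#' @param model Relaxed [sample_model()] (single photoelastic slab,
#'   typically).
#' @param calibration A [stretch_calibration()].
#' @param ratios Numeric vector of length ratios, all `>= 1` and within the
#'   calibration's anchored range.
#' @param repeats Replicates per ratio, `>= 1`.
#' @param config An [imaging_config()].
#' @param noise A [noise_model()]; each replicate r at ratio index k is
#'   simulated with seed `noise$seed + 1000 * k + r`.
#' @param stress_slope_Pa Slope of the synthetic stress-stretch law, Pa per
#'   unit strain.
#' @param fit_window Fit window passed to [fit_birefringence()] (default
#'   10 um below the surface to the detected bottom).
#' @param width_um Lateral averaging width, um.
#' @return A `psoct_campaign` tibble with one row per (ratio, replicate):
#'   `curing_ratio`, `length_ratio`, `replicate`, `delta_n` (measured),
#'   `true_delta_n` (calibration value), `force_P_N`, `stress_Pa`,
#'   `thickness_um` (measured), `r_squared`, `seed`.
#' @export
run_stretch_campaign <- function(model, calibration = default_stretch_calibration(),
                                 ratios = c(1, 1 + 2.5 / 6, 1 + 5 / 6),
                                 repeats = 5L,
                                 config = imaging_config(),
                                 noise = noise_off(),
                                 stress_slope_Pa = 5e4,
                                 fit_window = NULL,
                                 width_um = 2000) {
  stopifnot(inherits(model, "psoct_sample"))
  if (repeats < 1L) abort("`repeats` must be >= 1.")
  if (any(ratios < 1)) abort("Length ratios must be >= 1.")
  photo <- vapply(model$layers, function(l) l$material$photoelastic, logical(1))
  if (!any(photo)) abort("Campaign model has no photoelastic layer.")
  curing_ratio <- model$layers[[which(photo)[1]]]$material$curing_ratio
  base_seed <- if (is.null(noise$seed)) config$noise_seed else noise$seed

  rows <- list()
  for (k in seq_along(ratios)) {
    ratio <- ratios[k]
    stretched <- apply_stretch(model, stretch_state(length_ratio = ratio),
                               calibration)
    true_dn <- stretched$layers[[which(photo)[1]]]$birefringence
    stress <- stress_slope_Pa * (ratio - 1)
    force <- stress * model$width_L1_mm * model$relaxed_thickness_L2_0_mm * 1e-6
    for (r in seq_len(repeats)) {
      seed <- as.integer(base_seed + 1000L * k + r)
      nz <- noise
      nz$seed <- seed
      pair <- simulate_bscan(stretched, config, nz)
      seg <- detect_surfaces(pair)
      flat <- flatten(pair, seg)
      floor_deg <- 2 * estimate_retardation_noise(pair, seg)
      profile <- lateral_average(flat, width_um = width_um,
                                 refractive_index = model$refractive_index)
      est <- fit_birefringence(profile, config, fit_window = fit_window,
                               min_retardation_deg = floor_deg)
      px <- median(seg$max_depth[seg$valid] - seg$top[seg$valid] + 1L)
      rows[[length(rows) + 1L]] <- tibble(
        curing_ratio = curing_ratio,
        length_ratio = ratio,
        replicate = r,
        delta_n = est$delta_n,
        true_delta_n = true_dn,
        force_P_N = force,
        stress_Pa = compute_stress(force, model$width_L1_mm,
                                   model$relaxed_thickness_L2_0_mm),
        thickness_um = pixels_to_physical_thickness(px, config,
                                                    model$refractive_index),
        r_squared = est$r_squared,
        seed = seed
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("psoct_campaign", class(out))
  out
}

#' Assemble a stretch-characterization curve
#'
#' Groups stretch experiments by length ratio and summarizes the measured
#' birefringence (mean and sample standard deviation over replicates) and
#' the mean stress per group, sorted by length ratio.
#'
#' @param experiments A tibble of stretch experiments (e.g. from
#'   [run_stretch_campaign()]) with columns `curing_ratio`, `length_ratio`,
#'   `delta_n`, `stress_Pa`.
#' @param curing_ratio The curing ratio the experiments must share; defaults
#'   to the one present. Mixed curing ratios are an error.
#' @return A `psoct_curve` tibble: `curing_ratio`, `length_ratio`,
#'   `mean_delta_n`, `sd_delta_n` (`0` for a single replicate),
#'   `n_replicates`, `mean_stress_Pa`.
#' @export
build_characterization_curve <- function(experiments, curing_ratio = NULL) {
  experiments <- as_tibble(experiments)
  req <- c("curing_ratio", "length_ratio", "delta_n", "stress_Pa")
  if (!all(req %in% names(experiments))) {
    abort(sprintf("Experiments need columns: %s.", paste(req, collapse = ", ")))
  }
  crs <- unique(experiments$curing_ratio)
  if (length(crs) != 1L) {
    abort("Experiments mix curing ratios; build one curve per curing ratio.")
  }
  if (!is.null(curing_ratio) && curing_ratio != crs) {
    abort("`curing_ratio` does not match the experiments.")
  }
  out <- experiments |>
    dplyr::group_by(.data$length_ratio) |>
    dplyr::summarise(
      mean_delta_n = mean(.data$delta_n),
      sd_delta_n = if (dplyr::n() > 1L) sd(.data$delta_n) else 0,
      n_replicates = dplyr::n(),
      mean_stress_Pa = mean(.data$stress_Pa),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$length_ratio) |>
    dplyr::mutate(curing_ratio = crs, .before = 1L)
  class(out) <- c("psoct_curve", class(out))
  out
}

#' @export
tidy.psoct_curve <- function(x, ...) as_tibble(x)

#' @export
glance.psoct_curve <- function(x, ...) {
  tibble(
    curing_ratio = x$curing_ratio[1],
    n_ratios = nrow(x),
    max_mean_delta_n = max(x$mean_delta_n),
    max_length_ratio = max(x$length_ratio)
  )
}
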