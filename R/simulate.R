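#' Noise model for simulated B-scans
#'
#' Speckle is modelled as unit-mean exponential multiplicative noise on the
#' linear intensity (fully developed speckle); retardation noise as Gaussian
#' phase noise in degrees added to the unfolded cumulative retardation before
#' folding into \[0, 90\]. Pixels above the sample surface carry the constant
#' background intensity and retardation noise only.
#'
#' @param speckle_enabled Logical; multiply intensity by Exp(1) speckle?
#' @param retardation_noise_sd_deg Gaussian phase-noise sd, degrees, `>= 0`.
#' @param background_level Background intensity (linear units, `>= 0`),
#'   relative to a unit surface intensity.
#' @param seed Integer RNG seed; `NULL` falls back to the config's
#'   `noise_seed`.
#' @return A `psoct_noise` object.
#' @export
noise_model <- function(speckle_enabled = TRUE,
                        retardation_noise_sd_deg = 2,
                        background_level = 1e-3,
                        seed = NULL) {
  if (retardation_noise_sd_deg < 0) abort("`retardation_noise_sd_deg` must be >= 0.")
  if (background_level < 0) abort("`background_level` must be >= 0.")
  structure(
    list(
      speckle_enabled = isTRUE(speckle_enabled),
      retardation_noise_sd_deg = as.numeric(retardation_noise_sd_deg),
      background_level = as.numeric(background_level),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "psoct_noise"
  )
}

#' Noise-free settings
#'
#' Convenience constructor: speckle off, zero retardation noise.
#' @param background_level Background intensity level.
#' @return A `psoct_noise` object.
#' @export
noise_off <- function(background_level = 1e-3) {
  noise_model(
    speckle_enabled = FALSE, retardation_noise_sd_deg = 0,
    background_level = background_level, seed = 0L
  )
}

#' Fold cumulative retardation into the displayed range
#'
#' PS-OCT retardation maps display the cumulative phase retardation folded
#' into \[0, 90\] degrees by triangle-wave reflection (values are reflected at
#' 0 and 90). The unfolded phase grows without bound with depth; the folded
#' value is what the instrument reports.
#'
#' @param deg Unfolded retardation in degrees (any real values).
#' @return Values folded into \[0, 90\].
#' @export
#' @examples
#' fold_retardation(c(-10, 18, 100, 180))  # 10, 18, 80, 0
fold_retardation <- function(deg) {
  90 - abs(90 - (deg %% 180))
}

# Noise-free axial profiles for one layer stack.
# depth_opt_um: optical-path depths below the surface (um, in air-equivalent
# path). Returns intensity (unit surface intensity) and unfolded retardation
# in degrees at each depth; beyond the stack both are held at their values at
# the bottom (intensity is later replaced by background there).
axial_profiles <- function(layers, refractive_index, wavelength_nm,
                           depth_opt_um, delta_n_scale = 1) {
  n <- refractive_index
  z_phys <- depth_opt_um / n                       # physical depth, um
  th <- vapply(layers, `[[`, numeric(1), "thickness_um")
  mu <- vapply(layers, `[[`, numeric(1), "attenuation_mm")
  dn <- vapply(layers, `[[`, numeric(1), "birefringence") * delta_n_scale
  bounds <- cumsum(th)
  lower <- c(0, bounds[-length(bounds)])
  lambda_um <- wavelength_nm / 1000
  mu_cum <- numeric(length(z_phys))
  delta_deg <- numeric(length(z_phys))
  for (i in seq_along(layers)) {
    path_um <- pmin(pmax(z_phys - lower[i], 0), th[i])  # path inside layer i
    mu_cum <- mu_cum + mu[i] * path_um / 1000           # AC in 1/mm
    delta_deg <- delta_deg + 360 * dn[i] * path_um / lambda_um
  }
  list(
    intensity = exp(-mu_cum),
    retardation_deg = delta_deg,
    in_sample = z_phys <= bounds[length(bounds)]
  )
}

new_bscan_pair <- function(intensity, retardation, config,
                           provenance = "simulated") {
  stopifnot(identical(dim(intensity), dim(retardation)))
  if (any(retardation < 0 | retardation > 90)) {
    abort("Retardation must lie in [0, 90] degrees.")
  }
  if (any(intensity < 0)) abort("Intensity must be >= 0.")
  structure(
    list(
      intensity = intensity,
      retardation = retardation,
      config = config,
      provenance = provenance
    ),
    class = "psoct_bscan"
  )
}

#' @export
print.psoct_bscan <- function(x, ...) {
  cat(sprintf(
    "<psoct_bscan> %d x %d px (%s), retardation %.1f-%.1f deg\n",
    nrow(x$intensity), ncol(x$intensity), x$provenance,
    min(x$retardation), max(x$retardation)
  ))
  invisible(x)
}

#' Simulate a co-registered intensity/retardation B-scan
#'
#' Forward model of a layered, scattering, birefringent sample under PS-OCT.
#' Per lateral column, pixels above the surface carry the background intensity
#' and retardation noise only. Below the surface, the noise-free linear
#' intensity decays as a Beer-Lambert exponential accumulating each layer's
#' attenuation coefficient over the physical path traversed, optionally
#' multiplied by unit-mean exponential speckle. The noise-free cumulative
#' retardation grows as `delta = 2 pi * sum_i(dn_i * z_i) / lambda` (radians;
#' `z_i` = one-way physical path in layer i), is expressed in degrees, has
#' Gaussian phase noise added, and is folded into \[0, 90\]. The axial pixel
#' grid samples optical path (physical depth times refractive index).
#'
#' @param model A [sample_model()], or a [simulate_manipulation_scene()]
#'   result for laterally varying birefringence.
#' @param config An [imaging_config()].
#' @param noise A [noise_model()]; default noise-free.
#' @param surface_standoff_um Optical path of air between the top of the
#'   imaging window and the reference surface plane, um. The per-column
#'   `surface_profile` offsets of the model add to this standoff.
#' @param allow_truncated_bottom If `FALSE`, a layer stack whose optical path
#'   extends past the imaging window is an error; the default `TRUE` permits
#'   it (the bottom surface is then simply not visible, as for thick tissue).
#' @return A `psoct_bscan` with `intensity` and `retardation` matrices of
#'   dimension `depth_pixels` x `lateral_pixels` and the true per-column
#'   surface pixel row stored in attribute `"surface_row"`.
#' @export
#' @examples
#' slab <- sample_model(list(layer_spec("slab", 1500, 1.5, 1e-4)))
#' bs <- simulate_bscan(slab, imaging_config(lateral_pixels = 64))
simulate_bscan <- function(model, config, noise = noise_off(),
                           surface_standoff_um = 150,
                           allow_truncated_bottom = TRUE) {
  scene <- NULL
  if (inherits(model, "psoct_scene")) {
    scene <- model
    model <- scene$base
  }
  stopifnot(inherits(model, "psoct_sample"), inherits(config, "psoct_config"))
  if (!inherits(noise, "psoct_noise")) abort("`noise` must be a psoct_noise.")
  if (surface_standoff_um < 0) abort("`surface_standoff_um` must be >= 0.")

  D <- config$depth_pixels
  W <- config$lateral_pixels
  dz <- config$axial_pixel_spacing_um
  n <- model$refractive_index

  offsets <- rep_len(model$surface_profile, W)
  surface_row <- 1L + as.integer(round((surface_standoff_um + offsets) / dz))
  if (any(surface_row > D)) abort("Surface lies below the imaging window.")

  if (!allow_truncated_bottom) {
    depth_opt_total <- n * total_thickness_um(model)
    if (max(surface_row - 1L) * dz + depth_opt_total > config$max_imaging_depth_um) {
      abort("Layer stack is deeper than the imaging window.")
    }
  }

  factors <- rep(1, W)
  if (!is.null(scene)) factors <- scene$delta_n_factor

  intensity <- matrix(noise$background_level, D, W)
  retardation_true <- matrix(0, D, W)   # unfolded, noise-free
  in_sample <- matrix(FALSE, D, W)

  # profiles depend only on (surface_row, factor); cache per unique pair
  key <- paste(surface_row, factors)
  for (k in unique(key)) {
    cols <- which(key == k)
    s <- surface_row[cols[1]]
    fac <- factors[cols[1]]
    rows <- s:D
    depth_opt <- (rows - s) * dz
    prof <- axial_profiles(model$layers, n, config$wavelength_nm,
                           depth_opt, delta_n_scale = fac)
    ivec <- ifelse(prof$in_sample, prof$intensity, noise$background_level)
    intensity[rows, cols] <- ivec
    retardation_true[rows, cols] <- prof$retardation_deg
    in_sample[rows, cols] <- prof$in_sample
  }

  seed <- if (is.null(noise$seed)) config$noise_seed else noise$seed
  ret_noise <- matrix(0, D, W)
  if (noise$speckle_enabled || noise$retardation_noise_sd_deg > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
    if (noise$speckle_enabled) {
      speckle <- matrix(rexp(D * W), D, W)      # unit-mean exponential
      intensity[in_sample] <- intensity[in_sample] * speckle[in_sample]
    }
    if (noise$retardation_noise_sd_deg > 0) {
      ret_noise <- matrix(rnorm(D * W, sd = noise$retardation_noise_sd_deg), D, W)
    }
  }
  retardation <- fold_retardation(retardation_true + ret_noise)

  out <- new_bscan_pair(intensity, retardation, config, "simulated")
  attr(out, "surface_row") <- surface_row
  out
}

#' Laterally varying manipulation scene
#'
#' Models local manipulation of a stretched sample (e.g. pressing with a
#' surgical tool): columns within `affected_halfwidth` pixels of the
#' manipulation site carry all their layers' birefringence multiplied by
#' `delta_n_factor`; columns elsewhere are unchanged.
#'
#' @param base A [sample_model()] (typically a stretched slab).
#' @param site_column Lateral pixel index of the manipulation site.
#' @param affected_halfwidth Half-width of the affected region, pixels.
#' @param delta_n_factor Multiplier `>= 1` applied to birefringence in the
#'   affected columns (`1` = no manipulation).
#' @param lateral_pixels Width of the scene (must match the imaging config
#'   used to simulate it).
#' @return A `psoct_scene` accepted by [simulate_bscan()].
#' @export
simulate_manipulation_scene <- function(base, site_column, affected_halfwidth,
                                        delta_n_factor, lateral_pixels) {
  stopifnot(inherits(base, "psoct_sample"))
  if (delta_n_factor < 1) abort("`delta_n_factor` must be >= 1.")
  lateral_pixels <- as.integer(lateral_pixels)
  if (site_column < 1L || site_column > lateral_pixels) {
    abort("`site_column` lies outside the image.")
  }
  fac <- rep(1, lateral_pixels)
  cols <- seq_len(lateral_pixels)
  fac[abs(cols - site_column) <= affected_halfwidth] <- delta_n_factor
  structure(
    list(
      base = base,
      site_column = as.integer(site_column),
      affected_halfwidth = as.integer(affected_halfwidth),
      delta_n_factor = fac
    ),
    class = "psoct_scene"
  )
}
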