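#' Material specification
#'
#' Describes a phantom material. PDMS-like silicones are photoelastic: large
#' elastic deformation aligns their polymer chains and induces birefringence
#' that grows with stretch and depends on the base:curing-agent weight ratio.
#' Dragon-Skin-like silicones are elastic but show no stretch-induced
#' birefringence, so `photoelastic = FALSE` pins their birefringence at 0 in
#' every stretch state. The TiO2 scatterer weight fraction controls the
#' attenuation coefficient only; it does not alter the photoelastic response.
#'
#' @param name Text label, e.g. `"PDMS"` or `"DragonSkin"`.
#' @param photoelastic Logical; does stretching induce birefringence?
#' @param curing_ratio Base:agent weight ratio (e.g. `15` for 15:1). Must be
#'   positive.
#' @param scatterer_weight_fraction TiO2 weight percent, `>= 0`.
#' @return A `psoct_material` object.
#' @export
#' @examples
#' pdms <- material_spec("PDMS", photoelastic = TRUE, curing_ratio = 20)
material_spec <- function(name, photoelastic = TRUE, curing_ratio = 15,
                          scatterer_weight_fraction = 0.2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.logical(photoelastic) || length(photoelastic) != 1L || is.na(photoelastic)) {
    abort("`photoelastic` must be TRUE or FALSE.")
  }
  if (!is.numeric(curing_ratio) || curing_ratio <= 0) {
    abort("`curing_ratio` must be a positive number.")
  }
  if (!is.numeric(scatterer_weight_fraction) || scatterer_weight_fraction < 0) {
    abort("`scatterer_weight_fraction` must be >= 0.")
  }
  structure(
    list(
      name = name,
      photoelastic = photoelastic,
      curing_ratio = as.numeric(curing_ratio),
      scatterer_weight_fraction = as.numeric(scatterer_weight_fraction)
    ),
    class = "psoct_material"
  )
}

#' @export
print.psoct_material <- function(x, ...) {
  cat(sprintf(
    "<psoct_material> %s (%s, curing ratio %g:1, TiO2 %g w%%)\n",
    x$name, if (x$photoelastic) "photoelastic" else "non-photoelastic",
    x$curing_ratio, x$scatterer_weight_fraction
  ))
  invisible(x)
}

# maximum |delta n| any layer may declare; well above stretched-PDMS levels
MAX_BIREFRINGENCE <- 5e-3

#' Layer specification
#'
#' One slab of a layered sample, described by its physical thickness in the
#' current stretch state, its OCT attenuation coefficient and its
#' birefringence.
#'
#' @param name Layer label (e.g. `"urothelium"`, `"LP"`, `"MP"`, `"fused"`).
#' @param thickness_um Physical thickness in micrometres, `> 0`.
#' @param attenuation_mm Attenuation coefficient in 1/mm, `>= 0` (one-way
#'   exponential decay of linear OCT intensity).
#' @param birefringence Dimensionless delta-n; `|birefringence| <= 5e-3`.
#' @param material A [material_spec()] object.
#' @return A `psoct_layer` object.
#' @export
layer_spec <- function(name, thickness_um, attenuation_mm,
                       birefringence = 0,
                       material = material_spec("PDMS")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(thickness_um) || thickness_um <= 0) {
    abort(sprintf("Layer '%s': `thickness_um` must be > 0.", name))
  }
  if (!is.numeric(attenuation_mm) || attenuation_mm < 0) {
    abort(sprintf("Layer '%s': `attenuation_mm` must be >= 0.", name))
  }
  if (!is.numeric(birefringence) || abs(birefringence) > MAX_BIREFRINGENCE) {
    abort(sprintf(
      "Layer '%s': `birefringence` must satisfy |delta n| <= %g.",
      name, MAX_BIREFRINGENCE
    ))
  }
  if (!inherits(material, "psoct_material")) {
    abort("`material` must be a psoct_material (see material_spec()).")
  }
  if (!material$photoelastic && birefringence != 0) {
    abort(sprintf(
      "Layer '%s': non-photoelastic material cannot carry birefringence.", name
    ))
  }
  structure(
    list(
      name = name,
      thickness_um = as.numeric(thickness_um),
      attenuation_mm = as.numeric(attenuation_mm),
      birefringence = as.numeric(birefringence),
      material = material
    ),
    class = "psoct_layer"
  )
}

#' Layered sample model
#'
#' Declarative description of a layered sample: an ordered stack of layers
#' (top, i.e. first-illuminated, layer first), the group refractive index used
#' for optical-path conversion, an optional per-column surface height profile,
#' and the clamp geometry of the relaxed sample (used for stress computation).
#'
#' @param layers List of [layer_spec()] objects, top layer first.
#' @param refractive_index Group refractive index, `>= 1` (default 1.4, the
#'   value used for pixel-to-thickness conversion).
#' @param surface_profile Per-column surface height offsets in micrometres of
#'   air above the reference plane (default `0`, a flat surface; recycled to
#'   the lateral width at simulation time).
#' @param width_L1_mm Clamp-contact width of the sample, mm.
#' @param relaxed_thickness_L2_0_mm Total relaxed thickness, mm. Defaults to
#'   the current layer-thickness sum (valid when the model describes the
#'   relaxed state).
#' @return A `psoct_sample` object.
#' @export
#' @examples
#' slab <- sample_model(list(layer_spec("slab", 1500, 1.5, 1e-4)))
#' total_thickness_um(slab)
sample_model <- function(layers, refractive_index = 1.4,
                         surface_profile = 0,
                         width_L1_mm = 10,
                         relaxed_thickness_L2_0_mm = NULL) {
  if (inherits(layers, "psoct_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) == 0L ||
      !all(vapply(layers, inherits, logical(1), "psoct_layer"))) {
    abort("`layers` must be a non-empty list of psoct_layer objects.")
  }
  if (!is.numeric(refractive_index) || refractive_index < 1) {
    abort("`refractive_index` must be >= 1.")
  }
  if (!is.numeric(surface_profile) || any(surface_profile < 0)) {
    abort("`surface_profile` offsets must be >= 0 (um of air).")
  }
  if (!is.numeric(width_L1_mm) || width_L1_mm <= 0) {
    abort("`width_L1_mm` must be > 0.")
  }
  total_mm <- sum(vapply(layers, `[[`, numeric(1), "thickness_um")) / 1000
  if (is.null(relaxed_thickness_L2_0_mm)) relaxed_thickness_L2_0_mm <- total_mm
  if (!is.numeric(relaxed_thickness_L2_0_mm) || relaxed_thickness_L2_0_mm <= 0) {
    abort("`relaxed_thickness_L2_0_mm` must be > 0.")
  }
  structure(
    list(
      layers = layers,
      refractive_index = as.numeric(refractive_index),
      surface_profile = as.numeric(surface_profile),
      width_L1_mm = as.numeric(width_L1_mm),
      relaxed_thickness_L2_0_mm = as.numeric(relaxed_thickness_L2_0_mm)
    ),
    class = "psoct_sample"
  )
}

#' Total sample thickness
#'
#' @param model A [sample_model()].
#' @return Total physical thickness in micrometres (sum over layers).
#' @export
total_thickness_um <- function(model) {
  stopifnot(inherits(model, "psoct_sample"))
  sum(vapply(model$layers, `[[`, numeric(1), "thickness_um"))
}

#' Tidy view of a sample model's layer stack
#'
#' @param x A [sample_model()].
#' @param ... Unused.
#' @return A tibble with one row per layer (top first): name, thickness,
#'   attenuation coefficient, birefringence, material fields.
#' @export
tidy.psoct_sample <- function(x, ...) {
  purrr::map_dfr(x$layers, function(l) {
    tibble(
      layer = l$name,
      thickness_um = l$thickness_um,
      attenuation_mm = l$attenuation_mm,
      birefringence = l$birefringence,
      material = l$material$name,
      photoelastic = l$material$photoelastic,
      curing_ratio = l$material$curing_ratio
    )
  })
}

#' @export
print.psoct_sample <- function(x, ...) {
  cat(sprintf(
    "<psoct_sample> %d layer(s), total %g um, n = %g\n",
    length(x$layers), total_thickness_um(x), x$refractive_index
  ))
  print(tidy(x))
  invisible(x)
}

#' Imaging configuration
#'
#' Geometry of the PS-OCT acquisition. Defaults describe a 1300-nm
#' swept-source system with 5.5-um axial and 7.8-um lateral resolution; the
#' axial pixel spacing defaults to half the axial resolution. The axial pixel
#' grid samples *optical path in air*: a physical depth `z` inside a medium of
#' index `n` lands at pixel `round(n * z / axial_pixel_spacing_um)`.
#'
#' @param wavelength_nm Centre wavelength, nm (`> 0`).
#' @param axial_pixel_spacing_um Axial pixel spacing in optical path, um/px.
#' @param lateral_pixel_spacing_um Lateral pixel spacing, um/px.
#' @param depth_pixels Number of axial pixels.
#' @param lateral_pixels Number of A-scans per B-scan.
#' @param max_imaging_depth_um Imaging window depth in optical path, um.
#'   Defaults to `depth_pixels * axial_pixel_spacing_um`.
#' @param noise_seed Default RNG seed used when a noise model carries none.
#' @return A `psoct_config` object.
#' @export
imaging_config <- function(wavelength_nm = 1300,
                           axial_pixel_spacing_um = 2.75,
                           lateral_pixel_spacing_um = 7.8,
                           depth_pixels = 1024L,
                           lateral_pixels = 512L,
                           max_imaging_depth_um = NULL,
                           noise_seed = 1L) {
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0) {
    abort("`wavelength_nm` must be > 0.")
  }
  if (axial_pixel_spacing_um <= 0 || lateral_pixel_spacing_um <= 0) {
    abort("Pixel spacings must be > 0.")
  }
  depth_pixels <- as.integer(depth_pixels)
  lateral_pixels <- as.integer(lateral_pixels)
  if (depth_pixels < 1L || lateral_pixels < 1L) {
    abort("Pixel counts must be >= 1.")
  }
  if (is.null(max_imaging_depth_um)) {
    max_imaging_depth_um <- depth_pixels * axial_pixel_spacing_um
  }
  if (depth_pixels * axial_pixel_spacing_um < max_imaging_depth_um) {
    abort("depth_pixels * axial_pixel_spacing_um must cover max_imaging_depth_um.")
  }
  structure(
    list(
      wavelength_nm = as.numeric(wavelength_nm),
      axial_pixel_spacing_um = as.numeric(axial_pixel_spacing_um),
      lateral_pixel_spacing_um = as.numeric(lateral_pixel_spacing_um),
      depth_pixels = depth_pixels,
      lateral_pixels = lateral_pixels,
      max_imaging_depth_um = as.numeric(max_imaging_depth_um),
      noise_seed = as.integer(noise_seed)
    ),
    class = "psoct_config"
  )
}

#' @export
print.psoct_config <- function(x, ...) {
  cat(sprintf(
    "<psoct_config> %g nm, %d x %d px (%g um/px axial, %g um/px lateral)\n",
    x$wavelength_nm, x$depth_pixels, x$lateral_pixels,
    x$axial_pixel_spacing_um, x$lateral_pixel_spacing_um
  ))
  invisible(x)
}

#' Stretch state of a clamped sample
#'
#' The stretch variable is the length ratio: elongated clamp separation
#' divided by the original (relaxed) separation of 6 mm by default.
#'
#' @param length_ratio Elongated / original length, `>= 1`. Supply either this
#'   or `elongated_length_mm`.
#' @param original_length_mm Relaxed clamp separation, mm.
#' @param elongated_length_mm Stretched clamp separation, mm.
#' @return A `psoct_stretch` object.
#' @export
#' @examples
#' stretch_state(length_ratio = 2)
#' stretch_state(elongated_length_mm = 8.5)  # 6-mm original -> ratio ~1.417
stretch_state <- function(length_ratio = NULL, original_length_mm = 6,
                          elongated_length_mm = NULL) {
  if (!is.numeric(original_length_mm) || original_length_mm <= 0) {
    abort("`original_length_mm` must be > 0.")
  }
  if (is.null(length_ratio)) {
    if (is.null(elongated_length_mm)) {
      abort("Supply `length_ratio` or `elongated_length_mm`.")
    }
    length_ratio <- elongated_length_mm / original_length_mm
  } else if (is.null(elongated_length_mm)) {
    elongated_length_mm <- length_ratio * original_length_mm
  } else if (abs(length_ratio - elongated_length_mm / original_length_mm) > 1e-12) {
    abort("`length_ratio` must equal elongated / original length exactly.")
  }
  if (length_ratio < 1) {
    abort("`length_ratio` must be >= 1 (samples are stretched, not compressed).")
  }
  structure(
    list(
      original_length_mm = as.numeric(original_length_mm),
      elongated_length_mm = as.numeric(elongated_length_mm),
      length_ratio = as.numeric(length_ratio)
    ),
    class = "psoct_stretch"
  )
}

#' Apply a stretch to a sample model
#'
#' Stretching a clamped slab by length ratio `r` thins every layer by `1/r`:
#' the clamps hold the width fixed, so incompressibility puts all the thinning
#' into the thickness. Photoelastic layers acquire the stretch-induced
#' birefringence given by the calibration curve for their curing ratio at this
#' length ratio; non-photoelastic layers stay at delta-n = 0. Attenuation
#' coefficients are unchanged (scatterer density does not affect the
#' photoelastic response).
#'
#' @param model A [sample_model()] describing the relaxed sample.
#' @param stretch A [stretch_state()].
#' @param calibration A [stretch_calibration()] covering every photoelastic
#'   material's curing ratio. Defaults to the shipped anchor table.
#' @return A new `psoct_sample` in the stretched state. The relaxed clamp
#'   geometry (`width_L1_mm`, `relaxed_thickness_L2_0_mm`) is preserved.
#' @export
#' @examples
#' slab <- sample_model(list(layer_spec("slab", 1500, 1.5,
#'   material = material_spec("PDMS", curing_ratio = 20))))
#' stretched <- apply_stretch(slab, stretch_state(length_ratio = 5))
#' stretched$layers[[1]]$thickness_um   # 300
#' stretched$layers[[1]]$birefringence  # 2.1e-4
apply_stretch <- function(model, stretch,
                          calibration = default_stretch_calibration()) {
  stopifnot(inherits(model, "psoct_sample"), inherits(stretch, "psoct_stretch"))
  r <- stretch$length_ratio
  if (r < 1) abort("`length_ratio` must be >= 1.")
  if (r == 1) return(model)  # identity stretch leaves every field untouched
  new_layers <- lapply(model$layers, function(l) {
    dn <- if (l$material$photoelastic) {
      evaluate_stretch_calibration(calibration, l$material$curing_ratio, r)
    } else {
      0
    }
    layer_spec(
      name = l$name,
      thickness_um = l$thickness_um / r,
      attenuation_mm = l$attenuation_mm,
      birefringence = dn,
      material = l$material
    )
  })
  out <- model
  out$layers <- new_layers
  out
}
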