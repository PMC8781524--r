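#' Write and read sample/imaging configuration files
#'
#' Sample models, imaging configurations and stretch calibrations share one
#' structured-text dialect: a YAML document (JSON-compatible schema) with
#' top-level sections `sample`, `imaging` and `calibration`, any subset of
#' which may be present. Writing then reading a configuration reproduces it
#' exactly (round-trippable).
#'
#' Schema sketch:
#' \preformatted{
#' sample:
#'   refractive_index: 1.4
#'   width_L1_mm: 10
#'   relaxed_thickness_L2_0_mm: 1.5
#'   surface_profile: [0]
#'   layers:
#'   - {name: slab, thickness_um: 1500, attenuation_mm: 1.5,
#'      birefringence: 0.0,
#'      material: {name: PDMS, photoelastic: yes, curing_ratio: 15,
#'                 scatterer_weight_fraction: 0.2}}
#' imaging:
#'   wavelength_nm: 1300
#'   ...
#' calibration:
#' - {curing_ratio: 20, length_ratio: 1, delta_n: 0, source: relaxed}
#' - ...
#' }
#'
#' @param path File path.
#' @param sample Optional [sample_model()].
#' @param imaging Optional [imaging_config()].
#' @param calibration Optional [stretch_calibration()].
#' @return `write_psoct_config()` returns `path` invisibly;
#'   `read_psoct_config()` returns a list with elements `sample`, `imaging`,
#'   `calibration` (those present in the file, as package objects).
#' @export
write_psoct_config <- function(path, sample = NULL, imaging = NULL,
                               calibration = NULL) {
  doc <- list()
  if (!is.null(sample)) {
    stopifnot(inherits(sample, "psoct_sample"))
    doc$sample <- list(
      refractive_index = sample$refractive_index,
      width_L1_mm = sample$width_L1_mm,
      relaxed_thickness_L2_0_mm = sample$relaxed_thickness_L2_0_mm,
      surface_profile = as.list(sample$surface_profile),
      layers = lapply(sample$layers, function(l) {
        list(
          name = l$name,
          thickness_um = l$thickness_um,
          attenuation_mm = l$attenuation_mm,
          birefringence = l$birefringence,
          material = list(
            name = l$material$name,
            photoelastic = l$material$photoelastic,
            curing_ratio = l$material$curing_ratio,
            scatterer_weight_fraction = l$material$scatterer_weight_fraction
          )
        )
      })
    )
  }
  if (!is.null(imaging)) {
    stopifnot(inherits(imaging, "psoct_config"))
    doc$imaging <- unclass(imaging)
  }
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "psoct_calibration"))
    doc$calibration <- purrr::transpose(as.list(as_tibble(calibration)))
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_psoct_config
#' @export
read_psoct_config <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(doc$sample)) {
    s <- doc$sample
    layers <- lapply(s$layers, function(l) {
      m <- l$material
      layer_spec(
        name = l$name,
        thickness_um = l$thickness_um,
        attenuation_mm = l$attenuation_mm,
        birefringence = l$birefringence,
        material = material_spec(m$name, m$photoelastic, m$curing_ratio,
                                 m$scatterer_weight_fraction)
      )
    })
    out$sample <- sample_model(
      layers,
      refractive_index = s$refractive_index,
      surface_profile = unlist(s$surface_profile),
      width_L1_mm = s$width_L1_mm,
      relaxed_thickness_L2_0_mm = s$relaxed_thickness_L2_0_mm
    )
  }
  if (!is.null(doc$imaging)) {
    i <- doc$imaging
    out$imaging <- imaging_config(
      wavelength_nm = i$wavelength_nm,
      axial_pixel_spacing_um = i$axial_pixel_spacing_um,
      lateral_pixel_spacing_um = i$lateral_pixel_spacing_um,
      depth_pixels = i$depth_pixels,
      lateral_pixels = i$lateral_pixels,
      max_imaging_depth_um = i$max_imaging_depth_um,
      noise_seed = i$noise_seed
    )
  }
  if (!is.null(doc$calibration)) {
    out$calibration <- stretch_calibration(
      dplyr::bind_rows(lapply(doc$calibration, as_tibble))
    )
  }
  out
}

#' Write and read B-scan pairs as multi-page image stacks
#'
#' A `psoct_bscan` is stored as a two-page 32-bit-float TIFF (page 1:
#' intensity, page 2: retardation in degrees) plus a YAML sidecar
#' (`<stem>.yml`) carrying the imaging configuration, provenance and the
#' normalization scales. TIFF float storage is normalized to \[0, 1\]:
#' intensity is divided by its maximum and retardation by 90; the sidecar
#' records both scales and the reader undoes them.
#'
#' @param pair A `psoct_bscan`.
#' @param path Path to the `.tif` file; the sidecar lives alongside it.
#' @return `write_bscan()` returns `path` invisibly; `read_bscan()` returns
#'   the restored `psoct_bscan`.
#' @export
write_bscan <- function(pair, path) {
  stopifnot(inherits(pair, "psoct_bscan"))
  iscale <- max(pair$intensity, 1e-300)
  tiff::writeTIFF(
    list(pair$intensity / iscale, pair$retardation / 90),
    path, bits.per.sample = 32L, reduce = FALSE, compression = "none"
  )
  sidecar <- sub("\\.tiff?$", ".yml", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".yml")
  yaml::write_yaml(
    list(
      provenance = pair$provenance,
      intensity_scale = iscale,
      retardation_scale = 90,
      imaging = unclass(pair$config)
    ),
    sidecar, precision = 15L
  )
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  sidecar <- sub("\\.tiff?$", ".yml", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar)) {
    abort(sprintf("Sidecar metadata file not found: %s", sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) abort("Expected a two-page image stack.")
  i <- meta$imaging
  config <- imaging_config(
    wavelength_nm = i$wavelength_nm,
    axial_pixel_spacing_um = i$axial_pixel_spacing_um,
    lateral_pixel_spacing_um = i$lateral_pixel_spacing_um,
    depth_pixels = i$depth_pixels,
    lateral_pixels = i$lateral_pixels,
    max_imaging_depth_um = i$max_imaging_depth_um,
    noise_seed = i$noise_seed
  )
  new_bscan_pair(
    pages[[1]] * meta$intensity_scale,
    pmin(pmax(pages[[2]] * meta$retardation_scale, 0), 90),
    config,
    provenance = meta$provenance %||% "imported"
  )
}
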