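#' Reference bladder-wall sample models
#'
#' Layered models of the human bladder wall as seen from the lumen.
#'
#' Normal condition: a thin, non-birefringent urothelium (50 um, AC
#' 0.8 /mm), the collagen-rich, birefringent lamina propria (LP; 400 um, AC
#' 3.5 /mm) and the smooth-muscle muscularis propria (MP; 1600 um, AC
#' 1.5 /mm). Default birefringence values are the measured tissue means:
#' urothelium 0 (not birefringent), LP 1.18e-4; the MP, which lies too deep
#' to measure in tissue, defaults to 4.50e-5 (lower than the LP but
#' non-zero, as expected for smooth muscle).
#'
#' Diseased (carcinoma-in-situ-like) condition: the urothelium and LP lose
#' their stratification and appear as a single fused, essentially
#' non-birefringent layer (450 um total, graded AC 2.2 to 1.8 /mm top to
#' bottom, modelled as three 150-um sublayers named `"fused"`), atop an MP
#' identical to the normal condition. The fused layer's default delta-n is
#' the diseased-LP tissue mean, 3.21e-5.
#'
#' @param condition `"normal"` or `"diseased"`.
#' @param delta_n Optional named numeric vector overriding layer
#'   birefringence: names among `urothelium`, `LP`, `MP` (normal) or
#'   `fused`, `MP` (diseased). Used e.g. to build a phantom with its
#'   realized, rather than target, values.
#' @param stretched Unused placeholder for symmetry with slab workflows;
#'   bladder models are specified directly in their imaged state.
#' @return A [sample_model()] with refractive index 1.4.
#' @export
#' @examples
#' tidy(make_bladder_model("normal"))
#' make_bladder_model("diseased", delta_n = c(fused = 4.61e-6, MP = 3.59e-5))
make_bladder_model <- function(condition = c("normal", "diseased"),
                               delta_n = NULL, stretched = FALSE) {
  condition <- match.arg(condition)
  defaults <- switch(condition,
    normal = c(urothelium = 0, LP = 1.18e-4, MP = 4.50e-5),
    diseased = c(fused = 3.21e-5, MP = 4.50e-5)
  )
  if (!is.null(delta_n)) {
    bad <- setdiff(names(delta_n), names(defaults))
    if (length(bad)) {
      abort(sprintf("Unknown layer name(s): %s.", paste(bad, collapse = ", ")))
    }
    defaults[names(delta_n)] <- delta_n
  }
  pdms15 <- material_spec("PDMS", photoelastic = TRUE, curing_ratio = 15,
                          scatterer_weight_fraction = 0.3)
  pdms25 <- material_spec("PDMS", photoelastic = TRUE, curing_ratio = 25,
                          scatterer_weight_fraction = 0.15)
  dskin <- material_spec("DragonSkin", photoelastic = FALSE, curing_ratio = 1,
                         scatterer_weight_fraction = 0.04)
  # non-photoelastic material cannot carry delta-n != 0, so near-zero layers
  # with a measured residual (e.g. a realized phantom urothelium of 3.11e-7)
  # are represented on a photoelastic carrier when needed
  carrier <- function(dn, preferred) {
    if (dn == 0) preferred else pdms15
  }
  layers <- switch(condition,
    normal = list(
      layer_spec("urothelium", 50, 0.8, defaults[["urothelium"]],
                 material = carrier(defaults[["urothelium"]], dskin)),
      layer_spec("LP", 400, 3.5, defaults[["LP"]], material = pdms15),
      layer_spec("MP", 1600, 1.5, defaults[["MP"]], material = pdms25)
    ),
    diseased = list(
      layer_spec("fused", 150, 2.2, defaults[["fused"]],
                 material = carrier(defaults[["fused"]], dskin)),
      layer_spec("fused", 150, 2.0, defaults[["fused"]],
                 material = carrier(defaults[["fused"]], dskin)),
      layer_spec("fused", 150, 1.8, defaults[["fused"]],
                 material = carrier(defaults[["fused"]], dskin)),
      layer_spec("MP", 1600, 1.5, defaults[["MP"]], material = pdms25)
    )
  )
  sample_model(layers, refractive_index = 1.4)
}

#' Default per-layer analysis windows for bladder samples
#'
#' Depth windows below the detected surface used to extract per-layer
#' birefringence: the urothelium extends 50 um below the surface and the LP
#' the next 200 um. The MP window starts below the full LP (450 um below the
#' surface) and spans 200 um; in the diseased condition the fused
#' urothelium+LP region is analyzed as one 450-um window.
#'
#' @param condition `"normal"` or `"diseased"`.
#' @param mp_window_um Width of the MP window, um.
#' @return A [layer_windows()] tibble.
#' @export
bladder_windows <- function(condition = c("normal", "diseased"),
                            mp_window_um = 200) {
  condition <- match.arg(condition)
  switch(condition,
    normal = layer_windows(
      layer = c("urothelium", "LP", "MP"),
      zmin_um = c(0, 50, 450),
      zmax_um = c(50, 250, 450 + mp_window_um)
    ),
    diseased = layer_windows(
      layer = c("fused", "MP"),
      zmin_um = c(0, 450),
      zmax_um = c(450, 450 + mp_window_um)
    )
  )
}
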