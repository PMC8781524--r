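# Shared fixtures: everything is generated in code at test time.

# a small imaging geometry that keeps simulations fast
small_config <- function(depth_pixels = 256L, lateral_pixels = 64L, ...) {
  imaging_config(depth_pixels = depth_pixels, lateral_pixels = lateral_pixels,
                 ...)
}

# single-layer PDMS slab in its imaged state
slab_model <- function(delta_n = 1e-4, thickness_um = 1500,
                       attenuation_mm = 1.5, refractive_index = 1.4,
                       curing_ratio = 20, ...) {
  sample_model(
    list(layer_spec("slab", thickness_um, attenuation_mm, delta_n,
                    material = material_spec("PDMS",
                                             curing_ratio = curing_ratio))),
    refractive_index = refractive_index, ...
  )
}

# run the full extraction on a simulated pair, returning one delta-n
extract_slab_delta_n <- function(pair, config, width_um = 400,
                                 fit_window = NULL) {
  seg <- detect_surfaces(pair)
  flat <- flatten(pair, seg)
  floor_deg <- 2 * estimate_retardation_noise(pair, seg)
  prof <- lateral_average(flat, width_um = width_um)
  fit_birefringence(prof, config, fit_window = fit_window,
                    min_retardation_deg = floor_deg)$delta_n
}

# independent brute-force Otsu: exhaustive search over all splits, computing
# the between-class variance from first principles (class weights and means)
otsu_oracle <- function(h) {
  nb <- length(h)
  total <- sum(h)
  bins <- 0:(nb - 1)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 1:(nb - 1)) {
    w0 <- sum(h[1:t])
    w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * bins[1:t]) / w0
    mu1 <- sum(h[(t + 1):nb] * bins[(t + 1):nb]) / w1
    sb <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (sb > best) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# between-class variance of one split, for symmetry checks
between_class_variance <- function(h, t) {
  nb <- length(h)
  total <- sum(h)
  bins <- 0:(nb - 1)
  w0 <- sum(h[1:t]) / total
  w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(-Inf)
  mu0 <- sum(h[1:t] * bins[1:t]) / sum(h[1:t])
  mu1 <- sum(h[(t + 1):nb] * bins[(t + 1):nb]) / sum(h[(t + 1):nb])
  w0 * w1 * (mu0 - mu1)^2
}
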