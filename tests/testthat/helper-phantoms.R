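# Shared phantom fixtures, generated once per test run and cached.
# Each configuration isolates the optical effects a test needs:
#   default    - full realism (cross-talk, decay, noise, random orientation)
#   clean      - identity optics: identity mixing, no decay, no noise,
#                unit brightness; channel k equals fluorophore k exactly
#   optics     - wavelength-dependent exponential decay only (identity
#                mixing, no noise, unit brightness, ubiquitous channel-2
#                marker) for decay-fit / ratio / normalization tests
#   mixed      - strong cross-talk incl. fluor-2 bleed into channel 4, with
#                noise, for calibration and unmixing tests
#   tangential - two-compartment 2:1 density step with boundary-tangential
#                nuclear elongation, for density-step recovery
#   aligned    - sharper 4:1 step, same tangential elongation, for the
#                alignment-field construction (a 2:1 step at this sample
#                size leaves the coarse-grained gradient dominated by
#                packing noise)
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(name) {
  if (!is.null(.phantom_cache[[name]])) return(.phantom_cache[[name]])
  ph <- switch(
    name,
    default = generate_phantom(phantom_spec(seed = 7)),
    clean = generate_phantom(phantom_spec(
      organoid_radius = 20, target_volume_fraction = 0.25,
      noise_sd = 0, brightness_sdlog = 0,
      mixing_matrix = diag(4), decay_lengths = rep(Inf, 4),
      marker_lengths = c(Inf, 30), seed = 11)),
    optics = generate_phantom(phantom_spec(
      organoid_radius = 24, target_volume_fraction = 0.25,
      noise_sd = 0, brightness_sdlog = 0,
      mixing_matrix = diag(4), decay_lengths = c(100, 208, 170, 140),
      marker_lengths = c(Inf, 30), seed = 13)),
    mixed = generate_phantom(phantom_spec(
      organoid_radius = 22, target_volume_fraction = 0.25,
      noise_sd = 0.01,
      mixing_matrix = rbind(c(0.80, 0.10, 0.05, 0.05),
                            c(0.10, 0.70, 0.05, 0.15),
                            c(0.05, 0.10, 0.80, 0.05),
                            c(0.02, 0.03, 0.10, 0.85)),
      marker_lengths = c(25, 25), mitotic_prob = 0.05, seed = 21)),
    aligned = generate_phantom(phantom_spec(
      organoid_radius = 26, target_volume_fraction = 0.22,
      nuclei_axis_ratio_range = c(0.65, 1.45),
      orientation = "tangential", wall_layer = FALSE,
      compartment_ratio = 4,
      noise_sd = 0, brightness_sdlog = 0, mixing_matrix = diag(4),
      decay_lengths = rep(Inf, 4), seed = 41)),
    tangential = generate_phantom(phantom_spec(
      organoid_radius = 26, target_volume_fraction = 0.22,
      nuclei_axis_ratio_range = c(0.65, 1.45),
      orientation = "tangential", wall_layer = FALSE,
      compartment_ratio = 2,
      noise_sd = 0, brightness_sdlog = 0, mixing_matrix = diag(4),
      decay_lengths = rep(Inf, 4), seed = 31)),
    stop("unknown phantom fixture: ", name))
  assign(name, ph, envir = .phantom_cache)
  ph
}

nuclei_mask <- function(ph) array(unclass(ph$labels) > 0L, dim(ph$labels))

# median of a field per z-plane over mask voxels (planes with thin support
# are dropped: a median needs enough voxels to be meaningful)
plane_medians <- function(img, mask, min_voxels = 50) {
  arr <- unclass(img)
  vapply(seq_len(dim(arr)[1]), function(z) {
    v <- arr[z, , ][mask[z, , ]]
    v <- v[is.finite(v)]
    if (length(v) >= min_voxels) stats::median(v) else NA_real_
  }, numeric(1))
}

# planes at least one truncated-kernel radius (3 sigma) away from the first
# and last nuclei-bearing plane: masked-smoothing estimates within a kernel
# radius of the domain edge are boundary-extrapolated and excluded from
# flatness statistics
bulk_planes <- function(ph, sigma) {
  m <- nuclei_mask(ph)
  has <- which(apply(m, 1, any))
  sp <- vox_spacing(ph$labels)[1]
  margin <- ceiling(3 * sigma / sp)
  seq(min(has) + margin, max(has) - margin)
}
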