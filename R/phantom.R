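#' Synthetic organoid phantoms with full ground truth
#'
#' Every downstream stage of the pipeline is testable without microscope data
#' through a phantom generator: non-overlapping ellipsoidal nuclei are packed
#' by rejection sampling into a spherical sample mask, each nucleus carries
#' per-fluorophore brightness, marker classes with a known radial probability
#' law, and a mitotic flag; detector channels are rendered as
#' `sum_i brightness_i * mixing[i, k] * exp(-z / d_k)` plus additive Gaussian
#' noise, emulating spectral cross-talk and wavelength-dependent exponential
#' intensity decay with depth. A second view is generated by transforming the
#' ground-truth geometry with a known rigid transform (180 degree flip about X
#' plus a residual rotation), re-rasterizing, and re-applying the decay from
#' the opposite face, as happens when the sample slide is flipped and
#' re-imaged.
#'
#' @param organoid_radius sample sphere radius, um.
#' @param nuclei_mean_radius mean nuclear semi-axis, um (nuclei diameters of
#'   10-15 um are typical for these aggregates).
#' @param nuclei_axis_ratio_range range of per-axis scale factors relative to
#'   the mean radius.
#' @param target_volume_fraction nuclear volume fraction to reach, in
#'   (0, 0.64] (0.64 is the random-close-packing bound for spheres; measured
#'   aggregates reach about 0.61).
#' @param n_channels number of detector channels.
#' @param mixing_matrix `n_fluor x n_channels` nonnegative weights; rows are
#'   normalized to sum 1.
#' @param decay_lengths per-channel decay length `d` in um (may be `Inf` for
#'   no decay). The defaults give a blue/far-red decay-length ratio of
#'   100/208 = 0.48, the order measured for Hoechst vs far-red nuclear
#'   stains.
#' @param voxel_spacing um triple (z, y, x).
#' @param residual_rotation_deg residual view-B rotation (about Z, Y, X,
#'   degrees) composed with the 180 degree X flip; residual flip errors of
#'   order 10 degrees are typical.
#' @param residual_translation_um residual view-B translation (z, y, x um).
#' @param noise_sd additive Gaussian noise SD (intensity units; nuclei have
#'   brightness of order 1).
#' @param brightness_sdlog log-SD of the per-nucleus log-normal brightness
#'   (the distribution of per-nucleus staining intensity is not tightly
#'   constrained; log-normal is the package default).
#' @param marker_lengths length-2 um: fluorophore 2 is a surface marker with
#'   positivity probability `exp(-dist_border / marker_lengths[1])`;
#'   fluorophore 3 an interior marker with `1 - exp(-dist_border /
#'   marker_lengths[2])`. Use `Inf` for the first to make fluorophore 2
#'   ubiquitous.
#' @param mitotic_prob uniform Bernoulli probability that a nucleus is
#'   mitotic (fluorophore 4 signal).
#' @param orientation `"random"` (isotropic nuclear orientations) or
#'   `"tangential"` (major axes perpendicular to the local radial direction,
#'   emulating boundary-aligned deformation).
#' @param wall_layer place a dense tangential monolayer of nuclei along the
#'   sample border before bulk packing, as aggregates present at their
#'   surface. Disable when a strict radial placement law (e.g. a density
#'   step) must hold all the way to the border.
#' @param compartment_ratio inner:outer placement density ratio across
#'   `step_radius_frac * organoid_radius` (1 = homogeneous; 2 emulates two
#'   tissue-scale density populations).
#' @param step_radius_frac radius fraction of the density step.
#' @param margin_um empty margin around the sphere, um.
#' @param seed integer seed fixing all randomness.
#' @param max_attempts placement attempts before giving up on the target
#'   fraction (a warning then reports the achieved fraction).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(organoid_radius = 30,
                         nuclei_mean_radius = 4.5,
                         nuclei_axis_ratio_range = c(0.8, 1.25),
                         target_volume_fraction = 0.3,
                         n_channels = 4,
                         mixing_matrix = NULL,
                         decay_lengths = c(100, 140, 170, 208),
                         voxel_spacing = c(1, 1, 1),
                         residual_rotation_deg = c(-10, 5, -5),
                         residual_translation_um = c(0, 0, 0),
                         noise_sd = 0.01,
                         brightness_sdlog = 0.25,
                         marker_lengths = c(30, 30),
                         mitotic_prob = 0.05,
                         orientation = c("random", "tangential"),
                         wall_layer = TRUE,
                         compartment_ratio = 1,
                         step_radius_frac = 0.5,
                         margin_um = 6,
                         seed = 1,
                         max_attempts = 40000) {
  orientation <- match.arg(orientation)
  if (is.null(mixing_matrix)) {
    mixing_matrix <- diag(n_channels) * 0.75 + 0.25 / n_channels
  }
  mixing_matrix <- as.matrix(mixing_matrix)
  if (ncol(mixing_matrix) != n_channels) stop("mixing_matrix needs n_channels columns")
  if (any(mixing_matrix < 0)) stop("mixing_matrix must be nonnegative")
  mixing_matrix <- mixing_matrix / rowSums(mixing_matrix)
  if (!(target_volume_fraction > 0 && target_volume_fraction <= 0.64))
    stop("target_volume_fraction must be in (0, 0.64]")
  if (length(decay_lengths) != n_channels) stop("one decay length per channel")
  if (any(voxel_spacing <= 0)) stop("voxel spacings must be > 0")
  structure(list(organoid_radius = organoid_radius,
                 nuclei_mean_radius = nuclei_mean_radius,
                 nuclei_axis_ratio_range = nuclei_axis_ratio_range,
                 target_volume_fraction = target_volume_fraction,
                 n_channels = n_channels, mixing_matrix = mixing_matrix,
                 decay_lengths = decay_lengths,
                 voxel_spacing = as.numeric(voxel_spacing),
                 residual_rotation_deg = residual_rotation_deg,
                 residual_translation_um = residual_translation_um,
                 noise_sd = noise_sd, brightness_sdlog = brightness_sdlog,
                 marker_lengths = marker_lengths,
                 mitotic_prob = mitotic_prob, orientation = orientation,
                 wall_layer = wall_layer,
                 compartment_ratio = compartment_ratio,
                 step_radius_frac = step_radius_frac,
                 margin_um = margin_um, seed = seed,
                 max_attempts = max_attempts),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> R = %g um, nuclei ~%g um, target ",
                     "fraction %.2f, %d channels, seed %d\n"),
              x$organoid_radius, x$nuclei_mean_radius,
              x$target_volume_fraction, x$n_channels, x$seed))
  invisible(x)
}

random_rotation <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    q <- qr(M)
    Q <- qr.Q(q)
    Q <- Q %*% diag(sign(diag(qr.R(q))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-8) return(Q)
  }
}

# orthonormal frame whose first column is perpendicular to `radial`
tangential_frame <- function(radial) {
  r <- radial / sqrt(sum(radial^2))
  v <- stats::rnorm(3)
  t1 <- v - sum(v * r) * r
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(r[2] * t1[3] - r[3] * t1[2],
          r[3] * t1[1] - r[1] * t1[3],
          r[1] * t1[2] - r[2] * t1[1])
  cbind(t1, t2, r)
}

#' Generate a phantom organoid dataset
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `labels`, `channels` (list of per-channel
#'   `voxel_image`s), `labels_b`, `channels_b` (second view), `transform_ab`
#'   (true rigid transform mapping view-A physical coordinates to view-B),
#'   `truth` (per-nucleus data.frame: centroid, semi-axes, major axis,
#'   brightness, marker and mitotic flags, distance to border), `mask` /
#'   `mask_b` (binary sample masks), `achieved_fraction`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  sp <- spec$voxel_spacing
  R <- spec$organoid_radius
  ext <- 2 * (R + spec$margin_um)
  d <- as.integer(floor(ext / sp)) + 1L
  centre <- (d - 1) * sp / 2
  coords <- list(z = axis_coords(d[1], sp[1]), y = axis_coords(d[2], sp[2]),
                 x = axis_coords(d[3], sp[3]))
  r2 <- outer(outer((coords$z - centre[1])^2, (coords$y - centre[2])^2, `+`),
              (coords$x - centre[3])^2, `+`)
  mask <- array(r2 <= R^2, d)
  mask_n <- sum(mask)

  labels <- array(0L, d)
  cent <- list(); axes <- list(); frames <- list()
  placed_vox <- 0L
  attempts <- 0L
  rng_ax <- spec$nuclei_axis_ratio_range
  step_R <- spec$step_radius_frac * R
  sample_semi <- function() sort(spec$nuclei_mean_radius *
                                   stats::runif(3, rng_ax[1], rng_ax[2]),
                                 decreasing = TRUE)
  place <- function(c_um, semi, Q) {
    vx <- rasterize_ellipsoid(c_um, semi, Q, coords, d)
    if (length(vx) < 4 || any(labels[vx] != 0L) || any(!mask[vx]))
      return(FALSE)
    lab <- length(cent) + 1L
    labels[vx] <<- lab
    cent[[lab]] <<- c_um
    axes[[lab]] <<- semi
    frames[[lab]] <<- Q
    placed_vox <<- placed_vox + length(vx)
    TRUE
  }
  # phase 1: dense tangential wall layer -- aggregates present a packed
  # outer cell layer, and without it no mask recipe could recover the
  # sample boundary from the nuclei channel
  wall_attempts <- if (isTRUE(spec$wall_layer))
    min(5000L, spec$max_attempts %/% 4L) else 0L
  for (i in seq_len(wall_attempts)) {
    if (placed_vox / mask_n >= spec$target_volume_fraction) break
    attempts <- attempts + 1L
    semi <- sample_semi()
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    rad <- R - semi[3]
    c_um <- centre + rad * dir
    if (spec$compartment_ratio != 1 && rad > step_R &&
        stats::runif(1) > 1 / spec$compartment_ratio) next
    place(c_um, semi, tangential_frame(rad * dir))
  }
  # phase 2: bulk rejection-sampling packing
  while (placed_vox / mask_n < spec$target_volume_fraction &&
         attempts < spec$max_attempts) {
    attempts <- attempts + 1L
    semi <- sample_semi()
    # uniform position in the sphere, with margin for the smallest axis only
    # (a tangentially oriented nucleus can sit that close to the border; the
    # containment check below rejects orientations that cross it)
    rad <- (R - semi[3]) * stats::runif(1)^(1 / 3)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    c_um <- centre + rad * dir
    if (spec$compartment_ratio != 1 && rad > step_R &&
        stats::runif(1) > 1 / spec$compartment_ratio) next
    # nuclei in wall contact orient tangentially (as surface cells do, and
    # as needed to fit); interior nuclei follow the requested orientation
    Q <- if (spec$orientation == "tangential" || rad + semi[1] > R)
      tangential_frame(c_um - centre) else random_rotation()
    place(c_um, semi, Q)
  }
  achieved <- placed_vox / mask_n
  if (achieved < spec$target_volume_fraction)
    warning(sprintf(
      "packing stopped at volume fraction %.3f (target %.3f) after %d attempts",
      achieved, spec$target_volume_fraction, spec$max_attempts))
  n <- length(cent)
  if (n == 0) stop("no nucleus could be placed; check the spec")
  cents <- do.call(rbind, cent)
  semis <- do.call(rbind, axes)

  # per-nucleus classes and brightness
  dist_border <- R - sqrt(rowSums(sweep(cents, 2, centre)^2))
  p_surface <- exp(-dist_border / spec$marker_lengths[1])
  p_interior <- 1 - exp(-dist_border / spec$marker_lengths[2])
  nf <- nrow(spec$mixing_matrix)
  marker2 <- stats::runif(n) < p_surface
  marker3 <- stats::runif(n) < p_interior
  mitotic <- stats::runif(n) < spec$mitotic_prob
  bright <- matrix(0, n, nf)
  on_flags <- cbind(rep(TRUE, n), marker2, marker3, mitotic)
  for (i in seq_len(nf)) {
    on <- if (i <= 4) on_flags[, i] else rep(TRUE, n)
    bright[on, i] <- stats::rlnorm(sum(on), 0, spec$brightness_sdlog)
  }

  channels <- render_channels(labels, bright, spec$mixing_matrix,
                              spec$decay_lengths, sp, spec$noise_sd)

  # view B: transform geometry, re-rasterize, re-apply decay from other face
  flip <- rigid_flip_x(centre = centre)
  resid <- rigid_transform(euler_zyx(spec$residual_rotation_deg),
                           translation = spec$residual_translation_um,
                           centre = centre)
  T_ab <- compose_rigid(resid, flip)
  cents_b <- transform_points(T_ab, cents)
  Rtot <- as_affine(T_ab)[1:3, 1:3]
  labels_b <- array(0L, d)
  for (i in seq_len(n)) {
    vx <- rasterize_ellipsoid(cents_b[i, ], semis[i, ], Rtot %*% frames[[i]],
                              coords, d)
    labels_b[vx] <- i
  }
  channels_b <- render_channels(labels_b, bright, spec$mixing_matrix,
                                spec$decay_lengths, sp, spec$noise_sd)
  r2b <- outer(outer((coords$z - centre[1])^2, (coords$y - centre[2])^2, `+`),
               (coords$x - centre[3])^2, `+`)
  maj <- t(vapply(seq_len(n), function(i) frames[[i]][, 1], numeric(3)))

  truth <- data.frame(label = seq_len(n),
                      cz = cents[, 1], cy = cents[, 2], cx = cents[, 3],
                      L1 = semis[, 1], L2 = semis[, 2], L3 = semis[, 3],
                      major_z = maj[, 1], major_y = maj[, 2],
                      major_x = maj[, 3],
                      dist_border = dist_border,
                      marker2 = marker2, marker3 = marker3, mitotic = mitotic)
  for (i in seq_len(nf)) truth[[paste0("brightness", i)]] <- bright[, i]

  list(labels = labels3d(labels, sp), channels = channels,
       labels_b = labels3d(labels_b, sp), channels_b = channels_b,
       transform_ab = T_ab, truth = truth,
       mask = array(mask, d), mask_b = array(r2b <= R^2, d),
       achieved_fraction = achieved, centre = centre, spec = spec)
}

# linear voxel indices inside an ellipsoid (centre um, semi-axes um, frame Q
# with axes as columns)
rasterize_ellipsoid <- function(c_um, semi, Q, coords, d) {
  rmax <- max(semi)
  rng <- lapply(1:3, function(ax) {
    which(coords[[ax]] >= c_um[ax] - rmax & coords[[ax]] <= c_um[ax] + rmax)
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
  p <- cbind(coords$z[g$z], coords$y[g$y], coords$x[g$x])
  rel <- sweep(p, 2, c_um)
  loc <- rel %*% Q  # components along the ellipsoid axes
  inside <- (loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
    (loc[, 3] / semi[3])^2 <= 1
  idx <- as.matrix(g[inside, , drop = FALSE])
  idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
}

render_channels <- function(labels, bright, mix, decays, sp, noise_sd) {
  d <- dim(labels)
  nf <- nrow(mix)
  m <- ncol(mix)
  pos <- labels > 0L
  labv <- labels[pos]
  fluor <- lapply(seq_len(nf), function(i) {
    a <- array(0, d)
    a[pos] <- bright[labv, i]
    a
  })
  z_decay <- function(k) exp(-axis_coords(d[1], sp[1]) / decays[k])
  out <- vector("list", m)
  for (k in seq_len(m)) {
    ch <- array(0, d)
    for (i in seq_len(nf)) if (mix[i, k] > 0) ch <- ch + mix[i, k] * fluor[[i]]
    dk <- if (is.finite(decays[k])) z_decay(k) else rep(1, d[1])
    ch <- ch * array(rep(dk, times = d[2] * d[3]), d)
    if (noise_sd > 0) ch <- ch + array(stats::rnorm(length(ch), 0, noise_sd), d)
    out[[k]] <- vox(ch, sp, channel = paste0("ch", k))
  }
  out
}

#' Render single-fluorophore calibration stacks from a phantom
#'
#' Emulates calibration acquisitions of samples stained with one fluorophore
#' species only: the phantom's geometry is kept, every nucleus is given the
#' (ubiquitous) fluorophore-1 brightness, and channels are rendered through
#' the mixing matrix row of the requested fluorophore with the usual decay
#' and noise.
#'
#' @param ph a generated phantom (list from [generate_phantom()]).
#' @param fluors fluorophore indices to render (default: all).
#' @return list (per fluorophore) of lists of channel `voxel_image`s.
#' @export
single_fluor_stacks <- function(ph, fluors = NULL) {
  spec <- ph$spec
  nf <- nrow(spec$mixing_matrix)
  if (is.null(fluors)) fluors <- seq_len(nf)
  n <- nrow(ph$truth)
  with_seed(spec$seed + 1000L, lapply(fluors, function(i) {
    b <- matrix(0, n, nf)
    b[, i] <- ph$truth$brightness1
    render_channels(unclass_arr_int(ph$labels), b, spec$mixing_matrix,
                    spec$decay_lengths, spec$voxel_spacing, spec$noise_sd)
  }))
}

unclass_arr_int <- function(x) {
  x <- as_array3d(x)
  attributes(x) <- list(dim = dim(x))
  x
}

#' Write a phantom dataset to disk
#'
#' Channel stacks are written as one TIFF per channel and view (ZYX planes,
#' 32-bit float), labels as 16-bit TIFF, the ground-truth table as CSV, and
#' the spec plus true transform as JSON.
#'
#' @param ph phantom from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(ph$channels)) {
    write_stack(ph$channels[[k]], file.path(dir, sprintf("viewA_ch%02d.tif", k)))
    write_stack(ph$channels_b[[k]], file.path(dir, sprintf("viewB_ch%02d.tif", k)))
  }
  write_stack(ph$labels, file.path(dir, "viewA_labels.tif"))
  write_stack(ph$labels_b, file.path(dir, "viewB_labels.tif"))
  utils::write.csv(ph$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_rigid_json(ph$transform_ab, file.path(dir, "transform_ab.json"))
  sp <- ph$spec
  sp$mixing_matrix <- as.matrix(sp$mixing_matrix)
  jsonlite::write_json(unclass(sp), file.path(dir, "phantom_spec.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
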