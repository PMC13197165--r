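#' Nuclear shape: inertia tensors, equivalent ellipsoids, true strain
#'
#' Each segmented object is summarised by the inertia tensor of its voxel
#' positions about its centroid (in physical um coordinates),
#' `I_ij = sum_k (delta_ij r_k^2 - r_ki r_kj)`. Its eigenvectors are the
#' principal axes; for a uniform ellipsoid the semi-axis lengths follow from
#' the principal moments as `L_i^2 = (5 / 2N) (I1 + I2 + I3 - 2 I_i)`. The
#' true strain tensor `T = V diag(T_i) V'` with
#' `T_i = (1/3) log(L_i^3 / (L1 L2 L3))` is a trace-free, size-independent
#' measure of the deviation of the principal lengths from the equal-volume
#' sphere, which makes it suitable for averaging across objects of different
#' sizes.
#'
#' @name morphometrics
NULL

#' Per-object morphometrics from a label image
#'
#' Computes, for every label: voxel count, centroid, inertia tensor,
#' principal moments/axes, equivalent-ellipsoid semi-axes (sorted
#' descending), true-strain eigenvalues and major axis. Degenerate objects
#' (fewer than 4 voxels, coplanar, or with a non-positive semi-axis bracket)
#' are flagged and get `NA` shape entries.
#'
#' @param labels `label_image`.
#' @param degeneracy_gap eigenvalue gap `T1 - T2` under which the major axis
#'   is considered unstable (flagged in `axis_stable`).
#' @return data.frame (one row per label) with columns `label`, `n_voxels`,
#'   `cz`, `cy`, `cx`, `volume`, `L1`..`L3`, `T1`..`T3`, major-axis
#'   components `major_z/y/x`, `degenerate`, `axis_stable`; the full strain
#'   tensors (n x 6: zz, yy, xx, zy, zx, yx) in attribute `strain_tensors`.
#' @export
morphometry_table <- function(labels, degeneracy_gap = 0.02) {
  st <- label_stats(labels)
  sp <- vox_spacing(labels)
  n <- length(st$ids)
  out <- data.frame(label = st$ids, n_voxels = st$counts,
                    cz = st$centroids[, 1], cy = st$centroids[, 2],
                    cx = st$centroids[, 3],
                    volume = st$counts * voxel_volume(labels),
                    L1 = NA_real_, L2 = NA_real_, L3 = NA_real_,
                    T1 = NA_real_, T2 = NA_real_, T3 = NA_real_,
                    major_z = NA_real_, major_y = NA_real_,
                    major_x = NA_real_,
                    degenerate = FALSE, axis_stable = TRUE)
  tens <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("zz", "yy", "xx", "zy", "zx", "yx")))
  dims <- dim(labels)
  for (j in seq_len(n)) {
    ai <- arrayInd(st$index[[j]], dims)
    r <- index_to_um(ai, sp)
    it <- inertia_tensor(r)
    if (it$degenerate) { out$degenerate[j] <- TRUE; next }
    sa <- semi_axes(it$tensor, nrow(r))
    if (is.null(sa)) { out$degenerate[j] <- TRUE; next }
    ts <- true_strain(sa$lengths, sa$axes)
    out[j, c("L1", "L2", "L3")] <- sa$lengths
    out[j, c("T1", "T2", "T3")] <- ts$eigenvalues
    out[j, c("major_z", "major_y", "major_x")] <- ts$major_axis
    out$axis_stable[j] <- (ts$eigenvalues[1] - ts$eigenvalues[2]) >=
      degeneracy_gap
    Tm <- ts$tensor
    tens[j, ] <- c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[1, 3], Tm[2, 3])
  }
  attr(out, "strain_tensors") <- tens
  out
}

#' @describeIn morphometrics Inertia tensor of a set of physical positions
#'   (n x 3 um matrix) about their centroid: a list with `tensor`, `moments`
#'   (ascending), `axes` (columns, matching `moments`) and `degenerate`
#'   (`TRUE` for sets of fewer than 4 or coplanar points, whose
#'   equivalent-ellipsoid fit is undefined although the tensor itself is
#'   still well defined).
#' @param positions n x 3 matrix of voxel positions in um.
#' @export
inertia_tensor <- function(positions) {
  p <- as.matrix(positions)
  r <- sweep(p, 2, colMeans(p))
  cov_ <- crossprod(r)           # sum r_i r_j
  I <- diag(sum(diag(cov_)), 3) - cov_
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  degenerate <- nrow(p) < 4 ||
    min(eigen(cov_, symmetric = TRUE, only.values = TRUE)$values) <
      1e-9 * max(diag(cov_))     # coplanar / collinear
  list(tensor = I, moments = e$values[ord],
       axes = e$vectors[, ord, drop = FALSE], degenerate = degenerate)
}

#' @describeIn morphometrics Equivalent-ellipsoid semi-axes (um, sorted
#'   descending) with their axes, from an inertia tensor and voxel count.
#'   Returns `NULL` when a bracket `I1 + I2 + I3 - 2 I_i` is non-positive.
#' @param tensor 3x3 inertia tensor.
#' @param n_voxels number of voxels the tensor was computed from.
#' @export
semi_axes <- function(tensor, n_voxels) {
  e <- eigen(tensor, symmetric = TRUE)
  tr <- sum(e$values)
  br <- tr - 2 * e$values
  if (any(br <= 0)) return(NULL)
  L <- sqrt(5 / (2 * n_voxels) * br)
  ord <- order(L, decreasing = TRUE)
  list(lengths = L[ord], axes = e$vectors[, ord, drop = FALSE])
}

#' @describeIn morphometrics True strain tensor from semi-axes and their
#'   axes: `T_i = (1/3) log(L_i^3 / (L1 L2 L3))`, reassembled as
#'   `V diag(T_i) V'`. Trace-free by construction; the major axis is the
#'   eigenvector of the largest `T_i`, reported with a sign convention
#'   (largest-magnitude component positive) since nuclear axes are
#'   directionless.
#' @param lengths semi-axes (um), any order; must be > 0.
#' @param axes 3x3 matrix with the matching axes as columns.
#' @export
true_strain <- function(lengths, axes = diag(3)) {
  if (any(lengths <= 0)) stop("semi-axes must be positive")
  Ti <- log(lengths^3 / prod(lengths)) / 3
  Tm <- axes %*% diag(Ti) %*% t(axes)
  ord <- order(Ti, decreasing = TRUE)
  major <- axes[, ord[1]]
  if (major[which.max(abs(major))] < 0) major <- -major
  list(tensor = Tm, eigenvalues = Ti[ord], major_axis = major)
}

#' Tissue-scale strain field from per-nucleus tensors
#'
#' Component-wise sparse Gaussian averaging of the per-nucleus true-strain
#' tensors, with the major axis of the averaged tensor extracted at each
#' query point. Averaging the size-independent true strain (rather than the
#' inertia tensor) avoids over-weighting large nuclei.
#'
#' @param morpho data.frame from [morphometry_table()] (rows with
#'   `degenerate == TRUE` are dropped).
#' @param sigma averaging scale, um.
#' @param output as in [smooth_sparse()]: `"positions"`, a query matrix, or a
#'   mask image for dense evaluation.
#' @return for sparse outputs, a list with `positions`, `tensors` (n x 6),
#'   `eigenvalues` (n x 3, descending), `major_axes` (n x 3); for dense
#'   output, a list of six component images plus `major_axes` at mask voxels.
#' @export
strain_field <- function(morpho, sigma, output = "positions") {
  keep <- !morpho$degenerate
  tens <- attr(morpho, "strain_tensors")[keep, , drop = FALSE]
  pos <- as.matrix(morpho[keep, c("cz", "cy", "cx")])
  sf <- sparse_field(pos, tens)
  sm <- smooth_sparse(sf, sigma, output = output)
  if (inherits(sm, "sparse_field")) {
    vals <- sm$values
    n <- nrow(vals)
    eig <- matrix(NA_real_, n, 3)
    maj <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      if (anyNA(vals[i, ])) next
      Tm <- tensor_from6(vals[i, ])
      e <- eigen(Tm, symmetric = TRUE)   # values in decreasing order
      eig[i, ] <- e$values
      v <- e$vectors[, 1]
      if (v[which.max(abs(v))] < 0) v <- -v
      maj[i, ] <- v
    }
    return(list(positions = sm$positions, tensors = vals,
                eigenvalues = eig, major_axes = maj))
  }
  sm  # list of component images (dense case)
}

tensor_from6 <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Squared-cosine alignment between axes and a reference direction
#'
#' `cos^2` of the angle between each (directionless) axis and a gradient
#' vector: 1 for parallel, 0 for perpendicular, and mean 1/3 for
#' isotropically random axes.
#'
#' @param axes n x 3 matrix of axis vectors (need not be unit length).
#' @param gradients length-3 vector or n x 3 matrix of reference directions.
#' @return numeric vector of `cos^2` values; `NA` where either vector is
#'   (near) zero.
#' @export
axis_alignment <- function(axes, gradients) {
  a <- as.matrix(axes)
  g <- if (is.null(dim(gradients)))
    matrix(gradients, nrow(a), 3, byrow = TRUE) else as.matrix(gradients)
  num <- rowSums(a * g)^2
  den <- rowSums(a^2) * rowSums(g^2)
  out <- num / den
  out[den <= 0 | !is.finite(den)] <- NA_real_
  out
}

#' Tissue-scale alignment field of nuclear deformation vs density gradient
#'
#' For each nucleus, the squared cosine of the angle between its true-strain
#' major axis and the local cell-density gradient (central differences in um
#' on the sigma-smoothed density field) is computed; the scalar values are
#' then sparse-smoothed at the same sigma. Values near 1 mean deformation
#' parallel to the density gradient, near 0 perpendicular (tangential to
#' density contours); isotropic orientations average 1/3. Companion outputs
#' carry the gradient norm and strain magnitude for perspective.
#'
#' @param morpho data.frame from [morphometry_table()].
#' @param density_field `voxel_image` of cell density, smoothed at `sigma`.
#' @param sigma averaging scale, um.
#' @param output as in [smooth_sparse()].
#' @param min_gradient nuclei with gradient norm below this (um^-4) are
#'   excluded (zero-gradient regions); the count is reported.
#' @param use_stable_only exclude nuclei with degenerate or unstable major
#'   axes.
#' @return list with `field` (sparse_field or image of smoothed cos^2),
#'   `per_nucleus` data.frame (label, cos2, gradient norm, strain magnitude),
#'   and `n_excluded`.
#' @export
alignment_field <- function(morpho, density_field, sigma,
                            output = "positions", min_gradient = 0,
                            use_stable_only = TRUE) {
  keep <- !morpho$degenerate
  if (use_stable_only) keep <- keep & morpho$axis_stable
  mm <- morpho[keep, , drop = FALSE]
  grad <- gradient_at(density_field, as.matrix(mm[, c("cz", "cy", "cx")]))
  gnorm <- sqrt(rowSums(grad^2))
  cos2 <- axis_alignment(as.matrix(mm[, c("major_z", "major_y", "major_x")]),
                         grad)
  ok <- is.finite(cos2) & gnorm > min_gradient
  per <- data.frame(label = mm$label, cos2 = cos2, gradient_norm = gnorm,
                    strain_magnitude = mm$T1)
  sf <- sparse_field(as.matrix(mm[ok, c("cz", "cy", "cx")]),
                     cbind(cos2[ok], gnorm[ok], abs(mm$T1[ok])))
  sm <- smooth_sparse(sf, sigma, output = output)
  field <- if (inherits(sm, "sparse_field"))
    list(positions = sm$positions, cos2 = sm$values[, 1],
         gradient_norm = sm$values[, 2], strain_magnitude = sm$values[, 3])
  else list(cos2 = sm[[1]], gradient_norm = sm[[2]], strain_magnitude = sm[[3]])
  list(field = field, per_nucleus = per, n_excluded = sum(!ok))
}

# central-difference gradient of a field, sampled at physical positions (um)
gradient_at <- function(field, positions) {
  arr <- unclass_arr(field)
  sp <- vox_spacing(field)
  d <- dim(arr)
  idx <- round(um_to_index(as.matrix(positions), sp))
  idx <- pmin(pmax(idx, 2), matrix(d - 1L, nrow(idx), 3, byrow = TRUE))
  g <- matrix(NA_real_, nrow(idx), 3)
  for (ax in 1:3) {
    up <- idx; up[, ax] <- up[, ax] + 1L
    dn <- idx; dn[, ax] <- dn[, ax] - 1L
    g[, ax] <- (arr[up] - arr[dn]) / (2 * sp[ax])
  }
  g
}
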