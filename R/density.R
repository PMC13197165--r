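#' Multiscale object-abundance fields
#'
#' Local abundance of segmented objects (nuclei, mitotic nuclei,
#' marker-positive cells) is described by three complementary fields, all
#' obtained by Gaussian coarse-graining at a chosen scale sigma:
#' the density (objects per um^3, from unit impulses at centroids), the volume
#' fraction (smoothed binary object mask, in [0, 1]) and the map of object
#' volumes (sparse average of per-object volumes). Division density divided by
#' cell density yields the local proliferation probability.
#'
#' @name density_fields
NULL

# per-label voxel counts, centroids (um) and linear-index lists
label_stats <- function(labels) {
  arr <- unclass_arr_int(labels)
  sp <- vox_spacing(labels)
  pos <- which(arr > 0L)
  if (!length(pos))
    return(list(ids = integer(0), counts = integer(0),
                centroids = matrix(0, 0, 3), index = list()))
  labv <- arr[pos]
  ids <- sort(unique(labv))
  counts <- tabulate(labv)[ids]
  ai <- arrayInd(pos, dim(arr))
  um <- index_to_um(ai, sp)
  cz <- rowsum(um[, 1], labv)[, 1] / counts
  cy <- rowsum(um[, 2], labv)[, 1] / counts
  cx <- rowsum(um[, 3], labv)[, 1] / counts
  list(ids = ids, counts = counts,
       centroids = cbind(z = cz, y = cy, x = cx),
       index = split(pos, labv))
}

#' Object centroids, volumes and classes from a label image
#'
#' @param labels `label_image`.
#' @return data.frame with `label`, centroid columns `cz`, `cy`, `cx` (um)
#'   and `volume` (um^3).
#' @export
object_table <- function(labels) {
  st <- label_stats(labels)
  data.frame(label = st$ids,
             cz = st$centroids[, 1], cy = st$centroids[, 2],
             cx = st$centroids[, 3],
             volume = st$counts * voxel_volume(labels))
}

# unit impulses at centroids (counts per voxel)
impulse_image <- function(centroids, template) {
  arr <- array(0, dim(template))
  if (nrow(centroids)) {
    idx <- round(um_to_index(as.matrix(centroids), vox_spacing(template)))
    idx <- pmin(pmax(idx, 1), matrix(dim(template), nrow(idx), 3, byrow = TRUE))
    lin <- idx[, 1] + (idx[, 2] - 1) * dim(template)[1] +
      (idx[, 3] - 1) * dim(template)[1] * dim(template)[2]
    for (l in lin) arr[l] <- arr[l] + 1
  }
  arr
}

#' @describeIn density_fields Object density in objects per um^3: unit
#'   impulses at centroids, mask-corrected smoothing at `sigma`, divided by
#'   the voxel volume.
#' @param objects `label_image`, or a data.frame with centroid columns
#'   `cz`, `cy`, `cx` (um) as from [object_table()].
#' @param sigma coarse-graining scale, um.
#' @param sample_mask binary inside-sample mask (`NULL` = everywhere).
#' @param template `voxel_image`/`label_image` defining the grid when
#'   `objects` is a data.frame.
#' @return `voxel_image` (NA where invalid).
#' @export
density_field <- function(objects, sigma, sample_mask = NULL,
                          template = NULL) {
  if (inherits(objects, "label_image")) {
    template <- objects
    cents <- object_table(objects)[, c("cz", "cy", "cx")]
  } else {
    if (is.null(template)) stop("need a template grid for centroid tables")
    cents <- objects[, c("cz", "cy", "cx")]
  }
  if (nrow(cents) == 0) {
    warning("no objects: density field is zero")
    out <- array(0, dim(template))
    if (!is.null(sample_mask)) out[unclass_arr(sample_mask) == 0] <- NA_real_
    return(vox(out, vox_spacing(template)))
  }
  imp <- vox(impulse_image(cents, template), vox_spacing(template))
  sm <- if (is.null(sample_mask)) smooth_dense(imp, sigma) else
    smooth_masked(imp, sample_mask, sigma)
  vox_like(unclass_arr(sm) / voxel_volume(template), sm)
}

#' @describeIn density_fields Volume fraction in [0, 1]: mask-corrected
#'   smoothing of the binarized label image.
#' @param labels `label_image` of the target objects.
#' @export
volume_fraction_field <- function(labels, sigma, sample_mask = NULL) {
  bin <- vox((unclass_arr_int(labels) > 0L) * 1, vox_spacing(labels))
  if (is.null(sample_mask)) smooth_dense(bin, sigma) else
    smooth_masked(bin, sample_mask, sigma)
}

#' @describeIn density_fields Map of object volumes (um^3): per-object
#'   volumes at centroids, sparse-averaged (values are averaged, not summed)
#'   and evaluated densely over the sample mask.
#' @export
volume_map_field <- function(objects, sigma, sample_mask = NULL,
                             template = NULL) {
  if (inherits(objects, "label_image")) {
    template <- objects
    objects <- object_table(objects)
  }
  if (is.null(template)) stop("need a template grid for centroid tables")
  sf <- sparse_field(as.matrix(objects[, c("cz", "cy", "cx")]),
                     objects$volume)
  mask <- if (is.null(sample_mask)) array(1, dim(template)) else sample_mask
  smooth_sparse(sf, sigma,
                output = vox((unclass_arr(mask) != 0) * 1,
                             vox_spacing(template)))
}

#' @describeIn density_fields Proliferation probability: division density
#'   divided by cell density, pointwise on valid voxels (both fields must
#'   share grid and sigma). Near-zero cell density is flagged `NA`.
#' @param division_density,cell_density `voxel_image`s from
#'   [density_field()] at the same sigma.
#' @param eps relative floor under which cell density is treated as zero.
#' @export
proliferation_field <- function(division_density, cell_density, eps = 1e-12) {
  if (!all(dim(division_density) == dim(cell_density)))
    stop("fields must share a grid")
  cd <- unclass_arr(cell_density)
  dd <- unclass_arr(division_density)
  floor_ <- eps * max(cd, na.rm = TRUE)
  out <- dd / cd
  out[!is.na(cd) & cd <= floor_] <- NA_real_
  vox_like(out, cell_density)
}

#' Filter detections by volume and position
#'
#' Removes objects smaller than `min_volume` (spurious detections) or whose
#' centroid falls outside the sample mask (background or dead-cell events),
#' then relabels the survivors contiguously in ascending original order.
#'
#' @param labels `label_image`.
#' @param min_volume minimum object volume in um^3.
#' @param sample_mask optional binary inside-sample mask.
#' @return filtered `label_image`; attribute `removed` lists the dropped
#'   original labels.
#' @export
filter_detections <- function(labels, min_volume = 0, sample_mask = NULL) {
  st <- label_stats(labels)
  keep <- st$counts * voxel_volume(labels) >= min_volume
  if (!is.null(sample_mask)) {
    m <- unclass_arr(sample_mask) != 0
    idx <- round(um_to_index(st$centroids, vox_spacing(labels)))
    idx <- pmin(pmax(idx, 1), matrix(dim(labels), nrow(idx), 3, byrow = TRUE))
    inside <- m[idx]
    keep <- keep & inside
  }
  arr <- unclass_arr_int(labels)
  map <- integer(max(st$ids, 0L) + 1L)  # old label + 1 -> new label
  map[st$ids[keep] + 1L] <- seq_len(sum(keep))
  pos <- which(arr > 0L)
  arr[pos] <- map[arr[pos] + 1L]
  out <- labels3d(arr, vox_spacing(labels))
  attr(out, "removed") <- st$ids[!keep]
  out
}

#' Inside-sample mask from the ubiquitous nuclei channel
#'
#' Recipe: light Gaussian denoising (1 um), Otsu threshold to segment the
#' bright nuclei, morphological closing at about two nucleus radii to bridge
#' the internuclear gaps, 3D hole filling, largest connected component. The
#' threshold acts on the compact bright nuclei themselves (robust to the
#' depth decay of the absolute intensity), and the closing makes the mask hug
#' the outer nuclear surface. If several disjoint samples are present only
#' the largest is returned and the count is reported.
#'
#' @param nuclei_image `voxel_image` of the nuclei channel.
#' @param nucleus_radius typical nucleus radius in um (closing scale).
#' @param denoise_sigma pre-threshold Gaussian blur in um.
#' @param border_allowance final outward dilation in um, compensating the
#'   thin cytoplasmic rim beyond the outermost nuclear surfaces and the
#'   erosion of dim nuclear edges by the threshold.
#' @return logical array (sample mask) with attribute `n_components`.
#' @export
sample_mask_from_nuclei <- function(nuclei_image, nucleus_radius = 5,
                                    denoise_sigma = 1,
                                    border_allowance = 1.5) {
  sm <- smooth_dense(nuclei_image, denoise_sigma)
  v <- as.vector(unclass_arr(sm))
  if (max(v) <= min(v)) {
    warning("blank nuclei image: empty sample mask")
    out <- array(FALSE, dim(nuclei_image))
    attr(out, "n_components") <- 0L
    return(out)
  }
  thr <- otsu_threshold(v)
  m <- unclass_arr(sm) > thr
  sp <- vox_spacing(nuclei_image)
  m <- binary_closing(m, 2 * nucleus_radius, sp)
  m <- fill_holes3d(m)
  cc <- connected_components3d(m)
  ncomp <- max(cc)
  if (ncomp > 1) {
    sizes <- tabulate(cc[cc > 0])
    message(sprintf("%d disjoint components; keeping the largest", ncomp))
    m <- cc == which.max(sizes)
  }
  if (border_allowance > 0)
    m <- edt3d_sq(m, sp) <= border_allowance^2
  attr(m, "n_components") <- as.integer(max(ncomp, 0L))
  m
}

#' Anisotropic Euclidean distance transforms
#'
#' Exact squared Euclidean distance transform (separable lower-envelope
#' algorithm) honouring the physical voxel spacing.
#'
#' @param mask logical/binary 3D array.
#' @param spacing voxel spacing in um (z, y, x).
#' @return array of distances in um from each `TRUE` voxel to the nearest
#'   `FALSE` voxel (`distance_to_border`: 0 outside the mask).
#' @export
distance_to_border <- function(mask, spacing = NULL) {
  sp <- if (is.null(spacing)) vox_spacing(mask) else as.numeric(spacing)
  m <- unclass_arr(mask) != 0
  d2 <- edt3d_sq(!m, sp)  # distance from each voxel to nearest outside voxel
  out <- sqrt(d2)
  out[!m] <- 0
  out
}

# squared EDT to the nearest TRUE voxel of `seed`
edt3d_sq <- function(seed, sp) {
  d <- dim(seed)
  INF <- sum((d * sp)^2) * 4 + 1
  f <- array(ifelse(seed, 0, INF), d)
  for (ax in 1:3) {
    step <- sp[ax]
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(f, perm)
    da <- dim(a)
    mat <- matrix(a, nrow = da[1])
    for (j in seq_len(ncol(mat))) mat[, j] <- edt1d_sq(mat[, j], step)
    f <- aperm(array(mat, da), order(perm))
  }
  f
}

# 1D squared distance transform (lower envelope of parabolas), grid step h
edt1d_sq <- function(f, h) {
  n <- length(f)
  if (all(!is.finite(f)) || n == 1L) return(f)
  v <- integer(n); zlo <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  zlo[1L] <- -Inf; zlo[2L] <- Inf
  x <- (seq_len(n) - 1) * h
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= zlo[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    zlo[k] <- s
    zlo[k + 1L] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (zlo[k + 1L] < x[q]) k <- k + 1L
    p <- v[k]
    out[q] <- (x[q] - x[p])^2 + f[p]
  }
  out
}

# morphological closing via two distance transforms (radius um)
binary_closing <- function(m, radius, sp) {
  dil <- edt3d_sq(m, sp) <= radius^2
  !(edt3d_sq(!dil, sp) <= radius^2)
}

# fill 3D holes: background connected to the border stays background
fill_holes3d <- function(m) {
  d <- dim(m)
  bg <- !m
  seed <- array(FALSE, d)
  seed[c(1, d[1]), , ] <- TRUE
  seed[, c(1, d[2]), ] <- TRUE
  seed[, , c(1, d[3])] <- TRUE
  seed <- seed & bg
  reach <- flood6(seed, bg)
  m | (bg & !reach)
}

# 6-connected flood fill of `domain` from `seed` by frontier dilation
flood6 <- function(seed, domain) {
  d <- dim(seed)
  reach <- seed & domain
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & domain
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# 6-connected component labelling by repeated flood fill
connected_components3d <- function(m) {
  d <- dim(m)
  cc <- array(0L, d)
  remaining <- m
  lab <- 0L
  while (any(remaining)) {
    lab <- lab + 1L
    seed <- array(FALSE, d)
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood6(seed, remaining)
    cc[comp] <- lab
    remaining <- remaining & !comp
  }
  cc
}
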