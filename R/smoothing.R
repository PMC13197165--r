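#' Gaussian coarse-graining of dense, masked and sparse 3D signals
#'
#' Tissue-scale fields are obtained by convolving voxel-scale signals with a
#' normalized Gaussian kernel of physical size `sigma` (um). Three variants
#' cover the data types met in practice:
#'
#' * [smooth_dense()] - plain truncated Gaussian convolution,
#' * [smooth_masked()] - mask-corrected convolution that divides by the
#'   smoothed mask, preventing the artifactual decay of the signal near mask
#'   boundaries and allowing evaluation outside the signal's own support,
#' * [smooth_sparse()] - the masked formulation specialised to values defined
#'   only at scattered positions (e.g. per-nucleus quantities at centroids),
#'   using a spatial bucket index to find in-range neighbours.
#'
#' The kernel is truncated at `a = a_factor * sigma` (default 3 sigma) and
#' renormalized to unit sum so constant signals are preserved exactly.
#' Anisotropic voxel spacing is handled by expressing the kernel in physical
#' coordinates.
#'
#' @name smoothing
NULL

# per-axis truncated, normalized 1D kernels for a physical sigma (um)
gauss_kernels <- function(sigma, spacing, a_factor = 3) {
  a <- a_factor * sigma
  lapply(seq_len(3), function(i) {
    h <- floor(a / spacing[i])
    off <- (-h):h
    k <- exp(-(off * spacing[i])^2 / (2 * sigma^2))
    k / sum(k)
  })
}

# convolve along one axis with zero padding outside the array
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  n <- d[axis]
  h <- (length(kern) - 1L) %/% 2L
  if (h == 0L) return(arr * kern[1L])
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in (-h):h) {
    j <- idx - o
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- kern[o + h + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  out <- K %*% matrix(a, nrow = n)
  aperm(array(out, dim = d[perm]), order(perm))
}

conv_separable <- function(arr, kernels) {
  for (ax in 1:3) arr <- conv_axis(arr, kernels[[ax]], ax)
  arr
}

#' Dense Gaussian smoothing at a physical scale
#'
#' @param image `voxel_image` or 3D array.
#' @param sigma smoothing scale in um.
#' @param a_factor kernel truncation radius in units of sigma (>= 2).
#' @param spacing voxel spacing override (um, z/y/x); defaults to the image's.
#' @return smoothed `voxel_image`. Voxels outside the array are treated as 0.
#'   If `sigma` is below half the smallest voxel edge the input is returned
#'   unchanged with a warning.
#' @seealso [smooth_masked()], [smooth_sparse()]
#' @export
smooth_dense <- function(image, sigma, a_factor = 3, spacing = NULL) {
  spacing <- if (is.null(spacing)) vox_spacing(image) else as.numeric(spacing)
  stopifnot(sigma > 0, a_factor >= 2)
  if (sigma < 0.5 * min(spacing)) {
    warning("sigma below half a voxel; returning input unchanged")
    return(vox(unclass_arr(image), spacing))
  }
  ker <- gauss_kernels(sigma, spacing, a_factor)
  num <- conv_separable(unclass_arr(image), ker)
  # renormalize by the in-image kernel mass so truncation at the array
  # borders cannot dim the signal (constants are preserved exactly)
  den <- conv_separable(array(1, dim(image)), ker)
  vox(num / den, spacing)
}

#' Mask-corrected Gaussian smoothing
#'
#' Computes `(k * (I M)) / (k * M)` for a binary mask `M`: the Gaussian mean
#' of the signal over mask voxels only. Valid wherever the denominator exceeds
#' a small fraction of the kernel peak; elsewhere the output is `NA`.
#'
#' @inheritParams smooth_dense
#' @param mask binary 3D array (logical or 0/1), same grid as `image`.
#' @param valid_frac validity threshold: denominator must exceed
#'   `valid_frac * max(kernel)`.
#' @return `voxel_image` with `NA` at invalid voxels.
#' @export
smooth_masked <- function(image, mask, sigma, a_factor = 3, spacing = NULL,
                          valid_frac = 1e-3) {
  spacing <- if (is.null(spacing)) vox_spacing(image) else as.numeric(spacing)
  stopifnot(sigma > 0, a_factor >= 2)
  m <- unclass_arr(mask)
  if (!all(dim(m) == dim(image))) stop("mask and image grids differ")
  m <- (m != 0) * 1
  if (sum(m) == 0) stop("mask is empty")
  if (sigma < 0.5 * min(spacing)) {
    warning("sigma below half a voxel; returning input unchanged")
    out <- unclass_arr(image)
    out[m == 0] <- NA_real_
    return(vox(out, spacing))
  }
  ker <- gauss_kernels(sigma, spacing, a_factor)
  num <- conv_separable(unclass_arr(image) * m, ker)
  den <- conv_separable(m, ker)
  kmax <- prod(vapply(ker, max, numeric(1)))
  out <- num / den
  out[den <= valid_frac * kmax] <- NA_real_
  vox(out, spacing)
}

unclass_arr <- function(x) {
  x <- as_array3d(x)
  attributes(x) <- list(dim = dim(x))
  storage.mode(x) <- "double"
  x
}

#' Sparse fields: values attached to scattered 3D positions
#'
#' @param positions n x 3 matrix of physical positions in um (z, y, x).
#' @param values numeric vector (scalar field) or n x p matrix (vector /
#'   flattened-tensor field), one row per position.
#' @return object of class `sparse_field`.
#' @export
sparse_field <- function(positions, values) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3 (z, y, x um)")
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) != nrow(positions))
    stop("values must have one row per position")
  structure(list(positions = positions, values = values),
            class = "sparse_field")
}

#' @export
print.sparse_field <- function(x, ...) {
  cat(sprintf("<sparse_field> %d positions, %d value component(s)\n",
              nrow(x$positions), ncol(x$values)))
  invisible(x)
}

#' Gaussian smoothing of a sparse field
#'
#' Masked Gaussian convolution where the mask is nonzero only at the field's
#' positions: the value at a query point is the Gaussian-weighted mean of all
#' field values within the truncation radius `a = a_factor * sigma`. Queries
#' with no position in range are `NA` (invalid).
#'
#' @param field a [sparse_field()].
#' @param sigma smoothing scale in um.
#' @param output `"positions"` (evaluate at the field's own positions), a
#'   numeric n x 3 matrix of query positions in um, or a `voxel_image` /
#'   `label_image` mask on whose nonzero voxels a dense field is evaluated.
#' @param a_factor truncation radius in sigmas.
#' @return For matrix / `"positions"` output: a [sparse_field()] at the query
#'   positions. For a mask: a `voxel_image` (first value component only unless
#'   `p == 1`, otherwise a list of images, one per component) with `NA`
#'   outside the mask or out of range.
#' @export
smooth_sparse <- function(field, sigma, output = "positions", a_factor = 3) {
  stopifnot(inherits(field, "sparse_field"), sigma > 0, a_factor >= 2)
  pos <- field$positions
  val <- field$values
  dense <- FALSE
  if (is.character(output) && identical(output, "positions")) {
    q <- pos
  } else if (is.matrix(output) || is.data.frame(output)) {
    q <- as.matrix(output)
  } else {
    # mask image: evaluate on its nonzero voxels
    dense <- TRUE
    mask <- output
    sp <- vox_spacing(mask)
    keep <- which(unclass_arr(mask) != 0)
    idx <- arrayInd(keep, dim(mask))
    q <- index_to_um(idx, sp)
  }
  a <- a_factor * sigma
  res <- sparse_gauss_query(pos, val, q, sigma, a)
  if (!dense) return(sparse_field(q, res))
  p <- ncol(val)
  imgs <- lapply(seq_len(p), function(j) {
    out <- array(NA_real_, dim(mask))
    out[keep] <- res[, j]
    vox(out, vox_spacing(mask))
  })
  if (p == 1) imgs[[1]] else imgs
}

# weighted-mean evaluation via a uniform bucket grid of cell size a:
# in-range neighbours of any query lie in the 27 cells around it
sparse_gauss_query <- function(pos, val, q, sigma, a) {
  m <- nrow(q)
  p <- ncol(val)
  num <- matrix(0, m, p)
  den <- numeric(m)
  key_of <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3])
  qcell <- floor(sweep(q, 2, a, `/`))
  buckets <- split(seq_len(m), key_of(qcell))
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  pcell <- floor(sweep(pos, 2, a, `/`))
  for (j in seq_len(nrow(pos))) {
    ids <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(pcell[j, 1] + offsets[o, 1], pcell[j, 2] + offsets[o, 2],
                 pcell[j, 3] + offsets[o, 3])
      b <- buckets[[k]]
      if (!is.null(b)) ids <- c(ids, b)
    }
    if (!length(ids)) next
    d2 <- (q[ids, 1] - pos[j, 1])^2 + (q[ids, 2] - pos[j, 2])^2 +
      (q[ids, 3] - pos[j, 3])^2
    inr <- d2 <= a^2
    if (!any(inr)) next
    ids <- ids[inr]
    w <- exp(-d2[inr] / (2 * sigma^2))
    num[ids, ] <- num[ids, ] + outer(w, val[j, ])
    den[ids] <- den[ids] + w
  }
  out <- num / den
  out[den == 0, ] <- NA_real_
  out
}
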