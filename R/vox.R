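#' Voxel images with physical spacing
#'
#' A `voxel_image` is a plain 3D numeric array carrying its per-axis voxel
#' spacing in micrometres (order `z, y, x`, matching array dimensions) and an
#' optional channel tag. All physical-scale operations in the package (Gaussian
#' coarse-graining, resampling, rigid transforms, decay fits) read the spacing
#' from the object so that parameters can be given in micrometres.
#'
#' @param data 3D numeric array (z, y, x).
#' @param spacing numeric length-3, voxel spacing in um for (z, y, x). All > 0.
#' @param channel optional character tag (e.g. `"hoechst"`).
#' @return `data` with class `voxel_image` and attributes `spacing`, `channel`.
#' @examples
#' img <- vox(array(rnorm(4 * 5 * 6), c(4, 5, 6)), spacing = c(1, 0.62, 0.62))
#' vox_spacing(img)
#' @export
vox <- function(data, spacing = c(1, 1, 1), channel = NULL) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (z, y, x um)")
  structure(data,
            spacing = spacing, channel = channel,
            class = c("voxel_image", "array"))
}

#' Integer label images
#'
#' A `label_image` is a 3D integer array where 0 is background and positive
#' integers are object instances (e.g. segmented nuclei). Carries spacing like
#' [vox()].
#'
#' @inheritParams vox
#' @return `data` coerced to integer with class `label_image`.
#' @export
labels3d <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3d(data)
  storage.mode(data) <- "integer"
  if (any(data < 0, na.rm = TRUE)) stop("labels must be >= 0")
  structure(data,
            spacing = as.numeric(spacing),
            class = c("label_image", "array"))
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("input must be an array, not a vector")
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) != 3L) stop("input must be a 3D array")
  x
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x)
  sp <- vox_spacing(x)
  cat(sprintf("<voxel_image> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g um%s\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              if (is.null(attr(x, "channel"))) "" else
                paste0(", channel '", attr(x, "channel"), "'")))
  cat(sprintf("  range [%.4g, %.4g], %d NA\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))))
  invisible(x)
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_image> %d x %d x %d (z,y,x), %d labels\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

#' Voxel spacing of an image
#'
#' @param x array, `voxel_image` or `label_image`.
#' @param default spacing returned when `x` carries none.
#' @return numeric length-3 spacing (z, y, x) in um.
#' @export
vox_spacing <- function(x, default = c(1, 1, 1)) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) default else as.numeric(sp)
}

#' @rdname vox
#' @param x object to test / strip.
#' @export
is_vox <- function(x) inherits(x, "voxel_image")

# rebuild a voxel_image around new data, keeping metadata from a template
vox_like <- function(data, template, spacing = NULL) {
  vox(data,
      spacing = if (is.null(spacing)) vox_spacing(template) else spacing,
      channel = attr(template, "channel"))
}

# physical (um) coordinates of voxel centres along one axis (1-based index 0 um)
axis_coords <- function(n, step) (seq_len(n) - 1) * step

# voxel volume in um^3
voxel_volume <- function(x) prod(vox_spacing(x))

# matrix (n x 3) of physical coordinates for given array indices (n x 3)
index_to_um <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}

um_to_index <- function(pos, spacing) {
  sweep(pos, 2, spacing, `/`) + 1
}

# run expr with a local, restored RNG state; all package randomness goes
# through this so no global state leaks
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
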