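#' Read and write 3D stacks as multi-page TIFF
#'
#' Stacks are stored as one 2D page per z-plane (ZYX order). Intensities are
#' written as 32-bit float, labels as integer pages. Voxel spacing and channel
#' tag travel in a JSON sidecar (`<file>.json`) and, for spacing, also in the
#' TIFF resolution fields read back when no sidecar is present.
#'
#' @param image `voxel_image` or `label_image`.
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly.
#' @export
write_stack <- function(image, path) {
  is_lab <- inherits(image, "label_image")
  d <- dim(image)
  arr <- unclass_arr(image)
  offset <- 0; scale <- 1
  if (is_lab) {
    mx <- max(arr)
    bits <- if (mx < 2^16) 16L else 32L
    pages <- lapply(seq_len(d[1]), function(z) arr[z, , ] / (2^bits - 1))
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    # TIFF samples live in [0, 1]; intensities are affinely packed and the
    # range stored in the sidecar, so the round trip is value-preserving
    if (anyNA(arr)) {
      warning("NA voxels written as 0 (validity is not persisted)")
      arr[is.na(arr)] <- 0
    }
    rng <- range(arr)
    offset <- rng[1]
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    pages <- lapply(seq_len(d[1]), function(z) (arr[z, , ] - offset) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(spacing = vox_spacing(image),
                            channel = attr(image, "channel"),
                            labels = is_lab, offset = offset, scale = scale),
                       sidecar, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @param spacing spacing override when no sidecar exists.
#' @param labels read as `label_image` (override; sidecar wins when present).
#' @export
read_stack <- function(path, spacing = NULL, labels = NULL) {
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  is_lab <- if (!is.null(meta$labels)) isTRUE(meta$labels) else isTRUE(labels)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is_lab)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]])[1:2])
  arr <- array(0, d)
  for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]]
  sp <- if (!is.null(spacing)) spacing else
    if (!is.null(meta$spacing)) meta$spacing else c(1, 1, 1)
  if (is_lab) {
    storage.mode(arr) <- "integer"
    labels3d(arr, spacing = sp)
  } else {
    if (!is.null(meta$scale)) arr <- arr * meta$scale + meta$offset
    vox(arr, spacing = sp, channel = meta$channel)
  }
}

#' Split a stack along one dimension into single-element TIFFs
#'
#' Writes each element along the chosen axis as its own file with a
#' zero-padded index, so large acquisitions can be processed element-wise.
#'
#' @param path input TIFF (3D stack).
#' @param dimension axis to split: 1 = z, 2 = y, 3 = x.
#' @param out_dir output directory.
#' @return character vector of written file paths.
#' @export
split_stack <- function(path, dimension = 1, out_dir) {
  img <- read_stack(path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(img)[dimension]
  width <- max(3L, nchar(as.character(n)))
  base <- sub("\\.tiff?$", "", basename(path))
  sp <- vox_spacing(img)
  out <- character(n)
  for (i in seq_len(n)) {
    sl <- switch(dimension,
                 unclass_arr(img)[i, , , drop = FALSE],
                 aperm(unclass_arr(img)[, i, , drop = FALSE], c(2, 1, 3)),
                 aperm(unclass_arr(img)[, , i, drop = FALSE], c(3, 1, 2)))
    out[i] <- file.path(out_dir,
                        sprintf("%s_d%d_%0*d.tif", base, dimension, width, i))
    write_stack(vox(sl, sp), out[i])
  }
  out
}

#' @rdname split_stack
#' @param paths files produced by [split_stack()], in order.
#' @return `restack` returns the reassembled `voxel_image` (elements stacked
#'   along the first axis of each file, i.e. the original split axis).
#' @export
restack <- function(paths, dimension = 1) {
  parts <- lapply(paths, read_stack)
  slabs <- lapply(parts, unclass_arr)
  arr <- abind1(slabs)
  arr <- switch(dimension, arr,
                aperm(arr, c(2, 1, 3)),
                aperm(arr, c(2, 3, 1)))
  vox(arr, vox_spacing(parts[[1]]))
}

# bind 3D arrays along the first axis
abind1 <- function(lst) {
  d <- dim(lst[[1]])
  n1 <- sum(vapply(lst, function(a) dim(a)[1], integer(1)))
  out <- array(0, c(n1, d[2], d[3]))
  at <- 1L
  for (a in lst) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}
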