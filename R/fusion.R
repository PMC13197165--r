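#' Sigmoid fusion of registered dual views
#'
#' After registration, the reference and floating views are blended inside
#' their overlap with depth-dependent weights, because each view's
#' signal-to-noise degrades with distance from its own objective. The
#' coordinate across the overlap is mapped to [0, 1] and the reference-view
#' weight is the logistic
#' `f1(z) = 1 / (1 + exp(p (z - z0)))`, with `f2 = 1 - f1`, so the weights
#' always sum to one. The slope `p` sets the decay length `l = 4 / p` and the
#' effective fusion width `delta = 2 l` (fractions of the overlap); with the
#' default `p = 15`, `l = 0.27` and `delta = 0.53`. `z0` is the inflection
#' point, where `f1(z0) = 0.5`.
#'
#' @param z normalized overlap coordinate(s) in [0, 1] (0 = reference side).
#' @param p sigmoid slope (> 0), on the normalized coordinate.
#' @param z0 inflection point in [0, 1].
#' @return `fusion_weights()` returns a list with vectors `f1`, `f2`
#'   (`f1 + f2 == 1`) plus the derived constants `l` and `delta`.
#' @export
fusion_weights <- function(z, p = 15, z0 = 0.5) {
  if (p <= 0) stop("sigmoid slope p must be > 0")
  f1 <- 1 / (1 + exp(p * (z - z0)))
  list(f1 = f1, f2 = 1 - f1, l = 4 / p, delta = 8 / p)
}

#' @describeIn fusion_weights Fuse two registered views on a common grid.
#'   The overlap is the z-range where both validity masks contain voxels;
#'   inside it, voxels valid in both views are blended, while voxels valid in
#'   only one view (anywhere) pass through unweighted.
#' @param ref reference-view `voxel_image`.
#' @param flt floating view already resampled onto the reference grid (e.g.
#'   by [apply_rigid()]); its `valid` attribute, if present, is used as
#'   validity mask.
#' @param ref_valid,flt_valid optional logical arrays overriding the validity
#'   masks (default: reference all-valid; floating from its attribute).
#' @return fused `voxel_image`; attributes `overlap` (z index range) and
#'   `weights` (per-plane f1).
#' @export
fuse_sigmoid <- function(ref, flt, p = 15, z0 = 0.5,
                         ref_valid = NULL, flt_valid = NULL) {
  if (!all(dim(ref) == dim(flt))) stop("views must share a grid")
  d <- dim(ref)
  rv <- if (is.null(ref_valid)) array(TRUE, d) else ref_valid != 0
  fv <- if (is.null(flt_valid)) {
    v <- attr(flt, "valid")
    if (is.null(v)) array(TRUE, d) else v
  } else flt_valid != 0
  both_z <- which(vapply(seq_len(d[1]), function(z)
    any(rv[z, , ] & fv[z, , ]), logical(1)))
  if (!length(both_z))
    stop("views do not overlap; check the registration")
  z1 <- min(both_z); z2 <- max(both_z)
  zn <- if (z2 > z1) (seq_len(d[1]) - z1) / (z2 - z1) else
    rep(0.5, d[1])
  w <- fusion_weights(pmin(pmax(zn, 0), 1), p = p, z0 = z0)
  rr <- unclass_arr(ref); ff <- unclass_arr(flt)
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    both <- rv[z, , ] & fv[z, , ]
    ronly <- rv[z, , ] & !fv[z, , ]
    fonly <- fv[z, , ] & !rv[z, , ]
    pl <- matrix(0, d[2], d[3])
    pl[both] <- w$f1[z] * rr[z, , ][both] + w$f2[z] * ff[z, , ][both]
    pl[ronly] <- rr[z, , ][ronly]
    pl[fonly] <- ff[z, , ][fonly]
    out[z, , ] <- pl
  }
  out <- vox(out, vox_spacing(ref), channel = attr(ref, "channel"))
  attr(out, "overlap") <- c(z1, z2)
  attr(out, "weights") <- w$f1
  attr(out, "valid") <- rv | fv
  out
}
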