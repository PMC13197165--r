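#' Depth-intensity normalization against a ubiquitous nuclear stain
#'
#' In scattering tissue the measured intensity of a channel decays with depth,
#' to first order exponentially with a wavelength-dependent decay length `d`.
#' Writing a channel as `I = M_inst * S * A + noise` (instance mask, true
#' expression field, artifact field), and assuming the reference nuclear stain
#' (Hoechst) has homogeneous true expression, the masked Gaussian average of
#' the reference channel over nuclei estimates its artifact field up to a
#' constant. Because decay lengths scale multiplicatively across imaging
#' conditions, their ratio `r(lambda2, lambda1) = d(lambda2) / d(lambda1)`
#' depends only on the two wavelengths, and the artifact field of a target
#' channel is the reference's raised to the power `r`. The corrected channel
#' is therefore `I_b / (reference_field ^ r)`.
#'
#' Orientation convention: with two ubiquitous channels,
#' `log(I_1) = r * log(I_2) + const` where `r = d2 / d1`; equivalently
#' [estimate_ratio_loglog()]`(I_target, I_ref)` returns exactly the exponent
#' to apply to the reference field when normalizing the target channel.
#'
#' @name intensity_normalization
NULL

#' Binary mask of a central column along z
#'
#' Decay fitting uses a central column to minimise boundary artifacts: a
#' cylinder around the sample-mask centroid axis with radius a fraction of
#' the sample's equivalent radius.
#'
#' @param sample_mask binary 3D array (inside-sample mask).
#' @param spacing voxel spacing (um) if the mask carries none.
#' @param radius_frac cylinder radius as a fraction of the sample radius.
#' @return logical array: column voxels inside the sample.
#' @export
central_column_mask <- function(sample_mask, spacing = NULL,
                                radius_frac = 0.25) {
  sp <- if (is.null(spacing)) vox_spacing(sample_mask) else as.numeric(spacing)
  m <- unclass_arr(sample_mask) != 0
  d <- dim(m)
  idx <- which(m)
  ai <- arrayInd(idx, d)
  cy <- mean((ai[, 2] - 1) * sp[2])
  cx <- mean((ai[, 3] - 1) * sp[3])
  # equivalent radius from the mask's largest xy cross-section
  area_max <- max(vapply(seq_len(d[1]), function(z) sum(m[z, , ]), numeric(1)))
  r_eq <- sqrt(area_max * sp[2] * sp[3] / pi)
  yy <- matrix((axis_coords(d[2], sp[2]) - cy)^2, d[2], d[3])
  xx <- matrix((axis_coords(d[3], sp[3]) - cx)^2, d[2], d[3], byrow = TRUE)
  disk <- (yy + xx) <= (radius_frac * r_eq)^2
  col <- array(rep(disk, each = d[1]), d)
  col & m
}

#' Fit the exponential decay length of a depth profile
#'
#' The mean masked intensity per z-plane is fitted to `A * exp(-z / d)` by
#' nonlinear least squares (initialised from the log-linear fit). A profile
#' with no decaying trend returns `d = Inf` (reported as "no decay").
#'
#' @param image `voxel_image`.
#' @param column_mask binary array selecting the fitted voxels (e.g. from
#'   [central_column_mask()], intersected with a signal mask).
#' @param min_planes minimum number of populated z-planes.
#' @return list with `d` (um), `amplitude`, `r_squared`, and the per-plane
#'   `profile` data.frame.
#' @export
fit_decay_length <- function(image, column_mask, min_planes = 10) {
  arr <- unclass_arr(image)
  m <- unclass_arr(column_mask) != 0
  sp <- vox_spacing(image)
  d <- dim(arr)
  z_um <- axis_coords(d[1], sp[1])
  means <- vapply(seq_len(d[1]), function(z) {
    v <- arr[z, , ][m[z, , ]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ok <- is.finite(means) & means > 0
  if (sum(ok) < min_planes)
    stop(sprintf("decay fit needs signal on >= %d z-planes, found %d",
                 min_planes, sum(ok)))
  z <- z_um[ok]; y <- means[ok]
  lf <- stats::lm(log(y) ~ z)
  slope <- stats::coef(lf)[2]
  r2_log <- suppressWarnings(summary(lf)$r.squared)  # exact fits warn
  profile <- data.frame(z_um = z, mean_intensity = y)
  if (!is.finite(slope) || slope >= -1e-12) {
    return(list(d = Inf, amplitude = exp(stats::coef(lf)[1]),
                r_squared = r2_log, profile = profile,
                note = "no decay"))
  }
  # an (almost) exactly log-linear profile needs no nonlinear refinement --
  # and zero-residual data makes nls's convergence test degenerate
  loglinear_exact <- r2_log > 1 - 1e-9
  fit <- if (loglinear_exact) NULL else tryCatch(
    stats::nls(y ~ A * exp(-z / dd),
               start = list(A = exp(stats::coef(lf)[1]), dd = -1 / slope),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    dd <- -1 / slope
    A <- exp(stats::coef(lf)[1])
    pred <- A * exp(-z / dd)
  } else {
    co <- stats::coef(fit)
    dd <- co[["dd"]]; A <- co[["A"]]
    pred <- stats::predict(fit)
  }
  if (dd <= 0) stop("decay fit produced a non-positive decay length")
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(d = unname(dd), amplitude = unname(A), r_squared = r2,
       profile = profile)
}

#' Estimate the decay-length ratio of two channels on log-log scale
#'
#' For two co-registered ubiquitous signals, `log(I1) = r log(I2) + const`
#' with `r = d2 / d1` the ratio of their decay lengths. Returns the
#' least-squares slope over masked voxels with positive intensities in both
#' channels.
#'
#' @param i1,i2 `voxel_image`s of the same structure at two wavelengths.
#' @param mask binary array of signal voxels.
#' @param min_voxels minimum usable voxels.
#' @param per_plane regress per-z-plane masked medians instead of raw voxels:
#'   robust when per-instance brightness varies (voxel-wise regression is
#'   attenuated by brightness scatter that is independent between the two
#'   stains).
#' @return slope `r`; attribute `r_squared`.
#' @export
estimate_ratio_loglog <- function(i1, i2, mask, min_voxels = 100,
                                  per_plane = FALSE) {
  m <- unclass_arr(mask) != 0
  if (per_plane) {
    nz <- dim(m)[1]
    med <- function(img) vapply(seq_len(nz), function(z) {
      v <- unclass_arr(img)[z, , ][m[z, , ]]
      v <- v[is.finite(v) & v > 0]
      if (length(v) >= 20) stats::median(v) else NA_real_
    }, numeric(1))
    a <- med(i1); b <- med(i2)
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 10) stop("need >= 10 populated z-planes")
    la <- log(a[ok]); lb <- log(b[ok])
    if (stats::var(lb) == 0) stop("predictor channel is constant on the mask")
    r <- stats::cov(la, lb) / stats::var(lb)
    res <- la - r * lb
    attr(r, "r_squared") <- 1 - stats::var(res) / stats::var(la)
    return(r)
  }
  a <- unclass_arr(i1)[m]; b <- unclass_arr(i2)[m]
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  if (sum(ok) < min_voxels)
    stop(sprintf("need >= %d positive masked voxels, found %d",
                 min_voxels, sum(ok)))
  la <- log(a[ok]); lb <- log(b[ok])
  if (stats::var(lb) == 0) stop("predictor channel is constant on the mask")
  r <- stats::cov(la, lb) / stats::var(lb)
  res <- la - r * lb
  attr(r, "r_squared") <- 1 - stats::var(res) / stats::var(la)
  r
}

#' Reference artifact field from the ubiquitous nuclear channel
#'
#' Masked Gaussian average of the reference (Hoechst) signal over nuclei
#' voxels, evaluated across the whole sample mask: with homogeneous true
#' expression this estimates the optical artifact field up to a constant.
#'
#' @param i_h reference-channel `voxel_image`.
#' @param m_nuc binary nuclei mask (binarized instance labels).
#' @param sigma Gaussian scale in um (typically around the nucleus diameter,
#'   10-15 um; see [select_sigma()]).
#' @param sample_mask optional inside-sample mask limiting the output.
#' @return `voxel_image`, `NA` outside validity / sample.
#' @export
reference_field <- function(i_h, m_nuc, sigma, sample_mask = NULL) {
  if (sum(unclass_arr(m_nuc) != 0) == 0) stop("nuclei mask is empty")
  out <- smooth_masked(i_h, m_nuc, sigma)
  if (!is.null(sample_mask)) {
    o <- unclass_arr(out)
    o[unclass_arr(sample_mask) == 0] <- NA_real_
    out <- vox_like(o, out)
  }
  out
}

#' Normalize a channel by the reference field
#'
#' `I_hat = I_b / reference_field ^ r`, with `r` the decay-length ratio
#' between the reference wavelength and the channel's (see
#' [estimate_ratio_loglog()]). Invalid (NA) or non-positive reference voxels
#' propagate as `NA`.
#'
#' @param i_b channel to normalize (`voxel_image`).
#' @param ref_field reference field from [reference_field()].
#' @param r positive exponent.
#' @return normalized `voxel_image`.
#' @export
normalize_channel <- function(i_b, ref_field, r) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0)
    stop("r must be a single positive number")
  den <- unclass_arr(ref_field)
  den[!is.na(den) & den <= 0] <- NA_real_
  vox_like(unclass_arr(i_b) / den^r, i_b)
}

#' Select the reference-field scale by z-profile homogeneity
#'
#' For each candidate sigma the reference channel is normalized by its own
#' reference field (`r = 1`), the median of the normalized signal over nuclei
#' voxels is taken per z-plane, and the sigma minimising the median absolute
#' deviation (MAD) of those plane medians is returned. Ties break towards the
#' smallest sigma.
#'
#' @param i_h reference `voxel_image`.
#' @param m_nuc binary nuclei mask.
#' @param candidate_sigmas numeric vector of scales in um (>= 2 values).
#' @return the selected sigma; attribute `mad` holds the per-candidate MADs.
#' @export
select_sigma <- function(i_h, m_nuc,
                         candidate_sigmas = seq(5, 30, by = 5)) {
  if (length(candidate_sigmas) < 2) stop("need at least 2 candidate sigmas")
  cand <- sort(candidate_sigmas)
  m <- unclass_arr(m_nuc) != 0
  arr <- unclass_arr(i_h)
  d <- dim(arr)
  mads <- vapply(cand, function(s) {
    ref <- unclass_arr(smooth_masked(i_h, m_nuc, s))
    nrm <- arr / ref
    med <- vapply(seq_len(d[1]), function(z) {
      v <- nrm[z, , ][m[z, , ]]
      v <- v[is.finite(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    stats::mad(med[is.finite(med)])
  }, numeric(1))
  best <- cand[which.min(mads)]   # which.min takes the first (smallest) tie
  attr(best, "mad") <- stats::setNames(mads, cand)
  best
}

#' Rescale a normalized channel to transmit the raw bright-region median
#'
#' Normalization divides out a sample-dependent constant; to compare samples,
#' each normalized stack is multiplied by a single factor chosen so that the
#' median raw reference intensity over the brightest region (top decile of
#' the reference field by default, i.e. the artifact-free outer layers) is
#' transmitted to the normalized reference.
#'
#' @param normalized normalized `voxel_image` to rescale.
#' @param normalized_ref the reference channel normalized the same way.
#' @param raw_ref raw reference `voxel_image`.
#' @param ref_field reference field used for the normalization.
#' @param signal_mask binary mask of signal voxels (e.g. nuclei); medians are
#'   taken over bright-region voxels that carry signal, since the reference
#'   stain is zero between nuclei.
#' @param bright_quantile quantile of the reference field defining the bright
#'   region.
#' @return rescaled `voxel_image`; attribute `factor` holds the multiplier.
#' @export
rescale_global <- function(normalized, normalized_ref, raw_ref, ref_field,
                           signal_mask = NULL, bright_quantile = 0.9) {
  rf <- unclass_arr(ref_field)
  thr <- stats::quantile(rf[is.finite(rf)], bright_quantile, names = FALSE)
  sel <- !is.na(rf) & rf >= thr
  if (!is.null(signal_mask)) sel <- sel & (unclass_arr(signal_mask) != 0)
  if (!any(sel)) stop("empty bright-region selection")
  raw_med <- stats::median(unclass_arr(raw_ref)[sel], na.rm = TRUE)
  nrm_med <- stats::median(unclass_arr(normalized_ref)[sel], na.rm = TRUE)
  if (!is.finite(nrm_med) || nrm_med == 0)
    stop("normalized reference median is degenerate in the bright region")
  f <- raw_med / nrm_med
  out <- vox_like(unclass_arr(normalized) * f, normalized)
  attr(out, "factor") <- f
  out
}
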