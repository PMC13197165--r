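#' Depth-calibrated linear spectral unmixing
#'
#' Emission of each fluorophore bleeds into several detector channels, and the
#' apparent spectrum drifts with imaging depth because absorption and
#' scattering are wavelength dependent. Unmixing proceeds in three steps:
#'
#' 1. [calibrate_patterns()] measures, per depth bin, the apparent emission
#'    pattern `p_i^k(z)` of each fluorophore `i` over the `m` detector
#'    channels `k`, from calibration stacks of samples carrying a single
#'    fluorophore species.
#' 2. [compute_filters()] converts the pattern matrix `P` (with `P[k, i] =
#'    p_i^k`) into unmixing filter functions
#'    `f = (P' D P)^-1 P' D`, with `D = diag(1 / <I^k>)` built from the mean
#'    channel intensities of the stack to unmix. The filters are unbiased:
#'    `sum_k f_i^k p_j^k = delta_ij` in every depth bin.
#' 3. [unmix()] applies `I_i(x) = sum_k f_i^k(z) I^k(x)` plane by plane.
#'    Negative outputs are legitimate noise fluctuations and are preserved.
#'
#' @name spectral_unmixing
NULL

#' Pattern tables of apparent emission spectra
#'
#' @param patterns array `n_fluor x n_channels x n_bins` of nonnegative
#'   weights; each fluorophore row is normalized to sum 1 within each bin.
#' @param bin_edges depth bin edges in um, length `n_bins + 1`, increasing.
#' @param fluor_names,channel_names optional names.
#' @return object of class `pattern_table`.
#' @export
pattern_table <- function(patterns, bin_edges, fluor_names = NULL,
                          channel_names = NULL) {
  patterns <- as.array(patterns)
  if (length(dim(patterns)) == 2L) dim(patterns) <- c(dim(patterns), 1L)
  stopifnot(length(dim(patterns)) == 3L)
  if (any(patterns < 0)) stop("patterns must be nonnegative")
  if (length(bin_edges) != dim(patterns)[3] + 1L ||
      any(diff(bin_edges) <= 0))
    stop("bin_edges must be increasing with length n_bins + 1")
  rs <- apply(patterns, c(1, 3), sum)
  if (any(rs <= 0)) stop("every fluorophore needs signal in every bin")
  patterns <- sweep_rows3(patterns, rs)
  structure(list(patterns = patterns, bin_edges = as.numeric(bin_edges),
                 fluor_names = fluor_names, channel_names = channel_names),
            class = "pattern_table")
}

# divide patterns[i, , b] by rs[i, b]
sweep_rows3 <- function(patterns, rs) {
  d <- dim(patterns)
  for (b in seq_len(d[3]))
    patterns[, , b] <- patterns[, , b] / rs[, b]
  patterns
}

#' @export
print.pattern_table <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("<pattern_table> %d fluorophore(s) x %d channel(s) x %d depth bin(s)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

n_bins <- function(pt) dim(pt$patterns)[3]

bin_of_depth <- function(z_um, edges) {
  b <- findInterval(z_um, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Calibrate apparent emission patterns from single-fluorophore stacks
#'
#' For each fluorophore, the mean masked intensity per channel is computed in
#' each depth bin and normalized across channels. Bins with fewer than
#' `min_voxels` masked voxels inherit the nearest populated bin.
#'
#' @param single_fluor_stacks list (one per fluorophore) of lists of `m`
#'   channel `voxel_image`s from a sample stained with that fluorophore only.
#' @param masks list of binary arrays (one per fluorophore) selecting signal
#'   voxels well above background (e.g. nuclei).
#' @param bin_width depth bin width in um.
#' @param min_voxels minimum masked voxels for a bin to be used directly.
#' @return a [pattern_table()].
#' @export
calibrate_patterns <- function(single_fluor_stacks, masks, bin_width = 10,
                               min_voxels = 50) {
  n <- length(single_fluor_stacks)
  stopifnot(n >= 1, length(masks) == n)
  m <- length(single_fluor_stacks[[1]])
  sp <- vox_spacing(single_fluor_stacks[[1]][[1]])
  nz <- dim(single_fluor_stacks[[1]][[1]])[1]
  zmax <- nz * sp[1]
  edges <- seq(0, zmax, by = bin_width)
  if (edges[length(edges)] < zmax) edges <- c(edges, zmax)
  nb <- length(edges) - 1L
  z_um <- axis_coords(nz, sp[1])
  bins <- bin_of_depth(z_um, edges)
  pats <- array(NA_real_, c(n, m, nb))
  for (i in seq_len(n)) {
    mk <- unclass_arr(masks[[i]]) != 0
    counts <- numeric(nb)
    sums <- matrix(0, m, nb)
    for (b in seq_len(nb)) {
      sel_planes <- which(bins == b)
      if (!length(sel_planes)) next
      msub <- mk[sel_planes, , , drop = FALSE]
      counts[b] <- sum(msub)
      if (counts[b] == 0) next
      for (k in seq_len(m)) {
        arr <- unclass_arr(single_fluor_stacks[[i]][[k]])
        sums[k, b] <- sum(arr[sel_planes, , , drop = FALSE][msub])
      }
    }
    ok <- counts >= min_voxels & colSums(sums) > 0
    if (!any(ok))
      stop(sprintf("calibration failure: fluorophore %d has no usable signal", i))
    for (b in seq_len(nb)) {
      src <- if (ok[b]) b else which(ok)[which.min(abs(which(ok) - b))]
      p <- sums[, src] / counts[src]
      pats[i, , b] <- p / sum(p)
    }
  }
  pattern_table(pats, edges)
}

#' Rescale a pattern table to different detector gains
#'
#' Gains change per-channel count rates multiplicatively; patterns calibrated
#' at one gain set transfer to another by multiplying each channel column by
#' the measured count ratio and re-normalizing the rows.
#'
#' @param patterns a [pattern_table()].
#' @param count_ratios positive factor per channel (new counts / old counts).
#' @return rescaled [pattern_table()].
#' @export
interpolate_gain <- function(patterns, count_ratios) {
  stopifnot(inherits(patterns, "pattern_table"))
  d <- dim(patterns$patterns)
  if (length(count_ratios) != d[2] || any(count_ratios <= 0) ||
      any(!is.finite(count_ratios)))
    stop("count_ratios must be positive, one per channel")
  p <- patterns$patterns
  for (b in seq_len(d[3]))
    p[, , b] <- sweep(p[, , b, drop = TRUE], 2, count_ratios, `*`)
  pattern_table(p, patterns$bin_edges, patterns$fluor_names,
                patterns$channel_names)
}

#' Compute unbiased spectral filter functions
#'
#' Per depth bin, builds `F = (P' D P)^-1 P' D` with `P[k, i] = p_i^k` and
#' `D = diag(1 / channel_means)`. Refuses rank-deficient or ill-conditioned
#' pattern matrices (noise amplification would destroy the result).
#'
#' @param patterns a [pattern_table()] with `n <= m`.
#' @param channel_means `m x n_bins` matrix (or length-m vector recycled over
#'   bins) of mean channel intensities `<I^k>`, all > 0.
#' @param max_condition condition-number threshold for refusal.
#' @return object of class `filter_bank`: list with `filters`
#'   (`n_fluor x n_channels x n_bins`) and `bin_edges`.
#' @export
compute_filters <- function(patterns, channel_means,
                            max_condition = 1e6) {
  stopifnot(inherits(patterns, "pattern_table"))
  d <- dim(patterns$patterns)
  n <- d[1]; m <- d[2]; nb <- d[3]
  if (n > m) stop("more fluorophores than channels: underdetermined")
  cm <- channel_means
  if (is.null(dim(cm))) cm <- matrix(cm, m, nb)
  if (!all(dim(cm) == c(m, nb))) stop("channel_means must be m x n_bins")
  if (any(cm <= 0)) stop("channel_means must be > 0")
  filt <- array(NA_real_, c(n, m, nb))
  for (b in seq_len(nb)) {
    P <- t(matrix(patterns$patterns[, , b], n, m))  # m x n, P[k, i]
    D <- diag(1 / cm[, b], m)
    sP <- sqrt(D) %*% P
    if (qr(sP)$rank < n || kappa(crossprod(sP), exact = TRUE) > max_condition)
      stop(sprintf("pattern matrix rank-deficient or ill-conditioned in bin %d", b))
    filt[, , b] <- solve(crossprod(sP), t(P) %*% D)
  }
  structure(list(filters = filt, bin_edges = patterns$bin_edges),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  d <- dim(x$filters)
  cat(sprintf("<filter_bank> %d fluorophore(s) x %d channel(s) x %d depth bin(s)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Mean channel intensity per depth bin
#'
#' @param stacks list of `m` channel `voxel_image`s.
#' @param bin_edges depth bin edges in um.
#' @param mask optional binary array restricting the mean.
#' @return `m x n_bins` matrix of means.
#' @export
channel_means_by_bin <- function(stacks, bin_edges, mask = NULL) {
  m <- length(stacks)
  sp <- vox_spacing(stacks[[1]])
  nz <- dim(stacks[[1]])[1]
  bins <- bin_of_depth(axis_coords(nz, sp[1]), bin_edges)
  nb <- length(bin_edges) - 1L
  out <- matrix(NA_real_, m, nb)
  mk <- if (is.null(mask)) NULL else unclass_arr(mask) != 0
  for (b in seq_len(nb)) {
    pl <- which(bins == b)
    for (k in seq_len(m)) {
      arr <- unclass_arr(stacks[[k]])[pl, , , drop = FALSE]
      if (!is.null(mk)) {
        ms <- mk[pl, , , drop = FALSE]
        out[k, b] <- if (any(ms)) mean(arr[ms]) else NA_real_
      } else out[k, b] <- mean(arr)
    }
  }
  # empty bins inherit nearest populated
  ok <- apply(is.finite(out), 2, all)
  if (!any(ok)) stop("no populated depth bin")
  for (b in which(!ok))
    out[, b] <- out[, which(ok)[which.min(abs(which(ok) - b))]]
  out
}

#' Unmix multi-channel stacks into per-fluorophore images
#'
#' @param stacks list of `m` channel `voxel_image`s on a common grid.
#' @param filters a `filter_bank` from [compute_filters()].
#' @param blend if `TRUE`, filter values are interpolated linearly between
#'   depth-bin centres instead of applied piecewise-constant per bin.
#' @param saturation_level optional intensity at/above which a voxel is
#'   counted as saturated (reported in attribute `saturated`, not masked).
#' @return list of `n_fluor` `voxel_image`s; attribute `saturated` holds the
#'   per-channel count of saturated voxels.
#' @export
unmix <- function(stacks, filters, blend = FALSE, saturation_level = NULL) {
  stopifnot(inherits(filters, "filter_bank"))
  d <- dim(filters$filters)
  n <- d[1]; m <- d[2]; nb <- d[3]
  if (length(stacks) != m) stop("channel count does not match filter bank")
  sp <- vox_spacing(stacks[[1]])
  dd <- dim(stacks[[1]])
  nz <- dd[1]
  z_um <- axis_coords(nz, sp[1])
  sat <- if (is.null(saturation_level)) NULL else
    vapply(stacks, function(s) sum(unclass_arr(s) >= saturation_level),
           numeric(1))
  fz <- filters_at_depth(filters, z_um, blend)  # list over planes: n x m
  out <- lapply(seq_len(n), function(i) array(0, dd))
  for (z in seq_len(nz)) {
    Fz <- fz[[z]]
    planes <- vapply(stacks, function(s) unclass_arr(s)[z, , ],
                     matrix(0, dd[2], dd[3]))  # y x x x m
    pm <- matrix(planes, ncol = m)
    res <- pm %*% t(Fz)  # voxels x n
    for (i in seq_len(n)) out[[i]][z, , ] <- res[, i]
  }
  out <- lapply(seq_len(n), function(i) vox(out[[i]], sp))
  if (!is.null(sat)) attr(out, "saturated") <- sat
  out
}

filters_at_depth <- function(filters, z_um, blend) {
  edges <- filters$bin_edges
  nb <- length(edges) - 1L
  if (!blend || nb == 1L) {
    bins <- bin_of_depth(z_um, edges)
    return(lapply(bins, function(b) filters$filters[, , b, drop = TRUE] |>
                    as_filter_mat(dim(filters$filters))))
  }
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  lapply(z_um, function(z) {
    if (z <= centres[1]) return(as_filter_mat(filters$filters[, , 1],
                                              dim(filters$filters)))
    if (z >= centres[nb]) return(as_filter_mat(filters$filters[, , nb],
                                               dim(filters$filters)))
    j <- findInterval(z, centres)
    t <- (z - centres[j]) / (centres[j + 1] - centres[j])
    as_filter_mat((1 - t) * filters$filters[, , j] +
                    t * filters$filters[, , j + 1], dim(filters$filters))
  })
}

as_filter_mat <- function(x, d3) matrix(x, d3[1], d3[2])
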