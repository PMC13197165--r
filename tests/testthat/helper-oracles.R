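# Independent brute-force oracles used to pin down the fast implementations.

# truncated normalized Gaussian kernel value for an integer offset triple
.oracle_kernel <- function(sigma, spacing, a_factor = 3) {
  h <- floor(a_factor * sigma / spacing)
  k1 <- lapply(1:3, function(i) {
    o <- (-h[i]):h[i]
    k <- exp(-(o * spacing[i])^2 / (2 * sigma^2))
    k / sum(k)
  })
  list(h = h, k1 = k1)
}

# triple-loop dense Gaussian convolution; the kernel is renormalized over the
# part of the window that falls inside the array (cropped-window semantics)
oracle_smooth_dense <- function(arr, sigma, spacing, a_factor = 3) {
  kk <- .oracle_kernel(sigma, spacing, a_factor)
  d <- dim(arr)
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    s <- 0; wsum <- 0
    for (oz in (-kk$h[1]):kk$h[1]) for (oy in (-kk$h[2]):kk$h[2])
      for (ox in (-kk$h[3]):kk$h[3]) {
        zz <- z - oz; yy <- y - oy; xx <- x - ox
        if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] &&
            xx >= 1 && xx <= d[3]) {
          w <- kk$k1[[1]][oz + kk$h[1] + 1] * kk$k1[[2]][oy + kk$h[2] + 1] *
            kk$k1[[3]][ox + kk$h[3] + 1]
          s <- s + w * arr[zz, yy, xx]
          wsum <- wsum + w
        }
      }
    out[z, y, x] <- s / wsum
  }
  out
}

# triple-loop zero-padded convolution (no renormalization)
.oracle_conv_raw <- function(arr, sigma, spacing, a_factor = 3) {
  kk <- .oracle_kernel(sigma, spacing, a_factor)
  d <- dim(arr)
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    s <- 0
    for (oz in (-kk$h[1]):kk$h[1]) for (oy in (-kk$h[2]):kk$h[2])
      for (ox in (-kk$h[3]):kk$h[3]) {
        zz <- z - oz; yy <- y - oy; xx <- x - ox
        if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] &&
            xx >= 1 && xx <= d[3])
          s <- s + kk$k1[[1]][oz + kk$h[1] + 1] * kk$k1[[2]][oy + kk$h[2] + 1] *
            kk$k1[[3]][ox + kk$h[3] + 1] * arr[zz, yy, xx]
      }
    out[z, y, x] <- s
  }
  out
}

# triple-loop masked Gaussian convolution: num / den, NA where den ~ 0
oracle_smooth_masked <- function(arr, mask, sigma, spacing, a_factor = 3,
                                 valid_frac = 1e-3) {
  m <- (mask != 0) * 1
  num <- .oracle_conv_raw(arr * m, sigma, spacing, a_factor)
  den <- .oracle_conv_raw(m, sigma, spacing, a_factor)
  kk <- .oracle_kernel(sigma, spacing, a_factor)
  kmax <- prod(vapply(kk$k1, max, numeric(1)))
  out <- num / den
  out[den <= valid_frac * kmax] <- NA_real_
  out
}

# double-loop sparse Gaussian weighted mean with hard radius cutoff
oracle_smooth_sparse <- function(pos, val, q, sigma, a_factor = 3) {
  a <- a_factor * sigma
  val <- as.matrix(val)
  out <- matrix(NA_real_, nrow(q), ncol(val))
  for (i in seq_len(nrow(q))) {
    d2 <- rowSums(sweep(pos, 2, q[i, ])^2)
    w <- exp(-d2 / (2 * sigma^2)) * (d2 <= a^2)
    if (sum(w) > 0) out[i, ] <- colSums(w * val) / sum(w)
  }
  out
}

# per-voxel local percentile enhancement (cropped windows), exact
oracle_enhance_local <- function(arr, w, p_min = 1, p_max = 99) {
  d <- dim(arr)
  h <- w %/% 2
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    win <- arr[max(1, z - h):min(d[1], z + h),
               max(1, y - h):min(d[2], y + h),
               max(1, x - h):min(d[3], x + h)]
    pr <- stats::quantile(win, c(p_min, p_max) / 100, names = FALSE)
    out[z, y, x] <- if (pr[2] > pr[1])
      min(max((arr[z, y, x] - pr[1]) / (pr[2] - pr[1]), 0), 1) else 0
  }
  out
}

# exhaustive Otsu: try every histogram cut, maximize between-class variance;
# ties (the empty-gap plateau) resolve to the middle cut
oracle_otsu <- function(v, n_bins = 256) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  bcv <- rep(-Inf, n_bins - 1)
  for (t in 1:(n_bins - 1)) {
    lo <- v[bin <= t]; hi <- v[bin > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    # between-class variance with bin-centre means, as in the histogram method
    clo <- mean((edges[pmin(bin[bin <= t], n_bins)] +
                   edges[pmin(bin[bin <= t], n_bins) + 1]) / 2)
    chi <- mean((edges[pmin(bin[bin > t], n_bins)] +
                   edges[pmin(bin[bin > t], n_bins) + 1]) / 2)
    bcv[t] <- w0 * (1 - w0) * (clo - chi)^2
  }
  ties <- which(bcv >= max(bcv) * (1 - 1e-12))
  edges[ties[ceiling(length(ties) / 2)] + 1]
}

# voxelize a solid ellipsoid with semi-axes `semi` (um), optional rotation R
# (columns = ellipsoid axes), on a grid of the given spacing; returns a
# label_image with one object
voxel_ellipsoid <- function(semi, spacing = c(0.25, 0.25, 0.25), R = diag(3)) {
  ext <- max(semi) * 1.3
  n <- ceiling(2 * ext / spacing) + 1
  cz <- (n - 1) / 2 * spacing
  g <- expand.grid(z = seq_len(n[1]), y = seq_len(n[2]), x = seq_len(n[3]))
  p <- cbind((g$z - 1) * spacing[1] - cz[1], (g$y - 1) * spacing[2] - cz[2],
             (g$x - 1) * spacing[3] - cz[3])
  loc <- p %*% R   # coordinates along the ellipsoid axes
  inside <- (loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
    (loc[, 3] / semi[3])^2 <= 1
  arr <- array(0L, n)
  arr[cbind(g$z, g$y, g$x)[inside, ]] <- 1L
  labels3d(arr, spacing)
}

# all permutations of 1..n (for brute-force assignment)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# empirical Kolmogorov-Smirnov distance between two samples
ks_distance <- function(a, b) {
  e <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(e) - stats::ecdf(b)(e)))
}
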