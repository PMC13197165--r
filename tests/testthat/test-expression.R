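test_that("per-nucleus means recover the generated brightness", {
  ph <- cached_phantom("clean")   # identity optics: channel k = fluor k
  cells <- nuclei_mean_intensities(ph$labels,
                                   list(hoechst = ph$channels[[1]],
                                        marker = ph$channels[[2]]))
  expect_equal(nrow(cells), nrow(ph$truth))
  expect_equal(cells$mean_hoechst, ph$truth$brightness1, tolerance = 1e-12)
  expect_equal(cells$mean_marker, ph$truth$brightness2, tolerance = 1e-12)

  # constant channel: every cell mean equals the constant
  cst <- vox(array(2.5, dim(ph$labels)), vox_spacing(ph$labels))
  cc <- nuclei_mean_intensities(ph$labels, list(c0 = cst))
  expect_true(all(cc$mean_c0 == 2.5))

  # with noise, the per-cell mean error scales as noise / sqrt(n_voxels)
  phm <- cached_phantom("mixed")
  cm <- nuclei_mean_intensities(phm$labels, list(ch1 = phm$channels[[1]]))
  ot <- object_table(phm$labels)
  nvox <- ot$volume / prod(vox_spacing(phm$labels))
  lab <- unclass(phm$labels)
  # reconstruct the noiseless expectation for channel 1
  mix <- phm$spec$mixing_matrix
  bright <- as.matrix(phm$truth[, paste0("brightness", 1:4)])
  exp_b <- as.numeric(bright %*% mix[, 1])
  # per-cell depth factor from the centroid
  decay <- exp(-cm$cz / phm$spec$decay_lengths[1])
  resid <- cm$mean_ch1 - exp_b * decay
  tol <- 6 * phm$spec$noise_sd / sqrt(nvox) + 0.03 * exp_b * decay
  expect_gt(mean(abs(resid) <= tol), 0.9)

  expect_error(nuclei_mean_intensities(
    labels3d(array(0L, dim(ph$labels)), vox_spacing(ph$labels)),
    list(x = cst)), "no objects")
})

test_that("Otsu threshold separates a bimodal mixture and matches the
           exhaustive search", {
  set.seed(901)
  v <- c(stats::rnorm(500, 1, 0.1), stats::rnorm(500, 5, 0.1))
  thr <- otsu_threshold(v)
  expect_gt(thr, 2); expect_lt(thr, 4)
  acc <- mean((v > as.numeric(thr)) == rep(c(FALSE, TRUE), each = 500))
  expect_gt(acc, 0.99)
  expect_equal(as.numeric(thr), oracle_otsu(v), tolerance = 1e-12)

  # random continuous values: still identical to the exhaustive search
  set.seed(902)
  for (i in 1:5) {
    w <- stats::rlnorm(300, 0, 0.7)
    expect_equal(suppressWarnings(as.numeric(otsu_threshold(w))),
                 oracle_otsu(w), tolerance = 1e-12)
  }

  # two distinct constants: threshold strictly between them
  v2 <- rep(c(1, 3), each = 50)
  t2 <- suppressWarnings(as.numeric(otsu_threshold(v2)))
  expect_gt(t2, 1); expect_lt(t2, 3)
  expect_error(otsu_threshold(rep(1, 10)), "distinct")
})

test_that("positive-fraction field recovers the radial positivity law", {
  # cells placed uniformly in a sphere, P(positive) = exp(-d_border / 30)
  set.seed(903)
  R <- 50; n <- 4000
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- R * stats::runif(n)^(1 / 3)
  cents <- sweep(u * rad, 2, c(60, 60, 60), `+`)
  db <- R - rad
  positive <- stats::runif(n) < exp(-db / 30)
  cells <- data.frame(label = seq_len(n), cz = cents[, 1], cy = cents[, 2],
                      cx = cents[, 3])
  sp <- c(2, 2, 2)
  dgrid <- c(61, 61, 61)
  tem <- vox(array(0, dgrid), sp)
  cc <- (dgrid - 1) * sp / 2
  rr2 <- outer(outer(((seq_len(dgrid[1]) - 1) * sp[1] - cc[1])^2,
                     ((seq_len(dgrid[2]) - 1) * sp[2] - cc[2])^2, `+`),
               ((seq_len(dgrid[3]) - 1) * sp[3] - cc[3])^2, `+`)
  mask <- rr2 <= R^2
  pf <- positive_fraction_field(cells, positive, sigma = 3, template = tem,
                                sample_mask = mask)
  v <- unclass(pf)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  prof <- radial_profile(pf, mask, bin_width = 5)
  prof <- prof[prof$n > 200 & prof$mean > 0 & prof$bin_mid <= 36, ]
  fit <- stats::lm(log(mean) ~ bin_mid, data = prof,
                   weights = prof$n)
  expect_lt(abs(-1 / stats::coef(fit)[2] - 30), 3)

  # all-positive and none-positive extremes
  pf1 <- positive_fraction_field(cells, rep(TRUE, n), sigma = 6,
                                 template = tem, sample_mask = mask)
  v1 <- unclass(pf1)
  expect_equal(range(v1[!is.na(v1)]), c(1, 1), tolerance = 1e-9)
  pf0 <- positive_fraction_field(cells, rep(FALSE, n), sigma = 6,
                                 template = tem, sample_mask = mask)
  expect_true(all(unclass(pf0) == 0, na.rm = TRUE))
})

test_that("radial profiles are self-consistent", {
  d <- c(40, 40, 40)
  m <- array(FALSE, d); m[5:36, 5:36, 5:36] <- TRUE
  cst <- vox(array(3.3, d))
  p1 <- radial_profile(cst, m, bin_width = 4)
  expect_true(all(abs(p1$mean - 3.3) < 1e-12))

  dist <- distance_to_border(m, c(1, 1, 1))
  p2 <- radial_profile(vox(dist), m, bin_width = 4)
  expect_true(all(abs(p2$mean - p2$bin_mid) <= 2 + 1e-9))
})

test_that("coexpression quadrants partition the cells exactly", {
  set.seed(904)
  n <- 2000
  a_pos <- stats::runif(n) < 0.3
  b_pos <- stats::runif(n) < 0.2
  cells <- data.frame(
    label = seq_len(n),
    mean_a = ifelse(a_pos, stats::rnorm(n, 5, 0.3), stats::rnorm(n, 1, 0.2)),
    mean_b = ifelse(b_pos, stats::rnorm(n, 4, 0.3), stats::rnorm(n, 0.5, 0.2)))
  q <- coexpression_quadrants(cells, "mean_a", "mean_b")
  expect_equal(sum(q$counts), n)
  expect_equal(sort(unlist(q$ids, use.names = FALSE)), 1:n)
  # independent markers: double-positive fraction near p * q = 0.06
  expect_lt(abs(q$fractions["A+", "B+"] - 0.06), 0.015)

  # perfectly correlated markers: everything on the diagonal
  cells2 <- data.frame(label = 1:500, a = c(rnorm(250, 1, .1), rnorm(250, 4, .1)))
  cells2$b <- cells2$a
  q2 <- coexpression_quadrants(cells2, "a", "b")
  expect_equal(unname(q2$correlation["pearson"]), 1, tolerance = 1e-12)
  expect_equal(q2$counts["A+", "B-"] + q2$counts["A-", "B+"], 0)

  # mutually exclusive populations: empty double-positive quadrant
  ex <- data.frame(label = 1:600,
                   a = c(rnorm(300, 5, .2), rnorm(300, 0.5, .1)),
                   b = c(rnorm(300, 0.5, .1), rnorm(300, 4, .2)))
  q3 <- coexpression_quadrants(ex, "a", "b")
  expect_lt(q3$fractions["A+", "B+"], 0.01)

  expect_error(coexpression_quadrants(
    data.frame(label = 1:10, a = rnorm(10), b = rep(1, 10)), "a", "b"),
    "degenerate")
})

test_that("radial profiles are invariant under rigid rotation of the sample", {
  ph <- cached_phantom("clean")
  f <- volume_fraction_field(ph$labels, sigma = 8, sample_mask = ph$mask)
  p0 <- radial_profile(f, ph$mask, bin_width = 5)
  Tz <- rigid_transform(deepvox:::euler_zyx(c(90, 0, 0)),
                        centre = (dim(f) - 1) * vox_spacing(f) / 2)
  fr <- apply_rigid(vox(ifelse(is.na(unclass(f)), 0, unclass(f)),
                        vox_spacing(f)), Tz)
  mr <- apply_rigid(labels3d((ph$mask) * 1L, vox_spacing(f)), Tz)
  p1 <- radial_profile(fr, unclass(mr) > 0, bin_width = 5)
  shared <- seq_len(min(nrow(p0), nrow(p1)))
  expect_lt(max(abs(p0$mean[shared] - p1$mean[shared])), 0.05)
})
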