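test_that("inertia tensor matches the hand-evaluated two-point case", {
  # two voxels along x at +-1 um (axis order z, y, x): r_k^2 = 1 for both, so
  # I = diag(2, 2, 0) by direct evaluation; the ellipsoid fit is degenerate
  two <- rbind(c(0, 0, 1), c(0, 0, -1))
  it <- inertia_tensor(two)
  expect_equal(it$tensor, diag(c(2, 2, 0)), tolerance = 1e-14)
  expect_true(it$degenerate)
  expect_null(semi_axes(it$tensor, 2))  # non-positive bracket is flagged
  # 4 non-coplanar points: compare against direct summation of the formula
  p4 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0.2, 1))
  it4 <- inertia_tensor(p4)
  r <- sweep(p4, 2, colMeans(p4))
  want <- diag(sum(r^2), 3) - crossprod(r)
  expect_equal(it4$tensor, want, tolerance = 1e-12)
  expect_false(it4$degenerate)
})

test_that("a voxelized ball is isotropic with semi-axes equal to its radius", {
  ball <- voxel_ellipsoid(c(3, 3, 3))
  mt <- morphometry_table(ball)
  expect_false(mt$degenerate[1])
  mom <- inertia_tensor(deepvox:::index_to_um(
    arrayInd(which(unclass(ball) > 0), dim(ball)), vox_spacing(ball)))$moments
  expect_lt(diff(range(mom)) / mean(mom), 0.02)
  expect_lt(max(abs(c(mt$L1[1], mt$L2[1], mt$L3[1]) - 3)) / 3, 0.03)
  # true strain of a sphere is the zero matrix
  expect_lt(max(abs(c(mt$T1[1], mt$T2[1], mt$T3[1]))), 0.02)
})

test_that("ellipsoid semi-axes (4, 3, 2) um are recovered within 3%", {
  ell <- voxel_ellipsoid(c(4, 3, 2))
  mt <- morphometry_table(ell)
  expect_lt(abs(mt$L1[1] - 4) / 4, 0.03)
  expect_lt(abs(mt$L2[1] - 3) / 3, 0.03)
  expect_lt(abs(mt$L3[1] - 2) / 2, 0.03)
  # volume consistency: (4/3) pi L1 L2 L3 vs voxel count x voxel volume
  vol_ell <- 4 / 3 * pi * mt$L1[1] * mt$L2[1] * mt$L3[1]
  expect_lt(abs(vol_ell / mt$volume[1] - 1), 0.05)
})

test_that("semi-axes scale linearly with the object", {
  a <- morphometry_table(voxel_ellipsoid(c(4, 3, 2)))
  b <- morphometry_table(voxel_ellipsoid(c(8, 6, 4),
                                         spacing = c(0.5, 0.5, 0.5)))
  expect_equal(c(b$L1, b$L2, b$L3) / c(a$L1, a$L2, a$L3), rep(2, 3),
               tolerance = 0.01)
  # true strain is size independent
  expect_equal(c(b$T1, b$T2, b$T3), c(a$T1, a$T2, a$T3), tolerance = 0.01)
})

test_that("the inertia tensor is equivariant under rotation", {
  th <- 35 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  plain <- voxel_ellipsoid(c(4, 3, 2))
  rot <- voxel_ellipsoid(c(4, 3, 2), R = R)
  ia <- inertia_tensor(deepvox:::index_to_um(
    arrayInd(which(unclass(plain) > 0), dim(plain)), vox_spacing(plain)))
  ib <- inertia_tensor(deepvox:::index_to_um(
    arrayInd(which(unclass(rot) > 0), dim(rot)), vox_spacing(rot)))
  # voxel_ellipsoid treats R's columns as the ellipsoid axes, so the rotated
  # tensor is the conjugation R I R'
  expect_lt(max(abs(R %*% ia$tensor %*% t(R) - ib$tensor)) /
              max(abs(ia$tensor)), 0.02)  # voxelization-limited agreement
  # major axis of the rotated object within 3 degrees of the rotated axis
  mtb <- morphometry_table(rot)
  maj <- c(mtb$major_z, mtb$major_y, mtb$major_x)
  want <- R[, 1]
  ang <- acos(min(1, abs(sum(maj * want))))
  expect_lt(ang * 180 / pi, 3)
})

test_that("true strain follows its closed form and is trace-free", {
  ts <- true_strain(c(2, 1, 1))
  expect_equal(ts$eigenvalues[1], log(4) / 3, tolerance = 1e-12)
  expect_equal(ts$eigenvalues[2:3], rep(-log(2) / 3, 2), tolerance = 1e-12)
  expect_lt(abs(sum(diag(ts$tensor))), 1e-14)
  # uniform scaling leaves the strain unchanged
  expect_equal(true_strain(7 * c(2, 1, 1))$eigenvalues, ts$eigenvalues,
               tolerance = 1e-12)
  expect_error(true_strain(c(2, 0, 1)), "positive")

  ph <- cached_phantom("default")
  mt <- morphometry_table(ph$labels)
  tens <- attr(mt, "strain_tensors")
  tr <- tens[, "zz"] + tens[, "yy"] + tens[, "xx"]
  expect_lt(max(abs(tr[!mt$degenerate])), 1e-12)
})

test_that("phantom morphometry recovers the generated nuclei shapes", {
  ph <- cached_phantom("default")
  mt <- morphometry_table(ph$labels)
  truth <- ph$truth
  keep <- !mt$degenerate & mt$n_voxels > 150
  rel <- abs(mt$L1[keep] - truth$L1[keep]) / truth$L1[keep]
  expect_lt(stats::median(rel), 0.1)
  vol_ell <- 4 / 3 * pi * mt$L1 * mt$L2 * mt$L3
  expect_lt(stats::median(abs(vol_ell[keep] / mt$volume[keep] - 1)), 0.05)
})

test_that("strain fields average tensors; mixed orientations cancel", {
  # identical tensors: the field equals the common tensor everywhere
  set.seed(801)
  pos <- matrix(runif(90, 0, 30), 30, 3)
  ts <- true_strain(c(2, 1, 1))
  t6 <- c(ts$tensor[1, 1], ts$tensor[2, 2], ts$tensor[3, 3],
          ts$tensor[1, 2], ts$tensor[1, 3], ts$tensor[2, 3])
  mor <- data.frame(cz = pos[, 1], cy = pos[, 2], cx = pos[, 3],
                    degenerate = FALSE)
  attr(mor, "strain_tensors") <- matrix(rep(t6, each = 30), 30, 6)
  sf <- strain_field(mor, sigma = 8)
  expect_lt(max(abs(sf$tensors - matrix(rep(t6, each = 30), 30, 6))), 1e-10)
  expect_equal(sf$eigenvalues[1, ], ts$eigenvalues, tolerance = 1e-10)

  # two populations with random orientations: the average tensor shrinks
  set.seed(802)
  n <- 400
  posr <- matrix(runif(3 * n, 0, 20), n, 3)
  tens <- t(vapply(seq_len(n), function(i) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    Tm <- Q %*% diag(ts$eigenvalues) %*% t(Q)
    c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[1, 3], Tm[2, 3])
  }, numeric(6)))
  morr <- data.frame(cz = posr[, 1], cy = posr[, 2], cx = posr[, 3],
                     degenerate = FALSE)
  attr(morr, "strain_tensors") <- tens
  sfr <- strain_field(morr, sigma = 15,
                      output = matrix(c(10, 10, 10), 1, 3))
  expect_lt(max(abs(sfr$eigenvalues[1, ])), 0.2 * max(abs(ts$eigenvalues)))
})

test_that("cos^2 alignment: parallel 1, perpendicular 0, isotropic 1/3", {
  g <- c(0, 0, 2)
  expect_equal(axis_alignment(rbind(c(0, 0, 1), c(0, 0, -3)), g), c(1, 1))
  expect_equal(axis_alignment(rbind(c(1, 0, 0), c(0, 2, 0)), g), c(0, 0))
  set.seed(803)
  n <- 1e5
  axes <- matrix(stats::rnorm(3 * n), n, 3)  # isotropic directions
  expect_lt(abs(mean(axis_alignment(axes, g)) - 1 / 3), 0.005)
  expect_true(is.na(axis_alignment(rbind(c(0, 0, 0)), g)))
})

test_that("boundary-tangential nuclei give a near-zero alignment field", {
  # two-compartment phantom with all nuclei elongated tangentially to the
  # radial density gradient: inside the band around the density step, where
  # the gradient is real (not packing noise), the alignment field must stay
  # near the perpendicular limit 0
  ph <- cached_phantom("aligned")
  mt <- morphometry_table(ph$labels)
  cd <- density_field(ph$labels, sigma = 9, sample_mask = ph$mask)
  # exclude nuclei whose local gradient is below the median norm: where the
  # gradient is packing noise, the angle is meaningless
  al0 <- alignment_field(mt, cd, sigma = 9, min_gradient = 0)
  gthr <- stats::quantile(al0$per_nucleus$gradient_norm, 0.5, na.rm = TRUE)
  al <- alignment_field(mt, cd, sigma = 9, min_gradient = gthr)
  pos <- al$field$positions
  centre <- (dim(ph$mask) - 1) * vox_spacing(ph$labels) / 2
  rad <- sqrt(rowSums(sweep(pos, 2, centre)^2))
  step_r <- ph$spec$step_radius_frac * ph$spec$organoid_radius
  band <- abs(rad - step_r) <= 6
  v <- al$field$cos2[band]
  expect_gt(sum(band), 5)
  expect_lt(stats::median(v, na.rm = TRUE), 0.1)
})
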