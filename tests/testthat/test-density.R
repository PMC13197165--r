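test_that("density of uniformly placed objects approaches N / V", {
  set.seed(701)
  d <- c(40, 40, 40)
  n <- 500
  cents <- data.frame(cz = runif(n, 1, 39), cy = runif(n, 1, 39),
                      cx = runif(n, 1, 39))
  tem <- vox(array(0, d))
  f <- density_field(cents, sigma = 12, sample_mask = array(TRUE, d),
                     template = tem)
  core <- unclass(f)[15:26, 15:26, 15:26]
  expect_lt(abs(mean(core) / (n / prod(d)) - 1), 0.10)
})

test_that("the unmasked impulse density integrates to the object count", {
  # impulses deep enough that no kernel support touches the array border
  d <- c(30, 30, 30)
  set.seed(702)
  cents <- data.frame(cz = runif(7, 13.5, 16.5), cy = runif(7, 13.5, 16.5),
                      cx = runif(7, 13.5, 16.5))
  tem <- vox(array(0, d))
  f <- density_field(cents, sigma = 2, template = tem)
  expect_equal(sum(unclass(f)) * 1, 7, tolerance = 1e-9)  # voxel volume 1 um^3

  # single object: integral 1
  f1 <- density_field(cents[1, ], sigma = 2, template = tem)
  expect_equal(sum(unclass(f1)), 1, tolerance = 1e-12)

  expect_warning(f0 <- density_field(cents[0, ], sigma = 2, template = tem),
                 "no objects")
  expect_true(all(unclass(f0) == 0))
})

test_that("volume fraction field matches the generator packing", {
  ph <- cached_phantom("default")
  vf <- volume_fraction_field(ph$labels, sigma = 12, sample_mask = ph$mask)
  v <- unclass(vf)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  expect_lt(abs(mean(v[ph$mask & !is.na(v)]) - 0.30), 0.02)

  # filled and empty label images give the two extremes
  full <- labels3d(array(1L, c(10, 10, 10)))
  expect_equal(max(abs(unclass(
    volume_fraction_field(full, 3, array(TRUE, c(10, 10, 10)))) - 1)), 0,
    tolerance = 1e-10)
  none <- labels3d(array(0L, c(10, 10, 10)))
  expect_true(all(unclass(
    volume_fraction_field(none, 3, array(TRUE, c(10, 10, 10)))) == 0))
})

test_that("a two-compartment density step is recovered at the right radius", {
  ph <- cached_phantom("tangential")  # inner:outer placement ratio 2
  R <- ph$spec$organoid_radius
  f <- density_field(ph$labels, sigma = 6, sample_mask = ph$mask)
  dist <- distance_to_border(ph$mask, vox_spacing(ph$labels))
  radius <- R - dist  # distance from the sample centre, inside the mask
  v <- unclass(f)
  ok <- ph$mask & !is.na(v)
  shell_mean <- function(lo, hi) mean(v[ok & radius >= lo & radius < hi])
  inner <- shell_mean(0, 0.3 * R)
  outer <- shell_mean(0.7 * R, 0.92 * R)
  expect_gt(inner / outer, 1.3)  # the 2:1 step survives coarse-graining
  # the transition is localised near the programmed step radius R / 2
  rs <- seq(2, R - 2, by = 2)
  prof <- vapply(rs, function(r0) shell_mean(r0 - 2, r0 + 2), numeric(1))
  mid <- (inner + outer) / 2
  cross <- rs[which(diff(sign(prof - mid)) != 0)[1]]
  expect_lt(abs(cross - R / 2), 6)
})

test_that("volume maps average object volumes, not sum them", {
  d <- c(24, 24, 24)
  tem <- vox(array(0, d))
  # two spatially separated populations with volumes v and 2v
  left <- data.frame(cz = rep(12, 20), cy = runif(20, 2, 22),
                     cx = runif(20, 2, 8), volume = 100)
  right <- data.frame(cz = rep(12, 20), cy = runif(20, 2, 22),
                      cx = runif(20, 16, 22), volume = 200)
  obj <- rbind(left, right)
  vm <- volume_map_field(obj, sigma = 3, sample_mask = array(TRUE, d),
                         template = tem)
  v <- unclass(vm)
  expect_lt(max(abs(v[, , 2:6] - 100), na.rm = TRUE), 25)
  expect_lt(max(abs(v[, , 18:22] - 200), na.rm = TRUE), 50)
  # monodisperse volumes give a constant map
  mono <- data.frame(cz = runif(30, 4, 20), cy = runif(30, 4, 20),
                     cx = runif(30, 4, 20), volume = 55)
  vmono <- unclass(volume_map_field(mono, sigma = 4,
                                    sample_mask = array(TRUE, d),
                                    template = tem))
  expect_equal(range(vmono, na.rm = TRUE), c(55, 55), tolerance = 1e-9)
})

test_that("proliferation field is division density over cell density", {
  ph <- cached_phantom("default")
  tr <- ph$truth
  sig <- 12
  cd <- density_field(ph$labels, sig, sample_mask = ph$mask)
  div <- tr[tr$mitotic, c("cz", "cy", "cx")]
  dd <- density_field(div, sig, sample_mask = ph$mask,
                      template = ph$labels)
  pf <- proliferation_field(dd, cd)
  v <- unclass(pf)
  ok <- !is.na(v)
  # pointwise identity with the two inputs
  expect_equal(v[ok], (unclass(dd) / unclass(cd))[ok], tolerance = 1e-12)
  # spatial mean close to the realized mitotic fraction
  realized <- mean(tr$mitotic)
  expect_lt(abs(mean(v[ok & ph$mask]) - realized), 0.01)
  # and the realized fraction is consistent with the Bernoulli rate 0.05
  expect_lt(abs(realized - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(tr)) + 1e-9)

  # all cells mitotic gives 1; none gives 0
  all1 <- proliferation_field(cd, cd)
  expect_equal(range(unclass(all1), na.rm = TRUE), c(1, 1), tolerance = 1e-12)
})

test_that("detection filtering removes specks and out-of-mask events", {
  ph <- cached_phantom("clean")
  lab <- unclass(ph$labels)
  n0 <- max(lab)
  # inject 10 sub-threshold specks (2 voxels each) in free corners
  free <- which(lab == 0L & !ph$mask)
  set.seed(703)
  picked <- sample(free[free < length(lab) - 1], 10)
  for (i in seq_along(picked)) lab[picked[i] + 0:1] <- n0 + i
  labi <- labels3d(lab, vox_spacing(ph$labels))
  filt <- filter_detections(labi, min_volume = 20, sample_mask = ph$mask)
  expect_setequal(attr(filt, "removed"), n0 + 1:10)
  expect_equal(max(unclass(filt)), n0)   # survivors relabelled contiguously

  # nothing below threshold: unchanged count
  same <- filter_detections(ph$labels, min_volume = 20,
                            sample_mask = ph$mask)
  expect_length(attr(same, "removed"), 0)
  expect_equal(max(unclass(same)), n0)

  # an object whose centroid is outside the mask is removed even if large
  lab2 <- unclass(ph$labels)
  corner <- as.integer(n0 + 1)
  lab2[2:4, 2:4, 2:4] <- corner
  filt2 <- filter_detections(labels3d(lab2, vox_spacing(ph$labels)),
                             min_volume = 0, sample_mask = ph$mask)
  expect_true(corner %in% attr(filt2, "removed"))
})

test_that("the sample mask recipe recovers the phantom sphere", {
  ph <- cached_phantom("default")
  m <- sample_mask_from_nuclei(ph$channels[[1]], nucleus_radius = 4.5)
  inter <- sum(m & ph$mask)
  dice <- 2 * inter / (sum(m) + sum(ph$mask))
  expect_gt(dice, 0.95)
  expect_equal(attr(m, "n_components"), 1L)

  expect_warning(b <- sample_mask_from_nuclei(vox(array(0, c(10, 10, 10)))),
                 "blank")
  expect_equal(sum(b), 0)
})

test_that("distance transform and flood fill primitives are exact", {
  set.seed(704)
  m <- array(runif(10^3) > 0.7, c(10, 10, 10))
  sp <- c(2, 1, 1)
  d <- distance_to_border(m, sp)
  idx <- which(m); ai <- arrayInd(idx, dim(m))
  ao <- arrayInd(which(!m), dim(m))
  bf <- vapply(seq_along(idx), function(i)
    sqrt(min(colSums((t(ao) * sp - ai[i, ] * sp)^2))), numeric(1))
  expect_equal(d[idx], bf, tolerance = 1e-12)
  expect_true(all(d[!m] == 0))

  # hole filling: a hollow cube becomes solid
  hollow <- array(FALSE, c(12, 12, 12))
  hollow[3:10, 3:10, 3:10] <- TRUE
  hollow[5:8, 5:8, 5:8] <- FALSE
  filled <- deepvox:::fill_holes3d(hollow)
  expect_true(all(filled[3:10, 3:10, 3:10]))
  expect_equal(sum(filled), 8^3)
})
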