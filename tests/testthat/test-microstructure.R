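make_tf <- function(yy, xx, zz, yx = 0, yz = 0, xz = 0) {
  one <- function(v) array(v, c(1, 1, 1))
  structure(list(yy = one(yy), yx = one(yx), yz = one(yz), xx = one(xx),
                 xz = one(xz), zz = one(zz), dim = c(1L, 1L, 1L),
                 sigma = c(grad = 0.5, tensor = 0.5, fiber = 5)),
            class = "tensor_field")
}

test_that("FA hits its closed-form limits", {
  expect_equal(as.numeric(fractional_anisotropy(make_tf(1, 1, 1))$fa), 0)
  expect_equal(as.numeric(fractional_anisotropy(make_tf(1, 0, 0))$fa), 1)
  # radial analog is the mean of the two minor eigenvalues
  fa <- fractional_anisotropy(make_tf(3, 2, 1))
  expect_equal(as.numeric(fa$radial), 1.5)
  # energy floor forces FA to zero
  fa0 <- fractional_anisotropy(make_tf(1, 0, 0), energy_floor = 10)
  expect_equal(as.numeric(fa0$fa), 0)
})

test_that("eigenvalue closed form agrees with base eigen()", {
  set.seed(51)
  for (i in 1:25) {
    s <- rnorm(6)
    tf <- make_tf(s[1]^2 + 1, s[2]^2 + 1, s[3]^2 + 1, s[4] / 2, s[5] / 2,
                  s[6] / 2)
    ev <- cectquant:::tensor_eigenvalues(tf)
    A <- matrix(c(tf$yy, tf$yx, tf$yz, tf$yx, tf$xx, tf$xz,
                  tf$yz, tf$xz, tf$zz), 3, 3)
    ref <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(c(ev$l1, ev$l2, ev$l3), pmax(ref, 0), tolerance = 1e-8)
  }
})

test_that("constant volumes give zero tensors and FA 0", {
  tf <- structure_tensor(array(500, c(12, 12, 12)), 0.5, 0.5, 2)
  expect_equal(max(abs(tf$yy)), 0)
  expect_equal(max(fractional_anisotropy(tf)$fa), 0)
  expect_error(structure_tensor(array(1, c(4, 30, 30)), 2, 0.5, 2),
               "smaller")
})

test_that("a grating along y concentrates gradient energy on y", {
  d <- c(36L, 36L, 36L)
  vol <- array(2000 + 1000 * sin(2 * pi * seq_len(d[1]) / 9), d)
  tf <- structure_tensor(vol, 0.5, 0.5, 4)
  core <- 10:27
  expect_gt(mean(tf$yy[core, core, core]),
            1e3 * mean(abs(tf$xx[core, core, core])))
  fa <- fractional_anisotropy(tf)
  expect_gt(mean(fa$fa[core, core, core]), 0.8)
  # fiber direction (minor eigenvector) lies in the xz-plane
  idx <- which(array(TRUE, d))[c(20000, 25000, 30000)]
  dirs <- fiber_directions(tf, idx)
  expect_lt(max(abs(dirs[, "y"])), 0.05)
})

test_that("fiber direction along a cylinder is recovered within 5 degrees", {
  d <- c(32L, 32L, 48L)
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  vol <- array(30000, d)
  vol[(Y - 16.5)^2 + (X - 16.5)^2 <= 36] <- 18000
  set.seed(52)
  vol <- vol + rnorm(length(vol), 0, 300)
  tf <- structure_tensor(vol, 0.5, 0.5, 5)
  wall <- (Y - 16.5)^2 + (X - 16.5)^2
  sel <- which(wall >= 16 & wall <= 64 & Z >= 15 & Z <= 35)
  set.seed(53)
  dirs <- fiber_directions(tf, sample(sel, 300))
  ang <- acos(pmin(abs(dirs[, "z"]), 1)) * 180 / pi
  expect_lt(median(ang), 5)
})

test_that("noise yields low FA, aligned lamina high FA, and lower fiber
           contrast lowers FA", {
  set.seed(54)
  noise <- array(rnorm(40^3, 30000, 600), c(40, 40, 40))
  fa_n <- fractional_anisotropy(structure_tensor(noise))
  core <- 10:30
  expect_lt(mean(fa_n$fa[core, core, core]), 0.2)

  lam <- array(20000 + 8000 * sin(2 * pi * seq_len(40) / 8), c(40, 40, 40))
  fa_l <- fractional_anisotropy(structure_tensor(lam))
  expect_gt(mean(fa_l$fa[core, core, core]), 0.8)

  mk <- function(contrast) {
    d <- c(40L, 40L, 40L)
    Y <- array(seq_len(d[1]), d)
    X <- array(rep(seq_len(d[2]), each = d[1]), d)
    vol <- array(30000, d)
    vol[(Y - 20.5)^2 + (X - 20.5)^2 <= 36] <- 30000 - contrast
    set.seed(55)
    vol + rnorm(prod(d), 0, 600)
  }
  fa_hi <- fractional_anisotropy(structure_tensor(mk(12000)))
  fa_lo <- fractional_anisotropy(structure_tensor(mk(6000)))
  expect_lt(mean(fa_lo$fa[core, core, core]),
            mean(fa_hi$fa[core, core, core]))
})

test_that("FA stays within [0, 1] on arbitrary volumes", {
  set.seed(56)
  v <- array(runif(20^3, 0, 65535), c(20, 20, 20))
  fa <- fractional_anisotropy(structure_tensor(v, 0.5, 0.5, 2))
  expect_true(all(fa$fa >= 0 & fa$fa <= 1))
})

test_that("volume fraction recovers analytic fiber content", {
  expect_equal(volume_fraction(array(10, c(4, 4, 4)), threshold = 20,
                               polarity = "hypo"), 1)
  expect_equal(volume_fraction(array(50, c(4, 4, 4)), threshold = 20,
                               polarity = "hypo"), 0)
  ph <- make_fiber_phantom(phantom_spec(grid = c(72L, 72L, 72L),
                                        voxel_size_um = 6, noise_sd = 600,
                                        seed = 57))
  m <- ph$manifest
  vf <- volume_fraction(ph$volume, m$fiber_voi, m$vf_threshold_gray,
                        m$polarity)
  expect_lt(abs(vf - m$vf_analytic), 0.02)
})

test_that("cylinder correlation finds a matching tube and ignores noise", {
  d <- c(36L, 36L, 48L)
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  cyl <- (Y - 18)^2 + (X - 18)^2 <= 25
  vol <- array(30000, d)
  vol[cyl] <- 18000
  set.seed(58)
  vol <- vol + rnorm(length(vol), 0, 400)
  zdir <- matrix(c(0, 0, 1), 1)
  det <- detect_fibers(vol, radii = 5, length = 15, directions = zdir,
                       polarity = "hypo", cutoff = 0.5)
  # correlation is maximal on (and near) the axis
  axis_corr <- det$correlation[18, 18, 24]
  expect_gt(axis_corr, 0.8)
  expect_gt(axis_corr, max(det$correlation) - 0.05)
  # the painted mask covers at least 90% of the cylinder
  expect_gt(mean(unclass(det$mask)[cyl]), 0.9)

  # pure noise: nothing at the same cutoff
  set.seed(59)
  nv <- array(rnorm(prod(d), 30000, 600), d)
  det_n <- detect_fibers(nv, radii = 5, length = 15, directions = zdir,
                         polarity = "hypo", cutoff = 0.5)
  expect_lt(mean(unclass(det_n$mask)), 0.01)

  # flipped polarity sees (almost) nothing
  det_f <- detect_fibers(vol, radii = 5, length = 15, directions = zdir,
                         polarity = "hyper", cutoff = 0.5)
  expect_lt(mean(unclass(det_f$mask)), 0.01)
})

test_that("watershed labeling separates bundles and tolerates empty masks", {
  d <- c(30L, 30L, 40L)
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  one <- (Y - 15)^2 + (X - 15)^2 <= 16
  vol <- array(30000, d); vol[one] <- 18000
  zdir <- matrix(c(0, 0, 1), 1)
  det1 <- detect_fibers(vol, radii = 4, length = 11, directions = zdir,
                        polarity = "hypo", cutoff = 0.5)
  lab1 <- label_fibers(det1$mask, det1$correlation, min_separation = 4)
  expect_equal(lab1$n_labels, 1L)

  d2 <- c(30L, 44L, 40L)
  Y2 <- array(seq_len(d2[1]), d2)
  X2 <- array(rep(seq_len(d2[2]), each = d2[1]), d2)
  vol2 <- array(30000, d2)
  vol2[(Y2 - 15)^2 + (X2 - 13)^2 <= 16] <- 18000
  vol2[(Y2 - 15)^2 + (X2 - 32)^2 <= 16] <- 18000
  det2 <- detect_fibers(vol2, radii = 4, length = 11, directions = zdir,
                        polarity = "hypo", cutoff = 0.5)
  lab2 <- label_fibers(det2$mask, det2$correlation, min_separation = 4)
  expect_equal(lab2$n_labels, 2L)
  # every mask voxel is labeled
  expect_true(all(lab2$labels[unclass(det2$mask) == 1] > 0))

  empty <- label_fibers(array(0L, d), array(0, d))
  expect_equal(empty$n_labels, 0L)
})

test_that("local thickness matches analytic diameters and the brute-force
           oracle", {
  cyl <- digit_cylinder(5, 40)
  th <- fiber_thickness(cyl, 6)
  expect_lt(abs(th$per_label$thickness_um - 60), 6)
  expect_equal(th$median_um, th$per_label$thickness_um)

  for (R in c(2, 4)) {
    ball <- digit_ball(R)
    thb <- fiber_thickness(ball, 1)
    expect_lt(abs(thb$per_label$thickness_um - (2 * R + 1)), 1)
  }

  lab1 <- array(0L, c(5, 5, 5)); lab1[3, 3, 3] <- 1L
  expect_equal(fiber_thickness(lab1, 1)$per_label$thickness_um, 1)

  set.seed(60)
  m <- array(as.integer(rnorm(14^3) > 0.3), c(14L, 14L, 14L))
  thc <- cectquant:::cpp_local_thickness(m, dim(m))
  expect_equal(as.numeric(thc[m == 1]), oracle_thickness(m))

  # invariance to gray rescaling: thickness depends only on labels
  expect_equal(fiber_thickness(cyl, 6)$median_um, th$median_um)
})

test_that("rotating a fiber phantom rotates the modal fiber direction", {
  d <- c(40L, 40L, 40L)
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  vol <- array(30000, d)
  vol[(Y - 20.5)^2 + (X - 20.5)^2 <= 36] <- 18000
  v <- gray_volume(vol, 6)
  rot <- reorient(v, c(0, 90, 0), order = "zyx", interpolation = "nearest")
  # cylinder axis z rotates onto x under a 90-degree rotation about y
  tf <- structure_tensor(rot, 0.5, 0.5, 4)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  sel <- which((Y - 20.5)^2 + (Z - 20.5)^2 >= 16 &
                 (Y - 20.5)^2 + (Z - 20.5)^2 <= 64 & X >= 15 & X <= 25)
  set.seed(61)
  dirs <- fiber_directions(tf, sample(sel, 200))
  ang <- acos(pmin(abs(dirs[, "x"]), 1)) * 180 / pi
  expect_lt(median(ang), 10)
})

test_that("regional gray report normalizes and detects demyelination", {
  base <- make_fiber_phantom(phantom_spec(grid = c(72L, 72L, 72L),
                                          voxel_size_um = 6,
                                          noise_sd = 600, seed = 62))
  dem <- make_fiber_phantom(phantom_spec(grid = c(72L, 72L, 72L),
                                         voxel_size_um = 6,
                                         noise_sd = 600, seed = 62,
                                         fiber = list(demyelination = 0.6)))
  m <- base$manifest
  refs_b <- measure_reference_grays(base$volume, m$refs$bead, m$refs$tube,
                                    m$refs$air)
  refs_d <- measure_reference_grays(dem$volume, m$refs$bead, m$refs$tube,
                                    m$refs$air)
  rep_b <- regional_gray_report(base$volume, refs_b, m$regions)
  rep_same <- regional_gray_report(base$volume, refs_b, m$regions,
                                   baseline = rep_b)
  expect_equal(rep_same$pct_change, rep(0, 4))
  rep_d <- regional_gray_report(dem$volume, refs_d, m$regions,
                                baseline = rep_b)
  expect_true(all(rep_d$pct_change > 0)) # demyelination raises gray values
  expect_error(regional_gray_report(dem$volume, refs_d, m$regions,
                                    baseline = rep_b[1:2, ]),
               "missing regions")
  refs_bad <- refs_b; refs_bad$G_B <- refs_bad$G_E
  expect_error(regional_gray_report(base$volume, refs_bad, m$regions),
               "degenerate")
})
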