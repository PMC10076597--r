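test_that("spherical approximation matches hand-computed cube roots", {
  # unit sphere fully stained
  k1 <- spherical_kinetics(V_e = 4 * pi / 3, V_u = 0)
  expect_equal(k1$R_e, 1, tolerance = 1e-12)
  expect_equal(k1$r_p, 1, tolerance = 1e-12)
  # nothing stained
  k2 <- spherical_kinetics(V_e = 2.5, V_u = 2.5)
  expect_equal(k2$r_p, 0, tolerance = 1e-12)
  # 2:1 radius ratio
  k3 <- spherical_kinetics(V_e = 8 * 4 * pi / 3, V_u = 4 * pi / 3)
  expect_equal(k3$R_e, 2, tolerance = 1e-12)
  expect_equal(k3$r_u, 1, tolerance = 1e-12)
  expect_equal(k3$r_p, 1, tolerance = 1e-12)
  expect_error(spherical_kinetics(1, 2), "V_u")
  expect_error(spherical_kinetics(0, 0), "V_e")
})

test_that("radii reconstruct the input volumes (round trip) and r_p is
           monotone in V_u", {
  set.seed(21)
  V_e <- 10
  V_us <- sort(runif(10, 0, V_e))
  ks <- lapply(V_us, function(vu) spherical_kinetics(V_e, vu))
  for (k in ks) {
    expect_equal(4 / 3 * pi * k$R_e^3, k$V_e, tolerance = 1e-12)
    expect_equal(4 / 3 * pi * k$r_u^3, k$V_u, tolerance = 1e-12)
  }
  rps <- vapply(ks, `[[`, 0, "r_p")
  expect_true(all(diff(rps) <= 0))
})

test_that("decay fit recovers noiseless parameters to 1e-6 and passes
           through the origin", {
  t <- c(1, 2, 4, 9)
  rp <- 2 * (1 - exp(-0.5 * t))
  f <- fit_penetration_decay(t, rp)
  expect_true(f$converged)
  expect_lt(abs(f$R_e_hat - 2), 1e-6)
  expect_lt(abs(f$k - 0.5), 1e-6)
  expect_equal(predict(f, 0), 0)
  expect_error(fit_penetration_decay(c(1, 2), c(0.1, 0.2)), "3 distinct")
})

test_that("decay fit under noise keeps median asymptote error below 5%", {
  set.seed(22)
  t <- c(1, 2, 4, 9)
  errs <- replicate(50, {
    rp <- pmax(2 * (1 - exp(-0.5 * t)) + rnorm(4, 0, 0.05), 0)
    abs(fit_penetration_decay(t, rp)$R_e_hat - 2) / 2
  })
  expect_lt(median(errs), 0.05)
})

test_that("a flat penetration series is flagged as unidentifiable", {
  f <- fit_penetration_decay(c(1, 2, 4, 9), rep(1.5, 4))
  expect_false(f$converged)
  expect_true(f$at_bound)
})

test_that("volume change series is relative to the first time point", {
  vs <- volume_change_series(c(1, 2, 4), c(10, 10, 10))
  expect_equal(vs$pct_change, c(0, 0, 0))
  vs2 <- volume_change_series(c(1, 2), c(5, 10))
  expect_equal(vs2$pct_change, c(0, 100))
  # a 7% linear scale factor on radii is a 22.5% volume change
  vs3 <- volume_change_series(c(1, 9), c(3, 3 * 1.07^3))
  expect_equal(vs3$pct_change[2], (1.07^3 - 1) * 100, tolerance = 1e-9)
  expect_error(volume_change_series(1, 10), "2 time points")
  expect_error(volume_change_series(c(1, 2), c(1, -2)), "> 0")
})

test_that("mask volume arithmetic is exact", {
  m <- array(0L, c(20, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
  expect_equal(measure_volume(m, 10), 1000 * (10 / 1000)^3)
  expect_equal(measure_volume(array(0L, c(4, 4, 4)), 10), 0)
  ball <- digit_ball(20, pad = 2L)
  expect_lt(abs(sum(ball) / (4 / 3 * pi * 20^3) - 1), 0.01)
})

test_that("tissue segmentation keeps the largest blob and fails on
           background-only input", {
  a <- array(1000, c(30, 30, 30))
  a[3:20, 3:20, 3:20] <- 30000  # big blob with a cavity
  a[8:12, 8:12, 8:12] <- 2000   # internal hole, must be filled
  a[24:26, 24:26, 24:26] <- 30000 # small blob, must vanish
  v <- gray_volume(a, 6)
  m <- segment_tissue(v, "fixed", threshold = 10000)
  expect_equal(sum(m), 18^3)
  expect_equal(unclass(m)[10, 10, 10], 1L) # hole filled
  expect_equal(unclass(m)[25, 25, 25], 0L) # minor blob gone
  expect_error(segment_tissue(gray_volume(array(10, c(8, 8, 8)), 6),
                              "fixed", threshold = 500), "empty foreground")
})

test_that("stain threshold derivation follows the tissue percentile", {
  tis <- vox_mask(array(TRUE, c(10, 10, 10)))
  vc <- gray_volume(array(7777, c(10, 10, 10)), 6)
  expect_equal(derive_stain_threshold(vc, tis)$value, 7777)
  ramp <- gray_volume(array(seq_len(1000), c(10, 10, 10)), 6)
  thr <- derive_stain_threshold(ramp, tis, percentile = 1)
  expect_equal(thr$value, oracle_percentile(seq_len(1000), 1))
  thr0 <- derive_stain_threshold(ramp, tis, percentile = 0)
  expect_equal(thr0$value, 1)
})

test_that("stained segmentation splits tissue at the threshold", {
  v <- rand_gray_volume(c(10L, 10L, 10L), seed = 23, lo = 5000, hi = 20000)
  tis <- vox_mask(array(TRUE, dim(v)))
  all_st <- segment_stained(v, tis, 5000)
  expect_equal(sum(all_st), length(v)) # thr <= min: everything stained
  none <- segment_stained(v, tis, 20001)
  expect_equal(sum(none), 0)           # thr > max: V_u = V_e
})

test_that("a sharp-front shell phantom yields the analytic core volume", {
  spec <- phantom_spec(front_blur_vox = 0, noise_sd = 0, seed = 31)
  sc <- make_scene(spec, t = 1)
  man <- sc$manifest
  tis <- segment_tissue(sc$volume, "fixed",
                        threshold = (man$grays$solution +
                                       man$grays$stained) / 2,
                        exclude = list(man$vois$bead))
  expect_lt(abs(measure_volume(tis, man$voxel_size_um) / man$V_e_mm3 - 1),
            0.02)
  st <- segment_stained(sc$volume, tis, (man$grays$unstained +
                                           man$grays$stained) / 2)
  V_u <- measure_volume(tis, man$voxel_size_um) -
    measure_volume(st, man$voxel_size_um)
  expect_lt(abs(V_u / man$V_u_mm3 - 1), 0.03)
})
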