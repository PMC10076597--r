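test_that("auto window matches the brute-force percentile oracle", {
  v <- rand_gray_volume(c(14L, 13L, 11L), seed = 11)
  w <- auto_window(v, 0, 100)
  expect_equal(w$low, min(v))
  expect_equal(w$high, max(v))
  w2 <- auto_window(v, 0.1, 99.9)
  g <- as.numeric(v)
  expect_equal(w2$low, oracle_percentile(g, 0.1))
  expect_equal(w2$high, oracle_percentile(g, 99.9))
  expect_error(auto_window(gray_volume(array(5, c(3, 3, 3)), 6), 0, 100),
               "degenerate")
  expect_error(auto_window(v, 50, 10))
})

test_that("windowing maps linearly with clipping and half-up rounding", {
  w <- window_spec(100, 1100)
  v <- gray_volume(array(c(50, 100, 600, 1100, 5000, 350),
                         c(6, 1, 1)), 6, 16L)
  out <- as.numeric(apply_window(v, w))
  expect_equal(out[2], 0)   # value = low
  expect_equal(out[4], 255) # value = high
  expect_equal(out[3], 128) # midpoint rounds half up
  expect_equal(out[1], 0)   # clipped below
  expect_equal(out[5], 255) # clipped above
  expect_equal(out[6], floor((350 - 100) / 1000 * 255 + 0.5))

  # monotone non-decreasing against the input ordering
  vr <- rand_gray_volume(c(10L, 10L, 10L), seed = 12)
  wr <- auto_window(vr, 1, 99)
  o <- order(as.numeric(vr))
  mapped <- as.numeric(apply_window(vr, wr))[o]
  expect_true(all(diff(mapped) >= 0))
})

test_that("full-range window uses the whole 8-bit scale", {
  v <- rand_gray_volume(c(8L, 8L, 8L), seed = 13)
  v8 <- apply_window(v, auto_window(v, 0, 100))
  expect_equal(min(v8), 0)
  expect_equal(max(v8), 255)
})

test_that("normalized gray value hits its defining endpoints", {
  refs <- reference_grays(G_B = 40000, G_E = 10000)
  expect_equal(normalized_gray(10000, refs), 0)
  expect_equal(normalized_gray(40000, refs), 1)
  expect_equal(normalized_gray(25000, refs), 0.5)
  expect_error(reference_grays(G_B = 10000, G_E = 10000), "G_B > G_E")
})

test_that("normalized gray value is affine invariant", {
  set.seed(14)
  for (i in 1:20) {
    G <- sort(runif(3, 0, 60000)) # air-ish, tube, bead
    a <- runif(1, 0.2, 3); b <- runif(1, -500, 5000)
    g1 <- normalized_gray(G[1], reference_grays(G[3], G[2]))
    g2 <- normalized_gray(a * G[1] + b,
                          reference_grays(a * G[3] + b, a * G[2] + b))
    expect_equal(g1, g2, tolerance = 1e-9)
  }
})

test_that("reference measurement: exact on constants, overlap rejected", {
  v <- gray_volume(array(5000, c(20, 20, 20)), 6)
  a <- unclass(v); a[1:4, 1:4, 1:4] <- 50000; a[10:13, 10:13, 10:13] <- 9000
  a[16:19, 16:19, 16:19] <- 1000
  v <- gray_volume(a, 6)
  bead <- voi_box(y = c(1, 4), x = c(1, 4), z = c(1, 4))
  tube <- voi_box(y = c(10, 13), x = c(10, 13), z = c(10, 13))
  air <- voi_box(y = c(16, 19), x = c(16, 19), z = c(16, 19))
  refs <- measure_reference_grays(v, bead, tube, air)
  expect_equal(refs$G_B, 50000)
  expect_equal(refs$G_E, 9000)
  expect_equal(refs$G_air, 1000)
  expect_equal(refs$sd_B, 0)
  expect_equal(refs$n_B, 64L)
  expect_error(measure_reference_grays(v, bead, bead, air), "overlap")
})

test_that("reference means under noise agree within sampling error", {
  set.seed(15)
  d <- c(24L, 24L, 24L)
  a <- array(9000, d)
  a[1:10, 1:10, 1:10] <- 45000
  a <- a + rnorm(prod(d), 0, 400)
  v <- gray_volume(pmin(pmax(round(a), 0), 65535), 6)
  bead <- voi_box(y = c(2, 9), x = c(2, 9), z = c(2, 9))
  tube <- voi_box(y = c(14, 23), x = c(14, 23), z = c(14, 23))
  refs <- measure_reference_grays(v, bead, tube)
  expect_lt(abs(refs$G_B - 45000), 3 * 400 / sqrt(refs$n_B))
  expect_lt(abs(refs$G_E - 9000), 3 * 400 / sqrt(refs$n_E))
})

test_that("reference-based rescaling recovers an affine-distorted dataset", {
  anchor <- rand_gray_volume(c(16L, 16L, 16L), seed = 16,
                             lo = 3000, hi = 50000)
  a <- unclass(anchor)
  a[1:4, 1:4, 1:4] <- 1000       # air
  a[12:15, 12:15, 12:15] <- 9000 # tube
  anchor <- gray_volume(a, 6)
  distorted <- gray_volume(round(0.8 * a + 2000), 6)
  tube <- voi_box(y = c(12, 15), x = c(12, 15), z = c(12, 15))
  air <- voi_box(y = c(1, 4), x = c(1, 4), z = c(1, 4))
  refs <- lapply(list(anchor, distorted), measure_reference_grays,
                 bead_voi = voi_box(y = c(7, 8), x = c(7, 8), z = c(7, 8)),
                 tube_voi = tube, air_voi = air)
  out <- normalize_to_references(list(anchor, distorted), refs, anchor = 1)
  expect_identical(unclass(out[[1]]), unclass(anchor)) # anchor untouched
  expect_lte(max(abs(unclass(out[[2]]) - unclass(anchor))), 2)

  # equal tube and air grays are degenerate
  flat <- gray_volume(array(9000, c(16, 16, 16)), 6)
  refs_flat <- list(refs[[1]],
                    reference_grays(G_B = 9001, G_E = 9000, G_air = 9000))
  refs_flat[[2]]$G_air <- 9000; refs_flat[[2]]$G_E <- 9000
  expect_error(normalize_to_references(list(anchor, flat), refs_flat, 1),
               "degenerate")
})

test_that("rescaling makes normalized tissue grays agree across datasets", {
  anchor <- rand_gray_volume(c(16L, 16L, 16L), seed = 17,
                             lo = 3000, hi = 50000)
  a <- unclass(anchor)
  a[1:4, 1:4, 1:4] <- 1000; a[12:15, 12:15, 12:15] <- 9000
  a[6:9, 6:9, 6:9] <- 52000 # bead
  anchor <- gray_volume(a, 6)
  other <- gray_volume(pmin(round(1.2 * a + 1500), 65535), 6)
  bead <- voi_box(y = c(6, 9), x = c(6, 9), z = c(6, 9))
  tube <- voi_box(y = c(12, 15), x = c(12, 15), z = c(12, 15))
  air <- voi_box(y = c(1, 4), x = c(1, 4), z = c(1, 4))
  refs <- lapply(list(anchor, other), measure_reference_grays,
                 bead_voi = bead, tube_voi = tube, air_voi = air)
  out <- normalize_to_references(list(anchor, other), refs, anchor = 1)
  refs_out <- lapply(out, measure_reference_grays, bead_voi = bead,
                     tube_voi = tube, air_voi = air)
  roi <- voi_box(y = c(2, 5), x = c(10, 13), z = c(2, 5))
  g <- vapply(1:2, function(i)
    normalized_gray(roi_stats(out[[i]], roi)$mu, refs_out[[i]]), 0)
  expect_equal(g[1], g[2], tolerance = 0.01)
})
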