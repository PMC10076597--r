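#' Phantom specification
#'
#' Ground-truth generative model for synthetic CECT scenes: a quasi-spherical
#' hemisphere (a convex ellipsoidal blob) immersed in staining solution inside a sample
#' tube, with a ceramic bead and air in the field of view, a stained shell
#' that advances inward following exponential-decay front kinetics, optional
#' volume swelling/shrinkage over time, a parallel fiber-bundle system with
#' configurable contrast polarity and demyelination, and additive Gaussian
#' acquisition noise. Every scene returns a manifest with the analytic
#' ground truth for all downstream metrics, and a fixed seed makes output
#' bit-identical.
#'
#' Default gray levels (16-bit, 0 = air-like no attenuation): air 1000,
#' staining solution 8000, tube wall 12000, unstained tissue 18000, stained
#' tissue 32000, ceramic bead 52000; fiber scenes use background (gray
#' matter) 30000 and hypointense fibers 18000. The default noise SD, 700
#' gray values, is 5% of the stained/unstained tissue contrast.
#'
#' @param grid lattice dimensions `(ny, nx, nz)`.
#' @param voxel_size_um voxel edge, micrometers.
#' @param radii_mm hemisphere semi-axes (y, x, z) in mm.
#' @param k front growth rate (1/day).
#' @param R_e asymptotic penetration depth (mm); `NULL` uses the
#'   sphere-equivalent radius of the hemisphere, so staining saturates
#'   exactly when the front meets the center.
#' @param swelling_pct_per_day volume change per day, percent (volume-based;
#'   +7 means the tissue volume grows 7% per day).
#' @param grays named list overriding compartment gray levels.
#' @param front_blur_vox Gaussian blur of the scene (voxels), emulating the
#'   finite PSF; 0 gives sharp interfaces.
#' @param noise_sd Gaussian noise SD in gray values.
#' @param fiber list overriding the fiber system: `orientation` (unit
#'   vector, y/x/z), `radius_um`, `target_vf`, `polarity` ("hypo"/"hyper"),
#'   `demyelination` in `[0, 1]` (0 healthy, 1 contrast fully erased),
#'   `jitter_vox` center jitter.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(128L, 128L, 96L), voxel_size_um = 40,
                         radii_mm = c(1.6, 1.7, 1.5), k = 0.5, R_e = NULL,
                         swelling_pct_per_day = 0, grays = list(),
                         front_blur_vox = 1, noise_sd = 700,
                         fiber = list(), seed = 1L) {
  g <- list(air = 1000, solution = 8000, tube = 12000, unstained = 18000,
            stained = 32000, bead = 52000, background = 30000,
            fiber = 18000)
  g[names(grays)] <- grays
  stopifnot(all(unlist(g) >= 0), all(unlist(g) <= 65535))
  fib <- list(orientation = c(0, 0, 1), radius_um = 30, target_vf = 0.20,
              polarity = "hypo", demyelination = 0, jitter_vox = 1.5)
  fib[names(fiber)] <- fiber
  fib$orientation <- fib$orientation / sqrt(sum(fib$orientation^2))
  if (fib$demyelination < 0 || fib$demyelination > 1)
    stop("demyelination factor must be in [0, 1]", call. = FALSE)
  structure(list(grid = as.integer(grid), voxel_size_um = voxel_size_um,
                 radii_mm = radii_mm, k = k, R_e = R_e,
                 swelling_pct_per_day = swelling_pct_per_day, grays = g,
                 front_blur_vox = front_blur_vox, noise_sd = noise_sd,
                 fiber = fib, seed = seed),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

finish_scene <- function(scene, spec, seed) {
  d <- dim(scene)
  if (spec$front_blur_vox > 0)
    scene <- array(cpp_gauss_smooth(scene, d, spec$front_blur_vox), d)
  clip_frac <- 0
  if (spec$noise_sd > 0) {
    noisy <- with_seed(seed,
                       scene + stats::rnorm(length(scene), 0, spec$noise_sd))
    clip_frac <- mean(noisy < 0 | noisy > 65535)
    scene <- pmin(pmax(noisy, 0), 65535)
  }
  list(vol = gray_volume(array(round(scene), d), spec$voxel_size_um, 16L),
       clip_frac = clip_frac)
}

#' Generate a staining-kinetics scene
#'
#' Builds the hemisphere-in-tube scene at staining time `t` days. The
#' stained shell's depth follows `r_p(t) = R_e (1 - exp(-k t))` on the
#' sphere-equivalent scale: the unstained core is the hemisphere scaled so
#' that its sphere-equivalent radius is `R_e(t) - r_p(t)`, which makes the
#' spherical volume relations exact by construction even though the
#' specimen is not a perfect sphere. Swelling is applied as a volume scale
#' factor `(1 + s/100)^t` on the specimen.
#'
#' @param spec a [phantom_spec()].
#' @param t staining time in days (>= 0).
#' @param seed overrides `spec$seed` (used by [make_timeseries()] to vary
#'   noise across time points).
#' @return List with `volume` (16-bit [gray_volume()]) and `manifest`
#'   (analytic truths: `V_e_mm3`, `V_u_mm3`, `R_e_sph_mm`, `r_u_mm`,
#'   `r_p_mm`, compartment grays, reference and solution VOIs, clip
#'   fraction, seed).
#' @export
make_scene <- function(spec, t, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), t >= 0)
  d <- spec$grid
  vox_mm <- spec$voxel_size_um / 1000
  g <- spec$grays

  swell <- (1 + spec$swelling_pct_per_day / 100)^t
  if (swell <= 0) stop("swelling factor drove the volume to zero",
                       call. = FALSE)
  rad <- spec$radii_mm * swell^(1 / 3)
  V_e <- 4 / 3 * pi * prod(rad)
  R_sph <- (3 * V_e / (4 * pi))^(1 / 3)
  R_kin <- if (is.null(spec$R_e)) R_sph else spec$R_e
  r_p <- min(R_kin * (1 - exp(-spec$k * t)), R_sph)
  r_u <- max(R_sph - r_p, 0)
  s_u <- r_u / R_sph # core scale; V_u = s_u^3 V_e exactly
  V_u <- s_u^3 * V_e

  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2, d[3] / 2)
  tube_inner_vox <- 54; tube_outer_vox <- 58
  rad_vox <- rad / vox_mm
  if (ctr[3] - rad_vox[3] < 3 || ctr[3] + rad_vox[3] > d[3] - 2 ||
      max(rad_vox[1:2]) >= tube_inner_vox - 4)
    stop("specimen geometry exceeds the grid/tube", call. = FALSE)

  yy <- seq_len(d[1]) - ctr[1]
  xx <- seq_len(d[2]) - ctr[2]
  r_2d <- sqrt(outer(yy^2, xx^2, `+`))
  scene2d_air <- r_2d > tube_outer_vox
  scene2d_tube <- r_2d > tube_inner_vox & !scene2d_air

  scene <- array(g$solution, d)
  for (k3 in seq_len(d[3])) {
    sl <- scene[, , k3]
    sl[scene2d_tube] <- g$tube
    sl[scene2d_air] <- g$air
    scene[, , k3] <- sl
  }

  # specimen: quasi-spherical convex blob (full ellipsoid); the stained
  # shell advances inward from the whole surface, the unstained core is the
  # concentric similar ellipsoid so V_u = s_u^3 V_e exactly
  zz <- seq_len(d[3]) - ctr[3]
  E <- outer(outer((yy / rad_vox[1])^2, (xx / rad_vox[2])^2, `+`),
             (zz / rad_vox[3])^2, `+`)
  scene[E <= 1] <- g$stained
  if (s_u > 0) {
    Eu <- outer(outer((yy / (rad_vox[1] * s_u))^2,
                      (xx / (rad_vox[2] * s_u))^2, `+`),
                (zz / (rad_vox[3] * s_u))^2, `+`)
    scene[Eu <= 1] <- g$unstained
  }

  # ceramic bead between specimen and tube wall, on the -y/-x diagonal
  bead_c <- c(ctr[1] - 34, ctr[2] - 34, 20)
  bead_r <- 4
  zb <- seq_len(d[3]) - bead_c[3]
  B <- outer(outer((seq_len(d[1]) - bead_c[1])^2,
                   (seq_len(d[2]) - bead_c[2])^2, `+`), zb^2, `+`)
  scene[B <= bead_r^2] <- g$bead

  fin <- finish_scene(scene, spec, seed)
  manifest <- list(
    t = t, V_e_mm3 = V_e, V_u_mm3 = V_u, R_e_sph_mm = R_sph,
    r_u_mm = r_u, r_p_mm = r_p, R_e_kin_mm = R_kin, k = spec$k,
    swell_factor = swell, grays = g, voxel_size_um = spec$voxel_size_um,
    clip_frac = fin$clip_frac, seed = seed,
    vois = list(
      bead = voi_sphere(bead_c, bead_r - 1.5),
      tube = voi_box(y = round(ctr[1]) + c(-3, 2),
                     x = round(ctr[2]) + c(55, 57), z = c(30, 49)),
      air = voi_box(y = c(3, 10), x = c(3, 10), z = c(30, 49)),
      solution = voi_box(y = round(ctr[1]) + c(-5, 4),
                         x = c(13, 16), z = c(25, 45))))
  list(volume = fin$vol, manifest = manifest)
}

#' Generate a staining time series
#'
#' One scene per time point from a shared spec, with independent noise
#' (seed offset by the time index) so replicates behave like separate
#' acquisitions of the same specimen.
#'
#' @param spec a [phantom_spec()].
#' @param times staining times in days (default the 1, 2, 4, 9 day design).
#' @return List of `make_scene` results, one per time point.
#' @export
make_timeseries <- function(spec, times = c(1, 2, 4, 9)) {
  lapply(seq_along(times), function(i)
    make_scene(spec, times[i],
               seed = if (is.null(spec$seed)) NULL else spec$seed + i))
}

#' Generate a fiber-bundle phantom
#'
#' A block of gray matter containing parallel white-matter fiber bundles
#' (cylinders spanning the volume along the fiber orientation), reference
#' materials in the corners, and Gaussian noise. Bundle contrast polarity is
#' configurable: hypointense bundles emulate a stain repelled by myelin,
#' hyperintense bundles one attracted to it. The demyelination factor `d`
#' moves the bundle gray level toward the background by `d` times the
#' healthy contrast, emulating increased stain uptake after myelin loss;
#' the fixed segmentation threshold is always derived from the healthy
#' gray levels. Bundle centers sit on a deterministic quadrant layout with
#' seeded jitter so that every report region contains bundles.
#'
#' @param spec a [phantom_spec()]; the fiber system is taken from
#'   `spec$fiber`, grays from `spec$grays` (`background`, `fiber`, `bead`,
#'   `tube`, `air`), noise and seed from the spec. The grid defaults to a
#'   compact block; pass `grid = c(72, 72, 72)` scale for tests.
#' @return List with `volume`, and `manifest` carrying: per-cylinder axes
#'   (`centers_yx`, `orientation`), `radius_vox`, analytic and voxelized
#'   volume fraction in `fiber_voi`, per-cylinder voxel index lists
#'   (`fiber_voxels`), the fixed segmentation threshold
#'   (`vf_threshold_gray`, healthy-based), effective fiber gray, reference
#'   VOIs, report `regions` (caudal/rostral x medial/lateral), `fa_voi`,
#'   and the clip fraction.
#' @export
make_fiber_phantom <- function(spec = phantom_spec(grid = c(72L, 72L, 72L),
                                                   voxel_size_um = 6,
                                                   noise_sd = 600)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid
  g <- spec$grays
  fib <- spec$fiber
  r_vox <- fib$radius_um / spec$voxel_size_um
  if (fib$target_vf > 0.5)
    stop("target volume fraction above 0.5 is not packable", call. = FALSE)

  # fiber VOI: central box, cylinders fully inside its cross-section
  m <- ceiling(r_vox) + 2
  lo <- m + 6; hi <- d[1] - m - 5
  fiber_voi <- voi_box(y = c(lo, hi), x = c(lo, hi))
  A <- (hi - lo + 1)^2
  n_cyl <- max(1L, round(fib$target_vf * A / (pi * r_vox^2)))
  vf_analytic <- n_cyl * pi * r_vox^2 / A

  # regular grid layout + seeded jitter, cylinders fully inside the VOI
  qlo <- lo + r_vox + fib$jitter_vox + 0.5
  qhi <- hi - r_vox - fib$jitter_vox - 0.5
  ncol_g <- ceiling(sqrt(n_cyl))
  nrow_g <- ceiling(n_cyl / ncol_g)
  gxs <- if (ncol_g == 1) (qlo + qhi) / 2 else
    seq(qlo, qhi, length.out = ncol_g)
  gys <- if (nrow_g == 1) (qlo + qhi) / 2 else
    seq(qlo, qhi, length.out = nrow_g)
  base_centers <- as.matrix(expand.grid(y = gys, x = gxs))[seq_len(n_cyl),
                                                           , drop = FALSE]
  centers <- with_seed(spec$seed, {
    jit <- matrix(stats::runif(2 * n_cyl, -fib$jitter_vox, fib$jitter_vox),
                  ncol = 2)
    base_centers + jit
  })
  if (n_cyl > 1 && min(stats::dist(centers)) < 2 * r_vox + 1)
    stop("unachievable packing: bundles overlap", call. = FALSE)

  fiber_gray <- g$fiber + fib$demyelination * (g$background - g$fiber)
  if (fib$polarity == "hyper")
    fiber_gray <- g$fiber - fib$demyelination * (g$fiber - g$background)

  scene <- array(g$background, d)
  u <- fib$orientation
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  fiber_voxels <- vector("list", n_cyl)
  for (i in seq_len(n_cyl)) {
    p0 <- c(centers[i, 1], centers[i, 2], (d[3] + 1) / 2)
    dy <- Y - p0[1]; dx <- X - p0[2]; dz <- Z - p0[3]
    ax <- dy * u[1] + dx * u[2] + dz * u[3]
    rad2 <- dy^2 + dx^2 + dz^2 - ax^2
    inside <- rad2 <= r_vox^2
    scene[inside] <- fiber_gray
    fiber_voxels[[i]] <- which(inside)
  }

  # reference materials: corner columns (bead, tube plastic, air)
  ref_box <- function(y, x) voi_box(y = y, x = x, z = c(5, d[3] - 4))
  corners <- list(bead = ref_box(c(2, 9), c(2, 9)),
                  tube = ref_box(c(d[1] - 8, d[1] - 1), c(2, 9)),
                  air = ref_box(c(2, 9), c(d[2] - 8, d[2] - 1)))
  paint_box <- function(w, value) {
    r <- voi_ranges(w, d)
    scene[r$y[1]:r$y[2], r$x[1]:r$x[2], r$z[1]:r$z[2]] <<- value
  }
  paint_box(corners$bead, g$bead)
  paint_box(corners$tube, g$tube)
  paint_box(corners$air, g$air)

  fin <- finish_scene(scene, spec, spec$seed)

  fvm <- unclass(voi_mask(fin$vol, fiber_voi))
  all_fib <- Reduce(union, fiber_voxels, integer(0))
  vf_voxelized <- length(intersect(all_fib, which(fvm == 1))) / sum(fvm)

  zr <- round(d[3] * c(0.14, 0.48, 0.52, 0.86))
  xr <- round(c(lo, lo + (hi - lo) * 0.45, lo + (hi - lo) * 0.55, hi))
  regions <- list(
    caudal_medial  = voi_box(y = c(lo, hi), x = c(xr[1], xr[2]),
                             z = c(zr[1], zr[2])),
    caudal_lateral = voi_box(y = c(lo, hi), x = c(xr[3], xr[4]),
                             z = c(zr[1], zr[2])),
    rostral_medial = voi_box(y = c(lo, hi), x = c(xr[1], xr[2]),
                             z = c(zr[3], zr[4])),
    rostral_lateral = voi_box(y = c(lo, hi), x = c(xr[3], xr[4]),
                              z = c(zr[3], zr[4])))

  ctr <- (d + 1) / 2
  fa_voi <- voi_sphere(ctr, min(25, floor((d[3] - 2) / 2)))

  manifest <- list(
    centers_yx = centers, orientation = u, radius_vox = r_vox,
    n_cylinders = n_cyl, fiber_voi = fiber_voi,
    vf_analytic = vf_analytic, vf_voxelized = vf_voxelized,
    fiber_voxels = fiber_voxels,
    fiber_gray = fiber_gray, background_gray = g$background,
    vf_threshold_gray = (g$fiber + g$background) / 2,
    polarity = fib$polarity, demyelination = fib$demyelination,
    refs = corners, regions = regions, fa_voi = fa_voi,
    voxel_size_um = spec$voxel_size_um, noise_sd = spec$noise_sd,
    clip_frac = fin$clip_frac, seed = spec$seed)
  list(volume = fin$vol, manifest = manifest)
}
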