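#' Fiber volume fraction in a VOI
#'
#' Fraction of VOI voxels on the fiber side of a fixed gray-value
#' threshold. With a negatively charged agent (Hexabrix-like) myelinated
#' fibers repel the stain and are hypointense (fiber = gray `<=`
#' threshold); with a positively charged agent (CA4+-like) they are weakly
#' hyperintense (fiber = gray `>=` threshold). The threshold must be on the
#' same scale as `v` (16-bit reference-matched gray, or the dimensionless
#' normalized scale if `v` is already normalized) and is held constant
#' across datasets.
#'
#' @param v a [gray_volume()] or 3D numeric array.
#' @param voi optional VOI (default: whole volume).
#' @param threshold gray cutoff on the scale of `v`.
#' @param polarity `"hypo"` or `"hyper"`.
#' @return Fraction in `[0, 1]`.
#' @export
volume_fraction <- function(v, voi = NULL, threshold,
                            polarity = c("hypo", "hyper")) {
  polarity <- match.arg(polarity)
  a <- if (inherits(v, "gray_volume")) as_volume_array(v) else v
  g <- if (is.null(voi)) as.numeric(a) else {
    m <- voi_mask(a, voi)
    as.numeric(a[unclass(m) == 1])
  }
  if (length(g) == 0) stop("empty VOI", call. = FALSE)
  if (polarity == "hypo") mean(g <= threshold) else mean(g >= threshold)
}

# Deterministic near-uniform directions on the upper hemisphere: the poles
# plus a Fibonacci lattice sized to the requested angular step.
hemisphere_directions <- function(angular_step_deg) {
  step <- angular_step_deg * pi / 180
  n <- max(1L, as.integer(round(2 * pi / step^2)))
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n) - 0.5
  z <- k / n            # upper hemisphere only
  rho <- sqrt(pmax(1 - z^2, 0))
  th <- gold * (seq_len(n) - 1)
  dirs <- cbind(y = rho * sin(th), x = rho * cos(th), z = z)
  rbind(c(0, 0, 1), dirs)
}

# binary cylinder membership offsets inside a ball support of radius rb
cylinder_offsets <- function(dir, radius, half_len, rb) {
  R <- as.integer(ceiling(rb))
  s <- seq(-R, R)
  dy <- rep(s, times = (2 * R + 1)^2)
  dx <- rep(rep(s, each = 2 * R + 1), times = 2 * R + 1)
  dz <- rep(s, each = (2 * R + 1)^2)
  ball <- dy^2 + dx^2 + dz^2 <= rb^2
  dy <- dy[ball]; dx <- dx[ball]; dz <- dz[ball]
  ax <- dy * dir[1] + dx * dir[2] + dz * dir[3]
  rad2 <- dy^2 + dx^2 + dz^2 - ax^2
  inside <- abs(ax) <= half_len & rad2 <= radius^2
  list(dy = dy, dx = dx, dz = dz, inside = inside)
}

# embed values at integer offsets into a D-sized array centered at the
# origin with wraparound (for FFT correlation)
embed_kernel <- function(off, values, D) {
  k <- array(0, D)
  idx <- cbind(off$dy %% D[1], off$dx %% D[2], off$dz %% D[3]) + 1L
  k[idx] <- values
  k
}

fft_corr <- function(FV, kernel) {
  n <- length(kernel)
  Re(stats::fft(FV * Conj(stats::fft(kernel)), inverse = TRUE)) / n
}

#' Detect tubular (fiber-like) structures by cylinder correlation
#'
#' Normalized cross-correlation of oriented cylindrical templates against
#' the volume, maximized per voxel over a set of orientations and template
#' radii. Voxels whose best correlation reaches `cutoff` form the detection
#' core; the returned detection mask is the union of the best-matching
#' oriented template footprints painted at the core voxels, which
#' reconstructs the full tube cross-section around the high-correlation
#' centerline.
#'
#' @param v a [gray_volume()] or 3D array.
#' @param voi optional VOI; detection is restricted to its bounding box.
#' @param radii template radius or radii in voxels (>= 1).
#' @param length template length in voxels (>= 3).
#' @param angular_step_deg angular sampling of orientations (ignored when
#'   `directions` is given).
#' @param directions optional matrix of unit direction vectors
#'   (columns y, x, z), one per row, overriding the automatic sampling.
#' @param polarity `"hypo"` (dark tubes; volume is inverted before
#'   correlation) or `"hyper"` (bright tubes).
#' @param cutoff correlation threshold in `[-1, 1]`.
#' @return List with `mask` (painted [vox_mask()]), `core` (correlation
#'   `>=` cutoff), `correlation` (per-voxel max NCC array), `best_dir`
#'   (index array into `directions`), `best_radius`, `directions`.
#' @export
detect_fibers <- function(v, voi = NULL, radii = 5, length = 15,
                          angular_step_deg = 30, directions = NULL,
                          polarity = c("hyper", "hypo"), cutoff = 0.5) {
  polarity <- match.arg(polarity)
  if (any(radii < 1) || length < 3)
    stop("need radii >= 1 voxel and length >= 3 voxels", call. = FALSE)
  a <- if (inherits(v, "gray_volume")) as_volume_array(v) else v
  full_dim <- dim(a)
  if (!is.null(voi)) {
    r <- voi_ranges(voi, full_dim)
    a <- a[r$y[1]:r$y[2], r$x[1]:r$x[2], r$z[1]:r$z[2], drop = FALSE]
  }
  d <- dim(a)
  half_len <- length / 2
  rb <- sqrt(max(radii)^2 + half_len^2) + 0.5
  if (any(d < 2 * ceiling(rb) + 1))
    stop("template larger than the VOI", call. = FALSE)
  if (is.null(directions)) directions <- hemisphere_directions(angular_step_deg)
  if (polarity == "hypo") a <- max(a) - a

  pad <- as.integer(ceiling(rb))
  D <- d + 2L * pad
  # edge-replicate padding so tubes reaching the VOI border continue
  # smoothly instead of terminating against a constant fill
  yi <- pmin(pmax(seq_len(D[1]) - pad, 1L), d[1])
  xi <- pmin(pmax(seq_len(D[2]) - pad, 1L), d[2])
  zi <- pmin(pmax(seq_len(D[3]) - pad, 1L), d[3])
  ap <- a[yi, xi, zi, drop = FALSE]
  FV <- stats::fft(ap)
  FV2 <- stats::fft(ap^2)

  # support ball local statistics (shared by all orientations)
  off0 <- cylinder_offsets(c(0, 0, 1), max(radii), half_len, rb)
  nball <- base::length(off0$dy)
  ones <- embed_kernel(off0, rep(1, nball), D)
  S1 <- fft_corr(FV, ones)
  S2 <- fft_corr(FV2, ones)
  locvar <- pmax(S2 - S1^2 / nball, 0)

  best <- array(-Inf, D)
  best_dir <- array(0L, D)
  best_rad <- array(NA_real_, D)
  for (di in seq_len(nrow(directions))) {
    u <- directions[di, ] / sqrt(sum(directions[di, ]^2))
    for (rr in radii) {
      off <- cylinder_offsets(u, rr, half_len, rb)
      tvals <- as.numeric(off$inside)
      t0 <- tvals - mean(tvals)
      nrm <- sqrt(sum(t0^2))
      if (nrm == 0) next
      kern <- embed_kernel(off, t0 / nrm, D)
      ncc <- fft_corr(FV, kern) / sqrt(pmax(locvar, 1e-12))
      ncc[locvar <= 1e-9] <- 0
      upd <- ncc > best
      best[upd] <- ncc[upd]
      best_dir[upd] <- di
      best_rad[upd] <- rr
    }
  }
  crop <- function(x) x[pad + seq_len(d[1]), pad + seq_len(d[2]),
                        pad + seq_len(d[3]), drop = FALSE]
  corr <- pmin(pmax(crop(best), -1), 1)
  bdir <- crop(best_dir)
  brad <- crop(best_rad)
  core <- corr >= cutoff

  # paint the best-matching template footprint at every core voxel
  painted <- array(FALSE, d)
  if (any(core)) {
    for (di in sort(unique(bdir[core]))) {
      u <- directions[di, ] / sqrt(sum(directions[di, ]^2))
      for (rr in sort(unique(brad[core & bdir == di]))) {
        sel <- core & bdir == di & brad == rr
        selp <- array(0, D)
        selp[pad + seq_len(d[1]), pad + seq_len(d[2]),
             pad + seq_len(d[3])] <- as.numeric(sel)
        off <- cylinder_offsets(u, rr, half_len, rb)
        foot <- embed_kernel(off, as.numeric(off$inside), D)
        # correlation of the core with the (symmetric-flipped) footprint
        hit <- Re(stats::fft(stats::fft(selp) * stats::fft(foot),
                             inverse = TRUE)) / base::length(foot)
        painted <- painted | (crop(hit) > 0.5)
      }
    }
  }
  list(mask = vox_mask(painted,
                       provenance = sprintf("cylinder-correlation cutoff=%g",
                                            cutoff)),
       core = vox_mask(core, provenance = "cylinder-correlation core"),
       correlation = corr, best_dir = bdir, best_radius = brad,
       directions = directions)
}

#' Label fiber bundles by marker-based watershed inside a mask
#'
#' Markers are the regional maxima of the correlation map inside the mask
#' (minimum separation configurable, plateau ties broken toward the lowest
#' linear voxel index); the watershed then floods the inverted correlation
#' map restricted to the mask, so every mask voxel receives a label.
#'
#' @param mask a [vox_mask()] (or logical array) of detected fibers.
#' @param correlation correlation (or any seeding score) array congruent
#'   with `mask`.
#' @param min_separation minimum marker separation in voxels (defaults to
#'   the template radius used upstream, 5).
#' @return A `fiber_labels`: list with `labels` (integer array, background
#'   0), `n_labels`, `voxels` (per-label voxel counts).
#' @export
label_fibers <- function(mask, correlation, min_separation = 5) {
  m <- array(as.integer(unclass(mask) != 0), dim(correlation))
  d <- dim(correlation)
  if (!any(m == 1)) {
    return(structure(list(labels = array(0L, d), n_labels = 0L,
                          voxels = integer(0)), class = "fiber_labels"))
  }
  # quantize the score so exact plateaus survive FFT round-off (one marker
  # per plateau, lowest linear index)
  score <- round(as.numeric(correlation), 6)
  markers <- cpp_local_maxima(score, m, d, as.numeric(min_separation))
  lab <- cpp_watershed(-as.numeric(correlation), markers, m, d, 26L)
  # any mask voxel left unlabeled (marker-free component) gets its own label
  orphan <- m == 1 & lab == 0
  if (any(orphan)) {
    extra <- cpp_label_components(array(as.integer(orphan), d), d, 26L)
    lab[orphan] <- max(lab) + extra[orphan]
  }
  counts <- tabulate(lab[lab > 0])
  structure(list(labels = lab, n_labels = length(counts), voxels = counts),
            class = "fiber_labels")
}

#' Fiber bundle thickness (inscribed-sphere local thickness)
#'
#' Local thickness at a voxel is the diameter of the largest sphere that
#' fits entirely inside the structure and contains the voxel, computed from
#' the Euclidean distance transform; a bundle's thickness is the mean local
#' thickness over its voxels, and the overall summary is the median across
#' bundles, in micrometers.
#'
#' @param labels a `fiber_labels` from [label_fibers()], or an integer label
#'   array.
#' @param voxel_size_um voxel size in micrometers.
#' @return List with `per_label` (data frame: label, n_voxels,
#'   thickness_um), `median_um`, and the voxelwise `thickness_map` (um).
#' @export
fiber_thickness <- function(labels, voxel_size_um) {
  lab <- if (inherits(labels, "fiber_labels")) labels$labels else labels
  d <- dim(lab)
  if (!any(lab > 0)) stop("no labels to measure", call. = FALSE)
  m <- array(as.integer(lab > 0), d)
  th <- cpp_local_thickness(m, d) # voxel units
  ids <- sort(unique(lab[lab > 0]))
  per <- data.frame(
    label = ids,
    n_voxels = vapply(ids, function(i) sum(lab == i), 0L),
    thickness_um = vapply(ids, function(i) mean(th[lab == i]), 0) *
      voxel_size_um)
  list(per_label = per,
       median_um = stats::median(per$thickness_um),
       thickness_map = th * voxel_size_um)
}
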