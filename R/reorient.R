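#' Reorient (rotate and resample) a volume
#'
#' Rigid rotation about the volume center, resampled onto the same voxel
#' grid. Used to align the coronal plane with the xy slice plane before
#' regional gray-value and microstructure analyses. Angles are intrinsic
#' Euler rotations applied in the order given by `order` (default `"zyx"`:
#' first about z, then y, then x). Voxels that map outside the field of view
#' are set to 0, the attenuation of air.
#'
#' @param v a [gray_volume()].
#' @param angles_deg numeric length 3, rotation angles in degrees for the
#'   axes named in `order`.
#' @param order axis order string, a permutation of `"zyx"`.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A [gray_volume()] with the same dimensions and voxel size.
#' @export
reorient <- function(v, angles_deg, order = "zyx",
                     interpolation = c("linear", "nearest")) {
  stopifnot(inherits(v, "gray_volume"), length(angles_deg) == 3L)
  interpolation <- match.arg(interpolation)
  axes <- strsplit(order, "")[[1]]
  if (length(axes) != 3L || !setequal(axes, c("x", "y", "z")))
    stop("`order` must be a permutation of \"zyx\"", call. = FALSE)
  R <- diag(3)
  for (i in 1:3) R <- R %*% rot_axis(axes[i], angles_deg[i] * pi / 180)

  d <- dim(v)
  a <- as_volume_array(v)
  ctr <- (d + 1) / 2
  Y <- array(seq_len(d[1]), d)
  X <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  # inverse mapping: source = R^T (target - center) + center (R orthogonal)
  Rt <- t(R)
  yc <- Y - ctr[1]; xc <- X - ctr[2]; zc <- Z - ctr[3]
  sy <- Rt[1, 1] * yc + Rt[1, 2] * xc + Rt[1, 3] * zc + ctr[1]
  sx <- Rt[2, 1] * yc + Rt[2, 2] * xc + Rt[2, 3] * zc + ctr[2]
  sz <- Rt[3, 1] * yc + Rt[3, 2] * xc + Rt[3, 3] * zc + ctr[3]
  rm(Y, X, Z, yc, xc, zc)

  out <- if (interpolation == "nearest") {
    sample_nearest(a, d, round(sy), round(sx), round(sz))
  } else {
    sample_trilinear(a, d, sy, sx, sz)
  }
  out <- pmin(pmax(out, 0), bit_range(bit_depth(v)))
  gray_volume(array(out, d), voxel_size(v), bit_depth(v))
}

# rotation matrices act on (y, x, z) coordinate triples: the named axis is
# the invariant one
rot_axis <- function(axis, th) {
  c0 <- cos(th); s0 <- sin(th)
  switch(axis,
    z = matrix(c(c0, -s0, 0, s0, c0, 0, 0, 0, 1), 3, byrow = TRUE),
    x = matrix(c(c0, 0, s0, 0, 1, 0, -s0, 0, c0), 3, byrow = TRUE),
    y = matrix(c(1, 0, 0, 0, c0, -s0, 0, s0, c0), 3, byrow = TRUE))
}

sample_nearest <- function(a, d, sy, sx, sz) {
  ok <- sy >= 1 & sy <= d[1] & sx >= 1 & sx <= d[2] & sz >= 1 & sz <= d[3]
  out <- numeric(length(a))
  idx <- sy[ok] + d[1] * (sx[ok] - 1) + d[1] * d[2] * (sz[ok] - 1)
  out[ok] <- a[idx]
  out
}

sample_trilinear <- function(a, d, sy, sx, sz) {
  y0 <- floor(sy); x0 <- floor(sx); z0 <- floor(sz)
  fy <- sy - y0; fx <- sx - x0; fz <- sz - z0
  out <- numeric(length(a))
  gather <- function(yy, xx, zz) {
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2] & zz >= 1 & zz <= d[3]
    g <- numeric(length(a))
    g[ok] <- a[yy[ok] + d[1] * (xx[ok] - 1) + d[1] * d[2] * (zz[ok] - 1)]
    g
  }
  for (dy in 0:1) for (dx in 0:1) for (dz in 0:1) {
    w <- (if (dy) fy else 1 - fy) * (if (dx) fx else 1 - fx) *
         (if (dz) fz else 1 - fz)
    out <- out + w * gather(y0 + dy, x0 + dx, z0 + dz)
  }
  out
}
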