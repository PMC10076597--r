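#' Volumes of interest
#'
#' A VOI is either a box (inclusive 1-based voxel ranges per axis) or a
#' sphere (center voxel + radius in voxels), optionally restricted to a slice
#' interval (slab). VOIs must lie fully inside the parent lattice when used.
#'
#' @param y,x,z length-2 inclusive voxel ranges `c(first, last)`. For
#'   `voi_box`, any axis may be `NULL` meaning the full extent.
#' @param center length-3 voxel coordinate `c(y, x, z)` of the sphere center.
#' @param radius sphere radius in voxels (> 0).
#' @param slices optional length-2 inclusive slice interval for slab VOIs.
#' @return An object of class `voi`.
#' @export
voi_box <- function(y = NULL, x = NULL, z = NULL) {
  chk <- function(r, nm) {
    if (is.null(r)) return(NULL)
    if (length(r) != 2L || any(r < 1) || r[2] < r[1])
      stop("invalid ", nm, " range", call. = FALSE)
    as.integer(r)
  }
  structure(list(kind = "box", y = chk(y, "y"), x = chk(x, "x"),
                 z = chk(z, "z")),
            class = "voi")
}

#' @rdname voi_box
#' @export
voi_sphere <- function(center, radius, slices = NULL) {
  if (length(center) != 3L || radius <= 0)
    stop("sphere VOI needs a length-3 center and radius > 0", call. = FALSE)
  if (!is.null(slices) && (length(slices) != 2L || slices[2] < slices[1]))
    stop("invalid slice interval", call. = FALSE)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius),
                 slices = if (is.null(slices)) NULL else as.integer(slices)),
            class = "voi")
}

voi_ranges <- function(voi, dim) {
  full <- function(n) c(1L, n)
  if (voi$kind == "box") {
    r <- list(y = if (is.null(voi$y)) full(dim[1]) else voi$y,
              x = if (is.null(voi$x)) full(dim[2]) else voi$x,
              z = if (is.null(voi$z)) full(dim[3]) else voi$z)
  } else {
    c0 <- voi$center; rad <- voi$radius
    r <- list(y = c(ceiling(c0[1] - rad), floor(c0[1] + rad)),
              x = c(ceiling(c0[2] - rad), floor(c0[2] + rad)),
              z = c(ceiling(c0[3] - rad), floor(c0[3] + rad)))
    if (!is.null(voi$slices))
      r$z <- c(max(r$z[1], voi$slices[1]), min(r$z[2], voi$slices[2]))
  }
  for (ax in 1:3)
    if (r[[ax]][1] < 1 || r[[ax]][2] > dim[ax])
      stop("VOI out of bounds on axis ", c("y", "x", "z")[ax], call. = FALSE)
  r
}

#' Logical membership mask of a VOI
#'
#' @param v a [gray_volume()] (or any 3D array) giving the parent lattice.
#' @param voi a [voi_box()] or [voi_sphere()].
#' @return A [vox_mask()] congruent with `v`.
#' @export
voi_mask <- function(v, voi) {
  d <- dim(v)
  r <- voi_ranges(voi, d)
  m <- array(FALSE, d)
  if (voi$kind == "box") {
    m[r$y[1]:r$y[2], r$x[1]:r$x[2], r$z[1]:r$z[2]] <- TRUE
  } else {
    ys <- r$y[1]:r$y[2]; xs <- r$x[1]:r$x[2]; zs <- r$z[1]:r$z[2]
    c0 <- voi$center
    d2 <- outer(outer((ys - c0[1])^2, (xs - c0[2])^2, `+`),
                (zs - c0[3])^2, `+`)
    m[ys, xs, zs] <- d2 <= voi$radius^2
  }
  vox_mask(m, provenance = paste0("voi:", voi$kind))
}

#' Extract a VOI as a sub-volume
#'
#' Returns the sub-lattice covered by the VOI (for spheres, the bounding box
#' of the sphere, with the spherical membership mask attached as attribute
#' `"mask"`).
#'
#' @inheritParams voi_mask
#' @return A [gray_volume()]; for sphere VOIs with a congruent `vox_mask` in
#'   `attr(, "mask")`.
#' @export
extract_voi <- function(v, voi) {
  stopifnot(inherits(v, "gray_volume"))
  d <- dim(v)
  r <- voi_ranges(voi, d)
  a <- as_volume_array(v)
  sub <- a[r$y[1]:r$y[2], r$x[1]:r$x[2], r$z[1]:r$z[2], drop = FALSE]
  out <- gray_volume(sub, voxel_size(v), bit_depth(v))
  if (voi$kind == "sphere") {
    ys <- r$y[1]:r$y[2]; xs <- r$x[1]:r$x[2]; zs <- r$z[1]:r$z[2]
    c0 <- voi$center
    d2 <- outer(outer((ys - c0[1])^2, (xs - c0[2])^2, `+`),
                (zs - c0[3])^2, `+`)
    attr(out, "mask") <- vox_mask(d2 <= voi$radius^2, "voi:sphere")
  }
  out
}

#' Gray values inside a VOI or mask
#'
#' @param v a [gray_volume()].
#' @param roi a `voi`, a `vox_mask`, or a logical/0-1 array congruent with
#'   `v`.
#' @return Numeric vector of gray values.
#' @export
voi_values <- function(v, roi) {
  if (inherits(roi, "voi")) roi <- voi_mask(v, roi)
  if (!is.array(roi) || !all(dim(roi) == dim(v)))
    stop("ROI must be a voi or an array congruent with the volume",
         call. = FALSE)
  as.numeric(unclass(v)[roi != 0])
}
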