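#' Gradient structure tensor field of a volume
#'
#' Computes per-voxel orientation tensors from image gradients, the
#' DTI-like analysis used to quantify white-matter fiber orientation in
#' gray-value volumes. Three Gaussian scales control the estimate, all in
#' voxel units: `sigma_grad` for the Gaussian-derivative gradients,
#' `sigma_tensor` for smoothing the gradient outer products into the local
#' orientation tensor, and `sigma_fiber` for a second smoothing that
#' aggregates the tensor to the fiber-bundle scale. Because image gradients
#' are perpendicular to fiber axes, the fiber direction at a voxel is the
#' eigenvector of the smallest eigenvalue. Defaults follow the mouse-brain
#' settings (0.5, 0.5, 5).
#'
#' @param v a [gray_volume()] or 3D numeric array.
#' @param sigma_grad,sigma_tensor,sigma_fiber Gaussian scales in voxels
#'   (> 0).
#' @return A `tensor_field`: list of the six upper-triangle component arrays
#'   `yy, yx, yz, xx, xz, zz` of the fiber-scale tensor, the same six of the
#'   pre-aggregation tensor in `$local`, plus `dim` and the scales used.
#' @export
structure_tensor <- function(v, sigma_grad = 0.5, sigma_tensor = 0.5,
                             sigma_fiber = 5) {
  if (any(c(sigma_grad, sigma_tensor, sigma_fiber) <= 0))
    stop("all sigmas must be > 0", call. = FALSE)
  a <- if (inherits(v, "gray_volume")) as_volume_array(v) else v
  d <- dim(a)
  if (any(d < 6 * sigma_grad))
    stop("volume smaller than 6*sigma_grad in some axis", call. = FALSE)
  storage.mode(a) <- "double"
  gy <- cpp_gauss_smooth(a, d, sigma_grad, 0L)
  gx <- cpp_gauss_smooth(a, d, sigma_grad, 1L)
  gz <- cpp_gauss_smooth(a, d, sigma_grad, 2L)
  sm <- function(u, s) cpp_gauss_smooth(u, d, s)
  local <- list(yy = sm(gy * gy, sigma_tensor),
                yx = sm(gy * gx, sigma_tensor),
                yz = sm(gy * gz, sigma_tensor),
                xx = sm(gx * gx, sigma_tensor),
                xz = sm(gx * gz, sigma_tensor),
                zz = sm(gz * gz, sigma_tensor))
  fiber <- lapply(local, sm, s = sigma_fiber)
  structure(c(fiber,
              list(local = local, dim = d,
                   sigma = c(grad = sigma_grad, tensor = sigma_tensor,
                             fiber = sigma_fiber))),
            class = "tensor_field")
}

# Sorted eigenvalues (descending) of the per-voxel symmetric tensors,
# vectorized closed form (trigonometric method for symmetric 3x3).
tensor_eigenvalues <- function(tf) {
  A11 <- as.numeric(tf$yy); A12 <- as.numeric(tf$yx); A13 <- as.numeric(tf$yz)
  A22 <- as.numeric(tf$xx); A23 <- as.numeric(tf$xz); A33 <- as.numeric(tf$zz)
  q <- (A11 + A22 + A33) / 3
  p2 <- (A11 - q)^2 + (A22 - q)^2 + (A33 - q)^2 +
    2 * (A12^2 + A13^2 + A23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    B11 <- (A11[nz] - q[nz]) / p[nz]; B22 <- (A22[nz] - q[nz]) / p[nz]
    B33 <- (A33[nz] - q[nz]) / p[nz]
    B12 <- A12[nz] / p[nz]; B13 <- A13[nz] / p[nz]; B23 <- A23[nz] / p[nz]
    detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
      B13 * (B12 * B23 - B22 * B13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  list(l1 = pmax(l1, 0), l2 = pmax(l2, 0), l3 = pmax(l3, 0))
}

#' Fractional anisotropy of a tensor field
#'
#' The standard DTI fractional anisotropy applied to the sorted eigenvalues
#' of the fiber-scale structure tensor:
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, in `[0, 1]`
#' (0 isotropic, 1 a single dominant direction). Voxels whose tensor trace
#' (gradient energy) is at or below `energy_floor` get FA 0. The radial
#' diffusivity analog is the mean of the two minor eigenvalues.
#'
#' @param tf a `tensor_field` from [structure_tensor()].
#' @param energy_floor trace cutoff below which FA is set to 0. The default
#'   `1e-8` (squared gray values per voxel) only suppresses numerically-zero
#'   tensors, e.g. in perfectly flat regions; raise it to mask weak-gradient
#'   background.
#' @return An `fa_result`: list with arrays `fa` and `radial`, and the
#'   eigenvalue arrays `l1 >= l2 >= l3`.
#' @export
fractional_anisotropy <- function(tf, energy_floor = 1e-8) {
  stopifnot(inherits(tf, "tensor_field"))
  ev <- tensor_eigenvalues(tf)
  l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(3 / 2) * sqrt(ifelse(den > 0, num / den, 0))
  fa[(l1 + l2 + l3) <= energy_floor] <- 0
  fa <- pmin(fa, 1)
  d <- tf$dim
  structure(list(fa = array(fa, d),
                 radial = array((l2 + l3) / 2, d),
                 l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d)),
            class = "fa_result")
}

#' Fiber directions at selected voxels
#'
#' The per-voxel fiber axis: the eigenvector of the smallest eigenvalue of
#' the fiber-scale tensor (gradients are perpendicular to the fiber).
#' Intended for sampling orientations in a region, not for whole-volume
#' maps.
#'
#' @param tf a `tensor_field`.
#' @param idx linear voxel indices at which to extract directions.
#' @return Matrix `length(idx) x 3` of unit vectors, columns `(y, x, z)`.
#' @export
fiber_directions <- function(tf, idx) {
  stopifnot(inherits(tf, "tensor_field"))
  out <- matrix(NA_real_, length(idx), 3,
                dimnames = list(NULL, c("y", "x", "z")))
  for (i in seq_along(idx)) {
    j <- idx[i]
    A <- matrix(c(tf$yy[j], tf$yx[j], tf$yz[j],
                  tf$yx[j], tf$xx[j], tf$xz[j],
                  tf$yz[j], tf$xz[j], tf$zz[j]), 3, 3)
    e <- eigen(A, symmetric = TRUE)
    vec <- e$vectors[, 3]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    out[i, ] <- vec
  }
  out
}
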