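#' Segment the whole tissue volume
#'
#' Binarizes the specimen (e.g. a hemisphere immersed in staining solution)
#' from the surrounding scene. In place of interactive region-growing tools,
#' the segmentation is fully automatic and reproducible: threshold (Otsu on
#' a 256-bin histogram, or a fixed gray value), keep the largest
#' 26-connected component, fill internal cavities (6-connected background),
#' optionally excluding reference-material VOIs beforehand.
#'
#' @param v a [gray_volume()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold gray value for `method = "fixed"` (voxels `>=` threshold
#'   are foreground).
#' @param exclude optional list of VOIs (reference materials) removed from
#'   the foreground before component analysis.
#' @return A [vox_mask()] of the tissue.
#' @export
segment_tissue <- function(v, method = c("otsu", "fixed"), threshold = NULL,
                           exclude = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(v, "gray_volume"))
  a <- as_volume_array(v)
  if (method == "otsu") {
    threshold <- otsu_threshold(as.numeric(a), bit_range(bit_depth(v)))
  } else if (is.null(threshold)) {
    stop("method = \"fixed\" requires `threshold`", call. = FALSE)
  }
  fg <- a >= threshold
  if (!is.null(exclude))
    for (w in exclude) fg[unclass(voi_mask(v, w)) == 1] <- FALSE
  if (!any(fg)) stop("empty foreground: no voxel above threshold",
                     call. = FALSE)
  lab <- cpp_label_components(array(as.integer(fg), dim(a)), dim(a), 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m <- array(as.integer(lab == keep), dim(a))
  m <- cpp_fill_holes(m, dim(a))
  vox_mask(m, provenance = sprintf(
    "segment_tissue:%s thr=%.6g largest-cc-26 hole-fill-6", method,
    threshold))
}

#' Physical volume of a mask
#'
#' `voxel count * (voxel_size_um / 1000)^3`, in cubic millimeters.
#'
#' @param m a [vox_mask()] or logical/0-1 array.
#' @param voxel_size_um voxel size in micrometers.
#' @return Volume in mm^3.
#' @export
measure_volume <- function(m, voxel_size_um) {
  if (voxel_size_um <= 0) stop("voxel size must be > 0", call. = FALSE)
  sum(m != 0) * (voxel_size_um / 1000)^3
}

#' Derive the stain threshold from the fully stained end point
#'
#' The gray value above which tissue counts as stained, taken as a low
#' percentile (default 1st) of the tissue gray values at the final time
#' point, i.e. the least attenuating part of the tissue after complete
#' staining. The percentile rather than the strict minimum buffers against
#' noise outliers.
#'
#' @param v_final [gray_volume()] of the fully stained end point.
#' @param tissue tissue [vox_mask()].
#' @param percentile percentile in `[0, 100]`, default 1.
#' @return A `stain_threshold`: list with `value`, `percentile`, `source`.
#' @export
derive_stain_threshold <- function(v_final, tissue, percentile = 1) {
  stopifnot(inherits(v_final, "gray_volume"))
  g <- voi_values(v_final, tissue)
  if (length(g) == 0) stop("empty tissue mask", call. = FALSE)
  thr <- gray_percentile(g, percentile)
  structure(list(value = thr, percentile = percentile,
                 source = "final-time-point tissue percentile"),
            class = "stain_threshold")
}

#' Segment stained tissue
#'
#' Stained = tissue voxels with gray `>=` threshold; the unstained volume is
#' the tissue volume minus the stained volume.
#'
#' @param v a [gray_volume()].
#' @param tissue tissue [vox_mask()].
#' @param thr a `stain_threshold` from [derive_stain_threshold()], or a
#'   plain gray value.
#' @return A [vox_mask()] of stained tissue.
#' @export
segment_stained <- function(v, tissue, thr) {
  if (inherits(thr, "stain_threshold")) thr <- thr$value
  a <- as_volume_array(v)
  m <- (a >= thr) & (unclass(tissue) != 0)
  vox_mask(m, provenance = sprintf("segment_stained thr=%.6g", thr))
}

#' Spherical approximation of the staining front
#'
#' The specimen is approximated as a sphere from its total and unstained
#' volumes: the radius of the entire sphere is `R_e = (3 V_e / 4 pi)^(1/3)`,
#' the unstained core radius `r_u = (3 V_u / 4 pi)^(1/3)`, and the depth of
#' the penetration front is their difference `r_p = R_e - r_u`.
#'
#' @param V_e entire tissue volume (mm^3, > 0).
#' @param V_u unstained volume (mm^3, `0 <= V_u <= V_e`).
#' @param t time in days (carried through to the result).
#' @return A `spherical_kinetics`: list with `t`, `V_e`, `V_u`, `R_e`,
#'   `r_u`, `r_p` (mm).
#' @export
spherical_kinetics <- function(V_e, V_u, t = NA_real_) {
  if (V_e <= 0) stop("V_e must be > 0", call. = FALSE)
  if (V_u < 0 || V_u > V_e)
    stop("V_u must satisfy 0 <= V_u <= V_e", call. = FALSE)
  R_e <- (3 * V_e / (4 * pi))^(1 / 3)
  r_u <- (3 * V_u / (4 * pi))^(1 / 3)
  structure(list(t = t, V_e = V_e, V_u = V_u,
                 R_e = R_e, r_u = r_u, r_p = R_e - r_u),
            class = "spherical_kinetics")
}

#' Fit the exponential-decay penetration model
#'
#' Least-squares fit of `r_p(t) = R_e * (1 - exp(-k t))` to observed
#' penetration depths: the front advances fast at first and saturates at the
#' asymptote `R_e` as the concentration gradient vanishes. By construction
#' the curve passes through 0 at `t = 0`. Fitting is bounded
#' Levenberg-Marquardt, initialized at `R_e = max(r_p)` and
#' `k = 1 / median(t)`; a fit that does not converge or runs into the `k`
#' bound is flagged, not raised as an error.
#'
#' @param t times in days (> 0, at least 3 distinct).
#' @param r_p penetration depths in mm (>= 0), same length as `t`.
#' @param weights optional fit weights.
#' @param k_max upper bound on the rate constant (1/day).
#' @return A `decay_fit`: list with `R_e_hat` (mm), `k` (1/day), `rss`,
#'   `converged`, `at_bound`.
#' @export
fit_penetration_decay <- function(t, r_p, weights = NULL, k_max = 50) {
  if (length(t) != length(r_p) || length(unique(t)) < 3)
    stop("need >= 3 distinct time points", call. = FALSE)
  if (any(t <= 0) || any(r_p < 0))
    stop("need t > 0 and r_p >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(t))
  model <- function(p) p[1] * (1 - exp(-p[2] * t))
  start <- c(R_e = max(r_p), k = 1 / stats::median(t))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) sqrt(weights) * (r_p - model(p)),
      lower = c(1e-9, 1e-9), upper = c(Inf, k_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(R_e_hat = NA_real_, k = NA_real_, rss = NA_real_,
                          converged = FALSE, at_bound = FALSE),
                     class = "decay_fit"))
  }
  p <- fit$par
  # k is unidentifiable once the curve is saturated at the first time point
  at_bound <- p[2] >= k_max * (1 - 1e-6) || exp(-p[2] * min(t)) < 1e-6
  structure(list(R_e_hat = unname(p[1]), k = unname(p[2]),
                 rss = sum(weights * (r_p - model(p))^2),
                 converged = fit$info %in% 1:4 && !at_bound,
                 at_bound = at_bound),
            class = "decay_fit")
}

#' Predict from a decay fit
#' @param object a `decay_fit`.
#' @param t times in days.
#' @param ... unused.
#' @return Predicted penetration depths (mm).
#' @export
predict.decay_fit <- function(object, t, ...) {
  object$R_e_hat * (1 - exp(-object$k * t))
}

#' Relative total-volume change over time
#'
#' Percent change of the total tissue volume relative to the first time
#' point, the readout used to assess staining-induced swelling or
#' shrinkage.
#'
#' @param t times (days), length >= 2.
#' @param V_e total volumes (mm^3, > 0), same length.
#' @return Data frame with `t`, `V_e`, `pct_change`.
#' @export
volume_change_series <- function(t, V_e) {
  if (length(t) != length(V_e) || length(t) < 2)
    stop("need >= 2 time points", call. = FALSE)
  if (any(V_e <= 0)) stop("volumes must be > 0", call. = FALSE)
  o <- order(t)
  t <- t[o]; V_e <- V_e[o]
  data.frame(t = t, V_e = V_e,
             pct_change = (V_e / V_e[1] - 1) * 100)
}
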