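#' Automatic histogram window
#'
#' Picks window bounds at the given percentiles of the volume's gray-value
#' histogram. The defaults (0.1, 99.9) are robust to isolated hot or dead
#' voxels; (0, 100) reproduces a plain min/max stretch. The low bound maps
#' to 0 and the high bound to the maximum of the target bit depth when the
#' window is applied.
#'
#' @param v a [gray_volume()].
#' @param p_low,p_high percentiles in `[0, 100]` with `p_low < p_high`.
#' @return A `window_spec`: list with `low`, `high`, `source`.
#' @export
auto_window <- function(v, p_low = 0.1, p_high = 99.9) {
  stopifnot(inherits(v, "gray_volume"))
  if (p_low < 0 || p_high > 100 || p_low >= p_high)
    stop("need 0 <= p_low < p_high <= 100", call. = FALSE)
  g <- as.numeric(v)
  lo <- gray_percentile(g, p_low)
  hi <- gray_percentile(g, p_high)
  if (lo >= hi)
    stop("degenerate window: volume histogram has no spread between the ",
         "requested percentiles", call. = FALSE)
  window_spec(lo, hi, source = sprintf("auto-percentile(%g,%g)",
                                       p_low, p_high))
}

# percentile as the smallest observed gray value with cumulative
# frequency >= p/100 (p = 0 gives the minimum)
gray_percentile <- function(g, p) {
  s <- sort(g)
  n <- length(s)
  k <- max(1L, ceiling(p / 100 * n))
  s[k]
}

#' @rdname auto_window
#' @param low,high gray values mapped to 0 and to the target-depth maximum.
#' @param source provenance tag.
#' @export
window_spec <- function(low, high, source = "manual") {
  if (!(low < high)) stop("window requires low < high", call. = FALSE)
  structure(list(low = low, high = high, source = source),
            class = "window_spec")
}

#' Apply a window: 16-bit to 8-bit conversion
#'
#' Linear map of `[low, high]` onto `[0, 255]` with clipping outside the
#' window and round-half-up to integers; monotone non-decreasing in the
#' input gray value.
#'
#' @param v a [gray_volume()].
#' @param w a `window_spec` from [auto_window()] or [window_spec()].
#' @return An 8-bit [gray_volume()].
#' @export
apply_window <- function(v, w) {
  stopifnot(inherits(v, "gray_volume"), inherits(w, "window_spec"))
  a <- as_volume_array(v)
  scaled <- (a - w$low) / (w$high - w$low) * 255
  scaled <- pmin(pmax(scaled, 0), 255)
  out <- floor(scaled + 0.5) # round half up
  gray_volume(array(out, dim(a)), voxel_size(v), 8L)
}

#' Reference gray values of a dataset
#'
#' Mean gray values of the reference materials present in every scan: a
#' ceramic alumina bead (`G_B`, strongly attenuating), the polypropylene
#' sample tube (`G_E`) and optionally air (`G_air`). These anchor the
#' dimensionless normalization of [normalized_gray()] and the cross-dataset
#' rescaling of [normalize_to_references()].
#'
#' @param G_B,G_E,G_air mean gray values (bead > tube >= air).
#' @param sd_B,sd_E,sd_air standard deviations.
#' @param n_B,n_E,n_air voxel counts (> 0).
#' @return An object of class `reference_grays`.
#' @export
reference_grays <- function(G_B, G_E, G_air = NA_real_,
                            sd_B = NA_real_, sd_E = NA_real_,
                            sd_air = NA_real_,
                            n_B = 1L, n_E = 1L, n_air = 1L) {
  if (!is.na(G_air)) {
    if (!(G_B > G_E && G_E >= G_air))
      stop("references must satisfy G_B > G_E >= G_air", call. = FALSE)
  } else if (!(G_B > G_E)) {
    stop("references must satisfy G_B > G_E", call. = FALSE)
  }
  if (any(c(n_B, n_E, n_air) <= 0))
    stop("reference voxel counts must be > 0", call. = FALSE)
  structure(list(G_B = G_B, G_E = G_E, G_air = G_air,
                 sd_B = sd_B, sd_E = sd_E, sd_air = sd_air,
                 n_B = n_B, n_E = n_E, n_air = n_air),
            class = "reference_grays")
}

#' Measure reference gray values from VOIs
#'
#' @param v a [gray_volume()].
#' @param bead_voi,tube_voi VOIs over the ceramic bead and the tube wall.
#' @param air_voi optional VOI over air.
#' @return A [reference_grays()] with means, SDs and voxel counts.
#' @export
measure_reference_grays <- function(v, bead_voi, tube_voi, air_voi = NULL) {
  vois <- list(bead = bead_voi, tube = tube_voi)
  if (!is.null(air_voi)) vois$air <- air_voi
  masks <- lapply(vois, function(w) voi_mask(v, w))
  counts <- vapply(masks, sum, 0)
  if (any(counts == 0)) stop("empty reference VOI", call. = FALSE)
  for (i in seq_along(masks)) for (j in seq_along(masks)) {
    if (i < j && any(masks[[i]] & masks[[j]]))
      stop("reference VOIs overlap (", names(masks)[i], ", ",
           names(masks)[j], ")", call. = FALSE)
  }
  vals <- lapply(masks, function(m) voi_values(v, m))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  reference_grays(
    G_B = mean(vals$bead), G_E = mean(vals$tube),
    G_air = if (is.null(air_voi)) NA_real_ else mean(vals$air),
    sd_B = pop_sd(vals$bead), sd_E = pop_sd(vals$tube),
    sd_air = if (is.null(air_voi)) NA_real_ else pop_sd(vals$air),
    n_B = length(vals$bead), n_E = length(vals$tube),
    n_air = if (is.null(air_voi)) 1L else length(vals$air))
}

#' Dimensionless normalized gray value
#'
#' `g_X = (G_X - G_E) / (G_B - G_E)`: 0 at the tube reference, 1 at the
#' ceramic bead. Invariant under any affine transform applied jointly to the
#' measurement and both references, which makes values comparable across
#' scans acquired with different effective gray scales. Computed on the
#' 16-bit gray values, before any 8-bit conversion.
#'
#' @param G_X measured mean gray value (scalar or vector).
#' @param refs a [reference_grays()].
#' @return Normalized gray value(s).
#' @export
normalized_gray <- function(G_X, refs) {
  stopifnot(inherits(refs, "reference_grays"))
  den <- refs$G_B - refs$G_E
  if (den == 0) stop("degenerate references: G_B equals G_E", call. = FALSE)
  (G_X - refs$G_E) / den
}

#' Rescale datasets onto a common gray scale via their references
#'
#' Each volume is linearly rescaled so that its measured tube and air (or
#' tube and bead, if air is absent) reference grays coincide with those of
#' the anchor dataset; the anchor is returned unchanged. Values are clipped
#' to the bit range and rounded.
#'
#' @param vols named list of [gray_volume()]s.
#' @param refs list of [reference_grays()], parallel to `vols`.
#' @param anchor index or name of the anchor dataset (default first).
#' @return List of volumes on the anchor's gray scale.
#' @export
normalize_to_references <- function(vols, refs, anchor = 1L) {
  stopifnot(length(vols) == length(refs))
  ra <- refs[[anchor]]
  pick <- function(r) {
    if (!is.na(r$G_air)) c(r$G_E, r$G_air) else c(r$G_B, r$G_E)
  }
  pa <- pick(ra)
  anchor_idx <- if (is.character(anchor)) match(anchor, names(vols)) else
    anchor
  out <- vols
  for (i in seq_along(vols)) {
    if (i == anchor_idx) next
    pi <- pick(refs[[i]])
    if (pi[1] == pi[2])
      stop("degenerate references in dataset ", i,
           ": equal reference grays", call. = FALSE)
    slope <- (pa[1] - pa[2]) / (pi[1] - pi[2])
    inter <- pa[1] - slope * pi[1]
    v <- vols[[i]]
    a <- as_volume_array(v) * slope + inter
    a <- floor(pmin(pmax(a, 0), bit_range(bit_depth(v))) + 0.5)
    out[[i]] <- gray_volume(array(a, dim(a)), voxel_size(v), bit_depth(v))
  }
  out
}
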