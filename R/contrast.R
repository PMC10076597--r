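#' Gray-value statistics of a region of interest
#'
#' Mean, standard deviation (population SD by default, i.e. divide by n;
#' set `sample_sd = TRUE` for the n-1 denominator) and voxel count of the
#' gray values inside a ROI.
#'
#' @param v a [gray_volume()].
#' @param roi a `voi`, [vox_mask()] or congruent logical array.
#' @param label region label carried into the result.
#' @param sample_sd use the sample (n-1) SD instead of the population SD.
#' @return A `roi_stats`: list with `mu`, `sigma`, `n`, `label`.
#' @export
roi_stats <- function(v, roi, label = "", sample_sd = FALSE) {
  g <- voi_values(v, roi)
  if (length(g) == 0) stop("empty ROI", call. = FALSE)
  mu <- mean(g)
  sigma <- if (sample_sd && length(g) > 1) stats::sd(g) else
    sqrt(mean((g - mu)^2))
  structure(list(mu = mu, sigma = sigma, n = length(g), label = label),
            class = "roi_stats")
}

#' Contrast-to-noise ratio between two regions
#'
#' `CNR = |mu_1 - mu_2| / ((sigma_1 + sigma_2) / 2)`: the absolute
#' difference of the two region means divided by the average of their
#' standard deviations. Symmetric in its arguments and invariant under any
#' affine rescaling applied jointly to the whole volume. If both SDs are 0,
#' the CNR is 0 for equal means and `Inf` otherwise.
#'
#' @param a,b `roi_stats` (see [roi_stats()]), e.g. corpus callosum and
#'   cerebral cortex.
#' @return Dimensionless CNR.
#' @export
cnr <- function(a, b) {
  stopifnot(inherits(a, "roi_stats"), inherits(b, "roi_stats"))
  num <- abs(a$mu - b$mu)
  den <- (a$sigma + b$sigma) / 2
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Otsu threshold on a 256-bin histogram
#'
#' Exhaustive search over the 256 histogram bin edges for the threshold
#' maximizing the between-class variance. Gray values are binned linearly
#' over `[0, vmax]`; the returned threshold is the lower edge of the first
#' bin of the upper class, so that `gray >= threshold` selects the bright
#' class.
#'
#' @param g numeric vector of gray values.
#' @param vmax top of the gray scale (255 or 65535).
#' @return Threshold gray value.
#' @export
otsu_threshold <- function(g, vmax) {
  if (length(unique(g)) < 2)
    stop("Otsu requires at least 2 distinct gray values", call. = FALSE)
  nb <- 256L
  bin <- pmin(floor(g / (vmax + 1) * nb), nb - 1L) # 0-based bin index
  h <- tabulate(bin + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (seq_len(nb) - 0.5) / nb * (vmax + 1)
  mu <- cumsum(p * centers)
  mu_t <- mu[nb]
  # between-class variance for split after bin k (classes [1..k], [k+1..nb])
  valid <- omega > 0 & omega < 1
  bcv <- rep(-Inf, nb)
  bcv[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(bcv)
  k / nb * (vmax + 1) # lower edge of bin k+1
}

#' Otsu binarization of a VOI
#'
#' Thresholds the VOI at the Otsu criterion (256-bin between-class-variance
#' maximization); the mask selects `gray >= threshold`, the more attenuating
#' class.
#'
#' @param v a [gray_volume()].
#' @param voi optional VOI restricting the analysis (default whole volume).
#' @return A [vox_mask()] congruent with `v` (zero outside the VOI), with
#'   the threshold in `attr(, "threshold")`.
#' @export
otsu_binarize <- function(v, voi = NULL) {
  stopifnot(inherits(v, "gray_volume"))
  inside <- if (is.null(voi)) array(TRUE, dim(v)) else
    unclass(voi_mask(v, voi)) == 1
  g <- as.numeric(unclass(v)[inside])
  thr <- otsu_threshold(g, bit_range(bit_depth(v)))
  m <- array(FALSE, dim(v))
  m[inside] <- unclass(v)[inside] >= thr
  out <- vox_mask(m, provenance = sprintf("otsu thr=%.6g", thr))
  attr(out, "threshold") <- thr
  out
}
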