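#' Erode a mask by a Euclidean radius
#'
#' Keeps voxels whose distance to the mask boundary exceeds `r_vox`
#' (computed from the exact Euclidean distance transform). Used by the
#' kinetics pipeline to restrict gray-value classification to interior
#' tissue, away from partial-volume surface voxels.
#'
#' @param m a [vox_mask()] or 0/1 array.
#' @param r_vox erosion radius in voxels.
#' @return A [vox_mask()].
#' @export
erode_mask <- function(m, r_vox) {
  d <- dim(m)
  mi <- array(as.integer(unclass(m) != 0), d)
  edt2 <- cpp_edt_sq(mi, d, TRUE)
  vox_mask(array(edt2 > r_vox^2, d),
           provenance = sprintf("erode r=%g", r_vox))
}

#' Gaussian denoising of a volume
#'
#' Isotropic Gaussian smoothing in gray-value space, the package's stand-in
#' for the median/volume filters a scanner's reconstruction pipeline
#' applies before analysis.
#'
#' @param v a [gray_volume()].
#' @param sigma_vox smoothing scale in voxels.
#' @return A smoothed [gray_volume()].
#' @export
smooth_volume <- function(v, sigma_vox = 1) {
  stopifnot(inherits(v, "gray_volume"))
  if (sigma_vox <= 0) return(v)
  d <- dim(v)
  a <- cpp_gauss_smooth(as_volume_array(v) * 1.0, d, sigma_vox)
  gray_volume(array(pmin(pmax(a, 0), bit_range(bit_depth(v))), d),
              voxel_size(v), bit_depth(v))
}

largest_component_volume <- function(mask, voxel_size_um) {
  d <- dim(mask)
  mi <- array(as.integer(unclass(mask) != 0), d)
  if (!any(mi == 1)) return(0)
  lab <- cpp_label_components(mi, d, 26L)
  max(tabulate(lab[lab > 0])) * (voxel_size_um / 1000)^3
}

#' Run the staining-kinetics study
#'
#' Full penetration-rate workflow over a staining time series: segment the
#' specimen, derive the stain threshold, split stained from unstained
#' tissue, apply the spherical approximation, fit the exponential-decay
#' penetration model and tabulate the relative volume change.
#'
#' Per time point, the volume is denoised (`smooth_sigma`), the tissue is
#' segmented by fixed threshold or Otsu (largest component, holes filled,
#' reference VOIs excluded), and the unstained volume is measured inside
#' the tissue eroded by `erode_vox` (avoiding partial-volume surface
#' voxels), keeping only the largest connected unstained component (the
#' core; isolated noise voxels are discarded). The stain threshold is
#' shared across the series: either `"interior-otsu"` (Otsu between the
#' unstained and stained tissue modes of the first time point, unbiased
#' front localization) or `"final-percentile"` (a low percentile of the
#' interior tissue at the final, fully stained time point — the
#' least-attenuating-tissue rule), or a fixed numeric gray value.
#'
#' @param volumes list of [gray_volume()]s, one per time point.
#' @param times staining times in days.
#' @param tissue_threshold numeric gray value separating specimen from
#'   solution, or `"otsu"`.
#' @param stain_rule `"interior-otsu"`, `"final-percentile"`, or a numeric
#'   gray value.
#' @param stain_percentile percentile for `"final-percentile"`.
#' @param smooth_sigma denoising scale (voxels); 0 disables.
#' @param erode_vox interior erosion radius (voxels).
#' @param exclude optional list of VOIs (reference materials) excluded from
#'   tissue segmentation.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return Report list: `kinetics` (data frame per time point: `t`, `V_e`,
#'   `V_u`, `R_e`, `r_u`, `r_p`), `fit` (a `decay_fit`, or `NULL` with
#'   `fit_skipped = TRUE` for a single time point), `volume_series`,
#'   `stain_threshold`, `tissue_threshold`.
#' @export
run_kinetics_study <- function(volumes, times,
                               tissue_threshold = "otsu",
                               stain_rule = "interior-otsu",
                               stain_percentile = 1,
                               smooth_sigma = 1, erode_vox = 3,
                               exclude = NULL, out_dir = NULL) {
  stopifnot(length(volumes) == length(times), length(volumes) >= 1)
  vs_um <- voxel_size(volumes[[1]])
  o <- order(times)
  volumes <- volumes[o]; times <- times[o]

  sm <- lapply(volumes, smooth_volume, sigma_vox = smooth_sigma)
  tissues <- lapply(seq_along(sm), function(i) {
    if (identical(tissue_threshold, "otsu"))
      segment_tissue(sm[[i]], "otsu", exclude = exclude)
    else
      segment_tissue(sm[[i]], "fixed", threshold = tissue_threshold,
                     exclude = exclude)
  })
  interiors <- lapply(tissues, erode_mask, r_vox = erode_vox)

  thr <- if (is.numeric(stain_rule)) {
    structure(list(value = stain_rule, percentile = NA,
                   source = "fixed"), class = "stain_threshold")
  } else if (stain_rule == "interior-otsu") {
    g <- voi_values(sm[[1]], interiors[[1]])
    structure(list(value = otsu_threshold(g, bit_range(bit_depth(sm[[1]]))),
                   percentile = NA, source = "interior-otsu(first)"),
              class = "stain_threshold")
  } else if (stain_rule == "final-percentile") {
    derive_stain_threshold(sm[[length(sm)]], interiors[[length(sm)]],
                           percentile = stain_percentile)
  } else stop("unknown stain_rule", call. = FALSE)

  rows <- lapply(seq_along(sm), function(i) {
    V_e <- measure_volume(tissues[[i]], vs_um)
    stained <- segment_stained(sm[[i]], interiors[[i]], thr)
    unstained <- vox_mask(unclass(interiors[[i]]) == 1 &
                            unclass(stained) == 0, "unstained-core")
    V_u <- largest_component_volume(unstained, vs_um)
    k <- spherical_kinetics(V_e, min(V_u, V_e), t = times[i])
    data.frame(t = k$t, V_e = k$V_e, V_u = k$V_u, R_e = k$R_e,
               r_u = k$r_u, r_p = k$r_p)
  })
  kin <- do.call(rbind, rows)

  fit <- NULL; fit_skipped <- FALSE
  if (length(unique(times)) >= 3) {
    fit <- fit_penetration_decay(kin$t, kin$r_p)
  } else fit_skipped <- TRUE
  vol_series <- if (nrow(kin) >= 2) volume_change_series(kin$t, kin$V_e)
                else NULL

  report <- list(kinetics = kin, fit = fit, fit_skipped = fit_skipped,
                 volume_series = vol_series, stain_threshold = thr,
                 tissue_threshold = tissue_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(kin, file.path(out_dir, "kinetics.csv"),
                     row.names = FALSE)
    if (!is.null(vol_series))
      utils::write.csv(vol_series, file.path(out_dir, "volume_series.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(fit = fit[c("R_e_hat", "k", "rss", "converged", "at_bound")],
           stain_threshold = thr$value, stain_rule = thr$source),
      file.path(out_dir, "kinetics_fit.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }
  report
}

#' Run the contrast (CNR) study
#'
#' Contrast-to-noise ratio between a white-matter and a gray-matter ROI for
#' each dataset (e.g. one per staining agent), plus an Otsu binarization of
#' the comparison VOI as the ease-of-segmentation readout.
#'
#' @param datasets named list; each element a list with `volume` (a
#'   [gray_volume()]), `roi_white`, `roi_gray` (VOIs or masks), and
#'   optionally `voi` for the Otsu binarization (defaults to `roi_white`'s
#'   bounding region union not being required, the whole volume).
#' @param out_dir optional output directory.
#' @return List with `table` (data frame: dataset, mu/sigma per ROI, `cnr`,
#'   `otsu_threshold`), and `masks` (list of Otsu [vox_mask()]s).
#' @export
run_contrast_study <- function(datasets, out_dir = NULL) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  masks <- list()
  rows <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    if (is.null(ds$roi_white) || is.null(ds$roi_gray))
      stop("dataset ", nm, ": missing ROI", call. = FALSE)
    a <- roi_stats(ds$volume, ds$roi_white, label = "white matter")
    b <- roi_stats(ds$volume, ds$roi_gray, label = "gray matter")
    bm <- otsu_binarize(ds$volume, ds$voi)
    masks[[nm]] <<- bm
    data.frame(dataset = nm, mu_white = a$mu, sd_white = a$sigma,
               mu_gray = b$mu, sd_gray = b$sigma, cnr = cnr(a, b),
               otsu_threshold = attr(bm, "threshold"))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$cnr), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "cnr.csv"), row.names = FALSE)
  }
  list(table = tab, masks = masks)
}

cuprizone_metrics <- function(volume, refs_vois, regions, fiber_voi, fa_voi,
                              vf_threshold_gray, polarity, radii, length,
                              directions, cutoff, sigma = c(0.5, 0.5, 5)) {
  refs <- measure_reference_grays(volume, refs_vois$bead, refs_vois$tube,
                                  refs_vois$air)
  # structure tensor / FA inside the spherical VOI
  sub <- extract_voi(volume, fa_voi)
  sphere <- unclass(attr(sub, "mask")) == 1
  tf <- structure_tensor(sub, sigma[1], sigma[2], sigma[3])
  fa <- fractional_anisotropy(tf)
  fa_mean <- mean(fa$fa[sphere])
  radial_mean <- mean(fa$radial[sphere])

  vf <- volume_fraction(volume, fiber_voi, threshold = vf_threshold_gray,
                        polarity = polarity)

  det <- detect_fibers(volume, voi = fiber_voi, radii = radii,
                       length = length, directions = directions,
                       polarity = polarity, cutoff = cutoff)
  r <- voi_ranges(fiber_voi, dim(volume))
  gray_sub <- unclass(volume)[r$y[1]:r$y[2], r$x[1]:r$x[2],
                              r$z[1]:r$z[2], drop = FALSE]
  fiber_side <- if (polarity == "hypo") gray_sub <= vf_threshold_gray else
    gray_sub >= vf_threshold_gray
  bundle_mask <- unclass(det$mask) == 1 & fiber_side
  labs <- label_fibers(bundle_mask, det$correlation,
                       min_separation = max(radii))
  thick <- if (labs$n_labels > 0)
    fiber_thickness(labs, voxel_size(volume)) else
    list(per_label = NULL, median_um = 0)

  report <- regional_gray_report(volume, refs, regions)
  list(refs = refs, fa_mean = fa_mean, radial_mean = radial_mean,
       volume_fraction = vf, n_bundles = labs$n_labels,
       median_thickness_um = thick$median_um, gray_report = report)
}

#' Run the cuprizone (demyelination) comparison study
#'
#' Compares a healthy and a treated dataset with the four white-matter
#' readouts: structure-tensor fractional anisotropy (plus the
#' radial-diffusivity analog) in a spherical VOI, fiber volume fraction at
#' a fixed normalized threshold, median fiber-bundle thickness
#' (cylinder-correlation detection, gray-value gating, marker-based
#' watershed labeling, inscribed-sphere thickness), and normalized gray
#' values at four named corpus-callosum positions with percent change vs
#' the healthy baseline. With demyelination, volume fraction, thickness and
#' FA decrease while normalized gray values increase.
#'
#' @param healthy,treated lists with `volume` (a [gray_volume()]) and
#'   `refs` (list of VOIs `bead`, `tube`, `air`).
#' @param regions named list of report VOIs (shared).
#' @param fiber_voi,fa_voi analysis VOIs (shared).
#' @param vf_threshold_gray fixed fiber segmentation threshold (16-bit
#'   gray, held constant between datasets).
#' @param polarity `"hypo"` or `"hyper"` fiber contrast.
#' @param radii,template_length cylinder-correlation template geometry
#'   (voxels).
#' @param directions optional orientation matrix for [detect_fibers()].
#' @param cutoff correlation cutoff.
#' @param out_dir optional output directory.
#' @return List with `healthy`, `treated` (per-dataset metric lists),
#'   `comparison` (data frame of the four metrics, values and deltas) and
#'   `gray_report` (treated vs healthy, percent change per region).
#' @export
run_cuprizone_study <- function(healthy, treated, regions, fiber_voi,
                                fa_voi, vf_threshold_gray,
                                polarity = "hypo", radii = 5,
                                template_length = 15, directions = NULL,
                                cutoff = 0.5, out_dir = NULL) {
  if (is.null(healthy$refs) || is.null(treated$refs))
    stop("missing reference VOIs", call. = FALSE)
  mh <- cuprizone_metrics(healthy$volume, healthy$refs, regions, fiber_voi,
                          fa_voi, vf_threshold_gray, polarity, radii,
                          template_length, directions, cutoff)
  mt <- cuprizone_metrics(treated$volume, treated$refs, regions, fiber_voi,
                          fa_voi, vf_threshold_gray, polarity, radii,
                          template_length, directions, cutoff)
  gray_rep <- regional_gray_report(treated$volume, mt$refs, regions,
                                   baseline = mh$gray_report)
  comparison <- data.frame(
    metric = c("volume_fraction", "median_thickness_um", "fa_mean",
               "radial_mean", "mean_norm_gray"),
    healthy = c(mh$volume_fraction, mh$median_thickness_um, mh$fa_mean,
                mh$radial_mean, mean(mh$gray_report$g_norm)),
    treated = c(mt$volume_fraction, mt$median_thickness_um, mt$fa_mean,
                mt$radial_mean, mean(mt$gray_report$g_norm)))
  comparison$delta <- comparison$treated - comparison$healthy
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparison, file.path(out_dir, "cuprizone_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(gray_rep, file.path(out_dir, "gray_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(healthy = mh[c("fa_mean", "radial_mean", "volume_fraction",
                          "median_thickness_um", "n_bundles")],
           treated = mt[c("fa_mean", "radial_mean", "volume_fraction",
                          "median_thickness_um", "n_bundles")]),
      file.path(out_dir, "cuprizone_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(healthy = mh, treated = mt, comparison = comparison,
       gray_report = gray_rep)
}
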