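#' Regional normalized gray-value report
#'
#' Mean gray value of each named region (e.g. the four corpus-callosum
#' positions caudal-medial, caudal-lateral, rostral-medial,
#' rostral-lateral, each over a 50-slice slab), normalized against the
#' dataset's reference materials (`g = (G - G_E) / (G_B - G_E)`). If a
#' baseline report is supplied (e.g. a healthy animal), the percent change
#' `(g - g_baseline) / g_baseline * 100` is added per region; demyelinated
#' white matter admits more of a myelin-repelled agent and shows increased
#' normalized gray values.
#'
#' @param v a [gray_volume()] (16-bit gray values).
#' @param refs a [reference_grays()] for this dataset.
#' @param regions named list of VOIs.
#' @param baseline optional `gray_report` to compare against; must contain
#'   every region name.
#' @return A `gray_report` data frame: `region`, `mean_gray`, `g_norm`,
#'   `n_voxels`, `slices`, and `pct_change` when a baseline is given.
#' @export
regional_gray_report <- function(v, refs, regions, baseline = NULL) {
  stopifnot(inherits(refs, "reference_grays"), length(regions) > 0,
            !is.null(names(regions)))
  if (refs$G_B == refs$G_E)
    stop("degenerate references: G_B equals G_E", call. = FALSE)
  rows <- lapply(names(regions), function(nm) {
    w <- regions[[nm]]
    vals <- voi_values(v, w)
    if (length(vals) == 0) stop("empty region: ", nm, call. = FALSE)
    zr <- voi_ranges(if (inherits(w, "voi")) w else voi_box(), dim(v))$z
    data.frame(region = nm, mean_gray = mean(vals),
               g_norm = normalized_gray(mean(vals), refs),
               n_voxels = length(vals),
               slices = sprintf("%d-%d", zr[1], zr[2]))
  })
  rep_df <- do.call(rbind, rows)
  if (!is.null(baseline)) {
    i <- match(rep_df$region, baseline$region)
    if (anyNA(i))
      stop("baseline report is missing regions: ",
           paste(rep_df$region[is.na(i)], collapse = ", "), call. = FALSE)
    g0 <- baseline$g_norm[i]
    rep_df$pct_change <- (rep_df$g_norm - g0) / g0 * 100
  }
  class(rep_df) <- c("gray_report", "data.frame")
  rep_df
}
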