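#' Plausibility rules for diffusion maps
#'
#' Physically implausible voxels are excluded per map: negative diffusivity
#' or kurtosis, kurtosis above `mk_max` (default 2.5, the conventional upper
#' cutoff for tissue kurtosis), FA outside [0, 1], diffusivity above
#' `diffusivity_max`. The diffusivity ceiling defaults to 3.0e-3 mm^2/s, the
#' free-water value at body temperature; it is configurable because published
#' exclusion rules are often stated in reporting units of 1e-3 mm^2/s.
#'
#' @param mk_max upper kurtosis bound (dimensionless).
#' @param mk_min lower kurtosis bound.
#' @param diffusivity_min,diffusivity_max diffusivity bounds in mm^2/s.
#' @param fa_max upper FA bound.
#' @return object of class `plausibility_rules`.
#' @export
plausibility_rules <- function(mk_max = 2.5, mk_min = 0,
                               diffusivity_min = 0, diffusivity_max = 3.0e-3,
                               fa_max = 1) {
  if (mk_max <= mk_min) stop("mk_max must exceed mk_min")
  if (diffusivity_max <= diffusivity_min) {
    stop("diffusivity_max must exceed diffusivity_min")
  }
  structure(list(mk_max = mk_max, mk_min = mk_min,
                 diffusivity_min = diffusivity_min,
                 diffusivity_max = diffusivity_max,
                 fa_max = fa_max),
            class = "plausibility_rules")
}

#' Per-map plausibility exclusion masks
#'
#' A voxel is excluded in a map iff it violates that map's rule set; NaN
#' voxels are always excluded. Masks are per map: a voxel can be excluded in
#' MK yet retained in MD.
#'
#' @param maps a [scalar_maps()].
#' @param rules a [plausibility_rules()].
#' @return named list of logical arrays (TRUE = excluded), one per map, with
#'   attribute `counts`: per-map excluded-voxel counts.
#' @export
plausibility_mask <- function(maps, rules = plausibility_rules()) {
  stopifnot(inherits(maps, "scalar_maps"))
  masks <- list()
  for (nm in map_names(maps)) {
    m <- maps[[nm]]
    excl <- is.na(m)
    if (nm == "mk") {
      excl <- excl | m < rules$mk_min | m > rules$mk_max
    } else if (nm == "fa") {
      excl <- excl | m < 0 | m > rules$fa_max
    } else if (nm %in% c("md", "ad", "rd", "adc")) {
      excl <- excl | m < rules$diffusivity_min | m > rules$diffusivity_max
    } else {
      excl <- excl  # baseline maps: NaN-only exclusion
    }
    excl[is.na(excl)] <- TRUE
    masks[[nm]] <- excl
  }
  attr(masks, "counts") <- vapply(masks, sum, 0L)
  masks
}

#' Percentage of ROI voxels excluded by a mask
#'
#' @param mask logical exclusion array (TRUE = excluded).
#' @param roi a [roi_label_map()].
#' @param label ROI label (default 1, the pancreas).
#' @return percentage in [0, 100].
#' @export
excluded_fraction <- function(mask, roi, label = 1L) {
  stopifnot(inherits(roi, "roi_label_map"))
  if (!all(dim(mask) == dim(roi$labels))) stop("mask and ROI grids differ")
  inroi <- roi$labels == label
  n <- sum(inroi)
  if (n == 0L) stop(sprintf("validation error: empty ROI for label %d", label))
  100 * sum(mask & inroi) / n
}

#' ROI summary statistics of a scalar map
#'
#' Median, IQR (p75 - p25), and the 10th/90th percentiles over retained ROI
#' voxels, using linear-interpolation percentiles, plus the excluded
#' fraction. With zero retained voxels the statistics are NaN and the
#' excluded fraction is 100.
#'
#' @param map 3-D numeric array.
#' @param roi a [roi_label_map()].
#' @param label ROI label (default 1).
#' @param mask optional logical exclusion array (TRUE = excluded), e.g. one
#'   entry of [plausibility_mask()].
#' @param map_name name recorded in the summary row.
#' @return one-row data.frame: map_name, roi_label, median, iqr, p10, p90,
#'   excluded_fraction (%), n_voxels (retained).
#' @export
roi_statistics <- function(map, roi, label = 1L, mask = NULL,
                           map_name = deparse(substitute(map))) {
  stopifnot(inherits(roi, "roi_label_map"))
  inroi <- roi$labels == label
  if (sum(inroi) == 0L) stop(sprintf("validation error: empty ROI for label %d", label))
  if (is.null(mask)) mask <- is.na(map)
  vals <- map[inroi & !mask]
  vals <- vals[is.finite(vals)]
  excl <- 100 * (1 - length(vals) / sum(inroi))
  if (length(vals) == 0L) {
    return(data.frame(map_name = map_name, roi_label = label,
                      median = NaN, iqr = NaN, p10 = NaN, p90 = NaN,
                      excluded_fraction = 100, n_voxels = 0L))
  }
  q <- stats::quantile(vals, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = 7, names = FALSE)
  data.frame(map_name = map_name, roi_label = label,
             median = q[3], iqr = q[4] - q[2], p10 = q[1], p90 = q[5],
             excluded_fraction = excl, n_voxels = length(vals))
}

#' Cohort summary over subjects with repeat averaging
#'
#' Repeat acquisitions of a subject are arithmetically averaged per metric,
#' then cohort median, IQR and min-max range are computed per metric (and per
#' protocol when present).
#'
#' @param summaries data.frame with columns `subject`, `metric`, `value` and
#'   optionally `repeat_idx` and `protocol` (as produced by the pipeline's
#'   ROI stage, with `value` typically the per-subject ROI median).
#' @return data.frame with one row per (protocol,) metric: n_subjects,
#'   median, iqr, min, max.
#' @export
summarize_cohort <- function(summaries) {
  req <- c("subject", "metric", "value")
  if (!all(req %in% names(summaries))) {
    stop("summaries needs columns subject, metric, value")
  }
  if (!"protocol" %in% names(summaries)) summaries$protocol <- "all"
  bad <- !is.finite(summaries$value)
  if (any(bad)) {
    warning(sprintf("dropping %d non-finite subject value(s)", sum(bad)))
    summaries <- summaries[!bad, , drop = FALSE]
  }
  # average repeats within subject
  per_subj <- stats::aggregate(value ~ protocol + metric + subject,
                               data = summaries, FUN = mean)
  out <- do.call(rbind, lapply(
    split(per_subj, list(per_subj$protocol, per_subj$metric), drop = TRUE),
    function(d) {
      q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(protocol = d$protocol[1], metric = d$metric[1],
                 n_subjects = nrow(d), median = q[2], iqr = q[3] - q[1],
                 min = min(d$value), max = max(d$value))
    }))
  rownames(out) <- NULL
  out
}
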