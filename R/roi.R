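#' Mean of a parameter map over an ROI
#'
#' Arithmetic mean of the finite (valid) map values inside the ROI, the
#' per-ovary summary used for group comparisons.
#'
#' @param map 3D numeric array (`NA` marks invalid voxels).
#' @param roi 3D mask (logical or nonzero labels).
#' @return Scalar mean.
#' @export
roi_average <- function(map, roi) {
  map <- as.array(map)
  roi <- .as_roi_mask(roi, dim(map))
  v <- map[roi]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("ROI contains no valid map voxels")
  mean(v)
}

#' Fixed-range histogram of a parameter map over an ROI
#'
#' Bins the valid ROI values of a parameter map into `n_bins` uniform bins
#' over a stated range (conventionally 0-0.1 or 0-0.5 for fBV and
#' 0-0.02 min^-1 for PS, in 50 bins). Bins are left-closed/right-open with
#' the last bin right-closed. Values outside the range are counted in
#' `out_of_range_low`/`out_of_range_high`, never silently dropped, so that
#' `sum(counts) + out_of_range_low + out_of_range_high` equals the number
#' of valid ROI voxels. Percentages are relative to that same total.
#'
#' @param map 3D numeric array.
#' @param roi 3D mask.
#' @param range Length-2 numeric, histogram range (min < max).
#' @param n_bins Number of bins (>= 1), default 50.
#' @param roi_id,map_name Optional identifiers echoed in the result.
#' @return Object of class `roi_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `percent`, `out_of_range_low/high`,
#'   `n_total` (valid ROI voxels), `n_missing` (non-finite ROI voxels),
#'   `roi_id`, `map_name`, `range`.
#' @export
roi_histogram <- function(map, roi, range, n_bins = 50L,
                          roi_id = NA_character_, map_name = NA_character_) {
  map <- as.array(map)
  roi <- .as_roi_mask(roi, dim(map))
  range <- as.numeric(range)
  stopifnot(length(range) == 2L)
  if (!(range[1] < range[2])) stop("range must satisfy min < max")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  vals <- map[roi]
  n_missing <- sum(!is.finite(vals))
  vals <- vals[is.finite(vals)]
  width <- (range[2] - range[1]) / n_bins
  low <- sum(vals < range[1])
  high <- sum(vals > range[2])
  inr <- vals[vals >= range[1] & vals <= range[2]]
  bin <- pmin(floor((inr - range[1]) / width) + 1L, n_bins)  # top edge closed
  counts <- tabulate(bin, nbins = n_bins)
  n_total <- length(vals)
  structure(list(bin_edges = seq(range[1], range[2], length.out = n_bins + 1L),
                 counts = counts,
                 percent = if (n_total > 0) 100 * counts / n_total
                           else rep(0, n_bins),
                 out_of_range_low = low, out_of_range_high = high,
                 n_total = n_total, n_missing = n_missing,
                 roi_id = roi_id, map_name = map_name, range = range),
            class = "roi_histogram")
}

#' @export
print.roi_histogram <- function(x, ...) {
  cat(sprintf("roi_histogram%s%s: %d bins on [%g, %g], %d voxels (%d below, %d above range)\n",
              if (!is.na(x$map_name)) paste0(" of ", x$map_name) else "",
              if (!is.na(x$roi_id)) paste0(" in ", x$roi_id) else "",
              length(x$counts), x$range[1], x$range[2],
              x$n_total, x$out_of_range_low, x$out_of_range_high))
  invisible(x)
}

#' Per-bin comparison of histogram distributions between groups
#'
#' Given one histogram per subject in each group (identical binning),
#' performs a two-sided Student's t-test per bin on the percent-of-voxels
#' values across subjects — unpaired or paired. No multiple-testing
#' correction is applied by default, matching the per-bin p < 0.05
#' convention for these histogram comparisons; Benjamini-Hochberg (or any
#' [stats::p.adjust()] method) is available via `p_adjust`.
#'
#' Bins where both groups are constant (zero variance) have no defined t
#' statistic and are flagged `degenerate` with `p_value = NA` (or 1 when
#' the constant means are equal), rather than raising an error.
#'
#' @param hists_a,hists_b Lists of [roi_histogram()] objects, one per
#'   subject.
#' @param paired Logical; paired test requires equal lengths and matched
#'   order.
#' @param p_adjust Method for [stats::p.adjust()]; `"none"` (default)
#'   leaves per-bin p-values uncorrected.
#' @return `data.frame` with one row per bin: `bin_lo`, `bin_hi`,
#'   `mean_a`, `mean_b`, `statistic`, `p_value`, `p_adjusted`,
#'   `degenerate`; attribute `p_adjust` records the method.
#' @export
compare_histograms <- function(hists_a, hists_b, paired = FALSE,
                               p_adjust = "none") {
  get_mat <- function(hl)
    do.call(rbind, lapply(hl, function(h) {
      stopifnot(inherits(h, "roi_histogram"))
      h$percent
    }))
  if (length(hists_a) < 2L || length(hists_b) < 2L)
    stop("need at least 2 subjects per group")
  edges <- hists_a[[1]]$bin_edges
  for (h in c(hists_a, hists_b))
    if (length(h$bin_edges) != length(edges) ||
        any(abs(h$bin_edges - edges) > 1e-12))
      stop("histograms must share identical binning")
  if (paired && length(hists_a) != length(hists_b))
    stop("paired comparison requires equal group sizes")
  a <- get_mat(hists_a); b <- get_mat(hists_b)
  nb <- ncol(a)
  stat <- p <- rep(NA_real_, nb)
  degen <- logical(nb)
  for (j in seq_len(nb)) {
    if (paired) {
      d <- a[, j] - b[, j]
      if (stats::sd(d) == 0) {
        degen[j] <- TRUE
        p[j] <- if (all(d == 0)) 1 else 0
      } else {
        tt <- stats::t.test(a[, j], b[, j], paired = TRUE)
        stat[j] <- unname(tt$statistic); p[j] <- tt$p.value
      }
    } else {
      if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0) {
        degen[j] <- TRUE
        p[j] <- if (mean(a[, j]) == mean(b[, j])) 1 else 0
      } else {
        tt <- stats::t.test(a[, j], b[, j], var.equal = TRUE)
        stat[j] <- unname(tt$statistic); p[j] <- tt$p.value
      }
    }
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    mean_a = colMeans(a), mean_b = colMeans(b),
                    statistic = stat, p_value = p,
                    p_adjusted = stats::p.adjust(p, method = p_adjust),
                    degenerate = degen)
  attr(out, "p_adjust") <- p_adjust
  attr(out, "paired") <- paired
  out
}

#' Average per-ovary values within animals
#'
#' When both ovaries of an animal are imaged, their per-ovary summaries
#' are averaged so that each animal contributes one value to group
#' statistics.
#'
#' @param values Numeric vector of per-ovary scalars.
#' @param animal Grouping vector (animal identifier per ovary).
#' @return Named numeric vector, one mean per animal, in order of first
#'   appearance.
#' @export
aggregate_subject <- function(values, animal) {
  if (length(values) != length(animal))
    stop("values and animal must have equal length")
  animal <- as.character(animal)
  out <- vapply(unique(animal),
                function(a) mean(values[animal == a]), numeric(1))
  out
}

#' Paired t-test of per-subject ROI means between two conditions
#'
#' Two-sided paired Student's t-test on matched per-subject summaries
#' (e.g. mean PS of dominant vs. subordinate follicle ROIs in the same
#' animals). Zero-variance differences are degenerate: `p_value` is 1 when
#' the groups are identical (no evidence of difference) or 0 for a
#' constant nonzero shift, flagged rather than raising an error.
#'
#' @param group_a,group_b Numeric vectors of equal length >= 2, matched by
#'   subject.
#' @return List: `statistic`, `df`, `p_value`, `mean_difference`,
#'   `degenerate`.
#' @export
compare_roi_groups_paired <- function(group_a, group_b) {
  if (length(group_a) != length(group_b))
    stop("paired comparison requires equal-length groups")
  n <- length(group_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- group_a - group_b
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, df = n - 1L,
                p_value = if (all(d == 0)) 1 else 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Classify a follicle ROI as dominant or subordinate
#'
#' Applies the two-parameter rule separating follicles destined to
#' ovulate from those destined for atresia: a dominant follicle (DF) shows
#' low permeability together with positive late enhancement in its antrum,
#' whereas a subordinate follicle (SF) shows high permeability with zero
#' or negative late enhancement. ROI means falling in neither quadrant are
#' `indeterminate`.
#'
#' @param vmaps A `vascular_maps` object whose `late_rate` slot is filled
#'   (see [run_pipeline()] or merge a [fit_late_enhancement()] result).
#' @param roi 3D mask of the follicle ROI.
#' @param ps_threshold PS decision threshold in min^-1 (e.g. the median
#'   mean-PS across the candidate follicles, see [classify_follicles()]).
#' @param late_threshold Late-rate decision threshold in mM/min,
#'   default 0.
#' @param roi_id Optional identifier echoed in the result.
#' @return Object of class `follicle_call`: `roi_id`, `mean_ps`,
#'   `mean_late_rate`, `call` (`"DF"`, `"SF"` or `"indeterminate"`) and
#'   the thresholds used.
#' @export
classify_follicle <- function(vmaps, roi, ps_threshold, late_threshold = 0,
                              roi_id = NA_character_) {
  stopifnot(inherits(vmaps, "vascular_maps"))
  if (is.null(vmaps$late_rate))
    stop("vmaps$late_rate is empty; run fit_late_enhancement() and merge, ",
         "or use run_pipeline()")
  mean_ps <- roi_average(vmaps$ps, roi)
  mean_late <- roi_average(vmaps$late_rate, roi)
  call <- if (mean_ps < ps_threshold && mean_late > late_threshold) "DF"
          else if (mean_ps >= ps_threshold && mean_late <= late_threshold) "SF"
          else "indeterminate"
  structure(list(roi_id = roi_id, mean_ps = mean_ps,
                 mean_late_rate = mean_late, call = call,
                 ps_threshold = ps_threshold,
                 late_threshold = late_threshold),
            class = "follicle_call")
}

#' @export
print.follicle_call <- function(x, ...) {
  cat(sprintf("follicle_call%s: %s (mean PS %.5f min^-1 vs %.5f; mean late rate %.5f mM/min vs %.5f)\n",
              if (!is.na(x$roi_id)) paste0(" ", x$roi_id) else "",
              x$call, x$mean_ps, x$ps_threshold, x$mean_late_rate,
              x$late_threshold))
  invisible(x)
}

#' Classify several follicle ROIs with a data-driven PS threshold
#'
#' Convenience wrapper around [classify_follicle()] for a set of candidate
#' follicle ROIs. When `ps_threshold` is `NULL` it defaults to the median
#' of the ROI-mean PS values across the candidates (the rule separates
#' "low" from "high" permeability within the imaged cohort, for which no
#' absolute calibration exists); the threshold used is echoed in every
#' call.
#'
#' @param vmaps A `vascular_maps` with `late_rate` filled.
#' @param rois Named list of 3D ROI masks.
#' @param ps_threshold PS threshold in min^-1, or `NULL` for the median
#'   rule.
#' @param late_threshold Late-rate threshold in mM/min, default 0.
#' @return List of `follicle_call` objects, one per ROI.
#' @export
classify_follicles <- function(vmaps, rois, ps_threshold = NULL,
                               late_threshold = 0) {
  if (length(rois) == 0L) return(list())
  if (is.null(ps_threshold)) {
    mps <- vapply(rois, function(r) roi_average(vmaps$ps, r), numeric(1))
    ps_threshold <- stats::median(mps)
  }
  nms <- names(rois)
  if (is.null(nms)) nms <- paste0("roi", seq_along(rois))
  out <- lapply(seq_along(rois), function(i)
    classify_follicle(vmaps, rois[[i]], ps_threshold, late_threshold,
                      roi_id = nms[i]))
  names(out) <- nms
  out
}
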