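#' Kinetic analysis windows and spike threshold
#'
#' The vascular parameters are derived from two linear-regression windows
#' of the concentration time course: an early window (default the first
#' 15 min post-injection) for the fBV/PS fit, and a late window (default
#' 25-35 min) for the signed late-enhancement/clearance rate. A maximum
#' concentration threshold (default 10 mM) flags spike artifacts for
#' exclusion from late-enhancement mapping.
#'
#' @param early Length-2 numeric, early window in minutes.
#' @param late Length-2 numeric, late window in minutes.
#' @param spike_threshold Maximum plausible concentration in mM.
#' @return An object of class `kinetic_windows`.
#' @export
kinetic_windows <- function(early = c(0, 15), late = c(25, 35),
                            spike_threshold = 10) {
  early <- as.numeric(early); late <- as.numeric(late)
  stopifnot(length(early) == 2L, length(late) == 2L)
  if (!(early[1] < early[2] && early[2] <= late[1] && late[1] < late[2]))
    stop("windows must satisfy early.start < early.end <= late.start < late.end")
  if (spike_threshold <= 0) stop("spike_threshold must be positive (mM)")
  structure(list(early = early, late = late,
                 spike_threshold = spike_threshold),
            class = "kinetic_windows")
}

# Frames whose time lies in [lo, hi] (closed interval).
.frames_in_window <- function(frame_times, window) {
  which(frame_times >= window[1] & frame_times <= window[2])
}

# Per-voxel OLS of concentration on time over the selected frames; returns
# intercept and slope matrices flattened over voxels. Y: n_frames x n_vox.
.voxelwise_ols <- function(y, t) {
  n <- length(t)
  x <- cbind(1, t)
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)  # 2 x n_vox
  list(intercept = beta[1, ], slope = beta[2, ])
}

#' Estimate the blood reference concentration at injection time
#'
#' Regresses the ROI-mean concentration of a blood-pool region on time over
#' the early window and extrapolates to t = 0, giving the initial blood
#' concentration cb0 that normalizes fBV and PS. For a slowly-clearing
#' macromolecular agent the curve is nearly flat, so the extrapolation is
#' mild.
#'
#' @param conc A [dce_series()] of concentration (mM).
#' @param blood_roi Logical/integer 3D mask of blood-pool voxels.
#' @param windows A [kinetic_windows()].
#' @return Scalar cb0 in mM (always > 0; an error is raised otherwise).
#' @export
estimate_blood_reference <- function(conc, blood_roi,
                                     windows = kinetic_windows()) {
  stopifnot(inherits(conc, "dce_series"), inherits(windows, "kinetic_windows"))
  roi <- .as_roi_mask(blood_roi, dim(conc$data)[1:3])
  if (!any(roi)) stop("blood_roi is empty")
  idx <- .frames_in_window(conc$frame_times, windows$early)
  if (length(idx) < 2L)
    stop("need at least 2 frames inside the early window")
  nv <- prod(dim(conc$data)[1:3])
  mat <- matrix(conc$data, nrow = nv)[as.vector(roi), idx, drop = FALSE]
  means <- colMeans(mat, na.rm = TRUE)
  if (any(!is.finite(means)))
    stop("blood ROI has no valid concentration values in some early frames")
  fit <- stats::lm.fit(cbind(1, conc$frame_times[idx]), means)
  cb0 <- unname(fit$coefficients[1])
  if (!is.finite(cb0) || cb0 <= 0)
    stop("blood reference extrapolation gave a non-positive concentration; ",
         "supply cb0 explicitly")
  cb0
}

#' Voxel-wise fractional blood volume and permeability maps
#'
#' Fits, per voxel, an ordinary least-squares line to the concentration
#' time course over the early window. The intercept extrapolated to the
#' injection time, normalized by the initial blood concentration, is the
#' fractional blood volume (fBV, dimensionless); the slope normalized the
#' same way is the permeability surface area product (PS, min^-1):
#' \deqn{fBV = C(0)/c_{b0}, \qquad PS = (dC/dt)_{early}/c_{b0}.}
#'
#' No non-negativity constraint is imposed: noise-driven negative
#' estimates are retained (clamping would bias ROI histograms) and flagged
#' in `qc_negative`.
#'
#' @param conc A [dce_series()] of concentration (mM).
#' @param cb0 Initial blood concentration in mM (> 0), e.g. from
#'   [estimate_blood_reference()].
#' @param windows A [kinetic_windows()].
#' @return An object of class `vascular_maps`: 3D arrays `fbv`, `ps`
#'   (min^-1), logical `valid_mask` and `qc_negative`, plus `cb0` and the
#'   windows used. `late_rate` is `NULL` until [fit_late_enhancement()] is
#'   merged in (see [run_pipeline()]).
#' @export
fit_vascular_params <- function(conc, cb0, windows = kinetic_windows()) {
  stopifnot(inherits(conc, "dce_series"), inherits(windows, "kinetic_windows"))
  if (!is.finite(cb0) || cb0 <= 0) stop("cb0 must be positive (mM)")
  idx <- .frames_in_window(conc$frame_times, windows$early)
  if (length(idx) < 3L)
    stop("need at least 3 frames inside the early window [",
         windows$early[1], ", ", windows$early[2], "] min")
  dims <- dim(conc$data)
  nv <- prod(dims[1:3])
  y <- t(matrix(conc$data, nrow = nv)[, idx, drop = FALSE])
  valid <- colSums(!is.finite(y)) == 0L
  fbv <- rep(NA_real_, nv); ps <- rep(NA_real_, nv)
  if (any(valid)) {
    ols <- .voxelwise_ols(y[, valid, drop = FALSE], conc$frame_times[idx])
    fbv[valid] <- ols$intercept / cb0
    ps[valid] <- ols$slope / cb0
  }
  structure(list(fbv = array(fbv, dims[1:3]),
                 ps = array(ps, dims[1:3]),
                 late_rate = NULL,
                 valid_mask = array(valid, dims[1:3]),
                 qc_negative = array(valid & (fbv < 0 | ps < 0), dims[1:3]),
                 cb0 = cb0, windows = windows),
            class = "vascular_maps")
}

#' @export
print.vascular_maps <- function(x, ...) {
  cat(sprintf("vascular_maps: %s grid, %d/%d valid voxels, cb0 = %g mM\n",
              paste(dim(x$fbv), collapse = " x "),
              sum(x$valid_mask), length(x$valid_mask), x$cb0))
  if (any(x$valid_mask))
    cat(sprintf("  median fBV %.4f, median PS %.5f min^-1%s\n",
                stats::median(x$fbv[x$valid_mask]),
                stats::median(x$ps[x$valid_mask]),
                if (!is.null(x$late_rate))
                  sprintf(", median late rate %.5f mM/min",
                          stats::median(x$late_rate[x$valid_mask]))
                else ""))
  invisible(x)
}

#' Voxel-wise late enhancement / clearance rate map
#'
#' Per-voxel OLS slope of concentration against time over the late window
#' (default 25-35 min post-injection), in mM/min. Positive rates indicate
#' continued accumulation (dominant-follicle antra, interstitial
#' convection); zero-to-negative rates indicate stasis or clearance
#' (subordinate follicles). Voxels flagged in `exclude_mask` (typically
#' spike artifacts from [apply_spike_threshold()]) are set invalid.
#'
#' @param conc A [dce_series()] of concentration (mM).
#' @param windows A [kinetic_windows()].
#' @param exclude_mask Optional logical 3D mask of voxels to exclude.
#' @return List of class `late_rate_map`: `late_rate` (mM/min, 3D) and
#'   logical `valid_mask`.
#' @export
fit_late_enhancement <- function(conc, windows = kinetic_windows(),
                                 exclude_mask = NULL) {
  stopifnot(inherits(conc, "dce_series"), inherits(windows, "kinetic_windows"))
  idx <- .frames_in_window(conc$frame_times, windows$late)
  if (length(idx) < 2L)
    stop("need at least 2 frames inside the late window [",
         windows$late[1], ", ", windows$late[2], "] min")
  dims <- dim(conc$data)
  nv <- prod(dims[1:3])
  y <- t(matrix(conc$data, nrow = nv)[, idx, drop = FALSE])
  valid <- colSums(!is.finite(y)) == 0L
  if (!is.null(exclude_mask)) valid <- valid & !as.vector(exclude_mask)
  rate <- rep(NA_real_, nv)
  if (any(valid)) {
    ols <- .voxelwise_ols(y[, valid, drop = FALSE], conc$frame_times[idx])
    rate[valid] <- ols$slope
  }
  structure(list(late_rate = array(rate, dims[1:3]),
                 valid_mask = array(valid, dims[1:3]),
                 windows = windows),
            class = "late_rate_map")
}

#' Flag concentration spikes above a maximum plausible value
#'
#' Voxels whose concentration exceeds the threshold (default 10 mM) in any
#' frame are flagged as artifacts and excluded from late-enhancement
#' mapping; the excluded fraction is reported so it can be checked against
#' the expectation that only a small minority of ROI voxels are affected.
#' The fBV/PS fit is not masked (the threshold exists to clean the late
#' map for follicle identification).
#'
#' @param conc A [dce_series()] of concentration (mM).
#' @param threshold Spike threshold in mM (> 0).
#' @param roi Optional 3D mask restricting the reported fraction's
#'   denominator; default all voxels.
#' @return List: `masked` (a [dce_series()] with flagged voxels set `NA`),
#'   `excluded_mask` (logical 3D), `excluded_fraction` (of ROI voxels).
#' @export
apply_spike_threshold <- function(conc, threshold = 10, roi = NULL) {
  stopifnot(inherits(conc, "dce_series"))
  if (threshold <= 0) stop("threshold must be positive (mM)")
  dims <- dim(conc$data)
  nv <- prod(dims[1:3])
  mat <- matrix(conc$data, nrow = nv)
  exceeds <- rowSums(mat > threshold, na.rm = TRUE) > 0L
  excluded <- array(exceeds, dims[1:3])
  roi <- if (is.null(roi)) array(TRUE, dims[1:3])
         else .as_roi_mask(roi, dims[1:3])
  frac <- if (any(roi)) sum(excluded & roi) / sum(roi) else 0
  mat[exceeds, ] <- NA_real_
  list(masked = dce_series(array(mat, dims), conc$frame_times, unit = conc$unit),
       excluded_mask = excluded,
       excluded_fraction = frac)
}

# Normalize a mask argument (logical or 0/1/label integer array) to logical
# with the expected 3D shape.
.as_roi_mask <- function(roi, dims) {
  roi <- as.array(roi)
  if (!all(dim(roi) == dims))
    stop("ROI mask shape ", paste(dim(roi), collapse = "x"),
         " does not match volume shape ", paste(dims, collapse = "x"))
  if (!is.logical(roi)) roi <- roi != 0
  roi[is.na(roi)] <- FALSE
  roi
}
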