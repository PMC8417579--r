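#' Acquisition parameters for a VFA + dynamic SPGR protocol
#'
#' Bundles the pulse-sequence and timing information needed to convert raw
#' spoiled gradient-echo (SPGR / 3D-GE) signal into longitudinal relaxation
#' rates and contrast-agent concentration: repetition time, the pre-contrast
#' variable-flip-angle (VFA) schedule, the flip angle of the dynamic series,
#' the frame times of the dynamic series, and the contrast agent relaxivity.
#'
#' Units are normalized on construction: TR is stored in seconds (`tr_ms`
#' offered as a convenience), frame times in minutes post-injection, and
#' relaxivity in mM^-1 s^-1. All downstream code assumes these units.
#'
#' @param flip_angles Numeric vector of VFA flip angles in degrees, each in
#'   (0, 90].
#' @param tr Repetition time in seconds. Supply either `tr` or `tr_ms`.
#' @param tr_ms Repetition time in milliseconds (alternative to `tr`).
#' @param dynamic_flip_angle Flip angle (degrees) of the dynamic
#'   post-contrast series. Default 15, the usual choice when the VFA set
#'   includes it.
#' @param frame_times Numeric vector of dynamic frame times in minutes
#'   post-injection, strictly increasing, all >= 0. May be `NULL` when only
#'   pre-contrast fitting is needed.
#' @param relaxivity_r1 Longitudinal relaxivity r1 of the contrast agent in
#'   mM^-1 s^-1 (measured per agent batch; no universal default exists, so a
#'   value must be supplied before concentration conversion).
#'
#' @return An object of class `acq_params`: a list with elements `tr` (s),
#'   `flip_angles` (deg), `dynamic_flip_angle` (deg), `frame_times` (min)
#'   and `relaxivity_r1` (mM^-1 s^-1).
#' @examples
#' acq <- acq_params(flip_angles = c(5, 15, 30, 50, 70), tr_ms = 10,
#'                   frame_times = seq(1, 35, by = 2), relaxivity_r1 = 3.3)
#' acq$tr  # 0.01 s
#' @export
acq_params <- function(flip_angles, tr = NULL, tr_ms = NULL,
                       dynamic_flip_angle = 15, frame_times = NULL,
                       relaxivity_r1 = NA_real_) {
  if (is.null(tr) && is.null(tr_ms))
    stop("supply the repetition time as `tr` (seconds) or `tr_ms` (milliseconds)")
  if (!is.null(tr) && !is.null(tr_ms))
    stop("supply only one of `tr` and `tr_ms`")
  if (!is.null(tr_ms)) tr <- tr_ms / 1000
  stopifnot(is.numeric(tr), length(tr) == 1L, is.finite(tr))
  if (tr <= 0) stop("tr must be positive")
  flip_angles <- as.numeric(flip_angles)
  if (length(flip_angles) < 1L || any(!is.finite(flip_angles)))
    stop("flip_angles must be a non-empty finite numeric vector")
  if (any(flip_angles <= 0 | flip_angles > 90))
    stop("all flip angles must lie in (0, 90] degrees")
  stopifnot(length(dynamic_flip_angle) == 1L)
  if (dynamic_flip_angle <= 0 || dynamic_flip_angle > 90)
    stop("dynamic_flip_angle must lie in (0, 90] degrees")
  if (!is.null(frame_times)) {
    frame_times <- as.numeric(frame_times)
    if (any(!is.finite(frame_times)) || any(frame_times < 0))
      stop("frame_times must be finite and non-negative (minutes post-injection)")
    if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  if (!is.na(relaxivity_r1) && relaxivity_r1 <= 0)
    stop("relaxivity_r1 must be positive (mM^-1 s^-1)")
  structure(list(tr = tr,
                 flip_angles = flip_angles,
                 dynamic_flip_angle = dynamic_flip_angle,
                 frame_times = frame_times,
                 relaxivity_r1 = relaxivity_r1),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("SPGR acquisition parameters\n")
  cat(sprintf("  TR: %g ms\n", x$tr * 1000))
  cat(sprintf("  VFA flip angles: %s deg\n", paste(x$flip_angles, collapse = ", ")))
  cat(sprintf("  dynamic flip angle: %g deg\n", x$dynamic_flip_angle))
  if (!is.null(x$frame_times))
    cat(sprintf("  dynamic frames: %d (%g-%g min)\n", length(x$frame_times),
                min(x$frame_times), max(x$frame_times)))
  cat(sprintf("  relaxivity r1: %s mM^-1 s^-1\n",
              ifelse(is.na(x$relaxivity_r1), "<unset>", format(x$relaxivity_r1))))
  invisible(x)
}

#' Dynamic concentration / signal series
#'
#' A light container pairing a 4D array, ordered (x, y, z, t), with its frame
#' times in minutes post-injection. Used both for simulated/measured signal
#' and for derived concentration (mM).
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param frame_times Frame times in minutes, strictly increasing, length
#'   equal to `dim(data)[4]`.
#' @param unit Character label, e.g. `"mM"` or `"a.u."`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, frame_times, unit = "a.u.") {
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 4D array (x, y, z, t)")
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != dim(data)[4])
    stop("length(frame_times) must equal the number of frames")
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (any(frame_times < 0)) stop("frame_times must be non-negative")
  structure(list(data = data, frame_times = frame_times, unit = unit),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dce_series: %d x %d x %d volume, %d frames (%g-%g min), unit %s\n",
              d[1], d[2], d[3], d[4], min(x$frame_times), max(x$frame_times),
              x$unit))
  invisible(x)
}
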