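#' Read a NIfTI-1 volume
#'
#' Thin wrapper over [RNifti::readNifti()] returning a plain numeric array
#' (3D or 4D, ordered x, y, z\[, t\]) with the voxel size attached as the
#' `voxel_size` attribute (mm).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array with attribute `voxel_size`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  arr
}

#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array (x, y, z\[, t\]).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm (length 3); taken from the array's
#'   `voxel_size` attribute when present.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  if (is.null(voxel_size)) voxel_size <- attr(vol, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- c(voxel_size,
                           rep(1, max(0L, length(dim(vol)) - 3L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated phantom dataset to disk
#'
#' Writes the VFA image set (4D, flip-angle last), the dynamic signal
#' series (4D), the ground-truth parameter maps and label volume as
#' NIfTI-1, plus a JSON sidecar echoing the phantom specification,
#' acquisition parameters and frame times.
#'
#' @param sim Output of [simulate_acquisition()].
#' @param truth The `phantom_truth` that generated `sim`.
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
write_phantom_dataset <- function(sim, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- truth$spec$voxel_size
  paths <- c(vfa = file.path(dir, "vfa.nii.gz"),
             dynamic = file.path(dir, "dynamic.nii.gz"),
             labels = file.path(dir, "truth_labels.nii.gz"),
             fbv = file.path(dir, "truth_fbv.nii.gz"),
             ps = file.path(dir, "truth_ps.nii.gz"),
             late = file.path(dir, "truth_late_rate.nii.gz"),
             r1pre = file.path(dir, "truth_r1pre.nii.gz"),
             sidecar = file.path(dir, "dataset.json"))
  write_volume(sim$vfa, paths["vfa"], vs)
  write_volume(sim$dynamic$data, paths["dynamic"], vs)
  write_volume(truth$label_volume, paths["labels"], vs)
  write_volume(truth$fbv_true, paths["fbv"], vs)
  write_volume(truth$ps_true, paths["ps"], vs)
  write_volume(truth$late_rate_true, paths["late"], vs)
  write_volume(truth$r1pre_true, paths["r1pre"], vs)
  sidecar <- list(spec = unclass(truth$spec),
                  acquisition = unclass(sim$acq),
                  frame_times_min = sim$dynamic$frame_times,
                  cb0_true_mM = truth$cb0_true,
                  labels = as.list(PHANTOM_LABELS),
                  follicles = truth$follicles)
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The configuration mirrors the analysis stages: an `acquisition` block
#' (`tr_ms` or `tr_s`, `flip_angles_deg`, `dynamic_flip_angle_deg`,
#' `frame_times_min`, `relaxivity_per_mM_s`), optional `windows`
#' (`early_min`, `late_min`, `spike_threshold_mM`), optional `histograms`
#' (`fbv_range`, `ps_range`, `n_bins`), input paths (`vfa`, `dynamic`,
#' `ovary_roi`, optional `blood_roi`) and either a `blood_roi` path or an
#' explicit `cb0_mM`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A list of class `pipeline_config` with a parsed
#'   `acq` ([acq_params()]) and `windows` ([kinetic_windows()]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  as_pipeline_config(raw, base_dir = dirname(path))
}

#' Build a pipeline configuration from a list
#'
#' @param x List with the blocks described in [read_pipeline_config()].
#' @param base_dir Directory against which relative paths are resolved.
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x, base_dir = ".") {
  ac <- x$acquisition
  if (is.null(ac)) stop("config lacks an `acquisition` block")
  acq <- acq_params(
    flip_angles = ac$flip_angles_deg,
    tr = if (!is.null(ac$tr_s)) ac$tr_s else NULL,
    tr_ms = if (!is.null(ac$tr_ms)) ac$tr_ms else NULL,
    dynamic_flip_angle = if (!is.null(ac$dynamic_flip_angle_deg))
      ac$dynamic_flip_angle_deg else 15,
    frame_times = ac$frame_times_min,
    relaxivity_r1 = if (!is.null(ac$relaxivity_per_mM_s))
      ac$relaxivity_per_mM_s else NA_real_)
  w <- x$windows
  windows <- kinetic_windows(
    early = if (!is.null(w$early_min)) w$early_min else c(0, 15),
    late = if (!is.null(w$late_min)) w$late_min else c(25, 35),
    spike_threshold = if (!is.null(w$spike_threshold_mM))
      w$spike_threshold_mM else 10)
  h <- x$histograms
  hist_cfg <- list(
    fbv_range = if (!is.null(h$fbv_range)) as.numeric(h$fbv_range) else c(0, 0.1),
    ps_range = if (!is.null(h$ps_range)) as.numeric(h$ps_range) else c(0, 0.02),
    n_bins = if (!is.null(h$n_bins)) as.integer(h$n_bins) else 50L)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  cfg <- list(acq = acq, windows = windows, histograms = hist_cfg,
              vfa = resolve(x$vfa), dynamic = resolve(x$dynamic),
              ovary_roi = resolve(x$ovary_roi),
              blood_roi = resolve(x$blood_roi),
              cb0 = if (!is.null(x$cb0_mM)) as.numeric(x$cb0_mM) else NULL,
              seed = if (!is.null(x$seed)) as.integer(x$seed) else 1L,
              raw = x)
  class(cfg) <- "pipeline_config"
  cfg
}

# Stable hash of the configuration for provenance: md5 of its canonical
# JSON serialization.
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg$raw, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full DCE-MRI analysis pipeline
#'
#' Executes the analysis end to end on one dataset: voxel-wise VFA T1
#' mapping, conversion of the dynamic series to concentration, blood
#' reference estimation (unless `cb0` is given), early-window fBV/PS
#' mapping, spike thresholding and late-enhancement mapping, and ROI
#' summaries/histograms. Each stage's errors are tagged with the stage
#' name. Outputs (NIfTI maps, histogram CSVs, a JSON report carrying the
#' config hash, cb0, windows and excluded spike fraction) are written to
#' `out_dir` when given; reruns on identical inputs produce byte-identical
#' files.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()] /
#'   [as_pipeline_config()]), or a path to a config file. In-memory inputs
#'   can be supplied directly via `vfa`, `dynamic`, `ovary_roi`,
#'   `blood_roi` arguments, which override the config paths.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param vfa,dynamic,ovary_roi,blood_roi Optional in-memory inputs: 4D
#'   VFA array, [dce_series()] (or 4D array) of dynamic signal, and 3D
#'   masks.
#' @return List of class `pipeline_result`: `relax` (relaxometry maps),
#'   `conc` (concentration series), `vmaps` (vascular maps with
#'   `late_rate` merged), `spike` (spike-threshold output), `histograms`,
#'   `ovary_means`, and `report` (the JSON-serializable provenance
#'   report).
#' @export
run_pipeline <- function(config, out_dir = NULL, vfa = NULL, dynamic = NULL,
                         ovary_roi = NULL, blood_roi = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  acq <- config$acq; windows <- config$windows

  vfa <- .stage("load", {
    if (is.null(vfa)) {
      if (is.null(config$vfa)) stop("no VFA input given")
      read_volume(config$vfa)
    } else vfa
  })
  dynamic <- .stage("load", {
    if (is.null(dynamic)) {
      if (is.null(config$dynamic)) stop("no dynamic input given")
      dce_series(read_volume(config$dynamic), acq$frame_times)
    } else if (inherits(dynamic, "dce_series")) dynamic
    else dce_series(dynamic, acq$frame_times)
  })
  dims <- dim(dynamic$data)[1:3]
  ovary_roi <- .stage("load", {
    if (is.null(ovary_roi) && !is.null(config$ovary_roi))
      ovary_roi <- read_volume(config$ovary_roi)
    if (is.null(ovary_roi)) array(TRUE, dims)
    else .as_roi_mask(ovary_roi, dims)
  })
  if (is.null(blood_roi) && !is.null(config$blood_roi))
    blood_roi <- .stage("load", read_volume(config$blood_roi))

  relax <- .stage("fit-t1", fit_r1_vfa(vfa, acq))
  pre_ref <- .stage("concentration", {
    j <- which(abs(acq$flip_angles - acq$dynamic_flip_angle) < 1e-9)
    if (length(j) == 0L)
      stop("no VFA volume matches the dynamic flip angle (",
           acq$dynamic_flip_angle, " deg) to serve as the pre-contrast reference")
    vfa[, , , j[1]]
  })
  conc <- .stage("concentration",
                 concentration_series(dynamic, pre_ref, relax, acq))
  cb0 <- .stage("kinetics", {
    if (!is.null(config$cb0)) config$cb0
    else if (!is.null(blood_roi))
      estimate_blood_reference(conc, blood_roi, windows)
    else stop("supply a blood ROI or an explicit cb0_mM in the config")
  })
  vmaps <- .stage("kinetics", fit_vascular_params(conc, cb0, windows))
  spike <- .stage("kinetics",
                  apply_spike_threshold(conc, windows$spike_threshold,
                                        roi = ovary_roi))
  late <- .stage("kinetics",
                 fit_late_enhancement(conc, windows,
                                      exclude_mask = spike$excluded_mask))
  vmaps$late_rate <- late$late_rate
  vmaps$late_valid_mask <- late$valid_mask

  hist_cfg <- config$histograms
  histograms <- .stage("roi-analysis", list(
    fbv = roi_histogram(vmaps$fbv, ovary_roi, hist_cfg$fbv_range,
                        hist_cfg$n_bins, roi_id = "ovary", map_name = "fbv"),
    ps = roi_histogram(vmaps$ps, ovary_roi, hist_cfg$ps_range,
                       hist_cfg$n_bins, roi_id = "ovary", map_name = "ps")))
  ovary_means <- .stage("roi-analysis", list(
    fbv = roi_average(vmaps$fbv, ovary_roi),
    ps = roi_average(vmaps$ps, ovary_roi),
    late_rate = roi_average(vmaps$late_rate, ovary_roi)))

  report <- list(package_version = as.character(utils::packageVersion("ovadce")),
                 config_hash = .config_hash(config),
                 seed = config$seed,
                 tr_s = acq$tr, flip_angles_deg = acq$flip_angles,
                 dynamic_flip_angle_deg = acq$dynamic_flip_angle,
                 relaxivity_per_mM_s = acq$relaxivity_r1,
                 windows = list(early_min = windows$early,
                                late_min = windows$late,
                                spike_threshold_mM = windows$spike_threshold),
                 cb0_mM = cb0,
                 n_valid_voxels = sum(vmaps$valid_mask),
                 spike_excluded_fraction = spike$excluded_fraction,
                 ovary_means = ovary_means)

  result <- structure(list(relax = relax, conc = conc, vmaps = vmaps,
                           spike = spike, histograms = histograms,
                           ovary_means = ovary_means, report = report),
                      class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vm <- result$vmaps
  na0 <- function(x) { x[!is.finite(x)] <- NA_real_; x }
  write_volume(na0(result$relax$r1pre), file.path(out_dir, "r1pre.nii.gz"))
  write_volume(na0(result$relax$m0), file.path(out_dir, "m0.nii.gz"))
  write_volume(na0(vm$fbv), file.path(out_dir, "fbv.nii.gz"))
  write_volume(na0(vm$ps), file.path(out_dir, "ps.nii.gz"))
  write_volume(na0(vm$late_rate), file.path(out_dir, "late_rate.nii.gz"))
  write_volume(vm$valid_mask + 0, file.path(out_dir, "qc_valid_mask.nii.gz"))
  write_volume(result$spike$excluded_mask + 0,
               file.path(out_dir, "qc_spike_mask.nii.gz"))
  for (nm in names(result$histograms)) {
    h <- result$histograms[[nm]]
    utils::write.csv(
      data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
                 bin_hi = h$bin_edges[-1],
                 count = h$counts, percent = h$percent),
      file.path(out_dir, paste0("histogram_", nm, ".csv")),
      row.names = FALSE)
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("DCE-MRI pipeline result\n")
  cat(sprintf("  cb0: %g mM; valid voxels: %d; spike-excluded fraction: %.4f\n",
              x$report$cb0_mM, x$report$n_valid_voxels,
              x$report$spike_excluded_fraction))
  cat(sprintf("  ovary means: fBV %.4f, PS %.5f min^-1, late rate %.5f mM/min\n",
              x$ovary_means$fbv, x$ovary_means$ps, x$ovary_means$late_rate))
  invisible(x)
}
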