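#' Specification of a digital ovary phantom
#'
#' Describes the geometry, kinetic ground truth layout, acquisition noise
#' and timing of a synthetic ovary-like DCE-MRI dataset. The phantom places
#' spherical follicles in a stromal background: dominant follicles (DF) and
#' subordinate follicles (SF) are avascular antral cavities wrapped in a
#' vascularized theca-like shell, while corpora lutea (CL) are filled
#' spheres with markedly elevated blood volume. A small blood-pool block in
#' one corner provides a pure-blood reference region.
#'
#' Kinetic signatures follow the biology the analysis is designed to
#' detect: DF antra accumulate macromolecular contrast late (positive
#' late-enhancement rate, interstitial convection into the cavity), SF
#' antra plateau and then clear (non-positive late rate), CL show high
#' fractional blood volume with permeability similar to DF.
#'
#' @param grid_shape Integer length-3, voxels per axis; each >= 16.
#' @param voxel_size Numeric length-3, voxel size in mm.
#' @param n_follicles Number of follicles to place (>= 0).
#' @param follicle_kinds Character vector recycled to `n_follicles`, values
#'   in `c("DF", "SF", "CL")`.
#' @param radius_range Follicle radius range in voxels (sampled uniformly).
#' @param shell_thickness Theca shell thickness in voxels (>= 1).
#' @param noise_sigma Acquisition noise standard deviation as a fraction of
#'   the peak noiseless dynamic signal (0 disables noise).
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude).
#' @param seed Integer seed controlling geometry and noise.
#' @param frame_times Dynamic frame times, minutes post-injection; default
#'   a 2-min cadence over 35 min as in a long macromolecular-agent
#'   protocol.
#' @param blood_curve `"constant"` (macromolecular agent, long circulation)
#'   or `"monoexp"` decay with half-life `blood_half_life`.
#' @param blood_half_life Blood half-life in minutes (monoexp curve only).
#' @param cb0 Blood plasma concentration at injection, mM.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size = c(0.117, 0.117, 0.5),
                         n_follicles = 3,
                         follicle_kinds = c("DF", "SF", "CL"),
                         radius_range = c(5, 8),
                         shell_thickness = 2,
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L,
                         frame_times = seq(1, 35, by = 2),
                         blood_curve = c("constant", "monoexp"),
                         blood_half_life = 120,
                         cb0 = 1.0) {
  noise_model <- match.arg(noise_model)
  blood_curve <- match.arg(blood_curve)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L)
  if (any(grid_shape < 16L))
    stop("grid_shape must be at least 16 voxels per axis")
  if (n_follicles < 0) stop("n_follicles must be >= 0")
  if (shell_thickness < 1) stop("shell_thickness must be >= 1 voxel")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cb0 <= 0) stop("cb0 must be positive (mM)")
  if (blood_half_life <= 0) stop("blood_half_life must be positive (min)")
  frame_times <- as.numeric(frame_times)
  if (frame_times[1] < 0 || any(diff(frame_times) <= 0))
    stop("frame_times must be non-negative and strictly increasing")
  if (n_follicles > 0) {
    if (!all(follicle_kinds %in% c("DF", "SF", "CL")))
      stop("follicle_kinds must be drawn from {DF, SF, CL}")
    follicle_kinds <- rep_len(follicle_kinds, n_follicles)
  } else follicle_kinds <- character(0)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 n_follicles = as.integer(n_follicles),
                 follicle_kinds = follicle_kinds,
                 radius_range = as.numeric(radius_range),
                 shell_thickness = shell_thickness,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed), frame_times = frame_times,
                 blood_curve = blood_curve, blood_half_life = blood_half_life,
                 cb0 = cb0),
            class = "phantom_spec")
}

# Compartment labels in the phantom label volume.
PHANTOM_LABELS <- c(stroma = 0L, antrum = 1L, shell = 2L, blood_pool = 3L)

# Ground-truth tissue parameters per compartment: fractional blood volume,
# permeability (min^-1), late-enhancement rate (mM/min), pre-contrast R1
# (s^-1) and M0. Values are the study conditions the phantom emulates:
# DF shells are tight (low PS), SF shells leaky, CL filled and blood-rich;
# DF antra accumulate late, SF antra clear.
.phantom_tissue_table <- function(cb0) {
  tab <- list(
    stroma     = list(fbv = 0.02, ps = 0.005,  late = NA,     r1 = 0.70, m0 = 1000),
    DF_shell   = list(fbv = 0.04, ps = 0.002,  late = NA,     r1 = 0.75, m0 = 1050),
    SF_shell   = list(fbv = 0.04, ps = 0.010,  late = -0.003, r1 = 0.75, m0 = 1050),
    CL_body    = list(fbv = 0.15, ps = 0.002,  late = NA,     r1 = 0.80, m0 = 1100),
    DF_antrum  = list(fbv = 0.00, ps = 0.0005, late = 0.020,  r1 = 0.35, m0 = 1200),
    SF_antrum  = list(fbv = 0.00, ps = 0.004,  late = -0.003, r1 = 0.35, m0 = 1200),
    blood_pool = list(fbv = 1.00, ps = 0.000,  late = 0.0,    r1 = 0.45, m0 = 1150))
  # DF-side and stromal compartments keep accumulating slowly at late
  # times; SF compartments plateau early and then clear (fixed above,
  # shallow enough that concentration never goes negative by 35 min)
  for (nm in c("stroma", "DF_shell", "CL_body"))
    tab[[nm]]$late <- 0.5 * tab[[nm]]$ps * cb0
  tab
}

#' Build a digital ovary phantom with known ground truth
#'
#' Realizes the geometry described by a [phantom_spec()]: spherical
#' follicles are placed by rejection sampling (non-overlapping, fully
#' inside the grid) and each voxel is assigned ground-truth fractional
#' blood volume, permeability, late-enhancement rate, pre-contrast R1 and
#' M0 according to its compartment. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth`: 3D arrays `label_volume`
#'   (0 stroma, 1 antrum, 2 shell/CL body, 3 blood pool), `follicle_id`
#'   (0 outside follicles), `fbv_true`, `ps_true` (min^-1),
#'   `late_rate_true` (mM/min), `r1pre_true` (s^-1), `m0_true`; scalar
#'   `cb0_true` (mM); a `follicles` data frame (id, kind, center, radius);
#'   and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  tab <- .phantom_tissue_table(spec$cb0)
  lab <- array(PHANTOM_LABELS[["stroma"]], gs)
  fid <- array(0L, gs)
  fbv <- array(tab$stroma$fbv, gs); ps <- array(tab$stroma$ps, gs)
  late <- array(tab$stroma$late, gs); r1 <- array(tab$stroma$r1, gs)
  m0 <- array(tab$stroma$m0, gs)

  ax <- seq_len(gs[1]); ay <- seq_len(gs[2]); az <- seq_len(gs[3])
  # blood-pool reference block in the low corner
  bp <- min(4L, gs[1] - 1L)
  bp_mask <- array(FALSE, gs); bp_mask[1:bp, 1:bp, 1:bp] <- TRUE
  set_comp <- function(mask, nm, label, id = 0L) {
    p <- tab[[nm]]
    lab[mask] <<- label; fid[mask] <<- id
    fbv[mask] <<- p$fbv; ps[mask] <<- p$ps; late[mask] <<- p$late
    r1[mask] <<- p$r1; m0[mask] <<- p$m0
  }
  set_comp(bp_mask, "blood_pool", PHANTOM_LABELS[["blood_pool"]])

  place_one_config <- function() {
    placed <- list()
    for (i in seq_len(spec$n_follicles)) {
      kind <- spec$follicle_kinds[i]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        rad <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        r_out <- rad + spec$shell_thickness
        if (any(gs < 2 * (r_out + 1) + 1))
          stop("follicle of radius ", round(rad, 1),
               " + shell cannot fit inside the grid")
        ctr <- vapply(gs, function(n) stats::runif(1, r_out + 1, n - r_out),
                      numeric(1))
        # keep clear of previously placed follicles and the blood pool
        clear <- all(vapply(placed, function(p)
          sqrt(sum((p$ctr - ctr)^2)) > p$r_out + r_out + 1, logical(1)))
        if (clear && sqrt(sum((ctr - 1)^2)) > r_out + bp * sqrt(3) + 1) {
          placed[[length(placed) + 1L]] <- list(ctr = ctr, r_out = r_out,
                                                rad = rad, kind = kind)
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)  # this configuration painted itself into a corner
    }
    placed
  }
  # rejection sampling is bounded per follicle; an unlucky early placement
  # can make the rest infeasible, so restart the whole configuration a
  # bounded number of times before declaring the geometry impossible
  place_follicles <- function() {
    for (restart in seq_len(20L)) {
      placed <- place_one_config()
      if (!is.null(placed)) return(placed)
    }
    stop("could not place ", spec$n_follicles, " non-overlapping follicles ",
         "in the grid after bounded retries; reduce n_follicles or radius_range")
  }
  placed <- if (spec$n_follicles > 0) .with_seed(spec$seed, place_follicles())
            else list()
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    d2 <- outer(outer((ax - p$ctr[1])^2, (ay - p$ctr[2])^2, "+"),
                (az - p$ctr[3])^2, "+")
    outer_mask <- d2 <= (p$rad + spec$shell_thickness)^2
    inner_mask <- d2 <= p$rad^2
    if (p$kind == "CL") {
      set_comp(outer_mask, "CL_body", PHANTOM_LABELS[["shell"]], i)
    } else {
      shell_nm <- if (p$kind == "DF") "DF_shell" else "SF_shell"
      antrum_nm <- if (p$kind == "DF") "DF_antrum" else "SF_antrum"
      set_comp(outer_mask & !inner_mask, shell_nm,
               PHANTOM_LABELS[["shell"]], i)
      set_comp(inner_mask, antrum_nm, PHANTOM_LABELS[["antrum"]], i)
    }
  }
  follicles <- if (length(placed))
    do.call(rbind, lapply(seq_along(placed), function(i)
      data.frame(id = i, kind = placed[[i]]$kind, cx = placed[[i]]$ctr[1],
                 cy = placed[[i]]$ctr[2], cz = placed[[i]]$ctr[3],
                 radius = placed[[i]]$rad)))
  else data.frame(id = integer(0), kind = character(0), cx = numeric(0),
                  cy = numeric(0), cz = numeric(0), radius = numeric(0))
  structure(list(label_volume = lab, follicle_id = fid,
                 fbv_true = fbv, ps_true = ps, late_rate_true = late,
                 r1pre_true = r1, m0_true = m0, cb0_true = spec$cb0,
                 follicles = follicles, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s grid, %d follicles (%s), cb0 = %g mM\n",
              paste(dim(x$label_volume), collapse = " x "),
              nrow(x$follicles),
              if (nrow(x$follicles)) paste(x$follicles$kind, collapse = ", ")
              else "none", x$cb0_true))
  invisible(x)
}

# Blood concentration curve Cb(t) in mM at times t (minutes).
.blood_curve <- function(spec, t) {
  switch(spec$blood_curve,
         constant = rep(spec$cb0, length(t)),
         monoexp = spec$cb0 * exp(-log(2) * t / spec$blood_half_life))
}

#' Forward-simulate tissue contrast concentration
#'
#' Generates the voxel-wise concentration time course implied by the
#' phantom ground truth. In the early regime each voxel follows the linear
#' uptake model underlying the fBV/PS analysis,
#' \eqn{C(t) = fBV \cdot C_b(t) + PS \cdot c_{b0} \cdot t}, and beyond 20
#' min the slope hands over to the compartment's ground-truth late rate
#' through a linear cross-fade between 18 and 22 min, producing the
#' DF-accumulation / SF-clearance contrast in the 25-35 min window.
#'
#' @param truth A `phantom_truth` from [build_phantom()].
#' @param frame_times Frame times in minutes; defaults to the ones in the
#'   phantom's [phantom_spec()].
#' @return A [dce_series()] of concentration in mM.
#' @export
simulate_concentration <- function(truth, frame_times = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(frame_times)) frame_times <- truth$spec$frame_times
  frame_times <- as.numeric(frame_times)
  if (any(frame_times < 0)) stop("frame_times must be non-negative")
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  gs <- dim(truth$label_volume)
  cb <- .blood_curve(truth$spec, frame_times)
  t_break <- 20; fade <- c(18, 22)
  cb_break <- .blood_curve(truth$spec, t_break)
  conc <- array(NA_real_, c(gs, length(frame_times)))
  early_at <- function(t, cbt)
    truth$fbv_true * cbt + truth$ps_true * truth$cb0_true * t
  c_break <- early_at(t_break, cb_break)
  for (k in seq_along(frame_times)) {
    t <- frame_times[k]
    w <- min(max((t - fade[1]) / diff(fade), 0), 1)
    conc[, , , k] <- (1 - w) * early_at(t, cb[k]) +
      w * (c_break + truth$late_rate_true * (t - t_break))
  }
  dce_series(conc, frame_times, unit = "mM")
}

#' Forward-simulate the MRI acquisition of a phantom
#'
#' Converts ground-truth relaxometry and a concentration series into raw
#' SPGR magnitudes: a pre-contrast VFA image set at `R1 = r1pre_true` and
#' a dynamic post-contrast series at the dynamic flip angle with
#' `R1(t) = r1pre_true + r1 * C(t)`. Seeded acquisition noise (Gaussian
#' additive or Rician magnitude) is added last, with standard deviation
#' `spec$noise_sigma` times the peak noiseless dynamic signal.
#'
#' @param truth A `phantom_truth`.
#' @param conc A [dce_series()] of concentration in mM, e.g. from
#'   [simulate_concentration()].
#' @param acq An [acq_params()] with `relaxivity_r1` set.
#' @return List with `vfa` (4D array, x,y,z,flip angle), `dynamic`
#'   (a [dce_series()] of signal), `acq`, and `noise_sigma_abs` (the
#'   absolute noise SD applied).
#' @export
simulate_acquisition <- function(truth, conc, acq) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(conc, "dce_series"),
            inherits(acq, "acq_params"))
  if (length(acq$flip_angles) < 1L) stop("acq$flip_angles must be non-empty")
  if (is.na(acq$relaxivity_r1) || acq$relaxivity_r1 <= 0)
    stop("acq$relaxivity_r1 must be positive")
  gs <- dim(truth$label_volume)
  nfa <- length(acq$flip_angles)
  vfa <- array(NA_real_, c(gs, nfa))
  for (j in seq_len(nfa))
    vfa[, , , j] <- spgr_signal(truth$m0_true, truth$r1pre_true,
                                acq$flip_angles[j], acq$tr)
  nt <- length(conc$frame_times)
  dyn <- array(NA_real_, c(gs, nt))
  for (k in seq_len(nt)) {
    r1t <- truth$r1pre_true + acq$relaxivity_r1 * conc$data[, , , k]
    dyn[, , , k] <- spgr_signal(truth$m0_true, pmax(r1t, 1e-6),
                                acq$dynamic_flip_angle, acq$tr)
  }
  sigma <- truth$spec$noise_sigma * max(dyn)
  if (truth$spec$noise_sigma > 0) {
    .with_seed(truth$spec$seed + 1L, {
      vfa <- .add_noise(vfa, sigma, truth$spec$noise_model)
      dyn <- .add_noise(dyn, sigma, truth$spec$noise_model)
    })
  }
  list(vfa = vfa,
       dynamic = dce_series(dyn, conc$frame_times, unit = "a.u."),
       acq = acq, noise_sigma_abs = sigma)
}

.add_noise <- function(x, sigma, model) {
  n <- length(x)
  if (model == "gaussian") {
    x + stats::rnorm(n, 0, sigma)
  } else {
    # Rician: magnitude of the complex signal with iid Gaussian noise on
    # the real (signal-bearing) and imaginary channels
    sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
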