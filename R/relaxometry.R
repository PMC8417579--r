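#' Steady-state SPGR signal
#'
#' Signal intensity of a spoiled gradient-echo acquisition as a function of
#' flip angle, repetition time and longitudinal relaxation rate:
#' \deqn{I(\alpha) = M_0 \sin\alpha \, \frac{1 - E}{1 - \cos\alpha \, E},
#'       \quad E = e^{-TR \cdot R_1}.}
#' `M0` absorbs spin density, coil sensitivity and the (fixed-TE) T2*
#' weighting; no separate T2* term is modelled.
#'
#' All arguments are vectorized and recycled against each other.
#'
#' @param m0 Equilibrium signal amplitude (arbitrary units), > 0 for
#'   physical voxels.
#' @param r1 Longitudinal relaxation rate in s^-1, > 0.
#' @param alpha Flip angle in degrees, in (0, 90].
#' @param tr Repetition time in seconds, > 0.
#' @return Signal intensity, same units as `m0`.
#' @examples
#' spgr_signal(1000, 1, 15, 0.01)  # about 58.95
#' @export
spgr_signal <- function(m0, r1, alpha, tr) {
  if (any(r1 <= 0, na.rm = TRUE)) stop("r1 must be positive (s^-1)")
  if (any(tr <= 0, na.rm = TRUE)) stop("tr must be positive (s)")
  if (any(alpha <= 0 | alpha > 90, na.rm = TRUE))
    stop("alpha must lie in (0, 90] degrees")
  a <- alpha * pi / 180
  e1 <- exp(-tr * r1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# DESPOT1 linearization: regressing I/sin(a) on I/tan(a) across flip angles
# gives slope E = exp(-TR R1) and intercept M0 (1 - E). Exact on noiseless
# data; used to seed the nonlinear fit. `sig` is an n_vox x n_fa matrix.
.vfa_linear_init <- function(sig, alpha_deg, tr, r1_bounds) {
  a <- alpha_deg * pi / 180
  y <- sweep(sig, 2L, sin(a), "/")
  x <- sweep(sig, 2L, tan(a), "/")
  n <- ncol(sig)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- n * sxx - sx * sx
  slope <- (n * sxy - sx * sy) / denom
  icept <- (sy - slope * sx) / n
  e_lo <- exp(-tr * r1_bounds[2]); e_hi <- exp(-tr * r1_bounds[1])
  e <- pmin(pmax(slope, e_lo), e_hi)
  r1 <- -log(e) / tr
  m0 <- icept / (1 - e)
  bad <- !is.finite(r1) | !is.finite(m0) | m0 <= 0
  r1[bad] <- 1
  m0[bad] <- rowSums(sig)[bad] / n  # crude fallback scale
  list(m0 = m0, r1 = r1)
}

# Vectorized Levenberg-Marquardt for the two-parameter SPGR model, run
# simultaneously over all voxels (rows of `sig`). Analytic Jacobian; the
# 2x2 normal equations are solved in closed form per voxel. Voxels whose
# step does not reduce the RSS keep their parameters and get a larger
# damping factor, so the iteration is monotone per voxel.
.vfa_lm_fit <- function(sig, alpha_deg, tr, init, r1_bounds,
                        max_iter = 60L, tol = 1e-12) {
  a <- alpha_deg * pi / 180
  sa <- sin(a); ca <- cos(a)
  nv <- nrow(sig)
  m0 <- init$m0; r1 <- init$r1
  model_rss <- function(m0, r1) {
    e1 <- exp(outer(-tr * r1, rep(1, length(a))))
    den <- 1 - outer(rep(1, nv), ca) * e1
    fit <- outer(m0, sa) * (1 - e1) / den
    list(fit = fit, rss = rowSums((sig - fit)^2), e1 = e1, den = den)
  }
  cur <- model_rss(m0, r1)
  lambda <- rep(1e-3, nv)
  for (it in seq_len(max_iter)) {
    resid <- sig - cur$fit
    # dI/dM0 = I / M0 ; dI/dR1 = M0 sin(a) (1 - cos a) TR E / (1 - cos a E)^2
    j1 <- cur$fit / m0
    j2 <- outer(m0, sa) * outer(rep(1, nv), 1 - ca) * tr * cur$e1 / cur$den^2
    a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
    g1 <- rowSums(j1 * resid); g2 <- rowSums(j2 * resid)
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12 * a12
    det[det == 0 | !is.finite(det)] <- NA_real_
    dm0 <- (d22 * g1 - a12 * g2) / det
    dr1 <- (d11 * g2 - a12 * g1) / det
    dm0[!is.finite(dm0)] <- 0; dr1[!is.finite(dr1)] <- 0
    m0_new <- m0 + dm0
    r1_new <- pmin(pmax(r1 + dr1, r1_bounds[1]), r1_bounds[2])
    m0_new[m0_new <= 0] <- m0[m0_new <= 0]
    new <- model_rss(m0_new, r1_new)
    better <- is.finite(new$rss) & new$rss < cur$rss
    m0 <- ifelse(better, m0_new, m0)
    r1 <- ifelse(better, r1_new, r1)
    lambda <- ifelse(better, pmax(lambda / 3, 1e-10), pmin(lambda * 10, 1e8))
    step <- pmax(abs(dm0) / pmax(abs(m0), 1e-12),
                 abs(dr1) / pmax(abs(r1), 1e-12))
    cur <- model_rss(m0, r1)
    if (all(!better | step < tol)) break
  }
  # given R1, the model is linear in M0: close with the exact LS amplitude
  g <- outer(rep(1, nv), sa) * (1 - cur$e1) / cur$den
  m0_lin <- rowSums(sig * g) / rowSums(g * g)
  ok <- is.finite(m0_lin) & m0_lin > 0
  upd <- model_rss(ifelse(ok, m0_lin, m0), r1)
  keep <- upd$rss <= cur$rss + 1e-30
  m0 <- ifelse(ok & keep, m0_lin, m0)
  cur <- model_rss(m0, r1)
  list(m0 = m0, r1 = r1, rss = cur$rss)
}

#' Voxel-wise T1 mapping from variable-flip-angle SPGR data
#'
#' Fits the two-parameter SPGR model (see [spgr_signal()]) to each voxel of
#' a multi-flip-angle pre-contrast acquisition by nonlinear least squares,
#' producing maps of the pre-contrast relaxation rate `R1pre` and amplitude
#' `M0`. The solver is a damped Gauss-Newton (Levenberg-Marquardt)
#' iteration run simultaneously over all voxels, seeded by the classical
#' linearized regression of I/sin(a) on I/tan(a), with R1 constrained to
#' `r1_bounds`.
#'
#' Voxels whose maximum signal across flip angles does not exceed
#' `signal_floor` (default: 2% of the volume's 99th-percentile signal) are
#' marked invalid and carry `NA` in all maps; a failed or non-finite fit
#' likewise yields an invalid voxel rather than an error.
#'
#' @param vfa_images 4D array (x, y, z, flip angle) of pre-contrast SPGR
#'   magnitudes, one volume per flip angle in the order of
#'   `acq$flip_angles`.
#' @param acq An [acq_params()] object; at least 3 flip angles required.
#' @param signal_floor Validity threshold on the per-voxel maximum signal;
#'   `NULL` (default) uses 2% of the whole-volume 99th percentile.
#' @param r1_bounds Length-2 vector, admissible R1 range in s^-1.
#' @return An object of class `relaxometry_maps`: list of 3D arrays
#'   `r1pre` (s^-1), `m0`, `fit_rss`, and logical `valid_mask`.
#' @export
fit_r1_vfa <- function(vfa_images, acq, signal_floor = NULL,
                       r1_bounds = c(0.05, 20)) {
  stopifnot(inherits(acq, "acq_params"))
  fa <- acq$flip_angles
  if (length(fa) < 3L)
    stop("T1 mapping requires at least 3 flip angles")
  vfa_images <- as.array(vfa_images)
  dims <- dim(vfa_images)
  if (length(dims) != 4L || dims[4] != length(fa))
    stop("vfa_images must be a 4D array with one volume per flip angle")
  vol_dim <- dims[1:3]
  nv <- prod(vol_dim)
  sig <- matrix(vfa_images, nrow = nv, ncol = dims[4])
  smax <- apply(sig, 1L, max)
  if (is.null(signal_floor))
    signal_floor <- 0.02 * stats::quantile(sig, 0.99, names = FALSE)
  valid <- is.finite(smax) & smax > signal_floor &
    rowSums(!is.finite(sig)) == 0L
  r1 <- rep(NA_real_, nv); m0 <- rep(NA_real_, nv); rss <- rep(NA_real_, nv)
  if (any(valid)) {
    sv <- sig[valid, , drop = FALSE]
    init <- .vfa_linear_init(sv, fa, acq$tr, r1_bounds)
    fit <- .vfa_lm_fit(sv, fa, acq$tr, init, r1_bounds)
    ok <- is.finite(fit$r1) & is.finite(fit$m0) & fit$r1 > 0 & fit$m0 > 0
    r1[valid] <- ifelse(ok, fit$r1, NA_real_)
    m0[valid] <- ifelse(ok, fit$m0, NA_real_)
    rss[valid] <- ifelse(ok, fit$rss, NA_real_)
    valid[valid] <- ok
  }
  structure(list(r1pre = array(r1, vol_dim),
                 m0 = array(m0, vol_dim),
                 fit_rss = array(rss, vol_dim),
                 valid_mask = array(valid, vol_dim),
                 signal_floor = signal_floor),
            class = "relaxometry_maps")
}

#' @export
print.relaxometry_maps <- function(x, ...) {
  cat(sprintf("relaxometry_maps: %s grid, %d/%d valid voxels\n",
              paste(dim(x$r1pre), collapse = " x "),
              sum(x$valid_mask), length(x$valid_mask)))
  if (any(x$valid_mask))
    cat(sprintf("  R1pre median %.3f s^-1, M0 median %.1f\n",
                stats::median(x$r1pre[x$valid_mask]),
                stats::median(x$m0[x$valid_mask])))
  invisible(x)
}

#' Closed-form post-contrast R1 from a pre/post signal ratio
#'
#' Inverts the ratio of post- to pre-contrast SPGR signals acquired at the
#' same flip angle and TR for the post-contrast relaxation rate. Writing
#' \eqn{f(R_1) = (1-E)/(1-\cos\alpha\,E)} with \eqn{E = e^{-TR R_1}}, the
#' signal ratio gives \eqn{f_{post} = f(R_{1,pre}) \cdot I_{post}/I_{pre}},
#' from which \eqn{E_{post} = (1-f_{post})/(1-\cos\alpha\,f_{post})} and
#' \eqn{R_{1,post} = -\ln E_{post} / TR}. `M0` cancels in the ratio.
#'
#' Ratios that drive `E_post` outside (0, 1) are non-physical (e.g. noise
#' pushing the signal past the saturation ceiling); those voxels return
#' `NA` rather than raising an error.
#'
#' @param i_pre,i_post Pre- and post-contrast signal intensities (same
#'   units); vectorized.
#' @param r1pre Pre-contrast relaxation rate in s^-1.
#' @param alpha Flip angle in degrees.
#' @param tr Repetition time in seconds.
#' @return Post-contrast R1 in s^-1, `NA` where inversion is non-physical.
#' @export
invert_r1_post <- function(i_pre, i_post, r1pre, alpha, tr) {
  if (any(tr <= 0)) stop("tr must be positive")
  if (any(alpha <= 0 | alpha > 90)) stop("alpha must lie in (0, 90] degrees")
  ca <- cos(alpha * pi / 180)
  e_pre <- exp(-tr * r1pre)
  f_pre <- (1 - e_pre) / (1 - ca * e_pre)
  f_post <- f_pre * (i_post / i_pre)
  e_post <- (1 - f_post) / (1 - ca * f_post)
  bad <- !is.finite(e_post) | e_post <= 0 | e_post >= 1 |
    !is.finite(i_pre) | i_pre <= 0 | !is.finite(r1pre) | r1pre <= 0
  e_post[bad] <- NA_real_
  -log(e_post) / tr
}

#' Convert a dynamic signal series to contrast concentration
#'
#' For each frame, derives the post-contrast relaxation rate from the ratio
#' of the dynamic signal to the pre-contrast reference image at the dynamic
#' flip angle (see [invert_r1_post()]) and converts the relaxation
#' enhancement to concentration through the agent's relaxivity:
#' \deqn{c(t) = (R_{1,post}(t) - R_{1,pre}) / r_1.}
#'
#' Negative concentrations arising from noise are retained (not clamped) so
#' that downstream histogram and regression statistics remain unbiased.
#' Voxels invalid in `relax` propagate `NA` through all frames.
#'
#' @param dynamic_signal A [dce_series()] of post-contrast SPGR magnitudes.
#' @param pre_reference 3D array: pre-contrast image acquired at
#'   `acq$dynamic_flip_angle` (typically the matching VFA volume).
#' @param relax A `relaxometry_maps` object from [fit_r1_vfa()].
#' @param acq An [acq_params()] with `relaxivity_r1` set.
#' @return A [dce_series()] of concentrations in mM.
#' @export
concentration_series <- function(dynamic_signal, pre_reference, relax, acq) {
  stopifnot(inherits(dynamic_signal, "dce_series"),
            inherits(relax, "relaxometry_maps"),
            inherits(acq, "acq_params"))
  if (is.null(pre_reference))
    stop("pre_reference volume (pre-contrast image at the dynamic flip angle) is required")
  if (is.na(acq$relaxivity_r1))
    stop("acq$relaxivity_r1 must be set to convert R1 change to concentration")
  pre_reference <- as.array(pre_reference)
  dims <- dim(dynamic_signal$data)
  if (!all(dim(pre_reference) == dims[1:3]) ||
      !all(dim(relax$r1pre) == dims[1:3]))
    stop("pre_reference / relaxometry maps must match the dynamic volume shape")
  nt <- dims[4]
  r1pre <- relax$r1pre
  r1pre[!relax$valid_mask] <- NA_real_
  conc <- array(NA_real_, dims)
  for (k in seq_len(nt)) {
    r1post <- invert_r1_post(pre_reference, dynamic_signal$data[, , , k],
                             r1pre, acq$dynamic_flip_angle, acq$tr)
    conc[, , , k] <- (r1post - r1pre) / acq$relaxivity_r1
  }
  dce_series(conc, dynamic_signal$frame_times, unit = "mM")
}
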