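#' Physical geometry of the digital lung phantom
#'
#' Describes a coronal thoracic slice in physical units (mm): a torso
#' ellipse, two lung ellipses either side of the midline, and a circular
#' arterial blob between them (a stand-in for the descending aorta /
#' pulmonary trunk used for AIF detection). Because everything is defined in
#' mm, the same anatomy can be rasterised onto grids of different
#' resolution, which is what the registration-free subdivision scheme
#' exploits.
#'
#' @param fov field of view in mm (isotropic).
#' @param torso,lung_left,lung_right,artery lists with `center` (mm) and
#'   `semi` (semi-axes, mm; `artery` takes a scalar `radius`).
#' @return a list of class `lung_geometry`.
#' @export
lung_geometry <- function(fov = 500,
                          torso = list(center = c(0, 0), semi = c(200, 235)),
                          lung_left = list(center = c(-105, 10), semi = c(80, 150)),
                          lung_right = list(center = c(105, 10), semi = c(80, 150)),
                          artery = list(center = c(0, 40), radius = 22)) {
  structure(list(fov = fov, torso = torso, lung_left = lung_left,
                 lung_right = lung_right, artery = artery),
            class = "lung_geometry")
}

in_ellipse <- function(cx, cy, center, semi) {
  ((cx - center[1]) / semi[1])^2 + ((cy - center[2]) / semi[2])^2 <= 1
}

#' Rasterise phantom lungs, defect blobs and auxiliary masks
#'
#' Produces the label map (0 background, 1 left lung, 2 right lung), a
#' perfusion-defect mask drawn as a union of random elliptical blobs inside
#' the lungs, plus torso and artery masks. The blob union is grown until it
#' occupies the requested fraction of the lung mask and the final blob is
#' trimmed (outermost voxels first) so the achieved fraction matches the
#' request to within a voxel.
#'
#' @param grid an [image_grid()].
#' @param geometry a [lung_geometry()].
#' @param defect_fraction target fraction of lung voxels inside the defect
#'   mask, in `[0, 0.9]`.
#' @param seed RNG seed for blob placement.
#' @param blob_semi range (mm) from which blob semi-axes are drawn.
#' @return list with `grid`, `geometry`, `labels` (integer matrix),
#'   `defect`, `body`, `artery` (logical matrices), `defect_fraction`
#'   (achieved) and `seed`.
#' @export
make_lungs <- function(grid, geometry = lung_geometry(),
                       defect_fraction = 0.2, seed = 1L,
                       blob_semi = c(12, 35)) {
  stopifnot(inherits(grid, "image_grid"))
  if (defect_fraction < 0 || defect_fraction > 0.9)
    stop("defect_fraction must lie in [0, 0.9]")
  cc <- grid_coords(grid)
  body <- in_ellipse(cc$x, cc$y, geometry$torso$center, geometry$torso$semi)
  left <- in_ellipse(cc$x, cc$y, geometry$lung_left$center, geometry$lung_left$semi)
  right <- in_ellipse(cc$x, cc$y, geometry$lung_right$center, geometry$lung_right$semi)
  labels <- matrix(0L, grid$shape[1], grid$shape[2])
  labels[left] <- 1L
  labels[right] <- 2L
  artery <- in_ellipse(cc$x, cc$y, geometry$artery$center,
                       rep(geometry$artery$radius, 2)) & labels == 0L & body
  lung <- labels > 0L
  n_lung <- sum(lung)
  if (n_lung == 0L) stop("geometry rasterises to an empty lung mask")

  defect <- matrix(FALSE, grid$shape[1], grid$shape[2])
  target <- round(defect_fraction * n_lung)
  if (target > 0L) {
    lung_idx <- which(lung)
    with_seed(seed, {
      for (it in seq_len(1000L)) {
        if (sum(defect) >= target) break
        ctr_i <- sample(lung_idx, 1L)
        ctr <- c(cc$x[ctr_i], cc$y[ctr_i])
        semi <- stats::runif(2, blob_semi[1], blob_semi[2])
        blob <- in_ellipse(cc$x, cc$y, ctr, semi) & lung
        new <- blob & !defect
        overshoot <- sum(defect) + sum(new) - target
        if (overshoot > 0L) {
          # trim the outermost freshly added voxels so the count lands exactly
          idx <- which(new)
          d2 <- ((cc$x[idx] - ctr[1]) / semi[1])^2 +
                ((cc$y[idx] - ctr[2]) / semi[2])^2
          drop <- idx[order(d2, decreasing = TRUE)][seq_len(overshoot)]
          new[drop] <- FALSE
        }
        defect <- defect | new
      }
    })
    achieved <- sum(defect) / n_lung
    if (abs(achieved - defect_fraction) > 0.02)
      stop(sprintf("requested defect fraction %.3f unreachable; achieved %.3f",
                   defect_fraction, achieved))
  }
  list(grid = grid, geometry = geometry, labels = labels, defect = defect,
       body = body, artery = artery,
       defect_fraction = sum(defect) / n_lung, seed = seed)
}

#' Phantom ground truth
#'
#' Extends the output of [make_lungs()] with the per-voxel parameter fields
#' downstream recovery tests compare against: true pulmonary blood flow
#' (with a gravitational-style vertical gradient and an 80% reduction inside
#' defects by default), compartment volume fractions and relaxation
#' constants for the two-compartment (blood / extravascular tissue) model of
#' echo-time-dependent observed T1, plus the AIF parameters of the DCE
#' forward model.
#'
#' The compartment defaults place lung parenchyma at T1 = 1,100 ms with a
#' very short T2* (700 us) and blood at T1 = 1,400 ms with a long T2*
#' (50,000 us), so that observed T1 drifts from a parenchyma-weighted value
#' at the shortest echo time towards the blood T1 as TE grows. Defects
#' shorten tissue T1 by `defect_t1_drop` and reduce the blood fraction,
#' giving the shorter observed T1 in hypoperfused regions that the analysis
#' is designed to detect.
#'
#' @param masks output of [make_lungs()].
#' @param params named list overriding any of the defaults listed in the
#'   function definition (units: T1 in ms, T2* in us, PBF in 1/s, MTT in s,
#'   AIF scale in s).
#' @return list of class `phantom_truth`.
#' @export
phantom_truth <- function(masks, params = list()) {
  p <- utils::modifyList(list(
    t1_blood = 1400, t1_tissue = 1100, defect_t1_drop = 0.15,
    t2s_blood = 50000, t2s_tissue = 700,
    f_blood = 0.15, f_blood_defect = 0.05,
    pbf0 = 0.05, pbf_gradient = 0.5, defect_pbf_drop = 0.8,
    mtt = 6,
    aif_amp = 1, aif_onset_frame = 3, aif_shape = 3, aif_scale = 1.5,
    sigma = 0.05
  ), params)
  lung <- masks$labels > 0L
  cc <- grid_coords(masks$grid)
  ynorm <- matrix(0, nrow(lung), ncol(lung))
  if (any(lung)) {
    yr <- range(cc$y[lung])
    ynorm[lung] <- if (diff(yr) > 0) (cc$y[lung] - yr[1]) / diff(yr) else 0.5
  }
  pbf <- matrix(0, nrow(lung), ncol(lung))
  pbf[lung] <- p$pbf0 * (1 - p$pbf_gradient / 2 + p$pbf_gradient * ynorm[lung])
  pbf[masks$defect] <- pbf[masks$defect] * (1 - p$defect_pbf_drop)

  f_blood <- matrix(0, nrow(lung), ncol(lung))
  f_blood[lung] <- p$f_blood
  f_blood[masks$defect] <- p$f_blood_defect

  t1_tissue <- matrix(NA_real_, nrow(lung), ncol(lung))
  t1_tissue[lung] <- p$t1_tissue
  t1_tissue[masks$defect] <- p$t1_tissue * (1 - p$defect_t1_drop)

  structure(c(masks, list(params = p, pbf = pbf, f_blood = f_blood,
                          t1_tissue = t1_tissue)),
            class = "phantom_truth")
}

#' Convenience constructor: masks + truth in one call
#' @inheritParams make_lungs
#' @inheritParams phantom_truth
#' @export
make_phantom <- function(grid, geometry = lung_geometry(),
                         defect_fraction = 0.2, seed = 1L,
                         params = list(), blob_semi = c(12, 35)) {
  phantom_truth(make_lungs(grid, geometry, defect_fraction, seed, blob_semi),
                params)
}

#' Ground-truth observed T1 at a given echo time
#'
#' The observed T1 in a voxel containing both blood and extravascular
#' tissue protons is modelled as the signal-weighted mean of the compartment
#' T1s, with weights `w_i = f_i * exp(-TE / T2*_i)`: at very short TE both
#' compartments contribute according to their volume fractions, while at
#' longer TE the short-T2* parenchyma signal has decayed and observed T1
#' approaches the blood value. Voxels where both weights have decayed to
#' (numerically) zero are flagged invalid.
#'
#' @param truth a `phantom_truth`.
#' @param te echo time in microseconds (>= 0).
#' @return matrix of observed T1 (ms), `NA` outside the lungs and in
#'   invalid voxels; attribute `n_invalid` counts flagged lung voxels.
#' @export
observed_t1 <- function(truth, te) {
  stopifnot(inherits(truth, "phantom_truth"), te >= 0)
  p <- truth$params
  lung <- truth$labels > 0L
  wb <- truth$f_blood * exp(-te / p$t2s_blood)
  wt <- (1 - truth$f_blood) * exp(-te / p$t2s_tissue)
  wsum <- wb + wt
  t1 <- (wb * p$t1_blood + wt * truth$t1_tissue) / wsum
  t1[!lung] <- NA_real_
  invalid <- lung & (wsum < .Machine$double.eps * 100)
  t1[invalid] <- NA_real_
  attr(t1, "n_invalid") <- sum(invalid)
  t1
}

#' Total compartment signal weight at a given echo time
#' @keywords internal
signal_weight <- function(truth, te) {
  p <- truth$params
  truth$f_blood * exp(-te / p$t2s_blood) +
    (1 - truth$f_blood) * exp(-te / p$t2s_tissue)
}

#' Simulate inversion-recovery UTE series
#'
#' For every requested echo time, generates the magnitude inversion-recovery
#' signal `S(TI) = |A - B exp(-TI / T1_obs(TE))| + noise` per voxel, with
#' `A` proportional to the proton-density-weighted compartment signal at
#' that TE and `B = inv_eff * A` (2 for a perfect inversion). Background
#' voxels carry noise only. The exponent uses the apparent (Look-Locker)
#' T1 star equal to the ground-truth observed T1, so with the default
#' `inv_eff = 2` the corrected fit target is the ground truth itself.
#'
#' @param truth a `phantom_truth`.
#' @param te_list echo times in microseconds.
#' @param ti_list ascending inversion times in ms.
#' @param sigma Gaussian noise SD in signal units (signal scale is ~1 at the
#'   shortest TE, so `sigma = 0.05` is SNR 20).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param inv_eff inversion efficiency factor B/A.
#' @param slice_position,slice_thickness slice geometry (mm).
#' @return a list of `ti_series` objects, one per TE, each with fields
#'   `te`, `ti`, `stack` (x, y, TI array), `grid`, `slice_thickness`,
#'   `slice_position`.
#' @export
simulate_ir_series <- function(truth, te_list = c(70, 500, 1200, 1650, 2300),
                               ti_list = c(300, 600, 900, 1200),
                               sigma = truth$params$sigma, seed = 1L,
                               inv_eff = 2, slice_position = 0,
                               slice_thickness = 15) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (length(ti_list) == 0L || is.unsorted(ti_list, strictly = TRUE))
    stop("ti_list must be nonempty and strictly increasing")
  if (sigma < 0) stop("sigma must be >= 0")
  shape <- truth$grid$shape
  lung <- truth$labels > 0L
  with_seed(seed, {
    lapply(te_list, function(te) {
      t1 <- observed_t1(truth, te)
      a <- signal_weight(truth, te)
      stack <- array(0, c(shape, length(ti_list)))
      for (k in seq_along(ti_list)) {
        s <- matrix(0, shape[1], shape[2])
        ok <- lung & !is.na(t1)
        s[ok] <- abs(a[ok] - inv_eff * a[ok] * exp(-ti_list[k] / t1[ok]))
        if (sigma > 0) s <- s + matrix(stats::rnorm(prod(shape), 0, sigma),
                                       shape[1], shape[2])
        stack[, , k] <- s
      }
      structure(list(te = te, ti = ti_list, stack = stack, grid = truth$grid,
                     slice_thickness = slice_thickness,
                     slice_position = slice_position),
                class = "ti_series")
    })
  })
}

#' Gamma-variate arterial input function
#'
#' `aif(t) = amp * ((t - t0) / (shape * scale))^shape * exp(shape - (t - t0)/scale)`
#' for `t > t0`, zero before; normalised so the peak value equals `amp`.
#'
#' @param times time points in s.
#' @param onset bolus arrival time in s.
#' @param amp,shape,scale gamma-variate parameters (scale in s).
#' @return numeric vector of the same length as `times`.
#' @export
gamma_variate_aif <- function(times, onset, amp = 1, shape = 3, scale = 1.5) {
  tau <- pmax(times - onset, 0)
  ifelse(tau > 0, amp * (tau / (shape * scale))^shape * exp(shape - tau / scale), 0)
}

#' Simulate a dynamic contrast-enhanced series
#'
#' Tissue concentration follows the indicator-dilution forward model
#' `C_v(t) = dt * sum_{k<=t} AIF(k) * PBF_v * R(t-k)` with a
#' mono-exponential residue `R(tau) = exp(-tau / MTT)`; the arterial blob
#' carries the AIF itself (peak relative enhancement `aif_amp`, roughly an
#' order of magnitude above tissue enhancement); signal is
#' `S = S0 * (1 + C) + noise` with `S0 = 1` inside the body and noise-only
#' background. The 2D phantom slice is extruded into `nz` identical 5 mm
#' DCE partitions so slab projection onto the thicker UTE slice can be
#' exercised.
#'
#' @param truth a `phantom_truth`.
#' @param dt frame interval (s). @param nt number of frames (>= 3).
#' @param sigma noise SD relative to `S0`.
#' @param seed RNG seed.
#' @param nz number of DCE slices.
#' @param slice_thickness DCE slice thickness (mm).
#' @return a `dce_series`: `stack` (x, y, z, t), `dt`, `grid`,
#'   `slice_centers` (mm), `true_aif`, `times`, `s0`.
#' @export
simulate_dce <- function(truth, dt = 1.7, nt = 20,
                         sigma = truth$params$sigma, seed = 1L, nz = 8,
                         slice_thickness = 5) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (dt <= 0) stop("dt must be > 0")
  if (nt < 3) stop("need at least 3 frames")
  p <- truth$params
  times <- (seq_len(nt) - 1) * dt
  onset <- (p$aif_onset_frame - 1) * dt
  if (onset > times[nt]) stop("bolus onset lies beyond the last frame")
  aif <- gamma_variate_aif(times, onset, p$aif_amp, p$aif_shape, p$aif_scale)
  resid_true <- exp(-times / p$mtt)
  # unit-PBF tissue curve: discrete causal convolution of AIF with R
  unit_curve <- dt * vapply(seq_len(nt), function(t)
    sum(aif[seq_len(t)] * resid_true[t - seq_len(t) + 1L]), numeric(1))
  shape <- truth$grid$shape
  lung <- truth$labels > 0L
  stack <- array(0, c(shape, nz, nt))
  s0 <- 1
  base <- matrix(0, shape[1], shape[2])
  base[truth$body] <- s0
  with_seed(seed, {
    for (t in seq_len(nt)) {
      sl <- base
      sl[lung] <- s0 * (1 + truth$pbf[lung] * unit_curve[t])
      sl[truth$artery] <- s0 * (1 + aif[t])
      for (z in seq_len(nz)) {
        fr <- sl
        if (sigma > 0)
          fr <- fr + matrix(stats::rnorm(prod(shape), 0, sigma * s0),
                            shape[1], shape[2])
        stack[, , z, t] <- fr
      }
    }
  })
  structure(list(stack = stack, dt = dt, grid = truth$grid,
                 slice_thickness = slice_thickness,
                 slice_centers = (seq_len(nz) - (nz + 1) / 2) * slice_thickness,
                 true_aif = aif, times = times, s0 = s0, seed = seed),
            class = "dce_series")
}

#' Synthetic anatomical reference image
#'
#' A noiseless morphology-like image (bright body, dark lungs, brightest
#' artery) used to exercise intensity-based region growing.
#'
#' @param truth a `phantom_truth`.
#' @return numeric matrix.
#' @export
anatomy_image <- function(truth) {
  img <- matrix(0.05, truth$grid$shape[1], truth$grid$shape[2])
  img[truth$body] <- 1
  img[truth$labels > 0L] <- 0.25
  img[truth$artery] <- 1.2
  img
}
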