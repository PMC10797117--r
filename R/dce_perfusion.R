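#' @name dce_perfusion
#' @title Perfusion quantification from dynamic contrast-enhanced series
#' @description
#' Implements the indicator-dilution pipeline: signal-to-concentration
#' conversion by relative enhancement, automatic arterial input function
#' detection, voxel-wise truncated-SVD deconvolution to the residue
#' function R(t), pulmonary blood flow as max R(t), the lung-mean peak
#' frame t_max, Otsu two-threshold classification of R(t_max) into
#' perfusion defect vs normal, the defect percentage QDP, and projection of
#' thin DCE partitions onto the thicker 2D UTE slab.
NULL

#' Convert a DCE signal series to relative-enhancement concentration
#'
#' `C(t) = (S(t) - S0) / S0` with `S0` the mean of the first `n_baseline`
#' frames. Assumes signal linearity in concentration (reasonable for a
#' low-dose protocol); voxels whose baseline falls below `s0_floor` are
#' flagged and excluded (set to `NA`).
#'
#' @param series a `dce_series`.
#' @param n_baseline number of baseline frames (>= 1, < number of frames).
#' @param s0_floor minimum admissible baseline signal.
#' @return a `dce_conc`: list with `conc` (x, y, z, t array, `NA` where
#'   excluded), `dt`, `grid`, `slice_centers`, `n_excluded`.
#' @export
to_concentration <- function(series, n_baseline = 2L, s0_floor = 0.1) {
  stopifnot(inherits(series, "dce_series"))
  nt <- dim(series$stack)[4]
  if (n_baseline < 1L || n_baseline >= nt)
    stop("n_baseline must be >= 1 and leave at least one dynamic frame")
  dims <- dim(series$stack)
  s0 <- apply(series$stack[, , , seq_len(n_baseline), drop = FALSE], 1:3, mean)
  low <- s0 < s0_floor
  conc <- sweep(series$stack, 1:3, s0, "-")
  conc <- sweep(conc, 1:3, s0, "/")
  conc[array(low, dims)] <- NA_real_
  structure(list(conc = conc, dt = series$dt, grid = series$grid,
                 slice_centers = series$slice_centers,
                 n_excluded = sum(low)),
            class = "dce_conc")
}

#' Automatic arterial input function detection
#'
#' Candidate voxels are those within the body mask whose peak enhancement
#' lies in the top `q`-th percentile and whose time-to-peak is no later
#' than the median time-to-peak of all enhancing voxels (peak above
#' `floor`); the AIF is the mean curve of the top `n_aif` candidates by
#' peak enhancement. Negative samples after baseline subtraction are
#' clamped to zero and counted.
#'
#' @param conc a `dce_conc`.
#' @param body_mask logical matrix (applied to every slice).
#' @param q percentile (0-100) defining the peak-enhancement candidate set.
#' @param n_aif number of candidate voxels averaged.
#' @param floor minimum peak enhancement for a voxel to count as enhancing.
#' @return an `aif_curve`: list with `values`, `dt`, `n_voxels`,
#'   `peak_frame`, `n_candidates`, `n_clamped`.
#' @export
detect_aif <- function(conc, body_mask, q = 99, n_aif = 20L, floor = 0.2) {
  stopifnot(inherits(conc, "dce_conc"))
  dims <- dim(conc$conc)
  nt <- dims[4]
  vox <- matrix(conc$conc, ncol = nt)
  in_body <- rep(as.vector(body_mask), dims[3])
  ok <- in_body & apply(is.finite(vox), 1L, all)
  peaks <- rep(NA_real_, nrow(vox))
  ttp <- rep(NA_integer_, nrow(vox))
  peaks[ok] <- apply(vox[ok, , drop = FALSE], 1L, max)
  ttp[ok] <- apply(vox[ok, , drop = FALSE], 1L, which.max)
  enh <- ok & !is.na(peaks) & peaks > floor
  if (!any(enh)) stop("AIF detection failed: no voxel exceeds the enhancement floor")
  med_ttp <- stats::median(ttp[enh])
  thresh <- stats::quantile(peaks[enh], q / 100)
  cand <- which(enh & peaks >= thresh & ttp <= med_ttp)
  if (length(cand) == 0L) cand <- which(enh & ttp <= med_ttp)
  if (length(cand) < n_aif) {
    warning(sprintf("only %d AIF candidates available (requested %d)",
                    length(cand), n_aif))
    top <- cand
  } else {
    top <- cand[order(peaks[cand], decreasing = TRUE)[seq_len(n_aif)]]
  }
  curve <- colMeans(vox[top, , drop = FALSE])
  n_clamped <- sum(curve < 0)
  curve[curve < 0] <- 0
  structure(list(values = curve, dt = conc$dt, n_voxels = length(top),
                 index = top, peak_frame = which.max(curve),
                 n_candidates = length(cand), n_clamped = n_clamped),
            class = "aif_curve")
}

#' Voxel-wise deconvolution by truncated SVD
#'
#' Builds the lower-triangular Toeplitz convolution matrix from
#' `dt * AIF`, decomposes it once, and solves for every voxel's residue
#' function with singular values below `lambda * sigma_max` zeroed - the
#' standard regularised inversion of the indicator-dilution convolution
#' `C = dt * (AIF (*) PBF R)`.
#'
#' @param conc a `dce_conc`.
#' @param aif an `aif_curve` with the same frame count.
#' @param segmentation logical matrix: voxels to deconvolve (per slice).
#' @param lambda relative truncation threshold in (0, 1).
#' @return a `residual_maps`: list with `r` (matrix: lung voxel x frame),
#'   `index` (voxel linear indices into each slice), `nz`, `dims`,
#'   `lambda`, `dt`, `grid`, `slice_centers`.
#' @export
deconvolve <- function(conc, aif, segmentation, lambda = 0.15) {
  stopifnot(inherits(conc, "dce_conc"), inherits(aif, "aif_curve"))
  dims <- dim(conc$conc)
  nt <- dims[4]
  if (length(aif$values) != nt) stop("AIF and series frame counts differ")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  if (all(aif$values == 0)) stop("AIF is identically zero")
  a <- conc$dt * aif$values
  G <- matrix(0, nt, nt)
  for (i in seq_len(nt)) G[i, seq_len(i)] <- a[i - seq_len(i) + 1L]
  sv <- svd(G)
  keep <- sv$d >= lambda * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))

  seg_idx <- which(segmentation)
  nz <- dims[3]
  # rows: all segmented voxels across slices, in slice-major order
  rows <- as.vector(outer(seg_idx, (seq_len(nz) - 1L) * prod(dims[1:2]), "+"))
  cmat <- matrix(conc$conc, ncol = nt)[rows, , drop = FALSE]
  cmat[!is.finite(cmat)] <- 0
  r <- cmat %*% t(pinv)
  structure(list(r = r, index = seg_idx, nz = nz, dims = dims,
                 lambda = lambda, dt = conc$dt, grid = conc$grid,
                 slice_centers = conc$slice_centers),
            class = "residual_maps")
}

# reshape a per-voxel statistic of the residue rows back into (x, y, z)
residual_to_volume <- function(res, values) {
  vol <- array(NA_real_, res$dims[1:3])
  nseg <- length(res$index)
  for (z in seq_len(res$nz)) {
    sl <- matrix(NA_real_, res$dims[1], res$dims[2])
    sl[res$index] <- values[(z - 1L) * nseg + seq_len(nseg)]
    vol[, , z] <- sl
  }
  vol
}

#' Pulmonary blood flow map: per-voxel maximum of the residue function
#'
#' @param res a `residual_maps`.
#' @param scale calibration factor from raw 1/s units to mL/100 mL/min
#'   (default 1 keeps raw units; correlations are rank-based and therefore
#'   scale-free).
#' @return a `pbf_map`: list with `pbf` (x, y, z array, `NA` outside the
#'   segmentation), `n_clamped`, `grid`, `slice_centers`, `scale`.
#' @export
compute_pbf <- function(res, scale = 1) {
  stopifnot(inherits(res, "residual_maps"))
  if (nrow(res$r) == 0L) stop("empty residual maps")
  m <- apply(res$r, 1L, max)
  n_clamped <- sum(m < 0)
  m[m < 0] <- 0
  structure(list(pbf = residual_to_volume(res, m * scale),
                 n_clamped = n_clamped, grid = res$grid,
                 slice_centers = res$slice_centers, scale = scale),
            class = "pbf_map")
}

#' Frame of maximum lung-mean residue
#'
#' `t_max` is the frame at which the mean of R(t) over the whole segmented
#' lung peaks; ties resolve to the earliest frame.
#'
#' @param res a `residual_maps`.
#' @return integer frame index.
#' @export
find_tmax <- function(res) {
  stopifnot(inherits(res, "residual_maps"))
  if (nrow(res$r) == 0L) stop("empty segmentation")
  which.max(colMeans(res$r))
}

#' Otsu's method with two thresholds
#'
#' Histograms the values into `n_bins` equal-width bins over their range
#' and exhaustively searches all bin pairs for the split into three classes
#' maximising the between-class variance. Thresholds are returned as bin
#' edges, `theta_low < theta_high`.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @param n_bins number of histogram bins.
#' @return named numeric vector `c(low = , high = )`.
#' @export
otsu_two_thresholds <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3L) stop("degenerate histogram: fewer than 3 distinct values")
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  cw <- cumsum(p)               # cumulative weight up to bin i
  cm <- cumsum(p * mids)        # cumulative first moment
  tot <- cm[n_bins]
  best <- -Inf
  bi <- bj <- NA_integer_
  for (i in seq_len(n_bins - 2L)) {
    w1 <- cw[i]
    if (w1 == 0) next
    m1 <- cm[i]
    js <- (i + 1L):(n_bins - 1L)
    w2 <- cw[js] - w1
    w3 <- 1 - cw[js]
    m2 <- cm[js] - m1
    m3 <- tot - cm[js]
    valid <- w2 > 0 & w3 > 0
    sb <- rep(-Inf, length(js))
    sb[valid] <- m1^2 / w1 + m2[valid]^2 / w2[valid] + m3[valid]^2 / w3[valid]
    jbest <- which.max(sb)
    if (sb[jbest] > best) {
      best <- sb[jbest]
      bi <- i
      bj <- js[jbest]
    }
  }
  if (!is.finite(best)) stop("degenerate histogram: no admissible threshold pair")
  c(low = edges[bi + 1L], high = edges[bj + 1L])
}

#' Classify perfusion defects from R(t_max)
#'
#' Voxels whose residue at `t_max` falls below the lower Otsu threshold are
#' labelled perfusion defect, the remainder normal; QDP is the defect
#' percentage of the segmented lung.
#'
#' @param res a `residual_maps`.
#' @param t_max frame index from [find_tmax()].
#' @param thresholds output of [otsu_two_thresholds()] on the same
#'   R(t_max) distribution.
#' @return a `defect_classification`: list with `defect` (x, y, z logical
#'   array, `NA` outside segmentation), `qdp` (percent), `thresholds`,
#'   `t_max`, `n_lung`, `n_defect`, `grid`, `slice_centers`.
#' @export
classify_defects <- function(res, t_max, thresholds) {
  stopifnot(inherits(res, "residual_maps"))
  rt <- res$r[, t_max]
  lab <- rt < thresholds["low"]
  vol <- residual_to_volume(res, as.numeric(lab))
  structure(list(defect = vol > 0.5, qdp = 100 * sum(lab) / length(lab),
                 thresholds = thresholds, t_max = t_max,
                 n_lung = length(lab), n_defect = sum(lab),
                 grid = res$grid, slice_centers = res$slice_centers),
            class = "defect_classification")
}

#' Project thin 3D partitions onto a thick 2D slab
#'
#' Selects the `n_average` DCE slices whose centres lie nearest the UTE
#' slice centre and averages them: plain mean for continuous maps,
#' majority vote for label maps with ties resolved towards defect (the
#' conservative choice for defect detection).
#'
#' @param vol 3D array (x, y, z).
#' @param slice_centers z positions (mm) of the DCE slice centres.
#' @param ute_center z position (mm) of the UTE slice centre.
#' @param type `"continuous"` (mean) or `"label"` (majority vote, TRUE wins
#'   ties).
#' @param n_average number of slices to average.
#' @return list with `map` (2D) and `slices` (selected indices).
#' @export
project_to_slab <- function(vol, slice_centers, ute_center,
                            type = c("continuous", "label"),
                            n_average = 3L) {
  type <- match.arg(type)
  nz <- dim(vol)[3]
  if (nz < n_average) stop("need at least as many slices as n_average")
  if (ute_center < min(slice_centers) - diff(range(slice_centers)) ||
      ute_center > max(slice_centers) + diff(range(slice_centers)))
    stop("UTE slice centre lies outside the DCE volume")
  sel <- order(abs(slice_centers - ute_center))[seq_len(n_average)]
  sel <- sort(sel)
  sub <- vol[, , sel, drop = FALSE]
  map <- if (type == "continuous") {
    apply(sub, 1:2, mean)
  } else {
    votes <- apply(sub, 1:2, function(v) {
      if (all(is.na(v))) return(NA)
      sum(v, na.rm = TRUE) >= length(v[!is.na(v)]) / 2  # TRUE wins ties
    })
    votes
  }
  list(map = map, slices = sel)
}

#' Pulmonary blood volume and mean transit time maps
#'
#' `PBV = sum_t C(t) / sum_t AIF(t)`; `MTT = PBV / PBF` by the central
#' volume principle, invalid where PBF is zero.
#'
#' @param conc a `dce_conc`.
#' @param aif an `aif_curve`.
#' @param pbf a `pbf_map` (raw units, i.e. `scale = 1`).
#' @param segmentation logical matrix.
#' @return list with `pbv` and `mtt` (x, y, z arrays, `NA` invalid).
#' @export
compute_pbv_mtt <- function(conc, aif, pbf, segmentation) {
  stopifnot(inherits(conc, "dce_conc"), inherits(aif, "aif_curve"))
  sa <- sum(aif$values)
  if (sa == 0) stop("AIF integral is zero")
  dims <- dim(conc$conc)
  pbv <- apply(conc$conc, 1:3, sum) / sa
  mask3 <- array(rep(as.vector(segmentation), dims[3]), dims[1:3])
  pbv[!mask3] <- NA_real_
  mtt <- pbv / ifelse(pbf$pbf > 0, pbf$pbf, NA_real_)
  list(pbv = pbv, mtt = mtt)
}
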