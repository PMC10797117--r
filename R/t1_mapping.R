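#' @name t1_mapping
#' @title Per-voxel T1 fitting of inversion-recovery magnitude data
#' @description
#' The three-parameter magnitude model `S(TI) = |A - B exp(-TI / T1*)|` is
#' fitted per voxel and the apparent `T1*` converted to T1 via the
#' Look-Locker correction `T1 = T1* (B/A - 1)`, the standard correction for
#' continuous low-flip-angle sampling after inversion. Because only a
#' handful of TI samples are available, polarity is handled inside the
#' model (magnitude fit) rather than by polarity restoration of the data.
#'
#' The optimiser exploits the model structure: for a fixed `T1*` and a fixed
#' number `k` of initial samples lying before the zero crossing, the model
#' is linear in `(A, B)` after flipping the sign of those samples, so the
#' fit reduces to a 1D search over `T1*` (coarse log-spaced grid sweep over
#' all voxels at once, then a bounded 1D refinement per voxel) with an
#' exact inner linear solve. The reported residual is always that of the
#' magnitude model.
NULL

# Inner solve: given restored (sign-flipped) signal s and e = exp(-TI/T1*),
# the least-squares (A, B) of s = A - B*e, plus the magnitude-model RSS
# against the original magnitudes.
ir_inner_fit <- function(s_orig, flip, e, n) {
  s <- s_orig
  s[flip] <- -s[flip]
  me <- mean(e)
  ms <- mean(s)
  den <- sum((e - me)^2)
  if (den < .Machine$double.eps) return(NULL)
  b <- -sum((e - me) * (s - ms)) / den
  a <- ms + b * me
  rss <- sum((abs(a - b * e) - s_orig)^2)
  list(a = a, b = b, rss = rss)
}

ir_objective <- function(t1s, s_orig, k, tis, n) {
  e <- exp(-tis / t1s)
  f <- ir_inner_fit(s_orig, seq_len(n) <= k, e, n)
  if (is.null(f)) Inf else f$rss
}

#' Fit many inversion-recovery curves at once
#'
#' @param signal numeric matrix, one row per voxel, one column per TI.
#' @param tis ascending inversion times (ms), length >= 3.
#' @param t1_window plausibility window (ms) for the corrected T1; fits
#'   outside it are flagged invalid.
#' @param n_grid size of the coarse log-spaced `T1*` grid.
#' @return data.frame with columns `a`, `b`, `t1_star`, `t1`, `rmse`,
#'   `valid` (one row per voxel).
#' @export
fit_ir_curves <- function(signal, tis, t1_window = c(100, 3000),
                          n_grid = 48L) {
  signal <- as.matrix(signal)
  n <- length(tis)
  if (n < 3L) stop("need at least 3 TI samples")
  if (is.unsorted(tis, strictly = TRUE)) stop("TIs must be ascending")
  if (ncol(signal) != n) stop("signal columns must match length(tis)")
  nv <- nrow(signal)
  bad <- !is.finite(rowSums(signal))

  # search range a bit wider than the plausibility window so boundary truths
  # are not biased inward before the validity check
  lo <- t1_window[1] / 2
  hi <- t1_window[2] * 2
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))

  best_rss <- rep(Inf, nv)
  best_i <- rep(1L, nv)
  best_k <- rep(0L, nv)
  for (gi in seq_along(grid)) {
    e <- exp(-tis / grid[gi])
    me <- mean(e)
    den <- sum((e - me)^2)
    for (k in 0:n) {
      flip <- seq_len(n) <= k
      sgn <- ifelse(flip, -1, 1)
      s <- sweep(signal, 2L, sgn, "*")
      ms <- rowMeans(s)
      b <- -(s %*% (e - me)) / den
      a <- ms + b[, 1] * me
      pred <- abs(outer(a, rep(1, n)) - outer(b[, 1], e))
      rss <- rowSums((pred - signal)^2)
      upd <- which(rss < best_rss & !bad)
      if (length(upd)) {
        best_rss[upd] <- rss[upd]
        best_i[upd] <- gi
        best_k[upd] <- k
      }
    }
  }

  a_out <- b_out <- t1s_out <- rep(NA_real_, nv)
  rmse_out <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    if (bad[v]) next
    bracket <- grid[c(max(1L, best_i[v] - 1L), min(n_grid, best_i[v] + 1L))]
    opt <- stats::optimize(ir_objective, interval = bracket,
                           s_orig = signal[v, ], k = best_k[v],
                           tis = tis, n = n, tol = 0.05)
    t1s <- opt$minimum
    f <- ir_inner_fit(signal[v, ], seq_len(n) <= best_k[v],
                      exp(-tis / t1s), n)
    if (is.null(f)) next
    a_out[v] <- f$a
    b_out[v] <- f$b
    t1s_out[v] <- t1s
    rmse_out[v] <- sqrt(f$rss / n)
  }
  t1 <- t1s_out * (b_out / a_out - 1)
  valid <- !bad & is.finite(t1) & a_out > 0 & b_out > a_out &
    t1s_out > 0 & t1 >= t1_window[1] & t1 <= t1_window[2]
  data.frame(a = a_out, b = b_out, t1_star = t1s_out, t1 = t1,
             rmse = rmse_out, valid = valid)
}

#' Fit a single voxel's inversion-recovery curve
#'
#' @param signal magnitude signal over TI.
#' @param tis ascending inversion times (ms).
#' @inheritParams fit_ir_curves
#' @return list with `a`, `b`, `t1_star`, `t1`, `rmse`, `valid`.
#' @export
fit_ir_voxel <- function(signal, tis, t1_window = c(100, 3000)) {
  res <- fit_ir_curves(matrix(signal, nrow = 1L), tis, t1_window)
  as.list(res[1L, ])
}

#' Compute a T1 map over a segmentation
#'
#' Applies [fit_ir_curves()] to every segmented voxel of a TI series.
#' Background is untouched; invalid fits are excluded through the validity
#' mask.
#'
#' @param series a `ti_series` (one echo time).
#' @param segmentation logical matrix on the same grid.
#' @inheritParams fit_ir_curves
#' @return a `t1_map`: list with `t1` (matrix, ms, `NA` where unfitted or
#'   invalid), `valid` (logical matrix), `te`, `grid`, `n_fit`, `n_valid`.
#' @export
map_t1 <- function(series, segmentation, t1_window = c(100, 3000)) {
  stopifnot(inherits(series, "ti_series"))
  if (!all(dim(segmentation) == series$grid$shape))
    stop(sprintf("grid mismatch: series %s vs segmentation %s",
                 paste(series$grid$shape, collapse = "x"),
                 paste(dim(segmentation), collapse = "x")))
  idx <- which(segmentation)
  t1 <- matrix(NA_real_, series$grid$shape[1], series$grid$shape[2])
  valid <- matrix(FALSE, series$grid$shape[1], series$grid$shape[2])
  if (length(idx) == 0L) {
    warning("empty segmentation: returning an empty T1 map")
  } else {
    nti <- length(series$ti)
    sig <- matrix(series$stack, ncol = nti)[idx, , drop = FALSE]
    fit <- fit_ir_curves(sig, series$ti, t1_window)
    t1[idx] <- ifelse(fit$valid, fit$t1, NA_real_)
    valid[idx] <- fit$valid
  }
  structure(list(t1 = t1, valid = valid, te = series$te, grid = series$grid,
                 n_fit = length(idx), n_valid = sum(valid)),
            class = "t1_map")
}

#' Median T1 over a region
#'
#' @param map a `t1_map`.
#' @param region logical matrix; only valid voxels inside it contribute.
#' @return the median T1 (ms) with attributes `n_used` and `n_excluded`
#'   (region voxels dropped as invalid).
#' @export
median_t1 <- function(map, region) {
  stopifnot(inherits(map, "t1_map"))
  use <- region & map$valid
  if (!any(use)) stop("region does not intersect the validity mask")
  out <- stats::median(map$t1[use])
  attr(out, "n_used") <- sum(use)
  attr(out, "n_excluded") <- sum(region) - sum(use)
  out
}
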