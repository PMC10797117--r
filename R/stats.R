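#' @name lung_stats
#' @title Inter-patient and local correlation statistics
#' @description
#' Rank-based statistics relating observed T1(TE) to perfusion: Spearman
#' correlations across patients (median T1 vs median PBF and vs QDP), local
#' correlations per patient (voxel-wise over registered maps, or over the
#' 100 equal-volume areas per lung), Wilcoxon rank-sum comparison of T1 in
#' defect vs normally perfused voxels with the relative difference dT1, and
#' the second-order correlation between per-patient median T1 and the
#' per-patient local correlation coefficients.
NULL

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(rep(i, nrow(q)), q)
  }))
}

#' Spearman rank correlation with tie handling
#'
#' Pearson correlation of average-ranked values; non-finite pairs are
#' deleted pairwise. The p-value comes from the t approximation, or from
#' exact enumeration of all permutations for n <= 9.
#'
#' @param x,y numeric vectors of equal length.
#' @param kind optional tag describing which reported coefficient this is.
#' @param te optional echo time tag (microseconds).
#' @return a `correlation_result`: list with `rho`, `p`, `n`, `kind`, `te`,
#'   `significant` (p < 0.05), `degenerate` (TRUE when either variable is
#'   constant after deletion, in which case `rho` and `p` are `NA`).
#' @export
spearman <- function(x, y, kind = NA_character_, te = NA_real_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 valid pairs")
  rx <- rank(x); ry <- rank(y)
  degenerate <- stats::sd(rx) == 0 || stats::sd(ry) == 0
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    rho <- stats::cor(rx, ry)
    if (n <= 9L) {
      pm <- perm_matrix(n)
      ryp <- matrix(ry[pm], nrow(pm), n)
      sxy <- as.vector(ryp %*% rx)
      rho_perm <- (sxy / n - mean(rx) * mean(ry)) /
        (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
      p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      p <- min(p, 1)
    }
  }
  structure(list(rho = rho, p = p, n = n, kind = kind, te = te,
                 significant = isTRUE(p < 0.05), degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho%s = %.3f (n = %d, p = %.3g%s)\n",
              if (is.na(x$kind)) "" else paste0("_", x$kind),
              x$rho, x$n, x$p, if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when both groups have at most 8 observations
#' and no ties are present; tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b numeric vectors (both nonempty, combined length >= 3).
#' @return list with `statistic` (Mann-Whitney U of `a`), `rank_sum`
#'   (rank sum of `a`), `p`, `n_a`, `n_b`, `exact`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  if (length(a) + length(b) < 3L) stop("need at least 3 observations combined")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  u <- unname(wt$statistic)
  list(statistic = u, rank_sum = u + length(a) * (length(a) + 1) / 2,
       p = wt$p.value, n_a = length(a), n_b = length(b), exact = exact)
}

#' Inter-patient correlations of median T1(TE) with PBF and QDP
#'
#' @param t1_medians matrix, one row per subject, one column per TE
#'   (ms); `NA` for missing subject/TE combinations (dropped pairwise).
#' @param median_pbf per-subject median PBF.
#' @param qdp per-subject QDP (percent).
#' @param te_list echo times labelling the columns.
#' @return data.frame with columns `te`, `kind` ("IPBF" / "IQDP"), `rho`,
#'   `p`, `n`, `significant`, `absent` (TRUE when fewer than 3 complete
#'   pairs were available).
#' @export
interpatient_correlations <- function(t1_medians, median_pbf, qdp, te_list) {
  t1_medians <- as.matrix(t1_medians)
  stopifnot(ncol(t1_medians) == length(te_list),
            nrow(t1_medians) == length(median_pbf),
            nrow(t1_medians) == length(qdp))
  rows <- list()
  for (j in seq_along(te_list)) {
    for (kind in c("IPBF", "IQDP")) {
      yv <- if (kind == "IPBF") median_pbf else qdp
      res <- tryCatch(spearman(t1_medians[, j], yv, kind = kind,
                               te = te_list[j]),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        te = te_list[j], kind = kind,
        rho = if (is.null(res)) NA_real_ else res$rho,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) sum(is.finite(t1_medians[, j]) & is.finite(yv))
            else res$n,
        significant = if (is.null(res)) FALSE else isTRUE(res$significant),
        absent = is.null(res) || isTRUE(res$degenerate))
    }
  }
  do.call(rbind, rows)
}

#' Voxel-wise local correlation over registered maps
#'
#' @param t1map a `t1_map`.
#' @param pbf_2d 2D PBF map on the same grid (already slab-projected and
#'   warped).
#' @param mask logical matrix restricting the comparison.
#' @return a `correlation_result` tagged "regPBF".
#' @export
local_correlation_registered <- function(t1map, pbf_2d, mask) {
  stopifnot(inherits(t1map, "t1_map"))
  use <- mask & t1map$valid & is.finite(pbf_2d)
  if (sum(use) < 3L) stop("fewer than 3 valid voxel pairs")
  spearman(t1map$t1[use], pbf_2d[use], kind = "regPBF", te = t1map$te)
}

#' Local correlation over corresponding subdivided areas
#'
#' @param t1_areas per-area median T1 (both lungs concatenated).
#' @param x_areas per-area median PBF or per-area defect fraction.
#' @param kind "subPBF" or "subQDP".
#' @param te echo time tag.
#' @return a `correlation_result`; degenerate inputs (e.g. every area
#'   fully defect or fully normal) give `rho = NA` with
#'   `degenerate = TRUE`.
#' @export
local_correlation_subdivided <- function(t1_areas, x_areas,
                                         kind = "subPBF", te = NA_real_) {
  spearman(t1_areas, x_areas, kind = kind, te = te)
}

#' Compare T1 between perfusion-defect and normal voxels
#'
#' Classifies valid T1 voxels by the (warped / projected) defect map,
#' reports class medians, the relative difference
#' `dT1 = 100 * (median_normal - median_defect) / median_normal`, and a
#' Wilcoxon rank-sum p-value with a three-way direction flag.
#'
#' @param t1map a `t1_map`.
#' @param defect_2d logical matrix on the T1 grid (`NA` outside lung).
#' @param mask logical matrix of lung voxels to consider.
#' @return list with `median_normal`, `median_defect`, `delta_t1`
#'   (percent), `statistic`, `p`, `n_normal`, `n_defect`, `direction`
#'   ("defect_shorter", "defect_longer", "no_significant_difference") and
#'   `evaluable`.
#' @export
defect_normal_comparison <- function(t1map, defect_2d, mask) {
  stopifnot(inherits(t1map, "t1_map"))
  use <- mask & t1map$valid & !is.na(defect_2d)
  t1_def <- t1map$t1[use & defect_2d]
  t1_nor <- t1map$t1[use & !defect_2d]
  if (length(t1_def) == 0L || length(t1_nor) == 0L) {
    return(list(median_normal = if (length(t1_nor)) stats::median(t1_nor) else NA_real_,
                median_defect = if (length(t1_def)) stats::median(t1_def) else NA_real_,
                delta_t1 = NA_real_, statistic = NA_real_, p = NA_real_,
                n_normal = length(t1_nor), n_defect = length(t1_def),
                direction = "not_evaluable", evaluable = FALSE))
  }
  mn <- stats::median(t1_nor)
  md <- stats::median(t1_def)
  w <- wilcoxon_ranksum(t1_def, t1_nor)
  direction <- if (w$p >= 0.05) "no_significant_difference"
               else if (md < mn) "defect_shorter" else "defect_longer"
  list(median_normal = mn, median_defect = md,
       delta_t1 = if (mn > 0) 100 * (mn - md) / mn else NA_real_,
       statistic = w$statistic, p = w$p,
       n_normal = length(t1_nor), n_defect = length(t1_def),
       direction = direction, evaluable = TRUE)
}

#' Correlation of per-patient local correlations with median T1
#'
#' Across a cohort, correlates each patient's median T1 (at the shortest
#' TE) with that patient's local T1-PBF correlation coefficient - the
#' check that weak local correlations concentrate in patients with overall
#' short T1 (more uniformly damaged lungs).
#'
#' @param median_t1 per-patient median T1 at the reference TE.
#' @param local_rho per-patient local correlation coefficients.
#' @param kind "regcorr" or "subcorr".
#' @return a `correlation_result`.
#' @export
correlation_of_correlations <- function(median_t1, local_rho,
                                        kind = "regcorr") {
  spearman(median_t1, local_rho, kind = kind)
}
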