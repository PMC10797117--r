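make_conc <- function(arr, dt = 1.7, slice_centers = NULL) {
  structure(list(conc = arr, dt = dt, grid = test_grid(dim(arr)[1]),
                 slice_centers = slice_centers %||% seq_len(dim(arr)[3]),
                 n_excluded = 0L),
            class = "dce_conc")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_aif <- function(values, dt = 1.7) {
  structure(list(values = values, dt = dt, n_voxels = 1L, index = 1L,
                 peak_frame = which.max(values), n_candidates = 1L,
                 n_clamped = 0L),
            class = "aif_curve")
}

test_that("relative enhancement conversion is exact and flags low baselines", {
  stack <- array(100, c(2, 2, 1, 6))
  stack[1, 1, 1, 5] <- 150
  stack[2, 2, 1, ] <- 0.01   # below floor
  ser <- structure(list(stack = stack, dt = 1.7, grid = test_grid(2L),
                        slice_centers = 0, s0 = 100),
                   class = "dce_series")
  conc <- to_concentration(ser, n_baseline = 2L)
  expect_equal(conc$conc[1, 1, 1, 5], 0.5)
  expect_equal(conc$conc[1, 2, 1, ], rep(0, 6))
  expect_true(all(is.na(conc$conc[2, 2, 1, ])))
  expect_equal(conc$n_excluded, 1L)
  expect_error(to_concentration(ser, n_baseline = 6L), "n_baseline")

  # phantom round trip: noiseless concentration equals the simulated curves
  subj <- noiseless_subject()
  pc <- to_concentration(subj$dce)
  lung <- subj$truth$labels > 0L
  v <- which(lung)[3]
  nt <- dim(subj$dce$stack)[4]
  sim_curve <- vapply(seq_len(nt), function(t) subj$dce$stack[, , 2, t][v],
                      numeric(1))
  got <- vapply(seq_len(nt), function(t) pc$conc[, , 2, t][v], numeric(1))
  expect_equal(got, sim_curve / subj$dce$s0 - 1, tolerance = 1e-12)
})

test_that("AIF detection selects the arterial blob and fails on flat series", {
  subj <- noiseless_subject()
  conc <- to_concentration(subj$dce)
  aif <- detect_aif(conc, subj$truth$body)
  expect_gt(stats::cor(aif$values, subj$dce$true_aif), 0.99)
  art3 <- rep(as.vector(subj$truth$artery), dim(conc$conc)[3])
  expect_true(all(art3[aif$index]))

  flat <- make_conc(array(0, c(4, 4, 2, 5)))
  expect_error(detect_aif(flat, matrix(TRUE, 4, 4)), "failed")

  expect_warning(detect_aif(conc, subj$truth$body, n_aif = 10000L), "candidates")
})

test_that("deconvolution honours the convolution identity and recovers R", {
  nt <- 8; dt <- 1.7
  # impulse AIF scaled 1/dt makes the convolution matrix the identity
  aif <- make_aif(c(1 / dt, rep(0, nt - 1)), dt)
  tissue <- 0.06 * exp(-(0:(nt - 1)) * dt / 6)
  arr <- array(0, c(2, 2, 1, nt))
  arr[1, 1, 1, ] <- tissue
  conc <- make_conc(arr, dt)
  seg <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  res <- deconvolve(conc, aif, seg, lambda = 1e-6)
  expect_equal(res$r[1, ], tissue, tolerance = 1e-9)
  expect_equal(max(res$r[1, ]), 0.06, tolerance = 1e-9)
  expect_equal(res$r[2, ], rep(0, nt))   # zero tissue curve -> R == 0

  expect_error(deconvolve(conc, make_aif(rep(0, nt), dt), seg), "zero")
  expect_error(deconvolve(conc, aif, seg, lambda = 2), "lambda")

  # forward-convolution consistency on the phantom at lambda -> 0
  subj <- noiseless_subject()
  pc <- to_concentration(subj$dce)
  paif <- detect_aif(pc, subj$truth$body)
  lung <- subj$truth$labels > 0L
  res0 <- deconvolve(pc, paif, lung, lambda = 1e-8)
  a <- pc$dt * paif$values
  G <- matrix(0, 20, 20)
  for (i in 1:20) G[i, seq_len(i)] <- a[i - seq_len(i) + 1L]
  rows <- as.vector(outer(which(lung),
                          (seq_len(res0$nz) - 1L) * prod(dim(pc$conc)[1:2]), "+"))
  cmat <- matrix(pc$conc, ncol = 20)[rows, ]
  fwd <- res0$r %*% t(G)
  expect_lt(max(abs(fwd - cmat)) / max(abs(cmat)), 1e-6)

  # and PBF recovery within 15% at the default truncation
  res <- deconvolve(pc, paif, lung, lambda = 0.15)
  pbf <- compute_pbf(res)
  truth3 <- array(rep(subj$truth$pbf, res$nz), dim(pc$conc)[1:3])
  lung3 <- array(rep(lung, res$nz), dim(pc$conc)[1:3])
  rel <- abs(pbf$pbf[lung3] - truth3[lung3]) / truth3[lung3]
  expect_gte(mean(rel <= 0.15), 0.9)
})

test_that("PBF is the per-voxel residue maximum with negative clamping", {
  res <- structure(list(r = rbind(c(0.1, 0.5, 0.3), c(-0.2, -0.1, -0.4)),
                        index = c(1L, 2L), nz = 1L, dims = c(2L, 1L, 1L, 3L),
                        lambda = 0.15, dt = 1.7, grid = test_grid(2L),
                        slice_centers = 0),
                   class = "residual_maps")
  pbf <- compute_pbf(res)
  expect_equal(pbf$pbf[1, 1, 1], 0.5)
  expect_equal(pbf$pbf[2, 1, 1], 0)
  expect_equal(pbf$n_clamped, 1L)
})

test_that("t_max is the arg-max of the lung-mean residue with earliest-frame ties", {
  res <- structure(list(r = rbind(c(0.1, 0.5, 0.3), c(0.3, 0.1, 0.1)),
                        index = 1:2, nz = 1L, dims = c(2L, 1L, 1L, 3L),
                        lambda = 0.15, dt = 1.7, grid = test_grid(2L),
                        slice_centers = 0), class = "residual_maps")
  expect_equal(find_tmax(res), 2L)
  res$r <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(find_tmax(res), 1L)
  set.seed(2)
  res$r <- matrix(rnorm(2 * 12), 2, 12)
  means <- colMeans(res$r)
  expect_equal(find_tmax(res), which(means == max(means))[1])
})

test_that("two-threshold Otsu separates modes and matches the brute-force oracle", {
  tri <- c(rep(0, 50), rep(10, 30), rep(20, 20)) +
    rep(c(-0.1, 0.1), length.out = 100)
  thr <- otsu_two_thresholds(tri)
  expect_gt(thr[["low"]], 0.1)
  expect_lt(thr[["low"]], 9.9)
  expect_gt(thr[["high"]], 10.1)
  expect_lt(thr[["high"]], 19.9)
  cls <- cut(tri, c(-Inf, thr, Inf))
  expect_equal(as.integer(table(cls)), c(50L, 30L, 20L))

  set.seed(9)
  for (i in 1:5) {
    v <- c(rnorm(200, 0, 1), rnorm(150, 4, 1.2), rnorm(150, 9, 1.5))
    expect_equal(otsu_two_thresholds(v, n_bins = 48L), otsu_brute(v, 48L))
  }
  expect_error(otsu_two_thresholds(rep(1, 10)), "degenerate")
  expect_error(otsu_two_thresholds(c(1, 1, 2, 2)), "degenerate")
})

test_that("defect classification counts below-threshold voxels into QDP", {
  r <- matrix(c(rep(0.1, 25), rep(1, 75)), ncol = 1)
  res <- structure(list(r = r, index = 1:100, nz = 1L,
                        dims = c(10L, 10L, 1L, 1L), lambda = 0.15, dt = 1.7,
                        grid = test_grid(10L), slice_centers = 0),
                   class = "residual_maps")
  cls <- classify_defects(res, 1L, c(low = 0.5, high = 0.9))
  expect_equal(cls$qdp, 25)
  cls0 <- classify_defects(res, 1L, c(low = 0.05, high = 0.9))
  expect_equal(cls0$qdp, 0)
})

test_that("scaling all tissue curves scales PBF and leaves the classification unchanged", {
  subj <- noiseless_subject()
  pc <- to_concentration(subj$dce)
  aif <- detect_aif(pc, subj$truth$body)
  lung <- subj$truth$labels > 0L
  res <- deconvolve(pc, aif, lung, lambda = 0.15)
  pc2 <- pc
  pc2$conc <- pc$conc * 3.7
  res2 <- deconvolve(pc2, aif, lung, lambda = 0.15)
  expect_equal(res2$r, 3.7 * res$r, tolerance = 1e-9)
  tm <- find_tmax(res)
  expect_equal(find_tmax(res2), tm)
  thr <- otsu_two_thresholds(res$r[, tm])
  thr2 <- otsu_two_thresholds(res2$r[, tm])
  expect_equal(unname(thr2), unname(3.7 * thr), tolerance = 1e-9)
  expect_equal(classify_defects(res2, tm, thr2)$qdp,
               classify_defects(res, tm, thr)$qdp)
})

test_that("slab projection averages the nearest slices and majority-votes labels", {
  vol <- array(rep(c(1, 2, 3, 9, 9), each = 4), c(2, 2, 5))
  centers <- c(-10, -5, 0, 5, 10)
  pr <- project_to_slab(vol, centers, ute_center = -5)
  expect_equal(pr$slices, 1:3)
  expect_equal(pr$map, matrix(2, 2, 2))
  # identical slices project to themselves
  same <- array(7, c(2, 2, 3))
  expect_equal(project_to_slab(same, 1:3, 2)$map, matrix(7, 2, 2))
  # label maps: defect (TRUE) wins 2-of-3 and ties
  lab <- array(c(TRUE, FALSE), c(2, 2, 3)) + 0
  lab[1, 1, ] <- c(1, 1, 0); lab[2, 1, ] <- c(0, 0, 1)
  pl <- project_to_slab(lab, 1:3, 2, type = "label")
  expect_true(pl$map[1, 1])
  expect_false(pl$map[2, 1])
  # selection matches a brute-force nearest-centre scan
  set.seed(4)
  centers <- sort(runif(9, -20, 20))
  for (target in c(-15, 0, 13)) {
    pr <- project_to_slab(array(0, c(1, 1, 9)), centers, target)
    expect_setequal(pr$slices, order(abs(centers - target))[1:3])
  }
  expect_error(project_to_slab(vol, c(-10, -5, 0, 5, 10), 1e5), "outside")
})

test_that("PBV and MTT follow the central volume principle", {
  subj <- noiseless_subject()
  pc <- to_concentration(subj$dce)
  aif <- detect_aif(pc, subj$truth$body)
  lung <- subj$truth$labels > 0L
  res <- deconvolve(pc, aif, lung, lambda = 0.15)
  pbf <- compute_pbf(res)
  out <- compute_pbv_mtt(pc, aif, pbf, lung)
  lung3 <- array(rep(lung, res$nz), dim(pc$conc)[1:3])
  relm <- abs(out$mtt[lung3] - subj$truth$params$mtt) / subj$truth$params$mtt
  expect_gte(mean(relm <= 0.2, na.rm = TRUE), 0.8)
  # a voxel carrying the AIF itself has PBV = 1
  art <- subj$truth$artery
  pbv_art <- compute_pbv_mtt(pc, aif, pbf, art)$pbv
  art3 <- array(rep(art, res$nz), dim(pc$conc)[1:3])
  expect_equal(stats::median(pbv_art[art3]), 1, tolerance = 0.02)
  # PBF = 0 -> MTT invalid
  pbf0 <- pbf
  pbf0$pbf[] <- 0
  expect_true(all(is.na(compute_pbv_mtt(pc, aif, pbf0, lung)$mtt)))
})
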