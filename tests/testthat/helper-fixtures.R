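# Shared fixtures, built once per test run.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

test_grid <- function(n = 64L) image_grid(c(n, n), 500 / n)

test_truth <- function() fixture("truth", function()
  make_phantom(test_grid(), defect_fraction = 0.2, seed = 1L))

noiseless_config <- function() {
  cfg <- default_config()
  cfg$snr <- Inf
  cfg
}

noiseless_subject <- function() fixture("noiseless_subject", function()
  make_subject(noiseless_config(), seed = 5L, defect_fraction = 0.2))

# Independent average-rank oracle (counting definition, no call to rank())
avg_rank_oracle <- function(v)
  vapply(seq_along(v), function(i) sum(v < v[i]) + (1 + sum(v == v[i])) / 2,
         numeric(1))

# Exhaustive brute-force two-threshold Otsu: direct between-class variance
# with explicit class means, naive O(bins^3)
otsu_brute <- function(values, n_bins = 48L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; bi <- bj <- NA_integer_
  for (i in 1:(n_bins - 2L)) for (j in (i + 1L):(n_bins - 1L)) {
    w1 <- sum(p[1:i]); w2 <- sum(p[(i + 1):j]); w3 <- sum(p[(j + 1):n_bins])
    if (w1 == 0 || w2 == 0 || w3 == 0) next
    m1 <- sum(p[1:i] * mids[1:i]) / w1
    m2 <- sum(p[(i + 1):j] * mids[(i + 1):j]) / w2
    m3 <- sum(p[(j + 1):n_bins] * mids[(j + 1):n_bins]) / w3
    mu <- w1 * m1 + w2 * m2 + w3 * m3
    sb <- w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2
    if (sb > best) { best <- sb; bi <- i; bj <- j }
  }
  c(low = edges[bi + 1L], high = edges[bj + 1L])
}

# Full-enumeration two-sided rank-sum p-value (tie-free inputs)
wilcox_enum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  sets <- utils::combn(n + m, n)
  ws <- apply(sets, 2L, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
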