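# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately simple, brute-force and separate from the
# package's own code paths.

# Gaussian-mixture trace on a known baseline; areas are analytic.
# peaks: tibble/list with mu, sigma, area
make_gaussian_trace <- function(peaks, x = seq(0, 60, by = 0.2),
                                baseline = 0, slope = 0, noise_sd = 0,
                                seed = NULL, ...) {
  y <- baseline + slope * x
  for (i in seq_along(peaks$mu)) {
    y <- y + peaks$area[i] *
      dnorm(x, peaks$mu[i], peaks$sigma[i])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(x), 0, noise_sd)
  }
  profile_trace(x, pmax(y, 0), ...)
}

# analytic mass of Gaussian peaks inside [lo, hi]
gaussian_region_area <- function(peaks, lo, hi) {
  sum(peaks$area * (pnorm(hi, peaks$mu, peaks$sigma) -
                      pnorm(lo, peaks$mu, peaks$sigma)))
}

# Exhaustive grid-search least squares for the pinned decay/rise model
# value(t) = E + P (1 - E), E = exp(-k t). Brute force, no profiling.
grid_search_pinned <- function(t, y, k_grid, p_grid) {
  best <- c(k = NA_real_, plateau = NA_real_, sse = Inf)
  np <- length(p_grid)
  for (k in k_grid) {
    e <- exp(-k * t)
    pred <- outer(e, rep(1, np)) + outer(1 - e, p_grid)
    sse <- colSums((y - pred)^2)
    j <- which.min(sse)
    if (sse[j] < best["sse"]) best <- c(k = k, plateau = p_grid[j], sse = sse[j])
  }
  best
}

# Brute-force Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# tiny runoff series from exact model points
model_series <- function(k, C, t = c(0, 1, 5, 10), kind = "polysome_decline") {
  if (kind == "monosome_rise") {
    runoff_series(t, C - (C - 1) * exp(-k * t), kind = kind)
  } else {
    runoff_series(t, C + (1 - C) * exp(-k * t), kind = kind)
  }
}

write_tmp_trace_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
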