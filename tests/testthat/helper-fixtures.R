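# shared fixture builders; all randomness is seeded at the call site

# small segment table with log-ratios chosen directly (counts back-computed
# from a fixed normal count so log(tumor/normal) = y exactly up to rounding)
seg_fixture <- function(gc, y, normal = 1e6, chrom = "chr1") {
  n <- length(gc)
  start <- seq(0, by = 2e6, length.out = n)
  segment_table(chrom = rep(chrom, n), start = start, end = start + 1e6,
                gc = gc, tumor_reads = normal * exp(y),
                normal_reads = rep(normal, n))
}

# two parallel stripes with slope `m`, gap `gap`, iid normal scatter
two_stripe_fixture <- function(n = 200, m = -0.7, gap = log(2),
                               frac2 = 0.5, sd = 0.02, seed = 1) {
  set.seed(seed)
  gc <- runif(n, 0.25, 0.65)
  hi <- runif(n) < frac2
  y <- m * gc + 0.3 + ifelse(hi, gap, 0) + rnorm(n, 0, sd)
  list(table = seg_fixture(gc, y), stripe = hi + 1L, gc = gc, y = y)
}

# brute-force Gaussian KDE on the same grid convention as density_peaks()
kde_brute <- function(values, h, grid_size = 1024) {
  xs <- seq(min(values) - 3 * h, max(values) + 3 * h,
            length.out = grid_size)
  ys <- vapply(xs, function(x0) mean(stats::dnorm(x0, values, h)), 0)
  list(x = xs, y = ys)
}

# brute-force peak finding on a gridded curve
peaks_brute <- function(xs, ys) {
  mid <- 2:(length(ys) - 1)
  idx <- mid[ys[mid] > ys[mid - 1] & ys[mid] > ys[mid + 1]]
  ord <- order(-ys[idx])
  data.frame(location = xs[idx][ord], height = ys[idx][ord])
}

# quick MCMC settings for pipeline-level tests where full chain length is
# not the property under test
fast_mcmc <- function(seed = 1, ...) {
  mcmc_config(n_iter = 800, burn_in = 200, seed = seed, ...)
}
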