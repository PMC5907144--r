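test_that("anchor line passes through the low/high GC median points", {
  # medians: low (0.35, 1.0), high (0.55, 0.86) -> slope -0.7, icpt 1.245
  tab <- seg_fixture(gc = c(0.34, 0.36, 0.54, 0.56),
                     y = c(0.9, 1.1, 0.82, 0.90))
  an <- anchor_line(tab, low_q = 0.4, high_q = 0.6)
  expect_equal(an$a, -0.7, tolerance = 1e-9)
  expect_equal(an$c, 1.245, tolerance = 1e-9)
  # duplicating every segment leaves the medians (hence the line) unchanged
  tab2 <- seg_fixture(gc = rep(c(0.34, 0.36, 0.54, 0.56), 2),
                      y = rep(c(0.9, 1.1, 0.82, 0.90), 2))
  an2 <- anchor_line(tab2, low_q = 0.4, high_q = 0.6)
  expect_equal(an2$a, an$a, tolerance = 1e-9)
  expect_equal(an2$c, an$c, tolerance = 1e-9)
})

test_that("anchor line on flat data is horizontal at that level", {
  tab <- seg_fixture(gc = seq(0.3, 0.6, length.out = 20),
                     y = rep(0.4, 20))
  an <- anchor_line(tab)
  expect_equal(an$a, 0, tolerance = 1e-9)
  expect_equal(an$c, 0.4, tolerance = 1e-9)
})

test_that("anchor line demands populated GC areas", {
  tab <- seg_fixture(gc = c(0.3, 0.5, 0.51), y = c(1, 1, 1))
  expect_error(anchor_line(tab, 0.05, 0.95), "anchor area")
})

test_that("the correction formula removes the trend and recentres", {
  y <- c(1, 2, 3); x <- c(0.3, 0.4, 0.5)
  expect_equal(correct_logratio(y, x, 10, 0), c(0, 0, 0))
  expect_equal(correct_logratio(y, x, 0, median(y)), y)
  expect_equal(correct_logratio(y, x, 0, 0), y + median(y))
  expect_error(correct_logratio(numeric(0), numeric(0), 0, 0), "empty")
})

test_that("density peaks match a brute-force KDE evaluation", {
  set.seed(21)
  vals <- c(rnorm(120, 0, 0.05), rnorm(120, 2, 0.05))
  h <- stats::bw.nrd0(vals)
  got <- density_peaks(vals, grid_size = 512)
  want <- peaks_brute(kde_brute(vals, h, 4096)$x, kde_brute(vals, h, 4096)$y)
  expect_equal(nrow(got), 2)
  expect_equal(sort(got$location), sort(want$location[1:2]),
               tolerance = 0.02)
  expect_equal(sort(got$height), sort(want$height[1:2]), tolerance = 0.02)
  # equal-size clusters: near-equal heights
  expect_lt(abs(got$height[1] - got$height[2]) / got$height[1], 0.15)
  # single tight cluster: one dominant peak
  expect_equal(nrow(density_peaks(rnorm(100, 1, 0.05))), 1)
})

test_that("peak heights are invariant under translation", {
  set.seed(22)
  vals <- c(rnorm(80, 0, 0.04), rnorm(40, 1, 0.04))
  a <- density_peaks(vals)
  b <- density_peaks(vals + 5)
  expect_equal(a$height, b$height, tolerance = 1e-9)
  expect_equal(b$location - a$location, rep(5, nrow(a)), tolerance = 1e-9)
})

test_that("identical values give one degenerate peak", {
  pk <- density_peaks(rep(1.5, 10))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$location, 1.5)
})

test_that("stripe likelihood peaks at the true slope and ignores c", {
  fx <- two_stripe_fixture(n = 300, m = -0.7, seed = 31)
  y <- log_ratio(fx$table); x <- fx$table$gc
  cfg <- mcmc_config()
  ll_true <- stripe_log_likelihood(y, x, -0.7, 0, cfg)
  expect_gt(ll_true, stripe_log_likelihood(y, x, -1.7, 0, cfg))
  expect_gt(ll_true, stripe_log_likelihood(y, x, 0.3, 0, cfg))
  # intercept only translates Y'
  expect_equal(ll_true, stripe_log_likelihood(y, x, -0.7, 12.3, cfg),
               tolerance = 1e-9)
})

test_that("the top-K cap is inert when the density has a single peak", {
  set.seed(32)
  tab <- seg_fixture(gc = runif(200, 0.3, 0.6), y = rnorm(200, 1, 0.03))
  y <- log_ratio(tab); x <- tab$gc
  # a bandwidth wide enough that the gridded density is truly unimodal
  expect_equal(nrow(density_peaks(y, bandwidth = 0.05)), 1)
  ll1 <- stripe_log_likelihood(y, x, 0, 0,
                               mcmc_config(tau = 1, max_cn = 1,
                                           kde_bandwidth = 0.05))
  ll2 <- stripe_log_likelihood(y, x, 0, 0,
                               mcmc_config(tau = 3, max_cn = 8,
                                           kde_bandwidth = 0.05))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("the sampler is deterministic under a fixed seed", {
  fx <- two_stripe_fixture(n = 150, seed = 41)
  f1 <- stripe_fit(fx$table, fast_mcmc(seed = 7))
  f2 <- stripe_fit(fx$table, fast_mcmc(seed = 7))
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$map_slope, f2$map_slope)
  expect_identical(f1$y_corrected, f2$y_corrected)
})

test_that("all sampled slopes respect the uniform prior bounds", {
  fx <- two_stripe_fixture(n = 150, seed = 42)
  cfg <- fast_mcmc(seed = 5, delta = 0.5)
  fit <- stripe_fit(fx$table, cfg)
  expect_true(all(fit$chain$slope >= fit$anchor_slope - 0.5 - 1e-12))
  expect_true(all(fit$chain$slope <= fit$anchor_slope + 0.5 + 1e-12))
  expect_gte(fit$map_slope, fit$anchor_slope - 0.5)
  expect_lte(fit$map_slope, fit$anchor_slope + 0.5)
})

test_that("a prior window excluding the truth pins the MAP at the boundary", {
  # seed chosen so the anchor line tilts away from the generating slope:
  # with delta = 0.25 the prior window then excludes the truth entirely
  fx <- two_stripe_fixture(n = 300, m = -0.7, frac2 = 0.5, seed = 53)
  fit <- stripe_fit(fx$table, fast_mcmc(seed = 6, delta = 0.25))
  lo <- fit$anchor_slope - 0.25
  expect_gt(lo, -0.7)   # fixture property: truth below the window
  expect_lt(abs(fit$map_slope - lo), 0.05)
})

test_that("constant log-ratios short-circuit with slope zero", {
  tab <- seg_fixture(gc = c(0.3, 0.4, 0.5, 0.6), y = rep(0.2, 4))
  expect_warning(fit <- stripe_fit(tab), "constant")
  expect_equal(fit$map_slope, 0)
  expect_equal(fit$y_corrected, rep(0.2, 4))
})

test_that("MAP likelihood matches an exhaustive grid search", {
  for (seed in c(51, 52, 53)) {
    fx <- two_stripe_fixture(n = 200, seed = seed)
    cfg <- fast_mcmc(seed = seed)
    fit <- stripe_fit(fx$table, cfg)
    gr <- grid_search_slope(fx$table, cfg, n_grid = 120)
    expect_lte(abs(fit$map_log_posterior - gr$loglik_best),
               0.01 * abs(gr$loglik_best) + 1e-9)
  }
})

test_that("the grid oracle is invariant to segment order", {
  fx <- two_stripe_fixture(n = 120, seed = 61)
  cfg <- fast_mcmc(seed = 1)
  g1 <- grid_search_slope(fx$table, cfg, n_grid = 60)
  set.seed(2)
  perm <- fx$table[sample(nrow(fx$table)), ]
  g2 <- grid_search_slope(perm, cfg, n_grid = 60)
  expect_equal(g1$m_best, g2$m_best, tolerance = 1e-12)
  expect_equal(g1$loglik_best, g2$loglik_best, tolerance = 1e-9)
  # degenerate single-point grid returns the anchor slope
  g3 <- grid_search_slope(fx$table, cfg, n_grid = 1)
  expect_equal(g3$m_best, anchor_line(fx$table)$a, tolerance = 1e-12)
})

test_that("regression correction agrees with its definitional form", {
  fx <- two_stripe_fixture(n = 100, frac2 = 0, sd = 0.05, seed = 71)
  y <- log_ratio(fx$table); x <- fx$table$gc
  fit <- lm(y ~ x)
  manual <- correct_logratio(y, x, coef(fit)[2], coef(fit)[1])
  expect_equal(regression_correct(fx$table, "linear"), manual,
               tolerance = 1e-9)
  # perfectly collinear single stripe: residuals all equal median(y)
  flat <- seg_fixture(gc = c(0.3, 0.4, 0.5, 0.6),
                      y = -0.7 * c(0.3, 0.4, 0.5, 0.6) + 1)
  yc <- regression_correct(flat, "linear")
  expect_equal(yc, rep(median(log_ratio(flat)), 4), tolerance = 1e-9)
  # loess mode runs and returns centred values
  expect_length(regression_correct(fx$table, "loess"), 100)
  expect_error(regression_correct(flat[1:2, ], "linear"), "at least 3")
})

test_that("stripe labels follow the corrected density peaks", {
  fx <- two_stripe_fixture(n = 200, gap = log(2), seed = 81)
  fit <- stripe_fit(fx$table, fast_mcmc(seed = 81))
  # recovered labels must match the generating stripe up to relabeling
  tab_match <- table(fx$stripe, fit$stripe)
  expect_gt(sum(apply(tab_match, 1, max)) / 200, 0.95)
})
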