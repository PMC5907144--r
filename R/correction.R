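#' MCMC configuration for the stripe-slope sampler
#'
#' @param delta Half-range \eqn{\delta} of the uniform slope prior around the
#'   anchor slope (default 1.0).
#' @param n_iter Total Metropolis iterations (default 5000).
#' @param burn_in Iterations discarded from the reported chain (default
#'   1000); the MAP search still covers every evaluated slope.
#' @param proposal_sd Random-walk step scale; defaults to `delta / 10`.
#' @param seed RNG seed for the sampler.
#' @param tau Assumed number of subclonal populations (default 2).
#' @param max_cn Maximum copy number considered (default 6).
#' @param kde_bandwidth Either `"silverman"` or a fixed numeric bandwidth for
#'   the Gaussian kernel density.
#' @param grid_size Number of evenly spaced density evaluation points
#'   (default 1024).
#' @param low_q,high_q GC quantiles bounding the low- and high-GC anchor
#'   areas (defaults 0.10 and 0.90).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(delta = 1.0, n_iter = 5000, burn_in = 1000,
                        proposal_sd = delta / 10, seed = 1L,
                        tau = 2, max_cn = 6, kde_bandwidth = "silverman",
                        grid_size = 1024, low_q = 0.10, high_q = 0.90) {
  stopifnot(delta > 0, burn_in < n_iter, tau >= 1, max_cn >= 1,
            low_q > 0, high_q < 1, low_q < high_q, proposal_sd > 0,
            grid_size >= 16)
  structure(list(delta = delta, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), proposal_sd = proposal_sd,
                 seed = as.integer(seed), tau = as.integer(tau),
                 max_cn = as.integer(max_cn), kde_bandwidth = kde_bandwidth,
                 grid_size = as.integer(grid_size),
                 low_q = low_q, high_q = high_q),
            class = "mcmc_config")
}

#' Anchor line through the low- and high-GC median points
#'
#' The slope prior is centred on the line through two points: the (median GC,
#' median Y) of segments in the low-GC area (GC at or below the `low_q`
#' quantile) and of segments in the high-GC area (GC at or above the
#' `high_q` quantile).  Medians make the anchor robust to segments from
#' minority stripes.
#'
#' @param table A [segment_table()] with positive read counts.
#' @param low_q,high_q GC quantiles bounding the anchor areas.
#' @return A list with slope `a` and intercept `c`.
#' @export
anchor_line <- function(table, low_q = 0.10, high_q = 0.90) {
  y <- log_ratio(table)
  ok <- !is.na(y)
  x <- table$gc[ok]
  y <- y[ok]
  lo <- x <= stats::quantile(x, low_q, names = FALSE)
  hi <- x >= stats::quantile(x, high_q, names = FALSE)
  if (sum(lo) < 2 || sum(hi) < 2)
    stop("fewer than 2 segments in a GC anchor area; widen low_q/high_q")
  p_lo <- c(stats::median(x[lo]), stats::median(y[lo]))
  p_hi <- c(stats::median(x[hi]), stats::median(y[hi]))
  if (p_hi[1] == p_lo[1])
    stop("anchor areas have identical median GC; widen low_q/high_q")
  a <- (p_hi[2] - p_lo[2]) / (p_hi[1] - p_lo[1])
  list(a = a, c = p_lo[2] - a * p_lo[1])
}

#' Apply a slope/intercept correction to log-ratios
#'
#' \eqn{Y' = Y - (mX + c) + \mathrm{median}(Y)}: removes the fitted GC trend
#' and recentres at the original median so corrected values stay on the raw
#' log-ratio scale.
#'
#' @param y Log-ratios.
#' @param x GC fractions (same length as `y`).
#' @param m Slope.
#' @param c Intercept.
#' @return Corrected log-ratios \eqn{Y'}.
#' @export
correct_logratio <- function(y, x, m, c) {
  if (!length(y)) stop("empty input")
  if (length(y) != length(x)) stop("y and x must have equal length")
  y - (m * x + c) + stats::median(y)
}

#' Peaks of a Gaussian kernel density
#'
#' Evaluates a Gaussian KDE on `grid_size` evenly spaced points spanning
#' `[min - 3h, max + 3h]` and returns every strict interior local maximum,
#' sorted by height descending.  If all values coincide the density is a
#' point mass; a single peak at that value with infinite height is returned.
#'
#' @param values Numeric vector (length at least 2 for a proper density).
#' @param bandwidth `"silverman"` (the default rule, [stats::bw.nrd0()]) or a
#'   fixed positive number.
#' @param grid_size Grid length (default 1024).
#' @return A `data.frame` with columns `location` and `height`.
#' @export
density_peaks <- function(values, bandwidth = "silverman", grid_size = 1024) {
  if (length(values) < 2) stop("need at least 2 values for a density")
  if (stats::sd(values) == 0)
    return(data.frame(location = values[1], height = Inf))
  h <- if (is.numeric(bandwidth)) bandwidth else stats::bw.nrd0(values)
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = min(values) - 3 * h, to = max(values) + 3 * h,
                      n = grid_size)
  n <- length(d$y)
  mid <- 2:(n - 1)
  is_peak <- d$y[mid] > d$y[mid - 1] & d$y[mid] > d$y[mid + 1]
  idx <- mid[is_peak]
  out <- data.frame(location = d$x[idx], height = d$y[idx])
  out[order(-out$height), , drop = FALSE]
}

#' Density-peak log-likelihood of a stripe slope
#'
#' Corrects `y` with slope `m` and intercept `c` and returns the log of the
#' summed heights of the top \eqn{K = \tau \cdot \max(cn)} kernel-density
#' peaks of \eqn{Y'} (all peaks, if fewer than K exist).  Sharp stripes give
#' tall peaks, so the likelihood is maximized when `m` matches the common
#' stripe slope.  K is capped at 24 so pathological configs cannot reward
#' noise peaks.
#'
#' @param y Log-ratios.
#' @param x GC fractions.
#' @param m Candidate slope.
#' @param c Intercept (only translates \eqn{Y'}; provably irrelevant to the
#'   likelihood).
#' @param config An [mcmc_config()].
#' @return The log-likelihood (a real number, possibly `Inf` for degenerate
#'   point-mass input).
#' @export
stripe_log_likelihood <- function(y, x, m, c, config = mcmc_config()) {
  pk <- density_peaks(correct_logratio(y, x, m, c),
                      bandwidth = config$kde_bandwidth,
                      grid_size = config$grid_size)
  k <- min(config$tau * config$max_cn, 24L, nrow(pk))
  log(sum(pk$height[seq_len(k)]))
}

#' Fit the stripe-slope model by Metropolis MCMC
#'
#' Estimates the common GC-bias slope of the copy-number stripes in the GC
#' versus log-ratio plane.  The sampler is a Gaussian random walk on the
#' slope `m` under a hard uniform prior `[a - delta, a + delta]` centred on
#' the [anchor_line()] slope `a` (out-of-bounds proposals are rejected); the
#' likelihood is [stripe_log_likelihood()].  The MAP slope is the
#' best-scoring slope over every likelihood evaluation (burn-in included:
#' the posterior is one-dimensional and each evaluation is exact, so there
#' is no reason to discard early visits).  Corrected log-ratios use the MAP
#' slope with the anchor intercept, which only recentres and does not affect
#' the fit.
#'
#' @param table A [segment_table()]; all segments must have positive tumor
#'   and normal counts (zero-count segments are excluded upstream by
#'   [read_segments()]).
#' @param config An [mcmc_config()].
#' @param slope Optional fixed slope: skips sampling and applies the given
#'   slope directly (manual correction).
#' @return An object of class `stripe_fit` with components `anchor_slope`,
#'   `anchor_intercept`, `chain` (iteration, slope, log_posterior, accepted),
#'   `slope_samples` (post-burn-in slopes), `map_slope`,
#'   `map_log_posterior`, `y`, `gc`, `y_corrected`, `stripe` (nearest-peak
#'   stripe label per segment), `n_segments`, `config`, and `call`.
#' @examples
#' sim <- simulate_genome(sim_config(n_segments = 120, seed = 7))
#' fit <- stripe_fit(sim$segments, mcmc_config(n_iter = 600, burn_in = 100))
#' coef(fit)
#' @export
stripe_fit <- function(table, config = mcmc_config(), slope = NULL) {
  y <- log_ratio(table)
  if (anyNA(y))
    stop("segments with zero reads present; filter with read_segments() ",
         "or drop them before fitting")
  x <- table$gc
  cl <- match.call()

  if (stats::sd(y) == 0) {
    warning("constant log-ratios: nothing to correct, returning slope 0")
    return(new_stripe_fit(0, y[1], data.frame(iteration = integer(0),
                                              slope = numeric(0),
                                              log_posterior = numeric(0),
                                              accepted = logical(0)),
                          0, Inf, y, x, y, config, cl))
  }

  anchor <- anchor_line(table, config$low_q, config$high_q)
  a <- anchor$a
  c0 <- anchor$c

  if (!is.null(slope)) {
    ll <- stripe_log_likelihood(y, x, slope, c0, config)
    return(new_stripe_fit(a, c0, data.frame(iteration = 0L, slope = slope,
                                            log_posterior = ll,
                                            accepted = TRUE),
                          slope, ll, y, x,
                          correct_logratio(y, x, slope, c0), config, cl))
  }

  lo <- a - config$delta
  hi <- a + config$delta
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  m_cur <- a
  ll_cur <- stripe_log_likelihood(y, x, m_cur, c0, config)
  best_m <- m_cur
  best_ll <- ll_cur
  n <- config$n_iter
  chain_m <- numeric(n)
  chain_ll <- numeric(n)
  chain_acc <- logical(n)
  for (i in seq_len(n)) {
    m_prop <- m_cur + stats::rnorm(1, 0, config$proposal_sd)
    acc <- FALSE
    if (m_prop >= lo && m_prop <= hi) {
      ll_prop <- stripe_log_likelihood(y, x, m_prop, c0, config)
      if (ll_prop > best_ll) {
        best_ll <- ll_prop
        best_m <- m_prop
      }
      if (log(stats::runif(1)) < ll_prop - ll_cur) {
        m_cur <- m_prop
        ll_cur <- ll_prop
        acc <- TRUE
      }
    }
    chain_m[i] <- m_cur
    chain_ll[i] <- ll_cur
    chain_acc[i] <- acc
  }
  chain <- data.frame(iteration = seq_len(n), slope = chain_m,
                      log_posterior = chain_ll, accepted = chain_acc)
  new_stripe_fit(a, c0, chain, best_m, best_ll, y, x,
                 correct_logratio(y, x, best_m, c0), config, cl)
}

new_stripe_fit <- function(a, c0, chain, map_slope, map_ll, y, x,
                           y_corrected, config, call) {
  pk <- if (stats::sd(y_corrected) == 0)
    data.frame(location = y_corrected[1], height = Inf)
  else density_peaks(y_corrected, config$kde_bandwidth, config$grid_size)
  k <- min(config$tau * config$max_cn, 24L, nrow(pk))
  top <- pk[seq_len(k), , drop = FALSE]
  top <- top[order(top$location), , drop = FALSE]
  stripe <- vapply(y_corrected,
                   function(v) which.min(abs(v - top$location)), 0L)
  structure(list(anchor_slope = a, anchor_intercept = c0, chain = chain,
                 slope_samples = chain$slope[chain$iteration > config$burn_in],
                 map_slope = map_slope, map_log_posterior = map_ll,
                 y = y, gc = x, y_corrected = y_corrected,
                 stripe = as.integer(stripe), peaks = top,
                 n_segments = length(y), config = config, call = call),
            class = "stripe_fit")
}

#' Exhaustive grid search for the stripe slope
#'
#' Brute-force maximizer of [stripe_log_likelihood()] over `n_grid` evenly
#' spaced slopes in the prior window; serves as an independent check of the
#' Metropolis sampler.
#'
#' @param table A [segment_table()].
#' @param config An [mcmc_config()].
#' @param n_grid Number of grid points (default 200).
#' @return A list with `m_best`, `loglik_best`, and the full `grid`
#'   data.frame (slope, log_likelihood).
#' @export
grid_search_slope <- function(table, config = mcmc_config(), n_grid = 200) {
  y <- log_ratio(table)
  if (anyNA(y)) stop("segments with zero reads present")
  x <- table$gc
  anchor <- anchor_line(table, config$low_q, config$high_q)
  ms <- if (n_grid == 1) anchor$a else
    seq(anchor$a - config$delta, anchor$a + config$delta, length.out = n_grid)
  ll <- vapply(ms, function(m)
    stripe_log_likelihood(y, x, m, anchor$c, config), 0)
  best <- which.max(ll)
  list(m_best = ms[best], loglik_best = ll[best],
       grid = data.frame(slope = ms, log_likelihood = ll))
}

#' Regression-based GC correction (comparison baseline)
#'
#' The conventional approach: fit the GC trend of Y by ordinary least
#' squares or a loess smoother, subtract it, and recentre at the median.
#' With unbalanced stripes the fitted line tilts toward the majority stripe
#' and leaves residual GC dependence — the failure mode the density-peak
#' sampler is designed to avoid.
#'
#' @param table A [segment_table()] with at least 3 segments.
#' @param mode `"linear"` or `"loess"`.
#' @return Corrected log-ratios.
#' @export
regression_correct <- function(table, mode = c("linear", "loess")) {
  mode <- match.arg(mode)
  y <- log_ratio(table)
  if (anyNA(y)) stop("segments with zero reads present")
  x <- table$gc
  if (length(y) < 3) stop("need at least 3 segments")
  if (mode == "linear") {
    if (stats::sd(x) == 0) stop("rank-deficient fit: GC values are constant")
    fit <- stats::lm(y ~ x)
    unname(y - stats::fitted(fit) + stats::median(y))
  } else {
    fit <- stats::lowess(x, y, f = 2 / 3)
    y - stats::approx(fit$x, fit$y, xout = x, rule = 2)$y + stats::median(y)
  }
}
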