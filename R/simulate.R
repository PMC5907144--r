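#' Simulation configuration
#'
#' Parameters of the forward generator: SCNA-scale segments whose expected
#' tumor and normal read counts follow the GC-bias model (so the log-ratio
#' stripes have slope `a1 - a2`), and het-SNP allele counts drawn
#' binomially around the segment BAF with random maternal/paternal
#' orientation.
#'
#' @param n_segments Number of segments (default 400).
#' @param length_range Segment length bounds in bp; lengths are log-uniform
#'   (default 100 kb to 10 Mb, the SCNA scale).
#' @param gc_range Uniform GC-fraction bounds (default 0.25 to 0.65, the
#'   bulk of human genome GC).
#' @param bias A [bias_model()]; the default pairs curvature/scale
#'   (1.3, 2.3) for the normal with (2, 3) for the tumor, giving a stripe
#'   slope of -0.7.
#' @param purity Subclone frequency \eqn{\phi} applied to every altered
#'   segment (default 0.8; single-clone genomes).
#' @param copy_number_states List of `list(C, b, weight)` states including
#'   the copy-neutral baseline `(C = 2, b = 1)`; weights must sum to 1.
#'   Default: 40% baseline, 60% a (4, 2) gain.  A state may carry its own
#'   `gc_range`, emulating the GC/copy-state correlation of real tumors
#'   (amplified regions are often GC-shifted); states without one use the
#'   global `gc_range`.
#' @param depth_scale Expected normal reads per bp at the reference GC
#'   (default 0.3, i.e. 30x coverage with 100 bp reads).
#' @param g_ref Reference GC at which `depth_scale` is anchored (default
#'   0.45), making depth interpretable independently of the bias
#'   parameters.
#' @param theta_sd Lognormal sd of the per-segment efficiency factor
#'   (mappability/length effects; default 0.05).  The factor multiplies
#'   both samples' expected counts, so it cancels in the ratio.
#' @param snp_rate Usable germline-het sites per kb (default 0.2).
#' @param snp_depth Mean sequencing depth at a SNP site (default 30).
#' @param seed RNG seed.
#' @return A list of class `sim_config`; `baseline_frac` is derived as the
#'   total weight on the (2, 1) state.
#' @export
sim_config <- function(n_segments = 400, length_range = c(1e5, 1e7),
                       gc_range = c(0.25, 0.65), bias = bias_model(),
                       purity = 0.8,
                       copy_number_states = list(
                         list(C = 2L, b = 1L, weight = 0.4),
                         list(C = 4L, b = 2L, weight = 0.6)),
                       depth_scale = 0.3, g_ref = 0.45, theta_sd = 0.05,
                       snp_rate = 0.2, snp_depth = 30, seed = 1L) {
  w <- vapply(copy_number_states, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("copy-state weights must sum to 1")
  is_base <- vapply(copy_number_states, function(s)
    s$C == 2L && s$b == 1L, FALSE)
  if (!any(is_base))
    stop("copy_number_states must include the baseline state (C = 2, b = 1)")
  baseline_frac <- sum(w[is_base])
  if (baseline_frac <= 0 || baseline_frac >= 1)
    stop("baseline weight must lie strictly in (0, 1)")
  stopifnot(purity > 0, purity <= 1, depth_scale > 0, snp_depth > 0,
            snp_rate >= 0, theta_sd >= 0, n_segments >= 2,
            length_range[1] > 0, length_range[2] >= length_range[1],
            gc_range[1] > 0, gc_range[2] <= 1)
  structure(list(n_segments = as.integer(n_segments),
                 length_range = length_range, gc_range = gc_range,
                 bias = bias, purity = purity,
                 copy_number_states = copy_number_states,
                 baseline_frac = baseline_frac,
                 depth_scale = depth_scale, g_ref = g_ref,
                 theta_sd = theta_sd, snp_rate = snp_rate,
                 snp_depth = snp_depth, seed = as.integer(seed)),
            class = "sim_config")
}

# segment layout: everything except the purity-dependent counts/BAFs
sim_layout <- function(config) {
  n <- config$n_segments
  len <- round(exp(stats::runif(n, log(config$length_range[1]),
                                log(config$length_range[2]))))
  theta <- stats::rlnorm(n, 0, config$theta_sd)
  states <- config$copy_number_states
  w <- vapply(states, `[[`, 0, "weight")
  state_id <- sample.int(length(states), n, replace = TRUE, prob = w)
  gc_lo <- vapply(states, function(s)
    if (is.null(s$gc_range)) config$gc_range[1] else s$gc_range[1], 0)
  gc_hi <- vapply(states, function(s)
    if (is.null(s$gc_range)) config$gc_range[2] else s$gc_range[2], 0)
  gc <- stats::runif(n, gc_lo[state_id], gc_hi[state_id])
  # pack segments onto chromosomes with 10 kb gaps
  chrom <- character(n); start <- numeric(n)
  chr_i <- 1L; pos <- 0
  for (i in seq_len(n)) {
    if (pos + len[i] > 2.4e8) { chr_i <- chr_i + 1L; pos <- 0 }
    chrom[i] <- paste0("chr", chr_i)
    start[i] <- pos
    pos <- pos + len[i] + 1e4
  }
  list(chrom = chrom, start = start, end = start + len, len = len,
       gc = gc, theta = theta, state_id = state_id)
}

sim_expected_counts <- function(layout, config, phi) {
  bm <- config$bias
  states <- config$copy_number_states
  C <- vapply(states, `[[`, 0, "C")[layout$state_id]
  b <- vapply(states, `[[`, 0, "b")[layout$state_id]
  is_base <- C == 2 & b == 1
  seg_phi <- ifelse(is_base, 0, phi)
  cbar <- seg_phi * C + (1 - seg_phi) * 2
  xi <- (seg_phi * C * ifelse(C > 0, b / C, 0) + (1 - seg_phi)) / cbar
  base_rate <- layout$theta * layout$len * config$depth_scale
  wn <- expected_depth(layout$gc, bm, "normal") /
    expected_depth(config$g_ref, bm, "normal")
  ws <- expected_depth(layout$gc, bm, "tumor") /
    expected_depth(config$g_ref, bm, "tumor")
  list(C = C, b = b, phi = seg_phi, cbar = cbar, xi = xi,
       lambda_n = base_rate * wn, lambda_s = base_rate * ws * cbar / 2)
}

sim_realize <- function(layout, config, phi, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- config$n_segments
  ex <- sim_expected_counts(layout, config, phi)
  if (any(ex$lambda_n <= 0) || any(ex$lambda_s <= 0))
    stop("configuration yields zero expected counts")
  normal_reads <- stats::rpois(n, ex$lambda_n)
  tumor_reads <- stats::rpois(n, ex$lambda_s)
  segments <- segment_table(layout$chrom, layout$start, layout$end,
                            layout$gc, tumor_reads, normal_reads,
                            source = "simulated", genome = "synthetic")

  n_sites <- stats::rpois(n, config$snp_rate * layout$len / 1000)
  seg_of_site <- rep(seq_len(n), n_sites)
  total <- sum(n_sites)
  if (total > 0) {
    offset <- unlist(lapply(seq_len(n), function(i)
      if (n_sites[i] > 0) sort(sample.int(layout$len[i], n_sites[i],
                                          replace = FALSE))
      else integer(0)))
    pos <- layout$start[seg_of_site] + offset     # start < pos <= end
    ndep <- stats::rpois(total, config$snp_depth)
    nalt <- stats::rbinom(total, ndep, 0.5)
    tdep <- stats::rpois(total, config$snp_depth)
    flip <- stats::runif(total) < 0.5             # maternal/paternal coin
    p <- ifelse(flip, ex$xi[seg_of_site], 1 - ex$xi[seg_of_site])
    talt <- stats::rbinom(total, tdep, p)
    snps <- data.frame(chrom = layout$chrom[seg_of_site], pos = pos,
                       normal_ref = ndep - nalt, normal_alt = nalt,
                       tumor_ref = tdep - talt, tumor_alt = talt,
                       stringsAsFactors = FALSE)
  } else {
    snps <- data.frame(chrom = character(0), pos = numeric(0),
                       normal_ref = integer(0), normal_alt = integer(0),
                       tumor_ref = integer(0), tumor_alt = integer(0))
  }

  stripe <- match(ex$cbar, sort(unique(ex$cbar)))
  truth <- data.frame(segment = seq_len(n), C = ex$C, b_copies = ex$b,
                      phi = ex$phi, cbar = ex$cbar, xi = ex$xi,
                      stripe = stripe,
                      is_baseline = ex$C == 2 & ex$b == 1)
  bm <- config$bias
  y <- log(tumor_reads / normal_reads)
  attr(truth, "true_slope") <- bm$a1 - bm$a2
  attr(truth, "true_ploidy") <- sum(ex$cbar * layout$len) / sum(layout$len)
  attr(truth, "baseline_mean_y") <- mean(y[truth$is_baseline])
  list(segments = segments, snps = snps, truth = truth)
}

#' Simulate a segmented tumor/normal genome with known truth
#'
#' Draws segment lengths, GC fractions and copy states, then generates
#' Poisson read counts whose means follow the GC-bias model for each sample
#' (tumor means carry an extra \eqn{\bar C / 2} factor), and binomial
#' het-SNP allele counts around each segment's expected BAF with a fair
#' maternal/paternal coin.  A per-segment lognormal efficiency factor
#' multiplies both samples' means, emulating mappability and length effects
#' that cancel in the ratio.
#'
#' @param config A [sim_config()].
#' @return A list with `segments` (a [segment_table()]), `snps` (SNP
#'   allele-count table), and `truth` (per-segment copy state, subclone
#'   frequency, average copy number, expected BAF and stripe id, with
#'   attributes `true_slope`, `true_ploidy` and `baseline_mean_y`).
#' @examples
#' sim <- simulate_genome(sim_config(n_segments = 50, seed = 42))
#' head(sim$truth)
#' @export
simulate_genome <- function(config = sim_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  layout <- sim_layout(config)
  sim_realize(layout, config, config$purity, config$seed + 1L)
}

#' Simulate a purity (normal-contamination) series
#'
#' One dataset per purity value, all sharing the same segment layout (the
#' same lengths, GC fractions, copy states and SNP placement scheme) and
#' differing only in the subclone frequency — mirroring a tumor/normal
#' titration series.
#'
#' @param config A [sim_config()]; its `purity` field is overridden.
#' @param purities Subclone frequencies in (0, 1].
#' @return A named list of [simulate_genome()]-style datasets, one per
#'   purity.
#' @export
mixture_series <- function(config = sim_config(),
                           purities = c(0.95, 0.8, 0.6, 0.4, 0.2, 0.05)) {
  if (any(purities <= 0) || any(purities > 1))
    stop("purities must lie in (0, 1]")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  layout <- sim_layout(config)
  out <- lapply(seq_along(purities), function(i)
    sim_realize(layout, config, purities[i], config$seed + i))
  names(out) <- paste0("phi_", purities)
  out
}
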