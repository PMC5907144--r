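run_config_defaults <- function() {
  list(seed = 1L,
       segio = list(min_reads = 1, gc_clip = c(0.05, 0.95),
                    het_low = 0.4, het_high = 0.6, min_depth = 10),
       mcmc = list(delta = 1.0, n_iter = 5000, burn_in = 1000,
                   proposal_sd = NULL, tau = 2, max_cn = 6,
                   kde_bandwidth = "silverman", grid_size = 1024,
                   low_q = 0.10, high_q = 0.90),
       baseline = list(baf_tol = 0.08, min_sites = 5, linkage = "average",
                       max_clusters = 6, min_cluster_frac = 0.05),
       bias = bias_model_to_config(bias_model()),
       sim = list(n_segments = 400, purity = 0.8),
       assume_cn = NULL,
       verbosity = 1L)
}

#' Load a run configuration
#'
#' Reads a YAML config with sections `seed`, `segio`, `mcmc`, `baseline`,
#' `bias`, `sim`, `assume_cn`, `verbosity`; unknown keys are rejected so
#' typos fail loudly.  Values not given keep their defaults.
#'
#' @param path Optional YAML file; `NULL` gives pure defaults.
#' @param overrides Named list merged over the file values (CLI flags take
#'   precedence over the file).
#' @return A nested configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  merge_section <- function(base, new, where) {
    bad <- setdiff(names(new), names(base))
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    base[names(new)] <- new
    base
  }
  apply_layer <- function(cfg, layer, label) {
    top_scalar <- c("seed", "assume_cn", "verbosity")
    for (key in names(layer)) {
      if (key %in% top_scalar) cfg[[key]] <- layer[[key]]
      else if (key %in% names(cfg))
        cfg[[key]] <- merge_section(cfg[[key]], layer[[key]],
                                    paste0(label, "$", key))
      else stop("unknown config section in ", label, ": ", key)
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_layer(cfg, yaml::read_yaml(path), path)
  }
  apply_layer(cfg, overrides, "overrides")
}

mcmc_config_from_run <- function(cfg) {
  m <- cfg$mcmc
  mcmc_config(delta = m$delta, n_iter = m$n_iter, burn_in = m$burn_in,
              proposal_sd = if (is.null(m$proposal_sd)) m$delta / 10
                            else m$proposal_sd,
              seed = cfg$seed, tau = m$tau, max_cn = m$max_cn,
              kde_bandwidth = m$kde_bandwidth, grid_size = m$grid_size,
              low_q = m$low_q, high_q = m$high_q)
}

baseline_config_from_run <- function(cfg) {
  b <- cfg$baseline
  baseline_config(baf_tol = b$baf_tol, min_sites = b$min_sites,
                  linkage = b$linkage, max_clusters = b$max_clusters,
                  min_cluster_frac = b$min_cluster_frac)
}

#' Run the full correction pipeline
#'
#' read segments -> (attach SNPs) -> fit stripe slope -> select baseline ->
#' export.  Writes `corrected.tsv`, `chain.tsv`, `summary.json`, a
#' before/after scatter `stripes.png`, and — when SNPs are available —
#' `baseline.bed`.  If the SNP table is missing the baseline stage is
#' skipped with a warning and the correction outputs are still produced.
#'
#' @param segments_path Segment TSV (see [read_segments()]).
#' @param snps_path Optional SNP TSV (see [read_snp_sites()]).
#' @param config_path Optional YAML run config (see [load_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param overrides Named list of config overrides.
#' @return Invisibly, a list with the fitted objects and the summary list.
#' @export
run_pipeline <- function(segments_path, snps_path = NULL,
                         config_path = NULL, out_dir = ".",
                         overrides = list()) {
  cfg <- load_run_config(config_path, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (cfg$verbosity > 0) message(...)

  note("stage read: ", segments_path)
  table <- read_segments(segments_path, min_reads = cfg$segio$min_reads,
                         gc_clip = cfg$segio$gc_clip)

  have_snps <- !is.null(snps_path) && file.exists(snps_path)
  if (!is.null(snps_path) && !have_snps)
    warning("SNP file not found (", snps_path,
            "): baseline stage will be skipped")
  if (have_snps) {
    note("stage read: ", snps_path)
    sites <- read_snp_sites(snps_path)
    table <- attach_snp_sites(table, sites,
                              het_low = cfg$segio$het_low,
                              het_high = cfg$segio$het_high,
                              min_depth = cfg$segio$min_depth)
  }

  note("stage correct: fitting stripe slope")
  mc <- mcmc_config_from_run(cfg)
  fit <- stripe_fit(table, mc)
  write_corrected(table, fit, file.path(out_dir, "corrected.tsv"))
  utils::write.table(fit$chain, file.path(out_dir, "chain.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  plot_stripes(table, fit, file.path(out_dir, "stripes.png"))

  summary <- list(n_segments = fit$n_segments,
                  anchor_slope = fit$anchor_slope,
                  anchor_intercept = fit$anchor_intercept,
                  map_slope = fit$map_slope,
                  map_log_posterior = fit$map_log_posterior,
                  seed = cfg$seed)

  bl <- NULL
  if (have_snps) {
    note("stage baseline: selecting copy-neutral segments")
    bl <- baseline_fit(table, fit, baseline_config_from_run(cfg))
    write_baseline_bed(table, bl, file.path(out_dir, "baseline.bed"))
    summary$baseline_mean_y <- bl$baseline_mean_y
    summary$ploidy <- bl$ploidy
    summary$ploidy_int <- bl$ploidy_int
    summary$n_baseline_segments <- length(baseline_segments(bl))
    if (!is.null(cfg$assume_cn) && cfg$assume_cn != 2) {
      peaks <- fit$peaks$location
      nonbase <- setdiff(seq_along(peaks),
                         which.min(abs(peaks - bl$baseline_mean_y)))
      summary$stripe_phi <- lapply(nonbase, function(i) {
        est <- estimate_subclonal_freq(peaks[i], bl$baseline_mean_y,
                                       cfg$assume_cn)
        list(stripe = i, phi = est$phi, cbar = est$cbar)
      })
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = table, fit = fit, baseline = bl,
                 summary = summary, config = cfg))
}

#' Write the before/after stripe scatter to a PNG
#'
#' @param table A [segment_table()] (used only for its row count).
#' @param fit A `stripe_fit`.
#' @param out_path Output PNG path.
#' @return Invisibly, `out_path`; plotting failures warn rather than abort.
#' @export
plot_stripes <- function(table, fit, out_path) {
  ok <- tryCatch({
    grDevices::png(out_path, width = 1200, height = 520)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(fit)
    TRUE
  }, error = function(e) {
    warning("plotting failed: ", conditionMessage(e))
    FALSE
  })
  invisible(out_path)
}
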