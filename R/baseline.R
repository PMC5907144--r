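#' Configuration for baseline (copy-neutral) segment selection
#'
#' @param baf_tol Maximum allowed median |BAF - 1/2| for a segment to count
#'   as balanced (default 0.08, tracking binomial BAF noise at ~30x depth).
#' @param min_sites Minimum heterozygous sites per candidate segment
#'   (default 5).
#' @param linkage Agglomeration rule for [stats::hclust()] (default
#'   `"average"`).
#' @param max_clusters Upper bound on the number of clusters (default 6).
#' @param min_cluster_frac Minimum fraction of candidates a cluster must
#'   hold to be eligible as baseline (default 0.05), guarding against a few
#'   stray segments forming a spurious lowest cluster.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(baf_tol = 0.08, min_sites = 5,
                            linkage = "average", max_clusters = 6,
                            min_cluster_frac = 0.05) {
  stopifnot(baf_tol > 0, baf_tol < 0.5, max_clusters >= 1,
            min_sites >= 1, min_cluster_frac >= 0, min_cluster_frac < 1)
  structure(list(baf_tol = baf_tol, min_sites = as.integer(min_sites),
                 linkage = linkage, max_clusters = as.integer(max_clusters),
                 min_cluster_frac = min_cluster_frac),
            class = "baseline_config")
}

#' Fold B-allele fractions onto [0, 1/2]
#'
#' The B allele at a germline het site is the maternal or the paternal copy
#' with equal probability, so the BAF distribution of a segment is symmetric
#' about its expected value; folding with `min(v, 1 - v)` removes the
#' arbitrary allele orientation.
#'
#' @param values BAF values in \[0, 1\].
#' @return Folded values in \[0, 1/2\].
#' @export
fold_baf <- function(values) {
  if (any(values < 0 | values > 1)) stop("BAF values must lie in [0, 1]")
  pmin(values, 1 - values)
}

#' Is a segment's BAF consistent with the balanced (xi = 1/2) state?
#'
#' TRUE iff the segment carries at least `min_sites` heterozygous-site BAFs
#' and their median distance from 1/2 is within `baf_tol`.  Only segments
#' with equal maternal and paternal copy (mu = 1/2) have xi = 1/2 at every
#' subclone frequency, so these are the candidates for the copy-neutral
#' baseline.
#'
#' @param segment One row of a [segment_table()] (or any list with a `baf`
#'   element).
#' @param config A [baseline_config()].
#' @return Logical.
#' @export
is_half_baf <- function(segment, config = baseline_config()) {
  baf <- if (is.list(segment$baf) && !is.numeric(segment$baf))
    segment$baf[[1]] else segment$baf
  if (length(baf) < config$min_sites) return(FALSE)
  stats::median(abs(baf - 0.5)) <= config$baf_tol
}

#' Cluster corrected log-ratios hierarchically
#'
#' Agglomerative clustering of the one-dimensional corrected log-ratios.
#' The tree is cut into K clusters, K at most `max_clusters`, where K is
#' chosen by the largest relative gap between successive merge heights; if
#' the largest merge height is (numerically) zero all points coincide and a
#' single cluster is returned.
#'
#' @param y_corrected Corrected log-ratios of the candidate segments.
#' @param config A [baseline_config()].
#' @return Integer cluster labels in input order.
#' @export
cluster_candidates <- function(y_corrected, config = baseline_config()) {
  n <- length(y_corrected)
  if (n < 2) return(rep(1L, n))
  hc <- stats::hclust(stats::dist(y_corrected), method = config$linkage)
  h <- hc$height                      # ascending, length n - 1
  if (h[n - 1] <= 1e-12) return(rep(1L, n))
  ks <- 2:min(config$max_clusters, n - 1)
  if (!length(ks) || config$max_clusters == 1) return(rep(1L, n))
  # cutting into K clusters removes the top K - 1 merges; the gap for K is
  # between the lowest removed merge and the highest kept one
  rel_gap <- vapply(ks, function(k) {
    top <- h[n - k + 1]
    below <- h[n - k]
    if (below <= 1e-12) Inf else top / below
  }, 0)
  k_best <- ks[which.max(rel_gap)]
  as.integer(stats::cutree(hc, k = k_best))
}

#' Select the baseline cluster
#'
#' Among clusters holding at least `min_cluster_frac` of the candidates,
#' picks the one with the smallest mean corrected log-ratio: baseline
#' (copy-neutral) segments have the smallest average copy number among
#' balanced segments, hence the lowest stripe.  Ties go to the larger
#' cluster, then to the cluster containing the earliest candidate.
#'
#' @param labels Cluster labels from [cluster_candidates()].
#' @param y_corrected Corrected log-ratios, aligned with `labels`.
#' @param config A [baseline_config()].
#' @return A list with `baseline_cluster_id`, `baseline_mean_y`, and
#'   `cluster_means`.
#' @export
select_baseline <- function(labels, y_corrected,
                            config = baseline_config()) {
  stopifnot(length(labels) == length(y_corrected), length(labels) > 0)
  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(i) sum(labels == i), 0L)
  means <- vapply(ids, function(i) mean(y_corrected[labels == i]), 0)
  ok <- sizes >= config$min_cluster_frac * length(labels)
  if (!any(ok))
    stop("no cluster holds min_cluster_frac of candidates; ",
         "relax min_cluster_frac")
  first_member <- vapply(ids, function(i) which(labels == i)[1], 0L)
  ord <- order(!ok, means, -sizes, first_member)
  best <- ord[1]
  list(baseline_cluster_id = ids[best], baseline_mean_y = means[best],
       cluster_means = stats::setNames(means, ids),
       cluster_sizes = stats::setNames(sizes, ids))
}

#' Identify copy-neutral baseline segments
#'
#' The two-step baseline search: (1) keep segments whose het-site BAFs are
#' consistent with the balanced state xi = 1/2 ([is_half_baf()]); (2)
#' cluster their corrected log-ratios hierarchically and take the eligible
#' cluster with the smallest mean as baseline ([select_baseline()]).  The
#' genome ploidy is then estimated from all segments relative to the
#' baseline level ([estimate_ploidy()]).
#'
#' @param table A [segment_table()] with attached `baf` lists (see
#'   [attach_snp_sites()]).
#' @param fit A `stripe_fit` aligned 1:1 with `table` rows.
#' @param config A [baseline_config()].
#' @return An object of class `baseline_fit` with `candidate_ids` (row
#'   indices into `table`), `cluster_labels`, `baseline_cluster_id`,
#'   `baseline_mean_y`, `cluster_means`, `ploidy` (real) and `ploidy_int`.
#' @export
baseline_fit <- function(table, fit, config = baseline_config()) {
  if (length(fit$y_corrected) != nrow(table))
    stop("stripe fit and segment table have different lengths")
  cand <- which(vapply(seq_len(nrow(table)), function(i)
    is_half_baf(list(baf = table$baf[[i]]), config), FALSE))
  if (length(cand) == 0)
    stop("no candidate segments pass the BAF filter; ",
         "check attach_snp_sites() and baf_tol/min_sites")
  yc <- fit$y_corrected[cand]
  labels <- cluster_candidates(yc, config)
  sel <- select_baseline(labels, yc, config)
  res <- structure(list(candidate_ids = cand, cluster_labels = labels,
                        baseline_cluster_id = sel$baseline_cluster_id,
                        baseline_mean_y = sel$baseline_mean_y,
                        cluster_means = sel$cluster_means,
                        cluster_sizes = sel$cluster_sizes,
                        ploidy = NA_real_, ploidy_int = NA_integer_,
                        config = config),
                   class = "baseline_fit")
  pl <- estimate_ploidy(table, fit, res)
  res$ploidy <- pl$ploidy
  res$ploidy_int <- pl$ploidy_int
  res
}

#' @export
print.baseline_fit <- function(x, ...) {
  nb <- sum(x$cluster_labels == x$baseline_cluster_id)
  cat("Baseline (copy-neutral) segment selection\n")
  cat(sprintf("  candidates passing BAF filter: %d\n",
              length(x$candidate_ids)))
  cat(sprintf("  clusters: %d; baseline cluster %d holds %d segments\n",
              length(x$cluster_means), x$baseline_cluster_id, nb))
  cat(sprintf("  baseline mean corrected log-ratio: %.4f\n",
              x$baseline_mean_y))
  cat(sprintf("  estimated ploidy: %.3f (rounded: %d)\n",
              x$ploidy, x$ploidy_int))
  invisible(x)
}

#' Baseline segment row indices
#'
#' @param x A `baseline_fit`.
#' @return Integer indices (into the original segment table) of the
#'   segments assigned to the baseline cluster.
#' @export
baseline_segments <- function(x) {
  x$candidate_ids[x$cluster_labels == x$baseline_cluster_id]
}

#' Estimate genome ploidy from the baseline level
#'
#' Each segment's relative copy estimate is
#' \eqn{r_i = 2 \exp(Y'_i - \bar Y'_{baseline})}; the ploidy is the
#' segment-length-weighted mean of \eqn{r_i} over all segments (baseline
#' segments contribute exactly 2).
#'
#' @param table A [segment_table()].
#' @param fit A `stripe_fit` aligned with `table`.
#' @param baseline A `baseline_fit` (or any list with `baseline_mean_y`).
#' @return A list with `ploidy` (real) and `ploidy_int` (rounded).
#' @export
estimate_ploidy <- function(table, fit, baseline) {
  r <- 2 * exp(fit$y_corrected - baseline$baseline_mean_y)
  w <- table$end - table$start
  ploidy <- sum(r * w) / sum(w)
  list(ploidy = ploidy, ploidy_int = as.integer(round(ploidy)))
}
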