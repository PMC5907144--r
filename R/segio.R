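#' Build a segment table
#'
#' A segment table is a `data.frame` of SCNA-scale genomic intervals with GC
#' fraction and tumor/normal read counts, plus a list-column `baf` holding the
#' per-segment tumor B-allele fractions observed at germline heterozygous SNP
#' sites (filled by [attach_snp_sites()]).  Segment coordinates are 0-based
#' half-open (BED convention); SNP positions are 1-based (VCF convention).
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds, `end > start`.
#' @param gc GC fractions in \[0, 1\].
#' @param tumor_reads,normal_reads Non-negative read counts.
#' @param baf Optional list of numeric BAF vectors, one per segment.
#' @param source Optional provenance label (e.g. the source file).
#' @param genome Optional genome label.
#' @return A `data.frame` with class `segment_table`.
#' @export
segment_table <- function(chrom, start, end, gc, tumor_reads, normal_reads,
                          baf = NULL, source = NA_character_,
                          genome = NA_character_) {
  tab <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    gc = as.numeric(gc),
                    tumor_reads = as.numeric(tumor_reads),
                    normal_reads = as.numeric(normal_reads),
                    stringsAsFactors = FALSE)
  tab$baf <- if (is.null(baf)) rep(list(numeric(0)), nrow(tab)) else baf
  class(tab) <- c("segment_table", "data.frame")
  attr(tab, "source") <- source
  attr(tab, "genome") <- genome
  validate_segments(tab)
  tab
}

validate_segments <- function(tab) {
  bad <- which(tab$end <= tab$start)
  if (length(bad))
    stop(sprintf("segment row %d: end (%g) must exceed start (%g)",
                 bad[1], tab$end[bad[1]], tab$start[bad[1]]))
  if (any(tab$gc < 0 | tab$gc > 1))
    stop("gc fractions must lie in [0, 1]")
  if (any(tab$tumor_reads < 0) || any(tab$normal_reads < 0))
    stop("read counts must be non-negative")
  for (chr in unique(tab$chrom)) {
    idx <- which(tab$chrom == chr)
    ord <- idx[order(tab$start[idx])]
    if (length(ord) > 1L) {
      ov <- which(tab$start[ord[-1]] < tab$end[ord[-length(ord)]])
      if (length(ov))
        stop(sprintf(
          "overlapping segments on %s: rows %d and %d",
          chr, ord[ov[1]], ord[ov[1] + 1]))
    }
  }
  invisible(tab)
}

#' Log read-count ratio of each segment
#'
#' \eqn{Y = \log(D^S / D^N)} (natural log); `NA` where either count is zero.
#'
#' @param table A [segment_table()].
#' @return Numeric vector of log-ratios.
#' @export
log_ratio <- function(table) {
  y <- rep(NA_real_, nrow(table))
  ok <- table$tumor_reads > 0 & table$normal_reads > 0
  y[ok] <- log(table$tumor_reads[ok] / table$normal_reads[ok])
  y
}

#' Read a tab-separated segment table
#'
#' Expects a header naming at least `chrom start end gc tumor_reads
#' normal_reads`.  Rows whose tumor or normal count falls below `min_reads`
#' are dropped (and reported); GC fractions are clipped into `gc_clip` so
#' that the bias model's `d * gc` factor never degenerates to zero.
#'
#' @param path Path to a TSV file.
#' @param min_reads Minimum read count required in both samples (default 1,
#'   which drops zero-count segments and keeps the log-ratio defined).
#' @param gc_clip Length-2 vector of clipping bounds for GC (default
#'   `c(0.05, 0.95)`).
#' @return A [segment_table()]; the number of dropped rows is attached as
#'   attribute `n_dropped` and reported via [message()].
#' @export
read_segments <- function(path, min_reads = 1, gc_clip = c(0.05, 0.95)) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "tumor_reads", "normal_reads")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("segment file lacks required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("start", "end", "gc", "tumor_reads", "normal_reads")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   col, bad[1], path))
    raw[[col]] <- v
  }
  keep <- raw$tumor_reads >= min_reads & raw$normal_reads >= min_reads
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("read_segments: dropped %d of %d rows with < %g reads",
                    n_dropped, nrow(raw), min_reads))
  raw <- raw[keep, , drop = FALSE]
  gc <- pmin(gc_clip[2], pmax(gc_clip[1], raw$gc))
  tab <- segment_table(raw$chrom, raw$start, raw$end, gc,
                       raw$tumor_reads, raw$normal_reads,
                       source = path)
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Read a tab-separated SNP allele-count table
#'
#' Expects header `chrom pos normal_ref normal_alt tumor_ref tumor_alt`;
#' positions are 1-based.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of SNP sites.
#' @export
read_snp_sites <- function(path) {
  if (!file.exists(path)) stop("SNP file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "normal_ref", "normal_alt",
            "tumor_ref", "tumor_alt")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("SNP file lacks required column(s): ", paste(miss, collapse = ", "))
  if (any(raw$pos != round(raw$pos)) || any(raw$pos < 1))
    stop("SNP positions must be positive integers (1-based)")
  raw
}

#' Attach germline-heterozygous SNP BAFs to segments
#'
#' A site is called germline-heterozygous iff its normal-sample depth is at
#' least `min_depth` and its normal-sample alt fraction lies in
#' `[het_low, het_high]`.  Each heterozygous site falling inside a segment
#' contributes the tumor alt fraction `tumor_alt / (tumor_ref + tumor_alt)`
#' to that segment's `baf` list (sites with zero tumor depth contribute
#' nothing).  A 1-based site at position p belongs to the 0-based half-open
#' segment `[start, end)` iff `start < p <= end`.  The `baf` lists are
#' recomputed from scratch, so the operation is idempotent and independent of
#' site order.
#'
#' @param table A [segment_table()].
#' @param sites A SNP site table as from [read_snp_sites()].
#' @param het_low,het_high Normal-sample alt-fraction window for calling a
#'   site heterozygous (defaults 0.4 and 0.6, tracking binomial noise at
#'   around 30x depth).
#' @param min_depth Minimum normal-sample depth (default 10).
#' @return The segment table with refreshed `baf` lists.
#' @export
attach_snp_sites <- function(table, sites, het_low = 0.4, het_high = 0.6,
                             min_depth = 10) {
  stopifnot(het_low <= het_high)
  baf <- rep(list(numeric(0)), nrow(table))
  ndep <- sites$normal_ref + sites$normal_alt
  tdep <- sites$tumor_ref + sites$tumor_alt
  het <- ndep >= min_depth & tdep > 0 &
    (sites$normal_alt / ndep) >= het_low &
    (sites$normal_alt / ndep) <= het_high
  het[is.na(het)] <- FALSE
  sites <- sites[het, , drop = FALSE]
  tb <- sites$tumor_alt / (sites$tumor_ref + sites$tumor_alt)
  for (chr in unique(table$chrom)) {
    seg_idx <- which(table$chrom == chr)
    site_idx <- which(sites$chrom == chr)
    if (!length(seg_idx) || !length(site_idx)) next
    ord <- seg_idx[order(table$start[seg_idx])]
    # start < p <= end  <=>  p in (start, end] on the 1-based axis
    slot <- findInterval(sites$pos[site_idx] - 1L, table$start[ord],
                         left.open = FALSE)
    inside <- slot >= 1 &
      sites$pos[site_idx] <= table$end[ord[pmax(slot, 1L)]] &
      sites$pos[site_idx] > table$start[ord[pmax(slot, 1L)]]
    assigned <- ord[slot[inside]]
    sp <- split(tb[site_idx[inside]], assigned)
    for (seg_chr in names(sp)) {
      seg <- as.integer(seg_chr)
      baf[[seg]] <- c(baf[[seg]], sp[[seg_chr]])
    }
  }
  baf <- lapply(baf, sort)
  table$baf <- baf
  table
}

#' Write a corrected segment table
#'
#' Writes the input columns plus the corrected log-ratio `y_corrected` and
#' the `stripe` label assigned by [stripe_fit()].  Optionally also writes an
#' interval-count file (`ID chrm start end tumorCount normalCount`) of the
#' form consumed by interval-based subclonal reconstruction tools.
#'
#' @param table A [segment_table()].
#' @param result A `stripe_fit` object aligned 1:1 with `table` rows.
#' @param path Output TSV path.
#' @param theta_path Optional path for the interval-count file.
#' @return Invisibly, the written data frame.
#' @export
write_corrected <- function(table, result, path, theta_path = NULL) {
  if (length(result$y_corrected) != nrow(table))
    stop("correction result and segment table have different lengths")
  out <- as.data.frame(table)[, c("chrom", "start", "end", "gc",
                                  "tumor_reads", "normal_reads")]
  out$y_corrected <- result$y_corrected
  out$stripe <- result$stripe
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(theta_path)) {
    iv <- data.frame(ID = paste0("seg_", seq_len(nrow(table))),
                     chrm = table$chrom,
                     start = format(table$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(table$end, scientific = FALSE, trim = TRUE),
                     tumorCount = table$tumor_reads,
                     normalCount = table$normal_reads)
    utils::write.table(iv, theta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Write baseline segments as BED
#'
#' BED columns: chrom, start, end, name (cluster label), score (the cluster's
#' mean corrected log-ratio).
#'
#' @param table A [segment_table()].
#' @param baseline A `baseline_fit` object.
#' @param path Output BED path.
#' @return Invisibly, the written data frame.
#' @export
write_baseline_bed <- function(table, baseline, path) {
  idx <- baseline$candidate_ids[baseline$cluster_labels ==
                                  baseline$baseline_cluster_id]
  bed <- data.frame(chrom = table$chrom[idx],
                    start = format(table$start[idx], scientific = FALSE,
                                   trim = TRUE),
                    end = format(table$end[idx], scientific = FALSE,
                                 trim = TRUE),
                    name = paste0("cluster_", baseline$baseline_cluster_id),
                    score = round(baseline$baseline_mean_y, 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}

#' Write a segment table as TSV
#'
#' @param table A [segment_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(table, path) {
  out <- as.data.frame(table)[, c("chrom", "start", "end", "gc",
                                  "tumor_reads", "normal_reads")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  out$gc <- formatC(out$gc, digits = 6, format = "f")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
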