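test_that("segment tables round-trip through TSV unchanged", {
  tab <- segment_table(chrom = c("chr1", "chr1", "chr2"),
                       start = c(0, 2e6, 100),
                       end = c(1e6, 3e6, 50100),
                       gc = c(0.41, 0.52, 0.335),
                       tumor_reads = c(1000, 2000, 1500),
                       normal_reads = c(900, 2100, 1400))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(tab, path)
  back <- read_segments(path)
  expect_equal(nrow(back), 3)
  expect_identical(back$chrom, tab$chrom)
  expect_identical(back$start, tab$start)
  expect_identical(back$end, tab$end)
  expect_identical(back$tumor_reads, tab$tumor_reads)
  expect_identical(back$normal_reads, tab$normal_reads)
  expect_equal(back$gc, tab$gc, tolerance = 1e-6)
})

test_that("invalid segment geometry is rejected with the offending row", {
  expect_error(
    segment_table("chr1", start = 100, end = 100, gc = 0.4,
                  tumor_reads = 1, normal_reads = 1),
    "row 1.*end")
  expect_error(
    segment_table(c("chr1", "chr1"), start = c(0, 500),
                  end = c(1000, 1500), gc = c(0.4, 0.5),
                  tumor_reads = c(1, 1), normal_reads = c(1, 1)),
    "overlapping")
  # same intervals on different chromosomes are fine
  expect_silent(
    segment_table(c("chr1", "chr2"), start = c(0, 0),
                  end = c(1000, 1000), gc = c(0.4, 0.5),
                  tumor_reads = c(1, 1), normal_reads = c(1, 1)))
})

test_that("low-count rows are dropped and accounted for", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc\ttumor_reads\tnormal_reads",
               "chr1\t0\t1000\t0.4\t100\t90",
               "chr1\t2000\t3000\t0.5\t120\t0",
               "chr1\t4000\t5000\t0.6\t0\t80",
               "chr2\t0\t1000\t0.45\t50\t60",
               "chr2\t2000\t3000\t0.02\t70\t75"), path)
  expect_message(tab <- read_segments(path, min_reads = 1),
                 "dropped 2 of 5")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_dropped"), 2)
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), 5)
  # gc clipped into [0.05, 0.95]
  expect_equal(tab$gc[3], 0.05)
})

test_that("malformed numeric fields name the bad line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc\ttumor_reads\tnormal_reads",
               "chr1\t0\t1000\t0.4\t100\t90",
               "chr1\t2000\t3000\tnot_a_number\t120\t100"), path)
  expect_error(read_segments(path), "gc.*line 2")
})

test_that("heterozygous sites contribute tumor BAFs to their segment", {
  tab <- segment_table(c("chr1", "chr1"), start = c(100, 5000),
                       end = c(200, 6000), gc = c(0.4, 0.5),
                       tumor_reads = c(10, 10), normal_reads = c(10, 10))
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr3"),
    pos = c(150, 160, 170, 150),
    normal_ref = c(15, 30, 14, 15),
    normal_alt = c(15, 0, 16, 15),
    tumor_ref = c(10, 10, 5, 10),
    tumor_alt = c(20, 10, 15, 20))
  out <- attach_snp_sites(tab, sites)
  # het site (15,15)/(10,20) -> 20/30; homozygous (30,0) ignored;
  # chr3 site covered by no segment ignored
  expect_equal(out$baf[[1]], sort(c(20 / 30, 15 / 20)), tolerance = 1e-12)
  expect_identical(out$baf[[2]], numeric(0))
})

test_that("site-in-segment containment uses start < pos <= end", {
  # 0-based half-open [100, 200) covers 1-based positions 101..200
  tab <- segment_table("chr1", 100, 200, 0.4, 10, 10)
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                 normal_ref = 15, normal_alt = 15,
                                 tumor_ref = 10, tumor_alt = 10)
  expect_length(attach_snp_sites(tab, mk(100))$baf[[1]], 0)
  expect_length(attach_snp_sites(tab, mk(101))$baf[[1]], 1)
  expect_length(attach_snp_sites(tab, mk(200))$baf[[1]], 1)
  expect_length(attach_snp_sites(tab, mk(201))$baf[[1]], 0)
})

test_that("attach_snp_sites is idempotent and order-independent", {
  set.seed(4)
  tab <- segment_table(rep("chr1", 3), start = c(0, 2e4, 5e4),
                       end = c(1e4, 3e4, 6e4), gc = c(0.3, 0.4, 0.5),
                       tumor_reads = rep(10, 3), normal_reads = rep(10, 3))
  sites <- data.frame(chrom = "chr1",
                      pos = sample(c(1:1e4, 20001:3e4, 50001:6e4), 60),
                      normal_ref = rpois(60, 15), normal_alt = rpois(60, 15),
                      tumor_ref = rpois(60, 15), tumor_alt = rpois(60, 15))
  once <- attach_snp_sites(tab, sites)
  twice <- attach_snp_sites(once, sites)
  shuffled <- attach_snp_sites(tab, sites[sample(nrow(sites)), ])
  expect_identical(once$baf, twice$baf)
  expect_identical(once$baf, shuffled$baf)
})

test_that("corrected tables are written with stripe labels intact", {
  fx <- two_stripe_fixture(n = 60, seed = 11)
  fit <- stripe_fit(fx$table, fast_mcmc(seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  theta <- withr::local_tempfile(fileext = ".txt")
  write_corrected(fx$table, fit, path, theta_path = theta)
  out <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(out), 60)
  expect_equal(out$y_corrected, fit$y_corrected, tolerance = 1e-9)
  expect_equal(length(unique(out$stripe)), length(unique(fit$stripe)))
  iv <- read.table(theta, header = TRUE, sep = "\t")
  expect_identical(names(iv), c("ID", "chrm", "start", "end",
                                "tumorCount", "normalCount"))
  expect_equal(iv$tumorCount, fx$table$tumor_reads)
  # alignment is enforced
  expect_error(write_corrected(fx$table[1:10, ], fit, path),
               "different lengths")
})
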