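chrom1 <- c(chr1 = 100000L)

uniform_fragments <- function(per_window, window = 200L, chrom_len = 100000L,
                              jitter_seed = NULL) {
  # exactly per_window fragment midpoints in every window
  n_win <- chrom_len %/% window
  mids <- rep((seq_len(n_win) - 1L) * window, each = per_window) +
    seq(10, window - 10, length.out = per_window)
  GenomicRanges::GRanges("chr1", IRanges::IRanges(as.integer(mids) - 99L,
                                                  as.integer(mids) + 100L))
}

test_that("identical treatment and input yield no peaks", {
  fr <- uniform_fragments(5)
  expect_length(call_peaks(fr, fr, chrom1), 0)
})

test_that("window p-value equals the upper Poisson tail at the local lambda", {
  input <- uniform_fragments(5)
  spike_mid <- 50100L # inside window 251
  spike <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rep(spike_mid - 99L, 25),
                                                           rep(spike_mid + 100L, 25)))
  treatment <- c(uniform_fragments(5), spike)
  pk <- call_peaks(treatment, input, chrom1, fdr_threshold = 0.05)
  expect_length(pk, 1)
  expect_equal(S4Vectors::mcols(pk)$fragment_count, 30L)
  # independent Poisson-tail oracle: lambda = depth ratio x input count 5
  ratio <- length(treatment) / length(input)
  p_oracle <- 1 - sum(exp(-5 * ratio) * (5 * ratio)^(0:29) / factorial(0:29))
  expect_equal(unname(S4Vectors::mcols(pk)$pvalue), p_oracle, tolerance = 1e-9)
})

test_that("zero input depth falls back to the genome-wide rate with a warning", {
  tr <- uniform_fragments(5)
  empty <- GenomicRanges::GRanges()
  expect_warning(pk <- call_peaks(tr, empty, chrom1), "genome-wide")
  expect_length(pk, 0)
})

test_that("null fragment data keeps the fraction of significant windows at bay", {
  set.seed(51)
  n_seeds <- 30
  frac <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    # 2000 windows of 200 bp; both sides Poisson with the same rate
    n <- rpois(2, 2000 * 5)
    tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      sample.int(399800, n[1], replace = TRUE), width = 200))
    inp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      sample.int(399800, n[2], replace = TRUE), width = 200))
    pk <- call_peaks(tr, inp, c(chr1 = 400000L))
    n_sig_windows <- sum(GenomicRanges::width(pk)) / 200
    frac[i] <- n_sig_windows / 2000
  }
  expect_lte(mean(frac), 0.05)
})

test_that("consensus retains loci at the support boundary and merges bookended peaks", {
  mk <- function(...) GenomicRanges::GRanges("chr1", IRanges::IRanges(...))
  # locus A (100-200) in 4 of 12 samples, locus B (5000-5100) in 3 of 12
  peaks <- c(
    lapply(1:4, function(i) mk(100, 200)),
    lapply(1:3, function(i) mk(5000, 5100)),
    lapply(1:5, function(i) mk(9000, 9050)))
  names(peaks) <- paste0("s", 1:12)
  cs <- build_consensus(peaks, min_support = 4)
  expect_equal(GenomicRanges::start(cs$loci), c(100, 9000))
  expect_equal(cs$support, c(4, 5))
  # [100,200) and [150,300) 0-based merge into [100,300)
  two <- list(a = genomic_interval("chr1", 100, 200),
              b = genomic_interval("chr1", 150, 300),
              c = mk(1, 10), d = mk(1, 10))
  cs2 <- build_consensus(two, min_support = 2)
  merged <- cs2$loci[GenomicRanges::start(cs2$loci) > 50]
  expect_equal(GenomicRanges::start(merged), 101) # 0-based 100
  expect_equal(GenomicRanges::end(merged), 300)
})

test_that("concordance labels follow the all-4-replicates rule", {
  mk <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  none <- GenomicRanges::GRanges()
  # locus X: MR 4/4, GR 0/4 -> selective_MR
  # locus Y: MR 4/4, GR 4/4 -> overlapping
  # locus Z: MR 4/4, GR 1/4 -> unclassified
  mr <- lapply(1:4, function(i) c(mk(100, 300), mk(1000, 1200), mk(5000, 5200)))
  gr <- c(lapply(1:3, function(i) mk(1000, 1200)),
          list(c(mk(1000, 1200), mk(5000, 5200))))
  # every locus is MR-full here, so the Fisher margin degenerates (warns)
  cc <- suppressWarnings(classify_concordance(mr, gr, condition = "FS30"))
  expect_equal(unname(cc$venn["selective_MR"]), 1L)
  expect_equal(unname(cc$venn["selective_GR"]), 0L)
  expect_equal(unname(cc$venn["overlapping"]), 1L)
  expect_equal(unname(cc$venn["unclassified"]), 1L)
  expect_error(classify_concordance(mr[1:3], gr), "4 replicates")
})

test_that("concordance labels reproduce brute-force set logic on random peaks", {
  for (seed in c(61, 62)) {
    mr <- random_peak_list(4, 40, seed)
    gr <- random_peak_list(4, 40, seed + 100)
    cc <- classify_concordance(mr, gr)
    # brute force: for each merged locus, recount overlaps per replicate
    for (i in seq_along(cc$loci)) {
      locus <- cc$loci[i]
      mr_n <- sum(vapply(mr, function(p) any(IRanges::overlapsAny(locus, p)), TRUE))
      gr_n <- sum(vapply(gr, function(p) any(IRanges::overlapsAny(locus, p)), TRUE))
      want <- if (mr_n == 4 && gr_n == 0) "selective_MR"
      else if (gr_n == 4 && mr_n == 0) "selective_GR"
      else if (mr_n == 4 && gr_n == 4) "overlapping"
      else "unclassified"
      expect_equal(cc$labels[i], want)
    }
  }
})

test_that("occupancy matrices round-trip through TSV bit-exactly", {
  peaks <- random_peak_list(12, 30, seed = 71)
  names(peaks) <- paste0("s", 1:12)
  cs <- build_consensus(peaks, min_support = 4)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_occupancy(cs, f1)
  back <- read_occupancy(f1)
  write_occupancy(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(back$support, cs$support)
  expect_equal(unname(back$occupancy), unname(cs$occupancy))
})

test_that("narrowPeak files round-trip through write/read", {
  input <- uniform_fragments(5)
  spike <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rep(50001L, 30),
                                                           rep(50200L, 30)))
  pk <- call_peaks(c(uniform_fragments(5), spike), input, chrom1)
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(back$signalValue, as.numeric(S4Vectors::mcols(pk)$fragment_count))
})

test_that("genomic distribution percentages sum to 100 with condition summaries", {
  ann <- toy_annotation()
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(30000, 40000),
                                                         c(30200, 40200)))
  pk_list <- list(s1 = far, s2 = far)
  gd <- genomic_distribution(pk_list, ann, conditions = c(s1 = "BLAM", s2 = "BLAM"))
  expect_equal(unname(gd$per_sample[, "distal_intergenic"]), c(100, 100))
  expect_equal(unname(rowSums(gd$per_sample)), c(100, 100), tolerance = 0.1)
  expect_equal(gd$summary$mean[gd$summary$class == "distal_intergenic"], 100)
})
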