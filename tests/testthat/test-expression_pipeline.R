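test_that("fractional counting splits fragments across (gene, space) units", {
  ann <- toy_annotation()
  frags <- list(s1 = GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1400, 1150, 12250), c(1599, 1349, 12449))))
  # frag1: fully inside geneA's intron [1201,2000]      -> intronic +1
  # frag2: spans geneA exon1 [1001,1200] and the intron -> +0.5 each space
  # frag3: spans geneB exon [12001,12300] and intron    -> +0.5 each space
  ct <- count_features(frags, ann)
  expect_equal(ct$intronic["geneA", "s1"], 1.5)
  expect_equal(ct$exonic["geneA", "s1"], 0.5)
  expect_equal(ct$intronic["geneB", "s1"], 0.5)
  expect_equal(ct$exonic["geneB", "s1"], 0.5)
  expect_equal(ct$exonic["geneC", "s1"], 0)
  # a fragment overlapping exons of two genes contributes 0.5 exonic each
  ex2 <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(101, 451), c(400, 700)),
    strand = "+", gene_id = c("g1", "g2"),
    transcript_id = c("g1.t1", "g2.t1"))
  ann2 <- genome_annotation(ex2, c(chr1 = 5000L))
  both <- list(s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(350, 500)))
  ct2 <- count_features(both, ann2)
  expect_equal(unname(ct2$exonic[, "s1"]), c(0.5, 0.5))
  # feature lengths: merged exon and total intron
  expect_equal(unname(ct$lengths$exonic["geneA"]), 600)
  expect_equal(unname(ct$lengths$intronic["geneA"]), 800)
  expect_equal(unname(ct$lengths$intronic["geneC"]), 0)
})

test_that("counting conserves mass: intronic + exonic never exceeds fragments", {
  sim <- tiny_sim()
  sub <- sim$rna$fragments[1:3]
  ct <- count_features(sub, sim$annotation)
  tot <- colSums(ct$intronic) + colSums(ct$exonic)
  expect_true(all(tot <= ct$lib_sizes + 1e-9))
  expect_true(all(tot >= 0.8 * ct$lib_sizes)) # most fragments hit features
})

test_that("expression filter requires > min reads in every replicate of one group", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  tab <- rbind(
    g1 = c(11, 12, 0, 0),    # all A replicates > 10 -> kept
    g2 = c(10, 50, 10, 50),  # one replicate exactly 10 in each group -> dropped
    g3 = c(0, 0, 0, 0),      # all zero -> dropped
    g4 = c(9, 9, 11, 12))    # all B replicates > 10 -> kept
  colnames(tab) <- names(groups)
  kept <- filter_expressed(tab, groups)
  expect_setequal(rownames(kept), c("g1", "g4"))
  # idempotent
  expect_identical(filter_expressed(kept, groups), kept)
})

test_that("time-course DE assigns categories and merges the stress table", {
  set.seed(91)
  groups <- stats::setNames(rep(c("BLAM", "FS30", "FS60", "BLPM"), each = 4),
                            paste0(rep(c("BLAM", "FS30", "FS60", "BLPM"), each = 4),
                                   "_r", 1:4))
  G <- 120
  mu <- exp(runif(G, 4, 6))
  eff30 <- rep(1, G); eff60 <- rep(1, G); effpm <- rep(1, G)
  eff30[1:20] <- 3; eff60[1:20] <- 6      # stress genes peak at FS60
  eff60[21:30] <- 0.25                     # down-regulated at FS60 only
  effpm[31:40] <- 4                        # circadian genes
  mk <- function(eff) matrix(rnbinom(G * 4, mu = rep(mu * eff, 4), size = 15), G)
  tab <- cbind(mk(rep(1, G)), mk(eff30), mk(eff60), mk(effpm))
  dimnames(tab) <- list(paste0("g", 1:G), names(groups))
  de <- de_timecourse(list(intronic = tab), groups)
  cats <- de$categories$intronic
  expect_true(all(cats[paste0("g", 1:40)] == "RES"))
  expect_gt(mean(cats[paste0("g", 41:120)] == "CON"), 0.9)
  merged <- de$merged_stress$intronic
  m1 <- merged[merged$gene == "g1", ]
  expect_equal(m1$timepoint, "FS60")
  expect_gt(m1$log2FC, 1.5)
  m25 <- merged[merged$gene == "g25", ]
  expect_lt(m25$log2FC, -1) # sign retained for the down response
  # merged magnitude dominates each individual stress time point
  res <- de$results[de$results$group %in% c("FS30", "FS60"), ]
  for (g in c("g1", "g5", "g25")) {
    expect_gte(abs(merged$log2FC[merged$gene == g]) + 1e-9,
               max(abs(res$log2FC[res$gene == g])))
  }
  expect_error(de_timecourse(list(intronic = tab), groups, baseline = "XX"),
               "baseline")
})

test_that("TPM normalizes rates to a million and baseline ratios to one", {
  tab <- rbind(g1 = c(10, 20), g2 = c(30, 60))
  colnames(tab) <- c("BLAM_r1", "BLAM_r2")
  lens <- c(g1 = 1000, g2 = 3000)
  tt <- tpm(tab, lens, groups = c(BLAM_r1 = "BLAM", BLAM_r2 = "BLAM"))
  expect_equal(unname(tt$tpm[, 1]), c(5e5, 5e5))
  expect_equal(unname(colSums(tt$tpm)), c(1e6, 1e6), tolerance = 1e-6)
  expect_equal(unname(tt$ratio[, "BLAM"]), c(1, 1))
})

test_that("variable-gene projection separates planted groups and orders variance", {
  set.seed(92)
  G <- 400
  base <- exp(runif(G, 3, 6))
  grpA <- matrix(rnbinom(G * 5, mu = base, size = 20), G)
  shift <- c(rep(4, 150), rep(1, G - 150))
  grpB <- matrix(rnbinom(G * 5, mu = base * shift, size = 20), G)
  tab <- cbind(grpA, grpB)
  dimnames(tab) <- list(paste0("g", 1:G), paste0("s", 1:10))
  pr <- top_variable_projection(tab, n_top = 200)
  expect_true(all(diff(pr$variance_explained) <= 1e-9))
  expect_lte(sum(pr$variance_explained), 100 + 1e-6)
  expect_true(all(sign(pr$scores[1:5, 1]) != sign(pr$scores[6:10, 1])))
  # duplicated sample projects to identical coordinates
  tab2 <- cbind(tab, s11 = tab[, 1])
  pr2 <- top_variable_projection(tab2, n_top = 200)
  expect_equal(pr2$scores["s11", ], pr2$scores["s1", ], tolerance = 1e-9)
  expect_warning(top_variable_projection(tab, n_top = 1000), "n_top")
  # heat-map export: centered rows over the union of top DE genes
  de_like <- list(results = data.frame(
    space = "intronic", comparison = "FS30_vs_BLAM", group = "FS30",
    gene = paste0("g", 1:G), log2FC = 0,
    pvalue = runif(G), fdr = runif(G)))
  hm <- top_de_matrix(de_like, tab, k = 25)
  expect_equal(nrow(hm), 25)
  expect_equal(unname(rowMeans(hm)), rep(0, 25), tolerance = 1e-9)
})
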