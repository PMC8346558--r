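named_mat <- function(x, nr) {
  m <- matrix(x, nr)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  rownames(m) <- paste0("locus", seq_len(nr))
  m
}

test_that("fragment counting uses the midpoint rule", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 5000), c(1400, 5400)))
  cs <- structure(list(loci = loci,
                       occupancy = matrix(1, 2, 1), support = c(1, 1)),
                  class = "ConsensusPeakSet")
  frags <- list(
    s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(1100, 950, 5350, 20000), # midpoints 1199(in), 1049(in), 5449(out), out
      c(1299, 1149, 5549, 20199))))
  bm <- count_in_consensus(frags, cs)
  expect_equal(unname(bm$counts[, 1]), c(2L, 0L))
  expect_equal(unname(bm$lib_sizes), 4L)
  # empty locus rows are retained as zeros
  expect_equal(nrow(bm$counts), 2)
})

test_that("TMM factors behave on identity, scaling and random data", {
  set.seed(81)
  y <- matrix(rnbinom(400 * 2, mu = 100, size = 10), 400)
  same <- cbind(y[, 1], y[, 1])
  expect_equal(tmm_factors(same), c(1, 1))
  doubled <- cbind(y[, 1], 2L * y[, 1])
  f <- tmm_factors(doubled)
  expect_equal(f, c(1, 1), tolerance = 1e-9) # library-size offset absorbs x2
  ymix <- matrix(rnbinom(2000 * 4, mu = rep(exp(rnorm(2000, 4, 1)), 4), size = 5), 2000)
  f4 <- tmm_factors(ymix)
  expect_equal(exp(mean(log(f4))), 1, tolerance = 1e-12)
  ref <- edgeR::calcNormFactors(ymix, method = "TMM")
  expect_equal(f4, ref, tolerance = 0.03)
  expect_error(tmm_factors(cbind(y[, 1], 0L * y[, 1])), "zero")
})

test_that("identical groups give zero fold change and p near 1", {
  set.seed(82)
  a <- matrix(rnbinom(50 * 2, mu = 50, size = 10), 50)
  Y <- named_mat(cbind(a, a), 50) # group B duplicates group A
  r <- nb_test(Y, c("s1", "s2"), c("s3", "s4"))
  expect_equal(r$log2FC, rep(0, 50))
  expect_true(all(r$pvalue > 0.99))
  # all-zero rows are retained and flagged converged with p = 1
  Y0 <- named_mat(rbind(cbind(a, a), 0), 51)
  r0 <- nb_test(Y0, c("s1", "s2"), c("s3", "s4"))
  expect_equal(nrow(r0), 51)
  expect_equal(r0$pvalue[51], 1)
})

test_that("zero-dispersion limit reproduces the Poisson GLM likelihood-ratio test", {
  set.seed(83)
  G <- 40
  Y <- named_mat(rpois(G * 8, lambda = rep(exp(runif(G, 2, 5)), 8) *
                         rep(c(1, 1, 1, 1, 1.5, 1.5, 1.5, 1.5), each = G)), G)
  libs <- stats::setNames(rep(1e5, 8), colnames(Y))
  unit <- stats::setNames(rep(1, 8), colnames(Y))
  r <- nb_test(Y, paste0("s", 1:4), paste0("s", 5:8), lib_sizes = libs,
               norm_factors = unit, dispersion = 1e-12)
  grp <- factor(rep(c("A", "B"), each = 4))
  for (g in seq_len(G)) {
    fit1 <- stats::glm(Y[g, ] ~ grp, family = poisson())
    p_glm <- stats::pchisq(fit1$null.deviance - fit1$deviance, 1, lower.tail = FALSE)
    expect_equal(r$pvalue[g], p_glm, tolerance = 1e-6)
  }
  # direction also agrees with the exact conditional (binomial) test
  p_exact <- vapply(seq_len(G), function(g) {
    tot <- sum(Y[g, ])
    stats::binom.test(sum(Y[g, 5:8]), tot, 0.5)$p.value
  }, 0)
  expect_gt(cor(log10(pmax(r$pvalue, 1e-300)), log10(pmax(p_exact, 1e-300))), 0.99)
})

test_that("planted log2 fold change of 2 is recovered on average", {
  set.seed(84)
  G <- 500
  muA <- exp(runif(G, 3.5, 5))
  Y <- named_mat(cbind(matrix(rnbinom(G * 4, mu = muA, size = 10), G),
                       matrix(rnbinom(G * 4, mu = 4 * muA, size = 10), G)), G)
  libs <- stats::setNames(rep(sum(Y) / 8, 8), colnames(Y))
  unit <- stats::setNames(rep(1, 8), colnames(Y))
  r <- nb_test(Y, paste0("s", 1:4), paste0("s", 5:8),
               lib_sizes = libs, norm_factors = unit)
  expect_gt(mean(r$log2FC), 1.8)
  expect_lt(mean(r$log2FC), 2.2)
  expect_gt(mean(r$dispersion), 0.05)
  expect_lt(mean(r$dispersion), 0.2)
  # estimates correlate with an independent NB engine on the same data
  dge <- edgeR::DGEList(counts = Y, lib.size = libs, norm.factors = unit,
                        group = rep(c("A", "B"), each = 4))
  dge <- edgeR::estimateDisp(dge, model.matrix(~rep(c("A", "B"), each = 4)))
  fit <- edgeR::glmFit(dge, model.matrix(~rep(c("A", "B"), each = 4)))
  lrt <- edgeR::glmLRT(fit)
  expect_gt(cor(r$log2FC, lrt$table$logFC), 0.995)
})

test_that("labels are invariant to column order and per-sample scaling", {
  set.seed(85)
  G <- 300
  mu <- exp(runif(G, 3, 5))
  eff <- ifelse(seq_len(G) <= 60, 4, 1)
  Y <- named_mat(cbind(matrix(rnbinom(G * 4, mu = mu, size = 12), G),
                       matrix(rnbinom(G * 4, mu = mu * eff, size = 12), G)), G)
  libs <- stats::setNames(rep(1e5, 8), colnames(Y))
  unit <- stats::setNames(rep(1, 8), colnames(Y))
  r1 <- nb_test(Y, paste0("s", 1:4), paste0("s", 5:8),
                lib_sizes = libs, norm_factors = unit)
  # permute columns
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  r2 <- nb_test(Y[, perm], paste0("s", 1:4), paste0("s", 5:8),
                lib_sizes = libs[perm], norm_factors = unit)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-8)
  # triple one sample's counts and its offset: the offset absorbs the scale
  # (scaled counts are not exactly NB, so boundary loci may flip; the fold
  # changes and virtually all labels must be preserved)
  Y3 <- Y; Y3[, 2] <- 3L * Y[, 2]
  libs3 <- libs; libs3[2] <- 3 * libs[2]
  r3 <- nb_test(Y3, paste0("s", 1:4), paste0("s", 5:8),
                lib_sizes = libs3, norm_factors = unit)
  expect_equal(r1$log2FC, r3$log2FC, tolerance = 0.05)
  expect_gte(mean((r1$fdr <= 0.05) == (r3$fdr <= 0.05)), 0.99)
})

test_that("global-null false discovery stays controlled over seeds", {
  frac <- vapply(1:15, function(seed) {
    set.seed(900 + seed)
    G <- 500
    Y <- named_mat(rnbinom(G * 8, mu = 80, size = 1 / 0.08), G)
    libs <- stats::setNames(rep(1e5, 8), colnames(Y))
    unit <- stats::setNames(rep(1, 8), colnames(Y))
    r <- nb_test(Y, paste0("s", 1:4), paste0("s", 5:8),
                 lib_sizes = libs, norm_factors = unit)
    mean(r$fdr <= 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("response taxonomy follows the two-comparison threshold rule", {
  mk <- function(fdr) data.frame(locus = paste0("l", seq_along(fdr)), fdr = fdr)
  rs <- mk(c(0.04, 0.5, 0.01, 0.2))
  rc <- mk(c(0.2, 0.5, 0.03, 0.04))
  out <- classify_response(rs, rc)
  expect_equal(as.character(out$labels), c("STRESS", "NON_RES", "STRESS_and_CIRC", "CIRC"))
  expect_equal(out$constant, c(FALSE, TRUE, FALSE, FALSE))
  # reported constant share: 490 constant of 1753 loci -> 28% (rounded)
  rs2 <- mk(c(rep(0.5, 490), rep(0.001, 1263)))
  rc2 <- mk(c(rep(0.5, 490), rep(0.001, 1263)))
  out2 <- classify_response(rs2, rc2)
  expect_equal(out2$summary$n_constant, 490)
  expect_equal(round(out2$summary$pct_constant), 28)
  expect_error(classify_response(rs, mk(c(1, 1, 1))), "different loci")
})
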