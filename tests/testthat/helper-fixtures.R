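# Shared fixtures: a hand-built two-gene annotation and a scaled-down
# simulation configuration used by the faster module tests. The acceptance
# suite runs the generator at its default (study-condition) scale.

toy_annotation <- function() {
  # gene A (+): chr1 exons [1001,1200], [2001,2400]  -> intron [1201,2000]
  # gene B (-): chr1 exons [12001,12300], [14001,14500] -> intron [12301,14000]
  # gene C (+): chr2 single exon [5001,5600]
  ex <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1001, 2001, 12001, 14001, 5001),
                     c(1200, 2400, 12300, 14500, 5600)),
    strand = c("+", "+", "-", "-", "+"),
    gene_id = c("geneA", "geneA", "geneB", "geneB", "geneC"),
    transcript_id = c("geneA.t1", "geneA.t1", "geneB.t1", "geneB.t1", "geneC.t1"))
  genome_annotation(ex, c(chr1 = 50000L, chr2 = 20000L))
}

tiny_sim_config <- function(seed = 101, ...) {
  simulation_config(seed = seed, n_genes = 60L, chrom_length = 6e5, ...)
}

# cached small simulation shared across test files (built once per run)
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(tiny_sim_config())
    cache
  }
})

random_peak_list <- function(n_samples, n_loci, seed, chrom_len = 1e5) {
  set.seed(seed)
  centers <- sort(sample(seq(500, chrom_len - 500, by = 1000), n_loci))
  lapply(seq_len(n_samples), function(i) {
    keep <- runif(n_loci) < 0.7
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(centers[keep] - 150, centers[keep] + 150))
  })
}
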