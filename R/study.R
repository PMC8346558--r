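#' Reported summary counts of the hippocampal MR/GR study
#'
#' The peak, locus and gene counts reported by the rat hippocampus MR/GR
#' ChIP-seq + RNA-seq study whose analysis workflow this package
#' re-implements: mean significant peak numbers per condition, selective
#' peak counts, consensus locus and constant locus counts, and the
#' receptor-class gene counts from the binding-expression integration.
#' Used as inputs for printed-arithmetic consistency checks; the synthetic
#' generator's defaults mimic the proportions among them.
#'
#' @return data.frame with columns metric, key, value.
#' @export
study_summary <- function() {
  path <- system.file("extdata", "study_summary.tsv", package = "nr3cseq")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Derived quantities from the reported study counts
#'
#' Recomputes, from \link{study_summary}, the arithmetic the study reports
#' in its text: fold increases in mean peak numbers over the morning
#' baseline, constant-locus percentages of each receptor's consensus set,
#' and receptor-class percentages over the detected receptor-bound genes.
#'
#' @return Named list of numeric values (fold changes as plain ratios,
#'   percentages on the 0-100 scale).
#' @export
study_arithmetic <- function() {
  s <- study_summary()
  val <- function(metric, key) s$value[s$metric == metric & s$key == key]
  mp <- function(key) val("mean_peaks", key)
  class_n <- vapply(c("MR_only", "MR_and_GR", "GR_only"),
                    function(k) val("class_genes", k), 0)
  total_classified <- sum(class_n)
  list(
    mr_stress_fold = mp("MR_FS30") / mp("MR_BLAM"),
    mr_circadian_fold = mp("MR_BLPM") / mp("MR_BLAM"),
    gr_stress_fold = mp("GR_FS30") / mp("GR_BLAM"),
    gr_circadian_fold = mp("GR_BLPM") / mp("GR_BLAM"),
    mr_constant_pct = 100 * val("constant_loci", "MR") / val("consensus_loci", "MR"),
    gr_constant_pct = 100 * val("constant_loci", "GR") / val("consensus_loci", "GR"),
    mr_only_pct = 100 * class_n[["MR_only"]] / total_classified,
    mr_and_gr_pct = 100 * class_n[["MR_and_GR"]] / total_classified,
    gr_only_pct = 100 * class_n[["GR_only"]] / total_classified
  )
}
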