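#' Classify genes by receptor binding with per-sample exclusivity
#'
#' Genes associated with either receptor's consensus loci (and detected by
#' RNA) are labelled MR_only, MR_and_GR or GR_only from the consensus-level
#' annotation. Exclusivity additionally requires no opposite-receptor peak
#' within \code{max_distance} of the gene in ANY individual sample.
#'
#' @param mr_genes,gr_genes Character vectors of genes annotated to the MR /
#'   GR consensus loci.
#' @param mr_sample_peaks,gr_sample_peaks Named lists of per-sample peak
#'   \code{GRanges} (all replicates, all conditions).
#' @param detected_genes Genes detected by expression (see
#'   \link{filter_expressed}); classification is restricted to these.
#' @param annotation A \code{GenomeAnnotation}.
#' @param max_distance Gene-to-peak distance defining association (default
#'   5000 bp, edge-to-edge).
#' @return List with \code{classes} (data.frame gene_id, class, exclusive)
#'   and \code{summary} (per-class count and percentage over detected,
#'   receptor-bound genes; exclusive counts for the *_only classes).
#' @export
classify_receptor_binding <- function(mr_genes, gr_genes,
                                      mr_sample_peaks, gr_sample_peaks,
                                      detected_genes, annotation,
                                      max_distance = 5000L) {
  mr_genes <- intersect(unique(mr_genes), detected_genes)
  gr_genes <- intersect(unique(gr_genes), detected_genes)
  universe <- union(mr_genes, gr_genes)
  class <- ifelse(universe %in% mr_genes & universe %in% gr_genes, "MR_and_GR",
                  ifelse(universe %in% mr_genes, "MR_only", "GR_only"))
  stopifnot(!any(class == "MR_only" & universe %in% gr_genes))

  genes_near_any <- function(peak_list) {
    hit <- character()
    gr_gene <- annotation$gene_ranges
    expanded <- GenomicRanges::resize(
      gr_gene, GenomicRanges::width(gr_gene) + 2L * max_distance, fix = "center")
    for (p in peak_list) {
      if (length(p) == 0) next
      ov <- IRanges::overlapsAny(expanded, p, ignore.strand = TRUE)
      hit <- union(hit, S4Vectors::mcols(gr_gene)$gene_id[ov])
    }
    hit
  }
  gr_any <- genes_near_any(gr_sample_peaks)
  mr_any <- genes_near_any(mr_sample_peaks)
  exclusive <- rep(NA, length(universe))
  exclusive[class == "MR_only"] <- !(universe[class == "MR_only"] %in% gr_any)
  exclusive[class == "GR_only"] <- !(universe[class == "GR_only"] %in% mr_any)

  classes <- data.frame(gene_id = universe, class = class,
                        exclusive = exclusive, stringsAsFactors = FALSE)
  tab <- table(factor(class, levels = c("MR_only", "MR_and_GR", "GR_only")))
  summary <- data.frame(
    class = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / length(universe),
    n_exclusive = c(sum(exclusive[class == "MR_only"], na.rm = TRUE), NA,
                    sum(exclusive[class == "GR_only"], na.rm = TRUE)),
    stringsAsFactors = FALSE)
  list(classes = classes, summary = summary)
}

#' Correlate binding fold change with expression fold change
#'
#' Genes qualifying for the correlation must be significant in both the
#' binding and the expression comparison. When several loci annotate one
#' gene, the locus with the smallest binding FDR is used. Returns the
#' Spearman correlation over qualifying genes with per-gene direction
#' concordance.
#'
#' @param binding data.frame with columns gene_id, log2FC, fdr (one row per
#'   locus; from \link{nb_test} plus gene annotation).
#' @param expression data.frame with columns gene, log2FC, fdr (one row per
#'   gene; e.g. a merged stress table or one comparison).
#' @param binding_fdr,expr_fdr Significance thresholds (default 0.05 each).
#' @return List with \code{cor} (\link{spearman_cor} result), \code{pairs}
#'   (data.frame gene_id, binding_log2FC, expr_log2FC, direction in
#'   \{same, opposing\}).
#' @export
correlate_binding_expression <- function(binding, expression,
                                         binding_fdr = 0.05, expr_fdr = 0.05) {
  b <- binding[!is.na(binding$gene_id) & binding$fdr <= binding_fdr, , drop = FALSE]
  b <- b[order(b$gene_id, b$fdr), , drop = FALSE]
  b <- b[!duplicated(b$gene_id), , drop = FALSE]
  e <- expression[expression$fdr <= expr_fdr, , drop = FALSE]
  shared <- intersect(b$gene_id, e$gene)
  if (length(shared) < 3) {
    stop(sprintf("correlate_binding_expression: only %d qualifying genes (need >= 3)",
                 length(shared)))
  }
  bb <- b$log2FC[match(shared, b$gene_id)]
  ee <- e$log2FC[match(shared, e$gene)]
  pairs <- data.frame(gene_id = shared, binding_log2FC = bb, expr_log2FC = ee,
                      direction = ifelse(sign(bb) == sign(ee), "same", "opposing"),
                      stringsAsFactors = FALSE)
  list(cor = spearman_cor(bb, ee), pairs = pairs)
}

#' Export ranked gene lists for external pathway tools
#'
#' One list per (receptor, comparison) at the chosen FDR mode, with per-gene
#' maximum-|log2FC| binding (when several loci annotate a gene) ranked by
#' FDR, plus a pairwise Jaccard similarity report between the comparisons'
#' gene lists per receptor.
#'
#' @param binding_results data.frame with columns gene_id, receptor,
#'   comparison, log2FC, fdr (one row per locus).
#' @param fdr_mode FDR cutoff: 0.05, 0.1 or 1.0 (1.0 = all annotated genes).
#' @param out_dir Optional directory; when given, one TSV per list and a
#'   Jaccard TSV are written.
#' @return List with \code{lists} (named list of data.frames) and
#'   \code{jaccard} (data.frame receptor, comparison_a, comparison_b,
#'   jaccard_pct).
#' @export
export_pathway_inputs <- function(binding_results, fdr_mode = 0.1,
                                  out_dir = NULL) {
  br <- binding_results[!is.na(binding_results$gene_id), , drop = FALSE]
  lists <- list()
  for (rec in unique(br$receptor)) {
    for (cmp in unique(br$comparison[br$receptor == rec])) {
      sub <- br[br$receptor == rec & br$comparison == cmp &
                  br$fdr <= fdr_mode, , drop = FALSE]
      sub <- sub[order(sub$gene_id, -abs(sub$log2FC)), , drop = FALSE]
      sub <- sub[!duplicated(sub$gene_id), , drop = FALSE]
      sub <- sub[order(sub$fdr), c("gene_id", "receptor", "comparison",
                                   "log2FC", "fdr"), drop = FALSE]
      lists[[paste(rec, cmp, sep = ".")]] <- sub
    }
  }
  jac <- list()
  for (rec in unique(br$receptor)) {
    cmps <- unique(br$comparison[br$receptor == rec])
    if (length(cmps) >= 2) {
      for (i in seq_len(length(cmps) - 1)) {
        for (j in (i + 1):length(cmps)) {
          a <- lists[[paste(rec, cmps[i], sep = ".")]]$gene_id
          b <- lists[[paste(rec, cmps[j], sep = ".")]]$gene_id
          jac[[length(jac) + 1L]] <- data.frame(
            receptor = rec, comparison_a = cmps[i], comparison_b = cmps[j],
            jaccard_pct = 100 * jaccard_index(a, b), stringsAsFactors = FALSE)
        }
      }
    }
  }
  jac <- if (length(jac)) do.call(rbind, jac) else
    data.frame(receptor = character(), comparison_a = character(),
               comparison_b = character(), jaccard_pct = numeric())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(lists)) {
      utils::write.table(lists[[nm]],
                         file.path(out_dir, paste0("genes_", nm, "_fdr", fdr_mode, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(jac, file.path(out_dir, "jaccard_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(lists = lists, jaccard = jac)
}
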