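#' Count fragments on exonic and intronic features with fractional weights
#'
#' A fragment overlapping (>= 1 bp) k distinct (gene, feature-space) units
#' contributes 1/k to each, where the units are the per-gene merged exon set
#' and the per-gene intron set. So a fragment spanning an exon/intron
#' junction of one gene adds 0.5 to that gene in each table, and a fragment
#' over exons of two genes adds 0.5 exonic to each gene. Paired fragments
#' are assumed to arrive as single intervals and are counted once.
#'
#' @param fragments Named list of per-sample fragment \code{GRanges}.
#' @param annotation A \code{GenomeAnnotation}.
#' @return An \code{ExpressionCountTable} pair: list with \code{intronic}
#'   and \code{exonic} (genes x samples fractional count matrices over the
#'   shared gene universe), \code{lengths} (list with per-gene merged exon
#'   and total intron lengths), and \code{lib_sizes}.
#' @export
count_features <- function(fragments, annotation) {
  if (is.null(names(fragments))) stop("count_features: fragments must be a named list")
  genes <- annotation$genes$gene_id
  ex <- annotation$merged_exons
  intr <- annotation$introns
  ex_gene <- S4Vectors::mcols(ex)$gene_id
  in_gene <- if (length(intr)) S4Vectors::mcols(intr)$gene_id else character()
  count_one <- function(fr) {
    hits_ex <- GenomicRanges::findOverlaps(fr, ex, ignore.strand = TRUE)
    hits_in <- GenomicRanges::findOverlaps(fr, intr, ignore.strand = TRUE)
    frag <- c(S4Vectors::queryHits(hits_ex), S4Vectors::queryHits(hits_in))
    gene <- c(ex_gene[S4Vectors::subjectHits(hits_ex)],
              in_gene[S4Vectors::subjectHits(hits_in)])
    space <- rep(c("exonic", "intronic"),
                 c(length(hits_ex), length(hits_in)))
    if (length(frag) == 0) {
      return(list(exonic = numeric(length(genes)), intronic = numeric(length(genes))))
    }
    key <- paste(frag, gene, space)
    dup <- duplicated(key)
    frag <- frag[!dup]; gene <- gene[!dup]; space <- space[!dup]
    k <- tabulate(frag, nbins = length(fr))[frag]
    w <- 1 / k
    gi <- match(gene, genes)
    out <- list(exonic = numeric(length(genes)), intronic = numeric(length(genes)))
    for (sp in c("exonic", "intronic")) {
      sel <- space == sp
      if (any(sel)) {
        agg <- rowsum(w[sel], gi[sel])
        out[[sp]][as.integer(rownames(agg))] <- agg[, 1]
      }
    }
    out
  }
  per_sample <- lapply(fragments, count_one)
  exonic <- vapply(per_sample, `[[`, numeric(length(genes)), "exonic")
  intronic <- vapply(per_sample, `[[`, numeric(length(genes)), "intronic")
  rownames(exonic) <- rownames(intronic) <- genes
  ex_len <- tapply(GenomicRanges::width(ex), ex_gene, sum)
  intronic_len <- stats::setNames(numeric(length(genes)), genes)
  if (length(intr)) {
    in_len <- tapply(GenomicRanges::width(intr), in_gene, sum)
    hit <- !is.na(in_len[genes])
    intronic_len[hit] <- as.numeric(in_len[genes][hit])
  }
  lengths <- list(
    exonic = stats::setNames(as.numeric(ex_len[genes]), genes),
    intronic = intronic_len)
  structure(list(intronic = intronic, exonic = exonic, lengths = lengths,
                 lib_sizes = vapply(fragments, length, 0L)),
            class = "ExpressionCountTable")
}

#' Filter to expressed genes
#'
#' A gene is kept iff there exists at least one design group in which every
#' replicate has strictly more than \code{min_reads} counts.
#'
#' @param table Genes x samples count matrix.
#' @param groups Named character vector mapping sample (column) name to
#'   group.
#' @param min_reads Strict lower bound (default 10: "greater than 10").
#' @return The filtered matrix (possibly zero rows).
#' @export
filter_expressed <- function(table, groups, min_reads = 10) {
  groups <- groups[colnames(table)]
  if (anyNA(groups)) stop("filter_expressed: sample missing from design")
  keep <- rep(FALSE, nrow(table))
  for (g in unique(groups)) {
    sub <- table[, groups == g, drop = FALSE]
    keep <- keep | apply(sub > min_reads, 1, all)
  }
  table[keep, , drop = FALSE]
}

#' Differential expression across the stress time course and BLPM
#'
#' Each group is compared with the baseline by the NB likelihood-ratio test
#' (\link{nb_test}), separately per feature space, with BH correction within
#' each comparison x space. Genes significant in at least one comparison are
#' labelled RES, the rest CON. The merged stress table records, per gene,
#' the maximum-magnitude log2FC across the FS time points (sign retained),
#' the time point attaining it, and the FDR at that time point.
#'
#' @param tables List with filtered \code{intronic} and/or \code{exonic}
#'   count matrices (apply \link{filter_expressed} first).
#' @param groups Named character vector sample -> group.
#' @param baseline Baseline group name (default "BLAM").
#' @param stress_groups Groups forming the stress time course (default the
#'   FS* groups present).
#' @param fdr_threshold RES/CON threshold (default 0.05).
#' @param ... Passed to \link{nb_test} (e.g. \code{dispersion},
#'   \code{shrink_weight}).
#' @return List with \code{results} (long data.frame: space, comparison,
#'   gene, log2FC, pvalue, fdr), \code{categories} (per space: named RES/CON
#'   factor), \code{merged_stress} (per space: data.frame gene, log2FC,
#'   timepoint, fdr), and \code{res_counts} (RES genes per space).
#' @export
de_timecourse <- function(tables, groups, baseline = "BLAM",
                          stress_groups = NULL, fdr_threshold = 0.05, ...) {
  out_res <- list()
  categories <- list()
  merged <- list()
  for (space in names(tables)) {
    tab <- tables[[space]]
    gr <- groups[colnames(tab)]
    if (anyNA(gr)) stop("de_timecourse: sample missing from design")
    if (!baseline %in% gr) stop("de_timecourse: baseline group absent")
    others <- setdiff(unique(gr), baseline)
    sg <- if (is.null(stress_groups)) grep("^FS", others, value = TRUE) else stress_groups
    res_space <- lapply(others, function(g) {
      r <- nb_test(round(tab), groupA = colnames(tab)[gr == baseline],
                   groupB = colnames(tab)[gr == g], ...)
      data.frame(space = space, comparison = paste0(g, "_vs_", baseline),
                 group = g, gene = r$locus, log2FC = r$log2FC,
                 pvalue = r$pvalue, fdr = r$fdr, stringsAsFactors = FALSE)
    })
    res_space <- do.call(rbind, res_space)
    out_res[[space]] <- res_space
    sig <- tapply(res_space$fdr <= fdr_threshold, res_space$gene, any)
    categories[[space]] <- factor(ifelse(sig[rownames(tab)], "RES", "CON"),
                                  levels = c("RES", "CON"))
    names(categories[[space]]) <- rownames(tab)
    fs <- res_space[res_space$group %in% sg, , drop = FALSE]
    if (nrow(fs)) {
      ord <- order(fs$gene, -abs(fs$log2FC))
      fs <- fs[ord, ]
      top <- fs[!duplicated(fs$gene), ]
      merged[[space]] <- data.frame(gene = top$gene, log2FC = top$log2FC,
                                    timepoint = top$group, fdr = top$fdr,
                                    stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, c(out_res, list(make.row.names = FALSE))),
       categories = categories,
       merged_stress = merged,
       res_counts = vapply(categories, function(x) sum(x == "RES", na.rm = TRUE), 0L))
}

#' Transcripts-per-million normalization and baseline ratios
#'
#' \eqn{TPM_g = 10^6 (c_g / L_g) / \sum_h (c_h / L_h)} per sample; the ratio
#' output divides each group's mean TPM by the baseline group's mean TPM.
#'
#' @param table Genes x samples counts.
#' @param lengths Per-gene feature length in bp (> 0; genes with zero-length
#'   features are dropped with a warning).
#' @param groups Optional named sample -> group vector for the ratio output.
#' @param baseline Baseline group (default "BLAM").
#' @return List with \code{tpm} (matrix, columns sum to 1e6) and, when
#'   groups are given, \code{ratio} (genes x groups matrix of mean-TPM
#'   ratios vs baseline).
#' @export
tpm <- function(table, lengths, groups = NULL, baseline = "BLAM") {
  lengths <- lengths[rownames(table)]
  if (any(lengths <= 0 | is.na(lengths))) {
    warning("tpm: dropping genes with zero-length features")
    keep <- !is.na(lengths) & lengths > 0
    table <- table[keep, , drop = FALSE]
    lengths <- lengths[keep]
  }
  rate <- table / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("tpm: zero total rate in a sample")
  tpm_mat <- sweep(rate, 2, tot, "/") * 1e6
  out <- list(tpm = tpm_mat)
  if (!is.null(groups)) {
    groups <- groups[colnames(table)]
    gm <- vapply(unique(groups), function(g) {
      rowMeans(tpm_mat[, groups == g, drop = FALSE])
    }, numeric(nrow(tpm_mat)))
    if (!baseline %in% colnames(gm)) stop("tpm: baseline group absent")
    out$ratio <- gm / gm[, baseline]
  }
  out
}

#' PCA of the most variable genes
#'
#' Counts are log2(x + 1)-transformed, genes ranked by variance, the top
#' \code{n_top} retained and row-centered, and the samples projected on the
#' principal axes of the centered matrix.
#'
#' @param table Genes x samples counts.
#' @param n_top Number of most-variable genes (default 1000; capped at the
#'   gene count with a warning).
#' @return List with \code{scores} (samples x PCs), \code{variance_explained}
#'   (percentages, non-increasing), \code{genes} (the genes used).
#' @export
top_variable_projection <- function(table, n_top = 1000) {
  if (ncol(table) < 3) stop("top_variable_projection: need >= 3 samples")
  lg <- log2(table + 1)
  v <- apply(lg, 1, stats::var)
  if (n_top > nrow(lg)) {
    warning("top_variable_projection: n_top exceeds gene count, using all")
    n_top <- nrow(lg)
  }
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  x <- lg[top, , drop = FALSE]
  x <- x - rowMeans(x)
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, genes = rownames(table)[top])
}

#' Export matrix for top differentially expressed genes (heat-map input)
#'
#' Union of the top \code{k} genes per comparison by FDR, with centered
#' log2(count + 1) values.
#'
#' @param de Result of \link{de_timecourse}.
#' @param table The count matrix of the chosen feature space.
#' @param space Feature space name in \code{de$results} (default
#'   "intronic").
#' @param comparisons Comparison groups to draw from (default all).
#' @param k Top genes per comparison (default 50).
#' @return Centered log-scale matrix (genes x samples).
#' @export
top_de_matrix <- function(de, table, space = "intronic", comparisons = NULL, k = 50) {
  res <- de$results[de$results$space == space, ]
  if (!is.null(comparisons)) res <- res[res$group %in% comparisons, ]
  picks <- unlist(lapply(split(res, res$group), function(df) {
    df$gene[order(df$fdr)][seq_len(min(k, nrow(df)))]
  }), use.names = FALSE)
  genes <- intersect(unique(picks), rownames(table))
  x <- log2(table[genes, , drop = FALSE] + 1)
  x - rowMeans(x)
}
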