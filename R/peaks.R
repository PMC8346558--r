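#' Call enriched regions from fragment coverage against an input control
#'
#' A window-based caller in the spirit of local-lambda Poisson peak callers:
#' the genome is tiled into fixed windows, fragment midpoints are counted,
#' and each window's treatment count is tested against an upper-tail Poisson
#' null with
#' \eqn{\lambda_{local} = r \cdot \max(c_{win}, \bar c_{\pm 5 win}, \bar c_{genome})}
#' where the input-side quantities are scaled by the treatment/input depth
#' ratio \eqn{r}. Window p-values are BH-corrected genome-wide and
#' significant adjacent windows are merged into peaks. This is a deliberately
#' transparent stand-in for a full fragment-shift model caller; externally
#' produced narrowPeak files can be substituted anywhere peaks are consumed
#' (see \link{read_narrowpeak}).
#'
#' @param treatment,input \code{GRanges} of sequenced fragments (not reads).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param window_size Window width in bp (default 200).
#' @param fdr_threshold Report windows/peaks with BH FDR at or below this
#'   (default 0.05).
#' @param local_halfwidth Number of flanking windows on each side entering
#'   the regional background average (default 5).
#' @return \code{GRanges} of peaks with metadata columns
#'   \code{fragment_count}, \code{local_lambda}, \code{pvalue}, \code{fdr}
#'   (per-peak minimum window p/fdr, summed counts/lambda).
#' @export
call_peaks <- function(treatment, input, chrom_sizes, window_size = 200L,
                       fdr_threshold = 0.05, local_halfwidth = 5L) {
  if (length(treatment) == 0) stop("call_peaks: empty treatment fragment set")
  if (window_size <= 0) stop("call_peaks: window_size must be positive")
  tiles <- .genome_windows(chrom_sizes, window_size)
  tc <- .window_counts(treatment, chrom_sizes, window_size, tiles)
  n_input <- length(input)
  if (n_input == 0) {
    warning("call_peaks: zero input depth, using genome-wide treatment rate")
    lambda <- rep(length(treatment) / length(tiles$chrom), length(tiles$chrom))
  } else {
    ic <- .window_counts(input, chrom_sizes, window_size, tiles)
    ratio <- length(treatment) / n_input
    regional <- .running_mean_by_chrom(ic, tiles$chrom_index, local_halfwidth)
    genome_rate <- n_input / length(tiles$chrom)
    lambda <- ratio * pmax(ic, regional, genome_rate)
  }
  pvals <- stats::ppois(tc - 1, lambda, lower.tail = FALSE)
  fdr <- bh_adjust(pvals)$adjusted
  sig <- which(fdr <= fdr_threshold & tc > 0)
  if (length(sig) == 0) {
    return(GenomicRanges::GRanges(fragment_count = integer(), local_lambda = numeric(),
                                  pvalue = numeric(), fdr = numeric()))
  }
  # merge runs of adjacent significant windows on the same chromosome
  brk <- c(TRUE, diff(sig) != 1L | diff(tiles$chrom_index[sig]) != 0L)
  run <- cumsum(brk)
  first <- sig[!duplicated(run)]
  last <- sig[!duplicated(run, fromLast = TRUE)]
  gr <- GenomicRanges::GRanges(
    tiles$chrom[first],
    IRanges::IRanges(tiles$start[first], tiles$end[last]))
  S4Vectors::mcols(gr)$fragment_count <-
    as.integer(rowsum(tc[sig], run)[, 1])
  S4Vectors::mcols(gr)$local_lambda <- rowsum(lambda[sig], run)[, 1]
  S4Vectors::mcols(gr)$pvalue <- unname(vapply(split(pvals[sig], run), min, 0))
  S4Vectors::mcols(gr)$fdr <- unname(vapply(split(fdr[sig], run), min, 0))
  gr
}

# shared window bookkeeping: global window index space over all chromosomes
.genome_windows <- function(chrom_sizes, window_size) {
  n_win <- pmax(1L, as.integer(ceiling(chrom_sizes / window_size)))
  chrom <- rep(names(chrom_sizes), n_win)
  within <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  start <- (within - 1L) * window_size + 1L
  end <- pmin(within * window_size, rep(unname(chrom_sizes), n_win))
  list(chrom = chrom, start = start, end = end,
       chrom_index = rep(seq_along(chrom_sizes), n_win),
       offset = stats::setNames(cumsum(c(0L, n_win[-length(n_win)])),
                                names(chrom_sizes)),
       n_win = n_win)
}

.window_counts <- function(fragments, chrom_sizes, window_size, tiles) {
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  if (!all(chrom %in% names(chrom_sizes))) {
    stop("fragments on unknown chromosome")
  }
  mid <- floor((GenomicRanges::start(fragments) + GenomicRanges::end(fragments)) / 2)
  widx <- tiles$offset[chrom] + pmin((mid - 1L) %/% window_size + 1L,
                                     tiles$n_win[match(chrom, names(chrom_sizes))])
  tabulate(widx, nbins = length(tiles$chrom))
}

.running_mean_by_chrom <- function(x, chrom_index, halfwidth) {
  w <- 2L * halfwidth + 1L
  out <- numeric(length(x))
  for (ci in unique(chrom_index)) {
    idx <- which(chrom_index == ci)
    v <- x[idx]
    cs <- cumsum(c(0, v))
    n <- length(v)
    lo <- pmax(seq_len(n) - halfwidth, 1L)
    hi <- pmin(seq_len(n) + halfwidth, n)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Build a consensus peak set across samples
#'
#' All peaks from all samples are merged (overlapping and bookended
#' intervals coalesce); a merged locus is kept when at least
#' \code{min_support} samples have a peak intersecting it by >= 1 bp.
#'
#' @param peak_list Named list of per-sample peak \code{GRanges}.
#' @param min_support Minimum number of supporting samples (default 4).
#' @return A \code{ConsensusPeakSet}: list with \code{loci} (merged, sorted,
#'   non-overlapping \code{GRanges}), \code{occupancy} (loci x samples 0/1
#'   matrix) and \code{support} (per-locus sample count).
#' @export
build_consensus <- function(peak_list, min_support = 4L) {
  if (length(peak_list) < min_support) {
    stop("build_consensus: fewer samples than min_support")
  }
  if (is.null(names(peak_list))) names(peak_list) <- paste0("sample_", seq_along(peak_list))
  all_peaks <- suppressWarnings(do.call(
    c, lapply(unname(peak_list), GenomicRanges::granges)))
  loci <- GenomicRanges::reduce(GenomicRanges::sort(all_peaks))
  occupancy <- vapply(peak_list, function(p) {
    as.integer(IRanges::overlapsAny(loci, p, ignore.strand = TRUE))
  }, integer(length(loci)))
  if (length(loci) == 1L) occupancy <- matrix(occupancy, nrow = 1,
                                              dimnames = list(NULL, names(peak_list)))
  support <- rowSums(occupancy)
  keep <- support >= min_support
  structure(list(loci = loci[keep],
                 occupancy = occupancy[keep, , drop = FALSE],
                 support = support[keep]),
            class = "ConsensusPeakSet")
}

#' @export
print.ConsensusPeakSet <- function(x, ...) {
  cat(sprintf("ConsensusPeakSet: %d loci x %d samples (median support %d)\n",
              length(x$loci), ncol(x$occupancy), as.integer(stats::median(x$support))))
  invisible(x)
}

#' Classify receptor selectivity by replicate concordance within a condition
#'
#' Over the universe of merged loci from both receptors' peaks in one
#' condition: a locus is \code{selective_MR} when present in all 4 MR
#' replicates and 0 GR replicates, \code{selective_GR} symmetrically,
#' \code{overlapping} when present in all 4 replicates of both receptors,
#' and \code{unclassified} otherwise. A Fisher's exact test (upper tail) of
#' full-concordance MR-membership x GR-membership over the locus universe
#' accompanies the Venn counts.
#'
#' @param mr_peaks,gr_peaks Lists of exactly 4 per-replicate peak
#'   \code{GRanges}.
#' @param condition Condition label carried into the output.
#' @return A \code{ConcordanceClass}: list with \code{loci}, \code{labels},
#'   \code{occupancy} (loci x 8 samples), \code{venn} (named counts),
#'   \code{fisher_p}, \code{condition}.
#' @export
classify_concordance <- function(mr_peaks, gr_peaks, condition = "condition") {
  if (length(mr_peaks) != 4L || length(gr_peaks) != 4L) {
    stop("classify_concordance: the concordance rule is defined for 4 replicates per receptor")
  }
  names(mr_peaks) <- paste0("MR_rep", 1:4)
  names(gr_peaks) <- paste0("GR_rep", 1:4)
  peaks <- c(mr_peaks, gr_peaks)
  all_peaks <- suppressWarnings(do.call(c, lapply(unname(peaks), GenomicRanges::granges)))
  loci <- GenomicRanges::reduce(GenomicRanges::sort(all_peaks))
  occupancy <- vapply(peaks, function(p) {
    as.integer(IRanges::overlapsAny(loci, p, ignore.strand = TRUE))
  }, integer(length(loci)))
  if (length(loci) == 1L) occupancy <- matrix(occupancy, nrow = 1,
                                              dimnames = list(NULL, names(peaks)))
  mr_n <- rowSums(occupancy[, 1:4, drop = FALSE])
  gr_n <- rowSums(occupancy[, 5:8, drop = FALSE])
  labels <- rep("unclassified", length(loci))
  labels[mr_n == 4L & gr_n == 0L] <- "selective_MR"
  labels[gr_n == 4L & mr_n == 0L] <- "selective_GR"
  labels[mr_n == 4L & gr_n == 4L] <- "overlapping"
  venn <- c(selective_MR = sum(labels == "selective_MR"),
            selective_GR = sum(labels == "selective_GR"),
            overlapping = sum(labels == "overlapping"),
            unclassified = sum(labels == "unclassified"))
  mr_full <- mr_n == 4L
  gr_full <- gr_n == 4L
  ft <- fisher_exact(sum(mr_full & gr_full), sum(mr_full & !gr_full),
                     sum(!mr_full & gr_full), sum(!mr_full & !gr_full),
                     alternative = "greater")
  structure(list(loci = loci, labels = labels, occupancy = occupancy,
                 venn = venn, fisher_p = ft$p, condition = condition),
            class = "ConcordanceClass")
}

#' @export
print.ConcordanceClass <- function(x, ...) {
  cat(sprintf("ConcordanceClass [%s]: %d selective MR, %d selective GR, %d overlapping (Fisher p = %.3g)\n",
              x$condition, x$venn["selective_MR"], x$venn["selective_GR"],
              x$venn["overlapping"], x$fisher_p))
  invisible(x)
}

#' Genomic feature distribution of peaks, per sample and per condition
#'
#' @param peaks_by_sample Named list of per-sample peak \code{GRanges}.
#' @param annotation A \code{GenomeAnnotation}.
#' @param conditions Named character vector mapping sample name to condition
#'   (optional; when given, condition means and SEM over replicates are
#'   added).
#' @return List with \code{per_sample} (samples x classes percentage matrix,
#'   rows sum to 100) and \code{summary} (data.frame condition, class, mean,
#'   sem) when conditions are supplied.
#' @export
genomic_distribution <- function(peaks_by_sample, annotation, conditions = NULL) {
  lv <- c("promoter", "five_prime_utr", "three_prime_utr", "exon", "intron",
          "downstream", "distal_intergenic")
  pct <- t(vapply(peaks_by_sample, function(p) {
    if (length(p) == 0) return(stats::setNames(rep(NA_real_, length(lv)), lv))
    100 * as.vector(prop.table(table(classify_feature(p, annotation))))
  }, stats::setNames(numeric(length(lv)), lv)))
  out <- list(per_sample = pct)
  if (!is.null(conditions)) {
    cond <- conditions[rownames(pct)]
    rows <- list()
    for (cc in unique(cond)) {
      sub <- pct[cond == cc, , drop = FALSE]
      rows[[cc]] <- data.frame(
        condition = cc, class = colnames(pct),
        mean = colMeans(sub, na.rm = TRUE),
        sem = apply(sub, 2, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
        stringsAsFactors = FALSE)
    }
    out$summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' Read an ENCODE narrowPeak (BED6+4) file
#' @param path File path.
#' @return \code{GRanges} with signalValue, pValue, qValue, peak columns.
#' @export
read_narrowpeak <- function(path) {
  cols <- c(signalValue = "numeric", pValue = "numeric",
            qValue = "numeric", peak = "integer")
  rtracklayer::import(path, format = "BED", extraCols = cols)
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks \code{GRanges} from \link{call_peaks}.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = sprintf("peak_%d", seq_along(peaks)),
    score = pmin(1000L, as.integer(round(-10 * log10(
      pmax(S4Vectors::mcols(peaks)$pvalue, 1e-100))))),
    strand = ".",
    signalValue = S4Vectors::mcols(peaks)$fragment_count,
    pValue = -log10(pmax(S4Vectors::mcols(peaks)$pvalue, 1e-300)),
    qValue = -log10(pmax(S4Vectors::mcols(peaks)$fdr, 1e-300)),
    peak = -1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a consensus occupancy matrix as TSV (locus coordinates in columns 1-3)
#' @param consensus A \code{ConsensusPeakSet}.
#' @param path Output path.
#' @export
write_occupancy <- function(consensus, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(consensus$loci)),
    start = GenomicRanges::start(consensus$loci) - 1L,
    end = GenomicRanges::end(consensus$loci),
    consensus$occupancy, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consensus occupancy matrix written by \link{write_occupancy}
#' @param path TSV path.
#' @return A \code{ConsensusPeakSet} (support recomputed from occupancy).
#' @export
read_occupancy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  loci <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  occ <- as.matrix(df[, -(1:3), drop = FALSE])
  structure(list(loci = loci, occupancy = occ, support = rowSums(occ)),
            class = "ConsensusPeakSet")
}
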