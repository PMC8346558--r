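#' Construct a genomic interval from 0-based half-open coordinates
#'
#' Convenience constructor mirroring the BED convention (0-based start,
#' exclusive end). Internally all interval arithmetic uses
#' \link[GenomicRanges]{GRanges} (1-based closed, the Bioconductor
#' convention); this helper performs the conversion once at the boundary.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open coordinates, \code{start < end}.
#' @param strand "+", "-" or "*" (unstranded).
#' @return A \code{GRanges} object.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (any(start >= end)) stop("genomic_interval: start must be < end")
  if (any(start < 0)) stop("genomic_interval: negative start")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

#' Build a genome annotation object
#'
#' Assembles gene models from exon records and derives the feature sets used
#' downstream: per-gene merged exons, per-gene introns (transcript span minus
#' the union of all annotated exons of the gene), promoters (a window around
#' the strand-aware TSS) and strand-aware downstream windows.
#'
#' @param exons \code{GRanges} of exon records with metadata columns
#'   \code{gene_id} and \code{transcript_id}, exons of one transcript
#'   non-overlapping.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param promoter_upstream,promoter_downstream Promoter window half-widths
#'   around the TSS in bp (defaults 3000/3000, a common annotation-tool
#'   default; configurable because published analyses rarely state theirs).
#' @param downstream_window Width of the "downstream" class window past the
#'   strand-aware 3' end of a gene (default 3000 bp).
#' @return An object of class \code{GenomeAnnotation}: a list with elements
#'   \code{genes} (data.frame: gene_id, chrom, start, end, strand, tss),
#'   \code{gene_ranges}, \code{exons}, \code{transcripts},
#'   \code{merged_exons}, \code{introns} (gene-level),
#'   \code{transcript_introns}, \code{promoters}, \code{downstream} (all
#'   \code{GRanges}) and \code{chrom_sizes}.
#' @export
genome_annotation <- function(exons, chrom_sizes,
                              promoter_upstream = 3000L,
                              promoter_downstream = 3000L,
                              downstream_window = 3000L) {
  mc <- S4Vectors::mcols(exons)
  if (!all(c("gene_id", "transcript_id") %in% colnames(mc))) {
    stop("genome_annotation: exons need gene_id and transcript_id metadata")
  }
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  gene_id <- as.character(S4Vectors::mcols(exons)$gene_id)
  tx_id <- as.character(S4Vectors::mcols(exons)$transcript_id)

  # transcript spans
  ex_by_tx <- GenomicRanges::split(exons, tx_id)
  tx <- unlist(range(ex_by_tx))
  tx_gene <- gene_id[match(names(tx), tx_id)]
  S4Vectors::mcols(tx)$transcript_id <- names(tx)
  S4Vectors::mcols(tx)$gene_id <- tx_gene

  # gene spans and TSS
  ex_by_gene <- GenomicRanges::split(exons, gene_id)
  gr_gene <- unlist(range(ex_by_gene))
  S4Vectors::mcols(gr_gene)$gene_id <- names(gr_gene)
  neg <- as.logical(GenomicRanges::strand(gr_gene) == "-")
  tss <- ifelse(neg, GenomicRanges::end(gr_gene), GenomicRanges::start(gr_gene))
  genes <- data.frame(
    gene_id = names(gr_gene),
    chrom = as.character(GenomicRanges::seqnames(gr_gene)),
    start = GenomicRanges::start(gr_gene),
    end = GenomicRanges::end(gr_gene),
    strand = as.character(GenomicRanges::strand(gr_gene)),
    tss = tss,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- genes$gene_id

  merged <- unlist(GenomicRanges::reduce(ex_by_gene))
  S4Vectors::mcols(merged)$gene_id <- names(merged)

  ann <- structure(
    list(genes = genes, gene_ranges = gr_gene, exons = exons,
         transcripts = tx, merged_exons = merged,
         chrom_sizes = chrom_sizes,
         promoter_upstream = promoter_upstream,
         promoter_downstream = promoter_downstream,
         downstream_window = downstream_window),
    class = "GenomeAnnotation"
  )
  intr <- derive_introns(ann)
  ann$transcript_introns <- intr
  gi <- GenomicRanges::reduce(GenomicRanges::split(intr, S4Vectors::mcols(intr)$gene_id))
  gi <- unlist(gi)
  if (length(gi)) S4Vectors::mcols(gi)$gene_id <- names(gi)
  ann$introns <- gi

  # promoters: [tss - upstream, tss + downstream] on the strand-aware axis
  pstart <- ifelse(neg, tss - promoter_downstream, tss - promoter_upstream)
  pend <- ifelse(neg, tss + promoter_upstream, tss + promoter_downstream)
  lens <- chrom_sizes[genes$chrom]
  ann$promoters <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(1, pstart), pmin(lens, pend)),
    strand = genes$strand, gene_id = genes$gene_id
  )
  # downstream window past the 3' end
  tes <- ifelse(neg, genes$start, genes$end)
  dstart <- ifelse(neg, tes - downstream_window, tes + 1)
  dend <- ifelse(neg, tes - 1, tes + downstream_window)
  ok <- dstart <= dend
  ann$downstream <- GenomicRanges::GRanges(
    genes$chrom[ok], IRanges::IRanges(pmax(1, dstart[ok]), pmin(lens[ok], dend[ok])),
    strand = genes$strand[ok], gene_id = genes$gene_id[ok]
  )
  .validate_annotation(ann)
  ann
}

.validate_annotation <- function(ann) {
  lens <- ann$chrom_sizes[ann$genes$chrom]
  if (anyNA(lens)) stop("genome_annotation: gene on unknown chromosome")
  if (any(ann$genes$end > lens)) stop("genome_annotation: gene beyond chromosome end")
  invisible(TRUE)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes, %d transcripts, %d exons, %d chromosomes\n",
              nrow(x$genes), length(x$transcripts), length(x$exons),
              length(x$chrom_sizes)))
  invisible(x)
}

#' Derive intron features by subtracting exons from transcript spans
#'
#' For each transcript, introns are the transcript span minus the union of
#' ALL annotated exons of the parent gene (from any transcript), so an exon
#' of one isoform punches a hole in another isoform's intron. Single-exon
#' transcripts yield no introns.
#'
#' @param annotation A \code{GenomeAnnotation}.
#' @return \code{GRanges} of intron intervals with \code{gene_id} and
#'   \code{transcript_id} metadata.
#' @export
derive_introns <- function(annotation) {
  tx <- annotation$transcripts
  exons <- annotation$exons
  gene_of_tx <- S4Vectors::mcols(tx)$gene_id
  ex_gene <- as.character(S4Vectors::mcols(exons)$gene_id)
  ex_tx <- as.character(S4Vectors::mcols(exons)$transcript_id)
  # validation: every exon inside its transcript span
  span_idx <- match(ex_tx, S4Vectors::mcols(tx)$transcript_id)
  bad <- GenomicRanges::start(exons) < GenomicRanges::start(tx)[span_idx] |
    GenomicRanges::end(exons) > GenomicRanges::end(tx)[span_idx]
  if (any(bad)) {
    stop(sprintf("derive_introns: exon outside transcript span for transcript %s",
                 ex_tx[which(bad)[1]]))
  }
  ex_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(GenomicRanges::granges(exons), ex_gene))
  holes <- ex_by_gene[match(gene_of_tx, names(ex_by_gene))]
  intr <- GenomicRanges::psetdiff(
    GenomicRanges::granges(tx),
    methods::as(holes, "GRangesList"))
  n_per_tx <- lengths(intr)
  out <- unlist(intr, use.names = FALSE)
  S4Vectors::mcols(out)$gene_id <- rep(gene_of_tx, n_per_tx)
  S4Vectors::mcols(out)$transcript_id <-
    rep(S4Vectors::mcols(tx)$transcript_id, n_per_tx)
  out
}

#' Annotate intervals to their nearest gene within a distance cutoff
#'
#' Distance is 0 when the interval overlaps the gene span, otherwise the
#' edge-to-edge gap to the nearest span edge. Intervals farther than
#' \code{max_distance} from every gene are unannotated. The returned distance
#' is signed: negative when the interval lies on the lower-coordinate side of
#' the gene, positive on the higher-coordinate side. Ties are broken by
#' smaller distance then lexicographically smaller gene_id.
#'
#' @param peaks \code{GRanges} of query intervals.
#' @param annotation A \code{GenomeAnnotation}.
#' @param max_distance Maximum edge-to-edge gap in bp (default 5000).
#' @return data.frame with columns \code{gene_id} (NA when unannotated) and
#'   \code{distance}.
#' @export
annotate_nearest_gene <- function(peaks, annotation, max_distance = 5000L) {
  if (!all(as.character(GenomicRanges::seqnames(peaks)) %in%
           names(annotation$chrom_sizes))) {
    stop("annotate_nearest_gene: unknown chromosome in peaks")
  }
  genes <- annotation$gene_ranges
  ord <- order(S4Vectors::mcols(genes)$gene_id)
  genes <- genes[ord] # lexicographic tie-break: nearest() keeps first hit
  hits <- GenomicRanges::distanceToNearest(peaks, genes, ignore.strand = TRUE,
                                           select = "all")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dd <- S4Vectors::mcols(hits)$distance
  # keep, per query, the smallest distance then smallest gene_id (subject order)
  o <- order(qh, dd, sh)
  first <- !duplicated(qh[o])
  qh <- qh[o][first]; sh <- sh[o][first]; dd <- dd[o][first]
  gene_id <- rep(NA_character_, length(peaks))
  distance <- rep(NA_real_, length(peaks))
  keep <- dd <= max_distance
  gid <- S4Vectors::mcols(genes)$gene_id[sh[keep]]
  gene_id[qh[keep]] <- gid
  sgn <- ifelse(GenomicRanges::end(peaks[qh[keep]]) <
                  GenomicRanges::start(genes[sh[keep]]), -1, 1)
  distance[qh[keep]] <- sgn * dd[keep]
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Classify intervals into genomic feature classes by midpoint
#'
#' The class of an interval is the class of its midpoint under the priority
#' promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal_intergenic,
#' so every interval receives exactly one class and class percentages over a
#' peak set sum to 100. UTR classes require UTR records in the annotation
#' (absent from minimal gene models, in which case those classes are empty).
#'
#' @param peaks \code{GRanges}.
#' @param annotation A \code{GenomeAnnotation}.
#' @return Factor of classes with levels promoter, five_prime_utr,
#'   three_prime_utr, exon, intron, downstream, distal_intergenic.
#' @export
classify_feature <- function(peaks, annotation) {
  lv <- c("promoter", "five_prime_utr", "three_prime_utr", "exon", "intron",
          "downstream", "distal_intergenic")
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  midp <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                 IRanges::IRanges(mid, mid))
  cls <- rep("distal_intergenic", length(peaks))
  layer <- function(feature) {
    if (is.null(feature) || length(feature) == 0) return(logical(length(peaks)))
    IRanges::overlapsAny(midp, feature, ignore.strand = TRUE)
  }
  # applied lowest priority first so higher-priority layers overwrite
  order_low_to_high <- list(
    c("downstream", "downstream"),
    c("introns", "intron"),
    c("merged_exons", "exon"),
    c("utr3", "three_prime_utr"),
    c("utr5", "five_prime_utr"),
    c("promoters", "promoter")
  )
  for (nm in order_low_to_high) {
    hit <- layer(annotation[[nm[1]]])
    cls[hit] <- nm[2]
  }
  factor(cls, levels = lv)
}

#' Read a GTF file into a GenomeAnnotation
#'
#' Imports exon records (attribute keys \code{gene_id}, \code{transcript_id})
#' with \link[rtracklayer]{import}; GTF 1-based closed coordinates are the
#' internal convention so no shifting is needed.
#'
#' @param path GTF file path.
#' @param chrom_sizes Named integer vector, or path to a two-column
#'   chrom.sizes text file.
#' @param ... Passed to \link{genome_annotation}.
#' @return A \code{GenomeAnnotation}.
#' @export
read_annotation_gtf <- function(path, chrom_sizes, ...) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  genome_annotation(ex, chrom_sizes, ...)
}

#' Read a two-column chrom.sizes file
#' @param path Path to whitespace-separated chromosome/length text.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Write intervals to a BED file (0-based half-open on disk)
#' @param gr \code{GRanges}, optionally with \code{name} and \code{score} columns.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into GRanges (converted to 1-based closed in memory)
#' @param path BED3/BED6 file path.
#' @return \code{GRanges}.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a GenomeAnnotation's gene models to GTF
#' @param annotation A \code{GenomeAnnotation}.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ex <- annotation$exons
  S4Vectors::mcols(ex)$type <- "exon"
  S4Vectors::mcols(ex)$source <- "nr3cseq"
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}
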