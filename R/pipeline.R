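#' Pipeline configuration
#'
#' Collects the analysis thresholds with their defaults: peak FDR 0.05,
#' differential FDR 0.05 (0.1 for the pathway-export mode), motif p-value
#' 1e-4, consensus support 4 of 12, expression filter > 10 reads in every
#' replicate of some group, nearest-gene distance 5 kb.
#'
#' @param seed Integer seed used by any stochastic stage.
#' @param ... Named overrides of the defaults below.
#' @return A \code{PipelineConfig} list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    peak_fdr = 0.05,
    diff_fdr = 0.05,
    pathway_fdr = 0.1,
    motif_p = 1e-4,
    min_support = 4L,
    min_reads = 10,
    nearest_gene_bp = 5000L,
    window_size = 200L,
    shrink_weight = 10
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("pipeline_config: unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  stopifnot(cfg$peak_fdr > 0, cfg$peak_fdr <= 1, cfg$diff_fdr > 0,
            cfg$diff_fdr <= 1, cfg$motif_p > 0, cfg$min_support >= 1)
  structure(cfg, class = "PipelineConfig")
}

#' Built-in synthetic motif library
#'
#' A small JASPAR-format library of synthetic position frequency matrices
#' constructed for this package (GRE, RFX, KLF, SP, ZNF, EGR, NR, STAT
#' family representatives); the GRE and RFX consensus sequences match the
#' motifs the simulator plants. This is not a copy of any external motif
#' database.
#'
#' @param pseudocount Passed to \link{read_jaspar}.
#' @return List of \code{PWM} objects.
#' @export
default_motif_library <- function(pseudocount = 1) {
  path <- system.file("extdata", "motifs_synthetic.jaspar", package = "nr3cseq")
  read_jaspar(path, pseudocount = pseudocount)
}

#' Run the full analysis on a simulated (or equivalently structured) experiment
#'
#' Executes, in dependency order: per-sample peak calling against pooled
#' input, per-receptor consensus construction (support >= 4 of 12),
#' per-condition selectivity/concordance classification, genomic feature
#' distribution, NB differential binding (FS30 vs BLAM and BLPM vs BLAM)
#' with the constant/responsive taxonomy, motif scanning of consensus locus
#' sequences, intronic/exonic RNA counting with the expression filter, NB
#' differential expression across the time course, and binding-expression
#' integration.
#'
#' @param sim Output of \link{simulate_experiment} (or a list with the same
#'   components built from real data files).
#' @param config A \code{PipelineConfig}.
#' @param motif_library List of \code{PWM}s (default the built-in synthetic
#'   library).
#' @return A nested list with components \code{peaks}, \code{consensus},
#'   \code{concordance}, \code{distribution}, \code{diffbind},
#'   \code{motifs}, \code{expression}, \code{integration}.
#' @export
run_synthetic_pipeline <- function(sim, config = pipeline_config(),
                                   motif_library = default_motif_library()) {
  ann <- sim$annotation
  chrom_sizes <- sim$chrom_sizes
  info <- sim$chip$sample_info
  pooled_input <- suppressWarnings(do.call(c, unname(sim$chip$input)))

  peaks <- lapply(sim$chip$fragments, function(fr) {
    call_peaks(fr, pooled_input, chrom_sizes,
               window_size = config$window_size, fdr_threshold = config$peak_fdr)
  })

  consensus <- list()
  counts <- list()
  diffbind <- list()
  for (receptor in c("MR", "GR")) {
    sids <- info$sample_id[info$receptor == receptor]
    consensus[[receptor]] <- build_consensus(peaks[sids],
                                             min_support = config$min_support)
    counts[[receptor]] <- count_in_consensus(sim$chip$fragments[sids],
                                             consensus[[receptor]])
    cmat <- counts[[receptor]]$counts
    # background (non-peak) library offsets: with a large responsive
    # majority (as here and in the study), in-peak TMM would violate the
    # majority-non-changing assumption, and the full library is itself
    # shifted by the global gain in peak signal; fragments outside the
    # consensus loci estimate the sequencing depth unconfounded by binding
    libs <- counts[[receptor]]$lib_sizes - colSums(cmat)
    unit <- stats::setNames(rep(1, length(libs)), names(libs))
    grp <- function(cond) info$sample_id[info$receptor == receptor &
                                           info$condition == cond]
    res_fs <- nb_test(cmat, grp("BLAM"), grp("FS30"), lib_sizes = libs,
                      norm_factors = unit, shrink_weight = config$shrink_weight)
    res_pm <- nb_test(cmat, grp("BLAM"), grp("BLPM"), lib_sizes = libs,
                      norm_factors = unit, shrink_weight = config$shrink_weight)
    loci_genes <- annotate_nearest_gene(consensus[[receptor]]$loci, ann,
                                        max_distance = config$nearest_gene_bp)
    diffbind[[receptor]] <- list(
      FS30_vs_BLAM = res_fs,
      BLPM_vs_BLAM = res_pm,
      genes = loci_genes,
      response = classify_response(res_fs, res_pm,
                                   fdr_threshold = config$diff_fdr))
  }

  concordance <- lapply(stats::setNames(nm = unique(info$condition)), function(cond) {
    mr <- peaks[info$sample_id[info$receptor == "MR" & info$condition == cond]]
    gr <- peaks[info$sample_id[info$receptor == "GR" & info$condition == cond]]
    classify_concordance(mr, gr, condition = cond)
  })

  distribution <- genomic_distribution(
    peaks, ann, conditions = stats::setNames(
      paste(info$receptor, info$condition, sep = "_"), info$sample_id))

  motifs <- lapply(consensus, function(cs) {
    seqs <- peak_sequences(cs$loci, sim$genome_seq)
    scan_motifs(seqs, motif_library, p_threshold = config$motif_p)
  })

  tables <- count_features(sim$rna$fragments, ann)
  groups <- stats::setNames(sim$rna$sample_info$group, sim$rna$sample_info$sample_id)
  filtered <- list(
    intronic = filter_expressed(tables$intronic, groups, min_reads = config$min_reads),
    exonic = filter_expressed(tables$exonic, groups, min_reads = config$min_reads))
  de <- de_timecourse(filtered, groups, baseline = "BLAM",
                      fdr_threshold = config$diff_fdr,
                      shrink_weight = config$shrink_weight)
  detected <- union(rownames(filtered$intronic), rownames(filtered$exonic))

  gene_of <- function(receptor) {
    g <- diffbind[[receptor]]$genes$gene_id
    g[!is.na(g)]
  }
  sids_mr <- info$sample_id[info$receptor == "MR"]
  sids_gr <- info$sample_id[info$receptor == "GR"]
  classes <- classify_receptor_binding(
    gene_of("MR"), gene_of("GR"), peaks[sids_mr], peaks[sids_gr],
    detected, ann, max_distance = config$nearest_gene_bp)

  binding_fs_mr <- data.frame(
    gene_id = diffbind$MR$genes$gene_id,
    log2FC = diffbind$MR$FS30_vs_BLAM$log2FC,
    fdr = diffbind$MR$FS30_vs_BLAM$fdr, stringsAsFactors = FALSE)
  corr_fs <- tryCatch(
    correlate_binding_expression(binding_fs_mr, de$merged_stress$intronic,
                                 binding_fdr = config$diff_fdr,
                                 expr_fdr = config$diff_fdr),
    error = function(e) e)

  binding_results <- do.call(rbind, lapply(c("MR", "GR"), function(rec) {
    do.call(rbind, lapply(c("FS30_vs_BLAM", "BLPM_vs_BLAM"), function(cmp) {
      data.frame(gene_id = diffbind[[rec]]$genes$gene_id, receptor = rec,
                 comparison = cmp, log2FC = diffbind[[rec]][[cmp]]$log2FC,
                 fdr = diffbind[[rec]][[cmp]]$fdr, stringsAsFactors = FALSE)
    }))
  }))
  pathway <- export_pathway_inputs(binding_results, fdr_mode = config$pathway_fdr)

  list(peaks = peaks, consensus = consensus, concordance = concordance,
       distribution = distribution, diffbind = diffbind, motifs = motifs,
       expression = list(tables = tables, filtered = filtered, de = de,
                         detected = detected),
       integration = list(classes = classes, correlation_fs_mr = corr_fs,
                          binding_results = binding_results,
                          pathway = pathway))
}

#' Run the pipeline from a configuration, writing artifacts and a manifest
#'
#' Simulates an experiment (when \code{simulate = TRUE}) or loads one from
#' disk, runs \link{run_synthetic_pipeline}, and writes the stage outputs,
#' a resolved copy of the configuration and a manifest (package version,
#' seed, md5 checksums of every written file) to \code{out_dir}.
#' Deterministic stages are bit-identical across re-runs with the same
#' configuration and inputs.
#'
#' @param config A \code{PipelineConfig}.
#' @param out_dir Output directory.
#' @param sim_config A \code{SimulationConfig} (defaults to
#'   \code{simulation_config(config$seed)}).
#' @return The pipeline result list, invisibly; artifacts under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         sim_config = NULL) {
  if (missing(out_dir)) stop("run_pipeline: out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sim_config)) sim_config <- simulation_config(config$seed)
  sim <- simulate_experiment(sim_config)
  res <- run_synthetic_pipeline(sim, config)

  for (rec in c("MR", "GR")) {
    write_occupancy(res$consensus[[rec]],
                    file.path(out_dir, paste0("consensus_", rec, ".tsv")))
    write_diffbind(cbind(res$diffbind[[rec]]$FS30_vs_BLAM,
                         comparison = "FS30_vs_BLAM"),
                   file.path(out_dir, paste0("diffbind_", rec, "_FS30.tsv")))
    write_diffbind(cbind(res$diffbind[[rec]]$BLPM_vs_BLAM,
                         comparison = "BLPM_vs_BLAM"),
                   file.path(out_dir, paste0("diffbind_", rec, "_BLPM.tsv")))
    utils::write.table(res$motifs[[rec]]$composition,
                       file.path(out_dir, paste0("motif_composition_", rec, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$expression$de$results,
                     file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$integration$classes$classes,
                     file.path(out_dir, "gene_receptor_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.yaml"))
  manifest <- list(
    package = "nr3cseq",
    version = as.character(utils::packageVersion("nr3cseq")),
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
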