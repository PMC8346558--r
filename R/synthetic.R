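#' Simulation configuration for the synthetic MR/GR experiment
#'
#' Defines the study design the generator emulates: 2 receptors x 3 ChIP
#' conditions (BLAM, FS30, BLPM) x 4 replicates plus input controls, and an
#' RNA time course over 7 groups (BLAM, FS30-FS360, BLPM). Gene-level
#' receptor classes follow the reported 48/39/13 MR-only / MR-and-GR /
#' GR-only split; per-class constant fractions are set so that ~28% of MR
#' loci and ~5.5% of GR loci are constant. Binding log2 fold changes for
#' responsive loci are drawn from a truncated normal centred at ~2, and
#' gene expression responses are rank-coupled to binding via a Gaussian
#' copula calibrated to the target Spearman correlation.
#'
#' @param seed Integer seed (mandatory; every generator derives its stream
#'   from it).
#' @param ... Named overrides of any default listed below.
#' @return A \code{SimulationConfig} list.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed)) stop("simulation_config: seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chromosomes = 2L,
    chrom_length = 4e6,
    base_composition = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
    n_genes = 600L,
    p_single_exon = 0.05,
    exon_width = c(150L, 400L),
    intron_width = c(1000L, 3000L),
    n_exons = c(2L, 5L),
    # gaps exceed the 3 kb promoter window so one gene's promoter never
    # reaches into a neighbour's body
    gene_gap = c(3200L, 6000L),
    # design
    conditions_chip = c("BLAM", "FS30", "BLPM"),
    n_reps_chip = 4L,
    n_input = 4L,
    conditions_rna = c("BLAM", "FS30", "FS60", "FS120", "FS180", "FS360", "BLPM"),
    n_reps_rna = 5L,
    # locus classes
    receptor_class_fracs = c(MR_only = 0.48, MR_and_GR = 0.39, GR_only = 0.13),
    constant_fracs = c(MR_only = 0.462, MR_and_GR = 0.055, GR_only = 0.055),
    responsive_split = c(stress = 0.2, circ = 0.2, stress_circ = 0.6),
    # effect sizes and noise
    binding_fc = list(mean = 2.4, sd = 1.6, lo = 0.5, hi = 7.0),
    expr_fc = list(mean = 2.2, sd = 1.5, lo = 0.5, hi = 7.0),
    target_rho = 0.9,
    rho_stress_circ = 0.93,
    dispersion_chip = 0.06,
    dispersion_rna = 0.06,
    # ChIP signal
    mu_enrich_constant = 60,
    mu_enrich_base = 60,
    bg_lambda = 5,
    window_size = 200L,
    fragment_length = 200L,
    frag_spread = 80,
    locus_halfwidth = 200L,
    # RNA signal
    rna_mu_meanlog = log(120),
    rna_mu_sdlog = 0.5,
    exonic_factor = 1.3,
    stress_profile_intronic = c(FS30 = 1, FS60 = 0.85, FS120 = 0.5,
                                FS180 = 0.25, FS360 = 0.1),
    stress_profile_exonic = c(FS30 = 0.08, FS60 = 0.16, FS120 = 0.12,
                              FS180 = 0.08, FS360 = 0.04),
    circ_exonic_factor = 0.3,
    # planted motifs
    gre_consensus = "AGAACAGAATGTTCT",
    rfx_consensus = "GTTGCCATGGCAAC"
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("simulation_config: unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  if (abs(sum(cfg$receptor_class_fracs) - 1) > 1e-8 ||
      any(cfg$receptor_class_fracs < 0)) {
    stop("simulation_config: receptor class fractions must be non-negative and sum to 1")
  }
  if (sum(cfg$responsive_split) > 1 + 1e-8) {
    stop("simulation_config: responsive split fractions sum above 1")
  }
  if (cfg$dispersion_chip <= 0 || cfg$dispersion_rna <= 0) {
    stop("simulation_config: dispersions must be positive")
  }
  structure(cfg, class = "SimulationConfig")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  .qtrunc_norm(stats::runif(n), mean, sd, lo, hi)
}

.qtrunc_norm <- function(u, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pl + u * (ph - pl), mean, sd)
}

.trunc_norm_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  v <- 1 + (a * da - b * db) / z - ((da - db) / z)^2
  sd * sqrt(v)
}

#' Simulate a genome with gene models
#'
#' Chromosome sequences are i.i.d. draws from the configured zero-order base
#' composition; genes (one transcript each, alternating exons and introns)
#' are packed left to right with random intergenic gaps. Deterministic per
#' seed.
#'
#' @param config A \code{SimulationConfig}.
#' @return List with \code{annotation} (a \code{GenomeAnnotation}),
#'   \code{seqs} (named character vector of chromosome sequences) and
#'   \code{chrom_sizes}.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chromosomes), chroms)
  bases <- names(config$base_composition)
  seqs <- vapply(chroms, function(cc) {
    paste(sample(bases, config$chrom_length, replace = TRUE,
                 prob = config$base_composition), collapse = "")
  }, "")
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  gene_i <- 0L
  ex_chrom <- character(); ex_start <- integer(); ex_end <- integer()
  ex_gene <- character(); ex_tx <- character(); ex_strand <- character()
  for (ci in seq_along(chroms)) {
    pos <- 5000L
    for (g in seq_len(per_chrom[ci])) {
      gene_i <- gene_i + 1L
      gid <- sprintf("gene_%04d", gene_i)
      n_ex <- if (stats::runif(1) < config$p_single_exon) 1L else
        sample(config$n_exons[1]:config$n_exons[2], 1L)
      ew <- sample(config$exon_width[1]:config$exon_width[2], n_ex, replace = TRUE)
      iw <- if (n_ex > 1) sample(config$intron_width[1]:config$intron_width[2],
                                 n_ex - 1L, replace = TRUE) else integer()
      glen <- sum(ew) + sum(iw)
      if (pos + glen > config$chrom_length - 5000L) {
        stop("simulate_genome: infeasible packing, genes do not fit on ", chroms[ci])
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- pos + cumsum(c(0L, ew[-n_ex] + iw))
      ends <- starts + ew - 1L
      ex_chrom <- c(ex_chrom, rep(chroms[ci], n_ex))
      ex_start <- c(ex_start, starts)
      ex_end <- c(ex_end, ends)
      ex_gene <- c(ex_gene, rep(gid, n_ex))
      ex_tx <- c(ex_tx, rep(paste0(gid, ".t1"), n_ex))
      ex_strand <- c(ex_strand, rep(strand, n_ex))
      pos <- pos + glen + sample(config$gene_gap[1]:config$gene_gap[2], 1L)
    }
  }
  exons <- GenomicRanges::GRanges(ex_chrom, IRanges::IRanges(ex_start, ex_end),
                                  strand = ex_strand, gene_id = ex_gene,
                                  transcript_id = ex_tx)
  list(annotation = genome_annotation(exons, chrom_sizes),
       seqs = seqs, chrom_sizes = chrom_sizes)
}

# exact integer allocation of n items to fractions (largest remainder)
.allocate <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' Simulate ChIP fragment data with planted ground truth
#'
#' Every gene receives one binding locus (placed in the promoter or, when
#' the gene has an intron far enough from the TSS, inside an intron).
#' Receptor and response classes are assigned exactly per the configured
#' fractions. Responsive loci receive condition-specific NB-distributed
#' enrichment on top of uniform background; selective loci are enriched in
#' one receptor's samples only; motif consensus sequences are written into
#' the genome at planted loci (GRE at responsive loci, RFX at constant
#' MR-only loci). Input samples contain background only.
#'
#' @param config A \code{SimulationConfig}.
#' @param genome Output of \link{simulate_genome}.
#' @return List with \code{fragments} (named list of per-sample
#'   \code{GRanges}, samples \code{MR_BLAM_1} ... \code{GR_BLPM_4}),
#'   \code{input} (list of input-control fragment sets), \code{sample_info}
#'   (data.frame sample_id, receptor, condition, replicate), \code{truth}
#'   (per-locus data.frame) and \code{genome_seq} (chromosome sequences with
#'   motifs planted, as a \code{Biostrings::DNAStringSet}).
#' @export
simulate_chip <- function(config, genome) {
  set.seed(config$seed + 1L)
  ann <- genome$annotation
  genes <- ann$genes
  n <- nrow(genes)

  # receptor class, exactly allocated then shuffled over genes
  rc_counts <- .allocate(n, config$receptor_class_fracs)
  receptor_class <- sample(rep(names(rc_counts), rc_counts))
  # response class within each receptor class
  response_class <- character(n)
  for (cl in names(rc_counts)) {
    idx <- which(receptor_class == cl)
    n_const <- round(length(idx) * config$constant_fracs[[cl]])
    resp_counts <- .allocate(length(idx) - n_const, config$responsive_split)
    lab <- sample(c(rep("constant", n_const),
                    rep(names(resp_counts), resp_counts)))
    response_class[idx] <- lab
  }

  # binding fold changes
  fc <- config$binding_fc
  fc_fs30 <- numeric(n)
  fc_blpm <- numeric(n)
  st <- response_class %in% c("stress", "stress_circ")
  ci <- response_class %in% c("circ", "stress_circ")
  fc_fs30[st] <- .rtrunc_norm(sum(st), fc$mean, fc$sd, fc$lo, fc$hi)
  sc <- response_class == "stress_circ"
  fc_blpm[sc] <- pmin(pmax(fc_fs30[sc] * 2^stats::rnorm(sum(sc), 0, 0.2),
                           fc$lo), fc$hi)
  co <- response_class == "circ"
  fc_blpm[co] <- .rtrunc_norm(sum(co), fc$mean, fc$sd, fc$lo, fc$hi)

  # locus placement: promoter or deep intron
  intr <- ann$introns
  intr_gene <- S4Vectors::mcols(intr)$gene_id
  center <- integer(n)
  placement <- character(n)
  want_intron <- stats::runif(n) < 0.5
  for (g in seq_len(n)) {
    tssg <- genes$tss[g]
    placed <- FALSE
    if (want_intron[g]) {
      gi <- which(intr_gene == genes$gene_id[g])
      if (length(gi)) {
        st_i <- GenomicRanges::start(intr)[gi]
        en_i <- GenomicRanges::end(intr)[gi]
        # candidate centers clear of the promoter window (3 kb) by a margin
        lo <- pmax(st_i + 50L, 1L)
        hi <- pmin(en_i - 50L, config$chrom_length)
        ok <- which(hi > lo & pmax(abs(lo - tssg), abs(hi - tssg)) > 3500)
        cand <- integer()
        for (j in ok) {
          rng <- lo[j]:hi[j]
          rng <- rng[abs(rng - tssg) > 3500]
          if (length(rng)) cand <- c(cand, rng[sample.int(length(rng), 1L)])
        }
        if (length(cand)) {
          center[g] <- cand[sample.int(length(cand), 1L)]
          placement[g] <- "intron"
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      off <- sample(seq(-800L, 800L), 1L)
      center[g] <- max(config$locus_halfwidth + 1L,
                       min(tssg + off,
                           config$chrom_length - config$locus_halfwidth))
      placement[g] <- "promoter"
    }
  }

  # plant motifs
  seqs <- genome$seqs
  motif <- rep("none", n)
  motif[st | ci] <- "GRE"
  motif[response_class == "constant" & receptor_class == "MR_only"] <- "RFX"
  for (g in which(motif != "none")) {
    m <- if (motif[g] == "GRE") config$gre_consensus else config$rfx_consensus
    s0 <- center[g] - nchar(m) %/% 2
    substr(seqs[[genes$chrom[g]]], s0, s0 + nchar(m) - 1L) <- m
  }

  truth <- data.frame(
    locus_id = sprintf("locus_%04d", seq_len(n)),
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = center - config$locus_halfwidth,
    end = center + config$locus_halfwidth,
    center = center,
    receptor_class = receptor_class,
    response_class = response_class,
    motif = motif,
    placement = placement,
    fc_fs30 = fc_fs30,
    fc_blpm = fc_blpm,
    stringsAsFactors = FALSE)

  # detectability check at the configured depth
  lam <- config$bg_lambda
  crit <- stats::qpois(1 - 0.05 / (config$n_chromosomes * config$chrom_length /
                                     config$window_size), lam)
  power_proxy <- stats::ppois(crit, lam + 0.5 * config$mu_enrich_base,
                              lower.tail = FALSE)
  if (power_proxy < 0.5) {
    warning(sprintf("simulate_chip: enrichment near detection limit (power proxy %.2f)",
                    power_proxy))
  }

  chrom_sizes <- genome$chrom_sizes
  n_windows <- sum(ceiling(chrom_sizes / config$window_size))
  n_bg <- round(config$bg_lambda * n_windows)
  chrom_prob <- chrom_sizes / sum(chrom_sizes)

  bg_fragments <- function() {
    cc <- sample(names(chrom_sizes), n_bg, replace = TRUE, prob = chrom_prob)
    mid <- floor(stats::runif(n_bg, 1, chrom_sizes[cc]))
    .mk_fragments(cc, mid, config, chrom_sizes)
  }

  cond_fc <- function(cond) {
    switch(cond, BLAM = numeric(n), FS30 = fc_fs30, BLPM = fc_blpm)
  }
  mu_base <- ifelse(response_class == "constant",
                    config$mu_enrich_constant, config$mu_enrich_base)

  fragments <- list()
  sample_rows <- list()
  for (receptor in c("MR", "GR")) {
    active <- if (receptor == "MR") {
      receptor_class %in% c("MR_only", "MR_and_GR")
    } else {
      receptor_class %in% c("GR_only", "MR_and_GR")
    }
    for (cond in config$conditions_chip) {
      mu <- mu_base * 2^cond_fc(cond)
      for (rep_i in seq_len(config$n_reps_chip)) {
        sid <- paste(receptor, cond, rep_i, sep = "_")
        cnt <- integer(n)
        cnt[active] <- stats::rnbinom(sum(active), mu = mu[active],
                                      size = 1 / config$dispersion_chip)
        idx <- rep(seq_len(n), cnt)
        mid <- center[idx] + round(stats::rnorm(length(idx), 0, config$frag_spread))
        cc <- genes$chrom[idx]
        enr <- .mk_fragments(cc, mid, config, chrom_sizes)
        fragments[[sid]] <- c(bg_fragments(), enr)
        sample_rows[[sid]] <- data.frame(sample_id = sid, receptor = receptor,
                                         condition = cond, replicate = rep_i,
                                         stringsAsFactors = FALSE)
      }
    }
  }
  input <- lapply(seq_len(config$n_input), function(i) bg_fragments())
  names(input) <- sprintf("input_%d", seq_len(config$n_input))

  list(fragments = fragments, input = input,
       sample_info = do.call(rbind, c(sample_rows, list(make.row.names = FALSE))),
       truth = truth,
       genome_seq = Biostrings::DNAStringSet(seqs))
}

.mk_fragments <- function(chrom, mid, config, chrom_sizes) {
  half <- config$fragment_length %/% 2L
  lens <- chrom_sizes[chrom]
  mid <- pmin(pmax(mid, half + 1L), lens - half)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(mid - half + 1L, mid + half))
}

# Gaussian-copula latent correlation required to reach a target Spearman
# correlation between *estimated* fold changes, given true-effect spread and
# estimation noise variance on each side. Errors when unattainable.
.copula_rho <- function(target, sd_b, var_b_noise, sd_e, var_e_noise) {
  r_b <- sd_b / sqrt(sd_b^2 + var_b_noise)
  r_e <- sd_e / sqrt(sd_e^2 + var_e_noise)
  max_spearman <- (6 / pi) * asin(r_b * r_e / 2)
  pearson_target <- 2 * sin(pi * target / 6)
  rho <- pearson_target / (r_b * r_e)
  if (rho > 1.02) {
    stop(sprintf(
      "target Spearman rho %.3f unattainable at this noise level; max achievable ~ %.3f",
      target, max_spearman))
  }
  min(rho, 0.9995)
}

#' Simulate RNA fragment data coupled to the binding ground truth
#'
#' Per-gene NB fragment counts over the gene's introns and merged exons for
#' 7 groups (baseline, five post-stress time points, evening baseline).
#' Responsive genes follow a stress time profile in which the intronic
#' (hnRNA) response leads and exceeds the exonic one, mirroring intronic
#' reads being the more direct index of transcriptional activity. The
#' maximal intronic log2 fold change of stress-responsive genes is
#' rank-coupled to the binding fold change of the gene's locus through a
#' Gaussian copula calibrated (accounting for count-estimation noise) to
#' the configured target Spearman correlation; circadian responses are
#' coupled to the stress responses the same way at
#' \code{rho_stress_circ}.
#'
#' @param config A \code{SimulationConfig}.
#' @param genome Output of \link{simulate_genome}.
#' @param truth Per-locus truth from \link{simulate_chip}.
#' @return List with \code{fragments} (named list, samples
#'   \code{BLAM_r1} ...), \code{sample_info}, \code{truth_expr} (per-gene
#'   data.frame with planted expression classes and fold changes) and
#'   \code{fc_profiles} (list of intronic/exonic genes x groups log2FC
#'   matrices).
#' @export
simulate_rna <- function(config, genome, truth) {
  set.seed(config$seed + 2L)
  ann <- genome$annotation
  genes <- ann$genes
  n <- nrow(genes)
  stopifnot(identical(truth$gene_id, genes$gene_id))

  mu_int <- stats::rlnorm(n, config$rna_mu_meanlog, config$rna_mu_sdlog)
  mu_ex <- mu_int * config$exonic_factor
  has_intron <- genes$gene_id %in% S4Vectors::mcols(ann$introns)$gene_id
  mu_int[!has_intron] <- 0

  # estimation-noise variances (log2 scale) used for copula calibration
  ln2sq <- log(2)^2
  mu_b <- config$mu_enrich_base
  var_b <- ((1 / mu_b + config$dispersion_chip) +
              (1 / (mu_b * 2^config$binding_fc$mean) + config$dispersion_chip)) /
    config$n_reps_chip / ln2sq
  mu_r <- exp(config$rna_mu_meanlog)
  var_e <- ((1 / mu_r + config$dispersion_rna) +
              (1 / (mu_r * 2^config$expr_fc$mean) + config$dispersion_rna)) /
    config$n_reps_rna / ln2sq
  efc <- config$expr_fc
  sd_e <- .trunc_norm_sd(efc$mean, efc$sd, efc$lo, efc$hi)

  fc_int_fs <- numeric(n)
  fc_int_blpm <- numeric(n)
  st <- truth$response_class %in% c("stress", "stress_circ")
  if (any(st)) {
    b <- truth$fc_fs30[st]
    rho <- .copula_rho(config$target_rho, stats::sd(b), var_b, sd_e, var_e)
    zb <- stats::qnorm((rank(b, ties.method = "average") - 0.5) / length(b))
    ze <- rho * zb + sqrt(1 - rho^2) * stats::rnorm(length(b))
    fc_int_fs[st] <- .qtrunc_norm(stats::pnorm(ze), efc$mean, efc$sd, efc$lo, efc$hi)
  }
  sc <- truth$response_class == "stress_circ"
  if (any(sc)) {
    base <- fc_int_fs[sc]
    rho2 <- .copula_rho(config$rho_stress_circ, sd_e, var_e, sd_e, var_e)
    zb <- stats::qnorm((rank(base, ties.method = "average") - 0.5) / length(base))
    ze <- rho2 * zb + sqrt(1 - rho2^2) * stats::rnorm(length(base))
    fc_int_blpm[sc] <- .qtrunc_norm(stats::pnorm(ze), efc$mean, efc$sd, efc$lo, efc$hi)
  }
  co <- truth$response_class == "circ"
  if (any(co)) {
    b <- truth$fc_blpm[co]
    rho <- .copula_rho(config$target_rho, stats::sd(b), var_b, sd_e, var_e)
    zb <- stats::qnorm((rank(b, ties.method = "average") - 0.5) / length(b))
    ze <- rho * zb + sqrt(1 - rho^2) * stats::rnorm(length(b))
    fc_int_blpm[co] <- .qtrunc_norm(stats::pnorm(ze), efc$mean, efc$sd, efc$lo, efc$hi)
  }

  groups <- config$conditions_rna
  fs_groups <- intersect(names(config$stress_profile_intronic), groups)
  fc_intronic <- matrix(0, n, length(groups), dimnames = list(genes$gene_id, groups))
  fc_exonic <- fc_intronic
  for (g in fs_groups) {
    fc_intronic[, g] <- fc_int_fs * config$stress_profile_intronic[[g]]
    fc_exonic[, g] <- fc_int_fs * config$stress_profile_exonic[[g]]
  }
  if ("BLPM" %in% groups) {
    fc_intronic[, "BLPM"] <- fc_int_blpm
    fc_exonic[, "BLPM"] <- fc_int_blpm * config$circ_exonic_factor
  }

  # per-gene sampling blocks
  intr <- ann$introns
  intr_gene <- S4Vectors::mcols(intr)$gene_id
  ex <- ann$merged_exons
  ex_gene <- S4Vectors::mcols(ex)$gene_id
  block_list <- function(feats, feat_gene) {
    sp <- split(data.frame(start = GenomicRanges::start(feats),
                           width = GenomicRanges::width(feats),
                           chrom = as.character(GenomicRanges::seqnames(feats)),
                           stringsAsFactors = FALSE), feat_gene)
    sp[genes$gene_id]
  }
  intron_blocks <- block_list(intr, intr_gene)
  exon_blocks <- block_list(ex, ex_gene)

  draw_positions <- function(blocks, counts) {
    idx <- which(counts > 0)
    if (!length(idx)) {
      return(list(chrom = character(), mid = integer()))
    }
    chroms <- vector("list", length(idx))
    mids <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      g <- idx[k]
      bl <- blocks[[g]]
      c_g <- counts[g]
      bi <- if (nrow(bl) == 1L) rep(1L, c_g) else
        sample.int(nrow(bl), c_g, replace = TRUE, prob = bl$width)
      mids[[k]] <- bl$start[bi] + floor(stats::runif(c_g) * bl$width[bi])
      chroms[[k]] <- rep(bl$chrom[1], c_g)
    }
    list(chrom = unlist(chroms), mid = unlist(mids))
  }

  fragments <- list()
  sample_rows <- list()
  sz <- 1 / config$dispersion_rna
  for (grp in groups) {
    for (rep_i in seq_len(config$n_reps_rna)) {
      sid <- sprintf("%s_r%d", grp, rep_i)
      cnt_int <- stats::rnbinom(n, mu = mu_int * 2^fc_intronic[, grp], size = sz)
      cnt_int[mu_int == 0] <- 0L
      cnt_ex <- stats::rnbinom(n, mu = mu_ex * 2^fc_exonic[, grp], size = sz)
      pi_ <- draw_positions(intron_blocks, cnt_int)
      pe_ <- draw_positions(exon_blocks, cnt_ex)
      fragments[[sid]] <- .mk_fragments(c(pi_$chrom, pe_$chrom),
                                        c(pi_$mid, pe_$mid),
                                        config, genome$chrom_sizes)
      sample_rows[[sid]] <- data.frame(sample_id = sid, group = grp,
                                       replicate = rep_i, stringsAsFactors = FALSE)
    }
  }

  truth_expr <- data.frame(
    gene_id = genes$gene_id,
    expr_class = ifelse(truth$response_class == "constant", "CON", "RES"),
    has_intron = has_intron,
    fc_int_fs = fc_int_fs,
    fc_int_blpm = fc_int_blpm,
    fc_ex_fs = fc_int_fs * max(config$stress_profile_exonic),
    fc_ex_blpm = fc_int_blpm * config$circ_exonic_factor,
    stringsAsFactors = FALSE)

  list(fragments = fragments,
       sample_info = do.call(rbind, c(sample_rows, list(make.row.names = FALSE))),
       truth_expr = truth_expr,
       fc_profiles = list(intronic = fc_intronic, exonic = fc_exonic))
}

#' Simulate a complete synthetic experiment
#'
#' Runs \link{simulate_genome}, \link{simulate_chip} and \link{simulate_rna}
#' under one configuration.
#'
#' @param config A \code{SimulationConfig}.
#' @return List with \code{config}, \code{annotation}, \code{genome_seq},
#'   \code{chip} and \code{rna}.
#' @export
simulate_experiment <- function(config) {
  genome <- simulate_genome(config)
  chip <- simulate_chip(config, genome)
  rna <- simulate_rna(config, genome, chip$truth)
  list(config = config, annotation = genome$annotation,
       chrom_sizes = genome$chrom_sizes,
       genome_seq = chip$genome_seq, chip = chip, rna = rna)
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA (genome with planted motifs), GTF (gene models), BED
#' (fragments and truth loci), TSV truth tables and a YAML copy of the
#' configuration with its seed.
#'
#' @param sim Output of \link{simulate_experiment}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome_seq, file.path(dir, "genome.fa"))
  write_annotation_gtf(sim$annotation, file.path(dir, "genes.gtf"))
  truth <- sim$chip$truth
  write_bed(GenomicRanges::GRanges(truth$chrom,
                                   IRanges::IRanges(truth$start, truth$end),
                                   name = truth$locus_id),
            file.path(dir, "truth_loci.bed"))
  utils::write.table(truth, file.path(dir, "truth_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$rna$truth_expr, file.path(dir, "truth_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  frag_dir <- file.path(dir, "fragments")
  dir.create(frag_dir, showWarnings = FALSE)
  for (sid in names(sim$chip$fragments)) {
    write_bed(sim$chip$fragments[[sid]], file.path(frag_dir, paste0(sid, ".bed")))
  }
  for (sid in names(sim$chip$input)) {
    write_bed(sim$chip$input[[sid]], file.path(frag_dir, paste0(sid, ".bed")))
  }
  for (sid in names(sim$rna$fragments)) {
    write_bed(sim$rna$fragments[[sid]], file.path(frag_dir, paste0("RNA_", sid, ".bed")))
  }
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
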