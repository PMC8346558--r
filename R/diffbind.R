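#' Count fragments on consensus loci
#'
#' A fragment is assigned to a locus when its midpoint falls within the
#' locus (midpoint assignment keeps counts additive over disjoint loci).
#'
#' @param fragments Named list of per-sample fragment \code{GRanges}.
#' @param consensus A \code{ConsensusPeakSet}.
#' @return A \code{BindingCountMatrix}: list with \code{counts} (loci x
#'   samples integer matrix), \code{loci}, and \code{lib_sizes} (total
#'   fragments per sample).
#' @export
count_in_consensus <- function(fragments, consensus) {
  if (is.null(names(fragments))) stop("count_in_consensus: fragments must be a named list")
  loci <- consensus$loci
  counts <- vapply(fragments, function(fr) {
    mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
    mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(fr),
                                   IRanges::IRanges(mid, mid))
    GenomicRanges::countOverlaps(loci, mids, ignore.strand = TRUE)
  }, integer(length(loci)))
  if (length(loci) == 1L) counts <- matrix(counts, nrow = 1,
                                           dimnames = list(NULL, names(fragments)))
  rownames(counts) <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(loci)),
                              GenomicRanges::start(loci), GenomicRanges::end(loci))
  structure(list(counts = counts, loci = loci,
                 lib_sizes = vapply(fragments, length, 0L)),
            class = "BindingCountMatrix")
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample scaling factors relative to a reference column (the sample
#' whose upper-quartile count rate is closest to the mean): M-values
#' (log-ratios) are trimmed by 30% on each side, A-values (average
#' log-abundance) by 5%, and the factor is the precision-weighted mean of
#' the surviving M-values. Factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative count matrix (features x samples).
#' @param lib_sizes Per-sample library sizes (default column sums).
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.3 / 0.05).
#' @return Numeric vector of normalization factors, one per column.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        trim_m = 0.3, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("tmm_factors: need >= 2 samples")
  if (any(lib_sizes == 0)) stop("tmm_factors: all-zero column")
  uq <- apply(counts, 2, function(y) stats::quantile(y[y > 0], 0.75)) / lib_sizes
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
              trim_m, trim_a)
  }, 0)
  f / exp(mean(log(f)))
}

.tmm_pair <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0) return(1)
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr) # delta-method var of M
  if (max(abs(m)) < 1e-10) return(1) # identical relative profiles
  nkeep <- length(m)
  lo_m <- floor(nkeep * trim_m) + 1
  hi_m <- nkeep + 1 - lo_m
  lo_a <- floor(nkeep * trim_a) + 1
  hi_a <- nkeep + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(sel)) return(1)
  2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
}

#' Negative-binomial likelihood-ratio test between two sample groups
#'
#' Per-locus NB log-linear model with log(library size x normalization
#' factor) offsets. A common dispersion is estimated by profile-likelihood
#' maximization across loci; per-locus dispersions are then shrunk toward
#' the common value by maximizing the per-locus likelihood plus
#' \code{shrink_weight} times the average (common) likelihood over a
#' dispersion grid. The group effect is tested by a likelihood-ratio chi-squared
#' test on 1 degree of freedom; p-values are BH-adjusted within the
#' comparison. log2 fold changes come from the fitted group means with a
#' pseudo-count of 0.5 (unshrunken).
#'
#' @param counts Loci x samples count matrix.
#' @param groupA,groupB Column names or indices of the two groups (B vs A;
#'   log2FC > 0 means higher in B).
#' @param lib_sizes Per-sample library sizes (default column sums).
#' @param norm_factors Per-sample normalization factors (default TMM via
#'   \link{tmm_factors}).
#' @param dispersion Fixed dispersion value to use for every locus
#'   (skips estimation), or NULL (default) to estimate.
#' @param shrink_weight Weight of the common likelihood in the per-locus
#'   dispersion estimate (default 10; larger means stronger shrinkage).
#' @param pseudo Pseudo-count for the fold-change (default 0.5).
#' @return data.frame with locus, baseMean, log2FC, dispersion, pvalue, fdr,
#'   converged. Non-converged loci are flagged and given p = 1, never
#'   dropped.
#' @export
nb_test <- function(counts, groupA, groupB, lib_sizes = colSums(counts),
                    norm_factors = NULL, dispersion = NULL,
                    shrink_weight = 10, pseudo = 0.5) {
  counts <- as.matrix(counts)
  A <- .resolve_cols(counts, groupA)
  B <- .resolve_cols(counts, groupB)
  if (length(A) < 2 || length(B) < 2) stop("nb_test: need >= 2 samples per group")
  if (is.null(norm_factors)) {
    norm_factors <- tryCatch(tmm_factors(counts[, c(A, B), drop = FALSE],
                                         lib_sizes[c(A, B)]),
                             error = function(e) rep(1, length(c(A, B))))
    names(norm_factors) <- c(A, B)
    s <- lib_sizes[c(A, B)] * norm_factors
  } else {
    s <- (lib_sizes * norm_factors)[c(A, B)]
  }
  Y <- counts[, c(A, B), drop = FALSE]
  ia <- seq_along(A)
  ib <- length(A) + seq_along(B)
  G <- nrow(Y)

  if (is.null(dispersion)) {
    prof <- function(log_phi) {
      phi <- exp(log_phi)
      fa <- .nb_fit_mean(Y[, ia, drop = FALSE], s[ia], phi)
      fb <- .nb_fit_mean(Y[, ib, drop = FALSE], s[ib], phi)
      sum(fa$apl) + sum(fb$apl)
    }
    opt <- stats::optimize(prof, c(log(1e-6), log(5)), maximum = TRUE, tol = 1e-4)
    phi_common <- exp(opt$maximum)
    grid <- phi_common * 2^seq(-8, 8, length.out = 33)
    grid <- pmin(pmax(grid, 1e-8), 20)
    ll_grid <- vapply(grid, function(phi) {
      .nb_fit_mean(Y[, ia, drop = FALSE], s[ia], phi)$apl +
        .nb_fit_mean(Y[, ib, drop = FALSE], s[ib], phi)$apl
    }, numeric(G))
    if (G == 1L) ll_grid <- matrix(ll_grid, nrow = 1)
    common_curve <- colMeans(ll_grid)
    score <- ll_grid + shrink_weight * matrix(common_curve, G, length(grid), byrow = TRUE)
    phi_i <- grid[max.col(score, ties.method = "first")]
  } else {
    phi_common <- dispersion
    phi_i <- rep(dispersion, G)
  }

  fa <- .nb_fit_mean(Y[, ia, drop = FALSE], s[ia], phi_i)
  fb <- .nb_fit_mean(Y[, ib, drop = FALSE], s[ib], phi_i)
  f0 <- .nb_fit_mean(Y, s, phi_i)
  dev <- pmax(0, 2 * (fa$ll + fb$ll - f0$ll))
  pvalue <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  converged <- fa$converged & fb$converged & f0$converged
  pvalue[!converged] <- 1
  sbar <- mean(s)
  log2fc <- log2((fb$m * sbar + pseudo) / (fa$m * sbar + pseudo))
  data.frame(
    locus = if (is.null(rownames(Y))) as.character(seq_len(G)) else rownames(Y),
    baseMean = f0$m * sbar,
    log2FC = log2fc,
    dispersion = phi_i,
    pvalue = pvalue,
    fdr = bh_adjust(pvalue)$adjusted,
    converged = converged,
    stringsAsFactors = FALSE)
}

.resolve_cols <- function(counts, g) {
  if (is.character(g)) {
    if (!all(g %in% colnames(counts))) stop("nb_test: unknown sample id in group")
    g
  } else colnames(counts)[g]
}

# Newton fit of a single NB mean per locus (shared across the group), with
# per-sample offsets s and dispersion phi (scalar or per-locus vector).
# Returns relative abundance m, per-locus log-likelihood, convergence flag.
.nb_fit_mean <- function(Y, s, phi, max_iter = 50L, tol = 1e-10) {
  G <- nrow(Y)
  if (length(phi) == 1L) phi <- rep(phi, G)
  zero <- rowSums(Y) == 0 # all-zero rows: MLE mean 0, log-likelihood 0
  m <- numeric(G)
  conv <- rep(FALSE, G)
  act <- which(!zero)
  if (length(act)) {
    Ya <- Y[act, , drop = FALSE]
    phia <- phi[act]
    beta <- log(rowSums(Ya) / sum(s))
    done <- rep(FALSE, length(act))
    for (it in seq_len(max_iter)) {
      mu <- exp(beta) %o% s
      denom <- 1 + phia * mu
      U <- rowSums((Ya - mu) / denom)
      Info <- rowSums(mu / denom)
      delta <- U / pmax(Info, 1e-12)
      delta <- pmin(pmax(delta, -3), 3)
      beta <- beta + delta
      done <- done | abs(delta) < tol
      if (all(done)) break
    }
    m[act] <- exp(beta)
    conv[act] <- done
  }
  conv[zero] <- TRUE
  ll <- numeric(G)
  info <- numeric(G)
  if (length(act)) {
    mu <- m[act] %o% s
    ll[act] <- rowSums(.nb_log_density(Y[act, , drop = FALSE], mu, phi[act]))
    info[act] <- rowSums(mu / (1 + phi[act] * mu))
  }
  # apl: Cox-Reid adjusted profile log-likelihood, for dispersion estimation
  list(m = m, ll = ll, apl = ll - 0.5 * log(pmax(info, 1e-8)),
       converged = conv)
}

.nb_log_density <- function(Y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (length(phi) == 1L) phi <- rep(phi, nrow(Y))
  pois <- phi < 1e-8
  out <- matrix(0, nrow(Y), ncol(Y))
  if (any(pois)) {
    out[pois, ] <- stats::dpois(Y[pois, , drop = FALSE],
                                mu[pois, , drop = FALSE], log = TRUE)
  }
  if (any(!pois)) {
    sz <- 1 / phi[!pois]
    out[!pois, ] <- stats::dnbinom(Y[!pois, , drop = FALSE],
                                   mu = mu[!pois, , drop = FALSE],
                                   size = sz, log = TRUE)
  }
  out
}

#' Assign the constant/responsive taxonomy from two differential comparisons
#'
#' A locus is STRESS when significant (FDR at or below the threshold) in the
#' stress comparison only, CIRC in the circadian comparison only,
#' STRESS_and_CIRC in both, and NON_RES (equivalently constant) in neither.
#'
#' @param results_stress,results_circ data.frames from \link{nb_test} over
#'   the same loci in the same order (typically FS30 vs BLAM and BLPM vs
#'   BLAM).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return List with \code{labels} (per-locus factor), \code{constant}
#'   (logical), and \code{summary} (counts and percentages of responsive vs
#'   constant).
#' @export
classify_response <- function(results_stress, results_circ, fdr_threshold = 0.05) {
  if (!identical(results_stress$locus, results_circ$locus)) {
    stop("classify_response: comparisons cover different loci")
  }
  sig_s <- results_stress$fdr <= fdr_threshold
  sig_c <- results_circ$fdr <= fdr_threshold
  labels <- rep("NON_RES", length(sig_s))
  labels[sig_s & !sig_c] <- "STRESS"
  labels[!sig_s & sig_c] <- "CIRC"
  labels[sig_s & sig_c] <- "STRESS_and_CIRC"
  labels <- factor(labels, levels = c("STRESS", "CIRC", "STRESS_and_CIRC", "NON_RES"))
  n <- length(labels)
  n_const <- sum(labels == "NON_RES")
  list(labels = labels,
       constant = labels == "NON_RES",
       summary = data.frame(
         n_loci = n,
         n_responsive = n - n_const,
         n_constant = n_const,
         pct_responsive = 100 * (n - n_const) / n,
         pct_constant = 100 * n_const / n))
}

#' Write differential-binding results as TSV and BED
#' @param results data.frame from \link{nb_test} with coordinate-style locus ids.
#' @param path Output TSV path; a .bed with log2FC/FDR columns is written
#'   alongside when \code{bed = TRUE}.
#' @param bed Also write a BED version (default FALSE).
#' @export
write_diffbind <- function(results, path, bed = FALSE) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed) {
    parts <- regmatches(results$locus,
                        regexec("^(.+):(\\d+)-(\\d+)$", results$locus))
    ok <- lengths(parts) == 4
    df <- data.frame(
      chrom = vapply(parts[ok], `[`, "", 2),
      start = as.integer(vapply(parts[ok], `[`, "", 3)) - 1L,
      end = as.integer(vapply(parts[ok], `[`, "", 4)),
      name = results$locus[ok],
      log2FC = results$log2FC[ok],
      fdr = results$fdr[ok])
    utils::write.table(df, sub("\\.tsv$", ".bed", path), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
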