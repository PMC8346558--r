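#' Read a JASPAR-format PFM motif library
#'
#' Parses the JASPAR text format: a header line \code{>motif_id name}
#' followed by four rows of per-position counts for A, C, G, T (with or
#' without the \code{A [ ... ]} decoration). Counts are kept raw; the
#' pseudocount is applied when probabilities are formed.
#'
#' @param path Path to the PFM text file.
#' @param family_map Optional named character vector or two-column data.frame
#'   mapping motif_id to a family label (e.g. GRE, RFX, KLF). Defaults to the
#'   name on the header line.
#' @param pseudocount Total pseudocount added per column (default 1,
#'   distributed uniformly over the four bases).
#' @return A list of \code{PWM} objects (see \link{pwm}).
#' @export
read_jaspar <- function(path, family_map = NULL, pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("read_jaspar: no motif headers found")
  if (is.data.frame(family_map)) {
    family_map <- stats::setNames(as.character(family_map[[2]]),
                                  as.character(family_map[[1]]))
  }
  ends <- c(idx[-1] - 1L, length(lines))
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    hdr <- sub("^>\\s*", "", lines[idx[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- parts[1]
    name <- if (length(parts) > 1) parts[2] else parts[1]
    body <- lines[(idx[i] + 1L):ends[i]]
    if (length(body) < 4) stop("read_jaspar: motif ", motif_id, " lacks 4 rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]?\\s*\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    fam <- if (!is.null(family_map) && motif_id %in% names(family_map)) {
      unname(family_map[motif_id])
    } else name
    out[[i]] <- pwm(counts, motif_id = motif_id, name = name, family = fam,
                    pseudocount = pseudocount)
  }
  stats::setNames(out, vapply(out, function(m) m$motif_id, ""))
}

#' Construct a position weight matrix object
#'
#' @param counts 4 x L matrix of base counts (rows A, C, G, T), L >= 4.
#' @param motif_id,name,family Identifiers.
#' @param pseudocount Total pseudocount per column, spread uniformly.
#' @return A \code{PWM} object: counts, column-normalized probabilities
#'   (each column sums to 1), and metadata.
#' @export
pwm <- function(counts, motif_id = "motif", name = motif_id,
                family = name, pseudocount = 1) {
  if (nrow(counts) != 4) stop("pwm: counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("pwm: motif length must be >= 4")
  if (any(counts < 0)) stop("pwm: negative counts")
  probs <- sweep(counts + pseudocount / 4, 2, colSums(counts) + pseudocount, "/")
  structure(list(motif_id = motif_id, name = name, family = family,
                 counts = counts, probs = probs, length = ncol(counts),
                 pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s (%s, family %s), length %d, consensus %s\n",
              x$motif_id, x$name, x$family, x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (per-column argmax base)
#' @param x A \code{PWM}.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$probs)[apply(x$probs, 2, which.max)], collapse = "")
}

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_seq <- function(s) {
  v <- .base_codes[strsplit(toupper(s), "")[[1]]]
  v[is.na(v)] <- 5L # N and other ambiguity codes
  v
}

# 5 x L log-odds matrix in bits; row 5 (N) contributes 0
.lods_matrix <- function(pwm, background) {
  lods <- log2(pwm$probs / background)
  rbind(lods, N = 0)
}

#' Log-odds score of a PWM against a sequence window
#'
#' \eqn{\sum_i \log_2(p_\mathrm{motif}(b_i, i) / p_\mathrm{bg}(b_i))}, in
#' bits. N bases contribute 0 (scored as background).
#'
#' @param pwm A \code{PWM}.
#' @param window Character scalar, same length as the motif.
#' @param background Length-4 base probability vector (A, C, G, T); default
#'   uniform.
#' @return Numeric score in bits.
#' @export
log_odds <- function(pwm, window, background = rep(0.25, 4)) {
  codes <- .encode_seq(window)
  if (length(codes) != pwm$length) stop("log_odds: window/motif length mismatch")
  lods <- .lods_matrix(pwm, background)
  sum(lods[cbind(codes, seq_along(codes))])
}

#' Exact null score distribution of a PWM
#'
#' Dynamic programming over discretized log-odds scores: per-column score
#' distributions under the zero-order background are convolved to give the
#' exact distribution of the window score for random background sequence.
#' Scores are rounded to integer multiples of \code{granularity} bits; the
#' same rounded matrix is used by \link{scan_motifs}, so scan p-values are
#' exact for the discretized score. The discretization perturbs any
#' continuous score by at most \code{granularity * L / 2} bits.
#'
#' @param pwm A \code{PWM}.
#' @param background Length-4 base probabilities; default uniform.
#' @param granularity Score discretization in bits (default 1e-3).
#' @return A \code{PWMScoreDistribution}: list with \code{p_value(score)}
#'   (P(S >= score) for a random background window), \code{score_threshold(p)}
#'   (smallest discretized score with p-value <= p, or Inf if unattainable),
#'   the integer log-odds matrix \code{int_lods}, \code{granularity}, and the
#'   support/probability vectors of the null distribution.
#' @export
score_distribution <- function(pwm, background = rep(0.25, 4),
                               granularity = 1e-3) {
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    stop("score_distribution: invalid background")
  }
  lods <- log2(pwm$probs / background)
  int_lods <- round(lods / granularity)
  L <- ncol(int_lods)
  col_min <- apply(int_lods, 2, min)
  col_max <- apply(int_lods, 2, max)
  tot_min <- sum(col_min)
  tot_max <- sum(col_max)
  # probability vector indexed by integer score offset from running minimum
  d <- 1
  run_min <- 0
  for (j in seq_len(L)) {
    width <- length(d)
    new <- numeric(width + col_max[j] - col_min[j])
    for (b in 1:4) {
      sh <- int_lods[b, j] - col_min[j]
      new[(sh + 1):(sh + width)] <- new[(sh + 1):(sh + width)] + background[b] * d
    }
    d <- new
    run_min <- run_min + col_min[j]
  }
  support <- seq(tot_min, tot_max)
  upper <- rev(cumsum(rev(d))) # P(S_int >= support[i])
  pv_fun <- function(score) {
    s_int <- round(score / granularity)
    # a continuous score can exceed the rounded-matrix maximum by the
    # accumulated rounding slack (at most L/2 units); clamp within it
    s_int <- ifelse(s_int > tot_max & s_int - tot_max <= ceiling(L / 2),
                    tot_max, s_int)
    i <- s_int - tot_min + 1
    ifelse(i <= 1, 1, ifelse(i > length(upper), 0, upper[pmax(pmin(i, length(upper)), 1)]))
  }
  thr_fun <- function(p) {
    ok <- which(upper <= p)
    if (length(ok) == 0) return(Inf)
    support[min(ok)] * granularity
  }
  structure(list(p_value = pv_fun, score_threshold = thr_fun,
                 int_lods = rbind(int_lods, N = 0), granularity = granularity,
                 support = support * granularity, probs = d,
                 background = background, motif_id = pwm$motif_id),
            class = "PWMScoreDistribution")
}

.revcomp_int_lods <- function(int_lods) {
  # reverse-complement scan: reverse columns, swap A<->T and C<->G rows
  m <- int_lods[c(4, 3, 2, 1, 5), rev(seq_len(ncol(int_lods))), drop = FALSE]
  rownames(m) <- rownames(int_lods)
  m
}

.window_scores <- function(codes, int_lods) {
  L <- ncol(int_lods)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(L)) {
    sc <- sc + int_lods[cbind(codes[i:(n + i - 1)], i)]
  }
  sc
}

#' Estimate a zero-order background from sequences
#' @param seqs Character vector or \code{DNAStringSet}.
#' @return Length-4 probability vector (A, C, G, T); ambiguous bases ignored.
#' @export
sequence_background <- function(seqs) {
  seqs <- as.character(seqs)
  codes <- unlist(lapply(seqs, .encode_seq), use.names = FALSE)
  tab <- tabulate(codes[codes <= 4L], nbins = 4L)
  if (sum(tab) == 0) return(rep(0.25, 4))
  stats::setNames(tab / sum(tab), c("A", "C", "G", "T"))
}

#' Scan sequences with a PWM library
#'
#' All windows on both strands with exact p-value at or below the threshold
#' are reported, together with a per-peak family-presence table and a motif
#' composition summary partitioned by GRE presence.
#'
#' @param seqs Named character vector or \code{DNAStringSet} of peak
#'   sequences.
#' @param library List of \code{PWM} objects (e.g. from \link{read_jaspar}).
#' @param p_threshold Per-window p-value threshold (default 1e-4).
#' @param background Length-4 base probabilities, or NULL to estimate from
#'   the scanned sequences (the default).
#' @param gre_families Family labels treated as GRE-type motifs (default
#'   "GRE"; the NR3C1/NR3C2/AR receptor dimers share this element).
#' @param granularity Score discretization in bits.
#' @return A list of class \code{MotifScan}: \code{hits} (data.frame:
#'   seq_id, motif_id, family, start, end, strand, score, pvalue),
#'   \code{presence} (logical peaks x families matrix), \code{composition}
#'   (data.frame: family, pct_all, pct_gre_present, pct_gre_absent),
#'   \code{gre_present} (logical per peak), and \code{background}.
#' @export
scan_motifs <- function(seqs, library, p_threshold = 1e-4, background = NULL,
                        gre_families = "GRE", granularity = 1e-3) {
  seq_chr <- as.character(seqs)
  if (!is.null(names(seqs))) names(seq_chr) <- names(seqs)
  if (is.null(names(seq_chr)) || any(!nzchar(names(seq_chr)))) {
    names(seq_chr) <- paste0("seq_", seq_along(seq_chr))
  }
  if (length(library) == 0) {
    return(structure(list(
      hits = data.frame(seq_id = character(), motif_id = character(),
                        family = character(), start = integer(),
                        end = integer(), strand = character(),
                        score = numeric(), pvalue = numeric()),
      presence = matrix(FALSE, length(seq_chr), 0,
                        dimnames = list(names(seq_chr), NULL)),
      composition = data.frame(family = character(), pct_all = numeric(),
                               pct_gre_present = numeric(),
                               pct_gre_absent = numeric()),
      gre_present = stats::setNames(rep(FALSE, length(seq_chr)), names(seq_chr)),
      background = background), class = "MotifScan"))
  }
  if (is.null(background)) background <- sequence_background(seq_chr)
  codes_list <- lapply(seq_chr, .encode_seq)
  hit_rows <- list()
  for (m in library) {
    sd <- score_distribution(m, background, granularity)
    thr <- sd$score_threshold(p_threshold)
    if (!is.finite(thr)) next
    thr_int <- round(thr / sd$granularity)
    fw <- sd$int_lods
    rv <- .revcomp_int_lods(fw)
    for (si in seq_along(codes_list)) {
      codes <- codes_list[[si]]
      for (strand in c("+", "-")) {
        mat <- if (strand == "+") fw else rv
        sc <- .window_scores(codes, mat)
        pass <- which(sc >= thr_int)
        if (length(pass)) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            seq_id = names(seq_chr)[si], motif_id = m$motif_id,
            family = m$family, start = pass,
            end = pass + m$length - 1L, strand = strand,
            score = sc[pass] * sd$granularity,
            pvalue = sd$p_value(sc[pass] * sd$granularity),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_id = character(), motif_id = character(),
               family = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(), pvalue = numeric())
  families <- sort(unique(vapply(library, function(m) m$family, "")))
  presence <- matrix(FALSE, length(seq_chr), length(families),
                     dimnames = list(names(seq_chr), families))
  if (nrow(hits)) {
    idx <- cbind(match(hits$seq_id, names(seq_chr)),
                 match(hits$family, families))
    presence[idx] <- TRUE
  }
  gre_cols <- intersect(gre_families, families)
  gre_present <- if (length(gre_cols)) {
    rowSums(presence[, gre_cols, drop = FALSE]) > 0
  } else stats::setNames(rep(FALSE, length(seq_chr)), names(seq_chr))
  pct <- function(rows) {
    if (sum(rows) == 0) return(rep(NA_real_, length(families)))
    100 * colMeans(presence[rows, , drop = FALSE])
  }
  composition <- data.frame(
    family = families,
    pct_all = 100 * colMeans(presence),
    pct_gre_present = pct(gre_present),
    pct_gre_absent = pct(!gre_present),
    stringsAsFactors = FALSE)
  composition <- composition[order(-composition$pct_all), ]
  rownames(composition) <- NULL
  structure(list(hits = hits, presence = presence, composition = composition,
                 gre_present = gre_present, background = background),
            class = "MotifScan")
}

#' @export
print.MotifScan <- function(x, ...) {
  cat(sprintf("MotifScan: %d hits over %d sequences, %d families; GRE present in %.1f%%\n",
              nrow(x$hits), nrow(x$presence), ncol(x$presence),
              100 * mean(x$gre_present)))
  invisible(x)
}

#' Extract peak sequences from chromosome sequences
#'
#' @param peaks \code{GRanges}.
#' @param genome_seq \code{DNAStringSet} named by chromosome.
#' @return Named character vector of sequences (names = chrom:start-end).
#' @export
peak_sequences <- function(peaks, genome_seq) {
  if (is.character(genome_seq)) genome_seq <- Biostrings::DNAStringSet(genome_seq)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(chrom %in% names(genome_seq))) {
    stop("peak_sequences: peak chromosome missing from genome")
  }
  lens <- Biostrings::width(genome_seq)[match(chrom, names(genome_seq))]
  if (any(GenomicRanges::end(peaks) > lens) || any(GenomicRanges::start(peaks) < 1)) {
    stop("peak_sequences: peak beyond sequence bounds")
  }
  out <- as.character(Biostrings::subseq(
    genome_seq[chrom],
    start = GenomicRanges::start(peaks),
    end = GenomicRanges::end(peaks)))
  names(out) <- sprintf("%s:%d-%d", chrom, GenomicRanges::start(peaks),
                        GenomicRanges::end(peaks))
  out
}
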