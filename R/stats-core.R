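#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: for p-values sorted increasingly,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, capped at 1 and mapped back
#' to the input order.
#'
#' @param pvalues Numeric vector of p-values, all in \[0, 1\].
#' @return A list with components \code{raw} (the input) and \code{adjusted}
#'   (BH-adjusted values, same order).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("bh_adjust: empty p-value vector")
  if (anyNA(pvalues)) stop("bh_adjust: NA p-values not allowed")
  if (any(pvalues < 0 | pvalues > 1)) stop("bh_adjust: p-values must lie in [0, 1]")
  list(raw = pvalues, adjusted = stats::p.adjust(pvalues, method = "BH"))
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric test computed with log-space factorials so that
#' p-values far below double underflow of the naive product (down to about
#' 1e-300) remain representable. The two-sided p-value sums the probabilities
#' of all tables, under the fixed margins, that are no more probable than the
#' observed one (mid-p is not used); \code{alternative = "greater"} gives the
#' upper hypergeometric tail of cell \code{a}.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are membership in
#'   set 1, columns membership in set 2.
#' @param alternative \code{"two_sided"} (default) or \code{"greater"}.
#' @return A list with \code{p} and logical \code{degenerate} (TRUE when a
#'   row or column margin is zero, in which case p = 1 with a warning).
#' @examples
#' fisher_exact(5, 0, 0, 5, alternative = "greater")$p  # 1 / choose(10, 5)
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact: cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("fisher_exact: total count is zero")
  m1 <- a + b # row 1 margin
  k1 <- a + c # column 1 margin
  if (m1 == 0 || m1 == n || k1 == 0 || k1 == n) {
    warning("fisher_exact: degenerate margin, p = 1")
    return(list(p = 1, degenerate = TRUE))
  }
  lo <- max(0L, k1 - (n - m1))
  hi <- min(m1, k1)
  support <- lo:hi
  logp <- stats::dhyper(support, m1, n - m1, k1, log = TRUE)
  log_obs <- stats::dhyper(a, m1, n - m1, k1, log = TRUE)
  p <- if (alternative == "greater") {
    sum(exp(logp[support >= a] - log_obs)) * exp(log_obs)
  } else {
    # relative tolerance guards ties against floating-point noise
    keep <- logp <= log_obs + 1e-7
    sum(exp(logp[keep] - log_obs)) * exp(log_obs)
  }
  list(p = min(1, p), degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of freedom;
#' for \eqn{n \le 9} with untied data the exact permutation p-value is
#' computed instead, which also covers the \eqn{\rho = \pm 1} boundary where
#' the t statistic degenerates.
#'
#' @param x,y Numeric vectors of equal length \eqn{\ge 3}; ties allowed.
#' @return A list with \code{rho}, \code{n} and \code{pvalue} (two-sided).
#' @examples
#' spearman_cor(1:4, c(2, 1, 4, 3))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: unequal lengths")
  n <- length(x)
  if (n < 3) stop("spearman_cor: need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("spearman_cor: NA values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_cor: constant input, correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  no_ties <- !anyDuplicated(rx) && !anyDuplicated(ry)
  if (n <= 9 && no_ties) {
    pvalue <- .spearman_perm_p(rx, ry, rho)
  } else if (abs(rho) >= 1 - 1e-12) {
    # tied data at the boundary: fall back on the permutation floor 2/n!
    pvalue <- min(1, 2 / factorial(min(n, 170)))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pvalue <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, n = n, pvalue = max(pvalue, .Machine$double.xmin))
}

# Exact two-sided permutation p-value for Spearman's rho, untied ranks, n <= 9.
.spearman_perm_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- .all_permutations(n)
  # rho is a decreasing affine function of sum of squared rank differences,
  # so compare |rho| directly across all n! pairings
  mu <- (n + 1) / 2
  denom <- sum((rx - mu)^2)
  rhos <- as.vector(perms %*% (ry - mu)) # perms holds permuted rx values
  rhos <- (rhos - 0) / denom
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

.all_permutations <- function(n) {
  # rows = n! permutations of centered ranks 1..n
  perm_idx <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    sub <- perm_idx(k - 1L)
    out <- matrix(0L, nrow(sub) * k, k)
    for (i in seq_len(k)) {
      rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
      out[rows, 1L] <- i
      rest <- seq_len(k)[-i]
      out[rows, -1L] <- matrix(rest[sub], nrow(sub), k - 1L)
    }
    out
  }
  idx <- perm_idx(n)
  matrix((seq_len(n) - (n + 1) / 2)[idx], nrow(idx), n)
}

#' One-way ANOVA with Dunnett's comparisons against a control group
#'
#' Classical one-way ANOVA (F = MSB/MSW against F(k-1, N-k)) followed by
#' Dunnett-style many-to-one comparisons. The Dunnett adjustment is computed
#' by seeded Monte Carlo sampling of the null distribution of the maximum
#' absolute Dunnett t statistic (an approximation to the exact multivariate-t
#' quantile; accuracy ~ 1/sqrt(nsim) in the tail probability).
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @param control_index 1-based index of the control group.
#' @param seed Integer seed for the Monte Carlo draw (required).
#' @param nsim Number of Monte Carlo draws (default 1e5).
#' @return List with \code{F}, \code{p} (omnibus), \code{df}, and a data frame
#'   \code{dunnett} with per-group t statistics, raw two-sample p, and
#'   Monte-Carlo adjusted p versus the control.
#' @export
one_way_anova_dunnett <- function(groups, control_index = 1L, seed, nsim = 1e5) {
  if (missing(seed)) stop("one_way_anova_dunnett: seed is required")
  k <- length(groups)
  if (k < 2) stop("one_way_anova_dunnett: need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("one_way_anova_dunnett: each group needs >= 2 values")
  if (control_index < 1 || control_index > k) stop("invalid control_index")
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  means <- vapply(groups, mean, 0)
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2),
                dunnett = .dunnett_frame(k, control_index, NA, NA, NA)))
  }
  if (ssw == 0) {
    warning("one_way_anova_dunnett: zero within-group variance, p = 0")
    return(list(F = Inf, p = 0, df = c(df1, df2),
                dunnett = .dunnett_frame(k, control_index, Inf, 0, 0)))
  }
  msw <- ssw / df2
  Fstat <- (ssb / df1) / msw
  p_overall <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  others <- setdiff(seq_len(k), control_index)
  n0 <- sizes[control_index]
  tstat <- (means[others] - means[control_index]) /
    sqrt(msw * (1 / sizes[others] + 1 / n0))
  p_raw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  # Monte-Carlo null of max |t| over the correlated many-to-one family:
  # t_i = (Z_i/sqrt(n_i) - Z_c/sqrt(n0)) / sqrt(s2 * (1/n_i + 1/n0))
  set.seed(seed)
  z0 <- matrix(stats::rnorm(nsim * length(others)), nsim, length(others))
  zc <- stats::rnorm(nsim)
  s2 <- stats::rchisq(nsim, df2) / df2
  num <- sweep(z0, 2, sqrt(1 / sizes[others]), `*`) - zc * sqrt(1 / n0)
  den <- sqrt(s2 %o% (1 / sizes[others] + 1 / n0))
  tmax <- apply(abs(num / den), 1, max)
  p_adj <- vapply(abs(tstat), function(tt) mean(tmax >= tt), 0)
  p_adj <- pmax(p_adj, p_raw) # multiplicity never reduces evidence
  list(F = Fstat, p = p_overall, df = c(df1, df2),
       dunnett = data.frame(group = others, t = as.vector(tstat),
                            p_raw = as.vector(p_raw), p_adj = p_adj))
}

.dunnett_frame <- function(k, control_index, t, p_raw, p_adj) {
  others <- setdiff(seq_len(k), control_index)
  data.frame(group = others, t = rep(t, length(others)),
             p_raw = rep(p_raw, length(others)), p_adj = rep(p_adj, length(others)))
}

#' Jaccard similarity of two identifier sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; reported as a fraction in \[0, 1\]
#' (multiply by 100 for the percentage form). Two empty sets are defined as
#' identical (1.0) with a warning.
#'
#' @param a,b Vectors of identifiers (coerced to character, deduplicated).
#' @return Numeric scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0) {
    warning("jaccard_index: both sets empty, returning 1")
    return(1)
  }
  length(intersect(a, b)) / length(u)
}
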