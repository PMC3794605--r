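#' Upper-tail binomial probability for motif enrichment
#'
#' Computes \eqn{P(X \ge M)} for \eqn{X \sim Binomial(N, f)}: the probability
#' of observing at least \code{M} occurrences of a k-mer among \code{N}
#' foreground windows when the k-mer's background frequency is \code{f}.
#' Evaluated through the survival function so it is numerically stable for
#' \code{N} up to millions of windows.
#'
#' @param M Observed occurrence count of the motif (0 <= M <= N).
#' @param N Total number of k-mer windows in the foreground.
#' @param f Background frequency of the motif, a probability.
#' @return Upper-tail p-value(s). Vectorised over \code{M}, \code{N}, \code{f}.
#' @export
binomial_uppertail <- function(M, N, f) {
  if (any(f < 0 | f > 1)) stop("background frequency f must lie in [0, 1]")
  if (any(M < 0 | M > N)) stop("require 0 <= M <= N")
  stats::pbinom(M - 1, N, f, lower.tail = FALSE)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of drawing at least \code{observed} members of a category of
#' size \code{category_size} when \code{draws} items are sampled without
#' replacement from a universe of \code{universe} items.
#'
#' @param observed Number of drawn items falling in the category.
#' @param category_size Category size within the universe.
#' @param universe Universe size.
#' @param draws Number of items drawn.
#' @return A list with \code{statistic} (the observed count), \code{p_value}
#'   and \code{n} (the number of draws).
#' @export
hypergeom_enrichment <- function(observed, category_size, universe, draws) {
  if (draws > universe || category_size > universe)
    stop("category and draws must fit inside the universe")
  if (observed > min(category_size, draws))
    stop("observed count exceeds category size or number of draws")
  p <- stats::phyper(observed - 1, category_size, universe - category_size,
                     draws, lower.tail = FALSE)
  list(statistic = observed, p_value = p, n = draws)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; preserves input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return \code{min(1, p * n)} in the input order.
#' @export
bonferroni <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Welch two-sample t-test with zero-variance conventions
#'
#' Two-sided Welch (unequal variance) t-test between two replicate groups.
#' Degenerate inputs common in noise-free simulations are handled by
#' convention: if both groups have zero variance the p-value is 1 when the
#' means agree and 0 when they differ.
#'
#' @param a,b Numeric vectors of replicate values (each of length >= 2).
#' @return A list with \code{statistic} (sign = mean(a) - mean(b)),
#'   \code{p_value} and \code{n}.
#' @export
probe_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per group")
  d <- mean(a) - mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (d == 0) return(list(statistic = 0, p_value = 1, n = length(a) + length(b)))
    return(list(statistic = sign(d) * Inf, p_value = 0, n = length(a) + length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(a) + length(b))
}

#' Row-wise Welch t-tests for probe matrices
#'
#' Vectorised Welch test for each row of a value matrix split into two
#' sample groups, with the same zero-variance conventions as
#' \code{\link{probe_t_test}}.
#'
#' @param x Numeric matrix (rows = probes/exons, columns = samples).
#' @param group Logical or factor-like vector over columns; \code{TRUE} (or
#'   the first level) defines group A.
#' @return A data.frame with \code{delta} (mean A - mean B), \code{statistic},
#'   \code{df} and \code{p_value} per row.
#' @export
row_welch_t <- function(x, group) {
  g <- as.logical(group)
  if (sum(g) < 2 || sum(!g) < 2) stop("need >= 2 replicates per group")
  A <- x[, g, drop = FALSE]; B <- x[, !g, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    p[zero] <- 0; p[eq] <- 1
    tt[zero] <- sign(ma[zero] - mb[zero]) * Inf; tt[eq] <- 0
    df[zero] <- NA_real_
  }
  data.frame(delta = ma - mb, statistic = tt, df = df, p_value = p)
}

#' Permutation estimate of the probe-level false-discovery rate
#'
#' Re-labels the sample columns and recomputes the per-probe test; the FDR is
#' the average number of probes passing the p-value threshold under permuted
#' labels divided by the number passing under the true labels. Balanced
#' label splits are enumerated exhaustively when there are at most
#' \code{max_exhaustive} of them (20 for a 3-vs-3 design), otherwise sampled.
#'
#' @param x Numeric probe-by-sample matrix.
#' @param group Logical vector over columns defining the two tissues.
#' @param threshold Per-probe p-value cutoff.
#' @param n_perm Number of permutations when sampling is needed.
#' @param seed Integer seed used only when sampling permutations.
#' @param test Row-wise testing function, defaulting to \code{row_welch_t}.
#' @param max_exhaustive Enumerate all balanced splits when their count is at
#'   most this value.
#' @return A list with \code{fdr}, \code{n_pass_true} and \code{n_perm_used}.
#' @export
permutation_fdr <- function(x, group, threshold = 0.005, n_perm = 100,
                            seed = 1, test = row_welch_t,
                            max_exhaustive = 100) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  g <- as.logical(group)
  n <- length(g); k <- sum(g)
  obs <- sum(test(x, g)$p_value < threshold)
  all_splits <- utils::combn(n, k)
  if (ncol(all_splits) <= max_exhaustive) {
    idx <- seq_len(ncol(all_splits))
  } else {
    set.seed(seed)
    idx <- sample.int(ncol(all_splits), n_perm)
  }
  pass <- vapply(idx, function(i) {
    gp <- rep(FALSE, n); gp[all_splits[, i]] <- TRUE
    sum(test(x, gp)$p_value < threshold)
  }, numeric(1))
  list(fdr = mean(pass) / max(1, obs), n_pass_true = obs,
       n_perm_used = length(idx))
}

#' Two-proportion z-test
#'
#' Two-sided z-test (pooled variance, no continuity correction) for
#' H0: p1 = p2 given successes \code{k1}/\code{n1} and \code{k2}/\code{n2}.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @return A list with \code{statistic} (the z value), \code{p_value} and
#'   \code{n}.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both sample sizes must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) stop("require 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pb <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)), n = n1 + n2)
}
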