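# Entropy / mutual-information machinery and the contingency-table tests
# used by QC and the single-SNP baseline.  All entropies are in bits
# (base-2 logs); normalized quantities are base-invariant.

#' Binary class entropy
#'
#' Shannon entropy, in bits, of the case/control composition of a sample
#' set.  This is the node impurity underlying [discriminating_score()].
#'
#' @param n_case,n_control Non-negative counts of cases and controls.
#' @return Entropy in bits, a value in `[0, 1]`.
#' @examples
#' class_entropy(4, 4)  # 1 bit
#' class_entropy(5, 0)  # 0 bits
#' @export
class_entropy <- function(n_case, n_control) {
  if (n_case < 0 || n_control < 0) stop("class counts must be non-negative")
  n <- n_case + n_control
  if (n == 0) stop("empty class counts: entropy undefined")
  p <- c(n_case, n_control) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Split quality of a candidate cut-point
#'
#' Information gain, in bits, of partitioning a parent sample set into a
#' left and a right child: the parent class entropy minus the
#' size-weighted child entropies.  This is the score maximized when a
#' cut-point is chosen, both inside embedded trees and at meta-nodes.
#'
#' @param parent,left,right Length-2 numeric vectors `c(n_case, n_control)`;
#'   `left + right` must equal `parent` componentwise.
#' @return Gain in bits, in `[0, H(parent)]`; an empty child contributes 0.
#' @examples
#' discriminating_score(c(4, 4), c(4, 0), c(0, 4))  # perfect split: 1 bit
#' @export
discriminating_score <- function(parent, left, right) {
  if (length(parent) != 2L || length(left) != 2L || length(right) != 2L)
    stop("counts must be length-2 vectors c(n_case, n_control)")
  if (any(left + right != parent))
    stop("inconsistent counts: left + right must equal parent")
  if (sum(parent) == 0) stop("empty parent set")
  n <- sum(parent)
  h_child <- function(cc) if (sum(cc) == 0) 0 else sum(cc) / n * class_entropy(cc[1], cc[2])
  class_entropy(parent[1], parent[2]) - h_child(left) - h_child(right)
}

#' Mutual information of a joint count table
#'
#' @param table An r x s matrix of non-negative joint occurrence counts
#'   with at least one positive entry.
#' @return Mutual information in bits (non-negative).
#' @examples
#' mutual_information(matrix(c(2, 0, 0, 2), 2))  # identical variables: 1 bit
#' @export
mutual_information <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("joint counts must be non-negative")
  n <- sum(table)
  if (n == 0) stop("all-zero joint table")
  p <- table / n
  px <- rowSums(p)
  py <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  pxy <- p[idx]
  sum(pxy * log2(pxy / (px[idx[, 1]] * py[idx[, 2]])))
}

marginal_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information
#'
#' Mutual information divided by the maximum of the two marginal
#' entropies; a base-invariant fraction in `[0, 1]`.  This is the
#' similarity used both to cluster SNPs and to validate latent variables.
#'
#' @inheritParams mutual_information
#' @return A fraction in `[0, 1]`.
#' @export
normalized_mi <- function(table) {
  table <- as.matrix(table)
  n <- sum(table)
  if (n == 0) stop("all-zero joint table")
  hx <- marginal_entropy(rowSums(table) / n)
  hy <- marginal_entropy(colSums(table) / n)
  if (hx == 0 || hy == 0)
    stop("normalized MI undefined for a constant margin (zero entropy)")
  mi <- mutual_information(table)
  min(1, max(0, mi / max(hx, hy)))
}

check_2x3 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 3L))) stop("expected a 2x3 case/control x genotype table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0)) stop("degenerate table: a zero row")
  table
}

#' Cochran-Armitage trend test
#'
#' One-degree-of-freedom trend test on a 2x3 case/control x genotype
#' table, with allele-dosage scores (0, 1, 2) and no continuity
#' correction; the p-value comes from the chi-squared distribution with
#' 1 df.
#'
#' @param table 2x3 matrix: rows = (case, control), columns = genotype
#'   0/1/2 counts.
#' @return A list with `statistic` and `p.value`.
#' @export
trend_test <- function(table) {
  table <- check_2x3(table)
  if (sum(colSums(table) > 0) < 2L)
    stop("degenerate table: fewer than two genotype classes observed")
  stat <- trend_stat_rows(rbind(table[1, ]), rbind(table[2, ]))
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Vectorized Cochran-Armitage statistic: `cases` and `controls` are
# m x 3 matrices of genotype counts, one row per SNP.  Returns NA for
# rows where the score variance is zero (monomorphic tables).
trend_stat_rows <- function(cases, controls) {
  s <- c(0, 1, 2)
  tot <- cases + controls
  n <- rowSums(tot)
  r1 <- rowSums(cases)
  sr <- as.vector(cases %*% s)
  sc <- as.vector(tot %*% s)
  sc2 <- as.vector(tot %*% s^2)
  num <- (n * sr - r1 * sc)^2 * n
  den <- r1 * (n - r1) * (n * sc2 - sc^2)
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' General (2 df) chi-squared genotype test
#'
#' Pearson chi-squared test on a 2x3 case/control x genotype table.
#' Genotype columns with zero total are dropped and the degrees of
#' freedom collapse accordingly (a 2x2 table gives a 1-df test).
#'
#' @inheritParams trend_test
#' @return A list with `statistic`, `p.value` and `df`.
#' @export
general_chi2_test <- function(table) {
  table <- check_2x3(table)
  keep <- colSums(table) > 0
  if (sum(keep) < 2L)
    stop("degenerate table: fewer than two genotype classes observed")
  t2 <- table[, keep, drop = FALSE]
  expected <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  stat <- sum((t2 - expected)^2 / expected)
  df <- ncol(t2) - 1L
  list(statistic = stat, p.value = pchisq(stat, df = df, lower.tail = FALSE), df = df)
}

# Vectorized Pearson chi-squared over m x 3 count matrices (df collapse
# for empty genotype columns).  Returns list(stat, df); NA stat when the
# table is degenerate.
chi2_stat_rows <- function(cases, controls) {
  m <- nrow(cases)
  tot <- cases + controls
  n <- rowSums(tot)
  r1 <- rowSums(cases)
  stat <- numeric(m)
  df <- integer(m)
  for (j in 1:3) {
    cj <- tot[, j]
    e1 <- r1 * cj / n
    e0 <- (n - r1) * cj / n
    term <- ifelse(cj > 0, (cases[, j] - e1)^2 / pmax(e1, .Machine$double.eps) +
                     (controls[, j] - e0)^2 / pmax(e0, .Machine$double.eps), 0)
    stat <- stat + term
    df <- df + as.integer(cj > 0)
  }
  df <- pmax(df - 1L, 0L)
  stat[df == 0L] <- NA_real_
  list(stat = stat, df = df)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact HWE test by full enumeration of heterozygote counts
#' conditional on the observed allele counts, summing the probabilities
#' of all configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous major, heterozygous,
#'   homozygous minor).
#' @return Exact two-sided p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty genotype counts")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  rare_hom <- min(n_AA, n_aa)
  # all heterozygote counts sharing the parity of n_rare and feasible
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log-probabilities of each configuration (conditional on allele counts)
  log_prob <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_com <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) - lgamma(hom_com + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- which(hets == n_Aa)
  if (length(obs) == 0) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
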