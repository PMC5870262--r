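# Genotype quality control (simulated-data and WTCCC-style rule sets)
# and the single-SNP association baseline.

#' QC rule sets
#'
#' Two presets.  `simulated`: remove SNPs with MAF < 0.05 or exact HWE
#' p < 0.001.  `wtccc`: remove SNPs with missingness > 5%, missingness
#' > 1% together with MAF < 5%, exact HWE p < 5.7e-7, or trend / general
#' association p < 5.7e-7 (association rules computed on the combined
#' cohort).
#'
#' @param name `"simulated"` or `"wtccc"`.
#' @return A list of thresholds (class `qc_rules`); disabled rules are `NA`.
#' @export
qc_rules <- function(name = c("simulated", "wtccc")) {
  name <- match.arg(name)
  rules <- switch(name,
    simulated = list(maf_min = 0.05, hwe_p_min = 0.001, miss_max = NA,
                     miss_max_if_rare = NA, maf_min_if_missing = NA,
                     assoc_p_min_trend = NA, assoc_p_min_general = NA),
    wtccc = list(maf_min = NA, hwe_p_min = 5.7e-7, miss_max = 0.05,
                 miss_max_if_rare = 0.01, maf_min_if_missing = 0.05,
                 assoc_p_min_trend = 5.7e-7, assoc_p_min_general = 5.7e-7))
  structure(c(list(name = name), rules), class = "qc_rules")
}

#' Minor allele frequency of a genotype row
#'
#' @param g Integer vector of 0/1/2 codes (`NA` = missing).
#' @return `min(f, 1 - f)` where `f` is the frequency of the counted
#'   allele over non-missing genotypes.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("all genotypes missing: MAF undefined")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

# Per-SNP 2x3 genotype count matrices (cases and controls separately).
genotype_counts <- function(ds) {
  case <- is_case(ds)
  g <- ds$genotypes
  count3 <- function(m) {
    cbind(rowSums(m == 0L, na.rm = TRUE),
          rowSums(m == 1L, na.rm = TRUE),
          rowSums(m == 2L, na.rm = TRUE))
  }
  list(cases = count3(g[, case, drop = FALSE]),
       controls = count3(g[, !case, drop = FALSE]))
}

#' Apply a QC rule set to a dataset
#'
#' A SNP is removed iff it violates at least one enabled rule; the order
#' of retained SNPs is preserved and every removed SNP carries its
#' reasons.
#'
#' @param ds A [genotype_dataset()].
#' @param rules A [qc_rules()] preset.
#' @return A list with `dataset` (filtered), `removed` (a `data.frame`
#'   of `snp_id` and comma-separated `reasons`), and `kept_index` (the
#'   original row indices of the retained SNPs).
#' @export
apply_qc <- function(ds, rules = qc_rules("simulated")) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(rules, "qc_rules"))
  n <- n_snps(ds)
  if (n == 0L) stop("empty dataset")
  g <- ds$genotypes
  n_obs <- rowSums(!is.na(g))
  miss <- 1 - n_obs / ncol(g)
  maf <- vapply(seq_len(n), function(i) {
    if (n_obs[i] == 0L) return(NA_real_)
    compute_maf(g[i, ])
  }, numeric(1))
  cc <- genotype_counts(ds)
  tot <- cc$cases + cc$controls
  hwe_p <- vapply(seq_len(n), function(i) {
    if (n_obs[i] == 0L) return(NA_real_)
    # counts by code: 0 = hom major of the counted allele convention
    hwe_exact_test(tot[i, 1L], tot[i, 2L], tot[i, 3L])
  }, numeric(1))

  reasons <- vector("list", n)
  add <- function(idx, tag) for (i in idx) reasons[[i]] <<- c(reasons[[i]], tag)
  add(which(n_obs == 0L), "all_missing")
  if (!is.na(rules$maf_min)) add(which(maf < rules$maf_min), "maf")
  if (!is.na(rules$hwe_p_min)) add(which(hwe_p < rules$hwe_p_min), "hwe")
  if (!is.na(rules$miss_max)) add(which(miss > rules$miss_max), "missingness")
  if (!is.na(rules$miss_max_if_rare))
    add(which(miss > rules$miss_max_if_rare & maf < rules$maf_min_if_missing),
        "missingness_rare")
  if (!is.na(rules$assoc_p_min_trend) || !is.na(rules$assoc_p_min_general)) {
    tr <- trend_stat_rows(cc$cases, cc$controls)
    p_tr <- pchisq(tr, df = 1, lower.tail = FALSE)
    ch <- chi2_stat_rows(cc$cases, cc$controls)
    p_ch <- pchisq(ch$stat, df = ch$df, lower.tail = FALSE)
    if (!is.na(rules$assoc_p_min_trend))
      add(which(!is.na(p_tr) & p_tr < rules$assoc_p_min_trend), "assoc_trend")
    if (!is.na(rules$assoc_p_min_general))
      add(which(!is.na(p_ch) & p_ch < rules$assoc_p_min_general), "assoc_general")
  }
  removed <- which(vapply(reasons, length, 1L) > 0L)
  kept <- setdiff(seq_len(n), removed)
  removed_df <- data.frame(
    snp_id = ds$snps$snp_id[removed],
    reasons = vapply(reasons[removed], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  out <- genotype_dataset(ds$snps[kept, , drop = FALSE],
                          ds$genotypes[kept, , drop = FALSE],
                          ds$phenotype, ds$individual_ids)
  list(dataset = out, removed = removed_df, kept_index = kept)
}

#' Single-SNP association scan
#'
#' Tests each SNP for association with case/control status on its 2x3
#' genotype table (built over non-missing genotypes) and ranks SNPs by
#' ascending p-value; ties keep dataset order.  Monomorphic SNPs are
#' assigned p = 1.
#'
#' @param ds A (QC'd) [genotype_dataset()].
#' @param test `"general"` (2-df Pearson chi-squared, the default) or
#'   `"trend"` (1-df Cochran-Armitage).
#' @return A `data.frame` with `snp_id`, `statistic`, `p_value`, `rank`,
#'   in dataset order.
#' @export
single_snp_scan <- function(ds, test = c("general", "trend")) {
  test <- match.arg(test)
  cc <- genotype_counts(ds)
  if (test == "trend") {
    stat <- trend_stat_rows(cc$cases, cc$controls)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    ch <- chi2_stat_rows(cc$cases, cc$controls)
    stat <- ch$stat
    p <- pchisq(stat, df = ch$df, lower.tail = FALSE)
  }
  stat[is.na(stat)] <- 0
  p[is.na(p)] <- 1
  ord <- order(p, seq_along(p))
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  data.frame(snp_id = ds$snps$snp_id, statistic = stat, p_value = p,
             rank = rank, stringsAsFactors = FALSE)
}
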