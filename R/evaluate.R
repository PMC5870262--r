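# Evaluation harness: top-k causal recovery, cross-validated predictive
# power (AUC), importance-distribution comparison, and top-100
# intersections across GWAS strategies.

#' Top-k recovery of planted causal SNPs
#'
#' For each k, the percentage of causal SNPs ranked in the top k,
#' pooled over replicates: `100 * sum_r |causal_r intersect top-k_r| /
#' sum_r |causal_r|`.
#'
#' @param rankings List (one per replicate) of `data.frame`s with
#'   `snp_id` and `rank`.
#' @param causal_ids List (one per replicate) of causal SNP id vectors.
#' @param ks Integer vector of list sizes (default the reference grid).
#' @return `data.frame` with `k` and `percent` (non-decreasing in `k`).
#' @export
topk_recovery <- function(rankings, causal_ids,
                          ks = c(25, 50, 100, 200, 1000)) {
  stopifnot(length(rankings) == length(causal_ids))
  total <- sum(lengths(causal_ids))
  percent <- vapply(ks, function(k) {
    found <- 0L
    for (r in seq_along(rankings)) {
      rk <- rankings[[r]]
      kk <- min(k, nrow(rk))
      top <- rk$snp_id[rk$rank <= kk]
      found <- found + length(intersect(top, causal_ids[[r]]))
    }
    100 * found / total
  }, numeric(1))
  data.frame(k = ks, percent = percent)
}

#' ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen case receives a higher score than
#' a randomly chosen control, ties credited 0.5.
#'
#' @param scores Numeric predictions.
#' @param labels Logical or 0/1 vector (TRUE/1 = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, individuals are
# shuffled and dealt round-robin into n_folds.
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated AUC of a forest
#'
#' Stratified k-fold cross-validation: the cluster map is built once on
#' the full dataset and reused for every fold; per fold, a forest is
#' fitted on the training 9/10 and the held-out tenth is scored.
#'
#' @param ds A [genotype_dataset()].
#' @param map A [cluster_map()] (shared across folds).
#' @param params A [forest_params()].
#' @param n_folds Number of folds.
#' @param seed Master seed (fold assignment and per-fold forests).
#' @return A list of class `cv_result`: `fold_auc`, `mean_auc`, `folds`.
#' @export
cross_validate <- function(ds, map, params = forest_params(preset = "desk"),
                           n_folds = 10, seed = 1) {
  y <- is_case(ds)
  fold <- stratified_folds(ds$phenotype, n_folds, seed)
  aucs <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    train_ds <- subset_individuals(ds, !test)
    test_ds <- subset_individuals(ds, test)
    forest <- fit_forest(train_ds, map, params, seed = seed + 1000L * f)
    p <- predict_proba(forest, test_ds)
    aucs[f] <- roc_auc(p, is_case(test_ds))
  }
  structure(list(fold_auc = aucs, mean_auc = mean(aucs), folds = fold),
            class = "cv_result")
}

#' Subset a dataset by individuals
#'
#' @param ds A [genotype_dataset()].
#' @param keep Logical or integer index over individuals.
#' @return A [genotype_dataset()] with the selected individuals.
#' @export
subset_individuals <- function(ds, keep) {
  genotype_dataset(ds$snps, ds$genotypes[, keep, drop = FALSE],
                   ds$phenotype[keep], ds$individual_ids[keep])
}

#' Compare two importance distributions
#'
#' Two-sided Wilcoxon rank-sum test on the two score samples, Pearson
#' correlation on the paired scores, and a quantile table at 25/50/75%
#' plus the quantile positions matching the top-300/200/100/50/20/10
#' lists and the maximum.
#'
#' @param v1,v2 Numeric score vectors over the same SNP universe (equal
#'   length, aligned).
#' @return A list of class `importance_comparison`: `wilcoxon`
#'   (statistic, p.value), `pearson_r`, `quantiles` (a `data.frame`).
#' @export
compare_importances <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("importance vectors must cover the same SNP universe")
  n <- length(v1)
  w <- wilcox.test(as.numeric(v1), as.numeric(v2))
  tops <- c(300, 200, 100, 50, 20, 10)
  tops <- tops[tops < n]
  top_labels <- if (length(tops)) paste0("top", tops) else character(0)
  probs <- c(0.25, 0.50, 0.75, 1 - tops / n, 1)
  labels <- c("25%", "50%", "75%", top_labels, "max")
  q <- data.frame(label = labels, prob = probs,
                  v1 = as.numeric(quantile(v1, probs)),
                  v2 = as.numeric(quantile(v2, probs)))
  structure(list(wilcoxon = list(statistic = unname(w$statistic),
                                 p.value = w$p.value),
                 pearson_r = cor(as.numeric(v1), as.numeric(v2)),
                 quantiles = q),
            class = "importance_comparison")
}

#' Top-n intersections across rankings
#'
#' Pairwise and full intersections of the top-n SNP sets of two or more
#' named rankings; for each jointly-top-n SNP the maximum rank across
#' methods; and the top*m membership (SNPs with max-rank <= m) for any
#' m.
#'
#' @param rankings Named list of `data.frame`s with `snp_id` and `rank`
#'   over the same SNPs.
#' @param n Top-list size (default 100).
#' @return A list of class `intersection_report`: `top_sets`,
#'   `pairwise` (`data.frame` of method pairs and intersection sizes),
#'   `joint` (`data.frame` of jointly-top-n SNPs with per-method ranks
#'   and `max_rank`, ascending), `n`.  Use `joint$snp_id[joint$max_rank
#'   <= m]` for the top*m set.
#' @export
top_intersections <- function(rankings, n = 100) {
  if (n < 1) stop("n must be >= 1")
  if (length(rankings) < 2L) stop("need at least two rankings")
  if (is.null(names(rankings)) || any(names(rankings) == ""))
    stop("rankings must be named")
  top_sets <- lapply(rankings, function(r) r$snp_id[r$rank <= n])
  methods <- names(rankings)
  pairs <- utils::combn(methods, 2)
  pairwise <- data.frame(
    method1 = pairs[1, ], method2 = pairs[2, ],
    size = apply(pairs, 2, function(pr)
      length(intersect(top_sets[[pr[1]]], top_sets[[pr[2]]]))))
  joint_ids <- Reduce(intersect, top_sets)
  rank_of <- function(r, ids) r$rank[match(ids, r$snp_id)]
  joint <- data.frame(snp_id = joint_ids, stringsAsFactors = FALSE)
  for (m in methods) joint[[paste0("rank_", m)]] <- rank_of(rankings[[m]], joint_ids)
  joint$max_rank <- if (nrow(joint)) apply(joint[, -1, drop = FALSE], 1, max)
                    else integer(0)
  joint <- joint[order(joint$max_rank), , drop = FALSE]
  rownames(joint) <- NULL
  structure(list(top_sets = top_sets, pairwise = pairwise, joint = joint,
                 n = n),
            class = "intersection_report")
}
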