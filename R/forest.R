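# The "trees inside trees" ensemble: bagged meta-trees whose nodes embed
# Extra-trees grown on blocks/clusters of SNPs; split on the embedded
# tree's leaf case probability (the meta-variable).  Heavy lifting is in
# compiled code; this file is parameterization, wrappers, prediction and
# importance.

#' Forest parameters
#'
#' Defaults are the full-scale settings (1000 meta-trees, meta-leaf
#' threshold 2000 observations, 1000 candidate clusters per meta-node,
#' embedded trees of at most 5 split nodes, every SNP of a drawn cluster
#' a candidate).  `preset = "desk"` scales the ensemble down (T = 50,
#' K = 100, S_n = 250) for desk-size experiments.
#'
#' @param n_trees Number of meta-trees (T).
#' @param S_n Meta-leaf threshold: a meta-node with fewer observations
#'   becomes a leaf.
#' @param S_t Meta-tree split-node budget (`Inf` = no budget).
#' @param K Clusters drawn (without replacement) per meta-node.
#' @param s_n Embedded-tree leaf threshold (observations).
#' @param s_t Embedded-tree split-node budget.
#' @param k Variables drawn per embedded-tree node; `"all"` uses every
#'   SNP of the cluster (the hybrid/T-Trees equal-footing policy).
#' @param B Contiguous block size for [make_block_map()].
#' @param preset `"full"` or `"desk"`.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 1000, S_n = 2000, S_t = Inf, K = 1000,
                          s_n = 1, s_t = 5, k = "all", B = 20,
                          preset = c("full", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    if (missing(n_trees)) n_trees <- 50
    if (missing(K)) K <- 100
    if (missing(S_n)) S_n <- 250
  }
  stopifnot(n_trees >= 1, S_n >= 2, K >= 1, s_n >= 1, s_t >= 1, B >= 1)
  k_num <- if (identical(k, "all")) 0L else as.integer(k)
  structure(list(n_trees = as.integer(n_trees), S_n = as.integer(S_n),
                 S_t = S_t, K = as.integer(K), s_n = as.integer(s_n),
                 s_t = as.integer(s_t), k = k_num, B = as.integer(B)),
            class = "forest_params")
}

#' Contiguous block map
#'
#' Partitions the (coordinate-sorted) SNPs into consecutive blocks of
#' `B`; the last block may be shorter.
#'
#' @param ds A [genotype_dataset()].
#' @param B Block size.
#' @return A [cluster_map()] with provenance `contiguous_blocks`.
#' @export
make_block_map <- function(ds, B = 20) {
  if (B < 1) stop("block size must be >= 1")
  n <- n_snps(ds)
  cluster_map(split(seq_len(n), ceiling(seq_len(n) / B)),
              n_snps = n, provenance = "contiguous_blocks")
}

# Mode imputation of missing genotypes, per SNP (ties -> smallest code).
# Returns list(X = individuals x SNPs complete integer matrix, modes).
impute_mode <- function(ds) {
  g <- ds$genotypes
  modes <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    if (anyNA(gi)) {
      tab <- tabulate(gi + 1L, 3L)
      modes[i] <- which.max(tab) - 1L
      gi[is.na(gi)] <- modes[i]
      g[i, ] <- gi
    } else {
      modes[i] <- which.max(tabulate(gi + 1L, 3L)) - 1L
    }
  }
  X <- t(g)
  storage.mode(X) <- "integer"
  list(X = X, modes = modes)
}

#' Grow one Extra-tree
#'
#' Recursive extremely randomized tree on a set of candidate variables:
#' at each node, `k` variables are drawn without replacement, one uniform
#' threshold is drawn in the (min, max) of each non-constant variable,
#' and the cut maximizing [discriminating_score()] is kept (ties go to
#' the first drawn).  Growth is depth-first, left child first; a node
#' becomes a leaf when pure, smaller than `s_n`, out of split budget
#' `s_t`, or when all candidates are constant.
#'
#' @param X Complete integer matrix, individuals x SNPs.
#' @param y Logical or 0/1 vector (TRUE/1 = case).
#' @param vars 1-based column indices of the candidate cluster.
#' @param k Variables drawn per node (0 or `"all"` = all of `vars`).
#' @param s_n,s_t Leaf threshold and split-node budget.
#' @param seed RNG seed.
#' @return A list with `tree` (parallel node arrays: `var`, `thr`,
#'   `left`, `right`, `prob`, `n_node`, `n_case`, `score`) and `nu`
#'   (leaf case probability assigned to each training observation).
#' @export
grow_extra_tree <- function(X, y, vars, k = 0, s_n = 1, s_t = 5, seed = 1) {
  if (identical(k, "all")) k <- 0L
  set.seed(seed)
  cpp_grow_extra_tree(X, as.integer(y), seq_len(nrow(X)), as.integer(vars),
                      as.integer(k), as.integer(s_n), as.integer(s_t))
}

#' Meta-variable values of an Extra-tree
#'
#' Routes observations through a grown tree; each observation receives
#' the case probability of the leaf it reaches.
#'
#' @param tree The `tree` component of [grow_extra_tree()].
#' @param X Complete integer matrix, individuals x SNPs (full SNP
#'   universe: the tree's `var` indices index its columns).
#' @return A list with `nu` (one value per row of `X`) and `dom` (the
#'   sorted distinct leaf labels reached).
#' @export
meta_variable_values <- function(tree, X) {
  nu <- route_tree(tree, X, seq_len(nrow(X)))
  list(nu = nu, dom = sort(unique(nu)))
}

# Vectorized routing of rows through an Extra-tree's node arrays.
route_tree <- function(tree, X, rows) {
  nu <- numeric(length(rows))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (is.na(tree$var[node])) {
      nu[idx] <<- tree$prob[node]
      return()
    }
    left <- X[rows[idx], tree$var[node]] <= tree$thr[node]
    recurse(tree$left[node], idx[left])
    recurse(tree$right[node], idx[!left])
  }
  recurse(1L, seq_along(rows))
  nu
}

#' Optimal cut-point on a meta-variable
#'
#' Scans the sorted distinct values of `nu` (except the maximum) as
#' thresholds of the partition `nu <= theta` vs `nu > theta` and returns
#' the threshold maximizing [discriminating_score()]; ties go to the
#' smallest threshold.  With fewer than two distinct values no split
#' exists.
#'
#' @param nu Meta-variable values.
#' @param y Logical or 0/1 class labels.
#' @return A list with `split` (logical), `theta` and `score`.
#' @export
optimal_meta_cutpoint <- function(nu, y) {
  cpp_optimal_meta_cut(as.numeric(nu), as.integer(y))
}

#' Grow one meta-tree
#'
#' @param X Complete integer matrix, individuals x SNPs.
#' @param y Logical or 0/1 labels.
#' @param map A [cluster_map()].
#' @param params A [forest_params()].
#' @param rows Training rows (default all) — the bootstrap sample.
#' @param seed RNG seed.
#' @return Flat list of meta-nodes (`type` `"leaf"` or `"split"` with
#'   `cluster`, `theta`, `score`, `n`, the winning embedded `tree`, and
#'   `left`/`right` node indices).
#' @export
grow_meta_tree <- function(X, y, map, params = forest_params(), rows = NULL,
                           seed = 1) {
  if (is.null(rows)) rows <- seq_len(nrow(X))
  set.seed(seed)
  cpp_grow_meta_tree(X, as.integer(y), as.integer(rows), map$clusters,
                     params$S_n, params$S_t, params$K, params$k,
                     params$s_n, params$s_t)
}

#' Fit a T-Trees / hybrid forest
#'
#' Grows `n_trees` meta-trees, each on a bootstrap sample of the
#' individuals (same size, with replacement, seeded `seed + t` for tree
#' `t`).  Missing genotypes are mode-imputed per SNP before learning.
#' The result is deterministic given `(ds, map, params, seed)`.
#'
#' @param ds A QC'd [genotype_dataset()].
#' @param map A [cluster_map()] partitioning its SNPs (contiguous blocks
#'   for T-Trees, FLTM layer-1 clusters for the hybrid approach).
#' @param params A [forest_params()].
#' @param seed Master seed.
#' @return An object of class `ttrees_forest`.
#' @export
fit_forest <- function(ds, map, params = forest_params(), seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(map, "cluster_map"))
  if (map$n_snps != n_snps(ds))
    stop("cluster map covers ", map$n_snps, " SNPs but dataset has ", n_snps(ds))
  imp <- impute_mode(ds)
  y <- as.integer(is_case(ds))
  n <- length(y)
  trees <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    set.seed(seed + t)
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- cpp_grow_meta_tree(imp$X, y, boot, map$clusters,
                                     params$S_n, params$S_t, params$K,
                                     params$k, params$s_n, params$s_t)
  }
  structure(list(trees = trees, map = map, params = params, seed = seed,
                 snp_id = ds$snps$snp_id, modes = imp$modes,
                 n_train = n),
            class = "ttrees_forest")
}

#' @export
print.ttrees_forest <- function(x, ...) {
  sizes <- vapply(x$trees, length, 1L)
  cat("ttrees_forest:", length(x$trees), "meta-trees on a",
      x$map$provenance, "map of", length(x$map$clusters), "clusters;",
      "meta-nodes/tree", min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Predict case probabilities
#'
#' Routes each individual through every meta-tree (embedded tree gives
#' the meta-variable value, compared to the meta-threshold) and averages
#' the meta-leaf case probabilities over the ensemble.
#'
#' @param forest A [fit_forest()] result.
#' @param ds A [genotype_dataset()] on the same SNP universe (matched by
#'   `snp_id`); missing genotypes are imputed with the training modes.
#' @return Numeric vector of probabilities in `[0, 1]`, one per
#'   individual.
#' @export
predict_proba <- function(forest, ds) {
  stopifnot(inherits(forest, "ttrees_forest"))
  if (!identical(ds$snps$snp_id, forest$snp_id))
    stop("dataset SNPs do not match the forest's SNP universe")
  g <- ds$genotypes
  if (anyNA(g)) {
    for (i in which(rowSums(is.na(g)) > 0L))
      g[i, is.na(g[i, ])] <- forest$modes[i]
  }
  X <- t(g)
  storage.mode(X) <- "integer"
  p <- numeric(nrow(X))
  for (tree in forest$trees) p <- p + route_meta(tree, X)
  p / length(forest$trees)
}

route_meta <- function(nodes, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, idx) {
    if (length(idx) == 0L) return()
    node <- nodes[[id]]
    if (node$type == "leaf") {
      out[idx] <<- node$prob
      return()
    }
    nu <- route_tree(node$tree, X, idx)
    left <- nu <= node$theta
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(1L, seq_len(nrow(X)))
  out
}

#' SNP importance of a fitted forest
#'
#' For every split node of every winning embedded tree, over all
#' meta-trees, the SNP used to split is credited with
#' `(n_node / n_train) * gain`; per-SNP credits are summed over the
#' forest and optionally normalized.
#'
#' @param forest A [fit_forest()] result.
#' @param normalize `"sum"` (scores sum to 1), `"max"` (max score 1) or
#'   `"none"`.
#' @return Named numeric vector (one score per SNP, dataset order) with
#'   attribute `mode`.
#' @export
variable_importance <- function(forest, normalize = c("sum", "max", "none")) {
  normalize <- match.arg(normalize)
  raw <- numeric(length(forest$snp_id))
  n_tot <- forest$n_train
  for (tree in forest$trees) {
    for (node in tree) {
      if (node$type != "split") next
      tr <- node$tree
      internal <- which(!is.na(tr$var))
      if (length(internal) == 0L) next
      for (e in internal) {
        raw[tr$var[e]] <- raw[tr$var[e]] + tr$n_node[e] / n_tot * tr$score[e]
      }
    }
  }
  if (normalize == "sum" && sum(raw) > 0) raw <- raw / sum(raw)
  if (normalize == "max" && max(raw) > 0) raw <- raw / max(raw)
  names(raw) <- forest$snp_id
  attr(raw, "mode") <- normalize
  raw
}

#' Rank SNPs by importance
#'
#' @param importance A [variable_importance()] vector.
#' @return `data.frame` with `snp_id`, `score`, `rank` (1 = most
#'   important; ties keep dataset order).
#' @export
importance_ranking <- function(importance) {
  ord <- order(-importance, seq_along(importance))
  rank <- integer(length(importance))
  rank[ord] <- seq_along(importance)
  data.frame(snp_id = names(importance), score = as.numeric(importance),
             rank = rank, stringsAsFactors = FALSE)
}
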