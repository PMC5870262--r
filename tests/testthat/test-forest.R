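test_that("block map slices coordinate-sorted SNPs into runs of B", {
  ds <- random_dataset(45, 20, seed = 20)
  map <- make_block_map(ds, 20)
  expect_equal(vapply(map$clusters, length, 1L), c(20L, 20L, 5L))
  expect_equal(map$provenance, "contiguous_blocks")
  one <- make_block_map(random_dataset(20, 10, seed = 21), 20)
  expect_equal(length(one$clusters), 1L)
  expect_error(make_block_map(ds, 0), ">= 1")
})

test_that("Extra-trees terminate on purity, budget and constant candidates", {
  n <- 20
  X <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3)
  # all cases: single leaf labeled 1
  et <- grow_extra_tree(X, rep(1L, n), vars = 1:3, seed = 1)
  expect_equal(length(et$tree$var), 1L)
  expect_equal(et$tree$prob[1], 1.0)
  expect_equal(unique(et$nu), 1.0)

  # s_t = 1 with a separating variable: one split, two leaves
  y <- rep(c(0L, 1L), each = n / 2)
  Xs <- cbind(ifelse(y == 1, 2L, 0L))
  et2 <- grow_extra_tree(Xs, y, vars = 1, s_t = 1, seed = 2)
  expect_equal(sum(!is.na(et2$tree$var)), 1L)
  expect_equal(length(et2$tree$var), 3L)

  # constant candidates: leaf
  et3 <- grow_extra_tree(matrix(1L, n, 2), y, vars = 1:2, seed = 3)
  expect_equal(length(et3$tree$var), 1L)

  # genotype {0,2} split separates perfectly whatever theta is drawn
  for (seed in 1:10) {
    et4 <- grow_extra_tree(Xs, y, vars = 1, seed = seed)
    expect_equal(et4$nu, as.numeric(y))  # training accuracy 1
  }
})

test_that("meta-variable values equal brute-force leaf routing", {
  set.seed(22)
  n <- 8
  X <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4)
  y <- sample(0:1, n, replace = TRUE)
  et <- grow_extra_tree(X, y, vars = 1:4, s_n = 2, seed = 5)
  mv <- meta_variable_values(et$tree, X)
  expect_equal(mv$nu, et$nu)
  # manual routing, observation by observation
  manual <- vapply(seq_len(n), function(i) {
    node <- 1L
    while (!is.na(et$tree$var[node])) {
      node <- if (X[i, et$tree$var[node]] <= et$tree$thr[node])
        et$tree$left[node] else et$tree$right[node]
    }
    et$tree$prob[node]
  }, numeric(1))
  expect_equal(mv$nu, manual)
  expect_equal(mv$dom, sort(unique(manual)))

  # single-leaf tree: constant nu
  one <- grow_extra_tree(X, rep(1L, n), vars = 1:4, seed = 6)
  expect_equal(meta_variable_values(one$tree, X)$dom, 1.0)
})

test_that("meta cut-point search scans the meta-variable domain", {
  res <- optimal_meta_cutpoint(c(0.1, 0.1, 0.9, 0.9), c(0L, 0L, 1L, 1L))
  expect_true(res$split)
  expect_equal(res$theta, 0.1)
  expect_equal(res$score, 1.0)

  expect_false(optimal_meta_cutpoint(rep(0.5, 4), c(0L, 1L, 0L, 1L))$split)

  # exhaustive oracle over both candidate thresholds
  nu <- c(0.1, 0.3, 0.3, 0.8, 0.8, 0.8)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  cand <- c(0.1, 0.3)
  scores <- vapply(cand, function(th) {
    l <- nu <= th
    oracle_gain(c(sum(y), sum(1 - y)), c(sum(y[l]), sum(1 - y[l])),
                c(sum(y[!l]), sum(1 - y[!l])))
  }, numeric(1))
  res2 <- optimal_meta_cutpoint(nu, y)
  expect_equal(res2$score, max(scores))
  expect_equal(res2$theta, cand[which.max(scores)])
})

test_that("meta-trees honor S_n, use the map, and pick signal clusters", {
  ds <- random_dataset(40, 30, seed = 23)
  imp <- ldforest:::impute_mode(ds)
  y <- as.integer(ds$phenotype == "case")
  map <- make_block_map(ds, 10)

  # |D| below S_n: single meta-leaf
  mt <- grow_meta_tree(imp$X, y, map, forest_params(S_n = 100, n_trees = 1),
                       seed = 1)
  expect_equal(length(mt), 1L)
  expect_equal(mt[[1]]$type, "leaf")
  expect_equal(mt[[1]]$prob, mean(y))

  # single-cluster map: that cluster chosen at every meta-node
  phen <- rep(c("case", "control"), each = 50)
  sep <- rbind(ifelse(phen == "case", 2L, 0L),
               matrix(rbinom(3 * 100, 2, 0.3), 3, 100))
  ds2 <- toy_dataset(sep, phen)
  one_map <- cluster_map(list(1:4), 4, "contiguous_blocks")
  mt2 <- grow_meta_tree(t(ds2$genotypes), as.integer(phen == "case"),
                        one_map, forest_params(S_n = 10, K = 5), seed = 2)
  splits <- Filter(function(nd) nd$type == "split", mt2)
  expect_gt(length(splits), 0L)
  expect_true(all(vapply(splits, function(nd) nd$cluster, 1L) == 1L))
  # meta-thresholds belong to the embedded tree's domain
  for (nd in splits) {
    dom <- meta_variable_values(nd$tree, t(ds2$genotypes))$dom
    expect_true(any(abs(dom - nd$theta) < 1e-12))
  }
})

test_that("root meta-node tends to pick a causal cluster under strong signal", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed + 400)
    n_ind <- 200
    phen <- rep(c("case", "control"), each = n_ind / 2)
    causal <- ifelse(phen == "case",
                     rbinom(n_ind, 2, 0.65), rbinom(n_ind, 2, 0.3))
    noise <- matrix(rbinom(19 * n_ind, 2, 0.3), 19, n_ind)
    ds <- toy_dataset(rbind(causal, noise), phen)
    map <- make_block_map(ds, 4)  # causal SNP lives in cluster 1
    mt <- grow_meta_tree(ldforest:::impute_mode(ds)$X,
                         as.integer(phen == "case"), map,
                         forest_params(S_n = 50, K = 5), seed = seed)
    if (mt[[1]]$type == "split" && mt[[1]]$cluster == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 10L)
})

test_that("forests are deterministic and aggregate predictions", {
  ds <- random_dataset(30, 80, seed = 24)
  map <- make_block_map(ds, 10)
  params <- forest_params(n_trees = 5, S_n = 20, K = 3)
  f1 <- fit_forest(ds, map, params, seed = 7)
  f2 <- fit_forest(ds, map, params, seed = 7)
  expect_identical(variable_importance(f1), variable_importance(f2))
  expect_identical(predict_proba(f1, ds), predict_proba(f2, ds))
  f3 <- fit_forest(ds, map, params, seed = 8)
  expect_false(identical(variable_importance(f1), variable_importance(f3)))

  expect_equal(length(fit_forest(ds, map,
                                 forest_params(n_trees = 1, S_n = 20),
                                 seed = 1)$trees), 1L)
  expect_error(fit_forest(ds, cluster_map(list(1:3), 3, "contiguous_blocks"),
                          params), "covers")

  # every meta-tree a single leaf: prediction equals the leaf label
  fleaf <- fit_forest(ds, map, forest_params(n_trees = 3, S_n = 1000), seed = 2)
  p <- predict_proba(fleaf, ds)
  labs <- vapply(fleaf$trees, function(tr) tr[[1]]$prob, numeric(1))
  expect_equal(unique(p), mean(labs))
})

test_that("prediction equals manual routing through the meta-trees", {
  set.seed(25)
  phen <- rep(c("case", "control"), each = 40)
  g <- rbind(ifelse(phen == "case", rbinom(80, 2, 0.7), rbinom(80, 2, 0.2)),
             matrix(rbinom(7 * 80, 2, 0.4), 7, 80))
  ds <- toy_dataset(g, phen)
  f <- fit_forest(ds, make_block_map(ds, 4),
                  forest_params(n_trees = 3, S_n = 20, K = 2), seed = 3)
  p <- predict_proba(f, ds)
  X <- t(ds$genotypes)
  manual <- vapply(seq_len(nrow(X)), function(i) {
    preds <- vapply(f$trees, function(nodes) {
      id <- 1L
      while (nodes[[id]]$type == "split") {
        nd <- nodes[[id]]
        tree <- nd$tree
        node <- 1L
        while (!is.na(tree$var[node])) {
          node <- if (X[i, tree$var[node]] <= tree$thr[node])
            tree$left[node] else tree$right[node]
        }
        id <- if (tree$prob[node] <= nd$theta) nd$left else nd$right
      }
      nodes[[id]]$prob
    }, numeric(1))
    mean(preds)
  }, numeric(1))
  expect_equal(p, manual)
})

test_that("importance credits only retained split nodes and normalizes", {
  set.seed(26)
  phen <- rep(c("case", "control"), each = 50)
  g <- rbind(ifelse(phen == "case", rbinom(100, 2, 0.75), rbinom(100, 2, 0.2)),
             matrix(rbinom(5 * 100, 2, 0.4), 5, 100))
  ds <- toy_dataset(g, phen)
  f <- fit_forest(ds, make_block_map(ds, 3),
                  forest_params(n_trees = 1, S_n = 25, K = 2), seed = 4)
  imp_sum <- variable_importance(f, "sum")
  expect_equal(sum(imp_sum), 1)
  imp_none <- variable_importance(f, "none")
  expect_true(all(imp_none >= 0))

  # hand accumulation over the single meta-tree's winning embedded trees
  hand <- numeric(n_snps(ds))
  for (nd in f$trees[[1]]) {
    if (nd$type != "split") next
    tr <- nd$tree
    for (e in seq_along(tr$var)) {
      if (!is.na(tr$var[e]))
        hand[tr$var[e]] <- hand[tr$var[e]] +
          tr$n_node[e] / f$n_train * tr$score[e]
    }
  }
  expect_equal(as.numeric(imp_none), hand)

  # SNPs in no retained split score exactly zero
  used <- unique(unlist(lapply(f$trees[[1]], function(nd)
    if (nd$type == "split") nd$tree$var[!is.na(nd$tree$var)] else integer(0))))
  expect_true(all(imp_none[setdiff(seq_len(n_snps(ds)), used)] == 0))

  imp_max <- variable_importance(f, "max")
  expect_equal(max(imp_max), 1)
})
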