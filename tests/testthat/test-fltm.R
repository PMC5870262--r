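test_that("LD graph respects the distance window and MI weights", {
  # two identical SNPs 1 kb apart: dissimilarity 0
  g <- rbind(c(0L, 1L, 2L, 1L, 0L, 2L), c(0L, 1L, 2L, 1L, 0L, 2L))
  ds <- toy_dataset(g, rep(c("case", "control"), 3), positions = c(1000L, 2000L))
  gr <- ld_distance_graph(ds, delta_bp = 50000)
  expect_equal(nrow(gr$edges), 1L)
  expect_equal(gr$edges$dist, 0)

  # 60 kb apart with delta = 50 kb: no edge
  ds2 <- toy_dataset(g, rep(c("case", "control"), 3),
                     positions = c(1000L, 61000L))
  expect_equal(nrow(ld_distance_graph(ds2, 50000)$edges), 0L)

  # constant SNP is isolated
  g3 <- rbind(c(0L, 1L, 2L, 1L), rep(1L, 4))
  ds3 <- toy_dataset(g3, rep(c("case", "control"), 2))
  expect_equal(nrow(ld_distance_graph(ds3, 50000)$edges), 0L)

  # independent SNPs at large n: dissimilarity near 1
  set.seed(8)
  n <- 10000
  g4 <- rbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  ds4 <- toy_dataset(g4, rep(c("case", "control"), n / 2))
  d <- ld_distance_graph(ds4, 50000)$edges$dist
  expect_gt(d, 0.95)
})

test_that("DBSCAN matches a brute-force reachability oracle", {
  # all distances above R: singletons
  far <- structure(list(edges = data.frame(i = 1L, j = 2L, dist = 0.9), n = 3L),
                   class = "ld_graph")
  m <- dbscan_cluster(far, dbscan_params(R = 0.3))
  expect_equal(canon_partition(m$clusters), list(1L, 2L, 3L))

  # all distances zero: one cluster
  pairs <- t(combn(4, 2))
  zero <- structure(list(edges = data.frame(i = pairs[, 1], j = pairs[, 2],
                                            dist = 0), n = 4L),
                    class = "ld_graph")
  m <- dbscan_cluster(zero, dbscan_params(R = 0.3))
  expect_equal(canon_partition(m$clusters), list(1:4))

  # random 6-point toy matrices against the closure oracle
  set.seed(9)
  for (rep in 1:25) {
    D <- matrix(0, 6, 6)
    D[upper.tri(D)] <- runif(15)
    D <- D + t(D)
    pairs <- t(combn(6, 2))
    gr <- structure(list(edges = data.frame(i = pairs[, 1], j = pairs[, 2],
                                            dist = D[pairs]), n = 6L),
                    class = "ld_graph")
    got <- dbscan_cluster(gr, dbscan_params(R = 0.3, N_min = 2))
    expect_equal(canon_partition(got$clusters),
                 canon_partition(oracle_dbscan(D, 0.3, 2)))
  }
})

test_that("latent cardinality follows the affine heuristic with cap", {
  p <- fltm_params()
  expect_equal(latent_cardinality(2, p), 4L)   # round(0.2 + 2*2)
  expect_equal(latent_cardinality(5, p), 10L)  # cap
  expect_equal(latent_cardinality(100, p), 10L)
  expect_error(latent_cardinality(1, p), "size < 2")
})

test_that("EM fits latent class models with monotone log-likelihood", {
  # two constant children: degenerate CPTs, loglik 0
  X <- matrix(0L, 30, 2)
  lcm <- fit_lcm(X, cardinality = 2, nb_restarts = 2, seed = 1)
  expect_equal(lcm$loglik, 0, tolerance = 1e-9)

  # monotone trace on random data
  set.seed(10)
  for (rep in 1:20) {
    Xr <- matrix(sample(0:2, 40 * 3, replace = TRUE), 40, 3)
    lcm <- fit_lcm(Xr, cardinality = 3, nb_restarts = 2, seed = rep)
    expect_true(all(diff(lcm$trace) >= -1e-8))
  }

  # perfectly correlated binary pair reaches the grid-search optimum
  set.seed(11)
  x <- rbinom(80, 1, 0.4)
  X2 <- cbind(x, x)
  lcm <- fit_lcm(X2, cardinality = 2, nb_restarts = 10, seed = 2)
  counts <- table(factor(X2[, 1], 0:1), factor(X2[, 2], 0:1))
  best <- oracle_lcm_grid(counts, step = 0.05)
  expect_gte(lcm$loglik, best - 1e-3)
})

test_that("imputed latent columns follow the posterior", {
  # degenerate posterior: latent equals the shared child value
  x <- rep(c(0L, 1L), each = 40)
  lcm <- fit_lcm(cbind(x, x), cardinality = 2, nb_restarts = 5, seed = 3)
  lat <- impute_latent(lcm, cbind(x, x), seed = 4)
  expect_equal(length(unique(lat[x == 0])), 1L)
  expect_equal(length(unique(lat[x == 1])), 1L)
  expect_false(lat[1] == lat[80])

  # determinism under a fixed seed
  expect_identical(impute_latent(lcm, cbind(x, x), seed = 5),
                   impute_latent(lcm, cbind(x, x), seed = 5))

  # empirical marginal close to the analytic mixture marginal
  set.seed(12)
  Xr <- matrix(rbinom(3 * 10000, 1, 0.5), ncol = 3)
  lcm2 <- fit_lcm(Xr, cardinality = 2, nb_restarts = 3, seed = 6)
  lat2 <- impute_latent(lcm2, Xr, seed = 7)
  post <- colMeans(ldforest:::lcm_posterior(lcm2, Xr))
  emp <- tabulate(lat2 + 1L, 2L) / length(lat2)
  expect_lt(sum(abs(emp - post)) / 2, 0.05)
})

test_that("latent validation scores mean normalized MI against tau", {
  x <- rep(0:1, each = 30)
  val <- validate_latent(x, cbind(x, x), tau = 0.3)
  expect_equal(val$score, 1.0)
  expect_true(val$valid)
  # threshold is inclusive
  expect_true(validate_latent(x, cbind(x, x), tau = 1.0 - 1e-12)$valid)

  set.seed(13)
  lat <- rbinom(10000, 1, 0.5)
  kids <- matrix(rbinom(2 * 10000, 1, 0.5), ncol = 2)
  val2 <- validate_latent(lat, kids, tau = 0.3)
  expect_lt(val2$score, 0.05)
  expect_false(val2$valid)

  expect_equal(validate_latent(rep(0L, 10), cbind(rep(0:1, 5), rep(0:1, 5)))$score, 0)
})

test_that("FLTM learning subsumes LD blocks and leaves noise alone", {
  # independent SNPs: no validated latent
  ds <- random_dataset(20, 300, seed = 14)
  model <- learn_fltm(ds, fltm_params(nb_em_restarts = 3), dbscan_params(0.5),
                      seed = 1)
  expect_equal(model$n_latents, 0L)
  map <- layer1_map(model)
  expect_equal(length(map$clusters), 20L)

  # one tight block of 5 near-identical SNPs is captured by one latent
  set.seed(15)
  base <- rbinom(300, 2, 0.4)
  block <- vapply(1:5, function(i) {
    flip <- runif(300) < 0.03
    out <- base; out[flip] <- sample(0:2, sum(flip), replace = TRUE)
    as.integer(out)
  }, integer(300))
  noise <- matrix(rbinom(5 * 300, 2L, 0.3), ncol = 5)
  ds2 <- toy_dataset(t(cbind(block, noise)), rep(c("case", "control"), 150))
  model2 <- learn_fltm(ds2, fltm_params(nb_em_restarts = 3),
                       dbscan_params(0.5), seed = 2)
  expect_gte(model2$n_latents, 1L)
  l1 <- model2$layers[[1]]
  covering <- vapply(l1, function(l) all(1:5 %in% l$children), TRUE)
  expect_true(any(covering))
  # structural bound
  expect_lte(model2$n_latents, 3 * n_snps(ds2))

  # layer-1 map partitions and validated latents re-check above tau
  map2 <- layer1_map(model2)
  expect_equal(sort(unlist(map2$clusters)), 1:10)
  for (l in l1) {
    Xc <- t(ds2$genotypes[l$children, , drop = FALSE])
    re <- validate_latent(l$data, Xc, tau = 0.3)
    expect_gte(re$score, 0.3)
  }
})

test_that("layer-1 map covers orphans as singletons", {
  ds <- random_dataset(3, 50, seed = 16)
  model <- learn_fltm(ds, fltm_params(nb_em_restarts = 2), dbscan_params(0.2),
                      seed = 1)
  map <- layer1_map(model, 3)
  expect_equal(sort(unlist(map$clusters)), 1:3)
  expect_equal(map$provenance, "fltm_layer1")
})

test_that("radius selection is deterministic and self-consistent", {
  ds <- random_dataset(12, 120, seed = 17)
  sel <- select_R(ds, fltm_params(nb_em_restarts = 2),
                  R_grid = c(0.4), seed = 3)
  expect_equal(sel$R, 0.4)
  expect_equal(sel$criterion, fltm_criterion(sel$model))
  expect_error(select_R(ds, R_grid = numeric(0)), "empty")

  # full pipeline determinism
  m1 <- learn_fltm(ds, fltm_params(nb_em_restarts = 2), dbscan_params(0.5),
                   seed = 9)
  m2 <- learn_fltm(ds, fltm_params(nb_em_restarts = 2), dbscan_params(0.5),
                   seed = 9)
  expect_identical(layer1_map(m1)$clusters, layer1_map(m2)$clusters)
  expect_identical(m1$n_latents, m2$n_latents)
})
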