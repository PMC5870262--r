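# Forest of latent tree models: mutual-information LD graph, DBSCAN
# clustering, latent class models fitted by EM, tau-validation, latent
# data imputation, and the layered learning loop whose layer-1 cluster
# map feeds the hybrid forest.

#' FLTM learning parameters
#'
#' @param alpha,beta Intercept and slope of the latent-cardinality
#'   heuristic `card(L) = min(alpha + beta * n_c, card_max)` where `n_c`
#'   is the number of children.
#' @param card_max Maximum latent cardinality.
#' @param tau Validity threshold on the mean normalized mutual
#'   information between a latent variable and its children (inclusive).
#' @param nb_em_restarts Number of random EM restarts per latent class
#'   model.
#' @param delta_bp Maximal physical distance, in base pairs, allowed
#'   between two variables of the same cluster (inclusive).
#' @param em_tol,em_max_iter EM convergence tolerance (log-likelihood
#'   improvement, nats) and iteration cap.
#' @return A list of class `fltm_params`.
#' @export
fltm_params <- function(alpha = 0.2, beta = 2, card_max = 10, tau = 0.3,
                        nb_em_restarts = 10, delta_bp = 50000,
                        em_tol = 1e-4, em_max_iter = 200) {
  stopifnot(card_max >= 2, tau > 0, tau < 1, nb_em_restarts >= 1, delta_bp > 0)
  structure(list(alpha = alpha, beta = beta, card_max = card_max, tau = tau,
                 nb_em_restarts = nb_em_restarts, delta_bp = delta_bp,
                 em_tol = em_tol, em_max_iter = em_max_iter),
            class = "fltm_params")
}

#' DBSCAN parameters
#'
#' @param R Maximum neighborhood radius on the `1 - normalized MI`
#'   dissimilarity scale, in `(0, 1]`.
#' @param N_min Minimum number of neighbors (self excluded) for a core
#'   point.
#' @return A list of class `dbscan_params`.
#' @export
dbscan_params <- function(R, N_min = 2) {
  stopifnot(R > 0, R <= 1, N_min >= 1)
  structure(list(R = R, N_min = N_min), class = "dbscan_params")
}

# Dissimilarity edges among m discrete variables: edge iff same
# chromosome and |pos_i - pos_j| <= delta_bp; weight = 1 - normalized MI.
# Constant variables (zero entropy) get no edges.
mi_edges <- function(X, levels, chromosome, position, delta_bp) {
  m <- ncol(X)
  ii <- integer(0); jj <- integer(0)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    idx <- idx[order(position[idx])]
    pos <- position[idx]
    hi <- 1L
    for (a in seq_along(idx)) {
      while (hi < length(idx) && pos[hi + 1L] - pos[a] <= delta_bp) hi <- hi + 1L
      if (hi > a) {
        ii <- c(ii, rep(idx[a], hi - a))
        jj <- c(jj, idx[(a + 1L):hi])
      }
    }
  }
  if (length(ii) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  nmi <- cpp_pairwise_nmi(X, ii, jj, levels)
  keep <- !is.na(nmi)
  data.frame(i = ii[keep], j = jj[keep], dist = 1 - nmi[keep])
}

#' LD dissimilarity graph of a dataset
#'
#' Sparse graph whose edges connect SNPs on the same chromosome within
#' `delta_bp` base pairs, weighted by `1 - normalized mutual information`
#' of their genotype columns (pairwise-complete).  SNPs with constant
#' genotype (zero entropy) are isolated.
#'
#' @param ds A [genotype_dataset()] with at least 2 SNPs.
#' @param delta_bp Maximal physical distance for an edge (inclusive).
#' @return A list of class `ld_graph` with `edges` (`data.frame` of
#'   `i`, `j`, `dist`) and `n`.
#' @export
ld_distance_graph <- function(ds, delta_bp = 50000) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (n_snps(ds) < 2L) stop("need at least 2 SNPs")
  X <- t(ds$genotypes)
  X[is.na(X)] <- -1L
  storage.mode(X) <- "integer"
  edges <- mi_edges(X, rep(3L, n_snps(ds)), ds$snps$chromosome,
                    ds$snps$position_bp, delta_bp)
  structure(list(edges = edges, n = n_snps(ds), delta_bp = delta_bp),
            class = "ld_graph")
}

#' DBSCAN on a dissimilarity graph
#'
#' Core points have at least `N_min` neighbors at distance `<= R`;
#' clusters are connected components of core points under `<= R`
#' reachability; border points attach to the cluster of their
#' smallest-index core neighbor; noise points become singleton clusters,
#' so the result is always a partition.
#'
#' @param graph An [ld_distance_graph()] result (or any list with
#'   `edges` and `n`).
#' @param params A [dbscan_params()].
#' @return A [cluster_map()] ordered by smallest member index.
#' @export
dbscan_cluster <- function(graph, params) {
  stopifnot(inherits(params, "dbscan_params"))
  cl <- dbscan_partition(graph$edges, graph$n, params$R, params$N_min)
  cluster_map(cl, n_snps = graph$n, provenance = "fltm_layer1")
}

# Internal partition (list of integer vectors, ordered by smallest member).
dbscan_partition <- function(edges, n, R, N_min) {
  keep <- edges$dist <= R
  ei <- edges$i[keep]; ej <- edges$j[keep]
  nbr <- vector("list", n)
  if (length(ei)) {
    for (k in seq_along(ei)) {
      nbr[[ei[k]]] <- c(nbr[[ei[k]]], ej[k])
      nbr[[ej[k]]] <- c(nbr[[ej[k]]], ei[k])
    }
  }
  deg <- vapply(nbr, length, 1L)
  core <- deg >= N_min
  label <- integer(n)  # 0 = unassigned
  next_label <- 0L
  # components of core points under <=R edges between cores
  for (s in which(core)) {
    if (label[s] != 0L) next
    next_label <- next_label + 1L
    queue <- s
    label[s] <- next_label
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbr[[v]]) {
        if (core[w] && label[w] == 0L) {
          label[w] <- next_label
          queue <- c(queue, w)
        }
      }
    }
  }
  # border points: claimed by cores in index order
  for (s in which(core)) {
    for (w in nbr[[s]]) {
      if (!core[w] && label[w] == 0L) label[w] <- label[s]
    }
  }
  # noise -> singletons
  for (s in which(label == 0L)) {
    next_label <- next_label + 1L
    label[s] <- next_label
  }
  cl <- split(seq_len(n), label)
  names(cl) <- NULL
  cl[order(vapply(cl, min, 1L))]
}

#' Latent cardinality heuristic
#'
#' `max(2, round(min(alpha + beta * n_c, card_max)))` for a cluster of
#' `n_c` child variables.
#'
#' @param n_c Number of children (>= 2).
#' @param params An [fltm_params()].
#' @return Integer cardinality in `[2, card_max]`.
#' @export
latent_cardinality <- function(n_c, params = fltm_params()) {
  if (n_c < 2) stop("no latent class model for clusters of size < 2")
  as.integer(max(2, round(min(params$alpha + params$beta * n_c,
                              params$card_max))))
}

#' Fit a latent class model by EM
#'
#' One discrete latent variable with conditionally independent discrete
#' children, fitted by EM with random restarts; the restart with the
#' best final log-likelihood wins.  Missing child values are
#' marginalized out of the E-step.  Log-likelihoods are in nats.
#'
#' @param X Integer matrix, individuals x children, values `0..L-1`
#'   (`NA` = missing).
#' @param cardinality Number of latent states (>= 2).
#' @param levels Number of levels per child; defaults to
#'   `max(column) + 1`.
#' @param nb_restarts,tol,max_iter EM control.
#' @param seed Base seed; restart `r` uses `seed + r`.
#' @return A list of class `lcm`: `prior`, `cpts` (per-child `levels x
#'   cardinality` matrices of `P(child | latent)`), `loglik`, `trace`
#'   (per-iteration log-likelihood of the winning run), `cardinality`,
#'   `levels`.
#' @export
fit_lcm <- function(X, cardinality, levels = NULL, nb_restarts = 10,
                    tol = 1e-4, max_iter = 200, seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("a latent class model needs >= 2 children")
  if (cardinality < 2) stop("latent cardinality must be >= 2")
  storage.mode(X) <- "integer"
  X[is.na(X)] <- -1L
  if (is.null(levels)) levels <- pmax(apply(X, 2L, max) + 1L, 1L)
  best <- NULL
  for (r in seq_len(nb_restarts)) {
    set.seed(seed + r)
    fit <- cpp_lcm_em_once(X, as.integer(levels), as.integer(cardinality),
                           tol, as.integer(max_iter))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(prior = best$prior, cpts = best$cpts, loglik = best$loglik,
                 trace = best$trace, cardinality = as.integer(cardinality),
                 levels = as.integer(levels)),
            class = "lcm")
}

# Posterior P(L | children) for every individual: n x cardinality matrix.
lcm_posterior <- function(lcm, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  lw <- matrix(rep(log(lcm$prior), each = n), n, lcm$cardinality)
  for (j in seq_len(ncol(X))) {
    cpt <- lcm$cpts[[j]]
    obs <- !is.na(X[, j]) & X[, j] >= 0
    lw[obs, ] <- lw[obs, ] + log(pmax(cpt[X[obs, j] + 1L, , drop = FALSE],
                                      .Machine$double.xmin))
  }
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

#' Impute latent values by posterior sampling
#'
#' Draws, for each individual, a latent state from `P(L | observed
#' children)`; deterministic given `seed`.
#'
#' @param lcm A fitted [fit_lcm()] model.
#' @param X Child value matrix (individuals x children).
#' @param seed RNG seed.
#' @return Integer vector of latent states in `0..cardinality-1`.
#' @export
impute_latent <- function(lcm, X, seed = 1) {
  post <- lcm_posterior(lcm, X)
  set.seed(seed)
  u <- runif(nrow(post))
  cum <- t(apply(post, 1L, cumsum))
  as.integer(rowSums(u > cum))
}

#' Validate a latent variable
#'
#' The validation score is the mean, over the children, of the
#' normalized mutual information between the imputed latent column and
#' the child column; the latent is valid iff `score >= tau` (inclusive).
#' A zero-entropy latent is invalid with score 0; a constant child
#' contributes 0.
#'
#' @param latent Integer vector of imputed latent states.
#' @param X Child value matrix (individuals x children).
#' @param tau Validity threshold.
#' @return A list with `valid` and `score`.
#' @export
validate_latent <- function(latent, X, tau = 0.3) {
  X <- as.matrix(X)
  if (length(unique(latent)) < 2L) return(list(valid = FALSE, score = 0))
  scores <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) return(0)
    normalized_mi(table(latent[ok], x[ok]))
  }, numeric(1))
  score <- mean(scores)
  list(valid = score >= tau, score = score)
}

#' Learn a forest of latent tree models
#'
#' Iterates: cluster the active variables on the `1 - normalized MI`
#' graph (respecting the physical-distance constraint), fit a latent
#' class model to every cluster of size >= 2, impute the latent column,
#' validate it against `tau`; validated latents replace their children
#' as active variables.  Stops when a layer creates no valid latent, the
#' active set shrinks to one variable, or `max_layers` is reached.
#' Invalid latents leave their children active.
#'
#' @param ds A QC'd [genotype_dataset()].
#' @param params An [fltm_params()].
#' @param dbscan A [dbscan_params()].
#' @param seed Master seed; all EM restarts and imputation draws derive
#'   from it.
#' @param max_layers Cap on the number of layers (default unlimited).
#' @return A list of class `fltm_model`: `layers` (per layer, a list of
#'   validated latents, each with `id`, `children` (SNP indices for
#'   layer 1, variable ids deeper), `child_ids`, `cardinality`, `score`,
#'   `lcm`, `data` (imputed column)), `n_snps`, `orphans` (SNP indices
#'   never subsumed), `n_latents`.
#' @export
learn_fltm <- function(ds, params = fltm_params(), dbscan = dbscan_params(0.3),
                       seed = 1, max_layers = Inf) {
  stopifnot(inherits(ds, "genotype_dataset"), inherits(params, "fltm_params"))
  n <- n_snps(ds)
  X <- t(ds$genotypes)
  X[is.na(X)] <- -1L
  storage.mode(X) <- "integer"
  active <- list(
    data = X,                       # individuals x active variables
    levels = rep(3L, n),
    chromosome = ds$snps$chromosome,
    position = as.numeric(ds$snps$position_bp),
    id = as.list(seq_len(n)),       # SNP index for observed, "Lx.y" for latents
    snps = lapply(seq_len(n), identity))  # SNP leaves under each active var
  layers <- list()
  fit_counter <- 0L
  layer <- 0L
  repeat {
    layer <- layer + 1L
    if (layer > max_layers || ncol(active$data) < 2L) break
    edges <- mi_edges(active$data, active$levels, active$chromosome,
                      active$position, params$delta_bp)
    part <- dbscan_partition(edges, ncol(active$data), dbscan$R, dbscan$N_min)
    new_latents <- list()
    subsumed <- integer(0)
    for (ci in seq_along(part)) {
      members <- part[[ci]]
      if (length(members) < 2L) next
      card <- latent_cardinality(length(members), params)
      Xc <- active$data[, members, drop = FALSE]
      Xc[Xc < 0L] <- NA_integer_
      fit_counter <- fit_counter + 1L
      seed_fit <- seed + 97L * fit_counter
      lcm <- fit_lcm(Xc, card, levels = active$levels[members],
                     nb_restarts = params$nb_em_restarts,
                     tol = params$em_tol, max_iter = params$em_max_iter,
                     seed = seed_fit)
      lat <- impute_latent(lcm, Xc, seed = seed_fit + 1L)
      val <- validate_latent(lat, Xc, tau = params$tau)
      if (!val$valid) next
      new_latents[[length(new_latents) + 1L]] <- list(
        id = sprintf("L%d.%d", layer, length(new_latents) + 1L),
        members = members,
        child_ids = active$id[members],
        children = sort(unlist(active$snps[members])),
        cardinality = card,
        score = val$score,
        lcm = lcm,
        data = lat)
      subsumed <- c(subsumed, members)
    }
    if (length(new_latents) == 0L) break
    layers[[layer]] <- new_latents
    keep <- setdiff(seq_len(ncol(active$data)), subsumed)
    lat_data <- vapply(new_latents, function(l) l$data,
                       integer(nrow(active$data)))
    active <- list(
      data = cbind(active$data[, keep, drop = FALSE], lat_data),
      levels = c(active$levels[keep],
                 vapply(new_latents, function(l) l$cardinality, 1L)),
      chromosome = c(active$chromosome[keep],
                     vapply(new_latents, function(l)
                       active$chromosome[l$members[1L]], "")),
      position = c(active$position[keep],
                   vapply(new_latents, function(l)
                     mean(active$position[l$members]), 1.0)),
      id = c(active$id[keep], lapply(new_latents, function(l) l$id)),
      snps = c(active$snps[keep], lapply(new_latents, function(l) l$children)))
  }
  n_latents <- sum(vapply(layers, length, 1L))
  covered <- if (length(layers)) sort(unique(unlist(
    lapply(layers[[1L]], function(l) l$children)))) else integer(0)
  structure(list(layers = layers, n_snps = n, n_latents = n_latents,
                 orphans = setdiff(seq_len(n), covered)),
            class = "fltm_model")
}

#' @export
print.fltm_model <- function(x, ...) {
  cat("fltm_model:", x$n_latents, "validated latents over",
      length(x$layers), "layer(s);", x$n_snps, "SNPs,",
      length(x$orphans), "never subsumed at layer 1\n")
  invisible(x)
}

#' Layer-1 cluster map of an FLTM model
#'
#' The LD map used by the hybrid forest: the child sets of validated
#' layer-1 latent variables, with every uncovered SNP as a singleton.
#'
#' @param model An [learn_fltm()] result.
#' @param n_snps Number of SNPs (defaults to the model's).
#' @return A [cluster_map()] with provenance `fltm_layer1`.
#' @export
layer1_map <- function(model, n_snps = model$n_snps) {
  stopifnot(inherits(model, "fltm_model"))
  clusters <- if (length(model$layers) >= 1L)
    lapply(model$layers[[1L]], function(l) l$children) else list()
  covered <- sort(unlist(clusters))
  singles <- setdiff(seq_len(n_snps), covered)
  clusters <- c(clusters, lapply(singles, identity))
  clusters <- clusters[order(vapply(clusters, min, 1L))]
  cluster_map(clusters, n_snps = n_snps, provenance = "fltm_layer1")
}

#' Select the DBSCAN radius over a grid
#'
#' Learns one FLTM per candidate radius and retains the model whose
#' layer-1 latents maximize the cluster-size-weighted mean tau-validation
#' score (0 when no latent is validated); ties go to the smallest R.
#'
#' @param ds A [genotype_dataset()].
#' @param params An [fltm_params()].
#' @param R_grid Candidate radii.
#' @param N_min DBSCAN neighbor minimum.
#' @param seed Master seed.
#' @param max_layers Layer cap passed to [learn_fltm()].
#' @return A list with `R`, `model`, `criterion`, and `grid` (a
#'   `data.frame` of criterion values per candidate).
#' @export
select_R <- function(ds, params = fltm_params(),
                     R_grid = seq(0.05, 0.90, by = 0.05), N_min = 2,
                     seed = 1, max_layers = Inf) {
  if (length(R_grid) == 0L) stop("empty R grid")
  best <- NULL
  crits <- numeric(length(R_grid))
  for (g in seq_along(R_grid)) {
    R <- R_grid[g]
    model <- learn_fltm(ds, params, dbscan_params(R, N_min), seed = seed,
                        max_layers = max_layers)
    crits[g] <- fltm_criterion(model)
    if (is.null(best) || crits[g] > best$criterion)
      best <- list(R = R, model = model, criterion = crits[g])
  }
  best$grid <- data.frame(R = R_grid, criterion = crits)
  best
}

#' Cluster-quality criterion of a learned FLTM model
#'
#' Mean per-SNP tau-validation score of the layer-1 clustering: every
#' SNP subsumed by a validated latent contributes that latent's score,
#' every never-subsumed SNP contributes 0.  Rewards both cluster quality
#' and coverage, so neither an all-singleton map (high scores, no
#' coverage) nor an over-merged one (high coverage, low scores) wins.
#' This is the quantity maximized by [select_R()].
#'
#' @param model An [learn_fltm()] result.
#' @return A fraction in `[0, 1]`.
#' @export
fltm_criterion <- function(model) {
  if (length(model$layers) == 0L) return(0)
  l1 <- model$layers[[1L]]
  if (length(l1) == 0L) return(0)
  sizes <- vapply(l1, function(l) length(l$children), 1L)
  scores <- vapply(l1, function(l) l$score, 1.0)
  sum(sizes * scores) / model$n_snps
}
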