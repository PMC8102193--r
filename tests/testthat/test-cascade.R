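test_that("cluster assignment ranks onset times", {
  res <- data.frame(feature = c("a", "a", "b", "c"),
                    time = c(1, 4, 1, 4),
                    q_value = c(0.001, 0.5, 0.004, 0.002),
                    log2fc_mean = 1)
  cl <- assign_clusters(res, alpha = 0.01)
  expect_equal(unname(cl$m[c("a", "b", "c")]), c(1, 1, 2))
  expect_equal(unname(cl$onset[c("a", "b", "c")]), c(1, 1, 4))
  # single shared onset collapses to one cluster
  res2 <- data.frame(feature = c("a", "b"), time = 1, q_value = 0.001,
                     log2fc_mean = 1)
  expect_equal(max(assign_clusters(res2)$m), 1)
  # features without a significant time are excluded with a message
  res3 <- rbind(res, data.frame(feature = "d", time = 2, q_value = 0.9,
                                log2fc_mean = 0))
  expect_message(cl3 <- assign_clusters(res3, alpha = 0.01), "excluded")
  expect_false("d" %in% names(cl3$m))
})

test_that("onset clusters recover the planted layers for most actors", {
  accs <- vapply(1:6, function(seed) {
    net <- generate_network(30, 3, mean_out_degree = 1.5,
                            knockout_fraction_of_cluster1 = 0, seed = seed)
    cfg <- sim_config(noise_sd = 0.2, count_dispersion = 0,
                      protein_missing_rate = 0, seed = seed)
    sim <- simulate_dataset(net, cfg, "proliferative")
    cl <- assign_clusters_from_series(sim$latent[, -1L, , drop = FALSE])
    mean(cl$m[net$actors] == net$cluster_of[net$actors], na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("build_predictor applies strictly causal transfer matrices", {
  S <- cascadeomics:::shift_matrix(5)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(build_predictor(S, x), c(0, 3, 1, 4, 1))
  expect_equal(build_predictor(matrix(0, 5, 5), x), rep(0, 5))
  set.seed(1)
  F <- matrix(rnorm(25), 5, 5); F[upper.tri(F, diag = TRUE)] <- 0
  e1 <- c(1, 0, 0, 0, 0)
  expect_equal(build_predictor(F, e1), F[, 1])
  expect_error(build_predictor(F, c(1, 2)), "mismatch")
  Fbad <- F; Fbad[1, 2] <- 1
  expect_error(build_predictor(Fbad, x), "triangular")
})

test_that("lambda = 0 reproduces the normal-equation least-squares oracle", {
  inst <- noiseless_instance(6, 2, seed = 2)
  fit <- fit_cascade(inst$x, inst$clusters, lambda = 0, max_iter = 1)
  xs <- cascadeomics:::scale_series(inst$x)
  m <- inst$clusters$m[dimnames(xs)[[1]]]
  actors <- dimnames(xs)[[1]]
  Fl <- list()
  for (i in 1:2) for (j in i:2)
    Fl[[cascadeomics:::fkey(i, j)]] <- cascadeomics:::shift_matrix(8)
  D <- cascadeomics:::cascade_design(xs, m, Fl)
  for (l in actors[m == 2]) {
    cand <- cascadeomics:::candidates_of(actors, m, l)
    X <- D[["2"]][, cand, drop = FALSE]
    y <- as.numeric(xs[l, , ])
    beta <- solve(crossprod(X), crossprod(X, y))   # brute-force normal equations
    expect_equal(unname(fit$omega[cand, l]), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("an overwhelming penalty empties the model", {
  inst <- noiseless_instance(8, 2, seed = 3)
  fit <- fit_cascade(inst$x, inst$clusters, lambda = 100, max_iter = 1)
  expect_true(all(fit$omega == 0))
})

test_that("noiseless generator data yields exact support recovery", {
  inst <- noiseless_instance(10, 2, seed = 1)
  grid <- lambda_grid_default(inst$x, inst$clusters)
  lam <- cross_validate_lambda(inst$x, inst$clusters, NULL, grid)$lambda_best
  fit <- fit_cascade(inst$x, inst$clusters, lambda = lam, max_iter = 1L,
                     refit_ols = TRUE)
  m <- score_recovery(network_from_model(fit), inst$net)
  expect_equal(m$f_score, 1)
})

test_that("the alternating objective is non-increasing up to tolerance", {
  set.seed(8)
  inst <- noiseless_instance(12, 3, seed = 8)
  x <- inst$x + array(rnorm(length(inst$x), 0, 0.2), dim = dim(inst$x))
  fit <- fit_cascade(x, inst$clusters, lambda = 0.05, max_iter = 4, tol = 1e-10)
  expect_true(all(diff(fit$objective) <= 1e-6 * pmax(fit$objective[-length(fit$objective)], 1)))
})

test_that("cross-validation returns the sparser penalty on ties and pure noise", {
  inst <- noiseless_instance(8, 2, seed = 5)
  one <- cross_validate_lambda(inst$x, inst$clusters, NULL, lambda_grid = 0.3)
  expect_equal(one$lambda_best, 0.3)
  # pure noise: the largest penalty (empty model) wins
  wins <- 0L
  grid <- c(1, 0.3, 0.1, 0.03, 0.01)
  for (s in 1:10) {
    set.seed(s)
    xn <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3),
                dimnames = list(sprintf("A%03d", 1:8), paste0("T", 1:8), NULL))
    cl <- cascadeomics:::cluster_assignment(
      setNames(rep(c(1, 2), each = 4), dimnames(xn)[[1]]))
    cv <- cross_validate_lambda(xn, cl, NULL, grid)
    if (cv$lambda_best == 1) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("stability selection is reproducible and monotone in its threshold", {
  inst <- noiseless_instance(10, 2, seed = 4)
  x <- inst$x + array(rnorm(length(inst$x), 0, 0.3), dim = dim(inst$x))
  n1 <- stability_select(x, inst$clusters, lambda = 0.05, B = 20, seed = 17)
  n2 <- stability_select(x, inst$clusters, lambda = 0.05, B = 20, seed = 17)
  expect_identical(n1$edges, n2$edges)
  expect_identical(attr(n1, "frequencies"), attr(n2, "frequencies"))
  strict <- stability_select(x, inst$clusters, lambda = 0.05, B = 20,
                             pi_thr = 1, seed = 17)
  loose <- stability_select(x, inst$clusters, lambda = 0.05, B = 20,
                            pi_thr = 0.6, seed = 17)
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("every inferred edge respects cluster causality", {
  inst <- noiseless_instance(15, 3, seed = 9)
  x <- inst$x + array(rnorm(length(inst$x), 0, 0.3), dim = dim(inst$x))
  net <- stability_select(x, inst$clusters, lambda = 0.03, B = 20, seed = 1)
  m <- inst$clusters$m
  expect_true(all(m[net$edges$source] <= m[net$edges$target]))
  # the constructor itself enforces the invariant
  nodes <- data.frame(id = c("a", "b"), symbol = c("a", "b"),
                      modality = "transcript", cluster = c(2L, 1L))
  bad <- data.frame(source = "a", target = "b", omega_hat = 1)
  expect_error(inferred_network(bad, nodes), "causality")
})

test_that("prior weighting never hurts recall of prior-listed true edges", {
  skipped <- 0L
  for (s in 1:5) {
    inst <- noiseless_instance(15, 3, seed = s)
    x <- inst$x + array(rnorm(length(inst$x), 0, 0.4), dim = dim(inst$x))
    prior <- generate_prior(inst$net, coverage = 0.5, seed = s)
    pk <- paste(prior$source, prior$target)
    tk <- paste(inst$net$edges$source, inst$net$edges$target)
    listed <- intersect(pk, tk)
    recall_of <- function(kappa) {
      fit <- fit_cascade(x, inst$clusters, prior = prior, lambda = 0.05,
                         kappa = kappa, max_iter = 1)
      found <- paste(network_from_model(fit)$edges$source,
                     network_from_model(fit)$edges$target)
      mean(listed %in% found)
    }
    expect_gte(recall_of(0.5), recall_of(1))
  }
})

test_that("degree summary flags hubs at the link threshold", {
  nodes <- data.frame(id = c("a", "b", "c"), symbol = c("a", "b", "c"),
                      modality = "transcript", cluster = 1L)
  edges <- data.frame(source = rep("a", 12),
                      target = rep(c("b", "c"), 6),
                      omega_hat = 1)
  net <- inferred_network(edges, nodes)
  ds <- degree_summary(net, threshold = 10)
  expect_identical(ds$hubs, "a")
  expect_setequal(degree_summary(net, threshold = 0)$hubs, c("a", "b", "c"))
})
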