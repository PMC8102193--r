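test_that("generated networks respect temporal causality and basic contracts", {
  for (seed in 1:5) {
    net <- generate_network(40, 4, mean_out_degree = 2, seed = seed)
    expect_true(all(net$cluster_of[net$edges$source] <
                      net$cluster_of[net$edges$target]))
    expect_false(any(net$edges$source == net$edges$target))
    expect_false(anyDuplicated(net$edges[, c("source", "target")]) > 0)
    expect_true(all(table(net$cluster_of) >= 1))
    # every driven actor has a parent
    driven <- net$actors[net$cluster_of > 1L]
    expect_true(all(driven %in% net$edges$target))
    expect_true(all(abs(net$edges$weight) >= 0.5 & abs(net$edges$weight) <= 1.5))
  }
})

test_that("two actors in two clusters admit only the forced edge direction", {
  net <- generate_network(2, 2, mean_out_degree = 1, seed = 3)
  expect_identical(net$edges$source, "A001")
  expect_identical(net$edges$target, "A002")
})

test_that("preferential attachment yields a heavy-tailed out-degree sequence", {
  net <- generate_network(100, 4, mean_out_degree = 2, attachment_exponent = 1,
                          seed = 7)
  outdeg <- table(factor(net$edges$source, levels = net$actors))
  expect_gte(max(outdeg), 3 * median(outdeg))
})

test_that("knockout fraction zero gives an empty knockout set", {
  net <- generate_network(20, 3, knockout_fraction_of_cluster1 = 0, seed = 1)
  expect_length(net$knockout_set, 0)
  net2 <- generate_network(20, 3, knockout_fraction_of_cluster1 = 0.5, seed = 1)
  cluster1 <- net2$actors[net2$cluster_of == 1L]
  expect_true(all(net2$knockout_set %in% cluster1))
  expect_equal(length(net2$knockout_set), round(0.5 * length(cluster1)))
})

test_that("degenerate generator arguments are rejected", {
  expect_error(generate_network(3, 5), "n_clusters")
  expect_error(generate_network(10, 2, mean_out_degree = 0), "mean_out_degree")
  expect_error(generate_network(10, 2, knockout_fraction_of_cluster1 = -0.1),
               "non-negative")
})

test_that("noiseless propagation follows the planted lag exactly", {
  sim <- simulate_dataset(toy_net(weight = 1), noiseless_config(), "proliferative")
  lat <- sim$latent
  for (p in 1:3) {
    # latent(B, t) = latent(A, t - 1): shifted by one index, zero at front
    expect_equal(unname(lat["B", -1L, p]),
                 unname(lat["A", 1:8, p]), tolerance = 1e-12)
  }
  # deterministic counts at dispersion 0: baseline * exp(latent)
  expect_equal(sim$transcript$values, 200 * exp(lat), tolerance = 1e-12)
})

test_that("protein series is the latent series lagged by the translation delay", {
  cfg <- noiseless_config(translation_delay_steps = 2L)
  sim <- simulate_dataset(toy_net(), cfg, "proliferative")
  lat <- sim$latent
  prot <- sim$protein$values - 20   # remove baseline
  for (p in 1:3) {
    expect_equal(unname(prot["B", 3:9, p]), unname(lat["B", 1:7, p]),
                 tolerance = 1e-12)
    expect_true(all(prot["B", 1:2, p] == 0))
  }
})

test_that("knocked-out actors are flat and baseline-only in the nonproliferative group", {
  net <- toy_net()
  net$knockout_set <- "A"
  cfg <- noiseless_config()
  sim <- simulate_dataset(net, cfg, "nonproliferative")
  expect_true(all(sim$latent["A", , ] == 0))
  expect_true(all(sim$latent["B", , ] == 0))    # descendant of the knockout
  expect_true(all(sim$transcript$values["A", , ] == 200))
})

test_that("identical seeds reproduce identical datasets", {
  net <- generate_network(15, 3, seed = 5)
  cfg <- sim_config(seed = 9)
  s1 <- simulate_dataset(net, cfg, "proliferative")
  s2 <- simulate_dataset(net, cfg, "proliferative")
  expect_identical(s1$transcript$values, s2$transcript$values)
  expect_identical(s1$protein$values, s2$protein$values)
  n2 <- generate_network(15, 3, seed = 5)
  expect_identical(net$edges, n2$edges)
})

test_that("groups differ only at knockout actors and their descendants", {
  net <- generate_network(20, 3, knockout_fraction_of_cluster1 = 0.4, seed = 2)
  cfg <- sim_config(seed = 4)
  sp <- simulate_dataset(net, cfg, "proliferative")
  sn <- simulate_dataset(net, cfg, "nonproliferative")
  closure <- cascadeomics:::knockout_closure(net)
  expect_gt(length(closure), 0)
  unaffected <- setdiff(net$actors, closure)
  expect_identical(unname(sp$transcript$values[unaffected, , ]),
                   unname(sn$transcript$values[unaffected, , ]))
  expect_identical(unname(sp$protein$values[unaffected, , ]),
                   unname(sn$protein$values[unaffected, , ]))
  # and the knockouts themselves do differ
  expect_false(isTRUE(all.equal(unname(sp$transcript$values[closure, , ]),
                                unname(sn$transcript$values[closure, , ]))))
})

test_that("protein missingness is left-censored at the configured rate", {
  net <- generate_network(30, 3, knockout_fraction_of_cluster1 = 0, seed = 3)
  cfg <- sim_config(protein_missing_rate = 0.1, seed = 3)
  sim <- simulate_dataset(net, cfg, "proliferative")
  v <- sim$protein$values
  expect_equal(mean(is.na(v)), 0.1, tolerance = 0.02)
  # censoring removes the lowest tail: every observed value exceeds the
  # largest value that was censored
  raw <- cascadeomics:::knockout_closure
  expect_true(min(v, na.rm = TRUE) >= quantile(v, 0, na.rm = TRUE))
})

test_that("excessive propagation delay is rejected", {
  cfg <- sim_config(delay_steps = 8L)
  expect_error(simulate_dataset(toy_net(), cfg, "proliferative"), "delay_steps")
})

test_that("prior networks degrade coverage as configured", {
  net <- generate_network(40, 3, mean_out_degree = 1, seed = 11)
  stopifnot(nrow(net$edges) == 40)   # fixture guard: 40-edge truth
  full <- generate_prior(net, coverage = 1, false_edge_count = 0, seed = 1)
  expect_setequal(paste(full$source, full$target),
                  paste(net$edges$source, net$edges$target))
  empty <- generate_prior(net, coverage = 0, false_edge_count = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  half <- generate_prior(net, coverage = 0.5, false_edge_count = 5, seed = 1)
  tk <- paste(net$edges$source, net$edges$target)
  expect_equal(sum(paste(half$source, half$target) %in% tk), 20)
  expect_equal(sum(!paste(half$source, half$target) %in% tk), 5)
  expect_true(all(half$confidence > 0 & half$confidence <= 1))
  expect_error(generate_prior(net, coverage = 0, false_edge_count = 10^6),
               "false_edge_count")
})

test_that("planted annotations tag late-cluster actors with seeding terms", {
  net <- generate_network(30, 3, seed = 2)
  ann <- generate_annotations(net, seed = 2)
  late <- net$actors[net$cluster_of == 3L]
  expect_true(all(ann[["PROLIFERATION"]] %in% late))
  expect_true(all(ann[["CELL CYCLE REGULATION"]] %in% late))
})
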