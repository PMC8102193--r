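# a small two-modality network: proteins Pn, genes Gn share symbols
demo_network <- function() {
  nodes <- data.frame(
    id = c("CDK2|P", "PCNA|P", "EGR1|G", "CDK2|G", "TANK|G", "KMO|P"),
    symbol = c("CDK2", "PCNA", "EGR1", "CDK2", "TANK", "KMO"),
    modality = c("protein", "protein", "transcript", "transcript",
                 "transcript", "protein"),
    cluster = c(3L, 3L, 1L, 2L, 1L, 3L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("EGR1|G", "TANK|G", "CDK2|G", "EGR1|G"),
    target = c("CDK2|P", "CDK2|P", "PCNA|P", "CDK2|G"),
    omega_hat = c(1.2, -0.8, 0.9, 0.5),
    stringsAsFactors = FALSE)
  inferred_network(edges, nodes)
}

demo_ann <- list(
  "CELL CYCLE REGULATION" = c("CDK2", "PCNA"),
  "PROLIFERATION" = c("PCNA", "KMO"),
  "SIGNALING" = c("TANK", "EGR1"))

test_that("seeding proteins are annotated network proteins", {
  net <- demo_network()
  seeds <- select_seeding_proteins(demo_ann, network = net)
  expect_setequal(seeds, c("CDK2", "PCNA", "KMO"))
  expect_length(select_seeding_proteins(demo_ann, terms = character(0),
                                        network = net), 0)
  expect_message(select_seeding_proteins(demo_ann, terms = "nonexistent process",
                                         network = net), "not found")
  # case-insensitive term lookup, default terms
  expect_setequal(select_seeding_proteins(demo_ann,
                                          terms = c("Cell Cycle Regulation"),
                                          network = net), c("CDK2", "PCNA"))
})

test_that("subnetwork extraction keeps linked seeds plus neighbors in layers", {
  net <- demo_network()
  sub <- extract_subnetwork(net, c("CDK2", "PCNA", "KMO"))
  # KMO|P has no link and is dropped; neighbors of CDK2|P and PCNA|P join
  expect_setequal(sub$actors,
                  c("CDK2|P", "PCNA|P", "EGR1|G", "TANK|G", "CDK2|G"))
  expect_setequal(sub$layer1, c("CDK2|P", "PCNA|P"))
  expect_setequal(sub$layer2, "CDK2|G")            # gene encoding a layer-1 protein
  expect_setequal(sub$layer3, c("EGR1|G", "TANK|G"))
  expect_equal(nrow(sub$induced_edges), 4)
  # exact partition invariant
  expect_length(intersect(sub$layer1, sub$layer2), 0)
  expect_length(intersect(sub$layer2, sub$layer3), 0)
  expect_setequal(c(sub$layer1, sub$layer2, sub$layer3), sub$actors)
  # every actor is a seed or adjacent to one
  adj <- unique(c(sub$induced_edges$source, sub$induced_edges$target))
  expect_true(all(setdiff(sub$actors, sub$layer1) %in% adj))
})

test_that("empty and star-shaped seed sets behave as declared", {
  net <- demo_network()
  empty <- extract_subnetwork(net, character(0))
  expect_length(empty$actors, 0)
  # star: one seed with three neighbors -> 4 actors, 3 edges
  nodes <- data.frame(id = c("HUB", "N1", "N2", "N3"),
                      symbol = c("HUB", "N1", "N2", "N3"),
                      modality = "protein", cluster = 1L)
  edges <- data.frame(source = "HUB", target = c("N1", "N2", "N3"),
                      omega_hat = 1)
  star <- inferred_network(edges, nodes)
  sub <- extract_subnetwork(star, "HUB")
  expect_length(sub$actors, 4)
  expect_equal(nrow(sub$induced_edges), 3)
})

test_that("subnetwork extraction is monotone in the seed set", {
  net <- demo_network()
  small <- extract_subnetwork(net, "CDK2")
  big <- extract_subnetwork(net, c("CDK2", "PCNA"))
  expect_true(all(small$actors %in% big$actors))
})

test_that("network comparison reports overlap fractions both ways", {
  mk_sub <- function(ids) {
    structure(list(layer1 = ids, layer2 = character(0), layer3 = character(0),
                   actors = ids,
                   induced_edges = data.frame(source = character(0),
                                              target = character(0)),
                   nodes = NULL),
              class = "subnetwork_layers")
  }
  # the worked 388-vs-114 overlap: 60 common is 15% and 52%
  a <- mk_sub(sprintf("a%03d", 1:388))
  b <- mk_sub(c(sprintf("a%03d", 1:60), sprintf("b%03d", 1:54)))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$n_common, 60)
  expect_equal(cmp$fraction_a, 60 / 388, tolerance = 1e-12)
  expect_equal(cmp$fraction_b, 60 / 114, tolerance = 1e-12)
  expect_equal(round(100 * cmp$fraction_a), 15)
  expect_equal(round(100 * cmp$fraction_b), 53)
  # symmetry of the common set and degenerate cases
  rev <- compare_networks(b, a)
  expect_identical(cmp$common, rev$common)
  expect_equal(compare_networks(a, a)$fraction_a, 1)
  expect_equal(compare_networks(a, mk_sub("zzz"))$n_common, 0)
})

test_that("temporal function counts tabulate signature proteins per process", {
  sig <- structure(list(
    features = c("CDK2", "PCNA", "TANK"),
    direction = data.frame(
      feature = c("CDK2", "PCNA", "PCNA", "TANK"),
      time = c(7L, 7L, 8L, 1L),
      direction = c("up", "up", "up", "down"),
      log2fc = c(2, 3, 3.5, -1)),
    first_time = c(CDK2 = 7L, PCNA = 7L, TANK = 1L),
    alpha = 0.01), class = "signature_set")
  tab <- temporal_function_counts(sig, demo_ann)
  pick <- function(term, t, dir)
    tab$count[tab$term == term & tab$time == t & tab$direction == dir]
  expect_equal(pick("CELL CYCLE REGULATION", 7, "up"), 2)
  expect_equal(pick("PROLIFERATION", 8, "up"), 1)
  expect_equal(pick("SIGNALING", 1, "down"), 1)
  expect_true(all(tab$count[tab$term == "PROLIFERATION" & tab$time == 1] == 0))
  # a term with no annotated signature proteins gives an all-zero row
  tab2 <- temporal_function_counts(sig, list(EMPTY = "NOTHERE"))
  expect_true(all(tab2$count == 0))
})

test_that("late planted responders concentrate proliferation counts late", {
  net <- generate_network(30, 3, knockout_fraction_of_cluster1 = 0, seed = 12)
  ann <- generate_annotations(net, seed = 12)
  sim <- simulate_dataset(net, sim_config(noise_sd = 0.2, seed = 12),
                          "proliferative")
  fc <- log2fc_vs_t0(normalize_library_size(sim$transcript))
  sig <- temporal_signature(temporal_tests(fc), alpha = 0.01)
  tab <- temporal_function_counts(sig, ann)
  prolif <- tab[tab$term == "PROLIFERATION", ]
  early <- sum(prolif$count[prolif$time <= 2])
  late <- sum(prolif$count[prolif$time >= 3])
  expect_gt(late, early)
})
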