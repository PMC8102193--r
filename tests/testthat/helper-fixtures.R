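# small fixtures shared across test files, all generated in code

# a two-actor, two-cluster network with one unit edge a -> b
toy_net <- function(weight = 1) {
  structure(
    list(actors = c("A", "B"),
         cluster_of = c(A = 1L, B = 2L),
         edges = data.frame(source = "A", target = "B", weight = weight,
                            stringsAsFactors = FALSE),
         delay_steps = 1L,
         knockout_set = character(0)),
    class = "ground_truth_network")
}

noiseless_config <- function(seed = 1L, ...) {
  sim_config(noise_sd = 0, count_dispersion = 0, protein_missing_rate = 0,
             seed = seed, ...)
}

# a small transcript dataset with exact counts
toy_transcript <- function(values) {
  temporal_omics(values, "transcript",
                 time_hours = seq(0, length.out = dim(values)[2L]),
                 groups = rep("proliferative", dim(values)[3L]))
}

# fold-change tensor straight from a numeric array
toy_fc <- function(a, modality = "transcript") {
  if (is.null(dimnames(a)[[1L]]))
    dimnames(a) <- list(sprintf("F%03d", seq_len(dim(a)[1L])),
                        paste0("T", seq_len(dim(a)[2L])),
                        paste0("I", seq_len(dim(a)[3L])))
  fold_change(a, modality, pseudocount = 1,
              time_hours = seq_len(dim(a)[2L]),
              groups = rep("proliferative", dim(a)[3L]))
}

# latent series + truth for inference tests: layered noiseless instance
noiseless_instance <- function(n_actors = 10L, n_clusters = 2L, seed = 1L) {
  net <- generate_network(n_actors, n_clusters, mean_out_degree = 1.5,
                          attachment_exponent = 1,
                          knockout_fraction_of_cluster1 = 0, seed = seed)
  sim <- simulate_dataset(net, noiseless_config(seed), "proliferative")
  x <- sim$latent[, -1L, , drop = FALSE]
  list(net = net, x = x, clusters = assign_clusters_from_series(x))
}
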