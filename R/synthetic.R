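#' Simulation configuration
#'
#' Bundles the knobs of the paired transcript/protein simulator. Defaults
#' mirror the study design being emulated: nine measurement indices T0-T8 on
#' staggered nominal-hour grids for the two modalities, three individuals per
#' group, negative-binomial counts for transcripts and Gaussian log2
#' intensities with left-censored missingness for proteins.
#'
#' @param n_individuals_per_group individuals per group (default 3).
#' @param time_grid_transcript_hours transcript sampling grid in hours,
#'   starting at 0.
#' @param time_grid_protein_hours protein sampling grid in hours, same length.
#' @param noise_sd latent propagation noise sd (sigma >= 0). The default 0.25
#'   gives a signal-to-noise variance ratio of about 4:1 against unit-scale
#'   latent trajectories.
#' @param count_dispersion negative-binomial dispersion phi (variance
#'   mu + phi mu^2); `0` switches counts to their deterministic mean.
#' @param translation_delay_steps index lag between a latent gene trajectory
#'   and its protein observation (default 2, roughly 3-6 nominal hours in
#'   mid-course).
#' @param delay_steps index lag of network propagation (default 1).
#' @param protein_missing_rate fraction of lowest-intensity protein values set
#'   to missing (left-censoring), in `[0, 1)`.
#' @param count_baseline expected count at latent 0.
#' @param protein_baseline log2-intensity offset at latent 0.
#' @param seed integer RNG seed.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals_per_group = 3L,
                       time_grid_transcript_hours = c(0, 1, 1.5, 3.5, 6.5, 12, 24, 48, 96),
                       time_grid_protein_hours = c(0, 1, 2, 4, 7, 12, 24, 48, 96),
                       noise_sd = 0.25,
                       count_dispersion = 0.1,
                       translation_delay_steps = 2L,
                       delay_steps = 1L,
                       protein_missing_rate = 0.05,
                       count_baseline = 200,
                       protein_baseline = 20,
                       seed = 1L) {
  if (length(time_grid_transcript_hours) != length(time_grid_protein_hours))
    stop("both time grids must have the same length")
  if (time_grid_transcript_hours[1L] != 0 || time_grid_protein_hours[1L] != 0)
    stop("time grids must start at 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (count_dispersion < 0) stop("count_dispersion must be >= 0")
  if (protein_missing_rate < 0 || protein_missing_rate >= 1)
    stop("protein_missing_rate must be in [0, 1)")
  if (delay_steps < 1L) stop("delay_steps must be >= 1")
  structure(
    list(n_individuals_per_group = as.integer(n_individuals_per_group),
         time_grid_transcript_hours = time_grid_transcript_hours,
         time_grid_protein_hours = time_grid_protein_hours,
         noise_sd = noise_sd, count_dispersion = count_dispersion,
         translation_delay_steps = as.integer(translation_delay_steps),
         delay_steps = as.integer(delay_steps),
         protein_missing_rate = protein_missing_rate,
         count_baseline = count_baseline,
         protein_baseline = protein_baseline,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a planted ground-truth cascade network
#'
#' Actors are partitioned into temporal clusters; directed edges run from each
#' cluster to the next (the exogenous first cluster is the stimulus layer and
#' receives no edges), so that under delay-1 propagation an actor's first
#' response index equals its cluster index. Sources are drawn by preferential
#' attachment on current out-degree, producing heavy-tailed hub structure for
#' positive attachment exponents. Every actor outside cluster 1 receives at
#' least one parent so its trajectory is driven.
#'
#' @param n_actors number of actors (>= n_clusters).
#' @param n_clusters number of temporal clusters M (>= 2).
#' @param mean_out_degree target mean number of outgoing edges per actor.
#' @param attachment_exponent preferential-attachment exponent (0 = uniform).
#' @param knockout_fraction_of_cluster1 fraction of cluster-1 actors silenced
#'   in the nonproliferative group.
#' @param seed integer RNG seed.
#'
#' @return A `ground_truth_network` with fields `actors`, `cluster_of` (named
#'   integer), `edges` (data.frame source/target/weight), `delay_steps`, and
#'   `knockout_set`.
#' @export
generate_network <- function(n_actors, n_clusters, mean_out_degree = 2,
                             attachment_exponent = 1,
                             knockout_fraction_of_cluster1 = 0.5,
                             seed = 1L) {
  if (n_clusters > n_actors) stop("n_clusters cannot exceed n_actors")
  if (n_clusters < 2L) stop("at least 2 clusters are required")
  if (mean_out_degree <= 0) stop("mean_out_degree must be positive")
  if (knockout_fraction_of_cluster1 < 0)
    stop("knockout_fraction_of_cluster1 must be non-negative")
  set.seed(as.integer(seed))
  actors <- sprintf("A%03d", seq_len(n_actors))
  cluster_of <- sort(rep_len(seq_len(n_clusters), n_actors))
  names(cluster_of) <- actors

  targets <- actors[cluster_of > 1L]
  outdeg <- setNames(integer(n_actors), actors)
  parents <- setNames(vector("list", n_actors), actors)

  # parents come from the immediately preceding cluster, so that an actor's
  # first response index equals its cluster index under delay-1 propagation
  # (clusters are onset layers by construction)
  pick_source <- function(target) {
    allowed <- actors[cluster_of == cluster_of[target] - 1L]
    allowed <- setdiff(allowed, parents[[target]])
    if (length(allowed) == 0L) return(NA_character_)
    w <- (outdeg[allowed] + 1)^attachment_exponent
    allowed[sample.int(length(allowed), 1L, prob = w)]
  }

  # one guaranteed parent per driven actor
  for (tg in targets) {
    src <- pick_source(tg)
    parents[[tg]] <- c(parents[[tg]], src)
    outdeg[src] <- outdeg[src] + 1L
  }
  total_edges <- max(round(mean_out_degree * n_actors), length(targets))
  extra <- total_edges - length(targets)
  attempts <- 0L
  while (extra > 0L && attempts < 50L * total_edges) {
    attempts <- attempts + 1L
    tg <- targets[sample.int(length(targets), 1L)]
    src <- pick_source(tg)
    if (is.na(src)) next
    parents[[tg]] <- c(parents[[tg]], src)
    outdeg[src] <- outdeg[src] + 1L
    extra <- extra - 1L
  }

  edges <- do.call(rbind, lapply(targets, function(tg) {
    if (length(parents[[tg]]) == 0L) return(NULL)
    data.frame(source = parents[[tg]], target = tg,
               stringsAsFactors = FALSE)
  }))
  edges$weight <- runif(nrow(edges), 0.5, 1.5) *
    sample(c(-1, 1), nrow(edges), replace = TRUE)
  rownames(edges) <- NULL

  cluster1 <- actors[cluster_of == 1L]
  n_ko <- round(knockout_fraction_of_cluster1 * length(cluster1))
  knockout_set <- if (n_ko > 0L) sort(sample(cluster1, n_ko)) else character(0)

  structure(
    list(actors = actors, cluster_of = cluster_of, edges = edges,
         delay_steps = 1L, knockout_set = knockout_set),
    class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("<ground_truth_network> %d actors, %d clusters, %d edges, %d knockouts\n",
              length(x$actors), max(x$cluster_of), nrow(x$edges),
              length(x$knockout_set)))
  invisible(x)
}

# descendants of a set of actors under the directed edge list (excluding
# unreachable actors; includes the seeds themselves)
knockout_closure <- function(net) {
  reach <- net$knockout_set
  repeat {
    nxt <- union(reach, net$edges$target[net$edges$source %in% reach])
    if (length(nxt) == length(reach)) return(reach)
    reach <- nxt
  }
}

# deterministic per-actor substream seed, kept well below 2^31
actor_seed <- function(seed, n, salt) {
  as.integer((abs(seed) %% 100000L) * 10007L + n * 97L + salt) %% 2147483L
}

#' Simulate a paired transcript/protein temporal dataset
#'
#' Forward simulation of the cascade model. Cluster-1 actors carry exogenous
#' impulse trajectories (zero at T0, peak at the first post-stimulation index,
#' then a damped-oscillation relaxation with per-actor amplitude, sign, decay
#' rate and frequency); every other
#' actor's latent value at index t is the weighted sum of its parents' latent
#' values at index `t - delay_steps` plus Gaussian noise. In the
#' nonproliferative group the knockout actors are silenced (flat zero latent),
#' which propagates to their descendants. Transcripts are observed as
#' negative-binomial counts with mean `baseline * exp(latent)`; proteins as
#' the latent series lagged by `translation_delay_steps` plus baseline and
#' Gaussian noise, with the lowest-intensity quantile left-censored to `NA`.
#'
#' Identical seeds give bit-identical output, and per-actor RNG substreams
#' guarantee that the two groups differ only at knockout actors and their
#' network descendants.
#'
#' @param net a `ground_truth_network`.
#' @param config a [sim_config()].
#' @param group `"proliferative"` or `"nonproliferative"`.
#'
#' @return list with elements `transcript` and `protein`
#'   ([temporal_omics] objects), `latent` (the noiseless-observation latent
#'   array) and `protein_latent` (lagged latent before noise/censoring).
#' @export
simulate_dataset <- function(net, config, group = c("proliferative", "nonproliferative")) {
  group <- match.arg(group)
  stopifnot(inherits(net, "ground_truth_network"), inherits(config, "sim_config"))
  T1 <- length(config$time_grid_transcript_hours)
  Tpost <- T1 - 1L
  if (config$delay_steps >= Tpost)
    stop("delay_steps must be smaller than the number of post-stimulation points")
  if (!all(names(net$cluster_of) == net$actors))
    stop("every actor must carry a cluster assignment")
  P <- config$n_individuals_per_group
  N <- length(net$actors)
  d <- config$delay_steps

  ids <- paste0(if (group == "proliferative") "P" else "NP", seq_len(P))
  groups <- rep(group, P)
  silenced <- if (group == "nonproliferative") net$knockout_set else character(0)

  # per-actor random ingredients from dedicated substreams; impulse kinetics
  # carry per-individual jitter (inter-individual biological variability)
  sgn <- numeric(N)
  amp <- matrix(0, N, P); dec <- matrix(0, N, P); frq <- matrix(0, N, P)
  eps <- vector("list", N); pnoise <- vector("list", N)
  for (n in seq_len(N)) {
    set.seed(actor_seed(config$seed, n, 0L))
    sgn[n] <- sample(c(-1, 1), 1L)
    a0 <- runif(1L, 1, 3); d0 <- runif(1L, 0.35, 0.85); f0 <- runif(1L, 0, pi / 2)
    amp[n, ] <- a0 * runif(P, 0.7, 1.3)
    dec[n, ] <- pmin(pmax(d0 + runif(P, -0.1, 0.1), 0.2), 0.95)
    frq[n, ] <- pmax(f0 + runif(P, -0.2, 0.2), 0)
    eps[[n]] <- matrix(rnorm(Tpost * P, 0, config$noise_sd), Tpost, P)
    pnoise[[n]] <- matrix(rnorm(T1 * P, 0, config$noise_sd), T1, P)
  }

  latent <- array(0, dim = c(N, T1, P),
                  dimnames = list(net$actors, paste0("T", 0:Tpost), ids))
  parent_idx <- split(match(net$edges$source, net$actors),
                      factor(net$edges$target, levels = net$actors))
  parent_w <- split(net$edges$weight,
                    factor(net$edges$target, levels = net$actors))
  ord <- order(net$cluster_of)            # topological: edges increase cluster
  for (n in ord) {
    a <- net$actors[n]
    if (a %in% silenced) next              # flat zero latent
    if (net$cluster_of[n] == 1L) {
      # damped-oscillation impulse: zero at T0, peak magnitude at the first
      # post-stimulation index, decaying envelope; per-actor decay rate and
      # relaxation frequency keep the stimulus layer linearly diverse
      for (p in seq_len(P)) {
        prof <- amp[n, p] * sgn[n] * dec[n, p]^(0:(Tpost - 1L)) *
          cos(frq[n, p] * (0:(Tpost - 1L)))
        latent[n, -1L, p] <- prof + eps[[n]][, p]
      }
    } else {
      pk <- parent_idx[[a]]; pw <- parent_w[[a]]
      for (p in seq_len(P)) {
        for (t in seq_len(Tpost)) {        # t is post index; column t + 1
          tc <- t - d + 1L                 # parent column (T0 = column 1)
          contrib <- if (tc >= 1L) sum(pw * latent[pk, tc, p]) else 0
          latent[n, t + 1L, p] <- contrib + eps[[n]][t, p]
        }
      }
    }
  }

  # transcript observation: NB counts around baseline * exp(latent)
  mu <- config$count_baseline * exp(pmin(pmax(latent, -20), 20))
  counts <- array(0, dim = dim(latent), dimnames = dimnames(latent))
  if (config$count_dispersion == 0) {
    counts[] <- mu
  } else {
    size <- 1 / config$count_dispersion
    for (n in seq_len(N)) {
      set.seed(actor_seed(config$seed, n, 1L))
      counts[n, , ] <- rnbinom(T1 * P, mu = mu[n, , ], size = size)
    }
  }

  # protein observation: lagged latent + baseline + noise, left-censored
  dt <- config$translation_delay_steps
  plat <- array(0, dim = dim(latent), dimnames = dimnames(latent))
  if (dt < T1) plat[, (dt + 1L):T1, ] <- latent[, seq_len(T1 - dt), ]
  prot <- plat + config$protein_baseline
  for (n in seq_len(N)) prot[n, , ] <- prot[n, , ] + pnoise[[n]]
  if (config$protein_missing_rate > 0) {
    unaffected <- setdiff(net$actors, knockout_closure(net))
    pool <- prot[unaffected, , , drop = FALSE]
    thr <- quantile(pool, config$protein_missing_rate, names = FALSE)
    prot[prot < thr] <- NA_real_
  }

  list(
    transcript = temporal_omics(counts, "transcript",
                                config$time_grid_transcript_hours, groups),
    protein = temporal_omics(prot, "protein",
                             config$time_grid_protein_hours, groups),
    latent = latent,
    protein_latent = plat)
}

#' Generate a degraded prior-knowledge network
#'
#' Emulates an external interaction database: a configurable fraction of the
#' true edges plus a number of false edges absent from the truth, each with a
#' confidence score in (0, 1].
#'
#' @param net a `ground_truth_network`.
#' @param coverage fraction of true edges included, in `[0, 1]`.
#' @param false_edge_count number of non-true ordered pairs added.
#' @param seed integer RNG seed.
#'
#' @return A `prior_network`: data.frame `(source, target, confidence)`.
#' @export
generate_prior <- function(net, coverage = 0.5, false_edge_count = 0L, seed = 1L) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  set.seed(as.integer(seed))
  n_true <- round(coverage * nrow(net$edges))
  keep <- if (n_true > 0L) sort(sample.int(nrow(net$edges), n_true)) else integer(0)
  true_part <- net$edges[keep, c("source", "target"), drop = FALSE]

  all_pairs <- expand.grid(source = net$actors, target = net$actors,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  key <- function(d) paste(d$source, d$target, sep = "\r")
  non_true <- all_pairs[!(key(all_pairs) %in% key(net$edges)), ]
  if (false_edge_count > nrow(non_true))
    stop("false_edge_count exceeds the number of possible non-true ordered pairs")
  false_part <- non_true[sample.int(nrow(non_true), false_edge_count), , drop = FALSE]

  out <- rbind(true_part, false_part)
  out$confidence <- if (nrow(out)) runif(nrow(out), 0.5, 1) else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("prior_network", "data.frame")
  out
}

#' Generate planted annotation terms for a network
#'
#' Tags the last-cluster actors (the late responders) with the
#' proliferation-related biological-process terms used for subnetwork seeding,
#' and distributes generic terms over the remaining actors, emulating a GMT
#' annotation resource.
#'
#' @param net a `ground_truth_network`.
#' @param seed integer RNG seed.
#' @param seed_terms terms attached to late-cluster actors.
#'
#' @return named list term -> character vector of symbols (uppercase).
#' @export
generate_annotations <- function(net, seed = 1L,
                                 seed_terms = c("CELL CYCLE REGULATION", "PROLIFERATION")) {
  set.seed(as.integer(seed))
  M <- max(net$cluster_of)
  late <- net$actors[net$cluster_of == M]
  early <- setdiff(net$actors, late)
  ann <- list()
  half <- ceiling(length(late) / 2)
  ann[[toupper(seed_terms[1L])]] <- sort(sample(late, half))
  ann[[toupper(seed_terms[2L])]] <- sort(sample(late, max(half, 1L)))
  ann[["SIGNALING"]] <- sort(sample(early, max(1L, floor(length(early) / 2))))
  ann[["METABOLISM"]] <- sort(sample(net$actors, max(1L, floor(length(net$actors) / 3))))
  ann
}
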