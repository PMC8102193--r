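#' Write an expression matrix and sample metadata as TSV
#'
#' The matrix has feature symbols as rows and sample IDs
#' (`<individual>_<Tindex>`) as columns; the metadata table carries one row
#' per sample with columns `sample_id, individual, group, time_index,
#' time_hours, modality`.
#'
#' @param ds a [temporal_omics].
#' @param matrix_path,metadata_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(ds, matrix_path, metadata_path) {
  m <- flatten_samples(ds$values)
  md <- expand.grid(time_index = time_labels(ds), individual = individual_ids(ds),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md$sample_id <- paste(md$individual, md$time_index, sep = "_")
  md$group <- rep(ds$groups, each = dim(ds$values)[2L])
  md$time_hours <- rep(ds$time_hours, times = dim(ds$values)[3L])
  md$modality <- ds$modality
  md <- md[, c("sample_id", "individual", "group", "time_index", "time_hours",
               "modality")]
  write.table(data.frame(feature = rownames(m), m, check.names = FALSE),
              matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Read an expression matrix with its sample metadata
#'
#' Reassembles feature x time x individual tensors from the TSV pair written
#' by [write_expression()], one [temporal_omics] per modality found. Every
#' matrix column must be covered by a metadata row (the error names the
#' offending column), duplicate (individual, time, modality) combinations are
#' rejected, transcript values must be non-negative and complete.
#'
#' @param matrix_path,metadata_path TSV paths.
#' @return named list of [temporal_omics] (by modality).
#' @export
read_expression <- function(matrix_path, metadata_path) {
  m <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(m$feature)) stop("duplicate feature rows in matrix")
  rownames(m) <- toupper(m$feature)
  m$feature <- NULL
  md <- read.delim(metadata_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(colnames(m), md$sample_id)
  if (length(missing_cols))
    stop("matrix column(s) without metadata: ", paste(missing_cols, collapse = ", "))
  if (!all(md$group %in% c("proliferative", "nonproliferative")))
    stop("metadata group labels must be 'proliferative' or 'nonproliferative'")
  if (!all(md$modality %in% c("transcript", "protein")))
    stop("metadata modality must be 'transcript' or 'protein'")
  if (anyDuplicated(md[, c("individual", "time_index", "modality")]))
    stop("duplicate (individual, time, modality) in metadata")
  md <- md[md$sample_id %in% colnames(m), , drop = FALSE]
  out <- list()
  for (mod in unique(md$modality)) {
    sub <- md[md$modality == mod, ]
    times <- unique(sub[, c("time_index", "time_hours")])
    times <- times[order(times$time_hours), ]
    inds <- unique(sub[, c("individual", "group")])
    a <- array(NA_real_,
               dim = c(nrow(m), nrow(times), nrow(inds)),
               dimnames = list(rownames(m), times$time_index, inds$individual))
    for (r in seq_len(nrow(sub))) {
      a[, sub$time_index[r], sub$individual[r]] <- m[[sub$sample_id[r]]]
    }
    if (mod == "transcript" && any(a < 0, na.rm = TRUE))
      stop("transcript matrix contains a negative entry")
    out[[mod]] <- temporal_omics(a, mod, times$time_hours, inds$group)
  }
  out
}

#' Read a GMT annotation file
#'
#' Standard GMT: term, description, then member symbols, tab-separated.
#' Symbols and terms are uppercased. Malformed lines (fewer than 3 fields)
#' raise an error naming the line number. Parsing uses
#' [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return named list term -> character vector of symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " (fewer than 3 fields)")
  ann <- fgsea::gmtPathways(path)
  ann <- lapply(ann, function(v) sort(unique(toupper(v))))
  names(ann) <- toupper(names(ann))
  ann
}

#' Write an annotation map as GMT
#'
#' @param ann named list term -> symbols.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(names(ann), function(tm)
    paste(c(tm, "planted", ann[[tm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed edge table
#'
#' 2-3 column TSV `(source, target[, confidence])`; symbols are uppercased,
#' duplicate edges merged keeping the maximum confidence.
#'
#' @param path TSV path.
#' @param default_confidence confidence assigned when the column is absent.
#' @return A `prior_network` data.frame `(source, target, confidence)`.
#' @export
read_edges <- function(path, default_confidence = 1) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("edge table needs at least source and target columns")
  names(d)[1:2] <- c("source", "target")
  d$source <- toupper(d$source); d$target <- toupper(d$target)
  if (ncol(d) < 3L) d$confidence <- default_confidence
  else names(d)[3L] <- "confidence"
  if (any(d$confidence <= 0)) stop("confidences must be positive")
  d <- d[order(d$source, d$target, -d$confidence), ]
  d <- d[!duplicated(d[, c("source", "target")]), c("source", "target", "confidence")]
  rownames(d) <- NULL
  class(d) <- c("prior_network", "data.frame")
  d
}

#' Write an edge table as TSV
#'
#' @param edges data.frame with at least source and target columns.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in SIF format
#'
#' One line per edge: `source <tab> regulates <tab> target`.
#'
#' @param net an `inferred_network` (or data.frame with source/target).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sif <- function(net, path) {
  e <- if (inherits(net, "inferred_network")) net$edges else net
  writeLines(paste(e$source, "regulates", e$target, sep = "\t"), path)
  invisible(path)
}

#' Read a SIF file back to an edge data.frame
#'
#' @param path SIF path.
#' @return data.frame `(source, target)`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(source = vapply(parts, `[`, "", 1L),
             target = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Write a network as GraphML
#'
#' Cytoscape-compatible export via igraph, carrying `omega`,
#' `stability_frequency` edge attributes and `symbol`, `modality`, `cluster`
#' (and `layer`, when given) node attributes.
#'
#' @param net an `inferred_network`.
#' @param path output path.
#' @param layers optional `subnetwork_layers` supplying a layer attribute.
#' @return invisibly, the path.
#' @export
write_graphml <- function(net, path, layers = NULL) {
  nodes <- net$nodes
  if (!is.null(layers)) {
    nodes$layer <- NA_integer_
    nodes$layer[nodes$id %in% layers$layer1] <- 1L
    nodes$layer[nodes$id %in% layers$layer2] <- 2L
    nodes$layer[nodes$id %in% layers$layer3] <- 3L
  }
  e <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target,
               omega = e$omega_hat, stability_frequency = e$stability_frequency),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the ground-truth edge table
#'
#' @param net a `ground_truth_network`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_truth <- function(net, path) {
  write_edges(net$edges, path)
}

pipeline_config_keys <- c(
  "outdir", "seed", "simulate", "expression", "metadata", "prior",
  "annotations", "min_cpm", "min_samples", "pseudocount", "alpha_temporal",
  "alpha_response", "max_lag", "min_points", "lambda", "kappa", "B", "pi_thr",
  "subsample_fraction", "seeding_terms", "hub_threshold", "truth")

simulate_config_keys <- c("n_actors", "n_clusters", "mean_out_degree",
                          "attachment_exponent", "knockout_fraction_of_cluster1",
                          "noise_sd", "count_dispersion",
                          "translation_delay_steps", "protein_missing_rate",
                          "prior_coverage", "prior_false_edges")

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; defaults fill the rest. Either a `simulate`
#' block or `expression` + `metadata` paths must be supplied.
#'
#' @param config named list (for example from [yaml::read_yaml()]).
#' @return completed config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), simulate_config_keys)
    if (length(bad))
      stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(seed = 1L, min_cpm = 1, min_samples = 1L, pseudocount = 1,
                   alpha_temporal = 0.01, alpha_response = 0.05, max_lag = 3L,
                   min_points = 3L, lambda = "cv", kappa = 0.5, B = 100L,
                   pi_thr = 0.6, subsample_fraction = 0.5,
                   seeding_terms = c("cell cycle regulation", "proliferation"),
                   hub_threshold = 10L)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$outdir)) stop("config requires an outdir")
  if (is.null(config$simulate) &&
      (is.null(config$expression) || is.null(config$metadata)))
    stop("config requires either a simulate block or expression+metadata paths")
  class(config) <- "pipeline_config"
  config
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> signatures -> concordance ->
#' inference -> subnetwork -> benchmark (when a ground truth is available),
#' writing every stage's outputs plus the resolved configuration under
#' `config$outdir`. The global seed threads every stochastic stage; reruns
#' with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()] (or plain list passed through it).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out, "resolved_config.yaml"))
  res <- list()
  truth <- NULL

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    truth <- generate_network(
      n_actors = sc$n_actors %||% 50L, n_clusters = sc$n_clusters %||% 3L,
      mean_out_degree = sc$mean_out_degree %||% 1.5,
      attachment_exponent = sc$attachment_exponent %||% 1,
      knockout_fraction_of_cluster1 = sc$knockout_fraction_of_cluster1 %||% 0.5,
      seed = config$seed)
    cfg <- sim_config(noise_sd = sc$noise_sd %||% 0.25,
                      count_dispersion = sc$count_dispersion %||% 0.1,
                      translation_delay_steps = sc$translation_delay_steps %||% 2L,
                      protein_missing_rate = sc$protein_missing_rate %||% 0.05,
                      seed = config$seed)
    sim_p <- simulate_dataset(truth, cfg, "proliferative")
    sim_np <- simulate_dataset(truth, cfg, "nonproliferative")
    ann <- generate_annotations(truth, seed = config$seed,
                                seed_terms = config$seeding_terms)
    prior <- generate_prior(truth, coverage = sc$prior_coverage %||% 0.5,
                            false_edge_count = sc$prior_false_edges %||% 0L,
                            seed = config$seed)
    write_truth(truth, file.path(out, "truth_edges.tsv"))
    write_edges(prior, file.path(out, "prior_edges.tsv"))
    write_gmt(ann, file.path(out, "annotations.gmt"))
    datasets <- list(
      transcript = list(proliferative = sim_p$transcript,
                        nonproliferative = sim_np$transcript),
      protein = list(proliferative = sim_p$protein,
                     nonproliferative = sim_np$protein))
    for (mod in names(datasets)) for (grp in names(datasets[[mod]]))
      write_expression(datasets[[mod]][[grp]],
                       file.path(out, sprintf("%s_%s_matrix.tsv", mod, grp)),
                       file.path(out, sprintf("%s_%s_metadata.tsv", mod, grp)))
    res$simulate <- list(truth = truth, prior = prior, ann = ann)
  } else {
    datasets <- NULL
    loaded <- read_expression(config$expression, config$metadata)
    datasets <- lapply(loaded, function(ds) split_groups(ds))
    prior <- if (!is.null(config$prior)) read_edges(config$prior) else NULL
    ann <- if (!is.null(config$annotations)) read_gmt(config$annotations) else list()
    if (!is.null(config$truth)) truth <-
      list(edges = read_edges(config$truth))
    res$simulate <- NULL
  }

  # preprocess: filter + CPM for transcripts, quantile normalization for
  # proteins, then per-individual log2 fold changes
  fc <- list()
  for (grp in c("proliferative", "nonproliferative")) {
    tr <- datasets$transcript[[grp]]
    tr <- filter_low_expression(tr, config$min_cpm, config$min_samples)
    tr <- normalize_library_size(tr)
    fc$transcript[[grp]] <- log2fc_vs_t0(tr, config$pseudocount)
    pr <- datasets$protein[[grp]]
    pr <- quantile_normalize(pr)
    fc$protein[[grp]] <- log2fc_vs_t0(pr)
  }
  res$fold_changes <- fc

  # signatures per modality
  sig <- lapply(fc, function(f)
    compute_signatures(f$proliferative, f$nonproliferative,
                       config$alpha_temporal, config$alpha_response))
  pairs_temporal <- match_pairs(sig$transcript$temporal_p, sig$protein$temporal_p)
  write_signatures(sig, pairs_temporal, out)
  res$signatures <- sig
  res$matched_pairs <- pairs_temporal

  # concordance on matched temporal-signature pairs
  if (length(pairs_temporal) >= 1L) {
    g <- fc$transcript$proliferative$log2fc[pairs_temporal, , , drop = FALSE]
    p <- fc$protein$proliferative$log2fc[pairs_temporal, , , drop = FALSE]
    prof <- correlation_profile(g, p, config$min_points)
    dl <- delay_summary(g, p, config$max_lag,
                        protein_hours = fc$protein$proliferative$time_hours)
    write.table(prof, file.path(out, "concordance_correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dl$lags, file.path(out, "concordance_delays.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$concordance <- list(profile = prof, delay = dl,
                            concordance = sign_concordance(
                              pairs_temporal, sig$transcript$temporal_p,
                              sig$protein$temporal_p))
  }

  # joint cascade inference per group (gene and protein actors are distinct)
  nets <- list()
  for (grp in c("proliferative", "nonproliferative")) {
    joint <- joint_actor_series(fc, sig, grp)
    if (length(joint$clusters$m) < 2L) next
    lam <- config$lambda
    if (identical(lam, "cv")) {
      grid <- lambda_grid_default(joint$x, joint$clusters, length_out = 10L)
      lam <- cross_validate_lambda(joint$x, joint$clusters, prior, grid,
                                   kappa = config$kappa)$lambda_best
    }
    net <- stability_select(joint$x, joint$clusters, prior, lambda = lam,
                            kappa = config$kappa, B = config$B,
                            subsample_fraction = config$subsample_fraction,
                            pi_thr = config$pi_thr, seed = config$seed)
    net$nodes <- joint$nodes[match(net$nodes$id, joint$nodes$id), ]
    write_edges(cbind(net$edges,
                      source_cluster = joint$clusters$m[net$edges$source],
                      target_cluster = joint$clusters$m[net$edges$target]),
                file.path(out, sprintf("network_%s_edges.tsv", grp)))
    write_sif(net, file.path(out, sprintf("network_%s.sif", grp)))
    write_graphml(net, file.path(out, sprintf("network_%s.graphml", grp)))
    nets[[grp]] <- net
  }
  res$networks <- nets

  # subnetwork extraction and comparison
  subs <- list()
  for (grp in names(nets)) {
    seeds <- select_seeding_proteins(ann, config$seeding_terms, nets[[grp]])
    subs[[grp]] <- extract_subnetwork(nets[[grp]], seeds)
    write_graphml(nets[[grp]],
                  file.path(out, sprintf("subnetwork_%s.graphml", grp)),
                  layers = subs[[grp]])
  }
  if (length(subs) == 2L) {
    cmp <- compare_networks(subs$proliferative, subs$nonproliferative)
    jsonlite::write_json(cmp[c("n_common", "fraction_a", "fraction_b")],
                         file.path(out, "subnetwork_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    res$comparison <- cmp
  }
  res$subnetworks <- subs

  # benchmark against the planted truth (transcript-actor edges)
  if (!is.null(truth) && !is.null(nets$proliferative)) {
    tr_edges <- nets$proliferative$edges
    tr_nodes <- nets$proliferative$nodes
    tr_ids <- tr_nodes$id[tr_nodes$modality == "transcript"]
    tr_edges <- tr_edges[tr_edges$source %in% tr_ids & tr_edges$target %in% tr_ids, ]
    tr_edges$source <- tr_nodes$symbol[match(tr_edges$source, tr_nodes$id)]
    tr_edges$target <- tr_nodes$symbol[match(tr_edges$target, tr_nodes$id)]
    metr <- score_recovery(tr_edges, truth$edges)
    jsonlite::write_json(metr[c("tp", "fp", "fn", "sensitivity", "precision",
                                "f_score")],
                         file.path(out, "benchmark_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    res$benchmark <- metr
  }
  invisible(res)
}

# split one multi-group dataset into per-group datasets
split_groups <- function(ds) {
  out <- list()
  for (grp in unique(ds$groups)) {
    sel <- ds$groups == grp
    out[[grp]] <- temporal_omics(ds$values[, , sel, drop = FALSE], ds$modality,
                                 ds$time_hours, ds$groups[sel])
  }
  out
}

# assemble the joint (gene + protein) scaled actor series for one group,
# restricted to signature actors with clusters; protein NAs are mean-imputed
# within each series before scaling
joint_actor_series <- function(fc, sig, grp) {
  grab <- function(mod, suffix) {
    tests <- if (grp == "proliferative") sig[[mod]]$tests_temporal_p else
      sig[[mod]]$tests_temporal_np
    sig_set <- if (grp == "proliferative") sig[[mod]]$temporal_p else
      sig[[mod]]$temporal_np
    cl <- suppressMessages(
      assign_clusters(tests, alpha = sig_set$alpha, features = sig_set$features))
    if (length(cl$onset) == 0L) return(NULL)
    a <- fc[[mod]][[grp]]$log2fc[names(cl$onset), , , drop = FALSE]
    for (i in seq_len(dim(a)[1L])) for (p in seq_len(dim(a)[3L])) {
      v <- a[i, , p]
      if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
      if (anyNA(v)) v[] <- 0
      a[i, , p] <- v
    }
    dimnames(a)[[1L]] <- paste0(dimnames(a)[[1L]], suffix)
    list(x = a, onset = setNames(cl$onset, dimnames(a)[[1L]]),
         symbol = sub(suffix, "", dimnames(a)[[1L]], fixed = TRUE),
         modality = rep(mod, dim(a)[1L]))
  }
  gt <- grab("transcript", "|G")
  gp <- grab("protein", "|P")
  parts <- Filter(Negate(is.null), list(gt, gp))
  if (length(parts) == 0L)
    return(list(x = NULL, clusters = cluster_assignment(setNames(numeric(0), character(0))),
                nodes = NULL))
  x <- do.call(abind3, lapply(parts, `[[`, "x"))
  onset <- do.call(c, lapply(parts, `[[`, "onset"))
  nodes <- data.frame(
    id = unlist(lapply(parts, function(p) dimnames(p$x)[[1L]])),
    symbol = unlist(lapply(parts, `[[`, "symbol")),
    modality = unlist(lapply(parts, `[[`, "modality")),
    stringsAsFactors = FALSE)
  cl <- cluster_assignment(onset)
  nodes$cluster <- as.integer(cl$m[nodes$id])
  list(x = x, clusters = cl, nodes = nodes)
}

# bind arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1L) return(arrs[[1L]])
  d2 <- dim(arrs[[1L]])[2L]; d3 <- dim(arrs[[1L]])[3L]
  out <- array(NA_real_, dim = c(sum(vapply(arrs, function(a) dim(a)[1L], 0L)), d2, d3))
  dimnames(out) <- list(unlist(lapply(arrs, function(a) dimnames(a)[[1L]])),
                        dimnames(arrs[[1L]])[[2L]], dimnames(arrs[[1L]])[[3L]])
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

write_signatures <- function(sig, pairs_temporal, out) {
  rows <- list()
  for (mod in names(sig)) {
    for (set in c("temporal_p", "temporal_np", "response", "proliferative")) {
      s <- sig[[mod]][[set]]
      if (length(s$features) == 0L) next
      first <- s$first_time[s$features]
      dirs <- vapply(s$features, function(f) {
        d <- s$direction[s$direction$feature == f, ]
        d$direction[which.min(d$time)]
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = s$features, modality = mod, set = set,
        first_significant_time = as.integer(first), direction = dirs,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(symbol = character(0), modality = character(0),
               set = character(0), first_significant_time = integer(0),
               direction = character(0))
  write.table(tab, file.path(out, "signatures.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sizes <- lapply(sig, function(s) list(
    temporal_p = length(s$temporal_p$features),
    temporal_np = length(s$temporal_np$features),
    response = length(s$response$features),
    proliferative = length(s$proliferative$features)))
  sizes$matched_temporal_pairs <- length(pairs_temporal)
  jsonlite::write_json(sizes, file.path(out, "signature_sizes.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
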