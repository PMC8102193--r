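#' Select seeding proteins by annotation
#'
#' Protein actors annotated with any of the listed biological-process terms
#' and present in the network. Terms missing from the annotation map are
#' reported with a message, not an error.
#'
#' @param ann annotation map: named list term -> character vector of symbols
#'   (uppercase), as returned by [read_gmt()].
#' @param terms character vector of term names (case-insensitive). The default
#'   seeding terms are cell cycle regulation and proliferation.
#' @param network an `inferred_network` (or a character vector of protein
#'   symbols standing for the network's protein actors).
#'
#' @return character vector of seeding protein symbols.
#' @export
select_seeding_proteins <- function(ann,
                                    terms = c("cell cycle regulation", "proliferation"),
                                    network) {
  names(ann) <- toupper(names(ann))
  terms <- toupper(terms)
  missing_terms <- setdiff(terms, names(ann))
  if (length(missing_terms))
    message("annotation term(s) not found: ", paste(missing_terms, collapse = ", "))
  annotated <- sort(unique(toupper(unlist(ann[intersect(terms, names(ann))]))))
  if (inherits(network, "inferred_network")) {
    prot <- network$nodes$symbol[network$nodes$modality == "protein"]
    if (length(prot) == 0L) prot <- network$nodes$symbol
    intersect(annotated, toupper(prot))
  } else {
    intersect(annotated, toupper(network))
  }
}

#' Extract the seeded subnetwork and its three layers
#'
#' Subnetwork actors are the seeds having at least one link plus their direct
#' neighbors (distance 1, ignoring edge direction); induced edges are all
#' network edges with both endpoints inside. Layers: layer 1 the retained
#' seed proteins, layer 2 the genes whose symbol matches a layer-1 protein,
#' layer 3 the remaining actors. The three layers partition the subnetwork
#' exactly.
#'
#' @param net an `inferred_network` whose nodes carry `id`, `symbol`,
#'   `modality`.
#' @param seeds character vector of seeding protein symbols.
#'
#' @return A `subnetwork_layers`: list with `layer1`, `layer2`, `layer3`
#'   (node ids), `actors`, `induced_edges`, `nodes`.
#' @export
extract_subnetwork <- function(net, seeds) {
  nodes <- net$nodes
  seeds <- toupper(seeds)
  seed_ids <- nodes$id[toupper(nodes$symbol) %in% seeds &
                         (nodes$modality == "protein" |
                            !any(nodes$modality == "protein"))]
  e <- net$edges
  linked <- unique(c(e$source, e$target))
  seed_ids <- intersect(seed_ids, linked)          # isolated seeds are dropped
  nb <- unique(c(e$target[e$source %in% seed_ids],
                 e$source[e$target %in% seed_ids]))
  actors <- union(seed_ids, nb)
  induced <- e[e$source %in% actors & e$target %in% actors, , drop = FALSE]
  rownames(induced) <- NULL
  sub_nodes <- nodes[nodes$id %in% actors, , drop = FALSE]
  layer1 <- intersect(seed_ids, actors)
  l1_symbols <- toupper(nodes$symbol[nodes$id %in% layer1])
  layer2 <- sub_nodes$id[sub_nodes$modality == "transcript" &
                           toupper(sub_nodes$symbol) %in% l1_symbols]
  layer2 <- setdiff(layer2, layer1)
  layer3 <- setdiff(actors, union(layer1, layer2))
  structure(
    list(layer1 = sort(layer1), layer2 = sort(layer2), layer3 = sort(layer3),
         actors = sort(actors), induced_edges = induced, nodes = sub_nodes),
    class = "subnetwork_layers")
}

#' @export
print.subnetwork_layers <- function(x, ...) {
  cat(sprintf("<subnetwork_layers> %d actors (%d | %d | %d), %d induced edges\n",
              length(x$actors), length(x$layer1), length(x$layer2),
              length(x$layer3), nrow(x$induced_edges)))
  invisible(x)
}

#' Compare two subnetworks
#'
#' Common actors, the fraction they represent of each network, a per-layer
#' breakdown, and shared edges.
#'
#' @param a,b `subnetwork_layers` objects.
#' @return list with `common`, `n_common`, `fraction_a`, `fraction_b`,
#'   `per_layer` (data.frame), `shared_edges`.
#' @export
compare_networks <- function(a, b) {
  common <- intersect(a$actors, b$actors)
  key <- function(e) paste(e$source, e$target, sep = "\r")
  shared_edges <- a$induced_edges[key(a$induced_edges) %in% key(b$induced_edges), ,
                                  drop = FALSE]
  per_layer <- data.frame(
    layer = paste0("layer", 1:3),
    n_a = c(length(a$layer1), length(a$layer2), length(a$layer3)),
    n_b = c(length(b$layer1), length(b$layer2), length(b$layer3)),
    n_common = c(length(intersect(a$layer1, b$layer1)),
                 length(intersect(a$layer2, b$layer2)),
                 length(intersect(a$layer3, b$layer3))))
  list(common = sort(common), n_common = length(common),
       fraction_a = if (length(a$actors)) length(common) / length(a$actors) else NA_real_,
       fraction_b = if (length(b$actors)) length(common) / length(b$actors) else NA_real_,
       per_layer = per_layer,
       shared_edges = shared_edges)
}

#' Temporal biological-process counts
#'
#' For every annotation term and time index, counts the up- and downregulated
#' signature proteins annotated with the term, tracing how each process's
#' involvement evolves over the time course.
#'
#' @param sig a `signature_set` with a per-time `direction` table (proteins).
#' @param ann annotation map (named list term -> symbols).
#' @param times time indices to tabulate (default all present in `sig`).
#' @return data.frame `term, time, direction, count` (complete grid).
#' @export
temporal_function_counts <- function(sig, ann, times = NULL) {
  names(ann) <- toupper(names(ann))
  d <- sig$direction
  if (is.null(times))
    times <- if (nrow(d)) sort(unique(d$time)) else integer(0)
  grid <- expand.grid(term = names(ann), time = times,
                      direction = c("up", "down"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- vapply(seq_len(nrow(grid)), function(r) {
    members <- ann[[grid$term[r]]]
    sum(toupper(d$feature) %in% toupper(members) &
          d$time == grid$time[r] & d$direction == grid$direction[r])
  }, integer(1))
  grid[order(grid$term, grid$time, grid$direction), ]
}
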