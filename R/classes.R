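#' Temporal omics dataset container
#'
#' Holds one modality's feature x time x individual tensor together with the
#' time grid and individual group labels. Transcript values are non-negative
#' counts (or normalized counts); protein values are log2 intensities and may
#' be missing (`NA`).
#'
#' @param values numeric array `[n_features x (T+1) x n_individuals]` with
#'   dimnames `(feature, time index label, individual)`.
#' @param modality `"transcript"` or `"protein"`.
#' @param time_hours numeric vector of nominal hours, same length as the time
#'   dimension, starting at 0.
#' @param groups character vector of `"proliferative"`/`"nonproliferative"`,
#'   one per individual.
#'
#' @return An object of class `temporal_omics`.
#' @export
temporal_omics <- function(values, modality = c("transcript", "protein"),
                           time_hours, groups) {
  modality <- match.arg(modality)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (length(time_hours) != dim(values)[2L])
    stop("time_hours length must match the time dimension")
  if (time_hours[1L] != 0) stop("time grid must start at 0")
  if (length(groups) != dim(values)[3L])
    stop("one group label per individual is required")
  if (!all(groups %in% c("proliferative", "nonproliferative")))
    stop("groups must be 'proliferative' or 'nonproliferative'")
  if (is.null(dimnames(values)[[1L]]))
    stop("values must carry feature symbols as rownames")
  if (anyDuplicated(dimnames(values)[[1L]]))
    stop("feature symbols must be unique within a modality")
  if (modality == "transcript") {
    if (anyNA(values)) stop("transcript values cannot be missing")
    if (any(values < 0)) stop("transcript values must be non-negative")
  }
  if (is.null(dimnames(values)[[2L]]))
    dimnames(values)[[2L]] <- paste0("T", seq_len(dim(values)[2L]) - 1L)
  if (is.null(dimnames(values)[[3L]]))
    dimnames(values)[[3L]] <- paste0("I", seq_len(dim(values)[3L]))
  structure(
    list(values = values, modality = modality,
         time_hours = as.numeric(time_hours),
         groups = as.character(groups)),
    class = "temporal_omics")
}

#' @export
print.temporal_omics <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<temporal_omics> %s: %d features x %d time points x %d individuals\n",
              x$modality, d[1L], d[2L], d[3L]))
  cat("  hours:", paste(x$time_hours, collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.temporal_omics <- function(x) dim(x$values)

feature_symbols <- function(ds) dimnames(ds$values)[[1L]]
individual_ids <- function(ds) dimnames(ds$values)[[3L]]
time_labels <- function(ds) dimnames(ds$values)[[2L]]

#' Fold-change tensor
#'
#' Per-individual log2 fold changes of every post-baseline time point against
#' T0, as produced by [log2fc_vs_t0()].
#'
#' @param log2fc numeric array `[n_features x T x n_individuals]`.
#' @param modality `"transcript"` or `"protein"`.
#' @param pseudocount pseudocount used for count data (recorded for audit).
#' @param time_hours nominal hours of the T post-baseline points.
#' @param groups group labels per individual.
#'
#' @return An object of class `fold_change`.
#' @export
fold_change <- function(log2fc, modality, pseudocount = NA_real_,
                        time_hours = NULL, groups = NULL) {
  stopifnot(is.array(log2fc), length(dim(log2fc)) == 3L)
  structure(
    list(log2fc = log2fc, modality = modality, pseudocount = pseudocount,
         time_hours = time_hours, groups = groups),
    class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  d <- dim(x$log2fc)
  cat(sprintf("<fold_change> %s: %d features x %d times x %d individuals\n",
              x$modality, d[1L], d[2L], d[3L]))
  invisible(x)
}
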