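# helpers to flatten feature x time x individual tensors to feature x sample
# matrices (samples ordered individual-major) and back
flatten_samples <- function(values) {
  d <- dim(values)
  m <- matrix(values, d[1L], d[2L] * d[3L])
  rownames(m) <- dimnames(values)[[1L]]
  colnames(m) <- as.vector(outer(dimnames(values)[[2L]], dimnames(values)[[3L]],
                                 function(t, i) paste(i, t, sep = "_")))
  m
}

unflatten_samples <- function(m, template) {
  a <- array(m, dim = dim(template), dimnames = dimnames(template))
  a
}

#' Filter lowly expressed transcript features
#'
#' Keeps features whose counts-per-million reach `min_norm_count` in at least
#' `min_samples` samples (a sample being one individual x time point).
#' Feature order is preserved.
#'
#' @param ds a transcript [temporal_omics].
#' @param min_norm_count CPM threshold (default 1).
#' @param min_samples minimum number of samples reaching it (default 1).
#'
#' @return Filtered [temporal_omics].
#' @export
filter_low_expression <- function(ds, min_norm_count = 1, min_samples = 1L) {
  stopifnot(inherits(ds, "temporal_omics"))
  if (ds$modality != "transcript")
    stop("filtering applies to the transcript modality")
  cpm <- flatten_samples(normalize_library_size(ds)$values)
  keep <- rowSums(cpm >= min_norm_count) >= min_samples
  if (!any(keep)) warning("all features removed by expression filter")
  temporal_omics(ds$values[keep, , , drop = FALSE], ds$modality,
                 ds$time_hours, ds$groups)
}

#' Library-size normalization to counts per million
#'
#' Each sample (individual x time point) column is scaled so its total count
#' is one million.
#'
#' @param ds a transcript [temporal_omics] of counts.
#' @return [temporal_omics] of CPM values.
#' @export
normalize_library_size <- function(ds) {
  stopifnot(inherits(ds, "temporal_omics"))
  if (ds$modality != "transcript")
    stop("library-size normalization applies to the transcript modality")
  m <- flatten_samples(ds$values)
  tot <- colSums(m)
  if (any(tot == 0)) stop("all-zero sample column cannot be normalized")
  m <- sweep(m, 2L, tot, "/") * 1e6
  temporal_omics(unflatten_samples(m, ds$values), ds$modality,
                 ds$time_hours, ds$groups)
}

#' Quantile normalization of protein log-intensities
#'
#' Replaces each column's observed values by the mean quantile profile across
#' samples (average-rank ties), leaving missing entries missing. Uses
#' [limma::normalizeQuantiles()].
#'
#' @param ds a protein [temporal_omics] (NAs allowed).
#' @return [temporal_omics] with quantile-normalized values.
#' @export
quantile_normalize <- function(ds) {
  stopifnot(inherits(ds, "temporal_omics"))
  if (ds$modality != "protein")
    stop("quantile normalization applies to the protein modality")
  m <- flatten_samples(ds$values)
  if (any(colSums(!is.na(m)) < 2L))
    stop("every sample column needs at least 2 observed values")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  temporal_omics(unflatten_samples(qn, ds$values), ds$modality,
                 ds$time_hours, ds$groups)
}

#' Per-individual log2 fold changes against T0
#'
#' For transcripts, `log2((v_t + pseudocount) / (v_0 + pseudocount))`; for
#' proteins (already on log2 scale) the difference `v_t - v_0`, with missing
#' entries propagating: a missing protein T0 makes the whole feature x
#' individual series missing.
#'
#' @param ds a normalized [temporal_omics].
#' @param pseudocount non-negative pseudocount for count data (default 1).
#'
#' @return A [fold_change] tensor over T1..T8.
#' @export
log2fc_vs_t0 <- function(ds, pseudocount = 1) {
  stopifnot(inherits(ds, "temporal_omics"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  v <- ds$values
  v0 <- array(v[, 1L, ], dim = dim(v)[c(1L, 3L)])
  vt <- v[, -1L, , drop = FALSE]
  if (ds$modality == "transcript") {
    fc <- log2(sweep(vt + pseudocount, c(1L, 3L), v0 + pseudocount, "/"))
  } else {
    fc <- sweep(vt, c(1L, 3L), v0, "-")
    # missing T0 censors the whole series for that feature x individual
    na0 <- which(is.na(v0), arr.ind = TRUE)
    for (r in seq_len(nrow(na0))) fc[na0[r, 1L], , na0[r, 2L]] <- NA_real_
  }
  dimnames(fc) <- list(dimnames(v)[[1L]], dimnames(v)[[2L]][-1L], dimnames(v)[[3L]])
  fold_change(fc, ds$modality, pseudocount,
              time_hours = ds$time_hours[-1L], groups = ds$groups)
}
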