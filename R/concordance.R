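#' Median gene-to-protein correlation at a time point
#'
#' For every matched gene-protein pair and individual, the Pearson correlation
#' between the gene and protein log2 fold changes over the cumulative window
#' of indices 1..t is computed; the median across pairs x individuals is
#' returned. Windows with fewer than `min_points` complete observations or
#' zero variance in either series are dropped.
#'
#' @param gene_fc numeric array `[n_pairs x T x n_individuals]` of gene log2
#'   fold changes (pairs in matched order).
#' @param protein_fc matching array of protein log2 fold changes (NAs
#'   allowed).
#' @param t time index (cumulative window 1..t); must be >= `min_points`.
#' @param min_points minimum complete points per window (default 3).
#'
#' @return list with `median_correlation` (NA-flagged when no valid window),
#'   `n_windows` used.
#' @export
correlation_by_time <- function(gene_fc, protein_fc, t, min_points = 3L) {
  stopifnot(identical(dim(gene_fc), dim(protein_fc)))
  if (t < min_points) stop("cumulative window must hold at least min_points points")
  cors <- c()
  for (i in seq_len(dim(gene_fc)[1L])) {
    for (p in seq_len(dim(gene_fc)[3L])) {
      g <- gene_fc[i, seq_len(t), p]
      q <- protein_fc[i, seq_len(t), p]
      ok <- !is.na(g) & !is.na(q)
      if (sum(ok) < min_points) next
      if (sd(g[ok]) == 0 || sd(q[ok]) == 0) next
      cors <- c(cors, cor(g[ok], q[ok]))
    }
  }
  list(median_correlation = if (length(cors)) median(cors) else NA_real_,
       n_windows = length(cors))
}

#' Median correlation profile over all time points
#'
#' Applies [correlation_by_time()] at every `t` from `min_points` to T.
#'
#' @inheritParams correlation_by_time
#' @return data.frame with `time`, `median_correlation`, `n_windows`.
#' @export
correlation_profile <- function(gene_fc, protein_fc, min_points = 3L) {
  ts <- seq.int(min_points, dim(gene_fc)[2L])
  out <- lapply(ts, function(t) {
    r <- correlation_by_time(gene_fc, protein_fc, t, min_points)
    data.frame(time = t, median_correlation = r$median_correlation,
               n_windows = r$n_windows)
  })
  do.call(rbind, out)
}

#' Estimate the translation delay of one gene-protein pair
#'
#' The index lag in `[0, max_lag]` maximizing the Pearson correlation between
#' the gene series and the protein series shifted back by that many steps
#' (overlapping support only); ties go to the smaller lag.
#'
#' @param gene numeric gene log2 fold-change series (length T).
#' @param protein numeric protein log2 fold-change series (length T, NAs
#'   allowed).
#' @param max_lag maximum lag searched; must be < T - 2 so at least 3 points
#'   overlap.
#'
#' @return integer lag, or `NA` (flagged) when every candidate window is
#'   degenerate (constant series).
#' @export
estimate_delay <- function(gene, protein, max_lag = 3L) {
  T <- length(gene)
  stopifnot(length(protein) == T)
  if (max_lag >= T - 2L) stop("max_lag must be < T - 2")
  best_lag <- NA_integer_
  best_cor <- -Inf
  for (lag in 0:max_lag) {
    g <- gene[seq_len(T - lag)]
    q <- protein[seq.int(lag + 1L, T)]
    ok <- !is.na(g) & !is.na(q)
    if (sum(ok) < 3L) next
    if (sd(g[ok]) == 0 || sd(q[ok]) == 0) next
    r <- cor(g[ok], q[ok])
    if (r > best_cor + 1e-12) {           # strict improvement: ties keep smaller lag
      best_cor <- r
      best_lag <- lag
    }
  }
  best_lag
}

#' Cohort translation-delay summary
#'
#' Runs [estimate_delay()] on every pair x individual series and summarizes
#' the lag distribution, converting the median lag to nominal hours via the
#' protein time grid (median spacing of `lag` index steps across the grid).
#'
#' @inheritParams correlation_by_time
#' @param max_lag maximum lag searched.
#' @param protein_hours nominal hours of the T post-stimulation protein time
#'   points (optional; enables the hour conversion).
#'
#' @return list with `lags` (data.frame pair/individual/lag),
#'   `median_lag_steps`, `median_lag_hours` (NA without a grid).
#' @export
delay_summary <- function(gene_fc, protein_fc, max_lag = 3L, protein_hours = NULL) {
  rows <- list()
  for (i in seq_len(dim(gene_fc)[1L])) {
    for (p in seq_len(dim(gene_fc)[3L])) {
      lag <- estimate_delay(gene_fc[i, , p], protein_fc[i, , p], max_lag)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = dimnames(gene_fc)[[1L]][i] %||% as.character(i),
        individual = p, lag = lag)
    }
  }
  lags <- do.call(rbind, rows)
  med <- median(lags$lag, na.rm = TRUE)
  med_h <- NA_real_
  if (!is.null(protein_hours) && is.finite(med) && med >= 1) {
    steps <- round(med)
    idx <- seq.int(steps + 1L, length(protein_hours))
    med_h <- median(protein_hours[idx] - protein_hours[idx - steps])
  } else if (is.finite(med) && med == 0) med_h <- 0
  list(lags = lags, median_lag_steps = med, median_lag_hours = med_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Directional concordance of matched gene-protein pairs
#'
#' Each pair's dominant gene direction is the sign of the log2 fold change at
#' its largest-magnitude significant time (per the supplied signature
#' directions); likewise for the protein. The returned fraction is the share
#' of pairs whose dominant directions agree, among pairs with both directions
#' defined.
#'
#' @param pairs character vector of matched symbols.
#' @param gene_sig `signature_set` for genes (with `direction` table).
#' @param protein_sig `signature_set` for proteins.
#'
#' @return list with `concordance` fraction, `n_used`, `n_excluded`.
#' @export
sign_concordance <- function(pairs, gene_sig, protein_sig) {
  if (length(pairs) == 0L) stop("empty pair list")
  dominant <- function(sig, sym) {
    d <- sig$direction[sig$direction$feature == sym, ]
    if (nrow(d) == 0L || all(is.na(d$log2fc))) return(NA_character_)
    d$direction[which.max(abs(d$log2fc))]
  }
  g <- vapply(pairs, dominant, character(1), sig = gene_sig)
  p <- vapply(pairs, dominant, character(1), sig = protein_sig)
  ok <- !is.na(g) & !is.na(p)
  list(concordance = if (any(ok)) mean(g[ok] == p[ok]) else NA_real_,
       n_used = sum(ok), n_excluded = sum(!ok))
}
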