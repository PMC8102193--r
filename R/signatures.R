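# Newton inversion of the trigamma function, used by the variance-shrinkage
# moment estimator. Monotone decreasing on (0, Inf).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes variance shrinkage
#'
#' Shrinks per-feature sample variances toward a pooled prior variance,
#' estimating the prior degrees of freedom `d0` and scale `s0^2` by method of
#' moments on the log variances (the observed log variance of a feature with
#' `d` residual degrees of freedom is modeled as log s0^2 plus a scaled log-F
#' fluctuation).
#'
#' @param s2 vector of sample variances (zeros allowed).
#' @param df vector (or scalar) of residual degrees of freedom.
#'
#' @return list with `d0`, `s02` and `s2_shrunk = (d0 s0^2 + d s^2)/(d0 + d)`.
#' @export
squeeze_variances <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) return(list(d0 = Inf, s02 = 0, s2_shrunk = rep(0, length(s2))))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1L) var(e) - mean(trigamma(df[ok] / 2)) else 0
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    shrunk <- (d0 * s02 + df * ifelse(is.finite(s2), s2, 0)) / (d0 + df)
  } else {
    d0 <- Inf
    s02 <- exp(emean)
    shrunk <- rep(s02, length(s2))
  }
  list(d0 = d0, s02 = s02, s2_shrunk = shrunk)
}

# shared grid machinery: build one row per feature x time with summary stats,
# then moderate variances across the whole family
moderated_grid <- function(stats_df) {
  sq <- squeeze_variances(stats_df$s2[!stats_df$untestable],
                          stats_df$df[!stats_df$untestable])
  stats_df$s2_shrunk <- NA_real_
  stats_df$s2_shrunk[!stats_df$untestable] <- sq$s2_shrunk
  with_stat <- !stats_df$untestable
  se <- sqrt(stats_df$s2_shrunk[with_stat]) * stats_df$se_mult[with_stat]
  eff <- stats_df$effect[with_stat]
  stat <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, sign(eff) * Inf))
  dft <- if (is.finite(sq$d0)) sq$d0 + stats_df$df[with_stat] else Inf
  p <- 2 * pt(-abs(stat), df = dft)
  stats_df$statistic <- NA_real_
  stats_df$p_value <- NA_real_
  stats_df$statistic[with_stat] <- stat
  stats_df$p_value[with_stat] <- p
  stats_df$q_value <- bh_fdr(stats_df$p_value)
  attr(stats_df, "d0") <- sq$d0
  attr(stats_df, "s02") <- sq$s02
  stats_df
}

#' Moderated one-sample tests of log2 fold change versus zero
#'
#' For every feature and post-stimulation time point, a one-sample moderated t
#' statistic on the per-individual log2 fold changes:
#' `mean * sqrt(n) / s_tilde`, with the shrunken standard deviation from
#' [squeeze_variances()] estimated across the full feature x time family, and
#' a two-sided p from a t distribution on `d0 + n - 1` degrees of freedom.
#' Cells with fewer than 2 non-missing individuals are flagged untestable and
#' excluded from the BH family.
#'
#' @param fc a [fold_change] tensor.
#'
#' @return data.frame with columns `feature, time, n, log2fc_mean, s2, df,
#'   statistic, p_value, q_value, untestable`; attributes `d0`, `s02`.
#' @export
temporal_tests <- function(fc) {
  stopifnot(inherits(fc, "fold_change"))
  a <- fc$log2fc
  d <- dim(a)
  feats <- rep(dimnames(a)[[1L]], times = d[2L])
  times <- rep(seq_len(d[2L]), each = d[1L])
  n <- apply(!is.na(a), c(1L, 2L), sum)
  m <- apply(a, c(1L, 2L), function(x) mean(x, na.rm = TRUE))
  s2 <- apply(a, c(1L, 2L), function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else var(x)
  })
  df <- data.frame(
    feature = feats, time = times,
    n = as.vector(n), log2fc_mean = as.vector(m),
    s2 = as.vector(s2), df = as.vector(n) - 1,
    stringsAsFactors = FALSE)
  df$untestable <- df$n < 2L
  df$effect <- ifelse(df$untestable, NA_real_, df$log2fc_mean)
  df$se_mult <- 1 / sqrt(df$n)
  out <- moderated_grid(df)
  out$effect <- NULL; out$se_mult <- NULL
  out
}

#' Moderated two-sample tests between groups
#'
#' For every feature and time, a two-sample moderated t on the per-individual
#' log2 fold changes of the proliferative versus nonproliferative group, using
#' a pooled within-group variance shrunk across the full family. Cells with
#' fewer than 2 non-missing individuals in either group are untestable.
#'
#' @param fc_p [fold_change] of the proliferative group.
#' @param fc_np [fold_change] of the nonproliferative group (same features and
#'   times).
#'
#' @return data.frame as in [temporal_tests()], with `log2fc_mean` the group
#'   difference (P minus NP).
#' @export
response_tests <- function(fc_p, fc_np) {
  stopifnot(inherits(fc_p, "fold_change"), inherits(fc_np, "fold_change"))
  if (!identical(dim(fc_p$log2fc)[1:2], dim(fc_np$log2fc)[1:2]))
    stop("fold-change tensors must share features and times")
  a <- fc_p$log2fc; b <- fc_np$log2fc
  d <- dim(a)
  stat1 <- function(x) {
    x <- x[!is.na(x)]
    c(length(x), if (length(x)) mean(x) else NA_real_,
      if (length(x) > 1L) var(x) else NA_real_)
  }
  grid <- expand.grid(fi = seq_len(d[1L]), ti = seq_len(d[2L]))
  res <- t(vapply(seq_len(nrow(grid)), function(r) {
    xa <- a[grid$fi[r], grid$ti[r], ]
    xb <- b[grid$fi[r], grid$ti[r], ]
    sa <- stat1(xa); sb <- stat1(xb)
    n1 <- sa[1L]; n2 <- sb[1L]
    if (n1 < 2L || n2 < 2L)
      return(c(n1, n2, NA, NA, NA, NA))
    s2p <- ((n1 - 1) * sa[3L] + (n2 - 1) * sb[3L]) / (n1 + n2 - 2)
    c(n1, n2, sa[2L] - sb[2L], s2p, n1 + n2 - 2, sqrt(1 / n1 + 1 / n2))
  }, numeric(6)))
  df <- data.frame(
    feature = dimnames(a)[[1L]][grid$fi], time = grid$ti,
    n = res[, 1L] + res[, 2L], log2fc_mean = res[, 3L],
    s2 = res[, 4L], df = res[, 5L],
    stringsAsFactors = FALSE)
  df$untestable <- is.na(res[, 4L])
  df$df[df$untestable] <- 0
  df$effect <- res[, 3L]
  df$se_mult <- res[, 6L]
  out <- moderated_grid(df)
  out$effect <- NULL; out$se_mult <- NULL
  out
}

#' One-sample moderated test for a single feature and time
#'
#' Convenience accessor running [temporal_tests()] and extracting one cell.
#'
#' @param fc a [fold_change] tensor.
#' @param feature feature symbol.
#' @param t time index (1..T).
#' @return list with `statistic` and `p_value`.
#' @export
moderated_paired_test <- function(fc, feature, t) {
  res <- temporal_tests(fc)
  row <- res[res$feature == feature & res$time == t, ]
  if (nrow(row) != 1L) stop("feature/time not found")
  if (row$untestable) stop("feature is untestable at this time (fewer than 2 observations)")
  list(statistic = row$statistic, p_value = row$p_value)
}

#' Two-group moderated test for a single feature and time
#'
#' @param fc_p,fc_np [fold_change] tensors of the two groups.
#' @param feature feature symbol.
#' @param t time index (1..T).
#' @return list with `statistic` and `p_value`.
#' @export
two_group_test <- function(fc_p, fc_np, feature, t) {
  res <- response_tests(fc_p, fc_np)
  row <- res[res$feature == feature & res$time == t, ]
  if (nrow(row) != 1L) stop("feature/time not found")
  if (row$untestable) stop("feature is untestable at this time")
  list(statistic = row$statistic, p_value = row$p_value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment via [stats::p.adjust()], with `NA` (untestable)
#' entries excluded from the family and returned as `NA`.
#'
#' @param p_values numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return q values, same length.
#' @export
bh_fdr <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p values must lie in [0, 1]")
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Temporal (or response) signature from a test grid
#'
#' The union over time of features with `q <= alpha`, with the up/down
#' direction recorded at each significant time from the sign of the mean log2
#' fold change, and the first significant time per feature.
#'
#' @param results a test grid from [temporal_tests()] or [response_tests()].
#' @param alpha FDR threshold (default 0.01 for the temporal signature; use
#'   0.05 for the response signature).
#'
#' @return A `signature_set`: list with `features` (sorted character),
#'   `direction` (data.frame feature/time/direction/log2fc), `first_time`
#'   (named integer), and `alpha`.
#' @export
temporal_signature <- function(results, alpha = 0.01) {
  sig <- !is.na(results$q_value) & results$q_value <= alpha
  dir <- results[sig, c("feature", "time", "log2fc_mean")]
  dir$direction <- ifelse(dir$log2fc_mean >= 0, "up", "down")
  names(dir)[3L] <- "log2fc"
  dir <- dir[order(dir$feature, dir$time), c("feature", "time", "direction", "log2fc")]
  rownames(dir) <- NULL
  first_time <- if (nrow(dir)) vapply(split(dir$time, dir$feature), min, numeric(1)) else
    setNames(numeric(0), character(0))
  structure(
    list(features = sort(unique(dir$feature)), direction = dir,
         first_time = first_time, alpha = alpha),
    class = "signature_set")
}

#' Response signature (proliferative versus nonproliferative)
#'
#' Identical union/direction logic to [temporal_signature()] at the response
#' FDR threshold (default 5%).
#'
#' @inheritParams temporal_signature
#' @return A `signature_set`.
#' @export
response_signature <- function(results, alpha = 0.05) {
  temporal_signature(results, alpha = alpha)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d features (alpha = %g)\n",
              length(x$features), x$alpha))
  invisible(x)
}

#' Proliferative signature: intersection of temporal and response signatures
#'
#' @param temporal_p `signature_set` of the proliferative group's temporal
#'   signature.
#' @param response `signature_set` of the response (P vs NP) signature.
#' @return A `signature_set` on the exact intersection, directions taken from
#'   the temporal signature.
#' @export
proliferative_signature <- function(temporal_p, response) {
  feats <- intersect(temporal_p$features, response$features)
  dir <- temporal_p$direction[temporal_p$direction$feature %in% feats, ]
  rownames(dir) <- NULL
  first_time <- temporal_p$first_time[names(temporal_p$first_time) %in% feats]
  structure(
    list(features = sort(feats), direction = dir, first_time = first_time,
         alpha = c(temporal = temporal_p$alpha, response = response$alpha)),
    class = "signature_set")
}

#' Match gene and protein signature symbols
#'
#' Symbols are uppercased and matched by exact string.
#'
#' @param gene_set character vector (or `signature_set`) of gene symbols.
#' @param protein_set character vector (or `signature_set`) of protein symbols.
#' @return sorted character vector of shared symbols.
#' @export
match_pairs <- function(gene_set, protein_set) {
  g <- if (inherits(gene_set, "signature_set")) gene_set$features else gene_set
  p <- if (inherits(protein_set, "signature_set")) protein_set$features else protein_set
  sort(intersect(toupper(g), toupper(p)))
}

#' Summarize the gene/protein symbol overlap of two signature sets
#'
#' Reports the modality set sizes, the number of unique symbols in the union,
#' and the number of shared symbols (which equals
#' `n_gene + n_protein - n_unique`).
#'
#' @inheritParams match_pairs
#' @return list with `n_gene`, `n_protein`, `n_unique_symbols`, `n_shared`,
#'   `shared`.
#' @export
signature_summary <- function(gene_set, protein_set) {
  g <- toupper(if (inherits(gene_set, "signature_set")) gene_set$features else gene_set)
  p <- toupper(if (inherits(protein_set, "signature_set")) protein_set$features else protein_set)
  shared <- sort(intersect(g, p))
  list(n_gene = length(unique(g)), n_protein = length(unique(p)),
       n_unique_symbols = length(union(g, p)), n_shared = length(shared),
       shared = shared)
}

#' Compute the full signature-set bundle for one modality
#'
#' Runs the temporal tests in both groups and the response tests, then forms
#' the temporal, response, and proliferative signatures.
#'
#' @param fc_p,fc_np [fold_change] tensors of the proliferative and
#'   nonproliferative groups.
#' @param alpha_temporal temporal FDR threshold (default 0.01).
#' @param alpha_response response FDR threshold (default 0.05).
#'
#' @return list with `tests_temporal_p`, `tests_temporal_np`,
#'   `tests_response`, `temporal_p`, `temporal_np`, `response`,
#'   `proliferative`.
#' @export
compute_signatures <- function(fc_p, fc_np, alpha_temporal = 0.01,
                               alpha_response = 0.05) {
  tt_p <- temporal_tests(fc_p)
  tt_np <- temporal_tests(fc_np)
  tr <- response_tests(fc_p, fc_np)
  sig_t_p <- temporal_signature(tt_p, alpha_temporal)
  sig_t_np <- temporal_signature(tt_np, alpha_temporal)
  sig_r <- response_signature(tr, alpha_response)
  list(tests_temporal_p = tt_p, tests_temporal_np = tt_np, tests_response = tr,
       temporal_p = sig_t_p, temporal_np = sig_t_np, response = sig_r,
       proliferative = proliferative_signature(sig_t_p, sig_r))
}
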