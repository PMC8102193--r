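#' Score an inferred network against the planted truth
#'
#' Edge-set confusion counts (directed by default): sensitivity (recall)
#' TP/(TP+FN), precision TP/(TP+FP), and their harmonic mean F-score (0 when
#' both are 0). An empty truth flags sensitivity as undefined; an empty
#' inferred set flags precision as undefined.
#'
#' @param inferred an `inferred_network` (or data.frame with source/target).
#' @param truth a `ground_truth_network` (or data.frame with source/target).
#' @param directed compare oriented edges (default `TRUE`); undirected
#'   comparison collapses each edge to an unordered pair.
#'
#' @return A `recovery_metrics` list: `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `f_score`, `undefined` (character flags).
#' @export
score_recovery <- function(inferred, truth, directed = TRUE) {
  ie <- if (inherits(inferred, "inferred_network")) inferred$edges else inferred
  te <- if (inherits(truth, "ground_truth_network")) truth$edges else truth
  ekey <- function(e) {
    if (nrow(e) == 0L) return(character(0))
    if (directed) paste(e$source, e$target, sep = "\r")
    else paste(pmin(e$source, e$target), pmax(e$source, e$target), sep = "\r")
  }
  ik <- unique(ekey(ie)); tk <- unique(ekey(te))
  tp <- length(intersect(ik, tk))
  fp <- length(setdiff(ik, tk))
  fn <- length(setdiff(tk, ik))
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  prec <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "precision"); NA_real_ }
  f <- if (is.na(sens) || is.na(prec)) NA_real_
  else if (sens + prec == 0) 0
  else 2 * sens * prec / (sens + prec)
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, f_score = f, undefined = undefined),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("<recovery_metrics> TP %d FP %d FN %d | sens %.3f prec %.3f F %.3f\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$f_score))
  invisible(x)
}

#' One simulate-infer-score run on latent series
#'
#' Generates a planted network, simulates the proliferative group, assigns
#' temporal clusters from the latent response onsets, infers the network
#' (single LASSO fit and, optionally, stability selection), and scores both
#' against the truth. Inference runs on the latent abundance series, the
#' scale on which the model's unit-variance residual contract is stated.
#'
#' @param n_actors,n_clusters network size.
#' @param noise_sd latent propagation noise sd. Alternatively set `snr` to
#'   calibrate it against the planted signal.
#' @param snr optional signal-to-noise variance ratio; when given, a noiseless
#'   pilot simulation measures the RMS amplitude of the driven actors' latent
#'   trajectories and the noise sd is set to `rms / sqrt(snr)`.
#' @param prior_coverage fraction of true edges given to the prior (`NA`
#'   disables the prior).
#' @param kappa prior penalty factor.
#' @param lambda LASSO penalty; `"cv"` selects one pooled penalty by grouped
#'   cross-validation on the default grid, `"cv_target"` one penalty per
#'   target (the package default).
#' @param stability run stability selection as well (default `TRUE`).
#' @param B,pi_thr stability-selection constants.
#' @param seed integer seed driving network, data, prior, and resampling.
#' @param mean_out_degree planted mean out-degree.
#' @param refit_ols apply the post-selection OLS refit to the single fit
#'   (default `FALSE`).
#'
#' @return list with `metrics_single`, `metrics_stability` (or NULL),
#'   `lambda`, `net_truth`, `clusters`.
#' @export
recovery_run <- function(n_actors = 50L, n_clusters = 3L, noise_sd = 0.25,
                         snr = NULL, prior_coverage = NA, kappa = 0.5,
                         lambda = "cv_target", stability = TRUE, B = 100L,
                         pi_thr = 0.6, seed = 1L, mean_out_degree = 1.5,
                         refit_ols = FALSE) {
  net <- generate_network(n_actors, n_clusters, mean_out_degree = mean_out_degree,
                          attachment_exponent = 1,
                          knockout_fraction_of_cluster1 = 0, seed = seed)
  if (!is.null(snr)) {
    pilot <- simulate_dataset(net, sim_config(noise_sd = 0,
                                              protein_missing_rate = 0,
                                              seed = seed), "proliferative")
    rms <- sqrt(mean(pilot$latent[net$cluster_of > 1L, -1L, ]^2))
    noise_sd <- rms / sqrt(snr)
  }
  cfg <- sim_config(noise_sd = noise_sd, count_dispersion = 0.1,
                    protein_missing_rate = 0, seed = seed)
  sim <- simulate_dataset(net, cfg, "proliferative")
  x <- sim$latent[, -1L, , drop = FALSE]          # post-stimulation series
  clusters <- assign_clusters_from_series(x)
  x <- x[names(clusters$m), , , drop = FALSE]
  prior <- if (!is.na(prior_coverage))
    generate_prior(net, coverage = prior_coverage, false_edge_count = 0L,
                   seed = seed) else NULL
  lam <- if (identical(lambda, "cv") || identical(lambda, "cv_target")) {
    grid <- lambda_grid_default(x, clusters, length_out = 10L)
    cv <- cross_validate_lambda(x, clusters, prior, grid, kappa = kappa,
                                per_target = identical(lambda, "cv_target"))
    if (identical(lambda, "cv_target")) cv$lambda_targets else cv$lambda_best
  } else lambda
  single <- fit_cascade(x, clusters, prior, lambda = lam, kappa = kappa,
                        max_iter = 1L, refit_ols = refit_ols)
  ms <- score_recovery(network_from_model(single), net)
  mstab <- NULL
  if (stability) {
    stab <- stability_select(x, clusters, prior, lambda = lam, kappa = kappa,
                             B = B, pi_thr = pi_thr, seed = seed)
    mstab <- score_recovery(stab, net)
  }
  list(metrics_single = ms, metrics_stability = mstab, lambda = lam,
       net_truth = net, clusters = clusters, x = x, prior = prior,
       noise_sd = noise_sd)
}

#' Run the recovery experiment over a configuration grid
#'
#' For each grid row and seed: simulate, assign clusters, infer, and score.
#' Failures of individual runs are recorded per row rather than aborting the
#' experiment.
#'
#' @param grid data.frame with columns among `n_actors`, `n_clusters`,
#'   `noise_sd`, `prior_coverage`, `kappa` (missing columns take
#'   [recovery_run()] defaults).
#' @param seeds integer vector of seeds.
#' @param ... further arguments passed to [recovery_run()].
#'
#' @return list with `metrics` (tidy data.frame, one row per grid x seed) and
#'   `summary` (medians and IQRs of F-scores per grid row).
#' @export
run_recovery_experiment <- function(grid, seeds, ...) {
  defaults <- list(n_actors = 50L, n_clusters = 3L, noise_sd = 0.25,
                   prior_coverage = NA, kappa = 0.5)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    pars <- defaults
    for (cn in intersect(names(grid), names(defaults))) pars[[cn]] <- grid[[cn]][g]
    for (s in seeds) {
      res <- tryCatch(
        do.call(recovery_run, c(pars, list(seed = s), list(...))),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          grid_row = g, seed = s, pars, error = conditionMessage(res),
          sensitivity_single = NA, precision_single = NA, f_single = NA,
          sensitivity_stability = NA, precision_stability = NA, f_stability = NA)
        next
      }
      ms <- res$metrics_single; mb <- res$metrics_stability
      rows[[length(rows) + 1L]] <- data.frame(
        grid_row = g, seed = s, pars, error = NA_character_,
        sensitivity_single = ms$sensitivity, precision_single = ms$precision,
        f_single = ms$f_score,
        sensitivity_stability = if (is.null(mb)) NA_real_ else mb$sensitivity,
        precision_stability = if (is.null(mb)) NA_real_ else mb$precision,
        f_stability = if (is.null(mb)) NA_real_ else mb$f_score)
    }
  }
  metrics <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(metrics, metrics$grid_row), function(d) {
    data.frame(grid_row = d$grid_row[1L],
               median_f_single = median(d$f_single, na.rm = TRUE),
               iqr_f_single = IQR(d$f_single, na.rm = TRUE),
               median_f_stability = median(d$f_stability, na.rm = TRUE),
               iqr_f_stability = IQR(d$f_stability, na.rm = TRUE),
               n_failed = sum(!is.na(d$error)))
  }))
  rownames(summ) <- NULL
  list(metrics = metrics, summary = summ)
}
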