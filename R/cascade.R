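#' Cluster assignment from differential-test onsets
#'
#' Each actor's temporal cluster is the rank of its first significant time
#' index among the distinct onset times present in the cohort (cluster 1 =
#' earliest onset). Actors with no significant time are excluded with a
#' message.
#'
#' @param results test grid from [temporal_tests()] (with q values).
#' @param alpha FDR threshold defining significance (default 0.01).
#' @param features optional restriction to a feature subset.
#'
#' @return A `cluster_assignment`: list with `m` (named integer clusters) and
#'   `onset` (named integer first significant time).
#' @export
assign_clusters <- function(results, alpha = 0.01, features = NULL) {
  sig <- !is.na(results$q_value) & results$q_value <= alpha
  d <- results[sig, c("feature", "time")]
  if (!is.null(features)) d <- d[d$feature %in% features, ]
  excluded <- setdiff(if (is.null(features)) unique(results$feature) else features,
                      unique(d$feature))
  if (length(excluded))
    message(length(excluded), " actor(s) without a significant time were excluded")
  if (nrow(d) == 0L)
    return(structure(list(m = setNames(integer(0), character(0)),
                          onset = setNames(integer(0), character(0))),
                     class = "cluster_assignment"))
  onset <- vapply(split(d$time, d$feature), min, numeric(1))
  cluster_assignment(onset)
}

#' Cluster assignment from response onsets of abundance series
#'
#' Onset detection for latent or otherwise continuous series: an actor's
#' onset is the first index where the absolute individual-mean value reaches
#' `threshold_frac` of its maximum absolute mean. Flat actors are excluded.
#'
#' @param x numeric array `[n_actors x T x n_individuals]` of post-stimulation
#'   series.
#' @param threshold_frac half-max style onset fraction (default 0.5).
#' @return A `cluster_assignment`.
#' @export
assign_clusters_from_series <- function(x, threshold_frac = 0.5) {
  m <- apply(x, c(1L, 2L), mean)
  onset <- apply(abs(m), 1L, function(v) {
    top <- max(v)
    if (top <= 0) return(NA_real_)
    which(v >= threshold_frac * top)[1L]
  })
  onset <- onset[!is.na(onset)]
  cluster_assignment(onset)
}

# build a cluster_assignment from named onset times
cluster_assignment <- function(onset) {
  lev <- sort(unique(onset))
  m <- setNames(match(onset, lev), names(onset))
  structure(list(m = m, onset = setNames(as.integer(onset), names(onset))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d actors in %d clusters\n",
              length(x$m), if (length(x$m)) max(x$m) else 0L))
  invisible(x)
}

# strictly-lower-triangular unit subdiagonal shift matrix (delay 1)
shift_matrix <- function(T) {
  F <- matrix(0, T, T)
  if (T > 1L) F[cbind(2:T, 1:(T - 1L))] <- 1
  F
}

lower_tri_mask <- function(T) lower.tri(matrix(0, T, T))

#' Apply a time-transfer matrix to a source series
#'
#' Returns `F %*% source_series`. `F` must be strictly lower triangular in
#' time so that entry t of the output depends only on source entries s < t.
#'
#' @param F `T x T` strictly lower-triangular matrix.
#' @param source_series numeric vector of length T.
#' @return numeric vector of length T.
#' @export
build_predictor <- function(F, source_series) {
  if (!is.matrix(F) || nrow(F) != ncol(F)) stop("F must be square")
  if (length(source_series) != nrow(F)) stop("dimension mismatch")
  if (any(F[upper.tri(F, diag = TRUE)] != 0))
    stop("F must be strictly lower triangular in time")
  as.numeric(F %*% source_series)
}

# scale each actor's series to unit root-mean-square amplitude, jointly over
# all individuals (flat actors stay at zero). The series are baseline-anchored
# (zero-referenced fold changes), so no mean is subtracted: centering within
# the window would destroy the strict time-lag structure the transfer matrices
# encode; and the scale is shared across individuals so that one regression
# weight per edge is meaningful for the stacked fit.
scale_series <- function(x) {
  for (n in seq_len(dim(x)[1L])) {
    s <- sqrt(mean(x[n, , ]^2))
    if (s > 0) x[n, , ] <- x[n, , ] / s else x[n, , ] <- 0
  }
  x
}

fkey <- function(i, j) paste(i, j, sep = "_")

# stacked design cache: for each target cluster j, a (P*T) x N matrix whose
# column k is the stacked transfer-mapped series of actor k toward cluster j
cascade_design <- function(x, m, F_list) {
  N <- dim(x)[1L]; T <- dim(x)[2L]; P <- dim(x)[3L]
  out <- list()
  for (j in sort(unique(m))) {
    D <- matrix(0, P * T, N, dimnames = list(NULL, dimnames(x)[[1L]]))
    for (k in seq_len(N)) {
      if (m[k] > j) next
      F <- F_list[[fkey(m[k], j)]]
      for (p in seq_len(P))
        D[((p - 1L) * T + 1L):(p * T), k] <- F %*% x[k, , p]
    }
    out[[as.character(j)]] <- D
  }
  out
}

stack_response <- function(x, n) as.numeric(x[n, , ])

# single-target sparse solve at glmnet's objective
# (1/(2n)) ||y - X b||^2 + lambda * sum(pf' |b|), pf' rescaled to sum to nvars
lasso_solve <- function(X, y, lambda, pf = rep(1, ncol(X))) {
  nv <- ncol(X)
  if (nv == 0L) return(numeric(0))
  if (lambda == 0) {
    b <- qr.coef(qr(X), y)
    b[is.na(b)] <- 0
    return(as.numeric(b))
  }
  if (nv == 1L) {
    n <- length(y)
    bls <- sum(X * y) / n
    xx <- sum(X * X) / n
    if (xx == 0) return(0)
    b <- sign(bls) * max(0, abs(bls) - lambda) / xx   # pf rescales to 1
    return(b)
  }
  # decreasing warm-start path down to the requested penalty: glmnet is
  # unreliable when handed a single small lambda
  n <- length(y)
  pfr <- pf * nv / sum(pf)
  lmax <- max(abs(crossprod(X, y)) / (n * pfr))
  if (!is.finite(lmax) || lmax <= lambda) lmax <- lambda * 1.5
  path <- exp(seq(log(lmax * 1.05), log(lambda), length.out = 25L))
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                        penalty.factor = pf, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-10, maxit = 10^6)
  as.numeric(coef(fit, s = lambda, exact = FALSE))[-1L]
}

# candidate predecessors of target l: same-or-earlier cluster, no self-loop.
# Cluster-1 targets are the exogenous stimulus layer and get no predecessors
# (empty models), so within-cluster candidates exist for clusters >= 2 only.
candidates_of <- function(actors, m, l) {
  if (m[l] == 1L) return(character(0))
  actors[m <= m[l] & actors != l]
}

prior_key <- function(prior) {
  if (is.null(prior) || nrow(prior) == 0L) return(character(0))
  paste(toupper(prior$source), toupper(prior$target), sep = "\r")
}

penalty_factors <- function(cand, target, prior_keys, kappa) {
  if (length(prior_keys) == 0L) return(rep(1, length(cand)))
  k <- paste(toupper(cand), toupper(target), sep = "\r")
  ifelse(k %in% prior_keys, kappa, 1)
}

#' Fit the temporal cascade model
#'
#' Alternating estimation of the model in which every actor's scaled profile
#' is a sparse weighted sum of same-or-earlier-cluster actors' profiles mapped
#' through cluster-pair time-transfer matrices: (1) transfer matrices start at
#' the unit subdiagonal shift; (2) per target, a LASSO over the stacked
#' individuals selects the weights, with prior-listed edges penalized by the
#' factor `kappa`; (3) the transfer matrices are refit entrywise by ridge
#' least squares over all active edges of each cluster pair, preserving strict
#' lower-triangularity; (4) repeat until the relative objective change drops
#' below `tol`.
#'
#' @param x numeric array `[n_actors x T x n_individuals]` of post-stimulation
#'   series (scaled internally per actor x individual to zero mean, unit
#'   variance).
#' @param clusters a `cluster_assignment` covering all actors of `x`.
#' @param prior optional `prior_network` data.frame (source, target,
#'   confidence).
#' @param lambda LASSO penalty (glmnet scale): a scalar, or a named vector
#'   with one penalty per target actor (e.g. `lambda_targets` from
#'   [cross_validate_lambda()]).
#' @param kappa multiplicative penalty factor in (0, 1] for prior edges
#'   (default 0.5; 1 disables the prior).
#' @param max_iter maximum alternating iterations (default 5).
#' @param tol relative objective tolerance (default 1e-4).
#' @param ridge ridge regularizer of the transfer-matrix refit (default 1e-6).
#' @param refit_ols after convergence, refit the selected weights per target
#'   by ordinary least squares on the support and drop refitted weights below
#'   `min_effect` (removes LASSO shrinkage bias; default `FALSE`).
#' @param min_effect magnitude floor used by the OLS refit (default 0.05).
#'
#' @return A `cascade_model`: `omega` (N x N matrix, entry \[k, l\] the weight
#'   of edge k -> l), `F` (named list of T x T matrices per cluster pair),
#'   `clusters`, `objective` (trajectory), `converged`, hyperparameters.
#' @export
fit_cascade <- function(x, clusters, prior = NULL, lambda = 0.05, kappa = 0.5,
                        max_iter = 5L, tol = 1e-4, ridge = 1e-6,
                        refit_ols = FALSE, min_effect = 0.05) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  actors <- dimnames(x)[[1L]]
  if (!all(actors %in% names(clusters$m)))
    stop("every actor needs a cluster assignment")
  m <- clusters$m[actors]
  T <- dim(x)[2L]; P <- dim(x)[3L]
  x <- scale_series(x)
  pk <- prior_key(prior)

  cl_levels <- sort(unique(m))
  F_list <- list()
  for (i in cl_levels) for (j in cl_levels[cl_levels >= i])
    F_list[[fkey(i, j)]] <- shift_matrix(T)

  N <- length(actors)
  omega <- matrix(0, N, N, dimnames = list(actors, actors))
  cand_list <- lapply(actors, function(l) candidates_of(actors, m, l))
  names(cand_list) <- actors
  pf_list <- lapply(actors, function(l)
    penalty_factors(cand_list[[l]], l, pk, kappa))
  names(pf_list) <- actors
  ntot <- P * T
  lam_of <- function(l) if (length(lambda) > 1L) unname(lambda[[l]]) else lambda

  objective <- function(D_by_cluster) {
    J <- 0
    for (l in actors) {
      cand <- cand_list[[l]]
      y <- stack_response(x, match(l, actors))
      if (length(cand)) {
        Xl <- D_by_cluster[[as.character(m[l])]][, cand, drop = FALSE]
        w <- omega[cand, l]
        r <- y - Xl %*% w
        pf <- pf_list[[l]]
        pfr <- pf * length(pf) / sum(pf)
        J <- J + sum(r^2) / (2 * ntot) + lam_of(l) * sum(pfr * abs(w))
      } else J <- J + sum(y^2) / (2 * ntot)
    }
    J
  }

  traj <- numeric(0)
  converged <- FALSE
  D <- cascade_design(x, m, F_list)
  for (iter in seq_len(max_iter)) {
    # omega step
    for (l in actors) {
      cand <- cand_list[[l]]
      omega[, l] <- 0
      if (length(cand) == 0L) next
      Xl <- D[[as.character(m[l])]][, cand, drop = FALSE]
      y <- stack_response(x, match(l, actors))
      omega[cand, l] <- lasso_solve(Xl, y, lam_of(l), pf_list[[l]])
    }
    # F step: entrywise ridge refit per cluster pair, strict lower triangle
    for (i in cl_levels) for (j in cl_levels[cl_levels >= i]) {
      targets_j <- actors[m == j & colSums(abs(omega)) > 0]
      targets_j <- targets_j[vapply(targets_j, function(l)
        any(omega[m[actors] == i, l] != 0), logical(1))]
      if (length(targets_j) == 0L) next
      # z[l, p, ] = weighted source-sum series of cluster-i parents of l
      new_F <- matrix(0, T, T)
      for (t in 2:T) {
        Z <- NULL; r <- NULL
        for (l in targets_j) {
          li <- match(l, actors)
          for (p in seq_len(P)) {
            other <- 0
            for (i2 in cl_levels[cl_levels <= j]) {
              src <- actors[m == i2 & omega[, li] != 0]
              if (length(src) == 0L || i2 == i) next
              zi2 <- rowSums(sapply(src, function(s)
                omega[s, li] * x[match(s, actors), , p]))
              other <- other + (F_list[[fkey(i2, j)]] %*% zi2)[t]
            }
            src_i <- actors[m == i & omega[, li] != 0]
            if (length(src_i) == 0L) next
            zi <- rowSums(sapply(src_i, function(s)
              omega[s, li] * x[match(s, actors), , p]))
            Z <- rbind(Z, zi[seq_len(t - 1L)])
            r <- c(r, x[li, t, p] - other)
          }
        }
        if (is.null(Z) || nrow(Z) == 0L) next
        A <- crossprod(Z) + ridge * diag(t - 1L)
        new_F[t, seq_len(t - 1L)] <- as.numeric(solve(A, crossprod(Z, r)))
      }
      F_list[[fkey(i, j)]] <- new_F
    }
    D <- cascade_design(x, m, F_list)
    traj <- c(traj, objective(D))
    if (iter > 1L &&
        abs(traj[iter - 1L] - traj[iter]) <= tol * max(traj[iter - 1L], 1e-12)) {
      converged <- TRUE
      break
    }
  }

  if (refit_ols) {
    for (l in actors) {
      sel <- actors[abs(omega[, l]) > min_effect]
      omega[, l] <- 0
      if (length(sel) == 0L) next
      Xl <- D[[as.character(m[l])]][, sel, drop = FALSE]
      y <- stack_response(x, match(l, actors))
      b <- qr.coef(qr(Xl), y)
      b[is.na(b)] <- 0
      b[abs(b) < min_effect] <- 0
      omega[sel, l] <- b
    }
  }

  structure(
    list(omega = omega, F = F_list, clusters = clusters,
         lambda = lambda, kappa = kappa, max_iter = max_iter, tol = tol,
         objective = traj, converged = converged, scaled = x, prior = prior),
    class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %d actors, %d edges (lambda = %g, kappa = %g, %s)\n",
              nrow(x$omega), sum(x$omega != 0), x$lambda, x$kappa,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Choose the LASSO penalty by grouped cross-validation
#'
#' Folds leave out one individual's full time series (P folds); with a single
#' individual the fall-back is time-blocked folds, with a warning. The
#' transfer matrices stay at the subdiagonal shift during CV. The returned
#' penalty minimizes mean held-out squared prediction error, with ties broken
#' toward the larger (sparser) value.
#'
#' @inheritParams fit_cascade
#' @param lambda_grid numeric vector of candidate penalties.
#' @param per_target also select one penalty per target from the same fold
#'   errors (targets differ widely in parent signal strength); the returned
#'   `lambda_targets` can be passed to [fit_cascade()] or
#'   [stability_select()] (default `FALSE`).
#'
#' @return list with `lambda_best`, `cv_table` (lambda x mean error), and,
#'   with `per_target = TRUE`, a named vector `lambda_targets`.
#' @export
cross_validate_lambda <- function(x, clusters, prior = NULL, lambda_grid,
                                  kappa = 0.5, per_target = FALSE) {
  actors <- dimnames(x)[[1L]]
  m <- clusters$m[actors]
  T <- dim(x)[2L]; P <- dim(x)[3L]
  x <- scale_series(x)
  pk <- prior_key(prior)
  F_list <- list()
  for (i in sort(unique(m))) for (j in sort(unique(m))[sort(unique(m)) >= i])
    F_list[[fkey(i, j)]] <- shift_matrix(T)
  D <- cascade_design(x, m, F_list)

  if (P >= 2L) {
    folds <- lapply(seq_len(P), function(p) ((p - 1L) * T + 1L):(p * T))
  } else {
    warning("single individual: falling back to time-blocked folds")
    folds <- split(seq_len(T), cut(seq_len(T), 2L))
  }
  err <- array(NA_real_,
               dim = c(length(lambda_grid), length(folds), length(actors)),
               dimnames = list(NULL, NULL, actors))
  for (gi in seq_along(lambda_grid)) {
    lam <- lambda_grid[gi]
    for (fi in seq_along(folds)) {
      hold <- folds[[fi]]
      for (l in actors) {
        cand <- candidates_of(actors, m, l)
        y <- stack_response(x, match(l, actors))
        if (length(cand) == 0L) {
          err[gi, fi, l] <- mean(y[hold]^2)
          next
        }
        Xl <- D[[as.character(m[l])]][, cand, drop = FALSE]
        pf <- penalty_factors(cand, l, pk, kappa)
        w <- lasso_solve(Xl[-hold, , drop = FALSE], y[-hold], lam, pf)
        pred <- Xl[hold, , drop = FALSE] %*% w
        err[gi, fi, l] <- mean((y[hold] - pred)^2)
      }
    }
  }
  mean_err <- rowMeans(err, dims = 1L)
  pick <- function(e) max(lambda_grid[e <= min(e) * (1 + 1e-8) + 1e-12])
  out <- list(lambda_best = pick(mean_err),
              cv_table = data.frame(lambda = lambda_grid,
                                    mean_error = mean_err))
  if (per_target) {
    per <- apply(err, 3L, function(ef) pick(rowMeans(ef)))
    out$lambda_targets <- setNames(as.numeric(per), actors)
  }
  out
}

#' Default logarithmic penalty grid
#'
#' Spans from the smallest penalty zeroing every weight (computed from the
#' design-response inner products) down by three decades.
#'
#' @inheritParams fit_cascade
#' @param length_out grid size (default 15).
#' @return decreasing numeric vector.
#' @export
lambda_grid_default <- function(x, clusters, length_out = 15L) {
  actors <- dimnames(x)[[1L]]
  m <- clusters$m[actors]
  T <- dim(x)[2L]
  x <- scale_series(x)
  F_list <- list()
  for (i in sort(unique(m))) for (j in sort(unique(m))[sort(unique(m)) >= i])
    F_list[[fkey(i, j)]] <- shift_matrix(T)
  D <- cascade_design(x, m, F_list)
  ntot <- T * dim(x)[3L]
  lmax <- 0
  for (l in actors) {
    cand <- candidates_of(actors, m, l)
    if (length(cand) == 0L) next
    Xl <- D[[as.character(m[l])]][, cand, drop = FALSE]
    y <- stack_response(x, match(l, actors))
    lmax <- max(lmax, max(abs(crossprod(Xl, y))) / ntot)
  }
  if (lmax == 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * 1e-3), length.out = length_out))
}

#' Weighted stability selection of cascade edges
#'
#' Repeatedly refits the sparse cascade regression on random subsamples
#' (without replacement) of the stacked observation rows, recording how often
#' each candidate edge is selected; edges with selection frequency at least
#' `pi_thr` are retained. The prior weighting acts through `kappa` in every
#' refit. Deterministic given `seed`.
#'
#' @inheritParams fit_cascade
#' @param B number of subsample refits (default 100).
#' @param subsample_fraction fraction of stacked rows kept per refit
#'   (default 0.5).
#' @param pi_thr selection-frequency threshold in `[0.5, 1]` (default 0.6).
#' @param seed integer RNG seed.
#' @param min_effect minimum absolute scaled weight counting as a selection
#'   (default 0.05; see [network_from_model()]).
#'
#' @return An `inferred_network` (see [inferred_network()]), with
#'   `frequencies` (full candidate frequency matrix) attached.
#' @export
stability_select <- function(x, clusters, prior = NULL, lambda = 0.05,
                             kappa = 0.5, B = 100L, subsample_fraction = 0.5,
                             pi_thr = 0.6, seed = 1L, min_effect = 0.05) {
  stopifnot(B >= 2L, subsample_fraction > 0, subsample_fraction < 1,
            pi_thr >= 0.5, pi_thr <= 1)
  actors <- dimnames(x)[[1L]]
  m <- clusters$m[actors]
  T <- dim(x)[2L]; P <- dim(x)[3L]
  x <- scale_series(x)
  pk <- prior_key(prior)
  F_list <- list()
  for (i in sort(unique(m))) for (j in sort(unique(m))[sort(unique(m)) >= i])
    F_list[[fkey(i, j)]] <- shift_matrix(T)
  D <- cascade_design(x, m, F_list)
  ntot <- P * T
  nsub <- max(2L, floor(subsample_fraction * ntot))
  max_cand <- max(vapply(actors, function(l)
    length(candidates_of(actors, m, l)), integer(1)))
  lambda_eff <- lambda
  if (nsub < 2L * max_cand && any(lambda <= 0)) {
    lambda_eff[lambda_eff <= 0] <- 1e-4
    message("subsample smaller than twice the candidate count; applying lambda floor 1e-4")
  }
  lam_of <- function(l) if (length(lambda_eff) > 1L) unname(lambda_eff[[l]]) else lambda_eff

  N <- length(actors)
  counts <- matrix(0, N, N, dimnames = list(actors, actors))
  wsum <- matrix(0, N, N, dimnames = list(actors, actors))
  set.seed(as.integer(seed))
  rowsets <- lapply(seq_len(B), function(b) sort(sample.int(ntot, nsub)))
  cand_list <- lapply(actors, function(l) candidates_of(actors, m, l))
  names(cand_list) <- actors
  pf_list <- lapply(actors, function(l)
    penalty_factors(cand_list[[l]], l, pk, kappa))
  names(pf_list) <- actors
  ys <- lapply(seq_len(N), function(n) stack_response(x, n))

  for (b in seq_len(B)) {
    rows <- rowsets[[b]]
    for (li in seq_len(N)) {
      l <- actors[li]
      cand <- cand_list[[l]]
      if (length(cand) == 0L) next
      Xl <- D[[as.character(m[l])]][rows, cand, drop = FALSE]
      w <- lasso_solve(Xl, ys[[li]][rows], lam_of(l), pf_list[[l]])
      sel <- abs(w) > min_effect
      counts[cand[sel], li] <- counts[cand[sel], li] + 1
      wsum[cand, li] <- wsum[cand, li] + w
    }
  }
  freq <- counts / B
  keep <- which(freq >= pi_thr, arr.ind = TRUE)
  edges <- data.frame(
    source = actors[keep[, 1L]], target = actors[keep[, 2L]],
    omega_hat = wsum[keep] / pmax(counts[keep], 1),
    stability_frequency = freq[keep],
    stringsAsFactors = FALSE)
  edges$sign <- sign(edges$omega_hat)
  edges$in_prior <- paste(toupper(edges$source), toupper(edges$target),
                          sep = "\r") %in% pk
  net <- inferred_network(edges,
                          nodes = data.frame(id = actors, symbol = actors,
                                             modality = "transcript",
                                             cluster = as.integer(m),
                                             stringsAsFactors = FALSE))
  attr(net, "frequencies") <- freq
  attr(net, "lambda") <- unname(lambda_eff)
  net
}

#' Construct an inferred network
#'
#' Directed edge list with stability frequencies and signs plus a node table.
#' Validates cluster causality: every edge must run from a same-or-earlier
#' cluster.
#'
#' @param edges data.frame with at least `source`, `target`, `omega_hat`;
#'   optional `stability_frequency`, `sign`, `in_prior`.
#' @param nodes data.frame with `id`, `symbol`, `modality`, `cluster`.
#' @return An `inferred_network`.
#' @export
inferred_network <- function(edges, nodes) {
  stopifnot(all(c("source", "target", "omega_hat") %in% names(edges)),
            all(c("id", "cluster") %in% names(nodes)))
  if (!"stability_frequency" %in% names(edges))
    edges$stability_frequency <- rep(NA_real_, nrow(edges))
  if (!"sign" %in% names(edges)) edges$sign <- sign(edges$omega_hat)
  if (!"in_prior" %in% names(edges)) edges$in_prior <- rep(NA, nrow(edges))
  cl <- setNames(nodes$cluster, nodes$id)
  if (nrow(edges) &&
      any(cl[edges$source] > cl[edges$target], na.rm = TRUE))
    stop("edge violates cluster causality (source in a later cluster than target)")
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "inferred_network")
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("<inferred_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network from a single cascade fit
#'
#' The support of the fitted weight matrix as an `inferred_network` (stability
#' frequency 1 for every retained edge). Coefficients below `min_effect` on
#' the unit-amplitude scale are treated as numerically zero: the LASSO leaves
#' shrinkage-compensation dust of order lambda on correlated null predictors.
#'
#' @param model a `cascade_model`.
#' @param modality node modality label (default `"transcript"`).
#' @param min_effect minimum absolute scaled weight of a retained edge
#'   (default 0.05).
#' @return An `inferred_network`.
#' @export
network_from_model <- function(model, modality = "transcript",
                               min_effect = 0.05) {
  actors <- rownames(model$omega)
  keep <- which(abs(model$omega) > min_effect, arr.ind = TRUE)
  pk <- prior_key(model$prior)
  edges <- data.frame(
    source = actors[keep[, 1L]], target = actors[keep[, 2L]],
    omega_hat = model$omega[keep],
    stability_frequency = rep(1, nrow(keep)),
    stringsAsFactors = FALSE)
  edges$sign <- sign(edges$omega_hat)
  edges$in_prior <- paste(toupper(edges$source), toupper(edges$target),
                          sep = "\r") %in% pk
  inferred_network(edges,
                   nodes = data.frame(id = actors, symbol = actors,
                                      modality = modality,
                                      cluster = as.integer(model$clusters$m[actors]),
                                      stringsAsFactors = FALSE))
}

#' Degree table and hub set of an inferred network
#'
#' Total degree (in + out) per actor over the retained edges, and the hub set
#' at the given link threshold (default 10, the usual hub criterion).
#'
#' @param net an `inferred_network`.
#' @param threshold minimum total degree of a hub (default 10).
#' @return list with `degrees` (data.frame id/degree) and `hubs` (character).
#' @export
degree_summary <- function(net, threshold = 10L) {
  ids <- net$nodes$id
  deg <- table(factor(c(net$edges$source, net$edges$target), levels = ids))
  degrees <- data.frame(id = ids, degree = as.integer(deg),
                        stringsAsFactors = FALSE)
  list(degrees = degrees, hubs = degrees$id[degrees$degree >= threshold])
}
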