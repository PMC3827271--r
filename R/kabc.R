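#' Table of simulated parameter / summary pairs
#'
#' The training set of the kernel regression: `n` draws of the parameter
#' vector theta with their simulated summary vectors s.
#'
#' @param theta numeric matrix (n x p) of parameter draws (column names are
#'   parameter names).
#' @param s numeric matrix (n x d) of summary vectors.
#' @return an object of class `sim_table`.
#' @export
sim_table <- function(theta, s) {
  theta <- as.matrix(theta); s <- as.matrix(s)
  stopifnot(nrow(theta) == nrow(s), nrow(theta) >= 2)
  structure(list(theta = theta, s = s, n = nrow(theta)), class = "sim_table")
}

#' @export
print.sim_table <- function(x, ...) {
  cat(sprintf("Simulation table: n = %d draws, %d parameter(s), %d summary coordinates\n",
              x$n, ncol(x$theta), ncol(x$s)))
  invisible(x)
}

#' Persist / load a simulation table as TSV
#'
#' Stored as a tab-separated file with parameter columns (prefixed
#' `theta.`) followed by summary columns (`s.`), so that expensive
#' simulation batches can be reused across replications and grids.
#'
#' @param table a [sim_table()].
#' @param path file path.
#' @return `write_sim_table()` the path invisibly; `read_sim_table()` a
#'   `sim_table`.
#' @export
write_sim_table <- function(table, path) {
  stopifnot(inherits(table, "sim_table"))
  th <- table$theta
  colnames(th) <- paste0("theta.", colnames(th) %||% seq_len(ncol(th)))
  s <- table$s
  colnames(s) <- paste0("s.", colnames(s) %||% seq_len(ncol(s)))
  utils::write.table(cbind(th, s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_table
#' @export
read_sim_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  th <- as.matrix(df[grepl("^theta\\.", names(df))])
  s <- as.matrix(df[grepl("^s\\.", names(df))])
  colnames(th) <- sub("^theta\\.", "", colnames(th))
  colnames(s) <- sub("^s\\.", "", colnames(s))
  sim_table(th, s)
}

#' Gaussian radial basis function kernel
#'
#' `k(u, v) = exp(-||u - v||^2 / (2 sigma2))`.
#'
#' @param u,v numeric vectors of equal length.
#' @param sigma2 bandwidth (> 0).
#' @return a number in (0, 1].
#' @export
rbf_kernel <- function(u, v, sigma2) {
  stopifnot(length(u) == length(v), sigma2 > 0)
  exp(-sum((u - v)^2) / (2 * sigma2))
}

# All pairwise squared distances between rows of A and rows of B.
sq_dists <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

#' Kernel / regression configuration
#'
#' @param sigma2 RBF bandwidth (> 0).
#' @param lambda ridge regularization (> 0; the solved system is
#'   `G + n * lambda * I`).
#' @param standardize z-standardize each summary coordinate with the
#'   training mean/SD before kernel evaluation (recommended: site and
#'   haplotype counts live on different scales).
#' @return an object of class `kernel_config`.
#' @export
kernel_config <- function(sigma2, lambda, standardize = TRUE) {
  stopifnot(sigma2 > 0, lambda >= 0)
  structure(list(sigma2 = sigma2, lambda = lambda, standardize = standardize),
            class = "kernel_config")
}

#' Median-heuristic bandwidth
#'
#' The median of pairwise squared distances between (standardized) training
#' summary vectors, a standard default center for the sigma2 grid.
#'
#' @param s summary matrix (n x d).
#' @param standardize apply column standardization first.
#' @param max_rows subsample cap for the pairwise computation.
#' @return a positive scalar.
#' @export
median_heuristic <- function(s, standardize = TRUE, max_rows = 1000L) {
  s <- as.matrix(s)
  if (nrow(s) > max_rows) s <- s[seq_len(max_rows), , drop = FALSE]
  if (standardize) s <- standardize_cols(s)$x
  d <- sq_dists(s)
  m <- stats::median(d[upper.tri(d)])
  if (!is.finite(m) || m <= 0) 1 else m
}

standardize_cols <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1 # constant coordinates carry no signal
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`), center = center, scale = scale)
}

#' Kernel ridge-regression posterior mean
#'
#' The kernel-ABC estimator: with Gram matrix `G_ij = k(s_i, s_j)` and
#' mean-centered targets, the posterior-mean prediction at an observed
#' summary vector is
#' `mean(theta) + k_obs' (G + n lambda I)^{-1} (theta - mean(theta))`.
#' One Cholesky solve of the shared Gram system serves every parameter
#' coordinate (and every observation).
#'
#' @param table a [sim_table()].
#' @param s_obs observed summary vector, or a matrix of observations (one
#'   per row).
#' @param config a [kernel_config()].
#' @return a named numeric vector of posterior means (or a matrix, one row
#'   per observation).
#' @export
krr_posterior_mean <- function(table, s_obs, config) {
  stopifnot(inherits(table, "sim_table"), inherits(config, "kernel_config"))
  s_obs <- if (is.matrix(s_obs)) s_obs else matrix(s_obs, nrow = 1)
  if (ncol(s_obs) != ncol(table$s))
    stop("observed summary length ", ncol(s_obs),
         " does not match training summaries (", ncol(table$s), ")")
  fit <- krr_fit(table, config)
  pred <- krr_predict(fit, s_obs)
  if (nrow(pred) == 1L) drop(pred) else pred
}

krr_fit <- function(table, config) {
  S <- table$s
  std <- if (config$standardize) standardize_cols(S) else
    list(x = S, center = rep(0, ncol(S)), scale = rep(1, ncol(S)))
  G <- exp(-sq_dists(std$x) / (2 * config$sigma2))
  n <- table$n
  A <- G + diag(n * config$lambda, n)
  theta_bar <- colMeans(table$theta)
  Yc <- sweep(table$theta, 2, theta_bar)
  alpha <- tryCatch(
    chol2inv(chol(A)) %*% Yc,
    error = function(e) {
      if (config$lambda <= 0)
        stop("Gram system is singular; use lambda > 0 (duplicate training rows?)")
      stop(e)
    })
  list(table = table, config = config, std = std, alpha = alpha,
       theta_bar = theta_bar, Xs = std$x)
}

krr_predict <- function(fit, s_obs) {
  Z <- sweep(sweep(as.matrix(s_obs), 2, fit$std$center), 2, fit$std$scale, `/`)
  Kx <- exp(-sq_dists(Z, fit$Xs) / (2 * fit$config$sigma2))
  pred <- Kx %*% fit$alpha
  pred <- sweep(pred, 2, -fit$theta_bar)
  colnames(pred) <- colnames(fit$table$theta)
  pred
}

#' 10-fold cross-validated hyperparameter selection
#'
#' Picks the `(sigma2, lambda)` grid pair minimizing the mean squared
#' held-out prediction error of theta (averaged over parameter coordinates
#' after per-coordinate standardization of the targets). Folds are
#' contiguous blocks after a seeded shuffle. On large tables the search can
#' run on a row subsample (`subsample`), since the error surface is stable
#' well below the full training size.
#'
#' @param table a [sim_table()].
#' @param sigma2_grid bandwidth grid; defaults to the median heuristic
#'   scaled by 1/4, 1, 4.
#' @param lambda_grid regularization grid; default `10^(-6..-1)`.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @param standardize passed through to [kernel_config()].
#' @param subsample optional cap on rows used during selection.
#' @return the selected [kernel_config()]; attribute `cv` holds the full
#'   error grid.
#' @export
select_hyperparams_cv <- function(table, sigma2_grid = NULL,
                                  lambda_grid = 10^seq(-6, -1),
                                  folds = 10L, seed = NULL,
                                  standardize = TRUE, subsample = NULL) {
  stopifnot(inherits(table, "sim_table"))
  if (!length(lambda_grid)) stop("empty lambda grid")
  work <- table
  if (!is.null(subsample) && subsample < table$n) {
    idx <- with_seed(seed, sample.int(table$n, subsample))
    work <- sim_table(table$theta[idx, , drop = FALSE], table$s[idx, , drop = FALSE])
  }
  if (work$n < folds) stop("need at least as many rows as folds")
  if (is.null(sigma2_grid)) {
    m <- median_heuristic(work$s, standardize = standardize)
    sigma2_grid <- m * c(0.25, 1, 4)
  }
  if (!length(sigma2_grid)) stop("empty sigma2 grid")

  perm <- with_seed(if (is.null(seed)) NULL else seed + 1L, sample.int(work$n))
  blocks <- rep(seq_len(folds), each = ceiling(work$n / folds))[seq_len(work$n)]
  fold_id <- integer(work$n)
  fold_id[perm] <- blocks   # contiguous blocks in shuffled order
  t_sd <- apply(work$theta, 2, stats::sd)
  t_sd[t_sd == 0] <- 1

  err <- matrix(NA_real_, length(sigma2_grid), length(lambda_grid),
                dimnames = list(sigma2 = signif(sigma2_grid, 4),
                                lambda = signif(lambda_grid, 4)))
  for (a in seq_along(sigma2_grid)) {
    for (b in seq_along(lambda_grid)) {
      cfg <- kernel_config(sigma2_grid[a], lambda_grid[b], standardize)
      sq <- 0; m <- 0
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- krr_fit(sim_table(work$theta[tr, , drop = FALSE],
                                 work$s[tr, , drop = FALSE]), cfg)
        pred <- krr_predict(fit, work$s[!tr, , drop = FALSE])
        res <- sweep(pred - work$theta[!tr, , drop = FALSE], 2, t_sd, `/`)
        sq <- sq + sum(res^2); m <- m + length(res)
      }
      err[a, b] <- sq / m
    }
  }
  best <- which(err == min(err), arr.ind = TRUE)[1, ]
  out <- kernel_config(sigma2_grid[best[1]], lambda_grid[best[2]], standardize)
  attr(out, "cv") <- err
  out
}

#' One kernel-ABC run
#'
#' The core algorithm: draw `n` parameter sets from the prior, simulate a
#' dataset and its summary vector for each, select kernel hyperparameters
#' by 10-fold cross-validation (unless a fixed `config` is supplied), and
#' return the kernel ridge-regression posterior mean evaluated at the
#' observed summary vector.
#'
#' @param s_obs observed summary vector.
#' @param prior a function `(n, seed) -> matrix` of parameter draws (e.g.
#'   built from [prior_spec()] via [prior_sampler()]).
#' @param simulate_fn a function `(theta_row, seed) -> summary vector`.
#' @param n number of simulations.
#' @param seed master seed; per-draw seeds are derived from it.
#' @param config optional fixed [kernel_config()] (skips cross-validation).
#' @param cv list of arguments forwarded to [select_hyperparams_cv()]
#'   (e.g. `subsample`).
#' @return named posterior-mean vector; attributes `config` and `table`
#'   carry the fitted hyperparameters and the simulation table.
#' @export
run_abc <- function(s_obs, prior, simulate_fn, n, seed = NULL, config = NULL,
                    cv = list(subsample = 1000L)) {
  stopifnot(is.function(prior), is.function(simulate_fn), n >= 2)
  seeds <- derive_seeds(seed, n + 2L)
  theta <- prior(n, seeds[[n + 1L]])
  stopifnot(is.matrix(theta), nrow(theta) == n)
  s_list <- vector("list", n)
  for (i in seq_len(n))
    s_list[[i]] <- tryCatch(as.numeric(simulate_fn(theta[i, ], seeds[[i]])),
                            error = function(e)
                              stop("simulator failed at draw ", i, " (theta = ",
                                   paste(signif(theta[i, ], 4), collapse = ", "),
                                   "): ", conditionMessage(e), call. = FALSE))
  s <- do.call(rbind, s_list)
  if (ncol(s) != length(s_obs))
    stop("simulated summary length ", ncol(s), " does not match observed (",
         length(s_obs), "); check the bin specification")
  tab <- sim_table(theta, s)
  if (is.null(config))
    config <- do.call(select_hyperparams_cv,
                      c(list(table = tab, seed = seeds[[n + 2L]]), cv))
  est <- krr_posterior_mean(tab, as.numeric(s_obs), config)
  attr(est, "config") <- config
  attr(est, "table") <- tab
  est
}

#' Replicated kernel-ABC with posterior-mean dispersion
#'
#' Runs [run_abc()] `R` times with independent simulation batches and
#' reports the mean and standard deviation of the posterior-mean estimates
#' across replications — the Monte-Carlo uncertainty of the estimator, not
#' a posterior credible interval.
#'
#' @inheritParams run_abc
#' @param R number of replications.
#' @param share_config select hyperparameters on the first replication and
#'   reuse them (substantially cheaper; the error surface is flat across
#'   batches of the same size). Set `FALSE` to re-select every time.
#' @return an object of class `posterior_estimate` with fields `mean`,
#'   `sd`, `R`, `n`, `reps` (matrix of per-replication estimates) and
#'   `config`.
#' @export
replicate_abc <- function(s_obs, prior, simulate_fn, n, R = 100L, seed = NULL,
                          config = NULL, cv = list(subsample = 1000L),
                          share_config = TRUE) {
  stopifnot(R >= 1)
  seeds <- derive_seeds(seed, R)
  reps <- NULL
  for (r in seq_len(R)) {
    est <- run_abc(s_obs, prior, simulate_fn, n, seed = seeds[[r]],
                   config = config, cv = cv)
    if (share_config && is.null(config)) config <- attr(est, "config")
    reps <- rbind(reps, est)
  }
  rownames(reps) <- NULL
  if (R == 1L) warning("R = 1: replication SD reported as 0")
  posterior_estimate(mean = colMeans(reps),
                     sd = if (R > 1L) apply(reps, 2, stats::sd) else
                       stats::setNames(rep(0, ncol(reps)), colnames(reps)),
                     R = R, n = n, reps = reps, config = config)
}

#' @rdname replicate_abc
#' @param mean,sd,reps components of the estimate (constructor).
#' @export
posterior_estimate <- function(mean, sd, R, n, reps = NULL, config = NULL) {
  stopifnot(all(sd >= 0), R >= 1)
  structure(list(mean = mean, sd = sd, R = as.integer(R), n = as.integer(n),
                 reps = reps, config = config),
            class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("Posterior means (R = %d replications, n = %d simulations each):\n",
              x$R, x$n))
  for (nm in names(x$mean))
    cat(sprintf("  %-8s %12.1f  (S.D. %.1f)\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}
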