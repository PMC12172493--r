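#' Working covariance proxy for a random-intercept mixed model
#'
#' For cluster \eqn{i} with \eqn{m_i} observations and random-intercept design
#' \eqn{Z_i = 1_{m_i}}, the proxy is \eqn{\Sigma_a^i = a Z_i Z_i^\top + I}.
#' The tuning scalar \eqn{a \ge 0} stands in for the unknown ratio of
#' random-intercept to residual variance; it is chosen by cross-validation
#' (see [select_a()]), so the variance components themselves are never
#' estimated in the high-dimensional outcome model. Inverse square roots are
#' taken blockwise by symmetric eigendecomposition (eigenvalue floor 1e-12),
#' and \eqn{Tr(\Sigma_a^{-1})} — the effective sample size — is accumulated
#' over clusters.
#'
#' @param cluster length-N vector of cluster labels (any order; blocks need
#'   not be contiguous).
#' @param a non-negative tuning scalar; `a = 0` yields identity blocks.
#' @return An object of class `cov_proxy`: cluster index list, per-cluster
#'   inverse square roots, per-cluster traces of the inverse, and `trace_inv`.
#' @export
covariance_proxy <- function(cluster, a) {
  if (!is.finite(a) || a < 0) stop("'a' must be a finite non-negative scalar")
  cluster <- as.character(cluster)
  levels <- unique(cluster)
  idx <- split(seq_along(cluster), factor(cluster, levels = levels))
  inv_sqrt <- vector("list", length(levels))
  tr <- numeric(length(levels))
  for (i in seq_along(levels)) {
    m <- length(idx[[i]])
    S <- matrix(a, m, m) + diag(m)
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 1e-12)
    inv_sqrt[[i]] <- e$vectors %*% (t(e$vectors) / sqrt(ev))
    tr[i] <- sum(1 / ev)
  }
  structure(list(a = a, levels = levels, idx = idx, sizes = lengths(idx),
                 inv_sqrt = inv_sqrt, trace_by_cluster = tr,
                 trace_inv = sum(tr)),
            class = "cov_proxy")
}

#' Whiten observations with a covariance proxy
#'
#' Left-multiplies each cluster's rows of `X` and `y` by that cluster's
#' \eqn{(\Sigma_a^i)^{-1/2}}, giving the transformed data the lasso operates
#' on. With `a = 0` this is the identity.
#'
#' @param X N x p design matrix (may be `NULL` to whiten `y` alone).
#' @param y N-vector.
#' @param proxy a [covariance_proxy()] built from the same cluster labels.
#' @param cluster the cluster labels of the rows; checked against the proxy.
#' @return An object of class `whitened_data`: `Xa`, `ya`, `cluster`, `proxy`.
#' @export
whiten_data <- function(X, y, proxy, cluster) {
  cluster <- as.character(cluster)
  if (!identical(unname(lengths(split(seq_along(cluster),
                                      factor(cluster, levels = proxy$levels)))),
                 unname(proxy$sizes)))
    stop("cluster structure does not match the covariance proxy")
  Xa <- X
  ya <- y
  for (i in seq_along(proxy$levels)) {
    rows <- proxy$idx[[i]]
    R <- proxy$inv_sqrt[[i]]
    if (!is.null(X)) Xa[rows, ] <- R %*% X[rows, , drop = FALSE]
    ya[rows] <- as.vector(R %*% y[rows])
  }
  structure(list(Xa = Xa, ya = ya, cluster = cluster, proxy = proxy),
            class = "whitened_data")
}

#' Regularization grid for the scaled lasso
#'
#' The grid is `multipliers * sqrt(2 * log(p) / N)` with multipliers 2.0 down
#' to 0.1 by default. When `p < 2` the rate is degenerate and a fixed small
#' grid (`multipliers * 0.05`) is used instead, with a logged notice.
#'
#' @param p number of design columns; `N` total sample size.
#' @param N total sample size.
#' @param multipliers decreasing multiplier sequence.
#' @return decreasing numeric vector of lambda values.
#' @export
lambda_grid <- function(p, N, multipliers = seq(2, 0.1, by = -0.1)) {
  if (p < 2) {
    msg_log("warn", "p < 2: falling back to a fixed small lambda grid")
    return(multipliers * 0.05)
  }
  multipliers * sqrt(2 * log(p) / N)
}

#' Lasso for fixed effects on whitened data
#'
#' Minimizes \deqn{\frac{1}{2\,Tr(\Sigma_a^{-1})}\|y_a - X_a\beta\|_2^2 +
#' \lambda \sum_j pf_j |\beta_j|} by cyclic coordinate descent (compiled inner
#' loop, residual updates, warm starts). Convergence: largest coefficient
#' change within a sweep below `tol`.
#'
#' @param Xa,ya whitened design and response.
#' @param trace_inv effective sample size \eqn{Tr(\Sigma_a^{-1})}.
#' @param lambda non-negative regularization parameter.
#' @param penalty_factor per-column penalty multipliers; 0 = unpenalized.
#' @param beta_init warm start (defaults to zero).
#' @param tol,maxit convergence tolerance and sweep cap.
#' @return `list(beta, lambda, objective, support, niter, converged)`.
#' @export
lasso_fixed_effects <- function(Xa, ya, trace_inv, lambda,
                                penalty_factor = rep(1, ncol(Xa)),
                                beta_init = NULL, tol = 1e-8, maxit = 1e5) {
  stopifnot(lambda >= 0, trace_inv > 0, length(penalty_factor) == ncol(Xa))
  if (is.null(beta_init)) beta_init <- numeric(ncol(Xa))
  fit <- cd_lasso_gram_cpp(crossprod(Xa), as.vector(crossprod(Xa, ya)),
                           sum(ya^2), trace_inv, lambda, penalty_factor,
                           beta_init, tol, as.integer(maxit))
  if (!fit$converged)
    stop(sprintf(
      "lasso did not converge in %d sweeps (last max coefficient change %.3e)",
      as.integer(maxit), fit$max_delta))
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(Xa)
  list(beta = beta, lambda = lambda, objective = fit$objective,
       support = which(beta != 0 & penalty_factor > 0),
       niter = fit$niter, converged = fit$converged)
}

# Assign clusters to K cross-validation folds, never splitting a cluster.
make_cluster_folds <- function(levels, nfolds, fold_seed = NULL) {
  n <- length(levels)
  if (n < nfolds)
    stop("fewer clusters (", n, ") than folds (", nfolds, ")")
  draw <- function() sample(rep_len(seq_len(nfolds), n))
  f <- if (is.null(fold_seed)) draw() else with_preserved_seed(fold_seed, draw())
  setNames(f, levels)
}

# Evaluate code with a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Cluster-level K-fold CV error for a (a, lambda-grid) combination.
# Each fold's whitened training data enters the solver in Gram form and the
# whole decreasing lambda grid is fit as a warm-started path. Held-out error
# is computed on the raw scale, ||y_h - X_h beta||^2, matching the criterion
# used to choose `a`. Returns a vector over the lambda grid.
cv_path_error <- function(X, y, cluster, a, lambdas, folds, penalty_factor,
                          tol = 1e-8, maxit = 1e5) {
  err <- numeric(length(lambdas))
  for (k in sort(unique(folds))) {
    hold_levels <- names(folds)[folds == k]
    hold <- cluster %in% hold_levels
    Xtr <- X[!hold, , drop = FALSE]; ytr <- y[!hold]
    ctr <- cluster[!hold]
    proxy <- covariance_proxy(ctr, a)
    wh <- whiten_data(Xtr, ytr, proxy, ctr)
    path <- cd_lasso_path_cpp(crossprod(wh$Xa),
                              as.vector(crossprod(wh$Xa, wh$ya)),
                              proxy$trace_inv, lambdas, penalty_factor,
                              tol, as.integer(maxit))
    resid <- y[hold] - X[hold, , drop = FALSE] %*% path$beta
    err <- err + colSums(resid^2)
  }
  err
}

#' Select the covariance-proxy tuning parameter by cross-validation
#'
#' Cluster-level K-fold CV with the prediction error criterion
#' \eqn{\|Y_{held} - X_{held}\hat\beta(a)\|_2^2}. For each candidate `a` the
#' error is minimized over the lambda multiplier grid; the candidate with the
#' smallest CV error wins, ties going to the smaller `a`.
#'
#' @param X design matrix (including any unpenalized intercept column).
#' @param y response.
#' @param cluster cluster labels.
#' @param candidate_as non-negative candidates; a single candidate is returned
#'   unchanged.
#' @param multipliers lambda multiplier grid (see [lambda_grid()]).
#' @param nfolds number of cluster-level folds.
#' @param penalty_factor per-column penalty multipliers.
#' @param fold_seed optional seed for the fold assignment; by default folds
#'   are drawn from the current RNG stream.
#' @return `list(a, cv_error)` with the per-candidate CV error (min over the
#'   grid).
#' @export
select_a <- function(X, y, cluster, candidate_as = default_candidate_as(),
                     multipliers = seq(2, 0.1, by = -0.1), nfolds = 5,
                     penalty_factor = rep(1, ncol(X)), fold_seed = NULL) {
  if (!length(candidate_as)) stop("empty candidate list for 'a'")
  if (any(!is.finite(candidate_as)) || any(candidate_as < 0))
    stop("candidates for 'a' must be finite and >= 0")
  candidate_as <- sort(candidate_as)
  if (length(candidate_as) == 1L)
    return(list(a = candidate_as, cv_error = NA_real_))
  folds <- make_cluster_folds(unique(as.character(cluster)), nfolds, fold_seed)
  lambdas <- lambda_grid(ncol(X), length(y), multipliers)
  errs <- vapply(candidate_as, function(a)
    min(cv_path_error(X, y, cluster, a, lambdas, folds, penalty_factor)),
    numeric(1))
  list(a = candidate_as[which.min(errs)],
       cv_error = setNames(errs, candidate_as))
}

default_candidate_as <- function() c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8)

#' Select the lasso regularization parameter by cross-validation
#'
#' Cluster-level K-fold CV of the raw-scale prediction error at a fixed proxy
#' parameter `a`, over the grid `multipliers * sqrt(2 log(p) / N)`. Ties go to
#' the larger (sparser) lambda.
#'
#' @inheritParams select_a
#' @param a covariance-proxy tuning parameter.
#' @return `list(lambda, cv_error)`.
#' @export
select_lambda <- function(X, y, cluster, a,
                          multipliers = seq(2, 0.1, by = -0.1), nfolds = 5,
                          penalty_factor = rep(1, ncol(X)), fold_seed = NULL) {
  if (!length(multipliers)) stop("empty lambda multiplier grid")
  lambdas <- lambda_grid(ncol(X), length(y), multipliers)
  if (length(lambdas) == 1L)
    return(list(lambda = lambdas, cv_error = NA_real_))
  folds <- make_cluster_folds(unique(as.character(cluster)), nfolds, fold_seed)
  errs <- cv_path_error(X, y, cluster, a, lambdas, folds, penalty_factor)
  # grid is decreasing, so the first minimum is the largest qualifying lambda
  list(lambda = lambdas[which.min(errs)], cv_error = setNames(errs, lambdas))
}

#' Nodewise correction score for one coordinate
#'
#' Regresses the whitened column \eqn{(X_a)_{\cdot j}} on all other whitened
#' columns with an \eqn{\ell_1} penalty and returns the residual
#' \eqn{\hat w_j = (X_a)_{\cdot j} - (X_a)_{\cdot -j}\hat\kappa_j}, the score
#' that debiasing projects the lasso residual onto. `lambda_j` is selected by
#' cluster-level CV over the multiplier grid unless supplied.
#'
#' @param wh a `whitened_data` object (see [whiten_data()]).
#' @param j column index to correct.
#' @param multipliers lambda multiplier grid.
#' @param nfolds folds for lambda_j selection.
#' @param lambda_j optional fixed penalty, bypassing CV.
#' @param fold_seed optional fold seed.
#' @return `list(w, kappa, lambda_j, denom)` where `denom` is
#'   \eqn{\hat w_j^\top (X_a)_{\cdot j}}.
#' @export
nodewise_score <- function(wh, j, multipliers = seq(2, 0.1, by = -0.1),
                           nfolds = 5, lambda_j = NULL, fold_seed = NULL) {
  out <- nodewise_scores(wh, j, multipliers = multipliers, nfolds = nfolds,
                         lambda_j = lambda_j, fold_seed = fold_seed)
  out[[1]]
}

# Nodewise scores for several coordinates at once. The per-fold Gram matrices
# of the whitened design are computed a single time and shared across all
# requested coordinates (column j's nodewise problem only needs the full
# Gram with row/column j carved out), which makes debiasing every coordinate
# affordable.
nodewise_scores <- function(wh, js, multipliers = seq(2, 0.1, by = -0.1),
                            nfolds = 5, lambda_j = NULL, fold_seed = NULL) {
  Xa <- wh$Xa
  p <- ncol(Xa)
  stopifnot(all(js >= 1), all(js <= p))
  tr <- wh$proxy$trace_inv
  if (p == 1L) {
    xj <- Xa[, 1]
    denom <- sum(xj * xj)
    if (abs(denom) < 1e-12) stop("degenerate correction score for column 1")
    return(list(list(w = xj, kappa = numeric(0), lambda_j = NA_real_,
                     denom = denom)))
  }
  G <- crossprod(Xa)
  need_cv <- is.null(lambda_j)
  if (need_cv) {
    lambdas <- lambda_grid(p, nrow(Xa), multipliers)
    folds <- make_cluster_folds(wh$proxy$levels, nfolds, fold_seed)
    cache <- lapply(sort(unique(folds)), function(k) {
      hold_levels <- names(folds)[folds == k]
      hold <- wh$cluster %in% hold_levels
      list(G = crossprod(Xa[!hold, , drop = FALSE]),
           Xh = Xa[hold, , drop = FALSE],
           tr = sum(wh$proxy$trace_by_cluster[!(wh$proxy$levels %in% hold_levels)]))
    })
  }
  pf <- rep(1, p - 1L)
  lapply(js, function(j) {
    lj <- lambda_j
    if (need_cv) {
      err <- numeric(length(lambdas))
      for (fc in cache) {
        path <- cd_lasso_path_cpp(fc$G[-j, -j, drop = FALSE], fc$G[-j, j],
                                  fc$tr, lambdas, pf, 1e-8, 100000L)
        resid <- fc$Xh[, j] - fc$Xh[, -j, drop = FALSE] %*% path$beta
        err <- err + colSums(resid^2)
      }
      lj <- lambdas[which.min(err)]
    }
    fit <- cd_lasso_gram_cpp(G[-j, -j, drop = FALSE], G[-j, j], G[j, j],
                             tr, lj, pf, numeric(p - 1L), 1e-8, 100000L)
    if (!fit$converged) stop("nodewise lasso did not converge for column ", j)
    kappa <- as.numeric(fit$beta)
    xj <- Xa[, j]
    w <- xj - as.vector(Xa[, -j, drop = FALSE] %*% kappa)
    denom <- sum(w * xj)
    if (abs(denom) < 1e-10 * max(1, sum(xj^2)))
      stop("degenerate correction score for column ", j)
    list(w = w, kappa = kappa, lambda_j = lj, denom = denom)
  })
}

#' Debias lasso coordinates with nodewise correction scores
#'
#' One-step correction
#' \deqn{\hat\beta_j^{(db)} = \hat\beta_j + \frac{\hat w_j^\top (y_a -
#' X_a\hat\beta)}{\hat w_j^\top (X_a)_{\cdot j}},}
#' with the clustered empirical variance
#' \deqn{\hat V_j = \frac{\sum_i [(\hat w_j^i)^\top (y_a^i - X_a^i\hat\beta)]^2}
#' {(\hat w_j^\top (X_a)_{\cdot j})^2}} summing squared per-cluster score-
#' residual products, and \eqn{SE_j = \sqrt{\hat V_j}}.
#'
#' @param beta lasso coefficient vector (length p, on the whitened design).
#' @param wh `whitened_data` object.
#' @param scores named list of [nodewise_score()] results, names = column
#'   indices or column names of the coordinates to debias.
#' @return `list(beta_db, se, V)` named by coordinate.
#' @export
debias_lasso <- function(beta, wh, scores) {
  resid <- wh$ya - as.vector(wh$Xa %*% beta)
  cl <- factor(wh$cluster, levels = wh$proxy$levels)
  out_b <- out_v <- numeric(length(scores))
  names(out_b) <- names(out_v) <- names(scores)
  for (s in seq_along(scores)) {
    sc <- scores[[s]]
    j <- attr(sc, "column")
    wres <- sc$w * resid
    out_b[s] <- beta[j] + sum(wres) / sc$denom
    per_cluster <- rowsum(wres, cl)
    out_v[s] <- sum(per_cluster^2) / sc$denom^2
  }
  list(beta_db = out_b, se = sqrt(out_v), V = out_v)
}

#' Control parameters for the debiased-lasso mixed-model fit
#'
#' @param candidate_as candidate grid for the covariance-proxy parameter.
#' @param multipliers lambda multiplier grid, 2.0 down to 0.1 by default.
#' @param nfolds cluster-level CV folds.
#' @param tol,maxit coordinate-descent convergence controls.
#' @param fold_seed optional fold-assignment seed (recorded in the fit).
#' @param standardize scale design columns to unit standard deviation before
#'   the lasso (coefficients are returned on the original scale). Off by
#'   default: log-proportion mediators share a scale and the exposure is
#'   binary.
#' @param center mean-center the design columns before fitting. With an
#'   unpenalized intercept this is an exact reparametrization of the same
#'   model (the intercept absorbs the means and is corrected back), but it
#'   conditions the coordinate-descent problem dramatically better for
#'   log-proportion designs whose column means dwarf their variances.
#' @return list of class `hdlmm_control`.
#' @export
hdlmm_control <- function(candidate_as = default_candidate_as(),
                          multipliers = seq(2, 0.1, by = -0.1), nfolds = 5,
                          tol = 1e-8, maxit = 1e5, fold_seed = NULL,
                          standardize = FALSE, center = TRUE) {
  structure(list(candidate_as = candidate_as, multipliers = multipliers,
                 nfolds = nfolds, tol = tol, maxit = maxit,
                 fold_seed = fold_seed, standardize = standardize,
                 center = center),
            class = "hdlmm_control")
}

#' Debiased-lasso estimation for a high-dimensional linear mixed model
#'
#' Fits the random-intercept outcome model
#' \eqn{y = X\beta + \gamma_{cluster} + \epsilon} when p may exceed N:
#' (1) choose the covariance-proxy parameter `a` by cluster-level CV;
#' (2) whiten all observations blockwise with \eqn{\Sigma_a^{-1/2}};
#' (3) choose lambda by cluster-level CV and fit the scaled lasso;
#' (4) compute a nodewise correction score for every requested coordinate and
#' debias it, with a clustered empirical variance.
#'
#' An unpenalized intercept column is prepended unless `intercept = FALSE`;
#' the intercept is excluded from the penalty and from debiasing.
#'
#' @param X N x p design matrix (without intercept), columns named.
#' @param y numeric response of length N.
#' @param cluster cluster labels of length N.
#' @param debias columns to debias: indices or names of `X` (default all).
#' @param a optional fixed proxy parameter, bypassing [select_a()].
#' @param lambda optional fixed lasso penalty, bypassing [select_lambda()].
#' @param intercept include an unpenalized intercept.
#' @param penalty_factor penalty multipliers for the columns of `X`.
#' @param control a [hdlmm_control()] list.
#' @return An object of class `hdlmm` with lasso coefficients, debiased
#'   estimates and standard errors, the selected `(a, lambda)`, nodewise
#'   penalties, and the effective sample size.
#' @examples
#' d <- simulate_mediation_data(n = 20, m_range = c(3, 5), H = 8, s = 2,
#'                              seed = 1)
#' M <- lognorm_transform(d$counts)
#' X <- cbind(exposure = d$metadata$exposure, M)
#' fit <- hdlmm(X, d$metadata$fev1_pct, d$metadata$cluster_id,
#'              debias = "exposure", a = 1, lambda = 0.5)
#' coef(fit, "debiased")
#' @export
hdlmm <- function(X, y, cluster, debias = NULL, a = NULL, lambda = NULL,
                  intercept = TRUE, penalty_factor = rep(1, ncol(X)),
                  control = hdlmm_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), length(cluster) == length(y),
            length(penalty_factor) == ncol(X))
  if (is.null(debias)) debias <- which(penalty_factor > 0)
  if (is.character(debias)) debias <- match(debias, colnames(X))
  if (anyNA(debias)) stop("unknown column in 'debias'")

  scl <- rep(1, ncol(X))
  if (isTRUE(control$standardize)) {
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- sweep(X, 2, scl, "/")
  }
  xbar <- rep(0, ncol(X))
  if (intercept && isTRUE(control$center)) {
    # exact reparametrization: the unpenalized intercept absorbs the column
    # means; corrected back below
    xbar <- colMeans(X)
    X <- sweep(X, 2, xbar, "-")
  }
  if (intercept) {
    Xf <- cbind(`(Intercept)` = 1, X)
    pf <- c(0, penalty_factor)
    debias_f <- debias + 1L
  } else {
    Xf <- X; pf <- penalty_factor; debias_f <- debias
  }

  if (is.null(a)) {
    sel_a <- select_a(Xf, y, cluster, control$candidate_as,
                      control$multipliers, control$nfolds, pf,
                      control$fold_seed)
    a <- sel_a$a
  }
  proxy <- covariance_proxy(cluster, a)
  wh <- whiten_data(Xf, y, proxy, cluster)
  if (is.null(lambda)) {
    sel_l <- select_lambda(Xf, y, cluster, a, control$multipliers,
                           control$nfolds, pf, control$fold_seed)
    lambda <- sel_l$lambda
  }
  fit <- lasso_fixed_effects(wh$Xa, wh$ya, proxy$trace_inv, lambda, pf,
                             tol = control$tol, maxit = control$maxit)
  scores <- nodewise_scores(wh, debias_f, control$multipliers,
                            control$nfolds, fold_seed = control$fold_seed)
  for (i in seq_along(scores)) attr(scores[[i]], "column") <- debias_f[i]
  names(scores) <- colnames(Xf)[debias_f]
  db <- debias_lasso(fit$beta, wh, scores)

  # undo centering (intercept only) and column scaling
  full_scl <- if (intercept) c(1, scl) else scl
  beta <- fit$beta
  if (intercept) beta[1] <- beta[1] - sum(xbar * beta[-1])
  beta <- beta / full_scl
  beta_db <- db$beta_db / full_scl[debias_f]
  se <- db$se / full_scl[debias_f]

  structure(list(coefficients = beta, beta_db = beta_db, se = se,
                 V = db$V / full_scl[debias_f]^2,
                 a = a, lambda = lambda,
                 lambda_j = setNames(vapply(scores, `[[`, numeric(1), "lambda_j"),
                                     names(scores)),
                 trace_inv = proxy$trace_inv,
                 support = names(fit$beta)[fit$beta != 0 & pf > 0],
                 n = length(unique(cluster)), N = length(y),
                 objective = fit$objective, converged = fit$converged,
                 call = match.call()),
            class = "hdlmm")
}

#' @export
print.hdlmm <- function(x, ...) {
  cat("High-dimensional linear mixed model (debiased lasso)\n")
  cat(sprintf("  N = %d observations in %d clusters; effective sample size %.2f\n",
              x$N, x$n, x$trace_inv))
  cat(sprintf("  a = %g, lambda = %.4g; lasso support size %d\n",
              x$a, x$lambda, length(x$support)))
  cat("Debiased coefficients:\n")
  print(round(x$beta_db, 4))
  invisible(x)
}

#' @export
coef.hdlmm <- function(object, type = c("debiased", "lasso"), ...) {
  type <- match.arg(type)
  if (type == "lasso") object$coefficients else object$beta_db
}

#' @export
summary.hdlmm <- function(object, ...) {
  z <- object$beta_db / object$se
  tab <- cbind(Estimate = object$beta_db, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(table = tab, a = object$a, lambda = object$lambda,
                 n = object$n, N = object$N), class = "summary.hdlmm")
}

#' @export
print.summary.hdlmm <- function(x, ...) {
  cat(sprintf("Debiased lasso LMM: N = %d, clusters = %d, a = %g, lambda = %.4g\n",
              x$N, x$n, x$a, x$lambda))
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.hdlmm <- function(object, parm, level = 0.95, ...) {
  est <- object$beta_db
  if (!missing(parm)) est <- est[parm]
  z <- qnorm(1 - (1 - level) / 2)
  se <- object$se[names(est)]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}
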