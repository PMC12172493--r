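#' REML fit of a random-intercept linear mixed model
#'
#' Low-dimensional companion to [hdlmm()]: fits
#' \eqn{y = X b + \gamma_{cluster} + \epsilon}, with
#' \eqn{\gamma_i \sim (0, \psi)} and \eqn{\epsilon \sim (0, \sigma_e^2 I)}, by
#' restricted maximum likelihood. The REML criterion is profiled down to the
#' single variance ratio \eqn{\theta = \psi / \sigma_e^2}, which for a
#' random intercept admits closed-form per-cluster downdates (no general
#' matrix solves), and optimized over \eqn{\log\theta} with an explicit
#' boundary comparison at \eqn{\theta = 0}; \eqn{\hat\psi} is therefore
#' constrained non-negative. When \eqn{\hat\psi = 0} the fixed effects reduce
#' to ordinary least squares.
#'
#' @param y numeric response, length N.
#' @param X fixed-effects design matrix, including the intercept column if one
#'   is wanted; must have full column rank.
#' @param cluster cluster labels, length N; at least 2 clusters.
#' @param theta_max upper bound for the variance ratio during optimization.
#' @return Object of class `reml_ri`: `coefficients` (fixed effects), `psi`,
#'   `sigma2` (residual variance), `theta`, `vcov` of the fixed effects,
#'   `fitted`, `n` clusters, `N`, and a `converged` flag.
#' @examples
#' y <- c(1, 1.1, 3, 2.9, 2, 2.2)
#' f <- reml_ri(y, cbind(1, c(0, 1, 0, 1, 0, 1)), c(1, 1, 2, 2, 3, 3))
#' coef(f); f$psi; f$sigma2
#' @export
reml_ri <- function(y, X, cluster, theta_max = 1e7) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  N <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == N, length(cluster) == N)
  cl <- factor(as.character(cluster), levels = unique(as.character(cluster)))
  n <- nlevels(cl)
  if (n < 2) stop("need at least 2 clusters")
  if (N < p + 2) stop("too few observations (N = ", N, ") for ", p, " fixed effects")
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("fixed-effects design is singular (rank ", qrX$rank, " < ", p, " columns)")

  m <- as.vector(table(cl))
  S <- rowsum(X, cl)                   # n x p cluster sums
  sy <- as.vector(rowsum(cbind(y), cl))
  XtX <- crossprod(X); Xty <- as.vector(crossprod(X, y)); yty <- sum(y * y)

  components <- function(theta) {
    ci <- theta / (1 + theta * m)
    XtWX <- XtX - crossprod(S * sqrt(ci))
    XtWy <- Xty - colSums(S * (ci * sy))
    yWy <- yty - sum(ci * sy^2)
    ch <- chol(XtWX)
    b <- backsolve(ch, forwardsolve(t(ch), XtWy))
    rss <- max(yWy - sum(b * XtWy), 1e-300)
    list(b = b, rss = rss, chol = ch,
         crit = sum(log1p(theta * m)) + 2 * sum(log(diag(ch))) +
           (N - p) * log(rss))
  }
  crit <- function(ltheta) components(exp(ltheta))$crit

  opt <- optimize(crit, c(log(1e-10), log(theta_max)), tol = 1e-10)
  theta <- exp(opt$minimum)
  at_zero <- components(0)
  if (at_zero$crit <= opt$objective + 1e-10) theta <- 0
  cm <- components(theta)
  sigma2 <- cm$rss / (N - p)
  b <- setNames(as.vector(cm$b), colnames(X))
  Vb <- chol2inv(cm$chol) * sigma2
  dimnames(Vb) <- list(colnames(X), colnames(X))
  structure(list(coefficients = b, psi = theta * sigma2, sigma2 = sigma2,
                 theta = theta, vcov = Vb,
                 fitted = as.vector(X %*% b), n = n, N = N,
                 converged = TRUE, call = match.call()),
            class = "reml_ri")
}

#' @export
print.reml_ri <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (REML): N = %d in %d clusters\n", x$N, x$n))
  cat("Fixed effects:\n"); print(round(x$coefficients, 4))
  cat(sprintf("Variance components: psi = %.4g, sigma_e^2 = %.4g\n",
              x$psi, x$sigma2))
  invisible(x)
}

#' @export
coef.reml_ri <- function(object, ...) object$coefficients

#' @export
vcov.reml_ri <- function(object, ...) object$vcov

#' Mediator model: regress one mediator on the exposure
#'
#' Random-intercept REML fit of
#' \eqn{M^{log}_t = \delta_0 + \delta_T T + \delta_C C + \gamma_{cluster} +
#' \eta}. An intercept is always included (log-proportions are strongly
#' negative-mean). Returns the exposure coefficient \eqn{\hat\delta_T^t}
#' alongside the full fit.
#'
#' @param m numeric mediator values, length N (one column of the transformed
#'   mediator matrix, or an alpha-diversity index).
#' @param exposure binary 0/1 exposure of length N; must take both values.
#' @param C covariate matrix (or `NULL`).
#' @param cluster cluster labels.
#' @return the [reml_ri()] fit with an added `delta_T` element.
#' @export
fit_mediator_model <- function(m, exposure, C, cluster) {
  if (length(unique(exposure)) < 2) stop("exposure has one level")
  X <- cbind(`(Intercept)` = 1, exposure = exposure)
  if (!is.null(C)) X <- cbind(X, C)
  fit <- reml_ri(m, X, cluster)
  fit$delta_T <- unname(fit$coefficients["exposure"])
  fit
}
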