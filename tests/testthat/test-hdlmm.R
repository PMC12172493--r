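test_that("covariance proxy blocks and effective sample size are exact", {
  # a = 0: identity blocks, trace = N
  p0 <- covariance_proxy(rep(c("A", "B"), c(3, 2)), a = 0)
  expect_equal(p0$trace_inv, 5)
  expect_equal(p0$inv_sqrt[[1]], diag(3), tolerance = 1e-12)

  # compound symmetry: eigenvalues 1 + a*m (once) and 1 (m - 1 times)
  p2 <- covariance_proxy(rep("A", 3), a = 2)
  S <- matrix(2, 3, 3) + diag(3)
  expect_equal(p2$trace_inv, 1 / 7 + 2, tolerance = 1e-12)
  expect_equal(p2$trace_inv, 2.142857, tolerance = 1e-6)
  # inverse square root reconstructs the identity
  R <- p2$inv_sqrt[[1]]
  expect_equal(R %*% S %*% R, diag(3), tolerance = 1e-10)
  expect_error(covariance_proxy(rep("A", 3), a = NA), "non-negative")
})

test_that("whitening is blockwise, linear, and preserves the quadratic form", {
  set.seed(2)
  cl <- rep(c("A", "B", "C"), c(4, 3, 5))
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- rnorm(12)

  wh0 <- whiten_data(X, y, covariance_proxy(cl, 0), cl)
  expect_equal(wh0$Xa, X, tolerance = 1e-12)
  expect_equal(wh0$ya, y, tolerance = 1e-12)

  pr <- covariance_proxy(cl, 1.7)
  wh <- whiten_data(X, y, pr, cl)
  wh_scaled <- whiten_data(X, 3 * y, pr, cl)
  expect_equal(wh_scaled$ya, 3 * wh$ya, tolerance = 1e-12)

  # ||ya||^2 = y' Sigma_a^{-1} y, computed by dense per-cluster solves
  quad <- sum(sapply(unique(cl), function(l) {
    rows <- cl == l
    V <- matrix(1.7, sum(rows), sum(rows)) + diag(sum(rows))
    t(y[rows]) %*% solve(V, y[rows])
  }))
  expect_equal(sum(wh$ya^2), quad, tolerance = 1e-8)
  expect_error(whiten_data(X[1:5, ], y[1:5], pr, cl[c(1:3, 8, 9)]), "match")
})

test_that("the scaled lasso obeys its closed forms", {
  # orthonormal design: soft-thresholding at lambda * Tr
  fit <- lasso_fixed_effects(diag(2), c(3, 0.5), trace_inv = 2, lambda = 1)
  expect_equal(unname(fit$beta), c(1, 0), tolerance = 1e-8)

  # lambda above lambda_max = max|Xa' ya| / Tr gives the zero solution
  set.seed(4)
  Xa <- matrix(rnorm(40), 10, 4); ya <- rnorm(10)
  tr <- 10
  lmax <- max(abs(crossprod(Xa, ya))) / tr
  expect_equal(unname(lasso_fixed_effects(Xa, ya, tr, lmax * 1.0001)$beta),
               rep(0, 4))
  expect_gt(sum(lasso_fixed_effects(Xa, ya, tr, lmax * 0.9)$beta != 0), 0)

  # lambda = 0, p < N, full rank: least squares
  ls <- lasso_fixed_effects(Xa, ya, tr, 0)
  expect_equal(unname(ls$beta), unname(coef(lm(ya ~ Xa - 1))), tolerance = 1e-6)
})

test_that("the solver agrees with glmnet on a random instance", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 60; p <- 25
  Xa <- matrix(rnorm(n * p), n, p); ya <- rnorm(n, sd = 2)
  tr <- 47.3   # arbitrary effective sample size
  lambda <- 0.08
  ours <- lasso_fixed_effects(Xa, ya, tr, lambda)$beta
  # glmnet minimizes 1/(2n)||y-Xb||^2 + lam||b||_1, so lam = lambda * tr / n
  g <- glmnet::glmnet(Xa, ya, lambda = lambda * tr / n, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(ours), as.numeric(g$beta), tolerance = 1e-5)
})

test_that("the lambda grid follows the sqrt(2 log(p) / N) rate", {
  g <- lambda_grid(exp(2), 2)
  expect_equal(max(g), 2 * sqrt(2), tolerance = 1e-6)
  expect_equal(max(g), 2.828427, tolerance = 1e-6)
  expect_equal(length(g), 20)
  expect_true(all(diff(g) < 0))
  expect_message(g1 <- lambda_grid(1, 100), "fixed small lambda grid")
  expect_equal(length(g1), 20)
})

test_that("cross-validated tuning returns the error-minimizing candidate", {
  set.seed(31)
  n <- 12; m <- rep(4, n); cl <- rep(sprintf("c%02d", 1:n), m)
  N <- sum(m); p <- 6
  X <- cbind(1, matrix(rnorm(N * (p - 1)), N, p - 1))
  y <- X %*% c(1, 2, -2, 0, 0, 0) + rep(rnorm(n, 0, 2), m) + rnorm(N)
  pf <- c(0, rep(1, p - 1))

  expect_equal(select_a(X, y, cl, candidate_as = 0.7)$a, 0.7)
  expect_error(select_a(X, y, cl, candidate_as = c(-1, 2)), ">= 0")
  expect_error(select_a(X, y, cl[1:8], candidate_as = c(1, 2), nfolds = 5),
               "fewer clusters")

  # exhaustive evaluation oracle: recompute each candidate's CV error with an
  # independent fold loop (dense whitening, fixed per-fold lasso path) and
  # check select_a returns the argmin under the same fold assignment
  cands <- c(0.1, 8)
  sel <- select_a(X, y, cl, candidate_as = cands, penalty_factor = pf,
                  fold_seed = 99)
  folds <- medilmm:::make_cluster_folds(unique(cl), 5, fold_seed = 99)
  lambdas <- lambda_grid(p, N)
  oracle_err <- sapply(cands, function(a) {
    tot <- rep(0, length(lambdas))
    for (k in 1:5) {
      hold <- cl %in% names(folds)[folds == k]
      Xtr <- X[!hold, , drop = FALSE]; ytr <- y[!hold]; ctr <- cl[!hold]
      # dense whitening: left-multiply each block by solve(sqrtm(V))
      Xw <- Xtr; yw <- ytr; trace <- 0
      for (l in unique(ctr)) {
        rows <- ctr == l
        V <- matrix(a, sum(rows), sum(rows)) + diag(sum(rows))
        e <- eigen(V, symmetric = TRUE)
        Ri <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
        Xw[rows, ] <- Ri %*% Xtr[rows, , drop = FALSE]
        yw[rows] <- Ri %*% ytr[rows]
        trace <- trace + sum(1 / e$values)
      }
      for (li in seq_along(lambdas)) {
        b <- lasso_fixed_effects(Xw, yw, trace, lambdas[li], pf)$beta
        tot[li] <- tot[li] + sum((y[hold] - X[hold, , drop = FALSE] %*% b)^2)
      }
    }
    min(tot)
  })
  expect_equal(sel$a, cands[which.min(oracle_err)])
  expect_equal(unname(sel$cv_error), oracle_err, tolerance = 1e-6)

  # lambda selection: single-value grid passes through; ties prefer sparser
  sl <- select_lambda(X, y, cl, a = 1, multipliers = 0.7)
  expect_equal(sl$lambda, 0.7 * sqrt(2 * log(p) / N))
  # pure-noise response selects a sparse-end lambda (large multiplier)
  set.seed(77)
  ynoise <- rnorm(N)
  sln <- select_lambda(X, ynoise, cl, a = 0.5, fold_seed = 5)
  expect_gte(sln$lambda / sqrt(2 * log(p) / N), 1.0)
})

test_that("nodewise scores handle orthogonal, single, and collinear designs", {
  cl <- rep(c("A", "B", "C"), each = 4)
  pr <- covariance_proxy(cl, 0)
  # exactly orthogonal columns: kappa = 0, w = the column itself
  Xo <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3))) * 3
  wh <- whiten_data(Xo, rnorm(12), pr, cl)
  sc <- nodewise_score(wh, 2, lambda_j = 0.05)
  expect_equal(sc$kappa, rep(0, 2), tolerance = 1e-8)
  expect_equal(sc$w, Xo[, 2], tolerance = 1e-8)

  # p = 1: the score is the column by definition
  wh1 <- whiten_data(Xo[, 1, drop = FALSE], rnorm(12), pr, cl)
  expect_equal(nodewise_score(wh1, 1)$w, Xo[, 1])

  # duplicated column with lambda_j = 0: zero residual, degenerate score
  Xd <- cbind(Xo[, 1], Xo[, 1], Xo[, 2])
  whd <- whiten_data(Xd, rnorm(12), pr, cl)
  expect_error(nodewise_score(whd, 1, lambda_j = 0), "degenerate correction score")
})

test_that("debiasing follows the correction-score formulas", {
  cl <- rep(c("A", "B", "C"), each = 2)
  pr <- covariance_proxy(cl, 0)
  set.seed(14)
  Xa <- matrix(rnorm(18), 6, 3)
  beta <- c(1, -2, 0.5)

  # zero residual: debiased estimate equals the lasso estimate, variance 0
  wh <- whiten_data(Xa, as.vector(Xa %*% beta), pr, cl)
  sc <- lapply(1:3, function(j) {
    s <- nodewise_score(wh, j, lambda_j = 0.1); attr(s, "column") <- j; s
  })
  names(sc) <- paste0("b", 1:3)
  db <- debias_lasso(beta, wh, sc)
  expect_equal(unname(db$beta_db), beta, tolerance = 1e-10)
  expect_equal(unname(db$V), rep(0, 3), tolerance = 1e-14)

  # identity design with unit scores: debiased estimate is ya_j regardless
  # of the initial lasso value
  cl6 <- paste0("u", 1:6)
  wh_id <- whiten_data(diag(6), rnorm(6), covariance_proxy(cl6, 0), cl6)
  sc_id <- list(structure(list(w = diag(6)[, 2], kappa = NULL, lambda_j = 0,
                               denom = 1), column = 2))
  names(sc_id) <- "e2"
  start <- c(0, 9, 0, 0, 0, 0)
  expect_equal(unname(debias_lasso(start, wh_id, sc_id)$beta_db),
               wh_id$ya[2], tolerance = 1e-12)

  # clustered variance equals the brute-force per-cluster sum on a 3-cluster toy
  y2 <- as.vector(Xa %*% beta) + rnorm(6)
  wh2 <- whiten_data(Xa, y2, pr, cl)
  s2 <- nodewise_score(wh2, 1, lambda_j = 0.2); attr(s2, "column") <- 1
  db2 <- debias_lasso(beta, wh2, list(x1 = s2))
  r <- wh2$ya - as.vector(wh2$Xa %*% beta)
  brute <- sum(sapply(c("A", "B", "C"), function(l)
    sum(s2$w[cl == l] * r[cl == l])^2)) / s2$denom^2
  expect_equal(unname(db2$V), brute, tolerance = 1e-12)
})

test_that("with negligible penalty the debiased fit reduces to proxy GLS", {
  set.seed(55)
  n <- 25; m <- sample(3:6, n, TRUE); N <- sum(m)
  cl <- rep(sprintf("g%02d", 1:n), m)
  p <- 4
  X <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(2, -1, 0.5, 0)
  a_true <- 1.5  # psi / sigma_e^2
  y <- X %*% beta + rep(rnorm(n, 0, sqrt(1.5)), m) + rnorm(N)

  fit <- hdlmm(X, y, cl, a = a_true, lambda = 0, intercept = FALSE,
               control = hdlmm_control(center = FALSE))
  gls <- gls_proxy(X, y, cl, a_true)
  expect_equal(unname(fit$beta_db), as.vector(gls), tolerance = 1e-4)
  expect_equal(unname(coef(fit, "lasso")), as.vector(gls), tolerance = 1e-4)
})

test_that("estimates are invariant to sample order within clusters", {
  set.seed(66)
  n <- 10; m <- rep(4, n); N <- sum(m)
  cl <- rep(sprintf("g%02d", 1:n), m)
  X <- matrix(rnorm(N * 6), N, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 1] * 2 + rep(rnorm(n), m) + rnorm(N)
  # permute rows within each cluster (cluster label sequence unchanged)
  perm <- unlist(lapply(split(seq_len(N), cl), sample))
  stopifnot(identical(cl[perm], cl))
  ctl <- hdlmm_control(fold_seed = 11)
  f1 <- hdlmm(X, y, cl, a = 0.8, lambda = 0.05, control = ctl)
  f2 <- hdlmm(X[perm, ], y[perm], cl, a = 0.8, lambda = 0.05, control = ctl)
  expect_equal(f1$beta_db, f2$beta_db, tolerance = 1e-10)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("debiased intervals cover a null coordinate at the nominal rate", {
  # property check at reduced problem size; coverage band per the estimator's
  # design target of 90-98% for beta_j = 0
  set.seed(123)
  reps <- 120
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 25; m <- sample(3:5, n, TRUE); N <- sum(m)
    cl <- rep(sprintf("g%02d", 1:n), m)
    X <- matrix(rnorm(N * 12), N, 12, dimnames = list(NULL, paste0("x", 1:12)))
    y <- X[, 1] - 1.5 * X[, 2] + rep(rnorm(n), m) + rnorm(N)
    fit <- hdlmm(X, y, cl, debias = 5, a = 1,
                 control = hdlmm_control(fold_seed = r))
    ci <- confint(fit)["x5", ]
    covered[r] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})
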