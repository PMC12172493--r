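# Small in-code fixtures shared across the suite.

# Count table from a plain matrix, default generic lineages.
toy_counts <- function(mat, lineage = NULL, domains = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (is.null(lineage)) {
    if (is.null(domains)) domains <- rep("Bacteria", nrow(mat))
    lineage <- paste0(domains, ";", rownames(mat))
  }
  count_table(mat, lineage)
}

# Metadata covering given sample ids; states/clusters recycled.
toy_meta <- function(sample_ids, cluster = NULL, state = "baseline",
                     aggressiveness = NULL, age = 30, fev1 = 60) {
  n <- length(sample_ids)
  d <- data.frame(sample_id = sample_ids,
                  cluster_id = rep_len(cluster %||% paste0("P", seq_len(max(1, n %/% 2))), n),
                  clinical_state = rep_len(state, n),
                  age = rep_len(age, n), fev1_pct = rep_len(fev1, n),
                  stringsAsFactors = FALSE)
  if (!is.null(aggressiveness)) d$aggressiveness <- rep_len(aggressiveness, n)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct dense GLS under the proxy covariance, computed independently of the
# package's whitening path (explicit per-cluster solves).
gls_proxy <- function(X, y, cluster, a) {
  cl <- unique(cluster)
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  for (l in cl) {
    rows <- which(cluster == l)
    m <- length(rows)
    V <- matrix(a, m, m) + diag(m)
    Vi <- solve(V)
    Xi <- X[rows, , drop = FALSE]
    XtVX <- XtVX + t(Xi) %*% Vi %*% Xi
    XtVy <- XtVy + t(Xi) %*% Vi %*% y[rows]
  }
  solve(XtVX, XtVy)
}

# Balanced one-way ANOVA estimators of the variance components (the REML
# closed form for balanced designs when MSB > MSW > 0).
anova_oneway <- function(y, cluster) {
  cl <- factor(cluster)
  m <- as.vector(table(cl))[1]
  n <- nlevels(cl)
  means <- tapply(y, cl, mean)
  msw <- sum((y - means[cl])^2) / (n * (m - 1))
  msb <- m * sum((means - mean(y))^2) / (n - 1)
  list(sigma2 = msw, psi = (msb - msw) / m, mean = mean(y))
}
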