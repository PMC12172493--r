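#' Resample a study frame at the cluster level
#'
#' Draws n cluster labels with replacement and concatenates their full sample
#' blocks, preserving the intracluster correlation structure. Clusters drawn
#' more than once receive fresh unique labels so downstream models treat the
#' copies as distinct clusters. Uses the current RNG stream.
#'
#' @param frame a [study_frame()] with at least one cluster.
#' @return a resampled `study_frame`.
#' @export
cluster_resample <- function(frame) {
  levels <- unique(frame$cluster)
  n <- length(levels)
  draw <- sample(levels, n, replace = TRUE)
  frame_take_clusters(frame, draw, new_labels = paste0("bs", seq_len(n)))
}

#' BCa confidence interval from bootstrap and jackknife estimates
#'
#' Bias-corrected and accelerated interval: bias correction
#' \eqn{z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)} (proportions of 0 or 1
#' are clamped to 1/(2B) and 1 - 1/(2B) and logged), acceleration from the
#' cluster-level jackknife skewness
#' \eqn{\hat a = \sum(\bar\theta_{(\cdot)} - \theta_{(i)})^3 /
#' \{6 [\sum(\bar\theta_{(\cdot)} - \theta_{(i)})^2]^{3/2}\}}, and empirical
#' quantiles of the bootstrap distribution by linear interpolation at the
#' adjusted percentiles. With fewer than 3 jackknife values (or none) the
#' acceleration falls back to 0. If all bootstrap estimates coincide, the
#' degenerate interval (c, c) is returned and logged.
#'
#' @param theta_hat original-sample estimate.
#' @param boot_estimates numeric vector of bootstrap estimates.
#' @param jackknife_estimates numeric vector of leave-one-cluster-out
#'   estimates, or `NULL` for zero acceleration.
#' @param level confidence level, default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
bca_interval <- function(theta_hat, boot_estimates, jackknife_estimates = NULL,
                         level = 0.95) {
  b <- boot_estimates[is.finite(boot_estimates)]
  B <- length(b)
  if (B < 1) stop("no bootstrap estimates")
  if (max(b) - min(b) < .Machine$double.eps * max(1, abs(b[1]))) {
    msg_log("warn", "degenerate bootstrap distribution; interval collapsed to a point")
    return(c(lower = b[1], upper = b[1]))
  }
  prop <- mean(b < theta_hat)
  if (prop <= 0 || prop >= 1) {
    msg_log("warn", "bootstrap distribution entirely on one side of theta_hat; ",
            "z0 proportion clamped")
    prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  }
  z0 <- qnorm(prop)
  a <- 0
  if (!is.null(jackknife_estimates)) {
    jk <- jackknife_estimates[is.finite(jackknife_estimates)]
    if (length(jk) >= 3) {
      d <- mean(jk) - jk
      denom <- 6 * sum(d^2)^1.5
      if (denom > 0) a <- sum(d^3) / denom
    }
  }
  alpha <- (1 - level) / 2
  adj <- function(z) {
    zz <- z0 + z
    pnorm(z0 + zz / (1 - a * zz))
  }
  probs <- c(adj(qnorm(alpha)), adj(qnorm(1 - alpha)))
  out <- quantile(b, probs = probs, names = FALSE, type = 7)
  c(lower = out[1], upper = out[2])
}

#' Two-tailed bootstrap p-value
#'
#' The proportion of bootstrap estimates at or below zero, adjusted for
#' two-tailed testing by doubling the smaller tail:
#' \eqn{p = \min\{1, \max(2 \min(\#\{\theta^* \le 0\},
#' \#\{\theta^* > 0\})/B,\ 1/B)\}}. The 1/B floor keeps finite resampling
#' from reporting a literal zero.
#'
#' @param boot_estimates numeric vector of bootstrap estimates.
#' @return p-value in (0, 1].
#' @export
bootstrap_pvalue <- function(boot_estimates) {
  b <- boot_estimates[is.finite(boot_estimates)]
  B <- length(b)
  if (B < 1) stop("no bootstrap estimates")
  p <- 2 * min(mean(b <= 0), mean(b > 0))
  min(max(p, 1 / B), 1)
}

#' Cluster bootstrap of a full mediation analysis
#'
#' Repeats the entire mediation analysis — including tuning-parameter
#' selection in taxa mode — on `B` independent cluster-level resamples.
#' Per-resample RNG substreams are derived from `seed` and the resample
#' index, so results are identical for a given `(seed, B)` regardless of
#' `threads`. Point estimates are the means of the resample estimates;
#' intervals are BCa with cluster-level jackknife acceleration; p-values are
#' two-tailed bootstrap proportions, BH-adjusted across the mediator indirect
#' effects.
#'
#' Resamples whose fit fails are recorded and excluded; more than 5\% failures
#' is a hard error.
#'
#' @param frame a [study_frame()].
#' @param mode `"taxa"` (debiased-lasso outcome model) or `"community"`
#'   (single-mediator REML).
#' @param B number of bootstrap resamples (default 3000).
#' @param seed integer seed governing all resampling randomness.
#' @param level confidence level for the BCa intervals.
#' @param threads parallel workers (forked; 1 = serial).
#' @param jackknife compute cluster-jackknife acceleration (set `FALSE` to
#'   force zero acceleration and skip the n extra fits).
#' @param control an [hdlmm_control()] for taxa mode.
#' @return object of class `boot_mediation`: `estimates` (B x E matrix),
#'   `point` (bootstrap means), `theta_hat` (original-sample effects), `ci`,
#'   `p_raw`, `p_bh`, `n_failed`, `B`, `seed`.
#' @export
bootstrap_mediation <- function(frame, mode = c("taxa", "community"),
                                B = 3000, seed = 1L, level = 0.95,
                                threads = 1L, jackknife = TRUE,
                                control = hdlmm_control()) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  if (length(unique(frame$cluster)) < 2) stop("need at least 2 clusters")

  # independent substreams for the B resamples, the original-sample fit, and
  # the jackknife, all derived from `seed`: the whole result is a pure
  # function of (frame, mode, B, seed), whatever the ambient RNG state
  seeds <- with_preserved_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                B + 2L))
  theta_full <- with_preserved_seed(seeds[B + 1L],
                                    mediation_point(frame, mode,
                                                    control = control))
  theta_hat <- effects_vector(theta_full)
  one <- function(b) {
    set.seed(seeds[b])
    tryCatch(effects_vector(mediation_point(cluster_resample(frame), mode,
                                            control = control)),
             error = function(e) {
               msg_log("warn", "bootstrap resample ", b, " failed: ",
                       conditionMessage(e))
               rep(NA_real_, length(theta_hat))
             })
  }
  res <- if (threads > 1L) {
    parallel::mclapply(seq_len(B), one, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(B), one)
  }
  est <- do.call(rbind, res)
  colnames(est) <- names(theta_hat)
  failed <- apply(est, 1, function(r) any(!is.finite(r)))
  if (mean(failed) > 0.05)
    stop(sprintf("%d of %d bootstrap resamples failed (> 5%%)", sum(failed), B))
  est_ok <- est[!failed, , drop = FALSE]

  jack <- NULL
  if (jackknife) {
    levels <- unique(frame$cluster)
    if (length(levels) >= 3) {
      jack <- with_preserved_seed(seeds[B + 2L], t(vapply(levels, function(l) {
        keep <- setdiff(levels, l)
        tryCatch(effects_vector(mediation_point(
          frame_take_clusters(frame, keep), mode, control = control)),
          error = function(e) rep(NA_real_, length(theta_hat)))
      }, numeric(length(theta_hat)))))
    }
  }

  ci <- t(vapply(seq_along(theta_hat), function(e)
    bca_interval(theta_hat[e], est_ok[, e],
                 if (is.null(jack)) NULL else jack[, e], level),
    numeric(2)))
  rownames(ci) <- names(theta_hat)
  p_raw <- vapply(seq_along(theta_hat), function(e) bootstrap_pvalue(est_ok[, e]),
                  numeric(1))
  names(p_raw) <- names(theta_hat)
  ind <- grep("^indirect\\.", names(theta_hat))
  p_bh <- p_raw
  if (length(ind)) p_bh[ind] <- p.adjust(p_raw[ind], method = "BH")

  structure(list(estimates = est_ok, point = colMeans(est_ok),
                 theta_hat = theta_hat, ci = ci, p_raw = p_raw, p_bh = p_bh,
                 jackknife = jack, n_failed = sum(failed), B = B,
                 level = level, seed = seed, mode = mode),
            class = "boot_mediation")
}

#' @export
print.boot_mediation <- function(x, ...) {
  cat(sprintf("Cluster bootstrap (%s mode): B = %d (%d failed), %g%% BCa intervals\n",
              x$mode, x$B, x$n_failed, 100 * x$level))
  show <- c("direct", "total")
  for (e in show)
    cat(sprintf("  %-7s %8.3f  [%8.3f, %8.3f]  p = %.4g\n", e, x$point[e],
                x$ci[e, 1], x$ci[e, 2], x$p_raw[e]))
  cat(sprintf("  (+ %d indirect effect(s))\n",
              sum(grepl("^indirect\\.", names(x$point)))))
  invisible(x)
}
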