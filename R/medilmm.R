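#' Mediation analysis of a longitudinal microbiome study
#'
#' The end-to-end fit: preprocesses a raw count table (domain exclusion, genus
#' aggregation, depth and prevalence filters, single-sample patient
#' exclusion), builds the mediator matrix — log10-proportion-transformed
#' genera in `"taxa"` mode, one genus-level alpha-diversity index in
#' `"community"` mode — restricts to a pairwise exposure contrast, and runs
#' the cluster bootstrap of the full mediation analysis: a debiased-lasso
#' high-dimensional outcome model (taxa) or a single-mediator REML outcome
#' model (community), per-mediator random-intercept REML models, and
#' product-of-coefficients composition of the direct, indirect, and total
#' effects, with BCa intervals and Benjamini-Hochberg-adjusted bootstrap
#' p-values across the indirect effects.
#'
#' @param counts a [count_table()] of raw genus/OTU counts.
#' @param metadata per-sample metadata (see [read_sample_metadata()]); an
#'   in-memory data.frame is validated with [validate_metadata()].
#' @param exposure `"clinical_state"` or `"aggressiveness"`.
#' @param ref,comparison the contrast's reference (T = 0) and comparison
#'   (T = 1) levels.
#' @param mode `"taxa"` for the high-dimensional genus-level analysis,
#'   `"community"` for a single alpha-diversity mediator.
#' @param index alpha-diversity index for community mode.
#' @param covariates metadata columns used as adjustment covariates; default
#'   age. Use `NULL` for an unadjusted model.
#' @param outcome metadata column holding the response.
#' @param n_boot bootstrap resamples (default 3000).
#' @param seed integer seed governing the bootstrap.
#' @param level confidence level.
#' @param threads forked parallel workers for the bootstrap.
#' @param pseudo pseudo-count placement for [lognorm_transform()].
#' @param excluded,min_reads,min_count,min_fraction preprocessing thresholds
#'   (see [preprocess_counts()]).
#' @param control an [hdlmm_control()] for the taxa-mode outcome model.
#' @param jackknife compute cluster-jackknife BCa acceleration.
#' @return Object of class `medilmm`: `effects` (the effect table, see
#'   [write_effect_table()]), `boot` (the [bootstrap_mediation()] result),
#'   `frame`, `filter_report`, and the run configuration.
#' @examples
#' d <- simulate_mediation_data(n = 25, m_range = c(2, 6), H = 12, s = 3,
#'                              seed = 7)
#' fit <- medilmm(d$counts, d$metadata, ref = "baseline",
#'                comparison = "exacerbation", mode = "community",
#'                index = "shannon", n_boot = 50, seed = 7)
#' fit
#' @export
medilmm <- function(counts, metadata,
                    exposure = c("clinical_state", "aggressiveness"),
                    ref, comparison, mode = c("taxa", "community"),
                    index = c("shannon", "observed", "simpson"),
                    covariates = "age", outcome = "fev1_pct",
                    n_boot = 3000, seed = 1L, level = 0.95, threads = 1L,
                    pseudo = c("count", "proportion"),
                    excluded = c("Archaea", "Eukarya"), min_reads = 1000,
                    min_count = 3, min_fraction = 0.05,
                    control = hdlmm_control(), jackknife = TRUE) {
  exposure <- match.arg(exposure)
  mode <- match.arg(mode)
  index <- match.arg(index)
  pseudo <- match.arg(pseudo)
  metadata <- validate_metadata(metadata)

  pp <- preprocess_counts(counts, metadata, excluded = excluded,
                          min_reads = min_reads, min_count = min_count,
                          min_fraction = min_fraction)
  mediators <- if (mode == "taxa") {
    lognorm_transform(pp$counts, pseudo = pseudo)
  } else {
    # alpha diversity computed on counts, not log-transformed
    matrix(alpha_diversity(pp$counts, index), ncol = 1,
           dimnames = list(colnames(pp$counts$counts), index))
  }
  frame <- subset_contrast(pp$metadata, mediators, exposure = exposure,
                           ref = ref, comparison = comparison,
                           outcome = outcome, covariates = covariates)
  boot <- bootstrap_mediation(frame, mode = mode, B = n_boot, seed = seed,
                              level = level, threads = threads,
                              jackknife = jackknife, control = control)
  effects <- effect_table(boot, contrast_label(frame))
  structure(list(effects = effects, boot = boot, frame = frame,
                 filter_report = pp$report,
                 config = list(exposure = exposure, ref = ref,
                               comparison = comparison, mode = mode,
                               index = if (mode == "community") index else NA,
                               covariates = covariates, outcome = outcome,
                               n_boot = n_boot, seed = seed, level = level,
                               pseudo = pseudo, min_reads = min_reads,
                               min_count = min_count,
                               min_fraction = min_fraction),
                 call = match.call()),
            class = "medilmm")
}

# Assemble the tabular effect summary from a bootstrap result.
# Estimates are bootstrap means (the original-sample fit is kept in
# boot$theta_hat); p_adjusted applies BH across the indirect effects only,
# leaving the single direct/total tests unadjusted.
effect_table <- function(boot, contrast) {
  nm <- names(boot$point)
  type <- ifelse(nm == "direct", "direct",
                 ifelse(nm == "total", "total", "indirect"))
  mediator <- ifelse(type == "indirect", sub("^indirect\\.", "", nm), "")
  out <- data.frame(contrast = contrast, effect_type = type,
                    mediator = mediator, estimate = unname(boot$point),
                    ci_lower = unname(boot$ci[, 1]),
                    ci_upper = unname(boot$ci[, 2]),
                    p_value = unname(boot$p_raw),
                    p_adjusted = unname(boot$p_bh),
                    stringsAsFactors = FALSE)
  ord <- c(which(type == "total"), which(type == "direct"),
           which(type == "indirect"))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.medilmm <- function(x, ...) {
  cfg <- x$config
  cat("Longitudinal microbiome mediation analysis\n")
  cat(sprintf("  contrast: %s %s (ref) vs %s;  mode: %s%s\n", cfg$exposure,
              cfg$ref, cfg$comparison, cfg$mode,
              if (cfg$mode == "community") paste0(" (", cfg$index, ")") else ""))
  cat(sprintf("  N = %d samples in %d clusters; %d mediator(s); B = %d\n",
              length(x$frame$Y), length(unique(x$frame$cluster)),
              ncol(x$frame$M), x$boot$B))
  e <- x$effects
  for (ty in c("total", "direct")) {
    r <- e[e$effect_type == ty, ][1, ]
    cat(sprintf("  %-6s effect %8.3f  [%.3f, %.3f]  p = %.4g\n", ty,
                r$estimate, r$ci_lower, r$ci_upper, r$p_value))
  }
  sig <- e[e$effect_type == "indirect" & e$p_adjusted <= 0.05, ]
  cat(sprintf("  indirect effects: %d mediator(s), %d with BH-adjusted p <= 0.05\n",
              sum(e$effect_type == "indirect"), nrow(sig)))
  invisible(x)
}

#' @export
summary.medilmm <- function(object, ...) {
  structure(list(effects = object$effects, config = object$config,
                 filter_report = object$filter_report,
                 n_failed = object$boot$n_failed, B = object$boot$B),
            class = "summary.medilmm")
}

#' @export
print.summary.medilmm <- function(x, ...) {
  cat(sprintf("Mediation effects (%s; bootstrap B = %d, %d resample(s) failed)\n",
              x$effects$contrast[1], x$B, x$n_failed))
  e <- x$effects
  e$estimate <- round(e$estimate, 4)
  e$ci_lower <- round(e$ci_lower, 4)
  e$ci_upper <- round(e$ci_upper, 4)
  e$p_value <- signif(e$p_value, 3)
  e$p_adjusted <- signif(e$p_adjusted, 3)
  print(e, row.names = FALSE)
  invisible(x)
}

#' @export
coef.medilmm <- function(object, ...) {
  setNames(object$effects$estimate,
           ifelse(object$effects$effect_type == "indirect",
                  paste0("indirect.", object$effects$mediator),
                  object$effects$effect_type))
}

#' @export
confint.medilmm <- function(object, parm, level, ...) {
  ci <- object$boot$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Forest plot of mediation effects
#'
#' Point estimates (bootstrap means) with BCa intervals for the total effect,
#' the direct effect, and the mediator indirect effects, drawn with base
#' graphics. Mediators are ordered by absolute estimate; with many mediators
#' only the `max_mediators` largest are shown.
#'
#' @param x a [medilmm()] fit.
#' @param max_mediators indirect effects displayed at most.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.medilmm <- function(x, max_mediators = 20, ...) {
  e <- x$effects
  ind <- e[e$effect_type == "indirect", ]
  ind <- ind[order(-abs(ind$estimate)), ]
  if (nrow(ind) > max_mediators) ind <- ind[seq_len(max_mediators), ]
  show <- rbind(e[e$effect_type %in% c("total", "direct"), ], ind)
  labels <- ifelse(show$effect_type == "indirect", show$mediator,
                   show$effect_type)
  k <- nrow(show)
  ypos <- rev(seq_len(k))
  xlim <- range(show$ci_lower, show$ci_upper, 0)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(show$estimate, ypos, xlim = xlim, ylim = c(0.5, k + 0.5),
                 pch = 19, yaxt = "n", xlab = "effect on outcome", ylab = "",
                 panel.first = graphics::abline(v = 0, lty = 2, col = "grey60"),
                 ...)
  graphics::segments(show$ci_lower, ypos, show$ci_upper, ypos)
  graphics::axis(2, at = ypos, labels = labels, las = 1, cex.axis = 0.8)
  graphics::title(main = paste0(e$contrast[1], " (", x$config$mode, " mode)"))
  invisible(x)
}
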