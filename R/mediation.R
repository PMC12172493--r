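#' Fit the high-dimensional outcome model of a taxa-level mediation analysis
#'
#' Builds the design `[T, C, Mlog]` (an unpenalized intercept is added
#' internally), runs the full debiased-lasso chain — proxy selection,
#' whitening, lambda selection, lasso, nodewise correction — and returns
#' debiased estimates for the exposure, every covariate, and every mediator
#' coordinate.
#'
#' @param frame a [study_frame()] with at least one mediator column.
#' @param a,lambda optional fixed tuning parameters (bypass cross-validation).
#' @param control an [hdlmm_control()] list.
#' @return the [hdlmm()] fit.
#' @export
fit_taxa_outcome <- function(frame, a = NULL, lambda = NULL,
                             control = hdlmm_control()) {
  if (ncol(frame$M) < 1) stop("taxa-level outcome model requires mediators")
  X <- cbind(exposure = frame$Tr, frame$C, frame$M)
  hdlmm(X, frame$Y, frame$cluster, debias = seq_len(ncol(X)),
        a = a, lambda = lambda, control = control)
}

#' Fit every mediator model of a taxa-level mediation analysis
#'
#' One random-intercept REML fit per mediator column, each regressing the
#' mediator on the exposure and covariates. Per-mediator failures are caught
#' and surfaced: a failed mediator's exposure coefficient is `NA` (and its
#' indirect effect is treated as missing downstream, never as silently zero).
#'
#' @param frame a [study_frame()].
#' @return `list(delta_T = named vector, fits = list of reml_ri or NULL,
#'   failed = character vector of failed mediator names)`.
#' @export
fit_all_mediator_models <- function(frame) {
  H <- ncol(frame$M)
  if (H < 1) stop("no mediators to model")
  fits <- vector("list", H)
  delta <- rep(NA_real_, H)
  names(fits) <- names(delta) <- colnames(frame$M)
  for (t in seq_len(H)) {
    fits[[t]] <- tryCatch(
      fit_mediator_model(frame$M[, t], frame$Tr, frame$C, frame$cluster),
      error = function(e) {
        msg_log("warn", "mediator model failed for '", colnames(frame$M)[t],
                "': ", conditionMessage(e))
        NULL
      })
    if (!is.null(fits[[t]])) delta[t] <- fits[[t]]$delta_T
  }
  failed <- names(delta)[is.na(delta)]
  if (length(failed))
    msg_log("warn", length(failed),
            " mediator model(s) failed; their indirect effects are missing")
  list(delta_T = delta, fits = fits, failed = failed)
}

#' Compose direct, indirect, and total mediation effects
#'
#' Product-of-coefficients composition: the direct effect is the debiased
#' exposure coefficient of the outcome model; the indirect effect through
#' mediator \eqn{t} is \eqn{\hat\delta_T^t \hat\beta_{M_t}}; the total effect
#' is the direct effect plus the sum of the indirect effects. Mediators with a
#' missing \eqn{\hat\delta_T^t} contribute `NA` indirect effects and are
#' excluded from the total-effect sum (with a warning upstream).
#'
#' @param beta_T debiased exposure coefficient (direct effect).
#' @param beta_M named vector of debiased mediator coefficients.
#' @param delta_T named vector of exposure-to-mediator coefficients; names
#'   must match `beta_M`.
#' @return object of class `mediation_effects`: `direct`, `indirect` (named),
#'   `total`.
#' @export
compose_effects <- function(beta_T, beta_M, delta_T) {
  if (!setequal(names(beta_M), names(delta_T)))
    stop("mediator names of the outcome and mediator models disagree")
  delta_T <- delta_T[names(beta_M)]
  indirect <- delta_T * beta_M
  total <- beta_T + sum(indirect, na.rm = TRUE)
  structure(list(direct = unname(beta_T), indirect = indirect, total = total),
            class = "mediation_effects")
}

#' @export
print.mediation_effects <- function(x, ...) {
  cat(sprintf("direct %.4g + indirect (sum %.4g over %d mediator(s)) = total %.4g\n",
              x$direct, sum(x$indirect, na.rm = TRUE),
              length(x$indirect), x$total))
  invisible(x)
}

# Flatten a mediation_effects object into the named vector the bootstrap
# aggregates: direct, one entry per mediator, total.
effects_vector <- function(eff) {
  c(direct = eff$direct,
    setNames(eff$indirect, paste0("indirect.", names(eff$indirect))),
    total = eff$total)
}

#' Taxa-level mediation point estimates for one study frame
#'
#' One full pass of the high-dimensional analysis: debiased-lasso outcome
#' model, per-mediator REML models, product-of-coefficients composition.
#'
#' @inheritParams fit_taxa_outcome
#' @return `mediation_effects` with the outcome and mediator fits attached as
#'   attributes `outcome_fit` and `mediator_fits`.
#' @export
taxa_mediation <- function(frame, a = NULL, lambda = NULL,
                           control = hdlmm_control()) {
  out <- fit_taxa_outcome(frame, a = a, lambda = lambda, control = control)
  med <- fit_all_mediator_models(frame)
  beta_db <- out$beta_db
  eff <- compose_effects(beta_db[["exposure"]],
                         beta_db[colnames(frame$M)], med$delta_T)
  attr(eff, "outcome_fit") <- out
  attr(eff, "mediator_fits") <- med
  eff
}

#' Community-level single-mediator mediation
#'
#' The low-dimensional analogue used for alpha-diversity mediators: both the
#' outcome model \eqn{Y = \beta_0 + \beta_T T + \beta_M M + \beta_C C +
#' \gamma_{cluster} + \epsilon} and the mediator model are random-intercept
#' REML fits (no lasso), and the effects are composed exactly as in the
#' taxa-level analysis.
#'
#' @param frame a [study_frame()] with exactly one mediator column.
#' @return `mediation_effects` with fits attached as attributes.
#' @export
community_mediation <- function(frame) {
  if (ncol(frame$M) != 1)
    stop("community mode requires exactly one mediator column, got ",
         ncol(frame$M))
  mname <- colnames(frame$M)
  constant_med <- sd(frame$M[, 1]) == 0
  if (constant_med) {
    # a constant mediator (e.g. identical richness everywhere) carries no
    # effect and would make the design singular; drop it, beta_M = 0
    msg_log("warn", "mediator '", mname, "' is constant; beta_M fixed at 0")
    X <- cbind(`(Intercept)` = 1, exposure = frame$Tr, frame$C)
  } else {
    X <- cbind(`(Intercept)` = 1, exposure = frame$Tr, frame$M, frame$C)
  }
  out <- reml_ri(frame$Y, X, frame$cluster)
  med <- fit_mediator_model(frame$M[, 1], frame$Tr, frame$C, frame$cluster)
  beta_M <- if (constant_med) 0 else out$coefficients[[mname]]
  eff <- compose_effects(out$coefficients[["exposure"]],
                         setNames(beta_M, mname),
                         setNames(med$delta_T, mname))
  attr(eff, "outcome_fit") <- out
  attr(eff, "mediator_fits") <- list(delta_T = setNames(med$delta_T, mname),
                                     fits = setNames(list(med), mname),
                                     failed = character(0))
  eff
}

# Dispatch one point-estimate pass for the bootstrap / jackknife.
mediation_point <- function(frame, mode, a = NULL, lambda = NULL,
                            control = hdlmm_control()) {
  if (mode == "taxa") taxa_mediation(frame, a = a, lambda = lambda,
                                     control = control)
  else community_mediation(frame)
}
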