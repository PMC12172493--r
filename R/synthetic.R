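#' Simulate a clustered longitudinal microbiome mediation dataset
#'
#' Generates the full data structure the taxa-level analysis consumes: a
#' taxon-by-sample count table, per-sample clinical metadata, and the ground
#' truth of the generative mediation model. Per cluster (patient) i: a random
#' cluster size \eqn{m_i}, a mean-zero Gaussian outcome random intercept
#' (variance `psi`) and one per mediator (variance `psi_med`); exposure
#' assigned per observation (`within_cluster`, clinical-state-like) or per
#' cluster (`between_cluster`, phenotype-like). Latent genus log10-abundances
#' are `baseline + delta_T * T + random intercept + noise`; proportions are
#' the softmax \eqn{10^{lat}/\sum 10^{lat}} and counts are multinomial draws
#' at a uniform random depth (optionally Dirichlet-overdispersed). The outcome
#' is built from the true log10-proportions — not the pseudo-counted
#' transform — so estimation error attributable to the pseudo-count is a
#' measured property, never baked into the truth:
#' \deqn{Y = intercept + \beta_T T + \sum_t \beta_{M_t} \log_{10} p_t +
#' \beta_C age + \gamma_i + \epsilon.}
#'
#' Defaults mimic a decade-long CF sputum cohort: 89 patients with 2-24
#' samples each, 47 genera, an FEV1\%-like outcome (intercept 58, residual SD
#' 8, patient SD 8), ages 6-54, and depths 1000-50000 reads.
#'
#' @param n number of clusters (patients).
#' @param m_range inclusive range cluster sizes are drawn from uniformly.
#' @param H number of taxa (mediators).
#' @param s number of truly active mediators (first `s` taxa carry both a
#'   nonzero `delta_T` and a nonzero `beta_M`).
#' @param beta_T true direct effect of the exposure on the outcome.
#' @param beta_M length-`s` mediator-to-outcome coefficients (recycled /
#'   defaulted to alternating-sign magnitudes 1, 1.5, ...).
#' @param delta_T length-`s` exposure-to-mediator shifts on the log10 scale
#'   (default 0.5).
#' @param psi outcome random-intercept variance.
#' @param sigma_e outcome residual SD.
#' @param psi_med,sigma_med mediator random-intercept variance and residual SD.
#' @param intercept outcome grand intercept.
#' @param age_effect covariate coefficient for age.
#' @param age_range patient age range (years), uniform.
#' @param depth_range per-sample sequencing depth range, uniform integer.
#' @param exposure_mode `"within_cluster"` (exposure varies across repeated
#'   samples, labelled baseline/exacerbation) or `"between_cluster"`
#'   (patient-level phenotype, labelled mild/moderate_severe).
#' @param dirichlet_scale optional positive scalar; when given, multinomial
#'   probabilities are drawn from a Dirichlet with concentration
#'   `dirichlet_scale * p`, adding overdispersion.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return `list(counts, metadata, truth)`: a [count_table()], a validated
#'   metadata data.frame (with an extra `exposure` 0/1 column), and a truth
#'   list with `direct`, `indirect` (named, \eqn{\delta_T^t \beta_{M_t}}),
#'   `total`, the full coefficient vectors, the active-taxon names, and the
#'   realized true log10-proportion matrix `Mlog_true` (samples x taxa).
#' @export
simulate_mediation_data <- function(n = 89, m_range = c(2, 24), H = 47, s = 5,
                                    beta_T = -5, beta_M = NULL, delta_T = NULL,
                                    psi = 64, sigma_e = 8,
                                    psi_med = 0.25, sigma_med = 0.8,
                                    intercept = 58, age_effect = 0,
                                    age_range = c(6, 54),
                                    depth_range = c(1000, 50000),
                                    exposure_mode = c("within_cluster",
                                                      "between_cluster"),
                                    dirichlet_scale = NULL, seed = NULL) {
  exposure_mode <- match.arg(exposure_mode)
  stopifnot(n >= 2, H >= s, s >= 0, psi >= 0, sigma_e > 0,
            depth_range[1] >= 1)
  gen <- function() {
    if (is.null(beta_M)) beta_M <- rep_len(c(1, -1.5, 1.25, -1, 1.5), s)
    beta_M <- rep_len(beta_M, s)
    if (is.null(delta_T)) delta_T <- rep(0.5, s)
    delta_T <- rep_len(delta_T, s)
    beta_full <- c(beta_M, rep(0, H - s))
    delta_full <- c(delta_T, rep(0, H - s))
    taxa <- sprintf("Genus%03d", seq_len(H))
    names(beta_full) <- names(delta_full) <- taxa

    m <- sample(seq(m_range[1], m_range[2]), n, replace = TRUE)
    N <- sum(m)
    cluster <- rep(sprintf("P%03d", seq_len(n)), times = m)
    age <- rep(round(runif(n, age_range[1], age_range[2]), 1), times = m)
    if (exposure_mode == "within_cluster") {
      Tr <- rbinom(N, 1, 0.5)
      state <- c("baseline", "exacerbation")[Tr + 1]
      aggr <- rep(NA_character_, N)
    } else {
      Tcl <- rbinom(n, 1, 0.5)
      Tr <- rep(Tcl, times = m)
      state <- rep("baseline", N)
      aggr <- c("mild", "moderate_severe")[Tr + 1]
    }

    sample_id <- sprintf("S%04d", seq_len(N))
    if (H > 0) {
      b0 <- rnorm(H, 0, 1)                                 # genus baselines
      u <- matrix(rnorm(n * H, 0, sqrt(psi_med)), n, H)    # mediator RIs
      lat <- matrix(b0, N, H, byrow = TRUE) +
        outer(Tr, delta_full) + u[rep(seq_len(n), times = m), ] +
        matrix(rnorm(N * H, 0, sigma_med), N, H)
      prop <- 10^lat
      prop <- prop / rowSums(prop)
      Mlog_true <- log10(prop)
      depth <- sample(seq(depth_range[1], depth_range[2]), N, replace = TRUE)
      counts <- matrix(0L, H, N)
      for (k in seq_len(N)) {
        pk <- prop[k, ]
        if (!is.null(dirichlet_scale)) {
          g <- rgamma(H, shape = dirichlet_scale * pk)
          pk <- g / sum(g)
        }
        counts[, k] <- rmultinom(1, depth[k], pk)
      }
      dimnames(counts) <- list(taxa, sample_id)
      dimnames(Mlog_true) <- list(sample_id, taxa)
    } else {
      counts <- NULL
      Mlog_true <- matrix(numeric(0), N, 0, dimnames = list(sample_id, NULL))
    }

    gamma <- rnorm(n, 0, sqrt(psi))
    Y <- intercept + beta_T * Tr + as.vector(Mlog_true %*% beta_full) +
      age_effect * age + gamma[rep(seq_len(n), times = m)] +
      rnorm(N, 0, sigma_e)

    meta <- data.frame(sample_id = sample_id, cluster_id = cluster,
                       clinical_state = state, aggressiveness = aggr,
                       age = age, fev1_pct = Y, exposure = Tr,
                       stringsAsFactors = FALSE)
    lineage <- setNames(paste0("Bacteria;", taxa), taxa)
    indirect <- delta_full * beta_full
    list(counts = if (is.null(counts)) NULL else count_table(counts, lineage),
         metadata = meta,
         truth = list(direct = beta_T, indirect = indirect,
                      total = beta_T + sum(indirect),
                      beta_M = beta_full, delta_T = delta_full,
                      active = taxa[seq_len(s)], Mlog_true = Mlog_true,
                      intercept = intercept, age_effect = age_effect))
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}

#' Simulate a community-level single-mediator dataset
#'
#' One continuous Gaussian mediator (an alpha-diversity-like index) with a
#' cluster random intercept, and an outcome driven by the exposure, the
#' mediator, age, and an outcome random intercept. Truth satisfies
#' `total = direct + indirect` exactly with `indirect = delta_T * beta_M`.
#'
#' @param n,m_range clusters and cluster-size range.
#' @param delta_T exposure effect on the mediator.
#' @param beta_M mediator effect on the outcome.
#' @param beta_T direct exposure effect on the outcome.
#' @param psi,sigma_e outcome random-intercept variance and residual SD.
#' @param psi_med,sigma_med mediator variance components.
#' @param intercept,med_intercept outcome and mediator grand intercepts.
#' @param age_effect covariate coefficient for age.
#' @param age_range patient age range.
#' @param seed optional integer seed.
#' @return `list(frame, truth)` where `frame` is a ready [study_frame()] with
#'   a single mediator column `diversity`.
#' @export
simulate_community_data <- function(n = 40, m_range = c(2, 10), delta_T = 1,
                                    beta_M = -2, beta_T = -3, psi = 4,
                                    sigma_e = 2, psi_med = 0.25,
                                    sigma_med = 0.5, intercept = 58,
                                    med_intercept = 3, age_effect = 0,
                                    age_range = c(6, 54), seed = NULL) {
  gen <- function() {
    m <- sample(seq(m_range[1], m_range[2]), n, replace = TRUE)
    N <- sum(m)
    idx <- rep(seq_len(n), times = m)
    cluster <- sprintf("P%03d", idx)
    age <- round(runif(n, age_range[1], age_range[2]), 1)[idx]
    Tr <- rbinom(N, 1, 0.5)
    med <- med_intercept + delta_T * Tr + rnorm(n, 0, sqrt(psi_med))[idx] +
      rnorm(N, 0, sigma_med)
    Y <- intercept + beta_T * Tr + beta_M * med + age_effect * age +
      rnorm(n, 0, sqrt(psi))[idx] + rnorm(N, 0, sigma_e)
    frame <- study_frame(Y = Y, Tr = Tr,
                         M = matrix(med, ncol = 1,
                                    dimnames = list(NULL, "diversity")),
                         cluster = cluster, C = cbind(age = age),
                         contrast = list(exposure = "clinical_state",
                                         ref = "baseline",
                                         comparison = "exacerbation"))
    list(frame = frame,
         truth = list(direct = beta_T, indirect = c(diversity = delta_T * beta_M),
                      total = beta_T + delta_T * beta_M,
                      delta_T = delta_T, beta_M = beta_M))
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}
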