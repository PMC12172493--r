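#' Assemble a study frame for one pairwise contrast
#'
#' Restricts the samples to the two requested exposure levels, codes the
#' comparison level as `T = 1` and the reference as `T = 0`, and bundles the
#' outcome, covariates, mediator matrix, and cluster labels into the unit all
#' models consume. Clusters left with zero samples are dropped; clusters
#' reduced to a single sample are retained (the random intercept absorbs
#' them — the single-sample patient exclusion happens once, during
#' preprocessing).
#'
#' @param meta metadata data.frame (see [read_sample_metadata()]); rows must
#'   cover the rows of `mediators`.
#' @param mediators numeric matrix, samples x mediators, with sample ids as
#'   rownames — the output of [lognorm_transform()], or a one-column matrix of
#'   an alpha-diversity index for community mode.
#' @param exposure `"clinical_state"` or `"aggressiveness"`.
#' @param ref,comparison the reference and comparison levels; must differ and
#'   both be present.
#' @param outcome metadata column holding the response (default `fev1_pct`).
#' @param covariates metadata columns entering as adjustment covariates
#'   (default `"age"`); may be `NULL` or empty for an unadjusted model.
#' @return Object of class `study_frame`: `Y`, `Tr` (0/1 exposure), `C`
#'   (covariate matrix or `NULL`), `M` (mediator matrix), `cluster` (character),
#'   `sample_id`, and the contrast description.
#' @export
subset_contrast <- function(meta, mediators,
                            exposure = c("clinical_state", "aggressiveness"),
                            ref, comparison, outcome = "fev1_pct",
                            covariates = "age") {
  exposure <- match.arg(exposure)
  if (identical(ref, comparison)) stop("contrast levels must differ")
  if (!exposure %in% names(meta) || all(is.na(meta[[exposure]])))
    stop("metadata has no usable '", exposure, "' column")
  lev <- as.character(meta[[exposure]])
  for (l in c(ref, comparison))
    if (!any(lev == l, na.rm = TRUE)) stop("no samples with ", exposure, " = '", l, "'")
  keep <- !is.na(lev) & lev %in% c(ref, comparison)
  meta <- meta[keep, , drop = FALSE]
  mediators <- as.matrix(mediators)
  if (is.null(rownames(mediators))) stop("mediator matrix needs sample rownames")
  missing_m <- setdiff(meta$sample_id, rownames(mediators))
  if (length(missing_m))
    stop("mediator matrix lacks sample(s): ", paste(missing_m, collapse = ", "))
  M <- mediators[meta$sample_id, , drop = FALSE]
  if (anyNA(M)) stop("mediator matrix contains missing values")
  Tr <- as.integer(as.character(meta[[exposure]]) == comparison)
  C <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(meta))
    if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    C <- as.matrix(meta[, covariates, drop = FALSE])
    if (anyNA(C)) stop("missing covariate values")
  }
  study_frame(Y = meta[[outcome]], Tr = Tr, M = M, cluster = meta$cluster_id,
              C = C, sample_id = meta$sample_id,
              contrast = list(exposure = exposure, ref = ref,
                              comparison = comparison))
}

#' Construct a study frame directly
#'
#' Lower-level constructor used by [subset_contrast()] and the simulators.
#'
#' @param Y outcome vector, length N.
#' @param Tr binary 0/1 exposure, length N.
#' @param M mediator matrix, N x H.
#' @param cluster cluster labels, length N.
#' @param C covariate matrix (N x c) or `NULL`.
#' @param sample_id optional sample identifiers.
#' @param contrast optional contrast description list.
#' @return object of class `study_frame`.
#' @export
study_frame <- function(Y, Tr, M, cluster, C = NULL, sample_id = NULL,
                        contrast = NULL) {
  M <- as.matrix(M)
  N <- length(Y)
  stopifnot(length(Tr) == N, nrow(M) == N, length(cluster) == N)
  if (!all(Tr %in% c(0, 1))) stop("exposure must be coded 0/1")
  if (anyNA(Y) || anyNA(M)) stop("study frame cannot contain missing values")
  if (!is.null(C)) {
    C <- as.matrix(C)
    stopifnot(nrow(C) == N)
  }
  if (ncol(M) > 0 && is.null(colnames(M)))
    colnames(M) <- paste0("M", seq_len(ncol(M)))
  structure(list(Y = as.numeric(Y), Tr = as.integer(Tr), M = M,
                 C = C, cluster = as.character(cluster),
                 sample_id = sample_id %||% as.character(seq_len(N)),
                 contrast = contrast),
            class = "study_frame")
}

#' @export
print.study_frame <- function(x, ...) {
  cat(sprintf("study_frame: N = %d samples, %d clusters, %d mediator(s)\n",
              length(x$Y), length(unique(x$cluster)), ncol(x$M)))
  if (!is.null(x$contrast))
    cat(sprintf("  contrast: %s  %s (T=0) vs %s (T=1)\n", x$contrast$exposure,
                x$contrast$ref, x$contrast$comparison))
  cat(sprintf("  exposure split: %d / %d\n", sum(x$Tr == 0), sum(x$Tr == 1)))
  invisible(x)
}

contrast_label <- function(frame) {
  if (is.null(frame$contrast)) return("contrast")
  paste0(frame$contrast$ref, "-", frame$contrast$comparison)
}

# Subset a frame to a set of clusters (used by the bootstrap and jackknife);
# `new_labels` relabels the drawn clusters so duplicates stay distinct.
frame_take_clusters <- function(frame, clusters, new_labels = NULL) {
  idx_by <- split(seq_along(frame$cluster), frame$cluster)
  rows <- unlist(idx_by[clusters], use.names = FALSE)
  labels <- if (is.null(new_labels)) clusters else new_labels
  cl <- rep(labels, times = lengths(idx_by[clusters]))
  study_frame(Y = frame$Y[rows], Tr = frame$Tr[rows],
              M = frame$M[rows, , drop = FALSE], cluster = cl,
              C = if (is.null(frame$C)) NULL else frame$C[rows, , drop = FALSE],
              sample_id = frame$sample_id[rows], contrast = frame$contrast)
}
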