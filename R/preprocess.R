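#' Remove taxa from excluded domains
#'
#' Drops taxa whose domain rank (Archaea and Eukarya by default) is on the
#' exclusion list. Taxa whose domain cannot be parsed from the lineage are
#' retained — a conservative choice — and logged.
#'
#' @param ct a [count_table()] with lineage information.
#' @param excluded character vector of domain names to drop.
#' @return filtered [count_table()].
#' @export
exclude_domains <- function(ct, excluded = c("Archaea", "Eukarya")) {
  if (!length(excluded)) return(ct)
  dom <- lineage_rank(ct, "domain")
  unknown <- !nzchar(dom)
  if (any(unknown))
    msg_log("warn", sum(unknown), " taxa with unparseable domain rank retained")
  keep <- unknown | !(dom %in% excluded)
  if (sum(!keep))
    msg_log("info", "exclude_domains: dropped ", sum(!keep), " of ", length(keep), " taxa")
  ct_subset(ct, taxa = which(keep))
}

#' Aggregate counts to genus level
#'
#' Counts of taxa sharing a genus are summed; taxa with an empty genus rank are
#' pooled into `"unclassified"`. Per-sample depths are preserved exactly. The
#' aggregated lineage keeps the domain of the first contributing taxon so a
#' second pass through the preprocessing chain is a no-op.
#'
#' @param ct a [count_table()] with lineage information.
#' @return genus-level [count_table()] (rownames are genus names).
#' @export
aggregate_genus <- function(ct) {
  genus <- lineage_rank(ct, "genus")
  genus[!nzchar(genus)] <- "unclassified"
  dom <- lineage_rank(ct, "domain")
  counts <- rowsum(ct$counts, group = genus, reorder = FALSE)
  first <- !duplicated(genus)
  lineage <- paste(dom[first], genus[first], sep = ";")
  names(lineage) <- genus[first]
  count_table(counts, lineage[rownames(counts)])
}

#' Drop low-depth samples
#'
#' Removes samples whose total read count is below `min_reads`
#' (a depth of exactly `min_reads` is retained).
#'
#' @param ct a [count_table()].
#' @param min_reads minimum sample depth, default 1000.
#' @return filtered [count_table()].
#' @export
filter_sample_depth <- function(ct, min_reads = 1000) {
  stopifnot(min_reads >= 1)
  depth <- colSums(ct$counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop("all samples fall below the ", min_reads, "-read depth threshold")
  if (any(!keep))
    msg_log("info", "filter_sample_depth: dropped ", sum(!keep), " sample(s) with < ",
            min_reads, " reads")
  ct_subset(ct, samples = which(keep))
}

#' Prevalence filter
#'
#' Keeps a taxon when the fraction of samples in which its count strictly
#' exceeds `min_count` is at least `min_fraction` (defaults: over 3 counts in
#' at least 5\% of samples).
#'
#' @param ct a [count_table()].
#' @param min_count count threshold (strict inequality), default 3.
#' @param min_fraction minimum fraction of qualifying samples, default 0.05.
#' @return filtered [count_table()].
#' @export
prevalence_filter <- function(ct, min_count = 3, min_fraction = 0.05) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(ct$counts > min_count)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("prevalence filter removed every taxon")
  if (any(!keep))
    msg_log("info", "prevalence_filter: dropped ", sum(!keep), " of ", length(keep), " taxa")
  ct_subset(ct, taxa = which(keep))
}

#' Exclude patients with a single sample
#'
#' Repeated-measures models need at least two observations per cluster to
#' separate the random intercept from noise, so clusters of size one are
#' removed once, before any contrast subsetting.
#'
#' @param meta metadata data.frame.
#' @return filtered metadata.
#' @export
drop_singleton_clusters <- function(meta) {
  sizes <- table(meta$cluster_id)
  singletons <- names(sizes)[sizes == 1]
  if (length(singletons) == length(sizes))
    stop("every cluster has a single sample; nothing left to model")
  if (length(singletons))
    msg_log("info", "drop_singleton_clusters: dropped ", length(singletons),
            " patient(s) with a single sample")
  meta[!(meta$cluster_id %in% singletons), , drop = FALSE]
}

#' Log-proportion transform of a count table
#'
#' The mediator transform: for count \eqn{M_{kt}} of taxon \eqn{t} in sample
#' \eqn{k} with depth \eqn{D_k = \sum_t M_{kt}},
#' \deqn{M^{log}_{kt} = \log_{10}\{(M_{kt} + 0.5) / D_k\}.}
#' The 0.5 pseudo-count keeps zeros finite. `pseudo = "proportion"` instead
#' adds 0.5 to the proportion itself, \eqn{\log_{10}(M_{kt}/D_k + 0.5)} — an
#' alternative reading of the same recipe, exposed for sensitivity analysis.
#'
#' @param ct a [count_table()]; every sample must have depth > 0.
#' @param pseudo where the 0.5 pseudo-count enters; default `"count"`.
#' @return numeric matrix, samples x taxa (note the transpose relative to the
#'   count table: rows are now observations, ready to enter a model design).
#' @export
lognorm_transform <- function(ct, pseudo = c("count", "proportion")) {
  pseudo <- match.arg(pseudo)
  depth <- colSums(ct$counts)
  if (any(depth <= 0))
    stop("zero-depth sample(s): ",
         paste(colnames(ct$counts)[depth <= 0], collapse = ", "))
  m <- if (pseudo == "count") {
    log10(sweep(ct$counts + 0.5, 2, depth, "/"))
  } else {
    log10(sweep(ct$counts, 2, depth, "/") + 0.5)
  }
  t(m)
}

#' Genus-level alpha diversity
#'
#' Non-phylogenetic within-sample diversity, computed on counts:
#' observed richness (number of taxa with count > 0), Shannon
#' \eqn{-\sum p \ln p} (natural log), and Gini-Simpson \eqn{1 - \sum p^2}.
#' Shannon and Simpson are delegated to \pkg{vegan}.
#'
#' @param ct a [count_table()], typically genus-aggregated.
#' @param index one of `"observed"`, `"shannon"`, `"simpson"`.
#' @param inverse_simpson return inverse Simpson \eqn{1/\sum p^2} instead of
#'   the Gini-Simpson form.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(ct, index = c("observed", "shannon", "simpson"),
                            inverse_simpson = FALSE) {
  index <- match.arg(index)
  depth <- colSums(ct$counts)
  if (any(depth <= 0))
    stop("zero-depth sample(s): ",
         paste(colnames(ct$counts)[depth <= 0], collapse = ", "))
  x <- t(ct$counts)  # vegan convention: sites x species
  switch(index,
    observed = vegan::specnumber(x),
    shannon  = vegan::diversity(x, index = "shannon"),
    simpson  = if (inverse_simpson) vegan::diversity(x, index = "invsimpson")
               else vegan::diversity(x, index = "simpson"))
}

#' Run the full count-table preprocessing chain
#'
#' Fixed order: align samples with metadata, exclude Archaea/Eukarya,
#' aggregate to genus, drop samples under `min_reads`, apply the prevalence
#' filter, then drop single-sample patients. Taxa are filtered on the full
#' aligned sample set before the singleton exclusion. A step-by-step filter
#' report records how many taxa and samples enter and leave each stage.
#'
#' @param ct a [count_table()].
#' @param meta metadata data.frame.
#' @param excluded domains to exclude.
#' @param min_reads sample depth threshold.
#' @param min_count,min_fraction prevalence filter parameters.
#' @param drop_singletons apply the single-sample patient exclusion.
#' @return `list(counts, metadata, report)` where `report` is a data.frame
#'   with columns `step, n_taxa_in, n_taxa_out, n_samples_in, n_samples_out`.
#' @export
preprocess_counts <- function(ct, meta, excluded = c("Archaea", "Eukarya"),
                              min_reads = 1000, min_count = 3,
                              min_fraction = 0.05, drop_singletons = TRUE) {
  report <- list()
  note <- function(step, ct_in, ct_out) {
    report[[length(report) + 1L]] <<- data.frame(
      step = step,
      n_taxa_in = nrow(ct_in$counts), n_taxa_out = nrow(ct_out$counts),
      n_samples_in = ncol(ct_in$counts), n_samples_out = ncol(ct_out$counts),
      stringsAsFactors = FALSE)
  }
  al <- align_samples(ct, meta)
  note("align", ct, al$counts)
  ct <- al$counts; meta <- al$metadata

  ct2 <- exclude_domains(ct, excluded);          note("exclude_domains", ct, ct2)
  ct3 <- aggregate_genus(ct2);                   note("aggregate_genus", ct2, ct3)
  ct4 <- filter_sample_depth(ct3, min_reads);    note("filter_sample_depth", ct3, ct4)
  meta <- meta[colnames(ct4$counts), , drop = FALSE]
  ct5 <- prevalence_filter(ct4, min_count, min_fraction)
  note("prevalence_filter", ct4, ct5)
  if (drop_singletons) {
    meta2 <- drop_singleton_clusters(meta)
    ct6 <- ct_subset(ct5, samples = meta2$sample_id)
    note("drop_singleton_clusters", ct5, ct6)
    meta <- meta2; ct5 <- ct6
  }
  list(counts = ct5, metadata = meta,
       report = do.call(rbind, report))
}

#' Write a preprocessing filter report as TSV
#' @param report the `report` element of [preprocess_counts()] output.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
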