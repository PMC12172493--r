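#' Construct a taxon-by-sample count table
#'
#' The basic container for raw sequencing counts: an integer matrix with taxa
#' as rows and samples as columns, plus one taxonomic lineage string per taxon
#' (semicolon-separated ranks, e.g. `"Bacteria;Firmicutes;...;Streptococcus"`;
#' greengenes-style `d__`/`g__` prefixes are understood).
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples, with
#'   unique rownames (taxon ids) and colnames (sample ids).
#' @param lineage character vector of lineage strings, one per taxon, in row
#'   order (or named by taxon id). May be `NULL` when taxonomy is not needed.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `lineage` (character vector named by taxon id).
#' @seealso [read_count_table()], [aggregate_genus()], [lognorm_transform()]
#' @export
count_table <- function(counts, lineage = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!all(is.finite(counts)))
    stop("non-finite count in cell ", bad_cell(counts, !is.finite(counts)))
  if (any(counts < 0))
    stop("negative count in cell ", bad_cell(counts, counts < 0))
  if (any(counts != round(counts)))
    stop("non-integer count in cell ", bad_cell(counts, counts != round(counts)))
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  if (!is.null(lineage)) {
    if (!is.null(names(lineage))) {
      if (!all(rownames(counts) %in% names(lineage)))
        stop("lineage is missing entries for some taxa")
      lineage <- lineage[rownames(counts)]
    } else {
      if (length(lineage) != nrow(counts))
        stop("lineage length (", length(lineage), ") != number of taxa (",
             nrow(counts), ")")
      names(lineage) <- rownames(counts)
    }
    lineage <- as.character(lineage)
    names(lineage) <- rownames(counts)
  }
  structure(list(counts = counts, lineage = lineage), class = "count_table")
}

bad_cell <- function(m, idx) {
  w <- which(idx, arr.ind = TRUE)[1, ]
  sprintf("(%s, %s)", rownames(m)[w[1]] %||% w[1], colnames(m)[w[2]] %||% w[2])
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (total reads %.0f)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  if (!is.null(x$lineage)) cat("taxonomy: present\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

# Extract one taxonomic rank from the lineage strings.
# Prefixed lineages ("d__Bacteria;...;g__Gemella") are matched by prefix
# (k__ treated as domain); plain ordered lineages positionally, with domain
# the first rank and genus the sixth (or the last rank when fewer are given).
lineage_rank <- function(ct, rank = c("domain", "genus")) {
  rank <- match.arg(rank)
  lin <- ct$lineage
  if (is.null(lin)) stop("count table has no lineage information")
  # sentinel keeps trailing empty ranks ("Bacteria;" = empty genus)
  parts <- lapply(strsplit(paste0(lin, ";\x01"), ";", fixed = TRUE),
                  function(p) p[-length(p)])
  vapply(parts, function(p) {
    p <- trimws(p)
    pref <- grepl("^[a-z]__", p)
    if (any(pref)) {
      key <- if (rank == "domain") c("d__", "k__") else "g__"
      hit <- p[substr(p, 1, 3) %in% key]
      if (!length(hit)) return("")
      return(sub("^[a-z]__", "", hit[1]))
    }
    if (rank == "domain") return(if (length(p)) p[1] else "")
    if (length(p) >= 6) p[6] else p[length(p)]
  }, character(1))
}

# Subset helper keeping counts and lineage in step.
ct_subset <- function(ct, taxa = NULL, samples = NULL) {
  counts <- ct$counts
  if (!is.null(taxa)) counts <- counts[taxa, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  lin <- if (is.null(ct$lineage)) NULL else ct$lineage[rownames(counts)]
  structure(list(counts = counts, lineage = lin), class = "count_table")
}
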