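#' Read a taxon-by-sample count table
#'
#' TSV dialect: taxa as rows, first column the taxon id, remaining columns one
#' per sample, optional last column `lineage` holding semicolon-separated
#' taxonomic ranks. BIOM input (JSON flavour) is parsed with the biomformat
#' package when installed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose set `TRUE` when the TSV stores samples as rows.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    lineage <- NULL
    if (is.data.frame(om) && ncol(om) > 0)
      lineage <- apply(om, 1, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
    return(count_table(counts, lineage))
  }
  # header check first: duplicated sample columns would otherwise be renamed
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr[-1]))
    stop("duplicate sample id in header: ",
         paste(unique(hdr[-1][duplicated(hdr[-1])]), collapse = ", "))
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]]))
    stop("duplicate taxon id: ", paste(unique(d[[1]][duplicated(d[[1]])]), collapse = ", "))
  lineage <- NULL
  lin_col <- which(tolower(names(d)) == "lineage")
  if (length(lin_col)) {
    lineage <- as.character(d[[lin_col[1]]])
    d <- d[, -lin_col, drop = FALSE]
  }
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- as.character(d[[1]])
  if (transpose) counts <- t(counts)
  if (!is.null(lineage) && !transpose) names(lineage) <- rownames(counts)
  if (transpose) lineage <- NULL  # lineage column is per-row; meaningless transposed
  count_table(counts, lineage)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]'s TSV dialect; round-trips counts exactly.
#'
#' @param ct a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(ct, path) {
  d <- data.frame(taxon_id = rownames(ct$counts), ct$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(ct$lineage)) d$lineage <- unname(ct$lineage)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical metadata
#'
#' Expects a CSV or TSV (sniffed from the header line) with required columns
#' `sample_id`, `cluster_id`, `clinical_state`, `age`, `fev1_pct` and optional
#' `aggressiveness`. Clinical states must be one of baseline, exacerbation,
#' treatment, recovery; aggressiveness one of mild, moderate_severe
#' (`"moderate/severe"` is accepted as an alias). Labels are normalized
#' case-insensitively. Rows with non-positive `age` or `fev1_pct`, or missing
#' values in required columns, are a hard error — no imputation is attempted.
#'
#' @param path file path.
#' @return A `data.frame`, one row per sample, with factor columns for the
#'   categorical variables and `sample_id` as row names.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- read.delim(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_metadata(d)
}

#' Validate and normalize a metadata data frame
#'
#' The same checks [read_sample_metadata()] applies, usable on in-memory data
#' (e.g. output of [simulate_mediation_data()]).
#'
#' @param d data.frame with the columns documented in [read_sample_metadata()].
#' @return the normalized data.frame.
#' @export
validate_metadata <- function(d) {
  required <- c("sample_id", "cluster_id", "clinical_state", "age", "fev1_pct")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  for (col in c("age", "fev1_pct")) {
    v <- d[[col]]
    if (any(is.na(v))) stop("missing ", col, " for sample(s): ",
                            paste(d$sample_id[is.na(v)], collapse = ", "))
    if (any(v <= 0)) stop(col, " must be > 0; offending sample(s): ",
                          paste(d$sample_id[v <= 0], collapse = ", "))
  }
  st <- normalize_levels(d$clinical_state, clinical_states(), "clinical_state")
  d$clinical_state <- factor(st, levels = clinical_states())
  if ("aggressiveness" %in% names(d) && !all(is.na(d$aggressiveness))) {
    ag <- tolower(trimws(as.character(d$aggressiveness)))
    ag[ag == "moderate/severe"] <- "moderate_severe"
    ag <- normalize_levels(ag, aggressiveness_levels(), "aggressiveness")
    d$aggressiveness <- factor(ag, levels = aggressiveness_levels())
  }
  d$sample_id <- as.character(d$sample_id)
  d$cluster_id <- as.character(d$cluster_id)
  rownames(d) <- d$sample_id
  d
}

clinical_states <- function() c("baseline", "exacerbation", "treatment", "recovery")
aggressiveness_levels <- function() c("mild", "moderate_severe")

normalize_levels <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop("unknown ", what, " label(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' Align a count table and metadata on shared samples
#'
#' Both objects are restricted to the intersection of their sample ids, in the
#' count table's order; dropped samples are logged. An empty intersection is a
#' hard error.
#'
#' @param ct a [count_table()].
#' @param meta metadata data.frame (see [read_sample_metadata()]).
#' @return `list(counts = , metadata = )`, both covering the same samples in
#'   the same order.
#' @export
align_samples <- function(ct, meta) {
  shared <- intersect(colnames(ct$counts), meta$sample_id)
  if (!length(shared))
    stop("no samples shared between count table and metadata")
  drop_ct <- setdiff(colnames(ct$counts), shared)
  drop_meta <- setdiff(meta$sample_id, shared)
  if (length(drop_ct))
    msg_log("warn", length(drop_ct), " count-table sample(s) lack metadata and were dropped")
  if (length(drop_meta))
    msg_log("warn", length(drop_meta), " metadata sample(s) lack counts and were dropped")
  list(counts = ct_subset(ct, samples = shared),
       metadata = meta[shared, , drop = FALSE])
}

#' Write a mediation effect table as TSV
#'
#' Fixed column order `contrast, effect_type, mediator, estimate, ci_lower,
#' ci_upper, p_value, p_adjusted`; numeric columns at 6 significant digits.
#'
#' @param effects data.frame as returned in `$effects` of a [medilmm()] fit.
#' @param path output path.
#' @export
write_effect_table <- function(effects, path) {
  cols <- c("contrast", "effect_type", "mediator", "estimate",
            "ci_lower", "ci_upper", "p_value", "p_adjusted")
  missing <- setdiff(cols, names(effects))
  if (length(missing)) stop("effect table lacks column(s): ", paste(missing, collapse = ", "))
  out <- effects[, cols, drop = FALSE]
  for (col in c("estimate", "ci_lower", "ci_upper", "p_value", "p_adjusted"))
    out[[col]] <- signif(out[[col]], 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an effect table written by [write_effect_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_effect_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
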