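## Feature-table, metadata and taxonomy I/O and transforms.
##
## A feature table is a plain integer matrix, taxa in rows and samples in
## columns, with unique dimnames. Sample metadata is a data.frame keyed by
## `sample_id`; taxonomy a data.frame with `taxon_id` and `lineage`
## (semicolon-separated ranks, domain first). Plain base objects keep the
## fixtures human-diffable and the functions composable.

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

SAMPLE_ROLES <- c("specimen", "negative_control")

#' Validate a feature table
#'
#' Checks the invariants every downstream stage relies on: a numeric matrix
#' of non-negative integers with unique, non-missing taxon row names and
#' sample column names.
#'
#' @param counts Matrix of read counts, taxa x samples.
#' @return The validated matrix (storage mode integer), invisibly usable as
#'   a feature table.
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("feature table must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("feature table must have taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate taxon ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid count at taxon '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a feature table
#'
#' TSV dialect: first column taxon id, header row sample ids. BIOM files are
#' read through the biomformat package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return Validated integer matrix, taxa x samples.
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(validate_feature_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed feature table header in ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric counts in ", path)
  }
  rownames(m) <- ids
  validate_feature_table(m)
}

#' Write a feature table
#'
#' @param counts Feature table matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  counts <- validate_feature_table(counts)
  if (format == "biom") {
    biomformat::write_biom(biomformat::make_biom(counts), path)
    return(invisible(path))
  }
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata against a feature table
#'
#' @param metadata Data frame with at least `sample_id`, `role` and
#'   `replicate` columns; `role` must be `"specimen"` or
#'   `"negative_control"`.
#' @param counts Optional feature table; when given, every sample column
#'   must have exactly one metadata row.
#' @return The metadata with rownames set to `sample_id`.
#' @export
validate_sample_metadata <- function(metadata, counts = NULL) {
  need <- c("sample_id", "role", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample ids in metadata")
  }
  bad <- setdiff(unique(metadata$role), SAMPLE_ROLES)
  if (length(bad) > 0) {
    stop("unknown role value(s): ", paste(bad, collapse = ", "))
  }
  rownames(metadata) <- metadata$sample_id
  if (!is.null(counts)) {
    missing_meta <- setdiff(colnames(counts), metadata$sample_id)
    if (length(missing_meta) > 0) {
      stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
    }
  }
  metadata
}

#' Read sample metadata (TSV, first column sample id)
#' @param path Path to the TSV file.
#' @return Validated metadata data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  validate_sample_metadata(df)
}

#' Write sample metadata as TSV
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (TSV: taxon id + semicolon-separated lineage)
#'
#' Lineages are ordered domain downward and may be truncated at any rank.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `taxon_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("taxon_id", "lineage")
  df$taxon_id <- as.character(df$taxon_id)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in taxonomy")
  df
}

#' Write a taxonomy table as TSV
#' @param taxonomy Taxonomy data frame (`taxon_id`, `lineage`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("taxon_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Split lineages into a taxon x rank character matrix (NA where truncated).
lineage_ranks <- function(taxonomy) {
  parts <- strsplit(taxonomy$lineage, ";", fixed = TRUE)
  m <- matrix(NA_character_, nrow = nrow(taxonomy),
              ncol = length(TAXONOMIC_RANKS),
              dimnames = list(taxonomy$taxon_id, TAXONOMIC_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    k <- min(length(p), length(TAXONOMIC_RANKS))
    if (k > 0) m[i, seq_len(k)] <- p[seq_len(k)]
  }
  m
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total so columns sum to one.
#' Zero-total samples are an error unless `drop_empty = TRUE`, because every
#' downstream diversity formula is undefined on them.
#'
#' @param counts Feature table matrix.
#' @param drop_empty Drop zero-total sample columns instead of erroring.
#' @return Numeric matrix of proportions, same shape (minus dropped
#'   samples).
#' @export
relative_abundance <- function(counts, drop_empty = FALSE) {
  counts <- validate_feature_table(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    empty <- colnames(counts)[totals == 0]
    if (!drop_empty) {
      stop("zero-total sample(s): ", paste(empty, collapse = ", "),
           " (use drop_empty = TRUE to discard them)")
    }
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(counts, 2, totals, "/")
}

#' Remove taxa whose lineage matches any exclusion term
#'
#' Matching is a case-insensitive substring test against the full lineage
#' string, the operation used to strip host-derived mitochondrial and
#' chloroplast ASVs before analysis. Samples are never dropped.
#'
#' @param counts Feature table matrix.
#' @param taxonomy Taxonomy data frame.
#' @param exclude_terms Non-empty character vector of lineage substrings.
#' @return Filtered feature table; the number of removed taxa is attached as
#'   attribute `n_removed`.
#' @export
filter_taxa_by_lineage <- function(counts, taxonomy, exclude_terms) {
  counts <- validate_feature_table(counts)
  if (length(exclude_terms) == 0) stop("exclude_terms must be non-empty")
  lin <- taxonomy$lineage[match(rownames(counts), taxonomy$taxon_id)]
  lin[is.na(lin)] <- ""
  hit <- rep(FALSE, nrow(counts))
  for (term in exclude_terms) {
    hit <- hit | grepl(term, lin, ignore.case = TRUE, fixed = FALSE)
  }
  if (all(hit)) warning("all taxa matched the exclusion terms")
  message(sum(hit), " taxa removed by lineage filter")
  out <- counts[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Aggregate a feature table at a taxonomic rank
#'
#' Rows are summed by their label at `rank`. Taxa unannotated at that rank
#' are grouped under their deepest available label rather than dropped, so
#' per-sample totals are conserved exactly.
#'
#' @param counts Feature table matrix.
#' @param taxonomy Taxonomy data frame.
#' @param rank One of `r paste(TAXONOMIC_RANKS, collapse = ", ")`.
#' @return Aggregated feature table (labels as row names).
#' @export
aggregate_by_rank <- function(counts, taxonomy, rank = "genus") {
  counts <- validate_feature_table(counts)
  if (!rank %in% TAXONOMIC_RANKS) {
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  }
  ranks <- lineage_ranks(taxonomy)
  ranks <- ranks[match(rownames(counts), rownames(ranks)), , drop = FALSE]
  k <- match(rank, TAXONOMIC_RANKS)
  label <- ranks[, k]
  for (j in rev(seq_len(k - 1))) {       # deepest-available-rank fallback
    fill <- is.na(label) & !is.na(ranks[, j])
    label[fill] <- ranks[fill, j]
  }
  label[is.na(label)] <- "Unclassified"
  agg <- rowsum(counts, group = label, reorder = TRUE)
  validate_feature_table(as.matrix(agg))
}

#' Subset samples by a metadata predicate
#'
#' The predicate is an unevaluated expression over metadata columns, as in
#' [base::subset()]. With `keep_controls = TRUE` every negative control is
#' retained regardless of the predicate (controls-first reporting).
#'
#' @param counts Feature table matrix.
#' @param metadata Sample metadata.
#' @param predicate Logical expression on metadata fields, e.g.
#'   `treatment == "control"`.
#' @param keep_controls Always retain negative controls.
#' @return Feature table restricted to the selected samples.
#' @export
subset_samples <- function(counts, metadata, predicate, keep_controls = FALSE) {
  counts <- validate_feature_table(counts)
  metadata <- validate_sample_metadata(metadata, counts)
  expr <- substitute(predicate)
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(metadata))
  if (length(unknown) > 0) {
    stop("predicate references unknown metadata field(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- eval(expr, metadata, parent.frame())
  keep <- !is.na(keep) & keep
  ids <- metadata$sample_id[keep]
  if (keep_controls) {
    ids <- union(ids, metadata$sample_id[metadata$role == "negative_control"])
  }
  ids <- intersect(colnames(counts), ids)   # preserve column order
  meta_sel <- metadata[ids, ]
  if (!any(meta_sel$role == "specimen")) {
    stop("predicate selects zero specimens: ", deparse(expr))
  }
  counts[, ids, drop = FALSE]
}
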