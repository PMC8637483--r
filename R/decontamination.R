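## Contaminant classification against extraction negative controls.
##
## Two classifiers are provided. The major-contaminant rule flags a taxon
## when it is (i) present in at least `prevalence_threshold` of specimens
## and (ii) on average strictly more abundant in the negative controls than
## in the specimens. The prevalence rule is the simplified
## presence/absence comparison used as the reference method: a taxon is a
## contaminant when its presence fraction among controls outweighs its
## presence fraction among specimens.

split_roles <- function(counts, metadata) {
  metadata <- validate_sample_metadata(metadata, counts)
  meta <- metadata[colnames(counts), ]
  spec <- colnames(counts)[meta$role == "specimen"]
  ctrl <- colnames(counts)[meta$role == "negative_control"]
  if (length(ctrl) == 0) {
    stop("no negative controls: control-based classification is undefined")
  }
  if (length(spec) == 0) stop("no specimen samples")
  list(specimens = spec, controls = ctrl)
}

new_contaminant_report <- function(df, method, mode, threshold) {
  df <- df[order(-df$mean_abund_controls, df$taxon_id), ]
  rownames(df) <- NULL
  structure(df, class = c("contaminant_report", "data.frame"),
            method = method, mode = mode, threshold = threshold)
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat("Contaminant report (", attr(x, "method"), ", mode = ",
      attr(x, "mode") %||% "presence", ", threshold = ",
      attr(x, "threshold"), "): ", sum(x$flag), " of ", nrow(x),
      " taxa flagged\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify major contaminants against negative controls
#'
#' A taxon is flagged as a major contaminant when both hold:
#' \enumerate{
#'   \item it is present (count > 0) in at least `prevalence_threshold` of
#'     the specimen samples (strictly more with `strict_prevalence`);
#'   \item its mean abundance over the negative controls is strictly higher
#'     than its mean abundance over the specimens, with zeros included in
#'     both means.
#' }
#' Abundance is relative abundance per sample (`mode = "relative"`, the
#' default) or raw read counts (`mode = "raw"`). With comparable library
#' sizes across samples and controls the two modes agree.
#'
#' @param counts Feature table matrix (raw integer counts).
#' @param metadata Sample metadata with `role`.
#' @param mode `"relative"` or `"raw"`.
#' @param prevalence_threshold Fraction of specimens a contaminant must be
#'   present in (default 0.8).
#' @param strict_prevalence Use a strict `>` comparison on prevalence
#'   instead of the default inclusive `>=`.
#' @param include_controls_in_prevalence Compute prevalence over all samples
#'   (specimens + controls) rather than specimens only.
#' @return A `contaminant_report` data frame (one row per taxon, sorted by
#'   mean control abundance, descending) with columns `taxon_id`,
#'   `prevalence_specimens`, `prevalence_controls`,
#'   `mean_abund_specimens`, `mean_abund_controls`, `flag`.
#' @export
classify_major_contaminants <- function(counts, metadata,
                                        mode = c("relative", "raw"),
                                        prevalence_threshold = 0.8,
                                        strict_prevalence = FALSE,
                                        include_controls_in_prevalence = FALSE) {
  mode <- match.arg(mode)
  counts <- validate_feature_table(counts)
  roles <- split_roles(counts, metadata)
  abund <- if (mode == "relative") relative_abundance(counts) else counts
  spec_a <- abund[, roles$specimens, drop = FALSE]
  ctrl_a <- abund[, roles$controls, drop = FALSE]
  spec_c <- counts[, roles$specimens, drop = FALSE]
  ctrl_c <- counts[, roles$controls, drop = FALSE]

  prev_spec <- rowMeans(spec_c > 0)
  prev_ctrl <- rowMeans(ctrl_c > 0)
  prev <- if (include_controls_in_prevalence) {
    rowMeans(counts[, c(roles$specimens, roles$controls), drop = FALSE] > 0)
  } else {
    prev_spec
  }
  mean_spec <- rowMeans(spec_a)
  mean_ctrl <- rowMeans(ctrl_a)
  prevalent <- if (strict_prevalence) prev > prevalence_threshold else
    prev >= prevalence_threshold
  flag <- prevalent & (mean_ctrl > mean_spec)

  new_contaminant_report(
    data.frame(taxon_id = rownames(counts),
               prevalence_specimens = prev_spec,
               prevalence_controls = prev_ctrl,
               mean_abund_specimens = mean_spec,
               mean_abund_controls = mean_ctrl,
               flag = unname(flag),
               stringsAsFactors = FALSE),
    method = "major", mode = mode, threshold = prevalence_threshold)
}

#' Classify contaminants by the prevalence rule
#'
#' Presence/absence comparison between negative controls and specimens. At
#' the default threshold 0.5 a taxon is flagged iff its presence fraction
#' among controls strictly exceeds its presence fraction among specimens.
#' Other thresholds shift the decision boundary monotonically on the score
#' `control_prevalence / (control_prevalence + specimen_prevalence)`.
#'
#' @inheritParams classify_major_contaminants
#' @param threshold Decision threshold on the prevalence score (default
#'   0.5).
#' @return A `contaminant_report` data frame (see
#'   [classify_major_contaminants()]); the score column is
#'   `prevalence_score`.
#' @export
classify_prevalence_rule <- function(counts, metadata, threshold = 0.5) {
  counts <- validate_feature_table(counts)
  roles <- split_roles(counts, metadata)
  abund <- relative_abundance(counts)
  prev_spec <- rowMeans(counts[, roles$specimens, drop = FALSE] > 0)
  prev_ctrl <- rowMeans(counts[, roles$controls, drop = FALSE] > 0)
  denom <- prev_spec + prev_ctrl
  score <- ifelse(denom > 0, prev_ctrl / denom, 0)
  flag <- denom > 0 & score > threshold

  new_contaminant_report(
    data.frame(taxon_id = rownames(counts),
               prevalence_specimens = prev_spec,
               prevalence_controls = prev_ctrl,
               prevalence_score = score,
               mean_abund_specimens =
                 rowMeans(abund[, roles$specimens, drop = FALSE]),
               mean_abund_controls =
                 rowMeans(abund[, roles$controls, drop = FALSE]),
               flag = unname(flag),
               stringsAsFactors = FALSE),
    method = "prevalence_rule", mode = "presence", threshold = threshold)
}

#' Compare two contaminant classifications
#'
#' @param a,b `contaminant_report` objects over the same taxa.
#' @return List with flag counts, the intersection size, and a per-taxon
#'   agreement data frame.
#' @export
compare_classifications <- function(a, b) {
  if (!setequal(a$taxon_id, b$taxon_id)) {
    stop("reports cover different taxon sets")
  }
  b <- b[match(a$taxon_id, b$taxon_id), ]
  agreement <- data.frame(taxon_id = a$taxon_id,
                          flag_a = a$flag, flag_b = b$flag,
                          agree = a$flag == b$flag,
                          stringsAsFactors = FALSE)
  list(method_a = attr(a, "method"), method_b = attr(b, "method"),
       n_flagged_a = sum(a$flag), n_flagged_b = sum(b$flag),
       n_intersection = sum(a$flag & b$flag),
       agreement = agreement)
}

#' Remove flagged contaminant taxa from a feature table
#'
#' Flagged taxa are removed from every sample, negative controls included;
#' no sample column is ever dropped. The removed taxa and their evidence
#' rows are attached as the `removal_log` attribute.
#'
#' @param counts Feature table matrix.
#' @param report A `contaminant_report` over the table's taxa.
#' @param which Name of the logical flag column to use (default `"flag"`).
#' @return The polished feature table.
#' @export
remove_contaminants <- function(counts, report, which = "flag") {
  counts <- validate_feature_table(counts)
  if (!which %in% names(report)) {
    stop("no flag column '", which, "' in report")
  }
  flagged <- report$taxon_id[as.logical(report[[which]])]
  out <- counts[!rownames(counts) %in% flagged, , drop = FALSE]
  attr(out, "removal_log") <- report[as.logical(report[[which]]), ,
                                     drop = FALSE]
  out
}
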