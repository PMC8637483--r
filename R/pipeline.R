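## End-to-end controls-first pipeline: lineage filter, dual contaminant
## classification, removal, diversity with controls retained, proximity
## screen, planned hypothesis tests, genus-level differential abundance,
## and a JSON manifest. Every output that contains samples carries the
## role column; negative controls are never dropped at any stage.

#' Pipeline configuration
#'
#' @param counts,metadata,taxonomy In-memory inputs (see
#'   [read_feature_table()] and friends), or leave `NULL` and give paths.
#' @param counts_path,metadata_path,taxonomy_path File inputs (TSV).
#' @param out_dir Output directory (created if absent).
#' @param lineage_exclude Lineage substrings to strip before analysis
#'   (e.g. `c("Mitochondria", "Chloroplast")`); `NULL` to skip.
#' @param removal_method Which classification drives removal: `"major"`,
#'   `"prevalence"`, or `"none"` (classify and compare, remove nothing).
#' @param mode Abundance mode for the major-contaminant rule.
#' @param prevalence_threshold Major-contaminant prevalence threshold.
#' @param prevalence_rule_threshold Prevalence-rule threshold.
#' @param proximity_k Number of closest-to-control specimens to flag.
#' @param aggregate_rank Rank for differential-abundance aggregation.
#' @param diffabund_contrasts List of length-3 character vectors
#'   `c(field, level_A, level_B)`.
#' @param permanova_factors List of character vectors (1 or 2 metadata
#'   fields each; two-field entries include their interaction).
#' @param anova Two-element character vector of factors for the two-way
#'   ANOVA on the Shannon index, or `NULL`.
#' @param n_permutations PERMANOVA permutations.
#' @param seed Mandatory integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, taxonomy = NULL,
                            counts_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL,
                            out_dir,
                            lineage_exclude = NULL,
                            removal_method = c("major", "prevalence", "none"),
                            mode = c("relative", "raw"),
                            prevalence_threshold = 0.8,
                            prevalence_rule_threshold = 0.5,
                            proximity_k = 6,
                            aggregate_rank = "genus",
                            diffabund_contrasts = list(),
                            permanova_factors = list("replicate"),
                            anova = NULL,
                            n_permutations = 999,
                            seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory: permutation tests are planned")
  removal_method <- match.arg(removal_method)
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; table inputs must be
#' given as `*_path` entries.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$diffabund_contrasts)) {
    y$diffabund_contrasts <- lapply(y$diffabund_contrasts, as.character)
  }
  if (!is.null(y$permanova_factors)) {
    y$permanova_factors <- lapply(y$permanova_factors, as.character)
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the controls-first analysis pipeline
#'
#' Stages, in order: (1) optional lineage filter; (2) contaminant
#' classification by both the major-contaminant rule and the prevalence
#' rule, plus their comparison; (3) removal by the chosen method (controls
#' are never removed, flagged taxa are removed from all samples);
#' (4) alpha diversity, Bray-Curtis and PCoA with controls retained;
#' (5) specimen-to-control proximity screen; (6) planned PERMANOVA /
#' two-way ANOVA / Wilcoxon tests; (7) genus aggregation and differential
#' abundance per contrast; (8) a JSON manifest recording every parameter,
#' seed and per-stage record count.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results plus the manifest.
#'   Files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- cf$counts %||% read_feature_table(cf$counts_path)
  metadata <- cf$metadata %||% read_sample_metadata(cf$metadata_path)
  taxonomy <- cf$taxonomy %||%
    (if (!is.null(cf$taxonomy_path)) read_taxonomy(cf$taxonomy_path))
  counts <- validate_feature_table(counts)
  metadata <- validate_sample_metadata(metadata, counts)
  n_controls <- sum(metadata$role == "negative_control")
  manifest <- list(
    parameters = list(
      lineage_exclude = cf$lineage_exclude,
      removal_method = cf$removal_method, mode = cf$mode,
      prevalence_threshold = cf$prevalence_threshold,
      prevalence_rule_threshold = cf$prevalence_rule_threshold,
      proximity_k = cf$proximity_k, aggregate_rank = cf$aggregate_rank,
      n_permutations = cf$n_permutations, seed = cf$seed),
    stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  log_stage("input", n_taxa = nrow(counts), n_samples = ncol(counts),
            n_controls = n_controls)

  ## (1) lineage filter
  if (!is.null(cf$lineage_exclude)) {
    if (is.null(taxonomy)) stop("stage lineage_filter: taxonomy required")
    counts <- suppressMessages(
      filter_taxa_by_lineage(counts, taxonomy, cf$lineage_exclude))
    log_stage("lineage_filter", n_removed = attr(counts, "n_removed"),
              n_taxa = nrow(counts))
  }

  ## (2) classify with both methods, compare
  rep_major <- classify_major_contaminants(
    counts, metadata, mode = cf$mode,
    prevalence_threshold = cf$prevalence_threshold)
  rep_prev <- classify_prevalence_rule(
    counts, metadata, threshold = cf$prevalence_rule_threshold)
  comparison <- compare_classifications(rep_major, rep_prev)
  write_tsv(rep_major, file.path(cf$out_dir, "contaminant_report_major.tsv"))
  write_tsv(rep_prev,
            file.path(cf$out_dir, "contaminant_report_prevalence.tsv"))
  jsonlite::write_json(comparison[c("method_a", "method_b", "n_flagged_a",
                                    "n_flagged_b", "n_intersection")],
                       file.path(cf$out_dir, "classifier_comparison.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("classification", n_flagged_major = sum(rep_major$flag),
            n_flagged_prevalence = sum(rep_prev$flag),
            n_intersection = comparison$n_intersection)

  ## (3) removal
  polished <- switch(cf$removal_method,
    major = remove_contaminants(counts, rep_major),
    prevalence = remove_contaminants(counts, rep_prev),
    none = counts)
  write_feature_table(polished, file.path(cf$out_dir, "polished_table.tsv"))
  log_stage("removal", method = cf$removal_method,
            n_taxa_before = nrow(counts), n_taxa_after = nrow(polished),
            n_controls = n_controls)

  ## (4) diversity, controls retained
  alpha <- alpha_diversity(polished, metadata)
  write_tsv(alpha, file.path(cf$out_dir, "alpha.tsv"))
  d <- bray_curtis(polished)
  dm <- as.matrix(d)
  write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
            file.path(cf$out_dir, "bray_curtis.tsv"))
  ord <- pcoa(d)
  meta_ord <- metadata[rownames(ord$coordinates), ]
  write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                       role = meta_ord$role, ord$coordinates,
                       check.names = FALSE),
            file.path(cf$out_dir, "pcoa_coordinates.tsv"))
  write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues),
            file.path(cf$out_dir, "pcoa_eigenvalues.tsv"))
  log_stage("diversity", n_samples = nrow(alpha),
            n_controls = sum(alpha$role == "negative_control"))

  ## (5) proximity screen
  prox <- control_proximity(polished, metadata, k = cf$proximity_k)
  write_tsv(prox$per_specimen, file.path(cf$out_dir, "proximity.tsv"))
  jsonlite::write_json(prox$summary,
                       file.path(cf$out_dir, "proximity_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("proximity", n_flagged = sum(prox$per_specimen$flag))

  ## (6) planned tests
  dir.create(file.path(cf$out_dir, "tests"), showWarnings = FALSE)
  permanova_results <- list()
  for (i in seq_along(cf$permanova_factors)) {
    fac <- cf$permanova_factors[[i]]
    res <- permanova(d, metadata, fac,
                     include_interaction = length(fac) == 2,
                     n_permutations = cf$n_permutations,
                     seed = cf$seed + i)
    name <- paste(fac, collapse = "_x_")
    permanova_results[[name]] <- res
    write_tsv(res, file.path(cf$out_dir, "tests",
                             paste0("permanova_", name, ".tsv")))
  }
  anova_result <- NULL
  if (!is.null(cf$anova)) {
    spec_meta <- metadata[metadata$role == "specimen", ]
    resp <- alpha$shannon[match(spec_meta$sample_id, alpha$sample_id)]
    anova_result <- two_way_anova(resp, spec_meta, cf$anova[1], cf$anova[2])
    write_tsv(anova_result, file.path(cf$out_dir, "tests", "anova.tsv"))
  }
  log_stage("tests", n_permanova = length(permanova_results),
            anova = !is.null(anova_result))

  ## (7) genus aggregation + differential abundance
  diffabund_results <- list()
  if (length(cf$diffabund_contrasts) > 0) {
    if (is.null(taxonomy)) stop("stage diffabund: taxonomy required")
    genus_tab <- aggregate_by_rank(polished, taxonomy,
                                   rank = cf$aggregate_rank)
    dir.create(file.path(cf$out_dir, "diffabund"), showWarnings = FALSE)
    for (ct in cf$diffabund_contrasts) {
      res <- suppressMessages(
        nb_wald_diff_abundance(genus_tab, metadata, ct))
      name <- paste(ct, collapse = "_")
      diffabund_results[[name]] <- res
      write_tsv(res, file.path(cf$out_dir, "diffabund",
                               paste0(name, ".tsv")))
    }
    log_stage("diffabund", n_genera = nrow(genus_tab),
              n_contrasts = length(diffabund_results))
  }

  ## (8) manifest
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, polished = polished,
                 report_major = rep_major, report_prevalence = rep_prev,
                 comparison = comparison, alpha = alpha,
                 bray_curtis = d, pcoa = ord, proximity = prox,
                 permanova = permanova_results, anova = anova_result,
                 diffabund = diffabund_results, manifest = manifest))
}
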