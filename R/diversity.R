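## Alpha diversity, Bray-Curtis, classical-scaling PCoA, and the
## specimen-to-matched-control proximity screen. Negative controls are
## carried through every output so residual contamination stays visible.

#' Chao1 richness estimator with standard error
#'
#' Bias-corrected form: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with `F1`,
#' `F2` the singleton and doubleton counts. The standard error comes from
#' the usual asymptotic variance of this estimator.
#'
#' @param counts Integer count vector for one sample.
#' @return Named numeric vector `c(chao1 = ..., se = ...)`.
#' @export
chao1 <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("chao1 requires non-negative integer counts")
  }
  if (sum(counts) == 0) {
    warning("all-zero sample: Chao1 reported as 0")
    return(c(chao1 = 0, se = 0))
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  v <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
    f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
    f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  c(chao1 = est, se = sqrt(v))
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over taxa with nonzero abundance; natural log by
#' default. Counts and proportions are both accepted (counts are normalized
#' internally).
#'
#' @param x Count or proportion vector for one sample.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (numeric scalar).
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(is.na(x)) || any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("shannon is undefined on a zero-sum vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity with sample roles
#'
#' @param counts Feature table matrix.
#' @param metadata Optional sample metadata; when given, the `role` column
#'   is copied into the output so controls remain identifiable.
#' @return Data frame with `sample_id`, `observed_richness`, `chao1`,
#'   `chao1_se`, `shannon`, and `role` when metadata is supplied.
#' @export
alpha_diversity <- function(counts, metadata = NULL) {
  counts <- validate_feature_table(counts)
  est <- apply(counts, 2, chao1)
  out <- data.frame(
    sample_id = colnames(counts),
    observed_richness = colSums(counts > 0),
    chao1 = est["chao1", ],
    chao1_se = est["se", ],
    shannon = apply(counts, 2, shannon),
    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    metadata <- validate_sample_metadata(metadata, counts)
    out$role <- metadata[out$sample_id, "role"]
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_xy = sum |x_i - y_i| / sum (x_i + y_i)`, computed on per-sample
#' proportions by default to neutralize sequencing-depth differences;
#' `normalize = FALSE` uses the raw counts.
#'
#' @param counts Feature table or abundance matrix (taxa x samples).
#' @param normalize Convert columns to proportions first (default `TRUE`).
#' @return A [stats::dist] object labelled with sample ids.
#' @export
bray_curtis <- function(counts, normalize = TRUE) {
  if (ncol(counts) < 2) stop("need at least two samples")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  m <- if (normalize) sweep(counts, 2, totals, "/") else counts
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-d^2/2`, eigendecomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues. Negative eigenvalues —
#' expected for semi-metric dissimilarities such as Bray-Curtis — are
#' reported as-is, with no Lingoes/Cailliez correction; coordinates are
#' returned only for axes with positive eigenvalues.
#'
#' @param d Distance matrix ([stats::dist] or square symmetric matrix).
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (relative to
#'   the sum of positive eigenvalues).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0)) {
    stop("d must be a symmetric zero-diagonal distance matrix")
  }
  n <- nrow(dm)
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  eig <- e$values
  pos <- eig > max(eig[1], 0) * 1e-12    # numerically positive axes
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(dm)
  if (ncol(coords) > 0) {
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  pos_sum <- sum(eig[eig > 0])
  prop <- if (pos_sum > 0) pmax(eig, 0)[pos][seq_len(ncol(coords))] / pos_sum
          else numeric(0)
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA: ", nrow(x$coordinates), " samples, ", ncol(x$coordinates),
      " positive axes (", sum(x$eigenvalues < 0),
      " negative eigenvalues)\n", sep = "")
  invisible(x)
}

#' Specimen-to-matched-control proximity screen
#'
#' For every specimen, the Bray-Curtis dissimilarity to its own replicate's
#' extraction negative control is computed (the mean over controls if a
#' replicate has several). Specimens suspiciously close to their control —
#' the `k` closest, or all below `threshold` — are flagged as possible
#' low-biomass / failed-extraction libraries, and mean +/- SEM summaries
#' are reported for the flagged set and for all specimens.
#'
#' @param counts Feature table matrix.
#' @param metadata Sample metadata with `role` and `replicate`.
#' @param k Flag the `k` specimens closest to their matched control.
#' @param threshold Alternatively, flag all specimens with distance below
#'   this value. Exactly one of `k`, `threshold` must be given.
#' @return List of class `control_proximity`: `per_specimen` data frame
#'   (`sample_id`, `replicate`, `d_to_matched_control`, `flag`), and a
#'   `summary` data frame with mean and SEM for flagged vs all specimens.
#' @export
control_proximity <- function(counts, metadata, k = NULL, threshold = NULL) {
  if (is.null(k) == is.null(threshold)) {
    stop("give exactly one of k or threshold")
  }
  counts <- validate_feature_table(counts)
  metadata <- validate_sample_metadata(metadata, counts)
  meta <- metadata[colnames(counts), ]
  spec <- meta$sample_id[meta$role == "specimen"]
  ctrl <- meta$sample_id[meta$role == "negative_control"]
  missing_ctrl <- setdiff(unique(meta[spec, "replicate"]),
                          unique(meta[ctrl, "replicate"]))
  if (length(missing_ctrl) > 0) {
    stop("replicate(s) without a negative control: ",
         paste(missing_ctrl, collapse = ", "))
  }
  dm <- as.matrix(bray_curtis(counts))
  d_ctrl <- vapply(spec, function(s) {
    mates <- ctrl[meta[ctrl, "replicate"] == meta[s, "replicate"]]
    mean(dm[s, mates])
  }, numeric(1))
  flag <- if (!is.null(k)) {
    rank(d_ctrl, ties.method = "first") <= k
  } else {
    d_ctrl < threshold
  }
  per <- data.frame(sample_id = spec,
                    replicate = meta[spec, "replicate"],
                    d_to_matched_control = unname(d_ctrl),
                    flag = unname(flag),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summary <- data.frame(
    group = c("flagged", "all"),
    n = c(sum(per$flag), nrow(per)),
    mean = c(mean(per$d_to_matched_control[per$flag]),
             mean(per$d_to_matched_control)),
    sem = c(sem(per$d_to_matched_control[per$flag]),
            sem(per$d_to_matched_control)),
    stringsAsFactors = FALSE)
  structure(list(per_specimen = per, summary = summary),
            class = "control_proximity")
}

#' @export
print.control_proximity <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Control proximity: %d/%d specimens flagged; flagged %.3f +/- %.4f vs all %.3f +/- %.4f\n",
    s$n[1], s$n[2], s$mean[1], s$sem[1], s$mean[2], s$sem[2]))
  invisible(x)
}
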