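## Hypothesis-testing layer: rank tests with multiplicity control, seeded
## distance-based PERMANOVA, two-way ANOVA, a simplified negative-binomial
## Wald differential-abundance test, and the Gehan-Breslow-Wilcoxon
## weighted log-rank survival comparison.

#' Two-sided Wilcoxon rank sum p-value
#'
#' Exact enumeration when the pooled sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_if_small Use the exact distribution for small untied
#'   samples (default `TRUE`).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_if_small = TRUE) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  small <- length(x) + length(y) <= 12
  ties <- anyDuplicated(c(x, y)) > 0
  if (exact_if_small && small && !ties) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

check_pvalues <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pvals
}

#' Holm step-down adjustment
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, input order preserved.
#' @export
holm_adjust <- function(pvals) {
  stats::p.adjust(check_pvalues(pvals), method = "holm")
}

#' Benjamini-Hochberg step-up adjustment
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, input order preserved.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(check_pvalues(pvals), method = "BH")
}

## Trace-form PERMANOVA machinery: Gower-center the squared distances once,
## then every (permuted) sum of squares is tr(H G) for a fixed hat matrix.
gower_center <- function(dm) {
  a <- -0.5 * dm^2
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

#' Distance-based PERMANOVA with sequential sums of squares
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = tr(G)` with `G` the Gower-centered `-d^2/2`) across model
#' terms taken sequentially in the stated order, with an optional
#' interaction for two factors. Pseudo-F per term is tested by free
#' permutation of sample labels with the add-one convention
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`.
#'
#' @param d Distance matrix ([stats::dist] or square symmetric matrix) with
#'   sample labels.
#' @param metadata Sample metadata covering the samples of `d`.
#' @param factors Character vector of one or two metadata field names,
#'   sequential order as given.
#' @param include_interaction Add the two-factor interaction term.
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional integer matrix, one permutation of
#'   `1:n` per row; when given it is used as the complete permutation set
#'   and `p = #(F_perm >= F_obs) / nrow(permutations)` (exact enumeration).
#' @return Data frame of class `permanova_result`, one row per term plus
#'   residual and total: `term`, `df`, `sum_sq`, `pseudo_F`, `p_perm`.
#' @export
permanova <- function(d, metadata, factors, include_interaction = FALSE,
                      n_permutations = 999, seed = NULL,
                      permutations = NULL) {
  dm <- as.matrix(d)
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix must carry sample labels")
  metadata <- validate_sample_metadata(metadata)
  if (!all(ids %in% metadata$sample_id)) stop("samples missing from metadata")
  meta <- metadata[ids, ]
  if (length(factors) < 1 || length(factors) > 2) {
    stop("factors must name one or two metadata fields")
  }
  unknown <- setdiff(factors, names(meta))
  if (length(unknown) > 0) {
    stop("unknown metadata field(s): ", paste(unknown, collapse = ", "))
  }
  fs <- lapply(factors, function(f) factor(meta[[f]]))
  for (i in seq_along(fs)) {
    tab <- table(fs[[i]])
    if (length(tab) < 2) {
      stop("factor '", factors[i], "' has a single level: contrast undefined")
    }
    if (any(tab < 2)) {
      stop("factor '", factors[i], "' has a level with fewer than 2 samples")
    }
  }
  if (include_interaction && length(factors) != 2) {
    stop("interaction requires two factors")
  }
  if (is.null(permutations) && n_permutations < 99) {
    warning("fewer than 99 permutations gives a very coarse p-value")
  }

  n <- nrow(dm)
  g <- gower_center(dm)
  ss_total <- sum(diag(g))

  df_model <- data.frame(f1 = fs[[1]])
  terms <- factors[1]
  formulas <- c("~ f1")
  if (length(fs) == 2) {
    df_model$f2 <- fs[[2]]
    terms <- c(terms, factors[2])
    formulas <- c(formulas, "~ f1 + f2")
    if (include_interaction) {
      terms <- c(terms, paste0(factors[1], ":", factors[2]))
      formulas <- c(formulas, "~ f1 * f2")
    }
  }
  hats <- lapply(formulas, function(f) {
    hat_matrix(stats::model.matrix(stats::as.formula(f), df_model))
  })
  h0 <- matrix(1 / n, n, n)
  dfs <- vapply(formulas, function(f) {
    qr(stats::model.matrix(stats::as.formula(f), df_model))$rank
  }, numeric(1))
  term_df <- diff(c(1, dfs))
  df_res <- n - dfs[length(dfs)]
  if (df_res <= 0) stop("no residual degrees of freedom")

  ## differenced hat matrices: SS_k = tr((H_k - H_{k-1}) G)
  dh <- vector("list", length(hats))
  prev <- h0
  for (k in seq_along(hats)) {
    dh[[k]] <- hats[[k]] - prev
    prev <- hats[[k]]
  }
  h_resid <- diag(n) - hats[[length(hats)]]

  ss_terms <- vapply(dh, function(h) sum(h * g), numeric(1))
  ss_res <- sum(h_resid * g)
  f_obs <- (ss_terms / term_df) / (ss_res / df_res)

  f_stats <- function(gp) {
    ss <- vapply(dh, function(h) sum(h * gp), numeric(1))
    sr <- sum(h_resid * gp)
    (ss / term_df) / (sr / df_res)
  }

  if (!is.null(permutations)) {
    stopifnot(is.matrix(permutations), ncol(permutations) == n)
    count <- numeric(length(f_obs))
    for (r in seq_len(nrow(permutations))) {
      p <- permutations[r, ]
      count <- count + (f_stats(g[p, p]) >= f_obs - 1e-12)
    }
    p_perm <- count / nrow(permutations)
    n_used <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- numeric(length(f_obs))
    for (r in seq_len(n_permutations)) {
      p <- sample.int(n)
      count <- count + (f_stats(g[p, p]) >= f_obs - 1e-12)
    }
    p_perm <- (1 + count) / (1 + n_permutations)
    n_used <- n_permutations
  }

  out <- data.frame(
    term = c(terms, "residual", "total"),
    df = c(term_df, df_res, n - 1),
    sum_sq = c(ss_terms, ss_res, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("permanova_result", "data.frame"),
            n_permutations = n_used, seed = seed)
}

#' Two-way ANOVA with sequential (Type-I) sums of squares
#'
#' Fits `response ~ A * B` through [stats::aov()], terms in the stated
#' order, and returns per-term F and p against the residual mean square.
#'
#' @param response Numeric response, one value per metadata row (ordered as
#'   `metadata`).
#' @param metadata Data frame holding the factors.
#' @param factor_a,factor_b Metadata field names.
#' @return Data frame: `term`, `df`, `sum_sq`, `F`, `p`.
#' @export
two_way_anova <- function(response, metadata, factor_a, factor_b) {
  for (f in c(factor_a, factor_b)) {
    if (!f %in% names(metadata)) stop("unknown metadata field: ", f)
    if (length(unique(metadata[[f]])) < 2) {
      stop("factor '", f, "' needs at least 2 levels")
    }
  }
  a <- factor(metadata[[factor_a]])
  b <- factor(metadata[[factor_b]])
  cells <- table(a, b)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell makes the interaction inestimable: ",
         factor_a, "=", rownames(cells)[idx[1]], ", ",
         factor_b, "=", colnames(cells)[idx[2]])
  }
  fit <- stats::aov(response ~ a * b)
  tab <- summary(fit)[[1]]
  if (tab["Residuals", "Df"] <= 0) stop("no residual degrees of freedom")
  data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residual"),
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    F = tab$`F value`,
    p = tab$`Pr(>F)`,
    stringsAsFactors = FALSE)
}

## Median-of-ratios size factors over features with all-positive counts.
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    message("no feature with all-positive counts; ",
            "falling back to library-size factors")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  apply(counts[use, , drop = FALSE], 2, function(cnts) {
    exp(stats::median(log(cnts) - log_geo[use]))
  })
}

nb_irls <- function(y, x, offset, alpha, max_iter = 50, tol = 1e-10) {
  mu <- pmax(y, 0.5)
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- log(mu)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(x * w)
    fit <- solve(xtw %*% x, xtw %*% z)
    if (max(abs(fit - beta)) < tol) {
      beta <- fit
      break
    }
    beta <- fit
    mu <- pmax(exp(as.vector(x %*% beta) + offset), 1e-10)
  }
  w <- mu / (1 + alpha * mu)
  cov_beta <- solve(t(x * w) %*% x)
  list(beta = as.vector(beta), se = unname(sqrt(diag(cov_beta))))
}

#' Simplified negative-binomial Wald differential abundance
#'
#' Two-group genus-level test in the spirit of the standard
#' negative-binomial Wald workflow, deliberately stripped down: size
#' factors by median-of-ratios, a per-genus method-of-moments dispersion on
#' normalized counts (no shrinkage across genera, floored at 1e-8), a
#' log-linear two-group model fit by iteratively reweighted least squares
#' with log size factors as offset, Wald `z = beta / SE(beta)`, and BH
#' adjustment across genera. Genera observed in only one group get a 0.5
#' pseudo-count on the normalized group means and a delta-method standard
#' error, and are flagged as boundary estimates.
#'
#' @param genus_table Integer feature table (genera x samples).
#' @param metadata Sample metadata.
#' @param contrast Length-3 character vector `c(field, level_A, level_B)`;
#'   the reported fold change is level_A relative to baseline level_B.
#' @return Data frame of class `diff_abundance`: `genus`, `base_mean`,
#'   `log2_fc`, `se` (log2 scale), `wald_z`, `p`, `padj`, `boundary`;
#'   attributes `contrast_field`, `level_a`, `level_b`.
#' @export
nb_wald_diff_abundance <- function(genus_table, metadata, contrast) {
  stopifnot(length(contrast) == 3)
  field <- contrast[1]
  lev_a <- contrast[2]
  lev_b <- contrast[3]
  counts <- validate_feature_table(genus_table)
  metadata <- validate_sample_metadata(metadata, counts)
  meta <- metadata[colnames(counts), ]
  if (!field %in% names(meta)) stop("unknown metadata field: ", field)
  for (lev in c(lev_a, lev_b)) {
    if (sum(meta[[field]] == lev) < 2) {
      stop("contrast level '", lev, "' has fewer than 2 samples")
    }
  }
  ## blanks take part only when the contrast is about the role itself;
  ## mixing negative controls into a treatment level would attribute their
  ## contaminant load to that level
  keep <- meta[[field]] %in% c(lev_a, lev_b)
  if (field != "role") keep <- keep & meta$role == "specimen"
  for (lev in c(lev_a, lev_b)) {
    if (sum(keep & meta[[field]] == lev) < 2) {
      stop("contrast level '", lev, "' has fewer than 2 specimen samples")
    }
  }
  counts <- counts[, keep, drop = FALSE]
  grp <- factor(meta[[field]][keep], levels = c(lev_b, lev_a))

  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message(sum(zero), " all-zero genera dropped")
    counts <- counts[!zero, , drop = FALSE]
  }
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  x <- stats::model.matrix(~ grp)
  offset <- log(sf)
  is_a <- grp == lev_a
  n_a <- sum(is_a)
  n_b <- sum(!is_a)

  res <- lapply(seq_len(nrow(counts)), function(i) {
    qi <- q[i, ]
    m_a <- mean(qi[is_a])
    m_b <- mean(qi[!is_a])
    m_all <- mean(qi)
    v_within <- (sum((qi[is_a] - m_a)^2) + sum((qi[!is_a] - m_b)^2)) /
      (length(qi) - 2)
    alpha <- max((v_within - m_all) / m_all^2, 1e-8)
    if (m_a == 0 || m_b == 0) {
      beta <- log((m_a + 0.5) / (m_b + 0.5))
      se <- sqrt((1 / (m_a + 0.5) + alpha) / n_a +
                 (1 / (m_b + 0.5) + alpha) / n_b)
      c(beta = beta, se = se, alpha = alpha, base_mean = m_all, boundary = 1)
    } else {
      fit <- nb_irls(counts[i, ], x, offset, alpha)
      c(beta = fit$beta[2], se = fit$se[2], alpha = alpha,
        base_mean = m_all, boundary = 0)
    }
  })
  res <- do.call(rbind, res)
  z <- res[, "beta"] / res[, "se"]
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)  # p > 0 always
  out <- data.frame(
    genus = rownames(counts),
    base_mean = res[, "base_mean"],
    log2_fc = res[, "beta"] / log(2),
    se = res[, "se"] / log(2),
    wald_z = z,
    p = p,
    padj = bh_adjust(p),
    dispersion = res[, "alpha"],
    boundary = res[, "boundary"] == 1,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("diff_abundance", "data.frame"),
            contrast_field = field, level_a = lev_a, level_b = lev_b)
}

#' Gehan-Breslow-Wilcoxon weighted log-rank test
#'
#' Weighted log-rank comparison of survival curves with weight equal to the
#' number at risk at each event time, emphasizing early deaths. The
#' statistic is the quadratic form of the weighted observed-minus-expected
#' death counts, chi-square distributed with (groups - 1) degrees of
#' freedom under the null. Per-group Kaplan-Meier median survival times are
#' reported alongside.
#'
#' @param records Data frame with columns `time` (days, > 0), `event`
#'   (`"death"`/`"censored"`, or 1/0 logical-numeric), `group`.
#' @return List of class `gehan_wilcoxon`: `chisq`, `df`, `p`,
#'   `median_survival` (named per group).
#' @export
gehan_wilcoxon_test <- function(records) {
  time <- records$time
  event <- records$event
  if (is.character(event) || is.factor(event)) {
    event <- as.character(event)
    bad <- setdiff(unique(event), c("death", "censored"))
    if (length(bad) > 0) stop("unknown event value(s): ",
                              paste(bad, collapse = ", "))
    event <- as.integer(event == "death")
  } else {
    event <- as.integer(as.logical(event))
  }
  if (any(time <= 0)) stop("times must be positive")
  group <- factor(records$group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (sum(event) == 0) stop("all observations censored: test undefined")

  lev <- levels(group)
  g_count <- length(lev)
  times <- sort(unique(time[event == 1]))
  u <- numeric(g_count - 1)
  v <- matrix(0, g_count - 1, g_count - 1)
  for (t in times) {
    at_risk <- time >= t
    n_k <- sum(at_risk)
    d_k <- sum(event == 1 & time == t)
    if (n_k == 0 || d_k == 0) next
    n_gk <- vapply(lev, function(g) sum(at_risk & group == g), numeric(1))
    d_gk <- vapply(lev, function(g) sum(event == 1 & time == t & group == g),
                   numeric(1))
    w <- n_k                               # Gehan weight: number at risk
    u <- u + w * (d_gk[-g_count] - d_k * n_gk[-g_count] / n_k)
    if (n_k > 1) {
      hyper <- d_k * (n_k - d_k) / (n_k - 1)
      p_g <- n_gk[-g_count] / n_k
      vk <- hyper * (diag(p_g, nrow = g_count - 1) - tcrossprod(p_g))
      v <- v + w^2 * vk
    }
  }
  chisq <- tryCatch(as.numeric(t(u) %*% solve(v, u)),
                    error = function(e) {
                      as.numeric(t(u) %*% pseudo_inverse(v) %*% u)
                    })
  df <- g_count - 1
  p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)

  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  med <- summary(sf)$table
  med_col <- if (is.matrix(med)) med[, "median"] else med["median"]
  names(med_col) <- sub("^group=", "", names(med_col))

  structure(list(chisq = chisq, df = df, p = p, median_survival = med_col),
            class = "gehan_wilcoxon")
}

## Small Moore-Penrose fallback so a degenerate covariance (e.g. a group
## with no events at shared risk sets) still yields a statistic.
pseudo_inverse <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.gehan_wilcoxon <- function(x, ...) {
  cat(sprintf("Gehan-Breslow-Wilcoxon: chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
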