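# Shared fixture builders and independent oracles. Oracles deliberately use
# scalar loops and per-sample arithmetic so they share no code path with the
# vectorized package implementations.

# Random feature table with role metadata; multinomial columns guarantee
# positive sample totals.
random_study_table <- function(n_taxa = NULL, n_samples = NULL,
                               n_controls = NULL) {
  if (is.null(n_taxa)) n_taxa <- sample(3:20, 1)
  if (is.null(n_samples)) n_samples <- sample(4:12, 1)
  if (is.null(n_controls)) n_controls <- sample(1:3, 1)
  n_controls <- min(n_controls, n_samples - 1)
  counts <- sapply(seq_len(n_samples), function(j) {
    depth <- sample(50:500, 1)
    probs <- rgamma(n_taxa, shape = 0.5)
    rmultinom(1, depth, probs / sum(probs))[, 1]
  })
  rownames(counts) <- paste0("t", seq_len(n_taxa))
  colnames(counts) <- paste0("s", seq_len(n_samples))
  storage.mode(counts) <- "integer"
  metadata <- data.frame(
    sample_id = colnames(counts),
    role = rep(c("negative_control", "specimen"),
               c(n_controls, n_samples - n_controls)),
    replicate = "r1",
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

# Brute-force major-contaminant oracle: per-taxon scalar evaluation of both
# criteria, relative abundances computed one sample at a time.
oracle_major_flags <- function(counts, metadata, mode = "relative",
                               tau = 0.8) {
  spec <- metadata$sample_id[metadata$role == "specimen"]
  ctrl <- metadata$sample_id[metadata$role == "negative_control"]
  totals <- sapply(colnames(counts), function(s) sum(counts[, s]))
  flags <- logical(nrow(counts))
  names(flags) <- rownames(counts)
  for (tx in rownames(counts)) {
    n_present <- 0
    for (s in spec) if (counts[tx, s] > 0) n_present <- n_present + 1
    prev <- n_present / length(spec)
    val <- function(s) {
      if (mode == "relative") counts[tx, s] / totals[s] else counts[tx, s]
    }
    mean_spec <- sum(sapply(spec, val)) / length(spec)
    mean_ctrl <- sum(sapply(ctrl, val)) / length(ctrl)
    flags[tx] <- (prev >= tau) && (mean_ctrl > mean_spec)
  }
  flags
}

# Direct Bray-Curtis between two abundance vectors.
oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# One-factor PERMANOVA oracle from the group-sum definition of the sums of
# squares, with exhaustive enumeration of label permutations.
oracle_permanova_exact <- function(dm, labels) {
  n <- nrow(dm)
  f_of <- function(lab) {
    ss_total <- sum(dm[upper.tri(dm)]^2) / n
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- dm[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    a <- length(unique(lab))
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  f_obs <- f_of(labels)
  perms <- all_permutations(n)
  f_all <- apply(perms, 1, function(p) f_of(labels[p]))
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12), perms = perms)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Two-group Gehan-Breslow-Wilcoxon oracle: scalar loop over event times with
# the closed-form two-sample hypergeometric variance.
oracle_gehan_two_group <- function(time, status, group) {
  lev <- sort(unique(group))
  u <- 0
  v <- 0
  for (t in sort(unique(time[status == 1]))) {
    n_k <- sum(time >= t)
    d_k <- sum(status == 1 & time == t)
    n1 <- sum(time >= t & group == lev[1])
    d1 <- sum(status == 1 & time == t & group == lev[1])
    u <- u + n_k * (d1 - d_k * n1 / n_k)
    if (n_k > 1) {
      v <- v + n_k^2 * d_k * (n_k - d_k) / (n_k - 1) *
        (n1 / n_k) * (1 - n1 / n_k)
    }
  }
  chisq <- u^2 / v
  list(u = u, v = v, chisq = chisq,
       p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Exact two-sided Wilcoxon p by enumerating all rank assignments (no ties).
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- combn(length(pooled), length(x))
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - length(x) * (length(x) + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
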