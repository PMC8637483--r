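test_that("wilcoxon rank sum: exact small-sample p and approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  set.seed(401)
  for (i in 1:20) {
    x <- sample(1:100, sample(3:5, 1))
    y <- sample(101:200, sample(3:5, 1)) - runif(1) # distinct values
    p_exact <- oracle_wilcoxon_exact(x, y)
    expect_equal(wilcoxon_rank_sum(x, y), p_exact, tolerance = 1e-12)
    p_approx <- wilcoxon_rank_sum(x, y, exact_if_small = FALSE)
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("holm and BH adjustments match hand computations", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06),
               tolerance = 1e-12)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_error(holm_adjust(c(0.5, 1.2)), "p-values")
  expect_error(bh_adjust(c(-0.1)), "p-values")

  # permutation equivariance and BH monotonicity on random inputs
  set.seed(402)
  for (i in 1:20) {
    p <- runif(8)
    perm <- sample(8)
    expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    expect_true(all(diff(sort(bh_adjust(p))) >= -1e-12))
    expect_true(all(bh_adjust(p) >= p - 1e-12))
  }
})

test_that("permanova matches exhaustive enumeration and vegan", {
  make_d <- function(n) {
    pts <- matrix(rnorm(n * 2), n, dimnames = list(paste0("s", 1:n), NULL))
    dist(pts)
  }
  set.seed(403)
  for (n in c(4, 6)) {
    d <- make_d(n)
    md <- data.frame(sample_id = paste0("s", 1:n), role = "specimen",
                     replicate = "r",
                     g = rep(c("a", "b"), each = n / 2),
                     stringsAsFactors = FALSE)
    oracle <- oracle_permanova_exact(as.matrix(d), md$g)
    res <- permanova(d, md, "g", permutations = oracle$perms)
    expect_equal(res$pseudo_F[1], oracle$f, tolerance = 1e-10)
    expect_equal(res$p_perm[1], oracle$p, tolerance = 1e-12)
    ref <- vegan::adonis2(d ~ g, data = md, permutations = 99)
    expect_equal(res$pseudo_F[1], ref$F[1], tolerance = 1e-8)
    expect_equal(res$sum_sq[res$term == "total"],
                 ref["Total", "SumOfSqs"], tolerance = 1e-8)
  }
})

test_that("permanova partitions two-factor designs sequentially", {
  set.seed(404)
  n <- 24
  md <- data.frame(sample_id = paste0("s", 1:n), role = "specimen",
                   replicate = "r",
                   f1 = rep(c("a", "b"), each = n / 2),
                   f2 = rep(c("x", "y"), n / 2),
                   stringsAsFactors = FALSE)
  pts <- matrix(rnorm(n * 3), n, dimnames = list(md$sample_id, NULL))
  pts[md$f1 == "b", 1] <- pts[md$f1 == "b", 1] + 2
  d <- dist(pts)
  res <- permanova(d, md, c("f1", "f2"), include_interaction = TRUE,
                   n_permutations = 199, seed = 9)
  ref <- vegan::adonis2(d ~ f1 * f2, data = md, by = "terms",
                        permutations = 99)
  expect_equal(res$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(res$sum_sq[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  # SS terms sum to SS_total
  expect_equal(sum(res$sum_sq[res$term != "total"]),
               res$sum_sq[res$term == "total"], tolerance = 1e-8)
  # bit-reproducible given a seed
  res2 <- permanova(d, md, c("f1", "f2"), include_interaction = TRUE,
                    n_permutations = 199, seed = 9)
  expect_identical(res$p_perm, res2$p_perm)
})

test_that("permanova separates well-separated clouds and rejects degenerates", {
  set.seed(405)
  n <- 20
  pts <- matrix(rnorm(n * 2, sd = 0.2), n,
                dimnames = list(paste0("s", 1:n), NULL))
  pts[11:20, 1] <- pts[11:20, 1] + 10
  md <- data.frame(sample_id = paste0("s", 1:n), role = "specimen",
                   replicate = "r", g = rep(c("a", "b"), each = 10),
                   one = "same", stringsAsFactors = FALSE)
  res <- permanova(dist(pts), md, "g", n_permutations = 999, seed = 5)
  expect_equal(res$p_perm[1], 0.001)     # minimum attainable at 999 perms
  expect_error(permanova(dist(pts), md, "one"), "single level")
  expect_warning(permanova(dist(pts), md, "g", n_permutations = 49),
                 "coarse")
})

test_that("two-way anova gives sequential SS with analytic zeros", {
  md <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                    rep = 1:3, stringsAsFactors = FALSE)
  resp_a <- ifelse(md$a == "a1", 1, 5)     # depends only on factor a
  res <- two_way_anova(resp_a, md, "a", "b")
  expect_equal(res$sum_sq[res$term == "b"], 0, tolerance = 1e-12)
  expect_equal(res$sum_sq[res$term == "a:b"], 0, tolerance = 1e-12)

  set.seed(406)
  resp <- rnorm(nrow(md)) + ifelse(md$a == "a1", 0, 1)
  res <- two_way_anova(resp, md, "a", "b")
  # direct-summation oracle for a balanced design
  gm <- mean(resp)
  ma <- tapply(resp, md$a, mean); mb <- tapply(resp, md$b, mean)
  mab <- tapply(resp, paste(md$a, md$b), mean)
  ss_a <- sum(9 * (ma - gm)^2)
  ss_b <- sum(6 * (mb - gm)^2)
  ss_ab <- sum(3 * (mab[paste(md$a, md$b)] - ma[md$a] - mb[md$b] + gm)^2) / 3
  expect_equal(res$sum_sq[res$term == "a"], ss_a, tolerance = 1e-8)
  expect_equal(res$sum_sq[res$term == "b"], ss_b, tolerance = 1e-8)
  expect_equal(res$sum_sq[res$term == "a:b"], ss_ab, tolerance = 1e-8)

  md_miss <- md[!(md$a == "a2" & md$b == "b3"), ]
  expect_error(two_way_anova(resp[seq_len(nrow(md_miss))], md_miss,
                             "a", "b"), "empty design cell")
})

test_that("two-way anova interaction holds its nominal type-I error", {
  set.seed(407)
  md <- expand.grid(a = c("a1", "a2", "a3"), b = c("b1", "b2"),
                    rep = 1:4, stringsAsFactors = FALSE)
  rej <- replicate(500, {
    res <- two_way_anova(rnorm(nrow(md)), md, "a", "b")
    res$p[res$term == "a:b"] <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("nb wald test is symmetric, handles zero groups and boundaries", {
  set.seed(408)
  base <- matrix(rnbinom(10 * 6, mu = 50, size = 10), nrow = 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  counts <- cbind(base, base)
  colnames(counts) <- paste0("s", 1:12)
  storage.mode(counts) <- "integer"
  md <- data.frame(sample_id = colnames(counts), role = "specimen",
                   replicate = "r",
                   grp = rep(c("A", "B"), each = 6),
                   stringsAsFactors = FALSE)
  res <- nb_wald_diff_abundance(counts, md, c("grp", "A", "B"))
  expect_true(all(abs(res$log2_fc) < 1e-6))
  expect_true(all(res$padj >= res$p - 1e-12))
  expect_true(all(sign(res$log2_fc) == sign(res$wald_z) |
                    res$wald_z == 0))

  # genus observed only in group A: finite large positive fold change
  counts2 <- counts
  counts2["g1", md$grp == "B"] <- 0L
  counts2["g1", md$grp == "A"] <- 400L
  res2 <- nb_wald_diff_abundance(counts2, md, c("grp", "A", "B"))
  row <- res2[res2$genus == "g1", ]
  expect_true(row$boundary)
  expect_true(is.finite(row$log2_fc))
  expect_gt(row$log2_fc, 5)

  # all-zero genus is dropped with a message
  counts3 <- counts
  counts3["g2", ] <- 0L
  expect_message(res3 <- nb_wald_diff_abundance(counts3, md,
                                                c("grp", "A", "B")),
                 "all-zero")
  expect_false("g2" %in% res3$genus)

  expect_error(nb_wald_diff_abundance(counts, md, c("grp", "A", "C")),
               "fewer than 2 samples")
})

test_that("gehan-wilcoxon matches the direct-summation oracle", {
  # identical groups: statistic 0, p = 1
  rec_same <- data.frame(time = rep(c(2, 4, 6, 8, 10), 2),
                         event = "death",
                         group = rep(c("a", "b"), each = 5))
  res_same <- gehan_wilcoxon_test(rec_same)
  expect_equal(res_same$chisq, 0, tolerance = 1e-12)
  expect_equal(res_same$p, 1)

  set.seed(409)
  for (i in 1:10) {
    rec <- data.frame(time = sample(1:50, 10),
                      event = "death",
                      group = rep(c("a", "b"), each = 5))
    res <- gehan_wilcoxon_test(rec)
    orc <- oracle_gehan_two_group(rec$time, rep(1, 10), rec$group)
    expect_equal(res$chisq, orc$chisq, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }

  # complete separation: all a-deaths before b-deaths
  rec_sep <- data.frame(time = c(1:5, 11:15), event = "death",
                        group = rep(c("a", "b"), each = 5))
  res_sep <- gehan_wilcoxon_test(rec_sep)
  expect_lt(res_sep$p, 0.01)
  # permutation oracle over group labelings agrees on significance
  set.seed(410)
  perm_stats <- replicate(999, {
    g <- sample(rec_sep$group)
    oracle_gehan_two_group(rec_sep$time, rep(1, 10), g)$chisq
  })
  p_perm <- (1 + sum(perm_stats >= res_sep$chisq - 1e-12)) / 1000
  expect_lt(p_perm, 0.01)
  expect_equal(unname(res_sep$median_survival), c(3, 13))

  expect_error(gehan_wilcoxon_test(
    data.frame(time = 1:4, event = "censored",
               group = rep(c("a", "b"), 2))), "censored")
  expect_error(gehan_wilcoxon_test(
    data.frame(time = 1:4, event = "death", group = "a")), "two groups")
})
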