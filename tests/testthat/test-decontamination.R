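# The toy cohort from the classifier's contract: 5 specimens + 2 controls.
toy_cohort <- function() {
  counts <- rbind(
    A = c(50, 50, 50, 50, 50, 90, 90),   # everywhere, enriched in controls
    B = c(30, 30, 0, 0, 0, 5, 5),        # only 2/5 specimens
    C = c(20, 20, 50, 50, 50, 5, 5))     # everywhere, depleted in controls
  counts <- counts + 0L
  storage.mode(counts) <- "integer"
  colnames(counts) <- c(paste0("sp", 1:5), "nc1", "nc2")
  metadata <- data.frame(
    sample_id = colnames(counts),
    role = rep(c("specimen", "negative_control"), c(5, 2)),
    replicate = "r1", stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

test_that("major-contaminant rule applies both criteria conjunctively", {
  tc <- toy_cohort()
  rep <- classify_major_contaminants(tc$counts, tc$metadata)
  flags <- setNames(rep$flag, rep$taxon_id)
  expect_true(flags["A"])      # prevalent and control-enriched
  expect_false(flags["B"])     # prevalence 0.4 < 0.8
  expect_false(flags["C"])     # control mean below specimen mean
  expect_true(all(rep$prevalence_specimens >= 0 &
                    rep$prevalence_specimens <= 1))
  expect_true(all(diff(rep$mean_abund_controls) <= 0))  # sorted descending
})

test_that("a taxon absent from all controls is never a major contaminant", {
  tc <- toy_cohort()
  tc$counts["A", c("nc1", "nc2")] <- 0L
  rep <- classify_major_contaminants(tc$counts, tc$metadata)
  expect_false(rep$flag[rep$taxon_id == "A"])
  rep_raw <- classify_major_contaminants(tc$counts, tc$metadata, mode = "raw")
  expect_false(rep_raw$flag[rep_raw$taxon_id == "A"])
})

test_that("classification requires negative controls", {
  tc <- toy_cohort()
  md <- tc$metadata
  md$role <- "specimen"
  expect_error(classify_major_contaminants(tc$counts, md),
               "no negative controls")
  expect_error(classify_prevalence_rule(tc$counts, md),
               "no negative controls")
})

test_that("prevalence rule compares presence fractions at threshold 0.5", {
  # 3/3 controls vs 10/87 specimens: flagged; absent from controls: never
  n_spec <- 87
  counts <- rbind(
    hit = c(rep(1L, 10), rep(0L, n_spec - 10), 1L, 1L, 1L),
    clean = c(rep(1L, n_spec), 0L, 0L, 0L))
  common <- rep(2L, n_spec + 3)           # keeps sample totals positive
  counts <- rbind(counts, common = common)
  colnames(counts) <- c(paste0("sp", seq_len(n_spec)), "nc1", "nc2", "nc3")
  md <- data.frame(sample_id = colnames(counts),
                   role = rep(c("specimen", "negative_control"),
                              c(n_spec, 3)),
                   replicate = "r1", stringsAsFactors = FALSE)
  rep <- classify_prevalence_rule(counts, md)
  flags <- setNames(rep$flag, rep$taxon_id)
  expect_true(flags["hit"])
  expect_false(flags["clean"])
  expect_equal(rep$prevalence_score[rep$taxon_id == "hit"],
               1 / (1 + 10 / 87), tolerance = 1e-12)
})

test_that("classifier flags match the brute-force oracle on random tables", {
  set.seed(201)
  for (i in 1:200) {
    st <- random_study_table()
    rep <- classify_major_contaminants(st$counts, st$metadata)
    oracle <- oracle_major_flags(st$counts, st$metadata)
    expect_identical(setNames(rep$flag, rep$taxon_id)[names(oracle)],
                     oracle)
  }
})

test_that("lowering the prevalence threshold never unflags a taxon", {
  set.seed(202)
  for (i in 1:50) {
    st <- random_study_table()
    hi <- classify_major_contaminants(st$counts, st$metadata,
                                      prevalence_threshold = 0.8)
    lo <- classify_major_contaminants(st$counts, st$metadata,
                                      prevalence_threshold = 0.4)
    expect_true(all(lo$flag[match(hi$taxon_id[hi$flag], lo$taxon_id)]))
  }
})

test_that("raw and relative modes agree when sample totals are equal", {
  set.seed(203)
  for (i in 1:20) {
    n_taxa <- sample(3:20, 1)
    n_samples <- sample(4:12, 1)
    depth <- 300
    counts <- sapply(seq_len(n_samples), function(j) {
      probs <- rgamma(n_taxa, 0.5)
      rmultinom(1, depth, probs / sum(probs))[, 1]
    })
    rownames(counts) <- paste0("t", seq_len(n_taxa))
    colnames(counts) <- paste0("s", seq_len(n_samples))
    storage.mode(counts) <- "integer"
    md <- data.frame(sample_id = colnames(counts),
                     role = rep(c("negative_control", "specimen"),
                                c(2, n_samples - 2)),
                     replicate = "r1", stringsAsFactors = FALSE)
    raw <- classify_major_contaminants(counts, md, mode = "raw")
    rel <- classify_major_contaminants(counts, md, mode = "relative")
    expect_identical(setNames(raw$flag, raw$taxon_id),
                     setNames(rel$flag, rel$taxon_id)[raw$taxon_id])
  }
})

test_that("classification comparison is a set intersection", {
  tc <- toy_cohort()
  a <- classify_major_contaminants(tc$counts, tc$metadata)
  b <- classify_prevalence_rule(tc$counts, tc$metadata)
  cmp <- compare_classifications(a, b)
  expect_identical(cmp$n_intersection,
                   length(intersect(a$taxon_id[a$flag], b$taxon_id[b$flag])))
  expect_lte(cmp$n_intersection, min(cmp$n_flagged_a, cmp$n_flagged_b))

  same <- compare_classifications(a, a)
  expect_identical(same$n_intersection, same$n_flagged_a)

  set.seed(204)
  for (i in 1:20) {
    fa <- a; fb <- b
    fa$flag <- sample(c(TRUE, FALSE), nrow(fa), replace = TRUE)
    fb$flag <- sample(c(TRUE, FALSE), nrow(fb), replace = TRUE)
    cmp_r <- compare_classifications(fa, fb)
    expect_identical(cmp_r$n_intersection,
                     length(intersect(fa$taxon_id[fa$flag],
                                      fb$taxon_id[fb$flag])))
  }

  b2 <- b[b$taxon_id != "A", ]
  expect_error(compare_classifications(a, b2), "different taxon sets")
})

test_that("contaminant removal drops flagged taxa from all samples only", {
  set.seed(205)
  st <- random_study_table(n_taxa = 20, n_samples = 10, n_controls = 2)
  rep <- classify_major_contaminants(st$counts, st$metadata)
  rep$flag <- seq_len(nrow(rep)) <= 6
  pol <- remove_contaminants(st$counts, rep)
  expect_identical(nrow(pol), 14L)
  expect_identical(colnames(pol), colnames(st$counts))
  expect_false(any(rep$taxon_id[rep$flag] %in% rownames(pol)))
  expect_identical(nrow(attr(pol, "removal_log")), 6L)

  rep$flag <- FALSE
  expect_equal(remove_contaminants(st$counts, rep), st$counts,
               ignore_attr = TRUE)

  # removed ids can never be re-flagged: they are gone from the table
  rep2 <- classify_major_contaminants(pol, st$metadata)
  expect_length(intersect(rep2$taxon_id, rep$taxon_id[seq_len(6)]), 0)
  expect_error(remove_contaminants(st$counts, rep, which = "nosuch"),
               "no flag column")
})
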