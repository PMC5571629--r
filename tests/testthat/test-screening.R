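test_that("depth/site filtering and first-specimen dedup follow the rules", {
  counts <- rbind(
    a1 = c(t1 = 999, t2 = 0), a2 = c(t1 = 1000, t2 = 0),
    a3 = c(t1 = 10000, t2 = 0))
  colnames(counts) <- c("t1", "t2")
  meta <- data.frame(sample_id = c("a1", "a2", "a3"),
                     subject_id = c("x", "y", "z"),
                     collection_order = 1, body_site = "feces")
  fl <- filter_and_dedup(as_count_table(counts), meta, min_depth = 1000,
                         site = "feces")
  expect_equal(nrow(fl$meta), 2L) # boundary inclusive at 1000

  # earliest retained specimen wins
  counts2 <- matrix(5000, 2, 1, dimnames = list(c("b1", "b2"), "t1"))
  meta2 <- data.frame(sample_id = c("b2", "b1"), subject_id = "s",
                      collection_order = c(2, 1), body_site = "feces")
  fl2 <- filter_and_dedup(as_count_table(counts2), meta2, min_depth = 1000)
  expect_equal(fl2$meta$sample_id, "b1")

  # hand-enumerated retention sequence: 6 samples, 3 subjects
  depths <- c(500, 20000, 15000, 800, 30000, 12000)
  counts3 <- matrix(depths, 6, 1,
                    dimnames = list(paste0("c", 1:6), "t1"))
  meta3 <- data.frame(sample_id = paste0("c", 1:6),
                      subject_id = c("A", "A", "A", "B", "B", "C"),
                      collection_order = c(1, 2, 3, 1, 2, 1),
                      body_site = c(rep("feces", 5), "skin"))
  fl3 <- filter_and_dedup(as_count_table(counts3), meta3, min_depth = 10000)
  # depth filter keeps c2,c3,c5,c6; site drops c6; dedup keeps c2 (A), c5 (B)
  expect_equal(unname(fl3$retention), c(6, 4, 3, 2))
  expect_setequal(fl3$meta$sample_id, c("c2", "c5"))

  # idempotence
  fl3b <- filter_and_dedup(fl3$counts, fl3$meta, min_depth = 10000)
  expect_identical(fl3b$counts, fl3$counts)
  expect_error(filter_and_dedup(as_count_table(counts3), meta3,
                                site = "tongue"), "feces")
})

test_that("detection thresholding is exact", {
  counts <- toy_counts()
  det <- detect_focal(counts, c("otuX", "otuY"))
  expect_false(det["s2", "otuX"]) # count 0
  expect_true(det["s1", "otuX"])  # count >= 1
  det5 <- detect_focal(counts, "otuX", threshold = 11)
  expect_false(det5["s1", "otuX"]) # 10 < 11
  expect_true(det5["s3", "otuX"])  # 50 >= 11
  expect_error(detect_focal(counts, "nope"), "nope")
})

test_that("focal summaries: prevalence, shares, geometric means", {
  counts <- toy_counts()
  det <- detect_focal(counts, c("otuX", "otuY"))
  s <- summarize_focal(counts, det)
  expect_equal(s$prevalence_percent[s$taxon == "otuX"], 50) # 2 of 4
  expect_equal(sum(s$share_percent), 100, tolerance = 1e-9)
  # geometric mean over detected samples only
  one <- matrix(c(1L, 100L, 9999L, 9900L), 2, 2,
                dimnames = list(c("r1", "r2"), c("f", "bg")))
  d1 <- detect_focal(as_count_table(one), "f")
  s1 <- summarize_focal(as_count_table(one), d1)
  expect_equal(s1$geo_mean_rel_abundance, 1e-3, tolerance = 1e-12)
  # never-detected taxon: NA marker, not zero
  z <- as_count_table(matrix(c(0L, 5000L), 1, 2,
                             dimnames = list("r", c("f", "bg"))))
  sz <- summarize_focal(z, detect_focal(z, "f"))
  expect_true(is.na(sz$geo_mean_rel_abundance))
})

test_that("overlap test equals exhaustive enumeration", {
  # N=10, |A|=|B|=5, full overlap: 1 / C(10,5)
  det <- matrix(FALSE, 10, 2, dimnames = list(paste0("s", 1:10), c("A", "B")))
  det[1:5, ] <- TRUE
  ot <- overlap_test(det, "A", "B")
  expect_equal(ot$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(ot$conditional_percent, 100)

  # property: hypergeometric tail equals brute-force placement counts
  set.seed(42)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    kA <- sample(1:N, 1); kB <- sample(1:N, 1)
    a <- sample(N, kA); b <- sample(N, kB)
    det <- matrix(FALSE, N, 2, dimnames = list(seq_len(N), c("A", "B")))
    det[a, 1] <- TRUE; det[b, 2] <- TRUE
    obs <- sum(det[, 1] & det[, 2])
    combos <- combn(N, kA)
    overlaps <- apply(combos, 2, function(s) length(intersect(s, b)))
    p_brute <- mean(overlaps >= obs)
    expect_equal(overlap_test(det, "A", "B")$p_value, p_brute,
                 tolerance = 1e-10)
  }
  expect_error(overlap_test(matrix(logical(0), 0, 2,
                                   dimnames = list(NULL, c("A", "B"))),
                            "A", "B"), "empty")
})

test_that("co-detection abundance shift: exact small-sample behavior", {
  # A-only relative abundances {1,2}, co-detected {3,4} (scaled): p = 1/6
  counts <- matrix(c(1, 2, 3, 4,    # taxon A
                     0, 0, 1, 1,    # taxon B presence marker
                     999, 998, 996, 995), 4, 3,
                   dimnames = list(paste0("s", 1:4), c("A", "B", "bg")))
  ctab <- as_count_table(counts)
  det <- detect_focal(ctab, c("A", "B"))
  cs <- codetection_shift(ctab, det, "A", "B")
  expect_equal(cs$p_value, 1 / 6, tolerance = 1e-12)

  # direction contract: co-detected all smaller -> p >= 0.5
  counts2 <- counts
  counts2[, "A"] <- c(30, 40, 1, 2)
  ctab2 <- as_count_table(counts2)
  cs2 <- codetection_shift(ctab2, detect_focal(ctab2, c("A", "B")), "A", "B")
  expect_gte(cs2$p_value, 0.5)

  # empty stratum errors name the stratum
  counts3 <- counts
  counts3[, "B"] <- c(1, 1, 1, 1)
  ctab3 <- as_count_table(counts3)
  expect_error(codetection_shift(ctab3, detect_focal(ctab3, c("A", "B")),
                                 "A", "B"), "alone")
})

test_that("identical strata give a calibrated one-sided shift test", {
  set.seed(7)
  ps <- replicate(200, {
    x <- rexp(15); y <- rexp(15)
    rank_test(x, y, "mann_whitney_one_sided")$p_value
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("longitudinal grouping partitions subjects exhaustively", {
  # six subjects with known detection patterns
  pats <- list(A = c(TRUE, TRUE), B = c(TRUE, FALSE), C = c(FALSE, FALSE),
               D = c(TRUE, TRUE, TRUE), E = c(FALSE, TRUE), F = c(FALSE, FALSE))
  ids <- unlist(lapply(names(pats), function(s)
    paste0(s, ".", seq_along(pats[[s]]))))
  meta <- data.frame(
    sample_id = ids,
    subject_id = rep(names(pats), lengths(pats)),
    collection_order = unlist(lapply(lengths(pats), seq_len)),
    body_site = "feces")
  y <- ifelse(unlist(pats), 50, 0)
  counts <- cbind(focal = y, bg = 10000 - y)
  rownames(counts) <- ids
  ctab <- as_count_table(counts)
  det <- detect_focal(ctab, "focal")
  lg <- longitudinal_groups(ctab, meta, det)
  tab <- table(lg$groups$group)
  expect_equal(unname(tab[c("I", "II", "III")]), c(2L, 2L, 2L),
               ignore_attr = TRUE)
  # exhaustive and exclusive
  expect_equal(nrow(lg$groups), 6L)
  expect_false(anyNA(lg$groups$group))
  # one-sided comparison produced for the focal taxon
  expect_true(is.finite(lg$comparisons$p_value[1]))
  # singleton subject errors
  meta_bad <- rbind(meta, data.frame(sample_id = "G.1", subject_id = "G",
                                     collection_order = 1,
                                     body_site = "feces"))
  counts_bad <- rbind(counts, G.1 = c(0, 10000))
  expect_error(longitudinal_groups(as_count_table(counts_bad), meta_bad,
                                   detect_focal(as_count_table(counts_bad),
                                                "focal")),
               "single sample")
})

test_that("rank tests match enumeration, wilcox.test, and Spearman limits", {
  # exact two-sided {1,2} vs {3,4}: p = 1/3
  expect_equal(rank_test(c(1, 2), c(3, 4), "mann_whitney_two_sided")$p_value,
               1 / 3, tolerance = 1e-12)
  # one-sided {3,4} over {1,2}: p = 1/6
  expect_equal(rank_test(c(3, 4), c(1, 2), "mann_whitney_one_sided")$p_value,
               1 / 6, tolerance = 1e-12)
  # cross-check exact p against wilcox.test on tie-free samples
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(rank_test(x, y, "mann_whitney_two_sided")$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(rank_test(x, y, "mann_whitney_one_sided")$p_value,
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value, tolerance = 1e-10)
  }
  # large-sample approximation close to wilcox.test's normal approx
  x <- rnorm(30); y <- rnorm(40) + 0.5
  p_pkg <- rank_test(x, y, "mann_whitney_two_sided")$p_value
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-8)

  # Spearman limits and guard
  expect_equal(rank_test(1:5, c(2, 4, 6, 8, 10), "spearman")$statistic, 1)
  expect_equal(rank_test(1:5, 5:1, "spearman")$statistic, -1)
  expect_error(rank_test(rep(1, 5), 1:5, "spearman"), "constant")
})
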