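test_that("rarefaction preserves depth and excludes shallow samples", {
  counts <- toy_counts()
  r <- rarefy_counts(counts, 5000, seed = 3)
  expect_true(all(rowSums(r) == 5000))
  expect_equal(attr(r, "excluded"), character(0))
  r2 <- rarefy_counts(counts, 9990, seed = 3)
  expect_true(all(rowSums(r2) == 9990))
  # full depth: multiset unchanged
  r3 <- rarefy_counts(counts, 10000, seed = 3)
  expect_equal(unname(r3[, ]), unname(counts[, ]))
  # shallow samples flagged, not an error
  cc <- as_count_table(matrix(c(100L, 9000L), 2, 1,
                              dimnames = list(c("lo", "hi"), "t")))
  r4 <- rarefy_counts(cc, 5000, seed = 1)
  expect_equal(attr(r4, "excluded"), "lo")
  expect_equal(nrow(r4), 1L)
  # single-taxon rows stay single-taxon
  one <- as_count_table(matrix(2000L, 1, 1, dimnames = list("s", "t")))
  expect_equal(as.numeric(rarefy_counts(one, 500, seed = 2)), 500)
  # two equal taxa: near 50/50 at large depth
  two <- as_count_table(matrix(c(50000L, 50000L), 1, 2,
                               dimnames = list("s", c("a", "b"))))
  r5 <- rarefy_counts(two, 20000, seed = 4)
  expect_lt(abs(r5[1, "a"] - 10000), 4 * sqrt(20000 * 0.25))
})

test_that("alpha metrics reproduce their closed forms", {
  # chao1 = S + F1^2/(2 F2) = 10 + 16/4 = 14
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  row <- matrix(x, 1, dimnames = list("s", sprintf("t%02d", 1:10)))
  expect_equal(unname(alpha_diversity(row, "chao1")), 14)
  # bias-corrected form when F2 = 0
  x2 <- c(rep(1, 3), rep(5, 2))
  row2 <- matrix(x2, 1, dimnames = list("s", paste0("u", 1:5)))
  expect_equal(unname(alpha_diversity(row2, "chao1")), 5 + 3 * 2 / 2)
  # shannon of 4 equal taxa = 2 bits
  eq <- matrix(rep(25, 4), 1, dimnames = list("s", paste0("t", 1:4)))
  expect_equal(unname(alpha_diversity(eq, "shannon")), 2, tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(eq, "observed_otus")), 4)
  # chao1 >= observed, equality iff no singletons
  set.seed(5)
  for (i in 1:20) {
    v <- rpois(30, 2)
    m <- matrix(v, 1, dimnames = list("s", paste0("t", 1:30)))
    ch <- alpha_diversity(m, "chao1")
    ob <- alpha_diversity(m, "observed_otus")
    expect_gte(ch, ob)
    if (sum(v == 1) == 0) expect_equal(unname(ch), unname(ob))
  }
})

test_that("Faith PD on a star tree counts unit branches of present taxa", {
  tree <- star_tree(paste0("t", 1:5))
  m <- matrix(c(3, 1, 2, 0, 0), 1, dimnames = list("s", paste0("t", 1:5)))
  expect_equal(unname(alpha_diversity(m, "faith_pd", tree = tree)), 3)
  bad <- matrix(1, 1, dimnames = list("s", "not_in_tree"))
  expect_error(alpha_diversity(bad, "faith_pd", tree = tree), "missing")
  expect_error(alpha_diversity(m, "faith_pd"), "tree")
})

test_that("alpha group comparisons: bounds, power and flags", {
  set.seed(11)
  g <- rep(c("0", "1", "2"), times = c(40, 40, 1))
  v <- c(rnorm(40), rnorm(40) + 3, 0)
  ac <- alpha_compare(v, g, seed = 2)
  expect_equal(ac$skipped, "2")
  expect_equal(nrow(ac$table), 1L) # only 0-vs-1 comparable
  expect_equal(ac$table$p_perm, 1 / 1000) # lower bound with 999 perms
  expect_lt(ac$table$p_t_bonf, 0.001)
  # reproducible given the seed
  ac2 <- alpha_compare(v, g, seed = 2)
  expect_identical(ac$table, ac2$table)
  expect_error(alpha_compare(v[81], g[81]), "two groups")
})

test_that("UniFrac matches the brute-force branch oracle", {
  tree <- star_tree(paste0("t", 1:5))
  # disjoint tip sets -> distance 1
  m <- rbind(A = c(1, 1, 0, 0, 0), B = c(0, 0, 1, 1, 0))
  colnames(m) <- paste0("t", 1:5)
  d <- beta_distance(m, "unweighted_unifrac", tree = tree)
  expect_equal(as.numeric(d), 1)
  # overlapping toy case: unique 2 of covered 3
  m2 <- rbind(A = c(1, 1, 0, 0, 0), B = c(0, 1, 1, 0, 0))
  colnames(m2) <- paste0("t", 1:5)
  d2 <- beta_distance(m2, "unweighted_unifrac", tree = tree)
  expect_equal(as.numeric(d2), 2 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(d2),
               unifrac_bruteforce(tree, c("t1", "t2"), c("t2", "t3")),
               tolerance = 1e-12)
  # property: random trees and random presence patterns
  set.seed(13)
  for (i in 1:15) {
    nt <- sample(4:9, 1)
    tr <- gen_tree(paste0("x", seq_len(nt)), seed = i)
    pres <- matrix(rbinom(2 * nt, 1, 0.6), 2,
                   dimnames = list(c("A", "B"), tr$tip.label))
    if (any(rowSums(pres) == 0)) next
    dd <- beta_distance(pres, "unweighted_unifrac", tree = tr)
    oracle <- unifrac_bruteforce(tr, tr$tip.label[pres["A", ] > 0],
                                 tr$tip.label[pres["B", ] > 0])
    expect_equal(as.numeric(dd), oracle, tolerance = 1e-10)
  }
  # identity and symmetry
  m3 <- rbind(A = c(1, 1, 0, 0, 0), B = c(1, 1, 0, 0, 0))
  colnames(m3) <- paste0("t", 1:5)
  expect_equal(as.numeric(beta_distance(m3, "unweighted_unifrac",
                                        tree = tree)), 0)
  expect_error(beta_distance(rbind(A = rep(0, 5), B = rep(1, 5)),
                             "bray_curtis"), "all-zero")
})

test_that("Bray-Curtis closed form", {
  m <- rbind(A = c(1, 1, 0), B = c(0, 1, 1))
  colnames(m) <- paste0("t", 1:3)
  expect_equal(as.numeric(beta_distance(m, "bray_curtis")), 0.5)
})

test_that("PCoA recovers geometry and reports negative eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  p <- pcoa(D)
  ev <- p$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  # Euclidean round trip up to rigid motion
  set.seed(17)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  rec <- pcoa(d)$coordinates[, 1:2]
  pr <- vegan::procrustes(pts, rec, symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)
  # duplicate samples get identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  rec2 <- pcoa(dist(pts2))$coordinates
  expect_equal(rec2[1, ], rec2[11, ], tolerance = 1e-8)
  # non-Euclidean input keeps negative eigenvalues visible
  Dn <- matrix(1, 4, 4) - diag(4)
  Dn[1, 2] <- Dn[2, 1] <- 1.9 # 3,4 cannot both sit 1 away from 1, 2 and
  dimnames(Dn) <- list(letters[1:4], letters[1:4]) # 1 from each other
  pb <- pcoa(Dn)
  expect_true(any(pb$eigenvalues < -1e-8))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA separates clusters and agrees with vegan", {
  # two tight, well-separated clusters
  set.seed(19)
  pts <- rbind(matrix(rnorm(20, 0, 0.05), 10), matrix(rnorm(20, 5, 0.05), 10))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(d, g, n_perm = 1000, seed = 5)
  expect_equal(pm$p_value, 1 / 1001)
  # pseudo-F matches vegan::adonis2 on the same distances
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-8)
  # reproducibility and guards
  expect_identical(permanova(d, g, seed = 7), permanova(d, g, seed = 7))
  expect_error(permanova(d, rep("a", 20)), "two groups")
  expect_error(permanova(d, c("a", rep("b", 19))), "n >= 2")
})

test_that("intra/intergroup distance partition matches hand counts", {
  # 4 samples, groups {1,2} and {3,4}
  D <- as.matrix(dist(c(0, 0.1, 5, 5.1)))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("x", "x", "y", "y")
  gd <- group_distance_compare(D, g)
  sets <- gd$sets
  expect_equal(sets$n_pairs[sets$label == "intra:x"], 1L)
  expect_equal(sets$n_pairs[sets$label == "intra:y"], 1L)
  expect_equal(sets$n_pairs[sets$label == "inter:x|y"], 4L)
  expect_gt(sets$mean[sets$label == "inter:x|y"],
            sets$mean[sets$label == "intra:x"])
  # duplicated points: intra means 0, inter positive
  D2 <- as.matrix(dist(c(0, 0, 3, 3)))
  dimnames(D2) <- dimnames(D)
  gd2 <- group_distance_compare(D2, g)
  expect_equal(gd2$sets$mean[gd2$sets$type == "intra"], c(0, 0))
  expect_gt(min(gd2$sets$mean[gd2$sets$type == "inter"]), 0)
  # size-1 group flagged with empty intra set
  gd3 <- group_distance_compare(D, c("x", "x", "x", "solo"))
  expect_equal(gd3$flagged, "solo")
  # bootstrap output shape
  gd4 <- group_distance_compare(D, g, bootstrap_k = 10, seed = 3)
  expect_equal(nrow(gd4$bootstrap), 20L)
})
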