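# Alpha and beta diversity, rarefaction, ordination and group tests.

#' Rarefy a count table to a fixed depth
#'
#' Subsamples reads without replacement so every retained sample has
#' exactly `depth` total reads. Samples shallower than `depth` are
#' excluded and flagged, not an error.
#'
#' @param counts Count table (samples x taxa).
#' @param depth Target depth.
#' @param seed Integer seed.
#' @return Rarefied count matrix with attribute `"excluded"` (sample ids
#'   below the target depth).
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  d <- sample_depths(counts)
  excluded <- rownames(counts)[d < depth]
  keep <- counts[d >= depth, , drop = FALSE]
  # rrarefy's "observed counts" heuristic misfires on tables whose
  # smallest positive entry exceeds 1; integrality is enforced upstream
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(keep, depth)))
  out <- as.matrix(out)
  attr(out, "excluded") <- excluded
  out
}

#' Per-sample alpha diversity
#'
#' Metrics: `"observed_otus"` (taxa with nonzero count), `"shannon"`
#' (log base 2 of the relative-abundance entropy), `"chao1"`
#' (`S + F1^2 / (2 F2)`, or the bias-corrected
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` when no doubletons exist), and
#' `"faith_pd"` (total branch length spanned by the present taxa,
#' including the path to the root).
#'
#' @param counts Count table.
#' @param metric One of `"faith_pd"`, `"chao1"`, `"shannon"`,
#'   `"observed_otus"`.
#' @param tree Rooted `phylo` tree; required for `"faith_pd"`, its tips
#'   must cover every taxon present in `counts`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(counts, metric = c("observed_otus", "shannon",
                                               "chao1", "faith_pd"),
                            tree = NULL) {
  metric <- match.arg(metric)
  switch(metric,
    observed_otus = rowSums(counts > 0),
    shannon = vegan::diversity(counts, index = "shannon", base = 2),
    chao1 = apply(counts, 1, chao1_index),
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a phylogenetic tree")
      present <- colnames(counts)[colSums(counts) > 0]
      missing <- setdiff(present, tree$tip.label)
      if (length(missing))
        stop("tree is missing tips for present taxa: ",
             paste(utils::head(missing, 5), collapse = ", "))
      pd <- picante::pd(counts, tree, include.root = TRUE)
      stats::setNames(pd$PD, rownames(counts))
    })
}

chao1_index <- function(x) {
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Pairwise group comparisons of an alpha-diversity vector
#'
#' For every pair of groups: a plain two-sample t-test (Welch by default)
#' and a Monte-Carlo permutation t-test (999 label permutations; p is
#' `(number of |t*| >= |t| + 1) / (n_perm + 1)`, so the smallest
#' attainable p is 1/1000). Bonferroni correction multiplies by the
#' number of pairwise comparisons performed. Groups with fewer than two
#' values are skipped and flagged.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (e.g. number of focal OTUs detected).
#' @param n_perm Number of label permutations (default 999).
#' @param pooled Use the pooled-variance t statistic instead of Welch.
#' @param seed Integer seed.
#' @return List: `table` (data.frame per pair: group sizes, t, `p_t`,
#'   `p_perm`, Bonferroni-corrected versions) and `skipped` (group labels
#'   with n < 2).
#' @export
alpha_compare <- function(values, groups, n_perm = 999, pooled = FALSE,
                          seed = 1L) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  skipped <- names(sizes)[sizes < 2]
  ok <- names(sizes)[sizes >= 2]
  if (length(ok) < 2L) stop("need at least two groups with n >= 2")
  pairs <- utils::combn(ok, 2)
  n_pairs <- ncol(pairs)
  rows <- with_seed(seed, lapply(seq_len(n_pairs), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- values[groups == g1]; y <- values[groups == g2]
    tt <- tryCatch(stats::t.test(x, y, var.equal = pooled),
                   error = function(e) NULL) # near-constant data
    if (is.null(tt))
      return(data.frame(group1 = g1, group2 = g2, n1 = length(x),
                        n2 = length(y), t = NA_real_, p_t = NA_real_,
                        p_perm = NA_real_))
    tobs <- unname(tt$statistic)
    pooled_v <- c(x, y)
    nx <- length(x)
    tperm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled_v), nx)
      tryCatch(stats::t.test(pooled_v[idx], pooled_v[-idx],
                             var.equal = pooled)$statistic,
               error = function(e) NA_real_)
    }, numeric(1))
    p_perm <- (sum(abs(tperm) >= abs(tobs), na.rm = TRUE) + 1) /
      (n_perm + 1)
    data.frame(group1 = g1, group2 = g2, n1 = nx, n2 = length(y),
               t = tobs, p_t = tt$p.value, p_perm = p_perm)
  }))
  tab <- do.call(rbind, rows)
  tab$p_t_bonf <- pmin(1, tab$p_t * n_pairs)
  tab$p_perm_bonf <- pmin(1, tab$p_perm * n_pairs)
  list(table = tab, skipped = skipped)
}

#' Beta-diversity distance matrix
#'
#' `"bray_curtis"` is computed on the (unrarefied) counts as
#' `1 - 2 sum(min(x, y)) / sum(x + y)`. `"unweighted_unifrac"` is the
#' fraction of the branch length covered by either sample's taxa that is
#' unique to one of them.
#'
#' @param counts Count table; no all-zero samples allowed.
#' @param metric `"unweighted_unifrac"` or `"bray_curtis"`.
#' @param tree Rooted `phylo`; required for UniFrac, tips must cover every
#'   taxon present.
#' @return A `dist` object over the samples, entries in [0, 1].
#' @export
beta_distance <- function(counts, metric = c("unweighted_unifrac",
                                             "bray_curtis"), tree = NULL) {
  metric <- match.arg(metric)
  if (any(rowSums(counts) == 0)) stop("all-zero sample in count table")
  if (metric == "bray_curtis") return(vegan::vegdist(counts, "bray"))
  if (is.null(tree)) stop("unweighted UniFrac requires a tree")
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("tree is missing tips for present taxa: ",
         paste(utils::head(missing, 5), collapse = ", "))
  unifrac_unweighted(counts, tree)
}

# edge incidence: which tips descend from each edge of the tree
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # accumulate children into parents in postorder
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  M <- matrix(FALSE, ntip, nrow(tree$edge),
              dimnames = list(tree$tip.label, NULL))
  for (e in seq_len(nrow(tree$edge))) M[desc[[tree$edge[e, 2]]], e] <- TRUE
  M
}

unifrac_unweighted <- function(counts, tree) {
  M <- edge_tip_incidence(tree) # tips x edges
  bl <- tree$edge.length
  pres <- counts[, , drop = FALSE] > 0
  # restrict to tree tip order; absent tips contribute nothing
  P <- matrix(FALSE, nrow(counts), nrow(M),
              dimnames = list(rownames(counts), rownames(M)))
  shared <- intersect(colnames(counts), rownames(M))
  P[, shared] <- pres[, shared]
  S <- (P %*% M) > 0 # samples x edges: does the sample cover the edge?
  n <- nrow(S)
  D <- matrix(0, n, n, dimnames = list(rownames(S), rownames(S)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      either <- S[i, ] | S[j, ]
      both <- S[i, ] & S[j, ]
      tot <- sum(bl[either])
      D[i, j] <- D[j, i] <- if (tot > 0) sum(bl[either & !both]) / tot else 0
    }
  }
  stats::as.dist(D)
}

#' Principal coordinates analysis
#'
#' Classical scaling of the double-centred squared-distance matrix.
#' Negative eigenvalues (from non-Euclidean dissimilarities) are reported,
#' not dropped.
#'
#' @param d A `dist` or symmetric matrix.
#' @param k Number of coordinate axes to return (default all positive).
#' @return List: `coordinates` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), `variance_percent` (relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; we report
  # the full eigenvalue spectrum ourselves, negatives included
  res <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  npos <- sum(eig > 1e-12)
  k <- k %||% npos
  k <- min(k, ncol(res$points))
  list(coordinates = res$points[, seq_len(k), drop = FALSE],
       eigenvalues = eig,
       variance_percent = 100 * pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from within- and between-group sums of squared distances;
#' the p-value is `(number of permuted F >= observed + 1) / (n_perm + 1)`.
#'
#' @param d `dist` or symmetric matrix.
#' @param groups Grouping factor, each level with n >= 2.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `pseudo_F`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 1000, seed = 1L) {
  D2 <- as.matrix(d)^2
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  fstat <- function(g) {
    ssw <- 0
    for (lv in levels(groups)) {
      idx <- which(g == lv)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  Fobs <- fstat(groups)
  with_seed(seed, {
    Fperm <- vapply(seq_len(n_perm),
                    function(i) fstat(sample(groups)), numeric(1))
    list(pseudo_F = Fobs,
         p_value = (sum(Fperm >= Fobs) + 1) / (n_perm + 1),
         n_perm = n_perm)
  })
}

#' Intra- and intergroup distance comparison
#'
#' Partitions all pairwise distances into intragroup sets (one per group)
#' and intergroup sets (one per group pair), reports mean and SEM for
#' each, and Bonferroni-corrected two-sample t-tests of every intergroup
#' set against the intragroup sets of its two member groups. Optionally
#' bootstraps the mean intragroup distance by resampling samples within
#' each group.
#'
#' @param d `dist` or symmetric matrix.
#' @param groups Grouping factor.
#' @param bootstrap_k Number of bootstrap resamples (default `NULL`, off).
#' @param seed Integer seed.
#' @return List: `sets` (data.frame: label, type, n_pairs, mean, sem),
#'   `tests` (data.frame of intergroup-vs-intragroup t-tests with
#'   Bonferroni correction), `flagged` (groups of size 1: empty intra
#'   set), `bootstrap` (data.frame of resampled intragroup means, or
#'   `NULL`).
#' @export
group_distance_compare <- function(d, groups, bootstrap_k = NULL, seed = 1L) {
  D <- as.matrix(d)
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  lv <- levels(groups)
  idx_of <- lapply(lv, function(g) which(groups == g))
  names(idx_of) <- lv
  flagged <- lv[vapply(idx_of, length, integer(1)) < 2L]
  pull_intra <- function(g) {
    i <- idx_of[[g]]
    if (length(i) < 2L) return(numeric(0))
    D[i, i][upper.tri(D[i, i])]
  }
  pull_inter <- function(g1, g2) as.vector(D[idx_of[[g1]], idx_of[[g2]]])
  sets <- list()
  for (g in lv)
    sets[[paste0("intra:", g)]] <- pull_intra(g)
  pr <- utils::combn(lv, 2)
  for (j in seq_len(ncol(pr)))
    sets[[paste0("inter:", pr[1, j], "|", pr[2, j])]] <-
      pull_inter(pr[1, j], pr[2, j])
  set_tab <- do.call(rbind, lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    data.frame(label = nm,
               type = if (startsWith(nm, "intra")) "intra" else "inter",
               n_pairs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_)
  }))
  tests <- list()
  for (j in seq_len(ncol(pr))) {
    inter_nm <- paste0("inter:", pr[1, j], "|", pr[2, j])
    for (g in pr[, j]) {
      intra <- sets[[paste0("intra:", g)]]
      if (length(intra) < 2L || length(sets[[inter_nm]]) < 2L) next
      tt <- tryCatch(stats::t.test(sets[[inter_nm]], intra),
                     error = function(e) NULL) # e.g. constant sets
      tests[[length(tests) + 1L]] <- data.frame(
        inter = inter_nm, intra = paste0("intra:", g),
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(tests)) tests$p_bonf <- pmin(1, tests$p * nrow(tests))
  boot <- NULL
  if (!is.null(bootstrap_k)) {
    boot <- with_seed(seed, {
      do.call(rbind, lapply(lv, function(g) {
        i <- idx_of[[g]]
        if (length(i) < 2L) return(NULL)
        means <- vapply(seq_len(bootstrap_k), function(b) {
          ii <- sample(i, length(i), replace = TRUE)
          sub <- D[ii, ii]
          mean(sub[upper.tri(sub)])
        }, numeric(1))
        data.frame(group = g, replicate = seq_len(bootstrap_k),
                   mean_intra = means)
      }))
    })
  }
  list(sets = set_tab, tests = tests, flagged = flagged, bootstrap = boot)
}
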