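# Sample filtering, focal-taxon detection, prevalence/abundance summaries,
# co-occurrence testing and longitudinal colonization grouping.

#' Filter samples by depth and body site, keep first specimen per subject
#'
#' Retains samples whose total read count is at least `min_depth`
#' (boundary inclusive) and whose body site matches `site`; for subjects
#' contributing several retained samples, only the earliest (lowest
#' `collection_order`) is kept. The operation is idempotent.
#'
#' @param counts Count table (samples x taxa).
#' @param meta Metadata with `sample_id`, `subject_id`, `collection_order`
#'   and `body_site` columns.
#' @param min_depth Minimum total reads per sample (default 10000).
#' @param site Body-site label to keep (default `"feces"`).
#' @return List: `counts`, `meta` (both filtered, same order), and
#'   `retention`, the per-step sample counts (input, after depth filter,
#'   after site filter, after deduplication).
#' @export
filter_and_dedup <- function(counts, meta, min_depth = 10000, site = "feces") {
  stopifnot(all(c("sample_id", "subject_id", "collection_order", "body_site")
                %in% names(meta)))
  if (!all(meta$sample_id %in% rownames(counts)))
    stop("metadata samples missing from count table")
  valid <- unique(meta$body_site)
  if (!site %in% valid)
    stop("unknown body site '", site, "'; valid sites: ",
         paste(valid, collapse = ", "))
  counts <- counts[meta$sample_id, , drop = FALSE]
  n0 <- nrow(meta)
  keep <- sample_depths(counts) >= min_depth
  n1 <- sum(keep)
  keep <- keep & meta$body_site == site
  n2 <- sum(keep)
  m <- meta[keep, , drop = FALSE]
  ord <- order(m$subject_id, m$collection_order)
  first <- !duplicated(m$subject_id[ord])
  kept_ids <- m$sample_id[ord][first]
  m <- m[m$sample_id %in% kept_ids, , drop = FALSE]
  list(counts = counts[m$sample_id, , drop = FALSE], meta = m,
       retention = c(input = n0, depth = n1, site = n2,
                     dedup = nrow(m)))
}

#' Detect focal taxa by a read-count threshold
#'
#' @param counts Count table.
#' @param focal_ids Taxon ids to score.
#' @param threshold Minimum reads to call a taxon present (default 1).
#' @return Logical matrix samples x focal taxa with attribute
#'   `"threshold"`.
#' @export
detect_focal <- function(counts, focal_ids, threshold = 1) {
  missing <- setdiff(focal_ids, colnames(counts))
  if (length(missing))
    stop("focal taxa not in table: ", paste(missing, collapse = ", "))
  det <- counts[, focal_ids, drop = FALSE] >= threshold
  attr(det, "threshold") <- threshold
  det
}

#' Prevalence and abundance summary per focal taxon
#'
#' Prevalence is the percentage of samples in which the taxon is detected;
#' `share_percent` is the taxon's percentage of all focal-taxon reads;
#' the geometric mean relative abundance is computed over detected samples
#' only (reported `NA` for a never-detected taxon, not 0).
#'
#' @param counts Count table.
#' @param detection Detection matrix from [detect_focal()] built on
#'   `counts`.
#' @return Data.frame, one row per focal taxon: `taxon`,
#'   `prevalence_percent`, `share_percent`, `geo_mean_rel_abundance`,
#'   `min_rel_abundance`, `max_rel_abundance`.
#' @export
summarize_focal <- function(counts, detection) {
  focal <- colnames(detection)
  depths <- sample_depths(counts)
  tot <- sum(counts[, focal, drop = FALSE])
  out <- lapply(focal, function(tx) {
    det <- detection[, tx]
    rel <- counts[det, tx] / depths[det]
    data.frame(taxon = tx,
               prevalence_percent = 100 * mean(det),
               share_percent = if (tot > 0) 100 * sum(counts[, tx]) / tot
                               else NA_real_,
               geo_mean_rel_abundance = if (any(det)) geometric_mean(rel)
                                        else NA_real_,
               min_rel_abundance = if (any(det)) min(rel) else NA_real_,
               max_rel_abundance = if (any(det)) max(rel) else NA_real_)
  })
  do.call(rbind, out)
}

#' Hypergeometric test of detection overlap between two taxa
#'
#' Tests whether taxa A and B are co-detected more often than expected by
#' chance, conditioning on their marginal detection counts in a universe
#' of N samples: the upper-tail hypergeometric probability of an overlap
#' at least as large as observed.
#'
#' @param detection Detection matrix covering both taxa.
#' @param taxonA,taxonB Column names in `detection`.
#' @return List: `n_universe`, `nA`, `nB`, `overlap`,
#'   `codetection_percent` (overlap / universe), `conditional_percent`
#'   (share of B-positive samples that are also A-positive), `p_value`.
#' @export
overlap_test <- function(detection, taxonA, taxonB) {
  N <- nrow(detection)
  if (N == 0L) stop("empty sample universe")
  a <- detection[, taxonA]
  b <- detection[, taxonB]
  kA <- sum(a); kB <- sum(b); x <- sum(a & b)
  p <- stats::phyper(x - 1, kA, N - kA, kB, lower.tail = FALSE)
  list(n_universe = N, nA = kA, nB = kB, overlap = x,
       codetection_percent = 100 * x / N,
       conditional_percent = if (kB > 0) 100 * x / kB else NA_real_,
       p_value = p)
}

#' Abundance shift of a taxon under co-detection
#'
#' One-sided Mann-Whitney test of whether taxon A's relative abundance is
#' higher in samples where taxon B is co-detected than in samples where A
#' alone is detected.
#'
#' @param counts Count table.
#' @param detection Detection matrix.
#' @param taxonA Taxon whose abundance is compared.
#' @param taxonB Co-detected taxon defining the strata.
#' @return List: `n_only`, `n_both`, `statistic` (Mann-Whitney U for the
#'   co-detected stratum), `p_value` (one-sided, co-detected greater).
#' @export
codetection_shift <- function(counts, detection, taxonA, taxonB) {
  a <- detection[, taxonA]; b <- detection[, taxonB]
  rel <- counts[, taxonA] / sample_depths(counts)
  only <- rel[a & !b]
  both <- rel[a & b]
  if (length(only) == 0L) stop("empty stratum: '", taxonA, "' detected alone")
  if (length(both) == 0L) stop("empty stratum: co-detection of '", taxonA,
                               "' and '", taxonB, "'")
  rt <- rank_test(both, only, kind = "mann_whitney_one_sided")
  list(n_only = length(only), n_both = length(both),
       statistic = rt$statistic, p_value = rt$p_value)
}

#' Longitudinal colonization groups
#'
#' Subjects with at least two samples are partitioned by the focal taxon's
#' detection trajectory: group I (never positive), group III (always
#' positive), group II (intermittently positive). Relative abundance in
#' the positive samples of group II is compared against group III by a
#' one-sided Mann-Whitney test (II less than III), per focal taxon and
#' for the summed focal counts; the sequencing depths of the two compared
#' sample sets are also compared (two-sided) as a depth-bias check.
#'
#' @param counts Count table.
#' @param meta Metadata restricted to subjects with >= 2 samples.
#' @param detection Detection matrix on the same samples.
#' @return List: `groups` (data.frame subject_id, group), `comparisons`
#'   (data.frame per taxon: n_II, n_III, p_value one-sided, depth_p
#'   two-sided).
#' @export
longitudinal_groups <- function(counts, meta, detection) {
  tab <- table(meta$subject_id)
  if (any(tab < 2L))
    stop("subjects with a single sample included: ",
         paste(utils::head(names(tab)[tab < 2L], 5), collapse = ", "))
  pos_any <- rowSums(detection) > 0
  bysub <- split(pos_any[match(meta$sample_id, rownames(detection))],
                 meta$subject_id)
  grp <- vapply(bysub, function(v) {
    if (!any(v)) "I" else if (all(v)) "III" else "II"
  }, character(1))
  groups <- data.frame(subject_id = names(grp), group = unname(grp),
                       row.names = NULL)
  sub_grp <- grp[meta$subject_id]
  depths <- sample_depths(counts)[meta$sample_id]
  targets <- c(colnames(detection),
               if (ncol(detection) > 1L) "focal_sum")
  comparisons <- lapply(targets, function(tx) {
    y <- if (tx == "focal_sum") {
      rowSums(counts[meta$sample_id, colnames(detection), drop = FALSE])
    } else counts[meta$sample_id, tx]
    rel <- y / depths
    selII <- sub_grp == "II" & y > 0   # positive samples of group II
    selIII <- sub_grp == "III" & y > 0 # group III samples with the taxon
    if (sum(selII) < 1L || sum(selIII) < 1L) {
      return(data.frame(taxon = tx, n_II = sum(selII), n_III = sum(selIII),
                        p_value = NA_real_, depth_p = NA_real_))
    }
    # alternative: group II abundance below group III
    rt <- rank_test(rel[selIII], rel[selII],
                    kind = "mann_whitney_one_sided")
    dp <- rank_test(depths[selII], depths[selIII],
                    kind = "mann_whitney_two_sided")
    data.frame(taxon = tx, n_II = sum(selII), n_III = sum(selIII),
               p_value = rt$p_value, depth_p = dp$p_value)
  })
  list(groups = groups, comparisons = do.call(rbind, comparisons))
}

#' Rank-based two-sample and correlation tests
#'
#' Mann-Whitney U tests use exact enumeration of all group assignments
#' when the combined sample size is at most 12, and the tie-corrected
#' normal approximation otherwise (mid-ranks for ties). The Spearman test
#' returns rho with the t-approximation p-value.
#'
#' @param x,y Numeric vectors. For `"spearman"`, paired vectors of equal
#'   length.
#' @param kind One of `"mann_whitney_one_sided"` (alternative: `x`
#'   stochastically greater than `y`), `"mann_whitney_two_sided"`,
#'   `"spearman"`.
#' @param exact_max Combined-n cutoff for exact enumeration (default 12).
#' @return List: `statistic` (U, or rho), `p_value`, `method`.
#' @export
rank_test <- function(x, y, kind = c("mann_whitney_one_sided",
                                     "mann_whitney_two_sided", "spearman"),
                      exact_max = 12L) {
  kind <- match.arg(kind)
  if (kind == "spearman") {
    stopifnot(length(x) == length(y), length(x) >= 2L)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant vector supplied to Spearman correlation")
    rho <- stats::cor(rank(x), rank(y))
    n <- length(x)
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    return(list(statistic = rho, p_value = p, method = "spearman"))
  }
  m <- length(x); n <- length(y)
  stopifnot(m >= 1L, n >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2 # pairs where x beats y
  N <- m + n
  if (N <= exact_max) {
    idx <- utils::combn(N, m)
    Us <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    p_ge <- mean(Us >= U)
    p_le <- mean(Us <= U)
    p <- if (kind == "mann_whitney_one_sided") p_ge
         else min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- if (kind == "mann_whitney_one_sided") stats::pnorm(z, lower.tail = FALSE)
         else 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p_value = p, method = method)
}
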