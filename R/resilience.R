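# Network topology and robustness: normalized centralities, natural
# connectivity, sequential-attack simulations, and resampled
# connectivity distributions with matched control taxa.

as_igraph <- function(net) {
  if (inherits(net, "signed_network")) return(net$graph)
  if (igraph::is_igraph(net)) return(net)
  if (is.matrix(net))
    return(igraph::graph_from_adjacency_matrix(net != 0, mode = "undirected",
                                               diag = FALSE))
  stop("expected a signed_network, igraph graph, or adjacency matrix")
}

#' Normalized node centralities
#'
#' Degree divided by `N - 1`; betweenness (unweighted shortest-path
#' fraction) divided by its theoretical maximum `(N - 1)(N - 2) / 2`.
#' Edge signs are ignored: topology only.
#'
#' @param net A `"signed_network"`, igraph graph, or adjacency matrix.
#' @param metric `"degree"` or `"betweenness"`.
#' @return Named numeric vector in [0, 1].
#' @export
centrality <- function(net, metric = c("degree", "betweenness")) {
  metric <- match.arg(metric)
  g <- as_igraph(net)
  N <- igraph::vcount(g)
  if (metric == "degree") {
    if (N < 2L) stop("degree centrality needs at least 2 nodes")
    return(igraph::degree(g) / (N - 1))
  }
  if (N < 3L) stop("betweenness centrality needs at least 3 nodes")
  igraph::betweenness(g, directed = FALSE, weights = NA) /
    ((N - 1) * (N - 2) / 2)
}

#' Natural connectivity of a graph
#'
#' A closed-walk robustness index based on the eigenvalues `lambda_i` of
#' the adjacency matrix. `"standard"` mode computes
#' `log(mean(exp(lambda)))/(N - log N)`; `"literal"` mode computes
#' `log(sum(exp(lambda)))/(N - log N)` (the two differ by
#' `log(N)/(N - log N)`). In standard mode an edgeless graph scores
#' exactly 0. Comparisons across networks should use one mode
#' consistently; the mode is recorded in the result's
#' `"mode"` attribute.
#'
#' @param net Graph (see [centrality()]).
#' @param mode `"standard"` (default) or `"literal"`.
#' @return Scalar with attribute `"mode"`.
#' @export
natural_connectivity <- function(net, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  g <- as_igraph(net)
  N <- igraph::vcount(g)
  if (N == 0L) stop("empty graph: natural connectivity undefined")
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  A <- (A != 0) * 1
  ev <- if (N == 1L) 0 else eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lse <- log_sum_exp(ev)
  num <- if (mode == "standard") lse - log(N) else lse
  denom <- N - log(N)
  structure(num / denom, mode = mode)
}

#' Sequential node-removal attack simulation
#'
#' Repeatedly removes the node with the highest ordering metric
#' (recomputed after every removal by default) or a uniformly random
#' node, recording natural connectivity as the network shrinks. Ties are
#' broken lexicographically by node label for determinism. The curve
#' starts at the intact network and stops when a single node remains, so
#' it has one row per network size `N, N-1, ..., 1`.
#'
#' @param net Graph (see [centrality()]).
#' @param ordering `"degree"`, `"betweenness"`, or `"random"`.
#' @param seed Integer seed (random ordering only).
#' @param mode Natural-connectivity mode.
#' @param recompute Recompute the ordering metric after each removal
#'   (default) or rank once on the intact network.
#' @return Data.frame: `remaining` (node count), `connectivity`,
#'   `removed` (label removed to reach that state; `NA` for the first
#'   row). Attribute `"ordering"` records the strategy.
#' @export
attack_simulation <- function(net, ordering = c("degree", "betweenness",
                                                "random"),
                              seed = NULL, mode = "standard",
                              recompute = TRUE) {
  ordering <- match.arg(ordering)
  g <- as_igraph(net)
  N0 <- igraph::vcount(g)
  if (N0 < 1L) stop("empty graph")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- sprintf("n%04d", seq_len(N0))
  pick_metric <- function(g) {
    if (ordering == "degree") igraph::degree(g)
    else igraph::betweenness(g, directed = FALSE, weights = NA)
  }
  res <- with_seed(seed, {
    remaining <- integer(0); conn <- numeric(0); removed <- character(0)
    remaining[1] <- N0
    conn[1] <- as.numeric(natural_connectivity(g, mode))
    removed[1] <- NA_character_
    if (ordering != "random" && !recompute) {
      m <- pick_metric(g)
      fixed_order <- names(m)[order(-m, names(m))] # lexicographic tie-break
    }
    step <- 1L
    while (igraph::vcount(g) > 1L) {
      if (ordering == "random") {
        victim <- sample(igraph::V(g)$name, 1L)
      } else if (recompute) {
        m <- pick_metric(g)
        victim <- names(m)[order(-m, names(m))][1L]
      } else {
        victim <- fixed_order[fixed_order %in% igraph::V(g)$name][1L]
      }
      g <- igraph::delete_vertices(g, victim)
      step <- step + 1L
      remaining[step] <- igraph::vcount(g)
      conn[step] <- as.numeric(natural_connectivity(g, mode))
      removed[step] <- victim
    }
    data.frame(remaining = remaining, connectivity = conn, removed = removed,
               stringsAsFactors = FALSE)
  })
  attr(res, "ordering") <- ordering
  res
}

#' Resampled natural-connectivity distributions by taxon presence
#'
#' For each of `iterations` rounds, draws `subsample` samples (without
#' replacement) from the condition-positive and condition-negative
#' sample sets, runs the full network-inference pipeline on each draw,
#' and records the natural connectivity of the resulting network. The
#' two distributions are compared with a one-sided Mann-Whitney test
#' (alternative: presence-associated connectivity greater).
#'
#' @param counts Count table (samples x species).
#' @param condition_taxon Taxon whose detection (count >= 1) splits the
#'   samples.
#' @param iterations Number of inference rounds per condition
#'   (default 100; must be >= 2 for the rank test).
#' @param subsample Samples drawn per round (default 1000).
#' @param seed Integer seed.
#' @param taxonomy Optional OTU-to-species map for [infer_network()].
#' @param mode Natural-connectivity mode.
#' @param ... Further arguments to [infer_network()] (e.g. `nlambda`,
#'   `rep_num`).
#' @return List: `present`, `absent` (numeric vectors of length
#'   `iterations`), `p_value` (one-sided Mann-Whitney), `iterations`,
#'   `subsample`.
#' @export
connectivity_distribution <- function(counts, condition_taxon,
                                      iterations = 100, subsample = 1000,
                                      seed = 1L, taxonomy = NULL,
                                      mode = "standard", ...) {
  if (iterations < 2L)
    stop("iterations must be >= 2 to compare the distributions")
  if (!condition_taxon %in% colnames(counts))
    stop("condition taxon '", condition_taxon, "' not in table")
  det <- counts[, condition_taxon] >= 1
  n_pos <- sum(det); n_neg <- sum(!det)
  if (n_pos < subsample || n_neg < subsample)
    stop("need at least ", subsample, " samples per condition (have ",
         n_pos, " positive, ", n_neg, " negative)")
  pos_ids <- rownames(counts)[det]
  neg_ids <- rownames(counts)[!det]
  run_one <- function(ids, it, cond) {
    sub <- counts[ids, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    net <- infer_network(sub, taxonomy = taxonomy,
                         seed = child_seed(seed, paste0(cond, it)), ...)
    as.numeric(natural_connectivity(net, mode))
  }
  with_seed(seed, {
    pres <- numeric(iterations); abs_ <- numeric(iterations)
    for (it in seq_len(iterations)) {
      pres[it] <- run_one(sample(pos_ids, subsample), it, "pos")
      abs_[it] <- run_one(sample(neg_ids, subsample), it, "neg")
    }
    rt <- rank_test(pres, abs_, kind = "mann_whitney_one_sided")
    list(present = pres, absent = abs_, p_value = rt$p_value,
         iterations = iterations, subsample = subsample)
  })
}

#' Select control taxa matched on prevalence and abundance
#'
#' Returns species whose detection rate falls in `prevalence_range` and
#' whose geometric-mean nonzero relative abundance falls in
#' `abundance_range`, excluding the focal taxon. An empty result is a
#' warning, not an error.
#'
#' @param counts Count table at species level.
#' @param focal Focal taxon id(s) to exclude.
#' @param prevalence_range Inclusive detection-rate bounds
#'   (default `c(0.30, 0.40)`).
#' @param abundance_range Inclusive geometric-mean relative-abundance
#'   bounds (default `c(1e-3, 1e-2)`).
#' @return Character vector of matching species.
#' @export
select_controls <- function(counts, focal = character(),
                            prevalence_range = c(0.30, 0.40),
                            abundance_range = c(1e-3, 1e-2)) {
  depths <- sample_depths(counts)
  prev <- colMeans(counts > 0)
  gm <- vapply(seq_len(ncol(counts)), function(j) {
    det <- counts[, j] > 0
    if (!any(det)) return(NA_real_)
    geometric_mean(counts[det, j] / depths[det])
  }, numeric(1))
  ok <- prev >= prevalence_range[1] & prev <= prevalence_range[2] &
    !is.na(gm) & gm >= abundance_range[1] & gm <= abundance_range[2]
  out <- setdiff(colnames(counts)[ok], focal)
  if (length(out) == 0L)
    warning("no control taxa match the prevalence/abundance ranges")
  out
}
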