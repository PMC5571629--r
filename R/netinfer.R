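# Compositional association-network inference: species aggregation,
# prevalence filtering, centered log-ratio transform, Meinshausen-
# Buhlmann neighborhood selection over a penalty path, StARS stability
# selection, and signed-edge extraction from the averaged beta matrix.

#' Aggregate, filter and CLR-transform a count table
#'
#' OTU counts are summed per species via the taxonomy map, species
#' detected in at least `prevalence_min` of samples are retained
#' (boundary inclusive), and the centered log-ratio transform of
#' `count + pseudocount` is returned.
#'
#' @param counts Count table (samples x OTUs).
#' @param taxonomy Named character vector or 2-column data.frame mapping
#'   every OTU to a species label; `NULL` treats columns as species.
#' @param prevalence_min Minimum detection fraction (default 0.20).
#' @param pseudocount Added before the log (default 1).
#' @return Object of class `"clr_matrix"`: list with `clr` (samples x
#'   species, rows sum to 0), `species_counts` (the aggregated, filtered
#'   counts), `pseudocount`, `prevalence_min`.
#' @export
prepare_matrix <- function(counts, taxonomy = NULL, prevalence_min = 0.20,
                           pseudocount = 1) {
  sp <- aggregate_species(counts, taxonomy)
  prev <- colMeans(sp > 0)
  keep <- prev >= prevalence_min
  if (!any(keep)) stop("no species pass the prevalence filter")
  sp <- sp[, keep, drop = FALSE]
  lx <- log(sp + pseudocount)
  clr <- lx - rowMeans(lx)
  structure(list(clr = clr, species_counts = sp,
                 pseudocount = pseudocount, prevalence_min = prevalence_min),
            class = "clr_matrix")
}

#' @rdname prepare_matrix
#' @export
aggregate_species <- function(counts, taxonomy = NULL) {
  if (is.null(taxonomy)) return(counts)
  if (is.data.frame(taxonomy))
    taxonomy <- stats::setNames(as.character(taxonomy[[2]]),
                                as.character(taxonomy[[1]]))
  missing <- setdiff(colnames(counts), names(taxonomy))
  if (length(missing))
    stop("taxonomy missing for OTUs: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sp <- factor(taxonomy[colnames(counts)])
  out <- t(rowsum(t(counts), sp))
  out
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat("CLR matrix:", nrow(x$clr), "samples x", ncol(x$clr), "species",
      "(pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

#' Penalty grid for neighborhood selection
#'
#' `lambda_max` is the largest absolute off-diagonal entry of the
#' empirical correlation matrix of the CLR columns; the grid is
#' log-spaced down to `lambda_max * min_ratio`.
#'
#' @param clr A `"clr_matrix"` (or plain numeric matrix).
#' @param nlambda Grid length (default 100).
#' @param min_ratio Ratio of smallest to largest penalty (default 0.2).
#' @return Strictly decreasing numeric vector of length `nlambda`, with
#'   attribute `"near_zero"` flagging a degenerate (uncorrelated) input.
#' @export
lambda_grid <- function(clr, nlambda = 100, min_ratio = 0.2) {
  S <- clr_mat(clr)
  if (ncol(S) < 2L) stop("need at least 2 species")
  stopifnot(nlambda >= 2)
  C <- stats::cor(S)
  lmax <- max(abs(C[upper.tri(C)]))
  near_zero <- lmax < 3 / sqrt(nrow(S))
  if (lmax <= 0) lmax <- .Machine$double.eps
  g <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
  attr(g, "near_zero") <- near_zero
  g
}

clr_mat <- function(clr) if (inherits(clr, "clr_matrix")) clr$clr else clr

# L1-penalized neighborhood regressions for every node over a whole
# penalty path. Columns are standardized internally; coefficients are on
# the standardized scale. Returns a p x p x nlambda array B where
# B[j, i, l] is the coefficient of species i in the regression of node j.
mb_path <- function(S, grid) {
  p <- ncol(S)
  n <- nrow(S)
  sds <- apply(S, 2, stats::sd)
  if (any(sds == 0))
    stop("constant CLR column for species: ",
         paste(colnames(S)[sds == 0], collapse = ", "))
  Z <- scale(S)
  B <- array(0, dim = c(p, p, length(grid)),
             dimnames = list(colnames(S), colnames(S), NULL))
  if (p == 2L) {
    # one predictor per regression: closed-form soft-thresholded lasso
    for (j in 1:2) {
      x <- Z[, -j]; yv <- Z[, j]
      cxy <- sum(x * yv) / n
      xx <- sum(x * x) / n
      B[j, -j, ] <- sign(cxy) * pmax(abs(cxy) - grid, 0) / xx
    }
    return(B)
  }
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Z[, -j, drop = FALSE], Z[, j], family = "gaussian",
                          lambda = grid, standardize = FALSE,
                          intercept = FALSE)
    cf <- as.matrix(fit$beta)
    # glmnet may return fewer columns than requested if it stops early
    l_used <- ncol(cf)
    B[j, -j, seq_len(l_used)] <- cf
    if (l_used < length(grid))
      for (l in (l_used + 1):length(grid)) B[j, -j, l] <- cf[, l_used]
  }
  B
}

#' Neighborhood selection at a single penalty
#'
#' For each species, an L1-penalized linear regression of its CLR column
#' on all other columns (standardized; coefficients on the standardized
#' scale). An edge is present if either directional coefficient is
#' nonzero (union rule).
#'
#' @param clr A `"clr_matrix"` or numeric matrix.
#' @param lambda Penalty, > 0.
#' @return List: `beta` (p x p coefficient matrix, `beta[j, i]` the
#'   coefficient of i in the regression of j), `edges` (logical p x p
#'   symmetric adjacency).
#' @export
mb_fit <- function(clr, lambda) {
  stopifnot(lambda > 0)
  S <- clr_mat(clr)
  B <- mb_path(S, c(lambda))[, , 1]
  A <- (B != 0) | (t(B) != 0)
  diag(A) <- FALSE
  list(beta = B, edges = A)
}

#' StARS stability selection of the penalty
#'
#' For every penalty on the grid, the edge-selection frequency over
#' `rep_num` random subsamples (without replacement) gives the per-edge
#' instability `2 theta (1 - theta)`; the graph instability `D(lambda)`
#' is its mean over all node pairs. `D` is monotonized from the sparsest
#' to the densest end of the path and the densest penalty with
#' monotonized instability at most `beta` is selected; the final network
#' is fitted on the full data at that penalty.
#'
#' @param clr A `"clr_matrix"` or numeric matrix.
#' @param grid Penalty grid from [lambda_grid()].
#' @param rep_num Number of subsamples (default 20; must be >= 2).
#' @param beta Instability threshold (default 0.05).
#' @param subsample_size Subsample size; default `ceiling(10 sqrt(n))`
#'   for n > 144, else `0.8 n`.
#' @param seed Integer seed.
#' @return List: `lambda_opt`, `opt_index`, `instability` (raw D per
#'   penalty), `instability_mono`, `stability` (p x p matrix of edge
#'   selection frequencies at the selected penalty), `beta_full`
#'   (full-data coefficient matrix at the selected penalty), `edges`
#'   (full-data adjacency), `grid`.
#' @export
stars_select <- function(clr, grid, rep_num = 20, beta = 0.05,
                         subsample_size = NULL, seed = 1L) {
  if (rep_num < 2L) stop("rep_num must be at least 2 for stability estimates")
  S <- clr_mat(clr)
  n <- nrow(S)
  p <- ncol(S)
  b <- subsample_size %||%
    (if (n > 144) ceiling(10 * sqrt(n)) else floor(0.8 * n))
  if (b >= n) stop("subsample size must be smaller than n")
  nl <- length(grid)
  npair <- p * (p - 1) / 2
  up <- upper.tri(matrix(0, p, p))
  freq <- matrix(0, npair, nl) # selection counts per edge per lambda
  with_seed(seed, {
    for (r in seq_len(rep_num)) {
      idx <- sample.int(n, b)
      B <- mb_path(S[idx, , drop = FALSE], grid)
      for (l in seq_len(nl)) {
        A <- (B[, , l] != 0) | (t(B[, , l]) != 0)
        freq[, l] <- freq[, l] + A[up]
      }
    }
  })
  theta <- freq / rep_num
  D <- colMeans(2 * theta * (1 - theta))
  Dmono <- cummax(D) # grid is sparsest (index 1) -> densest
  admissible <- which(Dmono <= beta)
  if (length(admissible) == 0L) {
    # even the sparsest penalty is unstable: fall back to it (the
    # most-regularized model), as stability selection prescribes
    warning("instability exceeds the threshold along the whole path; ",
            "returning the sparsest penalty")
    opt <- 1L
  } else {
    opt <- max(admissible)
  }
  Bfull <- mb_path(S, grid)
  Bopt <- Bfull[, , opt]
  A <- (Bopt != 0) | (t(Bopt) != 0)
  diag(A) <- FALSE
  stab <- matrix(0, p, p, dimnames = dimnames(Bopt))
  stab[up] <- theta[, opt]
  stab <- stab + t(stab)
  list(lambda_opt = grid[opt], opt_index = opt,
       instability = D, instability_mono = Dmono,
       stability = stab, beta_full = Bopt, edges = A, grid = grid)
}

#' Signed association network from a selected neighborhood fit
#'
#' Edge sign is the sign of the mean of the two directional coefficients;
#' if the mean is exactly zero while both are nonzero, the sign of the
#' larger-magnitude coefficient is used. Stability scores come from the
#' StARS selection frequencies.
#'
#' @param fit Output of [stars_select()] (or a list with `beta_full`,
#'   `edges`, `stability`, `lambda_opt`).
#' @return Object of class `"signed_network"`: list with `graph` (an
#'   igraph object whose edges carry `sign` ("+"/"-"), `stability` and
#'   `mean_coef` attributes), `lambda`, `nodes`.
#' @export
build_network <- function(fit) {
  B <- fit$beta_full
  A <- fit$edges
  p <- nrow(B)
  nodes <- rownames(B)
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  el <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                   stringsAsFactors = FALSE)
  mean_coef <- sign_chr <- stability <- numeric(nrow(idx))
  sign_chr <- character(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    b1 <- B[i, j]; b2 <- B[j, i]
    m <- (b1 + b2) / 2
    s <- if (m != 0) sign(m) else sign(c(b1, b2)[which.max(abs(c(b1, b2)))])
    mean_coef[r] <- m
    sign_chr[r] <- if (s >= 0) "+" else "-"
    stability[r] <- if (!is.null(fit$stability)) fit$stability[i, j] else NA
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (nrow(el)) {
    igraph::E(g)$sign <- sign_chr
    igraph::E(g)$stability <- stability
    igraph::E(g)$mean_coef <- mean_coef
  }
  structure(list(graph = g, lambda = fit$lambda_opt, nodes = nodes),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  ne <- igraph::ecount(x$graph)
  cat("Signed association network:", length(x$nodes), "species,",
      ne, "edges")
  if (ne) {
    s <- table(igraph::E(x$graph)$sign)
    cat(" (", paste(names(s), s, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("; lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Full network-inference pipeline
#'
#' Aggregation, prevalence filter, CLR, penalty grid, StARS selection and
#' signed-edge extraction, with the defaults used throughout the package
#' (nlambda 100, min_ratio 0.2, rep_num 20, beta 0.05).
#'
#' @inheritParams prepare_matrix
#' @inheritParams stars_select
#' @param nlambda,min_ratio Passed to [lambda_grid()].
#' @return A `"signed_network"` with the `stars_select()` result attached
#'   as attribute `"selection"`.
#' @export
infer_network <- function(counts, taxonomy = NULL, prevalence_min = 0.20,
                          pseudocount = 1, nlambda = 100, min_ratio = 0.2,
                          rep_num = 20, beta = 0.05, subsample_size = NULL,
                          seed = 1L) {
  cm <- prepare_matrix(counts, taxonomy, prevalence_min, pseudocount)
  grid <- lambda_grid(cm, nlambda, min_ratio)
  sel <- stars_select(cm, grid, rep_num = rep_num, beta = beta,
                      subsample_size = subsample_size, seed = seed)
  net <- build_network(sel)
  attr(net, "selection") <- sel
  net
}

#' Write a signed network as an edge-list TSV and GraphML
#'
#' @param net A `"signed_network"`.
#' @param path Output TSV path; a `.graphml` twin is written alongside.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  g <- net$graph
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(g, sub("\\.tsv$", ".graphml", path), format = "graphml")
  invisible(path)
}
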