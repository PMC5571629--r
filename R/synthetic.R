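# Synthetic AGP-like cohorts with known ground truth. The generator is
# first-class: every downstream stage of the package is validated against
# data whose detection model, abundance model and conditional-dependence
# graph are known exactly.

#' Describe a synthetic cohort
#'
#' @param n_subjects Positive integer.
#' @param samples_per_subject Probability vector over 1..5 repeat samples
#'   per subject (default: most subjects sampled once).
#' @param covariates List of covariate specs, each a list with `name`,
#'   `type` (`"continuous"` or `"categorical"`), and for categorical
#'   `levels` (+ optional `probs`), for continuous `mean`/`sd`;
#'   `missing_rate` in [0, 1).
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters.
#'   Defaults give a median depth of 2e4 reads so a 1e4-read inclusion
#'   filter is exercised non-trivially.
#' @param body_sites Named probability vector of body sites.
#' @param seed Integer seed.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects,
                        samples_per_subject = c(0.96, 0.02, 0.01, 0.006, 0.004),
                        covariates = default_covariates(),
                        depth_meanlog = log(2e4), depth_sdlog = 0.6,
                        body_sites = c(feces = 1),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive integer")
  stopifnot(length(samples_per_subject) == 5L,
            all(samples_per_subject >= 0),
            sum(samples_per_subject) > 0)
  for (cv in covariates) {
    mr <- cv$missing_rate %||% 0
    if (mr >= 1) stop("missing_rate must be < 1 for covariate ", cv$name)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 samples_per_subject = samples_per_subject / sum(samples_per_subject),
                 covariates = covariates,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 body_sites = body_sites, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_covariates <- function() {
  list(
    list(name = "age", type = "continuous", mean = 45, sd = 15,
         missing_rate = 0.02),
    list(name = "sex", type = "categorical",
         levels = c("Female", "Male"), probs = c(0.55, 0.45),
         missing_rate = 0.02),
    list(name = "race", type = "categorical",
         levels = c("Caucasian", "Asian", "Hispanic", "AfricanAmerican", "Other"),
         probs = c(0.75, 0.1, 0.07, 0.05, 0.03), missing_rate = 0.05),
    list(name = "bmi_cat", type = "categorical",
         levels = c("Normal", "Underweight", "Overweight", "Obese"),
         probs = c(0.5, 0.05, 0.3, 0.15), missing_rate = 0.1),
    list(name = "antibiotic_history", type = "categorical",
         levels = c("None_past_year", "Within_year"),
         probs = c(0.7, 0.3), missing_rate = 0.1),
    list(name = "country", type = "categorical",
         levels = c("USA", "UK"), probs = c(0.8, 0.2), missing_rate = 0.02)
  )
}

#' Generate per-sample metadata for a synthetic cohort
#'
#' Host covariates are drawn once per subject (they are host features) and
#' repeated across that subject's samples; repeat samples get a strictly
#' increasing `collection_order`. Missing values are injected per subject
#' at the spec'd rates. A `depth` column holds the log-normal total read
#' count per sample.
#'
#' @param spec A [cohort_spec()].
#' @return Data.frame: `sample_id`, `subject_id`, `collection_order`,
#'   `body_site`, `depth`, plus one column per covariate.
#' @export
gen_metadata <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_subjects
    nsamp <- sample.int(5L, ns, replace = TRUE, prob = spec$samples_per_subject)
    subj <- sprintf("S%05d", seq_len(ns))
    cov_df <- data.frame(row.names = seq_len(ns))
    for (cv in spec$covariates) {
      v <- if (cv$type == "continuous") {
        stats::rnorm(ns, cv$mean %||% 0, cv$sd %||% 1)
      } else {
        sample(cv$levels, ns, replace = TRUE,
               prob = cv$probs %||% rep(1, length(cv$levels)))
      }
      mr <- cv$missing_rate %||% 0
      if (mr > 0) v[stats::runif(ns) < mr] <- NA
      cov_df[[cv$name]] <- v
    }
    idx <- rep(seq_len(ns), nsamp)
    ord <- sequence(nsamp)
    n <- length(idx)
    meta <- data.frame(
      sample_id = sprintf("%s.%d", subj[idx], ord),
      subject_id = subj[idx],
      collection_order = ord,
      body_site = sample(names(spec$body_sites), n, replace = TRUE,
                         prob = spec$body_sites),
      depth = pmax(1, round(stats::rlnorm(n, spec$depth_meanlog,
                                          spec$depth_sdlog))),
      stringsAsFactors = FALSE)
    cbind(meta, cov_df[idx, , drop = FALSE], row.names = NULL)
  })
}

#' Ground truth for the focal-taxon detection/abundance model
#'
#' Coefficients are named by design columns of [build_design()] applied to
#' the generated metadata (intercept first). The generator inverts the
#' zero-inflated model fitted downstream: structural absence with
#' probability `plogis(x'gamma + log T)`, otherwise an NB count with mean
#' `T * exp(x'beta)` and dispersion `k`. `coupling` is a shared latent
#' Bernoulli factor added (centred, on the logit scale) to every focal
#' taxon's zero component, inducing co-detection beyond what covariates
#' explain.
#'
#' @param gamma Matrix (design columns x focal taxa) of logistic
#'   coefficients, or a vector for a single taxon.
#' @param beta Matrix/vector of count-component coefficients.
#' @param dispersion Positive NB dispersion(s), recycled across taxa.
#' @param coupling Log-odds magnitude of the shared co-detection factor.
#' @param covariates,references Covariates used to build the design.
#' @return Object of class `"focal_truth"`.
#' @export
focal_model_truth <- function(gamma, beta, dispersion = 1, coupling = 0,
                              covariates = character(), references = NULL) {
  gamma <- as.matrix(gamma)
  beta <- as.matrix(beta)
  stopifnot(ncol(gamma) == ncol(beta), nrow(gamma) == nrow(beta))
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  m <- ncol(gamma)
  if (is.null(colnames(gamma)))
    colnames(gamma) <- colnames(beta) <- sprintf("focal_%d", seq_len(m))
  structure(list(gamma = gamma, beta = beta,
                 dispersion = rep_len(dispersion, m),
                 coupling = coupling,
                 covariates = covariates, references = references),
            class = "focal_truth")
}

#' Simulate focal-taxon counts from known truth
#'
#' @param meta Metadata from [gen_metadata()] (no missing values allowed in
#'   the continuous covariates used by `truth`; categorical missingness is
#'   routed through the hidden category, as in the fitted model).
#' @param truth A [focal_model_truth()].
#' @param depths Positive total read counts (default `meta$depth`).
#' @param seed Integer seed.
#' @return Count matrix, samples x focal taxa, with a `"latent_coupling"`
#'   attribute holding the shared Bernoulli draw.
#' @export
gen_focal_counts <- function(meta, truth, depths = meta$depth, seed = 1L) {
  stopifnot(inherits(truth, "focal_truth"))
  if (any(depths <= 0)) stop("depths must be positive")
  d <- build_design(meta, truth$covariates, references = truth$references,
                    depth = depths)
  if (length(d$keep) != nrow(meta))
    stop("metadata has missing continuous covariates; impute or subset first")
  X <- d$X
  need <- rownames(truth$gamma)
  if (!is.null(need)) {
    if (!all(need %in% colnames(X)))
      stop("truth coefficients reference design columns not present: ",
           paste(setdiff(need, colnames(X)), collapse = ", "))
    X <- X[, need, drop = FALSE]
  } else if (nrow(truth$gamma) != ncol(X)) {
    stop("truth coefficient length does not match design columns")
  }
  n <- nrow(X)
  m <- ncol(truth$gamma)
  with_seed(seed, {
    u <- stats::rbinom(n, 1, 0.5) # shared co-detection factor
    counts <- matrix(0, n, m,
                     dimnames = list(meta$sample_id, colnames(truth$gamma)))
    for (j in seq_len(m)) {
      eta_z <- drop(X %*% truth$gamma[, j]) + log(depths) +
        truth$coupling * (u - 0.5)
      eta_c <- drop(X %*% truth$beta[, j]) + log(depths)
      pi_ <- stats::plogis(eta_z)
      z <- stats::rbinom(n, 1, pi_)
      y <- stats::rnbinom(n, size = truth$dispersion[j], mu = exp(eta_c))
      counts[, j] <- ifelse(z == 1, 0, y)
    }
    attr(counts, "latent_coupling") <- u
    counts
  })
}

#' Ground truth for the background community's dependence graph
#'
#' Latent log-abundances follow a multivariate normal whose precision
#' matrix encodes a known sparse conditional-dependence graph; observed
#' counts are a multinomial draw from the softmax of the latent vector
#' (logistic-normal-multinomial).
#'
#' @param precision Symmetric positive-definite matrix, or `NULL` to build
#'   one from `graph`.
#' @param p Number of species (when building from `graph`).
#' @param graph `"chain"`, `"hub"`, `"empty"`, or `"random"`.
#' @param strength Off-diagonal precision magnitude (association strength;
#'   edges carry `-strength`, giving positive partial correlations).
#' @param negative_edges Number of edges flipped to `+strength`
#'   (negative associations), taken from the start of the edge list.
#' @param base_log_abundance Mean latent log-abundances (length `p`);
#'   default a gently decaying gradient so species differ in typical share.
#' @param prob Edge probability for `graph = "random"`.
#' @param seed Seed for the random graph pattern (used only when
#'   `graph = "random"`).
#' @return Object of class `"community_truth"` with fields `precision`,
#'   `edges` (2-column matrix of the off-diagonal zero pattern),
#'   `base_log_abundance`, `species`.
#' @export
community_truth <- function(precision = NULL, p = NULL,
                            graph = c("chain", "hub", "empty", "random"),
                            strength = 0.45, negative_edges = 0,
                            base_log_abundance = NULL, prob = 0.1,
                            seed = 1L) {
  if (is.null(precision)) {
    graph <- match.arg(graph)
    stopifnot(!is.null(p), p >= 2)
    A <- matrix(0, p, p)
    if (graph == "chain") {
      for (i in seq_len(p - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    } else if (graph == "hub") {
      # groups of hub_size nodes, each a star around its first member
      hub_size <- 5L
      grp <- split(seq_len(p), ceiling(seq_len(p) / hub_size))
      for (g in grp) {
        if (length(g) < 2L) next
        A[g[1], g[-1]] <- A[g[-1], g[1]] <- 1
      }
      strength <- min(strength, 0.9 / sqrt(max(rowSums(A))))
    } else if (graph == "random") {
      A[upper.tri(A)] <- with_seed(seed, stats::rbinom(p * (p - 1) / 2, 1, prob))
      A <- A + t(A)
    }
    precision <- diag(p) - strength * A
    if (negative_edges > 0) {
      e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
      flip <- e[seq_len(min(negative_edges, nrow(e))), , drop = FALSE]
      precision[flip] <- strength
      precision[flip[, 2:1, drop = FALSE]] <- strength
    }
    # guarantee positive definiteness
    ev <- min(eigen(precision, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-6) precision <- precision + (1e-6 - ev + 0.05) * diag(p)
  }
  p <- nrow(precision)
  if (!isSymmetric(unname(precision), tol = 1e-10))
    stop("precision matrix must be symmetric")
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix must be positive definite")
  species <- colnames(precision) %||% sprintf("sp%03d", seq_len(p))
  dimnames(precision) <- list(species, species)
  off <- abs(precision) > 1e-12 & upper.tri(precision)
  edges <- which(off, arr.ind = TRUE)
  base <- base_log_abundance %||% seq(1, 0, length.out = p)
  structure(list(precision = precision, edges = unname(edges),
                 base_log_abundance = base, species = species),
            class = "community_truth")
}

#' Simulate compositional community counts
#'
#' @param n Number of samples.
#' @param truth A [community_truth()].
#' @param depths Positive integer read depths, length `n` (recycled).
#' @param seed Integer seed.
#' @return Count matrix (samples x species) with attribute `"latent"`
#'   holding the latent Gaussian draws.
#' @export
gen_community <- function(n, truth, depths, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"), n >= 1)
  depths <- rep_len(depths, n)
  if (any(depths <= 0)) stop("depths must be positive")
  sigma <- solve(truth$precision)
  with_seed(seed, {
    Z <- MASS::mvrnorm(n, mu = truth$base_log_abundance, Sigma = sigma)
    if (n == 1L) Z <- matrix(Z, nrow = 1)
    P <- exp(Z - apply(Z, 1, max))
    P <- P / rowSums(P)
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, depths[i], P[i, ])[, 1],
                       numeric(ncol(P))))
    dimnames(counts) <- list(sprintf("sample_%05d", seq_len(n)), truth$species)
    attr(counts, "latent") <- Z
    counts
  })
}

#' Random rooted phylogeny over a taxon set
#'
#' @param taxa Character vector of (unique) tip labels, length >= 2.
#' @param seed Integer seed.
#' @param rate Rate of the exponential branch-length distribution.
#' @return A rooted binary `phylo` tree with positive branch lengths.
#' @export
gen_tree <- function(taxa, seed = 1L, rate = 10) {
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  with_seed(seed, {
    tr <- ape::rtree(length(taxa), rooted = TRUE,
                     br = function(k) stats::rexp(k, rate) + 1e-6)
    tr$tip.label <- sample(taxa) # random placement, bijective labelling
    tr
  })
}

#' Assemble a complete synthetic dataset
#'
#' Generates metadata, background community counts at the drawn depths,
#' focal-taxon counts, a phylogeny over all taxa, and returns everything
#' with the generating truth attached. Focal columns are appended to the
#' community table, so row sums equal the drawn community depth plus the
#' focal counts.
#'
#' @param spec A [cohort_spec()].
#' @param focal_truth A [focal_model_truth()].
#' @param community_truth A [community_truth()].
#' @return List: `counts` (samples x (species + focal)), `meta`, `tree`,
#'   `truth` (list of the three truth objects), `focal_ids`.
#' @export
assemble_dataset <- function(spec, focal_truth, community_truth) {
  meta <- gen_metadata(spec)
  focal <- gen_focal_counts(meta, focal_truth, depths = meta$depth,
                            seed = child_seed(spec$seed, "focal"))
  comm <- gen_community(nrow(meta), community_truth, depths = meta$depth,
                        seed = child_seed(spec$seed, "community"))
  rownames(comm) <- meta$sample_id
  if (length(intersect(colnames(comm), colnames(focal))))
    stop("taxon-name collision between community and focal taxa")
  counts <- as_count_table(cbind(comm, focal))
  tree <- gen_tree(colnames(counts), seed = child_seed(spec$seed, "tree"))
  list(counts = counts, meta = meta, tree = tree,
       truth = list(spec = spec, focal = focal_truth,
                    community = community_truth),
       focal_ids = colnames(focal))
}

#' Write a synthetic dataset bundle to disk
#'
#' Counts as TSV and BIOM JSON, metadata as TSV, tree as Newick, and the
#' generating parameters as JSON.
#'
#' @param dataset Output of [assemble_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  write_count_biom(dataset$counts, file.path(dir, "counts.biom"))
  write_metadata_tsv(dataset$meta, file.path(dir, "metadata.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(focal_ids = dataset$focal_ids,
         focal = list(gamma = truth$focal$gamma, beta = truth$focal$beta,
                      dispersion = truth$focal$dispersion,
                      coupling = truth$focal$coupling),
         community_edges = truth$community$edges,
         n_subjects = truth$spec$n_subjects,
         seed = truth$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
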