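# Small fixtures built in code, shared across test files.

# toy count table with explicit depths and focal taxa
toy_counts <- function() {
  m <- rbind(
    s1 = c(bgA = 9990, bgB = 0,    otuX = 10, otuY = 0),
    s2 = c(bgA = 5000, bgB = 4900, otuX = 0,  otuY = 100),
    s3 = c(bgA = 8000, bgB = 1930, otuX = 50, otuY = 20),
    s4 = c(bgA = 7000, bgB = 3000, otuX = 0,  otuY = 0))
  as_count_table(m)
}

toy_meta <- function() {
  data.frame(sample_id = c("s1", "s2", "s3", "s4"),
             subject_id = c("A", "A", "B", "C"),
             collection_order = c(1, 2, 1, 1),
             body_site = c("feces", "feces", "feces", "skin"),
             depth = c(10000, 10000, 10000, 10000),
             stringsAsFactors = FALSE)
}

# star tree: all tips hang off the root with unit branch lengths
star_tree <- function(tips) {
  n <- length(tips)
  txt <- paste0("(", paste0(tips, ":1", collapse = ","), "):0;")
  ape::read.tree(text = txt)
}

# quick synthetic cohort for model tests: single-visit subjects,
# complete covariates, constant-ish depths
quick_cohort <- function(n, seed = 1, depth_sdlog = 0.4) {
  spec <- cohort_spec(
    n_subjects = n,
    samples_per_subject = c(1, 0, 0, 0, 0),
    covariates = list(
      list(name = "age", type = "continuous", mean = 45, sd = 15,
           missing_rate = 0),
      list(name = "sex", type = "categorical",
           levels = c("Female", "Male"), probs = c(0.5, 0.5),
           missing_rate = 0)),
    depth_sdlog = depth_sdlog, seed = seed)
  gen_metadata(spec)
}

# truth for an intercept + age + sex ZINB generator; pi targets ~0.6 at
# the median depth through the literal log-depth offset in the logit
quick_truth <- function(k = 1, coupling = 0, gamma_extra = c(0.02, -0.5),
                        beta_extra = c(0.01, 0.3), n_focal = 1) {
  nm <- c("(Intercept)", "age", "sex_Male")
  g <- matrix(rep(c(qlogis(0.6) - log(2e4), gamma_extra), n_focal),
              ncol = n_focal, dimnames = list(nm, NULL))
  b <- matrix(rep(c(-8.5, beta_extra), n_focal), ncol = n_focal,
              dimnames = list(nm, NULL))
  focal_model_truth(g, b, dispersion = k, coupling = coupling,
                    covariates = c("age", "sex"),
                    references = c(sex = "Female"))
}

# precision/recall of a recovered edge set against a community_truth
edge_precision_recall <- function(adj, truth) {
  p <- nrow(adj)
  tru <- matrix(FALSE, p, p)
  for (r in seq_len(nrow(truth$edges)))
    tru[truth$edges[r, 1], truth$edges[r, 2]] <- TRUE
  tru <- tru | t(tru)
  up <- upper.tri(adj)
  tp <- sum(adj & tru & up)
  fp <- sum(adj & !tru & up)
  fn <- sum(!adj & tru & up)
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

# brute-force unweighted UniFrac: enumerate branches, classify each as
# shared/unique by set membership of its descendant tips
unifrac_bruteforce <- function(tree, tips_a, tips_b) {
  desc_tips <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tl <- desc_tips(tree$edge[e, 2])
    inA <- any(tl %in% tips_a); inB <- any(tl %in% tips_b)
    if (inA || inB) {
      den <- den + tree$edge.length[e]
      if (xor(inA, inB)) num <- num + tree$edge.length[e]
    }
  }
  if (den == 0) 0 else num / den
}
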