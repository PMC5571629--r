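# End-to-end orchestration of the analysis flow on synthetic or user
# data: screening -> abundance modelling -> diversity -> network
# inference -> resilience, with per-stage artifacts and a manifest.

#' Assemble a pipeline run configuration
#'
#' Every stochastic stage receives an explicit seed derived from the
#' master seed. Values given in `...` override the defaults.
#'
#' @param focal_ids Focal taxon ids (required).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides: `min_depth`, `site`, `covariates`, `references`,
#'   `candidates`, `baseline`, `rarefaction_depth`, `alpha_metrics`,
#'   `beta_metric`, `nlambda`, `min_ratio`, `rep_num`, `stars_beta`,
#'   `subsample_size`, `run_connectivity_distribution`, `iterations`,
#'   `subsample`, `n_perm`.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(focal_ids, out_dir = tempfile("focalecol_run_"),
                       seed = 1L, ...) {
  cfg <- list(
    focal_ids = focal_ids, out_dir = out_dir, seed = as.integer(seed),
    min_depth = 10000, site = "feces",
    covariates = NULL, references = NULL, candidates = NULL,
    baseline = c("age", "sex", "race"),
    rarefaction_depth = NULL,
    alpha_metrics = c("observed_otus", "shannon", "chao1", "faith_pd"),
    beta_metric = "unweighted_unifrac",
    n_perm = 1000,
    prevalence_min = 0.20, pseudocount = 1,
    nlambda = 100, min_ratio = 0.2, rep_num = 20, stars_beta = 0.05,
    subsample_size = NULL,
    run_connectivity_distribution = FALSE, iterations = 20, subsample = 200)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes screening, zero-inflated abundance modelling, diversity,
#' network inference and resilience on a count table + metadata (+ tree),
#' writing per-stage TSV/JSON artifacts, a machine-readable manifest and
#' a human-readable summary under `config$out_dir`. A stage failure
#' halts the run with the stage name; artifacts of completed stages are
#' preserved.
#'
#' @param counts Count table (samples x taxa).
#' @param meta Metadata (see [filter_and_dedup()]).
#' @param config A [run_config()].
#' @param tree Rooted `phylo` (required for Faith PD / UniFrac).
#' @param taxonomy Optional OTU-to-species map for the network stage.
#' @return Invisibly, a list of per-stage results plus the manifest.
#' @export
run_pipeline <- function(counts, meta, config, tree = NULL, taxonomy = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stages_done <- character(0)
  manifest <- list(package = "focalecol",
                   version = as.character(utils::packageVersion("focalecol")),
                   seed = config$seed,
                   parameters = unclass(config))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      write_json_artifact(
        c(manifest, list(stages = stages_done, failed_stage = name,
                         error = conditionMessage(e))),
        file.path(out, "manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    res
  }

  results$screening <- stage("screening", {
    fl <- filter_and_dedup(counts, meta, config$min_depth, config$site)
    det <- detect_focal(fl$counts, config$focal_ids)
    summ <- summarize_focal(fl$counts, det)
    utils::write.table(summ, file.path(out, "focal_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- NULL
    if (length(config$focal_ids) >= 2) {
      pr <- utils::combn(config$focal_ids, 2)
      ov <- lapply(seq_len(ncol(pr)), function(j) {
        o <- overlap_test(det, pr[1, j], pr[2, j])
        c(list(taxonA = pr[1, j], taxonB = pr[2, j]), o)
      })
    }
    # longitudinal grouping on the pre-dedup multi-sample subjects
    keep0 <- meta$body_site == config$site &
      sample_depths(counts[meta$sample_id, , drop = FALSE]) >= config$min_depth
    m_all <- meta[keep0, , drop = FALSE]
    multi <- names(which(table(m_all$subject_id) >= 2))
    longi <- NULL
    if (length(multi) >= 2) {
      m2 <- m_all[m_all$subject_id %in% multi, , drop = FALSE]
      det2 <- detect_focal(counts[m2$sample_id, , drop = FALSE],
                           config$focal_ids)
      longi <- longitudinal_groups(counts[m2$sample_id, , drop = FALSE],
                                   m2, det2)
    }
    write_json_artifact(list(retention = as.list(fl$retention),
                             overlap = ov,
                             longitudinal_groups =
                               if (!is.null(longi)) table(longi$groups$group)),
                        file.path(out, "screening.json"))
    list(filtered = fl, detection = det, summary = summ, overlap = ov,
         longitudinal = longi)
  })

  fl <- results$screening$filtered
  det <- results$screening$detection
  y <- round(rowSums(fl$counts[, config$focal_ids, drop = FALSE]))

  results$zinb <- stage("zinb", {
    covs <- config$covariates %||%
      setdiff(names(fl$meta),
              c("sample_id", "subject_id", "collection_order", "body_site",
                "depth"))
    cand <- config$candidates %||% covs
    scr <- univariate_screen(y, fl$meta, cand,
                             baseline = intersect(config$baseline, cand),
                             references = config$references)
    d <- build_design(fl$meta, scr$selected, references = config$references)
    fit <- zinb_fit(y[d$keep], d, family = "negbin")
    fit_zip <- zinb_fit(y[d$keep], d, family = "poisson")
    cmp <- compare_models(fit, fit_zip)
    apv <- lapply(intersect(scr$selected, names(d$levels)), function(cv)
      apv_proportions(fit, d, cv))
    s <- summary(fit)
    tab <- rbind(cbind(component = "logistic", s$zero),
                 cbind(component = "negbin", s$count))
    utils::write.table(tab, file.path(out, "zinb_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_artifact(list(screen = scr$table,
                             aic = fit$aic, bic = fit$bic,
                             loglik = fit$loglik, df = fit$df,
                             zip_aic = fit_zip$aic, lrt_p = cmp$lrt_p,
                             apv = apv),
                        file.path(out, "zinb.json"))
    list(screen = scr, design = d, fit = fit, fit_zip = fit_zip,
         comparison = cmp, apv = apv)
  })

  results$diversity <- stage("diversity", {
    groups <- rowSums(det)
    metrics <- config$alpha_metrics
    if (is.null(tree) && any(metrics == "faith_pd"))
      stop("faith_pd requested but no phylogenetic tree was supplied")
    rdepth <- config$rarefaction_depth %||% config$min_depth
    rare <- rarefy_counts(fl$counts, rdepth,
                          seed = child_seed(config$seed, "rarefy"))
    gr <- groups[rownames(rare)]
    alpha <- lapply(metrics, function(mt) {
      v <- alpha_diversity(rare, mt, tree = tree)
      cmpz <- tryCatch(alpha_compare(v, gr,
                                     seed = child_seed(config$seed, mt)),
                       error = function(e) NULL)
      list(metric = mt, values = v, compare = cmpz)
    })
    names(alpha) <- metrics
    bd <- beta_distance(fl$counts, config$beta_metric, tree = tree)
    ord <- pcoa(bd)
    gsize <- table(groups)
    ok <- groups %in% names(gsize)[gsize >= 2]
    pm <- permanova(as.matrix(bd)[ok, ok], groups[ok],
                    n_perm = config$n_perm,
                    seed = child_seed(config$seed, "permanova"))
    gd <- group_distance_compare(bd, groups,
                                 seed = child_seed(config$seed, "gdist"))
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(out, "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    adf <- do.call(rbind, lapply(alpha, function(a)
      data.frame(metric = a$metric, sample_id = names(a$values),
                 value = unname(a$values))))
    utils::write.table(adf, file.path(out, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_artifact(list(permanova = pm,
                             group_distances = gd$sets),
                        file.path(out, "diversity.json"))
    list(alpha = alpha, beta = bd, pcoa = ord, permanova = pm,
         group_distances = gd)
  })

  results$network <- stage("netinfer", {
    net <- infer_network(fl$counts, taxonomy = taxonomy,
                         prevalence_min = config$prevalence_min,
                         pseudocount = config$pseudocount,
                         nlambda = config$nlambda,
                         min_ratio = config$min_ratio,
                         rep_num = config$rep_num, beta = config$stars_beta,
                         subsample_size = config$subsample_size,
                         seed = child_seed(config$seed, "netinfer"))
    write_network(net, file.path(out, "network_edges.tsv"))
    net
  })

  results$resilience <- stage("resilience", {
    net <- results$network
    g <- net$graph
    cen <- list(degree = centrality(g, "degree"),
                betweenness = if (igraph::vcount(g) >= 3)
                  centrality(g, "betweenness"))
    nc <- as.numeric(natural_connectivity(g))
    attacks <- lapply(c("degree", "betweenness", "random"), function(o)
      attack_simulation(g, o, seed = child_seed(config$seed, o)))
    names(attacks) <- c("degree", "betweenness", "random")
    ad <- do.call(rbind, lapply(names(attacks), function(o)
      cbind(ordering = o, attacks[[o]])))
    utils::write.table(ad, file.path(out, "attack_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    controls <- select_controls(fl$counts, focal = config$focal_ids)
    cdist <- NULL
    if (isTRUE(config$run_connectivity_distribution)) {
      cdist <- connectivity_distribution(
        fl$counts, config$focal_ids[1],
        iterations = config$iterations, subsample = config$subsample,
        seed = child_seed(config$seed, "cdist"), taxonomy = taxonomy,
        nlambda = config$nlambda, min_ratio = config$min_ratio,
        rep_num = config$rep_num, beta = config$stars_beta)
    }
    write_json_artifact(list(natural_connectivity = nc,
                             controls = controls,
                             connectivity_p =
                               if (!is.null(cdist)) cdist$p_value),
                        file.path(out, "resilience.json"))
    list(centrality = cen, natural_connectivity = nc, attacks = attacks,
         controls = controls, connectivity = cdist)
  })

  manifest$stages <- stages_done
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  summary_lines <- c(
    "focalecol pipeline run",
    sprintf("stages completed: %s", paste(stages_done, collapse = ", ")),
    sprintf("samples retained: %d of %d",
            results$screening$filtered$retention[["dedup"]],
            results$screening$filtered$retention[["input"]]),
    sprintf("ZINB AIC %.1f vs ZIP AIC %.1f",
            results$zinb$fit$aic, results$zinb$fit_zip$aic),
    sprintf("PERMANOVA pseudo-F %.2f (p = %.4g)",
            results$diversity$permanova$pseudo_F,
            results$diversity$permanova$p_value),
    sprintf("network: %d nodes, %d edges; natural connectivity %.4f",
            length(results$network$nodes),
            igraph::ecount(results$network$graph),
            results$resilience$natural_connectivity))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  results$manifest <- manifest
  invisible(results)
}
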