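#' Build a regression design for focal-abundance modelling
#'
#' Dummy-codes categorical host covariates against stated reference levels,
#' appends a hidden `"(missing)"` level for every categorical covariate
#' with missing values, and attaches the log total-read-count offset.
#' Samples missing a *continuous* covariate are dropped (the hidden-category
#' device applies to categorical variables only); the retained sample ids
#' are recorded in `$keep`.
#'
#' @param meta Data.frame of per-sample covariates. Must contain a `depth`
#'   column (total reads per sample) unless `depth` is supplied.
#' @param covariates Character vector of covariate names to include.
#' @param references Named character vector of reference levels for
#'   categorical covariates; unnamed covariates default to their first
#'   observed level.
#' @param depth Optional numeric vector of total reads per sample
#'   (overrides `meta$depth`).
#' @param missing_label Label for the hidden missing category.
#' @return An object of class `"zinb_design"`: list with the model matrix
#'   `X` (including intercept), `offset` (log depth), `keep` (row indices
#'   of `meta` retained), `meta`, `covariates`, `references`, `levels`
#'   (observed level sets per categorical, missing level last), and
#'   `assign` (covariate of origin per column).
#' @export
build_design <- function(meta, covariates, references = NULL, depth = NULL,
                         missing_label = "(missing)") {
  stopifnot(is.data.frame(meta))
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov))
    stop("covariates not in metadata: ", paste(missing_cov, collapse = ", "))
  depth <- depth %||% meta$depth
  if (is.null(depth)) stop("supply per-sample depth (meta$depth or depth=)")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("depths must be positive and finite")

  is_cont <- vapply(meta[covariates], is.numeric, logical(1))
  keep <- rep(TRUE, nrow(meta))
  for (cv in covariates[is_cont]) keep <- keep & !is.na(meta[[cv]])
  keep <- which(keep)
  m <- meta[keep, , drop = FALSE]
  depth <- depth[keep]

  X <- matrix(1, nrow(m), 1, dimnames = list(NULL, "(Intercept)"))
  assign <- "(Intercept)"
  levels_used <- list()
  for (cv in covariates) {
    if (is_cont[[cv]]) {
      X <- cbind(X, stats::setNames(m[, cv, drop = FALSE], cv)[[1]])
      colnames(X)[ncol(X)] <- cv
      assign <- c(assign, cv)
      next
    }
    v <- as.character(m[[cv]])
    obs <- unique(v[!is.na(v)])
    if (length(obs) < 1L) stop("covariate '", cv, "' has no observed levels")
    ref <- if (!is.null(references) && cv %in% names(references))
      references[[cv]] else obs[[1L]]
    if (!ref %in% obs) {
      warning("reference level '", ref, "' absent from data for '", cv,
              "'; using first observed level")
      ref <- obs[[1L]]
    }
    lv <- c(ref, sort(setdiff(obs, ref)))
    has_na <- anyNA(m[[cv]])
    if (has_na) {
      v[is.na(v)] <- missing_label
      lv <- c(lv, missing_label)
    }
    levels_used[[cv]] <- lv
    for (l in lv[-1L]) { # reference excluded
      X <- cbind(X, as.numeric(v == l))
      colnames(X)[ncol(X)] <- paste0(cv, "_", l)
      assign <- c(assign, cv)
    }
  }
  if (any(colSums(abs(X)) == 0)) stop("design contains an all-zero column")
  rownames(X) <- rownames(m)
  structure(list(X = X, offset = log(depth), keep = keep, meta = m,
                 covariates = covariates, references = references,
                 levels = levels_used, assign = assign,
                 missing_label = missing_label),
            class = "zinb_design")
}

#' @export
print.zinb_design <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "samples x", ncol(x$X), "columns\n")
  cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# design with one covariate pinned to a given level/value for every sample
design_at_level <- function(design, covariate, level) {
  if (!covariate %in% design$covariates)
    stop("covariate '", covariate, "' not in design")
  X <- design$X
  if (covariate %in% names(design$levels)) { # categorical
    lv <- design$levels[[covariate]]
    if (!level %in% lv)
      stop("level '", level, "' never observed for '", covariate, "'")
    cols <- which(design$assign == covariate)
    X[, cols] <- 0
    if (level != lv[[1L]])
      X[, paste0(covariate, "_", level)] <- 1
  } else {
    X[, covariate] <- as.numeric(level)
  }
  out <- design
  out$X <- X
  out
}
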