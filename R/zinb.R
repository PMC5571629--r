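# Zero-inflated count regression of focal-taxon reads on host features.
#
# The model mixes a structural-absence component (logistic, logit link)
# with a count component (negative binomial or Poisson, log link). The
# log of total reads per sample enters BOTH linear predictors as an
# offset with coefficient fixed at 1, so the count component models the
# focal taxon's proportion of the community:
#
#   logit(pi_i) = x_i' gamma + log T_i
#   log(mu_i)   = x_i' beta  + log T_i
#   y_i = 0                 with probability pi_i
#   y_i ~ NB(mu_i, k)       otherwise (Poisson in the k -> Inf limit)
#
# Fitting is direct joint maximum likelihood with an analytic gradient
# and multiple starting points; the dispersion is optimized as log(k).

zinb_loglik_parts <- function(par, y, X, off, negbin, zero_inflated) {
  q <- ncol(X)
  if (zero_inflated) {
    gamma <- par[seq_len(q)]
    beta <- par[q + seq_len(q)]
    eta_z <- drop(X %*% gamma) + off
  } else {
    beta <- par[seq_len(q)]
    eta_z <- NULL
  }
  eta_c <- drop(X %*% beta) + off
  mu <- exp(eta_c)
  k <- if (negbin) exp(par[length(par)]) else Inf
  list(eta_z = eta_z, mu = mu, k = k)
}

zinb_negloglik <- function(par, y, X, off, negbin, zero_inflated) {
  p <- zinb_loglik_parts(par, y, X, off, negbin, zero_inflated)
  mu <- p$mu; k <- p$k
  z <- y == 0
  logf0 <- if (negbin) k * (log(k) - log(k + mu)) else -mu
  if (zero_inflated) {
    lp <- stats::plogis(p$eta_z, log.p = TRUE)       # log pi
    l1mp <- stats::plogis(-p$eta_z, log.p = TRUE)    # log(1 - pi)
    a <- lp[z]; b <- l1mp[z] + logf0[z]
    m <- pmax(a, b)
    ll0 <- m + log(exp(a - m) + exp(b - m))
    llpos <- l1mp[!z]
  } else {
    ll0 <- logf0[z]
    llpos <- 0
  }
  if (negbin) {
    llc <- stats::dnbinom(y[!z], size = k, mu = mu[!z], log = TRUE)
  } else {
    llc <- stats::dpois(y[!z], lambda = mu[!z], log = TRUE)
  }
  -(sum(ll0) + sum(llpos + llc))
}

zinb_negscore <- function(par, y, X, off, negbin, zero_inflated) {
  p <- zinb_loglik_parts(par, y, X, off, negbin, zero_inflated)
  mu <- p$mu; k <- p$k
  n <- length(y)
  z <- y == 0
  s_count <- numeric(n)
  if (negbin) {
    logf0 <- k * (log(k) - log(k + mu))
    dlogf0_dk <- log(k / (k + mu)) + mu / (k + mu)
  } else {
    logf0 <- -mu
  }
  s_logk <- numeric(n)
  if (zero_inflated) {
    pi_ <- stats::plogis(p$eta_z)
    # y = 0: L = pi + (1-pi) f0
    f0 <- exp(logf0[z])
    L0 <- pi_[z] + (1 - pi_[z]) * f0
    s_zero <- numeric(n)
    s_zero[z] <- pi_[z] * (1 - pi_[z]) * (1 - f0) / L0
    s_zero[!z] <- -pi_[!z]
    if (negbin) {
      s_count[z] <- -(1 - pi_[z]) * f0 * (k * mu[z] / (k + mu[z])) / L0
      s_logk[z] <- k * (1 - pi_[z]) * f0 * dlogf0_dk[z] / L0
    } else {
      s_count[z] <- -(1 - pi_[z]) * f0 * mu[z] / L0
    }
  } else {
    s_zero <- NULL
    if (negbin) {
      s_count[z] <- -k * mu[z] / (k + mu[z])
      s_logk[z] <- k * dlogf0_dk[z]
    } else {
      s_count[z] <- -mu[z]
    }
  }
  yp <- y[!z]; mup <- mu[!z]
  if (negbin) {
    s_count[!z] <- k * (yp - mup) / (mup + k)
    s_logk[!z] <- k * (digamma(yp + k) - digamma(k) + log(k / (k + mup)) +
                         (mup - yp) / (mup + k))
  } else {
    s_count[!z] <- yp - mup
  }
  g <- c(if (zero_inflated) drop(crossprod(X, s_zero)),
         drop(crossprod(X, s_count)),
         if (negbin) sum(s_logk))
  -g
}

# central-difference Hessian of the analytic gradient
fd_hessian <- function(gr, par, ...) {
  np <- length(par)
  H <- matrix(0, np, np)
  h <- 1e-5 * pmax(1, abs(par))
  for (j in seq_len(np)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    H[, j] <- (gr(up, ...) - gr(dn, ...)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Fit a (zero-inflated) count regression with read-depth offsets
#'
#' Maximizes the joint likelihood of a zero-inflated negative binomial
#' (default) or zero-inflated Poisson model in which the log total read
#' count enters both the logistic and the count linear predictor as an
#' offset. With `zero_inflated = FALSE` the plain NB/Poisson regression is
#' fitted instead (via [MASS::glm.nb()] / [stats::glm()]).
#'
#' @param y Non-negative integer response (focal-taxon counts).
#' @param design A `"zinb_design"` from [build_design()], or a list with
#'   elements `X` (model matrix) and `offset` (log total reads).
#' @param family `"negbin"` for ZINB / NB, `"poisson"` for ZIP / Poisson.
#' @param zero_inflated Logical; fit the two-component mixture?
#' @param control List: `maxit` (default 1000), `reltol` (default 1e-12),
#'   `start` (optional full parameter vector).
#' @return Object of class `"zinb_fit"` with components `coefficients`
#'   (list `zero`, `count`), `dispersion` (`k`; `Inf` for Poisson),
#'   `loglik`, `df`, `nobs`, `aic`, `bic`, `se`, `zvalues`, `pvalues`,
#'   `vcov`, `fitted` (list `pi`, `mu`, `mean`), `grad_norm`, `design`,
#'   `y`.
#' @seealso [compare_models()], [apv_proportions()], [univariate_screen()]
#' @export
#' @examples
#' set.seed(1)
#' n <- 500; T_ <- rep(2e4, n)
#' x <- rnorm(n)
#' pi_ <- plogis(-0.5 + 0.8 * x)
#' mu <- T_ * exp(-9 + 0.5 * x)
#' y <- ifelse(rbinom(n, 1, pi_) == 1, 0, rnbinom(n, size = 1, mu = mu))
#' d <- list(X = cbind("(Intercept)" = 1, x = x), offset = log(T_))
#' f <- zinb_fit(y, d)
#' coef(f)
zinb_fit <- function(y, design, family = c("negbin", "poisson"),
                     zero_inflated = TRUE, control = list()) {
  family <- match.arg(family)
  negbin <- family == "negbin"
  X <- design$X
  off <- design$offset
  stopifnot(length(y) == nrow(X), length(off) == nrow(X))
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  q <- ncol(X)
  n <- length(y)
  df <- (if (zero_inflated) 2L else 1L) * q + (if (negbin) 1L else 0L)
  if (n <= df) stop("more parameters than observations")

  if (!zero_inflated) {
    fit <- zinb_fit_plain(y, X, off, negbin)
  } else {
    fit <- zinb_fit_mixture(y, X, off, negbin, control)
  }

  ll <- fit$loglik
  out <- structure(c(fit, list(
    family = family, zero_inflated = zero_inflated,
    nobs = n, df = df,
    aic = 2 * df - 2 * ll, bic = df * log(n) - 2 * ll,
    design = design, y = y)), class = "zinb_fit")
  out
}

zinb_fit_plain <- function(y, X, off, negbin) {
  dat <- data.frame(y = y)
  if (negbin) {
    g <- suppressWarnings(MASS::glm.nb(y ~ X - 1 + offset(off), data = dat))
    k <- g$theta
  } else {
    g <- stats::glm(y ~ X - 1 + offset(off), family = stats::poisson(),
                    data = dat)
    k <- Inf
  }
  beta <- stats::setNames(stats::coef(g), colnames(X))
  se <- sqrt(diag(stats::vcov(g)))
  zs <- beta / se
  mu <- exp(drop(X %*% beta) + off)
  list(coefficients = list(zero = NULL, count = beta),
       dispersion = k,
       loglik = as.numeric(stats::logLik(g)),
       se = list(zero = NULL, count = stats::setNames(se, colnames(X))),
       zvalues = list(zero = NULL, count = zs),
       pvalues = list(zero = NULL, count = 2 * stats::pnorm(-abs(zs))),
       vcov = stats::vcov(g),
       fitted = list(pi = rep(0, length(y)), mu = mu, mean = mu),
       grad_norm = NA_real_, convergence = 0L)
}

zinb_fit_mixture <- function(y, X, off, negbin, control) {
  q <- ncol(X)
  n <- length(y)
  maxit <- control$maxit %||% 1000L
  reltol <- control$reltol %||% 1e-12

  starts <- list()
  if (!is.null(control$start)) starts <- list(control$start)
  # null-model start
  p0 <- min(max(mean(y == 0), 0.02), 0.98)
  g0 <- c(stats::qlogis(p0) - mean(off), rep(0, q - 1L))
  b0 <- c(log(sum(y) / sum(exp(off))) - 0, rep(0, q - 1L))
  starts <- c(starts, list(c(g0, b0, if (negbin) 0)))
  # two-stage start: logistic on zeros, count model on positives
  ts <- tryCatch({
    gz <- suppressWarnings(stats::glm.fit(X, as.numeric(y == 0),
                                          offset = off,
                                          family = stats::binomial()))
    pos <- y > 0
    bc <- if (negbin) {
      fitp <- suppressWarnings(
        MASS::glm.nb(yy ~ Xp - 1 + offset(op),
                     data = list(yy = y[pos], Xp = X[pos, , drop = FALSE],
                                 op = off[pos])))
      c(stats::coef(fitp), log(max(fitp$theta, 1e-3)))
    } else {
      fitp <- stats::glm.fit(X[pos, , drop = FALSE], y[pos],
                             offset = off[pos], family = stats::poisson())
      stats::coef(fitp)
    }
    c(stats::coef(gz), bc)
  }, error = function(e) NULL)
  if (!is.null(ts) && all(is.finite(ts))) starts <- c(starts, list(ts))

  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      suppressWarnings( # optim may probe extreme dispersion values
        stats::optim(st, zinb_negloglik, zinb_negscore, y = y, X = X,
                     off = off, negbin = negbin, zero_inflated = TRUE,
                     method = "BFGS",
                     control = list(maxit = maxit, reltol = reltol))),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("zero-inflated fit failed from all starting values")
  # polish
  o <- suppressWarnings(
    stats::optim(best$par, zinb_negloglik, zinb_negscore, y = y, X = X,
                 off = off, negbin = negbin, zero_inflated = TRUE,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol)))
  if (o$value <= best$value) best <- o
  par <- best$par
  ll <- -best$value
  g <- zinb_negscore(par, y, X, off, negbin, TRUE)
  grad_norm <- max(abs(g)) / max(1, abs(ll))
  if (best$convergence != 0 && grad_norm > 1e-4)
    stop("zero-inflated fit did not converge (scaled gradient ",
         format(grad_norm), "); best fit attached to condition",
         call. = FALSE)

  gamma <- stats::setNames(par[seq_len(q)], colnames(X))
  beta <- stats::setNames(par[q + seq_len(q)], colnames(X))
  if (max(abs(gamma)) > 20)
    warning("very large logistic coefficients: possible separation in the zero component")
  k <- if (negbin) exp(par[length(par)]) else Inf

  H <- fd_hessian(zinb_negscore, par, y = y, X = X, off = off,
                  negbin = negbin, zero_inflated = TRUE)
  V <- tryCatch(solve(H), error = function(e) {
    warning("Hessian is singular; standard errors unavailable")
    matrix(NA_real_, length(par), length(par))
  })
  se_all <- suppressWarnings(sqrt(diag(V)))
  se_z <- stats::setNames(se_all[seq_len(q)], colnames(X))
  se_c <- stats::setNames(se_all[q + seq_len(q)], colnames(X))
  zz <- gamma / se_z
  zc <- beta / se_c
  pi_ <- stats::plogis(drop(X %*% gamma) + off)
  mu <- exp(drop(X %*% beta) + off)
  list(coefficients = list(zero = gamma, count = beta),
       dispersion = k,
       loglik = ll,
       se = list(zero = se_z, count = se_c,
                 log_dispersion = if (negbin) se_all[length(par)]),
       zvalues = list(zero = zz, count = zc),
       pvalues = list(zero = 2 * stats::pnorm(-abs(zz)),
                      count = 2 * stats::pnorm(-abs(zc))),
       vcov = V,
       fitted = list(pi = pi_, mu = mu, mean = (1 - pi_) * mu),
       grad_norm = grad_norm, convergence = best$convergence)
}

#' @export
print.zinb_fit <- function(x, ...) {
  lab <- if (x$zero_inflated) {
    if (x$family == "negbin") "Zero-inflated negative binomial" else "Zero-inflated Poisson"
  } else {
    if (x$family == "negbin") "Negative binomial" else "Poisson"
  }
  cat(lab, "regression with log-read-count offset\n")
  cat("n =", x$nobs, " df =", x$df,
      " logLik =", formatC(x$loglik, format = "f", digits = 1),
      " AIC =", formatC(x$aic, format = "f", digits = 1), "\n")
  if (!is.null(x$coefficients$zero)) {
    cat("\nZero (logistic) component:\n")
    print(round(x$coefficients$zero, 4))
  }
  cat("\nCount component:\n")
  print(round(x$coefficients$count, 4))
  if (is.finite(x$dispersion))
    cat("\nDispersion k =", formatC(x$dispersion, format = "f", digits = 4), "\n")
  invisible(x)
}

#' @export
summary.zinb_fit <- function(object, ...) {
  comp <- function(which) {
    est <- object$coefficients[[which]]
    if (is.null(est)) return(NULL)
    data.frame(term = names(est), estimate = unname(est),
               std_error = unname(object$se[[which]]),
               z = unname(object$zvalues[[which]]),
               p_value = unname(object$pvalues[[which]]),
               row.names = NULL)
  }
  out <- list(family = object$family, zero_inflated = object$zero_inflated,
              zero = comp("zero"), count = comp("count"),
              dispersion = object$dispersion, loglik = object$loglik,
              df = object$df, nobs = object$nobs,
              aic = object$aic, bic = object$bic)
  class(out) <- "summary.zinb_fit"
  out
}

#' @export
print.summary.zinb_fit <- function(x, ...) {
  cat("Family:", x$family, if (x$zero_inflated) "(zero-inflated)", "\n")
  if (!is.null(x$zero)) {
    cat("\nZero (logistic) component:\n")
    print(x$zero, digits = 4)
  }
  cat("\nCount component:\n")
  print(x$count, digits = 4)
  if (is.finite(x$dispersion)) cat("\nDispersion k =", x$dispersion, "\n")
  cat("logLik =", x$loglik, " df =", x$df, " AIC =", x$aic,
      " BIC =", x$bic, "\n")
  invisible(x)
}

#' @export
coef.zinb_fit <- function(object, component = c("both", "count", "zero"), ...) {
  component <- match.arg(component)
  switch(component,
         both = object$coefficients,
         count = object$coefficients$count,
         zero = object$coefficients$zero)
}

#' @export
logLik.zinb_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
vcov.zinb_fit <- function(object, ...) object$vcov

#' Predict from a fitted zero-inflated count model
#'
#' @param object A `"zinb_fit"`.
#' @param design Optional new design (same structure as used for fitting).
#' @param type `"mean"` for the unconditional mean `(1 - pi) * mu`,
#'   `"count"` for `mu`, `"zero"` for `pi`.
#' @param ... Unused.
#' @export
predict.zinb_fit <- function(object, design = NULL,
                             type = c("mean", "count", "zero"), ...) {
  type <- match.arg(type)
  if (is.null(design)) {
    f <- object$fitted
    return(switch(type, mean = f$mean, count = f$mu, zero = f$pi))
  }
  off <- design$offset
  pick <- function(cf) {
    nm <- names(cf)
    if (!is.null(nm) && all(nm %in% colnames(design$X)))
      return(design$X[, nm, drop = FALSE])
    if (ncol(design$X) != length(cf))
      stop("design columns do not match the fitted coefficients")
    design$X
  }
  mu <- exp(drop(pick(object$coefficients$count) %*%
                   object$coefficients$count) + off)
  pi_ <- if (is.null(object$coefficients$zero)) rep(0, length(off)) else
    stats::plogis(drop(pick(object$coefficients$zero) %*%
                         object$coefficients$zero) + off)
  switch(type, mean = (1 - pi_) * mu, count = mu, zero = pi_)
}

#' @export
residuals.zinb_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  f <- object$fitted
  r <- object$y - f$mean
  if (type == "response") return(r)
  k <- object$dispersion
  extra <- f$pi + if (is.finite(k)) 1 / k else 0
  v <- (1 - f$pi) * f$mu * (1 + f$mu * extra)
  r / sqrt(v)
}

#' @export
simulate.zinb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    f <- object$fitted
    n <- object$nobs
    k <- object$dispersion
    out <- replicate(nsim, {
      z <- stats::rbinom(n, 1, f$pi)
      ypos <- if (is.finite(k)) stats::rnbinom(n, size = k, mu = f$mu)
              else stats::rpois(n, f$mu)
      ifelse(z == 1, 0, ypos)
    })
    as.data.frame(out)
  })
}

#' Compare two nested zero-inflated fits
#'
#' Reports AIC/BIC differences and the likelihood-ratio test. For the
#' ZINB-vs-ZIP comparison the tested parameter (the dispersion) lies on
#' the boundary of its space, so the nominal chi-square reference is
#' conservative; the p-value is reported with that caveat.
#'
#' @param fitA,fitB Two `"zinb_fit"` objects on identical data, nested.
#' @return List with `delta_aic`, `delta_bic` (larger minus smaller model),
#'   `lrt_stat`, `lrt_df`, `lrt_p`, and which fit is the larger model.
#' @export
compare_models <- function(fitA, fitB) {
  if (fitA$nobs != fitB$nobs)
    stop("fits use different numbers of observations")
  big <- if (fitA$df >= fitB$df) fitA else fitB
  small <- if (fitA$df >= fitB$df) fitB else fitA
  stat <- 2 * (big$loglik - small$loglik)
  dfd <- big$df - small$df
  p <- if (dfd == 0) {
    if (abs(stat) < 1e-8) 1 else NA_real_
  } else {
    stats::pchisq(max(stat, 0), df = dfd, lower.tail = FALSE)
  }
  list(delta_aic = big$aic - small$aic,
       delta_bic = big$bic - small$bic,
       lrt_stat = stat, lrt_df = dfd, lrt_p = p,
       larger = if (identical(big, fitA)) "fitA" else "fitB")
}

#' Overall fitted mean proportions by the average-predicted-value method
#'
#' For each level of a categorical covariate, every sample's covariate is
#' set to that level, the unconditional mean count `(1 - pi) * mu` is
#' predicted, averaged over samples, and divided by the mean total read
#' count; the result is reported as a percentage.
#'
#' @param fit A `"zinb_fit"`.
#' @param design The `"zinb_design"` the model was fitted on.
#' @param covariate Name of a categorical covariate in the design.
#' @param alpha Significance cut for flagging levels (per component).
#' @return Data.frame: level, `apv_percent`, `sig_zero`, `sig_count`.
#' @export
apv_proportions <- function(fit, design, covariate, alpha = 0.05) {
  if (!covariate %in% names(design$levels))
    stop("'", covariate, "' is not a categorical covariate of the design")
  lv <- design$levels[[covariate]]
  Tbar <- mean(exp(design$offset))
  apv <- vapply(lv, function(l) {
    d2 <- design_at_level(design, covariate, l)
    mean(predict(fit, d2, type = "mean")) / Tbar
  }, numeric(1))
  sig <- function(which) {
    p <- fit$pvalues[[which]]
    vapply(lv, function(l) {
      nm <- paste0(covariate, "_", l)
      if (is.null(p) || !nm %in% names(p)) NA else unname(p[nm]) < alpha
    }, logical(1))
  }
  data.frame(covariate = covariate, level = lv,
             apv_percent = 100 * apv,
             sig_zero = sig("zero"), sig_count = sig("count"),
             row.names = NULL)
}

#' Univariate covariate screen with offsets
#'
#' Screens candidate host covariates one at a time: a logistic regression
#' of focal-taxon presence and a negative binomial regression of counts,
#' both with the log total-read offset in the linear predictor. A
#' candidate passes if any non-reference level has Wald p below `alpha`
#' in either model; baseline covariates are always retained.
#'
#' @param y Focal-taxon counts.
#' @param meta Metadata with a `depth` column (or supply `depth`).
#' @param candidates Character vector of covariate names to screen.
#' @param baseline Covariates always kept (default the intersection of
#'   `c("age", "sex", "race")` with `candidates`).
#' @param references Named reference levels, as in [build_design()].
#' @param alpha Screening threshold (default 0.1).
#' @param positives_only Fit the NB screen on detected samples only
#'   instead of all samples.
#' @param depth Optional depth vector.
#' @return List: `selected` (character), `table` (per-candidate minimum p
#'   in each model and selection flag).
#' @export
univariate_screen <- function(y, meta, candidates,
                              baseline = intersect(c("age", "sex", "race"),
                                                   candidates),
                              references = NULL, alpha = 0.1,
                              positives_only = FALSE, depth = NULL) {
  stopifnot(length(y) == nrow(meta))
  res <- data.frame(candidate = candidates, p_logistic = NA_real_,
                    p_negbin = NA_real_, selected = FALSE)
  for (i in seq_along(candidates)) {
    cv <- candidates[[i]]
    if (!is.numeric(meta[[cv]]) &&
        length(unique(stats::na.omit(as.character(meta[[cv]])))) < 2L) {
      warning("candidate '", cv, "' has a single observed level; excluded")
      next
    }
    d <- build_design(meta, cv, references = references, depth = depth)
    yy <- y[d$keep]
    off <- d$offset
    Xc <- d$X[, -1, drop = FALSE]
    # logistic component: presence/absence with offset
    pl <- tryCatch({
      g <- suppressWarnings(stats::glm.fit(d$X, as.numeric(yy > 0),
                                           offset = off,
                                           family = stats::binomial()))
      wald_min_p(g, d$X)
    }, error = function(e) NA_real_)
    # NB component
    pn <- tryCatch({
      use <- if (positives_only) yy > 0 else rep(TRUE, length(yy))
      dat <- list(yy = yy[use], Xs = Xc[use, , drop = FALSE],
                  os = off[use])
      g <- suppressWarnings(MASS::glm.nb(yy ~ Xs + offset(os), data = dat))
      p <- stats::coef(summary(g))[-1, 4]
      min(p)
    }, error = function(e) NA_real_)
    res$p_logistic[i] <- pl
    res$p_negbin[i] <- pn
    res$selected[i] <- isTRUE(min(pl, pn, na.rm = TRUE) < alpha)
  }
  res$selected[res$candidate %in% baseline] <- TRUE
  list(selected = res$candidate[res$selected], table = res)
}

# minimum Wald p over non-intercept coefficients of a glm.fit object
wald_min_p <- function(g, X) {
  cf <- stats::coef(g)
  w <- g$weights
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  z <- (cf / se)[-1]
  min(2 * stats::pnorm(-abs(z)))
}
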