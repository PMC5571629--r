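test_that("design construction codes references and hidden categories", {
  meta <- data.frame(
    depth = rep(1000, 8),
    age = c(30, 40, NA, 50, 60, 70, 80, 90),
    sex = c("Female", "Male", "Male", NA, "Female", "Male", "Female", "Male"),
    race = c("a", "b", "c", "d", "e", "a", "b", NA))
  d <- build_design(meta, c("sex"), references = c(sex = "Female"))
  # 1 dummy for Male + 1 hidden missing column
  expect_setequal(colnames(d$X), c("(Intercept)", "sex_Male",
                                   "sex_(missing)"))
  d2 <- build_design(meta, c("race"))
  # 5 levels + missing, minus reference -> 5 columns
  expect_equal(sum(d2$assign == "race"), 5L)
  # no missingness -> no hidden category
  meta$sex2 <- rep(c("F", "M"), 4)
  d3 <- build_design(meta, "sex2")
  expect_setequal(colnames(d3$X), c("(Intercept)", "sex2_M"))
  # rows missing a continuous covariate are dropped
  d4 <- build_design(meta, c("age", "sex"))
  expect_equal(length(d4$keep), 7L)
  expect_warning(build_design(meta, "sex", references = c(sex = "Unknown")),
                 "absent")
})

test_that("information criteria follow from the likelihood identities", {
  meta <- quick_cohort(300, seed = 2)
  tr <- quick_truth()
  y <- gen_focal_counts(meta, tr, seed = 1)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f <- zinb_fit(y, d)
  expect_equal(f$aic, 2 * f$df - 2 * f$loglik, tolerance = 1e-10)
  expect_equal(f$bic, f$df * log(f$nobs) - 2 * f$loglik, tolerance = 1e-10)
  expect_equal(f$df, 2 * ncol(d$X) + 1)
  expect_gt(f$dispersion, 0)
  ll <- logLik(f)
  expect_equal(as.numeric(ll), f$loglik)
  expect_equal(attr(ll, "df"), f$df)
})

test_that("joint MLE recovers simulated parameters within 3 SE", {
  meta <- quick_cohort(5000, seed = 31)
  tr <- quick_truth(k = 1)
  y <- gen_focal_counts(meta, tr, seed = 32)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f <- zinb_fit(y, d)
  expect_lt(f$grad_norm, 1e-5)
  truth_g <- tr$gamma[, 1]
  truth_b <- tr$beta[, 1]
  for (nm in names(truth_g)) {
    expect_lt(abs(f$coefficients$zero[nm] - truth_g[nm]) /
                f$se$zero[nm], 3)
    expect_lt(abs(f$coefficients$count[nm] - truth_b[nm]) /
                f$se$count[nm], 3)
  }
  expect_lt(abs(log(f$dispersion) - log(1)) / f$se$log_dispersion, 3)
  # fitted probabilities are probabilities; mixture mean matches data scale
  expect_true(all(f$fitted$pi >= 0 & f$fitted$pi <= 1))
  expect_equal(mean(f$fitted$mean), mean(y), tolerance = 0.15)
})

test_that("ZINB fit agrees with an independent mixture implementation", {
  skip_if_not_installed("glmmTMB")
  # constant depth so the logistic offset is a pure intercept shift
  meta <- quick_cohort(1500, seed = 41, depth_sdlog = 0)
  tr <- quick_truth(k = 1)
  y <- gen_focal_counts(meta, tr, seed = 42)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f <- zinb_fit(y, d)
  dat <- data.frame(y = y, age = meta$age,
                    male = as.numeric(meta$sex == "Male"),
                    off = log(meta$depth))
  g <- glmmTMB::glmmTMB(y ~ age + male + offset(off),
                        ziformula = ~ age + male,
                        family = glmmTMB::nbinom2(), data = dat)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
  cf <- glmmTMB::fixef(g)
  expect_equal(unname(f$coefficients$count),
               unname(cf$cond), tolerance = 1e-3)
  # zi intercept absorbs the constant offset
  off0 <- log(meta$depth[1])
  expect_equal(unname(f$coefficients$zero[1]) + off0,
               unname(cf$zi[1]), tolerance = 1e-3)
  expect_equal(unname(f$coefficients$zero[-1]),
               unname(cf$zi[-1]), tolerance = 1e-3)
  expect_equal(unname(f$dispersion), as.numeric(glmmTMB::sigma(g)),
               tolerance = 1e-3)
})

test_that("ZINB nests ZIP and the comparison reports it", {
  meta <- quick_cohort(2000, seed = 51)
  tr <- quick_truth(k = 0.5)
  y <- gen_focal_counts(meta, tr, seed = 52)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f_nb <- zinb_fit(y, d, family = "negbin")
  f_zip <- zinb_fit(y, d, family = "poisson")
  expect_gte(f_nb$loglik, f_zip$loglik) # nesting
  expect_lt(f_nb$aic, f_zip$aic)        # overdispersed truth
  cmp <- compare_models(f_nb, f_zip)
  expect_equal(cmp$lrt_df, 1L)
  expect_lt(cmp$lrt_p, 0.05)
  # identical fits
  cmp0 <- compare_models(f_nb, f_nb)
  expect_equal(cmp0$delta_aic, 0)
  expect_equal(cmp0$lrt_p, 1)
})

test_that("APV reproduces closed forms and effect directions", {
  # no-inflation Poisson with intercept only: APV == sum(y)/sum(T)
  set.seed(61)
  n <- 400
  T_ <- round(runif(n, 5000, 20000))
  y <- rpois(n, T_ * 1e-4)
  meta <- data.frame(depth = T_, grp = rep(c("a", "b"), n / 2))
  d <- build_design(meta, "grp")
  d0 <- d; d0$X <- d$X[, 1, drop = FALSE]; d0$assign <- "(Intercept)"
  f <- zinb_fit(y, d0, family = "poisson", zero_inflated = FALSE)
  apv <- apv_proportions(f, d, "grp")
  expect_equal(apv$apv_percent, rep(100 * sum(y) / sum(T_), 2),
               tolerance = 1e-8)
  expect_error(apv_proportions(f, d, "absent_cov"), "not a categorical")
})

test_that("APV with structural absence everywhere is zero and effects order", {
  meta <- quick_cohort(2500, seed = 71)
  tr <- quick_truth(beta_extra = c(0, 1.2)) # strong positive Male effect
  y <- gen_focal_counts(meta, tr, seed = 72)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f <- zinb_fit(y, d)
  apv <- apv_proportions(f, d, "sex")
  expect_gt(apv$apv_percent[apv$level == "Male"],
            apv$apv_percent[apv$level == "Female"])
  expect_true(all(apv$apv_percent >= 0 & apv$apv_percent <= 100))
  # force pi = 1: predictions vanish
  f2 <- f
  f2$coefficients$zero[] <- 0
  f2$coefficients$zero["(Intercept)"] <- 50
  apv2 <- apv_proportions(f2, d, "sex")
  expect_equal(apv2$apv_percent, rep(0, nrow(apv2)), tolerance = 1e-6)
  expect_error(apv_proportions(f, d, "age"), "categorical")
})

test_that("univariate screen keeps baselines and finds planted effects", {
  meta <- quick_cohort(1200, seed = 81)
  set.seed(82)
  meta$noise <- sample(c("u", "v"), nrow(meta), replace = TRUE)
  # strong NB effect, null logistic effect, via the count component only
  tr <- quick_truth(gamma_extra = c(0, 0), beta_extra = c(0, 1.5))
  y <- gen_focal_counts(meta, tr, seed = 83)[, 1]
  scr <- univariate_screen(y, meta, c("age", "sex", "noise"),
                           references = c(sex = "Female"))
  expect_true(all(c("age", "sex") %in% scr$selected)) # baselines forced
  expect_true("sex" %in% scr$selected)
  # single-level candidate is excluded with a warning
  meta$mono <- "only"
  expect_warning(univariate_screen(y, meta, c("age", "mono")),
                 "single observed level")
})

test_that("predict/residuals/simulate are coherent with the fit", {
  meta <- quick_cohort(800, seed = 91)
  tr <- quick_truth()
  y <- gen_focal_counts(meta, tr, seed = 92)[, 1]
  d <- build_design(meta, c("age", "sex"), references = c(sex = "Female"))
  f <- zinb_fit(y, d)
  expect_equal(predict(f), f$fitted$mean)
  expect_equal(predict(f, d, type = "zero"), f$fitted$pi, tolerance = 1e-12)
  r <- residuals(f)
  expect_equal(length(r), length(y))
  sims <- simulate(f, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(length(y), 3L))
  expect_identical(simulate(f, nsim = 2, seed = 7),
                   simulate(f, nsim = 2, seed = 7))
  # simulated zero fraction matches observed
  expect_equal(mean(as.matrix(sims) == 0), mean(y == 0), tolerance = 0.05)
})
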