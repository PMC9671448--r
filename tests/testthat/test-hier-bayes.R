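# Metropolis-within-Gibbs sampler for the three-level logistic model.

naive_log_posterior <- function(params, data, spec, priors) {
  dig <- function(x) priors$ig_shape * log(priors$ig_scale) -
    lgamma(priors$ig_shape) - (priors$ig_shape + 1) * log(x) -
    priors$ig_scale / x
  lp <- 0
  for (b in params$beta)
    lp <- lp + dnorm(b, priors$beta_mean, sqrt(priors$beta_var), log = TRUE)
  if (!is.null(params$u)) {
    for (ui in params$u) lp <- lp + dnorm(ui, 0, sqrt(params$sigma2_C), TRUE)
    lp <- lp + dig(params$sigma2_C)
  }
  if (!is.null(params$v)) {
    for (vi in params$v) lp <- lp + dnorm(vi, 0, sqrt(params$sigma2_R), TRUE)
    lp <- lp + dig(params$sigma2_R)
  }
  for (i in seq_len(nrow(data))) {
    eta <- params$beta[["intercept"]]
    for (nm in spec$l1_covariates)
      eta <- eta + params$beta[[nm]] * data[[nm]][i]
    eta <- eta + params$u[[data$cluster_id[i]]] +
      params$v[[data$region_id[i]]]
    pr <- plogis(eta)
    lp <- lp + ifelse(data$cs[i] == 1, log(pr), log(1 - pr))
  }
  lp
}

test_that("log_posterior equals term-by-term summation on a random instance", {
  set.seed(40)
  n <- 50
  data <- data.frame(
    cs = rbinom(n, 1, 0.4),
    education = rbinom(n, 1, 0.5),
    age = runif(n),
    cluster_id = sample(paste0("C", 1:5), n, TRUE),
    region_id = NA
  )
  data$region_id <- ifelse(data$cluster_id %in% c("C1", "C2"), "R1", "R2")
  spec <- hier_model_spec(l1_covariates = c("education", "age"))
  priors <- prior_spec()
  params <- list(
    beta = c(intercept = -0.3, education = 0.8, age = -0.5),
    u = setNames(rnorm(5, 0, 0.5), paste0("C", 1:5)),
    v = setNames(rnorm(2, 0, 0.5), c("R1", "R2")),
    sigma2_C = 0.7, sigma2_R = 1.2
  )
  expect_equal(log_posterior(params, data, spec, priors),
               naive_log_posterior(params, data, spec, priors),
               tolerance = 1e-10)
  # empty data reduces to the log-prior
  empty <- data[0, ]
  expect_equal(log_posterior(params, empty, spec, priors),
               naive_log_posterior(params, empty, spec, priors),
               tolerance = 1e-10)
  # one observation with linear predictor 0 contributes log(1/2)
  p0 <- list(beta = c(intercept = 0), sigma2_C = 1, sigma2_R = 1)
  one <- data.frame(cs = 1, cluster_id = "C1", region_id = "R1")
  sp0 <- hier_model_spec(l1_covariates = character(0))
  expect_equal(log_posterior(p0, one, sp0, priors) -
                 log_posterior(p0, one[0, ], sp0, priors),
               log(0.5))
  # non-positive variance is outside the support
  bad <- params; bad$sigma2_C <- -1
  expect_equal(log_posterior(bad, data, spec, priors), -Inf)
})

test_that("posterior summaries: constant chains, normal quantiles, OR mapping", {
  const <- matrix(2.5, 200, 1, dimnames = list(NULL, "b"))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)
  set.seed(41)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_posterior(z)
  expect_equal(s$lower, -1.96, tolerance = 0.05)
  expect_equal(s$upper, 1.96, tolerance = 0.05)
  # exponentiation preserves order and endpoints
  expect_equal(s$or_lower, exp(s$lower))
  expect_equal(s$or_upper, exp(s$upper))
  expect_true(s$or_lower < s$or && s$or < s$or_upper)
  expect_error(summarize_posterior(z[1:50, , drop = FALSE]), "100")
})

test_that("DIC identities: degenerate chain and hand-computed two-draw chain", {
  # all draws identical => Dbar = Dhat => pD = 0, DIC = Dhat
  s <- c(1, -1, 1)          # y = 1, 0, 1
  eta <- c(0.5, -0.2, 1.1)
  dev <- -2 * sum(-log(1 + exp(-s * eta)))
  fit <- structure(list(deviance = rep(dev, 10), eta_bar = eta, s = s),
                   class = "cs_hierfit")
  d <- dic(fit)
  expect_equal(d$pD, 0, tolerance = 1e-12)
  expect_equal(d$dic, d$Dhat)
  # two draws with different linear predictors: hand arithmetic
  eta1 <- c(0, 0, 0); eta2 <- c(1, 1, 1)
  dev1 <- -2 * sum(-log(1 + exp(-s * eta1)))
  dev2 <- -2 * sum(-log(1 + exp(-s * eta2)))
  ebar <- (eta1 + eta2) / 2
  dhat <- -2 * sum(-log(1 + exp(-s * ebar)))
  fit2 <- structure(list(deviance = c(dev1, dev2), eta_bar = ebar, s = s),
                    class = "cs_hierfit")
  d2 <- dic(fit2)
  expect_equal(d2$Dbar, (dev1 + dev2) / 2)
  expect_equal(d2$Dhat, dhat)
  expect_equal(d2$pD, (dev1 + dev2) / 2 - dhat)
  expect_equal(d2$dic, dhat + 2 * d2$pD)
  expect_error(dic(structure(list(deviance = dev1), class = "cs_hierfit")),
               "2 retained")
})

test_that("retained-draw accounting follows the two documented modes", {
  expect_equal(mcmc_config(1500, 500, 5)$n_retained, 200)
  expect_equal(mcmc_config(1500, 500, 5, burnin_additional = TRUE)$n_retained,
               300)
  # survey-scale accounting: 6,000 by default, 7,000 in the alternative mode
  expect_equal(mcmc_config(scale = "paper")$n_retained, 6000)
  expect_equal(mcmc_config(scale = "paper",
                           burnin_additional = TRUE)$n_retained, 7000)
})

test_that("variance Gibbs step matches the analytic inverse-gamma full conditional", {
  set.seed(42)
  u <- rnorm(80, 0, 0.7)
  ssq <- sum(u^2)
  draws <- rinvgamma_full_conditional(4000, ssq, length(u), 0.01, 0.01)
  # 1/sigma2 should be Gamma(shape + n/2, rate = scale + ssq/2)
  ks <- ks.test(1 / draws, pgamma, shape = 0.01 + 40, rate = 0.01 + ssq / 2)
  expect_gt(ks$p.value, 0.01)
  qs <- quantile(draws, c(0.1, 0.5, 0.9))
  analytic <- 1 / qgamma(c(0.9, 0.5, 0.1), shape = 40.01, rate = 0.01 + ssq / 2)
  expect_equal(as.numeric(qs), analytic, tolerance = 0.05)
})

test_that("prior-only run recovers the prior for fixed effects and variances", {
  spec <- hier_model_spec(l1_covariates = "education")
  fit <- fit_hier_logistic(NULL, spec, prior_spec(),
                           mcmc_config(30000, 5000, 5, seed = 43))
  b <- fit$beta[, "intercept"]
  expect_equal(mean(b), 0, tolerance = 3)         # sd(mean) ~ 31.6/sqrt(ESS)
  expect_equal(sd(b), sqrt(1000), tolerance = 0.15)
  # IG(0.01, 0.01) has no mean; compare on the CDF scale instead
  s2 <- fit$variances[, "sigma2_C"]
  uq <- pgamma(1 / s2, shape = 0.01, rate = 0.01)
  expect_gt(suppressWarnings(ks.test(uq, punif)$p.value), 0.001)
})

test_that("chains are seed-reproducible and match glm when variances vanish", {
  ds <- small_simdata(seed = 11, s2c = 1e-6, s2r = 1e-6, regions = 4,
                      cpr = 25, wpc = 15)
  spec <- hier_model_spec(l1_covariates = "education")
  mc <- mcmc_config(4000, 1500, 5, seed = 44)
  f1 <- fit_hier_logistic(ds$women, spec, prior_spec(), mc)
  f2 <- fit_hier_logistic(ds$women, spec, prior_spec(), mc)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$variances, f2$variances)
  g <- glm(cs ~ education, binomial, ds$women)
  se <- summary(g)$coefficients[, 2]
  expect_lt(abs(coef(f1)[["intercept"]] - coef(g)[[1]]), 4 * se[1])
  expect_lt(abs(coef(f1)[["education"]] - coef(g)[[2]]), 4 * se[2])
})

test_that("sampler guards: constant outcome, separation, missing columns", {
  ds <- small_simdata(seed = 12, regions = 2, cpr = 3, wpc = 4)
  w <- ds$women
  w$cs <- 1L
  expect_error(fit_hier_logistic(w, hier_model_spec(l1_covariates = "education")),
               "constant")
  w2 <- ds$women
  w2$sep <- w2$cs            # perfectly separating covariate
  expect_warning(
    fit_hier_logistic(w2, hier_model_spec(l1_covariates = "sep"),
                      mcmc = mcmc_config(600, 200, 2, seed = 1)),
    "separates")
  expect_error(fit_hier_logistic(ds$women,
                                 hier_model_spec(l1_covariates = "absent")),
               "absent")
})

test_that("the model ladder explains planted cluster-level variance with distance", {
  cfg <- sim_config(n_regions = 5, clusters_per_region = rep(30, 5),
                    women_per_cluster = 10,
                    fixed_effects = c(intercept = -0.5, education = 0.7),
                    sigma2_cluster = 0.8, sigma2_region = 0.3,
                    distance_effect = -3.5, seed = 45)
  ds <- simulate_population(cfg)
  women <- ds$women
  women$distance01 <- ds$truth$distance01[
    match(women$cluster_id, ds$clusters$cluster_id)]
  spec <- hier_model_spec(l1_covariates = "education",
                          l2_covariate = "distance01")
  lad <- model_ladder(women, spec, prior_spec(),
                      mcmc_config(4000, 1500, 5, seed = 46))
  tab <- lad$table
  expect_equal(nrow(tab), 4)
  expect_true(is.na(tab$PCV_C_pct[1]))
  expect_true(all(is.finite(tab$DIC)))
  # distance is a cluster-level covariate: only Model 3 can absorb it
  expect_gt(tab$PCV_C_pct[4], tab$PCV_C_pct[2])
  # rerun of the same ladder is deterministic
  lad2 <- model_ladder(women, spec, prior_spec(),
                       mcmc_config(4000, 1500, 5, seed = 46))
  expect_identical(lad$table$DIC, lad2$table$DIC)
})
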