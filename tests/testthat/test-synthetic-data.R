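# Three-level synthetic population generator with known ground truth.

test_that("intercept-only generator with no variance yields Bernoulli(1/2)", {
  cfg <- sim_config(n_regions = 4, clusters_per_region = rep(25, 4),
                    women_per_cluster = 25,
                    fixed_effects = c(intercept = 0),
                    sigma2_cluster = 0, sigma2_region = 0, seed = 30)
  ds <- simulate_population(cfg)
  n <- nrow(ds$women)
  expect_equal(mean(ds$women$cs), 0.5, tolerance = 4 * 0.5 / sqrt(n))
})

test_that("empirical prevalence matches the closed-form mean of the linear predictors", {
  cfg <- sim_config(n_regions = 5, clusters_per_region = rep(30, 5),
                    women_per_cluster = 15,
                    fixed_effects = c(intercept = qlogis(0.0365),
                                      education = 0.5),
                    sigma2_cluster = 0.01, sigma2_region = 0.01, seed = 31)
  ds <- simulate_population(cfg)
  n <- nrow(ds$women)
  p_true <- ds$truth$marginal_prevalence
  # oracle: mean of plogis over the realized linear predictors
  expect_equal(p_true, mean(plogis(ds$truth$eta)), tolerance = 1e-12)
  mc_err <- 4 * sqrt(p_true * (1 - p_true) / n)
  expect_equal(mean(ds$women$cs), p_true, tolerance = mc_err / p_true)
  # with small variances the marginal sits near the intercept's target
  expect_equal(p_true, 0.0365, tolerance = 0.15)
})

test_that("generator truth variances imply the published empty-model ICCs", {
  cfg <- sim_config(sigma2_cluster = 1.04, sigma2_region = 2.19, seed = 32)
  icc <- icc_three_level(cfg$sigma2_cluster, cfg$sigma2_region)
  expect_equal(round(icc, 4), c(ICC_C = 0.1595, ICC_R = 0.3359))
  ds <- simulate_population(cfg)
  # realized cluster effects are a sample from the configured variance
  expect_equal(var(ds$truth$u), 1.04, tolerance = 0.2)
})

test_that("identical seeds give identical tables; facility flags count 179", {
  cfg <- sim_config(n_regions = 3, clusters_per_region = rep(10, 3),
                    women_per_cluster = 5, n_facilities = 214,
                    n_cs_facilities = 179, seed = 33)
  d1 <- simulate_population(cfg)
  d2 <- simulate_population(cfg)
  expect_identical(d1$women, d2$women)
  expect_identical(d1$clusters, d2$clusters)
  expect_identical(d1$facilities, d2$facilities)
  expect_equal(sum(d1$facilities$cs_flag), 179)
  expect_equal(nrow(d1$facilities), 214)
  # default scale matches the survey design being emulated
  cfg_full <- sim_config(seed = 1)
  expect_equal(sum(sapply(cfg_full$clusters_per_region, sum)), 622)
  expect_equal(cfg_full$n_regions, 11)
})

test_that("zero caesarean facilities break the linkage downstream", {
  cfg <- sim_config(n_regions = 2, clusters_per_region = c(5, 5),
                    women_per_cluster = 5,
                    n_facilities = 10, n_cs_facilities = 0, seed = 34)
  expect_warning(fac <- simulate_facilities(cfg), "caesarean")
  cl <- data.frame(cluster_id = "C1", x = 0, y = 0)
  expect_error(link_nearest_cs_facility(cl, fac), "no linkable facility")
})

test_that("svc surfaces honour their specs", {
  pts <- random_points(60, extent = 200, seed = 35)
  expect_equal(simulate_svc_surface(pts, list(type = "gradient", mean = 2,
                                              amplitude = 0)),
               rep(2, 60))
  f <- simulate_svc_surface(pts, list(type = "gradient", amplitude = 1.5,
                                      direction = c(0, 1)))
  expect_equal(abs(cor(f, pts$y)), 1, tolerance = 1e-12)
  expect_equal(max(f) - min(f), 1.5, tolerance = 1e-9)
  # degenerate coordinates
  same <- data.frame(x = rep(1, 5), y = rep(2, 5))
  expect_warning(g <- simulate_svc_surface(same, list(type = "gradient",
                                                      mean = 3)),
                 "identical")
  expect_equal(g, rep(3, 5))
  # mixture variance agrees with dense direct evaluation of the same field
  spec <- list(type = "gaussian_mixture", amplitude = 2,
               centers = rbind(c(50, 50), c(150, 120)), bandwidth = 40)
  f1 <- simulate_svc_surface(random_points(4000, extent = 200, seed = 36),
                             spec)
  f2 <- simulate_svc_surface(random_points(4000, extent = 200, seed = 99),
                             spec)
  expect_equal(var(f1), var(f2), tolerance = 0.05)
})

test_that("with zero variances outcomes are homogeneous across clusters", {
  # chi-square test of homogeneity rejects at roughly the nominal rate
  rej <- 0
  for (r in 1:20) {
    cfg <- sim_config(n_regions = 2, clusters_per_region = c(15, 15),
                      women_per_cluster = 20,
                      fixed_effects = c(intercept = 0),
                      sigma2_cluster = 0, sigma2_region = 0, seed = 300 + r)
    ds <- simulate_population(cfg)
    tab <- table(ds$women$cluster_id, ds$women$cs)
    p <- suppressWarnings(chisq.test(tab)$p.value)
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 4)  # P(X >= 5 | Binom(20, 0.05)) < 0.003
})

test_that("between-cluster log-odds spread grows with the cluster variance", {
  mom <- sapply(c(0, 0.5, 1.5, 4), function(s2) {
    cfg <- sim_config(n_regions = 2, clusters_per_region = c(40, 40),
                      women_per_cluster = 100,
                      fixed_effects = c(intercept = 0),
                      sigma2_cluster = s2, sigma2_region = 0, seed = 37)
    ds <- simulate_population(cfg)
    rates <- cluster_cs_rates(ds$women)
    # Anscombe-style empirical log-odds per cluster
    lo <- log((rates$cs_count + 0.5) / (rates$births - rates$cs_count + 0.5))
    var(lo)
  })
  expect_true(all(diff(mom) > 0))
})
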