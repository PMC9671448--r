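# Spatial weights, Moran's I, incremental scan, Gi*, FDR classes.

test_that("mean nearest-neighbour distance matches brute force", {
  two <- data.frame(x = c(0, 10), y = c(0, 0))
  expect_equal(min_distance_for_neighbors(two), 10)
  grid <- expand.grid(x = 0:2, y = 0:2)
  expect_equal(min_distance_for_neighbors(grid), 1)
  pts <- random_points(30, seed = 50)
  d <- dist_oracle(pts, pts)
  diag(d) <- Inf
  expect_equal(min_distance_for_neighbors(pts), mean(apply(d, 1, min)))
})

test_that("distance-band weights match brute-force thresholding", {
  pts <- random_points(25, seed = 51)
  w <- suppressWarnings(build_distance_band_weights(pts, 30))
  d <- dist_oracle(pts, pts)
  for (i in 1:25)
    expect_equal(sort(w$neighbors[[i]]),
                 setdiff(which(d[i, ] <= 30), i))
  # self-inclusion and row standardization
  ws <- suppressWarnings(
    build_distance_band_weights(pts, 30, scheme = "row_standardized",
                                include_self = TRUE))
  expect_true(all(sapply(1:25, function(i) i %in% ws$neighbors[[i]])))
  expect_equal(sapply(ws$weights, sum), rep(1, 25))
  # tiny band: only self when included, empty otherwise
  wt <- suppressWarnings(build_distance_band_weights(pts, 1e-9))
  expect_true(all(lengths(wt$neighbors) == 0))
  # huge band: complete graph
  wb <- build_distance_band_weights(pts, 1e6)
  expect_true(all(lengths(wb$neighbors) == 24))
})

test_that("global Moran's I equals the double-sum oracle and flags degeneracy", {
  pts <- random_points(12, seed = 52)
  w <- suppressWarnings(build_distance_band_weights(pts, 40))
  vals <- rnorm(12)
  mr <- global_morans_i(vals, w)
  expect_equal(mr$I, moran_oracle(vals, dense_weights(w)), tolerance = 1e-12)
  expect_equal(mr$expectation, -1 / 11)
  expect_error(global_morans_i(rep(1, 12), w), "zero variance")
  # checkerboard on a rook grid is negatively autocorrelated
  g <- expand.grid(x = 1:4, y = 1:4)
  wg <- build_distance_band_weights(g, 1.0)
  chk <- ifelse((g$x + g$y) %% 2 == 0, 1, -1)
  expect_lt(global_morans_i(chk, wg)$I, 0)
})

test_that("Moran permutation mean matches -1/(n-1)", {
  pts <- random_points(25, seed = 53)
  w <- suppressWarnings(build_distance_band_weights(pts, 35))
  vals <- rnorm(25)
  Is <- replicate(500, global_morans_i(sample(vals), w)$I)
  se <- sd(Is) / sqrt(500)
  expect_equal(mean(Is), -1 / 24, tolerance = 6 * se / abs(1 / 24))
})

test_that("incremental scan finds the peak band and handles a single band", {
  set.seed(54)
  pts <- random_points(80, extent = 200)
  vals <- rnorm(80)
  one <- suppressWarnings(
    incremental_spatial_autocorrelation(vals, pts, start_km = 50, n_bands = 1))
  expect_equal(one$peak_km, 50)
  # a planted circular cluster of high values: peak at/after its radius
  ctr <- c(100, 100); r <- 40
  inside <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2) <= r
  vals2 <- rnorm(80, mean = ifelse(inside, 3, 0), sd = 0.5)
  isa <- suppressWarnings(
    incremental_spatial_autocorrelation(vals2, pts, start_km = 10,
                                        step_km = 10, n_bands = 10))
  expect_gte(isa$peak_km, 20)
  expect_gt(isa$peak_z, 2)
})

test_that("Gi* matches the formula oracle and its invariances", {
  pts <- random_points(15, seed = 55)
  w <- suppressWarnings(
    build_distance_band_weights(pts, 40, include_self = TRUE))
  vals <- rnorm(15)
  gi <- getis_ord_gi_star(vals, w)
  expect_equal(gi$z, gi_star_oracle(vals, dense_weights(w)),
               tolerance = 1e-12)
  # all-equal values: z identically zero
  gi0 <- getis_ord_gi_star(rep(4, 15), w)
  expect_equal(gi0$z, rep(0, 15))
  # invariant to adding a constant; sign flips under negation
  gi_shift <- getis_ord_gi_star(vals + 100, w)
  expect_equal(gi_shift$z, gi$z, tolerance = 1e-9)
  gi_neg <- getis_ord_gi_star(-vals, w)
  expect_equal(gi_neg$z, -gi$z, tolerance = 1e-9)
  # one extreme high value with modest neighbourhoods dominates
  w_self <- suppressWarnings(
    build_distance_band_weights(pts, 1e-6, include_self = TRUE))
  vals3 <- rnorm(15); vals3[7] <- 50
  gi3 <- getis_ord_gi_star(vals3, w_self)
  expect_equal(which.max(gi3$z), 7)
  # complete-coverage neighbourhood degenerates to z = 0 with a flag
  wall <- build_distance_band_weights(pts, 1e6, include_self = TRUE)
  giw <- getis_ord_gi_star(vals, wall)
  expect_true(all(giw$degenerate))
  expect_equal(giw$z, rep(0, 15))
})

test_that("FDR classification matches the textbook BH oracle and its bounds", {
  expect_equal(nrow(fdr_classify(numeric(0))), 0)
  z0 <- rep(0, 8)
  expect_true(all(fdr_classify(z0)$class == "not_significant"))
  set.seed(56)
  z <- c(10, rnorm(30))
  cl <- fdr_classify(z)
  expect_equal(as.character(cl$class[1]), "hot99")
  expect_equal(cl$p_adjusted, bh_oracle(cl$p_value), tolerance = 1e-12)
  # BH sits between unadjusted and Bonferroni at every alpha
  for (alpha in c(0.1, 0.05, 0.01)) {
    raw <- cl$p_value <= alpha
    bh <- cl$p_adjusted <= alpha
    bonf <- pmin(cl$p_value * length(z), 1) <= alpha
    expect_true(all(bh <= raw))    # never more liberal than unadjusted
    expect_true(all(bonf <= bh))   # never more conservative than Bonferroni
  }
  # signed classes: strong negative z becomes a cold spot
  cl2 <- fdr_classify(c(-10, rnorm(20)))
  expect_equal(as.character(cl2$class[1]), "cold99")
})

test_that("per-cluster rates equal an independent aggregation", {
  w <- data.frame(cluster_id = rep("A", 10), cs = c(rep(1, 3), rep(0, 7)))
  r <- cluster_cs_rates(w)
  expect_equal(r$cs_count, 3)
  expect_equal(r$cs_rate, 0.3)
  set.seed(57)
  w2 <- data.frame(cluster_id = sample(paste0("C", 1:6), 120, TRUE),
                   cs = rbinom(120, 1, 0.3))
  r2 <- cluster_cs_rates(w2)
  agg <- aggregate(cs ~ cluster_id, w2, function(x) c(sum(x), length(x)))
  expect_equal(r2$cs_count, agg$cs[, 1][match(r2$cluster_id, agg$cluster_id)])
  expect_equal(r2$births, agg$cs[, 2][match(r2$cluster_id, agg$cluster_id)])
  expect_equal(r2$cs_rate, r2$cs_count / r2$births)
})
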