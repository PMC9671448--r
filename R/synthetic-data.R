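# Synthetic population / cluster / facility generator with the three-level
# structure the downstream analysis assumes: women nested in survey clusters
# nested in regions, a binary caesarean outcome from a logistic model with
# cluster and region random intercepts (and optional random slopes), and
# facility locations inducing a distance covariate.

#' Simulation configuration
#'
#' Defaults emulate the scale of a national DHS-style design: 11 regions,
#' 622 clusters, about 11 women per cluster (~6,950 women), 214 facilities
#' of which 179 provide caesarean sections, and empty-model variance
#' components sigma2_cluster = 1.04, sigma2_region = 2.19. The default
#' intercept (-4.58) is chosen so the marginal caesarean prevalence is about
#' 3.65% under those variances. Continuous covariates (age, age at first
#' birth, parity) are generated already min-max scaled to \[0,1\].
#'
#' @param n_regions number of regions (level 3).
#' @param clusters_per_region integer vector (length `n_regions`) of cluster
#'   counts, or a length-2 range sampled uniformly per region. Default: 622
#'   clusters split as evenly as possible.
#' @param women_per_cluster length-2 integer range (uniform per cluster) or a
#'   single count.
#' @param spatial_extent c(width, height) of the study rectangle in km.
#' @param fixed_effects named log-odds vector; must include `intercept`.
#'   Recognised covariates: `education`, `wealth`, `anc1_3`, `anc4plus`,
#'   `age`, `parity`, `age_first_birth`.
#' @param sigma2_region,sigma2_cluster random-intercept variances (>= 0).
#' @param slope_variances optional list with named numeric vectors `cluster`
#'   and/or `region`: per-covariate random-slope variances.
#' @param covariate_model list of marginal parameters: `p_education`,
#'   `p_wealth_rich`, `anc_probs` (length 3, sums to 1), `parity_lambda`
#'   (truncated-Poisson rate).
#' @param n_facilities,n_cs_facilities facility counts (flagged subset
#'   provides caesarean sections).
#' @param distance_effect log-odds per unit of min-max scaled distance to the
#'   nearest caesarean facility (cluster-level covariate).
#' @param svc_surface_spec optional spec (see [simulate_svc_surface()]) for a
#'   spatially varying coefficient on `svc_covariate`.
#' @param svc_covariate covariate whose coefficient varies spatially.
#' @param displacement_km GPS displacement noise sd (km) applied to cluster
#'   coordinates; default 0 (off).
#' @param p_urban probability a cluster is urban.
#' @param seed integer RNG seed.
#' @return list of class `"cs_simconfig"`.
#' @export
sim_config <- function(n_regions = 11,
                       clusters_per_region = NULL,
                       women_per_cluster = c(8, 14),
                       spatial_extent = c(1000, 1000),
                       fixed_effects = c(intercept = -4.58),
                       sigma2_region = 2.19,
                       sigma2_cluster = 1.04,
                       slope_variances = NULL,
                       covariate_model = list(),
                       n_facilities = 214,
                       n_cs_facilities = 179,
                       distance_effect = 0,
                       svc_surface_spec = NULL,
                       svc_covariate = "anc4plus",
                       displacement_km = 0,
                       p_urban = 0.26,
                       seed = 1) {
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (is.null(clusters_per_region)) {
    # split 622 clusters as evenly as possible across the regions
    base <- 622 %/% n_regions
    extra <- 622 %% n_regions
    clusters_per_region <- rep(base, n_regions) + c(rep(1L, extra),
                                                    rep(0L, n_regions - extra))
  }
  if (length(clusters_per_region) == 2L && n_regions != 2L) {
    # treat as a range
    clusters_per_region <- list(range = clusters_per_region)
  }
  if (any(unlist(clusters_per_region) < 1) || any(women_per_cluster < 1))
    stop("counts must be >= 1")
  if (sigma2_region < 0 || sigma2_cluster < 0)
    stop("variances must be non-negative")
  if (!is.null(slope_variances)) {
    if (any(unlist(slope_variances) < 0)) stop("slope variances must be >= 0")
  }
  if (!("intercept" %in% names(fixed_effects)))
    stop("fixed_effects must include an 'intercept'")
  if (n_cs_facilities > n_facilities)
    stop("n_cs_facilities cannot exceed n_facilities")
  cm <- utils::modifyList(list(p_education = 0.48, p_wealth_rich = 0.40,
                               anc_probs = c(0.37, 0.31, 0.32),
                               parity_lambda = 2.5), covariate_model)
  if (abs(sum(cm$anc_probs) - 1) > 1e-8) stop("anc_probs must sum to 1")
  structure(list(
    n_regions = n_regions, clusters_per_region = clusters_per_region,
    women_per_cluster = women_per_cluster, spatial_extent = spatial_extent,
    fixed_effects = fixed_effects, sigma2_region = sigma2_region,
    sigma2_cluster = sigma2_cluster, slope_variances = slope_variances,
    covariate_model = cm, n_facilities = n_facilities,
    n_cs_facilities = n_cs_facilities, distance_effect = distance_effect,
    svc_surface_spec = svc_surface_spec, svc_covariate = svc_covariate,
    displacement_km = displacement_km, p_urban = p_urban,
    seed = as.integer(seed)
  ), class = "cs_simconfig")
}

# covariate names the generator knows how to produce
.cs_l1_covariates <- c("education", "wealth", "anc1_3", "anc4plus",
                       "age", "parity", "age_first_birth")

#' Simulate facility locations and service indicators
#'
#' Facilities are placed uniformly over the spatial extent; a random subset
#' of size `n_cs_facilities` carries the caesarean-provision flag. Binary
#' service indicators (6 general readiness, 7 obstetric availability, 9
#' obstetric readiness items) are drawn from a one-factor logistic model
#' (facility-level latent quality), which induces the positive inter-item
#' correlation the PCA scores rely on.
#'
#' @param config a [sim_config()] object.
#' @return facility data frame: `facility_id`, `x`, `y`, `cs_flag`, and the
#'   22 indicator columns named in [cs_indicator_sets()].
#' @export
simulate_facilities <- function(config) {
  stopifnot(inherits(config, "cs_simconfig"))
  set.seed(config$seed + 1L)
  nf <- config$n_facilities
  ext <- config$spatial_extent
  if (any(ext <= 0)) stop("spatial_extent must be positive")
  fac <- data.frame(
    facility_id = sprintf("F%03d", seq_len(nf)),
    x = stats::runif(nf, 0, ext[1L]),
    y = stats::runif(nf, 0, ext[2L]),
    stringsAsFactors = FALSE
  )
  flag <- logical(nf)
  flag[sample.int(nf, config$n_cs_facilities)] <- TRUE
  fac$cs_flag <- flag
  if (config$n_cs_facilities == 0L)
    warning("no facility carries the caesarean flag; linkage will fail")
  sets <- cs_indicator_sets()
  quality <- stats::rnorm(nf)
  items <- unlist(sets, use.names = FALSE)
  # item-specific base rates spread over a plausible range
  base <- stats::qlogis(seq(0.55, 0.9, length.out = length(items)))
  for (k in seq_along(items)) {
    fac[[items[k]]] <- as.integer(
      stats::runif(nf) < stats::plogis(base[k] + quality))
  }
  fac
}

#' Evaluate a spatially varying coefficient surface
#'
#' Smooth coefficient field evaluated at point coordinates. Supported types:
#' `"constant"`; `"gradient"` (linear trend along a direction, scaled so the
#' field spans `amplitude` over the extent of the points); and
#' `"gaussian_mixture"` (sum of Gaussian bumps at `centers` with common
#' `bandwidth`, scaled by `amplitude`).
#'
#' @param coords data frame with `x`, `y`.
#' @param spec list: `type`, `mean` (default 0), `amplitude` (default 1),
#'   `direction` (length-2, gradient only; default c(0,1) = northing),
#'   `centers` (k x 2 matrix, mixture only), `bandwidth` (km, mixture only),
#'   `weights` (length k, default 1).
#' @return numeric vector of per-location coefficient values.
#' @export
simulate_svc_surface <- function(coords, spec) {
  n <- nrow(coords)
  if (is.null(n) || n == 0L) stop("coords must be non-empty")
  spec <- utils::modifyList(list(type = "constant", mean = 0, amplitude = 1,
                                 direction = c(0, 1)), spec)
  xy <- cbind(coords$x, coords$y)
  if (all(xy[, 1L] == xy[1L, 1L]) && all(xy[, 2L] == xy[1L, 2L]) && n > 1L) {
    warning("all coordinates identical: returning a constant field")
    return(rep(spec$mean, n))
  }
  if (spec$amplitude == 0 || spec$type == "constant")
    return(rep(spec$mean, n))
  if (spec$type == "gradient") {
    d <- spec$direction / sqrt(sum(spec$direction^2))
    proj <- xy %*% d
    r <- range(proj)
    sc <- if (r[2L] > r[1L]) (proj - mean(r)) / (r[2L] - r[1L]) else proj * 0
    return(spec$mean + spec$amplitude * as.numeric(sc))
  }
  if (spec$type == "gaussian_mixture") {
    if (is.null(spec$centers) || is.null(spec$bandwidth))
      stop("gaussian_mixture spec needs 'centers' and 'bandwidth'")
    ctr <- as.matrix(spec$centers)
    wts <- if (is.null(spec$weights)) rep(1, nrow(ctr)) else spec$weights
    f <- numeric(n)
    for (k in seq_len(nrow(ctr))) {
      d2 <- (xy[, 1L] - ctr[k, 1L])^2 + (xy[, 2L] - ctr[k, 2L])^2
      f <- f + wts[k] * exp(-d2 / (2 * spec$bandwidth^2))
    }
    return(spec$mean + spec$amplitude * f)
  }
  stop("unknown surface type: ", spec$type)
}

#' Simulate the three-level population
#'
#' Generates regions (vertical strips of the extent), clusters (uniform
#' within their region's strip), women with individual covariates, and a
#' binary caesarean outcome from
#' \deqn{logit P(y=1) = X\beta + u_{cluster} + v_{region} + slope terms
#'   + \delta \cdot distance,}
#' with `u ~ N(0, sigma2_cluster)`, `v ~ N(0, sigma2_region)` and optional
#' per-covariate random slopes. Facilities are generated with
#' [simulate_facilities()] and linked to clusters to form the min-max scaled
#' distance covariate. The realized random effects, linear predictors and the
#' config used are stored in `truth`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `"cs_simdata"` with `women`, `clusters`,
#'   `facilities`, `truth`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "cs_simconfig"))
  facilities <- simulate_facilities(config)   # uses seed + 1
  set.seed(config$seed)
  R <- config$n_regions
  ext <- config$spatial_extent
  cpr <- config$clusters_per_region
  if (is.list(cpr)) {
    cpr <- sample(cpr$range[1L]:cpr$range[2L], R, replace = TRUE)
  }
  m <- sum(cpr)
  region_of_cluster <- rep(seq_len(R), cpr)
  # regions occupy contiguous vertical strips; clusters uniform within strip
  strip_w <- ext[1L] / R
  cx <- stats::runif(m, (region_of_cluster - 1L) * strip_w,
                     region_of_cluster * strip_w)
  cy <- stats::runif(m, 0, ext[2L])
  if (config$displacement_km > 0) {
    cx <- cx + stats::rnorm(m, 0, config$displacement_km)
    cy <- cy + stats::rnorm(m, 0, config$displacement_km)
  }
  clusters <- data.frame(
    cluster_id = sprintf("C%04d", seq_len(m)),
    region_id = sprintf("R%02d", region_of_cluster),
    x = cx, y = cy,
    urban = stats::runif(m) < config$p_urban,
    stringsAsFactors = FALSE
  )
  # women counts per cluster
  wpc <- config$women_per_cluster
  n_per <- if (length(wpc) == 1L) rep(as.integer(wpc), m) else
    sample(wpc[1L]:wpc[2L], m, replace = TRUE)
  n <- sum(n_per)
  ci <- rep(seq_len(m), n_per)
  ri <- region_of_cluster[ci]
  cm <- config$covariate_model
  anc <- sample.int(3L, n, replace = TRUE, prob = cm$anc_probs)
  parity_raw <- pmin(1L + stats::rpois(n, cm$parity_lambda), 12L)
  age_raw <- pmin(pmax(round(stats::rnorm(n, 28, 7)), 15L), 49L)
  afb_raw <- pmin(pmax(round(stats::rnorm(n, 19, 3.5)), 12L), age_raw)
  women <- data.frame(
    woman_id = sprintf("W%05d", seq_len(n)),
    cluster_id = clusters$cluster_id[ci],
    region_id = clusters$region_id[ci],
    education = as.integer(stats::runif(n) < cm$p_education),
    wealth = as.integer(stats::runif(n) < cm$p_wealth_rich),
    anc1_3 = as.integer(anc == 2L),
    anc4plus = as.integer(anc == 3L),
    age = (age_raw - 15) / 34,                 # min-max scaled over 15-49
    parity = (parity_raw - 1) / 11,            # over 1-12
    age_first_birth = (afb_raw - 12) / 37,     # over 12-49
    stringsAsFactors = FALSE
  )
  # distance covariate from the facility linkage
  distance01 <- rep(0, m)
  linked <- NULL
  if (config$n_cs_facilities > 0L) {
    linked <- link_nearest_cs_facility(clusters, facilities)
    distance01 <- minmax_scale(linked$distance_km)
  }
  # random effects
  u <- stats::rnorm(m, 0, sqrt(config$sigma2_cluster))
  v <- stats::rnorm(R, 0, sqrt(config$sigma2_region))
  beta <- config$fixed_effects
  eta <- rep(beta[["intercept"]], n)
  for (nm in intersect(names(beta), .cs_l1_covariates))
    eta <- eta + beta[[nm]] * women[[nm]]
  eta <- eta + u[ci] + v[ri] + config$distance_effect * distance01[ci]
  slope_dev <- list()
  sv <- config$slope_variances
  if (!is.null(sv)) {
    for (nm in names(sv$cluster)) {
      a <- stats::rnorm(m, 0, sqrt(sv$cluster[[nm]]))
      eta <- eta + a[ci] * women[[nm]]
      slope_dev[[paste0("cluster.", nm)]] <- a
    }
    for (nm in names(sv$region)) {
      b <- stats::rnorm(R, 0, sqrt(sv$region[[nm]]))
      eta <- eta + b[ri] * women[[nm]]
      slope_dev[[paste0("region.", nm)]] <- b
    }
  }
  svc_field <- NULL
  if (!is.null(config$svc_surface_spec)) {
    svc_field <- simulate_svc_surface(clusters, config$svc_surface_spec)
    eta <- eta + svc_field[ci] * women[[config$svc_covariate]]
  }
  p <- stats::plogis(eta)
  women$cs <- as.integer(stats::runif(n) < p)
  truth <- list(config = config, u = u, v = v, slope_dev = slope_dev,
                svc_field = svc_field, eta = eta,
                marginal_prevalence = mean(p),
                distance01 = distance01)
  structure(list(women = women, clusters = clusters,
                 facilities = facilities, linked = linked, truth = truth),
            class = "cs_simdata")
}

#' @export
print.cs_simdata <- function(x, ...) {
  cat("Synthetic linked dataset:", nrow(x$women), "women in",
      nrow(x$clusters), "clusters in",
      length(unique(x$clusters$region_id)), "regions;",
      nrow(x$facilities), "facilities (",
      sum(x$facilities$cs_flag), "caesarean-providing)\n")
  cat(sprintf("Caesarean outcome prevalence: %.2f%% (true marginal %.2f%%)\n",
              100 * mean(x$women$cs), 100 * x$truth$marginal_prevalence))
  invisible(x)
}
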