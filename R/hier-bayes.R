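# Three-level Bayesian hierarchical logistic model fitted by an adaptive
# Metropolis-within-Gibbs sampler: component-wise random-walk Metropolis for
# fixed effects and random effects (vectorized across conditionally
# independent clusters/regions), conjugate inverse-gamma Gibbs steps for all
# variance components.

#' Hierarchical model specification
#'
#' @param outcome name of the binary outcome column.
#' @param l1_covariates individual-level covariate names.
#' @param l2_covariate optional cluster-level covariate name (e.g. the scaled
#'   distance to the nearest caesarean facility), or `NULL`.
#' @param random_slopes subset of `l1_covariates` whose coefficients get
#'   cluster- and region-level random slopes.
#' @param cluster,region grouping column names.
#' @return list of class `"cs_modelspec"`.
#' @export
hier_model_spec <- function(outcome = "cs",
                            l1_covariates = c("education", "wealth", "anc1_3",
                                              "anc4plus", "age", "parity",
                                              "age_first_birth"),
                            l2_covariate = NULL,
                            random_slopes = character(0),
                            cluster = "cluster_id", region = "region_id") {
  if (!all(random_slopes %in% l1_covariates))
    stop("random_slopes must be a subset of l1_covariates")
  structure(list(outcome = outcome, l1_covariates = l1_covariates,
                 l2_covariate = l2_covariate, random_slopes = random_slopes,
                 cluster = cluster, region = region),
            class = "cs_modelspec")
}

#' Prior specification
#'
#' Weakly informative defaults: fixed effects Normal(0, 1000); every
#' random-effect variance InverseGamma(shape 0.01, scale 0.01).
#'
#' @param beta_mean,beta_var normal prior moments for fixed effects.
#' @param ig_shape,ig_scale inverse-gamma hyperparameters for variances.
#' @return list of class `"cs_priorspec"`.
#' @export
prior_spec <- function(beta_mean = 0, beta_var = 1000,
                       ig_shape = 0.01, ig_scale = 0.01) {
  if (beta_var <= 0 || ig_shape <= 0 || ig_scale <= 0)
    stop("prior variance and IG parameters must be positive")
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 ig_shape = ig_shape, ig_scale = ig_scale),
            class = "cs_priorspec")
}

#' MCMC configuration
#'
#' The default is a test-scale chain (15,000 iterations, 5,000 burn-in, thin
#' 5). `scale = "paper"` selects the survey-scale configuration (175,000 /
#' 25,000 / 25). With `burnin_additional = FALSE` (default) the retained draw
#' count is `floor((n_iter - burn_in)/thin)`; with `TRUE`, `n_iter` counts
#' post-burn-in iterations, so `burn_in + n_iter` are run and
#' `floor(n_iter/thin)` draws are retained (the alternative accounting under
#' which the survey-scale chain keeps 7,000 draws instead of 6,000).
#'
#' @param n_iter,burn_in,thin chain dimensions.
#' @param seed RNG seed.
#' @param scale `"test"` (default) or `"paper"`; overrides the three chain
#'   dimensions unless they are supplied explicitly.
#' @param adapt adapt proposal scales during burn-in (target acceptance band
#'   0.2-0.5).
#' @param burnin_additional see Details.
#' @param store_random_effects keep per-draw random effects (memory heavy at
#'   survey scale).
#' @return list of class `"cs_mcmcconfig"`.
#' @export
mcmc_config <- function(n_iter = NULL, burn_in = NULL, thin = NULL, seed = 1,
                        scale = c("test", "paper"), adapt = TRUE,
                        burnin_additional = FALSE,
                        store_random_effects = TRUE) {
  scale <- match.arg(scale)
  def <- if (scale == "paper") c(175000L, 25000L, 25L) else c(15000L, 5000L, 5L)
  if (is.null(n_iter)) n_iter <- def[1L]
  if (is.null(burn_in)) burn_in <- def[2L]
  if (is.null(thin)) thin <- def[3L]
  if (!burnin_additional && burn_in >= n_iter)
    stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  n_retained <- if (burnin_additional) floor(n_iter / thin)
                else floor((n_iter - burn_in) / thin)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt = adapt, burnin_additional = burnin_additional,
                 store_random_effects = store_random_effects,
                 n_retained = as.integer(n_retained)),
            class = "cs_mcmcconfig")
}

# numerically safe Bernoulli-logit log-likelihood terms, s = 2y - 1:
# -log(1 + exp(-x)) = min(x, 0) - log1p(exp(-|x|)), stable for large |x|
.ll_logit <- function(s_eta) {
  pmin(s_eta, 0) - log1p(exp(-abs(s_eta)))
}

# O(n) group sums over a grouping that is contiguous in memory;
# `ends` marks the last row of each group
.make_gsum <- function(ends) {
  force(ends)
  function(x) {
    cs <- cumsum(x)[ends]
    cs - c(0, cs[-length(cs)])
  }
}

#' Draw a variance from its inverse-gamma full conditional
#'
#' Given random effects with sum of squares `sum_sq` over `n_effects`
#' components and an IG(shape, scale) prior, the full conditional is
#' IG(shape + n_effects/2, scale + sum_sq/2). Used by the Gibbs variance
#' steps of [fit_hier_logistic()].
#'
#' @param n number of draws.
#' @param sum_sq sum of squared random effects.
#' @param n_effects number of random effects.
#' @param shape,scale prior hyperparameters.
#' @return numeric vector of variance draws.
#' @export
rinvgamma_full_conditional <- function(n, sum_sq, n_effects,
                                       shape = 0.01, scale = 0.01) {
  1 / stats::rgamma(n, shape = shape + n_effects / 2,
                    rate = scale + sum_sq / 2)
}

#' Joint log-posterior of the three-level logistic model
#'
#' Bernoulli-logit log-likelihood plus Normal log-priors on fixed effects
#' and random effects and inverse-gamma log-priors on variances. Reference
#' implementation used for validation; the sampler maintains the same
#' quantity incrementally.
#'
#' @param params list with `beta` (named: intercept first), optional `u`
#'   (cluster intercepts), `v` (region intercepts), `sigma2_C`, `sigma2_R`,
#'   optional `slopes_C`/`slopes_R` (matrices clusters/regions x slope
#'   covariates) and `tau2_C`/`tau2_R` (their variances).
#' @param data women data frame (may have zero rows).
#' @param spec [hier_model_spec()].
#' @param priors [prior_spec()].
#' @return scalar log-posterior (`-Inf` for non-positive variances).
#' @export
log_posterior <- function(params, data, spec, priors) {
  vars <- c(params$sigma2_C, params$sigma2_R, params$tau2_C, params$tau2_R)
  if (any(vars <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(params$beta, priors$beta_mean,
                         sqrt(priors$beta_var), log = TRUE))
  dig <- function(x) priors$ig_shape * log(priors$ig_scale) -
    lgamma(priors$ig_shape) - (priors$ig_shape + 1) * log(x) -
    priors$ig_scale / x
  if (!is.null(params$u)) {
    lp <- lp + sum(stats::dnorm(params$u, 0, sqrt(params$sigma2_C), log = TRUE)) +
      dig(params$sigma2_C)
  }
  if (!is.null(params$v)) {
    lp <- lp + sum(stats::dnorm(params$v, 0, sqrt(params$sigma2_R), log = TRUE)) +
      dig(params$sigma2_R)
  }
  if (!is.null(params$slopes_C)) {
    for (k in seq_len(ncol(params$slopes_C)))
      lp <- lp + sum(stats::dnorm(params$slopes_C[, k], 0,
                                  sqrt(params$tau2_C[k]), log = TRUE)) +
        dig(params$tau2_C[k])
  }
  if (!is.null(params$slopes_R)) {
    for (k in seq_len(ncol(params$slopes_R)))
      lp <- lp + sum(stats::dnorm(params$slopes_R[, k], 0,
                                  sqrt(params$tau2_R[k]), log = TRUE)) +
        dig(params$tau2_R[k])
  }
  if (nrow(data) == 0L) return(lp)
  eta <- .hier_eta(params, data, spec)
  s <- 2 * data[[spec$outcome]] - 1
  lp + sum(.ll_logit(s * eta))
}

# linear predictor for explicit parameter values (reference path)
.hier_eta <- function(params, data, spec) {
  covs <- c(spec$l1_covariates, spec$l2_covariate)
  covs <- covs[covs %in% names(params$beta)]
  eta <- rep(params$beta[["intercept"]], nrow(data))
  for (nm in covs) eta <- eta + params$beta[[nm]] * data[[nm]]
  if (!is.null(params$u)) {
    ci <- match(data[[spec$cluster]], names(params$u))
    eta <- eta + params$u[ci]
  }
  if (!is.null(params$v)) {
    ri <- match(data[[spec$region]], names(params$v))
    eta <- eta + params$v[ri]
  }
  if (!is.null(params$slopes_C)) {
    ci <- match(data[[spec$cluster]], rownames(params$slopes_C))
    for (nm in colnames(params$slopes_C))
      eta <- eta + params$slopes_C[ci, nm] * data[[nm]]
  }
  if (!is.null(params$slopes_R)) {
    ri <- match(data[[spec$region]], rownames(params$slopes_R))
    for (nm in colnames(params$slopes_R))
      eta <- eta + params$slopes_R[ri, nm] * data[[nm]]
  }
  eta
}

#' Fit the three-level Bayesian hierarchical logistic model
#'
#' Adaptive Metropolis-within-Gibbs: each fixed effect is updated by
#' random-walk Metropolis against the full-data likelihood; cluster and
#' region random intercepts (and random slopes) are updated jointly in a
#' vectorized single-site sweep, valid because groups are conditionally
#' independent given the rest; variance components are drawn exactly from
#' their inverse-gamma full conditionals. Proposal scales adapt only during
#' burn-in (Robbins-Monro toward 35% acceptance). Stored draws are
#' post-swept: group means of random effects are folded into their parent
#' level (cluster means into regions, region mean into the intercept), which
#' leaves every linear predictor unchanged but reports the identified
#' quantities.
#'
#' @param data women data frame carrying the outcome, covariates, cluster and
#'   region ids. Zero rows gives a prior-only run (no random-effect levels).
#' @param spec [hier_model_spec()].
#' @param priors [prior_spec()].
#' @param mcmc [mcmc_config()].
#' @return object of class `"cs_hierfit"`: retained draws (`beta`,
#'   `variances`, optionally `u`, `v`, slope deviations), per-draw
#'   `deviance`, mean linear predictor `eta_bar`, acceptance rates, and the
#'   three input specs.
#' @export
fit_hier_logistic <- function(data, spec = hier_model_spec(),
                              priors = prior_spec(), mcmc = mcmc_config()) {
  set.seed(mcmc$seed)
  prior_only <- is.null(data) || nrow(data) == 0L
  covs <- c(spec$l1_covariates, spec$l2_covariate)
  p <- 1L + length(covs)
  beta_names <- c("intercept", covs)
  if (!prior_only) {
    miss <- setdiff(c(spec$outcome, covs, spec$cluster, spec$region),
                    names(data))
    if (length(miss))
      stop("data lacks column(s): ", paste(miss, collapse = ", "))
    y <- data[[spec$outcome]]
    if (!all(y %in% c(0, 1))) stop("outcome must be strictly 0/1")
    if (all(y == 0) || all(y == 1))
      stop("outcome is constant; the model is not identifiable")
    n <- length(y)
    s <- 2 * y - 1
    X <- cbind(intercept = rep(1, n))
    for (nm in covs) X <- cbind(X, data[[nm]])
    colnames(X) <- beta_names
    # cheap separation screen on binary covariates
    for (nm in covs) {
      xv <- data[[nm]]
      if (all(xv %in% c(0, 1)) && length(unique(xv)) == 2L) {
        t1 <- unique(y[xv == 1]); t0 <- unique(y[xv == 0])
        if (length(t1) == 1L && length(t0) == 1L && t1 != t0)
          warning("covariate '", nm, "' separates the outcome; ",
                  "the prior regularizes the fit")
      }
    }
    cl_lev <- sort(unique(data[[spec$cluster]]))
    rg_lev <- sort(unique(data[[spec$region]]))
    m <- length(cl_lev); R <- length(rg_lev)
    if (m < 2L || R < 2L)
      stop("need at least 2 clusters in at least 2 regions")
    ci <- match(data[[spec$cluster]], cl_lev)
    ri <- match(data[[spec$region]], rg_lev)
    # sort rows by (region, cluster) so both groupings are contiguous and
    # group sums reduce to cumsum differences (clusters nest in regions)
    ord <- order(ri, ci)
    ci <- ci[ord]; ri <- ri[ord]; y <- y[ord]; s <- s[ord]
    # relabel clusters in sorted order
    cl_pos <- match(unique(ci), ci)
    cl_lev <- cl_lev[ci[cl_pos]]
    ci <- rep(seq_len(m), times = diff(c(which(!duplicated(ci)), n + 1L)))
    reg_of_cl <- ri[cl_pos]
    ends_c <- c(which(diff(ci) != 0L), n)
    ends_r <- c(which(diff(ri) != 0L), n)
    gsum_c <- .make_gsum(ends_c)
    gsum_r <- .make_gsum(ends_r)
    data <- data[ord, , drop = FALSE]
    X <- X[ord, , drop = FALSE]
    S <- length(spec$random_slopes)
    Xs <- if (S) sapply(spec$random_slopes, function(nm) data[[nm]]) else NULL
    if (S == 1L) Xs <- matrix(Xs, ncol = 1L)
  } else {
    n <- 0L; m <- 0L; R <- 0L; S <- 0L
    s <- numeric(0); X <- matrix(0, 0, p, dimnames = list(NULL, beta_names))
    ci <- ri <- integer(0); reg_of_cl <- integer(0); Xs <- NULL
    cl_lev <- rg_lev <- character(0)
  }

  # state
  beta <- rep(0, p); names(beta) <- beta_names
  u <- rep(0, m); v <- rep(0, R)
  A <- if (S) matrix(0, m, S) else NULL       # cluster slope deviations
  B <- if (S) matrix(0, R, S) else NULL       # region slope deviations
  sig2_C <- 1; sig2_R <- 1
  tau2_C <- rep(1, S); tau2_R <- rep(1, S)
  eta <- as.numeric(X %*% beta)
  ll <- .ll_logit(s * eta)
  sum_ll <- sum(ll)
  pv <- priors$beta_var; pm <- priors$beta_mean
  a0 <- priors$ig_shape; b0 <- priors$ig_scale

  # proposal scales (log) and acceptance tracking
  ls_beta <- rep(log(ifelse(prior_only, sqrt(pv), 0.3)), p)
  ls_u <- log(0.5); ls_v <- log(0.5)
  ls_A <- rep(log(0.5), max(S, 1L)); ls_B <- rep(log(0.5), max(S, 1L))
  acc_beta <- rep(0, p); acc_u <- 0; acc_v <- 0
  acc_A <- rep(0, max(S, 1L)); acc_B <- rep(0, max(S, 1L))
  batch <- 100L; batch_no <- 0L

  total_iter <- if (mcmc$burnin_additional) mcmc$burn_in + mcmc$n_iter
                else mcmc$n_iter
  burn <- mcmc$burn_in
  n_keep <- mcmc$n_retained
  draws_beta <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, beta_names))
  var_names <- c("sigma2_C", "sigma2_R",
                 if (S) paste0("tau2_C.", spec$random_slopes),
                 if (S) paste0("tau2_R.", spec$random_slopes))
  draws_var <- matrix(NA_real_, n_keep, length(var_names),
                      dimnames = list(NULL, var_names))
  deviance <- rep(NA_real_, n_keep)
  keep_re <- mcmc$store_random_effects && m > 0L
  draws_u <- if (keep_re) matrix(NA_real_, n_keep, m,
                                 dimnames = list(NULL, cl_lev)) else NULL
  draws_v <- if (keep_re) matrix(NA_real_, n_keep, R,
                                 dimnames = list(NULL, rg_lev)) else NULL
  eta_sum <- numeric(n)
  kept <- 0L

  # group-mean helper: mean of u within region, expanded per cluster
  grp_mean <- function(x, g, ng) {
    mns <- rowsum(x, g) / tabulate(g, ng)
    list(per_group = as.numeric(mns), expanded = as.numeric(mns)[g])
  }

  for (it in seq_len(total_iter)) {
    # --- fixed effects, component-wise RW Metropolis
    for (j in seq_len(p)) {
      delta <- stats::rnorm(1, 0, exp(ls_beta[j]))
      bj_new <- beta[j] + delta
      if (n > 0L) {
        eta_new <- eta + X[, j] * delta
        ll_new <- .ll_logit(s * eta_new)
        dll <- sum(ll_new) - sum_ll
      } else dll <- 0
      dpr <- ((beta[j] - pm)^2 - (bj_new - pm)^2) / (2 * pv)
      if (log(stats::runif(1)) < dll + dpr) {
        beta[j] <- bj_new
        if (n > 0L) { eta <- eta_new; ll <- ll_new; sum_ll <- sum(ll_new) }
        acc_beta[j] <- acc_beta[j] + 1
      }
    }
    if (m > 0L) {
      # --- cluster intercepts, vectorized single-site sweep
      delta <- stats::rnorm(m, 0, exp(ls_u))
      eta_new <- eta + delta[ci]
      ll_new <- .ll_logit(s * eta_new)
      dll_c <- gsum_c(ll_new - ll)
      u_new <- u + delta
      dpr_c <- (u^2 - u_new^2) / (2 * sig2_C)
      acc <- log(stats::runif(m)) < dll_c + dpr_c
      if (any(acc)) {
        u[acc] <- u_new[acc]
        rows <- acc[ci]
        eta[rows] <- eta_new[rows]; ll[rows] <- ll_new[rows]
        sum_ll <- sum(ll)
      }
      acc_u <- acc_u + mean(acc)
      # --- region intercepts
      delta <- stats::rnorm(R, 0, exp(ls_v))
      eta_new <- eta + delta[ri]
      ll_new <- .ll_logit(s * eta_new)
      dll_r <- gsum_r(ll_new - ll)
      v_new <- v + delta
      dpr_r <- (v^2 - v_new^2) / (2 * sig2_R)
      acc <- log(stats::runif(R)) < dll_r + dpr_r
      if (any(acc)) {
        v[acc] <- v_new[acc]
        rows <- acc[ri]
        eta[rows] <- eta_new[rows]; ll[rows] <- ll_new[rows]
        sum_ll <- sum(ll)
      }
      acc_v <- acc_v + mean(acc)
      # --- random slopes
      if (S) {
        for (k in seq_len(S)) {
          xk <- Xs[, k]
          # cluster level
          delta <- stats::rnorm(m, 0, exp(ls_A[k]))
          eta_new <- eta + delta[ci] * xk
          ll_new <- .ll_logit(s * eta_new)
          dll_c <- gsum_c(ll_new - ll)
          a_new <- A[, k] + delta
          dpr_c <- (A[, k]^2 - a_new^2) / (2 * tau2_C[k])
          acc <- log(stats::runif(m)) < dll_c + dpr_c
          if (any(acc)) {
            A[acc, k] <- a_new[acc]
            rows <- acc[ci]
            eta[rows] <- eta_new[rows]; ll[rows] <- ll_new[rows]
            sum_ll <- sum(ll)
          }
          acc_A[k] <- acc_A[k] + mean(acc)
          # region level
          delta <- stats::rnorm(R, 0, exp(ls_B[k]))
          eta_new <- eta + delta[ri] * xk
          ll_new <- .ll_logit(s * eta_new)
          dll_r <- gsum_r(ll_new - ll)
          b_new <- B[, k] + delta
          dpr_r <- (B[, k]^2 - b_new^2) / (2 * tau2_R[k])
          acc <- log(stats::runif(R)) < dll_r + dpr_r
          if (any(acc)) {
            B[acc, k] <- b_new[acc]
            rows <- acc[ri]
            eta[rows] <- eta_new[rows]; ll[rows] <- ll_new[rows]
            sum_ll <- sum(ll)
          }
          acc_B[k] <- acc_B[k] + mean(acc)
        }
      }
    }
    # --- conjugate inverse-gamma variance updates
    sig2_C <- rinvgamma_full_conditional(1, sum(u^2), m, a0, b0)
    sig2_R <- rinvgamma_full_conditional(1, sum(v^2), R, a0, b0)
    if (S) {
      for (k in seq_len(S)) {
        tau2_C[k] <- rinvgamma_full_conditional(1, sum(A[, k]^2), m, a0, b0)
        tau2_R[k] <- rinvgamma_full_conditional(1, sum(B[, k]^2), R, a0, b0)
      }
    }
    # --- proposal adaptation (burn-in only)
    if (mcmc$adapt && it <= burn && it %% batch == 0L) {
      batch_no <- batch_no + 1L
      gam <- min(0.5, 5 / sqrt(batch_no))
      ls_beta <- ls_beta + gam * (acc_beta / batch - 0.35)
      if (m > 0L) {
        ls_u <- ls_u + gam * (acc_u / batch - 0.35)
        ls_v <- ls_v + gam * (acc_v / batch - 0.35)
        if (S) {
          ls_A <- ls_A + gam * (acc_A / batch - 0.35)
          ls_B <- ls_B + gam * (acc_B / batch - 0.35)
        }
      }
      acc_beta[] <- 0; acc_u <- 0; acc_v <- 0; acc_A[] <- 0; acc_B[] <- 0
    }
    # --- storage with post-sweeping of random-effect means
    post <- if (mcmc$burnin_additional) it - burn else it
    if (it > burn && post >= 1L && post %% mcmc$thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      if (m > 0L) {
        gm <- grp_mean(u, reg_of_cl, R)
        u_rep <- u - gm$expanded
        v_rep <- v + gm$per_group
        v_mean <- mean(v_rep)
        v_rep <- v_rep - v_mean
        b_rep <- beta
        b_rep["intercept"] <- b_rep["intercept"] + v_mean
        if (S) {
          for (k in seq_len(S)) {
            gmk <- grp_mean(A[, k], reg_of_cl, R)
            bmk <- mean(B[, k] + gmk$per_group)
            b_rep[spec$random_slopes[k]] <-
              b_rep[spec$random_slopes[k]] + bmk
          }
        }
        draws_beta[kept, ] <- b_rep
        if (keep_re) { draws_u[kept, ] <- u_rep; draws_v[kept, ] <- v_rep }
      } else {
        draws_beta[kept, ] <- beta
      }
      draws_var[kept, ] <- c(sig2_C, sig2_R,
                             if (S) tau2_C, if (S) tau2_R)
      deviance[kept] <- -2 * sum_ll
      eta_sum <- eta_sum + eta
    }
  }
  if (kept < n_keep) {
    draws_beta <- draws_beta[seq_len(kept), , drop = FALSE]
    draws_var <- draws_var[seq_len(kept), , drop = FALSE]
    deviance <- deviance[seq_len(kept)]
    if (keep_re) {
      draws_u <- draws_u[seq_len(kept), , drop = FALSE]
      draws_v <- draws_v[seq_len(kept), , drop = FALSE]
    }
  }
  final_acc <- list(beta = acc_beta, u = acc_u, v = acc_v)
  structure(list(
    beta = draws_beta, variances = draws_var, deviance = deviance,
    u = draws_u, v = draws_v,
    eta_bar = if (kept > 0L && n > 0L) eta_sum / kept else NULL,
    s = if (n > 0L) s else NULL,
    n_retained = kept, n_obs = n, n_clusters = m, n_regions = R,
    spec = spec, priors = priors, mcmc = mcmc,
    proposal_log_sd = list(beta = ls_beta, u = ls_u, v = ls_v)
  ), class = "cs_hierfit")
}

#' Posterior summary with equal-tail 95% credible intervals
#'
#' @param chain a `"cs_hierfit"` object, or a numeric matrix of draws.
#' @param prob interval mass (default 0.95, equal-tail).
#' @return data frame: `parameter`, `mean`, `lower`, `upper`, and for
#'   coefficients the exponentiated (odds-ratio) columns `or`, `or_lower`,
#'   `or_upper`.
#' @export
summarize_posterior <- function(chain, prob = 0.95) {
  if (inherits(chain, "cs_hierfit")) {
    draws <- cbind(chain$beta, chain$variances)
    is_coef <- c(rep(TRUE, ncol(chain$beta)), rep(FALSE, ncol(chain$variances)))
  } else {
    draws <- as.matrix(chain)
    is_coef <- rep(TRUE, ncol(draws))
  }
  if (nrow(draws) < 100L)
    stop("need at least 100 retained draws to summarize")
  alpha <- (1 - prob) / 2
  qs <- apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    lower = qs[1L, ], upper = qs[2L, ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$or <- ifelse(is_coef, exp(out$mean), NA_real_)
  out$or_lower <- ifelse(is_coef, exp(out$lower), NA_real_)
  out$or_upper <- ifelse(is_coef, exp(out$upper), NA_real_)
  out
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance; `Dhat` the deviance at the
#' posterior-mean parameters (computed from the stored mean linear
#' predictor, exact because the predictor is linear in the parameters);
#' `pD = Dbar - Dhat`; `DIC = Dhat + 2 pD`.
#'
#' @param fit a `"cs_hierfit"` object with at least 2 retained draws.
#' @return named list `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "cs_hierfit"))
  if (length(fit$deviance) < 2L) stop("need at least 2 retained draws")
  Dbar <- mean(fit$deviance)
  if (is.null(fit$eta_bar)) {  # prior-only chain: no data deviance
    Dhat <- 0
  } else {
    Dhat <- -2 * sum(.ll_logit(fit$s * fit$eta_bar))
  }
  pD <- Dbar - Dhat
  list(dic = Dhat + 2 * pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' @export
print.cs_hierfit <- function(x, ...) {
  cat("Three-level Bayesian hierarchical logistic fit\n")
  cat(sprintf("  %d women, %d clusters, %d regions; %d retained draws\n",
              x$n_obs, x$n_clusters, x$n_regions, x$n_retained))
  cat("  Posterior means (log-odds):\n")
  print(round(colMeans(x$beta), 3))
  cat("  Variance components (posterior means):\n")
  print(round(colMeans(x$variances), 3))
  invisible(x)
}

#' @export
summary.cs_hierfit <- function(object, ...) summarize_posterior(object, ...)

#' @export
coef.cs_hierfit <- function(object, ...) colMeans(object$beta)

#' Fit the standard model ladder
#'
#' Model 0: intercept + cluster/region random intercepts. Model 1: + the
#' individual-level fixed effects. Model 2: + random slopes for all
#' individual-level covariates at both levels. Model 3: + the cluster-level
#' distance covariate. Returns the variance-partition table (ICC, PCV, DIC)
#' via [build_variance_table()].
#'
#' @param data women data frame (with the distance covariate merged in).
#' @param spec full model spec (Model 3); the ladder strips it down.
#' @param priors,mcmc passed to each fit; per-model seeds are offset from
#'   `mcmc$seed`.
#' @param models which rungs to fit (default 0:3).
#' @return list of class `"cs_ladder"`: `fits` (list of `"cs_hierfit"`),
#'   `table` (the `"cs_variance_table"`).
#' @export
model_ladder <- function(data, spec = hier_model_spec(), priors = prior_spec(),
                         mcmc = mcmc_config(), models = 0:3) {
  if (models[1L] != 0L) stop("the ladder must start with the empty model 0")
  specs <- list(
    `Model 0` = hier_model_spec(outcome = spec$outcome,
                                l1_covariates = character(0),
                                cluster = spec$cluster, region = spec$region),
    `Model 1` = hier_model_spec(outcome = spec$outcome,
                                l1_covariates = spec$l1_covariates,
                                cluster = spec$cluster, region = spec$region),
    `Model 2` = hier_model_spec(outcome = spec$outcome,
                                l1_covariates = spec$l1_covariates,
                                random_slopes = spec$l1_covariates,
                                cluster = spec$cluster, region = spec$region),
    `Model 3` = hier_model_spec(outcome = spec$outcome,
                                l1_covariates = spec$l1_covariates,
                                l2_covariate = spec$l2_covariate,
                                random_slopes = spec$l1_covariates,
                                cluster = spec$cluster, region = spec$region)
  )[models + 1L]
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (i in seq_along(specs)) {
    mc <- mcmc
    mc$seed <- mcmc$seed + i - 1L
    fits[[i]] <- tryCatch(
      fit_hier_logistic(data, specs[[i]], priors, mc),
      error = function(e) stop("ladder failed at ", names(specs)[i], ": ",
                               conditionMessage(e)))
  }
  ladder <- lapply(fits, function(f) {
    vm <- colMeans(f$variances)
    slopes <- f$spec$random_slopes
    list(sigma2_C = vm[["sigma2_C"]], sigma2_R = vm[["sigma2_R"]],
         dic = dic(f)$dic,
         slope_variances_C = if (length(slopes))
           stats::setNames(vm[paste0("tau2_C.", slopes)], slopes),
         slope_variances_R = if (length(slopes))
           stats::setNames(vm[paste0("tau2_R.", slopes)], slopes))
  })
  structure(list(fits = fits, table = build_variance_table(ladder)),
            class = "cs_ladder")
}

#' @export
print.cs_ladder <- function(x, ...) {
  print(x$table)
  invisible(x)
}
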