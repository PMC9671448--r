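# Moran-eigenvector spatially and non-spatially varying coefficient (SNVC)
# regression on cluster-level counts, with a normalizing response
# transformation (log-Gaussian approximation, optionally followed by a
# sinh-arcsinh (SAL) adjustment fitted by maximum likelihood).

#' Moran eigenvector basis
#'
#' Builds the exponential proximity matrix `C_ij = exp(-d_ij / r)` (zero
#' diagonal) with kernel range `r` equal to the maximum nearest-neighbour
#' distance, double-centres it (`M C M`, `M = I - 11'/n`) and retains the
#' eigenvectors whose eigenvalues satisfy `lambda / lambda_max >
#' retention_fraction` — the positively autocorrelated map patterns.
#'
#' @param coords data frame with `x`, `y` (km); at least 3 distinct points.
#' @param retention_fraction eigenvalue retention threshold (default 0.25).
#' @return list of class `"cs_eigenbasis"`: `E` (n x L orthonormal columns),
#'   `lambda` (descending), `range_km`, `retention_fraction`.
#' @export
moran_eigenvectors <- function(coords, retention_fraction = 0.25) {
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 locations")
  d <- euclidean_distance_matrix(coords, coords)
  diag(d) <- Inf
  r <- max(apply(d, 1L, min))
  if (r == 0) stop("all points coincide; no spatial structure")
  diag(d) <- 0
  C <- exp(-d / r)
  diag(C) <- 0
  Cc <- sweep(C, 1L, rowMeans(C))
  Cc <- sweep(Cc, 2L, colMeans(Cc))
  eg <- eigen(Cc, symmetric = TRUE)
  keep <- eg$values > 0 & eg$values / eg$values[1L] > retention_fraction
  if (!any(keep)) stop("no positive spatial structure retained")
  structure(list(E = eg$vectors[, keep, drop = FALSE],
                 lambda = eg$values[keep],
                 range_km = r, retention_fraction = retention_fraction),
            class = "cs_eigenbasis")
}

#' Transform specification for cluster-level counts
#'
#' @param mode `"log_gaussian"` (default) or `"sal"` (log-Gaussian followed
#'   by a maximum-likelihood sinh-arcsinh adjustment).
#' @param offset constant added before the log (default 0.5).
#' @return list of class `"cs_transformspec"`.
#' @export
transform_spec <- function(mode = c("log_gaussian", "sal"), offset = 0.5) {
  mode <- match.arg(mode)
  structure(list(mode = mode, offset = offset), class = "cs_transformspec")
}

# sinh-arcsinh forward map and log-Jacobian; par = (a, log_b, eps, log_delta)
.sal_forward <- function(z, par) {
  a <- par[1L]; b <- exp(par[2L]); eps <- par[3L]; delta <- exp(par[4L])
  w <- (z - a) / b
  sinh(delta * asinh(w) - eps)
}
.sal_logjac <- function(z, par) {
  a <- par[1L]; b <- exp(par[2L]); eps <- par[3L]; delta <- exp(par[4L])
  w <- (z - a) / b
  log(delta) + log(cosh(delta * asinh(w) - eps)) -
    0.5 * log1p(w^2) - log(b)
}

#' Normalizing transformation of caesarean counts
#'
#' `"log_gaussian"` mode returns `log(count + offset)`. `"sal"` mode further
#' applies a sinh-arcsinh transformation `sinh(delta * asinh((z - a)/b) -
#' eps)` whose four parameters are fitted by maximum likelihood so the
#' transformed response is as close to standard normal as the family allows;
#' with `eps = 0`, `delta = 1` it reduces to an affine rescaling of the log.
#' The returned object retains the exact inverse.
#'
#' @param counts non-negative counts.
#' @param births unused by the transform itself; kept alongside for
#'   downstream exposure adjustment.
#' @param spec a [transform_spec()].
#' @return list of class `"cs_transform"`: `y_star`, `mode`, `offset`,
#'   `sal_par` (or NULL), `births`.
#' @export
transform_counts <- function(counts, births = NULL, spec = transform_spec()) {
  if (any(counts < 0)) stop("counts must be non-negative")
  z <- log(counts + spec$offset)
  if (spec$mode == "log_gaussian") {
    return(structure(list(y_star = z, mode = spec$mode, offset = spec$offset,
                          sal_par = NULL, births = births),
                     class = "cs_transform"))
  }
  nll <- function(par) {
    t <- .sal_forward(z, par)
    lj <- .sal_logjac(z, par)
    val <- -sum(stats::dnorm(t, log = TRUE) + lj)
    if (!is.finite(val)) 1e10 else val
  }
  start <- c(mean(z), log(stats::sd(z) + 1e-8), 0, 0)
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(y_star = .sal_forward(z, opt$par), mode = spec$mode,
                 offset = spec$offset, sal_par = opt$par, births = births),
            class = "cs_transform")
}

#' Invert a count transformation
#'
#' @param trans a `"cs_transform"` object.
#' @param y values on the transformed scale.
#' @return values on the original count scale.
#' @export
inverse_transform <- function(trans, y) {
  z <- if (trans$mode == "sal") {
    par <- trans$sal_par
    par[1L] + exp(par[2L]) * sinh((asinh(y) + par[3L]) / exp(par[4L]))
  } else y
  exp(z) - trans$offset
}

# REML machinery ------------------------------------------------------------

# assemble covariance pieces for given log-parameters
# theta layout: per svc covariate k: log_tau2_k, alpha_k; then per
# nonspatial covariate k: log_psi2_k
.snvc_pieces <- function(theta, X, E, lambda, svc_idx, ns_idx) {
  n <- nrow(X)
  L <- ncol(E)
  nsvc <- length(svc_idx)
  D <- rep(1, n)
  for (j in seq_along(ns_idx)) {
    psi2 <- exp(theta[2 * nsvc + j])
    D <- D + psi2 * X[, ns_idx[j]]^2
  }
  if (nsvc > 0L) {
    Z <- matrix(0, n, nsvc * L)
    g <- numeric(nsvc * L)
    lam_rel <- lambda / lambda[1L]
    for (k in seq_len(nsvc)) {
      tau2 <- exp(theta[2 * k - 1L])
      alpha <- theta[2 * k]
      lamw <- lam_rel^alpha
      lamw <- lamw / mean(lamw)
      cols <- (k - 1L) * L + seq_len(L)
      Z[, cols] <- E * X[, svc_idx[k]]
      g[cols] <- tau2 * lamw
    }
  } else {
    Z <- matrix(0, n, 0L)
    g <- numeric(0)
  }
  list(D = D, Z = Z, g = g)
}

# profiled REML negative log-likelihood plus the GLS solves
.snvc_reml <- function(theta, y, X, E, lambda, svc_idx, ns_idx,
                       return_fit = FALSE) {
  n <- nrow(X); p <- ncol(X)
  pc <- .snvc_pieces(theta, X, E, lambda, svc_idx, ns_idx)
  D <- pc$D; Z <- pc$Z; g <- pc$g
  Di <- 1 / D
  q <- length(g)
  if (q > 0L) {
    ZDi <- Z * Di
    K <- diag(1 / g, q) + crossprod(Z, ZDi)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(if (return_fit) NULL else 1e10)
    logdetV <- sum(log(D)) + 2 * sum(log(diag(ch))) + sum(log(g))
    Vi <- function(x) {
      Dx <- Di * x
      Dx - ZDi %*% backsolve(ch, forwardsolve(t(ch), crossprod(Z, Dx)))
    }
  } else {
    logdetV <- sum(log(D))
    Vi <- function(x) Di * x
  }
  ViX <- apply(X, 2L, Vi)
  if (p == 1L) ViX <- matrix(ViX, ncol = 1L)
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(ViX, y)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(if (return_fit) NULL else 1e10)
  b <- backsolve(chX, forwardsolve(t(chX), XtViy))
  Viy <- Vi(y)
  quad <- sum(y * Viy) - sum(XtViy * b)
  if (quad <= 0) return(if (return_fit) NULL else 1e10)
  sigma2 <- quad / (n - p)
  reml <- 0.5 * ((n - p) * log(sigma2) + logdetV +
                   2 * sum(log(diag(chX))) + (n - p))
  if (!is.finite(reml)) return(if (return_fit) NULL else 1e10)
  if (!return_fit) return(reml)
  # GLS inference and BLUPs at the optimum
  XtViX_inv <- chol2inv(chX)
  se <- sqrt(sigma2 * diag(XtViX_inv))
  r <- y - X %*% b
  Vir <- Vi(r)
  list(reml = reml, sigma2 = sigma2, b = as.numeric(b), se = se,
       Vir = as.numeric(Vir), D = D, Z = Z, g = g, logdetV = logdetV)
}

#' Fit the Moran-eigenvector SNVC regression
#'
#' Linear mixed model on the transformed response:
#' \deqn{y^* = X b + \sum_k diag(x_k) E \gamma_k + \sum_k x_k \circ \delta_k
#'   + \epsilon,}
#' with spatial random coefficients \eqn{\gamma_k \sim N(0, \tau_k^2
#' \Lambda(\alpha_k))} (eigenvalue-proportional shrinkage with fitted decay
#' exponent) and non-spatial deviations \eqn{\delta_k \sim N(0, \psi_k^2)}.
#' Variance parameters are estimated by profiled restricted maximum
#' likelihood; constant coefficients are reported with SE, t (df = n -
#' rank(X)) and p. Per-location coefficient surfaces are assembled from the
#' empirical BLUPs.
#'
#' @param y_star transformed response vector.
#' @param X design matrix (must include an intercept column; full rank).
#' @param basis a `"cs_eigenbasis"` from [moran_eigenvectors()], or `NULL`
#'   for no spatial term.
#' @param svc_covariates column names of `X` given spatially varying
#'   coefficients (default: all columns).
#' @param nonspatial_covariates column names given non-spatial random
#'   coefficients (default: same as `svc_covariates`).
#' @return object of class `"cs_snvc"`: coefficient table pieces (`b`, `se`,
#'   `t_value`, `p_value`), `tau2`, `alpha`, `psi2`, `sigma2`, per-location
#'   `surfaces` (n x K matrix), `reml_loglik` (the restricted log-likelihood
#'   up to an additive constant), `converged`.
#' @export
fit_snvc <- function(y_star, X, basis = NULL,
                     svc_covariates = colnames(X),
                     nonspatial_covariates = svc_covariates) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  n <- nrow(X); p <- ncol(X)
  if (length(y_star) != n) stop("length(y_star) != nrow(X)")
  if (qr(X)$rank < p) stop("X is rank deficient")
  has_basis <- !is.null(basis) && ncol(basis$E) > 0L
  svc_idx <- if (has_basis) match(svc_covariates, colnames(X)) else integer(0)
  ns_idx <- match(nonspatial_covariates, colnames(X))
  ns_idx <- ns_idx[!is.na(ns_idx)]
  if (anyNA(svc_idx)) stop("svc_covariates must name columns of X")
  E <- if (has_basis) basis$E else matrix(0, n, 0L)
  lambda <- if (has_basis) basis$lambda else numeric(0)
  nsvc <- length(svc_idx); nns <- length(ns_idx)
  ntheta <- 2L * nsvc + nns
  if (ntheta == 0L) {
    # degenerate limit: ordinary least squares
    fit <- .snvc_reml(numeric(0), y_star, X, E, lambda, svc_idx, ns_idx,
                      return_fit = TRUE)
    surfaces <- matrix(rep(fit$b, each = n), n, p,
                       dimnames = list(NULL, colnames(X)))
    return(structure(list(
      b = stats::setNames(fit$b, colnames(X)), se = fit$se,
      t_value = fit$b / fit$se,
      p_value = 2 * stats::pt(-abs(fit$b / fit$se), df = n - p),
      tau2 = numeric(0), alpha = numeric(0), psi2 = numeric(0),
      sigma2 = fit$sigma2, surfaces = surfaces,
      svc_covariates = character(0), reml_loglik = -fit$reml,
      converged = TRUE, n = n, p = p), class = "cs_snvc"))
  }
  obj <- function(theta) .snvc_reml(theta, y_star, X, E, lambda,
                                    svc_idx, ns_idx)
  theta0 <- c(rbind(rep(log(0.1), nsvc), rep(1, nsvc)))[seq_len(2 * nsvc)]
  theta0 <- c(theta0, rep(log(0.1), nns))
  lower <- c(rbind(rep(-18, nsvc), rep(0, nsvc)))[seq_len(2 * nsvc)]
  lower <- c(lower, rep(-18, nns))
  upper <- c(rbind(rep(8, nsvc), rep(8, nsvc)))[seq_len(2 * nsvc)]
  upper <- c(upper, rep(8, nns))
  opt <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 200, factr = 1e9))
  converged <- opt$convergence == 0L && opt$value < 1e9
  fit <- .snvc_reml(opt$par, y_star, X, E, lambda, svc_idx, ns_idx,
                    return_fit = TRUE)
  if (is.null(fit)) stop("SNVC REML fit failed at the optimum")
  tau2 <- exp(opt$par[2 * seq_len(nsvc) - 1L]) * fit$sigma2
  alpha <- opt$par[2 * seq_len(nsvc)]
  psi2 <- if (nns) exp(opt$par[2 * nsvc + seq_len(nns)]) * fit$sigma2
          else numeric(0)
  names(tau2) <- names(alpha) <- colnames(X)[svc_idx]
  if (nns) names(psi2) <- colnames(X)[ns_idx]
  # surfaces from BLUPs: gamma_k = G_k Z_k' V^{-1} r ; delta_ki = psi~2 x_ki (V^{-1}r)_i
  surfaces <- matrix(rep(fit$b, each = n), n, p,
                     dimnames = list(NULL, colnames(X)))
  L <- ncol(E)
  for (k in seq_len(nsvc)) {
    cols <- (k - 1L) * L + seq_len(L)
    gamma_k <- fit$g[cols] * crossprod(fit$Z[, cols, drop = FALSE], fit$Vir)
    surfaces[, svc_idx[k]] <- surfaces[, svc_idx[k]] +
      as.numeric(E %*% gamma_k)
  }
  for (j in seq_len(nns)) {
    psi2_rel <- exp(opt$par[2 * nsvc + j])
    surfaces[, ns_idx[j]] <- surfaces[, ns_idx[j]] +
      psi2_rel * X[, ns_idx[j]] * fit$Vir
  }
  tval <- fit$b / fit$se
  structure(list(
    b = stats::setNames(fit$b, colnames(X)), se = fit$se, t_value = tval,
    p_value = 2 * stats::pt(-abs(tval), df = n - p),
    tau2 = tau2, alpha = alpha, psi2 = psi2, sigma2 = fit$sigma2,
    surfaces = surfaces, svc_covariates = colnames(X)[svc_idx],
    reml_loglik = -opt$value, converged = converged, n = n, p = p
  ), class = "cs_snvc")
}

#' Constant-coefficient table and surface export of an SNVC fit
#'
#' @param fit a `"cs_snvc"` object.
#' @param coords optional data frame with `x`, `y` to attach to the surface
#'   export.
#' @return list: `table` (Variable / Estimate / Std. error / t-value /
#'   p-value), `surfaces` (data frame of per-location coefficients, with
#'   coordinates when supplied).
#' @export
snvc_report <- function(fit, coords = NULL) {
  stopifnot(inherits(fit, "cs_snvc"))
  if (!fit$converged) stop("SNVC fit did not converge; no report produced")
  tab <- data.frame(
    variable = names(fit$b),
    estimate = as.numeric(fit$b),
    std_error = fit$se,
    t_value = fit$t_value,
    p_value = fit$p_value,
    stringsAsFactors = FALSE
  )
  surf <- as.data.frame(fit$surfaces)
  names(surf) <- paste0("beta_", names(surf))
  if (!is.null(coords)) surf <- cbind(coords[c("x", "y")], surf)
  list(table = tab, surfaces = surf)
}

#' @export
print.cs_snvc <- function(x, ...) {
  cat("Moran-eigenvector SNVC regression:", x$n, "locations,",
      x$p, "covariates\n")
  tab <- data.frame(Estimate = round(x$b, 3), `Std.err` = round(x$se, 3),
                    t = round(x$t_value, 2), p = signif(x$p_value, 3))
  print(tab)
  if (length(x$tau2)) {
    cat("Spatial variance components (tau^2):\n")
    print(signif(x$tau2, 3))
  }
  invisible(x)
}

#' @export
coef.cs_snvc <- function(object, ...) object$b
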