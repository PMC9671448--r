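# Variance partitioning for the three-level logistic model:
# latent-scale intraclass correlations and proportional change in variance.

#' Three-level intraclass correlation coefficients
#'
#' Computes the cluster-level and region-level ICC of a three-level
#' random-intercept logistic model. In `"latent_logistic"` mode the level-1
#' residual is the standard logistic latent error with variance \eqn{\pi^2/3},
#' so
#' \deqn{ICC_C = \sigma^2_C / (\pi^2/3 + \sigma^2_C + \sigma^2_R), \quad
#'       ICC_R = \sigma^2_R / (\pi^2/3 + \sigma^2_C + \sigma^2_R).}
#' In `"explicit"` mode a supplied level-1 residual variance `sigma2_e`
#' replaces \eqn{\pi^2/3} in the denominator.
#'
#' @param sigma2_C cluster-level (level-2) intercept variance, >= 0.
#' @param sigma2_R region-level (level-3) intercept variance, >= 0.
#' @param sigma2_e level-1 residual variance; required in `"explicit"` mode,
#'   ignored in `"latent_logistic"` mode.
#' @param residual_mode `"latent_logistic"` (default) or `"explicit"`.
#' @return named numeric vector `c(ICC_C =, ICC_R =)` as proportions in
#'   \[0, 1\].
#' @examples
#' icc_three_level(1.04, 2.19)        # c(0.1595..., 0.3359...)
#' icc_three_level(0.05, 0.14)
#' @export
icc_three_level <- function(sigma2_C, sigma2_R, sigma2_e = NULL,
                            residual_mode = c("latent_logistic", "explicit")) {
  residual_mode <- match.arg(residual_mode)
  stopifnot(is.numeric(sigma2_C), is.numeric(sigma2_R),
            length(sigma2_C) == 1L, length(sigma2_R) == 1L)
  if (sigma2_C < 0 || sigma2_R < 0)
    stop("variance components must be non-negative")
  if (residual_mode == "latent_logistic") {
    denom <- pi^2 / 3 + sigma2_C + sigma2_R
  } else {
    if (is.null(sigma2_e))
      stop("explicit residual mode requires 'sigma2_e'")
    if (sigma2_e < 0) stop("'sigma2_e' must be non-negative")
    denom <- sigma2_e + sigma2_C + sigma2_R
    if (denom == 0)
      stop("all variance components are zero: ICC undefined in explicit mode")
  }
  c(ICC_C = sigma2_C / denom, ICC_R = sigma2_R / denom)
}

#' Proportional change in variance
#'
#' Relative reduction of a variance component between a reference model
#' (usually the empty model) and a richer model:
#' `(v_reference - v_model) / v_reference`. Negative when the variance grew.
#'
#' @param v_reference variance in the reference model; must be > 0.
#' @param v_model variance in the comparison model; >= 0.
#' @return proportion (may be negative).
#' @examples
#' pcv(1.04, 0.05)   # 0.9519...
#' @export
pcv <- function(v_reference, v_model) {
  stopifnot(is.numeric(v_reference), is.numeric(v_model))
  if (any(v_reference <= 0))
    stop("'v_reference' must be strictly positive")
  if (any(v_model < 0)) stop("'v_model' must be non-negative")
  (v_reference - v_model) / v_reference
}

#' Build the model-ladder variance table
#'
#' Assembles, from an ordered ladder of fitted models, the standard
#' variance-partition table: per-model cluster and region intercept
#' variances, random-slope variances, latent-scale ICCs (in percent), PCVs
#' relative to the first (empty) model (in percent), and DIC.
#'
#' @param ladder a list of per-model summaries; each element is a list with
#'   numeric `sigma2_C`, `sigma2_R`, `dic`, and optionally a named numeric
#'   vector `slope_variances_C` / `slope_variances_R`. The first element must
#'   be the empty (reference) model; names are used as model labels.
#' @param digits decimal places used for the percentage columns (presentation
#'   only; default 2). Use `NA` to keep full precision.
#' @return a `data.frame` with one row per model: variances, `ICC_C_pct`,
#'   `ICC_R_pct`, `PCV_C_pct`, `PCV_R_pct` (NA for the reference row), `DIC`.
#' @export
build_variance_table <- function(ladder, digits = 2) {
  if (!is.list(ladder) || length(ladder) < 1L)
    stop("'ladder' must be a non-empty list of model summaries")
  need <- c("sigma2_C", "sigma2_R")
  for (i in seq_along(ladder)) {
    if (!all(need %in% names(ladder[[i]])))
      stop("ladder element ", i, " lacks variance components")
  }
  labs <- names(ladder)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- paste0("Model ", seq_along(ladder) - 1L)
  if (all(grepl("^Model [0-9]+$", labs))) {
    num <- as.integer(sub("^Model ", "", labs))
    if (is.unsorted(num, strictly = TRUE))
      stop("ladder must be ordered from the empty model upward")
  }
  s2C <- vapply(ladder, function(m) m$sigma2_C, numeric(1))
  s2R <- vapply(ladder, function(m) m$sigma2_R, numeric(1))
  dic <- vapply(ladder, function(m) if (is.null(m$dic)) NA_real_ else m$dic,
                numeric(1))
  icc <- t(vapply(seq_along(ladder),
                  function(i) icc_three_level(s2C[i], s2R[i]), numeric(2)))
  pcv_C <- c(NA_real_, pcv(s2C[1L], s2C[-1L]))
  pcv_R <- c(NA_real_, pcv(s2R[1L], s2R[-1L]))
  rnd <- function(x) if (is.na(digits)) x else round(x, digits)
  out <- data.frame(
    model      = labs,
    sigma2_C   = s2C,
    sigma2_R   = s2R,
    ICC_C_pct  = rnd(100 * icc[, 1L]),
    ICC_R_pct  = rnd(100 * icc[, 2L]),
    PCV_C_pct  = rnd(100 * pcv_C),
    PCV_R_pct  = rnd(100 * pcv_R),
    DIC        = dic,
    stringsAsFactors = FALSE
  )
  # carry slope variances when present (ragged across the ladder)
  slopes <- lapply(ladder, function(m) {
    sc <- m$slope_variances_C
    sr <- m$slope_variances_R
    if (is.null(sc) && is.null(sr)) return(NULL)
    list(cluster = sc, region = sr)
  })
  attr(out, "slope_variances") <- slopes
  class(out) <- c("cs_variance_table", "data.frame")
  out
}
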