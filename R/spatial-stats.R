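# Hotspot pipeline: distance-band spatial weights, global Moran's I with
# randomization inference, incremental spatial autocorrelation scanning,
# Getis-Ord Gi* with FDR-corrected hotspot classes.

#' Mean nearest-neighbour distance
#'
#' The average, over features, of each feature's distance to its nearest
#' neighbour — the conventional smallest distance band at which every feature
#' has at least one neighbour on average.
#'
#' @param coords data frame with `x`, `y` (km).
#' @return distance in km.
#' @export
min_distance_for_neighbors <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  d <- euclidean_distance_matrix(coords, coords)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Fixed distance-band spatial weights
#'
#' Binary weights `w_ij = 1` iff `d_ij <= band_km` (`i != j` unless
#' `include_self`), optionally row-standardized. Isolated features (no
#' neighbours) are retained with a warning.
#'
#' @param coords data frame with `x`, `y` (km).
#' @param band_km band distance, > 0.
#' @param scheme `"binary"` (default) or `"row_standardized"`.
#' @param include_self include the focal feature itself (required for Gi*).
#' @return list of class `"cs_weights"`: `neighbors` (list of integer
#'   indices), `weights` (list of numeric weights), `n`, `band_km`,
#'   `scheme`, `include_self`.
#' @export
build_distance_band_weights <- function(coords, band_km,
                                        scheme = c("binary", "row_standardized"),
                                        include_self = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(band_km > 0)
  n <- nrow(coords)
  d <- euclidean_distance_matrix(coords, coords)
  nb <- vector("list", n)
  wt <- vector("list", n)
  isolated <- 0L
  for (i in seq_len(n)) {
    j <- which(d[i, ] <= band_km)
    if (!include_self) j <- j[j != i]
    if (length(j) == 0L || (include_self && length(j) == 1L))
      isolated <- isolated + 1L
    w <- rep(1, length(j))
    if (scheme == "row_standardized" && length(j)) w <- w / length(j)
    nb[[i]] <- j
    wt[[i]] <- w
  }
  if (isolated > 0L)
    warning(isolated, " feature(s) have no neighbour at band ", band_km, " km")
  structure(list(neighbors = nb, weights = wt, n = n, band_km = band_km,
                 scheme = scheme, include_self = include_self),
            class = "cs_weights")
}

# dense matrix view of a weights object (internal; fine at survey scale)
.weights_matrix <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

#' Global Moran's I with randomization inference
#'
#' \eqn{I = (n/S_0) \sum_i \sum_j w_{ij} z_i z_j / \sum_i z_i^2} with `z`
#' the deviations from the mean. The z-score and two-sided p-value use the
#' randomization-assumption variance (the standard permutation-moment
#' formula involving the kurtosis of the values).
#'
#' @param values numeric vector, non-constant.
#' @param weights a `"cs_weights"` object with `include_self = FALSE`.
#' @return list of class `"cs_moran"`: `I`, `expectation`, `variance`,
#'   `z`, `p_value`, `n`.
#' @export
global_morans_i <- function(values, weights) {
  if (weights$include_self)
    stop("Moran's I requires weights without self-neighbours")
  n <- weights$n
  if (length(values) != n) stop("length(values) != number of features")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("zero variance: values are constant")
  W <- .weights_matrix(weights)
  S0 <- sum(W)
  if (S0 == 0) stop("all-empty weights")
  I <- (n / S0) * sum(W * outer(z, z)) / m2
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / m2^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  VI <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zsc <- (I - EI) / sqrt(VI)
  structure(list(I = I, expectation = EI, variance = VI, z = zsc,
                 p_value = 2 * stats::pnorm(-abs(zsc)), n = n),
            class = "cs_moran")
}

#' @export
print.cs_moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), z = %.2f, p = %.4g\n",
              x$I, x$expectation, x$z, x$p_value))
  invisible(x)
}

#' Incremental spatial autocorrelation scan
#'
#' Computes the Moran z-score over an increasing sequence of distance bands
#' and reports the band of peak clustering (maximum z; ties go to the
#' smallest band). Bands whose weights are degenerate (no links) are skipped
#' with a note.
#'
#' @param values numeric vector.
#' @param coords data frame with `x`, `y`.
#' @param start_km first band distance; defaults to
#'   [min_distance_for_neighbors()].
#' @param step_km band increment; defaults to `start_km`.
#' @param n_bands number of bands (default 10).
#' @return list of class `"cs_isa"`: `bands` data frame (`band_km`, `I`,
#'   `z`, `p_value`, `skipped`), `peak_km`, `peak_z`.
#' @export
incremental_spatial_autocorrelation <- function(values, coords,
                                                start_km = NULL,
                                                step_km = NULL,
                                                n_bands = 10) {
  mindist <- min_distance_for_neighbors(coords)
  if (is.null(start_km)) start_km <- mindist
  if (is.null(step_km)) step_km <- start_km
  if (start_km < mindist)
    warning("start_km below the mean nearest-neighbour distance (",
            signif(mindist, 4), " km); early bands may have isolated features")
  bands <- start_km + (seq_len(n_bands) - 1L) * step_km
  res <- data.frame(band_km = bands, I = NA_real_, z = NA_real_,
                    p_value = NA_real_, skipped = FALSE)
  for (k in seq_along(bands)) {
    w <- suppressWarnings(
      build_distance_band_weights(coords, bands[k], include_self = FALSE))
    mr <- tryCatch(global_morans_i(values, w), error = function(e) NULL)
    if (is.null(mr) || !is.finite(mr$z)) {
      res$skipped[k] <- TRUE
      next
    }
    res$I[k] <- mr$I; res$z[k] <- mr$z; res$p_value[k] <- mr$p_value
  }
  ok <- which(!res$skipped)
  if (length(ok) == 0L) stop("every band had degenerate weights")
  peak <- ok[which.max(res$z[ok])]  # which.max takes the first (smallest band)
  structure(list(bands = res, peak_km = res$band_km[peak],
                 peak_z = res$z[peak]), class = "cs_isa")
}

#' @export
print.cs_isa <- function(x, ...) {
  cat("Incremental spatial autocorrelation:", nrow(x$bands), "bands; peak at",
      signif(x$peak_km, 5), "km (z =", sprintf("%.2f", x$peak_z), ")\n")
  invisible(x)
}

#' Getis-Ord Gi* local hotspot statistic
#'
#' Self-inclusive local statistic
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar X W_i}
#'   {S \sqrt{(n \sum_j w_{ij}^2 - W_i^2)/(n-1)}}}
#' with global mean \eqn{\bar X} and standard deviation \eqn{S} computed over
#' all features including `i`. A zero denominator (neighbourhood covering all
#' features) yields z = 0 with a flag.
#'
#' @param values numeric vector.
#' @param weights `"cs_weights"` with `include_self = TRUE`.
#' @return data frame: `z` (Gi* z-score), `degenerate` (logical flag).
#' @export
getis_ord_gi_star <- function(values, weights) {
  if (!weights$include_self)
    stop("Gi* requires self-inclusive weights (include_self = TRUE)")
  n <- weights$n
  if (n < 3L) stop("need at least 3 features")
  if (length(values) != n) stop("length(values) != number of features")
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    w <- weights$weights[[i]]
    j <- weights$neighbors[[i]]
    Wi <- sum(w)
    num <- sum(w * values[j]) - xbar * Wi
    den2 <- (n * sum(w^2) - Wi^2) / (n - 1)
    if (den2 <= .Machine$double.eps * n || S == 0) {
      degen[i] <- TRUE
      z[i] <- 0
    } else {
      z[i] <- num / (S * sqrt(den2))
    }
  }
  data.frame(z = z, degenerate = degen)
}

#' FDR-corrected hotspot classification
#'
#' Two-sided normal p-values from local z-scores, Benjamini-Hochberg
#' adjustment, and classification into the standard hotspot-map tiers by the
#' smallest alpha at which a feature stays significant, signed by z:
#' `hot99/hot95/hot90`, `not_significant`, `cold90/cold95/cold99`.
#'
#' @param z_scores numeric vector of local z-scores.
#' @param alpha_levels significance tiers (default 0.10, 0.05, 0.01).
#' @return data frame: `z`, `p_value`, `p_adjusted`, `class` (factor).
#' @export
fdr_classify <- function(z_scores, alpha_levels = c(0.10, 0.05, 0.01)) {
  lev <- c("cold99", "cold95", "cold90", "not_significant",
           "hot90", "hot95", "hot99")
  if (length(z_scores) == 0L)
    return(data.frame(z = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0),
                      class = factor(character(0), levels = lev)))
  if (!all(is.finite(z_scores))) stop("z-scores must be finite")
  alpha_levels <- sort(alpha_levels, decreasing = TRUE)  # 0.10, 0.05, 0.01
  p <- 2 * stats::pnorm(-abs(z_scores))
  padj <- stats::p.adjust(p, method = "BH")
  tier <- rep("", length(z_scores))
  cls <- rep("not_significant", length(z_scores))
  sig90 <- padj <= alpha_levels[1L]
  sig95 <- padj <= alpha_levels[2L]
  sig99 <- padj <= alpha_levels[3L]
  tier[sig90] <- "90"; tier[sig95] <- "95"; tier[sig99] <- "99"
  hot <- z_scores > 0
  cls[sig90] <- paste0(ifelse(hot[sig90], "hot", "cold"), tier[sig90])
  data.frame(z = z_scores, p_value = p, p_adjusted = padj,
             class = factor(cls, levels = lev))
}

#' Per-cluster caesarean counts and rates
#'
#' @param women data frame with `cluster_id` and binary `cs` outcome.
#' @return data frame: `cluster_id`, `births`, `cs_count`, `cs_rate`.
#' @export
cluster_cs_rates <- function(women) {
  if (is.null(women$cluster_id) || is.null(women$cs))
    stop("'women' must carry cluster_id and cs columns")
  births <- tapply(women$cs, women$cluster_id, length)
  cnt <- tapply(women$cs, women$cluster_id, sum)
  data.frame(cluster_id = names(births),
             births = as.integer(births),
             cs_count = as.integer(cnt),
             cs_rate = as.numeric(cnt / births),
             stringsAsFactors = FALSE)
}
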