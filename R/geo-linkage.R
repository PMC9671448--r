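# Euclidean-buffer linkage of survey clusters to caesarean-providing
# facilities. Coordinates are planar kilometres in a projected frame.

#' Pairwise Euclidean distance matrix
#'
#' @param a,b data frames (or lists) with numeric `x` and `y` columns in km.
#' @return matrix of distances (km), `nrow(a)` by `nrow(b)`.
#' @export
euclidean_distance_matrix <- function(a, b) {
  ax <- as.numeric(a$x); ay <- as.numeric(a$y)
  bx <- as.numeric(b$x); by <- as.numeric(b$y)
  if (length(ax) == 0L || length(bx) == 0L)
    stop("point sets must be non-empty")
  if (!all(is.finite(c(ax, ay, bx, by))))
    stop("non-finite coordinates")
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  sqrt(dx * dx + dy * dy)
}

#' Link clusters to the nearest caesarean-providing facility
#'
#' Assigns each survey cluster its nearest facility among those flagged as
#' providing caesarean sections (straight-line planar distance). Ties are
#' broken by the lexicographically smallest facility id. All clusters receive
#' a distance (the continuous model covariate); `within_buffer` flags those
#' within `buffer_km`.
#'
#' @param clusters data frame with `cluster_id`, `x`, `y` (km) and optionally
#'   `region_id`.
#' @param facilities data frame with `facility_id`, `x`, `y` and logical /
#'   0-1 `cs_flag`.
#' @param buffer_km buffer radius in km (default 25).
#' @return data frame: `cluster_id`, `region_id` (if present),
#'   `nearest_cs_facility_id`, `distance_km`, `within_buffer`.
#' @export
link_nearest_cs_facility <- function(clusters, facilities, buffer_km = 25) {
  stopifnot(buffer_km > 0)
  flagged <- facilities[as.logical(facilities$cs_flag), , drop = FALSE]
  if (nrow(flagged) == 0L)
    stop("no linkable facility: no facility carries the caesarean flag")
  # order by id so which.min's first-hit tie break is the smallest id
  flagged <- flagged[order(as.character(flagged$facility_id)), , drop = FALSE]
  d <- euclidean_distance_matrix(clusters, flagged)
  idx <- apply(d, 1L, which.min)
  dist_km <- d[cbind(seq_len(nrow(d)), idx)]
  out <- data.frame(
    cluster_id = clusters$cluster_id,
    nearest_cs_facility_id = flagged$facility_id[idx],
    distance_km = dist_km,
    within_buffer = dist_km <= buffer_km,
    stringsAsFactors = FALSE
  )
  if (!is.null(clusters$region_id))
    out <- cbind(out[1L], region_id = clusters$region_id, out[-1L])
  out
}

#' Per-region and national mean distance to the nearest caesarean facility
#'
#' @param linked output of [link_nearest_cs_facility()]; must carry
#'   `region_id` and `distance_km`.
#' @return data frame with `region_id` (plus a `"national"` row) and
#'   `mean_distance_km`.
#' @export
region_distance_summary <- function(linked) {
  if (nrow(linked) == 0L) stop("'linked' is empty")
  if (is.null(linked$region_id)) stop("'linked' lacks region_id")
  m <- tapply(linked$distance_km, linked$region_id, mean)
  data.frame(
    region_id = c(names(m), "national"),
    mean_distance_km = c(as.numeric(m), mean(linked$distance_km)),
    stringsAsFactors = FALSE
  )
}

#' Min-max rescale to \[0, 1\]
#'
#' Covariates (age, parity, distance, ...) enter the hierarchical model on a
#' min-max \[0,1\] scale so that per-unit odds ratios are comparable across
#' covariates of very different raw ranges.
#'
#' @param x numeric vector.
#' @return rescaled vector; constant input maps to 0.
#' @export
minmax_scale <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[1L] == r[2L]) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}
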