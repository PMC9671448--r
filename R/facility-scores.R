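# PCA-based service availability and readiness scores for facilities.

# default indicator sets; the 6/7/9 groupings follow WHO service availability
# and readiness conventions and are configurable
.cs_general_indicators <- c(
  "communication_equipment", "external_supervision", "client_opinion_feedback",
  "quality_assurance", "emergency_transport", "client_latrine"
)
.cs_availability_indicators <- c(
  "parenteral_antibiotics", "parenteral_oxytocics", "parenteral_anticonvulsants",
  "manual_placenta_removal", "retained_products_removal",
  "assisted_vaginal_delivery", "caesarean_surgery"
)
.cs_readiness_indicators <- c(
  "obstetric_surgeon", "anaesthesia_provider", "operating_theatre",
  "blood_supply", "iv_fluids", "antibiotic_stock", "oxytocin_stock",
  "anaesthesia_equipment", "sterilisation_equipment"
)

#' Default service indicator sets
#'
#' Names of the binary indicator columns used for the general readiness
#' (6 items), obstetric-care availability (7 items) and obstetric-care
#' readiness (9 items) indices.
#'
#' @return named list of character vectors (`general`, `availability`,
#'   `readiness`).
#' @export
cs_indicator_sets <- function() {
  list(general = .cs_general_indicators,
       availability = .cs_availability_indicators,
       readiness = .cs_readiness_indicators)
}

#' Correlation-matrix principal component analysis of service indicators
#'
#' PCA on centred, unit-variance columns (i.e. the correlation matrix),
#' suitable for mixed binary/ordinal indicators. Constant columns are dropped
#' with a warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param m numeric matrix or data frame of indicators (facilities x items).
#' @param n_components number of components to retain.
#' @return list of class `"cs_pca"`: `loadings` (items x components),
#'   `scores` (facilities x components), `explained` (proportions of
#'   variance), `dropped` (names of constant columns removed).
#' @export
pca_scores <- function(m, n_components = 2) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 facilities for PCA")
  if (anyNA(m)) stop("indicator matrix contains missing values")
  v <- apply(m, 2L, stats::var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped)) {
    warning("dropping constant indicator column(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  if (n_components > ncol(m))
    stop("n_components exceeds the number of non-degenerate columns")
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  rot <- p$rotation
  # deterministic sign: largest-|loading| element of each component positive
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- scale(m, center = p$center, scale = p$scale) %*% rot
  keep <- seq_len(n_components)
  structure(list(
    loadings = rot[, keep, drop = FALSE],
    scores = scores[, keep, drop = FALSE],
    explained = (p$sdev^2 / sum(p$sdev^2))[keep],
    dropped = dropped
  ), class = "cs_pca")
}

#' Attach the six PCA score columns to a facility table
#'
#' Computes three correlation-matrix PCAs — general readiness (6 items),
#' obstetric-care availability (7 items), obstetric-care readiness (9 items)
#' — and appends the first two component scores of each:
#' `general_pc1`, `general_pc2`, `avail_pc1`, `avail_pc2`,
#' `ready_pc1`, `ready_pc2`.
#'
#' @param facilities facility data frame carrying all indicator columns named
#'   in `indicator_sets`.
#' @param indicator_sets named list as returned by [cs_indicator_sets()].
#' @return `facilities` with six score columns appended.
#' @export
build_score_set <- function(facilities, indicator_sets = cs_indicator_sets()) {
  for (set in names(indicator_sets)) {
    missing <- setdiff(indicator_sets[[set]], names(facilities))
    if (length(missing))
      stop("missing indicator column(s) for ", set, " index: ",
           paste(missing, collapse = ", "))
  }
  add <- function(set, prefix) {
    m <- facilities[, indicator_sets[[set]], drop = FALSE]
    res <- pca_scores(m, n_components = 2)
    out <- res$scores
    colnames(out) <- paste0(prefix, c("_pc1", "_pc2"))
    out
  }
  cbind(facilities,
        add("general", "general"),
        add("availability", "avail"),
        add("readiness", "ready"))
}

#' @export
print.cs_pca <- function(x, ...) {
  cat("Correlation-matrix PCA:", nrow(x$loadings), "indicators,",
      ncol(x$scores), "retained component(s)\n")
  cat("Explained variance proportions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  if (length(x$dropped))
    cat("Dropped constant columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
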