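# End-to-end orchestration: simulate -> link -> score -> fit -> variance
# table -> hotspots -> SNVC, with per-stage seeds fanned out from one global
# seed and every table stamped with the config hash that produced it.

#' Pipeline configuration
#'
#' @param sim a [sim_config()]; its `seed` is overridden by the pipeline
#'   seed fan-out.
#' @param buffer_km buffer radius for the facility linkage.
#' @param spec,priors,mcmc model specification for the hierarchical stage.
#' @param hotspot_band_km Gi* distance band; `NULL` selects the peak of the
#'   incremental autocorrelation scan.
#' @param svc_formula_covariates cluster-level covariates for the SNVC stage.
#' @param svc_retention eigenvalue retention fraction.
#' @param transform [transform_spec()] for the SNVC response.
#' @param stages character subset of
#'   `c("simulate","link","score","fit","hotspots","svc")`.
#' @param seed single global seed; per-stage seeds are `seed + stage index`.
#' @param out_dir optional output directory; when given, tables are written
#'   as CSV and spatial layers as GeoJSON.
#' @return list of class `"cs_pipeconfig"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            buffer_km = 25,
                            spec = hier_model_spec(l2_covariate = "distance01"),
                            priors = prior_spec(),
                            mcmc = mcmc_config(),
                            hotspot_band_km = NULL,
                            svc_formula_covariates = c("education", "wealth",
                                                       "anc4plus",
                                                       "age_first_birth"),
                            svc_retention = 0.25,
                            transform = transform_spec(),
                            stages = c("simulate", "link", "score", "fit",
                                       "hotspots", "svc"),
                            seed = 1,
                            out_dir = NULL) {
  structure(list(sim = sim, buffer_km = buffer_km, spec = spec,
                 priors = priors, mcmc = mcmc,
                 hotspot_band_km = hotspot_band_km,
                 svc_formula_covariates = svc_formula_covariates,
                 svc_retention = svc_retention, transform = transform,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "cs_pipeconfig")
}

#' Descriptive caesarean-rate summary
#'
#' Caesarean rates overall, by urban/rural and by region, plus facilities
#' per million population.
#'
#' @param women women table with `cs`, `cluster_id`, `region_id`.
#' @param clusters cluster table with `cluster_id`, `urban`.
#' @param facilities facility table with `cs_flag`.
#' @param population total population represented (defaults to the number of
#'   women, a documented stand-in at synthetic scale).
#' @return list: `rates` data frame (`group`, `births`, `cs_count`,
#'   `cs_rate_pct`), `facilities_per_million`.
#' @export
descriptive_summary <- function(women, clusters, facilities,
                                population = nrow(women)) {
  urb <- clusters$urban[match(women$cluster_id, clusters$cluster_id)]
  grp <- function(label, idx) {
    data.frame(group = label, births = sum(idx), cs_count = sum(women$cs[idx]),
               cs_rate_pct = 100 * mean(women$cs[idx]),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    grp("national", rep(TRUE, nrow(women))),
    grp("urban", urb), grp("rural", !urb)
  )
  for (r in sort(unique(women$region_id)))
    rows <- rbind(rows, grp(r, women$region_id == r))
  fpm <- if (population > 0)
    1e6 * sum(facilities$cs_flag) / population else NA_real_
  list(rates = rows, facilities_per_million = fpm)
}

#' Run the analysis pipeline end to end
#'
#' Stages run in a fixed order; disabling a stage simply omits its outputs
#' (downstream stages that need it are skipped too). Every table in the
#' returned bundle carries the config hash and seed as attributes; when
#' `out_dir` is set the tables are also written to disk.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"cs_report"`: `descriptives`, `linked`,
#'   `posterior_summary`, `variance_table`, `hotspots`, `svc_table`,
#'   `svc_surfaces`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cs_pipeconfig"))
  stages_all <- c("simulate", "link", "score", "fit", "hotspots", "svc")
  on_stage <- function(s) s %in% config$stages
  stage_seed <- function(s) config$seed + match(s, stages_all)
  out <- list()
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])

  sim <- config$sim
  sim$seed <- stage_seed("simulate")
  ds <- simulate_population(sim)
  out$descriptives <- descriptive_summary(ds$women, ds$clusters,
                                          ds$facilities)
  linked <- NULL
  if (on_stage("link")) {
    linked <- link_nearest_cs_facility(ds$clusters, ds$facilities,
                                       buffer_km = config$buffer_km)
    linked$distance01 <- minmax_scale(linked$distance_km)
    if (on_stage("score")) {
      scored <- build_score_set(ds$facilities)
      sc_cols <- c("general_pc1", "general_pc2", "avail_pc1", "avail_pc2",
                   "ready_pc1", "ready_pc2")
      idx <- match(linked$nearest_cs_facility_id, scored$facility_id)
      linked[sc_cols] <- scored[idx, sc_cols]
    }
    out$linked <- linked
  }
  if (on_stage("fit") && !is.null(linked)) {
    women <- ds$women
    women$distance01 <- linked$distance01[match(women$cluster_id,
                                                linked$cluster_id)]
    mc <- config$mcmc
    mc$seed <- stage_seed("fit")
    ladder <- model_ladder(women, config$spec, config$priors, mc)
    out$posterior_summary <- summarize_posterior(
      ladder$fits[[length(ladder$fits)]])
    out$variance_table <- ladder$table
  }
  rates <- cluster_cs_rates(ds$women)
  rates <- cbind(rates, ds$clusters[match(rates$cluster_id,
                                          ds$clusters$cluster_id),
                                    c("x", "y")])
  if (on_stage("hotspots")) {
    band <- config$hotspot_band_km
    if (is.null(band)) {
      isa <- incremental_spatial_autocorrelation(rates$cs_rate, rates)
      band <- isa$peak_km
      out$isa <- isa
    }
    w <- suppressWarnings(
      build_distance_band_weights(rates, band, include_self = TRUE))
    gi <- getis_ord_gi_star(rates$cs_rate, w)
    out$hotspots <- cbind(rates, fdr_classify(gi$z))
    out$hotspot_band_km <- band
  }
  if (on_stage("svc")) {
    set.seed(stage_seed("svc"))
    cm <- stats::aggregate(ds$women[config$svc_formula_covariates],
                           by = list(cluster_id = ds$women$cluster_id), mean)
    cm <- cm[match(rates$cluster_id, cm$cluster_id), ]
    tr <- transform_counts(rates$cs_count, rates$births, config$transform)
    X <- cbind(intercept = 1, as.matrix(cm[config$svc_formula_covariates]))
    # exposure adjustment; dropped when cluster sizes are constant
    if (stats::var(rates$births) > 0)
      X <- cbind(X, log_births = log(rates$births))
    basis <- moran_eigenvectors(rates, config$svc_retention)
    fit <- fit_snvc(tr$y_star, X, basis,
                    svc_covariates = config$svc_formula_covariates)
    rep_ <- snvc_report(fit, coords = rates)
    out$svc_table <- rep_$table
    out$svc_surfaces <- rep_$surfaces
  }
  out$manifest <- list(config_hash = hash, seed = config$seed,
                       stages = config$stages,
                       n_women = nrow(ds$women), n_clusters = nrow(ds$clusters),
                       n_facilities = nrow(ds$facilities),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  for (nm in names(out)) {
    if (is.data.frame(out[[nm]])) {
      attr(out[[nm]], "config_hash") <- hash
      attr(out[[nm]], "seed") <- config$seed
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      if (!is.null(obj) && is.data.frame(obj))
        utils::write.csv(obj, file.path(config$out_dir,
                                        paste0(name, ".csv")),
                         row.names = FALSE)
    }
    wr(out$linked, "linked_clusters")
    wr(out$posterior_summary, "posterior_summary")
    wr(out$variance_table, "variance_table")
    wr(out$hotspots, "hotspots")
    wr(out$svc_table, "svc_table")
    wr(out$svc_surfaces, "svc_surfaces")
    wr(out$descriptives$rates, "descriptive_rates")
    if (!is.null(out$hotspots))
      write_geojson_points(out$hotspots,
                           file.path(config$out_dir, "hotspots.geojson"))
    manifest <- out$manifest
    manifest$timestamp <- NULL  # keep reruns byte-identical
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(out, class = "cs_report")
}

#' @export
print.cs_report <- function(x, ...) {
  cat("Caesarean-delivery analysis bundle\n")
  cat(sprintf("  config hash %s, seed %d\n",
              x$manifest$config_hash, x$manifest$seed))
  cat(sprintf("  %d women / %d clusters / %d facilities\n",
              x$manifest$n_women, x$manifest$n_clusters,
              x$manifest$n_facilities))
  nat <- x$descriptives$rates
  cat(sprintf("  national caesarean rate: %.2f%%\n",
              nat$cs_rate_pct[nat$group == "national"]))
  if (!is.null(x$variance_table)) {
    cat("  variance-partition table:\n")
    print(x$variance_table)
  }
  invisible(x)
}
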