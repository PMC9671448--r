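# CSV / GeoJSON / manifest I/O helpers for pipeline outputs.

#' Write a point table as a GeoJSON FeatureCollection
#'
#' @param df data frame with coordinate columns and attribute columns.
#' @param path output file.
#' @param x,y names of the coordinate columns.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path, x = "x", y = "y") {
  props <- setdiff(names(df), c(x, y))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df[[x]][i], df[[y]][i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON Point FeatureCollection into a data frame
#'
#' @param path GeoJSON file.
#' @return data frame with `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection")
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("only Point geometries are supported")
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1L], y = cc[2L]), f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Write the tables of a synthetic dataset to disk
#'
#' Women, cluster and facility tables as CSV; cluster and facility points
#' also as GeoJSON; the ground truth (config plus realized random effects)
#' as JSON.
#'
#' @param ds a `"cs_simdata"` object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cs_simdata"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    women = file.path(dir, "women.csv"),
    clusters = file.path(dir, "clusters.csv"),
    facilities = file.path(dir, "facilities.csv"),
    clusters_geojson = file.path(dir, "clusters.geojson"),
    facilities_geojson = file.path(dir, "facilities.geojson"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(ds$women, paths["women"], row.names = FALSE)
  utils::write.csv(ds$clusters, paths["clusters"], row.names = FALSE)
  utils::write.csv(ds$facilities, paths["facilities"], row.names = FALSE)
  write_geojson_points(ds$clusters, paths["clusters_geojson"])
  write_geojson_points(ds$facilities[c("facility_id", "x", "y", "cs_flag")],
                       paths["facilities_geojson"])
  truth <- ds$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(paths)
}

# stable hash of a config list: serialize with sorted keys, then sum a
# polynomial over the bytes (no external digest dependency)
.config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  txt <- jsonlite::toJSON(canon(unclass(x)), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
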