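RESOURCE_CATEGORIES <- c("weight_management_program", "park_playground",
                         "fitness_sports_center", "community_recreation_center",
                         "grocery_store", "farmers_market", "csa",
                         "food_pantry", "community_garden")

EARTH_RADIUS_KM <- 6371.0

#' Geographic point
#'
#' @param lat Latitude in degrees, \[-90, 90\].
#' @param lon Longitude in degrees, \[-180, 180\].
#' @return List of class `geo_point`.
#' @export
geo_point <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || length(lat) != 1 ||
      length(lon) != 1 || !is.finite(lat) || !is.finite(lon) ||
      lat < -90 || lat > 90 || lon < -180 || lon > 180) {
    stop("lat must be in [-90, 90] and lon in [-180, 180]", call. = FALSE)
  }
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

#' Great-circle distance (haversine)
#'
#' Straight-line distance on a sphere of radius 6371.0 km; the offline proxy
#' for travel routing.
#'
#' @param a,b `geo_point`s (or lists with lat/lon).
#' @return Distance in km.
#' @export
haversine_km <- function(a, b) {
  if (!inherits(a, "geo_point")) a <- geo_point(a$lat, a$lon)
  if (!inherits(b, "geo_point")) b <- geo_point(b$lat, b$lon)
  to_rad <- pi / 180
  dlat <- (b$lat - a$lat) * to_rad
  dlon <- (b$lon - a$lon) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a$lat * to_rad) * cos(b$lat * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Category display colors
#'
#' A total color-coding over the nine resource categories, so map pins and
#' printed lists distinguish resource types at a glance.
#'
#' @return Named character vector, one color per category.
#' @export
resource_category_colors <- function() {
  c(weight_management_program = "purple",
    park_playground = "darkgreen",
    fitness_sports_center = "blue",
    community_recreation_center = "teal",
    grocery_store = "orange",
    farmers_market = "olive",
    csa = "brown",
    food_pantry = "red",
    community_garden = "limegreen")
}

validate_resource_record <- function(rec, idx) {
  problems <- character()
  name <- rec$name
  if (is.null(name) || !nzchar(trimws(as.character(name %||% "")))) {
    problems <- c(problems, "missing name")
  }
  cat_ <- as.character(rec$category %||% "")
  if (!cat_ %in% RESOURCE_CATEGORIES) {
    problems <- c(problems, paste0("unknown category '", cat_, "'"))
  }
  lat <- suppressWarnings(as.numeric(rec$lat))
  lon <- suppressWarnings(as.numeric(rec$lon))
  if (is.na(lat) || lat < -90 || lat > 90) {
    problems <- c(problems, paste0("latitude ", rec$lat, " outside [-90, 90]"))
  }
  if (is.na(lon) || lon < -180 || lon > 180) {
    problems <- c(problems, paste0("longitude ", rec$lon, " outside [-180, 180]"))
  }
  if (length(problems)) {
    return(list(ok = FALSE,
                diagnostic = sprintf("record %d: %s", idx,
                                     paste(problems, collapse = "; "))))
  }
  list(ok = TRUE,
       row = data.frame(name = as.character(name), category = cat_,
                        lat = lat, lon = lon,
                        address = as.character(rec$address %||% ""),
                        hours = as.character(rec$hours %||% ""),
                        amenities = paste(as.character(rec$amenities %||% ""),
                                          collapse = "; "),
                        stringsAsFactors = FALSE))
}

#' Load a community-resource catalog
#'
#' Accepts a GeoJSON FeatureCollection (Point geometries with name/category/
#' address/hours/amenities properties) or a CSV with name, category, lat, lon
#' and optional address/hours/amenities columns. Invalid records are rejected
#' with per-record diagnostics rather than aborting the load.
#'
#' @param path Catalog file (.geojson/.json or .csv).
#' @return List of class `resource_catalog` with `resources` (data frame),
#'   `n_loaded`, `n_rejected` and `diagnostics`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  records <- if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::read_json(path)
    if (!identical(gj$type, "FeatureCollection")) {
      stop("GeoJSON catalog must be a FeatureCollection", call. = FALSE)
    }
    lapply(gj$features, function(f) {
      coords <- f$geometry$coordinates
      props <- f$properties %||% list()
      bad_geom <- !identical(f$geometry$type, "Point") || length(coords) < 2
      list(name = props$name, category = props$category,
           lon = if (bad_geom) NA else coords[[1]],
           lat = if (bad_geom) NA else coords[[2]],
           address = props$address, hours = props$hours,
           amenities = unlist(props$amenities))
    })
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "category", "lat", "lon")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("catalog CSV missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    lapply(seq_len(nrow(tab)), function(i) {
      r <- as.list(tab[i, , drop = FALSE])
      r$amenities <- if (is.null(r$amenities)) character() else
        trimws(strsplit(as.character(r$amenities), ";")[[1]])
      r
    })
  } else {
    stop("unsupported catalog format: .", ext, " (use GeoJSON or CSV)",
         call. = FALSE)
  }
  rows <- list(); diagnostics <- character()
  for (i in seq_along(records)) {
    v <- validate_resource_record(records[[i]], i)
    if (v$ok) rows[[length(rows) + 1]] <- v$row
    else diagnostics <- c(diagnostics, v$diagnostic)
  }
  resources <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), category = character(), lat = numeric(),
               lon = numeric(), address = character(), hours = character(),
               amenities = character(), stringsAsFactors = FALSE)
  rownames(resources) <- NULL
  structure(list(resources = resources,
                 n_loaded = nrow(resources),
                 n_rejected = length(diagnostics),
                 diagnostics = diagnostics),
            class = "resource_catalog")
}

#' @export
print.resource_catalog <- function(x, ...) {
  cat(sprintf("Resource catalog: %d loaded, %d rejected\n",
              x$n_loaded, x$n_rejected))
  if (x$n_rejected) cat(paste0("  ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Find nearby community resources
#'
#' Category-filtered nearest-resource query around the patient's home:
#' great-circle distances to every catalog entry, filtered to the requested
#' categories and radius, sorted by nondecreasing distance (ties broken by
#' name, then catalog order) and truncated to the top k.
#'
#' @param catalog A `resource_catalog`.
#' @param home The patient's home `geo_point`.
#' @param categories Categories to include; default all nine.
#' @param radius_km Search radius (default 8 km, about 5 miles).
#' @param k Maximum number of hits (default 10).
#' @return Data frame of hits with a `distance_km` column (rounded to 0.01 km
#'   in `distance_km`; exact distances in `distance_km_exact`).
#' @export
find_nearby <- function(catalog, home, categories = RESOURCE_CATEGORIES,
                        radius_km = 8, k = 10) {
  stopifnot(inherits(catalog, "resource_catalog"))
  if (!inherits(home, "geo_point")) home <- geo_point(home$lat, home$lon)
  unknown <- setdiff(categories, RESOURCE_CATEGORIES)
  if (length(unknown)) {
    stop("unknown categories: ", paste(unknown, collapse = ", "),
         "; valid categories: ", paste(RESOURCE_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  res <- catalog$resources
  if (!nrow(res)) return(res_with_distance(res))
  res$catalog_order <- seq_len(nrow(res))
  res <- res[res$category %in% categories, , drop = FALSE]
  if (!nrow(res)) return(res_with_distance(res))
  res$distance_km_exact <- vapply(seq_len(nrow(res)), function(i) {
    haversine_km(home, geo_point(res$lat[i], res$lon[i]))
  }, numeric(1))
  res <- res[res$distance_km_exact <= radius_km, , drop = FALSE]
  res <- res[order(res$distance_km_exact, res$name, res$catalog_order), ,
             drop = FALSE]
  res <- utils::head(res, k)
  res$distance_km <- round(res$distance_km_exact, 2)
  res$catalog_order <- NULL
  rownames(res) <- NULL
  res
}

res_with_distance <- function(res) {
  res$distance_km_exact <- numeric(nrow(res))
  res$distance_km <- numeric(nrow(res))
  res$catalog_order <- NULL
  rownames(res) <- NULL
  res
}
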