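#' Read a GeoJSON FeatureCollection into a study area
#'
#' Accepts Polygon, MultiPolygon or Point features. Polygon centroids are
#' computed as the area-weighted centroid of the largest outer ring (a
#' representative point, adequate for centroid-based scanning); Point
#' features are used as-is. Population, case counts and covariates are
#' read from the feature properties, and the polygon rings are retained so
#' that [export_geojson()] can round-trip the geometry.
#'
#' @param path Path to a GeoJSON file.
#' @param property_map Named character vector mapping the canonical fields
#'   (`id`, `name`, `population`, `cases`) to property names in the file;
#'   unmapped fields use their canonical names.
#' @param covariates Property names to attach as covariates.
#' @param coordinate_mode Passed to [study_area()]; GeoJSON coordinates
#'   are longitude/latitude, so the default is `"spherical"`.
#' @return A `study_area` with `geometry` attached.
#' @export
read_geojson_regions <- function(path, property_map = character(),
                                 covariates = character(),
                                 coordinate_mode = c("spherical",
                                                     "planar")) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  field <- function(props, name) {
    src <- if (name %in% names(property_map)) property_map[[name]] else name
    props[[src]]
  }
  rows <- lapply(gj$features, function(f) {
    ctr <- geometry_centroid(f$geometry)
    props <- f$properties
    row <- list(id = as.character(field(props, "id")),
                name = as.character(
                  if (is.null(field(props, "name"))) field(props, "id")
                  else field(props, "name")),
                x = ctr[1L], y = ctr[2L],
                population = as.numeric(field(props, "population")),
                cases = as.numeric(field(props, "cases")))
    for (cv in covariates) row[[cv]] <- as.numeric(props[[cv]])
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  geometry <- lapply(gj$features, function(f) f$geometry)
  study_area(df, covariates = covariates,
             coordinate_mode = match.arg(coordinate_mode),
             geometry = geometry)
}

# Representative point of a GeoJSON geometry (area centroid of the
# largest outer ring for polygons).
geometry_centroid <- function(geom) {
  ring_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  if (geom$type == "Point") {
    return(c(geom$coordinates[[1]], geom$coordinates[[2]]))
  }
  rings <- switch(geom$type,
    Polygon = list(ring_matrix(geom$coordinates[[1]])),
    MultiPolygon = lapply(geom$coordinates,
                          function(poly) ring_matrix(poly[[1]])),
    stop("unsupported geometry type: ", geom$type))
  areas <- vapply(rings, ring_area, 0)
  polygon_centroid(rings[[which.max(abs(areas))]])
}

ring_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(m) {
  a <- ring_area(m)
  if (abs(a) < 1e-12) return(colMeans(m))
  x <- m[, 1L]; y <- m[, 2L]
  n <- nrow(m)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Export a study area (with optional scan results) as GeoJSON
#'
#' Writes one feature per region carrying its population, case count,
#' crude prevalence, covariates, cluster membership (rank, p-value and
#' prevalence ratio of the containing reported cluster, if any) and an
#' optional choropleth class index from [jenks_breaks()]. Polygon
#' geometry is reused when the area carries it; otherwise point features
#' at the centroids are written (with a warning).
#'
#' @param area A `study_area`.
#' @param path Output path.
#' @param result Optional `scan_result` whose reported clusters tag the
#'   features.
#' @param breaks Optional numeric break points classifying `class_values`.
#' @param class_values Values to classify (default crude region
#'   prevalence, in percent).
#' @return `path`, invisibly.
#' @export
export_geojson <- function(area, path, result = NULL, breaks = NULL,
                           class_values = NULL) {
  stopifnot(inherits(area, "study_area"))
  df <- area$regions
  n <- nrow(df)
  rank_of <- rep(NA_integer_, n)
  p_of <- rep(NA_real_, n)
  pr_of <- rep(NA_real_, n)
  if (!is.null(result)) {
    stopifnot(inherits(result, "scan_result"))
    if (nrow(result$clusters) > 0L) {
      pr_col <- result$config$pr_definition
      for (i in seq_len(nrow(result$clusters))) {
        ix <- match(result$clusters$members[[i]], df$id)
        rank_of[ix] <- result$clusters$rank[i]
        p_of[ix] <- result$clusters$p_value[i]
        pr_of[ix] <- result$clusters[[pr_col]][i]
      }
    }
  }
  if (is.null(class_values)) {
    class_values <- 100 * df$cases / df$population
  }
  class_ix <- if (is.null(breaks)) rep(NA_integer_, n) else
    findInterval(class_values, breaks, left.open = TRUE) + 1L
  have_geom <- !is.null(area$geometry)
  if (!have_geom) {
    warning("no polygon geometry on the study area; writing point features",
            call. = FALSE)
  }
  features <- lapply(seq_len(n), function(i) {
    props <- list(id = df$id[i], name = df$name[i],
                  population = df$population[i], cases = df$cases[i],
                  prevalence_pct = 100 * df$cases[i] / df$population[i])
    for (cv in area$covariates) props[[cv]] <- df[[cv]][i]
    if (!is.na(rank_of[i])) {
      props$cluster_rank <- rank_of[i]
      props$cluster_p <- p_of[i]
      props$cluster_pr <- pr_of[i]
    }
    if (!is.na(class_ix[i])) props$class <- class_ix[i]
    geom <- if (have_geom) area$geometry[[i]] else
      list(type = "Point", coordinates = c(df$x[i], df$y[i]))
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
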