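#' Construct a study area from a region table
#'
#' A study area is the basic container for areal count data: one row per
#' areal unit (e.g. a county) holding an identifier, a display name, a
#' centroid, an adult population denominator, an observed case count and
#' optionally region-level covariates expressed as percentages of the
#' population.
#'
#' @param regions A data frame with columns `id`, `name`, `x`, `y`,
#'   `population`, `cases`, plus one numeric column per covariate.
#' @param covariates Character vector naming the covariate columns of
#'   `regions` (may be empty).
#' @param coordinate_mode Either `"planar"` (Euclidean distances in the
#'   units of `x`/`y`) or `"spherical"` (`x` = longitude, `y` = latitude in
#'   degrees; great-circle distances in km).
#' @param geometry Optional list of polygon rings (one per region, each a
#'   two-column matrix of vertices) carried along for GeoJSON export.
#'
#' @return An object of class `study_area`: a list with elements `regions`
#'   (the validated data frame), `covariates`, `coordinate_mode`,
#'   `geometry`, and the study-area totals `C` (cases) and `N`
#'   (population).
#' @examples
#' df <- data.frame(id = c("a", "b"), name = c("A", "B"),
#'                  x = c(0, 1), y = c(0, 0),
#'                  population = c(100, 300), cases = c(4, 9))
#' area <- study_area(df)
#' area$C  # 13
#' @export
study_area <- function(regions, covariates = character(),
                       coordinate_mode = c("spherical", "planar"),
                       geometry = NULL) {
  coordinate_mode <- match.arg(coordinate_mode)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "population", "cases")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0L) {
    stop("region table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!("name" %in% names(regions))) regions$name <- as.character(regions$id)
  regions$id <- as.character(regions$id)
  validate_regions(regions, covariates)
  structure(
    list(
      regions = regions,
      covariates = covariates,
      coordinate_mode = coordinate_mode,
      geometry = geometry,
      C = sum(as.numeric(regions$cases)),
      N = sum(as.numeric(regions$population))
    ),
    class = "study_area"
  )
}

validate_regions <- function(regions, covariates) {
  if (nrow(regions) < 2L) stop("a study area needs at least 2 regions")
  dup <- regions$id[duplicated(regions$id)]
  if (length(dup) > 0L) {
    stop("duplicate region id(s): ", paste(unique(dup), collapse = ", "))
  }
  for (col in c("x", "y", "population", "cases")) {
    v <- regions[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- regions$id[!is.finite(suppressWarnings(as.numeric(v)))]
      stop("non-numeric or non-finite '", col, "' for region(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (any(regions$population <= 0)) {
    stop("non-positive population for region(s): ",
         paste(regions$id[regions$population <= 0], collapse = ", "))
  }
  if (any(regions$cases < 0)) {
    stop("negative case count for region(s): ",
         paste(regions$id[regions$cases < 0], collapse = ", "))
  }
  over <- regions$cases > regions$population
  if (any(over)) {
    stop("cases exceed population for region(s): ",
         paste(regions$id[over], collapse = ", "))
  }
  missing_cov <- setdiff(covariates, names(regions))
  if (length(missing_cov) > 0L) {
    stop("covariate column(s) not in table: ",
         paste(missing_cov, collapse = ", "))
  }
  for (cv in covariates) {
    if (!is.numeric(regions[[cv]]) || any(!is.finite(regions[[cv]]))) {
      stop("covariate '", cv, "' has non-finite values")
    }
  }
  invisible(TRUE)
}

#' @export
print.study_area <- function(x, ...) {
  cat("<study_area> ", nrow(x$regions), " regions (", x$coordinate_mode,
      " coordinates)\n", sep = "")
  cat("  total cases C = ", format(x$C, big.mark = ","),
      ", total population N = ", format(x$N, big.mark = ","),
      " (crude prevalence ", sprintf("%.2f%%", 100 * x$C / x$N), ")\n",
      sep = "")
  if (length(x$covariates) > 0L) {
    cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a delimited region table into a study area
#'
#' Reads a CSV/TSV file with a header row, maps its columns onto the fields
#' a study area needs, and validates the result (unique ids, positive
#' populations, cases within populations). Row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical field
#'   names (`id`, `name`, `x`, `y`, `population`, `cases`) to the column
#'   names used in the file. Fields absent from the map are assumed to use
#'   their canonical names.
#' @param covariates Covariate column names (post-mapping) to attach.
#' @param coordinate_mode Passed to [study_area()].
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A `study_area`.
#' @seealso [write_region_table()] for the inverse operation.
#' @export
load_region_table <- function(path, column_map = character(),
                              covariates = character(),
                              coordinate_mode = c("spherical", "planar"),
                              sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (field in names(column_map)) {
    src <- column_map[[field]]
    if (!(src %in% names(df))) {
      stop("mapped column '", src, "' (for field '", field,
           "') not found in ", path)
    }
    names(df)[names(df) == src] <- field
  }
  study_area(df, covariates = covariates,
             coordinate_mode = match.arg(coordinate_mode))
}

#' Write a study area back to a delimited region table
#'
#' @param area A `study_area`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(area, path, sep = ",") {
  stopifnot(inherits(area, "study_area"))
  utils::write.table(area$regions, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Pairwise centroid distances for a study area
#'
#' Planar mode uses Euclidean distance in coordinate units; spherical mode
#' treats `x`/`y` as longitude/latitude in degrees and returns great-circle
#' (haversine) distances in kilometres on a sphere of radius 6371 km.
#'
#' @param area A `study_area`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the region ids.
#' @export
region_distances <- function(area) {
  stopifnot(inherits(area, "study_area"))
  xy <- as.matrix(area$regions[, c("x", "y")])
  n <- nrow(xy)
  if (area$coordinate_mode == "planar") {
    d <- as.matrix(stats::dist(xy))
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      dij <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                      xy[j, , drop = FALSE],
                                      r = 6371000) / 1000
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  dimnames(d) <- list(area$regions$id, area$regions$id)
  d
}

#' Nearest-neighbour ordering of regions
#'
#' For every region, the ids of the other regions sorted by ascending
#' centroid distance, truncated to the `K - 1` nearest. Distance ties are
#' broken by region id (lexicographic), which makes window enumeration
#' invariant to the row order of the input table.
#'
#' @param area A `study_area`.
#' @param K Window size bound: each region's list keeps its `K - 1`
#'   nearest neighbours. `K` must lie in `[1, n]`.
#' @param dist_matrix Optional precomputed output of [region_distances()].
#' @return A named list (one element per region id, in table order) of
#'   character vectors of neighbour ids, each of length `K - 1`.
#' @export
k_nearest <- function(area, K, dist_matrix = NULL) {
  stopifnot(inherits(area, "study_area"))
  n <- nrow(area$regions)
  if (K < 1L || K > n) stop("K must be between 1 and the number of regions")
  if (is.null(dist_matrix)) dist_matrix <- region_distances(area)
  ids <- area$regions$id
  out <- vector("list", n)
  names(out) <- ids
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dist_matrix[i, others], ids[others], method = "radix")]
    out[[i]] <- ids[ord[seq_len(K - 1L)]]
  }
  out
}

#' Symmetrised k-nearest-neighbour adjacency
#'
#' Builds an undirected adjacency pair list in which two regions are
#' neighbours if either is among the other's `k` nearest. Used as the
#' default connectivity for the flexible scan when no polygon adjacency is
#' supplied.
#'
#' @param area A `study_area`.
#' @param k Number of nearest neighbours per region.
#' @param dist_matrix Optional precomputed distance matrix.
#' @return A two-column character matrix of id pairs (each unordered pair
#'   once).
#' @export
knn_adjacency <- function(area, k, dist_matrix = NULL) {
  nb <- k_nearest(area, K = k + 1L, dist_matrix = dist_matrix)
  pairs <- do.call(rbind, lapply(names(nb), function(id) {
    if (length(nb[[id]]) == 0L) return(NULL)
    cbind(id, nb[[id]])
  }))
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  unique(cbind(a, b))
}
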