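#' Define a simulation scenario for areal count data
#'
#' A scenario fixes everything the generator needs: the lattice (regular
#' grid or random planar points), the population distribution, the
#' baseline prevalence, embedded high-risk zones of controlled shape and
#' relative risk, and region-level covariates with optional effects on the
#' log rate. The defaults emulate the structure of US county-level
#' prevalence data: populations spanning roughly 1e4 to 2.5e6 and a
#' baseline prevalence of 3.7%.
#'
#' @param name Scenario label.
#' @param lattice `list(type = "grid", nrow, ncol)` or
#'   `list(type = "random", n)` (uniform points on a 100x100 square).
#' @param population `list(type = "fixed", value)` or
#'   `list(type = "loguniform", min, max)`.
#' @param baseline Baseline prevalence pi0 (cases per person), default
#'   0.037.
#' @param zones List of embedded high-risk zones. Each zone is a list
#'   with `rr` (relative risk) and a shape: `shape = "disk"` with `center
#'   = c(row, col)` and `radius` (grid rook-distance disk); `shape = "L"`
#'   with `corner = c(row, col)` and `arm` (arm length, cells); `shape =
#'   "line"` with `start = c(row, col)`, `length`, `dir = "h"/"v"`;
#'   `shape = "knn"` with `center` (region index) and `k` (the k regions
#'   nearest that region, any lattice); or `shape = "set"` with explicit
#'   `ids`.
#' @param covariates Named list; each element is
#'   `list(mean, sd, beta = 0, zone_shift = 0)` describing a region-level
#'   percentage drawn from a normal distribution, an effect `beta` per
#'   unit on the log rate (applied to the covariate centred at its
#'   realised mean, so `baseline` stays the marginal prevalence), and an
#'   optional additive `zone_shift` inside embedded zones (for
#'   covariate-driven hotspots).
#' @param seed Default seed used by [generate_region_data()] when none is
#'   supplied.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(name = "scenario",
                                lattice = list(type = "grid", nrow = 10,
                                               ncol = 10),
                                population = list(type = "loguniform",
                                                  min = 1e4, max = 2.5e6),
                                baseline = 0.037,
                                zones = list(),
                                covariates = list(),
                                seed = NULL) {
  stopifnot(baseline > 0, baseline < 1)
  for (z in zones) {
    if (is.null(z$rr) || z$rr <= 0) stop("every zone needs rr > 0")
  }
  if (length(zones) > 0L && baseline * max(vapply(zones, `[[`, 0, "rr")) >= 1) {
    stop("baseline * max(rr) must stay below 1")
  }
  structure(list(name = name, lattice = lattice, population = population,
                 baseline = baseline, zones = zones,
                 covariates = covariates, seed = seed),
            class = "simulation_scenario")
}

#' Rook adjacency of a regular grid
#'
#' @param nrow,ncol Grid dimensions.
#' @param ids Region ids in row-major order; defaults to the generator's
#'   `r001`, `r002`, ... naming.
#' @return Two-column character matrix of adjacent id pairs.
#' @export
lattice_adjacency <- function(nrow, ncol, ids = NULL) {
  n <- nrow * ncol
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * ncol + c
  pairs <- list()
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      if (c < ncol) pairs[[length(pairs) + 1L]] <-
          c(idx(r, c), idx(r, c + 1L))
      if (r < nrow) pairs[[length(pairs) + 1L]] <-
          c(idx(r, c), idx(r + 1L, c))
    }
  }
  m <- do.call(rbind, pairs)
  cbind(ids[m[, 1L]], ids[m[, 2L]])
}

resolve_zone <- function(zone, coords, nrow_g, ncol_g) {
  shape <- zone$shape
  if (is.null(shape)) shape <- "set"
  n <- nrow(coords)
  if (shape == "set") {
    return(match(zone$ids, rownames(coords)))
  }
  if (shape == "knn") {
    d <- sqrt((coords[, 1] - coords[zone$center, 1])^2 +
                (coords[, 2] - coords[zone$center, 2])^2)
    return(order(d)[seq_len(zone$k)])
  }
  # grid shapes, row-major indexing
  idx <- function(r, c) as.integer((r - 1) * ncol_g + c)
  ok <- function(r, c) r >= 1 && r <= nrow_g && c >= 1 && c <= ncol_g
  cells <- switch(shape,
    disk = {
      ctr <- zone$center
      out <- list()
      for (dr in -zone$radius:zone$radius) {
        for (dc in -zone$radius:zone$radius) {
          if (abs(dr) + abs(dc) <= zone$radius &&
              ok(ctr[1] + dr, ctr[2] + dc)) {
            out[[length(out) + 1L]] <- idx(ctr[1] + dr, ctr[2] + dc)
          }
        }
      }
      unlist(out)
    },
    L = {
      cr <- zone$corner
      arm <- zone$arm
      vert <- vapply(0:(arm - 1L), function(k) idx(cr[1] - k, cr[2]), 0L)
      horiz <- vapply(1:(arm - 1L), function(k) idx(cr[1], cr[2] + k), 0L)
      c(rev(vert), horiz)
    },
    line = {
      st <- zone$start
      if (zone$dir == "h") {
        vapply(0:(zone$length - 1L), function(k) idx(st[1], st[2] + k), 0L)
      } else {
        vapply(0:(zone$length - 1L), function(k) idx(st[1] + k, st[2]), 0L)
      }
    },
    stop("unknown zone shape: ", shape)
  )
  sort.int(unique(cells))
}

#' Generate a synthetic study area with known truth
#'
#' Draws an areal dataset from a [simulation_scenario()]: region rates are
#' `lambda_i = pi0 * RR(zone membership) * exp(sum(beta_k * (x_ik -
#' mean(x_k))))` and case counts are Poisson(`lambda_i * N_i`), truncated
#' at the population with a warning (prevalence counts cannot exceed their
#' denominators). Covariates are centred at their realised means before
#' effects apply, so the marginal prevalence stays at `pi0`. Output is
#' fully reproducible from (scenario, seed).
#'
#' @param scenario A `simulation_scenario`.
#' @param seed Integer seed; defaults to the scenario's own.
#' @return A list with `area` (a validated `study_area`, planar
#'   coordinates), `truth` (logical vector marking embedded-zone members),
#'   `rates` (the true per-person rates), and `adjacency` (rook pairs for
#'   grids, `NULL` otherwise).
#' @export
generate_region_data <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  lat <- scenario$lattice
  if (lat$type == "grid") {
    nrow_g <- lat$nrow; ncol_g <- lat$ncol
    n <- nrow_g * ncol_g
    coords <- cbind(x = rep(seq_len(ncol_g), times = nrow_g),
                    y = rep(seq_len(nrow_g), each = ncol_g))
  } else if (lat$type == "random") {
    n <- lat$n
    nrow_g <- ncol_g <- NA_integer_
    coords <- cbind(x = stats::runif(n, 0, 100),
                    y = stats::runif(n, 0, 100))
  } else {
    stop("unknown lattice type: ", lat$type)
  }
  ids <- sprintf("r%03d", seq_len(n))
  rownames(coords) <- ids

  pop <- scenario$population
  population <- switch(pop$type,
    fixed = rep(as.integer(pop$value), n),
    loguniform = as.integer(round(exp(stats::runif(n, log(pop$min),
                                                   log(pop$max))))),
    stop("unknown population type: ", pop$type))
  if (identical(pop$scale_largest_to, NULL) == FALSE) {
    # pin the largest region at a fixed share of the total
    share <- pop$scale_largest_to
    imax <- which.max(population)
    population[imax] <- as.integer(floor(share / (1 - share) *
                                           sum(population[-imax])))
  }

  rr <- rep(1, n)
  truth <- rep(FALSE, n)
  zone_members <- lapply(scenario$zones, resolve_zone, coords = coords,
                         nrow_g = nrow_g, ncol_g = ncol_g)
  for (k in seq_along(scenario$zones)) {
    mem <- zone_members[[k]]
    rr[mem] <- rr[mem] * scenario$zones[[k]]$rr
    truth[mem] <- TRUE
  }

  df <- data.frame(id = ids, name = ids, x = coords[, "x"],
                   y = coords[, "y"], population = population,
                   cases = 0L, stringsAsFactors = FALSE)
  log_cov_effect <- rep(0, n)
  for (cv in names(scenario$covariates)) {
    spec <- scenario$covariates[[cv]]
    x <- stats::rnorm(n, spec$mean, spec$sd)
    shift <- if (is.null(spec$zone_shift)) 0 else spec$zone_shift
    if (shift != 0) x[truth] <- x[truth] + shift
    df[[cv]] <- x
    beta <- if (is.null(spec$beta)) 0 else spec$beta
    log_cov_effect <- log_cov_effect + beta * (x - mean(x))
  }

  rates <- scenario$baseline * rr * exp(log_cov_effect)
  if (any(rates >= 1)) {
    stop("infeasible scenario: per-person rate >= 1 in ",
         sum(rates >= 1), " region(s)")
  }
  cases <- stats::rpois(n, rates * population)
  if (any(cases > population)) {
    warning("truncating ", sum(cases > population),
            " case count(s) at the population")
    cases <- pmin(cases, population)
  }
  df$cases <- cases
  area <- study_area(df, covariates = names(scenario$covariates),
                     coordinate_mode = "planar")
  adjacency <- if (lat$type == "grid") {
    lattice_adjacency(nrow_g, ncol_g, ids)
  } else NULL
  list(area = area, truth = stats::setNames(truth, ids), rates = rates,
       adjacency = adjacency, zone_members = zone_members)
}

#' Named scenario suite used throughout the tests
#'
#' Fixed, versioned study conditions:
#' \describe{
#'   \item{`null-10x10`}{100-cell grid, population 5,000 per cell,
#'     baseline prevalence 3.7%, no embedded zones: the size (type-I
#'     error) benchmark.}
#'   \item{`disk-hotspot`}{Same grid with a 5-cell rook disk at relative
#'     risk 2.0: the circular-scan power benchmark.}
#'   \item{`l-hotspot`}{Same grid with a 5-cell L-shaped zone at relative
#'     risk 2.0: the irregular-cluster benchmark where the flexible scan
#'     should outperform the circular one.}
#'   \item{`covariate-driven`}{Same grid where a 5-cell disk's excess risk
#'     (relative risk 1.6) is carried entirely by a hypertension-like
#'     covariate (10-point in-zone shift, beta = log(1.6)/10), so the
#'     unadjusted scan flags it and the covariate-adjusted scan should
#'     not.}
#'   \item{`florida-like`}{67 random planar regions with log-uniform
#'     populations (1e4 to 2.5e6) whose largest region is pinned at 13%
#'     of the study total, a compact 5-region hotspot at relative risk
#'     1.6, a second 4-region hotspot at 1.4, and hypertension- and
#'     diabetes-like covariates with mild effects on risk.}
#' }
#'
#' @return Named list of `simulation_scenario` objects.
#' @export
scenario_suite <- function() {
  grid10 <- list(type = "grid", nrow = 10, ncol = 10)
  pop5k <- list(type = "fixed", value = 5000)
  list(
    "null-10x10" = simulation_scenario(
      name = "null-10x10", lattice = grid10, population = pop5k),
    "disk-hotspot" = simulation_scenario(
      name = "disk-hotspot", lattice = grid10, population = pop5k,
      zones = list(list(shape = "disk", center = c(5, 5), radius = 1,
                        rr = 2.0))),
    "l-hotspot" = simulation_scenario(
      name = "l-hotspot", lattice = grid10, population = pop5k,
      zones = list(list(shape = "L", corner = c(6, 3), arm = 3,
                        rr = 2.0))),
    "covariate-driven" = simulation_scenario(
      name = "covariate-driven", lattice = grid10, population = pop5k,
      zones = list(list(shape = "disk", center = c(5, 5), radius = 1,
                        rr = 1.0)),
      covariates = list(
        hypertension = list(mean = 34.6, sd = 3,
                            beta = log(1.6) / 10, zone_shift = 10))),
    "florida-like" = simulation_scenario(
      name = "florida-like",
      lattice = list(type = "random", n = 67),
      population = list(type = "loguniform", min = 1e4, max = 2.5e6,
                        scale_largest_to = 0.13),
      zones = list(list(shape = "knn", center = 10, k = 5, rr = 1.6),
                   list(shape = "knn", center = 50, k = 4, rr = 1.4)),
      covariates = list(
        hypertension = list(mean = 34.6, sd = 5, beta = 0.01),
        diabetes = list(mean = 11.2, sd = 2, beta = 0.02)))
  )
}
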