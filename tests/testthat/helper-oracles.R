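# Independent brute-force oracles used across the test files.

# Tiny study area from vectors.
toy_area <- function(x, y, population, cases, ids = NULL,
                     coordinate_mode = "planar", ...) {
  n <- length(x)
  if (is.null(ids)) ids <- LETTERS[seq_len(n)]
  df <- data.frame(id = ids, name = ids, x = x, y = y,
                   population = population, cases = cases,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  study_area(df, covariates = names(extra), coordinate_mode = coordinate_mode)
}

# Exhaustive connected-subset enumeration by bitmask (n <= ~14):
# all subsets S with centre i, S inside allowed(i), |S| <= K, S connected
# on the adjacency; deduplicated across centres.
oracle_flexible_zones <- function(area, K, adjacency) {
  ids <- area$regions$id
  n <- length(ids)
  nb <- k_nearest(area, K)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(adjacency))) {
    i <- match(adjacency[r, 1], ids)
    j <- match(adjacency[r, 2], ids)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  connected <- function(set) {
    if (length(set) == 1L) return(TRUE)
    seen <- set[1L]
    frontier <- set[1L]
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(lapply(frontier, function(v)
        set[adj[v, set] & !(set %in% seen)])))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    length(seen) == length(set)
  }
  keys <- character(0)
  out <- list()
  for (i in seq_len(n)) {
    allowed <- c(i, match(nb[[ids[i]]], ids))
    m <- length(allowed)
    for (mask in seq_len(2^m) - 1L) {
      set <- allowed[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
      if (!(i %in% set)) next
      if (length(set) > K) next
      if (!connected(set)) next
      key <- paste(sort(set), collapse = ",")
      if (!(key %in% keys)) {
        keys <- c(keys, key)
        out[[length(out) + 1L]] <- sort(set)
      }
    }
  }
  out
}

zone_key_set <- function(members_list, ids = NULL) {
  sort(vapply(members_list, function(m) {
    if (!is.null(ids)) m <- ids[m]
    paste(sort(as.character(m)), collapse = ",")
  }, ""))
}

# Direct Poisson log-likelihood difference (alternative minus null),
# evaluated through dpois rather than the closed form.
oracle_llr <- function(c, e, C) {
  r_in <- c / e
  r_out <- (C - c) / (C - e)
  alt <- stats::dpois(c, r_in * e, log = TRUE) +
    stats::dpois(C - c, r_out * (C - e), log = TRUE)
  null <- stats::dpois(c, e, log = TRUE) +
    stats::dpois(C - c, C - e, log = TRUE)
  alt - null
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Exhaustive Jenks partition search for small inputs: best split of the
# sorted values into k contiguous classes by total within-class SSE.
oracle_jenks <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  best <- NULL
  best_cost <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (col in seq_len(ncol(splits))) {
    cuts <- c(0L, splits[, col], n)
    cost <- sum(vapply(seq_len(k), function(m)
      sse(v[(cuts[m] + 1L):cuts[m + 1L]]), 0))
    if (cost < best_cost) {
      best_cost <- cost
      best <- v[splits[, col]]
    }
  }
  best
}
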