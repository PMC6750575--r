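#' Site geography table
#'
#' @param site character vector of unique site labels.
#' @param x_km,y_km projected planar coordinates in kilometres.
#' @param population optional human population per site (metadata).
#' @return a `site_geography` data frame.
#' @export
site_geography <- function(site, x_km, y_km, population = NA_real_) {
  if (anyDuplicated(site)) stop("duplicate site label")
  if (any(!is.finite(x_km)) || any(!is.finite(y_km))) {
    stop("coordinates must be finite")
  }
  structure(data.frame(site = as.character(site), x_km = x_km, y_km = y_km,
                       population = population),
            class = c("site_geography", "data.frame"))
}

#' Transport network between sites
#'
#' Nodes are site labels; edges carry a mode (`fluvial` or `terrestrial`)
#' and a length in km. Vehicle types have an infestation probability
#' `gamma` and per-pair trip counts, the inputs to the propagule pressure
#' index.
#'
#' @param nodes character vector of site labels.
#' @param edges data frame with columns `from, to, mode, length_km`.
#' @param gamma named numeric vector: infestation probability per vehicle
#'   type, in \[0, 1\].
#' @param trips data frame with columns `vehicle_type, from, to, n_trips`
#'   (non-negative integer counts); may be empty.
#' @return a `transport_network` object.
#' @export
transport_network <- function(nodes, edges, gamma,
                              trips = data.frame(vehicle_type = character(0),
                                                 from = character(0),
                                                 to = character(0),
                                                 n_trips = integer(0))) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node")
  stopifnot(all(c("from", "to", "mode", "length_km") %in% names(edges)))
  if (!all(edges$mode %in% c("fluvial", "terrestrial"))) {
    stop("edge mode must be 'fluvial' or 'terrestrial'")
  }
  if (any(edges$length_km <= 0)) stop("edge lengths must be positive")
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoint not among nodes")
  }
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]")
  stopifnot(all(c("vehicle_type", "from", "to", "n_trips") %in% names(trips)))
  if (any(trips$n_trips < 0) || any(trips$n_trips != round(trips$n_trips))) {
    stop("trip counts must be non-negative integers")
  }
  if (nrow(trips) && !all(trips$vehicle_type %in% names(gamma))) {
    stop("unknown vehicle type in trips: ",
         paste(setdiff(trips$vehicle_type, names(gamma)), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, gamma = gamma, trips = trips),
            class = "transport_network")
}

.distance_matrix <- function(m, model, similarity = FALSE) {
  sym <- (m == t(m)) | (is.na(m) & is.na(t(m)))
  stopifnot(nrow(m) == ncol(m), all(sym), all(diag(m) == 0))
  structure(m, model = model, similarity = similarity,
            class = c("distance_matrix", class(m)))
}

#' Euclidean distance matrix between sites
#'
#' Straight-line planar distances in km from projected coordinates.
#'
#' @param geo a [site_geography()].
#' @return a labelled symmetric `distance_matrix` (model `"euclidean"`).
#' @export
euclidean_matrix <- function(geo) {
  if (nrow(geo) < 2) stop("need at least two sites")
  m <- as.matrix(stats::dist(cbind(geo$x_km, geo$y_km)))
  dimnames(m) <- list(geo$site, geo$site)
  .distance_matrix(m, "euclidean")
}

#' Shortest-path distances on a mode-filtered transport network
#'
#' Sums edge lengths along the shortest route using only edges of the
#' requested modes; pairs not connected by the filtered subgraph are
#' `Inf`. `modes = "fluvial"` gives the fluvial-path model; both modes give
#' the shortest accessible route.
#'
#' @param net a [transport_network()].
#' @param modes subset of `c("fluvial", "terrestrial")`.
#' @return a `distance_matrix` (model `"fluvial_path"` when fluvial-only,
#'   else `"shortest_path"`).
#' @export
path_matrix <- function(net, modes = c("fluvial", "terrestrial")) {
  if (!length(modes)) stop("empty mode set")
  if (!all(modes %in% c("fluvial", "terrestrial"))) stop("unknown mode")
  e <- net$edges[net$edges$mode %in% modes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  m <- igraph::distances(g, weights = e$length_km)
  m <- m[net$nodes, net$nodes]
  model <- if (identical(sort(modes), "fluvial")) "fluvial_path" else "shortest_path"
  .distance_matrix(m, model)
}

#' Propagule pressure index between two sites
#'
#' Trip counts between the pair, weighted by each vehicle type's
#' probability of carrying the invader and summed over vehicle types:
#' `PrPI = sum_j gamma_j * trips_j`. A similarity (large = strong
#' transport linkage), not a distance. `symmetric = TRUE` (default) sums
#' trips in both directions.
#'
#' @param net a [transport_network()].
#' @param origin,destination site labels.
#' @param symmetric sum both directions.
#' @return PrPI value (>= 0).
#' @export
propagule_pressure_index <- function(net, origin, destination,
                                     symmetric = TRUE) {
  tr <- net$trips
  sel <- (tr$from == origin & tr$to == destination)
  if (symmetric) sel <- sel | (tr$from == destination & tr$to == origin)
  tr <- tr[sel, , drop = FALSE]
  if (!nrow(tr)) return(0)
  sum(net$gamma[tr$vehicle_type] * tr$n_trips)
}

#' Pairwise PrPI matrix
#'
#' @param net a [transport_network()].
#' @param sites site labels (defaults to all nodes).
#' @param missing_as_na mark pairs with no trip record at all as `NA`
#'   (unknown) rather than 0; default `TRUE`, since absence of survey data
#'   is not evidence of zero traffic.
#' @return a symmetric `distance_matrix` flagged as a similarity (model
#'   `"prpi"`).
#' @export
prpi_matrix <- function(net, sites = net$nodes, missing_as_na = TRUE) {
  k <- length(sites)
  m <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tr <- net$trips
    has <- any((tr$from == sites[i] & tr$to == sites[j]) |
                 (tr$from == sites[j] & tr$to == sites[i]))
    v <- if (has) propagule_pressure_index(net, sites[i], sites[j])
         else if (missing_as_na) NA_real_ else 0
    m[i, j] <- m[j, i] <- v
  }
  .distance_matrix(m, "prpi", similarity = TRUE)
}
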