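# Composite environmental constructs: land-use mix entropy, street
# connectivity (true intersections per km^2), z-scored component densities
# and the six-component walkability index normalised to 0-100.

#' The six walkability components
#' @export
WALKABILITY_COMPONENTS <- c("population_density", "retail_service_density",
                            "land_use_mix", "street_connectivity",
                            "green_space_density", "sidewalk_density")

#' Land-use mix entropy
#'
#' Normalised Shannon entropy of land-use class area shares over k tracked
#' classes: E = -sum(p_i log p_i) / log k with p_i the shares renormalised
#' over the tracked classes. 0 for a single class, 1 for k equal shares.
#'
#' @param shares non-negative class area shares (need not sum to 1; they
#'   are renormalised over the k tracked classes).
#' @param k number of tracked classes; defaults to `length(shares)`.
#' @return entropy in [0, 1]; `NA` when all shares are zero (the zone has
#'   none of the tracked classes).
#' @examples
#' entropy_mix(rep(0.2, 5))          # 1
#' entropy_mix(c(0.5, 0.5, 0, 0, 0)) # log(2)/log(5)
#' @export
entropy_mix <- function(shares, k = length(shares)) {
  if (k < 2) stop("entropy needs at least 2 tracked classes")
  if (any(shares < 0)) stop("shares must be >= 0")
  tot <- sum(shares)
  if (tot <= 0) return(NA_real_)
  p <- shares / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(k)
}

#' Planarize a line network
#'
#' Splits every polyline into elementary segments, then splits segments at
#' their mutual crossing points and snaps endpoints within `snap_tol`. After
#' planarization a crossing of two through-streets is a shared node with
#' four legs even if the input lines had no vertex there.
#'
#' @param network a [line_network].
#' @param snap_tol node-merge tolerance in metres.
#' @return list with `nodes` (matrix x, y), `degree` (legs per node) and
#'   `segments` (elementary segment list).
#' @export
planarize_network <- function(network, snap_tol = 0.01) {
  segs <- list()
  for (pl in network$segments) {
    for (i in seq_len(nrow(pl) - 1))
      segs[[length(segs) + 1L]] <- pl[i:(i + 1), , drop = FALSE]
  }
  n <- length(segs)
  if (n == 0)
    return(list(nodes = matrix(numeric(0), 0, 2), degree = integer(0),
                segments = list()))
  # collect split points per segment (parameter t along the segment)
  cuts <- vector("list", n)
  for (i in seq_len(n)) cuts[[i]] <- c(0, 1)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ip <- segment_intersection(segs[[i]][1, ], segs[[i]][2, ],
                                 segs[[j]][1, ], segs[[j]][2, ])
      if (is.null(ip)) next
      for (k in c(i, j)) {
        a <- segs[[k]][1, ]; b <- segs[[k]][2, ]
        len2 <- sum((b - a)^2)
        t <- sum((ip - a) * (b - a)) / len2
        cuts[[k]] <- c(cuts[[k]], min(max(t, 0), 1))
      }
    }
  }
  pieces <- list()
  for (i in seq_len(n)) {
    t <- sort(unique(round(cuts[[i]], 12)))
    a <- segs[[i]][1, ]; b <- segs[[i]][2, ]
    len <- sqrt(sum((b - a)^2))
    for (m in seq_len(length(t) - 1)) {
      if ((t[m + 1] - t[m]) * len < snap_tol) next  # degenerate sliver
      pieces[[length(pieces) + 1L]] <-
        rbind(a + t[m] * (b - a), a + t[m + 1] * (b - a))
    }
  }
  # snap endpoints to a tolerance grid and tally legs per node
  key <- function(p) paste(round(p[1] / snap_tol), round(p[2] / snap_tol))
  tab <- new.env(parent = emptyenv())
  coords <- new.env(parent = emptyenv())
  for (pc in pieces) for (v in 1:2) {
    k <- key(pc[v, ])
    assign(k, (get0(k, envir = tab, ifnotfound = 0L)) + 1L, envir = tab)
    if (is.null(get0(k, envir = coords))) assign(k, pc[v, ], envir = coords)
  }
  keys <- ls(tab)
  nodes <- do.call(rbind, lapply(keys, function(k) get(k, envir = coords)))
  degree <- vapply(keys, function(k) get(k, envir = tab), integer(1))
  list(nodes = nodes, degree = unname(degree), segments = pieces)
}

#' True street intersections
#'
#' Nodes of the planarized network where three or more distinct legs meet.
#' T-junctions (3 legs) count; bends and pass-through vertices (2 legs) do
#' not.
#'
#' @param network a [line_network].
#' @param snap_tol node-merge tolerance in metres.
#' @return matrix of intersection coordinates (x, y) with a `legs` column.
#' @export
true_intersections <- function(network, snap_tol = 0.01) {
  pn <- planarize_network(network, snap_tol)
  sel <- pn$degree >= 3L
  cbind(pn$nodes[sel, , drop = FALSE], legs = pn$degree[sel])
}

#' Street connectivity of a zone
#'
#' The ratio of true intersections (three or more legs) inside the zone to
#' the zone area in km^2.
#'
#' @param network a [line_network].
#' @param zone a polygon vertex matrix, or a [zone_set] (vectorised over
#'   its zones).
#' @param snap_tol node-merge tolerance in metres.
#' @return intersections per km^2 (numeric; one value per zone).
#' @export
street_connectivity <- function(network, zone, snap_tol = 0.01) {
  xi <- true_intersections(network, snap_tol)
  one <- function(poly) {
    area_km2 <- poly_area(poly) / 1e6
    if (area_km2 <= 0) stop("zone area must be > 0")
    if (nrow(xi) == 0) return(0)
    sum(points_in_polygon(xi[, 1], xi[, 2], poly)) / area_km2
  }
  if (inherits(zone, "zone_set"))
    vapply(zone$geoms, one, numeric(1))
  else one(as.matrix(zone))
}

#' Z-scores over a reference set of zones
#'
#' Standardises raw per-zone values with the sample (n-1) standard
#' deviation. `NA` inputs propagate to `NA` and are excluded from the
#' reference mean/SD.
#'
#' @param values numeric vector of per-zone raw values.
#' @param name component name used in error messages.
#' @return numeric vector of z-values (mean 0, SD 1 over non-NA entries).
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("z-scores need at least 2 zones with values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("component '", name, "' is constant over the reference set")
  (values - mean(values[ok])) / s
}

#' Six-component walkability index
#'
#' Sums the z-scores of the six components (population density, retail and
#' service density, land-use mix, street connectivity, green space density,
#' sidewalk density; equal weights) and min-max rescales the sums to
#' 0-100 over the reference set: the least walkable zone in the set scores
#' exactly 0 and the most walkable exactly 100. Scores are therefore
#' relative to the set of zones in the run.
#'
#' @param components data frame with a `zone_id` column and the six raw
#'   component columns named as in [WALKABILITY_COMPONENTS].
#' @return data frame `zone_id`, the six z columns (`z_<component>`),
#'   `raw_sum`, `score`. Zones missing any component get `NA` score.
#' @export
walkability <- function(components) {
  missing_cols <- setdiff(WALKABILITY_COMPONENTS, names(components))
  if (length(missing_cols))
    stop("missing walkability components: ", paste(missing_cols, collapse = ", "))
  if (nrow(components) < 2) stop("walkability needs >= 2 reference zones")
  zs <- lapply(WALKABILITY_COMPONENTS, function(cn)
    zscore(components[[cn]], name = cn))
  names(zs) <- paste0("z_", WALKABILITY_COMPONENTS)
  zmat <- do.call(cbind, zs)
  raw_sum <- rowSums(zmat)  # NA when any component missing for the zone
  rng <- range(raw_sum, na.rm = TRUE)
  if (diff(rng) == 0) stop("all zones have identical component sums")
  # divide before scaling so the set max maps to exactly 100 (x/x == 1)
  score <- 100 * ((raw_sum - rng[1]) / (rng[2] - rng[1]))
  out <- data.frame(zone_id = components$zone_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(zmat))
  out$raw_sum <- raw_sum
  out$score <- score
  out
}
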