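# Exposure zones (circular buffers around addresses, administrative units)
# and statistical aggregation of rasters, point layers and classified
# polygons over them.

#' Canonical exposure radii presets (metres)
#' @export
EXPOSURE_RADII <- c(150, 250, 350, 500, 750, 1000, 1650, 2000)

#' Exposure-zone specification
#'
#' @param mode `"radius"` (circular buffers around addresses) or `"admin"`
#'   (administrative units).
#' @param radius buffer radius in metres (mode = "radius"). May be given as
#'   a preset name, e.g. `"500"`.
#' @param level admin level (mode = "admin").
#' @return an object of class `zone_spec`.
#' @export
zone_spec <- function(mode = c("radius", "admin"), radius = NULL,
                      level = "neighbourhood") {
  mode <- match.arg(mode)
  if (mode == "radius") {
    radius <- as.numeric(radius)
    if (!length(radius) || !is.finite(radius) || radius <= 0)
      stop("radius must be a positive number of metres")
  }
  structure(list(mode = mode, radius = radius, level = level),
            class = "zone_spec")
}

#' Zone set constructor
#' @noRd
zone_set <- function(zone_id, geoms, level = "address") {
  structure(list(zone_id = as.character(zone_id), geoms = geoms,
                 area = vapply(geoms, poly_area, numeric(1)),
                 level = level),
            class = "zone_set")
}

#' @export
length.zone_set <- function(x) length(x$geoms)

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (level %s), total area %.4g km^2\n",
              length(x$geoms), x$level, sum(x$area) / 1e6))
  invisible(x)
}

#' Circular exposure buffers around addresses
#'
#' One zone per address: a regular-polygon circle of the given radius
#' (vertices on the true circle; 128 segments keep the polygon area within
#' 0.05% of pi r^2).
#'
#' @param addresses an [address_set].
#' @param spec a [zone_spec] with mode "radius", or a bare radius in metres.
#' @param segments vertices of the circle approximation.
#' @return a [zone_set] keyed by address_id.
#' @examples
#' ad <- address_set("A1", 0, 0)
#' z <- make_buffers(ad, 500)
#' z$area / (pi * 500^2)  # ~ 0.9996
#' @export
make_buffers <- function(addresses, spec, segments = 128L) {
  r <- if (inherits(spec, "zone_spec")) {
    if (spec$mode != "radius") stop("make_buffers needs a radius-mode zone_spec")
    spec$radius
  } else as.numeric(spec)
  if (!is.finite(r) || r <= 0) stop("radius must be > 0")
  geoms <- lapply(seq_len(nrow(addresses)), function(i)
    circle_polygon(addresses$x[i], addresses$y[i], r, segments))
  zone_set(addresses$address_id, geoms, level = "address")
}

#' Zones from administrative units
#'
#' @param units an [admin_units] object.
#' @return a [zone_set] keyed by unit_id.
#' @export
admin_zones <- function(units) {
  zone_set(units$unit_id, units$geoms, level = units$level)
}

#' Zonal statistics of a raster
#'
#' Aggregates the raster over each zone using the cell-centre rule: a cell
#' contributes iff its centre falls inside the (closed) zone polygon. NA
#' cells are excluded; a zone containing no cell centre gets `NA` with a
#' warning.
#'
#' @param raster an [exp_raster].
#' @param zones a [zone_set].
#' @param stat one of `"mean"`, `"sum"`, `"min"`, `"max"`, `"count"`.
#' @return a component table: data frame `zone_id`, `variable`, `value`.
#' @export
zonal_raster_stat <- function(raster, zones,
                              stat = c("mean", "sum", "min", "max", "count")) {
  stat <- match.arg(stat)
  cc <- cell_centres(raster)
  vals <- as.vector(t(raster$values))  # row-major to match cell_centres
  out <- vapply(seq_along(zones$geoms), function(i) {
    poly <- zones$geoms[[i]]
    bb <- poly_bbox(poly)
    cand <- cc[, "x"] >= bb[1] & cc[, "x"] <= bb[3] &
            cc[, "y"] >= bb[2] & cc[, "y"] <= bb[4]
    if (!any(cand)) return(NA_real_)
    idx <- which(cand)
    inside <- points_in_polygon(cc[idx, "x"], cc[idx, "y"], poly)
    v <- vals[idx[inside]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    switch(stat, mean = mean(v), sum = sum(v), min = min(v), max = max(v),
           count = length(v))
  }, numeric(1))
  if (anyNA(out))
    warning(sum(is.na(out)), " zone(s) contain no raster cell centre; NA assigned")
  data.frame(zone_id = zones$zone_id, variable = paste0("raster_", stat),
             value = out, stringsAsFactors = FALSE)
}

#' Zonal statistics of a point layer
#'
#' Points on the zone boundary count as inside (closed-zone convention).
#'
#' @param points a [point_layer].
#' @param zones a [zone_set].
#' @param stat `"count"`, `"density_per_km2"` (count per km^2 of zone area)
#'   or `"weight_sum"`.
#' @return data frame `zone_id`, `variable`, `value`.
#' @export
zonal_point_stat <- function(points, zones,
                             stat = c("count", "density_per_km2", "weight_sum")) {
  stat <- match.arg(stat)
  out <- vapply(seq_along(zones$geoms), function(i) {
    poly <- zones$geoms[[i]]
    if (nrow(points) == 0) {
      inside <- logical(0)
    } else {
      bb <- poly_bbox(poly)
      cand <- which(points$x >= bb[1] - 1e-9 & points$x <= bb[3] + 1e-9 &
                    points$y >= bb[2] - 1e-9 & points$y <= bb[4] + 1e-9)
      inside <- cand[points_in_polygon(points$x[cand], points$y[cand], poly)]
    }
    switch(stat,
           count = length(inside),
           density_per_km2 = length(inside) / (zones$area[i] / 1e6),
           weight_sum = if (length(inside)) sum(points$weight[inside]) else 0)
  }, numeric(1))
  data.frame(zone_id = zones$zone_id, variable = paste0("points_", stat),
             value = out, stringsAsFactors = FALSE)
}

#' Per-class land-use area shares within zones
#'
#' share_k = area(class-k polygons intersected with the zone) / zone area.
#' Computed by exact convex clipping, so zones must be convex (buffers and
#' rectangular admin tiles are). Overlapping same-class polygons are
#' dissolved (inclusion-exclusion over overlap groups, exact for convex
#' pieces) so area is never double-counted. Shares of the listed classes
#' sum to <= 1; unlisted classes absorb the remainder.
#'
#' @param polygons a [polygon_layer].
#' @param zones a [zone_set] of convex zones.
#' @param classes classes to report; defaults to the layer's vocabulary.
#' @return data frame `zone_id`, `variable` (`share_<class>`), `value`.
#' @export
zonal_polygon_share <- function(polygons, zones,
                                classes = polygons$classes) {
  not_convex <- which(!vapply(zones$geoms, is_convex, logical(1)))
  if (length(not_convex))
    stop("zonal_polygon_share requires convex zones; non-convex: ",
         paste(zones$zone_id[not_convex], collapse = ", "))
  res <- vector("list", length(zones$geoms))
  pbbs <- lapply(polygons$geoms, poly_bbox)
  for (i in seq_along(zones$geoms)) {
    zpoly <- zones$geoms[[i]]
    zbb <- poly_bbox(zpoly)
    shares <- vapply(classes, function(cl) {
      sel <- which(polygons$class_label == cl)
      sel <- sel[vapply(sel, function(j) bboxes_overlap(pbbs[[j]], zbb),
                        logical(1))]
      if (!length(sel)) return(0)
      pieces <- Filter(Negate(is.null),
                       lapply(polygons$geoms[sel],
                              function(g) clip_polygon_convex(g, zpoly)))
      if (!length(pieces)) return(0)
      union_area(pieces) / zones$area[i]
    }, numeric(1))
    res[[i]] <- data.frame(zone_id = zones$zone_id[i],
                           variable = paste0("share_", classes),
                           value = unname(shares), stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# Area of the union of polygons; exact sum when disjoint, inclusion-
# exclusion over connected overlap groups otherwise (requires convex
# members in that case).
union_area <- function(pieces) {
  n <- length(pieces)
  if (n == 1) return(poly_area(pieces[[1]]))
  bbs <- lapply(pieces, poly_bbox)
  inter <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!bboxes_overlap(bbs[[i]], bbs[[j]])) next
    ij <- clip_polygon_convex(pieces[[i]], pieces[[j]])
    if (!is.null(ij) && poly_area(ij) > 1e-9) inter[i, j] <- inter[j, i] <- TRUE
  }
  if (!any(inter)) return(sum(vapply(pieces, poly_area, numeric(1))))
  # connected components of the overlap graph
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cid
      stack <- c(stack, which(inter[v, ] & comp == 0L))
    }
  }
  total <- 0
  for (g in split(seq_len(n), comp)) {
    if (length(g) == 1) { total <- total + poly_area(pieces[[g]]); next }
    if (!all(vapply(pieces[g], is_convex, logical(1))))
      stop("overlapping non-convex same-class polygons cannot be dissolved ",
           "exactly; dissolve the input layer first")
    if (length(g) > 20)
      stop("overlap group too large to dissolve by inclusion-exclusion")
    # inclusion-exclusion over subsets; convex intersections via clipping
    for (k in seq_along(g)) {
      sgn <- (-1)^(k + 1)
      for (subset in utils::combn(g, k, simplify = FALSE)) {
        cur <- pieces[[subset[1]]]
        for (m in subset[-1]) {
          cur <- clip_polygon_convex(cur, pieces[[m]])
          if (is.null(cur)) break
        }
        if (!is.null(cur)) total <- total + sgn * poly_area(cur)
      }
    }
  }
  total
}
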