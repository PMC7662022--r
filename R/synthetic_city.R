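# Deterministic synthetic study region: every layer kind the toolkit
# consumes, generated from a seeded configuration so the full processing
# chain runs without any external geodata.

#' Synthetic-city configuration
#'
#' Defines a rectangular study region with an orthogonal street grid,
#' square land-use patches drawn from the five walkability classes, points
#' of interest, residential addresses and observation stations. Identical
#' configurations yield byte-identical layers; each generator draws from its
#' own seeded stream, so adding one generator never perturbs another.
#'
#' @param extent c(width, height) of the region in metres.
#' @param street_spacing spacing of the orthogonal street grid, metres.
#' @param n_pois points of interest per category.
#' @param land_use_patch side of the square land-use patches, metres.
#' @param n_addresses number of residential addresses.
#' @param n_stations number of observation stations.
#' @param seed integer master seed.
#' @return an object of class `city_config`.
#' @examples
#' cfg <- city_config(extent = c(2000, 2000), seed = 7)
#' streets <- make_street_grid(cfg)
#' @export
city_config <- function(extent = c(5000, 5000), street_spacing = 250,
                        n_pois = 40, land_use_patch = 250,
                        n_addresses = 200, n_stations = 25, seed = 1L) {
  stopifnot(length(extent) == 2, all(extent > 0), street_spacing > 0,
            land_use_patch > 0, n_pois >= 0, n_addresses >= 0,
            n_stations >= 0)
  structure(list(extent = as.numeric(extent),
                 street_spacing = as.numeric(street_spacing),
                 n_pois = as.integer(n_pois),
                 land_use_patch = as.numeric(land_use_patch),
                 n_addresses = as.integer(n_addresses),
                 n_stations = as.integer(n_stations),
                 seed = as.integer(seed)),
            class = "city_config")
}

# run expr with an isolated RNG stream derived from (seed, stream label);
# the caller's .Random.seed is untouched
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  # fold the stream label into the seed; keep within 32-bit integer range
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  set.seed((abs(seed) %% 1000003L) * 1009L + h %% 100003L)
  force(expr)
}

#' Orthogonal street grid
#'
#' Horizontal and vertical streets at `street_spacing`, including the
#' boundary lines. A 1000 x 1000 m extent at 500 m spacing yields 3
#' horizontal and 3 vertical streets with 9 crossings.
#'
#' @param config a [city_config].
#' @return a [line_network].
#' @export
make_street_grid <- function(config) {
  w <- config$extent[1]; h <- config$extent[2]; s <- config$street_spacing
  xs <- unique(c(seq(0, w, by = s), w))
  ys <- unique(c(seq(0, h, by = s), h))
  segs <- c(lapply(ys, function(y) rbind(c(0, y), c(w, y))),
            lapply(xs, function(x) rbind(c(x, 0), c(x, h))))
  line_network(segs)
}

#' Land-use patch tiling
#'
#' Tiles the extent with square patches of side `land_use_patch`, each
#' assigned one of the five walkability land-use classes by a seeded draw.
#' Default class shares approximate a Dutch urban mix: residential 0.40,
#' commercial 0.15, social-cultural 0.10, offices/public 0.15,
#' greenspace/recreation 0.20. With `forced_shares = TRUE` the classes are
#' dealt round-robin over a shuffled patch order, so per-class patch counts
#' differ by at most one (area shares equal within one patch area).
#'
#' @param config a [city_config].
#' @param shares named numeric class probabilities (summing to 1).
#' @param forced_shares logical; equal-count assignment instead of sampling.
#' @return a [polygon_layer] whose attribute `class_shares` records the
#'   realised per-class area shares.
#' @export
make_land_use <- function(config,
                          shares = c(residential = 0.40, commercial = 0.15,
                                     social_cultural = 0.10,
                                     offices_public = 0.15, greenspace = 0.20),
                          forced_shares = FALSE) {
  stopifnot(setequal(names(shares), LAND_USE_CLASSES))
  w <- config$extent[1]; h <- config$extent[2]; p <- config$land_use_patch
  nx <- max(1L, floor(w / p + 1e-9)); ny <- max(1L, floor(h / p + 1e-9))
  geoms <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    geoms[[k]] <- rect_polygon((ix - 1) * p, (iy - 1) * p,
                               min(ix * p, w), min(iy * p, h))
  }
  cls <- with_stream(config$seed, "land_use", {
    if (forced_shares) {
      base <- rep(LAND_USE_CLASSES, length.out = k)
      base[sample.int(k)]
    } else {
      sample(names(shares), k, replace = TRUE, prob = shares)
    }
  })
  layer <- polygon_layer(geoms, cls)
  realised <- tapply(layer$area, factor(cls, levels = LAND_USE_CLASSES), sum)
  realised[is.na(realised)] <- 0
  attr(layer, "class_shares") <- realised / sum(layer$area)
  layer
}

#' Uniformly placed points of interest
#'
#' @param config a [city_config].
#' @param category category label assigned to all points.
#' @param n number of points; defaults to `config$n_pois`.
#' @return a [point_layer].
#' @export
make_points <- function(config, category = "poi", n = config$n_pois) {
  xy <- with_stream(config$seed, paste0("points_", category), {
    cbind(stats::runif(n, 0, config$extent[1]),
          stats::runif(n, 0, config$extent[2]))
  })
  if (n == 0) return(point_layer(numeric(0), numeric(0)))
  point_layer(xy[, 1], xy[, 2], category = category)
}

#' Residential address set
#'
#' @param config a [city_config].
#' @return an [address_set] with ids `A0001`, `A0002`, ...
#' @export
make_addresses <- function(config) {
  n <- config$n_addresses
  xy <- with_stream(config$seed, "addresses", {
    cbind(stats::runif(n, 0, config$extent[1]),
          stats::runif(n, 0, config$extent[2]))
  })
  if (n == 0) return(address_set(character(0), numeric(0), numeric(0)))
  address_set(sprintf("A%04d", seq_len(n)), xy[, 1], xy[, 2])
}

#' Observation stations on a known surface
#'
#' Stations are placed uniformly and carry `value = field(x, y)`, so an
#' interpolation method can be checked against the generating surface.
#'
#' @param config a [city_config].
#' @param field function of (x, y) returning the observed value. Default is
#'   a smooth tilted-plane-plus-sine temperature-like surface.
#' @return a [point_layer] with a `value` column.
#' @export
make_stations <- function(config,
                          field = function(x, y)
                            15 + 2e-4 * x - 1e-4 * y +
                            0.5 * sin(x / max(config$extent) * pi)) {
  n <- config$n_stations
  xy <- with_stream(config$seed, "stations", {
    cbind(stats::runif(n, 0, config$extent[1]),
          stats::runif(n, 0, config$extent[2]))
  })
  if (n == 0) return(point_layer(numeric(0), numeric(0)))
  point_layer(xy[, 1], xy[, 2], value = field(xy[, 1], xy[, 2]))
}

#' Administrative unit tiling
#'
#' A k x k tiling of the extent, partitioning it exactly. Two nesting
#' levels mimic the neighbourhood-contains-postal-code hierarchy: call with
#' `k` for neighbourhoods and `2 * k` (level = "PC4") for the finer mock.
#'
#' @param config a [city_config].
#' @param k tiles per side.
#' @param level admin level label.
#' @return an [admin_units] object with ids `<level>_<ix>_<iy>`.
#' @export
make_admin_units <- function(config, k = 5L, level = "neighbourhood") {
  w <- config$extent[1]; h <- config$extent[2]
  geoms <- list(); ids <- character(0)
  for (iy in seq_len(k)) for (ix in seq_len(k)) {
    geoms[[length(geoms) + 1L]] <-
      rect_polygon((ix - 1) * w / k, (iy - 1) * h / k, ix * w / k, iy * h / k)
    ids <- c(ids, sprintf("%s_%d_%d", level, ix, iy))
  }
  admin_units(geoms, ids, level = level)
}

#' Generate the full synthetic city
#'
#' @param config a [city_config].
#' @param poi_categories categories of points of interest to generate.
#' @param k_units admin tiles per side (neighbourhood level; the PC4 mock
#'   uses `2 * k_units`).
#' @return named list: `config`, `streets`, `land_use`, `pois` (list by
#'   category), `addresses`, `stations`, `units` (neighbourhood), `units_pc4`.
#' @export
make_city <- function(config = city_config(),
                      poi_categories = c("supermarket", "pt_stop"),
                      k_units = 5L) {
  pois <- lapply(poi_categories, function(cat) make_points(config, cat))
  names(pois) <- poi_categories
  list(config = config,
       streets = make_street_grid(config),
       land_use = make_land_use(config),
       pois = pois,
       addresses = make_addresses(config),
       stations = make_stations(config),
       units = make_admin_units(config, k_units, "neighbourhood"),
       units_pc4 = make_admin_units(config, 2L * k_units, "PC4"))
}

#' Write synthetic-city fixtures to a directory
#'
#' Emits GeoJSON (vector layers), CSV (addresses, stations) and a YAML
#' manifest recording the configuration.
#'
#' @param config a [city_config].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  city <- make_city(config)
  write_layer(city$streets, file.path(dir, "streets.geojson"))
  write_layer(city$land_use, file.path(dir, "land_use.geojson"))
  for (cat in names(city$pois))
    write_layer(city$pois[[cat]], file.path(dir, paste0("poi_", cat, ".geojson")))
  write_layer(city$units, file.path(dir, "units_nb.geojson"))
  write_layer(city$units_pc4, file.path(dir, "units_pc4.geojson"))
  utils::write.csv(as.data.frame(unclass(city$addresses[c("address_id", "x", "y")])),
                   file.path(dir, "addresses.csv"), row.names = FALSE)
  st <- city$stations
  utils::write.csv(data.frame(x = st$x, y = st$y, value = st$value),
                   file.path(dir, "stations.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(generator = "exposcape synthetic city",
                        config = unclass(config)), manifest)
  invisible(manifest)
}
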