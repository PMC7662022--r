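# Config-driven orchestration: from raw layers (or the synthetic city) to
# the linkable exposure table plus one metadata sheet per output column.

PIPELINE_RECIPES <- c("point_density", "kernel_density", "entropy",
                      "land_use_share", "connectivity", "idw", "walkability")

#' Walkability component table for a zone set
#'
#' Computes the six raw walkability components for each zone:
#' \describe{
#'   \item{population_density}{weighted population points per km^2
#'     (zonal point statistic).}
#'   \item{retail_service_density}{retail/service destination points per
#'     km^2.}
#'   \item{land_use_mix}{normalised entropy of the five land-use class area
#'     shares.}
#'   \item{street_connectivity}{true intersections (>= 3 legs) per km^2.}
#'   \item{green_space_density}{area share of the greenspace class.}
#'   \item{sidewalk_density}{sidewalk/street centreline length (m) per km^2
#'     of zone area.}
#' }
#'
#' @param zones a [zone_set] (convex zones).
#' @param population a [point_layer] of population points (weights =
#'   persons).
#' @param retail a [point_layer] of retail/service destinations.
#' @param land_use a classified [polygon_layer] with the five walkability
#'   classes.
#' @param streets a [line_network] of streets.
#' @param sidewalks a [line_network] of sidewalks; defaults to `streets`
#'   when no separate sidewalk layer exists.
#' @return data frame `zone_id` plus the six raw component columns.
#' @export
walkability_components <- function(zones, population, retail, land_use,
                                   streets, sidewalks = streets) {
  pop <- zonal_point_stat(population, zones, "weight_sum")
  pop_d <- pop$value / (zones$area / 1e6)
  ret <- zonal_point_stat(retail, zones, "density_per_km2")
  shares <- zonal_polygon_share(land_use, zones, classes = land_use$classes)
  ent <- vapply(zones$zone_id, function(z)
    entropy_mix(shares$value[shares$zone_id == z], k = length(land_use$classes)),
    numeric(1))
  green <- vapply(zones$zone_id, function(z)
    shares$value[shares$zone_id == z & shares$variable == "share_greenspace"],
    numeric(1))
  conn <- street_connectivity(streets, zones)
  side <- vapply(seq_along(zones$geoms), function(i)
    network_length_in_convex(sidewalks, zones$geoms[[i]]) / (zones$area[i] / 1e6),
    numeric(1))
  data.frame(zone_id = zones$zone_id,
             population_density = pop_d,
             retail_service_density = ret$value,
             land_use_mix = unname(ent),
             street_connectivity = conn,
             green_space_density = unname(green),
             sidewalk_density = side,
             stringsAsFactors = FALSE)
}

#' Validate a pipeline manifest (fail-fast)
#'
#' @param manifest manifest list (see [run_pipeline()]).
#' @return the manifest, invisibly, after normalisation.
#' @export
validate_manifest <- function(manifest) {
  if (is.null(manifest$variables)) manifest$variables <- list()
  for (v in manifest$variables) {
    if (is.null(v$name) || is.null(v$recipe))
      stop("config error: every variable needs 'name' and 'recipe'")
    if (!v$recipe %in% PIPELINE_RECIPES)
      stop("config error: unknown variable recipe '", v$recipe,
           "' (known: ", paste(PIPELINE_RECIPES, collapse = ", "), ")")
    if (v$recipe %in% c("point_density", "kernel_density") &&
        is.null(v$category))
      stop("config error: recipe '", v$recipe, "' needs a point 'category'")
    if (v$recipe == "land_use_share" && is.null(v$class))
      stop("config error: recipe 'land_use_share' needs a land-use 'class'")
  }
  invisible(manifest)
}

#' Run the exposure pipeline
#'
#' Executes every variable recipe in the manifest against the synthetic
#' city defined by `manifest$city` (+ `manifest$seed`), producing an
#' exposure table with one row per address and one column per
#' variable x radius, named `<theme>_<stat>_A<radius>_<year>`, plus one
#' metadata sheet per column. The run is deterministic: identical manifest
#' and seed give byte-identical output tables. A variable whose
#' computation fails is skipped and the reason recorded in the log.
#'
#' Recipes: `point_density` (points per km^2 in the buffer),
#' `kernel_density` (quartic kernel surface sampled at the address),
#' `entropy` (land-use mix), `land_use_share` (area share of one class),
#' `connectivity` (true intersections per km^2), `idw`
#' (inverse-distance-weighted station value at the address) and
#' `walkability` (six-component 0-100 index over the buffer).
#'
#' @param manifest a list (or path to a YAML file) with elements `seed`,
#'   `city` (arguments of [city_config()]), `variables` (list of recipe
#'   specs), optional `year` and `linkage`
#'   (`"address"`, `"neighbourhood"` or `"PC4"`).
#' @return list of class `exposure_run`: `table` (the exposure data frame,
#'   keyed by `address_id` or unit id), `metadata` (one sheet per column),
#'   `log` (stage messages), `city` (the generated layers).
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  validate_manifest(manifest)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  cfg_args <- manifest$city %||% list()
  if (!is.null(manifest$seed)) cfg_args$seed <- manifest$seed
  cfg <- do.call(city_config, cfg_args)
  addresses <- make_addresses(cfg)
  land_use <- make_land_use(cfg)
  streets <- make_street_grid(cfg)
  stations <- make_stations(cfg)
  say("layers ready: %d addresses, %d land-use patches, %d streets, %d stations",
      nrow(addresses), length(land_use$geoms), length(streets$segments),
      nrow(stations))

  year <- manifest$year %||% format(Sys.Date(), "%Y")
  table <- data.frame(address_id = addresses$address_id,
                      stringsAsFactors = FALSE)
  metadata <- list()
  buffers <- list()  # cache per radius
  get_buffers <- function(r) {
    key <- as.character(r)
    if (is.null(buffers[[key]])) buffers[[key]] <<- make_buffers(addresses, r)
    buffers[[key]]
  }

  for (v in manifest$variables) {
    radii <- v$radii %||% v$radius %||% 500
    for (r in radii) {
      colname <- sprintf("%s_%s_A%d_%s", v$name, recipe_stat(v$recipe),
                         as.integer(r), year)
      vals <- tryCatch({
        zones <- get_buffers(r)
        switch(v$recipe,
          point_density = {
            pts <- make_points(cfg, v$category)
            zonal_point_stat(pts, zones, "density_per_km2")$value
          },
          kernel_density = {
            pts <- make_points(cfg, v$category)
            spec <- kernel_spec(r, cell_size = v$cell_size %||% (r / 10))
            grid <- raster_template(c(0, 0, cfg$extent[1], cfg$extent[2]),
                                    spec$cell_size)
            surf <- kernel_density(pts, spec, grid)
            sample_at_points(surf, addresses)$value
          },
          entropy = {
            sh <- zonal_polygon_share(land_use, zones)
            vapply(zones$zone_id, function(z)
              entropy_mix(sh$value[sh$zone_id == z],
                          k = length(land_use$classes)), numeric(1))
          },
          land_use_share = {
            sh <- zonal_polygon_share(land_use, zones, classes = v$class)
            sh$value
          },
          connectivity = street_connectivity(streets, zones),
          idw = {
            spec <- idw_spec(power = v$power %||% 2.0,
                             search_radius = v$search_radius %||% 110000,
                             block_size = v$block_size)
            if (is.null(spec$block_size)) {
              idw_predict(addresses$x, addresses$y, stations, spec$power,
                          spec$search_radius)
            } else {
              grid <- raster_template(c(0, 0, cfg$extent[1], cfg$extent[2]),
                                      v$cell_size %||% 100)
              sample_at_points(idw_interpolate(stations, spec, grid),
                               addresses)$value
            }
          },
          walkability = {
            comp <- walkability_components(
              zones,
              population = point_layer(addresses$x, addresses$y),
              retail = make_points(cfg, "retail"),
              land_use = land_use, streets = streets)
            walkability(comp)$score
          })
      }, error = function(e) {
        say("variable %s skipped: %s", colname, conditionMessage(e))
        NULL
      })
      if (is.null(vals)) next
      table[[colname]] <- unname(vals)
      metadata[[colname]] <- metadata_sheet(colname, v, r, year)
      say("variable %s: %d addresses, %d non-missing", colname, nrow(table),
          sum(!is.na(vals)))
    }
  }

  linkage <- manifest$linkage %||% "address"
  if (linkage != "address") {
    k <- manifest$k_units %||% 5L
    units <- make_admin_units(cfg, if (linkage == "PC4") 2L * k else k, linkage)
    table <- link_level(table, addresses, units)
    say("linked to %s level: %d units", linkage, nrow(table))
  }
  structure(list(table = table, metadata = metadata, log = log,
                 city = list(config = cfg, addresses = addresses,
                             land_use = land_use, streets = streets,
                             stations = stations)),
            class = "exposure_run")
}

recipe_stat <- function(recipe) {
  switch(recipe, point_density = "density", kernel_density = "kdens",
         entropy = "entropy", land_use_share = "share",
         connectivity = "conn", idw = "idw", walkability = "walk")
}

metadata_sheet <- function(colname, v, radius, year) {
  list(variable = colname,
       source_layer = v$category %||% v$class %||%
         switch(v$recipe, entropy = "land_use", connectivity = "streets",
                idw = "stations", walkability = "multiple", "unknown"),
       year = as.character(year),
       exposure_zone = sprintf("address radius %d m", as.integer(radius)),
       processing = switch(v$recipe,
         point_density = "count of points in buffer / buffer area (km^2)",
         kernel_density = "quartic kernel surface summed at cell centres, sampled at the address cell",
         entropy = "normalised Shannon entropy of 5 land-use class area shares",
         land_use_share = "exact clipped polygon area / buffer area",
         connectivity = "true intersections (>= 3 legs) per km^2 after planarization",
         idw = "inverse-distance-weighted station mean (power decay, search radius)",
         walkability = "sum of 6 component z-scores, min-max rescaled to 0-100"),
       formula_choices = switch(v$recipe,
         entropy = "E = -sum(p_i ln p_i)/ln k over tracked classes",
         idw = sprintf("power %.1f, search radius %g m", v$power %||% 2.0,
                       v$search_radius %||% 110000),
         walkability = "equal component weights; sample (n-1) SD; min-max over run zones",
         "module defaults"),
       units = switch(v$recipe,
         point_density = "per km^2", kernel_density = "per km^2",
         entropy = "dimensionless [0,1]", land_use_share = "share [0,1]",
         connectivity = "intersections per km^2",
         idw = "station units", walkability = "score [0,100]"))
}

#' Aggregate an address-level exposure table to an administrative level
#'
#' Per-unit mean of the address values (`NA` excluded) with a column
#' `n_addresses` counting contributors. Addresses outside every unit are
#' excluded with a warning; units without addresses are absent from the
#' output.
#'
#' @param table address-level exposure data frame (first column
#'   `address_id`).
#' @param addresses the [address_set] the table refers to.
#' @param units an [admin_units] object.
#' @return data frame keyed by `unit_id`.
#' @export
link_level <- function(table, addresses, units) {
  idx <- match(table$address_id, addresses$address_id)
  ax <- addresses$x[idx]; ay <- addresses$y[idx]
  unit_of <- rep(NA_character_, nrow(table))
  for (i in seq_along(units$geoms)) {
    hit <- is.na(unit_of) & points_in_polygon(ax, ay, units$geoms[[i]])
    unit_of[hit] <- units$unit_id[i]
  }
  if (anyNA(unit_of))
    warning(sum(is.na(unit_of)), " address(es) outside all units; excluded")
  keep <- !is.na(unit_of)
  vars <- setdiff(names(table), "address_id")
  split_idx <- split(which(keep), unit_of[keep])
  rows <- lapply(names(split_idx), function(u) {
    sel <- split_idx[[u]]
    means <- vapply(vars, function(vn) {
      v <- table[[vn]][sel]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(unit_id = u, n_addresses = length(sel),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  out[order(out$unit_id), , drop = FALSE]
}

#' Write an exposure table as CSV
#'
#' Deterministic formatting (17 significant digits, `NA` as empty field) so
#' identical runs give byte-identical files.
#'
#' @param table exposure data frame.
#' @param path output CSV path.
#' @export
write_exposure_table <- function(table, path) {
  fmt <- as.data.frame(lapply(table, function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- ""
      out
    } else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write metadata sheets as YAML
#'
#' One YAML document per output column, mirroring the practice of shipping
#' a metadata sheet with every exposure variable.
#'
#' @param metadata the `metadata` element of an `exposure_run`.
#' @param path output YAML path.
#' @export
write_metadata_sheets <- function(metadata, path) {
  yaml::write_yaml(metadata, path)
  invisible(path)
}

#' @export
print.exposure_run <- function(x, ...) {
  cat(sprintf("<exposure_run> %d rows x %d exposure columns\n",
              nrow(x$table), ncol(x$table) - 1L))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
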