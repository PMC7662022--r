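# Domain types and readers/writers for the layer kinds the toolkit consumes:
# categorised points, classified land-use polygons, street networks, rasters,
# administrative units and address sets. Everything lives in one projected
# metric CRS; geographic (lon/lat) input is refused, never reprojected.

# the five land-use classes entering the walkability land-use mix
LAND_USE_CLASSES <- c("residential", "commercial", "social_cultural",
                      "offices_public", "greenspace")

ADMIN_LEVELS <- c("neighbourhood", "PC4", "PC6", "district", "municipality")

GEOGRAPHIC_CRS <- c("EPSG:4326", "CRS84", "OGC:CRS84", "WGS84",
                    "urn:ogc:def:crs:OGC:1.3:CRS84",
                    "urn:ogc:def:crs:EPSG::4326")

stop_if_geographic_crs <- function(crs) {
  if (!is.null(crs) && toupper(crs) %in% toupper(GEOGRAPHIC_CRS)) {
    stop("layer declares a geographic (lon/lat) CRS '", crs,
         "'; exposcape requires planar metre coordinates and does not reproject",
         call. = FALSE)
  }
}

#' Point layer
#'
#' A set of point features with an optional category label and a non-negative
#' weight per point (default 1). Carrier for points of interest, public
#' transport stops, station observations (via the `value` column) and similar
#' xy-coordinate datasets.
#'
#' @param x,y point coordinates in metres (projected CRS).
#' @param category optional character vector of per-point categories.
#' @param weight non-negative numeric weights, recycled to length.
#' @param value optional numeric observation per point (used by stations).
#' @return an object of class `point_layer` (a data frame with columns
#'   `x`, `y`, and optionally `category`, `weight`, `value`).
#' @examples
#' pl <- point_layer(c(10, 20), c(5, 5), category = "supermarket")
#' nrow(pl)
#' @export
point_layer <- function(x, y, category = NULL, weight = 1, value = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && !all(is.finite(x)) || length(y) && !all(is.finite(y)))
    stop("point coordinates must be finite")
  weight <- rep_len(as.numeric(weight), length(x))
  if (any(weight < 0)) stop("point weights must be >= 0")
  df <- data.frame(x = x, y = y, weight = weight)
  if (!is.null(category)) df$category <- rep_len(as.character(category), length(x))
  if (!is.null(value)) df$value <- rep_len(as.numeric(value), length(x))
  class(df) <- c("point_layer", "data.frame")
  df
}

#' Polygon layer with land-use class labels
#'
#' @param geoms list of two-column vertex matrices (simple rings, not closed).
#' @param class_label character vector, one land-use class per polygon.
#' @param classes declared class vocabulary; defaults to the five walkability
#'   land-use classes.
#' @param repair attempt light repair (duplicate/collinear vertex removal)
#'   before validity checking.
#' @return an object of class `polygon_layer`: list with `geoms`,
#'   `class_label`, `area` (m^2, derived) and `classes`.
#' @export
polygon_layer <- function(geoms, class_label,
                          classes = LAND_USE_CLASSES, repair = TRUE) {
  if (length(geoms) != length(class_label))
    stop("one class label per polygon required")
  geoms <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    if (!all(is.finite(g))) stop("polygon coordinates must be finite")
    if (repair) g <- clean_ring(g)
    if (nrow(g) < 3) stop("degenerate polygon (fewer than 3 distinct vertices)")
    ccw(g)
  })
  bad <- which(vapply(geoms, ring_self_intersects, logical(1)))
  if (length(bad))
    stop("invalid (self-intersecting) polygons at positions: ",
         paste(bad, collapse = ", "))
  class_label <- as.character(class_label)
  unknown <- setdiff(unique(class_label), classes)
  if (length(unknown))
    stop("class labels outside declared vocabulary: ",
         paste(unknown, collapse = ", "))
  structure(list(geoms = geoms, class_label = class_label,
                 area = vapply(geoms, poly_area, numeric(1)),
                 classes = classes),
            class = "polygon_layer")
}

#' Street / sidewalk line network
#'
#' @param segments list of two-column polyline vertex matrices (>= 2 vertices).
#' @return an object of class `line_network`.
#' @export
line_network <- function(segments) {
  segments <- lapply(segments, function(s) {
    s <- as.matrix(s)
    if (!all(is.finite(s))) stop("line coordinates must be finite")
    if (nrow(s) < 2) stop("polyline needs at least 2 vertices")
    lens <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
    if (any(lens <= 0)) stop("zero-length segment in polyline")
    s
  })
  structure(list(segments = segments), class = "line_network")
}

#' Administrative units (neighbourhood / postal-code polygons)
#'
#' @param geoms list of polygon vertex matrices.
#' @param unit_id character ids, unique within the level.
#' @param level one of `r paste(ADMIN_LEVELS, collapse = ", ")`.
#' @return an object of class `admin_units`.
#' @export
admin_units <- function(geoms, unit_id, level = "neighbourhood") {
  level <- match.arg(level, ADMIN_LEVELS)
  if (length(geoms) != length(unit_id)) stop("one unit_id per polygon required")
  unit_id <- as.character(unit_id)
  if (anyDuplicated(unit_id)) stop("unit ids must be unique within a level")
  geoms <- lapply(geoms, function(g) {
    g <- ccw(clean_ring(as.matrix(g)))
    if (nrow(g) < 3 || poly_area(g) <= 0) stop("admin unit polygon is empty")
    g
  })
  structure(list(geoms = geoms, unit_id = unit_id, level = level,
                 area = vapply(geoms, poly_area, numeric(1))),
            class = "admin_units")
}

#' Address set
#'
#' @param address_id unique character identifiers.
#' @param x,y coordinates in metres.
#' @param membership optional data frame of per-level unit memberships.
#' @return an object of class `address_set` (data frame with `address_id`,
#'   `x`, `y`).
#' @export
address_set <- function(address_id, x, y, membership = NULL) {
  address_id <- as.character(address_id)
  if (anyDuplicated(address_id)) stop("address ids must be unique")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("address coordinates must be finite")
  df <- data.frame(address_id = address_id, x = x, y = y,
                   stringsAsFactors = FALSE)
  if (!is.null(membership)) df <- cbind(df, membership)
  class(df) <- c("address_set", "data.frame")
  df
}

#' Regular raster grid
#'
#' North-up convention: `origin` is the OUTER top-left corner of cell (1,1),
#' row 1 is the northernmost row, and the centre of cell (r, c) is at
#' `origin + (c - 0.5, -(r - 0.5)) * cell_size`. Cells are half-open: a point
#' on a shared vertical edge belongs to the cell to its east, on a shared
#' horizontal edge to the cell to its south. Missing cells are `NA` in
#' memory and the `nodata` sentinel on disk.
#'
#' @param values numeric matrix, `n_rows` x `n_cols`, row 1 at the top.
#' @param origin numeric length-2: (x, y) of the top-left outer corner.
#' @param cell_size cell side in metres (square cells only).
#' @param nodata sentinel written to Esri ASCII files for `NA` cells.
#' @return an object of class `exp_raster`.
#' @examples
#' r <- exp_raster(matrix(1:16, 4, 4, byrow = TRUE), origin = c(0, 400),
#'                 cell_size = 100)
#' cell_centres(r)[1, ]  # centre of cell (1,1): (50, 350)
#' @export
exp_raster <- function(values, origin, cell_size, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop("origin must be finite (x, y)")
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), nodata = nodata),
            class = "exp_raster")
}

#' @export
dim.exp_raster <- function(x) dim(x$values)

#' @export
print.exp_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<exp_raster> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                             sum(!is.finite(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of every raster cell
#'
#' @param raster an [exp_raster].
#' @return matrix with columns `x`, `y`, `row`, `col`, one row per cell in
#'   row-major order.
#' @export
cell_centres <- function(raster) {
  d <- dim(raster$values)
  cs <- raster$cell_size
  rows <- rep(seq_len(d[1]), each = d[2])
  cols <- rep(seq_len(d[2]), times = d[1])
  cbind(x = raster$origin[1] + (cols - 0.5) * cs,
        y = raster$origin[2] - (rows - 0.5) * cs,
        row = rows, col = cols)
}

#' Raster extent as c(xmin, ymin, xmax, ymax)
#' @param raster an [exp_raster].
#' @export
raster_extent <- function(raster) {
  d <- dim(raster$values)
  c(raster$origin[1], raster$origin[2] - d[1] * raster$cell_size,
    raster$origin[1] + d[2] * raster$cell_size, raster$origin[2])
}

#' Blank raster template covering an extent
#'
#' @param extent c(xmin, ymin, xmax, ymax) in metres.
#' @param cell_size cell side in metres.
#' @param fill initial cell value.
#' @export
raster_template <- function(extent, cell_size, fill = 0) {
  ncol <- max(1L, ceiling((extent[3] - extent[1]) / cell_size - 1e-9))
  nrow <- max(1L, ceiling((extent[4] - extent[2]) / cell_size - 1e-9))
  exp_raster(matrix(fill, nrow, ncol), origin = c(extent[1], extent[4]),
             cell_size = cell_size)
}

# ---- vector layer IO (GeoJSON) ----------------------------------------------

#' Read a vector layer from GeoJSON
#'
#' Coordinates must be planar metres; a file declaring a geographic CRS
#' (EPSG:4326 / CRS84) is refused. Feature properties used: `category` and
#' `weight` for points, `class` for land-use polygons, `unit_id` and `level`
#' for administrative units.
#'
#' @param path GeoJSON file.
#' @param kind one of `"points"`, `"polygons"`, `"lines"`, `"admin"`.
#' @param ... passed to the layer constructor (e.g. `classes`, `level`).
#' @return the matching layer object.
#' @export
read_layer <- function(path, kind = c("points", "polygons", "lines", "admin"),
                       ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("unknown format: expected a GeoJSON FeatureCollection in ", path)
  stop_if_geographic_crs(gj$crs$properties$name)
  feats <- gj$features
  prop <- function(f, name) {
    v <- f$properties[[name]]
    if (is.null(v)) NA else v
  }
  geom_type <- vapply(feats, function(f) f$geometry$type %||% "", character(1))

  if (kind == "points") {
    ok <- geom_type %in% "Point"
    if (!all(ok)) stop("geometry type mismatch: expected Point features")
    xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates)[1:2],
                   numeric(2)))
    if (!length(feats)) return(point_layer(numeric(0), numeric(0)))
    cat_v <- vapply(feats, function(f) as.character(prop(f, "category")), character(1))
    w_v <- vapply(feats, function(f) {
      w <- prop(f, "weight"); if (is.na(w)) 1 else as.numeric(w)
    }, numeric(1))
    val <- vapply(feats, function(f) as.numeric(prop(f, "value")), numeric(1))
    point_layer(xy[, 1], xy[, 2],
                category = if (all(is.na(cat_v))) NULL else cat_v,
                weight = w_v,
                value = if (all(is.na(val))) NULL else val)
  } else if (kind == "lines") {
    ok <- geom_type %in% "LineString"
    if (!all(ok)) stop("geometry type mismatch: expected LineString features")
    segs <- lapply(feats, function(f)
      do.call(rbind, lapply(f$geometry$coordinates, function(c2) unlist(c2)[1:2])))
    line_network(segs)
  } else {
    ok <- geom_type %in% "Polygon"
    if (!all(ok)) stop("geometry type mismatch: expected Polygon features")
    rings <- lapply(feats, function(f)
      do.call(rbind, lapply(f$geometry$coordinates[[1]],
                            function(c2) unlist(c2)[1:2])))
    if (kind == "polygons") {
      cls <- vapply(feats, function(f) as.character(prop(f, "class")), character(1))
      polygon_layer(rings, cls, ...)
    } else {
      ids <- vapply(feats, function(f) as.character(prop(f, "unit_id")), character(1))
      lev <- unique(vapply(feats, function(f) as.character(prop(f, "level")),
                           character(1)))
      lev <- lev[!is.na(lev)]
      admin_units(rings, ids,
                  level = if (length(lev) == 1) lev else "neighbourhood")
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a vector layer to GeoJSON
#'
#' @param layer a `point_layer`, `polygon_layer`, `line_network` or
#'   `admin_units` object.
#' @param path output file.
#' @export
write_layer <- function(layer, path) {
  feat <- function(geometry, properties = NULL) {
    list(type = "Feature",
         properties = if (is.null(properties)) structure(list(), names = character(0)) else properties,
         geometry = geometry)
  }
  close_ring <- function(g) rbind(g, g[1, , drop = FALSE])
  coords_list <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  features <- if (inherits(layer, "point_layer")) {
    lapply(seq_len(nrow(layer)), function(i) {
      p <- list(weight = layer$weight[i])
      if (!is.null(layer$category)) p$category <- layer$category[i]
      if (!is.null(layer$value)) p$value <- layer$value[i]
      feat(list(type = "Point",
                coordinates = c(layer$x[i], layer$y[i])), p)
    })
  } else if (inherits(layer, "polygon_layer")) {
    lapply(seq_along(layer$geoms), function(i)
      feat(list(type = "Polygon",
                coordinates = list(coords_list(close_ring(layer$geoms[[i]])))),
           list(class = layer$class_label[i])))
  } else if (inherits(layer, "line_network")) {
    lapply(layer$segments, function(s)
      feat(list(type = "LineString", coordinates = coords_list(s))))
  } else if (inherits(layer, "admin_units")) {
    lapply(seq_along(layer$geoms), function(i)
      feat(list(type = "Polygon",
                coordinates = list(coords_list(close_ring(layer$geoms[[i]])))),
           list(unit_id = layer$unit_id[i], level = layer$level)))
  } else stop("unsupported layer class: ", paste(class(layer), collapse = "/"))
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- raster IO (Esri ASCII grid) --------------------------------------------

#' Read a raster from an Esri ASCII grid
#'
#' The `.asc` text format is the supported raster container (square cells
#' only). Values equal to the file's `NODATA_value` become `NA`.
#'
#' @param path file path (`.asc`).
#' @return an [exp_raster].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF is not supported; supply an Esri ASCII grid (.asc)")
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("unsupported geometry: non-square raster cells")
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("unknown format: missing Esri ASCII grid header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("value count does not match nrows x ncols in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  # xllcorner/yllcorner give the lower-left corner; convert to top-left origin
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  exp_raster(m, origin = c(xll, yll + nr * hdr$cellsize),
             cell_size = hdr$cellsize, nodata = nodata)
}

#' Write a raster as an Esri ASCII grid
#'
#' Values are written with 17 significant digits so that a write-then-read
#' round trip reproduces the doubles exactly.
#'
#' @param raster an [exp_raster].
#' @param path output file (`.asc`).
#' @export
write_raster <- function(raster, path) {
  d <- dim(raster$values)
  m <- raster$values
  m[!is.finite(m)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.17g", raster$origin[1]),
    sprintf("yllcorner %.17g", raster$origin[2] - d[1] * raster$cell_size),
    sprintf("cellsize %.17g", raster$cell_size),
    sprintf("NODATA_value %g", raster$nodata)), con)
  for (r in seq_len(d[1]))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}

# ---- address sets / stations (CSV) ------------------------------------------

#' Read an address set from CSV (columns address_id, x, y)
#' @param path CSV file.
#' @export
read_addresses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("address_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("address CSV must have columns: ", paste(need, collapse = ", "))
  extra <- df[setdiff(names(df), need)]
  address_set(df$address_id, df$x, df$y,
              membership = if (ncol(extra)) extra else NULL)
}

#' Read station observations from CSV (columns x, y, value)
#' @param path CSV file.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "value") %in% names(df)))
    stop("station CSV must have columns: x, y, value")
  point_layer(df$x, df$y, value = df$value)
}

# ---- direct at-address assignment -------------------------------------------

#' Sample a raster at address locations (direct at-address assignment)
#'
#' Each address receives the value of the cell containing it. Cells are
#' half-open: a point on a shared edge belongs to the cell to its east /
#' south. Addresses outside the raster extent get `NA` and a warning, not an
#' error, because partial-coverage layers are common.
#'
#' @param raster an [exp_raster].
#' @param addresses an [address_set].
#' @return data frame with columns `address_id`, `value`.
#' @export
sample_at_points <- function(raster, addresses) {
  if (!inherits(raster, "exp_raster")) stop("raster must be an exp_raster")
  n <- nrow(addresses)
  if (n == 0)
    return(data.frame(address_id = character(0), value = numeric(0)))
  d <- dim(raster$values)
  cs <- raster$cell_size
  col <- floor((addresses$x - raster$origin[1]) / cs) + 1
  row <- floor((raster$origin[2] - addresses$y) / cs) + 1
  inside <- row >= 1 & row <= d[1] & col >= 1 & col <= d[2]
  out <- rep(NA_real_, n)
  out[inside] <- raster$values[cbind(row[inside], col[inside])]
  if (any(!inside))
    warning(sum(!inside), " address(es) outside raster extent; assigned NA")
  data.frame(address_id = addresses$address_id, value = out,
             stringsAsFactors = FALSE)
}
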