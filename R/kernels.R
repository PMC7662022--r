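# Surface-construction engines: quartic kernel density and inverse-distance-
# weighted interpolation. Both evaluate at raster cell centres in a projected
# metric CRS.

#' Quartic kernel density specification
#'
#' @param radius search radius r in metres. The kernel value falls smoothly
#'   from the point to exactly zero at distance r.
#' @param cell_size output raster cell side in metres; defaults to r / 10.
#'   A warning is issued when `cell_size > radius` (the surface is then
#'   undersampled).
#' @param output_units `"per_m2"` or `"per_km2"` (the per-m^2 density
#'   scaled by exactly 1e6).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(radius, cell_size = radius / 10,
                        output_units = c("per_km2", "per_m2")) {
  output_units <- match.arg(output_units)
  if (!is.numeric(radius) || radius <= 0) stop("search radius must be > 0")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (cell_size > radius)
    warning("cell_size exceeds the search radius; kernel surface undersampled")
  structure(list(radius = radius, cell_size = cell_size,
                 output_units = output_units), class = "kernel_spec")
}

#' Quartic kernel density surface
#'
#' Builds the density surface used for distance-weighted access measures.
#' Each point contributes a radially symmetric quartic (biweight) bump
#' K(d) = 3/(pi r^2) (1 - (d/r)^2)^2 for d < r and exactly 0 beyond; the
#' value of an output cell is the sum of the bumps of all points within r of
#' its centre, times the point weights. The kernel integrates to 1, so a
#' point far from the raster edge contributes total mass equal to its weight
#' (cell sum times cell area). No edge correction is applied: mass of
#' near-boundary points falls partly outside the raster and is lost, as in
#' the moving-window GIS tools this reproduces.
#'
#' @param points a [point_layer]; `weight` scales each point's contribution.
#' @param spec a [kernel_spec].
#' @param grid an [exp_raster] template defining the output geometry, or
#'   NULL to build one covering the points padded by r.
#' @return an [exp_raster] of densities in `spec$output_units`.
#' @examples
#' pts <- point_layer(500, 500)
#' surf <- kernel_density(pts, kernel_spec(250, cell_size = 25),
#'                        grid = raster_template(c(0, 0, 1000, 1000), 25))
#' max(surf$values)  # 3/(pi * 250^2) * 1e6 per km^2 at the point
#' @export
kernel_density <- function(points, spec, grid = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  r <- spec$radius
  if (is.null(grid)) {
    if (nrow(points) == 0) stop("cannot infer a grid from an empty point layer")
    grid <- raster_template(c(min(points$x) - r, min(points$y) - r,
                              max(points$x) + r, max(points$y) + r),
                            spec$cell_size)
  }
  d <- dim(grid$values)
  if (any(d == 0)) stop("empty template grid")
  cs <- grid$cell_size
  vals <- matrix(0, d[1], d[2])
  if (nrow(points) > 0) {
    norm <- 3 / (pi * r^2)
    # per-point window update: only cells within r of the point are touched
    xc <- grid$origin[1] + (seq_len(d[2]) - 0.5) * cs
    yc <- grid$origin[2] - (seq_len(d[1]) - 0.5) * cs
    for (i in seq_len(nrow(points))) {
      px <- points$x[i]; py <- points$y[i]; w <- points$weight[i]
      if (w == 0) next
      c1 <- max(1L, floor((px - r - grid$origin[1]) / cs) + 1L)
      c2 <- min(d[2], ceiling((px + r - grid$origin[1]) / cs))
      r1 <- max(1L, floor((grid$origin[2] - (py + r)) / cs) + 1L)
      r2 <- min(d[1], ceiling((grid$origin[2] - (py - r)) / cs))
      if (c1 > c2 || r1 > r2) next
      dx2 <- (xc[c1:c2] - px)^2
      dy2 <- (yc[r1:r2] - py)^2
      d2 <- outer(dy2, dx2, "+")
      u2 <- d2 / r^2
      contrib <- ifelse(d2 < r^2, w * norm * (1 - u2)^2, 0)
      vals[r1:r2, c1:c2] <- vals[r1:r2, c1:c2] + contrib
    }
  }
  if (spec$output_units == "per_km2") vals <- vals * 1e6
  exp_raster(vals, grid$origin, cs, nodata = grid$nodata)
}

#' Inverse-distance-weighting specification
#'
#' Defaults follow common national-scale station interpolation practice:
#' power 2.0, search radius 110 km, optional 20 km block averaging.
#'
#' @param power distance-decay exponent p > 0.
#' @param search_radius only stations within this distance (metres)
#'   contribute to a cell.
#' @param block_size optional block side in metres: cell-centre predictions
#'   are averaged within non-overlapping blocks aligned to the raster origin
#'   and the block mean is assigned to all member cells.
#' @return an object of class `idw_spec`.
#' @export
idw_spec <- function(power = 2.0, search_radius = 110000, block_size = NULL) {
  if (!is.numeric(power) || power <= 0) stop("power must be > 0")
  if (search_radius <= 0) stop("search_radius must be > 0")
  if (!is.null(block_size) && block_size <= 0) stop("block_size must be > 0")
  structure(list(power = power, search_radius = search_radius,
                 block_size = block_size), class = "idw_spec")
}

#' Inverse-distance-weighted interpolation of station observations
#'
#' Cell value = sum(w_i z_i) / sum(w_i) with w_i = d_i^(-p) over stations at
#' distance 0 < d_i <= search_radius. A cell centre coinciding with a
#' station returns that station's value exactly; cells with no station in
#' radius become `NA`.
#'
#' @param stations a [point_layer] with a `value` column.
#' @param spec an [idw_spec].
#' @param grid an [exp_raster] template.
#' @return an [exp_raster] of interpolated values.
#' @export
idw_interpolate <- function(stations, spec, grid) {
  stopifnot(inherits(spec, "idw_spec"), inherits(grid, "exp_raster"))
  if (nrow(stations) == 0) stop("at least one station is required")
  if (is.null(stations$value) || !all(is.finite(stations$value)))
    stop("stations must carry finite values")
  d <- dim(grid$values)
  cc <- cell_centres(grid)
  pred <- idw_predict(cc[, "x"], cc[, "y"], stations, spec$power,
                      spec$search_radius)
  vals <- matrix(pred, d[1], d[2], byrow = TRUE)
  if (!is.null(spec$block_size)) {
    bs <- spec$block_size
    cs <- grid$cell_size
    rows <- matrix(rep(seq_len(d[1]), each = d[2]), d[1], d[2], byrow = TRUE)
    cols <- matrix(rep(seq_len(d[2]), times = d[1]), d[1], d[2], byrow = TRUE)
    cells_per_block <- max(1L, round(bs / cs))
    bid <- paste((rows - 1L) %/% cells_per_block,
                 (cols - 1L) %/% cells_per_block)
    means <- tapply(as.vector(vals), bid, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    vals <- matrix(means[bid], d[1], d[2])
  }
  exp_raster(vals, grid$origin, grid$cell_size, nodata = grid$nodata)
}

#' IDW prediction at arbitrary locations
#'
#' The point-wise engine behind [idw_interpolate()], exposed so addresses
#' can be predicted directly without building a surface.
#'
#' @param x,y prediction coordinates.
#' @param stations a [point_layer] with a `value` column.
#' @param power decay exponent.
#' @param search_radius neighbourhood radius in metres.
#' @return numeric vector of predictions (`NA` where no station is in range).
#' @export
idw_predict <- function(x, y, stations, power = 2.0, search_radius = 110000) {
  vapply(seq_along(x), function(i) {
    dx <- stations$x - x[i]; dy <- stations$y - y[i]
    dist <- sqrt(dx * dx + dy * dy)
    hit <- which(dist < 1e-9)
    if (length(hit)) return(stations$value[hit[1]])
    use <- dist <= search_radius
    if (!any(use)) return(NA_real_)
    w <- dist[use]^(-power)
    sum(w * stations$value[use]) / sum(w)
  }, numeric(1))
}
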