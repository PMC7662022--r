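# Shared fixtures and independent brute-force oracles. The oracles use
# different algorithms from the package (winding-number containment, naive
# double loops, spreadsheet-style arithmetic) so agreement is evidence, not
# tautology.

# winding-number point-in-polygon, boundary inclusive
oracle_pip <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    ang <- 0
    for (j in seq_len(n)) {
      a <- poly[j, ]; b <- poly[if (j == n) 1 else j + 1, ]
      # boundary: distance to segment
      d <- b - a; len2 <- sum(d^2)
      t <- if (len2 > 0) max(0, min(1, ((x - a[1]) * d[1] + (y - a[2]) * d[2]) / len2)) else 0
      proj <- a + t * d
      if ((x - proj[1])^2 + (y - proj[2])^2 <= eps^2) return(TRUE)
      v1 <- a - c(x, y); v2 <- b - c(x, y)
      ang <- ang + atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
    }
    abs(ang) > pi
  }, logical(1))
}

# naive O(points x cells) quartic kernel density, per m^2
oracle_kernel <- function(points, radius, grid) {
  d <- dim(grid$values)
  cs <- grid$cell_size
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    cx <- grid$origin[1] + (c - 0.5) * cs
    cy <- grid$origin[2] - (r - 0.5) * cs
    acc <- 0
    for (i in seq_len(nrow(points))) {
      di <- sqrt((cx - points$x[i])^2 + (cy - points$y[i])^2)
      if (di < radius)
        acc <- acc + points$weight[i] * 3 / (pi * radius^2) *
          (1 - (di / radius)^2)^2
    }
    out[r, c] <- acc
  }
  out
}

# naive zonal mean over cell centres inside a polygon
oracle_zonal_mean <- function(raster, poly) {
  d <- dim(raster$values)
  cs <- raster$cell_size
  acc <- numeric(0)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    cx <- raster$origin[1] + (c - 0.5) * cs
    cy <- raster$origin[2] - (r - 0.5) * cs
    if (oracle_pip(cx, cy, poly)) {
      v <- raster$values[r, c]
      if (!is.na(v)) acc <- c(acc, v)
    }
  }
  if (length(acc)) mean(acc) else NA_real_
}

# spreadsheet-style walkability: explicit mean/SD/min/max arithmetic
oracle_walkability <- function(components) {
  comp_cols <- setdiff(names(components), "zone_id")
  zsum <- rep(0, nrow(components))
  for (cn in comp_cols) {
    x <- components[[cn]]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    zsum <- zsum + (x - m) / s
  }
  lo <- min(zsum); hi <- max(zsum)
  100 * (zsum - lo) / (hi - lo)
}

# orthogonal crossing grid whose lines extend past the crossings, so every
# crossing is a 4-leg node
crossing_grid <- function(xs, ys, overshoot = 100) {
  segs <- c(lapply(ys, function(y) rbind(c(min(xs) - overshoot, y),
                                         c(max(xs) + overshoot, y))),
            lapply(xs, function(x) rbind(c(x, min(ys) - overshoot),
                                         c(x, max(ys) + overshoot))))
  line_network(segs)
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
}

zone_set_for_test <- function(id, ring) {
  admin_zones(admin_units(list(ring), id, level = "neighbourhood"))
}

# small deterministic city shared across tests
test_city <- function(seed = 42) {
  city_config(extent = c(2000, 2000), street_spacing = 250, n_pois = 50,
              land_use_patch = 250, n_addresses = 25, n_stations = 8,
              seed = seed)
}
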