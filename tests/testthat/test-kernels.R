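test_that("quartic kernel has the analytic peak and compact support", {
  r <- 1000
  # grid aligned so one cell centre coincides with the point
  grid <- raster_template(c(-2000, -2000, 2000, 2000), 100)
  pts <- point_layer(50, 50)  # centre of a cell
  surf <- kernel_density(pts, kernel_spec(r, cell_size = 100), grid)
  cc <- cell_centres(surf)
  vals <- as.vector(t(surf$values))
  d <- sqrt((cc[, "x"] - 50)^2 + (cc[, "y"] - 50)^2)
  # peak at the point: 3/(pi r^2) per m^2 = 0.954930 per km^2
  expect_equal(max(vals), 3 / (pi * r^2) * 1e6, tolerance = 1e-12)
  expect_equal(max(vals), 0.954930, tolerance = 1e-6)
  # exact zero at every cell centre at or beyond the search radius
  expect_true(all(vals[d >= r] == 0))
  expect_true(all(vals[d < r] > 0))
})

test_that("empty and zero-weight inputs give an all-zero surface", {
  grid <- raster_template(c(0, 0, 500, 500), 50)
  surf <- kernel_density(point_layer(numeric(0), numeric(0)),
                         kernel_spec(200), grid)
  expect_true(all(surf$values == 0))
  surf0 <- kernel_density(point_layer(250, 250, weight = 0),
                          kernel_spec(200), grid)
  expect_true(all(surf0$values == 0))
})

test_that("interior-point kernel mass is conserved within 1% at cell r/20", {
  r <- 500
  grid <- raster_template(c(0, 0, 2000, 2000), r / 20)
  surf <- kernel_density(point_layer(1000, 1000, weight = 1),
                         kernel_spec(r, cell_size = r / 20,
                                     output_units = "per_m2"), grid)
  mass <- sum(surf$values) * (r / 20)^2
  expect_lt(abs(mass - 1), 0.01)
  # refines as the cell shrinks
  grid2 <- raster_template(c(0, 0, 2000, 2000), r / 40)
  surf2 <- kernel_density(point_layer(1000, 1000),
                          kernel_spec(r, cell_size = r / 40,
                                      output_units = "per_m2"), grid2)
  expect_lt(abs(sum(surf2$values) * (r / 40)^2 - 1), abs(mass - 1) + 1e-9)
})

test_that("kernel surface is monotone non-increasing away from a point", {
  grid <- raster_template(c(0, 0, 1000, 1000), 20)
  surf <- kernel_density(point_layer(510, 510), kernel_spec(300, 20), grid)
  row <- surf$values[which.max(apply(surf$values, 1, max)), ]
  peak <- which.max(row)
  expect_true(all(diff(row[peak:length(row)]) <= 1e-15))
  expect_true(all(diff(row[1:peak]) >= -1e-15))
})

test_that("superposition: density of a union is the sum of densities", {
  set.seed(21)
  a <- point_layer(runif(10, 0, 1000), runif(10, 0, 1000))
  b <- point_layer(runif(7, 0, 1000), runif(7, 0, 1000))
  ab <- point_layer(c(a$x, b$x), c(a$y, b$y))
  grid <- raster_template(c(0, 0, 1000, 1000), 50)
  spec <- kernel_spec(300, 50)
  expect_equal(kernel_density(ab, spec, grid)$values,
               kernel_density(a, spec, grid)$values +
                 kernel_density(b, spec, grid)$values,
               tolerance = 1e-12)
})

test_that("windowed kernel implementation matches the naive double loop", {
  set.seed(77)
  pts <- point_layer(runif(50, 0, 2000), runif(50, 0, 2000),
                     weight = runif(50, 0.5, 2))
  grid <- raster_template(c(0, 0, 2000, 2000), 50)  # 40 x 40 cells
  spec <- kernel_spec(400, 50, output_units = "per_m2")
  fast <- kernel_density(pts, spec, grid)
  slow <- oracle_kernel(pts, 400, grid)
  expect_lt(max(abs(fast$values - slow)), 1e-10)
})

test_that("kernel and IDW are translation-equivariant", {
  set.seed(3)
  pts <- point_layer(runif(5, 200, 800), runif(5, 200, 800))
  grid <- raster_template(c(0, 0, 1000, 1000), 50)
  spec <- kernel_spec(300, 50)
  base <- kernel_density(pts, spec, grid)
  shift <- c(5000, -3000)
  pts2 <- point_layer(pts$x + shift[1], pts$y + shift[2])
  grid2 <- raster_template(c(shift[1], shift[2], 1000 + shift[1],
                             1000 + shift[2]), 50)
  expect_equal(kernel_density(pts2, spec, grid2)$values, base$values,
               tolerance = 1e-12)

  st <- point_layer(runif(4, 0, 1000), runif(4, 0, 1000), value = rnorm(4, 10))
  ispec <- idw_spec(2, 5000)
  ibase <- idw_interpolate(st, ispec, grid)
  st2 <- point_layer(st$x + shift[1], st$y + shift[2], value = st$value)
  expect_equal(idw_interpolate(st2, ispec, grid2)$values, ibase$values,
               tolerance = 1e-9)
})

test_that("IDW reproduces the hand-evaluated two-station value", {
  st <- point_layer(c(1000, 2000), c(0, 0), value = c(10, 20))
  # at the origin: (10 * 1e-6 + 20 * 0.25e-6) / 1.25e-6 = 12
  expect_equal(idw_predict(0, 0, st, power = 2, search_radius = 1e6), 12.0)
})

test_that("IDW exact-hit, constant-field and range-bound rules hold", {
  st <- point_layer(c(0, 500, 900), c(0, 100, 800),
                    value = c(12.5, 30, 18))
  expect_equal(idw_predict(0, 0, st, 2, 1e5), 12.5)  # exact hit short-circuit

  const <- point_layer(st$x, st$y, value = rep(7.25, 3))
  grid <- raster_template(c(0, 0, 1000, 1000), 100)
  surf <- idw_interpolate(const, idw_spec(2, 1e5), grid)
  expect_equal(max(abs(surf$values - 7.25)), 0, tolerance = 1e-12)

  surf2 <- idw_interpolate(st, idw_spec(2, 1e5), grid)
  expect_true(all(surf2$values >= min(st$value) - 1e-12))
  expect_true(all(surf2$values <= max(st$value) + 1e-12))

  # out-of-radius cells are NA; no stations at all is an error
  far <- idw_interpolate(st, idw_spec(2, 50), grid)
  expect_true(anyNA(far$values))
  expect_error(idw_interpolate(point_layer(numeric(0), numeric(0)),
                               idw_spec(), grid), "station")
})

test_that("block averaging assigns the block mean to all member cells", {
  st <- point_layer(c(100, 900), c(500, 500), value = c(0, 10))
  grid <- raster_template(c(0, 0, 1000, 1000), 100)
  plain <- idw_interpolate(st, idw_spec(2, 1e5), grid)
  blocked <- idw_interpolate(st, idw_spec(2, 1e5, block_size = 500), grid)
  # 2 x 2 blocks of 5 x 5 cells; each block is constant
  for (br in 0:1) for (bc in 0:1) {
    rows <- br * 5 + 1:5; cols <- bc * 5 + 1:5
    block <- blocked$values[rows, cols]
    expect_equal(max(block) - min(block), 0)
    expect_equal(block[1, 1], mean(plain$values[rows, cols]))
  }
})

test_that("kernel and IDW specs validate their parameters", {
  expect_error(kernel_spec(-5), "> 0")
  expect_warning(kernel_spec(100, cell_size = 500), "undersampled")
  expect_error(idw_spec(power = 0), "> 0")
  expect_error(kernel_density(point_layer(1, 1), kernel_spec(100),
                              exp_raster(matrix(numeric(0), 0, 0), c(0, 0), 10)),
               "empty")
})
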