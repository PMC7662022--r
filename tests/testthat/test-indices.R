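test_that("entropy attains its analytic limits", {
  expect_equal(entropy_mix(c(1, 0, 0, 0, 0)), 0)
  expect_equal(entropy_mix(rep(0.2, 5)), 1.0)
  expect_equal(entropy_mix(c(0.5, 0.5, 0, 0, 0)), log(2) / log(5))
  expect_equal(entropy_mix(c(0.5, 0.5, 0, 0, 0)), 0.430677, tolerance = 1e-5)
  # shares are renormalised over the tracked classes
  expect_equal(entropy_mix(c(3, 3, 0, 0, 0)), log(2) / log(5))
  expect_true(is.na(entropy_mix(rep(0, 5))))
  expect_error(entropy_mix(0.5, k = 1), "at least 2")
  expect_error(entropy_mix(c(-0.1, 0.5)), ">= 0")
})

test_that("entropy is permutation-invariant and maximal only at equal shares", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(5)
    expect_equal(entropy_mix(p), entropy_mix(sample(p)))
    expect_lte(entropy_mix(p), 1)
    expect_gte(entropy_mix(p), 0)
    if (max(p) / sum(p) - 0.2 > 1e-6) expect_lt(entropy_mix(p), 1)
  }
})

test_that("true intersections need three or more legs", {
  # a single straight street: no junctions
  one <- line_network(list(rbind(c(0, 0), c(1000, 0))))
  km2 <- rect_ring(-500, -500, 500, 500)
  expect_equal(street_connectivity(one, km2), 0)

  # a right-angle bend of one street: 2 legs, not an intersection
  bend <- line_network(list(rbind(c(0, 0), c(500, 0), c(500, 500))))
  expect_equal(street_connectivity(bend, km2), 0)

  # a T-junction: 3 legs, counts
  tee <- line_network(list(rbind(c(-400, 0), c(400, 0)),
                           rbind(c(0, 0), c(0, 400))))
  expect_equal(street_connectivity(tee, km2), 1)

  # empty network
  expect_equal(street_connectivity(line_network(list()), km2), 0)
})

test_that("a 3x3 crossing grid in 1 km^2 yields 9 intersections per km^2", {
  net <- crossing_grid(xs = c(250, 500, 750), ys = c(250, 500, 750))
  zone <- rect_ring(0, 0, 1000, 1000)
  expect_equal(street_connectivity(net, zone), 9)
  xi <- true_intersections(net)
  expect_equal(nrow(xi), 9)
  expect_true(all(xi[, "legs"] == 4))
})

test_that("crossings without a shared vertex are found by planarization", {
  # two through-streets crossing mid-segment: one 4-leg node
  net <- line_network(list(rbind(c(0, 500), c(1000, 500)),
                           rbind(c(500, 0), c(500, 1000))))
  xi <- true_intersections(net)
  expect_equal(nrow(xi), 1)
  expect_equal(unname(xi[1, "legs"]), 4)
  expect_equal(unname(xi[1, 1:2]), c(500, 500))
})

test_that("connectivity is invariant under translation and rotation", {
  net <- crossing_grid(xs = c(300, 600), ys = c(300, 600))
  zone <- rect_ring(100, 100, 900, 900)
  base <- street_connectivity(net, zone)
  expect_equal(base, 4 / 0.64)

  shift <- c(12345, -6789)
  net_t <- line_network(lapply(net$segments, function(s)
    cbind(s[, 1] + shift[1], s[, 2] + shift[2])))
  zone_t <- cbind(zone[, 1] + shift[1], zone[, 2] + shift[2])
  expect_equal(street_connectivity(net_t, zone_t), base)

  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  net_r <- line_network(lapply(net$segments, function(s) s %*% t(R)))
  zone_r <- zone %*% t(R)
  expect_equal(street_connectivity(net_r, zone_r), base)
})

test_that("z-scores standardise with the sample (n-1) SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(30, 50, 9)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(4, 10), name = "flat"), "flat")
  expect_error(zscore(1), "at least 2")
  # NA propagates without poisoning the reference statistics
  z2 <- zscore(c(1, 2, 3, NA))
  expect_true(is.na(z2[4]))
  expect_equal(z2[1:3], c(-1, 0, 1))
})

test_that("two-zone walkability maps exactly to 0 and 100", {
  comp <- data.frame(zone_id = c("a", "b"),
                     population_density = c(10, 20),
                     retail_service_density = c(1, 3),
                     land_use_mix = c(0.2, 0.9),
                     street_connectivity = c(5, 30),
                     green_space_density = c(0.5, 0.1),
                     sidewalk_density = c(1000, 4000))
  w <- walkability(comp)
  expect_setequal(w$score, c(0, 100))
})

test_that("a zone at the component-wise mean has raw_sum 0", {
  set.seed(10)
  comp <- data.frame(zone_id = sprintf("z%d", 1:4),
                     population_density = c(10, 20, 30, 20),
                     retail_service_density = c(0, 4, 8, 4),
                     land_use_mix = c(0.1, 0.5, 0.9, 0.5),
                     street_connectivity = c(0, 10, 20, 10),
                     green_space_density = c(0.9, 0.5, 0.1, 0.5),
                     sidewalk_density = c(1, 2, 3, 2))
  w <- walkability(comp)
  # zone 4 sits at the mean of every component
  expect_equal(w$raw_sum[4], 0, tolerance = 1e-12)
})

test_that("25-zone walkability matches the spreadsheet oracle to 1e-10", {
  set.seed(99)
  comp <- data.frame(zone_id = sprintf("z%02d", 1:25),
                     population_density = rlnorm(25, 6, 1),
                     retail_service_density = rlnorm(25, 2, 0.8),
                     land_use_mix = runif(25),
                     street_connectivity = rlnorm(25, 3, 0.5),
                     green_space_density = runif(25),
                     sidewalk_density = rlnorm(25, 8, 0.6))
  w <- walkability(comp)
  expect_lt(max(abs(w$score - oracle_walkability(comp))), 1e-10)
  expect_true(all(w$score >= 0 & w$score <= 100))
  expect_equal(min(w$score), 0)
  expect_equal(max(w$score), 100)
})

test_that("walkability is shift-invariant and componentwise monotone", {
  set.seed(6)
  comp <- data.frame(zone_id = sprintf("z%d", 1:10),
                     population_density = runif(10, 10, 100),
                     retail_service_density = runif(10, 0, 10),
                     land_use_mix = runif(10),
                     street_connectivity = runif(10, 0, 50),
                     green_space_density = runif(10),
                     sidewalk_density = runif(10, 500, 5000))
  base <- walkability(comp)
  shifted <- comp
  shifted$street_connectivity <- shifted$street_connectivity + 1000
  expect_equal(walkability(shifted)$score, base$score, tolerance = 1e-9)

  bumped <- comp
  bumped$retail_service_density[3] <- bumped$retail_service_density[3] + 5
  expect_gte(walkability(bumped)$score[3], base$score[3] - 1e-9)
})

test_that("walkability rejects incomplete or degenerate component tables", {
  comp <- data.frame(zone_id = c("a", "b"), population_density = c(1, 2))
  expect_error(walkability(comp), "missing walkability components")
  full <- data.frame(zone_id = c("a", "b"),
                     population_density = c(1, 1),
                     retail_service_density = c(2, 2),
                     land_use_mix = c(0.5, 0.5),
                     street_connectivity = c(3, 3),
                     green_space_density = c(0.2, 0.2),
                     sidewalk_density = c(4, 4))
  expect_error(walkability(full), "constant")
  # a zone missing one component value gets NA score, others still scored
  part <- full
  part$population_density <- c(1, 2)
  part$retail_service_density <- c(2, 5)
  part$land_use_mix <- c(0.1, 0.9)
  part$street_connectivity <- c(1, 8)
  part$green_space_density <- c(0.7, 0.2)
  part$sidewalk_density <- c(9, 3)
  part <- rbind(part, data.frame(zone_id = "c", population_density = 3,
                                 retail_service_density = NA,
                                 land_use_mix = 0.5, street_connectivity = 4,
                                 green_space_density = 0.4,
                                 sidewalk_density = 6))
  w <- walkability(part)
  expect_true(is.na(w$score[3]))
  expect_false(anyNA(w$score[1:2]))
})
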