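test_that("cleaning rules flag the documented record types", {
  pts <- tibble::tibble(
    latitude = c(55, 23.5, 55.7, 40.123, 12.5, 41.9),
    longitude = c(12, 23.5, 12.6, -3.456, 77, 12.49))
  cfg <- occ_clean_config(
    capitals = data.frame(latitude = 41.9028, longitude = 12.4964))
  out <- clean_occurrences(pts, cfg)
  flags <- setNames(out$flagged$flag, round(out$flagged$latitude, 3))
  expect_equal(unname(flags["55"]), "no_decimal")
  expect_equal(unname(flags["23.5"]), "lat_eq_lon")
  expect_equal(unname(flags["55.7"]), "hq_radius")
  expect_equal(unname(flags["41.9"]), "capital_radius")
  # one integer coordinate alone is enough for the no-decimal rule
  expect_equal(unname(flags["12.5"]), "no_decimal")
  expect_equal(out$clean$latitude, 40.123)
})

test_that("cleaning is idempotent", {
  occ <- simulate_occurrences(c(-20, 130), 3, 300, dirty_fraction = 0.3,
                              seed = 5)
  once <- clean_occurrences(occ)
  twice <- clean_occurrences(once$clean)
  expect_equal(nrow(twice$flagged), 0)
  expect_equal(twice$clean, once$clean)
})

test_that("every injected dirty record is flagged", {
  occ <- simulate_occurrences(c(40, -3), 2, 500, dirty_fraction = 0.2,
                              seed = 6)
  out <- clean_occurrences(occ)
  dirty <- occ[!is.na(occ$dirty_type), ]
  expect_equal(nrow(dirty), 100)
  key <- function(d) paste(d$latitude, d$longitude)
  expect_true(all(key(dirty) %in% key(out$flagged)))
  # a fully clean cloud loses nothing
  occ0 <- simulate_occurrences(c(40, -3), 2, 200, dirty_fraction = 0,
                               seed = 7)
  expect_equal(nrow(clean_occurrences(occ0)$flagged), 0)
})

test_that("quantile trimming keeps the central band, boundary inclusive", {
  pts <- tibble::tibble(latitude = 1:100, longitude = rep(5.5, 100))
  kept <- quantile_trim(pts)
  qs <- quantile(1:100, c(0.02, 0.98))  # type-7 linear interpolation
  expect_equal(kept$latitude, seq(ceiling(qs[1]), floor(qs[2])))
  expect_equal(nrow(kept), 96)
  same <- tibble::tibble(latitude = rep(3.3, 8), longitude = rep(2.2, 8))
  expect_equal(nrow(quantile_trim(same)), 8)
  expect_equal(nrow(quantile_trim(pts, 0, 1)), 100)
  expect_error(quantile_trim(pts[1:4, ]), "at least 5")
})

test_that("hull area matches the spherical-excess oracle", {
  sq <- tibble::tibble(latitude = c(0, 0, 1, 1), longitude = c(0, 1, 0, 1))
  a <- hull_area_km2(sq)
  oracle <- spherical_polygon_area_km2(c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_lt(abs(a - oracle) / oracle, 0.005)
  expect_equal(a, 1.236e4, tolerance = 0.005)
  # small equatorial hulls match the planar degree-area conversion
  tri <- tibble::tibble(latitude = c(0, 0.2, 0.1),
                        longitude = c(0, 0, 0.25))
  planar <- 0.5 * 0.2 * 0.25 * 111.1949^2
  expect_lt(abs(hull_area_km2(tri) - planar) / planar, 0.01)
})

test_that("hull area is order/duplicate-invariant and hull-monotone", {
  set.seed(9)
  pts <- tibble::tibble(latitude = runif(20, 10, 12),
                        longitude = runif(20, 40, 42))
  a1 <- hull_area_km2(pts)
  a2 <- hull_area_km2(pts[sample(20), ])
  expect_equal(a1, a2, tolerance = 1e-10)
  a3 <- hull_area_km2(dplyr::bind_rows(pts, pts[1:5, ]))
  expect_equal(a1, a3, tolerance = 1e-10)
  # interior points do not change the hull
  inner <- tibble::tibble(latitude = rep(11, 3), longitude = rep(41, 3))
  expect_equal(hull_area_km2(dplyr::bind_rows(pts, inner)), a1,
               tolerance = 1e-10)
  # adding an exterior point can only grow the area
  outer <- tibble::tibble(latitude = 13, longitude = 43)
  expect_gte(hull_area_km2(dplyr::bind_rows(pts, outer)), a1)
})

test_that("degenerate hulls raise errors", {
  col <- tibble::tibble(latitude = c(1, 2, 3), longitude = c(1, 2, 3))
  expect_error(hull_area_km2(col), "collinear|degenerate")
  expect_error(hull_area_km2(col[1:2, ]), "3 distinct")
  wide <- tibble::tibble(latitude = c(0, 1, 0), longitude = c(-179, 0, 179))
  expect_error(hull_area_km2(wide), "antimeridian")
})

test_that("mean population size respects the count-unit rule", {
  expect_equal(mean_population_size(c(10, 20, 30), "number of individuals"),
               20)
  expect_true(is.na(mean_population_size(c(1, 2), "index")))
  expect_equal(mean_population_size(7, "pairs"), 7)
})

test_that("habitat specificity counts distinct categories", {
  expect_equal(habitat_specificity(c("forest", "forest", "wetland")), 2)
  expect_equal(habitat_specificity("forest"), 1)
  expect_equal(habitat_specificity(letters[1:9]), 9)
  expect_true(is.na(habitat_specificity(character(0))))
})

test_that("independently generated rarity metrics are weakly correlated", {
  set.seed(30)
  n_sp <- 200
  ranges <- exp(rnorm(n_sp, 10, 1))
  pops <- exp(rnorm(n_sp, 4, 1))
  habs <- sample(1:10, n_sp, replace = TRUE)
  cors <- abs(c(cor(log(ranges), log(pops)),
                cor(log(ranges), habs),
                cor(log(pops), habs)))
  expect_true(all(cors < 0.2))
})

test_that("the per-species driver assembles all three metrics", {
  occ <- dplyr::bind_rows(
    simulate_occurrences(c(45, 10), 1.5, 120, seed = 11, species = "A b"),
    simulate_occurrences(c(-10, 60), 0.8, 80, seed = 12, species = "C d"))
  meta <- tibble::tibble(series_id = c("s1", "s2"),
                         species = c("A b", "C d"),
                         unit = c("number of individuals", "index"))
  obs <- dplyr::bind_rows(
    tibble::tibble(series_id = "s1", year = 2001:2005,
                   abundance = c(10, 20, 30, 40, 50)),
    tibble::tibble(series_id = "s2", year = 2001:2005,
                   abundance = 1:5))
  coll <- pop_collection(meta, obs)
  habs <- tibble::tibble(species = c("A b", "A b", "C d"),
                         habitat = c("forest", "wetland", "forest"))
  rm <- rarity_metrics(occ, coll, habs)
  expect_equal(nrow(rm), 2)
  expect_true(all(rm$range_km2 > 0))
  expect_equal(rm$mean_pop_size[rm$species == "A b"], 30)
  expect_true(is.na(rm$mean_pop_size[rm$species == "C d"]))
  expect_equal(rm$habitat_specificity, c(2, 1))
})
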