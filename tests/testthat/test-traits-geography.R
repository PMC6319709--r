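test_that("derived traits follow their defining formulas and are idempotent", {
  raw <- data.frame(
    HS_start = c(10, 20), HS_end = c(15, 10),
    dry_mass = c(0.2, 0.5), fresh_mass = c(1, 2),
    AGBM = c(5, 2), BGBM = c(2.5, 3),
    AG_C = c(42, 40), AG_N_pct = c(1.4, 2),
    BG_C = c(30, 45), BG_N_pct = c(1.5, 1.5),
    root_before_1 = c(10, 8), root_after_1 = c(12.5, 10),
    root_before_2 = c(10, 8), root_after_2 = c(12.5, 10),
    root_before_3 = c(10, 8), root_after_3 = c(12.5, 10))
  d <- derive_traits(raw)
  expect_equal(d$RGR, c(0.5, -0.5))
  expect_equal(d$LDMC, c(0.2, 0.25))
  expect_equal(d$root_shoot, c(0.5, 1.5))
  expect_equal(d$AG_CN, c(30, 20))
  expect_equal(d$BG_CN, c(20, 30))
  expect_equal(d$AG_N, c(1.4 / 100 * 5, 2 / 100 * 2))
  expect_equal(d$POR, c(2.5 / 12.5, 2 / 10))
  expect_identical(derive_traits(d), d)        # idempotent
  # k_specific rescales porosity linearly
  expect_equal(derive_traits(raw, k_specific = 2)$POR, 2 * d$POR)
})

test_that("zero denominators give NA with a warning, not an error", {
  raw <- data.frame(HS_start = c(0, 10), HS_end = c(5, 20))
  expect_warning(d <- derive_traits(raw), "zero denominator")
  expect_true(is.na(d$RGR[1]))
  expect_equal(d$RGR[2], 1)
})

test_that("seed volume is a prolate spheroid with the expected limits", {
  expect_equal(seed_volume(2, 2), 4 / 3 * pi)          # sphere
  expect_equal(seed_volume(2, 1), 4 / 3 * pi * 0.25)
  expect_equal(seed_volume(4, 2), 8 * seed_volume(2, 1))  # cube scaling
  expect_error(seed_volume(0, 1), "positive")
})

test_that("geodesic distances have analytic values and metric structure", {
  eq <- data.frame(population_id = c("a", "b"),
                   latitude = c(0, 0), longitude = c(0, 1))
  d <- geodesic_distance_matrix(eq)
  expect_equal(d["a", "b"], 2 * pi * 6371.0088 / 360, tolerance = 1e-6)
  same <- data.frame(population_id = c("x", "y"),
                     latitude = c(51.2, 51.2), longitude = c(12, 12))
  expect_equal(geodesic_distance_matrix(same)["x", "y"], 0)
  # property: symmetry, zero diagonal, triangle inequality
  set.seed(42)
  for (rep in 1:3) {
    m <- data.frame(population_id = paste0("p", 1:6),
                    latitude = runif(6, -80, 80),
                    longitude = runif(6, -179, 179))
    D <- geodesic_distance_matrix(m)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 6))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
  miss <- data.frame(population_id = c("a", "b", "c"),
                     latitude = c(0, NA, 1), longitude = c(0, 5, 1))
  expect_warning(D2 <- geodesic_distance_matrix(miss), "missing coordinates")
  expect_equal(rownames(D2), c("a", "c"))
})

test_that("soil aggregation averages points in a closed 15 km ball", {
  meta <- data.frame(population_id = "P", latitude = 51, longitude = 12)
  # ~1 km north, ~5 km north, and a third point whose exact haversine
  # distance (independent oracle) is used as the radius: closed-ball
  # semantics must include it
  km_per_deg <- 2 * pi * 6371.0088 / 360
  pts <- data.frame(latitude = 51 + c(1, 5, 15) / km_per_deg,
                    longitude = 12, ph = c(1, 2, 3), oc = c(4, 5, 6))
  d3 <- geosphere::distHaversine(c(12, 51), c(12, pts$latitude[3]),
                                 r = 6371008.8) / 1000
  agg <- aggregate_soil(pts, meta, radius_km = d3)
  expect_equal(agg$n_points, 3L)              # boundary point included
  expect_equal(agg$ph, 2); expect_equal(agg$oc, 5)
  inner <- aggregate_soil(pts, meta, radius_km = d3 * (1 - 1e-9))
  expect_equal(inner$n_points, 2L)            # just inside the boundary
  one <- aggregate_soil(pts[1, ], meta)
  expect_equal(one$ph, 1)                     # single point verbatim
  far <- data.frame(latitude = 52, longitude = 12, ph = 9, oc = 9)
  expect_warning(none <- aggregate_soil(far, meta), "no soil points")
  expect_true(is.na(none$ph))
})
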