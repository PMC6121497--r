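test_that("NDVI follows its defining ratio", {
  mk <- function(v) grid_create(matrix(v, 1, 1), 30)
  expect_equal(compute_ndvi(mk(0.1), mk(0.5))$values[1, 1], 2 / 3)
  expect_equal(compute_ndvi(mk(0.3), mk(0.3))$values[1, 1], 0)
  expect_equal(compute_ndvi(mk(0.5), mk(0.1))$values[1, 1], -2 / 3)
  expect_true(is.na(compute_ndvi(mk(0), mk(0))$values[1, 1]))
  expect_error(compute_ndvi(grid_create(matrix(0, 2, 2), 30),
                            grid_create(matrix(0, 2, 3), 30)))
})

test_that("Horn slope is exact on flats and planes", {
  flat <- compute_slope(grid_create(matrix(7, 5, 5), 30))
  expect_equal(flat$values, matrix(0, 5, 5))

  # plane rising 30 m per 30 m cell eastwards: 45 degrees in the interior
  plane <- grid_create(matrix(rep((0:5) * 30, each = 4), 4, 6), 30)
  sl <- compute_slope(plane)
  expect_equal(sl$values[2:3, 2:5], matrix(45, 2, 4))

  # interior cells of a random surface match direct stencil arithmetic
  set.seed(9)
  z <- matrix(stats::runif(49, 0, 20), 7, 7)
  got <- compute_slope(grid_create(z, 30))$values
  for (r in 2:6) for (c in 2:6) {
    dzdx <- ((z[r - 1, c + 1] + 2 * z[r, c + 1] + z[r + 1, c + 1]) -
             (z[r - 1, c - 1] + 2 * z[r, c - 1] + z[r + 1, c - 1])) / 240
    dzdy <- ((z[r - 1, c - 1] + 2 * z[r - 1, c] + z[r - 1, c + 1]) -
             (z[r + 1, c - 1] + 2 * z[r + 1, c] + z[r + 1, c + 1])) / 240
    expect_equal(got[r, c], atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
  }
})

test_that("factor classification picks the covering class", {
  tab <- default_coefficients()
  p600 <- classify_factor(tab, "R", 600)
  expect_equal(p600$coef, 1)       # the standard-farmland band
  expect_match(p600$label, "400")

  s30 <- classify_factor(tab, "P", 30)
  expect_equal(s30$label, "[25,Inf)")
  expect_gte(s30$coef, 1)

  far <- classify_factor(tab, "D", 25000)
  expect_equal(far$coef, 0)

  expect_equal(classify_factor(tab, "L", "cultivated")$coef, 1)
  expect_error(classify_factor(tab, "S", "peat"), "matches 0 classes")
})

test_that("distance decay is linear with the 20 km cap", {
  expect_equal(distance_coefficient(0), 1)
  expect_equal(distance_coefficient(20000), 0)
  expect_equal(distance_coefficient(10000), 0.5)
  expect_equal(distance_coefficient(25000), 0)
  d <- seq(0, 20000, by = 500)
  expect_true(all(diff(distance_coefficient(d)) < 0))
  expect_error(distance_coefficient(-1), "non-negative")
})

test_that("coefficient tables round-trip through YAML and are validated", {
  tab <- default_coefficients()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(tab, tmp)
  back <- read_coefficients(tmp)
  expect_equal(back$factors, tab$factors)
  expect_equal(back$distance_cap_m, tab$distance_cap_m)

  # gap in the interval cover is rejected
  bad <- tab
  bad$factors$TN$R$min[2] <- 500
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(bad, tmp2)
  expect_error(read_coefficients(tmp2), "cover")

  # a factor without a baseline class is rejected
  bad2 <- tab
  bad2$factors$TN$P$coef <- c(0.9, 1.2)
  tmp3 <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(bad2, tmp3)
  expect_error(read_coefficients(tmp3), "baseline")
})

test_that("weights compose multiplicatively with annihilating zeros", {
  fv <- tibble::tibble(
    hru_id = 1:3, subbasin_id = 1L, area_ha = 1,
    landuse_group = c("cultivated", "cultivated", "cultivated"),
    slope_deg = c(5, 30, 5), precip_mm = 600, ndvi = 0,
    distance_m = c(0, 10000, 25000), fertilizer_kgha = 450,
    soil_texture = "loam", soil_moisture = "medium"
  )
  w <- hru_weights(fv, default_coefficients(), "TN")
  expect_equal(w$w_raw[1], 1)                # all-baseline product
  expect_equal(w$w_raw[2], 1.2 * 0.5)        # slope class x half distance
  expect_equal(w$w_raw[3], 0)                # beyond the distance cap
})

test_that("weights respond monotonically to the inhibiting factors", {
  base <- tibble::tibble(
    hru_id = 1L, subbasin_id = 1L, area_ha = 1,
    landuse_group = "cultivated", slope_deg = 5, precip_mm = 600,
    ndvi = 0, distance_m = 0, fertilizer_kgha = 450,
    soil_texture = "loam", soil_moisture = "medium"
  )
  tab <- default_coefficients()
  w_of <- function(fv) hru_weights(fv, tab, "TN")$w_raw

  ndvi_seq <- seq(-0.5, 1, by = 0.1)
  w_ndvi <- vapply(ndvi_seq, function(n) {
    w_of(dplyr::mutate(base, ndvi = n))
  }, numeric(1))
  expect_true(all(diff(w_ndvi) <= 1e-12))

  dist_seq <- seq(0, 25000, by = 1000)
  w_dist <- vapply(dist_seq, function(d) {
    w_of(dplyr::mutate(base, distance_m = d))
  }, numeric(1))
  expect_true(all(diff(w_dist) <= 1e-12))

  expect_gte(w_of(dplyr::mutate(base, fertilizer_kgha = 600)), w_of(base))

  # land-use ordering encoded in the defaults
  w_lu <- vapply(c("cultivated", "orchard", "other", "forest"), function(g) {
    w_of(dplyr::mutate(base, landuse_group = g))
  }, numeric(1))
  expect_true(all(diff(w_lu) < 0))
})

test_that("normalization scales to a unit maximum and is scale invariant", {
  expect_equal(normalize_weights(c(2, 4)), c(0.5, 1))
  expect_equal(normalize_weights(5), 1)
  set.seed(4)
  w <- stats::runif(20)
  expect_equal(normalize_weights(w), normalize_weights(w * 37.5))
  expect_equal(max(normalize_weights(w)), 1)
  expect_equal(which.max(normalize_weights(w)), which.max(w))
  expect_error(normalize_weights(c(0, 0)), "zero")
})

test_that("per-HRU factor aggregation is the mean over member cells", {
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  hrus <- structure(list(
    labels = labels,
    table = tibble::tibble(hru_id = 1:2, subbasin_id = 1L,
                           landuse_code = c(3L, 1L), soil_code = 2L,
                           ncell = 2L, area_m2 = 1800, area_ha = 0.18),
    cell_size = 30,
    landuse_legend = LANDUSE_LEGEND
  ), class = "lci_hrus")
  mk <- function(v) grid_create(matrix(v, 2, 2), 30)
  soil <- catgrid_create(matrix(2L, 2, 2), 30,
                         c(sandy = 1L, loam = 2L, clay = 3L))
  fv <- hru_factor_values(
    hrus,
    list(slope = mk(c(1, 3, 5, 7)), precip = mk(c(500, 700, 600, 600)),
         ndvi = mk(0.2), distance = mk(100), fertilizer = mk(450)),
    soil = soil
  )
  expect_equal(fv$precip_mm, c(600, 600))
  expect_equal(fv$slope_deg, c(2, 6))
  expect_equal(fv$landuse_group, c("cultivated", "forest"))
  expect_equal(fv$soil_moisture, c("medium", "medium"))
})
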