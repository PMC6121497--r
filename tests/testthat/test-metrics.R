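legend3 <- c(a = 1L, b = 2L, c = 3L)

test_that("patch labelling follows the declared connectivity", {
  g <- catgrid_create(matrix(c(1, 1, 2, 1, 2, 2, 3, 3, 3), 3, byrow = TRUE),
                      30, legend3)
  ps <- label_patches(g, 4)
  expect_equal(sort(ps$patches$ncell), c(3, 3, 3))
  expect_equal(nrow(ps$patches), 3)

  uni <- catgrid_create(matrix(1L, 5, 5), 30, c(a = 1L))
  expect_equal(nrow(label_patches(uni, 8)$patches), 1)

  diag2 <- catgrid_create(matrix(c(1L, 2L, 2L, 1L), 2, 2), 30, legend3[1:2])
  expect_equal(nrow(label_patches(diag2, 4)$patches), 4)
  expect_equal(nrow(label_patches(diag2, 8)$patches), 2)
})

test_that("patch areas and perimeters match direct edge enumeration", {
  one <- catgrid_create(matrix(c(1L, 2L, 2L, 2L), 2, 2), 30, legend3[1:2])
  geom <- patch_geometry(label_patches(one, 8))
  expect_equal(geom$area_m2[geom$class_code == 1], 900)
  expect_equal(geom$perimeter_m[geom$class_code == 1], 120)

  sq <- catgrid_create(rbind(c(2L, 2L, 2L, 2L),
                             c(2L, 1L, 1L, 2L),
                             c(2L, 1L, 1L, 2L),
                             c(2L, 2L, 2L, 2L)), 30, legend3[1:2])
  geom2 <- patch_geometry(label_patches(sq, 8))
  expect_equal(geom2$area_m2[geom2$class_code == 1], 3600)
  expect_equal(geom2$perimeter_m[geom2$class_code == 1], 240)

  for (seed in 1:6) {
    g <- random_catgrid(seed, 10, 10, 3, p_na = 0.1)
    ps <- label_patches(g, 8)
    geom <- patch_geometry(ps)
    per <- oracle_perimeters(g$values, oracle_label(g$values, 8), 30)
    expect_equal(sort(unname(geom$perimeter_m)), sort(unname(per)))
  }
})

test_that("patches partition the non-nodata area", {
  for (seed in 1:5) {
    g <- random_catgrid(seed + 100, 12, 9, 4, p_na = 0.15)
    ps <- label_patches(g, 8)
    expect_equal(sum(ps$patches$ncell), sum(!is.na(g$values)))
    expect_identical(is.na(ps$labels), is.na(g$values))
  }
})

test_that("composition metrics follow their definitions", {
  uni <- catgrid_create(matrix(1L, 5, 5), 30, c(a = 1L))
  comp <- np_pd_lpi(label_patches(uni))
  expect_equal(comp$np, 1)
  expect_equal(comp$lpi, 100)

  g <- catgrid_create(matrix(c(1, 1, 2, 1, 2, 2, 3, 3, 3), 3, byrow = TRUE),
                      30, legend3)
  expect_equal(np_pd_lpi(label_patches(g, 4))$lpi, 100 * 3 / 9)

  # one patch covering exactly 100 ha -> PD = 1 patch per 100 ha
  hundred_ha <- catgrid_create(matrix(1L, 100, 100), 10, c(a = 1L))
  expect_equal(np_pd_lpi(label_patches(hundred_ha))$pd, 1)
})

test_that("LSI is zero without internal edge and counts interior edges once", {
  uni <- catgrid_create(matrix(1L, 6, 6), 30, c(a = 1L))
  expect_equal(lsi(uni), 0)

  m <- matrix(2L, 8, 8)
  m[3:5, 3:5] <- 1L  # interior 3x3 square: 4*3 cell edges
  g <- catgrid_create(m, 30, legend3[1:2])
  e_expected <- 4 * 3 * 30
  a <- 64 * 900
  expect_equal(lsi(g), e_expected / (2 * sqrt(pi * a)))
})

test_that("shape indices reproduce the square normalization", {
  sq <- catgrid_create(matrix(1L, 4, 4), 30, c(a = 1L))
  expect_equal(awmsi(label_patches(sq)), 1.0)

  rect <- catgrid_create(rbind(c(1L, 1L, 1L, 1L), c(2L, 2L, 2L, 2L)), 30,
                         legend3[1:2])
  geom <- patch_geometry(label_patches(rect))
  shape <- 0.25 * (geom$perimeter_m / 30) / sqrt(geom$ncell)
  expect_equal(shape, c(1.25, 1.25))  # two 1x4 patches
  expect_equal(awmsi(label_patches(rect)), 1.25)
})

test_that("nearest-neighbour distance handles pairs and lone patches", {
  v <- matrix(2L, 1, 7)
  v[1, 1] <- 1L; v[1, 4] <- 1L
  g <- catgrid_create(v, 30, legend3[1:2])
  ps <- label_patches(g, 4)
  # class 1: two single-cell patches 3 cells apart (90 m each); class 2:
  # patches {2,3} and {5,6,7}, nearest cells 2 apart (60 m each)
  expect_equal(enn_mn(ps), mean(c(90, 90, 60, 60)))

  lone <- catgrid_create(matrix(c(1L, 2L), 1, 2), 30, legend3[1:2])
  expect_true(is.na(enn_mn(label_patches(lone))))
})

test_that("IJI attains its extremes and needs three classes", {
  # vertical stripes 1|2|3: edges 1-2 and 2-3 only
  stripes <- catgrid_create(matrix(rep(1:3, each = 4), 2, 6), 30, legend3)
  e <- adjacency_table(stripes)
  expect_equal(e["1", "2"], e["2", "3"])
  # latin square: all three pair edge lengths equal -> maximum entropy
  m <- rbind(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  g <- catgrid_create(m, 30, legend3)
  et <- adjacency_table(g)
  expect_equal(et["1", "2"], et["1", "3"])
  expect_equal(et["1", "2"], et["2", "3"])
  expect_equal(iji(g), 100)

  # only one adjacent pair among three present classes -> zero entropy
  solo <- catgrid_create(matrix(c(1L, 2L, NA, 3L), 1, 4), 30, legend3)
  expect_equal(iji(solo), 0)

  two <- catgrid_create(matrix(c(1L, 2L), 2, 2), 30, legend3[1:2])
  expect_true(is.na(iji(two)))

  for (seed in 1:5) {
    g <- random_catgrid(seed + 30, 9, 9, 4)
    pairs <- oracle_pair_edges(g$values, 30)
    e_total <- sum(unlist(pairs))
    p <- unlist(pairs) / e_total
    expected <- -sum(p * log(p)) / log(4 * 3 / 2) * 100
    expect_equal(iji(g), expected, tolerance = 1e-12)
  }
})

test_that("aggregation index spans its range and matches adjacency counts", {
  solid <- catgrid_create(matrix(1L, 7, 4), 30, c(a = 1L))
  expect_equal(ai(solid)$landscape, 100)

  cb <- catgrid_create(outer(1:6, 1:6, function(r, c) (r + c) %% 2L + 1L),
                       30, legend3[1:2])
  res <- ai(cb)
  expect_equal(res$class$ai, c(0, 0))
  expect_equal(res$landscape, 0)

  for (seed in 1:6) {
    g <- random_catgrid(seed + 60, 10, 10, 3)
    got <- ai(g)$class
    g_oracle <- oracle_like_adjacencies(g$values)
    expect_equal(got$g_ii, unname(g_oracle[as.character(got$class_code)]))
  }
})

test_that("the metric report agrees with the individual metrics", {
  g <- random_catgrid(7, 12, 12, 3)
  rep <- metric_report(g)
  ps <- label_patches(g, 8)
  comp <- np_pd_lpi(ps)
  expect_equal(rep$value[rep$metric == "NP"], comp$np)
  expect_equal(rep$value[rep$metric == "LSI"], lsi(g))
  expect_equal(rep$value[rep$metric == "AWMSI"], awmsi(ps))
  expect_equal(rep$value[rep$metric == "AI"], ai(g)$landscape)

  uni <- catgrid_create(matrix(1L, 5, 5), 30, c(a = 1L))
  rep_u <- metric_report(uni)
  expect_equal(rep_u$value[rep_u$metric == "NP"], 1)
  expect_equal(rep_u$value[rep_u$metric == "LPI"], 100)
  expect_equal(rep_u$value[rep_u$metric == "LSI"], 0)
  expect_true(is.na(rep_u$value[rep_u$metric == "ENN_MN"]))
  expect_true(is.na(rep_u$value[rep_u$metric == "IJI"]))

  # CSV round trip preserves the values
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$value, rep$value)
})

test_that("filling a gap between same-class patches cannot raise NP or lower AI", {
  v <- matrix(2L, 5, 5)
  v[3, 1:2] <- 1L; v[3, 4:5] <- 1L   # two class-1 patches with a gap
  g <- catgrid_create(v, 30, legend3[1:2])
  v2 <- v; v2[3, 3] <- 1L            # fill the gap
  g2 <- catgrid_create(v2, 30, legend3[1:2])
  expect_lte(nrow(label_patches(g2)$patches), nrow(label_patches(g)$patches))
  ai1 <- ai(g)$class; ai2 <- ai(g2)$class
  expect_gte(ai2$ai[ai2$class_code == 1], ai1$ai[ai1$class_code == 1])
})
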