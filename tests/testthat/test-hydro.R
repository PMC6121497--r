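# hand-built flow field helper: directions given as a matrix of codes
make_flow <- function(direction, cell_size = 30) {
  nr <- nrow(direction); nc <- ncol(direction)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  receiver <- matrix(NA_integer_, nr, nc)
  for (i in which(!is.na(direction) & direction > 0L)) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    receiver[i] <- (c - 1L + dc[direction[i]]) * nr + r + dr[direction[i]]
  }
  structure(list(direction = direction, receiver = receiver,
                 cell_size = cell_size), class = "lci_flowfield")
}

test_that("sink filling raises pits to their spill and leaves slopes alone", {
  pit <- matrix(5, 3, 3); pit[2, 2] <- 1
  filled <- fill_sinks(grid_create(pit, 30))
  expect_equal(filled$values[2, 2], 5, tolerance = 1e-5)
  expect_true(all(filled$values >= pit))

  plane <- grid_create(matrix(rep(seq(50, 10, length.out = 5), 6), 5, 6), 30)
  expect_equal(fill_sinks(plane)$values, plane$values)
})

test_that("filled random surfaces have no interior strict local minima", {
  for (seed in 1:6) {
    set.seed(seed)
    dem <- grid_create(matrix(stats::runif(400, 0, 50), 20, 20), 30)
    f <- fill_sinks(dem)$values
    expect_true(all(f >= dem$values - 1e-12))
    for (r in 2:19) for (c in 2:19) {
      nb <- f[(r - 1):(r + 1), (c - 1):(c + 1)]
      expect_true(min(nb[-5]) <= f[r, c] + 1e-12)
    }
  }
})

test_that("D8 directions follow steepest descent with the documented tie-break", {
  chain <- d8_flow_direction(grid_create(matrix(c(5, 4, 3, 2, 1), 1), 30))
  expect_equal(chain$direction[1, ], c(1L, 1L, 1L, 1L, 0L))

  z <- matrix(6, 3, 3); z[2, 2] <- 5; z[3, 3] <- 1
  d <- d8_flow_direction(grid_create(z, 30))
  expect_equal(d$direction[2, 2], 2L)  # SE is the unique lowest neighbour

  # equal drops east and south: the E,SE,S,... order picks east
  z2 <- matrix(6, 3, 3); z2[2, 2] <- 5; z2[2, 3] <- 4; z2[3, 2] <- 4
  d2 <- d8_flow_direction(grid_create(z2, 30))
  expect_equal(d2$direction[2, 2], 1L)
})

test_that("flow accumulation counts upstream cells and conserves mass", {
  chain <- make_flow(matrix(c(1L, 1L, 1L, 1L, 0L), 1))
  expect_equal(flow_accumulation(chain)$values[1, ], c(1, 2, 3, 4, 5))

  for (seed in 1:5) {
    set.seed(seed)
    dem <- grid_create(matrix(stats::runif(225, 0, 30), 15, 15), 30)
    flow <- d8_flow_direction(fill_sinks(dem))
    acc <- flow_accumulation(flow)
    expect_equal(acc$values, oracle_accumulation(flow))
    outlets <- flow$direction == 0L
    expect_equal(sum(acc$values[outlets]), 225)
  }
})

test_that("stream extraction is a monotone threshold", {
  acc <- grid_create(matrix(c(1, 2, 3, 4, 5), 1), 30)
  expect_equal(extract_streams(acc, 3)[1, ],
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(all(extract_streams(acc, 1)))
  s4 <- extract_streams(acc, 4)
  expect_true(all(which(s4) %in% which(extract_streams(acc, 2))))
  expect_error(extract_streams(acc, 0), ">= 1")
})

test_that("a single chain with a downstream stream forms one sub-basin", {
  flow <- make_flow(matrix(c(1L, 1L, 1L, 1L, 0L), 1))
  streams <- matrix(c(FALSE, FALSE, FALSE, TRUE, TRUE), 1)
  sb <- delineate_subbasins(flow, streams)
  expect_equal(length(unique(as.vector(sb$labels$values))), 1)
  expect_equal(sum(!is.na(sb$labels$values)), 5)
})

test_that("a Y-shaped stream junction yields three sub-basins", {
  # arms at (1,1) and (1,3) meet at (2,2), draining to outlet (3,2)
  dir <- matrix(NA_integer_, 3, 3)
  dir[1, 1] <- 2L  # SE
  dir[1, 3] <- 4L  # SW
  dir[2, 2] <- 3L  # S
  dir[3, 2] <- 0L  # outlet
  dir[1, 2] <- 3L  # feeds the junction from the north
  dir[2, 1] <- 1L; dir[2, 3] <- 5L  # side cells feed the junction
  dir[3, 1] <- 1L; dir[3, 3] <- 5L  # bottom corners feed the outlet
  flow <- make_flow(dir)
  streams <- matrix(FALSE, 3, 3)
  streams[1, 1] <- TRUE; streams[1, 3] <- TRUE
  streams[2, 2] <- TRUE; streams[3, 2] <- TRUE
  sb <- delineate_subbasins(flow, streams)
  labs <- sb$labels$values
  expect_equal(length(unique(labs[!is.na(labs)])), 3)
  # the two arms carry different labels; the junction a third
  expect_true(labs[1, 1] != labs[1, 3])
  expect_true(!labs[2, 2] %in% c(labs[1, 1], labs[1, 3]))
  expect_equal(labs[3, 2], labs[2, 2])
  # partition: every drainable cell labelled exactly once
  expect_true(all(!is.na(labs)))
})

test_that("HRUs are single-code connected components that partition the basin", {
  set.seed(11)
  dem <- grid_create(matrix(stats::runif(256, 0, 40) +
                              rep(seq(40, 0, length.out = 16), 16), 16, 16),
                     30)
  flow <- d8_flow_direction(fill_sinks(dem))
  sb <- delineate_subbasins(flow, extract_streams(flow_accumulation(flow), 20))
  lu <- random_catgrid(2, 16, 16, 3)
  so <- random_catgrid(3, 16, 16, 2)
  hrus <- build_hrus(sb, lu, so)
  lab <- hrus$labels
  expect_true(all(!is.na(lab)))
  expect_equal(sum(hrus$table$ncell), 256)
  for (i in seq_len(nrow(hrus$table))) {
    cells <- which(lab == hrus$table$hru_id[i])
    expect_equal(length(unique(lu$values[cells])), 1)
    expect_equal(length(unique(so$values[cells])), 1)
    expect_equal(length(unique(sb$labels$values[cells])), 1)
  }
})

test_that("simple overlays give the expected HRU counts", {
  # columns of constant elevation decreasing eastwards: flow due east,
  # accumulation grows along rows, streams in the last two columns
  dem <- grid_create(matrix(rep(seq(12, 2, length.out = 6), each = 6),
                            6, 6), 30)
  flow <- d8_flow_direction(fill_sinks(dem))
  sb <- delineate_subbasins(flow, extract_streams(flow_accumulation(flow), 5))
  n_sb <- length(unique(as.vector(sb$labels$values)))
  expect_equal(n_sb, 6)  # one sub-basin per row
  uniform_soil <- catgrid_create(matrix(1L, 6, 6), 30, c(loam = 1L))
  split_lu <- catgrid_create(cbind(matrix(1L, 6, 3), matrix(2L, 6, 3)), 30,
                             c(forestland = 1L, `cultivated land` = 2L))
  hr <- build_hrus(sb, split_lu, uniform_soil)
  expect_equal(nrow(hr$table), 12)  # land use splits every row in two
  uniform_lu <- catgrid_create(matrix(1L, 6, 6), 30, c(forestland = 1L))
  hr_u <- build_hrus(sb, uniform_lu, uniform_soil)
  expect_equal(nrow(hr_u$table), n_sb)
})

test_that("merging small HRUs conserves area and respects min_area", {
  set.seed(5)
  dem <- grid_create(matrix(stats::runif(144, 0, 10) +
                              rep(seq(30, 0, length.out = 12), 12), 12, 12),
                     30)
  flow <- d8_flow_direction(fill_sinks(dem))
  sb <- delineate_subbasins(flow, extract_streams(flow_accumulation(flow), 15))
  lu <- random_catgrid(21, 12, 12, 3)
  so <- random_catgrid(22, 12, 12, 2)
  hrus <- build_hrus(sb, lu, so)
  total_before <- sum(hrus$table$area_m2)
  merged <- suppressWarnings(merge_small_hrus(hrus, min_area = 4 * 900))
  expect_equal(sum(merged$table$area_m2), total_before)
  # labels and table stay consistent
  for (i in seq_len(nrow(merged$table))) {
    expect_equal(sum(merged$labels == merged$table$hru_id[i], na.rm = TRUE),
                 merged$table$ncell[i])
  }

  # all HRUs already large enough -> identity
  big <- merge_small_hrus(hrus, min_area = 900)
  expect_identical(big$table, hrus$table)
})
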