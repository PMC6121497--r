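#' Canonical six-class land-use legend
#'
#' Class codes used throughout: forestland 1, residential land 2,
#' cultivated land 3, water 4, unused land 5, orchards 6.
#'
#' @export
LANDUSE_LEGEND <- c(
  "forestland" = 1L, "residential land" = 2L, "cultivated land" = 3L,
  "water" = 4L, "unused land" = 5L, "orchards" = 6L
)

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# separable gaussian smoothing with edge replication, via banded row/column
# operators; sigma in cells
smooth_field <- function(m, sigma) {
  if (sigma < 0.3) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  op <- function(n) {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax(i + (-half:half), 1L), n)  # replicate edges
      for (j in seq_along(idx)) s[i, idx[j]] <- s[i, idx[j]] + k[j]
    }
    s
  }
  op(nrow(m)) %*% m %*% t(op(ncol(m)))
}

#' Synthetic basin scenario
#'
#' Bundles every tunable of the synthetic generators.  The defaults emulate
#' a small subtropical coastal catchment of the kind the method targets: a
#' 64 x 64 grid of 30 m cells (~3.7 km2), moderate relief, annual
#' precipitation well above 800 mm, forest-dominated cover with cultivated
#' land and orchards, fertilizer applied to cultivated land above the
#' standard-farmland band and to orchards within it.  The same spec and
#' seed always generate bit-identical layers.
#'
#' @param shape integer c(rows, cols).
#' @param cell_size cell edge in meters.
#' @param seed integer RNG seed.
#' @param classes names of the land-use classes present (subset of
#'   `names(LANDUSE_LEGEND)`, 2..6 of them).
#' @param class_props target areal proportions, same length as `classes`.
#' @param patch_clustering 0 (i.i.d. cells) .. 1 (few large patches).
#' @param relief total elevation range in meters.
#' @param precip_range c(min, max) annual precipitation in mm.
#' @param ndvi_means named per-class NDVI means.
#' @param fertilizer_rates named kg/ha/yr rates for fertilized classes.
#' @return A `lci_scenario` list.
#' @export
scenario_spec <- function(shape = c(64, 64),
                          cell_size = 30,
                          seed = 42,
                          classes = c("forestland", "cultivated land",
                                      "orchards"),
                          class_props = NULL,
                          patch_clustering = 0.7,
                          relief = 120,
                          precip_range = c(1200, 1600),
                          ndvi_means = c(
                            "forestland" = 0.80, "residential land" = 0.15,
                            "cultivated land" = 0.35, "water" = -0.10,
                            "unused land" = 0.10, "orchards" = 0.55
                          ),
                          fertilizer_rates = c("cultivated land" = 600,
                                               "orchards" = 450)) {
  stopifnot(length(shape) == 2L, all(shape >= 4L))
  if (!all(classes %in% names(LANDUSE_LEGEND))) {
    stop("unknown land-use class(es)", call. = FALSE)
  }
  if (length(classes) < 2L || length(classes) > 6L) {
    stop("between 2 and 6 land-use classes required", call. = FALSE)
  }
  if (is.null(class_props)) {
    defaults <- c(
      "forestland" = 0.55, "residential land" = 0.10,
      "cultivated land" = 0.30, "water" = 0.05, "unused land" = 0.05,
      "orchards" = 0.15
    )
    class_props <- defaults[classes] / sum(defaults[classes])
  }
  stopifnot(length(class_props) == length(classes), all(class_props > 0))
  if (patch_clustering < 0 || patch_clustering > 1) {
    stop("patch_clustering must be in [0, 1]", call. = FALSE)
  }
  if (relief <= 0) stop("relief must be positive", call. = FALSE)
  structure(
    list(shape = as.integer(shape), cell_size = cell_size, seed = seed,
         classes = classes,
         class_props = class_props / sum(class_props),
         patch_clustering = patch_clustering, relief = relief,
         precip_range = precip_range, ndvi_means = ndvi_means,
         fertilizer_rates = fertilizer_rates),
    class = "lci_scenario"
  )
}

#' Synthetic DEM
#'
#' An inclined plane draining towards the southern border plus seeded
#' smooth bumps (amplitude a quarter of the relief, correlation length ~6
#' cells), guaranteeing at least one border outlet while leaving a modest
#' number of depressions for the filler to resolve.
#'
#' @param spec a [scenario_spec()].
#' @return A `lci_grid` of elevations in meters.
#' @export
synth_dem <- function(spec) {
  stopifnot(inherits(spec, "lci_scenario"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  tilt <- matrix(rep(spec$relief * (nr - seq_len(nr)) / (nr - 1), nc),
                 nr, nc)
  bumps <- with_seed(spec$seed, {
    smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 6)
  })
  bumps <- bumps / max(abs(bumps)) * 0.25 * spec$relief
  grid_create(tilt + bumps, spec$cell_size)
}

#' Synthetic land-use map
#'
#' A white-noise field smoothed with a kernel whose width grows with
#' `patch_clustering` (sigma = 10 * clustering cells) is cut at the target
#' class-proportion quantiles: clustering 0 gives i.i.d. cells, clustering
#' near 1 a handful of large patches.  If a requested class comes out
#' empty (possible only on tiny grids) the generator retries with the seed
#' incremented, then errors.
#'
#' @param spec a [scenario_spec()].
#' @return A `lci_catgrid` whose legend is exactly the requested classes.
#' @export
synth_landuse <- function(spec) {
  stopifnot(inherits(spec, "lci_scenario"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  legend <- LANDUSE_LEGEND[spec$classes]
  for (try in 0:9) {
    field <- with_seed(spec$seed + 1000L + try, {
      smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                   sigma = 10 * spec$patch_clustering)
    })
    cuts <- stats::quantile(field, probs = cumsum(spec$class_props),
                            names = FALSE)
    cuts[length(cuts)] <- Inf
    codes <- matrix(legend[findInterval(field, c(-Inf, cuts[-length(cuts)]))],
                    nr, nc)
    if (all(legend %in% codes)) {
      return(catgrid_create(codes, spec$cell_size, legend))
    }
  }
  stop("could not realise all requested classes on this grid",
       call. = FALSE)
}

#' Synthetic geographic factor surfaces
#'
#' Generates, aligned with a land-use map: a smooth west-to-east annual
#' precipitation gradient spanning `precip_range`; an NDVI surface drawn
#' per land-use class around the class mean (forest high, cultivated
#' intermediate, residential/water low; sd 0.08, clipped to [-1, 1]);
#' red/NIR reflectance bands that reproduce that NDVI exactly (constant
#' total reflectance 0.5); a fertilizer surface positive only on
#' cultivated land and orchards; and categorical soil-texture and
#' soil-moisture maps as smoothed-noise class mosaics (25/50/25%).
#'
#' @param spec a [scenario_spec()].
#' @param landuse the matching [synth_landuse()] output.
#' @return Named list: `precip`, `ndvi`, `red`, `nir`, `fertilizer`
#'   (`lci_grid`s), `soil`, `moisture` (`lci_catgrid`s).
#' @export
synth_factor_surfaces <- function(spec, landuse) {
  stopifnot(inherits(spec, "lci_scenario"), inherits(landuse, "lci_catgrid"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cs <- spec$cell_size
  with_seed(spec$seed + 2000L, {
    grad <- matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)
    wiggle <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 8)
    wiggle <- wiggle / max(abs(wiggle)) * 0.1
    p01 <- pmin(pmax(grad + wiggle, 0), 1)
    precip <- spec$precip_range[1] + diff(spec$precip_range) * p01

    means <- spec$ndvi_means[names(LANDUSE_LEGEND)[match(landuse$values,
                                                         LANDUSE_LEGEND)]]
    ndvi <- matrix(means + stats::rnorm(nr * nc, sd = 0.08), nr, nc)
    ndvi <- pmin(pmax(ndvi, -1), 1)

    total <- 0.5
    red <- total * (1 - ndvi) / 2
    nir <- total * (1 + ndvi) / 2

    fert <- matrix(0, nr, nc)
    for (cl in names(spec$fertilizer_rates)) {
      sel <- landuse$values == LANDUSE_LEGEND[[cl]]
      fert[sel] <- pmax(0, spec$fertilizer_rates[[cl]] +
                           stats::rnorm(sum(sel), sd = 25))
    }

    classify3 <- function(field, legend) {
      cuts <- stats::quantile(field, probs = c(0.25, 0.75), names = FALSE)
      codes <- matrix(legend[findInterval(field, cuts) + 1L], nr, nc)
      catgrid_create(codes, cs, legend)
    }
    soil <- classify3(
      smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 7),
      c(sandy = 1L, loam = 2L, clay = 3L)
    )
    moisture <- classify3(
      smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 7),
      c(low = 1L, medium = 2L, high = 3L)
    )

    list(
      precip = grid_create(precip, cs),
      ndvi = grid_create(ndvi, cs),
      red = grid_create(red, cs),
      nir = grid_create(nir, cs),
      fertilizer = grid_create(fert, cs),
      soil = soil,
      moisture = moisture
    )
  })
}

#' Generate every layer of a synthetic basin
#'
#' Convenience wrapper: DEM, land use and all factor surfaces from one
#' scenario, mutually aligned and fully determined by the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return Named list of layers: `dem`, `landuse`, plus everything from
#'   [synth_factor_surfaces()].
#' @export
synth_basin <- function(spec = scenario_spec()) {
  landuse <- synth_landuse(spec)
  c(list(dem = synth_dem(spec), landuse = landuse),
    synth_factor_surfaces(spec, landuse))
}

#' The standard-farmland reference plot
#'
#' A small idealized scenario in which every factor sits in its baseline
#' class: a gently inclined (far below 25 degrees) all-cultivated plot on
#' loam with medium soil moisture, 600 mm annual precipitation, 450
#' kg/ha/yr fertilizer, NDVI 0, directly bordering the water body
#' (distance 0 everywhere).  Its raw weight is exactly 1 by construction,
#' which anchors the per-unit-area index scale.
#'
#' @param n grid edge in cells (default 6).
#' @param cell_size cell edge in meters.
#' @return Named list of layers as in [synth_basin()], plus `distance`
#'   (all-zero grid standing for immediate adjacency to water).
#' @export
standard_farmland_fixture <- function(n = 6, cell_size = 30) {
  z <- matrix(rep(seq(n, 1) * 0.1, n), n, n)  # 0.1 m drop per cell
  dem <- grid_create(z, cell_size)
  lu <- catgrid_create(matrix(LANDUSE_LEGEND[["cultivated land"]], n, n),
                       cell_size,
                       LANDUSE_LEGEND["cultivated land"])
  soil <- catgrid_create(matrix(2L, n, n), cell_size,
                         c(sandy = 1L, loam = 2L, clay = 3L))
  moisture <- catgrid_create(matrix(2L, n, n), cell_size,
                             c(low = 1L, medium = 2L, high = 3L))
  const <- function(v) grid_create(matrix(v, n, n), cell_size)
  ndvi <- const(0)
  list(
    dem = dem, landuse = lu, soil = soil, moisture = moisture,
    precip = const(600), ndvi = ndvi,
    red = const(0.25), nir = const(0.25),
    fertilizer = const(450), distance = const(0)
  )
}
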