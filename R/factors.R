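#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - red) / (NIR + red)` per cell; cells where both bands are
#' zero become nodata.
#'
#' @param red,nir aligned reflectance grids (`lci_grid`).
#' @return A `lci_grid` of NDVI values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  assert_aligned(red = red, nir = nir)
  s <- red$values + nir$values
  out <- (nir$values - red$values) / s
  out[!is.na(s) & s == 0] <- NA_real_
  grid_create(out, red$cell_size, red$origin)
}

#' Terrain slope in degrees (Horn stencil)
#'
#' Third-order finite difference over the 3x3 neighbourhood (Horn's
#' weights), with border cells handled by edge replication.
#'
#' @param dem a `lci_grid` of elevations in meters.
#' @return A `lci_grid` of slope in degrees.
#' @export
compute_slope <- function(dem) {
  stopifnot(inherits(dem, "lci_grid"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # edge-replicated padding
  zp <- matrix(NA_real_, nr + 2L, nc + 2L)
  zp[2:(nr + 1L), 2:(nc + 1L)] <- z
  zp[1L, ] <- zp[2L, ]; zp[nr + 2L, ] <- zp[nr + 1L, ]
  zp[, 1L] <- zp[, 2L]; zp[, nc + 2L] <- zp[, nc + 1L]
  sub <- function(dr, dc) zp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  # Horn: a b c / d e f / g h i, x east, y north (row 1 is north)
  a <- sub(-1L, -1L); b <- sub(-1L, 0L); cc <- sub(-1L, 1L)
  d <- sub(0L, -1L);                     f <- sub(0L, 1L)
  g <- sub(1L, -1L);  h <- sub(1L, 0L);  i <- sub(1L, 1L)
  cs <- dem$cell_size
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  grid_create(slope, cs, dem$origin)
}

#' Distance correction coefficient
#'
#' Linear decay of pollutant delivery with surface distance to the water
#' body: `D = max(0, 1 - distance / cap)`.  The default cap of 20 km is the
#' farthest distance at which a non-point source still affects the water
#' body; the coefficient is exactly 1 at the water's edge and exactly 0 at
#' and beyond the cap.
#'
#' @param distance_m distance(s) to the nearest water cell, meters (>= 0).
#' @param cap_m decay cap in meters (default 20000).
#' @return Coefficient(s) in `[0, 1]`.
#' @export
distance_coefficient <- function(distance_m, cap_m = 20000) {
  if (any(distance_m < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  pmax(0, 1 - distance_m / cap_m)
}

#' NDVI correction coefficient
#'
#' Piecewise-linear decrease with vegetation amount: 1 for NDVI <= 0 (bare
#' or water-like surfaces offer no interception) falling linearly to
#' `min_coef` at NDVI = 1 (closed canopy, maximum interception of
#' pollutants in transit).
#'
#' @param ndvi NDVI value(s) in `[-1, 1]`.
#' @param min_coef coefficient at full vegetation cover (default 0.3).
#' @return Coefficient(s) in `[min_coef, 1]`.
#' @export
ndvi_coefficient <- function(ndvi, min_coef = 0.3) {
  if (any(abs(ndvi) > 1 + 1e-9, na.rm = TRUE)) {
    stop("NDVI must lie in [-1, 1]", call. = FALSE)
  }
  1 - (1 - min_coef) * pmax(0, ndvi)
}

#' Map a land-use class to its correction-factor group
#'
#' The land-use factor distinguishes cultivated land, orchards, forestland
#' and everything else ("other": residential land, water, unused land).
#'
#' @param code land-use code(s).
#' @param legend named integer legend of the land-use grid.
#' @return Character vector of `"cultivated"`, `"orchard"`, `"forest"` or
#'   `"other"`.
#' @export
landuse_group <- function(code, legend) {
  nm <- names(legend)[match(code, legend)]
  if (anyNA(nm)) {
    stop("land-use code(s) not in legend: ",
         paste(unique(code[is.na(nm)]), collapse = ", "), call. = FALSE)
  }
  dplyr::case_when(
    grepl("cultivat", nm, ignore.case = TRUE) ~ "cultivated",
    grepl("orchard", nm, ignore.case = TRUE) ~ "orchard",
    grepl("forest", nm, ignore.case = TRUE) ~ "forest",
    TRUE ~ "other"
  )
}

#' Default geographic correction-coefficient table
#'
#' Class-based multipliers for the eight geographic factors: land use (L),
#' slope (P), annual precipitation (R), distance to water (D), NDVI (N),
#' soil texture (S), fertilizer application (F) and effective soil moisture
#' (A).  The standard-farmland class of every factor carries coefficient
#' exactly 1 (plain below 25 degrees, 400-800 mm precipitation, loam,
#' 375-525 kg/ha/yr fertilizer, medium moisture, cultivated land at the
#' water's edge), so a standard farmland plot has raw weight 1 and every
#' other unit is expressed relative to that baseline.  Interval classes are
#' lower-closed, upper-open.  The non-baseline magnitudes encode the
#' ordinal structure of the factors (steeper, wetter and more fertilized
#' export more; vegetated and distant units export less; cultivated >
#' orchard > other > forest) and are meant to be overridden from a measured
#' calibration where one exists; see the methods vignette.
#'
#' @param pollutants character vector of pollutant names.
#' @return A `lci_coeftable`: nested list `pollutant -> factor -> tibble`
#'   (`label`, `min`, `max`, `coef`; `min`/`max` are `NA` for label-matched
#'   factors), plus `baseline_export` (kg/ha/yr per pollutant) and the
#'   functional parameters `distance_cap_m` and `ndvi_min_coef`.
#' @export
default_coefficients <- function(pollutants = c("TN", "TP", "COD")) {
  interval <- function(mins, maxs, coefs) {
    tibble::tibble(label = sprintf("[%s,%s)", mins, maxs),
                   min = mins, max = maxs, coef = coefs)
  }
  labelled <- function(labels, coefs) {
    tibble::tibble(label = labels, min = NA_real_, max = NA_real_,
                   coef = coefs)
  }
  one <- list(
    L = labelled(c("cultivated", "orchard", "other", "forest"),
                 c(1.0, 0.85, 0.6, 0.3)),
    P = interval(c(0, 25), c(25, Inf), c(1.0, 1.2)),
    R = interval(c(0, 400, 800), c(400, 800, Inf), c(0.8, 1.0, 1.3)),
    S = labelled(c("sandy", "loam", "clay"), c(1.1, 1.0, 0.9)),
    F = interval(c(0, 375, 525), c(375, 525, Inf), c(0.8, 1.0, 1.2)),
    A = labelled(c("low", "medium", "high"), c(0.9, 1.0, 1.1))
  )
  # nominal export of standard farmland, kg/ha/yr, used only for scaling
  # absolute loads; the index itself is relative
  baseline <- c(TN = 20, TP = 2, COD = 30)[pollutants]
  baseline[is.na(baseline)] <- 1
  names(baseline) <- pollutants
  structure(
    list(
      factors = stats::setNames(rep(list(one), length(pollutants)),
                                pollutants),
      baseline_export = baseline,
      distance_cap_m = 20000,
      ndvi_min_coef = 0.3
    ),
    class = "lci_coeftable"
  )
}

#' @export
print.lci_coeftable <- function(x, ...) {
  cat(sprintf("<coefficient table> pollutants: %s; distance cap %g km\n",
              paste(names(x$factors), collapse = ", "),
              x$distance_cap_m / 1000))
  invisible(x)
}

#' Write / read a coefficient table as YAML
#'
#' The on-disk schema is `pollutants -> factors -> list of {label, min,
#' max, coef}` plus `baseline_export`, `distance_cap_m` and
#' `ndvi_min_coef`.  Reading validates the table: interval classes of each
#' factor must cover `[0, Inf)` without overlap, and each factor must have
#' exactly one class with coefficient 1 (the standard-farmland class).
#'
#' @param table a `lci_coeftable`.
#' @param path YAML file path.
#' @return `read_coefficients()` returns a validated `lci_coeftable`.
#' @export
write_coefficients <- function(table, path) {
  stopifnot(inherits(table, "lci_coeftable"))
  obj <- list(
    pollutants = lapply(table$factors, function(fl) {
      lapply(fl, function(tb) {
        lapply(seq_len(nrow(tb)), function(i) {
          row <- as.list(tb[i, ])
          row$min <- if (is.na(row$min)) NULL else row$min
          row$max <- if (is.na(row$max)) NULL
                     else if (is.infinite(row$max)) ".inf" else row$max
          row
        })
      })
    }),
    baseline_export = as.list(table$baseline_export),
    distance_cap_m = table$distance_cap_m,
    ndvi_min_coef = table$ndvi_min_coef
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  obj <- yaml::read_yaml(path)
  parse_num <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (identical(x, ".inf")) return(Inf)
    as.numeric(x)
  }
  factors <- lapply(obj$pollutants, function(fl) {
    lapply(fl, function(classes) {
      tibble::tibble(
        label = vapply(classes, function(cl) cl$label, character(1)),
        min = vapply(classes, function(cl) parse_num(cl$min), numeric(1)),
        max = vapply(classes, function(cl) parse_num(cl$max), numeric(1)),
        coef = vapply(classes, function(cl) as.numeric(cl$coef), numeric(1))
      )
    })
  })
  tab <- structure(
    list(
      factors = factors,
      baseline_export = unlist(obj$baseline_export),
      distance_cap_m = obj$distance_cap_m %||% 20000,
      ndvi_min_coef = obj$ndvi_min_coef %||% 0.3
    ),
    class = "lci_coeftable"
  )
  validate_coefficients(tab)
  tab
}

validate_coefficients <- function(table) {
  for (pol in names(table$factors)) {
    for (fac in names(table$factors[[pol]])) {
      tb <- table$factors[[pol]][[fac]]
      if (any(!is.finite(tb$coef)) || any(tb$coef < 0)) {
        stop(sprintf("factor %s/%s: coefficients must be finite and >= 0",
                     pol, fac), call. = FALSE)
      }
      if (!any(tb$coef == 1)) {
        stop(sprintf("factor %s/%s: no class with coefficient 1 ",
                     pol, fac),
             "(the standard-farmland baseline class)", call. = FALSE)
      }
      if (all(!is.na(tb$min))) {
        o <- order(tb$min)
        if (tb$min[o][1] != 0 || !is.infinite(tb$max[o][nrow(tb)]) ||
            any(tb$max[o][-nrow(tb)] != tb$min[o][-1])) {
          stop(sprintf("factor %s/%s: interval classes must cover [0, Inf)",
                       pol, fac), " without gaps or overlap", call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Classify a factor value and look up its coefficient
#'
#' Interval factors (P slope, R precipitation, F fertilizer) use
#' lower-closed upper-open classes; label factors (L land-use group, S soil
#' texture, A soil moisture) match by class label; the two functional
#' factors delegate to [distance_coefficient()] (D) and
#' [ndvi_coefficient()] (N).
#'
#' @param table a `lci_coeftable`.
#' @param factor one of `"L","P","R","D","N","S","F","A"`.
#' @param value numeric value (interval/functional factors) or class label.
#' @param pollutant pollutant name (default first in the table).
#' @return List with `label` and `coef`.
#' @export
classify_factor <- function(table, factor, value,
                            pollutant = names(table$factors)[1]) {
  stopifnot(inherits(table, "lci_coeftable"))
  if (factor == "D") {
    co <- distance_coefficient(value, table$distance_cap_m)
    return(list(label = if (co > 0) "within cap" else "beyond cap",
                coef = co))
  }
  if (factor == "N") {
    return(list(label = "ndvi", coef = ndvi_coefficient(value,
                                                        table$ndvi_min_coef)))
  }
  tb <- table$factors[[pollutant]][[factor]]
  if (is.null(tb)) stop("unknown factor: ", factor, call. = FALSE)
  if (all(!is.na(tb$min))) {
    hit <- which(value >= tb$min & value < tb$max)
  } else {
    hit <- which(tb$label == value)
  }
  if (length(hit) != 1L) {
    stop(sprintf("value '%s' matches %d classes of factor %s",
                 as.character(value), length(hit), factor), call. = FALSE)
  }
  list(label = tb$label[hit], coef = tb$coef[hit])
}

# modal (most frequent) code of a categorical layer over a cell index set
modal_code <- function(values, cells) {
  v <- values[cells]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_integer_)
  t <- table(v)
  as.integer(names(t)[which.max(t)])
}

#' Per-HRU geographic factor values
#'
#' Aggregates the continuous factor surfaces (slope, precipitation, NDVI,
#' distance to water, fertilizer) over each HRU by the mean of its
#' non-nodata cells, and attaches the HRU's land-use group, soil-texture
#' class and (modal) soil-moisture class.  HRUs whose cells are entirely
#' nodata in some factor are flagged incomplete and excluded from the index
#' with a warning.
#'
#' @param hrus a `lci_hrus`.
#' @param surfaces named list of `lci_grid`s: `slope`, `precip`, `ndvi`,
#'   `distance`, `fertilizer`.
#' @param soil a `lci_catgrid` whose legend names are the texture classes
#'   (`sandy`, `loam`, `clay`).
#' @param moisture a `lci_catgrid` whose legend names are the moisture
#'   classes (`low`, `medium`, `high`), or `NULL` for `medium` everywhere.
#' @return Tibble: one row per complete HRU with columns `hru_id`,
#'   `subbasin_id`, `area_ha`, `landuse_group`, `slope_deg`, `precip_mm`,
#'   `ndvi`, `distance_m`, `fertilizer_kgha`, `soil_texture`,
#'   `soil_moisture`.
#' @export
hru_factor_values <- function(hrus, surfaces, soil, moisture = NULL) {
  stopifnot(inherits(hrus, "lci_hrus"))
  need <- c("slope", "precip", "ndvi", "distance", "fertilizer")
  missing <- setdiff(need, names(surfaces))
  if (length(missing)) {
    stop("missing factor surfaces: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- hrus$labels
  tab <- hrus$table
  cell_sets <- split(seq_along(lab), factor(lab, levels = tab$hru_id))
  agg <- function(g) {
    unname(vapply(cell_sets, function(cells) {
      v <- g$values[cells]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)))
  }
  out <- tibble::tibble(
    hru_id = tab$hru_id,
    subbasin_id = tab$subbasin_id,
    area_ha = tab$area_ha,
    landuse_group = landuse_group(tab$landuse_code, hrus$landuse_legend),
    slope_deg = agg(surfaces$slope),
    precip_mm = agg(surfaces$precip),
    ndvi = agg(surfaces$ndvi),
    distance_m = agg(surfaces$distance),
    fertilizer_kgha = agg(surfaces$fertilizer),
    soil_texture = names(soil$legend)[match(tab$soil_code, soil$legend)],
    soil_moisture = if (is.null(moisture)) "medium" else {
      codes <- vapply(cell_sets, function(cells) {
        modal_code(moisture$values, cells)
      }, integer(1))
      names(moisture$legend)[match(codes, moisture$legend)]
    }
  )
  incomplete <- !stats::complete.cases(
    out[, c("slope_deg", "precip_mm", "ndvi", "distance_m",
            "fertilizer_kgha", "soil_texture", "soil_moisture")]
  )
  if (any(incomplete)) {
    warning(sum(incomplete), " HRU(s) with all-nodata factor cells ",
            "excluded from the index", call. = FALSE)
    out <- out[!incomplete, ]
  }
  out
}

#' Raw generation/inhibition weight of each HRU
#'
#' Composes the eight factor coefficients into the per-HRU weight.  The
#' default composition is the product `W = L * P * R * D * N * S * F * A`,
#' the standard export-coefficient correction scheme: a standard farmland
#' plot (all coefficients 1) then has raw weight exactly 1 and any factor
#' at 0 (e.g. beyond the distance cap) annihilates the weight.  A weighted
#' arithmetic mean is available for sensitivity analysis.
#'
#' @param factor_values tibble from [hru_factor_values()].
#' @param table a `lci_coeftable`.
#' @param pollutants pollutant names to evaluate (default: all in table).
#' @param composition `"product"` (default) or `"mean"`.
#' @return Long tibble: `hru_id`, `pollutant`, the eight coefficient
#'   columns (`L`,`P`,`R`,`D`,`N`,`S`,`F`,`A`) and `w_raw`.
#' @export
hru_weights <- function(factor_values, table,
                        pollutants = names(table$factors),
                        composition = c("product", "mean")) {
  stopifnot(inherits(table, "lci_coeftable"))
  composition <- match.arg(composition)
  lookup <- function(fac, values, pol) {
    unname(vapply(values, function(v) classify_factor(table, fac, v, pol)$coef,
                  numeric(1)))
  }
  purrr::map_dfr(pollutants, function(pol) {
    co <- tibble::tibble(
      hru_id = factor_values$hru_id,
      pollutant = pol,
      L = lookup("L", factor_values$landuse_group, pol),
      P = lookup("P", factor_values$slope_deg, pol),
      R = lookup("R", factor_values$precip_mm, pol),
      D = distance_coefficient(factor_values$distance_m,
                               table$distance_cap_m),
      N = ndvi_coefficient(factor_values$ndvi, table$ndvi_min_coef),
      S = lookup("S", factor_values$soil_texture, pol),
      F = lookup("F", factor_values$fertilizer_kgha, pol),
      A = lookup("A", factor_values$soil_moisture, pol)
    )
    w <- if (composition == "product") {
      co$L * co$P * co$R * co$D * co$N * co$S * co$F * co$A
    } else {
      (co$L + co$P + co$R + co$D + co$N + co$S + co$F + co$A) / 8
    }
    dplyr::mutate(co, w_raw = w)
  })
}

#' Normalize weights to the basin maximum
#'
#' Standardizes the raw weights of one pollutant so the most
#' pollution-prone HRU scores 1: `W = W_i / W_max`.  Order and ratios are
#' preserved; multiplying all raw weights by a positive constant leaves the
#' result unchanged.
#'
#' @param w numeric vector of raw weights, at least one positive.
#' @return Normalized weights in `[0, 1]` with maximum exactly 1.
#' @export
normalize_weights <- function(w) {
  if (any(w < 0, na.rm = TRUE)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  w_max <- max(w, na.rm = TRUE)
  if (!is.finite(w_max) || w_max <= 0) {
    stop("all weights are zero; nothing to normalize", call. = FALSE)
  }
  w / w_max
}
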