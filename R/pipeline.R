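#' Run the full source-sink landscape index pipeline
#'
#' From co-registered input layers to per-HRU and per-sub-basin index
#' values: fills the DEM, routes flow (D8), extracts the stream network at
#' an accumulation threshold, delineates sub-basins, overlays land use and
#' soil into HRUs, merges undersized HRUs, builds the effective-distance
#' and slope surfaces, classifies the eight geographic factors, composes
#' and normalizes the weights, and evaluates the index per pollutant.
#'
#' @param layers named list with `dem`, `landuse`, `soil` (required) and
#'   `precip`, `fertilizer`, `moisture` plus either `ndvi` or `red`/`nir`;
#'   optionally a precomputed `distance` grid (otherwise the Euclidean
#'   distance to the stream network union water land-use cells is used).
#' @param coefficients a `lci_coeftable` (default [default_coefficients()]).
#' @param pollutants pollutants to evaluate.
#' @param stream_threshold accumulation threshold (cells) for stream
#'   extraction.
#' @param min_area_cells minimum HRU size in cells before merging.
#' @param connectivity HRU component connectivity.
#' @return A `hrulci_result`: list with `hrus` (`lci_hrus`), `records`
#'   (per-HRU per-pollutant tibble incl. the combined pollutant),
#'   `subbasin_scores`, `factor_values`, `weights`, `subbasins`, `streams`
#'   (logical mask) and the derived `slope`, `distance` grids.
#' @export
run_hrulci <- function(layers,
                       coefficients = default_coefficients(),
                       pollutants = names(coefficients$factors),
                       stream_threshold = 100,
                       min_area_cells = 5,
                       connectivity = 8) {
  need <- c("dem", "landuse", "soil")
  if (!all(need %in% names(layers))) {
    stop("`layers` must contain at least dem, landuse and soil",
         call. = FALSE)
  }
  if (is.null(layers$ndvi)) {
    if (is.null(layers$red) || is.null(layers$nir)) {
      stop("provide either `ndvi` or both `red` and `nir`", call. = FALSE)
    }
    layers$ndvi <- compute_ndvi(layers$red, layers$nir)
  }
  core <- layers[!vapply(layers, is.null, logical(1))]
  assert_aligned(core[vapply(core, inherits, logical(1), "lci_grid")])

  filled <- fill_sinks(layers$dem)
  flow <- d8_flow_direction(filled)
  acc <- flow_accumulation(flow)
  streams <- extract_streams(acc, stream_threshold)
  subbasins <- delineate_subbasins(flow, streams)
  hrus <- build_hrus(subbasins, layers$landuse, layers$soil, connectivity)
  cs <- layers$dem$cell_size
  hrus <- merge_small_hrus(hrus, min_area = min_area_cells * cs^2)

  if (is.null(layers$distance)) {
    water_mask <- streams
    if ("water" %in% names(layers$landuse$legend)) {
      water_mask <- water_mask |
        (!is.na(layers$landuse$values) &
           layers$landuse$values == layers$landuse$legend[["water"]])
    }
    layers$distance <- euclidean_distance_to(water_mask, cs)
  }
  slope <- compute_slope(layers$dem)

  fv <- hru_factor_values(
    hrus,
    surfaces = list(slope = slope, precip = layers$precip,
                    ndvi = layers$ndvi, distance = layers$distance,
                    fertilizer = layers$fertilizer),
    soil = layers$soil,
    moisture = layers$moisture
  )
  w <- hru_weights(fv, coefficients, pollutants)
  records <- hrulci(w, fv) |> combine_pollutants()
  scores <- subbasin_index(records, hrus$table)

  structure(
    list(hrus = hrus, records = records, subbasin_scores = scores,
         factor_values = fv, weights = w, subbasins = subbasins,
         streams = streams, slope = slope, distance = layers$distance,
         landuse = layers$landuse, coefficients = coefficients),
    class = "hrulci_result"
  )
}

#' @export
print.hrulci_result <- function(x, ...) {
  cat(sprintf(
    "<HRULCI result> %d HRUs, %d sub-basins, pollutants: %s\n",
    nrow(x$hrus$table), nrow(x$subbasins$outlets),
    paste(setdiff(unique(x$records$pollutant), "combined"), collapse = ", ")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-HRU index records
#'
#' One row per HRU and pollutant with the land-use group and source/sink
#' role attached.
#'
#' @param x a `hrulci_result`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.hrulci_result <- function(x, ...) {
  groups <- x$factor_values[, c("hru_id", "landuse_group")]
  lu_code <- stats::setNames(x$hrus$table$landuse_code, x$hrus$table$hru_id)
  x$records |>
    dplyr::left_join(groups, by = "hru_id") |>
    dplyr::mutate(
      role = classify_source_sink(lu_code[as.character(.data$hru_id)],
                                  x$landuse$legend)
    )
}

#' One-row summary of a pipeline result
#'
#' @param x a `hrulci_result`.
#' @param ... unused.
#' @return Tibble: HRU and sub-basin counts and the mean per-unit-area
#'   index of source and sink HRUs (combined rows excluded).
#' @export
glance.hrulci_result <- function(x, ...) {
  td <- tidy(x) |> dplyr::filter(.data$pollutant != "combined")
  tibble::tibble(
    n_hru = nrow(x$hrus$table),
    n_subbasin = nrow(x$subbasins$outlets),
    mean_per_area_source = mean(td$per_area_index[td$role == "source"]),
    mean_per_area_sink = mean(td$per_area_index[td$role == "sink"]),
    total_index = sum(td$value)
  )
}

grid_df <- function(values, cell_size) {
  nr <- nrow(values)
  tibble::tibble(
    x = rep(seq_len(ncol(values)), each = nr) * cell_size,
    y = rep(seq(nr, 1), ncol(values)) * cell_size,
    value = as.vector(values)
  )
}

#' Plot a grid as a raster map
#'
#' @param object a `lci_grid` or `lci_catgrid`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lci_grid <- function(object, ...) {
  df <- grid_df(object$values, object$cell_size)
  if (inherits(object, "lci_catgrid")) {
    df$value <- factor(df$value, levels = object$legend,
                       labels = names(object$legend))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Map the combined per-HRU index
#'
#' Joins the HRU label raster to the chosen pollutant's index values.
#'
#' @param object a `hrulci_result`.
#' @param pollutant which pollutant to map (default `"combined"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hrulci_result <- function(object, pollutant = "combined", ...) {
  rec <- object$records[object$records$pollutant == pollutant, ]
  val <- stats::setNames(rec$value, rec$hru_id)
  m <- matrix(val[as.character(object$hrus$labels)],
              nrow(object$hrus$labels))
  df <- grid_df(m, object$hrus$cell_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste("HRULCI", pollutant)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
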