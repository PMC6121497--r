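#' Location-weighted landscape contrast index per HRU
#'
#' The per-unit index is the normalized generation/inhibition weight times
#' the HRU area in hectares: `HRULCI_i = W_i * A_i`.  The companion column
#' `per_area_index` reports the raw (un-normalized) weight, i.e. the index
#' per unit area relative to the standard-farmland baseline of 1: values
#' above 1 mark units that export non-point source pollutants more readily
#' than standard farmland, values below 1 units that inhibit transmission.
#'
#' @param weights long tibble from [hru_weights()] (needs `hru_id`,
#'   `pollutant`, `w_raw`).
#' @param areas_ha named numeric vector or tibble (`hru_id`, `area_ha`)
#'   giving each HRU's area in hectares.
#' @return Tibble: `hru_id`, `pollutant`, `w_raw`, `weight` (normalized per
#'   pollutant), `area_ha`, `value` (= `weight * area_ha`) and
#'   `per_area_index` (= `w_raw`).
#' @export
hrulci <- function(weights, areas_ha) {
  if (is.data.frame(areas_ha)) {
    areas <- stats::setNames(areas_ha$area_ha, areas_ha$hru_id)
  } else {
    areas <- areas_ha
  }
  a <- as.numeric(areas[as.character(weights$hru_id)])
  if (anyNA(a)) stop("missing area for some HRU(s)", call. = FALSE)
  if (any(a <= 0)) stop("HRU areas must be positive", call. = FALSE)
  if (any(weights$w_raw < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  weights |>
    dplyr::mutate(area_ha = a) |>
    dplyr::group_by(.data$pollutant) |>
    dplyr::mutate(weight = normalize_weights(.data$w_raw)) |>
    dplyr::ungroup() |>
    dplyr::mutate(value = .data$weight * .data$area_ha,
                  per_area_index = .data$w_raw) |>
    dplyr::select("hru_id", "pollutant", "w_raw", "weight", "area_ha",
                  "value", "per_area_index")
}

#' Combine pollutant indices per HRU
#'
#' The multi-pollutant index of an HRU is the plain sum of its
#' per-pollutant indices.  The per-pollutant rows are kept; the combined
#' value is appended as pollutant `"combined"`.
#'
#' @param records tibble from [hrulci()].
#' @return The input with one extra row per HRU (`pollutant = "combined"`,
#'   `value` = sum over pollutants; weight columns are `NA`).
#' @export
combine_pollutants <- function(records) {
  combined <- records |>
    dplyr::group_by(.data$hru_id) |>
    dplyr::summarise(
      pollutant = "combined",
      w_raw = NA_real_,
      weight = NA_real_,
      area_ha = .data$area_ha[1],
      value = sum(.data$value),
      per_area_index = NA_real_,
      .groups = "drop"
    )
  dplyr::bind_rows(records, combined)
}

#' Aggregate HRU indices to sub-basins
#'
#' The sub-basin index is the sum of its member HRU indices; higher values
#' mean greater spread of non-point source pollution within that
#' sub-basin.  Sub-basins are ranked per pollutant (rank 1 = highest).
#'
#' @param records tibble from [hrulci()] or [combine_pollutants()].
#' @param hru_table tibble with `hru_id` and `subbasin_id` (e.g.
#'   `hrus$table`).
#' @return Tibble: `subbasin_id`, `pollutant`, `value`, `n_hru`, `rank`.
#' @export
subbasin_index <- function(records, hru_table) {
  sb <- stats::setNames(hru_table$subbasin_id, hru_table$hru_id)
  ids <- sb[as.character(records$hru_id)]
  if (anyNA(ids)) {
    stop("record(s) reference HRU(s) absent from `hru_table`",
         call. = FALSE)
  }
  records |>
    dplyr::mutate(subbasin_id = as.integer(ids)) |>
    dplyr::group_by(.data$subbasin_id, .data$pollutant) |>
    dplyr::summarise(value = sum(.data$value),
                     n_hru = dplyr::n_distinct(.data$hru_id),
                     .groups = "drop") |>
    dplyr::group_by(.data$pollutant) |>
    dplyr::mutate(rank = rank(-.data$value, ties.method = "min")) |>
    dplyr::ungroup()
}

#' Source or sink role of a land-use class
#'
#' Under source-sink landscape theory, residential land, cultivated land
#' and orchards generate and accelerate non-point source pollution
#' (sources), while forestland, water and unused land intercept or absorb
#' pollutants in transit (sinks).
#'
#' @param code land-use code(s).
#' @param legend named integer legend; names must identify the six classes
#'   (forestland, residential land, cultivated land, water, unused land,
#'   orchards).
#' @return Character vector of `"source"` / `"sink"`.
#' @export
classify_source_sink <- function(code, legend) {
  nm <- names(legend)[match(code, legend)]
  if (anyNA(nm)) {
    stop("land-use code(s) not in legend: ",
         paste(unique(code[is.na(nm)]), collapse = ", "), call. = FALSE)
  }
  role <- dplyr::case_when(
    grepl("cultivat|residen|orchard", nm, ignore.case = TRUE) ~ "source",
    grepl("forest|water|unused", nm, ignore.case = TRUE) ~ "sink",
    TRUE ~ NA_character_
  )
  if (anyNA(role)) {
    stop("cannot assign source/sink role to class(es): ",
         paste(unique(nm[is.na(role)]), collapse = ", "), call. = FALSE)
  }
  role
}

#' Land-use change between two dates
#'
#' Cross-tabulates the areas (hectares) of every from-class/to-class
#' combination over the cells that carry data on both dates, together with
#' each date's class shares in percent.
#'
#' @param grid_a,grid_b aligned `lci_catgrid`s with a common legend.
#' @return List with `matrix_ha` (classes x classes area matrix),
#'   `transitions` (long tibble: `from`, `to`, `area_ha`, `percent_of_a`)
#'   and `shares` (tibble: `class`, `share_a_pct`, `share_b_pct`).
#' @export
landuse_change <- function(grid_a, grid_b) {
  assert_aligned(a = grid_a, b = grid_b)
  if (!identical(sort(grid_a$legend), sort(grid_b$legend))) {
    stop("the two dates use different legends", call. = FALSE)
  }
  ok <- !is.na(grid_a$values) & !is.na(grid_b$values)
  lv <- sort(grid_a$legend)
  f_a <- factor(grid_a$values[ok], levels = lv, labels = names(lv))
  f_b <- factor(grid_b$values[ok], levels = lv, labels = names(lv))
  cell_ha <- grid_a$cell_size^2 / 1e4
  m <- table(f_a, f_b) * cell_ha
  total <- sum(m)
  trans <- as.data.frame(m, stringsAsFactors = FALSE) |>
    stats::setNames(c("from", "to", "area_ha")) |>
    tibble::as_tibble() |>
    dplyr::mutate(percent_of_a = .data$area_ha / total * 100)
  shares <- tibble::tibble(
    class = names(lv),
    share_a_pct = as.numeric(rowSums(m)) / total * 100,
    share_b_pct = as.numeric(colSums(m)) / total * 100
  )
  list(matrix_ha = unclass(m), transitions = trans, shares = shares)
}

#' Overall accuracy and Cohen's kappa from a confusion matrix
#'
#' @param confusion square matrix of counts, reference classes in rows,
#'   mapped classes in columns.
#' @return Tibble with `overall_accuracy_pct` and `kappa` (`NA` with a
#'   warning when chance agreement is exactly 1).
#' @export
accuracy_from_confusion <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square",
                               call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix is empty", call. = FALSE)
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps * 4) {
    warning("chance agreement is 1; kappa undefined", call. = FALSE)
    NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  tibble::tibble(overall_accuracy_pct = 100 * p_o, kappa = kappa)
}
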