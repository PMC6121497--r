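#' Raster grid objects
#'
#' A `lci_grid` is a minimal in-memory raster: a numeric matrix of cell
#' values (row 1 = northern-most row), a cell size in meters, and an origin
#' (the x/y map coordinate of the lower-left corner).  Missing cells are
#' stored as `NA`; all arithmetic in the package skips and propagates them.
#' The model is deliberately CRS-agnostic: every computation in the pipeline
#' only needs the cell size, so projection metadata is neither stored nor
#' interpreted.
#'
#' A `lci_catgrid` additionally constrains values to positive integer class
#' codes and carries a `legend`, a named integer vector mapping class names
#' to codes (e.g. `c(forestland = 1L)`).  Code 0 is reserved and illegal.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size edge length of a cell in meters (> 0).
#' @param origin numeric length-2, map x/y of the lower-left corner.
#' @param legend named integer vector of class codes (categorical grids).
#' @return A `lci_grid` (or `lci_catgrid`) object.
#' @examples
#' g <- grid_create(matrix(1:9, 3), cell_size = 30)
#' cat_g <- catgrid_create(matrix(1L, 2, 2), 30, legend = c(forestland = 1L))
#' @export
grid_create <- function(values, cell_size, origin = c(0, 0)) {
  stopifnot(is.matrix(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "lci_grid"
  )
}

#' @rdname grid_create
#' @export
catgrid_create <- function(values, cell_size, legend, origin = c(0, 0)) {
  stopifnot(is.matrix(values))
  v <- values[!is.na(values)]
  if (length(v) && any(v != round(v))) {
    stop("categorical grid values must be integers", call. = FALSE)
  }
  if (!is.integer(values)) {
    storage.mode(values) <- "integer"
  }
  legend <- as.integer(legend) |> stats::setNames(names(legend))
  if (is.null(names(legend)) || any(!nzchar(names(legend)))) {
    stop("`legend` must be a named integer vector", call. = FALSE)
  }
  if (any(legend < 1L)) {
    stop("legend codes must be positive integers (0 is reserved for nodata)",
         call. = FALSE)
  }
  present <- unique(values[!is.na(values)])
  missing_codes <- setdiff(present, legend)
  if (length(missing_codes)) {
    stop("codes not in legend: ", paste(missing_codes, collapse = ", "),
         call. = FALSE)
  }
  g <- grid_create(values, cell_size, origin)
  g$legend <- legend
  class(g) <- c("lci_catgrid", class(g))
  g
}

#' @export
print.lci_grid <- function(x, ...) {
  kind <- if (inherits(x, "lci_catgrid")) "categorical grid" else "grid"
  cat(sprintf("<%s> %d x %d cells, cell size %g m, %d nodata\n",
              kind, nrow(x$values), ncol(x$values), x$cell_size,
              sum(is.na(x$values))))
  if (inherits(x, "lci_catgrid")) {
    cat("legend:", paste(sprintf("%s=%d", names(x$legend), x$legend),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.lci_grid <- function(x) dim(x$values)

#' Nodata mask of a grid
#'
#' @param grid a `lci_grid`.
#' @return Logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

#' Read a raster from an ESRI ASCII grid file
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by row-major cell
#' values, northern row first.  `kind = "categorical"` additionally requires
#' integer cell values and attaches a legend.
#'
#' @param path file path to an `.asc` file.
#' @param kind `"continuous"` or `"categorical"`.
#' @param legend named integer vector of class codes; required when
#'   `kind = "categorical"`.  Codes present in the file but absent from the
#'   legend are an error.
#' @return A [grid_create()] or [catgrid_create()] object.
#' @export
read_raster <- function(path, kind = c("continuous", "categorical"),
                        legend = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("raster file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header fields): ", path,
         call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  n_header <- sum(names(hdr) %in% c("ncols", "nrows", "xllcorner",
                                    "yllcorner", "cellsize", "nodata_value"))
  vals <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    stop("cell count does not match header in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  origin <- c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0)
  if (kind == "continuous") {
    return(grid_create(m, hdr$cellsize, origin))
  }
  if (any(m[!is.na(m)] != round(m[!is.na(m)]))) {
    stop("non-integer values in categorical raster: ", path, call. = FALSE)
  }
  if (is.null(legend)) {
    codes <- sort(unique(as.integer(m[!is.na(m)])))
    legend <- stats::setNames(codes, paste0("class_", codes))
  }
  catgrid_create(m, hdr$cellsize, legend, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a raster to an ESRI ASCII grid file
#'
#' Continuous grids are written with full double precision (round-trips
#' within 1e-6); categorical grids write bare integers.  Nodata cells are
#' written as -9999.
#'
#' @param grid a `lci_grid` or `lci_catgrid`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "lci_grid"))
  v <- grid$values
  nodata <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  fmt <- if (inherits(grid, "lci_catgrid")) "%d" else "%.10g"
  body <- apply(v, 1L, function(row) {
    row_chr <- ifelse(is.na(row), as.character(nodata), sprintf(fmt, row))
    paste(row_chr, collapse = " ")
  })
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write raster to ", path, call. = FALSE)
  invisible(path)
}

#' Check that a set of grids shares one geometry
#'
#' All layers that are overlaid in the pipeline (DEM, land use, soil,
#' precipitation, ...) must agree in shape, cell size (tolerance 1e-6 m) and
#' origin (tolerance 1e-3 map units).
#'
#' @param ... grids, or a single list of grids; give names to get them in
#'   error messages.
#' @return Invisibly `TRUE`; mismatches raise an error naming the layer.
#' @export
assert_aligned <- function(...) {
  grids <- list(...)
  if (length(grids) == 1L && !inherits(grids[[1]], "lci_grid")) {
    grids <- grids[[1]]
  }
  stopifnot(length(grids) >= 1L)
  nms <- names(grids) %||% rep("", length(grids))
  nms <- ifelse(nzchar(nms), nms, paste0("layer_", seq_along(grids)))
  ref <- grids[[1]]
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values))) {
      stop(sprintf("grid '%s' has shape %dx%d, expected %dx%d", nms[i],
                   nrow(g$values), ncol(g$values),
                   nrow(ref$values), ncol(ref$values)), call. = FALSE)
    }
    if (abs(g$cell_size - ref$cell_size) > 1e-6) {
      stop(sprintf("grid '%s' has cell size %g, expected %g", nms[i],
                   g$cell_size, ref$cell_size), call. = FALSE)
    }
    if (any(abs(g$origin - ref$origin) > 1e-3)) {
      stop(sprintf("grid '%s' origin differs from '%s'", nms[i], nms[1]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# 1-D squared distance transform (lower envelope of parabolas), the core of
# the exact 2-D transform below.  f is a vector of squared distances.
dt_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)          # locations of parabolas in the lower envelope
  z <- numeric(n + 1L)     # boundaries between parabolas
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in seq_len(n)[-1L]) {
    if (!is.finite(f[q]) && f[q] > 0) {
      # Inf parabola never contributes to the envelope unless all are Inf
      next
    }
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

#' Euclidean distance to the nearest marked cell
#'
#' Exact center-to-center Euclidean distance from every cell to the nearest
#' `TRUE` cell of `mask`, computed with the two-pass separable parabola
#' envelope algorithm (exact, O(n) per row/column).  Used to build the
#' effective-distance-to-water surface for the distance correction factor.
#'
#' @param mask logical matrix with at least one `TRUE` cell.
#' @param cell_size cell edge length in meters.
#' @return A [grid_create()] grid of distances in meters; 0 on the mask.
#' @export
euclidean_distance_to <- function(mask, cell_size) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask, na.rm = TRUE)) {
    stop("distance transform needs at least one TRUE cell", call. = FALSE)
  }
  f <- matrix(Inf, nrow(mask), ncol(mask))
  f[which(mask)] <- 0
  # pass 1: along columns
  for (j in seq_len(ncol(f))) f[, j] <- dt_1d(f[, j])
  # pass 2: along rows
  for (i in seq_len(nrow(f))) f[i, ] <- dt_1d(f[i, ])
  grid_create(sqrt(f) * cell_size, cell_size)
}
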