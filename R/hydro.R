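# D8 neighbour scheme.  Directions are coded 1..8 in the fixed order
# E, SE, S, SW, W, NW, N, NE (ties in steepest descent resolved by this
# order); 0 marks an outlet.  Rows increase southwards, columns eastwards.
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- sqrt(D8_DR^2 + D8_DC^2)
D8_NAMES <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")

# simple binary min-heap keyed on (priority, insertion order) so that the
# priority flood pops equal elevations first-in-first-out
heap_new <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$prio <- numeric(capacity)
  env$ord <- numeric(capacity)
  env$item <- integer(capacity)
  env$n <- 0L
  env$pushed <- 0
  env
}

heap_less <- function(h, a, b) {
  h$prio[a] < h$prio[b] ||
    (h$prio[a] == h$prio[b] && h$ord[a] < h$ord[b])
}

heap_push <- function(h, priority, item) {
  h$n <- h$n + 1L
  h$pushed <- h$pushed + 1
  i <- h$n
  h$prio[i] <- priority; h$ord[i] <- h$pushed; h$item[i] <- item
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(h, i, p)) {
      tmp <- c(h$prio[p], h$ord[p], h$item[p])
      h$prio[p] <- h$prio[i]; h$ord[p] <- h$ord[i]; h$item[p] <- h$item[i]
      h$prio[i] <- tmp[1]; h$ord[i] <- tmp[2]; h$item[i] <- as.integer(tmp[3])
      i <- p
    } else break
  }
}

heap_pop <- function(h) {
  top <- h$item[1L]
  n <- h$n
  h$prio[1L] <- h$prio[n]; h$ord[1L] <- h$ord[n]; h$item[1L] <- h$item[n]
  h$n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    smallest <- i
    if (l <= h$n && heap_less(h, l, smallest)) smallest <- l
    if (r <= h$n && heap_less(h, r, smallest)) smallest <- r
    if (smallest == i) break
    tmp <- c(h$prio[smallest], h$ord[smallest], h$item[smallest])
    h$prio[smallest] <- h$prio[i]; h$ord[smallest] <- h$ord[i]
    h$item[smallest] <- h$item[i]
    h$prio[i] <- tmp[1]; h$ord[i] <- tmp[2]; h$item[i] <- as.integer(tmp[3])
    i <- smallest
  }
  top
}

#' Fill depressions in a DEM
#'
#' Priority-flood filling: the surface is flooded inward from the grid
#' border (and from cells bordering nodata), visiting cells lowest-first, so
#' every cell ends at least as high as the spill elevation of any depression
#' containing it.  A small epsilon gradient (default 1e-6 m per step) is
#' imposed on filled flats so that steepest descent is defined everywhere
#' and the subsequent D8 field is guaranteed acyclic.
#'
#' @param dem a `lci_grid` of elevations (m).
#' @param eps elevation increment applied along filled flats.
#' @return A `lci_grid`; values >= the input everywhere, no interior cell a
#'   strict local minimum among its non-nodata neighbours.
#' @export
fill_sinks <- function(dem, eps = 1e-6) {
  stopifnot(inherits(dem, "lci_grid"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (!any(!is.na(z))) stop("DEM is entirely nodata", call. = FALSE)
  filled <- matrix(NA_real_, nr, nc)
  closed <- is.na(z)
  h <- heap_new(nr * nc)
  # seed: every non-nodata cell on the grid border or touching nodata
  for (idx in seq_along(z)) {
    if (is.na(z[idx])) next
    r <- ((idx - 1L) %% nr) + 1L; c <- ((idx - 1L) %/% nr) + 1L
    on_edge <- r == 1L || r == nr || c == 1L || c == nc
    if (!on_edge) {
      for (k in 1:8) {
        rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
        if (is.na(z[(cc - 1L) * nr + rr])) { on_edge <- TRUE; break }
      }
    }
    if (on_edge) {
      heap_push(h, z[idx], idx)
      closed[idx] <- TRUE
      filled[idx] <- z[idx]
    }
  }
  while (h$n > 0L) {
    cur <- heap_pop(h)
    r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      nb <- (cc - 1L) * nr + rr
      if (closed[nb]) next
      closed[nb] <- TRUE
      filled[nb] <- max(z[nb], filled[cur] + eps)
      heap_push(h, filled[nb], nb)
    }
  }
  grid_create(filled, dem$cell_size, dem$origin)
}

#' D8 flow directions
#'
#' Every cell drains to its steepest-descent neighbour of eight (drop
#' divided by center distance, diagonals sqrt(2) further).  Ties pick the
#' first direction in the fixed order E, SE, S, SW, W, NW, N, NE.  Cells
#' with no lower neighbour are outlets (direction 0); after [fill_sinks()]
#' these can only occur on the drainage boundary.
#'
#' @param filled_dem a depression-filled `lci_grid`.
#' @return A `lci_flowfield`: list with `direction` (integer matrix, codes
#'   1..8 as above, 0 = outlet, `NA` = nodata), `receiver` (linear index of
#'   the downstream cell, `NA` for outlets/nodata) and `cell_size`.
#' @export
d8_flow_direction <- function(filled_dem) {
  stopifnot(inherits(filled_dem, "lci_grid"))
  z <- filled_dem$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  best_drop <- matrix(-Inf, nr, nc)
  direction <- matrix(NA_integer_, nr, nc)
  receiver <- matrix(NA_integer_, nr, nc)
  for (k in 1:8) {
    nb <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + D8_DR[k]; cs <- seq_len(nc) + D8_DC[k]
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    nb[ok_r, ok_c] <- z[rs[ok_r], cs[ok_c]]
    drop <- (z - nb) / D8_DIST[k]
    better <- !is.na(z) & !is.na(drop) & drop > best_drop
    # strict > keeps the first direction in the E..NE order on ties
    best_drop[better] <- drop[better]
    direction[better] <- k
    rcv <- matrix(seq_len(n), nr, nc)
    rcv_k <- matrix(NA_integer_, nr, nc)
    rcv_k[ok_r, ok_c] <- rcv[rs[ok_r], cs[ok_c]]
    receiver[better] <- rcv_k[better]
  }
  no_drop <- !is.na(z) & (is.na(direction) | best_drop <= 0)
  direction[no_drop] <- 0L
  receiver[no_drop] <- NA_integer_
  structure(
    list(direction = direction, receiver = receiver,
         cell_size = filled_dem$cell_size),
    class = "lci_flowfield"
  )
}

#' @export
print.lci_flowfield <- function(x, ...) {
  cat(sprintf("<D8 flow field> %d x %d, %d outlet cell(s)\n",
              nrow(x$direction), ncol(x$direction),
              sum(x$direction == 0L, na.rm = TRUE)))
  invisible(x)
}

# cells in drainage (topological) order, upstream before downstream;
# errors if the receiver graph has a cycle
topological_order <- function(flow) {
  dir <- flow$direction
  rcv <- flow$receiver
  cells <- which(!is.na(dir))
  indeg <- integer(length(dir))
  tab <- table(rcv[cells])
  indeg[as.integer(names(tab))] <- as.integer(tab)
  queue <- cells[indeg[cells] == 0L]
  out <- integer(length(cells))
  head <- 1L; tail <- length(queue)
  out[seq_len(tail)] <- queue
  while (head <= tail) {
    cur <- out[head]; head <- head + 1L
    r <- rcv[cur]
    if (!is.na(r)) {
      indeg[r] <- indeg[r] - 1L
      if (indeg[r] == 0L) {
        tail <- tail + 1L
        out[tail] <- r
      }
    }
  }
  if (tail != length(cells)) {
    stop("flow field contains a cycle", call. = FALSE)
  }
  out
}

#' Flow accumulation
#'
#' Number of cells draining through each cell, itself included, computed in
#' topological order over the D8 receiver graph.
#'
#' @param flow a `lci_flowfield`.
#' @return A `lci_grid` of counts (>= 1 on drainable cells).
#' @export
flow_accumulation <- function(flow) {
  stopifnot(inherits(flow, "lci_flowfield"))
  acc <- matrix(NA_real_, nrow(flow$direction), ncol(flow$direction))
  cells <- which(!is.na(flow$direction))
  acc[cells] <- 1
  for (cur in topological_order(flow)) {
    r <- flow$receiver[cur]
    if (!is.na(r)) acc[r] <- acc[r] + acc[cur]
  }
  grid_create(acc, flow$cell_size)
}

#' Extract the stream network by accumulation threshold
#'
#' @param acc accumulation grid from [flow_accumulation()].
#' @param threshold minimum contributing-cell count (>= 1) for a cell to be
#'   part of the stream network.
#' @return Logical matrix, `TRUE` on stream cells.
#' @export
extract_streams <- function(acc, threshold) {
  stopifnot(inherits(acc, "lci_grid"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1) {
    stop("`threshold` must be a single count >= 1", call. = FALSE)
  }
  m <- !is.na(acc$values) & acc$values >= threshold
  m
}

#' Delineate sub-basins from a stream network
#'
#' The stream network is split into segments at junctions (stream cells
#' receiving flow from two or more stream cells); each stream head, each
#' junction, and each outlet starts a new segment.  Every drainable cell is
#' then labelled by the segment its flow path first reaches, giving a
#' partition of the basin into sub-basins, one per stream segment.
#'
#' @param flow a `lci_flowfield`.
#' @param streams logical stream mask from [extract_streams()].
#' @return A `lci_subbasins`: list with `labels` (`lci_catgrid` of sub-basin
#'   ids), `outlets` (tibble: `subbasin_id`, `cell` linear index) and
#'   `cell_size`.
#' @export
delineate_subbasins <- function(flow, streams) {
  stopifnot(inherits(flow, "lci_flowfield"), is.logical(streams))
  if (!any(streams, na.rm = TRUE)) {
    stop("stream mask is empty", call. = FALSE)
  }
  dir <- flow$direction
  rcv <- flow$receiver
  is_stream <- streams
  is_stream[is.na(dir)] <- FALSE
  # outlets that are not stream cells still terminate flow paths; treat
  # them as one-cell stream segments so the labels partition the basin
  extra_outlets <- which(!is.na(dir) & dir == 0L & !is_stream)
  is_stream[extra_outlets] <- TRUE
  stream_cells <- which(is_stream)
  # stream inflow counts
  inflow <- integer(length(dir))
  from_stream <- stream_cells[!is.na(rcv[stream_cells])]
  to <- rcv[from_stream]
  on_stream <- is_stream[to]
  tab <- table(to[on_stream])
  inflow[as.integer(names(tab))] <- as.integer(tab)
  # assign segment ids walking the stream network in topological order
  seg <- integer(length(dir))
  next_seg <- 0L
  ord <- topological_order(flow)
  ord_stream <- ord[is_stream[ord]]
  for (cur in ord_stream) {
    ups <- inflow[cur]
    if (ups == 1L) {
      # find the single upstream stream cell's segment: it was recorded
      # when that cell was processed (stored in seg via receiver pass) --
      # handled below by propagation, so mark for inheritance
      seg[cur] <- -1L
    } else {
      next_seg <- next_seg + 1L
      seg[cur] <- next_seg
    }
  }
  # propagate inherited segments downstream along the stream network
  for (cur in ord_stream) {
    r <- rcv[cur]
    if (!is.na(r) && is_stream[r] && seg[r] == -1L) {
      seg[r] <- seg[cur]
    }
  }
  if (any(seg[ord_stream] <= 0L)) {
    stop("internal error: unlabelled stream segment", call. = FALSE)
  }
  # every cell takes the segment of the first stream cell on its flow path;
  # walk in reverse topological order so downstream labels already exist
  label <- matrix(NA_integer_, nrow(dir), ncol(dir))
  label[is_stream] <- seg[which(is_stream)]
  for (cur in rev(ord)) {
    if (!is.na(label[cur])) next
    r <- rcv[cur]
    if (!is.na(r) && !is.na(label[r])) label[cur] <- label[r]
  }
  # any remaining unlabelled cells drain to a non-stream outlet; those were
  # promoted above, so everything drainable is labelled
  seg_ids <- sort(unique(label[!is.na(label)]))
  legend <- stats::setNames(seg_ids, paste0("subbasin_", seg_ids))
  labels_grid <- catgrid_create(label, flow$cell_size, legend)
  # outlet of a segment: its cell whose receiver leaves the segment
  outlet_cell <- vapply(seg_ids, function(s) {
    cells <- which(!is.na(label) & label == s & is_stream)
    leaves <- vapply(cells, function(cc) {
      r <- rcv[cc]
      is.na(r) || is.na(label[r]) || label[r] != s || !is_stream[r]
    }, logical(1))
    cells[which(leaves)[1]]
  }, integer(1))
  structure(
    list(labels = labels_grid,
         outlets = tibble::tibble(subbasin_id = as.integer(seg_ids),
                                  cell = outlet_cell),
         cell_size = flow$cell_size),
    class = "lci_subbasins"
  )
}

#' @export
print.lci_subbasins <- function(x, ...) {
  cat(sprintf("<sub-basins> %d sub-basin(s)\n", nrow(x$outlets)))
  invisible(x)
}

#' Build hydrological response units
#'
#' An HRU is a connected region with a single land-use class and a single
#' soil class inside one sub-basin: the connected components of the
#' three-way overlay of sub-basin, land-use and soil layers.
#'
#' @param subbasins a `lci_subbasins`.
#' @param landuse,soil aligned `lci_catgrid` layers.
#' @param connectivity component connectivity (default 8).
#' @return A `lci_hrus`: list with `labels` (integer matrix of HRU ids) and
#'   `table` (tibble: `hru_id`, `subbasin_id`, `landuse_code`, `soil_code`,
#'   `ncell`, `area_m2`, `area_ha`).
#' @export
build_hrus <- function(subbasins, landuse, soil, connectivity = 8) {
  stopifnot(inherits(subbasins, "lci_subbasins"))
  assert_aligned(subbasin = subbasins$labels, landuse = landuse, soil = soil)
  sb <- subbasins$labels$values
  lu <- landuse$values
  so <- soil$values
  ok <- !is.na(sb) & !is.na(lu) & !is.na(so)
  # encode the (subbasin, landuse, soil) triple as one categorical code
  key <- matrix(NA_integer_, nrow(sb), ncol(sb))
  base_lu <- max(lu, na.rm = TRUE) + 1L
  base_so <- max(so, na.rm = TRUE) + 1L
  key[ok] <- ((sb[ok] - 1L) * base_lu + lu[ok]) * base_so + so[ok] + 1L
  codes <- sort(unique(key[!is.na(key)]))
  kg <- catgrid_create(key, subbasins$cell_size,
                       stats::setNames(codes, paste0("k", codes)))
  ps <- label_patches(kg, connectivity)
  lab <- ps$labels
  first_cell <- match(ps$patches$patch_id, lab)
  cs <- subbasins$cell_size
  tab <- tibble::tibble(
    hru_id = ps$patches$patch_id,
    subbasin_id = as.integer(sb[first_cell]),
    landuse_code = as.integer(lu[first_cell]),
    soil_code = as.integer(so[first_cell]),
    ncell = ps$patches$ncell,
    area_m2 = ps$patches$ncell * cs^2,
    area_ha = ps$patches$ncell * cs^2 / 1e4
  )
  structure(
    list(labels = lab, table = tab, cell_size = cs,
         landuse_legend = landuse$legend),
    class = "lci_hrus"
  )
}

#' @export
print.lci_hrus <- function(x, ...) {
  cat(sprintf("<HRUs> %d unit(s) in %d sub-basin(s)\n",
              nrow(x$table), length(unique(x$table$subbasin_id))))
  invisible(x)
}

# shared rook boundary length (in cell edges) between HRU `id` and each of
# its neighbouring HRUs
hru_neighbours <- function(labels, id) {
  nr <- nrow(labels); nc <- ncol(labels)
  others <- integer(0)
  collect <- function(a, b) {
    sel <- !is.na(a) & !is.na(b) &
      ((a == id & b != id) | (b == id & a != id))
    if (any(sel)) {
      others <<- c(others, ifelse(a[sel] == id, b[sel], a[sel]))
    }
  }
  if (nc > 1L) collect(labels[, -nc], labels[, -1L])
  if (nr > 1L) collect(labels[-nr, ], labels[-1L, ])
  if (length(others) == 0L) return(integer(0))
  t <- table(others)
  stats::setNames(as.integer(t), names(t))
}

#' Merge undersized HRUs into their neighbours
#'
#' Repeatedly absorbs every HRU below `min_area` into the neighbouring HRU
#' of the same sub-basin with which it shares the longest boundary (ties:
#' larger neighbour, then lower id).  Absorbed cells adopt the absorber's
#' land-use and soil codes, so the single-code invariant is preserved and
#' total area is conserved.  An undersized HRU with no same-sub-basin
#' neighbour is kept as-is with a warning.
#'
#' @param hrus a `lci_hrus`.
#' @param min_area minimum HRU area in m2.
#' @return A `lci_hrus` with every remaining unit at or above `min_area`
#'   (except isolated ones noted above).
#' @export
merge_small_hrus <- function(hrus, min_area) {
  stopifnot(inherits(hrus, "lci_hrus"))
  tab <- hrus$table
  if (!any(tab$area_m2 >= min_area)) {
    stop("no HRU reaches `min_area`; nothing can absorb the rest",
         call. = FALSE)
  }
  labels <- hrus$labels
  kept <- tab
  skip <- integer(0)
  repeat {
    small <- kept[kept$area_m2 < min_area & !(kept$hru_id %in% skip), ]
    if (nrow(small) == 0L) break
    victim <- small$hru_id[which.min(small$area_m2)]
    vrow <- kept[kept$hru_id == victim, ]
    nb <- hru_neighbours(labels, victim)
    same_sb <- kept$hru_id[kept$subbasin_id == vrow$subbasin_id]
    nb <- nb[names(nb) %in% as.character(setdiff(same_sb, victim))]
    if (length(nb) == 0L) {
      warning("HRU ", victim, " is below min_area but has no neighbour in ",
              "its sub-basin; kept unmerged", call. = FALSE)
      skip <- c(skip, victim)
      next
    }
    cand <- as.integer(names(nb)[nb == max(nb)])
    if (length(cand) > 1L) {
      areas <- kept$area_m2[match(cand, kept$hru_id)]
      cand <- cand[areas == max(areas)]
      cand <- min(cand)
    }
    absorber <- cand
    labels[labels == victim] <- absorber
    arow <- which(kept$hru_id == absorber)
    kept$ncell[arow] <- kept$ncell[arow] + vrow$ncell
    kept$area_m2[arow] <- kept$area_m2[arow] + vrow$area_m2
    kept$area_ha[arow] <- kept$area_ha[arow] + vrow$area_ha
    kept <- kept[kept$hru_id != victim, ]
  }
  structure(
    list(labels = labels, table = kept, cell_size = hrus$cell_size,
         landuse_legend = hrus$landuse_legend),
    class = "lci_hrus"
  )
}
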