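#' Label patches of a categorical raster
#'
#' A patch is a maximal set of same-class cells connected under the chosen
#' neighbourhood rule (8-neighbour queen connectivity by default, the usual
#' convention for patch delineation; 4-neighbour rook available).  Nodata
#' cells belong to no patch.
#'
#' @param grid a `lci_catgrid`.
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return A `lci_patchset`: list with `labels` (integer matrix, `NA` on
#'   nodata), `patches` (tibble: `patch_id`, `class_code`, `ncell`),
#'   `connectivity` and `cell_size`.
#' @export
label_patches <- function(grid, connectivity = 8) {
  stopifnot(inherits(grid, "lci_catgrid"), connectivity %in% c(4, 8))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  labels <- matrix(NA_integer_, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  next_id <- 0L
  ids <- integer(); codes <- integer(); sizes <- integer()
  stack <- integer(nr * nc)
  for (start in seq_along(v)) {
    if (is.na(v[start]) || !is.na(labels[start])) next
    next_id <- next_id + 1L
    code <- v[start]
    top <- 1L
    stack[1L] <- start
    labels[start] <- next_id
    n_in_patch <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      n_in_patch <- n_in_patch + 1L
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]; c <- c0 + dc[k]
        if (r < 1L || r > nr || c < 1L || c > nc) next
        idx <- (c - 1L) * nr + r
        if (is.na(labels[idx]) && !is.na(v[idx]) && v[idx] == code) {
          labels[idx] <- next_id
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
    ids <- c(ids, next_id); codes <- c(codes, code)
    sizes <- c(sizes, n_in_patch)
  }
  structure(
    list(
      labels = labels,
      patches = tibble::tibble(patch_id = ids, class_code = codes,
                               ncell = sizes),
      connectivity = connectivity,
      cell_size = grid$cell_size,
      legend = grid$legend
    ),
    class = "lci_patchset"
  )
}

#' @export
print.lci_patchset <- function(x, ...) {
  cat(sprintf("<patch set> %d patches, %d classes, connectivity %d\n",
              nrow(x$patches), length(unique(x$patches$class_code)),
              x$connectivity))
  invisible(x)
}

# per-cell count of the 4 rook neighbours that lie outside the cell's class
# (different class, nodata, or beyond the grid border)
edge_count_matrix <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  cnt <- matrix(0L, nr, nc)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in shifts) {
    nb <- matrix(NA, nr, nc)
    rs <- seq_len(nr) + s[1]; cs <- seq_len(nc) + s[2]
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    nb[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
    differs <- is.na(nb) | nb != v
    differs[is.na(differs)] <- TRUE
    cnt <- cnt + differs
  }
  cnt[is.na(v)] <- NA_integer_
  cnt
}

#' Per-patch area and perimeter
#'
#' Area is cell count times the squared cell size.  Perimeter counts every
#' cell edge shared with a different class, a nodata cell, or the grid
#' border, times the cell size.
#'
#' @param patchset result of [label_patches()].
#' @return Tibble: `patch_id`, `class_code`, `ncell`, `area_m2`,
#'   `perimeter_m`.
#' @export
patch_geometry <- function(patchset) {
  stopifnot(inherits(patchset, "lci_patchset"))
  v <- class_matrix(patchset)
  cnt <- edge_count_matrix(v)
  lab <- patchset$labels
  per_cells <- rowsum(as.integer(cnt[!is.na(lab)]), lab[!is.na(lab)])
  per <- stats::setNames(per_cells[, 1], rownames(per_cells))
  cs <- patchset$cell_size
  dplyr::mutate(
    patchset$patches,
    area_m2 = .data$ncell * cs^2,
    perimeter_m = as.numeric(per[as.character(.data$patch_id)]) * cs
  )
}

# rebuild the class-code matrix from labels + patch table
class_matrix <- function(patchset) {
  lab <- patchset$labels
  code_of <- integer(max(patchset$patches$patch_id, 0L))
  code_of[patchset$patches$patch_id] <- patchset$patches$class_code
  v <- matrix(NA_integer_, nrow(lab), ncol(lab))
  ok <- !is.na(lab)
  v[ok] <- code_of[lab[ok]]
  v
}

#' Class adjacency table
#'
#' Lengths (meters) of shared cell edges between every pair of classes under
#' rook adjacency, each shared edge counted once.  Edges against nodata or
#' the grid border are tallied under pseudo-class `0`.
#'
#' @param grid a `lci_catgrid`.
#' @return Symmetric numeric matrix, dimnames = class codes plus `"0"`.
#' @export
adjacency_table <- function(grid) {
  stopifnot(inherits(grid, "lci_catgrid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  codes <- sort(unique(v[!is.na(v)]))
  all_codes <- c(0L, codes)
  lv <- as.character(all_codes)
  directed <- matrix(0, length(all_codes), length(all_codes),
                     dimnames = list(lv, lv))
  tally <- function(a, b) {
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
    directed <<- directed +
      table(factor(a, levels = all_codes), factor(b, levels = all_codes))
  }
  if (nc > 1L) tally(v[, -nc], v[, -1L])   # horizontal shared edges
  if (nr > 1L) tally(v[-nr, ], v[-1L, ])   # vertical shared edges
  # each directed entry is one shared edge; fold into a symmetric matrix
  e <- directed + t(directed)
  diag(e) <- diag(directed)
  # grid-border edges (one per cell side on the boundary) against class 0
  border <- c(v[1L, ], v[nr, ], v[, 1L], v[, nc])
  border[is.na(border)] <- 0L
  bt <- as.numeric(table(factor(border, levels = all_codes)))
  e[, 1L] <- e[, 1L] + bt
  e[1L, ] <- e[1L, ] + bt
  e["0", "0"] <- e["0", "0"] - sum(bt[1])  # class-0 border edges once
  e * grid$cell_size
}

#' Composition metrics: NP, PD and LPI
#'
#' NP is the patch count, PD the number of patches per 100 hectares, and LPI
#' the percentage of the landscape occupied by the largest patch.
#'
#' @param patchset result of [label_patches()].
#' @return Tibble with one row: `np`, `pd`, `lpi`.
#' @export
np_pd_lpi <- function(patchset) {
  stopifnot(inherits(patchset, "lci_patchset"))
  area_m2 <- sum(patchset$patches$ncell) * patchset$cell_size^2
  if (area_m2 <= 0) stop("landscape has zero area", call. = FALSE)
  area_ha <- area_m2 / 1e4
  np <- nrow(patchset$patches)
  tibble::tibble(
    np = np,
    pd = np / area_ha * 100,
    lpi = 100 * max(patchset$patches$ncell) * patchset$cell_size^2 / area_m2
  )
}

# total inter-class edge length in meters (each edge once); grid border and
# nodata edges are neutral and excluded
total_internal_edge <- function(grid) {
  e <- adjacency_table(grid)
  real <- setdiff(rownames(e), "0")
  em <- e[real, real, drop = FALSE]
  sum(em[upper.tri(em)])
}

#' Landscape shape index
#'
#' Total inter-class edge length divided by the circumference of a circle
#' with the same area as the landscape: `LSI = E / (2 * sqrt(pi * A))`.
#' A landscape consisting of a single class has no internal edge and LSI 0.
#'
#' @param grid a `lci_catgrid`.
#' @return LSI (dimensionless, >= 0).
#' @export
lsi <- function(grid) {
  stopifnot(inherits(grid, "lci_catgrid"))
  area_m2 <- sum(!is.na(grid$values)) * grid$cell_size^2
  if (area_m2 <= 0) stop("landscape has zero area", call. = FALSE)
  total_internal_edge(grid) / (2 * sqrt(pi * area_m2))
}

#' Area-weighted mean shape index
#'
#' The shape index of a patch is `0.25 * p / sqrt(a)` with perimeter `p` in
#' cell-edge units and area `a` in cells, so a square patch scores exactly
#' 1.  AWMSI weights each patch by its share of total patch area.
#'
#' @param patchset result of [label_patches()].
#' @return AWMSI (>= 1 for any non-empty landscape).
#' @export
awmsi <- function(patchset) {
  geom <- patch_geometry(patchset)
  if (nrow(geom) == 0L) stop("no patches", call. = FALSE)
  cs <- patchset$cell_size
  shape <- 0.25 * (geom$perimeter_m / cs) / sqrt(geom$ncell)
  sum(shape * geom$ncell) / sum(geom$ncell)
}

#' Mean Euclidean nearest-neighbour distance
#'
#' For each patch of a class with at least two patches, the minimum
#' center-to-center distance between any of its cells and any cell of
#' another patch of the same class.  ENN_MN averages these over all such
#' patches; classes with a single patch are excluded.  Returns `NA` when no
#' class has two patches (the metric is undefined there).
#'
#' @param patchset result of [label_patches()].
#' @return ENN_MN in meters, or `NA_real_`.
#' @export
enn_mn <- function(patchset) {
  stopifnot(inherits(patchset, "lci_patchset"))
  tab <- patchset$patches
  classes <- tab$class_code[duplicated(tab$class_code)] |> unique()
  if (length(classes) == 0L) return(NA_real_)
  lab <- patchset$labels
  enn <- numeric(0)
  for (cl in classes) {
    ids <- tab$patch_id[tab$class_code == cl]
    for (id in ids) {
      other_mask <- matrix(FALSE, nrow(lab), ncol(lab))
      other_mask[lab %in% setdiff(ids, id)] <- TRUE
      dist_g <- euclidean_distance_to(other_mask, patchset$cell_size)
      enn <- c(enn, min(dist_g$values[lab == id], na.rm = TRUE))
    }
  }
  mean(enn)
}

#' Interspersion and juxtaposition index
#'
#' Entropy of the inter-class edge-length distribution relative to its
#' maximum (all class pairs equally adjacent), as a percentage.  Needs at
#' least three classes; returns `NA` otherwise.
#'
#' @param grid a `lci_catgrid`, or a precomputed [adjacency_table()].
#' @return IJI in percent, or `NA_real_`.
#' @export
iji <- function(grid) {
  e <- if (inherits(grid, "lci_catgrid")) adjacency_table(grid) else grid
  real <- setdiff(rownames(e), "0")
  t_n <- length(real)
  if (t_n < 3L) return(NA_real_)
  em <- e[real, real, drop = FALSE]
  eik <- em[upper.tri(em)]
  e_total <- sum(eik)
  if (e_total <= 0) return(NA_real_)
  p <- eik[eik > 0] / e_total
  -sum(p * log(p)) / log(t_n * (t_n - 1) / 2) * 100
}

# maximum possible like-adjacency count for n cells of one class: the
# largest-square packing bound
max_like_adjacencies <- function(n_cells) {
  n <- floor(sqrt(n_cells))
  m <- n_cells - n * n
  base <- 2 * n * (n - 1)
  if (m == 0) base
  else if (m <= n) base + 2 * m - 1
  else base + 2 * m - 2
}

#' Aggregation index
#'
#' For each class, the realised fraction of the maximum possible number of
#' like adjacencies (rook rule, each adjacency counted once), as a percent:
#' `AI_i = 100 * g_ii / max_g_ii`.  A class packed into a solid block scores
#' 100, a perfectly dispersed class 0.  A single-cell class (max 0
#' adjacencies) is treated as fully aggregated.  The landscape value is the
#' area-weighted mean over classes.
#'
#' @param grid a `lci_catgrid`.
#' @return List with `class` (tibble: `class_code`, `g_ii`, `max_g_ii`,
#'   `ai`) and `landscape` (scalar percent).
#' @export
ai <- function(grid) {
  stopifnot(inherits(grid, "lci_catgrid"))
  v <- grid$values
  if (!any(!is.na(v))) stop("empty grid", call. = FALSE)
  codes <- sort(unique(v[!is.na(v)]))
  like <- stats::setNames(numeric(length(codes)), codes)
  count_like <- function(a, b) {
    same <- !is.na(a) & !is.na(b) & a == b
    tab <- table(factor(a[same], levels = codes))
    like <<- like + as.numeric(tab)
  }
  nr <- nrow(v); nc <- ncol(v)
  if (nc > 1L) count_like(v[, -nc], v[, -1L])
  if (nr > 1L) count_like(v[-nr, ], v[-1L, ])
  n_cells <- table(factor(v[!is.na(v)], levels = codes))
  max_g <- vapply(as.numeric(n_cells), max_like_adjacencies, numeric(1))
  ai_i <- ifelse(max_g > 0, 100 * like / max_g, 100)
  cls <- tibble::tibble(
    class_code = as.integer(codes),
    g_ii = as.numeric(like),
    max_g_ii = max_g,
    ai = as.numeric(ai_i)
  )
  list(class = cls,
       landscape = sum(ai_i * as.numeric(n_cells)) / sum(n_cells))
}

#' Landscape-level report of the eight pattern metrics
#'
#' Computes NP, PD, LPI, LSI, AWMSI, ENN_MN, IJI and AI on one categorical
#' raster, matching the individual metric functions exactly.  Metrics that
#' are undefined for the landscape at hand (ENN_MN with no repeated class,
#' IJI with fewer than three classes) are reported as `NA`.
#'
#' @param grid a `lci_catgrid`.
#' @param connectivity patch connectivity passed to [label_patches()].
#' @return Tibble: `metric`, `level`, `class`, `value`.
#' @export
metric_report <- function(grid, connectivity = 8) {
  ps <- label_patches(grid, connectivity)
  comp <- np_pd_lpi(ps)
  vals <- c(
    NP = comp$np, PD = comp$pd, LPI = comp$lpi,
    LSI = lsi(grid), AWMSI = awmsi(ps), ENN_MN = enn_mn(ps),
    IJI = iji(grid), AI = ai(grid)$landscape
  )
  tibble::tibble(
    metric = names(vals),
    level = "landscape",
    class = NA_character_,
    value = as.numeric(vals)
  )
}
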