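# Brute-force reference implementations used as independent oracles.
# They are deliberately naive (label propagation to a fixed point, all-pairs
# scans, per-cell path walks) and share no code with the package internals.

neighbour_offsets <- function(conn) {
  if (conn == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
}

# connected-component labels by iterated minimum-label propagation
oracle_label <- function(v, conn = 8) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(seq_along(v), nr, nc)
  lab[is.na(v)] <- NA
  offs <- neighbour_offsets(conn)
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(v[r, c])) next
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!is.na(v[rr, cc]) && v[rr, cc] == v[r, c] &&
            lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# per-patch perimeter (meters) by enumerating all four edges of every cell
oracle_perimeters <- function(v, lab, cell_size) {
  nr <- nrow(v); nc <- ncol(v)
  per <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    id <- as.character(lab[r, c])
    if (is.null(per[id]) || is.na(per[id])) per[id] <- 0
    for (o in neighbour_offsets(4)) {
      rr <- r + o[1]; cc <- c + o[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc ||
        is.na(v[rr, cc]) || v[rr, cc] != v[r, c]
      if (outside) per[id] <- per[id] + cell_size
    }
  }
  per
}

# symmetric class-pair edge lengths (meters, each shared edge once) among
# real classes only
oracle_pair_edges <- function(v, cell_size) {
  nr <- nrow(v); nc <- ncol(v)
  out <- list()
  add <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "-")
    out[[key]] <<- (out[[key]] %||% 0) + cell_size
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    if (c < nc && !is.na(v[r, c + 1]) && v[r, c + 1] != v[r, c]) {
      add(v[r, c], v[r, c + 1])
    }
    if (r < nr && !is.na(v[r + 1, c]) && v[r + 1, c] != v[r, c]) {
      add(v[r, c], v[r + 1, c])
    }
  }
  out
}

# like-adjacency count per class, rook rule, each adjacency once
oracle_like_adjacencies <- function(v) {
  codes <- sort(unique(v[!is.na(v)]))
  g <- stats::setNames(numeric(length(codes)), codes)
  nr <- nrow(v); nc <- ncol(v)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    if (c < nc && !is.na(v[r, c + 1]) && v[r, c + 1] == v[r, c]) {
      g[as.character(v[r, c])] <- g[as.character(v[r, c])] + 1
    }
    if (r < nr && !is.na(v[r + 1, c]) && v[r + 1, c] == v[r, c]) {
      g[as.character(v[r, c])] <- g[as.character(v[r, c])] + 1
    }
  }
  g
}

# minimum center-to-center distance between two cell sets (linear indices)
oracle_set_distance <- function(cells_a, cells_b, nr, cell_size) {
  ra <- ((cells_a - 1) %% nr) + 1; ca <- ((cells_a - 1) %/% nr) + 1
  rb <- ((cells_b - 1) %% nr) + 1; cb <- ((cells_b - 1) %/% nr) + 1
  best <- Inf
  for (i in seq_along(cells_a)) {
    d <- sqrt((ra[i] - rb)^2 + (ca[i] - cb)^2)
    best <- min(best, min(d))
  }
  best * cell_size
}

# mean nearest-neighbour distance over patches of classes with >= 2 patches
oracle_enn_mn <- function(v, lab, cell_size) {
  ids <- sort(unique(lab[!is.na(lab)]))
  cls <- vapply(ids, function(id) as.integer(v[which(lab == id)[1]]),
                integer(1))
  enn <- numeric(0)
  for (id in ids) {
    same <- ids[cls == cls[match(id, ids)] & ids != id]
    if (length(same) == 0) next
    d <- vapply(same, function(o) {
      oracle_set_distance(which(lab == id), which(lab == o), nrow(v),
                          cell_size)
    }, numeric(1))
    enn <- c(enn, min(d))
  }
  if (length(enn) == 0) NA_real_ else mean(enn)
}

# per-cell flow accumulation by walking the full path from every cell
oracle_accumulation <- function(flow) {
  rcv <- flow$receiver
  dirm <- flow$direction
  acc <- matrix(0, nrow(dirm), ncol(dirm))
  acc[is.na(dirm)] <- NA
  for (start in which(!is.na(dirm))) {
    cur <- start
    repeat {
      acc[cur] <- acc[cur] + 1
      cur <- rcv[cur]
      if (is.na(cur)) break
    }
  }
  acc
}

# all-pairs nearest-TRUE-cell distances
oracle_edt <- function(mask, cell_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  src <- which(mask)
  rs <- ((src - 1) %% nr) + 1; cs <- ((src - 1) %/% nr) + 1
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- min(sqrt((r - rs)^2 + (c - cs)^2)) * cell_size
  }
  out
}

# random categorical grid helper
random_catgrid <- function(seed, nr, nc, k, cell_size = 30, p_na = 0) {
  set.seed(seed)
  v <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
  if (p_na > 0) v[stats::runif(nr * nc) < p_na] <- NA
  catgrid_create(v, cell_size,
                 stats::setNames(seq_len(k), paste0("class_", seq_len(k))))
}

# the eight metrics computed from the oracle primitives alone
oracle_metrics <- function(grid, conn = 8) {
  v <- grid$values
  cs <- grid$cell_size
  lab <- oracle_label(v, conn)
  ids <- sort(unique(lab[!is.na(lab)]))
  ncell <- vapply(ids, function(id) sum(lab == id, na.rm = TRUE), numeric(1))
  area_m2 <- sum(!is.na(v)) * cs^2
  np <- length(ids)
  pd <- np / (area_m2 / 1e4) * 100
  lpi <- 100 * max(ncell) * cs^2 / area_m2
  pairs <- oracle_pair_edges(v, cs)
  e_total <- sum(unlist(pairs))
  lsi_v <- e_total / (2 * sqrt(pi * area_m2))
  per <- oracle_perimeters(v, lab, cs)
  shape <- 0.25 * (per[as.character(ids)] / cs) / sqrt(ncell)
  awmsi_v <- sum(shape * ncell) / sum(ncell)
  enn_v <- oracle_enn_mn(v, lab, cs)
  codes <- sort(unique(v[!is.na(v)]))
  t_n <- length(codes)
  iji_v <- if (t_n < 3 || e_total <= 0) NA_real_ else {
    p <- unlist(pairs) / e_total
    p <- p[p > 0]
    -sum(p * log(p)) / log(t_n * (t_n - 1) / 2) * 100
  }
  g <- oracle_like_adjacencies(v)
  n_by_class <- vapply(codes, function(cd) sum(v == cd, na.rm = TRUE),
                       numeric(1))
  max_g <- vapply(n_by_class, function(n) {
    s <- floor(sqrt(n)); m <- n - s * s
    base <- 2 * s * (s - 1)
    if (m == 0) base else if (m <= s) base + 2 * m - 1 else base + 2 * m - 2
  }, numeric(1))
  ai_class <- ifelse(max_g > 0, 100 * g[as.character(codes)] / max_g, 100)
  ai_v <- sum(ai_class * n_by_class) / sum(n_by_class)
  c(NP = np, PD = pd, LPI = lpi, LSI = lsi_v, AWMSI = awmsi_v,
    ENN_MN = enn_v, IJI = iji_v, AI = ai_v)
}
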