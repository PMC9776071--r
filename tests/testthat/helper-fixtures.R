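# Shared fixtures, built once per test run. Phantom grids are kept small:
# short vessels and 0.25-0.5 mm spacing keep every suite fast while staying
# inside the regime the estimators are designed for.

# short straight tube (no stenosis) for annulus-style checks
straight_tube_geometry <- function(r = 2, h = 3, len = 12) {
  make_bifurcation_geometry(phantom_config(
    stenosis_fraction = 0, wall_thickness = h, outer_bulge = 0, bulb_amp = 0,
    cca_length = len, ica_length = len / 2, eca_length = len / 2,
    r_cca = r, r_ica = r, r_eca = r))
}

# small full bifurcation phantom with plaque, cached per (case, spacing, sd)
.phantom_cache <- new.env(parent = emptyenv())
phantom_fixture <- function(case = 1, spacing = 0.3, noise_sd = 0.05,
                            seed = 7) {
  key <- paste(case, spacing, noise_sd, seed, sep = "_")
  if (!is.null(.phantom_cache[[key]])) return(.phantom_cache[[key]])
  pc <- phantom_case(case)
  geom <- make_bifurcation_geometry(pc$config)
  labels <- rasterize_labels(geom, pc$plaque(geom), grid = spacing)
  stack <- render_contrasts(labels, noise_sd = noise_sd, seed = seed)
  fx <- list(geom = geom, labels = labels, stack = stack,
             plaque = pc$plaque(geom))
  .phantom_cache[[key]] <- fx
  fx
}

# 2D slice fixture: disk or annulus image
disk_slice <- function(r_lumen = 2, r_outer = NA, n = 80, spacing = 0.25,
                       center = c(10, 10), bg = 0.05, lumen = 0.95,
                       wall = 0.55) {
  ax <- (seq_len(n) - 1) * spacing
  img <- outer(ax, ax, function(x, y) {
    d <- sqrt((x - center[1])^2 + (y - center[2])^2)
    v <- ifelse(d <= r_lumen, lumen, bg)
    if (!is.na(r_outer)) v <- ifelse(d > r_lumen & d <= r_outer, wall, v)
    v
  })
  list(image = img, spacing = c(spacing, spacing), origin = c(0, 0),
       z = 0, slice_index = 0L, center = center)
}

# independent Bellman-Ford shortest path on a 26-connected grid (oracle)
bellman_ford_grid <- function(costs, spacing, src, dst) {
  dims <- dim(costs)
  n <- prod(dims)
  idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  # build edge list
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] & nb[, 2] >= 0 &
      nb[, 2] < dims[2] & nb[, 3] >= 0 & nb[, 3] < dims[3]
    u <- which(ok)
    v <- 1 + nb[ok, 1] + dims[1] * (nb[ok, 2] + dims[2] * nb[ok, 3])
    w <- 0.5 * (costs[u] + costs[v]) *
      sqrt(sum((offs[k, ] * spacing)^2))
    edges <- rbind(edges, cbind(u, v, w))
  }
  d <- rep(Inf, n)
  s <- 1 + src[1] + dims[1] * (src[2] + dims[2] * src[3])
  t <- 1 + dst[1] + dims[1] * (dst[2] + dims[2] * dst[3])
  d[s] <- 0
  for (it in seq_len(n)) {
    nd <- pmin(d, unname(tapply(d[edges[, 1]] + edges[, 3], edges[, 2],
                                min)[as.character(seq_len(n))]))
    nd[is.na(nd)] <- d[is.na(nd)]
    if (all(nd + 1e-12 >= d)) break
    d <- nd
  }
  d[t]
}

# exhaustive min-plus (tropical) closure oracle for the cyclic polar DP
minplus_cycle_cost <- function(C, lambda, max_step = 2) {
  nt <- nrow(C); nr <- ncol(C)
  Tm <- matrix(Inf, nr, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr))
    if (abs(i - j) <= max_step) Tm[i, j] <- lambda * abs(i - j)
  best <- Inf
  for (j0 in seq_len(nr)) {
    v <- rep(Inf, nr)
    v[j0] <- C[1, j0]
    for (t in 2:nt) {
      v <- vapply(seq_len(nr), function(j) min(v + Tm[, j]) + C[t, j], 0)
    }
    best <- min(best, min(v + Tm[, j0]))
  }
  best
}

# literal recursive enumeration of all constrained cyclic radial paths
enumerate_cycle_cost <- function(C, lambda, max_step = 2) {
  nt <- nrow(C); nr <- ncol(C)
  best <- Inf
  recurse <- function(t, j, j0, acc) {
    if (acc >= best) return()
    if (t > nt) {
      if (abs(j - j0) <= max_step)
        best <<- min(best, acc + lambda * abs(j - j0))
      return()
    }
    for (jn in seq_len(nr)) {
      if (abs(jn - j) <= max_step)
        recurse(t + 1, jn, j0, acc + C[t, jn] + lambda * abs(jn - j))
    }
  }
  for (j0 in seq_len(nr)) recurse(2, j0, j0, C[1, j0])
  best
}
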