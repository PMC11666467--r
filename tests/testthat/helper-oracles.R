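# Independent oracles and fixture builders used across the suite.
# Fixtures are generated in code; no binary data ships with the package.

# --- independent Dijkstra oracle on the 26-connected voxel graph ----------
# Edge weights use the same dyadic quantization as the implementation
# (q = 2^-20 * max spacing, integer-valued weights), so path sums are exact
# and tie-breaks are well defined; the algorithm (igraph's shortest paths)
# is independent of the package's own search.
oracle_geodesic <- function(mask, sources_idx, spacing) {
  dims <- dim(mask)
  vox <- which(mask)
  q <- max(spacing) / 2^20
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  kji <- arrayInd(vox, dims)
  idmap <- integer(prod(dims))
  idmap[vox] <- seq_along(vox)
  from <- integer(0); to <- integer(0); wts <- numeric(0)
  for (r in seq_len(nrow(off))) {
    nk <- kji[, 1] + off[r, 1]
    nj <- kji[, 2] + off[r, 2]
    ni <- kji[, 3] + off[r, 3]
    ok <- nk >= 1 & nk <= dims[1] & nj >= 1 & nj <= dims[2] &
      ni >= 1 & ni <= dims[3]
    lin <- (nk - 1) + dims[1] * ((nj - 1) + dims[2] * (ni - 1)) + 1
    ok[ok] <- mask[lin[ok]]
    w <- round(sqrt(sum((off[r, ] * spacing)^2)) / q)
    from <- c(from, idmap[vox[ok]])
    to <- c(to, idmap[lin[ok]])
    wts <- c(wts, rep(w, sum(ok)))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(vox), directed = FALSE)
  D <- igraph::distances(g, v = match(sources_idx, vox), weights = wts) * q
  list(vox = vox, D = D) # D: sources x voxels, um
}

# nearest-seed partition with the (distance, label) tie-break
oracle_partition <- function(mask, seeds_arr, spacing) {
  src <- which(seeds_arr > 0L)
  src_lab <- seeds_arr[src]
  o <- oracle_geodesic(mask, src, spacing)
  ord <- order(src_lab)
  D <- o$D[ord, , drop = FALSE]
  labs_sorted <- src_lab[ord]
  dist <- apply(D, 2, min)
  lab <- vapply(seq_along(dist), function(c) {
    if (!is.finite(dist[c])) return(0L)
    cand <- which(D[, c] == dist[c])
    as.integer(min(labs_sorted[cand]))
  }, integer(1))
  out_lab <- array(0L, dim(mask))
  out_lab[o$vox] <- lab
  out_dist <- array(Inf, dim(mask))
  out_dist[o$vox] <- dist
  list(label = out_lab, dist = out_dist)
}

# --- digitized solids ------------------------------------------------------
digitized_sphere <- function(r_vox = 20, spacing = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * (r_vox + pad) / spacing)
  ctr <- (n - 1) / 2 * spacing
  g <- expand.grid(k = 0:(n[1] - 1), j = 0:(n[2] - 1), i = 0:(n[3] - 1))
  ins <- ((g$k * spacing[1] - ctr[1])^2 + (g$j * spacing[2] - ctr[2])^2 +
            (g$i * spacing[3] - ctr[3])^2) <= r_vox^2
  array(as.integer(ins), n)
}

digitized_box <- function(box_um = c(20, 10, 10), spacing = c(1, 1, 1),
                          pad = 3) {
  n <- ceiling((box_um + 2 * pad) / spacing)
  g <- expand.grid(k = 0:(n[1] - 1), j = 0:(n[2] - 1), i = 0:(n[3] - 1))
  lo <- rep(pad, 3); hi <- lo + box_um
  ins <- g$k * spacing[1] >= lo[1] & g$k * spacing[1] < hi[1] &
    g$j * spacing[2] >= lo[2] & g$j * spacing[2] < hi[2] &
    g$i * spacing[3] >= lo[3] & g$i * spacing[3] < hi[3]
  array(as.integer(ins), n)
}

# upright cylinder mask rising from z index z0 (inclusive), height h um
digitized_cylinder <- function(r_um, h_um, spacing = c(1, 1, 1), z0 = 2,
                               lateral_pad = 3) {
  nz <- ceiling(h_um / spacing[1]) + z0 + 2
  nl <- ceiling(2 * (r_um + lateral_pad) / spacing[2:3])
  ctr <- (nl - 1) / 2 * spacing[2:3]
  g <- expand.grid(k = 0:(nz - 1), j = 0:(nl[1] - 1), i = 0:(nl[2] - 1))
  zc <- (g$k - z0) * spacing[1]
  ins <- zc >= 0 & zc < h_um &
    ((g$j * spacing[2] - ctr[1])^2 + (g$i * spacing[3] - ctr[2])^2) <= r_um^2
  array(ins, c(nz, nl[1], nl[2]))
}

# random blobby 3D mask (union of a few balls), guaranteed nonempty
random_blob_mask <- function(dims, spacing, n_balls = 3, seed = 1) {
  set.seed(seed)
  g <- expand.grid(k = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   i = 0:(dims[3] - 1))
  m <- rep(FALSE, nrow(g))
  ext <- (dims - 1) * spacing
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 0.2, 0.8) * ext
    r <- runif(1, 0.15, 0.35) * min(ext)
    m <- m | (((g$k * spacing[1] - c0[1])^2 + (g$j * spacing[2] - c0[2])^2 +
                 (g$i * spacing[3] - c0[3])^2) <= r^2)
  }
  m <- array(m, dims)
  if (sum(m) < 30) {
    # coarse spacings can leave tiny balls without voxel centres; guarantee
    # a usable core
    ctr <- pmax(dims %/% 2, 2L)
    m[(ctr[1] - 1):ctr[1], (ctr[2] - 1):ctr[2], (ctr[3] - 1):ctr[3]] <- TRUE
  }
  m
}

# the acceptance-scale seeding parameters used for phantom work
phantom_params <- function() {
  seeding_params(downsample_factors = c(2L, 4L, 4L),
                 sigma_schedule = c(8, 6), erosion_step = 2,
                 max_iterations = 8L, min_seed_volume = 100)
}

# small two-cohort config used by pipeline tests
small_cohort_config <- function(out_dir, seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    cohorts = list(
      list(group = "nulliparous", n_mice = 2,
           phantom = list(n_rows = 1, n_cols = 2, pitch_y = 30, pitch_x = 30,
                          margin = 14, shaft_length = 40, radius = 8,
                          flattening = 1, jitter = 1, spacing = c(1, 0.5, 0.5),
                          clearance = 2)),
      list(group = "lactation", n_mice = 2,
           phantom = list(n_rows = 1, n_cols = 2, pitch_y = 40, pitch_x = 40,
                          margin = 20, shaft_length = 64, radius = 8,
                          flattening = 2, jitter = 1, spacing = c(1, 0.5, 0.5),
                          clearance = 2))),
    params = list(downsample_factors = c(2, 4, 4), sigma_schedule = c(8, 6),
                  erosion_step = 2, max_iterations = 8, min_seed_volume = 100),
    surface_method = "crofton",
    compare = list(metrics = c("length", "flatness"),
                   design = "multi_group"))
}
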