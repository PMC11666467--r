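# Geodesic distance maps, lengths, volumes, surfaces, flatness, ratios,
# EdU migration, organoid areas, and the scaling/dominance properties.

test_that("geodesic distance: single voxel, straight run, input validation", {
  one <- array(TRUE, c(1, 1, 1))
  expect_equal(geodesic_distance(one, 1L, c(1, 1, 1))[1, 1, 1], 0)

  # straight axis-aligned run of 11 voxels at dz = 2.15 um
  line <- array(FALSE, c(11, 3, 3)); line[, 2, 2] <- TRUE
  src <- which(line & slice.index(line, 1) == 1L)
  d <- geodesic_distance(line, src, c(2.15, 0.62, 0.62))
  expect_equal(d[11, 2, 2], 21.5, tolerance = 1e-6)

  expect_error(geodesic_distance(line, integer(0), c(1, 1, 1)), "empty")
  expect_error(geodesic_distance(line, which(!line)[1], c(1, 1, 1)),
               "inside the instance")
})

test_that("geodesic distance equals the independent Dijkstra oracle bit-for-bit", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:8) {
    dims <- c(sample(6:18, 1), sample(6:18, 1), sample(6:18, 1))
    sp <- runif(3, 0.4, 2.2)
    m <- random_blob_mask(dims, sp, n_balls = 2, seed = 200 + rep)
    mvox <- which(m)
    src <- mvox[sample.int(length(mvox), sample(1:3, 1))]
    d <- geodesic_distance(m, src, sp)
    o <- oracle_geodesic(m, src, sp)
    dist_o <- apply(o$D, 2, min)
    mine <- d[o$vox]
    fin <- is.finite(dist_o)
    expect_true(all(is.finite(mine) == fin))
    expect_lt(max(abs(mine[fin] - dist_o[fin]) / pmax(dist_o[fin], 1e-12)),
              1e-9)
  }
})

test_that("villus length: upright cylinder, exact spacing scaling, fallback base", {
  sp <- c(1, 0.8, 0.8)
  tube <- digitized_cylinder(5, 50, spacing = sp, z0 = 2)
  lab <- label_volume(array(as.integer(tube), dim(tube)), sp)
  base_idx <- which(tube & slice.index(tube, 1) == 3L)
  base <- base_surface(base_idx, dim(tube), sp)
  len <- villus_length(lab, base)
  expect_lt(abs(len$length - (50 - sp[1])), sqrt(sum(sp^2)) + 1e-9)

  # doubling the spacing on the same voxel grid doubles the length exactly
  lab2 <- label_volume(lab$data, sp * 2)
  base2 <- base_surface(base_idx, dim(tube), sp * 2)
  len2 <- villus_length(lab2, base2)
  expect_equal(len2$length, 2 * len$length, tolerance = 1e-12)

  # no base voxels: lowest-z fallback with a flag
  none <- base_surface(integer(0), dim(tube), sp)
  lf <- villus_length(lab, none)
  expect_match(lf$flags, "fallback_base")
  expect_lt(abs(lf$length - (50 - sp[1])), sqrt(sum(sp^2)) + 1e-9)
})

test_that("L-shaped tube length matches the graph-search oracle and ~ sums its arms", {
  skip_if_not_installed("igraph")
  sp <- c(1, 1, 1)
  dims <- c(55L, 8L, 55L)
  arr <- array(FALSE, dims)
  arr[2:52, 3:5, 3:5] <- TRUE     # vertical arm ~ 50 um
  arr[50:52, 3:5, 3:53] <- TRUE   # horizontal arm ~ 50 um
  lab <- label_volume(array(as.integer(arr), dims), sp)
  base_idx <- which(arr & slice.index(arr, 1) == 2L)
  len <- villus_length(lab, base_surface(base_idx, dims, sp))
  o <- oracle_geodesic(arr, base_idx, sp)
  expect_equal(len$length, max(apply(o$D, 2, min)), tolerance = 1e-9)
  expect_gt(len$length, 90)
  expect_lt(len$length, 110)
})

test_that("villus volume is exact voxel arithmetic with flags for absent ids", {
  arr <- array(0L, c(3, 3, 3)); arr[2, 2, 2] <- 1L
  v <- villus_volume(label_volume(arr, c(2, 1, 1)))
  expect_equal(v$volume, 2)
  v2 <- villus_volume(label_volume(arr, c(2, 1, 1)), ids = c(1L, 4L))
  expect_equal(v2$volume, c(2, 0))
  expect_identical(v2$flags, c("", "absent_label"))
})

test_that("surface estimators: digitized sphere within 3%, box mesh within 5%", {
  sph <- label_volume(digitized_sphere(20), c(1, 1, 1))
  s <- villus_surface(sph, method = "both")
  truth <- 4 * pi * 400
  expect_lt(abs(s$surface_area_crofton - truth) / truth, 0.03)
  expect_lt(abs(s$surface_area_mesh - truth) / truth, 0.03)

  box <- label_volume(digitized_box(c(20, 10, 10)), c(1, 1, 1))
  sb <- villus_surface(box, method = "mesh")
  expect_lt(abs(sb$surface_area_mesh - 1000) / 1000, 0.05)

  # anisotropic digitization of the same sphere: the 2:1 z-staircase costs
  # the mesh estimator about one extra percent
  sph_a <- label_volume(digitized_sphere(20, spacing = c(2, 1, 1)), c(2, 1, 1))
  sa <- villus_surface(sph_a, method = "both")
  expect_lt(abs(sa$surface_area_crofton - truth) / truth, 0.03)
  expect_lt(abs(sa$surface_area_mesh - truth) / truth, 0.04)

  empty <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_identical(nrow(villus_surface(empty)), 0L)
  expect_error(villus_surface(sph, method = "voxel"), "unknown")
})

test_that("flatness: circular capsule ~ 1, tiny instance flagged", {
  spec <- phantom_grid_spec(1, 1, 30, 30, 20, shaft_length = 40, radius = 10,
                            spacing = c(1, 0.5, 0.5), seed = 3)
  ph <- generate_phantom(spec, channels = "actin")
  fl <- villus_flatness(ph$truth_labels)
  expect_lt(abs(fl$flatness - 1), 0.1)

  small <- array(0L, c(3, 3, 3)); small[1:3, 1:3, 1] <- 1L # 9 voxels
  fs <- villus_flatness(label_volume(small, c(1, 1, 1)))
  expect_identical(fs$flags, "too_small")
  expect_true(is.na(fs$flatness))
})

test_that("flatness of a = 2 villi recovers the axis ratio a^2 = 4 within 15%", {
  spec <- phantom_grid_spec(1, 1, 40, 40, 22, shaft_length = 60, radius = 8,
                            flattening = 2, spacing = c(1, 0.5, 0.5), seed = 5)
  ph <- generate_phantom(spec, channels = "actin")
  fl <- villus_flatness(ph$truth_labels)
  expect_lt(abs(fl$flatness - 4) / 4, 0.15)
  # flat axis direction: major axis along x (orientation 0)
  expect_gt(abs(fl$flat_axis_x), 0.95)
})

test_that("villus/crypt ratio arithmetic and flags", {
  r <- villus_crypt_ratio(300, 100)
  expect_equal(r$ratio, 3)
  expect_equal(villus_crypt_ratio(123.4, 123.4)$ratio, 1)
  bad <- villus_crypt_ratio(c(100, 200), c(0, NA))
  expect_true(all(is.na(bad$ratio)))
  expect_identical(bad$flags, c("undefined_ratio", "undefined_ratio"))
})

test_that("EdU migration distance: source point, empty set, oracle maximum", {
  skip_if_not_installed("igraph")
  sp <- c(1, 1, 1)
  dims <- c(40L, 8L, 40L)
  arr <- array(FALSE, dims)
  arr[2:38, 3:5, 3:5] <- TRUE
  arr[36:38, 3:5, 3:38] <- TRUE
  epi <- binary_mask(arr, sp)
  base_idx <- which(arr & slice.index(arr, 1) == 2L)
  base <- base_surface(base_idx, dims, sp)

  # a point on a base voxel has distance 0
  kji0 <- arrayInd(base_idx[1], dims)
  p0 <- point_set(matrix((kji0 - 1) * sp, 1))
  r0 <- edu_migration_distance(epi, base, p0)
  expect_equal(r0$distance, 0)

  rn <- edu_migration_distance(epi, base, point_set(matrix(numeric(0), 0, 3)))
  expect_equal(rn$distance, 0)
  expect_identical(rn$flags, "no_points")

  set.seed(51)
  in_idx <- sample(which(arr), 5)
  pts <- (arrayInd(in_idx, dims) - 1) * matrix(sp, 5, 3, byrow = TRUE)
  res <- edu_migration_distance(epi, base, point_set(pts))
  o <- oracle_geodesic(arr, base_idx, sp)
  dist_all <- apply(o$D, 2, min)
  exp_d <- max(dist_all[match(in_idx, o$vox)])
  expect_equal(res$distance, exp_d, tolerance = 1e-9)

  off <- point_set(matrix(c(39, 7, 39) * sp, 1)) # far from tissue
  ro <- edu_migration_distance(epi, base, off)
  expect_true(ro$per_point$off_tissue)
})

test_that("organoid areas equal the exhaustive pixel-count oracle", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  a <- organoid_area(sq, c(1, 1))
  expect_equal(a$area, 100)
  expect_false(a$touches_border)

  expect_identical(nrow(organoid_area(matrix(FALSE, 5, 5), c(1, 1))), 0L)

  set.seed(61)
  m <- matrix(runif(40 * 30) > 0.7, 40, 30)
  res <- organoid_area(m, c(0.8, 1.2))
  dims3 <- c(1L, 40L, 30L)
  lab <- array(villimorph:::.label_components_cpp(array(m, dims3), dims3, 26L),
               c(40, 30))
  for (row in seq_len(nrow(res))) {
    id <- res$label_id[row]
    expect_equal(res$area[row], sum(lab == id) * 0.8 * 1.2)
    expect_identical(res$touches_border[row],
                     any(lab[1, ] == id) || any(lab[40, ] == id) ||
                       any(lab[, 1] == id) || any(lab[, 30] == id))
  }
})

test_that("scaling law: spacing x s scales lengths, areas, volumes by s, s^2, s^3", {
  arr <- digitized_sphere(8, spacing = c(1, 1, 1))
  arr[3:5, 3:5, 3:5] <- 1L # add an irregular lump
  s <- 2.5
  for (sp0 in list(c(1, 1, 1), c(2, 0.7, 0.7))) {
    l1 <- label_volume(arr, sp0)
    l2 <- label_volume(arr, sp0 * s)
    base1 <- base_surface(which(arr > 0 & slice.index(arr, 1) == 3L),
                          dim(arr), sp0)
    base2 <- base_surface(base1$index, dim(arr), sp0 * s)
    expect_equal(villus_length(l2, base2)$length,
                 s * villus_length(l1, base1)$length, tolerance = 1e-12)
    expect_equal(villus_volume(l2)$volume, s^3 * villus_volume(l1)$volume,
                 tolerance = 1e-12)
    s1 <- villus_surface(l1, "both"); s2 <- villus_surface(l2, "both")
    expect_equal(s2$surface_area_crofton, s^2 * s1$surface_area_crofton,
                 tolerance = 1e-12)
    expect_equal(s2$surface_area_mesh, s^2 * s1$surface_area_mesh,
                 tolerance = 1e-12)
  }
})

test_that("geodesic dominance: length >= Euclidean base-to-farthest minus a diagonal", {
  set.seed(71)
  for (rep in 1:5) {
    dims <- c(14L, 12L, 12L)
    sp <- runif(3, 0.5, 2)
    m <- random_blob_mask(dims, sp, n_balls = 2, seed = 300 + rep)
    comp <- array(villimorph:::.label_components_cpp(m, dims, 26L), dims)
    lab <- label_volume(comp, sp)
    kmin <- min(arrayInd(which(m), dims)[, 1])
    base_idx <- which(m & slice.index(m, 1) == kmin)
    base <- base_surface(base_idx, dims, sp)
    len <- suppressWarnings(villus_length(lab, base))
    for (row in seq_len(nrow(len))) {
      id <- len$label_id[row]
      vox <- which(comp == id)
      src <- intersect(vox, base_idx)
      if (length(src) == 0) next
      P <- (arrayInd(vox, dims) - 1) * matrix(sp, length(vox), 3, byrow = TRUE)
      S <- (arrayInd(src, dims) - 1) * matrix(sp, length(src), 3, byrow = TRUE)
      # max over voxels of min distance to a base voxel
      dmax <- max(apply(P, 1, function(p) {
        min(sqrt(colSums((t(S) - p)^2)))
      }))
      expect_gte(len$length[row], dmax - sqrt(sum(sp^2)) - 1e-9)
    }
  }
})

test_that("appending voxels at the tip never decreases length or volume", {
  sp <- c(1, 1, 1)
  tube <- digitized_cylinder(4, 30, spacing = sp, z0 = 2)
  dims <- dim(tube)
  lab1 <- label_volume(array(as.integer(tube), dims), sp)
  base <- base_surface(which(tube & slice.index(tube, 1) == 3L), dims, sp)
  l1 <- villus_length(lab1, base)$length
  v1 <- villus_volume(lab1)$volume

  ext <- tube
  top <- max(which(apply(tube, 1, any)))
  ext[top + 1, , ] <- tube[top, , ] # one more slice at the tip
  lab2 <- label_volume(array(as.integer(ext), dims), sp)
  expect_gte(villus_length(lab2, base)$length, l1)
  expect_gte(villus_volume(lab2)$volume, v1)
})

test_that("full morphometry table has one row per label with merged flags", {
  spec <- phantom_grid_spec(1, 2, 30, 30, 16, shaft_length = 30, radius = 8,
                            spacing = c(1, 0.5, 0.5), clearance = 2, seed = 29)
  ph <- generate_phantom(spec, channels = "actin")
  labs <- ph$truth_labels
  base_idx <- which(labs$data > 0L &
                      slice.index(labs$data, 1) ==
                        min(arrayInd(which(labs$data > 0), dim(labs$data))[, 1]))
  base <- base_surface(base_idx, dim(labs$data), labs$spacing)
  m <- measure_villi(labs, base, sample_id = "ph", surface_method = "both")
  expect_identical(nrow(m), 2L)
  expect_true(all(c("length", "volume", "surface_area_crofton",
                    "surface_area_mesh", "flatness") %in% names(m)))
  expect_identical(m$sample_id, rep("ph", 2))
})
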