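# Downsampling, binarization, LoG seeding, marker regrowth, upsampling.

test_that("downsample identity and spacing arithmetic", {
  set.seed(4)
  v <- intensity_volume(array(rnorm(4 * 6 * 8), c(4, 6, 8)),
                        c(2.15, 0.6, 0.6))
  id <- downsample(v, c(1, 1, 1))
  expect_identical(id$data, v$data)
  expect_equal(id$spacing, v$spacing)

  d <- downsample(v, c(1, 2, 2))
  expect_equal(d$spacing, c(2.15, 1.2, 1.2))
  expect_identical(dim(d$data), c(4L, 3L, 4L))
  expect_error(downsample(v, c(5, 1, 1)), "exceeds")
})

test_that("mask downsampling is an exhaustive per-block majority vote", {
  set.seed(5)
  m <- binary_mask(array(runif(8 * 8 * 8) > 0.5, c(8, 8, 8)), c(1, 1, 1))
  d <- downsample(m, c(2, 2, 2))
  for (k in 1:4) for (j in 1:4) for (i in 1:4) {
    block <- m$data[(2 * k - 1):(2 * k), (2 * j - 1):(2 * j),
                    (2 * i - 1):(2 * i)]
    expect_identical(d$data[k, j, i], mean(block) >= 0.5)
  }
})

test_that("foreground_mask separates well-separated modes exactly", {
  set.seed(6)
  dims <- c(12L, 20L, 20L)
  obj <- array(FALSE, dims); obj[4:9, 6:15, 6:15] <- TRUE
  img <- array(10 + runif(prod(dims)) * 2 - 1, dims)
  img[obj] <- 200 + runif(sum(obj)) * 2 - 1
  v <- intensity_volume(img, c(1, 1, 1))
  expect_message(fg <- foreground_mask(v, min_volume = 0, presmooth = 0),
                 "threshold")
  expect_identical(fg$data, obj)

  expect_error(foreground_mask(intensity_volume(array(5, dims), c(1, 1, 1))),
               "no foreground separable")
  expect_error(foreground_mask(v, method = "median"), "unknown")
})

test_that("phantom actin foreground overlaps truth tissue with Jaccard >= 0.95", {
  spec <- phantom_grid_spec(1, 2, 30, 30, 16, shaft_length = 40, radius = 10,
                            spacing = c(1, 0.5, 0.5), clearance = 2, seed = 13)
  ph <- generate_phantom(spec, channels = "actin") # noise_sd = 5 default
  fg <- suppressMessages(foreground_mask(ph$actin))
  truth <- ph$truth_labels$data > 0L | ph$crypt_mask$data
  jacc <- sum(fg$data & truth) / sum(fg$data | truth)
  expect_gte(jacc, 0.95)
})

test_that("a single capsule yields exactly one seed, inside the capsule", {
  spec <- phantom_grid_spec(1, 1, 30, 30, 20, shaft_length = 40, radius = 10,
                            spacing = c(1, 0.5, 0.5), seed = 17)
  ph <- generate_phantom(spec, channels = "actin")
  vm <- binary_mask(ph$truth_labels$data > 0L, spec$spacing)
  seeds <- generate_seeds(vm, phantom_params())
  expect_identical(max(seeds$data), 1L)
  expect_true(all(ph$truth_labels$data[seeds$data > 0L] == 1L))
})

test_that("two basally fused capsules yield two seeds, one per capsule", {
  # centres 19 um apart with r = 10: the capsules merge over their base
  spec <- phantom_spec(c(60, 80, 120), c(1, 0.5, 0.5),
                       villi = rbind(villus_params(20, 20, 40, 10),
                                     villus_params(20, 39, 40, 10)),
                       floor_thickness = 4, crypt_layer_depth = 11.5,
                       rng_seed = 3)
  # bypass validation: the fusion is intentional
  shape <- spec$volume_shape
  lab <- array(0L, shape)
  for (i in 1:2) {
    vb <- villimorph:::villus_voxels(spec$villi[i, ], spec)
    sub <- lab[vb$kr, vb$jr, vb$ir]
    sub[vb$block] <- i
    lab[vb$kr, vb$jr, vb$ir] <- sub
  }
  fused <- binary_mask(lab > 0L, spec$spacing)
  comp <- villimorph:::.label_components_cpp(fused$data, shape, 26L)
  expect_identical(max(comp), 1L) # really fused
  seeds <- generate_seeds(fused, seeding_params(sigma_schedule = c(8, 6),
                                                erosion_step = 2,
                                                min_seed_volume = 100))
  expect_identical(max(seeds$data), 2L)
  # each seed lies inside exactly one capsule's upper shaft
  for (s in 1:2) {
    under <- lab[seeds$data == s]
    expect_identical(length(unique(under)), 1L)
  }
})

test_that("empty mask gives zero seeds without error", {
  m <- binary_mask(array(FALSE, c(6, 6, 6)), c(1, 1, 1))
  seeds <- generate_seeds(m, seeding_params())
  expect_identical(max(seeds$data), 0L)
})

test_that("seeding is anti-monotone in erosion: seeds lie inside the first eroded mask", {
  spec <- phantom_grid_spec(1, 2, 30, 30, 16, shaft_length = 40, radius = 10,
                            spacing = c(1, 0.5, 0.5), clearance = 2, seed = 19)
  ph <- generate_phantom(spec, channels = "actin")
  vm <- binary_mask(ph$truth_labels$data > 0L, spec$spacing)
  prm <- phantom_params()
  seeds <- generate_seeds(vm, prm)
  edt <- array(villimorph:::.edt_cpp(vm$data, dim(vm$data), vm$spacing),
               dim(vm$data))
  eroded1 <- edt > prm$erosion_step
  expect_true(all(eroded1[seeds$data > 0L]))
})

test_that("watershed with component seeds reproduces the components", {
  set.seed(23)
  dims <- c(14L, 14L, 14L)
  m <- array(FALSE, dims)
  m[2:6, 2:6, 2:6] <- TRUE
  m[9:13, 8:13, 3:10] <- TRUE
  comp <- array(villimorph:::.label_components_cpp(m, dims, 26L), dims)
  seeds <- label_volume(comp, c(1, 1, 1), kind = "seed")
  out <- watershed_regrow(seeds, binary_mask(m, c(1, 1, 1)))
  # labels renumbered by volume; partition must match the components
  expect_identical(out$data > 0L, m)
  tab <- table(comp[m], out$data[m])
  expect_identical(sum(tab > 0), 2L) # one-to-one
})

test_that("two point seeds in a tube split at the midpoint", {
  dims <- c(5L, 5L, 101L)
  m <- array(FALSE, dims); m[3, 3, ] <- TRUE
  seeds <- array(0L, dims)
  seeds[3, 3, 11] <- 1L  # x = 10 um
  seeds[3, 3, 91] <- 2L  # x = 90 um
  out <- watershed_regrow(label_volume(seeds, c(1, 1, 1), kind = "seed"),
                          binary_mask(m, c(1, 1, 1)))
  lab_line <- out$data[3, 3, ]
  boundary <- max(which(lab_line == lab_line[11]))
  expect_lte(abs((boundary - 1) - 50), 1)
})

test_that("watershed equals the nearest-seed geodesic oracle on random masks", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:6) {
    dims <- c(sample(8:16, 1), sample(8:16, 1), sample(8:16, 1))
    sp <- runif(3, 0.5, 2)
    m <- random_blob_mask(dims, sp, n_balls = 3, seed = 100 + rep)
    vox <- which(m)
    ns <- min(sample(2:4, 1), length(vox))
    seeds <- array(0L, dims)
    seeds[vox[sample.int(length(vox), ns)]] <- seq_len(ns)
    out <- suppressWarnings(
      watershed_regrow(label_volume(seeds, sp, kind = "seed"),
                       binary_mask(m, sp)))
    oracle <- oracle_partition(m, seeds, sp)
    # output is relabelled by volume; compare partitions up to bijection
    t1 <- table(oracle$label[m], out$data[m])
    expect_true(all(rowSums(t1 > 0) == 1) && all(colSums(t1 > 0) <= 1))
    # partition property: every mask voxel labelled, volumes sum to mask
    reached <- oracle$label[m] > 0
    expect_true(all((out$data[m] > 0) == reached))
  }
})

test_that("watershed is deterministic and validates seed placement", {
  set.seed(37)
  dims <- c(10L, 10L, 10L)
  m <- random_blob_mask(dims, c(1, 1, 1), seed = 55)
  seeds <- array(0L, dims)
  seeds[sample(which(m), 3)] <- 1:3
  sv <- label_volume(seeds, c(1, 1, 1), kind = "seed")
  bm <- binary_mask(m, c(1, 1, 1))
  a <- suppressWarnings(watershed_regrow(sv, bm))
  b <- suppressWarnings(watershed_regrow(sv, bm))
  expect_identical(a$data, b$data)

  bad <- array(0L, dims)
  bad[which(!m)[1]] <- 1L
  expect_error(watershed_regrow(label_volume(bad, c(1, 1, 1), kind = "seed"),
                                bm),
               "outside the mask")
  none <- label_volume(array(0L, dims), c(1, 1, 1), kind = "seed")
  expect_warning(z <- watershed_regrow(none, bm), "no seeds")
  expect_identical(max(z$data), 0L)
})

test_that("upsample_labels: identity, voxel-count arithmetic, masking", {
  lab <- label_volume(array(rep(1:8, each = 8), c(4, 4, 4))[1:4, 1:4, 1:4],
                      c(2, 2, 2), kind = "seed")
  id <- upsample_labels(lab, c(4, 4, 4), c(2, 2, 2))
  expect_identical(id$data, lab$data)

  # checkerboard x2 upsample: every label count multiplies by 8
  cb <- array(as.integer((slice.index(array(0, c(4, 4, 4)), 1) +
                            slice.index(array(0, c(4, 4, 4)), 2) +
                            slice.index(array(0, c(4, 4, 4)), 3)) %% 2 + 1),
              c(4, 4, 4))
  lv <- label_volume(cb, c(2, 2, 2), kind = "seed")
  up <- upsample_labels(lv, c(8, 8, 8), c(1, 1, 1))
  expect_identical(tabulate(up$data), tabulate(cb) * 8L)

  expect_error(upsample_labels(lv, c(9, 9, 2), c(1, 1, 1)), "factors")
})
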