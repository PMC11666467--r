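# Two-level cohort summaries, group comparisons, pipeline determinism.

fake_cohort <- function() {
  set.seed(81)
  rows <- do.call(rbind, lapply(1:3, function(g) {
    do.call(rbind, lapply(1:4, function(m) {
      data.frame(group = paste0("g", g), mouse_id = sprintf("g%d_m%d", g, m),
                 sample_id = sprintf("g%d_m%d", g, m),
                 label_id = 1:5,
                 length = rnorm(5, 300 + 30 * g, 20),
                 volume = rnorm(5, 4e4, 3e3),
                 surface_area = rnorm(5, 7e3, 5e2),
                 flatness = rnorm(5, 1.2, 0.1))
    }))
  }))
  class(rows) <- c("cohort_table", class(rows))
  rows
}

test_that("s.e.m. of [1,2,3] is 0.5774 and summaries match a direct oracle", {
  tab <- data.frame(group = "a", mouse_id = c("m1", "m2", "m3"),
                    length = c(1, 2, 3))
  s <- summarize_cohort(tab, "villus", metrics = "length")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0.5774, tolerance = 1e-4)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)

  big <- fake_cohort()
  sv <- summarize_cohort(big, "villus")
  for (row in seq_len(nrow(sv))) {
    v <- big[big$group == sv$group[row], sv$metric[row]]
    expect_equal(sv$mean[row], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(sv$sem[row],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                   sqrt(length(v)),
                 tolerance = 1e-12)
    expect_equal(sv$n[row], length(v))
  }
  sm <- summarize_cohort(big, "mouse")
  expect_true(all(sm$n == 4))
})

test_that("single observations give flagged NA s.e.m., unknown level errors", {
  tab <- data.frame(group = "a", mouse_id = "m1", length = 5)
  s <- summarize_cohort(tab, "villus", metrics = "length")
  expect_true(is.na(s$sem))
  expect_identical(s$flags, "n_lt_2")
  expect_error(summarize_cohort(tab, "banana"), "level")
})

test_that("mouse- and villus-level summaries coincide at one villus per mouse", {
  set.seed(9)
  tab <- data.frame(group = "a", mouse_id = paste0("m", 1:6),
                    length = rnorm(6, 100, 10))
  sv <- summarize_cohort(tab, "villus", metrics = "length")
  sm <- summarize_cohort(tab, "mouse", metrics = "length")
  expect_equal(sv$mean, sm$mean, tolerance = 1e-12)
  expect_equal(sv$sem, sm$sem, tolerance = 1e-12)
  expect_equal(sv$n, sm$n)
})

test_that("two identical groups give t ~ 0 and p ~ 1", {
  v <- c(4.1, 5.2, 6.3, 5.5, 4.9)
  tab <- data.frame(group = rep(c("a", "b"), each = 5),
                    mouse_id = paste0("m", 1:10), length = c(v, v))
  r <- compare_groups(tab, "length", design = "two_group")
  expect_lt(abs(r$statistic), 1e-10)
  expect_gt(r$p_value, 0.999)
})

test_that("N(300,20) vs N(450,20), n = 30: Tukey p < 0.001 and CI covers 150", {
  set.seed(1234)
  tab <- data.frame(group = rep(c("ctrl", "lact"), each = 30),
                    mouse_id = paste0("m", rep(1:10, 6)),
                    length = c(rnorm(30, 300, 20), rnorm(30, 450, 20)))
  r <- compare_groups(tab, "length", design = "multi_group")
  expect_lt(r$pairs$p_adj, 0.001)
  expect_gt(150, r$pairs$lwr)
  expect_lt(150, r$pairs$upr)
  expect_equal(abs(r$pairs$diff), 150, tolerance = 20)

  w <- compare_groups(tab, "length", design = "two_group")
  expect_lt(w$p_value, 1e-10)
})

test_that("p-values are invariant to group relabeling and row order", {
  set.seed(17)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 8),
                    mouse_id = paste0("m", 1:24),
                    length = rnorm(24, 200, 25))
  r1 <- compare_groups(tab, "length", design = "multi_group")
  tab2 <- tab[sample(nrow(tab)), ]
  tab2$group <- chartr("abc", "zyx", tab2$group)
  r2 <- compare_groups(tab2, "length", design = "multi_group")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(sort(r1$pairs$p_adj), sort(r2$pairs$p_adj), tolerance = 1e-12)
})

test_that("groups with fewer than 2 observations are named in the error", {
  tab <- data.frame(group = c("a", "a", "b"), mouse_id = c("1", "2", "3"),
                    length = c(1, 2, 3))
  expect_error(compare_groups(tab, "length", design = "two_group"), "b")
})

test_that("ANOVA type-I error is calibrated at the 5% level", {
  set.seed(2024)
  n_sim <- 400 # three equal-mean groups; binomial sd ~ 1.1% at 400 draws
  rejected <- 0L
  for (s in seq_len(n_sim)) {
    tab <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                      mouse_id = paste0("m", 1:30),
                      length = rnorm(30))
    r <- compare_groups(tab, "length", design = "multi_group")
    if (r$p_value < 0.05) rejected <- rejected + 1L
  }
  expect_lt(abs(rejected / n_sim - 0.05), 0.03)
})

test_that("run_pipeline writes all artifacts and reruns byte-identically", {
  tmp <- withr::local_tempdir()
  cfg <- small_cohort_config(file.path(tmp, "run1"), seed = 3)
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
  out1 <- file.path(tmp, "run1")
  expect_true(file.exists(file.path(out1, "morphometry.csv")))
  expect_true(file.exists(file.path(out1, "summary.csv")))
  expect_true(file.exists(file.path(out1, "comparisons.json")))
  expect_true(file.exists(file.path(out1, "runlog.json")))

  morph <- read_table(file.path(out1, "morphometry.csv"))
  expect_identical(nrow(morph), 8L) # 2 groups x 2 mice x 2 villi
  expect_true(all(c("group", "mouse_id", "length", "volume") %in% names(morph)))

  comp <- jsonlite::read_json(file.path(out1, "comparisons.json"),
                              simplifyVector = TRUE)
  expect_true("length" %in% names(comp))
  expect_true(is.numeric(comp$length$p_value))

  cfg2 <- small_cohort_config(file.path(tmp, "run2"), seed = 3)
  suppressMessages(suppressWarnings(run_pipeline(cfg2)))
  for (f in c("morphometry.csv", "summary.csv", "comparisons.json",
              "runlog.json")) {
    expect_identical(readLines(file.path(tmp, "run1", f)),
                     readLines(file.path(tmp, "run2", f)),
                     label = f)
  }
})

test_that("bind_cohorts rejects mixed schemas", {
  a <- cohort_table(data.frame(sample_id = "s", label_id = 1L, length = 1),
                    group = "g", mouse_id = "m")
  b <- cohort_table(data.frame(sample_id = "s", label_id = 1L, volume = 1),
                    group = "g", mouse_id = "m")
  expect_error(bind_cohorts(a, b), "schema")
})

test_that("stack-ingest pipeline mode runs from TIFFs and JSON annotations", {
  tmp <- withr::local_tempdir()
  spec <- phantom_grid_spec(1, 2, 30, 30, 16, shaft_length = 40, radius = 10,
                            spacing = c(1, 0.5, 0.5), clearance = 2, seed = 33)
  ph <- generate_phantom(spec, channels = "actin")
  stack_path <- file.path(tmp, "actin.ome.tif")
  write_volume(ph$actin, stack_path)

  # polygon annotations: the slab footprint on a few slices, closed above
  shape <- dim(ph$actin$data)
  ext <- (shape - 1) * spec$spacing
  crypt_top <- max(which(apply(ph$crypt_mask$data, 1, any)))
  footprint <- list(c(0.5, 0.5), c(0.5, ext[3] - 0.5),
                    c(ext[2] - 0.5, ext[3] - 0.5), c(ext[2] - 0.5, 0.5))
  annos <- lapply(c(1L, 8L, crypt_top), function(z)
    list(z = z, polygon = footprint))
  # slices above the last annotation copy it, so the annotator closes the
  # crypt region with a (near-)empty region a few slices higher
  tiny <- list(c(0.2, 0.2), c(0.2, 1.2), c(1.2, 0.7))
  annos <- c(annos, list(list(z = crypt_top + 3L, polygon = tiny)))
  anno_path <- file.path(tmp, "annos.json")
  jsonlite::write_json(annos, anno_path, auto_unbox = TRUE, digits = NA)
  expect_length(read_annotations(anno_path), 4L)

  cfg <- list(
    seed = 5,
    out_dir = file.path(tmp, "out"),
    stacks = list(list(actin = stack_path, annotations = anno_path,
                       spacing = c(1, 0.5, 0.5), sample_id = "s1",
                       group = "g1", mouse_id = "m1"),
                  list(actin = stack_path, annotations = anno_path,
                       spacing = c(1, 0.5, 0.5), sample_id = "s2",
                       group = "g2", mouse_id = "m2")),
    params = list(downsample_factors = c(2, 4, 4), sigma_schedule = c(8, 6),
                  erosion_step = 2, max_iterations = 8,
                  min_seed_volume = 100))
  suppressMessages(suppressWarnings(run_pipeline(cfg)))
  morph <- read_table(file.path(cfg$out_dir, "morphometry.csv"))
  expect_identical(nrow(morph), 4L) # 2 stacks x 2 villi
  expect_true(all(morph$length > 30 & morph$length < 60))
})

test_that("pipeline errors carry the sample id", {
  tmp <- withr::local_tempdir()
  cfg <- list(seed = 1, out_dir = file.path(tmp, "x"),
              stacks = list(list(actin = file.path(tmp, "missing.tif"),
                                 annotations = "none.json",
                                 spacing = c(1, 1, 1),
                                 sample_id = "bad_sample", group = "g",
                                 mouse_id = "m")))
  expect_error(run_pipeline(cfg), "bad_sample")
})
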