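# Cohort aggregation and group comparisons.
#
# Whole-mount studies report two n's ("n = 5 mice, n = 88 villi"): summaries
# and tests can be computed over villi or over per-mouse means, and
# pseudo-replication at the villus level is a known hazard, so both levels
# are always available and the pipeline emits both rather than silently
# choosing one.

#' Build a cohort table
#'
#' @param morphometry per-villus measurement data.frame (from
#'   [measure_villi()]).
#' @param group group name for these rows.
#' @param mouse_id animal identifier for these rows.
#' @return A `cohort_table` data.frame (schema version attribute attached).
#' @export
cohort_table <- function(morphometry, group, mouse_id) {
  out <- cbind(group = group, mouse_id = mouse_id, morphometry)
  attr(out, "schema_version") <- "1"
  class(out) <- c("cohort_table", class(out))
  out
}

#' Bind cohort tables
#'
#' @param ... cohort tables sharing one schema.
#' @return A combined `cohort_table`.
#' @export
bind_cohorts <- function(...) {
  parts <- list(...)
  cols <- lapply(parts, names)
  if (length(unique(vapply(cols, paste, "", collapse = "|"))) != 1L) {
    stop("cohort tables have mixed schemas", call. = FALSE)
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "schema_version") <- "1"
  class(out) <- c("cohort_table", class(out))
  out
}

#' Per-group summaries at the villus or mouse level
#'
#' Mean, s.e.m. (`sd/sqrt(n)`), median and IQR per group for each requested
#' metric. At the villus level n counts villi; at the mouse level each
#' mouse contributes its per-mouse mean and n counts mice. Groups with a
#' single observation get a flagged `NA` s.e.m.
#'
#' @param table a cohort table.
#' @param level "villus" or "mouse".
#' @param metrics metric column names; defaults to the numeric measurement
#'   columns present.
#' @return data.frame: group, metric, level, n, mean, sem, median, iqr, flags.
#' @export
summarize_cohort <- function(table, level = c("villus", "mouse"),
                             metrics = NULL) {
  if (!level[1] %in% c("villus", "mouse")) {
    stop(sprintf("unknown summary level: %s", level[1]), call. = FALSE)
  }
  level <- match.arg(level)
  if (is.null(metrics)) {
    metrics <- intersect(c("length", "volume", "surface_area", "flatness"),
                         names(table))
  }
  rows <- list()
  for (g in unique(table$group)) {
    sub <- table[table$group == g, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      keep <- !is.na(v)
      v <- v[keep]
      if (level == "mouse") {
        v <- tapply(v, sub$mouse_id[keep], mean)
        v <- as.numeric(v[!is.na(v)])
      }
      n <- length(v)
      sem <- if (n >= 2) sd(v) / sqrt(n) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, level = level, n = n,
        mean = if (n > 0) mean(v) else NA_real_,
        sem = sem,
        median = if (n > 0) median(v) else NA_real_,
        iqr = if (n > 0) IQR(v) else NA_real_,
        flags = if (n < 2) "n_lt_2" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare groups for one metric
#'
#' Two groups: Welch two-tailed t-test by default (`var_equal = TRUE` gives
#' the classical pooled test), with the mean difference and its 95% CI.
#' More than two groups: one-way ANOVA plus all-pairs Tukey HSD adjusted
#' p-values with difference CIs. Observations are villi (`level =
#' "villus"`) or per-mouse means (`level = "mouse"`).
#'
#' @param table a cohort table.
#' @param metric metric column to compare.
#' @param design "two_group" or "multi_group".
#' @param level "villus" or "mouse".
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list report: design, metric, level, per-group n, and the test
#'   results (statistic, df, p_value, and a `pairs` data.frame of effect
#'   sizes with 95% CIs).
#' @export
compare_groups <- function(table, metric,
                           design = c("two_group", "multi_group"),
                           level = c("villus", "mouse"),
                           var_equal = FALSE) {
  design <- match.arg(design)
  level <- match.arg(level)
  v <- table[[metric]]
  keep <- !is.na(v)
  df0 <- data.frame(value = v[keep], group = as.character(table$group[keep]),
                    mouse = as.character(table$mouse_id[keep]),
                    stringsAsFactors = FALSE)
  if (level == "mouse") {
    agg <- aggregate(value ~ group + mouse, df0, mean)
    df0 <- data.frame(value = agg$value, group = agg$group,
                      stringsAsFactors = FALSE)
  }
  ng <- table(df0$group)
  if (length(ng) < 2L) stop("need at least two groups", call. = FALSE)
  small <- names(ng)[ng < 2]
  if (length(small) > 0) {
    stop(sprintf("groups with fewer than 2 observations: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  if (design == "two_group") {
    if (length(ng) != 2L) stop("two_group design requires exactly 2 groups",
                               call. = FALSE)
    gs <- sort(names(ng))
    x <- df0$value[df0$group == gs[2]]
    y <- df0$value[df0$group == gs[1]]
    tt <- t.test(x, y, var.equal = var_equal)
    pairs <- data.frame(
      comparison = sprintf("%s-%s", gs[2], gs[1]),
      diff = unname(tt$estimate[1] - tt$estimate[2]),
      lwr = tt$conf.int[1], upr = tt$conf.int[2],
      p_adj = tt$p.value, stringsAsFactors = FALSE)
    report <- list(design = design, metric = metric, level = level,
                   n = as.list(ng),
                   test = if (var_equal) "two-tailed pooled t-test"
                          else "two-tailed Welch t-test",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value,
                   pairs = pairs)
  } else {
    fit <- aov(value ~ group, data = df0)
    ss <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pairs <- data.frame(comparison = rownames(tk),
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p_adj = tk[, "p adj"],
                        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    report <- list(design = design, metric = metric, level = level,
                   n = as.list(ng),
                   test = "one-way ANOVA + Tukey HSD",
                   statistic = ss$`F value`[1],
                   df = c(ss$Df[1], ss$Df[2]),
                   p_value = ss$`Pr(>F)`[1],
                   pairs = pairs)
  }
  report
}

# rethrow any stage error with the sample id attached
with_sample_context <- function(sample_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("sample '%s': %s", sample_id, conditionMessage(e)),
         call. = FALSE)
  })
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(master, n) {
  (as.integer(master) * 1103L + 12345L + 7919L * seq_len(n)) %% 2147483647L
}

#' Run the end-to-end pipeline from a config
#'
#' The config (an R list or a YAML file path) describes either phantom
#' cohorts to generate or stacks to ingest, plus segmentation parameters and
#' comparisons. All stages are executed per sample (phantom/ingest, crypt
#' masking, segmentation, morphometry), cohort summaries at both levels and
#' the requested group comparisons are computed, and everything is written
#' under `out_dir`: `morphometry.csv`, `summary.csv`, `comparisons.json`,
#' `runlog.json` and per-sample label volumes. Outputs contain no
#' timestamps; rerunning the same config gives byte-identical tabular
#' outputs.
#'
#' Config schema (YAML keys):
#' \preformatted{
#' seed: 1
#' out_dir: path
#' cohorts:                 # phantom mode
#'   - group: nulliparous
#'     n_mice: 5
#'     phantom: {n_rows: 2, n_cols: 3, pitch_y: 30, pitch_x: 30, margin: 14,
#'               shaft_length: 40, radius: 8, flattening: 1, jitter: 1.5,
#'               spacing: [1, 0.5, 0.5]}
#' params: {downsample_factors: [1, 2, 2], sigma_schedule: [12, 8, 5],
#'          erosion_step: 2, max_iterations: 8, min_seed_volume: 100}
#' surface_method: crofton
#' compare: {metrics: [length, flatness], design: multi_group}
#' }
#'
#' @param config list or YAML file path.
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (!is.null(config$params)) do.call(seeding_params, config$params)
            else seeding_params()
  surface_method <- if (!is.null(config$surface_method))
    config$surface_method else "crofton"
  master_seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L

  tables <- list()
  runlog <- list(package = "villimorph",
                 version = as.character(packageVersion("villimorph")),
                 seed = master_seed,
                 params = unclass(params),
                 samples = list())
  if (!is.null(config$cohorts)) {
    total <- sum(vapply(config$cohorts, function(co) co$n_mice, numeric(1)))
    seeds <- derive_seeds(master_seed, total)
    si <- 0L
    for (co in config$cohorts) {
      for (mi in seq_len(co$n_mice)) {
        si <- si + 1L
        sample_id <- sprintf("%s_m%02d", co$group, mi)
        ph_args <- co$phantom
        if (!is.null(ph_args$spacing)) {
          ph_args$spacing <- as.numeric(unlist(ph_args$spacing))
        }
        ph_args$seed <- seeds[si]
        res <- with_sample_context(sample_id, {
          spec <- do.call(phantom_grid_spec, ph_args)
          process_phantom_sample(spec, params, surface_method)
        })
        tables[[si]] <- cohort_table(res$morphometry, group = co$group,
                                     mouse_id = sample_id)
        write_volume(res$labels,
                     file.path(out_dir, paste0(sample_id, "_labels.ome.tif")))
        runlog$samples[[sample_id]] <- c(res$runlog, list(seed = seeds[si]))
      }
    }
  } else if (!is.null(config$stacks)) {
    for (si in seq_along(config$stacks)) {
      st <- config$stacks[[si]]
      seg_res <- with_sample_context(st$sample_id, {
        actin <- read_stack(st$actin,
                            spacing_override = if (!is.null(st$spacing))
                              as.numeric(unlist(st$spacing)) else NULL)
        annos <- read_annotations(st$annotations)
        crypt <- interpolate_annotations(annos, dim(actin$data),
                                         actin$spacing)
        seg <- segment_villi(actin, crypt, params)
        morph <- measure_villi(seg$labels, seg$base,
                               sample_id = st$sample_id,
                               surface_method = surface_method)
        list(seg = seg, morph = morph)
      })
      seg <- seg_res$seg
      morph <- seg_res$morph
      tables[[si]] <- cohort_table(morph, group = st$group,
                                   mouse_id = st$mouse_id)
      write_volume(seg$labels,
                   file.path(out_dir, paste0(st$sample_id, "_labels.ome.tif")))
      runlog$samples[[st$sample_id]] <- seg$runlog
    }
  } else {
    stop("config must provide `cohorts` (phantom mode) or `stacks`",
         call. = FALSE)
  }

  all_rows <- do.call(bind_cohorts, tables)
  write_table(as.data.frame(all_rows), file.path(out_dir, "morphometry.csv"))
  summ <- rbind(summarize_cohort(all_rows, "villus"),
                summarize_cohort(all_rows, "mouse"))
  write_table(summ, file.path(out_dir, "summary.csv"))

  comparisons <- list()
  if (!is.null(config$compare) && length(unique(all_rows$group)) >= 2) {
    for (m in config$compare$metrics) {
      comparisons[[m]] <- compare_groups(
        all_rows, m,
        design = if (!is.null(config$compare$design)) config$compare$design
                 else "multi_group")
    }
  }
  jsonlite::write_json(comparisons, file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(runlog, file.path(out_dir, "runlog.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

# one phantom sample through the full pipeline (annotation emulation: the
# crypt slab is annotated on every 4th slice plus its last slice; on the two
# slices just above the slab the annotator traces the crypt region around
# the villus cross-sections - the mucosal plane minus the villus disks - and
# an annotated-empty slice terminates the region)
process_phantom_sample <- function(spec, params, surface_method = "crofton") {
  ph <- generate_phantom(spec, channels = "actin")
  shape <- dim(ph$actin$data)
  crypt_top <- max(which(apply(ph$crypt_mask$data, 1, any)))
  zs <- unique(c(seq(1L, crypt_top, by = 4L), crypt_top))
  annos <- lapply(zs, function(k) {
    slice_annotation(k, mask = matrix(ph$crypt_mask$data[k, , ],
                                      shape[2], shape[3]))
  })
  for (k in crypt_top + 1:2) {
    if (k <= shape[1]) {
      annos <- c(annos, list(slice_annotation(
        k, mask = matrix(ph$truth_labels$data[k, , ] == 0L,
                         shape[2], shape[3]))))
    }
  }
  if (crypt_top + 3L <= shape[1]) {
    annos <- c(annos, list(slice_annotation(
      crypt_top + 3L, mask = matrix(FALSE, shape[2], shape[3]))))
  }
  crypt <- interpolate_annotations(annos, shape, ph$actin$spacing)
  seg <- segment_villi(ph$actin, crypt, params)
  morph <- measure_villi(seg$labels, seg$base,
                         sample_id = sprintf("phantom_seed%d", spec$rng_seed),
                         surface_method = surface_method)
  list(labels = seg$labels, base = seg$base, morphometry = morph,
       truth = ph$truth, truth_labels = ph$truth_labels, runlog = seg$runlog)
}
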