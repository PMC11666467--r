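# Reading and writing volumes (TIFF + OME-XML companion metadata), tables
# (CSV + JSON units sidecar) and point sets (JSON).

companion_path <- function(path) paste0(path, ".companion.ome")

ome_xml_string <- function(dims, spacing, type, channel, scale = NULL) {
  doc <- xml2::xml_new_root("OME",
    xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = channel)
  px <- xml2::xml_add_child(img, "Pixels",
    ID = "Pixels:0", DimensionOrder = "XYZCT", Type = type,
    SizeX = dims[3], SizeY = dims[2], SizeZ = dims[1],
    SizeC = 1L, SizeT = 1L,
    PhysicalSizeX = format(spacing[3], digits = 17),
    PhysicalSizeY = format(spacing[2], digits = 17),
    PhysicalSizeZ = format(spacing[1], digits = 17),
    PhysicalSizeXUnit = "µm", PhysicalSizeYUnit = "µm",
    PhysicalSizeZUnit = "µm")
  if (!is.null(scale)) {
    xml2::xml_add_child(px, "ScaleFactor", Value = format(scale, digits = 17))
  }
  as.character(doc)
}

parse_ome_spacing <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  sp <- suppressWarnings(as.numeric(c(
    xml2::xml_attr(px, "PhysicalSizeZ"),
    xml2::xml_attr(px, "PhysicalSizeY"),
    xml2::xml_attr(px, "PhysicalSizeX"))))
  if (anyNA(sp)) return(NULL)
  scale_node <- xml2::xml_find_first(doc, ".//*[local-name()='ScaleFactor']")
  scale <- if (!inherits(scale_node, "xml_missing")) {
    suppressWarnings(as.numeric(xml2::xml_attr(scale_node, "Value")))
  } else NA_real_
  name <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name()='Image']"), "Name")
  list(spacing = sp, scale = scale, channel = name)
}

# best-effort ImageJ-style "spacing=2.15" description parsing (z only)
parse_imagej_spacing <- function(txt) {
  m <- regmatches(txt, regexec("spacing=([0-9.eE+-]+)", txt))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NULL
}

#' Read a 3D TIFF / OME-TIFF stack
#'
#' Pages become z-slices; the returned grid is in (z, y, x) order. Voxel
#' spacing is taken from OME-XML metadata when present (embedded
#' ImageDescription or a `<path>.companion.ome` sidecar written by
#' [write_volume()]); an embedded ImageJ-style `spacing=` tag is read
#' best-effort for the z-step. If `spacing_override` is supplied it always
#' wins (with a warning when metadata was also present). With no metadata
#' and no override the read fails: spacing is mandatory.
#'
#' @param path TIFF file path.
#' @param spacing_override optional (dz, dy, dx) in um.
#' @param channel optional channel name; defaults to the metadata name.
#' @return An [intensity_volume()].
#' @export
read_stack <- function(path, spacing_override = NULL, channel = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && nzchar(desc)) {
    meta <- parse_ome_spacing(desc)
    if (is.null(meta)) {
      zstep <- parse_imagej_spacing(desc)
      if (!is.null(zstep)) meta <- list(spacing = c(zstep, NA, NA),
                                        scale = NA_real_, channel = NA)
    }
  }
  if (is.null(meta) && file.exists(companion_path(path))) {
    meta <- parse_ome_spacing(paste(readLines(companion_path(path),
                                              warn = FALSE), collapse = "\n"))
  }
  spacing <- NULL
  if (!is.null(meta) && !anyNA(meta$spacing)) spacing <- meta$spacing
  if (!is.null(spacing_override)) {
    if (!is.null(spacing)) {
      warning("spacing metadata present; spacing_override takes precedence",
              call. = FALSE)
    }
    spacing <- check_spacing(spacing_override)
  }
  if (is.null(spacing)) {
    stop(sprintf(
      "no voxel spacing: %s carries no usable metadata and no spacing_override was given",
      path), call. = FALSE)
  }

  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) arr[k, , ] <- pages[[k]]

  scale <- if (!is.null(meta)) meta$scale else NA_real_
  if (!is.null(scale) && length(scale) == 1L && !is.na(scale)) {
    # float volume stored as scaled [0,1] 32-bit; undo the scaling
    arr <- arr * scale
  } else if (is.integer(pages[[1]])) {
    storage.mode(arr) <- "integer"
  }
  if (is.null(channel)) {
    channel <- if (!is.null(meta) && length(meta$channel) == 1L &&
                   !is.na(meta$channel)) meta$channel else "unknown"
  }
  intensity_volume(arr, spacing, channel = channel)
}

#' Write a volume as TIFF with OME-XML metadata
#'
#' Accepts an [intensity_volume()], [binary_mask()] or [label_volume()].
#' Integer-valued data (labels, masks, detector counts) in 0..65535 are
#' stored losslessly as 8- or 16-bit pages; other numeric data are scaled to
#' `[0, 1]` and stored as 32-bit samples (quantized to ~2^-32 relative
#' precision, recorded via a ScaleFactor element so reads invert the
#' scaling). Voxel spacing, pixel type and channel name are written as
#' OME-XML to the `<path>.companion.ome` sidecar.
#'
#' @param vol the volume to write.
#' @param path output TIFF path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  }
  data <- vol$data
  dims <- dim(data)
  channel <- if (inherits(vol, "intensity_volume")) vol$channel
             else if (inherits(vol, "label_volume")) paste0("labels:", vol$kind)
             else "mask"
  if (inherits(vol, "binary_mask")) data <- data * 1L

  is_int <- is.integer(data) ||
    (is.numeric(data) && !anyNA(data) && all(data == round(data)) &&
       min(data) >= 0 && max(data) <= 65535)
  scale <- NULL
  if (is_int) {
    lo <- 0; hi <- max(data)
    bits <- if (hi <= 255) 8L else 16L
    denom <- if (bits == 8L) 255 else 65535
    if (hi > 65535 || min(data) < 0) {
      is_int <- FALSE
    } else {
      pages <- lapply(seq_len(dims[1]),
                      function(k) matrix(data[k, , ] / denom, dims[2], dims[3]))
      type <- if (bits == 8L) "uint8" else "uint16"
      suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                       compression = "none"))
    }
  }
  if (!is_int) {
    scale <- max(abs(range(data)), 1e-300)
    pages <- lapply(seq_len(dims[1]),
                    function(k) matrix(pmax(data[k, , ], 0) / scale,
                                       dims[2], dims[3]))
    if (min(data) < 0) {
      stop("float volumes with negative values are not supported by the TIFF writer",
           call. = FALSE)
    }
    type <- "float"
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                     compression = "none"))
  }
  xml <- ome_xml_string(dims, vol$spacing, type, channel, scale = scale)
  writeLines(xml, companion_path(path))
  invisible(path)
}

#' Read a label volume written by [write_volume()]
#'
#' @param path TIFF path.
#' @param spacing_override optional (dz, dy, dx) um.
#' @param kind label kind.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, spacing_override = NULL, kind = "villus") {
  v <- read_stack(path, spacing_override = spacing_override)
  label_volume(v$data, v$spacing, kind = kind)
}

#' Read a binary mask written by [write_volume()]
#'
#' @inheritParams read_labels
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, spacing_override = NULL) {
  v <- read_stack(path, spacing_override = spacing_override)
  binary_mask(v$data > 0, v$spacing)
}

# units of the standard morphometry columns (sidecar metadata)
morphometry_units <- function(cols) {
  lut <- c(sample_id = "text", label_id = "id", group = "text",
           mouse_id = "text",
           length = "um", volume = "um^3", surface_area = "um^2",
           surface_area_crofton = "um^2", surface_area_mesh = "um^2",
           flatness = "dimensionless", base_contact_area = "um^2",
           crypt_depth = "um", villus_crypt_ratio = "dimensionless",
           migration_distance = "um", area = "um^2", flags = "text",
           flat_axis_z = "unit vector component",
           flat_axis_y = "unit vector component",
           flat_axis_x = "unit vector component")
  out <- lut[cols]
  out[is.na(out)] <- "unknown"
  names(out) <- cols
  as.list(out)
}

#' Write a morphometry / cohort table as CSV with a JSON units sidecar
#'
#' Rows are written in a deterministic order (sample id, then label id when
#' those columns exist). Numeric fields are serialized with 17 significant
#' digits so a write/parse round trip reproduces doubles exactly. Column
#' units are documented in `<path>.units.json`.
#'
#' @param rows a data.frame sharing one schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame", call. = FALSE)
  if (nrow(rows) > 0) {
    ord <- seq_len(nrow(rows))
    if (all(c("sample_id", "label_id") %in% names(rows))) {
      ord <- order(rows$sample_id, rows$label_id)
    } else if ("label_id" %in% names(rows)) {
      ord <- order(rows$label_id)
    }
    rows <- rows[ord, , drop = FALSE]
  }
  out <- rows
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      out[[cn]] <- ifelse(is.na(rows[[cn]]), NA_character_,
                          sprintf("%.17g", rows[[cn]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  jsonlite::write_json(morphometry_units(names(rows)),
                       paste0(path, ".units.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a point set to JSON
#'
#' @param ps a [point_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  jsonlite::write_json(
    list(label = ps$label,
         points = lapply(seq_len(nrow(ps$points)),
                         function(r) as.numeric(ps$points[r, ]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point set from JSON
#'
#' @param path JSON path with fields `label` and `points` (list of (z,y,x)).
#' @return A [point_set()].
#' @export
read_points <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  if (is.null(pts) || length(pts) == 0) pts <- matrix(numeric(0), 0, 3)
  point_set(matrix(as.numeric(pts), ncol = 3), label = obj$label)
}
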