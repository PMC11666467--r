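# From sparse per-slice crypt annotations to a 3D crypt mask, crypt removal,
# and the villus base surface.
#
# Interpolation is shape-based: each annotated slice becomes a signed 2D
# Euclidean distance field (negative inside the region, clamped to the slice
# diagonal so empty and full annotations stay finite), unannotated slices
# between two annotated ones get the linear interpolation of the bracketing
# fields, slices outside the annotated range copy the nearest field, and the
# mask is the <= 0 level set. This realizes "interpolate sparse 2D
# annotations to 3D" deterministically and handles growing/shrinking regions
# (a disk whose radius changes linearly between annotated slices stays a
# disk with linearly interpolated radius).

#' Create a per-slice crypt annotation
#'
#' The unit of manual crypt annotation: one closed region on one z-slice,
#' given either as a 2D logical mask (ny, nx) or as a simple closed polygon
#' in physical (y, x) um coordinates. An empty mask is allowed and marks a
#' slice as annotated-empty (useful to terminate the crypt region).
#'
#' @param z_index 1-based slice index.
#' @param mask 2D logical matrix (ny, nx), or NULL.
#' @param polygon numeric matrix with columns (y, x) in um, or NULL.
#' @return A `slice_annotation` object.
#' @export
slice_annotation <- function(z_index, mask = NULL, polygon = NULL) {
  if (is.null(mask) == is.null(polygon)) {
    stop("provide exactly one of `mask` or `polygon`", call. = FALSE)
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
      stop("polygon must be a (y, x) matrix with at least 3 vertices",
           call. = FALSE)
    }
    if (polygon_self_intersects(polygon)) {
      stop("polygon must be simple (non-self-intersecting)", call. = FALSE)
    }
  }
  structure(list(z_index = as.integer(z_index), mask = mask,
                 polygon = polygon),
            class = "slice_annotation")
}

# segment intersection test for polygon simplicity (non-adjacent edges)
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  segs <- cbind(poly, poly[c(2:n, 1), ])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      a <- segs[i, ]; b <- segs[j, ]
      d1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (d1 != d2 && d3 != d4 && d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon with the even-odd rule at pixel centres
#'
#' @param polygon (y, x) um matrix of vertices of a closed simple polygon.
#' @param shape2d (ny, nx).
#' @param spacing2d (dy, dx) um.
#' @return 2D logical matrix.
#' @export
rasterize_polygon <- function(polygon, shape2d, spacing2d) {
  ny <- shape2d[1]; nx <- shape2d[2]
  yc <- (seq_len(ny) - 1) * spacing2d[1]
  xc <- (seq_len(nx) - 1) * spacing2d[2]
  Y <- matrix(yc, ny, nx)
  X <- matrix(xc, ny, nx, byrow = TRUE)
  n <- nrow(polygon)
  inside <- matrix(FALSE, ny, nx)
  j <- n
  for (i in seq_len(n)) {
    yi <- polygon[i, 1]; xi <- polygon[i, 2]
    yj <- polygon[j, 1]; xj <- polygon[j, 2]
    crosses <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# signed distance field of a 2D mask (um): negative inside, clamped
signed_distance_2d <- function(mask2d, spacing2d, cap) {
  dims <- c(1L, dim(mask2d))
  m <- array(mask2d, dim = dims)
  sp <- c(1, spacing2d)
  if (!any(mask2d)) return(matrix(cap, dim(mask2d)[1], dim(mask2d)[2]))
  if (all(mask2d)) return(matrix(-cap, dim(mask2d)[1], dim(mask2d)[2]))
  d_out <- .edt_cpp(!m, dims, sp)   # distance to mask, positive outside
  d_in <- .edt_cpp(m, dims, sp)     # distance to background, positive inside
  sdf <- matrix(d_out - d_in, dim(mask2d)[1], dim(mask2d)[2])
  pmax(pmin(sdf, cap), -cap)
}

#' Interpolate sparse slice annotations to a 3D mask
#'
#' @param annos list of [slice_annotation()] (at most one per slice; multiple
#'   regions for one slice should be unioned into one mask first).
#' @param shape (nz, ny, nx) of the target volume.
#' @param spacing (dz, dy, dx) um.
#' @return A [binary_mask()] covering the annotated region in 3D.
#' @export
interpolate_annotations <- function(annos, shape, spacing) {
  if (length(annos) == 0L) stop("at least one annotation is required",
                                call. = FALSE)
  spacing <- check_spacing(spacing)
  shape <- as.integer(shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zs <- vapply(annos, function(a) a$z_index, integer(1))
  if (anyDuplicated(zs)) stop("at most one annotation per slice", call. = FALSE)
  if (any(zs < 1L | zs > nz)) {
    stop("annotation z_index outside the volume extent", call. = FALSE)
  }
  cap <- sqrt(sum(((shape - 1) * spacing)^2)) + 1

  fields <- vector("list", length(annos))
  for (ai in seq_along(annos)) {
    a <- annos[[ai]]
    m <- if (!is.null(a$mask)) {
      if (!identical(dim(a$mask), c(ny, nx))) {
        stop("annotation mask shape does not match the volume", call. = FALSE)
      }
      a$mask
    } else {
      if (any(a$polygon[, 1] < 0 | a$polygon[, 1] > (ny - 1) * spacing[2] |
              a$polygon[, 2] < 0 | a$polygon[, 2] > (nx - 1) * spacing[3])) {
        stop("annotation polygon outside the volume extent", call. = FALSE)
      }
      rasterize_polygon(a$polygon, c(ny, nx), spacing[2:3])
    }
    fields[[ai]] <- signed_distance_2d(m, spacing[2:3], cap)
  }
  ord <- order(zs)
  zs <- zs[ord]
  fields <- fields[ord]

  out <- array(FALSE, dim = shape)
  for (k in seq_len(nz)) {
    if (k <= zs[1]) {
      f <- fields[[1]]
    } else if (k >= zs[length(zs)]) {
      f <- fields[[length(zs)]]
    } else {
      hi <- findInterval(k, zs)    # zs[hi] <= k < zs[hi+1]
      if (zs[hi] == k) {
        f <- fields[[hi]]
      } else {
        w <- (k - zs[hi]) / (zs[hi + 1] - zs[hi])
        f <- (1 - w) * fields[[hi]] + w * fields[[hi + 1]]
      }
    }
    out[k, , ] <- f <= 0
  }
  binary_mask(out, spacing)
}

#' Remove the crypt region from the tissue foreground
#'
#' `villus_mask = foreground AND NOT crypt_mask`; the base surface contains
#' the villus-mask voxels 26-adjacent to the crypt mask. When the crypt mask
#' is empty, the base falls back to the villus-mask voxels on the z = 1
#' boundary face (logged with a message), which keeps cropped stacks and
#' floorless phantoms measurable.
#'
#' @param foreground tissue [binary_mask()].
#' @param crypt_mask crypt [binary_mask()] on the same grid.
#' @return list(villus_mask = [binary_mask()], base = base-surface object
#'   with linear voxel `index`, `shape`, `spacing`, `fallback` flag).
#' @export
remove_crypts <- function(foreground, crypt_mask) {
  stop_grid_mismatch(foreground, crypt_mask, "foreground and crypt mask")
  dims <- dim(foreground$data)
  villus <- foreground$data & !crypt_mask$data
  if (any(crypt_mask$data)) {
    adj <- .adjacent_to_cpp(villus, crypt_mask$data, dims)
    base_idx <- which(array(adj, dims))
    fallback <- FALSE
  } else {
    message("crypt mask empty: falling back to the z = 1 face as villus base")
    face <- array(FALSE, dims)
    face[1, , ] <- TRUE
    base_idx <- which(villus & face)
    fallback <- TRUE
  }
  list(villus_mask = binary_mask(villus, foreground$spacing),
       base = base_surface(base_idx, dims, foreground$spacing,
                           fallback = fallback))
}

#' Construct a base-surface object
#'
#' @param index linear (1-based) voxel indices of the base voxels.
#' @param shape (nz, ny, nx) of the parent grid.
#' @param spacing (dz, dy, dx) um.
#' @param fallback whether the z = 1 fallback rule produced these voxels.
#' @return A `base_surface` object.
#' @export
base_surface <- function(index, shape, spacing, fallback = FALSE) {
  structure(list(index = as.integer(index), shape = as.integer(shape),
                 spacing = check_spacing(spacing), fallback = fallback),
            class = "base_surface")
}

#' Per-crypt depth from the luminal opening
#'
#' Depth of each crypt instance is the maximum geodesic (within-crypt)
#' distance from the crypt's opening voxels. Crypts whose label contains no
#' opening voxel yield a flagged row with `NA` depth rather than an error.
#'
#' @param crypt_labels [label_volume()] partitioning the crypt mask.
#' @param opening a [base_surface()]-like object marking the luminal opening
#'   voxels (linear indices on the same grid).
#' @return data.frame: label_id, depth (um), flags.
#' @export
crypt_depth <- function(crypt_labels, opening) {
  stopifnot(inherits(crypt_labels, "label_volume"))
  dims <- dim(crypt_labels$data)
  ids <- sort(setdiff(unique(as.vector(crypt_labels$data)), 0L))
  depth <- rep(NA_real_, length(ids))
  flags <- character(length(ids))
  open_set <- opening$index
  for (t in seq_along(ids)) {
    id <- ids[t]
    inst <- crypt_labels$data == id
    src <- intersect(which(inst), open_set)
    if (length(src) == 0L) {
      flags[t] <- "no_opening"
      next
    }
    seeds <- array(0L, dims)
    seeds[src] <- 1L
    res <- .geodesic_cpp(inst, seeds, dims, crypt_labels$spacing)
    d <- res$dist[inst]
    fin <- is.finite(d)
    depth[t] <- max(d[fin])
    if (any(!fin)) flags[t] <- "disconnected_voxels"
  }
  data.frame(label_id = ids, depth = depth, flags = flags,
             stringsAsFactors = FALSE)
}

#' Read slice annotations from a sparse multi-page mask TIFF
#'
#' Every page with at least one nonzero pixel is taken as an annotated slice
#' (its nonzero pixels form the region); all-zero pages are treated as
#' unannotated. Annotated-empty slices cannot be expressed in this format -
#' use the JSON form with a degenerate polygon, or pass masks directly to
#' [slice_annotation()].
#'
#' @param path multi-page TIFF whose page k is the annotation of slice k.
#' @return list of [slice_annotation()].
#' @export
read_annotations_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- list()
  for (k in seq_along(pages)) {
    m <- pages[[k]] > 0
    if (any(m)) out[[length(out) + 1L]] <- slice_annotation(k, mask = m)
  }
  out
}

#' Read slice annotations from JSON
#'
#' Accepts a JSON list of `{"z": <int>, "polygon": [[y, x], ...]}` records
#' (coordinates in um).
#'
#' @param path JSON file path.
#' @return list of [slice_annotation()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(rec) {
    poly <- do.call(rbind, lapply(rec$polygon, function(p) as.numeric(p)))
    slice_annotation(z_index = rec$z, polygon = poly)
  })
}
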