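# Core containers: 3D grids with physical voxel spacing.
#
# Axis order is (z, y, x) everywhere: a volume with dim (nz, ny, nx) has the
# confocal slice index leading, and voxel (k, j, i) (1-based in R) sits at
# the physical position ((k-1)*dz, (j-1)*dy, (i-1)*dx) micrometres
# (voxel-centre convention, 0-based physical indexing).

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L ||
      anyNA(spacing) || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive finite values (dz, dy, dx) in um",
         call. = FALSE)
  }
  as.numeric(spacing)
}

check_grid <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1 on every axis",
                                call. = FALSE)
  invisible(data)
}

#' Create a 3D intensity volume
#'
#' A single imaging channel on an anisotropic grid. Data are stored in
#' (z, y, x) axis order so that the leading index is the confocal slice;
#' `spacing` gives the physical voxel size (dz, dy, dx) in micrometres.
#' Spacing is mandatory: every downstream measurement is in physical units
#' and whole-mount confocal stacks are strongly anisotropic (a z-step of
#' 2.15 um against sub-micrometre pixels is typical), so a silent default of
#' 1 um would corrupt all morphometry.
#'
#' @param data 3D numeric array, dim (nz, ny, nx).
#' @param spacing numeric length-3, voxel size (dz, dy, dx) in um, all > 0.
#' @param channel free-text channel name (e.g. "actin", "nuclei").
#' @return An `intensity_volume` object.
#' @export
#' @examples
#' v <- intensity_volume(array(0, c(4, 8, 8)), spacing = c(2.15, 0.62, 0.62))
#' dim(v$data)
intensity_volume <- function(data, spacing, channel = "unknown") {
  check_grid(data)
  structure(list(data = data, spacing = check_spacing(spacing),
                 channel = as.character(channel)[1]),
            class = "intensity_volume")
}

#' Create a 3D binary mask
#'
#' @param data 3D logical array, dim (nz, ny, nx).
#' @param spacing voxel size (dz, dy, dx) in um.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing) {
  check_grid(data)
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "binary_mask")
}

#' Create a 3D label volume
#'
#' Non-negative integer labels partition the foreground into instances;
#' 0 is background. `kind` records what the instances are.
#'
#' @param data 3D integer array, dim (nz, ny, nx), values >= 0.
#' @param spacing voxel size (dz, dy, dx) in um.
#' @param kind one of "villus", "crypt", "seed".
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, spacing, kind = c("villus", "crypt", "seed")) {
  kind <- match.arg(kind)
  check_grid(data)
  if (!is.integer(data)) storage.mode(data) <- "integer"
  if (anyNA(data) || min(data) < 0L) {
    stop("labels must be non-negative integers (0 = background)", call. = FALSE)
  }
  structure(list(data = data, spacing = check_spacing(spacing), kind = kind),
            class = "label_volume")
}

#' Relabel a label volume to consecutive ids 1..N
#'
#' Label ids are remapped to a gap-free 1..N set. With
#' `order = "volume"` ids are assigned by descending voxel count (ties broken
#' by the previous id, ascending); with `order = "first"` ids keep the order
#' of their first occurrence in the array.
#'
#' @param labels a `label_volume`.
#' @param order "volume" or "first".
#' @return A `label_volume` with labels 1..N and no gaps.
#' @export
relabel <- function(labels, order = c("volume", "first")) {
  order <- match.arg(order)
  stopifnot(inherits(labels, "label_volume"))
  x <- labels$data
  ids <- sort(unique(x[x > 0L]))
  if (length(ids) == 0L) return(labels)
  if (order == "volume") {
    counts <- tabulate(x, nbins = max(ids))[ids]
    ids <- ids[order(-counts, ids)]
  } else {
    first <- match(ids, x)
    ids <- ids[order(first)]
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  y <- x
  y[x > 0L] <- map[x[x > 0L]]
  label_volume(y, labels$spacing, labels$kind)
}

#' Create a point set in physical coordinates
#'
#' @param points numeric matrix with columns (z, y, x) in um.
#' @param label free-text label, e.g. "EdU+".
#' @return A `point_set` object.
#' @export
point_set <- function(points, label = "points") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have columns (z, y, x) in um",
                               call. = FALSE)
  colnames(points) <- c("z", "y", "x")
  structure(list(points = points, label = as.character(label)[1]),
            class = "point_set")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> channel '%s', %s voxels (z,y,x), spacing %s um\n",
              x$channel, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels (z,y,x), %d foreground, spacing %s um\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$data)), 0L))
  cat(sprintf("<label_volume> kind '%s', %s voxels (z,y,x), %d instances, spacing %s um\n",
              x$kind, paste(dim(x$data), collapse = "x"), n,
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s must share shape and spacing (got %s @ [%s] vs %s @ [%s])",
                 what,
                 paste(dim(a$data), collapse = "x"),
                 paste(format(a$spacing), collapse = ","),
                 paste(dim(b$data), collapse = "x"),
                 paste(format(b$spacing), collapse = ",")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# linear (1-based) indices <-> (k,j,i) voxel indices for dim (nz,ny,nx)
voxel_index_to_kji <- function(idx, dims) {
  idx0 <- idx - 1L
  k <- idx0 %% dims[1]
  r <- idx0 %/% dims[1]
  j <- r %% dims[2]
  i <- r %/% dims[2]
  cbind(k = k + 1L, j = j + 1L, i = i + 1L)
}

kji_to_voxel_index <- function(kji, dims) {
  (kji[, 1] - 1L) + dims[1] * ((kji[, 2] - 1L) + dims[2] * (kji[, 3] - 1L)) + 1L
}
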