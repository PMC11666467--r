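# Synthetic two-channel mucosa phantoms with analytic per-villus geometry.
#
# A phantom is a mucosal floor topped by a crypt layer (together a solid slab
# of thickness floor_thickness + crypt_layer_depth), from which finger-like
# villi rise. Each villus is a capsule: an elliptic cylinder of shaft length
# L_c standing on the slab, closed by a half-ellipsoid tip with vertical
# semi-axis r. The cross-section has semi-axes (a*r, r/a), so a = 1 is a
# circular villus and a > 1 a flattened one with the cross-section area
# pi*r^2 preserved. Closed forms (base disk excluded from the surface):
#   L = L_c + r
#   V = pi r^2 L_c + (2/3) pi r^3            (independent of a)
#   S = P(a r, r/a) L_c + S_cap(a r, r/a, r)
# with P the ellipse perimeter (complete elliptic integral of the second
# kind) and S_cap the half-ellipsoid area (numerical quadrature, relative
# tolerance 1e-9).

#' Describe one villus of a phantom
#'
#' @param base_y,base_x base-centre position in um.
#' @param shaft_length shaft (cylinder) length L_c in um, >= 0.
#' @param radius tip radius r in um, > 0; villus length is L_c + r.
#' @param flattening cross-section anisotropy a >= 1; semi-axes (a*r, r/a).
#' @param tilt axis tilt from the z axis, degrees in `[0, 30]`.
#' @param tilt_azimuth direction of the tilt in the (y, x) plane, degrees.
#' @param orientation angle of the major cross-section axis in the (y, x)
#'   plane, degrees; 0 puts the major axis along x.
#' @return A one-row data.frame of villus parameters.
#' @export
villus_params <- function(base_y, base_x, shaft_length, radius,
                          flattening = 1, tilt = 0, tilt_azimuth = 0,
                          orientation = 0) {
  n <- length(base_y)
  data.frame(base_y = base_y, base_x = base_x,
             shaft_length = rep_len(shaft_length, n),
             radius = rep_len(radius, n),
             flattening = rep_len(flattening, n),
             tilt = rep_len(tilt, n),
             tilt_azimuth = rep_len(tilt_azimuth, n),
             orientation = rep_len(orientation, n))
}

#' Specify a synthetic mucosa phantom
#'
#' Defaults follow the scale of mouse small-intestinal whole-mounts: villus
#' radii of a few tens of um, lengths of a few hundred um, a z-step coarser
#' than the lateral pixel size, and detector-count intensities with additive
#' Gaussian noise.
#'
#' @param volume_shape (nz, ny, nx) voxels.
#' @param spacing (dz, dy, dx) um.
#' @param villi data.frame of [villus_params()] rows (one per villus).
#' @param floor_thickness mucosal floor thickness, um.
#' @param crypt_layer_depth crypt layer thickness above the floor, um.
#' @param noise_sd additive Gaussian noise sd, detector counts.
#' @param psf_sigma Gaussian PSF sigma (z, y, x) in um.
#' @param rng_seed integer seed; all stochastic rendering flows from it.
#' @return A `phantom_spec` object (unvalidated; see [validate_spec()]).
#' @export
phantom_spec <- function(volume_shape, spacing,
                         villi = villus_params(numeric(0), numeric(0),
                                               numeric(0), numeric(0)),
                         floor_thickness = 15,
                         crypt_layer_depth = 60,
                         noise_sd = 5,
                         psf_sigma = c(1.5, 0.5, 0.5),
                         rng_seed = 1L) {
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = check_spacing(spacing),
                 villi = villi,
                 floor_thickness = as.numeric(floor_thickness),
                 crypt_layer_depth = as.numeric(crypt_layer_depth),
                 noise_sd = as.numeric(noise_sd),
                 psf_sigma = as.numeric(psf_sigma),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

villus_axis <- function(v) {
  th <- v$tilt * pi / 180
  ph <- v$tilt_azimuth * pi / 180
  c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph)) # (z, y, x)
}

# pairwise surface clearance. Untilted villi are vertical prisms over their
# cross-section ellipses, so the exact clearance is the 2D distance between
# the two ellipses (evaluated on a dense boundary sampling; the tips only
# shrink the cross-section, so the shaft projection is the binding case).
# Tilted villi fall back to a conservative bound: distance between the axis
# segments minus the two major semi-axes.
villus_pair_clearance <- function(v1, v2, z_base) {
  if (v1$tilt == 0 && v2$tilt == 0) {
    e1 <- ellipse_boundary(v1)
    e2 <- ellipse_boundary(v2)
    d2 <- outer(e1[, 1], e2[, 1], "-")^2 + outer(e1[, 2], e2[, 2], "-")^2
    gap <- sqrt(min(d2))
    # overlapping ellipses: boundary distance is positive but a centre of
    # one may lie inside the other; detect containment/overlap
    if (point_in_ellipse(c(v2$base_y, v2$base_x), v1) ||
        point_in_ellipse(c(v1$base_y, v1$base_x), v2) ||
        any(apply(e1, 1, point_in_ellipse, vi = v2))) {
      return(-gap)
    }
    return(gap)
  }
  p1 <- c(z_base, v1$base_y, v1$base_x)
  p2 <- c(z_base, v2$base_y, v2$base_x)
  u1 <- villus_axis(v1); u2 <- villus_axis(v2)
  q1 <- p1 + (v1$shaft_length + v1$radius) * u1
  q2 <- p2 + (v2$shaft_length + v2$radius) * u2
  segment_distance(p1, q1, p2, q2) -
    v1$flattening * v1$radius - v2$flattening * v2$radius
}

# dense (y, x) boundary sampling of a villus cross-section ellipse
ellipse_boundary <- function(vi, n = 360L) {
  A <- vi$flattening * vi$radius
  B <- vi$radius / vi$flattening
  psi <- vi$orientation * pi / 180
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xe <- A * cos(t); ye <- B * sin(t) # major along x when psi = 0
  cbind(vi$base_y + ye * cos(psi) + xe * sin(psi),
        vi$base_x + xe * cos(psi) - ye * sin(psi))
}

point_in_ellipse <- function(p, vi) {
  A <- vi$flattening * vi$radius
  B <- vi$radius / vi$flattening
  psi <- vi$orientation * pi / 180
  dy <- p[1] - vi$base_y; dx <- p[2] - vi$base_x
  xr <- dx * cos(psi) + dy * sin(psi)
  yr <- dy * cos(psi) - dx * sin(psi)
  (xr / A)^2 + (yr / B)^2 < 1
}

# minimum distance between 3D segments [p1,q1] and [p2,q2]
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (a <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > tiny) min(max((b * f - c1 * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

phantom_z_base <- function(spec) spec$floor_thickness + spec$crypt_layer_depth

#' Validate a phantom specification
#'
#' Checks that spacing is positive, every villus fits inside the volume
#' bounding box, tilt is at most 30 degrees, and villi do not overlap
#' (pairwise clearance between capsule surfaces > `min_clearance`, assessed
#' conservatively from axis-segment distances and major semi-axes).
#'
#' @param spec a [phantom_spec()].
#' @param min_clearance required clearance between villus surfaces, um.
#' @return `spec`, invisibly unchanged, if valid; otherwise an error listing
#'   the offending villus ids.
#' @export
validate_spec <- function(spec, min_clearance = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_spacing(spec$spacing)
  if (length(spec$volume_shape) != 3L || any(spec$volume_shape < 1L)) {
    stop("volume_shape must be three positive integers (nz, ny, nx)",
         call. = FALSE)
  }
  v <- spec$villi
  n <- nrow(v)
  z_base <- phantom_z_base(spec)
  extent <- spec$volume_shape * spec$spacing
  if (z_base > extent[1]) {
    stop("floor + crypt layer exceed the volume extent", call. = FALSE)
  }
  if (n == 0L) return(invisible(spec))
  if (any(v$radius <= 0) || any(v$shaft_length < 0) || any(v$flattening < 1)) {
    bad <- which(v$radius <= 0 | v$shaft_length < 0 | v$flattening < 1)
    stop(sprintf("invalid villus geometry for ids: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(v$tilt < 0 | v$tilt > 30)) {
    stop(sprintf("tilt must be within [0, 30] degrees; offending ids: %s",
                 paste(which(v$tilt < 0 | v$tilt > 30), collapse = ", ")),
         call. = FALSE)
  }
  oob <- logical(n)
  for (i in seq_len(n)) {
    vi <- v[i, ]
    u <- villus_axis(vi)
    base <- c(z_base, vi$base_y, vi$base_x)
    apex <- base + (vi$shaft_length + vi$radius) * u
    rmax <- max(vi$flattening * vi$radius, vi$radius)
    sin_t <- sin(vi$tilt * pi / 180)
    # the apex already includes the cap extent along the axis; the radial
    # envelope is the cross-section ellipse (its exact axis-aligned bbox for
    # untilted villi, the major semi-axis in every direction otherwise,
    # plus rmax*sin(tilt) axially); the solid is clipped at the base plane
    if (vi$tilt == 0) {
      A <- vi$flattening * vi$radius
      B <- vi$radius / vi$flattening
      psi <- vi$orientation * pi / 180
      pad <- c(0,
               sqrt((A * sin(psi))^2 + (B * cos(psi))^2),
               sqrt((A * cos(psi))^2 + (B * sin(psi))^2))
    } else {
      pad <- c(rmax * sin_t, rmax, rmax)
    }
    lo <- pmin(base, apex) - pad
    hi <- pmax(base, apex) + pad
    oob[i] <- hi[1] > extent[1] || lo[2] < 0 || hi[2] > extent[2] ||
      lo[3] < 0 || hi[3] > extent[3]
  }
  if (any(oob)) {
    stop(sprintf("villi outside the volume bounding box: ids %s",
                 paste(which(oob), collapse = ", ")), call. = FALSE)
  }
  if (n >= 2L) {
    bad <- character(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (villus_pair_clearance(v[i, ], v[j, ], z_base) <= min_clearance) {
          bad <- c(bad, sprintf("(%d,%d)", i, j))
        }
      }
    }
    if (length(bad) > 0) {
      stop(sprintf("overlapping villi (surface clearance <= %g um): pairs %s",
                   min_clearance, paste(bad, collapse = " ")), call. = FALSE)
    }
  }
  invisible(spec)
}

ellipse_perimeter <- function(A, B) {
  # A >= B semi-axes; complete elliptic integral of the second kind
  if (A < B) { tmp <- A; A <- B; B <- tmp }
  if (A == 0) return(0)
  m <- 1 - (B / A)^2
  4 * A * pracma::ellipke(m)$e
}

half_ellipsoid_area <- function(A, B, C, tol = 1e-9) {
  # upper half of the ellipsoid with semi-axes (A, B, C), C vertical
  f <- function(th, ph) {
    sin(th) * sqrt(B^2 * C^2 * sin(th)^2 * cos(ph)^2 +
                   A^2 * C^2 * sin(th)^2 * sin(ph)^2 +
                   A^2 * B^2 * cos(th)^2)
  }
  pracma::integral2(f, 0, pi / 2, 0, 2 * pi, reltol = tol)$Q
}

#' Closed-form morphometry of a phantom's villi
#'
#' For each villus of a validated spec, the analytic length, volume and
#' surface area of the capsule (lateral wall plus tip; the base disk is
#' excluded, as it faces the crypt layer), the expected flatness (the
#' cross-section axis ratio `a*r : r/a`, i.e. `a^2`), and the base contact
#' area. Tilt changes none of these (the solid is rigid), and flattening
#' preserves volume by construction.
#'
#' @param spec a validated [phantom_spec()].
#' @param cap_tol relative tolerance of the tip-area quadrature.
#' @return A `phantom_truth` data.frame: label, length, volume, surface,
#'   flatness, a, base_area (um-based units).
#' @export
analytic_morphometry <- function(spec, cap_tol = 1e-9) {
  v <- spec$villi
  n <- nrow(v)
  out <- data.frame(label = integer(0), length = numeric(0),
                    volume = numeric(0), surface = numeric(0),
                    flatness = numeric(0), a = numeric(0),
                    base_area = numeric(0))
  if (n == 0L) {
    class(out) <- c("phantom_truth", class(out))
    return(out)
  }
  rows <- lapply(seq_len(n), function(i) {
    vi <- v[i, ]
    r <- vi$radius; Lc <- vi$shaft_length; a <- vi$flattening
    A <- a * r; B <- r / a
    S <- ellipse_perimeter(A, B) * Lc + half_ellipsoid_area(A, B, r, cap_tol)
    data.frame(label = i,
               length = Lc + r,
               volume = pi * r^2 * Lc + (2 / 3) * pi * r^3,
               surface = S,
               flatness = a^2,
               a = a,
               base_area = pi * r^2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phantom_truth", class(out))
  out
}

# physical coordinate vectors of voxel centres along each axis
axis_coords <- function(shape, spacing) {
  list(z = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       x = (seq_len(shape[3]) - 1) * spacing[3])
}

# voxel-centre inside test for one villus, evaluated on a cropped block.
# Returns the logical array for the block plus the block's index ranges.
villus_voxels <- function(vi, spec) {
  sp <- spec$spacing
  shape <- spec$volume_shape
  z_base <- phantom_z_base(spec)
  u <- villus_axis(vi)
  r <- vi$radius; Lc <- vi$shaft_length; a <- vi$flattening
  A <- a * r; B <- r / a
  base <- c(z_base, vi$base_y, vi$base_x)
  tip <- base + (Lc + r) * u
  rmax <- max(A, B)
  lo <- pmax(floor((pmin(base, tip) - rmax) / sp) + 1, 1)
  hi <- pmin(ceiling((pmax(base, tip) + rmax) / sp) + 1, shape)
  kr <- lo[1]:hi[1]; jr <- lo[2]:hi[2]; ir <- lo[3]:hi[3]
  zc <- (kr - 1) * sp[1]; yc <- (jr - 1) * sp[2]; xc <- (ir - 1) * sp[3]

  # in-plane basis: e1 = major axis, e2 = minor axis, orthonormal with u
  psi <- vi$orientation * pi / 180
  e1 <- c(0, sin(psi), cos(psi))
  e1 <- e1 - sum(e1 * u) * u
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) { # axis ~ parallel to e1; fall back to the y direction
    e1 <- c(0, 1, 0); e1 <- e1 - sum(e1 * u) * u; n1 <- sqrt(sum(e1^2))
  }
  e1 <- e1 / n1
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  nzb <- length(kr); nyb <- length(jr); nxb <- length(ir)
  dz <- rep(zc - base[1], times = nyb * nxb)
  dy <- rep(rep(yc - base[2], each = nzb), times = nxb)
  dx <- rep(xc - base[3], each = nzb * nyb)
  s  <- dz * u[1] + dy * u[2] + dx * u[3]
  p1 <- dz * e1[1] + dy * e1[2] + dx * e1[3]
  p2 <- dz * e2[1] + dy * e2[2] + dx * e2[3]
  rad <- (p1 / A)^2 + (p2 / B)^2
  inside <- (s >= 0 & s <= Lc & rad <= 1) |
    (s > Lc & rad + ((s - Lc) / r)^2 <= 1)
  # clip at the base plane (matters only for tilted villi)
  inside <- inside & (dz + base[1] >= z_base - 1e-9)
  list(block = array(inside, dim = c(nzb, nyb, nxb)), kr = kr, jr = jr, ir = ir)
}

gaussian_kernel <- function(sigma_um, spacing_um) {
  if (sigma_um <= 0) return(1)
  s_vox <- sigma_um / spacing_um
  r <- max(1L, ceiling(3 * s_vox))
  k <- dnorm(seq(-r, r), sd = s_vox)
  k / sum(k)
}

blur_volume <- function(arr, psf_sigma, spacing) {
  dims <- dim(arr)
  out <- as.double(arr)
  for (ax in 1:3) {
    kern <- gaussian_kernel(psf_sigma[ax], spacing[ax])
    if (length(kern) > 1L && dims[ax] > 1L) {
      out <- .conv_axis_cpp(out, dims, kern, ax - 1L)
    }
  }
  array(out, dim = dims)
}

# shell voxels: tissue voxels with a 6-neighbour outside the tissue, or on
# the volume border (so interior cavities are always sealed)
tissue_shell <- function(tissue) {
  dims <- dim(tissue)
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- tissue
  shell <- array(FALSE, dims)
  core <- function(dz, dy, dx) {
    pad[(2 + dz):(dims[1] + 1 + dz),
        (2 + dy):(dims[2] + 1 + dy),
        (2 + dx):(dims[3] + 1 + dx)]
  }
  open6 <- !core(-1, 0, 0) | !core(1, 0, 0) |
           !core(0, -1, 0) | !core(0, 1, 0) |
           !core(0, 0, -1) | !core(0, 0, 1)
  tissue & open6
}

#' Render a phantom into two imaging channels with ground truth
#'
#' Builds the solid tissue (floor + crypt slab + villi) by a voxel-centre
#' inside test, renders an actin-like channel (bright cortical shell over a
#' dimmer tissue interior - at whole-mount resolution the actin-rich
#' epithelium reads as a filled object with a brighter rim) and a
#' nuclei-like channel (random speckle inside the tissue), blurs both with
#' an anisotropic Gaussian PSF, adds Gaussian read noise, and rounds to
#' integer detector counts. All randomness flows from `spec$rng_seed`;
#' identical specs give bit-identical outputs.
#'
#' @param spec a validated [phantom_spec()].
#' @param channels "both" (default) or "actin"; rendering only the actin
#'   channel roughly halves the cost and leaves the actin channel
#'   bit-identical to a "both" render with the same seed (all nuclei-channel
#'   draws happen after the actin draws).
#' @return A list: `nuclei` and `actin` ([intensity_volume()]; `nuclei` is
#'   NULL when not rendered), `truth_labels` ([label_volume()]; villus
#'   voxels only), `crypt_mask` ([binary_mask()]; floor + crypt slab), and
#'   `truth` (the [analytic_morphometry()] table).
#' @export
generate_phantom <- function(spec, channels = c("both", "actin")) {
  channels <- match.arg(channels)
  validate_spec(spec)
  shape <- spec$volume_shape
  sp <- spec$spacing
  z_base <- phantom_z_base(spec)
  zc <- (seq_len(shape[1]) - 1) * sp[1]

  slab <- array(rep(zc < z_base, times = shape[2] * shape[3]), dim = shape)
  labels <- array(0L, dim = shape)
  for (i in seq_len(nrow(spec$villi))) {
    vb <- villus_voxels(spec$villi[i, ], spec)
    sub <- labels[vb$kr, vb$jr, vb$ir]
    sub[vb$block] <- i
    labels[vb$kr, vb$jr, vb$ir] <- sub
  }
  tissue <- slab | labels > 0L
  shell <- tissue_shell(tissue)

  # rendering model (detector counts before blur):
  #   actin: background 10, tissue interior 110, cortical shell 140
  #   nuclei: background 8, tissue 20, nuclear speckle 220 (2% of voxels)
  # the shell is kept close to the interior intensity so that thresholding
  # the blurred image places the tissue boundary at the true surface (a much
  # brighter rim would push the half-maximum crossing outward and bias all
  # volume and surface measurements)
  actin <- array(10, dim = shape)
  actin[tissue] <- 110
  actin[shell] <- 140

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$rng_seed)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  to_counts <- function(x) {
    x <- round(x)
    x[x < 0] <- 0
    x[x > 65535] <- 65535
    storage.mode(x) <- "integer"
    x
  }

  actin <- blur_volume(actin, spec$psf_sigma, sp)
  if (spec$noise_sd > 0) {
    actin <- actin + rnorm(length(actin), sd = spec$noise_sd)
  }

  nuclei <- NULL
  if (channels == "both") {
    nuclei <- array(8, dim = shape)
    nuclei[tissue] <- 20
    tiss_idx <- which(tissue)
    if (length(tiss_idx) > 0) {
      speck <- tiss_idx[runif(length(tiss_idx)) < 0.02]
      nuclei[speck] <- 220
    }
    nuclei <- blur_volume(nuclei, spec$psf_sigma, sp)
    if (spec$noise_sd > 0) {
      nuclei <- nuclei + rnorm(length(nuclei), sd = spec$noise_sd)
    }
    nuclei <- intensity_volume(to_counts(nuclei), sp, channel = "nuclei")
  }

  list(nuclei = nuclei,
       actin = intensity_volume(to_counts(actin), sp, channel = "actin"),
       truth_labels = label_volume(labels, sp, kind = "villus"),
       crypt_mask = binary_mask(slab, sp),
       truth = analytic_morphometry(spec))
}

#' The package's standard validation phantom
#'
#' A 20-villus mucosa phantom at (1, 0.5, 0.5) um spacing used throughout
#' the validation suite: 15 circular villi (r = 12 um, shaft 78 um, length
#' 90 um) in three rows and 5 flattened villi (a = 2, r = 8 um, shaft 82 um,
#' length 90 um, major axis along x) in a fourth row, all on a jittered grid
#' with at least 2 um surface clearance. The geometry is a scaled-down
#' mouse mucosa (real villi are 2-5 times larger); all validated properties
#' are relative errors and counts, which are scale-free, and this size keeps
#' a full phantom near 9M voxels.
#'
#' @param seed rng seed for jitter and rendering.
#' @return A validated [phantom_spec()].
#' @export
validation_phantom_spec <- function(seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  jit <- function() runif(1, -1.5, 1.5)
  rows <- list()
  for (ri in 1:3) {
    for (ci in 1:5) {
      rows[[length(rows) + 1L]] <- villus_params(
        base_y = 16 + (ri - 1) * 30 + jit(),
        base_x = 16 + (ci - 1) * 30 + jit(),
        shaft_length = 78, radius = 12)
    }
  }
  for (ci in 1:5) {
    rows[[length(rows) + 1L]] <- villus_params(
      base_y = 98 + jit(), base_x = 18 + (ci - 1) * 38 + jit(),
      shaft_length = 82, radius = 8, flattening = 2, orientation = 0)
  }
  spec <- phantom_spec(volume_shape = c(110L, 216L, 384L),
                       spacing = c(1, 0.5, 0.5),
                       villi = do.call(rbind, rows),
                       floor_thickness = 4, crypt_layer_depth = 11.5,
                       noise_sd = 5, psf_sigma = c(1, 0.5, 0.5),
                       rng_seed = seed)
  validate_spec(spec, min_clearance = 2)
  spec
}

#' Lay villi out on a jittered grid and build a phantom spec
#'
#' Convenience constructor for cohort work: villi are placed row by row on a
#' regular grid with uniform jitter, and the resulting spec is validated
#' with the requested surface clearance (an error is raised if the jittered
#' layout violates it).
#'
#' @param n_rows,n_cols grid layout; `n_rows * n_cols` villi.
#' @param pitch_y,pitch_x grid pitch in um.
#' @param margin distance from the volume border to the first row/column, um.
#' @param shaft_length,radius,flattening,orientation per-villus geometry,
#'   recycled across the grid.
#' @param jitter max absolute uniform jitter of each base centre, um.
#' @param spacing voxel spacing (dz, dy, dx) um.
#' @param z_margin empty space above the tallest villus, um.
#' @param clearance required surface clearance between villi, um.
#' @param seed rng seed (drives jitter and rendering).
#' @param ... further arguments passed to [phantom_spec()].
#' @return A validated [phantom_spec()].
#' @export
phantom_grid_spec <- function(n_rows, n_cols, pitch_y, pitch_x, margin,
                              shaft_length, radius, flattening = 1,
                              orientation = 0, jitter = 1.5,
                              spacing = c(1, 0.5, 0.5), z_margin = 5,
                              clearance = 0, seed = 1L, ...) {
  n <- n_rows * n_cols
  shaft_length <- rep(shaft_length, length.out = n)
  radius <- rep(radius, length.out = n)
  flattening <- rep(flattening, length.out = n)
  orientation <- rep(orientation, length.out = n)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  idx <- 1L
  rows <- vector("list", n)
  for (ri in seq_len(n_rows)) {
    for (ci in seq_len(n_cols)) {
      jy <- runif(1, -jitter, jitter)
      jx <- runif(1, -jitter, jitter)
      rows[[idx]] <- villus_params(
        base_y = margin + (ri - 1) * pitch_y + jy,
        base_x = margin + (ci - 1) * pitch_x + jx,
        shaft_length = shaft_length[idx], radius = radius[idx],
        flattening = flattening[idx], orientation = orientation[idx])
      idx <- idx + 1L
    }
  }
  villi <- do.call(rbind, rows)
  dots <- list(...)
  floor_thickness <- if (!is.null(dots$floor_thickness))
    dots$floor_thickness else 4
  crypt_layer_depth <- if (!is.null(dots$crypt_layer_depth))
    dots$crypt_layer_depth else 11.5
  z_base <- floor_thickness + crypt_layer_depth
  nz <- ceiling((z_base + max(shaft_length + radius) + z_margin) / spacing[1])
  ny <- ceiling((max(villi$base_y) + max(flattening * radius) + margin) /
                  spacing[2])
  nx <- ceiling((max(villi$base_x) + max(flattening * radius) + margin) /
                  spacing[3])
  args <- c(list(volume_shape = c(nz, ny, nx), spacing = spacing,
                 villi = villi, rng_seed = seed), dots)
  args$floor_thickness <- floor_thickness
  args$crypt_layer_depth <- crypt_layer_depth
  spec <- do.call(phantom_spec, args)
  validate_spec(spec, min_clearance = clearance)
  spec
}
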