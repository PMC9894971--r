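# Beer's-law forward projector. Line integrals are computed with Siddon's
# exact radiological-path traversal (compiled), so projections of
# piecewise-constant volumes are exact up to voxelization and analytic
# chord-length oracles hold tightly.

#' Projection geometry
#'
#' Ray layout for single-view radiographs. In parallel mode rays are
#' orthogonal to the detector; in cone mode they fan out from a point source.
#' The rotation axis is the volume's z axis; detector rows run along z and
#' columns along the in-plane direction perpendicular to the rays. Angles
#' default to `p = 72` views uniform over [0, 360).
#'
#' @param mode `"parallel"` or `"cone"`.
#' @param n_angles number of views p (used when `angles` is `NULL`).
#' @param angles view angles in degrees; defaults to `n_angles` uniform steps
#'   over `[0, 360)`.
#' @param det_rows,det_cols detector pixel counts.
#' @param pixel_size detector pixel pitch in mm.
#' @param source_distance,detector_distance (cone only) source-to-object and
#'   object-to-detector distances in mm.
#' @return A `proj_geometry` object.
#' @export
proj_geometry <- function(mode = c("parallel", "cone"), n_angles = 72,
                          angles = NULL, det_rows = 64, det_cols = 64,
                          pixel_size = 1, source_distance = NULL,
                          detector_distance = NULL) {
  mode <- match.arg(mode)
  if (is.null(angles)) {
    if (n_angles < 1) stop_f("`n_angles` must be >= 1")
    angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  }
  if (pixel_size <= 0) stop_f("`pixel_size` must be > 0")
  if (mode == "cone") {
    if (is.null(source_distance) || is.null(detector_distance) ||
        source_distance <= 0 || detector_distance <= 0)
      stop_f("cone mode needs positive source/detector distances")
  }
  structure(list(mode = mode, angles = as.numeric(angles),
                 det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 pixel_size = as.numeric(pixel_size),
                 source_distance = source_distance,
                 detector_distance = detector_distance),
            class = "proj_geometry")
}

#' Radiograph
#'
#' A single 2-D X-ray view in one of three value domains: `line_integral`
#' (attenuance along each ray, the projector's native output),
#' `photon_count` (detected intensity after Beer's law and possibly noise),
#' or `attenuance` (the negative log image recovered from counts).
#'
#' @param image numeric matrix (rows x cols).
#' @param domain one of `"line_integral"`, `"photon_count"`, `"attenuance"`.
#' @param pixel_size detector pixel pitch (mm).
#' @param angle view angle in degrees.
#' @param I_incident incident photon count (carried for domain conversions).
#' @return A `radiograph` object.
#' @export
radiograph <- function(image, domain = c("line_integral", "photon_count",
                                         "attenuance"),
                       pixel_size = 1, angle = 0, I_incident = NULL) {
  domain <- match.arg(domain)
  if (!is.matrix(image)) stop_f("`image` must be a matrix")
  if (domain %in% c("line_integral", "photon_count") && min(image) < 0)
    stop_f("%s images must be non-negative", domain)
  structure(list(image = image, domain = domain, pixel_size = pixel_size,
                 angle = angle, I_incident = I_incident),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px @ %g mm, domain=%s, angle=%g deg\n",
              nrow(x$image), ncol(x$image), x$pixel_size, x$domain, x$angle))
  invisible(x)
}

#' Forward-project an attenuation volume
#'
#' Computes the Beer's-law line integral `integral mu dl` seen by each
#' detector pixel, by Siddon's exact traversal of the voxel grid. Parallel
#' rays are orthogonal to the detector; cone mode casts rays from a point
#' source through each pixel. The view rotates about the volume's z axis.
#' If the object (any non-zero voxel) would project outside the detector the
#' call errors rather than silently truncating.
#'
#' @param vol an [attenuation_volume()].
#' @param geom a [proj_geometry()].
#' @param angle view angle in degrees (defaults to the first angle of
#'   `geom`).
#' @param supersample rays cast per pixel edge; each pixel value is the mean
#'   over a `supersample x supersample` sub-grid, approximating integration
#'   over the pixel aperture (1 = one central ray, exact for analytic chord
#'   checks; >= 2 suppresses voxel-edge aliasing at the object rim).
#' @return A [radiograph()] in the `line_integral` domain.
#' @export
forward_project <- function(vol, geom, angle = geom$angles[1],
                            supersample = 1) {
  stopifnot(inherits(vol, "attenuation_volume"),
            inherits(geom, "proj_geometry"))
  d <- dim(vol$grid)
  vs <- vol$voxel_size
  ext <- d * vs
  centre <- ext / 2
  a <- angle * pi / 180
  dir <- c(cos(a), sin(a), 0)          # ray direction
  u <- c(-sin(a), cos(a), 0)           # detector column direction
  ps <- geom$pixel_size
  nr <- geom$det_rows; nc <- geom$det_cols
  u_pix <- (seq_len(nc) - (nc + 1) / 2) * ps
  z_pix <- (seq_len(nr) - (nr + 1) / 2) * ps
  check_fov(vol, geom, a, centre, u_pix, z_pix)
  ss <- as.integer(supersample)
  if (ss < 1) stop_f("`supersample` must be >= 1")
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * ps
  img <- matrix(0, nr, nc)
  pix <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  for (su in sub) for (sz in sub) {
    u_off <- u_pix + su
    z_off <- z_pix + sz
    if (geom$mode == "parallel") {
      L <- sqrt(sum(ext^2))            # start rays behind the volume
      origin <- matrix(0, 3, nr * nc)
      origin[1, ] <- centre[1] + u[1] * u_off[pix$c] - dir[1] * L
      origin[2, ] <- centre[2] + u[2] * u_off[pix$c] - dir[2] * L
      origin[3, ] <- centre[3] + z_off[pix$r]
      dmat <- matrix(dir, 3, nr * nc)
    } else {
      src <- centre - dir * geom$source_distance
      det_c <- centre + dir * geom$detector_distance
      px <- det_c[1] + u[1] * u_off[pix$c]
      py <- det_c[2] + u[2] * u_off[pix$c]
      pz <- det_c[3] + z_off[pix$r]
      dmat <- rbind(px - src[1], py - src[2], pz - src[3])
      nrm <- sqrt(colSums(dmat^2))
      dmat <- sweep(dmat, 2, nrm, "/")
      origin <- matrix(src, 3, nr * nc)
    }
    li <- siddon_raycast(vol$grid, d, vs, origin, dmat)
    img <- img + matrix(li, nr, nc)
  }
  radiograph(img / (ss * ss), "line_integral", ps, angle)
}

# error if the object's bounding box projects outside the detector
check_fov <- function(vol, geom, a, centre, u_off, z_off) {
  occ <- which(vol$grid != 0)
  if (!length(occ)) return(invisible(TRUE))
  d <- dim(vol$grid); vs <- vol$voxel_size
  i <- range((occ - 1) %% d[1])
  j <- range(((occ - 1) %/% d[1]) %% d[2])
  k <- range((occ - 1) %/% (d[1] * d[2]))
  corners <- as.matrix(expand.grid(x = (c(i[1], i[2] + 1)) * vs,
                                   y = (c(j[1], j[2] + 1)) * vs,
                                   z = (c(k[1], k[2] + 1)) * vs))
  rel <- sweep(corners, 2, centre)
  u_vec <- c(-sin(a), cos(a), 0)
  if (geom$mode == "parallel") {
    uc <- rel %*% u_vec
    zc <- rel[, 3]
  } else {
    dir <- c(cos(a), sin(a), 0)
    along <- rel %*% dir
    mag <- (geom$source_distance + geom$detector_distance) /
      (geom$source_distance + along)
    uc <- (rel %*% u_vec) * mag
    zc <- rel[, 3] * mag
  }
  half_u <- (length(u_off) / 2) * geom$pixel_size
  half_z <- (length(z_off) / 2) * geom$pixel_size
  if (max(abs(uc)) > half_u || max(abs(zc)) > half_z)
    stop_f("object extends outside the detector field of view at %g deg",
           a * 180 / pi)
  invisible(TRUE)
}

#' Convert line integrals to photon counts (Beer's law)
#'
#' `I0 = I_incident * exp(-integral mu dl)` per pixel: the noiseless detected
#' intensity.
#'
#' @param proj a [radiograph()] in the `line_integral` domain.
#' @param I_incident incident photon count (> 0).
#' @return A [radiograph()] in the `photon_count` domain.
#' @export
attenuance_to_counts <- function(proj, I_incident = 1e4) {
  stopifnot(inherits(proj, "radiograph"))
  if (proj$domain != "line_integral")
    stop_f("expected a line_integral radiograph, got %s", proj$domain)
  if (I_incident <= 0) stop_f("`I_incident` must be > 0")
  radiograph(I_incident * exp(-proj$image), "photon_count",
             proj$pixel_size, proj$angle, I_incident)
}

#' Convert photon counts to an attenuance image
#'
#' `-log(max(I, eps) / I_incident)` per pixel, with `eps = 1` count guarding
#' the logarithm against zero counts. Inverse of [attenuance_to_counts()] on
#' noiseless data.
#'
#' @param proj a [radiograph()] in the `photon_count` domain.
#' @param I_incident incident photon count; defaults to the value carried by
#'   `proj`.
#' @param eps count floor before the log (default 1).
#' @return A [radiograph()] in the `attenuance` domain.
#' @export
counts_to_attenuance <- function(proj, I_incident = proj$I_incident,
                                 eps = 1) {
  stopifnot(inherits(proj, "radiograph"))
  if (proj$domain != "photon_count")
    stop_f("expected a photon_count radiograph, got %s", proj$domain)
  if (is.null(I_incident)) stop_f("`I_incident` unknown")
  radiograph(-log(pmax(proj$image, eps) / I_incident), "attenuance",
             proj$pixel_size, proj$angle, I_incident)
}

#' Write / read a radiograph as 32-bit float TIFF with JSON sidecar
#'
#' @param proj a [radiograph()].
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return `write_radiograph` returns `path` invisibly; `read_radiograph`
#'   the [radiograph()].
#' @export
write_radiograph <- function(proj, path) {
  stopifnot(inherits(proj, "radiograph"))
  # TIFF sample values are stored in [0, 1]; keep the affine map that
  # restores physical values in the sidecar
  offset <- min(proj$image, 0)
  scale <- max(proj$image - offset, 1)
  tiff::writeTIFF((proj$image - offset) / scale, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(
    list(domain = proj$domain, pixel_size = proj$pixel_size,
         angle = proj$angle, I_incident = proj$I_incident, scale = scale,
         offset = offset),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_radiograph
#' @export
read_radiograph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  img <- tiff::readTIFF(path) * (meta$scale %||% 1) + (meta$offset %||% 0)
  radiograph(img, meta$domain, meta$pixel_size, meta$angle,
             meta$I_incident %||% NULL)
}
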