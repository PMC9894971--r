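# Synthetic labelled-volume generators. These stand in for segmented CT
# scans: a homogeneous base object of unpredictable smooth shape with 0-2
# dense convex foreign objects (clay/stone case), a layered fruit with a
# sparse low-attenuation air phase (avocado case), and the didactic
# sphere-in-ball configuration-space example.

#' Sphere-in-ball phantom configuration
#'
#' The didactic foreign-object-detection example: a unit solid sphere (main
#' object) containing a small ball (foreign object). Each sample is a point in
#' a 4-dimensional configuration space: the inner-ball radius and the three
#' coordinates of the vector connecting the two centres.
#'
#' @param inner_radius radius of the inner ball, in units of the outer radius
#'   (which is fixed to 1); must be > 0.
#' @param offset_vector length-3 numeric, vector from the outer-ball centre to
#'   the inner-ball centre. Containment requires
#'   `sqrt(sum(offset^2)) + inner_radius <= 1`.
#' @return A `ball_phantom_config` object.
#' @export
ball_phantom_config <- function(inner_radius, offset_vector = c(0, 0, 0)) {
  if (!is.numeric(inner_radius) || length(inner_radius) != 1L ||
      inner_radius <= 0)
    stop_f("`inner_radius` must be a single positive number")
  if (length(offset_vector) != 3L || !is.numeric(offset_vector))
    stop_f("`offset_vector` must be a numeric 3-vector")
  if (sqrt(sum(offset_vector^2)) + inner_radius > 1 + 1e-12)
    stop_f("inner ball not contained: |offset| + inner_radius = %.3f > 1",
           sqrt(sum(offset_vector^2)) + inner_radius)
  structure(list(inner_radius = inner_radius,
                 offset_vector = as.numeric(offset_vector)),
            class = "ball_phantom_config")
}

#' Voxelize the sphere-in-ball phantom
#'
#' Rasterizes the configuration onto a cubic grid. The unit outer sphere is
#' centred in the grid and scaled so its diameter spans the full grid extent;
#' a voxel belongs to the inner `ball` iff its centre lies within
#' `inner_radius` of the inner centre, to `sphere` iff it lies inside the unit
#' sphere and not in the ball (voxel-centre membership, no partial volumes).
#'
#' @param config a [ball_phantom_config()].
#' @param shape integer length-3 grid dimensions (or a scalar for a cube).
#' @param voxel_size voxel edge in mm.
#' @return A [labeled_volume()] with materials exterior/sphere/ball.
#' @export
make_ball_phantom <- function(config, shape = c(128, 128, 128),
                              voxel_size = 2 / max(shape)) {
  stopifnot(inherits(config, "ball_phantom_config"))
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (min(shape) < 8L) stop_f("grid too small for the unit sphere")
  # unit-sphere coordinates: grid extent maps to [-e, e] per axis with the
  # shortest axis spanning exactly [-1, 1]
  half <- min(shape) / 2
  cx <- (seq_len(shape[1]) - 0.5 - shape[1] / 2) / half
  cy <- (seq_len(shape[2]) - 0.5 - shape[2] / 2) / half
  cz <- (seq_len(shape[3]) - 0.5 - shape[3] / 2) / half
  r2_outer <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  o <- config$offset_vector
  r2_inner <- outer(outer((cx - o[1])^2, (cy - o[2])^2, "+"),
                    (cz - o[3])^2, "+")
  g <- array(0L, shape)
  g[r2_outer <= 1] <- 1L
  g[r2_inner <= config$inner_radius^2] <- 2L
  labeled_volume(g, voxel_size,
                 c("0" = "exterior", "1" = "sphere", "2" = "ball"))
}

#' Phantom specification
#'
#' Parameterizes the generation of a random labelled phantom emulating the
#' two case-study sample populations: `clay` (homogeneous base of
#' unpredictable smooth shape with 0-2 convex pebble stones) and `avocado`
#' (concentric peel/flesh/pit layers with air pockets of a target volume
#' fraction). `ball` delegates to [make_ball_phantom()] with a random
#' configuration.
#'
#' @param kind one of `"ball"`, `"clay"`, `"avocado"`.
#' @param shape grid dimensions (scalar or length 3).
#' @param voxel_size voxel edge in mm.
#' @param n_foreign_objects number of pebble stones (clay only), 0-2.
#' @param air_fraction target air volume fraction of the whole fruit
#'   (avocado only), in `[0, 0.05]`.
#' @param seed RNG seed; identical spec + seed gives bit-identical volumes.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind = c("clay", "avocado", "ball"), shape = 64,
                         voxel_size = 1, n_foreign_objects = 1,
                         air_fraction = 0.02, seed = 1) {
  kind <- match.arg(kind)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (!n_foreign_objects %in% 0:2)
    stop_f("`n_foreign_objects` must be 0, 1 or 2")
  if (air_fraction < 0 || air_fraction > 0.05)
    stop_f("`air_fraction` must lie in [0, 0.05]")
  structure(list(kind = kind, shape = as.integer(shape),
                 voxel_size = voxel_size,
                 n_foreign_objects = as.integer(n_foreign_objects),
                 air_fraction = air_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom from a specification
#'
#' Dispatches on `spec$kind` to the clay, avocado or ball generator.
#'
#' @param spec a [phantom_spec()].
#' @return A [labeled_volume()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  switch(spec$kind,
         clay = make_clay_phantom(spec),
         avocado = make_avocado_phantom(spec),
         ball = with_seed(spec$seed, {
           r <- runif(1, 0.1, 0.3)
           u <- rnorm(3); u <- u / sqrt(sum(u^2))
           d <- runif(1, 0, 1 - r)
           make_ball_phantom(ball_phantom_config(r, u * d), spec$shape,
                             spec$voxel_size)
         }))
}

# smooth star-shaped random blob: direction-dependent radius built from a
# small number of random low-frequency angular harmonics. Returns a logical
# mask. centre/radius in voxel units.
random_blob_mask <- function(shape, centre, mean_radius, roughness = 0.15,
                             n_harmonics = 3) {
  idx <- function(n, c) seq_len(n) - 0.5 - c
  x <- idx(shape[1], centre[1])
  y <- idx(shape[2], centre[2])
  z <- idx(shape[3], centre[3])
  X <- array(rep(x, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(y, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(z, each = shape[1] * shape[2]), shape)
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r == 0] <- 1e-9
  theta <- acos(pmin(pmax(Z / r, -1), 1))
  phi <- atan2(Y, X)
  # radius modulation: sum of random cos/sin terms in theta and phi
  mod <- array(0, shape)
  for (m in seq_len(n_harmonics)) {
    a <- rnorm(4, sd = roughness / n_harmonics)
    mod <- mod + a[1] * cos(m * theta) + a[2] * sin(m * theta) +
      a[3] * cos(m * phi) * sin(theta) + a[4] * sin(m * phi) * sin(theta)
  }
  r <= mean_radius * (1 + mod)
}

# axis-aligned coordinate arrays centred on `centre` (voxel units)
coord_arrays <- function(shape, centre) {
  x <- seq_len(shape[1]) - 0.5 - centre[1]
  y <- seq_len(shape[2]) - 0.5 - centre[2]
  z <- seq_len(shape[3]) - 0.5 - centre[3]
  list(
    X = array(rep(x, times = shape[2] * shape[3]), shape),
    Y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
    Z = array(rep(z, each = shape[1] * shape[2]), shape)
  )
}

# mask of a rotated ellipsoid with semi-axes `ax` (voxel units)
ellipsoid_mask <- function(shape, centre, ax, rot = diag(3)) {
  co <- coord_arrays(shape, centre)
  # rotate coordinates into the ellipsoid frame
  P <- rbind(as.vector(co$X), as.vector(co$Y), as.vector(co$Z))
  Q <- t(rot) %*% P
  v <- (Q[1, ] / ax[1])^2 + (Q[2, ] / ax[2])^2 + (Q[3, ] / ax[3])^2
  array(v <= 1, shape)
}

random_rotation <- function() {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Generate a clay phantom with pebble stones
#'
#' Emulates the modelling-clay case study: the base object is a random smooth
#' blob (a star-shaped region whose radius is modulated by random low-order
#' angular harmonics, so the shape is unpredictable and varies with the
#' seed), and each foreign object is a random convex ellipsoid placed fully
#' inside the clay, pairwise separated so that 26-connected component
#' labelling counts them.
#'
#' @param spec a [phantom_spec()] with `kind = "clay"`.
#' @return A [labeled_volume()] with materials exterior/clay/stone.
#' @export
make_clay_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "clay")
  shape <- spec$shape
  with_seed(spec$seed, {
    centre <- shape / 2 + runif(3, -0.03, 0.03) * shape
    base_r <- 0.32 * min(shape)
    clay <- random_blob_mask(shape, centre, base_r, roughness = 0.18)
    g <- array(0L, shape)
    g[clay] <- 1L
    # place stones: random ellipsoids, fully inside the clay, pairwise
    # separated by at least one voxel so components stay countable
    placed <- 0L
    tries <- 0L
    stone_all <- array(FALSE, shape)
    while (placed < spec$n_foreign_objects) {
      tries <- tries + 1L
      if (tries > 400L)
        stop_f("could not place %d stones inside the clay base",
               spec$n_foreign_objects)
      # after many rejections, draw smaller stones so placement succeeds
      # for concave seed shapes too
      relax <- 0.9^(tries %/% 50)
      ax <- runif(3, 0.065, 0.095) * min(shape) * relax
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      d <- runif(1, 0, 0.55) * base_r
      sc <- centre + u * d
      stone <- ellipsoid_mask(shape, sc, ax, random_rotation())
      if (!any(stone)) next
      if (any(stone & !clay)) next              # must sit fully in the clay
      if (any(stone & dilate_mask(stone_all)))  # 26-separable from others
        next
      stone_all <- stone_all | stone
      placed <- placed + 1L
    }
    g[stone_all] <- 2L
    labeled_volume(g, spec$voxel_size,
                   c("0" = "exterior", "1" = "clay", "2" = "stone"))
  })
}

#' Generate an avocado phantom with air pockets
#'
#' Emulates the avocado case study: concentric deformed-ellipsoid layers
#' (thin peel, flesh, an offset pit) with the foreign object being a sparse
#' air phase of controllable volume fraction, placed as several random blobs
#' inside the flesh. The achieved fraction of air over all non-exterior
#' voxels is trimmed to within 10% relative of `spec$air_fraction`.
#'
#' @param spec a [phantom_spec()] with `kind = "avocado"`.
#' @return A [labeled_volume()] with materials
#'   exterior/peel/flesh/pit/air.
#' @export
make_avocado_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "avocado")
  shape <- spec$shape
  with_seed(spec$seed, {
    centre <- shape / 2 + runif(3, -0.02, 0.02) * shape
    # outer fruit: ellipsoid, slightly elongated along a random axis
    ax_out <- c(runif(1, 0.40, 0.46), runif(1, 0.33, 0.38),
                runif(1, 0.33, 0.38)) * min(shape)
    rot <- random_rotation()
    fruit <- ellipsoid_mask(shape, centre, ax_out, rot)
    peel_t <- max(1.5, 0.02 * min(shape))
    inner <- ellipsoid_mask(shape, centre, ax_out - peel_t, rot)
    pit_c <- centre + runif(3, -0.04, 0.04) * min(shape)
    pit <- ellipsoid_mask(shape, pit_c, runif(3, 0.13, 0.17) * min(shape),
                          random_rotation())
    pit <- pit & inner
    g <- array(0L, shape)
    g[fruit] <- 1L   # peel
    g[inner] <- 2L   # flesh
    g[pit] <- 3L     # pit
    n_obj <- sum(g != 0L)
    target <- spec$air_fraction * n_obj
    if (spec$air_fraction > 0) {
      flesh_ok <- g == 2L
      if (target > 0.8 * sum(flesh_ok))
        stop_f("air fraction %.3f unreachable for this shape",
               spec$air_fraction)
      air <- array(FALSE, shape)
      tries <- 0L
      while (sum(air) < target) {
        tries <- tries + 1L
        if (tries > 500L) stop_f("failed to reach target air fraction")
        # air pockets cluster near the pit/flesh interface region
        w <- which(flesh_ok & !air)
        if (!length(w)) stop_f("no flesh left for air placement")
        c_idx <- w[sample.int(length(w), 1)]
        kk <- (c_idx - 1) %/% (shape[1] * shape[2])
        jj <- ((c_idx - 1) %/% shape[1]) %% shape[2]
        ii <- (c_idx - 1) %% shape[1]
        ac <- c(ii, jj, kk) + 0.5
        ax_a <- runif(3, 0.02, 0.055) * min(shape)
        pocket <- ellipsoid_mask(shape, ac, ax_a, random_rotation()) & flesh_ok
        air <- air | pocket
      }
      # trim surplus voxels (farthest-from-centroid first within the last
      # pocket's ordering) to land inside the +/-10% band
      n_air <- sum(air)
      if (n_air > 1.05 * target) {
        w <- which(air)
        drop_n <- round(n_air - target)
        drop <- sample(w, drop_n)
        air[drop] <- FALSE
      }
      g[air] <- 4L
    }
    labeled_volume(g, spec$voxel_size,
                   c("0" = "exterior", "1" = "peel", "2" = "flesh",
                     "3" = "pit", "4" = "air"))
  })
}

# binary dilation by one voxel, 26-neighbourhood (shift-or)
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[sx, sy, sz]
  }
  out
}

# binary erosion by one voxel, 6-neighbourhood
erode_mask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xf <- xs + dx; yf <- ys + dy; zf <- zs + dz
    ok_x <- xf >= 1 & xf <= d[1]; ok_y <- yf >= 1 & yf <= d[2]
    ok_z <- zf >= 1 & zf <= d[3]
    out[xs[ok_x], ys[ok_y], zs[ok_z]] <- m[xf[ok_x], yf[ok_y], zf[ok_z]]
    out
  }
  mask & shift(mask, 1, 0, 0) & shift(mask, -1, 0, 0) &
    shift(mask, 0, 1, 0) & shift(mask, 0, -1, 0) &
    shift(mask, 0, 0, 1) & shift(mask, 0, 0, -1)
}
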