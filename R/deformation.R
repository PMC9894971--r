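# Deformation models applied to labelled volumes: affine transforms of whole
# objects or foreign objects, and the cluster-based region-removal algorithm.
# Label grids stay categorical throughout: resampling is inverse-mapped
# nearest-neighbour, never interpolated.

#' 3-D affine transform
#'
#' A linear part (composition of scale, shear and rotation) plus a
#' translation, acting about a centre point: `x -> linear %*% (x - centre) +
#' centre + translation` (all in mm).
#'
#' @param linear 3x3 matrix with non-zero determinant.
#' @param translation length-3 translation in mm.
#' @param centre length-3 point (mm) about which the linear part acts; when
#'   `NULL` the applying function substitutes the target's centroid.
#' @return An `affine3d` object.
#' @export
affine3d <- function(linear = diag(3), translation = c(0, 0, 0),
                     centre = NULL) {
  linear <- as.matrix(linear)
  if (!all(dim(linear) == c(3, 3))) stop_f("`linear` must be 3x3")
  if (abs(det(linear)) < 1e-12) stop_f("`linear` must be invertible")
  if (length(translation) != 3L) stop_f("`translation` must have length 3")
  structure(list(linear = linear, translation = as.numeric(translation),
                 centre = if (!is.null(centre)) as.numeric(centre)),
            class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> det =", round(det(x$linear), 4), "\n")
  print(round(x$linear, 4))
  cat("translation:", paste(round(x$translation, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Parameter ranges for random affine draws
#'
#' Bounds from which [sample_affine()] draws each transform component.
#' Scaling coefficients live in a neighbourhood of 1 and shear coefficients
#' around 0, so a deformed volume differs from — but still resembles — the
#' original; the defaults are the package's own choices, exposed as
#' configuration.
#'
#' @param scale length-2 low/high for the per-axis scale factors (unitless);
#'   set to `c(1, 1)` to disable. Must exclude 0.
#' @param shear length-2 low/high for the off-diagonal shear coefficients
#'   (unitless); `c(0, 0)` disables.
#' @param rotation maximum rotation angle in degrees (0 disables); the axis
#'   is drawn uniformly on the sphere.
#' @param translation maximum translation magnitude in mm (0 disables); the
#'   direction is uniform on the sphere.
#' @return An `affine_ranges` object.
#' @export
affine_ranges <- function(scale = c(0.9, 1.1), shear = c(-0.1, 0.1),
                          rotation = 0, translation = 0) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop_f("`%s` must be c(low, high)", nm)
  }
  chk(scale, "scale"); chk(shear, "shear")
  if (scale[1] <= 0) stop_f("scale range must exclude 0")
  if (rotation < 0 || translation < 0)
    stop_f("rotation/translation maxima must be >= 0")
  structure(list(scale = scale, shear = shear, rotation = rotation,
                 translation = translation), class = "affine_ranges")
}

rotation_matrix <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Draw a random affine transform
#'
#' Each enabled component is drawn uniformly from its range; the linear part
#' is composed in the fixed order scale, then shear, then rotation
#' (`R %*% Sh %*% S`), followed by the translation.
#'
#' @param ranges an [affine_ranges()].
#' @param centre optional centre of the linear action (mm); defaults to the
#'   target centroid at application time.
#' @return An [affine3d()].
#' @export
sample_affine <- function(ranges, centre = NULL) {
  stopifnot(inherits(ranges, "affine_ranges"))
  S <- diag(runif(3, ranges$scale[1], ranges$scale[2]))
  Sh <- diag(3)
  off <- which(row(Sh) != col(Sh))
  Sh[off] <- runif(6, ranges$shear[1], ranges$shear[2])
  R <- if (ranges$rotation > 0) {
    ax <- rnorm(3)
    rotation_matrix(ax, runif(1, -ranges$rotation, ranges$rotation) * pi / 180)
  } else diag(3)
  tr <- if (ranges$translation > 0) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    u * runif(1, 0, ranges$translation)
  } else c(0, 0, 0)
  affine3d(R %*% Sh %*% S, tr, centre)
}

# voxel-centre coordinates (mm) of all TRUE voxels of a mask
mask_coords_mm <- function(mask, voxel_size) {
  w <- which(mask)
  d <- dim(mask)
  i <- (w - 1) %% d[1]
  j <- ((w - 1) %/% d[1]) %% d[2]
  k <- (w - 1) %/% (d[1] * d[2])
  cbind(i + 0.5, j + 0.5, k + 0.5) * voxel_size
}

centroid_mm <- function(mask, voxel_size) {
  colMeans(mask_coords_mm(mask, voxel_size))
}

# indices (1-based linear) of grid voxels whose centre, pulled back through
# the inverse transform, lands in the source mask. `roi` restricts the
# output voxels examined (linear indices).
pullback_hits <- function(mask, voxel_size, Tf, centre, roi = NULL) {
  d <- dim(mask)
  roi <- roi %||% seq_len(prod(d))
  i <- (roi - 1) %% d[1]
  j <- ((roi - 1) %/% d[1]) %% d[2]
  k <- (roi - 1) %/% (d[1] * d[2])
  P <- rbind(i + 0.5, j + 0.5, k + 0.5) * voxel_size
  Minv <- solve(Tf$linear)
  # invert x' = M (x - c) + c + t  =>  x = Minv (x' - c - t) + c
  Q <- Minv %*% (P - centre - Tf$translation) + centre
  src <- floor(Q / voxel_size) + 1
  ok <- src[1, ] >= 1 & src[1, ] <= d[1] &
    src[2, ] >= 1 & src[2, ] <= d[2] &
    src[3, ] >= 1 & src[3, ] <= d[3]
  lin <- src[1, ok] + d[1] * (src[2, ok] - 1) + d[1] * d[2] * (src[3, ok] - 1)
  roi[ok][mask[lin]]
}

# conservative bounding region (linear indices) of the forward image of mask
forward_roi <- function(mask, voxel_size, Tf, centre) {
  d <- dim(mask)
  P <- t(mask_coords_mm(mask, voxel_size))
  rng <- apply(P, 1, range)
  corners <- as.matrix(expand.grid(rng[, 1], rng[, 2], rng[, 3]))
  Q <- Tf$linear %*% (t(corners) - centre) + centre + Tf$translation
  lo <- pmax(floor(apply(Q, 1, min) / voxel_size) - 1, 0)
  hi <- pmin(ceiling(apply(Q, 1, max) / voxel_size) + 1, d - 1)
  if (any(lo > hi)) return(integer(0))
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  g <- expand.grid(i = ii, j = jj, k = kk)
  as.integer(g$i + d[1] * g$j + d[1] * d[2] * g$k + 1)
}

# most common non-exterior label (used as the default base material)
base_label_of <- function(vol) {
  tab <- table(vol$grid[vol$grid != 0L])
  as.integer(names(tab)[which.max(tab)])
}

#' Apply an affine transform to a labelled volume
#'
#' Resamples the target voxel set under the transform with inverse-mapped
#' nearest-neighbour interpolation (labels are never interpolated). In
#' foreign-object mode (`target_label` a single material) the vacated voxels
#' become base material, destination voxels previously holding base material
#' are overwritten by the moved object, and moved voxels falling outside the
#' base object are discarded; moving the entire object outside the base is an
#' error. In whole-object mode (`target_label = "all"`) every non-exterior
#' label is resampled and vacated voxels become exterior.
#'
#' @param vol a [labeled_volume()].
#' @param target_label material name/code, or `"all"` for whole-object mode.
#' @param transform an [affine3d()]; a `NULL` centre defaults to the target's
#'   centroid.
#' @param base_label base material (FO mode); defaults to the most common
#'   non-exterior label.
#' @return A deformed [labeled_volume()].
#' @export
apply_affine_to_labels <- function(vol, target_label, transform,
                                   base_label = NULL) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(transform, "affine3d"))
  d <- dim(vol$grid)
  vs <- vol$voxel_size
  whole <- identical(target_label, "all")
  if (whole) {
    mask <- vol$grid != 0L
    if (!any(mask)) stop_f("volume has no object to transform")
    centre <- transform$centre %||% centroid_mm(mask, vs)
    g <- array(0L, d)
    # pull back every voxel; label = source voxel's label
    roi <- seq_len(prod(d))
    i <- (roi - 1) %% d[1]; j <- ((roi - 1) %/% d[1]) %% d[2]
    k <- (roi - 1) %/% (d[1] * d[2])
    P <- rbind(i + 0.5, j + 0.5, k + 0.5) * vs
    Minv <- solve(transform$linear)
    Q <- Minv %*% (P - centre - transform$translation) + centre
    src <- floor(Q / vs) + 1
    ok <- src[1, ] >= 1 & src[1, ] <= d[1] &
      src[2, ] >= 1 & src[2, ] <= d[2] &
      src[3, ] >= 1 & src[3, ] <= d[3]
    lin <- src[1, ok] + d[1] * (src[2, ok] - 1) + d[1] * d[2] * (src[3, ok] - 1)
    g[roi[ok]] <- vol$grid[lin]
    if (!any(g != 0L)) stop_f("transform moved the object out of the grid")
    return(labeled_volume(g, vs, vol$label_names))
  }
  code <- label_code(vol, target_label)
  if (is.null(base_label)) base_label <- base_label_of(vol)
  base_code <- label_code(vol, base_label)
  mask <- vol$grid == code
  if (!any(mask)) stop_f("target label has no voxels")
  centre <- transform$centre %||% centroid_mm(mask, vs)
  g <- vol$grid
  g[mask] <- base_code                       # vacate: FO interior -> base
  roi <- forward_roi(mask, vs, transform, centre)
  hits <- pullback_hits(mask, vs, transform, centre, roi)
  hits <- hits[g[hits] == base_code]         # only land inside base material
  if (!length(hits))
    stop_f("transform moved the foreign object entirely outside the base")
  g[hits] <- code
  labeled_volume(g, vs, vol$label_names)
}

#' Region-removal specification
#'
#' Parameters of the cluster-based region-removal deformation: the object's
#' voxels are partitioned by a nearest-seed (Voronoi) rule over `n_clusters`
#' random seed voxels, and clusters are removed either greedily until the
#' retained fraction first drops to at most `retain_fraction`, or as exactly
#' `n_remove` random clusters.
#'
#' @param n_clusters number of cluster seeds K (>= 1).
#' @param retain_fraction target fraction of the object's voxels to keep, in
#'   `[0, 1]` (exclusive with `n_remove`).
#' @param n_remove number of clusters to drop (exclusive with
#'   `retain_fraction`).
#' @return A `region_removal_spec` object.
#' @export
region_removal_spec <- function(n_clusters, retain_fraction = NULL,
                                n_remove = NULL) {
  if (n_clusters < 1) stop_f("`n_clusters` must be >= 1")
  if (is.null(retain_fraction) == is.null(n_remove))
    stop_f("give exactly one of `retain_fraction` or `n_remove`")
  if (!is.null(retain_fraction) &&
      (retain_fraction < 0 || retain_fraction > 1))
    stop_f("`retain_fraction` must lie in [0, 1]")
  if (!is.null(n_remove) && (n_remove < 0 || n_remove > n_clusters))
    stop_f("`n_remove` must lie in [0, n_clusters]")
  structure(list(n_clusters = as.integer(n_clusters),
                 retain_fraction = retain_fraction,
                 n_remove = if (!is.null(n_remove)) as.integer(n_remove)),
            class = "region_removal_spec")
}

# nearest-seed (Voronoi) assignment of target voxels, distances in mm,
# ties broken by lowest seed index
nearest_seed_partition <- function(coords, seeds_idx) {
  S <- coords[seeds_idx, , drop = FALSE]
  n <- nrow(coords)
  best_d <- rep(Inf, n)
  assign <- integer(n)
  for (s in seq_len(nrow(S))) {
    dd <- (coords[, 1] - S[s, 1])^2 + (coords[, 2] - S[s, 2])^2 +
      (coords[, 3] - S[s, 3])^2
    upd <- dd < best_d        # strict: earlier seed wins ties
    assign[upd] <- s
    best_d[upd] <- dd[upd]
  }
  assign
}

#' Cluster-based region removal
#'
#' Splits the target material's voxels into regions by drawing `n_clusters`
#' seed voxels uniformly without replacement and assigning every other target
#' voxel to its Euclidean-nearest seed (distances in mm; ties go to the
#' lowest seed index). A number of clusters is then removed — greedily in
#' random order until the retained fraction first drops to at most
#' `retain_fraction`, or exactly `n_remove` random clusters — and the removed
#' voxels are relabelled to `replacement_label`. Shape changes considerably
#' while the object's position is preserved.
#'
#' @param vol a [labeled_volume()].
#' @param target_label material to carve (name or code).
#' @param spec a [region_removal_spec()].
#' @param replacement_label material the removed voxels become (e.g. flesh
#'   for air, clay for stone).
#' @return A [labeled_volume()].
#' @export
region_removal <- function(vol, target_label, spec, replacement_label) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(spec, "region_removal_spec"))
  code <- label_code(vol, target_label)
  rep_code <- label_code(vol, replacement_label)
  w <- which(vol$grid == code)
  n <- length(w)
  if (n == 0L) stop_f("target label has no voxels")
  if (spec$n_clusters > n)
    stop_f("n_clusters (%d) exceeds target voxel count (%d)",
           spec$n_clusters, n)
  if (!is.null(spec$n_remove) && spec$n_remove == 0L) return(vol)
  d <- dim(vol$grid)
  i <- (w - 1) %% d[1]; j <- ((w - 1) %/% d[1]) %% d[2]
  k <- (w - 1) %/% (d[1] * d[2])
  coords <- cbind(i + 0.5, j + 0.5, k + 0.5) * vol$voxel_size
  seeds <- sample.int(n, spec$n_clusters)
  assign <- nearest_seed_partition(coords, seeds)
  sizes <- tabulate(assign, nbins = spec$n_clusters)
  order_removed <- sample.int(spec$n_clusters)
  drop <- logical(spec$n_clusters)
  if (!is.null(spec$n_remove)) {
    drop[order_removed[seq_len(spec$n_remove)]] <- TRUE
  } else {
    kept <- n
    for (cl in order_removed) {
      if (kept / n <= spec$retain_fraction) break
      drop[cl] <- TRUE
      kept <- kept - sizes[cl]
    }
  }
  g <- vol$grid
  g[w[drop[assign]]] <- rep_code
  labeled_volume(g, vol$voxel_size, vol$label_names)
}

#' Remove a foreign object by relabelling it
#'
#' Replaces the target material — or a single 26-connected component of it —
#' with the replacement material (e.g. stone with modelling clay), leaving
#' the total non-exterior voxel count unchanged.
#'
#' @param vol a [labeled_volume()].
#' @param target_label material to remove.
#' @param replacement_label material written in its place.
#' @param component optional component index (1-based, scan order); `NULL`
#'   removes all components.
#' @return A [labeled_volume()].
#' @export
remove_object <- function(vol, target_label, replacement_label,
                          component = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  code <- label_code(vol, target_label)
  rep_code <- label_code(vol, replacement_label)
  if (!any(vol$grid == code)) {
    warn_f("target label '%s' absent; volume unchanged", target_label)
    return(vol)
  }
  g <- vol$grid
  if (is.null(component)) {
    g[g == code] <- rep_code
  } else {
    cm <- component_map(vol, code)
    k <- attr(cm, "n_components")
    if (component < 1 || component > k)
      stop_f("component index %d out of range (1..%d)", component, k)
    g[cm == component] <- rep_code
  }
  labeled_volume(g, vol$voxel_size, vol$label_names)
}

#' Duplicate a foreign object under an affine transform
#'
#' Adds a transformed copy of the (single-component) target object, leaving
#' the original untouched. The copy must land fully inside the base material
#' and stay 26-disjoint from the original; invalid draws are rejected and,
#' when `ranges` is given, resampled up to `max_retries` times.
#'
#' @param vol a [labeled_volume()].
#' @param target_label the foreign-object material (must form exactly one
#'   26-connected component).
#' @param transform an [affine3d()], or `NULL` to draw from `ranges`.
#' @param ranges an [affine_ranges()] used to (re)draw transforms on
#'   rejection.
#' @param base_label base material; defaults to the most common non-exterior
#'   label.
#' @param max_retries bound on reject-and-resample rounds.
#' @return A [labeled_volume()] in which `target_label` has two components.
#' @export
duplicate_object <- function(vol, target_label, transform = NULL,
                             ranges = NULL, base_label = NULL,
                             max_retries = 100) {
  stopifnot(inherits(vol, "labeled_volume"))
  code <- label_code(vol, target_label)
  if (is.null(base_label)) base_label <- base_label_of(vol)
  base_code <- label_code(vol, base_label)
  mask <- vol$grid == code
  if (!any(mask)) stop_f("target label has no voxels")
  cm <- component_map(vol, code)
  if (attr(cm, "n_components") != 1L)
    stop_f("duplicate_object requires exactly one component, found %d",
           attr(cm, "n_components"))
  if (is.null(transform) && is.null(ranges))
    stop_f("give `transform` or `ranges`")
  vs <- vol$voxel_size
  centre0 <- centroid_mm(mask, vs)
  forbidden <- dilate_mask(mask)   # copy must stay 26-disjoint from original
  tries <- if (is.null(ranges)) 1L else as.integer(max_retries)
  for (t in seq_len(tries)) {
    Tf <- if (is.null(transform)) sample_affine(ranges) else transform
    centre <- Tf$centre %||% centre0
    roi <- forward_roi(mask, vs, Tf, centre)
    hits <- pullback_hits(mask, vs, Tf, centre, roi)
    if (!length(hits)) next
    ok_inside <- all(vol$grid[hits] %in% c(base_code, code))
    ok_disjoint <- !any(forbidden[hits])
    if (ok_inside && ok_disjoint) {
      g <- vol$grid
      g[hits] <- code
      return(labeled_volume(g, vs, vol$label_names))
    }
    if (!is.null(transform)) break
  }
  stop_f("no valid duplicate placement found after %d attempt(s)", tries)
}

#' Serialize / deserialize an affine transform as JSON
#'
#' @param transform an [affine3d()].
#' @param path file path.
#' @return `write_affine` returns `path` invisibly; `read_affine` the
#'   [affine3d()].
#' @export
write_affine <- function(transform, path) {
  stopifnot(inherits(transform, "affine3d"))
  jsonlite::write_json(
    list(linear = transform$linear, translation = transform$translation,
         centre = transform$centre),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lin <- if (is.matrix(x$linear)) x$linear
         else matrix(x$linear, 3, 3, byrow = TRUE)
  affine3d(lin, x$translation, if (length(x$centre)) x$centre)
}
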