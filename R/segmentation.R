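# Segmentation of a reconstructed attenuation volume into a labelled volume
# plus a material table: multi-level Otsu thresholding (the lowest class is
# the exterior air), per-class morphological opening, a speckle filter, and
# an optional per-slice convex-hull closure that defines the base-object
# support.

# multi-level Otsu: k thresholds maximizing between-class variance on a
# 256-bin histogram (exhaustive over threshold combinations; k <= 3 keeps
# this cheap)
multi_otsu <- function(x, k, n_bins = if (k <= 2) 256 else 64) {
  rng <- range(x)
  if (diff(rng) <= 0) stop_f("degenerate histogram: volume is constant")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  w <- h / sum(h)
  mu <- w * mids
  cw <- cumsum(w); cmu <- cumsum(mu)
  tot <- cmu[n_bins]
  # between-class variance of a partition given cut bins (after bin b)
  seg_stat <- function(lo, hi) {
    ww <- cw[hi] - if (lo > 1) cw[lo - 1] else 0
    mm <- cmu[hi] - if (lo > 1) cmu[lo - 1] else 0
    if (ww <= 0) return(0)
    mm^2 / ww
  }
  cuts_best <- NULL; best <- -Inf
  combs <- utils::combn(n_bins - 1, k)
  for (ci in seq_len(ncol(combs))) {
    cuts <- combs[, ci]
    lo <- c(1, cuts + 1); hi <- c(cuts, n_bins)
    v <- sum(vapply(seq_len(k + 1),
                    function(s) seg_stat(lo[s], hi[s]), numeric(1)))
    if (v > best) { best <- v; cuts_best <- cuts }
  }
  br[cuts_best + 1]
}

# binary opening (erosion then dilation), 6-neighbourhood ball of radius r
open_mask <- function(mask, r = 1) {
  for (i in seq_len(r)) mask <- erode_mask(mask)
  for (i in seq_len(r)) mask <- dilate6_mask(mask)
  mask
}

dilate6_mask <- function(mask) {
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
  mask | shift(mask, 1, 0, 0) | shift(mask, -1, 0, 0) |
    shift(mask, 0, 1, 0) | shift(mask, 0, -1, 0) |
    shift(mask, 0, 0, 1) | shift(mask, 0, 0, -1)
}

# fill the convex hull of the TRUE pixels of each z-slice (axial closure)
convex_close_slices <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    w <- which(sl, arr.ind = TRUE)
    if (nrow(w) < 3) next
    hull <- w[chull(w), , drop = FALSE]
    # scanline fill: for each row, the convex polygon cuts one interval
    for (i in seq(min(hull[, 1]), max(hull[, 1]))) {
      xs <- polygon_row_interval(hull, i)
      if (!is.null(xs)) out[i, xs[1]:xs[2], k] <- TRUE
    }
  }
  out
}

# intersection of the polygon (vertex matrix, columns row/col) with row i
polygon_row_interval <- function(hull, i) {
  n <- nrow(hull)
  cols <- c()
  for (e in seq_len(n)) {
    a <- hull[e, ]; b <- hull[if (e == n) 1 else e + 1, ]
    if ((a[1] - i) * (b[1] - i) <= 0) {
      if (a[1] == b[1]) cols <- c(cols, a[2], b[2])
      else cols <- c(cols, a[2] + (i - a[1]) * (b[2] - a[2]) / (b[1] - a[1]))
    }
  }
  if (!length(cols)) return(NULL)
  c(max(1, floor(min(cols))), ceiling(max(cols)))
}

# drop 26-connected components smaller than min_size voxels from a mask
filter_small_components <- function(mask, min_size) {
  g <- array(as.integer(mask), dim(mask))
  comp <- cc_label_3d(g, dim(g), 1L)
  k <- attr(comp, "n_components")
  if (k == 0L) return(mask)
  sizes <- tabulate(comp[comp > 0], k)
  keep <- which(sizes >= min_size)
  array(comp %in% keep, dim(mask))
}

#' Segment an attenuation volume into materials
#'
#' Multi-level Otsu thresholding of the non-zero voxels into `n_materials`
#' classes plus exterior, followed by (a) a morphological opening of each
#' class with a configurable radius, (b) a minimum-component-size speckle
#' filter, and (c) an optional per-slice convex-hull closure of the union of
#' non-exterior classes that defines the base-object support; voxels inside
#' the support that fell to exterior (or were opened away) are relabelled as
#' the base material, so every voxel ends with exactly one label. Classes
#' are labelled 1..n in order of increasing attenuation.
#'
#' @param recon an [attenuation_volume()].
#' @param n_materials number of non-exterior materials (>= 1).
#' @param opening_radius morphological opening radius in voxels (0
#'   disables).
#' @param convex_hull close the object support by per-slice convex hulls
#'   (sensible for convex bases like clay; leave off where concavities are
#'   real, as for avocado).
#' @param min_component minimum component size in voxels (speckle filter).
#' @param material_names optional names for labels 1..n (by increasing
#'   attenuation); defaults to `material1..n`.
#' @return A [labeled_volume()].
#' @export
segment_materials <- function(recon, n_materials, opening_radius = 1,
                              convex_hull = FALSE, min_component = 27,
                              material_names = NULL) {
  stopifnot(inherits(recon, "attenuation_volume"))
  if (n_materials < 1) stop_f("`n_materials` must be >= 1")
  x <- recon$grid
  if (length(unique(as.vector(x))) <= n_materials)
    stop_f("n_materials (%d) exceeds the number of distinct values",
           n_materials)
  # n_materials Otsu cuts over all voxels partition into n_materials + 1
  # classes; the lowest (near-zero attenuation) class is the exterior air
  cuts <- multi_otsu(as.vector(x), n_materials)
  g <- array(0L, dim(x))
  for (tau in cuts) g[x > tau] <- g[x > tau] + 1L
  # per-class morphological cleanup
  if (opening_radius > 0 || min_component > 0) {
    for (cls in seq_len(n_materials)) {
      m <- g == cls
      m2 <- m
      if (opening_radius > 0) m2 <- open_mask(m2, opening_radius)
      if (min_component > 0) m2 <- filter_small_components(m2, min_component)
      g[m & !m2] <- 0L   # dropped voxels fall to exterior for now
    }
  }
  support <- g != 0L
  if (convex_hull) support <- convex_close_slices(support)
  # base material = most voxels after cleanup; exterior inside the support
  # becomes base
  tab <- tabulate(g[g > 0], n_materials)
  base_cls <- which.max(tab)
  g[support & g == 0L] <- base_cls
  nm <- material_names %||% paste0("material", seq_len(n_materials))
  if (length(nm) != n_materials) stop_f("need %d material names", n_materials)
  labeled_volume(g, recon$voxel_size,
                 setNames(c("exterior", nm), as.character(0:n_materials)))
}

#' Estimate material attenuations from a segmentation
#'
#' Computes the mean of the reconstructed attenuation over each label's
#' voxels (the segmentation acting as a mask); the exterior is forced to 0.
#' Labels with no voxels are omitted with a warning.
#'
#' @param recon an [attenuation_volume()].
#' @param seg a congruent [labeled_volume()].
#' @return A [material_table()].
#' @export
estimate_attenuations <- function(recon, seg) {
  stopifnot(inherits(recon, "attenuation_volume"),
            inherits(seg, "labeled_volume"))
  if (!all(dim(recon$grid) == dim(seg$grid)))
    stop_f("reconstruction and segmentation shapes differ")
  out <- c(exterior = 0)
  for (code in names(seg$label_names)) {
    nm <- seg$label_names[[code]]
    if (nm == "exterior") next
    sel <- seg$grid == as.integer(code)
    if (!any(sel)) {
      warn_f("label '%s' has no voxels; omitted from material table", nm)
      next
    }
    out[nm] <- mean(recon$grid[sel])
  }
  material_table(out)
}
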