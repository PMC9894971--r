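#' Labelled material volume
#'
#' The canonical object representation of the pipeline: a 3-D integer grid in
#' which every voxel holds exactly one material label. Label 0 is reserved for
#' the exterior (background air around the object). Grids are stored as R
#' arrays with `dim = c(nx, ny, nz)`; the voxel with index `(i, j, k)`
#' (1-based) covers the half-open physical box
#' `[(i-1) vs, i vs) x ... ` with its centre at `(i - 0.5) * vs` mm, where
#' `vs` is the isotropic voxel edge length.
#'
#' @param grid 3-D integer array of material labels.
#' @param voxel_size voxel edge length in mm (isotropic, > 0).
#' @param label_names named character vector mapping label codes (names, as
#'   characters) to material names, e.g. `c("0" = "exterior", "1" = "clay")`.
#'   Must cover every label present in `grid`.
#' @return An object of class `labeled_volume` with fields `grid`,
#'   `voxel_size`, `label_names`.
#' @examples
#' g <- array(0L, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- 1L
#' v <- labeled_volume(g, 0.5, c("0" = "exterior", "1" = "clay"))
#' material_fraction(v, "clay")
#' @export
labeled_volume <- function(grid, voxel_size, label_names) {
  if (!is.array(grid) || length(dim(grid)) != 3L || length(grid) == 0L)
    stop_f("`grid` must be a non-empty 3-D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_f("`voxel_size` must be a single positive number (mm)")
  storage.mode(grid) <- "integer"
  if (is.null(names(label_names)))
    stop_f("`label_names` must be named by label code")
  present <- sort(unique(as.vector(grid)))
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing))
    stop_f("labels present in grid but absent from label_names: %s",
           paste(missing, collapse = ", "))
  structure(
    list(grid = grid, voxel_size = as.numeric(voxel_size),
         label_names = label_names),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %g mm\n",
              d[1], d[2], d[3], x$voxel_size))
  tab <- table(factor(as.vector(x$grid), levels = names(x$label_names)))
  for (code in names(x$label_names)) {
    cat(sprintf("  %s (%s): %d voxels\n", x$label_names[[code]], code,
                tab[[code]]))
  }
  invisible(x)
}

#' @export
dim.labeled_volume <- function(x) dim(x$grid)

# resolve a material name or label code to the integer code
label_code <- function(vol, label) {
  if (is.numeric(label)) {
    code <- as.integer(label)
    if (!as.character(code) %in% names(vol$label_names))
      stop_f("label code %d not defined for this volume", code)
    return(code)
  }
  hit <- names(vol$label_names)[vol$label_names == label]
  if (length(hit) != 1L)
    stop_f("material '%s' not defined for this volume", label)
  as.integer(hit)
}

#' Attenuation volume
#'
#' A 3-D scalar field of X-ray attenuation coefficients (mm^-1), the form a CT
#' reconstruction takes. Same voxel convention as [labeled_volume()].
#'
#' @param grid 3-D numeric array of attenuation coefficients (mm^-1), finite.
#' @param voxel_size voxel edge length in mm (> 0).
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(grid, voxel_size) {
  if (!is.array(grid) || length(dim(grid)) != 3L || length(grid) == 0L)
    stop_f("`grid` must be a non-empty 3-D array")
  if (!all(is.finite(grid)))
    stop_f("attenuation values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_f("`voxel_size` must be a single positive number (mm)")
  storage.mode(grid) <- "double"
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<attenuation_volume> %d x %d x %d voxels @ %g mm, mu in [%g, %g] mm^-1\n",
              d[1], d[2], d[3], x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.attenuation_volume <- function(x) dim(x$grid)

#' Material attenuation table
#'
#' Maps material names to mean linear attenuation coefficients (mm^-1); the
#' bridge from a segmented label volume back to physics. The exterior must map
#' to 0.
#'
#' @param ... named attenuation values in mm^-1, or a single named numeric
#'   vector. Must include `exterior = 0`.
#' @return A named numeric vector of class `material_table`.
#' @examples
#' material_table(exterior = 0, clay = 0.06, stone = 0.25)
#' @export
material_table <- function(...) {
  args <- list(...)
  mu <- if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    unlist(args[[1]]) else unlist(args)
  if (is.null(names(mu)) || any(names(mu) == ""))
    stop_f("all materials must be named")
  if (any(mu < 0)) stop_f("attenuation coefficients must be >= 0")
  if (!"exterior" %in% names(mu)) mu <- c(exterior = 0, mu)
  if (mu[["exterior"]] != 0) stop_f("exterior must have attenuation 0")
  structure(mu, class = "material_table")
}

#' Default phantom material attenuations
#'
#' Plausible attenuation coefficients (mm^-1) for the built-in phantom
#' materials, ordered so that foreign objects contrast with their base:
#' pebble stone is ~4x denser than modelling clay, avocado tissues lie close
#' together and air attenuates nothing. These are configuration defaults, not
#' physical constants.
#'
#' @return A [material_table()].
#' @export
default_materials <- function() {
  material_table(
    exterior = 0, clay = 0.06, stone = 0.25,
    flesh = 0.05, peel = 0.07, pit = 0.08, air = 0,
    sphere = 0.1, ball = 1.0
  )
}

#' Convert a labelled volume to attenuation coefficients
#'
#' Replaces every voxel's material label with the material's mean attenuation
#' coefficient, so a segmented volume can be forward-projected. The exterior
#' maps to 0.
#'
#' @param vol a [labeled_volume()].
#' @param materials a [material_table()] with an entry for every material
#'   present in `vol`.
#' @return An [attenuation_volume()] of the same shape and voxel size.
#' @export
labels_to_attenuation <- function(vol, materials) {
  stopifnot(inherits(vol, "labeled_volume"))
  present <- sort(unique(as.vector(vol$grid)))
  mats <- vol$label_names[as.character(present)]
  missing <- setdiff(mats, names(materials))
  if (length(missing))
    stop_f("no attenuation entry for material(s): %s",
           paste(missing, collapse = ", "))
  mu_by_code <- setNames(as.numeric(materials[mats]), as.character(present))
  g <- array(mu_by_code[as.character(vol$grid)], dim = dim(vol$grid))
  attenuation_volume(g, vol$voxel_size)
}

#' Fraction of the object occupied by one material
#'
#' The number of voxels carrying `label` divided by the number of non-exterior
#' voxels. This is the quantity class assignment uses for the avocado case
#' (fraction of air with respect to the whole fruit).
#'
#' @param vol a [labeled_volume()].
#' @param label material name or integer label code.
#' @return A fraction in `[0, 1]`.
#' @export
material_fraction <- function(vol, label) {
  stopifnot(inherits(vol, "labeled_volume"))
  code <- label_code(vol, label)
  n_obj <- sum(vol$grid != 0L)
  if (n_obj == 0L) stop_f("volume has no non-exterior voxels")
  sum(vol$grid == code) / n_obj
}

#' Count 26-connected components of one material
#'
#' @param vol a [labeled_volume()].
#' @param label material name or integer label code.
#' @return Integer component count (0 if the label is absent).
#' @export
count_components <- function(vol, label) {
  stopifnot(inherits(vol, "labeled_volume"))
  code <- label_code(vol, label)
  comp <- cc_label_3d(vol$grid, dim(vol$grid), code)
  attr(comp, "n_components")
}

# component map as an integer array (0 = off target, 1..K)
component_map <- function(vol, label) {
  code <- label_code(vol, label)
  comp <- cc_label_3d(vol$grid, dim(vol$grid), code)
  k <- attr(comp, "n_components")
  m <- array(as.integer(comp), dim = dim(vol$grid))
  attr(m, "n_components") <- k
  m
}

#' Write a volume as a TIFF stack with JSON metadata
#'
#' Writes one TIFF page per z-slice (16-bit for labels, 32-bit float for
#' attenuation) plus a `meta.json` sidecar holding `voxel_size` and, for
#' labelled volumes, `label_names`.
#'
#' @param vol a [labeled_volume()] or [attenuation_volume()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_volume <- function(vol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$grid)
  is_label <- inherits(vol, "labeled_volume")
  # one page per z-slice; each page is a (rows = y, cols = x) matrix
  pages <- lapply(seq_len(d[3]), function(k) t(vol$grid[, , k]))
  scale <- 1
  if (is_label) {
    pages <- lapply(pages, function(p) p / 65535)
    # labels stored as value/65535 so 16-bit round-trips exactly
    tiff::writeTIFF(pages, file.path(dir, "volume.tif"), bits.per.sample = 16)
  } else {
    scale <- max(max(vol$grid), 1)   # TIFF samples live in [0, 1]
    tiff::writeTIFF(lapply(pages, function(p) {
      storage.mode(p) <- "double"; p / scale
    }), file.path(dir, "volume.tif"), bits.per.sample = 32, reduce = FALSE)
  }
  meta <- list(
    kind = if (is_label) "labeled" else "attenuation",
    voxel_size = vol$voxel_size,
    shape = as.integer(d),
    scale = scale
  )
  if (is_label) meta$label_names <- as.list(vol$label_names)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a volume written by [write_volume()]
#'
#' @param dir directory containing `volume.tif` and `meta.json`.
#' @return A [labeled_volume()] or [attenuation_volume()] according to the
#'   metadata.
#' @export
read_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  pages <- tiff::readTIFF(file.path(dir, "volume.tif"), all = TRUE)
  d <- vapply(meta$shape, as.integer, integer(1))
  g <- array(0, dim = d)
  for (k in seq_len(d[3])) g[, , k] <- t(pages[[k]])
  if (identical(meta$kind, "labeled")) {
    g <- round(g * 65535)
    ln <- unlist(meta$label_names)
    labeled_volume(g, meta$voxel_size, ln)
  } else {
    attenuation_volume(g * (meta$scale %||% 1), meta$voxel_size)
  }
}
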