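# Mixed Poisson-Gaussian detector noise and its mean-variance calibration.
# Pixel model: I_noisy ~ (1/lambda) * Poisson(lambda * I0) + Normal(0, sigma^2),
# so E[I_noisy] = I0 and Var[I_noisy] = I0 / lambda + sigma^2.

#' Mixed Poisson-Gaussian noise model
#'
#' `lambda` is the photon gain (unitless; larger means less shot noise per
#' detected count) and `sigma` the Gaussian read-out standard deviation in
#' detector counts. The default values are the clay-case detector
#' calibration used throughout the package.
#'
#' @param lambda photon gain, > 0.
#' @param sigma Gaussian standard deviation in counts, >= 0.
#' @return A `noise_model` object.
#' @export
noise_model <- function(lambda = 1.17, sigma = 20) {
  if (!is.numeric(lambda) || lambda <= 0) stop_f("`lambda` must be > 0")
  if (!is.numeric(sigma) || sigma < 0) stop_f("`sigma` must be >= 0")
  structure(list(lambda = lambda, sigma = sigma), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> lambda = %g, sigma = %g counts\n",
              x$lambda, x$sigma))
  invisible(x)
}

#' Apply mixed Poisson-Gaussian noise to a photon-count image
#'
#' Draws, independently per pixel,
#' `(1/lambda) * Poisson(lambda * I0) + Normal(0, sigma^2)` and clips the
#' result at zero (photon counts are physical, and the clip protects the
#' subsequent log transform; the unbounded model is otherwise unchanged).
#' The Poisson mean `lambda * I0` is used as-is, without rounding.
#'
#' @param proj a [radiograph()] in the `photon_count` domain with `I0 >= 0`.
#' @param model a [noise_model()].
#' @param seed optional RNG seed for reproducibility.
#' @return A [radiograph()] in the `photon_count` domain.
#' @export
add_mixed_noise <- function(proj, model, seed = NULL) {
  stopifnot(inherits(proj, "radiograph"), inherits(model, "noise_model"))
  if (proj$domain != "photon_count")
    stop_f("expected a photon_count radiograph, got %s", proj$domain)
  if (min(proj$image) < 0) stop_f("negative photon counts in input")
  img <- with_seed(seed, {
    n <- length(proj$image)
    pois <- rpois(n, model$lambda * as.vector(proj$image)) / model$lambda
    gaus <- if (model$sigma > 0) rnorm(n, 0, model$sigma) else 0
    matrix(pmax(pois + gaus, 0), nrow(proj$image), ncol(proj$image))
  })
  radiograph(img, "photon_count", proj$pixel_size, proj$angle,
             proj$I_incident)
}

#' Simulate flat-field calibration frames
#'
#' Generates repeated detector frames with no object at one or more exposure
#' levels, by applying the noise model to constant images. These are the
#' inputs the detector calibration consumes.
#'
#' @param levels mean count levels I0 (one or more).
#' @param n_frames frames per level.
#' @param shape detector shape `c(rows, cols)`.
#' @param model a [noise_model()].
#' @param seed RNG seed.
#' @return A list with one element per level: list of [radiograph()]s.
#' @export
simulate_flat_frames <- function(levels, n_frames, shape = c(64, 64),
                                 model = noise_model(), seed = 1) {
  with_seed(seed, {
    lapply(levels, function(I0) {
      flat <- radiograph(matrix(I0, shape[1], shape[2]), "photon_count",
                         I_incident = I0)
      lapply(seq_len(n_frames), function(f) add_mixed_noise(flat, model))
    })
  })
}

#' Calibrate the noise model from flat-field frames
#'
#' Mean-variance detector calibration: for each exposure level the pooled
#' sample mean `m` and variance `v` over all pixels and frames are computed,
#' and the line `v = m / lambda + sigma^2` is fitted by least squares over
#' the levels. Returns `lambda = 1/slope` and `sigma = sqrt(max(intercept,
#' 0))`.
#'
#' @param flat_frames list of levels, each a list of [radiograph()]s in the
#'   `photon_count` domain (as produced by [simulate_flat_frames()] or read
#'   from disk). At least 2 distinct mean levels are required.
#' @return A [noise_model()] with the fitted parameters, carrying the
#'   per-level means/variances as attribute `"calibration"`.
#' @export
calibrate_noise <- function(flat_frames) {
  if (length(flat_frames) < 2L)
    stop_f("need >= 2 exposure levels to identify the slope")
  stats <- lapply(flat_frames, function(frames) {
    x <- unlist(lapply(frames, function(f) {
      if (!inherits(f, "radiograph") || f$domain != "photon_count")
        stop_f("flat frames must be photon_count radiographs")
      as.vector(f$image)
    }))
    c(mean = mean(x), var = var(x))
  })
  m <- vapply(stats, `[[`, numeric(1), "mean")
  v <- vapply(stats, `[[`, numeric(1), "var")
  if (max(m) - min(m) < 1e-9)
    stop_f("exposure levels are not distinct; slope unidentifiable")
  fit <- lm(v ~ m)
  slope <- coef(fit)[["m"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (slope <= 0)
    stop_f("fitted mean-variance slope is not positive; non-physical data")
  out <- noise_model(lambda = 1 / slope, sigma = sqrt(max(intercept, 0)))
  attr(out, "calibration") <- data.frame(mean = m, var = v)
  out
}

#' Serialize / deserialize a noise model as JSON
#'
#' @param model a [noise_model()].
#' @param path file path.
#' @return `write_noise_model` returns `path` invisibly; `read_noise_model`
#'   the [noise_model()].
#' @export
write_noise_model <- function(model, path) {
  jsonlite::write_json(list(lambda = model$lambda, sigma = model$sigma),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  x <- jsonlite::read_json(path)
  noise_model(x$lambda, x$sigma)
}
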