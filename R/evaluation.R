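# Accuracy scoring, a desk-scale baseline classifier standing in for a deep
# network, and the repeated-seed evaluation protocol. The classifier works
# on engineered radiograph features: a foreign object adds a compact bump to
# the attenuance image on top of the smooth base-object background, so
# background-subtracted residual statistics (areas, blob counts, mass at
# several thresholds) carry the class signal.

#' Classification accuracy
#'
#' Fraction of exact matches between true and predicted classes,
#' `A = (1/N) * sum(1(pred == true))`.
#'
#' @param true_classes,predicted_classes equal-length vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(true_classes, predicted_classes) {
  if (length(true_classes) != length(predicted_classes))
    stop_f("class vectors differ in length (%d vs %d)",
           length(true_classes), length(predicted_classes))
  if (!length(true_classes)) stop_f("empty class vectors")
  mean(true_classes == predicted_classes)
}

# separable box blur (two passes approximate a Gaussian), reflected edges
blur2d <- function(img, radius = 4, passes = 2) {
  box1d <- function(m, r) {
    # running mean of width 2r+1 along columns via padded cumsum
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(min(r, n))), , drop = FALSE], m,
                 m[rev(seq_len(n))[seq_len(min(r, n))], , drop = FALSE])
    cs <- apply(pad, 2, cumsum)
    w <- 2 * r + 1
    (cs[(w):(w + n - 1), , drop = FALSE] -
        rbind(0, cs[seq_len(n - 1), , drop = FALSE])) / w
  }
  for (i in seq_len(passes)) {
    img <- box1d(img, radius)
    img <- t(box1d(t(img), radius))
  }
  img
}

n_components_2d <- function(mask) {
  if (!any(mask)) return(0L)
  g <- array(as.integer(mask), c(dim(mask), 1L))
  comp <- cc_label_3d(g, dim(g), 1L)
  attr(comp, "n_components")
}

# sizes of the two largest connected blobs of a 2-D mask (0 when absent)
top2_components_2d <- function(mask) {
  if (!any(mask)) return(c(0, 0))
  g <- array(as.integer(mask), c(dim(mask), 1L))
  comp <- cc_label_3d(g, dim(g), 1L)
  sizes <- sort(tabulate(comp[comp > 0]), decreasing = TRUE)
  c(sizes[1], if (length(sizes) > 1) sizes[2] else 0)
}

#' Extract classifier features from a radiograph
#'
#' Computes, from an attenuance image: global statistics (total attenuance,
#' maximum, object-support area) and, after subtracting a smoothed
#' background, the area, connected-blob count and integrated mass of the
#' positive residual at several thresholds. The residual statistics respond
#' to compact dense inclusions (stones) and to missing-mass cavities (air
#' pockets) irrespective of where the object sits in the field of view.
#'
#' @param proj a [radiograph()] in the `attenuance` domain (or a bare
#'   matrix).
#' @param thresholds residual thresholds, in attenuance units.
#' @param blur_radius background smoothing radius in pixels.
#' @return A named numeric feature vector.
#' @export
radiograph_features <- function(proj, thresholds = c(0.2, 0.4, 0.7, 1, 1.4),
                                blur_radius = 5) {
  img <- if (inherits(proj, "radiograph")) proj$image else proj
  bg <- blur2d(img, blur_radius)
  res_pos <- pmax(img - bg, 0)   # dense inclusions
  res_neg <- pmax(bg - img, 0)   # cavities
  sup <- img > 0.05 * max(img, 1e-9)
  out <- c(
    total = sum(img), max = max(img),
    support = sum(sup), mean_sup = sum(img) / max(sum(sup), 1),
    rp_max = max(res_pos), rp_sum = sum(res_pos),
    rn_max = max(res_neg), rn_sum = sum(res_neg)
  )
  for (tau in thresholds) {
    mp <- res_pos > tau
    mn <- res_neg > tau
    t2 <- top2_components_2d(mp)
    out <- c(out, setNames(
      c(sum(mp), n_components_2d(mp), sum(res_pos[mp]), t2,
        sum(mn), n_components_2d(mn)),
      paste0(c("area_p", "ncc_p", "mass_p", "blob1_p", "blob2_p",
               "area_n", "ncc_n"), "_", tau)
    ))
  }
  out
}

# feature matrix for every image of a manifest (reads TIFFs from disk)
manifest_features <- function(manifest, thresholds, blur_radius) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop_f("manifest carries no dataset directory")
  feats <- lapply(manifest$path, function(p) {
    radiograph_features(read_radiograph(file.path(dir, p)),
                        thresholds = thresholds, blur_radius = blur_radius)
  })
  do.call(rbind, feats)
}

#' Train the baseline classifier
#'
#' A gradient-boosted tree classifier over [radiograph_features()], standing
#' in for a deep network at desk scale: seconds to train, deterministic
#' given a seed (single-thread), and early-stopped on the validation score
#' so training length adapts to the data. The claims this package supports
#' concern data generation, not classifier architecture.
#'
#' @param manifest a `dataset_manifest` with `train` and `val` splits (see
#'   [split_train_val()]).
#' @param seed RNG/training seed.
#' @param thresholds,blur_radius passed to [radiograph_features()].
#' @param nrounds,early_stopping_rounds,max_depth,eta boosting
#'   hyper-parameters.
#' @param shuffle_labels permute the training+validation labels before
#'   fitting (permutation-null control; test accuracy should then sit at
#'   chance).
#' @param features optional precomputed feature matrix (one row per manifest
#'   row), to avoid re-reading images across repeated trainings.
#' @return A `foxray_classifier` object with a [predict][stats::predict]
#'   method.
#' @export
train_baseline_classifier <- function(manifest, seed = 1,
                                      thresholds = c(0.2, 0.4, 0.7, 1, 1.4),
                                      blur_radius = 5, nrounds = 150,
                                      early_stopping_rounds = 15,
                                      max_depth = 4, eta = 0.2,
                                      shuffle_labels = FALSE,
                                      features = NULL) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (!any(manifest$split == "val"))
    stop_f("manifest has no validation split; call split_train_val() first")
  X <- features %||% manifest_features(manifest, thresholds, blur_radius)
  y <- manifest$class
  classes <- sort(unique(y[manifest$split %in% c("train", "val")]))
  if (length(classes) < 2L) stop_f("training data contain a single class")
  if (shuffle_labels) {
    idx <- manifest$split %in% c("train", "val")
    y[idx] <- with_seed(seed, sample(y[idx]))
  }
  ytr <- match(y, classes) - 1L
  tr <- manifest$split == "train"
  va <- manifest$split == "val"
  dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = ytr[tr])
  dval <- xgboost::xgb.DMatrix(X[va, , drop = FALSE], label = ytr[va])
  fit <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = max_depth, eta = eta, nthread = 1,
                  eval_metric = "mlogloss", seed = seed,
                  subsample = 0.8, colsample_bytree = 0.8),
    data = dtrain, nrounds = nrounds,
    evals = list(val = dval),
    early_stopping_rounds = early_stopping_rounds, verbose = 0
  ))
  structure(list(fit = fit, classes = classes, thresholds = thresholds,
                 blur_radius = blur_radius, seed = seed),
            class = "foxray_classifier")
}

#' @export
print.foxray_classifier <- function(x, ...) {
  cat(sprintf("<foxray_classifier> %d classes, %d boosting rounds (seed %d)\n",
              length(x$classes), x$fit$best_iteration %||% x$fit$niter,
              x$seed))
  invisible(x)
}

#' Predict classes for a manifest of radiographs
#'
#' @param object a `foxray_classifier`.
#' @param manifest a `dataset_manifest` (features are extracted with the
#'   classifier's settings), or a precomputed feature matrix.
#' @param ... unused.
#' @return Integer class predictions, one per manifest row.
#' @export
predict.foxray_classifier <- function(object, manifest, ...) {
  X <- if (is.matrix(manifest)) manifest
       else manifest_features(manifest, object$thresholds,
                              object$blur_radius)
  pr <- predict(object$fit, xgboost::xgb.DMatrix(X))
  pm <- if (is.matrix(pr)) pr
        else matrix(pr, ncol = length(object$classes), byrow = TRUE)
  object$classes[max.col(pm, ties.method = "first")]
}

#' Repeated-seed evaluation
#'
#' Trains the baseline classifier `n_seeds` times on the same training data
#' with different random seeds, scores each on the test manifest, and
#' reports the mean accuracy `A`, its spread `dA` (sample standard
#' deviation over seeds), per-seed accuracies and pooled per-class confusion
#' counts.
#'
#' @param train_manifest manifest with `train`/`val` splits.
#' @param test_manifest manifest of test images (classes recomputed at build
#'   time are the ground truth).
#' @param n_seeds number of training repetitions (>= 2; the protocol default
#'   is 4).
#' @param seed base seed; repetition `s` trains with `seed + s`.
#' @param ... passed to [train_baseline_classifier()].
#' @return An `evaluation_report`: list with `A`, `dA`, `per_seed`,
#'   `confusion`.
#' @export
repeated_evaluation <- function(train_manifest, test_manifest, n_seeds = 4,
                                seed = 1, ...) {
  if (n_seeds < 2) stop_f("`n_seeds` must be >= 2")
  truth <- test_manifest$class
  dots <- list(...)
  thr <- dots$thresholds %||% formals(train_baseline_classifier)$thresholds
  thr <- eval(thr)
  br <- dots$blur_radius %||% 5
  Xtr <- manifest_features(train_manifest, thr, br)
  Xte <- manifest_features(test_manifest, thr, br)
  per_seed <- numeric(n_seeds)
  conf <- NULL
  for (s in seq_len(n_seeds)) {
    clf <- train_baseline_classifier(train_manifest, seed = seed + s,
                                     features = Xtr, ...)
    pred <- predict(clf, Xte)
    per_seed[s] <- accuracy(truth, pred)
    tab <- table(factor(truth, levels = clf$classes),
                 factor(pred, levels = clf$classes))
    conf <- if (is.null(conf)) tab else conf + tab
  }
  structure(list(A = mean(per_seed), dA = stats::sd(per_seed),
                 per_seed = per_seed, confusion = conf,
                 n_test = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> A = %.3f +/- %.3f over %d seeds (N_test = %d)\n",
              x$A, x$dA, length(x$per_seed), x$n_test))
  cat("per-seed:", paste(sprintf("%.3f", x$per_seed), collapse = ", "), "\n")
  invisible(x)
}
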