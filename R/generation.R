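# Dataset-generation strategies. Ground truth is defined by re-computable
# class rules: clay class = number of 26-connected stone components (0-2),
# avocado class = 1 iff the air fraction exceeds a threshold (default 1%,
# strict inequality).

#' Class rule for the clay case
#'
#' The class of a clay sample is its number of foreign objects: the count of
#' 26-connected components of the stone material, capped at 2.
#'
#' @param vol a [labeled_volume()] with a `stone` material defined.
#' @return Integer class in `{0, 1, 2}`.
#' @export
assign_class_clay <- function(vol) {
  min(count_components(vol, "stone"), 2L)
}

#' Class rule for the avocado case
#'
#' Class 1 iff the fraction of air volume with respect to the whole fruit
#' strictly exceeds `threshold` (default 1%), else class 0. The comparison is
#' strict, so a fraction exactly at the threshold is class 0.
#'
#' @param vol a [labeled_volume()] with an `air` material defined.
#' @param threshold air-fraction class boundary (default 0.01).
#' @return Integer class in `{0, 1}`.
#' @export
assign_class_avocado <- function(vol, threshold = 0.01) {
  as.integer(material_fraction(vol, "air") > threshold)
}

#' Generation recipe
#'
#' Parameters of a data-generation run: which strategy and case, how many
#' artificial volumes per real scan (`G`, from-one strategy), the affine
#' ranges for whole-object and foreign-object transforms, and the
#' distribution of the retained air fraction for artificial class-0
#' avocados (must lie strictly inside `(0, threshold)`: a class-0 fruit must
#' still contain some air).
#'
#' @param strategy `"basic_modification"` or `"from_one"`.
#' @param case `"clay"` or `"avocado"`.
#' @param G artificial volumes generated per real scan (from-one).
#' @param whole_ranges [affine_ranges()] for the whole-object transform.
#' @param fo_ranges [affine_ranges()] for the foreign-object transform
#'   (clay duplication: resize, shear, rotation and translation).
#' @param air_retain length-2 range (fractions of the whole fruit) from
#'   which the class-0 retained air fraction is drawn uniformly; must lie
#'   strictly inside `(0, threshold)`.
#' @param n_clusters cluster count for air region removal.
#' @param threshold avocado class threshold.
#' @param seed RNG seed of the run.
#' @return A `generation_recipe` object.
#' @export
generation_recipe <- function(strategy = c("basic_modification", "from_one"),
                              case = c("clay", "avocado"), G = 1,
                              whole_ranges = affine_ranges(
                                scale = c(0.92, 1.08), shear = c(-0.08, 0.08)),
                              fo_ranges = affine_ranges(
                                scale = c(0.85, 1.15), shear = c(-0.1, 0.1),
                                rotation = 180, translation = 12),
                              air_retain = c(0.001, 0.009),
                              n_clusters = 25, threshold = 0.01, seed = 1) {
  strategy <- match.arg(strategy)
  case <- match.arg(case)
  if (G < 1) stop_f("`G` must be >= 1")
  if (air_retain[1] <= 0 || air_retain[2] >= threshold)
    stop_f("`air_retain` must lie strictly inside (0, threshold)")
  structure(list(strategy = strategy, case = case, G = as.integer(G),
                 whole_ranges = whole_ranges, fo_ranges = fo_ranges,
                 air_retain = as.numeric(air_retain),
                 n_clusters = as.integer(n_clusters), threshold = threshold,
                 seed = as.integer(seed)),
            class = "generation_recipe")
}

#' Sample record
#'
#' One generated volume with its ground-truth class and provenance (source
#' scan id and the operations applied). The stored class must always agree
#' with the class rule recomputed on the volume.
#'
#' @param volume a [labeled_volume()].
#' @param class_label integer ground-truth class.
#' @param source_id identifier of the originating real scan.
#' @param provenance character vector of applied operations.
#' @return A `sample_record` object.
#' @export
sample_record <- function(volume, class_label, source_id,
                          provenance = character()) {
  structure(list(volume = volume, class_label = as.integer(class_label),
                 source_id = source_id, provenance = provenance),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> class %d from %s [%s]\n", x$class_label,
              x$source_id, paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

# carve the air phase down so the retained fraction lands strictly inside
# (0, threshold); resamples clusters on overshoot to zero air
reduce_air_to_class0 <- function(vol, recipe) {
  frac0 <- material_fraction(vol, "air")
  for (try in 1:25) {
    target <- runif(1, recipe$air_retain[1], recipe$air_retain[2])
    out <- region_removal(
      vol, "air",
      region_removal_spec(min(recipe$n_clusters, sum(vol$grid == label_code(vol, "air"))),
                          retain_fraction = target / frac0),
      replacement_label = "flesh"
    )
    f <- material_fraction(out, "air")
    if (f > 0 && f <= recipe$threshold) return(out)
  }
  stop_f("air region removal kept overshooting to zero air")
}

#' Basic-modification strategy, clay case
#'
#' Starts from a segmentation containing two stones (class 2) and derives
#' the other classes by stone removal: one randomly chosen stone is replaced
#' with clay for class 1, both for class 0. Each real scan thus contributes
#' 3 volumes (`N_train = 3 p S_train` images after projection).
#'
#' @param seg2 a class-2 [labeled_volume()].
#' @param source_id identifier of the real scan.
#' @param seed RNG seed (chooses which stone is removed).
#' @return List of 3 [sample_record()]s with classes 2, 1, 0.
#' @export
basic_modification_clay <- function(seg2, source_id = "scan", seed = NULL) {
  if (assign_class_clay(seg2) != 2L)
    stop_f("basic modification (clay) requires a class-2 input")
  with_seed(seed, {
    victim <- sample.int(2, 1)
    v1 <- remove_object(seg2, "stone", "clay", component = victim)
    v0 <- remove_object(seg2, "stone", "clay")
    list(
      sample_record(seg2, 2L, source_id, "original"),
      sample_record(v1, 1L, source_id,
                    sprintf("remove_stone(component=%d)", victim)),
      sample_record(v0, 0L, source_id, "remove_all_stones")
    )
  })
}

#' Basic-modification strategy, avocado case
#'
#' Takes a class-1 avocado and applies region removal to the air phase to
#' drive the air fraction strictly below the class threshold while keeping
#' some air — a class-0 sample without any air would teach the classifier
#' the wrong boundary. Each real scan contributes 2 volumes
#' (`N_train = 2 p S_train`).
#'
#' @param seg1 a class-1 [labeled_volume()].
#' @param recipe a [generation_recipe()] (supplies the retained-air
#'   distribution and cluster count).
#' @param source_id identifier of the real scan.
#' @param seed RNG seed.
#' @return List of 2 [sample_record()]s with classes 1, 0.
#' @export
basic_modification_avocado <- function(seg1, recipe = generation_recipe(
                                         case = "avocado"),
                                       source_id = "scan", seed = NULL) {
  if (assign_class_avocado(seg1, recipe$threshold) != 1L)
    stop_f("basic modification (avocado) requires a class-1 input")
  with_seed(seed, {
    v0 <- reduce_air_to_class0(seg1, recipe)
    list(
      sample_record(seg1, 1L, source_id, "original"),
      sample_record(v0, 0L, source_id, "air_region_removal")
    )
  })
}

#' Generation-from-one strategy
#'
#' Applies deformation models to a single real-world volume to generate `G`
#' artificial volumes. Clay rounds: a whole-object affine (resize + shear)
#' deforms the class-1 input, the pebble stone is duplicated under a
#' foreign-object affine (resize, shear, rotation, translation) giving a
#' class-2 volume, and stones are then removed for the class-1 and class-0
#' variants. Avocado rounds: whole-object affine gives a class-1 variant and
#' air region removal a class-0 variant. Class variants are allocated
#' round-robin so that `G` counts volumes and output classes are balanced to
#' within one.
#'
#' @param seg a class-1 [labeled_volume()] (one stone, or over-threshold
#'   air).
#' @param recipe a [generation_recipe()] with `strategy = "from_one"`.
#' @param source_id identifier of the real scan.
#' @return List of `G` [sample_record()]s.
#' @export
generate_from_one <- function(seg, recipe, source_id = "scan") {
  stopifnot(inherits(recipe, "generation_recipe"))
  n_classes <- if (recipe$case == "clay") 3L else 2L
  if (recipe$case == "clay") {
    if (assign_class_clay(seg) != 1L)
      stop_f("from-one (clay) requires a class-1 input")
  } else {
    if (assign_class_avocado(seg, recipe$threshold) != 1L)
      stop_f("from-one (avocado) requires a class-1 input")
  }
  out <- vector("list", recipe$G)
  with_seed(recipe$seed, {
    i <- 0L
    round_id <- 0L
    while (i < recipe$G) {
      round_id <- round_id + 1L
      if (round_id > 4L * recipe$G)
        stop_f("too many failed generation rounds")
      vols <- tryCatch(
        from_one_round(seg, recipe, round_id),
        error = function(e) {
          warn_f("generation round %d skipped: %s", round_id,
                 conditionMessage(e))
          NULL
        }
      )
      if (is.null(vols)) next
      # each round yields one volume of every class; take them in descending
      # class order until G volumes exist, so classes stay balanced within 1
      for (cls in rev(seq_len(n_classes)) - 1L) {
        if (i >= recipe$G) break
        i <- i + 1L
        out[[i]] <- sample_record(
          vols[[as.character(cls)]], cls, source_id,
          c(sprintf("round=%d", round_id), vols$provenance,
            sprintf("class=%d", cls))
        )
      }
    }
  })
  out
}

# one deformation round; returns named volumes per class plus provenance
from_one_round <- function(seg, recipe, round_id) {
  W <- sample_affine(recipe$whole_ranges)
  base <- apply_affine_to_labels(seg, "all", W)
  if (recipe$case == "clay") {
    v2 <- duplicate_object(base, "stone", ranges = recipe$fo_ranges,
                           max_retries = 50)
    victim <- sample.int(2, 1)
    v1 <- remove_object(v2, "stone", "clay", component = victim)
    v0 <- remove_object(v2, "stone", "clay")
    list("2" = v2, "1" = v1, "0" = v0,
         provenance = "whole_affine+duplicate_stone")
  } else {
    v1 <- base
    v0 <- reduce_air_to_class0(base, recipe)
    list("1" = v1, "0" = v0,
         provenance = "whole_affine+air_region_removal")
  }
}
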