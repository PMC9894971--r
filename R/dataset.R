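# Assembly of generated volumes into on-disk labelled image datasets, with
# the bookkeeping that relates image counts to source-scan counts:
# N = p * #volumes per strategy, and leakage-free train/validation splits at
# the volume level.

#' Expected dataset size per strategy
#'
#' The image-count formulas of the generation strategies: basic modification
#' yields `3 p S_train` images for the clay case (three class variants per
#' real scan) and `2 p S_train` for the avocado case; generation-from-one
#' yields `p G S_train` with `S_train = 1` in its intended use. Real-data
#' (identity) datasets have `p S` images.
#'
#' @param strategy `"basic_modification"`, `"from_one"` or `"real"`.
#' @param case `"clay"` or `"avocado"` (only basic modification differs by
#'   case).
#' @param S_train number of source scans.
#' @param p projections per volume.
#' @param G artificial volumes per real scan (from-one only).
#' @return Integer image count.
#' @examples
#' expected_dataset_size("basic_modification", "clay", S_train = 21, p = 72)
#' @export
expected_dataset_size <- function(strategy, case = "clay", S_train, p,
                                  G = NULL) {
  switch(strategy,
         basic_modification = {
           per_scan <- if (case == "clay") 3L else 2L
           as.integer(per_scan * p * S_train)
         },
         from_one = {
           if (is.null(G)) stop_f("from_one needs `G`")
           as.integer(p * G * S_train)
         },
         real = as.integer(p * S_train),
         stop_f("unknown strategy '%s'", strategy))
}

#' Build an on-disk radiograph dataset from sample records
#'
#' For every generated volume: convert labels to attenuation, project `p`
#' views at the geometry's angles, apply Beer's law at `I_incident`, add
#' detector noise (unless `noise` is `NULL`), convert back to attenuance
#' images, and write them as 32-bit float TIFFs. The manifest row of every
#' image carries the class label recomputed from the volume, never copied
#' blindly from the record.
#'
#' @param samples list of [sample_record()]s.
#' @param geom a [proj_geometry()] (its `angles` define p).
#' @param materials a [material_table()].
#' @param out_dir output directory for images and manifest.
#' @param noise a [noise_model()] or `NULL` for noiseless images.
#' @param I_incident incident photon count.
#' @param case `"clay"` or `"avocado"` (selects the class rule recomputed
#'   for the manifest).
#' @param seed RNG seed for the noise draws.
#' @return A `dataset_manifest`: a data.frame with columns `path`, `class`,
#'   `sample_id`, `angle_deg`, `split` and attributes `p`, `n_volumes`,
#'   `I_incident`.
#' @export
build_dataset <- function(samples, geom, materials = default_materials(),
                          out_dir, noise = noise_model(), I_incident = 1e4,
                          case = c("clay", "avocado"), seed = 1) {
  case <- match.arg(case)
  if (!length(samples)) stop_f("no samples to project")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- length(geom$angles)
  rows <- vector("list", length(samples) * p)
  r <- 0L
  with_seed(seed, {
    for (s in seq_along(samples)) {
      rec <- samples[[s]]
      stopifnot(inherits(rec, "sample_record"))
      cls <- if (case == "clay") assign_class_clay(rec$volume)
             else assign_class_avocado(rec$volume)
      if (cls != rec$class_label)
        stop_f("sample %d: stored class %d disagrees with recomputed %d",
               s, rec$class_label, cls)
      att <- labels_to_attenuation(rec$volume, materials)
      for (a in seq_along(geom$angles)) {
        li <- forward_project(att, geom, geom$angles[a])
        cnt <- attenuance_to_counts(li, I_incident)
        if (!is.null(noise)) cnt <- add_mixed_noise(cnt, noise)
        img <- counts_to_attenuance(cnt)
        fn <- sprintf("s%04d_a%03d.tif", s, a)
        path <- file.path(out_dir, fn)
        ok <- tryCatch(write_radiograph(img, path), error = function(e)
          stop_f("failed writing %s: %s", path, conditionMessage(e)))
        r <- r + 1L
        rows[[r]] <- data.frame(
          path = fn, class = cls, sample_id = sprintf("s%04d", s),
          angle_deg = geom$angles[a], split = "train",
          stringsAsFactors = FALSE
        )
      }
    }
  })
  manifest <- do.call(rbind, rows)
  attr(manifest, "p") <- p
  attr(manifest, "n_volumes") <- length(samples)
  attr(manifest, "I_incident") <- I_incident
  attr(manifest, "dir") <- out_dir
  class(manifest) <- c("dataset_manifest", "data.frame")
  write_manifest(manifest, out_dir)
  manifest
}

#' Split a manifest into training and validation sets
#'
#' Splits at the source-volume level — all projections of one volume stay in
#' the same subset, so near-duplicate views never leak across the split —
#' with the number of validation volumes chosen as `round(val_fraction *
#' n_volumes)` (at least one when `val_fraction > 0`). By construction the
#' validation image fraction matches the target up to volume granularity.
#'
#' @param manifest a `dataset_manifest`.
#' @param val_fraction target fraction of images used for validation
#'   (default 0.15).
#' @param seed RNG seed.
#' @return The manifest with its `split` column set to `"train"` /
#'   `"val"`.
#' @export
split_train_val <- function(manifest, val_fraction = 0.15, seed = 1) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  ids <- unique(manifest$sample_id[manifest$split != "test"])
  if (length(ids) < 2L) stop_f("need >= 2 source volumes to split")
  if (val_fraction < 0 || val_fraction >= 1)
    stop_f("`val_fraction` must lie in [0, 1)")
  n_val <- round(val_fraction * length(ids))
  if (val_fraction > 0) n_val <- max(1L, n_val)
  with_seed(seed, {
    val_ids <- if (n_val > 0) sample(ids, n_val) else character()
    manifest$split[manifest$sample_id %in% val_ids] <- "val"
    manifest$split[!(manifest$sample_id %in% val_ids) &
                     manifest$split != "test"] <- "train"
  })
  manifest
}

#' Write / read a dataset manifest
#'
#' The manifest is a CSV (`manifest.csv`: path, class, sample_id, angle_deg,
#' split) plus a JSON header sidecar (`manifest.json`) carrying `p`,
#' `n_volumes` and `I_incident`.
#'
#' @param manifest a `dataset_manifest`.
#' @param dir dataset directory.
#' @return `write_manifest` returns `dir` invisibly; `read_manifest` the
#'   `dataset_manifest`.
#' @export
write_manifest <- function(manifest, dir) {
  write.csv(as.data.frame(manifest), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(p = attr(manifest, "p"), n_volumes = attr(manifest, "n_volumes"),
         I_incident = attr(manifest, "I_incident")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  m <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"))
  attr(m, "p") <- meta$p
  attr(m, "n_volumes") <- meta$n_volumes
  attr(m, "I_incident") <- meta$I_incident
  attr(m, "dir") <- dir
  class(m) <- c("dataset_manifest", "data.frame")
  m
}
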