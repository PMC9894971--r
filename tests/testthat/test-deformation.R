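test_that("identity transform leaves the volume unchanged", {
  v <- fix_stone_in_clay(32, 6)
  out <- apply_affine_to_labels(v, "stone", affine3d())
  expect_identical(out$grid, v$grid)
})

test_that("affine scaling changes foreign-object volume by the determinant", {
  v <- fix_stone_in_clay(64, 10)
  for (s in c(0.85, 1.1, 1.25)) {
    out <- apply_affine_to_labels(v, "stone", affine3d(diag(3) * s))
    ratio <- sum(out$grid == 2L) / sum(v$grid == 2L)
    expect_lt(abs(ratio - s^3) / s^3, 0.05)
    # conservation: vacated voxels become clay, nothing leaves the object
    expect_identical(sum(out$grid != 0L), sum(v$grid != 0L))
  }
})

test_that("integer-voxel translation conserves the voxel set exactly", {
  v <- fix_stone_in_clay(64, 10)
  out <- apply_affine_to_labels(v, "stone", affine3d(diag(3), c(5, 0, 0)))
  expect_identical(sum(out$grid == 2L), sum(v$grid == 2L))
})

test_that("transforms that expel the foreign object are rejected", {
  v <- fix_stone_in_clay(32, 5)
  expect_error(
    apply_affine_to_labels(v, "stone", affine3d(diag(3), c(200, 0, 0))),
    "outside the base")
})

test_that("whole-object mode rescales every material and vacates to exterior", {
  v <- fix_clay(n_stones = 1, seed = 13, shape = 64)
  out <- apply_affine_to_labels(v, "all", affine3d(diag(3) * 0.9))
  ratio <- sum(out$grid != 0L) / sum(v$grid != 0L)
  expect_lt(abs(ratio - 0.9^3) / 0.9^3, 0.05)
  expect_identical(count_components(out, "stone"), 1L)
})

test_that("sampled affines respect their ranges and disabled components", {
  r <- affine_ranges(scale = c(1, 1), shear = c(0, 0))
  t0 <- sample_affine(r)
  expect_equal(t0$linear, diag(3))
  expect_equal(t0$translation, c(0, 0, 0))

  set.seed(5)
  r2 <- affine_ranges(scale = c(0.9, 1.1), shear = c(0, 0))
  draws <- replicate(10000, diag(sample_affine(r2)$linear))
  expect_lt(abs(mean(draws) - 1), 0.01)
  expect_gte(min(draws), 0.9)
  expect_lte(max(draws), 1.1)
})

test_that("affine_ranges validates its bounds", {
  expect_error(affine_ranges(scale = c(1.1, 0.9)), "low, high")
  expect_error(affine_ranges(scale = c(-0.5, 1)), "exclude 0")
  expect_error(affine_ranges(rotation = -3), ">= 0")
})

test_that("region removal conserves voxels and respects n_remove", {
  v <- fix_clay(n_stones = 1, seed = 3, shape = 48)
  set.seed(1)
  out <- region_removal(v, "clay", region_removal_spec(8, n_remove = 3),
                        "stone")
  expect_identical(sum(out$grid != 0L), sum(v$grid != 0L))
  # only clay voxels changed, all became the replacement
  changed <- which(out$grid != v$grid)
  expect_true(all(v$grid[changed] == 1L))
  expect_true(all(out$grid[changed] == 2L))

  # n_remove = 0 leaves the volume untouched
  same <- region_removal(v, "clay", region_removal_spec(8, n_remove = 0),
                         "stone")
  expect_identical(same$grid, v$grid)

  # n_remove = K erases the target label
  gone <- region_removal(v, "stone", region_removal_spec(3, n_remove = 3),
                         "clay")
  expect_false(any(gone$grid == 2L))
})

test_that("region removal with retain_fraction stops at the first crossing", {
  v <- fix_clay(n_stones = 0, seed = 21, shape = 48)
  n0 <- sum(v$grid == 1L)
  set.seed(2)
  out <- region_removal(v, "clay",
                        region_removal_spec(20, retain_fraction = 0.5),
                        "stone")
  kept <- sum(out$grid == 1L)
  expect_lte(kept / n0, 0.5)
  expect_gte(kept / n0, 0.5 - 1.5 / 20)   # overshoot bounded by ~1 cluster
})

test_that("nearest-seed partition matches brute force on small volumes", {
  set.seed(9)
  coords <- matrix(runif(3 * 400, 0, 10), ncol = 3)
  seeds <- sample.int(400, 7)
  got <- foxray:::nearest_seed_partition(coords, seeds)
  S <- coords[seeds, ]
  want <- apply(coords, 1, function(p) {
    dd <- colSums((t(S) - p)^2)
    which.min(dd)   # which.min breaks ties by lowest index, as specified
  })
  expect_identical(got, as.integer(want))
})

test_that("region_removal_spec rejects contradictory requests", {
  expect_error(region_removal_spec(4), "exactly one")
  expect_error(region_removal_spec(4, retain_fraction = 0.5, n_remove = 1),
               "exactly one")
  expect_error(region_removal_spec(4, n_remove = 5), "n_remove")
  expect_error(region_removal_spec(0, n_remove = 0), "n_clusters")
  v <- fix_clay(n_stones = 1, seed = 3, shape = 32)
  expect_error(
    region_removal(v, "stone",
                   region_removal_spec(1e6, n_remove = 1), "clay"),
    "exceeds")
})

test_that("remove_object relabels whole objects or single components", {
  v2 <- fix_clay(n_stones = 2, seed = 17, shape = 64)
  one <- remove_object(v2, "stone", "clay", component = 2)
  expect_identical(count_components(one, "stone"), 1L)
  none <- remove_object(v2, "stone", "clay")
  expect_identical(count_components(none, "stone"), 0L)
  expect_identical(sum(none$grid != 0L), sum(v2$grid != 0L))
  expect_error(remove_object(v2, "stone", "clay", component = 5),
               "out of range")
  # absent target: unchanged with a warning
  expect_warning(same <- remove_object(none, "stone", "clay"), "absent")
  expect_identical(same$grid, none$grid)
})

test_that("duplicate_object adds a disjoint interior copy", {
  v <- fix_clay(n_stones = 1, seed = 11, shape = 64)
  set.seed(4)
  out <- duplicate_object(
    v, "stone",
    ranges = affine_ranges(scale = c(0.9, 1.1), shear = c(-0.05, 0.05),
                           rotation = 180, translation = 12))
  expect_identical(count_components(out, "stone"), 2L)
  expect_identical(sum(out$grid != 0L), sum(v$grid != 0L))
  # the original stone is untouched
  expect_true(all(out$grid[v$grid == 2L] == 2L))
})

test_that("duplicate_object rejects the identity copy", {
  v <- fix_clay(n_stones = 1, seed = 11, shape = 48)
  expect_error(duplicate_object(v, "stone", transform = affine3d()),
               "no valid duplicate")
})

test_that("deformation outputs remain valid labelled volumes", {
  v <- fix_clay(n_stones = 2, seed = 23, shape = 48)
  set.seed(6)
  outs <- list(
    apply_affine_to_labels(v, "all", affine3d(diag(3) * 1.05)),
    region_removal(v, "clay", region_removal_spec(6, n_remove = 2),
                   "stone"),
    remove_object(v, "stone", "clay", component = 1)
  )
  for (o in outs) {
    expect_s3_class(o, "labeled_volume")
    expect_true(all(as.character(unique(as.vector(o$grid))) %in%
                      names(o$label_names)))
  }
})

test_that("affine transforms survive the JSON round trip", {
  tf <- affine3d(matrix(c(1.1, 0.02, 0, 0.01, 0.95, 0, 0, 0, 1), 3, 3),
                 c(1, -2, 0.5), centre = c(10, 10, 10))
  p <- withr::local_tempfile(fileext = ".json")
  write_affine(tf, p)
  tf2 <- read_affine(p)
  expect_equal(tf$linear, tf2$linear)
  expect_equal(tf$translation, tf2$translation)
  expect_equal(tf$centre, tf2$centre)
})
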