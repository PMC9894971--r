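test_that("clay class rule counts connected stones, capped at two", {
  expect_identical(assign_class_clay(fix_clay(0, seed = 2)), 0L)
  expect_identical(assign_class_clay(fix_clay(1, seed = 2)), 1L)
  expect_identical(assign_class_clay(fix_clay(2, seed = 2)), 2L)
})

test_that("avocado class rule uses a strict 1% threshold", {
  v1 <- fix_avocado(air = 0.02, seed = 5, shape = 64)
  expect_identical(assign_class_avocado(v1), 1L)
  expect_identical(assign_class_avocado(fix_avocado(air = 0, seed = 5)), 0L)
  # exactly at the threshold: strict comparison gives class 0
  g <- array(0L, c(10, 10, 10))
  g[1:10, 1:10, 1:10] <- 1L
  g[1:10, 1:1, 1:1] <- 4L    # 10 of 1000 voxels = 1%
  v <- labeled_volume(g, 1, c("0" = "exterior", "1" = "flesh", "4" = "air"))
  expect_equal(material_fraction(v, "air"), 0.01)
  expect_identical(assign_class_avocado(v), 0L)
})

test_that("basic modification (clay) yields verifiable classes 2, 1, 0", {
  seg2 <- fix_clay(2, seed = 19, shape = 64)
  recs <- basic_modification_clay(seg2, "scanA", seed = 4)
  expect_length(recs, 3)
  expect_identical(vapply(recs, function(r) r$class_label, integer(1)),
                   c(2L, 1L, 0L))
  for (r in recs)
    expect_identical(assign_class_clay(r$volume), r$class_label)
  expect_error(basic_modification_clay(fix_clay(1, seed = 3)), "class-2")
})

test_that("basic modification (avocado) keeps some air in the class-0 output", {
  seg1 <- fix_avocado(air = 0.02, seed = 6, shape = 64)
  recipe <- generation_recipe(case = "avocado")
  recs <- basic_modification_avocado(seg1, recipe, "scanB", seed = 8)
  expect_length(recs, 2)
  expect_identical(vapply(recs, function(r) r$class_label, integer(1)),
                   c(1L, 0L))
  f0 <- material_fraction(recs[[2]]$volume, "air")
  expect_gt(f0, 0)
  expect_lt(f0, 0.01)
  for (r in recs)
    expect_identical(assign_class_avocado(r$volume), r$class_label)
  expect_error(basic_modification_avocado(fix_avocado(air = 0.004, seed = 6),
                                          recipe), "class-1")
})

test_that("generation-from-one is balanced, sound, diverse and deterministic", {
  one <- fix_clay(1, seed = 31, shape = 64)
  recipe <- generation_recipe("from_one", "clay", G = 10, seed = 8)
  recs <- generate_from_one(one, recipe, "scanC")
  expect_length(recs, 10)
  classes <- vapply(recs, function(r) r$class_label, integer(1))
  tab <- table(factor(classes, levels = 0:2))
  expect_lte(max(tab) - min(tab), 1)
  for (r in recs)
    expect_identical(assign_class_clay(r$volume), r$class_label)
  # diversity: no two generated volumes identical
  grids <- lapply(recs, function(r) r$volume$grid)
  for (i in 1:9) for (j in (i + 1):10)
    expect_false(identical(grids[[i]], grids[[j]]))
  # determinism of provenance and content under the same seed
  recs2 <- generate_from_one(one, recipe, "scanC")
  expect_identical(lapply(recs, function(r) r$provenance),
                   lapply(recs2, function(r) r$provenance))
  expect_identical(grids, lapply(recs2, function(r) r$volume$grid))
})

test_that("generation-from-one works for the avocado case", {
  one <- fix_avocado(air = 0.02, seed = 41, shape = 64)
  recipe <- generation_recipe("from_one", "avocado", G = 6, seed = 12)
  recs <- generate_from_one(one, recipe, "scanD")
  expect_length(recs, 6)
  classes <- vapply(recs, function(r) r$class_label, integer(1))
  expect_lte(max(table(factor(classes, levels = 0:1))) -
               min(table(factor(classes, levels = 0:1))), 1)
  for (r in recs)
    expect_identical(assign_class_avocado(r$volume), r$class_label)
})

test_that("generation rejects inputs of the wrong class", {
  expect_error(generate_from_one(fix_clay(2, seed = 3, shape = 48),
                                 generation_recipe("from_one", "clay",
                                                   G = 3)),
               "class-1")
  expect_error(generate_from_one(fix_avocado(air = 0.004, seed = 3),
                                 generation_recipe("from_one", "avocado",
                                                   G = 2)),
               "class-1")
})

test_that("generation recipe validates the class-0 air band", {
  expect_error(generation_recipe(air_retain = c(0, 0.005)), "strictly")
  expect_error(generation_recipe(air_retain = c(0.002, 0.01)), "strictly")
  expect_silent(generation_recipe(air_retain = c(0.001, 0.009)))
})
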