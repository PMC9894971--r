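test_that("expected dataset sizes follow the strategy formulas", {
  expect_identical(
    expected_dataset_size("basic_modification", "clay", 21, 72), 4536L)
  expect_identical(
    expected_dataset_size("basic_modification", "avocado", 36, 72), 5184L)
  expect_identical(
    expected_dataset_size("basic_modification", "avocado", 12, 72), 1728L)
  expect_identical(
    expected_dataset_size("from_one", "clay", 1, 72, G = 45), 3240L)
  expect_identical(expected_dataset_size("real", "clay", 30, 72), 2160L)
  expect_error(expected_dataset_size("mystery", "clay", 1, 72), "unknown")
  expect_error(expected_dataset_size("from_one", "clay", 1, 72), "G")
})

test_that("built datasets match the manifest bookkeeping", {
  recs <- basic_modification_clay(fix_clay(2, seed = 19, shape = 48),
                                  "scanA", seed = 1)
  geom <- fix_geom(n_angles = 4, det = 63, ps = 1.2)
  dir <- withr::local_tempdir()
  man <- build_dataset(recs, geom, default_materials(), dir,
                       noise_model(), case = "clay", seed = 2)
  expect_identical(nrow(man), 12L)   # p * #samples = 4 * 3
  expect_identical(attr(man, "p"), 4L)
  # every file exists and loads to the declared detector shape
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$path[i])
    expect_true(file.exists(f))
    img <- read_radiograph(f)
    expect_identical(dim(img$image), c(63L, 63L))
    expect_identical(img$domain, "attenuance")
  }
  # manifest classes were recomputed from the volumes
  expect_identical(sort(unique(man$class)), c(0L, 1L, 2L))
  # CSV + JSON round trip
  man2 <- read_manifest(dir)
  expect_equal(as.data.frame(man2)[c("path", "class", "sample_id")],
               as.data.frame(man)[c("path", "class", "sample_id")])
  expect_identical(attr(man2, "p"), attr(man, "p"))
})

test_that("degenerate noise reproduces the noiseless pipeline", {
  recs <- list(sample_record(fix_clay(1, seed = 5, shape = 48), 1L, "s",
                             "phantom"))
  geom <- fix_geom(n_angles = 2, det = 63, ps = 1.2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- build_dataset(recs, geom, default_materials(), d1, noise = NULL,
                      case = "clay")
  m2 <- build_dataset(recs, geom, default_materials(), d2,
                      noise = noise_model(1e8, 0), case = "clay", seed = 3)
  for (i in seq_len(nrow(m1))) {
    a <- read_radiograph(file.path(d1, m1$path[i]))$image
    b <- read_radiograph(file.path(d2, m2$path[i]))$image
    expect_lt(sqrt(mean((a - b)^2)) / max(sqrt(mean(a^2)), 1e-9), 0.001)
  }
})

test_that("build_dataset refuses records whose stored class is stale", {
  v <- fix_clay(1, seed = 5, shape = 48)
  bad <- sample_record(v, 2L, "s", "mislabelled")
  expect_error(
    build_dataset(list(bad), fix_geom(1, det = 63, ps = 1.2),
                  default_materials(), withr::local_tempdir(),
                  case = "clay"),
    "disagrees")
})

test_that("train/val split is by volume, leak-free and reproducible", {
  one <- fix_clay(1, seed = 31, shape = 48)
  recs <- generate_from_one(one, generation_recipe("from_one", "clay",
                                                   G = 20, seed = 8), "s")
  geom <- fix_geom(n_angles = 2, det = 63, ps = 1.2)
  man <- build_dataset(recs, geom, default_materials(),
                       withr::local_tempdir(), noise = NULL, case = "clay")
  man <- split_train_val(man, 0.15, seed = 5)
  # 20 volumes at 15% -> 3 validation volumes
  val_ids <- unique(man$sample_id[man$split == "val"])
  expect_length(val_ids, 3)
  # no volume appears in both splits
  train_ids <- unique(man$sample_id[man$split == "train"])
  expect_length(intersect(val_ids, train_ids), 0)
  # image fraction within 5 percentage points of the target
  expect_lt(abs(mean(man$split == "val") - 0.15), 0.05)
  # reproducible
  man_b <- split_train_val(man, 0.15, seed = 5)
  expect_identical(man$split, man_b$split)
  # zero fraction leaves everything in train
  man0 <- split_train_val(man, 0, seed = 5)
  expect_false(any(man0$split == "val"))
})

test_that("split requires at least two source volumes", {
  recs <- list(sample_record(fix_clay(1, seed = 5, shape = 48), 1L, "s",
                             "x"))
  man <- build_dataset(recs, fix_geom(1, det = 63, ps = 1.2),
                       default_materials(), withr::local_tempdir(),
                       noise = NULL, case = "clay")
  expect_error(split_train_val(man, 0.15), ">= 2")
})
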