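test_that("accuracy equals the exact-match fraction", {
  expect_equal(accuracy(c(0, 1, 2, 0), c(0, 1, 0, 0)), 0.75)
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_error(accuracy(1:3, 1:4), "length")
  expect_error(accuracy(integer(), integer()), "empty")
})

test_that("accuracy agrees with a brute-force indicator loop", {
  set.seed(13)
  for (trial in 1:100) {
    n <- sample(1000, 1)
    y <- sample(0:2, n, replace = TRUE)
    yh <- sample(0:2, n, replace = TRUE)
    brute <- 0
    for (i in seq_len(n)) brute <- brute + as.integer(yh[i] == y[i])
    expect_equal(accuracy(y, yh), brute / n)
  }
})

test_that("a constant classifier scores 1/k on a balanced test set", {
  y <- rep(0:2, each = 40)
  expect_equal(accuracy(y, rep(1, 120)), 1 / 3)
})

test_that("radiograph features separate stone-bearing projections", {
  geom <- fix_geom(n_angles = 1, det = 80, ps = 1.1)
  mats <- default_materials()
  f_of <- function(k, seed) {
    v <- make_phantom(phantom_spec("clay", 64, n_foreign_objects = k,
                                   seed = seed))
    li <- forward_project(labels_to_attenuation(v, mats), geom, 0)
    img <- counts_to_attenuance(
      add_mixed_noise(attenuance_to_counts(li, 1e4), noise_model(),
                      seed = seed))
    radiograph_features(img)
  }
  f0 <- f_of(0, 301)
  f2 <- f_of(2, 302)
  expect_lt(f0[["rp_max"]], f2[["rp_max"]])
  expect_lt(f0[["area_p_0.7"]], f2[["area_p_0.7"]])
})

test_that("the baseline classifier is deterministic and learns the pilot task", {
  one <- fix_clay(1, seed = 101, shape = 64)
  recs <- generate_from_one(one, generation_recipe("from_one", "clay",
                                                   G = 9, seed = 7), "s")
  geom <- proj_geometry("parallel", n_angles = 8, det_rows = 80,
                        det_cols = 80, pixel_size = 1.1)
  man <- build_dataset(recs, geom, default_materials(),
                       withr::local_tempdir(), noise_model(), case = "clay",
                       seed = 3)
  man <- split_train_val(man, 0.15, seed = 2)
  clf_a <- train_baseline_classifier(man, seed = 1)
  clf_b <- train_baseline_classifier(man, seed = 1)

  test_recs <- lapply(1:24, function(i) {
    cls <- (i - 1) %% 3
    sample_record(make_phantom(phantom_spec("clay", 64,
                                            n_foreign_objects = cls,
                                            seed = 7000 + i)),
                  cls, paste0("t", i), "phantom")
  })
  tg <- proj_geometry("parallel", angles = 13, det_rows = 80, det_cols = 80,
                      pixel_size = 1.1)
  man_te <- build_dataset(test_recs, tg, default_materials(),
                          withr::local_tempdir(), noise_model(),
                          case = "clay", seed = 4)
  pa <- predict(clf_a, man_te)
  pb <- predict(clf_b, man_te)
  expect_identical(pa, pb)
  # far above chance even at pilot scale
  expect_gt(accuracy(man_te$class, pa), 0.6)
})

test_that("training refuses single-class data and missing validation split", {
  recs <- list(sample_record(fix_clay(1, seed = 5, shape = 48), 1L, "a",
                             "x"),
               sample_record(fix_clay(1, seed = 6, shape = 48), 1L, "b",
                             "x"))
  man <- build_dataset(recs, fix_geom(2, det = 63, ps = 1.2),
                       default_materials(), withr::local_tempdir(),
                       noise = NULL, case = "clay")
  expect_error(train_baseline_classifier(man), "validation")
  man <- split_train_val(man, 0.3, seed = 1)
  expect_error(train_baseline_classifier(man), "single class")
})

test_that("repeated evaluation reports per-seed scores and their spread", {
  # tiny synthetic feature task exercised through the report structure
  one <- fix_clay(1, seed = 55, shape = 48)
  recs <- generate_from_one(one, generation_recipe("from_one", "clay",
                                                   G = 6, seed = 9), "s")
  geom <- fix_geom(n_angles = 3, det = 63, ps = 1.2)
  man <- build_dataset(recs, geom, default_materials(),
                       withr::local_tempdir(), noise_model(),
                       case = "clay", seed = 1)
  man <- split_train_val(man, 0.2, seed = 1)
  te <- build_dataset(recs[1:3], geom, default_materials(),
                      withr::local_tempdir(), noise_model(),
                      case = "clay", seed = 2)
  rep <- repeated_evaluation(man, te, n_seeds = 4, seed = 3)
  expect_length(rep$per_seed, 4)
  expect_equal(rep$A, mean(rep$per_seed))
  expect_equal(rep$dA, sd(rep$per_seed))
  expect_identical(sum(rep$confusion), 4L * nrow(te))
  # confusion rows sum to per-class test counts (pooled over seeds)
  expect_equal(as.vector(rowSums(rep$confusion)),
               as.vector(table(factor(te$class, levels = 0:2))) * 4)
  expect_error(repeated_evaluation(man, te, n_seeds = 1), ">= 2")
})

test_that("noisy-trained models are no worse than noiseless-trained on noisy tests", {
  # training images carrying the detector noise model should transfer to a
  # noisy test set at least as well (within one seed-spread dA) as
  # noiseless training images
  geom <- proj_geometry("parallel", n_angles = 12, det_rows = 80,
                        det_cols = 80, pixel_size = 1.1)
  one <- fix_clay(1, seed = 101, shape = 64)
  recs <- suppressWarnings(
    generate_from_one(one, generation_recipe("from_one", "clay", G = 12,
                                             seed = 7), "s"))
  man_n <- split_train_val(
    build_dataset(recs, geom, default_materials(), withr::local_tempdir(),
                  noise_model(), case = "clay", seed = 3), 0.15, seed = 2)
  man_c <- split_train_val(
    build_dataset(recs, geom, default_materials(), withr::local_tempdir(),
                  noise = NULL, case = "clay", seed = 3), 0.15, seed = 2)
  tg <- proj_geometry("parallel", angles = 13, det_rows = 80,
                      det_cols = 80, pixel_size = 1.1)
  test_recs <- lapply(1:45, function(i) {
    cls <- (i - 1) %% 3
    sample_record(make_phantom(phantom_spec("clay", 64,
                                            n_foreign_objects = cls,
                                            seed = 8000 + i)),
                  cls, paste0("t", i), "p")
  })
  man_te <- build_dataset(test_recs, tg, default_materials(),
                          withr::local_tempdir(), noise_model(),
                          case = "clay", seed = 4)
  rn <- repeated_evaluation(man_n, man_te, n_seeds = 4, seed = 20)
  rc <- repeated_evaluation(man_c, man_te, n_seeds = 4, seed = 20)
  expect_gte(rn$A, rc$A - rn$dA)
})
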