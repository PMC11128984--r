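# Shared separable dataset for the training tests: low noise, so the two
# classes split on mean intensity alone and a pixel-threshold oracle can
# certify separability before any model sees the data.
separable_dir <- local({
  dir <- file.path(tempdir(), "fishclip-trainset")
  if (!dir.exists(dir)) {
    build_training_set(60, 60, dir, cfg = scene_config(noise_level = 0.05,
                                                       seed = 11))
  }
  dir
})

test_that("the hyper-parameter grid enumerates all 8 combinations", {
  grid <- grid_specs()
  expect_length(grid, 8L)
  combos <- unique(t(vapply(grid, function(s) {
    c(s$learning_rate, s$dropout_rate, s$dense_units)
  }, numeric(3))))
  expect_equal(nrow(combos), 8L)
  # defaults of the training regime travel with every spec
  expect_true(all(vapply(grid, function(s) s$batch_size == 32L, logical(1))))
  expect_true(all(vapply(grid, function(s) s$epochs == 3L, logical(1))))
})

test_that("classifier_spec validates its fields", {
  expect_error(classifier_spec(dense_units = 0),
               class = "fishclip_argument_error")
  expect_error(classifier_spec(dropout_rate = 1),
               class = "fishclip_argument_error")
  expect_error(classifier_spec(learning_rate = -1),
               class = "fishclip_argument_error")
  expect_error(grid_specs(learning_rates = numeric(0)),
               class = "fishclip_argument_error")
  expect_error(build_model("not a spec", backend = "features"),
               class = "fishclip_argument_error")
})

test_that("the deep backend degrades to a capability error without keras", {
  if (requireNamespace("keras", quietly = TRUE)) {
    expect_s3_class(build_model(classifier_spec()), "fish_model")
  } else {
    expect_error(build_model(classifier_spec(), backend = "keras"),
                 class = "fishclip_capability_error")
  }
})

test_that("mock predictor is pure and separates blob frames from background", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(seed = 5)
  fishy <- file.path(dir, "fish.png")
  empty <- file.path(dir, "empty.png")
  set.seed(5)
  png::writePNG(fishclip:::render_scene_frame(cfg, phase = 0.5), fishy)
  png::writePNG(fishclip:::render_scene_frame(cfg, phase = NA), empty)

  samples <- data.frame(image_path = c(fishy, empty),
                        stringsAsFactors = FALSE)
  p <- predict_batch(mock_predictor(), samples)$p_fish
  expect_gt(p[1], 0.5)
  expect_lt(p[2], 0.5)
  expect_true(all(p >= 0 & p <= 1))
  # identical bytes -> identical score
  p2 <- predict_batch(mock_predictor(), samples)$p_fish
  expect_identical(p, p2)
  # empty batch passes through
  expect_equal(nrow(predict_batch(mock_predictor(),
                                  samples[0, , drop = FALSE])), 0L)
})

test_that("unreadable images are scored NA with a warning, never dropped", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "missing.png")
  samples <- data.frame(image_path = bad, stringsAsFactors = FALSE)
  expect_warning(out <- predict_batch(mock_predictor(), samples),
                 "could not be read")
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$p_fish))
})

test_that("CSV replay reproduces stored probabilities exactly", {
  dir <- withr::local_tempdir()
  stored <- make_predictions(c(0.123456789, 0.5, 0.99))
  stored$image_path <- sprintf("img_%d.png", 1:3)
  csv <- file.path(dir, "scores.csv")
  write_manifest(stored, csv)

  samples <- stored[, setdiff(names(stored), "p_fish")]
  out <- predict_batch(csv_predictor(csv), samples)
  expect_identical(out$p_fish, stored$p_fish)
  # image_path matching is order-independent
  out2 <- predict_batch(csv_predictor(csv), samples[c(3, 1, 2), ])
  expect_identical(out2$p_fish, stored$p_fish[c(3, 1, 2)])
  expect_error(csv_predictor(file.path(dir, "nope.csv")),
               class = "fishclip_io_error")
})

test_that("training on the separable set reaches high validation accuracy", {
  # pixel-threshold oracle first: certify the set really is separable
  files <- list.files(separable_dir, recursive = TRUE, full.names = TRUE)
  is_fish <- grepl("/fish/", files)
  means <- vapply(files, function(f) mean(png::readPNG(f)), numeric(1))
  cut <- mean(c(max(means[!is_fish]), min(means[is_fish])))
  oracle_acc <- mean((means > cut) == is_fish)
  expect_gte(oracle_acc, 0.95)

  report <- train(build_model(classifier_spec(seed = 7),
                              backend = "features"), separable_dir)
  expect_s3_class(report, "training_report")
  expect_gte(report$val_accuracy, 0.9)
  # sanity floor: the trained model is not far below the pixel oracle
  expect_gte(report$val_accuracy, oracle_acc - 0.05)
  expect_equal(report$n_train + report$n_val, 120L)
  expect_equal(sum(report$class_counts), 120L)

  # trained model scores fish stills above background stills
  some <- data.frame(image_path = c(
    list.files(file.path(separable_dir, "fish"), full.names = TRUE)[1],
    list.files(file.path(separable_dir, "no_fish"), full.names = TRUE)[1]))
  p <- predict_batch(report, some)$p_fish
  expect_gt(p[1], p[2])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the train/validation split is seeded and stratified", {
  r1 <- train(build_model(classifier_spec(seed = 3), backend = "features"),
              separable_dir)
  r2 <- train(build_model(classifier_spec(seed = 3), backend = "features"),
              separable_dir)
  expect_identical(r1$split$is_train, r2$split$is_train)
  r3 <- train(build_model(classifier_spec(seed = 4), backend = "features"),
              separable_dir)
  expect_false(identical(r1$split$is_train, r3$split$is_train))
  # 80/20 within each class
  tr <- tapply(r1$split$is_train, r1$split$label, mean)
  expect_true(all(abs(tr - 0.8) < 0.05))
})

test_that("single-class or empty directories raise data errors", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "fish"))
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "fish", "a.png"))
  expect_error(train(build_model(classifier_spec(), backend = "features"),
                     dir),
               class = "fishclip_data_error")
  dir.create(file.path(dir, "no_fish"))
  expect_error(train(build_model(classifier_spec(), backend = "features"),
                     dir),
               class = "fishclip_data_error")
})

test_that("grid search selects the maximum accuracy with first-position ties", {
  res <- grid_search(separable_dir, grid = grid_specs(seed = 9))
  expect_length(res$reports, 8L)
  accs <- vapply(res$reports, function(r) r$val_accuracy, numeric(1))
  expect_equal(res$best$val_accuracy, max(accs))
  expect_equal(which.max(accs),
               match(res$best$val_accuracy, accs))  # earliest max wins
  expect_error(grid_search(separable_dir, grid = list()),
               class = "fishclip_argument_error")
  single <- grid_search(separable_dir, grid = grid_specs()[1])
  expect_equal(single$best$val_accuracy, single$reports[[1]]$val_accuracy)
})

test_that("trained predictors persist to JSON and reload without refitting", {
  dir <- withr::local_tempdir()
  report <- train(build_model(classifier_spec(seed = 7),
                              backend = "features"), separable_dir)
  path <- file.path(dir, "model.json")
  save_predictor(report, path)
  reloaded <- load_predictor(path)

  some <- data.frame(image_path = list.files(
    file.path(separable_dir, "fish"), full.names = TRUE)[1:5])
  expect_equal(predict_batch(reloaded, some)$p_fish,
               predict_batch(report, some)$p_fish, tolerance = 1e-10)
})

test_that("dataset summaries count per class and total", {
  s <- dataset_summary(separable_dir)
  expect_equal(sort(names(s$class_counts)), c("fish", "no_fish"))
  expect_equal(s$total, 120L)
  expect_equal(unname(dataset_summary(c(fish = 2, no_fish = 3))$total), 5)
  expect_error(dataset_summary(c(fish = -1)),
               class = "fishclip_argument_error")
})
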