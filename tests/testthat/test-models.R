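test_that("every algorithm family separates the separable toy perfectly", {
  ds <- toy_separable_dataset(25, seed = 42)
  for (algo in rama_algorithms()) {
    model <- train_model(ds, algo, seed = 7)
    pred <- predict_class(model, ds$features)
    acc <- mean(pred == ds$label)
    expect_equal(acc, 1, info = algo)
    p <- predict_probability(model, ds$features)
    expect_true(all(p >= 0 & p <= 1), info = algo)
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- toy_separable_dataset(25, seed = 42)
  probe <- toy_separable_dataset(10, seed = 99)$features
  for (algo in c("random-forest", "multilayer-perceptron", "svm-rbf")) {
    m1 <- train_model(ds, algo, seed = 7)
    m2 <- train_model(ds, algo, seed = 7)
    expect_identical(predict_probability(m1, probe),
                     predict_probability(m2, probe), info = algo)
  }
})

test_that("a short-positive model assigns > 0.5 to a short probe", {
  # positives are exactly the short sequences in the toy construction
  ds <- toy_separable_dataset(25, seed = 1)
  model <- train_model(ds, "random-forest", seed = 3)
  probe <- ds$features[1, ]; probe$length <- 100
  expect_gt(predict_probability(model, probe), 0.5)
  far_probe <- ds$features[26, ]; far_probe$length <- 500
  expect_lt(predict_probability(model, far_probe), 0.5)
})

test_that("flipping the labels complements tree-ensemble probabilities", {
  ds <- toy_separable_dataset(25, seed = 8)
  flipped <- labeled_dataset(ds$species, ds$task, ds$features,
                             ifelse(ds$class_name == "RP", "NRP", "RP"),
                             seed = ds$seed)
  probe <- ds$features[c(1, 10, 30, 45), ]
  m <- train_model(ds, "random-forest", seed = 5)
  mf <- train_model(flipped, "random-forest", seed = 5)
  expect_equal(predict_probability(m, probe),
               1 - predict_probability(mf, probe), tolerance = 0.05)
})

test_that("models persist and reload with identical predictions", {
  ds <- toy_separable_dataset(20, seed = 4)
  probe <- toy_separable_dataset(50, seed = 77)$features
  for (algo in c("random-forest", "naive-bayes", "svm-linear")) {
    model <- train_model(ds, algo, seed = 2)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(model, path)
    back <- load_model(path)
    expect_identical(predict_probability(back, probe),
                     predict_probability(model, probe), info = algo)
    expect_equal(back$dataset_hash, model$dataset_hash)
  }
  expect_error(load_model(withr::local_tempfile(fileext = ".rds",
                                                lines = "")), "")
})

test_that("training rejects degenerate inputs and mismatched probes", {
  ds <- toy_separable_dataset(10, seed = 4)
  single <- ds
  single$label <- factor(rep("positive", n_instances(ds)),
                         levels = c("negative", "positive"))
  expect_error(train_model(single, "random-forest"), "single-class")
  bad <- ds
  bad$features$volume[3] <- Inf
  expect_error(train_model(bad, "random-forest"), bad$ids[3])
  model <- train_model(ds, "random-forest", seed = 1)
  expect_error(predict_probability(model, ds$features[, 1:5]),
               "feature mismatch")
})

test_that("best-model selection maximizes MCC with documented tie-breaks", {
  ds <- toy_separable_dataset(15, seed = 2)
  m1 <- train_model(ds, "naive-bayes", seed = 1)
  m2 <- train_model(ds, "random-forest", seed = 1)
  m3 <- train_model(ds, "c45-tree", seed = 1)
  mk <- function(mcc, f) c(precision = 1, accuracy = 1, sensitivity = 1,
                           specificity = 1, f_measure = f, mcc = mcc)
  best <- select_best(list(m1, m2, m3), list(mk(0.3, .9), mk(0.8, .9), mk(0.5, .9)))
  expect_equal(best$algorithm, "random-forest")
  # MCC tie -> F-measure decides
  best2 <- select_best(list(m1, m2), list(mk(0.8, 0.95), mk(0.8, 0.90)))
  expect_equal(best2$algorithm, "naive-bayes")
  # full tie -> lexicographic algorithm id
  best3 <- select_best(list(m2, m3), list(mk(0.8, 0.9), mk(0.8, 0.9)))
  expect_equal(best3$algorithm, "c45-tree")
  expect_equal(select_best(list(m1), list(mk(0.1, 0.1)))$algorithm,
               "naive-bayes")
  expect_error(select_best(list(), list()), "empty")
})

test_that("forest and perceptron beat naive Bayes on the benchmark as a trend", {
  wins <- 0L
  for (s in 1:10) {
    bench <- default_benchmark(seed = 100 + s, n_species = 2)
    train <- bench[[1]]$datasets$RP_vs_NRP
    test <- bench[[2]]$datasets$RP_vs_NRP
    mcc_of <- function(algo) {
      m <- train_model(train, algo, seed = 3)
      interspecies_test(m, test)$metrics[["mcc"]]
    }
    nb <- mcc_of("naive-bayes")
    if (mcc_of("random-forest") > nb && mcc_of("multilayer-perceptron") > nb)
      wins <- wins + 1L
    else if (mcc_of("random-forest") > nb || mcc_of("multilayer-perceptron") > nb)
      wins <- wins + 0.5
  }
  expect_gte(wins, 6)
})
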