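test_that("class entropy matches closed forms", {
  expect_equal(class_entropy(rep("a", 10)), 0)
  expect_equal(class_entropy(rep(c("a", "b"), 25)), 1)
  # -0.25 log2 0.25 - 0.75 log2 0.75
  expect_equal(class_entropy(c(rep("a", 25), rep("b", 75))), 0.8112781,
               tolerance = 1e-6)
  expect_error(class_entropy(character(0)), "empty")
})

test_that("information gain hits its algebraic extremes", {
  labels <- rep(c("x", "y"), each = 20)
  sep <- c(rnorm(20, 0), rnorm(20, 100))
  expect_equal(information_gain(sep, labels), class_entropy(labels),
               tolerance = 1e-12)
  same <- rep(c(1, 2, 3, 4), 10)
  expect_equal(information_gain(same, labels, discretizer = "efreq", bins = 4), 0)
  # constant attribute: single bin, zero gain, not an error
  expect_equal(information_gain(rep(5, 40), labels), 0)
})

test_that("information gain equals the mutual-information oracle on small fixtures", {
  set.seed(11)
  for (rep_i in 1:60) {
    n <- sample(4:12, 1)
    n_bins <- sample(1:3, 1)
    labels <- sample(c("a", "b"), n, replace = TRUE)
    bins <- sample(seq_len(n_bins), n, replace = TRUE)
    values <- as.numeric(bins) + runif(n, -0.2, 0.2)  # values realize the bins
    fixed_binning <- function(v, l) bins
    got <- information_gain(values, labels, discretizer = fixed_binning)
    expect_equal(got, max(mi_oracle(bins, labels), 0), tolerance = 1e-12)
  }
})

test_that("MDL discretization collapses uninformative attributes and splits clean ones", {
  labels <- rep(c("a", "b"), each = 30)
  noise <- rep(seq(0, 1, length.out = 30), 2)     # same values in both classes
  expect_equal(length(unique(discretize_mdl(noise, labels))), 1L)
  clean <- c(seq(1, 2, length.out = 30), seq(10, 11, length.out = 30))
  bins <- discretize_mdl(clean, labels)
  expect_gt(length(unique(bins)), 1L)
  expect_equal(information_gain(clean, labels), 1, tolerance = 1e-12)
})

test_that("quantile-based IG is invariant under strictly monotone transforms", {
  set.seed(3)
  values <- rnorm(80)
  labels <- ifelse(values + rnorm(80, 0, 0.5) > 0, "p", "n")
  base <- information_gain(values, labels, discretizer = "efreq")
  expect_equal(information_gain(exp(values), labels, discretizer = "efreq"), base)
  expect_equal(information_gain(values^3, labels, discretizer = "efreq"), base)
})

test_that("IG is bounded by the class entropy over random datasets", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    values <- rnorm(n)
    labels <- sample(c("a", "b"), n, replace = TRUE)
    for (d in c("mdl", "efreq")) {
      ig <- information_gain(values, labels, discretizer = d)
      expect_gte(ig, 0)
      expect_lte(ig, class_entropy(labels) + 1e-12)
    }
  }
})

test_that("attribute ranking is a deterministic permutation with sensible winners", {
  ds <- toy_separable_dataset(40, seed = 9)
  rep1 <- rank_attributes(ds)
  expect_s3_class(rep1, "ig_report")
  expect_setequal(rep1$attribute, attribute_names())
  expect_equal(sort(rep1$rank), 1:9)
  # positively_charged and length are the constructed separators
  expect_setequal(rep1$attribute[1:2], c("positively_charged", "length"))

  # random labels: all IG near zero, ranks still a permutation (name-ordered)
  set.seed(21)
  shuffled <- labeled_dataset(ds$species, ds$task, ds$features,
                              sample(ds$class_name))
  rep2 <- rank_attributes(shuffled)
  expect_lt(max(rep2$ig), 0.15)
  expect_equal(sort(rep2$rank), 1:9)
  zero <- rep2[rep2$ig == 0, "attribute"]
  expect_equal(zero, sort(zero))  # tie-break by attribute name
})

test_that("class-conditional summaries conserve counts and separate means", {
  ds <- toy_separable_dataset(30, seed = 13)
  h <- class_conditional_summaries(ds, type = "histogram", grid_n = 20)
  for (cl in c("RP", "NRP")) {
    counts <- h$count[h$attribute == "length" & h$class == cl]
    expect_equal(sum(counts), 30L)
  }
  d <- class_conditional_summaries(ds, type = "density")
  expect_setequal(unique(d$class), c("RP", "NRP"))
  expect_true(all(d$y >= 0))
  # density mass sits at higher positively_charged for RP than NRP
  mean_of <- function(cl) {
    sl <- d[d$attribute == "positively_charged" & d$class == cl, ]
    sum(sl$x * sl$y) / sum(sl$y)
  }
  expect_gt(mean_of("RP"), mean_of("NRP"))

  # a class with < 2 instances is omitted with a warning
  tiny <- labeled_dataset("sp", "RP_vs_NRP",
                          ds$features[c(1, 2, 31), ],
                          c("RP", "RP", "NRP"))
  expect_warning(class_conditional_summaries(tiny), "omitted")
})
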