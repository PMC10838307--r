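test_that("training sets sample exact per-class counts reproducibly", {
  ctrl <- generate_population_table(population_spec(2000, 0, seed = 1))
  trt <- generate_population_table(population_spec(2000, 1, seed = 2))
  ts <- build_training_set(ctrl, trt, n_per_class = 500, seed = 9)
  expect_identical(unname(ts$class_counts), c(500L, 500L))
  expect_identical(ts$y, rep(c(0L, 1L), each = 500))
  ts2 <- build_training_set(ctrl, trt, n_per_class = 500, seed = 9)
  expect_identical(ts$x, ts2$x)
  expect_error(build_training_set(ctrl, trt, n_per_class = 5000),
               "allow_smaller")
  ts3 <- build_training_set(ctrl[1:100, ], trt, n_per_class = 500,
                            allow_smaller = TRUE)
  expect_identical(unname(ts3$class_counts), c(100L, 500L))
})

test_that("marker-based labeling restricts eligibility to marker status", {
  ctrl <- generate_population_table(population_spec(1000, 0, seed = 3))
  trt <- generate_population_table(population_spec(1000, 1, seed = 4))
  # marker channel: 40% of treated positive, tagged by a sentinel area shift
  trt$c12fdg <- rep(c(10, 0), c(400, 600))
  trt$Area[1:400] <- trt$Area[1:400] + 10000 # sentinel for positives
  ctrl$c12fdg <- 0
  pol <- labeling_policy("marker", channel = "c12fdg", threshold = 5)
  ts <- build_training_set(ctrl, trt, pol, n_per_class = 300, seed = 1)
  expect_true(all(ts$x$Area[ts$y == 1] > 9000)) # only the 40% eligible
  expect_error(build_training_set(ctrl, trt, pol, n_per_class = 500),
               "allow_smaller") # only 400 marker-positive cells exist
  expect_error(labeling_policy("marker"), "channel")
})

test_that("trees recover a 1-D separable split within the gap", {
  # exhaustive split-point oracle: any threshold in the gap separates
  x <- matrix(c(seq(1, 4.8, length.out = 40), seq(5.2, 9, length.out = 40)),
              ncol = 1)
  y <- rep(c(0L, 1L), each = 40)
  tree <- grow_cart(x, y, min_split = 10, min_bucket = 3)
  expect_false(tree$leaf)
  expect_true(tree$left$leaf && tree$right$leaf) # depth 1
  expect_gt(tree$val, 4.8)
  expect_lt(tree$val, 5.2)
  expect_identical(as.integer(predict_cart(tree, x) > 0.5), as.integer(y))
})

test_that("pruning collapses trees grown on label noise", {
  res <- vapply(1:10, function(s) {
    ts <- small_training_set(200, effect = 0, seed = 100 + s)
    tr <- train_tree(ts, seed = s)
    full <- grow_cart(as.matrix(ts$x), ts$y) # unpruned fit on all rows
    # generalization accuracy on fresh data (the alpha-selection holdout
    # itself is optimistically biased by the selection, see vignette)
    fresh <- generate_population_table(
      population_spec(500, 0.5, effect_scale = 0, seed = 9000 + s))
    c(acc = mean(predict(tr, fresh) == fresh$.truth),
      leaves = tr$metadata$n_leaves, full = cart_n_leaves(full))
  }, numeric(3))
  # labels independent of features: accuracy near the max class prior (0.5)
  expect_lt(abs(mean(res["acc", ]) - 0.5), 0.05)
  # and the selected subtrees collapse toward the root vs the unpruned fit
  expect_lt(mean(res["leaves", ]), 0.7 * mean(res["full", ]))
})

test_that("tree growth is invariant to duplicating every row", {
  ts <- small_training_set(150, seed = 2)
  X <- as.matrix(ts$x)
  t1 <- grow_cart(X, ts$y, min_split = 20, min_bucket = 7)
  t2 <- grow_cart(rbind(X, X), c(ts$y, ts$y), min_split = 40, min_bucket = 14)
  strip <- function(node) { # structure only: split variables and thresholds
    if (isTRUE(node$leaf)) return(list(pred = node$pred))
    list(var = node$var, val = node$val,
         left = strip(node$left), right = strip(node$right))
  }
  expect_identical(strip(t1), strip(t2))
})

test_that("forests separate well-shifted classes and respect the cutoff", {
  ts <- small_training_set(400, seed = 3)
  accs <- vapply(1:5, function(s) {
    fo <- train_forest(ts, n_trees = 40, seed = s)
    fo$metadata$holdout_accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.9)) # default effect sizes are well separated
  fo <- train_forest(ts, n_trees = 40, seed = 1)
  tab <- generate_population_table(population_spec(200, 0.5, seed = 77))
  prob <- predict(fo, tab, type = "prob")
  lab <- predict(fo, tab)
  expect_identical(lab, as.integer(prob > 0.5)) # strict: 0.5 -> normal
  if (any(prob == 0.5)) expect_true(all(lab[prob == 0.5] == 0L))
  expect_identical(predict(fo, tab), lab) # deterministic
})

test_that("single-class training input errors", {
  ts <- small_training_set(100, seed = 4)
  ts$y[] <- 1L
  expect_error(train_tree(ts), "both classes")
  expect_error(train_forest(ts), "both classes")
})

test_that("consensus voting uses strict majority with ties to normal", {
  # stub members that always vote a fixed label
  stub <- function(vote) {
    m <- structure(list(kind = "tree", feature_set = feature_set("core7"),
                        fit = list(leaf = TRUE, prob = vote, n = 1,
                                   n1 = vote, pred = vote),
                        cutoff = 0.5, metadata = list()),
                   class = "senescence_model")
    m
  }
  tab <- generate_population_table(population_spec(10, 0.5, seed = 1))
  ens8 <- consensus_ensemble(lapply(rep(1, 8), stub))
  expect_true(all(predict(ens8, tab) == 1L))      # 8 of 8
  ens44 <- consensus_ensemble(lapply(rep(c(1, 0), each = 4), stub))
  expect_true(all(predict(ens44, tab) == 0L))     # 4-4 tie -> normal
  ens53 <- consensus_ensemble(lapply(rep(c(1, 0), c(5, 3)), stub))
  expect_true(all(predict(ens53, tab) == 1L))     # 5 of 8
  expect_error(consensus_ensemble(list(stub(1))), "at least 2")
})

test_that("well summaries conserve cells and flag empty wells", {
  wells <- factor(rep(c("A1", "B1"), c(100, 40)), levels = c("A1", "B1", "C1"))
  labels <- c(rep(c(1L, 0L), c(30, 70)), rep(0L, 40))
  s <- summarize_wells(labels, wells)
  expect_equal(s$pct_senescent[s$well == "A1"], 30.0)
  expect_true(s$empty[s$well == "C1"])
  expect_true(is.na(s$pct_senescent[s$well == "C1"]))
  expect_identical(sum(s$n_cells), 140L)
  expect_error(summarize_wells(1L, c("A", "B")), "equal length")
})

test_that("mixture recovery: predicted well fractions track the truth", {
  ts <- small_training_set(800, seed = 5)
  tr <- train_tree(ts, seed = 5)
  fracs <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 3)
  pct <- vapply(seq_along(fracs), function(i) {
    tab <- generate_population_table(
      population_spec(200, fracs[i], seed = 4000 + i))
    100 * mean(predict(tr, tab))
  }, numeric(1))
  expect_gte(cor(pct, fracs), 0.95)
})

test_that("null classifiers show no systematic well bias", {
  # forest: tree models collapsed to the root call everything normal under
  # the strict > 0.5 rule, so the unbiasedness check uses the forest vote
  ts <- small_training_set(300, effect = 0, seed = 6)
  fo <- train_forest(ts, n_trees = 60, seed = 6)
  pcts <- vapply(1:8, function(i) {
    tab <- generate_population_table(
      population_spec(250, 0.5, effect_scale = 0, seed = 8000 + i))
    100 * mean(predict(fo, tab))
  }, numeric(1))
  expect_gte(mean(pcts), 40)
  expect_lte(mean(pcts), 60)
})

test_that("models round-trip through serialization with identical output", {
  ts <- small_training_set(200, seed = 7)
  fo <- train_forest(ts, n_trees = 25, seed = 7)
  tab <- generate_population_table(population_spec(300, 0.4, seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fo, path)
  fo2 <- load_model(path)
  expect_identical(predict(fo2, tab, type = "prob"),
                   predict(fo, tab, type = "prob"))
  expect_error(predict(fo, tab[, 1:3]), "missing model features")
})
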