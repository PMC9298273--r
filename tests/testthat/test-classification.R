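# Classifier grid: combination enumeration, folds, ROC-AUC, training,
# aggregation, cross-validation bookkeeping and transfer.

test_that("channel-combination enumeration follows the ablation rule", {
  five <- c("TDP43", "SFPQ", "FUS", "hnRNPA1", "hnRNPK")
  expect_length(enumerate_channel_combinations(five), 13)
  expect_length(enumerate_channel_combinations("FUS"), 5)
  expect_length(enumerate_channel_combinations(character(0)), 3)
  labels <- vapply(enumerate_channel_combinations("FUS"),
                   function(cb) cb$label, character(1))
  expect_equal(labels, c("DAPI", "BIII", "FUS", "DAPI:BIII", "DAPI:BIII:FUS"))
  expect_error(enumerate_channel_combinations(c("FUS", "FUS")), "duplicate")
})

test_that("stratified folds balance classes and partition the index set", {
  y <- rep(c(1, 0), c(50, 50))
  f <- make_stratified_folds(y, k = 10, seed = 1)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == 1), 5)
    expect_equal(sum(f == k & y == 0), 5)
  }
  y2 <- rep(c(1, 0), c(53, 47))
  f2 <- make_stratified_folds(y2, k = 10, seed = 2)
  expect_true(all(table(f2[y2 == 1]) %in% 5:6))
  expect_true(all(table(f2[y2 == 0]) %in% 4:5))
  expect_equal(sort(unique(f2)), 1:10)
  expect_length(f2, 100)
  expect_error(make_stratified_folds(rep(c(1, 0), c(5, 50)), k = 10), "fewer")
})

test_that("roc_auc equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(roc_auc(rep(0.5, 4), rep(0.5, 3)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
  pair_oracle <- function(p, n) {
    s <- 0
    for (a in p) for (b in n) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(p) * length(n))
  }
  for (s in 1:20) {
    neuroscreen:::with_seed(s, {
      p <- round(runif(7), 1); n <- round(runif(9), 1)  # forces ties
      expect_equal(roc_auc(p, n), pair_oracle(p, n))
    })
  }
})

test_that("roc_auc matches trapezoidal ROC integration and rank invariance", {
  trap_auc <- function(pos, neg) {
    th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  }
  for (s in 1:20) {
    neuroscreen:::with_seed(s, {
      pos <- rnorm(11); neg <- rnorm(13)
      expect_lt(abs(roc_auc(pos, neg) - trap_auc(pos, neg)), 1e-12)
      # invariance under a strictly increasing transform
      expect_equal(roc_auc(pos, neg), roc_auc(exp(pos / 2), exp(neg / 2)))
    })
  }
  skip_if_not_installed("pROC")
  neuroscreen:::with_seed(3, {
    pos <- rnorm(15); neg <- rnorm(12)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(1:0, c(15, 12)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(pos, neg), ref)
  })
})

test_that("training learns separable data and is deterministic", {
  d <- separable_crops(30, shift = 0.6)
  cfg <- classifier_config(learning_rate = 0.01, epochs = 10, seed = 4)
  m <- train_classifier(d$x, d$y, cfg)
  p <- predict(m, d$x)
  expect_gte(mean((p > 0.5) == d$y), 0.95)
  m2 <- train_classifier(d$x, d$y, cfg)
  expect_identical(predict(m2, d$x), p)
  expect_error(train_classifier(d$x, rep(1, length(d$y)), cfg),
               "single class")
  expect_error(train_classifier(d$x, d$y,
                                classifier_config(backbone = "pretrained_mobilenet_v2")),
               "externally supplied")
})

test_that("no class signal yields chance-level held-out AUC", {
  neuroscreen:::with_seed(8, {
    n <- 120
    x <- array(rnorm(32 * 32 * 3 * n), dim = c(32, 32, 3, n))
    y <- rep(0:1, n / 2)
  })
  m <- train_classifier(x[, , , 1:80], y[1:80],
                        classifier_config(learning_rate = 0.01, epochs = 3,
                                          seed = 2))
  p <- predict(m, x[, , , 81:n])
  auc <- roc_auc(p[y[81:n] == 1], p[y[81:n] == 0])
  expect_lt(abs(auc - 0.5), 0.2)
})

test_that("prediction aggregation averages crops to images to cultures", {
  tb <- data.frame(
    crop = paste0("c", 1:16), image = "img1", culture = "cult1",
    prob = rep(0.7, 16))
  expect_equal(aggregate_predictions(tb)$images$prob, 0.7)
  tb2 <- data.frame(crop = paste0("c", 1:16), image = "img1",
                    culture = "cult1", prob = rep(c(0.2, 0.8), each = 8))
  expect_equal(aggregate_predictions(tb2)$images$prob, 0.5)
  tb3 <- data.frame(crop = paste0("c", 1:3), image = paste0("i", 1:3),
                    culture = "cult1", prob = c(0.4, 0.6, 0.8))
  agg <- aggregate_predictions(tb3)
  expect_equal(agg$cultures$prob, 0.6)
  expect_equal(agg$cultures$n_images, 3)
  tb4 <- data.frame(crop = "c1", image = NA, culture = "cult1", prob = 0.5)
  expect_error(aggregate_predictions(tb4), "c1")
})

test_that("cross-validation bookkeeping: row counts and leak-free folds", {
  fields <- fake_two_class_fields(4)
  combos <- list(channel_combination("DAPI"), channel_combination("BIII"))
  tests <- list(isALS = list(positive = "mutant", negative = "control"))
  tab <- run_cv_grid(fields, tests, combos, n_subsets = 1, k = 2,
                     config = classifier_config(epochs = 1, seed = 1),
                     pp_config = tiny_pp)
  expect_s3_class(tab, "fold_auc_table")
  expect_equal(nrow(tab), length(tests) * length(combos) * 1 * 2)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  # a combination whose marker is absent is skipped with a warning
  expect_warning(
    tab2 <- run_cv_grid(fields, tests,
                        list(channel_combination("TDP43")),
                        n_subsets = 1, k = 2,
                        config = classifier_config(epochs = 1, seed = 1),
                        pp_config = tiny_pp),
    "TDP43")
  expect_null(tab2)
})

test_that("fold assignment keeps sibling crops together at image level", {
  fields <- fake_two_class_fields(6)
  combo <- channel_combination("DAPI")
  ds <- neuroscreen:::build_crop_dataset(fields, combo, tiny_pp)
  units <- unique(ds$meta[, c("image", "condition")])
  f <- make_stratified_folds(units$condition, k = 3, seed = 5)
  fold_of_crop <- f[match(ds$meta$image, units$image)]
  # all crops of one image share a fold
  per_img <- tapply(fold_of_crop, ds$meta$image, function(v) length(unique(v)))
  expect_true(all(per_img == 1))
})

test_that("transfer: brighter-phenotype model ranks conditions by magnitude", {
  # class signal is the intensity histogram; conditions share it at
  # different magnitude (gamma 0.5 = full phenotype, 0.75 = partial)
  fields <- fake_two_class_fields(6, gamma_pos = 0.5)
  half <- lapply(1:6, function(i)
    fake_field("heat", sprintf("WH%02d", i), 1, gamma = 0.75, seed = i + 50))
  none <- lapply(1:6, function(i)
    fake_field("osmotic", sprintf("WO%02d", i), 1, gamma = 1, seed = i + 80))
  combo <- channel_combination("DAPI")
  ds <- neuroscreen:::build_crop_dataset(fields, combo, tiny_pp)
  aug <- neuroscreen:::augment_crops(ds$crops,
                                     as.integer(ds$meta$condition == "mutant"))
  m <- train_classifier(aug$crops, aug$labels,
                        classifier_config(learning_rate = 0.01, epochs = 4,
                                          seed = 3))
  m$combo <- combo
  pt <- apply_classifier(m, c(fields, half, none), pp_config = tiny_pp)
  mu <- tapply(pt$cultures$prob, pt$cultures$condition, mean)
  expect_gt(mu[["mutant"]], mu[["heat"]])
  expect_gt(mu[["heat"]], mu[["osmotic"]])
  expect_lt(mu[["osmotic"]], 0.5)
  # marker mismatch is rejected
  expect_error(apply_classifier(m, fields, channel_combination("TDP43"),
                                tiny_pp), "TDP43")
})
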