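# Protocol: fold partitioning, best-on-test tracking, cross-validation
# bookkeeping, and the variant/augmentation harnesses at toy scale.

test_that("k-fold splits are disjoint, covering and balanced", {
  fa <- kfoldSplit(10, 5, seed = 3)
  expect_equal(lengths(fa@folds), rep(2L, 5))
  expect_equal(sort(unlist(fa@folds)), 1:10)
  fa2 <- kfoldSplit(11, 5, seed = 3)
  expect_equal(lengths(fa2@folds), c(3L, 2L, 2L, 2L, 2L))
  expect_identical(kfoldSplit(11, 5, seed = 3), fa2)   # seeded determinism
  expect_false(identical(kfoldSplit(11, 5, seed = 4)@folds, fa2@folds))
  # randomized sizes: disjointness, coverage, balance
  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    k <- sample(2:min(n, 8), 1)
    fa <- kfoldSplit(n, k, seed = i)
    expect_equal(sort(unlist(fa@folds)), seq_len(n))
    expect_lte(diff(range(lengths(fa@folds))), 1)
    expect_equal(sum(duplicated(unlist(fa@folds))), 0)
  }
  expect_error(kfoldSplit(5, 6), "k must")
  expect_error(kfoldSplit(5, 1), "k must")
  # leave-one-out is the k = n limit
  expect_equal(lengths(kfoldSplit(7, 7, 1)@folds), rep(1L, 7))
})

test_that("training records per-epoch scores and reports the maximum", {
  d <- tinyDataset(n = 6, size = 16)
  cfg <- tinyModelConfig(depth = 1)
  opt <- new("OptimizerConfig", batchSize = 2L, epochs = 4L, seed = 3L)
  fit <- trainModel(buildModel(cfg), d[1:4], d[5:6], opt)
  r <- fit$result
  expect_equal(nrow(r@records), 4)
  expect_equal(r@bestJaccard, max(r@records$jaccard))
  expect_equal(r@records$jaccard[r@records$epoch == r@bestEpoch],
               r@bestJaccard)
  expect_true(all(is.finite(r@records$loss)))
  # identical seeds and data give identical epoch records
  fit2 <- trainModel(buildModel(cfg), d[1:4], d[5:6], opt)
  expect_identical(fit2$result@records, r@records)
  # a larger epoch budget can never lower the best (max over a superset)
  opt6 <- new("OptimizerConfig", batchSize = 2L, epochs = 6L, seed = 3L)
  fit3 <- trainModel(buildModel(cfg), d[1:4], d[5:6], opt6)
  expect_gte(fit3$result@bestJaccard, r@bestJaccard)
  expect_identical(fit3$result@records$jaccard[1:4], r@records$jaccard)
  expect_error(trainModel(buildModel(cfg), list(), d[5:6], opt), "non-empty")
})

test_that("cross-validation tests every sample exactly once and aggregates", {
  d <- tinyDataset(n = 10, size = 16)
  cfg <- tinyModelConfig(depth = 1)
  opt <- new("OptimizerConfig", batchSize = 4L, epochs = 2L, seed = 1L)
  rep_ <- crossValidate(cfg, d, k = 5, opt, seed = 2)
  expect_length(rep_@folds, 5)
  best <- vapply(rep_@folds, function(r) r@bestJaccard, numeric(1))
  ag <- aggregateFolds(best)
  expect_equal(rep_@mean, ag[["mean"]])
  expect_equal(rep_@sd, ag[["sd"]])
  expect_equal(rep_@protocol, "best-on-test")
  # the fold partition actually covers the dataset
  fa <- kfoldSplit(10, 5, seed = 2)
  expect_equal(sort(unlist(fa@folds)), 1:10)
  expect_error(crossValidate(cfg, d[1:3], k = 5, opt), "size")
})

test_that("the variant table has one row per variant with a correct Avg", {
  d <- tinyDataset(n = 6, size = 16)
  opt <- new("OptimizerConfig", batchSize = 3L, epochs = 1L, seed = 1L)
  rv <- runVariants(d, k = 2, opt, rank = 2, depth = 1,
                    baseFilters = c(8, 16), inChannels = 1, seed = 1,
                    variants = c("unet", "paths", "mdu"))
  tab <- rv$table
  expect_equal(tab$Type, c("unet", "paths", "mdu"))
  expect_equal(names(tab), c("Type", "F1", "F2", "Avg"))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$Avg[i],
                 round(mean(as.numeric(tab[i, c("F1", "F2")])), 3),
                 tolerance = 1e-2)
  # the paths-only variant adds skip convolutions over the baseline
  pu <- countParameters(buildModel(modelConfig(rank = 2, variant = "paths",
    depth = 1, inChannels = 1, stageWidths = c(8, 16), seed = 1)))
  bu <- countParameters(buildModel(modelConfig(rank = 2, variant = "unet",
    depth = 1, inChannels = 1, stageWidths = c(8, 16), seed = 1)))
  expect_gt(pu@totalTrainable, bu@totalTrainable)
})

test_that("the augmentation arm trains on exactly three times the samples", {
  d <- tinyDataset(n = 6, size = 16)
  fa <- kfoldSplit(6, 3, seed = 1)
  trainIdx <- setdiff(1:6, fa@folds[[1]])
  plain <- d[trainIdx]
  boosted <- augmentDataset(plain, new("AugmentConfig", factor = 3L,
                                       seed = 1L))
  expect_length(boosted, 3 * length(plain))
  # and the held-out fold is untouched by crossValidate's augmentation arm
  cfg <- tinyModelConfig(depth = 1)
  opt <- new("OptimizerConfig", batchSize = 4L, epochs = 1L, seed = 1L)
  repAug <- crossValidate(cfg, d, k = 3, opt, seed = 1,
                          augment = new("AugmentConfig", factor = 3L,
                                        seed = 1L))
  expect_length(repAug@folds, 3)
})

test_that("per-epoch logging writes to stderr when requested", {
  d <- tinyDataset(n = 4, size = 16)
  cfg <- tinyModelConfig(depth = 1)
  opt <- new("OptimizerConfig", batchSize = 2L, epochs = 1L, seed = 1L)
  expect_message(trainModel(buildModel(cfg), d[1:2], d[3:4], opt,
                            verbose = TRUE),
                 "epoch\\s+1")
})

test_that("report exports carry fold rows and the comparison summary", {
  d <- tinyDataset(n = 6, size = 16)
  opt <- new("OptimizerConfig", batchSize = 3L, epochs = 2L, seed = 1L)
  rElems <- lapply(c("mdu", "unet"), function(v)
    crossValidate(tinyModelConfig(variant = v, depth = 1), d, k = 2, opt,
                  seed = 1, label = v))
  rows <- foldRows(rElems, dataset = "toy")
  expect_equal(nrow(rows), 4)
  expect_equal(names(rows),
               c("dataset", "model", "fold", "best_jaccard", "epoch"))
  expect_setequal(rows$model, c("mdu", "unet"))
  cmp <- comparisonTable(rElems[[1]], rElems[[2]], dataset = "toy")
  expect_equal(cmp$comparative_increase,
               rElems[[1]]@mean - rElems[[2]]@mean)
})
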