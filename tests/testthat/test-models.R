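# Model assembly: forward contracts, channel bookkeeping, parameter
# accounting against closed-form oracles, reproducibility, and the weight
# archive round trip.

test_that("a tiny model maps any admissible input to probabilities", {
  m <- buildModel(tinyModelConfig(depth = 1), inputSize = c(8, 8))
  set.seed(2)
  for (sz in list(c(8, 8), c(16, 12), c(6, 10))) {
    x <- array(stats::runif(prod(sz) * 2), c(sz, 1, 2))
    p <- predictModel(m, x)
    expect_equal(dim(p), c(sz, 2))
    expect_true(min(p) >= 0 && max(p) <= 1)
  }
  expect_error(predictModel(m, array(0, c(7, 8, 1, 1))), "divisible")
  expect_error(predictModel(m, array(0, c(8, 8, 3, 1))), "channels")
})

test_that("3D models honour the volumetric shape contract", {
  cfg <- tinyModelConfig(rank = 3, depth = 2, inChannels = 4)
  cfg@schedule <- scheduleConfig(mode = "formula",
                                 baseFilters = c(8, 16, 32))
  m <- buildModel(cfg, inputSize = c(20, 20, 12))
  x <- array(stats::runif(20 * 20 * 12 * 4), c(20, 20, 12, 4, 1))
  p <- predictModel(m, x)
  expect_equal(dim(p), c(20, 20, 12, 1))
  expect_true(min(p) >= 0 && max(p) <= 1)
  # full default 3D model admits the reference volume size symbolically
  full <- buildModel(modelConfig(rank = 3, variant = "mdu"),
                     inputSize = c(80, 80, 48))
  sh <- full@shapes[[full@output]]
  expect_equal(unname(sh), c(80, 80, 48, 1))
})

test_that("inference is deterministic and seeded builds are reproducible", {
  m <- buildModel(tinyModelConfig(seed = 42))
  set.seed(9)
  x <- array(stats::runif(8 * 8), c(8, 8, 1, 1))
  expect_identical(predictModel(m, x), predictModel(m, x))
  m2 <- buildModel(tinyModelConfig(seed = 42))   # fresh build, same seed
  expect_identical(m2@params, m@params)
  expect_identical(predictModel(m2, x), predictModel(m, x))
  m3 <- buildModel(tinyModelConfig(seed = 43))
  expect_false(identical(m3@params, m@params))
})

test_that("decoder concatenation widths follow the reference schedule", {
  # five-level 2D model: upsampled residual width + skip-path width
  m <- buildModel(modelConfig(rank = 2, variant = "mdu"),
                  inputSize = c(256, 256))
  expected <- c(51 + 32, 108 + 64, 216 + 128, 432 + 256)
  for (l in 1:4) {
    sh <- m@shapes[[sprintf("skipcat%d", l)]]
    expect_equal(unname(sh[length(sh)]), expected[l], info = paste("level", l))
  }
  # and the deepest concat splits as upsample 432 + path 256
  expect_equal(unname(m@shapes[["up4"]][3]), 432)
  expect_equal(unname(m@shapes[["path4.u1.out.relu"]][3]), 256)
})

test_that("parameter accounting matches closed-form conv/bn oracles", {
  # single conv layer: k^rank * Cin * Cout + Cout
  b <- newNetworkBuilder(2, 1)
  addConv(b, "input", 2, k = 3, activation = "none", bn = FALSE,
          name = "only")
  expect_equal(sum(vapply(b$params, length, numeric(1))), 1 * 2 * 9 + 2)

  # batch norm: 2C trainable, 4C with running statistics
  b2 <- newNetworkBuilder(2, 4)
  mducnn:::addBn(b2, "input", name = "bn0")
  expect_equal(sum(vapply(b2$params, length, numeric(1))), 8)
  expect_equal(sum(vapply(b2$state, length, numeric(1))), 8)

  # depth-1 baseline U-Net, widths (2, 4), one input channel, no BN:
  # closed-form sum of every convolution
  cfg <- tinyModelConfig(variant = "unet", depth = 1, batchNorm = FALSE)
  m <- buildModel(cfg)
  s <- countParameters(m)
  oracle <-
    (9 * 1 * 2 + 2) + (9 * 2 * 2 + 2) +       # encoder pair
    (9 * 2 * 4 + 4) + (9 * 4 * 4 + 4) +       # bottleneck pair
    (4 * 4 * 2 + 2) +                         # transposed conv 4 -> 2
    (9 * 4 * 2 + 2) + (9 * 2 * 2 + 2) +       # decoder pair (in 2+2)
    (1 * 2 * 1 + 1)                           # sigmoid head
  expect_equal(s@totalTrainable, oracle)
  expect_equal(s@totalAll, oracle)            # no BN, no running stats

  # per-layer rows always sum to the totals, and BN stats are 2C extra
  cfgBn <- tinyModelConfig(variant = "unet", depth = 1, batchNorm = TRUE)
  sBn <- countParameters(buildModel(cfgBn))
  expect_equal(sum(sBn@rows$trainable), sBn@totalTrainable)
  expect_equal(sBn@totalAll - sBn@totalTrainable, sum(sBn@rows$running))
})

test_that("parameter totals equal a brute-force enumeration of arrays", {
  for (variant in c("mdu", "unet", "blocks", "paths")) {
    m <- buildModel(tinyModelConfig(variant = variant, depth = 2))
    s <- countParameters(m)
    expect_equal(s@totalTrainable,
                 sum(vapply(m@params, length, numeric(1))),
                 info = variant)
    expect_equal(s@totalAll - s@totalTrainable,
                 sum(vapply(m@state, length, numeric(1))),
                 info = variant)
  }
})

test_that("matched configurations keep the proposed model under the baseline", {
  for (depth in 1:2) {
    base <- c(16, 32, 64)[seq_len(depth + 1)]
    mdu <- buildModel(modelConfig(rank = 2, variant = "mdu", depth = depth,
      inChannels = 1,
      schedule = scheduleConfig(mode = "formula", baseFilters = base),
      seed = 1))
    unet <- buildModel(modelConfig(rank = 2, variant = "unet", depth = depth,
      inChannels = 1, stageWidths = base, seed = 1))
    expect_lt(countParameters(mdu)@totalTrainable,
              countParameters(unet)@totalTrainable)
  }
})

test_that("weights survive a save/load round trip exactly", {
  m <- buildModel(tinyModelConfig(seed = 7))
  set.seed(1)
  x <- array(stats::runif(8 * 8), c(8, 8, 1, 1))
  before <- predictModel(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  saveWeights(m, path)
  m2 <- buildModel(tinyModelConfig(seed = 99))   # different init
  m2 <- loadWeights(m2, path)
  expect_identical(m2@params, m@params)
  expect_identical(predictModel(m2, x), before)
})

test_that("weight loading is guarded against mismatch and corruption", {
  m <- buildModel(tinyModelConfig(seed = 7))
  path <- withr::local_tempfile(fileext = ".rds")
  saveWeights(m, path)
  other <- buildModel(tinyModelConfig(depth = 2, seed = 7))
  expect_error(loadWeights(other, path), "depth")
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a weight archive", bad)
  expect_error(loadWeights(m, bad), "cannot read|archive")
  before <- m@params
  try(loadWeights(m, bad), silent = TRUE)
  expect_identical(m@params, before)   # model untouched on failure
})

test_that("model summary and configuration exports round-trip", {
  m <- buildModel(tinyModelConfig())
  s <- countParameters(m)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeModelSummary(s, csv)
  writeModelSummary(s, js)
  back <- utils::read.csv(csv)
  expect_equal(sum(back$trainable), s@totalTrainable)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$total_trainable, s@totalTrainable)

  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg <- tinyModelConfig(variant = "unet", depth = 2)
  modelConfigToYaml(cfg, yml)
  cfg2 <- modelConfigFromYaml(yml)
  expect_equal(cfg2@depth, cfg@depth)
  expect_equal(cfg2@variant, cfg@variant)
  expect_equal(countParameters(buildModel(cfg2))@totalTrainable,
               countParameters(buildModel(cfg))@totalTrainable)
})
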