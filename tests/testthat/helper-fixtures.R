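# Shared fixtures: all data are generated in code at test time.

tinySchedule <- function(levels = 2)
  scheduleConfig(mode = "formula", baseFilters = 8 * 2^(seq_len(levels) - 1))

tinyModelConfig <- function(rank = 2, variant = "mdu", depth = 1,
                            inChannels = 1, seed = 1, batchNorm = TRUE)
  modelConfig(rank = rank, variant = variant, depth = depth,
              inChannels = inChannels, schedule = tinySchedule(depth + 1),
              stageWidths = c(2, 4, 8, 16)[seq_len(depth + 1)],
              batchNorm = batchNorm, seed = seed)

tinyDataset <- function(n = 6, size = 16, seed = 5, preset = "fluorescence")
  generateSynthetic2d(syntheticConfig(preset, nImages = n, size = size,
                                      channels = 1, seed = seed))

randomMask <- function(size, p = 0.4) {
  m <- array(0, size)
  m[stats::runif(prod(size)) < p] <- 1
  m
}

# independent set-based Jaccard oracle: enumerates pixel index sets
jaccardOracle <- function(x, y) {
  xs <- which(x != 0)
  ys <- which(y != 0)
  u <- union(xs, ys)
  if (length(u) == 0) return(1)
  length(intersect(xs, ys)) / length(u)
}
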