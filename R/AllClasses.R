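#' @import methods
NULL

#' Filter-width schedule configuration
#'
#' Describes how per-level filter widths of a multi-dimensional U-shaped
#' network are derived. The level width is \eqn{M = \beta F_n}, where
#' \eqn{F_n} is the baseline U-Net width of level \eqn{n}; \eqn{M} is then
#' split across the block's three chained 3x3 convolutions according to
#' `fractions` (default 1/6, 1/3, 1/2). Two modes exist: `"formula"`
#' applies this rule directly, `"table_literal"` returns the fixed
#' five-level reference schedule (see [tableLiteralSchedule()]).
#'
#' @slot beta positive scale factor applied to the baseline widths
#'   (default 1.56, chosen so the resulting model stays smaller than the
#'   baseline U-Net it replaces).
#' @slot baseFilters integer vector of per-level baseline widths, strictly
#'   increasing and doubling per level (default 32, 64, 128, 256, 512).
#' @slot fractions numeric triple of allocation fractions summing to 1.
#' @slot rounding one of `"floor"`, `"ceil"`, `"nearest"`.
#' @slot mode one of `"table_literal"`, `"formula"`.
#' @exportClass ScheduleConfig
setClass("ScheduleConfig",
  representation(beta = "numeric", baseFilters = "numeric",
                 fractions = "numeric", rounding = "character",
                 mode = "character"),
  prototype(beta = 1.56, baseFilters = c(32, 64, 128, 256, 512),
            fractions = c(1 / 6, 1 / 3, 1 / 2), rounding = "floor",
            mode = "table_literal"))

setValidity("ScheduleConfig", function(object) {
  msg <- character()
  if (length(object@beta) != 1 || !is.finite(object@beta) || object@beta <= 0)
    msg <- c(msg, "beta must be a single positive number")
  bf <- object@baseFilters
  if (length(bf) < 1 || any(bf < 1) || any(bf != round(bf)))
    msg <- c(msg, "baseFilters must be positive integers")
  if (length(bf) > 1) {
    if (any(diff(bf) <= 0))
      msg <- c(msg, "baseFilters must be strictly increasing")
    if (any(bf[-1] != 2 * bf[-length(bf)]))
      msg <- c(msg, "each baseFilters level must double the previous")
  }
  if (length(object@fractions) != 3 ||
      abs(sum(object@fractions) - 1) > 1e-12)
    msg <- c(msg, "fractions must be a triple summing to 1 exactly")
  if (!object@rounding %in% c("floor", "ceil", "nearest"))
    msg <- c(msg, "rounding must be floor, ceil or nearest")
  if (!object@mode %in% c("table_literal", "formula"))
    msg <- c(msg, "mode must be table_literal or formula")
  if (length(msg)) msg else TRUE
})

#' Per-level filter allocation of a multi-dimensional block
#'
#' The three chained 3x3 convolutions of a block receive `conv3Filters`
#' (non-decreasing) filters; the residual 1x1 projection receives
#' `res1Filters`, which must equal the triple sum so the projection can be
#' added to the concatenated chain outputs. `printedRes1` optionally records
#' a published 1x1 width that differs from the triple sum; it is metadata
#' only and never used for construction.
#'
#' @slot level 1-based level index from the shallowest level.
#' @slot M real level width the allocation was derived from.
#' @slot conv3Filters integer triple (n1, n2, n3), non-decreasing.
#' @slot res1Filters integer, equal to `sum(conv3Filters)`.
#' @slot printedRes1 integer or NA; published 1x1 width when it differs.
#' @exportClass LevelAllocation
setClass("LevelAllocation",
  representation(level = "integer", M = "numeric", conv3Filters = "integer",
                 res1Filters = "integer", printedRes1 = "integer"),
  prototype(level = 1L, printedRes1 = NA_integer_))

setValidity("LevelAllocation", function(object) {
  msg <- character()
  f <- object@conv3Filters
  if (length(f) != 3 || any(f < 1))
    msg <- c(msg, "conv3Filters must be a triple of counts >= 1")
  if (length(f) == 3 && any(diff(f) < 0))
    msg <- c(msg, "conv3Filters must be non-decreasing (n1 <= n2 <= n3)")
  if (length(object@res1Filters) != 1 || object@res1Filters != sum(f))
    msg <- c(msg, "res1Filters must equal n1 + n2 + n3 (addition compatibility)")
  if (length(msg)) msg else TRUE
})

#' Residual skip-path plan
#'
#' One entry per skip level: `unitCounts[l]` residual convolution units are
#' chained along the skip connection of level `l`, each using
#' `unitWidths[l]` filters for both its 3x3 convolution and its 1x1
#' shortcut. Shallow skips carry more units (largest semantic gap); the
#' deepest skip carries one.
#'
#' @slot unitCounts integer vector, strictly decreasing, all >= 1.
#' @slot unitWidths integer vector, doubling per level.
#' @exportClass PathPlan
setClass("PathPlan",
  representation(unitCounts = "integer", unitWidths = "integer"))

setValidity("PathPlan", function(object) {
  msg <- character()
  u <- object@unitCounts; w <- object@unitWidths
  if (length(u) != length(w))
    msg <- c(msg, "unitCounts and unitWidths must have equal length")
  if (any(u < 1)) msg <- c(msg, "unitCounts must all be >= 1")
  if (length(u) > 1 && any(diff(u) >= 0))
    msg <- c(msg, "unitCounts must strictly decrease with depth")
  if (length(w) > 1 && any(w[-1] != 2 * w[-length(w)]))
    msg <- c(msg, "unitWidths must double per level")
  if (length(msg)) msg else TRUE
})

#' Model configuration
#'
#' Recipe for a segmentation network. `variant` selects the architecture:
#' `"mdu"` (multi-dimensional blocks + residual skip paths), `"unet"`
#' (classical baseline), `"blocks"` (multi-dimensional blocks with plain
#' skips) and `"paths"` (classical conv pairs with residual skip paths);
#' the last two are the ablation variants.
#'
#' @slot rank spatial rank, 2 or 3.
#' @slot depth number of pooling steps (block levels = depth + 1).
#' @slot inChannels input channels (3 for RGB 2D imagery, 4 for
#'   multi-modality MRI volumes).
#' @slot outClasses fixed at 1 (binary segmentation head).
#' @slot variant one of `"mdu"`, `"unet"`, `"blocks"`, `"paths"`.
#' @slot schedule a [ScheduleConfig-class] (block-based variants).
#' @slot stageWidths per-level widths for the classical conv pairs
#'   (`"unet"`/`"paths"` variants); length `depth + 1`.
#' @slot pathUnits,pathWidths residual skip-path plan overrides; `NA` means
#'   "derive the default" (counts depth..1, widths = base filters).
#' @slot batchNorm logical; batch-normalize every convolution.
#' @slot seed integer seed for weight initialization.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(rank = "integer", depth = "integer", inChannels = "integer",
                 outClasses = "integer", variant = "character",
                 schedule = "ScheduleConfig", stageWidths = "numeric",
                 pathUnits = "integer", pathWidths = "integer",
                 batchNorm = "logical", seed = "integer"),
  prototype(rank = 2L, depth = 4L, inChannels = 3L, outClasses = 1L,
            variant = "mdu", stageWidths = c(16, 32, 64, 128, 256, 512),
            pathUnits = NA_integer_, pathWidths = NA_integer_,
            batchNorm = TRUE, seed = 1L))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@rank %in% c(2L, 3L)) msg <- c(msg, "rank must be 2 or 3")
  if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
  if (object@outClasses != 1L)
    msg <- c(msg, "outClasses is fixed at 1 (binary segmentation)")
  if (!object@variant %in% c("mdu", "unet", "blocks", "paths"))
    msg <- c(msg, "variant must be one of mdu, unet, blocks, paths")
  if (object@inChannels < 1) msg <- c(msg, "inChannels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A constructed trainable network
#'
#' Opaque handle returned by [buildModel()] and friends: the layer graph in
#' topological order, the parameter arrays, batch-normalization running
#' statistics, and the configuration the network was built from. Use
#' [countParameters()] for the per-layer summary and [predictModel()] for
#' inference.
#'
#' @slot config the [ModelConfig-class] used for construction.
#' @slot nodes layer graph (list of node descriptors, topological order).
#' @slot params named list of numeric parameter arrays.
#' @slot state named list of batch-norm running statistics.
#' @slot output name of the output node.
#' @slot shapes reference shapes per node (channels; spatial when known).
#' @exportClass BuiltModel
setClass("BuiltModel",
  representation(config = "ModelConfig", nodes = "list", params = "list",
                 state = "list", output = "character", shapes = "list"))

#' Synthetic dataset configuration
#'
#' Seeded generator settings for the five difficulty presets. The same
#' seed and configuration always reproduce the identical dataset, and every
#' emitted mask is the exact pre-blur object geometry (ground truth is
#' exact by construction).
#'
#' @slot preset one of `"fluorescence"`, `"endoscopy"`, `"dermoscopy"`,
#'   `"electron"`, `"mri3d"`.
#' @slot nImages number of samples to generate.
#' @slot size per-axis spatial extents.
#' @slot objectsPerImage integer range (min, max) of foreground objects.
#' @slot contrast foreground-background intensity gap in \[0, 1\].
#' @slot boundaryBlurSigma Gaussian blur (pixels) applied to the rendered
#'   image (never the mask).
#' @slot noiseSd additive Gaussian intensity noise.
#' @slot debrisCount non-foreground distractor objects (fluorescence).
#' @slot channels image channels (4 for `mri3d`).
#' @slot seed integer seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(preset = "character", nImages = "integer", size = "integer",
                 objectsPerImage = "integer", contrast = "numeric",
                 boundaryBlurSigma = "numeric", noiseSd = "numeric",
                 debrisCount = "integer", channels = "integer",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (!object@preset %in%
      c("fluorescence", "endoscopy", "dermoscopy", "electron", "mri3d"))
    msg <- c(msg, "unknown preset")
  if (object@nImages < 1) msg <- c(msg, "nImages must be >= 1")
  if (any(object@size < 16))
    msg <- c(msg, "size must be >= 16 along every axis")
  if (object@preset == "mri3d" && object@channels != 4L)
    msg <- c(msg, "mri3d preset requires channels = 4")
  if (length(msg)) msg else TRUE
})

#' Augmentation configuration
#'
#' @slot hflip,vflip allow horizontal / vertical flips.
#' @slot rotations right-angle rotations (degrees) to sample from.
#' @slot factor integer dataset multiplier; the augmented set has exactly
#'   `factor` times the original size (default 3).
#' @slot seed integer seed for the per-sample transform draws.
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(hflip = "logical", vflip = "logical", rotations = "integer",
                 factor = "integer", seed = "integer"),
  prototype(hflip = TRUE, vflip = TRUE, rotations = c(90L, 180L, 270L),
            factor = 3L, seed = 1L))

setValidity("AugmentConfig", function(object) {
  if (object@factor < 1) "factor must be >= 1" else TRUE
})

#' Optimizer configuration
#'
#' Adaptive moment estimation over mini-batches of the pixelwise binary
#' cross-entropy loss. `alpha1` and `alpha2` are the decay rates of the
#' first and second gradient moments.
#'
#' @slot learningRate step size (default 1e-3).
#' @slot alpha1,alpha2 moment decay rates (defaults 0.9, 0.999).
#' @slot batchSize mini-batch size.
#' @slot epochs training epochs (default 150).
#' @slot seed integer seed for shuffling.
#' @exportClass OptimizerConfig
setClass("OptimizerConfig",
  representation(learningRate = "numeric", alpha1 = "numeric",
                 alpha2 = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer"),
  prototype(learningRate = 1e-3, alpha1 = 0.9, alpha2 = 0.999,
            batchSize = 8L, epochs = 150L, seed = 1L))

setValidity("OptimizerConfig", function(object) {
  msg <- character()
  if (object@alpha1 <= 0 || object@alpha1 >= 1 ||
      object@alpha2 <= 0 || object@alpha2 >= 1)
    msg <- c(msg, "alpha1 and alpha2 must lie strictly in (0, 1)")
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' k-fold partition of a dataset
#'
#' @slot k number of folds.
#' @slot n dataset size.
#' @slot folds list of k disjoint index vectors covering 1..n whose sizes
#'   differ by at most one.
#' @slot seed seed used for the shuffle.
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(k = "integer", n = "integer", folds = "list",
                 seed = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  all_idx <- sort(unlist(object@folds))
  if (!identical(all_idx, seq_len(object@n)))
    msg <- c(msg, "folds must disjointly cover 1..n")
  sizes <- lengths(object@folds)
  if (length(sizes) != object@k) msg <- c(msg, "must have exactly k folds")
  if (max(sizes) - min(sizes) > 1)
    msg <- c(msg, "fold sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' Per-layer parameter summary of a built model
#'
#' @slot rows data.frame with one row per parameterised layer: name, kind,
#'   output channels, trainable parameter count, and non-trainable count
#'   (batch-norm running statistics).
#' @slot totalTrainable sum of trainable parameter counts.
#' @slot totalAll trainable plus batch-norm running statistics.
#' @exportClass ModelSummary
setClass("ModelSummary",
  representation(rows = "data.frame", totalTrainable = "numeric",
                 totalAll = "numeric"))

setValidity("ModelSummary", function(object) {
  msg <- character()
  if (object@totalTrainable < 0 || object@totalAll < object@totalTrainable)
    msg <- c(msg, "totals must be non-negative and totalAll >= totalTrainable")
  if (nrow(object@rows) &&
      sum(object@rows$trainable) != object@totalTrainable)
    msg <- c(msg, "per-layer rows must sum to totalTrainable")
  if (length(msg)) msg else TRUE
})
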