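# Model assembly: the full multi-dimensional U-shaped network, the matched
# baseline U-Net, and the two ablation variants; parameter accounting,
# inference, and weight archive IO.

#' Create a model configuration
#'
#' Defaults follow the reference study: the 2D multi-dimensional model uses
#' 4 pooling steps (5 block levels) with the five-level reference schedule
#' and 3 input channels; the 3D variant reduces depth by one and takes 4
#' input channels (one per MRI modality); the baseline 2D U-Net uses 5
#' pooling steps with stage widths 16..512.
#'
#' @param rank spatial rank (2 or 3).
#' @param variant `"mdu"`, `"unet"`, `"blocks"` (multi-dimensional blocks,
#'   plain skips) or `"paths"` (classical conv pairs, residual skip paths).
#' @param depth number of pooling steps; `NULL` picks the variant default.
#' @param inChannels input channels; `NULL` picks 3 (2D) or 4 (3D).
#' @param schedule a [ScheduleConfig-class] for block-based variants;
#'   `NULL` picks the reference schedule (2D) or the formula schedule over
#'   base filters 32..256 (3D).
#' @param stageWidths per-level conv-pair widths for `"unet"`/`"paths"`.
#' @param pathUnits,pathWidths skip-path plan overrides (see [pathPlan()]).
#' @param batchNorm batch-normalize convolutions (default TRUE).
#' @param seed weight-initialization seed.
#' @return a [ModelConfig-class].
#' @examples
#' modelConfig(rank = 2, variant = "mdu")
#' @export
modelConfig <- function(rank = 2, variant = "mdu", depth = NULL,
                        inChannels = NULL, schedule = NULL,
                        stageWidths = NULL, pathUnits = NULL,
                        pathWidths = NULL, batchNorm = TRUE, seed = 1) {
  rank <- as.integer(rank)
  blockBased <- variant %in% c("mdu", "blocks")
  if (is.null(depth))
    depth <- if (blockBased) {
      if (rank == 2) 4L else 3L
    } else {
      if (rank == 2) 5L else 4L
    }
  if (is.null(inChannels)) inChannels <- if (rank == 2) 3L else 4L
  if (is.null(schedule))
    schedule <- if (rank == 2 && depth == 4L)
      scheduleConfig()
    else
      scheduleConfig(mode = "formula",
                     baseFilters = 32 * 2^(seq_len(depth + 1) - 1))
  if (is.null(stageWidths))
    stageWidths <- if (rank == 2) c(16, 32, 64, 128, 256, 512)
                   else c(32, 64, 128, 256, 512)
  if (length(stageWidths) < depth + 1 && !blockBased)
    stopf("stageWidths needs %d entries for depth %d", depth + 1, depth)
  new("ModelConfig", rank = rank, depth = as.integer(depth),
      inChannels = as.integer(inChannels), outClasses = 1L,
      variant = variant, schedule = schedule,
      stageWidths = as.numeric(stageWidths),
      pathUnits = if (is.null(pathUnits)) NA_integer_
                  else as.integer(pathUnits),
      pathWidths = if (is.null(pathWidths)) NA_integer_
                   else as.integer(pathWidths),
      batchNorm = isTRUE(batchNorm), seed = as.integer(seed))
}

# Resolve the skip-path plan for a config (counts depth..1 by default;
# widths default to the schedule base filters / stage widths).
resolvePathPlan <- function(config) {
  depth <- config@depth
  widths <- if (!anyNA(config@pathWidths)) config@pathWidths
            else if (config@variant %in% c("mdu", "blocks"))
              config@schedule@baseFilters[seq_len(depth)]
            else config@stageWidths[seq_len(depth)]
  if (!anyNA(config@pathUnits)) {
    if (length(config@pathUnits) != depth)
      stopf("pathUnits must have %d entries", depth)
    new("PathPlan", unitCounts = config@pathUnits,
        unitWidths = as.integer(widths))
  } else {
    pathPlan(depth, widths)
  }
}

#' Build a segmentation network
#'
#' Assembles the encoder-decoder network described by `config`:
#' encoder levels (block, then 2x max pool), a bottleneck block, and a
#' decoder that upsamples by stride-2 transposed convolution, concatenates
#' the level's skip features and applies the level block again; a final
#' 1x1 convolution with sigmoid activation produces the per-pixel
#' foreground probability. `buildMduCnn` and `buildBaselineUnet` are
#' convenience wrappers fixing the variant.
#'
#' For block-based variants the transposed convolution outputs the target
#' level's residual width (keeping decoder block inputs aligned with the
#' schedule); for the classical variants it halves channels down to the
#' target stage width.
#'
#' @param config a [ModelConfig-class].
#' @param inputSize optional reference spatial extents (divisible by
#'   `2^depth`) used for shape bookkeeping and build-time validation.
#' @return a [BuiltModel-class].
#' @examples
#' m <- buildModel(modelConfig(rank = 2, variant = "mdu",
#'   schedule = scheduleConfig(mode = "formula", baseFilters = c(8, 16)),
#'   depth = 1, inChannels = 1))
#' @export
buildModel <- function(config, inputSize = NULL) {
  validObject(config)
  depth <- config@depth
  levels <- depth + 1L
  blockBased <- config@variant %in% c("mdu", "blocks")
  withPaths <- config@variant %in% c("mdu", "paths")
  if (!is.null(inputSize)) {
    if (length(inputSize) != config@rank)
      stopf("inputSize must have %d extents", config@rank)
    if (any(inputSize %% 2^depth != 0))
      stopf("spatial extents (%s) must be divisible by 2^depth = %d",
            paste(inputSize, collapse = ", "), 2^depth)
  }
  allocs <- NULL
  widths <- NULL
  if (blockBased) {
    allocs <- scheduleLevels(config@schedule, levels)
  } else {
    if (length(config@stageWidths) < levels)
      stopf("stageWidths needs %d entries for depth %d", levels, depth)
    widths <- as.integer(config@stageWidths[seq_len(levels)])
  }
  plan <- if (withPaths) resolvePathPlan(config) else NULL

  withSeed(config@seed, {
    b <- newNetworkBuilder(config@rank, config@inChannels,
                           inputSize = inputSize,
                           batchNorm = config@batchNorm)
    levelBlock <- function(input, l, tag) {
      if (blockBased)
        addMultidimBlock(b, input, allocs[[l]],
                         name = sprintf("%s%d.block", tag, l))
      else {
        c1 <- addConv(b, input, widths[l], k = 3,
                      name = sprintf("%s%d.conv_a", tag, l))
        addConv(b, c1, widths[l], k = 3,
                name = sprintf("%s%d.conv_b", tag, l))
      }
    }
    cur <- "input"
    skips <- character(depth)
    for (l in seq_len(depth)) {
      enc <- levelBlock(cur, l, "enc")
      skips[l] <- if (withPaths)
        addSkipPath(b, enc, plan@unitCounts[l], plan@unitWidths[l],
                    name = sprintf("path%d", l))
      else enc
      cur <- addDownsample(b, enc, name = sprintf("pool%d", l))
    }
    cur <- levelBlock(cur, levels, "mid")
    for (l in rev(seq_len(depth))) {
      upCh <- if (blockBased) allocs[[l]]@res1Filters else widths[l]
      up <- addUpsample(b, cur, upCh, name = sprintf("up%d", l))
      cat_ <- addConcat(b, c(up, skips[l]), name = sprintf("skipcat%d", l))
      cur <- levelBlock(cat_, l, "dec")
    }
    out <- addConv(b, cur, config@outClasses, k = 1,
                   activation = "sigmoid", bn = FALSE, name = "head")
    new("BuiltModel", config = config, nodes = b$nodes, params = b$params,
        state = b$state, output = out, shapes = b$shapes)
  })
}

#' @rdname buildModel
#' @param ... forwarded to [modelConfig()].
#' @export
buildMduCnn <- function(config = modelConfig(variant = "mdu", ...),
                        inputSize = NULL, ...) {
  if (config@variant != "mdu") stopf("config variant must be 'mdu'")
  buildModel(config, inputSize)
}

#' @rdname buildModel
#' @export
buildBaselineUnet <- function(config = modelConfig(variant = "unet", ...),
                              inputSize = NULL, ...) {
  if (config@variant != "unet") stopf("config variant must be 'unet'")
  buildModel(config, inputSize)
}

# ------------------------------------------------------------ summary ----

#' Per-layer parameter accounting
#'
#' Sums every trainable array of the model: for a convolution with kernel
#' extent k, `k^rank * Cin * Cout` weights plus `Cout` biases; for a batch
#' normalization, `2C` trainable (scale, shift). `totalAll` additionally
#' counts the `2C` running statistics each batch normalization tracks.
#'
#' @param model a [BuiltModel-class].
#' @return a [ModelSummary-class]; its `rows` slot lists every
#'   parameterised layer.
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "BuiltModel"))
  rows <- list()
  for (node in model@nodes) {
    nm <- node$name
    all_p <- names(model@params)
    pref <- paste0(nm, ".")
    pnames <- all_p[startsWith(all_p, pref) &
                    substring(all_p, nchar(pref) + 1) %in%
                      c("w", "b", "gamma", "beta")]
    if (!length(pnames)) next
    trainable <- sum(vapply(model@params[pnames], length, numeric(1)))
    running <- if (node$op == "bn")
      length(model@state[[paste0(nm, ".mean")]]) +
      length(model@state[[paste0(nm, ".var")]]) else 0
    sh <- model@shapes[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, kind = node$op,
      output = paste(sh, collapse = "x"),
      trainable = trainable, running = running,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  new("ModelSummary", rows = rows,
      totalTrainable = sum(rows$trainable),
      totalAll = sum(rows$trainable) + sum(rows$running))
}

#' Write a model summary to CSV or JSON
#'
#' @param summary a [ModelSummary-class].
#' @param path output path; format chosen by extension (`.csv` / `.json`).
#' @return `path`, invisibly.
#' @export
writeModelSummary <- function(summary, path) {
  stopifnot(is(summary, "ModelSummary"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(layers = summary@rows,
           total_trainable = summary@totalTrainable,
           total_all = summary@totalAll),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(summary@rows, path, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------- inference ----

#' Forward inference
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the per-pixel foreground probabilities, guaranteed to lie in
#' \[0, 1\] by the sigmoid output.
#'
#' @param model a [BuiltModel-class].
#' @param batch array `(spatial..., channels, n)` or a single image
#'   `(spatial..., channels)`; spatial extents must be divisible by
#'   `2^depth` and channels must match the configuration.
#' @return probability array `(spatial..., n)`.
#' @export
predictModel <- function(model, batch) {
  stopifnot(is(model, "BuiltModel"))
  rank <- model@config@rank
  d <- dim(batch)
  if (is.null(d) || !length(d) %in% c(rank + 1L, rank + 2L))
    stopf("batch must be an array (spatial x channels [x n]) of rank %d",
          rank)
  if (length(d) == rank + 1L) dim(batch) <- c(d, 1L)
  d <- dim(batch)
  sp <- d[seq_len(rank)]
  if (d[rank + 1] != model@config@inChannels)
    stopf("batch has %d channels, model expects %d", d[rank + 1],
          model@config@inChannels)
  if (any(sp %% 2^model@config@depth != 0))
    stopf("spatial extents (%s) not divisible by 2^depth = %d",
          paste(sp, collapse = ", "), 2^model@config@depth)
  fw <- nnForward(model@nodes, model@params, model@state, batch, rank,
                  training = FALSE)
  out <- fw$vals[[model@output]]
  dim(out) <- c(sp, dim(out)[rank + 2])
  out
}

# ------------------------------------------------------------- weights ----

#' Save / load model weights
#'
#' `saveWeights` writes a single-file archive holding the configuration,
#' every parameter array and the batch-norm running statistics.
#' `loadWeights` restores them into a compatible model: the stored
#' configuration must match in rank, depth and variant and every parameter
#' array must agree in name and shape, otherwise an error is raised and
#' `model` is left untouched. The round trip is exact: predictions before
#' and after are identical.
#'
#' @param model a [BuiltModel-class].
#' @param path archive path.
#' @return `saveWeights`: `path`, invisibly. `loadWeights`: the model with
#'   restored weights.
#' @export
saveWeights <- function(model, path) {
  stopifnot(is(model, "BuiltModel"))
  saveRDS(list(format = "mducnn-weights", version = 1L,
               config = model@config, params = model@params,
               state = model@state),
          path)
  invisible(path)
}

#' @rdname saveWeights
#' @export
loadWeights <- function(model, path) {
  stopifnot(is(model, "BuiltModel"))
  obj <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read weight archive '%s': %s", path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "mducnn-weights"))
    stopf("'%s' is not a weight archive", path)
  oc <- obj$config
  mc <- model@config
  if (oc@rank != mc@rank || oc@depth != mc@depth ||
      oc@variant != mc@variant || oc@inChannels != mc@inChannels)
    stopf(paste0("weight archive was built for rank=%d depth=%d variant=%s ",
                 "in=%d; model is rank=%d depth=%d variant=%s in=%d"),
          oc@rank, oc@depth, oc@variant, oc@inChannels,
          mc@rank, mc@depth, mc@variant, mc@inChannels)
  if (!identical(names(obj$params), names(model@params)))
    stopf("weight archive parameter names do not match the model")
  for (nm in names(obj$params))
    if (!identical(dim(obj$params[[nm]]), dim(model@params[[nm]])) &&
        !identical(length(obj$params[[nm]]), length(model@params[[nm]])))
      stopf("parameter '%s' shape mismatch", nm)
  model@params <- obj$params
  model@state <- obj$state
  model
}

#' @describeIn BuiltModel-class compact display
#' @param object a `BuiltModel`
#' @export
setMethod("show", "BuiltModel", function(object) {
  s <- countParameters(object)
  cat(sprintf("BuiltModel: %s, rank %d, depth %d, in=%d\n",
              object@config@variant, object@config@rank,
              object@config@depth, object@config@inChannels))
  cat(sprintf("  %d nodes, %s trainable parameters (%s incl. BN stats)\n",
              length(object@nodes),
              format(s@totalTrainable, big.mark = ","),
              format(s@totalAll, big.mark = ",")))
})

#' @describeIn ModelSummary-class compact display
#' @param object a `ModelSummary`
#' @export
setMethod("show", "ModelSummary", function(object) {
  cat(sprintf("ModelSummary: %d layers, trainable %s, with BN stats %s\n",
              nrow(object@rows),
              format(object@totalTrainable, big.mark = ","),
              format(object@totalAll, big.mark = ",")))
})

#' Export / import a model configuration as YAML
#'
#' @param config a [ModelConfig-class].
#' @param path file path.
#' @export
modelConfigToYaml <- function(config, path) {
  s <- config@schedule
  yaml::write_yaml(list(
    rank = config@rank, variant = config@variant, depth = config@depth,
    in_channels = config@inChannels, batch_norm = config@batchNorm,
    seed = config@seed,
    stage_widths = as.integer(config@stageWidths),
    schedule = list(beta = s@beta, base_filters = as.integer(s@baseFilters),
                    rounding = s@rounding, mode = s@mode)), path)
  invisible(path)
}

#' @rdname modelConfigToYaml
#' @export
modelConfigFromYaml <- function(path) {
  o <- yaml::read_yaml(path)
  modelConfig(rank = o$rank, variant = o$variant, depth = o$depth,
              inChannels = o$in_channels,
              schedule = scheduleConfig(beta = o$schedule$beta,
                                        baseFilters = o$schedule$base_filters,
                                        rounding = o$schedule$rounding,
                                        mode = o$schedule$mode),
              stageWidths = o$stage_widths, batchNorm = o$batch_norm,
              seed = o$seed)
}
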