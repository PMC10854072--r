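# Training/evaluation protocol: k-fold cross-validation with per-epoch
# test-set Jaccard tracking ("best on test" over the epoch budget, the
# reference protocol, which peeks at the test set by design and is flagged
# as such in reports), ablation variants and the augmentation study.

#' Per-fold training result
#'
#' @slot fold fold index (0 for a plain train/test run).
#' @slot records data.frame with one row per epoch: `epoch`, `loss`
#'   (mean training batch loss), `jaccard` (mean test Jaccard, percent).
#' @slot bestJaccard maximum test Jaccard over the epochs, percent.
#' @slot bestEpoch epoch attaining it.
#' @exportClass FoldResult
setClass("FoldResult",
  representation(fold = "integer", records = "data.frame",
                 bestJaccard = "numeric", bestEpoch = "integer"))

setValidity("FoldResult", function(object) {
  msg <- character()
  if (nrow(object@records)) {
    if (abs(max(object@records$jaccard) - object@bestJaccard) > 1e-9)
      msg <- c(msg, "bestJaccard must be the maximum of the epoch records")
    if (object@bestEpoch < 1 || object@bestEpoch > max(object@records$epoch))
      msg <- c(msg, "bestEpoch out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation report for one model
#'
#' @slot model label of the evaluated model.
#' @slot protocol evaluation protocol (`"best-on-test"`).
#' @slot folds list of [FoldResult-class], one per fold.
#' @slot mean,sd aggregate of the per-fold best Jaccard percentages
#'   (sample standard deviation, n - 1).
#' @exportClass CVReport
setClass("CVReport",
  representation(model = "character", protocol = "character",
                 folds = "list", mean = "numeric", sd = "numeric"))

#' Partition indices into k folds
#'
#' Seeded shuffle followed by contiguous slicing; fold sizes differ by at
#' most one, with remainders assigned to the earliest folds.
#'
#' @param n dataset size.
#' @param k number of folds, `2 <= k <= n`; `k = n` is leave-one-out.
#' @param seed shuffle seed.
#' @return a [FoldAssignment-class].
#' @examples
#' kfoldSplit(11, 5, seed = 1)   # fold sizes 3,2,2,2,2
#' @export
kfoldSplit <- function(n, k, seed = 1) {
  if (!isCount(n)) stopf("kfoldSplit: n must be a positive integer")
  if (!isCount(k) || k < 2 || k > n)
    stopf("kfoldSplit: k must satisfy 2 <= k <= n (got k=%s, n=%s)", k, n)
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
  new("FoldAssignment", k = as.integer(k), n = as.integer(n),
      folds = folds, seed = as.integer(seed))
}

evalJaccard <- function(model, samples, batchSize, threshold = 0.5) {
  js <- numeric(length(samples))
  i <- 1L
  while (i <= length(samples)) {
    idx <- i:min(i + batchSize - 1L, length(samples))
    x <- stackImages(samples[idx])
    p <- predictModel(model, x)
    rank <- model@config@rank
    for (j in seq_along(idx)) {
      pj <- if (rank == 2) p[, , j] else p[, , , j]
      js[idx[j]] <- jaccard(samples[[idx[j]]]$mask, binarize(pj, threshold))
    }
    i <- i + batchSize
  }
  mean(js)
}

#' Train a model, tracking the best test-set Jaccard
#'
#' Minimizes the mean pixelwise binary cross-entropy over mini-batches
#' with adaptive moment estimation; after every epoch the mean per-image
#' test Jaccard (threshold 0.5) is recorded, and the maximum over all
#' epochs is reported (the best-on-test protocol). Identical seeds, data
#' and configuration reproduce identical epoch records.
#'
#' @param model a [BuiltModel-class] (freshly built or pre-trained).
#' @param train,test non-empty sample lists.
#' @param opt an [OptimizerConfig-class].
#' @param fold fold index recorded on the result.
#' @param verbose emit a per-epoch line on stderr.
#' @return list with `result` (a [FoldResult-class]) and `model` (the
#'   trained model).
#' @export
trainModel <- function(model, train, test, opt = new("OptimizerConfig"),
                       fold = 0L, verbose = FALSE) {
  stopifnot(is(model, "BuiltModel"))
  validObject(opt)
  if (!length(train) || !length(test))
    stopf("trainModel: train and test must be non-empty")
  rank <- model@config@rank
  params <- model@params
  state <- model@state
  ad <- adamInit(params)
  records <- data.frame(epoch = integer(), loss = numeric(),
                        jaccard = numeric())
  nTr <- length(train)
  withSeed(opt@seed, {
    for (epoch in seq_len(opt@epochs)) {
      ord <- sample.int(nTr)
      losses <- c()
      b0 <- 1L
      while (b0 <= nTr) {
        idx <- ord[b0:min(b0 + opt@batchSize - 1L, nTr)]
        x <- stackImages(train[idx])
        y <- stackMasks(train[idx])
        fw <- nnForward(model@nodes, params, state, x, rank,
                        training = TRUE)
        state <- fw$state
        p <- fw$vals[[model@output]]
        pc <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
        npix <- prod(dim(p)[seq_len(rank)])
        m <- length(idx)
        loss <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / (npix * m)
        if (!is.finite(loss))
          stopf("non-finite loss at epoch %d (fold %d); aborting", epoch,
                fold)
        losses <- c(losses, loss)
        dout <- (-(y / pc) + (1 - y) / (1 - pc)) / (npix * m)
        grads <- nnBackward(model@nodes, params, fw$caches, fw$vals,
                            model@output, dout, rank)
        stepped <- adamStep(params, grads, opt, ad)
        params <- stepped$params
        ad <- stepped$st
        b0 <- b0 + opt@batchSize
      }
      model@params <- params
      model@state <- state
      ji <- evalJaccard(model, test, opt@batchSize)
      records <- rbind(records,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  jaccard = 100 * ji))
      if (verbose)
        message(sprintf("[fold %d] epoch %3d  loss %.5f  test JI %.2f%%",
                        fold, epoch, mean(losses), 100 * ji))
    }
  })
  best <- which.max(records$jaccard)
  res <- new("FoldResult", fold = as.integer(fold), records = records,
             bestJaccard = records$jaccard[best],
             bestEpoch = as.integer(records$epoch[best]))
  list(result = res, model = model)
}

#' k-fold cross-validation of one model configuration
#'
#' For each fold a fresh model is built (fold-specific weight seed),
#' trained on the remaining folds and evaluated on the held-out fold;
#' per-fold best Jaccard percentages are aggregated as mean and sample
#' standard deviation. Every sample is tested exactly once.
#'
#' @param config a [ModelConfig-class].
#' @param samples dataset (list of samples).
#' @param k number of folds.
#' @param opt an [OptimizerConfig-class].
#' @param seed fold-assignment seed.
#' @param augment optional [AugmentConfig-class] applied to the training
#'   folds only (the held-out fold is never augmented).
#' @param label model label for the report.
#' @param verbose per-epoch logging.
#' @return a [CVReport-class].
#' @export
crossValidate <- function(config, samples, k = 5, opt = new("OptimizerConfig"),
                          seed = 1, augment = NULL, label = config@variant,
                          verbose = FALSE) {
  n <- length(samples)
  if (n < k) stopf("crossValidate: dataset size %d < k = %d", n, k)
  fa <- kfoldSplit(n, k, seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- fa@folds[[f]]
    trainIdx <- setdiff(seq_len(n), testIdx)
    stopifnot(length(intersect(trainIdx, testIdx)) == 0)
    tr <- samples[trainIdx]
    if (!is.null(augment)) tr <- augmentDataset(tr, augment)
    cfg <- config
    cfg@seed <- config@seed + as.integer(f)
    model <- buildModel(cfg)
    fit <- trainModel(model, tr, samples[testIdx], opt, fold = f,
                      verbose = verbose)
    folds[[f]] <- fit$result
  }
  best <- vapply(folds, function(r) r@bestJaccard, numeric(1))
  ag <- aggregateFolds(best)
  new("CVReport", model = label, protocol = "best-on-test", folds = folds,
      mean = ag[["mean"]], sd = ag[["sd"]])
}

#' @describeIn CVReport-class compact display
#' @param object a `CVReport`
#' @export
setMethod("show", "CVReport", function(object) {
  best <- vapply(object@folds, function(r) r@bestJaccard, numeric(1))
  cat(sprintf("CVReport [%s, %s protocol]: %d folds\n", object@model,
              object@protocol, length(object@folds)))
  cat(sprintf("  best JI per fold (%%): %s\n",
              paste(sprintf("%.2f", best), collapse = ", ")))
  cat(sprintf("  mean +/- sd: %.3f +/- %.3f\n", object@mean, object@sd))
})

#' Tabulate cross-validation reports
#'
#' One row per model, columns `F = 1 .. F = k` (per-fold best Jaccard,
#' percent) and `Avg`.
#'
#' @param reports list of [CVReport-class].
#' @return data.frame.
#' @export
cvTable <- function(reports) {
  k <- length(reports[[1]]@folds)
  rows <- lapply(reports, function(r) {
    best <- vapply(r@folds, function(x) x@bestJaccard, numeric(1))
    df <- as.data.frame(as.list(round(best, 2)))
    names(df) <- paste0("F", seq_len(k))
    cbind(data.frame(Type = r@model), df, data.frame(Avg = round(r@mean, 3)))
  })
  do.call(rbind, rows)
}

#' Run the ablation variants
#'
#' Cross-validates the four architectures (baseline U-Net, residual skip
#' paths only, multi-dimensional blocks only, full model) under one shared
#' protocol on the same dataset and fold assignment, and returns the
#' per-fold table.
#'
#' @param samples dataset.
#' @param k folds.
#' @param opt an [OptimizerConfig-class].
#' @param rank spatial rank.
#' @param depth pooling steps.
#' @param baseFilters schedule base filters for the block variants; the
#'   conv-pair variants use the same widths, keeping configurations
#'   matched.
#' @param inChannels input channels.
#' @param seed fold/weight seed.
#' @param variants subset of `c("unet", "paths", "blocks", "mdu")`.
#' @param verbose per-epoch logging.
#' @return list with `table` (Type, F1..Fk, Avg data.frame) and `reports`
#'   (named list of [CVReport-class]).
#' @export
runVariants <- function(samples, k = 5, opt = new("OptimizerConfig"),
                        rank = 2, depth = 3, baseFilters = c(8, 16, 32, 64),
                        inChannels = 1, seed = 1,
                        variants = c("unet", "paths", "blocks", "mdu"),
                        verbose = FALSE) {
  sched <- scheduleConfig(mode = "formula",
                          baseFilters = baseFilters[seq_len(depth + 1)])
  reports <- lapply(variants, function(v) {
    cfg <- modelConfig(rank = rank, variant = v, depth = depth,
                       inChannels = inChannels, schedule = sched,
                       stageWidths = baseFilters[seq_len(depth + 1)],
                       seed = seed)
    crossValidate(cfg, samples, k, opt, seed = seed, label = v,
                  verbose = verbose)
  })
  names(reports) <- variants
  list(table = cvTable(reports), reports = reports)
}

#' Run the with/without augmentation comparison
#'
#' Cross-validates the given configurations twice on the same folds, once
#' without and once with the (training-fold only) augmentation, and
#' returns both tables.
#'
#' @param samples dataset.
#' @param configs named list of [ModelConfig-class] objects.
#' @param k folds.
#' @param opt an [OptimizerConfig-class].
#' @param augment an [AugmentConfig-class] (default: factor 3).
#' @param seed fold seed.
#' @param verbose per-epoch logging.
#' @return list of data.frames `without` and `with`.
#' @export
runAugmentationStudy <- function(samples, configs, k = 5,
                                 opt = new("OptimizerConfig"),
                                 augment = new("AugmentConfig"),
                                 seed = 1, verbose = FALSE) {
  run <- function(aug) {
    reports <- lapply(names(configs), function(nm)
      crossValidate(configs[[nm]], samples, k, opt, seed = seed,
                    augment = aug, label = nm, verbose = verbose))
    cvTable(reports)
  }
  list(without = run(NULL), with = run(augment))
}

#' Write a cross-validation table as CSV
#'
#' @param table data.frame from [cvTable()] / [runVariants()].
#' @param path output path.
#' @export
writeCvTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Per-fold report rows
#'
#' One row per model and fold: dataset label, model, fold, best Jaccard
#' (percent) and the epoch attaining it.
#'
#' @param reports list of [CVReport-class].
#' @param dataset dataset label recorded on every row.
#' @return data.frame with columns `dataset, model, fold, best_jaccard,
#'   epoch`.
#' @export
foldRows <- function(reports, dataset = "synthetic") {
  do.call(rbind, lapply(reports, function(r)
    do.call(rbind, lapply(r@folds, function(f)
      data.frame(dataset = dataset, model = r@model, fold = f@fold,
                 best_jaccard = f@bestJaccard, epoch = f@bestEpoch,
                 stringsAsFactors = FALSE)))))
}

#' Two-model comparison summary
#'
#' Mean +/- standard deviation of both models and the comparative
#' increase (proposed minus traditional, percentage points).
#'
#' @param proposed,traditional [CVReport-class] objects.
#' @param dataset dataset label.
#' @return one-row data.frame with columns `dataset, proposed_mean,
#'   proposed_sd, traditional_mean, traditional_sd,
#'   comparative_increase`.
#' @export
comparisonTable <- function(proposed, traditional, dataset = "synthetic") {
  data.frame(dataset = dataset,
             proposed_mean = proposed@mean, proposed_sd = proposed@sd,
             traditional_mean = traditional@mean,
             traditional_sd = traditional@sd,
             comparative_increase = comparativeIncrease(proposed@mean,
                                                        traditional@mean),
             stringsAsFactors = FALSE)
}
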