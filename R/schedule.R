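# Filter-width calculus: per-level widths M = beta * F_n, split across the
# three chained 3x3 convolutions of a multi-dimensional block as
# (M/6, M/3, M/2), plus the fixed five-level reference schedule.

#' Create a schedule configuration
#'
#' @param beta positive scale factor (default 1.56).
#' @param baseFilters per-level baseline widths, doubling per level.
#' @param fractions allocation fractions for the three chained convolutions
#'   (must sum to 1; default 1/6, 1/3, 1/2).
#' @param rounding `"floor"`, `"ceil"` or `"nearest"`.
#' @param mode `"table_literal"` (the fixed five-level reference schedule)
#'   or `"formula"` (apply the width rule to `baseFilters`).
#' @return a [ScheduleConfig-class] object.
#' @examples
#' scheduleConfig(mode = "formula", baseFilters = c(8, 16, 32, 64))
#' @export
scheduleConfig <- function(beta = 1.56,
                           baseFilters = c(32, 64, 128, 256, 512),
                           fractions = c(1 / 6, 1 / 3, 1 / 2),
                           rounding = "floor",
                           mode = "table_literal") {
  new("ScheduleConfig", beta = beta, baseFilters = as.numeric(baseFilters),
      fractions = fractions, rounding = rounding, mode = mode)
}

#' Level width M = beta * F
#'
#' The real-valued width governing the filters of one block level.
#'
#' @param beta positive scale factor.
#' @param F positive integer baseline width of the level.
#' @return `beta * F`, exactly.
#' @examples
#' levelWidth(1.56, 32)   # 49.92
#' @export
levelWidth <- function(beta, F) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    stopf("levelWidth: beta must be a single positive number")
  if (!isCount(F)) stopf("levelWidth: F must be a positive integer")
  beta * F
}

roundCounts <- function(x, rounding) {
  switch(rounding,
         floor = floor(x),
         ceil = ceiling(x),
         nearest = round(x),
         stopf("unknown rounding '%s'", rounding))
}

#' Allocate block filters from a level width
#'
#' Splits a level width M into the integer filter counts of the three
#' chained 3x3 convolutions, `(M/6, M/3, M/2)` under the configured
#' rounding; the residual 1x1 projection receives their sum.
#'
#' @param M positive level width; must be at least 6 so every rounded count
#'   is positive under floor rounding.
#' @param config a [ScheduleConfig-class]; its `fractions` and `rounding`
#'   are used.
#' @param level level index recorded on the result.
#' @return a [LevelAllocation-class].
#' @examples
#' allocateBlockFilters(49.92)   # (8, 16, 24), res1 = 48
#' @export
allocateBlockFilters <- function(M, config = scheduleConfig(), level = 1L) {
  if (!is.numeric(M) || length(M) != 1 || !is.finite(M) || M <= 0)
    stopf("allocateBlockFilters: M must be a single positive number")
  counts <- as.integer(roundCounts(M * config@fractions, config@rounding))
  if (any(counts < 1))
    stopf("allocateBlockFilters: M = %g too small, a rounded count is < 1", M)
  new("LevelAllocation", level = as.integer(level), M = M,
      conv3Filters = counts, res1Filters = sum(counts))
}

# Published five-level reference schedule: printed 3x3 triples and printed
# 1x1 widths. The printed 1x1 widths disagree with the triple sums; the sum
# is normative (residual addition requires channel equality) and the
# printed value is kept as metadata.
.tableTriples <- list(c(7L, 18L, 26L), c(18L, 36L, 54L), c(36L, 73L, 107L),
                      c(72L, 144L, 216L), c(146L, 292L, 428L))
.tablePrintedRes1 <- c(52L, 106L, 214L, 428L, 856L)

#' The five-level reference schedule
#'
#' Returns the published per-level filter counts of the five-level 2D
#' model: 3x3 triples (7,18,26), (18,36,54), (36,73,107), (72,144,216),
#' (146,292,428). The residual 1x1 width of each level is the triple sum
#' (51, 108, 216, 432, 866); the published 1x1 widths (52, 106, 214, 428,
#' 856) differ slightly from those sums and are recorded in the
#' `printedRes1` slot as metadata.
#'
#' @return list of five [LevelAllocation-class] objects.
#' @export
tableLiteralSchedule <- function() {
  base <- c(32, 64, 128, 256, 512)
  lapply(seq_len(5), function(l)
    new("LevelAllocation", level = as.integer(l), M = 1.56 * base[l],
        conv3Filters = .tableTriples[[l]],
        res1Filters = sum(.tableTriples[[l]]),
        printedRes1 = .tablePrintedRes1[l]))
}

#' Per-level allocations for a schedule configuration
#'
#' @param config a [ScheduleConfig-class].
#' @param levels number of block levels required; defaults to
#'   `length(config@baseFilters)`.
#' @return list of [LevelAllocation-class], one per level.
#' @export
scheduleLevels <- function(config = scheduleConfig(),
                           levels = length(config@baseFilters)) {
  if (config@mode == "table_literal") {
    if (levels != 5L)
      stopf("table_literal mode defines exactly 5 levels, %d requested",
            levels)
    return(tableLiteralSchedule())
  }
  if (levels > length(config@baseFilters))
    stopf("schedule has %d base filters but %d levels requested",
          length(config@baseFilters), levels)
  lapply(seq_len(levels), function(l)
    allocateBlockFilters(levelWidth(config@beta, config@baseFilters[l]),
                         config, level = l))
}

#' Residual skip-path plan
#'
#' Level `l` (1 = shallowest) receives `depth - l + 1` residual units, so
#' the shallowest skip (largest semantic gap) gets the most nonlinear
#' processing and the deepest gets one unit. Unit widths are read from
#' `baseWidths`.
#'
#' @param depth number of skip levels (>= 1).
#' @param baseWidths per-level unit widths; needs at least `depth` entries.
#' @return a [PathPlan-class].
#' @examples
#' pathPlan(4, c(32, 64, 128, 256))  # counts 4,3,2,1
#' @export
pathPlan <- function(depth, baseWidths) {
  if (!isCount(depth)) stopf("pathPlan: depth must be a positive integer")
  if (length(baseWidths) < depth)
    stopf("pathPlan: need at least %d widths, got %d", depth,
          length(baseWidths))
  new("PathPlan", unitCounts = as.integer(depth - seq_len(depth) + 1L),
      unitWidths = as.integer(baseWidths[seq_len(depth)]))
}

#' Export / import a schedule as YAML
#'
#' @param config a [ScheduleConfig-class].
#' @param path file path.
#' @return `scheduleToYaml` returns `path` invisibly; `scheduleFromYaml`
#'   returns the reconstructed [ScheduleConfig-class].
#' @export
scheduleToYaml <- function(config, path) {
  levels <- scheduleLevels(config)
  obj <- list(beta = config@beta,
              base_filters = as.integer(config@baseFilters),
              fractions = config@fractions,
              rounding = config@rounding,
              mode = config@mode,
              levels = lapply(levels, function(a)
                list(conv3 = as.integer(a@conv3Filters),
                     res1 = as.integer(a@res1Filters),
                     printed_res1 = if (is.na(a@printedRes1)) NULL
                                    else as.integer(a@printedRes1))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname scheduleToYaml
#' @export
scheduleFromYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  scheduleConfig(beta = obj$beta, baseFilters = obj$base_filters,
                 fractions = if (is.null(obj$fractions))
                   c(1 / 6, 1 / 3, 1 / 2) else obj$fractions,
                 rounding = obj$rounding, mode = obj$mode)
}

#' @describeIn ScheduleConfig-class compact display
#' @param object a `ScheduleConfig`
#' @export
setMethod("show", "ScheduleConfig", function(object) {
  cat(sprintf("ScheduleConfig: mode=%s beta=%g rounding=%s\n",
              object@mode, object@beta, object@rounding))
  cat("  base filters:", paste(object@baseFilters, collapse = ", "), "\n")
})

#' @describeIn LevelAllocation-class compact display
#' @param object a `LevelAllocation`
#' @export
setMethod("show", "LevelAllocation", function(object) {
  cat(sprintf("Level %d (M=%.2f): conv3 = (%s), res1 = %d%s\n",
              object@level, object@M,
              paste(object@conv3Filters, collapse = ", "),
              object@res1Filters,
              if (!is.na(object@printedRes1))
                sprintf(" [printed 1x1: %d]", object@printedRes1) else ""))
})
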