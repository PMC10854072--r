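# Architectural primitives: the multi-dimensional block (three chained 3x3
# convolutions concatenated, plus an added 1x1 residual projection) and the
# residual encoder-decoder convolution path inserted along skip connections.

#' Append a multi-dimensional block
#'
#' Three chained size-preserving 3x3 convolutions with `n1 <= n2 <= n3`
#' filters (each convolution batch-normalized and ReLU-activated; the
#' second and third approximate 5x5 and 7x7 receptive fields), their three
#' outputs concatenated along channels, a 1x1 convolution of the block
#' input with `n1 + n2 + n3` filters added to the concatenation, and a
#' final batch-norm + ReLU. Spatial extents are preserved; output channels
#' equal the triple sum.
#'
#' @param b builder from [newNetworkBuilder()].
#' @param input input node name.
#' @param alloc a [LevelAllocation-class].
#' @param name node-name prefix.
#' @return output node name.
#' @export
addMultidimBlock <- function(b, input, alloc, name = "mdblock") {
  stopifnot(is(alloc, "LevelAllocation"))
  validObject(alloc)
  f <- alloc@conv3Filters
  if (alloc@res1Filters != sum(f))
    stopf("block residual width %d incompatible with triple sum %d",
          alloc@res1Filters, sum(f))
  a1 <- addConv(b, input, f[1], k = 3, name = paste0(name, ".c1"))
  a2 <- addConv(b, a1, f[2], k = 3, name = paste0(name, ".c2"))
  a3 <- addConv(b, a2, f[3], k = 3, name = paste0(name, ".c3"))
  cat_ <- addConcat(b, c(a1, a2, a3), name = paste0(name, ".cat"))
  res <- addConv(b, input, alloc@res1Filters, k = 1, activation = "none",
                 bn = FALSE, name = paste0(name, ".res"))
  s <- addAdd(b, c(cat_, res), name = paste0(name, ".add"))
  out <- addBn(b, s, name = paste0(name, ".out"))
  addAct(b, out, "relu", name = paste0(name, ".out"))
}

#' Append one residual convolution unit of a skip path
#'
#' A size-preserving 3x3 convolution with `width` filters plus a parallel
#' 1x1 convolution of the unit input (also `width` filters), added, then
#' batch-norm + ReLU. Output channels equal `width`.
#'
#' @param b builder.
#' @param input input node name.
#' @param width unit filter count.
#' @param name node-name prefix.
#' @return output node name.
#' @export
addRespathUnit <- function(b, input, width, name = "respath") {
  if (!isCount(width)) stopf("respath width must be a positive integer")
  main <- addConv(b, input, width, k = 3, activation = "none", bn = FALSE,
                  name = paste0(name, ".main"))
  short <- addConv(b, input, width, k = 1, activation = "none", bn = FALSE,
                   name = paste0(name, ".short"))
  s <- addAdd(b, c(main, short), name = paste0(name, ".add"))
  out <- addBn(b, s, name = paste0(name, ".out"))
  addAct(b, out, "relu", name = paste0(name, ".out"))
}

#' Append a full residual skip path
#'
#' Chains `unitCount` residual units of width `unitWidth` along a skip
#' connection, compensating the semantic gap between the shallow encoder
#' features and the deep decoder features they will be concatenated with.
#'
#' @param b builder.
#' @param input input node name (an encoder block output).
#' @param unitCount number of chained residual units (>= 1).
#' @param unitWidth filter count used by every unit in the path.
#' @param name node-name prefix.
#' @return output node name; output channels equal `unitWidth`.
#' @export
addSkipPath <- function(b, input, unitCount, unitWidth, name = "path") {
  if (!isCount(unitCount)) stopf("unitCount must be a positive integer")
  cur <- input
  for (u in seq_len(unitCount))
    cur <- addRespathUnit(b, cur, unitWidth,
                          name = sprintf("%s.u%d", name, u))
  cur
}
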