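# Architectural primitives: shape contracts (symbolic and by forward
# pass), channel bookkeeping, pooling/upsampling geometry, and gradient
# correctness of the constructed blocks.

test_that("multi-dimensional block preserves extents and sums channels", {
  cases <- list(
    list(rank = 2, size = c(64, 64), ch = 3, alloc = c(7, 18, 26)),
    list(rank = 2, size = c(8, 8), ch = 1, alloc = c(1, 2, 3)),
    list(rank = 3, size = c(16, 16, 16), ch = 4, alloc = c(8, 16, 24)))
  for (cs in cases) {
    b <- newNetworkBuilder(cs$rank, cs$ch, inputSize = cs$size)
    alloc <- new("LevelAllocation", level = 1L, M = sum(cs$alloc) * 1.0,
                 conv3Filters = as.integer(cs$alloc),
                 res1Filters = as.integer(sum(cs$alloc)))
    out <- addMultidimBlock(b, "input", alloc)
    expect_equal(unname(nodeShape(b, out)),
                 c(cs$size, sum(cs$alloc)))
  }
})

test_that("an allocation violating residual compatibility cannot build", {
  bad <- new("LevelAllocation", level = 1L, M = 6,
             conv3Filters = c(1L, 2L, 3L), res1Filters = 6L)
  bad@res1Filters <- 7L   # bypass constructor validity
  b <- newNetworkBuilder(2, 1, inputSize = c(8, 8))
  expect_error(addMultidimBlock(b, "input", bad), "res1Filters|incompatible")
})

test_that("block output channels equal the triple sum for random schedules", {
  set.seed(33)
  for (i in 1:20) {
    M <- stats::runif(1, 6, 400)
    alloc <- allocateBlockFilters(M)
    b <- newNetworkBuilder(2, sample(1:5, 1), inputSize = c(8, 8))
    out <- addMultidimBlock(b, "input", alloc)
    sh <- nodeShape(b, out)
    expect_equal(unname(sh[length(sh)]), sum(alloc@conv3Filters))
  }
})

test_that("respath units and skip paths set channels to the unit width", {
  b <- newNetworkBuilder(2, 51, inputSize = c(64, 64))
  u <- addRespathUnit(b, "input", 32)
  expect_equal(unname(nodeShape(b, u)), c(64, 64, 32))
  p <- addSkipPath(b, "input", 4, 32)
  sh <- nodeShape(b, p)
  expect_equal(unname(sh), c(64, 64, 32))

  b2 <- newNetworkBuilder(2, 216, inputSize = c(8, 8))
  expect_equal(unname(nodeShape(b2, addSkipPath(b2, "input", 1, 256))),
               c(8, 8, 256))
  b3 <- newNetworkBuilder(2, 5, inputSize = c(64, 64))
  expect_equal(unname(nodeShape(b3, addSkipPath(b3, "input", 1, 5))),
               c(64, 64, 5))
  b4 <- newNetworkBuilder(3, 48, inputSize = c(8, 8, 8))
  expect_equal(unname(nodeShape(b4, addRespathUnit(b4, "input", 32))),
               c(8, 8, 8, 32))
})

test_that("downsample halves extents; upsample doubles and sets channels", {
  b <- newNetworkBuilder(2, 51, inputSize = c(64, 64))
  expect_equal(unname(nodeShape(b, addDownsample(b, "input"))),
               c(32, 32, 51))
  b2 <- newNetworkBuilder(3, 4, inputSize = c(80, 80, 48))
  expect_equal(unname(nodeShape(b2, addDownsample(b2, "input"))),
               c(40, 40, 24, 4))
  b3 <- newNetworkBuilder(2, 1, inputSize = c(2, 2))
  expect_equal(unname(nodeShape(b3, addDownsample(b3, "input"))),
               c(1, 1, 1))
  b4 <- newNetworkBuilder(2, 1, inputSize = c(5, 6))
  expect_error(addDownsample(b4, "input"), "even")

  b5 <- newNetworkBuilder(2, 866, inputSize = c(8, 8))
  expect_equal(unname(nodeShape(b5, addUpsample(b5, "input", 432))),
               c(16, 16, 432))
  b6 <- newNetworkBuilder(3, 64, inputSize = c(10, 10, 6))
  expect_equal(unname(nodeShape(b6, addUpsample(b6, "input", 32))),
               c(20, 20, 12, 32))
})

test_that("forward passes realize the symbolic shapes, in both ranks", {
  set.seed(5)
  for (rank in 2:3) {
    size <- if (rank == 2) c(12, 8) else c(8, 6, 4)
    b <- newNetworkBuilder(rank, 2, inputSize = size)
    blk <- addMultidimBlock(b, "input", allocateBlockFilters(12))
    sp <- addSkipPath(b, blk, 2, 5)
    dn <- addDownsample(b, blk)
    up <- addUpsample(b, dn, 3)
    x <- array(stats::rnorm(prod(size) * 2 * 2), c(size, 2, 2))
    fw <- mducnn:::nnForward(b$nodes, b$params, b$state, x, rank,
                             training = TRUE)
    for (nm in c(blk, sp, dn, up))
      expect_equal(dim(fw$vals[[nm]])[seq_len(rank + 1)],
                   unname(nodeShape(b, nm)),
                   info = nm)
    # downsample then upsample restores the original spatial extents
    expect_equal(dim(fw$vals[[up]])[seq_len(rank)], size)
  }
})

test_that("constructed blocks are differentiable end to end", {
  # analytic gradients agree with central finite differences on a small
  # network containing every primitive (block, path, pool, upconv, concat)
  set.seed(7)
  rank <- 2
  b <- newNetworkBuilder(rank, 2, batchNorm = TRUE)
  blk <- addMultidimBlock(b, "input", allocateBlockFilters(6), name = "b1")
  sk <- addSkipPath(b, blk, 2, 3, name = "p1")
  dn <- addDownsample(b, blk)
  mid <- addMultidimBlock(b, dn, allocateBlockFilters(12), name = "mid")
  up <- addUpsample(b, mid, 4, name = "up")
  ct <- addConcat(b, c(up, sk))
  out <- addConv(b, ct, 1, k = 1, activation = "sigmoid", bn = FALSE,
                 name = "head")
  x <- array(stats::rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  nodes <- b$nodes; params <- b$params; state <- b$state
  lossOf <- function(p) {
    fw <- mducnn:::nnForward(nodes, p, state, x, rank, training = TRUE)
    sum(fw$vals[[out]]^2) / 2
  }
  fw <- mducnn:::nnForward(nodes, params, state, x, rank, training = TRUE)
  grads <- mducnn:::nnBackward(nodes, params, fw$caches, fw$vals, out,
                               fw$vals[[out]], rank)
  expect_true(all(vapply(grads, function(g) all(is.finite(g)), logical(1))))
  # spot-check three parameter tensors numerically
  eps <- 1e-5
  for (nm in c("b1.c2.conv.w", "p1.u1.out.bn.gamma", "up.b")) {
    g <- grads[[nm]]
    ng <- g * 0
    for (i in seq_along(ng)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      ng[i] <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
    }
    expect_lt(max(abs(g - ng)), 1e-4)
  }
})
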