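# Network engine: a small static-graph autodiff layer over the compiled
# kernels in src/ops.cpp. Activations are arrays with dims
# (spatial..., channels, batch); parameters live in a flat named list.
#
# Supported ops: input, conv (k in {1,3}, same padding), bn, relu, sigmoid,
# pool (2x stride-2 max), upconv (2x stride-2 transposed conv), concat
# (channel axis), add.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ------------------------------------------------------------ builder ----

#' Create a network builder
#'
#' Low-level graph construction surface used by the model assemblers and by
#' the block-level construction API ([addMultidimBlock()] and friends).
#' Weight initialization draws from the current RNG state; seed it (or build
#' through [buildModel()], which seeds internally) for reproducible weights.
#'
#' @param rank spatial rank (2 or 3).
#' @param inChannels input channel count.
#' @param inputSize optional reference spatial extents used for shape
#'   bookkeeping and build-time validation.
#' @param batchNorm default batch-norm flag for convolutions added later.
#' @return a builder environment; pass it to the `add*` functions.
#' @export
newNetworkBuilder <- function(rank, inChannels, inputSize = NULL,
                              batchNorm = TRUE) {
  if (!rank %in% c(2, 3)) stopf("rank must be 2 or 3")
  b <- new.env(parent = emptyenv())
  b$rank <- as.integer(rank)
  b$nodes <- list()
  b$shapes <- list()
  b$params <- list()
  b$state <- list()
  b$batchNorm <- isTRUE(batchNorm)
  b$counter <- 0L
  if (!is.null(inputSize) && length(inputSize) != rank)
    stopf("inputSize must have %d extents", rank)
  addNode(b, "input", op = "input", inputs = character(),
          shape = c(inputSize, channels = as.integer(inChannels)))
  b
}

nodeChannels <- function(b, name) {
  s <- b$shapes[[name]]
  unname(s[length(s)])
}

nodeSpatial <- function(b, name) {
  s <- b$shapes[[name]]
  if (length(s) > 1) unname(s[-length(s)]) else NULL
}

#' Shape of a builder node
#'
#' @param b a builder from [newNetworkBuilder()].
#' @param name node name.
#' @return integer vector `(spatial..., channels)`; spatial extents are
#'   present only when the builder was given a reference `inputSize`.
#' @export
nodeShape <- function(b, name) {
  force(name)   # allow nodeShape(b, add*(b, ...)) composition
  b$shapes[[name]]
}

addNode <- function(b, name = NULL, op, inputs, attrs = list(),
                    shape = NULL) {
  b$counter <- b$counter + 1L
  if (is.null(name)) name <- sprintf("%s_%d", op, b$counter)
  if (!is.null(b$shapes[[name]])) stopf("duplicate node name '%s'", name)
  for (i in inputs)
    if (is.null(b$shapes[[i]])) stopf("unknown input node '%s'", i)
  b$nodes[[name]] <- list(name = name, op = op, inputs = inputs,
                          attrs = attrs)
  if (!is.null(shape)) shape <- stats::setNames(as.integer(shape),
                                                names(shape))
  b$shapes[[name]] <- shape
  name
}

initConvW <- function(kdims, cin, cout, gain = sqrt(6)) {
  fan_in <- prod(kdims) * cin
  lim <- gain / sqrt(fan_in)
  array(stats::runif(prod(kdims) * cin * cout, -lim, lim),
        dim = c(kdims, cin, cout))
}

#' Add layers to a network builder
#'
#' `addConv` appends a same-padding convolution (kernel 1 or 3 per axis)
#' with optional batch normalization and activation; `addDownsample` a 2x
#' stride-2 max pool; `addUpsample` a 2x stride-2 transposed convolution;
#' `addConcat` channel concatenation; `addAdd` elementwise addition.
#' All return the name of the node appended last.
#'
#' @param b builder.
#' @param input,inputs input node name(s).
#' @param filters,outChannels output channel count.
#' @param k kernel extent per axis (1 or 3).
#' @param activation `"relu"`, `"sigmoid"` or `"none"`.
#' @param bn batch-normalize (defaults to the builder's flag); sigmoid
#'   output layers are never batch-normalized.
#' @param name optional node-name prefix.
#' @return node name (character).
#' @export
addConv <- function(b, input, filters, k = 3, activation = "relu",
                    bn = b$batchNorm, name = NULL) {
  if (!k %in% c(1, 3)) stopf("kernel extent must be 1 or 3")
  if (activation == "sigmoid" && bn)
    stopf("sigmoid output convolutions are not batch-normalized")
  cin <- nodeChannels(b, input)
  filters <- as.integer(filters)
  if (filters < 1) stopf("filters must be >= 1")
  sp <- nodeSpatial(b, input)
  nm <- addNode(b, if (is.null(name)) NULL else paste0(name, ".conv"),
                op = "conv", inputs = input,
                attrs = list(k = as.integer(k)),
                shape = c(sp, channels = filters))
  b$params[[paste0(nm, ".w")]] <- initConvW(rep(k, b$rank), cin, filters)
  b$params[[paste0(nm, ".b")]] <- numeric(filters)
  out <- nm
  if (bn) out <- addBn(b, out, name = name)
  if (activation != "none") out <- addAct(b, out, activation, name = name)
  out
}

addBn <- function(b, input, name = NULL) {
  ch <- nodeChannels(b, input)
  nm <- addNode(b, if (is.null(name)) NULL else paste0(name, ".bn"),
                op = "bn", inputs = input,
                shape = b$shapes[[input]])
  b$params[[paste0(nm, ".gamma")]] <- rep(1, ch)
  b$params[[paste0(nm, ".beta")]] <- numeric(ch)
  b$state[[paste0(nm, ".mean")]] <- numeric(ch)
  b$state[[paste0(nm, ".var")]] <- rep(1, ch)
  nm
}

addAct <- function(b, input, activation, name = NULL) {
  addNode(b, if (is.null(name)) NULL else paste0(name, ".", activation),
          op = activation, inputs = input, shape = b$shapes[[input]])
}

#' @rdname addConv
#' @export
addDownsample <- function(b, input, name = NULL) {
  sp <- nodeSpatial(b, input)
  if (!is.null(sp) && any(sp %% 2 != 0))
    stopf("downsample requires even spatial extents, got (%s)",
          paste(sp, collapse = ", "))
  addNode(b, name, op = "pool", inputs = input,
          shape = c(if (!is.null(sp)) sp %/% 2L,
                    channels = nodeChannels(b, input)))
}

#' @rdname addConv
#' @export
addUpsample <- function(b, input, outChannels, name = NULL) {
  cin <- nodeChannels(b, input)
  outChannels <- as.integer(outChannels)
  sp <- nodeSpatial(b, input)
  nm <- addNode(b, name, op = "upconv", inputs = input,
                shape = c(if (!is.null(sp)) 2L * sp,
                          channels = outChannels))
  b$params[[paste0(nm, ".w")]] <- initConvW(rep(2, b$rank), cin, outChannels)
  b$params[[paste0(nm, ".b")]] <- numeric(outChannels)
  nm
}

#' @rdname addConv
#' @export
addConcat <- function(b, inputs, name = NULL) {
  chs <- vapply(inputs, function(i) nodeChannels(b, i), integer(1))
  addNode(b, name, op = "concat", inputs = inputs,
          shape = c(nodeSpatial(b, inputs[[1]]), channels = sum(chs)))
}

#' @rdname addConv
#' @export
addAdd <- function(b, inputs, name = NULL) {
  chs <- vapply(inputs, function(i) nodeChannels(b, i), integer(1))
  if (length(unique(chs)) != 1)
    stopf("add requires equal channel counts, got (%s)",
          paste(chs, collapse = ", "))
  addNode(b, name, op = "add", inputs = inputs,
          shape = b$shapes[[inputs[[1]]]])
}

# ------------------------------------------------------------ forward ----

# x: array (spatial..., C, N). Returns list(vals, caches, state).
nnForward <- function(nodes, params, state, x, rank, training = FALSE) {
  vals <- list()
  caches <- list()
  for (node in nodes) {
    nm <- node$name
    ins <- lapply(node$inputs, function(i) vals[[i]])
    y <- switch(node$op,
      input = x,
      conv = {
        xin <- ins[[1]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        cin <- d[rank + 1]; n <- d[rank + 2]
        w <- params[[paste0(nm, ".w")]]
        cout <- dim(w)[rank + 2]
        out <- conv_fwd(xin, w, params[[paste0(nm, ".b")]],
                        as.integer(sp), cin, cout, n, node$attrs$k)
        dim(out) <- c(sp, cout, n)
        out
      },
      bn = {
        r <- bnForward(ins[[1]], params[[paste0(nm, ".gamma")]],
                       params[[paste0(nm, ".beta")]],
                       state[[paste0(nm, ".mean")]],
                       state[[paste0(nm, ".var")]], training)
        caches[[nm]] <- r$cache
        if (training) {
          state[[paste0(nm, ".mean")]] <- r$runMean
          state[[paste0(nm, ".var")]] <- r$runVar
        }
        r$y
      },
      relu = {
        out <- relu_fwd(ins[[1]])
        dim(out) <- dim(ins[[1]])
        out
      },
      sigmoid = 1 / (1 + exp(-ins[[1]])),
      pool = {
        xin <- ins[[1]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        if (any(sp %% 2 != 0))
          stopf("pool '%s': odd spatial extent (%s)", nm,
                paste(sp, collapse = ", "))
        r <- pool_fwd(xin, as.integer(sp), d[rank + 1], d[rank + 2])
        caches[[nm]] <- r$idx
        out <- r$y
        dim(out) <- c(sp %/% 2L, d[rank + 1], d[rank + 2])
        out
      },
      upconv = {
        xin <- ins[[1]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        w <- params[[paste0(nm, ".w")]]
        cout <- dim(w)[rank + 2]
        out <- upconv_fwd(xin, w, params[[paste0(nm, ".b")]],
                          as.integer(sp), d[rank + 1], cout, d[rank + 2])
        dim(out) <- c(2L * sp, cout, d[rank + 2])
        out
      },
      concat = {
        d1 <- dim(ins[[1]])
        sp <- d1[seq_len(rank)]
        n <- d1[rank + 2]
        chs <- vapply(ins, function(a) dim(a)[rank + 1], numeric(1))
        out <- array(0, c(prod(sp), sum(chs), n))
        at <- 0
        for (a in ins) {
          dim(a) <- c(prod(sp), dim(a)[rank + 1], n)
          out[, at + seq_len(dim(a)[2]), ] <- a
          at <- at + dim(a)[2]
        }
        dim(out) <- c(sp, sum(chs), n)
        out
      },
      add = Reduce(`+`, ins),
      stopf("unknown op '%s'", node$op))
    vals[[nm]] <- y
  }
  list(vals = vals, caches = caches, state = state)
}

bnForward <- function(x, gamma, beta, runMean, runVar, training) {
  d <- dim(x)
  C <- d[length(d) - 1]; n <- d[length(d)]
  P <- as.integer(prod(d) / C / n)
  r <- bn_fwd(x, P, C, n, gamma, beta, runMean, runVar, training,
              BN_MOMENTUM, BN_EPS)
  y <- r$y
  dim(y) <- d
  list(y = y,
       cache = list(m = r$m, ivar = r$ivar, P = P, C = C, n = n, dims = d),
       runMean = r$runMean, runVar = r$runVar)
}

# ----------------------------------------------------------- backward ----

# dout: gradient w.r.t. the output node. Returns named list of parameter
# gradients (same names as params).
nnBackward <- function(nodes, params, caches, vals, outName, dout, rank) {
  ngrad <- list()
  pgrad <- list()
  ngrad[[outName]] <- dout
  bump <- function(cur, g) if (is.null(cur)) g else cur + g
  for (node in rev(nodes)) {
    nm <- node$name
    g <- ngrad[[nm]]
    if (is.null(g)) next
    switch(node$op,
      input = NULL,
      conv = {
        xin <- vals[[node$inputs]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        w <- params[[paste0(nm, ".w")]]
        cout <- dim(w)[rank + 2]
        r <- conv_bwd(xin, w, g, as.integer(sp), d[rank + 1], cout,
                      d[rank + 2], node$attrs$k)
        dx <- r$dx; dim(dx) <- d
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
        dw <- r$dw; dim(dw) <- dim(w)
        pgrad[[paste0(nm, ".w")]] <- bump(pgrad[[paste0(nm, ".w")]], dw)
        pgrad[[paste0(nm, ".b")]] <- bump(pgrad[[paste0(nm, ".b")]], r$db)
      },
      bn = {
        cc <- caches[[nm]]
        r <- bn_bwd(vals[[node$inputs]], g, cc$P, cc$C, cc$n,
                    params[[paste0(nm, ".gamma")]], cc$m, cc$ivar)
        dx <- r$dx; dim(dx) <- cc$dims
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
        pgrad[[paste0(nm, ".gamma")]] <-
          bump(pgrad[[paste0(nm, ".gamma")]], r$dgamma)
        pgrad[[paste0(nm, ".beta")]] <-
          bump(pgrad[[paste0(nm, ".beta")]], r$dbeta)
      },
      relu = {
        dx <- relu_bwd(g, vals[[node$inputs]])
        dim(dx) <- dim(g)
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
      },
      sigmoid = {
        y <- vals[[nm]]
        dx <- g * y * (1 - y)
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
      },
      pool = {
        xin <- vals[[node$inputs]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        dx <- pool_bwd(g, caches[[nm]], as.integer(sp), d[rank + 1],
                       d[rank + 2])
        dim(dx) <- d
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
      },
      upconv = {
        xin <- vals[[node$inputs]]
        d <- dim(xin)
        sp <- d[seq_len(rank)]
        w <- params[[paste0(nm, ".w")]]
        cout <- dim(w)[rank + 2]
        r <- upconv_bwd(xin, w, g, as.integer(sp), d[rank + 1], cout,
                        d[rank + 2])
        dx <- r$dx; dim(dx) <- d
        ngrad[[node$inputs]] <- bump(ngrad[[node$inputs]], dx)
        dw <- r$dw; dim(dw) <- dim(w)
        pgrad[[paste0(nm, ".w")]] <- bump(pgrad[[paste0(nm, ".w")]], dw)
        pgrad[[paste0(nm, ".b")]] <- bump(pgrad[[paste0(nm, ".b")]], r$db)
      },
      concat = {
        d <- dim(g)
        sp <- d[seq_len(rank)]
        n <- d[rank + 2]
        gm <- g
        dim(gm) <- c(prod(sp), d[rank + 1], n)
        at <- 0
        for (i in node$inputs) {
          ci <- dim(vals[[i]])[rank + 1]
          piece <- gm[, at + seq_len(ci), , drop = FALSE]
          dim(piece) <- c(sp, ci, n)
          ngrad[[i]] <- bump(ngrad[[i]], piece)
          at <- at + ci
        }
      },
      add = {
        for (i in node$inputs) ngrad[[i]] <- bump(ngrad[[i]], g)
      })
    ngrad[[nm]] <- NULL   # release
  }
  pgrad
}

# --------------------------------------------------------------- adam ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, opt, st) {
  st$t <- st$t + 1L
  b1 <- opt@alpha1; b2 <- opt@alpha2
  lr <- opt@learningRate
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + 1e-8)
  }
  list(params = params, st = st)
}
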