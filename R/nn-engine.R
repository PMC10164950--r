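# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff engine for the segmentation network.
#
# Values are plain R arrays: feature maps H x W x C, vectors for pooled
# channel statistics, scalars for losses. A graph node is an environment
# holding the value (`v`), the accumulated gradient (`g`), and a backward
# closure (`bw`) that pushes the node's gradient into its parents. Nodes are
# recorded on a tape in execution order; `agBackward()` replays it in
# reverse. Samples are processed one at a time; minibatches are formed by
# gradient accumulation in the training loop.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$grad <- FALSE   # record the tape?
.ag$train <- FALSE  # training mode (enables dropout)
.ag$tape <- NULL

agRecording <- function() isTRUE(.ag$grad)

# Run `expr` with tape recording on; returns list(result, tape).
withTape <- function(expr, train = TRUE) {
  old_grad <- .ag$grad; old_train <- .ag$train; old_tape <- .ag$tape
  .ag$grad <- TRUE; .ag$train <- train
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- vector("list", 2048L)
  .ag$tape$n <- 0L
  on.exit({ .ag$grad <- old_grad; .ag$train <- old_train; .ag$tape <- old_tape })
  res <- force(expr)
  list(result = res, tape = .ag$tape)
}

# Run `expr` in plain inference mode (no tape, no dropout).
withNoGrad <- function(expr) {
  old_grad <- .ag$grad; old_train <- .ag$train
  .ag$grad <- FALSE; .ag$train <- FALSE
  on.exit({ .ag$grad <- old_grad; .ag$train <- old_train })
  force(expr)
}

agNode <- function(v, bw = NULL, leaf = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$bw <- bw
  n$leaf <- leaf
  class(n) <- "agNode"
  if (!leaf && !is.null(bw) && agRecording()) {
    t <- .ag$tape
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- n
  }
  n
}

agParam <- function(v) agNode(v, leaf = TRUE)
agConst <- function(v) agNode(v, leaf = TRUE)

agAccum <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the recorded tape.
agBackward <- function(loss, tape) {
  stopifnot(length(loss$v) == 1L)
  loss$g <- 1
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[tape$n - i + 1L]]
    if (!is.null(node$g) && !is.null(node$bw)) node$bw(node$g)
    node$bw <- NULL  # release closures (and captured intermediates) eagerly
  }
  invisible(NULL)
}

agZeroGrad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# --- elementary ops --------------------------------------------------------

# 2-D convolution, stride 1, 'same' padding. w: (Cin*k*k) x Cout matrix.
agConv <- function(x, w, b, k, dil = 1L) {
  pad <- as.integer(dil * (k - 1L) / 2L)
  v <- cpp_conv2d(x$v, w$v, b$v, k, pad, dil)
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    gr <- cpp_conv2d_bw(x$v, w$v, g, k, pad, dil)
    agAccum(x, gr$gx)
    agAccum(w, gr$gw)
    agAccum(b, as.numeric(gr$gb))
  })
}

# Per-sample channelwise spatial normalization with learnable gain/bias.
agInstNorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v)
  n <- d[1] * d[2]
  xm <- matrix(x$v, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, sd_inv, "*")
  ym <- sweep(xhat, 2, gamma$v, "*")
  ym <- sweep(ym, 2, beta$v, "+")
  v <- array(ym, d)
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    gm <- matrix(g, n, d[3])
    agAccum(gamma, colSums(gm * xhat))
    agAccum(beta, colSums(gm))
    gh <- sweep(gm, 2, gamma$v, "*")
    m1 <- colMeans(gh)
    m2 <- colMeans(gh * xhat)
    gx <- sweep(gh, 2, m1) - sweep(xhat, 2, m2, "*")
    gx <- sweep(gx, 2, sd_inv, "*")
    agAccum(x, array(gx, d))
  })
}

agRelu <- function(x) {
  v <- x$v * (x$v > 0)
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) agAccum(x, g * (x$v > 0)))
}

agSigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$v))
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) agAccum(x, g * v * (1 - v)))
}

agAdd <- function(a, b) {
  v <- a$v + b$v
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) { agAccum(a, g); agAccum(b, g) })
}

agScale <- function(x, k) {
  v <- x$v * k
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) agAccum(x, g * k))
}

# Channelwise concatenation of a list of H x W x C_i maps.
agConcat <- function(xs) {
  dims <- vapply(xs, function(x) dim(x$v)[3], numeric(1))
  v <- array(unlist(lapply(xs, function(x) x$v), use.names = FALSE),
             c(dim(xs[[1]]$v)[1:2], sum(dims)))
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      ci <- dims[i]
      agAccum(xs[[i]], g[, , off + seq_len(ci), drop = FALSE])
      off <- off + ci
    }
  })
}

# Channel-slice (used to split maps into groups without copying the graph).
agSliceChannels <- function(x, idx) {
  v <- x$v[, , idx, drop = FALSE]
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    gx <- array(0, dim(x$v))
    gx[, , idx] <- g
    agAccum(x, gx)
  })
}

agMaxPool2 <- function(x) {
  d <- dim(x$v)
  if (d[1] < 2L || d[2] < 2L)
    stop("max-pooling a ", d[1], "x", d[2], " map would fall below 1x1; ",
         "reduce the RSU level L or enlarge the input")
  r <- cpp_maxpool2(x$v)
  if (!agRecording()) return(agNode(r$y, leaf = TRUE))
  agNode(r$y, bw = function(g) agAccum(x, cpp_maxpool2_bw(g, r$idx, d[1], d[2])))
}

# Bilinear resize to an explicit target size (align-corners disabled).
agResize <- function(x, oh, ow) {
  d <- dim(x$v)
  if (d[1] == oh && d[2] == ow) return(x)
  v <- cpp_resize_bilinear(x$v, oh, ow)
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) agAccum(x, cpp_resize_bilinear_bw(g, d[1], d[2])))
}

# Global average pooling: H x W x C -> length-C vector.
agGap <- function(x) {
  d <- dim(x$v)
  v <- colMeans(matrix(x$v, d[1] * d[2], d[3]))
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    gx <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
    agAccum(x, gx)
  })
}

# Fully connected layer on a channel vector. w: Cin x Cout.
agLinear <- function(x, w, b) {
  v <- as.numeric(x$v %*% w$v) + b$v
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    agAccum(x, as.numeric(w$v %*% g))
    agAccum(w, outer(x$v, g))
    agAccum(b, g)
  })
}

# Multiply each channel of x by a scalar weight from vector a (length C).
agScaleChannels <- function(x, a) {
  d <- dim(x$v)
  av <- rep(a$v, each = d[1] * d[2])
  v <- array(x$v * av, d)
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    agAccum(x, array(g * av, d))
    agAccum(a, colSums(matrix(g * x$v, d[1] * d[2], d[3])))
  })
}

# Inverted dropout; active only in training mode.
agDropout <- function(x, p) {
  if (!isTRUE(.ag$train) || p <= 0) return(x)
  mask <- (array(stats::runif(length(x$v)), dim(x$v)) >= p) / (1 - p)
  v <- x$v * mask
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) agAccum(x, g * mask))
}

# --- loss ops (fused, scalar-valued) ---------------------------------------

agBce <- function(pred, target, eps = 1e-7) {
  y <- if (inherits(target, "agNode")) target$v else target
  p <- pmin(pmax(pred$v, eps), 1 - eps)
  n <- length(p)
  v <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    inside <- (pred$v > eps) & (pred$v < 1 - eps)
    gp <- g * (-(y / p) + (1 - y) / (1 - p)) / n * inside
    agAccum(pred, array(gp, dim(pred$v)))
  })
}

agDice <- function(pred, target, smooth = 1) {
  y <- if (inherits(target, "agNode")) target$v else target
  p <- pred$v
  s1 <- sum(p * y); sp <- sum(p); sy <- sum(y)
  num <- 2 * s1 + smooth
  den <- sp + sy + smooth
  v <- 1 - num / den
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) {
    gp <- -g * (2 * y * den - num) / den^2
    agAccum(pred, array(gp, dim(p)))
  })
}

agSumScalars <- function(xs) {
  v <- sum(vapply(xs, function(x) x$v, numeric(1)))
  if (!agRecording()) return(agNode(v, leaf = TRUE))
  agNode(v, bw = function(g) for (x in xs) agAccum(x, g))
}

# --- parameter initialization and SGD --------------------------------------

# He-uniform initialization (gain for ReLU fan-in); biases zero.
agInitConv <- function(cin, cout, k) {
  fan_in <- cin * k * k
  lim <- sqrt(6 / fan_in)
  list(w = agParam(matrix(stats::runif(fan_in * cout, -lim, lim), fan_in, cout)),
       b = agParam(numeric(cout)))
}

agInitLinear <- function(cin, cout) {
  lim <- sqrt(6 / cin)
  list(w = agParam(matrix(stats::runif(cin * cout, -lim, lim), cin, cout)),
       b = agParam(numeric(cout)))
}

agInitNorm <- function(c) {
  list(gamma = agParam(rep(1, c)), beta = agParam(numeric(c)))
}

# Plain SGD with momentum and optional weight decay over a named param list.
sgdState <- function(params) {
  lapply(params, function(p) {
    v <- p$v
    v[] <- 0
    v
  })
}

sgdStep <- function(params, state, lr, momentum = 0.9, weight_decay = 0) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0) g <- g + weight_decay * p$v
    state[[nm]] <- momentum * state[[nm]] + g
    p$v <- p$v - lr * state[[nm]]
  }
  state
}

# Collect every agNode parameter from a (nested) module structure into a
# flat named list.
collectParams <- function(module, prefix = "") {
  out <- list()
  walk <- function(x, pre) {
    if (inherits(x, "agNode")) {
      out[[pre]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        tag <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste0(pre, ".", tag))
      }
    }
  }
  walk(module, prefix)
  out
}
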