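# ---------------------------------------------------------------------------
# Network building blocks: conv-norm-ReLU units, residual U-blocks (RSU and
# the dilated RSU-4D), the Grouping Cross Merge (GCM) skip module and the
# Residual Attention Gate (RAG). Modules are lists holding parameter nodes
# plus a forward closure; `collectParams()` flattens them for the optimizer.
# ---------------------------------------------------------------------------

# conv(3x3 or 1x1) + channelwise normalization + ReLU
cnrInit <- function(cin, cout, k = 3L) {
  c(agInitConv(cin, cout, k), agInitNorm(cout), k = k)
}

cnrForward <- function(blk, x, dil = 1L) {
  agRelu(agInstNorm(agConv(x, blk$w, blk$b, blk$k, dil), blk$gamma, blk$beta))
}

#' Residual U-block configuration
#'
#' Describes one RSU stage: a U-shaped encoder-decoder of height `L` over
#' `midChannels` channels, wrapped in a residual connection around an input
#' convolution `inChannels -> outChannels`. The dilated variant (`dilated =
#' TRUE`, "RSU-4D") replaces pooling/upsampling with dilated convolutions at
#' rates 1, 2, 4, 8 so every internal feature keeps the input resolution.
#'
#' @param L U-structure height (integer >= 2). The first encoder stage of the
#'   full network uses `L = 7`.
#' @param inChannels,midChannels,outChannels positive channel counts.
#' @param dilated logical; build the resolution-preserving dilated variant
#'   (`L` is fixed at 4 internally for the dilated block).
#' @return An object of class `rsuConfig`.
#' @export
rsuConfig <- function(L, inChannels, midChannels, outChannels, dilated = FALSE) {
  stopifnot(L >= 2, inChannels >= 1, midChannels >= 1, outChannels >= 1)
  structure(list(L = as.integer(L), inChannels = as.integer(inChannels),
                 midChannels = as.integer(midChannels),
                 outChannels = as.integer(outChannels), dilated = isTRUE(dilated)),
            class = "rsuConfig")
}

#' Build a residual U-block
#'
#' Constructs the parameters and forward pass of one RSU: an input
#' convolution lifting `inChannels` to `outChannels`, an `L`-level U-shaped
#' encoder-decoder over `midChannels` (2x2 max-pool descents, bilinear
#' ascents, skip concatenations; or dilation rates 1,2,4,8 for the dilated
#' variant), and a residual sum of the two paths. Parameters are initialized
#' with the He-uniform scheme from the current RNG state.
#'
#' @param cfg an [rsuConfig()].
#' @return A module list with elements `params` and `forward(x)` where `x`
#'   is an `agNode` holding an H x W x C feature map.
#' @export
rsuBlock <- function(cfg) {
  stopifnot(inherits(cfg, "rsuConfig"))
  L <- cfg$L; M <- cfg$midChannels; Cin <- cfg$inChannels; Cout <- cfg$outChannels
  p <- list(convin = cnrInit(Cin, Cout))
  if (cfg$dilated) {
    rates <- c(1L, 2L, 4L, 8L)
    p$enc <- list(cnrInit(Cout, M), cnrInit(M, M), cnrInit(M, M), cnrInit(M, M))
    p$dec <- list(cnrInit(2L * M, M), cnrInit(2L * M, M), cnrInit(2L * M, Cout))
    forward <- function(x, collect = NULL) {
      hin <- cnrForward(p$convin, x)
      hs <- vector("list", 4L)
      h <- hin
      for (i in 1:4) {
        h <- cnrForward(p$enc[[i]], h, dil = rates[i])
        hs[[i]] <- h
        if (!is.null(collect)) collect(dim(h$v))
      }
      d <- hs[[4L]]
      for (i in 3:1) {
        d <- cnrForward(p$dec[[4L - i]], agConcat(list(d, hs[[i]])), dil = rates[i])
        if (!is.null(collect)) collect(dim(d$v))
      }
      agAdd(hin, d)
    }
  } else {
    p$enc <- vector("list", L)
    p$enc[[1L]] <- cnrInit(Cout, M)
    for (i in 2:L) p$enc[[i]] <- cnrInit(M, M)
    p$dec <- vector("list", L - 1L)
    for (i in seq_len(L - 2L)) p$dec[[i]] <- cnrInit(2L * M, M)
    p$dec[[L - 1L]] <- cnrInit(2L * M, Cout)
    forward <- function(x, collect = NULL) {
      hin <- cnrForward(p$convin, x)
      hs <- vector("list", L)
      h <- cnrForward(p$enc[[1L]], hin)
      hs[[1L]] <- h
      for (i in 2:(L - 1L)) {
        h <- cnrForward(p$enc[[i]], agMaxPool2(h))
        hs[[i]] <- h
      }
      # bottom level: dilated conv at the coarsest resolution
      hs[[L]] <- cnrForward(p$enc[[L]], hs[[L - 1L]], dil = 2L)
      d <- hs[[L]]
      for (i in (L - 1L):1L) {
        d <- cnrForward(p$dec[[L - i]], agConcat(list(d, hs[[i]])))
        if (i > 1L) d <- agResize(d, dim(hs[[i - 1L]]$v)[1L], dim(hs[[i - 1L]]$v)[2L])
      }
      agAdd(hin, d)
    }
  }
  list(params = p, forward = forward, config = cfg)
}

# --- Grouping Cross Merge ---------------------------------------------------

# Build one GCM skip module. Shallow (encoder) and deep (decoder-side) maps
# are each split channelwise into n groups; matching groups are concatenated
# and a 1x1 convolution halves each pair, so the re-concatenated output has
# (Cs + Cd) / 2 channels. A residual projection of the deep input is added.
# When the serial link is on, the previous (deeper) GCM's output is resized,
# projected to the deep input's channels, and summed into it before grouping.
gcmBlock <- function(cs, cd, n, carryChannels = NULL, stage = "") {
  if (cs %% n != 0L || cd %% n != 0L)
    stop("GCM at ", stage, ": group count n=", n, " must divide both channel ",
         "counts (shallow ", cs, ", deep ", cd, ")")
  gs <- cs %/% n; gd <- cd %/% n
  if ((gs + gd) %% 2L != 0L)
    stop("GCM at ", stage, ": per-group channel sum ", gs + gd, " is odd; ",
         "cannot halve")
  cout <- (cs + cd) %/% 2L
  # group convs and the carry projection are conv+norm+ReLU units so that
  # feature scale stays bounded along the serial GCM chain; the residual
  # path stays a pure projection (identity when channel counts agree).
  p <- list(group = lapply(seq_len(n), function(i) cnrInit(gs + gd, (gs + gd) %/% 2L, 1L)))
  if (cd != cout) p$proj <- agInitConv(cd, cout, 1L)
  if (!is.null(carryChannels)) p$carry <- cnrInit(carryChannels, cd, 1L)
  forward <- function(shallow, deep, carry = NULL) {
    if (!is.null(carry)) {
      stopifnot(!is.null(p$carry))
      cr <- agResize(carry, dim(deep$v)[1L], dim(deep$v)[2L])
      cr <- cnrForward(p$carry, cr)
      deep <- agAdd(deep, cr)
    }
    outs <- vector("list", n)
    for (i in seq_len(n)) {
      si <- agSliceChannels(shallow, (i - 1L) * gs + seq_len(gs))
      di <- agSliceChannels(deep, (i - 1L) * gd + seq_len(gd))
      outs[[i]] <- cnrForward(p$group[[i]], agConcat(list(si, di)))
    }
    merged <- agConcat(outs)
    res <- if (!is.null(p$proj)) agConv(deep, p$proj$w, p$proj$b, 1L) else deep
    agAdd(merged, res)
  }
  list(params = p, forward = forward, n = n, outChannels = cout)
}

# --- Residual Attention Gate ------------------------------------------------

# Channel attention gate over a skip feature x gated by the next-coarser
# feature g (spatially half of x): phi = ReLU(a(x) + b(upsample2(g))) with
# a, b 1x1 convolutions; d(phi) a further 1x1 convolution; global average
# pooling then a two-layer bottleneck (c -> c/r, ReLU, c/r -> c) and sigmoid
# give per-channel weights A in (0,1); output sum_k A_k d(phi)_k + d(phi).
ragBlock <- function(cx, cg, reductionRatio = 16L, interChannels = NULL) {
  ci <- if (is.null(interChannels)) cx else as.integer(interChannels)
  hidden <- max(4L, ci %/% as.integer(reductionRatio))
  hidden <- min(hidden, ci)
  p <- list(a = agInitConv(cx, ci, 1L), b = agInitConv(cg, ci, 1L),
            d = agInitConv(ci, ci, 1L),
            fc1 = agInitLinear(ci, hidden), fc2 = agInitLinear(hidden, ci))
  forward <- function(x, g, return_attention = FALSE) {
    dx <- dim(x$v); dg <- dim(g$v)
    if (dg[1L] * 2L != dx[1L] || dg[2L] * 2L != dx[2L])
      stop("RAG: gating feature must be exactly half the spatial size of x ",
           "(x ", dx[1L], "x", dx[2L], ", g ", dg[1L], "x", dg[2L], ")")
    gu <- agResize(g, dx[1L], dx[2L])
    phi <- agRelu(agAdd(agConv(x, p$a$w, p$a$b, 1L), agConv(gu, p$b$w, p$b$b, 1L)))
    dphi <- agConv(phi, p$d$w, p$d$b, 1L)
    z <- agGap(dphi)
    att <- agSigmoid(agLinear(agRelu(agLinear(z, p$fc1$w, p$fc1$b)), p$fc2$w, p$fc2$b))
    out <- agAdd(agScaleChannels(dphi, att), dphi)
    if (return_attention) list(out = out, attention = att, dphi = dphi) else out
  }
  list(params = p, forward = forward, interChannels = ci, hidden = hidden)
}
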