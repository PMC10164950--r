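# Numeric gradient checks for the autodiff engine: central differences on
# tiny tensors against the backward pass of each operation.

numGrad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

withTape <- organoidSeg:::withTape
agBackward <- organoidSeg:::agBackward

test_that("convolution gradients match central differences", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  init <- organoidSeg:::agInitConv(2, 3, 3)
  tp <- withTape({
    n <- organoidSeg:::agConst(x)
    y <- organoidSeg:::agConv(n, init$w, init$b, 3L)
    organoidSeg:::agNode(sum(y$v^2) / 2,
                         bw = function(g) organoidSeg:::agAccum(y, g * y$v))
  })
  agBackward(tp$result, tp$tape)
  gw_num <- numGrad(function(wv) {
    w2 <- organoidSeg:::agParam(matrix(wv, nrow(init$w$v)))
    n <- organoidSeg:::agConst(x)
    sum(organoidSeg:::agConv(n, w2, init$b, 3L)$v^2) / 2
  }, init$w$v, 1:6)
  expect_equal(as.numeric(init$w$g[1:6]), gw_num, tolerance = 1e-5)
})

test_that("instance-norm gradients match central differences", {
  set.seed(2)
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  nrm <- organoidSeg:::agInitNorm(3)
  nrm$gamma$v <- runif(3, 0.5, 1.5)
  nrm$beta$v <- rnorm(3)
  target <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  lossOf <- function(xv) {
    n <- organoidSeg:::agConst(array(xv, dim(x)))
    y <- organoidSeg:::agInstNorm(n, nrm$gamma, nrm$beta)
    sum((y$v - target)^2) / 2
  }
  tp <- withTape({
    n0 <- organoidSeg:::agConst(x)
    y <- organoidSeg:::agInstNorm(n0, nrm$gamma, nrm$beta)
    loss <- organoidSeg:::agNode(sum((y$v - target)^2) / 2,
      bw = function(g) organoidSeg:::agAccum(y, g * (y$v - target)))
    list(loss = loss, n0 = n0)
  })
  agBackward(tp$result$loss, tp$tape)
  idx <- sample(length(x), 10)
  expect_equal(as.numeric(tp$result$n0$g[idx]), numGrad(lossOf, x, idx),
               tolerance = 1e-4)
  gg_num <- numGrad(function(gv) {
    g2 <- organoidSeg:::agParam(gv)
    n <- organoidSeg:::agConst(x)
    y <- organoidSeg:::agInstNorm(n, g2, nrm$beta)
    sum((y$v - target)^2) / 2
  }, nrm$gamma$v, 1:3)
  expect_equal(as.numeric(nrm$gamma$g), gg_num, tolerance = 1e-4)
})

test_that("fused BCE and Dice loss gradients match central differences", {
  set.seed(3)
  p <- array(runif(6 * 6, 0.05, 0.95), c(6, 6, 1))
  y <- array(rbinom(36, 1, 0.5), c(6, 6, 1))
  for (op in c("bce", "dice")) {
    f <- function(pv) {
      n <- organoidSeg:::agConst(array(pv, dim(p)))
      if (op == "bce") organoidSeg:::agBce(n, y)$v
      else organoidSeg:::agDice(n, y)$v
    }
    tp <- withTape({
      n0 <- organoidSeg:::agConst(p)
      l <- if (op == "bce") organoidSeg:::agBce(n0, y)
           else organoidSeg:::agDice(n0, y)
      list(l = l, n0 = n0)
    })
    agBackward(tp$result$l, tp$tape)
    idx <- sample(length(p), 8)
    expect_equal(as.numeric(tp$result$n0$g[idx]), numGrad(f, p, idx),
                 tolerance = 1e-5, info = op)
  }
})

test_that("attention scaling and pooling gradients are exact adjoints", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  a <- runif(3)
  tp <- withTape({
    nx <- organoidSeg:::agConst(x)
    na <- organoidSeg:::agParam(a)
    y <- organoidSeg:::agScaleChannels(nx, na)
    z <- organoidSeg:::agGap(y)
    loss <- organoidSeg:::agNode(sum(z$v * c(1, 2, 3)),
      bw = function(g) organoidSeg:::agAccum(z, g * c(1, 2, 3)))
    list(loss = loss, nx = nx, na = na)
  })
  agBackward(tp$result$loss, tp$tape)
  f <- function(xv) {
    s <- array(xv, dim(x)) * rep(a, each = 16)
    sum(colMeans(matrix(s, 16, 3)) * c(1, 2, 3))
  }
  idx <- 1:10
  expect_equal(as.numeric(tp$result$nx$g[idx]), numGrad(f, x, idx),
               tolerance = 1e-6)
  fa <- function(av) {
    s <- x * rep(av, each = 16)
    sum(colMeans(matrix(s, 16, 3)) * c(1, 2, 3))
  }
  expect_equal(as.numeric(tp$result$na$g), numGrad(fa, a, 1:3),
               tolerance = 1e-6)
})

test_that("a single SGD step on one tile decreases the combined loss", {
  tiles <- makeTiles(1, size = 64, seedBase = 140L)
  setGlobalSeed(11)
  model <- acu2net(microConfig(), seed = 11)
  params <- model@modules$params
  tgt <- maskArray(tiles[[1L]])
  lossNow <- function() {
    pm <- predictMaps(model, tiles[[1L]])
    bceLoss(pm$fused, tgt) + diceLoss(pm$fused, tgt)
  }
  l0 <- lossNow()
  tp <- withTape({
    fwd <- organoidSeg:::acuForwardFull(model, tiles[[1L]], train = FALSE)
    organoidSeg:::trainingLossNode(fwd, tgt)
  }, train = FALSE)
  agBackward(tp$result, tp$tape)
  saved <- lapply(params, function(p) p$v)
  # gradient descent must decrease the loss for a small enough step
  decreased <- FALSE
  for (lr in c(1e-4, 1e-5, 1e-6)) {
    for (nm in names(params)) params[[nm]]$v <- saved[[nm]]
    st <- organoidSeg:::sgdState(params)
    organoidSeg:::sgdStep(params, st, lr = lr, momentum = 0)
    if (lossNow() < l0) { decreased <- TRUE; break }
  }
  expect_true(decreased)
})
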