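test_that("generator honours the shape contract and inference determinism", {
  cfg <- new("NetworkConfig", depth = 5L, baseFilters = 2L,
             inChannels = 3L, patchEdge = 32L)
  g <- buildGenerator(cfg, seed = 1)
  x <- array(runif(32^3 * 3, -1, 1), c(32, 32, 32, 3))
  y <- predictPatch(g, x)
  expect_equal(dim(y), c(32, 32, 32))
  expect_true(all(abs(y) <= 1))
  expect_identical(y, predictPatch(g, x))
  # extent not divisible by 2^(depth-1)
  bad <- array(0, c(24, 24, 24, 3))
  expect_error(predictPatch(g, bad), "divisible")
})

test_that("generator parameter count matches a layer-by-layer hand count", {
  cfg <- new("NetworkConfig", depth = 2L, baseFilters = 4L, kernel = 3L,
             inChannels = 2L, patchEdge = 16L)
  g <- buildGenerator(cfg, seed = 2)
  # filters per level: 4, 8; conv params = k^3*cin*cout + cout;
  # instance norm adds 2*cout per normalized conv
  hand <- (27 * 2 * 4 + 4 + 8) +      # enc1a: in 2 -> 4
    (27 * 4 * 4 + 4 + 8) +            # enc1b: 4 -> 4
    (27 * 4 * 8 + 8 + 16) +           # enc2a (down): 4 -> 8
    (27 * 8 * 8 + 8 + 16) +           # enc2b: 8 -> 8
    (27 * 8 * 4 + 4 + 8) +            # dec1a (post-upsample): 8 -> 4
    (27 * 8 * 4 + 4 + 8) +            # dec1b (skip concat): 8 -> 4
    (27 * 4 * 1 + 1)                  # final head: 4 -> 1, no norm
  expect_equal(nParameters(g), hand)
})

test_that("discriminator output lies in (0,1), shrinks spatially, checks shapes", {
  cfg <- tinyConfig()
  d <- buildDiscriminator(cfg, seed = 3)
  x <- array(runif(16^3 * 3, -1, 1), c(16, 16, 16, 3))
  cand <- array(runif(16^3, -1, 1), c(16, 16, 16))
  s <- discriminatorScore(d, x, cand)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(dim(s) < 16))
  expect_error(discriminatorScore(d, x, cand[1:8, , ]), "spatial")
})

test_that("discriminator receptive field matches the recurrence oracle", {
  cfg <- new("NetworkConfig", discStages = 3L, discKernel = 4L)
  # oracle: iterate r <- r*s + (k - s) from the head back to the input:
  # head (k4, s1): 1 -> 4; three stride-2 stages: 4 -> 10 -> 22 -> 46
  expect_equal(discriminatorReceptiveField(cfg), 46L)
  expect_equal(discriminatorReceptiveField(tinyConfig()), 22L)
})

test_that("generator loss closed forms hold", {
  set.seed(4)
  fake <- array(runif(8, -1, 1), c(2, 2, 2))
  # fake == real with 0.5 validity: adversarial ln 2, zero reconstruction
  v <- array(0.5, c(1, 1, 1))
  l <- generatorLoss(v, fake, fake, maeWeight = 100)
  expect_equal(l$total, log(2), tolerance = 1e-12)
  # lambda = 0: pure adversarial term
  real <- array(runif(8, -1, 1), c(2, 2, 2))
  l0 <- generatorLoss(v, fake, real, maeWeight = 0)
  expect_equal(l0$total, log(2), tolerance = 1e-12)
  # random tensors against a two-line recomputation
  p <- array(runif(8, 0.01, 0.99), c(2, 2, 2))
  l2 <- generatorLoss(p, fake, real, maeWeight = 7)
  expect_equal(l2$total, mean(-log(p)) + 7 * mean(abs(fake - real)),
               tolerance = 1e-12)
})

test_that("discriminator loss closed forms hold", {
  expect_equal(discriminatorLoss(array(0.5, 8), array(0.5, 8)), log(2),
               tolerance = 1e-12)
  expect_equal(discriminatorLoss(array(1, 8), array(0, 8)), 0,
               tolerance = 1e-6)
  set.seed(5)
  pr <- runif(27, 0.01, 0.99); pf <- runif(27, 0.01, 0.99)
  expect_equal(discriminatorLoss(pr, pf),
               (mean(-log(pr)) + mean(-log(1 - pf))) / 2,
               tolerance = 1e-12)
})

test_that("network gradients agree with finite differences", {
  cfg <- new("NetworkConfig", depth = 2L, baseFilters = 3L,
             inChannels = 2L, patchEdge = 16L, discStages = 2L,
             discBaseFilters = 3L)
  ns <- asNamespace("dirsynth")
  genF <- get("generatorForward", ns); genB <- get("generatorBackward", ns)
  g <- buildGenerator(cfg, seed = 6)
  set.seed(7)
  x <- array(runif(8^3 * 2, -1, 1), c(8, 8, 8, 2))
  fw <- genF(g, as.double(x), dim(x), train = TRUE)
  dy <- rnorm(length(fw$y)) * 0.1
  gr <- genB(g, fw, dy)
  L <- function(net) sum(genF(net, as.double(x), dim(x))$y * dy)
  for (probe in list(c("enc1a", "W"), c("enc2b", "gamma"),
                     c("dec1b", "W"), c("final", "b"))) {
    nm <- probe[1]; pn <- probe[2]
    i <- 1L + (length(g@layers[[nm]][[pn]]) - 1L) %/% 2L
    eps <- 1e-5
    gp <- g; gp@layers[[nm]][[pn]][i] <- gp@layers[[nm]][[pn]][i] + eps
    gm <- g; gm@layers[[nm]][[pn]][i] <- gm@layers[[nm]][[pn]][i] - eps
    fd <- (L(gp) - L(gm)) / (2 * eps)
    expect_equal(gr[[nm]][[pn]][i], fd, tolerance = 1e-4,
                 label = paste("grad", nm, pn))
  }
})

test_that("stitched whole-volume prediction equals the naive overlap oracle", {
  cfg <- tinyConfig()
  g <- buildGenerator(cfg, seed = 8)
  ph <- smallPhantom(seed = 41, nLesions = 0L)
  st <- simulateChannelStack(ph, seed = 7)
  out <- predictVolume(g, st, patchEdge = 16L, stride = 8L)
  # naive oracle: accumulate per-window predictions and average
  pred <- channelData(st)[, , , 1:3]
  acc <- array(0, c(32, 32, 32)); cnt <- array(0, c(32, 32, 32))
  starts <- c(1, 9, 17)
  for (sz in starts) for (sy in starts) for (sx in starts) {
    ix <- sx:(sx + 15); iy <- sy:(sy + 15); iz <- sz:(sz + 15)
    w <- predictPatch(g, pred[ix, iy, iz, , drop = FALSE])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + w
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  expect_lt(max(abs(out - acc / cnt)), 1e-6)
  # stride = patchEdge on an exactly tiling volume: per-tile forward passes
  out2 <- predictVolume(g, st, patchEdge = 16L, stride = 16L)
  tile <- predictPatch(g, pred[1:16, 1:16, 1:16, , drop = FALSE])
  expect_equal(out2[1:16, 1:16, 1:16], tile, tolerance = 1e-12)
})

test_that("a constant-zero generator stitches to all zeros", {
  cfg <- tinyConfig()
  g <- buildGenerator(cfg, seed = 9)
  # zero the final head so tanh(0) = 0 regardless of input
  g@layers$final$W[] <- 0
  g@layers$final$b[] <- 0
  ph <- smallPhantom(seed = 42, nLesions = 0L)
  st <- simulateChannelStack(ph, seed = 8)
  out <- predictVolume(g, st, patchEdge = 16L, stride = 12L)
  expect_true(all(out == 0))
})

test_that("one smoke epoch on tiny phantoms yields a finite history", {
  ph1 <- smallPhantom(seed = 43)
  ph2 <- smallPhantom(seed = 44)
  st1 <- simulateChannelStack(ph1, seed = 9)
  st2 <- simulateChannelStack(ph2, seed = 10)
  cfg <- tinyConfig(epochs = 1L)
  fit <- trainTranslator(list(st1, st2), cfg, seed = 100,
                         valStacks = list(st2))
  expect_equal(nrow(fit$history), 1)
  expect_true(all(is.finite(unlist(fit$history))))
  expect_s4_class(fit$generator, "ConvNet3D")
})

test_that("discriminator alone learns to separate real from a frozen generator", {
  ph <- smallPhantom(seed = 45)
  st <- simulateChannelStack(ph, seed = 11)
  cfg <- tinyConfig(epochs = 1L, lr = 2e-3)
  gen <- buildGenerator(cfg, seed = 12)
  disc <- buildDiscriminator(cfg, seed = 13)
  ns <- asNamespace("dirsynth")
  dF <- get("discriminatorForward", ns)
  dB <- get("discriminatorBackward", ns)
  adamInit <- get("adamInit", ns); adamStep <- get("adamStep", ns)
  accumulateGrads <- get("accumulateGrads", ns)
  opt <- adamInit(disc@layers)
  ctrs <- samplePatchCenters(brainMask(st), 40, seed = 14)
  losses <- numeric()
  for (it in 1:40) {
    pp <- extractPatch(st, ctrs[it, ], 16)
    fake <- predictPatch(gen, pp@predictors)
    dims <- c(16, 16, 16, 4)
    xr <- c(as.double(pp@predictors), as.double(pp@target))
    xf <- c(as.double(pp@predictors), as.double(fake))
    fr <- dF(disc, xr, dims, train = TRUE)
    ff <- dF(disc, xf, dims, train = TRUE)
    losses <- c(losses, discriminatorLoss(fr$p, ff$p))
    m <- length(fr$p)
    gr <- dB(disc, fr, (fr$p - 1) / (2 * m))$grads
    gf <- dB(disc, ff, ff$p / (2 * m))$grads
    upd <- adamStep(disc@layers, accumulateGrads(gr, gf), opt,
                    2e-3, 0.5, 0.999)
    disc@layers <- upd$params; opt <- upd$state
  }
  expect_lt(mean(tail(losses, 5)), log(2))
})
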