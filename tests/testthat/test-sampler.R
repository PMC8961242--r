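test_that("patch centers: forced choice, precondition, input validation", {
  m <- array(FALSE, c(16, 16, 16)); m[5, 9, 2] <- TRUE
  ctr <- samplePatchCenters(m, 7, seed = 1)
  expect_equal(nrow(ctr), 7)
  expect_true(all(ctr[, 1] == 5 & ctr[, 2] == 9 & ctr[, 3] == 2))
  expect_error(samplePatchCenters(m, 0), "> 0")
  expect_error(samplePatchCenters(array(FALSE, c(4, 4, 4)), 1), "empty")

  half <- array(FALSE, c(20, 20, 20)); half[1:10, , ] <- TRUE
  ctr <- samplePatchCenters(half, 10000, seed = 2)
  expect_true(all(half[ctr]))
})

test_that("patch centers are uniform over mask octants (chi-square)", {
  set.seed(0)
  m <- array(runif(24^3) > 0.4, c(24, 24, 24))
  ctr <- samplePatchCenters(m, 80000, seed = 3)
  oct <- function(ix) 1 + (ix[, 1] > 12) + 2 * (ix[, 2] > 12) +
    4 * (ix[, 3] > 12)
  got <- tabulate(oct(ctr), nbins = 8)
  expected <- tabulate(oct(arrayInd(which(m), dim(m))), nbins = 8)
  p <- suppressWarnings(
    chisq.test(got, p = expected / sum(expected))$p.value)
  expect_gt(p, 0.01)
})

test_that("extractPatch spans, pads and is deterministic", {
  set.seed(1)
  ph <- smallPhantom(seed = 31, nLesions = 0L)
  st <- simulateChannelStack(ph, seed = 1)
  ctr <- c(16, 16, 16)
  pp <- extractPatch(st, ctr, 16)
  expect_s4_class(pp, "PatchPair")
  expect_equal(dim(pp@predictors), c(16, 16, 16, 3))
  expect_equal(dim(pp@target), c(16, 16, 16))
  # interior patch has no padding: values match the source subcube
  expect_equal(pp@target, getChannel(st, "DIR")[8:23, 8:23, 8:23])
  # corner patch: the patch spans voxels -7..8, so exactly 8 of 16 planes
  # per axis fall outside the volume and must be zero-padded
  ppc <- extractPatch(st, c(1, 1, 1), 16)
  expect_true(all(ppc@predictors[1:8, , , ] == 0))
  expect_true(all(ppc@target[, 1:8, ] == 0))
  inside <- ppc@target[9:16, 9:16, 9:16]
  expect_identical(inside, getChannel(st, "DIR")[1:8, 1:8, 1:8])
  # determinism
  pp2 <- extractPatch(st, ctr, 16)
  expect_identical(pp@predictors, pp2@predictors)
  expect_error(extractPatch(st, ctr, 15), "even")
})

test_that("augmentation no-op draw returns the input unchanged", {
  ph <- smallPhantom(seed = 32)
  st <- simulateChannelStack(ph, seed = 2)
  pp <- extractPatch(st, c(16, 16, 16), 16)
  out <- augmentPatch(pp, augmentOff(), seed = 5)
  expect_identical(out@predictors, pp@predictors)
  expect_identical(out@target, pp@target)
  expect_identical(out@meta$ops, character())
})

test_that("mirroring is an involution", {
  ph <- smallPhantom(seed = 33)
  st <- simulateChannelStack(ph, seed = 3)
  pp <- extractPatch(st, c(16, 16, 16), 16)
  p <- augmentOff(pMirror = 1)
  once <- augmentPatch(pp, p, seed = 1)
  expect_false(identical(once@target, pp@target))
  twice <- augmentPatch(once, p, seed = 2)
  expect_equal(twice@predictors, pp@predictors, tolerance = 1e-14)
  expect_equal(twice@target, pp@target, tolerance = 1e-14)
})

test_that("gamma exponent 1 is the identity", {
  ns <- asNamespace("dirsynth")
  gammaCorrect <- get("gammaCorrect", ns)
  x <- seq(-1, 1, length.out = 101)
  expect_equal(gammaCorrect(x, 1), x, tolerance = 1e-14)
  # and monotone for other exponents
  expect_true(all(diff(gammaCorrect(x, 1.5)) > 0))
})

test_that("forced channel zeroing blanks exactly one predictor channel", {
  ph <- smallPhantom(seed = 34)
  st <- simulateChannelStack(ph, seed = 4)
  pp <- extractPatch(st, c(16, 16, 16), 16)
  out <- augmentPatch(pp, augmentOff(pChannelZero = 1), seed = 6)
  sums <- apply(abs(out@predictors), 4, sum)
  expect_equal(sum(sums == 0), 1)
  expect_identical(out@target, pp@target)
  # the oracle: remaining channels untouched
  keep <- which(sums != 0)
  expect_identical(out@predictors[, , , keep], pp@predictors[, , , keep])
})

test_that("geometric augmentation keeps values within [-1, 1]", {
  ph <- smallPhantom(seed = 35)
  st <- simulateChannelStack(ph, seed = 5)
  pp <- extractPatch(st, c(16, 16, 16), 16)
  for (s in 1:5) {
    out <- augmentPatch(pp, augmentOff(pRotScale = 1, pMirror = 0.5),
                        seed = s)
    expect_true(min(out@predictors) >= -1 && max(out@predictors) <= 1)
    expect_true(min(out@target) >= -1 && max(out@target) <= 1)
  }
})

test_that("augmentation trigger rates match configured probabilities", {
  ph <- smallPhantom(seed = 36, shape = c(32, 32, 32))
  st <- simulateChannelStack(ph, seed = 6)
  pp <- extractPatch(st, c(16, 16, 16), 16)
  params <- new("AugmentParams")   # reference probabilities
  n <- 10000
  pp16 <- extractPatch(st, c(16, 16, 16), 16)
  counts <- c(mirrorX = 0, rotscale = 0, gamma = 0, noise = 0, blur = 0,
              zero = 0)
  set.seed(99)
  seeds <- sample.int(1e7, n)
  for (i in seq_len(n)) {
    ops <- augmentPatch(pp16, params, seed = seeds[i])@meta$ops
    counts <- counts + c(any(ops == "mirrorX"), any(ops == "rotscale"),
                         any(ops == "gamma"), any(ops == "noise"),
                         any(ops == "blur"), any(startsWith(ops, "zero")))
  }
  probs <- c(mirrorX = params@pMirror,
             rotscale = params@pRotScale, gamma = params@pGamma,
             noise = params@pNoise, blur = params@pBlur,
             zero = params@pChannelZero)
  for (nm in names(probs)) {
    se <- sqrt(probs[nm] * (1 - probs[nm]) / n)
    expect_lt(abs(counts[nm] / n - probs[nm]), 3 * se + 1e-9,
              label = sprintf("%s trigger rate (%.4f vs %.4f)", nm,
                              counts[nm] / n, probs[nm]))
  }
})

test_that("epoch size formula and boundaries", {
  full <- array(TRUE, c(128, 128, 128))
  expect_equal(epochSize(list(full), 128, 8), 8L)
  almost <- full; almost[1, 1, 1] <- FALSE
  expect_equal(epochSize(list(almost), 128, 8), 0L)
  # masks totaling five million voxels
  m1 <- array(TRUE, c(100, 100, 250))
  m2 <- array(TRUE, c(100, 100, 250))
  expect_equal(epochSize(list(m1, m2), 128, 8),
               as.integer(floor(5e6 / 128^3) * 8))
  expect_equal(epochSize(full, 128, 8), 8L)   # single array accepted
})
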