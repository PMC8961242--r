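#' Train the conditional adversarial translation network
#'
#' Alternates one discriminator update and one generator update per batch
#' with Adam optimizers (`lr`, `beta1`, `beta2` from the configuration).
#' The number of patches per epoch follows [epochSize()] over the training
#' subjects' brain masks (with a floor of one batch so that toy volumes
#' smaller than a patch still train); patches are drawn uniformly inside
#' the brain masks, extracted with [extractPatch()] and augmented with
#' [augmentPatch()]. The discriminator learns to separate conventionally
#' simulated/acquired target patches from generated ones; the generator
#' minimizes the adversarial binary cross entropy plus `maeWeight` times
#' the mean absolute error ([generatorLoss()]).
#'
#' @param trainStacks list of [ChannelStack-class] objects with predictor
#'   channels and the target channel.
#' @param config a [NetworkConfig-class].
#' @param seed master RNG seed: weight initialization, patch draws and
#'   augmentation all derive from it, making runs reproducible.
#' @param valStacks optional list of held-out stacks; per-epoch validation
#'   MAE is computed on their central patch.
#' @param augment an [AugmentParams-class], or `NULL` to disable
#'   augmentation.
#' @param targetChannel name of the target channel.
#' @param verbose print a line per epoch.
#' @return list with elements `generator`, `discriminator` and `history`
#'   (data.frame: epoch, gen_adv, gen_mae, gen_total, disc_loss, val_mae).
#' @export
trainTranslator <- function(trainStacks, config = new("NetworkConfig"),
                            seed = 1L, valStacks = NULL, augment = NULL,
                            targetChannel = "DIR", verbose = FALSE) {
  stopifnot(length(trainStacks) >= 1L)
  validObject(config)
  seeds <- subSeeds(seed, 3L + config@epochs)
  gen <- buildGenerator(config, seed = seeds[1])
  disc <- buildDiscriminator(config, seed = seeds[2])
  optG <- adamInit(gen@layers)
  optD <- adamInit(disc@layers)
  masks <- lapply(trainStacks, brainMask)
  nPer <- max(epochSize(masks, config@patchEdge, config@epochMultiplier),
              config@batchSize)
  maskSizes <- vapply(masks, sum, numeric(1))
  hist <- data.frame(epoch = integer(), gen_adv = numeric(),
                     gen_mae = numeric(), gen_total = numeric(),
                     disc_loss = numeric(), val_mae = numeric())
  valPatches <- lapply(valStacks %||% list(), function(s)
    extractPatch(s, round(dim(s@data)[1:3] / 2), config@patchEdge,
                 targetChannel))
  for (ep in seq_len(config@epochs)) {
    epSeed <- seeds[3L + ep]
    draws <- withSeed(epSeed, {
      subj <- sample.int(length(trainStacks), nPer, replace = TRUE,
                         prob = maskSizes)
      list(subj = subj,
           seeds = sample.int(.Machine$integer.max %/% 2L, 2L * nPer))
    })
    eg <- em <- ed <- 0; nb <- 0L
    i <- 1L
    while (i <= nPer) {
      take <- i:min(i + config@batchSize - 1L, nPer)
      batch <- lapply(seq_along(take), function(j) {
        id <- take[j]
        s <- trainStacks[[draws$subj[id]]]
        ctr <- samplePatchCenters(brainMask(s), 1L,
                                  seed = draws$seeds[2L * id - 1L])
        pp <- extractPatch(s, ctr[1, ], config@patchEdge, targetChannel)
        if (!is.null(augment))
          pp <- augmentPatch(pp, augment, seed = draws$seeds[2L * id])
        pp
      })
      st <- trainStep(gen, disc, optG, optD, batch, config)
      gen <- st$gen; disc <- st$disc; optG <- st$optG; optD <- st$optD
      if (!all(is.finite(c(st$gAdv, st$gMae, st$dLoss))))
        stop("non-finite loss at epoch ", ep,
             "; training diverged (consider lowering lr)")
      eg <- eg + st$gAdv; em <- em + st$gMae; ed <- ed + st$dLoss
      nb <- nb + 1L
      i <- i + length(take)
    }
    vmae <- NA_real_
    if (length(valPatches)) {
      vmae <- mean(vapply(valPatches, function(pp) {
        fake <- predictPatch(gen, pp@predictors)
        mean(abs(fake - pp@target))
      }, numeric(1)))
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, gen_adv = eg / nb, gen_mae = em / nb,
      gen_total = (eg + config@maeWeight * em) / nb, disc_loss = ed / nb,
      val_mae = vmae))
    if (verbose)
      message(sprintf(
        "epoch %3d  G(adv %.4f mae %.4f)  D %.4f  val %.4f",
        ep, eg / nb, em / nb, ed / nb, vmae))
  }
  list(generator = gen, discriminator = disc, history = hist)
}

# One alternating discriminator + generator update on a batch of patch
# pairs. Gradients are averaged over the batch; instance normalization
# makes per-sample processing exact.
trainStep <- function(gen, disc, optG, optD, batch, config) {
  n <- length(batch)
  lam <- config@maeWeight
  # one taped generator forward per sample; its output feeds the
  # discriminator step (as a detached fake) and the generator step (with
  # gradients), since the discriminator update does not change it
  fws <- vector("list", n)
  # --- discriminator step (generator frozen)
  gradsD <- NULL; dLoss <- 0
  for (j in seq_len(n)) {
    pp <- batch[[j]]
    dims <- dim(pp@predictors)
    xdimsD <- c(dims[1:3], dims[4] + 1L)
    fws[[j]] <- generatorForward(gen, as.double(pp@predictors), dims,
                                 train = TRUE)
    xr <- c(as.double(pp@predictors), as.double(pp@target))
    xf <- c(as.double(pp@predictors), fws[[j]]$y)
    fr <- discriminatorForward(disc, xr, xdimsD, train = TRUE)
    ff <- discriminatorForward(disc, xf, xdimsD, train = TRUE)
    dLoss <- dLoss + discriminatorLoss(fr$p, ff$p)
    m <- length(fr$p)
    # d/dlogit of mean(BCE(real, 1), BCE(fake, 0))
    gr <- discriminatorBackward(disc, fr, (fr$p - 1) / (2 * m))$grads
    gf <- discriminatorBackward(disc, ff, ff$p / (2 * m))$grads
    gradsD <- accumulateGrads(accumulateGrads(gradsD, gr), gf)
  }
  upd <- adamStep(disc@layers, scaleGrads(gradsD, 1 / n), optD,
                  config@lr, config@beta1, config@beta2)
  disc@layers <- upd$params; optD <- upd$state
  # --- generator step (updated discriminator, frozen)
  gradsG <- NULL; gAdv <- 0; gMae <- 0
  for (j in seq_len(n)) {
    pp <- batch[[j]]
    dims <- dim(pp@predictors)
    xdimsD <- c(dims[1:3], dims[4] + 1L)
    fw <- fws[[j]]
    xf <- c(as.double(pp@predictors), fw$y)
    ff <- discriminatorForward(disc, xf, xdimsD, train = TRUE)
    tgt <- as.double(pp@target)
    ls <- generatorLoss(ff$p, fw$y, tgt, lam)
    gAdv <- gAdv + ls$adv; gMae <- gMae + ls$mae
    m <- length(ff$p)
    # adversarial gradient flows through the discriminator input back
    # to the candidate channel (the last channel of its input)
    db <- discriminatorBackward(disc, ff, (ff$p - 1) / m, need_dx = TRUE)
    nPred <- prod(dims)
    dFake <- db$dx[(nPred + 1L):(nPred + length(fw$y))]
    dFake <- dFake + lam * sign(fw$y - tgt) / length(tgt)
    gradsG <- accumulateGrads(gradsG, generatorBackward(gen, fw, dFake))
  }
  upd <- adamStep(gen@layers, scaleGrads(gradsG, 1 / n), optG,
                  config@lr, config@beta1, config@beta2)
  gen@layers <- upd$params; optG <- upd$state
  list(gen = gen, disc = disc, optG = optG, optD = optD,
       gAdv = gAdv / n, gMae = gMae / n, dLoss = dLoss / n)
}

#' Whole-volume inference by sliding-window stitching
#'
#' Translates a full volume with a generator trained on patches: cubic
#' windows of edge `patchEdge` are placed every `stride` voxels (with a
#' final window flush against each upper border), predicted independently,
#' and averaged with uniform weights where windows overlap. Volumes smaller
#' than a patch are zero-padded and trimmed back.
#'
#' @param generator a generator [ConvNet3D-class].
#' @param stack a [ChannelStack-class]; all channels except
#'   `targetChannel` (if present) are used as predictors.
#' @param patchEdge window edge length (voxels).
#' @param stride window step; must not exceed `patchEdge`.
#' @param targetChannel channel to exclude from the predictors.
#' @return numeric 3D array, the artificial target volume in [-1, 1].
#' @export
predictVolume <- function(generator, stack, patchEdge = NULL,
                          stride = NULL, targetChannel = "DIR") {
  stopifnot(is(generator, "ConvNet3D"), generator@kind == "generator",
            is(stack, "ChannelStack"))
  patchEdge <- as.integer(patchEdge %||% generator@config@patchEdge)
  stride <- as.integer(stride %||% patchEdge)
  if (stride > patchEdge) stop("stride must not exceed patchEdge")
  if (stride < 1L) stop("stride must be >= 1")
  pred <- stack@data[, , , !stack@channels %in% targetChannel,
                     drop = FALSE]
  shape <- dim(pred)[1:3]
  padded <- pmax(shape, patchEdge)
  if (any(padded != shape)) {
    tmp <- array(0, c(padded, dim(pred)[4]))
    tmp[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), ] <- pred
    pred <- tmp
  }
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, padded[a] - patchEdge + 1L, by = stride)
    unique(c(s, padded[a] - patchEdge + 1L))
  })
  acc <- array(0, padded)
  cnt <- array(0, padded)
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    ix <- sx:(sx + patchEdge - 1L)
    iy <- sy:(sy + patchEdge - 1L)
    iz <- sz:(sz + patchEdge - 1L)
    win <- pred[ix, iy, iz, , drop = FALSE]
    out <- predictPatch(generator, win)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + out
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  res <- acc / cnt
  res[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])]
}
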