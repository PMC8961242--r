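# Shared scaled-down training experiment: a depth-3 / base-8 generator
# trained on one noiseless 32^3 phantom with 16-voxel patches, evaluated
# on a held-out phantom. Used by the adversarial-learning checks; cached
# per session because it is by far the most expensive fixture.

scaledTrainingRun <- function(seed) {
  seeds <- seed + c(0L, 1000L, 2000L)
  phTr <- makeTissuePhantom(c(32, 32, 32), nLesions = 4,
                            lesionRadiusRange = c(1.2, 2),
                            seed = seeds[1])
  phTe <- makeTissuePhantom(c(32, 32, 32), nLesions = 4,
                            lesionRadiusRange = c(1.2, 2),
                            seed = seeds[2])
  stTr <- simulateChannelStack(phTr, noiseSd = 0, seed = seeds[1])
  stTe <- simulateChannelStack(phTe, noiseSd = 0, seed = seeds[2])
  cfg <- new("NetworkConfig", depth = 3L, baseFilters = 8L,
             inChannels = 3L, patchEdge = 16L, discStages = 2L,
             discBaseFilters = 8L, epochs = 200L, lr = 1e-3,
             maeWeight = 100)
  fit <- trainTranslator(list(stTr), cfg, seed = seeds[3],
                         valStacks = list(stTe))
  pred <- predictVolume(fit$generator, stTe, patchEdge = 16L, stride = 8L)
  truth <- getChannel(stTe, "DIR")
  bm <- brainMask(stTe)
  list(
    fit = fit,
    phantomTest = phTe, stackTest = stTe, prediction = pred,
    corr = stats::cor(pred[bm], truth[bm]),
    lesionContrast = mean(pred[lesionMask(phTe) > 0]) -
      mean(pred[tissueLabels(phTe) == 2L]),
    maeFirst = fit$history$val_mae[1],
    maeLast = utils::tail(fit$history$val_mae, 1))
}
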