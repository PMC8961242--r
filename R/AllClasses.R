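#' Pulse-sequence timing parameters
#'
#' Timing parameters of the simulated acquisition. Three sequence families
#' are supported: `"spin_echo"` (parameters `tr`, `te`), `"inversion_recovery"`
#' (`tr`, `te`, `ti`) and `"double_inversion_recovery"` (`tr`, `te`, `ti1`,
#' `ti2`). All times are milliseconds. For the double inversion recovery
#' (DIR) convention used throughout: the first inversion pulse is played at
#' t = 0, the second at t = `ti1`, and excitation/readout at t = `ti1 + ti2`.
#'
#' @slot kind sequence family.
#' @slot tr repetition time (ms).
#' @slot te echo time (ms).
#' @slot ti inversion time (ms), single inversion recovery only.
#' @slot ti1 delay between the two inversion pulses (ms), DIR only.
#' @slot ti2 delay between the second inversion and excitation (ms), DIR only.
#' @export
setClass("SequenceParams",
  representation(kind = "character", tr = "numeric", te = "numeric",
                 ti = "numeric", ti1 = "numeric", ti2 = "numeric"),
  prototype(ti = NA_real_, ti1 = NA_real_, ti2 = NA_real_))

setValidity("SequenceParams", function(object) {
  kinds <- c("spin_echo", "inversion_recovery", "double_inversion_recovery")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  if (object@tr <= 0 || object@te < 0) return("tr must be > 0 and te >= 0")
  if (object@kind == "inversion_recovery" &&
      (is.na(object@ti) || object@ti <= 0))
    return("inversion_recovery requires ti > 0")
  if (object@kind == "double_inversion_recovery") {
    if (is.na(object@ti1) || is.na(object@ti2) ||
        object@ti1 <= 0 || object@ti2 <= 0)
      return("double_inversion_recovery requires ti1 > 0 and ti2 > 0")
    if (object@ti1 + object@ti2 >= object@tr)
      return("ti1 + ti2 must be smaller than tr")
  }
  TRUE
})

#' Labeled tissue phantom with planted lesions
#'
#' A piecewise-constant 3D brain phantom: integer tissue labels (background,
#' cerebrospinal fluid, grey-matter ribbon, white-matter core, lesion), a
#' per-tissue relaxation table (T1, T2, proton density), a lesion id mask
#' with per-lesion type and lobe annotations, and a binary brain mask. It is
#' the ground truth object from which all simulated contrasts are derived.
#'
#' @slot labels integer 3D array of tissue class codes (see `tissueTable`).
#' @slot spacing voxel size per axis (mm).
#' @slot tissueTable data.frame with columns `label`, `name`, `t1`, `t2`, `pd`.
#' @slot lesionMask integer 3D array, 0 = no lesion, otherwise lesion id.
#' @slot lesionMeta data.frame with one row per lesion id: `lesion_id`,
#'   `type` (intracortical/juxtacortical/mixed), `lobe`
#'   (frontal/temporal/parietal/occipital), voxel-space centre and radius.
#' @slot brainMask logical 3D array.
#' @export
setClass("TissuePhantom",
  representation(labels = "array", spacing = "numeric",
                 tissueTable = "data.frame", lesionMask = "array",
                 lesionMeta = "data.frame", brainMask = "array"))

setValidity("TissuePhantom", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be 3D")
  if (!identical(dim(object@labels), dim(object@lesionMask)))
    return("labels and lesionMask must have identical shape")
  if (!identical(dim(object@labels), dim(object@brainMask)))
    return("labels and brainMask must have identical shape")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  tt <- object@tissueTable
  need <- c("label", "name", "t1", "t2", "pd")
  if (!all(need %in% names(tt)))
    return("tissueTable needs columns label, name, t1, t2, pd")
  if (any(tt$t1 <= 0) || any(tt$t2 <= 0)) return("t1 and t2 must be > 0")
  if (any(tt$t2 > tt$t1)) return("t2 must not exceed t1")
  if (any(tt$pd < 0 | tt$pd > 1)) return("pd must lie in [0, 1]")
  if (!all(unique(as.vector(object@labels)) %in% tt$label))
    return("every label in the volume needs a tissueTable entry")
  ids <- setdiff(unique(as.vector(object@lesionMask)), 0L)
  if (!all(ids %in% object@lesionMeta$lesion_id))
    return("every lesion id needs a lesionMeta row")
  if (any(object@lesionMask > 0 & !object@brainMask))
    return("lesion voxels must lie inside the brain mask")
  TRUE
})

#' Ordered multichannel volume stack
#'
#' Co-registered 3D intensity channels of one subject stored as a 4D array
#' with spatial dimensions first and channels last (the NIfTI convention).
#' For the translation task, predictor channels (T1, PD, T2) and the target
#' DIR channel live in one stack.
#'
#' @slot data numeric 4D array (X, Y, Z, C).
#' @slot channels channel names, length C.
#' @slot spacing voxel size per axis (mm).
#' @slot mask logical 3D brain mask.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @export
setClass("ChannelStack",
  representation(data = "array", channels = "character", spacing = "numeric",
                 mask = "array", affine = "matrix"))

setValidity("ChannelStack", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be 4D (X, Y, Z, C)")
  if (dim(object@data)[4] != length(object@channels))
    return("length(channels) must match dim(data)[4]")
  if (!identical(dim(object@data)[1:3], dim(object@mask)))
    return("mask shape must match the spatial dimensions")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    return("affine must be 4x4")
  TRUE
})

#' Intensity-normalized volume
#'
#' The result of the z-score / divide-by-four / clip normalization chain:
#' voxel values in [-1, 1] together with the mask-derived statistics that
#' produced them.
#'
#' @slot data normalized 3D array, values in [-1, 1].
#' @slot mask logical 3D array over which `mu` and `sigma` were computed.
#' @slot mu mean intensity inside the mask (original units).
#' @slot sigma standard deviation inside the mask (original units).
#' @export
setClass("NormalizedVolume",
  representation(data = "array", mask = "array", mu = "numeric",
                 sigma = "numeric"))

setValidity("NormalizedVolume", function(object) {
  if (min(object@data) < -1 - 1e-12 || max(object@data) > 1 + 1e-12)
    return("data must lie in [-1, 1]")
  if (object@sigma <= 0) return("sigma must be > 0")
  TRUE
})

#' Stochastic patch-augmentation parameters
#'
#' Probabilities and ranges of the training-time augmentation scheme.
#' Geometric operations (mirroring; combined rotation + scaling) are applied
#' to predictors and target alike; intensity operations (per-channel gamma,
#' additive Gaussian noise, shared-sigma blur, single-channel zeroing) touch
#' the predictors only. The three degradation operations trigger
#' independently, each with its own probability.
#'
#' @slot pMirror per-axis mirroring probability.
#' @slot pRotScale probability of the combined rotation + scaling transform.
#' @slot angleRange rotation angle range per axis (degrees).
#' @slot scaleRange per-axis scale factor range.
#' @slot pGamma probability of per-channel gamma correction.
#' @slot gammaRange gamma exponent range.
#' @slot pNoise probability of additive Gaussian noise.
#' @slot noiseSd standard deviation of the additive noise (normalized units).
#' @slot pBlur probability of Gaussian blurring.
#' @slot blurSigmaRange blur kernel sigma range (voxels), shared across
#'   channels.
#' @slot pChannelZero probability of zeroing one random predictor channel.
#' @export
setClass("AugmentParams",
  representation(pMirror = "numeric", pRotScale = "numeric",
                 angleRange = "numeric", scaleRange = "numeric",
                 pGamma = "numeric", gammaRange = "numeric",
                 pNoise = "numeric", noiseSd = "numeric",
                 pBlur = "numeric", blurSigmaRange = "numeric",
                 pChannelZero = "numeric"),
  prototype(pMirror = 0.5, pRotScale = 0.5, angleRange = c(-90, 90),
            scaleRange = c(0.8, 1.2), pGamma = 0.5, gammaRange = c(0.8, 1.5),
            pNoise = 0.3, noiseSd = 0.05, pBlur = 0.3,
            blurSigmaRange = c(0.2, 1.5), pChannelZero = 0.3))

setValidity("AugmentParams", function(object) {
  ps <- c(object@pMirror, object@pRotScale, object@pGamma, object@pNoise,
          object@pBlur, object@pChannelZero)
  if (any(ps < 0 | ps > 1)) return("probabilities must lie in [0, 1]")
  for (rng in list(object@angleRange, object@scaleRange, object@gammaRange,
                   object@blurSigmaRange)) {
    if (length(rng) != 2L || rng[1] > rng[2])
      return("ranges must be ordered length-2 vectors")
  }
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Co-located predictor/target patch pair
#'
#' One training sample: a channel-stacked predictor patch and the
#' corresponding target patch cut from the same location, both in [-1, 1].
#'
#' @slot predictors numeric 4D array (S, S, S, C).
#' @slot target numeric 3D array (S, S, S).
#' @slot center 1-based voxel coordinate of the patch center in the source
#'   volume.
#' @slot meta list of bookkeeping entries (applied augmentations etc.).
#' @export
setClass("PatchPair",
  representation(predictors = "array", target = "array", center = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("PatchPair", function(object) {
  dp <- dim(object@predictors)
  if (length(dp) != 4L) return("predictors must be 4D (S, S, S, C)")
  if (!identical(dp[1:3], dim(object@target)))
    return("predictor and target spatial extents must agree")
  if (length(unique(dp[1:3])) != 1L) return("patches must be cubic")
  TRUE
})

#' Architecture and training hyperparameters of the translation network
#'
#' All knobs of the 3D conditional adversarial network: the U-shaped
#' generator (depth, base filter count, kernel size, leaky-ReLU slope,
#' instance normalization), the PatchGAN discriminator (stride-2 stage count,
#' base filters, kernel), and the optimization settings (Adam learning rate
#' and betas, epochs, batch size, patch edge, reconstruction weight).
#'
#' @slot depth number of encoder resolution levels.
#' @slot baseFilters filters at the first level; doubled per level.
#' @slot kernel spatial kernel edge of generator convolutions.
#' @slot leakySlope negative slope of the leaky ReLU activations.
#' @slot inChannels number of predictor channels.
#' @slot maeWeight weight of the mean-absolute-error term in the generator
#'   loss.
#' @slot lr Adam learning rate.
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot epochs training epochs.
#' @slot batchSize patches per optimization step.
#' @slot patchEdge cubic patch edge length (voxels).
#' @slot epochMultiplier multiplier in the samples-per-epoch formula.
#' @slot discStages number of stride-2 discriminator stages.
#' @slot discBaseFilters discriminator filters at the first stage.
#' @slot discKernel discriminator kernel edge.
#' @export
setClass("NetworkConfig",
  representation(depth = "integer", baseFilters = "integer",
                 kernel = "integer", leakySlope = "numeric",
                 inChannels = "integer", maeWeight = "numeric",
                 lr = "numeric", beta1 = "numeric", beta2 = "numeric",
                 epochs = "integer", batchSize = "integer",
                 patchEdge = "integer", epochMultiplier = "integer",
                 discStages = "integer", discBaseFilters = "integer",
                 discKernel = "integer"),
  prototype(depth = 5L, baseFilters = 32L, kernel = 3L, leakySlope = 0.2,
            inChannels = 3L, maeWeight = 100, lr = 2e-4, beta1 = 0.5,
            beta2 = 0.999, epochs = 350L, batchSize = 2L, patchEdge = 128L,
            epochMultiplier = 8L, discStages = 3L, discBaseFilters = 32L,
            discKernel = 4L))

setValidity("NetworkConfig", function(object) {
  if (object@depth < 2L) return("depth must be >= 2")
  if (object@patchEdge %% as.integer(2^(object@depth - 1)) != 0L)
    return("patchEdge must be divisible by 2^(depth - 1)")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@kernel %% 2L != 1L) return("generator kernel must be odd")
  if (object@baseFilters < 1L || object@discBaseFilters < 1L)
    return("filter counts must be positive")
  if (object@leakySlope < 0) return("leakySlope must be >= 0")
  if (object@lr <= 0 || object@beta1 < 0 || object@beta1 >= 1 ||
      object@beta2 < 0 || object@beta2 >= 1)
    return("invalid optimizer settings")
  if (object@maeWeight < 0) return("maeWeight must be >= 0")
  TRUE
})

#' A 3D convolutional network (generator or discriminator)
#'
#' Container for the hand-rolled volumetric networks: an ordered list of
#' layer descriptors with their parameter matrices, plus the configuration
#' that built them.
#'
#' @slot kind `"generator"` or `"discriminator"`.
#' @slot config the [NetworkConfig-class] used to build the net.
#' @slot layers ordered list of layer descriptors.
#' @export
setClass("ConvNet3D",
  representation(kind = "character", config = "NetworkConfig",
                 layers = "list"))

#' One-to-one lesion matching result
#'
#' Bookkeeping of the greedy centroid matching between the lesions detected
#' on the artificial DIR image and those detected on the conventional DIR
#' image of the same subject: matched pairs (true positives), artificial-only
#' detections (false positives) and conventional-only detections (false
#' negatives).
#'
#' @slot subject subject identifier.
#' @slot pairs data.frame of matches: `a_id`, `c_id`, `dist_mm`.
#' @slot tp,fp,fn counts.
#' @export
setClass("MatchResult",
  representation(subject = "character", pairs = "data.frame",
                 tp = "integer", fp = "integer", fn = "integer"))

setValidity("MatchResult", function(object) {
  if (object@tp != nrow(object@pairs)) return("tp must equal nrow(pairs)")
  if (object@fp < 0 || object@fn < 0) return("fp and fn must be >= 0")
  if (anyDuplicated(object@pairs$a_id) || anyDuplicated(object@pairs$c_id))
    return("matching must be one-to-one")
  TRUE
})

#' Intraclass correlation result (two-way mixed, absolute agreement)
#'
#' Single-measure absolute-agreement intraclass correlation between k fixed
#' raters/methods over n subjects, with its 95% confidence interval and F
#' statistic.
#'
#' @slot icc the coefficient (at most 1; finite-sample estimates can
#'   fall slightly below the theoretical lower bound).
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot fStat F statistic (between-subjects over residual mean square).
#' @slot df1,df2 degrees of freedom of `fStat`.
#' @slot p p-value of the F test.
#' @slot n subjects; @slot k raters/methods.
#' @slot msr,msc,mse row, column and error mean squares.
#' @export
setClass("IccResult",
  representation(icc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 fStat = "numeric", df1 = "numeric", df2 = "numeric",
                 p = "numeric", n = "integer", k = "integer",
                 msr = "numeric", msc = "numeric", mse = "numeric"))

setValidity("IccResult", function(object) {
  # point estimates can undershoot -1/(k-1) slightly in finite samples,
  # but never exceed 1
  if (!is.finite(object@icc) || object@icc > 1 + 1e-12)
    return("icc must be finite and at most 1")
  if (!is.finite(object@ciLow) || !is.finite(object@ciHigh) ||
      object@ciLow > object@icc + 1e-8 ||
      object@ciHigh < object@icc - 1e-8)
    return("confidence bounds must be finite and bracket the estimate")
  TRUE
})
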