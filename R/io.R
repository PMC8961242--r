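#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file and returns the voxel data together with its
#' voxel-to-mm affine and the voxel spacing derived from the affine's
#' column norms.
#'
#' @param path NIfTI file path.
#' @param expectDims expected dimensionality (default 3; a 4D file then
#'   raises an error).
#' @return list with `data` (numeric array), `affine` (4x4 matrix) and
#'   `spacing` (mm per axis).
#' @export
readVolume <- function(path, expectDims = 3L) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != expectDims)
    stop(path, " is ", length(dim(im)), "D; expected ", expectDims, "D")
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  list(data = array(as.numeric(im), dim(im)), affine = aff,
       spacing = spacing)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param volume numeric 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-mm matrix.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(volume, path, affine = diag(4)) {
  stopifnot3d(volume)
  im <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read / write lesion record tables
#'
#' Lesion tables are plain CSV with the columns produced by
#' [detectCandidates()].
#'
#' @param path CSV path.
#' @return data.frame of lesion records.
#' @export
readLesionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "lesion_id", "centroid_x", "centroid_y",
            "centroid_z", "type", "lobe", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lesion table lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname readLesionTable
#' @param records lesion record data.frame.
#' @export
writeLesionTable <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The full configuration tree of [runPipeline()]: phantom geometry and
#' noise, network/training hyperparameters, augmentation probabilities and
#' evaluation thresholds. The clinical-scale defaults (128-voxel patches,
#' depth 5, 32 base filters, 350 epochs, Adam 2e-4 with betas 0.5/0.999,
#' batch size 2) are impractical without a GPU, so `profile = "smoke"`
#' (the default) scales everything down to a 32-voxel toy problem that
#' exercises every stage in minutes on one CPU, and `profile = "reduced"`
#' matches the problem sizes used for the package's accuracy checks.
#'
#' @param profile `"smoke"`, `"reduced"` or `"clinical"`.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(profile = c("smoke", "reduced", "clinical")) {
  profile <- match.arg(profile)
  base <- list(
    seed = 1L,
    profile = profile,
    phantom = list(shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                   n_lesions_range = c(2L, 8L),
                   lesion_radius_range = c(1.2, 2),
                   noise_sd = 0, n_train = 1L, n_val = 1L, n_test = 2L),
    network = list(depth = 3L, base_filters = 8L, kernel = 3L,
                   leaky_slope = 0.2, in_channels = 3L, mae_weight = 100,
                   lr = 1e-3, beta1 = 0.5, beta2 = 0.999, epochs = 10L,
                   batch_size = 2L, patch_edge = 16L,
                   epoch_multiplier = 8L, disc_stages = 2L,
                   disc_base_filters = 8L, disc_kernel = 4L),
    augment = list(enabled = FALSE, p_mirror = 0.5, p_rotscale = 0.5,
                   angle_range = c(-90, 90), scale_range = c(0.8, 1.2),
                   p_gamma = 0.5, gamma_range = c(0.8, 1.5),
                   p_noise = 0.3, noise_sd = 0.05, p_blur = 0.3,
                   blur_sigma_range = c(0.2, 1.5), p_channel_zero = 0.3),
    evaluate = list(tol_mm = 5, z_thresh = 3, min_area_mm2 = 3,
                    test_noise_sd = 0.05, stride = 8L))
  if (profile == "reduced") {
    base$network$epochs <- 200L
    base$phantom$n_test <- 4L
  } else if (profile == "clinical") {
    base$phantom$shape <- c(192L, 192L, 192L)
    base$phantom$n_lesions_range <- c(0L, 25L)
    base$phantom$lesion_radius_range <- c(2, 4)
    base$phantom$n_train <- 20L
    base$phantom$n_val <- 4L
    base$phantom$n_test <- 6L
    base$network <- modifyList(base$network, list(
      depth = 5L, base_filters = 32L, epochs = 350L, lr = 2e-4,
      patch_edge = 128L, disc_stages = 3L, disc_base_filters = 32L))
    base$augment$enabled <- TRUE
    base$evaluate$stride <- 64L
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Reads the YAML file and merges it onto [defaultRunConfig()] for its
#' profile, so partial files only need to state what differs.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(user$profile %||% "smoke")
  modifyList(cfg, user)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any field changes.
#'
#' @param config configuration list.
#' @return hex string.
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

networkConfigFromList <- function(nw) {
  new("NetworkConfig",
      depth = as.integer(nw$depth), baseFilters = as.integer(nw$base_filters),
      kernel = as.integer(nw$kernel), leakySlope = nw$leaky_slope,
      inChannels = as.integer(nw$in_channels), maeWeight = nw$mae_weight,
      lr = nw$lr, beta1 = nw$beta1, beta2 = nw$beta2,
      epochs = as.integer(nw$epochs), batchSize = as.integer(nw$batch_size),
      patchEdge = as.integer(nw$patch_edge),
      epochMultiplier = as.integer(nw$epoch_multiplier),
      discStages = as.integer(nw$disc_stages),
      discBaseFilters = as.integer(nw$disc_base_filters),
      discKernel = as.integer(nw$disc_kernel))
}

augmentParamsFromList <- function(au) {
  new("AugmentParams", pMirror = au$p_mirror, pRotScale = au$p_rotscale,
      angleRange = as.numeric(au$angle_range),
      scaleRange = as.numeric(au$scale_range), pGamma = au$p_gamma,
      gammaRange = as.numeric(au$gamma_range), pNoise = au$p_noise,
      noiseSd = au$noise_sd,
      pBlur = au$p_blur, blurSigmaRange = as.numeric(au$blur_sigma_range),
      pChannelZero = au$p_channel_zero)
}

logStage <- function(stage, seed, cfgHash, note = "") {
  message(sprintf("[%s] stage=%s seed=%s config=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  as.character(seed), substr(cfgHash, 1, 8), note))
}

#' Run the full phantom-to-evaluation pipeline
#'
#' Executes phantom generation, channel simulation/normalization,
#' adversarial training, whole-volume prediction on held-out test
#' phantoms, lesion detection on artificial and reference DIR, matching,
#' precision/recall, ICC and the lobe/type tabulation, writing all
#' artifacts under `outDir`. Every stage logs its seed and the
#' configuration hash; a rerun with the identical configuration reproduces
#' the evaluation report.
#'
#' @param config nested configuration list (see [defaultRunConfig()]).
#' @param outDir output directory.
#' @return invisibly, the evaluation report list.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = "adir_run") {
  h <- configHash(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  seed <- as.integer(config$seed)
  ph <- config$phantom
  nAll <- ph$n_train + ph$n_val + ph$n_test
  seeds <- subSeeds(seed, nAll + 2L)
  stage <- "phantom"
  res <- tryCatch({
    logStage(stage, seed, h, sprintf("n=%d", nAll))
    # lesion burden varies per subject, as in a real cohort, so that
    # count-agreement statistics have between-subject variance to explain
    nLes <- withSeed(seed, sample(ph$n_lesions_range[1]:
                                    ph$n_lesions_range[2],
                                  nAll, replace = TRUE))
    phantoms <- lapply(seq_len(nAll), function(i)
      makeTissuePhantom(ph$shape, ph$spacing, nLes[i],
                        ph$lesion_radius_range, seed = seeds[i]))
    stacks <- lapply(seq_along(phantoms), function(i)
      simulateChannelStack(phantoms[[i]], noiseSd = ph$noise_sd,
                           seed = seeds[i]))
    idxTrain <- seq_len(ph$n_train)
    idxVal <- ph$n_train + seq_len(ph$n_val)
    idxTest <- ph$n_train + ph$n_val + seq_len(ph$n_test)
    for (i in idxTest)
      writePhantom(phantoms[[i]], file.path(outDir,
                                            sprintf("test_phantom_%02d", i)))
    stage <- "train"
    logStage(stage, seeds[nAll + 1L], h,
             sprintf("epochs=%d", config$network$epochs))
    nc <- networkConfigFromList(config$network)
    aug <- if (isTRUE(config$augment$enabled))
      augmentParamsFromList(config$augment) else NULL
    fit <- trainTranslator(stacks[idxTrain], nc,
                           seed = seeds[nAll + 1L],
                           valStacks = stacks[idxVal], augment = aug)
    write.csv(fit$history, file.path(outDir, "training_log.csv"),
              row.names = FALSE)
    saveRDS(fit$generator, file.path(outDir, "generator.rds"))
    stage <- "predict+evaluate"
    logStage(stage, seeds[nAll + 2L], h)
    ev <- config$evaluate
    testSeeds <- subSeeds(seeds[nAll + 2L], length(idxTest))
    aAll <- cAll <- list(); matches <- list()
    countMat <- matrix(0, length(idxTest), 2,
                       dimnames = list(NULL, c("aDIR", "cDIR")))
    for (j in seq_along(idxTest)) {
      i <- idxTest[j]
      subj <- sprintf("s%02d", i)
      phan <- phantoms[[i]]
      # reference DIR reading: normalized simulation with test noise
      cDIR <- normalizeIntensity(
        simulateSequence(phan, defaultSequenceParams(
          "DIR", tissueTable = phan@tissueTable),
          noiseSd = ev$test_noise_sd, seed = testSeeds[j]),
        phan@brainMask)@data
      aDIR <- predictVolume(fit$generator, stacks[[i]],
                            patchEdge = nc@patchEdge, stride = ev$stride)
      writeVolume(aDIR, file.path(outDir, sprintf("aDIR_%s.nii.gz", subj)),
                  affine = diag(c(phan@spacing, 1)))
      gm <- phan@labels == 2L
      aRec <- detectCandidates(aDIR, gm, phan@spacing, ev$z_thresh,
                               ev$min_area_mm2, subject = subj,
                               source = "aDIR")
      cRec <- detectCandidates(cDIR, gm, phan@spacing, ev$z_thresh,
                               ev$min_area_mm2, subject = subj,
                               source = "cDIR")
      aAll[[j]] <- aRec; cAll[[j]] <- cRec
      matches[[j]] <- matchLesions(aRec, cRec, ev$tol_mm)
      countMat[j, ] <- c(nrow(aRec), nrow(cRec))
    }
    aAll <- do.call(rbind, aAll); cAll <- do.call(rbind, cAll)
    writeLesionTable(aAll, file.path(outDir, "lesions_aDIR.csv"))
    writeLesionTable(cAll, file.path(outDir, "lesions_cDIR.csv"))
    pr <- precisionRecall(matches)
    icc <- if (nrow(countMat) >= 3L)
      tryCatch(iccAbsoluteAgreement(countMat), error = function(e) NULL)
      else NULL
    tab <- tabulateLesions(aAll, cAll, matches)
    report <- list(
      config_hash = h,
      pooled = as.list(pr$pooled),
      mean_sd = as.list(pr$meanSd),
      per_subject = pr$perSubject,
      icc = if (!is.null(icc)) list(icc = icc@icc, ci_low = icc@ciLow,
                                    ci_high = icc@ciHigh, f = icc@fStat)
            else NULL,
      counts = as.data.frame(countMat),
      table_lobe = tab$lobe, table_type = tab$type,
      final_val_mae = utils::tail(fit$history$val_mae, 1))
    jsonlite::write_json(report, file.path(outDir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    report
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  invisible(res)
}
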