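#' Generate a labeled brain phantom with planted cortical lesions
#'
#' Builds a deformed concentric-shell head phantom: a white-matter core
#' wrapped in a grey-matter ribbon, surrounded by a CSF layer, inside a
#' background field of view. Hyperintense lesions are planted relative to
#' the grey-matter ribbon according to their requested type: entirely inside
#' the ribbon (`intracortical`), in white matter touching the ribbon
#' (`juxtacortical`), or straddling the interface (`mixed`). Lobes (frontal,
#' temporal, parietal, occipital) are assigned by a deterministic angular
#' partition of the axial plane into four sectors, standing in for an atlas
#' parcellation.
#'
#' The anatomy is an ellipsoid whose normalized radius is modulated by a few
#' random low-order angular harmonics, so that no two seeds give the same
#' shapes, while a fixed seed reproduces the phantom voxel for voxel.
#'
#' @param shape integer extent per axis (voxels), each >= 32.
#' @param spacing voxel size per axis (mm).
#' @param nLesions number of lesions to plant.
#' @param lesionRadiusRange lesion radius range (mm); sampled uniformly.
#' @param lesionTypes types to cycle through when planting.
#' @param tissueTable per-tissue relaxation table; see [defaultTissueTable()].
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @return a [TissuePhantom-class].
#' @examples
#' ph <- makeTissuePhantom(c(32, 32, 32), nLesions = 2, seed = 1)
#' table(tissueLabels(ph))
#' @export
makeTissuePhantom <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                              nLesions = 6L,
                              lesionRadiusRange = c(1.5, 3),
                              lesionTypes = c("intracortical",
                                              "juxtacortical", "mixed"),
                              tissueTable = defaultTissueTable(),
                              seed = NULL) {
  shape <- as.integer(rep(shape, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(shape < 32L)) stop("shape must be >= 32 voxels per axis")
  if (nLesions < 0L) stop("nLesions must be >= 0")
  stopifnot(all(lesionTypes %in% c("intracortical", "juxtacortical",
                                   "mixed")))
  withSeed(seed, {
    extent <- shape * spacing
    ctr <- (shape + 1) / 2 * spacing      # mm, voxel centers at i*spacing
    semi <- extent / 2 * c(0.84, 0.80, 0.76)
    # random low-order angular modulation of the outer radius
    eps <- runif(3, 0.02, 0.06)
    nf <- sample(2:4, 3, replace = TRUE)
    phs <- runif(6, 0, 2 * pi)
    # voxel-center coordinates in mm, relative to the centre
    gx <- (seq_len(shape[1]) * spacing[1] - ctr[1]) / semi[1]
    gy <- (seq_len(shape[2]) * spacing[2] - ctr[2]) / semi[2]
    gz <- (seq_len(shape[3]) * spacing[3] - ctr[3]) / semi[3]
    X <- array(gx, shape)
    Y <- array(rep(gy, each = shape[1]), shape)
    Z <- array(rep(gz, each = shape[1] * shape[2]), shape)
    r <- sqrt(X^2 + Y^2 + Z^2)
    theta <- atan2(Y, X)
    phi <- acos(ifelse(r > 0, pmin(pmax(Z / pmax(r, 1e-12), -1), 1), 1))
    gmod <- 1 + eps[1] * sin(nf[1] * theta + phs[1]) * sin(phi + phs[2]) +
      eps[2] * sin(nf[2] * phi + phs[3]) +
      eps[3] * sin(nf[3] * theta + phs[4]) * cos(2 * phi + phs[5])
    rho <- r * gmod
    labels <- array(0L, shape)
    labels[rho <= 1.0] <- 1L   # CSF layer
    labels[rho <= 0.90] <- 2L  # grey-matter ribbon
    labels[rho <= 0.75] <- 3L  # white-matter core
    brain <- rho <= 1.0
    lesionMask <- array(0L, shape)
    meta <- data.frame(lesion_id = integer(), type = character(),
                       lobe = character(), cx = numeric(), cy = numeric(),
                       cz = numeric(), radius_mm = numeric(),
                       stringsAsFactors = FALSE)
    if (nLesions > 0L) {
      types <- rep(lesionTypes, length.out = nLesions)
      for (i in seq_len(nLesions)) {
        radius <- runif(1, lesionRadiusRange[1], lesionRadiusRange[2])
        placed <- FALSE
        for (attempt in 1:200) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))    # direction in mm space
          # normalized radius along the ray p = ctr + s*u:
          # rho(s) = s * |u/semi| * g(angles of u)
          nrm <- sqrt(sum((u / semi)^2))
          th <- atan2(u[2] / semi[2], u[1] / semi[1])
          ph2 <- acos(pmin(pmax((u[3] / semi[3]) / nrm, -1), 1))
          g1 <- 1 + eps[1] * sin(nf[1] * th + phs[1]) * sin(ph2 + phs[2]) +
            eps[2] * sin(nf[2] * ph2 + phs[3]) +
            eps[3] * sin(nf[3] * th + phs[4]) * cos(2 * ph2 + phs[5])
          sPer <- 1 / (nrm * g1)            # mm per unit of normalized rho
          thick <- 0.15 * sPer              # GM ribbon thickness (mm)
          if (types[i] == "intracortical" && radius > thick) next
          rhoT <- switch(types[i],
            intracortical = 0.825,
            # centre in white matter with the sphere touching the ribbon
            juxtacortical = max(0.75 - 0.8 * radius / sPer, 0.05),
            mixed = 0.75)
          cen <- ctr + rhoT * sPer * u      # mm
          cvox <- round(cen / spacing)
          if (any(cvox < 2) || any(cvox > shape - 1)) next
          # keep lesions separated so components stay individually
          # identifiable in the ground truth
          if (nrow(meta) > 0) {
            dPrev <- sqrt(colSums((t(as.matrix(meta[, c("cx", "cy", "cz")]))
                                   * spacing - cen)^2))
            if (any(dPrev < meta$radius_mm + radius + 2 * max(spacing)))
              next
          }
          # voxelize the sphere on a bounding box
          rv <- ceiling(radius / spacing)
          idx <- lapply(1:3, function(a)
            max(1, cvox[a] - rv[a] - 1):min(shape[a], cvox[a] + rv[a] + 1))
          sub <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
          dmm <- sweep(sweep(sub, 2, cvox), 2, spacing, `*`)
          inside <- rowSums(dmm^2) <= radius^2
          sel <- sub[inside, , drop = FALSE]
          lin <- sel[, 1] + shape[1] * (sel[, 2] - 1) +
            shape[1] * shape[2] * (sel[, 3] - 1)
          lin <- lin[brain[lin] & lesionMask[lin] == 0L]
          if (length(lin) == 0L) next
          lesionMask[lin] <- i
          labels[lin] <- 4L
          az <- atan2(cen[2] - ctr[2], cen[1] - ctr[1]) * 180 / pi
          lobe <- if (az >= -45 && az < 45) "frontal"
            else if (az >= 45 && az < 135) "temporal"
            else if (az >= -135 && az < -45) "parietal"
            else "occipital"
          meta <- rbind(meta, data.frame(
            lesion_id = i, type = types[i], lobe = lobe,
            cx = cvox[1], cy = cvox[2], cz = cvox[3], radius_mm = radius,
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place a ", types[i], " lesion of radius ",
               signif(radius, 3),
               " mm: radius exceeds the grey-matter ribbon thickness")
      }
    }
    new("TissuePhantom", labels = labels, spacing = spacing,
        tissueTable = tissueTable, lesionMask = lesionMask,
        lesionMeta = meta, brainMask = brain)
  })
}

#' Simulate an MR contrast from a tissue phantom
#'
#' Maps every tissue class to its steady-state signal under the given
#' sequence (spin echo, inversion recovery, or double inversion recovery;
#' see [longitudinalDIR()] for the DIR convention) and adds zero-mean
#' Gaussian noise. The noise standard deviation is expressed as a fraction
#' of the grey-matter signal of the tissue table, so noise levels are
#' comparable across contrasts; background voxels carry noise only (their
#' proton density is zero).
#'
#' @param phantom a [TissuePhantom-class].
#' @param seq a [SequenceParams-class].
#' @param noiseSd noise standard deviation as a fraction of the mean
#'   grey-matter signal; 0 disables noise.
#' @param seed RNG seed for the noise draw.
#' @return numeric 3D array of signal intensities.
#' @export
simulateSequence <- function(phantom, seq, noiseSd = 0, seed = NULL) {
  stopifnot(is(phantom, "TissuePhantom"), is(seq, "SequenceParams"))
  tt <- phantom@tissueTable
  sig <- tissueSignal(seq, tt$t1, tt$t2, tt$pd)
  if (any(!is.finite(sig))) stop("non-finite tissue signal")
  lut <- numeric(max(tt$label) + 1L)
  lut[tt$label + 1L] <- sig
  img <- array(lut[phantom@labels + 1L], dim(phantom@labels))
  if (noiseSd > 0) {
    gmSig <- sig[match("GM", tt$name)]
    withSeed(seed, {
      img <- img + array(rnorm(length(img), sd = noiseSd * gmSig),
                         dim(img))
    })
  }
  img
}

#' Simulate and normalize the full channel stack of one phantom
#'
#' Convenience bridge from phantom to training data: simulates the T1, PD
#' and T2 predictor channels and the DIR target channel, normalizes each
#' with [normalizeIntensity()] over the brain mask, and stacks them into a
#' [ChannelStack-class].
#'
#' @param phantom a [TissuePhantom-class].
#' @param noiseSd per-channel noise level, as in [simulateSequence()].
#' @param seed RNG seed (one independent draw per channel).
#' @param sequences named list of [SequenceParams-class] with entries
#'   `T1`, `PD`, `T2`, `DIR`.
#' @return a [ChannelStack-class] with channels `T1`, `PD`, `T2`, `DIR`,
#'   all normalized to [-1, 1].
#' @export
simulateChannelStack <- function(phantom, noiseSd = 0, seed = NULL,
                                 sequences = NULL) {
  stopifnot(is(phantom, "TissuePhantom"))
  if (is.null(sequences)) {
    sequences <- list(
      T1 = defaultSequenceParams("T1"),
      PD = defaultSequenceParams("PD"),
      T2 = defaultSequenceParams("T2"),
      DIR = defaultSequenceParams("DIR",
                                  tissueTable = phantom@tissueTable))
  }
  stopifnot(all(c("T1", "PD", "T2", "DIR") %in% names(sequences)))
  chans <- c("T1", "PD", "T2", "DIR")
  seeds <- subSeeds(seed %||% 0L, length(chans))
  shape <- dim(phantom@labels)
  data <- array(0, c(shape, length(chans)))
  for (i in seq_along(chans)) {
    raw <- simulateSequence(phantom, sequences[[chans[i]]], noiseSd,
                            seed = if (is.null(seed)) NULL else seeds[i])
    data[, , , i] <- normalizeIntensity(raw, phantom@brainMask)@data
  }
  aff <- diag(c(phantom@spacing, 1))
  new("ChannelStack", data = data, channels = chans,
      spacing = phantom@spacing, mask = phantom@brainMask, affine = aff)
}

#' Write a phantom to disk
#'
#' Writes the label volume, lesion id mask and brain mask as NIfTI-1 files,
#' the lesion annotations as CSV (`lesion_id`, `type`, `lobe`, centroid in
#' mm, `volume_mm3`), and a sidecar JSON recording the coordinate
#' convention.
#'
#' @param phantom a [TissuePhantom-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "TissuePhantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- diag(c(phantom@spacing, 1))
  paths <- c(
    labels = file.path(dir, "labels.nii.gz"),
    lesion_mask = file.path(dir, "lesion_mask.nii.gz"),
    brain_mask = file.path(dir, "brain_mask.nii.gz"),
    lesion_meta = file.path(dir, "lesion_meta.csv"),
    sidecar = file.path(dir, "lesion_meta.json"))
  writeVolume(phantom@labels, paths["labels"], affine = aff)
  writeVolume(phantom@lesionMask, paths["lesion_mask"], affine = aff)
  writeVolume(phantom@brainMask + 0L, paths["brain_mask"], affine = aff)
  meta <- phantom@lesionMeta
  vox <- prod(phantom@spacing)
  n <- if (nrow(meta)) tabulate(phantom@lesionMask[phantom@lesionMask > 0],
                                nbins = max(meta$lesion_id)) else integer()
  out <- data.frame(
    lesion_id = meta$lesion_id, type = meta$type, lobe = meta$lobe,
    centroid_x = meta$cx * phantom@spacing[1],
    centroid_y = meta$cy * phantom@spacing[2],
    centroid_z = meta$cz * phantom@spacing[3],
    volume_mm3 = if (nrow(meta)) n[meta$lesion_id] * vox else numeric())
  write.csv(out, paths["lesion_meta"], row.names = FALSE)
  jsonlite::write_json(
    list(coordinate_convention =
           "1-based voxel index times spacing; axes as stored",
         units = "mm"),
    paths["sidecar"], auto_unbox = TRUE)
  invisible(paths)
}
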