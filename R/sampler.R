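#' Sample patch-center voxels uniformly inside a brain mask
#'
#' Draws patch centers with replacement, uniformly over the `TRUE` voxels
#' of the mask, so every training patch is centred on brain tissue.
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param n number of centers to draw (> 0).
#' @param seed RNG seed.
#' @return integer matrix (n x 3) of 1-based voxel coordinates.
#' @export
samplePatchCenters <- function(mask, n, seed = NULL) {
  stopifnot3d(mask, "mask")
  if (n <= 0) stop("n must be > 0")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  withSeed(seed, {
    sel <- idx[sample.int(length(idx), n, replace = TRUE)]
    arrayInd(sel, dim(mask))
  })
}

#' Extract a co-located predictor/target patch pair
#'
#' Cuts a cubic patch of edge `size` around `center` from every channel of
#' the stack; the patch spans `center - size/2` to `center + size/2 - 1`
#' (half-open upper bound). Voxels outside the volume are zero-padded.
#' Channels other than `targetChannel` become the predictor stack.
#'
#' @param stack a [ChannelStack-class] containing predictor channels and
#'   the target channel.
#' @param center 1-based voxel coordinate (length 3).
#' @param size patch edge length; even, >= 16.
#' @param targetChannel name of the target channel (default `"DIR"`).
#' @return a [PatchPair-class].
#' @export
extractPatch <- function(stack, center, size, targetChannel = "DIR") {
  stopifnot(is(stack, "ChannelStack"), length(center) == 3L)
  if (size %% 2L != 0L || size < 16L) stop("size must be even and >= 16")
  if (!targetChannel %in% stack@channels)
    stop("stack has no channel named ", targetChannel)
  shape <- dim(stack@data)[1:3]
  lo <- as.integer(center) - size %/% 2L
  pred <- setdiff(seq_along(stack@channels),
                  match(targetChannel, stack@channels))
  out <- array(0, c(size, size, size, length(stack@channels)))
  src <- lapply(1:3, function(a) {
    s <- (lo[a]):(lo[a] + size - 1L)
    keep <- s >= 1L & s <= shape[a]
    list(src = s[keep], dst = which(keep))
  })
  if (all(vapply(src, function(s) length(s$src) > 0L, logical(1))))
    out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst, ] <-
      stack@data[src[[1]]$src, src[[2]]$src, src[[3]]$src, , drop = FALSE]
  new("PatchPair",
      predictors = out[, , , pred, drop = FALSE],
      target = out[, , , match(targetChannel, stack@channels)],
      center = as.numeric(center),
      meta = list(channels = stack@channels[pred]))
}

# Gamma correction on [-1, 1] data: remap to [0, 1], exponentiate, map
# back. Exponent 1 is the identity.
gammaCorrect <- function(x, gamma) {
  p01 <- pmin(pmax((x + 1) / 2, 0), 1)
  p01^gamma * 2 - 1
}

#' Stochastically augment a patch pair
#'
#' Applies the training-time augmentation scheme: per-axis mirroring
#' (probability `pMirror` each), a combined rotation + scaling resample
#' (probability `pRotScale`; per-axis angles and scale factors drawn
#' uniformly from the configured ranges; cubic spline interpolation, values
#' re-clipped to [-1, 1]), both applied identically to predictors and
#' target, followed by predictor-only intensity operations: per-channel
#' gamma correction, additive Gaussian noise, shared-sigma Gaussian blur,
#' and zeroing of one random channel, each triggered independently. When
#' gamma, noise or blur fired, predictor channels are re-standardized
#' (z-scored over the patch, divided by four, clipped) before use, since
#' those operations shift the intensity distribution the network expects;
#' channels with (near-)zero variance are left untouched.
#'
#' @param pair a [PatchPair-class] with values in [-1, 1].
#' @param params an [AugmentParams-class].
#' @param seed RNG seed; a fixed seed reproduces the augmentation exactly.
#' @return an augmented [PatchPair-class]; `meta$ops` records which
#'   operations fired.
#' @export
augmentPatch <- function(pair, params = new("AugmentParams"), seed = NULL) {
  stopifnot(is(pair, "PatchPair"), is(params, "AugmentParams"))
  validObject(params)
  withSeed(seed, {
    pred <- pair@predictors
    targ <- pair@target
    nc <- dim(pred)[4]
    S <- dim(targ)[1]
    ops <- character()
    # mirroring, per axis, predictors and target alike
    flips <- runif(3) < params@pMirror
    for (a in which(flips)) {
      idx <- rev(seq_len(dim(targ)[a]))
      targ <- switch(a, targ[idx, , , drop = FALSE],
                     targ[, idx, , drop = FALSE],
                     targ[, , idx, drop = FALSE])
      pred <- switch(a, pred[idx, , , , drop = FALSE],
                     pred[, idx, , , drop = FALSE],
                     pred[, , idx, , drop = FALSE])
      ops <- c(ops, paste0("mirror", c("X", "Y", "Z")[a]))
    }
    dim(targ) <- c(S, S, S)
    # combined rotation + scaling about the patch center
    if (runif(1) < params@pRotScale) {
      ang <- runif(3, params@angleRange[1], params@angleRange[2]) * pi / 180
      scl <- runif(3, params@scaleRange[1], params@scaleRange[2])
      cx <- (S + 1) / 2 - 1              # 0-based center
      R <- rotationMatrix3(ang) %*% diag(scl)
      Minv <- solve(R)                   # target -> source mapping
      A <- cbind(Minv, as.numeric(cx - Minv %*% rep(cx, 3)))
      targ <- array(.affineResample(as.double(targ), dim(targ), A,
                                    dim(targ), 3L), dim(targ))
      for (ch in seq_len(nc))
        pred[, , , ch] <- .affineResample(as.double(pred[, , , ch]),
                                          c(S, S, S), A, c(S, S, S), 3L)
      targ[targ > 1] <- 1; targ[targ < -1] <- -1
      pred[pred > 1] <- 1; pred[pred < -1] <- -1
      ops <- c(ops, "rotscale")
    }
    # predictor-only intensity augmentation
    distorted <- FALSE
    if (runif(1) < params@pGamma) {
      gam <- runif(nc, params@gammaRange[1], params@gammaRange[2])
      for (ch in seq_len(nc))
        pred[, , , ch] <- gammaCorrect(pred[, , , ch], gam[ch])
      distorted <- TRUE
      ops <- c(ops, "gamma")
    }
    if (runif(1) < params@pNoise) {
      pred <- pred + array(rnorm(length(pred), sd = params@noiseSd),
                           dim(pred))
      distorted <- TRUE
      ops <- c(ops, "noise")
    }
    if (runif(1) < params@pBlur) {
      sig <- runif(1, params@blurSigmaRange[1], params@blurSigmaRange[2])
      for (ch in seq_len(nc))
        pred[, , , ch] <- .gaussianBlur3d(as.double(pred[, , , ch]),
                                          c(S, S, S), sig)
      distorted <- TRUE
      ops <- c(ops, "blur")
    }
    if (distorted) {
      for (ch in seq_len(nc)) {
        v <- pred[, , , ch]
        s <- sd(v)
        if (is.finite(s) && s > 1e-12) {
          v <- (v - mean(v)) / s / 4
          v[v > 1] <- 1; v[v < -1] <- -1
          pred[, , , ch] <- v
        }
      }
    }
    if (runif(1) < params@pChannelZero) {
      ch <- sample.int(nc, 1L)
      pred[, , , ch] <- 0
      ops <- c(ops, paste0("zero:", ch))
    }
    new("PatchPair", predictors = pred, target = targ,
        center = pair@center, meta = c(pair@meta, list(ops = ops)))
  })
}

# Rotation matrix from per-axis angles (radians), composed Rz %*% Ry %*% Rx.
rotationMatrix3 <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Samples per epoch from the total brain volume
#'
#' The number of patches presented per training epoch:
#' `floor(total brain voxels / patchEdge^3) * multiplier`, pooling the
#' brain masks of all training subjects.
#'
#' @param brainMasks list of logical 3D arrays (or a single array).
#' @param patchEdge cubic patch edge length (voxels).
#' @param multiplier oversampling multiplier.
#' @return integer sample count (possibly 0 for volumes smaller than one
#'   patch).
#' @export
epochSize <- function(brainMasks, patchEdge = 128, multiplier = 8) {
  if (is.array(brainMasks)) brainMasks <- list(brainMasks)
  stopifnot(length(brainMasks) > 0)
  total <- sum(vapply(brainMasks, function(m) sum(m != 0), numeric(1)))
  as.integer(floor(total / patchEdge^3) * multiplier)
}
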