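# Shared fixtures, built in code at test time.

# Small phantom suitable for 32^3 tests (thin ribbon -> small lesions).
smallPhantom <- function(seed = 11, nLesions = 4L, shape = c(32, 32, 32),
                         radius = c(1.2, 2)) {
  makeTissuePhantom(shape, nLesions = nLesions,
                    lesionRadiusRange = radius, seed = seed)
}

# Toy network configuration used for fast structural checks.
tinyConfig <- function(...) {
  args <- modifyList(
    list(depth = 3L, baseFilters = 8L, inChannels = 3L, patchEdge = 16L,
         discStages = 2L, discBaseFilters = 8L, epochs = 1L, lr = 1e-3),
    list(...))
  do.call(methods::new, c(list("NetworkConfig"), args))
}

# Build a ChannelStack directly from arrays (channels last).
stackFromArrays <- function(..., mask = NULL, spacing = c(1, 1, 1)) {
  chans <- list(...)
  d <- dim(chans[[1]])
  data <- array(0, c(d, length(chans)))
  for (i in seq_along(chans)) data[, , , i] <- chans[[i]]
  if (is.null(mask)) mask <- array(TRUE, d)
  new("ChannelStack", data = data, channels = names(chans),
      spacing = spacing, mask = mask, affine = diag(c(spacing, 1)))
}

# AugmentParams with every probability zero except those supplied.
augmentOff <- function(...) {
  p <- new("AugmentParams", pMirror = 0, pRotScale = 0, pGamma = 0,
           pNoise = 0, pBlur = 0, pChannelZero = 0)
  args <- list(...)
  for (nm in names(args)) slot(p, nm) <- args[[nm]]
  p
}

recFromPoints <- function(P, source, subject = "s") {
  data.frame(subject_id = subject, lesion_id = seq_len(nrow(P)),
             centroid_x = P[, 1], centroid_y = P[, 2], centroid_z = P[, 3],
             area_mm2 = 5, volume_mm3 = 1, type = "mixed",
             lobe = "frontal", source = source, stringsAsFactors = FALSE)
}

# brute-force maximum matching under the radius over all injections of
# the smaller point set into the larger one
bruteBestMatch <- function(A, C, tol) {
  na <- nrow(A); nc <- nrow(C)
  D <- as.matrix(dist(rbind(A, C)))[seq_len(na), na + seq_len(nc),
                                    drop = FALSE]
  perm <- function(v, k) if (k == 0) list(integer()) else
    unlist(lapply(seq_along(v), function(i)
      lapply(perm(v[-i], k - 1), function(p) c(v[i], p))),
      recursive = FALSE)
  small <- min(na, nc); big <- max(na, nc)
  best <- 0
  for (p in perm(seq_len(big), small)) {
    pairs <- if (na <= nc) cbind(seq_len(na), p)
      else cbind(p, seq_len(nc))
    best <- max(best, sum(D[pairs] <= tol))
  }
  best
}

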