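#' Build the U-shaped 3D translation generator
#'
#' Constructs the encoder-decoder generator: each encoder level halves the
#' spatial extent with a stride-2 convolution and doubles the filter count
#' starting from `baseFilters`; the decoder mirrors the encoder with
#' nearest-neighbour upsampling followed by convolution, concatenating the
#' same-resolution encoder activation (skip connection) before a second
#' convolution. Every convolution is followed by instance normalization and
#' a leaky ReLU with slope `leakySlope`; the final convolution maps to one
#' channel through a tanh, bounding the output in [-1, 1]. Input spatial
#' extents must be divisible by `2^(depth - 1)`; the output has the same
#' spatial shape as the input.
#'
#' @param config a [NetworkConfig-class].
#' @param seed RNG seed for weight initialization.
#' @return a [ConvNet3D-class] of kind `"generator"`.
#' @export
buildGenerator <- function(config = new("NetworkConfig"), seed = NULL) {
  validObject(config)
  d <- config@depth; f0 <- config@baseFilters; k <- config@kernel
  sl <- config@leakySlope
  withSeed(seed, {
    blocks <- list()
    fl <- f0 * 2^(seq_len(d) - 1L)
    for (i in seq_len(d)) {
      cin <- if (i == 1L) config@inChannels else fl[i - 1L]
      blocks[[sprintf("enc%da", i)]] <- initBlock(cin, fl[i], k, sl)
      blocks[[sprintf("enc%db", i)]] <- initBlock(fl[i], fl[i], k, sl)
    }
    for (i in rev(seq_len(d - 1L))) {
      blocks[[sprintf("dec%da", i)]] <- initBlock(fl[i + 1L], fl[i], k, sl)
      blocks[[sprintf("dec%db", i)]] <- initBlock(2L * fl[i], fl[i], k, sl)
    }
    blocks[["final"]] <- initConv(f0, 1L, k)
    new("ConvNet3D", kind = "generator", config = config, layers = blocks)
  })
}

#' Build the PatchGAN discriminator
#'
#' Constructs the conditional discriminator that judges whether a candidate
#' DIR volume is conventionally acquired or artificially generated given
#' the predictor channels: the candidate is channel-concatenated with the
#' predictors, passed through `discStages` stride-2 convolutions (instance
#' normalization from the second stage on, leaky ReLU throughout) and a
#' final one-strided convolution with sigmoid activation, producing a map
#' of validity scores in (0, 1), each conditioned on a limited receptive
#' field of the input rather than the whole volume.
#'
#' @param config a [NetworkConfig-class].
#' @param seed RNG seed for weight initialization.
#' @return a [ConvNet3D-class] of kind `"discriminator"`.
#' @export
buildDiscriminator <- function(config = new("NetworkConfig"), seed = NULL) {
  validObject(config)
  s <- config@discStages; f0 <- config@discBaseFilters
  k <- config@discKernel; sl <- config@leakySlope
  withSeed(seed, {
    blocks <- list()
    fl <- f0 * 2^(seq_len(s) - 1L)
    for (i in seq_len(s)) {
      cin <- if (i == 1L) config@inChannels + 1L else fl[i - 1L]
      blocks[[sprintf("disc%d", i)]] <- initBlock(cin, fl[i], k, sl,
                                                  inorm = i > 1L)
    }
    blocks[["head"]] <- initConv(fl[s], 1L, k)
    new("ConvNet3D", kind = "discriminator", config = config,
        layers = blocks)
  })
}

#' @rdname accessors
#' @export
setMethod("nParameters", "ConvNet3D", function(x, ...) {
  sum(vapply(x@layers, function(b) sum(vapply(b, length, numeric(1))),
             numeric(1)))
})

setMethod("show", "ConvNet3D", function(object) {
  cat(sprintf("ConvNet3D <%s>: %d parameter tensors in %d blocks, %d parameters\n",
              object@kind,
              sum(vapply(object@layers, length, numeric(1))),
              length(object@layers), nParameters(object)))
})

#' Receptive field of one discriminator output element
#'
#' Applies the standard receptive-field recurrence r <- r * s + (k - s)
#' backwards over the discriminator's convolution stack (stride-2 stages
#' followed by the one-strided head).
#'
#' @param config a [NetworkConfig-class].
#' @return receptive field edge length in input voxels.
#' @export
discriminatorReceptiveField <- function(config = new("NetworkConfig")) {
  r <- 1
  k <- config@discKernel
  r <- r * 1 + (k - 1)                      # one-strided head
  for (i in seq_len(config@discStages)) r <- r * 2 + (k - 2)
  as.integer(r)
}

# Generator forward pass over a (S, S, S, C) patch. Returns the tape when
# training.
generatorForward <- function(net, x, dims, train = FALSE) {
  cfg <- net@config
  d <- cfg@depth; k <- cfg@kernel; pad <- (k - 1L) %/% 2L
  sl <- cfg@leakySlope
  if (any(dims[1:3] %% 2L^(d - 1L) != 0L))
    stop("input extent must be divisible by 2^(depth-1)")
  bl <- net@layers
  tape <- list()
  skips <- list()
  h <- x; hd <- dims
  for (i in seq_len(d)) {
    nma <- sprintf("enc%da", i)
    o <- blockForward(bl[[nma]], h, hd, k, if (i == 1L) 1L else 2L, pad,
                      sl, train)
    if (train) tape[[nma]] <- o$cache
    h <- o$y; hd <- o$dims
    nmb <- sprintf("enc%db", i)
    o <- blockForward(bl[[nmb]], h, hd, k, 1L, pad, sl, train)
    if (train) tape[[nmb]] <- o$cache
    h <- o$y; hd <- o$dims
    if (i < d) skips[[i]] <- list(y = h, dims = hd)
  }
  for (i in rev(seq_len(d - 1L))) {
    o <- upsample2Forward(h, hd)
    h <- o$y; hd <- o$dims
    nma <- sprintf("dec%da", i)
    o <- blockForward(bl[[nma]], h, hd, k, 1L, pad, sl, train)
    if (train) tape[[nma]] <- o$cache
    h <- o$y; hd <- o$dims
    # concatenate the same-resolution encoder activation ahead of h
    h <- c(skips[[i]]$y, h)
    hd <- c(hd[1:3], skips[[i]]$dims[4] + hd[4])
    nmb <- sprintf("dec%db", i)
    o <- blockForward(bl[[nmb]], h, hd, k, 1L, pad, sl, train)
    if (train) tape[[nmb]] <- o$cache
    h <- o$y; hd <- o$dims
  }
  if (train) tape[["final"]] <- list(x = h, xdims = hd)
  o <- .conv3dForward(h, hd, bl$final$W, bl$final$b, k, 1L, pad)
  if (train) tape[["final"]]$odims <- o$dims
  y <- tanh(o$y)
  list(y = y, dims = o$dims, tape = tape)
}

# Backward pass matching generatorForward; dy is the gradient w.r.t. the
# tanh output. Returns parameter gradients.
generatorBackward <- function(net, fw, dy) {
  cfg <- net@config
  d <- cfg@depth; k <- cfg@kernel; pad <- (k - 1L) %/% 2L
  sl <- cfg@leakySlope
  bl <- net@layers; tape <- fw$tape
  grads <- list()
  dy <- dy * (1 - fw$y^2)                    # through tanh
  cb <- .conv3dBackward(dy, tape$final$odims, bl$final$W, tape$final$x,
                        tape$final$xdims, k, 1L, pad, TRUE)
  grads$final <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  skipGrad <- vector("list", d)
  for (i in seq_len(d - 1L)) {
    nmb <- sprintf("dec%db", i)
    o <- blockBackward(bl[[nmb]], dh, tape[[nmb]], k, 1L, pad, sl)
    grads[[nmb]] <- o$grads
    # split the concatenation: encoder skip first, decoder path second
    cSkip <- tape[[nmb]]$xdims[4] - tape[[sprintf("dec%da", i)]]$odims[4]
    nSkip <- prod(tape[[nmb]]$xdims[1:3]) * cSkip
    skipGrad[[i]] <- o$dx[seq_len(nSkip)]
    dh <- o$dx[-seq_len(nSkip)]
    nma <- sprintf("dec%da", i)
    o <- blockBackward(bl[[nma]], dh, tape[[nma]], k, 1L, pad, sl)
    grads[[nma]] <- o$grads
    dh <- upsample2Backward(o$dx, tape[[nma]]$xdims)
  }
  for (i in rev(seq_len(d))) {
    if (i < d) dh <- dh + skipGrad[[i]]
    nmb <- sprintf("enc%db", i)
    o <- blockBackward(bl[[nmb]], dh, tape[[nmb]], k, 1L, pad, sl)
    grads[[nmb]] <- o$grads
    dh <- o$dx
    nma <- sprintf("enc%da", i)
    o <- blockBackward(bl[[nma]], dh, tape[[nma]], k,
                       if (i == 1L) 1L else 2L, pad, sl, need_dx = i > 1L)
    grads[[nma]] <- o$grads
    dh <- o$dx
  }
  grads
}

# Discriminator forward on the channel-concatenated (predictors, candidate)
# input.
discriminatorForward <- function(net, x, dims, train = FALSE) {
  cfg <- net@config
  k <- cfg@discKernel; sl <- cfg@leakySlope
  bl <- net@layers
  tape <- list()
  h <- x; hd <- dims
  for (i in seq_len(cfg@discStages)) {
    nm <- sprintf("disc%d", i)
    o <- blockForward(bl[[nm]], h, hd, k, 2L, 1L, sl, train)
    if (train) tape[[nm]] <- o$cache
    h <- o$y; hd <- o$dims
  }
  if (train) tape[["head"]] <- list(x = h, xdims = hd)
  o <- .conv3dForward(h, hd, bl$head$W, bl$head$b, k, 1L, 1L)
  if (train) tape[["head"]]$odims <- o$dims
  p <- 1 / (1 + exp(-o$y))
  list(p = p, dims = o$dims, tape = tape)
}

# Backward from the gradient w.r.t. the pre-sigmoid logits (numerically
# stable for cross-entropy objectives); returns grads and the gradient
# w.r.t. the network input.
discriminatorBackward <- function(net, fw, dlogit, need_dx = FALSE) {
  cfg <- net@config
  k <- cfg@discKernel; sl <- cfg@leakySlope
  bl <- net@layers; tape <- fw$tape
  grads <- list()
  cb <- .conv3dBackward(dlogit, tape$head$odims, bl$head$W, tape$head$x,
                        tape$head$xdims, k, 1L, 1L, TRUE)
  grads$head <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  for (i in rev(seq_len(cfg@discStages))) {
    nm <- sprintf("disc%d", i)
    o <- blockBackward(bl[[nm]], dh, tape[[nm]], k, 2L, 1L, sl,
                       need_dx = i > 1L || need_dx)
    grads[[nm]] <- o$grads
    dh <- o$dx
  }
  list(grads = grads, dx = dh)
}

#' Translate a predictor patch with a generator
#'
#' Runs a forward pass of the generator in inference mode.
#'
#' @param generator a generator [ConvNet3D-class].
#' @param predictors numeric 4D array (X, Y, Z, C) in [-1, 1].
#' @return numeric 3D array in [-1, 1] of the same spatial shape.
#' @export
predictPatch <- function(generator, predictors) {
  stopifnot(is(generator, "ConvNet3D"), generator@kind == "generator")
  dims <- dim(predictors)
  stopifnot(length(dims) == 4L,
            dims[4] == generator@config@inChannels)
  fw <- generatorForward(generator, as.double(predictors), dims)
  array(fw$y, fw$dims[1:3])
}

#' Score a candidate volume with the discriminator
#'
#' @param discriminator a discriminator [ConvNet3D-class].
#' @param predictors numeric 4D array (X, Y, Z, C).
#' @param candidate numeric 3D array with the same spatial extent.
#' @return 3D array of validity scores in (0, 1), spatially reduced.
#' @export
discriminatorScore <- function(discriminator, predictors, candidate) {
  stopifnot(is(discriminator, "ConvNet3D"),
            discriminator@kind == "discriminator")
  dp <- dim(predictors)
  if (!identical(dp[1:3], dim(candidate)))
    stop("candidate and predictors must share their spatial extent")
  x <- c(as.double(predictors), as.double(candidate))
  fw <- discriminatorForward(discriminator, x, c(dp[1:3], dp[4] + 1L))
  array(fw$p, fw$dims[1:3])
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Generator loss: adversarial binary cross entropy plus weighted MAE
#'
#' Binary cross entropy of the discriminator's validity scores on the
#' generated volume against an all-ones target (the generator wants its
#' output judged real), plus `maeWeight` times the mean absolute error
#' between generated and reference volumes.
#'
#' @param validityOnFake validity score map in (0, 1).
#' @param fake,real generated and reference volumes (same shape).
#' @param maeWeight reconstruction weight.
#' @return named list with `total`, `adv` and `mae` terms.
#' @export
generatorLoss <- function(validityOnFake, fake, real, maeWeight = 100) {
  da <- dim(fake); db <- dim(real)
  if (length(fake) != length(real) ||
      (!is.null(da) && !is.null(db) && length(da) == length(db) &&
       !all(da == db)))
    stop("fake and real volumes must have the same shape")
  p <- clampProb(validityOnFake)
  adv <- -mean(log(p))
  mae <- mean(abs(fake - real))
  list(total = adv + maeWeight * mae, adv = adv, mae = mae)
}

#' Discriminator loss: mean of the real and fake binary cross entropies
#'
#' Mean of the binary cross entropy of the scores on conventionally
#' acquired volumes against ones and of the scores on generated volumes
#' against zeros.
#'
#' @param validityOnReal,validityOnFake validity score maps in (0, 1).
#' @return scalar loss.
#' @export
discriminatorLoss <- function(validityOnReal, validityOnFake) {
  pr <- clampProb(validityOnReal)
  pf <- clampProb(validityOnFake)
  (-mean(log(pr)) - mean(log(1 - pf))) / 2
}
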