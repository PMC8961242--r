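# Internal building blocks of the volumetric networks. Feature maps travel
# as numeric vectors with a dims attribute (X, Y, Z, C); parameters live in
# named lists so the Adam state can mirror their structure exactly.

EPS_INORM <- 1e-5

# He-style initialization for a conv block; gain 2/(1+slope^2) suits the
# leaky activation, plain Xavier for the linear output heads.
initConv <- function(cin, cout, k, slope = NULL) {
  fan <- cin * k^3
  sdv <- if (is.null(slope)) sqrt(1 / fan) else
    sqrt(2 / ((1 + slope^2) * fan))
  list(W = matrix(rnorm(fan * cout, sd = sdv), fan, cout),
       b = numeric(cout))
}

initBlock <- function(cin, cout, k, slope, inorm = TRUE) {
  p <- initConv(cin, cout, k, slope)
  if (inorm) { p$gamma <- rep(1, cout); p$beta <- numeric(cout) }
  p
}

# conv (+ optional instance norm) + leaky ReLU forward. Returns activation
# and a cache for the backward pass (the conv input is cached; the im2col
# matrix is recomputed in C++ during the backward pass).
blockForward <- function(par, x, dims, k, stride, pad, slope,
                         train = TRUE) {
  cv <- .conv3dForward(x, dims, par$W, par$b, k, stride, pad)
  y <- cv$y
  odims <- cv$dims
  C <- odims[4]
  N <- length(y) %/% C
  cache <- list(xdims = dims, odims = odims)
  if (train) cache$x <- x
  if (!is.null(par$gamma)) {
    ym <- matrix(y, N, C)
    mu <- colMeans(ym)
    xc <- ym - rep(mu, each = N)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + EPS_INORM)
    xhat <- xc * rep(istd, each = N)
    y <- as.vector(xhat * rep(par$gamma, each = N) +
                     rep(par$beta, each = N))
    if (train) { cache$xhat <- xhat; cache$istd <- istd }
  }
  neg <- y < 0
  y[neg] <- y[neg] * slope
  if (train) cache$neg <- neg
  list(y = y, dims = odims, cache = cache)
}

blockBackward <- function(par, dy, cache, k, stride, pad, slope,
                          need_dx = TRUE) {
  dy[cache$neg] <- dy[cache$neg] * slope
  grads <- list()
  odims <- cache$odims
  C <- odims[4]
  N <- length(dy) %/% C
  if (!is.null(par$gamma)) {
    dym <- matrix(dy, N, C)
    grads$gamma <- colSums(dym * cache$xhat)
    grads$beta <- colSums(dym)
    dxhat <- dym * rep(par$gamma, each = N)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dy <- as.vector((dxhat - rep(m1, each = N) -
                       cache$xhat * rep(m2, each = N)) *
                      rep(cache$istd, each = N))
  }
  cb <- .conv3dBackward(dy, odims, par$W, cache$x, cache$xdims,
                        k, stride, pad, need_dx)
  grads$W <- cb$dW
  grads$b <- cb$db
  list(dx = if (need_dx) cb$dx else NULL, grads = grads)
}

# nearest-neighbour upsampling by 2 along each spatial axis
upsample2Forward <- function(x, dims) {
  a <- array(x, dims)
  a <- a[rep(seq_len(dims[1]), each = 2),
         rep(seq_len(dims[2]), each = 2),
         rep(seq_len(dims[3]), each = 2), , drop = FALSE]
  list(y = as.vector(a), dims = c(dims[1:3] * 2L, dims[4]))
}

upsample2Backward <- function(dy, odims) {
  # sum each 2x2x2 block back onto the coarse grid
  a <- array(dy, odims)
  a <- a[seq(1, odims[1], 2), , , , drop = FALSE] +
    a[seq(2, odims[1], 2), , , , drop = FALSE]
  a <- a[, seq(1, odims[2], 2), , , drop = FALSE] +
    a[, seq(2, odims[2], 2), , , drop = FALSE]
  a <- a[, , seq(1, odims[3], 2), , drop = FALSE] +
    a[, , seq(2, odims[3], 2), , drop = FALSE]
  as.vector(a)
}

# Adam optimizer over a named list-of-lists parameter structure.
adamInit <- function(params) {
  zero <- function(p) lapply(p, function(v) v * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (is.null(g)) next
      m <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g * g
      state$m[[nm]][[pn]] <- m
      state$v[[nm]][[pn]] <- v
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

accumulateGrads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) for (pn in names(g[[nm]]))
    acc[[nm]][[pn]] <- acc[[nm]][[pn]] + g[[nm]][[pn]]
  acc
}

scaleGrads <- function(g, f) {
  for (nm in names(g)) for (pn in names(g[[nm]]))
    g[[nm]][[pn]] <- g[[nm]][[pn]] * f
  g
}
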