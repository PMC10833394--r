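# Parallel conditional image-translation networks.
#
# Two U-Net generators (one per scattering component) trained against two
# patch discriminators with the conditional-GAN objective plus a
# lambda-weighted pixel-wise L1 term, followed each iteration by a joint
# product-consistency step: the two generated components are multiplied and
# pulled toward the product of the normalized ground truths with a smooth
# L1 loss. Convolutions run through compiled kernels; parameters live in
# flat named lists so optimizer state and checkpoints stay simple and
# bit-exact.

# ---- small tensor helpers (arrays laid out (H, W, C)) ---------------------

.asTensor <- function(m) {
  if (is.matrix(m)) array(m, dim = c(dim(m), 1L)) else m
}

.cbind3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.downsampleSum <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  p1 <- seq(1, d[2], 2); p2 <- seq(2, d[2], 2)
  dy[o1, p1, , drop = FALSE] + dy[o2, p1, , drop = FALSE] +
    dy[o1, p2, , drop = FALSE] + dy[o2, p2, , drop = FALSE]
}

.lrelu <- function(z, a = 0.2) pmax(z, 0) + a * pmin(z, 0)
.lreluDeriv <- function(z, a = 0.2) (z > 0) + a * (z <= 0)

# ---- configuration --------------------------------------------------------

#' Network and training configuration
#'
#' Defaults scale the canonical encoder-decoder translation setup down to
#' the configured grid: `depth` stride-2 encoder convolutions (4x4),
#' mirrored nearest-neighbour-upsample + 3x3-conv decoder blocks with skip
#' concatenation, 50% dropout in the decoder as the generator's noise
#' source, and a 3-layer patch discriminator conditioned by channel
#' concatenation.
#'
#' @param gridSize input/output grid side (pixels).
#' @param baseChannels channel width of the first encoder level.
#' @param depth number of stride-2 encoder levels.
#' @param dropout generator dropout rate (the latent noise source z).
#' @param lambdaL1 weight of the pixel-wise L1 term (default 100).
#' @param smoothL1Beta transition point of the smooth L1 loss (default 1).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return configuration list.
#' @export
ganConfig <- function(gridSize = 64L, baseChannels = 8L, depth = 4L,
                      dropout = 0.5, lambdaL1 = 100, smoothL1Beta = 1,
                      lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  stopifnot(gridSize %% 2^depth == 0, lambdaL1 >= 0, smoothL1Beta > 0,
            dropout >= 0, dropout < 1)
  encCh <- pmin(8L, 2L^(seq_len(depth) - 1L)) * baseChannels
  list(gridSize = as.integer(gridSize), baseChannels = as.integer(baseChannels),
       depth = as.integer(depth), encCh = as.integer(encCh),
       dropout = dropout, lambdaL1 = lambdaL1, smoothL1Beta = smoothL1Beta,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

.initConv <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, sd = 0.02),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

.initGenerator <- function(cfg) {
  p <- list()
  d <- cfg$depth
  cin <- 1L
  for (k in seq_len(d)) {
    l <- .initConv(4, 4, cin, cfg$encCh[k])
    p[[sprintf("enc%d.w", k)]] <- l$w
    p[[sprintf("enc%d.b", k)]] <- l$b
    cin <- cfg$encCh[k]
  }
  for (k in seq_len(d)) {
    cin <- if (k == 1) cfg$encCh[d] else 2L * cfg$encCh[d - k + 1L]
    cout <- if (k == d) cfg$baseChannels else cfg$encCh[d - k]
    l <- .initConv(3, 3, cin, cout)
    p[[sprintf("dec%d.w", k)]] <- l$w
    p[[sprintf("dec%d.b", k)]] <- l$b
  }
  cin <- 2L * cfg$baseChannels   # last decoder concat with enc1... see forward
  l <- .initConv(3, 3, cin, 1L)
  p[["out.w"]] <- l$w
  p[["out.b"]] <- l$b
  p
}

.initDiscriminator <- function(cfg) {
  c1 <- cfg$baseChannels
  p <- list()
  l <- .initConv(4, 4, 2L, c1); p[["d1.w"]] <- l$w; p[["d1.b"]] <- l$b
  l <- .initConv(4, 4, c1, 2L * c1); p[["d2.w"]] <- l$w; p[["d2.b"]] <- l$b
  l <- .initConv(4, 4, 2L * c1, 1L); p[["d3.w"]] <- l$w; p[["d3.b"]] <- l$b
  p
}

# ---- generator forward / backward ----------------------------------------

# Skip wiring: decoder block k upsamples the running feature map, convolves,
# applies ReLU (+ dropout on all but the last block), then concatenates the
# encoder activation at the matching resolution (enc d-k, and the one
# before the final output conv concatenates enc1's resolution mate). The
# final 3x3 conv + tanh maps to one channel in [-1, 1].
.gForward <- function(params, x, cfg, sampleDropout = FALSE, keepCache = FALSE) {
  d <- cfg$depth
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  h <- .asTensor(x)
  xin <- h
  for (k in seq_len(d)) {
    z <- cpp_conv2d(if (k == 1) xin else h, params[[sprintf("enc%d.w", k)]],
                    params[[sprintf("enc%d.b", k)]], 2L, 1L)
    a <- .lrelu(z)
    if (keepCache) cache$enc[[k]] <- list(x = if (k == 1) xin else h, z = z, a = a)
    else cache$enc[[k]] <- list(a = a)
    h <- a
  }
  for (k in seq_len(d)) {
    up <- .upsample2(h)
    z <- cpp_conv2d(up, params[[sprintf("dec%d.w", k)]],
                    params[[sprintf("dec%d.b", k)]], 1L, 1L)
    a <- pmax(z, 0)
    mask <- NULL
    if (sampleDropout && cfg$dropout > 0 && k < d) {
      mask <- array((runif(length(a)) >= cfg$dropout) / (1 - cfg$dropout),
                    dim = dim(a))
      a <- a * mask
    }
    skip <- d - k
    h <- if (skip >= 1) .cbind3(a, cache$enc[[skip]]$a) else a
    if (keepCache) cache$dec[[k]] <- list(up = up, z = z, mask = mask,
                                          ca = dim(a)[3])
  }
  # final: concatenate the full-resolution decoder output with itself is
  # pointless; instead the last block has no encoder mate at full
  # resolution, so pair it with the network input channel broadcast
  h <- .cbind3(h, array(xin, dim = c(dim(xin)[1], dim(xin)[2],
                                     2L * cfg$baseChannels - dim(h)[3])))
  zo <- cpp_conv2d(h, params[["out.w"]], params[["out.b"]], 1L, 1L)
  y <- tanh(zo)
  if (keepCache) {
    cache$hFinal <- h
    cache$y <- y
    cache$xin <- xin
  }
  list(y = y, cache = cache)
}

.gBackward <- function(params, cache, dy, cfg) {
  d <- cfg$depth
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  y <- cache$y
  dzo <- dy * (1 - y * y)
  bk <- cpp_conv2d_backward(cache$hFinal, params[["out.w"]], dzo, 1L, 1L)
  grads[["out.w"]] <- bk$dw
  grads[["out.b"]] <- bk$db
  nExtra <- dim(cache$hFinal)[3] - cfg$baseChannels
  dh <- bk$dx[, , seq_len(cfg$baseChannels), drop = FALSE]
  dEnc <- vector("list", d)
  for (k in rev(seq_len(d))) {
    dc <- cache$dec[[k]]
    skip <- d - k
    if (skip >= 1) {
      da <- dh[, , seq_len(dc$ca), drop = FALSE]
      dskip <- dh[, , (dc$ca + 1):dim(dh)[3], drop = FALSE]
      dEnc[[skip]] <- if (is.null(dEnc[[skip]])) dskip else dEnc[[skip]] + dskip
    } else da <- dh
    if (!is.null(dc$mask)) da <- da * dc$mask
    dz <- da * (dc$z > 0)
    bk <- cpp_conv2d_backward(dc$up, params[[sprintf("dec%d.w", k)]], dz, 1L, 1L)
    grads[[sprintf("dec%d.w", k)]] <- bk$dw
    grads[[sprintf("dec%d.b", k)]] <- bk$db
    din <- .downsampleSum(bk$dx)
    if (k == 1) dEnc[[d]] <- if (is.null(dEnc[[d]])) din else dEnc[[d]] + din
    else dh <- din
  }
  for (k in rev(seq_len(d))) {
    ec <- cache$enc[[k]]
    dz <- dEnc[[k]] * .lreluDeriv(ec$z)
    bk <- cpp_conv2d_backward(ec$x, params[[sprintf("enc%d.w", k)]], dz, 2L, 1L)
    grads[[sprintf("enc%d.w", k)]] <- bk$dw
    grads[[sprintf("enc%d.b", k)]] <- bk$db
    if (k > 1)
      dEnc[[k - 1]] <- if (is.null(dEnc[[k - 1]])) bk$dx else dEnc[[k - 1]] + bk$dx
  }
  grads
}

# ---- discriminator forward / backward ------------------------------------

.dForward <- function(params, candidate, condition, keepCache = FALSE) {
  x <- .cbind3(.asTensor(candidate), .asTensor(condition))
  z1 <- cpp_conv2d(x, params[["d1.w"]], params[["d1.b"]], 2L, 1L)
  a1 <- .lrelu(z1)
  z2 <- cpp_conv2d(a1, params[["d2.w"]], params[["d2.b"]], 2L, 1L)
  a2 <- .lrelu(z2)
  z3 <- cpp_conv2d(a2, params[["d3.w"]], params[["d3.b"]], 1L, 1L)
  p <- 1 / (1 + exp(-z3))
  cache <- if (keepCache) list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                               z3 = z3, p = p) else NULL
  list(p = p, cache = cache)
}

# dp: gradient of the loss w.r.t. the probability map
.dBackward <- function(params, cache, dp) {
  grads <- list()
  dz3 <- dp * cache$p * (1 - cache$p)
  bk <- cpp_conv2d_backward(cache$a2, params[["d3.w"]], dz3, 1L, 1L)
  grads[["d3.w"]] <- bk$dw; grads[["d3.b"]] <- bk$db
  dz2 <- bk$dx * .lreluDeriv(cache$z2)
  bk <- cpp_conv2d_backward(cache$a1, params[["d2.w"]], dz2, 2L, 1L)
  grads[["d2.w"]] <- bk$dw; grads[["d2.b"]] <- bk$db
  dz1 <- bk$dx * .lreluDeriv(cache$z1)
  bk <- cpp_conv2d_backward(cache$x, params[["d1.w"]], dz1, 2L, 1L)
  grads[["d1.w"]] <- bk$dw; grads[["d1.b"]] <- bk$db
  grads$dInput <- bk$dx   # (H, W, 2): channel 1 is the candidate
  grads
}

# ---- losses ---------------------------------------------------------------

.clampP <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Conditional adversarial losses
#'
#' For patch-probability maps of the discriminator on real and generated
#' candidates, returns the discriminator loss
#' -mean(log D(real)) - mean(log(1 - D(fake))) and the (non-saturating)
#' generator loss -mean(log D(fake)).
#'
#' @param pReal,pFake probability maps in (0, 1).
#' @return list with elements `d` and `g`.
#' @export
adversarialLoss <- function(pReal, pFake) {
  if (any(pReal < 0 | pReal > 1) || any(pFake < 0 | pFake > 1))
    stop("discriminator outputs must be probabilities in (0, 1)", call. = FALSE)
  pReal <- .clampP(pReal); pFake <- .clampP(pFake)
  list(d = -mean(log(pReal)) - mean(log(1 - pFake)),
       g = -mean(log(pFake)))
}

#' Pixel-wise L1 loss
#'
#' @param generated,gt grids of identical shape.
#' @return mean absolute pixel difference.
#' @export
l1Loss <- function(generated, gt) {
  if (!all(dim(.asTensor(generated)) == dim(.asTensor(gt))))
    stop("shape mismatch", call. = FALSE)
  mean(abs(generated - gt))
}

#' Total generator loss
#'
#' adv + lambda * L1, the per-network translation objective.
#'
#' @param advTerm adversarial term.
#' @param l1Term pixel-wise L1 term.
#' @param weights list with `lambdaL1` (e.g. a [ganConfig()]).
#' @export
generatorTotalLoss <- function(advTerm, l1Term, weights = ganConfig()) {
  stopifnot(is.finite(advTerm), is.finite(l1Term))
  advTerm + weights$lambdaL1 * l1Term
}

.smoothL1 <- function(e, beta) {
  a <- abs(e)
  q <- a < beta
  q * e * e / (2 * beta) + (!q) * (a - beta / 2)
}
.smoothL1Deriv <- function(e, beta) {
  q <- abs(e) < beta
  q * e / beta + (!q) * sign(e)
}

#' Product-consistency loss
#'
#' Smooth L1 (quadratic below `beta`, linear above, with matched slope)
#' between the product of the two generated components and the product of
#' the normalized ground truths, averaged over pixels.
#'
#' @param genFF,genSRO generated component grids in [-1, 1].
#' @param gtFF,gtSRO normalized ground-truth grids.
#' @param weights list with `smoothL1Beta` (e.g. a [ganConfig()]).
#' @export
productConsistencyLoss <- function(genFF, genSRO, gtFF, gtSRO,
                                   weights = ganConfig()) {
  dims <- lapply(list(genFF, genSRO, gtFF, gtSRO), function(x) dim(.asTensor(x)))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("shape mismatch", call. = FALSE)
  e <- genFF * genSRO - gtFF * gtSRO
  mean(.smoothL1(e, weights$smoothL1Beta))
}

# ---- Adam -----------------------------------------------------------------

.adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))))
}

.adamStep <- function(params, grads, st, cfg) {
  st$t <- st$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + cfg$eps)
  }
  list(params = params, st = st)
}

# ---- training -------------------------------------------------------------

#' Initialize a training state
#'
#' Draws all network weights from N(0, 0.02^2) under the given seed.
#'
#' @param config from [ganConfig()].
#' @param seed integer seed, recorded in the state.
#' @return a [TrainState-class].
#' @export
initTrainState <- function(config = ganConfig(), seed = 1) {
  withSeed(seed, {
    gFF <- .initGenerator(config)
    gSRO <- .initGenerator(config)
    dFF <- .initDiscriminator(config)
    dSRO <- .initDiscriminator(config)
  })
  new("TrainState", config = config, gFF = gFF, gSRO = gSRO,
      dFF = dFF, dSRO = dSRO,
      opt = list(gFF = .adamInit(gFF), gSRO = .adamInit(gSRO),
                 dFF = .adamInit(dFF), dSRO = .adamInit(dSRO),
                 gFFprod = .adamInit(gFF), gSROprod = .adamInit(gSRO)),
      epoch = 0L, history = data.frame(), seed = as.integer(seed))
}

.checkFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("non-finite ", what, " encountered; aborting training", call. = FALSE)
  x
}

# One branch of training step (a): update a discriminator on (GT | clean)
# as real vs (G(artefact input, z) | clean) as fake; the generator is frozen.
.trainDStep <- function(gp, dp, dopt, xArt, xClean, gt, cfg) {
  fake <- .gForward(gp, xArt, cfg, sampleDropout = TRUE)$y
  fr <- .dForward(dp, .asTensor(gt), xClean, keepCache = TRUE)
  ff <- .dForward(dp, fake, xClean, keepCache = TRUE)
  pr <- .clampP(fr$p); pf <- .clampP(ff$p)
  loss <- -mean(log(pr)) - mean(log(1 - pf))
  n <- length(pr)
  gr <- .dBackward(dp, fr$cache, -1 / (n * pr))
  gf <- .dBackward(dp, ff$cache, 1 / (n * (1 - pf)))
  grads <- Map(`+`, gr[names(dp)], gf[names(dp)])
  res <- .adamStep(dp, grads, dopt, cfg)
  list(dp = res$params, dopt = res$st, loss = .checkFinite(loss, "D loss"))
}

# Training step (b) for one branch: update the generator with
# adv + lambda L1 against its (frozen) discriminator.
.trainGStep <- function(gp, gopt, dp, xArt, xClean, gt, cfg) {
  fw <- .gForward(gp, xArt, cfg, sampleDropout = TRUE, keepCache = TRUE)
  fake <- fw$y
  dfw <- .dForward(dp, fake, xClean, keepCache = TRUE)
  pf <- .clampP(dfw$p)
  adv <- -mean(log(pf))
  l1 <- mean(abs(fake - .asTensor(gt)))
  npix <- length(fake)
  dFromD <- .dBackward(dp, dfw$cache, -1 / (length(pf) * pf))$dInput
  dFake <- dFromD[, , 1, drop = FALSE] +
    cfg$lambdaL1 * sign(fake - .asTensor(gt)) / npix
  grads <- .gBackward(gp, fw$cache, dFake, cfg)
  res <- .adamStep(gp, grads, gopt, cfg)
  list(gp = res$params, gopt = res$st,
       adv = .checkFinite(adv, "adversarial loss"),
       l1 = .checkFinite(l1, "L1 loss"))
}

#' Run one training epoch
#'
#' Per sample and iteration: (a) each discriminator is updated on the
#' ground truth (real) versus the frozen generator's output (fake), both
#' conditioned on the clean scattering input; (b) each generator is updated
#' with the adversarial + lambda L1 objective against its frozen
#' discriminator; (c) a joint step multiplies the two generated components
#' and minimizes the smooth L1 distance to the product of the ground
#' truths through both generators. Sample order is reshuffled each epoch.
#' Deterministic given the state's seed and epoch counter.
#'
#' @param state a [TrainState-class].
#' @param samples list of [DatasetSample-class].
#' @return the updated state; one history row of mean losses is appended.
#' @export
trainEpoch <- function(state, samples) {
  stopifnot(length(samples) > 0)
  cfg <- state@config
  gFF <- state@gFF; gSRO <- state@gSRO
  dFF <- state@dFF; dSRO <- state@dSRO
  opt <- state@opt
  acc <- c(dFF = 0, dSRO = 0, advFF = 0, advSRO = 0, l1FF = 0, l1SRO = 0,
           prod = 0)
  withSeed(state@seed + 1000003L * (state@epoch + 1L), {
    ord <- sample(seq_along(samples))
    for (is in ord) {
      s <- samples[[is]]
      xArt <- .asTensor(s@input)
      xClean <- .asTensor(s@inputClean)
      yFF <- .asTensor(s@gtFF)
      ySRO <- .asTensor(s@gtSRO)

      r <- .trainDStep(gFF, dFF, opt$dFF, xArt, xClean, yFF, cfg)
      dFF <- r$dp; opt$dFF <- r$dopt; acc["dFF"] <- acc["dFF"] + r$loss
      r <- .trainDStep(gSRO, dSRO, opt$dSRO, xArt, xClean, ySRO, cfg)
      dSRO <- r$dp; opt$dSRO <- r$dopt; acc["dSRO"] <- acc["dSRO"] + r$loss

      r <- .trainGStep(gFF, opt$gFF, dFF, xArt, xClean, yFF, cfg)
      gFF <- r$gp; opt$gFF <- r$gopt
      acc["advFF"] <- acc["advFF"] + r$adv; acc["l1FF"] <- acc["l1FF"] + r$l1
      r <- .trainGStep(gSRO, opt$gSRO, dSRO, xArt, xClean, ySRO, cfg)
      gSRO <- r$gp; opt$gSRO <- r$gopt
      acc["advSRO"] <- acc["advSRO"] + r$adv; acc["l1SRO"] <- acc["l1SRO"] + r$l1

      # (c) joint product-consistency step through both generators
      fwF <- .gForward(gFF, xArt, cfg, sampleDropout = TRUE, keepCache = TRUE)
      fwS <- .gForward(gSRO, xArt, cfg, sampleDropout = TRUE, keepCache = TRUE)
      e <- fwF$y * fwS$y - yFF * ySRO
      pl <- mean(.smoothL1(e, cfg$smoothL1Beta))
      acc["prod"] <- acc["prod"] + .checkFinite(pl, "product loss")
      g <- .smoothL1Deriv(e, cfg$smoothL1Beta) / length(e)
      gradsF <- .gBackward(gFF, fwF$cache, g * fwS$y, cfg)
      gradsS <- .gBackward(gSRO, fwS$cache, g * fwF$y, cfg)
      res <- .adamStep(gFF, gradsF, opt$gFFprod, cfg)
      gFF <- res$params; opt$gFFprod <- res$st
      res <- .adamStep(gSRO, gradsS, opt$gSROprod, cfg)
      gSRO <- res$params; opt$gSROprod <- res$st
    }
  })
  n <- length(samples)
  acc <- acc / n
  row <- data.frame(epoch = state@epoch + 1L,
                    dFF = acc[["dFF"]], dSRO = acc[["dSRO"]],
                    advFF = acc[["advFF"]], advSRO = acc[["advSRO"]],
                    l1FF = acc[["l1FF"]], l1SRO = acc[["l1SRO"]],
                    gFF = acc[["advFF"]] + cfg$lambdaL1 * acc[["l1FF"]],
                    gSRO = acc[["advSRO"]] + cfg$lambdaL1 * acc[["l1SRO"]],
                    prod = acc[["prod"]])
  new("TrainState", config = cfg, gFF = gFF, gSRO = gSRO, dFF = dFF,
      dSRO = dSRO, opt = opt, epoch = state@epoch + 1L,
      history = rbind(state@history, row), seed = state@seed)
}

#' Train for several epochs
#'
#' @param state a [TrainState-class].
#' @param samples list of [DatasetSample-class].
#' @param epochs number of epochs (0 returns the state unchanged).
#' @param verbose print one line per epoch.
#' @return the updated state.
#' @export
trainEpochs <- function(state, samples, epochs, verbose = FALSE) {
  stopifnot(epochs >= 0)
  for (e in seq_len(epochs)) {
    state <- trainEpoch(state, samples)
    if (verbose) {
      h <- state@history[nrow(state@history), ]
      message(sprintf("epoch %d: L1(FF) %.4f L1(SRO) %.4f prod %.4f",
                      h$epoch, h$l1FF, h$l1SRO, h$prod))
    }
  }
  state
}

#' Separate a scattering plane into its two components
#'
#' Runs both trained generators on a normalized input plane. With
#' `sample = FALSE` (default) dropout is disabled and the output is
#' deterministic; with `sample = TRUE` the decoder dropout acts as the
#' latent noise source and repeated calls explore the output distribution.
#'
#' @param state a trained [TrainState-class].
#' @param input numeric matrix in [-1, 1] of the configured grid size
#'   (apply [sqrtNormalize()] upstream).
#' @param sample enable dropout sampling.
#' @return list with matrices `ff` and `sro`, both in [-1, 1].
#' @export
decompose <- function(state, input, sample = FALSE) {
  input <- as.matrix(input)
  n <- state@config$gridSize
  if (!all(dim(input) == c(n, n)))
    stop(sprintf("input must be %dx%d; resize upstream", n, n), call. = FALSE)
  ff <- .gForward(state@gFF, input, state@config, sampleDropout = sample)$y
  sro <- .gForward(state@gSRO, input, state@config, sampleDropout = sample)$y
  list(ff = matrix(ff, n, n), sro = matrix(sro, n, n))
}

#' Save a training checkpoint
#'
#' Checkpoints round-trip bit-exactly through [loadCheckpoint()].
#'
#' @param state a [TrainState-class].
#' @param path output file.
#' @export
saveCheckpoint <- function(state, path) {
  obj <- list(format = "diffsep-checkpoint", version = 1L, state = state)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#' @param path file written by [saveCheckpoint()].
#' @return the [TrainState-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "diffsep-checkpoint"))
    stop("not a checkpoint file", call. = FALSE)
  obj$state
}
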