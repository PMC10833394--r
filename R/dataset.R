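# Dataset assembly: Vegard lattices, plane selection, product composition,
# uniqueness filtering, normalization, artefact injection and manifest
# bookkeeping.

#' Vegard's-law lattice parameter for a molecule pair
#'
#' Each pure species is assigned a cubic lattice parameter of twice its
#' padded bounding-sphere radius, a_X = 2 (r_X + padding); the mixed crystal
#' interpolates linearly with composition: a = m_A a_A + (1 - m_A) a_B.
#'
#' @param radiusA,radiusB bounding-sphere radii of the two species
#'   (Angstrom, > 0).
#' @param mA concentration of A in [0, 1].
#' @param padding added to each radius before doubling (Angstrom).
#' @return lattice parameter a (Angstrom).
#' @export
vegardLattice <- function(radiusA, radiusB, mA, padding = 1.2) {
  if (radiusA <= 0 || radiusB <= 0)
    stop("radii must be positive", call. = FALSE)
  stopifnot(mA >= 0, mA <= 1)
  aA <- 2 * (radiusA + padding)
  aB <- 2 * (radiusB + padding)
  mA * aA + (1 - mA) * aB
}

#' Select reciprocal-space planes for a lattice
#'
#' "mc" mode picks 12 planes, 4 along each reciprocal axis with distinct
#' integer offsets; "symmetry" mode picks 4 planes normal to the unique
#' (third) axis. Each plane draws its own qMax uniformly from `qmaxRange`.
#'
#' @param cell unit cell (scalar a or length-6; see [planeDefinition()]).
#' @param mode "mc" or "symmetry".
#' @param seed integer seed (drives the qMax draws).
#' @param gridSize pixels per side.
#' @param qmaxRange range the per-plane qMax is drawn from (1/Angstrom).
#' @param offsets integer offsets available per axis (first 4 are used).
#' @return list of [PlaneDefinition-class].
#' @export
selectPlanes <- function(cell, mode = c("mc", "symmetry"), seed = 1,
                         gridSize = 256L, qmaxRange = c(6, 8),
                         offsets = 0:3) {
  mode <- match.arg(mode)
  specs <- if (mode == "mc") {
    do.call(rbind, lapply(1:3, function(ax)
      data.frame(fixedAxis = ax, offset = offsets[1:4])))
  } else {
    data.frame(fixedAxis = 3L, offset = offsets[1:4])
  }
  qmaxes <- withSeed(seed, runif(nrow(specs), qmaxRange[1], qmaxRange[2]))
  lapply(seq_len(nrow(specs)), function(i) {
    planeDefinition(cell, inPlaneAxes = setdiff(1:3, specs$fixedAxis[i]),
                    offset = specs$offset[i], gridSize = gridSize,
                    qMax = qmaxes[i])
  })
}

#' Compose the total diffuse scattering
#'
#' Pixel-wise product I_D = I_FF * I_SRO of two planes sharing one
#' [PlaneDefinition-class].
#'
#' @param iff,isro [ScatteringPlane-class] objects on the same plane.
#' @return a [ScatteringPlane-class] with componentTag "TOTAL".
#' @export
composeTotal <- function(iff, isro) {
  if (!.samePlane(iff@plane, isro@plane))
    stop("planes are not aligned: differing plane definitions", call. = FALSE)
  new("ScatteringPlane", intensities = intensities(iff) * intensities(isro),
      plane = iff@plane, componentTag = "TOTAL")
}

#' Square-root normalization to [-1, 1]
#'
#' Takes the square root of the intensities to emphasize low-intensity
#' features, then rescales per sample so zero intensity maps to -1 and the
#' maximum to +1: y = 2 sqrt(I) / max(sqrt(I)) - 1.
#'
#' @param x a [ScatteringPlane-class] or non-negative numeric matrix.
#' @return numeric matrix in [-1, 1].
#' @export
sqrtNormalize <- function(x) {
  I <- if (is(x, "ScatteringPlane")) intensities(x) else x
  if (min(I) < -1e-9) stop("intensities must be non-negative", call. = FALSE)
  I[I < 0] <- 0
  r <- sqrt(I)
  m <- max(r)
  if (m == 0) stop("degenerate all-zero plane", call. = FALSE)
  2 * r / m - 1
}

#' Synthetic detector artefact mask
#'
#' Emulates dead zones of reconstructed area-detector planes: 0-3 straight
#' axis-aligned module-gap bands (2-8 pixels wide), an optional central
#' beamstop disc with an arm, and rounded corners. Bands are dropped, most
#' recent first, if the live-pixel fraction would fall below 0.6.
#'
#' @param seed integer seed; masks are deterministic under it.
#' @param gridSize pixels per side.
#' @return an [ArtifactMask-class] (TRUE = dead).
#' @export
syntheticArtifactMask <- function(seed, gridSize = 256L) {
  n <- as.integer(gridSize)
  withSeed(seed, {
    dead <- matrix(FALSE, n, n)
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    # rounded corners: kill pixels outside the inscribed-corner radius
    rad <- n * runif(1, 0.55, 0.75)
    cen <- (n + 1) / 2
    rr <- sqrt((ij$i - cen)^2 + (ij$j - cen)^2)
    corner <- matrix(rr > rad, n, n)
    dead <- dead | corner
    # optional beamstop: central disc plus an arm to one edge
    if (runif(1) < 0.5) {
      br <- max(2, round(n * runif(1, 0.01, 0.03)))
      disc <- matrix(rr <= br, n, n)
      arm <- matrix(FALSE, n, n)
      aw <- max(1, round(br / 2))
      rows <- max(1, round(cen - aw)):min(n, round(cen + aw))
      arm[rows, 1:floor(cen)] <- TRUE
      dead <- dead | disc | arm
    }
    # module-gap bands
    nb <- sample(0:3, 1)
    bands <- list()
    if (nb > 0) for (b in seq_len(nb)) {
      w <- sample(2:8, 1)
      pos <- sample(seq_len(n - w), 1)
      horiz <- runif(1) < 0.5
      m <- matrix(FALSE, n, n)
      if (horiz) m[pos:(pos + w - 1), ] <- TRUE else m[, pos:(pos + w - 1)] <- TRUE
      bands[[b]] <- m
      dead <- dead | m
    }
    # guarantee the live fraction by construction
    while (mean(!dead) < 0.6 && length(bands) > 0) {
      bands <- bands[-length(bands)]
      dead <- corner
      if (exists("disc")) dead <- dead | disc | arm
      for (m in bands) dead <- dead | m
    }
    new("ArtifactMask", mask = dead, label = sprintf("synthetic-%d", seed))
  })
}

#' Imprint an artefact mask on a normalized plane
#'
#' Dead pixels are set to the lower bound -1; live pixels are unchanged.
#' Idempotent for a fixed mask.
#'
#' @param normalized numeric matrix in [-1, 1].
#' @param mask an [ArtifactMask-class] of the same size.
#' @return the masked matrix.
#' @export
applyArtifact <- function(normalized, mask) {
  m <- maskMatrix(mask)
  if (!all(dim(normalized) == dim(m)))
    stop("mask and plane sizes differ", call. = FALSE)
  normalized[m] <- -1
  normalized
}

#' Filter near-duplicate planes by 1D Wasserstein distance
#'
#' The distance between two planes is the 1D optimal-transport distance
#' between their pixel-intensity distributions, i.e. the mean absolute
#' difference of sorted pixel values. Scanning planes in input order, any
#' plane closer than the threshold to an already-kept plane is dropped
#' (the later of the pair), deterministically.
#'
#' @param planes list of numeric matrices (or [ScatteringPlane-class]).
#' @param threshold absolute distance threshold; if NULL, uses
#'   `relThreshold` times the larger dynamic range of each pair.
#' @param relThreshold relative threshold (default 1e-3 of dynamic range).
#' @return list with `kept` (indices), `removed` (count) and `keptPlanes`.
#' @export
wassersteinFilter <- function(planes, threshold = NULL, relThreshold = 1e-3) {
  mats <- lapply(planes, function(p)
    if (is(p, "ScatteringPlane")) intensities(p) else p)
  sorted <- lapply(mats, function(m) sort(as.numeric(m)))
  rng <- vapply(mats, function(m) diff(range(m)), numeric(1))
  kept <- integer(0)
  for (j in seq_along(mats)) {
    dup <- FALSE
    for (k in kept) {
      d <- mean(abs(sorted[[j]] - sorted[[k]]))
      thr <- if (is.null(threshold)) relThreshold * max(rng[j], rng[k], 1e-300)
             else threshold
      if (d < thr) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, j)
  }
  list(kept = kept, removed = length(mats) - length(kept),
       keptPlanes = planes[kept])
}

#' Default dataset configuration
#'
#' Per molecule pair: 12 MC-derived SRO models with 12 planes each plus 14
#' symmetry-restricted models with 4 planes each, i.e. 200 planes per pair.
#'
#' @param ... overrides of any default field.
#' @return configuration list.
#' @export
datasetConfig <- function(...) {
  cfg <- list(
    sroSetsMC = 12L, planesPerMC = 12L,
    sroSetsSym = 14L, planesPerSym = 4L,
    gridSize = 256L, qmaxRange = c(6, 8),
    relThreshold = 1e-3, padding = 1.2,
    mcDims = c(16L, 16L, 16L), mcSweeps = 60L,
    vectorCutoff = 5L, artifactProb = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Build a paired training dataset (or just its manifest)
#'
#' For each molecule pair: draw SRO models (MC-derived and
#' symmetry-restricted), build the Vegard lattice, select planes, compute
#' I_FF, I_SRO and their product, filter near-duplicates, square-root
#' normalize, and imprint synthetic artefacts while retaining the clean
#' copy. With `dryRun = TRUE` only the stage counts are computed, which
#' reproduces the bookkeeping of arbitrarily large configurations in
#' milliseconds.
#'
#' @param pairs either an integer (number of molecule pairs; required for
#'   dry runs) or a list of `list(molA, molB)` pairs.
#' @param config from [datasetConfig()].
#' @param seed integer master seed.
#' @param dryRun if TRUE, compute the manifest counts only.
#' @return list with `manifest` (stage counts + per-sample records) and
#'   `samples` (list of [DatasetSample-class]; empty for dry runs).
#' @export
buildDataset <- function(pairs, config = datasetConfig(), seed = 1,
                         dryRun = FALSE) {
  nPairs <- if (is.numeric(pairs)) as.integer(pairs) else length(pairs)
  planesPerPair <- config$sroSetsMC * config$planesPerMC +
    config$sroSetsSym * config$planesPerSym
  preFilter <- nPairs * planesPerPair
  counts <- list(pairs = nPairs,
                 sroSetsMC = config$sroSetsMC,
                 sroSetsSym = config$sroSetsSym,
                 planesPerPair = planesPerPair,
                 preFilter = preFilter)
  if (dryRun) {
    counts$removed <- 0L
    counts$final <- preFilter
    return(list(manifest = list(counts = counts,
                                samples = data.frame()),
                samples = list()))
  }
  if (is.numeric(pairs))
    stop("a list of molecule pairs is required unless dryRun = TRUE",
         call. = FALSE)

  samples <- list()
  records <- list()
  removedTotal <- 0L
  degenerate <- 0L
  seeds <- withSeed(seed, matrix(sample.int(2^30, nPairs * 4), nPairs, 4))

  for (ip in seq_len(nPairs)) {
    molA <- pairs[[ip]][[1]]
    molB <- pairs[[ip]][[2]]
    rA <- max(molRadius(molA), 0.5)
    rB <- max(molRadius(molB), 0.5)
    pairPlanes <- list()
    pairMeta <- list()

    # MC-derived models: 12 planes each on the pair's Vegard lattice
    for (im in seq_len(config$sroSetsMC)) {
      model <- sampleRealisticSRO(seeds[ip, 1] + im,
                                  vectorCutoff = config$vectorCutoff,
                                  dims = config$mcDims,
                                  sweeps = config$mcSweeps)
      a <- vegardLattice(rA, rB, model@mA, padding = config$padding)
      pds <- selectPlanes(a, "mc", seed = seeds[ip, 2] + im,
                          gridSize = config$gridSize,
                          qmaxRange = config$qmaxRange)
      pds <- pds[seq_len(min(config$planesPerMC, length(pds)))]
      for (iq in seq_along(pds)) {
        pairPlanes[[length(pairPlanes) + 1]] <-
          .simulateSample(molA, molB, model, pds[[iq]])
        pairMeta[[length(pairMeta) + 1]] <-
          list(pair = ip, model = sprintf("mc-%d", im), plane = iq)
      }
    }
    # symmetry-restricted oscillator models: hexagonal cell, 4 planes each
    for (im in seq_len(config$sroSetsSym)) {
      par <- randomOscillatorParams(seeds[ip, 3] + im)
      vecs <- canonicalVectors(config$vectorCutoff)
      model <- oscillatorAlphas(par, vecs, shellIndex(vecs, "hexagonal"))
      a <- vegardLattice(rA, rB, 0.5, padding = config$padding)
      cell <- c(a, a, a, 90, 90, 120)
      pds <- selectPlanes(cell, "symmetry", seed = seeds[ip, 4] + im,
                          gridSize = config$gridSize,
                          qmaxRange = config$qmaxRange)
      pds <- pds[seq_len(min(config$planesPerSym, length(pds)))]
      for (iq in seq_along(pds)) {
        pairPlanes[[length(pairPlanes) + 1]] <-
          .simulateSample(molA, molB, model, pds[[iq]])
        pairMeta[[length(pairMeta) + 1]] <-
          list(pair = ip, model = sprintf("sym-%d", im), plane = iq)
      }
    }

    ok <- !vapply(pairPlanes, is.null, logical(1))
    degenerate <- degenerate + sum(!ok)
    pairPlanes <- pairPlanes[ok]
    pairMeta <- pairMeta[ok]

    filt <- wassersteinFilter(lapply(pairPlanes, `[[`, "total"),
                              relThreshold = config$relThreshold)
    removedTotal <- removedTotal + filt$removed
    pairPlanes <- pairPlanes[filt$kept]
    pairMeta <- pairMeta[filt$kept]

    for (is in seq_along(pairPlanes)) {
      sm <- pairPlanes[[is]]
      maskSeed <- seeds[ip, 2] + 7919L * is
      inputClean <- sqrtNormalize(sm$total)
      input <- inputClean
      if (runif(1) < config$artifactProb) {
        mask <- syntheticArtifactMask(maskSeed, gridSize = config$gridSize)
        input <- applyArtifact(inputClean, mask)
      }
      meta <- pairMeta[[is]]
      meta$seed <- maskSeed
      samples[[length(samples) + 1]] <- new(
        "DatasetSample", input = input,
        gtFF = sqrtNormalize(sm$iff), gtSRO = sqrtNormalize(sm$isro),
        inputClean = inputClean, meta = meta)
      records[[length(records) + 1]] <-
        data.frame(pair = meta$pair, model = meta$model, plane = meta$plane,
                   seed = meta$seed)
    }
  }

  counts$removed <- removedTotal
  counts$degenerate <- degenerate
  counts$preFilter <- counts$preFilter - degenerate
  counts$final <- counts$preFilter - removedTotal
  list(manifest = list(counts = counts,
                       samples = if (length(records))
                         do.call(rbind, records) else data.frame()),
       samples = samples)
}

# Simulate one (I_FF, I_SRO, total) triple; NULL if the plane is degenerate.
.simulateSample <- function(molA, molB, model, pd) {
  iff <- iFFPlane(molA, molB, model@mA, model@mB, pd)
  isro <- iSROPlane(model, pd)
  tot <- composeTotal(iff, isro)
  if (max(intensities(tot)) == 0 || max(intensities(iff)) == 0 ||
      max(intensities(isro)) == 0) return(NULL)
  list(iff = intensities(iff), isro = intensities(isro),
       total = intensities(tot))
}
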