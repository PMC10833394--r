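# Warren-Cowley short-range-order machinery: occupancy configurations,
# Monte Carlo generation, alpha measurement, damped-oscillator models and
# the SRO component of the diffuse scattering.

#' Construct an SRO model
#'
#' @param mA concentration of species A (0 < mA < 1).
#' @param vectors m x 3 matrix of integer lattice vectors.
#' @param alphas Warren-Cowley parameters, parallel to `vectors`.
#' @return an [SROModel-class].
#' @export
sroModel <- function(mA, vectors, alphas) {
  vectors <- matrix(as.numeric(vectors), ncol = 3)
  new("SROModel", mA = mA, mB = 1 - mA, vectors = vectors,
      alphas = as.numeric(alphas))
}

#' Canonical half-space lattice vectors
#'
#' All integer vectors with components in [-cutoff, cutoff], keeping one
#' representative of each +/-v pair (and the origin), so cosine sums can
#' weight each non-origin vector by 2.
#'
#' @param cutoff maximum absolute component.
#' @param zOnly if TRUE keep only vectors with v3 = 0.
#' @return integer matrix with the origin as the first row.
#' @export
canonicalVectors <- function(cutoff = 5, zOnly = FALSE) {
  g <- expand.grid(n1 = -cutoff:cutoff, n2 = -cutoff:cutoff, n3 = -cutoff:cutoff)
  v <- as.matrix(g)
  keep <- v[, 3] > 0 |
    (v[, 3] == 0 & v[, 2] > 0) |
    (v[, 3] == 0 & v[, 2] == 0 & v[, 1] >= 0)
  v <- v[keep, , drop = FALSE]
  if (zOnly) v <- v[v[, 3] == 0, , drop = FALSE]
  ord <- order(rowSums(v^2), v[, 3], v[, 2], v[, 1])
  unname(v[ord, , drop = FALSE])
}

#' Build an occupancy configuration from a label array
#'
#' @param labels 3D array of 0/1 labels (1 = A).
#' @return an [OccupancyConfiguration-class].
#' @export
occupancyConfiguration <- function(labels) {
  labels <- array(as.integer(labels), dim = dim(labels))
  new("OccupancyConfiguration", dims = as.integer(dim(labels)),
      labels = labels, mA = mean(labels))
}

#' Measure Warren-Cowley parameters from a configuration
#'
#' Exact count-based measurement under periodic boundary conditions:
#' p_AB(v) is the fraction of A sites with a B at site + v, and
#' alpha_v = 1 - p_AB(v) / m_B with the realized concentrations.
#'
#' @param config an [OccupancyConfiguration-class]; must contain both species.
#' @param vectors m x 3 integer matrix of lattice vectors.
#' @return an [SROModel-class] over `vectors`.
#' @export
measureAlphas <- function(config, vectors) {
  mA <- config@mA
  if (mA <= 0 || mA >= 1)
    stop("degenerate configuration: only one species present", call. = FALSE)
  vectors <- matrix(as.numeric(vectors), ncol = 3)
  vi <- matrix(as.integer(round(vectors)), ncol = 3)
  p <- cpp_pair_probabilities(as.integer(config@labels),
                              config@dims, vi)
  alphas <- 1 - p / (1 - mA)
  sroModel(mA, vectors, alphas)
}

#' Generate a configuration matching target nearest-neighbour correlations
#'
#' Metropolis annealing with composition-conserving swap moves on a periodic
#' lattice. The cost is the summed squared deviation of the measured
#' nearest-neighbour alpha along each crystallographic axis from its target;
#' the temperature follows a geometric schedule. Swap moves preserve the
#' exact species counts.
#'
#' @param mA concentration of A (0 < mA < 1).
#' @param targets length-3 numeric: target alpha along [100], [010], [001].
#' @param dims unit cells per axis (>= 8 each).
#' @param seed integer seed.
#' @param sweeps annealing sweeps (one sweep = one attempted swap per site).
#' @param t0,t1 initial/final temperature of the geometric schedule.
#' @param tol warn if any achieved axis alpha deviates from its target by
#'   more than this.
#' @return an [OccupancyConfiguration-class]; attributes `achieved` (axis
#'   alphas) and `cost` record the annealing outcome.
#' @export
mcGenerateConfiguration <- function(mA, targets, dims = c(24, 24, 24),
                                    seed = 1, sweeps = 60,
                                    t0 = 1e-3, t1 = 1e-7, tol = 0.05) {
  stopifnot(length(targets) == 3, all(dims >= 8), mA > 0, mA < 1)
  p <- (1 - mA) * (1 - targets)
  if (any(p < 0 | p > 1 | mA * p > (1 - mA) + 1e-12))
    stop("infeasible targets: implied pair probability outside [0,1]",
         call. = FALSE)
  N <- prod(dims)
  nA <- round(mA * N)
  if (nA == 0 || nA == N)
    stop("concentration too extreme for this lattice size", call. = FALSE)
  withSeed(seed, {
    lab <- integer(N)
    lab[sample.int(N, nA)] <- 1L
    res <- cpp_mc_anneal(lab, as.integer(dims), as.numeric(targets),
                         as.integer(sweeps), t0, t1)
  })
  dev <- abs(res$achieved - targets)
  if (any(dev > tol))
    warning(sprintf(
      "annealing did not reach targets within %.3g (achieved %s vs %s)",
      tol, paste(round(res$achieved, 3), collapse = ","),
      paste(round(targets, 3), collapse = ",")), call. = FALSE)
  cfg <- occupancyConfiguration(array(res$labels, dim = dims))
  attr(cfg, "achieved") <- res$achieved
  attr(cfg, "cost") <- res$cost
  cfg
}

#' Draw a realistic SRO model
#'
#' Draws a random concentration and random feasible axis correlation
#' targets, generates a matching configuration by [mcGenerateConfiguration()]
#' and measures the full Warren-Cowley vector set from it. Emulates the
#' construction of a large pre-computed list of mutually consistent SRO
#' parameter sets.
#'
#' @param seed integer seed.
#' @param vectorCutoff maximum absolute vector component measured.
#' @param dims lattice size for the generating configuration.
#' @param sweeps annealing sweeps.
#' @return an [SROModel-class] over [canonicalVectors()] of the cutoff.
#' @export
sampleRealisticSRO <- function(seed, vectorCutoff = 5, dims = c(16, 16, 16),
                               sweeps = 60) {
  draws <- withSeed(seed, {
    mA <- runif(1, 0.2, 0.8)
    lo <- pmax(-0.45, 1 - 1 / max(mA, 1 - mA) + 0.02)
    list(mA = mA, targets = runif(3, lo, 0.45),
         mcSeed = sample.int(2^30, 1))
  })
  cfg <- mcGenerateConfiguration(draws$mA, draws$targets, dims = dims,
                                 seed = draws$mcSeed, sweeps = sweeps)
  measureAlphas(cfg, canonicalVectors(vectorCutoff))
}

#' Neighbour-shell indices for a vector set
#'
#' Ranks vectors by squared lattice distance (through the real-space metric
#' of the given lattice type) and assigns shell 1 to the nearest
#' neighbours, 2 to the next, and so on. The origin gets shell 0.
#'
#' @param vectors m x 3 integer matrix.
#' @param lattice "cubic" (identity metric) or "hexagonal" (gamma = 120
#'   degrees in-plane metric, c/a = 1).
#' @return integer vector of shell indices.
#' @export
shellIndex <- function(vectors, lattice = c("cubic", "hexagonal")) {
  lattice <- match.arg(lattice)
  v <- matrix(as.numeric(vectors), ncol = 3)
  d2 <- if (lattice == "cubic") rowSums(v^2)
  else v[, 1]^2 + v[, 2]^2 - v[, 1] * v[, 2] + v[, 3]^2
  d2 <- round(d2, 9)
  lev <- sort(unique(d2[d2 > 0]))
  idx <- integer(nrow(v))
  idx[d2 > 0] <- match(d2[d2 > 0], lev)
  idx
}

#' Damped-oscillator SRO model
#'
#' alpha(x) = A exp(-d x) cos(pi omega x) on neighbour-shell index x, with
#' all symmetry-equivalent vectors of a shell sharing one alpha and both
#' concentrations fixed at 0.5. Values are clamped into the feasible range
#' implied by p = m_B (1 - alpha) in [0, 1] (i.e. [-1, 1] at m = 0.5).
#' Shells beyond `maxShell` get alpha = 0.
#'
#' @param params an [OscillatorParams-class] (or list with amplitude, decay,
#'   frequency).
#' @param vectors m x 3 integer matrix (should include the origin).
#' @param shells shell index per vector, e.g. from [shellIndex()].
#' @param maxShell largest shell carrying a non-zero alpha (default 5).
#' @return an [SROModel-class] with mA = mB = 0.5.
#' @export
oscillatorAlphas <- function(params, vectors,
                             shells = shellIndex(vectors), maxShell = 5) {
  if (is.list(params) && !is(params, "OscillatorParams"))
    params <- new("OscillatorParams", amplitude = params$amplitude,
                  decay = params$decay, frequency = params$frequency)
  validObject(params)
  vectors <- matrix(as.numeric(vectors), ncol = 3)
  stopifnot(length(shells) == nrow(vectors))
  x <- shells
  a <- params@amplitude * exp(-params@decay * x) * cos(pi * params@frequency * x)
  a[x == 0] <- 1
  a[x > maxShell] <- 0
  a <- pmin(1, pmax(-1, a))   # feasibility clamp at m = 0.5
  sroModel(0.5, vectors, a)
}

#' Draw random oscillator parameters
#'
#' Amplitude, decay and frequency uniform over [0.6, 1.5], [0.1, 1.2] and
#' [0, 1] respectively.
#'
#' @param seed integer seed.
#' @return an [OscillatorParams-class].
#' @export
randomOscillatorParams <- function(seed) {
  withSeed(seed, new("OscillatorParams",
                     amplitude = runif(1, 0.6, 1.5),
                     decay = runif(1, 0.1, 1.2),
                     frequency = runif(1, 0, 1)))
}

#' Short-range-order component of the diffuse scattering
#'
#' Evaluates the Warren-Cowley cosine series
#' I(Q) = N m_A m_B sum_v w_v alpha_v cos(2 pi (h, k, l) . v) per pixel.
#' Under the default "pair" convention the model stores one representative
#' of each +/-v pair and non-origin vectors carry weight 2; under "full"
#' every stored vector carries weight 1 (use this when the stored set is
#' already +/- symmetric or covers a full periodic box). Negative values,
#' possible for hand-specified alpha sets, are clipped at zero; the clipped
#' fraction is recorded in attribute `clipFraction` of the intensities.
#'
#' @param model an [SROModel-class]; must include the origin vector.
#' @param plane a [PlaneDefinition-class].
#' @param nCells scale factor N (default 1).
#' @param convention "pair" or "full" (see above).
#' @return a [ScatteringPlane-class] with componentTag "SRO".
#' @export
iSROPlane <- function(model, plane, nCells = 1,
                      convention = c("pair", "full")) {
  convention <- match.arg(convention)
  zero <- rowSums(model@vectors != 0) == 0
  if (!any(zero))
    stop("model must store alpha at (0,0,0)", call. = FALSE)
  w <- if (convention == "pair") ifelse(zero, 1, 2) else rep(1, nrow(model@vectors))
  raw <- cpp_cosine_plane(plane@frac, model@vectors, model@alphas, w)
  raw <- raw * nCells * model@mA * model@mB
  clip <- mean(raw < -1e-12)
  raw[raw < 0] <- 0
  I <- matrix(raw, plane@gridSize, plane@gridSize)
  out <- new("ScatteringPlane", intensities = I, plane = plane,
             componentTag = "SRO")
  attr(out, "clipFraction") <- clip
  out
}

#' Brute-force SRO scattering of an explicit configuration
#'
#' Exact finite-lattice reference: the scattering of the occupancy
#' deviations, |sum_j (c_j - m_A) exp(2 pi i (h,k,l) . r_j)|^2 / N_cells,
#' summed over all cells j of the periodic box. Serves as an independent
#' oracle for the cosine-series evaluation.
#'
#' @param config an [OccupancyConfiguration-class], at most 32^3 cells.
#' @param plane a [PlaneDefinition-class].
#' @return a [ScatteringPlane-class] with componentTag "SRO".
#' @export
directSumOracle <- function(config, plane) {
  if (prod(config@dims) > 32^3)
    stop("configuration too large for the brute-force oracle (max 32^3)",
         call. = FALSE)
  d <- config@dims
  g <- expand.grid(n1 = 0:(d[1] - 1), n2 = 0:(d[2] - 1), n3 = 0:(d[3] - 1))
  pos <- as.matrix(g)                      # matches column-major label order
  dev <- as.numeric(config@labels) - config@mA
  npix <- nrow(plane@frac)
  I <- numeric(npix)
  chunk <- max(1, floor(2e6 / nrow(pos)))
  for (s in seq(1, npix, by = chunk)) {
    e <- min(npix, s + chunk - 1)
    ph <- 2 * pi * (pos %*% t(plane@frac[s:e, , drop = FALSE]))
    amp <- colSums(dev * exp(1i * ph))
    I[s:e] <- Mod(amp)^2 / nrow(pos)
  }
  new("ScatteringPlane", intensities = matrix(I, plane@gridSize, plane@gridSize),
      plane = plane, componentTag = "SRO")
}

#' Serialize an SRO model to a tabular text file
#'
#' Columns n1, n2, n3, alpha; a header comment carries the concentrations.
#'
#' @param model an [SROModel-class].
#' @param path output path.
#' @export
writeSROModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mA=%.10g mB=%.10g", model@mA, model@mB), con)
  writeLines("n1\tn2\tn3\talpha", con)
  writeLines(sprintf("%d\t%d\t%d\t%.12g",
                     as.integer(model@vectors[, 1]),
                     as.integer(model@vectors[, 2]),
                     as.integer(model@vectors[, 3]), model@alphas), con)
  invisible(path)
}

#' Read an SRO model written by [writeSROModel()]
#' @param path file path.
#' @return an [SROModel-class].
#' @export
readSROModel <- function(path) {
  hdr <- readLines(path, n = 1)
  mA <- as.numeric(sub(".*mA=([0-9.eE+-]+).*", "\\1", hdr))
  tab <- read.table(path, header = TRUE, skip = 1, sep = "\t")
  sroModel(mA, as.matrix(tab[, c("n1", "n2", "n3")]), tab$alpha)
}
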