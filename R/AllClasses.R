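# S4 classes for the core domain objects.

#' Molecule: an ordered list of atoms
#'
#' A rigid scattering unit: element symbols plus Cartesian coordinates in
#' Angstrom. The zero-atom "vacancy" sentinel (see [vacancyMolecule()])
#' represents an unoccupied site and scatters nothing.
#'
#' @slot label identifier.
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @slot radius bounding-sphere radius about the centroid (Angstrom), cached.
#' @export
setClass("Molecule",
  representation(label = "character", elements = "character",
                 coords = "matrix", radius = "numeric"),
  validity = function(object) {
    n <- length(object@elements)
    if (nrow(object@coords) != n) return("elements/coords length mismatch")
    if (n > 0) {
      if (ncol(object@coords) != 3) return("coords must have 3 columns")
      if (!all(is.finite(object@coords))) return("non-finite coordinates")
      bad <- setdiff(unique(object@elements), supportedElements())
      if (length(bad))
        return(paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
    }
    TRUE
  })

#' Reciprocal-space plane definition
#'
#' A square pixel grid over a planar cut of reciprocal space. Two reciprocal
#' axes vary across the grid while the third is held at a fixed integer
#' offset (e.g. the hk1 plane). Fractional (h,k,l) coordinates and Cartesian
#' scattering vectors Q (physicists' convention, |Q| = 2 pi / d) are stored
#' per pixel.
#'
#' @slot gridSize pixels per side.
#' @slot qMax maximum |Q| along each in-plane axis (1/Angstrom).
#' @slot reciprocalBasis 3x3 matrix, rows are the reciprocal-lattice vectors
#'   including the 2 pi factor (1/Angstrom).
#' @slot inPlaneAxes the two reciprocal axes (indices in 1:3) spanning the grid.
#' @slot offset fixed fractional coordinate of the remaining axis.
#' @slot frac n^2 x 3 matrix of fractional (h,k,l) per pixel (column-major
#'   pixel order, matching `as.vector(matrix)`).
#' @slot cartQ n^2 x 3 matrix of Cartesian Q per pixel (1/Angstrom).
#' @export
setClass("PlaneDefinition",
  representation(gridSize = "integer", qMax = "numeric",
                 reciprocalBasis = "matrix", inPlaneAxes = "integer",
                 offset = "numeric", frac = "matrix", cartQ = "matrix"),
  validity = function(object) {
    n <- object@gridSize
    if (length(n) != 1 || n < 2) return("gridSize must be a single value >= 2")
    if (nrow(object@frac) != n * n) return("frac size inconsistent with grid")
    if (nrow(object@cartQ) != n * n) return("cartQ size inconsistent with grid")
    if (!all(dim(object@reciprocalBasis) == c(3, 3)))
      return("reciprocalBasis must be 3x3")
    # fractional and Cartesian coordinates must agree through the basis
    err <- max(abs(object@frac %*% object@reciprocalBasis - object@cartQ))
    if (err > 1e-8) return("frac and cartQ inconsistent with reciprocalBasis")
    # corner bound applies to the in-plane component; the fixed offset adds
    # a constant out-of-plane contribution on top
    p3 <- setdiff(1:3, object@inPlaneAxes)
    qin <- object@cartQ -
      object@frac[, p3] %*% object@reciprocalBasis[p3, , drop = FALSE]
    if (max(sqrt(rowSums(qin^2))) > object@qMax * sqrt(2) + 1e-6)
      return("in-plane |Q| exceeds qMax * sqrt(2)")
    TRUE
  })

#' Complex molecular form-factor field on a plane
#'
#' @slot values complex matrix (gridSize x gridSize) of F(Q).
#' @slot plane the [PlaneDefinition-class] the field was evaluated on.
#' @export
setClass("ComplexFieldPlane",
  representation(values = "matrix", plane = "PlaneDefinition"),
  validity = function(object) {
    if (!is.complex(object@values)) return("values must be complex")
    if (!all(is.finite(Re(object@values))) || !all(is.finite(Im(object@values))))
      return("non-finite field values")
    TRUE
  })

#' Real intensity plane
#'
#' @slot intensities real matrix (gridSize x gridSize).
#' @slot plane the [PlaneDefinition-class].
#' @slot componentTag one of "FF", "SRO", "TOTAL".
#' @export
setClass("ScatteringPlane",
  representation(intensities = "matrix", plane = "PlaneDefinition",
                 componentTag = "character"),
  validity = function(object) {
    if (!all(is.finite(object@intensities))) return("non-finite intensities")
    if (!object@componentTag %in% c("FF", "SRO", "TOTAL"))
      return("componentTag must be FF, SRO or TOTAL")
    if (nrow(object@intensities) != object@plane@gridSize ||
        ncol(object@intensities) != object@plane@gridSize)
      return("intensity grid does not match plane definition")
    if (min(object@intensities) < -1e-9) return("negative intensities")
    TRUE
  })

#' Warren-Cowley short-range-order model
#'
#' Concentrations of the two species plus a map from integer lattice vectors
#' v to the Warren-Cowley parameter alpha_v = 1 - p_AB(v) / m_B. alpha at
#' v = (0,0,0) is identically 1 and every stored alpha must imply a pair
#' probability p = m_B (1 - alpha) inside [0, 1].
#'
#' @slot mA,mB species concentrations (sum to 1).
#' @slot vectors m x 3 matrix of integer lattice vectors.
#' @slot alphas numeric vector of alpha_v, parallel to `vectors`.
#' @export
setClass("SROModel",
  representation(mA = "numeric", mB = "numeric", vectors = "matrix",
                 alphas = "numeric"),
  validity = function(object) {
    if (abs(object@mA + object@mB - 1) > 1e-9) return("mA + mB must be 1")
    if (object@mA <= 0 || object@mA >= 1) return("concentrations must lie in (0,1)")
    if (nrow(object@vectors) != length(object@alphas))
      return("vectors/alphas length mismatch")
    if (ncol(object@vectors) != 3) return("vectors must have 3 columns")
    zero <- rowSums(object@vectors != 0) == 0
    if (any(zero) && any(abs(object@alphas[zero] - 1) > 1e-9))
      return("alpha at (0,0,0) must be 1")
    p <- object@mB * (1 - object@alphas)
    if (any(p < -1e-9 | p > 1 + 1e-9))
      return("some alpha implies a pair probability outside [0,1]")
    TRUE
  })

#' Occupancy configuration on a periodic lattice
#'
#' @slot dims unit cells per axis (3 integers).
#' @slot labels 3D integer array, 1 = species A, 0 = species B.
#' @slot mA realized fraction of A sites.
#' @export
setClass("OccupancyConfiguration",
  representation(dims = "integer", labels = "array", mA = "numeric"),
  validity = function(object) {
    if (!all(dim(object@labels) == object@dims)) return("labels/dims mismatch")
    if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
    if (abs(mean(object@labels) - object@mA) > 1 / prod(object@dims))
      return("mA inconsistent with label counts")
    TRUE
  })

#' Damped-oscillator parameters for symmetry-restricted SRO
#'
#' alpha(x) = A exp(-d x) cos(pi omega x) evaluated on neighbour-shell index
#' x = 1, 2, ... All symmetry-equivalent vectors of a shell share one alpha.
#'
#' @slot amplitude A, in [0.6, 1.5].
#' @slot decay d, in [0.1, 1.2].
#' @slot frequency omega, in [0, 1].
#' @export
setClass("OscillatorParams",
  representation(amplitude = "numeric", decay = "numeric", frequency = "numeric"),
  validity = function(object) {
    if (object@amplitude < 0.6 || object@amplitude > 1.5)
      return("amplitude outside [0.6, 1.5]")
    if (object@decay < 0.1 || object@decay > 1.2)
      return("decay outside [0.1, 1.2]")
    if (object@frequency < 0 || object@frequency > 1)
      return("frequency outside [0, 1]")
    TRUE
  })

#' Detector artefact mask
#'
#' @slot mask logical matrix, TRUE = dead pixel.
#' @slot label provenance tag.
#' @export
setClass("ArtifactMask",
  representation(mask = "matrix", label = "character"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (all(object@mask)) return("mask must leave at least one live pixel")
    TRUE
  })

#' One normalized training sample
#'
#' All grids share one size; values lie in [-1, 1]; artefact pixels of the
#' input are exactly -1 and live pixels equal the clean input.
#'
#' @slot input artefact-stained normalized total scattering.
#' @slot gtFF,gtSRO normalized clean component ground truths.
#' @slot inputClean normalized artefact-free total scattering.
#' @slot meta provenance list (pair id, SRO model id, plane id, seed).
#' @export
setClass("DatasetSample",
  representation(input = "matrix", gtFF = "matrix", gtSRO = "matrix",
                 inputClean = "matrix", meta = "list"),
  validity = function(object) {
    d <- dim(object@input)
    for (s in c("gtFF", "gtSRO", "inputClean"))
      if (!all(dim(slot(object, s)) == d)) return("grid size mismatch")
    for (s in c("input", "gtFF", "gtSRO", "inputClean")) {
      v <- slot(object, s)
      if (!all(is.finite(v))) return("non-finite values")
      if (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9)
        return("values outside [-1, 1]")
    }
    TRUE
  })

#' Projected reciprocal unit cell
#'
#' @slot values bins x bins matrix of per-bin mean intensity.
#' @slot counts contributing-pixel counts per bin.
#' @slot excluded logical matrix of excluded bins.
#' @slot bins bins per axis.
#' @export
setClass("ProjectedCell",
  representation(values = "matrix", counts = "matrix",
                 excluded = "matrix", bins = "integer"),
  validity = function(object) {
    b <- object@bins
    if (!all(dim(object@values) == c(b, b))) return("values size mismatch")
    if (!all(dim(object@counts) == c(b, b))) return("counts size mismatch")
    if (!all(dim(object@excluded) == c(b, b))) return("excluded size mismatch")
    if (any(object@counts < 0)) return("negative counts")
    TRUE
  })

#' Result of a Warren-Cowley least-squares refinement
#'
#' @slot alphas refined alpha per equivalence class (named by representative
#'   vector).
#' @slot classes list of integer matrices: the vectors of each class.
#' @slot scale overall scale factor (coefficient of the constant term).
#' @slot rss residual sum of squares over included bins.
#' @slot fitted,observed,difference bins x bins matrices.
#' @slot included logical matrix of bins used in the fit.
#' @export
setClass("RefinementResult",
  representation(alphas = "numeric", classes = "list", scale = "numeric",
                 rss = "numeric", fitted = "matrix", observed = "matrix",
                 difference = "matrix", included = "matrix"),
  validity = function(object) {
    if (length(object@alphas) != length(object@classes))
      return("alphas/classes length mismatch")
    if (object@rss < 0) return("negative residual")
    TRUE
  })

#' Isotropic Debye-Waller model
#'
#' Intensity damping exp(-B |Q|^2 / (8 pi^2)), i.e. the squared amplitude
#' factor exp(-B sin^2(theta)/lambda^2) expressed through |Q| = 4 pi
#' sin(theta)/lambda.
#'
#' @slot bIso isotropic displacement parameter B (Angstrom^2), >= 0.
#' @export
setClass("DebyeWallerModel",
  representation(bIso = "numeric"),
  validity = function(object) {
    if (object@bIso < 0) return("B must be >= 0")
    TRUE
  })

#' Training state of the parallel conditional translation networks
#'
#' Two U-Net generators (one per component) and two patch discriminators,
#' together with their Adam optimizer states, an epoch counter and an
#' append-only loss history. Parameter tensors live in nested plain lists so
#' states checkpoint bit-exactly through `saveRDS()`.
#'
#' @slot config network/training configuration (see [ganConfig()]).
#' @slot gFF,gSRO generator parameter lists.
#' @slot dFF,dSRO discriminator parameter lists.
#' @slot opt Adam state per network.
#' @slot epoch epochs completed.
#' @slot history data.frame of per-epoch mean losses.
#' @slot seed the integer seed the state was initialized with.
#' @export
setClass("TrainState",
  representation(config = "list", gFF = "list", gSRO = "list",
                 dFF = "list", dSRO = "list", opt = "list",
                 epoch = "integer", history = "data.frame", seed = "integer"))
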