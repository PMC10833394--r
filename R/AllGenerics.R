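# Generics, accessors and show methods.

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' Intensity grid of a scattering plane
#' @param x a [ScatteringPlane-class]
#' @return numeric matrix
#' @export
setMethod("intensities", "ScatteringPlane", function(x) x@intensities)

#' @export
setGeneric("planeDef", function(x) standardGeneric("planeDef"))
#' Plane definition of a plane-valued object
#' @param x a [ScatteringPlane-class] or [ComplexFieldPlane-class]
#' @return the [PlaneDefinition-class]
#' @export
setMethod("planeDef", "ScatteringPlane", function(x) x@plane)
#' @export
setMethod("planeDef", "ComplexFieldPlane", function(x) x@plane)

#' @export
setGeneric("componentTag", function(x) standardGeneric("componentTag"))
#' Component tag ("FF", "SRO" or "TOTAL") of a plane
#' @param x a [ScatteringPlane-class]
#' @export
setMethod("componentTag", "ScatteringPlane", function(x) x@componentTag)

#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' Complex values of a form-factor field
#' @param x a [ComplexFieldPlane-class]
#' @export
setMethod("fieldValues", "ComplexFieldPlane", function(x) x@values)

#' @export
setGeneric("fracCoords", function(x) standardGeneric("fracCoords"))
#' Per-pixel fractional (h,k,l) coordinates
#' @param x a [PlaneDefinition-class] or plane-valued object
#' @export
setMethod("fracCoords", "PlaneDefinition", function(x) x@frac)
#' @export
setMethod("fracCoords", "ScatteringPlane", function(x) x@plane@frac)

#' @export
setGeneric("cartesianQ", function(x) standardGeneric("cartesianQ"))
#' Per-pixel Cartesian scattering vectors (1/Angstrom)
#' @param x a [PlaneDefinition-class] or plane-valued object
#' @export
setMethod("cartesianQ", "PlaneDefinition", function(x) x@cartQ)
#' @export
setMethod("cartesianQ", "ScatteringPlane", function(x) x@plane@cartQ)

#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))
#' Pixels per side of a plane grid
#' @param x a [PlaneDefinition-class] or [ScatteringPlane-class]
#' @export
setMethod("gridSize", "PlaneDefinition", function(x) x@gridSize)
#' @export
setMethod("gridSize", "ScatteringPlane", function(x) x@plane@gridSize)

#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))
#' Element symbols of a molecule's atoms
#' @param x a [Molecule-class]
#' @export
setMethod("atomElements", "Molecule", function(x) x@elements)

#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' Cartesian coordinates (Angstrom) of a molecule's atoms
#' @param x a [Molecule-class]
#' @export
setMethod("atomCoords", "Molecule", function(x) x@coords)

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' Number of atoms
#' @param x a [Molecule-class]
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))

#' @export
setGeneric("molRadius", function(x) standardGeneric("molRadius"))
#' Bounding-sphere radius about the centroid (Angstrom)
#' @param x a [Molecule-class]
#' @export
setMethod("molRadius", "Molecule", function(x) x@radius)

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' Species concentrations of an SRO model or configuration
#' @param x an [SROModel-class] or [OccupancyConfiguration-class]
#' @return named numeric c(mA = ..., mB = ...)
#' @export
setMethod("concentrations", "SROModel", function(x) c(mA = x@mA, mB = x@mB))
#' @export
setMethod("concentrations", "OccupancyConfiguration",
          function(x) c(mA = x@mA, mB = 1 - x@mA))

#' @export
setGeneric("wcVectors", function(x) standardGeneric("wcVectors"))
#' Stored lattice vectors of a Warren-Cowley model
#' @param x an [SROModel-class]
#' @export
setMethod("wcVectors", "SROModel", function(x) x@vectors)

#' @export
setGeneric("wcAlphas", function(x) standardGeneric("wcAlphas"))
#' Warren-Cowley parameters
#' @param x an [SROModel-class] or [RefinementResult-class]
#' @export
setMethod("wcAlphas", "SROModel", function(x) x@alphas)
#' @export
setMethod("wcAlphas", "RefinementResult", function(x) x@alphas)

#' @export
setGeneric("refScale", function(x) standardGeneric("refScale"))
#' Overall scale factor of a refinement
#' @param x a [RefinementResult-class]
#' @export
setMethod("refScale", "RefinementResult", function(x) x@scale)

#' @export
setGeneric("residualSS", function(x) standardGeneric("residualSS"))
#' Residual sum of squares of a refinement
#' @param x a [RefinementResult-class]
#' @export
setMethod("residualSS", "RefinementResult", function(x) x@rss)

#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' Logical dead-pixel matrix of an artefact mask
#' @param x an [ArtifactMask-class]
#' @export
setMethod("maskMatrix", "ArtifactMask", function(x) x@mask)

#' @export
setGeneric("cellValues", function(x) standardGeneric("cellValues"))
#' Per-bin mean intensity of a projected cell
#' @param x a [ProjectedCell-class]
#' @export
setMethod("cellValues", "ProjectedCell", function(x) x@values)

#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' Contributing-pixel counts of a projected cell
#' @param x a [ProjectedCell-class]
#' @export
setMethod("cellCounts", "ProjectedCell", function(x) x@counts)

#' @export
setGeneric("excludedBins", function(x) standardGeneric("excludedBins"))
#' Logical matrix of excluded bins
#' @param x a [ProjectedCell-class]
#' @export
setMethod("excludedBins", "ProjectedCell", function(x) x@excluded)

# ---- show methods ---------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms, radius %.2f A\n",
              object@label, nAtoms(object), object@radius))
  if (nAtoms(object) > 0) {
    tab <- table(object@elements)
    cat("  composition:", paste(sprintf("%s%d", names(tab), tab), collapse = " "), "\n")
  }
})

setMethod("show", "PlaneDefinition", function(object) {
  ax <- c("h", "k", "l")
  cat(sprintf("PlaneDefinition: %dx%d grid, axes (%s,%s), %s = %g, qMax %.2f 1/A\n",
              object@gridSize, object@gridSize,
              ax[object@inPlaneAxes[1]], ax[object@inPlaneAxes[2]],
              ax[setdiff(1:3, object@inPlaneAxes)], object@offset, object@qMax))
})

setMethod("show", "ScatteringPlane", function(object) {
  cat(sprintf("ScatteringPlane [%s]: %dx%d, intensity range [%.4g, %.4g]\n",
              object@componentTag, nrow(object@intensities),
              ncol(object@intensities), min(object@intensities),
              max(object@intensities)))
})

setMethod("show", "SROModel", function(object) {
  cat(sprintf("SROModel: mA = %.3f, mB = %.3f, %d vectors, alpha range [%.3f, %.3f]\n",
              object@mA, object@mB, nrow(object@vectors),
              min(object@alphas), max(object@alphas)))
})

setMethod("show", "OccupancyConfiguration", function(object) {
  cat(sprintf("OccupancyConfiguration: %s cells, mA = %.4f\n",
              paste(object@dims, collapse = "x"), object@mA))
})

setMethod("show", "RefinementResult", function(object) {
  cat(sprintf("RefinementResult: %d alpha classes, scale %.4g, RSS %.4g\n",
              length(object@alphas), object@scale, object@rss))
  print(round(object@alphas, 4))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf("TrainState: grid %d, %d epochs trained, seed %d\n",
              object@config$gridSize, object@epoch, object@seed))
})
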