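# Reciprocal-space plane grids and the form-factor component of the
# diffuse scattering.

.realBasis <- function(cell) {
  if (length(cell) == 1) cell <- c(cell, cell, cell, 90, 90, 90)
  stopifnot(length(cell) == 6, all(cell[1:3] > 0))
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v3x <- cc * cos(be)
  v3y <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  v3z <- sqrt(cc^2 - v3x^2 - v3y^2)
  rbind(c(a, 0, 0),
        c(b * cos(ga), b * sin(ga), 0),
        c(v3x, v3y, v3z))
}

#' Define a reciprocal-space plane grid
#'
#' Builds a square pixel grid over a planar cut of reciprocal space for a
#' given unit cell. Two reciprocal axes span the grid symmetrically about
#' the origin (pixel centres run from -span to +span inclusive, so an odd
#' grid centres Q = 0 exactly and the default even grid carries a half-pixel
#' offset); the third axis is fixed at an integer offset, e.g. l = 1 for the
#' hk1 plane. Spans are chosen so the in-plane |Q| reaches `qMax` along each
#' axis, shrunk if necessary so no corner exceeds sqrt(2) * qMax.
#'
#' @param cell unit cell: either a single cubic lattice parameter a
#'   (Angstrom) or c(a, b, c, alpha, beta, gamma) (Angstrom / degrees).
#' @param inPlaneAxes the two reciprocal axes (indices in 1:3, i.e. h=1,
#'   k=2, l=3) varying across the grid.
#' @param offset fixed fractional coordinate of the remaining axis.
#' @param gridSize pixels per side (default 256).
#' @param qMax target maximum in-plane |Q| (1/Angstrom).
#' @return a [PlaneDefinition-class].
#' @examples
#' pd <- planeDefinition(10, inPlaneAxes = c(1, 2), offset = 1,
#'                       gridSize = 64, qMax = 6)
#' @export
planeDefinition <- function(cell, inPlaneAxes = c(1L, 2L), offset = 0,
                            gridSize = 256L, qMax = 7) {
  stopifnot(length(inPlaneAxes) == 2, !anyDuplicated(inPlaneAxes),
            all(inPlaneAxes %in% 1:3), qMax > 0, gridSize >= 2)
  A <- .realBasis(cell)
  B <- 2 * pi * t(solve(A))          # rows are reciprocal vectors incl. 2 pi
  n <- as.integer(gridSize)
  p1 <- inPlaneAxes[1]; p2 <- inPlaneAxes[2]
  p3 <- setdiff(1:3, inPlaneAxes)
  span1 <- qMax / sqrt(sum(B[p1, ]^2))
  span2 <- qMax / sqrt(sum(B[p2, ]^2))
  # shrink so corners stay within sqrt(2) * qMax (relevant for oblique bases)
  corners <- expand.grid(h = c(-span1, span1), k = c(-span2, span2))
  cq <- as.matrix(corners) %*% B[c(p1, p2), ]
  inplaneMax <- max(sqrt(rowSums(cq^2)))
  if (inplaneMax > sqrt(2) * qMax) {
    fac <- sqrt(2) * qMax / inplaneMax
    span1 <- span1 * fac
    span2 <- span2 * fac
  }
  g1 <- seq(-span1, span1, length.out = n)
  g2 <- seq(-span2, span2, length.out = n)
  frac <- matrix(0, n * n, 3)
  frac[, p1] <- rep(g1, times = n)
  frac[, p2] <- rep(g2, each = n)
  frac[, p3] <- offset
  cartQ <- frac %*% B
  new("PlaneDefinition", gridSize = n, qMax = qMax, reciprocalBasis = B,
      inPlaneAxes = as.integer(c(p1, p2)), offset = offset,
      frac = frac, cartQ = cartQ)
}

.samePlane <- function(p1, p2) {
  p1@gridSize == p2@gridSize &&
    max(abs(p1@frac - p2@frac)) < 1e-9 &&
    max(abs(p1@reciprocalBasis - p2@reciprocalBasis)) < 1e-9
}

#' Molecular form factor on a plane
#'
#' Evaluates the complex molecular form factor
#' F(Q) = sum_i f_i(|Q|) exp(i Q . x_i) per pixel. The vacancy sentinel
#' yields an identically zero field.
#'
#' @param mol a [Molecule-class].
#' @param plane a [PlaneDefinition-class].
#' @return a [ComplexFieldPlane-class].
#' @export
molecularFormFactor <- function(mol, plane) {
  n <- plane@gridSize
  if (isVacancy(mol)) {
    return(new("ComplexFieldPlane",
               values = matrix(complex(real = 0), n, n), plane = plane))
  }
  qn <- sqrt(rowSums(plane@cartQ^2))
  F <- complex(real = numeric(n * n))
  for (el in unique(atomElements(mol))) {
    idx <- which(atomElements(mol) == el)
    phases <- plane@cartQ %*% t(mol@coords[idx, , drop = FALSE])
    F <- F + atomicFormFactor(el, qn) *
      rowSums(exp(1i * phases))
  }
  new("ComplexFieldPlane", values = matrix(F, n, n), plane = plane)
}

#' Form-factor component of the diffuse scattering
#'
#' I_FF(Q) = N m_A m_B |F_A(Q) - F_B(Q)|^2 per pixel, where N is the number
#' of unit cells (an overall scale) and m_A, m_B the species concentrations.
#'
#' @param molA,molB the two [Molecule-class] species (either may be the
#'   vacancy sentinel).
#' @param mA,mB concentrations; must sum to 1 and lie in [0, 1].
#' @param plane a [PlaneDefinition-class].
#' @param nCells scale factor N (default 1; all dataset samples are
#'   renormalized downstream).
#' @return a [ScatteringPlane-class] with componentTag "FF".
#' @export
iFFPlane <- function(molA, molB, mA, mB = 1 - mA, plane, nCells = 1) {
  if (mA < 0 || mA > 1 || mB < 0 || mB > 1)
    stop("concentrations must lie in [0, 1]", call. = FALSE)
  if (abs(mA + mB - 1) > 1e-9) stop("mA + mB must equal 1", call. = FALSE)
  stopifnot(nCells >= 1)
  FA <- molecularFormFactor(molA, plane)@values
  FB <- molecularFormFactor(molB, plane)@values
  I <- nCells * mA * mB * Mod(FA - FB)^2
  I[I < 0] <- 0
  new("ScatteringPlane", intensities = I, plane = plane, componentTag = "FF")
}
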