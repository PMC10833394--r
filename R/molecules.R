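# Molecular structures: construction, XYZ I/O, synthetic generation and
# rigid-body manipulation.

.molRadius <- function(coords) {
  if (nrow(coords) == 0) return(0)
  cen <- colMeans(coords)
  max(sqrt(rowSums(sweep(coords, 2, cen)^2)))
}

#' Construct a molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates, Angstrom.
#' @param label identifier.
#' @return a [Molecule-class].
#' @export
molecule <- function(elements, coords, label = "mol") {
  coords <- as.matrix(coords)
  if (length(elements) < 1) stop("a molecule needs at least one atom; use vacancyMolecule() for an empty site", call. = FALSE)
  storage.mode(coords) <- "double"
  new("Molecule", label = label, elements = as.character(elements),
      coords = coords, radius = .molRadius(coords))
}

#' The vacancy sentinel
#'
#' A zero-atom placeholder representing an unoccupied site. Its molecular
#' form factor is identically zero; scattering operations handle it
#' explicitly.
#'
#' @return a [Molecule-class] with no atoms.
#' @export
vacancyMolecule <- function() {
  new("Molecule", label = "vacancy", elements = character(0),
      coords = matrix(numeric(0), 0, 3), radius = 0)
}

#' Test for the vacancy sentinel
#' @param mol a [Molecule-class]
#' @export
isVacancy <- function(mol) nAtoms(mol) == 0

#' Read a molecule from an XYZ file
#'
#' Standard XYZ convention: an atom-count line, a comment line, then one
#' "Element x y z" row per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @return a [Molecule-class]; atoms in file order.
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2]
  if (length(lines) < 1) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("line 1: expected an atom count", call. = FALSE)
  if (length(lines) < n + 2)
    stop(sprintf("expected %d atom rows, found %d", n, max(0, length(lines) - 2)),
         call. = FALSE)
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("line %d: malformed atom row '%s'", ln, lines[ln]), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("line %d: non-numeric coordinate in '%s'", ln, lines[ln]),
           call. = FALSE)
    if (!tok[1] %in% supportedElements())
      stop(sprintf("line %d: unsupported element '%s'", ln, tok[1]), call. = FALSE)
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  molecule(elements, coords, label = sub("\\.xyz$", "", basename(path)))
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [Molecule-class].
#' @param path output path.
#' @param comment comment line.
#' @export
writeXYZ <- function(mol, path, comment = mol@label) {
  n <- nAtoms(mol)
  rows <- sprintf("%s %.8f %.8f %.8f", atomElements(mol),
                  mol@coords[, 1], mol@coords[, 2], mol@coords[, 3])
  writeLines(c(as.character(n), comment, rows), path)
  invisible(path)
}

#' Generate a random synthetic molecule
#'
#' Places atoms uniformly inside a sphere with a hard minimum pairwise
#' separation of 0.9 Angstrom (rejection sampling), then recentres the
#' centroid at the origin. Stands in for a curated molecular-fragment
#' library when assembling simulated datasets.
#'
#' @param seed integer seed; the result is deterministic under it.
#' @param nAtomsRange integer range c(min, max) of atom counts, within
#'   [1, 200].
#' @param elementPool symbols to draw from.
#' @param extent placement sphere radius, Angstrom (> 0).
#' @return a [Molecule-class].
#' @export
randomMolecule <- function(seed, nAtomsRange = c(6, 30),
                           elementPool = c("H", "C", "N", "O", "F", "S", "Cl"),
                           extent = 5) {
  stopifnot(extent > 0, nAtomsRange[1] >= 1, nAtomsRange[2] <= 200,
            nAtomsRange[1] <= nAtomsRange[2])
  withSeed(seed, {
    n <- if (nAtomsRange[1] == nAtomsRange[2]) nAtomsRange[1]
         else sample(seq(nAtomsRange[1], nAtomsRange[2]), 1)
    coords <- matrix(NA_real_, n, 3)
    maxTries <- 10L * n
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        # uniform in the ball of radius `extent`
        p <- rnorm(3)
        p <- p / sqrt(sum(p^2)) * extent * runif(1)^(1 / 3)
        if (i == 1 ||
            min(sqrt(rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE], 2, p)^2))) >= 0.9) {
          coords[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place atoms with 0.9 A separation; increase extent",
             call. = FALSE)
    }
    coords <- sweep(coords, 2, colMeans(coords))
    elements <- sample(elementPool, n, replace = TRUE)
    molecule(elements, coords, label = sprintf("synthetic-%d", seed))
  })
}

.rotationMatrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rigidly rotate a molecule about its centroid
#'
#' @param mol a [Molecule-class].
#' @param angles Euler angles (radians) about the Cartesian x, y, z axes,
#'   applied in that order.
#' @return the rotated [Molecule-class]; interatomic distances are preserved.
#' @export
rotateMolecule <- function(mol, angles) {
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  if (isVacancy(mol)) return(mol)
  cen <- colMeans(mol@coords)
  rot <- .rotationMatrix(angles)
  coords <- sweep(sweep(mol@coords, 2, cen) %*% t(rot), 2, cen, "+")
  molecule(atomElements(mol), coords, label = mol@label)
}

#' Rotate a group of atoms about a bond
#'
#' Rotates the listed atoms rigidly about the axis through atom `axisA`
#' toward atom `axisB` (e.g. a tert-butyl rotor about its C-N bond). All
#' other atoms, including the axis atoms, stay fixed.
#'
#' @param mol a [Molecule-class].
#' @param axisA,axisB indices of the two distinct axis atoms.
#' @param group indices of the atoms to rotate; must exclude the axis atoms.
#' @param angle rotation angle, radians.
#' @return the modified [Molecule-class].
#' @export
rotateGroupAboutBond <- function(mol, axisA, axisB, group, angle) {
  n <- nAtoms(mol)
  stopifnot(axisA != axisB, axisA %in% seq_len(n), axisB %in% seq_len(n))
  if (any(group %in% c(axisA, axisB)))
    stop("group must not contain the axis atoms", call. = FALSE)
  if (!all(group %in% seq_len(n))) stop("group index out of range", call. = FALSE)
  origin <- mol@coords[axisA, ]
  axis <- mol@coords[axisB, ] - origin
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues rotation
  k <- axis
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  rot <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  coords <- mol@coords
  g <- sweep(coords[group, , drop = FALSE], 2, origin)
  coords[group, ] <- sweep(g %*% t(rot), 2, origin, "+")
  molecule(atomElements(mol), coords, label = mol@label)
}
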