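# Quantitative analysis of separated components: Warren-Cowley refinement
# from the SRO component and form-factor model discrimination with a
# Debye-Waller correction.

#' Project a scattering plane into one reciprocal unit cell
#'
#' Each pixel's two in-plane fractional coordinates are reduced modulo 1
#' and binned on a bins x bins grid whose bin i is centred on i/bins.
#' Because the SRO cosine series is periodic in (h, k), the modulation
#' accumulates in a single cell while non-periodic contributions average
#' out. Bin values are means of contributing pixels; counts are recorded
#' and empty bins are flagged excluded.
#'
#' @param plane a [ScatteringPlane-class] (or matrix with `frac` attribute
#'   pairing). A logical `exclude` matrix of pixels may be given.
#' @param bins bins per axis (>= 8).
#' @param exclude optional logical matrix of pixels to ignore.
#' @return a [ProjectedCell-class].
#' @export
projectToUnitCell <- function(plane, bins = 64L, exclude = NULL) {
  stopifnot(bins >= 8)
  bins <- as.integer(bins)
  I <- intensities(plane)
  pd <- planeDef(plane)
  ax <- pd@inPlaneAxes
  h <- pd@frac[, ax[1]] %% 1
  k <- pd@frac[, ax[2]] %% 1
  vals <- as.numeric(I)
  keep <- rep(TRUE, length(vals))
  if (!is.null(exclude)) keep <- !as.logical(exclude)
  # nearest-lattice-point binning: bin i is centred on h = i/bins, so bin
  # means carry no systematic half-bin phase shift against the cosine basis
  bi <- (as.integer(round(h * bins)) %% bins) + 1L
  bj <- (as.integer(round(k * bins)) %% bins) + 1L
  idx <- (bj - 1L) * bins + bi
  sums <- counts <- numeric(bins * bins)
  t1 <- tapply(vals[keep], idx[keep], sum)
  t2 <- tapply(rep(1, sum(keep)), idx[keep], sum)
  sums[as.integer(names(t1))] <- t1
  counts[as.integer(names(t2))] <- t2
  values <- matrix(0, bins, bins)
  cmat <- matrix(counts, bins, bins)
  nz <- cmat > 0
  values[nz] <- matrix(sums, bins, bins)[nz] / cmat[nz]
  if (any(!nz))
    warning(sum(!nz), " empty bins flagged as excluded", call. = FALSE)
  new("ProjectedCell", values = values, counts = cmat,
      excluded = !nz, bins = bins)
}

#' Exclude low-intensity regions
#'
#' Flags bins (or pixels) below `fraction` of the maximum as excluded, the
#' usual guard against refining against noise-dominated regions.
#'
#' @param x a [ProjectedCell-class] or numeric matrix.
#' @param fraction threshold as a fraction of the maximum (default 0.05).
#' @return for a cell, the cell with the exclusion flags extended; for a
#'   matrix, a logical exclusion matrix.
#' @export
maskLowIntensity <- function(x, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 1)
  if (is(x, "ProjectedCell")) {
    thr <- fraction * max(x@values[!x@excluded])
    excl <- x@excluded | (x@values < thr)
    new("ProjectedCell", values = x@values, counts = x@counts,
        excluded = excl, bins = x@bins)
  } else {
    x < fraction * max(x)
  }
}

# Integer rotation generator acting on in-plane REAL-space lattice vectors
# (n1, n2): hexagonal sixfold sends (n1, n2) -> (n1 - n2, n1); tetragonal
# fourfold sends (n1, n2) -> (-n2, n1).
.rotGenReal <- function(order) {
  switch(as.character(order),
         "1" = diag(2),
         "2" = -diag(2),
         "3" = matrix(c(0, 1, -1, -1), 2, 2),   # (R6)^2
         "4" = matrix(c(0, 1, -1, 0), 2, 2),
         "6" = matrix(c(1, 1, -1, 0), 2, 2),
         stop("unsupported rotation order ", order, call. = FALSE))
}

# The reciprocal-space companion (inverse transpose), also integer.
.rotGenRecip <- function(order) {
  M <- .rotGenReal(order)
  t(solve(M))
}

#' Symmetrize a projected cell under an n-fold rotation
#'
#' Replaces each bin by the mean over its rotation orbit (excluded bins are
#' omitted from the mean; a bin whose whole orbit is excluded stays
#' excluded). The rotation acts on the fractional reciprocal coordinates
#' through the exact integer index map of the lattice rotation, so
#' symmetrization is idempotent and its output invariant under the
#' rotation to machine precision.
#'
#' @param cell a [ProjectedCell-class].
#' @param order rotation order (1, 2, 3, 4 or 6).
#' @return the symmetrized [ProjectedCell-class].
#' @export
symmetrize <- function(cell, order = 6L) {
  stopifnot(order >= 1)
  if (order == 1) return(cell)
  B <- cell@bins
  R <- .rotGenRecip(order)
  # orbit of each bin index under the reciprocal rotation, mod B
  ij <- as.matrix(expand.grid(i = 0:(B - 1), j = 0:(B - 1)))
  maps <- vector("list", order)
  cur <- ij
  for (s in seq_len(order)) {
    cur <- cbind(cur[, 1] * R[1, 1] + cur[, 2] * R[1, 2],
                 cur[, 1] * R[2, 1] + cur[, 2] * R[2, 2])
    cur <- round(cur) %% B
    maps[[s]] <- cur[, 1] + B * cur[, 2] + 1L
  }
  v <- as.numeric(cell@values)
  ex <- as.logical(cell@excluded)
  num <- den <- numeric(B * B)
  for (s in seq_len(order)) {
    m <- maps[[s]]
    ok <- !ex[m]
    num <- num + ifelse(ok, v[m], 0)
    den <- den + ok
  }
  out <- numeric(B * B)
  out[den > 0] <- num[den > 0] / den[den > 0]
  new("ProjectedCell", values = matrix(out, B, B), counts = cell@counts,
      excluded = matrix(den == 0, B, B), bins = B)
}

#' Equivalence classes of lattice vectors under a rotation
#'
#' Partitions a set of in-plane integer vectors into orbits of the n-fold
#' lattice rotation (the orbit of v always contains -v for even orders).
#'
#' @param vectors m x 3 integer matrix with v3 = 0.
#' @param order rotation order.
#' @return list of integer matrices, one per class, named by a
#'   representative "n1,n2,n3"; classes are ordered by shell distance.
#' @export
symmetryClasses <- function(vectors, order = 6L) {
  v <- matrix(as.integer(round(vectors)), ncol = 3)
  stopifnot(all(v[, 3] == 0))
  M <- .rotGenReal(order)
  keyOf <- function(p) paste(p, collapse = ",")
  seen <- new.env()
  classes <- list()
  for (r in seq_len(nrow(v))) {
    p <- v[r, 1:2]
    if (all(p == 0)) next
    if (!is.null(seen[[keyOf(c(p, 0))]])) next
    orbit <- list()
    cur <- p
    for (s in seq_len(order)) {
      cur <- as.integer(M %*% cur)
      k <- keyOf(c(cur, 0))
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        orbit[[length(orbit) + 1]] <- c(cur, 0L)
      }
    }
    classes[[keyOf(c(p, 0))]] <- do.call(rbind, orbit)
  }
  ord <- order(vapply(classes, function(m)
    m[1, 1]^2 + m[1, 2]^2 - m[1, 1] * m[1, 2], numeric(1)))
  classes[ord]
}

#' Linear least-squares refinement of Warren-Cowley parameters
#'
#' Fits scale * (1 + sum_classes alpha_class B_class(h, k)) to the included
#' bins of a projected cell, where B_class is the sum of cos(2 pi (h n1 +
#' k n2)) over the vectors of the equivalence class. The problem is linear
#' in (scale, scale * alpha); the scale/alpha degeneracy is resolved by
#' pinning alpha at the origin to 1 (the constant column), after which
#' alpha_class = coefficient_class / scale. Vectors failing the exclusion
#' predicate (e.g. v_z != 0) must be filtered before building classes.
#'
#' @param cell a [ProjectedCell-class] (symmetrized/masked as desired).
#' @param classes list of vector classes from [symmetryClasses()], or an
#'   m x 3 matrix (each vector its own class, +/- pair implied).
#' @return a [RefinementResult-class].
#' @export
refineAlphas <- function(cell, classes) {
  if (is.matrix(classes)) {
    cl <- lapply(seq_len(nrow(classes)), function(r)
      rbind(classes[r, ], -classes[r, ]))
    names(cl) <- apply(classes, 1, paste, collapse = ",")
    classes <- cl
  }
  B <- cell@bins
  inc <- !cell@excluded
  if (sum(inc) < length(classes) + 1)
    stop("fewer included bins than free parameters", call. = FALSE)
  hh <- (rep(0:(B - 1), times = B)) / B
  kk <- (rep(0:(B - 1), each = B)) / B
  X <- matrix(1, sum(inc), length(classes) + 1)
  hi <- hh[as.logical(inc)]
  ki <- kk[as.logical(inc)]
  for (ci in seq_along(classes)) {
    m <- classes[[ci]]
    basis <- 0
    for (r in seq_len(nrow(m)))
      basis <- basis + cos(2 * pi * (hi * m[r, 1] + ki * m[r, 2]))
    X[, ci + 1] <- basis
  }
  y <- as.numeric(cell@values)[as.logical(inc)]
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qr_$pivot[seq_len(qr_$rank)])
    stop("singular design; collinear classes: ",
         paste(c("const", names(classes))[bad], collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  scale <- beta[1]
  alphas <- beta[-1] / scale
  names(alphas) <- names(classes)
  fittedVec <- as.numeric(X %*% beta)
  fitted <- matrix(0, B, B)
  fitted[as.logical(inc)] <- fittedVec
  diffm <- matrix(0, B, B)
  diffm[as.logical(inc)] <- y - fittedVec
  new("RefinementResult", alphas = alphas, classes = classes,
      scale = unname(scale), rss = sum((y - fittedVec)^2),
      fitted = fitted, observed = cell@values, difference = diffm,
      included = inc)
}

#' Forward model of a projected cell from alpha classes
#'
#' Convenience inverse of [refineAlphas()]: builds the cell
#' scale * (1 + sum alpha_class B_class) on the same bin convention.
#'
#' @param alphas numeric vector, one per class.
#' @param classes list of vector classes (see [symmetryClasses()]).
#' @param bins bins per axis.
#' @param scale overall scale factor.
#' @return a [ProjectedCell-class].
#' @export
cellFromAlphas <- function(alphas, classes, bins = 64L, scale = 1) {
  bins <- as.integer(bins)
  hh <- (rep(0:(bins - 1), times = bins)) / bins
  kk <- (rep(0:(bins - 1), each = bins)) / bins
  v <- rep(1, bins * bins)
  for (ci in seq_along(classes)) {
    m <- classes[[ci]]
    basis <- 0
    for (r in seq_len(nrow(m)))
      basis <- basis + cos(2 * pi * (hh * m[r, 1] + kk * m[r, 2]))
    v <- v + alphas[ci] * basis
  }
  new("ProjectedCell", values = matrix(scale * v, bins, bins),
      counts = matrix(1, bins, bins),
      excluded = matrix(FALSE, bins, bins), bins = bins)
}

#' Apply an isotropic Debye-Waller correction to a calculated plane
#'
#' Multiplies the intensities pixel-wise by exp(-B |Q|^2 / (8 pi^2)), the
#' squared amplitude factor exp(-B sin^2(theta) / lambda^2), damping the
#' calculated pattern to match experimental attenuation from thermal
#' displacements.
#'
#' @param plane a [ScatteringPlane-class].
#' @param dw a [DebyeWallerModel-class] or non-negative B (Angstrom^2).
#' @return the damped [ScatteringPlane-class].
#' @export
dwCorrect <- function(plane, dw) {
  b <- if (is(dw, "DebyeWallerModel")) dw@bIso else dw
  if (b < 0) stop("B must be >= 0", call. = FALSE)
  q2 <- rowSums(planeDef(plane)@cartQ^2)
  fac <- matrix(exp(-b * q2 / (8 * pi^2)),
                gridSize(plane), gridSize(plane))
  new("ScatteringPlane", intensities = intensities(plane) * fac,
      plane = planeDef(plane), componentTag = componentTag(plane))
}

#' Fit the Debye-Waller B by least squares
#'
#' One-parameter fit of B (with a profiled overall scale) so that
#' scale * calc * exp(-B |Q|^2 / (8 pi^2)) best matches the reference in a
#' least-squares sense.
#'
#' @param reference observed/separated intensity plane (matrix or
#'   [ScatteringPlane-class]).
#' @param calc calculated [ScatteringPlane-class] (undamped).
#' @param bMax upper search bound for B (Angstrom^2).
#' @return list with `b`, `scale` and `rss`.
#' @export
fitDebyeWaller <- function(reference, calc, bMax = 30) {
  ref <- if (is(reference, "ScatteringPlane")) intensities(reference) else reference
  I <- intensities(calc)
  q2 <- rowSums(planeDef(calc)@cartQ^2)
  rv <- as.numeric(ref)
  iv <- as.numeric(I)
  obj <- function(b) {
    d <- iv * exp(-b * q2 / (8 * pi^2))
    s <- sum(rv * d) / max(sum(d * d), 1e-300)
    sum((rv - s * d)^2)
  }
  op <- optimize(obj, c(0, bMax))
  d <- iv * exp(-op$minimum * q2 / (8 * pi^2))
  s <- sum(rv * d) / max(sum(d * d), 1e-300)
  list(b = op$minimum, scale = s, rss = op$objective)
}

#' Mean-squared-error rotation scan of a molecular fragment
#'
#' For each angle, rotates the given atom group about the a->b bond axis,
#' recomputes the form-factor component against the partner molecule,
#' applies the Debye-Waller correction, square-root-normalizes, and records
#' the MSE against the (identically normalized) reference plane. Because
#' the comparison runs on normalized planes it is invariant to any global
#' positive rescaling of the reference.
#'
#' @param mol the [Molecule-class] carrying the rotor.
#' @param axisA,axisB indices of the bond axis atoms.
#' @param group indices of the rotating atoms.
#' @param angles angle grid in degrees (within [-180, 180]).
#' @param referenceFF reference normalized plane (matrix in [-1, 1]).
#' @param partner the partner [Molecule-class] of the disordered pair
#'   (default: the vacancy sentinel).
#' @param plane a [PlaneDefinition-class].
#' @param mA concentration of `mol` (default 0.5).
#' @param dw Debye-Waller B or model (default 0 = no damping).
#' @return data.frame with columns `angle` and `mse`; attribute `argmin`
#'   holds the angle of minimum MSE.
#' @export
rotationScan <- function(mol, axisA, axisB, group, angles = seq(-60, 60, 1),
                         referenceFF, partner = vacancyMolecule(), plane,
                         mA = 0.5, dw = 0) {
  stopifnot(all(angles >= -180), all(angles <= 180))
  mse <- vapply(angles, function(deg) {
    m <- rotateGroupAboutBond(mol, axisA, axisB, group, deg * pi / 180)
    iff <- iFFPlane(m, partner, mA, 1 - mA, plane)
    iff <- dwCorrect(iff, dw)
    nrm <- sqrtNormalize(iff)
    mean((nrm - referenceFF)^2)
  }, numeric(1))
  out <- data.frame(angle = angles, mse = mse)
  attr(out, "argmin") <- angles[which.min(mse)]
  out
}
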