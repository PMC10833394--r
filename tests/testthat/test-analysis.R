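test_that("projection into one reciprocal cell conserves pixels and periodicity", {
  pd <- planeDefinition(1, c(1, 2), offset = 0, gridSize = 33, qMax = pi)
  const <- new("ScatteringPlane", intensities = matrix(2.5, 33, 33),
               plane = pd, componentTag = "SRO")
  pc <- projectToUnitCell(const, bins = 8)
  expect_equal(cellValues(pc)[!excludedBins(pc)],
               rep(2.5, sum(!excludedBins(pc))))
  expect_equal(sum(cellCounts(pc)), 33 * 33)

  # an exactly periodic cosine input projects onto its single-period values
  mod <- sroModel(0.5, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), c(1, -0.4, 0.2))
  ip <- iSROPlane(mod, planeDefinition(1, c(1, 2), offset = 0, gridSize = 65,
                                       qMax = 2 * pi))
  pc2 <- projectToUnitCell(ip, bins = 32)
  hh <- (0:31) / 32
  expect_lt(max(abs(cellValues(pc2) -
                    0.25 * outer(hh, hh, function(h, k)
                      pmax(0, 1 - 0.8 * cos(2 * pi * h) + 0.4 * cos(2 * pi * k))))),
            1e-9)
})

test_that("low-intensity masking excludes exactly the intended regions", {
  m <- matrix(1, 8, 8); m[1:4, ] <- 0
  cell <- new("ProjectedCell", values = m, counts = matrix(1, 8, 8),
              excluded = matrix(FALSE, 8, 8), bins = 8L)
  expect_equal(sum(excludedBins(maskLowIntensity(cell, 0))), 0)
  mk <- maskLowIntensity(cell, 0.05)
  expect_equal(unname(excludedBins(mk)), unname(m == 0))
  constCell <- new("ProjectedCell", values = matrix(3, 8, 8),
                   counts = matrix(1, 8, 8),
                   excluded = matrix(FALSE, 8, 8), bins = 8L)
  expect_equal(sum(excludedBins(maskLowIntensity(constCell, 0.05))), 0)
})

test_that("symmetrization is idempotent and produces invariant cells", {
  set.seed(3)
  cell <- new("ProjectedCell", values = matrix(runif(64 * 64), 64, 64),
              counts = matrix(1, 64, 64), excluded = matrix(FALSE, 64, 64),
              bins = 64L)
  expect_equal(cellValues(symmetrize(cell, 1)), cellValues(cell))
  s1 <- symmetrize(cell, 6)
  s2 <- symmetrize(s1, 6)
  expect_lt(max(abs(cellValues(s2) - cellValues(s1))), 1e-10)
  s4 <- symmetrize(symmetrize(cell, 4), 4)
  expect_lt(max(abs(cellValues(s4) - cellValues(symmetrize(cell, 4)))), 1e-10)
})

test_that("sixfold orbits merge the hexagonally equivalent vectors", {
  cls <- hexClasses(2)
  expect_equal(names(cls), c("1,0,0", "2,1,0", "2,0,0"))
  orb1 <- apply(cls[["1,0,0"]], 1, paste, collapse = ",")
  expect_setequal(orb1, c("1,0,0", "1,1,0", "0,1,0", "-1,0,0", "-1,-1,0", "0,-1,0"))
})

test_that("refinement recovers a benchmark alpha set exactly and under noise", {
  cls <- hexClasses(5)
  truth <- unname(benchmarkAlphas[names(cls)])
  cell <- cellFromAlphas(truth, cls, bins = 64, scale = 3.1)
  rr <- refineAlphas(cell, cls)
  expect_lt(max(abs(wcAlphas(rr) - truth)), 1e-8)
  expect_equal(refScale(rr), 3.1, tolerance = 1e-10)
  expect_lt(residualSS(rr), 1e-16)

  # flat cell refines to all-zero alphas with scale = mean
  flat <- new("ProjectedCell", values = matrix(1.7, 64, 64),
              counts = matrix(1, 64, 64), excluded = matrix(FALSE, 64, 64),
              bins = 64L)
  rf <- refineAlphas(flat, cls)
  expect_lt(max(abs(wcAlphas(rf))), 1e-12)
  expect_equal(refScale(rf), 1.7, tolerance = 1e-12)

  # 5% additive noise: mean max-abs error over 20 seeds below 0.01
  errs <- vapply(1:20, function(s) {
    v <- cellValues(cell) + withr::with_seed(s, matrix(
      rnorm(64 * 64, sd = 0.05 * max(cellValues(cell))), 64, 64))
    nc <- new("ProjectedCell", values = v, counts = cellCounts(cell),
              excluded = excludedBins(cell), bins = 64L)
    max(abs(wcAlphas(refineAlphas(nc, cls)) - truth))
  }, numeric(1))
  expect_lt(mean(errs), 0.01)

  # collinear classes are reported
  dup <- c(cls[1], cls[1])
  expect_error(refineAlphas(cell, dup), "singular design")
})

test_that("the full SRO pipeline recovers measured alphas from a projected plane", {
  cfg <- mcGenerateConfiguration(0.5, c(-0.35, 0.2, 0), dims = c(24, 24, 24),
                                 seed = 11)
  mm <- measureAlphas(cfg, canonicalVectors(5, zOnly = TRUE))
  # span 9.5 cells on a 65-pixel grid puts every pixel on the 1/64 bin
  # lattice, so the projection samples each bin centre exactly
  pd <- planeDefinition(10, c(1, 2), offset = 0, gridSize = 65,
                        qMax = 2 * pi / 10 * 9.5)
  pc <- projectToUnitCell(iSROPlane(mm, pd), bins = 64)
  v2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0),
              c(2, 0, 0), c(0, 2, 0))
  rr <- refineAlphas(pc, v2)
  truth <- vapply(seq_len(nrow(v2)), function(r) {
    key <- apply(wcVectors(mm), 1, paste, collapse = ",")
    i <- which(key == paste(v2[r, ], collapse = ",") |
                 key == paste(-v2[r, ], collapse = ","))
    wcAlphas(mm)[i[1]]
  }, numeric(1))
  expect_lt(max(abs(wcAlphas(rr) - truth)), 0.02)
})

test_that("Debye-Waller correction damps monotonically and B is recoverable", {
  pd <- tinyPlane(n = 33, qMax = 5)
  mol <- randomMolecule(5, nAtomsRange = c(8, 8))
  iff <- iFFPlane(mol, vacancyMolecule(), 0.5, 0.5, pd)

  expect_equal(intensities(dwCorrect(iff, 0)), intensities(iff))
  damped <- dwCorrect(iff, 3.5)
  q2 <- rowSums(cartesianQ(pd)^2)
  ratio <- as.numeric(intensities(damped)) / pmax(as.numeric(intensities(iff)), 1e-12)
  ord <- order(q2)
  expect_true(all(diff(ratio[ord])[diff(q2[ord]) > 1e-9] < 0))
  expect_error(dwCorrect(iff, -1), ">= 0")

  fit <- fitDebyeWaller(intensities(damped), iff)
  expect_lt(abs(fit$b - 3.5) / 3.5, 0.01)
})

test_that("rotation scans localize the reference angle and respect symmetry", {
  # build a molecule with a 3-atom rotor off an axis
  s3 <- 0.6 * sqrt(3)
  base <- rbind(c(0, 0, 0), c(0, 0, 1.5),
                c(1.2, 0, 2.2), c(-0.6, s3, 2.2), c(-0.6, -s3, 2.2))
  mol <- molecule(c("N", "C", "C", "C", "C"), base)
  pd <- tinyPlane(n = 25, qMax = 4)
  grp <- 3:5

  theta0 <- 20
  ref <- sqrtNormalize(dwCorrect(
    iFFPlane(rotateGroupAboutBond(mol, 1, 2, grp, theta0 * pi / 180),
             vacancyMolecule(), 0.5, 0.5, pd), 2))
  scan <- rotationScan(mol, 1, 2, grp, angles = seq(-60, 60, 5),
                       referenceFF = ref, plane = pd, dw = 2)
  expect_equal(attr(scan, "argmin"), theta0)
  expect_lt(min(scan$mse), 1e-12)

  # scaling the reference's underlying intensities changes nothing:
  # normalization is scale-free by construction
  ref2 <- sqrtNormalize(3.7 * intensities(dwCorrect(
    iFFPlane(rotateGroupAboutBond(mol, 1, 2, grp, theta0 * pi / 180),
             vacancyMolecule(), 0.5, 0.5, pd), 2)))
  expect_equal(ref2, ref, tolerance = 1e-12)

  # exact threefold rotor: the scan is 120-degree periodic
  scanA <- rotationScan(mol, 1, 2, grp, angles = seq(-60, 0, 10),
                        referenceFF = ref, plane = pd, dw = 2)
  scanB <- rotationScan(mol, 1, 2, grp, angles = seq(-60, 0, 10) + 120,
                        referenceFF = ref, plane = pd, dw = 2)
  expect_equal(scanA$mse, scanB$mse, tolerance = 1e-8)
})
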