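test_that("atomic form factors hit the electron count at q = 0 and decay", {
  for (el in supportedElements()) {
    cf <- formFactorCoefficients(el)
    expect_lt(abs(atomicFormFactor(el, 0) - cf$z) / cf$z, 0.02)
  }
  # dense evaluation: carbon non-increasing on [0, 2] 1/A
  q <- seq(0, 2, length.out = 400)
  f <- atomicFormFactor("C", q)
  expect_true(all(diff(f) <= 1e-12))
  expect_error(atomicFormFactor("C", -0.1), "non-negative")
})

test_that("molecular form factors obey phase-free, translation and closed-form checks", {
  pd <- tinyPlane()
  one <- molecule("C", rbind(c(0, 0, 0)))
  F1 <- fieldValues(molecularFormFactor(one, pd))
  expect_lt(max(abs(Im(F1))), 1e-10)
  qn <- sqrt(rowSums(cartesianQ(pd)^2))
  expect_equal(as.numeric(Re(F1)), atomicFormFactor("C", qn), tolerance = 1e-12)

  # rigid translation changes the phase only
  m <- randomMolecule(9, nAtomsRange = c(6, 6))
  mt <- molecule(atomElements(m), sweep(atomCoords(m), 2, c(1.3, -0.4, 2.0), "+"))
  expect_lt(max(abs(Mod(fieldValues(molecularFormFactor(mt, pd))) -
                    Mod(fieldValues(molecularFormFactor(m, pd))))), 1e-8)

  # homonuclear diatomic: F = 2 f cos(Qx d / 2), against brute-force sum
  d <- 1.4
  di <- diatomic("C", d)
  Fd <- fieldValues(molecularFormFactor(di, pd))
  qx <- cartesianQ(pd)[, 1]
  closed <- 2 * atomicFormFactor("C", qn) * cos(qx * d / 2)
  expect_lt(max(abs(as.numeric(Fd) - closed)), 1e-8)
  brute <- vapply(seq_len(nrow(cartesianQ(pd))), function(p)
    sum(atomicFormFactor("C", qn[p]) *
          exp(1i * cartesianQ(pd)[p, ] %*% t(atomCoords(di)))), complex(1))
  expect_lt(max(Mod(as.numeric(Fd) - brute)), 1e-8)

  expect_equal(max(Mod(fieldValues(molecularFormFactor(vacancyMolecule(), pd)))), 0)
})

test_that("the form-factor component satisfies its identities", {
  pd <- tinyPlane()
  a <- randomMolecule(1, nAtomsRange = c(5, 5))
  b <- randomMolecule(2, nAtomsRange = c(7, 7))

  expect_equal(max(intensities(iFFPlane(a, a, 0.3, 0.7, pd))), 0)
  expect_equal(max(intensities(iFFPlane(a, b, 0, 1, pd))), 0)

  # vacancy partner reduces to a |F_A|^2 measurement
  iv <- iFFPlane(a, vacancyMolecule(), 0.4, 0.6, pd)
  FA <- fieldValues(molecularFormFactor(a, pd))
  expect_equal(intensities(iv), 0.4 * 0.6 * Mod(FA)^2, tolerance = 1e-10)

  # swapping the species leaves I_FF unchanged; N scales exactly
  i1 <- iFFPlane(a, b, 0.3, 0.7, pd)
  i2 <- iFFPlane(b, a, 0.7, 0.3, pd)
  expect_equal(intensities(i1), intensities(i2), tolerance = 1e-12)
  i5 <- iFFPlane(a, b, 0.3, 0.7, pd, nCells = 5)
  expect_equal(intensities(i5), 5 * intensities(i1), tolerance = 1e-12)

  expect_error(iFFPlane(a, b, -0.1, 1.1, pd), "\\[0, 1\\]")
})

test_that("Friedel symmetry holds on a symmetric in-plane grid", {
  # odd grid, offset 0: pixel (i, j) pairs with (n+1-i, n+1-j) as -Q
  pd <- tinyPlane(n = 33, offset = 0)
  a <- randomMolecule(4, nAtomsRange = c(8, 8))
  b <- randomMolecule(8, nAtomsRange = c(6, 6))
  I <- intensities(iFFPlane(a, b, 0.45, 0.55, pd))
  rev2 <- I[rev(seq_len(33)), rev(seq_len(33))]
  expect_lt(max(abs(I - rev2)) / max(I), 1e-8)
})
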