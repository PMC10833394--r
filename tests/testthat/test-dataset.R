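test_that("Vegard's law interpolates linearly between pure lattices", {
  expect_equal(vegardLattice(3, 5, 1), 2 * (3 + 1.2))
  expect_equal(vegardLattice(3, 5, 0), 2 * (5 + 1.2))
  expect_equal(vegardLattice(3, 5, 0.5),
               (vegardLattice(3, 5, 1) + vegardLattice(3, 5, 0)) / 2)
  a <- vapply(seq(0, 1, 0.1), function(m) vegardLattice(5, 3, m), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_error(vegardLattice(-1, 3, 0.5), "positive")
})

test_that("plane selection yields 12 MC planes (4 per axis) or 4 symmetry planes", {
  mc <- selectPlanes(10, "mc", seed = 3, gridSize = 16)
  expect_length(mc, 12)
  fixedAxis <- vapply(mc, function(p) setdiff(1:3, p@inPlaneAxes), integer(1))
  expect_equal(unname(table(fixedAxis)), rep(4L, 3), ignore_attr = TRUE)
  for (ax in 1:3) {
    offs <- vapply(mc[fixedAxis == ax], slot, numeric(1), "offset")
    expect_false(anyDuplicated(offs) > 0)
  }
  qm <- vapply(mc, slot, numeric(1), "qMax")
  expect_true(all(qm >= 6 & qm <= 8))

  sym <- selectPlanes(c(10, 10, 10, 90, 90, 120), "symmetry", seed = 3,
                      gridSize = 16)
  expect_length(sym, 4)
  expect_true(all(vapply(sym, function(p)
    all(p@inPlaneAxes == c(1, 2)), logical(1))))

  mc2 <- selectPlanes(10, "mc", seed = 3, gridSize = 16)
  expect_equal(vapply(mc2, slot, numeric(1), "qMax"), qm)
})

test_that("the total scattering is the pixel-wise component product", {
  pd <- tinyPlane(n = 17)
  a <- randomMolecule(1, nAtomsRange = c(4, 4))
  b <- randomMolecule(2, nAtomsRange = c(4, 4))
  iff <- iFFPlane(a, b, 0.5, 0.5, pd)
  flat <- iSROPlane(sroModel(0.5, rbind(c(0, 0, 0)), 1), pd)
  tot <- composeTotal(iff, flat)
  expect_equal(intensities(tot), intensities(iff) * 0.25, tolerance = 1e-12)

  mod <- sroModel(0.5, rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -0.3))
  isro <- iSROPlane(mod, pd)
  t1 <- intensities(composeTotal(iff, isro))
  expect_equal(t1, intensities(iff) * intensities(isro), tolerance = 1e-12)

  other <- tinyPlane(n = 17, qMax = 2.5)
  expect_error(composeTotal(iff, iSROPlane(mod, other)), "not aligned")
})

test_that("square-root normalization maps [0, max] onto [-1, +1] exactly", {
  m <- matrix(c(0, 1, 4, 9), 2, 2)
  y <- sqrtNormalize(m)
  expect_equal(y[1, 1], -1)
  expect_equal(y[2, 2], 1)
  expect_equal(y[2, 1], 2 * 1 / 3 - 1)
  y2 <- sqrtNormalize(matrix(runif(64) * 100, 8, 8))
  expect_true(all(y2 >= -1 & y2 <= 1))
  expect_equal(max(y2), 1)
  expect_error(sqrtNormalize(matrix(0, 4, 4)), "degenerate")
})

test_that("synthetic artefact masks are seeded, band-structured and mostly live", {
  m1 <- syntheticArtifactMask(5, gridSize = 128)
  m2 <- syntheticArtifactMask(5, gridSize = 128)
  expect_identical(maskMatrix(m1), maskMatrix(m2))

  live <- vapply(1:1000, function(s)
    mean(!maskMatrix(syntheticArtifactMask(s, gridSize = 64))), numeric(1))
  expect_true(all(live >= 0.6))
})

test_that("artefact application floors dead pixels at -1 and is idempotent", {
  p <- matrix(runif(64 * 64, -1, 1), 64, 64)
  mk <- syntheticArtifactMask(12, gridSize = 64)
  ap <- applyArtifact(p, mk)
  expect_true(all(ap[maskMatrix(mk)] == -1))
  expect_equal(ap[!maskMatrix(mk)], p[!maskMatrix(mk)])
  expect_equal(applyArtifact(ap, mk), ap)

  empty <- new("ArtifactMask", mask = matrix(FALSE, 64, 64), label = "empty")
  expect_equal(applyArtifact(p, empty), p)
  expect_error(applyArtifact(p[1:10, 1:10], mk), "sizes differ")
})

test_that("the Wasserstein filter removes duplicates and shifted copies as expected", {
  base <- matrix(runif(32 * 32), 32, 32)
  out <- wassersteinFilter(list(base, base + 0, base * 2), threshold = 1e-9)
  expect_equal(out$kept, c(1, 3))
  expect_equal(out$removed, 1)

  # constant shift c has 1D transport distance exactly c
  shifted <- base + 0.37
  d <- mean(abs(sort(as.numeric(base)) - sort(as.numeric(shifted))))
  expect_equal(d, 0.37, tolerance = 1e-12)
  out2 <- wassersteinFilter(list(base, shifted), threshold = 0.36)
  expect_equal(out2$removed, 0)
  out3 <- wassersteinFilter(list(base, shifted), threshold = 0.38)
  expect_equal(out3$removed, 1)

  # independent random planes sit far above the relative default threshold
  rnd <- withr::with_seed(1, lapply(1:6, function(i) matrix(runif(256), 16, 16)))
  expect_equal(wassersteinFilter(rnd)$removed, 0)
  expect_equal(wassersteinFilter(rnd, threshold = 0)$removed, 0)
})

test_that("dataset bookkeeping reproduces configured totals and invariants", {
  dry <- buildDataset(3, datasetConfig(), seed = 1, dryRun = TRUE)
  expect_equal(dry$manifest$counts$planesPerPair, 200)
  expect_equal(dry$manifest$counts$preFilter, 600)
  expect_equal(dry$manifest$counts$final, 600)

  ds <- smokeDataset()
  cts <- ds$manifest$counts
  expect_equal(cts$final, cts$preFilter - cts$removed)
  expect_equal(length(ds$samples), cts$final)
  expect_equal(nrow(ds$manifest$samples), cts$final)

  for (s in ds$samples[seq_len(min(5, length(ds$samples)))]) {
    expect_true(validObject(s))
    dead <- s@input == -1 & s@inputClean != -1
    live <- !dead
    expect_equal(s@input[live], s@inputClean[live])
    # product of normalized components is a monotone image of the clean input
    expect_gt(cor(as.numeric((s@gtFF + 1) * (s@gtSRO + 1)),
                  as.numeric(s@inputClean), method = "spearman"), 0.99)
  }
})
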