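test_that("Warren-Cowley measurement reproduces exact closed-form cases", {
  cb <- checkerboardConfig(8)
  m <- measureAlphas(cb, rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(wcAlphas(m), c(1, -1, 1))

  # uniformly random labels: |alpha_100| bounded by binomial sampling noise
  for (s in 1:5) {
    lab <- withr::with_seed(s, array(as.integer(runif(32^3) < 0.5), dim = c(32, 32, 32)))
    cfg <- occupancyConfiguration(lab)
    a <- wcAlphas(measureAlphas(cfg, rbind(c(1, 0, 0))))
    expect_lt(abs(a), 4 / sqrt(32^3))
  }

  allA <- occupancyConfiguration(array(1L, dim = c(8, 8, 8)))
  expect_error(measureAlphas(allA, rbind(c(1, 0, 0))), "degenerate")
})

test_that("MC annealing reaches axis targets and conserves composition", {
  cfg0 <- mcGenerateConfiguration(0.5, c(0, 0, 0), dims = c(24, 24, 24), seed = 2)
  expect_lt(attr(cfg0, "cost"), 1e-3)

  cfg1 <- mcGenerateConfiguration(0.5, c(-0.5, 0, 0), dims = c(24, 24, 24), seed = 3)
  a100 <- attr(cfg1, "achieved")[1]
  expect_gte(a100, -0.55); expect_lte(a100, -0.45)

  # swap moves conserve the exact species count
  expect_equal(sum(cfg1@labels), round(0.5 * 24^3))
  expect_error(mcGenerateConfiguration(0.9, c(-5, 0, 0), seed = 1), "infeasible")
})

test_that("realistic SRO draws are seeded, feasible and origin-normalized", {
  m1 <- sampleRealisticSRO(1, vectorCutoff = 3, dims = c(12, 12, 12), sweeps = 30)
  m2 <- sampleRealisticSRO(2, vectorCutoff = 3, dims = c(12, 12, 12), sweeps = 30)
  expect_false(isTRUE(all.equal(wcAlphas(m1), wcAlphas(m2))))
  m1b <- sampleRealisticSRO(1, vectorCutoff = 3, dims = c(12, 12, 12), sweeps = 30)
  expect_identical(wcAlphas(m1), wcAlphas(m1b))

  for (m in list(m1, m2)) {
    p <- (1 - concentrations(m)["mA"]) * (1 - wcAlphas(m))
    expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
    zero <- rowSums(wcVectors(m) != 0) == 0
    expect_equal(unname(wcAlphas(m)[zero]), 1)
  }
})

test_that("damped-oscillator models decay, clamp and stay feasible", {
  vecs <- canonicalVectors(3)
  sh <- shellIndex(vecs)

  m0 <- oscillatorAlphas(list(amplitude = 1.2, decay = 0.5, frequency = 0),
                         vecs, sh)
  a0 <- wcAlphas(m0)[sh > 0 & sh <= 5]
  x0 <- sh[sh > 0 & sh <= 5]
  expect_true(all(a0 > 0))
  expect_true(all(tapply(a0, x0, unique) == sort(tapply(a0, x0, unique), decreasing = TRUE)))

  # bound |alpha(x)| <= A exp(-d) for x >= 1
  mb <- oscillatorAlphas(list(amplitude = 1.5, decay = 1.2, frequency = 0.7),
                         vecs, sh)
  expect_lt(max(abs(wcAlphas(mb)[sh >= 1])), 0.46)

  # exhaustive scan: all alphas within the global bound and p feasible
  for (s in 1:20) {
    p <- randomOscillatorParams(s)
    m <- oscillatorAlphas(p, vecs, sh)
    a <- wcAlphas(m)[sh >= 1]
    expect_true(all(abs(a) <= max(1.5 * exp(-0.1), 1) + 1e-12))
    pp <- 0.5 * (1 - wcAlphas(m))
    expect_true(all(pp >= 0 & pp <= 1))
  }
  expect_error(oscillatorAlphas(list(amplitude = 2, decay = 0.5, frequency = 0),
                                vecs, sh), "amplitude")
})

test_that("the cosine series matches its closed form and stays periodic", {
  pd <- tinyPlane(n = 41, qMax = 3)
  flat <- iSROPlane(sroModel(0.4, rbind(c(0, 0, 0)), 1), pd)
  expect_equal(intensities(flat), matrix(0.4 * 0.6, 41, 41), tolerance = 1e-12)

  a <- 0.3
  mod <- sroModel(0.5, rbind(c(0, 0, 0), c(1, 0, 0)), c(1, a))
  I <- intensities(iSROPlane(mod, pd))
  h <- matrix(fracCoords(pd)[, 1], 41, 41)
  expect_lt(max(abs(I - 0.25 * pmax(0, 1 + 2 * a * cos(2 * pi * h)))), 1e-10)

  # periodicity under h -> h + 1: evaluate on a shifted plane
  pdShift <- new("PlaneDefinition", gridSize = pd@gridSize, qMax = pd@qMax * 3,
                 reciprocalBasis = pd@reciprocalBasis,
                 inPlaneAxes = pd@inPlaneAxes, offset = pd@offset,
                 frac = sweep(pd@frac, 2, c(1, 1, 0), "+"),
                 cartQ = sweep(pd@frac, 2, c(1, 1, 0), "+") %*% pd@reciprocalBasis)
  I2 <- intensities(iSROPlane(mod, pdShift))
  expect_lt(max(abs(I - I2)), 1e-9)

  expect_error(iSROPlane(sroModel(0.5, rbind(c(1, 0, 0)), 0.2), pd), "0,0,0")
})

test_that("cosine series from measured alphas equals the direct occupancy-sum oracle", {
  cfg <- mcGenerateConfiguration(0.4, c(-0.2, 0.15, 0.05), dims = c(16, 16, 16),
                                 seed = 9)
  # full in-box symmetric vector set; "full" convention counts each once
  vecs <- as.matrix(expand.grid(-8:7, -8:7, -8:7))
  mm <- measureAlphas(cfg, vecs)
  pd <- planeDefinition(1, c(1, 2), offset = 0, gridSize = 17, qMax = pi)
  serie <- intensities(iSROPlane(mm, pd, convention = "full"))
  orac <- intensities(directSumOracle(cfg, pd))
  expect_lt(max(abs(serie - orac)) / max(orac), 0.01)

  # all-A would be degenerate upstream; checkerboard peaks at zone boundary
  cb <- checkerboardConfig(8)
  pdc <- planeDefinition(1, c(1, 2), offset = 0.5, gridSize = 9, qMax = pi)
  Icb <- intensities(directSumOracle(cb, pdc))
  pk <- which(Icb == max(Icb), arr.ind = TRUE)
  hk <- fracCoords(pdc)[(pk[1, 2] - 1) * 9 + pk[1, 1], ]
  expect_equal(abs(hk[1:2] %% 1), c(0.5, 0.5), ignore_attr = TRUE)
  big <- occupancyConfiguration(array(rep_len(c(0L, 1L), 33^3), dim = c(33, 33, 33)))
  expect_error(directSumOracle(big, pdc), "too large")
})

test_that("SRO models serialize to tabular text and back", {
  m <- sampleRealisticSRO(4, vectorCutoff = 2, dims = c(10, 10, 10), sweeps = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSROModel(m, path)
  m2 <- readSROModel(path)
  expect_equal(concentrations(m2), concentrations(m), tolerance = 1e-9)
  expect_equal(wcVectors(m2), wcVectors(m))
  expect_equal(wcAlphas(m2), wcAlphas(m), tolerance = 1e-10)
})
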