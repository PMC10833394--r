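# Shared fixtures, built in code at test time.

# a small plane on a cubic 10 A cell; odd grid so Q = 0 sits on a pixel
tinyPlane <- function(n = 33, qMax = 3, offset = 0, axes = c(1, 2), cell = 10) {
  planeDefinition(cell, inPlaneAxes = axes, offset = offset,
                  gridSize = n, qMax = qMax)
}

# deterministic two-atom molecule along x
diatomic <- function(el = "C", d = 1.4) {
  molecule(c(el, el), rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)), label = "diatomic")
}

# checkerboard occupancy (perfect alternation, mA = 0.5)
checkerboardConfig <- function(L = 8) {
  g <- expand.grid(seq_len(L), seq_len(L), seq_len(L))
  occupancyConfiguration(array(as.integer((g[, 1] + g[, 2] + g[, 3]) %% 2),
                               dim = c(L, L, L)))
}

# hexagonal-plane sixfold classes for shells 1..nmax (Table-2-style set)
hexClasses <- function(nmax = 5) {
  reps <- do.call(rbind, lapply(seq_len(nmax), function(n1) cbind(n1, 0:(n1 - 1), 0)))
  symmetryClasses(reps, 6)
}

# literature-derived Warren-Cowley benchmark for a hexagonal columnar
# molecular crystal with negative nearest-neighbour in-plane correlation,
# keyed by representative vector (a realistic 15-parameter alpha set)
benchmarkAlphas <- c(
  "1,0,0" = -0.2474, "2,0,0" = 0.1094, "2,1,0" = 0.0824, "3,0,0" = -0.03075,
  "3,1,0" = -0.0529, "3,2,0" = -0.0378, "4,0,0" = 0.0109, "4,1,0" = 0.0186,
  "4,2,0" = 0.0252, "4,3,0" = 0.0107, "5,0,0" = -0.0026, "5,1,0" = -0.0055,
  "5,2,0" = -0.0104, "5,3,0" = -0.0086, "5,4,0" = -0.0037)

# tiny fast dataset for network tests
smokeDataset <- function(nPairs = 2, grid = 32L, seed = 7) {
  cfg <- datasetConfig(sroSetsMC = 2, planesPerMC = 2, sroSetsSym = 1,
                       planesPerSym = 2, gridSize = grid,
                       mcDims = c(10L, 10L, 10L), mcSweeps = 30L,
                       vectorCutoff = 3L)
  pairs <- lapply(seq_len(nPairs), function(i)
    list(randomMolecule(100 + i, nAtomsRange = c(4, 10)),
         randomMolecule(200 + i, nAtomsRange = c(4, 10))))
  buildDataset(pairs, cfg, seed = seed)
}
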