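# diffsep

Simulation and separation of single-crystal diffuse scattering from
binary substitutional disorder.

## The problem

In a crystal where each unit cell hosts one of two molecular units, A or
B (one disordered site per cell), the diffuse scattering factorizes into
a product of two components:

- a **form-factor** term from the contrast between the two units,
  *I*<sub>FF</sub>(**Q**) = *N m*<sub>A</sub>*m*<sub>B</sub> |*F*<sub>A</sub>(**Q**) − *F*<sub>B</sub>(**Q**)|²,
  with *F*(**Q**) = Σ<sub>i</sub> *f*<sub>i</sub>(|**Q**|) exp(*i* **Q**·**x**<sub>i</sub>) the molecular form factor — a
  slowly varying, continuous function carrying structural information;
- a **chemical short-range-order** term, the Warren–Cowley cosine series
  *I*<sub>SRO</sub>(**Q**) = *N m*<sub>A</sub>*m*<sub>B</sub> Σ<sub>**v**</sub> α<sub>**v**</sub> cos(2π (*h*,*k*,*l*)·**v**),
  with α<sub>**v**</sub> = 1 − *p*<sup>**v**</sup><sub>AB</sub>/*m*<sub>B</sub> —
  a sharp, periodic pattern carrying the local ordering.

Analysed separately, each component yields quantitative disorder and
structural models, but the measured product cannot be factorized
algebraically without knowing one factor. This package provides, for
crystallographers and methods developers working on disorder:

- simulation of both components on reciprocal-space plane grids
  (embedded atomic form factors, arbitrary unit cells, vacancy partners);
- Warren–Cowley machinery: exact pair-count measurement, Metropolis
  annealing to target correlations with composition-conserving swaps,
  damped-oscillator models for symmetry-restricted ordering, and a
  brute-force occupancy-sum oracle;
- a paired-dataset builder following a Vegard's-law lattice recipe with
  plane selection, Wasserstein de-duplication, square-root normalization
  and synthetic detector-artefact injection;
- a pair of parallel conditional image-translation networks (U-Net
  generators, patch discriminators, λ = 100 L1 term and a smooth-L1
  product-consistency step), implemented natively and exercisable at
  reduced scale on a CPU, that learn to separate the two components;
- refinement tools for the separated components: projection into one
  reciprocal unit cell, n-fold symmetrization, linear least-squares
  refinement of Warren–Cowley parameters under symmetry constraints,
  isotropic Debye–Waller correction/fitting, and MSE rotation scans for
  discriminating molecular-fragment orientations.

## Worked example

Simulate a disordered crystal with known short-range order, compose the
total scattering, then recover the Warren–Cowley parameters from the SRO
component:

```r
library(diffsep)

## a 24^3 configuration annealed to target axis correlations
cfg <- mcGenerateConfiguration(mA = 0.5, targets = c(-0.35, 0.2, 0),
                               dims = c(24, 24, 24), seed = 11)
model <- measureAlphas(cfg, canonicalVectors(5, zOnly = TRUE))
round(attr(cfg, "achieved"), 3)
#> [1] -0.35  0.20  0.00

## simulate both components and their product on an hk0 plane
molA <- randomMolecule(1); molB <- randomMolecule(2)
a <- vegardLattice(molRadius(molA), molRadius(molB), 0.5)
pd <- planeDefinition(a, inPlaneAxes = c(1, 2), offset = 0,
                      gridSize = 65, qMax = 2 * pi / a * 9.5)
iff   <- iFFPlane(molA, molB, 0.5, 0.5, pd)
isro  <- iSROPlane(model, pd)
total <- composeTotal(iff, isro)
total
#> ScatteringPlane [TOTAL]: 65x65, intensity range [0.2301, 2620]

## project the SRO component into one reciprocal cell and refine
pc  <- projectToUnitCell(isro, bins = 64)
fit <- refineAlphas(pc, rbind(c(1,0,0), c(0,1,0), c(1,1,0), c(2,0,0)))
round(wcAlphas(fit), 4)
#>   1,0,0   0,1,0   1,1,0   2,0,0
#> -0.3495  0.2002 -0.1256  0.1293
```

The refined values reproduce the parameters measured directly from the
configuration (−0.3495, 0.2002, −0.1256, 0.1293) to the fourth decimal:
the refinement is a linear problem and exact on noiseless data.

Training and separation at reduced scale:

```r
cfgD  <- datasetConfig(sroSetsMC = 3, planesPerMC = 6, sroSetsSym = 4,
                       planesPerSym = 4, gridSize = 64L)
pairs <- lapply(1:7, function(i) list(randomMolecule(100 + i),
                                      randomMolecule(200 + i)))
ds    <- buildDataset(pairs, cfgD, seed = 7)
st    <- trainEpochs(initTrainState(ganConfig(gridSize = 64), seed = 3),
                     ds$samples[1:200], epochs = 5)
out   <- decompose(st, ds$samples[[201]]@input)   # list(ff, sro) in [-1, 1]
```

A thin command-line front-end over the same functions lives in
`inst/cli/diffsep.R` (`build-dataset`, `train`, `decompose`,
`refine-sro`, `rotate-scan`).

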