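---
title: "Simulating and separating the components of binary-disorder diffuse scattering"
author: "diffsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and separating the components of binary-disorder diffuse scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffsep)
```

## The model

Consider a molecular crystal in which every unit cell hosts one of two
rigid units, A or B, with average concentrations $m_A + m_B = 1$ and one
disordered site per cell. For purely substitutional disorder the diffuse
intensity factorizes into the product of two components,

$$I_D(\mathbf{Q}) = I_{FF}(\mathbf{Q}) \cdot I_{SRO}(\mathbf{Q}),$$

with a *form-factor* term driven by the contrast between the two units,

$$I_{FF}(\mathbf{Q}) = N\, m_A m_B\, \lvert F_A(\mathbf{Q}) - F_B(\mathbf{Q})\rvert^2,
\qquad F(\mathbf{Q}) = \sum_{i=1}^{N_{mol}} f_i(\lvert\mathbf{Q}\rvert)\,
e^{i \mathbf{Q}\cdot\mathbf{x}_i},$$

and a *chemical short-range-order* term, the Warren–Cowley cosine series

$$I_{SRO}(\mathbf{Q}) = N\, m_A m_B \sum_{\mathbf{v}} \alpha_{\mathbf{v}}
\cos\!\big(2\pi\, (h,k,l)\cdot\mathbf{v}\big),
\qquad \alpha_{\mathbf{v}} = 1 - \frac{p^{\mathbf{v}}_{AB}}{m_B},$$

where $\mathbf{v}$ runs over integer lattice vectors,
$p^{\mathbf{v}}_{AB}$ is the conditional probability of finding B at
separation $\mathbf{v}$ from an A, $\alpha_{\mathbf{0}} = 1$, and
$\alpha_{\mathbf{v}} = \alpha_{-\mathbf{v}}$. $I_{FF}$ is a slowly varying
continuous function; $I_{SRO}$ is periodic in $(h, k, l)$ with sharp,
Bragg-like modulation. The package simulates both terms, composes their
product, and trains a pair of conditional image-translation networks to
invert the composition — i.e. to recover the two factors from a measured
plane, which is not possible algebraically without knowing one of them.

Atomic form factors use the standard crystallographic four-Gaussian +
constant parameterization with coefficients embedded for H, C, N, O, F, P,
S and Cl; $f(0)$ reproduces each element's electron count to well within
2%. Hydrogens are kept in all form-factor sums — dropping them changes
$I_{FF}$ measurably for organic fragments. Scattering vectors follow the
physicists' convention $\lvert\mathbf{Q}\rvert = 4\pi\sin\theta/\lambda$.

## Warren–Cowley machinery

`measureAlphas()` computes $\alpha_{\mathbf{v}}$ by exact pair counting
under periodic boundary conditions. `mcGenerateConfiguration()` produces a
configuration matching three target nearest-neighbour correlations (one
per crystallographic axis) by Metropolis annealing with
composition-conserving swap (Kawasaki) moves; the cost is the summed
squared deviation of the measured axis correlations from their targets and
the temperature follows a geometric schedule ($10^{-3} \to 10^{-7}$ over
60 sweeps by default — the cost increments per swap are of order
$10^{-3}$, which sets the useful temperature scale). Swap moves make the
species counts exactly invariant. Correlated parameter sets beyond the
three targets are *measured* from the annealed configuration rather than
drawn independently, which keeps every stored $\alpha_{\mathbf{v}}$
mutually consistent (an arbitrary collection of alphas generally
corresponds to no realizable configuration, which would surface as
negative cosine-series intensities; these are clipped at zero and the
clipped fraction recorded).

Two conventions govern the cosine sum. With `convention = "pair"`
(default) the model stores one representative of each $\pm\mathbf{v}$ pair
and non-origin vectors carry weight 2; with `"full"` every stored vector
counts once, which is what a complete periodic-box vector set requires.
With the full in-box set, the series evaluated at the supercell's allowed
reciprocal points equals the brute-force scattering of the occupancy
deviations (`directSumOracle()`) *identically* — the package's tests
verify agreement to floating-point precision, far inside the 1% the
acceptance checks demand.

Symmetry-restricted models use a damped oscillator on the neighbour-shell
index $x = 1, 2, \ldots$:
$\alpha(x) = A e^{-d x} \cos(\pi \omega x)$ with
$A \in [0.6, 1.5]$, $d \in [0.1, 1.2]$, $\omega \in [0, 1]$ and both
concentrations fixed at 0.5. The exact oscillator form is a design choice:
with $\omega \in [0, 1]$, the cosine spans the range from no oscillation
to sign alternation between successive shells, and the decay range ensures
the correlations die out before the fifth shell. Values are clamped into
the feasible range implied by $p = m_B(1 - \alpha) \in [0, 1]$. The
default vector cutoff stores all vectors with components in $[-5, 5]$
(five neighbour shells for the oscillator models).

## Dataset construction

`buildDataset()` follows a seven-stage recipe per molecule pair:

1. draw an SRO model (Monte Carlo-derived, or oscillator for the
   symmetry-restricted share) and build the lattice from the two units'
   padded bounding-sphere radii under Vegard's law,
   $a = m_A a_A + (1 - m_A) a_B$ with $a_X = 2(r_X + 1.2\,\text{Å})$;
2. select reciprocal planes — 12 for MC models (4 per axis, integer
   offsets 0–3) and 4 normal to the unique axis for symmetry models —
   each with its own $Q_{max}$ drawn uniformly from 6–8 Å$^{-1}$;
3. compute $I_{FF}$, $I_{SRO}$ and their product on each plane;
4. repeat over the configured number of SRO sets (12 MC + 14 symmetry by
   default, giving 200 planes per pair);
5. drop near-duplicate planes by a 1-D Wasserstein check: the distance
   between two planes is the mean absolute difference of their sorted
   pixel intensities, and the later plane of any pair closer than
   $10^{-3}$ of the dynamic range is removed;
6. take square roots (emphasizing low-intensity features) and normalize
   each plane to $[-1, 1]$ per sample, so zero intensity maps to $-1$ and
   each sample's maximum to $+1$;
7. imprint a synthetic detector-artefact mask — up to three straight
   module-gap bands 2–8 pixels wide, an optional central beamstop disc
   with an arm, rounded corners, always leaving at least 60% of pixels
   live — setting dead pixels to the floor value $-1$ while retaining the
   clean copy.

The manifest records exact stage counts (`final = preFilter - removed`
always). A dry-run mode computes the bookkeeping of arbitrarily large
configurations without simulating: the default configuration over 1049
pairs yields 209 800 pre-filter samples, and a 98-pair validation
configuration with 12 MC models × 12 planes yields 14 112.

Because each component is normalized per sample, the product of the
normalized ground truths differs from the normalized product by a
monotone rescaling only (Cauchy–Schwarz does not bite here because
the normalization is by the per-plane maximum); the dataset invariant
checked in the tests is a rank correlation above 0.99 between
$(gt_{FF}+1)(gt_{SRO}+1)$ and the clean input.

## The translation networks

Two conditional generator–discriminator pairs are trained in parallel, one
per component. The generator is a U-Net: four stride-2 4×4 encoder
convolutions (widths 8, 16, 32, 64 at the default 64-pixel grid), a
mirrored decoder of nearest-neighbour upsampling + 3×3 convolutions with
skip concatenation at matched resolutions, and a final tanh squashing to
$[-1, 1]$. Noise enters through 50% dropout in the decoder, active during
training and available at inference as an optional sampling mode (off by
default so separation is deterministic). The discriminator is a three-layer
patch classifier whose input is the candidate concatenated with the
conditioning scattering plane along the channel dimension.

Each iteration has three steps. (a) Each discriminator is updated on the
ground truth as real and the frozen generator's output as fake —
conditioned on the *clean* input in both cases, because a discriminator
that sees artefact-stained conditions cannot distinguish artefacts in the
condition from artefacts in the candidate, and the generators then never
learn to remove them. (b) Each generator is updated against its frozen
discriminator with the conditional-GAN objective plus a pixel-wise L1 term
weighted by $\lambda = 100$. (c) A joint step multiplies the two generated
components and minimizes the smooth L1 distance (quadratic below
$\beta = 1$, linear above) to the product of the normalized ground truths,
back-propagating through both generators simultaneously.

The networks are implemented natively on compiled 2-D convolution kernels
with Adam (learning rate $2\times10^{-4}$, $\beta_1 = 0.5$), weights
initialized from $N(0, 0.02^2)$ — the canonical settings for this
translation architecture. Normalization layers are omitted: at the reduced
widths used here they add cost without measurable benefit. Backpropagation
is verified against finite differences in the development checks, and the
test suite asserts the structural contracts: frozen opponents, loss
bookkeeping satisfying $\text{total} = \text{adv} + \lambda L_1$ exactly,
outputs bounded in $[-1, 1]$, and bit-exact checkpoint round trips.

Training is exercised at *reduced scale* throughout: 200 samples of
64×64 pixels for 5 epochs (a few CPU-minutes). That scale demonstrates
that the losses are wired correctly and that the networks learn — mean
generator L1 falls from the first to the last epoch and held-out MSE beats
a uniform-noise baseline for both components — but it does not approach
the quality of a full-scale training run (hundreds of thousands of
256×256 samples over hundreds of epochs on a GPU), and no claim about
real-data performance follows from it. The synthetic generator also
idealizes real measurements: no counting noise, no background or Bragg
remnants, no displacive or thermal diffuse contributions, and artefact
masks that are geometric stand-ins for real detector dead zones.

## Refinement of separated components

`projectToUnitCell()` folds a plane's in-plane fractional coordinates
modulo 1 onto a bin lattice (64² by default) centred on $i/\text{bins}$,
so bin means carry no systematic phase shift against the cosine basis.
Bins below 5% of the maximum can be excluded
(`maskLowIntensity()`), and `symmetrize()` averages rotation orbits using
the exact integer index map of the lattice rotation (sixfold for
hexagonal, acting as $(h, k) \to (-k, h+k)$ in reciprocal fractional
coordinates), which makes symmetrization exactly idempotent.

`refineAlphas()` fits $s\,(1 + \sum_c \alpha_c B_c(h, k))$ by linear least
squares, where each basis function $B_c$ sums the cosines of one symmetry
equivalence class (e.g. $\alpha_{[100]} = \alpha_{[110]} = \alpha_{[010]}$
under sixfold rotation) and vectors failing an exclusion rule — such as
$v_z \neq 0$ for a system with no out-of-plane disorder — are omitted.
The series is homogeneous in $s \times \alpha$; pinning the constant term
(the origin vector, $\alpha_0 = 1$) separates the scale. On data generated
by its own forward model the fit is exact to numerical precision; with 5%
additive noise on a 64² cell the parameters are recovered to better than
0.01. A single plane determines only the $v_3$-summed combinations of
alphas, so the end-to-end pipeline test restricts the generating model to
in-plane vectors; with commensurate pixel/bin lattices the round trip from
an annealed 24³ configuration through simulation, projection and
refinement recovers the measured in-plane parameters to well within 0.02.

For the form-factor component, `dwCorrect()` damps a calculated plane by
the squared isotropic Debye–Waller factor
$\exp(-B \lvert\mathbf{Q}\rvert^2 / 8\pi^2)$, with $B$ either supplied or
fitted by a one-parameter least squares with profiled scale
(`fitDebyeWaller()`), and `rotationScan()` maps out the MSE between a
reference (e.g. network-separated) plane and planes calculated while a
molecular fragment rotates about a bond — the basis for discriminating
between candidate orientations of, say, a tert-butyl rotor. MSE curves are
computed on square-root-normalized planes, so they are invariant to any
global rescaling of the reference.

## Numerical conventions and edge cases

* Pixel grids span $[-\text{span}, +\text{span}]$ inclusive per in-plane
  axis; an odd grid centres $\mathbf{Q} = 0$ on a pixel, the default 256
  (and the test grids of 64) accept a half-pixel offset.
* The vacancy "molecule" (an unoccupied site) is a zero-atom sentinel with
  an identically zero form factor, handled explicitly by the scattering
  operations; with a vacancy partner $I_{FF} \propto \lvert F_A \rvert^2$,
  the special case in which the separated component could be phased
  directly.
* Degenerate all-zero planes abort normalization with an error and are
  logged and skipped (never silently) by the dataset builder.
* All stochastic draws run through `withSeed()`, which restores the
  caller's RNG state; every artifact records the seed that produced it.
* Monte Carlo feasibility: a target $\alpha$ must imply a pair probability
  $p = m_B(1-\alpha) \in [0, 1]$ *and* a joint probability
  $m_A p \le m_B$; the sampler of random realistic models draws targets
  inside $[\max(-0.45,\, 1 - 1/\max(m_A, m_B) + 0.02),\, 0.45]$ with
  $m_A \sim U(0.2, 0.8)$.

## Problem sizes

The shipped tests and the acceptance script use: 16³–24³ lattices for
Monte Carlo and oracle checks, 64²-bin projected cells, 15 sixfold
equivalence classes (shells 1–5), and the 200-sample/5-epoch/64² training
smoke run described above. These sizes were chosen so the full suite
completes in minutes on a single CPU while every check remains far from
its tolerance.

## Limitations

Only single-site binary substitutional disorder is modelled: no displacive
(size-effect) relaxation, no thermal diffuse scattering, no multi-site
cells, no anomalous scattering, and no Bragg/background pre-processing.
Real-data separation quality is a property of full-scale training, which
is out of scope here; the package provides the complete data-generation,
training and analysis machinery at configurable scale.
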