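---
title: "RDC-based relative configuration analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RDC-based relative configuration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and the model

A one-bond C–H residual dipolar coupling is the difference between the total
splitting under weak alignment and the isotropic scalar coupling,
$^1D_{CH} = {}^1T_{CH} - {}^1J_{CH}$. For a rigid molecule partially aligned
in a stretched polymer gel, every RDC is a quadratic form in the C–H unit
vector $e_i$ (molecular frame):

$$D_i \;=\; D_{max}(r_i)\, e_i^{\top} S\, e_i, \qquad
D_{max}(r) = -\frac{\mu_0 \hbar \gamma_H \gamma_C}{8\pi^2 r^3},$$

with $S$ the Saupe order matrix: symmetric, traceless, eigenvalues in
$[-\tfrac12, 1]$, five independent elements
$(S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz})$. `RDCrank` fixes the sign
convention with the leading minus in $D_{max}$ and CODATA 2018 constants
($\gamma_H = 2.6752218744\times10^8$,
$\gamma_C = 6.728284\times10^7\,\mathrm{rad\,s^{-1}T^{-1}}$); the convention
is irrelevant to configuration discrimination because a fitted tensor
absorbs any global sign, but it is fixed and documented so back-calculated
values can be compared across tools. At $r = 1.09$ Å the interaction
constant is $\approx 23.3$ kHz, so order parameters of $10^{-3}$–$10^{-4}$
produce the observed few-tens-of-Hz couplings.

Given $n \ge 5$ couplings, the tensor is the linear least-squares solution
of the $n\times 5$ direction-cosine system with rows
$D_{max,i}\,[\,e_x^2-e_z^2,\; e_y^2-e_z^2,\; 2e_xe_y,\; 2e_xe_z,\;
2e_ye_z\,]$, solved by singular value decomposition (`svdFit()`). The
condition number of the design matrix is reported; a rank below 5 (all
vectors nearly parallel, or too few independent directions) aborts the fit
with the rank in the error message rather than returning a meaningless
pseudo-inverse solution.

**C–H distances.** By default the actual per-conformer coordinate distance
enters $D_{max}$; a fixed effective length (typically 1.09 Å) is available
via `effectiveR` because vibrationally averaged effective bond lengths
differ from equilibrium geometries and some tools adopt one convention, some
the other. The choice rescales all couplings of a vector identically and has
no effect on which configuration wins.

## Quality statistics and falsification

Three statistics are computed per candidate (`qualityReport()`):

- $Q = \sqrt{\sum_i (D_{calc,i}-D_{exp,i})^2 \,/\, \sum_i D_{exp,i}^2}$ — the
  Cornilescu factor, a *relative* criterion with no notion of experimental
  error;
- $\chi_i^2 = \big((D_{calc,i}-D_{exp,i})/\Delta D_{exp,i}\big)^2$ per
  coupling, where $\Delta D_{exp,i}$ is the per-coupling **maximum error
  estimate**, a conservative bound of roughly three standard deviations;
- $n/\chi^2 = n / \sum_i \chi_i^2$, an *absolute* criterion: $>1$ is
  necessary for a model that reproduces every coupling within its bound,
  and $<1$ proves at least one violation (if the mean of the $\chi_i^2$
  exceeds 1, so does the maximum).

An **outlier** is a coupling with $\chi_i^2$ *strictly* greater than 1.
The strict inequality matters at the boundary: the embedded experimental
table contains a coupling whose trajectory-averaged value deviates by
exactly its 0.3 Hz error, and it counts as fulfilled — consistent with the
ensemble column being reported as fully inside the error range. Because the
errors are ~3σ bounds, a single outlier falsifies a structural model;
`rankCandidates()` therefore orders by descending $n/\chi^2$, breaking ties
by ascending outlier count and then by running number. The tie-break beyond
$n/\chi^2$ is this package's own documented choice — the falsification
literature defines no combined ordering for ties.

A perfect fit has $\sum\chi_i^2 = 0$ and `nOverChi2()` returns `Inf`. In
floating point this occurs only for exactly identical inputs; a noiseless
synthetic round trip yields residuals near machine precision and hence
astronomically large but finite values, which is why pipeline-level tests
assert ranks and outlier counts rather than the sentinel itself.

## Methyl groups and the amine

Fast methyl rotation averages the dipolar interaction over the three C–H
bonds, so static tensor fits cannot use methyl RDCs as bond vectors;
`filterMethyls()` flags them out of the fits (they stay in the dataset, and
trajectory-averaged or externally supplied calculated values can still be
scored against them). For completeness `methylEffectiveVector()` implements
the fast-rotation model: the interaction collapses onto the rotation axis
scaled by $P_2(\cos\beta)$, $-1/3$ for ideal tetrahedral geometry.

A tertiary amine can invert through a planar transition state, which would
exchange axial and equatorial environments on the neighboring CH$_2$ groups
and average their $^1J_{CH}$ values. The Perlin effect makes the axial
$^1J_{CH}$ adjacent to a nitrogen lone pair systematically smaller than the
equatorial one, so a persistent difference $J_{eq}-J_{ax}$ of several Hz
diagnoses a configurationally locked amine. `amineInversionCheck()` uses a
5 Hz decision threshold: in the embedded data the decisive positions show
7.7 and 8.7 Hz differences while remote positions show 0.2–1.5 Hz, so 5 Hz
separates the regimes with a wide margin on both sides. The threshold is
exposed as an argument.

## Candidate enumeration

RDCs cannot distinguish enantiomers, so one reference center is fixed
(C2 = R); a second center (C4 = S) is fixed on steric grounds of the fused
lactone ring, a constraint taken as given from the compound's chemistry.
That leaves $2^5 = 32$ relative configurations over the centers
C2 C3 C4 C5 C6 N8 C23. `enumerateConfigs()` generates descriptor strings in
deterministic lexicographic order; `matchConfigId()` maps a string to its
published running number by table lookup, never by position, because the
published numbering is not lexicographic.

## Ensembles and trajectories

Two treatments of flexibility are implemented:

1. **Multi-conformer, single tensor** (`multiConformerFit()`): the design
   matrix rows are population-weighted averages of the per-conformer rows;
   one shared tensor is fitted. Conformers must share a molecular frame
   (`superposeConformers()`, least-squares/Kabsch on a named atom subset,
   default all heavy atoms). Row averaging precedes any error weighting.
   Populations come from energies (`boltzmannWeights()`, default 300 K, gas
   constant in kcal/mol) after an energy-window preselection
   (`energyWindowFilter()`, default keeps conformers strictly below
   6.0 kcal/mol above the minimum), or are optimized directly.
2. **Trajectory averaging** (`ensembleRdcFromTrajectory()`,
   `averageRdc()`): per-frame back-calculated RDCs are arithmetically
   averaged after discarding an initial equilibration segment. When a frame
   interval is known, `framesToSkip()` converts an equilibration time
   (default 1 ns) to frames; otherwise the skip must be given explicitly.
   The package evaluates externally produced or synthetically generated
   trajectories only — the constrained-dynamics engine that would produce
   experimentally restrained ensembles is a separate tool and out of scope.

**Population optimization** (`optimizePopulations()`): weights on the
simplex minimizing $\sum_i ((D_{calc,i}-D_{exp,i})/\Delta D_i)^2$, refitting
the shared tensor for every candidate weight vector (nested optimization;
the inner fit uses inverse-variance weighting so the nested optimum
minimizes the same objective). The simplex is parameterized by softmax and
searched with Nelder–Mead from the uniform-weight starting point — no
randomness, so results are reproducible; on a flat objective (duplicated
conformers) the uniform initialization is returned. Convergence is a
relative objective tolerance of $10^{-10}$ under an iteration cap of
$10^5$; non-convergence returns best-so-far with a warning and a
`converged = FALSE` flag rather than an error.

Conformer populations are read off a trajectory through a reporter torsion
(`dihedralPopulation()`): per-frame dihedrals (IUPAC sign convention,
path-reversal invariant, verified against an independent implementation)
classified into user-defined angle states, with a 5° default histogram bin
width — fine enough to resolve bimodality at trajectory lengths of order
$10^3$–$10^4$ frames without empty-bin noise.

## Fit weighting

`svdFit()` is unweighted by default, matching common practice of SVD-based
RDC tools; `weights = 1/ΔD²` (or `weighting = "inverse-variance"` in
`runPipeline()`) enables inverse-variance weighting. The distinction matters
when error estimates are strongly heteroscedastic: the embedded data and the
synthetic default profile span 0.3–5.0 Hz, a 16-fold σ range, and an
unweighted fit lets the noise of large-error couplings leak into the fitted
tensor and push small-error residuals past their 3σ bounds even for the true
structure. The synthetic benchmarks therefore run with inverse-variance
weighting, which is the efficient estimator under the generator's gaussian
error model; on experimental data the default reproduces the behavior of the
standard tools.

## The synthetic-data generators

The study data they stand in for — proprietary 3D candidate structures and
long constrained-dynamics trajectories — cannot be redistributed, so every
stage of the pipeline is exercised on generated inputs with the same
statistical structure (`makeTemplate()`, `randomTensor()`,
`perturbCandidate()`, `generateObservations()`,
`generateJumpTrajectory()`, tied together by `simulateScenario()`):

- **Geometry**: a deterministic trans-fused bicyclic chair–chair scaffold
  (decalin-like; idealized 1.53 Å C–C, 1.09 Å C–H, tetrahedral H placement)
  with 18 C–H vectors in general position whose design matrix has full rank
  5 — a stand-in for rigid polycyclic natural-product cores.
- **Alignment**: random traceless symmetric tensors rescaled so the largest
  back-calculated |RDC| on the template falls in 26–32 Hz, the span of the
  embedded experimental data.
- **Noise**: per-coupling maximum error estimates cycle through
  {0.3, 0.5, 1.0, 1.5, 5.0} Hz, mimicking the experimental spread; gaussian
  noise uses σ = ΔD/3 (the 3σ reading of the maximum error estimates),
  uniform noise has support ±ΔD.
- **Wrong candidates**: selected C–H vectors are reoriented — mirrored
  through the local heavy-atom plane (axial↔equatorial, epimer-like) or
  tilted by an exact angle about an axis perpendicular to the bond. Decoys
  default to 30° tilts on 3 vectors, the scale of reorientation a single
  epimerization imposes on nearby vectors.
- **Exchange**: a Markov jump chain over template conformers with a
  prescribed stationary distribution (default 90/10 and a 0.2 per-frame
  redraw probability, i.e. visibly persistent states), optional small
  rigid-body jitter. Occupancy checks at 4000 frames use a ±0.02 band at
  fixed seed; state persistence inflates the sampling variance relative to
  an independent-draws bound, so the band is asserted for the seeded runs
  the tests pin down, not as a distribution-free guarantee.

All generator randomness flows through explicit seeds (isolated from the
session RNG), making every benchmark bit-reproducible.

What the generators deliberately do *not* emulate: force-field energetics,
solvent and alignment-medium physics, vibrational corrections, and
correlated structural noise (a wrong diastereomer differs from the truth in
more coordinated ways than independent vector tilts). Passing benchmarks
therefore demonstrate the correctness and statistical calibration of the
fitting, scoring and ranking machinery — not that any given level of
experimental data can discriminate any given pair of real diastereomers.

## Benchmark problem sizes

The shipped tests and the acceptance script use: 25 noiseless plus 200
gaussian-noise discrimination replicates (4 candidates, 18 couplings each),
100 population-recovery replicates of a 90/10 two-conformer ensemble, and a
single 4000-frame two-state trajectory. These sizes give the recovery-rate
estimates standard errors of 1–3 percentage points while keeping the whole
suite in the tens of seconds on one core.

## Known limitations

- A single tensor per candidate: multiple-tensor-per-conformer fits need
  more couplings than small molecules typically provide and are not
  implemented; mean-field/additive-potential ensemble methods are likewise
  out of scope.
- Stereodescriptor strings are bookkeeping labels; the package does not
  assign CIP priorities from 3D coordinates nor embed descriptor strings
  into 3D structures — candidate geometries are inputs.
- The evaluate-only mode scores printed back-calculated columns exactly as
  printed; published rounding (0.1 Hz, one value to 1 Hz) limits how
  precisely aggregate statistics can be reproduced (the recomputed
  single-conformer $n/\chi^2$ of 0.0897 agrees with the published 0.093
  only within that rounding).
- Trajectory scoring assumes the per-frame RDCs (or the tensor used to
  compute them) are supplied; no orientational-constraint dynamics engine
  is included.
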