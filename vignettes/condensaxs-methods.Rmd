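---
title: "Models and methods in condensaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in condensaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`condensaxs` connects two arms of one scientific question — what do
flexible single-stranded RNA chains look like as they interact with
polybasic peptides and condense into ribonucleoprotein droplets? The
dilute-phase arm interprets contrast-variation SAXS profiles through
explicit all-atom conformer ensembles; the condensed-phase arm simulates
residue-level coarse-grained coacervates and quantifies their dynamics.
This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## Dilute phase: suites, pools and ensemble optimization

### The dinucleotide suite model

Single-stranded RNA backbones populate a discrete alphabet of
dinucleotide conformations ("suites"). A suite spans one dinucleotide
step and is parameterized by nine angles: backbone torsions
$\{\alpha,\beta,\gamma,\varepsilon,\zeta\}$, sugar puckers
$\{\delta_{i-1},\delta\}$ and glycosidic angles $\{\chi_{i-1},\chi\}$.
A 30-mer is a chain of 29 suites. The package builds all-atom chains by
natural-extension-reference-frame placement, so the requested torsions
are reproduced exactly (the test suite verifies < 0.5° round-trip error
for all 34 suites; in practice the error is at machine precision).
Template bond lengths and angles come from standard nucleotide
geometry; the ribose ring torsions are interpolated from $\delta$ via
the pseudorotation phase (C3'-endo at $\delta \approx 81^\circ$,
C2'-endo at $145^\circ$, amplitude 38°), which closes the ring to
within a few hundredths of an Ångström — adequate for scattering and
order-parameter work, though not a substitute for refined sugar
geometry.

The shipped 34-suite table contains *synthetic representative* per-suite
means spanning the standard suite classes; the exact published
crystallographic consensus means are not redistributed. Because every
test round-trips against the shipped table, correctness does not depend
on the specific values; users with access to a fitted suite table can
drop it in via `load_suite_library(path)`.

### Pool sampling

`sample_pool()` draws each linkage's suite independently from a weight
vector and rejects steric clashes (non-bonded heavy atoms closer than
2.0 Å — a van-der-Waals floor; the covalent phosphodiester bridge is
excluded) by resampling the offending linkage. Local resampling alone
can dead-end when the chain folds back onto itself and *every* suite
clashes, so the sampler backtracks one linkage after 500 failed draws
(up to 500 backtracks, then a whole-chain restart, then an error naming
the stuck linkage). This keeps runtime bounded while preserving the
local-move character of the scheme.

### Selection and reweighting

The genetic algorithm evolves $N$ ensembles of $M$ member curves
(defaults $N=50$, $M=20$, 1000 generations, 10 mutations per ensemble,
100 restarts — the reference protocol; desk-scale analyses use smaller
values). Fitness is the reduced
$\chi^2 = \frac{1}{Q-1}\sum_i \left(\frac{\mu I(q_i) -
I_\mathrm{exp}(q_i)}{\sigma_i}\right)^2$ with the scale factor $\mu$
solved analytically by weighted least squares. GA internals are not
dictated by the protocol, so the package uses standard, documented
components: tournament selection ($k=2$), single-point crossover of
member lists, mutation by uniform member resampling, elitism of the
single best ensemble, and independent restarts with the best final
population retained. Elitism makes the best fitness non-increasing —
a property the tests check. Repeat selections are allowed; additive
intensity offsets are not supported.

The outer loop reweights suite probabilities so the pool would
reproduce the selected ensembles' suite frequencies: the objective
$\chi_h^2=\sum_m\!\left(h_{\mathrm{ens},m} -
\frac{h_{\mathrm{pool},m} w_{\mathrm{new},m}/w_{\mathrm{old},m}}
{\sum_n h_{\mathrm{pool},n} w_{\mathrm{new},n}/w_{\mathrm{old},n}}\right)^2$
has an attainable zero at
$w_\mathrm{new} \propto w_\mathrm{old}\, h_\mathrm{ens}/h_\mathrm{pool}$
whenever the pool covers the observed suites, and the package uses that
closed-form minimizer (an optional Nelder–Mead polish on a softmax
parameterization confirms it numerically; a dense simplex grid search
serves as the oracle in the tests). A small weight floor (default
$10^{-4}$ inside `iterate_eom()`) keeps suites resamplable across
iterations — without it a suite that misses one selection round would
be extinguished forever. Convergence is declared when the
Jensen–Shannon divergence between consecutive weight vectors (natural
log; bounded by $\ln 2$) falls below 0.01 nats, or after `n_outer`
iterations.

### Scattering

Theoretical intensities use the Debye double sum with tabulated
4-Gaussian vacuum atomic form factors (C, N, O, P; hydrogens omitted —
negligible X-ray contribution). No hydration shell or excluded-volume
correction is applied: all internal analyses are self-consistent
synthetic loops, and for real data the missing solvation term shifts
$R_g$ by a systematic few percent that users should expect. The default
grid is 61 points to $q_\mathrm{max} = 0.3\,\text{Å}^{-1}$. The
molecular form factor for Flory-exponent fits is the closed-form
excluded-volume chain
$P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma\!\left(\tfrac{1}{2\nu},U\right) -
\frac{1}{\nu U^{1/\nu}}\gamma\!\left(\tfrac{1}{\nu},U\right)$ with
$U = (2\nu+1)(2\nu+2)(qR_g)^2/6$; it reduces to the Debye function at
$\nu = 1/2$ and decays as $q^{-1/\nu}$, which is what the fitted
exponent means operationally. The Guinier window is found by iterating
the fit-window search to self-consistency under
$q_\mathrm{max} R_g \le 1.3$ (the stated validity limit; sharp-boundary
particles such as spheres benefit from a more conservative limit, as
one test documents). The contrast match point is a linear fit of
$I(0)$ against buffer electron density — linear in $I(0)$, not
$\sqrt{I(0)}$ — extrapolated to its zero crossing, with a configurable
linear sucrose-density map $\rho(c) = 0.3344 + k\,c$ (the exact
laboratory relation is instrument-calibrated; $k$ defaults to
$6.4\times10^{-4}$ e/Å$^3$ per % w/v and should be set by the user).
The correlation-peak lengthscale is $d = 2\pi/q_\mathrm{peak}$.

### Order parameters

The orientation correlation function uses normalized bond vectors
between consecutive backbone phosphorus atoms and averages
$\cos\theta_{ij}$ at each separation $|i-j|$. The correlation length
convention is $l_\mathrm{OCF} = b \sum_{s=0}^{n-1} \mathrm{OCF}(s)$
with $b$ the mean observed bond length — the $s{=}0$ term is included,
so a delta-correlated chain gives $l_\mathrm{OCF} = b$ and a rigid rod
gives $n_\mathrm{bonds}\,b$. The summation range and normalization are
a package convention (reasonable alternatives exist), so printed
literature $l_\mathrm{OCF}$ values should be compared qualitatively,
not digit by digit. Base planes are fitted by total least squares
(smallest-eigenvector normal) for rotation invariance; "normals ≤ 5 Å
apart" is interpreted as plane-centroid distance, since normals are
directions without a length. A base counts as stacked with ≥ 1
qualifying partner; adjacency-restricted counting is available via
`adjacent_only = TRUE`.

## Condensed phase: coarse-grained coacervates

One bead per nucleotide or amino acid. Bonds:
$E = K(r-r_\mathrm{ref})^2$, $K = 9.6$ kJ/(mol Å²),
$r_\mathrm{ref} = 5.00$ Å (nucleic) / 3.81 Å (amino). Electrostatics:
Debye–Hückel, $\varepsilon_r = 80$ (temperature-independent,
configurable), 35 Å cutoff, with
$\kappa = \sqrt{c_\mathrm{Na}}/3.06\ \text{Å}^{-1}$ — 0.253 and
0.127 Å$^{-1}$ at 600 and 150 mM. Sticker interactions: per-pair
Wang–Frenkel wells, exactly zero at their cutoff ($3\sigma$), minimum
exactly $-\varepsilon$. The shipped parameter table is synthetic and
labelled as such: charges follow the standard convention (nucleotide
−1 e, Arg +1 e, Pro 0), masses are residue masses, and the well depths
are constructed so adenine is the strongest nucleotide π-sticker
(A–A 5.0 kJ/mol > C–C 2.6 ≈ U–U 2.4) with nucleotide–arginine cation-π
wells above nucleotide–proline contacts. Nucleotide bead diameters are
~6 Å: commensurate with the 5.00 Å bond and, critically, with the
7.5 Å chain-contact criterion — a bead diameter larger than the contact
cutoff would make RNA–RNA contacts geometrically impossible and the
model could not phase-separate into RNA clusters at all.

The integrator is BAOAB Langevin with friction $1/\tau$
($\tau = 100$ ps for condensate runs, 5 ps for propensity runs), 10 fs
steps, 298 K, seeded Maxwell–Boltzmann initialization, periodic
wrapping, and an abort on force blow-up. Setting $\tau = 0$ disables
the thermostat (used by the energy-conservation test: < 1% drift over
$10^5$ 1-fs steps on a dimer). Internal units are kJ/mol, Å, amu with a
100 fs natural time unit.

### Condensate analytics

Chains are linked when any inter-chain bead pair is within 7.5 Å
(minimum image); clusters are connected components; an RNA-only mode
ignores peptide beads, mirroring the contrast-matched experiment.
Exchange events come from the migration matrix
$M_f = A_{f+1} - A_f$ of same-cluster adjacency: positive entries are
arrivals, negative departures, deduplicated by a deterministic greedy
scan of the upper triangle in ascending row-then-column order that
counts at most one arrival and one departure per involved chain per
frame pair. Note the adjacency semantics: a move into an *empty*
cluster (or out of a singleton) creates no partnership change and is
invisible to $M$ — the synthetic script oracle counts with the same
convention, which is what makes the round-trip exact. Cluster identity
over time is tracked by maximal membership overlap (ties to the lower
id). Hull overlap uses an incremental 3D convex hull plus seeded
Monte-Carlo point-in-hull sampling over the union bounding box
(default $10^5$ samples; the binomial standard error is reported, and
a test checks the $1/\sqrt{n}$ convergence on nested cubes).
$\kappa^2$ is the standard relative shape anisotropy
$1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
\lambda_3\lambda_1)/(\sum_i \lambda_i)^2$ from the gyration tensor.

## What the synthetic generators emulate — and what they do not

The generators provide *ground truth*, not realism. Ideal helices give
closed-form OCFs; freely jointed coils give the $nb^2$ end-to-end law;
noisy profiles follow a 2% proportional Gaussian error model (a
synchrotron-like relative error — no detector geometry, buffer
subtraction artifacts or radiation damage); scripted trajectories place
chain blobs on deterministic grids so that clustering reproduces the
scripted membership *by construction*. Passing these tests shows the
algorithms are implemented correctly; it does not show that real
CV-SAXS data will be fit well, that the synthetic suite table matches
crystallographic consensus values, or that the synthetic force field
reproduces measured phase diagrams. The direction-of-effect results
(adenine condensates exchange less and hold their shape better than
uracil ones; lower salt clusters at least as strongly as high salt) are
emergent from the model's structure, but their magnitudes are specific
to the desk-scale systems below.

## Problem sizes

The analyses in the tests and the acceptance script use deliberately
reduced sizes, chosen as what a single workstation CPU handles in
minutes: conformer pools of 25–500 chains (the reference protocol's
2000 remains the default of `sample_pool()`); GA runs of a few hundred
generations with 1–2 restarts; planted-recovery studies on a 5-suite
reduced library whose pure-suite chains span $R_g \approx 4$–52 Å (the
well-separated length scales are what make a 5-point Spearman
correlation meaningful); and condensate property runs of 6 RNA + 6
peptide chains of 15 residues in a 100 Å box for 0.4 ns, which is
denser than the experimental 250 µM so that association statistics are
reachable on that timescale. The full production scale (20+20 chains of
30 residues in 250 Å via `desk_preset()`, or larger boxes and
microsecond trajectories via `sim_config()`) is expressible but not
exercised by the tests.

## Known limitations

* Vacuum form factors without a hydration shell: absolute $R_g$ from
  real data will be systematically offset by a few percent.
* The suite table and coarse-grained parameter table are synthetic
  representative sets; quantitative comparison with published ensemble
  or phase-diagram numbers requires substituting fitted tables.
* The ribose ring closes approximately (interpolated ring torsions),
  and no energy minimization is performed.
* Only A, U, C nucleotides and (Pro-Arg) peptides are modelled; no
  duplex RNA, no explicit ions or solvent, no pressure coupling.
* The Monte-Carlo Jaccard estimator is noisy for small clusters; the
  analytics average several frame pairs for stability.
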