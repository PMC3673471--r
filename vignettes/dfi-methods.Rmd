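---
title: "Dynamic flexibility from perturbation response scanning: model, choices, limits"
author: "dfiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flexibility from perturbation response scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfiscan)
```

## The model

A folded protein is reduced to its C-alpha trace and treated as an elastic
network: every residue pair (i, j) is connected by a harmonic spring. Near
equilibrium the network energy is quadratic, `V = 1/2 dR' H dR`, where `dR`
is the 3N-vector of residue displacements and `H` the 3N x 3N Hessian. Each
pair contributes the off-diagonal 3 x 3 block

    H_ij = -gamma_ij (d d') / r^2 ,

with `d` the separation vector, `r = |d|`, and diagonal blocks fixed by
translation invariance (`H_ii = -sum_j H_ij`). Instead of the classic hard
interaction cutoff, the spring constants are distance-weighted,
`gamma_ij = 1 / r^2`, so **all** pairs interact with smoothly decaying
strength and no arbitrary cutoff radius enters the model (a cutoff mode is
retained for cross-checks only).

Linear response theory gives the displacement field caused by a static
external force: `dR = H^-1 dF`. `H` is singular — a 3-D body has six
rigid-body zero modes — so `H^-1` is the eigendecomposition-based
pseudo-inverse with eigenvalues below `1e-10 * lambda_max` discarded. The
threshold is *relative*, which keeps the null-space detection stable across
structure sizes. Degenerate geometries are reported, not refused: three
collinear residues yield 7 zero modes, and a perfectly planar structure
(such as the ring fixture) frees all out-of-plane displacements, giving
N + 3. Both warn, and the pseudo-inverse remains well defined on the
complement.

## Perturbation response scanning and the flexibility index

Each residue i in turn receives a unit force and the response of every
residue j is recorded. Two routes are implemented:

* **Monte-Carlo** (`responseMatrixMC`): k random unit force directions
  (default k = 10), built as antipodal pairs so their vector sum is exactly
  zero and the forcing is isotropic by construction. Because that zero sum
  makes the directional average of the response *vector* vanish identically,
  the recorded quantity is the root-mean-square over directions of the
  response magnitude `|dR_j|` — the mean-square fluctuation of residue j
  under the random kicks.
* **Analytic** (`responseMatrixAnalytic`): the exact k -> infinity limit.
  For a uniformly distributed unit force at residue i, the mean squared
  displacement of residue j is `trace(G G') / 3`, with `G` the 3 x 3 block
  of `H^-1` coupling j to i, so `A[i, j] = sqrt(trace(G G') / 3)`.

The quadratic (RMS) averaging was chosen over the arithmetic mean of
magnitudes deliberately: it is the estimator whose expectation the analytic
expression computes, so the two modes are two routes to the *same* quantity
and the Monte-Carlo mode converges to the analytic one entry by entry
(verified at k = 10^4 within 2%).

The per-residue score is the column mean of the response matrix,
`S_j = mean_i A[i, j]` — the average displacement of residue j when every
site of the chain is perturbed in turn — and the dynamic flexibility index
is its normalization over the chain:

    dfi_j = S_j / sum_m S_m .

High dfi marks residues that are easily displaced by perturbations elsewhere
(structurally flexible sites); low dfi marks residues that absorb and relay
perturbations without moving, which is the signature of hinges. For pooling
across proteins, dfi is expressed as a per-protein percentile rank, %dfi =
`100 * rank / N` with average ranks for ties, so the most flexible residue
of any protein scores exactly 100.

Two conventions in this definition are genuinely open and are exposed as
parameters:

* **Self-perturbation.** The column mean includes the i = j row by default
  (the matrix-mean formulation); `excludeSelf = TRUE` restricts the mean to
  perturbations at *other* residues. The difference is O(1/N) and both paths
  are tested.
* **Tie detection.** Ranks are taken on 10 significant digits of dfi, so
  values equal up to floating-point noise — e.g. all residues of a symmetric
  ring — tie exactly as the mathematics says they should.

The global spring constant gamma is a pure scale: responses are proportional
to 1/gamma and dfi is a ratio, so gamma cancels. The implementation factors
it analytically (matrices are stored at unit gamma alongside the scalar), so
dfi is *bitwise* identical under any rescaling of the spring constants — an
exact invariance rather than a numerical one. Units (Angstrom, unit force)
cancel the same way; all reported quantities are relative.

## Effective mobility (%EM)

For comparison, `gnmMobility()` computes a one-dimensional (Kirchhoff/GNM)
mobility profile under the same inverse-square weighting: the diagonal of
the pseudo-inverse restricted to the `nSlowModes` slowest non-zero modes,
percentile-ranked. Effective mobility describes equilibrium fluctuations in
the slowest collective modes; dfi additionally probes the response to forces
that push the structure off equilibrium, through all modes. The default of
10 slow modes is a conventional choice (the appropriate count is not fixed
by theory) and is a parameter. One numerical subtlety: when the requested
mode count would split a degenerate eigenvalue multiplet, the selection is
extended to complete the multiplet — a partial sum over a degenerate
eigenspace is basis-dependent and would otherwise break exact symmetries.

## Downstream statistics

**Variant enrichment.** Residue positions are assigned to five %dfi
categories (edges 20/40/60/80; left-closed, last closed at 100). With M
variants over N positions, the expected count in bin i is
`E_i = (n_i / N) * M`; the report carries observed/expected ratios and the
chi-squared statistic `sum (O_i - E_i)^2 / E_i` over bins with `E_i > 0`,
with dof = bins - 1 (the total M is fixed). Bins with zero expectation are
excluded with a warning.

**Functional-site distributions.** `flexibilityDistribution()` histograms
%dfi over a labeled subset (catalytic, binding, ...) and reports the
fraction at or below a threshold (default 25%).

**Rate correlation.** `rateDfiSliding()` sorts residues by %dfi, slides a
window (default `max(50, N/20)` residues, step half a window — the window is
a parameter and is echoed in output headers, since no canonical value
exists), and correlates window-mean %dfi with window-mean evolutionary rate
(substitutions per site per billion years). `conservationGroups()` summarizes
%dfi within the conservation categories r = 0, 0 < r <= 1 and r > 1, and
`groupDifferenceTest()` is the Welch unequal-variance test used for group
contrasts, with the degenerate zero-variance cases fixed by convention
(p = 1 on equal means).

Positions carrying several labels are counted in each analysis
independently; rates are consumed as input (estimating them from alignments
is out of scope, as are accessible-surface-area and stability calculations).

## The synthetic world

`makeStructure()` generates the four fixture families the test-suite is
built on, each chosen to isolate one regime of the model:

* `linear_chain` — collinear residues at 3.8 A (the C-alpha virtual bond
  length): maximal end effects, degenerate geometry (the transverse
  displacements decouple under inverse-square weighting).
* `ring` — points on a circle with adjacent *chord* distances exactly equal
  to the spacing (the radius is `spacing / (2 sin(pi/N))`): by symmetry every
  residue must have identical dfi, a zero-tolerance oracle.
* `globule` — self-avoiding uniform points (minimum pair distance 3.5 A) in
  a sphere at 0.6 residues/nm^3: the simplest fixture with the full 6-mode
  rigid null space and a heterogeneous profile. The packing is deliberately
  sparse; it is a network testbed, not a protein decoy.
* `dumbbell` — two lobes joined by a collinear 3-residue linker. The lobes
  are packed at 6 residues/nm^3 (folded-domain-like density): at the generic
  globule density a 20-residue lobe would have a ~20 A radius, larger than
  the linker itself, and the fixture would not be a dumbbell at all.

`makeAnnotations()` plants ground truth on a profile: variants sampled with
probability proportional to per-bin weights (default 1.45/1/1/1/0.65 —
enriched at rigid sites, depleted at flexible ones), and rates following
`r = slope * %dfi/100 + N(0, sigma)` truncated at zero (defaults slope 1,
sigma 0.25, keeping most rates in the 0-1.5 substitutions/site/Byr range
typical of conserved proteins).

What a green test on this world establishes: the Hessian matches the second
derivatives of its defining potential; the pseudo-inverse, response and
normalization algebra are correct; planted statistical signal is recovered
at the expected sampling error. What it does not establish: agreement with
experimental fluctuation data, or behaviour on real folds with secondary
structure, side-chain packing and chain connectivity — the fixtures have
none of these.

One fixture-level finding is worth recording honestly: the dumbbell linker
is reliably among the most rigid sites (lowest ~quintile of %dfi across
seeds and lobe densities), but residues of the lobe *cores that lie near the
hinge axis* often score lower still — their soft-mode amplitude is as small
as the linker's and their local environment is stiffer. A requirement that
*all* linker residues occupy the lowest %dfi decile therefore holds only for
a minority of random lobes; the hinge signature itself (linker in the rigid
tail of the profile) is robust.

## Worked example

```{r example}
db <- makeStructure("dumbbell", seed = 7)
prof <- dfiProfile(db)
summary(pctDfi(prof)[dumbbellLinkerIdx()])   # the hinge linker, %dfi

ann <- makeAnnotations(prof, m = 2000, seed = 7)
enrichment(pctDfi(prof), ann$variants)
```

## Known limitations

* C-alpha-only, single-parameter harmonic springs: no sequence specificity,
  no anharmonicity, no solvent.
* Responses are linear; large conformational changes are outside the model.
* Planar or collinear inputs inflate the null space (warned, not refused);
  profiles on such structures reflect in-plane dynamics only.
* The Monte-Carlo mode at the default k = 10 reproduces analytic *rankings*
  well (Spearman >= 0.95 on test fixtures) but individual entries carry
  sampling noise; use the analytic mode unless emulating the sampling
  procedure itself.
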