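# dfiscan

Per-residue **dynamic flexibility** of protein structures from a
coarse-grained elastic network, for structural biologists and
variant-interpretation pipelines that need a fast, structure-only measure of
which residues a protein can afford to move — and which it cannot.

## The index

A structure's C-alpha trace defines an elastic network in which every
residue pair (i, j) at separation `r` is a harmonic spring of strength
`1/r²` (distance weighting in place of an interaction cutoff). With `H` the
3N×3N Hessian of that network, linear response theory gives the displacement
caused by a force `ΔF`:

```
ΔR = H⁻¹ ΔF            (H⁻¹ the pseudo-inverse over the non-rigid modes)
```

Unit forces are applied at each residue i in turn (perturbation response
scanning), isotropically over directions, and the magnitude response of
every residue j is recorded in a matrix `A`, either by Monte-Carlo sampling
of force directions (k = 10 antipodal pairs by default) or in closed form,
`A[i,j] = √(tr(G Gᵀ)/3)` with `G` the 3×3 coupling block of `H⁻¹`. Each
residue's total response and its chain-normalized index are

```
S_j  = ⟨A[i,j]⟩_i          dfi_j = S_j / Σ_m S_m
```

and `%dfi` is the per-protein percentile rank of `dfi_j`. High `%dfi`:
flexible, easily displaced sites. Low `%dfi`: dynamically robust, hinge-like
sites — where disease-associated variants concentrate. Downstream tools
compute variant enrichment by `%dfi` bin (`E_i = (n_i/N)·M`, chi-squared
test), flexibility distributions of annotated residues, sliding-window
correlation of `%dfi` with per-site evolutionary rates, and a GNM-style
effective-mobility profile (`%EM`) for comparison.

## Worked example

Everything runs on generated fixtures — no downloads. A dumbbell (two
packed lobes joined by a 3-residue linker) is the canonical hinge testbed:

```r
library(dfiscan)

db   <- makeStructure("dumbbell", seed = 7)   # 43 residues
prof <- dfiProfile(db)                        # analytic (deterministic) mode
prof
#> DfiProfile over 43 residues ( analytic mode )
#>   dfi: min 0.002308  median 0.02438  max 0.04237

round(pctDfi(prof)[dumbbellLinkerIdx()], 2)   # the linker = the hinge
#> [1]  4.65 13.95  6.98
```

The linker sits in the rigid tail of the profile (%dfi 5–14 of 43 residues)
while lobe-surface residues reach 100. Planting variants preferentially at
rigid sites (bin weights 1.45/1/1/1/0.65) and testing recovery:

```r
ann <- makeAnnotations(prof, m = 2000, seed = 7)
enrichment(pctDfi(prof), ann$variants)
#> EnrichmentResult (chi2 = 126.99 , dof = 4 , p = < 2.22e-16 )
#>       bin n observed expected ratio
#>    [0,20) 8      530  372.093 1.424
#>   [20,40) 9      387  418.605 0.924
#>   [40,60) 8      343  372.093 0.922
#>   [60,80) 9      466  418.605 1.113
#>  [80,100] 9      274  418.605 0.655
```

The observed/expected ratios recover the planted enrichment (≈1.45 in the
most rigid bin, ≈0.65 in the most flexible) and the uniform-placement null
is rejected. For real data, `computeDfi("protein.pdb", out = "dfi.tsv",
pdbOut = "colored.pdb")` reads a PDB file, writes the per-residue table and
a copy of the structure with `%dfi` in the B-factor column for ribbon
coloring.

A command-line driver covers the same surface
(`inst/scripts/dfi compute|mobility|enrich|correlate|fixtures|fixtures-annotations`),
with seeds and parameters echoed into output headers.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch — fixture
generation, Hessian construction and pseudo-inversion, response scanning,
dfi normalization, planted-variant enrichment and the rate correlation —
under a caller-supplied seed, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/dfi-methods.Rmd` documents the model and its assumptions, the
averaging and tie-breaking conventions, the synthetic-data world (what it
emulates and what it does not), and known limitations.
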