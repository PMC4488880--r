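---
title: "Structure-based conservation models for spherical viral capsids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based conservation models for spherical viral capsids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidprof)
library(dplyr)
```

## The two models

Icosahedral virus capsids are protein shells built from tens to hundreds
of copies of one or a few subunits. Along a capsid protein's sequence,
the evolutionary conservation of each site — the site-specific
substitution rate inferred from homologous sequences by tools such as
Rate4Site/ConSurf — varies in a characteristic pattern. `capsidprof`
implements two models that predict this pattern from the C&alpha;
coordinates of the assembled capsid alone:

**Packing density / weighted contact number (WCN).** The packing density
of residue $i$ is the cutoff-free inverse-square contact sum

$$n_i = \sum_{j \ne i} \frac{1}{r_{ij}^2},$$

where $r_{ij}$ is the C&alpha;–C&alpha; distance and the sum runs over
*every* residue of the whole capsid, its own subunit and all others.
There is no cutoff radius and no neighbour-list truncation; the package
computes the sum exactly (a blocked Gram-matrix expansion, numerically
equivalent to the double loop to better than $10^{-9}$ relative). The
profile value is the *weighted contact number*, the reciprocal
$w_i = 1/n_i$: a large $w$ means a loosely packed residue. After
z-normalization, densely packed core residues sit at negative $z_w$,
exposed loops at positive $z_w$.

**Centroid distance (c-distance).** The distance from each residue's
C&alpha; to the centroid of the capsid, the unweighted mean of all
C&alpha; positions. For a near-spherical particle this is a radial
coordinate; the model predicts that conservation decreases with radius.
It is isotropic, so it is a specialist model for highly symmetric shells
and degrades for non-spherical proteins, while the WCN model is general.

Both structural profiles and the sequence-conservation (SC) profile are
z-normalized to mean 0, standard deviation 1 — we use the *population*
standard deviation (divisor $N$); the choice of divisor is invisible to
every Pearson correlation downstream but must be fixed for the values
themselves to be reproducible. A note on ranges: z-scores are unbounded
by construction. One occasionally sees normalized WCN described as
confined to $[-1, 1]$; that cannot hold for a z-score and the package
does not clamp.

Conservation scores keep their native orientation everywhere: **lower
score = more conserved**. Nothing in the package ever flips signs, so a
structural model that tracks conservation shows up as a *positive*
correlation. A silent sign flip is the most dangerous bug this kind of
pipeline can have, which is why orientation is part of the data type's
documented contract rather than a plotting convention.

## The pipeline and its parameters

A per-capsid analysis is: read the structure (expanding the biological
assembly when the deposition stores only the asymmetric unit), compute
one subunit's structural profile *in the context of the whole capsid*,
z-normalize; smooth and z-normalize the conservation profile; map sites
to residues by author numbering; pair; correlate.

```{r pipeline}
capsid <- make_shell_capsid(n_subunits = 12, residues_per_subunit = 60,
                            radii = c(38, 42, 46), radial_jitter_sd = 1,
                            seed = 17)
cons <- make_conservation(capsid, "A", basis = "cdist",
                          noise_sd = noise_sd_for_rho(0.9), seed = 18)
cmp <- compare_capsid(capsid, cons, subunit = "A", model = "cdist",
                      smooth_window = 1)
glance(cmp)
```

Tunable parameters, their defaults, and why:

* **`smooth_window` (odd integer, residues; default 5, 1 = off).** The SC
  profile is smoothed with an unweighted sliding window before
  normalization, with the window truncated (shrunk) at the chain ends.
  Site-specific rate estimates are noisy, and a short window suppresses
  that noise without moving the profile's features; 5 residues is a
  common choice for conservation-profile work and the default here. The
  window and the edge policy change neither the sign nor the approximate
  magnitude of the correlations. For *synthetic* conservation the noise
  is independent per site and the attenuation formula below holds only
  unsmoothed, so analyses of generated data use `smooth_window = 1`.
  Smoothing structural profiles is possible (`smooth_profile()`) but off
  by default — only the SC profile needs denoising.
* **`offset` (integer, default 0) and `max_mismatch` (default 0.05).**
  Sites are mapped to residues by author numbering plus an offset, not by
  alignment; the mapping cross-checks amino-acid letters and refuses when
  more than 5% disagree (a wrong offset typically mismatches nearly
  everywhere, a point mutant a fraction of a percent). `force = TRUE`
  overrides. Insertion-coded residues stay unmapped, since grades files
  carry no insertion codes.
* **`bin_width` (z units, default 0.3).** The binned-trend analysis bins
  conservation z-scores into half-open intervals $[k w, (k+1) w)$
  anchored at 0 and fits an OLS line through the (bin center, bin mean)
  points. Anchoring at zero makes bins reproducible across datasets;
  bins are equal-width, occupancy-weighted only through which bins exist
  (`min_count` controls which bins enter the fit, default 1).
* **Coincident-atom tolerance ($10^{-6}$ Å).** The inverse-square sum is
  singular at $r_{ij} = 0$; a pair closer than the tolerance raises an
  error naming both residues rather than silently excluding anything.
* **Altloc policy.** Highest occupancy wins, ties broken by file order.
* **B-factor export.** The colored-structure writer renders values in the
  PDB's fixed-width `%6.2f` B-factor field, clamping to
  $[-99.99, 999.99]$ with a message; z-scores fit comfortably.

## What the synthetic generator emulates — and what it does not

`make_shell_capsid()` places C&alpha; points quasi-uniformly
(deterministic Fibonacci spiral, nudged so each shell's centroid is
numerically at the sphere center) on one or more concentric shells,
applies Gaussian radial jitter, and partitions the points into
contiguous chains. Defaults model a small icosahedral capsid at desk
scale: 60 subunits of 100 residues (a T=1 lattice has 60 chains), shell
radii near 100 Å (the outer radius of small ssDNA/ssRNA capsids), 1.5 Å
radial jitter (the radial spread of a backbone within a thin shell), and
a 1.0 Å minimum separation so the packing sum stays well-conditioned —
real C&alpha; pairs are never closer than about 3.8 Å.

`make_conservation()` generates scores as
$s_i = a\, z_i + \varepsilon_i$ with $\varepsilon_i \sim N(0, \sigma^2)$
on a structural z-profile $z$. Because $z$ has unit variance, the
population correlation with the basis is
$\rho = a / \sqrt{a^2 + \sigma^2}$, so a target $\rho$ is dialled in
exactly (`noise_sd_for_rho()`); e.g. $\sigma = 1.0203$ gives
$\rho = 0.7$. This closed form is what makes full-pipeline parameter
recovery a sharp test: the pipeline's mean estimated $r$ over 20 seeds
must land within a few hundredths of the dialled-in $\rho$.

What the generator deliberately does **not** emulate: protein fold
geometry and secondary structure (so along-chain autocorrelation of real
WCN profiles is absent), icosahedral T-number lattices and true 532
symmetry (subunits are contiguous patches, not symmetry copies),
realistic sequences, and phylogenetically structured conservation noise
(real Rate4Site errors are neither independent nor Gaussian). Passing
tests on synthetic data therefore validate the *computational machinery*
— sums, normalizations, mappings, correlations, file round-trips — and
the statistical calibration of the pipeline, not the biological claim
that real capsid conservation follows these structural profiles; that
claim requires real structures and real conservation scores, which the
package ingests but does not ship.

## Numerical and design choices

* **Exact pairwise summation.** The WCN contract forbids cutoff or
  neighbour-list approximations. The implementation expands
  $r_{ij}^2 = |x_i|^2 + |x_j|^2 - 2 x_i \cdot x_j$ in blocks of ~2000
  rows, so a 6000-residue capsid needs ~100 MB transiently and a
  whole-capsid profile takes well under a second; the brute-force double
  loop agrees to ~$10^{-11}$ relative.
* **Whole-model context is independent of the requested subunit**:
  `wcn_profile(model, s)` equals the `s`-rows of
  `wcn_profile(model, "all")` exactly, by construction (the same sum is
  evaluated, restricted to different output rows).
* **Assembly operators** come from REMARK 350 BIOMT records (PDB), from
  `_pdbx_struct_oper_list`/`_pdbx_struct_assembly_gen` (mmCIF), or from
  a plain-text operator file (12 numbers per row), since capsid
  depositions vary: some ship full particles, some asymmetric units.
  Rotations are validated ($R^\top R = I$ to $10^{-6}$, $\det R = +1$).
  mmCIF operator expressions of the composed form `(A)(B)` are rejected
  with a pointer to the external-operator route. Operators are applied
  to all chains; per-chain operator lists would need the label-to-author
  chain mapping, which C&alpha;-level capsid work does not require.
* **Degenerate inputs** fail loudly and specifically: constant profiles
  (an ideal jitter-free sphere's c-distances) raise a degenerate-profile
  error from `normalize_*()`; coincident atoms name both residues;
  pairing fewer than 3 residues is an insufficient-overlap error;
  batch runs record per-job failures and only fail when *every* job does.
* **Grades dialects.** The parser sniffs per row whether the second
  field is a residue letter (classic Rate4Site `POS SEQ SCORE ...`) or
  the score itself (bare two-column tables), and takes the continuous
  rate column by default; `score_column` overrides for dialects with a
  different layout. Positions must be strictly increasing; scores are
  never transformed.
* **Entropy stand-in.** `entropy_conservation()` (column Shannon entropy
  in bits, gaps excluded) exists so a full pipeline can run from an MSA
  with no external tools. It shares only the orientation with
  phylogeny-aware rate inference and is documented as a stand-in, not a
  replacement.

## Problem sizes in the test-bench

The packaged checks run the oracle comparison on 200 random
configurations of up to 500 residues, rigid-motion and
parameter-recovery checks on 60 × 100 = 6000-residue capsids (20
replicate seeds per dialled-in correlation, three correlations, both
models), and trend/round-trip checks on 3000-point samples — sizes at
which every property is sharp while a full run stays in the minutes
range on one CPU.

## Known limitations

* All-atom or side-chain-weighted WCN variants are out of scope; the
  models are C&alpha;-only by definition.
* Site-to-residue mapping is numbering-based; proteins whose deposited
  numbering does not follow the conservation file's sequence need the
  `offset` flag (or an external renumbering), not an alignment.
* Heteromeric capsids are compared per viral protein; `batch_compare()`
  averages per-structure correlations and `pool_pairs()` concatenates
  normalized pairs across structures for dataset-level trends — both
  conventions are reported explicitly in the outputs.
* Dataset-scale empirical statements (average correlations over real
  capsid collections, specific per-virus correlations) require
  downloaded structures and database-backed conservation scores and are
  intentionally not reproduced by the test-bench.
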