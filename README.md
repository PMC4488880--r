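# capsidprof

Structure-based conservation models for spherical viral capsids.

For the protein shells of icosahedral viruses, the per-site evolutionary
conservation pattern along a capsid protein can be predicted from the
Cα coordinates of the assembled particle alone. `capsidprof` implements
the two structural models behind that observation, for structural
virologists and molecular evolution researchers who want to compare
structure-derived profiles with sequence-derived conservation scores:

* **Weighted contact number (WCN, packing density).** For residue *i*,
  the cutoff-free packing density is

      n_i = Σ_{j≠i} 1 / r_ij²

  summed over **all** residues of the whole capsid (no cutoff radius, no
  neighbour truncation), with r_ij the Cα–Cα distance in Å. The profile
  value is the reciprocal w_i = 1/n_i; after z-normalization, densely
  packed residues sit at negative z_w, loosely packed ones at positive
  z_w.
* **Centroid distance (c-distance).** The distance from each Cα to the
  centroid of the capsid (the unweighted mean of all Cα positions),
  z-normalized to z_r — a radial coordinate for near-spherical shells.

Around the two models the package provides the full comparison
machinery: PDB/mmCIF reading with biological-assembly expansion
(REMARK 350, `_pdbx_struct_oper_list`, or external operator files),
Rate4Site/ConSurf grades-file ingestion (lower score = more conserved;
never sign-flipped), sliding-window smoothing and population-sd
z-normalization, site-to-residue mapping, Pearson correlation, the
binned conservation-trend analysis (bin width 0.3 z units), batch runs
over many capsids, score-colored structure export for molecular
viewers, and a synthetic capsid/conservation generator with closed-form
ground truth. Everything is data-frame-first: models and profiles are
tibbles, results have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Generate a three-layer synthetic capsid (12 chains × 60 residues, shell
radii 38/42/46 Å), derive conservation from the radial structure with
noise dialled to a true correlation of 0.9, and run the comparison
pipeline:

```r
library(capsidprof)

capsid <- make_shell_capsid(n_subunits = 12, residues_per_subunit = 60,
                            radii = c(38, 42, 46), radial_jitter_sd = 1,
                            seed = 17)
cons <- make_conservation(capsid, "A", basis = "cdist",
                          noise_sd = noise_sd_for_rho(0.9), seed = 18)

cmp <- compare_capsid(capsid, cons, subunit = "A", model = "cdist",
                      smooth_window = 1)
cmp
#> <capsid_comparison> model=cdist subunit=A: Pearson r = 0.872532 over 60 residues

binned_trend(cmp$pair)
#> <binned_trend> 16 bins (width 0.3) over 60 residues
#>   fit: slope 0.8827, intercept -0.0570, r^2 0.9132
```

The Pearson r of 0.87 is the sample estimate of the dialled-in
correlation 0.9 between conservation and the radial z-profile over one
60-residue subunit. The binned trend averages the structural z-score in
conservation bins of width 0.3 and fits a line through the bin means:
slope ≈ 0.88 with r² ≈ 0.91 says the radial model tracks conservation
roughly linearly across its range on this synthetic particle.
`autoplot(cmp)` draws the two profiles side by side; `autoplot()` on the
trend plots bin means with the fitted line. For real data, replace the
generator with `read_structure("capsid.pdb", assembly = 1)` and
`parse_rate4site("consurf.grades")`.

The same pipeline is available from a shell via the wrapper script
(`system.file("exec", "capsidprof", package = "capsidprof")`), with
subcommands `wcn`, `cdist`, `color`, `compare`, `batch`, `trend`,
`synth`, `synth-cons`; see `capsidprof <subcommand> --help`.

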