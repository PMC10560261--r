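# paccer

Analysis of **photo-activatable competition and chemoproteomic enrichment
(PACCE)** experiments: quantifying protein–RNA interactions in living cells
by measuring how UV-crosslinked cellular RNA blocks a cysteine-reactive
covalent probe at protein–RNA interfaces.

The package is written for chemoproteomics analysts who have site-level
probe-modified peptide identifications (PSMs) with SILAC channel
intensities and want to go from there to biological claims: which cysteines
are RNA-sensitive, whether they concentrate in RNA-binding domains, and
whether they sit close to bound RNA in co-crystal structures.

## The model

For a probe-modified site, the **SILAC ratio**

&nbsp;&nbsp;&nbsp;&nbsp;SR = I<sub>probe-only</sub> / I<sub>competition</sub>

is ≈ 1 without competition and grows when crosslinked RNA blocks probe
binding. Ratios are computed on a modified-site basis: the median over all
covering peptide forms (fully tryptic, half-tryptic, missed cleavages)
within a replicate, then the mean across replicates. A site is an
**RNA-sensitive cysteine (RS-Cys)** when mean PACCE SR ≥ 2, with
significance against the 1:1 mixing control from an **exact one-tailed
Mann–Whitney U test**: with n = 6 PACCE vs n = 3 mixing replicates all
C(9,3) = 84 orderings are enumerated, so attainable p-values are multiples
of 1/84 (minimum ≈ 0.0119). Domain enrichment uses an exact two-sided
binomial against the detection background with Benjamini–Hochberg
correction (enriched: q < 0.01); set overlaps use the hypergeometric upper
tail; structural validation computes minimum Euclidean distances from each
cysteine SG atom to any RNA atom in resolution-filtered, renumbered
protein–RNA structures.

A first-class synthetic-data module (proteome → tryptic digest → SILAC PSM
table with planted competition factors → toy coordinate files with planted
distances) makes every stage testable without external data.

## Worked example

```r
library(paccer)

# the printed p-value for complete separation at (6, 3) replicates
exact_mann_whitney_one_tailed(c(2.5, 2.6, 2.7, 2.8, 2.9, 3.1),
                              c(0.6, 0.7, 0.8))
#> $u_statistic
#> [1] 18
#> $p_value
#> [1] 0.01190476     # = 1/84, the smallest attainable p at this design
#> $method
#> [1] "exact_enumeration"

# full synthetic pipeline: simulate -> quantify -> call -> enrich -> distance
cfg <- pipeline_config(simulation_config(n_proteins = 25, seed = 42))
run_pipeline(cfg, "readme_run", quiet = TRUE)
cat(render_report("readme_run"))
```

```
PACCE synthetic pipeline report
===============================
config hash : 3b2d37d9ad73a6f6bb1d3f8c5614df9c
seed        : 42

proteins       : 25
PSM records    : 5922
quantified sites: 199
RS-Cys sites   : 57
RS proteins    : 25
RS/RBP overlap : 13 of 13 RBPs in universe (p = 1)

residue selectivity:
  C    126  0.633
  R     41  0.206
  ...

mean Cys-RNA distance by class (angstroms):
  all          n= 18  23.6
  rs           n=  6  8.0
  rs_in_rbd    n=  0  absent
  insensitive  n= 12  31.3
```

Reading the numbers: 57 of 199 quantified sites exceed the SR ≥ 2 cutoff
(the generator plants 40% of cysteines as RNA-sensitive with factors
uniform on [2, 20], so many sites sit near the threshold); the toy
structure plants RS sites 6–14 Å from RNA and insensitive sites 25–40 Å
away, which the distance stage recovers (8.0 vs 31.3 Å class means). With
25 proteins nearly every protein carries some RS cysteine, so the
protein-level RBP-overlap test is saturated (p = 1) — at realistic proteome
scale it is not. The residue-selectivity table reflects the planted ~72%
cysteine selectivity of the probe, diluted by ambiguous short-peptide
mappings.

A command-line front end is installed at `exec/pacce`
(`pacce run --seed 1 --outdir out`), with a flat key–value (TOML dialect)
config file.

## Layout

* `R/simulate.R` — synthetic proteomes, digests, PSM tables, toy structures
* `R/site-quant.R` — PSM I/O, SR computation, site mapping and aggregation
* `R/rs-calling.R` — exact Mann–Whitney, RS-Cys and base-competition calls
* `R/enrichment.R` — binomial domain enrichment, BH, hypergeometric overlap
* `R/structure.R` — PDB parsing, chain typing, renumbering, distances
* `R/pipeline.R` — orchestration, config, reports, CLI
* `vignettes/pacce-methods.Rmd` — the methods account: model, assumptions,
  parameter choices, limitations
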