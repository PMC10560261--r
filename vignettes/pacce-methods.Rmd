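---
title: "Methods: quantifying RNA-sensitive cysteines from photoaffinity competition chemoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RNA-sensitive cysteines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paccer)
```

## The measurement model

Photo-activatable competition and chemoproteomic enrichment (PACCE)
quantifies protein–RNA interactions through competition: 4-thiouridine
(4SU)-labeled cellular RNA is UV-crosslinked to proteins in living cells,
after which a cysteine-reactive covalent probe (a clickable electrophilic
purine, CEP) labels whatever cysteines remain accessible. At a cysteine
that sits in or near a protein–RNA interface, crosslinked RNA blocks probe
binding, so the probe signal drops relative to a control. Quantification
uses SILAC: the probe-only proteome in one isotope channel and the
RNA-competed proteome in the other, read out as an MS1 intensity ratio per
probe-modified peptide.

The central statistic is the **SILAC ratio (SR)** at a modified site,

> SR = (probe-only channel intensity) / (competition channel intensity),

which is ≈ 1 when RNA does not compete and grows with the degree of
blockade. A **1:1 mixing control** (equal probe labeling in both channels,
mixed 1:1) anchors the null at SR ≈ 1. A site is called an
**RNA-sensitive cysteine (RS-Cys)** when its mean PACCE SR is at least 2;
the relatively permissive cutoff reflects low fractional occupancy of
proteins by crosslinked RNA. Free-nucleobase competition experiments use a
stricter SR ≥ 5 rule (`call_base_competition()`).

### Channel orientation

Which SILAC channel receives the competitor is an experimental choice, not
a property of the data, so `compute_sr()` takes an explicit `orientation`.
The default, `"light_probe"` (light = probe-only, heavy = competition),
matches the base-competition design in which light cells receive probe
alone and heavy cells are co-treated. Flipping the orientation maps every
SR to its reciprocal; the label-swap property is pinned by tests. Records
whose competition channel is missing while the probe channel is present are
assigned a configurable cap (default 20) rather than an infinite ratio, the
usual convention in competition chemoproteomics; records missing the probe
channel are dropped with a logged count.

### Site aggregation

A single modified site is typically observed as several peptide forms —
fully tryptic, half-tryptic, and missed-cleavage peptides all covering the
same residue. Ratios are computed on a modified-site basis: within one
replicate the site SR is the **median** over all covering forms (midpoint
convention for even counts), and the site summary across replicates is the
**arithmetic mean** of the per-replicate medians. The median step is robust
to a stray form-level ratio; the mean step matches how replicate-level
summaries are conventionally reported (e.g. "mean SR = 2.7 vs. 0.7"). The
order (median within replicate, then mean across replicates) is a design
choice — pooling all forms across replicates before taking a single median
would be an alternative — and it is pinned by tests so it cannot drift
silently.

Peptides are localized by exact substring search against the supplied FASTA
proteome; a peptide occurring at several positions or shared between
accessions (a real phenomenon for paralogs sharing tryptic peptides) yields
one site per mapping, each flagged `ambiguous`, rather than being discarded.

## Significance: exact one-tailed Mann–Whitney U

The PACCE design is tiny: n = 6 PACCE replicates against n = 3 mixing
replicates. With 9 observations there are only C(9,3) = 84 equally likely
assignments under the null, so `exact_mann_whitney_one_tailed()` enumerates
them all and reports P(U ≥ U_obs), with U the number of (PACCE, mixing)
pairs in which the PACCE ratio is larger. Exactness matters at this scale:
the attainable p-values form a grid of multiples of 1/84, the smallest
possible p is 1/84 ≈ 0.0119, and complete separation, one discordant pair,
and ten concordant pairs force p = 0.0119, 0.0238 and 0.4524 respectively —
values the test suite checks against an independent brute-force enumeration
and against `wilcox.test()`. The test is run on per-replicate site SRs (not
raw peptide ratios), consistent with the 3-vs-6 replicate design; this is
an assumption, since form-level testing would also be defensible, and it is
documented here precisely because the data alone cannot distinguish the
two. Enumeration is used up to 10^6 arrangements; beyond that a normal
approximation with continuity correction takes over. Ties fall back to a
midrank permutation p with a warning. No multiple-testing correction is
applied to RS-Cys calls (BH is reserved for domain enrichment).

## Enrichment statistics

`binomial_domain_enrichment()` asks whether RS sites concentrate in
particular domain families. For each domain, x of the n RS sites fall
inside the domain's spans; the background proportion p0 is the fraction of
*all quantified* probe-modified sites in that domain (the detection
background — the least biased choice, since it conditions on what the
method can see). The p-value is the exact two-sided binomial by the
minimum-likelihood convention (sum of all point masses not exceeding the
observed one — the same convention as `binom.test`, but implemented
directly and checked against a brute-force sum). Benjamini–Hochberg
correction is applied across domains and enrichment requires q < 0.01 plus
an observed proportion above background. Domains absent from the background
receive a conservative pseudo-background p0 = 0.5/|background| instead of
an undefined test. All spans are 1-based and inclusive on both ends,
including intrinsically-disordered-region joins (`idr_annotation_join()`).

Set overlaps (e.g. RS proteins versus a reference RBP list) use the
hypergeometric upper tail over the universe of detected proteins —
overlap claims condition on detection. Peptide-resolution datasets are
harmonized to site resolution by the "average down" rule:
floor((start + end)/2) of the peptide span.

## Structure proximity

For protein–RNA co-structures, `min_cys_rna_distance()` measures the
minimum Euclidean distance from the cysteine's sulfur (SG) atom to any atom
of any RNA chain. Chains are typed by composition: RNA requires a majority
of A/U/G/C residue names *and* at least one O2' atom (the ribose 2'-OH
distinguishes RNA from DNA and survives modified nucleotides); DNA requires
a majority of DA/DT/DG/DC; protein a majority of standard amino acids.
Hydrogens count as RNA atoms when present (toggleable). Multi-model files
contribute only their first model; alternate locations resolve to the
highest-occupancy conformer (ties: first in file). Structures are filtered
to resolution ≤ 3 Å with a manual exclusion list for pathological entries.
Author numbering is renumbered to UniProt coordinates through an external
mapping table (the package does not reimplement SIFTS alignment); residues
without a mapping are excluded from site joins. When a structure contains
several copies of the same protein, every instance is emitted as its own
row, and per-site headline distances take the minimum across instances.
Summaries report mean distances for the classes all / RS / RS-in-RBD /
insensitive; empty classes are reported as absent, never as zero.

## What the synthetic generator emulates — and what it does not

`generate_proteome()` + `generate_psm_table()` produce a stated world in
which every downstream claim is checkable:

* **Design**: 3 mixing + 6 PACCE replicates (the experimental design), with
  per-form base intensities 10^U(5,7) (typical MS1 dynamic range) and
  multiplicative lognormal channel noise parameterized by a coefficient of
  variation (default 0.2, ordinary label-free MS1 variability).
* **Competition**: a planted per-cysteine competition factor divides the
  competition channel in the PACCE condition only; drawn uniform on
  [2, 20], spanning the SR ≥ 2 threshold and the upper range of reported
  site ratios. Insensitive cysteines have factor exactly 1. RNA occupancy,
  4SU incorporation and crosslinking efficiency are deliberately collapsed
  into this single factor — the pipeline observes only ratios, so nothing
  downstream could distinguish their contributions anyway. The
  `rnase_mode` switch forces every factor to 1, emulating RNase digestion
  before irradiation.
* **Digest realism**: fully tryptic peptides (cut after K/R, never before
  P), missed cleavages up to 2, and half-tryptic forms at a configurable
  rate (default 0.25) covering each cysteine, so the median-over-forms
  aggregation is actually exercised.
* **Residue selectivity**: 28% of planted sites land on non-cysteine
  nucleophilic residues, mirroring a probe with ~72% cysteine selectivity.
  Observed site-level fractions can drift below the planted value because
  short peptides map ambiguously to several positions; that is honest
  behavior of the mapping rule, not a generator defect.
* **Structures**: toy coordinate files place one O2' atom exactly at the
  planted distance from each SG along an axis, with all other atoms
  provably farther and sites 200 Å apart. Planted distances are honored to
  the PDB format's 0.001 Å precision.

The generator does **not** emulate spectra, retention times, search-engine
scoring (scores are a uniform scalar above the cutoff), protein inference,
interference between co-eluting peptides, or ratio compression. A green
test therefore establishes the correctness of the statistical pipeline
given site-level observations — not the upstream identification stack.

With `noise_cv = 0`, computed mean PACCE SRs equal the planted factors
*exactly* and mixing SRs equal 1 exactly; this noise-free identity is the
backbone of the acceptance suite. At `noise_cv = 0.2` the pipeline recovers
planted factors ≥ 4 with sensitivity ≥ 0.9 and planted nulls with
specificity ≥ 0.95 over 500+ sites (seed-pinned).

## Numerical and degenerate-input choices

* Adduct masses are matched within 0.01 Da (constants are printed to four
  decimals); unmatched masses are labeled `other`, not dropped.
* The score cutoff is inclusive (≥ 600), as is the SR threshold (≥ 2; a
  `strict_gt` flag provides the strictly-greater variant because the
  surrounding literature uses both phrasings).
* The two-sided binomial p is capped at 1 (floating-point sums of all
  point masses can exceed 1 by ~1e-16).
* Sites with no mixing counterpart are called on the threshold alone with
  an absent p-value; empty distance classes are absent, not zero; an empty
  site set is an error for enrichment (there is no meaningful test).
* Cysteines without a resolved SG atom are skipped with a recorded reason;
  structures without an RNA chain are an error for the distance stage.

## Known limitations

* Real-structure validation (published site distances on deposited PDB
  entries) requires network access to fetch coordinates and a residue
  renumbering map; the corresponding acceptance test runs the full code
  path but can only pass where the PDB is reachable.
* The hand-rolled PDB reader covers coordinate records, first-model
  selection, altloc resolution and the resolution remark — not mmCIF,
  insertion-code-heavy entries, or header metadata beyond resolution.
* The pipeline starts from identified PSMs; FDR control, mass calibration
  and protein inference belong to the upstream search engine.
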