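---
title: "Methods and models in nadkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models in nadkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadkit)
```

nadkit bundles the bespoke computations used to dissect NAD+ biosynthesis
genetics in *Chlamydomonas reinhardtii*: a column-conservation classifier
for protein alignments, CDS variant consequence calling with reversion
design and restriction-site scanning, a pathway reachability engine,
meiotic progeny statistics, a replicative-aging lineage simulator, and
comparative-Ct expression quantification. This vignette records the
models, the parameters that matter, and the design choices made where the
published description left room.

## Column-conservation classification

The classifier partitions the twenty amino acids into eight conservation
groups — {G,A}, {V,L,I}, {F,Y,W}, {C,M}, {K,R,H}, {D,E,N,Q}, {S,T}, {P} —
and scores each alignment column by percentage composition. Three
categories are possible:

* **Majority Identity** — at least 61% of the column's amino acids are
  identical; the driving percentage is that identity fraction.
* **Conserved Minority** — at least 61% belong to one conservation group
  while no single amino acid exceeds 60% of the column; the driving
  percentage is the group fraction.
* **Insufficient Conservation** — neither condition holds; the column is
  left uncolored.

When a column satisfies both definitions (e.g. 7 serines + 3 threonines:
identity 70%, group 100%), Majority Identity takes precedence. The driving
percentage maps to color bands Blue 61–70, Green 71–80, Gold 81–90 and Red
91–100, each with a dark shade (positions holding the majority residue)
and a light shade (other members of its group; the only shade a Conserved
Minority column uses).

Numerical choices where the published rules are silent:

* **Gaps.** Percentages are computed over the column's non-gap residues
  ("amino acids in that column" most naturally excludes gaps). A gap-only
  column is Insufficient Conservation, with a warning.
* **Non-integer percentages.** The printed bands are integer ranges; we
  treat them as half-open real intervals [61, 71), [71, 81), [81, 91),
  [91, 100], and compare thresholds exactly (identity ≥ 61.0, cap ≤ 60.0).
  This covers the continuum without holes; we do not round before banding.
* **Ties** for the majority residue or group are broken alphabetically.
  A tie can change the reported label but never the category.
* **Ambiguity letters.** `X` counts toward occupancy (it dilutes every
  percentage) but belongs to no group and can never be the majority
  residue. Lowercase input is uppercased.

```{r colorfy}
aln <- alignment(c("a", "b", "c"), c("AAA", "AAA", "AAV"))
sapply(colorfy_alignment(aln), function(x) c(x$category, x$band))
```

The test suite checks this classifier two independent ways: an exhaustive
comparison against a direct transcription of the three rules over every
column of up to six residues from a four-letter alphabet spanning
within-group and cross-group compositions, and threshold sweeps on
100-deep synthetic columns that locate the 61/60/91 boundaries.

## Variant consequences and the reversion screen

Coordinates are HGVS-like `c.` numbering: 1-based on the coding sequence,
no 5' UTR. This matches the arithmetic of the characterized point mutants
(c.1376 → codon 459; c.559 → codon 187). Translation uses the standard
genetic code throughout; no organelle codes. A deletion whose length is
not a multiple of three is a frameshift at the first affected codon; the
stop scan runs only to the end of the provided CDS, and a frameshifted
sequence with no in-frame stop is flagged rather than extended (genomic
readthrough is out of scope). `call_consequence` requires an ATG start but
tolerates a trailing partial codon, which the frameshifted products of
single-base deletions routinely produce. In-frame deletions and more than
one frameshifting variant per call are rejected rather than guessed at.

Reversion design enumerates the nine single-base neighbors of a codon and
keeps those translating to the target residue — for ATT (Ile), the single
edit reaching Ser is position 2 to G, giving AGT, which simultaneously
creates an SfcI site (CTRYAG) used to genotype revertants. Degenerate
site scanning goes through `Biostrings::matchPattern` with IUPAC matching
on both strands, reporting reverse-strand hits in forward coordinates and
collapsing the duplicate hits a palindromic pattern produces.

```{r reversion}
design_single_base_reversion("ATT", "S")
scan_restriction_sites("TTCTACAGTA", "SfcI")
```

## Pathway completeness and rescue

The network joins four routes to NAD+: the five-enzyme aspartate de novo
route (ASO, QS, QPT, NMNAT, NS), the six-enzyme tryptophan route (TDO or
IDO, then AFMID, KMO, KYNU, 3HAO, converging on quinolinate), the 4-step
salvage route from nicotinamide (NAMase, NAPRT, NMNAT, NS) and the 2-step
salvage route (NAMPT, NMNAT). NMNAT carries two reactions (NaMN→NaAD and
NMN→NAD) and the sirtuin consumes NAD+ back to nicotinamide.

Route *completeness* treats TDO/IDO as alternatives (one suffices) but the
*missing* tally counts each absent enzyme separately, which is how the
bundled Chlamydomonas profile is missing four of the six tryptophan-route
enzymes while still having IDO and KMO. *Viability* is metabolite
reachability: NAD+ must be reachable from the internal amino-acid
precursors (aspartate, tryptophan) plus an optional supplement, using only
reactions whose enzyme is present and not lesioned.

Design choices:

* **Transport.** Supplements are gated by a per-metabolite uptake flag
  (NAM and NMN: yes; nicotinic acid: weak; NaAD and 3-hydroxyanthranilate:
  no), reflecting the observed rescue pattern. A weak-uptake rescue is
  flagged `"weak"` but not scored viable. Note that in the Chlamydomonas
  profile nicotinic acid reaches nothing even if taken up, because NAPRT
  is absent — the faint rescue observed on plates is one of the open
  puzzles this model flags rather than resolves.
* **Leaky alleles.** A complete NMNAT loss is unrescuable by NAM or NMN in
  any reachability model (both salvage reactions need NMNAT), yet the
  NMNAT nonsense mutant grows on both. The truncated protein must retain
  partial activity, so `chlamy_mutants()` marks that allele `leaky` and
  `mutant_lesions()` drops leaky alleles from the lesion set. Leakiness is
  a binary pass/block here; partial flux is not modeled.
* **Known discrepancy.** Pure reachability predicts NMN rescues an
  NAMPT+NS double mutant via NMNAT, yet no such double mutants were
  recovered in crosses on NMN medium (hydrolysis, uptake, or meiotic
  expression differences are the candidate explanations). The engine
  reports the model's answer; the discrepancy is documented, not patched.
* Reachability is computed with `igraph` on the enzyme-filtered reaction
  graph; tests compare it against brute-force path enumeration and check
  monotonicity (adding an enzyme never kills a viable prediction, adding
  a lesion never revives one).

## Progeny statistics

`tally_progeny` gives exact integer sums per cross and medium for the
packaged cross table (198 viable progeny on NAM medium, 148 on NMN; the
double-mutant class is zero in every block). The evidence that an empty
class is synthetically lethal rather than unlucky is the exact tail
probability `(1 − p)^n` under Mendelian 1:1:1:1 segregation of two
unlinked loci (p = 1/4): a chi-square test is deliberately avoided because
an expected count of zero in the missing class invalidates its
asymptotics. The percent-increase helper reproduces the replicative-
capacity headline: on the upper bounds of the two generation ranges,
40 → 50 is exactly 25%; `lifespan_contrast` also reports the lower-bound
and midpoint variants (26.3% and 25.6%).

## Replicative-aging lineage simulator

Cell state is (flagellar number, completed divisions, per-lineage division
limit). Division rules: a uniflagellate or biflagellate cell yields one
aflagellate and one biflagellate daughter; an aflagellate cell yields one
aflagellate and one uniflagellate daughter. The aflagellate rule is not
stated explicitly in the source material; it is the only rule consistent
with "aflagellate cells never produce biflagellate daughters" while
letting a biflagellate appear after exactly two divisions, and the test
suite asserts that property over exhaustive pedigrees.

The transfer assay selects the swimming (biflagellate) cells every
transfer, advances the culture a fixed number of divisions (default 2 per
12-hour transfer; the organism divides one to three times per cycle, and
this is configurable), plates a sample (default 100 cells), and scores the
fraction able to complete at least one further division. Senescence is a
hard cutoff at the lineage's division limit, drawn uniformly per founder
from a configured range (e.g. 38–40) to reflect the spread of observed
lifespans; senescent cells persist in the tube and depress the plated
fraction. Fixed seeds give bit-identical trajectories. Default problem
sizes (100–200 founders, 25–30 transfers, plating 100–400 cells) keep a
run well under a second while leaving binomial noise visible; the
simulator reproduces the qualitative contrast — raising the limit from
38–40 to 48–50 shifts extinction of colony formation about 10 generations
later — not the published survival curves, which are not available as
numbers.

## Relative expression

`relative_expression` implements the comparative-Ct method: per replicate
ΔCt = Ct(target) − Ct(reference gene), replicates averaged on the ΔCt
scale (standard ΔΔCt practice), and each strain reported as
`100 × 2^−ΔΔCt` percent of wild type, so the wild-type strain is exactly
100. Amplification efficiency is fixed at 2 (perfect doubling),
configurable. Standard errors are computed on the percent scale from
per-replicate values — with two replicates, SE is half the absolute
difference. The two-fold rule is strict: above 200% is significant
upregulation, below 50% significant downregulation, anything else not
significant; no multiple-testing correction is applied, the two-fold rule
being the only filter.

## Synthetic data

Every generator is seeded and self-verifying: the planted truth is
recovered by the corresponding pipeline stage in the test suite.

* `gen_alignment` builds columns whose category and driving percentage are
  guaranteed by construction (identity counts exact, group residues spread
  below the 60% cap, fillers drawn from distinct other groups). A
  percentage that is not a whole residue count at the requested depth is
  an error, not a rounding.
* `gen_gene_with_variant` plants substitutions chosen from the codon's
  single-base neighbors, so the expected consequence is known without
  running the caller; frameshift truth uses a naive in-generator
  translation.
* `gen_progeny_table` draws multinomial 1:1:1:1 classes; a lethal class is
  fixed at zero with the viable progeny drawn over the remaining three —
  the conditional distribution when one class dies before scoring.
* `gen_ct_table` encodes the true percent as a ΔCt offset,
  `−log2(percent/100)`, against a shared wild-type baseline, adding
  Gaussian noise (default sd 0.2 cycles) to each mutant replicate's
  offset. The wild-type rows carry the baseline exactly: truth is defined
  relative to the wild-type calibration, so the noise models per-replicate
  ΔΔCt measurement error against that anchor. Under this model, two
  replicates at sd 0.2 recover the planted percent within ±20% for about
  96% of genes, which the recovery tests assert at a 95% threshold.

What the generators do **not** emulate: real amino-acid composition or
phylogenetic correlation between alignment rows, codon usage bias,
plating-efficiency losses in progeny counts, amplification-efficiency
drift or inter-run calibration in qPCR, and partial-flux (leaky) enzyme
activity. Passing tests therefore demonstrate correctness of the
computations under the stated models, not robustness to every artifact of
real data.
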