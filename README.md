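# nadkit

Tools for the genetics of NAD+ biosynthesis in the green alga
*Chlamydomonas reinhardtii*, aimed at researchers dissecting metabolic
pathways with conditional-lethal mutants. The unusual feature of this
organism is that it synthesizes NAD+ two ways — de novo from aspartate
(ASO → QS → QPT → NMNAT → NS, as in land plants) and by the two-step
nicotinamide salvage route (NAMPT, NMNAT, as in mammals) — and nadkit
packages the computations that analysis rests on:

* **Conservation coloring of protein alignments** — each alignment column
  is classified by percentage composition over eight amino-acid
  conservation groups ({G,A}, {V,L,I}, {F,Y,W}, {C,M}, {K,R,H}, {D,E,N,Q},
  {S,T}, {P}): *Majority Identity* when ≥ 61% of residues are identical,
  *Conserved Minority* when ≥ 61% share a group and no residue exceeds
  60%, else *Insufficient Conservation*; the driving percentage selects a
  color band (Blue 61–70, Green 71–80, Gold 81–90, Red 91–100), rendered
  as HTML, ANSI or TSV.
* **CDS variant annotation** — protein consequences (missense, nonsense,
  synonymous, frameshift with downstream stop scan) in HGVS-like `c.`
  coordinates, single-base reversion design, and degenerate
  restriction-site scanning (e.g. SfcI = CTRYAG) for genotyping
  revertants.
* **Pathway completeness and rescue** — a metabolite/reaction graph of the
  four NAD+ routes; route completeness per organism enzyme profile, and
  strain viability as reachability of NAD+ under lesions and media
  supplements.
* **Progeny statistics** — tallies of meiotic cross tables and the exact
  probability `(1 − p)^n` that a genotype class is empty under Mendelian
  1:1:1:1 segregation, the evidence behind calling a double mutant
  synthetically lethal.
* **Replicative-aging simulation** — the flagellar-number pedigree assay:
  biflagellate cells mark the oldest lineage, transfers propagate the
  swimmers, and colony-forming fraction versus generation estimates
  replicative lifespan.
* **qRT-PCR quantification** — comparative-Ct relative expression
  normalized to an internal control gene with wild type at 100%, and the
  strict two-fold significance rule.
* **Seeded synthetic-data generators** for every input type, with planted
  ground truth.

## Worked example

Classify a small alignment and annotate it:

```r
library(nadkit)
aln <- read_fasta_alignment(c(">Cr","GSFDSLVR", ">At","GSYDSLVK",
                              ">Os","GSFESLVR", ">Hs","GTFDALVK",
                              ">Sc","GSFDSIVK"))
writeLines(write_annotation_tsv(colorfy_alignment(aln)))
#> column  category           percent  band   majority_residue  majority_group
#> 1       MajorityIdentity   100      Red    G                 GA
#> 2       MajorityIdentity   80       Green  S                 ST
#> 3       MajorityIdentity   80       Green  F                 FYW
#> 4       MajorityIdentity   80       Green  D                 DENQ
#> 5       MajorityIdentity   80       Green  S                 ST
#> 6       MajorityIdentity   80       Green  L                 VLI
#> 7       MajorityIdentity   100      Red    V                 VLI
#> 8       ConservedMinority  100      Red    none              KRH
```

Column 8 (R/K/R/K/K) has no 61% residue but is 100% within the basic
group, so it is Conserved Minority in the light red shade; column 2 is
80% serine, dark green at the serines and light green at the threonine.

Variant arithmetic and the pathway engine:

```r
call_consequence("ATGTCCTAA", gene_variant("substitution", 5, "C", "T"))[[1]]
#> S2F                       # TCC -> TTC, a serine-to-phenylalanine missense
codon_index(1376)
#> [1] 459                   # the c.1376 change falls in codon 459

missing_class_test(198)
#> [1] 1.828648e-25          # chance that 0 of 198 progeny hit a 1/4 class

net <- build_default_network()
chl <- bundled_profiles("Chlamydomonas")
predict_rescue(net, chl, lesions = "QPT", supplement = "NAM")[c("viable", "rescue")]
#> $viable [1] TRUE          # nicotinamide feeds the 2-step salvage route
#> $rescue [1] "full"
```

A QPT lesion severs de novo synthesis, but supplementing nicotinamide
restores NAD+ through NAMPT and NMNAT, so the strain is predicted viable —
the conditional-lethal behavior that defines these mutants.

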