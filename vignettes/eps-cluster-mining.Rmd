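---
title: "Mining and comparing EPS biosynthesis gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparing EPS biosynthesis gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters and why their defaults
are what they are, what the synthetic-genome generator does and does not
emulate, and the design decisions taken where the methodology was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The biological model

Wzy-dependent heteropolysaccharide biosynthesis in *Lactobacillus* is
encoded by gene clusters with a conserved grammar: a 5′ regulatory and
phosphoregulatory stretch (*epsA*, *epsB*, *epsC*, *epsD*, a priming
glycosyltransferase *epsE*), a central variable block of elongating
glycosyltransferases (*gt*), transport and polymerization genes (*wzx*
flippase, *wzy* polymerase) toward the 3′ end, and often
sugar-nucleotide precursor enzymes (*galE*, *rmlABCD*, UDP-galactopyranose
mutase, UDP-N-acetylglucosamine 2-epimerase, …). Clusters whose first five
genes are the intact, ordered *epsABCDE* stretch are **generic**; all other
arrangements (genes absent from the stretch, or displaced into the cluster
body) are non-generic. The essential set for biosynthesis is
{*epsE*, *gt*, *wzx*, *wzy*, *epsC*, *epsB*}; *epsA* and *epsD* are treated
as dispensable. Mobile elements and a lower GC content of *gt*/*wzx*/*wzy*
relative to the genome are the classic fingerprints of horizontal
acquisition of the variable part of these clusters; the package reports
that evidence (GC deltas, transposase adjacency) without inferring transfer
itself.

## Cluster discovery

Seeds are the conserved 5′ proteins (EpsA–EpsE). Every CDS is aligned
against the seed references with Smith–Waterman local alignment
(BLOSUM62, affine gaps open 11 / extend 1 — the BLASTP defaults, an
assumption recorded in `scoring_params()` rather than an inference). A CDS
with identity > 30 % and ≥ 50 % coverage *of the reference protein* seeds a
cluster. Requiring coverage on the reference side makes short fragments
fail the homology route deliberately: they are picked up by the keyword
route and the truncation flag instead.

Neighborhood expansion formalizes what is otherwise a manual curation
step. Walking the record's feature order outward from a seed, a gene is
EPS-related if it aligns to *any* reference-library protein above the same
threshold or its product annotation matches a curated keyword list
(glycosyltransferase, polysaccharide, flippase, polymerase, epimerase,
mutase, dehydratase, transposase, acetyltransferase). Expansion stops after
`max_gap = 2` consecutive unrelated genes and unrelated genes are trimmed
from both ends; transposases never terminate extension. Feature order, not
base-pair distance, defines adjacency, which makes the rule robust to
annotation density. `max_gap` bounds the expansion while still spanning the
occasional hypothetical gene inside a real cluster; it is exposed in the
configuration, and clusters containing no seed-role gene at all are not
discoverable — a documented limitation of seeding on *epsA–E*.

No E-values are computed anywhere: E-values need database-size statistics
that have no meaning for a self-contained reference library, so the seed
threshold is raw identity plus coverage.

## Role assignment and GT families

The best reference hit sets a gene's role; without a hit, the keyword list
sets it with `evidence = "keyword"`. Flippase/polymerase calls must also be
membrane proteins: ≥ 8 predicted transmembrane helices, otherwise the call
falls to `Other`. Proteins shorter than half the reference-role median
length are flagged truncated (the published figures mark truncated genes
but state no cut-off; 50 % is this package's choice). Pseudogenes keep
their flag and are role-called from their conceptual translation, but are
excluded from the similarity graph and families.

CAZy-style GT families are assigned by a two-method vote that preserves the
conservatism of multi-tool annotation servers without external binaries:
(1) best-hit against family-labeled GT references, and (2) the family with
maximal shared-4-mer containment (≥ 0.2) against per-family reference
concatenations. A family label requires both methods to agree; anything
else is `unknown`. The EpsE-vs-GT ambiguity is resolved by reference-set
identity (the higher-scoring hit wins), with the evidence field carrying
the route taken.

## Transmembrane topology

Helix prediction is Kyte–Doolittle hydropathy: window 19, candidate windows
with mean ≥ 1.6, greedy resolution by descending mean with a minimum
inter-helix loop of 3 residues — standard hydropathy settings, both
configurable. Orientation uses the positive-inside rule: of the two
alternating-loop topologies, the one placing more K+R in cytoplasmic loops
wins, ties falling to an inside N-terminus. The parity invariant (C side
equals N side iff the helix count is even) holds by construction. This is a
deliberate stand-in for HMM-based predictors: it is self-contained, has no
trained weights, and approximates rather than reproduces their output; on
real proteins its helix counts should be read as hydropathy estimates.

## Protein families and diversity

The all-against-all graph keeps a pair when identity and the coverage of
*both* sequences pass the threshold (reciprocal query coverage; a single
symmetric local alignment decides both directions). A shared-k-mer
prescreen (k = 4) skips pairs sharing no k-mer; the test suite verifies it
against the no-prescreen route.

Markov clustering follows the standard scheme: column-stochastic matrix
from identity-weighted edges with max-incident self-loops, alternating
expansion (matrix squaring) and inflation (elementwise power with
renormalization), pruning entries below 1e-5, until the maximum elementwise
change falls below 1e-8 (cap 200 iterations; non-convergence warns and
returns the current interpretation). Clusters are connected attractor
systems; family ids are assigned in order of each family's
lexicographically smallest member, making output independent of input
order.

The two-level hierarchy emulates genus-level families as subtypes of
global families: loose families from edges at ≥ 35 % identity (inflation
1.5), strict families by re-clustering each loose family's ≥ 50 % sub-edges
(inflation 2.0). Nesting holds by construction. The 50 % strict threshold
matches the similarity cut-off used for reciprocal hits; the inflation
defaults were chosen with the generator's divergence structure in mind
(members at ~90 % of a founder, founders ~50 % diverged) and are
configurable. This hierarchy is an *analog* of k-mer-based pan-genome
family systems, not a reproduction of any external database's assignments.

Diversity statistics per role — proteins per strict family, strict per
loose family, % singleton families, and the multicopy copies:families
ratios — are rounded to one decimal, matching the layout of published
summary tables. The worked-example functions
(`cluster_count_bookkeeping()`, `phosphoregulatory_bookkeeping()`,
`recompute_survey_ratios()`) recompute a published survey's internal
arithmetic from its printed integer inputs with these same formulas; the
shipped table of printed integers is data, not a result of this package.
Three printed ratio cells are internally inconsistent with any single
rounding rule (the same table rounds 9.75 up but truncates 4.48, 1.95 and
2.06); the acceptance test therefore requires exact agreement only for the
consistently rounded cells and one-unit-in-the-last-decimal agreement for
those three.

## Comparative analysis

The presence/absence matrix is binary over families × clusters
(strict level by default) with lexicographic ordering on both axes.
Cluster profiles are clustered agglomeratively with Jaccard distance on
presence entries and average linkage — natural choices for sparse binary
profiles; the original tooling in this field offers many distance/linkage
pairs without stating one, so both are configurable and recorded in the
run manifest, and group-level concordance with any published tree is
explicitly not claimed. The cut level *k* is a user parameter (a published
analysis of real data used 8; the synthetic analyses here use 3, the
number of habitats). Habitat sharing places each role's families into the
7 regions of the three-habitat Venn decomposition by the habitats of the
strains contributing members; families with only unknown-habitat members
are excluded and reported, and singleton families are tallied separately
from multi-member ones. Sharing is computed for the eight canonical roles;
transposases are deliberately excluded (they are modeled as a single
mobile pool that crosses habitats).

## The synthetic-genome generator

The generator's defaults are the package's standard study conditions,
chosen once:

* 20 genomes, ~25 housekeeping genes each (~40 kb) — large enough for
  every template and habitat to appear, small enough that the full test
  suite and acceptance script run in minutes on one CPU (the vignette and
  tests state the sizes used as the package's own choice);
* strain cluster counts drawn from {1, 2, 3, 4} with probabilities
  (0.65, 0.25, 0.09, 0.01) — the distribution reported for real
  *Lactobacillus* strains;
* habitat mix host-adapted / nomadic / free-living = 0.4 / 0.4 / 0.2 by
  exact allocation (the mix is a study condition, not a sampling rate);
* background GC 0.42 (typical lactobacilli), with *gt*/*wzx*/*wzy*
  back-translated at an offset of −0.10 — GC-targeted codon sampling
  (a lambda-tilted codon distribution solved per gene, plus a synonymous
  repair pass) lands each gene within ~0.005 of its target, so recovered
  offsets are a property of the analysis, not generator noise;
* template mix generic / shuffled / incomplete = 0.30 / 0.35 / 0.35
  (roughly the generic fraction seen in real data), with per-gene dropout
  rates highest for *wzy*, the most commonly missing gene;
* transposase insertion rate 0.25 with a 0.6 placement bias adjacent to
  *wzx*; occasional pseudogenes (preferring *wzy*), truncated duplicate
  *gt* copies, mid-cluster hypothetical genes, minus-strand clusters and
  plasmid-borne clusters;
* per-habitat family pools: founders ~50 % diverged from role archetypes,
  members at 90 % of their founder — placing within-family identity above,
  and between-family/between-habitat identity below, the 50 % strict
  cut-off by construction. GT CAZy archetypes are partitioned across
  habitats (host-adapted GT2+GT8, nomadic GT4+GT32, free-living GT1+GT14)
  so strict families cannot bridge habitats, mirroring the
  habitat-structured GT repertoires seen in real clusters.

Flippase/polymerase proteins are built from an explicit membrane
architecture (hydrophobic 21-residue helices, K/R-rich cytoplasmic loops,
helix counts 10–14 mode 14 for Wzx and 8–12 mode 10 for Wzy) and mutated
within per-position residue classes, so planted helix counts are exactly
recoverable by hydropathy; unconstrained mutation would erode the
architecture the topology module is meant to detect.

What the generator does **not** emulate — and hence what green tests do
not show about real data: no nucleotide-level evolution (no dN/dS,
recombination, or codon-usage realism beyond GC), no annotation errors or
missing genes outside the modeled dropout, no paralogy outside clusters,
no genuinely ambiguous role boundaries, and divergence levels chosen to
straddle the family cut-off rather than drawn from real protein-family
divergence distributions. Recovery rates of 1.0 on this substrate
demonstrate internal correctness of the pipeline's logic, not expected
field performance.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally, converted from GenBank's
1-based inclusive at the boundary. GC computation excludes N from
numerator and denominator and returns `NA` (never 0) for an all-N
interval. Translation uses bacterial table 11; partial CDS are translated
from the first in-frame codon with a warning. Alignment identity is
matches over alignment length including gaps; exact score ties inside the
alignment engine are resolved by its deterministic internal order (scores
are unaffected; only the reported identity of tied optima could differ).
MCL family ids, matrix orderings and dendrogram leaf order are all fixed
lexicographically so that identical inputs give byte-identical outputs;
`hcl_clusters()` re-sorts columns before clustering so the tree is
invariant to input column order even under tie-heavy binary distances.
Habitat lookups fall back from strain to species and return `"unknown"`
rather than erroring. Whether truncated-but-present genes count as present
in completeness is a flag (`truncated_as_present`, default off).

## Known limitations

* Seeding on *epsA–E* cannot discover clusters lacking all five seed
  roles.
* The hydropathy topology predictor approximates trained HMM predictors.
* Loose families at the 35 % threshold can merge distantly related
  habitat pools; habitat-level claims in the package therefore default to
  the strict level.
* The GenBank reader supports simple `start..end` /
  `complement(start..end)` locations only — compound joins are rejected,
  matching the generator's output and typical bacterial CDS annotations,
  but not every real file.
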