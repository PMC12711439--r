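---
title: "Reassessing interkingdom HGT candidates from gene-tree topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reassessing interkingdom HGT candidates from gene-tree topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscreen)
```

## The procedure and its assumptions

Claims of interkingdom horizontal gene transfer (HGT) into plants rest
almost entirely on single-gene phylogenies: a plant sequence nesting
among bacterial, fungal, metazoan or viral homologs. Such topologies are
fragile. They depend on which homologs existed in databases at the time
of analysis, and a pattern read as a transfer can dissolve into vertical
inheritance with differential gene loss once homologs from additional
eukaryotic lineages surface. `hgtscreen` encodes the curation logic of a
systematic reassessment of published plant HGT candidates as a
deterministic, auditable pipeline.

The pipeline assumes:

* the unit of evidence is one unrooted gene tree per candidate, with
  branch supports (SH-aLRT or similar) on internal edges;
* every leaf can be tied to a taxonomic lineage, which is mapped onto a
  fixed supergroup scheme; biological interpretation happens entirely at
  supergroup resolution;
* tree inference itself (alignment, model selection, ML search) is
  upstream and out of scope — the package consumes Newick, the standard
  13-column tabular homology format, and plain-text lineage/metadata
  tables.

All topology semantics are **unrooted and bipartition-based**: a leaf set
is a clade exactly when it is one side of an edge-induced split. No
rooting is attempted, because rooting a single-gene tree would inject an
assumption the data do not support; "nested among donors" is expressed
through the census of leaves surrounding the maximal plant clade instead.

## The six verdicts

Each candidate receives exactly one category:

* **HGT** — the plant homologs form one clade restricted to the
  originally reported recipient lineage, surrounded by the reported
  donor supergroup, with no other eukaryotic kingdoms on the tree.
* **HGT_recipient_shifted** — as above, but the plant clade now contains
  homologs from plant lineages outside the reported recipient: the
  transfer signal survives, yet the event must have happened deeper in
  plant history than originally claimed.
* **NoHGT** — homologs from other eukaryotic kingdoms join the plants in
  one monophyletic eukaryote cluster; vertical inheritance with
  lineage-specific losses explains this more parsimoniously than an
  ancient interdomain transfer followed by widespread loss.
* **Inconclusive** — patchy or polyphyletic distributions (several
  disjoint plant clades, or multiple polyphyletic eukaryotic kingdoms),
  or too little evidence (no tree, fewer than four homologs).
* **Putative_EGT** — the plants cluster exclusively with cyanobacteria:
  the signature of plastid-derived endosymbiotic gene transfer, which
  must not be counted as interkingdom HGT from free-living organisms.
* **Potential_Contamination** — no eukaryotic homologs, and the genomic
  context (donor-kingdom flanking genes, short contig) points to foreign
  sequence in the assembly.

## Rule precedence

The category definitions do not by themselves impose an order, so the
classifier applies one as a design decision: **checks that can refute a
transfer fire before checks that would confirm one** (degenerate
evidence → patchiness → NoHGT → EGT → HGT/shifted → Inconclusive). This
mirrors the conservative stance of treating HGT as the explanation of
last resort, and it makes the partition property trivial to guarantee:
the first rule that fires decides, and every decision is recorded in the
verdict's evidence trail together with the measured quantities.

Two further design choices deserve explanation:

* **The reported donor is excluded from the extra-kingdom census.** The
  NoHGT reasoning penalises homologs in eukaryotic kingdoms *other than
  the recipient and the putative donor*. Without this exclusion a
  candidate reported as fungus-to-plant transfer could never be
  classified HGT — its fungal neighbours would always count as an "extra
  eukaryotic kingdom" — which would contradict the category definitions
  themselves. `eukaryote_kingdom_census()` still reports all non-ingroup
  eukaryotes; the exclusion is applied by the classifier.
* **The neighbourhood of a clade is the census of its complement.** For
  a clade defined by an edge, the subtrees attached at the node on the
  far side of that edge jointly cover everything outside the clade — in
  an unrooted tree a "one-node sister neighbourhood" and the full
  complement are the same leaf set. `neighbor_supergroups()` therefore
  reports the complement census, and the donor-domination test asks what
  fraction of *all* leaves surrounding the plant clade belong to the
  reported donor.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_support` | 0.8 | edges with SH-aLRT-scale support below this are contracted into polytomies before interpretation; supports given as 0–100 are normalised to 0–1 at parse time |
| `missing_support` | 1 | edges without a recorded support are trusted |
| `min_homologs` | 4 | below four leaves an unrooted tree carries no bipartition, so topology classification is not attempted |
| `donor_fraction` | 1 | fraction of the neighbourhood that must belong to the reported donor for the HGT rules; 1 demands an exclusive donor neighbourhood |
| `min_extra_kingdoms` | 1 | one additional eukaryotic kingdom monophyletic with the plants already triggers NoHGT |
| `flank_fraction` | 1 | fraction of examined flanking genes that must match the donor for the contamination rule |
| `short_contig_bp` | 100000 | contig length below which a contig counts as short; no published cutoff exists, so the value is explicit, configurable and recorded in every verdict's configuration fingerprint |
| `flanks_only` | FALSE | conjunctive mode (flanks **and** short contig) is the conservative default; disjunctive mode is exposed for sensitivity analysis |

The homolog filter defaults (`pident > 30`, coverage `> 60`, e-value
`< 1e-5`) follow the retention wording "above / exceeding / lower than",
hence strict inequalities; an inclusive mode exists for sensitivity
checks. Coverage uses the single HSP's query span over the query length
— whether merged HSPs or alignment length were used originally is
unknowable from the outputs, so the simplest auditable definition is
taken and logged. When several rows share a subject, each row is judged
independently and the subject survives if any row passes, which is the
reading most generous to homolog recovery.

## What the synthetic generator emulates

`generate_case()` builds, for each of seven scenarios, the exact gene-tree
pattern its category describes — by explicit grafting, not by birth–death
simulation, because ground truth must be guaranteed rather than probable:

* `true_hgt`: a recipient-only plant clade grafted inside a donor
  backbone (defaults: 4 plant, 8 donor leaves);
* `recipient_shifted`: the plant clade additionally contains plant
  homologs from a non-recipient lineage (3 + 3 plants, 8 donors);
* `vertical_loss`: plants plus two other eukaryotic kingdoms as one
  eukaryote cluster sister to prokaryotes (3 + 3 + 3 eukaryotes, 6
  bacteria);
* `egt`: plants sister to cyanobacteria only (3 + 6);
* `patchy`: two disjoint plant clades interleaved across kingdoms;
* `contamination`: a lone query with donor-kingdom flanks on a 5–50 kb
  contig (below the 100 kb short-contig default);
* `no_homologs`: no tree and no context.

Branch supports are drawn uniformly from `support_range`, default
`[0.9, 1]` so that cohorts are unambiguous at the 0.8 collapse threshold.
Lineage names reuse the real marker vocabulary (Viridiplantae,
Brassicales, Chlorophyta, Cyanobacteriota, …) so the taxonomy module is
exercised unmodified. The generated hit tables plant exact survivor
counts, with the first failing row of each criterion sitting precisely on
its boundary (identity 30, coverage 60, e-value 1e-5).

What the generator does **not** emulate: alignment error, model
misspecification, rogue taxa, long-branch attraction, paralogy, or
incomplete lineage sorting. Passing the recovery tests therefore shows
that the classifier implements its rules faithfully on trees whose
pattern is known — not that those rules recover the truth on real data,
where the tree itself may be wrong.

## Numerical choices and degenerate inputs

* Percentage arithmetic uses half-up rounding (`round_half_up()`), the
  convention behind the printed cohort percentages; banker's rounding
  would disagree at ties. Rounded percentages need not sum to exactly
  100 and the tests only require the residual to stay small.
* Supports exactly at `min_support` are kept; only strictly smaller
  supports are contracted. `min_support = 0` is the identity and
  reproduces the uncollapsed verdict exactly.
* Bipartition queries special-case the trivial sides (singletons, the
  full leaf set, and complements of singletons) that every pendant edge
  induces; 2- and 3-leaf trees have only trivial splits and are flagged
  degenerate for topology work.
* Unresolvable leaf labels either abort (strict mode) or are annotated
  `Unclassified`; such leaves never count as eukaryotic or prokaryotic
  evidence and their number is surfaced in the evidence trail.
* Ties in "largest all-ingroup side containing the query" cannot occur:
  sides containing a common leaf are nested, so the maximum is unique.

## Verification strategy and problem sizes

The test suite checks every operation against an oracle that is
independent of the implementation path: bipartition queries against
brute-force edge-deletion enumeration on all random trees with up to 8
leaves (1000 trees in the acceptance suite), support collapsing against
`phangorn::pruneTree`, filtering against planted survivor counts with
boundary probes, and the classifier against cohorts whose category is
guaranteed by construction (50 cases per scenario in the acceptance
suite, with ≥ 95% per-scenario recovery required; the shipped
configuration attains 100%). Property tests cover partition and
determinism of verdicts, invariance under leaf reordering and Newick
rewriting, monotonicity of the filter under threshold tightening, and
the guarantee that weakening branch supports degrades verdicts only
toward Inconclusive, never to a different definite category. These sizes
keep the full suite under two minutes on one CPU while exercising every
rule path.

## Known limitations

* The classifier formalises a manual curation protocol; a human curator
  may also weigh branch lengths, bitscores and biological plausibility.
  The evidence trail exposes the raw quantities so such judgement can be
  applied downstream, but no additional heuristic is invented.
* Agreement with an automated reference screen is implemented
  (`agreement_with_reference()`, Inconclusive excluded, both conventions
  for "Complex" reference calls exposed), but recomputing the published
  agreement figure would require the original screen's per-candidate
  output, which is external data.
* No gene–species tree reconciliation or coalescent network modelling:
  these remain impractical at cohort scale and are out of scope by
  design.
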