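# hgtscreen

Reassessment of interkingdom horizontal gene transfer (HGT) candidates in
plant genomes from taxonomically annotated gene trees.

## The problem

Hundreds of plant nuclear genes have been reported as interkingdom HGT —
acquisitions from bacteria, fungi, metazoans or viruses. Most of these
claims rest on single-gene phylogenies, which are highly sensitive to
taxon sampling: as databases grow, homologs appear in lineages where none
were known, and a topology that once looked like a transfer can turn into
ordinary vertical inheritance with gene loss. `hgtscreen` implements the
curation pipeline such reassessments use, for researchers who want to
re-examine published candidates (or screen new ones) reproducibly rather
than by eye:

1. **Homolog filtering** — parse 13-column BLAST/DIAMOND tabular hits
   (`qseqid … bitscore staxids`) and retain homologs with pairwise
   identity > 30%, query coverage > 60% and e-value < 1e-5 (strict
   inequalities, configurable).
2. **Taxonomy** — map NCBI-style lineages onto a fixed 12-label
   supergroup scheme (Viridiplantae, Fungi, Metazoa, Other_Opisthokonta,
   Amoebozoa, Excavata, SAR, Other_Eukaryota, Cyanobacteria,
   Other_Bacteria, Archaea, Viruses), with priority rules so that e.g.
   cyanobacteria never fall into the generic bacteria bin.
3. **Tree interrogation** — all topology semantics are unrooted and
   bipartition-based: a leaf set is a clade iff it is one side of an
   edge-induced split. Poorly supported edges (SH-aLRT < 0.8 by default)
   are contracted into polytomies before interpretation.
4. **Classification** — each candidate receives exactly one of six
   verdicts, with an evidence trail of fired rules and measured
   quantities: `HGT`, `HGT_recipient_shifted`, `NoHGT`, `Inconclusive`,
   `Putative_EGT`, `Potential_Contamination`.
5. **Contamination rule** — candidates without eukaryotic homologs are
   checked against their genomic context: donor-kingdom flanking genes on
   a short contig indicate assembly contamination rather than transfer.
6. **Cohort tallies** — per-category counts, half-up-rounded percentages,
   the combined HGT-consistent total, and donor breakdowns with a
   prokaryote rollup.

A synthetic-data module generates trees, hit tables and context records
realising each verdict pattern with known ground truth, so the entire
pipeline is testable without any downloads.

## The classifier in brief

For a candidate with query leaf $q$, annotated unrooted gene tree $T$ and
reported recipient lineage $r$ / donor supergroup $d$, after collapsing
edges with support below $s_{\min}$:

- let $C$ = the largest all-ingroup bipartition side containing $q$;
- let $N$ = the supergroup census of the leaves surrounding $C$ (the
  complement of its defining split);
- let $E$ = the census of non-ingroup eukaryotic supergroups, excluding
  the reported donor.

Rules fire in a refute-before-confirm order: degenerate evidence (no tree
or < 4 homologs) goes to the contamination rule or `Inconclusive`; a
patchy ingroup (> 1 maximal plant clade, or ≥ 2 polyphyletic eukaryotic
kingdoms) is `Inconclusive`; $E \neq \emptyset$ with a monophyletic
eukaryote cluster is `NoHGT`; an exclusively cyanobacterial neighbourhood
is `Putative_EGT`; a donor-dominated neighbourhood is `HGT` when every
leaf of $C$ carries the recipient marker and `HGT_recipient_shifted`
otherwise; anything else is `Inconclusive`.

## Worked example

```r
library(hgtscreen)

coh      <- generate_cohort(25, seed = 11)   # 25 cases x 7 scenarios
verdicts <- classify_cohort(coh$cases)
tab      <- tabulate_verdicts(verdicts, coh$cases)
writeLines(report_text(tab))
```

```
Of the 175 candidates analyzed:
  HGT                         25  (14.29%)
  HGT_recipient_shifted       25  (14.29%)
  NoHGT                       25  (14.29%)
  Inconclusive                50  (28.57%)
  Putative_EGT                25  (14.29%)
  Potential_Contamination     25  (14.29%)
Consistent with interkingdom HGT (HGT + recipient-shifted): 50 (28.6%)
Reported donors:
  Cyanobacteria               25
  Other_Bacteria             150
```

Two scenarios (`patchy` and `no_homologs`) are both constructed to be
uninterpretable, hence 50 `Inconclusive`; every other scenario is
recovered exactly, and each verdict carries its evidence trail:

```r
print(verdicts[[1]])
#> C0001 -> HGT
#>   rule2:ingroup_clade_size=4
#>   rule2:extra_eukaryote_kingdoms=0
#>   rule3:patchy=FALSE(n_ingroup_clades=1,polyphyletic=)
#>   rule6:neighbor_donor_fraction=1.000(donor=Other_Bacteria,n=8)
#>   rule6:ingroup_outside_recipient=0
```

Classifying real data follows the same path: `parse_gene_tree()` a
Newick file, `annotate_leaves()` with a lineage map
(`read_lineage_map()`), build a `candidate_case()` and call
`classify_case()`.

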