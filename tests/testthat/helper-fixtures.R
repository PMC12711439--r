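# Fixture builders used across the suite.

# Annotate a tree directly with supergroup labels (and default lineages
# derived from the label), bypassing the lineage-map file path.
annotate_direct <- function(tree, supergroup, lineage = NULL) {
  labs <- tree_leaves(tree)
  stopifnot(all(labs %in% names(supergroup)))
  if (is.null(lineage)) {
    default_lin <- list(
      Viridiplantae = c("Eukaryota", "Viridiplantae", "Streptophyta",
                        "Brassicales"),
      Fungi = c("Eukaryota", "Opisthokonta", "Fungi"),
      Metazoa = c("Eukaryota", "Opisthokonta", "Metazoa"),
      Other_Opisthokonta = c("Eukaryota", "Opisthokonta"),
      Amoebozoa = c("Eukaryota", "Amoebozoa"),
      Excavata = c("Eukaryota", "Excavata"),
      SAR = c("Eukaryota", "Sar"),
      Other_Eukaryota = c("Eukaryota"),
      Cyanobacteria = c("Bacteria", "Cyanobacteriota"),
      Other_Bacteria = c("Bacteria", "Pseudomonadota"),
      Archaea = c("Archaea"),
      Viruses = c("Viruses")
    )
    lineage <- lapply(labs, function(l) default_lin[[supergroup[[l]]]])
    names(lineage) <- labs
  }
  tree$supergroup <- supergroup[labs]
  tree$lineage <- lineage[labs]
  tree
}

# Annotated fixture tree from a newick string and label->supergroup map;
# per-leaf lineages can be overridden (named list).
fixture_tree <- function(newick, supergroup, lineage = NULL) {
  tr <- parse_gene_tree(text = newick)
  annotate_direct(tr, supergroup, lineage)
}

# One well-formed 13-column hit row as a tab-separated line.
hit_line <- function(qseqid = "Q1", sseqid = "S1", pident = 55.5,
                     length = 80, mismatch = 3, gapopen = 1,
                     qstart = 1, qend = 80, sstart = 5, send = 84,
                     evalue = 1e-30, bitscore = 200.1, staxids = "562") {
  paste(qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
        sstart, send, format(evalue), bitscore, staxids, sep = "\t")
}

brassicales_lineage <- c("Eukaryota", "Viridiplantae", "Streptophyta",
                         "Brassicales")
chlorophyta_lineage <- c("Eukaryota", "Viridiplantae", "Chlorophyta")
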