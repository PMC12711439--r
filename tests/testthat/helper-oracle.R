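# Independent brute-force oracle for unrooted-tree bipartition queries.
# Works directly on the phylo edge matrix as a graph: deleting one edge
# splits the tree into two components; the tip labels of one component
# are one side of the bipartition. Deliberately shares no code with the
# package's prop.part-based implementation.

oracle_sides <- function(phy) {
  ntip <- length(phy$tip.label)
  edges <- phy$edge
  nvert <- max(edges)
  sides <- list()
  for (drop in seq_len(nrow(edges))) {
    adj <- vector("list", nvert)
    for (i in seq_len(nrow(edges))) {
      if (i == drop) next
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    start <- edges[drop, 2]
    seen <- logical(nvert)
    seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    tips <- which(seen[seq_len(ntip)])
    sides[[length(sides) + 1L]] <- sort(phy$tip.label[tips])
  }
  unique(sides)
}

oracle_monophyletic <- function(phy, leaves) {
  labs <- phy$tip.label
  leaves <- unique(leaves)
  if (length(leaves) <= 1L || length(leaves) >= length(labs)) return(TRUE)
  key <- sort(leaves)
  comp <- sort(setdiff(labs, leaves))
  for (s in oracle_sides(phy))
    if (identical(s, key) || identical(s, comp)) return(TRUE)
  FALSE
}

oracle_max_ingroup <- function(phy, supergroup, query, ingroup) {
  labs <- phy$tip.label
  ing <- labs[supergroup[labs] == ingroup]
  if (length(ing) == length(labs)) return(sort(labs))
  best <- query
  for (s in oracle_sides(phy)) {
    for (side in list(s, sort(setdiff(labs, s)))) {
      if (query %in% side && all(supergroup[side] == ingroup) &&
          length(side) > length(best))
        best <- side
    }
  }
  sort(best)
}

# random unrooted tree with supports and random supergroup annotation
random_annotated_tree <- function(n_tips, groups = c("Viridiplantae",
                                                     "Other_Bacteria",
                                                     "Fungi")) {
  phy <- ape::rtree(n_tips, rooted = FALSE,
                    tip.label = paste0("t", seq_len(n_tips)))
  sup <- round(runif(phy$Nnode, 0, 1), 3)
  phy$node.label <- as.character(sup)
  tr <- parse_gene_tree(text = ape::write.tree(phy))
  sg <- sample(groups, n_tips, replace = TRUE)
  names(sg) <- tr$phylo$tip.label
  annotate_direct(tr, sg)
}
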