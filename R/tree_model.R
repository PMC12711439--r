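#' Annotated unrooted gene tree
#'
#' Internal constructor. An `annotated_tree` wraps an `ape::phylo` topology
#' (treated as unrooted throughout; the stored "root" is only a drawing
#' artefact) together with per-internal-node branch supports on the 0-1
#' scale and, after [annotate_leaves()], per-leaf supergroup labels and
#' lineages.
#'
#' @param phylo An `ape::phylo` object.
#' @param support Numeric vector, one entry per internal node (`NA` =
#'   support absent).
#' @param supergroup Named character vector keyed by tip label, or `NULL`.
#' @param lineage Named list of lineages keyed by tip label, or `NULL`.
#' @return An object of class `annotated_tree`.
#' @keywords internal
new_annotated_tree <- function(phylo, support = NULL, supergroup = NULL,
                               lineage = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (is.null(support)) support <- rep(NA_real_, phylo$Nnode)
  stopifnot(length(support) == phylo$Nnode)
  structure(list(phylo = phylo, support = support,
                 supergroup = supergroup, lineage = lineage),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  cat("Annotated unrooted gene tree:", n, "leaves,",
      x$phylo$Nnode, "internal nodes\n")
  if (!is.null(x$supergroup)) {
    cat("Leaf supergroup census:\n")
    print(table(x$supergroup))
  } else {
    cat("Leaves not yet annotated\n")
  }
  invisible(x)
}

#' Number of leaves
#' @param tree An `annotated_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) length(tree$phylo$tip.label)

#' Leaf labels
#' @param tree An `annotated_tree`.
#' @return Character vector of tip labels.
#' @export
tree_leaves <- function(tree) tree$phylo$tip.label

#' Is the tree too small for topology queries?
#'
#' Unrooted trees with fewer than four leaves carry no non-trivial
#' bipartition, so topology-based classification is impossible.
#'
#' @param tree An `annotated_tree`.
#' @return Logical.
#' @export
is_degenerate <- function(tree) n_leaves(tree) < 4L

#' Parse a Newick gene tree
#'
#' Reads a Newick string (or file) with `ape`. Numeric internal-node labels
#' are interpreted as branch supports, as written by maximum-likelihood
#' programs reporting SH-aLRT values; supports on a 0-100 scale are
#' normalised to 0-1 (any finite support above 1 triggers the rescaling of
#' all supports). Non-numeric or missing labels yield `NA` supports, which
#' downstream collapsing treats as trusted by default.
#'
#' @param text Newick string.
#' @param file Path to a Newick file (used when `text` is `NULL`).
#' @return An `annotated_tree` (leaves not yet annotated).
#' @export
parse_gene_tree <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text)
         else ape::read.tree(file = file)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree, found ", length(phy))
    phy <- phy[[1L]]
  }
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (length(phy$tip.label) > 2L && ape::is.rooted(phy))
    phy <- ape::unroot(phy)
  sup <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    if (any(is.finite(sup) & (sup < 0)))
      stop("negative branch support in input tree")
    if (any(is.finite(sup) & sup > 1)) {
      if (any(is.finite(sup) & sup > 100))
        stop("branch support above 100 in input tree")
      sup <- sup / 100
    }
  }
  phy <- ape::reorder.phylo(phy, "cladewise")
  new_annotated_tree(phy, support = sup)
}

#' Serialise a gene tree to Newick
#'
#' Supports are written back as internal node labels on the 0-1 scale.
#'
#' @param tree An `annotated_tree`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Digits for supports.
#' @return Newick string (invisibly when writing to a file).
#' @export
write_gene_tree <- function(tree, file = NULL, digits = 4) {
  phy <- tree$phylo
  lab <- ifelse(is.na(tree$support), "",
                formatC(tree$support, digits = digits, format = "g"))
  phy$node.label <- lab
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Write an annotated tree in Nexus format with supergroup comments
#'
#' Each leaf carries its supergroup as a NHX-style comment
#' (`[&supergroup=...]`) so the annotation survives inspection in standard
#' tree viewers.
#'
#' @param tree An annotated `annotated_tree`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_nexus_annotated <- function(tree, file) {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  phy <- tree$phylo
  labs <- phy$tip.label
  phy$tip.label <- paste0(labs, "[&supergroup=", tree$supergroup[labs], "]")
  lab <- ifelse(is.na(tree$support), "",
                formatC(tree$support, digits = 4, format = "g"))
  phy$node.label <- lab
  lines <- c("#NEXUS", "BEGIN TREES;",
             paste0("  TREE gene_tree = [&U] ", ape::write.tree(phy)),
             "END;")
  writeLines(lines, file)
  invisible(file)
}

#' Annotate leaves with supergroups and lineages
#'
#' Looks every leaf label up in the lineage map, extracting an accession
#' from the label first (by default the token before the first space or
#' `"|"`), and assigns a supergroup through the scheme. In strict mode an
#' unresolvable leaf is an error listing all offending labels; otherwise
#' such leaves are annotated `"Unclassified"` and surfaced by the
#' classifier's evidence trail.
#'
#' @param tree An `annotated_tree`.
#' @param lineage_map Named list from [read_lineage_map()].
#' @param scheme A `supergroup_scheme`.
#' @param strict Logical; error on unresolvable leaves (default `TRUE`).
#' @param accession_pattern Regular expression whose first capture group
#'   extracts the accession from a leaf label.
#' @return The tree with `supergroup` and `lineage` filled in.
#' @export
annotate_leaves <- function(tree, lineage_map,
                            scheme = default_supergroup_scheme(),
                            strict = TRUE,
                            accession_pattern = "^([^ |]+)") {
  labs <- tree_leaves(tree)
  mm <- regmatches(labs, regexec(accession_pattern, labs, perl = TRUE))
  acc <- vapply(seq_along(labs), function(i) {
    r <- mm[[i]]
    if (length(r) >= 2L) r[[2L]] else if (length(r)) r[[1L]] else labs[[i]]
  }, character(1))
  # direct label match wins over extracted accession
  key <- ifelse(labs %in% names(lineage_map), labs, acc)
  unresolved <- labs[!key %in% names(lineage_map)]
  if (length(unresolved) && strict)
    stop("leaves not resolvable in lineage map: ",
         paste(unresolved, collapse = ", "))
  sg <- rep("Unclassified", length(labs))
  lin <- vector("list", length(labs))
  ok <- key %in% names(lineage_map)
  lin[ok] <- lineage_map[key[ok]]
  sg[ok] <- vapply(lin[ok], assign_supergroup, character(1),
                   scheme = scheme, on_unmatched = "na")
  sg[is.na(sg)] <- "Unclassified"
  names(sg) <- labs
  names(lin) <- labs
  tree$supergroup <- sg
  tree$lineage <- lin
  tree
}

# clade tip sets, one per internal node, node order ntip+1, ntip+2, ...
.node_clades <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  lapply(pp, function(i) labs[i])
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One leaf-label set per internal edge; the complement is implied. Pendant
#' edges (singleton splits) are trivial and not listed. Multifurcations are
#' first class: splits are taken over edges only, so the children of a
#' polytomy are not assumed resolved.
#'
#' @param tree An `annotated_tree`.
#' @return List of character vectors, each one side of a bipartition.
#' @export
tree_bipartitions <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (ntip < 4L) return(list())
  clades <- .node_clades(phy)
  # first entry is the stored root (all tips): its "edge" does not exist
  clades[-1L]
}

# canonical key for a leaf set
.set_key <- function(x) paste(sort(x), collapse = "\r")

#' Is a leaf set monophyletic in the unrooted tree?
#'
#' A leaf set is monophyletic exactly when it is one side of an
#' edge-induced bipartition. Singletons and the full leaf set are trivially
#' monophyletic.
#'
#' @param tree An `annotated_tree`.
#' @param leaves Character vector of leaf labels (non-empty, all present in
#'   the tree).
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaves) {
  labs <- tree_leaves(tree)
  leaves <- unique(leaves)
  if (!length(leaves)) stop("empty leaf set")
  unknown <- setdiff(leaves, labs)
  if (length(unknown))
    stop("leaves not in tree: ", paste(unknown, collapse = ", "))
  k <- length(leaves)
  n <- length(labs)
  # trivial sides: singletons, the full set, and complements of singletons
  # (every pendant edge induces the latter two)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  if (n < 4L) return(TRUE)  # 2- and 3-leaf trees: every split trivial
  target <- .set_key(leaves)
  target_c <- .set_key(setdiff(labs, leaves))
  for (side in tree_bipartitions(tree)) {
    key <- .set_key(side)
    if (key == target || key == target_c) return(TRUE)
  }
  FALSE
}

#' Largest all-ingroup clade around a query leaf
#'
#' Returns the largest leaf set that contains the query, is one side of a
#' bipartition (or the full leaf set when every leaf is ingroup), and
#' contains only ingroup leaves. Falls back to the singleton query when no
#' larger all-ingroup side exists. Bipartition sides containing a common
#' leaf are nested, so the maximum is unique.
#'
#' @param tree An annotated `annotated_tree`.
#' @param query_leaf Leaf label of the candidate; must be ingroup.
#' @param ingroup Ingroup supergroup label.
#' @return Character vector of leaf labels.
#' @export
maximal_ingroup_clade <- function(tree, query_leaf,
                                  ingroup = "Viridiplantae") {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  labs <- tree_leaves(tree)
  if (!query_leaf %in% labs) stop("query leaf not in tree: ", query_leaf)
  sg <- tree$supergroup
  if (sg[[query_leaf]] != ingroup)
    stop("query leaf is not ingroup: ", query_leaf, " (",
         sg[[query_leaf]], ")")
  ing <- labs[sg[labs] == ingroup]
  if (length(ing) == length(labs)) return(labs)
  best <- query_leaf
  # every edge induces two sides; pendant edges contribute the
  # complement-of-a-leaf sides alongside the internal splits
  sides <- c(tree_bipartitions(tree),
             lapply(labs, function(l) setdiff(labs, l)))
  for (side in sides) {
    for (s in list(side, setdiff(labs, side))) {
      if (query_leaf %in% s && length(s) > length(best) &&
          length(s) < length(labs) && all(sg[s] == ingroup))
        best <- s
    }
  }
  best
}

#' Supergroup census of the neighbourhood surrounding a clade
#'
#' For a clade that is one side of a bipartition, returns the supergroup
#' counts of the leaves on the other side of its defining edge. In an
#' unrooted tree the subtrees attached at the node adjacent to that edge
#' jointly cover the whole complement, so this is the census of everything
#' "surrounding" the clade. The full leaf set has an empty neighbourhood.
#'
#' @param tree An annotated `annotated_tree`.
#' @param clade Character vector of leaf labels forming a bipartition side.
#' @return Named integer vector (a supergroup count table, possibly empty).
#' @export
neighbor_supergroups <- function(tree, clade) {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  labs <- tree_leaves(tree)
  clade <- unique(clade)
  unknown <- setdiff(clade, labs)
  if (length(unknown))
    stop("leaves not in tree: ", paste(unknown, collapse = ", "))
  if (length(clade) == length(labs)) return(integer(0))
  if (!is_monophyletic(tree, clade))
    stop("clade is not a bipartition side of the tree")
  comp <- setdiff(labs, clade)
  tab <- table(tree$supergroup[comp])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Contract poorly supported internal edges into polytomies
#'
#' Every internal edge whose support falls strictly below `min_support` is
#' contracted, turning its endpoints into a single polytomy. The leaf set
#' is unchanged and no new bipartition can appear. Edges without a recorded
#' support are given `missing_support` (default 1, i.e. trusted).
#'
#' @param tree An `annotated_tree`.
#' @param min_support Threshold on the 0-1 scale; 0 is the identity.
#' @param missing_support Support value substituted for `NA`.
#' @return A new `annotated_tree` (annotations carried over).
#' @export
collapse_low_support <- function(tree, min_support = 0.8,
                                 missing_support = 1) {
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      is.na(min_support) || min_support < 0 || min_support > 1)
    stop("min_support must be a single value in [0, 1]")
  phy <- ape::reorder.phylo(tree$phylo, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  sup <- tree$support
  filled <- ifelse(is.na(sup), missing_support, sup)
  # node numbers ntip+1 ... ntip+nnode; entry 1 is the stored root whose
  # "edge" does not exist in the unrooted tree and is never contracted
  contract <- c(FALSE, filled[-1L] < min_support)
  if (!any(contract)) return(tree)
  root <- ntip + 1L
  remap <- seq_len(ntip + nnode)
  # cladewise order guarantees parents are seen before children
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    if (ch > ntip && contract[ch - ntip]) remap[ch] <- remap[p]
  }
  child <- phy$edge[, 2L]
  contracted_child <- logical(nrow(phy$edge))
  contracted_child[child > ntip] <- contract[child[child > ntip] - ntip]
  keep_edge <- !contracted_child
  new_edge <- cbind(remap[phy$edge[keep_edge, 1L]], phy$edge[keep_edge, 2L])
  kept_nodes <- sort(unique(new_edge[new_edge > ntip]))
  kept_nodes <- union(root, kept_nodes)
  node_id <- integer(ntip + nnode)
  node_id[seq_len(ntip)] <- seq_len(ntip)
  node_id[kept_nodes] <- ntip + seq_along(kept_nodes)
  edge <- cbind(node_id[new_edge[, 1L]], node_id[new_edge[, 2L]])
  storage.mode(edge) <- "integer"
  out <- list(edge = edge, Nnode = length(kept_nodes),
              tip.label = phy$tip.label)
  if (!is.null(phy$edge.length))
    out$edge.length <- phy$edge.length[keep_edge]
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  new_sup <- sup[kept_nodes - ntip]
  new_annotated_tree(out, support = new_sup,
                     supergroup = tree$supergroup, lineage = tree$lineage)
}

#' Supergroup census over all leaves
#'
#' @param tree An annotated `annotated_tree`.
#' @return Named integer vector of supergroup counts.
#' @export
supergroup_census <- function(tree) {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  tab <- table(tree$supergroup)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
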