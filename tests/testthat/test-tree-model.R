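test_that("Newick parsing keeps topology and normalises supports", {
  tr <- parse_gene_tree("(A,B,(C,D)0.99);")
  expect_identical(n_leaves(tr), 4L)
  expect_length(tree_bipartitions(tr), 1L)
  expect_equal(sort(tr$support), 0.99)
  # percentage-scale supports are rescaled to 0-1
  tr2 <- parse_gene_tree("(A,B,(C,D)99);")
  expect_equal(sort(tr2$support), 0.99)
  # two-leaf trees are flagged degenerate
  expect_true(is_degenerate(parse_gene_tree("(A,B);")))
  expect_false(is_degenerate(parse_gene_tree("(A,B,(C,D));")))
  expect_error(parse_gene_tree("(A,B,(A,D));"), "duplicate")
})

test_that("parse -> serialise -> parse yields an isomorphic tree", {
  set.seed(5)
  for (rep in 1:20) {
    tr <- random_annotated_tree(sample(4:10, 1))
    rt <- parse_gene_tree(text = write_gene_tree(tr))
    key <- function(x) sort(vapply(tree_bipartitions(x), function(s)
      paste(sort(s), collapse = "|"), character(1)))
    expect_identical(key(rt), key(tr))
    expect_setequal(tree_leaves(rt), tree_leaves(tr))
  }
})

test_that("leaves are annotated through the lineage map", {
  lmap <- list(AEE29437.1 = brassicales_lineage)
  tr <- parse_gene_tree("(AEE29437.1,(X1,X2),X3);")
  # strict mode lists unresolved leaves
  err <- tryCatch(annotate_leaves(tr, lmap), error = conditionMessage)
  expect_match(err, "X1")
  expect_match(err, "X3")
  # lenient mode labels them Unclassified
  ann <- annotate_leaves(tr, lmap, strict = FALSE)
  expect_identical(unname(ann$supergroup["AEE29437.1"]), "Viridiplantae")
  expect_identical(unname(ann$supergroup["X1"]), "Unclassified")
  # accession extraction: token before first space or "|"
  lmap2 <- list(ACC9 = c("Bacteria", "Vibrionales"))
  tr2 <- parse_gene_tree("(ACC9|extra,(A,B),C);")
  ann2 <- annotate_leaves(tr2, c(lmap2, list(A = brassicales_lineage,
                                             B = brassicales_lineage,
                                             C = brassicales_lineage)))
  expect_identical(unname(ann2$supergroup["ACC9|extra"]), "Other_Bacteria")
  # mixed 6-leaf census
  lmap3 <- c(setNames(replicate(3, brassicales_lineage, simplify = FALSE),
                      c("P1", "P2", "P3")),
             setNames(replicate(3, c("Bacteria", "Pseudomonadota"),
                                simplify = FALSE),
                      c("B1", "B2", "B3")))
  tr3 <- annotate_leaves(parse_gene_tree("((P1,P2),P3,(B1,(B2,B3)));"),
                         lmap3)
  expect_identical(supergroup_census(tr3),
                   c(Other_Bacteria = 3L, Viridiplantae = 3L))
})

test_that("monophyly matches direct bipartition reasoning on a 5-leaf tree", {
  tr <- parse_gene_tree("((A,B),(C,D),E);")
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D", "E")))
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D", "E")))  # complement side
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_false(is_monophyletic(tr, c("A", "B", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "not in tree")
  expect_error(is_monophyletic(tr, character(0)), "empty")
})

test_that("maximal ingroup clade is found around the query", {
  sg <- c(P1 = "Viridiplantae", P2 = "Viridiplantae",
          B1 = "Other_Bacteria", B2 = "Other_Bacteria",
          B3 = "Other_Bacteria")
  tr <- fixture_tree("((P1,P2),(B1,B2),B3);", sg)
  expect_setequal(maximal_ingroup_clade(tr, "P1"), c("P1", "P2"))
  # query is the only plant among bacteria
  sg2 <- c(P1 = "Viridiplantae", B1 = "Other_Bacteria",
           B2 = "Other_Bacteria", B3 = "Other_Bacteria")
  tr2 <- fixture_tree("((P1,B1),(B2,B3));", sg2)
  expect_identical(maximal_ingroup_clade(tr2, "P1"), "P1")
  # all leaves ingroup -> full leaf set
  sg3 <- setNames(rep("Viridiplantae", 4), c("P1", "P2", "P3", "P4"))
  tr3 <- fixture_tree("((P1,P2),(P3,P4));", sg3)
  expect_setequal(maximal_ingroup_clade(tr3, "P1"),
                  c("P1", "P2", "P3", "P4"))
  expect_error(maximal_ingroup_clade(tr, "B1"), "not ingroup")
})

test_that("the neighbourhood census covers the clade's surroundings", {
  sg <- c(P1 = "Viridiplantae", P2 = "Viridiplantae",
          F1 = "Fungi", F2 = "Fungi", F3 = "Fungi")
  tr <- fixture_tree("((P1,P2),(F1,F2),F3);", sg)
  expect_identical(neighbor_supergroups(tr, c("P1", "P2")), c(Fungi = 3L))
  # cyanobacterial and proteobacterial neighbours both counted
  sg2 <- c(P1 = "Viridiplantae", P2 = "Viridiplantae",
           C1 = "Cyanobacteria", C2 = "Cyanobacteria",
           B1 = "Other_Bacteria")
  tr2 <- fixture_tree("((P1,P2),(C1,C2),B1);", sg2)
  expect_identical(neighbor_supergroups(tr2, c("P1", "P2")),
                   c(Cyanobacteria = 2L, Other_Bacteria = 1L))
  # full leaf set has no neighbourhood
  expect_length(neighbor_supergroups(tr, tree_leaves(tr)), 0L)
  expect_error(neighbor_supergroups(tr, c("P1", "F1")),
               "not a bipartition side")
})

test_that("collapsing removes exactly the weak bipartitions", {
  tr <- parse_gene_tree("((A,B)0.5,(C,D)0.95,E);")
  expect_length(tree_bipartitions(tr), 2L)
  col <- collapse_low_support(tr, 0.8)
  expect_length(tree_bipartitions(col), 1L)
  expect_setequal(tree_leaves(col), tree_leaves(tr))
  # threshold 0 is the identity
  expect_identical(ape::write.tree(collapse_low_support(tr, 0)$phylo),
                   ape::write.tree(tr$phylo))
  expect_error(collapse_low_support(tr, 1.0 + 1e-9), "min_support")
  # absent supports are trusted by default
  tr2 <- parse_gene_tree("((A,B),(C,D),E);")
  expect_length(tree_bipartitions(collapse_low_support(tr2, 0.9)), 2L)
})

test_that("collapsing never invents bipartitions and matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  key <- function(x) sort(vapply(tree_bipartitions(x), function(s)
    paste(sort(s), collapse = "|"), character(1)))
  for (rep in 1:25) {
    tr <- random_annotated_tree(sample(5:12, 1))
    thr <- runif(1)
    col <- collapse_low_support(tr, thr)
    expect_setequal(tree_leaves(col), tree_leaves(tr))
    expect_true(all(key(col) %in% key(tr)))
    # independent reference: phangorn prunes edges below the threshold
    phy <- tr$phylo
    phy$node.label <- as.character(ifelse(is.na(tr$support), 1,
                                          tr$support))
    ref <- phangorn::pruneTree(phy, thr)
    ref_at <- parse_gene_tree(text = ape::write.tree(ref))
    expect_identical(key(col), key(ref_at))
  }
})

test_that("bipartition queries agree with the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:150) {
    tr <- random_annotated_tree(sample(4:8, 1))
    phy <- tr$phylo
    labs <- tree_leaves(tr)
    sides <- oracle_sides(phy)
    for (s in sides) expect_true(is_monophyletic(tr, s))
    for (k in 1:4) {
      sub <- sample(labs, sample(2:(length(labs) - 1), 1))
      expect_identical(is_monophyletic(tr, sub),
                       oracle_monophyletic(phy, sub))
    }
    ing <- labs[tr$supergroup[labs] == "Viridiplantae"]
    if (length(ing)) {
      q <- sample(ing, 1)
      expect_identical(sort(maximal_ingroup_clade(tr, q, "Viridiplantae")),
                       oracle_max_ingroup(phy, tr$supergroup, q,
                                          "Viridiplantae"))
    }
  }
})

test_that("annotated trees serialise to Nexus with supergroup comments", {
  sg <- c(P1 = "Viridiplantae", B1 = "Other_Bacteria",
          B2 = "Other_Bacteria", B3 = "Other_Bacteria")
  tr <- fixture_tree("((P1,B1),(B2,B3));", sg)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus_annotated(tr, path)
  txt <- readLines(path)
  expect_identical(txt[1], "#NEXUS")
  expect_true(any(grepl("P1\\[&supergroup=Viridiplantae\\]", txt)))
})
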