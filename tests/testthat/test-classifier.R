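# Schematic fixture trees for the three exemplar patterns plus the other
# categories, built with explicit supergroup maps and lineages.

shifted_case <- function() {
  # recipient-lineage plants plus newly found Chlorophyta homologs form
  # one plant clade embedded among bacterial homologs
  sg <- c(Q1 = "Viridiplantae", Q2 = "Viridiplantae", G1 = "Viridiplantae",
          G2 = "Viridiplantae", B1 = "Other_Bacteria",
          B2 = "Other_Bacteria", B3 = "Other_Bacteria",
          B4 = "Other_Bacteria")
  lin <- c(setNames(replicate(2, brassicales_lineage, simplify = FALSE),
                    c("Q1", "Q2")),
           setNames(replicate(2, chlorophyta_lineage, simplify = FALSE),
                    c("G1", "G2")),
           setNames(replicate(4, c("Bacteria", "Pseudomonadota"),
                              simplify = FALSE),
                    c("B1", "B2", "B3", "B4")))
  tr <- fixture_tree("(((Q1,Q2)0.95,(G1,G2)0.93)0.97,(B1,B2)0.9,(B3,B4)0.9);",
                     sg, lin)
  candidate_case("AEE29437.1-style", "Q1", "Brassicales", "Other_Bacteria",
                 tree = tr, homolog_census = supergroup_census(tr))
}

vertical_loss_case <- function() {
  # plants + two more eukaryotic kingdoms in one cluster sister to bacteria
  sg <- c(Q1 = "Viridiplantae", Q2 = "Viridiplantae",
          O1 = "Other_Opisthokonta", O2 = "Other_Opisthokonta",
          E1 = "Excavata", E2 = "Excavata",
          B1 = "Other_Bacteria", B2 = "Other_Bacteria",
          B3 = "Other_Bacteria")
  tr <- fixture_tree(
    "(((Q1,Q2)0.95,(O1,O2)0.92,(E1,E2)0.94)0.98,B1,(B2,B3)0.9);", sg)
  candidate_case("Tawa019950-style", "Q1", "Brassicales", "Other_Bacteria",
                 tree = tr, homolog_census = supergroup_census(tr))
}

egt_case <- function() {
  sg <- c(Q1 = "Viridiplantae", Q2 = "Viridiplantae",
          C1 = "Cyanobacteria", C2 = "Cyanobacteria", C3 = "Cyanobacteria")
  tr <- fixture_tree("((Q1,Q2)0.96,(C1,C2)0.9,C3);", sg)
  candidate_case("egt-style", "Q1", "Brassicales", "Cyanobacteria",
                 tree = tr, homolog_census = supergroup_census(tr))
}

fungal_hgt_case <- function() {
  # recipient-only plant clade nested within fungi, no other eukaryotes
  sg <- c(Q1 = "Viridiplantae", Q2 = "Viridiplantae",
          F1 = "Fungi", F2 = "Fungi", F3 = "Fungi", F4 = "Fungi")
  tr <- fixture_tree("((Q1,Q2)0.97,(F1,F2)0.9,(F3,F4)0.88);", sg)
  candidate_case("fungal-hgt", "Q1", "Brassicales", "Fungi",
                 tree = tr, homolog_census = supergroup_census(tr))
}

patchy_case <- function() {
  sg <- c(Q1 = "Viridiplantae", Q2 = "Viridiplantae",
          P3 = "Viridiplantae", P4 = "Viridiplantae",
          F1 = "Fungi", F2 = "Fungi", S1 = "SAR", S2 = "SAR")
  tr <- fixture_tree(
    "((Q1,Q2)0.9,(F1,F2)0.9,((P3,P4)0.9,(S1,S2)0.9)0.9);", sg)
  candidate_case("patchy", "Q1", "Brassicales", "Other_Bacteria",
                 tree = tr, homolog_census = supergroup_census(tr))
}

test_that("eukaryote kingdom census ignores ingroup and prokaryotes", {
  sg <- c(P = "Viridiplantae", B = "Other_Bacteria", C = "Cyanobacteria",
          V = "Viruses")
  tr <- fixture_tree("((P,B),(C,V));", sg)
  expect_length(eukaryote_kingdom_census(tr), 0L)
  sg2 <- c(P = "Viridiplantae", F1 = "Fungi", F2 = "Fungi", S1 = "SAR")
  tr2 <- fixture_tree("((P,F1),(F2,S1));", sg2)
  expect_identical(eukaryote_kingdom_census(tr2), c(Fungi = 2L, SAR = 1L))
  sg3 <- setNames(rep("Viridiplantae", 4), c("A", "B", "C", "D"))
  tr3 <- fixture_tree("((A,B),(C,D));", sg3)
  expect_length(eukaryote_kingdom_census(tr3), 0L)
})

test_that("patchiness detects split ingroups and polyphyletic kingdoms", {
  sg <- c(P1 = "Viridiplantae", P2 = "Viridiplantae",
          B1 = "Other_Bacteria", B2 = "Other_Bacteria",
          B3 = "Other_Bacteria")
  tr <- fixture_tree("((P1,P2),(B1,B2),B3);", sg)
  d <- is_patchy(tr)
  expect_false(d$patchy)
  expect_identical(d$n_ingroup_clades, 1L)
  # plants split into two clades separated by fungi
  sg2 <- c(P1 = "Viridiplantae", P2 = "Viridiplantae",
           P3 = "Viridiplantae", P4 = "Viridiplantae",
           F1 = "Fungi", F2 = "Fungi", F3 = "Fungi")
  tr2 <- fixture_tree("((P1,P2),(F1,F2),((P3,P4),F3));", sg2)
  d2 <- is_patchy(tr2)
  expect_true(d2$patchy)
  expect_identical(d2$n_ingroup_clades, 2L)
  # a single plant leaf is one (singleton) clade
  sg3 <- c(P1 = "Viridiplantae", B1 = "Other_Bacteria",
           B2 = "Other_Bacteria", B3 = "Other_Bacteria")
  tr3 <- fixture_tree("((P1,B1),(B2,B3));", sg3)
  d3 <- is_patchy(tr3)
  expect_false(d3$patchy)
  expect_identical(d3$n_ingroup_clades, 1L)
})

test_that("worked-example topologies receive the documented verdicts", {
  expect_identical(classify_case(shifted_case())$category,
                   "HGT_recipient_shifted")
  expect_identical(classify_case(vertical_loss_case())$category, "NoHGT")
  expect_identical(classify_case(egt_case())$category, "Putative_EGT")
  expect_identical(classify_case(fungal_hgt_case())$category, "HGT")
  expect_identical(classify_case(patchy_case())$category, "Inconclusive")
})

test_that("candidates without usable trees fall to context or Inconclusive", {
  # no homologs at all
  v <- classify_case(candidate_case("c1", "q", "Brassicales",
                                    "Other_Bacteria"))
  expect_identical(v$category, "Inconclusive")
  # donor-kingdom flanks on a short contig
  ctx <- genomic_context("c2", 12000,
                         upstream = c("Other_Bacteria", "Other_Bacteria"),
                         downstream = "Other_Bacteria")
  v2 <- classify_case(candidate_case("c2", "q", "Brassicales",
                                     "Other_Bacteria", context = ctx))
  expect_identical(v2$category, "Potential_Contamination")
  # plant flanks: retained, but with no tree the verdict is Inconclusive
  ctx3 <- genomic_context("c3", 12000,
                          upstream = "Viridiplantae",
                          downstream = "Viridiplantae")
  v3 <- classify_case(candidate_case("c3", "q", "Brassicales",
                                     "Other_Bacteria", context = ctx3))
  expect_identical(v3$category, "Inconclusive")
  # a 3-leaf tree is below the homolog minimum
  sg <- c(Q1 = "Viridiplantae", B1 = "Other_Bacteria",
          B2 = "Other_Bacteria")
  tr <- fixture_tree("(Q1,B1,B2);", sg)
  v4 <- classify_case(candidate_case("c4", "Q1", "Brassicales",
                                     "Other_Bacteria", tree = tr,
                                     homolog_census = supergroup_census(tr)))
  expect_identical(v4$category, "Inconclusive")
})

test_that("every verdict has exactly one category and a non-empty trail", {
  set.seed(11)
  coh <- generate_cohort(3, seed = 17)
  verdicts <- classify_cohort(coh$cases)
  for (v in verdicts) {
    expect_length(v$category, 1)
    expect_true(v$category %in% verdict_categories())
    expect_gte(length(v$evidence), 1)
    expect_identical(v$config_fingerprint,
                     config_fingerprint(classifier_config()))
  }
  tab <- verdict_table(verdicts)
  expect_identical(nrow(tab), length(coh$cases))
})

test_that("verdicts are invariant under leaf reordering and rewriting", {
  set.seed(23)
  for (sc in c("true_hgt", "recipient_shifted", "vertical_loss", "egt",
               "patchy")) {
    g <- generate_case(scenario_spec(sc, seed = 31), "RW1")
    base <- classify_case(g$case)
    # rewrite: rotate children by re-reading through ape with rotated text
    phy <- g$case$tree$phylo
    phy2 <- ape::rotateConstr(phy, rev(sort(phy$tip.label)))
    phy2$node.label <- as.character(ifelse(is.na(g$case$tree$support),
                                           "", g$case$tree$support))
    tr2 <- parse_gene_tree(text = ape::write.tree(phy2))
    tr2$supergroup <- g$case$tree$supergroup
    tr2$lineage <- g$case$tree$lineage
    case2 <- candidate_case(g$case$candidate_id, g$case$query_leaf,
                            g$case$reported_recipient,
                            g$case$reported_donor, tree = tr2,
                            homolog_census = g$case$homolog_census)
    expect_identical(classify_case(case2)$category, base$category)
    # identical case classified twice gives an identical verdict
    expect_identical(classify_case(g$case), base)
  }
})

test_that("collapse threshold 0 reproduces the uncollapsed verdict", {
  set.seed(37)
  for (sc in c("true_hgt", "vertical_loss", "egt", "patchy")) {
    g <- generate_case(scenario_spec(sc, seed = 41,
                                     support_range = c(0.3, 1)), "CZ1")
    v0 <- classify_case(g$case, classifier_config(min_support = 0))
    # with threshold 0 no edge is contracted, whatever the supports
    expect_identical(
      ape::write.tree(collapse_low_support(g$case$tree, 0)$phylo),
      ape::write.tree(g$case$tree$phylo))
    expect_true(v0$category %in% verdict_categories())
  }
})

test_that("agreement with a reference screen is computed over calls", {
  verdicts <- c(a = "HGT", b = "HGT_recipient_shifted", c = "Putative_EGT",
                d = "NoHGT", e = "Potential_Contamination",
                f = "Inconclusive")
  ref_same <- c(a = "HGT", b = "HGT", c = "HGT", d = "NoHGT", e = "NoHGT",
                f = "HGT")
  res <- agreement_with_reference(verdicts, ref_same)
  expect_equal(res$percent, 100)
  expect_identical(res$n_compared, 5L)  # Inconclusive excluded
  # 4 of 5 matching
  ref4 <- ref_same
  ref4["d"] <- "HGT"
  expect_equal(agreement_with_reference(verdicts, ref4)$percent, 80)
  # Complex handling: both conventions exposed
  refc <- c(a = "Complex", b = "HGT", c = "HGT", d = "NoHGT", e = "NoHGT")
  expect_identical(
    agreement_with_reference(verdicts, refc, "exclude")$n_compared, 4L)
  res_hgt <- agreement_with_reference(verdicts, refc, "hgt")
  expect_identical(res_hgt$n_compared, 5L)
  expect_equal(res_hgt$percent, 100)
  # all Inconclusive -> undefined, signalled
  expect_warning(
    res0 <- agreement_with_reference(c(x = "Inconclusive"),
                                     c(x = "HGT")),
    "undefined")
  expect_true(is.na(res0$percent))
})
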