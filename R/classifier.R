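VERDICT_CATEGORIES <- c("HGT", "HGT_recipient_shifted", "NoHGT",
                        "Inconclusive", "Putative_EGT",
                        "Potential_Contamination")

#' Verdict categories
#'
#' The six categories a candidate can be assigned: HGT (topology still
#' consistent with interkingdom transfer into the reported recipient),
#' HGT_recipient_shifted (transfer signal intact but new plant homologs
#' push the event deeper into plant history), NoHGT (homologs in other
#' eukaryotic kingdoms make vertical inheritance with gene loss the more
#' parsimonious reading), Inconclusive (patchy or uninformative),
#' Putative_EGT (cyanobacteria-exclusive affinity, i.e. plastid-derived
#' endosymbiotic transfer) and Potential_Contamination (genomic context
#' points to foreign sequence in the assembly).
#'
#' @return Character vector of the six category names.
#' @export
verdict_categories <- function() VERDICT_CATEGORIES

#' Candidate case
#'
#' One HGT candidate under reassessment: its identifier, the leaf label of
#' the query sequence, the recipient lineage and donor supergroup reported
#' by the original study, and the available evidence (annotated gene tree,
#' post-filter homolog census, genomic context).
#'
#' @param candidate_id Unique identifier.
#' @param query_leaf Leaf label of the candidate sequence.
#' @param reported_recipient Clade name of the reported recipient lineage
#'   (e.g. `"Brassicales"`).
#' @param reported_donor Reported donor supergroup label.
#' @param tree An annotated [`annotated_tree`][parse_gene_tree] or `NULL`
#'   when no tree could be built.
#' @param homolog_census Named integer vector of retained homologs per
#'   supergroup, or `NULL`.
#' @param context A [genomic_context()] or `NULL`.
#' @return An object of class `candidate_case`.
#' @export
candidate_case <- function(candidate_id, query_leaf, reported_recipient,
                           reported_donor, tree = NULL,
                           homolog_census = NULL, context = NULL) {
  if (!reported_donor %in% supergroup_labels())
    stop("unknown reported donor label: ", reported_donor)
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "annotated_tree"))
    if (!query_leaf %in% tree_leaves(tree))
      stop("query leaf not in tree: ", query_leaf)
  }
  structure(list(candidate_id = as.character(candidate_id),
                 query_leaf = as.character(query_leaf),
                 reported_recipient = as.character(reported_recipient),
                 reported_donor = as.character(reported_donor),
                 tree = tree, homolog_census = homolog_census,
                 context = context),
            class = "candidate_case")
}

#' Classifier configuration
#'
#' @param ingroup Recipient supergroup (default Viridiplantae).
#' @param min_support Collapse threshold for internal edges, 0-1 scale
#'   (default 0.8 on the SH-aLRT scale; 0 disables collapsing).
#' @param missing_support Support substituted for edges lacking one
#'   (default 1: trusted).
#' @param min_homologs Minimum leaves required to attempt topology
#'   classification (default 4; an unrooted 3-leaf tree carries no
#'   bipartition information).
#' @param donor_fraction Minimum fraction of the ingroup clade's
#'   neighbourhood that must belong to the reported donor supergroup for
#'   the HGT rules (default 1: exclusive donor neighbourhood).
#' @param min_extra_kingdoms Number of additional eukaryotic supergroups,
#'   monophyletic with the ingroup, that triggers the NoHGT verdict
#'   (default 1).
#' @param contamination A [contamination_config()].
#' @param scheme A `supergroup_scheme`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(ingroup = "Viridiplantae",
                              min_support = 0.8,
                              missing_support = 1,
                              min_homologs = 4L,
                              donor_fraction = 1,
                              min_extra_kingdoms = 1L,
                              contamination = contamination_config(),
                              scheme = default_supergroup_scheme()) {
  stopifnot(min_support >= 0, min_support <= 1,
            donor_fraction > 0, donor_fraction <= 1,
            min_homologs >= 1, min_extra_kingdoms >= 1)
  structure(list(ingroup = ingroup, min_support = min_support,
                 missing_support = missing_support,
                 min_homologs = as.integer(min_homologs),
                 donor_fraction = donor_fraction,
                 min_extra_kingdoms = as.integer(min_extra_kingdoms),
                 contamination = contamination, scheme = scheme),
            class = "classifier_config")
}

#' Fingerprint of the thresholds behind a verdict
#'
#' Canonical key=value string of every tunable the classifier consulted,
#' stored in each verdict so that any two verdicts can be checked for
#' having been produced under the same configuration.
#'
#' @param config A [classifier_config()].
#' @return Single character string.
#' @export
config_fingerprint <- function(config) {
  cc <- config$contamination
  paste(
    sprintf("ingroup=%s", config$ingroup),
    sprintf("min_support=%g", config$min_support),
    sprintf("missing_support=%g", config$missing_support),
    sprintf("min_homologs=%d", config$min_homologs),
    sprintf("donor_fraction=%g", config$donor_fraction),
    sprintf("min_extra_kingdoms=%d", config$min_extra_kingdoms),
    sprintf("flank_fraction=%g", cc$flank_fraction),
    sprintf("short_contig_bp=%g", cc$short_contig_bp),
    sprintf("flanks_only=%s", cc$flanks_only),
    sprintf("relaxed_flanks=%s", cc$relaxed_flanks),
    sep = "|")
}

.new_verdict <- function(candidate_id, category, evidence, config) {
  stopifnot(category %in% VERDICT_CATEGORIES, length(evidence) >= 1)
  structure(list(candidate_id = candidate_id, category = category,
                 evidence = evidence,
                 config_fingerprint = config_fingerprint(config)),
            class = "hgt_verdict")
}

#' @export
print.hgt_verdict <- function(x, ...) {
  cat(x$candidate_id, "->", x$category, "\n")
  cat(paste0("  ", x$evidence, collapse = "\n"), "\n")
  invisible(x)
}

#' Census of non-ingroup eukaryotic supergroups on a tree
#'
#' Counts leaves per eukaryotic supergroup other than the ingroup;
#' prokaryotic, viral and unclassified leaves are excluded. The presence
#' of such homologs is what makes an interdomain transfer hard to defend.
#'
#' @param tree An annotated `annotated_tree`.
#' @param ingroup Ingroup supergroup label.
#' @return Named integer vector (possibly empty).
#' @export
eukaryote_kingdom_census <- function(tree, ingroup = "Viridiplantae") {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  sg <- tree$supergroup
  keep <- sg %in% EUKARYOTE_LABELS & sg != ingroup
  tab <- table(sg[keep])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Is the taxonomic distribution on a tree patchy?
#'
#' A distribution is patchy when the ingroup leaves split into more than
#' one maximal all-ingroup clade, or when at least two non-ingroup
#' eukaryotic supergroups are themselves polyphyletic on the tree. Patchy
#' or polyphyletic distributions across kingdoms admit several scenarios
#' and are not interpreted further.
#'
#' @param tree An annotated `annotated_tree` with at least 4 leaves.
#' @param ingroup Ingroup supergroup label.
#' @return List with `patchy` (logical), `n_ingroup_clades` and
#'   `nonmonophyletic_kingdoms` (character vector).
#' @export
is_patchy <- function(tree, ingroup = "Viridiplantae") {
  if (is.null(tree$supergroup)) stop("tree is not annotated")
  if (n_leaves(tree) < 4L)
    stop("tree too small for patchiness assessment (< 4 leaves)")
  labs <- tree_leaves(tree)
  sg <- tree$supergroup
  ing <- labs[sg[labs] == ingroup]
  n_clades <- if (!length(ing)) {
    0L
  } else if (length(ing) == length(labs)) {
    1L
  } else {
    remaining <- ing
    k <- 0L
    while (length(remaining)) {
      cl <- maximal_ingroup_clade(tree, remaining[1L], ingroup)
      remaining <- setdiff(remaining, cl)
      k <- k + 1L
    }
    k
  }
  euk <- eukaryote_kingdom_census(tree, ingroup)
  multi <- names(euk)[euk >= 2L]
  nonmono <- multi[!vapply(multi, function(g)
    is_monophyletic(tree, labs[sg[labs] == g]), logical(1))]
  list(patchy = n_clades > 1L || length(nonmono) >= 2L,
       n_ingroup_clades = n_clades,
       nonmonophyletic_kingdoms = nonmono)
}

#' Classify one candidate
#'
#' Applies the category rules in a fixed precedence in which checks that
#' can refute an interkingdom transfer fire before checks that would
#' confirm one:
#'
#' 1. No tree, or fewer retained homologs than `min_homologs`: the genomic
#'    context decides between Potential_Contamination and Inconclusive.
#' 2. Contract poorly supported edges; locate the maximal all-ingroup
#'    clade around the query, its surrounding supergroup census, and the
#'    census of non-ingroup eukaryotic kingdoms (the reported donor, when
#'    itself eukaryotic, is not counted as an extra kingdom).
#' 3. Patchy distribution: Inconclusive.
#' 4. Extra eukaryotic kingdoms present and all eukaryotic leaves form one
#'    monophyletic cluster: NoHGT (vertical inheritance with differential
#'    loss is the simpler reading).
#' 5. No extra eukaryotic kingdoms and every prokaryotic leaf surrounding
#'    the ingroup clade is cyanobacterial: Putative_EGT.
#' 6. No extra eukaryotic kingdoms and the neighbourhood is dominated by
#'    the reported donor: HGT when every ingroup leaf of the clade belongs
#'    to the reported recipient lineage, HGT_recipient_shifted when plant
#'    homologs outside that lineage joined the clade.
#' 7. Otherwise Inconclusive.
#'
#' @param case A [candidate_case()].
#' @param config A [classifier_config()].
#' @return An object of class `hgt_verdict` with the category, the ordered
#'   evidence trail of fired rules with measured quantities, and the
#'   configuration fingerprint.
#' @export
classify_case <- function(case, config = classifier_config()) {
  stopifnot(inherits(case, "candidate_case"),
            inherits(config, "classifier_config"))
  ingroup <- config$ingroup
  ev <- character(0)

  n_hom <- if (!is.null(case$tree)) n_leaves(case$tree)
           else if (!is.null(case$homolog_census)) sum(case$homolog_census)
           else 0L
  if (is.null(case$tree) || n_hom < config$min_homologs) {
    ev <- c(ev, sprintf("rule1:degenerate(n_homologs=%d,tree=%s)",
                        n_hom, !is.null(case$tree)))
    if (!is.null(case$context)) {
      a <- assess_contamination(case$context, case$reported_donor,
                                ingroup, config$contamination)
      ev <- c(ev, a$evidence)
      if (isTRUE(a$contamination_fired))
        return(.new_verdict(case$candidate_id, "Potential_Contamination",
                            ev, config))
    } else {
      ev <- c(ev, "rule1:no_context")
    }
    return(.new_verdict(case$candidate_id, "Inconclusive", ev, config))
  }

  tree <- case$tree
  if (is.null(tree$supergroup))
    stop("case ", case$candidate_id, ": tree is not annotated")
  tree <- collapse_low_support(tree, config$min_support,
                               config$missing_support)
  sg <- tree$supergroup
  n_uncl <- sum(sg == "Unclassified")
  if (n_uncl > 0)
    ev <- c(ev, sprintf("rule2:unclassified_leaves=%d", n_uncl))

  clade <- maximal_ingroup_clade(tree, case$query_leaf, ingroup)
  nbr <- neighbor_supergroups(tree, clade)
  euk <- eukaryote_kingdom_census(tree, ingroup)
  extra <- euk[setdiff(names(euk), case$reported_donor)]
  ev <- c(ev, sprintf("rule2:ingroup_clade_size=%d", length(clade)),
          sprintf("rule2:extra_eukaryote_kingdoms=%d", length(extra)))

  patch <- is_patchy(tree, ingroup)
  ev <- c(ev, sprintf("rule3:patchy=%s(n_ingroup_clades=%d,polyphyletic=%s)",
                      patch$patchy, patch$n_ingroup_clades,
                      paste(patch$nonmonophyletic_kingdoms, collapse = "+")))
  if (patch$patchy)
    return(.new_verdict(case$candidate_id, "Inconclusive", ev, config))

  labs <- tree_leaves(tree)
  if (length(extra) >= config$min_extra_kingdoms) {
    euk_leaves <- labs[sg[labs] %in% EUKARYOTE_LABELS]
    euk_mono <- is_monophyletic(tree, euk_leaves)
    ev <- c(ev, sprintf("rule4:eukaryote_cluster_monophyletic=%s", euk_mono))
    if (euk_mono)
      return(.new_verdict(case$candidate_id, "NoHGT", ev, config))
    return(.new_verdict(case$candidate_id, "Inconclusive",
                        c(ev, "rule7:no_rule_fired"), config))
  }

  nbr_labels <- rep(names(nbr), nbr)
  prok_nbr <- nbr_labels[supergroup_domain(nbr_labels) == "prokaryote"]
  if (length(prok_nbr) && all(prok_nbr == "Cyanobacteria") &&
      sum(nbr) == length(prok_nbr)) {
    ev <- c(ev, sprintf("rule5:cyanobacteria_exclusive(n=%d)",
                        length(prok_nbr)))
    return(.new_verdict(case$candidate_id, "Putative_EGT", ev, config))
  }

  donor_frac <- if (sum(nbr) > 0)
    sum(nbr[names(nbr) == case$reported_donor]) / sum(nbr) else 0
  ev <- c(ev, sprintf("rule6:neighbor_donor_fraction=%.3f(donor=%s,n=%d)",
                      donor_frac, case$reported_donor, sum(nbr)))
  if (sum(nbr) > 0 && donor_frac >= config$donor_fraction) {
    lin <- tree$lineage[clade]
    in_recipient <- vapply(lin, function(l)
      !is.null(l) && case$reported_recipient %in% trimws(l), logical(1))
    n_out <- sum(!in_recipient)
    ev <- c(ev, sprintf("rule6:ingroup_outside_recipient=%d", n_out))
    cat_out <- if (n_out == 0L) "HGT" else "HGT_recipient_shifted"
    return(.new_verdict(case$candidate_id, cat_out, ev, config))
  }

  .new_verdict(case$candidate_id, "Inconclusive",
               c(ev, "rule7:no_rule_fired"), config)
}

#' Classify a cohort of candidates
#'
#' @param cases List of [candidate_case()] objects.
#' @param config A [classifier_config()].
#' @return Named list of `hgt_verdict` objects keyed by candidate id.
#' @export
classify_cohort <- function(cases, config = classifier_config()) {
  ids <- vapply(cases, `[[`, character(1), "candidate_id")
  if (anyDuplicated(ids))
    stop("duplicate candidate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(cases, classify_case, config = config)
  names(out) <- ids
  out
}

#' Verdicts as a data frame
#'
#' @param verdicts Named list of `hgt_verdict` objects.
#' @return Data frame with columns `candidate_id`, `category`, `evidence`
#'   (rule trail joined by `" ; "`) and `config_fingerprint`.
#' @export
verdict_table <- function(verdicts) {
  data.frame(
    candidate_id = vapply(verdicts, `[[`, character(1), "candidate_id"),
    category = vapply(verdicts, `[[`, character(1), "category"),
    evidence = vapply(verdicts, function(v)
      paste(v$evidence, collapse = " ; "), character(1)),
    config_fingerprint = vapply(verdicts, `[[`, character(1),
                                "config_fingerprint"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Agreement with an automated reference classification
#'
#' Collapses the six categories onto the coarse HGT-signal / NoHGT axis of
#' automated phylogeny screens (HGT, HGT_recipient_shifted and
#' Putative_EGT count as HGT signal; NoHGT and Potential_Contamination as
#' NoHGT) and computes the percentage of agreement over candidates present
#' in both maps. Inconclusive verdicts are excluded from the denominator.
#' Reference values must be `"HGT"`, `"NoHGT"` or `"Complex"`; how
#' `"Complex"` is handled is explicit because either convention is
#' defensible.
#'
#' @param verdicts Named list of `hgt_verdict` objects (or named character
#'   vector of categories).
#' @param reference Named character vector of reference calls.
#' @param complex_as `"exclude"` (drop Complex reference calls, default)
#'   or `"hgt"` (count them as HGT signal).
#' @return List with `percent` (agreement in percent; `NA` with a warning
#'   when no comparable case remains), `n_compared` and `n_matched`.
#' @export
agreement_with_reference <- function(verdicts, reference,
                                     complex_as = c("exclude", "hgt")) {
  complex_as <- match.arg(complex_as)
  cats <- if (is.character(verdicts)) verdicts
          else vapply(verdicts, `[[`, character(1), "category")
  bad <- setdiff(unique(cats), VERDICT_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(reference), c("HGT", "NoHGT", "Complex"))
  if (length(bad))
    stop("unknown reference call: ", paste(bad, collapse = ", "))
  ids <- intersect(names(cats), names(reference))
  cats <- cats[ids]; ref <- reference[ids]
  signal <- ifelse(cats %in% c("HGT", "HGT_recipient_shifted",
                               "Putative_EGT"), "HGT",
            ifelse(cats %in% c("NoHGT", "Potential_Contamination"),
                   "NoHGT", NA))
  if (complex_as == "hgt") ref[ref == "Complex"] <- "HGT"
  else ref[ref == "Complex"] <- NA
  keep <- !is.na(signal) & !is.na(ref)
  n <- sum(keep)
  if (n == 0L) {
    warning("no comparable non-Inconclusive cases; agreement undefined")
    return(list(percent = NA_real_, n_compared = 0L, n_matched = 0L))
  }
  matched <- sum(signal[keep] == ref[keep])
  list(percent = 100 * matched / n, n_compared = n, n_matched = matched)
}
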