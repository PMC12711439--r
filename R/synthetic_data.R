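SCENARIOS <- c("true_hgt", "recipient_shifted", "vertical_loss", "egt",
               "patchy", "contamination", "no_homologs")

#' Synthetic scenario names
#'
#' The seven generator scenarios and the verdict each one is constructed
#' to receive: `true_hgt -> HGT`, `recipient_shifted ->
#' HGT_recipient_shifted`, `vertical_loss -> NoHGT`, `egt -> Putative_EGT`,
#' `patchy -> Inconclusive`, `contamination -> Potential_Contamination`,
#' `no_homologs -> Inconclusive`.
#'
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() SCENARIOS

#' Expected verdict for a scenario
#'
#' @param scenario Scenario name(s).
#' @return Character vector of verdict categories.
#' @export
scenario_truth <- function(scenario) {
  map <- c(true_hgt = "HGT",
           recipient_shifted = "HGT_recipient_shifted",
           vertical_loss = "NoHGT",
           egt = "Putative_EGT",
           patchy = "Inconclusive",
           contamination = "Potential_Contamination",
           no_homologs = "Inconclusive")
  bad <- setdiff(scenario, names(map))
  if (length(bad)) stop("unknown scenario: ", paste(bad, collapse = ", "))
  unname(map[scenario])
}

# reference lineages for the synthetic vocabulary, keyed by role
.synthetic_lineages <- function(recipient_marker) {
  shifted_clade <- if (identical(recipient_marker, "Chlorophyta"))
    "Brassicales" else "Chlorophyta"
  list(
    recipient = c("Eukaryota", "Viridiplantae", "Streptophyta",
                  recipient_marker),
    shifted = c("Eukaryota", "Viridiplantae", shifted_clade),
    Fungi = c("Eukaryota", "Opisthokonta", "Fungi", "Ascomycota"),
    Metazoa = c("Eukaryota", "Opisthokonta", "Metazoa", "Chordata"),
    Other_Opisthokonta = c("Eukaryota", "Opisthokonta", "Choanoflagellata"),
    Amoebozoa = c("Eukaryota", "Amoebozoa", "Mycetozoa"),
    Excavata = c("Eukaryota", "Excavata", "Discoba"),
    SAR = c("Eukaryota", "Sar", "Alveolata", "Apicomplexa"),
    Other_Eukaryota = c("Eukaryota", "Haptista"),
    Cyanobacteria = c("Bacteria", "Cyanobacteriota", "Nostocales"),
    Other_Bacteria = c("Bacteria", "Pseudomonadota", "Gammaproteobacteria"),
    Archaea = c("Archaea", "Euryarchaeota"),
    Viruses = c("Viruses", "Riboviria")
  )
}

#' Specification of one synthetic candidate
#'
#' Describes a candidate whose evidence is constructed to realise one of
#' the recurring gene-tree patterns: a recipient-only plant clade inside a
#' donor backbone (`true_hgt`); the same with additional plant lineages in
#' the clade (`recipient_shifted`); a monophyletic eukaryote cluster of
#' plants plus at least two other eukaryotic kingdoms sister to
#' prokaryotes (`vertical_loss`); plants surrounded exclusively by
#' cyanobacteria (`egt`); two or more disjoint plant clades interleaved
#' across kingdoms (`patchy`); a lone query with donor-kingdom flanks on a
#' short contig (`contamination`); and a candidate with no detectable
#' homologs at all (`no_homologs`).
#'
#' @param scenario One of [scenario_names()].
#' @param leaves_per_supergroup Named integer vector of leaf counts per
#'   supergroup; scenario-specific defaults are used when `NULL`.
#' @param recipient_marker Clade name of the reported recipient lineage.
#' @param donor Reported donor supergroup; defaults to Cyanobacteria for
#'   `egt` and Other_Bacteria otherwise.
#' @param n_shifted_ingroup For `recipient_shifted`: how many of the
#'   ingroup leaves come from a plant lineage outside the reported
#'   recipient (default half of them, at least 1).
#' @param support_range Range branch supports are drawn from, within
#'   0-1.
#' @param seed Integer seed; a fixed seed makes the case fully
#'   reproducible.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario,
                          leaves_per_supergroup = NULL,
                          recipient_marker = "Brassicales",
                          donor = NULL,
                          n_shifted_ingroup = NULL,
                          support_range = c(0.9, 1),
                          seed = 1L) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (is.null(donor))
    donor <- if (scenario == "egt") "Cyanobacteria" else "Other_Bacteria"
  if (!donor %in% supergroup_labels())
    stop("unknown donor supergroup: ", donor)
  if (scenario == "egt" && donor != "Cyanobacteria")
    stop("egt scenario requires donor Cyanobacteria")
  stopifnot(length(support_range) == 2, all(support_range >= 0),
            all(support_range <= 1), support_range[1] <= support_range[2])
  if (is.null(leaves_per_supergroup)) {
    leaves_per_supergroup <- switch(scenario,
      true_hgt = setNames(c(4L, 8L), c("Viridiplantae", donor)),
      recipient_shifted = setNames(c(6L, 8L), c("Viridiplantae", donor)),
      vertical_loss = c(Viridiplantae = 3L, Fungi = 3L, SAR = 3L,
                        Other_Bacteria = 6L),
      egt = c(Viridiplantae = 3L, Cyanobacteria = 6L),
      patchy = c(Viridiplantae = 4L, Fungi = 3L, SAR = 3L,
                 Other_Bacteria = 4L),
      contamination = ,
      no_homologs = setNames(integer(0), character(0))
    )
  }
  lps <- leaves_per_supergroup
  if (any(lps < 0)) stop("negative leaf count")
  bad <- setdiff(names(lps), supergroup_labels())
  if (length(bad)) stop("unknown supergroup: ", paste(bad, collapse = ", "))
  g <- function(x) if (x %in% names(lps)) lps[[x]] else 0L
  ing <- g("Viridiplantae")
  if (scenario %in% c("true_hgt", "recipient_shifted")) {
    if (ing < 1L || g(donor) < 2L)
      stop(scenario, " needs at least 1 ingroup leaf and 2 donor leaves")
  }
  if (scenario == "recipient_shifted") {
    if (is.null(n_shifted_ingroup))
      n_shifted_ingroup <- max(1L, ing %/% 2L)
    if (n_shifted_ingroup < 1L || n_shifted_ingroup >= ing)
      stop("recipient_shifted needs 1 <= n_shifted_ingroup < ingroup leaves")
  } else {
    n_shifted_ingroup <- 0L
  }
  if (scenario == "vertical_loss") {
    euk_extra <- names(lps)[names(lps) %in% EUKARYOTE_LABELS &
                              names(lps) != "Viridiplantae" & lps >= 1L]
    if (ing < 1L || length(euk_extra) < 2L || sum(lps) - ing -
        sum(lps[euk_extra]) < 2L)
      stop("vertical_loss needs ingroup leaves, >= 2 other eukaryotic ",
           "kingdoms and >= 2 prokaryote leaves")
  }
  if (scenario == "egt" && (ing < 1L || g("Cyanobacteria") < 2L))
    stop("egt needs at least 1 ingroup and 2 cyanobacterial leaves")
  if (scenario == "patchy" && (ing < 2L ||
      sum(names(lps) %in% EUKARYOTE_LABELS & names(lps) !=
            "Viridiplantae" & lps >= 1L) < 2L))
    stop("patchy needs >= 2 ingroup leaves and >= 2 other eukaryotic kingdoms")
  structure(list(scenario = scenario,
                 leaves_per_supergroup = lps,
                 recipient_marker = recipient_marker,
                 donor = donor,
                 n_shifted_ingroup = as.integer(n_shifted_ingroup),
                 support_range = support_range,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# support draw, formatted as a Newick internal label
.draw_support <- function(rng) sprintf("%.3f", stats::runif(1, rng[1], rng[2]))

# caterpillar subtree over labels, every internal node supported
.chain_nw <- function(labels, rng) {
  if (!length(labels)) stop("empty label set for subtree")
  out <- labels[length(labels)]
  for (lab in rev(labels[-length(labels)]))
    out <- sprintf("(%s,%s)%s", lab, out, .draw_support(rng))
  out
}

# leaf-label role prefix for a supergroup (alphanumeric only)
.role <- function(group) gsub("[^A-Za-z]", "", group)

#' Generate one synthetic candidate case
#'
#' Builds the Newick tree (when the scenario has one), the lineage map,
#' the metadata row and the optional context record for the scenario, and
#' assembles the annotated [candidate_case()]. Topologies are constructed
#' by explicit grafting so that the intended pattern is guaranteed, not
#' merely probable.
#'
#' @param spec A [scenario_spec()].
#' @param candidate_id Identifier (also used as the leaf-label prefix).
#' @param scheme Supergroup scheme used for annotation.
#' @return List with elements `case` (a [candidate_case()]), `truth` (the
#'   category the construction guarantees), `newick` (string or `NA`),
#'   `lineage_map`, `metadata` (one-row data frame) and `context`.
#' @export
generate_case <- function(spec, candidate_id = "CAND1",
                          scheme = default_supergroup_scheme()) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  rng <- spec$support_range
  lps <- spec$leaves_per_supergroup
  lmap <- list()
  lin <- .synthetic_lineages(spec$recipient_marker)
  mk <- function(role, lineage_key, n) {
    if (n == 0L) return(character(0))
    labs <- paste0(candidate_id, role, seq_len(n))
    for (l in labs) lmap[[l]] <<- lin[[lineage_key]]
    labs
  }
  donor <- spec$donor
  newick <- NA_character_
  context <- NULL
  query <- paste0(candidate_id, "Q1")

  if (spec$scenario %in% c("true_hgt", "recipient_shifted")) {
    n_ing <- lps[["Viridiplantae"]]
    n_rec <- n_ing - spec$n_shifted_ingroup
    rec <- mk("Q", "recipient", n_rec)
    shf <- mk("S", "shifted", spec$n_shifted_ingroup)
    don <- mk("D", donor, lps[[donor]])
    plant_clade <- if (length(shf))
      sprintf("(%s,%s)%s", .chain_nw(rec, rng), .chain_nw(shf, rng),
              .draw_support(rng))
    else .chain_nw(rec, rng)
    if (length(rec) == 1L && !length(shf)) plant_clade <- rec
    newick <- sprintf("(%s,%s,%s);", plant_clade, don[1],
                      .chain_nw(don[-1], rng))
  } else if (spec$scenario == "vertical_loss") {
    rec <- mk("Q", "recipient", lps[["Viridiplantae"]])
    extras <- names(lps)[names(lps) %in% EUKARYOTE_LABELS &
                           names(lps) != "Viridiplantae" & lps >= 1L]
    euk_parts <- c(.chain_nw(rec, rng),
                   vapply(extras, function(g)
                     .chain_nw(mk(.role(g), g, lps[[g]]), rng),
                     character(1)))
    euk <- sprintf("(%s)%s", paste(euk_parts, collapse = ","),
                   .draw_support(rng))
    prok <- mk("B", donor, lps[[donor]])
    newick <- sprintf("(%s,%s,%s);", euk, prok[1], .chain_nw(prok[-1], rng))
  } else if (spec$scenario == "egt") {
    rec <- mk("Q", "recipient", lps[["Viridiplantae"]])
    cya <- mk("C", "Cyanobacteria", lps[["Cyanobacteria"]])
    newick <- sprintf("(%s,%s,%s);", .chain_nw(rec, rng), cya[1],
                      .chain_nw(cya[-1], rng))
  } else if (spec$scenario == "patchy") {
    n_ing <- lps[["Viridiplantae"]]
    n1 <- max(1L, n_ing %/% 2L)
    rec <- mk("Q", "recipient", n1)
    rec2 <- mk("P", "recipient", n_ing - n1)
    extras <- names(lps)[names(lps) %in% EUKARYOTE_LABELS &
                           names(lps) != "Viridiplantae" & lps >= 1L]
    e1 <- extras[1]; e2 <- extras[2]
    g1 <- .chain_nw(mk(.role(e1), e1, lps[[e1]]), rng)
    g2 <- .chain_nw(mk(.role(e2), e2, lps[[e2]]), rng)
    inner <- sprintf("(%s,%s)%s", .chain_nw(rec2, rng), g2,
                     .draw_support(rng))
    prok <- if (donor %in% names(lps) && lps[[donor]] > 0L)
      mk("B", donor, lps[[donor]]) else character(0)
    parts <- c(.chain_nw(rec, rng), g1, inner,
               if (length(prok)) .chain_nw(prok, rng))
    newick <- sprintf("(%s);", paste(parts, collapse = ","))
  } else if (spec$scenario == "contamination") {
    contig <- round(stats::runif(1, 5e3, 5e4))
    context <- genomic_context(candidate_id, contig,
                               upstream = c(donor, donor),
                               downstream = c(donor, donor))
  }
  # no_homologs: neither tree nor context

  tree <- NULL
  census <- NULL
  if (!is.na(newick)) {
    tree <- parse_gene_tree(text = newick)
    tree <- annotate_leaves(tree, lmap, scheme = scheme)
    census <- supergroup_census(tree)
  }
  case <- candidate_case(candidate_id, query,
                         reported_recipient = spec$recipient_marker,
                         reported_donor = donor,
                         tree = tree, homolog_census = census,
                         context = context)
  metadata <- data.frame(candidate_id = candidate_id,
                         query_leaf = query,
                         reported_recipient = spec$recipient_marker,
                         reported_donor = donor,
                         scenario = spec$scenario,
                         stringsAsFactors = FALSE)
  list(case = case, truth = scenario_truth(spec$scenario),
       newick = newick, lineage_map = lmap, metadata = metadata,
       context = context)
}

#' Generate a balanced synthetic cohort
#'
#' `n_per_scenario` candidates for each scenario, fully determined by the
#' seed. When `dir` is given, all artifact input files are written there:
#' one Newick file per tree under `trees/`, plus `lineage_map.tsv`,
#' `metadata.tsv`, `context.tsv` and a `manifest.tsv` with the ground
#' truth.
#'
#' @param n_per_scenario Cases per scenario (>= 1).
#' @param seed Integer seed.
#' @param scenarios Scenario subset (default all seven).
#' @param dir Optional output directory.
#' @param ... Further arguments passed to [scenario_spec()] (e.g.
#'   `support_range`).
#' @return List with `cases` (list of [candidate_case()]), `truth` (named
#'   character vector), `scenario` (named character vector) and
#'   `generated` (the full per-case generator output).
#' @export
generate_cohort <- function(n_per_scenario, seed = 1L,
                            scenarios = scenario_names(), dir = NULL, ...) {
  stopifnot(n_per_scenario >= 1)
  set.seed(seed)
  n_total <- n_per_scenario * length(scenarios)
  case_seeds <- sample.int(2^20, n_total)
  gen <- vector("list", n_total)
  k <- 0L
  for (sc in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      k <- k + 1L
      id <- sprintf("C%04d", k)
      spec <- scenario_spec(sc, seed = case_seeds[k], ...)
      gen[[k]] <- generate_case(spec, candidate_id = id)
    }
  }
  cases <- lapply(gen, `[[`, "case")
  ids <- vapply(cases, `[[`, character(1), "candidate_id")
  truth <- setNames(vapply(gen, `[[`, character(1), "truth"), ids)
  scen <- setNames(vapply(gen, function(g) g$metadata$scenario,
                          character(1)), ids)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "trees"), recursive = TRUE,
               showWarnings = FALSE)
    lmap <- do.call(c, lapply(gen, `[[`, "lineage_map"))
    write_lineage_map(lmap, file.path(dir, "lineage_map.tsv"))
    meta <- do.call(rbind, lapply(gen, `[[`, "metadata"))
    utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ctx <- Filter(Negate(is.null), lapply(gen, `[[`, "context"))
    if (length(ctx)) write_context_table(ctx, file.path(dir, "context.tsv"))
    for (g in gen) {
      if (!is.na(g$newick))
        writeLines(g$newick, file.path(dir, "trees",
                                       paste0(g$metadata$candidate_id,
                                              ".nwk")))
    }
    manifest <- data.frame(candidate_id = ids, scenario = scen,
                           truth = truth, stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(cases = cases, truth = truth, scenario = scen, generated = gen)
}

#' Generate a hit table with a planted survivor count
#'
#' Constructs `n_pass` rows that satisfy all three retention thresholds
#' strictly, plus `n_fail_per_criterion` rows for each criterion that
#' violate exactly that criterion; the first failing row of each kind sits
#' exactly on the boundary (identity 30, coverage 60, e-value 1e-5), which
#' under strict thresholds must be rejected.
#'
#' @param n_pass Number of surviving rows to plant.
#' @param n_fail_per_criterion Failing rows per criterion.
#' @param seed Integer seed.
#' @param query_length Query length in residues (default 100).
#' @return List with `hits` (13-column data frame), `query_lengths`
#'   (named vector) and `expected_survivors` (`n_pass`).
#' @export
generate_hit_table <- function(n_pass, n_fail_per_criterion, seed = 1L,
                               query_length = 100L) {
  stopifnot(n_pass >= 0, n_fail_per_criterion >= 0)
  set.seed(seed)
  rows <- list()
  add <- function(pident, qend, evalue) {
    i <- length(rows) + 1L
    qstart <- 1L
    len <- qend - qstart + 1L
    taxid <- if (i %% 5L == 0L) "562;2" else as.character(sample(1e5, 1))
    rows[[i]] <<- data.frame(
      qseqid = "Q1", sseqid = sprintf("S%03d", i),
      pident = round(pident, 2), length = len,
      mismatch = sample(0:10, 1), gapopen = 0L,
      qstart = qstart, qend = qend, sstart = 1L, send = len,
      evalue = evalue, bitscore = round(stats::runif(1, 50, 300), 1),
      staxids = taxid, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_pass))
    add(stats::runif(1, 35, 95), sample(65:query_length, 1),
        10^stats::runif(1, -50, -6))
  for (i in seq_len(n_fail_per_criterion))   # identity failures
    add(if (i == 1L) 30 else stats::runif(1, 5, 29.9),
        sample(65:query_length, 1), 10^stats::runif(1, -50, -6))
  for (i in seq_len(n_fail_per_criterion))   # coverage failures
    add(stats::runif(1, 35, 95),
        if (i == 1L) as.integer(0.6 * query_length) else sample(10:50, 1),
        10^stats::runif(1, -50, -6))
  for (i in seq_len(n_fail_per_criterion))   # e-value failures
    add(stats::runif(1, 35, 95), sample(65:query_length, 1),
        if (i == 1L) 1e-5 else 10^stats::runif(1, -4, 0))
  hits <- if (length(rows)) do.call(rbind, rows) else
    read_hit_table(text = character(0))
  list(hits = hits, query_lengths = c(Q1 = query_length),
       expected_survivors = as.integer(n_pass))
}
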