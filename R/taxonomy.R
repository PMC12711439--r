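#' Supergroup labels used throughout the package
#'
#' The fixed 12-label scheme onto which every lineage is mapped. Eukaryotic
#' supergroups follow the major-clade nomenclature (Opisthokonta split into
#' Fungi, Metazoa and Other_Opisthokonta; SAR covering Stramenopila,
#' Alveolata and Rhizaria); prokaryotes are split into Cyanobacteria,
#' Other_Bacteria and Archaea because cyanobacterial affinity is the
#' signature of endosymbiotic gene transfer and donor tallies should not
#' conflate archaea with bacteria.
#'
#' @return Character vector of the twelve supergroup labels.
#' @export
supergroup_labels <- function() {
  c("Viridiplantae", "Fungi", "Metazoa", "Other_Opisthokonta",
    "Amoebozoa", "Excavata", "SAR", "Other_Eukaryota",
    "Cyanobacteria", "Other_Bacteria", "Archaea", "Viruses")
}

EUKARYOTE_LABELS <- c("Viridiplantae", "Fungi", "Metazoa", "Other_Opisthokonta",
                      "Amoebozoa", "Excavata", "SAR", "Other_Eukaryota")
PROKARYOTE_LABELS <- c("Cyanobacteria", "Other_Bacteria", "Archaea")

#' Domain bin of a supergroup label
#'
#' @param label Character vector of supergroup labels (or `"Unclassified"`).
#' @return Character vector: `"eukaryote"`, `"prokaryote"`, `"virus"` or
#'   `"unclassified"`.
#' @export
supergroup_domain <- function(label) {
  out <- rep("unclassified", length(label))
  out[label %in% EUKARYOTE_LABELS] <- "eukaryote"
  out[label %in% PROKARYOTE_LABELS] <- "prokaryote"
  out[label %in% "Viruses"] <- "virus"
  out
}

#' Default lineage-to-supergroup rule set
#'
#' Ordered first-match-wins rules mapping clade names appearing in an NCBI
#' style lineage to supergroup labels. More specific rules take priority:
#' Fungi and Metazoa fire before the Opisthokonta fallback, Cyanobacteria
#' before the generic Bacteria rule, and the bare Eukaryota marker is the
#' last resort (Other_Eukaryota). Marker synonyms (e.g. "Cyanobacteria" /
#' "Cyanobacteriota") are part of the rule set and can be replaced by
#' loading a scheme file with [read_supergroup_scheme()].
#'
#' @return An object of class `supergroup_scheme`: a data frame with columns
#'   `marker` (clade name to look for in the lineage) and `label`
#'   (supergroup assigned), in priority order.
#' @seealso [assign_supergroup()], [read_supergroup_scheme()]
#' @export
default_supergroup_scheme <- function() {
  rules <- list(
    Viridiplantae      = c("Viridiplantae"),
    Fungi              = c("Fungi"),
    Metazoa            = c("Metazoa"),
    Other_Opisthokonta = c("Opisthokonta", "Choanoflagellata"),
    Amoebozoa          = c("Amoebozoa"),
    Excavata           = c("Excavata", "Discoba", "Metamonada"),
    SAR                = c("Sar", "SAR", "Stramenopiles", "Stramenopila",
                           "Alveolata", "Rhizaria"),
    Cyanobacteria      = c("Cyanobacteriota", "Cyanobacteria"),
    Other_Bacteria     = c("Bacteria"),
    Archaea            = c("Archaea"),
    Viruses            = c("Viruses", "Viroids"),
    Other_Eukaryota    = c("Eukaryota")
  )
  df <- data.frame(
    marker = unlist(rules, use.names = FALSE),
    label = rep(names(rules), lengths(rules)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("supergroup_scheme", "data.frame"))
}

#' Read a supergroup scheme from a YAML file
#'
#' The file maps each supergroup label to the list of lineage markers that
#' select it, in priority order:
#' ```yaml
#' rules:
#'   - label: Cyanobacteria
#'     markers: [Cyanobacteriota, Cyanobacteria]
#'   - label: Other_Bacteria
#'     markers: [Bacteria]
#' ```
#'
#' @param path Path to the YAML scheme file.
#' @return A `supergroup_scheme` object (see [default_supergroup_scheme()]).
#' @export
read_supergroup_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$rules) || !length(doc$rules))
    stop("scheme file has no 'rules' entry: ", path)
  labels <- vapply(doc$rules, function(r) as.character(r$label), character(1))
  bad <- setdiff(labels, supergroup_labels())
  if (length(bad))
    stop("unknown supergroup label(s) in scheme: ", paste(bad, collapse = ", "))
  markers <- lapply(doc$rules, function(r) as.character(unlist(r$markers)))
  df <- data.frame(
    marker = unlist(markers, use.names = FALSE),
    label = rep(labels, lengths(markers)),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("supergroup_scheme", "data.frame"))
}

#' Assign a lineage to a supergroup
#'
#' Walks the scheme's rules in priority order and returns the label of the
#' first rule whose marker appears in the lineage (exact clade-name match,
#' case-sensitive, after trimming surrounding whitespace). Lineages matching
#' no rule fall back to Other_Eukaryota when a "Eukaryota" entry is present;
#' otherwise the lineage is unclassifiable.
#'
#' @param lineage Character vector of clade names, root first.
#' @param scheme A `supergroup_scheme`; defaults to the built-in scheme.
#' @param on_unmatched What to do with unclassifiable lineages: `"error"`
#'   (default) or `"na"` to return `NA_character_`.
#' @return A single supergroup label.
#' @examples
#' assign_supergroup(c("Eukaryota", "Viridiplantae", "Streptophyta"))
#' assign_supergroup(c("Bacteria", "Cyanobacteriota", "Nostocales"))
#' @export
assign_supergroup <- function(lineage, scheme = default_supergroup_scheme(),
                              on_unmatched = c("error", "na")) {
  on_unmatched <- match.arg(on_unmatched)
  lineage <- trimws(as.character(lineage))
  lineage <- lineage[nzchar(lineage)]
  if (!length(lineage)) stop("empty lineage")
  hit <- match(scheme$marker, lineage)
  idx <- which(!is.na(hit))
  if (length(idx)) return(scheme$label[idx[1]])
  if ("Eukaryota" %in% lineage) return("Other_Eukaryota")
  if (on_unmatched == "na") return(NA_character_)
  stop("unclassifiable lineage (no domain marker): ",
       paste(lineage, collapse = ";"))
}

#' Is a supergroup the ingroup?
#'
#' @param label Supergroup label(s) to test.
#' @param ingroup The recipient supergroup; the reassessed cohort uses
#'   Viridiplantae.
#' @param scheme Scheme whose label set defines validity.
#' @return Logical vector, `TRUE` where `label` equals `ingroup`.
#' @export
is_ingroup <- function(label, ingroup = "Viridiplantae",
                       scheme = default_supergroup_scheme()) {
  valid <- supergroup_labels()
  if (!ingroup %in% valid) stop("unknown ingroup label: ", ingroup)
  bad <- setdiff(label, valid)
  if (length(bad)) stop("unknown supergroup label(s): ",
                        paste(bad, collapse = ", "))
  label == ingroup
}

#' Count ingroup leaves inside and outside the reported recipient lineage
#'
#' Given the lineages of the ingroup leaves of a clade, counts how many
#' contain the reported recipient marker (e.g. "Brassicales") and how many
#' do not. Leaves outside the recipient lineage signal that newly available
#' plant homologs push the putative transfer deeper into plant history.
#'
#' @param lineages List of character vectors (one lineage per ingroup leaf).
#' @param recipient_marker Clade name identifying the reported recipient.
#' @param ingroup Supergroup every leaf must belong to.
#' @param scheme Supergroup scheme used to verify the contract.
#' @return Named integer vector `c(inside = , outside = )`.
#' @export
recipient_lineages_in <- function(lineages, recipient_marker,
                                  ingroup = "Viridiplantae",
                                  scheme = default_supergroup_scheme()) {
  if (!length(lineages)) return(c(inside = 0L, outside = 0L))
  sg <- vapply(lineages, assign_supergroup, character(1), scheme = scheme)
  if (any(sg != ingroup))
    stop("non-ingroup leaf passed to recipient_lineages_in: ",
         paste(unique(sg[sg != ingroup]), collapse = ", "))
  inside <- vapply(lineages, function(l) recipient_marker %in% trimws(l),
                   logical(1))
  c(inside = sum(inside), outside = sum(!inside))
}

#' Read a lineage map
#'
#' Tab-delimited text, no header: column 1 is a sequence or taxon id,
#' column 2 the semicolon-delimited lineage, root first.
#'
#' @param path Path to the file.
#' @return Named list of character vectors (lineages keyed by id).
#' @export
read_lineage_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2))
    stop("lineage map line(s) without a lineage column: line ",
         paste(which(nfield < 2), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate ids in lineage map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lin <- lapply(parts, function(p) {
    v <- trimws(strsplit(p[[2]], ";", fixed = TRUE)[[1]])
    v[nzchar(v)]
  })
  names(lin) <- ids
  lin
}

#' Write a lineage map
#'
#' @param lineage_map Named list of character-vector lineages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_map <- function(lineage_map, path) {
  lines <- paste(names(lineage_map),
                 vapply(lineage_map, paste, character(1), collapse = ";"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
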