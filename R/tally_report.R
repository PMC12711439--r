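#' Round half away from zero
#'
#' Decimal rounding in which ties go up (`0.5 -> 1`), matching how the
#' cohort percentages are printed; `base::round()` would use banker's
#' rounding instead. A small guard absorbs binary representation error
#' just below the tie point.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Cohort classification table
#'
#' Verdict counts per category plus reported-donor counts. Construct it
#' directly from counts, or from verdicts via [tabulate_verdicts()].
#'
#' @param counts Named integer vector; names must be verdict categories
#'   (missing categories count 0).
#' @param donor_counts Optional named integer vector of reported-donor
#'   supergroup counts.
#' @return An object of class `classification_table` with elements
#'   `counts` (all six categories), `total` and `donor_counts`.
#' @export
classification_table <- function(counts, donor_counts = NULL) {
  bad <- setdiff(names(counts), VERDICT_CATEGORIES)
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative count")
  full <- setNames(integer(length(VERDICT_CATEGORIES)), VERDICT_CATEGORIES)
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, total = sum(full),
                 donor_counts = donor_counts),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat("Cohort of", x$total, "candidates\n")
  df <- data.frame(category = names(x$counts), n = as.integer(x$counts))
  if (x$total > 0) {
    df$pct_2dp <- category_percentages(x, 2)[df$category]
    df$pct_1dp <- category_percentages(x, 1)[df$category]
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate verdicts into a classification table
#'
#' @param verdicts Named list of `hgt_verdict` objects.
#' @param cases Optional list of the matching [candidate_case()] objects;
#'   when given, reported-donor counts are tabulated as well.
#' @return A [classification_table()].
#' @export
tabulate_verdicts <- function(verdicts, cases = NULL) {
  ids <- vapply(verdicts, `[[`, character(1), "candidate_id")
  if (anyDuplicated(ids))
    stop("duplicate candidate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cats <- vapply(verdicts, `[[`, character(1), "category")
  tab <- table(factor(cats, levels = VERDICT_CATEGORIES))
  donor_counts <- NULL
  if (!is.null(cases)) {
    donors <- vapply(cases, `[[`, character(1), "reported_donor")
    dt <- table(donors)
    donor_counts <- setNames(as.integer(dt), names(dt))
  }
  classification_table(setNames(as.integer(tab), names(tab)), donor_counts)
}

#' Per-category percentages
#'
#' `100 * count / total`, rounded half-up to the requested number of
#' decimals. Printed percentages rounded this way need not sum exactly to
#' 100.
#'
#' @param table A [classification_table()].
#' @param decimals Decimal places (default 2).
#' @return Named numeric vector over the six categories.
#' @export
category_percentages <- function(table, decimals = 2) {
  stopifnot(inherits(table, "classification_table"))
  if (table$total == 0) stop("percentages undefined for an empty cohort")
  round_half_up(100 * table$counts / table$total, decimals)
}

#' Candidates still consistent with interkingdom HGT
#'
#' The HGT and HGT_recipient_shifted categories together: the candidates
#' whose topology still supports an interkingdom transfer after
#' reassessment.
#'
#' @param table A [classification_table()].
#' @return Named numeric vector `c(count = , percent = )`, the percentage
#'   rounded half-up to 1 decimal.
#' @export
hgt_consistent_total <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  if (table$total == 0) stop("undefined for an empty cohort")
  count <- table$counts[["HGT"]] + table$counts[["HGT_recipient_shifted"]]
  c(count = count,
    percent = round_half_up(100 * count / table$total, 1))
}

#' Reported-donor breakdown with prokaryote rollup
#'
#' Counts candidates by reported donor supergroup. With `rollup = TRUE`
#' the three prokaryotic bins (Other_Bacteria, Cyanobacteria, Archaea) are
#' summed into a single `Prokaryotes` entry, the granularity at which
#' interdomain transfers are usually discussed.
#'
#' @param cases List of [candidate_case()] objects, or a character vector
#'   of donor labels.
#' @param rollup Logical (default `TRUE`).
#' @return Named integer vector of counts (empty for an empty cohort).
#' @export
donor_breakdown <- function(cases, rollup = TRUE) {
  donors <- if (is.character(cases)) cases
            else vapply(cases, `[[`, character(1), "reported_donor")
  if (!length(donors)) return(integer(0))
  bad <- setdiff(unique(donors), supergroup_labels())
  if (length(bad))
    stop("unknown donor label(s): ", paste(bad, collapse = ", "))
  if (rollup)
    donors[donors %in% PROKARYOTE_LABELS] <- "Prokaryotes"
  tab <- table(donors)
  setNames(as.integer(tab), names(tab))
}

#' Plain-text cohort report
#'
#' One-paragraph summary mirroring how such cohort results are reported:
#' per-category counts with percentages and the combined HGT-consistent
#' total.
#'
#' @param table A [classification_table()].
#' @return Character vector of report lines.
#' @export
report_text <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  p2 <- category_percentages(table, 2)
  n <- table$counts
  hc <- hgt_consistent_total(table)
  lines <- c(
    sprintf("Of the %d candidates analyzed:", table$total),
    sprintf("  %-24s %5d  (%.2f%%)", names(n), as.integer(n), p2),
    sprintf("Consistent with interkingdom HGT (HGT + recipient-shifted): %d (%.1f%%)",
            as.integer(hc[["count"]]), hc[["percent"]]))
  if (!is.null(table$donor_counts)) {
    db <- table$donor_counts
    lines <- c(lines, "Reported donors:",
               sprintf("  %-24s %5d", names(db), as.integer(db)))
  }
  lines
}
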