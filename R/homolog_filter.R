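HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "staxids")
HIT_NUMERIC <- c("pident", "length", "mismatch", "gapopen", "qstart",
                 "qend", "sstart", "send", "evalue", "bitscore")

#' Parse a 13-column tabular homology hit table
#'
#' Reads the standard BLAST/DIAMOND tabular format (`--outfmt 6`) extended
#' with subject taxon ids: `qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore staxids`. Tab-delimited, no
#' header; `staxids` may hold several ids joined by `";"` and is kept as a
#' character column (see [split_staxids()]).
#'
#' @param path Path to the file, or a character vector of raw lines via
#'   `text =`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return Data frame with the 13 columns above, rows in input order.
#'   Malformed rows abort with the offending line number.
#' @export
read_hit_table <- function(path, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(matrix(nrow = 0, ncol = length(HIT_COLUMNS)))
  names(empty) <- HIT_COLUMNS
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- nfield != length(HIT_COLUMNS)
  if (any(bad))
    stop("hit table line ", lineno[which(bad)[1]], ": expected 13 columns, found ",
         nfield[which(bad)[1]])
  m <- do.call(rbind, parts)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- HIT_COLUMNS
  for (col in HIT_NUMERIC) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("hit table line ", lineno[i], ": non-numeric value '",
           df[[col]][i], "' in column ", col)
    }
    df[[col]] <- v
  }
  bad <- df$pident < 0 | df$pident > 100
  if (any(bad))
    stop("hit table line ", lineno[which(bad)[1]], ": pident outside [0, 100]")
  bad <- df$qstart < 1 | df$qend < df$qstart
  if (any(bad))
    stop("hit table line ", lineno[which(bad)[1]],
         ": invalid query coordinates (need 1 <= qstart <= qend)")
  bad <- df$evalue < 0
  if (any(bad))
    stop("hit table line ", lineno[which(bad)[1]], ": negative e-value")
  df
}

#' Write a hit table in the 13-column tabular format
#'
#' @param hits Data frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Split subject taxon ids
#'
#' @param staxids Character vector of `";"`-joined taxon ids.
#' @return List of character vectors.
#' @export
split_staxids <- function(staxids) {
  lapply(strsplit(as.character(staxids), ";", fixed = TRUE), trimws)
}

#' Homolog retention thresholds
#'
#' Thresholds the reassessment uses to retain homologs behind each gene
#' tree: pairwise identity above 30 percent, query coverage exceeding
#' 60 percent and an e-value below 1e-5. All three are strict inequalities
#' by default, following that wording; set `strict = FALSE` to make them
#' inclusive for sensitivity checks.
#'
#' @param min_pident Identity threshold in percent (default 30).
#' @param min_qcov Query-coverage threshold in percent (default 60).
#' @param max_evalue E-value ceiling (default 1e-5).
#' @param strict Logical; strict (`>`/`<`) vs inclusive (`>=`/`<=`)
#'   comparisons.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_pident = 30, min_qcov = 60,
                              max_evalue = 1e-5, strict = TRUE) {
  stopifnot(min_pident > 0, min_pident <= 100,
            min_qcov > 0, min_qcov <= 100, max_evalue > 0)
  structure(list(min_pident = min_pident, min_qcov = min_qcov,
                 max_evalue = max_evalue, strict = isTRUE(strict)),
            class = "filter_thresholds")
}

#' Query coverage of a hit
#'
#' Coverage of the query sequence by the single HSP's query span:
#' `100 * (qend - qstart + 1) / query_length`.
#'
#' @param qstart,qend 1-based query coordinates, `qstart <= qend`.
#' @param query_length Query length in residues; must be at least `qend`.
#' @return Coverage in percent. Vectorised.
#' @export
query_coverage <- function(qstart, qend, query_length) {
  if (any(qstart < 1) || any(qend < qstart))
    stop("invalid query coordinates (need 1 <= qstart <= qend)")
  if (any(query_length < qend))
    stop("query_length smaller than qend")
  100 * (qend - qstart + 1) / query_length
}

#' Filter homology hits by identity, coverage and e-value
#'
#' Applies the retention thresholds to every row independently and returns
#' the survivors, in input order, together with a per-row rejection log
#' naming the first criterion each discarded row failed. When several rows
#' share a subject, each row is judged on its own; the subject survives if
#' any of its rows does.
#'
#' @param hits Data frame from [read_hit_table()].
#' @param query_lengths Named numeric vector, query id to length in
#'   residues; every `qseqid` in `hits` must be present.
#' @param thresholds A [filter_thresholds()] object.
#' @return List with elements `kept` (surviving rows), `rejected`
#'   (discarded rows plus a `reason` column) and `thresholds`.
#' @export
filter_hits <- function(hits, query_lengths,
                        thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!nrow(hits)) {
    rej <- hits
    rej$reason <- character(0)
    return(list(kept = hits, rejected = rej, thresholds = thresholds))
  }
  missing <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(missing))
    stop("no query length for qseqid: ", paste(missing, collapse = ", "))
  qlen <- unname(query_lengths[hits$qseqid])
  cov <- query_coverage(hits$qstart, hits$qend, qlen)
  if (thresholds$strict) {
    ok_id <- hits$pident > thresholds$min_pident
    ok_cov <- cov > thresholds$min_qcov
    ok_ev <- hits$evalue < thresholds$max_evalue
  } else {
    ok_id <- hits$pident >= thresholds$min_pident
    ok_cov <- cov >= thresholds$min_qcov
    ok_ev <- hits$evalue <= thresholds$max_evalue
  }
  keep <- ok_id & ok_cov & ok_ev
  reason <- rep(NA_character_, nrow(hits))
  reason[!ok_ev] <- "evalue"
  reason[!ok_cov] <- "query_coverage"
  reason[!ok_id] <- "pident"
  rejected <- hits[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = hits[keep, , drop = FALSE], rejected = rejected,
       thresholds = thresholds)
}
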