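#' Genomic context of a candidate
#'
#' Precomputed evidence about where a candidate sits in its assembly: the
#' length of its contig and the best-hit supergroup of each flanking gene
#' (upstream and downstream). Flank supergroups are inputs; the homology
#' searches that produce them are upstream of this package.
#'
#' @param candidate_id Candidate identifier.
#' @param contig_length Contig length in bp (`NA` if unknown).
#' @param upstream,downstream Character vectors of supergroup labels, one
#'   per flanking gene examined (may be empty).
#' @return An object of class `genomic_context`.
#' @export
genomic_context <- function(candidate_id, contig_length = NA_real_,
                            upstream = character(0),
                            downstream = character(0)) {
  if (!is.na(contig_length) && contig_length <= 0)
    stop("contig_length must be positive")
  flanks <- c(upstream, downstream)
  bad <- setdiff(flanks, c(supergroup_labels(), "Unclassified"))
  if (length(bad))
    stop("unknown flank supergroup label(s): ", paste(bad, collapse = ", "))
  structure(list(candidate_id = as.character(candidate_id),
                 contig_length = as.numeric(contig_length),
                 upstream = as.character(upstream),
                 downstream = as.character(downstream),
                 n_flanks_examined = length(flanks)),
            class = "genomic_context")
}

#' Contamination-rule configuration
#'
#' @param flank_fraction Minimum fraction of examined flanks that must
#'   match the donor for the rule to fire (default 1: all flanks).
#' @param short_contig_bp Contig length below which a contig counts as
#'   short (default 100000 bp; the threshold is a package choice, recorded
#'   in every verdict's configuration fingerprint).
#' @param flanks_only If `TRUE`, donor-matching flanks alone fire the rule
#'   regardless of contig length (disjunctive mode); the default is the
#'   conservative conjunctive mode requiring a short contig as well.
#' @param relaxed_flanks If `TRUE`, any non-ingroup flank counts as
#'   donor-like, not only the reported donor supergroup.
#' @return An object of class `contamination_config`.
#' @export
contamination_config <- function(flank_fraction = 1,
                                 short_contig_bp = 1e5,
                                 flanks_only = FALSE,
                                 relaxed_flanks = FALSE) {
  stopifnot(flank_fraction > 0, flank_fraction <= 1, short_contig_bp > 0)
  structure(list(flank_fraction = flank_fraction,
                 short_contig_bp = short_contig_bp,
                 flanks_only = isTRUE(flanks_only),
                 relaxed_flanks = isTRUE(relaxed_flanks)),
            class = "contamination_config")
}

#' Apply the genomic-context contamination rule
#'
#' A candidate lacking eukaryotic homologs is flagged as potential
#' contamination when its flanking genes match the putative donor lineage
#' and it sits on a short contig; when the flanks do not match the donor,
#' the candidate is retained as a possibly genuine transfer. With neither
#' flanks nor a contig length the evidence is unresolved and the caller
#' maps the case to Inconclusive.
#'
#' @param context A [genomic_context()].
#' @param donor Reported donor supergroup label.
#' @param ingroup Ingroup supergroup (flanks matching it always count
#'   against firing).
#' @param config A [contamination_config()].
#' @return List with `contamination_fired` (logical, `NA` when
#'   unresolved) and `evidence` (character vector of measurements).
#' @export
assess_contamination <- function(context, donor,
                                 ingroup = "Viridiplantae",
                                 config = contamination_config()) {
  stopifnot(inherits(context, "genomic_context"),
            inherits(config, "contamination_config"))
  if (!donor %in% supergroup_labels())
    stop("unknown donor supergroup label: ", donor)
  flanks <- c(context$upstream, context$downstream)
  n <- length(flanks)
  no_len <- is.na(context$contig_length)
  if (n == 0L && no_len) {
    return(list(contamination_fired = NA,
                evidence = "context:unresolved(no_flanks,no_contig_length)"))
  }
  donor_like <- if (config$relaxed_flanks) {
    flanks != ingroup & flanks != "Unclassified"
  } else {
    flanks == donor
  }
  frac <- if (n > 0L) mean(donor_like) else 0
  flank_ok <- n > 0L && frac >= config$flank_fraction
  short <- !no_len && context$contig_length < config$short_contig_bp
  fired <- flank_ok && (config$flanks_only || short)
  ev <- c(sprintf("context:flanks_donor_fraction=%.3f(n=%d)", frac, n),
          if (no_len) "context:contig_length=NA"
          else sprintf("context:contig_length=%g(short=%s)",
                       context$contig_length, short),
          sprintf("context:fired=%s", fired))
  list(contamination_fired = fired, evidence = ev)
}

#' Read a genomic-context table
#'
#' Tab-delimited with a header line and columns `candidate_id`,
#' `contig_length`, `upstream_flanks`, `downstream_flanks`; flank labels
#' are comma-joined, empty fields mean no flanks examined, and a missing
#' or empty `contig_length` means unknown.
#'
#' @param path Path to the file.
#' @return Named list of [genomic_context()] objects keyed by candidate id.
#' @export
read_context_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("candidate_id", "contig_length", "upstream_flanks",
            "downstream_flanks")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("context table lacks column(s): ", paste(miss, collapse = ", "))
  split_flanks <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    len <- suppressWarnings(as.numeric(df$contig_length[i]))
    genomic_context(df$candidate_id[i], len,
                    split_flanks(df$upstream_flanks[i]),
                    split_flanks(df$downstream_flanks[i]))
  })
  names(out) <- df$candidate_id
  out
}

#' Write a genomic-context table
#'
#' @param contexts List of [genomic_context()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_table <- function(contexts, path) {
  df <- data.frame(
    candidate_id = vapply(contexts, `[[`, character(1), "candidate_id"),
    contig_length = vapply(contexts, function(x)
      if (is.na(x$contig_length)) "" else format(x$contig_length,
                                                 scientific = FALSE),
      character(1)),
    upstream_flanks = vapply(contexts, function(x)
      paste(x$upstream, collapse = ","), character(1)),
    downstream_flanks = vapply(contexts, function(x)
      paste(x$downstream, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
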