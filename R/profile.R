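#' Filter a read set by sequence length
#'
#' Keeps reads whose length lies in `[min_len, max_len]`, bounds inclusive;
#' abundances are unchanged. The removed read mass is attached as attribute
#' `"removed_abundance"`.
#'
#' @param reads data.frame with `sequence` and `abundance` columns.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 36 nt).
#' @return The filtered data.frame.
#' @export
filter_by_length <- function(reads, min_len = 18, max_len = 36) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_abundance") <- sum(reads$abundance[!keep])
  out
}

#' Abundance-weighted read-length histogram
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @return data.frame `length`, `abundance` covering every observed length;
#'   total abundance is conserved.
#' @export
length_distribution <- function(reads) {
  len <- nchar(reads$sequence)
  tab <- tapply(reads$abundance, len, sum)
  data.frame(length = as.integer(names(tab)),
             abundance = as.integer(tab), row.names = NULL)
}

#' Annotate reads by ordered-priority reference membership
#'
#' Each read is assigned to the first category (in the order of `refsets`)
#' containing a reference sequence of which the read is an exact substring;
#' reads matching no category are labelled `"other"`. T and U are treated as
#' equivalent. This substring rule is a deterministic desk-scale stand-in
#' for alignment-based annotation against miRBase/Rfam and applies the same
#' priority convention (known miRNA first, then rRNA, tRNA, snRNA, snoRNA).
#'
#' @param reads data.frame with `sequence` and `abundance`.
#' @param refsets ordered named list; each element a character vector of
#'   reference sequences.
#' @return List with `category` (character per read), `counts` (data.frame
#'   per category: unique-sequence count and summed read abundance).
#' @export
annotate_by_priority <- function(reads, refsets) {
  cats <- names(refsets)
  seqs <- as_rna(reads$sequence)
  category <- rep("other", nrow(reads))
  unmatched <- rep(TRUE, nrow(reads))
  for (cat in cats) {
    refs <- as_rna(refsets[[cat]])
    if (length(refs) == 0 || !any(unmatched)) next
    hay <- paste(refs, collapse = "\r")  # \r never occurs in a sequence
    hit <- unmatched & vapply(seqs, function(s) grepl(s, hay, fixed = TRUE),
                              logical(1), USE.NAMES = FALSE)
    category[hit] <- cat
    unmatched <- unmatched & !hit
  }
  levels <- c(cats, "other")
  counts <- data.frame(
    category = levels,
    n_unique = as.integer(table(factor(category, levels = levels))),
    abundance = as.integer(tapply(reads$abundance,
                                  factor(category, levels = levels),
                                  function(x) sum(x))),
    stringsAsFactors = FALSE)
  counts$abundance[is.na(counts$abundance)] <- 0L
  list(category = category, counts = counts)
}

#' First-nucleotide composition of miRNA reads by length
#'
#' For every read length in `[len_min, len_max]` present in the input,
#' reports the abundance-weighted fraction of reads starting with each of
#' A, C, G, U (fractions sum to 1 per length).
#'
#' @param reads data.frame with `sequence` and `abundance` (typically the
#'   miRNA-annotated subset).
#' @param len_min,len_max length range of interest (defaults 20 and 24 nt).
#' @return data.frame: `length`, `A`, `C`, `G`, `U`.
#' @export
first_base_preference <- function(reads, len_min = 20, len_max = 24) {
  len <- nchar(reads$sequence)
  keep <- len >= len_min & len <= len_max
  reads <- reads[keep, , drop = FALSE]
  len <- len[keep]
  first <- substr(as_rna(reads$sequence), 1, 1)
  lens <- sort(unique(len))
  out <- do.call(rbind, lapply(lens, function(l) {
    sel <- len == l
    tot <- sum(reads$abundance[sel])
    fr <- vapply(c("A", "C", "G", "U"), function(b)
      sum(reads$abundance[sel & first == b]) / tot, numeric(1))
    data.frame(length = l, A = fr[["A"]], C = fr[["C"]], G = fr[["G"]],
               U = fr[["U"]])
  }))
  rownames(out) <- NULL
  out
}

#' Per-chromosome abundance of annotated miRNAs
#'
#' Sums expression over miRNAs per chromosome. Chromosomes present in the
#' annotation but without expressed features report 0; the grand total is
#' conserved.
#'
#' @param annotation data.frame with `mirna_id` and `chrom`.
#' @param counts count matrix (rownames = miRNA ids) or a named numeric
#'   vector of per-miRNA abundances.
#' @return data.frame: `chrom`, `abundance`.
#' @export
chromosome_distribution <- function(annotation, counts) {
  ab <- if (is.matrix(counts)) rowSums(counts) else counts
  miss <- setdiff(names(ab), annotation$mirna_id)
  if (length(miss) > 0)
    stop("abundances for unannotated miRNAs: ", paste(miss, collapse = ", "))
  chrom <- annotation$chrom[match(names(ab), annotation$mirna_id)]
  chroms <- unique(annotation$chrom)
  tot <- tapply(ab, factor(chrom, levels = chroms), sum)
  tot[is.na(tot)] <- 0
  data.frame(chrom = chroms, abundance = as.numeric(tot), row.names = NULL)
}
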