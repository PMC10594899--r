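#' Read a miRNA annotation from BED6 or GFF3
#'
#' BED is 0-based half-open, GFF3 1-based closed; both are converted to the
#' package's internal 0-based half-open convention, so the same feature
#' yields identical coordinates regardless of source format. Feature ids are
#' taken from the BED name column or the GFF3 `ID` attribute.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame: `mirna_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("malformed ", format, " file '", path, "': ",
                        conditionMessage(e)))
  ids <- if (format == "bed") gr$name else gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("every feature needs an id (BED name column / GFF3 ID attribute)")
  data.frame(mirna_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a miRNA annotation as BED6 or GFF3
#'
#' @param annotation data.frame as returned by [read_annotation()]
#'   (0-based half-open coordinates).
#' @param path output file path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = strand)
  if (format == "bed") {
    gr$name <- annotation$mirna_id
    gr$score <- 0L
  } else {
    gr$source <- "mirlocus"
    gr$type <- "miRNA"
    gr$ID <- annotation$mirna_id
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Write / read a count matrix as TSV
#'
#' First column `mirna_id`, remaining columns one per sample.
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @return `path` / the count matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read the sample sheet (sample id, group) as TSV
#' @param groups named character vector: sample id -> group label.
#' @param path file path.
#' @return `path` / named character vector.
#' @export
write_samples <- function(groups, path) {
  write.table(data.frame(sample_id = names(groups), group = unname(groups)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$group, df$sample_id)
}

#' Write / read sequences as FASTA
#'
#' Backed by Biostrings. Abundances can be encoded in the header as
#' `">id count=N"` for deduplicated small-RNA read sets.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param abundance optional integer vector parallel to `seqs`.
#' @return `path` / named character vector; when headers carry `count=N`,
#'   the result has an `"abundance"` attribute.
#' @export
write_fasta <- function(seqs, path, abundance = NULL) {
  nm <- names(seqs)
  if (!is.null(abundance)) nm <- paste0(nm, " count=", abundance)
  x <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- names(x)
  out <- setNames(as.character(x), sub("\\s.*$", "", nm))
  cnt <- regmatches(nm, regexpr("count=\\d+", nm))
  if (length(cnt) == length(nm) && length(nm) > 0)
    attr(out, "abundance") <- as.integer(sub("count=", "", cnt))
  out
}

#' Write / read gene sets in GMT format
#'
#' GMT: one gene set per line, `id <tab> description <tab> gene1 <tab> ...`.
#' (Hand-rolled: no GMT reader ships with the installed stack.)
#'
#' @param genesets named list of gene-id character vectors.
#' @param path file path.
#' @return `path` / named list of gene-id vectors.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(names(genesets), function(pw)
    paste(c(pw, "na", genesets[[pw]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], " in '", path,
         "': need id, description and >= 1 gene")
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, character(1), 1L))
}

#' Write / read a qPCR Ct table as TSV
#' @param table data.frame with `sample_id`, `group`, `assay`, `ct`.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_qpcr <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) read.delim(path, stringsAsFactors = FALSE)
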