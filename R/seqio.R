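#' @include AllClasses.R
NULL

#' Read one demultiplexed FASTQ file
#'
#' Parses a 4-line-record Sanger (Phred+33) FASTQ into an
#' \linkS4class{AmpliconReadSet}. Residues are uppercased; malformed input
#' (truncated record, sequence/quality length mismatch, bad record markers)
#' raises an error naming the offending line. No records are silently
#' skipped.
#'
#' @param path FASTQ file.
#' @param sample Sample label attached to every read; defaults to the file
#'   name without its extension.
#' @return An \linkS4class{AmpliconReadSet} with qualities.
#' @export
readFastq <- function(path, sample = sub("\\.(fastq|fq)$", "",
                                         basename(path))) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(AmpliconReadSet(DNAStringSet(), character(0),
                           qualities = PhredQuality(character(0))))
  if (n %% 4L != 0L)
    stop(sprintf("%s: truncated FASTQ record at line %d (file has %d lines, not a multiple of 4)",
                 path, (n %/% 4L) * 4L + 1L, n))
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- toupper(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("%s: expected '@' header at line %d", path, (bad[1] - 1L) * 4L + 1L))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("%s: expected '+' separator at line %d", path, (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("%s: sequence/quality length mismatch at line %d",
                 path, (bad[1] - 1L) * 4L + 2L))
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate read id '%s'", path, ids[anyDuplicated(ids)]))
  seqs <- DNAStringSet(seq)
  names(seqs) <- ids
  AmpliconReadSet(seqs, sample, qualities = qual)
}

#' Read a directory of per-sample FASTQ files
#'
#' One file per sample; the sample label is the file name stem, overridable
#' through a sample map (see \code{\link{readSampleMap}}), in which case only
#' mapped samples are loaded and unmapped files raise an error.
#'
#' @param dir Directory containing \code{*.fastq} / \code{*.fq} files.
#' @param sampleMap Optional data.frame from \code{\link{readSampleMap}}.
#' @return A combined \linkS4class{AmpliconReadSet}.
#' @export
readFastqDir <- function(dir, sampleMap = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(fastq|fq)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no FASTQ files found in ", dir)
  sets <- lapply(files, readFastq)
  labels <- vapply(sets, function(s) s@sample[1], "")
  if (!is.null(sampleMap)) {
    missing <- setdiff(labels, sampleMap$sample_label)
    if (length(missing))
      stop("FASTQ sample(s) absent from sample map: ",
           paste(missing, collapse = ", "))
  }
  reads <- do.call(c, lapply(sets, function(s) s@reads))
  AmpliconReadSet(reads, unlist(lapply(sets, sampleLabels)))
}

#' Write an AmpliconReadSet as FASTQ
#'
#' @param x An \linkS4class{AmpliconReadSet} with qualities.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(x, path) {
  stopifnot(is(x, "AmpliconReadSet"))
  if (!hasQualities(x))
    stop("cannot write FASTQ without quality scores")
  writeXStringSet(DNAStringSet(x@reads), path, format = "fastq",
                  qualities = as(quality(x@reads), "BStringSet"))
  invisible(path)
}

#' Read a labeled reference FASTA
#'
#' Multi-line (wrapped) records are concatenated. The reference id is the
#' header token before the first whitespace; the taxon label is everything
#' after it (falling back to the id when the header has no description).
#' Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet} named by reference id, with a
#'   \code{taxon} metadata column accessible via \code{referenceTaxa}.
#' @export
readReferenceFasta <- function(path) {
  refs <- readDNAStringSet(path)
  hdr <- names(refs)
  ids <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(ids))
    stop(path, ": duplicate FASTA id '", ids[anyDuplicated(ids)], "'")
  taxa <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ids)
  ## labels with spaces become underscore-joined taxon names
  taxa <- gsub("\\s+", "_", taxa)
  names(refs) <- ids
  attr(refs, "taxon") <- setNames(taxa, ids)
  refs
}

#' Taxon labels of a reference set
#' @param refs Result of \code{\link{readReferenceFasta}}.
#' @return Named character vector, reference id to taxon label.
#' @export
referenceTaxa <- function(refs) {
  tx <- attr(refs, "taxon")
  if (is.null(tx)) setNames(names(refs), names(refs)) else tx
}

#' Read a sample map
#'
#' Tab-separated with header; requires columns \code{sample_label},
#' \code{sample_type}, \code{site} (extra columns such as a collection date
#' are carried along). Duplicate sample labels are an error.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSampleMap <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_label", "sample_type", "site")
  missing <- setdiff(need, names(map))
  if (length(missing))
    stop(path, ": sample map lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(map$sample_label))
    stop(path, ": duplicate sample_label '",
         map$sample_label[anyDuplicated(map$sample_label)], "'")
  map
}

#' Write a relative-abundance table as TSV
#'
#' Tab-delimited, UTF-8, '.' decimal separator, abundances printed to 4
#' decimals; the first column holds the sample label.
#'
#' @param table Numeric matrix, samples in rows.
#' @param path Output file.
#' @param rowLabel Header of the first column.
#' @return Invisibly, \code{path}.
#' @export
writeAbundanceTable <- function(table, path, rowLabel = "sample") {
  stopifnot(is.matrix(table))
  out <- data.frame(rownames(table),
                    matrix(sprintf("%.4f", table), nrow(table)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(rowLabel, colnames(table))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back an abundance table written by \code{writeAbundanceTable}
#' @param path TSV file.
#' @return Numeric matrix with samples as row names.
#' @export
readAbundanceTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
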