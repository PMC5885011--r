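#' @include AllClasses.R
NULL

#' Pipeline clean-up parameters
#'
#' Defaults mirror a strict 18S amplicon clean-up: a 20-bp 3' trim of the
#' merged reads, a mean-Q20 quality filter, symmetric 10-bp end trims and
#' truncation to a 320-nt positional window before entropy analysis, and a
#' 99\% de novo OTU identity threshold (94.9\% being the ITS2 analogue).
#'
#' @param forwardTrim3p Bases trimmed from the 3' end of merged reads.
#' @param minQuality Phred threshold for the quality filter.
#' @param qualityMode \code{"mean"} (default) removes reads whose mean Phred
#'   falls below \code{minQuality}; \code{"min"} applies the threshold
#'   per-base.
#' @param oligoEndTrim Bases trimmed from each read end before oligotyping.
#' @param targetLength Positional-window length after normalization.
#' @param otuIdentity De novo clustering identity threshold (fraction).
#' @param otuIdentityIts2 The ITS2-style companion threshold, kept for
#'   completeness.
#' @return A named list of validated parameters.
#' @export
pipelineConfig <- function(forwardTrim3p = 20L, minQuality = 20,
                           qualityMode = c("mean", "min"),
                           oligoEndTrim = 10L, targetLength = 320L,
                           otuIdentity = 0.99, otuIdentityIts2 = 0.949) {
  qualityMode <- match.arg(qualityMode)
  stopifnot(forwardTrim3p >= 0, oligoEndTrim >= 0, targetLength > 0,
            otuIdentity > 0, otuIdentity <= 1)
  if (targetLength <= 2L * oligoEndTrim)
    stop("targetLength must exceed twice the oligo end trim")
  list(forwardTrim3p = as.integer(forwardTrim3p), minQuality = minQuality,
       qualityMode = qualityMode, oligoEndTrim = as.integer(oligoEndTrim),
       targetLength = as.integer(targetLength), otuIdentity = otuIdentity,
       otuIdentityIts2 = otuIdentityIts2)
}

#' Trim the low-quality 3' end of every read
#'
#' Removes \code{nBases} from the 3' end of each read (qualities trimmed in
#' lock-step); reads not longer than \code{nBases} are discarded and counted
#' in the processing log.
#'
#' @param x An \linkS4class{AmpliconReadSet}.
#' @param nBases Non-negative number of bases to remove.
#' @return The trimmed \linkS4class{AmpliconReadSet}.
#' @export
trimReads3p <- function(x, nBases) {
  stopifnot(is(x, "AmpliconReadSet"))
  if (length(nBases) != 1L || is.na(nBases) || nBases < 0)
    stop("nBases must be a single non-negative integer")
  nBases <- as.integer(nBases)
  keep <- width(x@reads) > nBases
  out <- x@reads[keep]
  if (nBases > 0L && length(out))
    out <- narrow(out, start = 1L, end = width(out) - nBases)
  initialize(x, reads = out, sample = x@sample[keep],
             processLog = .append_log(x@processLog, "trim_3prime",
                                      length(x), sum(keep)))
}

#' Quality-filter reads
#'
#' Removes reads whose mean (default) or minimum per-base Phred score falls
#' below \code{minQuality}. Reads without quality scores are an error.
#'
#' @param x An \linkS4class{AmpliconReadSet} with qualities.
#' @param minQuality Phred threshold (default 20).
#' @param mode \code{"mean"} or \code{"min"}.
#' @return The filtered \linkS4class{AmpliconReadSet}.
#' @export
filterByQuality <- function(x, minQuality = 20, mode = c("mean", "min")) {
  stopifnot(is(x, "AmpliconReadSet"))
  mode <- match.arg(mode)
  if (!hasQualities(x)) {
    offender <- if (length(x)) names(x@reads)[1] else "<empty set>"
    stop("reads carry no quality scores (first read: ", offender, ")")
  }
  if (length(x) == 0L)
    return(initialize(x, processLog = .append_log(x@processLog,
                                                  "quality_filter", 0L, 0L)))
  q <- as(quality(x@reads), "IntegerList")
  score <- if (mode == "mean") BiocGenerics::mean(q) else min(q)
  keep <- score >= minQuality
  initialize(x, reads = x@reads[keep], sample = x@sample[keep],
             processLog = .append_log(x@processLog, "quality_filter",
                                      length(x), sum(keep)))
}

#' Chimera-removal placeholder stage
#'
#' Chimera screening is delegated to external tooling in this pipeline's
#' lineage; this stage passes all reads through and records itself in the
#' log so stage counts stay telescoping.
#'
#' @param x An \linkS4class{AmpliconReadSet}.
#' @return \code{x} with a log entry appended.
#' @export
removeChimeras <- function(x) {
  stopifnot(is(x, "AmpliconReadSet"))
  message("chimera removal: skipped (external tool in source study)")
  initialize(x, processLog = .append_log(x@processLog, "chimera_removal",
                                         length(x), length(x)))
}

#' Length-normalize reads into a positional matrix
#'
#' Each read loses \code{endTrim} bases from both ends (masking the
#' error-prone extremities), then is truncated at the 3' side to exactly
#' \code{targetLength}; reads still shorter than \code{targetLength} are
#' discarded and counted. The result is a gap-free alignment in which a
#' column index is positionally homologous.
#'
#' @param x An \linkS4class{AmpliconReadSet}.
#' @param endTrim Bases removed from each end (default 10).
#' @param targetLength Final uniform read length (default 320).
#' @return A \linkS4class{PositionalMatrix}.
#' @export
makePositionalMatrix <- function(x, endTrim = 10L, targetLength = 320L) {
  stopifnot(is(x, "AmpliconReadSet"))
  if (targetLength <= 0) stop("targetLength must be positive")
  endTrim <- as.integer(endTrim)
  keep <- width(x@reads) - 2L * endTrim >= targetLength
  reads <- x@reads[keep]
  if (length(reads))
    reads <- subseq(reads, start = endTrim + 1L, width = targetLength)
  new("PositionalMatrix", reads = DNAStringSet(reads),
      sample = x@sample[keep],
      processLog = .append_log(x@processLog, "length_normalization",
                               length(x), sum(keep)))
}

#' Collapse identical reads into unique sequences
#'
#' Identical residue strings are merged with per-sample counts; the result
#' is sorted by total abundance descending, ties broken lexicographically by
#' residues, which fixes the downstream greedy-clustering order.
#'
#' @param pm A \linkS4class{PositionalMatrix}.
#' @return A \linkS4class{UniqueSet}.
#' @export
dereplicate <- function(pm) {
  stopifnot(is(pm, "PositionalMatrix"))
  key <- as.character(pm@reads)
  samples <- sort(unique(pm@sample))
  if (length(key) == 0L)
    return(new("UniqueSet", sequences = DNAStringSet(),
               counts = matrix(0L, 0L, length(samples),
                               dimnames = list(NULL, samples))))
  tab <- table(factor(key), factor(pm@sample, levels = samples))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(rownames(tab), samples))
  total <- rowSums(counts)
  ## total desc; ties broken by residues ascending (table() rows are already
  ## lexicographically sorted, and order() is stable)
  ord <- order(-total)
  counts <- counts[ord, , drop = FALSE]
  seqs <- DNAStringSet(rownames(counts))
  rownames(counts) <- NULL
  new("UniqueSet", sequences = seqs, counts = counts)
}
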