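#' @include AllClasses.R
NULL

## substitution matrix for semiglobal identity: match +1, mismatch -1, and N
## matches nothing (including N itself)
.pid_submat <- local({
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

#' Percent identity between two sequences
#'
#' For equal-length inputs, identity is the fraction of matching positions
#' (an \code{N} matches nothing, not even another \code{N}). For unequal
#' lengths, the sequences are aligned end-gap-free (semiglobal / overlap
#' alignment) and identity is matches over the alignment length, with
#' internal gaps counting as columns. The measure is symmetric and equals 1
#' exactly for identical equal-length sequences.
#'
#' @param a,b Non-empty nucleotide strings (or \code{DNAString}s) over
#'   \{A,C,G,T,N\}.
#' @return Identity as a fraction in [0, 1].
#' @examples
#' percentIdentity(strrep("A", 320), strrep("A", 320))        # 1
#' a <- strrep("A", 320); b <- paste0(strrep("A", 319), "C")
#' round(100 * percentIdentity(a, b), 1)                       # 99.7
#' @export
percentIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("cannot compute identity of an empty sequence")
  if (nchar(a) == nchar(b)) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    return(sum(va == vb & va != "N") / length(va))
  }
  aln <- pairwiseAlignment(a, b, type = "overlap",
                           substitutionMatrix = .pid_submat,
                           gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(subject(aln)), "")[[1]]
  matches <- sum(pa == pb & pa != "N" & pa != "-")
  matches / length(pa)
}

#' Identity as a printed percentage
#'
#' One-decimal rounding of an identity fraction to the percent scale used in
#' similarity reports (e.g. 318/320 matches prints as 99.4).
#'
#' @param identity Fraction in [0, 1].
#' @return Numeric percentage rounded to one decimal.
#' @export
identityPercent <- function(identity) round(identity * 1000) / 10

#' Greedy de novo OTU clustering
#'
#' Abundance-sorted greedy centroid clustering (uclust-style): unique
#' sequences are processed in dereplication order; each joins the first
#' existing centroid with identity >= \code{threshold} (or the best such
#' centroid with \code{assign = "best"}), otherwise it founds a new OTU and
#' becomes its centroid. Because input is abundance-sorted, every centroid
#' is its OTU's most abundant member. The result is order-deterministic.
#'
#' @param uniques A \linkS4class{UniqueSet} from \code{\link{dereplicate}}.
#' @param threshold Identity threshold in (0, 1]; 0.99 is the strict 18S
#'   default, 0.949 the ITS2 analogue.
#' @param assign \code{"first"} (default, the common de novo behaviour) or
#'   \code{"best"}.
#' @return An \linkS4class{OtuSet}.
#' @export
greedyCluster <- function(uniques, threshold = 0.99,
                          assign = c("first", "best")) {
  stopifnot(is(uniques, "UniqueSet"))
  assign <- match.arg(assign)
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  seqs <- as.character(uniques@sequences)
  if (length(seqs) == 0L)
    return(new("OtuSet", centroids = DNAStringSet(), uniques = uniques,
               assignment = integer(0),
               counts = uniques@counts[integer(0), , drop = FALSE],
               threshold = threshold, log = list()))
  if (length(unique(nchar(seqs))) != 1L)
    stop("greedy clustering expects equal-length (length-normalized) input")
  member_of <- .cpp_greedy_cluster(seqs, threshold, assign == "best")
  founders <- sort(unique(member_of))
  otu_idx <- match(member_of, founders)
  ids <- sprintf("OTU_%04d", seq_along(founders))
  counts <- rowsum(uniques@counts, otu_idx, reorder = TRUE)
  rownames(counts) <- ids
  centroids <- uniques@sequences[founders]
  names(centroids) <- ids
  new("OtuSet", centroids = centroids, uniques = uniques,
      assignment = as.integer(otu_idx), counts = counts,
      threshold = threshold, log = list())
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is exactly 1 (sequences
#' observed once in the whole dataset); the number removed is recorded in
#' the object's log. Unique sequences of dropped OTUs are removed and the
#' remaining OTUs renumbered.
#'
#' @param otus An \linkS4class{OtuSet}.
#' @return The filtered \linkS4class{OtuSet}.
#' @export
removeSingletons <- function(otus) {
  stopifnot(is(otus, "OtuSet"))
  total <- rowSums(otus@counts)
  keep <- total > 1
  keep_unique <- keep[otus@assignment]
  uniques <- new("UniqueSet",
                 sequences = otus@uniques@sequences[keep_unique],
                 counts = otus@uniques@counts[keep_unique, , drop = FALSE])
  old_idx <- which(keep)
  new_assign <- match(otus@assignment[keep_unique], old_idx)
  ids <- sprintf("OTU_%04d", seq_along(old_idx))
  counts <- otus@counts[keep, , drop = FALSE]
  rownames(counts) <- ids
  centroids <- otus@centroids[keep]
  names(centroids) <- ids
  log <- otus@log
  log$singletons_removed <- sum(!keep)
  log$singleton_reads_removed <- sum(total[!keep])
  new("OtuSet", centroids = centroids, uniques = uniques,
      assignment = as.integer(new_assign), counts = counts,
      threshold = otus@threshold, log = log)
}

#' Per-OTU membership table
#'
#' Long-format membership: one row per (OTU, unique sequence), with the
#' sequence's total count.
#'
#' @param otus An \linkS4class{OtuSet}.
#' @return data.frame with columns otu_id, residues, count.
#' @export
otuMembership <- function(otus) {
  stopifnot(is(otus, "OtuSet"))
  data.frame(otu_id = names(otus@centroids)[otus@assignment],
             residues = as.character(otus@uniques@sequences),
             count = totalCounts(otus@uniques),
             stringsAsFactors = FALSE)
}
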