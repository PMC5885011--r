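#' @include AllClasses.R
NULL

#' Best-hit taxonomic assignment of OTU representatives
#'
#' Exhaustive best-hit search against a small labeled reference set: each
#' OTU centroid is assigned the taxon of the reference with the highest
#' percent identity (ties broken by reference order in the file). Hits below
#' \code{minIdentity} are reported as \code{"unassigned"}. This is a
#' semantic, not bit-exact, stand-in for a BLAST best hit, appropriate for
#' the curated few-sequence reference sets this pipeline targets.
#'
#' @param otus An \linkS4class{OtuSet}, or a named \code{DNAStringSet} of
#'   representative sequences.
#' @param references A named \code{DNAStringSet} from
#'   \code{\link{readReferenceFasta}} (non-empty).
#' @param minIdentity Minimum identity for an assignment (default 0.9).
#' @return data.frame with columns otu_id, best_ref_id, taxon, identity.
#' @export
assignBestHit <- function(otus, references, minIdentity = 0.9) {
  reps <- if (is(otus, "OtuSet")) otus@centroids else otus
  if (length(references) == 0L)
    stop("reference set is empty")
  taxa <- referenceTaxa(references)
  refs <- as.character(references)
  out <- lapply(seq_along(reps), function(i) {
    rep_seq <- as.character(reps[[i]])
    ident <- vapply(refs, function(r) percentIdentity(rep_seq, r), 0)
    best <- which.max(ident)  # ties: earliest reference in file order
    if (ident[best] < minIdentity)
      data.frame(otu_id = names(reps)[i], best_ref_id = NA_character_,
                 taxon = "unassigned", identity = unname(ident[best]),
                 stringsAsFactors = FALSE)
    else
      data.frame(otu_id = names(reps)[i],
                 best_ref_id = names(references)[best],
                 taxon = unname(taxa[names(references)[best]]),
                 identity = unname(ident[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a sample x taxon relative-abundance table
#'
#' Per sample, a taxon's abundance is the summed member counts of the OTUs
#' assigned to it, divided by the sample's total. With
#' \code{assignedOnly = TRUE} (default) unassigned OTUs are excluded from
#' both the table and the denominator, so rows are fractions of the
#' assignable community (their counts remain visible in the assignments
#' table); with \code{FALSE}, "unassigned" forms a regular column. Rows sum
#' to 1 (or are all zero for a sample with no counts). Columns are ordered
#' by global mean abundance, descending.
#'
#' @param assignments data.frame from \code{\link{assignBestHit}}.
#' @param otus The matching \linkS4class{OtuSet}.
#' @param sampleMap Optional sample map; every counted sample must appear in
#'   it.
#' @param assignedOnly Drop unassigned counts from the denominator
#'   (default TRUE).
#' @return Numeric matrix, samples x taxa, rows summing to 1.
#' @export
buildCommunityTable <- function(assignments, otus, sampleMap = NULL,
                                assignedOnly = TRUE) {
  stopifnot(is(otus, "OtuSet"))
  counts <- otus@counts
  if (!identical(assignments$otu_id, rownames(counts)))
    assignments <- assignments[match(rownames(counts), assignments$otu_id), ]
  if (anyNA(assignments$otu_id))
    stop("every OTU must be assigned or explicitly unassigned")
  if (!is.null(sampleMap)) {
    missing <- setdiff(colnames(counts), sampleMap$sample_label)
    if (length(missing))
      stop("sample(s) in counts but absent from sample map: ",
           paste(missing, collapse = ", "))
  }
  taxon <- assignments$taxon
  by_taxon <- rowsum(counts, taxon, reorder = FALSE)
  if (assignedOnly && "unassigned" %in% rownames(by_taxon))
    by_taxon <- by_taxon[rownames(by_taxon) != "unassigned", , drop = FALSE]
  tab <- t(by_taxon)  # samples x taxa
  totals <- rowSums(tab)
  rel <- tab
  nz <- totals > 0
  rel[nz, ] <- tab[nz, , drop = FALSE] / totals[nz]
  rel[!nz, ] <- 0
  rel <- rel[, order(-colMeans(rel)), drop = FALSE]
  stopifnot(all(abs(rowSums(rel)[nz] - 1) < 1e-9))
  rel
}

#' Smallest taxon set covering a target share of the community
#'
#' Taxa are ranked by global mean relative abundance (descending); the
#' shortest prefix whose cumulative summed abundance reaches
#' \code{coverage} is returned.
#'
#' @param table Community table from \code{\link{buildCommunityTable}}.
#' @param coverage Fraction in (0, 1].
#' @return Character vector of taxon names, most abundant first.
#' @export
topTaxa <- function(table, coverage = 0.99) {
  if (length(coverage) != 1L || coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]")
  ab <- colMeans(table)
  ord <- order(-ab)
  ab <- ab[ord]
  if (coverage == 1) return(names(ab)[ab > 0])
  k <- which(cumsum(ab) >= coverage - 1e-12)[1]
  if (is.na(k)) k <- length(ab)
  names(ab)[seq_len(k)]
}
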