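#' @include AllClasses.R
NULL

#' Oligotyping parameters
#'
#' @param entropyThreshold Positions with Shannon entropy above this many
#'   bits become components. The 0.2-bit default is the empirical Illumina
#'   noise ceiling: i.i.d. substitution errors at realistic rates keep
#'   non-variant columns at or below ~0.2 bits, so peaks above it indicate
#'   genomic variation.
#' @param maxComponents Cap on the number of components (default unlimited).
#' @param minOligotypeFraction A group must hold at least this fraction of
#'   the taxon's reads to be kept. Default 0.005: the floor must clear the
#'   per-base error artifact at a component position, which for a
#'   substitution rate e is e/3 per alternative base (~0.17\% at e = 0.5\%),
#'   and 0.5\% leaves a 3x margin over that floor.
#' @param minOligotypeCount Absolute minimum group size (default 10).
#' @param componentOrder Label/component ordering: \code{"entropy_desc"}
#'   (default; ties by ascending position) or \code{"position_asc"}.
#' @return Named list of validated parameters.
#' @export
oligotypeConfig <- function(entropyThreshold = 0.2, maxComponents = Inf,
                            minOligotypeFraction = 0.005,
                            minOligotypeCount = 10L,
                            componentOrder = c("entropy_desc",
                                               "position_asc")) {
  componentOrder <- match.arg(componentOrder)
  stopifnot(entropyThreshold >= 0, minOligotypeCount >= 1,
            minOligotypeFraction >= 0, minOligotypeFraction <= 1,
            maxComponents >= 1)
  list(entropyThreshold = entropyThreshold, maxComponents = maxComponents,
       minOligotypeFraction = minOligotypeFraction,
       minOligotypeCount = as.integer(minOligotypeCount),
       componentOrder = componentOrder)
}

#' Nucleotide counts at one alignment column
#'
#' @param pm A \linkS4class{PositionalMatrix}.
#' @param position 1-based column index.
#' @return Named integer counts over A/C/G/T (N residues excluded), with the
#'   N tally in attribute \code{"nCount"}.
#' @export
columnCounts <- function(pm, position) {
  stopifnot(is(pm, "PositionalMatrix"))
  if (length(position) != 1L || position < 1L || position > matrixWidth(pm))
    stop("position ", position, " out of range [1, ", matrixWidth(pm), "]")
  col <- as.character(subseq(pm@reads, start = position, width = 1L))
  counts <- vapply(.ALPHABET, function(b) sum(col == b), 0L)
  structure(counts, nCount = sum(col == "N"))
}

#' Shannon entropy of a nucleotide composition
#'
#' \eqn{H = -\sum p_i \log_2 p_i} over residues with positive count. A
#' monomorphic column scores 0; a balanced biallelic column scores exactly 1
#' bit (the scale's practical maximum for amplicon data, where columns are
#' effectively biallelic); the theoretical maximum is 2 bits at uniform
#' four-base composition. A zero-total (all-N) column is defined as 0 and
#' flagged with a warning.
#'
#' @param counts Non-negative counts (named by base or not).
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(c(A = 10))          # 0
#' shannonEntropy(c(A = 5, C = 5))    # 1
#' @export
shannonEntropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) {
    warning("zero-total column; entropy defined as 0")
    return(0)
  }
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Per-position Shannon entropy of a positional matrix
#'
#' @param pm A non-empty \linkS4class{PositionalMatrix}.
#' @return An \linkS4class{EntropyProfile}.
#' @export
entropyProfile <- function(pm) {
  stopifnot(is(pm, "PositionalMatrix"))
  if (length(pm) == 0L) stop("cannot profile an empty matrix")
  cm <- consensusMatrix(pm@reads, baseOnly = TRUE)
  acgt <- cm[.ALPHABET, , drop = FALSE]
  totals <- colSums(acgt)
  p <- sweep(acgt, 2, pmax(totals, 1), "/")
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  bits <- -colSums(plogp)
  bits[totals == 0] <- 0
  new("EntropyProfile", bits = unname(bits),
      nCount = as.integer(cm["other", ]))
}

#' Select high-entropy components
#'
#' Positions with entropy strictly above the threshold, ordered by the
#' configured convention (default: descending entropy, ties by ascending
#' position) and truncated to \code{maxComponents}. An empty selection is a
#' valid outcome (a monomorphic taxon).
#'
#' @param profile An \linkS4class{EntropyProfile}.
#' @param config From \code{\link{oligotypeConfig}}.
#' @return Integer vector of 1-based positions.
#' @export
selectComponents <- function(profile, config = oligotypeConfig()) {
  stopifnot(is(profile, "EntropyProfile"))
  bits <- profile@bits
  sel <- which(bits > config$entropyThreshold)
  if (length(sel) == 0L) return(integer(0))
  sel <- if (config$componentOrder == "entropy_desc")
    sel[order(-bits[sel], sel)]
  else sort(sel)
  if (is.finite(config$maxComponents))
    sel <- head(sel, config$maxComponents)
  sel
}

#' Partition reads by their residues at the selected components
#'
#' Each read maps to the string of its residues at the component positions;
#' reads carrying an N at any component are routed to the N-bucket and take
#' no part in any group. Groups partition all remaining reads and labels are
#' unique.
#'
#' @param pm A \linkS4class{PositionalMatrix}.
#' @param components Non-empty integer vector of in-range positions, in
#'   label order.
#' @return List with \code{labels} (per-read label, NA for N-bucket reads)
#'   and \code{nBucket} (logical per read).
#' @export
decomposeMatrix <- function(pm, components) {
  stopifnot(is(pm, "PositionalMatrix"))
  if (length(components) == 0L)
    stop("empty component list; run selectComponents() first")
  if (any(components < 1L | components > matrixWidth(pm)))
    stop("component position out of range")
  cols <- lapply(components, function(p)
    as.character(subseq(pm@reads, start = p, width = 1L)))
  labels <- unname(do.call(paste0, cols))
  n_mask <- unname(Reduce(`|`, lapply(cols, function(x) x == "N")))
  labels[n_mask] <- NA_character_
  list(labels = labels, nBucket = n_mask)
}

#' Split decomposed groups into kept and noise
#'
#' A group is kept iff its total count reaches
#' \code{max(minOligotypeCount, minOligotypeFraction * taxonTotal)} (the
#' \eqn{\ge} rule, so a group exactly at threshold is kept). Noise groups
#' are reported, never silently dropped.
#'
#' @param groupTotals Named total counts per group label.
#' @param config From \code{\link{oligotypeConfig}}.
#' @param taxonTotal Total reads of the taxon under decomposition.
#' @return List with \code{kept} and \code{noise} label vectors and the
#'   numeric \code{threshold} applied.
#' @export
filterNoise <- function(groupTotals, config = oligotypeConfig(),
                        taxonTotal = sum(groupTotals)) {
  thr <- max(config$minOligotypeCount,
             config$minOligotypeFraction * taxonTotal)
  keep <- groupTotals >= thr
  if (length(groupTotals) == 1L) keep[] <- TRUE  # a lone group stands
  list(kept = names(groupTotals)[keep], noise = names(groupTotals)[!keep],
       threshold = thr)
}

## group x sample count matrix for a label assignment
.group_counts <- function(labels, samples, all_samples) {
  ok <- !is.na(labels)
  tab <- table(factor(labels[ok]), factor(samples[ok],
                                          levels = all_samples))
  matrix(as.integer(tab), nrow(tab), ncol(tab),
         dimnames = list(rownames(tab), all_samples))
}

## most frequent full-length sequence per group (ties: lexicographically
## smallest, for determinism)
.representatives <- function(pm, labels, kept) {
  seqs <- as.character(pm@reads)
  reps <- vapply(kept, function(lb) {
    tab <- sort(table(seqs[!is.na(labels) & labels == lb]),
                decreasing = TRUE)
    best <- tab[tab == tab[1]]
    sort(names(best))[1]
  }, "")
  out <- DNAStringSet(reps)
  names(out) <- kept
  out
}

#' Entropy-driven oligotype decomposition with iterative refinement
#'
#' The core computation. An initial entropy profile over the taxon's
#' positional matrix selects components above the entropy threshold; reads
#' are partitioned by their residues at those components and groups below
#' the noise floor are set aside. Then, iteratively, the entropy profile of
#' each kept group is recomputed over the non-component positions; any
#' position still exceeding the threshold within a group is added to the
#' global component set (so labels stay fixed-length across groups), the
#' matrix is re-decomposed and re-filtered. Decomposition stops once no kept
#' group conceals any position above the threshold, or an iteration leaves
#' the kept partition unchanged; the component set grows monotonically and
#' is bounded by the matrix width, so termination is guaranteed.
#'
#' A matrix with no position above the threshold yields zero components and
#' one trivial group holding every read (label \code{""}).
#'
#' @param pm A non-empty \linkS4class{PositionalMatrix} of one taxon's
#'   reads.
#' @param config From \code{\link{oligotypeConfig}}.
#' @param taxon Taxon label recorded on the result.
#' @return An \linkS4class{OligotypeSet}.
#' @export
refineOligotypes <- function(pm, config = oligotypeConfig(),
                             taxon = "taxon") {
  stopifnot(is(pm, "PositionalMatrix"))
  if (length(pm) == 0L) stop("cannot oligotype an empty matrix")
  all_samples <- sort(unique(pm@sample))
  taxon_total <- length(pm)
  profile <- entropyProfile(pm)
  components <- selectComponents(profile, config)

  if (length(components) == 0L) {
    counts <- .group_counts(rep("", taxon_total), pm@sample, all_samples)
    return(new("OligotypeSet", taxon = taxon, components = integer(0),
               profile = profile, labels = "",
               counts = counts, noiseLabels = character(0),
               noiseCounts = counts[integer(0), , drop = FALSE],
               nBucket = setNames(numeric(length(all_samples)),
                                  all_samples),
               representatives = .representatives(
                 pm, rep("", taxon_total), ""),
               iterations = 0L))
  }

  order_components <- function(comp) {
    if (config$componentOrder == "entropy_desc")
      comp[order(-profile@bits[comp], comp)]
    else sort(comp)
  }

  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    dec <- decomposeMatrix(pm, components)
    gc_mat <- .group_counts(dec$labels, pm@sample, all_samples)
    flt <- filterNoise(rowSums(gc_mat), config, taxon_total)

    ## probe each kept group for residual entropy at non-component positions
    new_pos <- integer(0)
    for (lb in flt$kept) {
      idx <- which(!is.na(dec$labels) & dec$labels == lb)
      sub_prof <- entropyProfile(pm[idx])
      new_pos <- union(new_pos,
                       setdiff(which(sub_prof@bits > config$entropyThreshold),
                               components))
    }
    if (length(new_pos) == 0L || iterations > matrixWidth(pm)) break
    cand <- order_components(union(components, new_pos))
    if (is.finite(config$maxComponents) &&
        length(cand) > config$maxComponents) break
    ## stop if enlarging the component set leaves the partition unchanged
    dec2 <- decomposeMatrix(pm, cand)
    if (identical(split(seq_along(dec$labels), dec$labels),
                  split(seq_along(dec2$labels), dec2$labels))) break
    components <- cand
  }

  dec <- decomposeMatrix(pm, components)
  gc_mat <- .group_counts(dec$labels, pm@sample, all_samples)
  flt <- filterNoise(rowSums(gc_mat), config, taxon_total)
  kept_counts <- gc_mat[flt$kept, , drop = FALSE]
  ord <- order(-rowSums(kept_counts))
  kept_counts <- kept_counts[ord, , drop = FALSE]
  noise_counts <- gc_mat[flt$noise, , drop = FALSE]
  n_bucket <- vapply(all_samples, function(s)
    sum(dec$nBucket & pm@sample == s), 0)

  new("OligotypeSet", taxon = taxon, components = as.integer(components),
      profile = profile, labels = rownames(kept_counts) %||% character(0),
      counts = kept_counts,
      noiseLabels = rownames(noise_counts) %||% character(0),
      noiseCounts = noise_counts, nBucket = n_bucket,
      representatives = .representatives(pm, dec$labels,
                                         rownames(kept_counts) %||%
                                           character(0)),
      iterations = iterations)
}

#' Per-sample oligotype relative-abundance table
#'
#' Rows are samples, columns kept oligotypes; each row is normalized by the
#' sample's total kept-group reads for this taxon, so rows sum to 1. A
#' sample with no kept reads yields an all-zero row and a warning.
#'
#' @param oset An \linkS4class{OligotypeSet}.
#' @param sampleMap Optional sample map; every counted sample must appear.
#' @return Numeric matrix, samples x oligotype labels.
#' @export
oligotypeTable <- function(oset, sampleMap = NULL) {
  stopifnot(is(oset, "OligotypeSet"))
  counts <- t(oset@counts)  # samples x groups
  if (!is.null(sampleMap)) {
    missing <- setdiff(rownames(counts), sampleMap$sample_label)
    if (length(missing))
      stop("sample(s) absent from sample map: ",
           paste(missing, collapse = ", "))
  }
  totals <- rowSums(counts)
  rel <- counts
  nz <- totals > 0
  rel[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  rel[!nz, ] <- 0
  if (any(!nz))
    warning("sample(s) with no kept reads for taxon ", oset@taxon, ": ",
            paste(rownames(counts)[!nz], collapse = ", "))
  rel
}

#' Most similar reference for an oligotype representative
#'
#' Best percent-identity hit of a representative sequence over the trimmed
#' amplicon window against a labeled reference set; ties go to the earliest
#' reference.
#'
#' @param representative A sequence (character or \code{DNAString}).
#' @param references Non-empty named \code{DNAStringSet}.
#' @return List with \code{ref_id}, \code{taxon}, \code{identity}
#'   (fraction) and \code{identity_percent} (one-decimal percent).
#' @export
nearestReference <- function(representative, references) {
  if (length(references) == 0L)
    stop("reference set is empty")
  rep_seq <- as.character(representative)
  ident <- vapply(as.character(references),
                  function(r) percentIdentity(rep_seq, r), 0)
  best <- which.max(ident)
  taxa <- referenceTaxa(references)
  list(ref_id = names(references)[best],
       taxon = unname(taxa[names(references)[best]]),
       identity = unname(ident[best]),
       identity_percent = identityPercent(unname(ident[best])))
}
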