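#' @include AllGenerics.R
#' @import methods
#' @importClassesFrom Biostrings DNAStringSet QualityScaledDNAStringSet
#'   PhredQuality BStringSet
#' @importFrom Biostrings DNAStringSet QualityScaledDNAStringSet PhredQuality
#'   quality width consensusMatrix subseq writeXStringSet readDNAStringSet
#'   alphabetFrequency pairwiseAlignment nucleotideSubstitutionMatrix pattern
#'   subject
#' @importFrom IRanges narrow
#' @importFrom stats rnorm runif setNames quantile
#' @importFrom utils read.delim write.table head
#' @useDynLib oligodecomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ALPHABET <- c("A", "C", "G", "T")

.check_dna_alphabet <- function(seqs, allow_n = TRUE) {
  if (length(seqs) == 0L) return(TRUE)
  af <- colSums(alphabetFrequency(seqs))
  allowed <- c(.ALPHABET, if (allow_n) "N")
  bad <- af[setdiff(names(af), allowed)]
  if (sum(bad) > 0) {
    offending <- names(bad)[bad > 0]
    return(sprintf("residues outside {%s} found: %s",
                   paste(allowed, collapse = ","),
                   paste(offending, collapse = ",")))
  }
  TRUE
}

.empty_log <- function() {
  data.frame(stage = character(), input = integer(), passed = integer(),
             discarded = integer(), stringsAsFactors = FALSE)
}

.append_log <- function(log, stage, input, passed) {
  rbind(log, data.frame(stage = stage, input = as.integer(input),
                        passed = as.integer(passed),
                        discarded = as.integer(input - passed),
                        stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------------
## Read containers
## ---------------------------------------------------------------------------

#' Demultiplexed amplicon reads with per-read sample identity
#'
#' Container for merged amplicon reads. Sequences (and, when present, their
#' Phred qualities) live in a \linkS4class{DNAStringSet} (or
#' \linkS4class{QualityScaledDNAStringSet}); each read carries the label of
#' the sample it was sequenced from, and the object accumulates a per-stage
#' processing log (input/passed/discarded counts) as it moves through the
#' clean-up pipeline.
#'
#' @slot reads A \code{DNAStringSet}, possibly quality-scaled; names are read
#'   identifiers, unique within the set.
#' @slot sample Character vector parallel to \code{reads}.
#' @slot processLog data.frame with columns stage/input/passed/discarded.
#' @export
setClass("AmpliconReadSet",
  slots = c(reads = "DNAStringSet", sample = "character",
            processLog = "data.frame"))

setValidity("AmpliconReadSet", function(object) {
  msg <- character()
  if (length(object@sample) != length(object@reads))
    msg <- c(msg, "sample labels and reads differ in length")
  ids <- names(object@reads)
  if (length(object@reads) > 0L && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "read ids must be present and unique")
  chk <- .check_dna_alphabet(object@reads)
  if (!isTRUE(chk)) msg <- c(msg, chk)
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconReadSet
#'
#' @param reads A \code{DNAStringSet} (named by read id) or character vector.
#' @param sample Character vector of per-read sample labels (recycled if
#'   length 1).
#' @param qualities Optional per-read quality strings (Phred+33) or a
#'   \code{PhredQuality} object; when supplied the reads become
#'   quality-scaled.
#' @return An \linkS4class{AmpliconReadSet}.
#' @export
AmpliconReadSet <- function(reads, sample, qualities = NULL) {
  if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
  if (!is.null(qualities) && !is(reads, "QualityScaledDNAStringSet")) {
    if (!is(qualities, "PhredQuality")) qualities <- PhredQuality(qualities)
    reads <- QualityScaledDNAStringSet(reads, qualities)
  }
  if (length(sample) == 1L) sample <- rep(sample, length(reads))
  new("AmpliconReadSet", reads = reads, sample = as.character(sample),
      processLog = .empty_log())
}

#' @rdname accessors
#' @export
setMethod("readSequences", "AmpliconReadSet", function(x, ...) x@reads)

#' @rdname accessors
#' @export
setMethod("readQualities", "AmpliconReadSet", function(x, ...) {
  if (!hasQualities(x)) stop("read set carries no quality scores")
  quality(x@reads)
})

#' @rdname accessors
#' @export
setMethod("sampleLabels", "AmpliconReadSet", function(x, ...) x@sample)

#' @rdname accessors
#' @export
setMethod("processLog", "AmpliconReadSet", function(x, ...) x@processLog)

#' Does a read set carry quality scores?
#' @param x An \linkS4class{AmpliconReadSet}.
#' @return Logical scalar.
#' @export
hasQualities <- function(x) is(x@reads, "QualityScaledDNAStringSet")

setMethod("length", "AmpliconReadSet", function(x) length(x@reads))

setMethod("show", "AmpliconReadSet", function(object) {
  cat(sprintf("AmpliconReadSet: %d reads, %d sample(s)%s\n",
              length(object), length(unique(object@sample)),
              if (hasQualities(object)) ", with qualities" else ""))
  if (nrow(object@processLog)) {
    cat("processing log:\n")
    print(object@processLog, row.names = FALSE)
  }
})

setMethod("[", "AmpliconReadSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, reads = x@reads[i], sample = x@sample[i],
             processLog = x@processLog)
})

## ---------------------------------------------------------------------------
## Positional matrix
## ---------------------------------------------------------------------------

#' Gap-free positional alignment of equal-length reads
#'
#' All reads have been trimmed to one fixed length, so that a column index is
#' positionally homologous across reads; this is the substrate of the
#' Shannon-entropy analysis.
#'
#' @slot reads A \code{DNAStringSet} of constant width.
#' @slot sample Per-read sample labels.
#' @slot processLog Telescoping stage counts inherited from upstream stages.
#' @export
setClass("PositionalMatrix",
  slots = c(reads = "DNAStringSet", sample = "character",
            processLog = "data.frame"))

setValidity("PositionalMatrix", function(object) {
  msg <- character()
  if (length(object@sample) != length(object@reads))
    msg <- c(msg, "sample labels and reads differ in length")
  if (length(object@reads) > 0L) {
    w <- unique(width(object@reads))
    if (length(w) != 1L) msg <- c(msg, "reads must all have the same length")
    else if (w < 1L) msg <- c(msg, "reads must be non-empty")
  }
  chk <- .check_dna_alphabet(object@reads)
  if (!isTRUE(chk)) msg <- c(msg, chk)
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("readSequences", "PositionalMatrix", function(x, ...) x@reads)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "PositionalMatrix", function(x, ...) x@sample)

#' @rdname accessors
#' @export
setMethod("processLog", "PositionalMatrix", function(x, ...) x@processLog)

setMethod("length", "PositionalMatrix", function(x) length(x@reads))

#' Alignment width of a positional matrix
#' @param x A \linkS4class{PositionalMatrix}.
#' @return Integer read length (number of alignment columns).
#' @export
matrixWidth <- function(x) {
  stopifnot(is(x, "PositionalMatrix"))
  if (length(x) == 0L) 0L else width(x@reads)[1L]
}

setMethod("show", "PositionalMatrix", function(object) {
  cat(sprintf("PositionalMatrix: %d reads x %d positions, %d sample(s)\n",
              length(object), matrixWidth(object),
              length(unique(object@sample))))
})

setMethod("[", "PositionalMatrix", function(x, i, j, ..., drop = TRUE) {
  initialize(x, reads = x@reads[i], sample = x@sample[i],
             processLog = x@processLog)
})

## ---------------------------------------------------------------------------
## Dereplicated sequences and OTUs
## ---------------------------------------------------------------------------

#' Dereplicated unique sequences with per-sample counts
#'
#' @slot sequences Unique residue strings, sorted by total abundance
#'   (descending, ties broken lexicographically).
#' @slot counts Integer matrix, uniques x samples.
#' @export
setClass("UniqueSet",
  slots = c(sequences = "DNAStringSet", counts = "matrix"))

setValidity("UniqueSet", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@sequences))
    msg <- c(msg, "counts matrix must have one row per unique sequence")
  if (length(object@sequences) && any(rowSums(object@counts) < 1))
    msg <- c(msg, "every unique sequence must have total count >= 1")
  if (anyDuplicated(as.character(object@sequences)))
    msg <- c(msg, "sequences must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("length", "UniqueSet", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("readSequences", "UniqueSet", function(x, ...) x@sequences)

#' @rdname accessors
#' @export
setMethod("sampleCounts", "UniqueSet", function(x, ...) x@counts)

#' Total abundance of each unique sequence
#' @param x A \linkS4class{UniqueSet}.
#' @return Integer vector of totals, parallel to \code{readSequences(x)}.
#' @export
totalCounts <- function(x) {
  stopifnot(is(x, "UniqueSet"))
  as.integer(rowSums(x@counts))
}

setMethod("show", "UniqueSet", function(object) {
  cat(sprintf("UniqueSet: %d unique sequences, %d reads, %d sample(s)\n",
              length(object), sum(object@counts), ncol(object@counts)))
})

#' De novo OTUs from greedy centroid clustering
#'
#' @slot centroids Representative (most abundant member) sequence of each
#'   OTU, named by OTU id.
#' @slot uniques The clustered \linkS4class{UniqueSet}.
#' @slot assignment Integer OTU index for every unique sequence.
#' @slot counts Integer matrix, OTUs x samples.
#' @slot threshold The identity threshold used.
#' @slot log List of bookkeeping counts (e.g. singletons removed).
#' @export
setClass("OtuSet",
  slots = c(centroids = "DNAStringSet", uniques = "UniqueSet",
            assignment = "integer", counts = "matrix",
            threshold = "numeric", log = "list"))

setValidity("OtuSet", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@centroids))
    msg <- c(msg, "counts must have one row per OTU")
  if (length(object@assignment) != length(object@uniques))
    msg <- c(msg, "assignment must cover every unique sequence")
  if (length(msg)) msg else TRUE
})

setMethod("length", "OtuSet", function(x) length(x@centroids))

#' @rdname accessors
#' @export
setMethod("centroids", "OtuSet", function(x, ...) x@centroids)

#' @rdname accessors
#' @export
setMethod("sampleCounts", "OtuSet", function(x, ...) x@counts)

setMethod("show", "OtuSet", function(object) {
  cat(sprintf("OtuSet: %d OTUs (identity threshold %.3f), %d reads\n",
              length(object), object@threshold, sum(object@counts)))
})

## ---------------------------------------------------------------------------
## Entropy profile and oligotypes
## ---------------------------------------------------------------------------

#' Per-position Shannon entropy of a positional matrix
#'
#' Entropy is computed in bits over the A/C/G/T composition of each alignment
#' column; N residues are excluded from the composition and tallied
#' separately. Values range from 0 (monomorphic) to 2 bits (uniform over four
#' bases); a balanced biallelic column scores exactly 1 bit.
#'
#' @slot bits Numeric entropy per position.
#' @slot nCount Integer count of N residues per position.
#' @export
setClass("EntropyProfile", slots = c(bits = "numeric", nCount = "integer"))

setValidity("EntropyProfile", function(object) {
  msg <- character()
  if (length(object@nCount) != length(object@bits))
    msg <- c(msg, "nCount must be parallel to bits")
  if (length(object@bits) && (any(object@bits < -1e-12) ||
                              any(object@bits > 2 + 1e-9)))
    msg <- c(msg, "entropy values must lie in [0, 2] bits")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("entropyValues", "EntropyProfile", function(x, ...) x@bits)

setMethod("length", "EntropyProfile", function(x) length(x@bits))

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf("EntropyProfile: %d positions, max %.3f bits, %d above 0.2\n",
              length(object@bits),
              if (length(object@bits)) max(object@bits) else 0,
              sum(object@bits > 0.2)))
})

#' Oligotype decomposition of one taxon
#'
#' Result of the entropy-driven decomposition of a per-taxon positional
#' matrix. Reads are partitioned by the nucleotides they carry at the
#' selected high-entropy components; groups below the noise floor are kept
#' aside (never silently dropped), and reads with an N at any component go to
#' an N-bucket.
#'
#' @slot taxon Taxon label the matrix was extracted for.
#' @slot components Selected alignment positions (1-based), in label order.
#' @slot profile The full-matrix \linkS4class{EntropyProfile}.
#' @slot labels Kept oligotype labels (nucleotide strings over components).
#' @slot counts Kept oligotype x sample count matrix.
#' @slot noiseLabels,noiseCounts Same for below-threshold groups.
#' @slot nBucket Per-sample count of reads routed to the N-bucket.
#' @slot representatives Most frequent full-length member sequence per kept
#'   oligotype.
#' @slot iterations Number of refinement iterations performed.
#' @export
setClass("OligotypeSet",
  slots = c(taxon = "character", components = "integer",
            profile = "EntropyProfile", labels = "character",
            counts = "matrix", noiseLabels = "character",
            noiseCounts = "matrix", nBucket = "numeric",
            representatives = "DNAStringSet", iterations = "integer"))

setValidity("OligotypeSet", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@labels))
    msg <- c(msg, "counts must have one row per kept oligotype")
  if (nrow(object@noiseCounts) != length(object@noiseLabels))
    msg <- c(msg, "noiseCounts must have one row per noise group")
  if (length(object@components) &&
      any(nchar(object@labels) != length(object@components)))
    msg <- c(msg, "label length must equal the number of components")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "oligotype labels must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("oligotypeLabels", "OligotypeSet", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("oligoComponents", "OligotypeSet", function(x, ...) x@components)

#' @rdname accessors
#' @export
setMethod("sampleCounts", "OligotypeSet", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setMethod("noiseCounts", "OligotypeSet", function(x, ...) x@noiseCounts)

#' @rdname accessors
#' @export
setMethod("representatives", "OligotypeSet", function(x, ...)
  x@representatives)

setMethod("length", "OligotypeSet", function(x) length(x@labels))

setMethod("show", "OligotypeSet", function(object) {
  cat(sprintf(
    "OligotypeSet [%s]: %d kept oligotype(s) over %d component(s) %s\n",
    object@taxon, length(object@labels), length(object@components),
    if (length(object@components))
      paste0("(positions ", paste(object@components, collapse = ","), ")")
    else "(monomorphic)"))
  if (length(object@labels))
    cat("  labels:", paste(object@labels, collapse = ", "), "\n")
  cat(sprintf("  noise groups: %d; N-bucket reads: %d; iterations: %d\n",
              length(object@noiseLabels), sum(object@nBucket),
              object@iterations))
})

## ---------------------------------------------------------------------------
## Synthetic community
## ---------------------------------------------------------------------------

#' Configuration of a synthetic amplicon community
#'
#' Describes the haplotypes (per-taxon amplicon variants), per-sample mixing
#' proportions and depths, the i.i.d. substitution error rate, and the
#' positional quality model used to emit merged Illumina-like reads. Reads
#' are emitted as \code{flank5 | haplotype | flank3}: the flanks emulate the
#' low-quality read ends that the clean-up pipeline trims away, so the
#' haplotype occupies exactly the positional window that reaches the entropy
#' analysis.
#'
#' @slot name Preset name (or "custom").
#' @slot haplotypes data.frame with columns taxon, variant, residues; all
#'   residue strings share one length.
#' @slot sites data.frame with columns sample_label, sample_type, site,
#'   depth.
#' @slot mixing Numeric matrix, haplotype variants x samples; columns sum
#'   to 1.
#' @slot errorRate Per-base substitution probability (uniform over the three
#'   other bases), < 0.25.
#' @slot qualityModel Mean Phred per read position (length = flanked read
#'   length).
#' @slot flank5,flank3 Constant flanking sequence added 5' and 3' of the
#'   haplotype.
#' @slot references data.frame of labeled reference sequences (ref_id,
#'   taxon, residues) for taxonomic assignment.
#' @slot seed Default RNG seed for simulation.
#' @export
setClass("SynthConfig",
  slots = c(name = "character", haplotypes = "data.frame",
            sites = "data.frame", mixing = "matrix", errorRate = "numeric",
            qualityModel = "numeric", flank5 = "character",
            flank3 = "character", references = "data.frame",
            seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  h <- object@haplotypes
  if (!all(c("taxon", "variant", "residues") %in% names(h)))
    msg <- c(msg, "haplotypes needs columns taxon, variant, residues")
  else {
    if (length(unique(nchar(h$residues))) > 1L)
      msg <- c(msg, "all haplotypes must share one amplicon length")
    if (any(grepl("[^ACGT]", h$residues)))
      msg <- c(msg, "haplotype residues must be over {A,C,G,T}")
    if (anyDuplicated(h$variant))
      msg <- c(msg, "haplotype variant labels must be unique")
  }
  s <- object@sites
  if (!all(c("sample_label", "sample_type", "site", "depth") %in% names(s)))
    msg <- c(msg, "sites needs columns sample_label, sample_type, site, depth")
  else if (any(s$depth < 1))
    msg <- c(msg, "every site needs depth >= 1")
  if (!is.null(rownames(object@mixing)) &&
      !setequal(rownames(object@mixing), h$variant))
    msg <- c(msg, "mixing rows must match haplotype variant labels")
  if (ncol(object@mixing) != nrow(s))
    msg <- c(msg, "mixing must have one column per sample")
  else if (any(abs(colSums(object@mixing) - 1) > 1e-9))
    msg <- c(msg, "mixing proportions must sum to 1 per sample")
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msg <- c(msg, "errorRate must lie in [0, 0.25)")
  rl <- nchar(h$residues[1]) + nchar(object@flank5) + nchar(object@flank3)
  if (length(object@qualityModel) != rl)
    msg <- c(msg, "qualityModel must have one mean Phred per read position")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig '%s': %d haplotype(s) of %d taxa, %d sample(s), error %.4g, seed %d\n",
    object@name, nrow(object@haplotypes),
    length(unique(object@haplotypes$taxon)), nrow(object@sites),
    object@errorRate, object@seed))
})

#' A simulated amplicon community with its ground truth
#'
#' @slot reads The emitted \linkS4class{AmpliconReadSet} (quality-scaled).
#' @slot truth data.frame with one row per read: read_id, sample, taxon,
#'   variant.
#' @slot haplotypeCounts Realized haplotype x sample draw counts.
#' @slot config The generating \linkS4class{SynthConfig}.
#' @export
setClass("SimulatedCommunity",
  slots = c(reads = "AmpliconReadSet", truth = "data.frame",
            haplotypeCounts = "matrix", config = "SynthConfig"))

#' @rdname accessors
#' @export
setMethod("readSequences", "SimulatedCommunity", function(x, ...)
  x@reads@reads)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedCommunity", function(x, ...) x@truth)

#' @rdname accessors
#' @export
setMethod("haplotypeCounts", "SimulatedCommunity", function(x, ...)
  x@haplotypeCounts)

#' Extract the read container from a simulation
#' @param x A \linkS4class{SimulatedCommunity}.
#' @return The \linkS4class{AmpliconReadSet}.
#' @export
simulatedReads <- function(x) {
  stopifnot(is(x, "SimulatedCommunity"))
  x@reads
}

setMethod("show", "SimulatedCommunity", function(object) {
  cat(sprintf("SimulatedCommunity '%s': %d reads across %d sample(s)\n",
              object@config@name, length(object@reads),
              nrow(object@config@sites)))
})

## ---------------------------------------------------------------------------
## Pipeline result
## ---------------------------------------------------------------------------

#' End-to-end pipeline result
#'
#' @slot communityTable Sample x taxon relative-abundance matrix.
#' @slot assignments Per-OTU taxonomy data.frame.
#' @slot otus The post-singleton-removal \linkS4class{OtuSet}.
#' @slot oligotypes Named list of \linkS4class{OligotypeSet}, one per
#'   decomposed taxon.
#' @slot stageCounts Telescoping per-stage read counts.
#' @slot manifest Run manifest (config snapshot, seed, file inventory).
#' @export
setClass("PipelineResult",
  slots = c(communityTable = "matrix", assignments = "data.frame",
            otus = "OtuSet", oligotypes = "list", stageCounts = "data.frame",
            manifest = "list"))

setMethod("show", "PipelineResult", function(object) {
  cat(sprintf(
    "PipelineResult: %d sample(s), %d taxa, %d OTUs, %d taxon/taxa oligotyped\n",
    nrow(object@communityTable), ncol(object@communityTable),
    length(object@otus), length(object@oligotypes)))
  cat("stages:\n")
  print(object@stageCounts, row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("processLog", "PipelineResult", function(x, ...) x@stageCounts)
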