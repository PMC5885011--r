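## Shared fixtures and independent brute-force oracles. Oracles deliberately
## use naive R implementations (strsplit, double loops) so they stay
## independent of the package's vectorized / compiled paths.

BASES <- c("A", "C", "G", "T")

random_seq <- function(L) paste(sample(BASES, L, replace = TRUE),
                                collapse = "")

mutate_at <- function(seq, positions, to = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_along(positions)) {
    p <- positions[i]
    ch[p] <- if (is.null(to)) sample(setdiff(BASES, ch[p]), 1) else to[i]
  }
  paste(ch, collapse = "")
}

## Build a PositionalMatrix directly from character reads.
make_pm <- function(seqs, sample = "s1", ids = NULL) {
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- if (is.null(ids)) sprintf("r%04d", seq_along(seqs)) else ids
  if (length(sample) == 1L) sample <- rep(sample, length(seqs))
  new("PositionalMatrix", reads = reads, sample = sample,
      processLog = data.frame(stage = character(), input = integer(),
                              passed = integer(), discarded = integer()))
}

## Build an AmpliconReadSet with uniform or per-read quality strings.
make_reads <- function(seqs, quals = NULL, sample = "s1", q = 38L) {
  if (is.null(quals)) {
    qc <- rawToChar(as.raw(q + 33L))
    quals <- vapply(nchar(seqs), function(n) strrep(qc, n), "")
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("r%04d", seq_along(seqs))
  AmpliconReadSet(reads, sample, qualities = quals)
}

## Build a UniqueSet in dereplication order from sequences + total counts.
make_uniques <- function(seqs, counts, sample = "s1") {
  ord <- order(-counts, seqs)
  m <- matrix(as.integer(counts[ord]), ncol = 1,
              dimnames = list(NULL, sample))
  new("UniqueSet", sequences = Biostrings::DNAStringSet(seqs[ord]),
      counts = m)
}

## Minimal single-taxon SynthConfig for custom study-condition tests.
make_config <- function(haps, depth, error, mixing = NULL,
                        samples = paste0("s", seq_along(depth)),
                        taxon = "taxonA", seed = 7L) {
  L <- nchar(haps[1])
  hdf <- data.frame(taxon = taxon, variant = paste0("v", seq_along(haps)),
                    residues = haps, stringsAsFactors = FALSE)
  sites <- data.frame(sample_label = samples, sample_type = "dirty_ice",
                      site = "site1", depth = as.integer(depth),
                      stringsAsFactors = FALSE)
  if (is.null(mixing))
    mixing <- matrix(1 / length(haps), length(haps), length(depth))
  dimnames(mixing) <- list(hdf$variant, samples)
  refs <- data.frame(ref_id = paste0("REF", seq_along(haps)),
                     taxon = if (length(taxon) == 1L)
                       rep(taxon, length(haps)) else taxon,
                     residues = haps, stringsAsFactors = FALSE)
  new("SynthConfig", name = "custom", haplotypes = hdf, sites = sites,
      mixing = mixing, errorRate = error,
      qualityModel = rep(38, L), flank5 = "", flank3 = "",
      references = refs, seed = as.integer(seed))
}

## --- oracles -------------------------------------------------------------

## Equal-length identity by direct position count; N matches nothing.
oracle_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va == vb & va != "N" & vb != "N") / length(va)
}

## Greedy first/best-hit clustering by double loop over the oracle identity.
oracle_greedy <- function(seqs, threshold, best = FALSE) {
  cluster <- integer(length(seqs))
  centroid_at <- integer(0)
  for (i in seq_along(seqs)) {
    hit <- NA_integer_; best_id <- -1
    for (c in centroid_at) {
      id <- oracle_identity(seqs[i], seqs[c])
      if (id >= threshold - 1e-12) {
        if (!best) { hit <- c; break }
        if (id > best_id + 1e-12) { best_id <- id; hit <- c }
      }
    }
    if (is.na(hit)) { centroid_at <- c(centroid_at, i); cluster[i] <- i }
    else cluster[i] <- hit
  }
  cluster
}

## Component selection by brute filter + sort.
oracle_select <- function(bits, threshold, order = "entropy_desc",
                          max_components = Inf) {
  sel <- which(bits > threshold)
  sel <- if (order == "entropy_desc") sel[order(-bits[sel], sel)]
  else sort(sel)
  head(sel, max_components)
}

## Decomposition by substr over a character vector.
oracle_decompose <- function(seqs, components) {
  labels <- vapply(seqs, function(s)
    paste(vapply(components, function(p) substr(s, p, p), ""),
          collapse = ""), "", USE.NAMES = FALSE)
  labels[grepl("N", labels)] <- NA_character_
  labels
}

## Random unique-set instances for property tests.
random_unique_instance <- function(max_n = 20L, max_len = 30L) {
  L <- sample(5:max_len, 1)
  n <- sample(2:max_n, 1)
  base <- random_seq(L)
  seqs <- unique(vapply(seq_len(n), function(i) {
    k <- sample(0:min(4L, L), 1)
    if (k > 0) mutate_at(base, sample(L, k)) else base
  }, ""))
  counts <- sample(1:6, length(seqs), replace = TRUE)
  list(uniques = make_uniques(seqs, counts),
       seqs = seqs[order(-counts, seqs)])
}
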