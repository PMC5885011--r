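#' @include AllClasses.R
NULL

## Run expr with a private RNG state so preset construction and simulation
## never disturb (or depend on) the caller's RNG.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.random_dna <- function(n) paste(sample(.ALPHABET, n, replace = TRUE),
                                 collapse = "")

## Substitute the bases of `seq` at `positions`; each substituted base is
## forced to differ from the original (and from `to` when given).
.mutate <- function(seq, positions, to = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_along(positions)) {
    p <- positions[i]
    choices <- setdiff(.ALPHABET, ch[p])
    ch[p] <- if (is.null(to)) sample(choices, 1L) else to[i]
  }
  paste(ch, collapse = "")
}

## Generator-internal quality jitter (per-read offset and per-base noise, in
## Phred units); fixed model constants, not exposed as knobs.
.READ_QUALITY_SD <- 6
.BASE_QUALITY_SD <- 2

.default_quality_model <- function(read_length, tail = 30L,
                                   plateau = 36, tail_floor = 12) {
  stopifnot(read_length > tail)
  c(rep(plateau, read_length - tail),
    round(seq(plateau - 2, tail_floor, length.out = tail)))
}

#' Built-in synthetic community presets
#'
#' \code{buildPreset} returns a fully populated \linkS4class{SynthConfig}
#' emulating the data structure of a Greenland ice-surface 18S amplicon
#' survey at desk scale. Available presets:
#' \describe{
#'   \item{\code{"gris_transect"}}{One dominant ice-algal taxon (92\% of
#'     reads) carrying two haplotypes that differ at exactly one position of
#'     the 320-nt amplicon (forced to be A vs C, so oligotype labels read
#'     'A' and 'C'), mixed 70/30 in base-camp-like samples and 30/70 in
#'     inland-like samples; four minor taxa at 1--4.2\% whose haplotype sets
#'     span 93--99.7\% mutual identity, exercising both OTU merging and
#'     splitting at the 99\% threshold; substitution errors at 0.5\%;
#'     10\,000 reads per sample across 6 samples (3 base camp, 3 inland).}
#'   \item{\code{"single_taxon"}}{One haplotype, one sample, error rate 0 --
#'     the noiseless degenerate case.}
#'   \item{\code{"noise_only"}}{One haplotype, one sample of depth 10\,000,
#'     i.i.d. substitution errors at 1\% -- pure sequencing noise, used to
#'     probe the entropy noise floor.}
#' }
#'
#' Reads are emitted merged and full-length with a 10-bp flank on each side
#' of the amplicon plus a 20-bp low-quality 3' tail (total 360 nt), so the
#' default clean-up (20-bp 3' trim, 10-bp end trims, 320-nt length
#' normalization) recovers exactly the haplotype window.
#'
#' @param name One of \code{"gris_transect"}, \code{"single_taxon"},
#'   \code{"noise_only"}.
#' @return A schema-valid \linkS4class{SynthConfig} with a documented seed.
#' @examples
#' cfg <- buildPreset("single_taxon")
#' cfg
#' @export
buildPreset <- function(name) {
  presets <- c("gris_transect", "single_taxon", "noise_only")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(presets, collapse = ", "))
  ## Preset sequences are drawn once from a fixed internal seed so that
  ## buildPreset() is a pure function of its name.
  .with_seed(20160727L, {
    L <- 320L
    flank5 <- .random_dna(10L)
    flank3 <- .random_dna(30L)  # 10-bp end-trim window + 20-bp 3' tail
    qmodel <- .default_quality_model(L + 40L)
    switch(name,
      gris_transect = .preset_gris_transect(L, flank5, flank3, qmodel),
      single_taxon  = .preset_single_taxon(L, flank5, flank3, qmodel),
      noise_only    = .preset_noise_only(L, flank5, flank3, qmodel))
  })
}

.preset_gris_transect <- function(L, flank5, flank3, qmodel) {
  variant_pos <- 101L
  anc_a <- .random_dna(L)
  anc_a <- .mutate(anc_a, variant_pos, to = "A")
  anc_c <- .mutate(anc_a, variant_pos, to = "C")

  rap_1 <- .random_dna(L)
  rap_2 <- .mutate(rap_1, sample(setdiff(seq_len(L), variant_pos), 1L))
  hw_1  <- .random_dna(L)
  hw_2  <- .mutate(hw_1, sample(seq_len(L), 5L))
  dr_1  <- .mutate(hw_1, sample(seq_len(L), 22L))  # ~93.1 % identity to hw_1
  chl_1 <- .random_dna(L)

  haplotypes <- data.frame(
    taxon = c("Ancylonema_nordenskioeldii", "Ancylonema_nordenskioeldii",
              "Raphidonema_sempervirens", "Raphidonema_sempervirens",
              "Chlamydomonadaceae_HW0117", "Chlamydomonadaceae_HW0117",
              "Chlamydomonadaceae_DR1P27", "Chloromonas_polyptera"),
    variant = c("anc_A", "anc_C", "rap_1", "rap_2", "hw_1", "hw_2",
                "dr_1", "chl_1"),
    residues = c(anc_a, anc_c, rap_1, rap_2, hw_1, hw_2, dr_1, chl_1),
    stringsAsFactors = FALSE)

  sites <- data.frame(
    sample_label = c("GrIS16_5", "GrIS16_6", "GrIS16_12",
                     "GrIS16_2", "GrIS16_3", "GrIS16_10"),
    sample_type = c("dirty_ice", "dirty_ice", "clean_ice",
                    "dirty_ice", "dirty_ice", "dirty_ice"),
    site = c("base_camp", "base_camp", "base_camp", "2", "3", "3"),
    depth = rep(10000L, 6L),
    stringsAsFactors = FALSE)

  ## Taxon-level proportions (dominant taxon 92 %); within-taxon splits:
  ## dominant 70/30 at base camp, 30/70 inland; minors fixed everywhere.
  taxon_prop <- c(anc = 0.92, rap = 0.042, hw = 0.015, dr = 0.013,
                  chl = 0.010)
  mix_for <- function(anc_a_frac) c(
    anc_A = taxon_prop[["anc"]] * anc_a_frac,
    anc_C = taxon_prop[["anc"]] * (1 - anc_a_frac),
    rap_1 = taxon_prop[["rap"]] * 0.75,
    rap_2 = taxon_prop[["rap"]] * 0.25,
    hw_1  = taxon_prop[["hw"]] * 0.80,
    hw_2  = taxon_prop[["hw"]] * 0.20,
    dr_1  = taxon_prop[["dr"]],
    chl_1 = taxon_prop[["chl"]])
  is_base_camp <- sites$site == "base_camp"
  mixing <- vapply(is_base_camp,
                   function(bc) mix_for(if (bc) 0.70 else 0.30),
                   numeric(nrow(haplotypes)))
  dimnames(mixing) <- list(haplotypes$variant, sites$sample_label)

  ## References: one per taxon (identical to its first haplotype), plus a
  ## Mesotaenium-like near neighbour two substitutions away from anc_C so
  ## the C oligotype reports 99.7 %/99.4 % best/second-best identities.
  mes <- .mutate(anc_c, sample(setdiff(seq_len(L), 101L), 2L))
  references <- data.frame(
    ref_id = c("AF514397", "JF430424", "KM870611", "GU117575", "GU117586",
               "FR865586"),
    taxon = c("Ancylonema_nordenskioeldii", "Mesotaenium_berggrenii",
              "Raphidonema_sempervirens", "Chlamydomonadaceae_HW0117",
              "Chlamydomonadaceae_DR1P27", "Chloromonas_polyptera"),
    residues = c(anc_a, mes, rap_1, hw_1, dr_1, chl_1),
    stringsAsFactors = FALSE)

  new("SynthConfig", name = "gris_transect", haplotypes = haplotypes,
      sites = sites, mixing = mixing, errorRate = 0.005,
      qualityModel = qmodel, flank5 = flank5, flank3 = flank3,
      references = references, seed = 1016L)
}

.preset_single_taxon <- function(L, flank5, flank3, qmodel) {
  hap <- .random_dna(L)
  haplotypes <- data.frame(taxon = "Ancylonema_nordenskioeldii",
                           variant = "anc_A", residues = hap,
                           stringsAsFactors = FALSE)
  sites <- data.frame(sample_label = "GrIS16_5", sample_type = "dirty_ice",
                      site = "base_camp", depth = 10000L,
                      stringsAsFactors = FALSE)
  mixing <- matrix(1, 1, 1, dimnames = list("anc_A", "GrIS16_5"))
  references <- data.frame(ref_id = "AF514397",
                           taxon = "Ancylonema_nordenskioeldii",
                           residues = hap, stringsAsFactors = FALSE)
  new("SynthConfig", name = "single_taxon", haplotypes = haplotypes,
      sites = sites, mixing = mixing, errorRate = 0,
      qualityModel = qmodel, flank5 = flank5, flank3 = flank3,
      references = references, seed = 1016L)
}

.preset_noise_only <- function(L, flank5, flank3, qmodel) {
  cfg <- .preset_single_taxon(L, flank5, flank3, qmodel)
  cfg@name <- "noise_only"
  cfg@errorRate <- 0.01
  validObject(cfg)
  cfg
}

#' Simulate merged amplicon reads from a synthetic community
#'
#' Each read is drawn from one haplotype according to its sample's mixing
#' proportions; every base is independently substituted with probability
#' \code{errorRate} (uniformly over the three other bases). Per-base Phred
#' qualities are drawn around the positional quality model with a per-read
#' offset, giving the Q20 filter realistic casualties. The returned ground
#' truth records the source haplotype of every read and the realized
#' per-sample haplotype counts. Fixed seed implies byte-identical output.
#'
#' @param config A \linkS4class{SynthConfig}, e.g. from
#'   \code{\link{buildPreset}}.
#' @param seed Integer RNG seed; defaults to \code{config@seed}.
#' @return A \linkS4class{SimulatedCommunity}.
#' @examples
#' sim <- simulateCommunity(buildPreset("single_taxon"))
#' sim
#' @export
simulateCommunity <- function(config, seed = config@seed) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  if (sum(config@sites$depth) < 1L)
    stop("total depth across all sites is zero; nothing to simulate")
  .with_seed(seed, .simulate_impl(config))
}

.simulate_impl <- function(config) {
  h <- config@haplotypes
  full <- paste0(config@flank5, h$residues, config@flank3)
  L <- nchar(full[1])
  hap_chars <- do.call(rbind, strsplit(full, ""))  # haplotype x position

  ## base -> 3 alternatives lookup for vectorized substitution
  alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
               c("A", "C", "T"), c("A", "C", "G"))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  qmap <- vapply(0:41, function(q) rawToChar(as.raw(q + 33L)), "")

  sites <- config@sites
  all_seq <- all_qual <- all_id <- all_sample <- vector("list", nrow(sites))
  truth <- vector("list", nrow(sites))
  hap_counts <- matrix(0L, nrow(h), nrow(sites),
                       dimnames = list(h$variant, sites$sample_label))

  for (s in seq_len(nrow(sites))) {
    n <- sites$depth[s]
    smp <- sites$sample_label[s]
    idx <- sample.int(nrow(h), n, replace = TRUE, prob = config@mixing[, s])
    m <- hap_chars[idx, , drop = FALSE]
    if (config@errorRate > 0) {
      hit <- which(runif(n * L) < config@errorRate)
      if (length(hit))
        m[hit] <- alt[cbind(base_idx[m[hit]],
                            sample.int(3L, length(hit), replace = TRUE))]
    }
    q <- round(matrix(config@qualityModel, n, L, byrow = TRUE) +
               rnorm(n, sd = .READ_QUALITY_SD) +
               matrix(rnorm(n * L, sd = .BASE_QUALITY_SD), n, L))
    q[q < 2L] <- 2L; q[q > 40L] <- 40L
    qc <- matrix(qmap[q + 1L], n, L)

    all_seq[[s]] <- do.call(paste0, lapply(seq_len(L),
                                           function(j) m[, j]))
    all_qual[[s]] <- do.call(paste0, lapply(seq_len(L),
                                            function(j) qc[, j]))
    all_id[[s]] <- sprintf("%s_read%06d", smp, seq_len(n))
    all_sample[[s]] <- rep(smp, n)
    hap_counts[, s] <- tabulate(idx, nbins = nrow(h))
    truth[[s]] <- data.frame(read_id = all_id[[s]], sample = smp,
                             taxon = h$taxon[idx], variant = h$variant[idx],
                             stringsAsFactors = FALSE)
  }

  seqs <- DNAStringSet(unlist(all_seq))
  names(seqs) <- unlist(all_id)
  reads <- AmpliconReadSet(seqs, unlist(all_sample),
                           qualities = unlist(all_qual))
  new("SimulatedCommunity", reads = reads,
      truth = do.call(rbind, truth), haplotypeCounts = hap_counts,
      config = config)
}

#' Write a simulated community to disk
#'
#' Emits one Phred+33 FASTQ per sample, a sample map TSV (sample_label,
#' sample_type, site), a ground-truth TSV (read_id, sample, taxon, variant)
#' and the labeled reference FASTA.
#'
#' @param sim A \linkS4class{SimulatedCommunity}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the character vector of files written.
#' @export
writeSimulatedReads <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedCommunity"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  reads <- sim@reads
  for (smp in sim@config@sites$sample_label) {
    sel <- sampleLabels(reads) == smp
    path <- file.path(dir, paste0(smp, ".fastq"))
    writeFastq(reads[sel], path)
    files <- c(files, path)
  }
  map_path <- file.path(dir, "sample_map.tsv")
  write.table(sim@config@sites[, c("sample_label", "sample_type", "site")],
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth.tsv")
  write.table(sim@truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ref_path <- file.path(dir, "references.fasta")
  writeReferenceFasta(sim@config, ref_path)
  invisible(c(files, map_path, truth_path, ref_path))
}

#' Write a config's labeled reference FASTA
#'
#' Headers are \code{>ref_id taxon}; the taxon label is everything after the
#' first whitespace, matching what \code{\link{readReferenceFasta}} parses.
#'
#' @param config A \linkS4class{SynthConfig}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeReferenceFasta <- function(config, path) {
  stopifnot(is(config, "SynthConfig"))
  refs <- DNAStringSet(config@references$residues)
  names(refs) <- paste(config@references$ref_id, config@references$taxon)
  writeXStringSet(refs, path, width = 80L)
  invisible(path)
}

#' Position(s) at which two haplotypes of a config differ
#'
#' Convenience for synthetic-truth checks: the mismatching positions between
#' two named haplotype variants (1-based amplicon coordinates).
#'
#' @param config A \linkS4class{SynthConfig}.
#' @param v1,v2 Variant labels.
#' @return Integer vector of differing positions.
#' @export
haplotypeDiff <- function(config, v1, v2) {
  h <- config@haplotypes
  a <- strsplit(h$residues[match(v1, h$variant)], "")[[1]]
  b <- strsplit(h$residues[match(v2, h$variant)], "")[[1]]
  which(a != b)
}
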