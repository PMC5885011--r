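#' @include AllClasses.R
NULL

#' Run the full amplicon analysis pipeline
#'
#' Composes every stage: 3' trimming, quality filtering, (pass-through)
#' chimera stage, length normalization, dereplication, greedy OTU clustering
#' at the strict identity threshold, singleton removal, best-hit taxonomy,
#' community-table construction, per-taxon read extraction and
#' entropy-driven oligotype decomposition of the most abundant taxa.
#' All randomness upstream lives in the read generator; the pipeline itself
#' is deterministic, so re-running on the same inputs reproduces identical
#' tables.
#'
#' @param input A directory of per-sample FASTQ files, an
#'   \linkS4class{AmpliconReadSet}, or a \linkS4class{SimulatedCommunity}.
#' @param references Reference set: a named \code{DNAStringSet} (see
#'   \code{\link{readReferenceFasta}}) or a path to a labeled FASTA.
#' @param sampleMap Optional sample map data.frame or TSV path.
#' @param config Clean-up/clustering parameters from
#'   \code{\link{pipelineConfig}}.
#' @param oligoConfig Oligotyping parameters from
#'   \code{\link{oligotypeConfig}}.
#' @param nTopTaxa How many of the most abundant taxa (by assigned read
#'   count) to decompose (default 4).
#' @param minAssignIdentity Identity floor for taxonomic assignment.
#' @param outdir Optional output directory; when given, all tables, FASTA
#'   files and a JSON manifest are written there.
#' @return A \linkS4class{PipelineResult}.
#' @export
runPipeline <- function(input, references, sampleMap = NULL,
                        config = pipelineConfig(),
                        oligoConfig = oligotypeConfig(),
                        nTopTaxa = 4L, minAssignIdentity = 0.9,
                        outdir = NULL) {
  if (is.character(sampleMap)) sampleMap <- readSampleMap(sampleMap)
  if (is.character(references)) references <- readReferenceFasta(references)
  reads <- if (is(input, "SimulatedCommunity")) simulatedReads(input)
  else if (is(input, "AmpliconReadSet")) input
  else if (is.character(input) && dir.exists(input))
    readFastqDir(input, sampleMap)
  else stop("input must be a FASTQ directory, AmpliconReadSet or ",
            "SimulatedCommunity")
  if (length(reads) == 0L) stop("no input reads; nothing to analyse")

  reads <- trimReads3p(reads, config$forwardTrim3p)
  reads <- filterByQuality(reads, config$minQuality, config$qualityMode)
  reads <- suppressMessages(removeChimeras(reads))
  pm <- makePositionalMatrix(reads, config$oligoEndTrim,
                             config$targetLength)
  uniques <- dereplicate(pm)
  otus <- greedyCluster(uniques, config$otuIdentity)
  otus <- removeSingletons(otus)
  assignments <- assignBestHit(otus, references, minAssignIdentity)
  community <- buildCommunityTable(assignments, otus, sampleMap)

  ## per-taxon read extraction: map every matrix read to its (surviving)
  ## OTU's taxon, then decompose the most abundant taxa
  read_unique <- match(as.character(pm@reads),
                       as.character(otus@uniques@sequences))
  read_taxon <- assignments$taxon[otus@assignment[read_unique]]
  assigned_counts <- sort(tapply(
    rep(1L, sum(!is.na(read_taxon) & read_taxon != "unassigned")),
    read_taxon[!is.na(read_taxon) & read_taxon != "unassigned"], sum),
    decreasing = TRUE)
  top <- head(names(assigned_counts), nTopTaxa)
  oligos <- lapply(top, function(tx) {
    sel <- !is.na(read_taxon) & read_taxon == tx
    refineOligotypes(pm[sel], oligoConfig, taxon = tx)
  })
  names(oligos) <- top

  stage_counts <- pm@processLog
  stage_counts <- rbind(stage_counts, data.frame(
    stage = "singleton_removal",
    input = as.integer(sum(otus@counts) +
                       (otus@log$singleton_reads_removed %||% 0)),
    passed = as.integer(sum(otus@counts)),
    discarded = as.integer(otus@log$singleton_reads_removed %||% 0),
    stringsAsFactors = FALSE))

  manifest <- list(
    tool = paste("oligodecomp", as.character(utils::packageVersion("oligodecomp"))),
    parameters = c(config, oligoConfig,
                   list(nTopTaxa = nTopTaxa,
                        minAssignIdentity = minAssignIdentity)),
    stage_counts = stage_counts,
    samples = sort(unique(sampleLabels(pm))),
    decomposed_taxa = top,
    files = character(0))

  result <- new("PipelineResult", communityTable = community,
                assignments = assignments, otus = otus,
                oligotypes = oligos, stageCounts = stage_counts,
                manifest = manifest)
  if (!is.null(outdir)) result <- .write_outputs(result, references, outdir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_outputs <- function(result, references, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character()
  p <- function(...) file.path(outdir, paste0(...))

  write.table(result@stageCounts, p("stage_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, p("stage_counts.tsv"))
  writeAbundanceTable(result@communityTable, p("community_table.tsv"))
  files <- c(files, p("community_table.tsv"))
  write.table(result@assignments, p("assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, p("assignments.tsv"))
  write.table(otuMembership(result@otus), p("otu_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p("otu_membership.tsv"))
  writeXStringSet(result@otus@centroids, p("otu_representatives.fasta"),
                  width = 80L)
  files <- c(files, p("otu_representatives.fasta"))

  for (tx in names(result@oligotypes)) {
    oset <- result@oligotypes[[tx]]
    prof <- data.frame(position = seq_along(oset@profile@bits),
                       entropy_bits = sprintf("%.4f", oset@profile@bits))
    write.table(prof, p(tx, "_entropy.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeAbundanceTable(oligotypeTable(oset), p(tx, "_oligotypes.tsv"))
    noise <- data.frame(label = oset@noiseLabels,
                        count = rowSums(oset@noiseCounts))
    write.table(noise, p(tx, "_noise.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (length(oset@representatives)) {
      reps <- oset@representatives
      sim <- lapply(as.character(reps), nearestReference,
                    references = references)
      names(reps) <- sprintf("%s|%s nearest=%s identity=%.1f%%", tx,
                             oset@labels,
                             vapply(sim, `[[`, "", "ref_id"),
                             vapply(sim, `[[`, 0, "identity_percent"))
      writeXStringSet(reps, p(tx, "_oligotype_representatives.fasta"),
                      width = 80L)
      files <- c(files, p(tx, "_oligotype_representatives.fasta"))
    }
    files <- c(files, p(tx, "_entropy.tsv"), p(tx, "_oligotypes.tsv"),
               p(tx, "_noise.tsv"))
  }

  manifest <- result@manifest
  manifest$files <- files
  jsonlite::write_json(
    list(tool = manifest$tool,
         parameters = lapply(manifest$parameters, function(x)
           if (is.numeric(x) && !is.finite(x)) "unlimited" else x),
         stage_counts = manifest$stage_counts,
         samples = manifest$samples,
         decomposed_taxa = manifest$decomposed_taxa,
         files = basename(files)),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest$files <- c(files, p("manifest.json"))
  stopifnot(all(file.exists(manifest$files)))
  initialize(result, manifest = manifest)
}

#' Presence/absence and mean abundance of oligotypes by site
#'
#' Summarizes, for every kept oligotype of every decomposed taxon, whether
#' it occurs at each site (abundance > 0 in any of the site's samples) and
#' its mean relative abundance there.
#'
#' @param result A \linkS4class{PipelineResult} (or a named list of
#'   \linkS4class{OligotypeSet}s).
#' @param sampleMap Sample map data.frame mapping sample_label to site.
#' @return data.frame with columns taxon, oligotype, site, present,
#'   mean_abundance.
#' @export
summarizeOligotypeSharing <- function(result, sampleMap) {
  osets <- if (is(result, "PipelineResult")) result@oligotypes else result
  rows <- list()
  for (tx in names(osets)) {
    tab <- oligotypeTable(osets[[tx]])
    if (nrow(tab) == 0L || ncol(tab) == 0L) next
    site <- sampleMap$site[match(rownames(tab), sampleMap$sample_label)]
    for (lb in colnames(tab)) {
      ab <- tapply(tab[, lb], site, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, oligotype = lb, site = names(ab),
        present = as.vector(tapply(tab[, lb], site, function(x)
          any(x > 0))),
        mean_abundance = as.vector(ab), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(taxon = character(), oligotype = character(),
                      site = character(), present = logical(),
                      mean_abundance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
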