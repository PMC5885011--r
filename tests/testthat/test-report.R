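## Small end-to-end fixtures run the whole pipeline at reduced depth so the
## suite stays fast; the full preset-scale run lives in the acceptance tests.

write_refs <- function(cfg) {
  p <- tempfile(fileext = ".fasta")
  writeReferenceFasta(cfg, p)
  readReferenceFasta(p)
}

test_that("noiseless single-taxon run yields one OTU, zero components, one oligotype", {
  cfg <- buildPreset("single_taxon")
  sim <- simulateCommunity(cfg, seed = 5L)
  res <- runPipeline(sim, write_refs(cfg))
  expect_equal(length(res@otus), 1L)
  expect_equal(unname(res@communityTable[1, "Ancylonema_nordenskioeldii"]),
               1)
  oset <- res@oligotypes[[1]]
  expect_length(oligoComponents(oset), 0L)
  expect_equal(length(oset), 1L)
})

test_that("pipeline runs from FASTQ files on disk and writes a complete manifest", {
  set.seed(701)
  haps <- c(random_seq(360), mutate_at(random_seq(360), 50))
  cfg <- make_config(haps, depth = c(300, 300), error = 0,
                     mixing = matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2),
                     samples = c("sA", "sB"),
                     taxon = c("TaxOne", "TaxOne"), seed = 13L)
  ## flanked read structure so the default trims apply
  cfg@qualityModel <- rep(38, 360)
  sim <- simulateCommunity(cfg)
  dir <- tempfile(); outdir <- tempfile()
  writeSimulatedReads(sim, dir)
  res <- runPipeline(dir, file.path(dir, "references.fasta"),
                     sampleMap = file.path(dir, "sample_map.tsv"),
                     config = pipelineConfig(forwardTrim3p = 20,
                                             oligoEndTrim = 10,
                                             targetLength = 320),
                     outdir = outdir)
  expect_true(all(file.exists(res@manifest$files)))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  expect_true(file.exists(file.path(outdir, "community_table.tsv")))
  ## table on disk matches the in-memory table at print precision
  back <- readAbundanceTable(file.path(outdir, "community_table.tsv"))
  expect_equal(back, round(res@communityTable, 4), tolerance = 1e-9)
  ## re-running writes byte-identical tables
  outdir2 <- tempfile()
  runPipeline(dir, file.path(dir, "references.fasta"),
              sampleMap = file.path(dir, "sample_map.tsv"),
              config = pipelineConfig(), outdir = outdir2)
  expect_identical(readLines(file.path(outdir, "community_table.tsv")),
                   readLines(file.path(outdir2, "community_table.tsv")))
})

test_that("reads entering oligotyping telescope exactly from the OTU stage", {
  set.seed(702)
  haps <- c(random_seq(320), mutate_at(random_seq(320), 10))
  cfg <- make_config(haps, depth = 500, error = 0.002,
                     mixing = matrix(c(0.8, 0.2), 2, 1),
                     taxon = c("TaxOne", "TaxTwo"), seed = 17L)
  sim <- simulateCommunity(cfg)
  res <- runPipeline(sim, write_refs(cfg),
                     config = pipelineConfig(forwardTrim3p = 0,
                                             oligoEndTrim = 0),
                     oligoConfig = oligotypeConfig(minOligotypeCount = 5))
  ## for each decomposed taxon, kept + noise + N-bucket reads equal the
  ## post-singleton counts of the OTUs assigned to that taxon
  otu_taxon <- res@assignments$taxon
  for (tx in names(res@oligotypes)) {
    oset <- res@oligotypes[[tx]]
    in_oligo <- sum(sampleCounts(oset)) + sum(noiseCounts(oset)) +
      sum(oset@nBucket)
    from_otus <- sum(sampleCounts(res@otus)[otu_taxon == tx, , drop = FALSE])
    expect_equal(in_oligo, from_otus)
  }
  ## stage counts telescope throughout
  log <- res@stageCounts
  expect_equal(log$input, log$passed + log$discarded)
})

test_that("empty input fails before any stage runs", {
  dir <- tempfile(); dir.create(dir)
  refs <- Biostrings::DNAStringSet(c(R = strrep("A", 320)))
  expect_error(runPipeline(dir, refs), "no FASTQ files")
  expect_error(runPipeline("not-a-dir-or-object", refs), "input must be")
})

test_that("oligotype sharing summary flags site-exclusive oligotypes", {
  set.seed(703)
  hap <- random_seq(320)
  hapB <- mutate_at(hap, 100)
  hapC <- mutate_at(hap, 200)
  ## hapC ('base-camp-only' analogue) appears only in samples from one site
  mixing <- matrix(c(0.6, 0.4, 0.0,
                     0.5, 0.3, 0.2), 3, 2)
  cfg <- make_config(c(hap, hapB, hapC), depth = c(400, 400), error = 0,
                     mixing = mixing, samples = c("inland1", "bc1"),
                     taxon = rep("TaxOne", 3), seed = 19L)
  cfg@sites$site <- c("inland", "base_camp")
  sim <- simulateCommunity(cfg)
  res <- runPipeline(sim, write_refs(cfg),
                     config = pipelineConfig(forwardTrim3p = 0,
                                             oligoEndTrim = 0),
                     oligoConfig = oligotypeConfig(minOligotypeCount = 5))
  sharing <- summarizeOligotypeSharing(res, cfg@sites)
  expect_true(all(c("taxon", "oligotype", "site", "present",
                    "mean_abundance") %in% names(sharing)))
  ## exactly one (oligotype, site) pair is absent: hapC's label inland
  expect_equal(sum(!sharing$present), 1L)
  absent <- sharing[!sharing$present, ]
  expect_identical(absent$site, "inland")
})
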