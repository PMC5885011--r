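test_that("column counts tally A/C/G/T and route N aside", {
  pm <- make_pm(c(rep("AAT", 6), rep("CAT", 4)))
  cc <- columnCounts(pm, 1)
  expect_equal(unname(cc[c("A", "C")]), c(6L, 4L))
  expect_equal(attr(cc, "nCount"), 0L)
  pmN <- make_pm(c(rep("ATG", 9), "NTG"))
  ccN <- columnCounts(pmN, 1)
  expect_equal(unname(ccN["A"]), 9L)
  expect_equal(attr(ccN, "nCount"), 1L)
  expect_error(columnCounts(pm, 4), "out of range")
  expect_error(columnCounts(pm, 0), "out of range")
})

test_that("Shannon entropy closed forms: monomorphic 0, balanced biallelic 1, skewed noise boundary", {
  expect_equal(shannonEntropy(c(A = 10)), 0)
  expect_equal(shannonEntropy(c(A = 5, C = 5)), 1)
  ## direct-formula oracle for the 97/1/1/1 composition near the noise edge
  oracle <- -(0.97 * log2(0.97) + 3 * (0.01 * log2(0.01)))
  expect_equal(shannonEntropy(c(A = 97, C = 1, G = 1, T = 1)), oracle)
  expect_equal(round(oracle, 4), 0.2419)
  ## uniform four-base composition reaches the 2-bit ceiling
  expect_equal(shannonEntropy(c(A = 5, C = 5, G = 5, T = 5)), 2)
  expect_warning(h0 <- shannonEntropy(c(A = 0)), "zero-total")
  expect_equal(h0, 0)
  expect_error(shannonEntropy(c(A = -1)), "non-negative")
})

test_that("entropy profile: zero for identical reads, a 1-bit spike at a balanced variant site", {
  set.seed(601)
  hap <- random_seq(120)
  pm <- make_pm(rep(hap, 20))
  prof <- entropyProfile(pm)
  expect_equal(entropyValues(prof), rep(0, 120))
  ## two haplotypes 50/50 differing only at position 100
  hap2 <- mutate_at(hap, 100)
  pm2 <- make_pm(c(rep(hap, 10), rep(hap2, 10)))
  bits <- entropyValues(entropyProfile(pm2))
  expect_equal(bits[100], 1)
  expect_equal(bits[-100], rep(0, 119))
  expect_error(entropyProfile(make_pm(character(0))), "empty")
})

test_that("noise columns stay at or below 0.2 bits at 1 % error and kilo-read depth", {
  set.seed(602)
  hap <- random_seq(40)
  cfg <- make_config(hap, depth = 2000, error = 0.01, seed = 71L)
  for (s in 1:10) {
    sim <- simulateCommunity(cfg, seed = 7000L + s)
    pm <- make_pm(as.character(readSequences(sim)))
    expect_true(all(entropyValues(entropyProfile(pm)) <= 0.2))
  }
})

test_that("component selection filters and orders like the brute-force oracle", {
  prof <- new("EntropyProfile", bits = c(0, 0.95, 0.1, 0.3),
              nCount = integer(4))
  expect_identical(selectComponents(prof, oligotypeConfig()), c(2L, 4L))
  expect_identical(
    selectComponents(prof, oligotypeConfig(componentOrder = "position_asc")),
    c(2L, 4L))
  expect_identical(
    selectComponents(prof, oligotypeConfig(maxComponents = 1)), 2L)
  ## all-zero profile -> empty selection
  expect_length(selectComponents(new("EntropyProfile", bits = numeric(4),
                                     nCount = integer(4)),
                                 oligotypeConfig()), 0L)
  ## threshold 0 on a strictly positive profile selects all, entropy-ordered
  profp <- new("EntropyProfile", bits = c(0.3, 0.9, 0.5),
               nCount = integer(3))
  expect_identical(
    selectComponents(profp, oligotypeConfig(entropyThreshold = 0)),
    c(2L, 3L, 1L))
  ## randomized agreement with the oracle
  set.seed(603)
  for (rep in 1:20) {
    bits <- round(runif(15, 0, 1.2), 3)
    p <- new("EntropyProfile", bits = pmin(bits, 2), nCount = integer(15))
    for (ord in c("entropy_desc", "position_asc")) {
      cfgo <- oligotypeConfig(entropyThreshold = 0.2, componentOrder = ord)
      expect_identical(selectComponents(p, cfgo),
                       as.integer(oracle_select(p@bits, 0.2, ord)))
    }
  }
})

test_that("decomposition partitions reads by component residues with an N-bucket", {
  set.seed(604)
  hap <- random_seq(150)
  hapA <- mutate_at(hap, 100, to = "A")
  hapC <- mutate_at(hap, 100, to = "C")
  pm <- make_pm(c(rep(hapA, 60), rep(hapC, 40)))
  dec <- decomposeMatrix(pm, 100L)
  expect_equal(sum(dec$labels == "A"), 60L)
  expect_equal(sum(dec$labels == "C"), 40L)
  ## multi-component label construction
  r <- mutate_at(mutate_at(hap, 5, to = "A"), 9, to = "G")
  decm <- decomposeMatrix(make_pm(r), c(5L, 9L))
  expect_identical(decm$labels, "AG")
  ## N at a component routes the read to the N-bucket
  rn <- paste0(substr(hapA, 1, 99), "N", substr(hapA, 101, 150))
  decn <- decomposeMatrix(make_pm(c(hapA, rn)), 100L)
  expect_identical(decn$labels, c("A", NA))
  expect_identical(decn$nBucket, c(FALSE, TRUE))
  expect_error(decomposeMatrix(pm, integer(0)), "selectComponents")
  ## randomized agreement with the substr oracle
  for (rep in 1:10) {
    seqs <- vapply(1:15, function(i) {
      s <- random_seq(20)
      if (runif(1) < 0.3) s <- sub("A", "N", s)
      s
    }, "")
    comps <- sort(sample(20, 3))
    dec <- decomposeMatrix(make_pm(seqs), comps)
    expect_identical(dec$labels, oracle_decompose(seqs, comps))
  }
})

test_that("noise filtering applies the max(count, fraction) floor with a >= rule", {
  cfg <- oligotypeConfig(minOligotypeCount = 10,
                         minOligotypeFraction = 0.001)
  flt <- filterNoise(c(A = 990, G = 7, T = 3), cfg, taxonTotal = 1000)
  expect_identical(flt$kept, "A")
  expect_setequal(flt$noise, c("G", "T"))
  ## a group exactly at the floor is kept
  flt2 <- filterNoise(c(A = 90, C = 10), cfg, taxonTotal = 100)
  expect_setequal(flt2$kept, c("A", "C"))
  ## a lone group always stands
  flt3 <- filterNoise(c(A = 3), cfg, taxonTotal = 3)
  expect_identical(flt3$kept, "A")
  ## fraction term dominates at depth: 0.001 * 20000 = 20 > 10
  flt4 <- filterNoise(c(A = 19980, C = 15), cfg, taxonTotal = 20000)
  expect_identical(flt4$noise, "C")
})

test_that("refinement recovers two haplotypes in one pass and stops on monomorphic input", {
  set.seed(605)
  hap <- random_seq(100)
  hapA <- mutate_at(hap, 40, to = "A")
  hapC <- mutate_at(hap, 40, to = "C")
  pm <- make_pm(c(rep(hapA, 30), rep(hapC, 20)),
                sample = rep(c("s1", "s2"), each = 25))
  cfg <- oligotypeConfig(minOligotypeCount = 2)
  oset <- refineOligotypes(pm, cfg, taxon = "t")
  expect_equal(oligoComponents(oset), 40L)
  expect_setequal(oligotypeLabels(oset), c("A", "C"))
  expect_equal(oset@iterations, 1L)
  expect_equal(sum(sampleCounts(oset)), 50)
  ## representatives are real member sequences
  expect_setequal(as.character(representatives(oset)), c(hapA, hapC))
  ## monomorphic matrix: no components, one trivial group
  m <- refineOligotypes(make_pm(rep(hap, 10)), cfg, taxon = "t")
  expect_length(oligoComponents(m), 0L)
  expect_identical(oligotypeLabels(m), "")
  expect_equal(sum(sampleCounts(m)), 10)
})

test_that("refinement splits nested haplotypes hidden below the global entropy floor", {
  set.seed(606)
  base <- random_seq(80)
  p1 <- 20L; p2 <- 60L
  hapC <- mutate_at(mutate_at(base, p1, to = "C"), p2, to = "G")
  hapAG <- mutate_at(mutate_at(base, p1, to = "A"), p2, to = "G")
  hapAT <- mutate_at(mutate_at(base, p1, to = "A"), p2, to = "T")
  ## 400 C..G + 10 A..G + 10 A..T: globally, p2 entropy (410:10) is under
  ## 0.2 bits, but within the 'A' group it is a balanced 1-bit split
  pm <- make_pm(c(rep(hapC, 400), rep(hapAG, 10), rep(hapAT, 10)))
  glob <- entropyValues(entropyProfile(pm))
  expect_gt(glob[p1], 0.2)
  expect_lt(glob[p2], 0.2)
  cfg <- oligotypeConfig(minOligotypeCount = 5,
                         minOligotypeFraction = 0.005)
  oset <- refineOligotypes(pm, cfg, taxon = "t")
  ## hand-enumerated oracle: three final groups, components {p1, p2}
  expect_setequal(oligoComponents(oset), c(p1, p2))
  expect_setequal(oligotypeLabels(oset), c("CG", "AG", "AT"))
  expect_equal(unname(rowSums(sampleCounts(oset))[
    order(oligotypeLabels(oset))]), c(10, 10, 400))
  expect_gte(oset@iterations, 2L)
})

test_that("kept, noise and N-bucket reads partition the taxon exactly", {
  set.seed(607)
  hap <- random_seq(60)
  hapB <- mutate_at(hap, 30)
  reads <- c(rep(hap, 120), rep(hapB, 60),
             vapply(1:8, function(i) mutate_at(hap, sample(60, 2)), ""),
             sub("^.", "N", rep(hap, 3)))
  pm <- make_pm(reads, sample = sample(c("s1", "s2"), length(reads),
                                       replace = TRUE))
  oset <- refineOligotypes(pm, oligotypeConfig(minOligotypeCount = 10,
                                               minOligotypeFraction = 0.01),
                           taxon = "t")
  total <- sum(sampleCounts(oset)) + sum(noiseCounts(oset)) +
    sum(oset@nBucket)
  expect_equal(total, length(pm))
})

test_that("oligotype tables are per-sample relative abundances summing to 1", {
  set.seed(608)
  hap <- random_seq(50)
  hapB <- mutate_at(hap, 25)
  pm <- make_pm(c(rep(hap, 70), rep(hapB, 30)),
                sample = c(rep("s1", 50), rep("s2", 50)))
  oset <- refineOligotypes(pm, oligotypeConfig(minOligotypeCount = 2),
                           taxon = "t")
  tab <- oligotypeTable(oset)
  expect_equal(unname(rowSums(tab)), c(1, 1))
  expect_equal(dim(tab), c(2L, 2L))
  ## a sample absent from the map is an error
  map <- data.frame(sample_label = "s1", sample_type = "x", site = "y")
  expect_error(oligotypeTable(oset, sampleMap = map), "absent")
})

test_that("nearest reference reports one-decimal percent similarities", {
  set.seed(609)
  ref <- random_seq(320)
  refs <- Biostrings::DNAStringSet(c(R1 = ref,
                                     R2 = mutate_at(ref, c(3, 5, 7))))
  attr(refs, "taxon") <- c(R1 = "TaxR1", R2 = "TaxR2")
  exact <- nearestReference(ref, refs)
  expect_identical(exact$ref_id, "R1")
  expect_equal(exact$identity_percent, 100)
  one <- nearestReference(mutate_at(ref, 100), refs)
  expect_equal(one$identity_percent, 99.7)
  two <- nearestReference(mutate_at(ref, c(100, 200)), refs)
  expect_equal(two$identity_percent, 99.4)
  expect_error(nearestReference(ref, Biostrings::DNAStringSet()), "empty")
})

test_that("decomposition is deterministic for identical inputs", {
  set.seed(610)
  hap <- random_seq(60)
  reads <- c(rep(hap, 40), rep(mutate_at(hap, 15), 25),
             vapply(1:6, function(i) mutate_at(hap, sample(60, 1)), ""))
  pm <- make_pm(reads, sample = rep(c("a", "b"), length.out = length(reads)))
  cfg <- oligotypeConfig(minOligotypeCount = 5)
  o1 <- refineOligotypes(pm, cfg, taxon = "t")
  o2 <- refineOligotypes(pm, cfg, taxon = "t")
  expect_identical(oligotypeLabels(o1), oligotypeLabels(o2))
  expect_identical(sampleCounts(o1), sampleCounts(o2))
  expect_identical(as.character(representatives(o1)),
                   as.character(representatives(o2)))
})
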