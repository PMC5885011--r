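# oligodecomp

Shannon-entropy oligotyping of amplicon communities, with a synthetic
community generator for end-to-end verification.

## What problem this solves

High-throughput amplicon surveys of low-diversity communities — the
motivating case is 18S rRNA V4–V5 profiling of ice-algal communities on
glacial surfaces — hit a resolution wall: organisms whose amplicons differ
by a single nucleotide collapse into one OTU even at a strict 99 %
similarity threshold. Oligotyping recovers this hidden diversity by scoring
every alignment column with its Shannon entropy,

H = −Σ<sub>b∈{A,C,G,T}</sub> p<sub>b</sub> log₂ p<sub>b</sub>,

and partitioning reads by their residues at the highest-entropy columns
only. A monomorphic column scores 0 bits and a balanced biallelic column 1
bit, while independent substitution errors keep non-variant columns at or
below ~0.2 bits — so columns above that threshold carry genomic signal, and
groups of reads sharing residues there ("oligotypes") can separate
haplotypes a single base apart from sequencing noise.

The package implements the complete chain as composable, tested stages:

1. **Clean-up** — 3' trimming, mean-Q20 quality filtering, symmetric end
   trims and truncation to a fixed 320-nt positional window.
2. **OTU clustering** — dereplication, abundance-sorted greedy centroid
   clustering at 99 % identity (94.9 % for ITS2-like data), singleton
   removal.
3. **Taxonomy** — exhaustive best-hit percent identity against a labeled
   reference FASTA; sample × taxon relative-abundance tables.
4. **Oligotyping** — per-taxon entropy profiles, component selection,
   decomposition with noise filtering and an N-bucket, and iterative
   refinement until no group conceals further above-threshold entropy.
5. **Synthetic data** — a generator (`buildPreset("gris_transect")`)
   emulating a glacier-transect survey: one dominant taxon (92 % of reads)
   with two haplotypes one nucleotide apart mixed 70/30 vs 30/70 by site,
   minor taxa at 1–4 %, substitution errors, and realistic quality strings.

## Worked example

```r
library(oligodecomp)
cfg <- buildPreset("gris_transect")
sim <- simulateCommunity(cfg)            # uses the preset seed
ref_path <- tempfile(fileext = ".fasta")
writeReferenceFasta(cfg, ref_path)
res <- runPipeline(sim, ref_path, sampleMap = cfg@sites)
res
#> PipelineResult: 6 sample(s), 5 taxa, 724 OTUs, 4 taxon/taxa oligotyped
#> stages:
#>                 stage input passed discarded
#>           trim_3prime 60000  60000         0
#>        quality_filter 60000  59740       260
#>       chimera_removal 59740  59740         0
#>  length_normalization 59740  59740         0
#>     singleton_removal 59740  52768      6972
```

The community table recovers the configured 92 % dominant-taxon share per
sample:

```r
round(res@communityTable[, 1:2], 3)
#>           Ancylonema_nordenskioeldii Raphidonema_sempervirens
#> GrIS16_10                      0.921                    0.039
#> GrIS16_12                      0.914                    0.044
#> GrIS16_2                       0.919                    0.041
#> GrIS16_3                       0.923                    0.039
#> GrIS16_5                       0.914                    0.045
#> GrIS16_6                       0.918                    0.043
```

Oligotyping the dominant taxon finds exactly the two simulated haplotypes,
labeled by their bases at the single variant position (column 101), and
their site-flipped distribution — inland samples (GrIS16_2/3/10) majority
'C', base-camp samples (GrIS16_5/6/12) majority 'A':

```r
anc <- res@oligotypes[["Ancylonema_nordenskioeldii"]]
anc
#> OligotypeSet [Ancylonema_nordenskioeldii]: 2 kept oligotype(s) over 1 component(s) (positions 101)
#>   labels: C, A
#>   noise groups: 2; N-bucket reads: 0; iterations: 1
round(oligotypeTable(anc), 3)
#>               C     A
#> GrIS16_10 0.723 0.277
#> GrIS16_12 0.323 0.677
#> GrIS16_2  0.726 0.274
#> GrIS16_3  0.719 0.281
#> GrIS16_5  0.320 0.680
#> GrIS16_6  0.320 0.680
nearestReference(representatives(anc)[["C"]],
                 readReferenceFasta(ref_path))[c("ref_id", "identity_percent")]
#> $ref_id
#> [1] "AF514397"
#> $identity_percent
#> [1] 99.7
```

The 'C' representative sits one mismatch from the dominant-taxon reference
(319/320 matches prints as 99.7 %); the 'A' representative is identical to
it (100 %).

A thin command-line wrapper lives in `inst/scripts/oligodecomp.R`
(`simulate` and `run` subcommands); `runPipeline(..., outdir = ...)` writes
all tables, FASTA files and a JSON manifest.

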