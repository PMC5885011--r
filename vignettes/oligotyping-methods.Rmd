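---
title: "Entropy-based oligotyping of amplicon communities: methods and design"
author: "oligodecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based oligotyping of amplicon communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligodecomp)
```

## The problem

Conventional amplicon analysis bins reads into operational taxonomic units
(OTUs) at a fixed similarity threshold. Even a strict 99 % threshold cannot
separate organisms whose marker genes differ at a single nucleotide of the
sequenced fragment — a situation that is the rule, not the exception, for
the 18S rRNA V4–V5 region of closely related ice- and snow-algal lineages.
Oligotyping addresses this by asking, per alignment column, how much
information the column carries, and then partitioning reads by their
residues at the most informative columns only.

`oligodecomp` implements the full chain at desk scale: read clean-up, de
novo OTU clustering, best-hit taxonomy, per-taxon extraction, and
Shannon-entropy oligotype decomposition, together with a synthetic read
generator that reproduces the statistical structure this analysis assumes,
so every stage is testable without touching external archives.

## The entropy model

For one alignment column with nucleotide frequencies $p_A, p_C, p_G, p_T$
(N residues excluded from the denominator), the Shannon entropy in bits is

$$H = -\sum_{b \in \{A,C,G,T\}} p_b \log_2 p_b.$$

A monomorphic column has $H = 0$; a balanced biallelic column has exactly
$H = 1$ bit, which is the practical ceiling in amplicon data (columns are
effectively biallelic), while the theoretical four-base maximum is 2 bits.
Independent substitution errors at realistic Illumina rates leave
non-variant columns at or below roughly 0.2 bits: with error rate $e$ the
expected composition of a noise column is $(1 - e)$ on the true base and
$e/3$ on each other base, giving for example $H \approx 0.097$ bits at
$e = 0.01$ and $H \approx 0.053$ bits at $e = 0.005$. Positions above the
0.2-bit threshold are therefore treated as genomic signal and become
**components**; reads are labeled by their residues at the components, and
the resulting groups are the oligotypes.

```{r entropy}
shannonEntropy(c(A = 500, C = 500))        # balanced biallelic: 1 bit
shannonEntropy(c(A = 9900, C = 33, G = 33, T = 34))  # 1 % noise column
```

## Decomposition and refinement

The decomposition is iterative. An initial profile over the taxon's
positional matrix selects all columns above the entropy threshold. After
partitioning and noise filtering, the entropy profile of each kept group is
recomputed over the remaining columns: variation that is rare globally but
concentrated in one group (a nested haplotype) produces a high-entropy
column *within* that group even when the global column sits below
threshold. Any such column joins the *global* component set — so labels
stay fixed-length strings per taxon — and the matrix is re-partitioned.
Decomposition stops when no kept group conceals a column above the
threshold, or when an iteration leaves the partition unchanged; since the
component set grows monotonically and is bounded by the matrix width,
termination is guaranteed.

Reads carrying an N at any component go to an N-bucket and join no group;
kept groups, noise groups and the N-bucket form an exact partition of the
taxon's reads, an invariant asserted by the test suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `entropyThreshold` | 0.2 bits | noise ceiling for component selection |
| `minOligotypeCount` | 10 reads | absolute floor for a kept group |
| `minOligotypeFraction` | 0.005 | relative floor, fraction of taxon reads |
| `componentOrder` | entropy_desc | label ordering convention |
| `otuIdentity` | 0.99 | de novo clustering threshold (0.949 for ITS2-like data) |
| `minQuality` | Q20 | Phred threshold for read filtering |

The relative noise floor deserves a note. A substitution error at a
component position converts a read's label with probability $e/3$ per
alternative base, so spurious label groups appear at a relative abundance
of about $e/3$ — 0.17 % at $e = 0.5$ %. The kept/noise floor must clear
this artifact rate; the default of 0.5 % leaves a threefold margin at that
error rate while still admitting genuinely rare variants well below the
abundance of the oligotypes reported in comparable field studies. Both the
absolute and the relative floor are exposed in `oligotypeConfig()`.

Two readings of a "minimum Phred quality score of Q20" filter are possible:
a mean-quality rule and a per-base rule. The per-base rule discards nearly
every read under realistic 3' quality decay, so the mean rule is the
default and both are available (`qualityMode = "mean"` or `"min"`).

## The synthetic generator

`buildPreset("gris_transect")` encodes the community structure the analysis
targets: a dominant taxon at 92 % of reads carrying two haplotypes that
differ at exactly one position of a 320-nt amplicon (forced to A versus C,
so the oligotype labels read 'A' and 'C'), mixed 70/30 in three
base-camp-like samples and 30/70 in three inland-like samples; four minor
taxa at 1–4.2 % whose haplotype sets span 93–99.7 % mutual identity, so the
99 % OTU threshold is exercised on both sides; i.i.d. substitution errors
at 0.5 %; and 10 000 reads per sample. Depths of 10 000–50 000 reads per
sample are the intended desk-scale regime; 10 000 keeps a six-sample run
around half a minute on one core while leaving binomial 3σ bands around the
mixing proportions at about ±1.5 percentage points — tight enough to make
recovery checks meaningful.

Reads are emitted merged and full-length as `flank5 | amplicon | flank3`
(10 + 320 + 30 nt): the flanks emulate the error-prone read ends and the
low-quality 3' tail, so the default clean-up (20-bp 3' trim, 10-bp end
trims, truncation to 320 nt) recovers exactly the amplicon window.
Per-base qualities are drawn around a positional mean model with a
per-read offset, giving the Q20 filter a realistic casualty rate of
roughly half a percent.

What the generator deliberately does **not** emulate: indels (the
decomposition operates on gap-free positional matrices, so the error model
is substitution-only), chimeras and PCR bias, primer sequences, quality-
correlated error probabilities, and unmerged read pairs. Passing tests
therefore demonstrate correct recovery under the stated error model, not
robustness to every artifact of real sequencing runs; on real data,
chimera screening and merging must happen upstream.

## Pipeline composition and numerical choices

- Coordinates are 1-based and inclusive throughout, the R convention.
- Length normalization truncates from the 3' side after the symmetric
  end-trim, which is deterministic for slightly varying merged-read
  lengths.
- Dereplication sorts by total abundance, ties broken lexicographically;
  greedy clustering then processes uniques in this order with first-hit
  centroid assignment (the common de novo default; `assign = "best"` is
  available). Centroids are always each OTU's most abundant member. An
  identity of `matches / length` is used for equal-length sequences, with
  N matching nothing (conservative: low-quality reads cannot bridge
  clusters); unequal lengths fall back to end-gap-free semiglobal
  alignment with internal gaps counted as columns.
- Chimera removal is a pass-through stage that logs itself, keeping stage
  counts telescoping; screening belongs to external tools upstream of this
  package.
- Best-hit taxonomy is an exhaustive percent-identity search over a small
  labeled reference FASTA — a semantic stand-in for a BLAST best hit that
  is exact for the curated, few-sequence reference sets this pipeline
  targets. Ties resolve to the earliest reference in file order; hits
  below `minAssignIdentity` (default 0.9) are reported as "unassigned" and
  excluded from the community-table denominator by default.
- Oligotype labels order components by descending full-matrix entropy
  (ties by ascending position); the convention is configurable because no
  single standard exists.
- Noise groups are reported, never silently dropped or reassigned.
- The stopping rule reads "resolution can no longer be improved" as
  entropy exhaustion: no kept group retains an above-threshold column.
  An alternative reading (stop when taxonomy stops changing) would couple
  the decomposition to the reference set, which this design avoids.

## Known limitations

- Greedy first-hit clustering combined with singleton removal slightly
  depletes whichever haplotype is *not* the OTU centroid: reads of the
  non-centroid haplotype carrying exactly `allowed` mismatches fall
  outside the main OTU and are often removed as singletons. At 0.5 % error
  this biases full-pipeline per-sample haplotype fractions by roughly two
  percentage points toward the centroid haplotype. The decomposition
  itself is unbiased — recovery tests therefore judge abundances on the
  per-taxon matrix, and pipeline-level tables should be read with this
  caveat at high error rates.
- Identity is windowed: two sequences identical over the 320-nt window are
  indistinguishable regardless of variation outside it.
- The entropy model assumes positional homology; reads with indels would
  smear variant columns and must not be fed into the positional matrix.

## Problem sizes

The bundled test-suite and acceptance runs use the preset conditions
directly: six samples of 10 000 reads (60 000 reads, 320-nt window) for the
transect recovery analysis, 100 seeded replicates of a depth-10 000 noise
column for the entropy floor, and randomized instances of up to 20 unique
sequences for brute-force oracle comparisons.
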