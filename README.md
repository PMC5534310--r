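# rrnprofile

Species-level microbial community profiling from long nanopore amplicons
spanning the bacterial **rrn** region — the 16S rRNA gene, the internal
transcribed spacer (ITS) and the 23S rRNA gene, ~4.2–5.8 kb in one molecule.

Short 16S fragments rarely separate bacteria below the genus level. The rrn
amplicon carries three markers with complementary variability (the ITS also
varies structurally, often encoding tRNAs), which compensates for the high
per-base error of nanopore 1D reads (~69% median read identity on R9
chemistry, ~85% on R9.4). `rrnprofile` implements the complete analysis path
for this design, plus a synthetic-data generator so everything runs and is
tested at desk scale:

* **Database construction** — extract 16S–ITS–23S regions from annotated
  assemblies (GFF3-driven, minus-strand regions reverse-complemented to
  transcriptional order), drop aberrant lengths outside the two-sided
  nearest-rank percentile bounds, remove redundancy by greedy centroid
  clustering at an identity radius (`100 − radius_pct`%), and summarise
  variability as normalized diversity (clusters per kb, referenced to 16S at
  97% identity).
* **Demultiplexing** — assign noisy reads to samples by locally aligning
  *extended barcodes* (barcode + primer, IUPAC-aware) within a window at
  each read end, under a score stringency (default 25; match +1, mismatch
  −1, gap of length *k* costs 1 + *k*, the LAST-style scoring used
  throughout).
* **Taxonomy and abundance** — competitive best-hit mapping of each read
  against the whole database on both strands (seeded banded Smith–Waterman,
  full DP available and test-verified), matched-segment identity
  `1 − editdist/max(len)`, per-sample removal of hits up to the 50th (R9) or
  25th (R9.4) identity percentile, singleton removal, relative proportions,
  and a 1% predominance threshold for calling a species present. Coverage
  bias per designed taxon is `log2(observed/expected)`.
* **Platform statistics** — Pearson r (two-sided p, t distribution, n − 2
  df) between per-genus proportion columns and column summaries with ND
  handling; the published 25-row two-community comparison table ships as a
  fixture.
* **Simulation** — annotated genomes with planted operons, dual-barcoded
  amplicons, and an error process calibrated to the R9/R9.4 identity
  regimes, with per-read truth labels.

## Worked example

Simulate an annotated genome set, build the reference database, sequence a
small mock community, and profile it:

```r
library(rrnprofile)

sim <- synth_genomes(n_species = 8, divergence = 0.1, seed = 11)
db  <- build_rrn_db(sim$genomes, sim$features, sim$taxonomy,
                    low_pct = 0, high_pct = 100)$db

specs  <- read_barcode_specs(system.file("extdata", "barcodes_minion.tsv",
                                         package = "rrnprofile"))
design <- read_community_design(system.file("extdata", "design_d6305.tsv",
                                            package = "rrnprofile"))
design$taxon <- db$species   # map the 8 designed proportions onto the synthetic species

reads <- simulate_reads(db, list(D6305 = design), specs, n_reads = 640,
                        model = error_model_preset("R9.4"), seed = 5)
ps <- profile_sample(reads$reads, db, identity_percentile = 25)
ps$profile
#> abundance profile (species level): 8 taxa over 480 reads, 8 predominant
ps$accounting
#>  n_in  n_length_removed  n_identity_removed  n_ambiguous_removed  n_singletons  n_profiled
#>   640                 0                 160                    0             0         480
```

All 8 designed species are recovered as predominant (≥ 1%); the accounting
row is the pipeline's conservation ledger — every input read is either
length-filtered, identity-filtered, dropped as a singleton, or profiled.

The packaged platform-comparison table reproduces the published statistics:

```r
rep <- compare_platforms(load_platform_table())
rep$correlations
#>                 pair         r            p  n
#> 1 miseq_vs_reference 0.3953746 5.044006e-02 25
#> 2    r9_vs_reference 0.4329542 3.063275e-02 25
#> 3   r94_vs_reference 0.4101343 4.172360e-02 25
#> 4        r9_vs_miseq 0.7370830 2.636783e-05 25
#> 5       r94_vs_miseq 0.6435832 5.186795e-04 25
```

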