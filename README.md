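# g4landscape

Genome-wide G-quadruplex (G4) and microsatellite (SSR) landscape analysis
in R, with a tidyverse-style interface: every analysis function takes plain
tables (tibbles) in and returns tibbles out, so steps chain with the pipe.

G-quadruplexes are four-stranded structures formed by guanine-rich DNA
tracts; their positions relative to promoters, UTRs and gene bodies — and
the strand they sit on — carry regulatory signal. This package provides the
building blocks of a genome-scale G4 survey for anyone with a genome FASTA
and a GFF3 annotation:

* **Run-based G4 scoring and detection.** Each base in a maximal run of
  *k* guanines scores `+min(k, 4)`; cytosine runs score `−min(k, 4)`;
  A/T/N score 0. The score of a sequence is the mean of its per-base
  scores, so it lies in `[-4, 4]` and its sign says which strand is
  G-rich. Detection slides a window (default `W = 25`) and reports merged,
  trimmed regions wherever the absolute window mean reaches a threshold
  (default `T = 1.2`); minus-strand regions are plus-orientation regions
  of the reverse complement, so detection is exactly strand-symmetric.
* **MISA-style SSR detection.** Maximal perfect tandem repeats of
  primitive 1–6 bp units with minimum repeat counts `1-20 2-6 3-5 4-5 5-5
  6-5`, compound merging at interruptions of at most 100 bp, and SSR–G4
  association by coordinate overlap.
* **Feature regions and strand contexts.** Twelve region classes (exon,
  CDS, intron, 5'UTR, 3'UTR, gene, intergenic, promoter2000/1500/1000/500,
  TSS500) derived from gene models, with G4 counts and per-kbp densities
  under double-, template- and coding-strand contexts.
* **Gene-set analyses.** DEG classification (`|log2FC| >= 1`,
  `padj <= 0.05`), promoter G4-count gene classes (`0`…`5`, `6+`),
  selection of genes with >10 promoter template-strand G4s, and
  hypergeometric term over-representation with Benjamini–Hochberg
  correction.
* **A synthetic-genome simulator** that plants G4 motifs, SSRs, gene
  models and DE labels with a truth manifest, so the whole pipeline is
  testable without downloads.

## Worked example

```r
library(g4landscape)

hunter_score("GGGGGTGTGTACAGACTCCGGAGGGG")
#> [1] 1.423077

set.seed(1)
sim <- simulate_g4_study()          # 1 Mb genome with planted truth
g4  <- scan_g4(sim$genome)          # W = 25, T = 1.2

chromosome_summary(sim$genome, g4)
#> # A tibble: 2 × 6
#>   chrom length_bp gc_percent g4_count g4_density_per_kbp g4_density_display
#> 1 chr1     500000       20.1       60              0.12  0.1
#> 2 chr2     500000       20.1       54              0.108 0.1

head(motif_family_table(g4), 2)
#> # A tibble: 2 × 6
#>   g_rich_seq                 total plus_count minus_count length abs_score
#> 1 GGGGGTGTGTACAGACTCCGGAGGGG    27         11          16     26      1.42
#> 2 GGGTTAGGGTTAGGGTTAGGG         18          5          13     21      1.71

regions <- derive_region_sets(sim$models, chrom_lengths(sim$genome))
deg     <- classify_deg(sim$de)
dens    <- density_profile(g4, regions,
                           gene_sets = list(up = deg$gene_id[deg$status == "up"]))
dplyr::filter(dens, region_class == "promoter2000", gene_set == "all")
#>   region_class strand_context gene_set g4_count total_bp density_per_kbp
#> 1 promoter2000 double         all            39   240000          0.162
#> 2 promoter2000 template       all            21   240000          0.0875
#> 3 promoter2000 coding         all            18   240000          0.075
```

The chromosome table mirrors the usual genome-survey layout (length, GC%,
G4 count, density per kbp, plus a one-decimal display column); the motif
table counts exact G-rich sequences with their strand split; the density
table is the class × strand-context × gene-set cross-product, where
`template + coding = double` for every gene-linked class. `autoplot()`
methods draw the density profile and the promoter G4-count class
proportions; `run_pipeline()` executes the whole analysis from a config
list or YAML file and writes BED/bedGraph/TSV outputs with provenance
headers (a thin CLI wrapper lives in `inst/scripts/g4landscape.R`).

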