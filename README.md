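# fragmeth

Fragment-level analysis of DNA methylation sequencing data (WGBS, EM-seq,
and MM/ML-tagged long reads) in R.

Array platforms and per-CpG summary tracks report one average per CpG site
and discard what the sequencing actually measured: the joint methylation
pattern of neighbouring CpGs on each DNA molecule. That joint pattern is
where allele-specific methylation, cell-type mixtures and block structure
live. fragmeth is built for researchers who work at that level — it
represents, manipulates, segments, tests and visualizes methylomes
fragment-by-fragment.

## What it does

- **CpG coordinate system** — every CG dinucleotide of a reference FASTA is
  indexed CpG 1..N in genome order (`build_index`, `convert_bed`,
  `locus_to_cpg`); all other structures use these indices.
- **PAT** — a fragment is (chrom, first CpG index, pattern over
  `C`/`T`/`.`, count); identical patterns merge with summed counts.
  bgzip + tabix on disk, regional queries with clipping, length filters,
  seeded subsampling, CpG masking and in-silico mixing
  (`bam_to_pat`, `collapse_pat`, `query_pat`, `mask_pat`, `mix_pat`).
- **BETA** — per-CpG (methylated, total) counts as fixed-width unsigned
  integers; file size is exactly `2·N·w/8` bytes (`pat_to_beta`,
  `beta_to_table`).
- **Segmentation** — exact dynamic programming that partitions the CpG axis
  into blocks maximizing a Beta(α,α)-Bernoulli marginal likelihood summed
  over samples (`segment_genome`); the pseudocount α trades block length
  against homogeneity.
- **Homogeneity** — fragments classed mostly-unmethylated / mixed /
  mostly-methylated (U/X/M) at ≤25% / ≥75% of observed CpGs, ≥3 CpGs
  observed (`classify_fragment`, `count_homog`).
- **Bimodality** — a likelihood-ratio test of one set of per-site Bernoulli
  rates against a 50/50 two-allele mixture fitted by EM; flags
  allele-specific methylation such as imprinting (`test_bimodal`).
- **Markers** — one-vs-all discovery of group-specific differentially
  methylated blocks with quantile-trimmed deltas and t / Mann-Whitney /
  M-value Welch tests (`find_markers`).
- **Visualization** — terminal fragment stacks and 0-9 digit methylation
  heat lines (`render_pat_lines`, `render_beta_lines`).
- **Simulator** — synthetic genomes and reads with known per-CpG
  methylation probabilities, paired/long-read structure and optional
  two-allele mixtures, for ground-truth testing (`simulate_genome`,
  `simulate_reads`, `simulate_fragment_matrix`).

## The statistics at the core

**Block score.** A block with pooled counts (m methylated, u unmethylated)
per channel scores `log B(m+α, u+α) − log B(α, α)`; the genome-wide
partition maximizing the summed score is found exactly by dynamic
programming and verified in the tests against exhaustive enumeration of all
2^(n−1) partitions on small instances.

**Bimodality.** Single-allele: likelihood ∏ⱼ∏ᵢ θᵢ^rᵢⱼ (1−θᵢ)^(1−rᵢⱼ) with
θ̂ᵢ the per-site methylated fraction. Two-allele: each read draws an allele
with prior ½ and follows that allele's θ¹ or θ²; fitted by EM. The
statistic Λ = 2(ℓ₂ − ℓ₁) is referred to χ² with df = number of informative
sites.

## Worked example

Simulate a 40-CpG genome whose left half is highly methylated (θ = 0.95)
and right half unmethylated (θ = 0.05), sequence it with paired reads, and
run the pipeline:

```r
library(fragmeth)

g   <- simulate_genome(40, spacing = 25, seed = 7)
fa  <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
idx <- build_index(fa)

theta <- rep(c(0.95, 0.05), each = 20)
sim <- simulate_reads(g, theta = theta, depth = 40, read_len = 120,
                      paired = TRUE, insert_len = 260, seed = 8)
pat  <- bam_to_pat(sim$sam, idx)
head(pat, 4)
#>   chrom start_cpg     pattern count
#> 1  chrS         1   CCCC.CCCC     1
#> 2  chrS         1  CCCC.CCCCC     1
#> 3  chrS         1 CCCCC.CCCCC     1
#> 4  chrS         1 CCCCC.CCCCT     1
```

Each row is one fragment: its first CpG index, its pattern (`.` marks the
unsequenced gap between mates), and how many fragments showed exactly that
pattern. Reduce to per-CpG counts and segment:

```r
beta <- pat_to_beta(pat, idx$total_cpgs, width = 16L)
seg  <- segment_genome(beta, idx, alpha = 1)
seg
#>   chrom start  end startCpG endCpG     score
#> 1  chrS    50  527        1     21 -156.7402
#> 2  chrS   550 1027       21     41 -134.7351
```

The change point is recovered exactly at CpG 21. Fragment classes and the
bimodality test per block:

```r
count_homog(pat, seg)[, c("startCpG", "endCpG", "U", "X", "M")]
#>   startCpG endCpG  U X  M
#> 1        1     21  0 2 97
#> 2       21     41 99 0  0
test_bimodal_regions(pat, seg)[, c("startCpG", "n_reads", "p_value")]
#>   startCpG n_reads   p_value
#> 1        1     106 0.9128726
#> 2       21     106 0.9992261
```

Both blocks are internally uniform — almost every fragment is M on the
left, U on the right — so neither is bimodal (large p-values: the
two-allele model explains nothing a single allele cannot). A terminal view
across the boundary, one digit per CpG (9 ≈ fully methylated, 0 ≈
unmethylated, `|` = block boundary):

```r
cat(render_beta_lines(list(sample1 = beta), 15, 27,
                      boundaries = seg$endCpG), sep = "\n")
#> CpG 15-26 (12 sites)
#> sample1  999989|001000
```

A shell front end wrapping the same functions ships in
`inst/cli/fragmeth` (`fragmeth simulate | init_genome | bam2pat | view |
segment | homog | test_bimodal | find_markers | ...`).

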