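---
title: "Fragment-level methylation analysis with fragmeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level methylation analysis with fragmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmeth)
```

# The CpG coordinate system

Mammalian DNA methylation lives almost entirely on CpG dinucleotides, and
neighbouring CpGs on the same DNA molecule are strongly correlated. fragmeth
therefore replaces genomic coordinates with a CpG index: every CG
dinucleotide of the reference is numbered 1..N in genome order
(`build_index()`), and all downstream structures address the genome through
that index. Detection is case-insensitive, because reference FASTA files
soft-mask repeats with lowercase and excluding them would silently drop
roughly half of the genome's CpGs; dinucleotides containing N or another
IUPAC ambiguity code are excluded, since a site that cannot be confidently
read in the reference cannot anchor a methylation call. CpG index ranges are
half-open and 1-based; genomic BED intervals are 0-based half-open, matching
the BED convention.

# Fragment patterns (PAT) and per-CpG counts (BETA)

A sequenced fragment reduces to the tuple (chromosome, index of its first
covered CpG, pattern, count), where the pattern is a string over `C`
(methylated), `T` (unmethylated) and `.` (unknown). Identical patterns over
identical CpGs are merged with summed counts, which makes files compact and
diffable; sorting uses C-locale byte order (`.` < `C` < `T`) so output is
deterministic. Records are canonicalized by trimming leading and trailing
`.` characters — two fragments differing only in unobserved flanks are the
same observation. Files are bgzip-compressed and tabix-indexed on the CpG
index column for regional access.

The BETA representation is the marginal view: for each of the N CpGs, a
(methylated count, total count) pair stored as unsigned 8- or 16-bit
integers, interleaved little-endian with no header, so the file size is
exactly `2 N w/8` bytes and any site is reachable by offset. Counts
saturate at `2^w - 1` instead of wrapping, a deliberate trade: at saturated
sites the methylation fraction is still approximately right, whereas
wraparound would be silently wrong.

# Read calling

`bam_to_pat()` projects each aligned read onto the CpG grid through its
cigar. Top-strand (C→T converted) reads are inspected at the C of each
overlapped CpG: C means protected (methylated), T converted (unmethylated),
anything else — a mismatch, a deletion, a clip — is unknown. Bottom-strand
reads are inspected at the G one base to the right, with G/A playing the
roles of C/T. The bisulfite strand is inferred from the SAM flag (read 1
forward means top strand; the orientation flips for read 2), with an
explicit `XG` tag taking precedence when the aligner wrote one. Mates of a
pair are merged into one fragment: the unsequenced gap becomes `.`, and
where mates overlap, agreement keeps the call while disagreement becomes
`.` — with only two votes, masking is the only defensible tie-break.
Base quality is not consulted; only mapping quality filters reads
(defaults: require properly-paired flags 3 when the file is paired-end,
exclude 1796, mapq ≥ 10).

Long reads carry native methylation in MM/ML base-modification tags rather
than converted bases. fragmeth parses the `C+m` sub-tag (both
orientations), decodes each ML byte as `(ML + 0.5)/256`, and calls a CpG
methylated at probability ≥ 0.5 — a tag byte of 128 calls methylated, a
fixed and documented boundary convention. Sites without a modification call
are `.`; mates are never merged in long-read mode.

# Segmentation into methylation blocks

Blocks of neighbouring CpGs with a common methylation level are found by
exact dynamic programming on the CpG axis. The score of a candidate block
pools its counts (per channel) and evaluates the Bernoulli marginal
likelihood under a symmetric Beta(α, α) prior:

    score(m, u) = log B(m + α, u + α) − log B(α, α),

summed over channels, with per-CpG independence inside a block. The
pseudocount α is the single tuning knob: small α rewards splitting at any
level change, large α tolerates heterogeneity and yields longer blocks
(empirically, the block count is non-increasing in α). The DP recurrence
`best(i) = max_j best(j) + score(j..i)` is exact under the block-extent
constraints (`max_cpg`, default 5000; optional `max_bp` measured from the
first C to one past the last G; `min_cpg`, default 1); ties prefer the
longer final block so output is deterministic. Blocks tile the requested
range with no gaps or overlaps, and chromosomes are segmented
independently. The test suite pins this contract to an exhaustive oracle:
on instances of up to 12 CpGs the DP score equals the maximum over all
2^(n−1) partitions. The scoring model itself — pooled counts, Beta-Bernoulli
marginal, summed channels — is this package's defining choice of
"homogeneity"; other segmenters weight within-block variance differently.

# Fragment homogeneity (U/X/M)

Each fragment observing at least `min_sites` CpGs (default 3) is classed by
its methylated fraction f over observed sites only: U if f ≤ 0.25, M if
f ≥ 0.75, X otherwise, both boundaries inclusive. Unknown sites are
excluded from the denominator — an unobserved CpG carries no evidence and
must not dilute the fraction. When counting per region, fragments are
clipped to the region's CpG range before classification, so a fragment
spanning two blocks contributes its in-block portion to each; whole-fragment
classification is available behind `clip = FALSE` for comparison with tools
that count intersecting fragments unclipped.

# The bimodality (allele-specific methylation) test

Regions under genomic imprinting or methylation QTLs show two fragment
populations: one mostly methylated, one mostly unmethylated. The test
compares two nested models of the fragments in a region. Under the
single-allele model each CpG i has one methylation probability θ_i, reads
are independent, and sites within a read are independent given θ; the MLE
is the per-site methylated fraction. The two-allele model draws each read's
allele with fixed prior 1/2 and gives each allele its own per-site vector
θ¹, θ². The mixture is fitted by EM with soft responsibilities (hard
assignment is available as an option for fidelity experiments), initialized
at 0.9/0.1 across sites, iterating until the log-likelihood gains less than
1e-6 or 300 iterations. Probabilities are clamped to [1e-6, 1 − 1e-6]
during iteration to keep log-densities finite; at convergence, estimates
within the clamp of a boundary are snapped to 0/1 when that does not lower
the likelihood, so degenerate optima report their exact closed-form
likelihoods.

The statistic is Λ = 2(ℓ₂ − ℓ₁), clamped at 0, referred to χ² with df = k,
the number of informative sites — the parameter-count difference between
the 2k- and k-parameter models. The χ² reference is approximate here: the
null puts θ¹ = θ² on the boundary of the alternative and the components are
exchangeable, both of which make the test conservative. That is acceptable
for a screen whose follow-up threshold is stringent (p < 0.005), and the
simulated type-I error at nominal 0.05 stays below 0.10 in the test suite.
Reads observing a single site are retained; they inform θ, just weakly
bimodality.

# Marker (differential block) discovery

`find_markers()` runs one-versus-all over groups of samples. Per block and
sample the methylation value is the pooled ratio Σmeth/Σtotal over the
block's CpGs (robust at low coverage, unlike averaging per-CpG ratios),
with values below a coverage floor treated as missing; group summaries
average member samples unweighted so deep samples do not dominate. The
separation score is quantile-trimmed: for a hypomethylated marker, the
background's `bg_quant` quantile (default 2.5th percentile) minus the
target's `1 − tg_quant` quantile (default 75th percentile). The trimming
fractions are parameters precisely because a marker should survive a
minority of aberrant replicates; setting both to 0 recovers the strict
min(background) − max(target) difference, which is also reported.
Significance comes from three tests: Welch's t and Mann-Whitney U (exact
for ≤ 8 untied values per side, normal approximation with continuity and
tie correction otherwise) on the raw block values, and Welch's t on
per-sample M-values `log2((Σmeth + 1)/(Σunmeth + 1))` — the +1 offset keeps
zero counts finite and is configurable. Blocks are filtered by direction,
minimum delta, p-value, size and missingness, then ranked by robust delta
with smaller p breaking ties. No multiple-testing correction is applied by
default — the delta and p thresholds are the filter — but the bimodality
region scan reports Benjamini-Hochberg adjusted values where a block list
is tested wholesale.

# Terminal rendering

`render_pat_lines()` stacks fragments greedily (first row whose occupied
span the fragment does not overlap), one glyph column per CpG, colored by
site call or by whole-fragment U/X/M class; `render_beta_lines()` prints
one digit per CpG per sample, `min(floor(10·m/t), 9)`, `-` for no
coverage, optional bars at block boundaries. Stripping the color escapes
reproduces the plain rendering byte-for-byte, which is the property the
tests pin.

# The simulator and what passing tests mean

The simulator is first-class code: `simulate_genome()` plants a known CpG
set in CG-free A/T filler, and `simulate_reads()` draws fragments
uniformly, an allele by fair coin in two-allele mode, and per-CpG
methylation Bernoulli(θ_i) shared across the fragment, then writes
converted reads (both strands equally), proper SAM pairs with an
unsequenced gap when the insert exceeds twice the read length, or
MM/ML-tagged native long reads. It emulates exactly the generative
assumptions of the bimodality model: per-site Bernoulli, independence given
the allele. It does not emulate sequencing-error profiles beyond a uniform
substitution rate (off by default), M-bias, GC bias, mapping ambiguity, or
fragment-length biology. Passing round trips therefore demonstrate that
calling, merging, collapsing and counting are exact inverses of this
generative process — not that real libraries are free of upstream artifacts;
on real data those are the aligner's and trimmer's problems, honoured here
through the flag/mapq filters.

Default study conditions in the tests and acceptance script: null
bimodality calibration uses 500 regions of 5 CpGs × 20 reads with uniform
random θ; power uses 100 regions of 4 CpGs × 30 reads at alleles 0.95/0.05;
segmentation oracle checks 200 instances of ≤ 12 CpGs and 1-3 channels
(the exhaustive oracle is exponential, which caps the instance size);
end-to-end checks use a 30-CpG genome at depth 60. These sizes are chosen
so every property is exercised at full strength while the whole suite runs
in well under a minute.

# Numerical and design choices, in brief

- `min_sites` counts observed (non-`.`) CpGs, not pattern span, everywhere.
- Subsampling and mixing thin a count-k record as k independent Bernoulli
  trials, so thinning statistics are exact.
- Collapse order: chromosome (index order), start CpG, pattern in C locale.
- EM: soft E-step, fixed 1/2 mixture weights throughout (the prior is part
  of the model, not estimated), tol 1e-6, 300 iterations, clamp 1e-6 with
  boundary snapping at convergence.
- LRT df = k; conservative, documented above.
- Mate conflicts and non-C/T bases mask to `.` rather than dropping reads.
- Long-read ties (probability exactly 0.5) call methylated.
- Block genomic bounds run from the first CpG's C (0-based) to one past the
  last CpG's G.

# Known limitations

Fragment endpoints and non-CpG (CHH/CHG) contexts are discarded by design —
the representation trades fragmentomics for compactness and privacy.
Ternary modification codes (5hmC vs 5mC) are not represented; MM/ML parsing
handles the `C+m` channel only. The marker module's p-values are screening
statistics over user-supplied blocks, not genome-wide discovery-corrected
inferences. The segmentation scoring model is this package's own contract,
verified against exhaustive search, and may differ in detail from other
block callers.
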