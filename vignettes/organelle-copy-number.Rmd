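---
title: "Estimating organelle genome copy number from read depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating organelle genome copy number from read depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgcn)
```

# The problem

A plant cell is a mixture of genomes: one nuclear genome at low, even copy
number (2C in a diploid, non-endoreduplicating cell), a mitochondrial genome
at roughly 50–150 copies per cell, and a plastid genome at comparable
dosage. Whole-genome sequencing of such a cell samples reads from each
compartment in proportion to *copies per cell × genome length*, which makes
read depth a quantitative assay of organelle genome dosage — provided reads
can be attributed to the right compartment. Two obstacles make naive mapping
misleading:

* **Shared sequence between plastid and mitochondrial genomes.** Plant
  mitochondrial genomes carry plastid-derived insertions; plastid reads are
  abundant and will pile up on those tracts. The pipeline therefore removes
  everything that maps to the plastid reference *first*, and only then
  considers the mitochondrial and nuclear references.
* **NUMTs.** Nuclear insertions of mitochondrial DNA are nearly identical to
  the organellar original. Reads from a NUMT map happily onto the
  mitochondrial reference, inflating mitochondrial counts and — critically —
  leaving residual coverage over regions that are genuinely deleted from the
  mitochondrial genome. Diagnostic SNPs between NUMT and organellar copies
  are the only way to tell the read populations apart.

# Copy number per cell

For a region $R$ (a compartment or an interval) with $n_R$ assigned reads
and length $L_R$, against nuclear counts $n_{nuc}$ over length $L_{nuc}$:

$$\mathrm{copies}(R) \;=\; \frac{n_R / L_R}{n_{nuc} / L_{nuc}} \times C_{nuc}$$

with $C_{nuc}$ the nuclear copies per cell (default 2). The length
normalisation makes the absolute value meaningful; ratios between samples
("wild type as 1") are insensitive to it. `nuclear_copies_per_cell` accepts
a measured mean C-value so that tissue with substantial endoreduplication
can be put on a true per-cell scale — in such tissue the default of 2 makes
the estimate a *per-2C-equivalent* value, not per cell.

Assumptions worth stating: uniform mappability (the synthetic references
are random sequence; real genomes need this caveat), no GC bias, and reads
attributed by the assignment rules below. A sample whose mitochondrial
genome carries a deletion yields a whole-compartment estimate that is
*lower* than copies-per-cell by the deleted fraction, because the
denominator length still counts the deleted interval; region-level estimates
away from the deletion do not have this bias.

# Read assignment

The built-in mapper is an exact-k-mer-seeded, ungapped aligner: seeds of
k = 21 are taken every 10th read position (plus the final window), candidate
placements on either strand are verified by mismatch counting, and the
budget is $\max(2, \lceil 0.04\,\ell\rceil)$ for read length $\ell$. This is
deliberately minimal — adequate for the low-error synthetic reads the forge
produces and for any high-quality short-read data, and fully testable
against a brute-force oracle. Gapped or spliced alignment is out of scope;
`ingest_alignments()` accepts SAM/BAM from a production aligner behind the
same interface.

Assignment order and tie-breaking:

1. a read placing on the plastid reference within budget is `plastid`,
   unconditionally — the exclusion happens before anything else;
2. remaining reads take the best-scoring placement among mitochondrial and
   nuclear; an exact tie goes to **mitochondrial** and is flagged
   `unique = FALSE`.

The tie rule reproduces the field's practice of mapping to the
mitochondrial reference after plastid removal. It deliberately routes
NUMT-interior reads (identical to the organellar original away from the
SNPs) into the mitochondrial pool: the ~2–3% residual coverage they create
over a deleted region is part of what the analysis must display and then
explain via the SNP classifier, not an artefact to suppress. Reads spanning
a diagnostic SNP match the nuclear copy strictly better and are assigned
nuclear; because the SNP classifier must see exactly those reads, the
mapper records every read's best *mitochondrial* placement (`mt_pos`,
`mt_strand`, `mt_mm`) alongside the final assignment, and
`classify_snp_origin()` consumes the placements rather than the
assignments. This mirrors a map-everything-to-the-mitochondrial-reference
protocol while keeping the compartment partition clean.

Multi-mapping within a compartment is flagged (`unique = FALSE`) but not
down-weighted; the forge generates no PCR duplicates, so none are
collapsed.

# Windowed coverage, relative coverage, deletion calls

Reads are counted into tiling windows by **leftmost position** (window
width 500 bp; a trailing partial window is kept and flagged). Leftmost
counting, rather than overlap counting, guarantees that window counts sum
exactly to the compartment's assigned reads — the conservation property the
test suite asserts after every windowing. True sliding windows
(`step_bp < window_bp`) are supported but tiling is the default; outputs
state the grid.

CPM normalisation divides by the number of mapped reads. Which reads count
as "mapped" is genuinely ambiguous (total input? post-exclusion? nuclear
only?), so it is a parameter: the default `assigned` uses nuclear +
mitochondrial reads after plastid exclusion; `all` and `nuclear` are
available. Ratios of a sample against a reference use
$(\mathrm{cpm}_s + \tilde p_s)/(\mathrm{cpm}_r + \tilde p_r)$ with a
pseudocount of 0.5 reads converted to each sample's own CPM scale — this
keeps ratios defined over zero-coverage reference windows and makes a
sample relative to itself exactly 1 in every window.

Deletions are maximal runs of windows with relative coverage below 0.2,
requiring at least 3 low windows and bridging at most 1 high window. The
threshold sits between the two regimes the analysis must separate: residual
NUMT coverage over a true deletion (a few percent of wild type) and
biological copy-number variation (roughly 0.5–3×). On circular
compartments a run may wrap the origin and is flagged; the default is
linear. The caller is property-tested against an exhaustive run scan.

# qPCR relative quantification

$\Delta Ct = Ct_{target} - Ct_{control}$ per biological sample (technical
replicates are averaged on the Ct scale first), and
$\mathrm{rel} = E^{-(\Delta Ct - \overline{\Delta Ct}_{ref})}$ with
amplification efficiency $E = 2$ by default (configurable; no standard-curve
efficiency estimation is attempted). Centring on the *arithmetic* mean of
the reference ΔCt — equivalently the *geometric* mean of the fold changes —
is a deliberate choice: "reference as 1" does not specify a mean type, and
geometric centring makes the reference group's geometric mean exactly 1
regardless of noise, which is the natural invariant on a ratio scale.
Two-group comparisons use Welch's t test; two identical constant groups
degenerate to statistic 0, p = 1 rather than an error. Groups of n = 1
report their dispersion as unavailable, never as 0.

# Genome-stratified DEG proportions

DEG status uses strict inequalities — induced: $\log_2 FC > 1$ and
$FDR < 0.05$; suppressed: $\log_2 FC < -1$ and $FDR < 0.05$ — so boundary
genes are null. Proportions divide by all genes of the supplied table per
genome (restrict the table first for a protein-coding-only denominator),
plus a pooled `total` row. Genome contrasts are two-sided Fisher exact tests
on `[[A_dir, A_rest], [B_dir, B_rest]]` via `stats::fisher.test`; the test
suite checks it against exhaustive hypergeometric enumeration for all small
tables. Contrasts can be run per mutant or on pooled tables as the user
prefers; both are just different input tables to the same function.

The stand-in DEG caller exists so synthetic end-to-end runs need no
external framework: median-of-ratios size factors, log2 fold change of
normalised means with pseudocount 1, a per-gene moderated t test on
$\log_2(\mathrm{norm}+1)$, BH adjustment. Moderation
(`limma::squeezeVar`) is load-bearing: at the 3-vs-3 designs these
simulations target, raw per-gene variances on 2 + 2 degrees of freedom are
so noisy that an unmoderated t test retains almost no power after FDR
adjustment, while shrinking variances toward the genome-wide trend restores
it without disturbing null calibration (the suite checks both). The caller
is explicitly *not* equivalent to a negative-binomial framework; real-data
pipelines should ingest an externally produced DEG table.

# The synthetic forge

The forge generates the study conditions the analysis assumes:

| Parameter | Default | Why |
|---|---|---|
| nuclear / mitochondrial / plastid length | 200 / 50 / 30 kb | ~7× smaller than Arabidopsis organelle genomes, so 1e5 read pairs give deep organellar coverage in seconds |
| copies per cell | 2 / 100 / 50 | diploid 2C nucleus; mitochondrial dosage in the organism's 50–150 range; plastid intermediate |
| NUMT | 6 kb of the mitochondrial genome, 2 SNPs, 1 copy/haploid | long enough that reads sit fully inside it; two diagnostic SNPs; 2 copies per diploid cell |
| deletion | 5.5 kb, window-aligned, containing both SNPs | the knockout geometry: SNP positions covered only by the NUMT after deletion |
| read length / insert | 150 bp, 400 ± 60 | short-read paired-end defaults |
| qualities | constant Q30 | the analysis never consults qualities |
| expression | 30 mt genes, 80% induced at log2FC ~ N(1.5, 0.3), NB dispersion 0.05, 3 vs 3 | genome-level mitochondrial induction against a quiet nuclear background |

Sampling weights are copies × length per compartment; the NUMT travels
inside the nuclear sequence (extra copies beyond one per haploid are added
as extra weight over the insertion interval). Reads fully inside the NUMT
are truth-labelled `numt` even though they are physically nuclear. The
mutant genotype samples mitochondrial fragments from the deletion-bearing
genome, so reads from the deleted interval are impossible by construction;
the junction is either a simple join or a 20-bp microhomology patch —
junction *inference* from split reads is explicitly not modelled.
Diagnostic SNP positions within the segment are a fixture choice (offsets
2500 and 3500), as no canonical coordinates exist for them. All randomness
flows from one explicit seed per call, with the caller's RNG state
restored afterwards.

What the forge does **not** emulate — and hence what green tests do not
certify about real data: sequencing-error profiles beyond uniform
substitutions (no indels, no quality decay), GC and mappability bias,
repeat structure and substoichiometric recombination isoforms of real plant
mitochondrial genomes, heteroplasmy beyond a single mutant/wild-type
mixture, and PCR duplicates. On real data the plastid-first rule also
removes genuine mitochondrial reads from plastid-derived tracts; with
random synthetic sequence this cost is invisible.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; SAM positions convert on
  ingest (1-based → 0-based); GFF3 output is 1-based; BED output 0-based.
* Zero assigned reads give zero CPM, not division errors; zero nuclear
  depth is a hard error ("nuclear depth zero").
* SNP sites spanned by no read are reported missing and excluded from the
  pooled denominator; bases matching neither allele count as `other` and
  are never imputed.
* An all-zero gene in the stand-in caller reports log2FC 0, FDR 1.
* Fisher p-values come from point-probability summation with the standard
  tie tolerance; the enumeration oracle in the tests uses a relative
  tolerance of 1e-7.

# Problem sizes

The test suite runs most simulations on a one-third-scale fixture (60 kb
nucleus, 20 kb mitochondrial genome, 100-bp reads, 3–30 thousand read
pairs), with the full-scale fixture reserved for the end-to-end checks
(50–100 thousand pairs). The acceptance script uses 100–200 thousand pairs
per sample, the depth at which the copy-number estimator's sampling error
is a few percent. These sizes are the package's chosen trade-off between
statistical resolution and a desk-scale run.

# Known limitations

Breakpoint-resolution deletion calling, GC-bias correction, mappability
masks, per-base depth profiles, gapped alignment, multi-reference qPCR
normalisation (geNorm-style) and multi-group ANOVA inference are out of
scope; the deletion caller resolves to window width, and the copy-number
estimate is only as good as the compartment assignment feeding it.
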