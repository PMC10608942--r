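---
title: "MAG-centric quantification: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAG-centric quantification: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magquant)
```

magquant quantifies metagenome-assembled genomes (MAGs) and their expressed
functions from two count layers measured on the same microbial community: a
metagenomic layer (reads mapped onto predicted genes) and a metaproteomic
layer (MS/MS spectral counts assigned to genes). This vignette documents the
statistical procedures, the conventions chosen where several reasonable ones
exist, and what the synthetic-community generator does and does not emulate.

## The quantification model

### Genomic MAG abundance

For sample $s$, the relative abundance of MAG $m$ is the share of mapped
reads landing on its genes,

$$a_{m,s} = 100 \cdot \frac{\sum_{g \in m} c_{g,s}}{\sum_{g} c_{g,s}},$$

where $c_{g,s}$ is the read count of gene $g$. Three conventions matter:

* **Unmapped reads are excluded.** Only mapped counts enter the denominator;
  the per-sample unmapped totals are carried through the data model but never
  used in abundance estimation.
* **Unbinned contigs are a first-class category.** Genes on contigs not
  assigned to any MAG carry the reserved label `UNBINNED` and form their own
  profile row, so MAG abundances are fractions of the whole community rather
  than of the binned community only.
* **Replicates are combined by the median, then renormalized.** Per
  condition, the median of the replicate percentages is taken per MAG and
  the column rescaled to 100%. The order (median first, renormalize second)
  is a choice; it guarantees columns sum to exactly 100 after the median,
  which the reverse order does not.

The mapping signal is summed read counts by default. Within a MAG, gene
length bias cancels when abundances are formed from whole-MAG sums, but a
`signal = "coverage"` option (counts divided by gene length) is provided for
data where length effects across MAGs are a concern.

### Annotation filtering and KO counts

Functional annotations (KEGG orthologies and EC numbers) are kept only when
the sequence identity is at least 30% and the e-value at most $10^{-10}$.
The discard rule is stated on the strict side ("below 30%", "larger than
$10^{-10}$"), so both boundary values are kept. Genes failing the filter keep
their catalog row — membership and counts are untouched — but lose their
annotation. Annotations whose identity or e-value is missing are kept,
because the criteria cannot be evaluated for them; dropping them would
silently discard upstream annotations that carried no metrics. Read counts
are then summed per KO and sample; unannotated genes contribute nothing.

### Average genomic copy number (AGCN)

The AGCN of a feature is the average number of copies per genome in the
community. It is estimated by scaling length-normalized KO counts against a
set of universal single-copy genes (USiCGs) — genes present exactly once per
prokaryotic genome:

$$\mathrm{AGCN}_{k,s} = \frac{c_{k,s} / \ell_k}
  {\operatorname{median}_{u \in \mathrm{USiCG}} \left( c_{u,s} / \ell_u \right)},$$

with $\ell_k$ the mean length of the genes annotated with KO $k$. By
construction the median AGCN over the USiCG set is exactly 1 in every
sample. The packaged default set holds ten ribosomal-protein KOs and can be
overridden by any KO list. Only this inter-sample scaling is implemented; a
learned intra-sample correction (as in tools trained on reference genomes)
is out of scope because it requires fitted model weights. A sample in which
the USiCG median is zero has no usable single-copy reference and is an
error, not a silent zero.

### Metaproteomic quantification

Protein identifications sharing the same peptide set are grouped into one
metaprotein (counts summed, gene sets unioned). Metaproteins whose gene set
holds more than one gene cannot be attributed to a single gene and are
excluded before any normalization — the contractual order is **group →
exclude → normalize**, and an ordering test asserts that reversing the last
two steps changes the result. Spectral counts are then total-count
normalized so every sample column sums to the same constant. The default
constant, 78,119, is a dataset-specific total and is an explicit
configuration value; the second normalization round (after replicate
medians) reuses the same constant, another convention made explicit because
the alternative (renormalizing to the per-condition median total) is equally
defensible.

Per condition, gene-level medians are taken across replicates, KO-level
values are the sums of gene medians over each KO's genes, and both matrices
are normalized a second time.

### Completeness-adjusted proteomic MAG abundance

Summing a MAG's spectral counts under-represents incomplete MAGs: spectra of
their missing genes cannot be assigned. The adjustment divides each MAG's
raw sum by its completeness *as a fraction*,

$$\mathrm{adj}_m = \frac{\sum_{g \in m} \mathrm{spec}_g}{\mathrm{comp}_m / 100},$$

so a complete MAG is unadjusted — the natural reading of "dividing by the
completeness value" that leaves 100%-complete genomes untouched. The
unbinned fraction has no completeness estimate and is never adjusted
(equivalently, treated as 100%). Shares are computed per replicate, combined
by the median per condition, and renormalized to 100%. Two useful
consequences hold exactly at the single-replicate level and are tested:
MAG-to-MAG ratios equal $(\mathrm{raw}_i/\mathrm{comp}_i) /
(\mathrm{raw}_j/\mathrm{comp}_j)$, and rescaling every completeness by a
common factor changes only the unbinned share. After replicate medians these
hold only approximately, since the median may be realised by different
replicates for different MAGs.

### Fold changes and the pseudocount offset

KO-level fold changes between conditions $x$ and $y$ use
$\log_2\!\left(\frac{\mathrm{count}_x + s}{\mathrm{count}_y + s}\right)$
with a positive offset $s$ (default 2) keeping ratios finite at zero counts.
`derive_offset()` reproduces the percentile-based derivation: the 30th
percentile of the KO-level counts, rounded, floored at 1. Neither the
percentile definition nor the rounding rule nor the count universe is
canonical, so all three are explicit choices: linear-interpolation
percentile (R's default type 7), half-up rounding, and all cells including
zeros (`universe = "nonzero"` restricts to positive counts). The maximum
pairwise fold change of a profile row is the largest $|\log_2|$ ratio over
all unordered condition pairs with the same offset.

### Module completeness and activity

KEGG modules are parsed from a deliberately minimal block grammar: blocks
separated by spaces (all required), alternatives within a block by commas
(any one suffices), complex subunits joined by plus signs (all required
within that alternative). Nested parentheses and minus-prefixed optional KOs
are rejected with a clear error; this is a documented limitation, sufficient
for the module logic used downstream. A module is *retained* when it is
complete or missing at most one block. Module activity within a MAG is the
fraction of the MAG's total spectral counts carried by genes whose KO occurs
in the module — a number in $[0, 1]$, reported as a percentage in summaries.

### Enzyme-level summaries and presence calls

Key-enzyme groups map KOs to anaerobic-digestion process steps (hydrolysis,
acidogenesis, acetogenesis, methanogenesis sub-pathways). AGCNs are summed
over KOs with similar function and the median is taken where KOs are
subunits of one complex (a complex's copy number is not the sum of its
subunit counts); spectral counts are always summed. Display filtering keeps
enzymes with at least 10 spectral counts in some condition — the one
inclusive threshold, following the "≥ 10" convention, where the quality
thresholds below are strict. A pathway category is *present* for a MAG in a
condition when any member KO of any group in the category has a positive
spectral count; no minimum count is imposed, the most literal reading of
presence "based on the metaproteome counts", and the threshold is
configurable where stricter calls are wanted. The packaged
`key_enzymes.tsv` mapping is data, not code: users can and should edit it
for their own study.

### Quality filtering and category summaries

High-quality MAGs are those **above** 50% completeness, **below** 10%
contamination, and **above** 0.5% relative abundance in either omics layer
of any condition — all strict inequalities, matching the above/below
wording. The three-way category summary partitions each abundance column
into (1) unbinned plus quality-failing MAGs, (2) quality-passing MAGs at or
below the abundance threshold in both layers, and (3) quality-passing MAGs
above it; note that the abundance clause is a *category split* here, not a
quality criterion, so the partition always covers the whole community and
every column sums to 100.

### Metadata correlations

Taxon abundances against process parameters use plain Pearson correlation
with at least three paired observations. A constant vector makes $r$
undefined; it is reported as missing with a warning, never coerced to 0. The
clustered ordering in the correlation heatmap (average linkage on Euclidean
distance) is cosmetic, not contractual.

## The synthetic-community generator

The generator produces count tables — not sequences, reads or spectra —
because counts are the pipeline's true inputs. Its defaults encode the study
conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| conditions × replicates | 3 × 3 | three digesters sampled in triplicate |
| unmapped fraction | U(0.11, 0.18) | the stated 11–18% unmapped range |
| unbinned fraction | 0.2 | a substantial unbinned community share |
| abundance distribution | log-normal, $\sigma = 1.5$ | heavy-tailed MAG abundances |
| gene lengths | log-normal, median ≈ 900 bp | plausible prokaryotic gene lengths |
| spectral dispersion | 0.3 (negative binomial) | over-dispersion is the norm in spectral counting |
| activity multipliers | log-uniform on [0.25, 4] | per-MAG translation activity |
| non-unique metaproteins | 5% | exercises the exclusion rule |
| reads / spectra per sample | 200,000 / 20,000 | desk-scale yet informative |

Mechanics worth knowing:

* Expected read counts are proportional to (MAG abundance × gene length)
  with Poisson noise; expected spectral counts are proportional to (MAG
  abundance × activity multiplier), shared equally among the MAG's genes,
  with negative-binomial noise (Poisson at dispersion 0).
* Ten USiCG KOs are planted at exactly one copy per genome, and
  `planted_multicopy` KOs at any stated copy number, giving a ground-truth
  copy-number oracle for AGCN. Marker genes take the median gene length —
  mirroring the conserved lengths of ribosomal proteins — and always carry
  filter-passing annotations, so copy-number recovery is not confounded by
  length lottery or annotation loss on a handful of critical genes.
* Completeness is realised by withholding a random gene subset of
  deterministic size from each MAG, so incomplete MAGs genuinely miss genes
  (including, possibly, markers).
* Archaeal hyperactivity (high proteomic, low genomic abundance) is just a
  large activity multiplier; no special case exists.
* A fixed seed makes all outputs identical across runs; the read-count,
  spectral-count and community stages draw from seeds offset by fixed
  constants so each stage is independently reproducible.

What the generator does **not** emulate: mapping ambiguity and chimeric
contigs, contamination as foreign gene content (contamination is metadata
only), peptide-level identification error, protein length and detectability
effects on spectral counts, and compositional correlations between
conditions. Passing recovery tests on this generator therefore demonstrates
the correctness of the quantification arithmetic and the statistical
soundness of the normalizations — not robustness to the full error structure
of real sequencing and MS data.

Because ground-truth abundances are organism-level fractions while read
shares are genome-length weighted, recovery is assessed by rank correlation
(Spearman), not by absolute agreement. At the default scale (20 MAGs, nine
samples of 200,000 reads) the per-condition Spearman correlation between
estimated and true MAG abundances exceeds 0.95, and a KO planted at two
copies per genome recovers an AGCN within 10% of 2 — both recomputed by
`scripts/acceptance.R` and the test suite at exactly these problem sizes.

## Numerical conventions

* Percentages are carried as percentages (columns sum to 100, tolerance
  1e-9 in tests); activity fractions are carried in $[0,1]$.
* Missing values are the `NA` sentinel on disk and `NA`/`NaN` in memory;
  empty annotation cells mean *absent*, never zero.
* Ties in medians need no special handling (`stats::median` on even counts
  interpolates); the percentile for the offset uses quantile type 7.
* Degenerate inputs fail loudly and early: zero-read samples, zero-sum
  spectral columns, zero-completeness MAGs, a zero USiCG median, malformed
  module expressions and unknown config keys are all hard errors naming the
  offender. The two deliberate soft cases are an all-non-unique metaprotein
  table (empty result with a warning) and a MAG with zero spectra in a
  condition (activity 0 with a warning).

## Known limitations

* The module grammar excludes nested boolean structure; complex real module
  definitions must be flattened before use.
* AGCN is only as good as the USiCG set: communities where the packaged
  ribosomal KOs are poorly annotated need a custom set.
* The completeness adjustment assumes spectra missing due to incompleteness
  are missing at random with respect to expression, which is optimistic for
  strongly expressed operons on missing contigs.
* `metadata_correlations` with few samples is descriptive, not inferential;
  no p-values are attached by design.
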