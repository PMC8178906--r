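---
title: "Methods: snoRNA family expression statistics and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snoRNA family expression statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snofam)
```

## The problem

Small nucleolar RNAs guide the chemical modification of ribosomal and small
nuclear RNAs. In mammalian genomes they are heavily multi-copied:
recombination within a host gene and retrotransposition across the genome
leave families of near-identical copies, most of which are never detected
as expressed. `snofam` quantifies how such families behave across a panel
of tissues: which copies are expressed, how similar they remain in
sequence, whether the family buffers its total output while individual
members vary, and whether the identity of the most abundant copy switches
between tissues.

The package assumes its inputs are already quantified: a family-annotated
snoRNA table and a TPM matrix over tissue-replicate samples. Read
processing, alignment and multimapper-aware quantification are upstream
concerns; a TPM matrix produced by any pipeline can be used, with the
caveat that read assignment between *identical* copies is inherently
ambiguous — which is why families containing an identical pair are flagged
(`find_identical_pairs()`) rather than silently trusted.

## Expression status

A snoRNA is called expressed when its abundance reaches the threshold
(default 1 TPM) in **at least one sample**, not one tissue mean. The
comparison is inclusive (`>=`) by default. Both choices are exposed
(`threshold`, `inclusive`) because the boundary convention only matters for
values exactly at the threshold and users may need to match either
convention; the per-sample rule is the default and a tissue-mean rule can
be obtained by passing the tissue-means table as the matrix. Per-snoRNA
summaries report the average, minimum and maximum TPM over all samples and
the tissue with the highest mean abundance; top-tissue ties resolve by the
canonical tissue order of the sample panel, and a snoRNA at zero in every
tissue gets the sentinel `"none"`.

## Pairwise identity

Identity between two members is `100 * S(a, b) / min(|a|, |b|)` where
`S(a, b)` is the optimal global alignment score with reward 1 per matched
residue and no mismatch or gap penalty. This score equals the
longest-common-subsequence length, which is the implementation contract:
the Rcpp kernel computes only the DP score, never a traceback, because the
score is unique even when optimal alignments are not. Normalizing by the
shorter sequence makes a perfect containment score 100; for that reason
the identical-pair flag additionally requires *string equality*, since
only truly identical copies make read assignment ambiguous. Sequences are
normalized at ingest (uppercase, U→T) so RNA and DNA spellings never count
as mismatches. Identity is computed within families only; a singleton has
no partner and reports `NA`.

## Genomic context

Internal coordinates are 0-based half-open everywhere; GTF input (1-based
closed) is converted at the boundary. Conservation is averaged per
nucleotide over the snoRNA span; nucleotides not covered by any track
interval contribute 0 by default, matching a division by the full snoRNA
length (a covered-only average is available via `uncovered_zero = FALSE`,
returning `NA` when nothing is covered). SNP density is
`1000 * count / length`.

Host-transcript assignment sorts the host gene's transcripts by exon count
(descending) then transcript name (ascending) and picks the first
transcript whose span contains the snoRNA and whose exons it does not
overlap — i.e. the first transcript in which the snoRNA is fully
intronic, the only reading under which "distance to the downstream exon"
is well defined. The distance is the strand-aware gap from the snoRNA 3′
end to the nearest downstream exon edge in transcript orientation, a
non-negative count of intervening nucleotides under end-exclusive
arithmetic. When no transcript qualifies the snoRNA is called
non-intronic and the distance is undefined.

Family context is `coding_only` / `noncoding_only` / `intergenic_only`
when all considered members share that context and `mixed` otherwise;
mixtures involving intergenic plus intronic members fall in `mixed`, so
the four categories partition the families. The per-snoRNA biotype is
taken from the annotation table as given — when transcript-level biotypes
conflict within a gene, resolving them is the annotation's responsibility,
not this package's. The `same_host` flag is defined only for families with
at least two expressed members.

## Variability and the class comparison

The coefficient of variation is `100 * sd / mean`, computed over the seven
tissue means. The standard deviation uses the sample convention (n − 1) by
default with a population option (`ddof = 0`): the panel is small, and
exposing the convention lets users match externally computed tables under
either choice. The family CV reduces the per-tissue *sums* over expressed
members; only expressed members enter, since unexpressed copies contribute
no functional output. The diagonal distance
`(family_cv − mean_member_cv)/sqrt(2)` is the signed perpendicular
distance to the x = y line; the `sqrt(2)` scaling is monotone and
irrelevant to the rank test but makes the quantity an actual Euclidean
distance in the CV–CV plane. Classes are compared with a two-sided
Mann–Whitney U test using the normal approximation with continuity
correction — deterministic in the presence of ties, which exact methods
refuse.

The size–abundance correlation relates the number of expressed members to
the family's average total abundance (mean over samples of the summed
member TPM). Pearson is the default with a Spearman option; the summed
abundance includes all members by default (unexpressed members contribute
near-zero TPM either way), with a flag to restrict.

## Switches

Members rank by total abundance (sum of tissue means, ties by ascending
id). Per tissue, the expressed member with the highest mean is called;
exact ties resolve to the member with the better overall rank — not
lexicographically — so floating-point-level ties cannot manufacture
spurious switches. Tissues where every expressed member averages zero are
degenerate and contribute no switch evidence. A family switches when at
least two distinct members are called top in different tissues; families
with fewer than two expressed members are never eligible. No requirement
is imposed that the overall rank-1 member be expressed in every tissue.

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure of a 7-tissue,
3-replicate study of 200 box C/D and 100 box H/ACA families:

* **Family sizes** mix a singleton spike (40% of C/D families, 29% of
  H/ACA), negative-binomial multi-member sizes, and a 2% chance of a very
  large family (C/D up to 450 members, H/ACA up to 39) — many singletons,
  a heavy tail, H/ACA families larger on average except for the few giant
  C/D families.
* **Expression** targets overall fractions of 37.3% (C/D) and 41.0%
  (H/ACA); singletons are expressed with probability 0.96 and the
  multi-member rate is derived so the class-wide expectation hits the
  target.
* **Abundance** for expressed members is log10-normal (mean 1.5, sd 1.0,
  clamped to [2, 5·10^4] TPM), spanning more than three orders of
  magnitude in large families. Unexpressed members draw uniformly from
  [0, 0.5 · threshold) — never at the boundary, so status recovery is
  independent of the `>=` vs `>` convention.
* **Replicate noise** is multiplicative log-normal at 20% CV with the
  z-score clamped at ±2.5 sd. The clamp bounds the worst-case ratio of two
  noise factors at `exp(2 · 2.5 · sdlog) ≈ 2.69`, and every planted
  dominance gap is sized above that bound: switch owners dominate their
  tissue block 4-fold, each member's designated top tissue is boosted
  3-fold, and rank gaps in non-switch families are enforced at
  `3 · 2.69 · 1.1 ≈ 8.9`-fold. Planted statuses, top tissues, per-tissue
  top calls and switch sets are therefore recoverable *exactly*, by
  construction rather than with high probability. Raising the noise CV
  beyond the point where the planted effects clear this margin triggers a
  warning.
* **Sequences** mutate per-family random ancestors (C/D 70–130 nt, H/ACA
  110–145 nt) at 8% per site per copy; 8 C/D and 5 H/ACA families receive
  a planted identical pair, and accidental identities elsewhere are broken
  by a forced substitution so the identical-pair truth is exact.
* **Hosts**: 60% of C/D families place all copies in one host gene versus
  10% of H/ACA (cis-recombination versus retrotransposition); a small
  per-class fraction of families is entirely intergenic (2/126 and 14/91).
  Each host gene carries 1–3 transcripts — the full intron-chain isoform,
  sometimes a single-exon retained isoform, a duplicate isoform with an
  alphabetically later name, and sometimes an isoform with an extra exon
  overlapping the first snoRNA — so the exon-count sort, the name
  tie-break and the skip-on-overlap iteration are all exercised. Planted
  intron distances are log-normal with mode near 70 nt for C/D and a
  broader, larger distribution for H/ACA.
* **Conservation and SNPs**: Beta-distributed per-snoRNA scores (mean 0.7
  for expressed, 0.2 for unexpressed members), occasionally split into
  adjacent equal-score intervals; binomial SNP counts at 0.01/nt, scaled
  by 0.3 for the conserved (expressed) members.

What the generator does **not** emulate: read-assignment ambiguity and
multimapping (inputs are true abundances, not re-quantified reads);
correlation of expression status *within* families beyond the planted
switch structure, so the fraction of families expressing at least half
their members is lower than in real cohorts where member statuses are
strongly correlated; and the empirical enrichment of families below the
x = y CV diagonal — member profiles are generated independently rather
than anti-correlated, so the diagonal-distance distribution is roughly
centred rather than shifted negative. Passing the planted-truth tests
therefore demonstrates correctness of the statistics, not that real
cohorts will show any particular sign or effect size on these statistics.

## Numerical choices and degenerate inputs

Undefined quantities are sentinels, never silent zeros: CV of a zero-mean
vector is `NA`, the expressed-only context of a family with no expressed
member is `"undefined"`, the same-host flag below two expressed members is
`NA`, and columns depending on an absent optional input (conservation,
SNPs, GTF) are emitted as `NA`. Correlations with zero variance in either
variable return `NA`. All tie-breaks are deterministic (canonical tissue
order, ascending ids, transcript name order), which together with
seed-driven generation makes every emitted file byte-reproducible.

## Problem sizes

The test suite validates the identity kernel against an
exhaustive-subsequence oracle on strings up to 12 nt and a
dynamic-programming oracle on 1,000 random pairs, the rank test against
exhaustive pair counting on all list-length combinations up to 8, and the
full pipeline against planted truth on the default 200 + 100-family cohort
(seed 42) plus smaller cohorts of 25 + 15 families for the faster
structural checks. The acceptance script regenerates the default cohort
and recomputes all headline quantities in well under a minute on one CPU.
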