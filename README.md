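# snofam

Multi-copy regulation of small nucleolar RNAs (snoRNAs), analysed at the
family level. Mammalian genomes carry many snoRNA genes in families of
near-identical copies produced by recombination and retrotransposition; most
annotated copies are never detected as expressed, and the expressed ones can
differ in abundance by orders of magnitude and even swap rank between
tissues. `snofam` is an R package for scientists who have (i) a
family-annotated snoRNA table and (ii) a tissue-replicate TPM abundance
matrix, and who want the standard battery of family statistics: expression
status, pairwise sequence identity within families, conservation and SNP
summaries, family-versus-member abundance variability, tissue switches in
the most abundant member, and host-gene context classification.

## The statistics at the core

* **Expression rule.** A snoRNA is *expressed* when its abundance reaches
  1 TPM in at least one sample (inclusive comparison; both the threshold
  and the inclusivity are configurable).
* **Pairwise identity.** For sequences *a*, *b* the identity is
  `100 · S(a,b) / min(|a|, |b|)`, where `S(a,b)` is the optimal score of a
  global alignment with reward 1 per matched residue and no mismatch or gap
  penalty. That score equals the longest-common-subsequence length
  `LCS(a,b)`, which is how it is computed (Rcpp kernel); the score is unique
  even when optimal alignments are not.
* **Variability.** Per family, the *family CV* is the coefficient of
  variation (`CV = 100·σ/μ`) across tissues of the summed abundance of the
  expressed members, and the *mean member CV* averages each expressed
  member's own CV across tissues. The signed distance to the x = y diagonal,
  `(family CV − mean member CV)/√2`, is negative when member variability
  exceeds family variability; the two snoRNA classes are compared on it with
  a two-sided Mann–Whitney U test.
* **Switches.** Per tissue, the most abundant expressed member is called
  (ties resolve to the member with better overall rank); a family *switches*
  when at least two distinct members rank first in different tissues.
  Only families with ≥ 2 expressed members are switch-eligible.
* **Host context.** Intronic snoRNAs are assigned to the first host
  transcript — sorted by exon count (descending) then name (ascending) —
  whose span contains them and whose exons they do not overlap; the reported
  distance runs from the snoRNA 3′ end to the start of the first downstream
  exon, strand-aware. Families are classified `coding_only`,
  `noncoding_only`, `intergenic_only` or `mixed` over their (all or
  expressed) members.

A synthetic cohort generator (`synthetic_config()` / `simulate_cohort()`)
emits a complete input bundle — annotation TSV, FASTA, GTF host models,
bedGraph conservation, BED SNPs, replicate-structured TPM matrix — with
planted ground truth, so the whole pipeline runs and validates with no
external data.

## Worked example

```r
library(snofam)
library(dplyr)

config <- synthetic_config(seed = 7, n_cd_families = 60, n_haca_families = 40,
                           n_switch_families = c(CD = 6, HACA = 3))
sim    <- simulate_cohort(config)
bundle <- write_bundle(sim, "cohort")

result <- run_pipeline(bundle[["annotation"]], bundle[["abundance"]],
                       bundle[["samples"]], gtf = bundle[["gtf"]],
                       conservation = bundle[["conservation"]],
                       snps = bundle[["snps"]])
result
#> <snofam_result> 435 snoRNAs, 100 families; 172 expressed snoRNAs; 9 switch families

result$sno_summary |>
  filter(expressed) |>
  select(snorna_id, family_id, avg_tpm, top_tissue, cv, alignment_score) |>
  head(5)
#> # A tibble: 5 × 6
#>   snorna_id      family_id avg_tpm top_tissue    cv alignment_score
#>   <chr>          <chr>       <dbl> <chr>      <dbl>           <dbl>
#> 1 FAMCD0002.M001 FAMCD0002  108.   brain       73.9            NA
#> 2 FAMCD0003.M001 FAMCD0003  173.   liver       65.7            NA
#> 3 FAMCD0005.M001 FAMCD0005    3.36 prostate    67.4            NA
#> 4 FAMCD0007.M001 FAMCD0007    7.49 breast      54.2            NA
#> 5 FAMCD0008.M003 FAMCD0008  346.   testis      52.4            84.4
```

Each row is one snoRNA: its average TPM over the 21 samples, the tissue
where its mean abundance peaks, its CV across tissue means, and its mean
pairwise identity to the other members of its family (`NA` for singletons,
which have no family partner to align against).

```r
cd <- result$report$classes$CD
sprintf("C/D: %.1f%% of snoRNAs in multi-member families; %.1f%% expressed",
        cd$pct_snornas_in_multi_member, cd$pct_expressed)
#> "C/D: 87.9% of snoRNAs in multi-member families; 39.5% expressed"
sprintf("C/D switch families: %d of %d eligible; same-host: %.1f%%",
        cd$n_switch_families, cd$n_switch_eligible, cd$same_host$pct)
#> "C/D switch families: 6 of 17 eligible; same-host: 70.6%"

pairwise_identity("ACGT", "AGGT")   # LCS "AGT" over min length 4
#> [1] 75
```

The six planted C/D switch families are exactly the six recovered. Every
report statistic names its denominator (all snoRNAs of the class, families
with ≥ 2 members, or families with ≥ 2 expressed members) because those
denominators differ between statistics.

Plot helpers: `plot_family_profile()` (per-family abundance bars across
tissues), `plot_family_variability()` (family CV vs mean member CV),
`plot_top_member_heatmap()` (categorical switch heatmap),
`plot_family_sizes()`, and `autoplot()` on `family_identity()` objects.
`tidy()`/`glance()` methods cover the test, identity and pipeline-result
objects.

A thin command-line wrapper is installed with the package:

```sh
snofam simulate --seed 5 --out sim_dir
snofam run --annotation sim_dir/annotation.tsv --abundance sim_dir/abundance.tsv \
       --samples sim_dir/samples.tsv --gtf sim_dir/hosts.gtf --out out_dir
```

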