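# autozygmap

Mapping a monogenic autosomal recessive trait in a closed population — a dog
breed being the archetype — follows a well-worn path: genotype a modest
case/control cohort on a SNP array, run a kinship-corrected association scan,
refine the signal by autozygosity mapping (all affected animals must be
homozygous for the same ancestral haplotype around the causal variant), then
sequence a couple of cases and filter their variants down to the ones that
are shared homozygous, absent from a large panel of control genomes, inside
the critical interval, and protein-changing. `autozygmap` packages that whole
path as tested, reusable R functions, together with a gene-drop population
simulator that generates study data with known truth so every stage can be
validated end to end.

It is aimed at researchers doing Mendelian trait mapping in livestock and
companion-animal genetics (and at anyone teaching the method) who want the
pipeline's statistical steps — exact tests included — as auditable code
rather than a chain of one-off shell commands.

## The method

**Association.** After fixed-order QC (sample call rate ≥ 0.9, marker call
rate ≥ 0.9, MAF ≥ 0.1, exact Hardy–Weinberg test in controls at p ≥ 1e−5),
each marker is tested with the single-random-effect linear mixed model

    y = μ + x β + u + ε,   u ~ N(0, σ_g² K),   ε ~ N(0, σ_e² I)

where `K` is a centered genomic relationship matrix (or allele-sharing IBS
matrix). The variance ratio δ = σ_e²/σ_g² is re-estimated per marker by REML
through one eigendecomposition of `K` (the EMMA rotation), and β is tested
with a Wald statistic referred to F(1, n−2). The genomic inflation factor
λ = median(χ²)/0.4549 is reported for the uncorrected allelic χ² scan
(before) and the mixed-model p-values (after), along with the suggestive
(5×10⁻⁵) and Bonferroni (α/m) thresholds.

**Autozygosity mapping.** Across the cases only, maximal runs of consecutive
markers at which every case is homozygous for the same allele (missing calls
tolerated up to a per-marker fraction) are reported as shared segments; the
critical interval runs to the first flanking discordant marker on either
side, and segments are ranked by the best association p-value they contain.

**Prioritization cascade.** Sequence-tier case variants are filtered in the
order: shared homozygous genome-wide → private against the control panel
(any observed alt allele in the panel, heterozygous included, disqualifies)
→ restricted to the critical interval → private in the interval →
protein-changing, the last step via a built-in transcript-aware annotator
that emits HGVS `c.`/`p.` strings (e.g. `c.1438C>A`, `p.(Pro480Thr)`).

**Genotype–phenotype association.** Candidate variants are tabulated by
breed and phenotype and tested exactly (log-space hypergeometric Fisher
test, stable down to p ~ 1e−40) under recessive, dominant, allelic or full
genotypic codings.

## A worked example

```r
library(autozygmap)

cfg <- pipeline_config(
  sim = sim_config(seed = 1, n_neutral_private_variants = 1))
man <- full_run(cfg, "run1")

man$n_markers_after_qc   # 1948
man$lambda_before        # 1.298  (allelic scan, related cohort)
man$lambda_after         # 0.730  (mixed model)
man$cascade_counts       # step1 1353, step2 2, step3 96, step4 2, step5 1
man$candidate            # "chr1:10000000:C:A"
man$assoc_p              # 1.28e-11
```

The simulated cohort (14 cases, 29 controls, two 20-Mb chromosomes with
1,000 markers each) carries a recessive causal variant at chr1:10,000,000 on
an identical-by-descent haplotype; one non-coding decoy private variant was
planted beside it. After QC, 1,948 markers remain; the allelic scan is
inflated (λ = 1.30) by the relatedness the mixed model then absorbs
(λ = 0.73). The cases share one homozygous segment whose critical interval
contains the causal variant; the cascade reduces 1,353 shared homozygous
variants to exactly one private protein-changing candidate — the planted
missense variant — and the exact recessive test on the cohort genotypes
associates it with the phenotype at p ≈ 1.3e−11. All reports (association
tables, segment list, filter report, genotype counts, manifest with file
digests) are written into `run1/`.

Individual stages are plain functions (`qc_filter()`, `kinship()`,
`lmm_scan()`, `find_shared_homozygous_segments()`, `critical_interval()`,
`run_cascade()`, `annotate()`, `test_variant()`, …) and work on data read
with `read_genotypes()` (PLINK transposed text or VCF), `read_bed()` and
`read_transcript_table()`.

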