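---
title: "Mapping recessive traits in closed populations: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive traits in closed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`autozygmap` implements the standard positional-cloning strategy for a
monogenic autosomal recessive trait segregating in a closed population:
array QC, kinship-corrected association, autozygosity mapping, a
private-variant prioritization cascade against a control genome panel,
consequence annotation, and exact genotype–phenotype association. This
vignette explains the models behind each stage, the parameters that matter,
the choices we made where the design was genuinely open, and what the
simulation-based validation does and does not demonstrate.

## 1. The mixed-model association scan

The phenotype vector `y` (1 = case, 0 = control) is regressed on each
marker's allele dosage `x` under

$$ y = \mu + x\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\qquad \varepsilon \sim N(0, \sigma_e^2 I). $$

`K` is either the centered genomic relationship matrix (cross-product of
mean-centered dosages scaled by $\sum_j 2p_j(1-p_j)$, the default) or the
allele-sharing IBS matrix; both are provided because array studies use
either, and they differ mainly by an affine transform that the mixed model
absorbs. Closed populations make this correction essential: full siblings
and popular sires inflate the naive allelic test, and the genomic inflation
factor of that uncorrected scan (`lambda_before`) versus the mixed model
(`lambda_after`) quantifies how much structure the random effect removed.

Fitting uses the eigendecomposition rotation: with `K = U D U'`, rotating
`y`, the intercept and `x` by `U'` turns the covariance into the diagonal
`D + δI`, where `δ = σ_e²/σ_g²`. The profiled REML log-likelihood is then a
cheap 1-D function of `δ`, which we re-optimize for every marker
(`optimize()` on log δ over [1e−5, 1e5]; desk-scale marker counts make
per-marker re-optimization affordable, and it removes the approximation of
re-using the null model's δ). The marker effect is tested by a Wald
statistic referred to **F(1, n−2)**, not χ²(1): at cohort sizes around 40
the χ² reference is visibly anti-conservative, while the F form is exact in
the degenerate case `K = cI`, where the whole model collapses to ordinary
least squares for every `c > 0` — a property the test suite asserts.
Missing genotypes are mean-imputed per marker for the regression only; the
stored data keep their missingness.

QC runs in a fixed, logged order — sample call rate, marker call rate,
minor allele frequency (post-sample-QC, phenotypes pooled), exact
Hardy–Weinberg test in controls only (monomorphic-in-controls markers are
exempt) — with defaults 0.90 / 0.90 / 0.10 / 1e−5. The order is a package
decision; it makes removal counts auditable and the pass idempotent. The
HWE test is the exact conditional test: given the allele counts, the
two-sided p-value sums the probabilities of all heterozygote counts no more
probable than the observed one.

## 2. Autozygosity mapping

All cases descend from a common carrier ancestor, so around the causal
variant every case is homozygous for the same haplotype. The detector scans
each chromosome for maximal runs of markers at which (i) no case has a
heterozygous call, (ii) all non-missing homozygous calls agree, and
(iii) at most a fraction `max_missing_fraction` (default 0.2) of cases are
missing — a missing call cannot prove discordance, so it is
segment-compatible. Strictness (zero tolerated heterozygotes) is the
default because the critical interval is *defined* by the first flanking
discordant markers; a noisy-array tolerance knob exists but changes the
interval's meaning. Runs shorter than `min_markers` (default 25) are
dropped to suppress chance runs at array density. The critical interval is
closed and includes the flanking marker positions themselves, since those
coordinates are what delimit where a recessive causal variant can live;
a segment reaching a chromosome end falls back to the outermost marker
position. Segments are ranked by the best contained mixed-model p-value,
ties broken by marker count then position, so the ordering is reproducible
under input shuffles.

## 3. The prioritization cascade

Sequence-tier case variants pass five ordered filters: shared homozygous
genome-wide; private against the control panel genome-wide; the genome-wide
*shared* set restricted to the critical interval; private within the
interval; protein-changing. The third row is recomputed from the first, not
the second — the report mirrors the genome-wide/in-interval structure of
such filtering tables, which is why its counts are only partially ordered
(each row is bounded by its applicable predecessor, and the constructor
asserts exactly that partial order). "Private" means the alt allele is
observed in **zero** panel genomes; a single heterozygous panel carrier
disqualifies. That is the strict reading of absence and the right one for a
fully penetrant recessive disease allele, since any panel carrier would
have to be an undiagnosed case or a phenotyping error if the allele were
causal and common enough to observe.

The protein-changing step uses the built-in annotator: genomic positions
map to CDS coordinates by exon arithmetic (minus-strand transcripts count
from the CDS end with complemented alleles), codons come from a reference
CDS sequence carried with the transcript model, and translation uses the
standard genetic code. The codon context is supplied with the transcript
table rather than a genome FASTA because the pipeline needs only the
transcript under the peak; the annotator checks the declared ref allele
against that context and refuses to annotate on mismatch. Intronic
positions within 2 bp of an exon boundary are classed splice-site (the
canonical GT/AG dinucleotides); splice-site, missense, nonsense and the
indel proxy class count as protein-changing, synonymous/UTR/intronic/
intergenic do not. Predicted protein changes are written in the
parenthesized HGVS style, `p.(Pro480Thr)`.

## 4. Exact genotype–phenotype association

Candidate variants are tabulated by breed and phenotype and tested exactly.
The 2×2 Fisher test is computed in log space from the hypergeometric
likelihood, with the conventional probability-mass two-sided rule and a
relative tolerance of 1e−7 on the probability comparison; p-values of
magnitude 1e−40 are finite and stable to row reordering. The default
headline coding is **recessive** (homozygous-alt versus everything else),
the natural collapse for a recessive disease model; dominant, allelic and
full 2×3 genotypic codings are available, the last by exhaustive
enumeration up to a grand total of 400 and a seeded Monte Carlo estimate
beyond. A minimum-count guard (5 per phenotype margin, configurable)
refuses to test single-individual strata on their own; they are still
reported in the table. Odds ratios with a zero cell use the
Haldane–Anscombe +0.5 correction and are flagged as corrected.

## 5. The synthetic study generator

No raw genotype or sequence data ship with the package, so validation rests
on a gene-drop simulator whose defaults are the package's reference study
conditions: an array cohort of 14 cases and 29 controls from one breed, two
sequenced cases, a 60-genome control panel, two 20-Mb chromosomes carrying
1,000 array markers each (≈20 kb spacing, a typical high-density canine
array scaled down) drawn from 4,000 sequence-tier sites per chromosome, a
causal variant at chr1:10 Mb inside a 1-Mb identical-by-descent segment,
2% array missingness, and no phenotype error by default (the error knob
mislabels a non-homozygote as a case, emulating occasional clinical
misdiagnosis).

The demography is a founder bottleneck — six founder haplotypes, one
carrying the causal alt allele — followed by 20 generations of fixed-size
(300 diploids) random mating with uniform Poisson recombination at
3×10⁻⁸ per bp per meiosis. The product of generations and rate sets the LD
decay scale (~Mb-long shared haplotypes, the regime that makes autozygosity
mapping work in breeds); it was fixed once and the split between the two
factors chosen for simulation cost. The causal founder haplotype starts at
frequency 0.35: a strong popular-sire effect, consistent with a breed in
which roughly 5% of animals are affected homozygotes, and necessary for a
300-animal population to reliably contain 14 recruitable cases. Cases are
sampled from genuine homozygous carriers; an explicitly bounded retry loop
fails loudly if the configuration cannot produce enough homozygotes —
labels are never silently adjusted.

Two deliberate idealizations deserve emphasis:

* **The truth segment is exact.** Sampled cases' haplotypes are coerced to
  the causal founder over the configured segment around the causal variant,
  and identity-by-descent is broken decisively at the segment boundary
  (each case haplotype reverts to a random non-causal founder over a
  flanking window). Without the break, genuine carriers remain
  identical-by-descent for an emergent, seed-dependent distance beyond any
  configured segment, and "the detected region lies within the truth
  segment" would not be a testable invariant at marker resolution. With it,
  the configured `ibd_segment_length_bp` *is* the shared length, truth is
  exact, and the detector's output can be held to it strictly.
* **Neutral alleles are common.** Every neutral site places each allele on
  at least two of the six founder haplotypes, emulating the
  array/panel-ascertained common polymorphism a joint-called control panel
  sees. Consequently the only case-private variants are the causal one and
  any deliberately planted decoys, which makes cascade counts deterministic
  checks rather than draws.

What passing tests on this generator show: the QC, scan, segment detection,
interval definition, cascade and exact tests are internally correct and
recover planted truth under breed-like LD and relatedness. What they do not
show: performance under genotyping artifacts correlated with plate or
batch, allelic dropout, sequencing error in the variant tables (the
sequence tier is generated as called genotypes — the real pipeline consumes
caller output, so caller error is out of scope), structural variation,
locus heterogeneity, or phenocopies beyond simple mislabeling.

## 6. Numerical and procedural choices

* Coordinates are 1-based inclusive everywhere; BED files are converted at
  the I/O boundary (and that conversion is covered by a fixture test).
* PLINK transposed text is the canonical array format (desk-scale,
  human-inspectable); binary PLINK is out of scope. Multi-allelic VCF
  records are split into one biallelic record per alt allele on read, and
  `./.` maps to the same missing state as an array no-call.
* Marker allele labels from transposed text are assigned alphabetically;
  a marker whose file content shows only one allele cannot name the other,
  so bit-exact round-trips hold for markers where both alleles are
  observed.
* The REML search runs on log δ over [1e−5, 1e5]; kinship matrices are
  eigendecomposed once per scan and rejected (naming the offending
  eigenvalue) if meaningfully non-PSD. Monomorphic markers are flagged and
  carry p = 1 rather than being silently dropped.
* The uniformity check of the null scan uses 2,000 *independent* simulated
  markers: the Kolmogorov–Smirnov test presumes exchangeable draws, and on
  LD-structured genotypes its p-value reflects inter-marker correlation
  rather than miscalibration. Calibration and LD-robust behavior are thus
  tested separately (the latter through the 50-replicate recovery
  properties below).
* Validation problem sizes, chosen once: the recovery properties run 50
  replicate default studies and require the top segment's critical interval
  to contain the causal variant in ≥95% of them and the genome-wide best
  mixed-model marker to fall inside the truth segment in ≥90%; exact-test
  implementations are swept exhaustively against enumeration oracles over
  all 2×2 tables with total ≤60 and all HWE triples with n ≤30.

## 7. Known limitations

The annotator handles single-nucleotide substitutions fully; indels receive
a frameshift-proxy class without protein notation, and the full HGVS
grammar (dup/ins/delins), multi-transcript prioritization and conservation
scoring are out of scope. The association stage supports no covariates
beyond the intercept and no X-chromosome dosage model. Within-individual
runs of homozygosity (single-sample ROH calling) are deliberately not
implemented — the mapping rule here is *shared* homozygosity across cases.
The pipeline consumes called variant tables; read-level processing belongs
upstream.
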