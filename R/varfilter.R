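# Prioritization cascade for a recessive disease: variants shared homozygous
# across the sequenced cases, private against a control genome panel,
# restricted to the critical interval, and protein-changing.

.merge_case_sets <- function(cases) {
  if (inherits(cases, "variant_set")) return(cases)
  if (!is.list(cases) || !length(cases)) stop("at least one case variant set is required")
  keys <- unique(unlist(lapply(cases, variant_keys)))
  proto <- do.call(rbind, lapply(cases, function(v) v$variants))
  proto <- proto[match(keys, paste(proto$chrom, proto$pos, proto$ref, proto$alt, sep = ":")), ]
  samples <- unlist(lapply(cases, `[[`, "samples"))
  if (anyDuplicated(samples) > 0L) stop("duplicate sample ids across case variant sets")
  geno <- do.call(rbind, lapply(cases, function(v) {
    m <- matrix(0L, length(v$samples), length(keys))  # absent record = hom-ref
    hit <- match(variant_keys(v), keys)
    m[, hit] <- v$geno
    m
  }))
  variant_set(proto, geno, samples)
}

#' Control genome panel
#'
#' Wraps a [variant_set] of control genomes into an allele-presence index
#' queryable by (chromosome, position, ref, alt). An alt allele is "observed"
#' in the panel if any panel genome carries it in any genotype state
#' (heterozygous counts).
#'
#' @param vs a [variant_set] over the panel genomes (or an existing
#'   `control_panel`, returned unchanged).
#' @return a `control_panel` with the observed-allele key index and
#'   `n_genomes`.
#' @export
control_panel <- function(vs) {
  if (inherits(vs, "control_panel")) return(vs)
  stopifnot(inherits(vs, "variant_set"))
  seen <- colSums(vs$geno > 0L, na.rm = TRUE) > 0L
  structure(list(index = variant_keys(vs)[seen], n_genomes = length(vs$samples)),
            class = "control_panel")
}

#' Variants homozygous-alt in every sequenced case
#'
#' @param cases a [variant_set] holding all sequenced cases, or a list of
#'   per-case variant sets (merged by variant identity; a record absent from
#'   a case's set counts as hom-ref for that case).
#' @return a [variant_set] of the variants at which every case is genotyped
#'   homozygous for the same alt allele (missing calls do not qualify).
#' @export
shared_homozygous <- function(cases) {
  vs <- .merge_case_sets(cases)
  if (!length(vs$samples)) stop("at least one sequenced case is required")
  keep <- colSums(vs$geno == 2L & !is.na(vs$geno)) == length(vs$samples)
  subset_variants(vs, which(keep))
}

#' Variants private against a control panel
#'
#' Retains variants whose alt allele is observed in zero panel genomes;
#' any genotype state in the panel (including heterozygous) counts as
#' observed.
#'
#' @param vs a [variant_set].
#' @param panel a [control_panel] or a panel [variant_set].
#' @return the private subset of `vs`.
#' @export
private_against <- function(vs, panel) {
  panel <- control_panel(panel)
  subset_variants(vs, which(!(variant_keys(vs) %in% panel$index)))
}

#' Restrict a variant set to a genomic interval
#'
#' Keeps variants whose position lies in the closed, 1-based interval.
#'
#' @param vs a [variant_set].
#' @param interval a [genome_interval].
#' @return the restricted subset of `vs`.
#' @export
restrict_to <- function(vs, interval) {
  stopifnot(inherits(interval, "genome_interval"))
  v <- vs$variants
  subset_variants(vs, which(v$chrom == interval$chrom &
                              v$pos >= interval$start & v$pos <= interval$end))
}

#' Filter report
#'
#' Ordered per-step labels and surviving-variant counts, with the surviving
#' variant keys retained for audit. Construction asserts the cascade's
#' partial-order monotonicity: each count must not exceed its applicable
#' predecessor (the interval-restricted count is derived from the genome-wide
#' shared set, not from the genome-wide private set, so it is only bounded by
#' the former).
#'
#' @param steps character vector of step labels.
#' @param survivors list of character vectors of surviving variant keys, one
#'   per step.
#' @param predecessor integer vector: for each step, the index of the step
#'   whose count bounds it (0 for none).
#' @return a `filter_report` data frame with attribute `survivors`.
#' @export
filter_report <- function(steps, survivors, predecessor = c(0L, seq_len(length(steps) - 1L))) {
  counts <- lengths(survivors)
  for (i in seq_along(steps)) {
    p <- predecessor[i]
    if (p > 0L && counts[i] > counts[p])
      stop(sprintf("filter report not monotone: step '%s' (%d) exceeds '%s' (%d)",
                   steps[i], counts[i], steps[p], counts[p]))
  }
  df <- data.frame(step = seq_along(steps), label = steps, n_variants = counts,
                   stringsAsFactors = FALSE)
  attr(df, "survivors") <- survivors
  class(df) <- c("filter_report", "data.frame")
  df
}

#' Run the full prioritization cascade
#'
#' Executes, in order: (1) variants homozygous-alt in all sequenced cases
#' genome-wide; (2) those private against the control panel genome-wide;
#' (3) the genome-wide shared set restricted to the critical interval;
#' (4) the restricted set private against the panel; (5) the protein-changing
#' subset of step 4 (consequence annotation against the supplied transcript).
#' Step 3 is recomputed from step 1, not from step 2, mirroring the
#' genome-wide/in-interval structure of the report.
#'
#' @param cases case variant set(s), see [shared_homozygous()].
#' @param panel a [control_panel] or panel [variant_set].
#' @param interval the critical [genome_interval].
#' @param transcript a [transcript_model] for consequence annotation.
#' @return a [filter_report] with attributes `survivors` (variant keys per
#'   step) and `annotations` (consequence calls for the step-4 survivors).
#' @export
run_cascade <- function(cases, panel, interval, transcript) {
  panel <- control_panel(panel)
  r1 <- shared_homozygous(cases)
  r2 <- private_against(r1, panel)
  r3 <- restrict_to(r1, interval)
  r4 <- private_against(r3, panel)
  ann <- annotate_variants(r4, transcript)
  r5 <- subset_variants(r4, which(is_protein_changing(ann)))
  labels <- c("Shared homozygous variants in whole genome",
              sprintf("Private homozygous variants (absent from %d control genomes) in whole genome",
                      panel$n_genomes),
              sprintf("Shared homozygous variants in %d kb critical interval",
                      interval_length_kb(interval)),
              sprintf("Private variants (absent from %d control genomes) in critical interval",
                      panel$n_genomes),
              "Protein changing private variants in critical interval")
  rep <- filter_report(labels,
                       list(variant_keys(r1), variant_keys(r2), variant_keys(r3),
                            variant_keys(r4), variant_keys(r5)),
                       predecessor = c(0L, 1L, 1L, 3L, 4L))
  attr(rep, "annotations") <- ann
  rep
}
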