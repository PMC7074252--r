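#' Marker map
#'
#' A table of array marker coordinates with per-marker allele labels. Positions
#' are 1-based and must be strictly increasing within each chromosome;
#' marker ids must be unique.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based physical positions (bp).
#' @param a1,a2 allele labels (single nucleotides or array A/B codes). Calls
#'   in a [genotype_matrix] count copies of `a2`.
#' @return A `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chrom, pos, a1 = NA_character_, a2 = NA_character_) {
  df <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    a1 = as.character(a1),
    a2 = as.character(a2),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$marker_id) > 0L)
    stop("duplicate marker ids: ", paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  if (anyNA(df$pos) || any(df$pos < 1L)) stop("marker positions must be positive integers")
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions not strictly increasing on chromosome ", ch)
  }
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Genotype matrix
#'
#' Biallelic genotype calls for a set of samples at a set of mapped markers.
#' Calls are coded as the number of copies of the marker's `a2` allele
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing/no-call).
#'
#' @param calls integer matrix, samples in rows, markers in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param markers a [marker_map] with one row per column of `calls`.
#' @param samples character vector of unique sample ids, one per row of `calls`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  if (!inherits(markers, "marker_map")) stop("`markers` must be a marker_map")
  if (nrow(calls) != length(samples)) stop("rows of `calls` must match `samples`")
  if (ncol(calls) != nrow(markers)) stop("columns of `calls` must match `markers`")
  if (anyDuplicated(samples) > 0L) stop("duplicate sample ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) stop("calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(samples, markers$marker_id)
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d chromosome(s)), %.2f%% missing\n",
              length(x$samples), nrow(x$markers), length(unique(x$markers$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype matrix by sample ids
#' @param g a [genotype_matrix].
#' @param ids sample ids to keep (order preserved as given).
#' @return a [genotype_matrix] over the requested samples.
#' @export
subset_samples <- function(g, ids) {
  missing <- setdiff(ids, g$samples)
  if (length(missing)) stop("unknown sample ids: ", paste(missing, collapse = ", "))
  genotype_matrix(g$calls[ids, , drop = FALSE], g$markers, ids)
}

#' Subset a genotype matrix by marker index
#' @param g a [genotype_matrix].
#' @param idx integer column indices into the marker map.
#' @return a [genotype_matrix] over the requested markers.
#' @export
subset_markers <- function(g, idx) {
  mm <- g$markers[idx, , drop = FALSE]
  class(mm) <- c("marker_map", "data.frame")
  genotype_matrix(g$calls[, idx, drop = FALSE], mm, g$samples)
}

#' Sample metadata table
#'
#' Sample ids with breed and phenotype. The phenotype must be stated
#' explicitly for every sample; it is never defaulted.
#'
#' @param sample_id unique sample identifiers.
#' @param breed breed labels (free text).
#' @param phenotype one of `"case"`, `"control"`, `"unknown"` per sample.
#' @return A `sample_table` data frame.
#' @export
sample_table <- function(sample_id, breed, phenotype) {
  sample_id <- as.character(sample_id)
  phenotype <- as.character(phenotype)
  if (anyDuplicated(sample_id) > 0L) stop("duplicate sample ids")
  if (length(phenotype) != length(sample_id)) stop("phenotype must be given for every sample")
  ok <- phenotype %in% c("case", "control", "unknown")
  if (!all(ok)) stop("invalid phenotype value(s): ", paste(unique(phenotype[!ok]), collapse = ", "))
  df <- data.frame(sample_id = sample_id, breed = as.character(breed),
                   phenotype = phenotype, stringsAsFactors = FALSE)
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Genomic interval (1-based, closed)
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A `genome_interval` object.
#' @export
genome_interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("genome_interval is scalar; use a list for several intervals")
  if (is.na(start) || is.na(end) || start > end) stop("interval requires start <= end")
  if (start < 1) stop("coordinates are 1-based; start must be >= 1")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genome_interval")
}

#' Interval length in kb, rounded to the nearest integer
#'
#' Computed as `(end - start) / 1000`, i.e. the span between the two boundary
#' coordinates, matching the convention used when an interval is delimited by
#' its flanking marker positions.
#' @param x a [genome_interval].
#' @return integer length in kb.
#' @export
interval_length_kb <- function(x) {
  stopifnot(inherits(x, "genome_interval"))
  round((x$end - x$start) / 1000)
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%d kb)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              interval_length_kb(x)))
  invisible(x)
}

#' Sequence-level variant set
#'
#' Variant records (chromosome, position, ref, alt) with per-sample diploid
#' genotypes coded as alt-allele dosage (0/1/2, `NA` missing). Multi-allelic
#' records are represented as one row per alt allele.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param geno integer matrix, samples in rows, variants in columns.
#' @param samples character vector of sample ids.
#' @return A `variant_set` object.
#' @export
variant_set <- function(variants, geno, samples) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) stop("variants need columns chrom, pos, ref, alt")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  samples <- as.character(samples)
  if (nrow(geno) != length(samples)) stop("rows of `geno` must match `samples`")
  if (ncol(geno) != nrow(variants)) stop("columns of `geno` must match `variants`")
  o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  rownames(variants) <- NULL
  rownames(geno) <- samples
  structure(list(variants = variants, geno = geno, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d sample(s)\n", nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Variant identity keys ("chrom:pos:ref:alt")
#' @param vs a [variant_set] or a variants data frame.
#' @return character vector of keys.
#' @export
variant_keys <- function(vs) {
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), v$ref, v$alt, sep = ":")
}

#' Subset a variant set by column index
#' @keywords internal
subset_variants <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE], vs$geno[, idx, drop = FALSE], vs$samples)
}

#' Transcript model
#'
#' Exon/CDS structure of a single transcript, enabling genomic <-> CDS <->
#' protein coordinate mapping. The reference CDS sequence (`cds_seq`, always in
#' the coding orientation) supplies the codon context for consequence calls.
#'
#' @param gene gene symbol.
#' @param tx_id transcript accession label.
#' @param protein_id protein accession label.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with columns `start`, `end` (1-based inclusive
#'   genomic), non-overlapping, ordered by genomic position.
#' @param cds_start,cds_end genomic coordinates of the first and last coding
#'   base (`cds_start < cds_end` in genomic orientation regardless of strand).
#' @param cds_seq optional reference CDS sequence, length equal to the coding
#'   length, given 5'->3' in the coding orientation.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(gene, tx_id, protein_id, chrom, strand, exons,
                             cds_start, cds_end, cds_seq = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) stop("exons need columns start, end")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon start > end")
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap")
  in_exon <- function(p) any(exons$start <= p & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) stop("CDS boundaries must fall inside exons")
  if (cds_start > cds_end) stop("cds_start must be <= cds_end (genomic orientation)")
  tm <- structure(list(gene = gene, tx_id = tx_id, protein_id = protein_id,
                       chrom = as.character(chrom), strand = strand, exons = exons,
                       cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
                       cds_seq = if (is.null(cds_seq)) NULL else toupper(cds_seq)),
                  class = "transcript_model")
  len <- cds_length(tm)
  if (len %% 3L != 0L) stop("CDS length (", len, ") not divisible by 3")
  if (!is.null(tm$cds_seq) && nchar(tm$cds_seq) != len)
    stop("cds_seq length (", nchar(tm$cds_seq), ") does not match CDS length (", len, ")")
  tm
}

#' Coding pieces of a transcript (exon intervals intersected with the CDS)
#' @param t a [transcript_model].
#' @return data frame of genomic `start`/`end` coding intervals, genomic order.
#' @export
coding_exons <- function(t) {
  ex <- t$exons
  lo <- pmax(ex$start, t$cds_start)
  hi <- pmin(ex$end, t$cds_end)
  keep <- lo <= hi
  data.frame(start = lo[keep], end = hi[keep])
}

#' Total CDS length in bases
#' @param t a [transcript_model].
#' @return integer number of coding bases.
#' @export
cds_length <- function(t) {
  ce <- coding_exons(t)
  as.integer(sum(ce$end - ce$start + 1))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model: %s (%s / %s), %s strand %s, %d exon(s), CDS %d bp\n",
              x$gene, x$tx_id, x$protein_id, x$chrom, x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}
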