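# Minimal transcript-aware consequence annotation: genomic <-> CDS mapping,
# codon translation against a supplied reference CDS, and HGVS c./p. strings.

.revcomp <- function(x) chartr("ACGTacgt", "TGCAtgca", vapply(
  strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""), character(1)))

.aa3 <- function(aa1) {
  if (aa1 == "*") return("Ter")
  unname(Biostrings::AMINO_ACID_CODE[aa1])
}

#' Map a genomic position to a CDS coordinate (or non-coding category)
#'
#' For a plus-strand transcript the CDS coordinate counts coding bases from
#' `cds_start` rightward across exons; for a minus-strand transcript it counts
#' from `cds_end` leftward. Intronic positions within 2 bp of an exon boundary
#' (the canonical GT/AG dinucleotides) are classed `"splice-site"`; exonic
#' positions outside the CDS are `"utr"`; positions outside the transcript
#' span are `"intergenic"`.
#'
#' @param position_bp 1-based genomic position.
#' @param t a [transcript_model].
#' @param chrom optional chromosome of the queried position; if given it must
#'   match the transcript's chromosome.
#' @return list with `kind` (one of `"coding"`, `"splice-site"`, `"intronic"`,
#'   `"utr"`, `"intergenic"`) and `cds_pos` (integer, `NA` unless coding).
#' @export
genomic_to_cds <- function(position_bp, t, chrom = NULL) {
  stopifnot(inherits(t, "transcript_model"))
  if (!is.null(chrom) && chrom != t$chrom)
    stop("position is on ", chrom, " but transcript ", t$tx_id, " is on ", t$chrom)
  p <- as.numeric(position_bp)
  ex <- t$exons
  span <- c(min(ex$start), max(ex$end))
  if (p < span[1] || p > span[2]) return(list(kind = "intergenic", cds_pos = NA_integer_))
  hit <- which(ex$start <= p & p <= ex$end)
  if (!length(hit)) {
    # intronic; splice window = 2 bases beyond internal exon boundaries
    near <- any((p - ex$end[-nrow(ex)]) %in% c(1, 2)) ||
      any((ex$start[-1] - p) %in% c(1, 2))
    return(list(kind = if (near) "splice-site" else "intronic", cds_pos = NA_integer_))
  }
  if (p < t$cds_start || p > t$cds_end) return(list(kind = "utr", cds_pos = NA_integer_))
  ce <- coding_exons(t)
  k <- which(ce$start <= p & p <= ce$end)
  if (!length(k)) return(list(kind = "utr", cds_pos = NA_integer_))
  if (t$strand == "+") {
    cds <- sum(ce$end[seq_len(k - 1)] - ce$start[seq_len(k - 1)] + 1) + (p - ce$start[k] + 1)
  } else {
    later <- seq_len(nrow(ce)) > k
    cds <- sum(ce$end[later] - ce$start[later] + 1) + (ce$end[k] - p + 1)
  }
  list(kind = "coding", cds_pos = as.integer(cds))
}

#' Map a CDS coordinate back to its genomic position
#'
#' Inverse of [genomic_to_cds()] for coding positions.
#'
#' @param cds_pos 1-based CDS coordinate in `1..cds_length(t)`.
#' @param t a [transcript_model].
#' @return genomic position (numeric scalar).
#' @export
cds_to_genomic <- function(cds_pos, t) {
  stopifnot(inherits(t, "transcript_model"))
  len <- cds_length(t)
  if (cds_pos < 1 || cds_pos > len) stop("cds_pos out of range 1..", len)
  ce <- coding_exons(t)
  if (t$strand == "-") ce <- ce[rev(seq_len(nrow(ce))), , drop = FALSE]
  sizes <- ce$end - ce$start + 1
  cum <- cumsum(sizes)
  k <- which(cds_pos <= cum)[1]
  off <- cds_pos - c(0, cum)[k] - 1
  if (t$strand == "+") ce$start[k] + off else ce$end[k] - off
}

#' Annotate a single-nucleotide variant against a transcript
#'
#' Classifies the variant (missense, nonsense, synonymous, splice-site,
#' intronic, utr, intergenic; indels get the `"frameshift-proxy"` class
#' without protein notation), translates the reference and alternate codons
#' with the standard genetic code, and emits HGVS-style `c.` and `p.` strings
#' (predicted protein changes in the parenthesised form, e.g.
#' `p.(Pro480Thr)`). The reference codon is taken from the transcript's
#' `cds_seq` and must agree with the variant's declared ref allele at the
#' codon offset, otherwise a reference-mismatch error is raised.
#'
#' @param v variant record: a list or one-row data frame with `chrom`, `pos`,
#'   `ref`, `alt` (genomic-strand alleles).
#' @param t a [transcript_model] with `cds_seq`.
#' @return a `consequence_call`: one-row data frame with the variant, the
#'   transcript label, `cds_position`, `codon_index`, `ref_residue`,
#'   `alt_residue` (3-letter codes), `consequence_class`, `hgvs_c`, `hgvs_p`.
#' @export
annotate <- function(v, t) {
  v <- as.list(v)
  call <- data.frame(chrom = as.character(v$chrom), pos = as.numeric(v$pos),
                     ref = as.character(v$ref), alt = as.character(v$alt),
                     transcript = t$tx_id, cds_position = NA_integer_,
                     codon_index = NA_integer_, ref_residue = NA_character_,
                     alt_residue = NA_character_, consequence_class = NA_character_,
                     hgvs_c = NA_character_, hgvs_p = NA_character_,
                     stringsAsFactors = FALSE)
  if (call$chrom != t$chrom) {
    call$consequence_class <- "intergenic"
    class(call) <- c("consequence_call", "data.frame")
    return(call)
  }
  loc <- genomic_to_cds(call$pos, t)
  if (nchar(call$ref) != 1L || nchar(call$alt) != 1L) {
    call$consequence_class <- "frameshift-proxy"
    call$cds_position <- loc$cds_pos
    class(call) <- c("consequence_call", "data.frame")
    return(call)
  }
  if (loc$kind != "coding") {
    call$consequence_class <- loc$kind
    class(call) <- c("consequence_call", "data.frame")
    return(call)
  }
  if (is.null(t$cds_seq)) stop("transcript ", t$tx_id, " has no cds_seq; cannot translate")
  cds <- loc$cds_pos
  ci <- as.integer(ceiling(cds / 3))
  off <- (cds - 1L) %% 3L + 1L
  ref_c <- if (t$strand == "-") .revcomp(call$ref) else toupper(call$ref)
  alt_c <- if (t$strand == "-") .revcomp(call$alt) else toupper(call$alt)
  codon <- substr(t$cds_seq, 3L * ci - 2L, 3L * ci)
  if (substr(codon, off, off) != ref_c)
    stop(sprintf("reference mismatch at c.%d: transcript codon %s has '%s' at offset %d, variant ref is '%s'",
                 cds, codon, substr(codon, off, off), off, ref_c))
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_c
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  cls <- if (aa_ref == aa_alt) "synonymous" else if (aa_alt == "*") "nonsense" else "missense"
  call$cds_position <- cds
  call$codon_index <- ci
  call$ref_residue <- .aa3(aa_ref)
  call$alt_residue <- .aa3(aa_alt)
  call$consequence_class <- cls
  call$hgvs_c <- sprintf("c.%d%s>%s", cds, ref_c, alt_c)
  call$hgvs_p <- sprintf("p.(%s%d%s)", call$ref_residue, ci, call$alt_residue)
  class(call) <- c("consequence_call", "data.frame")
  call
}

#' Annotate every variant of a variant set
#' @param vs a [variant_set].
#' @param t a [transcript_model].
#' @return data frame of consequence calls, one row per variant.
#' @export
annotate_variants <- function(vs, t) {
  v <- vs$variants
  if (!nrow(v)) {
    out <- annotate(list(chrom = t$chrom, pos = 1, ref = "A", alt = "C"), t)[0, ]
    return(out)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) annotate(v[i, ], t)))
  rownames(out) <- NULL
  out
}

#' Is a consequence call protein-changing?
#'
#' TRUE for missense, nonsense, splice-site and frameshift-proxy calls; FALSE
#' for synonymous, intronic, UTR and intergenic calls.
#'
#' @param call a `consequence_call` (or the data frame from
#'   [annotate_variants()]); vectorized over rows.
#' @return logical vector.
#' @export
is_protein_changing <- function(call) {
  cls <- if (is.data.frame(call)) call$consequence_class else call[["consequence_class"]]
  cls %in% c("missense", "nonsense", "splice-site", "frameshift-proxy")
}
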