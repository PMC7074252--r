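#' Read array or sequence genotypes
#'
#' Reads genotypes from either the PLINK transposed-text dialect
#' (`.tped` + `.tfam`) or a VCF with GT fields, into a [genotype_matrix] plus
#' a [sample_table]. Coordinates are 1-based inclusive throughout; markers are
#' returned sorted by position within each chromosome (chromosomes keep their
#' file order of first appearance). PLINK "0" alleles and VCF `./.` genotypes
#' both map to the same missing state.
#'
#' For the PLINK dialect the `.tfam` family id is interpreted as the breed
#' label and the 6th column as phenotype (2 = case, 1 = control, 0/-9 =
#' unknown). A VCF carries no phenotype, so every sample is `"unknown"`.
#' Allele labels are assigned alphabetically (`a1 < a2`, calls count `a2`
#' copies); at a marker where only one allele is ever observed the dialect
#' cannot name the second allele, so such markers read back as `a1`
#' homozygotes — round-trips are bit-exact whenever both alleles are
#' observed.
#'
#' @param path path to the `.tped` file or the VCF.
#' @param dialect `"plink-transposed"` or `"vcf"`.
#' @param tfam path to the `.tfam` companion file; defaults to `path` with the
#'   extension swapped.
#' @return list with elements `genotypes` ([genotype_matrix]) and `samples`
#'   ([sample_table]).
#' @export
read_genotypes <- function(path, dialect = c("plink-transposed", "vcf"), tfam = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    vs <- read_vcf_variants(path)
    g <- as_genotype_matrix(vs)
    st <- sample_table(vs$samples, NA_character_, rep("unknown", length(vs$samples)))
    return(list(genotypes = g, samples = st))
  }
  if (is.null(tfam)) tfam <- sub("\\.tped$", ".tfam", path)
  if (!file.exists(path)) stop("tped file not found: ", path)
  if (!file.exists(tfam)) stop("tfam file not found: ", tfam)

  fam <- utils::read.table(tfam, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(fam) != 6L) stop("malformed tfam: expected 6 columns, got ", ncol(fam))
  if (anyDuplicated(fam[[2]]) > 0L)
    stop("duplicate sample id in tfam: ", paste(unique(fam[[2]][duplicated(fam[[2]])]), collapse = ", "))
  pheno <- c("1" = "control", "2" = "case")[fam[[6]]]
  pheno[is.na(pheno)] <- "unknown"
  st <- sample_table(fam[[2]], fam[[1]], unname(pheno))
  n_samp <- nrow(fam)

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n_mark <- length(lines)
  if (n_mark == 0L) stop("empty tped file: ", path)
  chrom <- character(n_mark); mid <- character(n_mark); pos <- integer(n_mark)
  calls <- matrix(NA_integer_, n_samp, n_mark)
  a1 <- rep(NA_character_, n_mark); a2 <- rep(NA_character_, n_mark)
  for (i in seq_len(n_mark)) {
    f <- strsplit(lines[[i]], "[ \t]+")[[1]]
    if (length(f) != 4L + 2L * n_samp)
      stop("malformed tped line ", i, ": expected ", 4L + 2L * n_samp,
           " fields, got ", length(f))
    chrom[i] <- f[1]; mid[i] <- f[2]
    p <- suppressWarnings(as.integer(f[4]))
    if (is.na(p)) stop("malformed tped line ", i, ": non-integer position '", f[4], "'")
    pos[i] <- p
    al <- matrix(f[-(1:4)], nrow = 2L)
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2L)
      stop("malformed tped line ", i, ": more than two alleles (", paste(obs, collapse = ","), ")")
    if (length(obs) >= 1L) a1[i] <- obs[1]
    if (length(obs) == 2L) a2[i] <- obs[2]
    miss <- al[1, ] == "0" | al[2, ] == "0"
    cnt <- if (length(obs) == 2L) (al[1, ] == obs[2]) + (al[2, ] == obs[2]) else rep(0L, n_samp)
    cnt[miss] <- NA_integer_
    calls[, i] <- as.integer(cnt)
  }
  if (anyDuplicated(mid) > 0L)
    stop("duplicate marker id in tped: ", paste(unique(mid[duplicated(mid)]), collapse = ", "))
  o <- order(match(chrom, unique(chrom)), pos)
  mm <- marker_map(mid[o], chrom[o], pos[o], a1[o], a2[o])
  list(genotypes = genotype_matrix(calls[, o, drop = FALSE], mm, st$sample_id),
       samples = st)
}

#' Write genotypes in the PLINK transposed-text dialect
#'
#' @param g a [genotype_matrix].
#' @param samples a [sample_table] covering the samples of `g`.
#' @param prefix output path prefix; writes `<prefix>.tped` and `<prefix>.tfam`.
#' @return invisibly, the two file paths.
#' @export
write_genotypes <- function(g, samples, prefix) {
  st <- samples[match(g$samples, samples$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("sample_table does not cover all samples of the genotype matrix")
  ph <- c(case = "2", control = "1", unknown = "0")[st$phenotype]
  fam <- data.frame(st$breed, st$sample_id, "0", "0", "0", unname(ph))
  fam[[1]][is.na(fam[[1]])] <- "0"
  tfam <- paste0(prefix, ".tfam"); tped <- paste0(prefix, ".tped")
  utils::write.table(fam, tfam, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mm <- g$markers
  rows <- vapply(seq_len(nrow(mm)), function(j) {
    cl <- g$calls[, j]
    a1 <- mm$a1[j]; a2 <- mm$a2[j]
    if (is.na(a2)) a2 <- a1  # monomorphic: only one allele ever observed
    al1 <- ifelse(is.na(cl), "0", ifelse(cl >= 1L, a2, a1))
    al2 <- ifelse(is.na(cl), "0", ifelse(cl == 2L, a2, a1))
    paste(c(mm$chrom[j], mm$marker_id[j], "0", mm$pos[j], rbind(al1, al2)), collapse = "\t")
  }, character(1))
  writeLines(rows, tped)
  invisible(c(tped = tped, tfam = tfam))
}

#' Read a VCF into a variant set
#'
#' Parses a VCF (v4.x, GT field required) with `vcfR` and returns a
#' [variant_set] of alt-allele dosages. Multi-allelic records are split into
#' one biallelic record per alt allele, preserving position; `./.` maps to
#' missing.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a [variant_set].
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF has no variant records: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  chrom <- c(); pos <- c(); ref <- c(); alt <- c()
  geno <- NULL
  gl <- matrix(strsplit(gsub("\\|", "/", ifelse(is.na(gt), ".", gt)), "/"),
               nrow = nrow(gt))
  out_geno <- list(); k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      doses <- vapply(seq_along(samples), function(s) {
        al <- gl[[i, s]]
        if (any(al == ".") || !length(al)) return(NA_integer_)
        sum(al == as.character(ai))
      }, integer(1))
      k <- k + 1L
      chrom[k] <- fix[i, "CHROM"]; pos[k] <- as.numeric(fix[i, "POS"])
      ref[k] <- fix[i, "REF"]; alt[k] <- alts[ai]
      out_geno[[k]] <- doses
    }
  }
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
              do.call(cbind, out_geno), samples)
}

#' Write a variant set as a minimal VCF (v4.2, GT only)
#'
#' @param vs a [variant_set].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", vs$samples), collapse = "\t"))
  gtmap <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vs$variants)), function(j) {
    gt <- vs$geno[, j]
    gts <- ifelse(is.na(gt), "./.", gtmap[gt + 1L])
    paste(c(vs$variants$chrom[j], format(vs$variants$pos[j], scientific = FALSE),
            ".", vs$variants$ref[j], vs$variants$alt[j], ".", ".", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a variant set to a genotype matrix
#'
#' Marker ids are `chrom:pos:ref:alt` keys; `a1` is the ref and `a2` the alt
#' allele, so calls keep their alt-dosage coding. Errors if two records share
#' a position on the same chromosome (a marker map requires strictly
#' increasing positions).
#'
#' @param vs a [variant_set].
#' @return a [genotype_matrix].
#' @export
as_genotype_matrix <- function(vs) {
  v <- vs$variants
  dup <- duplicated(v[c("chrom", "pos")])
  if (any(dup))
    stop("duplicate positions (e.g. split multi-allelics) cannot form a marker map: ",
         paste(utils::head(variant_keys(vs)[dup], 3), collapse = ", "))
  mm <- marker_map(variant_keys(vs), v$chrom, v$pos, v$ref, v$alt)
  genotype_matrix(vs$geno, mm, vs$samples)
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package-wide
#' 1-based closed convention on read (via `rtracklayer`).
#'
#' @param path path to a BED file.
#' @return list of [genome_interval] objects, one per BED record.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lapply(seq_along(gr), function(i)
    genome_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                    GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
}

#' Write genomic intervals to a BED file
#'
#' Converts from the internal 1-based closed convention to BED's 0-based
#' half-open convention.
#'
#' @param intervals a [genome_interval] or list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "genome_interval")) intervals <- list(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(intervals, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(intervals, `[[`, numeric(1), "start"),
      end = vapply(intervals, `[[`, numeric(1), "end")))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a transcript model from a tab-separated table
#'
#' One row per transcript with columns `gene`, `tx_id`, `protein_id`, `chrom`,
#' `strand`, `exon_starts`, `exon_ends` (comma-separated genomic coordinates),
#' `cds_start`, `cds_end` and optionally `cds_seq`.
#'
#' @param path path to the table.
#' @return a [transcript_model] (first row) or list of them if several rows.
#' @export
read_transcript_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  build <- function(r) {
    transcript_model(
      gene = r$gene, tx_id = r$tx_id, protein_id = r$protein_id, chrom = r$chrom,
      strand = r$strand,
      exons = data.frame(start = as.numeric(strsplit(r$exon_starts, ",")[[1]]),
                         end = as.numeric(strsplit(r$exon_ends, ",")[[1]])),
      cds_start = as.numeric(r$cds_start), cds_end = as.numeric(r$cds_end),
      cds_seq = if (!is.null(r$cds_seq) && !is.na(r$cds_seq)) r$cds_seq else NULL)
  }
  out <- lapply(seq_len(nrow(df)), function(i) build(as.list(df[i, , drop = FALSE])))
  if (length(out) == 1L) out[[1]] else out
}

#' Write transcript model(s) to a tab-separated table
#' @param t a [transcript_model] or list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_transcript_table <- function(t, path) {
  if (inherits(t, "transcript_model")) t <- list(t)
  df <- do.call(rbind, lapply(t, function(x) {
    data.frame(gene = x$gene, tx_id = x$tx_id, protein_id = x$protein_id,
               chrom = x$chrom, strand = x$strand,
               exon_starts = paste(format(x$exons$start, scientific = FALSE, trim = TRUE), collapse = ","),
               exon_ends = paste(format(x$exons$end, scientific = FALSE, trim = TRUE), collapse = ","),
               cds_start = format(x$cds_start, scientific = FALSE, trim = TRUE),
               cds_end = format(x$cds_end, scientific = FALSE, trim = TRUE),
               cds_seq = if (is.null(x$cds_seq)) NA_character_ else x$cds_seq,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tabular report to a tab-separated file
#'
#' Works for filter reports, genotype count tables, association results and
#' any plain data frame. Column order is deterministic and numbers are written
#' without locale grouping; an empty result yields a header-only file.
#'
#' @param report the object to serialize.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write report: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a tab-separated report
#' @param path path written by [write_report()].
#' @return data frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
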