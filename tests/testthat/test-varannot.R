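test_that("genomic-to-CDS mapping counts coding bases across exons", {
  tx <- toy_transcript()
  expect_equal(genomic_to_cds(120, tx), list(kind = "coding", cds_pos = 1L))   # origin
  expect_equal(genomic_to_cds(129, tx)$cds_pos, 10L)
  expect_equal(genomic_to_cds(200, tx)$cds_pos, 11L)  # first base of exon 2
  expect_equal(genomic_to_cds(225, tx)$cds_pos, 36L)
  expect_equal(genomic_to_cds(115, tx)$kind, "utr")        # exonic, before CDS
  expect_equal(genomic_to_cds(240, tx)$kind, "utr")        # exonic, after CDS
  expect_equal(genomic_to_cds(131, tx)$kind, "splice-site")  # intron +2 of exon 1
  expect_equal(genomic_to_cds(198, tx)$kind, "splice-site")  # intron -2 of exon 2
  expect_equal(genomic_to_cds(165, tx)$kind, "intronic")
  expect_equal(genomic_to_cds(50, tx)$kind, "intergenic")
  expect_error(genomic_to_cds(120, tx, chrom = "chrZ"), "chrZ")
})

test_that("CDS -> genomic -> CDS is the identity on random transcripts, both strands", {
  withr::with_seed(101, {
    for (rep in 1:8) {
      tx <- random_transcript()
      L <- max(tx$exons$end) + 500
      txm <- mirror_transcript(tx, L)
      len <- cds_length(tx)
      for (cds in sample.int(len, 40, replace = TRUE)) {
        gp <- cds_to_genomic(cds, tx)
        expect_equal(genomic_to_cds(gp, tx), list(kind = "coding", cds_pos = as.integer(cds)))
        gm <- cds_to_genomic(cds, txm)
        expect_equal(genomic_to_cds(gm, txm)$cds_pos, as.integer(cds))
        expect_equal(gm, L - gp + 1)  # the mirror maps coordinates consistently
      }
    }
  })
})

test_that("a C>A substitution at CDS 1438 of a CC-initial codon is Pro480Thr", {
  # transcript long enough to hold CDS position 1438: 481 codons, codon 480 CCT
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(6, body <- sample(sense, 479, replace = TRUE))
  cds_seq <- paste(c("ATG", body[-1], "CCT", "TAA"), collapse = "")
  tx <- transcript_model("G", "TX1", "TP1", "chr18", "+",
                         exons = data.frame(start = 1000, end = 1000 + 1443 - 1),
                         cds_start = 1000, cds_end = 1000 + 1443 - 1,
                         cds_seq = cds_seq)
  gp <- cds_to_genomic(1438, tx)
  call <- annotate(list(chrom = "chr18", pos = gp, ref = "C", alt = "A"), tx)
  expect_equal(call$cds_position, 1438L)
  expect_equal(call$codon_index, 480L)
  expect_equal(call$ref_residue, "Pro")
  expect_equal(call$alt_residue, "Thr")
  expect_equal(call$consequence_class, "missense")
  expect_equal(call$hgvs_c, "c.1438C>A")
  expect_equal(call$hgvs_p, "p.(Pro480Thr)")
})

test_that("synonymous, nonsense and mismatch cases behave per the genetic code", {
  # codon 2 = CCA; third base A>G keeps proline
  cds_seq <- paste0("ATG", "CCA", "TAC", "TAA")
  tx <- transcript_model("G", "TX2", "TP2", "chr1", "+",
                         exons = data.frame(start = 100, end = 111),
                         cds_start = 100, cds_end = 111, cds_seq = cds_seq)
  syn <- annotate(list(chrom = "chr1", pos = cds_to_genomic(6, tx), ref = "A", alt = "G"), tx)
  expect_equal(syn$consequence_class, "synonymous")
  expect_equal(syn$hgvs_p, "p.(Pro2Pro)")
  # codon 3 = TAC -> TAA is a stop gain
  non <- annotate(list(chrom = "chr1", pos = cds_to_genomic(9, tx), ref = "C", alt = "A"), tx)
  expect_equal(non$consequence_class, "nonsense")
  expect_equal(non$alt_residue, "Ter")
  # declared ref allele disagreeing with the codon context errors
  expect_error(annotate(list(chrom = "chr1", pos = cds_to_genomic(6, tx),
                             ref = "T", alt = "G"), tx),
               "reference mismatch")
})

test_that("non-coding classes and the indel proxy come out right", {
  tx <- toy_transcript()
  expect_equal(annotate(list(chrom = "chrT", pos = 131, ref = "A", alt = "C"), tx)$consequence_class,
               "splice-site")
  expect_equal(annotate(list(chrom = "chrT", pos = 165, ref = "A", alt = "C"), tx)$consequence_class,
               "intronic")
  expect_equal(annotate(list(chrom = "chrT", pos = 50, ref = "A", alt = "C"), tx)$consequence_class,
               "intergenic")
  expect_equal(annotate(list(chrom = "chrZ", pos = 50, ref = "A", alt = "C"), tx)$consequence_class,
               "intergenic")
  indel <- annotate(list(chrom = "chrT", pos = 205, ref = "AT", alt = "A"), tx)
  expect_equal(indel$consequence_class, "frameshift-proxy")
  expect_true(is.na(indel$hgvs_p))
})

test_that("protein-changing classification follows the class partition", {
  expect_true(is_protein_changing(list(consequence_class = "missense")))
  expect_true(is_protein_changing(list(consequence_class = "nonsense")))
  expect_true(is_protein_changing(list(consequence_class = "splice-site")))
  expect_true(is_protein_changing(list(consequence_class = "frameshift-proxy")))
  expect_false(is_protein_changing(list(consequence_class = "synonymous")))
  expect_false(is_protein_changing(list(consequence_class = "intronic")))
  expect_false(is_protein_changing(list(consequence_class = "utr")))
  expect_false(is_protein_changing(list(consequence_class = "intergenic")))
})

test_that("each residue owns exactly three CDS positions", {
  tx <- toy_transcript()
  idx <- vapply(1:36, function(c) as.integer(ceiling(c / 3)), integer(1))
  expect_equal(range(idx), c(1L, 12L))
  expect_true(all(table(idx) == 3))
  # and annotate() agrees with that arithmetic at every coding position
  for (cds in 1:36) {
    gp <- cds_to_genomic(cds, tx)
    ref <- substr(tx$cds_seq, cds, cds)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    call <- annotate(list(chrom = "chrT", pos = gp, ref = ref, alt = alt), tx)
    expect_equal(call$codon_index, idx[cds])
  }
})

test_that("annotation is strand-symmetric", {
  withr::with_seed(55, {
    for (rep in 1:6) {
      tx <- random_transcript()
      L <- max(tx$exons$end) + 300
      txm <- mirror_transcript(tx, L)
      for (cds in sample.int(cds_length(tx), 15)) {
        ref <- substr(tx$cds_seq, cds, cds)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        plus <- annotate(list(chrom = tx$chrom, pos = cds_to_genomic(cds, tx),
                              ref = ref, alt = alt), tx)
        minus <- annotate(list(chrom = txm$chrom, pos = cds_to_genomic(cds, txm),
                               ref = revcomp1(ref), alt = revcomp1(alt)), txm)
        expect_equal(minus$cds_position, plus$cds_position)
        expect_equal(minus$consequence_class, plus$consequence_class)
        expect_equal(minus$hgvs_p, plus$hgvs_p)
        expect_equal(minus$hgvs_c, plus$hgvs_c)
      }
    }
  })
})
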