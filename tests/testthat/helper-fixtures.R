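# Shared fixtures, built in code.

# genotype matrix from a plain matrix (rows = samples)
make_gm <- function(m, chrom = "chr1", pos = NULL, samples = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 1000L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  mm <- marker_map(sprintf("m%03d", seq_len(ncol(m))), chrom, pos, "A", "C")
  genotype_matrix(m, mm, samples)
}

# small, fast simulation used by module tests (single 6-Mb chromosome)
small_sim_config <- function(seed = 3, ...) {
  base <- list(seed = seed, n_chromosomes = 1, chromosome_length_bp = 6e6,
               causal_position_bp = 3e6, n_sites_per_chromosome = 1200,
               n_markers_per_chromosome = 400, population_size = 150,
               n_cases = 8, n_controls = 12, n_control_genomes = 25,
               n_generations = 12, recombination_rate = 5e-8)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# two-exon plus-strand toy transcript on chrT: exon1 = 100..129 with the CDS
# starting at 120 (exon1 coding length 10), exon2 = 200..249 with the CDS
# ending at 225 (26 coding bases), CDS length 36 = 12 codons. So genomic 120
# is c.1 and the first base of exon 2 (genomic 200) is c.11.
toy_transcript <- function(cds_seq = NULL) {
  if (is.null(cds_seq)) {
    codons <- names(Biostrings::GENETIC_CODE)
    sense <- codons[Biostrings::GENETIC_CODE != "*"]
    cds_seq <- paste(c("ATG", withr::with_seed(42, sample(sense, 10, replace = TRUE)),
                       "TAA"), collapse = "")
  }
  transcript_model(gene = "TOY", tx_id = "TX_TOY.1", protein_id = "TP_TOY.1",
                   chrom = "chrT", strand = "+",
                   exons = data.frame(start = c(100, 200), end = c(129, 249)),
                   cds_start = 120, cds_end = 225, cds_seq = cds_seq)
}

# mirror a plus-strand transcript onto the minus strand of a genome of length
# L: position p maps to L - p + 1, alleles reverse-complement, cds_seq kept.
mirror_transcript <- function(t, L) {
  ex <- data.frame(start = L - t$exons$end + 1, end = L - t$exons$start + 1)
  transcript_model(gene = t$gene, tx_id = t$tx_id, protein_id = t$protein_id,
                   chrom = t$chrom, strand = if (t$strand == "+") "-" else "+",
                   exons = ex,
                   cds_start = L - t$cds_end + 1, cds_end = L - t$cds_start + 1,
                   cds_seq = t$cds_seq)
}

revcomp1 <- function(x) chartr("ACGT", "TGCA", x)

# random toy transcript for property tests: n_ex exons on a 10-kb genome,
# plus strand, CDS covering part of the exons
random_transcript <- function(n_codons = 30) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  cds_seq <- paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA"),
                   collapse = "")
  need <- 3 * n_codons
  n_ex <- sample(2:4, 1)
  sizes <- rep(need %/% n_ex, n_ex)
  sizes[n_ex] <- sizes[n_ex] + need %% n_ex
  utr5 <- sample(5:30, 1); utr3 <- sample(5:30, 1)
  sizes[1] <- sizes[1] + utr5
  sizes[n_ex] <- sizes[n_ex] + utr3
  gaps <- sample(50:300, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(sample(100:500, 1), utils::head(sizes, -1) + gaps))
  ends <- starts + sizes - 1
  transcript_model(gene = "RND", tx_id = "TX_RND.1", protein_id = "TP_RND.1",
                   chrom = "chrR", strand = "+",
                   exons = data.frame(start = starts, end = ends),
                   cds_start = starts[1] + utr5, cds_end = ends[n_ex] - utr3,
                   cds_seq = cds_seq)
}

# build a variant_set quickly
make_vs <- function(chrom, pos, ref, alt, geno, samples = NULL) {
  geno <- as.matrix(geno)
  if (is.null(samples)) samples <- sprintf("v%02d", seq_len(nrow(geno)))
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE), geno, samples)
}

# independent enumeration oracle for the HWE exact test
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1; nB <- 2 * n2 + n1
  if (nA == 0 || nB == 0) return(1)
  ks <- seq(nA %% 2, min(nA, nB), by = 2)
  # unnormalized probability of each het count via exact multinomial weights
  w <- vapply(ks, function(k) {
    nn0 <- (nA - k) / 2; nn2 <- (nB - k) / 2
    exp(lgamma(n + 1) - lgamma(nn0 + 1) - lgamma(k + 1) - lgamma(nn2 + 1) + k * log(2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[match(n1, ks)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent enumeration oracle for the 2x2 Fisher test (probability-mass
# two-sided rule), written over raw choose() products
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  xs <- max(0, k - n2):min(k, m)
  pr <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  obs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}
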