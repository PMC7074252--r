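# Gene-drop simulator of a bottlenecked, random-mating (breed-like)
# population segregating a recessive causal variant on a shared
# identical-by-descent haplotype. Produces the array tier (genotype matrix +
# sample table), the sequence tier (case variant set), a control genome
# panel, a transcript model overlapping the causal variant, and a truth
# record for parameter-recovery tests.
#
# Haplotypes are stored as founder-origin mosaics: piecewise-constant maps
# from genomic position to founder haplotype id, represented by piece start
# positions (`brk`, first always 1) and founder ids (`fid`). Alleles are only
# materialized for sampled individuals, by founder lookup at the site
# positions.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: an array cohort of
#' 14 cases and 29 controls from one breed, two sequenced cases, a control
#' genome panel of 60 genomes, two 20-Mb chromosomes with 1,000 array markers
#' each (~20 kb spacing) drawn from 4,000 sequence-tier sites, a causal
#' variant at 10 Mb on chr1 inside a 1-Mb identical-by-descent segment, a
#' founder pool of 6 haplotypes with the causal haplotype at initial
#' frequency 0.35, 20 generations of random mating at a recombination rate of
#' 3e-8 per bp per meiosis, 2% array missingness and no phenotype error.
#'
#' @param seed integer RNG seed; every draw of the generator flows from it.
#' @param n_founder_haplotypes founder haplotype pool size (>= 4).
#' @param population_size diploid population size per generation.
#' @param n_generations generations of random mating after the founder
#'   bottleneck.
#' @param recombination_rate expected crossovers per bp per meiosis.
#' @param n_cases,n_controls array-cohort sizes.
#' @param n_sequenced_cases cases carried into the sequence tier.
#' @param n_control_genomes control genome panel size.
#' @param n_chromosomes,chromosome_length_bp genome shape.
#' @param n_markers_per_chromosome,n_sites_per_chromosome array markers are a
#'   subset of the sequence-tier sites.
#' @param causal_chromosome,causal_position_bp location of the causal
#'   variant (must lie inside its chromosome).
#' @param ibd_segment_length_bp length of the identical-by-descent segment
#'   around the causal variant shared by all (non-mislabeled) cases.
#' @param causal_founder_freq initial frequency of the causal-bearing founder
#'   haplotype (the popular-sire knob that makes homozygotes recruitable).
#' @param missing_rate per-entry no-call probability on the array tier.
#' @param phenotype_error_rate probability that a case slot is filled by a
#'   mislabeled non-homozygote.
#' @param n_neutral_private_variants default count for
#'   [plant_neutral_private_variants()] when driven from a pipeline config.
#' @param max_attempts bounded number of whole-population retries before an
#'   infeasible configuration fails explicitly.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_founder_haplotypes = 6L,
                       population_size = 300L,
                       n_generations = 20L,
                       recombination_rate = 3e-8,
                       n_cases = 14L,
                       n_controls = 29L,
                       n_sequenced_cases = 2L,
                       n_control_genomes = 60L,
                       n_chromosomes = 2L,
                       chromosome_length_bp = 2e7,
                       n_markers_per_chromosome = 1000L,
                       n_sites_per_chromosome = 4000L,
                       causal_chromosome = "chr1",
                       causal_position_bp = 1e7,
                       ibd_segment_length_bp = 1e6,
                       causal_founder_freq = 0.35,
                       missing_rate = 0.02,
                       phenotype_error_rate = 0,
                       n_neutral_private_variants = 0L,
                       max_attempts = 20L) {
  cfg <- list(seed = as.integer(seed),
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              population_size = as.integer(population_size),
              n_generations = as.integer(n_generations),
              recombination_rate = recombination_rate,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_sequenced_cases = as.integer(n_sequenced_cases),
              n_control_genomes = as.integer(n_control_genomes),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              n_markers_per_chromosome = as.integer(n_markers_per_chromosome),
              n_sites_per_chromosome = as.integer(n_sites_per_chromosome),
              causal_chromosome = causal_chromosome,
              causal_position_bp = causal_position_bp,
              ibd_segment_length_bp = ibd_segment_length_bp,
              causal_founder_freq = causal_founder_freq,
              missing_rate = missing_rate,
              phenotype_error_rate = phenotype_error_rate,
              n_neutral_private_variants = as.integer(n_neutral_private_variants),
              max_attempts = as.integer(max_attempts))
  probs <- c(missing_rate = missing_rate,
             phenotype_error_rate = phenotype_error_rate,
             causal_founder_freq = causal_founder_freq)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities must lie in [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_founder_haplotypes < 4L)
    stop("need at least 4 founder haplotypes (each neutral allele must be carried by >= 2)")
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (!causal_chromosome %in% chroms)
    stop("causal_chromosome must be one of ", paste(chroms, collapse = ", "))
  if (causal_position_bp < 1 || causal_position_bp > chromosome_length_bp)
    stop("causal position outside its chromosome")
  if (ibd_segment_length_bp < 1 || ibd_segment_length_bp > chromosome_length_bp)
    stop("ibd_segment_length_bp must be positive and fit the chromosome")
  if (cfg$n_sequenced_cases < 1L || cfg$n_sequenced_cases > cfg$n_cases)
    stop("n_sequenced_cases must be in 1..n_cases")
  if (cfg$n_sites_per_chromosome < cfg$n_markers_per_chromosome + 1L)
    stop("need more sequence sites than array markers per chromosome")
  cfg$chromosomes <- chroms
  class(cfg) <- "sim_config"
  cfg
}

# ---- haplotype mosaic primitives ------------------------------------------

# pieces of mosaic h overlapping [lo, hi), clipped on the left
.slice <- function(h, lo, hi) {
  if (lo >= hi) return(list(brk = numeric(0), fid = integer(0)))
  ends <- c(h$brk[-1], Inf)
  sel <- which(h$brk < hi & ends > lo)
  list(brk = pmax(h$brk[sel], lo), fid = h$fid[sel])
}

.collapse <- function(brk, fid) {
  if (length(fid) > 1L) {
    keep <- c(TRUE, fid[-1L] != fid[-length(fid)])
    brk <- brk[keep]; fid <- fid[keep]
  }
  list(brk = brk, fid = fid)
}

# one meiosis: recombine parental haplotypes hA/hB with Poisson crossovers
.recombine <- function(hA, hB, L, rate) {
  ncx <- stats::rpois(1L, rate * L)
  first <- sample.int(2L, 1L)
  if (ncx == 0L) return(if (first == 1L) hA else hB)
  cx <- sort(stats::runif(ncx, min = 1, max = L))
  bounds <- c(1, cx, L + 1)
  src <- rep_len(c(first, 3L - first), length(bounds) - 1L)
  haps <- list(hA, hB)
  brk <- numeric(0); fid <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    s <- .slice(haps[[src[i]]], bounds[i], bounds[i + 1L])
    brk <- c(brk, s$brk); fid <- c(fid, s$fid)
  }
  .collapse(brk, fid)
}

# overwrite founder origin over the closed interval [lo, hi]
.overwrite_segment <- function(h, lo, hi, f, L) {
  left <- .slice(h, 1, lo)
  right <- .slice(h, hi + 1, L + 1)
  .collapse(c(left$brk, lo, right$brk), c(left$fid, f, right$fid))
}

.fid_at <- function(h, pos) h$fid[findInterval(pos, h$brk)]

# ---- study assembly --------------------------------------------------------

.random_cds <- function(n_codons, fixed = list()) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  s <- sample(sense, n_codons, replace = TRUE)
  s[1] <- "ATG"
  s[n_codons] <- "TAA"
  for (i in seq_along(fixed)) s[as.integer(names(fixed)[i])] <- fixed[[i]]
  paste(s, collapse = "")
}

# Toy two-exon plus-strand transcript whose CDS position 1438 lands exactly on
# `causal_pos` with a CC-initial (proline) reference codon, so a C>A
# substitution there is the missense change at residue 480.
.causal_transcript <- function(chrom, causal_pos) {
  n_codons <- 481L                       # CDS length 1443, divisible by 3
  cds_seq <- .random_cds(n_codons, fixed = list("480" = "CCT"))
  exon1_coding <- 1200
  # CDS position 1438 sits at offset 238 of exon 2's coding part
  ex2_start <- causal_pos - 237
  ex2_end <- ex2_start + (1443 - exon1_coding) - 1 + 100      # + 3' UTR
  ex1_start <- ex2_start - 2000                               # intron of 700 bp
  ex1_end <- ex1_start + 100 + exon1_coding - 1               # 5' UTR of 100 bp
  transcript_model(
    gene = "GENE1", tx_id = "TX_000001.1", protein_id = "TP_000001.1",
    chrom = chrom, strand = "+",
    exons = data.frame(start = c(ex1_start, ex2_start), end = c(ex1_end, ex2_end)),
    cds_start = ex1_start + 100, cds_end = ex2_start + (1443 - exon1_coding) - 1,
    cds_seq = cds_seq)
}

#' Simulate a breed-like study
#'
#' Gene-drops a founder haplotype pool through `n_generations` of random
#' mating with Poisson recombination, then assembles a case/control array
#' cohort, a case sequence tier, and a control genome panel. One founder
#' haplotype carries the causal alt allele; cases are sampled from the
#' population's homozygous carriers and share an identical-by-descent segment
#' of the configured length around the causal variant (their haplotypes are
#' coerced to the causal founder over that segment, which is recorded as the
#' truth interval). The control panel is drawn from individuals without any
#' causal allele, and the generator asserts on every run that the panel
#' carries zero copies of it. With a nonzero `phenotype_error_rate`, case
#' slots may be filled by mislabeled non-homozygotes, mirroring occasional
#' phenotyping error. Deterministic given the config seed.
#'
#' Neutral site allele configurations place every allele on at least two
#' founder haplotypes, emulating the common, panel-ascertained polymorphisms
#' an array and a joint-called control panel would see; consequently the only
#' variants private to the cases are the causal one and any deliberately
#' planted ones.
#'
#' @param cfg a [sim_config].
#' @return a `simulated_study` list: `genotypes` + `samples` (array tier),
#'   `case_variants` (sequence tier for the sequenced cases), `panel`
#'   (control genome [variant_set]), `transcript`, `cohort_seq_geno`
#'   (cohort dosages at every sequence site, for targeted genotyping),
#'   `truth` (causal variant, IBD interval, mislabeled samples, attempt) and
#'   `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  for (attempt in seq_len(cfg$max_attempts)) {
    study <- .simulate_once(cfg, attempt)
    if (!is.null(study)) return(study)
  }
  stop("infeasible simulation config: could not realize ", cfg$n_cases,
       " homozygous cases plus a causal-free panel of ", cfg$n_control_genomes,
       " genomes in ", cfg$max_attempts, " attempts")
}

.simulate_once <- function(cfg, attempt) {
  nf <- cfg$n_founder_haplotypes
  L <- cfg$chromosome_length_bp
  N <- cfg$population_size
  chroms <- cfg$chromosomes

  # founder alleles: per site an alt count in 2..(nf-2), alt assigned to a
  # random founder subset; the causal site is alt only on founder 1
  sites <- list(); falle <- list(); refs <- list(); alts <- list()
  nt <- c("A", "C", "G", "T")
  for (ch in chroms) {
    ns <- cfg$n_sites_per_chromosome
    if (ch == cfg$causal_chromosome) {
      pos <- sample.int(L, ns + 10L)
      pos <- setdiff(pos, cfg$causal_position_bp)[seq_len(ns - 1L)]
      pos <- sort(c(pos, cfg$causal_position_bp))
    } else {
      pos <- sort(sample.int(L, ns))
    }
    Fm <- matrix(0L, nf, length(pos))
    cnt <- sample(2:(nf - 2L), length(pos), replace = TRUE)
    for (j in seq_along(pos)) Fm[sample.int(nf, cnt[j]), j] <- 1L
    r <- sample(nt, length(pos), replace = TRUE)
    a <- vapply(r, function(x) sample(setdiff(nt, x), 1L), character(1))
    if (ch == cfg$causal_chromosome) {
      jc <- match(cfg$causal_position_bp, pos)
      Fm[, jc] <- 0L; Fm[1L, jc] <- 1L
      r[jc] <- "C"; a[jc] <- "A"
    }
    sites[[ch]] <- pos; falle[[ch]] <- Fm; refs[[ch]] <- r; alts[[ch]] <- unname(a)
  }

  # transcript overlapping the causal position; harmonize coding-site ref
  # alleles with the transcript's CDS sequence
  tx <- .causal_transcript(cfg$causal_chromosome, cfg$causal_position_bp)
  ch <- cfg$causal_chromosome
  span <- c(min(tx$exons$start), max(tx$exons$end))
  for (j in which(sites[[ch]] >= span[1] & sites[[ch]] <= span[2])) {
    loc <- genomic_to_cds(sites[[ch]][j], tx)
    if (loc$kind == "coding") {
      base <- substr(tx$cds_seq, loc$cds_pos, loc$cds_pos)
      refs[[ch]][j] <- base
      if (alts[[ch]][j] == base) alts[[ch]][j] <- sample(setdiff(nt, base), 1L)
    }
  }

  # founder bottleneck: each initial haplotype is a single founder, genome-wide
  p1 <- cfg$causal_founder_freq
  fdraw <- sample.int(nf, 2L * N, replace = TRUE,
                      prob = c(p1, rep((1 - p1) / (nf - 1L), nf - 1L)))
  pop <- lapply(seq_len(N), function(i) {
    lapply(chroms, function(ch) list(
      list(brk = 1, fid = fdraw[2L * i - 1L]),
      list(brk = 1, fid = fdraw[2L * i])))
  })

  for (g in seq_len(cfg$n_generations)) {
    mo <- sample.int(N, N, replace = TRUE)
    fa <- sample.int(N, N, replace = TRUE)
    clash <- which(fa == mo)
    while (length(clash)) {
      fa[clash] <- sample.int(N, length(clash), replace = TRUE)
      clash <- clash[fa[clash] == mo[clash]]
    }
    pop <- lapply(seq_len(N), function(i) {
      lapply(seq_along(chroms), function(c_i) list(
        .recombine(pop[[mo[i]]][[c_i]][[1L]], pop[[mo[i]]][[c_i]][[2L]], L,
                   cfg$recombination_rate),
        .recombine(pop[[fa[i]]][[c_i]][[1L]], pop[[fa[i]]][[c_i]][[2L]], L,
                   cfg$recombination_rate)))
    })
  }

  ci <- match(cfg$causal_chromosome, chroms)
  causal_dose <- vapply(pop, function(ind)
    sum(.fid_at(ind[[ci]][[1L]], cfg$causal_position_bp) == 1L,
        .fid_at(ind[[ci]][[2L]], cfg$causal_position_bp) == 1L), numeric(1))
  hom <- which(causal_dose == 2)
  clear <- which(causal_dose == 0)
  nonhom <- which(causal_dose < 2)
  if (length(hom) < cfg$n_cases) return(NULL)

  case_idx <- sample(hom, cfg$n_cases)
  n_err <- stats::rbinom(1L, cfg$n_cases, cfg$phenotype_error_rate)
  err_idx <- integer(0)
  if (n_err > 0L) {
    pool <- setdiff(nonhom, case_idx)
    if (length(pool) < n_err) return(NULL)
    err_idx <- sample(pool, n_err)
    case_idx[seq.int(cfg$n_cases - n_err + 1L, cfg$n_cases)] <- err_idx
  }
  ctrl_pool <- setdiff(nonhom, case_idx)
  if (length(ctrl_pool) < cfg$n_controls) return(NULL)
  ctrl_idx <- sample(ctrl_pool, cfg$n_controls)
  panel_pool <- setdiff(clear, c(case_idx, ctrl_idx))
  if (length(panel_pool) < cfg$n_control_genomes) return(NULL)
  panel_idx <- sample(panel_pool, cfg$n_control_genomes)

  # coerce the IBD segment around the causal variant on the true cases, and
  # break identity-by-descent decisively just outside it: each case haplotype
  # reverts to a random non-causal founder over a flanking window, so the
  # configured segment length is the exact shared length (truth is exact)
  seg_hi <- min(L, cfg$causal_position_bp + floor(cfg$ibd_segment_length_bp / 2))
  seg_lo <- max(1, seg_hi - cfg$ibd_segment_length_bp + 1)
  seg_hi <- min(L, seg_lo + cfg$ibd_segment_length_bp - 1)
  flank <- ceiling(cfg$ibd_segment_length_bp / 2)
  for (i in setdiff(case_idx, err_idx)) {
    for (hpl in 1:2) {
      h <- pop[[i]][[ci]][[hpl]]
      if (seg_lo > 1) {
        f <- 1L + sample.int(nf - 1L, 1L)
        h <- .overwrite_segment(h, max(1, seg_lo - flank), seg_lo - 1, f, L)
      }
      if (seg_hi < L) {
        f <- 1L + sample.int(nf - 1L, 1L)
        h <- .overwrite_segment(h, seg_hi + 1, min(L, seg_hi + flank), f, L)
      }
      pop[[i]][[ci]][[hpl]] <- .overwrite_segment(h, seg_lo, seg_hi, 1L, L)
    }
  }

  dosages <- function(idx, c_i) {
    pos <- sites[[chroms[c_i]]]
    Fm <- falle[[chroms[c_i]]]
    t(vapply(idx, function(i) {
      f1 <- .fid_at(pop[[i]][[c_i]][[1L]], pos)
      f2 <- .fid_at(pop[[i]][[c_i]][[2L]], pos)
      Fm[cbind(f1, seq_along(pos))] + Fm[cbind(f2, seq_along(pos))]
    }, numeric(length(pos))))
  }

  case_ids <- sprintf("case_%02d", seq_len(cfg$n_cases))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(cfg$n_controls))
  cohort_idx <- c(case_idx, ctrl_idx)
  cohort_ids <- c(case_ids, ctrl_ids)
  st <- sample_table(cohort_ids, "SimBreed",
                     c(rep("case", cfg$n_cases), rep("control", cfg$n_controls)))

  cohort_geno <- do.call(cbind, lapply(seq_along(chroms), function(c_i) dosages(cohort_idx, c_i)))
  all_pos <- unlist(sites, use.names = FALSE)
  all_chrom <- rep(chroms, lengths(sites))
  all_ref <- unlist(refs, use.names = FALSE)
  all_alt <- unlist(alts, use.names = FALSE)
  rownames(cohort_geno) <- cohort_ids

  # array tier: evenly spread marker subset per chromosome, causal site excluded
  marker_cols <- unlist(lapply(seq_along(chroms), function(c_i) {
    off <- if (c_i == 1L) 0L else sum(lengths(sites)[seq_len(c_i - 1L)])
    cand <- seq_along(sites[[chroms[c_i]]])
    if (chroms[c_i] == cfg$causal_chromosome)
      cand <- setdiff(cand, match(cfg$causal_position_bp, sites[[chroms[c_i]]]))
    off + cand[unique(round(seq(1, length(cand),
                                length.out = cfg$n_markers_per_chromosome)))]
  }))
  calls <- cohort_geno[, marker_cols, drop = FALSE]
  calls[matrix(stats::runif(length(calls)) < cfg$missing_rate,
               nrow(calls), ncol(calls))] <- NA_integer_
  mm <- marker_map(paste0(all_chrom[marker_cols], "_",
                          format(all_pos[marker_cols], scientific = FALSE, trim = TRUE)),
                   all_chrom[marker_cols], all_pos[marker_cols],
                   all_ref[marker_cols], all_alt[marker_cols])
  g <- genotype_matrix(calls, mm, cohort_ids)

  # sequence tier: the sequenced cases (non-mislabeled ones first) at every
  # site where at least one of them carries the alt allele
  seq_ids <- c(setdiff(case_ids, case_ids[case_idx %in% err_idx]),
               case_ids[case_idx %in% err_idx])[seq_len(cfg$n_sequenced_cases)]
  seq_geno <- cohort_geno[seq_ids, , drop = FALSE]
  keep <- colSums(seq_geno > 0L) > 0L
  case_vs <- variant_set(data.frame(chrom = all_chrom[keep], pos = all_pos[keep],
                                    ref = all_ref[keep], alt = all_alt[keep]),
                         seq_geno[, keep, drop = FALSE], seq_ids)

  panel_geno <- do.call(cbind, lapply(seq_along(chroms), function(c_i) dosages(panel_idx, c_i)))
  pkeep <- colSums(panel_geno > 0L) > 0L
  panel_ids <- sprintf("panel_%03d", seq_len(cfg$n_control_genomes))
  rownames(panel_geno) <- panel_ids
  panel_vs <- variant_set(data.frame(chrom = all_chrom[pkeep], pos = all_pos[pkeep],
                                     ref = all_ref[pkeep], alt = all_alt[pkeep]),
                          panel_geno[, pkeep, drop = FALSE], panel_ids)

  causal_key <- paste(cfg$causal_chromosome,
                      format(cfg$causal_position_bp, scientific = FALSE, trim = TRUE),
                      "C", "A", sep = ":")
  stopifnot(!(causal_key %in% variant_keys(panel_vs)))  # panel never carries the causal allele

  truth <- list(
    causal_variant = list(chrom = cfg$causal_chromosome,
                          pos = cfg$causal_position_bp, ref = "C", alt = "A"),
    causal_key = causal_key,
    ibd_interval = genome_interval(cfg$causal_chromosome, seg_lo, seg_hi),
    phenotype_error_samples = case_ids[case_idx %in% err_idx],
    sequenced_samples = seq_ids,
    attempt = attempt,
    seed = cfg$seed)

  structure(list(genotypes = g, samples = st, case_variants = case_vs,
                 panel = panel_vs, transcript = tx,
                 cohort_seq_geno = cohort_geno,
                 site_map = data.frame(chrom = all_chrom, pos = all_pos,
                                       ref = all_ref, alt = all_alt,
                                       stringsAsFactors = FALSE),
                 truth = truth, config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d cases / %d controls, %d markers, %d case variants, panel of %d genomes\n",
              sum(x$samples$phenotype == "case"), sum(x$samples$phenotype == "control"),
              nrow(x$genotypes$markers), nrow(x$case_variants$variants),
              length(x$panel$samples)))
  cat("  causal:", x$truth$causal_key, " IBD:", format(x$truth$ibd_interval$start, scientific = FALSE),
      "-", format(x$truth$ibd_interval$end, scientific = FALSE), "\n")
  invisible(x)
}

#' Genotype the array cohort at an arbitrary sequence site
#'
#' Emulates targeted (Sanger-style) genotyping of the cohort at a candidate
#' variant: a lookup into the cohort's sequence-tier dosages, with no
#' missingness.
#'
#' @param study a `simulated_study`.
#' @param chrom,pos site coordinates.
#' @return named integer dosage vector over the cohort.
#' @export
genotype_cohort_at <- function(study, chrom, pos) {
  j <- which(study$site_map$chrom == chrom & study$site_map$pos == pos)
  if (!length(j)) stop("no sequence site at ", chrom, ":", pos)
  stats::setNames(as.integer(study$cohort_seq_geno[, j[1L]]),
                  rownames(study$cohort_seq_geno))
}

#' Plant neutral private variants
#'
#' Adds `n` variants that are homozygous-alt in every sequenced case and
#' absent from the control panel, at non-coding positions (outside the
#' transcript's exons) of the stated region. Used to give the prioritization
#' cascade known sterile decoys.
#'
#' @param study a `simulated_study`.
#' @param n number of variants to plant (`n = 0` returns the study
#'   unchanged).
#' @param region a [genome_interval], or `NULL` for anywhere in the genome.
#' @return the modified study; planted variants are recorded in
#'   `truth$planted`.
#' @export
plant_neutral_private_variants <- function(study, n, region = NULL) {
  stopifnot(inherits(study, "simulated_study"))
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(study)
  cfg <- study$config
  if (is.null(region)) {
    chrom <- sample(cfg$chromosomes, 1L)
    lo <- 1; hi <- cfg$chromosome_length_bp
  } else {
    stopifnot(inherits(region, "genome_interval"))
    chrom <- region$chrom
    lo <- max(1, region$start); hi <- min(cfg$chromosome_length_bp, region$end)
  }
  taken <- study$site_map$pos[study$site_map$chrom == chrom]
  tx <- study$transcript
  ok_pos <- function(p) {
    if (p %in% taken) return(FALSE)
    if (tx$chrom == chrom && any(tx$exons$start <= p & p <= tx$exons$end)) return(FALSE)
    TRUE
  }
  exon_bp <- if (tx$chrom == chrom)
    sum(pmax(0, pmin(tx$exons$end, hi) - pmax(tx$exons$start, lo) + 1)) else 0
  n_free <- (hi - lo + 1) - sum(taken >= lo & taken <= hi) - exon_bp
  if (n_free < n) stop("region too small to place ", n, " variants")
  pos <- numeric(0)
  tries <- 0L
  while (length(pos) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) stop("region too small to place ", n, " variants")
    p <- lo + sample.int(hi - lo + 1, 1L) - 1
    if (ok_pos(p) && !(p %in% pos)) pos <- c(pos, p)
  }
  pos <- sort(pos)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n, replace = TRUE)
  alt <- vapply(ref, function(x) sample(setdiff(nt, x), 1L), character(1))
  vs <- study$case_variants
  newv <- rbind(vs$variants,
                data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE))
  newg <- cbind(vs$geno, matrix(2L, length(vs$samples), n))
  study$case_variants <- variant_set(newv, newg, vs$samples)
  planted <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  study$truth$planted <- rbind(study$truth$planted, planted)
  study
}
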