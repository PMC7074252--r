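# Exact genotype-phenotype association on candidate variants and multi-breed
# genotype tabulation.

#' Tabulate genotype counts by breed and phenotype
#'
#' @param calls named integer vector of alt-dosage calls (0/1/2, `NA`
#'   missing), names are sample ids.
#' @param samples a [sample_table] covering every called sample.
#' @return a `genotype_count_table`: one row per (breed, phenotype) with
#'   `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing` and `n` (non-missing
#'   total). Rows are ordered by breed then phenotype, so the table is
#'   invariant to the sample order.
#' @export
tabulate_genotypes <- function(calls, samples) {
  ids <- names(calls)
  if (is.null(ids)) stop("`calls` must be a named vector of sample ids")
  m <- match(ids, samples$sample_id)
  if (anyNA(m))
    stop("sample(s) with a call but no metadata: ", paste(ids[is.na(m)], collapse = ", "))
  df <- data.frame(breed = samples$breed[m], phenotype = samples$phenotype[m],
                   call = as.integer(calls), stringsAsFactors = FALSE)
  key <- unique(df[c("breed", "phenotype")])
  key <- key[order(key$breed, key$phenotype), , drop = FALSE]
  tab <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    g <- df$call[df$breed == key$breed[i] & df$phenotype == key$phenotype[i]]
    data.frame(breed = key$breed[i], phenotype = key$phenotype[i],
               n_hom_ref = sum(g == 0L, na.rm = TRUE),
               n_het = sum(g == 1L, na.rm = TRUE),
               n_hom_alt = sum(g == 2L, na.rm = TRUE),
               n_missing = sum(is.na(g)),
               stringsAsFactors = FALSE)
  }))
  tab$n <- tab$n_hom_ref + tab$n_het + tab$n_hom_alt
  rownames(tab) <- NULL
  class(tab) <- c("genotype_count_table", "data.frame")
  tab
}

#' Exact Fisher test of a 2x2 table
#'
#' Exact hypergeometric test computed in log space, so p-values of magnitude
#' 1e-40 and below remain finite and stable. The two-sided p-value follows
#' the probability-mass rule: the summed probability of all tables (margins
#' fixed) whose probability does not exceed the observed table's, with a
#' relative tolerance of 1e-7 on the probability comparison.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcomes: table `rbind(c(a, b), c(c, d))`.
#' @param sidedness `"two-sided"` (default), `"greater"` or `"less"` (on the
#'   `a` cell).
#' @return exact p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sidedness = c("two-sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("cell counts must be non-negative integers")
  if (sum(cnt) == 0) stop("Fisher test undefined on an empty table")
  m <- a + b; n2 <- c + d; k <- a + c
  x <- max(0, k - n2):min(k, m)
  lp <- stats::dhyper(x, m, n2, k, log = TRUE)
  lobs <- lp[match(a, x)]
  p <- switch(sidedness,
    "two-sided" = sum(exp(lp[lp <= lobs + log1p(1e-7)])),
    "greater" = sum(exp(lp[x >= a])),
    "less" = sum(exp(lp[x <= a])))
  min(1, p)
}

#' Exact test of independence for a 2x3 genotype table
#'
#' Full enumeration of all tables with the observed margins (two-sided
#' probability-mass rule, log-space) when the grand total is at most
#' `max_enumeration`; otherwise a seeded Monte Carlo estimate over random
#' tables with the same margins.
#'
#' @param m 2x3 integer matrix (phenotype rows, genotype columns).
#' @param max_enumeration largest grand total for exhaustive enumeration.
#' @param n_sim number of Monte Carlo tables for larger inputs.
#' @param seed RNG seed for the Monte Carlo fallback (`NULL` = current RNG).
#' @return exact (or simulated) p-value in (0, 1].
#' @export
exact_test_2x3 <- function(m, max_enumeration = 400, n_sim = 1e5, seed = NULL) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L))) stop("expected a 2x3 table")
  if (any(m < 0) || any(m != round(m))) stop("cell counts must be non-negative integers")
  r1 <- sum(m[1, ]); N <- sum(m); cs <- colSums(m)
  if (N == 0) stop("empty table")
  ltab <- function(x11, x12, x13) {
    lchoose(cs[1], x11) + lchoose(cs[2], x12) + lchoose(cs[3], x13) - lchoose(N, r1)
  }
  lobs <- ltab(m[1, 1], m[1, 2], m[1, 3])
  if (N <= max_enumeration) {
    acc <- -Inf
    for (x11 in 0:min(r1, cs[1])) {
      x12max <- min(r1 - x11, cs[2])
      for (x12 in 0:x12max) {
        x13 <- r1 - x11 - x12
        if (x13 > cs[3]) next
        lp <- ltab(x11, x12, x13)
        if (lp <= lobs + log1p(1e-7)) {
          acc <- if (is.infinite(acc)) lp else max(acc, lp) + log1p(exp(-abs(acc - lp)))
        }
      }
    }
    return(min(1, exp(acc)))
  }
  if (!is.null(seed)) set.seed(seed)
  sims <- stats::r2dtable(n_sim, c(r1, N - r1), cs)
  lsim <- vapply(sims, function(s) ltab(s[1, 1], s[1, 2], s[1, 3]), numeric(1))
  (1 + sum(lsim <= lobs + log1p(1e-7))) / (n_sim + 1)
}

#' Exact genotype-phenotype association test
#'
#' Collapses a [genotype_count_table] according to the genetic coding and
#' tests cases against controls exactly. Codings: `"recessive"` (hom-alt vs
#' all other genotypes; the natural headline test for a recessive disease),
#' `"dominant"` (alt-carrier vs hom-ref), `"allelic"` (allele counts) and
#' `"genotypic"` (full 2x3 table via [exact_test_2x3()]).
#'
#' Rows with phenotype `"unknown"` are ignored. A minimum-count guard refuses
#' to test when either phenotype margin is below `min_margin` (default 5), so
#' single-individual strata are reported in the table but never tested alone;
#' set `min_margin = 0` to override. The odds ratio of a 2x2 collapse uses
#' the Haldane-Anscombe +0.5 correction when any cell is zero and is flagged
#' as corrected.
#'
#' @param table a [genotype_count_table].
#' @param coding one of `"recessive"`, `"dominant"`, `"allelic"`,
#'   `"genotypic"`.
#' @param breeds optional subset of breeds to test (default: all present).
#' @param min_margin minimum per-phenotype sample count.
#' @param seed passed to [exact_test_2x3()]'s Monte Carlo fallback.
#' @return an `assoc_test_result` list: `coding`, the collapsed contingency
#'   `table`, `p_value`, `odds_ratio`, `or_corrected`.
#' @export
test_variant <- function(table, coding = c("recessive", "dominant", "allelic", "genotypic"),
                         breeds = NULL, min_margin = 5, seed = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(table, "genotype_count_table"))
  if (!is.null(breeds)) {
    missing <- setdiff(breeds, table$breed)
    if (length(missing)) stop("breed(s) not present in table: ", paste(missing, collapse = ", "))
    table <- table[table$breed %in% breeds, , drop = FALSE]
  }
  table <- table[table$phenotype %in% c("case", "control"), , drop = FALSE]
  agg <- function(ph, col) sum(table[[col]][table$phenotype == ph])
  counts <- sapply(c("case", "control"), function(ph)
    c(hom_ref = agg(ph, "n_hom_ref"), het = agg(ph, "n_het"), hom_alt = agg(ph, "n_hom_alt")))
  if (any(colSums(counts) == 0)) stop("both phenotypes must be present")
  if (any(colSums(counts) < min_margin))
    stop("phenotype margin below the minimum count guard (", min_margin,
         "); set min_margin = 0 to override")
  ca <- counts[, "case"]; co <- counts[, "control"]
  tab2 <- switch(coding,
    recessive = rbind(case = c(hom_alt = ca[["hom_alt"]], other = ca[["hom_ref"]] + ca[["het"]]),
                      control = c(co[["hom_alt"]], co[["hom_ref"]] + co[["het"]])),
    dominant = rbind(case = c(carrier = ca[["het"]] + ca[["hom_alt"]], hom_ref = ca[["hom_ref"]]),
                     control = c(co[["het"]] + co[["hom_alt"]], co[["hom_ref"]])),
    allelic = rbind(case = c(alt = 2 * ca[["hom_alt"]] + ca[["het"]],
                             ref = 2 * ca[["hom_ref"]] + ca[["het"]]),
                    control = c(2 * co[["hom_alt"]] + co[["het"]],
                                2 * co[["hom_ref"]] + co[["het"]])),
    genotypic = NULL)
  if (coding == "genotypic") {
    m <- rbind(case = ca, control = co)
    p <- exact_test_2x3(m, seed = seed)
    res <- list(coding = coding, table = m, p_value = p,
                odds_ratio = NA_real_, or_corrected = FALSE)
  } else {
    p <- fisher_exact_2x2(tab2[1, 1], tab2[1, 2], tab2[2, 1], tab2[2, 2])
    zero <- any(tab2 == 0)
    t2 <- if (zero) tab2 + 0.5 else tab2
    or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    res <- list(coding = coding, table = tab2, p_value = p,
                odds_ratio = or, or_corrected = zero)
  }
  class(res) <- "assoc_test_result"
  res
}

#' @export
print.assoc_test_result <- function(x, ...) {
  cat(sprintf("exact association test (%s coding): p = %.3g", x$coding, x$p_value))
  if (is.finite(x$odds_ratio))
    cat(sprintf(", OR = %.3g%s", x$odds_ratio,
                if (x$or_corrected) " (Haldane-corrected)" else ""))
  cat("\n")
  print(x$table)
  invisible(x)
}
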