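#' Array QC configuration
#'
#' Thresholds for the fixed-order marker/sample quality-control pass:
#' sample call rate, then marker call rate, then minor allele frequency,
#' then exact Hardy-Weinberg equilibrium in controls.
#'
#' @param min_call_rate_sample minimum per-sample call rate (default 0.90).
#' @param min_call_rate_marker minimum per-marker call rate (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.10), computed on
#'   post-sample-QC calls with both phenotypes pooled.
#' @param hwe_p_floor_controls markers with an exact HWE p-value in controls
#'   below this floor are removed (default 1e-5); markers monomorphic in
#'   controls are exempt.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_call_rate_sample = 0.90, min_call_rate_marker = 0.90,
                      min_maf = 0.10, hwe_p_floor_controls = 1e-5) {
  v <- c(min_call_rate_sample, min_call_rate_marker, min_maf, hwe_p_floor_controls)
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("all QC thresholds must lie in (0, 1]")
  structure(list(min_call_rate_sample = min_call_rate_sample,
                 min_call_rate_marker = min_call_rate_marker,
                 min_maf = min_maf,
                 hwe_p_floor_controls = hwe_p_floor_controls),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditions on the observed allele counts and enumerates all feasible
#' heterozygote counts; the two-sided p-value is the summed probability of
#' every heterozygote count whose conditional probability does not exceed
#' that of the observed count. Computed in log space.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0L) stop("HWE test undefined: no genotypes observed")
  nA <- 2L * n_hom_ref + n_het
  nB <- 2L * n_hom_alt + n_het
  if (nA == 0L || nB == 0L) return(1.0)  # monomorphic
  ks <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  lp <- ks * log(2) + lfactorial(n) -
    lfactorial((nA - ks) / 2) - lfactorial(ks) - lfactorial((nB - ks) / 2)
  lp <- lp - max(lp)
  lp <- lp - log(sum(exp(lp)))  # normalize
  lobs <- lp[match(n_het, ks)]
  min(1, sum(exp(lp[lp <= lobs + log1p(1e-7)])))
}

#' Fixed-order marker/sample quality control
#'
#' One pass in fixed order: (1) samples below the sample call-rate threshold,
#' (2) markers below the marker call-rate threshold (on retained samples),
#' (3) markers below the MAF threshold (phenotypes pooled), (4) markers out of
#' Hardy-Weinberg equilibrium in controls. Every removal is logged with the
#' triggering rule and value; the pass is idempotent.
#'
#' @param g a [genotype_matrix].
#' @param samples a [sample_table]; controls are required for the HWE filter.
#' @param cfg a [qc_config].
#' @return list with `genotypes`, `samples` (pruned), `log` (data frame of
#'   removals), `n_samples`, `n_markers`.
#' @export
qc_filter <- function(g, samples, cfg = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "qc_config"))
  st <- samples[match(g$samples, samples$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("sample table does not cover all genotyped samples")
  if (!any(st$phenotype == "control")) stop("QC requires controls (HWE filter runs on controls only)")
  logs <- list()

  cr_s <- rowMeans(!is.na(g$calls))
  drop_s <- cr_s < cfg$min_call_rate_sample
  if (any(drop_s))
    logs$s <- data.frame(type = "sample", id = g$samples[drop_s],
                         rule = "sample-call-rate", value = cr_s[drop_s])
  if (all(drop_s)) stop("QC removed all samples (sample call-rate rule)")
  keep_s <- g$samples[!drop_s]
  calls <- g$calls[keep_s, , drop = FALSE]
  st <- st[match(keep_s, st$sample_id), , drop = FALSE]

  cr_m <- colMeans(!is.na(calls))
  drop_cr <- cr_m < cfg$min_call_rate_marker

  p_alt <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0
  drop_maf <- !drop_cr & maf < cfg$min_maf

  ctrl <- calls[st$phenotype == "control", , drop = FALSE]
  hwe_p <- rep(NA_real_, ncol(calls))
  cand <- which(!drop_cr & !drop_maf)
  for (j in cand) {
    cj <- ctrl[, j]
    n0 <- sum(cj == 0L, na.rm = TRUE); n1 <- sum(cj == 1L, na.rm = TRUE)
    n2 <- sum(cj == 2L, na.rm = TRUE)
    if (n0 + n1 + n2 == 0L) next
    if (min(2L * n0 + n1, 2L * n2 + n1) == 0L) next  # monomorphic in controls: exempt
    hwe_p[j] <- hwe_exact_test(n0, n1, n2)
  }
  drop_hwe <- !is.na(hwe_p) & hwe_p < cfg$hwe_p_floor_controls

  mk <- g$markers$marker_id
  if (any(drop_cr))
    logs$cr <- data.frame(type = "marker", id = mk[drop_cr],
                          rule = "marker-call-rate", value = cr_m[drop_cr])
  if (any(drop_maf))
    logs$maf <- data.frame(type = "marker", id = mk[drop_maf],
                           rule = "maf", value = maf[drop_maf])
  if (any(drop_hwe))
    logs$hwe <- data.frame(type = "marker", id = mk[drop_hwe],
                           rule = "hwe-controls", value = hwe_p[drop_hwe])

  keep_m <- which(!(drop_cr | drop_maf | drop_hwe))
  if (length(keep_m) == 0L) stop("QC removed all markers")
  g2 <- subset_markers(genotype_matrix(calls, g$markers, keep_s), keep_m)
  log <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
         else data.frame(type = character(), id = character(),
                         rule = character(), value = numeric())
  st_out <- st
  class(st_out) <- c("sample_table", "data.frame")
  list(genotypes = g2, samples = st_out, log = log,
       n_samples = length(keep_s), n_markers = length(keep_m))
}

#' Kinship estimation
#'
#' `"ibs"`: mean proportion of shared alleles per sample pair over markers
#' non-missing in both. `"centered-grm"`: cross-product of mean-centered
#' dosage vectors (missing calls mean-imputed per marker) scaled by the sum of
#' `2p(1-p)` over markers. Both are symmetric by construction.
#'
#' @param g a post-QC [genotype_matrix].
#' @param estimator `"centered-grm"` (default) or `"ibs"`.
#' @return a square `kinship_matrix` with attribute `estimator`.
#' @export
kinship <- function(g, estimator = c("centered-grm", "ibs")) {
  estimator <- match.arg(estimator)
  X <- g$calls
  n <- nrow(X)
  if (estimator == "ibs") {
    K <- matrix(1, n, n, dimnames = list(g$samples, g$samples))
    obs <- !is.na(X)
    Xz <- X; Xz[!obs] <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(i)) {
        both <- obs[i, ] & obs[j, ]
        if (!any(both)) stop("samples ", g$samples[i], " and ", g$samples[j],
                             " share no genotyped marker")
        s <- mean(1 - abs(Xz[i, both] - Xz[j, both]) / 2)
        K[i, j] <- K[j, i] <- s
      }
    }
  } else {
    cm <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X))
    if (length(idx)) X[idx] <- cm[(idx - 1L) %/% n + 1L]
    p <- cm / 2
    denom <- sum(2 * p * (1 - p))
    if (denom <= 0) stop("all markers monomorphic; centered GRM undefined")
    Z <- sweep(X, 2L, 2 * p)
    K <- tcrossprod(Z) / denom
    dimnames(K) <- list(g$samples, g$samples)
    K <- (K + t(K)) / 2
  }
  structure(K, estimator = estimator, class = c("kinship_matrix", "matrix", "array"))
}

#' Mixed-model association scan
#'
#' Per-marker single-random-effect linear mixed model
#' `y = mu + x b + u + e`, `cov(u) = sg^2 K`, `cov(e) = se^2 I`, fitted by
#' REML via one eigendecomposition of `K` (rotation trick). The variance
#' ratio `delta = se^2/sg^2` is re-optimized for every marker by 1-D
#' optimization of the profiled REML log-likelihood, and the marker effect is
#' tested with a Wald test referred to the F(1, n-2) distribution (the
#' small-sample-calibrated form; with `K = I` this reduces exactly to the
#' ordinary least-squares t-test). Missing genotypes are mean-imputed per
#' marker for the regression only.
#'
#' @param g a post-QC [genotype_matrix].
#' @param phenotype numeric vector coded 1 (case) / 0 (control), aligned with
#'   the samples of `g`.
#' @param K a [kinship] matrix over the same samples.
#' @param delta_range search range for `delta` (log-scaled 1-D optimization).
#' @return data frame (`assoc_result`): marker id, chromosome, position,
#'   effect `beta`, `se`, Wald `stat`, `p`, REML `delta`, and a `monomorphic`
#'   flag (such markers get `p = 1`).
#' @export
lmm_scan <- function(g, phenotype, K, delta_range = c(1e-5, 1e5)) {
  y <- as.numeric(phenotype)
  n <- length(g$samples)
  stopifnot(length(y) == n, nrow(K) == n)
  ed <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ed$values), 1)
  if (min(ed$values) < -tol)
    stop(sprintf("kinship matrix is not positive semi-definite (smallest eigenvalue %.3e)",
                 min(ed$values)))
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  yr <- drop(crossprod(U, y))
  ir <- drop(crossprod(U, rep(1, n)))
  np <- n - 2L
  lo <- log(delta_range[1]); hi <- log(delta_range[2])

  fit_one <- function(xr) {
    reml <- function(ldelta) {
      w <- 1 / (d + exp(ldelta))
      X <- cbind(ir, xr)
      XtWX <- crossprod(X * w, X)
      XtWy <- crossprod(X * w, yr)
      det2 <- XtWX[1, 1] * XtWX[2, 2] - XtWX[1, 2]^2
      if (det2 <= 0) return(1e10)
      beta <- solve(XtWX, XtWy)
      r <- yr - X %*% beta
      rss <- sum(w * r^2)
      0.5 * (np * log(rss) + sum(log(d + exp(ldelta))) + log(det2))
    }
    opt <- stats::optimize(reml, c(lo, hi))
    delta <- exp(opt$minimum)
    w <- 1 / (d + delta)
    X <- cbind(ir, xr)
    XtWX <- crossprod(X * w, X)
    beta <- solve(XtWX, crossprod(X * w, yr))
    r <- yr - X %*% beta
    sigma2 <- sum(w * r^2) / np
    covb <- sigma2 * solve(XtWX)
    se <- sqrt(covb[2, 2])
    stat <- (beta[2] / se)^2
    c(beta = beta[2], se = se, stat = stat,
      p = stats::pf(stat, 1, np, lower.tail = FALSE), delta = delta)
  }

  m <- ncol(g$calls)
  out <- matrix(NA_real_, m, 5L,
                dimnames = list(NULL, c("beta", "se", "stat", "p", "delta")))
  mono <- logical(m)
  for (j in seq_len(m)) {
    x <- as.numeric(g$calls[, j])
    miss <- is.na(x)
    if (all(miss) || stats::var(x, na.rm = TRUE) == 0) {
      mono[j] <- TRUE
      out[j, ] <- c(0, NA, 0, 1, NA)
      next
    }
    if (any(miss)) x[miss] <- mean(x[!miss])
    out[j, ] <- fit_one(drop(crossprod(U, x)))
  }
  res <- data.frame(marker_id = g$markers$marker_id, chrom = g$markers$chrom,
                    pos = g$markers$pos, out, monomorphic = mono,
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Uncorrected allelic chi-square scan
#'
#' Per-marker 2x2 allele-count chi-square (1 df, no continuity correction) of
#' cases versus controls. The genomic inflation of this scan is the
#' "before correction" lambda. Monomorphic markers are flagged and get
#' `p = 1`.
#'
#' @param g a post-QC [genotype_matrix].
#' @param phenotype numeric 1/0 vector aligned with the samples of `g`.
#' @return an `assoc_result` data frame with `stat`, `p`, `monomorphic`.
#' @export
allelic_chisq_scan <- function(g, phenotype) {
  y <- as.numeric(phenotype)
  case <- y == 1
  gc <- g$calls[case, , drop = FALSE]
  gk <- g$calls[!case, , drop = FALSE]
  a <- colSums(gc, na.rm = TRUE)                       # case alt alleles
  b <- 2 * colSums(!is.na(gc)) - a                     # case ref alleles
  cc <- colSums(gk, na.rm = TRUE)
  dd <- 2 * colSums(!is.na(gk)) - cc
  N <- a + b + cc + dd
  r1 <- a + b; r2 <- cc + dd; c1 <- a + cc; c2 <- b + dd
  mono <- c1 == 0 | c2 == 0 | r1 == 0 | r2 == 0
  stat <- rep(0, ncol(g$calls))
  ok <- !mono
  stat[ok] <- N[ok] * (a[ok] * dd[ok] - b[ok] * cc[ok])^2 /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  p <- ifelse(mono, 1, stats::pchisq(stat, 1, lower.tail = FALSE))
  res <- data.frame(marker_id = g$markers$marker_id, chrom = g$markers$chrom,
                    pos = g$markers$pos, stat = stat, p = p, monomorphic = mono,
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Genomic inflation factor (lambda)
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by the
#' null median 0.4549364.
#'
#' @param p_values vector of p-values; non-finite values are dropped.
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (!length(p)) stop("genomic inflation needs at least one finite p-value")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Genome-wide significance thresholds
#'
#' @param n_markers number of markers tested (post-QC).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param suggestive suggestive threshold, passed through unchanged.
#' @return list with `bonferroni` (= `alpha / n_markers`) and `suggestive`.
#' @export
significance_thresholds <- function(n_markers, alpha = 0.05, suggestive = 5e-5) {
  if (length(n_markers) != 1L || !is.finite(n_markers) || n_markers < 1)
    stop("n_markers must be a positive count")
  list(bonferroni = alpha / n_markers, suggestive = suggestive)
}

#' Scan diagnostics
#'
#' Bundles the inflation factor of the uncorrected allelic scan
#' (`lambda_before`), the inflation of the mixed-model p-values
#' (`lambda_after`), post-QC dimensions and the significance thresholds.
#'
#' @param allelic,lmm `assoc_result` data frames from [allelic_chisq_scan()]
#'   and [lmm_scan()].
#' @param n_samples post-QC sample count.
#' @param alpha,suggestive see [significance_thresholds()].
#' @return a `gwas_diagnostics` list.
#' @export
gwas_diagnostics <- function(allelic, lmm, n_samples, alpha = 0.05, suggestive = 5e-5) {
  th <- significance_thresholds(nrow(lmm), alpha = alpha, suggestive = suggestive)
  structure(list(lambda_before = genomic_inflation(allelic$p),
                 lambda_after = genomic_inflation(lmm$p),
                 n_markers_after_qc = nrow(lmm),
                 n_samples_after_qc = n_samples,
                 suggestive_threshold = th$suggestive,
                 bonferroni_threshold = th$bonferroni),
            class = "gwas_diagnostics")
}

#' Classical metric MDS of samples
#'
#' Classical (Torgerson) multidimensional scaling: double-centering of the
#' squared distance matrix and projection on the top eigenvectors scaled by
#' the root eigenvalues (via `stats::cmdscale`). An IBS kinship matrix is
#' converted to distances as `1 - ibs`; otherwise the input is taken to be a
#' distance matrix already.
#'
#' @param x square symmetric matrix: IBS kinship (attribute
#'   `estimator = "ibs"`) or pairwise distances.
#' @param n_dims number of embedding dimensions.
#' @return numeric matrix of per-sample coordinates (samples x `n_dims`).
#' @export
classical_mds <- function(x, n_dims = 2) {
  x <- unclass(x)
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("input must be a square matrix")
  if (max(abs(x - t(x))) > 1e-8) stop("input must be symmetric")
  D <- if (identical(attr(x, "estimator"), "ibs")) 1 - x else x
  stats::cmdscale(stats::as.dist(D), k = n_dims)
}
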