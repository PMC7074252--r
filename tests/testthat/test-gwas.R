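test_that("HWE exact test matches the enumeration oracle and handles edge cases", {
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)            # monomorphic
  expect_equal(hwe_exact_test(3, 5, 2), hwe_oracle(3, 5, 2))
  p <- hwe_exact_test(25, 50, 25)
  expect_equal(p, hwe_oracle(25, 50, 25))
  # 50 hets out of n=100 with balanced alleles is the modal count, so p = 1
  expect_equal(p, 1.0)
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
  # spot sweep over random triples (full exhaustive sweep lives in the
  # acceptance suite)
  withr::with_seed(11, {
    for (i in 1:50) {
      tr <- as.integer(stats::rmultinom(1, sample(1:30, 1), rep(1/3, 3)))
      expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                   hwe_oracle(tr[1], tr[2], tr[3]), tolerance = 1e-12)
    }
  })
})

test_that("QC removes nothing from a clean, common-variant matrix", {
  m <- matrix(rep(c(0L, 1L, 2L, 1L), 5), nrow = 4)  # MAF 0.5 everywhere
  g <- make_gm(m)
  st <- sample_table(g$samples, "B", c("case", "control", "control", "control"))
  qc <- qc_filter(g, st)
  expect_equal(qc$n_markers, 5L)
  expect_equal(qc$n_samples, 4L)
  expect_equal(nrow(qc$log), 0L)
})

test_that("a marker genotyped in 8 of 10 samples fails the marker call-rate rule", {
  withr::with_seed(5, m <- matrix(sample(0:2, 10 * 20, TRUE), nrow = 10))
  m[1:2, 1] <- NA  # call rate 0.8 at marker 1 (samples stay above 0.9)
  g <- make_gm(m)
  st <- sample_table(g$samples, "B", c(rep("case", 3), rep("control", 7)))
  qc <- qc_filter(g, st)
  expect_true("m001" %in% qc$log$id[qc$log$rule == "marker-call-rate"])
  expect_false("m001" %in% qc$genotypes$markers$marker_id)
})

test_that("one violation per rule is removed exactly as a hand enumeration says", {
  # 10 samples x 12 markers; constructed so that, by hand:
  #  - sample s10 is missing 7/12 calls (rate 0.42)         -> sample-call-rate
  #  - marker m1 is missing in s1, so 8/9 < 0.9 after s10   -> marker-call-rate
  #  - marker m2 carries one alt allele in 18 (MAF 0.056)   -> maf
  #  - marker m3 is all-heterozygous in the 7 controls
  #    (exact HWE p = 128/3432 = 0.037)                     -> hwe-controls
  #  - markers m4-m12 are clean (MAF 0.45, modal het count)
  clean <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L)
  m <- matrix(rep(clean, 12), 10, 12)
  m[10, 1:7] <- NA
  m[1, 1] <- NA
  m[, 2] <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, NA)
  m[, 3] <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, NA)
  g <- make_gm(m)
  st <- sample_table(g$samples, "B", c(rep("case", 2), rep("control", 8)))
  cfg <- qc_config(hwe_p_floor_controls = 0.05)
  qc <- qc_filter(g, st, cfg)
  expect_setequal(qc$log$id[qc$log$type == "sample"], "s10")
  expect_identical(sort(qc$log$id[qc$log$rule == "marker-call-rate"]), "m001")
  expect_identical(sort(qc$log$id[qc$log$rule == "maf"]), "m002")
  expect_identical(sort(qc$log$id[qc$log$rule == "hwe-controls"]), "m003")
  expect_identical(qc$genotypes$markers$marker_id, sprintf("m%03d", 4:12))
  # idempotence: rerunning on its own output changes nothing
  qc2 <- qc_filter(qc$genotypes, qc$samples, cfg)
  expect_identical(qc2$genotypes$calls, qc$genotypes$calls)
  expect_equal(nrow(qc2$log), 0L)
})

test_that("QC fails explicitly when everything is removed", {
  m <- matrix(NA_integer_, 3, 4)
  g <- make_gm(m)
  st <- sample_table(g$samples, "B", c("case", "control", "control"))
  expect_error(qc_filter(g, st), "all samples")
})

test_that("IBS kinship hits its boundary values and centered GRM matches hand arithmetic", {
  m <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L), c(2L, 2L, 0L, 0L))
  g <- make_gm(m)
  K <- kinship(g, "ibs")
  expect_equal(K[1, 2], 1.0)   # identical genotypes
  m2 <- rbind(c(0L, 0L, 0L), c(2L, 2L, 2L))
  expect_equal(kinship(make_gm(m2), "ibs")[1, 2], 0.0)  # opposite homozygotes

  # centered GRM: hand-computed cross-product on a 4-sample toy
  X <- matrix(as.numeric(m), 4, 4)
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  K_hand <- tcrossprod(Z) / sum(2 * p * (1 - p))
  expect_equal(unclass(kinship(g, "centered-grm")), K_hand,
               ignore_attr = TRUE, tolerance = 1e-12)

  # pair with zero overlapping markers errors
  m3 <- rbind(c(0L, NA, 1L), c(NA, 1L, NA))
  expect_error(kinship(make_gm(m3), "ibs"), "no genotyped marker")
})

test_that("with an identity kinship the mixed model degenerates to OLS", {
  withr::with_seed(21, {
    n <- 24
    m <- matrix(sample(0:2, n * 30, TRUE), n, 30)
    y <- sample(0:1, n, TRUE)
  })
  g <- make_gm(m)
  K <- diag(n); dimnames(K) <- list(g$samples, g$samples)
  res <- lmm_scan(g, y, K)
  ols_p <- apply(m, 2, function(x) {
    if (stats::var(x) == 0) return(1)
    summary(stats::lm(y ~ x))$coefficients["x", "Pr(>|t|)"]
  })
  expect_equal(res$p, unname(ols_p), tolerance = 1e-8)
  # scale invariance of the degenerate case: K = cI gives the same answer
  res5 <- lmm_scan(g, y, 5 * K)
  expect_equal(res5$p, res$p, tolerance = 1e-8)
})

test_that("per-marker REML delta matches a brute-force grid search on a toy", {
  withr::with_seed(33, {
    n <- 8
    A <- matrix(0.45, 4, 4) + 0.55 * diag(4)
    K <- as.matrix(Matrix::bdiag(A, A))  # two family blocks
    x <- sample(0:2, n, TRUE)
    u <- as.vector(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n))
    y <- 0.4 * x + u + rnorm(n, sd = 0.6)
  })
  dimnames(K) <- NULL
  g <- make_gm(matrix(x, ncol = 1))
  Kn <- K; dimnames(Kn) <- list(g$samples, g$samples)
  fit <- lmm_scan(g, y, Kn)

  # independent REML profile: dense GLS without the eigen rotation
  reml_ll <- function(delta) {
    V <- K + delta * diag(n)
    Vi <- solve(V)
    X <- cbind(1, x)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    -0.5 * ((n - 2) * log(rss) + determinant(V)$modulus + determinant(XtVX)$modulus)
  }
  grid <- 10^seq(-5, 5, length.out = 1e4)
  ll <- vapply(grid, reml_ll, numeric(1))
  best <- grid[which.max(ll)]
  step <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(fit$delta) - log(best)), 2 * step)
})

test_that("the scan rejects a non-PSD kinship matrix, naming the eigenvalue", {
  g <- make_gm(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2))
  K <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)  # eigenvalue -1
  dimnames(K) <- list(g$samples, g$samples)
  expect_error(lmm_scan(g, c(1, 0, 0), K), "positive semi-definite.*-1")
})

test_that("allelic chi-square matches the closed form and is label-symmetric", {
  # counts case A=30,a=10; control A=10,a=30 at one marker:
  # 10 cases hom-alt x ... construct allele counts directly via genotypes
  m <- matrix(c(rep(2L, 7), rep(1L, 2), rep(0L, 0), rep(0L, 7), rep(1L, 2), 2L), ncol = 1)
  g <- make_gm(m, samples = sprintf("s%02d", 1:19))
  y <- c(rep(1, 9), rep(0, 10))
  res <- allelic_chisq_scan(g, y)
  a <- sum(m[y == 1, 1]); b <- 2 * sum(y == 1) - a
  cc <- sum(m[y == 0, 1]); dd <- 2 * sum(y == 0) - cc
  oracle <- stats::chisq.test(rbind(c(a, b), c(cc, dd)), correct = FALSE)
  expect_equal(res$stat, unname(oracle$statistic))
  expect_equal(res$p, unname(oracle$p.value))
  # swapping case/control labels leaves the statistic unchanged
  expect_equal(allelic_chisq_scan(g, 1 - y)$stat, res$stat)
  # equal allele counts in both groups -> statistic 0, p 1
  m0 <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), ncol = 1)
  expect_equal(allelic_chisq_scan(make_gm(m0), c(1, 1, 1, 0, 0, 0))$stat, 0)
  expect_equal(allelic_chisq_scan(make_gm(m0), c(1, 1, 1, 0, 0, 0))$p, 1)
  # monomorphic marker flagged with p = 1
  mm <- matrix(rep(0L, 6), ncol = 1)
  rm_ <- allelic_chisq_scan(make_gm(mm), c(1, 1, 1, 0, 0, 0))
  expect_true(rm_$monomorphic)
  expect_equal(rm_$p, 1)
})

test_that("genomic inflation behaves like the median chi-square ratio it is", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1.0)
  stats <- c(0.1, 0.5, 1, 2, 5)
  p1 <- stats::pchisq(stats, 1, lower.tail = FALSE)
  p2 <- stats::pchisq(stats / 2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), genomic_inflation(p1) / 2)  # linear in the median
  withr::with_seed(8, lam <- genomic_inflation(stats::runif(1e4)))
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
  expect_error(genomic_inflation(numeric(0)), "at least one")
})

test_that("significance thresholds divide alpha by the marker count", {
  th <- significance_thresholds(116891, alpha = 0.05)
  expect_equal(signif(th$bonferroni, 2), 4.3e-7)
  expect_equal(th$suggestive, 5e-5)
  expect_equal(significance_thresholds(1)$bonferroni, 0.05)
  expect_equal(significance_thresholds(100)$bonferroni, 5e-4)
  expect_error(significance_thresholds(0), "positive")
})

test_that("classical MDS embeds distances faithfully", {
  # three mutually equidistant samples -> equal embedded distances
  D <- matrix(1, 3, 3) - diag(3)
  xy <- classical_mds(D)
  d <- as.matrix(stats::dist(xy))
  expect_equal(d[1, 2], d[1, 3], tolerance = 1e-8)
  expect_equal(d[1, 2], d[2, 3], tolerance = 1e-8)
  # exact 2-D configuration is reproduced up to isometry
  withr::with_seed(14, pts <- matrix(rnorm(20), 10, 2))
  D2 <- as.matrix(stats::dist(pts))
  emb <- classical_mds(D2)
  expect_equal(as.matrix(stats::dist(emb)), D2, ignore_attr = TRUE, tolerance = 1e-8)
  # sign-flipping an axis is an isometry
  emb2 <- emb %*% diag(c(-1, 1))
  expect_equal(as.matrix(stats::dist(emb2)), D2, ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
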