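# Orchestration: a single configuration object and a full-run driver chaining
# simulate -> QC -> mixed-model scan -> autozygosity mapping -> variant
# cascade -> consequence annotation -> exact genotype-phenotype association,
# writing every report plus a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. Serializable to and from a YAML
#' file; unknown keys are rejected on read.
#'
#' @param sim a [sim_config].
#' @param qc a [qc_config].
#' @param kinship_estimator `"centered-grm"` or `"ibs"`.
#' @param alpha,suggestive significance thresholds, see
#'   [significance_thresholds()].
#' @param autozyg_min_markers,autozyg_max_missing_fraction see
#'   [find_shared_homozygous_segments()].
#' @param assoc_coding genetic coding for the final exact association test.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            kinship_estimator = c("centered-grm", "ibs"),
                            alpha = 0.05, suggestive = 5e-5,
                            autozyg_min_markers = 25,
                            autozyg_max_missing_fraction = 0.2,
                            assoc_coding = "recessive") {
  structure(list(sim = sim, qc = qc,
                 kinship_estimator = match.arg(kinship_estimator),
                 alpha = alpha, suggestive = suggestive,
                 autozyg_min_markers = autozyg_min_markers,
                 autozyg_max_missing_fraction = autozyg_max_missing_fraction,
                 assoc_coding = assoc_coding),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param cfg a [pipeline_config].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  x$sim$chromosomes <- NULL   # derived field
  x$qc <- unclass(x$qc)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys at any level are rejected.
#'
#' @param path path to a YAML file written by [write_pipeline_config()] (or
#'   hand-edited).
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  check_keys <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) stop("unknown config key(s) in ", where, ": ",
                            paste(extra, collapse = ", "))
  }
  top <- c("sim", "qc", "kinship_estimator", "alpha", "suggestive",
           "autozyg_min_markers", "autozyg_max_missing_fraction", "assoc_coding")
  check_keys(x, top, "top level")
  sim_args <- setdiff(names(formals(sim_config)), "...")
  qc_args <- names(formals(qc_config))
  if (!is.null(x$sim)) check_keys(x$sim, sim_args, "sim")
  if (!is.null(x$qc)) check_keys(x$qc, qc_args, "qc")
  sim <- do.call(sim_config, x$sim %||% list())
  qc <- do.call(qc_config, x$qc %||% list())
  rest <- x[setdiff(names(x), c("sim", "qc"))]
  do.call(pipeline_config, c(list(sim = sim, qc = qc), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline
#'
#' Executes the stages in study order — simulate, array QC, kinship +
#' mixed-model and allelic scans with inflation diagnostics, shared-homozygous
#' segment detection and critical-interval definition, the private-variant
#' cascade with consequence annotation, and the exact genotype-phenotype test
#' on the surviving candidate — writing all tiers and reports into `out_dir`
#' together with a `manifest.json` recording the seed, per-stage counts and
#' file digests. A rerun with the same configuration reproduces identical
#' files. Any stage failure aborts with the failing stage named; outputs
#' written before the failure are retained.
#'
#' @param cfg a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
full_run <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  study <- stage("simulate", {
    s <- simulate_study(cfg$sim)
    if (cfg$sim$n_neutral_private_variants > 0L)
      s <- plant_neutral_private_variants(s, cfg$sim$n_neutral_private_variants,
                                          region = s$truth$ibd_interval)
    write_genotypes(s$genotypes, s$samples, pth("array"))
    write_vcf(s$case_variants, pth("cases.vcf"))
    write_vcf(s$panel, pth("panel.vcf"))
    write_bed(s$truth$ibd_interval, pth("truth_ibd.bed"))
    write_transcript_table(s$transcript, pth("transcript.tsv"))
    s
  })

  qc <- stage("gwas", qc_filter(study$genotypes, study$samples, cfg$qc))
  scan <- stage("gwas", {
    y <- as.numeric(qc$samples$phenotype == "case")
    K <- kinship(qc$genotypes, cfg$kinship_estimator)
    lmm <- lmm_scan(qc$genotypes, y, K)
    alle <- allelic_chisq_scan(qc$genotypes, y)
    diag <- gwas_diagnostics(alle, lmm, qc$n_samples,
                             alpha = cfg$alpha, suggestive = cfg$suggestive)
    mds <- classical_mds(kinship(qc$genotypes, "ibs"))
    write_report(lmm, pth("assoc_lmm.tsv"))
    write_report(alle, pth("assoc_allelic.tsv"))
    write_report(qc$log, pth("qc_removals.tsv"))
    write_report(data.frame(sample_id = rownames(mds), mds1 = mds[, 1], mds2 = mds[, 2]),
                 pth("mds.tsv"))
    write_report(data.frame(metric = names(unclass(diag)),
                            value = unlist(unclass(diag))), pth("gwas_diagnostics.tsv"))
    list(lmm = lmm, allelic = alle, diag = diag, K = K)
  })

  az <- stage("autozyg", {
    case_ids <- qc$samples$sample_id[qc$samples$phenotype == "case"]
    if (!length(case_ids)) stop("no cases survived QC")
    segs <- find_shared_homozygous_segments(
      subset_samples(qc$genotypes, case_ids),
      min_markers = cfg$autozyg_min_markers,
      max_missing_fraction = cfg$autozyg_max_missing_fraction)
    if (!length(segs)) stop("no shared homozygous segment found")
    segs <- rank_segments(segs, scan$lmm)
    ci <- critical_interval(segs[[1L]], qc$genotypes$markers)
    write_report(segments_table(segs), pth("segments.tsv"))
    write_bed(ci, pth("critical_interval.bed"))
    list(segments = segs, interval = ci)
  })

  casc <- stage("filter", {
    rep <- run_cascade(study$case_variants, study$panel, az$interval, study$transcript)
    write_report(rep, pth("filter_report.tsv"))
    write_report(attr(rep, "annotations"), pth("annotations.tsv"))
    rep
  })

  assoc <- stage("assoc", {
    surv <- attr(casc, "survivors")[[5L]]
    if (!length(surv)) stop("cascade left no protein-changing candidate")
    key <- strsplit(surv[1L], ":", fixed = TRUE)[[1L]]
    calls <- genotype_cohort_at(study, key[1L], as.numeric(key[2L]))
    tab <- tabulate_genotypes(calls, study$samples)
    res <- test_variant(tab, cfg$assoc_coding)
    write_report(tab, pth("genotype_counts.tsv"))
    write_report(data.frame(candidate = surv[1L], coding = res$coding,
                            p_value = res$p_value, odds_ratio = res$odds_ratio,
                            or_corrected = res$or_corrected), pth("assoc_exact.tsv"))
    list(candidate = surv[1L], result = res)
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "autozygmap",
    version = as.character(utils::packageVersion("autozygmap")),
    seed = cfg$sim$seed,
    n_markers_after_qc = scan$diag$n_markers_after_qc,
    n_samples_after_qc = scan$diag$n_samples_after_qc,
    lambda_before = scan$diag$lambda_before,
    lambda_after = scan$diag$lambda_after,
    top_segment = list(chrom = az$segments[[1L]]$chrom,
                       interval_start = az$interval$start,
                       interval_end = az$interval$end),
    cascade_counts = as.list(stats::setNames(casc$n_variants, paste0("step", casc$step))),
    candidate = assoc$candidate,
    assoc_p = assoc$result$p_value,
    files = as.list(stats::setNames(unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
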