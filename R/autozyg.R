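#' Detect shared homozygous segments across cases
#'
#' Finds, per chromosome, the maximal runs of consecutive markers at which
#' every case is homozygous and all cases carry the same allele. A marker with
#' missing calls in at most `max_missing_fraction` of the cases and no
#' discordant non-missing call is segment-compatible (missingness cannot prove
#' discordance). Runs shorter than `min_markers` are dropped. This is the
#' computational form of scanning a case genotype spreadsheet for a shared
#' homozygous haplotype.
#'
#' @param g a [genotype_matrix] restricted to the cases.
#' @param min_markers minimum run length in markers (default 25, to suppress
#'   chance runs).
#' @param max_missing_fraction maximum fraction of cases allowed to be missing
#'   at a segment-compatible marker (default 0.2).
#' @return list of `shared_segment` objects, per chromosome in position
#'   order. Each has the chromosome, global first/last marker indices into the
#'   marker map, marker count, boundary positions, the shared allele dosage at
#'   each in-segment marker, and per-case counts of homozygous-concordant
#'   markers.
#' @export
find_shared_homozygous_segments <- function(g, min_markers = 25, max_missing_fraction = 0.2) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_case <- length(g$samples)
  if (n_case == 0L) stop("at least one case is required")
  calls <- g$calls
  n_miss <- colSums(is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  compatible <- n_het == 0L & pmin(n0, n2) == 0L &
    n_miss / n_case <= max_missing_fraction
  shared <- ifelse(n0 > 0L, 0L, ifelse(n2 > 0L, 2L, NA_integer_))

  segs <- list()
  for (ch in unique(g$markers$chrom)) {
    idx <- which(g$markers$chrom == ch)
    r <- rle(compatible[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_markers)) {
      run <- idx[starts[k]:ends[k]]
      support <- rowSums(calls[, run, drop = FALSE] ==
                           matrix(shared[run], n_case, length(run), byrow = TRUE),
                         na.rm = TRUE)
      names(support) <- g$samples
      segs[[length(segs) + 1L]] <- structure(
        list(chrom = ch,
             first_marker_index = run[1L],
             last_marker_index = run[length(run)],
             n_markers = length(run),
             start_pos = g$markers$pos[run[1L]],
             end_pos = g$markers$pos[run[length(run)]],
             shared_allele = shared[run],
             support = support),
        class = "shared_segment")
    }
  }
  segs
}

#' @export
print.shared_segment <- function(x, ...) {
  cat(sprintf("shared_segment %s:%s-%s (%d markers)\n", x$chrom,
              format(x$start_pos, big.mark = ",", scientific = FALSE),
              format(x$end_pos, big.mark = ",", scientific = FALSE), x$n_markers))
  invisible(x)
}

#' Critical interval of a shared segment
#'
#' The interval between the first flanking discordant (e.g. heterozygous)
#' markers on either side of the homozygous segment: its start is the position
#' of the nearest marker left of the segment on the same chromosome (the
#' chromosome's first marker position if the segment reaches the chromosome
#' start), and symmetrically on the right. The interval is closed and includes
#' the flanking marker positions, because those positions are what delimit
#' the region that must contain a recessive causal variant.
#'
#' @param segment a `shared_segment` from [find_shared_homozygous_segments()].
#' @param map the [marker_map] the segment indices refer to.
#' @return a [genome_interval].
#' @export
critical_interval <- function(segment, map) {
  stopifnot(inherits(segment, "shared_segment"), inherits(map, "marker_map"))
  i1 <- segment$first_marker_index; i2 <- segment$last_marker_index
  if (i1 < 1L || i2 > nrow(map) || i1 > i2) stop("segment indices out of range for this map")
  if (map$chrom[i1] != segment$chrom || map$chrom[i2] != segment$chrom)
    stop("segment indices do not lie on chromosome ", segment$chrom)
  on_chr <- which(map$chrom == segment$chrom)
  left <- if (i1 > min(on_chr)) map$pos[i1 - 1L] else map$pos[min(on_chr)]
  right <- if (i2 < max(on_chr)) map$pos[i2 + 1L] else map$pos[max(on_chr)]
  genome_interval(segment$chrom, left, right)
}

#' Rank shared segments by association evidence
#'
#' Orders segments by the best (smallest) mixed-model p-value among the
#' markers they contain, breaking ties by marker count (more first) and then
#' by genomic position. The order is invariant to the input order.
#'
#' @param segments list of `shared_segment` objects.
#' @param assoc an `assoc_result` data frame over the same marker universe.
#' @return the reordered list of segments, each with a `best_p` element added.
#' @export
rank_segments <- function(segments, assoc) {
  if (!length(segments)) return(segments)
  best <- vapply(segments, function(s) {
    sel <- assoc$chrom == s$chrom & assoc$pos >= s$start_pos & assoc$pos <= s$end_pos
    if (!any(sel)) Inf else min(assoc$p[sel], na.rm = TRUE)
  }, numeric(1))
  segments <- Map(function(s, b) { s$best_p <- b; s }, segments, best)
  o <- order(best,
             -vapply(segments, `[[`, numeric(1), "n_markers"),
             vapply(segments, `[[`, character(1), "chrom"),
             vapply(segments, `[[`, numeric(1), "start_pos"))
  segments[o]
}

#' Tabular summary of shared segments
#' @param segments list of `shared_segment` objects.
#' @return data frame, one row per segment.
#' @export
segments_table <- function(segments) {
  if (!length(segments))
    return(data.frame(chrom = character(), start_pos = numeric(), end_pos = numeric(),
                      n_markers = integer(), best_p = numeric()))
  data.frame(
    chrom = vapply(segments, `[[`, character(1), "chrom"),
    start_pos = vapply(segments, `[[`, numeric(1), "start_pos"),
    end_pos = vapply(segments, `[[`, numeric(1), "end_pos"),
    n_markers = vapply(segments, function(s) as.integer(s$n_markers), integer(1)),
    best_p = vapply(segments, function(s) if (is.null(s$best_p)) NA_real_ else s$best_p,
                    numeric(1)),
    stringsAsFactors = FALSE)
}
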