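#' Remove annotated junctions and candidates in polymorphic regions
#'
#' Drops candidates whose junction exactly matches a canonical intron (both
#' boundaries) and candidates whose intron overlaps a blacklist interval
#' (e.g. the HLA locus). Junctions sharing only one boundary with an
#' annotated intron are retained — exon extension and shrinkage events
#' necessarily share one boundary with the canonical junction.
#'
#' @param candidates Candidate tibble (see [find_candidates()]).
#' @param annotation An `annotation_index`.
#' @param blacklist Optional tibble of 1-based closed intervals with
#'   `chrom`, `start`, `end` (see [read_blacklist_bed()]).
#' @return Filtered candidate tibble.
#' @export
filter_known_and_polymorphic <- function(candidates, annotation, blacklist = NULL) {
  if (nrow(candidates) == 0) return(candidates)
  canon <- annotation$canonical_junctions
  known <- paste(candidates$chrom, candidates$intron_start, candidates$intron_end) %in%
    paste(canon$chrom, canon$intron_start, canon$intron_end)
  in_black <- rep(FALSE, nrow(candidates))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    for (i in seq_len(nrow(blacklist))) {
      b <- blacklist[i, ]
      in_black <- in_black |
        (candidates$chrom == b$chrom &
           candidates$intron_start <= b$end &
           candidates$intron_end >= b$start)
    }
  }
  candidates[!known & !in_black, , drop = FALSE]
}

#' Heuristic junction-allele-fraction filter
#'
#' Removes candidates whose JAF falls strictly below `min_jaf`; a JAF equal
#' to the threshold passes (the published rule filters sites with <5% of
#' reads supporting the junction).
#'
#' @param candidates Candidate tibble with a `jaf` column.
#' @param min_jaf Minimum junction allele fraction.
#' @return Filtered candidate tibble.
#' @export
jaf_filter <- function(candidates, min_jaf = 0.05) {
  if (nrow(candidates) == 0) return(candidates)
  stopifnot("jaf" %in% names(candidates))
  candidates[candidates$jaf >= min_jaf, , drop = FALSE]
}

#' Binomial proportion-test filter with FDR correction
#'
#' For each candidate, computes the exact one-sided binomial upper-tail
#' p-value of observing at least the supporting-read count at the site's
#' depth under a null junction allele fraction, BH-corrects across the
#' candidate set, and retains candidates with `q_value <= alpha`.
#'
#' @param candidates Candidate tibble with `n_supporting_reads` and
#'   `depth_at_site` columns (depth > 0).
#' @param null_jaf Null junction allele fraction in (0, 1).
#' @param alpha FDR threshold.
#' @return Filtered tibble with `p_value` and `q_value` columns set.
#' @export
proportion_test_filter <- function(candidates, null_jaf = 0.05, alpha = 0.05) {
  if (null_jaf <= 0 || null_jaf >= 1) {
    stop("null_jaf must lie in (0, 1)", call. = FALSE)
  }
  if (nrow(candidates) == 0) {
    candidates$p_value <- numeric(0)
    candidates$q_value <- numeric(0)
    return(candidates)
  }
  stopifnot(all(c("n_supporting_reads", "depth_at_site") %in% names(candidates)),
            all(candidates$depth_at_site > 0))
  candidates$p_value <- binomial_upper_p(candidates$n_supporting_reads,
                                         candidates$depth_at_site, null_jaf)
  candidates$q_value <- bh_fdr(candidates$p_value)
  candidates[candidates$q_value <= alpha, , drop = FALSE]
}

#' Case/control top-fraction test for one junction
#'
#' Passes when strictly fewer than fraction `k` of control samples have a
#' supporting-read count greater than or equal to the case count; ties count
#' against the case.
#'
#' @param case_count Supporting reads in the case sample.
#' @param control_counts Integer vector of supporting-read counts, one per
#'   control sample (zero-filled for controls lacking the junction).
#' @param k Top fraction (default 0.05).
#' @return Logical: `TRUE` when the case stands in the top `k`.
#' @export
case_control_filter <- function(case_count, control_counts, k = 0.05) {
  if (length(control_counts) == 0) {
    stop("the case/control filter requires at least one control sample",
         call. = FALSE)
  }
  mean(control_counts >= case_count) < k
}

#' Supporting-read counts for given junctions in control samples
#'
#' Runs the same junction tally as the case over each control BAM, restricted
#' to the neighbourhood of the queried junctions, and zero-fills junctions a
#' control lacks.
#'
#' @param bams Character vector of control BAM paths (names become control
#'   ids; basenames are used otherwise).
#' @param junctions Tibble with `chrom`, `intron_start`, `intron_end`.
#' @param min_mapq Minimum mapping quality.
#' @param pad Flanking bp added to each junction query region.
#' @return Long tibble: `chrom`, `intron_start`, `intron_end`, `control_id`,
#'   `count`.
#' @export
control_junction_counts <- function(bams, junctions, min_mapq = 20L, pad = 500L) {
  if (length(bams) == 0) {
    stop("the case/control filter requires at least one control sample",
         call. = FALSE)
  }
  ids <- names(bams)
  if (is.null(ids)) ids <- basename(unname(bams))
  junctions <- dplyr::distinct(junctions, .data$chrom, .data$intron_start,
                               .data$intron_end)
  purrr::map2_dfr(unname(bams), ids, function(bam, id) {
    counts <- purrr::pmap_int(
      junctions,
      function(chrom, intron_start, intron_end, ...) {
        tal <- extract_junctions(bam, chrom,
                                 max(1L, intron_start - pad),
                                 intron_end + pad, min_mapq = min_mapq)
        hit <- tal$n_supporting_reads[tal$intron_start == intron_start &
                                        tal$intron_end == intron_end &
                                        tal$chrom == chrom]
        if (length(hit) == 0) 0L else hit[1]
      }
    )
    dplyr::mutate(junctions, control_id = id, count = counts)
  })
}

#' Apply the case/control filter across a candidate table
#'
#' Joins candidates with per-control junction counts (long format, as from
#' [control_junction_counts()] or [read_control_counts()]) and keeps
#' candidates passing [case_control_filter()]. Junctions absent from the
#' control table are treated as zero in every control.
#'
#' @param candidates Candidate tibble with `n_supporting_reads`.
#' @param control_counts Long tibble `chrom`, `intron_start`, `intron_end`,
#'   `control_id`, `count`.
#' @param k Top fraction.
#' @return Filtered tibble with added columns `n_controls` and
#'   `control_ge_case` (number of controls at or above the case count).
#' @export
apply_case_control <- function(candidates, control_counts, k = 0.05) {
  if (nrow(candidates) == 0) {
    candidates$n_controls <- integer(0)
    candidates$control_ge_case <- integer(0)
    return(candidates)
  }
  ids <- unique(control_counts$control_id)
  if (length(ids) == 0) {
    stop("the case/control filter requires at least one control sample",
         call. = FALSE)
  }
  res <- candidates
  res$n_controls <- length(ids)
  res$control_ge_case <- vapply(seq_len(nrow(res)), function(i) {
    cc <- control_counts[control_counts$chrom == res$chrom[i] &
                           control_counts$intron_start == res$intron_start[i] &
                           control_counts$intron_end == res$intron_end[i], ]
    counts <- stats::setNames(rep(0L, length(ids)), ids)
    counts[cc$control_id] <- cc$count
    sum(counts >= res$n_supporting_reads[i])
  }, integer(1))
  res[res$control_ge_case / res$n_controls < k, , drop = FALSE]
}
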