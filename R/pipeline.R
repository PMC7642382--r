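#' Partition mutations into batches
#'
#' Order-preserving split into consecutive batches of `batch_size` rows
#' (the last batch may be smaller), mirroring the MAF-splitting step used to
#' parallelise processing.
#'
#' @param mutations Mutation tibble.
#' @param batch_size Rows per batch (>= 1).
#' @return List of tibbles.
#' @export
chunk_mutations <- function(mutations, batch_size = 200L) {
  stopifnot(batch_size >= 1)
  n <- nrow(mutations)
  if (n == 0) return(list())
  idx <- ceiling(seq_len(n) / batch_size)
  unname(lapply(split(seq_len(n), idx),
                function(i) mutations[i, , drop = FALSE]))
}

#' Automated review of a final event
#'
#' Machine proxy for the manual review step: an event fails when its
#' junction support falls below `config$min_supporting_reads`, or when the
#' mutation is spliced in but fewer than `config$min_spliced_in_fraction` of
#' the mutation-covering junction reads carry the alternate allele.
#'
#' @param n_supporting_reads Junction-supporting read count.
#' @param spliced_in Whether the mutation lies in the retained segment.
#' @param spliced_in_fraction Mutant fraction among covering junction reads
#'   (NA when indeterminate).
#' @param config A [splice_config()].
#' @return Tibble with `review_pass` (logical) and `review_reason`
#'   (`"ok"`, `"support<M"`, `"spliced_in<min"`).
#' @export
auto_review <- function(n_supporting_reads, spliced_in, spliced_in_fraction,
                        config = splice_config()) {
  n <- length(n_supporting_reads)
  reason <- rep("ok", n)
  low_support <- n_supporting_reads < config$min_supporting_reads
  reason[low_support] <- "support<M"
  low_frac <- !low_support & spliced_in & !is.na(spliced_in_fraction) &
    spliced_in_fraction < config$min_spliced_in_fraction
  reason[low_frac] <- "spliced_in<min"
  tibble::tibble(review_pass = reason == "ok", review_reason = reason)
}

#' Run the mutation-induced splicing discovery pipeline
#'
#' Full orchestration: junction discovery around each non-coding mutation,
#' known-junction/blacklist removal, coverage/JAF filtering (heuristic or
#' binomial proportion-test mode), case/control comparison, spliced-in
#' evidence, splice-site scoring, seven-way event classification and
#' automated review. Deterministic given its inputs and configuration.
#'
#' @param maf Path to a MAF file, or a mutation tibble as from
#'   [read_maf_noncoding()].
#' @param bam Path to the case sample's indexed BAM.
#' @param controls Either a character vector of control BAM paths (named by
#'   control id) or a long control-count tibble / TSV path (see
#'   [read_control_counts()]). At least one control is required.
#' @param gtf Path to a GTF, or an `annotation_index`.
#' @param fasta Path to the indexed reference FASTA.
#' @param blacklist Optional BED path or interval tibble of polymorphic
#'   regions to exclude.
#' @param config A [splice_config()].
#' @param models Optional list with `donor` and `acceptor`
#'   `splice_site_model`s; by default models are trained from the supplied
#'   annotation when it has enough canonical junctions, otherwise scores are
#'   `NA`.
#' @param threads Parallel workers over mutation batches (forked; results
#'   are identical to serial execution).
#' @return Object of class `"splice_run"`: list with `events` (final
#'   reviewed event tibble), `stage_counts` (candidate counts through the
#'   filter cascade), `config`, `n_mutations`.
#' @importFrom parallel mclapply
#' @export
run_pipeline <- function(maf, bam, controls, gtf, fasta, blacklist = NULL,
                         config = splice_config(), models = NULL,
                         threads = 1L) {
  mutations <- if (is.character(maf)) read_maf_noncoding(maf) else
    tibble::as_tibble(maf)
  annotation <- if (inherits(gtf, "annotation_index")) gtf else
    build_annotation_index(gtf)
  genome <- Rsamtools::FaFile(fasta)
  if (is.character(blacklist)) blacklist <- read_blacklist_bed(blacklist)

  if (is.null(models)) {
    models <- list(donor = NULL, acceptor = NULL)
    if (nrow(annotation$canonical_junctions) >= 50) {
      models$donor <- tryCatch(
        train_site_model(annotation, genome, "donor"), error = function(e) NULL)
      models$acceptor <- tryCatch(
        train_site_model(annotation, genome, "acceptor"), error = function(e) NULL)
    }
  }

  stage <- function(name, n) tibble::tibble(stage = name, n_candidates = n)

  empty_run <- function() {
    structure(list(
      events = tibble::tibble(),
      stage_counts = stage("discovery", 0L),
      config = config, n_mutations = nrow(mutations)
    ), class = "splice_run")
  }
  if (nrow(mutations) == 0) return(empty_run())

  pad <- config$window + 500L
  discover_one <- function(mut) {
    tal <- extract_junctions(bam, mut$chrom, mut$pos - pad, mut$pos + pad,
                             min_mapq = config$min_mapq)
    cand <- find_candidates(mut, tal, annotation, config)
    if (nrow(cand) == 0) return(NULL)
    cand$tally <- list(tal)
    cand
  }
  batches <- chunk_mutations(mutations, config$batch_size)
  run_batch <- function(b) {
    dplyr::bind_rows(lapply(seq_len(nrow(b)), function(i) {
      discover_one(b[i, , drop = FALSE])
    }))
  }
  candidates <- if (threads > 1L) {
    dplyr::bind_rows(parallel::mclapply(batches, run_batch,
                                        mc.cores = threads))
  } else {
    dplyr::bind_rows(lapply(batches, run_batch))
  }
  counts <- stage("discovery", nrow(candidates))
  if (nrow(candidates) == 0) {
    out <- empty_run(); out$stage_counts <- counts; return(out)
  }

  # module 2: known junctions and polymorphic regions
  candidates <- filter_known_and_polymorphic(candidates, annotation, blacklist)
  counts <- dplyr::bind_rows(counts, stage("known_polymorphic", nrow(candidates)))
  if (nrow(candidates) == 0) {
    out <- empty_run(); out$stage_counts <- counts; return(out)
  }

  # depth and JAF at the exonic base flanking the mutated boundary
  candidates$assessed_pos <- flanking_exonic_base(
    candidates$pos, candidates$intron_start, candidates$intron_end)
  candidates$depth_at_site <- vapply(seq_len(nrow(candidates)), function(i) {
    as.integer(site_depth(bam, candidates$chrom[i], candidates$assessed_pos[i],
                          min_mapq = config$min_mapq))
  }, integer(1))
  candidates$jaf <- compute_jaf(
    pmin(candidates$n_supporting_reads, candidates$depth_at_site),
    candidates$depth_at_site)

  # module 3: coverage/JAF
  candidates <- if (config$mode == "heuristic") {
    jaf_filter(candidates, config$min_jaf)
  } else {
    ok <- candidates$depth_at_site > 0
    proportion_test_filter(candidates[ok, , drop = FALSE],
                           config$null_jaf, config$alpha)
  }
  counts <- dplyr::bind_rows(counts, stage("coverage_jaf", nrow(candidates)))
  if (nrow(candidates) == 0) {
    out <- empty_run(); out$stage_counts <- counts; return(out)
  }

  # module 4: case/control
  control_counts <- if (is.character(controls) &&
                        all(file.exists(controls))) {
    control_junction_counts(controls, candidates, min_mapq = config$min_mapq)
  } else if (is.character(controls)) {
    read_control_counts(controls)
  } else {
    tibble::as_tibble(controls)
  }
  candidates <- apply_case_control(candidates, control_counts,
                                   config$control_top_fraction)
  counts <- dplyr::bind_rows(counts, stage("case_control", nrow(candidates)))
  if (nrow(candidates) == 0) {
    out <- empty_run(); out$stage_counts <- counts; return(out)
  }

  # spliced-in evidence, strand, scores, classification
  extra <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    sif <- spliced_in_fraction(bam, cand$chrom, cand$pos, cand$ref_allele,
                               cand$alt_allele, cand$intron_start,
                               cand$intron_end, min_mapq = config$min_mapq)
    strand <- junction_strand(genome, cand$chrom, cand$intron_start,
                              cand$intron_end)
    sq <- candidate_site_sequences(genome, cand$chrom, cand$pos,
                                   cand$ref_allele, cand$alt_allele,
                                   cand$intron_start, cand$intron_end,
                                   strand)
    model <- models[[sq$site_type]]
    scores <- if (!is.null(model)) {
      score_site_pair(model, sq$ref_seq, sq$mut_seq)
    } else {
      tibble::tibble(ref_score = NA_real_, mut_score = NA_real_,
                     delta = NA_real_)
    }
    ev <- classify_event(cand, cand$tally[[1]], annotation, config,
                         genome = genome, model = models$donor,
                         strand = strand)
    tibble::tibble(
      strand = strand,
      spliced_in = sif$spliced_in,
      spliced_in_fraction = sif$fraction,
      site_type = sq$site_type, ref_seq = sq$ref_seq, mut_seq = sq$mut_seq,
      ref_score = scores$ref_score, mut_score = scores$mut_score,
      delta_score = scores$delta
    ) |> dplyr::bind_cols(ev)
  })
  events <- dplyr::bind_cols(
    dplyr::select(candidates, -"tally"),
    dplyr::bind_rows(extra)
  )

  review <- auto_review(events$n_supporting_reads, events$spliced_in,
                        events$spliced_in_fraction, config)
  events <- dplyr::bind_cols(events, review)
  events <- events[events$review_pass, , drop = FALSE]
  counts <- dplyr::bind_rows(counts, stage("auto_review", nrow(events)))

  structure(list(events = events, stage_counts = counts, config = config,
                 n_mutations = nrow(mutations)),
            class = "splice_run")
}

#' @export
print.splice_run <- function(x, ...) {
  cat("<splice_run>\n")
  cat(sprintf("  %d mutation(s) screened\n", x$n_mutations))
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-18s %d\n", x$stage_counts$stage[i],
                x$stage_counts$n_candidates[i]))
  }
  invisible(x)
}

#' Final events of a pipeline run
#'
#' @param x A `splice_run`.
#' @param ... Unused.
#' @return The final event tibble (one row per reviewed mutation-junction
#'   pair).
#' @export
tidy.splice_run <- function(x, ...) {
  tibble::as_tibble(x$events)
}

#' One-row pipeline run summary
#'
#' @param x A `splice_run`.
#' @param ... Unused.
#' @return Tibble with mutation count, per-stage candidate counts and the
#'   final event count.
#' @export
glance.splice_run <- function(x, ...) {
  wide <- stats::setNames(as.list(x$stage_counts$n_candidates),
                          x$stage_counts$stage)
  dplyr::bind_cols(tibble::tibble(n_mutations = x$n_mutations),
                   tibble::as_tibble(wide),
                   tibble::tibble(n_events = nrow(x$events)))
}

#' Plot the filter cascade of a pipeline run
#'
#' @param object A `splice_run`.
#' @param ... Unused.
#' @return A ggplot bar chart of candidate counts per stage.
#' @export
autoplot.splice_run <- function(object, ...) {
  df <- object$stage_counts
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_candidates)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_candidates),
                       vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "candidates",
                  title = "Candidate counts through the filter cascade") +
    ggplot2::theme_minimal()
}

#' Write final events to a TSV
#'
#' @param run A `splice_run` (or event tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(run, path) {
  events <- if (inherits(run, "splice_run")) run$events else run
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
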