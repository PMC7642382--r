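SPLICE_EVENT_CATEGORIES <- c("new_exon_first", "new_exon_middle",
                             "new_exon_last", "exon_extension",
                             "exon_shrinkage", "exon_splitting", "fusion",
                             "new_transcript", "complex")

# Annotation context of a genomic position: host genes, whether it falls in
# an annotated exon, in an intron (inside a transcript span but not an exon).
.position_context <- function(chrom, b, annotation) {
  ex <- annotation$exons
  tr <- annotation$transcripts
  in_exon_rows <- ex$chrom == chrom & ex$start <= b & ex$end >= b
  in_span <- tr$chrom == chrom & tr$start <= b & tr$end >= b
  genes <- unique(c(ex$gene_id[in_exon_rows], tr$gene_id[in_span]))
  list(genes = genes,
       in_exon = any(in_exon_rows),
       in_intron = any(in_span) && !any(in_exon_rows))
}

# The annotated intron (from the canonical junction set) containing position b,
# or NULL. When several transcripts imply different introns, the smallest
# containing intron is used.
.host_intron <- function(chrom, b, annotation) {
  jx <- annotation$canonical_junctions
  hit <- jx[jx$chrom == chrom & jx$intron_start <= b & jx$intron_end >= b, ]
  if (nrow(hit) == 0) return(NULL)
  hit[which.min(hit$intron_end - hit$intron_start), ]
}

#' Find the activated mate site pairing with a primary splice site
#'
#' A mutation-created primary splice site (PSS) junction has one boundary at
#' a canonical exon edge and one novel boundary inside the annotated intron.
#' A new exon requires a partner junction sharing the intron's other
#' canonical edge, with its own novel boundary inside the same intron, at
#' least `config$min_supporting_reads` supporting reads, and an enclosed
#' interval within the plausible exon-size bounds. When several partners
#' qualify, the one with most supporting reads wins; count ties are broken
#' by splice-site model score (when a model is supplied), then by genomic
#' position.
#'
#' @param chrom Chromosome.
#' @param intron_start,intron_end The PSS junction's intron.
#' @param co_junctions Junction tally near the candidate (tibble with
#'   `chrom`, `intron_start`, `intron_end`, `n_supporting_reads`).
#' @param annotation An `annotation_index`.
#' @param config A [splice_config()].
#' @param genome Optional FASTA (for score tie-breaks).
#' @param model Optional `splice_site_model` used for tie-breaks.
#' @return `NULL` when no partner qualifies, else a list with `ams_pos`,
#'   `ams_junction` (one-row tibble), `new_exon_start`, `new_exon_end`.
#' @export
locate_activated_mate <- function(chrom, intron_start, intron_end,
                                  co_junctions, annotation,
                                  config = splice_config(),
                                  genome = NULL, model = NULL) {
  canon <- annotation$canonical_junctions
  can_s <- intron_start %in% canon$intron_start[canon$chrom == chrom]
  can_e <- intron_end %in% canon$intron_end[canon$chrom == chrom]
  if (can_s == can_e) return(NULL) # needs exactly one canonical edge
  novel_b <- if (can_s) intron_end else intron_start
  host <- .host_intron(chrom, novel_b, annotation)
  if (is.null(host)) return(NULL)

  co <- co_junctions[co_junctions$chrom == chrom &
                       co_junctions$n_supporting_reads >=
                       config$min_supporting_reads, , drop = FALSE]
  if (can_s) {
    # PSS skips from the intron's donor edge; new exon starts at intron_end+1.
    # Partner: novel donor inside the intron, acceptor at the host intron end.
    part <- co[co$intron_end == host$intron_end &
                 co$intron_start > intron_end + 1L &
                 co$intron_start <= host$intron_end, , drop = FALSE]
    if (nrow(part) == 0) return(NULL)
    part$new_exon_start <- intron_end + 1L
    part$new_exon_end <- part$intron_start - 1L
    part$ams_pos <- part$intron_start
  } else {
    part <- co[co$intron_start == host$intron_start &
                 co$intron_end < intron_start - 1L &
                 co$intron_end >= host$intron_start, , drop = FALSE]
    if (nrow(part) == 0) return(NULL)
    part$new_exon_start <- part$intron_end + 1L
    part$new_exon_end <- intron_start - 1L
    part$ams_pos <- part$intron_end
  }
  len <- part$new_exon_end - part$new_exon_start + 1L
  part <- part[len >= config$new_exon_size[1] &
                 len <= config$new_exon_size[2], , drop = FALSE]
  if (nrow(part) == 0) return(NULL)

  score <- rep(0, nrow(part))
  if (!is.null(model) && !is.null(genome)) {
    score <- vapply(seq_len(nrow(part)), function(i) {
      boundary <- part$ams_pos[i]
      st <- if (can_s) "donor" else "acceptor"
      s <- try(extract_site_sequence(genome, chrom, boundary, st, "+"),
               silent = TRUE)
      if (inherits(s, "try-error")) 0 else score_sequence(model, s)
    }, numeric(1))
  }
  ord <- order(-part$n_supporting_reads, -score, part$ams_pos)
  best <- part[ord[1], ]
  list(ams_pos = best$ams_pos,
       ams_junction = best[, c("chrom", "intron_start", "intron_end",
                               "n_supporting_reads")],
       new_exon_start = best$new_exon_start,
       new_exon_end = best$new_exon_end)
}

#' Frame impact of an inserted exon
#'
#' For a new exon inserted inside the CDS of a transcript: a frameshift when
#' the inserted length is not a multiple of three, and a premature stop when
#' the inserted sequence, read in the CDS frame at the insertion point,
#' contains an in-frame stop codon.
#'
#' @param genome FASTA (`FaFile` or path).
#' @param chrom Chromosome.
#' @param new_exon_start,new_exon_end Inserted exon interval (1-based).
#' @param annotation `annotation_index` with CDS records.
#' @param strand Transcript strand.
#' @return List with `frameshift` and `premature_stop` (both `NA` with a
#'   warning when no CDS annotation brackets the insertion).
#' @export
frame_impact <- function(genome, chrom, new_exon_start, new_exon_end,
                         annotation, strand = "+") {
  len <- new_exon_end - new_exon_start + 1L
  cds <- annotation$cds
  cds <- cds[cds$chrom == chrom, , drop = FALSE]
  brackets <- nrow(cds) > 0 &&
    min(cds$start) < new_exon_start && max(cds$end) > new_exon_end
  if (!brackets) {
    warning("no CDS annotation brackets the inserted exon; frame impact unknown")
    return(list(frameshift = NA, premature_stop = NA))
  }
  frameshift <- (len %% 3L) != 0L
  ins <- .fetch_seq(genome, chrom, new_exon_start, new_exon_end)
  if (strand == "-") {
    ins <- .revcomp(ins)
    upstream <- sum(pmax(
      0L, cds$end[cds$start > new_exon_end] - cds$start[cds$start > new_exon_end] + 1L))
  } else {
    upstream <- sum(pmax(
      0L, cds$end[cds$end < new_exon_start] - cds$start[cds$end < new_exon_start] + 1L))
  }
  phase <- upstream %% 3L
  skip <- (3L - phase) %% 3L
  premature_stop <- FALSE
  i <- skip + 1L
  while (i + 2L <= nchar(ins)) {
    codon <- substr(ins, i, i + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      premature_stop <- TRUE
      break
    }
    i <- i + 3L
  }
  list(frameshift = frameshift, premature_stop = premature_stop)
}

#' Classify a candidate junction into the seven-way event taxonomy
#'
#' Assigns exactly one category to every candidate: `exon_extension` /
#' `exon_shrinkage` (one canonical boundary, novel boundary in the intron /
#' exon), `new_exon_first|middle|last` (a primary splice site paired with an
#' activated mate site bounding an internal exon inside one annotated
#' intron), `exon_splitting` (both boundaries inside one annotated exon),
#' `fusion` (boundaries in two different genes), `new_transcript` (junction
#' outside annotated transcripts), and `complex` for combinations of
#' elementary signatures.
#'
#' @param candidate One-row candidate tibble (`chrom`, `pos`,
#'   `intron_start`, `intron_end`, plus mutation columns).
#' @param co_junctions Junction tally near the candidate (for mate search).
#' @param annotation An `annotation_index`.
#' @param config A [splice_config()].
#' @param genome Optional FASTA for frame impact and score tie-breaks.
#' @param model Optional `splice_site_model` for mate-site tie-breaks.
#' @param strand Junction strand (`"+"`, `"-"` or `"unknown"`).
#' @return One-row tibble: `category`, `pss_pos`, `pss_site_type`,
#'   `ams_pos`, `new_exon_start`, `new_exon_end`, `new_exon_length`,
#'   `frameshift`, `premature_stop`, `gene_ids` (comma-separated).
#' @export
classify_event <- function(candidate, co_junctions, annotation,
                           config = splice_config(), genome = NULL,
                           model = NULL, strand = "+") {
  stopifnot(nrow(candidate) == 1)
  chrom <- candidate$chrom
  cs <- candidate$intron_start
  ce <- candidate$intron_end
  pos <- candidate$pos
  canon <- annotation$canonical_junctions
  can_s <- cs %in% canon$intron_start[canon$chrom == chrom]
  can_e <- ce %in% canon$intron_end[canon$chrom == chrom]
  ctx_s <- .position_context(chrom, cs, annotation)
  ctx_e <- .position_context(chrom, ce, annotation)
  genes <- unique(c(ctx_s$genes, ctx_e$genes))

  # PSS = boundary nearest the mutation
  d_start <- min(abs(pos - cs), abs(pos - (cs - 1L)))
  d_end <- min(abs(pos - ce), abs(pos - (ce + 1L)))
  pss_pos <- if (d_start <= d_end) cs else ce
  eff_strand <- if (strand %in% c("+", "-")) strand else "+"
  pss_site_type <- if ((pss_pos == cs) == (eff_strand == "+")) "donor" else "acceptor"

  ams_pos <- NA_integer_
  nx_start <- NA_integer_; nx_end <- NA_integer_
  category <- NULL

  if (can_s && can_e) {
    category <- "complex" # both edges canonical but the pair is novel
  } else if (xor(can_s, can_e)) {
    novel_b <- if (can_s) ce else cs
    novel_ctx <- if (can_s) ctx_e else ctx_s
    canon_ctx <- if (can_s) ctx_s else ctx_e
    cross_gene <- length(novel_ctx$genes) > 0 && length(canon_ctx$genes) > 0 &&
      length(intersect(novel_ctx$genes, canon_ctx$genes)) == 0
    if (cross_gene) {
      category <- "fusion"
    } else if (novel_ctx$in_intron) {
      mate <- locate_activated_mate(chrom, cs, ce, co_junctions, annotation,
                                    config, genome = genome, model = model)
      if (!is.null(mate)) {
        ams_pos <- mate$ams_pos
        nx_start <- mate$new_exon_start
        nx_end <- mate$new_exon_end
        category <- .new_exon_position(chrom, nx_start, nx_end, genes,
                                       annotation)
      } else {
        category <- "exon_extension"
      }
    } else if (novel_ctx$in_exon) {
      category <- "exon_shrinkage"
    } else {
      category <- "new_transcript"
    }
  } else {
    if (length(ctx_s$genes) == 0 && length(ctx_e$genes) == 0) {
      category <- "new_transcript"
    } else if (length(ctx_s$genes) > 0 && length(ctx_e$genes) > 0 &&
               length(intersect(ctx_s$genes, ctx_e$genes)) == 0) {
      category <- "fusion"
    } else if (ctx_s$in_exon && ctx_e$in_exon &&
               .same_exon(chrom, cs, ce, annotation)) {
      category <- "exon_splitting"
    } else {
      category <- "complex"
    }
  }

  frameshift <- NA; premature_stop <- NA
  if (!is.na(nx_start) && !is.null(genome) && nrow(annotation$cds) > 0) {
    fi <- suppressWarnings(
      frame_impact(genome, chrom, nx_start, nx_end, annotation, eff_strand))
    frameshift <- fi$frameshift
    premature_stop <- fi$premature_stop
  }

  tibble::tibble(
    category = category,
    pss_pos = pss_pos,
    pss_site_type = pss_site_type,
    ams_pos = ams_pos,
    new_exon_start = nx_start,
    new_exon_end = nx_end,
    new_exon_length = if (is.na(nx_start)) NA_integer_ else
      nx_end - nx_start + 1L,
    frameshift = frameshift,
    premature_stop = premature_stop,
    gene_ids = paste(genes, collapse = ",")
  )
}

.same_exon <- function(chrom, cs, ce, annotation) {
  ex <- annotation$exons
  any(ex$chrom == chrom & ex$start <= cs & ex$end >= ce)
}

# first/middle/last placement of a new exon relative to the host gene's
# coding span (longest transcript of the host gene; middle when no CDS).
.new_exon_position <- function(chrom, nx_start, nx_end, genes, annotation) {
  cds <- annotation$cds
  cds <- cds[cds$chrom == chrom & cds$gene_id %in% genes, , drop = FALSE]
  if (nrow(cds) == 0) return("new_exon_middle")
  if (nx_end < min(cds$start)) return("new_exon_first")
  if (nx_start > max(cds$end)) return("new_exon_last")
  "new_exon_middle"
}
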