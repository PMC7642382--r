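.bam_flags <- function() {
  Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                         isDuplicate = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isNotPassingQualityControls = FALSE)
}

.read_alignments <- function(bam, chrom, start, end, min_mapq) {
  bf <- if (inherits(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  hdr_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!chrom %in% hdr_chroms) {
    stop(sprintf("chromosome '%s' absent from alignment header", chrom),
         call. = FALSE)
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(max(1L, start), end))
  param <- Rsamtools::ScanBamParam(flag = .bam_flags(),
                                   mapqFilter = min_mapq, which = which)
  GenomicAlignments::readGAlignments(bf, param = param)
}

#' Extract splice junctions from spliced alignments in a region
#'
#' Tallies the introns implied by CIGAR skip (`N`) operations of reads
#' overlapping `chrom:start-end`, one tally per read per skip. Reads flagged
#' secondary, supplementary, duplicate or QC-fail are excluded, as are reads
#' below `min_mapq`. Junctions are keyed by their first and last intronic
#' base, 1-based inclusive.
#'
#' @param bam Path to an indexed BAM file (or a `BamFile`).
#' @param chrom,start,end Query region (1-based closed).
#' @param min_mapq Minimum mapping quality.
#' @return Tibble with `chrom`, `intron_start`, `intron_end`,
#'   `n_supporting_reads`, sorted by position.
#' @export
extract_junctions <- function(bam, chrom, start, end, min_mapq = 20L) {
  gal <- .read_alignments(bam, chrom, start, end, min_mapq)
  if (length(gal) == 0) {
    return(tibble::tibble(chrom = character(), intron_start = integer(),
                          intron_end = integer(),
                          n_supporting_reads = integer()))
  }
  j <- unlist(GenomicAlignments::junctions(gal), use.names = FALSE)
  if (length(j) == 0) {
    return(tibble::tibble(chrom = character(), intron_start = integer(),
                          intron_end = integer(),
                          n_supporting_reads = integer()))
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(j)),
    intron_start = GenomicRanges::start(j),
    intron_end = GenomicRanges::end(j)
  ) |>
    dplyr::count(.data$chrom, .data$intron_start, .data$intron_end,
                 name = "n_supporting_reads") |>
    dplyr::arrange(.data$intron_start, .data$intron_end)
}

#' Read depth of aligned bases at a genomic position
#'
#' Counts reads (after the standard flag and mapping-quality filters) with an
#' aligned base at `pos`. Reads spliced across `pos` (the position falls in a
#' CIGAR `N` gap) do not cover it and are not counted.
#'
#' @inheritParams extract_junctions
#' @param pos 1-based position.
#' @return Integer read count.
#' @export
site_depth <- function(bam, chrom, pos, min_mapq = 20L) {
  stopifnot(pos >= 1)
  gal <- .read_alignments(bam, chrom, pos, pos, min_mapq)
  if (length(gal) == 0) return(0L)
  blocks <- GenomicAlignments::grglist(gal)
  target <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  sum(GenomicRanges::countOverlaps(blocks, target) > 0)
}

#' Junction allele fraction
#'
#' Supporting reads over total reads at the assessed location; 0 when depth
#' is 0.
#'
#' @param n_supporting Supporting-read count.
#' @param depth Total read count at the site.
#' @return Fraction in \[0, 1\].
#' @export
compute_jaf <- function(n_supporting, depth) {
  stopifnot(all(n_supporting >= 0), all(depth >= 0))
  if (any(n_supporting > depth)) {
    stop("n_supporting exceeds depth", call. = FALSE)
  }
  ifelse(depth > 0, n_supporting / depth, 0)
}

#' Distance from a position to the nearest junction boundary
#'
#' Minimum absolute distance from `pos` to the four boundary bases of an
#' intron: its first and last intronic base and the two adjacent exonic
#' bases.
#'
#' @param pos Genomic position (vectorised).
#' @param intron_start,intron_end First/last intronic base.
#' @return Integer distance(s) in bp.
#' @export
junction_distance <- function(pos, intron_start, intron_end) {
  pmin(abs(pos - intron_start), abs(pos - (intron_start - 1L)),
       abs(pos - intron_end), abs(pos - (intron_end + 1L)))
}

#' Exonic base flanking the junction boundary nearest a mutation
#'
#' The assessed location for depth/JAF: the exonic base adjacent to whichever
#' intron boundary lies closer to the mutation. This base is present in both
#' the spliced and unspliced isoform, so junction-supporting and exon-only
#' reads both cover it.
#'
#' @inheritParams junction_distance
#' @return Genomic position of the flanking exonic base.
#' @export
flanking_exonic_base <- function(pos, intron_start, intron_end) {
  d_start <- pmin(abs(pos - intron_start), abs(pos - (intron_start - 1L)))
  d_end <- pmin(abs(pos - intron_end), abs(pos - (intron_end + 1L)))
  ifelse(d_start <= d_end, intron_start - 1L, intron_end + 1L)
}

#' Infer the strand of a novel junction from intronic dinucleotides
#'
#' GT..AG implies the plus strand, CT..AC the minus strand; anything else is
#' `"unknown"`.
#'
#' @param genome An open `Rsamtools::FaFile` (or FASTA path).
#' @param chrom Chromosome.
#' @param intron_start,intron_end First/last intronic base.
#' @return One of `"+"`, `"-"`, `"unknown"`.
#' @export
junction_strand <- function(genome, chrom, intron_start, intron_end) {
  fa <- if (inherits(genome, "FaFile")) genome else Rsamtools::FaFile(genome)
  don <- as.character(Biostrings::getSeq(
    fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(intron_start, intron_start + 1L))))
  acc <- as.character(Biostrings::getSeq(
    fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(intron_end - 1L, intron_end))))
  if (don == "GT" && acc == "AG") "+"
  else if (don == "CT" && acc == "AC") "-"
  else "unknown"
}

#' Pair mutations with nearby non-canonical junction candidates
#'
#' For one mutation, retains junctions from a tally (see
#' [extract_junctions()]) with at least `config$min_supporting_reads` reads
#' whose nearest boundary lies within `config$window` bp of the mutation.
#' The canonical flag marks junctions whose both boundaries match an
#' annotated intron.
#'
#' @param mutation One-row tibble with `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `sample_id`.
#' @param junctions Junction tally tibble.
#' @param annotation An `annotation_index`.
#' @param config A [splice_config()].
#' @return Candidate tibble: mutation columns plus `intron_start`,
#'   `intron_end`, `n_supporting_reads`, `distance_bp`, `is_canonical`.
#' @export
find_candidates <- function(mutation, junctions, annotation, config = splice_config()) {
  stopifnot(nrow(mutation) == 1)
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(),
    intron_start = integer(), intron_end = integer(),
    n_supporting_reads = integer(), distance_bp = integer(),
    is_canonical = logical()
  )
  if (nrow(junctions) == 0) return(empty)
  cand <- junctions |>
    dplyr::filter(.data$chrom == mutation$chrom,
                  .data$n_supporting_reads >= config$min_supporting_reads) |>
    dplyr::mutate(distance_bp = junction_distance(mutation$pos,
                                                  .data$intron_start,
                                                  .data$intron_end)) |>
    dplyr::filter(.data$distance_bp <= config$window)
  if (nrow(cand) == 0) return(empty)
  canon <- annotation$canonical_junctions
  cand |>
    dplyr::mutate(
      sample_id = mutation$sample_id,
      pos = mutation$pos,
      ref_allele = mutation$ref_allele,
      alt_allele = mutation$alt_allele,
      is_canonical = paste(.data$chrom, .data$intron_start, .data$intron_end) %in%
        paste(canon$chrom, canon$intron_start, canon$intron_end)
    ) |>
    dplyr::select("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                  "intron_start", "intron_end", "n_supporting_reads",
                  "distance_bp", "is_canonical")
}

# Query-space offset of a reference position within one aligned read.
# Returns NA when the position is deleted, spliced over, or outside the read.
.query_offset_at <- function(read_pos, cigar, target) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  r <- read_pos
  q <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (target >= r && target <= r + len - 1L) return(q + (target - r))
      r <- r + len; q <- q + len
    } else if (op == "I") {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (target >= r && target <= r + len - 1L) return(NA_integer_)
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  NA_integer_
}

#' Mutant-allele fraction among junction-supporting reads (spliced-in check)
#'
#' A mutation is *spliced in* when it lies in the transcribed segment
#' retained by the novel junction (i.e. outside the skipped intron). For
#' spliced-in mutations, this inspects the junction-supporting reads whose
#' aligned span covers the mutated base and returns the fraction carrying
#' the alternate allele — the published pipelines require at least 30%.
#' Returns `spliced_in = FALSE` and `fraction = NA` when the mutation is
#' spliced out, and `fraction = NA` ("indeterminate") for indel alleles or
#' when no junction read covers the base.
#'
#' @param bam Indexed BAM path or `BamFile`.
#' @param chrom,pos,ref_allele,alt_allele The mutation.
#' @param intron_start,intron_end The novel junction's intron.
#' @param min_mapq Minimum mapping quality.
#' @return List with `spliced_in` (logical), `fraction` (numeric or NA),
#'   `n_covering` (junction reads covering the base).
#' @export
spliced_in_fraction <- function(bam, chrom, pos, ref_allele, alt_allele,
                                intron_start, intron_end, min_mapq = 20L) {
  if (pos >= intron_start && pos <= intron_end) {
    return(list(spliced_in = FALSE, fraction = NA_real_, n_covering = 0L))
  }
  if (nchar(ref_allele) != 1 || nchar(alt_allele) != 1 ||
      ref_allele == "-" || alt_allele == "-") {
    return(list(spliced_in = TRUE, fraction = NA_real_, n_covering = 0L))
  }
  bf <- if (inherits(bam, "BamFile")) bam else Rsamtools::BamFile(bam)
  lo <- min(pos, intron_start) - 1000L
  hi <- max(pos, intron_end) + 1000L
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(max(1L, lo), hi))
  param <- Rsamtools::ScanBamParam(
    flag = .bam_flags(), mapqFilter = min_mapq, which = which,
    what = c("pos", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  if (length(res$pos) == 0) {
    return(list(spliced_in = TRUE, fraction = NA_real_, n_covering = 0L))
  }
  n_alt <- 0L
  n_cov <- 0L
  for (i in seq_along(res$pos)) {
    cig <- res$cigar[i]
    if (is.na(cig) || !grepl("N", cig, fixed = TRUE)) next
    ops <- GenomicAlignments::explodeCigarOps(cig)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cig)[[1]]
    r <- res$pos[i]
    supports <- FALSE
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X", "D", "N")) {
        if (ops[k] == "N" && r == intron_start &&
            r + lens[k] - 1L == intron_end) supports <- TRUE
        r <- r + lens[k]
      }
    }
    if (!supports) next
    qoff <- .query_offset_at(res$pos[i], cig, pos)
    if (is.na(qoff)) next
    n_cov <- n_cov + 1L
    base <- substr(as.character(res$seq[[i]]), qoff, qoff)
    if (identical(base, alt_allele)) n_alt <- n_alt + 1L
  }
  frac <- if (n_cov > 0) n_alt / n_cov else NA_real_
  list(spliced_in = TRUE, fraction = frac, n_covering = n_cov)
}
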