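MAF_REQUIRED_COLS <- c("Chromosome", "Start_Position", "Reference_Allele",
                       "Tumor_Seq_Allele2", "Variant_Classification",
                       "Tumor_Sample_Barcode")

#' Default coding classifications excluded from the non-coding search
#'
#' MAF `Variant_Classification` strings treated as coding and removed before
#' junction discovery: splice-site, missense, nonsense, nonstop, in-frame and
#' frameshift indel classes.
#'
#' @return Character vector of classification strings.
#' @export
coding_exclusion_classes <- function() {
  c("Splice_Site", "Missense_Mutation", "Nonsense_Mutation",
    "Nonstop_Mutation", "In_Frame_Del", "In_Frame_Ins",
    "Frame_Shift_Del", "Frame_Shift_Ins")
}

#' Read non-coding somatic mutations from a MAF file
#'
#' Parses a tab-separated MAF and retains records whose
#' `Variant_Classification` is not in `excluded_classes`. Only the six
#' mandatory columns are required; additional columns are ignored, so MC3-
#' and ICGC-style MAFs both parse. Coordinates are 1-based as in MAF.
#'
#' @param path Path to a MAF file (leading `#` comment lines allowed).
#' @param excluded_classes Classifications to drop
#'   (default [coding_exclusion_classes()]).
#' @return Tibble with columns `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `sample_id`, `variant_classification`, `dna_vaf` (NA when the MAF lacks
#'   an `i_VAF`/`dna_vaf` column), in input order. The number of excluded
#'   records is reported via `message()` and attached as attribute
#'   `n_excluded`.
#' @export
read_maf_noncoding <- function(path, excluded_classes = coding_exclusion_classes()) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  missing <- setdiff(MAF_REQUIRED_COLS, names(df))
  if (length(missing) > 0) {
    stop("MAF is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(df$Start_Position))
  bad <- which(is.na(pos) & nzchar(df$Start_Position))
  if (length(bad) > 0) {
    stop(sprintf("unparsable Start_Position at MAF record %d: '%s'",
                 bad[1], df$Start_Position[bad[1]]), call. = FALSE)
  }
  vaf_col <- intersect(c("dna_vaf", "i_VAF", "t_vaf"), names(df))[1]
  out <- tibble::tibble(
    chrom = df$Chromosome,
    pos = as.integer(pos),
    ref_allele = df$Reference_Allele,
    alt_allele = df$Tumor_Seq_Allele2,
    sample_id = df$Tumor_Sample_Barcode,
    variant_classification = df$Variant_Classification,
    dna_vaf = if (is.na(vaf_col)) NA_real_ else
      suppressWarnings(as.numeric(df[[vaf_col]]))
  )
  keep <- !(out$variant_classification %in% excluded_classes)
  n_excluded <- sum(!keep)
  message(sprintf("read_maf_noncoding: %d record(s) retained, %d coding record(s) excluded",
                  sum(keep), n_excluded))
  out <- out[keep, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write mutations back to a minimal MAF
#'
#' Inverse of [read_maf_noncoding()] over the six mandatory columns, so
#' write-then-read round-trips the retained mutation list.
#'
#' @param mutations Tibble as returned by [read_maf_noncoding()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(
    Chromosome = mutations$chrom,
    Start_Position = mutations$pos,
    Reference_Allele = mutations$ref_allele,
    Tumor_Seq_Allele2 = mutations$alt_allele,
    Variant_Classification = mutations$variant_classification,
    Tumor_Sample_Barcode = mutations$sample_id,
    check.names = FALSE
  )
  if (!all(is.na(mutations$dna_vaf))) df$dna_vaf <- mutations$dna_vaf
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an annotation index from exon records
#'
#' Core constructor behind [build_annotation_index()]: takes a table of exon
#' records and derives the canonical junction set (one entry per distinct
#' intron between consecutive exons of a transcript), per-gene spans, and
#' per-transcript exon lists.
#'
#' @param exons Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id` (1-based closed intervals).
#' @param cds Optional data frame of CDS intervals with the same columns.
#' @return An object of class `"annotation_index"`: a list with tibbles
#'   `exons`, `canonical_junctions` (chrom, intron_start, intron_end,
#'   strand), `gene_regions`, `transcripts`, `cds`.
#' @export
annotation_index <- function(exons, cds = NULL) {
  exons <- tibble::as_tibble(exons)
  req <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  stopifnot(all(req %in% names(exons)))
  if (any(is.na(exons$transcript_id) | !nzchar(exons$transcript_id))) {
    stop("exon feature without transcript_id", call. = FALSE)
  }
  stopifnot(all(exons$start <= exons$end))
  exons <- exons |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(exon_rank = dplyr::row_number()) |>
    dplyr::ungroup()

  overlap <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      bad = dplyr::n() > 1 && any(.data$start[-1] <= cummax(.data$end[-dplyr::n()])),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$bad)
  if (nrow(overlap) > 0) {
    stop("transcript(s) with overlapping exons: ",
         paste(overlap$transcript_id, collapse = ", "), call. = FALSE)
  }

  junctions <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::reframe(
      chrom = .data$chrom[-dplyr::n()],
      strand = .data$strand[-dplyr::n()],
      intron_start = .data$end[-dplyr::n()] + 1L,
      intron_end = .data$start[-1] - 1L
    ) |>
    dplyr::distinct(.data$chrom, .data$intron_start, .data$intron_end,
                    .keep_all = TRUE) |>
    dplyr::select("chrom", "intron_start", "intron_end", "strand")

  gene_regions <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), strand = .data$strand[1],
                     .groups = "drop")

  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
                     strand = .data$strand[1], start = min(.data$start),
                     end = max(.data$end), n_exons = dplyr::n(),
                     span = sum(.data$end - .data$start + 1L),
                     .groups = "drop")

  cds <- if (is.null(cds)) {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), gene_id = character(),
                   transcript_id = character())
  } else {
    tibble::as_tibble(cds)[, req]
  }

  structure(
    list(exons = exons, canonical_junctions = junctions,
         gene_regions = gene_regions, transcripts = transcripts, cds = cds),
    class = "annotation_index"
  )
}

#' Build an annotation index from a GTF file
#'
#' Reads an Ensembl-dialect GTF (exon and CDS features with
#' `gene_id`/`transcript_id` attributes) and derives the canonical splice
#' junction set used to separate annotated from novel junctions.
#'
#' @param gtf_path Path to a GTF file.
#' @return An `"annotation_index"` (see [annotation_index()]).
#' @export
build_annotation_index <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  feats <- as.character(gr$type)
  ex <- gr[feats == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features", call. = FALSE)
  to_tbl <- function(g) {
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      gene_id = as.character(g$gene_id),
      transcript_id = as.character(g$transcript_id)
    )
  }
  exons <- to_tbl(ex)
  if (any(is.na(exons$transcript_id))) {
    stop("exon feature without transcript_id", call. = FALSE)
  }
  cds_gr <- gr[feats == "CDS"]
  cds <- if (length(cds_gr) > 0) to_tbl(cds_gr) else NULL
  annotation_index(exons, cds = cds)
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("<annotation_index>\n")
  cat(sprintf("  %d transcripts / %d genes, %d exon records, %d canonical junctions\n",
              nrow(x$transcripts), nrow(x$gene_regions), nrow(x$exons),
              nrow(x$canonical_junctions)))
  invisible(x)
}

#' Read a blacklist of polymorphic regions from BED
#'
#' BED intervals (0-based half-open on disk) are converted to 1-based closed
#' coordinates matching the rest of the package.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` (1-based closed) and `name`
#'   when the BED carries one.
#' @export
read_blacklist_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Read a precomputed control junction-count table
#'
#' Alternative to a directory of control BAMs: a TSV with key columns
#' `chrom`, `intron_start`, `intron_end` followed by one integer column per
#' control sample.
#'
#' @param path Path to the TSV.
#' @return Tibble in long format: `chrom`, `intron_start`, `intron_end`,
#'   `control_id`, `count`.
#' @export
read_control_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "")
  key <- c("chrom", "intron_start", "intron_end")
  if (!all(key %in% names(df))) {
    stop("control count table must have columns chrom, intron_start, intron_end",
         call. = FALSE)
  }
  tibble::as_tibble(df) |>
    tidyr::pivot_longer(-dplyr::all_of(key), names_to = "control_id",
                        values_to = "count") |>
    dplyr::mutate(count = as.integer(.data$count))
}
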