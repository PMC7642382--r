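.revcomp <- function(x) {
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

.fetch_seq <- function(genome, chrom, start, end) {
  fa <- if (inherits(genome, "FaFile")) genome else Rsamtools::FaFile(genome)
  contig_len <- GenomicRanges::width(
    GenomicRanges::GRanges(Rsamtools::seqinfo(fa))[GenomicRanges::seqnames(
      GenomicRanges::GRanges(Rsamtools::seqinfo(fa))) == chrom])
  if (start < 1 || (length(contig_len) == 1 && end > contig_len)) {
    stop(sprintf("window %s:%d-%d exceeds contig bounds", chrom, start, end),
         call. = FALSE)
  }
  unname(as.character(Biostrings::getSeq(
    fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end)))))
}

# Genomic window of a donor 9-mer / acceptor 23-mer.
# boundary: first intronic base (donor) or last intronic base (acceptor),
# both in transcript orientation, as genomic coordinates.
.site_window <- function(boundary, site_type, strand) {
  if (site_type == "donor") {
    if (strand == "+") c(boundary - 3L, boundary + 5L)
    else c(boundary - 5L, boundary + 3L)
  } else {
    if (strand == "+") c(boundary - 19L, boundary + 3L)
    else c(boundary - 3L, boundary + 19L)
  }
}

#' Extract the donor 9-mer or acceptor 23-mer at an intron boundary
#'
#' Donor sites span 3 exonic + 6 intronic bases; acceptor sites span 20
#' intronic + 3 exonic bases. Minus-strand windows are reverse-complemented
#' so the returned string reads 5'->3' along the transcript.
#'
#' @param genome `Rsamtools::FaFile` or FASTA path (indexed).
#' @param chrom Chromosome.
#' @param boundary Genomic position of the first intronic base (donor) or
#'   last intronic base (acceptor), in transcript orientation: on the minus
#'   strand the donor boundary is the genomic intron end and the acceptor
#'   boundary the genomic intron start.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param strand `"+"` or `"-"`.
#' @return A 9- or 23-character string.
#' @export
extract_site_sequence <- function(genome, chrom, boundary,
                                  site_type = c("donor", "acceptor"),
                                  strand = c("+", "-")) {
  site_type <- match.arg(site_type)
  strand <- match.arg(strand)
  w <- .site_window(boundary, site_type, strand)
  s <- .fetch_seq(genome, chrom, w[1], w[2])
  if (strand == "-") s <- .revcomp(s)
  s
}

#' Train a position log-odds splice-site model from annotation
#'
#' Collects the donor 9-mers or acceptor 23-mers of every canonical junction
#' in the annotation and fits a first-order position weight model: per
#' position, log2 of the base frequency (pseudocount 1) over a uniform 0.25
#' background. A sequence's score is the sum of its per-position log-odds, so
#' a single-base change shifts the score by exactly the log-odds difference
#' at that position.
#'
#' @param annotation An `annotation_index` whose canonical junctions carry a
#'   usable strand.
#' @param genome `Rsamtools::FaFile` or FASTA path.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param min_sites Minimum number of training junctions (default 50).
#' @return Object of class `"splice_site_model"`.
#' @export
train_site_model <- function(annotation, genome,
                             site_type = c("donor", "acceptor"),
                             min_sites = 50L) {
  site_type <- match.arg(site_type)
  jx <- annotation$canonical_junctions
  jx <- jx[jx$strand %in% c("+", "-"), , drop = FALSE]
  if (nrow(jx) < min_sites) {
    stop(sprintf("need >= %d canonical junctions to train, have %d",
                 min_sites, nrow(jx)), call. = FALSE)
  }
  seqs <- vapply(seq_len(nrow(jx)), function(i) {
    boundary <- if (site_type == "donor") {
      if (jx$strand[i] == "+") jx$intron_start[i] else jx$intron_end[i]
    } else {
      if (jx$strand[i] == "+") jx$intron_end[i] else jx$intron_start[i]
    }
    extract_site_sequence(genome, jx$chrom[i], boundary, site_type,
                          jx$strand[i])
  }, character(1))
  splice_site_model_from_seqs(seqs, site_type)
}

#' Build a splice-site model from training sequences
#'
#' @param seqs Character vector of equal-length ACGT sequences (9 for donor,
#'   23 for acceptor).
#' @param site_type `"donor"` or `"acceptor"`.
#' @return Object of class `"splice_site_model"` with fields `site_type`,
#'   `expected_length`, `log_odds` (4 x L matrix, rows A/C/G/T), `n_sites`.
#' @export
splice_site_model_from_seqs <- function(seqs, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  len <- if (site_type == "donor") 9L else 23L
  stopifnot(length(seqs) > 0, all(nchar(seqs) == len))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  bases <- c("A", "C", "G", "T")
  counts <- sapply(seq_len(len), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.numeric(tab)
  })
  rownames(counts) <- bases
  freq <- sweep(counts + 1, 2, colSums(counts + 1), "/")
  structure(
    list(site_type = site_type, expected_length = len,
         log_odds = log2(freq / 0.25), n_sites = length(seqs)),
    class = "splice_site_model"
  )
}

#' Score a sequence with a splice-site model
#'
#' @param model A `splice_site_model`.
#' @param seq Sequence of the model's expected length over ACGT.
#' @return Numeric log2-odds score.
#' @export
score_sequence <- function(model, seq) {
  stopifnot(inherits(model, "splice_site_model"))
  seq <- toupper(seq)
  if (nchar(seq) != model$expected_length) {
    stop(sprintf("sequence length %d, expected %d", nchar(seq),
                 model$expected_length), call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("sequence contains non-ACGT bases", call. = FALSE)
  }
  ri <- match(chars, rownames(model$log_odds))
  sum(model$log_odds[cbind(ri, seq_along(chars))])
}

#' Score a reference/mutant splice-site sequence pair
#'
#' @param model A `splice_site_model`.
#' @param ref_seq,mut_seq Reference and mutant sequences of the model's
#'   expected length.
#' @return One-row tibble: `site_type`, `ref_seq`, `mut_seq`, `ref_score`,
#'   `mut_score`, `delta` (mutant minus reference).
#' @export
score_site_pair <- function(model, ref_seq, mut_seq) {
  rs <- score_sequence(model, ref_seq)
  ms <- score_sequence(model, mut_seq)
  tibble::tibble(site_type = model$site_type, ref_seq = ref_seq,
                 mut_seq = mut_seq, ref_score = rs, mut_score = ms,
                 delta = ms - rs)
}

#' Reference and mutant site sequences for a candidate's cryptic boundary
#'
#' Determines which intron boundary lies nearest the mutation (the cryptic
#' splice site), its site type given the junction strand, extracts the
#' reference window and substitutes the alternate allele when the mutation
#' falls inside the window.
#'
#' @param genome `Rsamtools::FaFile` or FASTA path.
#' @param chrom,pos,ref_allele,alt_allele The mutation.
#' @param intron_start,intron_end The junction's intron.
#' @param strand Junction strand (`"+"`/`"-"`; `"unknown"` is scored on
#'   `"+"`).
#' @return List with `site_type`, `ref_seq`, `mut_seq`, `mutated` (whether
#'   the mutation falls inside the scored window), `boundary`.
#' @export
candidate_site_sequences <- function(genome, chrom, pos, ref_allele, alt_allele,
                                     intron_start, intron_end, strand = "+") {
  if (!strand %in% c("+", "-")) strand <- "+"
  d_start <- min(abs(pos - intron_start), abs(pos - (intron_start - 1L)))
  d_end <- min(abs(pos - intron_end), abs(pos - (intron_end + 1L)))
  near_start <- d_start <= d_end
  if (strand == "+") {
    site_type <- if (near_start) "donor" else "acceptor"
    boundary <- if (near_start) intron_start else intron_end
  } else {
    site_type <- if (near_start) "acceptor" else "donor"
    boundary <- if (near_start) intron_start else intron_end
  }
  w <- .site_window(boundary, site_type, strand)
  ref_seq <- extract_site_sequence(genome, chrom, boundary, site_type, strand)
  mutated <- pos >= w[1] && pos <= w[2] &&
    nchar(ref_allele) == 1 && nchar(alt_allele) == 1 &&
    ref_allele != "-" && alt_allele != "-"
  mut_seq <- ref_seq
  if (mutated) {
    if (strand == "+") {
      idx <- pos - w[1] + 1L
      substr(mut_seq, idx, idx) <- alt_allele
    } else {
      idx <- w[2] - pos + 1L
      substr(mut_seq, idx, idx) <- .revcomp(alt_allele)
    }
  }
  list(site_type = site_type, ref_seq = ref_seq, mut_seq = mut_seq,
       mutated = mutated, boundary = boundary)
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("<splice_site_model> %s (%d-mer), trained on %d sites\n",
              x$site_type, x$expected_length, x$n_sites))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a splice-site model into per-position log-odds
#'
#' @param x A `splice_site_model`.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `log_odds`.
#' @export
tidy.splice_site_model <- function(x, ...) {
  lo <- x$log_odds
  tibble::tibble(
    position = rep(seq_len(ncol(lo)), each = nrow(lo)),
    base = rep(rownames(lo), ncol(lo)),
    log_odds = as.vector(lo)
  )
}

#' One-row model summary
#'
#' @param x A `splice_site_model`.
#' @param ... Unused.
#' @return Tibble with `site_type`, `expected_length`, `n_sites`,
#'   `max_score`, `min_score`.
#' @export
glance.splice_site_model <- function(x, ...) {
  tibble::tibble(
    site_type = x$site_type,
    expected_length = x$expected_length,
    n_sites = x$n_sites,
    max_score = sum(apply(x$log_odds, 2, max)),
    min_score = sum(apply(x$log_odds, 2, min))
  )
}

#' Plot the position log-odds profile of a splice-site model
#'
#' @param object A `splice_site_model`.
#' @param ... Unused.
#' @return A ggplot object (position x base tile map of log2 odds).
#' @export
autoplot.splice_site_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(
      title = sprintf("%s site model (%d training sites)", object$site_type,
                      object$n_sites),
      x = "position in site window", y = NULL, fill = "log2 odds"
    ) +
    ggplot2::theme_minimal()
}
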