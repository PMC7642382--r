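#' Simulate a genomic locus with a multi-exon gene
#'
#' Generates an i.i.d. random genome of the requested length and GC
#' fraction, then lays out a single plus-strand gene with `n_exons` exons
#' whose exon and intron lengths are drawn uniformly from the given ranges.
#' The transcript is the concatenation of the exon sequences with a 5'- and
#' 3'-UTR (absorbed into the first/last exon blocks, so they are genomically
#' contiguous) and a poly(A) tail. All output is a pure function of the
#' parameters and `seed`.
#'
#' @param length Genome length in bp (default 1e6).
#' @param gc Expected GC fraction (default 0.40).
#' @param n_exons Number of exons (default 100).
#' @param exon_range,intron_range Uniform length ranges in bp (defaults
#'   15-600 and 100-1000).
#' @param utr_len 5'/3' UTR length added to the terminal exons (default 200).
#' @param polya_len Poly(A) tail length (default 50).
#' @param seed Integer seed.
#' @return Object of class `"simulated_locus"`: `genome_seq`, `chrom`,
#'   `exons` (annotation tibble, UTR-extended terminal exons), `core_exons`
#'   (without UTRs), `tx_blocks` (transcript-to-genome block map),
#'   `polya_len`, `events` (empty list), `params`, `seed`.
#' @export
simulate_gene_locus <- function(length = 1e6L, gc = 0.40, n_exons = 100L,
                                exon_range = c(15L, 600L),
                                intron_range = c(100L, 1000L),
                                utr_len = 200L, polya_len = 50L, seed = 1L) {
  stopifnot(n_exons >= 2, exon_range[1] >= 1, intron_range[1] >= 1,
            exon_range[1] <= exon_range[2], intron_range[1] <= intron_range[2])
  set.seed(seed)
  length <- as.integer(length)
  draw_len <- function(rng, n) {
    if (rng[1] == rng[2]) rep(as.integer(rng[1]), n)
    else sample(seq(as.integer(rng[1]), as.integer(rng[2])), n, replace = TRUE)
  }
  exon_len <- draw_len(exon_range, n_exons)
  intron_len <- draw_len(intron_range, n_exons - 1L)
  margin <- 2000L
  total <- sum(exon_len) + sum(intron_len) + 2L * utr_len + 2L * margin
  if (total > length) {
    stop(sprintf(
      "gene structure (%d bp plus margins) exceeds genome length %d; increase `length`",
      total, length), call. = FALSE)
  }
  p_at <- (1 - gc) / 2
  p_gc <- gc / 2
  genome <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                         prob = c(p_at, p_gc, p_gc, p_at)), collapse = "")

  starts <- integer(n_exons)
  ends <- integer(n_exons)
  cur <- margin + utr_len + 1L
  for (i in seq_len(n_exons)) {
    starts[i] <- cur
    ends[i] <- cur + exon_len[i] - 1L
    if (i < n_exons) cur <- ends[i] + intron_len[i] + 1L
  }
  core <- tibble::tibble(
    chrom = "chrSim", start = starts, end = ends, strand = "+",
    gene_id = "GENE1", transcript_id = "TX1"
  )
  exons <- core
  exons$start[1] <- exons$start[1] - utr_len
  exons$end[n_exons] <- exons$end[n_exons] + utr_len

  structure(
    list(genome_seq = genome, chrom = "chrSim", exons = exons,
         core_exons = core, polya_len = as.integer(polya_len),
         utr_len = as.integer(utr_len), events = list(),
         params = list(length = length, gc = gc, n_exons = n_exons,
                       exon_range = exon_range, intron_range = intron_range),
         seed = as.integer(seed)),
    class = "simulated_locus"
  )
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf("<simulated_locus> %s: %d bp, %d exons, %d injected event(s), seed %d\n",
              x$chrom, nchar(x$genome_seq), nrow(x$exons), length(x$events),
              x$seed))
  invisible(x)
}

# transcript-to-genome block map for a set of plus-strand exon blocks
.tx_blocks <- function(exons) {
  w <- exons$end - exons$start + 1L
  tx_end <- cumsum(w)
  tibble::tibble(tx_start = tx_end - w + 1L, tx_end = tx_end,
                 g_start = exons$start, g_end = exons$end)
}

.exon_seq <- function(genome, exons) {
  paste(substring(genome, exons$start, exons$end), collapse = "")
}

#' Inject an exon-extension event into a simulated locus
#'
#' Extends one exon by `shift_bp` bases into the adjacent intron at its 5'
#' or 3' end, producing an altered transcript that differs from the
#' reference by exactly that contiguous block, a novel splice junction
#' (the shortened intron), and an anchoring point mutation placed on the
#' extension base adjacent to the novel boundary (the altered transcript
#' carries the alternate allele).
#'
#' @param locus A `simulated_locus`.
#' @param exon_index Index of the exon to extend (interior exons only).
#' @param shift_bp Extension size in bp (published benchmark range 5-50).
#' @param end `"3p"` (into the downstream intron) or `"5p"` (upstream).
#' @return The locus with the event appended to `locus$events`; each event
#'   holds `truth` (one-row tibble with the novel junction and mutation) and
#'   `alt_exons` (the altered exon block table).
#' @export
inject_exon_extension <- function(locus, exon_index, shift_bp,
                                  end = c("3p", "5p")) {
  end <- match.arg(end)
  shift_bp <- as.integer(shift_bp)
  ex <- locus$exons
  n <- nrow(ex)
  stopifnot(exon_index >= 2, exon_index <= n - 1)
  if (end == "3p") {
    intron_len <- ex$start[exon_index + 1L] - ex$end[exon_index] - 1L
    if (shift_bp >= intron_len) {
      stop(sprintf("extension of %d bp crosses the %d bp downstream intron",
                   shift_bp, intron_len), call. = FALSE)
    }
    new_end <- ex$end[exon_index] + shift_bp
    novel <- c(new_end + 1L, ex$start[exon_index + 1L] - 1L)
    mut_pos <- new_end
  } else {
    intron_len <- ex$start[exon_index] - ex$end[exon_index - 1L] - 1L
    if (shift_bp >= intron_len) {
      stop(sprintf("extension of %d bp crosses the %d bp upstream intron",
                   shift_bp, intron_len), call. = FALSE)
    }
    new_start <- ex$start[exon_index] - shift_bp
    novel <- c(ex$end[exon_index - 1L] + 1L, new_start - 1L)
    mut_pos <- new_start
  }
  alt_exons <- ex
  if (end == "3p") alt_exons$end[exon_index] <- ex$end[exon_index] + shift_bp
  else alt_exons$start[exon_index] <- ex$start[exon_index] - shift_bp

  ref_base <- substr(locus$genome_seq, mut_pos, mut_pos)
  alt_base <- c(A = "G", C = "T", G = "A", T = "C")[[ref_base]]
  truth <- tibble::tibble(
    event = "exon_extension", exon_index = exon_index, end = end,
    shift_bp = as.integer(shift_bp), chrom = locus$chrom,
    intron_start = novel[1], intron_end = novel[2],
    mut_pos = mut_pos, ref_allele = ref_base, alt_allele = alt_base
  )
  locus$events <- c(locus$events, list(list(truth = truth,
                                            alt_exons = alt_exons)))
  locus
}

#' Truth table of injected events
#'
#' @param locus A `simulated_locus`.
#' @return Tibble with one row per injected event.
#' @export
locus_truth <- function(locus) {
  if (length(locus$events) == 0) {
    stop("locus has no injected events", call. = FALSE)
  }
  dplyr::bind_rows(lapply(locus$events, function(e) e$truth))
}

# CIGAR + genomic pos for a read spanning transcript coords [s, s+len-1]
# over plus-strand blocks; transcript positions past `mappable_len`
# (the poly(A) tail) become trailing soft clips. Returns NULL when the read
# starts beyond the mappable transcript.
.tx_read_alignment <- function(blocks, s, len, mappable_len) {
  e <- s + len - 1L
  if (s > mappable_len) return(NULL)
  tail_clip <- if (e > mappable_len) e - mappable_len else 0L
  e_m <- min(e, mappable_len)
  hit <- blocks[blocks$tx_end >= s & blocks$tx_start <= e_m, , drop = FALSE]
  pos <- hit$g_start[1] + (s - hit$tx_start[1])
  ops <- character(0)
  prev_g_end <- NA_integer_
  for (i in seq_len(nrow(hit))) {
    b_s <- max(s, hit$tx_start[i])
    b_e <- min(e_m, hit$tx_end[i])
    g_s <- hit$g_start[i] + (b_s - hit$tx_start[i])
    g_e <- hit$g_start[i] + (b_e - hit$tx_start[i])
    if (!is.na(prev_g_end)) {
      ops <- c(ops, sprintf("%dN", g_s - prev_g_end - 1L))
    }
    ops <- c(ops, sprintf("%dM", b_e - b_s + 1L))
    prev_g_end <- g_e
  }
  if (tail_clip > 0L) ops <- c(ops, sprintf("%dS", tail_clip))
  list(pos = pos, cigar = paste(ops, collapse = ""))
}

.apply_substitutions <- function(reads, sub_rate) {
  if (sub_rate <= 0 || length(reads) == 0) return(reads)
  read_len <- nchar(reads[1])
  n_bases <- length(reads) * read_len
  k <- stats::rbinom(1, n_bases, sub_rate)
  if (k == 0) return(reads)
  idx <- sample.int(n_bases, k)
  ri <- ((idx - 1L) %/% read_len) + 1L
  off <- ((idx - 1L) %% read_len) + 1L
  for (j in seq_len(k)) {
    cur <- substr(reads[ri[j]], off[j], off[j])
    repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    substr(reads[ri[j]], off[j], off[j]) <- repl
  }
  reads
}

#' Simulate a mixed read set over reference and altered transcripts
#'
#' Draws 75-bp (by default) reads with uniformly random start positions from
#' the reference and altered transcript of one injected event, mixing
#' altered-origin reads at the requested fraction, applying a per-base
#' substitution rate, and emitting gold-standard spliced alignments (genomic
#' position + CIGAR with `N` ops across introns) derived from each read's
#' origin. No indel errors are simulated.
#'
#' @param locus A `simulated_locus`.
#' @param event_index Which injected event's altered transcript to use.
#' @param read_len Read length (default 75).
#' @param sub_rate Per-base substitution rate (default 0.001).
#' @param coverage Target per-base depth over the sampled region.
#' @param fraction Proportion of altered-origin reads, in \[0, 1\].
#' @param seed Integer seed.
#' @param window Optional genomic interval `c(start, end)` restricting read
#'   starts to transcript positions overlapping it (used to focus coverage
#'   on the assessed junction); `NULL` samples the whole transcript.
#' @return Tibble of reads: `qname`, `origin` (`"ref"`/`"alt"`), `chrom`,
#'   `pos`, `cigar`, `seq`.
#' @export
simulate_read_mixture <- function(locus, event_index = 1L, read_len = 75L,
                                  sub_rate = 0.001, coverage = 200,
                                  fraction = 0.25, seed = 1L, window = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, coverage > 0)
  set.seed(seed)
  ev <- locus$events[[event_index]]
  make_tx <- function(exons) {
    blocks <- .tx_blocks(exons)
    seq <- paste0(.exon_seq(locus$genome_seq, exons),
                  strrep("A", locus$polya_len))
    mappable <- sum(exons$end - exons$start + 1L)
    list(blocks = blocks, seq = seq, mappable = mappable)
  }
  ref <- make_tx(locus$exons)
  alt_exons <- ev$alt_exons
  alt <- make_tx(alt_exons)
  # plant the anchoring mutation's alternate allele in the altered transcript
  tmut <- .g_to_tx(alt$blocks, ev$truth$mut_pos)
  substr(alt$seq, tmut, tmut) <- ev$truth$alt_allele

  sample_range <- function(tx, exons) {
    lo <- 1L
    hi <- nchar(tx$seq) - read_len + 1L
    if (!is.null(window)) {
      tx_lo <- .g_to_tx(tx$blocks, max(window[1], exons$start[1]))
      tx_hi <- .g_to_tx(tx$blocks, min(window[2], exons$end[nrow(exons)]))
      lo <- max(lo, tx_lo - read_len + 1L)
      hi <- min(hi, tx_hi)
    }
    if (hi < lo) stop("transcript shorter than read length over the window",
                      call. = FALSE)
    c(lo, hi)
  }
  draw <- function(tx, exons, n, origin) {
    rng <- sample_range(tx, exons)
    starts <- if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(seq(rng[1], rng[2]), n, replace = TRUE)
    seqs <- substring(tx$seq, starts, starts + read_len - 1L)
    seqs <- .apply_substitutions(seqs, sub_rate)
    aln <- lapply(starts, function(s) {
      .tx_read_alignment(tx$blocks, s, read_len, tx$mappable)
    })
    keep <- !vapply(aln, is.null, logical(1))
    tibble::tibble(
      origin = origin,
      chrom = locus$chrom,
      pos = vapply(aln[keep], `[[`, integer(1), "pos"),
      cigar = vapply(aln[keep], `[[`, character(1), "cigar"),
      seq = seqs[keep]
    )
  }
  rng <- sample_range(ref, locus$exons)
  span <- rng[2] - rng[1] + read_len
  n_total <- max(1L, as.integer(round(coverage * span / read_len)))
  n_alt <- as.integer(round(n_total * fraction))
  parts <- list()
  if (n_total - n_alt > 0) {
    parts$ref <- draw(ref, locus$exons, n_total - n_alt, "ref")
  }
  if (n_alt > 0) parts$alt <- draw(alt, alt_exons, n_alt, "alt")
  out <- dplyr::bind_rows(parts)
  out$qname <- sprintf("ev%d_%s_%06d", event_index, out$origin,
                       seq_len(nrow(out)))
  dplyr::relocate(out, "qname")
}

# genomic position -> transcript coordinate over plus-strand blocks
.g_to_tx <- function(blocks, g) {
  i <- which(blocks$g_start <= g & blocks$g_end >= g)
  if (length(i) == 0) {
    # fall back to the nearest block edge (position intronic in this isoform)
    i <- which.min(pmin(abs(blocks$g_start - g), abs(blocks$g_end - g)))
    g <- min(max(g, blocks$g_start[i]), blocks$g_end[i])
  }
  blocks$tx_start[i[1]] + (g - blocks$g_start[i[1]])
}

#' Write a simulated locus and read sets to standard formats
#'
#' Emits the genome FASTA (indexed), the reference gene annotation as GTF,
#' reads as a coordinate-sorted indexed BAM (via an intermediate SAM), the
#' anchoring mutations as MAF, and the truth table as TSV.
#'
#' @param locus A `simulated_locus`.
#' @param reads Read tibble from [simulate_read_mixture()] (rows from
#'   several events can be concatenated); may be `NULL` to skip the BAM.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named list of file paths (`fasta`, `gtf`, `bam`, `maf`, `truth`).
#' @export
write_locus_files <- function(locus, reads, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  ss <- Biostrings::DNAStringSet(stats::setNames(locus$genome_seq, locus$chrom))
  Biostrings::writeXStringSet(ss, fasta)
  Rsamtools::indexFa(fasta)

  gtf <- file.path(dir, paste0(prefix, ".gtf"))
  ex <- locus$exons
  lines <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id
  )
  writeLines(lines, gtf)

  paths <- list(fasta = fasta, gtf = gtf)

  if (!is.null(reads) && nrow(reads) > 0) {
    sam <- file.path(dir, paste0(prefix, ".sam"))
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom, nchar(locus$genome_seq)))
    body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                    reads$qname, reads$chrom, reads$pos, reads$cigar,
                    reads$seq, strrep("I", nchar(reads$seq)))
    writeLines(c(hdr, body), sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam)
    paths$bam <- bam
  }

  if (length(locus$events) > 0) {
    truth <- locus_truth(locus)
    maf <- file.path(dir, paste0(prefix, ".maf"))
    write_maf(tibble::tibble(
      chrom = truth$chrom, pos = truth$mut_pos,
      ref_allele = truth$ref_allele, alt_allele = truth$alt_allele,
      variant_classification = "Intron", sample_id = "SIM_CASE",
      dna_vaf = NA_real_
    ), maf)
    truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$maf <- maf
    paths$truth <- truth_path
  }
  paths
}

#' Sensitivity of junction calls against a truth set
#'
#' Fraction of injected events whose novel junction is called with exactly
#' matching boundaries (off-by-one is a miss).
#'
#' @param calls Tibble with `chrom`, `intron_start`, `intron_end`.
#' @param truth Truth tibble (see [locus_truth()]).
#' @return Sensitivity in \[0, 1\].
#' @export
evaluate_sensitivity <- function(calls, truth) {
  if (is.null(truth) || nrow(truth) == 0) {
    stop("truth set is empty; sensitivity undefined", call. = FALSE)
  }
  if (is.null(calls) || nrow(calls) == 0) return(0)
  key <- function(d) paste(d$chrom, d$intron_start, d$intron_end)
  mean(key(truth) %in% key(calls))
}

#' Run the full sensitivity benchmark on one simulated locus
#'
#' Builds a simulated locus, injects `n_events` exon extensions (5-50 bp,
#' random interior exons separated by at least one exon, random 5'/3' end),
#' simulates a case read mixture and a mutation-free control read set over a
#' window around each novel junction, writes all inputs to `dir`, runs the
#' discovery pipeline on the gold-standard alignments, and scores
#' sensitivity against the truth.
#'
#' @param n_events Number of injected extensions (default 20).
#' @param coverage Per-base read depth over each window (default 200).
#' @param fraction Altered-read mixture fraction (default 0.25).
#' @param seed Integer seed.
#' @param dir Working directory (default a fresh temp dir).
#' @param config A [splice_config()].
#' @param window_pad Half-width in bp of the genomic window around each
#'   novel junction over which reads are simulated (default 450).
#' @param ... Passed to [simulate_gene_locus()].
#' @return List with `sensitivity`, `truth`, `calls` (final event tibble),
#'   `run` (the `splice_run`), `paths`.
#' @export
simulate_benchmark <- function(n_events = 20L, coverage = 200, fraction = 0.25,
                               seed = 1L, dir = tempfile("bench"),
                               config = splice_config(),
                               window_pad = 450L, ...) {
  locus <- simulate_gene_locus(seed = seed, ...)
  n_ex <- nrow(locus$exons)
  set.seed(seed + 1L)
  pool <- seq(2L, n_ex - 1L, by = 2L) # interior exons, non-adjacent
  stopifnot(length(pool) >= n_events)
  exon_idx <- sort(sample(pool, n_events))
  shifts <- sample(5:50, n_events, replace = TRUE)
  ends <- sample(c("5p", "3p"), n_events, replace = TRUE)
  for (i in seq_len(n_events)) {
    locus <- inject_exon_extension(locus, exon_idx[i], shifts[i], ends[i])
  }
  truth <- locus_truth(locus)

  case_reads <- list()
  ctrl_reads <- list()
  for (i in seq_len(n_events)) {
    w <- c(truth$intron_start[i] - window_pad, truth$intron_end[i] + window_pad)
    case_reads[[i]] <- simulate_read_mixture(
      locus, i, coverage = coverage, fraction = fraction,
      seed = seed + 100L + i, window = w)
    ctrl_reads[[i]] <- simulate_read_mixture(
      locus, i, coverage = coverage, fraction = 0,
      seed = seed + 5000L + i, window = w)
  }
  case <- dplyr::bind_rows(case_reads)
  case$qname <- sprintf("c%06d_%s", seq_len(nrow(case)), case$qname)
  ctrl <- dplyr::bind_rows(ctrl_reads)
  ctrl$qname <- sprintf("n%06d_%s", seq_len(nrow(ctrl)), ctrl$qname)

  paths <- write_locus_files(locus, case, dir, prefix = "case")
  ctrl_paths <- write_locus_files(locus, ctrl, dir, prefix = "ctrl")
  paths$control_bam <- ctrl_paths$bam

  run <- run_pipeline(
    maf = paths$maf, bam = paths$bam,
    controls = c(control1 = paths$control_bam),
    gtf = paths$gtf, fasta = paths$fasta, config = config
  )
  calls <- run$events
  list(sensitivity = evaluate_sensitivity(calls, truth), truth = truth,
       calls = calls, run = run, paths = paths)
}
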