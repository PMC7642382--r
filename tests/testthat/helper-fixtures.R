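# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing binary ships with the package.

fixture_genome <- function(seq, chrom = "chrT", dir = tempfile("fa")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(stats::setNames(seq, chrom))
  Biostrings::writeXStringSet(ss, path)
  Rsamtools::indexFa(path)
  path
}

random_genome <- function(len, seed = 1, gc = 0.45) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

# reads: data.frame with pos, cigar and optional qname, seq, mapq, flag
fixture_bam <- function(reads, chrom = "chrT", contig_len = 100000L,
                        dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  n <- nrow(reads)
  if (is.null(reads$qname)) reads$qname <- sprintf("r%04d", seq_len(n))
  if (is.null(reads$mapq)) reads$mapq <- 60L
  if (is.null(reads$flag)) reads$flag <- 0L
  if (is.null(reads$seq)) {
    qlen <- vapply(reads$cigar, cigar_query_len, integer(1))
    reads$seq <- vapply(qlen, function(L) strrep("A", L), character(1))
  }
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, contig_len))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, chrom, reads$pos, reads$mapq,
                  reads$cigar, reads$seq,
                  vapply(nchar(reads$seq), function(L) strrep("I", L),
                         character(1)))
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

cigar_query_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(len[op %in% c("M", "I", "S", "=", "X")])
}

# Independent CIGAR oracle: introns implied by the N operations of one read,
# computed by a plain text walk (no GenomicAlignments).
oracle_read_introns <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  r <- pos
  out <- list()
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      r <- r + len[i]
    } else if (op[i] == "N") {
      out[[length(out) + 1]] <- c(r, r + len[i] - 1L)
      r <- r + len[i]
    }
  }
  if (length(out) == 0) {
    return(data.frame(intron_start = integer(), intron_end = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(intron_start = m[, 1], intron_end = m[, 2])
}

# Brute-force junction tally over a read table (the oracle against
# extract_junctions): applies the same mapq/flag rules by construction.
oracle_junction_tally <- function(reads, min_mapq = 20L) {
  if (!is.null(reads$mapq)) {
    reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  }
  tallies <- list()
  for (i in seq_len(nrow(reads))) {
    tallies[[i]] <- oracle_read_introns(reads$pos[i], reads$cigar[i])
  }
  df <- do.call(rbind, tallies)
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(intron_start = integer(), intron_end = integer(),
                      n = integer()))
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = df[c("intron_start", "intron_end")], FUN = sum)
  agg[order(agg$intron_start, agg$intron_end), ]
}

# Small two-gene annotation used by the filter/classification tests.
# GENE_A (+): exons [1001,1200], [1501,1700], [2001,2200], [2501,2700]
#   canonical introns: (1201,1500), (1701,2000), (2201,2500)
# GENE_B (+): exons [6001,6200], [6501,6700]; canonical intron (6201,6500)
fixture_annotation <- function(with_cds = TRUE) {
  exons <- tibble::tibble(
    chrom = "chrT",
    start = c(1001L, 1501L, 2001L, 2501L, 6001L, 6501L),
    end = c(1200L, 1700L, 2200L, 2700L, 6200L, 6700L),
    strand = "+",
    gene_id = c(rep("GENE_A", 4), rep("GENE_B", 2)),
    transcript_id = c(rep("TX_A", 4), rep("TX_B", 2))
  )
  cds <- NULL
  if (with_cds) {
    cds <- tibble::tibble(
      chrom = "chrT",
      start = c(1051L, 1501L, 2001L, 2501L),
      end = c(1200L, 1700L, 2200L, 2650L),
      strand = "+",
      gene_id = "GENE_A", transcript_id = "TX_A"
    )
  }
  annotation_index(exons, cds = cds)
}

make_candidate <- function(chrom = "chrT", pos, intron_start, intron_end,
                           n_supporting_reads = 10L, ref = "A", alt = "G",
                           sample_id = "S1", ...) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref_allele = ref, alt_allele = alt,
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    n_supporting_reads = as.integer(n_supporting_reads),
    distance_bp = junction_distance(as.integer(pos),
                                    as.integer(intron_start),
                                    as.integer(intron_end)),
    is_canonical = FALSE,
    ...
  )
}
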