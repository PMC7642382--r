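# Genome paired with fixture_annotation(): CDS of GENE_A spans
# 1051-1200, 1501-1700, 2001-2200, 2501-2650 (all on the plus strand).
classify_genome <- function(plant_stop = TRUE) {
  g <- random_genome(10000, seed = 81)
  while (grepl("TAA|TAG|TGA", g)) g <- gsub("TAA|TAG|TGA", "ACC", g)
  if (plant_stop) substr(g, 1300, 1302) <- "TAA"
  g
}

empty_tally <- function() {
  tibble::tibble(chrom = character(), intron_start = integer(),
                 intron_end = integer(), n_supporting_reads = integer())
}

tally <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(chrom = "chrT", intron_start = r[1], intron_end = r[2],
                   n_supporting_reads = r[3])
  }))
}

test_that("a novel boundary inside the intron with no mate is exon extension", {
  idx <- fixture_annotation()
  cand <- make_candidate(pos = 1229, intron_start = 1230, intron_end = 1500)
  ev <- classify_event(cand, empty_tally(), idx)
  expect_equal(ev$category, "exon_extension")
  expect_true(is.na(ev$ams_pos))
  expect_equal(ev$gene_ids, "GENE_A")
})

test_that("a novel boundary inside the exon is exon shrinkage", {
  idx <- fixture_annotation()
  cand <- make_candidate(pos = 1189, intron_start = 1190, intron_end = 1500)
  ev <- classify_event(cand, empty_tally(), idx)
  expect_equal(ev$category, "exon_shrinkage")
})

test_that("a mate junction in the same intron makes an internal new exon", {
  idx <- fixture_annotation()
  fa <- fixture_genome(classify_genome())
  # PSS junction from the canonical donor edge; novel acceptor at 1299.
  cand <- make_candidate(pos = 1203, intron_start = 1201, intron_end = 1299)
  co <- tally(c(1201L, 1299L, 12L), c(1430L, 1500L, 8L),
              c(1201L, 1500L, 40L)) # canonical junction present too
  ev <- classify_event(cand, co, idx, genome = fa)
  expect_equal(ev$category, "new_exon_middle")
  expect_equal(ev$new_exon_start, 1300L)
  expect_equal(ev$new_exon_end, 1429L)
  expect_equal(ev$new_exon_length, 130L)
  expect_equal(ev$ams_pos, 1430L)
  # 130 mod 3 = 1: off-frame, and the planted TAA is read in frame
  expect_true(ev$frameshift)
  expect_true(ev$premature_stop)
})

test_that("junctions within a single annotated exon split that exon", {
  idx <- fixture_annotation()
  cand <- make_candidate(pos = 2049, intron_start = 2050, intron_end = 2150)
  ev <- classify_event(cand, empty_tally(), idx)
  expect_equal(ev$category, "exon_splitting")
})

test_that("junctions bridging two genes are fusions", {
  idx <- fixture_annotation()
  cand <- make_candidate(pos = 2099, intron_start = 2100, intron_end = 6100)
  ev <- classify_event(cand, empty_tally(), idx)
  expect_equal(ev$category, "fusion")
  expect_setequal(strsplit(ev$gene_ids, ",")[[1]], c("GENE_A", "GENE_B"))
  # also when one end sits on a canonical boundary of the first gene
  cand2 <- make_candidate(pos = 1203, intron_start = 1201, intron_end = 6100)
  expect_equal(classify_event(cand2, empty_tally(), idx)$category, "fusion")
})

test_that("junctions outside annotated transcripts are new transcripts", {
  idx <- fixture_annotation()
  cand <- make_candidate(pos = 7999, intron_start = 8000, intron_end = 8200)
  expect_equal(classify_event(cand, empty_tally(), idx)$category,
               "new_transcript")
})

test_that("mixed elementary signatures collapse to complex", {
  idx <- fixture_annotation()
  # non-canonical boundaries: one in an exon, one in an intron of GENE_A
  cand <- make_candidate(pos = 1189, intron_start = 1190, intron_end = 1400)
  expect_equal(classify_event(cand, empty_tally(), idx)$category, "complex")
})

test_that("mate search respects support, size bounds and tie-breaks", {
  idx <- fixture_annotation()
  cfg <- splice_config()
  # partner below M reads: no mate
  expect_null(locate_activated_mate("chrT", 1201L, 1299L,
                                    tally(c(1430L, 1500L, 4L)), idx, cfg))
  # partner bounding a 118-bp exon
  mate <- locate_activated_mate("chrT", 1201L, 1299L,
                                tally(c(1418L, 1500L, 6L)), idx, cfg)
  expect_equal(mate$new_exon_end - mate$new_exon_start + 1L, 118L)
  # size bounds: enclosed interval of 8 bp is rejected (minimum 15)
  expect_null(locate_activated_mate("chrT", 1201L, 1299L,
                                    tally(c(1308L, 1500L, 9L)), idx, cfg))
  # higher support wins
  mate2 <- locate_activated_mate(
    "chrT", 1201L, 1299L,
    tally(c(1430L, 1500L, 8L), c(1460L, 1500L, 6L)), idx, cfg)
  expect_equal(mate2$ams_pos, 1430L)
  # count tie: the splice-score tie-break picks the consensus-bearing site
  g <- classify_genome(plant_stop = FALSE)
  substr(g, 1457, 1465) <- "CAGGTAAGT" # consensus donor at partner 1460
  fa <- fixture_genome(g)
  model <- splice_site_model_from_seqs(rep("CAGGTAAGT", 50), "donor")
  mate3 <- locate_activated_mate(
    "chrT", 1201L, 1299L,
    tally(c(1430L, 1500L, 6L), c(1460L, 1500L, 6L)), idx, cfg,
    genome = fa, model = model)
  expect_equal(mate3$ams_pos, 1460L)
  # without a model the position tie-break is deterministic
  mate4 <- locate_activated_mate(
    "chrT", 1201L, 1299L,
    tally(c(1430L, 1500L, 6L), c(1460L, 1500L, 6L)), idx, cfg)
  expect_equal(mate4$ams_pos, 1430L)
})

test_that("frame impact follows inserted length mod 3 and stop codons", {
  idx <- fixture_annotation()
  fa <- fixture_genome(classify_genome(plant_stop = FALSE))
  # closed form over a sweep of inserted lengths
  for (L in c(1:10, sample(11:300, 20))) {
    fi <- frame_impact(fa, "chrT", 1300L, 1300L + L - 1L, idx)
    expect_equal(fi$frameshift, (L %% 3) != 0)
  }
  # 130-bp with an in-frame stop
  fa2 <- fixture_genome(classify_genome(plant_stop = TRUE))
  fi2 <- frame_impact(fa2, "chrT", 1300L, 1429L, idx)
  expect_true(fi2$frameshift)
  expect_true(fi2$premature_stop)
  # 120-bp clean insert: in frame, no stop
  fi3 <- frame_impact(fa, "chrT", 1300L, 1419L, idx)
  expect_false(fi3$frameshift)
  expect_false(fi3$premature_stop)
  # outside any CDS bracket: unknown with warning
  expect_warning(fi4 <- frame_impact(fa, "chrT", 9000L, 9100L, idx))
  expect_true(is.na(fi4$frameshift))
})

test_that("every candidate receives exactly one category", {
  idx <- fixture_annotation()
  set.seed(83)
  for (i in 1:200) {
    is <- sample(900:8000, 1)
    ie <- is + sample(20:800, 1)
    pos <- is + sample(c(-1L, 0L), 1)
    cand <- make_candidate(pos = pos, intron_start = is, intron_end = ie)
    co <- if (stats::runif(1) < 0.3) {
      tally(c(is, ie, 10L), c(is + sample(5:100, 1), ie, sample(1:20, 1)))
    } else {
      empty_tally()
    }
    ev <- classify_event(cand, co, idx)
    expect_equal(nrow(ev), 1L)
    expect_length(ev$category, 1)
    expect_true(ev$category %in% c("new_exon_first", "new_exon_middle",
                                   "new_exon_last", "exon_extension",
                                   "exon_shrinkage", "exon_splitting",
                                   "fusion", "new_transcript", "complex"))
    if (grepl("^new_exon", ev$category)) {
      # both novel junction boundaries confined to one annotated intron
      host <- idx$canonical_junctions
      inside <- any(host$intron_start <= ev$new_exon_start &
                      host$intron_end >= ev$new_exon_end)
      expect_true(inside)
    }
  }
})
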