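test_that("GTF coordinates are read 1-based closed and ordered by transcription", {
  f <- write_tmp_gtf(c(gtf_line("chr1", "exon", 101, 200, "+", "gA", "tA1")))
  g <- read_gtf(f)
  ex <- g$gA$transcripts$tA1$exons
  expect_equal(ex$start, 101)
  expect_equal(ex$end, 200)
  expect_equal(ex$end - ex$start + 1, 100)  # a 100 bp exon stays 100 bp

  # minus strand: transcription order is reverse genomic order
  f2 <- write_tmp_gtf(c(gtf_line("chr1", "exon", 1001, 1100, "-", "gB", "tB1"),
                        gtf_line("chr1", "exon", 2001, 2100, "-", "gB", "tB1")))
  ex2 <- read_gtf(f2)$gB$transcripts$tB1$exons
  expect_equal(ex2$start, c(2001, 1001))
  expect_equal(ex2$end, c(2100, 1100))
})

test_that("transcripts with overlapping exons are rejected", {
  f <- write_tmp_gtf(c(gtf_line("chr1", "exon", 101, 200, "+", "gA", "tA1"),
                       gtf_line("chr1", "exon", 150, 250, "+", "gA", "tA1")))
  expect_error(read_gtf(f), "overlap")
})

test_that("GTF write/read round trip preserves all coordinates", {
  gn <- get_sim(n_genes = 8)
  f <- tempfile(fileext = ".gtf")
  expect_no_warning(write_gtf(gn$genes, f))
  back <- expect_no_warning(read_gtf(f))
  expect_setequal(names(back), names(gn$genes))
  for (gid in names(gn$genes)) {
    for (tid in names(gn$genes[[gid]]$transcripts)) {
      a <- gn$genes[[gid]]$transcripts[[tid]]
      b <- back[[gid]]$transcripts[[tid]]
      expect_equal(b$exons, a$exons)
      expect_equal(b$cds_lo, a$cds_lo)
      expect_equal(b$cds_hi, a$cds_hi)
    }
  }
})

test_that("a 14-exon transcript with alternative 13th exon reports 13 of 14", {
  g <- make_gene(list(1:14, setdiff(1:14, 13)), 14)
  ev <- enumerate_splice_events(g)
  expect_length(ev, 1)
  kn <- alt_exon_position(g, ev[[1]])
  expect_equal(kn$k, 13)
  expect_equal(kn$N, 14)
})

test_that("cassette and mutually exclusive events are enumerated", {
  # transcripts ABC / AC: one cassette on B
  g <- make_gene(list(1:3, c(1, 3)), 3)
  ev <- enumerate_splice_events(g)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "cassette")
  expect_equal(nrow(ev[[1]]$alt), 1)

  # transcripts A B1 C / A B2 C with disjoint B1, B2: one MXE
  g2 <- make_gene(list(c(1, 2, 4), c(1, 3, 4)), 4)
  ev2 <- enumerate_splice_events(g2)
  expect_length(ev2, 1)
  expect_equal(ev2[[1]]$type, "mutually_exclusive")
  expect_equal(nrow(ev2[[1]]$alt), 2)

  # single transcript: nothing to enumerate
  expect_length(enumerate_splice_events(make_gene(list(1:3), 3)), 0)
})

test_that("inclusion and exclusion isoforms differ exactly by the alt exon(s)", {
  for (g in list(make_gene(list(1:5, c(1, 2, 4, 5)), 5),
                 make_gene(list(c(1, 2, 4), c(1, 3, 4)), 4),
                 make_gene(list(1:6, c(1, 2, 3, 5, 6), c(1, 3, 5, 6)), 6))) {
    for (ev in enumerate_splice_events(g)) {
      ki <- exon_key(g$transcripts[[ev$incl_tx]]$exons)
      ke <- exon_key(g$transcripts[[ev$excl_tx]]$exons)
      alt1 <- exon_key(ev$alt[1, , drop = FALSE])
      if (ev$type == "cassette") {
        expect_setequal(setdiff(ki, ke), alt1)
      } else {
        alt2 <- exon_key(ev$alt[2, , drop = FALSE])
        expect_setequal(setdiff(ki, ke), alt1)
        expect_setequal(setdiff(ke, ki), alt2)
      }
    }
  }
})

test_that("enumeration is invariant under transcript input reordering", {
  g1 <- make_gene(list(1:6, c(1, 2, 3, 5, 6), c(1, 3, 5, 6)), 6)
  g2 <- gene_model("g1", rev(unname(g1$transcripts)))
  e1 <- enumerate_splice_events(g1)
  e2 <- enumerate_splice_events(g2)
  expect_equal(lapply(e1, unclass), lapply(e2, unclass))
})

test_that("constitutive exon counting matches set intersection", {
  g <- make_gene(list(1:3, c(1, 3)), 3)
  ev <- enumerate_splice_events(g)[[1]]
  expect_equal(constitutive_exon_count(g, ev), 2)  # fails the >= 3 filter

  g2 <- make_gene(list(1:4, c(1, 3, 4)), 4)
  ev2 <- enumerate_splice_events(g2)[[1]]
  expect_equal(constitutive_exon_count(g2, ev2), 3)

  # 23-exon inclusion transcript, one alternative exon: oracle by key sets
  g3 <- make_gene(list(1:23, setdiff(1:23, 11)), 23)
  ev3 <- enumerate_splice_events(g3)[[1]]
  oracle <- length(Reduce(intersect,
                          lapply(g3$transcripts, function(t) exon_key(t$exons))))
  expect_equal(oracle, 22)
  expect_equal(constitutive_exon_count(g3, ev3), oracle)

  wrong <- splice_event(ev3$event_id, "other_gene", ev3$type, ev3$alt,
                        ev3$flank_up, ev3$flank_down, ev3$incl_tx, ev3$excl_tx)
  expect_error(constitutive_exon_count(g3, wrong), "does not belong")
})

test_that("BED output is 0-based half-open and round trips", {
  g <- make_gene(list(1:3, c(1, 3)), 3, len = 42, gap = 59)
  ev <- enumerate_splice_events(g)  # alt exon at 1102..1143 (1-based)
  f <- tempfile(fileext = ".bed")
  write_events_bed(ev, f)
  raw <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(raw[2]), ev[[1]]$alt$start - 1L)  # chromStart 0-based
  expect_equal(as.integer(raw[3]), ev[[1]]$alt$end)         # chromEnd half-open
  back <- read_events_bed(f)
  expect_equal(back$start, ev[[1]]$alt$start)
  expect_equal(back$end, ev[[1]]$alt$end)
  expect_equal(back$strand, ev[[1]]$alt$strand)

  # empty event list: empty file, empty table back
  f2 <- tempfile(fileext = ".bed")
  write_events_bed(list(), f2)
  expect_true(file.exists(f2))
  expect_equal(nrow(read_events_bed(f2)), 0)
})

test_that("events TSV round trips through splice_event objects", {
  gn <- get_sim(n_genes = 8)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(gn$events, f, genes = gn$genes)
  df <- read_events_tsv(f)
  expect_equal(nrow(df), length(gn$events))
  back <- psitrans:::events_from_tsv(df)
  expect_equal(lapply(back, unclass), lapply(gn$events, unclass))
  expect_equal(df$k, gn$truth$k)
  expect_equal(df$N, gn$truth$N)
})
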