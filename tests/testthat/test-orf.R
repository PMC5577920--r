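test_that("frame preservation follows the multiple-of-three rule", {
  expect_true(frame_preserved_lengths(42))    # Atp2a1-style in-frame exon
  expect_false(frame_preserved_lengths(73))   # Atp2a3-style frame shifter
  # mutually exclusive partners of equal length preserve frame even when
  # each partner is not a multiple of three
  expect_true(frame_preserved_lengths(194, 194))
  expect_false(frame_preserved_lengths(194, 193))
  # exhaustive check over 1..300
  for (L in 1:300) expect_equal(frame_preserved_lengths(L), L %% 3 == 0)
})

test_that("relative position is 100 k / N with validated bounds", {
  expect_equal(relative_position(13, 14), 100 * 13 / 14)
  expect_equal(round(relative_position(13, 14), 2), 92.86)
  expect_equal(relative_position(1, 10), 10)
  expect_equal(relative_position(7, 7), 100)
  expect_error(relative_position(8, 7), "k <= N",
               class = "psitrans_validation_error")
  expect_error(relative_position(0, 7), "k <= N",
               class = "psitrans_validation_error")
})

test_that("coordinate-rule classification recovers every planted category", {
  gn <- get_sim(n_genes = 60)
  for (i in seq_along(gn$events)) {
    ev <- gn$events[[i]]
    tr <- gn$truth[gn$truth$event_id == ev$event_id, ]
    g <- gn$genes[[tr$gene_id]]
    lab <- classify_coding_consequence(ev, g$transcripts[[ev$incl_tx]],
                                       dpsi_sign = tr$dpsi_sign,
                                       genome = gn$genome)
    expect_equal(lab$category, tr$category)
    expect_equal(lab$frame_preserved, tr$frame_preserved)
    expect_equal(lab$k, tr$k)
    expect_equal(lab$N, tr$N)
    expect_true(lab$relative_position > 0 && lab$relative_position <= 100)
  }
})

test_that("insertion vs deletion is oriented by the delta-PSI sign", {
  gn <- get_sim(n_genes = 60)
  ins <- gn$truth[gn$truth$category == "insertion", ][1, ]
  ev <- Filter(function(e) e$event_id == ins$event_id, gn$events)[[1]]
  ref <- gn$genes[[ins$gene_id]]$transcripts[[ev$incl_tx]]
  expect_equal(classify_coding_consequence(ev, ref, 1, gn$genome)$category,
               "insertion")
  expect_equal(classify_coding_consequence(ev, ref, -1, gn$genome)$category,
               "deletion")
  expect_error(classify_coding_consequence(ev, ref, 0, gn$genome), "sign")
})

test_that("classification requires an annotated CDS", {
  g <- make_gene(list(1:10, setdiff(1:10, 5)), 10)
  ev <- enumerate_splice_events(g)[[1]]
  expect_error(classify_coding_consequence(ev, g$transcripts$t1, 1),
               "no CDS")
})

test_that("position histogram partitions its input into bins", {
  gn <- get_sim(n_genes = 60)
  labs <- lapply(seq_along(gn$events), function(i) {
    ev <- gn$events[[i]]
    tr <- gn$truth[gn$truth$event_id == ev$event_id, ]
    classify_coding_consequence(ev, gn$genes[[tr$gene_id]]$transcripts[[ev$incl_tx]],
                                dpsi_sign = tr$dpsi_sign, genome = gn$genome)
  })
  h <- positional_frame_histogram(labs, bins = 10)
  expect_equal(sum(h$count), length(labs))

  one <- labs[[1]]; one$relative_position <- 95; one$category <- "insertion"
  h1 <- positional_frame_histogram(list(one), bins = 10)
  expect_equal(h1$bin[h1$count == 1], "(90,100]")

  h0 <- positional_frame_histogram(list(), bins = 10)
  expect_true(all(h0$count == 0))
})

test_that("the packaged calcium fixture is reproduced", {
  fx <- calcium_events_fixture()
  expect_equal(nrow(fx), 21)
  res <- classify_fixture_events(fx)
  cass <- res$event_type == "cassette"
  # printed in-frame flag, all cassette rows
  expect_equal(ifelse(res$frame_pred[cass], "Y", "N"), res$in_frame[cass])
  # printed effect-on-coding category, all rows
  expect_equal(res$effect_pred, res$effect)
  # MXE rows rely on the documented equal-length partner rule and say so
  expect_equal(res$mxe_partner_assumed, res$event_type == "mutually_exclusive")
  # spot checks against well-known rows
  expect_equal(res$category[res$event_id == "Ppp3ca_ex13"], "insertion")
  expect_equal(res$category[res$event_id == "Cask_ex14"], "deletion")
  expect_equal(res$category[res$event_id == "Camk2d_ex19"], "c_terminal_change")
  expect_equal(res$category[res$event_id == "Chrne_ex5"], "amino_acid_change")
})
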