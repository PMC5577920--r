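test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_genes = 10)
  d1 <- file.path(tempdir(), "sim_rep1"); d2 <- file.path(tempdir(), "sim_rep2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- setdiff(list.files(d1), "manifest.json")  # manifest has a timestamp
  expect_true(length(files) >= 9)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("frame-preserving constraint makes all cassette exons multiples of three", {
  gn <- get_sim(n_genes = 25, seed = 9, frac_frame_preserving = 1)
  for (ev in gn$events) {
    if (ev$type == "cassette") {
      expect_equal((ev$alt$end - ev$alt$start + 1) %% 3, 0)
    }
  }
})

test_that("planted UTR events lie outside the CDS on the correct side", {
  gn <- get_sim(n_genes = 60)
  for (cat in c("utr3_only", "utr5_only")) {
    ids <- gn$truth$event_id[gn$truth$category == cat]
    expect_gt(length(ids), 0)
    for (id in ids) {
      ev <- Filter(function(e) e$event_id == id, gn$events)[[1]]
      tx <- gn$genes[[ev$gene_id]]$transcripts[[ev$incl_tx]]
      s <- ev$alt$strand[1]
      after_cds_3p <- if (s == "+") ev$alt$start > tx$cds_hi
                      else ev$alt$end < tx$cds_lo
      expect_equal(after_cds_3p, cat == "utr3_only")
    }
  }
})

test_that("planted trajectories attain their delta PSI within tolerance", {
  cfg <- sim_config(seed = 42, n_genes = 60)
  gn <- get_sim(n_genes = 60)
  sim <- simulate_timecourse(gn$truth, cfg)
  tc <- cfg$tc
  d <- sim$true_psi[, -1] - sim$true_psi[, -5]
  colnames(d) <- tc$intervals$name
  a <- sim$assignments
  for (i in seq_len(nrow(a))) {
    if (!a$transition[i]) {
      # flat events: all interval changes stay well below the threshold
      expect_lt(max(abs(d[a$event_id[i], ])), 15)
      next
    }
    ivs <- strsplit(a$planted_intervals[i], ",")[[1]]
    planted <- as.numeric(strsplit(a$planted_dpsi[i], ",")[[1]])
    realized <- d[a$event_id[i], ivs]
    expect_lt(max(abs(unname(realized) - planted)), 0.5)
    # planted magnitudes always reach the calling threshold
    expect_true(all(abs(realized) >= 15))
    # no transition leaks into unassigned intervals
    expect_lt(max(abs(d[a$event_id[i], setdiff(tc$intervals$name, ivs)])), 15)
  }
})

test_that("calls on the true PSI matrix recover the planted timing exactly", {
  cfg <- sim_config(seed = 42, n_genes = 60)
  gn <- get_sim(n_genes = 60)
  sim <- simulate_timecourse(gn$truth, cfg)
  calls <- call_splicing_transitions(sim$true_psi, cfg$tc)
  merged <- merge(calls$timing, sim$assignments, by.x = "id",
                  by.y = "event_id")
  expect_equal(merged$timing_class, merged$planted_class)
})

test_that("junction counts follow the planted PSI", {
  cfg <- sim_config(seed = 3, n_genes = 5)
  m <- matrix(100, 2, 5,
              dimnames = list(c("a", "b"), cfg$tc$labels))
  cts <- simulate_counts(m, cfg)
  expect_true(all(cts$excl == 0))  # PSI 100: no exclusion reads

  cfg_deep <- sim_config(seed = 3, n_genes = 5, depth = 1e5)
  m2 <- matrix(37.5, 1, 5, dimnames = list("a", cfg$tc$labels))
  cts2 <- simulate_counts(m2, cfg_deep)
  est <- psi_from_junction_counts(cts2$incl, cts2$excl)$psi
  expect_true(all(abs(est - 37.5) < 1))
})

test_that("planted expression fold changes are realized on average", {
  cfg <- sim_config(seed = 12, n_genes = 80, de_fraction = 1,
                    de_log2fc_range = log2(c(2.5, 2.5)))
  ex <- simulate_expression(sprintf("g%03d", 1:80), cfg)
  tc <- cfg$tc
  ratios <- vapply(seq_len(80), function(g) {
    iv <- match(ex$truth$interval[g], tc$intervals$name)
    (ex$expr[g, iv + 1] + 0.1) / (ex$expr[g, iv] + 0.1)
  }, numeric(1))
  up <- ex$truth$direction == "increased"
  expect_gt(sum(up), 10)
  # median realized fold change near the planted 2.5 despite NB noise
  expect_equal(median(ratios[up]), 2.5, tolerance = 0.25)
  expect_equal(median(ratios[!up]), 1 / 2.5, tolerance = 0.25)
})

test_that("ortholog pairs recover the planted conservation at zero noise", {
  cfg0 <- sim_config(seed = 21, n_genes = 60, dpsi_noise_sd = 0,
                     conservation_rate = 1)
  gn <- get_sim(n_genes = 60, seed = 21)
  sim <- simulate_timecourse(gn$truth, cfg0)
  pairs <- simulate_ortholog_pairs(sim$true_psi, cfg0)
  expect_gt(nrow(pairs), 5)
  s <- conservation_summary(pairs)
  expect_equal(s$fraction, 1)

  cfg1 <- sim_config(seed = 21, n_genes = 60, dpsi_noise_sd = 0)
  pairs1 <- simulate_ortholog_pairs(sim$true_psi, cfg1)
  s1 <- conservation_summary(pairs1)
  expect_equal(s1$n_conserved, sum(pairs1$conserved_true))
})

test_that("generated GTFs re-parse without warnings", {
  d <- file.path(tempdir(), "sim_gtf")
  simulate_dataset(sim_config(seed = 8, n_genes = 6), d)
  expect_no_warning(read_gtf(file.path(d, "genes.gtf")))
  unlink(d, recursive = TRUE)
})
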