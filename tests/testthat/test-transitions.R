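tc5 <- developmental_timecourse()

traj_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("e", seq_along(rows)), tc5$labels)
  m
}

test_that("splicing transitions are called and time-classified per interval", {
  m <- traj_matrix(c(10, 12, 40, 42, 44),
                   c(10, 30, 60, 60, 60),
                   c(50, 55, 60, 58, 52))
  calls <- call_splicing_transitions(m, tc5, tau = 15)
  expect_equal(calls$timing$timing_class,
               c("single_interval", "multi_interval", "none"))
  expect_equal(calls$timing$single_interval[1], "PN2-PN14")
  e1 <- calls$calls[calls$calls$id == "e1", ]
  expect_equal(e1$pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(e1$direction[2], "increased")
})

test_that("the 15-point threshold is inclusive at the boundary", {
  m <- traj_matrix(c(10, 25, 25, 25, 25),      # exactly 15.0
                   c(10, 24.999, 24.999, 24.999, 24.999))
  calls <- call_splicing_transitions(m, tc5, tau = 15)
  expect_true(calls$calls$pass[calls$calls$id == "e1" &
                               calls$calls$interval == "E18.5-PN2"])
  expect_false(any(calls$calls$pass[calls$calls$id == "e2"]))
})

test_that("missing PSI makes an interval uncallable, not failed", {
  m <- traj_matrix(c(10, NA, 40, 42, 44))
  calls <- call_splicing_transitions(m, tc5)
  cc <- calls$calls[calls$calls$id == "e1", ]
  expect_equal(cc$callable, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(calls$timing$n_callable, 2)
})

test_that("timing summary reports the single-interval fraction over called events", {
  m <- traj_matrix(c(10, 40, 40, 40, 40),
                   c(10, 10, 40, 40, 40),
                   c(10, 10, 10, 40, 40),
                   c(10, 40, 80, 80, 80),
                   c(50, 52, 54, 52, 50))
  calls <- call_splicing_transitions(m, tc5)
  s <- classify_transition_timing(calls, tc5)
  expect_equal(s$n_called, 4)
  expect_equal(s$n_single, 3)
  expect_equal(s$single_fraction, 0.75)
  expect_equal(sum(s$per_interval$n_single_specific), 3)

  flat <- call_splicing_transitions(traj_matrix(c(50, 52, 54, 52, 50)), tc5)
  s0 <- classify_transition_timing(flat, tc5)
  expect_equal(s0$n_called, 0)
  expect_equal(s0$single_fraction, 0)
})

test_that("timing classes partition the events and calls are order invariant", {
  gn <- get_sim(n_genes = 30)
  sim <- simulate_timecourse(gn$truth, sim_config(seed = 42, n_genes = 30))
  calls <- call_splicing_transitions(sim$true_psi, tc5)
  expect_equal(sum(table(calls$timing$timing_class)), nrow(sim$true_psi))

  perm <- sample(nrow(sim$true_psi))
  calls2 <- call_splicing_transitions(sim$true_psi[perm, ], tc5)
  reord <- calls2$timing[match(calls$timing$id, calls2$timing$id), ]
  rownames(reord) <- NULL
  expect_equal(reord, calls$timing)

  # adding fully-missing events does not perturb existing calls
  extra <- rbind(sim$true_psi, matrix(NA_real_, 2, 5,
                                      dimnames = list(c("x1", "x2"), tc5$labels)))
  calls3 <- call_splicing_transitions(extra, tc5)
  expect_equal(calls3$timing[seq_len(nrow(sim$true_psi)), ], calls$timing)
  expect_equal(calls3$timing$timing_class[calls3$timing$id == "x1"], "none")
})

test_that("interval counts normalize by duration in days", {
  r <- rate_normalize(c(481, 3315, 636, 1496), tc5)
  expect_equal(r$rate_per_day[r$interval == "PN2-PN14"], 3315 / 12)
  expect_equal(r$rate_per_day[r$interval == "PN2-PN14"], 276.25)

  # equal counts, unequal durations: rates inversely ordered
  expect_equal(order(rate_normalize(rep(100, 4), tc5)$rate_per_day),
               order(-tc5$intervals$duration_days))

  tc1 <- timecourse(c("a", "b"), c(0, 1))
  expect_equal(rate_normalize(7, tc1)$rate_per_day, 7)
  expect_error(rate_normalize(c(1, 2, 3), tc5), "one count per interval")
})

test_that("expression changes use a floored fold-change rule", {
  m <- matrix(c(10, 25, 25, 25, 25,
                10, 6, 6, 6, 6,
                0, 5, 5, 5, 5), 3, 5, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), tc5$labels))
  calls <- call_expression_changes(m, tc5, fold = 2, floor = 0)
  c1 <- calls$calls[calls$calls$id == "g1" & calls$calls$interval == "E18.5-PN2", ]
  expect_equal(c1$statistic, 2.5)
  expect_true(c1$pass)
  expect_equal(c1$direction, "increased")
  c2 <- calls$calls[calls$calls$id == "g2" & calls$calls$interval == "E18.5-PN2", ]
  expect_equal(c2$statistic, 0.6)
  expect_false(c2$pass)

  calls_f <- call_expression_changes(m, tc5, fold = 2, floor = 1)
  c3 <- calls_f$calls[calls_f$calls$id == "g3" &
                      calls_f$calls$interval == "E18.5-PN2", ]
  expect_equal(c3$statistic, 6)
  expect_true(c3$pass)

  m_bad <- m; m_bad[1, 1] <- -1
  expect_error(call_expression_changes(m_bad, tc5), ">= 0",
               class = "psitrans_validation_error")
})

test_that("AS/DE set overlap reports counts and fractions", {
  ov <- overlap_sets(c("a", "b", "c", "d", "e"), c("a", "x", "y"))
  expect_equal(ov$n_both, 1)
  expect_equal(ov$fraction_as_de, 0.2)
  expect_equal(overlap_sets(c("a", "b"), c("x", "y"))$fraction_as_de, 0)
  expect_equal(overlap_sets(c("a", "b"), c("a", "b", "c"))$fraction_as_de, 1)
})

test_that("hypergeometric enrichment matches an enumeration oracle", {
  universe <- paste0("g", 1:100)
  cmap <- data.frame(gene = paste0("g", 1:10), category = "A")
  hits <- paste0("g", c(1:5, 11:15))  # 5 of 10 hits inside the category
  res <- enrichment_test(hits, cmap, universe)
  # brute-force tail: sum over j >= 5 of C(10,j) C(90,10-j) / C(100,10)
  oracle <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(res$p[res$category == "A"], oracle, tolerance = 1e-12)

  # category equal to the universe: p = 1
  cmap_all <- data.frame(gene = universe, category = "ALL")
  expect_equal(enrichment_test(hits, cmap_all, universe)$p, 1)

  # zero category hits: p = 1 for over-representation
  cmap_b <- data.frame(gene = paste0("g", 50:59), category = "B")
  expect_equal(enrichment_test(paste0("g", 1:10), cmap_b, universe)$p, 1)

  expect_error(enrichment_test("g1", cmap, character()), "empty universe")
  expect_error(enrichment_test("nope", cmap, universe), "subset")
})
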