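STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(as.vector(outer(c("T", "C", "A", "G"),
                                              c("T", "C", "A", "G"), paste0)),
                              c("T", "C", "A", "G"), paste0))
NON_STOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_bases <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
random_codons <- function(n) {
  if (n <= 0) return("")
  paste(sample(NON_STOP_CODONS, n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults encode the
#' emulated study design: a five-stage postnatal time course, junction read
#' depth 200 per event and sample, a 0.67 single-interval fraction among
#' transitioning events, interval weights following the observed timing
#' distribution (most transitions in the PN2-PN14 window), a 135/223
#' frame-preserving share, and an 11/17 ortholog conservation rate with
#' 5-point cross-species delta-PSI noise.
#'
#' @param seed Integer seed (mandatory); all stages derive independent
#'   sub-streams from it, so e.g. changing `depth` does not change the gene
#'   models.
#' @param n_genes Number of genes; each gene carries exactly one planted
#'   event.
#' @param exon_count_range,exon_length_range,intron_length_range Ranges (bp)
#'   for the inclusion transcript's exon count and exon/intron lengths.
#' @param frac_mutually_exclusive Fraction of events planted as mutually
#'   exclusive pairs (the rest are cassettes).
#' @param category_weights Named sampling weights over the cassette
#'   consequence categories.
#' @param frac_frame_preserving Probability that a frame-neutral alternative
#'   exon (UTR-only, start-codon) is a multiple of three; at the extremes 0/1
#'   the category weights are re-normalized so every cassette exon is
#'   frame-shifting/frame-preserving respectively.
#' @param tc A [timecourse()].
#' @param transition_fraction Fraction of events that transition at all.
#' @param single_interval_fraction Among transitioning events, fraction
#'   confined to a single interval.
#' @param interval_weights Assignment weights over the intervals.
#' @param dpsi_range_single,dpsi_range_multi Planted |delta PSI| magnitude
#'   ranges (points) for single- and multi-interval events.
#' @param flat_jitter Maximum |jitter| (points) added per time point to
#'   non-transitioning trajectories (kept below half the 15-point calling
#'   threshold).
#' @param depth Mean junction read depth per event and sample (Poisson).
#' @param expr_mean_log,expr_sdlog,expr_size Expression baseline (log-normal
#'   mean/sd on the log scale) and negative-binomial size.
#' @param de_fraction,de_log2fc_range Fraction of genes with a planted
#'   expression fold change, and its |log2 FC| range.
#' @param conservation_rate Fraction of ortholog pairs planted as conserved.
#' @param dpsi_noise_sd SD (points) of cross-species delta-PSI noise.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_genes = 500,
                       exon_count_range = c(10, 16),
                       exon_length_range = c(90, 240),
                       intron_length_range = c(80, 160),
                       frac_mutually_exclusive = 0.15,
                       category_weights = c(insertion = 0.33, deletion = 0.22,
                                            stop_codon = 0.015,
                                            start_codon = 0.015,
                                            utr5_only = 0.05, utr3_only = 0.07,
                                            n_terminal_change = 0.08,
                                            c_terminal_change = 0.17,
                                            amino_acid_change = 0.05),
                       frac_frame_preserving = 135 / 223,
                       tc = developmental_timecourse(),
                       transition_fraction = 0.8,
                       single_interval_fraction = 0.67,
                       interval_weights = c(13, 32, 5, 16),
                       dpsi_range_single = c(25, 65),
                       dpsi_range_multi = c(20, 45),
                       flat_jitter = 2.5,
                       depth = 200,
                       expr_mean_log = log(30), expr_sdlog = 1,
                       expr_size = 25,
                       de_fraction = 0.3, de_log2fc_range = c(1.5, 3),
                       conservation_rate = 11 / 17,
                       dpsi_noise_sd = 5) {
  assert_that(!missing(seed) && length(seed) == 1 && is.finite(seed),
              "seed is mandatory")
  fracs <- c(frac_mutually_exclusive, frac_frame_preserving,
             transition_fraction, single_interval_fraction, de_fraction,
             conservation_rate)
  assert_that(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1]")
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(exon_count_range[1] >= 10,
              "need >= 10 exons so terminal-quintile categories are plantable")
  w <- category_weights
  fs <- c("n_terminal_change", "c_terminal_change", "amino_acid_change")
  fp <- c("insertion", "deletion", "stop_codon")
  if (frac_frame_preserving == 1) w[fs] <- 0
  if (frac_frame_preserving == 0) w[fp] <- 0
  w <- w / sum(w)
  iw <- interval_weights / sum(interval_weights)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 exon_count_range = exon_count_range,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 frac_mutually_exclusive = frac_mutually_exclusive,
                 category_weights = w,
                 frac_frame_preserving = frac_frame_preserving,
                 tc = tc, transition_fraction = transition_fraction,
                 single_interval_fraction = single_interval_fraction,
                 interval_weights = iw,
                 dpsi_range_single = dpsi_range_single,
                 dpsi_range_multi = dpsi_range_multi,
                 flat_jitter = flat_jitter, depth = depth,
                 expr_mean_log = expr_mean_log, expr_sdlog = expr_sdlog,
                 expr_size = expr_size, de_fraction = de_fraction,
                 de_log2fc_range = de_log2fc_range,
                 conservation_rate = conservation_rate,
                 dpsi_noise_sd = dpsi_noise_sd),
            class = "sim_config")
}

# one attempt at constructing a gene with a planted event of the given
# category; returns NULL only via the caller's oracle check
build_gene_attempt <- function(gid, chrom, category, cfg) {
  mxe <- category == "mutually_exclusive_swap"
  N <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
  M <- if (mxe) N + 1L else N
  if (mxe) {
    j <- sample(3:(N - 2), 1)
    k <- j; chain_alt <- c(j, j + 1L); a_chain <- 2L; b_chain <- M
  } else {
    k <- switch(category,
                utr5_only = 2L,
                utr3_only = N - 1L,
                start_codon = 3L,
                n_terminal_change = 2L,
                c_terminal_change = N - 1L,
                amino_acid_change = sample(seq(ceiling(0.25 * N),
                                               floor(0.75 * N)), 1),
                sample(3:(N - 2), 1))
    chain_alt <- k
    a_chain <- switch(category, utr5_only = 3L, start_codon = k,
                      n_terminal_change = 1L, 2L)
    b_chain <- switch(category, utr3_only = N - 2L, N)
  }
  lr <- cfg$exon_length_range
  el <- sample(lr[1]:lr[2], M, replace = TRUE)
  if (mxe) el[j + 1L] <- el[j]
  fp_req <- switch(category,
                   insertion = TRUE, deletion = TRUE, stop_codon = TRUE,
                   n_terminal_change = FALSE, c_terminal_change = FALSE,
                   amino_acid_change = FALSE, NA)
  if (is.na(fp_req) && !mxe)
    fp_req <- stats::runif(1) < cfg$frac_frame_preserving
  if (isTRUE(fp_req) && !mxe) el[k] <- el[k] - el[k] %% 3L
  if (isFALSE(fp_req) && el[k] %% 3L == 0L) el[k] <- el[k] + 1L
  il <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
               M - 1, replace = TRUE)

  incl_chain <- setdiff(seq_len(M), if (mxe) j + 1L else integer(0))
  o_a <- if (category == "start_codon") sample(6:(el[a_chain] - 15L), 1)
         else sample(6:30, 1)
  u_b <- sample(10:30, 1)
  seg <- integer(M)
  for (i in incl_chain) {
    seg[i] <- if (i < a_chain || i > b_chain) 0L
              else if (i == a_chain) el[i] - o_a
              else if (i == b_chain) el[i] - u_b
              else el[i]
  }
  seg[b_chain] <- seg[b_chain] - sum(seg) %% 3L
  ncod <- sum(seg) %/% 3L
  cds_seq <- paste0("ATG", random_codons(ncod - 2L), "TAA")

  # CDS offset (nt, 0-based) at which each inclusion-chain exon begins
  off_before <- integer(M)
  cum <- 0L
  for (i in incl_chain) { off_before[i] <- cum; cum <- cum + seg[i] }

  if (category == "stop_codon") {
    S_k <- off_before[k]
    i_min <- (S_k + 5L) %/% 3L          # first codon fully inside the exon
    i_max <- (S_k + el[k]) %/% 3L
    pick <- sample(max(i_min + 1L, 3L):min(i_max - 1L, ncod - 2L), 1)
    substr(cds_seq, 3L * pick - 2L, 3L * pick) <- "TAA"
  }

  seqs <- character(M)
  cum <- 0L
  for (i in seq_len(M)) {
    if (mxe && i == j + 1L) {
      lead <- (3L - off_before[j] %% 3L) %% 3L
      nc2 <- (el[i] - lead) %/% 3L
      seqs[i] <- paste0(random_bases(lead), random_codons(nc2),
                        random_bases(el[i] - lead - 3L * nc2))
    } else if (seg[i] > 0L) {
      part <- substr(cds_seq, cum + 1L, cum + seg[i]); cum <- cum + seg[i]
      pre <- if (i == a_chain) random_bases(o_a) else ""
      seqs[i] <- paste0(pre, part, random_bases(el[i] - seg[i] - nchar(pre)))
    } else {
      seqs[i] <- random_bases(el[i])
    }
  }

  pad <- 50L
  ts_start <- integer(M); ts_end <- integer(M)
  pos <- pad
  parts <- list(random_bases(pad))
  for (i in seq_len(M)) {
    ts_start[i] <- pos + 1L; ts_end[i] <- pos + el[i]
    parts[[length(parts) + 1L]] <- seqs[i]; pos <- pos + el[i]
    if (i < M) { parts[[length(parts) + 1L]] <- random_bases(il[i]); pos <- pos + il[i] }
  }
  parts[[length(parts) + 1L]] <- random_bases(pad)
  G <- paste(unlist(parts), collapse = "")
  Lg <- pos + pad
  strand <- sample(c("+", "-"), 1)
  if (strand == "+") { g_start <- ts_start; g_end <- ts_end }
  else { g_start <- Lg - ts_end + 1L; g_end <- Lg - ts_start + 1L }
  chrom_seq <- if (strand == "+") G else revcomp(G)

  cds_ts <- c(ts_start[a_chain] + o_a, ts_start[b_chain] + seg[b_chain] - 1L)
  cds_g <- if (strand == "+") cds_ts else Lg - cds_ts + 1L
  cds_lo <- min(cds_g); cds_hi <- max(cds_g)

  excl_chain <- setdiff(seq_len(M), chain_alt[1])
  mk_tx <- function(id, idx, with_cds = TRUE) {
    transcript(id, exon_intervals(chrom, g_start[idx], g_end[idx], strand),
               cds_lo = if (with_cds) cds_lo else NA_integer_,
               cds_hi = if (with_cds) cds_hi else NA_integer_)
  }
  t_in <- mk_tx(paste0(gid, ".t1"), incl_chain)
  t_ex <- mk_tx(paste0(gid, ".t2"), excl_chain,
                with_cds = category != "start_codon")
  gene <- gene_model(gid, list(t_in, t_ex))

  alt <- exon_intervals(chrom, g_start[chain_alt], g_end[chain_alt], strand)
  up_i <- chain_alt[1] - 1L; down_i <- max(chain_alt) + 1L
  ev <- splice_event(sprintf("%s|%s|%s:%d-%d", gid,
                             if (mxe) "MXE" else "SE", chrom,
                             min(alt$start), max(alt$end)),
                     gid, if (mxe) "mutually_exclusive" else "cassette",
                     alt,
                     exon_intervals(chrom, g_start[up_i], g_end[up_i], strand),
                     exon_intervals(chrom, g_start[down_i], g_end[down_i], strand),
                     t_in$id, t_ex$id)
  list(gene = gene, event = ev, chrom_seq = chrom_seq,
       k = k, N = N, frame = frame_preserved(ev))
}

#' Simulate gene models, sequences and planted splice events
#'
#' Each gene gets a random exon chain with a CDS spanning internal exons,
#' one planted cassette or mutually exclusive event of a known
#' coding-consequence category, and a nucleotide sequence constructed so the
#' annotated CDS translates without premature stops in the clean isoform
#' (for planted stop-codon events, the included exon carries the stop by
#' design). Every gene is verified against the translation oracle at build
#' time; infeasible draws are retried and eventually raise an error. The
#' first `n` genes (one per category) guarantee category coverage; the rest
#' are sampled by the configured weights.
#'
#' @param cfg A [sim_config()].
#' @return List: `genes` (named list of [gene_model()]), `genome` (named
#'   character vector of chromosome sequences), `events` (list of
#'   [splice_event()]), `truth` (data.frame: `event_id`, `gene_id`,
#'   `category`, `dpsi_sign`, `k`, `N`, `frame_preserved`).
#' @export
simulate_genome <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 1))
  cats <- names(cfg$category_weights)
  covered <- c(cats[cfg$category_weights > 0],
               if (cfg$frac_mutually_exclusive > 0) "mutually_exclusive_swap")
  draw_cat <- function(i) {
    if (i <= length(covered)) return(covered[i])
    if (stats::runif(1) < cfg$frac_mutually_exclusive) "mutually_exclusive_swap"
    else sample(cats, 1, prob = cfg$category_weights)
  }
  genes <- list(); genome <- character(); events <- list()
  truth <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    chrom <- paste0("chr_", gid)
    category <- draw_cat(g)
    dpsi_sign <- switch(category, insertion = 1L, deletion = -1L,
                        sample(c(-1L, 1L), 1))
    built <- NULL
    for (try in 1:30) {
      cand <- build_gene_attempt(gid, chrom, category, cfg)
      chk <- verify_against_oracle(cand$event, cand$gene,
                                   stats::setNames(cand$chrom_seq, chrom),
                                   dpsi_sign)
      if (chk$agree && chk$category_oracle == category) { built <- cand; break }
    }
    assert_that(!is.null(built), "could not plant a ", category,
                " event for ", gid, " after 30 attempts")
    genes[[gid]] <- built$gene
    genome[[chrom]] <- built$chrom_seq
    events[[built$event$event_id]] <- built$event
    truth[[g]] <- data.frame(event_id = built$event$event_id, gene_id = gid,
                             category = category, dpsi_sign = dpsi_sign,
                             k = built$k, N = built$N,
                             frame_preserved = built$frame,
                             stringsAsFactors = FALSE)
  }
  list(genes = genes, genome = genome, events = unname(events),
       truth = do.call(rbind, truth))
}

#' Simulate true PSI trajectories over the time course
#'
#' Transitioning events follow logistic steps centered in their assigned
#' interval(s), scaled so the planted delta PSI between the interval's two
#' sampled time points is attained within 0.5 points; non-transitioning
#' events are flat with small (< `flat_jitter`) per-point jitter. Planted
#' magnitudes are at least 15 points, so calls on the true matrix recover
#' the planted timing exactly.
#'
#' @param truth Truth table from [simulate_genome()] (only `event_id` and
#'   `dpsi_sign` are used).
#' @param cfg A [sim_config()].
#' @return List: `true_psi` (events-by-time-points percent matrix),
#'   `assignments` (data.frame: `event_id`, `transition`, `planted_class`,
#'   `planted_intervals`, `planted_dpsi`).
#' @export
simulate_timecourse <- function(truth, cfg) {
  set.seed(sub_seed(cfg$seed, 2))
  tc <- cfg$tc
  ages <- tc$ages
  n_iv <- nrow(tc$intervals)
  mids <- (ages[-1] + ages[-length(ages)]) / 2
  widths <- diff(ages)
  eps <- 0.005
  steep <- 2 * log((1 - eps) / eps) / widths
  n <- nrow(truth)
  m <- matrix(NA_real_, n, length(ages),
              dimnames = list(truth$event_id, tc$labels))
  assignments <- vector("list", n)
  for (i in seq_len(n)) {
    transition <- stats::runif(1) < cfg$transition_fraction
    if (!transition) {
      base <- stats::runif(1, 5, 95)
      m[i, ] <- base + stats::runif(length(ages), -cfg$flat_jitter,
                                    cfg$flat_jitter)
      assignments[[i]] <- data.frame(event_id = truth$event_id[i],
                                     transition = FALSE,
                                     planted_class = "none",
                                     planted_intervals = "",
                                     planted_dpsi = "",
                                     stringsAsFactors = FALSE)
      next
    }
    single <- stats::runif(1) < cfg$single_interval_fraction
    if (single) {
      iv <- sample(n_iv, 1, prob = cfg$interval_weights)
      d <- truth$dpsi_sign[i] *
        stats::runif(1, cfg$dpsi_range_single[1], cfg$dpsi_range_single[2])
    } else {
      iv <- sort(sample(n_iv, 2, prob = cfg$interval_weights))
      d <- c(truth$dpsi_sign[i], sample(c(-1, 1), 1)) *
        stats::runif(2, cfg$dpsi_range_multi[1], cfg$dpsi_range_multi[2])
    }
    levels <- cumsum(c(0, d))
    lo <- 1 - min(levels); hi <- 99 - max(levels)
    base <- stats::runif(1, lo, hi)
    traj <- rep(base, length(ages))
    for (q in seq_along(iv)) {
      amp <- d[q] / (1 - 2 * eps)
      traj <- traj + amp * logistic(steep[iv[q]] * (ages - mids[iv[q]]))
    }
    m[i, ] <- pmin(99.5, pmax(0.5, traj))
    assignments[[i]] <- data.frame(event_id = truth$event_id[i],
                                   transition = TRUE,
                                   planted_class = if (single) "single_interval"
                                                   else "multi_interval",
                                   planted_intervals =
                                     paste(tc$intervals$name[iv], collapse = ","),
                                   planted_dpsi =
                                     paste(round(d, 2), collapse = ","),
                                   stringsAsFactors = FALSE)
  }
  list(true_psi = m, assignments = do.call(rbind, assignments))
}

#' Simulate junction counts from true PSI
#'
#' Per event and sample, total informative depth is Poisson(`depth`) and the
#' inclusion count binomial with the true PSI as success probability.
#'
#' @param true_psi Events-by-samples percent matrix.
#' @param cfg A [sim_config()].
#' @return Long-format `data.frame`: `event_id`, `sample`, `incl`, `excl`.
#' @export
simulate_counts <- function(true_psi, cfg) {
  set.seed(sub_seed(cfg$seed, 3))
  assert_that(all(true_psi >= 0 & true_psi <= 100), "true PSI must be in [0, 100]")
  long <- expand.grid(event_id = rownames(true_psi),
                      sample = colnames(true_psi),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- true_psi[cbind(long$event_id, long$sample)] / 100
  depth <- stats::rpois(nrow(long), cfg$depth)
  long$incl <- stats::rbinom(nrow(long), depth, p)
  long$excl <- depth - long$incl
  long[order(long$event_id, match(long$sample, colnames(true_psi))), ,
       drop = FALSE]
}

#' Simulate a gene expression table with planted fold changes
#'
#' Gene baselines are log-normal; a planted fraction of genes steps up or
#' down by a planted log2 fold change at one assigned interval; observed
#' values are negative-binomial around the expected trajectory.
#'
#' @param gene_ids Character vector of gene ids.
#' @param cfg A [sim_config()].
#' @return List: `expr` (genes-by-samples matrix), `truth` (data.frame:
#'   `gene_id`, `de`, `interval`, `direction`, `log2fc`).
#' @export
simulate_expression <- function(gene_ids, cfg) {
  set.seed(sub_seed(cfg$seed, 4))
  tc <- cfg$tc
  n <- length(gene_ids); ns <- length(tc$labels)
  mu <- stats::rlnorm(n, cfg$expr_mean_log, cfg$expr_sdlog)
  de <- stats::runif(n) < cfg$de_fraction
  iv <- sample(nrow(tc$intervals), n, replace = TRUE,
               prob = cfg$interval_weights)
  dirn <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- stats::runif(n, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
  expected <- matrix(mu, n, ns)
  for (g in which(de)) {
    expected[g, (iv[g] + 1):ns] <- mu[g] * 2^(dirn[g] * lfc[g])
  }
  expr <- matrix(stats::rnbinom(n * ns, mu = expected, size = cfg$expr_size),
                 n, ns, dimnames = list(gene_ids, tc$labels))
  list(expr = expr,
       truth = data.frame(gene_id = gene_ids, de = de,
                          interval = ifelse(de, tc$intervals$name[iv], ""),
                          direction = ifelse(de,
                                             ifelse(dirn > 0, "increased",
                                                    "decreased"), ""),
                          log2fc = ifelse(de, round(dirn * lfc, 3), 0),
                          stringsAsFactors = FALSE))
}

#' Simulate ortholog delta-PSI pairs
#'
#' Pairs are built for events whose true species-A delta PSI between the two
#' anchor time points reaches 15 points. Conserved pairs (planted at
#' `conservation_rate`) get the species-A value plus Gaussian noise;
#' non-conserved pairs are sign-flipped (plus noise) or shrunk below the
#' calling threshold.
#'
#' @param true_psi Events-by-samples percent matrix.
#' @param cfg A [sim_config()].
#' @param from,to Anchor time-point labels for the species-A delta PSI.
#' @return Data frame: `event_id`, `dpsi_a`, `dpsi_b`, `conserved_true`.
#' @export
simulate_ortholog_pairs <- function(true_psi, cfg, from = "PN2", to = "PN28") {
  set.seed(sub_seed(cfg$seed, 5))
  dpsi_a <- true_psi[, to] - true_psi[, from]
  keep <- abs(dpsi_a) >= 15
  dpsi_a <- dpsi_a[keep]
  n <- sum(keep)
  conserved <- stats::runif(n) < cfg$conservation_rate
  flip <- stats::runif(n) < 0.5
  noise <- stats::rnorm(n, 0, cfg$dpsi_noise_sd)
  dpsi_b <- ifelse(conserved, dpsi_a + noise,
                   ifelse(flip, -dpsi_a + noise, stats::runif(n, -12, 12)))
  data.frame(event_id = rownames(true_psi)[keep],
             dpsi_a = unname(dpsi_a),
             dpsi_b = pmin(100, pmax(-100, unname(dpsi_b))),
             conserved_true = conserved,
             stringsAsFactors = FALSE, row.names = NULL)
}
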