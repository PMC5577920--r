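SIM_CONFIG_KEYS <- c("seed", "n_genes", "exon_count_range",
                     "exon_length_range", "intron_length_range",
                     "frac_mutually_exclusive", "frac_frame_preserving",
                     "timepoints", "ages", "transition_fraction",
                     "single_interval_fraction", "interval_weights",
                     "dpsi_range_single", "dpsi_range_multi", "flat_jitter",
                     "depth", "expr_mean_log", "expr_sdlog", "expr_size",
                     "de_fraction", "de_log2fc_range", "conservation_rate",
                     "dpsi_noise_sd")

#' Read / write a simulation config as a plain-text key-value file
#'
#' One `key = value` pair per line; vector values are comma-separated;
#' `timepoints`/`ages` define the time course. Unknown keys raise an error
#' naming the valid keys.
#'
#' @param path File path.
#' @param cfg A [sim_config()] (write).
#' @return A [sim_config()] (read); `path` invisibly (write).
#' @export
read_sim_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  bad <- setdiff(keys, SIM_CONFIG_KEYS)
  assert_that(length(bad) == 0, "unknown config key(s): ",
              paste(bad, collapse = ", "), "; valid keys are: ",
              paste(SIM_CONFIG_KEYS, collapse = ", "))
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[2], "\\s*,\\s*")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  }), keys)
  args <- vals[setdiff(names(vals), c("timepoints", "ages"))]
  if (!is.null(vals$timepoints)) {
    args$tc <- timecourse(as.character(vals$timepoints), vals$ages)
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  fmt <- function(x) paste(x, collapse = ",")
  keys <- setdiff(SIM_CONFIG_KEYS, c("timepoints", "ages"))
  lines <- c(vapply(keys, function(k) paste(k, "=", fmt(cfg[[k]])),
                    character(1)),
             paste("timepoints =", fmt(cfg$tc$labels)),
             paste("ages =", fmt(cfg$tc$ages)))
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(outdir, subcommand, params, inputs = character()) {
  manifest <- list(tool = "psitrans",
                   version = as.character(utils::packageVersion("psitrans")),
                   subcommand = subcommand,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   params = params,
                   inputs = if (length(inputs))
                     data.frame(path = basename(inputs),
                                md5 = unname(tools::md5sum(inputs)),
                                stringsAsFactors = FALSE)
                   else list())
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

check_outdir <- function(outdir) {
  parent <- dirname(normalizePath(outdir, mustWork = FALSE))
  assert_that(dir.exists(parent),
              "parent directory of outdir does not exist: ", parent)
  if (!dir.exists(outdir)) dir.create(outdir)
  invisible(outdir)
}

#' Generate a full synthetic dataset on disk
#'
#' Runs the whole generator ([simulate_genome()], [simulate_timecourse()],
#' [simulate_counts()], [simulate_expression()],
#' [simulate_ortholog_pairs()]) and writes: `genes.gtf`, `genome.fa`,
#' `events.tsv`, `junction_counts.tsv`, `expression.tsv`,
#' `ortholog_pairs.tsv`, `truth_events.tsv`, `truth_psi.tsv`,
#' `truth_expression.tsv`, `config.txt` and `manifest.json`. Identical
#' configs (seed included) reproduce identical files.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (its parent must exist).
#' @return Invisibly, the list of generated in-memory objects.
#' @export
simulate_dataset <- function(cfg, outdir) {
  check_outdir(outdir)
  gn <- simulate_genome(cfg)
  tcres <- simulate_timecourse(gn$truth, cfg)
  counts <- simulate_counts(tcres$true_psi, cfg)
  ex <- simulate_expression(gn$truth$gene_id, cfg)
  pairs <- simulate_ortholog_pairs(tcres$true_psi, cfg)

  p <- function(f) file.path(outdir, f)
  write_gtf(gn$genes, p("genes.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gn$genome),
                              p("genome.fa"))
  write_events_tsv(gn$events, p("events.tsv"), genes = gn$genes)
  utils::write.table(counts, p("junction_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(ex$expr), ex$expr,
                                check.names = FALSE),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pairs, p("ortholog_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- merge(gn$truth, tcres$assignments, by = "event_id", sort = FALSE)
  utils::write.table(truth, p("truth_events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(event_id = rownames(tcres$true_psi),
                                round(tcres$true_psi, 3), check.names = FALSE),
                     p("truth_psi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ex$truth, p("truth_expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sim_config(cfg, p("config.txt"))
  write_manifest(outdir, "simulate", params = list(seed = cfg$seed,
                                                   n_genes = cfg$n_genes))
  invisible(list(genome = gn, timecourse = tcres, counts = counts,
                 expression = ex, pairs = pairs))
}

require_file <- function(dir, f, stage) {
  path <- file.path(dir, f)
  assert_that(file.exists(path), stage, ": required input file missing: ", path)
  path
}

#' Run the full analysis pipeline on a dataset directory
#'
#' PSI quantification from junction counts, splicing and expression
#' transition calling with timing classification and duration-normalized
#' rates, AS/DE overlap, ORF-impact classification of events passing the
#' delta-PSI filter between the anchor time points (with the
#' constitutive-exon filter), and conservation scoring of the ortholog
#' pairs. Writes per-stage TSVs plus a manifest into `outdir`.
#'
#' @param dataset_dir Directory produced by [simulate_dataset()] (or
#'   following the same layout).
#' @param outdir Output directory (parent must exist).
#' @param tau Delta-PSI threshold in points (default 15).
#' @param fold Expression fold-change threshold (default 2).
#' @param floor Expression pseudo-value (default 0.1).
#' @param min_constitutive Minimum constitutive exons for positional
#'   analysis (default 3).
#' @param bins Position histogram bins (default 10).
#' @param terminal_quintile Terminal fraction for frame-shifting exons
#'   (default 0.2).
#' @param anchor_from,anchor_to Time points bracketing the delta PSI used
#'   for the ORF-impact filter and sign (defaults PN2, PN28).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(dataset_dir, outdir, tau = 15, fold = 2,
                         floor = 0.1, min_constitutive = 3, bins = 10,
                         terminal_quintile = 0.2,
                         anchor_from = "PN2", anchor_to = "PN28") {
  check_outdir(outdir)
  cfg <- read_sim_config(require_file(dataset_dir, "config.txt", "config"))
  tc <- cfg$tc
  p <- function(f) file.path(outdir, f)

  # --- PSI quantification ---------------------------------------------------
  counts <- read_counts_tsv(require_file(dataset_dir, "junction_counts.tsv",
                                         "psi_quant"))
  psi <- psi_matrix(counts, tc$labels)
  write_psi_tsv(psi, p("psi_matrix.tsv"))

  # --- splicing transitions -------------------------------------------------
  spl <- call_splicing_transitions(psi, tc, tau = tau)
  spl_timing <- classify_transition_timing(spl, tc)
  spl_rates <- rate_normalize(stats::setNames(spl_timing$per_interval$n_pass,
                                              spl_timing$per_interval$interval),
                              tc)
  utils::write.table(merge(spl$calls, spl$timing[c("id", "timing_class")],
                           by = "id", sort = TRUE),
                     p("splicing_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- expression transitions -----------------------------------------------
  exdf <- utils::read.delim(require_file(dataset_dir, "expression.tsv",
                                         "expression"),
                            check.names = FALSE)
  expr <- as.matrix(exdf[, tc$labels, drop = FALSE])
  rownames(expr) <- exdf$gene_id
  de <- call_expression_changes(expr, tc, fold = fold, floor = floor)
  de_timing <- classify_transition_timing(de, tc)
  de_rates <- rate_normalize(stats::setNames(de_timing$per_interval$n_pass,
                                             de_timing$per_interval$interval),
                             tc)
  utils::write.table(merge(de$calls, de$timing[c("id", "timing_class")],
                           by = "id", sort = TRUE),
                     p("expression_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summary_df <- rbind(
    data.frame(layer = "splicing", spl_rates,
               n_single_specific = spl_timing$per_interval$n_single_specific),
    data.frame(layer = "expression", de_rates,
               n_single_specific = de_timing$per_interval$n_single_specific))
  utils::write.table(summary_df, p("interval_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- AS/DE overlap --------------------------------------------------------
  evdf <- read_events_tsv(require_file(dataset_dir, "events.tsv", "events"))
  ev_gene <- stats::setNames(evdf$gene_id, evdf$event_id)
  as_genes <- unique(ev_gene[spl$timing$id[spl$timing$n_pass >= 1]])
  de_genes <- de$timing$id[de$timing$n_pass >= 1]
  ov <- overlap_sets(as_genes, de_genes)
  utils::write.table(data.frame(ov), p("overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- ORF impact -----------------------------------------------------------
  genes <- read_gtf(require_file(dataset_dir, "genes.gtf", "orf_impact"))
  genome <- as_genome_chr(Biostrings::readDNAStringSet(
    require_file(dataset_dir, "genome.fa", "orf_impact")))
  names(genome) <- sub("\\s.*", "", names(genome))
  events <- events_from_tsv(evdf)
  d_anchor <- psi$psi[, anchor_to] - psi$psi[, anchor_from]
  labels <- list()
  for (ev in events) {
    dv <- d_anchor[ev$event_id]
    if (is.na(dv) || abs(dv) < tau) next
    g <- genes[[ev$gene_id]]
    if (constitutive_exon_count(g, ev) < min_constitutive) next
    ref <- g$transcripts[[ev$incl_tx]]
    if (is.null(ref) || !has_cds(ref)) next
    labels[[ev$event_id]] <-
      classify_coding_consequence(ev, ref, dpsi_sign = sign(dv),
                                  genome = genome,
                                  terminal_quintile = terminal_quintile)
  }
  cons_tab <- consequence_table(unname(labels))
  hist_tab <- positional_frame_histogram(cons_tab, bins = bins)
  utils::write.table(cons_tab, p("consequences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hist_tab, p("position_histogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- conservation ---------------------------------------------------------
  pairs <- utils::read.delim(require_file(dataset_dir, "ortholog_pairs.tsv",
                                          "conservation"))
  csum <- NULL
  if (nrow(pairs) > 0 &&
      any(!is.na(call_conservation(pairs$dpsi_a, pairs$dpsi_b, tau = tau)))) {
    csum <- conservation_summary(pairs, tau = tau)
    utils::write.table(data.frame(csum), p("conservation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  write_manifest(outdir, "run",
                 params = list(tau = tau, fold = fold, floor = floor,
                               min_constitutive = min_constitutive,
                               bins = bins),
                 inputs = file.path(dataset_dir,
                                    c("junction_counts.tsv", "expression.tsv",
                                      "events.tsv", "genes.gtf", "genome.fa",
                                      "ortholog_pairs.tsv")))
  invisible(list(psi = psi, splicing = spl, splicing_timing = spl_timing,
                 splicing_rates = spl_rates, expression = de,
                 expression_timing = de_timing, expression_rates = de_rates,
                 overlap = ov, consequences = cons_tab,
                 histogram = hist_tab, conservation = csum))
}

report_section <- function(title, body) c(paste("##", title), "", body, "")

#' Render a human-readable report from pipeline outputs
#'
#' Single markdown report with interval counts, single-interval fractions,
#' per-day rates, the consequence-category tally, AS/DE overlap, and the
#' conservation fraction. Missing result files are noted as missing rather
#' than failing; rerunning on identical inputs reproduces an identical
#' report body (no timestamps).
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param path Output path (default `report.md` inside `results_dir`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results_dir, path = file.path(results_dir, "report.md")) {
  grab <- function(f) {
    fp <- file.path(results_dir, f)
    if (file.exists(fp)) utils::read.delim(fp, check.names = FALSE) else NULL
  }
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, function(r) paste(trimws(r), collapse = "\t")))
  }
  missing_note <- function(f) paste0("_section unavailable: ", f, " missing_")
  out <- c("# psitrans pipeline report", "")

  s <- grab("interval_summary.tsv")
  out <- c(out, report_section("Transitions per interval",
                               if (is.null(s)) missing_note("interval_summary.tsv")
                               else fmt_tab(s)))
  sc <- grab("splicing_calls.tsv")
  out <- c(out, report_section("Splicing transition timing",
    if (is.null(sc)) missing_note("splicing_calls.tsv")
    else {
      tcl <- unique(sc[c("id", "timing_class")])
      n_called <- sum(tcl$timing_class != "none")
      if (n_called == 0) "0 events called."
      else sprintf("%d events called; %d single-interval (fraction %.3f), %d multi-interval.",
                   n_called, sum(tcl$timing_class == "single_interval"),
                   sum(tcl$timing_class == "single_interval") / n_called,
                   sum(tcl$timing_class == "multi_interval"))
    }))
  out <- c(out, report_section("Duration-normalized rates (per day)",
    if (is.null(s)) missing_note("interval_summary.tsv")
    else fmt_tab(s[c("layer", "interval", "count", "duration_days",
                     "rate_per_day")])))
  h <- grab("consequences.tsv")
  out <- c(out, report_section("Coding-consequence categories",
    if (is.null(h)) missing_note("consequences.tsv")
    else if (nrow(h) == 0) "0 events classified."
    else fmt_tab(as.data.frame(table(category = h$category),
                               responseName = "count"))))
  ov <- grab("overlap.tsv")
  out <- c(out, report_section("AS/DE gene-set overlap",
                               if (is.null(ov)) missing_note("overlap.tsv")
                               else fmt_tab(ov)))
  cs <- grab("conservation_summary.tsv")
  out <- c(out, report_section("Cross-species conservation",
    if (is.null(cs)) missing_note("conservation_summary.tsv")
    else sprintf("%d of %d callable pairs conserved (fraction %.3f).",
                 cs$n_conserved, cs$n_tested, cs$fraction)))
  writeLines(out, path)
  invisible(path)
}
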