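# toy gene-model builders shared across test files

# a chain of n equal exons in transcription order on one chromosome
chain_exons <- function(n, strand = "+", len = 100, gap = 100,
                        chrom = "chrT", origin = 1001) {
  starts <- origin + (0:(n - 1)) * (len + gap)
  ends <- starts + len - 1
  idx <- if (strand == "-") n:1 else 1:n
  exon_intervals(chrom, starts[idx], ends[idx], strand)
}

# gene whose transcripts are subsets (transcription-order indices) of a chain
make_gene <- function(subsets, n, strand = "+", cds_lo = NA_integer_,
                      cds_hi = NA_integer_, id = "g1", len = 100, gap = 100) {
  chain <- chain_exons(n, strand, len = len, gap = gap)
  # subsets index transcription-order positions along the chain
  txs <- lapply(seq_along(subsets), function(i) {
    transcript(paste0("t", i), chain[sort(subsets[[i]]), , drop = FALSE],
               cds_lo, cds_hi)
  })
  gene_model(id, txs)
}

# cached synthetic dataset so several test files can share one generation
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(n_genes = 60, seed = 42, ...) {
  key <- paste(n_genes, seed, ...)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_genome(sim_config(seed = seed,
                                                    n_genes = n_genes, ...))
  }
  .sim_cache[[key]]
}

write_tmp_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, type, start, end, strand, gene, tx)
}
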