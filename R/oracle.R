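# --- sequence-level helpers -------------------------------------------------

as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    stats::setNames(as.character(genome), names(genome))
  }
}

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates the exon sequences in transcription order; on the minus
#' strand each exon is reverse complemented.
#'
#' @param tx A [transcript()].
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return mRNA sequence (character scalar, sense strand).
#' @export
spliced_seq <- function(tx, genome) {
  genome <- as_genome_chr(genome)
  chrom <- tx$exons$chrom[1]
  assert_that(chrom %in% names(genome), "sequence for ", chrom, " not in genome")
  pieces <- substring(genome[[chrom]], tx$exons$start, tx$exons$end)
  if (tx$exons$strand[1] == "-") pieces <- vapply(pieces, revcomp, character(1))
  paste(pieces, collapse = "")
}

# 1-based position of a genomic base within the spliced mRNA (transcription
# coordinates); NA when the base is not exonic
mrna_position <- function(tx, gpos) {
  offset <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    e <- tx$exons[i, ]
    if (gpos >= e$start && gpos <= e$end) {
      within <- if (e$strand == "+") gpos - e$start + 1L else e$end - gpos + 1L
      return(offset + within)
    }
    offset <- offset + (e$end - e$start + 1L)
  }
  NA_integer_
}

# translate an mRNA from a start position to the first stop codon (standard
# nuclear code); returns the amino acid string without the stop
translate_from <- function(mrna, pos) {
  n <- nchar(mrna)
  if (is.na(pos) || pos > n - 2L) return("")
  starts <- seq.int(pos, n - 2L, by = 3L)
  codons <- substring(mrna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  hit <- which(aa == "*")
  if (length(hit)) aa <- aa[seq_len(hit[1] - 1L)]
  paste(aa, collapse = "")
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d)) d[1] - 1L else n
}

common_suffix_len <- function(a, b) {
  rev1 <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  rev2 <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  common_prefix_len(rev1, rev2)
}

# --- the oracle -------------------------------------------------------------

#' Verify a coding-consequence call by translating both isoforms
#'
#' Independent, sequence-level check of [classify_coding_consequence()]:
#' splices the inclusion and exclusion isoforms, translates both from the
#' annotated start codon, diffs the proteins, maps the empirical difference
#' to a category, and compares with the coordinate-rule call. The empirical
#' mapping is structural: identical proteins mean a UTR-only exon; a missing
#' start in the exclusion isoform means the exon carries the start codon; a
#' truncated inclusion protein (frame preserved) means an introduced stop; a
#' contiguous internal peptide indel means insertion/deletion (oriented by
#' the delta-PSI sign); anything else is a frameshift, assigned to the N-/C-
#' terminal or mid-ORF class by the exon's position quintile.
#'
#' @param event A [splice_event()].
#' @param gene The owning [gene_model()] (must contain the event's inclusion
#'   and exclusion transcripts).
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param dpsi_sign Sign of the developmental delta PSI (orients
#'   insertion/deletion, as in the coordinate rule).
#' @param terminal_quintile As in [classify_coding_consequence()].
#' @return List: `event_id`, `category_rule`, `category_oracle`, `agree`,
#'   `protein_incl`, `protein_excl`.
#' @export
verify_against_oracle <- function(event, gene, genome, dpsi_sign,
                                  terminal_quintile = 0.2) {
  genome <- as_genome_chr(genome)
  incl <- gene$transcripts[[event$incl_tx]]
  excl <- gene$transcripts[[event$excl_tx]]
  assert_that(!is.null(incl) && !is.null(excl),
              "event transcripts not found in gene ", gene$gene_id)
  assert_that(has_cds(incl), "inclusion transcript has no annotated CDS")

  rule <- classify_coding_consequence(event, ref = incl, dpsi_sign = dpsi_sign,
                                      genome = genome,
                                      terminal_quintile = terminal_quintile)
  start_g <- cds_landmarks(incl)$start_pos
  m_in <- spliced_seq(incl, genome)
  m_ex <- spliced_seq(excl, genome)
  p_in_start <- mrna_position(incl, start_g)
  p_ex_start <- mrna_position(excl, start_g)
  assert_that(!is.na(p_in_start),
              "annotated start is not exonic in the inclusion transcript")
  prot_in <- translate_from(m_in, p_in_start)
  prot_ex <- if (is.na(p_ex_start)) NA_character_
             else translate_from(m_ex, p_ex_start)

  k <- match(exon_key(event$alt[1, , drop = FALSE]), exon_key(incl$exons))
  pos <- relative_position(k, nrow(incl$exons))
  fp_len <- frame_preserved(event)

  oracle <-
    if (event$type == "mutually_exclusive") {
      "mutually_exclusive_swap"
    } else if (is.na(prot_ex)) {
      "start_codon"
    } else if (identical(prot_in, prot_ex)) {
      exon <- event$alt[1, , drop = FALSE]
      five_prime <- (exon$end < incl$cds_lo && exon$strand == "+") ||
                    (exon$start > incl$cds_hi && exon$strand == "-")
      if (five_prime) "utr5_only" else "utr3_only"
    } else if (fp_len && nchar(prot_in) < nchar(prot_ex)) {
      "stop_codon"
    } else if (fp_len && nchar(prot_in) > nchar(prot_ex) &&
               common_prefix_len(prot_in, prot_ex) +
               common_suffix_len(prot_in, prot_ex) >= nchar(prot_ex)) {
      if (dpsi_sign > 0) "insertion" else "deletion"
    } else {
      # frameshift: shared prefix then divergent tail
      if (pos <= 100 * terminal_quintile) "n_terminal_change"
      else if (pos >= 100 * (1 - terminal_quintile)) "c_terminal_change"
      else "amino_acid_change"
    }

  list(event_id = event$event_id, category_rule = rule$category,
       category_oracle = oracle, agree = identical(rule$category, oracle),
       protein_incl = prot_in, protein_excl = prot_ex)
}
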