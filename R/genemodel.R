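#' Construct an exon interval table
#'
#' Exons are stored 1-based, closed (the native R/Bioconductor convention),
#' one row per exon, in transcription order: ascending genomic coordinates on
#' the plus strand, descending on the minus strand.
#'
#' @param chrom Sequence (chromosome) name, recycled to the number of exons.
#' @param start,end Genomic coordinates, 1-based closed; `end >= start`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
exon_intervals <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  assert_that(length(start) == length(end), "start and end lengths differ")
  assert_that(all(end >= start), "exon end must be >= start (1-based closed)")
  assert_that(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  data.frame(chrom = rep_len(as.character(chrom), length(start)),
             start = start, end = end,
             strand = rep_len(as.character(strand), length(start)),
             stringsAsFactors = FALSE)
}

exon_width <- function(exons) exons$end - exons$start + 1L

#' Construct a transcript
#'
#' @param id Transcript identifier.
#' @param exons Exon table from [exon_intervals()], in transcription order.
#' @param cds_lo,cds_hi Genomic extent of the coding sequence (lowest and
#'   highest genomic coordinate, stop codon included), or `NA` for
#'   non-coding transcripts. On the minus strand translation starts at
#'   `cds_hi` and ends at `cds_lo`.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, exons, cds_lo = NA_integer_, cds_hi = NA_integer_) {
  assert_that(nrow(exons) >= 1, "transcript needs at least one exon")
  strand <- exons$strand[1]
  assert_that(all(exons$strand == strand) && all(exons$chrom == exons$chrom[1]),
              "transcript '", id, "': exons must share chrom and strand")
  if (nrow(exons) > 1) {
    if (strand == "+") {
      ok <- all(diff(exons$start) > 0) && all(exons$start[-1] > exons$end[-nrow(exons)])
    } else {
      ok <- all(diff(exons$start) < 0) && all(exons$end[-1] < exons$start[-nrow(exons)])
    }
    assert_that(ok, "transcript '", id,
                "': exons overlap or are not in transcription order",
                class = "psitrans_validation_error")
  }
  if (!is.na(cds_lo)) {
    assert_that(!is.na(cds_hi) && cds_hi >= cds_lo, "invalid CDS extent")
    inside <- function(p) any(p >= exons$start & p <= exons$end)
    assert_that(inside(cds_lo) && inside(cds_hi),
                "transcript '", id, "': CDS must lie within the exon union")
  }
  structure(list(id = id, exons = exons,
                 cds_lo = as.integer(cds_lo), cds_hi = as.integer(cds_hi)),
            class = "transcript")
}

has_cds <- function(tx) !is.na(tx$cds_lo)

# exonic length of the CDS (nt), used to pick the reference transcript
cds_exonic_length <- function(tx) {
  if (!has_cds(tx)) return(0L)
  ov_lo <- pmax(tx$exons$start, tx$cds_lo)
  ov_hi <- pmin(tx$exons$end, tx$cds_hi)
  sum(pmax(0L, ov_hi - ov_lo + 1L))
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param transcripts List of [transcript()] objects (at least one); all must
#'   share chromosome and strand.
#' @param symbol Gene symbol (defaults to `gene_id`).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts, symbol = gene_id) {
  assert_that(length(transcripts) >= 1, "gene model needs >= 1 transcript")
  chroms <- vapply(transcripts, function(t) t$exons$chrom[1], character(1))
  strands <- vapply(transcripts, function(t) t$exons$strand[1], character(1))
  assert_that(length(unique(chroms)) == 1 && length(unique(strands)) == 1,
              "gene '", gene_id, "': transcripts must share chrom and strand")
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "id")
  structure(list(gene_id = gene_id, symbol = symbol,
                 chrom = chroms[1], strand = strands[1],
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_id,
      if (!identical(x$symbol, x$gene_id)) paste0("(", x$symbol, ")"),
      "\n  ", x$chrom, x$strand, "-",
      length(x$transcripts), "transcript(s):",
      paste(names(x$transcripts), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a splice event
#'
#' A cassette event has one alternative exon; a mutually exclusive event has
#' two non-overlapping alternative exons (transcription order). Both are
#' bracketed by constitutive flanking exons.
#'
#' @param event_id Event identifier.
#' @param gene_id Owning gene.
#' @param type `"cassette"` or `"mutually_exclusive"`.
#' @param alt Exon table with 1 (cassette) or 2 (mutually exclusive) rows.
#' @param flank_up,flank_down One-row exon tables: the constitutive exons
#'   upstream/downstream of the alternative region in transcription order.
#' @param incl_tx,excl_tx Identifiers of the inclusion and exclusion
#'   transcripts (for mutually exclusive events, the transcripts carrying the
#'   first and the second alternative exon, respectively).
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(event_id, gene_id, type, alt, flank_up, flank_down,
                         incl_tx, excl_tx) {
  type <- match.arg(type, c("cassette", "mutually_exclusive"))
  n_alt <- if (type == "cassette") 1L else 2L
  assert_that(nrow(alt) == n_alt, "event '", event_id, "': expected ", n_alt,
              " alternative exon(s)")
  if (type == "mutually_exclusive") {
    assert_that(alt$end[1] < alt$start[2] || alt$end[2] < alt$start[1],
                "mutually exclusive exons must not overlap")
  }
  strand <- alt$strand[1]
  between <- function(e) {
    if (strand == "+") flank_up$end < e$start & e$end < flank_down$start
    else flank_down$end < e$start & e$end < flank_up$start
  }
  assert_that(all(between(alt)),
              "alternative exon(s) must lie strictly between the flanks")
  structure(list(event_id = event_id, gene_id = gene_id, type = type,
                 alt = alt, flank_up = flank_up, flank_down = flank_down,
                 incl_tx = incl_tx, excl_tx = excl_tx),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat("<splice_event>", x$event_id, sprintf("[%s]", x$type), "\n  alt:",
      paste(sprintf("%s:%d-%d(%s)", x$alt$chrom, x$alt$start, x$alt$end,
                    x$alt$strand), collapse = ", "), "\n")
  invisible(x)
}

#' Pick the reference transcript of a gene for ORF work
#'
#' The transcript with the longest exonic CDS; ties are broken by
#' lexicographic transcript id. Returns `NULL` when no transcript has a CDS.
#'
#' @param gene A [gene_model()].
#' @return A [transcript()] or `NULL`.
#' @export
reference_transcript <- function(gene) {
  lens <- vapply(gene$transcripts, cds_exonic_length, integer(1))
  if (all(lens == 0L)) return(NULL)
  ids <- names(gene$transcripts)
  ord <- order(-lens, ids)
  gene$transcripts[[ord[1]]]
}
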