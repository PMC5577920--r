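#' Read gene models from a GTF file
#'
#' Parses Ensembl-style GTF (1-based closed coordinates; `exon` and optional
#' `CDS` features with `gene_id`/`transcript_id` attributes) into a list of
#' [gene_model()] objects. Exons are sorted in transcription order (reverse
#' genomic order on the minus strand) and the CDS extent is recorded per
#' transcript. Transcripts with overlapping exons raise a validation error.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects (names are gene ids).
#' @export
read_gtf <- function(path) {
  assert_that(file.exists(path), "GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = as.character(gr$gene_id),
                   transcript_id = as.character(gr$transcript_id),
                   stringsAsFactors = FALSE)
  df$symbol <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else df$gene_id
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  assert_that(nrow(df) > 0, "no exon/CDS features in ", path)
  assert_that(!anyNA(df$transcript_id), "exon/CDS feature without transcript_id")

  genes <- list()
  for (gid in unique(df$gene_id)) {
    dg <- df[df$gene_id == gid, , drop = FALSE]
    txs <- lapply(split(dg, dg$transcript_id), function(dt) {
      ex <- dt[dt$type == "exon", , drop = FALSE]
      assert_that(nrow(ex) > 0, "transcript ", dt$transcript_id[1], " has no exons")
      ord <- if (ex$strand[1] == "+") order(ex$start) else order(-ex$start)
      ex <- ex[ord, , drop = FALSE]
      cds <- dt[dt$type == "CDS", , drop = FALSE]
      transcript(dt$transcript_id[1],
                 exon_intervals(ex$chrom, ex$start, ex$end, ex$strand),
                 cds_lo = if (nrow(cds)) min(cds$start) else NA_integer_,
                 cds_hi = if (nrow(cds)) max(cds$end) else NA_integer_)
    })
    genes[[gid]] <- gene_model(gid, unname(txs), symbol = dg$symbol[1])
  }
  genes
}

#' Write gene models to a GTF file
#'
#' Emits `exon` and (where a CDS is annotated) `CDS` features, 1-based closed,
#' with `gene_id`, `transcript_id` and `gene_name` attributes; inverse of
#' [read_gtf()] up to feature ordering.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                   strand = ex$strand, type = "exon", phase = NA_integer_,
                   gene_id = g$gene_id, transcript_id = tx$id,
                   gene_name = g$symbol, stringsAsFactors = FALSE)
      if (has_cds(tx)) {
        lo <- pmax(ex$start, tx$cds_lo); hi <- pmin(ex$end, tx$cds_hi)
        keep <- lo <= hi
        if (any(keep)) {
          w <- (hi - lo + 1L)[keep]
          # GTF frame: bases to skip before the next codon boundary
          phase <- c(0L, (3L - cumsum(w)[-sum(keep)] %% 3L) %% 3L)
          rows[[length(rows) + 1L]] <-
            data.frame(chrom = ex$chrom[keep], start = lo[keep], end = hi[keep],
                       strand = ex$strand[keep], type = "CDS", phase = phase,
                       gene_id = g$gene_id, transcript_id = tx$id,
                       gene_name = g$symbol, stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$source <- "psitrans"
  gr$type <- df$type
  gr$phase <- df$phase
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$gene_name <- df$gene_name
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write alternative exons of splice events to BED6
#'
#' One line per alternative exon (two for mutually exclusive events, suffixed
#' `_1`/`_2`), event id as the name field, score 0; BED is written 0-based
#' half-open per the format.
#'
#' @param events List of [splice_event()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  if (length(events) == 0) {
    file.create(path)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(events, function(ev) {
    nm <- if (ev$type == "cassette") ev$event_id else
      paste0(ev$event_id, "_", seq_len(nrow(ev$alt)))
    data.frame(chrom = ev$alt$chrom, start = ev$alt$start, end = ev$alt$end,
               name = nm, strand = ev$alt$strand, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$name <- rows$name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 file of event exons
#'
#' @param path Path to a BED file written by [write_events_bed()].
#' @return A `data.frame` (chrom, start, end, name, score, strand) with
#'   1-based closed coordinates (converted from BED's 0-based half-open).
#' @export
read_events_bed <- function(path) {
  assert_that(file.exists(path), "BED file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = gr$name, score = as.integer(gr$score %||% 0L),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read splice events as TSV
#'
#' Flat interchange format, one row per event: coordinates of the alternative
#' exon(s) and flanks, event type, and the `k of N` exon numbering of the
#' inclusion transcript.
#'
#' @param events List of [splice_event()] objects.
#' @param genes Named list of [gene_model()] objects (for `k of N`), or `NULL`
#'   to write `NA` numbering.
#' @param path Output path.
#' @return `path` invisibly (`write_events_tsv`); a `data.frame`
#'   (`read_events_tsv`).
#' @export
write_events_tsv <- function(events, path, genes = NULL) {
  rows <- lapply(events, function(ev) {
    kn <- if (!is.null(genes) && !is.null(genes[[ev$gene_id]]))
      alt_exon_position(genes[[ev$gene_id]], ev) else list(k = NA, N = NA)
    data.frame(event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
               chrom = ev$alt$chrom[1], strand = ev$alt$strand[1],
               alt_start = ev$alt$start[1], alt_end = ev$alt$end[1],
               alt2_start = if (nrow(ev$alt) > 1) ev$alt$start[2] else NA_integer_,
               alt2_end = if (nrow(ev$alt) > 1) ev$alt$end[2] else NA_integer_,
               flank_up_start = ev$flank_up$start, flank_up_end = ev$flank_up$end,
               flank_down_start = ev$flank_down$start,
               flank_down_end = ev$flank_down$end,
               incl_tx = ev$incl_tx, excl_tx = ev$excl_tx,
               k = kn$k, N = kn$N, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  assert_that(file.exists(path), "events TSV not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# rebuild splice_event objects from an events TSV row set
events_from_tsv <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    n_alt <- if (r$type == "cassette") 1L else 2L
    alt <- exon_intervals(r$chrom,
                          c(r$alt_start, r$alt2_start)[seq_len(n_alt)],
                          c(r$alt_end, r$alt2_end)[seq_len(n_alt)], r$strand)
    splice_event(r$event_id, r$gene_id, r$type, alt,
                 exon_intervals(r$chrom, r$flank_up_start, r$flank_up_end, r$strand),
                 exon_intervals(r$chrom, r$flank_down_start, r$flank_down_end, r$strand),
                 r$incl_tx, r$excl_tx)
  })
}
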