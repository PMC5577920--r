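#' Enumerate cassette and mutually exclusive events from a gene model
#'
#' Compares every ordered transcript pair. A cassette event is an internal
#' exon present in one transcript and absent from another while both flanking
#' exons are shared and adjacent in the other transcript. A mutually
#' exclusive event is a pair of non-overlapping internal exons between shared
#' flanks, each carried by exactly one of the two transcripts. Events whose
#' "alternative" exon occurs in every transcript are rejected; output order
#' and inclusion/exclusion transcript assignment are deterministic
#' (coordinate order; lexicographically smallest transcript ids).
#'
#' @param gene A [gene_model()] with at least two transcripts.
#' @return List of [splice_event()] objects (possibly empty).
#' @export
enumerate_splice_events <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) < 2) return(list())
  keys <- lapply(txs, function(t) exon_key(t$exons))
  all_shared <- Reduce(intersect, keys)
  found <- list()

  # prefer transcript pairs that differ exactly by the alt exon(s); break
  # remaining ties by lexicographic transcript ids
  add <- function(sig, rec) {
    alt_keys <- exon_key(rec$alt)
    ki <- keys[[rec$incl_tx]]; ke <- keys[[rec$excl_tx]]
    rec$exact <- if (rec$type == "cassette") {
      setequal(setdiff(ki, ke), alt_keys[1]) && length(setdiff(ke, ki)) == 0
    } else {
      setequal(setdiff(ki, ke), alt_keys[1]) &&
        setequal(setdiff(ke, ki), alt_keys[2])
    }
    cur <- found[[sig]]
    better <- is.null(cur) ||
      (rec$exact && !cur$exact) ||
      (rec$exact == cur$exact &&
         (rec$incl_tx < cur$incl_tx ||
          (rec$incl_tx == cur$incl_tx && rec$excl_tx < cur$excl_tx)))
    if (better) found[[sig]] <<- rec
  }

  ids <- sort(names(txs))
  for (ia in ids) for (ib in ids) {
    if (ia == ib) next
    ta <- txs[[ia]]; tb <- txs[[ib]]
    ka <- keys[[ia]]; kb <- keys[[ib]]
    na <- nrow(ta$exons)
    if (na < 3) next
    for (i in 2:(na - 1)) {
      ek <- ka[i]
      if (ek %in% kb || ek %in% all_shared) next
      up <- ka[i - 1]; down <- ka[i + 1]
      ju <- match(up, kb); jd <- match(down, kb)
      if (is.na(ju) || is.na(jd)) next
      if (jd == ju + 1) {
        # shared flanks directly adjacent in the other transcript: cassette
        add(paste("SE", up, ek, down),
            list(type = "cassette", alt = ta$exons[i, , drop = FALSE],
                 up = ta$exons[i - 1, , drop = FALSE],
                 down = ta$exons[i + 1, , drop = FALSE],
                 incl_tx = ia, excl_tx = ib))
      } else if (jd == ju + 2) {
        # one exon between the shared flanks in the other transcript: MXE?
        f <- kb[ju + 1]
        if (f %in% ka) next
        e1 <- ta$exons[i, , drop = FALSE]
        e2 <- tb$exons[ju + 1, , drop = FALSE]
        if (e1$end >= e2$start && e2$end >= e1$start) next  # overlapping
        # order partners in transcription order
        first_is_e1 <- if (e1$strand == "+") e1$start < e2$start else e1$start > e2$start
        alt <- if (first_is_e1) rbind(e1, e2) else rbind(e2, e1)
        sig <- paste("MXE", up, paste(sort(c(ek, f)), collapse = "/"), down)
        add(sig, list(type = "mutually_exclusive", alt = alt,
                      up = ta$exons[i - 1, , drop = FALSE],
                      down = ta$exons[i + 1, , drop = FALSE],
                      incl_tx = if (first_is_e1) ia else ib,
                      excl_tx = if (first_is_e1) ib else ia))
      }
    }
  }
  if (length(found) == 0) return(list())
  recs <- found[order(vapply(found, function(r) min(r$alt$start), numeric(1)),
                      vapply(found, function(r) max(r$alt$end), numeric(1)),
                      vapply(found, function(r) r$type, character(1)))]
  lapply(recs, function(r) {
    coord <- paste(sprintf("%s:%d-%d", r$alt$chrom, r$alt$start, r$alt$end),
                   collapse = ",")
    eid <- sprintf("%s|%s|%s", gene$gene_id,
                   if (r$type == "cassette") "SE" else "MXE", coord)
    splice_event(eid, gene$gene_id, r$type, r$alt, r$up, r$down,
                 r$incl_tx, r$excl_tx)
  })
}

#' Count constitutive exons of a gene
#'
#' Exons (by exact coordinates) present in every transcript of the gene.
#' Downstream positional analyses keep only events in genes with at least
#' three constitutive exons.
#'
#' @param gene A [gene_model()].
#' @param event A [splice_event()] belonging to `gene`.
#' @return Integer count.
#' @export
constitutive_exon_count <- function(gene, event) {
  assert_that(identical(event$gene_id, gene$gene_id),
              "event ", event$event_id, " does not belong to gene ",
              gene$gene_id)
  shared <- Reduce(intersect, lapply(gene$transcripts,
                                     function(t) exon_key(t$exons)))
  length(shared)
}

#' Exon numbering of the alternative exon ("k of N")
#'
#' Counts exons of the inclusion transcript in transcription order; the
#' alternative exon contributes to both `k` and `N` (so a 14-exon inclusion
#' transcript whose 13th exon is alternative reports k = 13, N = 14). For
#' mutually exclusive events, the first alternative exon (transcription
#' order) in its carrier transcript is numbered.
#'
#' @param gene A [gene_model()].
#' @param event A [splice_event()] belonging to `gene`.
#' @return List with elements `k` and `N`.
#' @export
alt_exon_position <- function(gene, event) {
  assert_that(identical(event$gene_id, gene$gene_id),
              "event ", event$event_id, " does not belong to gene ",
              gene$gene_id)
  tx <- gene$transcripts[[event$incl_tx]]
  assert_that(!is.null(tx), "inclusion transcript ", event$incl_tx,
              " not found in gene ", gene$gene_id)
  k <- match(exon_key(event$alt[1, , drop = FALSE]), exon_key(tx$exons))
  assert_that(!is.na(k), "alternative exon not found in inclusion transcript")
  list(k = as.integer(k), N = nrow(tx$exons))
}
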