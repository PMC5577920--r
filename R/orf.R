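CONSEQUENCE_CATEGORIES <- c("insertion", "deletion", "c_terminal_change",
                            "n_terminal_change", "start_codon", "stop_codon",
                            "utr5_only", "utr3_only",
                            "mutually_exclusive_swap", "amino_acid_change")

#' Reading-frame preservation of an alternative exon
#'
#' A cassette exon preserves the frame iff its length is a multiple of three.
#' A mutually exclusive pair preserves the frame iff the difference of the
#' two partner lengths is a multiple of three (the partners replace each
#' other, so only the length difference shifts the frame).
#'
#' @param event A [splice_event()], or a cassette exon length via
#'   [frame_preserved_lengths()].
#' @return Logical.
#' @export
frame_preserved <- function(event) {
  w <- exon_width(event$alt)
  if (event$type == "cassette") frame_preserved_lengths(w)
  else frame_preserved_lengths(w[1], w[2])
}

#' @rdname frame_preserved
#' @param len1,len2 Exon lengths in bp; `len2` only for mutually exclusive
#'   pairs.
#' @export
frame_preserved_lengths <- function(len1, len2 = NULL) {
  if (is.null(len2)) len1 %% 3 == 0 else abs(len1 - len2) %% 3 == 0
}

#' Relative position of the alternative exon along the mRNA
#'
#' `100 * k / N`, where `k` is the exon number of the alternative exon and
#' `N` the total exon count of the inclusion transcript (transcription
#' order, alternative exon counted in both).
#'
#' @param k Exon index, `1 <= k <= N`.
#' @param N Total exon count, `>= 1`.
#' @return Percent from the 5' end, in `(0, 100]`.
#' @export
relative_position <- function(k, N) {
  assert_that(all(N >= 1) && all(k >= 1) && all(k <= N),
              "need 1 <= k <= N", class = "psitrans_validation_error")
  100 * k / N
}

# positions of the annotated start codon base and stop codon span,
# strand-aware, on the genomic axis
cds_landmarks <- function(tx) {
  s <- tx$exons$strand[1]
  if (s == "+") {
    list(start_pos = tx$cds_lo, stop_span = c(tx$cds_hi - 2L, tx$cds_hi))
  } else {
    list(start_pos = tx$cds_hi, stop_span = c(tx$cds_lo, tx$cds_lo + 2L))
  }
}

# does the exon sequence introduce a stop codon in the annotated reading
# frame? Scans codons of the reference (inclusion) frame lying fully inside
# the exon's CDS portion.
exon_introduces_stop <- function(exon, ref, genome) {
  s <- exon$strand[1]
  mrna <- spliced_seq(ref, genome)
  p_cds <- mrna_position(ref, if (s == "+") ref$cds_lo else ref$cds_hi)
  p_cds_end <- mrna_position(ref, if (s == "+") ref$cds_hi else ref$cds_lo)
  p_ex <- mrna_position(ref, if (s == "+") exon$start else exon$end)
  if (is.na(p_ex)) stop_psitrans("alternative exon is not exonic in the reference transcript")
  len <- exon$end - exon$start + 1L
  from <- max(p_ex, p_cds); to <- min(p_ex + len - 1L, p_cds_end)
  if (from > to) return(FALSE)
  off <- from - p_cds                      # 0-based CDS offset of scan start
  cs <- from + (3L - off %% 3L) %% 3L      # first full codon inside the exon
  stops <- c("TAA", "TAG", "TGA")
  while (cs + 2L <= to) {
    if (substring(mrna, cs, cs + 2L) %in% stops) return(TRUE)
    cs <- cs + 3L
  }
  FALSE
}

#' Classify the protein-coding consequence of an alternative exon
#'
#' Decision cascade on the reference (inclusion) transcript's annotated CDS:
#' mutually exclusive events are a partner swap; an exon entirely outside
#' the CDS is UTR-only (5' or 3' by strand-aware position); an exon
#' containing the annotated start codon creates/removes the start; an exon
#' containing the annotated stop, or introducing an in-frame stop, truncates
#' the C-terminus; a frame-preserving exon fully inside the CDS is an
#' internal peptide insertion (gained during development, positive delta
#' PSI) or deletion (negative); a frame-shifting exon is assigned an
#' alternative N- or C-terminus when it falls in the 5'- or 3'-most position
#' quintile, otherwise a downstream amino acid change.
#'
#' @param event A [splice_event()].
#' @param ref The reference (inclusion) [transcript()] with an annotated CDS
#'   and containing the alternative exon.
#' @param dpsi_sign Sign of the developmental delta PSI for the event (+1 /
#'   -1, e.g. `sign(delta_psi)` between the bracketing time points); used to
#'   orient insertion vs deletion.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences, used to scan for introduced in-frame stop codons. When
#'   absent, supply `introduces_stop` directly (or leave `NA` to skip that
#'   check).
#' @param introduces_stop Logical event annotation: does the exon carry an
#'   in-frame translational stop? Ignored when `genome` is given.
#' @param terminal_quintile Fraction of the exon-position scale treated as
#'   "terminal" for frame-shifting exons (default 0.2: 5'-most and 3'-most
#'   quintiles).
#' @return An object of class `consequence_label`: `event_id`,
#'   `frame_preserved`, `k`, `N`, `relative_position`, `category`, `basis`
#'   (`"coordinate_rule"`), `mxe_partner_assumed`.
#' @export
classify_coding_consequence <- function(event, ref, dpsi_sign,
                                        genome = NULL, introduces_stop = NA,
                                        terminal_quintile = 0.2) {
  assert_that(has_cds(ref),
              "reference transcript has no CDS; use the UTR-only logic for non-coding genes")
  k <- match(exon_key(event$alt[1, , drop = FALSE]), exon_key(ref$exons))
  assert_that(!is.na(k), "event does not map onto the reference transcript")
  N <- nrow(ref$exons)
  pos <- relative_position(k, N)
  fp <- frame_preserved(event)

  label <- function(category, assumed = FALSE) {
    structure(list(event_id = event$event_id, frame_preserved = fp,
                   k = as.integer(k), N = as.integer(N),
                   relative_position = pos, category = category,
                   basis = "coordinate_rule", mxe_partner_assumed = assumed),
              class = "consequence_label")
  }

  if (event$type == "mutually_exclusive") return(label("mutually_exclusive_swap"))

  exon <- event$alt[1, , drop = FALSE]
  s <- exon$strand
  lo_side <- exon$end < ref$cds_lo    # exon entirely on the low-coordinate side
  hi_side <- exon$start > ref$cds_hi
  if (lo_side || hi_side) {
    five_prime <- (lo_side && s == "+") || (hi_side && s == "-")
    return(label(if (five_prime) "utr5_only" else "utr3_only"))
  }
  lm <- cds_landmarks(ref)
  if (lm$start_pos >= exon$start && lm$start_pos <= exon$end)
    return(label("start_codon"))
  if (lm$stop_span[1] <= exon$end && lm$stop_span[2] >= exon$start)
    return(label("stop_codon"))
  if (!is.null(genome)) introduces_stop <- exon_introduces_stop(exon, ref, genome)
  if (isTRUE(introduces_stop)) return(label("stop_codon"))

  inside_cds <- exon$start >= ref$cds_lo && exon$end <= ref$cds_hi
  if (fp && inside_cds) {
    assert_that(!is.na(dpsi_sign) && dpsi_sign != 0,
                "dpsi_sign (+/-) required to orient insertion vs deletion")
    return(label(if (dpsi_sign > 0) "insertion" else "deletion"))
  }
  # frame-shifting exon overlapping the CDS
  if (pos <= 100 * terminal_quintile) return(label("n_terminal_change"))
  if (pos >= 100 * (1 - terminal_quintile)) return(label("c_terminal_change"))
  label("amino_acid_change")
}

#' @export
print.consequence_label <- function(x, ...) {
  cat(sprintf("<consequence_label> %s: %s (%s), exon %d of %d (%.1f%%), %s\n",
              x$event_id, x$category,
              if (x$frame_preserved) "in-frame" else "frame-shifting",
              x$k, x$N, x$relative_position, x$basis))
  invisible(x)
}

#' Collapse consequence labels to a data frame
#'
#' @param labels List of `consequence_label` objects.
#' @return One row per label.
#' @export
consequence_table <- function(labels) {
  if (length(labels) == 0) {
    return(data.frame(event_id = character(), frame_preserved = logical(),
                      k = integer(), N = integer(),
                      relative_position = numeric(), category = character(),
                      basis = character(), mxe_partner_assumed = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(labels, function(l)
    data.frame(l[c("event_id", "frame_preserved", "k", "N",
                   "relative_position", "category", "basis",
                   "mxe_partner_assumed")], stringsAsFactors = FALSE)))
}

#' Histogram of exon positions by frame class and category
#'
#' Bins the relative positions (percent from the 5' end, half-open bins
#' `(0,10], (10,20], ...` for the default 10 bins) and cross-tabulates with
#' frame preservation and coding-consequence category. Bin totals always
#' partition the input.
#'
#' @param labels List of `consequence_label` objects or a
#'   [consequence_table()] data frame.
#' @param bins Number of position bins (default 10).
#' @return A `data.frame` with `bin`, `frame_class`, `category`, `count`
#'   (all combinations, zeros included).
#' @export
positional_frame_histogram <- function(labels, bins = 10) {
  df <- if (is.data.frame(labels)) labels else consequence_table(labels)
  breaks <- seq(0, 100, length.out = bins + 1)
  bin_labels <- sprintf("(%g,%g]", breaks[-length(breaks)], breaks[-1])
  frame_class <- factor(ifelse(df$frame_preserved, "in_frame", "out_of_frame"),
                        levels = c("in_frame", "out_of_frame"))
  bin <- cut(df$relative_position, breaks = breaks, labels = bin_labels,
             right = TRUE)
  category <- factor(df$category, levels = CONSEQUENCE_CATEGORIES)
  tab <- as.data.frame(table(bin = bin, frame_class = frame_class,
                             category = category),
                       responseName = "count", stringsAsFactors = FALSE)
  tab
}

#' Map categories to the printed effect-on-coding labels
#'
#' @param category Character vector of consequence categories.
#' @return Character vector of display labels ("Insertion", "Deletion",
#'   "C-term.", "N-term.", "Change of a.a.", "Mutually exclusive",
#'   "5' UTR", "3' UTR").
#' @export
effect_label <- function(category) {
  map <- c(insertion = "Insertion", deletion = "Deletion",
           c_terminal_change = "C-term.", n_terminal_change = "N-term.",
           amino_acid_change = "Change of a.a.",
           mutually_exclusive_swap = "Mutually exclusive",
           stop_codon = "C-term.",   # truncation changes the C-terminus
           start_codon = "N-term.",
           utr5_only = "5' UTR", utr3_only = "3' UTR")
  unname(map[category])
}

#' Classify fixture rows (printed event annotations, no coordinates)
#'
#' Applies the coding-consequence cascade to events described only by their
#' printed annotations: exon size, `k of N` numbering, delta PSI, event
#' type, and whether the exon carries an in-frame translational stop. All
#' fixture exons are within the ORF. Mutually exclusive rows use the
#' documented partner rule (unprinted partner length assumed equal, so frame
#' preserved) and are flagged via `mxe_partner_assumed`.
#'
#' @param df Data frame with columns `event_type`, `exon_bp`, `k`, `n`,
#'   `dpsi`, `introduces_stop` (logical or "Y"/"N").
#' @param terminal_quintile Terminal-quintile knob, as in
#'   [classify_coding_consequence()].
#' @return `df` with added columns `frame_pred` (logical), `category`,
#'   `effect_pred` (printed-style label), `mxe_partner_assumed`.
#' @export
classify_fixture_events <- function(df, terminal_quintile = 0.2) {
  need <- c("event_type", "exon_bp", "k", "n", "dpsi", "introduces_stop")
  assert_that(all(need %in% names(df)),
              "fixture needs columns ", paste(need, collapse = ", "))
  stops <- if (is.character(df$introduces_stop)) df$introduces_stop == "Y"
           else as.logical(df$introduces_stop)
  mxe <- df$event_type == "mutually_exclusive"
  frame <- ifelse(mxe, TRUE, df$exon_bp %% 3 == 0)
  pos <- relative_position(df$k, df$n)
  category <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    category[i] <-
      if (mxe[i]) "mutually_exclusive_swap"
      else if (stops[i]) "stop_codon"
      else if (frame[i]) { if (df$dpsi[i] > 0) "insertion" else "deletion" }
      else if (pos[i] <= 100 * terminal_quintile) "n_terminal_change"
      else if (pos[i] >= 100 * (1 - terminal_quintile)) "c_terminal_change"
      else "amino_acid_change"
  }
  df$frame_pred <- frame
  df$category <- category
  df$effect_pred <- effect_label(category)
  df$mxe_partner_assumed <- mxe
  df
}
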