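#' Packaged calcium-handling event fixture
#'
#' A 21-row table of validated developmental splicing events in
#' calcium-handling genes of postnatal mouse skeletal muscle: per event, the
#' PN2-to-PN28 delta PSI, alternative exon size, printed reading-frame flag,
#' `k of N` exon numbering, event type, whether the exon carries an in-frame
#' translational stop (sequence-derived annotation; the Atp2a1 exon does),
#' and the printed effect-on-coding category. Mutually exclusive rows do not
#' carry their unprinted partner exon length; classification of those rows
#' assumes an equal-length partner and is flagged accordingly.
#'
#' @return A `data.frame` with columns `event_id`, `gene_symbol`, `dpsi`,
#'   `exon_bp`, `in_frame`, `k`, `n`, `event_type`, `introduces_stop`,
#'   `effect`.
#' @export
calcium_events_fixture <- function() {
  path <- system.file("extdata", "calcium_events_fixture.tsv",
                      package = "psitrans", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
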