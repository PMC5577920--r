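#' Call cross-species conservation of a splicing transition
#'
#' A transition is conserved when both species show a delta PSI of at least
#' `tau` points (inclusive, default 15) in the same direction. A delta PSI
#' of exactly zero has no direction and can never be conserved; a missing
#' value makes the pair uncallable (`NA`).
#'
#' @param dpsi_a,dpsi_b Signed delta PSI in percent for the two species
#'   (vectorized; symmetric in species order).
#' @param tau Threshold in PSI points (default 15).
#' @return Logical vector (`NA` where uncallable).
#' @export
call_conservation <- function(dpsi_a, dpsi_b, tau = 15) {
  assert_that(all(abs(dpsi_a) <= 100, na.rm = TRUE) &&
              all(abs(dpsi_b) <= 100, na.rm = TRUE),
              "|delta PSI| cannot exceed 100",
              class = "psitrans_validation_error")
  ifelse(is.na(dpsi_a) | is.na(dpsi_b), NA,
         abs(dpsi_a) >= tau & abs(dpsi_b) >= tau &
           sign(dpsi_a) == sign(dpsi_b) & sign(dpsi_a) != 0)
}

#' Summarize conservation over ortholog pairs
#'
#' @param pairs Data frame with columns `dpsi_a` and `dpsi_b` (and
#'   optionally `event_id`).
#' @param tau Threshold passed to [call_conservation()].
#' @return List: `n_tested` (callable pairs), `n_conserved`, `fraction`.
#' @export
conservation_summary <- function(pairs, tau = 15) {
  assert_that(all(c("dpsi_a", "dpsi_b") %in% names(pairs)),
              "pairs need columns dpsi_a, dpsi_b")
  calls <- call_conservation(pairs$dpsi_a, pairs$dpsi_b, tau = tau)
  n_tested <- sum(!is.na(calls))
  assert_that(n_tested > 0, "no callable ortholog pairs")
  n_conserved <- sum(calls, na.rm = TRUE)
  list(n_tested = n_tested, n_conserved = n_conserved,
       fraction = n_conserved / n_tested)
}
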