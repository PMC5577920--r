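#' PSI from band intensities
#'
#' Percent spliced in from densitometry of inclusion and skipping RT-PCR
#' bands: `100 * inclusion / (inclusion + skipping)`.
#'
#' @param inclusion,skipping Non-negative band intensities (vectorized).
#' @return PSI in percent, in `[0, 100]`.
#' @export
psi_from_bands <- function(inclusion, skipping) {
  assert_that(all(inclusion >= 0) && all(skipping >= 0),
              "band intensities must be non-negative",
              class = "psitrans_validation_error")
  assert_that(all(inclusion + skipping > 0),
              "PSI undefined: inclusion + skipping is zero")
  100 * inclusion / (inclusion + skipping)
}

#' PSI from junction read counts
#'
#' Length-normalized point estimate
#' `psi = 100 * (incl/len_incl) / (incl/len_incl + excl/len_excl)` with a
#' credible interval from the Beta(incl + 1, excl + 1) posterior (flat prior)
#' on the read proportion, mapped through the same length normalization.
#' Effective lengths default to 1 (pure junction-read counting).
#'
#' @param incl,excl Non-negative junction read counts (vectorized).
#' @param len_incl,len_excl Effective positions (>= 1) of the inclusion and
#'   exclusion isoform junctions.
#' @param conf Credible-interval mass (default 0.95).
#' @return A `data.frame` with columns `psi`, `ci_low`, `ci_high`, `n_incl`,
#'   `n_excl` (percent scale).
#' @export
psi_from_junction_counts <- function(incl, excl, len_incl = 1, len_excl = 1,
                                     conf = 0.95) {
  assert_that(all(incl >= 0) && all(excl >= 0),
              "junction counts must be non-negative",
              class = "psitrans_validation_error")
  assert_that(all(len_incl >= 1) && all(len_excl >= 1),
              "effective lengths must be >= 1",
              class = "psitrans_validation_error")
  assert_that(all(incl + excl > 0),
              "PSI undefined: zero total junction count")
  norm <- function(theta) {
    a <- theta / len_incl; b <- (1 - theta) / len_excl
    100 * a / (a + b)
  }
  alpha <- (1 - conf) / 2
  data.frame(psi = norm(incl / (incl + excl)),
             ci_low = norm(stats::qbeta(alpha, incl + 1, excl + 1)),
             ci_high = norm(stats::qbeta(1 - alpha, incl + 1, excl + 1)),
             n_incl = incl, n_excl = excl)
}

#' Change in percent spliced in
#'
#' `delta_psi = psi_late - psi_early`; positive values mean increased
#' inclusion during development, negative values increased skipping.
#' Missing inputs propagate as `NA`.
#'
#' @param psi_early,psi_late PSI values in percent (vectorized).
#' @return Signed difference in PSI points.
#' @export
delta_psi <- function(psi_early, psi_late) psi_late - psi_early

#' Build a PSI matrix from long-format junction counts
#'
#' @param counts A `data.frame` with columns `event_id`, `sample`, `incl`,
#'   `excl` (one row per event/sample).
#' @param samples Ordered sample (time point) labels; must cover the samples
#'   present in `counts`.
#' @param len_incl,len_excl,conf Passed to [psi_from_junction_counts()].
#' @return An object of class `psi_matrix`: list with percent matrix `psi`
#'   (`NA` where the total count is zero), count matrices `incl`/`excl`,
#'   interval matrices `ci_low`/`ci_high`, and the `events`/`samples` ids.
#' @export
psi_matrix <- function(counts, samples, len_incl = 1, len_excl = 1,
                       conf = 0.95) {
  need <- c("event_id", "sample", "incl", "excl")
  assert_that(all(need %in% names(counts)),
              "counts must have columns ", paste(need, collapse = ", "))
  assert_that(all(counts$sample %in% samples),
              "counts contain samples not in the supplied sample order")
  events <- unique(counts$event_id)
  mk <- function(fill = NA_real_)
    matrix(fill, length(events), length(samples),
           dimnames = list(events, samples))
  incl <- mk(0); excl <- mk(0)
  i <- cbind(match(counts$event_id, events), match(counts$sample, samples))
  incl[i] <- counts$incl; excl[i] <- counts$excl
  psi <- mk(); lo <- mk(); hi <- mk()
  ok <- incl + excl > 0
  est <- psi_from_junction_counts(incl[ok], excl[ok], len_incl, len_excl, conf)
  psi[ok] <- est$psi; lo[ok] <- est$ci_low; hi[ok] <- est$ci_high
  structure(list(psi = psi, incl = incl, excl = excl,
                 ci_low = lo, ci_high = hi,
                 events = events, samples = samples),
            class = "psi_matrix")
}

#' @export
as.matrix.psi_matrix <- function(x, ...) x$psi

#' @export
print.psi_matrix <- function(x, ...) {
  cat("<psi_matrix>", length(x$events), "events x", length(x$samples),
      "samples;", sum(is.na(x$psi)), "undefined cell(s)\n")
  invisible(x)
}

#' Read / write junction-count and PSI tables
#'
#' `read_counts_tsv` expects columns `event_id`, `sample`, `incl`, `excl`.
#' `write_psi_tsv` writes the events-by-samples percent matrix with one
#' decimal place.
#'
#' @param path File path.
#' @param x A [psi_matrix()].
#' @return A `data.frame` (read) or `path` invisibly (write).
#' @export
read_counts_tsv <- function(path) {
  assert_that(file.exists(path), "counts TSV not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "sample", "incl", "excl")
  assert_that(all(need %in% names(df)),
              "counts TSV must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_counts_tsv
#' @export
write_psi_tsv <- function(x, path) {
  m <- round(x$psi, 1)
  df <- data.frame(event_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
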