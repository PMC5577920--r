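# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_psitrans <- function(..., class = "psitrans_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_psitrans(...)
  invisible(TRUE)
}

#' @importFrom Biostrings reverseComplement DNAString
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# logistic used for planted PSI trajectories
logistic <- function(x) 1 / (1 + exp(-x))

# exon identity key used for set operations on exon intervals
exon_key <- function(exons) paste(exons$start, exons$end, sep = "-")

# deterministic sub-seed derivation; keeps independent RNG streams per purpose
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% .Machine$integer.max
}
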