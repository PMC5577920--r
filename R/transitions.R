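#' Developmental time course
#'
#' Ordered time-point labels with ages in days relative to birth. The default
#' is the five-stage postnatal skeletal muscle design: E18.5 (-1.5 d), PN2,
#' PN14, PN28 and adult (22 weeks = 154 d).
#'
#' @param labels Time-point labels in developmental order.
#' @param ages Ages in days, strictly increasing, same length as `labels`.
#' @return An object of class `timecourse`: `labels`, `ages`, and an
#'   `intervals` data.frame (`name`, `from`, `to`, `duration_days`).
#' @export
timecourse <- function(labels, ages) {
  assert_that(length(labels) == length(ages) && length(labels) >= 2,
              "need >= 2 time points with one age each")
  assert_that(all(diff(ages) > 0), "ages must be strictly increasing")
  n <- length(labels)
  intervals <- data.frame(name = paste(labels[-n], labels[-1], sep = "-"),
                          from = labels[-n], to = labels[-1],
                          duration_days = diff(ages),
                          stringsAsFactors = FALSE)
  structure(list(labels = labels, ages = ages, intervals = intervals),
            class = "timecourse")
}

#' @rdname timecourse
#' @export
developmental_timecourse <- function() {
  timecourse(c("E18.5", "PN2", "PN14", "PN28", "Adult"),
             c(-1.5, 2, 14, 28, 154))
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse>", paste(x$labels, collapse = " -> "), "\n  ages (d):",
      paste(x$ages, collapse = ", "), "\n")
  invisible(x)
}

# shared builder for splicing / expression transition calls
build_calls <- function(stat, callable, pass, direction, tc, statistic, tau) {
  ids <- rownames(stat)
  calls <- do.call(rbind, lapply(seq_len(ncol(stat)), function(j) {
    data.frame(id = ids, interval = tc$intervals$name[j],
               statistic = stat[, j], callable = callable[, j],
               pass = pass[, j], direction = direction[, j],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  n_pass <- rowSums(pass, na.rm = TRUE)
  n_callable <- rowSums(callable)
  which_single <- ifelse(n_pass == 1,
                         tc$intervals$name[apply(pass, 1, function(p) which(p)[1])],
                         NA_character_)
  timing <- data.frame(id = ids, n_callable = n_callable, n_pass = n_pass,
                       timing_class = ifelse(n_pass == 0, "none",
                                      ifelse(n_pass == 1, "single_interval",
                                             "multi_interval")),
                       single_interval = which_single,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = calls, timing = timing, statistic = statistic,
                 tau = tau, intervals = tc$intervals$name),
            class = "transition_calls")
}

#' @export
print.transition_calls <- function(x, ...) {
  cat("<transition_calls>", nrow(x$timing), "ids x", length(x$intervals),
      "intervals;", x$statistic, "threshold", x$tau, "\n  timing:",
      sum(x$timing$timing_class == "single_interval"), "single /",
      sum(x$timing$timing_class == "multi_interval"), "multi /",
      sum(x$timing$timing_class == "none"), "none\n")
  invisible(x)
}

#' Call splicing transitions per developmental interval
#'
#' For each consecutive interval, `delta PSI = later - earlier`; an interval
#' passes iff `|delta PSI| >= tau` (inclusive, default 15 points). Direction
#' `increased` means more inclusion during development, `decreased` more
#' skipping. Intervals with a missing PSI on either side are flagged
#' uncallable and excluded from timing classification.
#'
#' @param psi A [psi_matrix()] or a plain events-by-samples percent matrix
#'   whose column names match the time-course labels.
#' @param tc A [timecourse()].
#' @param tau Calling threshold in PSI points (default 15).
#' @return A `transition_calls` object: per-interval `calls` data.frame and a
#'   per-event `timing` data.frame (`single_interval` / `multi_interval` /
#'   `none`).
#' @export
call_splicing_transitions <- function(psi, tc, tau = 15) {
  m <- if (inherits(psi, "psi_matrix")) psi$psi else as.matrix(psi)
  assert_that(identical(colnames(m), tc$labels),
              "PSI matrix samples must match the time-course labels")
  n <- ncol(m)
  d <- m[, -1, drop = FALSE] - m[, -n, drop = FALSE]
  colnames(d) <- tc$intervals$name
  callable <- !is.na(d)
  pass <- callable & abs(d) >= tau
  direction <- ifelse(!pass, NA_character_,
                      ifelse(d > 0, "increased", "decreased"))
  build_calls(d, callable, pass, direction, tc, "delta_psi", tau)
}

#' Call expression transitions per developmental interval
#'
#' Fold change per interval is `(later + floor) / (earlier + floor)`; an
#' interval passes iff the fold change is `>= fold` or `<= 1/fold`
#' (inclusive, default 2).
#'
#' @param expr Genes-by-samples matrix of non-negative expression values
#'   (FPKM-like), column names matching the time-course labels.
#' @param tc A [timecourse()].
#' @param fold Fold-change threshold (default 2).
#' @param floor Pseudo-value added to both sides to avoid division by zero
#'   (default 0.1).
#' @return A `transition_calls` object with statistic `fold_change`.
#' @export
call_expression_changes <- function(expr, tc, fold = 2, floor = 0.1) {
  m <- as.matrix(expr)
  assert_that(all(!is.na(m) & m >= 0), "expression values must be >= 0",
              class = "psitrans_validation_error")
  assert_that(identical(colnames(m), tc$labels),
              "expression matrix samples must match the time-course labels")
  n <- ncol(m)
  fc <- (m[, -1, drop = FALSE] + floor) / (m[, -n, drop = FALSE] + floor)
  colnames(fc) <- tc$intervals$name
  callable <- !is.na(fc)
  pass <- callable & (fc >= fold | fc <= 1 / fold)
  direction <- ifelse(!pass, NA_character_,
                      ifelse(fc > 1, "increased", "decreased"))
  build_calls(fc, callable, pass, direction, tc, "fold_change", fold)
}

#' Timing classification summary
#'
#' Counts events passing each interval, events passing exactly one interval
#' (and which), and the single-interval fraction among called events (those
#' passing at least one interval). When nothing is called, the fraction is
#' reported as 0 alongside `n_called = 0`.
#'
#' @param calls A `transition_calls` object.
#' @param tc The [timecourse()] used for calling.
#' @return A list: `per_interval` data.frame (`interval`, `n_pass`,
#'   `n_single_specific`), `n_called`, `n_single`, `n_multi`,
#'   `single_fraction`.
#' @export
classify_transition_timing <- function(calls, tc) {
  assert_that(identical(calls$intervals, tc$intervals$name),
              "calls were made on a different time course")
  cl <- calls$calls
  n_pass <- vapply(tc$intervals$name,
                   function(iv) sum(cl$pass[cl$interval == iv]), integer(1))
  single <- calls$timing[calls$timing$timing_class == "single_interval", ]
  n_single_specific <- vapply(tc$intervals$name,
                              function(iv) sum(single$single_interval == iv),
                              integer(1))
  n_called <- sum(calls$timing$n_pass >= 1)
  n_single <- nrow(single)
  list(per_interval = data.frame(interval = tc$intervals$name,
                                 n_pass = n_pass,
                                 n_single_specific = n_single_specific,
                                 stringsAsFactors = FALSE, row.names = NULL),
       n_called = n_called, n_single = n_single,
       n_multi = sum(calls$timing$timing_class == "multi_interval"),
       single_fraction = if (n_called == 0) 0 else n_single / n_called)
}

#' Normalize interval transition counts by interval duration
#'
#' @param counts Transition counts, one per interval (named or positional,
#'   matching `tc$intervals`).
#' @param tc A [timecourse()].
#' @return Data frame with `interval`, `count`, `duration_days`,
#'   `rate_per_day`.
#' @export
rate_normalize <- function(counts, tc) {
  dur <- tc$intervals$duration_days
  assert_that(all(dur > 0), "interval durations must be positive",
              class = "psitrans_validation_error")
  assert_that(length(counts) == nrow(tc$intervals),
              "need one count per interval")
  if (!is.null(names(counts))) {
    assert_that(setequal(names(counts), tc$intervals$name),
                "count names do not match the intervals")
    counts <- counts[tc$intervals$name]
  }
  data.frame(interval = tc$intervals$name, count = as.numeric(counts),
             duration_days = dur, rate_per_day = as.numeric(counts) / dur,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of alternative-splicing and differential-expression gene sets
#'
#' @param as_genes,de_genes Character vectors of gene ids over a shared
#'   namespace.
#' @return List with `n_as`, `n_de`, `n_both`, `n_as_only`, `n_de_only`, and
#'   `fraction_as_de` (fraction of AS genes that are also DE; 0 when there
#'   are no AS genes).
#' @export
overlap_sets <- function(as_genes, de_genes) {
  as_genes <- unique(as_genes); de_genes <- unique(de_genes)
  both <- intersect(as_genes, de_genes)
  list(n_as = length(as_genes), n_de = length(de_genes),
       n_both = length(both),
       n_as_only = length(setdiff(as_genes, de_genes)),
       n_de_only = length(setdiff(de_genes, as_genes)),
       fraction_as_de = if (length(as_genes) == 0) 0
                        else length(both) / length(as_genes))
}
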