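#' Classify individuals as infected from read summaries
#'
#' An individual is called infected when at least `min_reads` reads of at
#' least `min_len` bp pass the mapping-quality and flag filters. The default
#' threshold pair (5 reads of >= 80 bp) is the calibrated operating point for
#' GBS surveys of this kind; see [threshold_sweep()] for recalibration.
#'
#' @param x either a `"read_records"` data.frame (summarized internally at
#'   `min_len`/`mapq_min`) or a `"read_summary"` whose `len_min` attribute
#'   equals `min_len`.
#' @param min_reads minimum number of passing reads (inclusive).
#' @param min_len minimum read length in bp (inclusive).
#' @param mapq_min,exclude_mask passed to [summarize_individuals()] when `x`
#'   is a record stream.
#' @return data.frame of class `"infection_calls"`: `individual_id`,
#'   `n_pass`, `infected`; thresholds stored as attributes.
#' @export
classify_infection <- function(x, min_reads = 5, min_len = 80,
                               mapq_min = 20, exclude_mask = 2432) {
  stopifnot(min_reads >= 1)
  if (inherits(x, "read_summary")) {
    if (!is.null(attr(x, "len_min")) && attr(x, "len_min") != min_len) {
      stop("summary was computed at len_min = ", attr(x, "len_min"),
           " but min_len = ", min_len, "; pass the record stream instead")
    }
    s <- x
  } else if (inherits(x, "read_records") ||
             all(c("individual_id", "flag", "mapq", "read_length") %in% names(x))) {
    s <- summarize_individuals(x, mapq_min = mapq_min, len_min = min_len,
                               exclude_mask = exclude_mask)
  } else {
    stop("x must be read records or a read summary")
  }
  out <- data.frame(individual_id = s$individual_id, n_pass = s$n_pass,
                    infected = s$n_pass >= min_reads, stringsAsFactors = FALSE)
  attr(out, "min_reads") <- min_reads
  attr(out, "min_len") <- min_len
  class(out) <- c("infection_calls", "data.frame")
  out
}

#' Confusion statistics of calls against gold-standard labels
#'
#' Accuracy is concordance over individuals present in both tables; gold
#' individuals missing from the call set are treated as having zero mapped
#' reads, i.e. called uninfected (reported via a message). Rates with an
#' empty denominator are reported as `NA`, never as zero. Counts are kept as
#' exact integers; use `render = TRUE` columns for 3-decimal display values.
#'
#' @param calls an `"infection_calls"` data.frame.
#' @param gold data.frame with `individual_id` and logical `pcr_infected`.
#' @return list of class `"confusion_stats"`: `n_compared`, `n_concordant`,
#'   `accuracy`, `fnr` (P(called uninfected | gold infected)), `fpr`
#'   (P(called infected | gold uninfected)), plus the integer numerators and
#'   denominators.
#' @export
confusion_vs_gold <- function(calls, gold) {
  stopifnot(all(c("individual_id", "pcr_infected") %in% names(gold)))
  called <- setNames(calls$infected, calls$individual_id)
  if (length(intersect(gold$individual_id, names(called))) == 0L) {
    stop("no overlap between call set and gold labels")
  }
  missing_ids <- setdiff(gold$individual_id, names(called))
  if (length(missing_ids) > 0L) {
    message(length(missing_ids),
            " gold-labeled individual(s) absent from summaries; treated as 0 reads: ",
            paste(head(missing_ids, 5), collapse = ", "),
            if (length(missing_ids) > 5) ", ..." else "")
  }
  pred <- ifelse(gold$individual_id %in% names(called),
                 called[gold$individual_id], FALSE)
  truth <- gold$pcr_infected
  n <- length(truth)
  conc <- sum(pred == truth)
  n_pos <- sum(truth)
  n_neg <- n - n_pos
  fn <- sum(truth & !pred)
  fp <- sum(!truth & pred)
  out <- list(n_compared = n, n_concordant = conc,
              accuracy = conc / n,
              fnr = if (n_pos > 0) fn / n_pos else NA_real_,
              fpr = if (n_neg > 0) fp / n_neg else NA_real_,
              n_gold_positive = n_pos, n_gold_negative = n_neg,
              false_negatives = fn, false_positives = fp)
  class(out) <- "confusion_stats"
  out
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("confusion vs gold (n = %d): accuracy %s, FNR %s, FPR %s\n",
              x$n_compared, format(round(x$accuracy, 3)),
              ifelse(is.na(x$fnr), "NA", format(round(x$fnr, 3))),
              ifelse(is.na(x$fpr), "NA", format(round(x$fpr, 3)))))
  invisible(x)
}

#' Sweep detection thresholds against gold labels
#'
#' Recomputes calls and confusion statistics over a grid of (min_reads,
#' min_len) pairs, in the manner of the read-threshold calibration curves of
#' GBS infection surveys (the default read grid is log-spaced). The row with
#' maximal accuracy is flagged `best`; exact ties are broken toward the
#' smallest `min_reads`, then smallest `min_len`. All rows achieving the
#' maximal concordance form the accuracy-tie set (attribute `tie_set`).
#'
#' @param records a `"read_records"` data.frame, or a `"read_summary"` when
#'   `len_grid` is the single value the summary was computed at (records are
#'   required whenever `min_len` varies).
#' @param gold gold-standard labels (see [confusion_vs_gold()]).
#' @param read_grid vector of min_reads thresholds.
#' @param len_grid vector of min_len thresholds.
#' @param mapq_min,exclude_mask summarization parameters.
#' @return data.frame of class `"threshold_sweep"`: one row per grid point
#'   with `min_reads`, `min_len`, `n_infected`, `n_compared`, `n_concordant`,
#'   `accuracy`, `fnr`, `fpr`, `best`.
#' @export
threshold_sweep <- function(records, gold,
                            read_grid = c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000),
                            len_grid = 80, mapq_min = 20, exclude_mask = 2432) {
  if (length(read_grid) == 0L || length(len_grid) == 0L) {
    stop("read_grid and len_grid must be non-empty")
  }
  read_grid <- sort(unique(as.integer(read_grid)))
  len_grid <- sort(unique(as.integer(len_grid)))
  presummarized <- inherits(records, "read_summary")
  if (presummarized &&
      !(length(len_grid) == 1L && isTRUE(attr(records, "len_min") == len_grid))) {
    stop("a read summary can only be swept at its own len_min; pass records")
  }
  rows <- list()
  for (ml in len_grid) {
    s <- if (presummarized) records
         else summarize_individuals(records, mapq_min = mapq_min, len_min = ml,
                                    exclude_mask = exclude_mask)
    for (mr in read_grid) {
      calls <- classify_infection(s, min_reads = mr, min_len = ml)
      cs <- suppressMessages(confusion_vs_gold(calls, gold))
      rows[[length(rows) + 1L]] <- data.frame(
        min_reads = mr, min_len = ml,
        n_infected = sum(calls$infected),
        n_compared = cs$n_compared, n_concordant = cs$n_concordant,
        accuracy = cs$accuracy, fnr = cs$fnr, fpr = cs$fpr)
    }
  }
  out <- do.call(rbind, rows)
  tie <- out$n_concordant == max(out$n_concordant)
  ord <- order(!tie, out$min_reads, out$min_len)
  best_idx <- ord[1]
  out$best <- seq_len(nrow(out)) == best_idx
  attr(out, "tie_set") <- out[tie, c("min_reads", "min_len")]
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Infection prevalence by metadata group
#'
#' @param calls an `"infection_calls"` data.frame.
#' @param metadata data.frame with `individual_id` and the grouping column.
#' @param group_key name of the grouping column in `metadata`.
#' @return data.frame: `group`, `n`, `n_infected`, `fraction`.
#' @export
prevalence_by_group <- function(calls, metadata, group_key = "locality") {
  stopifnot(group_key %in% names(metadata))
  miss <- setdiff(calls$individual_id, metadata$individual_id)
  if (length(miss) > 0L) {
    stop("individuals missing metadata: ", paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) ", ..." else "")
  }
  if (nrow(calls) == 0L) {
    return(data.frame(group = character(), n = integer(), n_infected = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  grp <- metadata[[group_key]][match(calls$individual_id, metadata$individual_id)]
  agg <- aggregate(list(n_infected = as.integer(calls$infected)),
                   by = list(group = grp), FUN = sum)
  agg$n <- as.integer(table(grp)[agg$group])
  agg$fraction <- agg$n_infected / agg$n
  agg[, c("group", "n", "n_infected", "fraction")]
}
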