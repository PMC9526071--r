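#' Read endosymbiont alignment records
#'
#' Reads per-read alignment facts from either a text SAM file (header lines
#' beginning with `@` are skipped; read length is taken from the SEQ field,
#' or from the CIGAR string when SEQ is `*`) or a 4-column tab-separated
#' summary (`individual_id`, `flag`, `mapq`, `read_length`; `#` comment lines
#' and an optional header row are skipped). In SAM input the individual
#' identity is the QNAME prefix before `id_delim`, the usual convention for
#' demultiplexed GBS read names.
#'
#' @param path input file.
#' @param dialect `"sam"` or `"tsv"`.
#' @param id_delim delimiter separating the individual tag from the read
#'   suffix in SAM QNAMEs.
#' @return data.frame of class `"read_records"`: `individual_id`, `flag`,
#'   `mapq`, `read_length`, in input order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("ind1\t0\t60\t87", "ind1\t256\t60\t87"), f)
#' read_alignments(f, dialect = "tsv")
read_alignments <- function(path, dialect = c("sam", "tsv"), id_delim = ":") {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ", dialect[1],
                                               " (expected 'sam' or 'tsv')"))
  lines <- readLines(path)
  if (dialect == "sam") {
    keep <- !startsWith(lines, "@") & nzchar(lines)
    body <- lines[keep]
    lineno <- which(keep)
    if (length(body) == 0L) return(empty_records())
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      bad <- lineno[which(nf < 11L)[1]]
      stop("malformed SAM line ", bad, ": fewer than 11 fields")
    }
    qname <- vapply(fields, `[[`, "", 1L)
    flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    cigar <- vapply(fields, `[[`, "", 6L)
    seq <- vapply(fields, `[[`, "", 10L)
    if (anyNA(flag) || anyNA(mapq)) {
      bad <- lineno[which(is.na(flag) | is.na(mapq))[1]]
      stop("malformed SAM line ", bad, ": non-numeric FLAG or MAPQ")
    }
    len <- ifelse(seq == "*", cigar_query_length(cigar), nchar(seq))
    if (anyNA(len)) {
      bad <- lineno[which(is.na(len))[1]]
      stop("malformed SAM line ", bad, ": cannot determine read length")
    }
    id <- vapply(strsplit(qname, id_delim, fixed = TRUE), `[[`, "", 1L)
    out <- data.frame(individual_id = id, flag = flag, mapq = mapq,
                      read_length = as.integer(len), stringsAsFactors = FALSE)
  } else {
    keep <- !startsWith(lines, "#") & nzchar(lines)
    body <- lines[keep]
    lineno <- which(keep)
    if (length(body) > 0L && grepl("^individual_id\t", body[1])) {
      body <- body[-1]; lineno <- lineno[-1]
    }
    if (length(body) == 0L) return(empty_records())
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 4L)) {
      bad <- lineno[which(nf != 4L)[1]]
      stop("malformed TSV line ", bad, ": expected 4 tab-separated fields")
    }
    flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    len <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    if (anyNA(flag) || anyNA(mapq) || anyNA(len)) {
      bad <- lineno[which(is.na(flag) | is.na(mapq) | is.na(len))[1]]
      stop("malformed TSV line ", bad, ": non-numeric field")
    }
    out <- data.frame(individual_id = vapply(fields, `[[`, "", 1L),
                      flag = flag, mapq = mapq, read_length = len,
                      stringsAsFactors = FALSE)
  }
  if (any(out$read_length < 1L) || any(out$mapq < 0L)) {
    stop("invalid record: read_length must be >= 1 and mapq >= 0")
  }
  class(out) <- c("read_records", "data.frame")
  out
}

empty_records <- function() {
  out <- data.frame(individual_id = character(), flag = integer(),
                    mapq = integer(), read_length = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_records", "data.frame")
  out
}

# Query length from CIGAR: sum of M/I/S/=/X operation lengths.
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!nzchar(cg) || sum(nchar(ops)) != nchar(cg)) return(NA_integer_)
    use <- grepl("[MIS=X]$", ops)
    as.integer(sum(as.integer(sub(".$", "", ops[use]))))
  }, integer(1), USE.NAMES = FALSE)
}

#' Summarize alignment records per individual
#'
#' A read counts toward `n_pass` when its SAM flag has no bit in common with
#' `exclude_mask` (default 2432 = secondary + QC-fail + supplementary), its
#' mapping quality is strictly greater than `mapq_min`, and its length is at
#' least `len_min` bp.
#'
#' @param records a `"read_records"` data.frame from [read_alignments()].
#' @param mapq_min minimum mapping quality (exclusive).
#' @param len_min minimum read length in bp (inclusive).
#' @param exclude_mask SAM flag bits that disqualify a record.
#' @return data.frame of class `"read_summary"`: `individual_id`, `n_total`,
#'   `n_pass`, `median_length`, one row per individual (input order of first
#'   appearance). Thresholds are recorded as attributes.
#' @export
summarize_individuals <- function(records, mapq_min = 20, len_min = 80,
                                  exclude_mask = 2432) {
  stopifnot(mapq_min >= 0, len_min >= 1)
  ids <- unique(records$individual_id)
  pass <- bitwAnd(records$flag, as.integer(exclude_mask)) == 0L &
    records$mapq > mapq_min & records$read_length >= len_min
  f <- factor(records$individual_id, levels = ids)
  out <- data.frame(
    individual_id = ids,
    n_total = as.integer(tabulate(f, nbins = length(ids))),
    n_pass = as.integer(rowsum(as.integer(pass), f)[, 1]),
    median_length = as.numeric(tapply(records$read_length, f, median)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mapq_min") <- mapq_min
  attr(out, "len_min") <- len_min
  attr(out, "exclude_mask") <- exclude_mask
  class(out) <- c("read_summary", "data.frame")
  out
}

#' Per-individual read-length histogram
#'
#' @param records a `"read_records"` data.frame.
#' @return table of counts, individuals x read length.
#' @export
length_histogram <- function(records) {
  table(individual = records$individual_id, length = records$read_length)
}

#' Write a per-individual read summary as CSV
#'
#' @param summary output of [summarize_individuals()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_read_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
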