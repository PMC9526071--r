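#' Load a locality survey table
#'
#' Without a path, loads the packaged verbatim transcription of the
#' 107-locality *Lycaeides* survey (locality number, name, nominal species,
#' individuals sampled, individuals infected at the 5-reads/80-bp threshold,
#' data source, and the observed haplotype tallies, e.g. `"A2(5)A12(1)B1(2)"`).
#' The transcription keeps the source table's internal quirks: one row
#' (locality 87) lists more haplotyped individuals than infected individuals,
#' which triggers a warning, not an error, and is never "corrected".
#'
#' @param path CSV with columns `locality_no`, `locality`, `species`, `n`,
#'   `n_infected`, `data_source`, `haplotypes`; default: packaged table.
#' @return data.frame of class `"locality_table"`; attribute `hap_counts` is
#'   a per-row list of named integer haplotype counts.
#' @export
#' @examples
#' t1 <- load_locality_table()
#' nrow(t1)
load_locality_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "survey_localities.csv",
                                package = "wolbscan", mustWork = TRUE)
  t1 <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality_no", "locality", "species", "n", "n_infected", "haplotypes")
  miss <- setdiff(need, names(t1))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  t1$haplotypes[is.na(t1$haplotypes)] <- ""
  bad <- which(t1$n_infected > t1$n | t1$n_infected < 0 | t1$n < 0)
  if (length(bad) > 0L) {
    stop("invalid locality row ", bad[1], " (", t1$locality[bad[1]],
         "): n_infected outside [0, n]")
  }
  hap_counts <- lapply(t1$haplotypes, parse_haplotype_counts)
  over <- which(vapply(hap_counts, sum, 0) > t1$n_infected)
  if (length(over) > 0L) {
    warning("haplotype counts exceed infected count in row(s) ",
            paste(over, collapse = ", "), " (",
            paste(t1$locality[over], collapse = ", "),
            "); kept verbatim", call. = FALSE)
  }
  attr(t1, "hap_counts") <- hap_counts
  class(t1) <- c("locality_table", "data.frame")
  t1
}

#' Parse a haplotype tally string
#'
#' @param s string like `"A2(5)A12(1)B1(2)"` (empty string allowed).
#' @return named integer vector of counts per haplotype label.
#' @export
parse_haplotype_counts <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(integer(), character()))
  tok <- regmatches(s, gregexpr("[A-Z][0-9]+\\(\\d+\\)", s))[[1]]
  if (sum(nchar(tok)) != nchar(gsub("\\s", "", s))) {
    stop("unparseable haplotype tally: ", s)
  }
  setNames(as.integer(sub(".*\\((\\d+)\\)", "\\1", tok)), sub("\\(.*", "", tok))
}

#' Locality-level infection summary
#'
#' All counts are exact integer arithmetic; frequency cutoffs use strict
#' inequality (a locality at exactly 90% does not count as "above 90%"), and
#' the mean infection rate is the unweighted mean over localities.
#'
#' @param table a [load_locality_table()] result.
#' @param cutoffs infection-frequency cutoffs for the strict ">" counts.
#' @return list: `n_localities`, `n_with_infection`, `n_above` (named by
#'   cutoff), `n_at_100`, `mean_rate`, `mean_rate_pct` (rounded),
#'   `total_n`, `total_infected`.
#' @export
locality_stats <- function(table, cutoffs = c(0.5, 0.9, 0.95)) {
  r <- table$n_infected / table$n
  n_above <- vapply(cutoffs, function(cc) sum(r > cc), 0L)
  list(n_localities = nrow(table),
       n_with_infection = sum(table$n_infected > 0L),
       n_above = setNames(as.integer(n_above), paste0(">", cutoffs)),
       n_at_100 = sum(table$n_infected == table$n & table$n > 0L),
       mean_rate = mean(r),
       mean_rate_pct = round(100 * mean(r)),
       total_n = sum(table$n),
       total_infected = sum(table$n_infected))
}

#' Default locality-to-lineage map for the packaged survey table
#'
#' Lineage membership follows the table's nominal species column; the
#' admixed ("Hybrid") localities are split by locality number into the
#' Jackson (82-92), Warner (93-95) and Sierra/Whites (98-107) hybrid
#' lineages, with the remaining two hybrid localities (96-97) kept as
#' "Other Hybrid".
#'
#' @param table a [load_locality_table()] result.
#' @return named character vector, lineage per locality number.
#' @export
default_lineage_map <- function(table) {
  lin <- table$species
  hy <- table$species == "Hybrid"
  no <- table$locality_no
  lin[hy & no >= 82 & no <= 92] <- "Jackson Hybrid"
  lin[hy & no >= 93 & no <= 95] <- "Warner Hybrid"
  lin[hy & no >= 96 & no <= 97] <- "Other Hybrid"
  lin[hy & no >= 98] <- "Sierra/Whites Hybrid"
  setNames(lin, no)
}

#' Lineage-level infection and strain summary
#'
#' Rates are total infected over total sampled per lineage, rounded to two
#' decimals. Strain accounting at the lineage level treats the A1 and A2
#' haplotypes as separate strains (other haplotypes are grouped by their
#' letter prefix); the dominant strain is the one carried by the most
#' individuals in the lineage.
#'
#' @param table a [load_locality_table()] result.
#' @param lineage_map named character vector (names = locality numbers);
#'   default [default_lineage_map()].
#' @return data.frame: `lineage`, `n_localities`, `n`, `n_infected`, `rate`,
#'   `dominant_strain`, `minor_strains`.
#' @export
lineage_stats <- function(table, lineage_map = NULL) {
  lineage_map <- lineage_map %||% default_lineage_map(table)
  unmapped <- setdiff(as.character(table$locality_no), names(lineage_map))
  if (length(unmapped) > 0L) {
    stop("localities without lineage: ", paste(unmapped, collapse = ", "))
  }
  lin <- lineage_map[as.character(table$locality_no)]
  hap_counts <- attr(table, "hap_counts") %||% lapply(table$haplotypes, parse_haplotype_counts)
  out <- do.call(rbind, lapply(unique(lin), function(l) {
    rows <- which(lin == l)
    counts <- unlist(hap_counts[rows])
    strain <- if (length(counts) > 0L) {
      ifelse(names(counts) %in% c("A1", "A2"), names(counts),
             substr(names(counts), 1, 1))
    } else character()
    tal <- sort(tapply(as.integer(counts), strain, sum), decreasing = TRUE)
    data.frame(lineage = l,
               n_localities = length(rows),
               n = sum(table$n[rows]),
               n_infected = sum(table$n_infected[rows]),
               rate = render_rate(sum(table$n_infected[rows]), sum(table$n[rows]), 2),
               dominant_strain = if (length(tal) > 0) names(tal)[1] else NA_character_,
               minor_strains = paste(names(tal)[-1], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Strain tallies from a locality table
#'
#' Haplotype labels follow the strain-prefix convention (leading letter =
#' strain). Returns, per strain, the summed individual counts and the number
#' of distinct haplotype labels; strains below `min_major` individuals are
#' flagged rare.
#'
#' @param table a [load_locality_table()] result.
#' @param min_major minimum individuals for a major strain.
#' @return data.frame: `strain`, `n_individuals`, `n_haplotypes`, `major`,
#'   ordered by decreasing individuals. Attribute `rare`: total individuals
#'   and strain count in rare strains.
#' @export
strain_tallies <- function(table, min_major = 11) {
  hap_counts <- attr(table, "hap_counts") %||% lapply(table$haplotypes, parse_haplotype_counts)
  counts <- unlist(hap_counts)
  if (length(counts) == 0L) {
    out <- data.frame(strain = character(), n_individuals = integer(),
                      n_haplotypes = integer(), major = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "rare") <- list(n_individuals = 0L, n_strains = 0L)
    return(out)
  }
  bad <- !grepl("^[A-Z][0-9]+$", names(counts))
  if (any(bad)) stop("unparseable haplotype label: ", names(counts)[bad][1])
  prefix <- substr(names(counts), 1, 1)
  ind <- tapply(as.integer(counts), prefix, sum)
  nhap <- tapply(names(counts), prefix, function(x) length(unique(x)))
  out <- data.frame(strain = names(ind),
                    n_individuals = as.integer(ind),
                    n_haplotypes = as.integer(nhap),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_individuals, out$strain), , drop = FALSE]
  out$major <- out$n_individuals >= min_major
  rownames(out) <- NULL
  attr(out, "rare") <- list(n_individuals = sum(out$n_individuals[!out$major]),
                            n_strains = sum(!out$major))
  out
}

#' Strain co-occurrence per locality
#'
#' Tabulates which major strains are present in each locality and counts
#' localities where two or more co-occur, at two granularities: major-strain
#' prefixes (A, B, C, with A1/A2 collapsed into A) and with A1/A2 treated as
#' separate strains. Both counts are reported because published summaries do
#' not pin down the granularity.
#'
#' @param table a [load_locality_table()] result.
#' @param major_prefixes letter prefixes counted as major strains.
#' @return list: `per_locality` (data.frame locality_no, strains_major,
#'   strains_split), `n_multi_major`, `n_multi_split`.
#' @export
cooccurrence_table <- function(table, major_prefixes = c("A", "B", "C")) {
  hap_counts <- attr(table, "hap_counts") %||% lapply(table$haplotypes, parse_haplotype_counts)
  per <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    labs <- names(hap_counts[[i]])
    pre <- intersect(unique(substr(labs, 1, 1)), major_prefixes)
    split_lab <- unique(ifelse(labs %in% c("A1", "A2"), labs, substr(labs, 1, 1)))
    split_lab <- split_lab[substr(split_lab, 1, 1) %in% major_prefixes]
    data.frame(locality_no = table$locality_no[i],
               strains_major = paste(sort(pre), collapse = ","),
               n_major = length(pre),
               strains_split = paste(sort(split_lab), collapse = ","),
               n_split = length(split_lab),
               stringsAsFactors = FALSE)
  }))
  list(per_locality = per,
       n_multi_major = sum(per$n_major >= 2),
       n_multi_split = sum(per$n_split >= 2))
}
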