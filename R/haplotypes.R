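#' Construct a haplotype matrix
#'
#' The central container for haploid genotypes: an individuals-by-sites
#' integer matrix over 0 (reference allele), 1 (alternate allele) and `NA`
#' (missing).
#'
#' @param alleles integer matrix (individuals x sites) over 0/1/NA.
#' @param individuals,sites optional dimension names; defaults taken from
#'   `dimnames(alleles)` or generated.
#' @return object of class `"haplotype_matrix"`.
#' @export
haplotype_matrix <- function(alleles, individuals = NULL, sites = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L, NA_integer_))) {
    stop("alleles must be 0, 1 or NA")
  }
  rownames(alleles) <- individuals %||% rownames(alleles) %||%
    sprintf("ind%03d", seq_len(nrow(alleles)))
  colnames(alleles) <- sites %||% colnames(alleles) %||%
    sprintf("s%d", seq_len(ncol(alleles)))
  structure(list(alleles = alleles), class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  a <- x$alleles
  cat(sprintf("haplotype_matrix: %d individuals x %d sites, %d missing entries\n",
              nrow(a), ncol(a), sum(is.na(a))))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Call haploid alleles from per-site allele depths
#'
#' Under the haploid model the call at each site is simply the allele with
#' the larger quality-passing depth; a site with zero depth on both alleles
#' is missing. Equal nonzero depths are ambiguous: the default policy calls
#' them missing (conservative — a likelihood caller would flag the same
#' uncertainty); with `tie = "qual"` the allele with the higher summed base
#' quality wins (requires `ref_qual`/`alt_qual` columns). Sites carrying a
#' third allele (`other_depth > 0` anywhere) are dropped before calling,
#' matching biallelic-only variant filtering.
#'
#' @param depths data.frame: `individual_id`, `site`, `ref_depth`,
#'   `alt_depth`, optionally `other_depth`, `ref_qual`, `alt_qual`.
#' @param tie tie policy: `"missing"` (default) or `"qual"`.
#' @return a [haplotype_matrix()] with sites labeled `s<site>`.
#' @export
call_haploid <- function(depths, tie = c("missing", "qual")) {
  tie <- match.arg(tie)
  stopifnot(all(c("individual_id", "site", "ref_depth", "alt_depth") %in% names(depths)),
            all(depths$ref_depth >= 0), all(depths$alt_depth >= 0))
  if ("other_depth" %in% names(depths)) {
    bad_sites <- unique(depths$site[depths$other_depth > 0])
    if (length(bad_sites) > 0L) {
      message("dropping ", length(bad_sites), " site(s) with a third observed allele")
      depths <- depths[!(depths$site %in% bad_sites), , drop = FALSE]
    }
  }
  ids <- unique(depths$individual_id)
  sites <- sort(unique(depths$site))
  a <- matrix(NA_integer_, length(ids), length(sites),
              dimnames = list(ids, paste0("s", sites)))
  ri <- match(depths$individual_id, ids)
  ci <- match(depths$site, sites)
  call <- ifelse(depths$ref_depth == 0 & depths$alt_depth == 0, NA_integer_,
          ifelse(depths$ref_depth > depths$alt_depth, 0L,
          ifelse(depths$alt_depth > depths$ref_depth, 1L, NA_integer_)))
  if (tie == "qual") {
    if (!all(c("ref_qual", "alt_qual") %in% names(depths))) {
      stop("tie = 'qual' requires ref_qual and alt_qual columns")
    }
    tied <- depths$ref_depth == depths$alt_depth & depths$ref_depth > 0
    call[tied] <- ifelse(depths$ref_qual[tied] >= depths$alt_qual[tied], 0L, 1L)
  }
  a[cbind(ri, ci)] <- call
  haplotype_matrix(a)
}

#' Drop sites exceeding a missingness threshold
#'
#' Site missingness is computed over the individuals named in `among`
#' (typically the infected individuals: uninfected hosts carry no
#' endosymbiont reads, so including them would discard every site).
#'
#' @param mat a [haplotype_matrix()].
#' @param max_missing maximum tolerated missing fraction per site.
#' @param among individual IDs forming the missingness denominator
#'   (default: all rows).
#' @return filtered `haplotype_matrix`; dropped site names in attribute
#'   `dropped_sites`.
#' @export
filter_sites <- function(mat, max_missing = 0.25, among = NULL) {
  stopifnot(inherits(mat, "haplotype_matrix"),
            max_missing >= 0, max_missing <= 1)
  a <- mat$alleles
  rows <- if (is.null(among)) seq_len(nrow(a)) else {
    miss <- setdiff(among, rownames(a))
    if (length(miss) > 0L) stop("unknown individuals in 'among': ",
                                paste(head(miss, 5), collapse = ", "))
    match(among, rownames(a))
  }
  if (length(rows) == 0L) return(mat)
  frac <- colMeans(is.na(a[rows, , drop = FALSE]))
  keep <- frac <= max_missing
  out <- haplotype_matrix(a[, keep, drop = FALSE])
  attr(out, "dropped_sites") <- colnames(a)[!keep]
  out
}

#' Retain only individuals with complete haplotypes
#'
#' Complete-case filtering: every retained individual has an observed allele
#' at every (already site-filtered) variant position, so its haplotype is
#' fully phased by haploidy.
#'
#' @param mat a [haplotype_matrix()].
#' @return filtered `haplotype_matrix`; counts in attributes `n_dropped` and
#'   `n_retained`.
#' @export
filter_complete_individuals <- function(mat) {
  stopifnot(inherits(mat, "haplotype_matrix"))
  a <- mat$alleles
  keep <- rowSums(is.na(a)) == 0L
  out <- haplotype_matrix(a[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Haplotype strings and multiplicities
#'
#' @param mat a complete-case [haplotype_matrix()].
#' @return list with `by_individual` (named character vector of 0/1 strings)
#'   and `unique` (data.frame `haplotype`, `count`, ordered by decreasing
#'   count then string).
#' @export
unique_haplotypes <- function(mat) {
  stopifnot(inherits(mat, "haplotype_matrix"))
  a <- mat$alleles
  if (anyNA(a)) stop("matrix has missing entries; run filter_complete_individuals() first")
  strs <- apply(a, 1, paste, collapse = "")
  if (nrow(a) == 0L) strs <- character()
  tab <- table(strs)
  uq <- data.frame(haplotype = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  uq <- uq[order(-uq$count, uq$haplotype), , drop = FALSE]
  rownames(uq) <- NULL
  list(by_individual = strs, unique = uq)
}

#' Write a haplotype matrix as haploid VCF
#'
#' Minimal VCF 4.2 with one biallelic SNP per site and haploid GT fields
#' (`0`, `1`, or `.` for missing). Allele coding: REF=A is the 0 allele,
#' ALT=C is the 1 allele (recorded in a `##wolbscan_allele_coding` header).
#'
#' @param mat a [haplotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mat, path) {
  stopifnot(inherits(mat, "haplotype_matrix"))
  a <- mat$alleles
  pos <- site_positions(colnames(a))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wolbscan",
           "##wolbscan_allele_coding=0:A,1:C",
           "##contig=<ID=wolb_pan>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(a)), collapse = "\t"))
  gt <- t(a)
  gt_chr <- matrix(ifelse(is.na(gt), ".", as.character(gt)), nrow = nrow(gt))
  body <- vapply(seq_along(pos), function(i) {
    paste(c("wolb_pan", pos[i], colnames(a)[i], "A", "C", ".", "PASS", ".",
            "GT", gt_chr[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

site_positions <- function(site_names) {
  pos <- suppressWarnings(as.integer(sub("^s", "", site_names)))
  if (anyNA(pos)) pos <- seq_along(site_names)
  pos
}

#' Read a haploid VCF into a haplotype matrix
#'
#' Parses with vcfR and converts GT fields; genotypes containing `/` or `|`
#' (diploid or phased multi-allele calls) are rejected — this pipeline's
#' variant model is strictly haploid.
#'
#' @param path VCF file.
#' @return a [haplotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e)))
  gt <- vcfR::extract.gt(v)
  if (any(grepl("[/|]", gt[!is.na(gt)]))) {
    stop("diploid or phased genotypes found; expected haploid GT (0, 1 or .)")
  }
  num <- suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt),
                                 dimnames = dimnames(gt)))
  bad <- !is.na(gt) & gt != "." & is.na(num)
  if (any(bad)) stop("non-numeric haploid genotype at site ",
                     rownames(gt)[which(bad, arr.ind = TRUE)[1, 1]])
  ids <- vcfR::getID(v)
  if (anyNA(ids)) ids <- paste0("s", vcfR::getPOS(v))
  haplotype_matrix(t(num), individuals = colnames(gt), sites = ids)
}

#' Export complete haplotypes as a NEXUS data block
#'
#' One row per individual haplotype, standard datatype with symbols 0/1, the
#' form consumed by coalescent demographic tools.
#'
#' @param mat a complete-case [haplotype_matrix()] with at least one row.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_nexus <- function(mat, path) {
  stopifnot(inherits(mat, "haplotype_matrix"))
  a <- mat$alleles
  if (nrow(a) == 0L) stop("nothing to export: empty haplotype matrix")
  if (anyNA(a)) stop("NEXUS export requires complete haplotypes")
  seqs <- lapply(seq_len(nrow(a)), function(i) as.character(a[i, ]))
  names(seqs) <- rownames(a)
  ape::write.nexus.data(seqs, file = path, format = "standard",
                        datablock = TRUE, interleaved = FALSE)
  # drop the writer's timestamp comment so identical matrices give
  # byte-identical files
  lines <- readLines(path)
  lines[grepl("^\\[Data written by", lines)] <- "[Haploid 0/1 haplotypes]"
  writeLines(lines, path)
  invisible(path)
}

#' Export haplotypes as FASTA
#'
#' The binary alleles are rendered as nucleotides for compatibility with
#' sequence tools: 0 -> A, 1 -> C (missing -> N). The coding is fixed and
#' documented here rather than in the file, which stays plain FASTA.
#'
#' @param mat a [haplotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(mat, path) {
  stopifnot(inherits(mat, "haplotype_matrix"))
  a <- mat$alleles
  chars <- matrix(c("A", "C")[a + 1L], nrow = nrow(a))
  chars[is.na(a)] <- "N"
  lines <- character(2L * nrow(a))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(a))
  lines[c(FALSE, TRUE)] <- apply(chars, 1, paste, collapse = "")
  if (nrow(a) == 0L) lines <- character()
  writeLines(lines, path)
  invisible(path)
}
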