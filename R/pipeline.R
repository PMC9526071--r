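#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (detection at 5 reads of >= 80 bp with MAPQ > 20 and flag
#' mask 2432; 25% site missingness; 95% parsimony confidence; major-strain
#' cutoff 11 individuals), rejects unknown keys, and aggregates all range
#' errors into one message.
#'
#' @param config named list of overrides; see Details for keys.
#' @details Recognized keys: `min_reads`, `min_len`, `mapq_min`,
#'   `exclude_mask`, `max_missing`, `parsimony_confidence`,
#'   `connection_limit` (manual override of the parsimony limit, `NULL` =
#'   compute from confidence), `min_major`, `read_grid`, `dialect`
#'   (`"sam"` or `"tsv"` for simulated read output), `seed`, `out_dir`,
#'   `reads_path`, `depths_path`, `gold_path`, `metadata_path` (when unset,
#'   inputs are simulated), `sim` (a [simulation_config()] or list of its
#'   arguments).
#' @return validated config list of class `"wolbscan_pipeline_config"`.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(min_reads = 5L, min_len = 80L, mapq_min = 20L,
                   exclude_mask = 2432L, max_missing = 0.25,
                   parsimony_confidence = 0.95, connection_limit = NULL,
                   min_major = 11L,
                   read_grid = c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000),
                   dialect = "sam", seed = 1L, out_dir = tempfile("wolbscan_run_"),
                   reads_path = NULL, depths_path = NULL, gold_path = NULL,
                   metadata_path = NULL, sim = NULL)
  if (inherits(config, "wolbscan_pipeline_config")) return(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  errs <- character()
  if (length(unknown) > 0L) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)],
                           keep.null = TRUE)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is_count(cfg$min_reads, 1L), "min_reads must be an integer >= 1")
  chk(is_count(cfg$min_len, 1L), "min_len must be an integer >= 1")
  chk(is_count(cfg$mapq_min, 0L), "mapq_min must be an integer >= 0")
  chk(is_count(cfg$exclude_mask, 0L), "exclude_mask must be an integer >= 0")
  chk(is.numeric(cfg$max_missing) && cfg$max_missing >= 0 && cfg$max_missing <= 1,
      "max_missing must be in [0,1]")
  chk(is.numeric(cfg$parsimony_confidence) && cfg$parsimony_confidence > 0 &&
        cfg$parsimony_confidence < 1, "parsimony_confidence must be in (0,1)")
  chk(is.null(cfg$connection_limit) || is_count(cfg$connection_limit, 1L),
      "connection_limit must be NULL or an integer >= 1")
  chk(is_count(cfg$min_major, 1L), "min_major must be an integer >= 1")
  chk(is.numeric(cfg$read_grid) && length(cfg$read_grid) > 0 && all(cfg$read_grid >= 1),
      "read_grid must be a non-empty vector of thresholds >= 1")
  chk(length(cfg$dialect) == 1L && cfg$dialect %in% c("sam", "tsv"),
      "dialect must be 'sam' or 'tsv'")
  chk(is_count(cfg$seed) || (is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed)),
      "seed must be an integer")
  for (p in c("reads_path", "depths_path", "gold_path", "metadata_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      errs <- c(errs, paste0(p, " does not exist: ", cfg[[p]]))
    }
  }
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "wolbscan_sim_config")) {
    cfg$sim <- tryCatch(do.call(simulation_config, cfg$sim),
                        error = function(e) {
                          errs <<- c(errs, conditionMessage(e)); NULL
                        })
  }
  if (length(errs) > 0L) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- "wolbscan_pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full survey pipeline
#'
#' Chains the analysis stages in survey order: (optional) simulation, read
#' summarization, infection detection, threshold calibration (when gold
#' labels exist), haploid haplotype calling, site and complete-case
#' filtering, parsimony network and strain assignment, PCoA and divergence
#' table, and locality prevalence. All artifacts are written under
#' `config$out_dir` together with a parameter/record-count log and a JSON
#' manifest of md5 checksums; reruns with the same config and seed produce
#' identical checksums (no timestamps are written).
#'
#' @param config a [validate_config()] list (or raw list of overrides).
#' @return manifest data.frame (`file`, `md5`), invisibly; the manifest and
#'   log live next to the outputs.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_lines <- c("wolbscan pipeline log",
                 paste0("seed: ", cfg$seed),
                 paste0("params: min_reads=", cfg$min_reads, " min_len=", cfg$min_len,
                        " mapq_min=", cfg$mapq_min, " exclude_mask=", cfg$exclude_mask,
                        " max_missing=", cfg$max_missing,
                        " parsimony_confidence=", cfg$parsimony_confidence,
                        " min_major=", cfg$min_major))

  truth <- NULL
  if (is.null(cfg$reads_path)) {
    sim_cfg <- cfg$sim %||% simulation_config(seed = cfg$seed)
    ds <- stage("simulate", simulate_dataset(sim_cfg))
    truth <- ds$truth
    stage("simulate", {
      write_reads(ds$reads, out(paste0("reads.", cfg$dialect)), cfg$dialect, sim_cfg)
      write_depths(ds$depths, out("depths.tsv"), sim_cfg)
      write.csv(ds$truth, out("truth.csv"), row.names = FALSE, quote = FALSE)
      write.csv(ds$gold, out("gold_labels.csv"), row.names = FALSE, quote = FALSE)
    })
    cfg$reads_path <- out(paste0("reads.", cfg$dialect))
    cfg$depths_path <- out("depths.tsv")
    cfg$gold_path <- out("gold_labels.csv")
    metadata <- truth[, c("individual_id", "locality", "lineage")]
    log_lines <- c(log_lines, paste0("simulated individuals: ", nrow(truth)))
  } else if (!is.null(cfg$metadata_path)) {
    metadata <- read.csv(cfg$metadata_path, stringsAsFactors = FALSE)
  } else {
    metadata <- NULL
  }

  records <- stage("summarize", read_alignments(cfg$reads_path, dialect = cfg$dialect))
  summaries <- stage("summarize", summarize_individuals(
    records, mapq_min = cfg$mapq_min, len_min = cfg$min_len,
    exclude_mask = cfg$exclude_mask))
  write_read_summary(summaries, out("read_summary.csv"))
  log_lines <- c(log_lines, paste0("alignment records: ", nrow(records)),
                 paste0("individuals summarized: ", nrow(summaries)))

  calls <- stage("detect", classify_infection(summaries, min_reads = cfg$min_reads,
                                              min_len = cfg$min_len))
  if (!is.null(metadata)) {
    # individuals with no mapped reads never reach the SAM file; they are
    # part of the cohort and are called uninfected (0 passing reads)
    zero <- setdiff(metadata$individual_id, calls$individual_id)
    if (length(zero) > 0L) {
      add <- data.frame(individual_id = zero, n_pass = 0L, infected = FALSE,
                        stringsAsFactors = FALSE)
      atts <- attributes(calls)
      calls <- rbind(calls, add)
      attr(calls, "min_reads") <- atts$min_reads
      attr(calls, "min_len") <- atts$min_len
      class(calls) <- c("infection_calls", "data.frame")
      log_lines <- c(log_lines, paste0("cohort individuals with no mapped reads: ",
                                       length(zero)))
    }
  }
  write.csv(calls, out("infection_calls.csv"), row.names = FALSE, quote = FALSE)
  log_lines <- c(log_lines, paste0("infected called: ", sum(calls$infected)))

  if (!is.null(cfg$gold_path)) {
    gold <- read.csv(cfg$gold_path, stringsAsFactors = FALSE)
    gold$pcr_infected <- as.logical(gold$pcr_infected)
    sweep <- stage("calibrate", suppressMessages(
      threshold_sweep(records, gold, read_grid = cfg$read_grid,
                      len_grid = cfg$min_len, mapq_min = cfg$mapq_min,
                      exclude_mask = cfg$exclude_mask)))
    write.csv(sweep, out("threshold_sweep.csv"), row.names = FALSE, quote = FALSE)
    log_lines <- c(log_lines, paste0("calibration best min_reads: ",
                                     sweep$min_reads[sweep$best]))
  }

  if (!is.null(metadata)) {
    prev <- stage("prevalence", prevalence_by_group(calls, metadata, "locality"))
    write.csv(prev, out("locality_prevalence.csv"), row.names = FALSE, quote = FALSE)
  }

  depths <- stage("haplotypes", {
    d <- data.table::fread(cfg$depths_path, sep = "\t", header = TRUE,
                           skip = "individual_id")
    as.data.frame(d)
  })
  mat <- stage("haplotypes", call_haploid(depths))
  infected_ids <- intersect(calls$individual_id[calls$infected], rownames(mat$alleles))
  mat_f <- stage("haplotypes", filter_sites(mat, max_missing = cfg$max_missing,
                                            among = infected_ids))
  keep <- intersect(infected_ids, rownames(mat_f$alleles))
  mat_f <- haplotype_matrix(mat_f$alleles[keep, , drop = FALSE])
  mat_c <- stage("haplotypes", filter_complete_individuals(mat_f))
  log_lines <- c(log_lines,
                 paste0("sites after filtering: ", ncol(mat_c$alleles)),
                 paste0("complete-case individuals: ", nrow(mat_c$alleles)))
  write_vcf(mat_c, out("haplotypes.vcf"))

  uh <- stage("network", unique_haplotypes(mat_c))
  hap_labels <- setNames(paste0("H", seq_len(nrow(uh$unique))), uh$unique$haplotype)
  ind_hap <- data.frame(individual_id = names(uh$by_individual),
                        haplotype = as.character(hap_labels[uh$by_individual]),
                        stringsAsFactors = FALSE)
  hap_mat <- haplotype_matrix(
    do.call(rbind, lapply(strsplit(uh$unique$haplotype, ""), as.integer)),
    individuals = as.character(hap_labels))
  export_nexus(mat_c, out("haplotypes.nex"))
  export_fasta(hap_mat, out("haplotypes.fasta"))

  dst <- stage("network", hamming_matrix(hap_mat))
  limit <- cfg$connection_limit %||%
    parsimony_connection_limit(dst$n_sites, cfg$parsimony_confidence)
  net <- stage("network", build_network(
    dst, multiplicities = setNames(uh$unique$count, hap_labels), limit = limit))
  asg <- stage("network", assign_strains(net, ind_hap, min_major = cfg$min_major))
  write.csv(net$edges, out("network_edges.csv"), row.names = FALSE, quote = FALSE)
  write.csv(merge(asg$haplotype_strain,
                  data.frame(haplotype = as.character(hap_labels),
                             sequence = names(hap_labels)), by = "haplotype"),
            out("strain_assignment.csv"), row.names = FALSE, quote = FALSE)
  write.csv(asg$strains, out("strains.csv"), row.names = FALSE, quote = FALSE)
  write.csv(haplotype_spectrum(asg, ind_hap), out("haplotype_spectrum.csv"),
            row.names = FALSE, quote = FALSE)
  log_lines <- c(log_lines,
                 paste0("connection limit: ", limit),
                 paste0("strains (major/total): ", sum(asg$strains$major), "/",
                        nrow(asg$strains)))

  ord <- stage("ordination", suppressMessages(pcoa(dst)))
  write.csv(data.frame(haplotype = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            out("pcoa_coordinates.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues),
            out("pcoa_eigenvalues.csv"), row.names = FALSE, quote = FALSE)
  if (sum(asg$strains$major) >= 1) {
    div <- stage("ordination", divergence_table(dst, asg))
    write.csv(data.frame(strain = rownames(div$mean), div$mean, check.names = FALSE),
              out("divergence_mean.csv"), row.names = FALSE, quote = FALSE)
  }

  writeLines(log_lines, out("pipeline_log.txt"))
  files <- setdiff(list.files(cfg$out_dir), c("manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(file.path(cfg$out_dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, out("manifest.json"), dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
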