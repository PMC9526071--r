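#' Build and validate a simulation configuration
#'
#' The generator emulates the data-generating process of a GBS endosymbiont
#' survey: a small number of deeply divergent strains, each a star-like cloud
#' of haplotypes around a founder; per-locality strain dominance driven by
#' host lineage; a read-count mixture separating infected hosts (negative
#' binomial, mean far above the detection threshold) from uninfected hosts
#' (low-rate Poisson contamination); read lengths concentrated near the
#' maximum read length; and imperfect PCR labels for a calibration subset.
#'
#' Defaults mirror the published *Lycaeides* survey this pipeline targets:
#' 115 variant sites, 3 strains at pairwise p-distances 0.122/0.374/0.322
#' (founders 14/43/37 steps apart), haplotype pools of 19/44/3 per strain,
#' infected individuals with a median of roughly 3,500 mapped reads, more
#' than 90% of read lengths above 80 bp, and a maximum read length of 87 bp.
#' The uninfected read-count distribution is not observable in real surveys
#' (it is whatever contamination slips through); Poisson with mean 0.2 is a
#' modeling choice, not an estimate.
#'
#' @param n_localities number of sampling localities.
#' @param individuals_per_locality scalar count, or length-2 range sampled
#'   uniformly per locality.
#' @param n_strains number of divergent strains (founder lineages).
#' @param n_sites number of biallelic variant positions per haplotype.
#' @param strain_divergence target fraction of sites differing between strain
#'   founders; a scalar applied to all pairs, or `NULL` for the survey-like
#'   3-strain default (0.122/0.374/0.322).
#' @param within_strain_mutations mean of the Poisson number of sites at
#'   which a derived haplotype differs from its strain founder.
#' @param haplotypes_per_strain haplotype pool size per strain (recycled);
#'   default 19/44/3 for 3 strains, otherwise 12 each.
#' @param prevalence_per_locality planted infection prevalence; scalar or
#'   vector of length `n_localities`.
#' @param infected_read_count_dist,uninfected_read_count_dist lists
#'   `list(dist=, mean=, ...)`; supported dists: `"nbinom"` (fields `mean`,
#'   `dispersion` = size parameter) and `"poisson"` (field `mean`).
#' @param read_length_dist,mapq_dist categorical distributions as lists with
#'   `values` and `prob`.
#' @param depth_per_site_dist per-site sequencing depth for infected
#'   individuals, `list(dist="poisson", mean=, min=)` (depth = `min` +
#'   Poisson(`mean - min`); `min` defaults to 0). The default mean of 5.5
#'   yields roughly 60% of infected individuals with complete haplotypes
#'   across 115 sites, matching the retention rate seen in real surveys.
#' @param strain_dominance probability that an infected individual carries
#'   its locality lineage's dominant strain (the remainder is split evenly
#'   among the other strains).
#' @param dominant_haplotype_mass total frequency mass on the 1-6 dominant
#'   haplotypes of each strain; the remainder is spread evenly over the rare
#'   haplotypes, giving the right-skewed frequency spectra seen in real data.
#' @param pcr_sensitivity,pcr_specificity error rates of the simulated PCR
#'   assay used for gold-standard labels.
#' @param pcr_subset_size number of individuals in the PCR-tested subset.
#' @param seed master integer seed; all substreams are derived from it.
#'
#' @return A validated list of class `"wolbscan_sim_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_localities = 4, individuals_per_locality = 5)
#' truth <- simulate_truth(cfg)
#' table(truth$infected)
simulation_config <- function(n_localities = 100,
                              individuals_per_locality = 20,
                              n_strains = 3,
                              n_sites = 115,
                              strain_divergence = NULL,
                              within_strain_mutations = 1.5,
                              haplotypes_per_strain = NULL,
                              prevalence_per_locality = 0.9,
                              infected_read_count_dist = list(dist = "nbinom", mean = 3500, dispersion = 1),
                              uninfected_read_count_dist = list(dist = "poisson", mean = 0.2),
                              read_length_dist = NULL,
                              mapq_dist = NULL,
                              depth_per_site_dist = list(dist = "poisson", mean = 5.5),
                              strain_dominance = 0.9,
                              dominant_haplotype_mass = 0.93,
                              pcr_sensitivity = 0.96,
                              pcr_specificity = 0.98,
                              pcr_subset_size = 128,
                              seed = 1) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)

  chk(is_count(n_localities), "n_localities must be a non-negative integer")
  chk(is_count(n_strains, 1L), "n_strains must be >= 1")
  chk(is_count(n_sites, 1L), "n_sites must be >= 1")
  chk(is.numeric(individuals_per_locality) &&
        length(individuals_per_locality) %in% 1:2 &&
        all(individuals_per_locality >= 1),
      "individuals_per_locality must be a count or a range of counts")
  chk(is_fraction(prevalence_per_locality) &&
        length(prevalence_per_locality) %in% c(1L, n_localities),
      "prevalence_per_locality must be fraction(s) in [0,1], length 1 or n_localities")
  chk(is_fraction(strain_dominance), "strain_dominance must be in [0,1]")
  chk(is_fraction(dominant_haplotype_mass), "dominant_haplotype_mass must be in [0,1]")
  chk(is_fraction(pcr_sensitivity), "pcr_sensitivity must be in [0,1]")
  chk(is_fraction(pcr_specificity), "pcr_specificity must be in [0,1]")
  chk(is_count(pcr_subset_size), "pcr_subset_size must be a count")
  chk(is.numeric(within_strain_mutations) && within_strain_mutations >= 0,
      "within_strain_mutations must be >= 0")
  chk(is_count(seed) || (is.numeric(seed) && seed == as.integer(seed)),
      "seed must be an integer")

  if (is.null(haplotypes_per_strain)) {
    haplotypes_per_strain <- if (n_strains == 3) c(19L, 44L, 3L) else rep(12L, n_strains)
  }
  haplotypes_per_strain <- rep_len(as.integer(haplotypes_per_strain), n_strains)
  chk(all(haplotypes_per_strain >= 1), "haplotypes_per_strain must be >= 1")

  founder_steps <- founder_step_matrix(n_strains, n_sites, strain_divergence)
  if (!is.null(strain_divergence)) {
    chk(is_fraction(strain_divergence) && length(strain_divergence) == 1L,
        "strain_divergence must be a single fraction in [0,1]")
  }

  mean_of <- function(d) d$mean
  chk(is.list(infected_read_count_dist) && is.numeric(mean_of(infected_read_count_dist)),
      "infected_read_count_dist must be a list with a numeric mean")
  chk(is.list(uninfected_read_count_dist) && is.numeric(mean_of(uninfected_read_count_dist)),
      "uninfected_read_count_dist must be a list with a numeric mean")
  if (length(errs) == 0L) {
    chk(mean_of(infected_read_count_dist) > mean_of(uninfected_read_count_dist),
        "infected read-count mean must exceed the uninfected mean")
  }

  if (is.null(read_length_dist)) read_length_dist <- default_read_length_dist()
  if (is.null(mapq_dist)) mapq_dist <- default_mapq_dist()

  # Strains must be separable: three within-strain mutation radii must not
  # reach across the smallest founder gap, else components would merge.
  if (n_strains >= 2 && length(errs) == 0L) {
    min_gap <- min(founder_steps[upper.tri(founder_steps)])
    chk(3 * within_strain_mutations < min_gap,
        sprintf("strains not separable: 3 * within_strain_mutations (%.1f) >= smallest founder distance (%d)",
                3 * within_strain_mutations, min_gap))
  }

  if (length(errs) > 0L) stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "))

  cfg <- list(n_localities = as.integer(n_localities),
              individuals_per_locality = as.integer(individuals_per_locality),
              n_strains = as.integer(n_strains),
              n_sites = as.integer(n_sites),
              strain_divergence = strain_divergence,
              founder_steps = founder_steps,
              within_strain_mutations = within_strain_mutations,
              haplotypes_per_strain = haplotypes_per_strain,
              prevalence_per_locality = prevalence_per_locality,
              infected_read_count_dist = infected_read_count_dist,
              uninfected_read_count_dist = uninfected_read_count_dist,
              read_length_dist = read_length_dist,
              mapq_dist = mapq_dist,
              depth_per_site_dist = depth_per_site_dist,
              strain_dominance = strain_dominance,
              dominant_haplotype_mass = dominant_haplotype_mass,
              pcr_sensitivity = pcr_sensitivity,
              pcr_specificity = pcr_specificity,
              pcr_subset_size = as.integer(pcr_subset_size),
              seed = as.integer(seed))
  class(cfg) <- "wolbscan_sim_config"
  cfg
}

# Read lengths 30-87 bp with >= 0.90 mass above 80 bp (87 bp is the maximum
# read length after barcode trimming; most reads are full length).
default_read_length_dist <- function() {
  values <- 30:87
  prob <- numeric(length(values))
  prob[values <= 80] <- 0.07 / sum(values <= 80)
  prob[values %in% 81:86] <- c(0.01, 0.01, 0.02, 0.03, 0.05, 0.10)
  prob[values == 87] <- 0.71
  list(values = values, prob = prob / sum(prob))
}

default_mapq_dist <- function() {
  list(values = c(0L, 3L, 10L, 20L, 42L, 60L),
       prob = c(0.02, 0.02, 0.03, 0.03, 0.10, 0.80))
}

# Target pairwise founder Hamming distances. For the 3-strain default these
# follow the observed between-strain divergences (p = 0.122, 0.374, 0.322 on
# 115 sites); the smallest is raised to 14 steps because pairwise Hamming
# distances of binary strings must have an even triple sum.
founder_step_matrix <- function(n_strains, n_sites, strain_divergence) {
  if (n_strains < 2) return(matrix(0L, n_strains, n_strains))
  if (is.null(strain_divergence)) {
    if (n_strains == 3 && n_sites >= 60) {
      d <- round(c(0.374, 0.122, 0.322) * n_sites)  # (1,2), (1,3), (2,3)
      if (sum(d) %% 2 == 1) d[2] <- d[2] + 1L
    } else {
      strain_divergence <- 0.25
    }
  }
  if (!is.null(strain_divergence)) {
    d0 <- round(strain_divergence * n_sites)
    d <- rep(d0, n_strains * (n_strains - 1) / 2)
    if (n_strains == 3 && sum(d) %% 2 == 1) d[3] <- d[3] + 1L
  }
  m <- matrix(0L, n_strains, n_strains)
  m[upper.tri(m)] <- as.integer(d)
  m + t(m)
}

# Place founders as 0/1 vectors realizing the target distance matrix. For 3
# strains the site-pattern counts are solved exactly; for other counts each
# founder flips a private site block (distances then meet or exceed target).
place_founders <- function(cfg) {
  m <- cfg$n_sites
  k <- cfg$n_strains
  base <- rbinom(m, 1L, 0.5)
  founders <- matrix(rep(base, k), nrow = k, byrow = TRUE)
  if (k == 2) {
    idx <- sample.int(m, cfg$founder_steps[1, 2])
    founders[2, idx] <- 1L - founders[2, idx]
  } else if (k == 3) {
    d12 <- cfg$founder_steps[1, 2]; d13 <- cfg$founder_steps[1, 3]
    d23 <- cfg$founder_steps[2, 3]
    n_b <- (d12 + d23 - d13) / 2    # sites where only founder 2 flips
    n_c <- d23 - n_b                # only founder 3 flips
    n_bc <- d12 - n_b               # founders 2 and 3 both flip
    stopifnot(n_b >= 0, n_c >= 0, n_bc >= 0, n_b + n_c + n_bc <= m)
    idx <- sample.int(m, n_b + n_c + n_bc)
    i_b <- idx[seq_len(n_b)]
    i_c <- idx[n_b + seq_len(n_c)]
    i_bc <- idx[n_b + n_c + seq_len(n_bc)]
    founders[2, c(i_b, i_bc)] <- 1L - founders[2, c(i_b, i_bc)]
    founders[3, c(i_c, i_bc)] <- 1L - founders[3, c(i_c, i_bc)]
  } else if (k > 3) {
    d0 <- max(cfg$founder_steps)
    half <- ceiling(d0 / 2)
    stopifnot(k * half <= m)
    blocks <- split(sample.int(m, k * half), rep(seq_len(k), each = half))
    for (s in seq_len(k)) {
      founders[s, blocks[[s]]] <- 1L - founders[s, blocks[[s]]]
    }
  }
  rownames(founders) <- paste0("S", seq_len(k))
  founders
}

hap_to_string <- function(x) paste(x, collapse = "")

#' Simulate per-strain haplotype pools
#'
#' Generates strain founders at the configured pairwise Hamming distances and,
#' for each strain, a pool of derived haplotypes differing from the founder at
#' a Poisson-distributed number of uniformly chosen sites (no back-mutation
#' within a strain). Pool frequencies are right-skewed: 1-6 dominant
#' haplotypes share `dominant_haplotype_mass`, the remainder is spread evenly
#' over the rare haplotypes.
#'
#' @param config a [simulation_config()].
#' @return Named list, one element per strain, each a data.frame with columns
#'   `haplotype` (string over 0/1), `freq` (relative frequency within the
#'   strain) and `is_founder`; attributes `founders` (matrix) and
#'   `founder_steps` (target distances).
#' @export
simulate_strain_haplotypes <- function(config) {
  stopifnot(inherits(config, "wolbscan_sim_config"))
  with_seed(derive_seed(config$seed, "strain_haplotypes"), {
    founders <- place_founders(config)
    pools <- vector("list", config$n_strains)
    names(pools) <- rownames(founders)
    for (s in seq_len(config$n_strains)) {
      k_s <- config$haplotypes_per_strain[s]
      haps <- matrix(rep(founders[s, ], k_s), nrow = k_s, byrow = TRUE)
      if (k_s > 1) {
        for (i in 2:k_s) {
          n_mut <- rpois(1, config$within_strain_mutations)
          if (n_mut > 0) {
            n_mut <- min(n_mut, config$n_sites)
            idx <- sample.int(config$n_sites, n_mut)
            haps[i, idx] <- 1L - haps[i, idx]
          }
        }
      }
      strings <- apply(haps, 1, hap_to_string)
      n_dom <- min(k_s, 1L + min(rpois(1, 1), 5L))
      w <- numeric(k_s)
      dom_w <- 0.5 ^ (seq_len(n_dom) - 1)
      if (n_dom == k_s) {
        w <- dom_w / sum(dom_w)
      } else {
        w[seq_len(n_dom)] <- config$dominant_haplotype_mass * dom_w / sum(dom_w)
        w[(n_dom + 1):k_s] <- (1 - config$dominant_haplotype_mass) / (k_s - n_dom)
      }
      # merge duplicate strings (a derived haplotype can coincide with the
      # founder when its Poisson mutation count is 0)
      agg <- tapply(w, strings, sum)
      first <- !duplicated(strings)
      ord_strings <- strings[first]
      pool <- data.frame(haplotype = ord_strings,
                         freq = as.numeric(agg[ord_strings]),
                         is_founder = ord_strings == strings[1],
                         stringsAsFactors = FALSE)
      pools[[s]] <- pool
    }
    attr(pools, "founders") <- founders
    attr(pools, "founder_steps") <- config$founder_steps
    pools
  })
}

#' Simulate ground truth: localities, lineages, infection and haplotypes
#'
#' Each locality belongs to a host lineage; lineage `k` is dominated by strain
#' `k` (cycled). Infected individuals carry the dominant strain with
#' probability `strain_dominance`, otherwise a uniformly chosen other strain,
#' and draw their haplotype from the strain pool frequencies.
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `"wolbscan_truth"` with one row per individual:
#'   `individual_id`, `locality`, `lineage`, `infected`, `strain`,
#'   `haplotype` (NA for uninfected). Attributes: `pools`,
#'   `planted_prevalence` (per locality), `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "wolbscan_sim_config"))
  pools <- simulate_strain_haplotypes(config)
  with_seed(derive_seed(config$seed, "truth"), {
    nl <- config$n_localities
    if (nl == 0L) {
      out <- data.frame(individual_id = character(), locality = character(),
                        lineage = character(), infected = logical(),
                        strain = character(), haplotype = character(),
                        stringsAsFactors = FALSE)
      class(out) <- c("wolbscan_truth", "data.frame")
      attr(out, "pools") <- pools
      attr(out, "planted_prevalence") <- numeric()
      attr(out, "config") <- config
      return(out)
    }
    ipl <- config$individuals_per_locality
    n_per <- if (length(ipl) == 2L) sample(ipl[1]:ipl[2], nl, replace = TRUE) else rep(ipl, nl)
    prev <- rep_len(config$prevalence_per_locality, nl)
    loc_ids <- sprintf("L%03d", seq_len(nl))
    lineage_idx <- ((seq_len(nl) - 1L) %% config$n_strains) + 1L
    rows <- vector("list", nl)
    for (l in seq_len(nl)) {
      n <- n_per[l]
      infected <- runif(n) < prev[l]
      strain <- rep(NA_character_, n)
      hap <- rep(NA_character_, n)
      dom <- lineage_idx[l]
      for (i in which(infected)) {
        s <- if (config$n_strains == 1L || runif(1) < config$strain_dominance) dom
             else sample(setdiff(seq_len(config$n_strains), dom), 1L)
        pool <- pools[[s]]
        strain[i] <- names(pools)[s]
        hap[i] <- sample(pool$haplotype, 1L, prob = pool$freq)
      }
      rows[[l]] <- data.frame(
        individual_id = sprintf("%s.I%03d", loc_ids[l], seq_len(n)),
        locality = loc_ids[l],
        lineage = sprintf("lineage%d", lineage_idx[l]),
        infected = infected, strain = strain, haplotype = hap,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("wolbscan_truth", "data.frame")
    attr(out, "pools") <- pools
    attr(out, "planted_prevalence") <- setNames(prev, loc_ids)
    attr(out, "config") <- config
    out
  })
}

#' Simulate per-individual passing-read counts only
#'
#' Draws the per-individual counts of quality/length-passing reads from the
#' configured infected/uninfected mixtures without materializing individual
#' read records — the scale-friendly input for threshold calibration, where
#' only `n_pass` matters.
#'
#' @param config a [simulation_config()].
#' @param truth output of [simulate_truth()].
#' @return a `"read_summary"` data.frame (`individual_id`, `n_total`,
#'   `n_pass`, `median_length` = NA) with `len_min = 80`, `mapq_min = 20`
#'   attributes, matching [summarize_individuals()] output at the default
#'   filters.
#' @export
simulate_read_counts <- function(config, truth) {
  stopifnot(inherits(config, "wolbscan_sim_config"), inherits(truth, "wolbscan_truth"))
  with_seed(derive_seed(config$seed, "read_counts"), {
    n <- nrow(truth)
    n_pass <- integer(n)
    inf <- truth$infected
    n_pass[inf] <- draw_count(sum(inf), config$infected_read_count_dist)
    n_pass[!inf] <- draw_count(sum(!inf), config$uninfected_read_count_dist)
    out <- data.frame(individual_id = truth$individual_id,
                      n_total = n_pass, n_pass = n_pass,
                      median_length = NA_real_, stringsAsFactors = FALSE)
    attr(out, "mapq_min") <- 20
    attr(out, "len_min") <- 80
    attr(out, "exclude_mask") <- 2432
    class(out) <- c("read_summary", "data.frame")
    out
  })
}

draw_count <- function(n, d) {
  switch(d$dist,
         nbinom = rnbinom(n, mu = d$mean, size = d$dispersion %||% 1),
         poisson = rpois(n, d$mean),
         stop("unsupported count distribution: ", d$dist))
}

draw_cat <- function(n, d) {
  if (n == 0L) return(d$values[0])
  d$values[sample.int(length(d$values), n, replace = TRUE, prob = d$prob)]
}

draw_cat_cond <- function(n, d, keep) {
  p <- d$prob * keep(d$values)
  if (sum(p) <= 0) stop("conditional categorical draw has zero mass")
  d$values[sample.int(length(d$values), n, replace = TRUE, prob = p)]
}

#' Simulate alignment records and per-site allele depths
#'
#' Per-individual counts of quality/length-passing reads are drawn from the
#' infected or uninfected read-count distribution according to the planted
#' status; individual reads then realize those counts (passing reads have
#' length >= 80 bp, MAPQ > 20 and primary-alignment flags; failing reads fail
#' at least one criterion). Per-site ref/alt depths for infected individuals
#' are Poisson around the configured per-site mean and support the planted
#' allele only (no base-level sequencing error; see the package vignette).
#'
#' @param config a [simulation_config()].
#' @param truth output of [simulate_truth()] for the same config.
#' @return list with `reads` (data.frame: individual_id, flag, mapq,
#'   read_length) and `depths` (data.frame: individual_id, site, ref_depth,
#'   alt_depth). `site` is the 1-based variant index; the reference allele is
#'   0, the alternate 1.
#' @export
simulate_read_data <- function(config, truth) {
  stopifnot(inherits(config, "wolbscan_sim_config"), inherits(truth, "wolbscan_truth"))
  with_seed(derive_seed(config$seed, "reads"), {
    n <- nrow(truth)
    if (n == 0L) {
      return(list(reads = data.frame(individual_id = character(), flag = integer(),
                                     mapq = integer(), read_length = integer(),
                                     stringsAsFactors = FALSE),
                  depths = data.frame(individual_id = character(), site = integer(),
                                      ref_depth = integer(), alt_depth = integer(),
                                      stringsAsFactors = FALSE)))
    }
    n_pass <- integer(n)
    inf <- truth$infected
    n_pass[inf] <- draw_count(sum(inf), config$infected_read_count_dist)
    n_pass[!inf] <- draw_count(sum(!inf), config$uninfected_read_count_dist)
    n_fail <- rpois(n, 0.08 * n_pass + 0.3)

    total <- n_pass + n_fail
    id <- rep(truth$individual_id, total)
    pass <- unlist(lapply(seq_len(n), function(i) {
      c(rep(TRUE, n_pass[i]), rep(FALSE, n_fail[i]))
    }), use.names = FALSE)
    nr <- length(id)
    len <- integer(nr); mq <- integer(nr); flag <- integer(nr)

    np <- sum(pass)
    len[pass] <- draw_cat_cond(np, config$read_length_dist, function(v) v >= 80)
    mq[pass] <- draw_cat_cond(np, config$mapq_dist, function(v) v > 20)
    flag[pass] <- 0L

    nf <- sum(!pass)
    if (nf > 0) {
      mode <- sample.int(3L, nf, replace = TRUE)  # 1 short, 2 low MAPQ, 3 secondary
      len[!pass] <- ifelse(mode == 1L,
                           draw_cat_cond(nf, config$read_length_dist, function(v) v < 80),
                           draw_cat(nf, config$read_length_dist))
      mq[!pass] <- ifelse(mode == 2L,
                          draw_cat_cond(nf, config$mapq_dist, function(v) v <= 20),
                          draw_cat(nf, config$mapq_dist))
      flag[!pass] <- ifelse(mode == 3L, sample(c(256L, 2048L), nf, replace = TRUE), 0L)
      # modes 1 and 2 must actually fail their criterion; mode 3 fails by flag
    }
    reads <- data.frame(individual_id = id, flag = flag, mapq = mq,
                        read_length = len, stringsAsFactors = FALSE)

    dmin <- config$depth_per_site_dist$min %||% 0L
    dmean <- config$depth_per_site_dist$mean - dmin
    stopifnot(dmean >= 0)
    inf_idx <- which(inf)
    m <- config$n_sites
    if (length(inf_idx) > 0) {
      depth <- dmin + rpois(length(inf_idx) * m, dmean)
      allele <- do.call(rbind, lapply(truth$haplotype[inf_idx], function(h)
        as.integer(strsplit(h, "")[[1]])))
      depths <- data.frame(
        individual_id = rep(truth$individual_id[inf_idx], each = m),
        site = rep(seq_len(m), times = length(inf_idx)),
        ref_depth = ifelse(as.vector(t(allele)) == 0L, depth, 0L),
        alt_depth = ifelse(as.vector(t(allele)) == 1L, depth, 0L),
        stringsAsFactors = FALSE)
    } else {
      depths <- data.frame(individual_id = character(), site = integer(),
                           ref_depth = integer(), alt_depth = integer(),
                           stringsAsFactors = FALSE)
    }
    list(reads = reads, depths = depths)
  })
}

#' Simulate PCR gold-standard labels for a calibration subset
#'
#' @param truth output of [simulate_truth()].
#' @param sensitivity P(label positive | truly infected).
#' @param specificity P(label negative | truly uninfected).
#' @param seed integer seed for this substream.
#' @param subset_size number of individuals tested (sampled without
#'   replacement; capped at the cohort size).
#' @return data.frame `individual_id`, `pcr_infected` (logical).
#' @export
simulate_pcr_labels <- function(truth, sensitivity = 0.96, specificity = 0.98,
                                seed = 1, subset_size = 128) {
  stopifnot(is_fraction(sensitivity), is_fraction(specificity))
  with_seed(derive_seed(seed, "pcr"), {
    n <- min(subset_size, nrow(truth))
    idx <- sort(sample.int(nrow(truth), n))
    inf <- truth$infected[idx]
    lab <- ifelse(inf, runif(n) < sensitivity, runif(n) >= specificity)
    data.frame(individual_id = truth$individual_id[idx],
               pcr_infected = lab, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper chaining [simulate_truth()], [simulate_read_data()] and
#' [simulate_pcr_labels()] under one master seed.
#'
#' @param config a [simulation_config()].
#' @return list with elements `config`, `truth`, `reads`, `depths`, `gold`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  rd <- simulate_read_data(config, truth)
  gold <- simulate_pcr_labels(truth, config$pcr_sensitivity, config$pcr_specificity,
                              seed = config$seed, subset_size = config$pcr_subset_size)
  list(config = config, truth = truth, reads = rd$reads, depths = rd$depths, gold = gold)
}

# Stable short hash of a config for output provenance headers.
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "founder_steps")]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 268435399
  sprintf("%07x", h)
}

#' Write simulated reads as a SAM-subset or TSV file
#'
#' SAM output contains minimal headers plus a comment line naming the config
#' hash and seed; the TSV dialect has columns individual_id, flag, mapq,
#' read_length and the same provenance comment.
#'
#' @param reads data.frame from [simulate_read_data()].
#' @param path output file.
#' @param dialect `"sam"` or `"tsv"`.
#' @param config config used (for the provenance header).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, dialect = c("sam", "tsv"), config = NULL) {
  dialect <- match.arg(dialect)
  prov <- if (is.null(config)) "wolbscan"
          else sprintf("wolbscan config=%s seed=%d", config_hash(config), config$seed)
  if (dialect == "sam") {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             "@SQ\tSN:wolb_pan\tLN:3250000",
             paste0("@CO\t", prov))
    n_in_id <- ave(seq_len(nrow(reads)), reads$individual_id, FUN = seq_along)
    body <- sprintf("%s:r%05d\t%d\twolb_pan\t1\t%d\t%dM\t*\t0\t0\t%s\t*",
                    reads$individual_id, n_in_id, reads$flag, reads$mapq,
                    reads$read_length,
                    vapply(reads$read_length, function(l) strrep("A", l), ""))
    writeLines(c(hdr, body), path)
  } else {
    writeLines(paste0("# ", prov), path)
    suppressWarnings(utils::write.table(reads, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  invisible(path)
}

#' @rdname write_reads
#' @param depths data.frame from [simulate_read_data()].
#' @export
write_depths <- function(depths, path, config = NULL) {
  prov <- if (is.null(config)) "wolbscan"
          else sprintf("wolbscan config=%s seed=%d", config_hash(config), config$seed)
  writeLines(paste0("# ", prov), path)
  suppressWarnings(utils::write.table(depths, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
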