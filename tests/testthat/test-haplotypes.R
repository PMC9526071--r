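test_that("haploid calls follow depth majority with conservative ties", {
  depths <- data.frame(individual_id = "a", site = 1:4,
                       ref_depth = c(3L, 0L, 0L, 2L),
                       alt_depth = c(0L, 5L, 0L, 2L))
  mat <- call_haploid(depths)
  expect_equal(unname(mat$alleles["a", ]), c(0L, 1L, NA, NA))
  # base-quality tie-break behind a flag
  depths$ref_qual <- c(90, 10, 0, 80)
  depths$alt_qual <- c(0, 80, 0, 30)
  mat_q <- call_haploid(depths, tie = "qual")
  expect_equal(unname(mat_q$alleles["a", 4]), 0L)
  expect_true(is.na(mat_q$alleles["a", 3]))  # zero depth is still missing
})

test_that("sites with a third allele are dropped before calling", {
  depths <- data.frame(individual_id = rep("a", 2), site = 1:2,
                       ref_depth = c(3L, 3L), alt_depth = c(1L, 0L),
                       other_depth = c(0L, 2L))
  expect_message(mat <- call_haploid(depths), "third observed allele")
  expect_equal(ncol(mat$alleles), 1L)
})

test_that("site missingness filter uses the configured denominator", {
  a <- rbind(c(0L, 1L, NA), c(1L, NA, NA), c(0L, 1L, 0L), c(1L, 0L, NA))
  mat <- haplotype_matrix(a)
  # site 3 missing in 3/4 = 0.75 > 0.25; site 2 in 1/4 = 0.25 (kept, <=)
  f <- filter_sites(mat, 0.25)
  expect_equal(colnames(f$alleles), c("s1", "s2"))
  expect_equal(attr(f, "dropped_sites"), "s3")
  expect_equal(ncol(filter_sites(mat, 1)$alleles), 3L)     # keep everything
  full <- haplotype_matrix(matrix(0L, 3, 4))
  expect_equal(dim(filter_sites(full, 0.25)), c(3L, 4L))   # complete: unchanged
  # denominator restricted to a subset of individuals: sites 1-2 complete
  # there, site 3 missing for ind001 (1/2 > 0.25)
  f2 <- filter_sites(mat, 0.25, among = c("ind001", "ind003"))
  expect_equal(colnames(f2$alleles), c("s1", "s2"))
  expect_error(filter_sites(mat, 0.25, among = "ghost"), "unknown individuals")
})

test_that("complete-case filter drops any individual with missing data", {
  a <- matrix(0L, 4, 115)
  a[2, 57] <- NA  # one missing site out of 115 is enough to drop
  mat <- filter_complete_individuals(haplotype_matrix(a))
  expect_equal(nrow(mat$alleles), 3L)
  expect_equal(attr(mat, "n_dropped"), 1L)
  full <- haplotype_matrix(matrix(1L, 5, 10))
  expect_equal(nrow(filter_complete_individuals(full)$alleles), 5L)
})

test_that("planted incomplete individuals are recounted exactly", {
  set.seed(12)
  n <- 50; m <- 30
  a <- matrix(rbinom(n * m, 1, 0.5), n, m)
  incomplete <- sample(n, 5)
  for (i in incomplete) a[i, sample(m, sample(3, 1))] <- NA
  mat <- filter_complete_individuals(haplotype_matrix(a))
  expect_equal(nrow(mat$alleles), n - 5L)
  expect_equal(attr(mat, "n_dropped"), 5L)
})

test_that("site-then-individual filtering is idempotent", {
  set.seed(4)
  a <- matrix(rbinom(300, 1, 0.5), 20, 15)
  a[sample(300, 40)] <- NA
  step1 <- filter_complete_individuals(filter_sites(haplotype_matrix(a), 0.25))
  step2 <- filter_complete_individuals(filter_sites(step1, 0.25))
  expect_equal(step1$alleles, step2$alleles)
})

test_that("VCF round-trips haploid matrices including missing entries", {
  mat <- haplotype_matrix(rbind(c(0L, 1L, 0L), c(1L, 0L, NA)),
                          individuals = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(mat, f)
  expect_true(any(grepl("\t\\.$", readLines(f))))  # missing rendered as .
  back <- read_vcf(f)
  expect_equal(back$alleles, mat$alleles)

  set.seed(9)
  big <- haplotype_matrix(matrix(rbinom(200, 1, 0.4), 10, 20))
  write_vcf(big, f)
  expect_equal(read_vcf(f)$alleles, big$alleles)
})

test_that("diploid VCF input is rejected with a clear error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1",
               "chr1\t5\ts5\tA\tC\t.\tPASS\t.\tGT\t0/1"), f)
  expect_error(read_vcf(f), "haploid")
})

test_that("NEXUS export matches matrix dimensions and parses back", {
  set.seed(5)
  a <- matrix(rbinom(3 * 115, 1, 0.5), 3, 115)
  mat <- haplotype_matrix(a, individuals = c("h1", "h2", "h3"))
  f <- withr::local_tempfile(fileext = ".nex")
  export_nexus(mat, f)
  txt <- readLines(f)
  expect_true(any(grepl("NTAX=3", txt, ignore.case = TRUE)))
  expect_true(any(grepl("NCHAR=115", txt, ignore.case = TRUE)))
  back <- ape::read.nexus.data(f)
  expect_equal(names(back), c("h1", "h2", "h3"))
  for (i in 1:3) expect_equal(as.integer(back[[i]]), unname(a[i, ]))
  expect_error(export_nexus(haplotype_matrix(matrix(integer(), 0, 5)), f),
               "empty")
  withNA <- a; withNA[1, 1] <- NA
  expect_error(export_nexus(haplotype_matrix(withNA), f), "complete")
})

test_that("FASTA export renders 0/1 as A/C", {
  f <- withr::local_tempfile(fileext = ".fasta")
  export_fasta(toy_matrix(c("0011", "1100"), c("x", "y")), f)
  expect_equal(readLines(f), c(">x", "AACC", ">y", "CCAA"))
})

test_that("calls recover planted haplotypes exactly at guaranteed depth", {
  for (seed in c(1, 2)) {
    cfg <- simulation_config(n_localities = 6, individuals_per_locality = 10,
                             haplotypes_per_strain = c(5, 5, 3),
                             depth_per_site_dist = list(dist = "poisson", mean = 8, min = 3),
                             seed = seed)
    truth <- simulate_truth(cfg)
    rd <- simulate_read_data(cfg, truth)
    mat <- filter_complete_individuals(call_haploid(rd$depths))
    expect_equal(attr(mat, "n_dropped"), 0L)
    called <- unique_haplotypes(mat)$by_individual
    planted <- setNames(truth$haplotype, truth$individual_id)[names(called)]
    expect_identical(unname(called), unname(planted))
  }
})
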