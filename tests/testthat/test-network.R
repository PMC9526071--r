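test_that("hamming distances match direct site-by-site counting", {
  d <- hamming_matrix(c(h1 = "0101", h2 = "0101"))
  expect_equal(unname(d$steps[1, 2]), 0L)
  d2 <- hamming_matrix(c(h1 = "0101", h2 = "0110"))
  expect_equal(unname(d2$steps[1, 2]), 2L)
  expect_equal(unname(d2$p[1, 2]), 0.5)
  set.seed(14)
  haps <- vapply(1:12, function(i)
    paste(rbinom(115, 1, 0.5), collapse = ""), "")
  D <- hamming_matrix(haps)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(unname(D$steps[i, j]), oracle_hamming(haps[i], haps[j]))
  }
  expect_true(isSymmetric(D$steps))
  expect_true(all(diag(D$steps) == 0))
  # triangle inequality
  for (k in 1:12) expect_true(all(D$steps <= outer(D$steps[, k], D$steps[k, ], "+")))
  expect_error(hamming_matrix(c("01", "011")), "equal length")
})

test_that("parsimony probability matches an independent transcription", {
  for (m in c(60, 115, 360, 658)) {
    js <- 1:min(m - 1, 30)
    expect_equal(parsimony_probability(js, m),
                 vapply(js, oracle_parsimony_prob, 0, m = m),
                 tolerance = 1e-12)
    for (conf in c(0.9, 0.95, 0.99)) {
      expect_equal(parsimony_connection_limit(m, conf),
                   oracle_connection_limit(m, conf))
    }
  }
})

test_that("single-hit step probability agrees with Monte-Carlo simulation", {
  set.seed(77)
  for (q in c(2 / 115, 5 / 115, 10 / 115)) {
    mu <- -(3 / 4) * log(1 - 4 * q / 3)
    s_analytic <- mu * exp(-mu) / q
    expect_lt(abs(s_analytic - mc_single_hit_prob(q)), 0.01)
  }
})

test_that("the connection limit behaves as parsimony theory requires", {
  # limit is 5 steps at 115 sites / 95%: joins <=5-step pairs, separates
  # the 14+ step divergences that distinguish strains
  lim <- parsimony_connection_limit(115, 0.95)
  expect_gte(lim, 5L)
  expect_lt(lim, 14L)
  # non-increasing in confidence
  grid <- c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999)
  lims <- vapply(grid, function(cc) parsimony_connection_limit(115, cc), 0L)
  expect_true(all(diff(lims) <= 0))
  # vanishing stringency connects everything
  expect_equal(parsimony_connection_limit(115, 1e-300), 115L)
  expect_equal(parsimony_connection_limit(10, 1e-300), 10L)
})

test_that("network components respect the connection limit", {
  # distances: h1-h2 = 1, h2-h3 = 2, h3-h4 = 20
  h1 <- strrep("0", 30)
  h2 <- paste0("1", strrep("0", 29))
  h3 <- paste0("101", strrep("0", 27))
  h4 <- paste0(strrep("1", 22), strrep("0", 8))  # 20 steps from h3
  d <- hamming_matrix(c(h1 = h1, h2 = h2, h3 = h3, h4 = h4))
  expect_equal(unname(d$steps[3, 4]), 20L)
  net <- build_network(d, limit = 10)
  expect_equal(unname(net$membership[c("h1", "h2", "h3")]),
               rep(net$membership[["h1"]], 3))
  expect_false(net$membership[["h4"]] == net$membership[["h1"]])
  expect_equal(max(net$membership), 2L)
  # every edge within the limit; inter-component minimum beyond it
  expect_true(all(net$edges$steps <= 10))
  # single haplotype: one component, no edges
  net1 <- build_network(hamming_matrix(c(a = "0101")), limit = 3)
  expect_equal(max(net1$membership), 1L)
  expect_equal(nrow(net1$edges), 0L)
  # everything within limit: one component
  net_all <- build_network(d, limit = 30)
  expect_equal(max(net_all$membership), 1L)
})

test_that("components are invariant to haplotype input order", {
  set.seed(31)
  cfg <- simulation_config(n_localities = 6, individuals_per_locality = 10,
                           haplotypes_per_strain = c(6, 6, 4), seed = 31)
  pools <- simulate_strain_haplotypes(cfg)
  haps <- unlist(lapply(pools, function(p) p$haplotype))
  names(haps) <- paste0("H", seq_along(haps))
  base <- build_network(hamming_matrix(haps), limit = 5)
  base_parts <- split(names(sort(base$membership)), sort(base$membership))
  canon <- function(parts) unname(lapply(parts, sort))[order(vapply(lapply(parts, sort), `[`, "", 1))]
  for (i in 1:10) {
    perm <- sample(haps)
    net <- build_network(hamming_matrix(perm), limit = 5)
    parts <- split(names(net$membership), net$membership)
    expect_equal(canon(parts), canon(base_parts))
  }
})

test_that("partitions are nested as the limit grows", {
  set.seed(41)
  haps <- vapply(1:15, function(i) paste(rbinom(40, 1, 0.5), collapse = ""), "")
  names(haps) <- paste0("H", 1:15)
  d <- hamming_matrix(haps)
  prev <- NULL
  for (lim in c(2, 5, 10, 20, 40)) {
    mem <- build_network(d, limit = lim)$membership
    if (!is.null(prev)) {
      # merging only: same earlier component never splits
      for (comp in unique(prev)) {
        expect_equal(length(unique(mem[names(prev)[prev == comp]])), 1L)
      }
    }
    prev <- mem
  }
})

test_that("strain labels follow decreasing individual counts with rare flags", {
  haps <- c(H1 = strrep("0", 50),
            H2 = paste0("1", strrep("0", 49)),
            H3 = paste0(strrep("1", 25), strrep("0", 25)),
            H4 = paste0(strrep("0", 25), strrep("1", 25)))
  d <- hamming_matrix(haps)
  net <- build_network(d, limit = 5)
  ih <- data.frame(
    individual_id = paste0("i", 1:120),
    haplotype = rep(c("H1", "H2", "H3", "H4"), c(60, 32, 25, 3)))
  asg <- assign_strains(net, ih, min_major = 11)
  expect_equal(asg$strains$strain, c("A", "B", "C"))
  expect_equal(asg$strains$n_individuals, c(92L, 25L, 3L))
  expect_equal(asg$strains$major, c(TRUE, TRUE, FALSE))
  expect_equal(unname(asg$haplotype_strain$strain[asg$haplotype_strain$haplotype == "H2"]), "A")
  expect_error(assign_strains(net, data.frame(individual_id = "x", haplotype = "H9")),
               "not in network")
  # 10 singleton components -> 10 rare strains
  far <- vapply(0:9, function(k) paste(as.integer(1:50 <= 5 * k), collapse = ""), "")
  names(far) <- paste0("R", 1:10)
  d10 <- hamming_matrix(far)
  net10 <- build_network(d10, limit = 2)
  ih10 <- data.frame(individual_id = paste0("i", 1:10), haplotype = names(far))
  asg10 <- assign_strains(net10, ih10, min_major = 11)
  expect_equal(sum(!asg10$strains$major), 10L)
  # single component -> single strain, no rare
  asg1 <- assign_strains(build_network(d10, limit = 50), ih10, min_major = 2)
  expect_equal(nrow(asg1$strains), 1L)
  expect_true(all(asg1$strains$major))
})

test_that("haplotype spectra sum multiplicities per strain", {
  haps <- c(H1 = strrep("0", 20), H2 = paste0("1", strrep("0", 19)),
            H3 = paste0("11", strrep("0", 18)), H4 = paste0("10", strrep("0", 18)))
  net <- build_network(hamming_matrix(haps), limit = 3)
  ih <- data.frame(individual_id = paste0("i", 1:105),
                   haplotype = rep(c("H1", "H2", "H3", "H4"), c(100, 3, 1, 1)))
  asg <- assign_strains(net, ih)
  sp <- haplotype_spectrum(asg, ih)
  expect_equal(sp$n_haplotypes, 4L)
  expect_equal(sp$n_individuals, 105L)
  expect_equal(sp$multiplicities, "100,3,1,1")
})

test_that("planted strains are recovered and MST edges are deterministic", {
  for (seed in c(3, 4)) {
    cfg <- simulation_config(n_localities = 9, individuals_per_locality = 12,
                             haplotypes_per_strain = c(6, 8, 3), seed = seed)
    truth <- simulate_truth(cfg)
    inf <- truth[truth$infected, ]
    tab <- table(inf$haplotype)
    d <- hamming_matrix(setNames(unname(names(tab)), paste0("H", seq_along(tab))))
    net <- build_network(d, multiplicities = setNames(as.integer(tab), paste0("H", seq_along(tab))))
    ih <- data.frame(individual_id = inf$individual_id,
                     haplotype = paste0("H", match(inf$haplotype, names(tab))))
    asg <- assign_strains(net, ih)
    major_ids <- asg$individual_strain$individual_id[
      asg$individual_strain$strain %in% asg$strains$strain[asg$strains$major]]
    planted <- inf$strain[match(major_ids, inf$individual_id)]
    inferred <- asg$individual_strain$strain[match(major_ids, asg$individual_strain$individual_id)]
    expect_equal(ari(planted, inferred), 1)
    # identical rebuild gives identical MST edge set
    net2 <- build_network(d, multiplicities = setNames(as.integer(tab), paste0("H", seq_along(tab))))
    expect_identical(net$edges, net2$edges)
  }
})
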