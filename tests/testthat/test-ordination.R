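procrustes_residual <- function(X, Y) {
  # optimal rotation/reflection + translation alignment of Y onto X
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(sum((Yc %*% R - Xc)^2))
}

test_that("classical scaling recovers a collinear configuration", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  p <- pcoa(d)
  x <- p$coordinates[, 1]
  expect_equal(sort(unname(x - mean(x))), c(-1, 0, 1))
  expect_equal(ncol(p$coordinates), 1L)
})

test_that("identical points give all-zero coordinates and eigenvalues", {
  d <- matrix(0, 4, 4)
  p <- pcoa(d)
  expect_equal(ncol(p$coordinates), 0L)
  expect_true(all(abs(p$eigenvalues) < 1e-12))
})

test_that("euclidean configurations are reconstructed exactly", {
  set.seed(19)
  for (rep in 1:3) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    d <- as.matrix(dist(X))
    p <- pcoa(d)
    expect_lt(procrustes_residual(X, p$coordinates[, 1:3]), 1e-8)
    # pairwise distances reconstructed from full-rank coordinates
    expect_equal(as.matrix(dist(p$coordinates)), d,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("coordinates are centered and eigenvalues conserve dispersion", {
  set.seed(23)
  haps <- vapply(1:10, function(i) paste(rbinom(60, 1, 0.5), collapse = ""), "")
  d <- hamming_matrix(haps)
  p <- suppressMessages(pcoa(d))
  expect_true(all(abs(colMeans(p$coordinates)) < 1e-9))
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # sum of eigenvalues equals total dispersion (trace of the centered matrix)
  d2 <- d$p^2
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  expect_equal(sum(p$eigenvalues), sum(diag(B)), tolerance = 1e-8)
  # agreement with the standard classical-scaling implementation
  ref <- stats::cmdscale(d$p, k = ncol(p$coordinates), eig = TRUE)
  expect_equal(abs(p$coordinates), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p$eigenvalues, ref$eig, tolerance = 1e-8)
})

test_that("asymmetric input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(m), "symmetric")
})

test_that("strains separate on the first two PCoA axes", {
  cfg <- simulation_config(n_localities = 9, individuals_per_locality = 15, seed = 29)
  pools <- simulate_strain_haplotypes(cfg)
  haps <- unlist(lapply(pools, function(p) p$haplotype))
  strain <- rep(names(pools), vapply(pools, nrow, 0L))
  names(haps) <- paste0("H", seq_along(haps))
  p <- suppressMessages(pcoa(hamming_matrix(haps)))
  xy <- p$coordinates[, 1:2]
  centroids <- aggregate(xy, list(strain = strain), mean)
  nearest <- apply(xy, 1, function(v)
    centroids$strain[which.min(colSums((t(centroids[, -1]) - v)^2))])
  expect_equal(unname(nearest), strain)  # 100% nearest-centroid purity
})

test_that("divergence cells match direct pair averaging", {
  # two haplotypes in one strain differing at 4 of 115 sites
  h1 <- strrep("0", 115)
  h2 <- paste0(strrep("1", 4), strrep("0", 111))
  d <- hamming_matrix(c(H1 = h1, H2 = h2))
  asg <- data.frame(haplotype = c("H1", "H2"), strain = "A")
  div <- divergence_table(d, asg)
  expect_equal(unname(div$mean["A", "A"]), 100 * 4 / 115, tolerance = 1e-9)
  expect_equal(unname(div$sd["A", "A"]), 0)
  # identical haplotypes: zero divergence
  d0 <- hamming_matrix(c(H1 = h1, H2 = h1))
  expect_equal(unname(divergence_table(d0, asg)$mean["A", "A"]), 0)
  # single-haplotype strain: within cell missing
  asg1 <- data.frame(haplotype = c("H1", "H2"), strain = c("A", "B"))
  div1 <- divergence_table(d, asg1, strains = c("A", "B"))
  expect_true(is.na(div1$mean["A", "A"]))
  expect_equal(unname(div1$mean["B", "A"]), 100 * 4 / 115, tolerance = 1e-9)
})

test_that("between-strain cells track planted founder separations", {
  cfg <- simulation_config(n_localities = 9, individuals_per_locality = 15,
                           within_strain_mutations = 1, seed = 37)
  pools <- simulate_strain_haplotypes(cfg)
  haps <- unlist(lapply(pools, function(p) p$haplotype))
  strain <- rep(names(pools), vapply(pools, nrow, 0L))
  names(haps) <- paste0("H", seq_along(haps))
  d <- hamming_matrix(haps)
  asg <- data.frame(haplotype = names(haps), strain = strain)
  div <- divergence_table(d, asg, strains = c("S1", "S2", "S3"))
  # planted founder separations: S1-S2 43, S1-S3 14, S2-S3 37 steps; the
  # within-strain clouds inflate cross means by up to ~2x the mutation mean
  # (2 steps = 1.74 points here)
  expect_lt(abs(div$mean["S2", "S1"] - 100 * 43 / 115), 2.5)
  expect_lt(abs(div$mean["S3", "S1"] - 100 * 14 / 115), 2.5)
  expect_lt(abs(div$mean["S3", "S2"] - 100 * 37 / 115), 2.5)
  # oracle: independent averaging loop over all cross pairs
  cross <- expand.grid(a = names(haps)[strain == "S1"],
                       b = names(haps)[strain == "S2"], stringsAsFactors = FALSE)
  oracle <- mean(vapply(seq_len(nrow(cross)), function(i)
    oracle_hamming(haps[[cross$a[i]]], haps[[cross$b[i]]]), 0)) / 115 * 100
  expect_equal(unname(div$mean["S2", "S1"]), oracle, tolerance = 1e-9)
  # individual weighting is available and differs in general
  mult <- setNames(rep(c(10L, 1L), length.out = length(haps)), names(haps))
  div_w <- divergence_table(d, asg, strains = c("S1", "S2", "S3"),
                            weight = "individual", multiplicities = mult)
  expect_false(identical(div_w$mean, div$mean))
})
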