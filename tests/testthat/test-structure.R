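test_that("PCA separates populations on PC1 and is permutation invariant", {
  set.seed(10)
  d <- rbind(matrix(rbinom(15 * 80, 2, 0.1), 15, 80),
             matrix(rbinom(15 * 80, 2, 0.9), 15, 80))
  G <- toy_genotypes(d, rep(c("A", "B"), each = 15))
  pc <- genotype_pca(G, 5)
  expect_gt(pc$variance_fraction[1], max(pc$variance_fraction[-1]))
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_lte(sum(pc$variance_fraction_all), 1 + 1e-8)
  # PC1 separates the groups
  s1 <- pc$scores[1:15, 1]; s2 <- pc$scores[16:30, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
  # permuting individuals leaves variance fractions unchanged
  perm <- sample(30)
  pc2 <- genotype_pca(subset_genotypes(G, i = perm), 5)
  expect_equal(pc2$variance_fraction, pc$variance_fraction, tolerance = 1e-10)
  expect_warning(genotype_pca(G, 50), "reducing")
})

test_that("admixture fit respects the simplex and the K = 1 reduction", {
  set.seed(11)
  d <- matrix(rbinom(20 * 100, 2, 0.35), 20, 100)
  G <- toy_genotypes(d)
  fit <- admixture_fit(G, K = 3, n_replicates = 2, seed = 1, max_iter = 60)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-6))
  expect_true(all(fit$Q >= -1e-9 & fit$Q <= 1 + 1e-9))
  expect_true(all(fit$F >= 0 & fit$F <= 1))

  # K = 1: Q all ones, cross-entropy equals the global-frequency model's
  fit1 <- admixture_fit(G, K = 1, n_replicates = 1, seed = 2)
  expect_true(all(fit1$Q == 1))
  X <- d / 2
  set.seed(invadepop:::derive_seed(2, 0) %||% 2)
  expect_equal(dim(fit1$F), c(1, 100))
  expect_equal(as.numeric(fit1$F), colMeans(X), tolerance = 1e-12)
})

test_that("admixture recovers well-separated simulated populations", {
  G <- sim_star_pops(3, n_dip = 12, n_snps = 400, N = 400, t_split = 250,
                     seed = 21)
  fit <- admixture_fit(G, K = 3, n_replicates = 3, seed = 5, max_iter = 120)
  expect_gt(mean(apply(fit$Q, 1, max)), 0.9)
})

test_that("select_k minimizes mean cross-entropy with ties to smaller K", {
  fake <- function(K, ce) structure(list(K = K, replicate_ce = ce),
                                    class = "admixture_fit")
  fits <- list(fake(1, c(0.9, 0.9)), fake(2, c(0.7, 0.7)),
               fake(3, c(0.5, 0.6)), fake(4, c(0.8, 0.8)))
  expect_equal(select_k(fits), 3)
  flat <- list(fake(1, 0.5), fake(2, 0.5), fake(3, 0.5))
  expect_equal(select_k(flat), 1)
  expect_error(select_k(fits[1]), "two K values")
})

test_that("F_ST estimator agrees with the independent textbook oracle", {
  set.seed(12)
  for (rep in 1:5) {
    d1 <- matrix(rbinom(10 * 10, 2, runif(10, 0.1, 0.9)), 10, 10, byrow = TRUE)
    d2 <- matrix(rbinom(10 * 10, 2, runif(10, 0.1, 0.9)), 10, 10, byrow = TRUE)
    G <- toy_genotypes(rbind(d1, d2), rep(c("A", "B"), each = 10))
    fst <- pairwise_fst(G)
    expect_equal(fst["A", "B"], wc_theta_oracle(d1, d2), tolerance = 1e-10)
  }
  # two-population toy near p = 0.2 vs 0.8 over 100 loci
  d1 <- matrix(rbinom(10 * 100, 2, 0.2), 10, 100)
  d2 <- matrix(rbinom(10 * 100, 2, 0.8), 10, 100)
  G <- toy_genotypes(rbind(d1, d2), rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst(G)["A", "B"], wc_theta_oracle(d1, d2),
               tolerance = 1e-10)
})

test_that("F_ST hits its limits: identical frequencies vs fixed differences", {
  set.seed(13)
  d <- matrix(rbinom(60 * 200, 2, 0.5), 60, 200)
  G <- toy_genotypes(d, rep(c("A", "B"), each = 30))
  expect_lt(abs(pairwise_fst(G)["A", "B"]), 0.02)
  fixed <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  Gf <- toy_genotypes(fixed, rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst(Gf)["A", "B"], 1, tolerance = 1e-12)
  # structure contracts
  M <- pairwise_fst(G)
  expect_true(isSymmetric(unclass(M)))
  expect_true(all(diag(M) == 0))
})

test_that("AMOVA components are exact on degenerate and null data", {
  pm <- population_map(sprintf("i%02d", 1:24),
                       rep(c("w1", "w2", "w3", "w4"), each = 6),
                       rep(c("IslA", "IslB"), each = 12))
  # all individuals identical homozygotes: all components 0
  d0 <- matrix(0L, 24, 10)
  d0[, 1] <- 2L   # variation across loci but none across alleles or units
  G0 <- genotype_matrix(d0, data.frame(chrom = "c1", pos = 1:10 * 10,
                                       ref = "A", alt = "T"),
                        data.frame(id = pm$individual, pop = pm$watershed))
  res0 <- amova(G0, pm)
  expect_true(all(abs(res0$sigma2) < 1e-12))

  # random panmictic data: percentages sum to 100
  set.seed(14)
  d <- matrix(rbinom(24 * 300, 2, 0.4), 24, 300)
  G <- genotype_matrix(d, data.frame(chrom = "c1", pos = 1:300 * 10,
                                     ref = "A", alt = "T"),
                       data.frame(id = pm$individual, pop = pm$watershed))
  res <- amova(G, pm)
  expect_equal(sum(res$percent), 100, tolerance = 0.1)
  expect_equal(nrow(res), 4)
  # single island: among-island stratum absent
  pm1 <- population_map(pm$individual, pm$watershed, rep("IslA", 24))
  res1 <- amova(G, pm1)
  expect_false("among_islands" %in% res1$stratum)
  expect_equal(sum(res1$percent), 100, tolerance = 0.1)
})

test_that("AMOVA attributes little variance to islands under panmixia", {
  pcts <- vapply(1:8, function(r) {
    m <- demographic_model(500)
    sim <- simulate_coalescent(m, 48, n_loci = 150, mode = "snp",
                               seed = 300 + r)
    H <- sim$haplotypes
    d <- H[seq(1, 48, 2), ] + H[seq(2, 48, 2), ]
    pm <- population_map(sprintf("i%02d", 1:24),
                         rep(c("w1", "w2", "w3", "w4"), each = 6),
                         rep(c("IslA", "IslB"), each = 12))
    G <- genotype_matrix(d, data.frame(chrom = "c1", pos = seq_len(ncol(d)) * 7,
                                       ref = "A", alt = "T"),
                         data.frame(id = pm$individual, pop = pm$watershed))
    res <- amova(G, pm)
    res$percent[res$stratum == "among_islands"]
  }, numeric(1))
  expect_lt(abs(mean(pcts)), 3)
})

test_that("drift tree recovers a known topology with high support", {
  # ((A,B),(C,D)),O with long internal branches
  ev <- rbind(invadepop:::event_df(150, "join", 2, 1),
              invadepop:::event_df(150, "join", 4, 3),
              invadepop:::event_df(900, "join", 3, 1),
              invadepop:::event_df(3000, "join", 5, 1))
  m <- demographic_model(rep(400, 5), ev)
  sim <- simulate_coalescent(m, rep(20, 5), n_loci = 500, mode = "snp",
                             seed = 31)
  H <- sim$haplotypes
  d <- H[seq(1, 100, 2), ] + H[seq(2, 100, 2), ]
  pops <- rep(c("A", "B", "C", "D", "O"), each = 10)
  G <- toy_genotypes(d, pops)
  pm <- population_map(G$sample_meta$id, pops,
                       ifelse(pops == "O", "Native", "IslA"))
  tr <- drift_tree(G, pm, outgroup = "O", n_bootstrap = 100, seed = 1)
  expect_setequal(tr$tree$tip.label, c("A", "B", "C", "D", "O"))
  # (A,B) and (C,D) are clades of the unrooted topology
  ut <- ape::unroot(tr$tree)
  expect_true(ape::is.monophyletic(tr$tree, c("A", "B")))
  expect_true(ape::is.monophyletic(tr$tree, c("C", "D")))
  expect_true(all(tr$tree$node.label[tr$tree$node.label != ""] >= 0))
  sup <- suppressWarnings(as.numeric(tr$tree$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
  expect_error(drift_tree(G, pm, outgroup = "Z"), "outgroup")
})

test_that("zero-divergence populations give an unresolved star-like tree", {
  set.seed(15)
  d <- matrix(rbinom(40 * 120, 2, 0.5), 40, 120)
  pops <- rep(c("A", "B", "C", "D"), each = 10)
  G <- toy_genotypes(d, pops)
  pm <- population_map(G$sample_meta$id, pops, rep("IslA", 40))
  tr <- drift_tree(G, pm, outgroup = "D", n_bootstrap = 20, seed = 2)
  expect_setequal(tr$tree$tip.label, c("A", "B", "C", "D"))
})
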