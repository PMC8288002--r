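test_that("predator index applies the half-weighting for small-bodied taxa", {
  sv <- data.frame(watershed = c("w1", "w1", "w2"),
                   taxon = c("bass", "swordtail", "goby"),
                   density = c(2, 1, 0),
                   size_class = c("large", "small", "small"))
  idx <- predator_index(sv)
  expect_equal(unname(idx["w1"]), 2.5)
  expect_equal(unname(idx["w2"]), 0)
  # linearity in densities
  sv2 <- sv; sv2$density <- sv$density * 2
  expect_equal(unname(predator_index(sv2)["w1"]), 5)
  sv3 <- sv; sv3$size_class[1] <- "medium"
  expect_error(predator_index(sv3), "size class")
})

test_that("environmental PCA is deterministic and drops constant columns", {
  set.seed(30)
  raw <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(6, 4, 5, 1, 3, 2))
  pc <- env_pca(raw)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_gte(pc$loadings[1, 1], 0)   # sign convention on first variable
  expect_gte(pc$loadings[1, 2], 0)
  raw$c <- 1
  expect_warning(pc2 <- env_pca(raw), "constant")
  expect_equal(ncol(pc2$scores), 2)
})

test_that("K = 0 latent factors reduces to plain per-SNP regression", {
  set.seed(31)
  d <- matrix(rbinom(40 * 120, 2, 0.4), 40, 120)
  y <- rnorm(40)
  G <- toy_genotypes(d)
  a <- lfmm_associate(G, y, K_latent = 0)
  # oracle: per-SNP ordinary least squares t-statistics
  z_ora <- apply(d, 2, function(g) {
    f <- stats::lm(g ~ y)
    summary(f)$coefficients["y", "t value"]
  })
  lam <- attr(a, "lambda_gif")
  expect_equal(a$z * sqrt(lam), unname(z_ora), tolerance = 1e-8)
})

test_that("calibrated p-values are uniform on null structured data", {
  # archipelago simulation, QC-filtered, environment independent of drift
  cfg <- scenario_config(n_snps = 12000, seed = 32, missing_rate = 0)
  sim <- simulate_invasion(cfg)
  env <- simulate_environment(sim$truth, cfg)
  Gh <- apply_quality_filters(subset_genotypes(
    sim$genotypes,
    i = which(sim$genotypes$sample_meta$pop %in% env$watershed)))$genotypes
  y <- env_for_individuals(Gh, env, "predator_index")
  a <- lfmm_associate(Gh, y, K_latent = 4)
  ks <- suppressWarnings(stats::ks.test(a$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(attr(a, "lambda_gif"), 1)   # structure inflates raw scores
})

test_that("Storey q-values behave on boundary and null inputs", {
  expect_warning(q1 <- storey_qvalues(rep(1, 10)), "pi0")
  expect_true(all(q1 == 1))
  set.seed(34)
  p <- runif(2000)
  q <- storey_qvalues(p)
  # pi0 close to 1 on pure null
  pi0_implied <- max(q)   # q for the largest p approx pi0
  expect_lt(abs(pi0_implied - 1), 0.1)
  # monotone in p
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  # q <= BH when pi0 < 1
  p2 <- c(runif(500, 0, 1e-4), runif(1500))
  q2 <- storey_qvalues(p2)
  bh <- p.adjust(p2, "BH")
  expect_true(all(q2 <= bh + 1e-12))
})

test_that("extreme shift flags follow the tie-inclusive 0.95 quantile", {
  # 100 distinct shifts: exactly the top 5 plus the threshold value flagged
  set.seed(35)
  n_pop <- 2
  freqs_hi <- seq(0.005, 1, length.out = 100)
  d_hi <- rbind(round(2 * freqs_hi), round(2 * freqs_hi))  # 2 individuals
  d_lo <- matrix(0L, 2, 100)
  G <- toy_genotypes(rbind(d_hi, d_lo), rep(c("H", "L"), each = 2))
  sh <- allele_frequency_shift(G, "H", "L", quantile = 0.95)
  # oracle by sorting
  thr <- sort(sh$shift)[ceiling(0.95 * 100)]
  expect_true(all(sh$extreme == (sh$shift >= quantile(sh$shift, 0.95))))
  expect_gte(sum(sh$extreme), ceiling(0.05 * 100))
  # identical populations: degenerate tie case warns
  G2 <- toy_genotypes(rbind(d_hi, d_hi), rep(c("H", "L"), each = 2))
  expect_warning(sh2 <- allele_frequency_shift(G2, "H", "L"), "degenerate")
  expect_true(all(sh2$extreme))
})

test_that("extreme-set size with distinct shifts is ceil(0.05 N)", {
  # with N distinct values, 'at or above the 0.95 empirical quantile'
  # (type-7) flags ceil(0.05 N) loci: 613 of 12254
  set.seed(36)
  shift <- sample(seq_len(12254)) / 12254
  thr <- quantile(shift, 0.95, names = FALSE)
  expect_equal(sum(shift >= thr), ceiling(0.05 * 12254))
  expect_equal(sum(shift >= thr), 613)
})

test_that("hypergeometric enrichment matches brute-force summation", {
  # brute force via log-gamma PMF summation
  brute <- function(n_assoc, x, N, K) {
    lpmf <- function(k) lchoose(K, k) + lchoose(N - K, n_assoc - k) -
      lchoose(N, n_assoc)
    sum(exp(vapply(x:min(n_assoc, K), lpmf, numeric(1))))
  }
  expect_equal(enrichment_test(13, 1, 12254, 613), brute(13, 1, 12254, 613),
               tolerance = 1e-12)
  expect_equal(round(enrichment_test(13, 1, 12254, 613), 3), 0.487)
  expect_lt(enrichment_test(72, 19, 12254, 613), 1e-4)
  expect_equal(enrichment_test(5, 0, 100, 0), 1)
  set.seed(37)
  for (i in 1:20) {
    N <- sample(1000:20000, 1); K <- sample(50:800, 1)
    n <- sample(5:80, 1); x <- sample(0:min(n, 10), 1)
    expect_equal(enrichment_test(n, x, N, K), brute(n, x, N, K),
                 tolerance = 1e-12)
  }
  expect_error(enrichment_test(5, 6, 100, 50), "inconsistent")
})

test_that("H_e-environment correlation matches the direct formula", {
  div <- data.frame(pop = paste0("w", 1:5), n = 5,
                    He_variant = c(0.10, 0.12, 0.15, 0.11, 0.18))
  env <- data.frame(watershed = paste0("w", 1:5), island = "A",
                    predator_index = c(0.3, 0.5, 0.9, 0.4, 1.4))
  out <- he_env_correlation(div, env)
  x <- env$predator_index; y <- div$He_variant
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$variable == "predator_index"], r_direct,
               tolerance = 1e-12)
  # perfectly linear gives r = 1
  div2 <- div; div2$He_variant <- 0.05 + 0.1 * env$predator_index
  out2 <- he_env_correlation(div2, env)
  expect_equal(out2$r, 1, tolerance = 1e-12)
})

test_that("gene-window candidate mapping honours the 200 bp boundary", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tgene\t1900\t2600\t.\t-\t.\tID=gene2",
    "chr2\tsrc\tgene\t500\t900\t.\t+\t.\tID=gene3"), gff)
  snps <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
                     pos = c(800, 799, 1500, 2100, 100))
  expect_warning(hits <- map_candidates_to_genes(snps, gff), "absent")
  expect_true(any(hits$pos == 800 & hits$gene_id == "gene1"))   # start - 200
  expect_false(any(hits$pos == 799))                            # start - 201
  expect_true(any(hits$pos == 1500 & hits$gene_id == "gene1"))  # in body
  # SNP at 2100 overlaps both gene1 (end+200 >= 2100) and gene2
  expect_setequal(hits$gene_id[hits$pos == 2100], c("gene1", "gene2"))
  unlink(gff)
})

test_that("group frequency comparison counts reference-absent alleles", {
  d <- rbind(matrix(2L, 4, 3),             # focal: fixed alt
             matrix(0L, 4, 3))             # reference: absent
  d[5, 2] <- 1L                            # locus 2 present in reference
  G <- toy_genotypes(d, rep(c("F", "R"), each = 4))
  cmp <- compare_group_frequencies(G, 1:3, "F", "R")
  expect_equal(cmp$n_absent_in_reference, 2)
  expect_equal(cmp$freq$F, c(1, 1, 1))
})
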