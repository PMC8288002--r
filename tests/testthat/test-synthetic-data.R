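test_that("scenario validation rejects infeasible configurations", {
  expect_error(scenario_config(mu = 0), "mu")
  expect_error(scenario_config(gens_per_year = -1), "gens_per_year")
  expect_error(scenario_config(island_split_times = 400), "founding")
  expect_error(scenario_config(samples_per_watershed = 1), "2, ancestral_Ne")
  expect_error(scenario_config(
    translocation_edges = data.frame(source = "22004", dest = "33011",
                                     time = 400, fraction = 0.1)),
    "more recent")
  # translocation into a watershed before the watershed exists
  cfg <- scenario_config(
    translocation_edges = data.frame(source = "22004", dest = "33011",
                                     time = 280, fraction = 0.1),
    n_snps = 10)
  expect_error(simulate_invasion(cfg), "founding")
})

test_that("default archipelago scenario matches the study design shape", {
  cfg <- scenario_config(n_snps = 40)
  expect_equal(cfg$watersheds_per_island, c(3, 8, 4, 3))
  expect_equal(sum(cfg$watersheds_per_island), 18)
  expect_equal(sum(cfg$samples_per_watershed) + sum(cfg$native_samples), 282)
  expect_true(all(cfg$samples_per_watershed >= 3 &
                    cfg$samples_per_watershed <= 29))
  expect_equal(cfg$founder_time_generations, 350)

  sim <- simulate_invasion(cfg)
  pm <- sim$popmap
  haw <- pm[pm$island != "Native", ]
  expect_equal(length(unique(haw$watershed)), 18)
  expect_equal(length(unique(haw$island)), 4)
  expect_equal(nrow(pm), 282)
  expect_equal(ncol(sim$genotypes$dosage), 40)
  # chromosome labels usable for block resampling
  expect_gt(length(unique(sim$genotypes$locus_meta$chrom)), 1)
  # truth record events are time ordered
  expect_false(is.unsorted(sim$truth$events$time))
})

test_that("simulation is deterministic given the seed", {
  cfg <- scenario_config(watersheds_per_island = c(2, 2), n_islands = 2,
                         samples_per_watershed = 5, native_samples = c(5),
                         native_split_times = numeric(), n_snps = 60,
                         seed = 7)
  s1 <- simulate_invasion(cfg)
  s2 <- simulate_invasion(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  e1 <- simulate_environment(s1$truth, cfg)
  e2 <- simulate_environment(s2$truth, cfg)
  expect_identical(e1, e2)
})

test_that("neutral folded SFS matches the analytic expectation", {
  # constant-size single population, Poisson mutations over 1e5 sites
  N <- 1000; mu <- 1e-6; sites <- 50; n_loci <- 2000; n <- 20
  sim <- simulate_coalescent(demographic_model(N), n, n_loci = n_loci,
                             mode = "poisson", mu = mu,
                             sites_per_locus = sites, seed = 11)
  cnt <- colSums(sim$haplotypes)
  minor <- pmin(cnt, n - cnt)
  obs <- tabulate(minor, nbins = n %/% 2)
  theta <- 4 * N * mu * sites * n_loci
  expect_val <- expected_sfs_constant(n, theta)
  # Monte-Carlo SE per class from per-genealogy dispersion
  per_loc <- matrix(0, n_loci, n %/% 2)
  idx <- cbind(sim$locus, minor)
  for (i in seq_len(n %/% 2))
    per_loc[, i] <- tabulate(sim$locus[minor == i], nbins = n_loci)
  se <- apply(per_loc, 2, sd) * sqrt(n_loci)
  expect_true(all(abs(obs - expect_val) <= 3 * pmax(se, 1)))
})

test_that("zero post-split divergence gives F_ST near zero", {
  m <- demographic_model(c(500, 500),
                         invadepop:::event_df(1e-6, "join", 2, 1))
  sim <- simulate_coalescent(m, c(40, 40), n_loci = 400, mode = "snp",
                             seed = 3)
  H <- sim$haplotypes
  G <- toy_genotypes(H[seq(1, 80, 2), ] + H[seq(2, 80, 2), ],
                     rep(c("A", "B"), each = 20))
  fst <- pairwise_fst(G)
  expect_lt(abs(fst["A", "B"]), 0.02)
})

test_that("F_ST grows with post-split time in expectation", {
  mean_fst <- function(t_split) {
    vals <- vapply(1:10, function(r) {
      m <- demographic_model(c(300, 300),
                             invadepop:::event_df(t_split, "join", 2, 1))
      sim <- simulate_coalescent(m, c(30, 30), n_loci = 120, mode = "snp",
                                 seed = 100 * t_split + r)
      H <- sim$haplotypes
      G <- toy_genotypes(H[seq(1, 60, 2), ] + H[seq(2, 60, 2), ],
                         rep(c("A", "B"), each = 15))
      pairwise_fst(G)["A", "B"]
    }, numeric(1))
    mean(vals)
  }
  f <- vapply(c(20, 120, 400), mean_fst, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("environment table has 5 covariates per watershed and honours variance knobs", {
  cfg <- scenario_config(n_snps = 10)
  env <- simulate_environment(list(), cfg)
  expect_equal(nrow(env), 18)
  expect_equal(setdiff(names(env), c("watershed", "island")),
               c("landscape_pc1", "landscape_pc2", "waterquality_pc1",
                 "waterquality_pc2", "predator_index"))
  # zero-variance configuration: all watersheds identical
  cfg0 <- scenario_config(n_snps = 10, env_island_sd = 0, env_noise_sd = 0)
  env0 <- simulate_environment(list(), cfg0)
  expect_true(all(apply(env0[, 3:7], 2, sd) == 0))
})

test_that("no island-level shifts gives between-island ANOVA F near 1", {
  cfg <- scenario_config(n_snps = 10, env_island_sd = 0)
  Fs <- unlist(lapply(1:40, function(r) {
    env <- simulate_environment(list(), cfg, seed = r)
    vapply(3:7, function(j) {
      a <- anova(stats::lm(env[[j]] ~ env$island))
      a$`F value`[1]
    }, numeric(1))
  }))
  # F(2, 15) has mean df2/(df2-2) = 15/13 under the null; generous MC slack
  expect_lt(abs(mean(Fs) - 15 / 13), 0.35)
})

test_that("selection injection shapes allele frequencies along the gradient", {
  sim <- small_invasion()
  env <- simulate_environment(sim$truth, sim$config)
  G <- impute_missing(sim$genotypes, seed = 5)

  # b = 0: pooled frequencies unchanged in distribution
  spec0 <- data.frame(locus = 1:15, covariate = "predator_index", slope = 0)
  inj0 <- inject_environmental_selection(G, env, spec0, seed = 1)
  p_before <- invadepop:::allele_freq(G)[1:15]
  p_after <- invadepop:::allele_freq(inj0$genotypes)[1:15]
  expect_lt(max(abs(p_before - p_after)), 0.25)

  # |b| = 2: strong frequency-covariate correlation at target loci
  p <- invadepop:::allele_freq(G)
  targets <- which(p > 0.25 & p < 0.75)[1:20]
  spec2 <- data.frame(locus = targets, covariate = "predator_index", slope = 2)
  inj2 <- inject_environmental_selection(G, env, spec2, seed = 2)
  cors <- vapply(targets, function(l) {
    pw <- vapply(env$watershed, function(w)
      mean(inj2$genotypes$dosage[G$sample_meta$pop == w, l]) / 2, numeric(1))
    cor(pw, env$predator_index)
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
  # non-selected loci untouched
  other <- setdiff(seq_len(ncol(G$dosage)), targets)[1:10]
  expect_identical(G$dosage[, other], inj2$genotypes$dosage[, other])
})

test_that("default selection spec reproduces the 121/113 structure", {
  sim <- small_invasion()
  G <- impute_missing(sim$genotypes, seed = 5)
  spec <- default_selection_spec(G, seed = 3)
  per_locus <- table(spec$locus)
  expect_equal(length(per_locus), 121)
  expect_equal(sum(per_locus == 1), 113)
  expect_equal(sum(per_locus == 2), 8)
  expect_equal(length(unique(spec$covariate)), 5)
})

test_that("fixtures round-trip losslessly through the VCF reader", {
  sim <- small_invasion()
  env <- simulate_environment(sim$truth, sim$config)
  out <- tempfile("fixture_")
  files <- write_fixture(sim$genotypes, sim$popmap, env, sim$truth, out)
  expect_true(all(file.exists(files)))
  rt <- read_genotypes(files[["vcf"]], files[["popmap"]])
  expect_identical(unname(rt$genotypes$dosage), unname(sim$genotypes$dosage))
  expect_equal(rt$genotypes$locus_meta$pos, sim$genotypes$locus_meta$pos)
  expect_equal(rt$popmap$watershed, sim$popmap$watershed)
  # missing entries encoded ./. come back as NA
  expect_identical(is.na(rt$genotypes$dosage), is.na(sim$genotypes$dosage))
  unlink(out, recursive = TRUE)
})

test_that("a 2-individual 3-locus VCF has 3 records and 2 sample columns", {
  G <- toy_genotypes(matrix(c(0, 1, 2, NA, 1, 0), nrow = 2))
  path <- tempfile(fileext = ".vcf")
  write_vcf(G, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3)
  expect_equal(length(strsplit(body[1], "\t")[[1]]), 9 + 2)
  expect_match(body[2], "\\./\\.")
  unlink(path)
})
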