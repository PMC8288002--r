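# Self-contained validation experiments: each one simulates data with a
# known answer, runs the corresponding analysis, and returns the measured
# quantities.  They back both the test suite and scripts/acceptance.R, and
# the problem sizes used are the package's documented defaults (see the
# methods vignette).

#' Trio-enumeration counts for the study design
#'
#' Enumerates watershed trios for the 18-watershed / 4-island sampling
#' design (island sizes 3, 8, 4, 3).
#'
#' @return list with `n_all` and `n_cross_island`.
#' @export
bench_trio_counts <- function() {
  pm <- {
    cfg <- scenario_config(n_snps = 10)
    wlab <- watershed_labels(cfg)
    population_map(paste0(wlab, "_1"), wlab,
                   rep(island_labels(4), cfg$watersheds_per_island))
  }
  list(n_all = nrow(enumerate_trios(pm)),
       n_cross_island = nrow(enumerate_trios(pm, cross_island_only = TRUE)))
}

#' Enrichment p-values for the published contingency counts
#'
#' One-sided hypergeometric enrichment p for the two canonical cases:
#' 13 associated loci with 1 extreme, and 72 associated with 19 extreme,
#' among 12,254 loci with 613 in the 0.95-quantile tail.
#'
#' @return list with `p_13_1` and `p_72_19`.
#' @export
bench_enrichment <- function() {
  list(p_13_1 = enrichment_test(13, 1, 12254, 613),
       p_72_19 = enrichment_test(72, 19, 12254, 613))
}

#' Neutral-SFS engine accuracy
#'
#' Simulates a constant-size population (Poisson mutations over ~1e5 sites),
#' compares its folded SFS with the analytic expectation per entry, and
#' checks that the joint-SFS engine's marginals match the single-population
#' expectation.
#'
#' @param seed integer seed.
#' @return list with `max_abs_z` (max per-entry |obs - expected| / MC SE)
#'   and `marginal_max_rel_err` (joint-engine marginal vs `2/i`).
#' @export
bench_sfs_engine <- function(seed = 1) {
  N <- 1000; mu <- 1e-6; sites <- 50; n_loci <- 2000; n <- 20
  sim <- simulate_coalescent(demographic_model(N), n, n_loci = n_loci,
                             mode = "poisson", mu = mu,
                             sites_per_locus = sites,
                             seed = derive_seed(seed, 41L))
  cnt <- colSums(sim$haplotypes)
  minor <- pmin(cnt, n - cnt)
  obs <- tabulate(minor, nbins = n %/% 2)
  expect <- expected_sfs_constant(n, 4 * N * mu * sites * n_loci)
  per_loc <- vapply(seq_len(n %/% 2), function(i)
    sd(tabulate(sim$locus[minor == i], nbins = n_loci)) * sqrt(n_loci),
    numeric(1))
  max_abs_z <- max(abs(obs - expect) / pmax(per_loc, 1))

  spec <- branch_spectrum(split_model(1, 1, 0.3), c(8, 8), n_reps = 40000,
                          seed = derive_seed(seed, 42L))
  marg <- rowSums(spec)[2:8]
  rel <- abs(marg - 2 / (1:7)) / (2 / (1:7))
  list(max_abs_z = max_abs_z, marginal_max_rel_err = max(rel))
}

# one simulated trio dataset under ((P1,P2),P3),O with optional pulse P3->P2
sim_trio_dataset <- function(seed, pulse = 0, n_loci = 2000, n_dip = 12) {
  ev <- rbind(
    if (pulse > 0) event_df(100, "pulse", 2, 3, pulse) else NULL,
    event_df(400, "join", 2, 1),
    event_df(1600, "join", 3, 1),
    event_df(8000, "join", 4, 1))
  m <- demographic_model(rep(1000, 4), ev)
  sim <- simulate_coalescent(m, rep(2L * n_dip, 4), n_loci = n_loci,
                             mode = "snp", seed = seed)
  H <- sim$haplotypes
  d <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
  pops <- rep(c("P1", "P2", "P3", "OG"), each = n_dip)
  genotype_matrix(d, data.frame(chrom = "c1", pos = seq_len(ncol(d)) * 10,
                                ref = "A", alt = "T"),
                  data.frame(id = sprintf("i%03d", seq_len(nrow(d))),
                             pop = pops))
}

#' Null calibration of the D statistic
#'
#' Simulates strictly bifurcating trios (no admixture) and measures the
#' fraction of |Z| > 1.96, which should sit near the nominal 5%.
#'
#' @param n_trios independent simulated trios (default 200).
#' @param seed integer seed.
#' @return list with `reject_rate` and `n_trios`.
#' @export
bench_dstat_null <- function(n_trios = 200, seed = 1) {
  zs <- vapply(seq_len(n_trios), function(r) {
    G <- sim_trio_dataset(derive_seed(seed, 100L + r), n_loci = 3000,
                          n_dip = 16)
    d_statistic(G, c("P1", "P2", "P3"),
                G$sample_meta$id[G$sample_meta$pop == "OG"],
                block_size = 50)$Z
  }, numeric(1))
  list(reject_rate = mean(abs(zs) > 1.96), n_trios = n_trios)
}

#' Power of the D statistic against an admixture pulse
#'
#' Simulates a 15% pulse from P3 into P2 and measures how often D is
#' positive with |Z| > 3.
#'
#' @param n_reps replicate datasets (default 20).
#' @param pulse pulse fraction (default 0.15).
#' @param seed integer seed.
#' @return list with `power`, `mean_D`, `n_reps`.
#' @export
bench_dstat_pulse <- function(n_reps = 20, pulse = 0.15, seed = 1) {
  res <- vapply(seq_len(n_reps), function(r) {
    G <- sim_trio_dataset(derive_seed(seed, 300L + r), pulse = pulse,
                          n_loci = 6000, n_dip = 20)
    st <- d_statistic(G, c("P1", "P2", "P3"),
                      G$sample_meta$id[G$sample_meta$pop == "OG"],
                      block_size = 100)
    c(hit = st$D > 0 && st$Z > 3, D = st$D)
  }, numeric(2))
  list(power = mean(res["hit", ]), mean_D = mean(res["D", ]),
       n_reps = n_reps)
}

# simulate one two-population split dataset in diffusion units:
# Poisson mutations (so SFS expectations match the engine), chromosome
# labels in blocks of whole genealogies for the block bootstrap
sim_split_dataset <- function(T_split, seed, n_loci = 24000, n_dip = 5,
                              mu_locus = 0.15, n_chrom = 25) {
  m <- split_model(1, 1, T_split)
  sim <- simulate_coalescent(m, rep(2L * n_dip, 2), n_loci = n_loci,
                             mode = "poisson", mu = mu_locus,
                             sites_per_locus = 1, seed = seed)
  H <- sim$haplotypes
  S <- ncol(H)
  d <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
  chrom <- paste0("c", ceiling(sim$locus / ceiling(n_loci / n_chrom)))
  pos <- stats::ave(seq_len(S), chrom, FUN = seq_along) * 10L
  genotype_matrix(d, data.frame(chrom = chrom, pos = pos,
                                ref = "A", alt = "T"),
                  data.frame(id = sprintf("i%03d", seq_len(nrow(d))),
                             pop = rep(c("A", "B"), each = n_dip)))
}

#' Split-model recovery and adjusted-LRT calibration
#'
#' For each replicate: simulate a no-migration split at `T_true` (diffusion
#' units), fit the no-migration model, build the chromosome-block bootstrap
#' CI for T (alpha +/- 1.96 beta) and record whether it covers the truth;
#' fit the asymmetric-migration model and record whether the
#' Godambe-adjusted LRT rejects no-migration at alpha = 0.05.
#'
#' @param n_reps replicates (default 20).
#' @param T_true true split time (default 0.01, in 2 N_ref generations).
#' @param seed integer seed.
#' @param engine_reps Monte-Carlo genealogies per likelihood evaluation.
#' @param n_boot bootstrap replicates per CI.
#' @return list with `ci_coverage`, `lrt_nonreject_rate`, `mean_T_hat`,
#'   `n_reps`.
#' @export
bench_split_recovery <- function(n_reps = 20, T_true = 0.01, seed = 1,
                                 engine_reps = 10000, n_boot = 12) {
  res <- vapply(seq_len(n_reps), function(r) {
    es <- derive_seed(seed, 900L + r)
    G <- sim_split_dataset(T_true, seed = derive_seed(seed, 500L + r))
    sfs <- joint_folded_sfs(G, "A", "B", L = 1e6)
    fit <- fit_split_model(sfs, migration = FALSE, seed = r,
                           engine_reps = engine_reps, engine_seed = es,
                           n_starts = 2, maxit = 80)
    ci <- bootstrap_ci(fit, G, n_boot = n_boot, seed = derive_seed(seed, 600L + r),
                       maxit = 80, fresh_engine_noise = TRUE)
    cover <- ci$ci["T", "lower"] <= T_true && ci$ci["T", "upper"] >= T_true
    # the migration fit starts essentially at the null optimum (m ~ 0) so
    # its likelihood can only move up from there
    fitm <- fit_split_model(sfs, migration = TRUE, seed = r,
                            engine_reps = engine_reps, engine_seed = es,
                            n_starts = 2, maxit = 120,
                            start = c(fit$params[1:3], m12 = 1e-3, m21 = 1e-3))
    # score-covariance estimation reuses cached spectra, so extra bootstrap
    # replicates and re-evaluation genealogies are cheap
    boots <- bootstrap_joint_sfs(G, "A", "B", n_boot = 2L * n_boot, L = 1e6,
                                 seed = derive_seed(seed, 700L + r))
    lrt <- tryCatch(adjusted_lrt(fit, fitm, boots, ll_reps = 1e6),
                    error = function(e) list(p = NA_real_))
    c(cover = cover, reject = lrt$p < 0.05, T_hat = unname(fit$params["T"]))
  }, numeric(3))
  rej <- res["reject", ]
  list(ci_coverage = mean(res["cover", ]),
       lrt_nonreject_rate = mean(!rej[!is.na(rej)]),
       n_lrt_failed = sum(is.na(rej)),
       mean_T_hat = mean(res["T_hat", ]), n_reps = n_reps)
}

#' Cluster-number recovery on a five-population archipelago
#'
#' Simulates five drifted populations (star split), applies the standard
#' quality filters, scans K by held-out cross-entropy and records how often
#' the true K = 5 is selected.
#'
#' @param n_seeds independent simulations (default 10).
#' @param seed integer seed.
#' @return list with `k5_rate`, `selected` (vector of chosen K).
#' @export
bench_k_selection <- function(n_seeds = 10, seed = 1) {
  sel <- vapply(seq_len(n_seeds), function(s) {
    ev <- do.call(rbind, lapply(2:5, function(dd) event_df(250, "join", dd, 1)))
    m <- demographic_model(rep(500, 5), ev)
    sim <- simulate_coalescent(m, rep(24L, 5), n_loci = 4000, mode = "snp",
                               seed = derive_seed(seed, 800L + s))
    H <- sim$haplotypes   # 120 haploid genomes = 12 diploids per population
    d <- H[seq(1, 120, 2), ] + H[seq(2, 120, 2), ]
    G0 <- genotype_matrix(d, data.frame(chrom = "c1",
                                        pos = seq_len(ncol(d)) * 10,
                                        ref = "A", alt = "T"),
                          data.frame(id = sprintf("i%03d", 1:60),
                                     pop = rep(paste0("P", 1:5), each = 12)))
    G <- apply_quality_filters(G0)$genotypes
    scan <- admixture_scan(G, K_range = 1:7, n_replicates = 3,
                           mask_fraction = 0.05, seed = derive_seed(seed, s))
    scan$best_K
  }, integer(1))
  list(k5_rate = mean(sel == 5), selected = sel)
}

#' Association-scan calibration and power at study scale
#'
#' Simulates the default archipelago, applies the quality filters to the
#' Hawaiian subset, and (a) verifies the calibrated null p-values are
#' uniform (Kolmogorov-Smirnov), (b) injects loci responding to the
#' predator index and measures recovery at q < 0.05.
#'
#' @param seed integer seed.
#' @param n_snps simulated SNPs before filtering (default 40000, leaving
#'   roughly 5000 testable Hawaiian loci).
#' @param slope injected effect size (logit units per covariate SD).
#' @param n_inject injected loci (default 60).
#' @return list with `ks_p`, `n_null_loci`, `power`, `lambda_gif`.
#' @export
bench_association <- function(seed = 1, n_snps = 40000, slope = 2,
                              n_inject = 60) {
  cfg <- scenario_config(n_snps = n_snps, seed = derive_seed(seed, 1000L),
                         missing_rate = 0)
  sim <- simulate_invasion(cfg)
  env <- simulate_environment(sim$truth, cfg)
  Gh <- apply_quality_filters(subset_genotypes(
    sim$genotypes,
    i = which(sim$genotypes$sample_meta$pop %in% env$watershed)))$genotypes
  y <- env_for_individuals(Gh, env, "predator_index")
  a0 <- lfmm_associate(Gh, y, K_latent = 4)
  ks <- suppressWarnings(stats::ks.test(a0$p[!is.na(a0$p)], "punif"))

  local_seed(derive_seed(seed, 1001L))
  p <- allele_freq(Gh)
  targets <- sample(which(p > 0.1 & p < 0.9), n_inject)
  spec <- data.frame(locus = targets, covariate = "predator_index",
                     slope = slope)
  inj <- inject_environmental_selection(Gh, env, spec,
                                        seed = derive_seed(seed, 1002L))
  a1 <- lfmm_associate(inj$genotypes, y, K_latent = 4)
  list(ks_p = ks$p.value, n_null_loci = sum(!is.na(a0$p)),
       power = mean(a1$q[targets] < 0.05, na.rm = TRUE),
       lambda_gif = attr(a0, "lambda_gif"))
}
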