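test_that("folded SFS tallies minor-allele counts by hand", {
  # one locus, dosages (1, 1) in 2 diploids: minor count 2 of n = 4
  G <- toy_genotypes(matrix(c(1L, 1L), 2, 1))
  s <- folded_sfs(G, "P1", L = 100)
  expect_equal(unname(s$counts), c(0, 1))
  expect_equal(s$n, 4)
  expect_equal(s$L, 100)
  # all loci fixed: empty spectrum body
  G0 <- toy_genotypes(matrix(2L, 3, 5))
  s0 <- folded_sfs(G0, "P1")
  expect_equal(sum(s0$counts), 0)
  expect_equal(s0$n_monomorphic, 5)
  # degenerate sample size
  G1 <- toy_genotypes(matrix(1L, 1, 3))
  expect_error(folded_sfs(G1, "P1"), "4 haploid")
})

test_that("the constant-size expectation matches its closed form", {
  expect_equal(expected_sfs_constant(4, 1), c(1 / 1 + 1 / 3, 0.5),
               tolerance = 1e-12)
  # linear in theta
  expect_equal(expected_sfs_constant(10, 6), 3 * expected_sfs_constant(10, 2),
               tolerance = 1e-12)
  # Watterson identity: total unfolded mass = theta * sum 1/i
  n <- 12; theta <- 5
  i <- 1:(n - 1)
  unfolded <- theta / i
  folded <- expected_sfs_constant(n, theta)
  expect_equal(sum(folded), sum(unfolded), tolerance = 1e-12)
  expect_error(expected_sfs_constant(3, 1))
})

test_that("joint folded SFS conserves segregating sites and folds correctly", {
  set.seed(40)
  d <- matrix(rbinom(12 * 200, 2, runif(200, 0.1, 0.9)), 12, 200, byrow = TRUE)
  G <- toy_genotypes(d, rep(c("A", "B"), each = 6))
  s <- joint_folded_sfs(G, "A", "B", L = 1e5)
  seg <- sum(apply(d, 2, function(x) {
    ca <- sum(x[1:6]); cb <- sum(x[7:12])
    !(ca + cb == 0) && !(ca + cb == 24)
  }))
  expect_equal(sum(s$counts), seg)
  expect_equal(s$n, c(12, 12))
  # the fold leaves no mass above the antidiagonal
  idx <- which(s$counts > 0, arr.ind = TRUE)
  expect_true(all((idx[, 1] - 1) + (idx[, 2] - 1) <= 12))
})

test_that("piecewise expected SFS matches the closed form for constant size", {
  eng <- invadepop:::sfs_engine(20, n_reps = 6000, seed = 5)
  mu <- 1e-8; L <- 1e7; Ne <- 1000
  xi <- invadepop:::expected_sfs_piecewise(eng, numeric(), Ne, mu, L)
  exact <- expected_sfs_constant(20, 4 * Ne * mu * L)
  expect_true(all(abs(xi - exact) / exact < 0.03))
})

test_that("expected joint SFS marginals match the single-deme expectation", {
  # nu1 = nu2 = 1, no migration: each deme's marginal spectrum is the
  # constant-size expectation 2/i (in units of 2 N_ref generations)
  m <- invadepop:::split_model(1, 1, 0.3)
  spec <- branch_spectrum(m, c(8, 8), n_reps = 40000, seed = 6)
  marg <- rowSums(spec)[2:8]   # classes i = 1..7 for deme 1
  expect_true(all(abs(marg - 2 / (1:7)) / (2 / (1:7)) < 0.05))
  # no-split limit: T = 0 behaves like a single panmictic population
  m0 <- invadepop:::split_model(1, 1, 1e-9)
  sp0 <- branch_spectrum(m0, c(8, 8), n_reps = 20000, seed = 7)
  tot_by_d <- sapply(0:16, function(k) {
    ix <- which(outer(0:8, 0:8, "+") == k, arr.ind = TRUE)
    sum(sp0[ix])
  })
  expect_true(all(abs(tot_by_d[2:15] - 2 / (1:14)) / (2 / (1:14)) < 0.08))
})

test_that("stairway fit recovers a constant size and obeys theta scaling", {
  n <- 20; Ne <- 1000; mu <- 1e-8; L <- 5e6
  eng_theta <- 4 * Ne * mu * L
  set.seed(50)
  counts <- rpois(n %/% 2, expected_sfs_constant(n, eng_theta))
  sfs <- structure(list(kind = "folded1d", counts = counts, n = n, L = L,
                        n_monomorphic = 0, population = "P"), class = "sfs")
  fit <- stairway_fit(sfs, mu = mu, n_epochs_grid = 1:3, n_bootstrap = 25,
                      seed = 1)
  expect_true(all(abs(fit$epochs$Ne - Ne) / Ne < 0.25))
  # doubling L with the same counts halves the implied N_e
  sfs2 <- sfs; sfs2$L <- 2 * L
  fit2 <- stairway_fit(sfs2, mu = mu, n_epochs_grid = 1, n_bootstrap = 0,
                       seed = 1)
  fit1 <- stairway_fit(sfs, mu = mu, n_epochs_grid = 1, n_bootstrap = 0,
                       seed = 1)
  expect_equal(fit2$epochs$Ne / fit1$epochs$Ne, 0.5, tolerance = 0.02)
  # small samples are refused
  sfs_small <- structure(list(kind = "folded1d", counts = c(3, 2, 1), n = 6,
                              L = 1000, n_monomorphic = 0, population = "P"),
                         class = "sfs")
  expect_error(stairway_fit(sfs_small, mu = mu), "n < 8")
})

test_that("stairway detects a founder bottleneck at the right time", {
  # 10x bottleneck 350 generations ago: N_e 1000 recent, 100 during
  # [350, 550], ancestral 5000
  ev <- rbind(invadepop:::event_df(350, "size", 1, param = 100),
              invadepop:::event_df(550, "size", 1, param = 5000))
  m <- demographic_model(1000, ev)
  hits <- vapply(1:10, function(r) {
    sim <- simulate_coalescent(m, 20, n_loci = 3000, mode = "poisson",
                               mu = 2e-7, sites_per_locus = 50,
                               seed = 800 + r)
    H <- sim$haplotypes
    cnt <- colSums(H)
    minor <- pmin(cnt, 20 - cnt)
    counts <- tabulate(minor[minor > 0], nbins = 10)
    sfs <- structure(list(kind = "folded1d", counts = counts, n = 20,
                          L = 150000, n_monomorphic = 0, population = "P"),
                     class = "sfs")
    fit <- stairway_fit(sfs, mu = 2e-7, n_epochs_grid = 2:5, n_bootstrap = 0,
                        seed = r)
    ep <- fit$epochs
    # a forward-time size drop at the founding shows as a > 2x backward
    # increase in fitted N_e; locate that change-point
    drops <- which(ep$Ne[-1] > 2 * ep$Ne[-nrow(ep)])
    length(drops) > 0 && any(ep$from_generation[drops + 1] >= 200 &
                               ep$from_generation[drops + 1] <= 500)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("N_e point estimates summarize the pre-cutoff trajectory", {
  traj <- data.frame(time_generations = c(0, 70, 350, 1400),
                     time_years = c(0, 20, 100, 400),
                     Ne = c(500, 800, 1000, 1000),
                     Ne_lo = c(300, 500, 1000, 1000),
                     Ne_hi = c(900, 1200, 1000, 1000))
  est <- ne_point_estimate(traj, cutoff_years = 30)
  expect_equal(unname(est), c(1000, 1000, 1000))
  expect_error(ne_point_estimate(traj, cutoff_years = 1e4), "older")
})

test_that("split-model fitting is self-consistent on model-generated data", {
  truth <- c(nu1 = 1.2, nu2 = 0.8, T = 0.15)
  E <- expected_joint_sfs_split(truth[1], truth[2], truth[3], 0, 0,
                                n1 = 8, n2 = 8, engine_reps = 30000, seed = 7)
  counts <- round(E * 4000 / sum(E))
  sfs <- structure(list(kind = "folded2d", counts = counts, n = c(8, 8),
                        L = 1e6, populations = c("A", "B")), class = "sfs")
  fit <- fit_split_model(sfs, migration = FALSE, seed = 3,
                         engine_reps = 15000, n_starts = 2, maxit = 150)
  expect_true(all(abs(fit$params[1:3] - truth) / truth < 0.35))
  expect_equal(fit$model, "split_no_migration")
})

test_that("time conversion and effective length follow their identities", {
  expect_equal(convert_time(0, 1, 1e-8, 1000), 0)
  # N_ref = 1: years = T * 2 / gens_per_year
  mu <- 4.89e-8; L <- 1e6
  expect_equal(convert_time(1, 4 * mu * L, mu, L, gens_per_year = 3.5),
               2 / 3.5, tolerance = 1e-12)
  expect_error(convert_time(1, 0, mu, L), "positive")
  expect_error(convert_time(-1, 1, mu, L), "non-negative")

  expect_equal(effective_length(1000, 50, 50), 1000)
  expect_equal(effective_length(1e6, 216, 10000), 21600)
  expect_error(effective_length(1e6, 11, 10), "exceeds")
  expect_error(effective_length(1e6, 1, 0), "positive")
})

test_that("zero-variance chromosome bootstrap gives zero-width intervals", {
  # a single chromosome: every resample is the same data
  m <- invadepop:::split_model(1, 1, 0.1)
  sim <- simulate_coalescent(m, c(8, 8), n_loci = 800, mode = "snp", seed = 9)
  H <- sim$haplotypes
  d <- H[seq(1, 16, 2), ] + H[seq(2, 16, 2), ]
  G <- toy_genotypes(d, rep(c("A", "B"), each = 4), n_chrom = 1L)
  sfs <- joint_folded_sfs(G, "A", "B", L = 1e5)
  fit <- fit_split_model(sfs, migration = FALSE, seed = 2,
                         engine_reps = 8000, n_starts = 1, maxit = 80)
  ci <- bootstrap_ci(fit, G, n_boot = 12, seed = 3, maxit = 40)
  expect_true(all(abs(ci$ci[, "upper"] - ci$ci[, "lower"]) < 1e-6))
})

test_that("an exact likelihood tie gives adjusted LRT p = 1", {
  m <- invadepop:::split_model(1, 1, 0.1)
  sim <- simulate_coalescent(m, c(8, 8), n_loci = 1500, mode = "snp", seed = 10)
  H <- sim$haplotypes
  d <- H[seq(1, 16, 2), ] + H[seq(2, 16, 2), ]
  G <- toy_genotypes(d, rep(c("A", "B"), each = 4), n_chrom = 8L)
  sfs <- joint_folded_sfs(G, "A", "B", L = 1e5)
  fit_s <- fit_split_model(sfs, migration = FALSE, seed = 2,
                           engine_reps = 8000, n_starts = 1, maxit = 80)
  # a "full" model pinned at the same parameters with m = 0
  fit_f <- fit_s
  fit_f$n_free <- 5L
  fit_f$model <- "split_asym_migration"
  boots <- bootstrap_joint_sfs(G, "A", "B", n_boot = 8, L = 1e5, seed = 4)
  lrt <- adjusted_lrt(fit_s, fit_f, boots, ll_reps = 8000)
  expect_equal(lrt$raw_statistic, 0)
  expect_equal(lrt$p, 1)
})

test_that("the exact no-migration spectrum matches the Monte-Carlo engine", {
  for (pars in list(c(1, 1, 0.01), c(1.5, 0.7, 0.2), c(2, 2, 1.0))) {
    Ee <- expected_joint_sfs_split(pars[1], pars[2], pars[3], 0, 0,
                                   n1 = 10, n2 = 8)
    m <- invadepop:::split_model(pars[1], pars[2], max(pars[3], 1e-9))
    Em <- invadepop:::fold_joint(
      branch_spectrum(m, c(10, 8), n_reps = 1e5, seed = 4) / 2)
    big <- Em > 0.02
    expect_lt(max(abs(Ee[big] - Em[big]) / Em[big]), 0.08)
    expect_lt(abs(sum(Ee) - sum(Em)) / sum(Em), 0.01)
  }
  # marginal check against the constant-size closed form at nu = 1
  Ee <- invadepop:::exact_joint_split_spectrum(1, 1, 0.3, 8, 8)
  marg <- rowSums(Ee)[2:8]
  expect_lt(max(abs(marg - 2 / (1:7)) / (2 / (1:7))), 1e-6)
})
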