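#' Folded site frequency spectrum of one population
#'
#' Tallies per-locus minor-allele counts within the population; loci
#' monomorphic in the population fall into the 0 class and are excluded
#' from the spectrum body.
#'
#' @param G [genotype_matrix()] with no missing entries in the population.
#' @param population population id (a value of `G$sample_meta$pop`).
#' @param L total sequence length (variant + invariant sites) represented by
#'   the loci; carried on the spectrum for theta scaling.
#' @return object of class `sfs`: `kind = "folded1d"`, `counts` (classes
#'   `1..floor(n/2)`), haploid sample size `n`, `L`, and `n_monomorphic`.
#' @export
folded_sfs <- function(G, population, L = NULL) {
  rows <- which(G$sample_meta$pop == population)
  if (!length(rows)) stopf("population '%s' not found", population)
  sub <- G$dosage[rows, , drop = FALSE]
  if (anyNA(sub)) stopf("missing genotypes present; impute or filter first")
  n <- 2L * length(rows)
  if (n < 4) stopf("need at least 4 haploid genomes for a spectrum")
  cnt <- colSums(sub)
  minor <- pmin(cnt, n - cnt)
  body <- tabulate(minor[minor > 0], nbins = n %/% 2)
  names(body) <- seq_len(n %/% 2)
  structure(list(kind = "folded1d", counts = body, n = n, L = L,
                 n_monomorphic = sum(minor == 0), population = population),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  if (x$kind == "folded1d") {
    cat(sprintf("folded SFS: n = %d haploids, %d segregating sites%s\n",
                x$n, sum(x$counts),
                if (!is.null(x$L)) sprintf(", L = %g", x$L) else ""))
  } else {
    cat(sprintf("folded joint SFS: n = (%d, %d), %d segregating sites%s\n",
                x$n[1], x$n[2], round(sum(x$counts)),
                if (!is.null(x$L)) sprintf(", L = %g", x$L) else ""))
  }
  invisible(x)
}

fold_joint <- function(M) {
  # standard fold: combine each (i, j) cell with its conjugate
  # (n1-i, n2-j); keep the labeling with the smaller total minor count,
  # half-weighting self-conjugate cells on the antidiagonal
  n1 <- nrow(M) - 1L; n2 <- ncol(M) - 1L
  out <- matrix(0, n1 + 1L, n2 + 1L)
  half <- (n1 + n2) / 2
  for (i in 0:n1) for (j in 0:n2) {
    tot <- i + j
    ci <- n1 - i; cj <- n2 - j
    if (tot < half) out[i + 1, j + 1] <- M[i + 1, j + 1] + M[ci + 1, cj + 1]
    else if (tot == half)
      out[i + 1, j + 1] <- (M[i + 1, j + 1] + M[ci + 1, cj + 1]) / 2
  }
  out[1, 1] <- 0
  out
}

#' Folded joint (two-population) site frequency spectrum
#'
#' 2-D histogram of per-locus allele counts in two populations, folded by
#' summing each cell with its allele-relabeled conjugate and masking the
#' duplicate half (self-conjugate antidiagonal cells get half weight).
#'
#' @param G [genotype_matrix()] with no missing entries in both populations.
#' @param popA,popB population ids.
#' @param L total sequence length represented by the loci.
#' @return object of class `sfs` with `kind = "folded2d"`, `counts` a
#'   `(n1+1) x (n2+1)` matrix, `n = c(n1, n2)`.
#' @export
joint_folded_sfs <- function(G, popA, popB, L = NULL) {
  ra <- which(G$sample_meta$pop == popA)
  rb <- which(G$sample_meta$pop == popB)
  if (!length(ra) || !length(rb)) stopf("population not found")
  A <- G$dosage[ra, , drop = FALSE]; B <- G$dosage[rb, , drop = FALSE]
  if (anyNA(A) || anyNA(B)) stopf("missing genotypes present; impute first")
  n1 <- 2L * length(ra); n2 <- 2L * length(rb)
  if (n1 < 4 || n2 < 4) stopf("need at least 4 haploid genomes per population")
  ca <- colSums(A); cb <- colSums(B)
  raw <- matrix(0, n1 + 1L, n2 + 1L)
  tab <- table(factor(ca, levels = 0:n1), factor(cb, levels = 0:n2))
  raw[] <- as.numeric(tab)
  raw[1, 1] <- 0
  raw[n1 + 1, n2 + 1] <- 0   # monomorphic in the pair: excluded from body
  structure(list(kind = "folded2d", counts = fold_joint(raw),
                 n = c(n1, n2), L = L, populations = c(popA, popB)),
            class = "sfs")
}

#' Expected folded SFS of a constant-size population
#'
#' Analytic neutral expectation
#' `E[eta_i] = theta (1/i + 1/(n-i)) / (1 + delta_{i, n-i})`.
#'
#' @param n haploid sample size (`>= 4`).
#' @param theta population-scaled mutation rate (`4 N mu L`).
#' @return numeric vector of expected counts for classes `1..floor(n/2)`.
#' @export
expected_sfs_constant <- function(n, theta) {
  stopifnot(n >= 4, theta > 0)
  i <- seq_len(n %/% 2)
  theta * (1 / i + 1 / (n - i)) / (1 + (i == n - i))
}

# ---- expected SFS under piecewise-constant N(t) ---------------------------
#
# E[eta_i] = mu * L * sum_k k E[T_k] * C(n-i-1, k-2) / C(n-1, k-1), where
# T_k is the time during which the sample has k ancestral lineages.  For a
# piecewise-constant size history T_k is obtained by mapping the standard
# coalescent's exponential interval durations through the time rescaling
# tau(t) = int dt / (2 N(t)); the expectation is taken by Monte Carlo over a
# fixed set of draws (common random numbers), which makes the expected
# spectrum smooth in the size parameters and reproducible.

sfs_engine <- function(n, n_reps = 4000L, seed = 1L) {
  local_seed(seed)
  ks <- n:2
  S <- matrix(rexp(n_reps * length(ks)), n_reps, length(ks))
  S <- sweep(S, 2, ks * (ks - 1) / 2, "/")     # coalescent-unit durations
  ends <- t(apply(S, 1, cumsum))               # rescaled time at end of each interval
  starts <- cbind(0, ends[, -ncol(ends), drop = FALSE])
  i <- seq_len(n - 1)
  k <- 2:n
  lp <- outer(i, k, function(ii, kk)
    lchoose(n - ii - 1, kk - 2) - lchoose(n - 1, kk - 1))
  pnk <- exp(lp)                               # P(branch with k lineages subtends i)
  pnk[is.na(pnk)] <- 0
  list(n = n, starts = starts, ends = ends, pnk = pnk, ks = ks)
}

# map rescaled (coalescent-unit) times back to generations for a
# piecewise-constant trajectory: boundaries (gens, increasing, len E-1), Ne (len E)
rescaled_to_gens <- function(tau, boundaries, Ne) {
  tb <- c(0, boundaries)
  dt <- diff(c(tb, Inf))
  dtau <- dt / (2 * Ne)
  tau_b <- c(0, cumsum(dtau[-length(dtau)]))
  idx <- findInterval(tau, tau_b)
  tb[idx] + (tau - tau_b[idx]) * 2 * Ne[idx]
}

expected_sfs_piecewise <- function(engine, boundaries, Ne, mu, L,
                                   folded = TRUE) {
  n <- engine$n
  g_end <- rescaled_to_gens(engine$ends, boundaries, Ne)
  g_start <- rescaled_to_gens(engine$starts, boundaries, Ne)
  Tk <- colMeans(g_end - g_start)              # E[T_k] for k = n..2, generations
  Tk_by_k <- rev(Tk)                           # k = 2..n
  eta <- mu * L * as.numeric(engine$pnk %*% ((2:n) * Tk_by_k))
  if (!folded) return(eta)
  i <- seq_len(n %/% 2)
  xi <- eta[i] + ifelse(i == n - i, 0, eta[n - i])
  xi
}

#' Multi-epoch effective-size trajectory from a folded SFS
#'
#' Stairway-style estimator: a piecewise-constant N_e history with
#' breakpoints at expected coalescent event times is fitted by maximizing
#' the Poisson composite likelihood of the folded SFS entries, the epoch
#' count is chosen on a grid by BIC, and uncertainty comes from bootstrap
#' resampling of the SNPs (multinomial over frequency classes).
#'
#' @param sfs folded 1-D [folded_sfs()] with `L` set.
#' @param mu per-site per-generation mutation rate.
#' @param gens_per_year generations per year (for the year axis).
#' @param n_epochs_grid epoch counts tried (default `1:5`).
#' @param n_bootstrap bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param engine_reps Monte-Carlo draws for the expected-SFS engine.
#' @return object of class `epoch_model`: `epochs` (data frame
#'   `from_generation`, `Ne`, `Ne_lo`, `Ne_hi`), `n_epochs`, `loglik`,
#'   `trajectory` (long form with a year axis), `converged`.
#' @export
stairway_fit <- function(sfs, mu, gens_per_year = 3.5, n_epochs_grid = 1:5,
                         n_bootstrap = 100, seed = NULL, engine_reps = 4000L) {
  stopifnot(inherits(sfs, "sfs"), sfs$kind == "folded1d")
  if (is.null(sfs$L)) stopf("sfs must carry a sequence length L")
  n <- sfs$n
  if (n < 8) stopf("haploid sample size %d too small (populations with n < 8 are excluded)", n)
  obs <- as.numeric(sfs$counts)
  S <- sum(obs)
  if (S == 0) stopf("empty spectrum")
  local_seed(seed)
  engine <- sfs_engine(n, n_reps = engine_reps, seed = derive_seed(seed %||% 1L, 11L))

  a_n <- sum(1 / seq_len(n - 1))
  N0 <- S / (sfs$L * a_n) / (4 * mu)           # Watterson starting value
  # breakpoints at expected coalescent event times under N0
  k_all <- n:3
  ew <- 4 * N0 * (1 / (k_all - 1) - 1 / n)     # E[start of (k-1)-lineage interval]
  pick_bounds <- function(E) {
    if (E <= 1) return(numeric())
    qs <- seq_len(E - 1) / E
    unique(quantile(ew, probs = qs, names = FALSE, type = 7))
  }
  negll <- function(logNe, boundaries) {
    exp_xi <- expected_sfs_piecewise(engine, boundaries, exp(logNe), mu, sfs$L)
    exp_xi <- pmax(exp_xi, 1e-12)
    -sum(obs * log(exp_xi) - exp_xi)
  }
  fit_E <- function(E, start = NULL, counts = obs) {
    bounds <- pick_bounds(E)
    E_eff <- length(bounds) + 1
    par0 <- start %||% rep(log(N0), E_eff)
    f <- function(p) {
      exp_xi <- pmax(expected_sfs_piecewise(engine, bounds, exp(p), mu, sfs$L), 1e-12)
      -sum(counts * log(exp_xi) - exp_xi)
    }
    opt <- optim(par0, f, method = "L-BFGS-B",
                 lower = log(1), upper = log(1e9),
                 control = list(maxit = 300))
    list(Ne = exp(opt$par), boundaries = bounds, loglik = -opt$value,
         n_epochs = E_eff, converged = opt$convergence == 0)
  }
  fits <- lapply(n_epochs_grid, fit_E)
  bic <- vapply(seq_along(fits), function(i)
    -2 * fits[[i]]$loglik + fits[[i]]$n_epochs * log(max(S, 2)), numeric(1))
  best <- fits[[which.min(bic)]]

  boot_Ne <- NULL
  if (n_bootstrap > 0) {
    probs <- obs / S
    boot_Ne <- matrix(NA_real_, n_bootstrap, best$n_epochs)
    for (b in seq_len(n_bootstrap)) {
      cb <- as.numeric(rmultinom(1, S, probs))
      fb <- fit_E(best$n_epochs, start = log(best$Ne), counts = cb)
      boot_Ne[b, ] <- fb$Ne
    }
  }
  lo <- if (is.null(boot_Ne)) best$Ne else
    apply(boot_Ne, 2, quantile, 0.025, names = FALSE)
  hi <- if (is.null(boot_Ne)) best$Ne else
    apply(boot_Ne, 2, quantile, 0.975, names = FALSE)
  med <- if (is.null(boot_Ne)) best$Ne else
    apply(boot_Ne, 2, median)
  from_gen <- c(0, best$boundaries)
  epochs <- data.frame(from_generation = from_gen, Ne = best$Ne,
                       Ne_median_boot = med, Ne_lo = lo, Ne_hi = hi)
  trajectory <- data.frame(time_generations = from_gen,
                           time_years = from_gen / gens_per_year,
                           Ne = best$Ne, Ne_lo = lo, Ne_hi = hi)
  structure(list(epochs = epochs, n_epochs = best$n_epochs,
                 boundaries = best$boundaries, loglik = best$loglik,
                 bic = bic, grid = n_epochs_grid, trajectory = trajectory,
                 bootstrap_Ne = boot_Ne, converged = best$converged,
                 mu = mu, gens_per_year = gens_per_year, N0 = N0),
            class = "epoch_model")
}

#' @export
print.epoch_model <- function(x, ...) {
  cat(sprintf("epoch_model: %d epochs, log composite likelihood %.2f\n",
              x$n_epochs, x$loglik))
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Point estimate of N_e from a trajectory
#'
#' Summarizes the stairway trajectory over all time steps strictly older
#' than `cutoff_years`, returning the median of the per-step point estimate
#' and of its lower/upper confidence bounds.
#'
#' @param trajectory the `trajectory` data frame of an [stairway_fit()]
#'   result (or an `epoch_model`).
#' @param cutoff_years only epochs starting strictly before this many years
#'   ago contribute (default 30).
#' @param gens_per_year used if the trajectory lacks a year axis.
#' @return named numeric vector `(median, lower, upper)`.
#' @export
ne_point_estimate <- function(trajectory, cutoff_years = 30,
                              gens_per_year = 3.5) {
  if (inherits(trajectory, "epoch_model")) trajectory <- trajectory$trajectory
  if (is.null(trajectory$time_years))
    trajectory$time_years <- trajectory$time_generations / gens_per_year
  old <- trajectory$time_years > cutoff_years
  if (!any(old)) stopf("no trajectory step older than %g years", cutoff_years)
  c(median = median(trajectory$Ne[old]),
    lower = median(trajectory$Ne_lo[old]),
    upper = median(trajectory$Ne_hi[old]))
}

# ---- exact no-migration split spectrum ------------------------------------
#
# For the isolation (no-migration) model the expected joint SFS has a closed
# form: within each deme the lineage-count process is the standard
# coalescent observed for a finite duration (Tavare's distribution and the
# analytic interval expectations below), the block sizes of a coalescent
# partition are uniform over compositions, and the ancestral phase is a
# plain coalescent over the surviving lineages.  Everything is exact, smooth
# in the parameters and fast, so the composite likelihood carries no
# Monte-Carlo noise (which otherwise warps the optimum once the SNP count is
# large).  Numerically reliable for deme sample sizes up to ~25 haploids
# (the alternating Tavare sums lose precision beyond that).

# P(A(tau) = k | A(0) = n) for k = 1..n, and E[time with k lineages during
# [0, tau]] for k = 2..n, standard coalescent time scale
tavare_interval <- function(n, tau) {
  if (n == 1) return(list(probs = 1, Tk = 0))
  probs <- numeric(n)
  Tk <- numeric(n)              # Tk[k] = E[time with k lineages], k >= 2
  for (k in 1:n) {
    i <- k:n
    coef <- (2 * i - 1) * (-1)^(i - k) *
      exp(lgamma(k + i - 1) - lgamma(k) +            # (k)_(i-1) rising
          lgamma(n + 1) - lgamma(n - i + 1) -        # (n)_[i] falling
          lgamma(k + 1) - lgamma(i - k + 1) -        # 1/(k! (i-k)!)
          (lgamma(n + i) - lgamma(n)))               # 1/(n)_(i) rising
    rate <- i * (i - 1) / 2
    probs[k] <- sum(coef * exp(-rate * tau))
    if (k >= 2)
      Tk[k] <- sum(coef * ifelse(rate > 0, (1 - exp(-rate * tau)) / rate, tau))
  }
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  list(probs = probs, Tk = pmax(Tk, 0))
}

# P(a specific set of a blocks of the (n, k) coalescent partition carries
# i leaves in total): uniform-composition formula
block_sum_dist <- function(n, k, a) {
  p <- numeric(n + 1)
  if (a == 0) { p[1] <- 1; return(p) }          # i = 0
  if (a == k) { p[n + 1] <- 1; return(p) }      # all blocks: i = n
  ii <- a:(n - (k - a))
  p[ii + 1] <- exp(lchoose(ii - 1, a - 1) + lchoose(n - ii - 1, k - a - 1) -
                     lchoose(n - 1, k - 1))
  p / sum(p)
}

# exact unfolded expected joint spectrum at unit theta for the
# no-migration split (times in 2 N_ref generations)
exact_joint_split_spectrum <- function(nu1, nu2, T, n1, n2) {
  spec <- matrix(0, n1 + 1, n2 + 1)
  # within-deme phase: branch classes are (i, 0) and (0, i)
  deme <- function(n, nu) tavare_interval(n, T / nu)
  d1 <- deme(n1, nu1); d2 <- deme(n2, nu2)
  add_deme <- function(spec, n, ti, nu, first) {
    # E[T_k] in real (2 N_ref) units = nu * deme-scale expectation
    for (k in 2:n) {
      if (ti$Tk[k] == 0) next
      i <- 1:(n - 1)
      pk <- exp(lchoose(n - i - 1, k - 2) - lchoose(n - 1, k - 1))
      contrib <- nu * ti$Tk[k] * k * pk
      if (first) spec[i + 1, 1] <- spec[i + 1, 1] + contrib
      else spec[1, i + 1] <- spec[1, i + 1] + contrib
    }
    # a deme fully coalesced before T contributes a (n, 0) branch
    # E[T_1] = tau - sum_k E[T_k], converted to real units
    t1 <- max(T / nu - sum(ti$Tk), 0) * nu
    if (first) spec[n + 1, 1] <- spec[n + 1, 1] + t1
    else spec[1, n + 1] <- spec[1, n + 1] + t1
    spec
  }
  spec <- add_deme(spec, n1, d1, nu1, TRUE)
  spec <- add_deme(spec, n2, d2, nu2, FALSE)

  # ancestral phase: condition on surviving counts (k1, k2); the per-(k1,k2)
  # spectra do not depend on (nu1, nu2, T), so they are built once per
  # sample-size pair and reweighted by the survival probabilities
  basis <- exact_ancestral_basis(n1, n2)
  for (k1 in 1:n1) for (k2 in 1:n2) {
    w <- d1$probs[k1] * d2$probs[k2]
    if (w < 1e-14) next
    spec <- spec + w * basis[[(k1 - 1) * n2 + k2]]
  }
  spec[1, 1] <- 0
  spec[n1 + 1, n2 + 1] <- 0
  spec
}

# per-(k1, k2) ancestral-phase expected branch-class spectra, cached per
# (n1, n2) because they are parameter independent
.exact_cache <- new.env(parent = emptyenv())

exact_ancestral_basis <- function(n1, n2) {
  key <- paste(n1, n2, sep = "_")
  if (!is.null(.exact_cache[[key]])) return(.exact_cache[[key]])
  basis <- vector("list", n1 * n2)
  for (k1 in 1:n1) for (k2 in 1:n2) {
    M <- matrix(0, n1 + 1, n2 + 1)
    m <- k1 + k2
    for (j in 1:(m - 1)) {
      lj <- 2 / j                      # E[total length subtending j of m]
      for (a in max(0, j - k2):min(j, k1)) {
        hyp <- exp(lchoose(k1, a) + lchoose(k2, j - a) - lchoose(m, j))
        if (hyp < 1e-14) next
        M <- M + lj * hyp * outer(block_sum_dist(n1, k1, a),
                                  block_sum_dist(n2, k2, j - a))
      }
    }
    basis[[(k1 - 1) * n2 + k2]] <- M
  }
  .exact_cache[[key]] <- basis
  basis
}

# ---- two-population split models ------------------------------------------

# Demographic model for the split in diffusion scaling: time unit =
# 2 N_ref generations (N_ref = 0.5 internally), sizes nu1, nu2 relative to
# N_ref, split T time units ago, backward migration rates m12, m21 per
# lineage per time unit (continuous migration stops at the split).
split_model <- function(nu1, nu2, T, m12 = 0, m21 = 0) {
  ev <- rbind(
    if (m12 > 0) event_df(T, "migset", 1, 2, 0) else NULL,
    if (m21 > 0) event_df(T, "migset", 2, 1, 0) else NULL,
    event_df(T, "join", 2, 1),
    event_df(T, "size", 1, param = 0.5))
  mig <- matrix(0, 2, 2)
  mig[1, 2] <- m12
  mig[2, 1] <- m21
  demographic_model(c(nu1 * 0.5, nu2 * 0.5), ev, mig)
}

#' Expected folded joint SFS under a two-population split model
#'
#' Monte-Carlo coalescent expectation: an ancestral population of size
#' N_ref splits `T` (units of 2 N_ref generations) ago into populations of
#' relative size `nu1` and `nu2` with continuous asymmetric migration
#' (`m12`, `m21`, backward per-lineage rates per 2 N_ref generations).
#' The returned spectrum is scaled to unit theta (`theta = 4 N_ref mu L`);
#' multiply by theta for expected counts. Deterministic given `seed`.
#'
#' @param nu1,nu2 relative sizes of the two daughter populations.
#' @param T split time in units of 2 N_ref generations.
#' @param m12,m21 scaled migration rates (0 for the no-migration model).
#' @param n1,n2 haploid sample sizes.
#' @param engine_reps genealogies averaged (default 2e5).
#' @param seed integer seed.
#' @return folded `(n1+1) x (n2+1)` matrix of expected per-unit-theta counts.
#' @export
expected_joint_sfs_split <- function(nu1, nu2, T, m12 = 0, m21 = 0,
                                     n1, n2, engine_reps = 2e5, seed = 1L) {
  stopifnot(nu1 > 0, nu2 > 0, T >= 0, m12 >= 0, m21 >= 0)
  if (m12 == 0 && m21 == 0 && max(n1, n2) <= 25) {
    # closed form: no Monte-Carlo noise in the no-migration likelihood
    spec <- exact_joint_split_spectrum(nu1, nu2, T, n1, n2)
  } else {
    model <- split_model(nu1, nu2, max(T, 1e-9), m12, m21)
    spec <- branch_spectrum(model, c(n1, n2), n_reps = engine_reps, seed = seed)
  }
  fold_joint(spec / 2)
}

#' Fit a two-population split model to a folded joint SFS
#'
#' Maximizes the Poisson composite likelihood over `(nu1, nu2, T)` (plus
#' `(m12, m21)` when `migration = TRUE`) with theta profiled analytically
#' (`theta_hat` = total observed / total expected at unit theta). The
#' expected spectrum comes from the Monte-Carlo coalescent engine evaluated
#' with a fixed seed, so the objective is deterministic; optimization is
#' multi-start Nelder-Mead in log-parameter space.
#'
#' @param obs_sfs folded joint [joint_folded_sfs()] with `L` set.
#' @param migration fit the asymmetric-migration model (default `FALSE`).
#' @param seed integer seed for the multi-start jitter.
#' @param engine_reps genealogies per likelihood evaluation.
#' @param engine_seed fixed seed of the expected-SFS engine; keep identical
#'   across fits that are compared by likelihood.
#' @param n_starts random multi-starts (default 5).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param start optional named starting values on the natural scale
#'   (`nu1, nu2, T[, m12, m21]`), used as the first start (e.g. warm-start
#'   the migration model from the no-migration fit).
#' @return object of class `demographic_fit` with `params`
#'   (`nu1, nu2, T, m12, m21`), `theta_hat`, `loglik`, `model`,
#'   `boundary_flag`, and the data dimensions.
#' @export
fit_split_model <- function(obs_sfs, migration = FALSE, seed = NULL,
                            engine_reps = 3e4, engine_seed = 7L,
                            n_starts = 5, maxit = 150, start = NULL) {
  stopifnot(inherits(obs_sfs, "sfs"), obs_sfs$kind == "folded2d")
  obs <- obs_sfs$counts
  n1 <- obs_sfs$n[1]; n2 <- obs_sfs$n[2]
  S <- sum(obs)
  if (S == 0) stopf("empty joint spectrum")
  np <- if (migration) 5L else 3L
  local_seed(seed)

  lb <- c(log(0.02), log(0.02), log(1e-5), log(1e-4), log(1e-4))[seq_len(np)]
  ub <- c(log(50), log(50), log(10), log(20), log(20))[seq_len(np)]
  eval_ll <- function(logp) {
    if (any(logp < lb) || any(logp > ub)) return(-1e10)
    p <- exp(logp)
    E <- expected_joint_sfs_split(p[1], p[2], p[3],
                                  if (np == 5) p[4] else 0,
                                  if (np == 5) p[5] else 0,
                                  n1, n2, engine_reps, seed = engine_seed)
    tot <- sum(E)
    if (tot <= 0) return(-1e12)
    theta <- S / tot
    # floor at the engine's Monte-Carlo resolution: a cell expectation below
    # ~one genealogy's worth of mass is indistinguishable from it, and a hard
    # zero would otherwise dominate the likelihood through log(0) penalties
    Ec <- pmax(theta * E, S / engine_reps)
    sum(obs * log(Ec) - Ec)
  }
  base_start <- if (!is.null(start)) {
    log(pmax(unname(start[seq_len(np)]), 1e-4))
  } else {
    c(log(1), log(1), log(0.1),
      if (np == 5) c(log(0.5), log(0.5)) else NULL)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base_start + if (s == 1) 0 else rnorm(np, 0, 1)
    opt <- optim(start, function(p) -eval_ll(p), method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  p <- exp(best$par)
  params <- c(nu1 = p[1], nu2 = p[2], T = p[3],
              m12 = if (np == 5) p[4] else 0,
              m21 = if (np == 5) p[5] else 0)
  E <- expected_joint_sfs_split(params[1], params[2], params[3], params[4],
                                params[5], n1, n2, engine_reps, engine_seed)
  theta_hat <- S / sum(E)
  boundary <- params["T"] < 1e-4 ||
    (migration && any(params[c("m12", "m21")] < 1e-3))
  structure(list(params = params, theta_hat = unname(theta_hat),
                 loglik = -best$value, model = if (migration)
                   "split_asym_migration" else "split_no_migration",
                 boundary_flag = unname(boundary), n = c(n1, n2),
                 L = obs_sfs$L, S = S, engine_reps = engine_reps,
                 engine_seed = engine_seed, obs_sfs = obs_sfs,
                 n_free = np),
            class = "demographic_fit")
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat(sprintf("demographic_fit (%s): logLik = %.3f, theta_hat = %.3f\n",
              x$model, x$loglik, x$theta_hat))
  print(round(x$params, 5))
  if (x$boundary_flag) cat("note: a parameter converged at its boundary\n")
  invisible(x)
}

# log composite likelihood of a fit's model at given log-params for data X;
# engine_seed may be overridden (e.g. fresh Monte-Carlo noise per bootstrap)
split_ll_for_data <- function(fit, logp, counts, engine_seed = NULL) {
  p <- exp(logp)
  E <- expected_joint_sfs_split(p[1], p[2], p[3],
                                if (fit$n_free == 5) p[4] else 0,
                                if (fit$n_free == 5) p[5] else 0,
                                fit$n[1], fit$n[2], fit$engine_reps,
                                engine_seed %||% fit$engine_seed)
  tot <- sum(E)
  theta <- sum(counts) / tot
  Ec <- pmax(theta * E, sum(counts) / fit$engine_reps)
  sum(counts * log(Ec) - Ec)
}

#' Godambe-adjusted likelihood-ratio test for nested split models
#'
#' SNPs in linked data are not independent, so the composite-likelihood
#' ratio `2 * (LL_full - LL_simple)` is miscalibrated. The statistic is
#' rescaled using the Godambe information estimated from bootstrap spectra
#' (score covariance across bootstraps vs. observed-information Hessian),
#' then referred to a chi-squared distribution with df = number of extra
#' parameters. With migration rates fixed at their 0 boundary under the
#' null this is conservative; `mixture = TRUE` uses the boundary
#' mixture-chi-squared instead.
#'
#' @param fit_simple,fit_full nested [fit_split_model()] results (same data,
#'   same engine seed).
#' @param bootstrap_spectra list of folded joint spectra (e.g. from
#'   [bootstrap_joint_sfs()]) used to estimate the score covariance.
#' @param mixture use the 0-boundary mixture chi-squared null.
#' @param eps finite-difference step (log scale for size/time parameters,
#'   natural scale for migration rates, which use forward stencils so the
#'   m = 0 boundary is regular).
#' @param ll_reps Monte-Carlo genealogies for the likelihood re-evaluation
#'   (default 5x the fit's `engine_reps`).
#' @return list with `statistic` (adjusted), `raw_statistic`, `df`, `p`,
#'   `adjust_factor`.
#' @export
adjusted_lrt <- function(fit_simple, fit_full, bootstrap_spectra,
                         mixture = FALSE, eps = 0.1, ll_reps = NULL) {
  q <- fit_full$n_free - fit_simple$n_free
  if (q <= 0) stopf("models are not nested (full model has no extra parameters)")
  # re-evaluate both likelihoods at higher Monte-Carlo precision with a
  # shared seed so the ratio reflects model fit, not engine noise
  # the re-evaluation uses an independent Monte-Carlo stream: reusing the
  # fit's stream would retain the noise the optimizer exploited
  ll_reps <- ll_reps %||% (5L * fit_full$engine_reps)
  reval_seed <- derive_seed(fit_full$engine_seed, 99L)
  ll_at <- function(fit) {
    p <- fit$params
    E <- expected_joint_sfs_split(p[1], p[2], p[3], p[4], p[5],
                                  fit_full$n[1], fit_full$n[2],
                                  ll_reps, reval_seed)
    counts <- fit_full$obs_sfs$counts
    Ec <- pmax(sum(counts) / sum(E) * E, sum(counts) / ll_reps)
    sum(counts * log(Ec) - Ec)
  }
  # stored likelihoods from separate fits carry independent Monte-Carlo
  # noise, so only the matched-stream re-evaluation is comparable: a
  # negative difference means the extra parameters explain nothing (the
  # statistic is 0); a grossly negative one flags an optimization failure
  ll_s <- ll_at(fit_simple)
  ll_f <- ll_at(fit_full)
  if (2 * (ll_f - ll_s) < -50)
    stopf("full-model likelihood well below nested model's: optimization failure")
  delta <- max(2 * (ll_f - ll_s), 0)

  # Parameterization for the derivatives: size/time parameters on the log
  # scale (central differences), migration rates on the natural scale with
  # forward stencils so the m = 0 boundary is a regular point.  The
  # information matrices are evaluated at the null-model estimate augmented
  # with m = 0 -- the stable, well-identified point under the null the test
  # calibrates against (the full-model optimum can wander when migration is
  # weakly identified, making finite differences there unreliable).
  np <- fit_full$n_free
  p_null <- unname(fit_simple$params[seq_len(fit_simple$n_free)])
  x0 <- c(log(pmax(p_null[1:3], 1e-8)), rep(0, np - fit_simple$n_free))
  is_mig <- seq_len(np) > 3
  obs <- fit_full$obs_sfs$counts

  # expected spectra depend on parameters only, not on the data, so they are
  # memoized: bootstrap score evaluations reuse the same cached spectra
  cache <- new.env(parent = emptyenv())
  expected_at <- function(x) {
    key <- paste(signif(x, 12), collapse = "_")
    if (is.null(cache[[key]])) {
      p <- c(exp(x[1:3]), if (np == 5) pmax(x[4:5], 0) else c(0, 0))
      cache[[key]] <- expected_joint_sfs_split(
        p[1], p[2], p[3], p[4], p[5],
        fit_full$n[1], fit_full$n[2], fit_full$engine_reps,
        fit_full$engine_seed)
    }
    cache[[key]]
  }
  ll_fun <- function(x, counts) {
    E <- expected_at(x)
    theta <- sum(counts) / sum(E)
    Ec <- pmax(theta * E, sum(counts) / fit_full$engine_reps)
    sum(counts * log(Ec) - Ec)
  }
  ev <- function(i, h) { e <- rep(0, np); e[i] <- h; e }
  grad_for <- function(counts) {
    vapply(seq_len(np), function(i) {
      if (is_mig[i]) {
        (ll_fun(x0 + ev(i, eps), counts) - ll_fun(x0, counts)) / eps
      } else {
        (ll_fun(x0 + ev(i, eps), counts) -
         ll_fun(x0 - ev(i, eps), counts)) / (2 * eps)
      }
    }, numeric(1))
  }
  # Both information matrices are estimated as score covariances (no second
  # derivatives, which are ill-behaved at the m = 0 boundary): the
  # sensitivity H from iid multinomial resampling of the SNPs (what the
  # composite likelihood assumes), the variability J from the supplied
  # linkage-aware block-bootstrap spectra.  Their ratio is exactly the
  # linkage inflation the adjustment corrects for.
  local_seed(derive_seed(fit_full$engine_seed, 98L))
  S_tot <- sum(obs)
  prob <- as.numeric(obs) / S_tot
  U_iid <- t(vapply(seq_len(max(30L, length(bootstrap_spectra))), function(b) {
    cb <- obs
    cb[] <- rmultinom(1, S_tot, prob)
    grad_for(cb)
  }, numeric(np)))
  H <- stats::cov(U_iid)
  U <- t(vapply(bootstrap_spectra, function(s) grad_for(s$counts),
                numeric(np)))
  J <- stats::cov(U)
  ridge <- function(M) M + diag(1e-6 * max(abs(diag(M)), 1e-6), nrow(M))
  Hi <- solve(ridge(H))
  sandwich <- Hi %*% J %*% Hi
  uu <- (fit_simple$n_free + 1):np
  lam <- sum(diag(solve(ridge(Hi[uu, uu, drop = FALSE])) %*%
                    sandwich[uu, uu, drop = FALSE]))
  adj <- if (is.finite(lam) && lam > 0) q / lam else 1
  stat <- delta * adj
  p <- if (mixture && q == 2) {
    0.25 * (stat <= 0) + 0.5 * pchisq(stat, 1, lower.tail = FALSE) +
      0.25 * pchisq(stat, 2, lower.tail = FALSE)
  } else {
    pchisq(stat, df = q, lower.tail = FALSE)
  }
  list(statistic = stat, raw_statistic = delta, df = q, p = min(p, 1),
       adjust_factor = adj)
}

#' Bootstrap joint spectra over chromosomes
#'
#' Resamples chromosomes (linkage blocks) with replacement and rebuilds the
#' folded joint SFS from the loci they carry.
#'
#' @param G [genotype_matrix()].
#' @param popA,popB population ids.
#' @param n_boot number of bootstrap spectra.
#' @param L sequence length carried on each spectrum.
#' @param seed integer seed.
#' @return list of `sfs` objects.
#' @export
bootstrap_joint_sfs <- function(G, popA, popB, n_boot = 100, L = NULL,
                                seed = NULL) {
  local_seed(seed)
  chroms <- unique(G$locus_meta$chrom)
  lapply(seq_len(n_boot), function(b) {
    ch <- sample(chroms, length(chroms), replace = TRUE)
    loci <- unlist(lapply(ch, function(cc) which(G$locus_meta$chrom == cc)))
    Gb <- G
    Gb$dosage <- G$dosage[, loci, drop = FALSE]
    Gb$locus_meta <- data.frame(chrom = paste0("b", seq_along(loci)),
                                pos = 1L, ref = "A", alt = "T")
    # bypass position monotonicity checks: spectra only need dosages
    joint_folded_sfs(structure(Gb, class = "genotype_matrix"), popA, popB, L = L)
  })
}

#' Chromosome-block bootstrap confidence intervals for a split-model fit
#'
#' Resamples chromosomes with replacement, rebuilds the joint SFS, refits
#' the model (warm-started at the original estimate), and reports
#' `alpha +/- 1.96 beta` per parameter, `alpha` the original estimate and
#' `beta` the bootstrap standard deviation.
#'
#' @param fit a [fit_split_model()] result.
#' @param G the [genotype_matrix()] the spectrum came from.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param maxit Nelder-Mead cap for each warm-started refit.
#' @param fresh_engine_noise draw new Monte-Carlo genealogies per bootstrap
#'   refit so `beta` also reflects the engine's noise component; by default
#'   the fit's fixed engine seed is reused, making refits deterministic
#'   functions of the resampled data (identical data give identical
#'   estimates).
#' @return list with `ci` (parameter x lower/upper matrix), `beta`
#'   (bootstrap SDs), `estimates` (bootstrap parameter draws).
#' @export
bootstrap_ci <- function(fit, G, n_boot = 100, seed = NULL, maxit = 80,
                         n_starts = 2, fresh_engine_noise = FALSE) {
  pops <- fit$obs_sfs$populations
  spectra <- bootstrap_joint_sfs(G, pops[1], pops[2], n_boot = n_boot,
                                 L = fit$L, seed = seed)
  migration <- fit$n_free == 5
  # full multi-start refits (warm starts cling to the original optimum and
  # under-disperse beta); the original estimate is the first start and the
  # start jitter is seeded identically for every replicate, so identical
  # resampled data give identical refits
  refit_seed <- derive_seed(seed %||% 1L, 17L)
  ests <- matrix(NA_real_, n_boot, fit$n_free)
  for (b in seq_len(n_boot)) {
    sfs_b <- spectra[[b]]
    if (sum(sfs_b$counts) == 0) next
    es_b <- if (fresh_engine_noise) derive_seed(fit$engine_seed, b)
            else fit$engine_seed
    fb <- try(fit_split_model(sfs_b, migration = migration, seed = refit_seed,
                              engine_reps = fit$engine_reps,
                              engine_seed = es_b, n_starts = n_starts,
                              maxit = maxit,
                              start = fit$params[seq_len(fit$n_free)]),
              silent = TRUE)
    if (!inherits(fb, "try-error"))
      ests[b, ] <- fb$params[seq_len(fit$n_free)]
  }
  ok <- stats::complete.cases(ests)
  if (sum(ok) < 10) stopf("fewer than 10 successful bootstrap refits")
  beta <- apply(ests[ok, , drop = FALSE], 2, sd)
  alpha <- unname(fit$params[seq_len(fit$n_free)])
  ci <- cbind(lower = alpha - 1.96 * beta, upper = alpha + 1.96 * beta)
  rownames(ci) <- names(fit$params)[seq_len(fit$n_free)]
  list(ci = ci, beta = setNames(beta, rownames(ci)), alpha = setNames(alpha, rownames(ci)),
       estimates = ests[ok, , drop = FALSE])
}

#' Convert split time from diffusion units to years
#'
#' `years = T * 2 * N_ref / gens_per_year` with
#' `N_ref = theta_hat / (4 mu L_eff)`.
#'
#' @param T split time in units of 2 N_ref generations (may be a vector,
#'   e.g. estimate and CI bounds).
#' @param theta_hat optimal SFS scaling from the fitted model.
#' @param mu per-site per-generation mutation rate.
#' @param L_eff effective sequence length (see [effective_length()]).
#' @param gens_per_year generations per year.
#' @return time(s) in years.
#' @export
convert_time <- function(T, theta_hat, mu, L_eff, gens_per_year = 3.5) {
  if (any(T < 0)) stopf("T must be non-negative")
  if (theta_hat <= 0 || mu <= 0 || L_eff <= 0 || gens_per_year <= 0)
    stopf("theta_hat, mu, L_eff and gens_per_year must be positive")
  N_ref <- theta_hat / (4 * mu * L_eff)
  T * 2 * N_ref / gens_per_year
}

#' Effective sequence length after SNP filtering
#'
#' Rescales the raw sequence length by the fraction of SNPs surviving
#' filtering, so that theta-based scalings refer to the filtered data.
#'
#' @param L_raw sequence length of the unfiltered data (sites).
#' @param n_snps_filtered,n_snps_unfiltered SNP counts after and before
#'   filtering.
#' @return `L_raw * n_snps_filtered / n_snps_unfiltered`.
#' @export
effective_length <- function(L_raw, n_snps_filtered, n_snps_unfiltered) {
  if (n_snps_unfiltered <= 0) stopf("unfiltered SNP count must be positive")
  if (n_snps_filtered > n_snps_unfiltered)
    stopf("filtered SNP count exceeds unfiltered count")
  if (L_raw <= 0 || n_snps_filtered < 0) stopf("counts must be positive")
  L_raw * n_snps_filtered / n_snps_unfiltered
}
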