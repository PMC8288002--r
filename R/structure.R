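#' Principal component analysis of genotypes
#'
#' Column-centered (optionally frequency-scaled) decomposition of the
#' imputed dosage matrix. Deterministic up to component sign.
#'
#' @param G [genotype_matrix()] with no missing entries.
#' @param n_components number of components to retain.
#' @param scale_freq scale each locus by `sqrt(p(1-p))` (default `FALSE`).
#' @return object of class `pca_result`: `scores` (individuals x
#'   components), `variance_fraction`, `loadings`.
#' @export
genotype_pca <- function(G, n_components = 10, scale_freq = FALSE) {
  d <- G$dosage
  if (anyNA(d)) stopf("genotype_pca requires an imputed (no missing) matrix")
  if (n_components > nrow(d)) {
    warnf("fewer individuals than requested components; reducing to %d", nrow(d))
    n_components <- nrow(d)
  }
  x <- scale(d, center = TRUE, scale = FALSE)
  if (scale_freq) {
    p <- colMeans(d) / 2
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    x <- sweep(x, 2, s, "/")
  }
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf[seq_len(k)],
                 variance_fraction_all = vf,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of genotypes: %d components; variance fractions: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = " ")))
  invisible(x)
}

project_simplex <- function(Q) {
  # Euclidean projection of each row onto the probability simplex
  t(apply(Q, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
  }))
}

fit_nmf_once <- function(X, K, mask, max_iter, tol) {
  n <- nrow(X); L <- ncol(X)
  eps <- 1e-8
  Q <- matrix(rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  Fm <- matrix(runif(K * L, 0.05, 0.95), K, L)
  Xw <- X
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- Q %*% Fm
    if (length(mask)) Xw[mask] <- P[mask]
    # alternating least squares with simplex / box projection
    Q <- Xw %*% t(Fm) %*% solve(Fm %*% t(Fm) + eps * diag(K))
    Q <- project_simplex(Q)
    rs <- rowSums(Q)
    bad <- rs <= 0
    if (any(bad)) Q[bad, ] <- 1 / K
    Fm <- solve(t(Q) %*% Q + eps * diag(K)) %*% t(Q) %*% Xw
    Fm <- clamp(Fm, 0, 1)
    loss <- mean((Xw - Q %*% Fm)^2)
    if (is.finite(prev) && abs(prev - loss) <= tol * max(prev, 1e-12)) {
      converged <- TRUE
      break
    }
    prev <- loss
  }
  list(Q = Q, F = Fm, converged = converged)
}

masked_cross_entropy <- function(X, Q, Fm, mask) {
  P <- clamp(Q %*% Fm, 1e-6, 1 - 1e-6)
  x <- X[mask]; p <- P[mask]
  -mean(x * log(p) + (1 - x) * log(1 - p))
}

#' Sparse-NMF-style admixture estimation
#'
#' Nonnegative factorization of the individuals x loci allele-frequency
#' matrix (dosage/2) into ancestry proportions `Q` (rows on the probability
#' simplex) and cluster allele frequencies `F` in `[0, 1]`, by alternating
#' projected least squares. Model fit is scored by the cross-entropy of a
#' held-out random mask of matrix entries predicted by `Q F`; the best of
#' `n_replicates` random initializations is returned.
#'
#' @param G [genotype_matrix()] with no missing entries.
#' @param K number of ancestral clusters (`>= 1`).
#' @param n_replicates random restarts (default 10).
#' @param mask_fraction fraction of entries held out for the cross-entropy
#'   (default 0.05).
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and relative-loss convergence tolerance.
#' @param mask_seed seed for the held-out entry mask; fits compared across K
#'   must share it so their cross-entropies score the same entries
#'   (defaults to `seed`).
#' @return object of class `admixture_fit` with elements `K`, `Q`, `F`,
#'   `cross_entropy` (best replicate), `replicate_ce`, `converged`.
#' @export
admixture_fit <- function(G, K, n_replicates = 10, mask_fraction = 0.05,
                          seed = NULL, max_iter = 200, tol = 1e-6,
                          mask_seed = NULL) {
  stopifnot(K >= 1)
  d <- G$dosage
  if (anyNA(d)) stopf("admixture_fit requires an imputed matrix")
  X <- d / 2
  local_seed(mask_seed %||% seed)
  mask <- sample(length(X), max(1L, round(mask_fraction * length(X))))
  if (!is.null(seed)) set.seed(seed)   # restarts reproducible; caller's RNG
                                       # state is restored by local_seed()
  best <- NULL
  ces <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    if (K == 1) {
      fit <- list(Q = matrix(1, nrow(X), 1),
                  F = matrix(colMeans(X[, , drop = FALSE]), 1, ncol(X)),
                  converged = TRUE)
    } else {
      fit <- fit_nmf_once(X, K, mask, max_iter, tol)
    }
    ces[r] <- masked_cross_entropy(X, fit$Q, fit$F, mask)
    if (is.null(best) || ces[r] < best$cross_entropy) {
      best <- fit
      best$cross_entropy <- ces[r]
    }
  }
  structure(list(K = K, Q = best$Q, F = best$F,
                 cross_entropy = best$cross_entropy, replicate_ce = ces,
                 converged = best$converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, held-out cross-entropy %.5f (%d replicates)\n",
              x$K, x$cross_entropy, length(x$replicate_ce)))
  invisible(x)
}

#' Fit admixture models over a grid of K and pick the best
#'
#' @param G [genotype_matrix()] with no missing entries.
#' @param K_range integer vector of cluster numbers (default `1:12`).
#' @inheritParams admixture_fit
#' @return list with `fits` (one [admixture_fit()] per K) and `best_K`.
#' @export
admixture_scan <- function(G, K_range = 1:12, n_replicates = 10,
                           mask_fraction = 0.05, seed = NULL) {
  # one shared held-out mask: cross-entropies across K score the same
  # entries and are directly comparable
  ms <- derive_seed(seed %||% 1L, 0L)
  fits <- lapply(seq_along(K_range), function(i)
    admixture_fit(G, K_range[i], n_replicates, mask_fraction,
                  seed = derive_seed(seed, i), mask_seed = ms))
  list(fits = fits, best_K = select_k(fits))
}

#' Select the number of clusters by held-out cross-entropy
#'
#' By default applies the one-standard-error convention: the smallest K
#' whose mean held-out cross-entropy lies within one standard error (over
#' replicate restarts) of the overall minimum. Replicate noise at larger K
#' regularly produces sub-noise dips one past the true cluster number, and
#' the 1-SE rule absorbs them; `one_se = FALSE` gives the plain minimizer.
#' Exact ties always resolve to the smaller K.
#'
#' @param fits list of [admixture_fit()] objects over at least two K values.
#' @param one_se apply the one-standard-error selection rule
#'   (default `TRUE`).
#' @return the selected K (integer).
#' @export
select_k <- function(fits, one_se = TRUE) {
  if (length(fits) < 2) stopf("need fits for at least two K values")
  Ks <- vapply(fits, function(f) f$K, numeric(1))
  ce <- vapply(fits, function(f) mean(f$replicate_ce), numeric(1))
  ord <- order(Ks)
  Ks <- Ks[ord]; ce <- ce[ord]
  best <- which.min(ce)           # first (smallest K) on exact ties
  if (one_se) {
    reps <- fits[[ord[best]]]$replicate_ce
    se <- if (length(reps) > 1) sd(reps) / sqrt(length(reps)) else 0
    best <- which(ce <= ce[best] + se)[1]
  }
  as.integer(Ks[best])
}

# Per-population per-locus components used by the F_ST estimator:
# typed diploid counts, allele frequencies, heterozygote fractions.
fst_components <- function(G) {
  pops <- unique(G$sample_meta$pop)
  S <- ncol(G$dosage)
  n <- p <- h <- matrix(0, length(pops), S, dimnames = list(pops, NULL))
  for (k in seq_along(pops)) {
    sub <- G$dosage[G$sample_meta$pop == pops[k], , drop = FALSE]
    n[k, ] <- colSums(!is.na(sub))
    p[k, ] <- ifelse(n[k, ] > 0, colSums(sub, na.rm = TRUE) / (2 * n[k, ]), NA)
    h[k, ] <- ifelse(n[k, ] > 0, colSums(sub == 1, na.rm = TRUE) / n[k, ], NA)
  }
  list(pops = pops, n = n, p = p, h = h)
}

# Weir & Cockerham (1984) two-population theta, ratio-of-sums over loci;
# the moment estimator underlying Weir & Hill's (2002) theta for unequal
# sample sizes. Returns the raw (possibly negative) estimate.
pair_theta <- function(comp, i, j, loci = NULL) {
  S <- ncol(comp$n)
  if (is.null(loci)) loci <- seq_len(S)
  n1 <- comp$n[i, loci]; n2 <- comp$n[j, loci]
  ok <- n1 > 0 & n2 > 0 & (n1 + n2) > 2
  if (!any(ok)) return(NA_real_)
  n1 <- n1[ok]; n2 <- n2[ok]
  p1 <- comp$p[i, loci][ok]; p2 <- comp$p[j, loci][ok]
  h1 <- comp$h[i, loci][ok]; h2 <- comp$h[j, loci][ok]
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  den <- sum(a + b + cc)
  if (den == 0) return(NA_real_)
  sum(a) / den
}

#' Pairwise F_ST matrix (Weir & Cockerham / Weir & Hill theta)
#'
#' Moment estimator accommodating unequal sample sizes: the per-locus
#' numerator and denominator variance components are summed over loci before
#' taking the ratio. Raw (possibly slightly negative) estimates are retained
#' in the matrix; use `floor_zero = TRUE` for display.
#'
#' @param G [genotype_matrix()].
#' @param popmap optional [population_map()] (populations default to `G`'s
#'   sample metadata).
#' @param floor_zero floor negative estimates at 0 (default `FALSE`).
#' @return symmetric matrix of class `fst_matrix` with zero diagonal.
#' @export
pairwise_fst <- function(G, popmap = NULL, floor_zero = FALSE) {
  comp <- fst_components(G)
  k <- length(comp$pops)
  M <- matrix(0, k, k, dimnames = list(comp$pops, comp$pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    M[i, j] <- M[j, i] <- pair_theta(comp, i, j)
  }
  if (floor_zero) M[M < 0] <- 0
  diag(M) <- 0
  structure(M, class = c("fst_matrix", "matrix"))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Four-level nested decomposition of allelic variance: among islands, among
#' watersheds within islands, among individuals within watersheds, and
#' within individuals, treating the two alleles of a diploid as the lowest
#' level (Excoffier-style squared allele-count differences). Variance
#' components are obtained by equating observed sums of squares to their
#' exact expectations under the unbalanced nested random-effects model.
#'
#' @param G [genotype_matrix()] with no missing entries.
#' @param popmap [population_map()] giving the watershed -> island hierarchy;
#'   only populations present in `G` are used.
#' @return data frame of class `amova_result` with columns `stratum`, `df`,
#'   `SS`, `sigma2`, `percent`.
#' @export
amova <- function(G, popmap) {
  d <- G$dosage
  if (anyNA(d)) stopf("amova requires an imputed (no missing) matrix")
  w2i <- watershed_island(popmap)
  pop <- G$sample_meta$pop
  isl <- unname(w2i[pop])
  if (anyNA(isl)) stopf("individual population missing from popmap")
  n_ind <- nrow(d)
  y <- d / 2                      # individual allele-frequency means

  pop_f <- factor(pop); isl_f <- factor(isl)
  n_p <- as.vector(table(pop_f)); names(n_p) <- levels(pop_f)
  pop_mean <- rowsum(y, pop_f) / n_p
  isl_of_pop <- factor(unname(w2i[levels(pop_f)]), levels = levels(isl_f))
  n_g <- as.vector(rowsum(matrix(n_p), isl_of_pop)); names(n_g) <- levels(isl_f)
  isl_mean <- rowsum(pop_mean * n_p, isl_of_pop) / n_g
  grand <- colSums(y) / n_ind

  ss_wi <- 0.5 * sum(d == 1)
  ss_ai <- 2 * sum((y - pop_mean[as.integer(pop_f), , drop = FALSE])^2)
  ss_ap <- 2 * sum(n_p * rowSums((pop_mean -
           isl_mean[as.integer(isl_of_pop), , drop = FALSE])^2))
  ss_ag <- 2 * sum(n_g * rowSums(sweep(isl_mean, 2, grand)^2))

  # exact expected-SS coefficients for the unbalanced nested design,
  # units = alleles (2 per individual)
  unit_ind <- rep(seq_len(n_ind), each = 2)
  unit_pop <- rep(as.integer(pop_f), each = 2)
  unit_isl <- rep(as.integer(isl_f), each = 2)
  M <- 2 * n_ind
  trace_AZ <- function(avg, eff) {
    # tr(A_avg Z_eff Z_eff') for unit-level group vectors avg (averaging
    # level) and eff (random-effect level); exact for unbalanced nesting
    ta <- table(avg)
    cross <- table(avg, eff)
    sum(rowSums(cross^2) / ta)
  }
  levels_units <- list(islands = unit_isl, pops = unit_pop, inds = unit_ind)
  n_groups <- c(islands = nlevels(isl_f), pops = nlevels(pop_f), inds = n_ind)
  coef_row <- function(avg_fine, avg_coarse) {
    eff_coefs <- vapply(names(levels_units), function(k) {
      cf <- trace_AZ(levels_units[[avg_fine]], levels_units[[k]])
      cc <- if (is.null(avg_coarse)) sum(table(levels_units[[k]])^2) / M
            else trace_AZ(levels_units[[avg_coarse]], levels_units[[k]])
      cf - cc
    }, numeric(1))
    err <- n_groups[avg_fine] -
      (if (is.null(avg_coarse)) 1 else n_groups[avg_coarse])
    c(eff_coefs, error = unname(err))
  }
  multi_island <- nlevels(isl_f) > 1
  A <- rbind(
    if (multi_island) coef_row("islands", NULL) else NULL,
    coef_row("pops", if (multi_island) "islands" else NULL),
    coef_row("inds", "pops"),
    # within-individual stratum: all grouped effects average out (coef 0)
    c(islands = 0, pops = 0, inds = 0, error = M - n_ind))
  ss <- c(if (multi_island) ss_ag else NULL, ss_ap, ss_ai, ss_wi)
  keep <- c(if (multi_island) "islands" else NULL, "pops", "inds", "error")
  Ak <- A[, keep, drop = FALSE]
  sigma2 <- solve(Ak, ss)
  total <- sum(sigma2)
  lab <- c(islands = "among_islands", pops = "among_pops_within_islands",
           inds = "among_individuals_within_pops", error = "within_individuals")
  dfs <- c(if (multi_island) nlevels(isl_f) - 1 else NULL,
           nlevels(pop_f) - (if (multi_island) nlevels(isl_f) else 1),
           n_ind - nlevels(pop_f), M - n_ind)
  out <- data.frame(stratum = unname(lab[keep]), df = dfs, SS = ss,
                    sigma2 = as.numeric(sigma2),
                    percent = 100 * as.numeric(sigma2) / total)
  class(out) <- c("amova_result", "data.frame")
  out
}

#' Neighbor-joining drift tree with bootstrap support
#'
#' Builds a population tree from the pairwise drift distance
#' `theta / (1 - theta)` (monotone in F_ST), resolves node support by
#' bootstrap over loci, and roots at a declared outgroup. This serves as the
#' drift-graph summary of among-population divergence; no migration edges
#' are fitted.
#'
#' @param G [genotype_matrix()].
#' @param popmap [population_map()].
#' @param outgroup population id used to root the tree.
#' @param n_bootstrap bootstrap replicates over loci (default 100).
#' @param seed integer seed.
#' @return object of class `drift_tree`: `tree` (an `ape` `phylo` with node
#'   labels holding bootstrap counts), `newick`, `outgroup`, `n_bootstrap`.
#' @export
drift_tree <- function(G, popmap, outgroup, n_bootstrap = 100, seed = NULL) {
  comp <- fst_components(G)
  pops <- comp$pops
  if (length(pops) < 4) stopf("need at least 4 populations for a drift tree")
  if (!outgroup %in% pops) stopf("outgroup '%s' not found among populations", outgroup)
  local_seed(seed)
  drift_dist <- function(loci = NULL) {
    k <- length(pops)
    M <- matrix(0, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      th <- pair_theta(comp, i, j, loci)
      th <- clamp(ifelse(is.na(th), 0, th), 0, 0.999)
      M[i, j] <- M[j, i] <- th / (1 - th)
    }
    M
  }
  S <- ncol(G$dosage)
  main <- ape::nj(stats::as.dist(drift_dist()))
  boots <- lapply(seq_len(n_bootstrap), function(b)
    ape::nj(stats::as.dist(drift_dist(sample.int(S, S, replace = TRUE)))))
  support <- ape::prop.clades(main, boots, rooted = FALSE)
  support[is.na(support)] <- 0
  main$node.label <- support
  rooted <- ape::root(main, outgroup = outgroup, resolve.root = TRUE)
  structure(list(tree = rooted, newick = ape::write.tree(rooted),
                 outgroup = outgroup, n_bootstrap = n_bootstrap),
            class = "drift_tree")
}

#' @export
print.drift_tree <- function(x, ...) {
  cat(sprintf("drift_tree: %d populations, outgroup %s, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$outgroup, x$n_bootstrap))
  cat(x$newick, "\n")
  invisible(x)
}
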