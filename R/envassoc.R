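#' Size-weighted predator index
#'
#' Aggregates predator densities per watershed, counting small-bodied
#' predatory taxa (which cannot easily eat adult fish) at half the per
#' capita impact of large-bodied ones:
#' `index = sum(density_large) + 0.5 * sum(density_small)`.
#'
#' @param survey data frame with columns `watershed`, `taxon`, `density`
#'   (individuals per unit area, `>= 0`) and `size_class`
#'   (`"large"` or `"small"`).
#' @return named numeric vector of per-watershed index values.
#' @export
predator_index <- function(survey) {
  stopifnot(all(c("watershed", "density", "size_class") %in% names(survey)))
  if (any(survey$density < 0)) stopf("densities must be non-negative")
  bad <- setdiff(unique(survey$size_class), c("large", "small"))
  if (length(bad)) stopf("unknown size class: %s", paste(bad, collapse = ", "))
  w <- ifelse(survey$size_class == "large", 1, 0.5)
  agg <- rowsum(survey$density * w, survey$watershed)
  setNames(as.numeric(agg), rownames(agg))
}

#' PCA of raw environmental variables
#'
#' Standardized-variable PCA returning the leading components; the sign
#' convention fixes the loading of the first input variable to be
#' non-negative on every returned component.
#'
#' @param raw data frame or matrix, one row per watershed, numeric columns.
#' @param n_components number of components returned (default 2).
#' @return list with `scores`, `loadings`, `variance_fraction`.
#' @export
env_pca <- function(raw, n_components = 2) {
  X <- as.matrix(raw)
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warnf("dropping constant column(s): %s",
          paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  flip <- sign(pc$rotation[1, seq_len(k)])
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       variance_fraction = vf[seq_len(k)])
}

#' Latent-factor association scan
#'
#' Per-SNP test of association between genotype dosage and an environmental
#' covariate, with `K_latent` latent factors absorbing population structure:
#' factors are the leading left singular vectors of the genotype matrix
#' residualized on the covariate; each SNP is then regressed on covariate +
#' factors, and z-scores are calibrated by the genomic inflation factor
#' `lambda = median(z^2) / qchisq(0.5, 1)` before p-values are computed.
#'
#' @param G [genotype_matrix()] with no missing entries.
#' @param env_values covariate value per individual (broadcast population
#'   values before calling, or see [env_for_individuals()]).
#' @param K_latent number of latent factors (`0` = plain regression).
#' @param seed unused randomness guard (the scan is deterministic); kept for
#'   interface symmetry.
#' @return data frame of class `association_result` with per-SNP `z`
#'   (calibrated), `p` (calibrated), `q` (Storey), plus attributes
#'   `K_latent` and `lambda_gif`.
#' @export
lfmm_associate <- function(G, env_values, K_latent = 1, seed = NULL) {
  d <- G$dosage
  if (anyNA(d)) stopf("lfmm_associate requires an imputed matrix")
  y <- as.numeric(env_values)
  stopifnot(length(y) == nrow(d))
  if (sd(y) == 0) stopf("covariate is constant")
  y <- as.numeric(scale(y))
  X <- scale(d, center = TRUE, scale = FALSE)
  n <- nrow(X)

  if (K_latent > 0) {
    # latent factors from genotypes residualized on the covariate
    Xr <- X - y %*% (crossprod(y, X) / sum(y^2))
    sv <- svd(Xr, nu = min(K_latent, n - 2), nv = 0)
    U <- sv$u[, seq_len(min(K_latent, ncol(sv$u))), drop = FALSE]
    D <- cbind(1, y, U)
  } else {
    D <- cbind(1, y)
  }
  qrD <- qr(D)
  coefs <- qr.coef(qrD, X)           # (1 + 1 + K) x SNPs
  resid <- qr.resid(qrD, X)
  df_res <- n - ncol(D)
  if (df_res < 2) stopf("too few individuals for %d latent factors", K_latent)
  s2 <- colSums(resid^2) / df_res
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(pmax(XtXinv[2, 2] * s2, .Machine$double.eps))
  z <- coefs[2, ] / se
  mono <- colSums(X^2) == 0          # loci monomorphic in the tested samples
  z[mono] <- NA_real_
  lambda <- median(z^2, na.rm = TRUE) / qchisq(0.5, df = 1)
  lambda <- max(lambda, 1e-8)
  z_cal <- z / sqrt(lambda)
  p <- pchisq(z_cal^2, df = 1, lower.tail = FALSE)
  out <- data.frame(locus = seq_len(ncol(d)), z = z_cal, p = p,
                    q = storey_qvalues(p))
  attr(out, "K_latent") <- K_latent
  attr(out, "lambda_gif") <- lambda
  class(out) <- c("association_result", "data.frame")
  out
}

#' Broadcast per-watershed covariate values to individuals
#'
#' @param G [genotype_matrix()].
#' @param env `env_table` (or data frame with `watershed` plus covariates).
#' @param var covariate column name.
#' @return numeric vector, one value per individual in `G` (NA for
#'   individuals whose population is absent from `env`, e.g. native-range
#'   samples).
#' @export
env_for_individuals <- function(G, env, var) {
  env[[var]][match(G$sample_meta$pop, env$watershed)]
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid with smoothing
#' (natural cubic fit of `pi0(lambda)` evaluated at the largest lambda) and
#' converts p-values to monotone q-values
#' `q_(i) = min_{j >= i} pi0 * N * p_(j) / j`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid grid for pi0 estimation.
#' @return q-values in the order of `pvals`.
#' @export
storey_qvalues <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  if (anyNA(pvals)) {               # NA-safe: NAs stay NA
    out <- rep(NA_real_, length(pvals))
    ok <- !is.na(pvals)
    out[ok] <- storey_qvalues(pvals[ok], lambda_grid)
    return(out)
  }
  N <- length(pvals)
  if (N < 100) {
    warnf("fewer than 100 p-values; fixing pi0 = 1")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda_grid, function(l) mean(pvals > l) / (1 - l),
                    numeric(1))
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
    pi0 <- clamp(pi0, 1e-3, 1)
  }
  ord <- order(pvals)
  ranks <- seq_len(N)
  q_ord <- pi0 * N * pvals[ord] / ranks
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(N)
  q[ord] <- pmin(q_ord, 1)
  q
}

#' Per-locus allele-frequency shifts between gradient extremes
#'
#' Computes `|p_high - p_low|` per locus between the populations at the high
#' and low ends of an environmental gradient and flags loci whose shift is
#' at or above the empirical `quantile` of all shifts (ties share the flag).
#'
#' @param G [genotype_matrix()].
#' @param pop_high,pop_low population ids at the two gradient ends.
#' @param quantile tail threshold (default 0.95).
#' @return data frame with `locus`, `shift`, `extreme`; attribute
#'   `threshold` carries the quantile value. A degenerate all-equal shift
#'   distribution flags every locus and warns.
#' @export
allele_frequency_shift <- function(G, pop_high, pop_low, quantile = 0.95) {
  rh <- which(G$sample_meta$pop == pop_high)
  rl <- which(G$sample_meta$pop == pop_low)
  if (!length(rh) || !length(rl)) stopf("population not found")
  shift <- abs(allele_freq(G, rh) - allele_freq(G, rl))
  thr <- stats::quantile(shift, quantile, na.rm = TRUE, names = FALSE)
  extreme <- !is.na(shift) & shift >= thr
  if (all(extreme, na.rm = TRUE))
    warnf("degenerate shift distribution: all loci tied at the quantile")
  out <- data.frame(locus = seq_along(shift), shift = as.numeric(shift),
                    extreme = extreme)
  attr(out, "threshold") <- thr
  out
}

#' One-sided enrichment (hypergeometric) test
#'
#' Upper-tail probability that at least `x_extreme` of `n_assoc` associated
#' loci fall in the extreme-shift set of size `K_extreme` drawn from
#' `N_total` loci: `P(X >= x_extreme)`, `X ~ Hypergeom(N_total, K_extreme,
#' n_assoc)`.
#'
#' @param n_assoc number of environment-associated loci.
#' @param x_extreme associated loci that are also extreme.
#' @param N_total all tested loci.
#' @param K_extreme loci in the extreme-shift tail.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return the p-value.
#' @export
enrichment_test <- function(n_assoc, x_extreme, N_total, K_extreme,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (x_extreme > n_assoc || n_assoc > N_total || K_extreme > N_total ||
      x_extreme > K_extreme)
    stopf("inconsistent contingency counts")
  p_up <- phyper(x_extreme - 1, K_extreme, N_total - K_extreme, n_assoc,
                 lower.tail = FALSE)
  if (alternative == "greater") return(p_up)
  stats::fisher.test(matrix(c(x_extreme, n_assoc - x_extreme,
                              K_extreme - x_extreme,
                              N_total - K_extreme - (n_assoc - x_extreme)),
                            2, 2))$p.value
}

#' Correlation of diversity with environmental variables
#'
#' Pearson correlation (with two-sided t-test p) of per-population expected
#' heterozygosity against each environmental covariate.
#'
#' @param diversity [diversity_stats()] output.
#' @param env `env_table`; matched to `diversity$pop` by watershed.
#' @param he_column which H_e column to use (default `"He_variant"`).
#' @return data frame with `variable`, `r`, `p`.
#' @export
he_env_correlation <- function(diversity, env, he_column = "He_variant") {
  m <- match(env$watershed, diversity$pop)
  he <- diversity[[he_column]][m]
  ok <- !is.na(he)
  if (sum(ok) < 4) stopf("need at least 4 populations with diversity values")
  vars <- setdiff(names(env), c("watershed", "island"))
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- env[[v]][ok]
    if (sd(he[ok]) == 0 || sd(x) == 0)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_))
    ct <- cor.test(he[ok], x)
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value)
  }))
  out
}

#' Map candidate SNPs to annotated genes
#'
#' A SNP hits a gene when its position lies within the gene body extended by
#' `window` bp on both sides (1-based inclusive coordinates); all
#' overlapping genes are reported.
#'
#' @param candidate_loci data frame with `chrom` and `pos` (e.g. rows of a
#'   [genotype_matrix()]'s `locus_meta`).
#' @param gff_path path to a GFF3 annotation.
#' @param window flanking distance in bp (default 200).
#' @param feature_type GFF3 feature type to use (default `"gene"`).
#' @return data frame with one row per SNP-gene hit: `chrom`, `pos`,
#'   `gene_id`, `gene_start`, `gene_end`.
#' @export
map_candidates_to_genes <- function(candidate_loci, gff_path, window = 200,
                                    feature_type = "gene") {
  gff <- read.table(gff_path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
  genes <- gff[gff$type == feature_type, , drop = FALSE]
  if (!nrow(genes)) stopf("no '%s' features in %s", feature_type, gff_path)
  id <- sub('.*ID=([^;]+).*', "\\1", genes$attributes)
  unmatched <- setdiff(unique(candidate_loci$chrom), unique(genes$seqid))
  if (length(unmatched))
    warnf("%d SNP contig(s) absent from the annotation", length(unmatched))
  hits <- lapply(seq_len(nrow(candidate_loci)), function(i) {
    ch <- candidate_loci$chrom[i]; pos <- candidate_loci$pos[i]
    g <- genes$seqid == ch & pos >= genes$start - window &
      pos <= genes$end + window
    if (!any(g)) return(NULL)
    data.frame(chrom = ch, pos = pos, gene_id = id[g],
               gene_start = genes$start[g], gene_end = genes$end[g])
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), gene_start = integer(),
                      gene_end = integer())
  out
}

#' Compare candidate-locus allele frequencies across population groups
#'
#' Tabulates per-locus allele frequencies in a focal group (e.g. invaded
#' populations with the highest predation score) and in reference
#' populations, and counts loci whose allele is absent (frequency 0) from
#' every reference population.
#'
#' @param G [genotype_matrix()].
#' @param assoc_loci locus indices.
#' @param focal_pops,reference_pops character vectors of population ids.
#' @return list with `freq` (data frame: locus, one column per population)
#'   and `n_absent_in_reference`.
#' @export
compare_group_frequencies <- function(G, assoc_loci, focal_pops,
                                      reference_pops) {
  pops <- c(focal_pops, reference_pops)
  freq <- sapply(pops, function(pp) {
    rows <- which(G$sample_meta$pop == pp)
    allele_freq(G, rows)[assoc_loci]
  })
  freq <- as.data.frame(freq)
  freq <- cbind(locus = assoc_loci, freq)
  ref <- freq[, reference_pops, drop = FALSE]
  n_absent <- sum(apply(ref, 1, function(r) all(r == 0, na.rm = TRUE)))
  list(freq = freq, n_absent_in_reference = n_absent)
}
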