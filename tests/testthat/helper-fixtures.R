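# Shared fixture builders: everything is generated in code at test time.

# genotype_matrix from a plain dosage matrix
toy_genotypes <- function(dosage, pops = NULL, n_chrom = 1L) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); S <- ncol(dosage)
  if (is.null(pops)) pops <- rep("P1", n)
  chrom <- rep(paste0("chr", seq_len(n_chrom)),
               each = ceiling(S / n_chrom))[seq_len(S)]
  pos <- unlist(lapply(split(seq_len(S), chrom), seq_along), use.names = FALSE) * 100L
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE),
                  data.frame(id = sprintf("ind%03d", seq_len(n)), pop = pops,
                             stringsAsFactors = FALSE))
}

# star-shaped multi-population model: k demes of size N joining deme 1 at
# time t_split, used when a known population structure is needed
star_model <- function(k, N = 500, t_split = 250) {
  ev <- do.call(rbind, lapply(2:k, function(d)
    invadepop:::event_df(t_split, "join", d, 1)))
  demographic_model(rep(N, k), ev)
}

# simulate k populations of n_dip diploids each under a star model
sim_star_pops <- function(k, n_dip = 15, n_snps = 800, N = 500,
                          t_split = 250, seed = 1, n_chrom = 10L) {
  m <- star_model(k, N, t_split)
  sim <- simulate_coalescent(m, rep(2L * n_dip, k), n_loci = n_snps,
                             mode = "snp", seed = seed)
  H <- sim$haplotypes
  dosage <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
  pops <- rep(paste0("P", seq_len(k)), each = n_dip)
  toy_genotypes(dosage, pops, n_chrom = n_chrom)
}

# popmap for the study-shaped archipelago without simulating genotypes
archipelago_popmap <- function() {
  cfg <- scenario_config(n_snps = 10)
  wlab <- invadepop:::watershed_labels(cfg)
  ilab <- rep(invadepop:::island_labels(4), cfg$watersheds_per_island)
  population_map(individual = paste0(wlab, "_1"), watershed = wlab,
                 island = ilab)
}

# small invasion simulation shared by several tests (cached per session)
small_invasion <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(
        watersheds_per_island = c(2, 2, 2),
        n_islands = 3, samples_per_watershed = c(8, 8, 8, 8, 8, 8),
        native_samples = c(10, 6), n_snps = 600, n_chromosomes = 6,
        native_split_times = c(4000), missing_rate = 0.05, seed = 42)
      cache <<- c(simulate_invasion(cfg), list(config = cfg))
    }
    cache
  }
})

# Independent textbook Weir & Cockerham (1984) implementation, written as a
# direct per-locus transcription of the a/b/c variance components, used as
# an oracle for the vectorized ratio-of-sums estimator.
wc_theta_oracle <- function(d1, d2) {
  S <- ncol(d1)
  A <- B <- C <- numeric(S)
  for (l in seq_len(S)) {
    g1 <- d1[, l][!is.na(d1[, l])]
    g2 <- d2[, l][!is.na(d2[, l])]
    n1 <- length(g1); n2 <- length(g2)
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    A[l] <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    B[l] <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    C[l] <- hbar / 2
  }
  sum(A) / sum(A + B + C)
}
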