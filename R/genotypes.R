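#' Read genotypes from VCF plus a population map
#'
#' Parses diploid `GT` fields of a VCF (v4.x) into an alternate-allele
#' dosage matrix. Multiallelic and non-SNP records are skipped with a logged
#' count. The population map is a headerless tab-separated file with columns
#' individual, watershed, island/region.
#'
#' @param vcf_path path to the VCF file.
#' @param popmap_path path to the population-map TSV.
#' @return list with `genotypes` ([genotype_matrix()]) and `popmap`
#'   ([population_map()]).
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) stopf("VCF not found: %s", vcf_path)
  if (!file.exists(popmap_path)) stopf("popmap not found: %s", popmap_path)
  pm <- read.table(popmap_path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("individual", "watershed", "island"))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(sprintf("read_genotypes: skipped %d multiallelic/non-SNP records", n_skip))
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, pm$individual)
  if (length(missing_pm))
    stopf("sample(s) missing from popmap: %s",
          paste(missing_pm, collapse = ", "))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dose[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  dosage <- t(dose)   # individuals x loci
  locus_meta <- data.frame(chrom = fix[snp, "CHROM"],
                           pos = as.integer(fix[snp, "POS"]),
                           ref = ref[snp], alt = alt[snp],
                           stringsAsFactors = FALSE)
  ord <- order(match(locus_meta$chrom, unique(locus_meta$chrom)), locus_meta$pos)
  locus_meta <- locus_meta[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  pm <- pm[match(samples, pm$individual), , drop = FALSE]
  G <- genotype_matrix(dosage, locus_meta,
                       data.frame(id = samples, pop = pm$watershed,
                                  stringsAsFactors = FALSE))
  list(genotypes = G,
       popmap = population_map(pm$individual, pm$watershed, pm$island))
}

#' Apply the study's quality-control filters
#'
#' Filters are applied in a fixed order: (1) loci with minor allele frequency
#' at or below `maf_min` over all non-missing calls are removed; (2)
#' individuals with a missing-call fraction strictly above `max_ind_missing`
#' are removed; (3) loci with a missing fraction strictly above
#' `max_locus_missing` are removed. The MAF boundary is inclusive and the
#' missingness boundaries exclusive, matching the rules "0.03 or less",
#' ">75%" and "greater than 50%".
#'
#' @param G [genotype_matrix()].
#' @param maf_min minor-allele-frequency threshold (loci with MAF `<=` this
#'   are dropped).
#' @param max_ind_missing maximum tolerated individual missing fraction.
#' @param max_locus_missing maximum tolerated locus missing fraction.
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (class `filter_report`).
#' @export
apply_quality_filters <- function(G, maf_min = 0.03, max_ind_missing = 0.75,
                                  max_locus_missing = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_ind_missing >= 0,
            max_ind_missing <= 1, max_locus_missing >= 0, max_locus_missing <= 1)
  n_ind0 <- nrow(G$dosage); n_loc0 <- ncol(G$dosage)

  p <- allele_freq(G)
  maf <- pmin(p, 1 - p)
  keep_loc <- !is.na(maf) & maf > maf_min
  G1 <- subset_genotypes(G, j = which(keep_loc))
  n_maf <- sum(!keep_loc)

  ind_miss <- rowMeans(is.na(G1$dosage))
  keep_ind <- ind_miss <= max_ind_missing
  G2 <- subset_genotypes(G1, i = which(keep_ind))
  n_ind_rm <- sum(!keep_ind)
  if (!nrow(G2$dosage)) stopf("all individuals removed by filters")

  loc_miss <- colMeans(is.na(G2$dosage))
  keep_loc2 <- loc_miss <= max_locus_missing
  G3 <- subset_genotypes(G2, j = which(keep_loc2))
  n_loc_rm <- sum(!keep_loc2)
  if (!ncol(G3$dosage)) stopf("all loci removed by filters")

  report <- data.frame(
    step = c("maf", "individual_missingness", "locus_missingness"),
    unit = c("locus", "individual", "locus"),
    threshold = c(maf_min, max_ind_missing, max_locus_missing),
    input = c(n_loc0, n_ind0, ncol(G2$dosage)),
    removed = c(n_maf, n_ind_rm, n_loc_rm),
    retained = c(n_loc0 - n_maf, n_ind0 - n_ind_rm, ncol(G2$dosage) - n_loc_rm))
  class(report) <- c("filter_report", "data.frame")
  list(genotypes = G3, report = report)
}

#' Impute missing genotype calls
#'
#' Draws each missing dosage from Hardy-Weinberg genotype probabilities at
#' the within-population alternate-allele frequency, falling back to the
#' global frequency when a population carries no call at a locus.
#'
#' @param G [genotype_matrix()].
#' @param seed integer seed (imputation is stochastic but reproducible).
#' @return [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(G, seed = NULL) {
  d <- G$dosage
  if (!anyNA(d)) return(G)
  local_seed(seed)
  p_glob <- allele_freq(G)
  if (anyNA(p_glob))
    stopf("locus with no non-missing call in any population; filter first")
  pops <- G$sample_meta$pop
  for (pp in unique(pops)) {
    rows <- which(pops == pp)
    sub <- d[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    p_pop <- ifelse(n_obs > 0, colSums(sub, na.rm = TRUE) / (2 * n_obs), p_glob)
    miss <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(miss)) {
      d[cbind(rows[miss[, 1]], miss[, 2])] <-
        rbinom(nrow(miss), 2, p_pop[miss[, 2]])
    }
  }
  genotype_matrix(d, G$locus_meta, G$sample_meta)
}

#' Per-population diversity statistics
#'
#' Expected heterozygosity `H_e = 2 p (1 - p)` and nucleotide diversity
#' `pi = 2 p q n/(n - 1)` (the unbiased pairwise-difference estimator, `n`
#' the number of observed haploid genomes) are averaged per variant site;
#' when the total sequence length `L` (variant plus invariant sites) is
#' supplied they are additionally rescaled to per-sequence-site values,
#' the scale on which reduced-representation studies report them.
#'
#' @param G [genotype_matrix()].
#' @param popmap [population_map()] (optional; defaults to `G`'s sample
#'   populations).
#' @param L optional total sequence length in sites.
#' @return data frame of class `diversity_table` with columns `pop`, `n`,
#'   `He_variant`, `pi_variant` and, when `L` is given, `He_seq`, `pi_seq`.
#' @export
diversity_stats <- function(G, popmap = NULL, L = NULL) {
  pops <- G$sample_meta$pop
  out <- lapply(unique(pops), function(pp) {
    rows <- which(pops == pp)
    sub <- G$dosage[rows, , drop = FALSE]
    n_al <- 2 * colSums(!is.na(sub))
    p <- ifelse(n_al > 0, colSums(sub, na.rm = TRUE) / n_al, NA_real_)
    he <- 2 * p * (1 - p)
    use_pi <- !is.na(p) & n_al >= 2
    pi <- ifelse(use_pi, 2 * p * (1 - p) * n_al / pmax(n_al - 1, 1), NA_real_)
    if (length(rows) < 2) pi[] <- NA_real_
    res <- data.frame(pop = pp, n = length(rows),
                      He_variant = mean(he, na.rm = TRUE),
                      pi_variant = if (length(rows) < 2) NA_real_
                                   else mean(pi, na.rm = TRUE))
    if (!is.null(L)) {
      res$He_seq <- sum(he, na.rm = TRUE) / L
      res$pi_seq <- if (length(rows) < 2) NA_real_ else sum(pi, na.rm = TRUE) / L
    }
    res
  })
  tab <- do.call(rbind, out)
  class(tab) <- c("diversity_table", "data.frame")
  tab
}
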