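#' Enumerate watershed trios
#'
#' All unordered trios of Hawaiian watersheds, optionally restricted to
#' trios whose three watersheds lie on three distinct islands.
#'
#' @param popmap [population_map()].
#' @param cross_island_only keep only trios spanning three distinct islands.
#' @return data frame of class `trio_set` with columns `P1`, `P2`, `P3`
#'   and attribute `cross_island_only`.
#' @export
enumerate_trios <- function(popmap, cross_island_only = FALSE) {
  ws <- hawaiian_watersheds(popmap)
  if (length(ws) < 3) stopf("need at least 3 watersheds")
  w2i <- watershed_island(popmap)
  tri <- t(combn(sort(ws), 3))
  if (cross_island_only) {
    n_isl <- apply(tri, 1, function(r) length(unique(w2i[r])))
    tri <- tri[n_isl == 3, , drop = FALSE]
  }
  out <- data.frame(P1 = tri[, 1], P2 = tri[, 2], P3 = tri[, 3],
                    stringsAsFactors = FALSE)
  structure(out, class = c("trio_set", "data.frame"),
            cross_island_only = cross_island_only)
}

# Delete-one-block jackknife SE for a ratio statistic with per-locus
# numerator/denominator contributions and contiguous blocks.
block_jackknife_ratio <- function(num, den, block_id) {
  blocks <- unique(block_id)
  B <- length(blocks)
  tot_num <- sum(num); tot_den <- sum(den)
  d_j <- vapply(blocks, function(b) {
    in_b <- block_id == b
    (tot_num - sum(num[in_b])) / (tot_den - sum(den[in_b]))
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((d_j - mean(d_j))^2))
  list(se = se, n_blocks = B)
}

#' Patterson's D (ABBA-BABA) statistic for one trio
#'
#' Frequency-based D with all outgroup individuals pooled. Alleles are
#' polarized per locus so the outgroup's major allele is ancestral; loci
#' where the outgroup is polymorphic contribute through the `(1 - pO)`
#' weight rather than being discarded. With derived-allele frequencies
#' `p1, p2, p3, pO`:
#' `D = sum[(1-p1) p2 p3 (1-pO) - p1 (1-p2) p3 (1-pO)] /
#'      sum[(1-p1) p2 p3 (1-pO) + p1 (1-p2) p3 (1-pO)]`.
#' The standard error comes from a delete-one block jackknife over
#' contiguous blocks of `block_size` SNPs (loci ordered by chromosome and
#' position), `Z = D/SE`, and p is two-sided normal.
#'
#' @param G [genotype_matrix()].
#' @param trio character vector `(P1, P2, P3)` of population ids.
#' @param outgroup_individuals character vector of individual ids pooled as
#'   the outgroup.
#' @param block_size SNPs per jackknife block (default 1000).
#' @return one-row data frame of class `dstat_result`: trio, `D`, `se`, `Z`,
#'   `p`, `n_loci_used`, `block_size`, `n_blocks`.
#' @export
d_statistic <- function(G, trio, outgroup_individuals, block_size = 1000) {
  stopifnot(length(trio) == 3)
  rows_of <- function(pp) which(G$sample_meta$pop == pp)
  r1 <- rows_of(trio[1]); r2 <- rows_of(trio[2]); r3 <- rows_of(trio[3])
  ro <- match(outgroup_individuals, G$sample_meta$id)
  ro <- ro[!is.na(ro)]
  if (!length(r1) || !length(r2) || !length(r3) || !length(ro))
    stopf("empty group in trio/outgroup")
  f1 <- allele_freq(G, r1); f2 <- allele_freq(G, r2)
  f3 <- allele_freq(G, r3); fo <- allele_freq(G, ro)
  ok <- !is.na(f1) & !is.na(f2) & !is.na(f3) & !is.na(fo)
  # polarize: derived = the outgroup's minor allele
  flip <- fo > 0.5
  p1 <- ifelse(flip, 1 - f1, f1)[ok]
  p2 <- ifelse(flip, 1 - f2, f2)[ok]
  p3 <- ifelse(flip, 1 - f3, f3)[ok]
  pO <- ifelse(flip, 1 - fo, fo)[ok]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  num <- abba - baba
  den <- abba + baba
  if (sum(den) == 0) {
    return(structure(data.frame(P1 = trio[1], P2 = trio[2], P3 = trio[3],
                                D = NA_real_, se = NA_real_, Z = NA_real_,
                                p = NA_real_, n_loci_used = sum(ok),
                                block_size = block_size, n_blocks = 0L),
                     class = c("dstat_result", "data.frame")))
  }
  block_id <- (seq_along(num) - 1L) %/% as.integer(block_size)
  if (length(unique(block_id)) < 3)
    stopf("fewer than 3 jackknife blocks (%d loci at block size %d)",
          length(num), block_size)
  D <- sum(num) / sum(den)
  jk <- block_jackknife_ratio(num, den, block_id)
  Z <- D / jk$se
  p <- 2 * pnorm(-abs(Z))
  structure(data.frame(P1 = trio[1], P2 = trio[2], P3 = trio[3], D = D,
                       se = jk$se, Z = Z, p = p, n_loci_used = sum(ok),
                       block_size = block_size, n_blocks = jk$n_blocks),
            class = c("dstat_result", "data.frame"))
}

#' D statistics for a set of trios
#'
#' @param G [genotype_matrix()].
#' @param trios `trio_set` from [enumerate_trios()] (or a data frame with
#'   columns `P1`, `P2`, `P3`).
#' @param outgroup_individuals individual ids pooled as the outgroup
#'   (typically all native-range individuals).
#' @param block_size SNPs per jackknife block.
#' @param adjust_method multiple-testing method passed to
#'   [adjust_trio_pvalues()] (default `"holm"`).
#' @return data frame of per-trio results with `p_adjusted`.
#' @export
d_statistics <- function(G, trios, outgroup_individuals, block_size = 1000,
                         adjust_method = "holm") {
  res <- do.call(rbind, lapply(seq_len(nrow(trios)), function(i)
    d_statistic(G, unlist(trios[i, c("P1", "P2", "P3")]),
                outgroup_individuals, block_size)))
  adjust_trio_pvalues(res, method = adjust_method)
}

#' Adjust trio p-values for multiple testing
#'
#' @param results data frame with a `p` column (as from [d_statistics()]).
#' @param method any method accepted by [stats::p.adjust()]
#'   (default `"holm"`; `"BH"` gives Benjamini-Hochberg FDR).
#' @return `results` with a `p_adjusted` column.
#' @export
adjust_trio_pvalues <- function(results, method = "holm") {
  results$p_adjusted <- p.adjust(results$p, method = method)
  results
}
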