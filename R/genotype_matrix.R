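#' Construct a genotype matrix object
#'
#' Container for diploid biallelic SNP genotypes: an individuals x loci
#' matrix of alternate-allele dosages (0, 1, 2 or `NA` for missing calls)
#' plus locus metadata (chromosome, 1-based position, ref/alt alleles) and
#' sample metadata (individual id, population id).
#'
#' @param dosage integer matrix, individuals x loci, entries in
#'   `{0, 1, 2, NA}`.
#' @param locus_meta data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param sample_meta data frame with columns `id`, `pop`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, locus_meta, sample_meta) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(locus_meta) == ncol(dosage),
            nrow(sample_meta) == nrow(dosage),
            all(c("chrom", "pos", "ref", "alt") %in% names(locus_meta)),
            all(c("id", "pop") %in% names(sample_meta)))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stopf("dosage entries must be 0, 1, 2 or NA")
  for (ch in unique(locus_meta$chrom)) {
    p <- locus_meta$pos[locus_meta$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  rownames(dosage) <- sample_meta$id
  structure(list(dosage = dosage, locus_meta = locus_meta,
                 sample_meta = sample_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d chromosomes, %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$locus_meta$chrom)), 100 * miss))
  cat(sprintf("populations: %s\n",
              paste(unique(x$sample_meta$pop), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param G [genotype_matrix()].
#' @param i row (individual) indices; `NULL` keeps all.
#' @param j column (locus) indices; `NULL` keeps all.
#' @return the subsetted [genotype_matrix()], metadata kept in sync.
#' @export
subset_genotypes <- function(G, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(G$dosage))
  if (is.null(j)) j <- seq_len(ncol(G$dosage))
  genotype_matrix(G$dosage[i, j, drop = FALSE],
                  G$locus_meta[j, , drop = FALSE],
                  G$sample_meta[i, , drop = FALSE])
}

#' Construct a population map
#'
#' Maps each sampled individual to a watershed (the sampling population) and
#' each watershed to an island or native-range region.
#'
#' @param individual character vector of individual ids.
#' @param watershed character vector, same length, of watershed ids.
#' @param island character vector, same length, of island/region labels;
#'   native-range watersheds carry a region label distinguishing them from
#'   the invaded islands.
#' @param native_label label marking native-range watersheds
#'   (default `"Native"`).
#' @return object of class `population_map`: a data frame with columns
#'   `individual`, `watershed`, `island` and attribute `native_label`.
#' @export
population_map <- function(individual, watershed, island,
                           native_label = "Native") {
  stopifnot(length(individual) == length(watershed),
            length(watershed) == length(island))
  if (anyNA(island)) stopf("every watershed needs an island/region label")
  w2i <- unique(data.frame(watershed = watershed, island = island))
  if (anyDuplicated(w2i$watershed))
    stopf("a watershed maps to more than one island")
  pm <- data.frame(individual = as.character(individual),
                   watershed = as.character(watershed),
                   island = as.character(island),
                   stringsAsFactors = FALSE)
  structure(pm, class = c("population_map", "data.frame"),
            native_label = native_label)
}

hawaiian_watersheds <- function(popmap) {
  nl <- attr(popmap, "native_label") %||% "Native"
  unique(popmap$watershed[popmap$island != nl])
}

native_individuals <- function(popmap) {
  nl <- attr(popmap, "native_label") %||% "Native"
  popmap$individual[popmap$island == nl]
}

watershed_island <- function(popmap) {
  u <- unique(popmap[, c("watershed", "island")])
  setNames(u$island, u$watershed)
}

# Alternate-allele frequency per locus for a set of row indices (individuals).
allele_freq <- function(G, rows = NULL) {
  d <- if (is.null(rows)) G$dosage else G$dosage[rows, , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}
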