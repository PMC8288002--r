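#' Specify a demographic model for coalescent simulation
#'
#' A model is a set of demes with piecewise-constant diploid effective sizes,
#' a time-ordered list of demographic events (population joins looking
#' backward in time, i.e. splits looking forward; admixture pulses; size
#' changes) and an optional continuous backward migration-rate matrix.
#' Times are generations before present.
#'
#' @param pop_sizes numeric vector of present-day diploid effective sizes,
#'   one per deme.
#' @param events data frame with columns `time`, `type` (one of `"join"`,
#'   `"size"`, `"pulse"`, `"migset"`), `a`, `b` (deme indices; `b` ignored
#'   for `"size"`), and `param` (new size for `"size"`, movement probability
#'   for `"pulse"`, new backward rate a -> b for `"migset"`, ignored for
#'   `"join"`). May be `NULL` for a single panmictic deme.
#' @param migration optional square matrix of backward per-generation
#'   per-lineage migration rates (`migration[i, j]` = rate at which a lineage
#'   in deme `i` jumps to deme `j`).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(pop_sizes, events = NULL, migration = NULL) {
  stopifnot(is.numeric(pop_sizes), all(pop_sizes > 0))
  k <- length(pop_sizes)
  if (is.null(events)) {
    events <- data.frame(time = numeric(), type = character(),
                         a = integer(), b = integer(), param = numeric())
  }
  stopifnot(all(c("time", "type", "a", "b", "param") %in% names(events)))
  if (nrow(events)) {
    if (any(events$time <= 0)) stopf("event times must be strictly positive")
    if (is.unsorted(events$time)) events <- events[order(events$time), , drop = FALSE]
    if (!all(events$type %in% c("join", "size", "pulse", "migset")))
      stopf("unknown event type")
    if (any(events$a < 1 | events$a > k)) stopf("event deme index out of range")
    pl <- events$type == "pulse"
    if (any(pl & (events$param < 0 | events$param > 1)))
      stopf("pulse probability must lie in [0, 1]")
  }
  if (is.null(migration)) migration <- matrix(0, k, k)
  stopifnot(is.matrix(migration), nrow(migration) == k, ncol(migration) == k,
            all(migration >= 0))
  structure(list(pop_sizes = pop_sizes, events = events, migration = migration),
            class = "demographic_model")
}

event_df <- function(time, type, a, b = NA_integer_, param = NA_real_) {
  data.frame(time = time, type = type, a = a, b = b, param = param)
}

events_matrix <- function(model) {
  ev <- model$events
  if (!nrow(ev)) return(matrix(numeric(), 0, 5))
  type_code <- c(join = 0, size = 1, pulse = 2, migset = 3)[ev$type]
  cbind(ev$time, type_code, ev$a - 1L, ifelse(is.na(ev$b), 0L, ev$b - 1L),
        ifelse(is.na(ev$param), 0, ev$param))
}

#' Simulate unlinked SNP genotypes under a demographic model
#'
#' Draws independent genealogies (one per locus) under the structured
#' coalescent and places mutations on them. In `"snp"` mode each locus
#' yields exactly one segregating site (a mutation placed on a branch chosen
#' proportionally to its length), which fixes the number of SNPs; in
#' `"poisson"` mode each locus represents `sites_per_locus` base pairs and
#' carries a Poisson number of infinite-sites mutations with per-site
#' per-generation rate `mu`, so the mutational target (and theta) is
#' explicit.
#'
#' @param model a [demographic_model()].
#' @param sample_hap integer vector: haploid sample size per deme.
#' @param n_loci number of independent genealogies.
#' @param mode `"snp"` or `"poisson"`.
#' @param mu per-site per-generation mutation rate (`"poisson"` mode).
#' @param sites_per_locus sites represented by each genealogy
#'   (`"poisson"` mode).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return list with `haplotypes` (0/1 matrix, rows = haploid genomes in
#'   deme order), and `locus` (genealogy index per SNP column).
#' @export
simulate_coalescent <- function(model, sample_hap, n_loci,
                                mode = c("snp", "poisson"),
                                mu = NULL, sites_per_locus = 1L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "demographic_model"),
            length(sample_hap) == length(model$pop_sizes))
  local_seed(seed)
  mu_locus <- if (mode == "poisson") {
    if (is.null(mu) || mu <= 0) stopf("poisson mode requires mu > 0")
    mu * sites_per_locus
  } else 0
  cpp_coal_genotypes(as.integer(sample_hap), as.numeric(model$pop_sizes),
                     events_matrix(model), model$migration,
                     as.integer(n_loci), mu_locus, mode == "snp")
}

#' Monte-Carlo expected branch-length spectrum
#'
#' Averages, over replicate genealogies, the total branch length subtending
#' every (i, j) descendant-count class for one or two sampled demes. The
#' expected (unfolded) SFS at per-site rate `mu` over `L` sites is
#' `mu * L * spectrum`.
#'
#' @inheritParams simulate_coalescent
#' @param n_reps number of genealogies averaged.
#' @return numeric matrix `(n1+1) x (n2+1)` of mean branch lengths in
#'   generations (column count 1 when a single deme is sampled).
#' @export
branch_spectrum <- function(model, sample_hap, n_reps = 20000L, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  local_seed(seed)
  cpp_branch_spectrum(as.integer(sample_hap), as.numeric(model$pop_sizes),
                      events_matrix(model), model$migration, as.integer(n_reps))
}
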