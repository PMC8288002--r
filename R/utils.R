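#' @useDynLib invadepop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp rbinom rpois rnorm runif rmultinom optim pchisq
#'   pnorm phyper p.adjust cor.test qlogis plogis median sd quantile setNames
#'   rexp var qchisq aggregate
#' @importFrom utils combn read.table write.table write.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Set the RNG locally; the caller's RNG state is restored on exit.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (is.null(old)) {
    quote(rm(".Random.seed", envir = globalenv()))
  } else {
    substitute(assign(".Random.seed", old, envir = globalenv()), list(old = old))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# Derived per-stage seeds: stable counter scheme below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + stage) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
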