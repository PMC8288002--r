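#' Configure a full pipeline run
#'
#' Bundles all stage parameters with defaults matching the study settings:
#' MAF threshold 0.03, individual/locus missingness 0.75/0.5, admixture K
#' grid 1-12 with 10 replicates, jackknife block sizes
#' (100, 200, 1000, 2000), mu = 4.89e-8, 3.5 generations/year, q < 0.05,
#' shift quantile 0.95, gene window 200 bp.
#'
#' @param scenario a [scenario_config()] for synthetic mode, or `NULL` when
#'   reading files.
#' @param vcf,popmap,env_file input paths (ignored in synthetic mode).
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived by a counter scheme
#'   (`derive_seed(seed, stage)`), so stages are individually reproducible.
#' @param ... overrides for any default in the returned list.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, vcf = NULL, popmap = NULL,
                            env_file = NULL, out_dir = tempfile("invadepop_"),
                            seed = 1L, ...) {
  cfg <- list(
    scenario = scenario, vcf = vcf, popmap = popmap, env_file = env_file,
    out_dir = out_dir, seed = as.integer(seed),
    maf_min = 0.03, max_ind_missing = 0.75, max_locus_missing = 0.5,
    K_range = 1:12, admixture_replicates = 10, mask_fraction = 0.05,
    block_sizes = c(100, 200, 1000, 2000), block_size = 1000,
    adjust_method = "holm", cross_island_only = FALSE,
    mu = 4.89e-8, gens_per_year = 3.5,
    q_threshold = 0.05, shift_quantile = 0.95, gene_window = 200,
    n_bootstrap = 100, stairway_epochs = 1:5,
    run_structure = TRUE, run_dstats = TRUE, run_demography = FALSE,
    run_envassoc = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$scenario) && (is.null(cfg$vcf) || is.null(cfg$popmap)))
    stopf("either a scenario or vcf + popmap paths are required")
  if (!is.null(cfg$vcf) && !file.exists(cfg$vcf))
    stopf("input VCF not found: %s", cfg$vcf)
  if (!is.null(cfg$popmap) && !file.exists(cfg$popmap))
    stopf("popmap not found: %s", cfg$popmap)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate-or-read, QC (filters +
#' imputation + diversity), structure (PCA, admixture scan, F_ST, AMOVA),
#' D-statistics, and environmental association -- writing each stage's
#' outputs under `config$out_dir` before the next stage starts. Identical
#' config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`: per-stage summaries, seeds,
#'   wall-clock times and the output-file manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  stages <- list()
  t_all <- proc.time()[["elapsed"]]
  emit <- function(name, obj) {
    path <- file.path(config$out_dir, name)
    if (is.data.frame(obj) || is.matrix(obj)) {
      write.csv(as.data.frame(obj), path, row.names = !is.data.frame(obj))
    } else writeLines(as.character(obj), path)
    manifest[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    stages[[name]] <<- list(elapsed = proc.time()[["elapsed"]] - t0)
    res
  }

  # --- input ---------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$scenario)) {
      sim <- simulate_invasion(config$scenario)
      env <- simulate_environment(sim$truth, config$scenario)
      sim$env <- env
      sim
    } else {
      rd <- read_genotypes(config$vcf, config$popmap)
      rd$env <- if (!is.null(config$env_file))
        utils::read.csv(config$env_file, stringsAsFactors = FALSE) else NULL
      rd$truth <- NULL
      rd
    }
  })
  stages$input$n_individuals <- nrow(dat$genotypes$dosage)
  stages$input$n_snps <- ncol(dat$genotypes$dosage)

  # --- qc ------------------------------------------------------------------
  qc <- stage("qc", {
    flt <- apply_quality_filters(dat$genotypes, config$maf_min,
                                 config$max_ind_missing,
                                 config$max_locus_missing)
    imp <- impute_missing(flt$genotypes, seed = derive_seed(config$seed, 21L))
    div <- diversity_stats(imp)
    emit("filter_report.csv", flt$report)
    emit("diversity.csv", div)
    list(genotypes = imp, report = flt$report, diversity = div)
  })
  G <- qc$genotypes
  popmap <- dat$popmap
  popmap <- popmap[popmap$individual %in% G$sample_meta$id, , drop = FALSE]

  # --- structure -----------------------------------------------------------
  if (config$run_structure) {
    st <- stage("structure", {
      pca <- genotype_pca(G, n_components = min(10, nrow(G$dosage)))
      scan <- admixture_scan(G, config$K_range, config$admixture_replicates,
                             config$mask_fraction,
                             seed = derive_seed(config$seed, 22L))
      fst <- pairwise_fst(G)
      am <- amova(G, popmap)
      best <- scan$fits[[match(scan$best_K,
                               vapply(scan$fits, `[[`, 0, "K"))]]
      emit("pca_variance.csv",
           data.frame(component = seq_along(pca$variance_fraction),
                      variance_fraction = pca$variance_fraction))
      emit("admixture_Q.csv", as.data.frame(best$Q))
      emit("fst_matrix.csv", unclass(fst))
      emit("amova.csv", am)
      list(pca = pca, scan = scan, fst = fst, amova = am)
    })
    stages$structure$best_K <- st$scan$best_K
  } else st <- NULL

  # --- D statistics --------------------------------------------------------
  if (config$run_dstats) {
    ds <- stage("dstats", {
      trios <- enumerate_trios(popmap, config$cross_island_only)
      og <- native_individuals(popmap)
      res <- d_statistics(G, trios, og, block_size = config$block_size,
                          adjust_method = config$adjust_method)
      emit("dstats.csv", res)
      res
    })
    stages$dstats$n_trios <- nrow(ds)
    stages$dstats$n_significant <- sum(ds$p_adjusted < 0.05, na.rm = TRUE)
  } else ds <- NULL

  # --- environmental association -------------------------------------------
  ea <- NULL
  if (config$run_envassoc && !is.null(dat$env)) {
    ea <- stage("envassoc", {
      env <- dat$env
      haw <- G$sample_meta$pop %in% env$watershed
      Gh <- subset_genotypes(G, i = which(haw))
      K_latent <- max(1L, (if (!is.null(st)) st$scan$best_K else 2L) - 1L)
      vars <- setdiff(names(env), c("watershed", "island"))
      assoc <- lapply(vars, function(v) {
        y <- env_for_individuals(Gh, env, v)
        lfmm_associate(Gh, y, K_latent = K_latent)
      })
      names(assoc) <- vars
      enr <- do.call(rbind, lapply(vars, function(v) {
        a <- assoc[[v]]
        hit <- which(a$q < config$q_threshold)
        hi <- env$watershed[which.max(env[[v]])]
        lo <- env$watershed[which.min(env[[v]])]
        sh <- allele_frequency_shift(Gh, hi, lo, config$shift_quantile)
        K_ext <- sum(sh$extreme)
        x <- sum(sh$extreme[hit])
        data.frame(variable = v, n_assoc = length(hit), x_extreme = x,
                   N_total = nrow(sh), K_extreme = K_ext,
                   fisher_p = enrichment_test(length(hit), x, nrow(sh), K_ext))
      }))
      hecor <- he_env_correlation(diversity_stats(Gh), env)
      emit("enrichment.csv", enr)
      emit("he_env_correlation.csv", hecor)
      list(assoc = assoc, enrichment = enr, he_correlation = hecor,
           K_latent = K_latent)
    })
  }

  report <- structure(list(
    stages = stages, manifest = manifest, seed = config$seed,
    elapsed = proc.time()[["elapsed"]] - t_all,
    results = list(qc = qc, structure = st, dstats = ds, envassoc = ea,
                   data = dat)),
    class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d stages, %.1f s elapsed, seed %d\n",
              length(x$stages), x$elapsed, x$seed))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    extra <- setdiff(names(s), "elapsed")
    cat(sprintf("  %-10s %6.1f s%s\n", nm, s$elapsed,
                if (length(extra)) paste0("  (",
                  paste(sprintf("%s=%s", extra, unlist(s[extra])),
                        collapse = ", "), ")") else ""))
  }
  cat("outputs:\n")
  for (nm in names(x$manifest)) cat("  ", x$manifest[[nm]], "\n")
  invisible(x)
}
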