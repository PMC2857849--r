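#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: which relationship-matrix methods to
#' compare, how to restrict and filter the marker panel, the trajectory
#' extrapolation target, and either a simulation configuration or paths to
#' input files.
#'
#' @param methods Subset of `"PB"` (pedigree), `"SNPL"` (Loiselle),
#'   `"SNPC"` (averaged local relationship).
#' @param chromosome Chromosome label the SNP methods are restricted to.
#' @param maf_threshold Minor-allele-frequency filter applied before the
#'   SNPC method (the SNPL method uses the full panel of the chromosome).
#' @param n_points Number of positions for the SNPC local-matrix average.
#' @param extrapolation_time Time point to which trajectories are
#'   extrapolated.
#' @param top_n Selected-group size for the overlap metric.
#' @param bending_epsilon Minimum eigenvalue enforced on marker matrices.
#' @param seed Seed used when simulating.
#' @param simulation A [sim_config()] (used when `input_dir` is `NULL`).
#' @param input_dir Directory of input files in the [write_population()]
#'   layout; overrides simulation when given.
#' @param output_dir Directory for artifacts (matrices, variance components,
#'   EBVs, trajectories, predictions, report, manifest); `NULL` writes
#'   nothing.
#' @return A validated `snpblup_run_config` list.
#' @export
run_config <- function(methods = c("PB", "SNPL", "SNPC"),
                       chromosome = "chr1",
                       maf_threshold = 0.1,
                       n_points = 9,
                       extrapolation_time = 600,
                       top_n = 20,
                       bending_epsilon = 1e-6,
                       seed = 1L,
                       simulation = sim_config(seed = seed),
                       input_dir = NULL,
                       output_dir = NULL) {
  methods <- match.arg(methods, c("PB", "SNPL", "SNPC"), several.ok = TRUE)
  if (length(methods) < 1) stop("select at least one method", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  structure(
    list(methods = methods, chromosome = chromosome,
         maf_threshold = maf_threshold, n_points = n_points,
         extrapolation_time = extrapolation_time, top_n = top_n,
         bending_epsilon = bending_epsilon, seed = as.integer(seed),
         simulation = simulation, input_dir = input_dir,
         output_dir = output_dir),
    class = "snpblup_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulation` map
#' mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return A `snpblup_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation %||% list()
  if (!is.null(raw$seed) && is.null(sim_args$seed)) {
    sim_args$seed <- raw$seed
  }
  raw$simulation <- do.call(sim_config, sim_args)
  do.call(run_config, raw)
}

#' Run the full relationship-matrix comparison
#'
#' Simulates (or ingests) a population, builds the requested genetic
#' covariance matrices, fits an animal model at every phenotyping time point
#' per method, fits per-animal quadratic trajectories of EBV on time,
#' extrapolates to the target time, and evaluates predictions for the
#' masked (non-phenotyped) validation animals against true breeding values
#' when those are available. Deterministic given the seed.
#'
#' @param cfg A [run_config()].
#' @param population Optional pre-built `snpblup_population` (bypasses both
#'   simulation and file input; useful for reusing one population across
#'   configurations).
#' @return A `snpblup_report`: list with `metrics` (tibble, one row per
#'   method), `variance_components`, `ebv` (all methods), `predictions` (at
#'   the extrapolation time), `ebv_correlations` (named list of matrices),
#'   `family_spread` (validation families, per method), `log` (character),
#'   and `config`.
#' @export
run_pipeline <- function(cfg, population = NULL) {
  stopifnot(inherits(cfg, "snpblup_run_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  ## data ----
  if (!is.null(population)) {
    pop <- population
    note("population: supplied object (%d animals)", nrow(pop$pedigree))
  } else if (!is.null(cfg$input_dir)) {
    pop <- ingest_population(cfg$input_dir)
    note("population: read from %s (%d animals)", cfg$input_dir,
         nrow(pop$pedigree))
  } else {
    pop <- simulate_population(cfg$simulation)
    note("population: simulated with seed %d (%d animals, %d masked)",
         cfg$simulation$seed, nrow(pop$pedigree), length(pop$masked_ids))
  }
  ped <- pop$pedigree
  phenos <- pop$phenotypes
  validation_ids <- pop$masked_ids

  ## relationship matrices ----
  mats <- list()
  if ("PB" %in% cfg$methods) {
    mats$PB <- additive_relationship(ped)
    note("PB: additive relationship from pedigree (%d animals)", nrow(ped))
  }
  if (any(c("SNPL", "SNPC") %in% cfg$methods)) {
    Gc <- subset_chromosome(pop$genotypes, cfg$chromosome)
    note("SNP panel restricted to %s: %d loci", cfg$chromosome, n_loci(Gc))
    if ("SNPL" %in% cfg$methods) {
      M <- loiselle_relatedness(Gc)
      M <- fill_diagonal(M, ped)
      M <- bend_to_pd(M, cfg$bending_epsilon)
      note("SNPL: Loiselle matrix from %d loci; bending shift %.3g",
           n_loci(Gc), attr(M, "bending_shift"))
      mats$SNPL <- M
    }
    if ("SNPC" %in% cfg$methods) {
      Gf <- maf_filter(Gc, cfg$maf_threshold)
      note("SNPC: %d of %d loci pass MAF > %.2f", n_loci(Gf), n_loci(Gc),
           cfg$maf_threshold)
      M <- local_relationship_average(Gf, n_points = cfg$n_points)
      M <- bend_to_pd(M, cfg$bending_epsilon)
      note("SNPC: averaged %d local matrices; bending shift %.3g",
           cfg$n_points, attr(M, "bending_shift"))
      mats$SNPC <- M
    }
  }

  ## per-method model fits, trajectories, evaluation ----
  vc_all <- list()
  ebv_all <- list()
  pred_all <- list()
  metr_all <- list()
  corr_all <- list()
  fam_all <- list()
  has_truth <- !is.null(pop$true_bv)
  true600 <- if (has_truth) {
    dplyr::filter(pop$true_bv, .data$time == cfg$extrapolation_time)
  }
  for (m in cfg$methods) {
    fit <- fit_time_points(phenos, mats[[m]])
    if (!all(fit$variance_components$converged)) {
      note("%s: REML did not converge at time(s) %s", m,
           paste(fit$variance_components$time[
             !fit$variance_components$converged], collapse = ", "))
    }
    coeffs <- fit_quadratic(fit$ebv)
    preds <- extrapolate(coeffs, cfg$extrapolation_time)
    preds <- dplyr::left_join(preds, coeffs, by = "id")
    vc_all[[m]] <- dplyr::mutate(fit$variance_components, method = m,
                                 .before = 1)
    ebv_all[[m]] <- dplyr::mutate(fit$ebv, method = m, .before = 1)
    pred_all[[m]] <- dplyr::mutate(preds, method = m, .before = 1)
    corr_all[[m]] <- ebv_correlations(fit$ebv)
    val_pred <- preds[preds$id %in% validation_ids, ]
    fam_all[[m]] <- dplyr::mutate(
      family_spread(val_pred, ped), method = m, .before = 1)
    if (has_truth && length(validation_ids) > 0) {
      truth <- true600[true600$id %in% validation_ids,
                       c("id", "true_bv")]
      metr_all[[m]] <- dplyr::mutate(
        evaluate_predictions(val_pred, truth, top_n = cfg$top_n),
        method = m, .before = 1)
    } else {
      metr_all[[m]] <- tibble::tibble(
        method = m, n = nrow(val_pred), accuracy = NA_real_,
        regression = NA_real_, topn_overlap_pct = NA_real_,
        pred_variance = stats::var(val_pred$pred_bv))
    }
  }

  report <- structure(
    list(
      metrics = dplyr::bind_rows(metr_all),
      variance_components = dplyr::bind_rows(vc_all),
      ebv = dplyr::bind_rows(ebv_all),
      predictions = dplyr::bind_rows(pred_all),
      ebv_correlations = corr_all,
      family_spread = dplyr::bind_rows(fam_all),
      validation_ids = validation_ids,
      matrices = mats,
      population = pop,
      log = log_lines,
      config = cfg
    ),
    class = "snpblup_report"
  )
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

ingest_population <- function(input_dir) {
  raw <- read_population(input_dir)
  masked <- setdiff(raw$pedigree$id, unique(raw$phenotypes$id))
  list(pedigree = raw$pedigree, genotypes = raw$genotypes,
       phenotypes = raw$phenotypes, true_bv = raw$true_bv,
       masked_ids = masked)
}

#' @export
print.snpblup_report <- function(x, ...) {
  cat("<relationship-matrix comparison report>\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 3)
  cat("\nheritability by time point:\n")
  h2 <- tidyr::pivot_wider(
    x$variance_components[, c("method", "time", "h2")],
    names_from = "time", values_from = "h2", names_prefix = "T")
  print(as.data.frame(h2), row.names = FALSE, digits = 2)
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' Emits relationship matrices, variance components, EBVs, trajectory
#' coefficients with predictions, the evaluation metrics, a plain-text
#' summary, the run log and a JSON manifest echoing the full configuration.
#'
#' @param report A `snpblup_report`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (m in names(report$matrices)) {
    write_relmat(report$matrices[[m]],
                 file.path(directory, paste0("relmat_", m, ".txt")))
  }
  utils::write.csv(as.data.frame(report$variance_components),
                   file.path(directory, "variance_components.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$ebv),
                   file.path(directory, "ebv.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$predictions),
                   file.path(directory, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$metrics),
                   file.path(directory, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$family_spread),
                   file.path(directory, "family_spread.csv"),
                   row.names = FALSE)
  writeLines(report$log, file.path(directory, "run_log.txt"))
  summary_lines <- utils::capture.output(print(report))
  writeLines(summary_lines, file.path(directory, "summary.txt"))
  cfg <- report$config
  manifest <- list(
    config = cfg[setdiff(names(cfg), "simulation")],
    simulation = unclass(cfg$simulation),
    artifacts = list.files(directory)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(directory)
}
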