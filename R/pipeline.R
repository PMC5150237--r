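#' Run the full simulated analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate a population and choice events,
#' optionally simulate reads and re-call genotypes, compute index tables, fit
#' the choice GLMMs with parametric-bootstrap LRTs, run the candidate-pool
#' randomization tests, and screen loci for linkage disequilibrium. Every
#' stage draws its randomness from a named sub-stream of the master seed, so
#' re-runs with identical configuration and seed reproduce identical results.
#'
#' @param config Either a `population_config`, a named list with elements
#'   among `population` (a `population_config`), `preference` (a
#'   `preference_spec`), `n_offspring`, `indices`, `genes`, `n_boot`, `B`,
#'   `ld_n_perm`, `stages` (subset of `c("simulate", "infer", "randomize",
#'   "ld")`), or a path to a YAML file encoding the same structure.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, genotypes, events and a
#'   JSON report are written there.
#' @return A list of class `analysis_report` with per-gene, per-index GLMM
#'   and randomization results, LD screen, and provenance (`seed`, config).
#' @export
run_full_analysis <- function(config = list(), seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "population_config")) config <- list(population = config)
  cfg <- utils::modifyList(
    list(population = population_config(),
         preference = preference_spec(),
         n_offspring = 133,
         genes = c("MHC1", "MHC2"),
         indices = INDEX_NAMES,
         n_boot = 1000, B = 100000, ld_n_perm = 10000,
         ld_genes = c("TAAR2", "TAAR3", "TAAR8"),
         candidate_genotyped_prob = NULL,
         stages = c("simulate", "infer", "randomize", "ld")),
    config)
  if (!inherits(cfg$population, "population_config")) {
    cfg$population <- do.call(population_config, cfg$population)
  }
  if (!inherits(cfg$preference, "preference_spec")) {
    cfg$preference <- do.call(preference_spec, cfg$preference)
  }

  report <- list(seed = seed, config = cfg)

  fail_if(!("simulate" %in% cfg$stages), "the simulate stage is required")
  pop <- generate_population(cfg$population, seed = seed)
  sim <- simulate_choices(pop, cfg$preference, n_offspring = cfg$n_offspring,
                          seed = seed)
  report$events <- sim$events
  report$n_individuals <- nrow(sim$population$individuals)

  gprob <- cfg$candidate_genotyped_prob
  if (is.null(gprob)) gprob <- cfg$population$candidate_genotyped_prob

  if (any(c("infer", "randomize") %in% cfg$stages)) {
    report$tests <- list()
    for (g in cfg$genes) {
      D <- aa_distance_matrix(pop$catalogs[[g]])
      keep <- c(sim$events$mother_id, sim$events$father_id)
      geno <- mask_genotypes(sim$population$genotypes[[g]], gprob, keep = keep,
                             seed = substream_seed(seed, paste0("mask:", g)))
      for (ix in cfg$indices) {
        key <- paste(g, ix, sep = ":")
        entry <- list(gene = g, index = ix)
        if ("infer" %in% cfg$stages) {
          tab <- build_choice_table(sim$events, geno, ix, D = D)
          lrt <- lrt_parametric_bootstrap(
            tab, full = "MHC_INDEX", null = "1", n_boot = cfg$n_boot,
            seed = substream_seed(seed, paste0("lrt:", key)))
          entry$glmm <- list(slope = unname(lrt$full_fit$fixef["MHC_INDEX"]),
                             statistic = lrt$statistic, p = lrt$p_value,
                             n_rows = nrow(tab),
                             n_events = length(unique(tab$OFFSPRING)))
        }
        if ("randomize" %in% cfg$stages) {
          rt <- mc_randomization_test(
            sim$events, geno, ix, D = D, B = cfg$B,
            seed = substream_seed(seed, paste0("rand:", key)))
          entry$randomization <- list(observed_mean = rt$observed_mean,
                                      center = rt$center, p = rt$p_two_tailed,
                                      n_couples = rt$n_couples)
        }
        report$tests[[key]] <- entry
      }
    }
  }

  if ("ld" %in% cfg$stages) {
    report$ld <- ld_screen(sim$population$genotypes[cfg$ld_genes],
                           n_perm = cfg$ld_n_perm,
                           seed = substream_seed(seed, "ld_screen"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(sim$population$genotypes[cfg$genes],
                    file.path(out_dir, "genotypes.tsv"))
    write_choice_events(sim$events, file.path(out_dir, "events.tsv"))
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(report) <- "analysis_report"
  report
}

# internal: JSON-friendly flat summary of an analysis report
report_summary <- function(report) {
  out <- list(seed = report$seed, n_events = nrow(report$events))
  for (key in names(report$tests)) {
    e <- report$tests[[key]]
    if (!is.null(e$glmm)) out[[paste0(key, ":glmm_p")]] <- e$glmm$p
    if (!is.null(e$randomization))
      out[[paste0(key, ":randomization_p")]] <- e$randomization$p
  }
  if (!is.null(report$ld)) {
    for (i in seq_len(nrow(report$ld))) {
      out[[sprintf("ld:%s:%s", report$ld$locus_a[i], report$ld$locus_b[i])]] <-
        report$ld$p_value[i]
    }
  }
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (seed ", x$seed, "): ", nrow(x$events), " choice events\n",
      sep = "")
  for (key in names(x$tests)) {
    e <- x$tests[[key]]
    cat(sprintf("  %-14s", key))
    if (!is.null(e$glmm)) {
      cat(sprintf(" GLMM slope %+.3f (boot p = %.4g)", e$glmm$slope, e$glmm$p))
    }
    if (!is.null(e$randomization)) {
      cat(sprintf("  randomization p = %.4g", e$randomization$p))
    }
    cat("\n")
  }
  if (!is.null(x$ld)) {
    cat("LD screen:\n")
    for (i in seq_len(nrow(x$ld))) {
      cat(sprintf("  %s x %s: p = %.4g\n", x$ld$locus_a[i], x$ld$locus_b[i],
                  x$ld$p_value[i]))
    }
  }
  invisible(x)
}
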