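#' Configuration for the synthetic population generator
#'
#' Defaults emulate the study system the statistical machinery was designed
#' for: a polygynous bat population sampled over multiple colonies and mating
#' seasons, with pooled multi-locus MHC genotypes (MHC-I: 50 alleles, 3-6 per
#' individual; MHC-II: 25 alleles, 2-4 per individual), three diploid TAAR loci
#' (9/5/8 alleles, 1-2 distinct per individual), eight diploid microsatellite
#' loci, and candidate-male pools with mean size 9.6 (SD ~8, range 2-21).
#'
#' @param n_colonies Number of colonies.
#' @param males_per_colony Adult males per colony (must allow the largest pool).
#' @param n_females Number of breeding females.
#' @param years Vector of conception years.
#' @param mhc_genes Named list; per gene `n_alleles`, `aa_length`, `size_range`
#'   (bounds of the pooled allele-set size).
#' @param taar_genes Named list; per locus a numeric vector of allele
#'   frequencies (Hardy-Weinberg draws).
#' @param taar_linkage Probability in `[0,1]` that a gamete's three TAAR
#'   alleles derive from one comonotone haplotype draw (creates linkage
#'   disequilibrium among the TAAR loci while preserving marginal frequencies).
#' @param n_msat_loci Number of diploid microsatellite loci.
#' @param msat_alleles Alleles per microsatellite locus.
#' @param pool_size List with `min`, `max`, `w_small`, `small`, `large`
#'   describing the bimodal discrete-uniform mixture of roster sizes.
#' @param candidate_genotyped_prob Probability that a non-father candidate male
#'   is genotyped at an MHC gene (reproduces the sparsity of real choice
#'   tables, where roughly half the candidates carry a genotype).
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_colonies = 11,
                              males_per_colony = 22,
                              n_females = 185,
                              years = 1996:2003,
                              mhc_genes = list(
                                MHC1 = list(n_alleles = 50, aa_length = 60, size_range = c(3, 6)),
                                MHC2 = list(n_alleles = 25, aa_length = 60, size_range = c(2, 4))
                              ),
                              taar_genes = list(
                                TAAR2 = geometric_freqs(9),
                                TAAR3 = c(0.62, 0.30, 0.04, 0.02, 0.02),
                                TAAR8 = geometric_freqs(8)
                              ),
                              taar_linkage = 0.8,
                              n_msat_loci = 8,
                              msat_alleles = 10,
                              pool_size = list(min = 2, max = 21, w_small = 0.612,
                                               small = c(2, 4), large = c(19, 21)),
                              candidate_genotyped_prob = 0.42) {
  fail_if(pool_size$max > males_per_colony,
          "males_per_colony (%d) smaller than maximum pool size (%d)",
          males_per_colony, pool_size$max)
  for (g in names(taar_genes)) {
    fail_if(abs(sum(taar_genes[[g]]) - 1) > 1e-8, "%s frequencies must sum to 1", g)
  }
  structure(as.list(environment()), class = "population_config")
}

#' Geometrically decaying allele frequencies
#' @param n Number of alleles.
#' @param ratio Decay ratio between successive alleles.
#' @return Numeric vector summing to 1.
#' @export
geometric_freqs <- function(n, ratio = 0.6) {
  f <- ratio^(seq_len(n) - 1)
  f / sum(f)
}

# bimodal roster-size distribution: w_small * DU(small) + (1-w_small) * DU(large);
# the target moments (mean 9.6, SD ~8 on [2,21]) force a strongly bimodal shape
rpool_size <- function(n, ps) {
  small <- sample(seq(ps$small[1], ps$small[2]), n, replace = TRUE)
  large <- sample(seq(ps$large[1], ps$large[2]), n, replace = TRUE)
  ifelse(stats::runif(n) < ps$w_small, small, large)
}

#' Generate a synthetic population
#'
#' Creates individuals with pooled MHC genotypes, diploid TAAR and
#' microsatellite genotypes, and per-(colony, year) rosters of candidate males.
#'
#' @param config A [population_config()].
#' @param catalogs Optional named list of `allele_catalog` objects for the MHC
#'   genes; generated from `config` when `NULL`.
#' @param seed Master seed (all randomness flows through named sub-streams).
#' @param mhc_freqs Optional named list of allele sampling weights per MHC gene
#'   (default uniform).
#' @return A list of class `population` with elements `individuals` (data
#'   frame: `id`, `sex`, `colony`), `genotypes` (per gene, a named list of
#'   allele-ID vectors), `diploid` (per TAAR/microsatellite locus, a named list
#'   of length-2 allele vectors), `rosters` (per colony-year, the candidate
#'   male IDs), `catalogs`, and `config`.
#' @export
generate_population <- function(config = population_config(), catalogs = NULL,
                                seed = NULL, mhc_freqs = NULL) {
  cfg <- config
  set_substream(seed, "generate_population")

  if (is.null(catalogs)) {
    catalogs <- lapply(names(cfg$mhc_genes), function(g) {
      spec <- cfg$mhc_genes[[g]]
      generate_allele_catalog(g, spec$n_alleles, spec$aa_length,
                              seed = if (is.null(seed)) NULL else seed)
    })
    names(catalogs) <- names(cfg$mhc_genes)
    set_substream(seed, "generate_population")  # catalogs use their own streams
  }
  for (g in names(cfg$mhc_genes)) {
    fail_if(is.null(catalogs[[g]]) || nrow(catalogs[[g]]) == 0, "empty catalog for %s", g)
    fail_if(cfg$mhc_genes[[g]]$size_range[2] > nrow(catalogs[[g]]),
            "%s genotype bound exceeds catalog size", g)
  }

  n_males <- cfg$n_colonies * cfg$males_per_colony
  males <- data.frame(
    id = sprintf("M%03d", seq_len(n_males)),
    sex = "M",
    colony = rep(sprintf("C%02d", seq_len(cfg$n_colonies)), each = cfg$males_per_colony),
    stringsAsFactors = FALSE
  )
  females <- data.frame(
    id = sprintf("F%03d", seq_len(cfg$n_females)),
    sex = "F",
    colony = sprintf("C%02d", sample.int(cfg$n_colonies, cfg$n_females, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  individuals <- rbind(males, females)
  ids <- individuals$id

  # pooled MHC genotypes: set size uniform within bounds, alleles sampled
  # without replacement
  genotypes <- list()
  for (g in names(cfg$mhc_genes)) {
    spec <- cfg$mhc_genes[[g]]
    w <- if (!is.null(mhc_freqs[[g]])) mhc_freqs[[g]] else NULL
    sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                    length(ids), replace = TRUE)
    genotypes[[g]] <- stats::setNames(lapply(seq_along(ids), function(i) {
      sort(sample(catalogs[[g]]$allele_id, sizes[i], prob = w))
    }), ids)
  }

  # TAAR genotypes: two gamete draws per individual; with probability
  # taar_linkage a gamete carries a comonotone haplotype across the three loci
  taar_names <- names(cfg$taar_genes)
  diploid <- list()
  if (length(taar_names) > 0) {
    draw_gametes <- function(n) {
      linked <- stats::runif(n) < cfg$taar_linkage
      u <- stats::runif(n)
      out <- list()
      for (g in taar_names) {
        f <- cfg$taar_genes[[g]]
        idx_link <- findInterval(u, cumsum(f)) + 1L
        idx_free <- sample.int(length(f), n, replace = TRUE, prob = f)
        idx <- ifelse(linked, idx_link, idx_free)
        out[[g]] <- sprintf("%s-%d", g, idx)
      }
      out
    }
    g1 <- draw_gametes(length(ids))
    g2 <- draw_gametes(length(ids))
    for (g in taar_names) {
      diploid[[g]] <- stats::setNames(
        lapply(seq_along(ids), function(i) c(g1[[g]][i], g2[[g]][i])), ids)
      genotypes[[g]] <- lapply(diploid[[g]], function(p) sort(unique(p)))
    }
  }

  # microsatellites: independent diploid loci, uniform allele frequencies
  for (k in seq_len(cfg$n_msat_loci)) {
    g <- sprintf("MS%d", k)
    a1 <- sample.int(cfg$msat_alleles, length(ids), replace = TRUE)
    a2 <- sample.int(cfg$msat_alleles, length(ids), replace = TRUE)
    diploid[[g]] <- stats::setNames(lapply(seq_along(ids), function(i) {
      sprintf("%s-%02d", g, c(a1[i], a2[i]))
    }), ids)
    genotypes[[g]] <- lapply(diploid[[g]], function(p) sort(unique(p)))
  }

  # per-(colony, year) rosters of available candidate males
  rosters <- list()
  for (co in unique(males$colony)) {
    pool_males <- males$id[males$colony == co]
    for (yr in cfg$years) {
      sz <- min(rpool_size(1, cfg$pool_size), length(pool_males))
      rosters[[paste(co, yr, sep = ":")]] <- sort(sample(pool_males, sz))
    }
  }

  structure(list(individuals = individuals, genotypes = genotypes,
                 diploid = diploid, rosters = rosters, catalogs = catalogs,
                 config = cfg),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Synthetic population:", nrow(x$individuals), "individuals,",
      sum(x$individuals$sex == "F"), "females;",
      length(x$rosters), "colony-year rosters\n")
  cat("Genes:", paste(names(x$genotypes), collapse = ", "), "\n")
  invisible(x)
}

#' Pool microsatellite genotypes into one allele set per individual
#'
#' Joins the per-locus diploid genotypes of all microsatellite loci into a
#' single locus-prefixed allele set per individual, so that the allele-count
#' indices (MALDis, CALDis, MALDiv) can be applied to neutral markers exactly
#' as to the pooled MHC genotypes.
#'
#' @param population A `population`.
#' @return Named list mapping individual ID to a character vector of alleles.
#' @export
pooled_msat_genotypes <- function(population) {
  loci <- grep("^MS[0-9]+$", names(population$genotypes), value = TRUE)
  fail_if(length(loci) == 0, "population has no microsatellite loci")
  ids <- population$individuals$id
  stats::setNames(lapply(ids, function(i) {
    sort(unique(unlist(lapply(loci, function(g) population$genotypes[[g]][[i]]))))
  }), ids)
}

#' Randomly censor a genotype list
#'
#' Emulates incomplete genotyping success: each individual is retained with
#' probability `prob`, except IDs listed in `keep`, which are always retained.
#'
#' @param genotypes Named list of allele sets.
#' @param prob Retention probability.
#' @param keep IDs always retained.
#' @param seed Seed for the censoring draw.
#' @return The censored named list.
#' @export
mask_genotypes <- function(genotypes, prob, keep = character(0), seed = NULL) {
  set_substream(seed, "mask_genotypes")
  ids <- names(genotypes)
  keep_mask <- ids %in% keep | stats::runif(length(ids)) < prob
  genotypes[keep_mask]
}
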