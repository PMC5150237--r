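#' Specify a mate-preference mechanism for choice simulation
#'
#' In a simulated choice event, the father is drawn from the mother's
#' candidate pool with probability proportional to `exp(beta * index)`, where
#' `index` is one of the five MHC indices evaluated for the (mother, candidate)
#' pair. `beta = 0` reproduces uniform random choice within pools.
#'
#' `beta` may also be a named vector `c(het = ..., hom = ...)` together with
#' `taar_gene`, in which case the slope applied to a mother depends on her
#' heterozygosity status at that locus (used for interaction power studies).
#'
#' @param index Index name (see [mhc_index()]).
#' @param beta Log-odds slope per index unit (scalar, or named `het`/`hom` pair).
#' @param gene MHC gene whose genotypes feed the index.
#' @param taar_gene Optional TAAR locus moderating `beta`.
#' @param mode `muAADis` mode, see [mu_aadis()].
#' @return An object of class `preference_spec`.
#' @export
preference_spec <- function(index = "MALDiv", beta = 0, gene = "MHC1",
                            taar_gene = NULL, mode = "within_symdiff") {
  index <- match.arg(index, INDEX_NAMES)
  if (length(beta) > 1) {
    fail_if(is.null(names(beta)) || !all(c("het", "hom") %in% names(beta)),
            "vector beta must be named c(het=, hom=)")
    fail_if(is.null(taar_gene), "het/hom beta requires taar_gene")
  }
  structure(list(index = index, beta = beta, gene = gene,
                 taar_gene = taar_gene, mode = mode),
            class = "preference_spec")
}

# internal: is an individual heterozygous at a diploid locus?
is_heterozygous <- function(population, gene, id) {
  pair <- population$diploid[[gene]][[id]]
  fail_if(is.null(pair), "no diploid genotype for %s at %s", id, gene)
  pair[1] != pair[2]
}

# internal: Mendelian-consistent offspring allele set for a pooled MHC gene.
# The set size is drawn uniformly from the configured bounds; ceil(k/2) alleles
# come from one (randomly chosen) parent and the rest from the other, the
# union is deduplicated and topped up from the parental union so that the
# final size is min(k, |union|) (never below the lower bound, since the union
# is at least as large as either parent's set).
inherit_pooled <- function(mother_set, father_set, size_range) {
  k <- sample(seq(size_range[1], size_range[2]), 1)
  if (stats::runif(1) < 0.5) {
    p1 <- mother_set; p2 <- father_set
  } else {
    p1 <- father_set; p2 <- mother_set
  }
  k1 <- min(ceiling(k / 2), length(p1))
  k2 <- min(k - k1, length(p2))
  got <- unique(c(sample(p1, k1), sample(p2, max(k2, 1))))
  un <- union(mother_set, father_set)
  if (length(got) < k) {
    extra <- setdiff(un, got)
    if (length(extra) > 0) {
      got <- c(got, sample(extra, min(k - length(got), length(extra))))
    }
  }
  sort(got)
}

#' Simulate mate-choice events with preference-driven paternity
#'
#' For each offspring: a mother is drawn, her colony-year roster forms the
#' candidate pool, the father is drawn from the pool with weight
#' `exp(beta * index(mother, candidate))`, and Mendelian-consistent offspring
#' genotypes are generated (pooled-set inheritance for MHC genes, one allele
#' from each parent for diploid loci). Undefined index values (e.g. `muAADis`
#' for fully shared genotypes) enter the preference weight as zero.
#'
#' @param population A [generate_population()] result.
#' @param preference A [preference_spec()].
#' @param n_offspring Number of choice events to simulate.
#' @param seed Master seed.
#' @param D Optional distance matrix (computed from the catalog when required).
#' @return A list of class `choice_simulation` with `events` (data frame of
#'   class `choice_events`: `offspring_id`, `mother_id`, `father_id`,
#'   `candidate_ids` (semicolon-joined), `colony`, `year`) and `population`
#'   (the input population augmented with the offspring and their genotypes).
#' @export
simulate_choices <- function(population, preference = preference_spec(),
                             n_offspring = 133, seed = NULL, D = NULL) {
  set_substream(seed, "simulate_choices")
  cfg <- population$config
  gene <- preference$gene
  geno <- population$genotypes[[gene]]
  fail_if(is.null(geno), "population has no genotypes for gene %s", gene)
  needs_D <- preference$index %in% c("muAADis", "MAADiv")
  if (needs_D && is.null(D)) D <- aa_distance_matrix(population$catalogs[[gene]])

  females <- population$individuals[population$individuals$sex == "F", ]
  mothers <- females[sample.int(nrow(females), n_offspring, replace = TRUE), ]
  years <- sample(cfg$years, n_offspring, replace = TRUE)

  # per-male diversity values can be cached; dissimilarity values depend on
  # the mother and are computed per event
  div_cache <- NULL
  if (!index_is_dissimilarity(preference$index)) {
    males <- population$individuals$id[population$individuals$sex == "M"]
    div_cache <- vapply(males, function(m) {
      mhc_index(preference$index, male = geno[[m]], D = D)
    }, numeric(1))
  }

  events <- vector("list", n_offspring)
  new_ids <- sprintf("O%04d", seq_len(n_offspring))
  off_geno <- lapply(population$genotypes, function(x) list())
  off_dip <- lapply(population$diploid, function(x) list())

  for (i in seq_len(n_offspring)) {
    mo <- mothers$id[i]
    pool <- population$rosters[[paste(mothers$colony[i], years[i], sep = ":")]]
    if (index_is_dissimilarity(preference$index)) {
      v <- vapply(pool, function(m) {
        mhc_index(preference$index, male = geno[[m]], female = geno[[mo]],
                  D = D, mode = preference$mode)
      }, numeric(1))
    } else {
      v <- div_cache[pool]
    }
    beta <- preference$beta
    if (length(beta) > 1) {
      beta <- if (is_heterozygous(population, preference$taar_gene, mo))
        beta[["het"]] else beta[["hom"]]
    }
    if (all(is.na(v)) && beta != 0) {
      stop("all candidate index values undefined for event ", i, call. = FALSE)
    }
    w <- exp(beta * ifelse(is.na(v), 0, v))
    fa <- pool[sample.int(length(pool), 1, prob = w)]

    events[[i]] <- data.frame(
      offspring_id = new_ids[i], mother_id = mo, father_id = fa,
      candidate_ids = paste(pool, collapse = ";"),
      colony = mothers$colony[i], year = years[i], stringsAsFactors = FALSE)

    for (g in names(cfg$mhc_genes)) {
      off_geno[[g]][[new_ids[i]]] <- inherit_pooled(
        population$genotypes[[g]][[mo]], population$genotypes[[g]][[fa]],
        cfg$mhc_genes[[g]]$size_range)
    }
    for (g in names(population$diploid)) {
      pair <- c(sample(population$diploid[[g]][[mo]], 1),
                sample(population$diploid[[g]][[fa]], 1))
      off_dip[[g]][[new_ids[i]]] <- pair
      off_geno[[g]][[new_ids[i]]] <- sort(unique(pair))
    }
  }

  ev <- do.call(rbind, events)
  class(ev) <- c("choice_events", class(ev))

  pop2 <- population
  pop2$individuals <- rbind(
    population$individuals,
    data.frame(id = new_ids, sex = sample(c("F", "M"), n_offspring, replace = TRUE),
               colony = ev$colony, stringsAsFactors = FALSE))
  for (g in names(off_geno)) {
    pop2$genotypes[[g]] <- c(population$genotypes[[g]], off_geno[[g]])
  }
  for (g in names(off_dip)) {
    pop2$diploid[[g]] <- c(population$diploid[[g]], off_dip[[g]])
  }

  structure(list(events = ev, population = pop2, preference = preference),
            class = "choice_simulation")
}

#' Split the semicolon-joined candidate list of one or more events
#' @param events A `choice_events` data frame.
#' @return List of character vectors, one per event.
#' @export
event_candidates <- function(events) {
  strsplit(events$candidate_ids, ";", fixed = TRUE)
}

#' Family trios implied by a set of choice events
#' @param events A `choice_events` data frame.
#' @return Data frame with columns `offspring_id`, `mother_id`, `father_id`.
#' @export
event_trios <- function(events) {
  events[, c("offspring_id", "mother_id", "father_id")]
}
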