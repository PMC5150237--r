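#' Genotype category labels for LD testing
#'
#' Reduces an individual's genotype at one locus to a categorical label: the
#' sorted, comma-joined allele set. Diploid loci yield unordered-pair
#' categories; pooled multi-locus MHC genotypes yield allele-set-profile
#' categories (each distinct set is one category).
#'
#' @param genotypes Named list of allele sets for one locus.
#' @param ids Individual IDs to include (default all).
#' @return Named character vector of category labels.
#' @export
genotype_profile <- function(genotypes, ids = names(genotypes)) {
  vapply(genotypes[ids], set_to_string, character(1))
}

# internal: log hypergeometric-type probability of a contingency table given
# its margins (the statistic of the exact test on tables of arbitrary size)
log_table_prob <- function(counts, rows, cols, n) {
  sum(lgamma(rows + 1)) + sum(lgamma(cols + 1)) -
    lgamma(n + 1) - sum(lgamma(counts + 1))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Tests the independence of genotype categories at two loci over the same
#' individuals. The statistic is the probability of the genotype-by-genotype
#' contingency table under independence given its margins (the natural
#' extension of Fisher's exact test to tables of arbitrary size); the null is
#' generated by permuting the locus-B genotypes across individuals, and the
#' p-value is the (add-one corrected) fraction of permuted tables with a
#' probability smaller than or equal to the observed one.
#'
#' @param genotypes_a,genotypes_b Character vectors of genotype categories
#'   (see [genotype_profile()]) for the same individuals, in the same order.
#' @param n_perm Number of permutations.
#' @param seed Master seed.
#' @return Object of class `ld_test`: `observed_log_prob`, `p_value`,
#'   `n_perm`, `n`, `table_dim`.
#' @export
ld_mc_test <- function(genotypes_a, genotypes_b, n_perm = 100000, seed = NULL) {
  fail_if(length(genotypes_a) != length(genotypes_b),
          "loci genotyped over different individual sets")
  fail_if(n_perm < 1, "n_perm must be >= 1")
  a <- factor(genotypes_a); b <- factor(genotypes_b)
  n <- length(a)
  na <- nlevels(a); nb <- nlevels(b)
  if (na < 2 || nb < 2) {
    warning("fewer than 2 distinct genotypes at one locus; p = 1")
    return(structure(list(observed_log_prob = 0, p_value = 1, n_perm = n_perm,
                          n = n, table_dim = c(na, nb)), class = "ld_test"))
  }
  ia <- as.integer(a); ib <- as.integer(b)
  rows <- tabulate(ia, na); cols <- tabulate(ib, nb)
  cell <- function(jb) tabulate(ia + na * (jb - 1L), na * nb)
  obs <- log_table_prob(cell(ib), rows, cols, n)

  set_substream(seed, "ld_mc_test")
  base <- sum(lgamma(rows + 1)) + sum(lgamma(cols + 1)) - lgamma(n + 1)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    lp <- base - sum(lgamma(cell(ib[sample.int(n)]) + 1))
    if (lp <= obs + 1e-9) hits <- hits + 1L
  }
  structure(list(observed_log_prob = obs,
                 p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, n = n, table_dim = c(na, nb)),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf("LD permutation test: %dx%d table, n = %d, p = %.4g (%d permutations)\n",
              x$table_dim[1], x$table_dim[2], x$n, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise LD screen across loci
#'
#' Runs [ld_mc_test()] for every requested pair of loci over the individuals
#' genotyped at both. No multiplicity correction is applied.
#'
#' @param genotypes Named list (per locus) of named allele-set lists.
#' @param genes Loci to screen (default: all in `genotypes`).
#' @param n_perm Permutations per pair.
#' @param seed Master seed.
#' @return Data frame with columns `locus_a`, `locus_b`, `n`, `p_value`.
#' @export
ld_screen <- function(genotypes, genes = names(genotypes), n_perm = 10000,
                      seed = NULL) {
  if (length(genes) < 2) {
    warning("fewer than 2 loci requested; empty result")
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      n = integer(0), p_value = numeric(0)))
  }
  prs <- utils::combn(genes, 2)
  out <- lapply(seq_len(ncol(prs)), function(k) {
    ga <- genotypes[[prs[1, k]]]; gb <- genotypes[[prs[2, k]]]
    ids <- intersect(names(ga), names(gb))
    r <- ld_mc_test(genotype_profile(ga, ids), genotype_profile(gb, ids),
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else
                      substream_seed(seed, paste0("ld:", prs[1, k], ":", prs[2, k])))
    data.frame(locus_a = prs[1, k], locus_b = prs[2, k], n = r$n,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
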