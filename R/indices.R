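#' MHC dissimilarity and diversity indices
#'
#' Five indices summarise, for a (female, male) couple or for a male alone, the
#' dissimilarity or diversity of pooled multi-locus MHC allele sets:
#'
#' * `MALDis` — male allele dissimilarity: number of alleles present in the
#'   male and absent from the female.
#' * `CALDis` — couple allele dissimilarity: total number of non-shared alleles
#'   in the couple (size of the symmetric difference).
#' * `muAADis` — mean amino-acid distance among the non-shared alleles of the
#'   couple (see `mode`).
#' * `MALDiv` — male allele diversity: number of distinct alleles in the male.
#' * `MAADiv` — male amino-acid diversity: sum of pairwise amino-acid distances
#'   among the male's alleles.
#'
#' `muAADis` is undefined when fewer than two pairable non-shared alleles
#' exist; such values are returned as `NA` and flagged by downstream code.
#'
#' @name mhc-indices
NULL

INDEX_NAMES <- c("MALDis", "CALDis", "muAADis", "MALDiv", "MAADiv")
DISSIMILARITY_INDICES <- c("MALDis", "CALDis", "muAADis")
DIVERSITY_INDICES <- c("MALDiv", "MAADiv")

#' @rdname mhc-indices
#' @param female,male Character vectors of allele IDs (pooled genotype sets).
#' @return `maldis`, `caldis`, `maldiv` return a non-negative integer;
#'   `mu_aadis` and `maadiv` a non-negative real (`mu_aadis` may be `NA`).
#' @export
maldis <- function(female, male) {
  fail_if(length(female) == 0 || length(male) == 0, "empty genotype set")
  length(setdiff(male, female))
}

#' @rdname mhc-indices
#' @export
caldis <- function(female, male) {
  fail_if(length(female) == 0 || length(male) == 0, "empty genotype set")
  length(setdiff(male, female)) + length(setdiff(female, male))
}

#' @rdname mhc-indices
#' @param D An [aa_distance_matrix()] covering all alleles involved.
#' @param mode For `mu_aadis`: `"within_symdiff"` (default) averages distances
#'   over all unordered pairs within the symmetric difference of the two sets;
#'   `"cross"` averages over female-only x male-only pairs.
#' @export
mu_aadis <- function(female, male, D, mode = c("within_symdiff", "cross")) {
  mode <- match.arg(mode)
  fo <- setdiff(female, male)
  mo <- setdiff(male, female)
  all_ids <- c(fo, mo)
  missing <- setdiff(all_ids, rownames(D))
  fail_if(length(missing) > 0, "allele(s) not in distance matrix: %s",
          paste(missing, collapse = ", "))
  if (mode == "within_symdiff") {
    s <- all_ids
    if (length(s) < 2) return(NA_real_)
    sub <- D[s, s, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else {
    if (length(fo) == 0 || length(mo) == 0) return(NA_real_)
    mean(D[fo, mo, drop = FALSE])
  }
}

#' @rdname mhc-indices
#' @export
maldiv <- function(male) {
  fail_if(length(male) == 0, "empty genotype set")
  length(unique(male))
}

#' @rdname mhc-indices
#' @export
maadiv <- function(male, D) {
  male <- unique(male)
  missing <- setdiff(male, rownames(D))
  fail_if(length(missing) > 0, "allele(s) not in distance matrix: %s",
          paste(missing, collapse = ", "))
  if (length(male) < 2) return(0)
  sub <- D[male, male, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

#' Compute one index for a (female, male) pair
#'
#' Dispatches on the index name; diversity indices ignore the female set.
#'
#' @param index One of `"MALDis"`, `"CALDis"`, `"muAADis"`, `"MALDiv"`, `"MAADiv"`.
#' @param male Male allele set (character vector).
#' @param female Female allele set; required for dissimilarity indices.
#' @param D Amino-acid distance matrix; required for `muAADis` and `MAADiv`.
#' @param mode Passed to [mu_aadis()].
#' @return A numeric scalar (possibly `NA` for undefined `muAADis`).
#' @export
mhc_index <- function(index, male, female = NULL, D = NULL,
                      mode = "within_symdiff") {
  index <- match.arg(index, INDEX_NAMES)
  if (index %in% DISSIMILARITY_INDICES) {
    fail_if(is.null(female), "index %s requires the female genotype", index)
  }
  switch(index,
    MALDis = maldis(female, male),
    CALDis = caldis(female, male),
    muAADis = mu_aadis(female, male, D, mode = mode),
    MALDiv = maldiv(male),
    MAADiv = maadiv(male, D)
  )
}

#' Does an index depend on the female genotype?
#' @param index Index name.
#' @return Logical.
#' @export
index_is_dissimilarity <- function(index) {
  match.arg(index, INDEX_NAMES) %in% DISSIMILARITY_INDICES
}

#' Per-pair index table
#'
#' Computes one index for every row of a (female, male) pair list, using a
#' genotype list as produced by [generate_population()] or [read_genotypes()].
#'
#' @param pairs Data frame with columns `female_id`, `male_id`.
#' @param genotypes Named list mapping individual ID to allele-set character
#'   vectors for one gene.
#' @param index Index name.
#' @param D Distance matrix (needed for amino-acid indices).
#' @param mode Passed to [mu_aadis()].
#' @return `pairs` with an added numeric column `value`.
#' @export
pair_index_table <- function(pairs, genotypes, index, D = NULL,
                             mode = "within_symdiff") {
  index <- match.arg(index, INDEX_NAMES)
  vals <- vapply(seq_len(nrow(pairs)), function(i) {
    m <- genotypes[[pairs$male_id[i]]]
    f <- if (index_is_dissimilarity(index)) genotypes[[pairs$female_id[i]]] else NULL
    mhc_index(index, male = m, female = f, D = D, mode = mode)
  }, numeric(1))
  pairs$value <- vals
  pairs
}
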