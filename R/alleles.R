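#' Generate a synthetic allele catalog for one gene
#'
#' Creates `n_alleles` distinct in-frame coding DNA sequences by mutating a
#' random ancestral sequence, so that pairwise amino-acid distances have a
#' realistic spread. Sequences contain no internal stop codon and translate to
#' `aa_length` residues.
#'
#' @param gene Gene label, e.g. `"MHC1"`, `"MHC2"`, `"TAAR3"`.
#' @param n_alleles Number of distinct alleles to generate (>= 1).
#' @param aa_length Amino-acid length of the amplified fragment (>= 1).
#' @param seed Master seed; the catalog is byte-identical for a fixed seed.
#' @param mutations_per_allele Mean number of nucleotide substitutions
#'   separating each allele from the ancestral sequence.
#' @return A data frame of class `allele_catalog` with columns `allele_id`,
#'   `gene`, `dna`, `aa`.
#' @examples
#' cat1 <- generate_allele_catalog("MHC1", 50, 60, seed = 1)
#' nrow(cat1)  # 50
#' @export
generate_allele_catalog <- function(gene, n_alleles, aa_length, seed = NULL,
                                    mutations_per_allele = 8) {
  fail_if(n_alleles < 1, "n_alleles must be >= 1")
  fail_if(aa_length < 1, "aa_length must be >= 1")
  fail_if(n_alleles > 4^(3 * min(aa_length, 20)),
          "cannot generate %d distinct alleles of %d codons", n_alleles, aa_length)
  set_substream(seed, paste0("catalog:", gene))

  L <- 3L * aa_length
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")

  has_internal_stop <- function(nt) {
    codons <- substring(nt, seq(1L, L - 2L, by = 3L), seq(3L, L, by = 3L))
    any(codons[-length(codons)] %in% stops) || codons[length(codons)] %in% stops
  }
  random_seq <- function() {
    repeat {
      nt <- paste(sample(bases, L, replace = TRUE), collapse = "")
      if (!has_internal_stop(nt)) return(nt)
    }
  }
  ancestor <- random_seq()

  mutate <- function(nt) {
    k <- max(1L, stats::rpois(1, mutations_per_allele))
    v <- strsplit(nt, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, min(k, L))
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    paste(v, collapse = "")
  }

  seqs <- character(0)
  guard <- 0L
  while (length(seqs) < n_alleles) {
    cand <- mutate(ancestor)
    if (!has_internal_stop(cand) && !(cand %in% seqs)) {
      seqs <- c(seqs, cand)
    }
    guard <- guard + 1L
    fail_if(guard > 1000L * n_alleles,
            "failed to generate %d distinct stop-free alleles", n_alleles)
  }

  out <- data.frame(
    allele_id = sprintf("%s-%02d", gene, seq_len(n_alleles)),
    gene = gene,
    dna = seqs,
    aa = translate_dna(seqs),
    stringsAsFactors = FALSE
  )
  class(out) <- c("allele_catalog", class(out))
  out
}

#' Translate in-frame coding DNA to amino acids
#'
#' @param dna Character vector of nucleotide sequences with length divisible by 3.
#' @return Character vector of amino-acid sequences (stop codon = `*`).
#' @export
translate_dna <- function(dna) {
  fail_if(any(nchar(dna) %% 3 != 0), "sequence length not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                     if.fuzzy.codon = "X"))
}

#' Pairwise amino-acid distance matrix for an allele catalog
#'
#' The distance between two alleles is the Hamming distance between their
#' translations (number of differing residues). All translations must have
#' equal length; no alignment is attempted.
#'
#' @param catalog An `allele_catalog` data frame (columns `allele_id`, `aa`).
#' @return A symmetric integer matrix with zero diagonal, dimnames set to
#'   allele IDs, and attribute `gene`.
#' @export
aa_distance_matrix <- function(catalog) {
  fail_if(!all(c("allele_id", "aa") %in% names(catalog)),
          "catalog must have columns allele_id and aa")
  aa <- catalog$aa
  fail_if(length(unique(nchar(aa))) > 1,
          "translations have unequal lengths; distances are positional only")
  n <- length(aa)
  chars <- do.call(rbind, strsplit(aa, "", fixed = TRUE))
  d <- matrix(0L, n, n, dimnames = list(catalog$allele_id, catalog$allele_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
      }
    }
  }
  attr(d, "gene") <- if ("gene" %in% names(catalog)) catalog$gene[1] else NA_character_
  attr(d, "aa_length") <- nchar(aa[1])
  class(d) <- c("aa_dist", class(d))
  d
}

#' Write an allele catalog as FASTA
#'
#' One record per allele, identifier = allele ID.
#' @param catalog An `allele_catalog`.
#' @param path Output file path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  ss <- Biostrings::DNAStringSet(catalog$dna)
  names(ss) <- catalog$allele_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an allele catalog from FASTA
#'
#' @param path FASTA file with one record per allele; identifiers of the form
#'   `GENE-k` (the gene is taken as the part before the last `-`).
#' @param translate Translate sequences (requires in-frame coding DNA).
#' @return An `allele_catalog` data frame.
#' @export
read_catalog_fasta <- function(path, translate = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- data.frame(
    allele_id = ids,
    gene = sub("-[^-]*$", "", ids),
    dna = as.character(ss),
    aa = NA_character_,
    stringsAsFactors = FALSE
  )
  if (translate) out$aa <- translate_dna(out$dna)
  class(out) <- c("allele_catalog", class(out))
  out
}
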