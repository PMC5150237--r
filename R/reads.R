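# internal: run expr with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Deterministic primer pair for a gene
#'
#' Generates a fixed 20-nt forward/reverse primer pair from the gene name
#' alone, so that read simulation and demultiplexing agree without shared
#' state.
#' @param gene Gene name.
#' @return List with elements `fwd` and `rev`.
#' @export
gene_primers <- function(gene) {
  with_local_seed(substream_seed(20L, paste0("primer:", gene)), {
    bases <- c("A", "C", "G", "T")
    list(fwd = paste(sample(bases, 20, replace = TRUE), collapse = ""),
         rev = paste(sample(bases, 20, replace = TRUE), collapse = ""))
  })
}

#' Deterministic barcode map for a set of individuals
#'
#' Assigns a unique 8-nt barcode to every individual (deterministic in the
#' individual list).
#' @param ids Individual IDs.
#' @return Data frame `individual_id`, `barcode`.
#' @export
barcode_map <- function(ids) {
  with_local_seed(substream_seed(8L, "barcodes"), {
    bases <- c("A", "C", "G", "T")
    bc <- character(0)
    while (length(bc) < length(ids)) {
      cand <- paste(sample(bases, 8, replace = TRUE), collapse = "")
      if (!(cand %in% bc)) bc <- c(bc, cand)
    }
    data.frame(individual_id = ids, barcode = bc, stringsAsFactors = FALSE)
  })
}

# internal: apply iid substitution errors to a character vector of sequences
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(v)) < error_rate)
    for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon reads for one gene
#'
#' Each individual contributes `depth` reads drawn uniformly from its true
#' alleles. A read is chimeric with probability `chimera_rate` (when the
#' individual carries at least two alleles): its insert splices a prefix of
#' one allele to the suffix of another at a uniform breakpoint. Substitution
#' errors are i.i.d. per base over the whole read (barcode, primers and
#' insert). Reads are `barcode + forward primer + insert + reverse primer`.
#'
#' @param population A `population` (provides genotypes and catalogs).
#' @param gene Gene to amplify (must have a sequence catalog).
#' @param depth Reads per individual.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param chimera_rate Fraction of reads formed from two parent templates.
#' @param seed Master seed.
#' @param individuals IDs to sequence (default: all with a genotype).
#' @return Object of class `read_set`: `reads` (data frame `read_id`,
#'   `individual_id`, `gene`, `sequence`, `true_allele`, `is_chimera`),
#'   `barcodes`, `primers`, `gene`, `insert_length`, `error_rate`,
#'   `chimera_rate`.
#' @export
simulate_reads <- function(population, gene, depth = 300, error_rate = 0.005,
                           chimera_rate = 0, seed = NULL, individuals = NULL) {
  fail_if(depth < 1, "depth must be >= 1")
  fail_if(error_rate < 0 || error_rate >= 1, "error_rate must be in [0, 1)")
  fail_if(chimera_rate < 0 || chimera_rate >= 1, "chimera_rate must be in [0, 1)")
  geno <- population$genotypes[[gene]]
  fail_if(is.null(geno), "gene %s absent from genotypes", gene)
  catalog <- population$catalogs[[gene]]
  fail_if(is.null(catalog), "gene %s has no sequence catalog", gene)
  if (is.null(individuals)) individuals <- names(geno)
  seqs <- stats::setNames(catalog$dna, catalog$allele_id)
  L <- nchar(seqs[[1]])

  set_substream(seed, paste0("simulate_reads:", gene))
  bcs <- barcode_map(individuals)
  prm <- gene_primers(gene)

  out <- vector("list", length(individuals))
  for (k in seq_along(individuals)) {
    id <- individuals[k]
    alleles <- geno[[id]]
    pick <- sample(alleles, depth, replace = TRUE)
    chim <- stats::runif(depth) < chimera_rate & length(alleles) >= 2
    ins <- unname(seqs[pick])
    if (any(chim)) {
      for (r in which(chim)) {
        ab <- sample(alleles, 2)
        bp <- sample.int(L - 1L, 1)
        ins[r] <- paste0(substr(seqs[[ab[1]]], 1, bp),
                         substr(seqs[[ab[2]]], bp + 1, L))
        pick[r] <- NA_character_
      }
    }
    full <- paste0(bcs$barcode[k], prm$fwd, ins, prm$rev)
    full <- apply_substitutions(full, error_rate)
    out[[k]] <- data.frame(
      read_id = sprintf("%s_%s_%04d", id, gene, seq_len(depth)),
      individual_id = id, gene = gene, sequence = full,
      true_allele = pick, is_chimera = chim, stringsAsFactors = FALSE)
  }
  structure(list(reads = do.call(rbind, out), barcodes = bcs, primers = prm,
                 gene = gene, insert_length = L, error_rate = error_rate,
                 chimera_rate = chimera_rate),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set: %d reads, %s, %d individuals (error %.4g, chimera %.4g)\n",
              nrow(x$reads), x$gene, length(unique(x$reads$individual_id)),
              x$error_rate, x$chimera_rate))
  invisible(x)
}
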