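# Shared fixtures: tiny catalogs, genotypes and populations built in code.

# a minimal hand-made catalog with known translations
tiny_catalog <- function(gene = "MHC1", aa = c("ACDEF", "ACDEY", "ACDKY", "WCDKY")) {
  # reverse-translate with fixed codons so distances are exactly the AA Hamming
  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             K = "AAA", Y = "TAT", W = "TGG")
  dna <- vapply(aa, function(s) {
    paste(codon[strsplit(s, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(allele_id = sprintf("%s-%02d", gene, seq_along(aa)),
                    gene = gene, dna = dna, aa = aa, stringsAsFactors = FALSE)
  class(out) <- c("allele_catalog", class(out))
  out
}

# naive index oracles: explicit loops over sets and pairs, independent of the
# package's implementations
oracle_maldis <- function(f, m) {
  n <- 0L
  for (a in m) if (!(a %in% f)) n <- n + 1L
  n
}
oracle_caldis <- function(f, m) {
  oracle_maldis(f, m) + oracle_maldis(m, f)
}
oracle_maldiv <- function(m) {
  seen <- character(0)
  for (a in m) if (!(a %in% seen)) seen <- c(seen, a)
  length(seen)
}
oracle_maadiv <- function(m, D) {
  m <- unique(m); s <- 0
  if (length(m) < 2) return(0)
  for (i in seq_len(length(m) - 1)) {
    for (j in seq(i + 1, length(m))) s <- s + D[m[i], m[j]]
  }
  s
}
oracle_mu_aadis <- function(f, m, D, mode = "within_symdiff") {
  fo <- f[!(f %in% m)]; mo <- m[!(m %in% f)]
  if (mode == "within_symdiff") {
    s <- c(fo, mo)
    if (length(s) < 2) return(NA_real_)
    tot <- 0; np <- 0L
    for (i in seq_len(length(s) - 1)) {
      for (j in seq(i + 1, length(s))) { tot <- tot + D[s[i], s[j]]; np <- np + 1L }
    }
    tot / np
  } else {
    if (length(fo) == 0 || length(mo) == 0) return(NA_real_)
    tot <- 0; np <- 0L
    for (a in fo) for (b in mo) { tot <- tot + D[a, b]; np <- np + 1L }
    tot / np
  }
}

# random genotype set at paper-matched sizes
random_set <- function(ids, size_range) {
  sort(sample(ids, sample(seq(size_range[1], size_range[2]), 1)))
}

# a small fast population for GLMM / randomization tests
small_population <- function(seed = 1, ...) {
  generate_population(population_config(
    n_colonies = 6, males_per_colony = 22, n_females = 80, ...), seed = seed)
}

# hand-built choice events over explicit pools
manual_events <- function(mothers, fathers, pools, colony = "C01", year = 2000) {
  ev <- data.frame(
    offspring_id = sprintf("O%03d", seq_along(mothers)),
    mother_id = mothers, father_id = fathers,
    candidate_ids = vapply(pools, paste, character(1), collapse = ";"),
    colony = colony, year = year, stringsAsFactors = FALSE)
  class(ev) <- c("choice_events", class(ev))
  ev
}
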