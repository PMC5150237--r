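# a minimal population carrying the hand-made catalog, for read simulation
reads_fixture <- function(genos, gene = "MHC1",
                          aa = c("ACDEF", "ACDEY", "ACDKY", "WCDKY")) {
  cat <- tiny_catalog(gene, aa)
  list(genotypes = stats::setNames(list(genos), gene),
       catalogs = stats::setNames(list(cat), gene),
       individuals = data.frame(id = names(genos)))
}

test_that("noiseless reads demultiplex to the exact catalog inserts", {
  genos <- list(I1 = c("MHC1-01", "MHC1-02"), I2 = "MHC1-03",
                I3 = c("MHC1-02", "MHC1-04"))
  pop <- reads_fixture(genos)
  rs <- simulate_reads(pop, "MHC1", depth = 30, error_rate = 0, seed = 1)
  expect_equal(nrow(rs$reads), 90)
  dm <- demultiplex_and_trim(rs)
  lg <- attr(dm, "log")
  expect_equal(unname(lg["retained"]), 90)
  expect_equal(unname(lg["barcode_mismatch"] + lg["primer_mismatch"]), 0)
  seqs <- stats::setNames(pop$catalogs$MHC1$dna, pop$catalogs$MHC1$allele_id)
  for (id in names(genos)) {
    expect_setequal(unique(dm$insert[dm$individual_id == id]),
                    unname(seqs[genos[[id]]]))
  }

  # a corrupted barcode and a corrupted primer are discarded, not misassigned
  bad <- rs
  substr(bad$reads$sequence[1], 1, 1) <-
    setdiff(c("A", "C", "G", "T"), substr(bad$reads$sequence[1], 1, 1))[1]
  p2 <- 9 + 3   # inside the forward primer (8-mer barcode + position 4)
  substr(bad$reads$sequence[2], p2, p2) <-
    setdiff(c("A", "C", "G", "T"), substr(bad$reads$sequence[2], p2, p2))[1]
  dm2 <- demultiplex_and_trim(bad)
  lg2 <- attr(dm2, "log")
  expect_equal(unname(lg2["retained"]), 88)
  expect_equal(unname(lg2["barcode_mismatch"]), 1)
  expect_equal(unname(lg2["primer_mismatch"]), 1)
})

test_that("the chimera filter flags spliced reads and spares point errors", {
  A <- strrep("A", 12); B <- strrep("C", 12)
  chim <- paste0(strrep("A", 6), strrep("C", 6))
  err <- paste0("T", strrep("A", 11))
  inserts <- c(rep(A, 20), rep(B, 20), chim, err)
  fl <- flag_chimeras(inserts)
  expect_identical(unname(fl[inserts == chim]), TRUE)
  expect_identical(unname(fl[inserts == err]), FALSE)
  expect_false(any(fl[inserts %in% c(A, B)]))
  expect_equal(unname(attr(fl, "log")["flagged"]), 1)

  # below the abundance skew, the parents are not eligible and nothing is flagged
  fl2 <- flag_chimeras(c(rep(A, 3), rep(B, 3), rep(chim, 2)), skew = 2)
  expect_false(any(fl2))
  expect_error(flag_chimeras(c("AA", "AAA")), "equal length")
})

test_that("chimeric reads are removed from simulated data", {
  genos <- list(I1 = c("MHC1-01", "MHC1-04"), I2 = c("MHC1-01", "MHC1-04"))
  pop <- reads_fixture(genos)
  rs <- simulate_reads(pop, "MHC1", depth = 100, error_rate = 0,
                       chimera_rate = 0.05, seed = 2)
  expect_gt(sum(rs$reads$is_chimera), 0)
  dm <- demultiplex_and_trim(rs)
  fc <- filter_chimeras(dm)
  true_seqs <- pop$catalogs$MHC1$dna[c(1, 4)]
  # every distinguishable chimera is flagged, no true read is lost
  expect_true(all(fc$retained$insert %in% true_seqs))
  expect_false(any(fc$flagged$insert %in% true_seqs))
})

test_that("the homology filter translates and screens as documented", {
  dm <- data.frame(
    individual_id = "I1",
    insert = c("ATGAAATTT",   # MKF: identity 1
               "ATGAAAGGG",   # MKG: identity 2/3
               "ATGTAATTT",   # M*F: stop codon
               "CCCGGGAAA"),  # PGK: identity 0
    stringsAsFactors = FALSE)
  class(dm) <- c("demux_reads", class(dm))
  out <- homology_filter(dm, reference_aa = "MKF", min_identity = 2 / 3)
  expect_identical(out$aa, c("MKF", "MKG"))     # boundary identity is kept
  lg <- attr(out, "log")
  expect_equal(unname(lg["stop_codon"]), 1)
  expect_equal(unname(lg["below_identity"]), 1)
  out2 <- homology_filter(dm, reference_aa = "MKF", min_identity = 0.9)
  expect_identical(out2$aa, "MKF")
})

test_that("entropy-based calling recovers known genotypes from clean reads", {
  genos <- list(I1 = c("MHC1-01", "MHC1-02"), I2 = c("MHC1-02", "MHC1-03"),
                I3 = c("MHC1-01", "MHC1-03"), I4 = c("MHC1-01", "MHC1-04"),
                I5 = c("MHC1-02", "MHC1-04"))
  pop <- reads_fixture(genos)
  rs <- simulate_reads(pop, "MHC1", depth = 60, error_rate = 0, seed = 3)
  dm <- demultiplex_and_trim(rs)
  calls <- call_alleles(dm, gene = "X", min_reads_per_allele = 5)

  # entropy positions are exactly the polymorphic catalog columns
  dna <- pop$catalogs$MHC1$dna
  poly <- which(vapply(seq_len(nchar(dna[1])), function(j)
    length(unique(substr(dna, j, j))) > 1, logical(1)))
  expect_identical(calls$entropy_positions, poly - 1L)

  # map called IDs back to true alleles via the representative sequences
  map <- stats::setNames(
    pop$catalogs$MHC1$allele_id[match(calls$calls$representative_sequence, dna)],
    calls$calls$allele_id)
  expect_false(any(is.na(map)))
  for (id in names(genos)) {
    expect_setequal(unname(map[calls$genotypes[[id]]]), genos[[id]])
  }
})

test_that("read-support and rarity filters apply per individual and per allele", {
  dm <- data.frame(
    individual_id = rep(c("I1", "I2", "I3"), times = c(60, 32, 40)),
    insert = c(rep("AAAA", 30), rep("CCCC", 30),   # I1: both well supported
               rep("AAAA", 30), rep("CCCC", 2),    # I2: C below min_reads
               rep("CCCC", 40)),                   # I3: C only
    stringsAsFactors = FALSE)
  class(dm) <- c("demux_reads", class(dm))
  calls <- call_alleles(dm, gene = "G")
  # total abundance: CCCC (72 reads) outranks AAAA (60) => G-01 = CCCC
  expect_identical(calls$calls$oligotype, c("CCCC", "AAAA"))
  expect_identical(calls$genotypes$I1, c("G-01", "G-02"))
  expect_identical(calls$genotypes$I2, "G-02")
  expect_identical(calls$genotypes$I3, "G-01")

  # alleles carried by a single individual are deleted as unconfirmable:
  # replacing I3's reads makes GGGG a singleton, and CCCC loses its second
  # carrier (I2 is already below the read-support threshold), so both go
  dm2 <- dm
  dm2$insert[dm2$individual_id == "I3"] <- "GGGG"
  calls2 <- call_alleles(dm2, gene = "G")
  expect_equal(unname(calls2$log["alleles_deleted_rare"]), 2)
  expect_equal(unname(calls2$log["individuals_dropped"]), 1)
  expect_null(calls2$genotypes$I3)
  expect_identical(calls2$calls$oligotype, "AAAA")
  expect_identical(calls2$genotypes$I1, "G-01")

  # requiring two alleles per individual drops hemizygous-looking calls
  calls3 <- call_alleles(dm, gene = "G", min_alleles_per_individual = 2,
                         min_individuals_per_allele = 1)
  expect_identical(names(calls3$genotypes), "I1")

  # a monomorphic gene yields one allele for everyone
  dm4 <- dm
  dm4$insert <- "TTTT"
  calls4 <- call_alleles(dm4, gene = "G")
  expect_identical(unique(unlist(calls4$genotypes)), "G-01")
  expect_length(calls4$entropy_positions, 0)
})

test_that("Mendelian checks flag exactly the fabricated violations", {
  geno <- list(M = c("a", "b"), F = c("c", "d"), O1 = c("a", "c"),
               O2 = c("a", "e"), O3 = c("b"))
  trios <- data.frame(offspring_id = c("O1", "O2", "O3", "O4"),
                      mother_id = "M", father_id = "F",
                      stringsAsFactors = FALSE)
  chk <- mendelian_check(geno, trios)
  expect_identical(chk$violations$offspring_id, "O2")
  expect_identical(chk$violations$offending_alleles, "e")
  expect_equal(chk$skipped, 1)
  fixed <- mendelian_check(geno, trios, correct = TRUE)
  expect_identical(fixed$genotypes$O2, "a")
  expect_identical(fixed$genotypes$O1, c("a", "c"))
})

test_that("repeatability scores replicate pairs as documented", {
  geno <- list(A1 = c("x", "y"), A2 = c("x", "y"),
               B1 = c("x", "y", "z"), B2 = c("x", "y"),
               C1 = c("x"), C2 = character(0))
  pairs <- data.frame(id_a = c("A1", "B1", "C1"), id_b = c("A2", "B2", "C2"),
                      stringsAsFactors = FALSE)
  r <- repeatability(geno, pairs)
  expect_equal(r$mean, mean(c(1, 2 / 3)))
  expect_equal(r$excluded, 1)
  re <- repeatability(geno, pairs, method = "exact")
  expect_equal(re$mean, 0.5)
  expect_error(repeatability(geno, pairs[0, ]), "at least one")
})
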