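test_that("configuration is validated", {
  expect_error(population_config(males_per_colony = 10), "smaller than maximum")
  expect_error(population_config(taar_genes = list(TAAR2 = c(0.5, 0.4))),
               "sum to 1")
  f <- geometric_freqs(9)
  expect_equal(sum(f), 1)
  expect_true(all(diff(f) < 0))
})

test_that("generated populations respect the configuration", {
  pop <- small_population(seed = 3)
  ind <- pop$individuals
  expect_false(any(duplicated(ind$id)))
  expect_equal(sum(ind$sex == "M"), 6 * 22)
  expect_equal(sum(ind$sex == "F"), 80)

  cfg <- pop$config
  for (g in names(cfg$mhc_genes)) {
    sz <- lengths(pop$genotypes[[g]])
    rng <- cfg$mhc_genes[[g]]$size_range
    expect_true(all(sz >= rng[1] & sz <= rng[2]))
    expect_true(all(unlist(pop$genotypes[[g]]) %in% pop$catalogs[[g]]$allele_id))
    # allele sets are sorted and duplicate-free
    expect_true(all(vapply(pop$genotypes[[g]], function(s)
      identical(s, sort(unique(s))), logical(1))))
  }
  for (g in c("TAAR2", "TAAR3", "TAAR8")) {
    expect_true(all(lengths(pop$diploid[[g]]) == 2))
  }

  # rosters: candidate males of the right colony, sizes within bounds
  for (key in names(pop$rosters)) {
    co <- sub(":.*", "", key)
    r <- pop$rosters[[key]]
    expect_true(all(r %in% ind$id[ind$sex == "M" & ind$colony == co]))
    expect_gte(length(r), cfg$pool_size$min)
    expect_lte(length(r), cfg$pool_size$max)
  }

  expect_identical(pop$genotypes, small_population(seed = 3)$genotypes)
})

test_that("roster sizes follow the bimodal mixture moments", {
  ps <- population_config()$pool_size
  set.seed(1)
  x <- mhcmate:::rpool_size(40000, ps)
  expect_true(all(x >= 2 & x <= 21))
  expect_true(all(x <= 4 | x >= 19))        # bimodal: no mid-sized pools
  expect_equal(mean(x), 9.6, tolerance = 0.02)
  expect_equal(sd(x), 8.3, tolerance = 0.02)
})

test_that("full linkage makes comonotone TAAR haplotypes", {
  f <- c(0.5, 0.3, 0.2)
  pop <- generate_population(population_config(
    n_colonies = 2, n_females = 10,
    taar_genes = list(TAAR2 = f, TAAR3 = f, TAAR8 = f),
    taar_linkage = 1), seed = 4)
  # identical frequency vectors + comonotone draws => identical allele indices
  idx <- function(g) vapply(pop$diploid[[g]], function(p)
    paste(sort(as.integer(sub(".*-", "", p))), collapse = "/"), character(1))
  expect_identical(unname(idx("TAAR2")), unname(idx("TAAR3")))
  expect_identical(unname(idx("TAAR2")), unname(idx("TAAR8")))
})

test_that("microsatellite pooling joins locus-prefixed alleles", {
  pop <- small_population(seed = 5)
  pooled <- pooled_msat_genotypes(pop)
  id <- pop$individuals$id[1]
  manual <- sort(unique(unlist(lapply(sprintf("MS%d", 1:8), function(g)
    pop$genotypes[[g]][[id]]))))
  expect_identical(pooled[[id]], manual)
  expect_true(all(grepl("^MS[0-9]+-", pooled[[id]])))
})

test_that("genotype masking keeps protected IDs", {
  pop <- small_population(seed = 6)
  g <- pop$genotypes$MHC1
  keep <- names(g)[1:5]
  m <- mask_genotypes(g, prob = 0.3, keep = keep, seed = 9)
  expect_true(all(keep %in% names(m)))
  expect_lt(length(m), length(g))
  expect_identical(m, mask_genotypes(g, prob = 0.3, keep = keep, seed = 9))
})
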