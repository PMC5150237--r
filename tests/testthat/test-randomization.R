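# independent brute-force oracle: enumerate every assignment of one male per
# offspring with expand.grid and average the defined index values
oracle_randomization <- function(events, genotypes, index, D = NULL,
                                 mode = "within_symdiff") {
  cands <- event_candidates(events)
  vals <- list(); obs <- numeric(0)
  for (i in seq_len(nrow(events))) {
    pool <- cands[[i]]
    v <- vapply(pool, function(m) {
      mhc_index(index, male = genotypes[[m]],
                female = if (index_is_dissimilarity(index))
                  genotypes[[events$mother_id[i]]] else NULL,
                D = D, mode = mode)
    }, numeric(1))
    vals[[i]] <- unname(v)
    obs <- c(obs, v[match(events$father_id[i], pool)])
  }
  grid <- do.call(expand.grid, lapply(vals, seq_along))
  means <- apply(grid, 1, function(row) {
    x <- mapply(function(v, j) v[j], vals, row)
    mean(x, na.rm = TRUE)
  })
  ctr <- mean(means)
  obs_mean <- mean(obs)
  list(observed_mean = obs_mean, center = ctr,
       p = mean(abs(means - ctr) >= abs(obs_mean - ctr) - 1e-9))
}

rand_fixture <- local({
  cat <- tiny_catalog(aa = c("ACDEF", "ACDEY", "ACDKY", "WCDKY", "WCDEF"))
  geno <- list(
    F01 = c("MHC1-01", "MHC1-02"), F02 = c("MHC1-02", "MHC1-03"),
    M01 = c("MHC1-01", "MHC1-04"), M02 = c("MHC1-03", "MHC1-05"),
    M03 = c("MHC1-02", "MHC1-04", "MHC1-05"), M04 = c("MHC1-01", "MHC1-02"),
    M05 = c("MHC1-04", "MHC1-05"))
  ev <- manual_events(
    mothers = c("F01", "F02", "F01"),
    fathers = c("M02", "M03", "M05"),
    pools = list(c("M01", "M02", "M03"), c("M02", "M03", "M04"),
                 c("M01", "M04", "M05")))
  list(cat = cat, geno = geno, ev = ev, D = aa_distance_matrix(cat))
})

test_that("observed means match hand computation", {
  fx <- rand_fixture
  # MALDis of the three couples: F01/M02 -> both of M02's alleles unshared (2);
  # F02/M03 -> M03 shares only MHC1-02 (2 unshared); F01/M05 -> 2 unshared
  expect_equal(observed_index_mean(fx$ev, fx$geno, "MALDis"), mean(c(2, 2, 2)))
  expect_equal(observed_index_mean(fx$ev, fx$geno, "MALDiv"), mean(c(2, 3, 2)))
})

test_that("the MC test converges to the exact enumeration", {
  fx <- rand_fixture
  for (ix in c("MALDis", "CALDis", "MALDiv")) {
    orc <- oracle_randomization(fx$ev, fx$geno, ix)
    ex <- exact_enumeration_test(fx$ev, fx$geno, ix)
    expect_equal(ex$observed_mean, orc$observed_mean)
    expect_equal(ex$center, orc$center)
    expect_equal(ex$p_two_tailed, orc$p)
    expect_equal(sum(ex$support$prob), 1)

    mc <- mc_randomization_test(fx$ev, fx$geno, ix, B = 20000, seed = 2)
    expect_equal(mc$observed_mean, ex$observed_mean)
    expect_lt(abs(mc$p_two_tailed - ex$p_two_tailed), 0.02)
    expect_lt(abs(mean(mc$simulated_means) - ex$center), 0.02)
  }
})

test_that("undefined values are excluded from replicate means identically", {
  fx <- rand_fixture
  # muAADis is undefined for fully shared genotypes (F01 vs M04)
  orc <- oracle_randomization(fx$ev, fx$geno, "muAADis", D = fx$D)
  ex <- exact_enumeration_test(fx$ev, fx$geno, "muAADis", D = fx$D)
  expect_equal(ex$p_two_tailed, orc$p)
  expect_equal(ex$center, orc$center)
  mc <- mc_randomization_test(fx$ev, fx$geno, "muAADis", D = fx$D,
                              B = 20000, seed = 3)
  expect_lt(abs(mc$p_two_tailed - ex$p_two_tailed), 0.02)
})

test_that("inclusion rules drop events cleanly", {
  fx <- rand_fixture
  geno <- fx$geno
  geno$M05 <- NULL              # father of event 3 ungenotyped
  mc <- mc_randomization_test(fx$ev, geno, "MALDis", B = 100, seed = 1)
  expect_equal(mc$n_couples, 2)
  expect_equal(unname(mc$dropped["no_father"]), 1)
  geno$F02 <- NULL              # mother of event 2: needed for dissimilarity only
  mc2 <- mc_randomization_test(fx$ev, geno, "MALDis", B = 100, seed = 1)
  expect_equal(mc2$n_couples, 1)
  mc3 <- mc_randomization_test(fx$ev, geno, "MALDiv", B = 100, seed = 1)
  expect_equal(mc3$n_couples, 2)
  expect_error(mc_randomization_test(fx$ev, list(), "MALDis", B = 10),
               "no events")
})

test_that("seeds make simulated means reproducible and options work", {
  fx <- rand_fixture
  a <- mc_randomization_test(fx$ev, fx$geno, "MALDis", B = 500, seed = 11)
  b <- mc_randomization_test(fx$ev, fx$geno, "MALDis", B = 500, seed = 11)
  expect_identical(a$simulated_means, b$simulated_means)
  cm <- mc_randomization_test(fx$ev, fx$geno, "MALDis", B = 500, seed = 11,
                              center = "median")
  expect_equal(cm$center, median(a$simulated_means))
  pp <- mc_randomization_test(fx$ev, fx$geno, "MALDis", B = 500, seed = 11,
                              p_correction = "proportion")
  expect_equal(pp$p_two_tailed * 500,
               a$p_two_tailed * 501 - 1)
  expect_error(exact_enumeration_test(fx$ev, fx$geno, "MALDis",
                                      max_assignments = 10), "enumeration bound")
})
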