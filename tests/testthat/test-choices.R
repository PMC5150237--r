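test_that("preference specifications are validated", {
  expect_error(preference_spec(beta = c(0.5, 0)), "named")
  expect_error(preference_spec(beta = c(het = 0.5, hom = 0)), "taar_gene")
  p <- preference_spec("muAADis", beta = 0.3, gene = "MHC2", mode = "cross")
  expect_s3_class(p, "preference_spec")
  expect_error(preference_spec("NOPE"))
})

test_that("simulated events are structurally consistent and reproducible", {
  pop <- small_population(seed = 21)
  sim <- simulate_choices(pop, preference_spec("MALDis", beta = 0),
                          n_offspring = 60, seed = 7)
  ev <- sim$events
  expect_equal(nrow(ev), 60)
  cands <- event_candidates(ev)
  for (i in seq_len(nrow(ev))) {
    expect_true(ev$father_id[i] %in% cands[[i]])          # father from the pool
    expect_false(ev$mother_id[i] %in% cands[[i]])         # pools are male-only
    expect_identical(cands[[i]],
                     pop$rosters[[paste(ev$colony[i], ev$year[i], sep = ":")]])
  }
  sim2 <- simulate_choices(pop, preference_spec("MALDis", beta = 0),
                           n_offspring = 60, seed = 7)
  expect_identical(ev, sim2$events)
})

test_that("offspring genotypes are Mendelian-consistent and within bounds", {
  pop <- small_population(seed = 22)
  sim <- simulate_choices(pop, preference_spec("MALDiv", beta = 0.4),
                          n_offspring = 50, seed = 8)
  trios <- event_trios(sim$events)
  for (g in c("MHC1", "MHC2")) {
    chk <- mendelian_check(sim$population$genotypes[[g]], trios)
    expect_equal(nrow(chk$violations), 0)
    expect_equal(chk$skipped, 0)
    rng <- pop$config$mhc_genes[[g]]$size_range
    sz <- lengths(sim$population$genotypes[[g]][trios$offspring_id])
    expect_true(all(sz >= rng[1] & sz <= rng[2]))
  }
  for (g in c("TAAR2", "MS1")) {
    dip <- sim$population$diploid[[g]]
    for (i in seq_len(nrow(trios))) {
      pair <- dip[[trios$offspring_id[i]]]
      expect_length(pair, 2)
      expect_true(pair[1] %in% dip[[trios$mother_id[i]]])
      expect_true(pair[2] %in% dip[[trios$father_id[i]]])
    }
  }
})

test_that("a steep preference gradient selects the top-index candidate", {
  pop <- small_population(seed = 23)
  sim <- simulate_choices(pop, preference_spec("MALDiv", beta = 50),
                          n_offspring = 60, seed = 9)
  ev <- sim$events
  cands <- event_candidates(ev)
  top <- vapply(seq_len(nrow(ev)), function(i) {
    v <- vapply(cands[[i]], function(m) maldiv(pop$genotypes$MHC1[[m]]), numeric(1))
    # the father must attain the maximum (ties allowed)
    v[match(ev$father_id[i], cands[[i]])] == max(v)
  }, logical(1))
  expect_true(all(top))
})

test_that("heterozygosity-moderated preference uses the mother's TAAR genotype", {
  pop <- small_population(seed = 24)
  pref <- preference_spec("MALDiv", beta = c(het = 50, hom = 0),
                          taar_gene = "TAAR3")
  sim <- simulate_choices(pop, pref, n_offspring = 80, seed = 10)
  ev <- sim$events
  cands <- event_candidates(ev)
  het <- vapply(ev$mother_id, function(m) {
    p <- pop$diploid$TAAR3[[m]]; p[1] != p[2]
  }, logical(1))
  top <- vapply(seq_len(nrow(ev)), function(i) {
    v <- vapply(cands[[i]], function(m) maldiv(pop$genotypes$MHC1[[m]]), numeric(1))
    v[match(ev$father_id[i], cands[[i]])] == max(v)
  }, logical(1))
  expect_true(all(top[het]))          # het mothers always take the maximum
  expect_false(all(top[!het]))        # hom mothers choose uniformly
})
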