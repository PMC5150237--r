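# one shared moderate table keeps the model-fitting tests fast
glmm_fixture <- local({
  pop <- small_population(seed = 31)
  sim <- simulate_choices(pop, preference_spec("MALDiv", beta = 0.6),
                          n_offspring = 80, seed = 31)
  tab <- build_choice_table(sim$events, pop$genotypes$MHC1, "MALDiv")
  list(pop = pop, sim = sim, tab = tab)
})

test_that("the fitted model matches a direct lme4 fit", {
  tab <- glmm_fixture$tab
  fit <- fit_choice_glmm(tab)
  expect_s3_class(fit, "choice_glmm")
  expect_named(fit$fixef, c("(Intercept)", "MHC_INDEX"))

  dat <- as.data.frame(tab)
  for (v in c("COLONY", "YEAR", "CANDIDATEFATHER", "MOTHER")) dat[[v]] <- factor(dat[[v]])
  ref <- suppressMessages(lme4::glmer(
    CHOSEN ~ MHC_INDEX + (1 | COLONY) + (1 | YEAR) + (1 | CANDIDATEFATHER) + (1 | MOTHER),
    data = dat, family = binomial(), nAGQ = 0,
    control = lme4::glmerControl(calc.derivs = FALSE)))
  expect_equal(fit$fixef, lme4::fixef(ref), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)

  # a positive simulated preference yields a positive slope
  expect_gt(fit$fixef[["MHC_INDEX"]], 0)
  expect_error(fit_choice_glmm(data.frame(x = 1)), "choice table")
})

test_that("bootstrap LRT statistics and p-values behave", {
  tab <- glmm_fixture$tab
  r <- lrt_parametric_bootstrap(tab, n_boot = 9, seed = 5)
  full <- fit_choice_glmm(tab, "MHC_INDEX")
  null <- fit_choice_glmm(tab, "1")
  expect_equal(r$statistic, max(0, 2 * (full$logLik - null$logLik)))
  expect_gte(r$p_value, 1 / 10)       # add-one floor at n_boot = 9
  expect_lte(r$p_value, 1)
  expect_length(r$null_stats, r$n_boot_effective)
  expect_true(all(r$null_stats >= 0))

  r2 <- lrt_parametric_bootstrap(tab, n_boot = 9, seed = 5)
  expect_identical(r$null_stats, r2$null_stats)
  expect_identical(r$p_value, r2$p_value)
})

test_that("alpha_stop reproduces the full-run decision exactly", {
  tab <- glmm_fixture$tab
  # null-model simulation under the null fixture: use an index-free table by
  # permuting MHC_INDEX so the decision is usually non-rejection
  set.seed(99)
  tab0 <- tab
  tab0$MHC_INDEX <- sample(tab0$MHC_INDEX)
  for (sd in 1:3) {
    fullr <- lrt_parametric_bootstrap(tab0, n_boot = 19, seed = sd)
    early <- lrt_parametric_bootstrap(tab0, n_boot = 19, seed = sd,
                                      alpha_stop = 0.05)
    expect_identical(early$p_value <= 0.05, fullr$p_value <= 0.05)
    if (early$stopped_early) {
      expect_lt(early$n_boot_effective, 19)
      expect_gte(early$p_value, fullr$p_value)  # conservative upper bound
      # identical draws: the completed replicates agree with the full run
      expect_identical(early$null_stats,
                       fullr$null_stats[seq_along(early$null_stats)])
    }
  }
})

test_that("slope CIs come from the bootstrap distribution as documented", {
  fit <- fit_choice_glmm(glmm_fixture$tab)
  basic <- slope_bootstrap_ci(fit, n_boot = 19, seed = 3)
  perc <- slope_bootstrap_ci(fit, n_boot = 19, seed = 3, type = "percentile")
  expect_identical(basic$boot, perc$boot)
  q <- unname(quantile(basic$boot, c(0.025, 0.975)))
  expect_equal(perc$lower, q[1])
  expect_equal(perc$upper, q[2])
  expect_equal(basic$lower, 2 * basic$estimate - q[2])
  expect_equal(basic$upper, 2 * basic$estimate - q[1])
  expect_lt(basic$lower, basic$upper)
  expect_error(slope_bootstrap_ci(fit, parm = "NOPE"), "not in the fitted model")
})

test_that("TAAR factors attach to the mothers' rows", {
  tab <- glmm_fixture$tab
  dip <- glmm_fixture$pop$diploid$TAAR3
  t2 <- add_taar_factor(tab, dip)
  expect_identical(levels(t2$TAAR_FACTOR), c("hom", "het"))
  for (i in sample(nrow(t2), 20)) {
    pair <- dip[[t2$MOTHER[i]]]
    expect_identical(as.character(t2$TAAR_FACTOR[i]),
                     if (pair[1] != pair[2]) "het" else "hom")
  }
  al <- dip[[t2$MOTHER[1]]][1]
  t3 <- add_taar_factor(tab, dip, "allele_presence", allele = al)
  expect_identical(levels(t3$TAAR_FACTOR), c("absent", "present"))
  expect_identical(as.character(t3$TAAR_FACTOR[1]), "present")
  # a constant factor carries no testable contrast
  hom <- lapply(dip, function(p) c(p[1], p[1]))
  expect_error(add_taar_factor(tab, hom), "constant")

  r <- taar_interaction_test(tab, dip, n_boot = 3, seed = 2)
  expect_s3_class(r, "boot_lrt")
  expect_identical(r$full_fit$fixed, "MHC_INDEX * TAAR_FACTOR")
})

test_that("prediction curves stay on the probability scale", {
  fit <- fit_choice_glmm(glmm_fixture$tab)
  cur <- predicted_choice_curve(fit, n_boot = 9, seed = 4)
  expect_s3_class(cur, "choice_curve")
  expect_true(all(cur$fit >= 0 & cur$fit <= 1))
  expect_true(all(cur$lwr <= cur$upr))
  expect_false(any(attr(cur, "extrapolated")))
  expect_warning(
    predicted_choice_curve(fit, grid = c(0, 100), n_boot = 3, seed = 4),
    "outside the observed")
})
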