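#' Binomial GLMM for choice tables
#'
#' Fits the mixed model `CHOSEN ~ <fixed> + (1|COLONY) + (1|YEAR) +
#' (1|CANDIDATEFATHER) + (1|MOTHER)` with a binomial (logit) response by
#' maximum likelihood.
#'
#' Two likelihood approximations are available and must match between any two
#' models compared by a likelihood-ratio test: `"pirls"` (lme4's nAGQ = 0,
#' fast penalised iteratively reweighted least squares step; the default, and
#' what the parametric-bootstrap machinery uses) and `"laplace"` (nAGQ = 1).
#' For the balanced one-chosen-per-pool tables this package produces, the two
#' give nearly identical estimates.
#'
#' @param table A `choice_table` (optionally with a `TAAR_FACTOR` column).
#' @param fixed Character right-hand side of the fixed part, e.g.
#'   `"MHC_INDEX"`, `"1"`, `"MHC_INDEX * TAAR_FACTOR"`.
#' @param approx `"pirls"` or `"laplace"`.
#' @param standardize Centre and scale `MHC_INDEX` before fitting (slope and
#'   curve reported on the original scale is up to the caller; default off).
#' @return Object of class `choice_glmm`: list with `model` (the `glmerMod`),
#'   `fixef`, `ranef_var`, `logLik`, `converged`, `approx`, `fixed`.
#' @export
fit_choice_glmm <- function(table, fixed = "MHC_INDEX",
                            approx = c("pirls", "laplace"),
                            standardize = FALSE) {
  approx <- match.arg(approx)
  dat <- as.data.frame(table)
  fail_if(!all(c("CHOSEN", "COLONY", "YEAR", "CANDIDATEFATHER", "MOTHER")
               %in% names(dat)), "not a valid choice table")
  if (standardize && "MHC_INDEX" %in% names(dat)) {
    dat$MHC_INDEX <- as.numeric(scale(dat$MHC_INDEX))
  }
  for (v in c("COLONY", "YEAR", "CANDIDATEFATHER", "MOTHER")) {
    dat[[v]] <- factor(dat[[v]])
  }
  form <- stats::as.formula(paste(
    "CHOSEN ~", fixed,
    "+ (1|COLONY) + (1|YEAR) + (1|CANDIDATEFATHER) + (1|MOTHER)"))
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.grad = "ignore",
                             check.conv.singular = "ignore",
                             check.conv.hess = "ignore")
  converged <- TRUE
  model <- withCallingHandlers(
    suppressMessages(lme4::glmer(form, data = dat, family = stats::binomial(),
                                 nAGQ = if (approx == "pirls") 0L else 1L,
                                 control = ctrl)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(model = model,
                 fixef = lme4::fixef(model),
                 ranef_var = stats::setNames(vc$vcov, vc$grp),
                 logLik = as.numeric(stats::logLik(model)),
                 converged = converged,
                 approx = approx, fixed = fixed, data = dat),
            class = "choice_glmm")
}

#' @export
print.choice_glmm <- function(x, ...) {
  cat("Binomial choice GLMM (", x$approx, " approximation)\n", sep = "")
  cat("Fixed: CHOSEN ~", x$fixed, "+ 4 random intercepts\n")
  print(round(x$fixef, 4))
  cat("Random-effect variances:\n")
  print(round(x$ranef_var, 4))
  cat("logLik:", round(x$logLik, 3),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

# internal: refit a choice_glmm on a new response, returning logLik (NA on error)
refit_loglik <- function(fit, newresp) {
  tryCatch(
    as.numeric(stats::logLik(suppressMessages(lme4::refit(fit$model, newresp)))),
    error = function(e) NA_real_)
}

# internal: refit and return the updated glmerMod (NULL on failure)
refit_model <- function(fit, newresp) {
  tryCatch(suppressMessages(lme4::refit(fit$model, newresp)),
           error = function(e) NULL)
}

#' Parametric-bootstrap likelihood-ratio test of nested choice GLMMs
#'
#' The observed statistic is `2 * (logLik(full) - logLik(null))`. Its null
#' distribution is generated by simulating `n_boot` response vectors from the
#' fitted null model (drawing new random effects and binomial responses) and
#' refitting both models on each. The p-value uses the add-one Monte Carlo
#' correction: one plus the number of null statistics at least as large as the
#' observed one, divided by `n_boot + 1`. The uncorrected proportion is
#' available via `p_correction = "proportion"`.
#'
#' @param table A `choice_table` (with `TAAR_FACTOR` if the model formulas
#'   use it).
#' @param full,null Fixed-part right-hand sides; `null` must be nested in `full`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Master seed (bootstrap draws are bit-reproducible given it).
#' @param approx Likelihood approximation, identical for both models.
#' @param p_correction `"plus_one"` (default) or `"proportion"`.
#' @param alpha_stop Optional significance level. When given, the bootstrap
#'   loop stops as soon as enough null statistics have reached the observed one
#'   that the test can no longer reject at this level. The accept/reject
#'   decision (`p_value <= alpha_stop`) is then exactly the decision the full
#'   `n_boot` run would return, but the reported p-value is computed from the
#'   completed replicates only and is conservative (an upper bound). Useful
#'   when many tests are run and only the decision at a fixed level is needed.
#' @return Object of class `boot_lrt`: `statistic`, `null_stats`, `p_value`,
#'   `n_boot`, `n_boot_effective`, `full_fit`, `null_fit`, `stopped_early`,
#'   `flagged` (TRUE when more than 5% of refits failed).
#' @export
lrt_parametric_bootstrap <- function(table, full = "MHC_INDEX", null = "1",
                                     n_boot = 1000, seed = NULL,
                                     approx = "pirls",
                                     p_correction = c("plus_one", "proportion"),
                                     alpha_stop = NULL) {
  p_correction <- match.arg(p_correction)
  fail_if(n_boot < 1, "n_boot must be >= 1")
  full_fit <- fit_choice_glmm(table, full, approx = approx)
  null_fit <- fit_choice_glmm(table, null, approx = approx)
  obs <- max(0, 2 * (full_fit$logLik - null_fit$logLik))

  # largest exceedance count still rejecting at alpha_stop under the
  # add-one correction: (1 + k) / (n_boot + 1) <= alpha
  k_max <- if (is.null(alpha_stop)) Inf else floor(alpha_stop * (n_boot + 1) - 1)

  set_substream(seed, "lrt_parametric_bootstrap")
  ys <- stats::simulate(null_fit$model, nsim = n_boot, use.u = FALSE)
  null_stats <- rep(NA_real_, n_boot)
  exceed <- 0L
  done <- 0L
  for (b in seq_len(n_boot)) {
    llf <- refit_loglik(full_fit, ys[[b]])
    lln <- refit_loglik(null_fit, ys[[b]])
    if (!is.na(llf) && !is.na(lln)) {
      null_stats[b] <- max(0, 2 * (llf - lln))
      if (null_stats[b] >= obs - 1e-10) exceed <- exceed + 1L
    }
    done <- b
    if (exceed > k_max) break
  }
  stopped_early <- done < n_boot
  null_stats <- null_stats[seq_len(done)]

  ok <- !is.na(null_stats)
  p <- if (p_correction == "plus_one") {
    (1 + sum(null_stats[ok] >= obs - 1e-10)) / (sum(ok) + 1)
  } else {
    sum(null_stats[ok] >= obs - 1e-10) / sum(ok)
  }
  structure(list(statistic = obs, null_stats = null_stats[ok], p_value = p,
                 n_boot = n_boot, n_boot_effective = sum(ok),
                 full_fit = full_fit, null_fit = null_fit,
                 stopped_early = stopped_early,
                 flagged = !stopped_early && mean(!ok) > 0.05),
            class = "boot_lrt")
}

#' Parametric-bootstrap confidence interval for a GLMM slope
#'
#' Simulates `n_boot` response vectors from the fitted model (new random
#' effects and binomial draws), refits, and collects the bootstrap
#' distribution of one fixed-effect coefficient.
#'
#' The default interval is the basic (reflected) bootstrap interval
#' `2 * estimate - quantile(boot, c(1 - a, a))`, which corrects the downward
#' shift the bootstrap distribution acquires when random-effect variances are
#' estimated near zero; the raw `"percentile"` interval is also available.
#'
#' @param fit A converged `choice_glmm`.
#' @param parm Name of the fixed-effect coefficient (default `"MHC_INDEX"`).
#' @param n_boot Bootstrap replicates.
#' @param seed Master seed.
#' @param level Confidence level.
#' @param type `"basic"` (default) or `"percentile"`.
#' @return Object of class `slope_ci`: `estimate`, `lower`, `upper`, `boot`
#'   (the replicate estimates), `type`, `level`.
#' @export
slope_bootstrap_ci <- function(fit, parm = "MHC_INDEX", n_boot = 500,
                               seed = NULL, level = 0.95,
                               type = c("basic", "percentile")) {
  type <- match.arg(type)
  fail_if(!parm %in% names(fit$fixef), "coefficient not in the fitted model")
  est <- unname(fit$fixef[parm])

  set_substream(seed, "slope_bootstrap_ci")
  ys <- stats::simulate(fit$model, nsim = n_boot, use.u = FALSE)
  boot <- vapply(seq_len(n_boot), function(b) {
    m <- refit_model(fit, ys[[b]])
    if (is.null(m)) NA_real_ else unname(lme4::fixef(m)[parm])
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  fail_if(length(boot) < 2, "all bootstrap refits failed")

  a <- (1 - level) / 2
  q <- unname(stats::quantile(boot, c(a, 1 - a)))
  ci <- if (type == "basic") c(2 * est - q[2], 2 * est - q[1]) else q
  structure(list(estimate = est, lower = ci[1], upper = ci[2], boot = boot,
                 parm = parm, type = type, level = level),
            class = "slope_ci")
}

#' @export
print.slope_ci <- function(x, ...) {
  cat(sprintf("%s = %.4f, %d%% %s bootstrap CI [%.4f, %.4f] (%d replicates)\n",
              x$parm, x$estimate, round(100 * x$level), x$type,
              x$lower, x$upper, length(x$boot)))
  invisible(x)
}

#' @export
print.boot_lrt <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap LRT: statistic = %.3f, p %s %.4g (%d/%d replicates)%s\n",
              x$statistic, if (isTRUE(x$stopped_early)) "<=" else "=",
              x$p_value, x$n_boot_effective, x$n_boot,
              if (x$flagged) " [FLAGGED: >5% refits failed]" else ""))
  invisible(x)
}

#' Fixed-effects prediction curve with parametric-bootstrap confidence band
#'
#' Inverse-logit predictions of the probability of being chosen over a grid of
#' index values, using fixed effects only; the percentile confidence band is
#' obtained by simulating from the fitted model, refitting, and re-predicting.
#'
#' @param fit A converged `choice_glmm`.
#' @param grid Numeric grid of index values (defaults to 50 points over the
#'   observed range).
#' @param n_boot Bootstrap replicates for the band.
#' @param seed Master seed.
#' @param level Confidence level.
#' @param at Named list of values for additional fixed covariates (e.g.
#'   `list(TAAR_FACTOR = "het")`).
#' @return Data frame `MHC_INDEX`, `fit`, `lwr`, `upr`, with attribute
#'   `extrapolated` flagging grid points outside the observed range.
#' @export
predicted_choice_curve <- function(fit, grid = NULL, n_boot = 1000, seed = NULL,
                                   level = 0.95, at = list()) {
  fail_if(!fit$converged, "prediction from a non-converged fit")
  obs_range <- range(fit$data$MHC_INDEX)
  if (is.null(grid)) grid <- seq(obs_range[1], obs_range[2], length.out = 50)
  nd <- data.frame(MHC_INDEX = grid)
  for (v in names(at)) nd[[v]] <- factor(at[[v]], levels = levels(fit$data[[v]]))

  pred1 <- function(model) {
    as.numeric(stats::predict(model, newdata = nd, re.form = NA,
                              type = "response", allow.new.levels = TRUE))
  }
  est <- pred1(fit$model)

  set_substream(seed, "predicted_choice_curve")
  ys <- stats::simulate(fit$model, nsim = n_boot, use.u = FALSE)
  boots <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    m <- refit_model(fit, ys[[b]])
    if (!is.null(m)) boots[b, ] <- pred1(m)
  }
  a <- (1 - level) / 2
  qs <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(MHC_INDEX = grid, fit = est, lwr = qs[1, ], upr = qs[2, ])
  attr(out, "extrapolated") <- grid < obs_range[1] | grid > obs_range[2]
  if (any(attr(out, "extrapolated"))) {
    warning("some grid points lie outside the observed index range")
  }
  class(out) <- c("choice_curve", class(out))
  out
}

#' Interaction test between an MHC index and a maternal TAAR genotype factor
#'
#' Compares `MHC_INDEX * TAAR_FACTOR` against `MHC_INDEX + TAAR_FACTOR` by
#' parametric-bootstrap LRT; the factor is a property of the mother attached
#' to all her rows, either her heterozygosity status at the locus or the
#' presence of a specific allele.
#'
#' @param table A `choice_table`.
#' @param taar_diploid Named list of length-2 allele vectors (one TAAR locus).
#' @param factor_mode `"het_status"` or `"allele_presence"`.
#' @param allele Allele ID for `allele_presence`.
#' @inheritParams lrt_parametric_bootstrap
#' @param ... Passed on to [lrt_parametric_bootstrap()] (e.g. `alpha_stop`).
#' @return A `boot_lrt`.
#' @export
taar_interaction_test <- function(table, taar_diploid,
                                  factor_mode = "het_status", allele = NULL,
                                  n_boot = 1000, seed = NULL, approx = "pirls",
                                  ...) {
  tab <- add_taar_factor(table, taar_diploid, factor_mode, allele)
  lrt_parametric_bootstrap(tab, full = "MHC_INDEX * TAAR_FACTOR",
                           null = "MHC_INDEX + TAAR_FACTOR",
                           n_boot = n_boot, seed = seed, approx = approx, ...)
}
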