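# internal: per-event candidate index values for the randomization machinery.
# Returns a list with, per included event, the genotyped candidates' values and
# the father's value; events failing the inclusion rules are dropped and
# counted. Undefined (NA) values are kept and excluded from means downstream.
event_index_values <- function(events, genotypes, index, D = NULL,
                               mode = "within_symdiff") {
  index <- match.arg(index, INDEX_NAMES)
  needs_mother <- index_is_dissimilarity(index)
  cands <- event_candidates(events)
  vals <- list(); obs <- numeric(0)
  dropped <- c(no_father = 0L, no_mother = 0L, no_candidates = 0L,
               father_undefined = 0L)
  for (i in seq_len(nrow(events))) {
    fa <- events$father_id[i]; mo <- events$mother_id[i]
    if (is.null(genotypes[[fa]])) { dropped["no_father"] <- dropped["no_father"] + 1L; next }
    if (needs_mother && is.null(genotypes[[mo]])) {
      dropped["no_mother"] <- dropped["no_mother"] + 1L; next
    }
    pool <- cands[[i]]
    pool <- pool[vapply(pool, function(p) !is.null(genotypes[[p]]), logical(1))]
    if (length(pool) < 1) { dropped["no_candidates"] <- dropped["no_candidates"] + 1L; next }
    v <- vapply(pool, function(m) {
      mhc_index(index, male = genotypes[[m]],
                female = if (needs_mother) genotypes[[mo]] else NULL,
                D = D, mode = mode)
    }, numeric(1))
    fv <- v[match(fa, pool)]
    if (is.na(fv)) { dropped["father_undefined"] <- dropped["father_undefined"] + 1L; next }
    vals[[length(vals) + 1L]] <- unname(v)
    obs <- c(obs, fv)
  }
  fail_if(length(vals) == 0, "no events with computable index values")
  list(values = vals, observed = obs, dropped = dropped, index = index)
}

#' Observed mean of an MHC index over real couples
#'
#' Arithmetic mean of the index over all (mother, father) couples (diversity
#' indices: fathers only) that pass the inclusion rules; couples with an
#' undefined `muAADis` are excluded.
#'
#' @param events A `choice_events` data frame.
#' @param genotypes Named list of allele sets for one gene.
#' @param index Index name.
#' @param D Distance matrix for amino-acid indices.
#' @param mode `muAADis` mode.
#' @return Numeric scalar.
#' @export
observed_index_mean <- function(events, genotypes, index, D = NULL,
                                mode = "within_symdiff") {
  ev <- event_index_values(events, genotypes, index, D, mode)
  mean(ev$observed)
}

#' Monte Carlo randomization test of non-random mating
#'
#' Compares the observed mean of an MHC index over real couples with its
#' distribution under random reassembly: in each of `B` replicates, one male
#' is drawn uniformly (with replacement, independently per offspring) from the
#' offspring's genotyped candidate pool (father included), the index is
#' computed for the (mother, drawn male) pair, and the replicate mean is
#' recorded. The two-tailed p-value counts replicate means at least as distant
#' from the centre of the simulated distribution as the observed mean, with
#' the add-one correction.
#'
#' @inheritParams observed_index_mean
#' @param B Number of randomization replicates.
#' @param seed Master seed (simulated means are bit-reproducible).
#' @param center `"mean"` (default) or `"median"` of the simulated means.
#' @param p_correction `"plus_one"` or the raw `"proportion"`.
#' @return Object of class `randomization_test`: `index`, `observed_mean`,
#'   `simulated_means`, `center`, `p_two_tailed`, `B`, `n_couples`, `dropped`.
#' @export
mc_randomization_test <- function(events, genotypes, index, D = NULL,
                                  B = 100000, seed = NULL,
                                  mode = "within_symdiff", center = c("mean", "median"),
                                  p_correction = c("plus_one", "proportion")) {
  center <- match.arg(center)
  p_correction <- match.arg(p_correction)
  fail_if(B < 1, "B must be >= 1")
  ev <- event_index_values(events, genotypes, index, D, mode)
  obs <- mean(ev$observed)

  set_substream(seed, "mc_randomization_test")
  sums <- numeric(B); counts <- numeric(B)
  for (v in ev$values) {
    draw <- v[sample.int(length(v), B, replace = TRUE)]
    ok <- !is.na(draw)
    sums[ok] <- sums[ok] + draw[ok]
    counts <- counts + ok
  }
  sims <- sums / counts
  ctr <- if (center == "mean") mean(sims) else stats::median(sims)
  extreme <- abs(sims - ctr) >= abs(obs - ctr) - 1e-12
  p <- if (p_correction == "plus_one") (1 + sum(extreme)) / (B + 1) else mean(extreme)

  structure(list(index = ev$index, observed_mean = obs, simulated_means = sims,
                 center = ctr, p_two_tailed = p, B = B,
                 n_couples = length(ev$observed), dropped = ev$dropped),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("Randomization test (%s): observed mean = %.4f, centre = %.4f, p = %.4g (B = %d, n = %d couples)\n",
              x$index, x$observed_mean, x$center, x$p_two_tailed, x$B, x$n_couples))
  invisible(x)
}

#' Exact enumeration version of the randomization test
#'
#' Computes the exact distribution of the randomized mean by convolving the
#' per-offspring value distributions (each genotyped candidate equally
#' likely), and the exact two-tailed p-value with the centre set to the exact
#' expectation of the mean. Couples with undefined values are handled exactly
#' as in [mc_randomization_test()] (excluded from the replicate mean). Serves
#' as a brute-force oracle for the Monte Carlo test on small instances.
#'
#' @inheritParams observed_index_mean
#' @param max_assignments Guard on the total number of equally likely
#'   assignments (product of pool sizes).
#' @return List: `observed_mean`, `center` (exact expectation), `p_two_tailed`,
#'   `support` (data frame of attainable means and probabilities), `n_couples`.
#' @export
exact_enumeration_test <- function(events, genotypes, index, D = NULL,
                                   mode = "within_symdiff",
                                   max_assignments = 1e6) {
  ev <- event_index_values(events, genotypes, index, D, mode)
  n_assign <- prod(vapply(ev$values, length, numeric(1)))
  fail_if(n_assign > max_assignments,
          "%.3g assignments exceed the enumeration bound; use mc_randomization_test",
          n_assign)
  obs <- mean(ev$observed)

  # joint distribution of (sum of defined values, count of defined values)
  dist <- data.frame(sum = 0, count = 0, prob = 1)
  for (v in ev$values) {
    k <- length(v)
    parts <- lapply(v, function(val) {
      d <- dist
      if (is.na(val)) {
        d$prob <- d$prob / k
      } else {
        d$sum <- d$sum + val
        d$count <- d$count + 1
        d$prob <- d$prob / k
      }
      d
    })
    dist <- do.call(rbind, parts)
    key <- paste(signif(dist$sum, 12), dist$count)
    first <- !duplicated(key)
    agg <- rowsum(dist$prob, key)
    dist <- data.frame(sum = dist$sum[first], count = dist$count[first],
                       prob = agg[match(key[first], rownames(agg)), 1])
  }
  fail_if(any(dist$count == 0), "some assignments have no defined values")
  m <- dist$sum / dist$count
  ctr <- sum(dist$prob * m)
  p <- sum(dist$prob[abs(m - ctr) >= abs(obs - ctr) - 1e-9])
  list(observed_mean = obs, center = ctr, p_two_tailed = p,
       support = data.frame(mean = m, prob = dist$prob)[order(m), ],
       n_couples = length(ev$observed))
}
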