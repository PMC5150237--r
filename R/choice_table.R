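#' Build the one-row-per-candidate choice table
#'
#' Flattens choice events into the modelling table with one row per
#' (offspring, genotyped candidate) and a binary `CHOSEN` response that is 1
#' exactly for the assigned father's row.
#'
#' Inclusion rules: an event enters the table only if its father is genotyped
#' and at least one further candidate is genotyped; for dissimilarity indices
#' the mother must also be genotyped. Rows with undefined index values
#' (`muAADis` of fully shared genotypes) are excluded; if that removes the
#' father's row or leaves fewer than two rows, the whole event is excluded.
#' All exclusions are counted in the `log` attribute.
#'
#' @param events A `choice_events` data frame.
#' @param genotypes Named list mapping individual ID to allele sets for one
#'   gene; individuals absent from the list count as not genotyped.
#' @param index Index name (see [mhc_index()]).
#' @param D Distance matrix for amino-acid indices.
#' @param mode `muAADis` mode.
#' @return A data frame of class `choice_table` with columns `OFFSPRING`,
#'   `MOTHER`, `CANDIDATEFATHER`, `CHOSEN`, `MHC_INDEX`, `COLONY`, `YEAR`,
#'   and attributes `index` and `log`.
#' @export
build_choice_table <- function(events, genotypes, index, D = NULL,
                               mode = "within_symdiff") {
  index <- match.arg(index, INDEX_NAMES)
  needs_mother <- index_is_dissimilarity(index)
  cands <- event_candidates(events)
  log <- c(events_in = nrow(events), no_father_genotype = 0L,
           no_mother_genotype = 0L, single_candidate = 0L,
           undefined_index = 0L, events_out = 0L, rows_dropped_undefined = 0L)
  rows <- vector("list", nrow(events))

  for (i in seq_len(nrow(events))) {
    fa <- events$father_id[i]
    mo <- events$mother_id[i]
    if (is.null(genotypes[[fa]])) {
      log["no_father_genotype"] <- log["no_father_genotype"] + 1L
      next
    }
    if (needs_mother && is.null(genotypes[[mo]])) {
      log["no_mother_genotype"] <- log["no_mother_genotype"] + 1L
      next
    }
    pool <- cands[[i]]
    pool <- pool[vapply(pool, function(p) !is.null(genotypes[[p]]), logical(1))]
    if (length(pool) < 2) {
      log["single_candidate"] <- log["single_candidate"] + 1L
      next
    }
    v <- vapply(pool, function(m) {
      mhc_index(index, male = genotypes[[m]],
                female = if (needs_mother) genotypes[[mo]] else NULL,
                D = D, mode = mode)
    }, numeric(1))
    defined <- !is.na(v)
    log["rows_dropped_undefined"] <- log["rows_dropped_undefined"] + sum(!defined)
    if (!defined[match(fa, pool)] || sum(defined) < 2) {
      log["undefined_index"] <- log["undefined_index"] + 1L
      next
    }
    pool <- pool[defined]
    v <- v[defined]
    rows[[i]] <- data.frame(
      OFFSPRING = events$offspring_id[i], MOTHER = mo,
      CANDIDATEFATHER = pool, CHOSEN = as.integer(pool == fa),
      MHC_INDEX = as.numeric(v), COLONY = events$colony[i],
      YEAR = as.character(events$year[i]), stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  fail_if(is.null(out), "no events passed the inclusion rules")
  rownames(out) <- NULL
  log["events_out"] <- length(unique(out$OFFSPRING))
  attr(out, "index") <- index
  attr(out, "log") <- log
  class(out) <- c("choice_table", class(out))
  out
}

#' @export
print.choice_table <- function(x, ...) {
  cat(sprintf("Choice table (%s): %d rows, %d events (CHOSEN=1: %d, CHOSEN=0: %d)\n",
              attr(x, "index"), nrow(x), length(unique(x$OFFSPRING)),
              sum(x$CHOSEN == 1), sum(x$CHOSEN == 0)))
  invisible(x)
}

#' Attach a TAAR genotype factor (a property of the mother) to a choice table
#'
#' @param table A `choice_table`.
#' @param taar_diploid Named list mapping individual ID to a length-2 allele
#'   vector at one TAAR locus (e.g. `population$diploid$TAAR3`).
#' @param factor_mode `"het_status"` (levels `hom`/`het`) or
#'   `"allele_presence"` (levels `absent`/`present` of `allele`).
#' @param allele Allele ID, required for `factor_mode = "allele_presence"`.
#' @return The table with an added factor column `TAAR_FACTOR`.
#' @export
add_taar_factor <- function(table, taar_diploid,
                            factor_mode = c("het_status", "allele_presence"),
                            allele = NULL) {
  factor_mode <- match.arg(factor_mode)
  mothers <- unique(table$MOTHER)
  miss <- mothers[vapply(mothers, function(m) is.null(taar_diploid[[m]]), logical(1))]
  fail_if(length(miss) > 0, "mothers without TAAR genotype: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  lev <- vapply(table$MOTHER, function(m) {
    pair <- taar_diploid[[m]]
    if (factor_mode == "het_status") {
      if (pair[1] != pair[2]) "het" else "hom"
    } else {
      fail_if(is.null(allele), "allele_presence mode requires an allele ID")
      if (allele %in% pair) "present" else "absent"
    }
  }, character(1))
  table$TAAR_FACTOR <- factor(lev, levels = if (factor_mode == "het_status")
    c("hom", "het") else c("absent", "present"))
  fail_if(length(unique(lev)) < 2,
          "TAAR factor is constant across mothers; no contrast to test")
  table
}
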