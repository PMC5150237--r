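#' Read and write genotype tables
#'
#' The TSV dialect used throughout the package: UTF-8, tab-separated, header
#' row; allele sets comma-joined, candidate lists semicolon-joined.
#'
#' @param genotypes Named list (per gene) of named allele-set lists, or a
#'   single gene's named list.
#' @param path File path.
#' @return `write_genotypes` returns the path invisibly; `read_genotypes`
#'   returns a named list per gene of named allele-set lists.
#' @export
write_genotypes <- function(genotypes, path) {
  if (!is.list(genotypes[[1]])) genotypes <- list(GENE = genotypes)
  rows <- do.call(rbind, lapply(names(genotypes), function(g) {
    ids <- names(genotypes[[g]])
    data.frame(individual_id = ids, gene = g,
               alleles = vapply(genotypes[[g]], set_to_string, character(1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  fail_if(!all(c("individual_id", "gene", "alleles") %in% names(df)),
          "genotype TSV must have columns individual_id, gene, alleles")
  out <- lapply(split(df, df$gene), function(d) {
    fail_if(anyDuplicated(d$individual_id) > 0,
            "duplicate genotype record in gene %s", d$gene[1])
    stats::setNames(lapply(d$alleles, string_to_set), d$individual_id)
  })
  out
}

#' Read and write choice-event tables
#'
#' @param events A `choice_events` data frame.
#' @param path File path.
#' @export
write_choice_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_events
#' @export
read_choice_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("offspring_id", "mother_id", "father_id", "candidate_ids",
            "colony", "year")
  fail_if(!all(need %in% names(df)), "events TSV must have columns: %s",
          paste(need, collapse = ", "))
  class(df) <- c("choice_events", class(df))
  df
}

#' Validate genotype, event and catalog inputs
#'
#' Cross-checks ID references, genotype-set bounds, father-in-candidates and
#' duplicate records, distinguishing errors from warnings.
#'
#' @param genotypes Named list (per gene) of named allele-set lists.
#' @param events A `choice_events` data frame (optional).
#' @param catalogs Named list of `allele_catalog` objects (optional).
#' @param size_bounds Optional named list of `c(min, max)` per gene.
#' @return Data frame of class `validation_report` with columns `level`
#'   (`error`/`warning`), `check`, `message`; zero rows when fully valid.
#' @export
validate_inputs <- function(genotypes, events = NULL, catalogs = NULL,
                            size_bounds = NULL) {
  issues <- list()
  note <- function(level, check, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, check = check, message = msg, stringsAsFactors = FALSE)
  }
  for (g in names(genotypes)) {
    sets <- genotypes[[g]]
    if (any(vapply(sets, length, integer(1)) == 0)) {
      note("error", "empty_genotype", sprintf("empty allele set at %s", g))
    }
    if (!is.null(catalogs[[g]])) {
      unknown <- setdiff(unique(unlist(sets)), catalogs[[g]]$allele_id)
      if (length(unknown) > 0) {
        note("error", "unknown_allele",
             sprintf("%s: allele(s) missing from catalog: %s", g,
                     paste(utils::head(unknown, 5), collapse = ", ")))
      }
    }
    if (!is.null(size_bounds[[g]])) {
      sz <- vapply(sets, length, integer(1))
      if (any(sz < size_bounds[[g]][1] | sz > size_bounds[[g]][2])) {
        note("warning", "size_bounds",
             sprintf("%s: %d genotype(s) outside size bounds [%d, %d]", g,
                     sum(sz < size_bounds[[g]][1] | sz > size_bounds[[g]][2]),
                     size_bounds[[g]][1], size_bounds[[g]][2]))
      }
    }
  }
  if (!is.null(events)) {
    cands <- event_candidates(events)
    for (i in seq_len(nrow(events))) {
      if (!(events$father_id[i] %in% cands[[i]])) {
        note("error", "father_not_candidate",
             sprintf("event %s: father %s absent from candidate list",
                     events$offspring_id[i], events$father_id[i]))
      }
      if (events$mother_id[i] %in% cands[[i]]) {
        note("error", "mother_in_candidates",
             sprintf("event %s: mother listed as candidate", events$offspring_id[i]))
      }
      if (length(cands[[i]]) < 2) {
        note("warning", "small_pool",
             sprintf("event %s: fewer than 2 candidates", events$offspring_id[i]))
      }
    }
    if (anyDuplicated(events$offspring_id) > 0) {
      note("error", "duplicate_offspring", "duplicate offspring records")
    }
  }
  out <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(level = character(0), check = character(0), message = character(0))
  class(out) <- c("validation_report", class(out))
  out
}
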