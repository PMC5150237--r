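#' Demultiplex and trim amplicon reads
#'
#' Assigns each read to an individual by exact barcode match and trims it to
#' the inter-primer region; reads with any mismatch in the barcode or either
#' primer, or with an unexpected length, are discarded. Counts of every
#' discard reason are kept in the `log` attribute (input = retained +
#' discarded).
#'
#' @param reads A `read_set`, or a data frame with a `sequence` column.
#' @param barcodes Data frame `individual_id`, `barcode` (defaults to the
#'   read set's own map). Duplicate barcode assignments are an error.
#' @param primers List `fwd`, `rev` (defaults to the read set's own pair).
#' @return Data frame `individual_id`, `insert` (trimmed sequence) of class
#'   `demux_reads`, with a `log` attribute.
#' @export
demultiplex_and_trim <- function(reads, barcodes = NULL, primers = NULL) {
  if (inherits(reads, "read_set")) {
    if (is.null(barcodes)) barcodes <- reads$barcodes
    if (is.null(primers)) primers <- reads$primers
    reads <- reads$reads
  }
  fail_if(is.null(barcodes) || is.null(primers), "barcodes and primers required")
  fail_if(anyDuplicated(barcodes$barcode) > 0, "duplicate barcode assignment")
  fail_if(anyDuplicated(barcodes$individual_id) > 0,
          "individual with multiple barcodes")
  bl <- unique(nchar(barcodes$barcode))
  fail_if(length(bl) != 1, "barcodes of mixed length")
  fl <- nchar(primers$fwd); rl <- nchar(primers$rev)

  seqs <- reads$sequence
  n <- length(seqs)
  bc <- substr(seqs, 1, bl)
  idx <- match(bc, barcodes$barcode)
  bad_bc <- is.na(idx)
  fwd <- substr(seqs, bl + 1, bl + fl)
  len <- nchar(seqs)
  rev <- substr(seqs, len - rl + 1, len)
  bad_primer <- fwd != primers$fwd | rev != primers$rev
  insert <- substr(seqs, bl + fl + 1, len - rl)
  ins_len <- nchar(insert)
  modal_len <- as.integer(names(sort(table(ins_len[!bad_bc & !bad_primer]),
                                     decreasing = TRUE))[1])
  bad_len <- ins_len != modal_len

  keep <- !bad_bc & !bad_primer & !bad_len
  out <- data.frame(individual_id = barcodes$individual_id[idx[keep]],
                    insert = insert[keep], stringsAsFactors = FALSE)
  attr(out, "log") <- c(input = n, retained = sum(keep),
                        barcode_mismatch = sum(bad_bc),
                        primer_mismatch = sum(!bad_bc & bad_primer),
                        length_deviant = sum(!bad_bc & !bad_primer & bad_len))
  attr(out, "insert_length") <- modal_len
  class(out) <- c("demux_reads", class(out))
  out
}

#' Reference-free chimera filter
#'
#' Flags a read as chimeric when some prefix/suffix split of it is
#' reconstructed by two distinct more-abundant sequences with at most
#' `max_mismatch` total mismatches (default 0, i.e. exactly) and strictly
#' fewer mismatches than its best single-parent match. Requiring exact
#' reconstruction is what keeps genuine low-frequency alleles safe: a real
#' allele is almost never a perfect recombinant of two others, whereas a
#' template-switch chimera of clean reads is one by construction. Candidate
#' parents are sequences at least `skew` times more abundant than the read
#' (abundance-ordered, reference-free), capped at the `max_parents` most
#' abundant.
#'
#' @param inserts Character vector of equal-length trimmed reads.
#' @param skew Minimum abundance ratio parent/read.
#' @param max_parents Cap on the number of candidate parents considered.
#' @param max_mismatch Maximum total mismatches allowed in the two-parent
#'   reconstruction; raise above 0 only if chimeric molecules are expected to
#'   carry additional sequencing errors worth catching at this stage.
#' @return Logical vector (`TRUE` = flagged chimeric), with attribute `log`.
#' @export
flag_chimeras <- function(inserts, skew = 2, max_parents = 100,
                          max_mismatch = 0) {
  n <- length(inserts)
  if (n == 0) return(structure(logical(0), log = c(input = 0L, flagged = 0L)))
  fail_if(length(unique(nchar(inserts))) != 1, "reads must have equal length")
  L <- nchar(inserts[1])

  tab <- sort(table(inserts), decreasing = TRUE)
  useqs <- names(tab)
  counts <- as.integer(tab)
  U <- length(useqs)

  # integer code matrix of unique sequences
  code <- matrix(match(unlist(strsplit(useqs, "", fixed = TRUE)),
                       c("A", "C", "G", "T", "N")), nrow = U, byrow = TRUE)

  parents_all <- seq_len(min(max_parents, U))
  flagged_u <- logical(U)
  if (U >= 2) {
    # cumulative prefix-mismatch matrices against each candidate parent,
    # tracking the best and second-best parent per (read, position)
    bestPre <- matrix(Inf, U, L); best2Pre <- matrix(Inf, U, L)
    argPre <- matrix(0L, U, L)
    bestSuf <- matrix(Inf, U, L); best2Suf <- matrix(Inf, U, L)
    argSuf <- matrix(0L, U, L)
    bestTot <- rep(Inf, U)

    for (p in parents_all) {
      mm <- code != matrix(code[p, ], U, L, byrow = TRUE)
      pre <- mm
      for (j in 2:L) pre[, j] <- pre[, j - 1] + mm[, j]
      tot <- pre[, L]
      suf <- tot - pre  # mismatches strictly after position j
      elig <- counts[p] >= skew * counts & counts[p] > counts  # parent must out-rank read
      bestTot[elig] <- pmin(bestTot[elig], tot[elig])
      upd <- elig & (pre < bestPre)
      best2Pre[upd] <- bestPre[upd]; bestPre[upd] <- pre[upd]; argPre[upd] <- p
      upd2 <- elig & !upd & (pre < best2Pre)
      best2Pre[upd2] <- pre[upd2]
      upd <- elig & (suf < bestSuf)
      best2Suf[upd] <- bestSuf[upd]; bestSuf[upd] <- suf[upd]; argSuf[upd] <- p
      upd2 <- elig & !upd & (suf < best2Suf)
      best2Suf[upd2] <- suf[upd2]
    }

    # best two-parent (A != B) mismatch over breakpoints 1..L-1
    for (u in seq_len(U)) {
      if (!is.finite(bestTot[u])) next
      js <- seq_len(L - 1)
      same <- argPre[u, js] == argSuf[u, js] & argPre[u, js] != 0L
      two <- pmin(bestPre[u, js] + ifelse(same, best2Suf[u, js], bestSuf[u, js]),
                  ifelse(same, best2Pre[u, js], bestPre[u, js]) + bestSuf[u, js])
      flagged_u[u] <- any(is.finite(two) & two <= max_mismatch &
                            two < bestTot[u])
    }
  }

  flagged <- flagged_u[match(inserts, useqs)]
  attr(flagged, "log") <- c(input = n, flagged = sum(flagged),
                            retained = n - sum(flagged))
  flagged
}

#' Filter chimeras from demultiplexed reads
#'
#' @param demux A `demux_reads` data frame.
#' @inheritParams flag_chimeras
#' @return List `retained` and `flagged` (both `demux_reads`-shaped), with a
#'   `log` attribute on `retained`.
#' @export
filter_chimeras <- function(demux, skew = 2, max_parents = 100,
                            max_mismatch = 0) {
  fl <- flag_chimeras(demux$insert, skew = skew, max_parents = max_parents,
                      max_mismatch = max_mismatch)
  retained <- demux[!fl, , drop = FALSE]
  attr(retained, "log") <- attr(fl, "log")
  list(retained = retained, flagged = demux[fl, , drop = FALSE])
}

#' Translated-homology filter
#'
#' Retains a read if and only if its in-frame translation contains no stop
#' codon and has at least `min_identity` fractional identity (positional, no
#' alignment) to the best-matching reference protein. Reads whose insert is
#' not divisible into codons after applying `frame` are rejected and logged.
#'
#' @param demux A `demux_reads` data frame.
#' @param reference_aa Character vector of reference protein sequences of the
#'   amplicon's translated length.
#' @param min_identity Minimum identity fraction (boundary inclusive).
#' @param frame 0-based offset of the first codon within the insert.
#' @return The retained subset (same shape), with a `log` attribute and an
#'   added `aa` column.
#' @export
homology_filter <- function(demux, reference_aa, min_identity = 0.7, frame = 0) {
  fail_if(length(reference_aa) == 0, "no reference proteins supplied")
  ins <- substr(demux$insert, frame + 1, nchar(demux$insert))
  ok_frame <- nchar(ins) %% 3 == 0
  aa <- rep(NA_character_, length(ins))
  aa[ok_frame] <- translate_dna(ins[ok_frame])
  no_stop <- ok_frame & !grepl("*", aa, fixed = TRUE)

  ref_len <- unique(nchar(reference_aa))
  fail_if(length(ref_len) != 1, "reference proteins of unequal length")
  ident <- rep(0, length(ins))
  cand <- which(no_stop & nchar(aa) == ref_len)
  if (length(cand) > 0) {
    ua <- unique(aa[cand])
    um <- do.call(rbind, strsplit(ua, "", fixed = TRUE))
    best <- rep(0, length(ua))
    for (r in reference_aa) {
      rv <- strsplit(r, "", fixed = TRUE)[[1]]
      idr <- rowMeans(um == matrix(rv, length(ua), ref_len, byrow = TRUE))
      best <- pmax(best, idr)
    }
    ident[cand] <- best[match(aa[cand], ua)]
  }
  keep <- no_stop & ident >= min_identity - 1e-12
  out <- demux[keep, , drop = FALSE]
  out$aa <- aa[keep]
  attr(out, "log") <- c(input = nrow(demux), retained = sum(keep),
                        frame_error = sum(!ok_frame),
                        stop_codon = sum(ok_frame & !no_stop),
                        below_identity = sum(no_stop & ident < min_identity - 1e-12))
  attr(out, "insert_length") <- attr(demux, "insert_length")
  out
}

# internal: Shannon entropy (nats) of each alignment column
column_entropies <- function(code, L) {
  vapply(seq_len(L), function(j) {
    p <- tabulate(code[, j], 5)
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }, numeric(1))
}

#' Entropy-based (oligotype) allele calling
#'
#' Computes per-position Shannon entropy over the pooled alignment of all
#' individuals' reads; columns with entropy above `entropy_threshold` define
#' the oligotype of each read (the concatenated bases at those columns). An
#' oligotype becomes an allele of an individual when its reads in that
#' individual reach both `min_reads_per_allele` and `min_fraction_per_allele`
#' of the individual's reads. Alleles seen in fewer than
#' `min_individuals_per_allele` individuals are then deleted everywhere, and
#' individuals left with fewer than `min_alleles_per_individual` alleles are
#' dropped from the gene's genotype table.
#'
#' @param demux A `demux_reads` data frame (equal-length inserts).
#' @param gene Gene label used for allele IDs (`GENE-01`, ... in decreasing
#'   abundance order).
#' @param entropy_threshold Entropy cut-off in nats (default 0.2; a
#'   configuration default of this package, not an empirical constant).
#' @param min_reads_per_allele Minimum supporting reads per individual.
#' @param min_fraction_per_allele Minimum fraction of the individual's reads.
#' @param min_alleles_per_individual Individuals below this are dropped.
#' @param min_individuals_per_allele Alleles below this are deleted.
#' @return List of class `allele_calls`: `genotypes` (named list of allele-ID
#'   vectors), `calls` (data frame `allele_id`, `oligotype`,
#'   `representative_sequence`, `read_count`, `individual_count`),
#'   `entropy_positions`, `entropies`, `log`.
#' @export
call_alleles <- function(demux, gene = "GENE", entropy_threshold = 0.2,
                         min_reads_per_allele = 10,
                         min_fraction_per_allele = 0.05,
                         min_alleles_per_individual = 1,
                         min_individuals_per_allele = 2) {
  fail_if(nrow(demux) == 0, "no reads to call")
  fail_if(length(unique(nchar(demux$insert))) != 1, "reads must have equal length")
  L <- nchar(demux$insert[1])

  useqs <- unique(demux$insert)
  code <- matrix(match(unlist(strsplit(useqs, "", fixed = TRUE)),
                       c("A", "C", "G", "T", "N")), nrow = length(useqs), byrow = TRUE)
  ucount <- as.integer(table(factor(demux$insert, levels = useqs)))
  # entropy over the pooled reads (weight unique sequences by abundance)
  ent <- vapply(seq_len(L), function(j) {
    p <- vapply(1:5, function(b) sum(ucount[code[, j] == b]), numeric(1))
    p <- p[p > 0] / sum(p)
    -sum(p * log(p))
  }, numeric(1))
  pos <- which(ent > entropy_threshold)

  if (length(pos) == 0) {
    fail_if(length(useqs) > 1,
            "no entropy columns above threshold but >1 distinct sequence: gene unresolvable")
    ids <- unique(demux$individual_id)
    aid <- sprintf("%s-01", gene)
    calls <- data.frame(allele_id = aid, oligotype = "",
                        representative_sequence = useqs[1],
                        read_count = nrow(demux),
                        individual_count = length(ids), stringsAsFactors = FALSE)
    return(structure(list(
      genotypes = stats::setNames(rep(list(aid), length(ids)), ids),
      calls = calls, entropy_positions = integer(0), entropies = ent,
      log = c(input_reads = nrow(demux), individuals_in = length(ids),
              individuals_dropped = 0L, alleles_deleted_rare = 0L)),
      class = "allele_calls"))
  }

  olig_u <- do.call(paste0, lapply(pos, function(j)
    c("A", "C", "G", "T", "N")[code[, j]]))
  olig <- olig_u[match(demux$insert, useqs)]

  # per-individual oligotype counts and thresholds
  ids <- unique(demux$individual_id)
  per_ind <- split(olig, demux$individual_id)[ids]
  ind_calls <- lapply(per_ind, function(o) {
    tt <- table(o)
    names(tt)[tt >= min_reads_per_allele & tt / length(o) >= min_fraction_per_allele]
  })

  # allele-level rarity filter
  carrier_counts <- table(unlist(ind_calls))
  kept_types <- names(carrier_counts)[carrier_counts >= min_individuals_per_allele]
  deleted_rare <- sum(carrier_counts < min_individuals_per_allele)
  ind_calls <- lapply(ind_calls, function(a) a[a %in% kept_types])

  # individual-level minimum-allele filter
  ok_ind <- vapply(ind_calls, length, integer(1)) >= min_alleles_per_individual
  dropped <- sum(!ok_ind)
  ind_calls <- ind_calls[ok_ind]

  # canonical allele IDs in decreasing total-abundance order; the
  # representative sequence is the most abundant full-length read of the type
  type_reads <- vapply(kept_types, function(t) sum(olig == t), numeric(1))
  ord <- order(-type_reads, kept_types)
  kept_types <- kept_types[ord]
  aid <- stats::setNames(sprintf("%s-%02d", gene, seq_along(kept_types)), kept_types)
  rep_seq <- vapply(kept_types, function(t) {
    members <- useqs[olig_u == t]
    members[which.max(ucount[olig_u == t])]
  }, character(1))
  calls <- data.frame(
    allele_id = unname(aid), oligotype = kept_types,
    representative_sequence = unname(rep_seq),
    read_count = as.integer(type_reads[ord]),
    individual_count = as.integer(carrier_counts[kept_types]),
    stringsAsFactors = FALSE)

  genotypes <- lapply(ind_calls, function(a) sort(unname(aid[a])))
  structure(list(genotypes = genotypes, calls = calls,
                 entropy_positions = pos - 1L, entropies = ent,
                 log = c(input_reads = nrow(demux), individuals_in = length(ids),
                         individuals_dropped = dropped,
                         alleles_deleted_rare = deleted_rare)),
            class = "allele_calls")
}

#' @export
print.allele_calls <- function(x, ...) {
  cat(sprintf("Allele calls: %d alleles over %d individuals (%d entropy positions)\n",
              nrow(x$calls), length(x$genotypes), length(x$entropy_positions)))
  invisible(x)
}

#' Mendelian trio consistency check
#'
#' Emits a violation for every offspring allele absent from the union of its
#' parents' allele sets. With `correct = TRUE`, offending alleles are removed
#' from the offspring's set (never below one allele). Trios with an
#' ungenotyped member are skipped and logged.
#'
#' @param genotypes Named list of allele sets for one gene.
#' @param trios Data frame `offspring_id`, `mother_id`, `father_id`.
#' @param correct Remove offending alleles from offspring genotypes.
#' @return List: `violations` (data frame `offspring_id`,
#'   `offending_alleles`), `genotypes` (corrected when requested),
#'   `skipped` (number of incomplete trios).
#' @export
mendelian_check <- function(genotypes, trios, correct = FALSE) {
  viol <- list(); skipped <- 0L
  for (i in seq_len(nrow(trios))) {
    o <- trios$offspring_id[i]; m <- trios$mother_id[i]; f <- trios$father_id[i]
    if (is.null(genotypes[[o]]) || is.null(genotypes[[m]]) || is.null(genotypes[[f]])) {
      skipped <- skipped + 1L
      next
    }
    bad <- setdiff(genotypes[[o]], union(genotypes[[m]], genotypes[[f]]))
    if (length(bad) > 0) {
      viol[[length(viol) + 1L]] <- data.frame(
        offspring_id = o, offending_alleles = set_to_string(bad),
        stringsAsFactors = FALSE)
      if (correct) {
        kept <- setdiff(genotypes[[o]], bad)
        if (length(kept) >= 1) genotypes[[o]] <- kept
      }
    }
  }
  list(violations = if (length(viol) > 0) do.call(rbind, viol) else
         data.frame(offspring_id = character(0), offending_alleles = character(0)),
       genotypes = genotypes, skipped = skipped)
}

#' Repeatability of allele calling over replicate pairs
#'
#' Agreement between independently called genotypes of replicated samples.
#' The default metric is the Jaccard agreement `|A intersect B| / |A union B|`
#' averaged over pairs; `method = "exact"` scores a pair 1 when the sets are
#' identical and 0 otherwise. Pairs with an empty or missing genotype are
#' excluded and counted.
#'
#' @param genotypes Named list of allele sets.
#' @param replicate_pairs Data frame with columns `id_a`, `id_b`.
#' @param method `"jaccard"` or `"exact"`.
#' @return List: `mean` (fraction in `[0, 1]`), `per_pair` (data frame),
#'   `excluded`.
#' @export
repeatability <- function(genotypes, replicate_pairs,
                          method = c("jaccard", "exact")) {
  method <- match.arg(method)
  fail_if(nrow(replicate_pairs) < 1, "at least one replicate pair required")
  scores <- numeric(0); rows <- list(); excluded <- 0L
  for (i in seq_len(nrow(replicate_pairs))) {
    a <- genotypes[[replicate_pairs$id_a[i]]]
    b <- genotypes[[replicate_pairs$id_b[i]]]
    if (is.null(a) || is.null(b) || length(a) == 0 || length(b) == 0) {
      excluded <- excluded + 1L
      next
    }
    s <- if (method == "jaccard") {
      length(intersect(a, b)) / length(union(a, b))
    } else as.numeric(setequal(a, b))
    scores <- c(scores, s)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = replicate_pairs$id_a[i], id_b = replicate_pairs$id_b[i],
      agreement = s, stringsAsFactors = FALSE)
  }
  fail_if(length(scores) == 0, "no usable replicate pairs")
  list(mean = mean(scores), per_pair = do.call(rbind, rows), excluded = excluded)
}
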