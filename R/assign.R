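# Assignment of cDNA reads to HML-2 loci by diagnostic mismatches.

#' Assignment parameters
#'
#' @param max_mismatch maximum number of sequence differences for an
#'   assignment (default 2, i.e. reads are assigned when they match a locus
#'   with less than three mismatches).
#' @param indel_policy how indels count: `"per_run"` (one event per gap run,
#'   default) or `"per_base"`.
#' @param omit_np9_exon2 mask the short (23 nt excluding primer) exon 2 of
#'   np9 inserts during comparison (default TRUE). Masking is positional —
#'   differences falling in the masked columns are ignored — so coordinates
#'   stay interpretable.
#' @param min_read_len reads shorter than this (after trimming) are rejected
#'   (default 50).
#' @param orient_threshold if the best forward-orientation difference count
#'   exceeds this, the reverse complement is also tried and the better
#'   orientation kept (default 10).
#' @return list of class `hml2_assignment_params`.
#' @export
assignment_params <- function(max_mismatch = 2L,
                              indel_policy = c("per_run", "per_base"),
                              omit_np9_exon2 = TRUE,
                              min_read_len = 50L,
                              orient_threshold = 10L) {
  stopifnot(max_mismatch >= 0L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 indel_policy = match.arg(indel_policy),
                 omit_np9_exon2 = isTRUE(omit_np9_exon2),
                 min_read_len = as.integer(min_read_len),
                 orient_threshold = as.integer(orient_threshold)),
            class = "hml2_assignment_params")
}

# difference counts of one read set against every db entry; returns matrix
# reads x entries (masking applied per entry). A comparison that covers less
# than `min_coverage` of the longer of read and insert is no match at all
# (free end gaps must not let a partial overlap pass for an assignment).
.diff_matrix <- function(seqs, db, params, min_coverage = 0.9) {
  n <- length(seqs)
  m <- nrow(db)
  cnt <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    cm <- .compare_many(seqs, db$insert[j])
    mask <- if (params$omit_np9_exon2) db$mask_len[j] else 0L
    cj <- vapply(seq_len(n), function(i)
      .cm_count(cm, i, params$indel_policy, mask), 0L)
    need <- min_coverage * pmax(nchar(seqs), nchar(db$insert[j]))
    cj[cm$lengths < need] <- .Machine$integer.max
    cnt[, j] <- cj
  }
  cnt
}

#' Assign cDNA reads to loci against an amplicon database
#'
#' Compares each read with every predicted insert of the amplicon database
#' ([build_amplicon_db()]) and assigns it to the locus with the unique
#' minimal difference count at or below `max_mismatch`. Ties at the minimum
#' produce an `ambiguous` call carrying the full tie group (ambiguity is
#' reported, never resolved); reads whose minimum exceeds `max_mismatch` are
#' `unassignable`; reads shorter than `min_read_len` are `rejected`. When
#' `omit_np9_exon2` is set, differences inside the short np9 exon 2 are
#' ignored. Reads are compared in forward orientation after an orientation
#' check (best of read versus its reverse complement).
#'
#' @param reads data.frame with columns `read_id`, `seq` and optionally
#'   `tissue`; or a character vector of sequences.
#' @param db amplicon database from [build_amplicon_db()].
#' @param params an [assignment_params()] object.
#' @return data.frame of class `hml2_assignment`: columns `read_id`,
#'   `tissue`, `status` (`assigned`, `ambiguous`, `unassignable`,
#'   `rejected`), `locus` (best locus or `|`-collapsed ambiguity group),
#'   `isoform`, `mismatches`, `orientation`.
#' @export
assign_reads <- function(reads, db, params = assignment_params()) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  if (!"tissue" %in% names(reads)) reads$tissue <- NA_character_
  if (nrow(db) == 0L) stop("amplicon database is empty", call. = FALSE)
  n <- nrow(reads)
  res <- data.frame(read_id = reads$read_id, tissue = reads$tissue,
                    status = rep("rejected", n), locus = NA_character_,
                    isoform = NA_character_, mismatches = NA_integer_,
                    orientation = "+", stringsAsFactors = FALSE)
  seqs <- toupper(reads$seq)
  ok <- nchar(seqs) >= params$min_read_len
  if (any(ok)) {
    idx <- which(ok)
    cnt <- .diff_matrix(seqs[idx], db, params)
    # orientation check for reads that look wrong in forward sense
    mins <- apply(cnt, 1L, min)
    flip <- which(mins > params$orient_threshold)
    if (length(flip)) {
      rc <- vapply(seqs[idx][flip], .revcomp, "")
      cnt_rc <- .diff_matrix(rc, db, params)
      better <- apply(cnt_rc, 1L, min) < mins[flip]
      if (any(better)) {
        cnt[flip[better], ] <- cnt_rc[better, , drop = FALSE]
        res$orientation[idx[flip[better]]] <- "-"
      }
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      counts <- cnt[k, ]
      mn <- min(counts)
      if (mn > params$max_mismatch) {
        res$status[i] <- "unassignable"
        res$mismatches[i] <- if (mn == .Machine$integer.max) NA_integer_ else mn
        next
      }
      best <- which(counts == mn)
      best_loci <- unique(db$locus_id[best])
      res$mismatches[i] <- mn
      if (length(best_loci) == 1L) {
        res$status[i] <- "assigned"
        res$locus[i] <- best_loci
        res$isoform[i] <- db$isoform[best[1L]]
      } else {
        res$status[i] <- "ambiguous"
        res$locus[i] <- paste(sort(best_loci), collapse = "|")
        res$isoform[i] <- db$isoform[best[1L]]
      }
    }
  }
  class(res) <- c("hml2_assignment", class(res))
  res
}

#' Assign a single read
#'
#' Convenience wrapper around [assign_reads()] for one sequence.
#'
#' @param read nucleotide string.
#' @param db amplicon database.
#' @param params an [assignment_params()].
#' @return single-row `hml2_assignment` data.frame.
#' @export
assign_read <- function(read, db, params = assignment_params()) {
  assign_reads(data.frame(read_id = "read1", seq = read,
                          stringsAsFactors = FALSE), db, params)
}

#' Match unassignable reads against non-reference loci
#'
#' Partitions reads that could not be assigned to any reference locus by
#' comparing them with the predicted spliced inserts of proviruses absent
#' from the reference assembly (e.g. HERV-K111, the Venter locus). A read is
#' "identical to X" iff it shows zero differences over the comparable region
#' of X's predicted insert; reads identical to several entries (which differ
#' only outside the compared window) are labelled `ambiguous_nonref`; reads
#' identical to none are `unmatched`.
#'
#' @param reads data.frame with `read_id` and `seq` (e.g. the unassignable
#'   subset of an [assign_reads()] result joined back to sequences).
#' @param nonref_db amplicon database built from the annotated non-reference
#'   loci ([build_amplicon_db()]); entries with no predictable amplicon are
#'   simply absent from it (a warning is emitted at build time by the
#'   amplicon predictor).
#' @param min_overlap_frac minimum fraction of the insert that must be
#'   covered by the comparison for an "identical" call; shorter overlaps are
#'   flagged (default 0.5).
#' @return list of class `hml2_nonref_partition`: `table` (per-read
#'   data.frame with `read_id`, `subset`, `overlap_flagged`) and `counts`
#'   (named vector over `identical_to_<id>`, `ambiguous_nonref`,
#'   `unmatched`).
#' @export
match_nonreference <- function(reads, nonref_db, min_overlap_frac = 0.5) {
  if (nrow(nonref_db) == 0L) stop("non-reference database is empty",
                                  call. = FALSE)
  n <- nrow(reads)
  seqs <- toupper(reads$seq)
  hit <- matrix(FALSE, n, nrow(nonref_db))
  short <- matrix(FALSE, n, nrow(nonref_db))
  for (j in seq_len(nrow(nonref_db))) {
    cm <- .compare_many(seqs, nonref_db$insert[j])
    cnts <- cm$n_mism + cm$gap_runs
    hit[, j] <- cnts == 0L & cm$lengths > 0L
    short[, j] <- cm$lengths < min_overlap_frac * nchar(nonref_db$insert[j])
  }
  subset <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    js <- which(hit[i, ])
    if (length(js) == 0L) subset[i] <- "unmatched"
    else if (length(js) == 1L) {
      subset[i] <- paste0("identical_to_", nonref_db$locus_id[js])
      flagged[i] <- short[i, js]
    } else {
      subset[i] <- "ambiguous_nonref"
      flagged[i] <- any(short[i, js])
    }
  }
  tab <- data.frame(read_id = reads$read_id, subset = subset,
                    overlap_flagged = flagged, stringsAsFactors = FALSE)
  lv <- c(paste0("identical_to_", nonref_db$locus_id),
          "ambiguous_nonref", "unmatched")
  counts <- table(factor(subset, levels = lv))
  structure(list(table = tab, counts = c(counts)),
            class = "hml2_nonref_partition")
}

#' Tabulate assignment counts per tissue
#'
#' Builds the tissue-by-locus count table of an assignment run: one row per
#' assigned locus and per ambiguity group, optional rows for non-reference
#' identities, one `not_assignable` row, and a `total` row holding the
#' per-tissue read counts. Ambiguous reads are counted once, under their
#' ambiguity-group row.
#'
#' @param results an [assign_reads()] result (`tissue` column filled).
#' @param nonref optional [match_nonreference()] result; its per-read subsets
#'   replace the `not_assignable` row contribution of those reads.
#' @return integer matrix (loci x tissues) with a final `total` row.
#' @export
tabulate_counts <- function(results, nonref = NULL) {
  stopifnot(inherits(results, "hml2_assignment"))
  lab <- ifelse(results$status %in% c("assigned", "ambiguous"),
                results$locus, "not_assignable")
  lab[results$status == "rejected"] <- "rejected"
  if (!is.null(nonref)) {
    m <- match(results$read_id, nonref$table$read_id)
    take <- !is.na(m) & nonref$table$subset[m] != "unmatched"
    lab[take] <- nonref$table$subset[m][take]
  }
  tissues <- unique(results$tissue)
  rows <- unique(lab)
  # ordering: assigned loci, nonref subsets, ambiguity groups, then sinks
  is_sink <- rows %in% c("not_assignable", "rejected")
  is_nonref <- grepl("^(identical_to_|ambiguous_nonref)", rows)
  is_ambig <- grepl("\\|", rows)
  ord <- order(is_sink * 2L + (is_nonref | is_ambig), rows)
  rows <- rows[ord]
  tab <- matrix(0L, length(rows), length(tissues),
                dimnames = list(rows, tissues))
  for (k in seq_len(nrow(results)))
    tab[lab[k], results$tissue[k]] <- tab[lab[k], results$tissue[k]] + 1L
  rbind(tab, total = colSums(tab))
}
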