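# In-silico PCR with the degenerate rec/np9 primer pools.

#' The multiplex degenerate rec/np9 primer pool
#'
#' Returns the forward and reverse primer pools used for amplifying `rec` and
#' `np9` mRNA/cDNA: four forward primers mixed 85/5/5/5 and two reverse
#' primers mixed 95/5. The forward primers overlap the shared
#' Env/Rec/Np9 start codon in exon 2; the reverse primers bind in exon 3.
#' Weights are used only by the read simulator (to sample which primer
#' "amplified" a molecule); primer matching ignores them.
#'
#' @return An object of class `hml2_primer_pool`: list with data.frames
#'   `forward` and `reverse` (`name`, `seq`, `weight`).
#' @export
primer_pool <- function() {
  fwd <- data.frame(
    name = paste0("rec-np9-for-", 1:4),
    seq = c("ATGAACCCATCAGAGATGCAA",
            "ATGAATCCATCAGAGATGCAA",
            "GCGAACCCTTCAGAGATGCAA",
            "ATGAACCCATCGGAGATGAAA"),
    weight = c(85, 5, 5, 5),
    stringsAsFactors = FALSE
  )
  rev <- data.frame(
    name = paste0("rec-np9-rev-", 1:2),
    seq = c("AGCATCTGTTTAACAAAGCA",
            "AGCATGTTTAACAAAGCA"),
    weight = c(95, 5),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(fwd$weight) == 100, sum(rev$weight) == 100)
  structure(list(forward = fwd, reverse = rev), class = "hml2_primer_pool")
}

# All binding sites of one primer on a template, ungapped, with at most
# max_mismatch mismatches and the 3'-terminal `exact3` bases exact.
# `sense = "fwd"` matches the primer itself; `sense = "rev"` matches its
# reverse complement (so the primer's 3' end maps to the site's left edge).
.primer_hits <- function(primer, template, max_mismatch, sense, exact3 = 3L) {
  pat <- if (sense == "rev") .revcomp(primer) else primer
  subj <- Biostrings::DNAString(template)
  m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
  if (length(m) == 0L) return(NULL)
  starts <- Biostrings::start(m)
  mm <- vapply(starts, function(s)
    Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                starting.at = s), 0L)
  w <- nchar(pat)
  ok <- vapply(seq_along(starts), function(i) {
    site <- substr(template, starts[i], starts[i] + w - 1L)
    if (sense == "fwd") substr(site, w - exact3 + 1L, w) ==
                        substr(pat, w - exact3 + 1L, w)
    else substr(site, 1L, exact3) == substr(pat, 1L, exact3)
  }, logical(1))
  if (!any(ok)) return(NULL)
  data.frame(start = starts[ok], end = starts[ok] + w - 1L,
             mismatches = mm[ok], stringsAsFactors = FALSE)
}

#' Predict the PCR amplicon of a template
#'
#' Matches the degenerate primer pools against a transcript (or any
#' template) by ungapped sliding-window comparison: at most
#' `max_primer_mismatch` mismatches per primer with the 3'-terminal 3 nt
#' required exact. The reverse primers are matched as their reverse
#' complement. Returns the product between the best-matching forward and
#' reverse sites; when several forward (reverse) sites qualify, the
#' leftmost-outermost (rightmost-outermost) product is returned with a
#' warning.
#'
#' @param template a [splice()] isoform or a nucleotide string.
#' @param pool a [primer_pool()].
#' @param max_primer_mismatch maximum mismatches per primer site (default 2).
#' @return `NULL` when either primer finds no site; otherwise a list of class
#'   `hml2_amplicon` with `product` and `insert` sequences (the insert
#'   excludes the primer regions), 1-based `product_range` / `insert_range`
#'   on the template, primer names and mismatch counts.
#' @export
predict_amplicon <- function(template, pool = primer_pool(),
                             max_primer_mismatch = 2L) {
  seq <- if (inherits(template, "hml2_isoform")) template$seq else template
  best_side <- function(primers, sense) {
    hits <- NULL
    for (i in seq_len(nrow(primers))) {
      h <- .primer_hits(primers$seq[i], seq, max_primer_mismatch, sense)
      if (!is.null(h)) {
        h$primer <- primers$name[i]
        hits <- rbind(hits, h)
      }
    }
    if (is.null(hits)) return(NULL)
    hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
    # outermost product: leftmost forward site, rightmost reverse site
    pick <- if (sense == "fwd") which.min(hits$start) else which.max(hits$start)
    if (length(unique(hits$start)) > 1L)
      warning(sprintf("multiple %s primer sites; using %s",
                      if (sense == "fwd") "forward" else "reverse",
                      if (sense == "fwd") "leftmost" else "rightmost"))
    hits[pick, , drop = FALSE]
  }
  f <- best_side(pool$forward, "fwd")
  r <- best_side(pool$reverse, "rev")
  if (is.null(f) || is.null(r) || r$start <= f$end) return(NULL)
  structure(list(
    product = substr(seq, f$start, r$end),
    insert = substr(seq, f$end + 1L, r$start - 1L),
    product_range = c(f$start, r$end),
    insert_range = c(f$end + 1L, r$start - 1L),
    fwd_primer = f$primer, rev_primer = r$primer,
    fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches
  ), class = "hml2_amplicon")
}

#' Build the amplicon database of a locus panel
#'
#' Predicts, for every annotated locus, the spliced isoform(s) it can
#' produce under the rec/np9 primer pools and tabulates the resulting
#' inserts (the primer-excluded sequences used as the unit of read
#' assignment). Type 2 loci contribute their `rec` isoform; type 1 loci
#' their `np9` isoform, or `np9_alt` when the canonical SA2/SD2_np9 sites
#' are dead but the alternative +252/+7 site pair is intact; retrocopy loci
#' (intron-less) are amplified directly from their genomic sequence — the
#' reason genomic-DNA traces are indistinguishable from their cDNA products.
#'
#' @param loci list of annotated loci ([annotate_loci()]).
#' @param pool a [primer_pool()].
#' @param max_primer_mismatch maximum mismatches per primer site.
#' @return data.frame of class `hml2_amplicon_db` with columns `locus_id`,
#'   `isoform`, `insert`, `product`, `mask_len` (length of the short np9
#'   exon 2 portion inside the insert, used for exon-2 masking) and
#'   `genomic` (TRUE for intron-less templates), ordered by locus and
#'   isoform.
#' @export
build_amplicon_db <- function(loci, pool = primer_pool(),
                              max_primer_mismatch = 2L) {
  rows <- list()
  for (l in loci) {
    eff_type <- if (identical(l$provirus_type, "retrocopy")) "retrocopy"
                else if (isTRUE(l$type %in% c("type1", "type2"))) l$type
                else l$provirus_type
    entries <- list()
    if (eff_type == "retrocopy") {
      amp <- predict_amplicon(l$seq, pool, max_primer_mismatch)
      if (!is.null(amp))
        entries[["rec"]] <- list(amp = amp, mask = 0L, genomic = TRUE)
    } else if (eff_type == "type2") {
      entries[["rec"]] <- .db_isoform_entry(l, "rec", pool,
                                            max_primer_mismatch)
    } else if (eff_type == "type1") {
      e <- .db_isoform_entry(l, "np9", pool, max_primer_mismatch)
      if (is.null(e))
        e <- .db_isoform_entry(l, "np9_alt", pool, max_primer_mismatch)
      entries[[if (is.null(e)) "none" else e$iso]] <- e
    }
    for (nm in names(entries)) {
      e <- entries[[nm]]
      if (is.null(e) || is.null(e$amp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = l$locus_id, isoform = nm,
        insert = e$amp$insert, product = e$amp$product,
        mask_len = e$mask, genomic = e$genomic,
        stringsAsFactors = FALSE
      )
    }
  }
  db <- if (length(rows)) do.call(rbind, rows)
        else data.frame(locus_id = character(), isoform = character(),
                        insert = character(), product = character(),
                        mask_len = integer(), genomic = logical(),
                        stringsAsFactors = FALSE)
  db <- db[order(db$locus_id, db$isoform), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("hml2_amplicon_db", class(db))
  db
}

.db_isoform_entry <- function(locus, iso, pool, max_primer_mismatch) {
  tx <- tryCatch(splice(locus, iso), hml2_splice_error = function(e) NULL)
  if (is.null(tx)) return(NULL)
  amp <- predict_amplicon(tx, pool, max_primer_mismatch)
  if (is.null(amp)) return(NULL)
  mask <- 0L
  if (iso == "np9") {
    # the short (little informative) np9 exon 2 portion of the insert: from
    # the insert start to the end of exon 2 in transcript coordinates
    exon2_end_tx <- sum(tx$exons[1:2, 2] - tx$exons[1:2, 1])
    mask <- max(0L, exon2_end_tx - (amp$insert_range[1] - 1L))
  }
  list(amp = amp, mask = as.integer(mask), genomic = FALSE, iso = iso)
}
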