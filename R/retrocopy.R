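# L1-mediated retrocopy detection: target site duplications, poly-A tails,
# and exon-junction coincidence with a spliced mRNA model.

#' Find a target site duplication around an insertion
#'
#' L1-mediated insertions are flanked by short direct repeats (target site
#' duplications, TSDs): the duplicated word ends at the 5' insertion point
#' and begins again at the 3' insertion point (after the poly-A tail). The
#' longest duplicated word within the length bounds is reported (exact match
#' by default).
#'
#' @param flank5,flank3 genomic flanks immediately 5' and 3' of the
#'   insertion (the 3' flank starts after the poly-A tail); each must supply
#'   at least `max_len` nt.
#' @param min_len,max_len TSD length bounds (defaults 6 and 25; L1 TSDs are
#'   typically 7-20 nt).
#' @param max_mismatch mismatches tolerated between the two copies
#'   (default 0).
#' @return list with `tsd` (sequence) and `tsd_len`, or `NULL` when no
#'   duplicated word of at least `min_len` exists. Flanks shorter than
#'   `max_len` give an `inconclusive` error.
#' @export
find_tsd <- function(flank5, flank3, min_len = 6L, max_len = 25L,
                     max_mismatch = 0L) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (nchar(flank5) < max_len || nchar(flank3) < max_len)
    stop("flanks shorter than max_len (", max_len,
         " nt); TSD search inconclusive", call. = FALSE)
  n5 <- nchar(flank5)
  for (len in seq(max_len, min_len)) {
    a <- substr(flank5, n5 - len + 1L, n5)
    b <- substr(flank3, 1L, len)
    if (.hamming(a, b) <= max_mismatch)
      return(list(tsd = a, tsd_len = len))
  }
  NULL
}

#' Call a poly-A tail at the 3' end of an insertion
#'
#' Scans the 3'-terminal window of an insertion-forward candidate for an
#' A-run meeting length and purity thresholds: the longest terminal suffix
#' (up to `window` nt) whose A-fraction is at least `min_purity` and length
#' at least `min_len`. Also reports whether an AATAAA poly-A signal hexamer
#' occurs upstream of the tail.
#'
#' @param candidate nucleotide string, insertion-forward orientation.
#' @param min_len minimum tail length (default 8).
#' @param min_purity minimum A-fraction of the tail (default 0.8).
#' @param window terminal window scanned (default 50 nt).
#' @param signal_window how far upstream of the tail to look for AATAAA
#'   (default 100 nt).
#' @return list with `present`, `length`, `purity`, `polyA_signal`.
#' @export
find_polyA <- function(candidate, min_len = 8L, min_purity = 0.8,
                       window = 50L, signal_window = 100L) {
  s <- toupper(candidate)
  n <- nchar(s)
  w <- min(window, n)
  tail_chars <- strsplit(substr(s, n - w + 1L, n), "")[[1]]
  is_a <- rev(tail_chars) == "A"  # from the 3' end inwards
  best_len <- 0L; best_purity <- 0
  if (is_a[1L]) {
    # max-score suffix: +1 per A, -p per non-A with p chosen so the
    # break-even purity equals min_purity; longest suffix on score ties
    penalty <- min_purity / (1 - min_purity)
    score <- cumsum(ifelse(is_a, 1, -penalty))
    cand_len <- which(score >= max(score) - 1e-9)
    len <- cand_len[length(cand_len)]
    purity <- sum(is_a[seq_len(len)]) / len
    if (len >= min_len && purity >= min_purity) {
      best_len <- len; best_purity <- purity
    }
  }
  if (best_len == 0L)
    return(list(present = FALSE, length = 0L, purity = NA_real_,
                polyA_signal = FALSE))
  up_start <- max(1L, n - best_len - signal_window + 1L)
  upstream <- substr(s, up_start, n - best_len)
  list(present = TRUE, length = best_len, purity = best_purity,
       polyA_signal = grepl("AATAAA", upstream, fixed = TRUE))
}

#' Match internal deletions of a candidate against a spliced mRNA model
#'
#' Tests whether the sequence portions missing from a candidate locus
#' relative to the canonical provirus are exactly the introns of a spliced
#' mRNA model, i.e. whether the deletion boundaries coincide with the
#' model's splice donor/acceptor sites. Each expected exon-exon junction is
#' probed with the spliced join sequence (`probe_half` nt either side of the
#' junction) located in the candidate with bounded mismatches; retained
#' introns fail their probe because the join does not exist genomically.
#' The 5' truncation is the distance from the model's transcript start to
#' the first candidate-aligned base of the mRNA.
#'
#' @param candidate nucleotide string (insertion-forward, poly-A tail
#'   allowed).
#' @param mrna_model a [splice()] isoform on the canonical anatomy (for
#'   instance the canonical rec mRNA).
#' @param tol junction tolerance in nt (default 3); probe hits are accepted
#'   at shifted joins up to this offset and the offset reported.
#' @param probe_half half-width of junction probes (default 20 nt).
#' @param max_probe_mismatch mismatches tolerated per probe (default 4,
#'   absorbing sequence divergence of the retrocopied lineage).
#' @return list with `junctions` (data.frame `intron`, `matched`,
#'   `offset_error`), `five_prime_truncation_len` (NA when the candidate
#'   start cannot be placed on the model transcript), `coverage` (fraction
#'   of sampled candidate k-mers found in the model transcript or provirus)
#'   and `inconclusive` (TRUE when coverage < 0.3).
#' @export
match_junctions <- function(candidate, mrna_model, tol = 3L,
                            probe_half = 20L, max_probe_mismatch = 4L) {
  stopifnot(inherits(mrna_model, "hml2_isoform"))
  cand <- toupper(candidate)
  # strip a terminal poly-A tail so it cannot mask the 3' sequence
  pa <- find_polyA(cand)
  if (pa$present) cand <- substr(cand, 1L, nchar(cand) - pa$length)
  cand_dna <- Biostrings::DNAString(cand)
  exons <- mrna_model$exons
  model_seq <- mrna_model$seq

  # locus coordinates are those of the model's source (canonical anatomy)
  junctions <- NULL
  if (nrow(exons) >= 2L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      up_end <- exons[i, 2]      # exon i end (half-open): donor at up_end
      down_start <- exons[i + 1L, 1]
      matched <- FALSE; off <- NA_integer_
      for (d in c(0L, seq_len(tol), -seq_len(tol))) {
        # spliced join shifted by d at the donor side
        probe <- paste0(
          .sub0(.mj_locus_seq(mrna_model), up_end - probe_half + d, up_end + d),
          .sub0(.mj_locus_seq(mrna_model), down_start + d,
                down_start + probe_half + d))
        if (nchar(probe) < 2L * probe_half) next
        hits <- Biostrings::matchPattern(probe, cand_dna,
                                         max.mismatch = max_probe_mismatch)
        if (length(hits) > 0L) { matched <- TRUE; off <- d; break }
      }
      junctions <- rbind(junctions, data.frame(
        intron = i, matched = matched, offset_error = off,
        stringsAsFactors = FALSE))
    }
  }

  # 5' truncation: place the candidate start on the model transcript
  trunc <- NA_integer_
  k <- min(30L, nchar(cand))
  prefix <- substr(cand, 1L, k)
  hits <- Biostrings::matchPattern(prefix, Biostrings::DNAString(model_seq),
                                   max.mismatch = 3L)
  if (length(hits) > 0L)
    trunc <- Biostrings::start(hits)[1L] - 1L

  # coverage: fraction of sampled candidate 24-mers present in the provirus
  cov <- .kmer_coverage(cand, .mj_locus_seq(mrna_model))
  list(junctions = junctions, five_prime_truncation_len = trunc,
       coverage = cov, inconclusive = cov < 0.3)
}

# genomic sequence of the model's source locus (attached by splice() callers
# via attribute, else reconstructed from the canonical anatomy)
.mj_locus_seq <- function(mrna_model) {
  s <- attr(mrna_model, "locus_seq")
  if (!is.null(s)) return(s)
  hml2_anatomy()$seq
}

.kmer_coverage <- function(candidate, genomic, k = 24L, stride = 50L) {
  n <- nchar(candidate)
  if (n < k) return(0)
  starts <- seq(1L, n - k + 1L, by = stride)
  g <- Biostrings::DNAString(genomic)
  hits <- vapply(starts, function(s) {
    km <- substr(candidate, s, s + k - 1L)
    if (grepl("N", km)) return(FALSE)
    length(Biostrings::matchPattern(km, g, max.mismatch = 1L)) > 0L
  }, logical(1))
  mean(hits)
}

#' Classify retrocopy evidence
#'
#' Combines the three L1 retrotransposition hallmarks: `retrocopy` iff the
#' TSD length is within bounds AND a poly-A tail is present AND every
#' expected exon junction matched within tolerance; exactly two of the
#' three hallmarks give `inconclusive`; otherwise `not_retrocopy`.
#'
#' @param evidence a list as assembled by [detect_retrocopy()] (fields
#'   `tsd_len`, `polyA`, `junction_matches`).
#' @param tsd_bounds admissible TSD length range (default `c(6, 25)`).
#' @return character verdict.
#' @export
classify_retrocopy <- function(evidence, tsd_bounds = c(6L, 25L)) {
  tsd_ok <- !is.na(evidence$tsd_len) &&
    evidence$tsd_len >= tsd_bounds[1] && evidence$tsd_len <= tsd_bounds[2]
  polya_ok <- isTRUE(evidence$polyA$present)
  jm <- evidence$junction_matches
  junc_ok <- !is.null(jm) && nrow(jm) > 0L && all(jm$matched)
  n_ok <- sum(tsd_ok, polya_ok, junc_ok)
  if (n_ok == 3L) "retrocopy" else if (n_ok == 2L) "inconclusive"
  else "not_retrocopy"
}

#' Decide whether a candidate locus is an L1-mediated retrocopy
#'
#' Runs all three hallmark scans — target site duplication in the flanks,
#' 3' poly-A tail, and exon-junction coincidence with the spliced mRNA
#' model — and classifies the candidate. Detection is invariant to the
#' candidate's genomic strand: when the forward orientation covers the
#' model poorly, the reverse complement (with swapped, complemented flanks)
#' is used.
#'
#' @param candidate insertion sequence (locus only, flanks separate).
#' @param flank5,flank3 flanking sequences around the insertion.
#' @param mrna_model spliced mRNA model ([splice()] isoform on the canonical
#'   anatomy); defaults to the canonical rec mRNA.
#' @param anatomy a [hml2_anatomy()].
#' @param tsd_bounds,junction_tol detection parameters (defaults 6-25 nt
#'   and +/-3 nt).
#' @return list of class `hml2_retrocopy_evidence`: `tsd_seq`, `tsd_len`,
#'   `polyA`, `junction_matches`, `five_prime_truncation_len`, `coverage`,
#'   `strand`, `verdict`.
#' @export
detect_retrocopy <- function(candidate, flank5, flank3,
                             mrna_model = NULL, anatomy = hml2_anatomy(),
                             tsd_bounds = c(6L, 25L), junction_tol = 3L) {
  if (is.null(mrna_model)) mrna_model <- canonical_rec_mrna(anatomy)
  run <- function(cand, f5, f3, strand) {
    tsd <- tryCatch(find_tsd(f5, f3, min_len = tsd_bounds[1],
                             max_len = tsd_bounds[2]),
                    error = function(e) NULL)
    pa <- find_polyA(cand)
    mj <- match_junctions(cand, mrna_model, tol = junction_tol)
    ev <- list(tsd_seq = tsd$tsd %||% NA_character_,
               tsd_len = tsd$tsd_len %||% NA_integer_,
               polyA = pa, junction_matches = mj$junctions,
               five_prime_truncation_len = mj$five_prime_truncation_len,
               coverage = mj$coverage, strand = strand)
    ev$verdict <- if (mj$inconclusive && is.null(tsd) && !pa$present)
      "not_retrocopy" else classify_retrocopy(ev, tsd_bounds)
    ev
  }
  fwd <- run(toupper(candidate), toupper(flank5), toupper(flank3), "+")
  if (fwd$coverage < 0.3) {
    rev <- run(.revcomp(candidate), .revcomp(flank3), .revcomp(flank5), "-")
    if (rev$coverage > fwd$coverage) fwd <- rev
  }
  class(fwd) <- "hml2_retrocopy_evidence"
  fwd
}

#' Canonical rec mRNA model
#'
#' The rec transcript of the canonical anatomy, with the anatomy's genomic
#' sequence attached for junction probing.
#'
#' @param anatomy a [hml2_anatomy()].
#' @return a [splice()] isoform.
#' @export
canonical_rec_mrna <- function(anatomy = hml2_anatomy()) {
  key <- "rec_mrna"
  m <- .anatomy_cache[[key]]
  if (!is.null(m)) return(m)
  l <- hml2_locus("canonical", "chrU", 1L, nchar(anatomy$seq), "+",
                  anatomy$seq, "type2")
  l <- annotate_locus(l, anatomy)
  m <- splice(l, "rec")
  attr(m, "locus_seq") <- anatomy$seq
  .anatomy_cache[[key]] <- m
  m
}

#' @export
print.hml2_retrocopy_evidence <- function(x, ...) {
  cat(sprintf("<hml2_retrocopy_evidence> verdict: %s (strand %s)\n",
              x$verdict, x$strand))
  cat(sprintf("  TSD: %s (%s nt)\n", x$tsd_seq,
              x$tsd_len %||% NA))
  cat(sprintf("  poly-A: present=%s len=%s signal=%s\n", x$polyA$present,
              x$polyA$length, x$polyA$polyA_signal))
  if (!is.null(x$junction_matches))
    cat(sprintf("  junctions matched: %d/%d; 5' truncation: %s nt\n",
                sum(x$junction_matches$matched), nrow(x$junction_matches),
                x$five_prime_truncation_len))
  invisible(x)
}
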