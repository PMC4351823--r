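# Detection of alternative splicing in cDNA reads: the +252/+7 alternative
# donor/acceptor pattern and novel GT..AG introns relative to a locus's
# full-length cDNA.

#' Detect an alternative splice variant in a read
#'
#' Aligns a read against the unspliced (genomic) amplified window of each
#' candidate locus model and interprets the internal deletions of the read
#' as introns. Two variant patterns are reported:
#'
#' * `np9_alt`: the deletion boundaries coincide with the alternative donor
#'   located 252 nt downstream of the canonical np9 SD2 and the alternative
#'   acceptor 7 nt downstream of the canonical SA2 (reported with both
#'   offsets);
#' * `novel_intron`: an internal deletion relative to the locus's
#'   full-length cDNA whose boundaries read `GT..AG` in the locus (such as
#'   the 334-nt intron spliced out of transcripts of the intron-less
#'   chromosome 10 locus).
#'
#' Deletions matching the locus's canonical rec/np9 intron are recognised as
#' canonical splicing and yield no variant call. When several loci explain
#' the read equally well, all interpretations are returned, flagged.
#'
#' @param read nucleotide string (primer-trimmed or full product).
#' @param locus_models list of annotated loci ([annotate_loci()]).
#' @param pool a [primer_pool()] (locates the amplified window on each
#'   locus).
#' @param tol positional tolerance in nt when comparing deletion boundaries
#'   to annotated splice sites (default 3).
#' @return `NULL` when the read is canonical or unalignable; otherwise a
#'   data.frame with one row per variant interpretation: `locus_id`,
#'   `pattern`, `intron_length`, `donor_offset`, `acceptor_offset`
#'   (offsets relative to SD2_np9 and SA2), `mismatches`, `tied`.
#' @export
detect_alt_splice_variant <- function(read, locus_models,
                                      pool = primer_pool(), tol = 3L) {
  read <- toupper(read)
  interp <- list()
  for (l in locus_models) {
    amp <- l$amp_window %||%
      predict_amplicon(l$seq, pool, max_primer_mismatch = 2L)
    if (is.null(amp)) next
    win0 <- amp$product_range[1] - 1L  # 0-based locus offset of window start
    window <- amp$product
    # intron-aware alignment: long gaps are near-free beyond opening, so an
    # intron-scale deletion beats a mismatch-dense ungapped alignment
    pa <- Biostrings::pairwiseAlignment(
      pattern = read, subject = window, type = "global-local",
      substitutionMatrix = .dna_submat(),
      gapOpening = 8, gapExtension = 0.05)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    ev <- .aln_events(ap, as_, Biostrings::start(Biostrings::subject(pa)))
    gaps <- ev$events[ev$events$type == "gap", , drop = FALSE]
    mism <- sum(ev$events$type == "mismatch")
    if (ev$length < 0.3 * nchar(read)) next
    dels <- gaps[gaps$len >= 20L, , drop = FALSE]  # intron-scale deletions
    if (!nrow(dels)) next
    p <- function(nm) .site_pos(l$sites, nm)
    rows <- NULL
    canonical <- TRUE
    for (g in seq_len(nrow(dels))) {
      # deletion occupies locus coords [don, acc] (0-based, inclusive)
      don <- win0 + dels$subject_pos[g] - 1L
      acc <- don + dels$len[g] - 1L
      # alignment gaps can slide within repeats: snap to the nearest
      # GT..AG-consistent placement within the tolerance
      for (d in c(0L, as.vector(rbind(seq_len(tol), -seq_len(tol))))) {
        if (identical(.sub0(l$seq, don + d, don + d + 2L), "GT") &&
            identical(.sub0(l$seq, acc + d - 1L, acc + d + 1L), "AG")) {
          don <- don + d; acc <- acc + d; break
        }
      }
      near <- function(x, y) !is.na(x) && !is.na(y) && abs(x - y) <= tol
      can_intron <-
        (near(don, p("SD2_rec")) && near(acc, p("SA2"))) ||
        (near(don, p("SD2_np9")) && near(acc, p("SA2")))
      if (can_intron) next
      canonical <- FALSE
      if (near(don, p("alt_SD")) && near(acc, p("alt_SA"))) {
        rows <- rbind(rows, data.frame(
          locus_id = l$locus_id, pattern = "np9_alt",
          intron_length = dels$len[g],
          donor_offset = don - p("SD2_np9"),
          acceptor_offset = acc - p("SA2"),
          mismatches = mism, stringsAsFactors = FALSE))
      } else {
        don_motif <- .sub0(l$seq, don, don + 2L)
        acc_motif <- .sub0(l$seq, acc - 1L, acc + 1L)
        if (identical(don_motif, "GT") && identical(acc_motif, "AG")) {
          rows <- rbind(rows, data.frame(
            locus_id = l$locus_id, pattern = "novel_intron",
            intron_length = dels$len[g],
            donor_offset = NA_integer_, acceptor_offset = NA_integer_,
            mismatches = mism, stringsAsFactors = FALSE))
        }
      }
    }
    if (!canonical && !is.null(rows))
      interp[[l$locus_id]] <- rows
  }
  if (!length(interp)) return(NULL)
  all_rows <- do.call(rbind, unname(interp))
  best <- min(all_rows$mismatches)
  all_rows <- all_rows[all_rows$mismatches == best, , drop = FALSE]
  all_rows$tied <- length(unique(all_rows$locus_id)) > 1L
  rownames(all_rows) <- NULL
  all_rows
}
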