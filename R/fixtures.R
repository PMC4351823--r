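# Deterministic named fixtures reproducing hallmark cases of multi-tissue rec/np9 surveys:
# the +245-nt alternative splice variant, the 334-nt novel intron of the
# chromosome-10-style intron-less locus, a TSD-flanked retrocopy, a pair of
# sequence-identical loci, and a Rec frame with a premature stop.

# rec/np9 mRNA assembly from known ancestor coordinates (generator-side
# arithmetic, independent of the alignment-based pipeline path)
.truth_mrna <- function(chars, which = c("rec", "np9")) {
  g <- .ANAT
  which <- match.arg(which)
  w <- if (which == "rec")
    list(c(g$tx_start, g$SD1), c(g$SA1 + 1L, g$SD2_rec),
         c(g$SA2 + 1L, g$tx_end))
  else {
    d <- g$disc_len  # chars are type 1 (discriminator excised)
    list(c(g$tx_start, g$SD1), c(g$SA1 + 1L, g$SD2_np9),
         c(g$SA2 + 1L - d, g$tx_end - d))
  }
  .extract_windows(chars, w)
}

#' Curated deterministic fixtures
#'
#' Builds the small named fixtures used throughout the test suite, all
#' derived in code from the canonical anatomy (fixed internal seeds; no
#' stored sequence data):
#'
#' * `ambig_pair` — two type 2 loci identical over the rec amplicon insert
#'   but diverged elsewhere, so their reads form an irreducible two-locus
#'   ambiguity group;
#' * `alt245` — a type 1 locus and its SA2-mutated (AG->GG) sibling that
#'   splices via the alternative +252 donor / +7 acceptor, whose insert is
#'   exactly 245 nt longer;
#' * `chr10_334` — an intron-less (retrocopy-style) locus whose full-length
#'   cDNA carries a cryptic GT..AG intron of 334 nt, plus a read in which
#'   that intron is spliced out;
#' * `retro5q15` — a retrocopy of the canonical rec mRNA: 250-nt
#'   5'-truncated, 30-nt poly-A tail, flanked by TTAAAAATGT target site
#'   duplications;
#' * `rec_stop20` — a type 2 locus whose Rec frame stops at triplet 20
#'   (19-aa product);
#' * `chimera` — a transcript fusing Rec codons 1-40 to Np9 codons 30-74.
#'
#' @param anatomy a [hml2_anatomy()].
#' @return named list of fixtures; see each element's `description` field.
#' @export
make_fixture_suite <- function(anatomy = hml2_anatomy()) {
  .with_seed(20150305L, .make_fixtures_impl(anatomy))
}

.make_fixtures_impl <- function(anatomy) {
  g <- .ANAT
  anc <- strsplit(anatomy$seq, "")[[1]]
  protected <- .protected_positions(anatomy)
  fx <- list()

  # --- ambiguity pair: identical over the product window -------------------
  a <- .diverge(anc, 0.01, protected)$chars
  b <- a
  outside <- setdiff(1500:5500, protected)  # gag/pol region, 0-based
  pos <- sample(outside, 10L)
  for (p in pos) b[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                             b[p + 1L]), 1L)
  fx$ambig_pair <- list(
    description = "two type 2 loci identical over the rec insert",
    locus_a = hml2_locus("AMBIG_A", "chr1", 1001L, 1000L + length(a), "+",
                         paste(a, collapse = ""), "type2"),
    locus_b = hml2_locus("AMBIG_B", "chr1", 2e6L, 2e6L - 1L + length(b), "+",
                         paste(b, collapse = ""), "type2"),
    insert = .extract_windows(a, .truth_windows("type2_rec")))

  # --- +245 alternative splice variant ------------------------------------
  lin <- .diverge(anc, 0.01, protected)$chars
  t1 <- lin[-((g$disc_start + 1L):(g$disc_start + g$disc_len))]
  mut <- lin
  mut[g$SA2] <- "G"  # SA2 AG -> GG (R index = 0-based SA2-1 + 1)
  t1_mut <- mut[-((g$disc_start + 1L):(g$disc_start + g$disc_len))]
  fx$alt245 <- list(
    description = "np9 vs np9_alt insert pair (+252/+7 alternative sites)",
    locus_np9 = hml2_locus("ALT_NP9", "chr3", 1001L, 1000L + length(t1), "+",
                           paste(t1, collapse = ""), "type1"),
    locus_alt = hml2_locus("ALT_K111", "chr7", 1001L, 1000L + length(t1_mut),
                           "+", paste(t1_mut, collapse = ""), "type1"),
    np9_insert = .extract_windows(t1, .truth_windows("type1_np9")),
    np9_alt_insert = .extract_windows(t1_mut, .truth_windows("type1_np9_alt")))

  # --- chromosome-10-style novel 334-nt intron ----------------------------
  mrna <- strsplit(.truth_mrna(anc, "rec"), "")[[1]]
  mrna <- .plant(mrna, 520L, "GT")
  mrna <- .plant(mrna, 852L, "AG")
  cdna <- paste(mrna, collapse = "")
  read_334 <- paste0(substr(cdna, 491L, 520L), substr(cdna, 855L, 1029L))
  fx$chr10_334 <- list(
    description = "intron-less locus with cryptic 334-nt GT..AG intron",
    locus = hml2_locus("CHR10_STYLE", "chr10", 1001L, 1000L + nchar(cdna),
                       "+", cdna, "retrocopy"),
    full_cdna = cdna,
    variant_read = read_334,
    intron_length = 334L)

  # --- retrocopy with TSD/poly-A/250-nt truncation ------------------------
  rc_mrna <- .truth_mrna(anc, "rec")
  tsd <- "TTAAAAATGT"
  candidate <- paste0(substr(rc_mrna, 251L, nchar(rc_mrna)), strrep("A", 30L))
  fx$retro5q15 <- list(
    description = "rec-mRNA retrocopy: TSD TTAAAAATGT, poly-A 30, 250-nt 5' truncation",
    candidate = candidate,
    flank5 = paste0(paste(sample(c("A", "C", "G", "T"), 40L, TRUE),
                          collapse = ""), tsd),
    flank3 = paste0(tsd, paste(sample(c("A", "C", "G", "T"), 40L, TRUE),
                               collapse = "")),
    tsd = tsd, truncation = 250L, polyA_len = 30L)

  # --- premature Rec stop at triplet 20 -----------------------------------
  s20 <- .plant(anc, g$env_start + 57L, "TAA")  # codon 20 of the Rec ORF
  fx$rec_stop20 <- list(
    description = "type 2 locus whose Rec ORF stops at triplet 20",
    locus = hml2_locus("REC_STOP20", "chr5", 1001L, 1000L + length(s20), "+",
                       paste(s20, collapse = ""), "type2"))

  # --- Rec/Np9 chimera transcript -----------------------------------------
  cds_start <- (g$SD1 - g$tx_start) + (g$env_start - g$SA1 - 1L)  # 0-based
  rec_cds <- substr(.truth_mrna(anc, "rec"), cds_start + 1L,
                    cds_start + 3L * 106L)
  anc_t1 <- anc[-((g$disc_start + 1L):(g$disc_start + g$disc_len))]
  np9_cds <- substr(.truth_mrna(anc_t1, "np9"), cds_start + 1L,
                    cds_start + 3L * 75L)
  fx$chimera <- list(
    description = "transcript fusing Rec codons 1-40 to Np9 codons 30-74",
    transcript = paste0(substr(rec_cds, 1L, 120L),
                        substr(np9_cds, 88L, 225L)),
    breakpoint = 40L)

  fx
}
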