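#' Canonical HERV-K(HML-2) type 2 provirus anatomy
#'
#' Builds the canonical provirus model every other stage of the pipeline is
#' referenced against: a synthetic ~9.5-kb type 2 provirus with long terminal
#' repeats (LTRs), the full splice-site set of the doubly spliced `rec` and
#' `np9` mRNAs, the 292-bp type 1/type 2 discriminator region located 50 bp
#' into the `env` coding sequence, and the binding windows of the degenerate
#' `rec`/`np9` PCR primer pools.
#'
#' The sequence is synthetic (built deterministically in code, so the package
#' carries no third-party sequence data) but its geometry reproduces the
#' field's canonical type 2 anatomy:
#'
#' * the `rec` splice donor (SD2_rec) lies inside the 292-bp discriminator,
#'   220 nt downstream of the `np9` donor (SD2_np9), so the `rec` and `np9`
#'   PCR products differ by 220 nt (ca. 580 vs ca. 360 bp);
#' * type 1 loci (discriminator excised) retain SD2_np9 just upstream of the
#'   deletion point;
#' * an alternative donor lies 252 nt downstream of SD2_np9 (in type 1
#'   coordinates) and an alternative acceptor 7 nt downstream of the
#'   canonical SA2, so the alternatively spliced product carries 252 - 7 =
#'   245 nt extra;
#' * the SA2 region carries the composite acceptor context
#'   `TGTTAGTCTGCAGGTGT`: the canonical acceptor AG in `TGTTAGTCTG` and, 7 nt
#'   downstream, the alternative acceptor AG in `CTGCAGGTGT`.
#'
#' All offsets in the returned object are 0-based; splice donor positions are
#' the first intron base, acceptor positions the last intron base.
#'
#' @param full_length_aa named integer vector with the full-length protein
#'   thresholds used by the coding-capacity screen. Defaults to the lengths
#'   of the proteins encoded by this anatomy (Np9 74 aa, Rec 105 aa).
#' @return An object of class `hml2_anatomy`: a list with elements `seq`
#'   (character), `sites` (named 0-based offsets for SD1, SA1, SD2_rec,
#'   SD2_np9, alt_SD, SA2, alt_SA), `discriminator` (`offset`, `length`),
#'   `env_start`, `transcript_start`, `transcript_end`, `ltr5`, `ltr3`
#'   (0-based half-open), `primer_fwd`, `primer_rev` (binding windows) and
#'   `full_length_aa`.
#' @examples
#' an <- hml2_anatomy()
#' an$discriminator
#' substr(an$seq, an$sites[["SA2"]] - 4, an$sites[["SA2"]] + 5) # TGTTAGTCTG
#' @export
hml2_anatomy <- function(full_length_aa = c(Np9 = 74L, Rec = 105L)) {
  an <- .anatomy_cache$base
  if (is.null(an)) {
    an <- .build_anatomy()
    .anatomy_cache$base <- an
  }
  an$full_length_aa <- full_length_aa
  an
}

.anatomy_cache <- new.env(parent = emptyenv())

# Fixed geometry of the synthetic canonical provirus (0-based offsets).
.ANAT <- list(
  total        = 9528L,
  ltr_len      = 968L,
  ltr3_start   = 8560L,
  tx_start     = 600L,   # transcript start (R region of the 5' LTR)
  tx_end       = 9300L,  # transcript end, half-open (R region end, 3' LTR)
  SD1          = 1060L,  # first intron base of intron 1
  SA1          = 6100L,  # last intron base of intron 1
  env_start    = 6110L,  # shared Env/Rec/Np9 start codon
  SD2_np9      = 6154L,  # np9 donor, just upstream of the discriminator
  disc_start   = 6160L,  # 292-bp discriminator, 50 bp into env
  disc_len     = 292L,
  SD2_rec      = 6374L,  # rec donor, 220 nt downstream of SD2_np9
  alt_SD       = 6698L,  # = SD2_np9 + 252 in type 1 coordinates (+292 here)
  SA2          = 8210L,  # canonical acceptor, just upstream of the 3' LTR
  alt_SA       = 8217L,  # alternative acceptor 7 nt downstream
  rec_stop     = 8262L,  # TAA terminating the Rec frame (exon 3 offset 51)
  np9_stop     = 8389L,  # TAA terminating the Np9 frame (exon 3 offset 178)
  fwd_start    = 6110L,  # forward primer window, overlaps the start codon
  fwd_len      = 21L,
  rev_start    = 8507L,  # reverse primer binding window (forward strand)
  rev_len      = 20L
)

.build_anatomy <- function() {
  g <- .ANAT
  ltr <- .lcg_bases(g$ltr_len, seed = 20150305)
  # poly-A signal inside the LTR (upstream of the R-region 3' end)
  ltr <- .plant(ltr, 710L, "AATAAA")

  chars <- character(g$total)
  chars[seq_len(g$ltr_len)] <- ltr
  body <- .lcg_bases(g$ltr3_start - g$ltr_len, seed = 777)
  chars[(g$ltr_len + 1):g$ltr3_start] <- body
  chars[(g$ltr3_start + 1):g$total] <- ltr

  # env + exon 3 background is drawn over {A,C,G} only: with no T in the
  # background there are no stop codons and no GT donor dinucleotides other
  # than the planted ones, making the reading-frame ground truth provable.
  tless <- .lcg_bases(g$ltr3_start - g$env_start, seed = 4242,
                      alphabet = c("A", "C", "G"))
  chars[(g$env_start + 1):g$ltr3_start] <- tless

  chars <- .plant(chars, g$SD1, "GTAAGT")                 # intron 1 donor
  chars <- .plant(chars, g$SA1 - 5L, "CCCTAG")            # intron 1 acceptor
  chars <- .plant(chars, g$SA1 + 1L, "TTCTCTTCT")         # exon 2 5' UTR
  chars <- .plant(chars, g$fwd_start, "ATGAACCCATCAGAGATGCAA") # fwd primer
  chars <- .plant(chars, g$SD2_np9, "GTCA")               # np9 donor
  chars <- .plant(chars, g$SD2_rec, "GT")                 # rec donor
  chars <- .plant(chars, g$alt_SD, "GT")                  # alternative donor
  chars <- .plant(chars, g$SA2 - 5L, "TGTTAGTCTGCAGGTGTCC") # SA2 + alt SA
  # (trailing CC keeps the np9 reading frame open across the block's T)
  chars <- .plant(chars, g$rec_stop, "TAA")               # Rec stop
  chars <- .plant(chars, g$np9_stop, "TAA")               # Np9 stop
  chars <- .plant(chars, g$rev_start,
                  .revcomp("AGCATCTGTTTAACAAAGCA"))       # rev primer site

  an <- list(
    seq = paste(chars, collapse = ""),
    sites = c(SD1 = g$SD1, SA1 = g$SA1, SD2_rec = g$SD2_rec,
              SD2_np9 = g$SD2_np9, alt_SD = g$alt_SD,
              SA2 = g$SA2, alt_SA = g$alt_SA),
    discriminator = c(offset = g$disc_start, length = g$disc_len),
    env_start = g$env_start,
    transcript_start = g$tx_start,
    transcript_end = g$tx_end,
    ltr5 = c(0L, g$ltr_len),
    ltr3 = c(g$ltr3_start, g$total),
    primer_fwd = c(g$fwd_start, g$fwd_start + g$fwd_len),
    primer_rev = c(g$rev_start, g$rev_start + g$rev_len)
  )
  class(an) <- "hml2_anatomy"
  .validate_anatomy(an)
  an
}

.validate_anatomy <- function(an) {
  stopifnot(an$discriminator[["length"]] == 292L)
  # discriminator starts about 50 bp into env (validated within +/- 20 bp)
  off <- an$discriminator[["offset"]] - an$env_start
  stopifnot(abs(off - 50L) <= 20L)
  # donor introns start GT, acceptor introns end AG
  s <- an$seq
  for (d in c("SD1", "SD2_rec", "SD2_np9", "alt_SD")) {
    p <- an$sites[[d]]
    stopifnot(.sub0(s, p, p + 2L) == "GT")
  }
  for (a in c("SA1", "SA2", "alt_SA")) {
    p <- an$sites[[a]]
    stopifnot(.sub0(s, p - 1L, p + 1L) == "AG")
  }
  stopifnot(an$sites[["alt_SA"]] - an$sites[["SA2"]] == 7L)
  # alt donor is 252 nt downstream of the np9 donor in type 1 coordinates
  stopifnot(an$sites[["alt_SD"]] - an$sites[["SD2_np9"]] -
              an$discriminator[["length"]] == 252L)
  invisible(an)
}

#' @export
print.hml2_anatomy <- function(x, ...) {
  cat("Canonical HML-2 type 2 provirus anatomy\n")
  cat(sprintf("  sequence length : %d nt\n", nchar(x$seq)))
  cat(sprintf("  discriminator   : %d nt at offset %d (env + %d)\n",
              x$discriminator[["length"]], x$discriminator[["offset"]],
              x$discriminator[["offset"]] - x$env_start))
  cat("  splice sites (0-based):\n")
  for (nm in names(x$sites)) cat(sprintf("    %-8s %d\n", nm, x$sites[[nm]]))
  invisible(x)
}
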