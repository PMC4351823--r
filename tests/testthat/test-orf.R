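test_that("translation follows the stop-index law", {
  # a 408-nt ORF (stop included) encodes a 135-aa protein
  orf408 <- paste0("ATG", strrep("GCC", 134), "TAA")
  expect_equal(nchar(orf408), 408)
  tr <- translate_orf(orf408, 0)
  expect_equal(nchar(tr$protein), 135)
  expect_equal(tr$stop_codon_index, 136)
  # minimal case
  tr2 <- translate_orf("ATGTAA", 0)
  expect_identical(tr2$protein, "M")
  expect_equal(tr2$stop_codon_index, 2)
  # property: protein length == stop index - 1 for random ORFs
  for (seed in 1:6) {
    k <- withr::with_seed(seed, sample(5:80, 1))
    orf <- paste0("ATG", strrep("CAA", k - 1), "TGA")
    tr <- translate_orf(orf, 0)
    expect_equal(nchar(tr$protein), tr$stop_codon_index - 1)
  }
  # ambiguous codons translate to X; absent stop is flagged open-ended
  trx <- translate_orf("ATGANNGCC", 0)
  expect_identical(trx$protein, "MXA")
  expect_true(trx$open_ended)
})

test_that("a Rec frame stopping at triplet 20 gives 19 aa and no capacity", {
  fx <- test_fixtures()
  an <- test_anatomy()
  l <- annotate_locus(fx$rec_stop20$locus, an)
  rep <- scan_capacity(l, an, "Rec")
  expect_equal(nchar(rep$protein_seq), 19)
  expect_equal(rep$stop_codon_index, 20)
  expect_identical(rep$capacity, "none")
})

test_that("capacity classes track protein length against the reference", {
  an <- test_anatomy()
  pair <- test_canonical_pair()
  # unmodified type 1 locus: full-length Np9
  full <- scan_capacity(pair$t1, an, "Np9")
  expect_identical(full$capacity, "full_length")
  expect_equal(nchar(full$protein_seq), an$full_length_aa[["Np9"]])
  expect_true(all(full$criteria_flags))
  plant_stop <- function(pos0) {
    ch <- strsplit(pair$t1$seq, "")[[1]]
    ch[(pos0 + 1):(pos0 + 3)] <- c("T", "A", "A")
    annotate_locus(hml2_locus("STOPPED", "chr9", 1001L, 1000L + length(ch),
                              "+", paste(ch, collapse = ""), "type1"), an)
  }
  # a stop ~12 codons early -> short variant ("about ten or more aa shorter")
  short <- scan_capacity(plant_stop(8064L), an, "Np9")
  expect_identical(short$capacity, "short_variant")
  expect_equal(nchar(short$protein_seq), 63)
  expect_equal(short$stop_codon_index, 64)
  # a very early stop -> none; adding premature stops never upgrades class
  none <- scan_capacity(plant_stop(7929L), an, "Np9")
  expect_identical(none$capacity, "none")
  rank <- c(none = 0, short_variant = 1, full_length = 2)
  expect_true(rank[none$capacity] <= rank[short$capacity] &&
                rank[short$capacity] <= rank[full$capacity])
})

test_that("missing LTRs veto capacity even with an intact ORF", {
  an <- test_anatomy()
  pair <- test_canonical_pair()
  no_ltr <- substr(pair$t1$seq, 969, nchar(pair$t1$seq))
  l <- annotate_locus(hml2_locus("NO5LTR", "chr8", 1001L,
                                 1000L + nchar(no_ltr), "+", no_ltr,
                                 "type1"), an)
  rep <- scan_capacity(l, an, "Np9")
  expect_false(rep$criteria_flags[["has_5ltr"]])
  expect_identical(rep$capacity, "none")
})

test_that("N-terminal identity length is reported for diverged proteins", {
  an <- test_anatomy()
  pair <- test_canonical_pair()
  # mutate codon 16 of the Np9 ORF (exon 3, np9 frame, first full codon)
  g <- hml2tx:::.ANAT
  pos0 <- g$SA2 + 1L - g$disc_len + 1L  # exon 3 offset 1 in type 1 coords
  ch <- strsplit(pair$t1$seq, "")[[1]]
  ch[(pos0 + 1):(pos0 + 3)] <- c("G", "C", "C")  # L -> A at codon 16
  l <- annotate_locus(hml2_locus("NTERM", "chr6", 1001L, 1000L + length(ch),
                                 "+", paste(ch, collapse = ""), "type1"), an)
  rep <- scan_capacity(l, an, "Np9")
  expect_equal(rep$nterm_identity_aa, 15)
})

test_that("frameshifts rewrite the protein tail downstream of the deletion", {
  orf <- paste0("ATG", strrep("GCC", 20), "CAACAACAA", strrep("GCC", 5), "TAA")
  before <- translate_orf(orf, 0)$protein
  # delete one base upstream of the stop region
  shifted <- paste0(substr(orf, 1, 63), substr(orf, 65, nchar(orf)))
  after <- translate_orf(shifted, 0)$protein
  expect_identical(substr(before, 1, 20), substr(after, 1, 20))
  expect_false(identical(before, after))
})

test_that("protein variant comparison flags columns and deletion runs", {
  base <- "MNPSEMQKLRTGHWYVADEF"
  expect_length(compare_protein_variants(c(a = base, b = base))$flagged_columns, 0)
  two <- paste0(substr(base, 1, 4), "AA", substr(base, 7, nchar(base)))
  cmp2 <- compare_protein_variants(c(canonical = base, variant = two))
  expect_length(cmp2$flagged_columns, 2)
  del3 <- paste0(substr(base, 1, 8), substr(base, 12, nchar(base)))
  cmp3 <- compare_protein_variants(c(canonical = base, variant = del3))
  runs <- cmp3$deletion_runs[cmp3$deletion_runs$seq == "variant", ]
  expect_equal(nrow(runs), 1)
  expect_equal(runs$length, 3)
  expect_length(cmp3$flagged_columns, 3)
})

test_that("chimeric ORFs are segmented at the planted breakpoint", {
  fx <- test_fixtures()
  ch <- detect_chimeric_orf(fx$chimera$transcript)
  expect_true(ch$coding)
  expect_identical(ch$segments$source, c("Rec", "Np9"))
  expect_lte(abs(ch$breakpoint - fx$chimera$breakpoint), 1)
  # a pure Rec transcript yields a single Rec segment
  an <- test_anatomy()
  pair <- test_canonical_pair()
  rec_tx <- splice(pair$t2, "rec")
  pure <- detect_chimeric_orf(rec_tx$seq)
  expect_identical(pure$segments$source, "Rec")
  # immediate stop -> non-coding
  nc <- detect_chimeric_orf("GGGATGTAAGGGGGG")
  expect_false(nc$coding)
})
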