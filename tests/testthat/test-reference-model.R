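test_that("locus catalog round-trips through FASTA/TSV with orientation", {
  an <- test_anatomy()
  fwd <- substr(an$seq, 1, 1533)
  loci <- list(
    hml2_locus("L_PLUS", "chr5", 92818136L, 92818136L + 1532L, "+", fwd),
    hml2_locus("L_MINUS", "chr7", 1001L, 1001L + 1532L, "-", fwd)
  )
  names(loci) <- c("L_PLUS", "L_MINUS")
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_locus_catalog(loci, fa, tsv)
  loaded <- load_locus_catalog(fa, tsv)
  # provirus-forward sequence restored for the minus-strand locus
  expect_identical(loaded$L_MINUS$seq, fwd)
  expect_identical(loaded$L_PLUS$seq, fwd)
  # orientation round trip: re-projecting to genome coordinates reproduces
  # the FASTA record exactly
  fasta_seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(genome_sequence(loaded$L_MINUS),
                   as.character(fasta_seqs[["L_MINUS"]]))
  # 1-based inclusive coordinate arithmetic: end - start + 1 == length
  expect_equal(loaded$L_PLUS$end - loaded$L_PLUS$start + 1, 1533)
})

test_that("catalog validation rejects malformed input", {
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">A", "ACGT"), fa)
  writeLines(c("locus_id\tchrom\tstart\tend\tstrand\ttype\thgnc_name",
               "A\tchr1\t10\t5\t+\ttype2\t"), tsv)
  expect_error(load_locus_catalog(fa, tsv), "end < start")
  writeLines(c("locus_id\tchrom\tstart\tend\tstrand\ttype\thgnc_name",
               "B\tchr1\t1\t4\t+\ttype2\t"), tsv)
  expect_error(load_locus_catalog(fa, tsv), "no FASTA record.*B")
  writeLines(c("locus_id\tchrom\tstart\tend\tstrand\ttype\thgnc_name",
               "A\tchr1\t1\t400\t+\ttype2\t"), tsv)
  expect_error(load_locus_catalog(fa, tsv), "length")
  writeLines(c("locus_id\tchrom\tstart\tend\tstrand\ttype\thgnc_name",
               "A\tchr1\t1\t4\t+\ttype2\t",
               "A\tchr1\t1\t4\t+\ttype2\t"), tsv)
  expect_error(load_locus_catalog(fa, tsv), "duplicate")
  writeLines("locus_id\tchrom\tstart\tend\tstrand\ttype\thgnc_name", tsv)
  expect_warning(empty <- load_locus_catalog(fa, tsv), "empty")
  expect_length(empty, 0)
})

test_that("provirus type classification follows the 292-bp discriminator", {
  pair <- test_canonical_pair()
  expect_identical(unclass(pair$t2$type)[1], "type2")
  expect_identical(unclass(pair$t1$type)[1], "type1")
  # a solo LTR is undetermined
  an <- test_anatomy()
  solo <- hml2_locus("SOLO", "chr1", 1L, 968L, "+", substr(an$seq, 1, 968))
  expect_identical(unclass(classify_provirus_type(solo, an))[1],
                   "undetermined")
  short <- hml2_locus("SHORT", "chr1", 1L, 150L, "+",
                      substr(an$seq, 1, 150))
  cl <- classify_provirus_type(short, an)
  expect_identical(unclass(cl)[1], "undetermined")
  expect_match(attr(cl, "reason"), "200")
})

test_that("type classification is stable under 1% substitutions outside the discriminator", {
  an <- test_anatomy()
  d0 <- an$discriminator[["offset"]]; dl <- an$discriminator[["length"]]
  for (seed in 1:5) {
    withr::with_seed(seed, {
      ch <- strsplit(an$seq, "")[[1]]
      eligible <- setdiff(seq_along(ch), (d0 + 1):(d0 + dl))
      pos <- sample(eligible, round(0.01 * length(ch)))
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      mut <- paste(ch, collapse = "")
    })
    l <- hml2_locus(paste0("M", seed), "chr1", 1L, nchar(mut), "+", mut)
    expect_identical(unclass(classify_provirus_type(l, an))[1], "type2")
  }
})

test_that("splice sites project with correct motifs and alternative offsets", {
  pair <- test_canonical_pair()
  s2 <- pair$t2$sites
  expect_true(s2$motif_ok[s2$site == "SA2"])
  expect_match(s2$context[s2$site == "SA2"], "TGTTAGTCTG")
  expect_identical(s2$status[s2$site == "alt_SD"], "undefined")
  s1 <- pair$t1$sites
  expect_identical(s1$status[s1$site == "SD2_rec"], "undefined")
  # alternative site offsets recovered exactly on the type 1 locus
  p <- function(nm) s1$position[s1$site == nm]
  expect_equal(p("alt_SD") - p("SD2_np9"), 252)
  expect_equal(p("alt_SA") - p("SA2"), 7)
})

test_that("a dead SA2 with live +7 acceptor is annotated as usable alt_SA", {
  fx <- test_fixtures()
  an <- test_anatomy()
  l <- annotate_locus(fx$alt245$locus_alt, an)
  st <- l$sites
  expect_false(st$motif_ok[st$site == "SA2"])
  expect_identical(st$status[st$site == "SA2"], "dead")
  expect_match(st$context[st$site == "SA2"], "TGTTGGTCTG")
  expect_true(st$motif_ok[st$site == "alt_SA"])
  expect_match(st$context[st$site == "alt_SA"], "CTGCAGGTGT")
})

test_that("N-masked acceptor regions are reported unlocatable, not dropped", {
  an <- test_anatomy()
  ch <- strsplit(an$seq, "")[[1]]
  sa2 <- an$sites[["SA2"]]
  ch[(sa2 - 3):(sa2 + 3)] <- "N"
  l <- hml2_locus("NMASK", "chr1", 1L, length(ch), "+",
                  paste(ch, collapse = ""))
  st <- locate_splice_sites(l, an, provirus_type = "type2")
  expect_identical(st$status[st$site == "SA2"], "unlocatable")
  expect_true("SA2" %in% st$site)  # never silently dropped
})

test_that("projection fast path agrees with the alignment path", {
  an <- test_anatomy()
  pair <- test_canonical_pair()
  # appending a tail changes the length so the shortcut cannot apply and
  # the full alignment is used; shared site positions must agree
  tail30 <- strrep("ACGT", 10)
  l2 <- hml2_locus("T1_TAIL", "chr3", 1001L,
                   1000L + nchar(pair$t1$seq) + 40L, "+",
                   paste0(pair$t1$seq, tail30))
  a2 <- annotate_locus(l2, an)
  for (nm in c("SD1", "SA1", "SD2_np9", "SA2", "alt_SA")) {
    expect_equal(a2$sites$position[a2$sites$site == nm],
                 pair$t1$sites$position[pair$t1$sites$site == nm],
                 info = nm)
  }
  expect_identical(unclass(a2$type)[1], "type1")
})

test_that("annotated splice sites export to GFF3", {
  pair <- test_canonical_pair()
  path <- tempfile(fileext = ".gff3")
  gr <- export_sites_gff3(list(pair$t2), path)
  expect_true(file.exists(path))
  back <- rtracklayer::import(path)
  expect_equal(length(back), length(gr))
  expect_setequal(unique(as.character(back$type)),
                  c("splice_donor", "splice_acceptor"))
  # 1-based single-nucleotide features at the annotated positions
  sa2 <- pair$t2$sites$position[pair$t2$sites$site == "SA2"]
  expect_true((sa2 + 1) %in% GenomicRanges::start(back))
})
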