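test_that("compare_sequences counts substitutions and gap runs", {
  s <- random_dna(500, seed = 10)
  expect_equal(compare_sequences(s, s), c(0, 500), ignore_attr = TRUE)
  ch <- strsplit(s, "")[[1]]
  ch[250] <- setdiff(c("A", "C", "G", "T"), ch[250])[1]
  one_sub <- paste(ch, collapse = "")
  expect_equal(compare_sequences(one_sub, s), c(1, 500), ignore_attr = TRUE)
  # an internal 7-nt deletion is one difference event over 100 columns
  t100 <- random_dna(100, seed = 11)
  del7 <- paste0(substr(t100, 1, 46), substr(t100, 54, 100))
  expect_equal(compare_sequences(del7, t100), c(1, 100), ignore_attr = TRUE)
  # per-base indel policy counts the gapped columns instead
  expect_equal(unname(compare_sequences(del7, t100,
                                        indel_policy = "per_base"))[1], 7)
})

test_that("mismatch metric is symmetric", {
  for (seed in 1:8) {
    a <- random_dna(200, seed = seed)
    b_ch <- strsplit(a, "")[[1]]
    withr::with_seed(seed + 100, {
      pos <- sample(200, 5)
      for (p in pos) b_ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               b_ch[p]), 1)
    })
    b <- paste(b_ch, collapse = "")
    expect_equal(compare_sequences(a, b)[["differences"]],
                 compare_sequences(b, a)[["differences"]])
  }
})

test_that("high-N sequences are flagged low quality but still compared", {
  a <- paste0(strrep("N", 30), random_dna(170, seed = 3))
  b <- random_dna(200, seed = 3)
  out <- compare_sequences(a, substr(b, 31, 200))
  expect_true(is.finite(out[["differences"]]))
  expect_true(attr(out, "low_quality"))
})

test_that("reads are assigned, tied, rejected or unassignable correctly", {
  run <- test_small_run()
  db <- run$db
  params <- assignment_params()
  # exact insert -> assigned with 0 mismatches
  r <- assign_read(db$insert[1], db, params)
  expect_identical(r$status, "assigned")
  expect_identical(r$locus, db$locus_id[1])
  expect_equal(r$mismatches, 0)
  # reverse-complemented read still assigned, flagged as minus orientation
  rrc <- assign_read(hml2tx:::.revcomp(db$insert[1]), db, params)
  expect_identical(rrc$status, "assigned")
  expect_identical(rrc$locus, db$locus_id[1])
  expect_identical(rrc$orientation, "-")
  # a read far from everything is unassignable
  far <- assign_read(random_dna(400, seed = 77), db, params)
  expect_identical(far$status, "unassignable")
  # short reads are rejected
  shrt <- assign_read(substr(db$insert[1], 1, 30), db, params)
  expect_identical(shrt$status, "rejected")
})

test_that("sequence-identical loci give exactly the two-locus ambiguity group", {
  fx <- test_fixtures()
  an <- test_anatomy()
  annotated <- annotate_loci(list(AMBIG_A = fx$ambig_pair$locus_a,
                                  AMBIG_B = fx$ambig_pair$locus_b), an)
  db <- build_amplicon_db(annotated)
  r <- assign_read(fx$ambig_pair$insert, db)
  expect_identical(r$status, "ambiguous")
  expect_identical(r$locus, "AMBIG_A|AMBIG_B")
})

test_that("assignment partitions every read and recovers true loci", {
  run <- test_small_run()
  res <- run$results
  tally <- table(factor(res$status, levels = c("assigned", "ambiguous",
                                               "unassignable", "rejected")))
  expect_equal(sum(tally), nrow(res))
  tr <- merge(run$read_set$truth, res, by = "read_id")
  # recovery among reads that are assignable in principle (source in the
  # catalog, not contamination, at most max_mismatch planted errors)
  ok <- with(tr, !contamination & source_locus %in% names(run$panel$loci) &
               n_errors <= 2)
  hit <- with(tr[ok, ], status == "assigned" & locus == source_locus)
  expect_gte(mean(hit), 0.99)
})

test_that("np9 exon 2 masking ignores substitutions there but not indels", {
  pair <- test_canonical_pair()
  db <- build_amplicon_db(list(pair$t1))
  ins <- db$insert[db$isoform == "np9"]
  ch <- strsplit(ins, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  ch[12] <- setdiff(c("A", "C", "G", "T"), ch[12])[1]
  read <- paste(ch, collapse = "")
  masked <- assign_read(read, db, assignment_params(omit_np9_exon2 = TRUE))
  unmasked <- assign_read(read, db, assignment_params(omit_np9_exon2 = FALSE))
  expect_equal(masked$mismatches, 0)
  expect_equal(unmasked$mismatches, 2)
  # a structural insertion at the exon-2 boundary is never masked away
  with_ins <- paste0(substr(ins, 1, 20), strrep("ACG", 10),
                     substr(ins, 21, nchar(ins)))
  r_ins <- assign_read(with_ins, db, assignment_params())
  expect_gte(r_ins$mismatches, 1)
})

test_that("tissue count table conserves reads and isolates sink rows", {
  run <- test_small_run()
  tab <- tabulate_counts(run$results, run$nonref)
  expect_equal(unname(tab["total", ]),
               as.integer(table(run$results$tissue)[colnames(tab)]))
  body <- tab[setdiff(rownames(tab), "total"), , drop = FALSE]
  expect_equal(sum(body), nrow(run$results))
})
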