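test_that("target site duplications are found with length bounds", {
  tsd <- "TTAAAAATGT"
  f5 <- paste0(random_dna(40, seed = 1), tsd)
  f3 <- paste0(tsd, random_dna(40, seed = 2))
  hit <- find_tsd(f5, f3)
  expect_identical(hit$tsd, tsd)
  expect_equal(hit$tsd_len, 10)
  # positional contract: suffix of the upstream flank, prefix of the
  # downstream flank
  expect_identical(substr(f5, nchar(f5) - hit$tsd_len + 1, nchar(f5)),
                   hit$tsd)
  expect_identical(substr(f3, 1, hit$tsd_len), hit$tsd)
  # random flanks share no duplicated word of >= 6 nt
  expect_null(find_tsd(random_dna(40, seed = 3), random_dna(40, seed = 4)))
  # a 5-nt duplication is below the minimum length
  f5s <- paste0(random_dna(40, seed = 5), "TTAAA")
  f3s <- paste0("TTAAA", random_dna(40, seed = 6))
  expect_null(find_tsd(f5s, f3s))
  expect_error(find_tsd("ACGT", "ACGT"), "inconclusive")
})

test_that("poly-A calls respect length and purity thresholds", {
  body <- paste0(random_dna(150, seed = 7), "CG")
  pure <- find_polyA(paste0(body, strrep("A", 30)))
  expect_true(pure$present)
  expect_equal(pure$length, 30)
  expect_equal(pure$purity, 1.0)
  # 12-nt tail with one G: purity 11/12
  mixed <- find_polyA(paste0(strrep("CG", 40), "AAAAGAAAAAAA"))
  expect_true(mixed$present)
  expect_equal(mixed$length, 12)
  expect_equal(mixed$purity, 11 / 12, tolerance = 1e-9)
  # no terminal A run
  expect_false(find_polyA(paste0(random_dna(100, seed = 8), "CGCGCGCG"))$present)
  # poly-A signal hexamer reported when present upstream
  sig <- find_polyA(paste0(body, "AATAAA", random_dna(20, seed = 9),
                           strrep("A", 25)))
  expect_true(sig$polyA_signal)
})

test_that("junction matching recognises spliced-out introns and truncation", {
  an <- test_anatomy()
  model <- canonical_rec_mrna(an)
  # untruncated retrocopy of the canonical rec mRNA
  mj <- match_junctions(model$seq, model)
  expect_true(all(mj$junctions$matched))
  expect_true(all(mj$junctions$offset_error == 0))
  expect_equal(mj$five_prime_truncation_len, 0)
  # 250-nt truncated fixture
  fx <- test_fixtures()
  mj2 <- match_junctions(fx$retro5q15$candidate, model)
  expect_true(all(mj2$junctions$matched))
  expect_lte(abs(mj2$five_prime_truncation_len - 250), 3)
  # an ordinary provirus retains its introns: junction probes fail
  mj3 <- match_junctions(an$seq, model)
  expect_false(any(mj3$junctions$matched))
})

test_that("retrocopy verdict combines the three hallmarks", {
  fx <- test_fixtures()
  ev <- detect_retrocopy(fx$retro5q15$candidate, fx$retro5q15$flank5,
                         fx$retro5q15$flank3)
  expect_identical(ev$verdict, "retrocopy")
  expect_identical(ev$tsd_seq, "TTAAAAATGT")
  expect_lte(abs(ev$five_prime_truncation_len - 250), 3)
  # two hallmarks only -> inconclusive (drop the TSD)
  ev2 <- detect_retrocopy(fx$retro5q15$candidate,
                          random_dna(40, seed = 11), random_dna(40, seed = 12))
  expect_identical(ev2$verdict, "inconclusive")
  # an intact provirus with random flanks has no hallmark
  an <- test_anatomy()
  ev3 <- detect_retrocopy(an$seq, random_dna(40, seed = 13),
                          random_dna(40, seed = 14))
  expect_identical(ev3$verdict, "not_retrocopy")
  # explicit truth table of the classifier
  expect_identical(classify_retrocopy(list(
    tsd_len = 10L, polyA = list(present = TRUE),
    junction_matches = data.frame(matched = c(TRUE, TRUE)))), "retrocopy")
  expect_identical(classify_retrocopy(list(
    tsd_len = NA_integer_, polyA = list(present = TRUE),
    junction_matches = data.frame(matched = TRUE))), "inconclusive")
  expect_identical(classify_retrocopy(list(
    tsd_len = NA_integer_, polyA = list(present = FALSE),
    junction_matches = data.frame(matched = FALSE))), "not_retrocopy")
})

test_that("detection is invariant to the candidate's genomic strand", {
  fx <- test_fixtures()
  rc <- hml2tx:::.revcomp
  ev <- detect_retrocopy(rc(fx$retro5q15$candidate),
                         rc(fx$retro5q15$flank3), rc(fx$retro5q15$flank5))
  expect_identical(ev$verdict, "retrocopy")
  expect_identical(ev$strand, "-")
  expect_identical(ev$tsd_seq, "TTAAAAATGT")
})
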