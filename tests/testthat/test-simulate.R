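test_that("panel generation is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 7L, n_loci = 6L)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(vapply(p1$loci, `[[`, "", "seq"),
                   vapply(p2$loci, `[[`, "", "seq"))
  expect_identical(p1$truth, p2$truth)
  r1 <- simulate_reads(p1)
  r2 <- simulate_reads(p2)
  expect_identical(r1$reads$seq, r2$reads$seq)
  # a different seed changes the panel
  p3 <- generate_panel(simulation_config(seed = 8L, n_loci = 6L))
  expect_false(identical(vapply(p1$loci, `[[`, "", "seq"),
                         vapply(p3$loci, `[[`, "", "seq")))
})

test_that("type 1 loci are exactly 292 nt shorter than type 2 siblings", {
  p <- generate_panel(simulation_config(seed = 7L, n_loci = 8L,
                                        n_retrocopies = 0L))
  lens <- vapply(p$loci, function(l) nchar(l$seq), 0L)
  types <- p$truth$type[match(names(lens), p$truth$locus_id)]
  expect_true(all(lens[types == "type2"] - lens[types == "type1"] == 292))
})

test_that("read truth is complete and conserves counts", {
  cfg <- simulation_config(seed = 7L, n_loci = 5L, n_tissues = 4L,
                           reads_per_tissue = 15L)
  p <- generate_panel(cfg)
  rs <- simulate_reads(p)
  expect_equal(nrow(rs$reads), 4 * 15)
  expect_identical(rs$reads$read_id, rs$truth$read_id)  # one row per read
  expect_false(anyDuplicated(rs$reads$read_id) > 0)
  # per-tissue totals equal reads emitted per tissue
  expect_true(all(table(rs$reads$tissue) == 15))
})

test_that("error-free simulation reproduces source inserts exactly", {
  cfg <- simulation_config(seed = 7L, n_loci = 5L, n_tissues = 2L,
                           reads_per_tissue = 10L, read_error_rate = 0,
                           contamination_fraction = 0)
  p <- generate_panel(cfg)
  rs <- simulate_reads(p)
  src_insert <- p$truth$insert[match(rs$truth$source_locus,
                                     p$truth$locus_id)]
  expect_identical(rs$reads$seq, src_insert)
  expect_true(all(rs$truth$n_errors == 0))
})

test_that("planted read errors are recorded at their true positions", {
  cfg <- simulation_config(seed = 19L, n_loci = 4L, n_tissues = 2L,
                           reads_per_tissue = 20L, read_error_rate = 0.01,
                           contamination_fraction = 0)
  p <- generate_panel(cfg)
  rs <- simulate_reads(p)
  with_err <- which(rs$truth$n_errors > 0)[1:5]
  for (i in with_err) {
    tmpl <- p$truth$insert[p$truth$locus_id == rs$truth$source_locus[i]]
    pos <- as.integer(strsplit(rs$truth$error_positions[i], ",")[[1]])
    diff <- which(strsplit(rs$reads$seq[i], "")[[1]] !=
                    strsplit(tmpl, "")[[1]])
    expect_identical(diff, pos)
  }
})

test_that("all-zero activity tissues warn and emit nothing", {
  cfg <- simulation_config(seed = 7L, n_loci = 4L, n_tissues = 2L,
                           n_nonref_loci = 0L, n_retrocopies = 0L)
  p <- generate_panel(cfg)
  p$activity[, 2] <- 0
  expect_warning(rs <- simulate_reads(p), "all-zero activity")
  expect_equal(nrow(rs$reads), cfg$reads_per_tissue)
})

test_that("non-reference loci carry the SA2 mutation and splice np9_alt", {
  an <- test_anatomy()
  p <- generate_panel(simulation_config(seed = 7L, n_loci = 4L,
                                        n_nonref_loci = 2L))
  expect_identical(p$truth$isoform[!p$truth$in_catalog],
                   rep("np9_alt", 2))
  nr <- annotate_locus(p$nonref_loci$K111like, an)
  st <- nr$sites
  expect_identical(st$status[st$site == "SA2"], "dead")
  expect_true(st$motif_ok[st$site == "alt_SA"])
})

test_that("simulation artifacts serialize to plain-text formats", {
  cfg <- simulation_config(seed = 7L, n_loci = 4L, n_tissues = 2L,
                           reads_per_tissue = 8L)
  p <- generate_panel(cfg)
  rs <- simulate_reads(p)
  out <- tempfile()
  paths <- write_simulation(p, rs, out)
  expect_true(all(file.exists(paths)))
  reloaded <- load_locus_catalog(file.path(out, "loci.fa"),
                                 file.path(out, "loci.tsv"))
  expect_identical(vapply(reloaded, `[[`, "", "seq"),
                   vapply(p$loci, `[[`, "", "seq"))
})

test_that("per-locus read fractions respect configured weights", {
  # single tissue, large n: observed counts must fall inside simultaneous
  # exact binomial bands around the configured multinomial weights
  n <- 5000L
  cfg <- simulation_config(seed = 23L, n_loci = 6L, n_tissues = 1L,
                           reads_per_tissue = n, read_error_rate = 0,
                           contamination_fraction = 0, n_nonref_loci = 0L,
                           n_retrocopies = 0L)
  p <- generate_panel(cfg)
  rs <- simulate_reads(p)
  w <- p$activity[, 1] / sum(p$activity[, 1])
  obs <- table(factor(rs$truth$source_locus, levels = rownames(p$activity)))
  k <- length(w)
  alpha <- 0.01 / k  # Bonferroni split for a 99% simultaneous band
  for (i in seq_len(k)) {
    lo <- stats::qbinom(alpha / 2, n, w[i])
    hi <- stats::qbinom(1 - alpha / 2, n, w[i])
    expect_gte(obs[[i]], lo)
    expect_lte(obs[[i]], hi)
  }
})
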