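# Shared memoized objects so expensive artifacts are built once per run.

.memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  v <- .memo[[key]]
  if (is.null(v)) {
    v <- force(expr)
    .memo[[key]] <- v
  }
  v
}

test_anatomy <- function() memo("anatomy", hml2_anatomy())

test_fixtures <- function() memo("fixtures", make_fixture_suite(test_anatomy()))

# small default-condition pipeline run shared by several tests
test_small_run <- function() memo("small_run", {
  cfg <- simulation_config(seed = 42L, n_loci = 6L, n_tissues = 4L,
                           reads_per_tissue = 25L)
  run_pipeline(cfg, call_variants = FALSE)
})

# a canonical type 2 locus and its type 1 sibling, annotated
test_canonical_pair <- function() memo("canonical_pair", {
  an <- test_anatomy()
  t2 <- hml2_locus("CANON_T2", "chr2", 1001L, 1000L + nchar(an$seq), "+",
                   an$seq, "type2")
  d0 <- an$discriminator[["offset"]]
  dl <- an$discriminator[["length"]]
  s1 <- paste0(substr(an$seq, 1, d0), substr(an$seq, d0 + dl + 1,
                                             nchar(an$seq)))
  t1 <- hml2_locus("CANON_T1", "chr3", 1001L, 1000L + nchar(s1), "+",
                   s1, "type1")
  list(t2 = annotate_locus(t2, an), t1 = annotate_locus(t1, an))
})

random_dna <- function(n, seed = 1L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# full study-condition simulation shared by the acceptance tests
acceptance_run <- function() memo("acceptance_run", {
  run_pipeline(simulation_config(seed = 101L), call_variants = FALSE)
})
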