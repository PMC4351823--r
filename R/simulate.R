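# Synthetic-data generator: locus panels, transcript pools, Sanger-like
# reads, retrocopies and genomic contamination, all with complete ground
# truth so every pipeline stage is testable without downloads.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.TISSUES <- c("heart", "brain", "placenta", "lung", "liver",
              "skeletal_muscle", "kidney", "pancreas", "spleen", "thymus",
              "prostate", "testis", "ovary", "small_intestine", "colon",
              "leukocyte")

#' Simulation configuration
#'
#' Parameters of the synthetic multi-tissue cDNA survey. Defaults emulate
#' a multi-tissue Sanger cDNA survey: a panel of reference loci mixed half/half between
#' provirus types diverged 1% at diagnostic positions, 16 tissue types with
#' 41 Sanger reads each, a 0.3% per-base read error rate, one retrocopy
#' locus (truncated 250 nt, 30-nt poly-A, 10-nt TSD), three proviruses
#' absent from the reference catalog (two of which are in the
#' non-reference database), and a 5% genomic-DNA contamination fraction.
#'
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   byte-identical.
#' @param n_loci number of reference (cataloged) loci, including
#'   retrocopies.
#' @param type1_fraction fraction of non-retrocopy reference loci converted
#'   to type 1 by excising the 292-bp discriminator.
#' @param inter_locus_divergence substitution rate between paralogous
#'   lineages (functional elements are protected, emulating purifying
#'   selection on the features the assay depends on).
#' @param n_tissues,reads_per_tissue sampling depth (defaults 16 and 41).
#' @param read_error_rate per-base substitution rate of the Sanger-like
#'   reads.
#' @param n_nonref_loci loci withheld from the catalog (transcribed but not
#'   in the reference assembly); they carry the SA2 AG->GG mutation and
#'   splice via the alternative +252/+7 site pair.
#' @param n_nonref_in_db how many of those are present in the
#'   non-reference database handed to [match_nonreference()].
#' @param n_retrocopies how many reference loci are L1-mediated retrocopies
#'   of rec mRNA.
#' @param retrocopy_spec list with `tsd`, `polyA_len`, `truncation_len`.
#' @param contamination_fraction fraction of reads drawn from unspliced
#'   genomic sequence of retrocopy loci (indistinguishable from their cDNA
#'   by construction).
#' @param activity optional loci x tissues matrix of relative transcription
#'   weights; by default drawn per tissue from a gamma distribution.
#' @return list of class `hml2_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_loci = 10L,
                              type1_fraction = 0.5,
                              inter_locus_divergence = 0.01,
                              n_tissues = 16L,
                              reads_per_tissue = 41L,
                              read_error_rate = 0.003,
                              n_nonref_loci = 3L,
                              n_nonref_in_db = min(2L, n_nonref_loci),
                              n_retrocopies = 1L,
                              retrocopy_spec = list(tsd = "TTAAAAATGT",
                                                    polyA_len = 30L,
                                                    truncation_len = 250L),
                              contamination_fraction = 0.05,
                              activity = NULL) {
  stopifnot(inter_locus_divergence >= 0, inter_locus_divergence <= 1,
            read_error_rate >= 0, read_error_rate <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            type1_fraction >= 0, type1_fraction <= 1,
            n_tissues <= length(.TISSUES),
            n_nonref_in_db <= n_nonref_loci,
            n_retrocopies <= n_loci)
  if (!is.null(activity)) stopifnot(all(activity >= 0))
  structure(as.list(environment()), class = "hml2_sim_config")
}

# 0-based positions of functional elements protected from divergence
.protected_positions <- function(anatomy) {
  g <- .ANAT
  pr <- c(
    g$fwd_start:(g$fwd_start + g$fwd_len - 1L),
    g$rev_start:(g$rev_start + g$rev_len - 1L),
    g$SD1:(g$SD1 + 1L), (g$SA1 - 1L):g$SA1,
    g$SD2_np9:(g$SD2_np9 + 1L), g$SD2_rec:(g$SD2_rec + 1L),
    g$alt_SD:(g$alt_SD + 1L),
    (g$SA2 - 5L):(g$SA2 + 13L),               # SA2 + alt SA context block
    g$rec_stop:(g$rec_stop + 2L), g$np9_stop:(g$np9_stop + 2L),
    710L:715L, (g$ltr3_start + 710L):(g$ltr3_start + 715L)  # poly-A signals
  )
  sort(unique(pr))
}

# substitute a lineage away from the ancestor at `rate`, sparing protected
# positions; returns list(seq chars, positions (0-based), from, to)
.diverge <- function(chars, rate, protected) {
  n <- length(chars)
  free <- setdiff(seq_len(n) - 1L, protected)
  k <- stats::rbinom(1L, length(free), rate)
  pos <- sort(sample(free, k))
  from <- chars[pos + 1L]
  to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
               "")
  chars[pos + 1L] <- to
  list(chars = chars, positions = pos, from = from, to = unname(to))
}

# truth-side splicing arithmetic on known ancestor coordinates (independent
# of the alignment-based pipeline path)
.truth_windows <- function(type) {
  g <- .ANAT
  fe <- g$fwd_start + g$fwd_len        # insert start (after fwd primer)
  rs <- g$rev_start                    # insert end (before rev primer)
  d <- g$disc_len
  switch(type,
    type2_rec = list(c(fe, g$SD2_rec), c(g$SA2 + 1L, rs)),
    type1_np9 = list(c(fe, g$SD2_np9), c(g$SA2 + 1L - d, rs - d)),
    type1_np9_alt = list(c(fe, g$alt_SD - d), c(g$alt_SA + 1L - d, rs - d))
  )
}

.extract_windows <- function(seqchars, windows) {
  paste(vapply(windows, function(w)
    paste(seqchars[(w[1] + 1L):w[2]], collapse = ""), ""), collapse = "")
}

#' Generate a synthetic locus panel
#'
#' Derives a panel of paralogous HML-2 loci from the canonical synthetic
#' ancestor by seeded substitutions: reference type 1/type 2 loci (type 1
#' loci have the 292-bp discriminator excised, so they are exactly 292 nt
#' shorter than their type 2 siblings), retrocopy loci built by in-silico
#' L1 retrotransposition of a lineage's rec mRNA (5'-truncated, poly-A
#' tailed, TSD-flanked), and non-reference loci withheld from the catalog
#' carrying the SA2 AG->GG mutation (their transcripts splice via the
#' alternative +252/+7 sites). Loci receive random strands and invented
#' coordinates; the emitted FASTA holds genome-forward sequence.
#'
#' @param config a [simulation_config()].
#' @param anatomy a [hml2_anatomy()].
#' @return list of class `hml2_panel`: `loci` (cataloged [hml2_locus]
#'   objects), `nonref_loci`, `truth` (per-locus data.frame with true type,
#'   isoform, insert and product sequences, retrocopy flanks), `activity`
#'   (loci x tissues weight matrix over transcribed loci), `config`,
#'   `anatomy`.
#' @export
generate_panel <- function(config = simulation_config(),
                           anatomy = hml2_anatomy()) {
  .with_seed(config$seed, .generate_panel_impl(config, anatomy))
}

.generate_panel_impl <- function(config, anatomy) {
  anc <- strsplit(anatomy$seq, "")[[1]]
  protected <- .protected_positions(anatomy)
  g <- .ANAT
  n_ref <- config$n_loci
  n_retro <- config$n_retrocopies
  n_prov <- n_ref - n_retro
  n_t1 <- round(config$type1_fraction * n_prov)
  types <- c(rep("type1", n_t1), rep("type2", n_prov - n_t1),
             rep("retrocopy", n_retro))

  loci <- list(); truth <- NULL
  mk_coords <- function() {
    chrom <- paste0("chr", sample(1:22, 1L))
    start <- sample(1e6:2e8, 1L)
    strand <- sample(c("+", "-"), 1L)
    list(chrom = chrom, start = start, strand = strand)
  }
  for (i in seq_len(n_ref)) {
    id <- sprintf("HML2_%02d", i)
    lin <- .diverge(anc, config$inter_locus_divergence, protected)
    type <- types[i]
    flank5 <- flank3 <- NA_character_
    if (type == "type1") {
      chars <- lin$chars[-((g$disc_start + 1L):(g$disc_start + g$disc_len))]
      iso <- "np9"
      insert <- .extract_windows(chars, .truth_windows("type1_np9"))
    } else if (type == "type2") {
      chars <- lin$chars
      iso <- "rec"
      insert <- .extract_windows(chars, .truth_windows("type2_rec"))
    } else {  # retrocopy of this lineage's rec mRNA
      mrna <- .extract_windows(lin$chars, list(
        c(g$tx_start, g$SD1), c(g$SA1 + 1L, g$SD2_rec),
        c(g$SA2 + 1L, g$tx_end)))
      spec <- config$retrocopy_spec
      body <- substr(mrna, spec$truncation_len + 1L, nchar(mrna))
      chars <- strsplit(paste0(body, strrep("A", spec$polyA_len)), "")[[1]]
      tsd <- spec$tsd
      flank5 <- paste0(paste(sample(c("A", "C", "G", "T"), 40L, TRUE),
                             collapse = ""), tsd)
      flank3 <- paste0(tsd, paste(sample(c("A", "C", "G", "T"), 40L, TRUE),
                                  collapse = ""))
      iso <- "rec"
      insert <- .extract_windows(lin$chars, .truth_windows("type2_rec"))
    }
    co <- mk_coords()
    seq_fwd <- paste(chars, collapse = "")
    loci[[id]] <- hml2_locus(id, co$chrom, co$start,
                             co$start + length(chars) - 1L, co$strand,
                             seq_fwd, provirus_type = type,
                             hgnc_name = sprintf("ERVK-%d", 100 + i))
    truth <- rbind(truth, data.frame(
      locus_id = id, type = type, isoform = iso, in_catalog = TRUE,
      insert = insert, flank5 = flank5, flank3 = flank3,
      n_divergent = length(lin$positions), stringsAsFactors = FALSE))
  }

  nonref <- list()
  if (config$n_nonref_loci > 0L) {
    nr_names <- c("K111like", "VENTERlike",
                  sprintf("NONREF_%d", seq_len(max(0, config$n_nonref_loci - 2L))))
    for (j in seq_len(config$n_nonref_loci)) {
      id <- nr_names[j]
      lin <- .diverge(anc, config$inter_locus_divergence, protected)
      # SA2 AG -> GG kills the canonical acceptor; the +7 acceptor is used
      lin$chars[g$SA2] <- "G"   # 0-based SA2-1 (the A of AG) is R index SA2
      chars <- lin$chars[-((g$disc_start + 1L):(g$disc_start + g$disc_len))]
      co <- mk_coords()
      nonref[[id]] <- hml2_locus(id, co$chrom, co$start,
                                 co$start + length(chars) - 1L, co$strand,
                                 paste(chars, collapse = ""),
                                 provirus_type = "type1")
      truth <- rbind(truth, data.frame(
        locus_id = id, type = "type1", isoform = "np9_alt",
        in_catalog = FALSE,
        insert = .extract_windows(chars, lapply(
          .truth_windows("type1_np9_alt"), function(w) w)),
        flank5 = NA_character_, flank3 = NA_character_,
        n_divergent = length(lin$positions), stringsAsFactors = FALSE))
    }
  }

  tissues <- .TISSUES[seq_len(config$n_tissues)]
  act <- config$activity
  all_ids <- truth$locus_id
  if (is.null(act)) {
    act <- matrix(stats::rgamma(length(all_ids) * length(tissues),
                                shape = 0.7, rate = 1),
                  nrow = length(all_ids),
                  dimnames = list(all_ids, tissues))
  } else {
    stopifnot(nrow(act) == length(all_ids))
    if (is.null(rownames(act))) rownames(act) <- all_ids
    if (is.null(colnames(act))) colnames(act) <- tissues
  }

  structure(list(loci = loci, nonref_loci = nonref, truth = truth,
                 activity = act, config = config, anatomy = anatomy),
            class = "hml2_panel")
}

#' @export
print.hml2_panel <- function(x, ...) {
  tt <- table(x$truth$type[x$truth$in_catalog])
  cat(sprintf("<hml2_panel> %d cataloged loci (%s), %d non-reference\n",
              sum(x$truth$in_catalog),
              paste(names(tt), tt, sep = ":", collapse = ", "),
              sum(!x$truth$in_catalog)))
  invisible(x)
}

#' Simulate Sanger-like cDNA reads from a panel
#'
#' Draws, per tissue, `reads_per_tissue` reads multinomially over the
#' panel's transcribed loci according to the activity matrix. Each read is
#' the true amplicon insert of its source locus with seeded substitution
#' errors at `read_error_rate`; a `contamination_fraction` of reads is drawn
#' from the unspliced genomic sequence of retrocopy loci (identical in size
#' and sequence to their cDNA-derived product, as genomic DNA traces would
#' be).
#'
#' @param panel a [generate_panel()] result.
#' @return list of class `hml2_read_set`: `reads` (data.frame `read_id`,
#'   `seq`, `tissue`) and `truth` (one row per read: `read_id`, `tissue`,
#'   `source_locus`, `isoform`, `contamination`, `n_errors`,
#'   `error_positions`).
#' @export
simulate_reads <- function(panel) {
  config <- panel$config
  .with_seed(config$seed + 1L, .simulate_reads_impl(panel, config))
}

.simulate_reads_impl <- function(panel, config) {
  act <- panel$activity
  tissues <- colnames(act)
  truth_loci <- panel$truth
  retro_ids <- truth_loci$locus_id[truth_loci$type == "retrocopy"]
  total <- length(tissues) * config$reads_per_tissue
  rid <- src <- tis <- seqv <- errpos <- character(total)
  contamv <- logical(total)
  nerrs <- integer(total)
  i <- 0L
  for (t in seq_along(tissues)) {
    w <- act[, t]
    if (sum(w) == 0) {
      warning("tissue ", tissues[t], " has all-zero activity; no reads")
      next
    }
    n <- config$reads_per_tissue
    n_contam <- if (length(retro_ids) > 0L)
      stats::rbinom(1L, n, config$contamination_fraction) else 0L
    draw <- stats::rmultinom(1L, n - n_contam, w)[, 1L]
    sources <- c(rep(names(w), draw),
                 if (n_contam > 0L) sample(retro_ids, n_contam, replace = TRUE))
    contam <- c(rep(FALSE, n - n_contam), rep(TRUE, n_contam))
    for (k in seq_along(sources)) {
      i <- i + 1L
      row <- match(sources[k], truth_loci$locus_id)
      tmpl <- truth_loci$insert[row]
      nb <- nchar(tmpl)
      n_err <- stats::rbinom(1L, nb, config$read_error_rate)
      s <- tmpl
      pos <- integer(0)
      if (n_err > 0L) {
        pos <- sort(sample(nb, n_err))
        ch <- strsplit(tmpl, "")[[1]]
        for (p in pos)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        s <- paste(ch, collapse = "")
      }
      rid[i] <- sprintf("%s_r%04d", tissues[t], k)
      src[i] <- sources[k]; tis[i] <- tissues[t]; seqv[i] <- s
      contamv[i] <- contam[k]; nerrs[i] <- n_err
      errpos[i] <- paste(pos, collapse = ",")
    }
  }
  keep <- seq_len(i)
  iso <- truth_loci$isoform[match(src[keep], truth_loci$locus_id)]
  structure(list(
    reads = data.frame(read_id = rid[keep], seq = seqv[keep],
                       tissue = tis[keep], stringsAsFactors = FALSE),
    truth = data.frame(read_id = rid[keep], tissue = tis[keep],
                       source_locus = src[keep], isoform = iso,
                       contamination = contamv[keep], n_errors = nerrs[keep],
                       error_positions = errpos[keep],
                       stringsAsFactors = FALSE)),
    class = "hml2_read_set")
}

#' Write a simulated panel and reads to disk
#'
#' Emits `loci.fa`, `loci.tsv`, `reads.fa` (tissue carried in the FASTA
#' header), `tissues.tsv` and `truth.tsv` into a directory.
#'
#' @param panel a [generate_panel()] result.
#' @param read_set a [simulate_reads()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(panel, read_set, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("loci.fa", "loci.tsv", "reads.fa",
                               "tissues.tsv", "truth.tsv"))
  write_locus_catalog(panel$loci, paths[1], paths[2])
  rs <- Biostrings::DNAStringSet(read_set$reads$seq)
  names(rs) <- paste0(read_set$reads$read_id, " tissue=",
                      read_set$reads$tissue)
  Biostrings::writeXStringSet(rs, paths[3])
  utils::write.table(read_set$reads[, c("read_id", "tissue")], paths[4],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(read_set$truth, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
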