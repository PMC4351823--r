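# Coding-capacity screening: conceptual translation of predicted rec/np9
# mRNAs and comparison of Rec/Np9 protein variants.

#' Translate an open reading frame
#'
#' Standard-genetic-code translation of an mRNA from a given 0-based offset
#' to the first stop codon. Codons containing a non-ACGT base translate to
#' `X`.
#'
#' @param mrna nucleotide string.
#' @param start_offset 0-based offset of the first codon.
#' @return list with `protein` (amino-acid string, stop excluded),
#'   `stop_codon_index` (1-based triplet number of the stop codon, so a
#'   protein of N aa has stop index N + 1) and `open_ended` (TRUE when no
#'   stop occurs before the end of the sequence).
#' @examples
#' translate_orf("ATGTAA", 0)  # protein "M", stop at triplet 2
#' @export
translate_orf <- function(mrna, start_offset = 0L) {
  mrna <- toupper(mrna)
  stopifnot(start_offset + 3L <= nchar(mrna))
  n_codons <- (nchar(mrna) - start_offset) %/% 3L
  gc <- Biostrings::GENETIC_CODE
  aas <- character(0)
  for (i in seq_len(n_codons)) {
    codon <- substr(mrna, start_offset + 3L * (i - 1L) + 1L,
                    start_offset + 3L * i)
    if (grepl("[^ACGT]", codon)) { aas <- c(aas, "X"); next }
    aa <- gc[[codon]]
    if (aa == "*")
      return(list(protein = paste(aas, collapse = ""),
                  stop_codon_index = i, open_ended = FALSE))
    aas <- c(aas, aa)
  }
  list(protein = paste(aas, collapse = ""),
       stop_codon_index = NA_integer_, open_ended = TRUE)
}

#' Screen a locus for Rec or Np9 coding capacity
#'
#' Decides whether a locus can produce a spliced mRNA encoding a full-length
#' Rec (type 2 loci) or Np9 (type 1 loci) protein, following the criteria of
#' presence of both LTRs, intact splice donor and acceptor sites, and an
#' open reading frame in the predicted mRNA. The start codon is located by
#' homology projection of the shared Env/Rec/Np9 start from the canonical
#' anatomy. Capacity classes:
#'
#' * `full_length` — all criteria met and the protein is within
#'   `full_length_slack` aa of the canonical reference length;
#' * `short_variant` — a shorter but substantial ORF (at least
#'   `short_min_frac` of the reference length), covering proteins about ten
#'   or more aa shorter than full length and proteins identical to the
#'   canonical sequence only over their N-terminus;
#' * `none` — no spliceable mRNA, missing LTRs, or only a (very) short ORF.
#'
#' @param locus annotated locus ([annotate_locus()]).
#' @param anatomy a [hml2_anatomy()]; its `full_length_aa` entry for the
#'   protein kind is the reference length.
#' @param protein_kind `"Rec"` or `"Np9"`.
#' @param full_length_slack proteins within this many aa of the reference
#'   length count as full length (default 9: shorter Np9/Rec variants are
#'   described in the field as about ten or more aa short of full length).
#' @param short_min_frac minimum fraction of the reference length for a
#'   `short_variant` call (default 0.25).
#' @param reference_protein optional canonical protein sequence used to
#'   report the N-terminal identity length (defaults to the protein encoded
#'   by the canonical anatomy itself).
#' @return An object of class `hml2_orf_report`: list with `locus_id`,
#'   `protein_kind`, `capacity`, `criteria_flags` (`has_5ltr`, `has_3ltr`,
#'   `sd_ok`, `sa_ok`, `orf_ok`), `protein_seq`, `stop_codon_index`,
#'   `nterm_identity_aa`.
#' @export
scan_capacity <- function(locus, anatomy, protein_kind = c("Np9", "Rec"),
                          full_length_slack = 9L, short_min_frac = 0.25,
                          reference_protein = NULL) {
  protein_kind <- match.arg(protein_kind)
  iso <- if (protein_kind == "Np9") "np9" else "rec"
  want_type <- if (protein_kind == "Np9") "type1" else "type2"
  if (!identical(unclass(locus$type)[1], want_type))
    stop(protein_kind, " capacity is screened on ", want_type,
         " loci; locus ", locus$locus_id, " is ", locus$type, call. = FALSE)

  flags <- c(has_5ltr = FALSE, has_3ltr = FALSE, sd_ok = FALSE,
             sa_ok = FALSE, orf_ok = FALSE)
  flags["has_5ltr"] <- .ltr_present(locus, anatomy, "ltr5")
  flags["has_3ltr"] <- .ltr_present(locus, anatomy, "ltr3")
  need <- .ISOFORM_REQUIRES[[iso]]
  st <- locus$sites
  donors <- intersect(need, st$site[st$kind == "donor"])
  acceptors <- intersect(need, st$site[st$kind == "acceptor"])
  site_ok <- function(nm) isTRUE(st$motif_ok[match(nm, st$site)])
  flags["sd_ok"] <- all(vapply(donors, site_ok, logical(1)))
  flags["sa_ok"] <- all(vapply(acceptors, site_ok, logical(1)))

  report <- function(capacity, protein = "", stop_idx = NA_integer_,
                     nterm = NA_integer_) {
    structure(list(locus_id = locus$locus_id, protein_kind = protein_kind,
                   capacity = capacity, criteria_flags = flags,
                   protein_seq = protein, stop_codon_index = stop_idx,
                   nterm_identity_aa = nterm),
              class = "hml2_orf_report")
  }
  if (!all(flags[c("sd_ok", "sa_ok")]))
    return(report("none"))
  tx <- tryCatch(splice(locus, iso), hml2_splice_error = function(e) NULL)
  if (is.null(tx)) return(report("none"))
  start_locus <- .map_fallback(locus$map, anatomy$env_start, "down")
  start_tx <- if (is.na(start_locus)) NA_integer_ else .tx_coord(tx, start_locus)
  if (is.na(start_tx)) return(report("none"))
  tr <- translate_orf(tx$seq, start_tx)
  plen <- nchar(tr$protein)
  ref_len <- anatomy$full_length_aa[[protein_kind]]
  if (is.null(reference_protein))
    reference_protein <- .canonical_protein(anatomy, protein_kind)
  nterm <- .nterm_identity(tr$protein, reference_protein)
  capacity <-
    if (!all(flags[c("has_5ltr", "has_3ltr")])) "none"
    else if (plen >= ref_len - full_length_slack) "full_length"
    else if (plen >= short_min_frac * ref_len) "short_variant"
    else "none"
  flags["orf_ok"] <- capacity == "full_length"
  report(capacity, tr$protein, tr$stop_codon_index, nterm)
}

.ltr_present <- function(locus, anatomy, which_ltr) {
  rg <- anatomy[[which_ltr]]
  cols <- locus$map[(rg[1] + 1L):rg[2]]
  mean(!is.na(cols)) >= 0.8
}

.nterm_identity <- function(protein, reference) {
  n <- min(nchar(protein), nchar(reference))
  if (n == 0L) return(0L)
  a <- strsplit(substr(protein, 1, n), "")[[1]]
  b <- strsplit(substr(reference, 1, n), "")[[1]]
  d <- which(a != b)
  if (!length(d)) n else d[1L] - 1L
}

# canonical Rec/Np9 proteins encoded by the anatomy itself (cached)
.canonical_protein <- function(anatomy, protein_kind) {
  key <- paste0("prot_", protein_kind)
  p <- .anatomy_cache[[key]]
  if (!is.null(p)) return(p)
  if (protein_kind == "Rec") {
    l <- hml2_locus("canonical", "chrU", 1L, nchar(anatomy$seq), "+",
                    anatomy$seq, "type2")
    iso <- "rec"
  } else {
    d0 <- anatomy$discriminator[["offset"]]
    dl <- anatomy$discriminator[["length"]]
    s <- paste0(.sub0(anatomy$seq, 0L, d0), .sub0(anatomy$seq, d0 + dl,
                                                  nchar(anatomy$seq)))
    l <- hml2_locus("canonical_t1", "chrU", 1L, nchar(s), "+", s, "type1")
    iso <- "np9"
  }
  l <- annotate_locus(l, anatomy)
  tx <- splice(l, iso)
  start_tx <- .tx_coord(tx, .map_fallback(l$map, anatomy$env_start, "down"))
  p <- translate_orf(tx$seq, start_tx)$protein
  .anatomy_cache[[key]] <- p
  p
}

#' @export
print.hml2_orf_report <- function(x, ...) {
  cat(sprintf("<hml2_orf_report> %s %s: %s (%d aa%s)\n",
              x$locus_id, x$protein_kind, x$capacity, nchar(x$protein_seq),
              if (!is.na(x$stop_codon_index))
                sprintf(", stop at triplet %d", x$stop_codon_index) else ""))
  cat("  criteria:", paste(names(x$criteria_flags)[x$criteria_flags],
                           collapse = " "), "\n")
  invisible(x)
}

#' Compare protein variants by multiple alignment
#'
#' Aligns two or more protein sequences (center-star progressive alignment
#' against the longest sequence, built on pairwise global alignment with
#' BLOSUM62) and flags every column at which not all residues agree; gaps
#' disagree with residues. Deletions relative to the star reference are also
#' reported as runs per sequence.
#'
#' @param proteins character vector (length >= 2) of amino-acid strings,
#'   optionally named.
#' @return list of class `hml2_protein_cmp`: `alignment` (character matrix,
#'   rows = sequences), `flagged_columns` (integer vector of disagreeing
#'   columns), `deletion_runs` (data.frame `seq`, `start`, `length`, runs of
#'   gap columns per sequence).
#' @export
compare_protein_variants <- function(proteins) {
  stopifnot(length(proteins) >= 2L)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  ref_i <- which.max(nchar(proteins))
  ref <- proteins[[ref_i]]
  # per-sequence alignment to the star reference
  aligned_ref <- list(); aligned_seq <- list()
  for (i in seq_along(proteins)) {
    if (i == ref_i) { aligned_ref[[i]] <- ref; aligned_seq[[i]] <- ref; next }
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(proteins[[i]]),
      subject = Biostrings::AAString(ref),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    aligned_ref[[i]] <- as.character(Biostrings::alignedSubject(pa))
    aligned_seq[[i]] <- as.character(Biostrings::alignedPattern(pa))
  }
  # merge: collect insertion points relative to the reference
  ins <- rep(0L, nchar(ref) + 1L)  # max insertion length before ref pos k
  for (i in seq_along(proteins)) {
    r <- strsplit(aligned_ref[[i]], "")[[1]]
    pos <- 1L; run <- 0L
    for (ch in r) {
      if (ch == "-") run <- run + 1L
      else { ins[pos] <- max(ins[pos], run); run <- 0L; pos <- pos + 1L }
    }
    ins[pos] <- max(ins[pos], run)
  }
  ncol_out <- nchar(ref) + sum(ins)
  mat <- matrix("-", length(proteins), ncol_out,
                dimnames = list(names(proteins), NULL))
  for (i in seq_along(proteins)) {
    r <- strsplit(aligned_ref[[i]], "")[[1]]
    s <- strsplit(aligned_seq[[i]], "")[[1]]
    out <- character(0)
    pos <- 1L; pending <- character(0)
    flush_block <- function(out, pending, pos) {
      pad <- ins[pos] - length(pending)
      c(out, rep("-", pad), pending)
    }
    for (k in seq_along(r)) {
      if (r[k] == "-") pending <- c(pending, s[k])
      else {
        out <- flush_block(out, pending, pos)
        pending <- character(0)
        out <- c(out, s[k])
        pos <- pos + 1L
      }
    }
    out <- flush_block(out, pending, pos)
    mat[i, ] <- out
  }
  flagged <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  del <- NULL
  for (i in seq_along(proteins)) {
    r <- rle(mat[i, ] == "-")
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      del <- rbind(del, data.frame(seq = names(proteins)[i],
                                   start = ends[k] - r$lengths[k] + 1L,
                                   length = r$lengths[k],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(alignment = mat, flagged_columns = flagged,
                 deletion_runs = del %||%
                   data.frame(seq = character(), start = integer(),
                              length = integer())),
            class = "hml2_protein_cmp")
}

#' Detect a chimeric Rec/Np9 open reading frame
#'
#' Translates a splice-variant transcript and segments the resulting protein
#' by best identity against the canonical Rec and Np9 reference proteins:
#' every split point is scored as (local-alignment matches of the N-terminal
#' part against Rec) + (matches of the C-terminal part against Np9), and the
#' best split reported. A pure Rec (or Np9) protein yields a single segment.
#'
#' @param variant_transcript nucleotide string of the variant mRNA.
#' @param reference_models named list with `Rec` and `Np9` protein strings;
#'   defaults to the proteins encoded by the canonical anatomy.
#' @param anatomy a [hml2_anatomy()] (used for the default references).
#' @param start_offset 0-based offset of the start codon in the transcript;
#'   by default the first ATG.
#' @return list of class `hml2_chimera_report`: `coding` (FALSE for a
#'   non-coding variant), `protein`, `segments` (data.frame `source`,
#'   `start`, `end` in protein coordinates), `breakpoint` (last Rec codon,
#'   NA for single-segment proteins).
#' @export
detect_chimeric_orf <- function(variant_transcript, reference_models = NULL,
                                anatomy = hml2_anatomy(), start_offset = NULL) {
  if (is.null(reference_models))
    reference_models <- list(Rec = .canonical_protein(anatomy, "Rec"),
                             Np9 = .canonical_protein(anatomy, "Np9"))
  s <- toupper(variant_transcript)
  if (is.null(start_offset)) {
    m <- regexpr("ATG", s, fixed = TRUE)
    if (m < 0) return(structure(list(coding = FALSE, protein = "",
                                     segments = NULL, breakpoint = NA),
                                class = "hml2_chimera_report"))
    start_offset <- as.integer(m) - 1L
  }
  tr <- translate_orf(s, start_offset)
  prot <- tr$protein
  if (nchar(prot) < 10L)
    return(structure(list(coding = FALSE, protein = prot, segments = NULL,
                          breakpoint = NA), class = "hml2_chimera_report"))
  n <- nchar(prot)
  score_vs <- function(frag, ref) {
    if (!nzchar(frag)) return(0)
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(frag),
      subject = Biostrings::AAString(ref),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    Biostrings::nmatch(pa)
  }
  ks <- 0:n
  scores <- vapply(ks, function(k)
    score_vs(substr(prot, 1, k), reference_models$Rec) +
      score_vs(substr(prot, k + 1, n), reference_models$Np9), 0)
  k <- ks[which.max(scores)]
  segments <- NULL
  if (k == n) {
    segments <- data.frame(source = "Rec", start = 1L, end = n,
                           stringsAsFactors = FALSE)
    bp <- NA_integer_
  } else if (k == 0L) {
    segments <- data.frame(source = "Np9", start = 1L, end = n,
                           stringsAsFactors = FALSE)
    bp <- NA_integer_
  } else {
    segments <- data.frame(source = c("Rec", "Np9"),
                           start = c(1L, k + 1L), end = c(k, n),
                           stringsAsFactors = FALSE)
    bp <- k
  }
  structure(list(coding = TRUE, protein = prot, segments = segments,
                 breakpoint = bp),
            class = "hml2_chimera_report")
}
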