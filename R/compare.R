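# Mismatch counting between cDNA reads and predicted amplicon inserts.

# Difference events between aligned pattern/subject strings, after trimming
# terminal overhang columns (leading/trailing columns where either side is a
# gap). Returns a data.frame of events: type ("mismatch" | "gap"),
# subject_pos (1-based position in the original subject; for a gap run, the
# subject position where the run starts), len (gap run length in columns).
# `subj_start` is the 1-based subject position of the first aligned column
# (local/overlap alignments clip the subject).
.aln_events <- function(ap, as_, subj_start = 1L) {
  a <- strsplit(ap, "")[[1]]
  b <- strsplit(as_, "")[[1]]
  gap_a <- a == "-"
  gap_b <- b == "-"
  ncol_ <- length(a)
  # trim terminal overhangs
  lead <- 0L
  while (lead < ncol_ && (gap_a[lead + 1L] || gap_b[lead + 1L])) lead <- lead + 1L
  trail <- 0L
  while (trail < ncol_ - lead &&
         (gap_a[ncol_ - trail] || gap_b[ncol_ - trail])) trail <- trail + 1L
  keep <- if (lead + trail >= ncol_) integer(0) else (lead + 1L):(ncol_ - trail)
  subj_pos <- cumsum(!gap_b) + (subj_start - 1L)  # subject coord per column
  if (!length(keep))
    return(list(events = data.frame(type = character(), subject_pos = integer(),
                                    len = integer()), length = 0L))
  ka <- a[keep]; kb <- b[keep]
  kgap_a <- gap_a[keep]; kgap_b <- gap_b[keep]
  kpos <- subj_pos[keep]
  mism <- which(!kgap_a & !kgap_b & ka != kb)
  ev <- data.frame(type = rep("mismatch", length(mism)),
                   subject_pos = kpos[mism],
                   len = rep(1L, length(mism)), stringsAsFactors = FALSE)
  gap_col <- kgap_a | kgap_b
  if (any(gap_col)) {
    r <- rle(gap_col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    ev <- rbind(ev, data.frame(
      type = rep("gap", length(gi)),
      subject_pos = pmax(1L, kpos[starts[gi]]),
      len = r$lengths[gi], stringsAsFactors = FALSE))
  }
  list(events = ev, length = length(keep))
}

#' Count sequence differences between two nucleotide strings
#'
#' Globally aligns `a` against `b` with free end gaps (terminal overhangs are
#' excluded from the comparison) and counts difference events: substitution
#' columns plus the number of indel events. By default an indel of any length
#' counts as one event (one gap run); `indel_policy = "per_base"` counts each
#' gapped column instead, for sensitivity analysis.
#'
#' @param a,b non-empty nucleotide strings.
#' @param indel_policy `"per_run"` (default) or `"per_base"`.
#' @return named numeric vector `c(differences, compared_length)`;
#'   `compared_length` is the number of aligned columns excluding terminal
#'   overhangs. Attribute `low_quality` is TRUE when either input has more
#'   than 10% N.
#' @examples
#' compare_sequences(strrep("ACGT", 10), strrep("ACGT", 10))
#' @export
compare_sequences <- function(a, b, indel_policy = c("per_run", "per_base")) {
  indel_policy <- match.arg(indel_policy)
  stopifnot(nzchar(a), nzchar(b))
  lowq <- .n_frac(a) > 0.1 || .n_frac(b) > 0.1
  if (identical(a, b)) {
    out <- c(differences = 0, compared_length = nchar(a))
    attr(out, "low_quality") <- lowq
    return(out)
  }
  pa <- .align(a, b, type = "overlap")
  res <- .aln_events(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)),
                     Biostrings::start(Biostrings::subject(pa)))
  out <- c(differences = .count_events(res$events, indel_policy),
           compared_length = res$length)
  attr(out, "low_quality") <- lowq
  out
}

.n_frac <- function(x) {
  lengths(regmatches(x, gregexpr("N", x, fixed = TRUE))) / nchar(x)
}

# min_subject_pos masks substitution columns only (e.g. the short np9
# exon 2); indel events are structural and are never masked.
.count_events <- function(ev, indel_policy = "per_run", min_subject_pos = 0L) {
  n_mism <- sum(ev$type == "mismatch" & ev$subject_pos > min_subject_pos)
  gaps <- ev[ev$type == "gap", , drop = FALSE]
  n_gap <- if (indel_policy == "per_run") nrow(gaps) else sum(gaps$len)
  n_mism + n_gap
}

# Vectorised comparison of many reads against one insert, on the C-backed
# alignment accessors (nmismatch / mismatchTable / indel / nchar), which are
# far cheaper than materialising aligned strings. Overlap (ends-free)
# alignment clips terminal overhangs, so every reported event is internal.
# Returns per-read: mismatch count, mismatch subject positions, gap run
# count, gapped column count, and compared length (alignment columns).
.compare_many <- function(reads, insert) {
  n <- length(reads)
  n_mism <- integer(n); gap_runs <- integer(n); gap_cols <- integer(n)
  lens <- integer(n)
  mism_pos <- vector("list", n)
  todo <- which(reads != insert)
  lens[setdiff(seq_len(n), todo)] <- nchar(insert)
  if (length(todo)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads[todo]),
      subject = Biostrings::DNAString(insert),
      type = "overlap", substitutionMatrix = .dna_submat(),
      gapOpening = 4, gapExtension = 1)
    n_mism[todo] <- Biostrings::nmismatch(pa)
    ins <- Biostrings::insertion(Biostrings::indel(pa))
    del <- Biostrings::deletion(Biostrings::indel(pa))
    gap_runs[todo] <- S4Vectors::elementNROWS(ins) +
      S4Vectors::elementNROWS(del)
    gap_cols[todo] <- as.integer(sum(IRanges::width(ins))) +
      as.integer(sum(IRanges::width(del)))
    # alignment columns = matches + mismatches + gapped columns
    lens[todo] <- Biostrings::nmatch(pa) + n_mism[todo] + gap_cols[todo]
    mt <- Biostrings::mismatchTable(pa)
    if (nrow(mt)) {
      sp <- split(mt$SubjectStart, mt$PatternId)
      for (nm in names(sp)) mism_pos[[todo[as.integer(nm)]]] <- sp[[nm]]
    }
  }
  list(n_mism = n_mism, mism_pos = mism_pos, gap_runs = gap_runs,
       gap_cols = gap_cols, lengths = lens)
}

# difference count from a .compare_many slot, masking substitution columns
# at or before `min_subject_pos` (indel events are structural, never masked)
.cm_count <- function(cm, i, indel_policy = "per_run", min_subject_pos = 0L) {
  mism <- if (min_subject_pos > 0L && !is.null(cm$mism_pos[[i]]))
    sum(cm$mism_pos[[i]] > min_subject_pos) else cm$n_mism[i]
  gaps <- if (indel_policy == "per_run") cm$gap_runs[i] else cm$gap_cols[i]
  mism + gaps
}
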