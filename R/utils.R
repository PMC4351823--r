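# Internal helpers shared across modules.
#
# Coordinate conventions (package-wide):
#  - external files (catalog TSV, GFF3) are 1-based inclusive;
#  - all internal offsets are 0-based half-open.

# Deterministic pseudo-random bases from a package-internal LCG
# (Park-Miller), independent of R's global RNG so the canonical anatomy is
# identical no matter what seed the user session carries.
.lcg_bases <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  k <- length(alphabet)
  out <- character(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- alphabet[state %% k + 1]
  }
  out
}

# overwrite `word` into a character vector of single bases at 0-based offset
.plant <- function(chars, at0, word) {
  w <- strsplit(word, "", fixed = TRUE)[[1]]
  stopifnot(at0 >= 0, at0 + length(w) <= length(chars))
  chars[(at0 + 1):(at0 + length(w))] <- w
  chars
}

# substring by 0-based half-open interval
.sub0 <- function(seq, start0, end0) {
  if (end0 <= start0) return("")
  substr(seq, start0 + 1, end0)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# nucleotide scoring used for all DNA pairwise alignments
# (match = 1, mismatch = -1, affine gaps open 4 / extend 1)
.dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.align <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = type,
    substitutionMatrix = .dna_submat(),
    gapOpening = 4, gapExtension = 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
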