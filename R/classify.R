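# Locus annotation against the canonical anatomy: coordinate projection by
# global pairwise alignment, type 1/2 classification by the 292-bp env
# discriminator, and splice-site annotation.

# Global alignment of a locus against the anatomy; returns an integer map of
# length nchar(anatomy$seq): map[i] = 0-based locus offset aligned to
# 0-based anatomy offset i-1, NA where the anatomy column is deleted in the
# locus.
.project_locus <- function(locus, anatomy) {
  n_a <- nchar(anatomy$seq)
  n_l <- nchar(locus$seq)
  # verified fast paths for the two dominant colinear cases; anything that
  # fails verification falls through to the full global alignment
  if (n_l == n_a && .hamming(locus$seq, anatomy$seq) <= 0.05 * n_a)
    return(0:(n_a - 1L))
  d0 <- anatomy$discriminator[["offset"]]
  dl <- anatomy$discriminator[["length"]]
  if (n_l == n_a - dl) {
    anat_t1 <- .anatomy_cache$anat_minus_disc
    if (is.null(anat_t1)) {
      anat_t1 <- paste0(.sub0(anatomy$seq, 0L, d0), .sub0(anatomy$seq, d0 + dl, n_a))
      .anatomy_cache$anat_minus_disc <- anat_t1
    }
    if (.hamming(locus$seq, anat_t1) <= 0.05 * n_l) {
      map <- rep(NA_integer_, n_a)
      map[seq_len(d0)] <- 0:(d0 - 1L)
      map[(d0 + dl + 1L):n_a] <- d0:(n_l - 1L)
      return(map)
    }
  }
  pa <- .align(locus$seq, anatomy$seq, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  n_anat <- nchar(anatomy$seq)
  map <- rep(NA_integer_, n_anat)
  ai <- 0L  # anatomy offset of the current column (0-based, post-increment)
  li <- 0L
  for (k in seq_along(ap)) {
    pgap <- ap[k] == "-"
    sgap <- as_[k] == "-"
    if (!sgap) {
      ai <- ai + 1L
      if (!pgap) map[ai] <- li
    }
    if (!pgap) li <- li + 1L
  }
  map
}

#' Classify a locus as provirus type 1 or type 2
#'
#' Type 2 proviruses retain a characteristic 292-bp sequence located about
#' 50 bp into the `env` coding sequence; type 1 proviruses lack it (and with
#' it the `rec` splice donor). Classification projects the locus onto the
#' canonical anatomy by global pairwise alignment and inspects how much of
#' the discriminator region is aligned: `"type2"` when at least
#' `min_aligned_frac` of its columns are present, `"type1"` when it is
#' cleanly deleted (almost no columns aligned but both flanks are), and
#' `"undetermined"` otherwise (for instance large truncations, solo LTRs, or
#' retrocopies whose missing sequence extends well beyond the discriminator).
#'
#' @param locus a [hml2_locus].
#' @param anatomy a [hml2_anatomy].
#' @param min_aligned_frac fraction of discriminator columns that must align
#'   for a type 2 call (default 0.9).
#' @param map optional precomputed projection map (internal reuse).
#' @return character scalar: `"type1"`, `"type2"` or `"undetermined"`, with a
#'   `reason` attribute when undetermined.
#' @export
classify_provirus_type <- function(locus, anatomy, min_aligned_frac = 0.9,
                                   map = NULL) {
  if (nchar(locus$seq) < 200L)
    return(structure("undetermined", reason = "locus shorter than 200 nt"))
  if (is.null(map)) map <- .project_locus(locus, anatomy)
  d0 <- anatomy$discriminator[["offset"]]
  dl <- anatomy$discriminator[["length"]]
  disc_cols <- map[(d0 + 1):(d0 + dl)]
  frac <- mean(!is.na(disc_cols))
  if (frac >= min_aligned_frac) return("type2")
  flank <- 30L
  up <- map[(d0 - flank + 1):d0]
  down <- map[(d0 + dl + 1):(d0 + dl + flank)]
  flanks_ok <- mean(!is.na(up)) >= 0.8 && mean(!is.na(down)) >= 0.8
  if (frac <= 1 - min_aligned_frac && flanks_ok) return("type1")
  structure("undetermined",
            reason = sprintf("discriminator %.0f%% aligned, flanks %s",
                             100 * frac,
                             if (flanks_ok) "aligned" else "not aligned"))
}

.SITE_KIND <- c(SD1 = "donor", SA1 = "acceptor", SD2_rec = "donor",
                SD2_np9 = "donor", alt_SD = "donor", SA2 = "acceptor",
                alt_SA = "acceptor")

#' Annotate the splice-site set of a locus
#'
#' Projects each canonical splice site (SD1, SA1, SD2_rec, SD2_np9, alt_SD,
#' SA2, alt_SA) onto the locus via global pairwise alignment to the canonical
#' anatomy and checks the splice motif from the locus's own bases: a donor is
#' `motif_ok` when its intron starts `GT`, an acceptor when its intron ends
#' `AG`. Donor positions are the first intron base, acceptor positions the
#' last intron base (0-based offsets into the provirus-forward sequence).
#'
#' SD2_rec is only defined for type 2 loci (it lies inside the 292-bp
#' discriminator) and alt_SD only for type 1 loci (where it sits 252 nt
#' downstream of SD2_np9). Sites falling in deleted or N-masked regions are
#' reported with status `"unlocatable"`, never dropped.
#'
#' @inheritParams classify_provirus_type
#' @param provirus_type classification of the locus (from
#'   [classify_provirus_type()]); controls which sites are defined.
#' @return data.frame of class `hml2_sites` with columns `site`, `kind`,
#'   `position`, `motif_ok`, `context` (10-nt window) and `status`
#'   (`"ok"`, `"dead"`, `"unlocatable"`, `"undefined"`).
#' @export
locate_splice_sites <- function(locus, anatomy, provirus_type = NULL,
                                map = NULL) {
  if (is.null(map)) map <- .project_locus(locus, anatomy)
  if (is.null(provirus_type))
    provirus_type <- classify_provirus_type(locus, anatomy, map = map)

  sites <- names(anatomy$sites)
  out <- data.frame(site = sites, kind = unname(.SITE_KIND[sites]),
                    position = NA_integer_, motif_ok = NA,
                    context = NA_character_, status = "unlocatable",
                    stringsAsFactors = FALSE)
  n <- nchar(locus$seq)
  for (i in seq_along(sites)) {
    nm <- sites[i]
    if (nm == "SD2_rec" && provirus_type != "type2") {
      out$status[i] <- "undefined"; next
    }
    if (nm == "alt_SD" && provirus_type == "type2") {
      out$status[i] <- "undefined"; next
    }
    pos <- map[anatomy$sites[[nm]] + 1L]
    if (is.na(pos)) next  # unlocatable
    out$position[i] <- pos
    if (out$kind[i] == "donor") {
      dinuc <- .sub0(locus$seq, pos, pos + 2L)
      ctx <- .sub0(locus$seq, max(0L, pos - 4L), min(n, pos + 6L))
      ok <- identical(dinuc, "GT")
    } else {
      dinuc <- .sub0(locus$seq, pos - 1L, pos + 1L)
      ctx <- .sub0(locus$seq, max(0L, pos - 5L), min(n, pos + 5L))
      ok <- identical(dinuc, "AG")
    }
    if (grepl("N", dinuc)) { out$status[i] <- "unlocatable"; next }
    out$motif_ok[i] <- ok
    out$context[i] <- ctx
    out$status[i] <- if (ok) "ok" else "dead"
  }
  class(out) <- c("hml2_sites", class(out))
  out
}

#' Annotate a panel of loci
#'
#' Runs classification and splice-site annotation for each locus, reusing one
#' global alignment per locus. The projection map and the transcript
#' boundaries projected onto the locus are attached for downstream splicing.
#'
#' @param loci list of [hml2_locus].
#' @param anatomy a [hml2_anatomy].
#' @return list of annotated loci; each gains elements `type` (classifier
#'   call), `sites` ([locate_splice_sites()] table), `map` (projection) and
#'   `tx_bounds` (0-based half-open transcript window on the locus).
#' @export
annotate_loci <- function(loci, anatomy) {
  lapply(loci, annotate_locus, anatomy = anatomy)
}

#' @rdname annotate_loci
#' @param locus single [hml2_locus].
#' @export
annotate_locus <- function(locus, anatomy) {
  map <- .project_locus(locus, anatomy)
  locus$type <- classify_provirus_type(locus, anatomy, map = map)
  locus$sites <- locate_splice_sites(locus, anatomy,
                                     provirus_type = locus$type, map = map)
  locus$map <- map
  locus$tx_bounds <- c(.map_fallback(map, anatomy$transcript_start, "down"),
                       .map_fallback(map, anatomy$transcript_end - 1L, "up") + 1L)
  locus
}

# nearest mapped locus position at or after ("down") / at or before ("up")
# the given anatomy offset
.map_fallback <- function(map, anat0, direction) {
  n <- length(map)
  i <- anat0 + 1L
  idx <- if (direction == "down") i:n else i:1L
  for (k in idx) if (!is.na(map[k])) return(map[k])
  NA_integer_
}
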