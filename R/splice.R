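# In-silico splicing: assemble transcript isoforms from an annotated locus.

.ISOFORM_REQUIRES <- list(
  full_length = character(0),
  env     = c("SD1", "SA1"),
  rec     = c("SD1", "SA1", "SD2_rec", "SA2"),
  np9     = c("SD1", "SA1", "SD2_np9", "SA2"),
  np9_alt = c("SD1", "SA1", "alt_SD", "alt_SA")
)

.site_pos <- function(sites, name) {
  i <- match(name, sites$site)
  sites$position[i]
}

.splice_error <- function(msg, site = NA_character_) {
  stop(errorCondition(msg, site = site,
                      class = c("hml2_splice_error", "error", "condition")))
}

#' Assemble an in-silico spliced transcript isoform
#'
#' Builds the `env`, `rec`, `np9`, `np9_alt` or `full_length` transcript of
#' an annotated locus from its splice-site set. Each isoform requires its
#' sites to be located and `motif_ok`; a missing or dead required site raises
#' a splice error naming the site (condition class `hml2_splice_error`)
#' unless `force = TRUE`, in which case the transcript is built from the
#' projected positions anyway and flagged.
#'
#' `rec` is refused on type 1 loci (SD2_rec lies inside the missing 292-bp
#' discriminator); `np9` is refused on type 2 loci by default because `np9`
#' mRNA is the product of type 1 loci, where the upstream donor is used after
#' loss of SD2_rec (`force` overrides).
#'
#' @param locus an annotated locus (see [annotate_locus()]).
#' @param isoform_name one of `"env"`, `"rec"`, `"np9"`, `"np9_alt"`,
#'   `"full_length"`.
#' @param force build even if sites are dead or the type/isoform pairing is
#'   non-canonical.
#' @return An object of class `hml2_isoform`: list with `isoform_name`,
#'   `exons` (matrix of 0-based half-open locus intervals), `seq`,
#'   `source_locus_id`, `forced`.
#' @export
splice <- function(locus, isoform_name, force = FALSE) {
  isoform_name <- match.arg(isoform_name, names(.ISOFORM_REQUIRES))
  if (is.null(locus$sites))
    stop("locus must be annotated first (see annotate_locus())", call. = FALSE)
  type <- locus$type %||% locus$provirus_type
  if (!force) {
    if (isoform_name == "rec" && type == "type1")
      .splice_error("rec requires SD2_rec, absent from type 1 loci", "SD2_rec")
    if (isoform_name == "np9" && type == "type2")
      .splice_error("np9 is refused on type 2 loci (use force to override)",
                    "SD2_np9")
  }
  sites <- locus$sites
  for (nm in .ISOFORM_REQUIRES[[isoform_name]]) {
    i <- match(nm, sites$site)
    ok <- !is.na(sites$position[i]) && isTRUE(sites$motif_ok[i])
    if (!ok && !force)
      .splice_error(paste0("required splice site ", nm, " is ",
                           sites$status[i], " for locus ", locus$locus_id), nm)
    if (is.na(sites$position[i]))
      .splice_error(paste0("site ", nm, " has no position on locus ",
                           locus$locus_id), nm)
  }
  tx <- locus$tx_bounds
  if (any(is.na(tx)))
    .splice_error(paste0("transcript bounds unresolvable for locus ",
                         locus$locus_id))
  p <- function(nm) .site_pos(sites, nm)
  exons <- switch(isoform_name,
    full_length = rbind(c(tx[1], tx[2])),
    env     = rbind(c(tx[1], p("SD1")), c(p("SA1") + 1L, tx[2])),
    rec     = rbind(c(tx[1], p("SD1")), c(p("SA1") + 1L, p("SD2_rec")),
                    c(p("SA2") + 1L, tx[2])),
    np9     = rbind(c(tx[1], p("SD1")), c(p("SA1") + 1L, p("SD2_np9")),
                    c(p("SA2") + 1L, tx[2])),
    np9_alt = rbind(c(tx[1], p("SD1")), c(p("SA1") + 1L, p("alt_SD")),
                    c(p("alt_SA") + 1L, tx[2]))
  )
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2] <= exons[, 1]) ||
      (nrow(exons) > 1 && any(diff(exons[, 1]) <= 0)))
    .splice_error(paste0("degenerate exon structure for ", isoform_name,
                         " on locus ", locus$locus_id))
  seq <- paste(vapply(seq_len(nrow(exons)), function(i)
    .sub0(locus$seq, exons[i, 1], exons[i, 2]), ""), collapse = "")
  structure(
    list(isoform_name = isoform_name, exons = exons, seq = seq,
         source_locus_id = locus$locus_id, forced = force),
    class = "hml2_isoform"
  )
}

#' @export
print.hml2_isoform <- function(x, ...) {
  cat(sprintf("<hml2_isoform> %s from %s: %d exon(s), %d nt%s\n",
              x$isoform_name, x$source_locus_id, nrow(x$exons),
              nchar(x$seq), if (x$forced) " (forced)" else ""))
  invisible(x)
}

# transcript coordinate of a locus position (0-based); NA if intronic
.tx_coord <- function(isoform, locus_pos) {
  off <- 0L
  for (i in seq_len(nrow(isoform$exons))) {
    s <- isoform$exons[i, 1]; e <- isoform$exons[i, 2]
    if (locus_pos >= s && locus_pos < e) return(off + (locus_pos - s))
    off <- off + (e - s)
  }
  NA_integer_
}
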