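#' Construct a proviral locus record
#'
#' A `hml2_locus` carries a genomic HML-2 locus in provirus-forward
#' orientation together with its catalog metadata. Sequences of minus-strand
#' loci must already be reverse-complemented (as [load_locus_catalog()] does).
#'
#' @param locus_id unique identifier.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @param seq nucleotide string (A/C/G/T/N) in provirus-forward orientation.
#' @param provirus_type one of `"type1"`, `"type2"`, `"retrocopy"`,
#'   `"undetermined"`.
#' @param hgnc_name optional HGNC-style locus name.
#' @return An object of class `hml2_locus`.
#' @export
hml2_locus <- function(locus_id, chrom, start, end, strand, seq,
                       provirus_type = "undetermined", hgnc_name = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start)
    stop("locus '", locus_id, "': end < start", call. = FALSE)
  seq <- toupper(seq)
  if (nchar(seq) != end - start + 1L)
    stop("locus '", locus_id, "': sequence length ", nchar(seq),
         " does not match coordinates (", end - start + 1L, ")", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("locus '", locus_id, "': sequence contains non-ACGTN characters",
         call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("locus '", locus_id, "': strand must be '+' or '-'", call. = FALSE)
  provirus_type <- match.arg(provirus_type,
                             c("undetermined", "type1", "type2", "retrocopy"))
  structure(
    list(locus_id = locus_id, chrom = chrom, start = start, end = end,
         strand = strand, provirus_type = provirus_type, seq = seq,
         hgnc_name = hgnc_name),
    class = "hml2_locus"
  )
}

#' @export
print.hml2_locus <- function(x, ...) {
  cat(sprintf("<hml2_locus> %s  %s:%d-%d(%s)  %s  %d nt%s\n",
              x$locus_id, x$chrom, x$start, x$end, x$strand,
              x$provirus_type, nchar(x$seq),
              if (!is.na(x$hgnc_name)) paste0("  [", x$hgnc_name, "]") else ""))
  invisible(x)
}

#' Load a locus catalog and its sequences
#'
#' Reads a tab-separated locus catalog (header
#' `locus_id chrom start end strand type hgnc_name`, coordinates 1-based
#' inclusive) together with a FASTA file of genomic sequences keyed by
#' `locus_id`. FASTA records hold the genome-forward sequence; minus-strand
#' loci are reverse-complemented into provirus-forward orientation on load.
#'
#' @param fasta_path path to the locus FASTA.
#' @param catalog_path path to the catalog TSV.
#' @return A list of [hml2_locus] objects (possibly empty, with a warning).
#' @export
load_locus_catalog <- function(fasta_path, catalog_path) {
  if (!file.exists(catalog_path))
    stop("catalog file not found: ", catalog_path, call. = FALSE)
  cat_df <- utils::read.delim(catalog_path, header = TRUE,
                              colClasses = "character")
  required <- c("locus_id", "chrom", "start", "end", "strand", "type")
  missing_cols <- setdiff(required, names(cat_df))
  if (length(missing_cols))
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cat_df) == 0L) {
    warning("empty locus catalog: ", catalog_path)
    return(list())
  }
  if (anyDuplicated(cat_df$locus_id))
    stop("duplicate locus_id in catalog: ",
         paste(unique(cat_df$locus_id[duplicated(cat_df$locus_id)]),
               collapse = ", "), call. = FALSE)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  loci <- vector("list", nrow(cat_df))
  for (i in seq_len(nrow(cat_df))) {
    row <- cat_df[i, ]
    if (!row$locus_id %in% names(seqs))
      stop("no FASTA record for locus '", row$locus_id, "'", call. = FALSE)
    s <- as.character(seqs[[row$locus_id]])
    if (row$strand == "-") s <- .revcomp(s)
    loci[[i]] <- hml2_locus(
      locus_id = row$locus_id, chrom = row$chrom,
      start = as.integer(row$start), end = as.integer(row$end),
      strand = row$strand, seq = s,
      provirus_type = row$type,
      hgnc_name = if ("hgnc_name" %in% names(cat_df) &&
                      nzchar(row$hgnc_name %||% "")) row$hgnc_name
                  else NA_character_
    )
  }
  names(loci) <- cat_df$locus_id
  loci
}

#' Project a locus back to genome orientation
#'
#' Inverse of the orientation handling in [load_locus_catalog()]: returns the
#' genome-forward sequence of a locus (reverse-complementing minus-strand
#' loci), so a load/re-project round trip reproduces the FASTA record.
#'
#' @param locus a [hml2_locus].
#' @return character, genome-forward sequence.
#' @export
genome_sequence <- function(locus) {
  stopifnot(inherits(locus, "hml2_locus"))
  if (locus$strand == "-") .revcomp(locus$seq) else locus$seq
}

#' Write loci to FASTA + catalog TSV
#'
#' Counterpart of [load_locus_catalog()]; sequences are written
#' genome-forward.
#'
#' @param loci list of [hml2_locus].
#' @param fasta_path,catalog_path output paths.
#' @return invisibly, the catalog data.frame.
#' @export
write_locus_catalog <- function(loci, fasta_path, catalog_path) {
  df <- data.frame(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, `[[`, 0L, "start"),
    end = vapply(loci, `[[`, 0L, "end"),
    strand = vapply(loci, `[[`, "", "strand"),
    type = vapply(loci, `[[`, "", "provirus_type"),
    hgnc_name = vapply(loci, function(l) l$hgnc_name %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  seqs <- Biostrings::DNAStringSet(vapply(loci, genome_sequence, ""))
  names(seqs) <- df$locus_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(df, catalog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Export annotated splice sites as GFF3
#'
#' Writes the splice-site annotations of a set of annotated loci as GFF3
#' (`splice_donor` / `splice_acceptor` features, 1-based coordinates on the
#' locus's own provirus-forward sequence).
#'
#' @param annotated list of annotated loci, as returned by [annotate_loci()].
#' @param path output GFF3 path.
#' @return invisibly, the exported `GRanges`.
#' @export
export_sites_gff3 <- function(annotated, path) {
  rows <- list()
  for (l in annotated) {
    st <- l$sites
    st <- st[!st$status %in% c("unlocatable", "undefined"), , drop = FALSE]
    if (!nrow(st)) next
    st$locus_id <- l$locus_id
    rows[[l$locus_id]] <- st
  }
  gr <- if (length(rows)) {
    all <- do.call(rbind, unname(rows))
    GenomicRanges::GRanges(
      seqnames = all$locus_id,
      ranges = IRanges::IRanges(start = all$position + 1L, width = 1L),
      strand = "+",
      type = ifelse(all$kind == "donor", "splice_donor", "splice_acceptor"),
      site = all$site,
      motif_ok = all$motif_ok
    )
  } else GenomicRanges::GRanges()
  rtracklayer::export.gff3(gr, path)
  invisible(gr)
}
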