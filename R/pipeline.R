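# Pipeline orchestration: annotate -> splice -> pcr -> assign -> variants ->
# tabulate, with a run manifest.

#' Run the full analysis pipeline
#'
#' Chains the pipeline stages end to end: generate (or load) a locus panel
#' and reads, annotate loci against the canonical anatomy, build the
#' amplicon database, assign reads, route unassignable reads to
#' non-reference matching, call alternative splice variants on them, and
#' tabulate tissue-by-locus counts. Fails fast on stage errors and is
#' deterministic for a fixed config.
#'
#' @param config a [simulation_config()]; its seed drives every random
#'   draw.
#' @param params an [assignment_params()].
#' @param anatomy a [hml2_anatomy()].
#' @param call_variants detect alternative splice variants on unassignable
#'   reads (default TRUE).
#' @param outdir optional directory; when given, all artifacts (panel,
#'   reads, results, counts, manifest) are serialized there and digested in
#'   the manifest.
#' @return list of class `hml2_run`: `panel`, `read_set`, `annotated`, `db`,
#'   `results`, `nonref` (partition or NULL), `variants`, `counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         params = assignment_params(),
                         anatomy = hml2_anatomy(),
                         call_variants = TRUE,
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- stage("simulate", generate_panel(config, anatomy))
  read_set <- stage("simulate", simulate_reads(panel))
  annotated <- stage("annotate", annotate_loci(panel$loci, anatomy))
  db <- stage("pcr", build_amplicon_db(annotated))
  results <- stage("assign", assign_reads(read_set$reads, db, params))

  nonref <- NULL
  nonref_ids <- names(panel$nonref_loci)
  if (length(nonref_ids) > 0L && config$n_nonref_in_db > 0L) {
    in_db <- panel$nonref_loci[seq_len(config$n_nonref_in_db)]
    nr_annot <- stage("annotate", annotate_loci(in_db, anatomy))
    nr_db <- stage("pcr", build_amplicon_db(nr_annot))
    un <- results$read_id[results$status == "unassignable"]
    if (length(un) > 0L && nrow(nr_db) > 0L) {
      un_reads <- read_set$reads[read_set$reads$read_id %in% un, ]
      nonref <- stage("nonref", match_nonreference(un_reads, nr_db))
    }
  }

  variants <- NULL
  if (call_variants) {
    un <- results$read_id[results$status %in% c("unassignable", "ambiguous")]
    un <- un[!un %in% (if (!is.null(nonref))
      nonref$table$read_id[nonref$table$subset != "unmatched"] else character(0))]
    models <- c(annotated,
                if (length(nonref_ids)) annotate_loci(panel$nonref_loci,
                                                      anatomy))
    models <- lapply(models, function(l) {
      l$amp_window <- suppressWarnings(predict_amplicon(l$seq))
      l
    })
    models <- models[!vapply(models, function(l) is.null(l$amp_window),
                             logical(1))]
    vres <- list()
    for (id in un) {
      r <- read_set$reads$seq[read_set$reads$read_id == id]
      v <- stage("variants", detect_alt_splice_variant(r, models))
      if (!is.null(v)) { v$read_id <- id; vres[[id]] <- v }
    }
    variants <- if (length(vres)) do.call(rbind, unname(vres)) else NULL
  }

  counts <- stage("tabulate", tabulate_counts(results, nonref))

  n <- nrow(results)
  tally <- table(factor(results$status,
                        levels = c("assigned", "ambiguous", "unassignable",
                                   "rejected")))
  if (sum(tally) != n)
    stop("pipeline stage 'tabulate' failed: assignment partition violated",
         call. = FALSE)
  manifest <- list(
    tool = "hml2tx", version = as.character(utils::packageVersion("hml2tx")),
    seed = config$seed, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = c(n_loci = length(panel$loci),
               n_nonref = length(panel$nonref_loci),
               n_reads = n, as.vector(tally)),
    config = config[setdiff(names(config), "activity")]
  )
  names(manifest$counts)[4:7] <- names(tally)

  run <- structure(list(panel = panel, read_set = read_set,
                        annotated = annotated, db = db, results = results,
                        nonref = nonref, variants = variants,
                        counts = counts, manifest = manifest),
                   class = "hml2_run")
  if (!is.null(outdir)) run <- .serialize_run(run, outdir)
  run
}

.serialize_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(run$panel, run$read_set, outdir)
  utils::write.table(run$results, file.path(outdir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$counts),
                     file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  export_sites_gff3(run$annotated, file.path(outdir, "sites.gff3"))
  files <- list.files(outdir, full.names = TRUE)
  run$manifest$digests <- as.list(tools::md5sum(files))
  names(run$manifest$digests) <- basename(files)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  run
}

#' @export
print.hml2_run <- function(x, ...) {
  cat("<hml2_run>\n")
  cat(sprintf("  loci: %d cataloged, %d non-reference\n",
              x$manifest$counts[["n_loci"]], x$manifest$counts[["n_nonref"]]))
  cat(sprintf("  reads: %d (assigned %d, ambiguous %d, unassignable %d, rejected %d)\n",
              x$manifest$counts[["n_reads"]],
              x$manifest$counts[["assigned"]],
              x$manifest$counts[["ambiguous"]],
              x$manifest$counts[["unassignable"]],
              x$manifest$counts[["rejected"]]))
  if (!is.null(x$variants))
    cat(sprintf("  splice variants: %d call(s)\n",
                length(unique(x$variants$read_id))))
  invisible(x)
}

#' Render a count table
#'
#' Formats a [tabulate_counts()] matrix as a human-readable grid with locus
#' coordinates and names as row annotations, non-reference and
#' not-assignable rows below the reference loci, and per-tissue totals at
#' the bottom; optionally writes it as TSV.
#'
#' @param counts matrix from [tabulate_counts()].
#' @param loci optional list of [hml2_locus] supplying coordinates and HGNC
#'   names.
#' @param file optional TSV output path.
#' @return invisibly, the annotated data.frame.
#' @export
render_count_table <- function(counts, loci = NULL, file = NULL) {
  df <- as.data.frame(counts)
  ann <- data.frame(locus = rownames(counts), coordinates = "", hgnc = "",
                    stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    for (i in seq_len(nrow(ann))) {
      l <- loci[[ann$locus[i]]]
      if (!is.null(l)) {
        ann$coordinates[i] <- sprintf("%s:%d-%d", l$chrom, l$start, l$end)
        ann$hgnc[i] <- if (!is.na(l$hgnc_name)) l$hgnc_name else ""
      }
    }
  }
  out <- cbind(ann, df)
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  print(out, right = FALSE)
  invisible(out)
}
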