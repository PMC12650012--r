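# File interfaces: FASTA in, BED6+ motifs, scored TSV, report TSV, JSON
# run manifests.  All coordinates on disk are 0-based half-open (BED).

#' Read a (multi-record) FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) g4_input_error("no such file: ", path)
  # read without alphabet coercion so invalid letters surface as input
  # errors downstream instead of being silently dropped
  s <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) g4_input_error("cannot read FASTA ", path,
                                                   ": ", conditionMessage(e)))
  out <- toupper(as.character(s))
  names(out) <- sub("\\s.*$", "", names(s))  # first token of the header
  out
}

# columns written after the six BED fields, in a stable order
.BED_EXTRA <- c("n_tetrads", "loop1_len", "loop2_len", "loop3_len",
                "bulge_size", "bulge_tract", "flank5", "flank3", "perm_label",
                "loop1_seq", "loop2_seq", "loop3_seq", "total_loop_len",
                "n_bulges", "bulge_offset", "bulge_seq", "g_counts",
                "tract_starts", "tract_spans", "seq")

#' Write motifs as BED6+ with structural decomposition columns
#'
#' Standard BED6 (chrom, start, end, name, score, strand; score = tetrad
#' layers) followed by tab-separated decomposition columns: tetrad layers,
#' loop lengths, bulge size and tract, flanks, permutation label, and the
#' remaining decomposition fields, so the table round-trips through
#' [read_motif_bed()].
#'
#' @param motifs A `g4_motifs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(motifs, path) {
  n <- nrow(motifs)
  perm <- if (n) classify_permutation(motifs)$label else character(0)
  bed <- data.frame(
    chrom = motifs$chrom, start = motifs$start, end = motifs$end,
    name = if (n) sprintf("PQS_%05d%s", seq_len(n),
                          ifelse(motifs$n_bulges > 0L, "_bulged", ""))
           else character(0),
    score = motifs$n_tetrads, strand = motifs$strand,
    stringsAsFactors = FALSE)
  m2 <- motifs
  m2$perm_label <- perm
  for (col in .BED_EXTRA) bed[[col]] <- m2[[col]]
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a motif BED6+ file written by [write_motif_bed()]
#'
#' @param path BED6+ file.
#' @return A `g4_motifs` data frame.
#' @export
read_motif_bed <- function(path) {
  if (!file.exists(path)) g4_input_error("no such file: ", path)
  if (file.size(path) == 0L) return(.empty_motifs())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", na.strings = ".",
                          showProgress = FALSE,
                          colClasses = list(character = c(1L, 4L, 6L)))
  if (!nrow(dt)) return(.empty_motifs())
  if (ncol(dt) != 6L + length(.BED_EXTRA))
    g4_input_error("not a g4strat motif BED6+ file: ", path)
  names(dt) <- c("chrom", "start", "end", "name", "score", "strand",
                 .BED_EXTRA)
  df <- as.data.frame(dt)
  df <- df[c("chrom", "start", "end", "strand", "seq", "n_tetrads",
             "tract_starts", "tract_spans", "g_counts",
             "loop1_len", "loop2_len", "loop3_len",
             "loop1_seq", "loop2_seq", "loop3_seq", "total_loop_len",
             "n_bulges", "bulge_tract", "bulge_offset", "bulge_size",
             "bulge_seq")]
  df$bulge_seq <- as.character(df$bulge_seq)
  df$bulge_seq[is.na(df$bulge_seq)] <- ""
  for (col in c("start", "end", "n_tetrads", "loop1_len", "loop2_len",
                "loop3_len", "total_loop_len", "n_bulges", "bulge_tract",
                "bulge_offset", "bulge_size"))
    df[[col]] <- as.integer(df[[col]])
  df$flank5 <- as.character(as.data.frame(dt)$flank5)
  df$flank3 <- as.character(as.data.frame(dt)$flank3)
  df$flank5[is.na(df$flank5)] <- ""
  df$flank3[is.na(df$flank3)] <- ""
  class(df) <- c("g4_motifs", "data.frame")
  df
}

#' Write scored motifs to TSV
#'
#' Full motif table plus `score`, `coverage`, `n_covered`, `excluded`; the
#' track kind (and hence the score scale) is recorded on a leading comment
#' line.
#'
#' @param scored A `g4_scored_motifs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_tsv <- function(scored, path) {
  kind <- attr(scored, "kind") %||% "mm_pct"
  scale <- if (kind == "phred_quality") "ln(41.1 - x)" else "raw"
  writeLines(sprintf("# g4strat scored motifs; kind=%s; score_scale=%s",
                     kind, scale), path)
  data.table::fwrite(as.data.frame(scored), path, sep = "\t", quote = FALSE,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a scored-motif TSV written by [write_scored_tsv()]
#'
#' @param path TSV file.
#' @return A `g4_scored_motifs` data frame with its `kind` attribute.
#' @export
read_scored_tsv <- function(path) {
  if (!file.exists(path)) g4_input_error("no such file: ", path)
  first <- readLines(path, n = 1L)
  kind <- sub("^.*kind=([a-z_]+);.*$", "\\1", first)
  if (!kind %in% .SIGNAL_KINDS)
    g4_input_error("missing/unknown kind header in ", path)
  df <- as.data.frame(data.table::fread(path, skip = 1L, header = TRUE,
                                        sep = "\t", showProgress = FALSE))
  for (col in c("bulge_seq", "flank5", "flank3", "loop1_seq", "loop2_seq",
                "loop3_seq"))
    df[[col]][is.na(df[[col]])] <- ""
  attr(df, "kind") <- kind
  class(df) <- c("g4_scored_motifs", "g4_motifs", "data.frame")
  df
}

#' Write a feature report to TSV
#'
#' Group summary rows preceded by comment lines carrying the report
#' metadata (feature, track kind, resampling settings, exclusions).
#'
#' @param report A `g4_feature_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  hdr <- c(
    sprintf("# g4strat feature report; feature=%s; kind=%s", report$feature_id,
            report$kind),
    sprintf("# resample_n=%d; seed=%d; n_total=%d; excluded=%d",
            report$resample_n, report$seed, report$n_total, report$excluded))
  writeLines(hdr, path)
  data.table::fwrite(report$groups, path, sep = "\t", quote = FALSE,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Serialises the full configuration (plus any extra fields) so a run can be
#' reproduced exactly; no timestamps, so identical runs produce identical
#' manifests.
#'
#' @param path Output path.
#' @param config Configuration list.
#' @param extra Named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, extra = list()) {
  obj <- c(list(tool = "g4strat",
                version = as.character(utils::packageVersion("g4strat"))),
           list(config = unclass(config)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
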