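# Signal model: per-base stability tracks and per-motif stability scores.
#
# Two score kinds are supported.  "mm_pct" is the mismatch percentage left by
# polymerase stalling in stabilising-vs-control sequencing runs, already on a
# "higher = more stable" scale.  "phred_quality" is the per-base Phred+33
# quality (0-41) of standard resequencing reads: stable quadruplexes depress
# quality, so values are mapped through ln(41.1 - x), which flips the sign
# and stretches resolution near the 41 ceiling, putting both kinds on a
# common scale where larger numbers mean a more stable structure.

.SIGNAL_KINDS <- c("mm_pct", "phred_quality")

# tolerance absorbed at the upper quality bound (float round-trips)
.Q_TOL <- 1e-6

.kind_range <- function(kind) {
  switch(kind, mm_pct = c(0, 100), phred_quality = c(0, 41),
         g4_config_error("unknown signal kind: ", kind))
}

#' Transform a Phred quality score to the common stability scale
#'
#' Applies `ln(41.1 - x)` to quality scores `x` in `[0, 41]`.  The transform
#' is strictly decreasing, so depressed quality (a stalled polymerase over a
#' stable quadruplex) maps to a high transformed value, aligned with the
#' mismatch-percentage scale.  Its inverse is `41.1 - exp(t)`
#' ([inverse_transform_quality()]).
#'
#' @param x Numeric vector of quality scores, each in `[0, 41]` (values up to
#'   1e-6 above 41 are clamped to 41).
#' @return `log(41.1 - x)`.
#' @examples
#' transform_quality(c(0, 31, 41))  # 3.716, 2.313, -2.303
#' @export
transform_quality <- function(x) {
  bad <- which(!is.finite(x) | x < 0 | x > 41 + .Q_TOL)
  if (length(bad))
    g4_input_error("quality score out of [0, 41] at position ", bad[1L],
                   " (value ", format(x[bad[1L]]), ")")
  log(41.1 - pmin(x, 41))
}

#' Inverse of the quality transform
#'
#' @param t Transformed values.
#' @return `41.1 - exp(t)`, the quality score that produced `t`.
#' @export
inverse_transform_quality <- function(t) 41.1 - exp(t)

#' Construct a per-base signal track
#'
#' A `g4_signal_track` stores, per chromosome, a dense numeric vector indexed
#' from base 0 (position `i` in 0-based coordinates lives at R index
#' `i + 1`); `NA` marks uncovered bases.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param kind `"mm_pct"` or `"phred_quality"`.
#' @return A `g4_signal_track` object.
#' @export
signal_track <- function(values, kind = c("mm_pct", "phred_quality")) {
  kind <- match.arg(kind)
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    g4_input_error("values must be a named list of numeric vectors")
  rng <- .kind_range(kind)
  for (nm in names(values)) {
    v <- values[[nm]]
    bad <- which(!is.na(v) & (v < rng[1L] | v > rng[2L] + .Q_TOL))
    if (length(bad))
      g4_input_error(kind, " value ", format(v[bad[1L]]), " outside [",
                     rng[1L], ", ", rng[2L], "] at ", nm, ":", bad[1L] - 1L)
  }
  structure(list(kind = kind, values = values), class = "g4_signal_track")
}

#' @export
print.g4_signal_track <- function(x, ...) {
  cov <- vapply(x$values, function(v) sum(!is.na(v)), 0)
  cat(sprintf("g4_signal_track (%s): %d chromosome(s), %.0f covered bases\n",
              x$kind, length(x$values), sum(cov)))
  invisible(x)
}

#' Read a bedGraph file into a signal track
#'
#' Expects the standard 4-column bedGraph layout (chrom, 0-based start,
#' half-open end, value), expands interval values to per-base coverage, and
#' validates values against the declared score kind (`mm_pct` in `[0, 100]`,
#' `phred_quality` in `[0, 41]`).  Overlapping intervals are resolved
#' last-wins in file order, with a warning.
#'
#' @param path Path to a bedGraph file (plain text; `track`/`#` header lines
#'   are skipped).
#' @param kind Score kind of the values.
#' @return A [signal_track()] object.
#' @export
read_bedgraph <- function(path, kind = c("mm_pct", "phred_quality")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) g4_input_error("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  line_no <- which(keep)
  if (!length(line_no))
    return(signal_track(structure(list(), names = character(0)), kind))
  dt <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t",
                          fill = TRUE, colClasses = list(character = 1L),
                          showProgress = FALSE)
  if (ncol(dt) < 4L)
    g4_input_error("malformed bedGraph (need 4 columns): ", path)
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  val <- suppressWarnings(as.numeric(dt[[4L]]))
  bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0 |
                 end <= start | start != floor(start) | end != floor(end))
  if (length(bad))
    g4_input_error("malformed bedGraph line ", line_no[bad[1L]], " in ", path)
  rng <- .kind_range(kind)
  bad <- which(val < rng[1L] | val > rng[2L] + .Q_TOL)
  if (length(bad))
    g4_input_error(kind, " value ", format(val[bad[1L]]), " outside [",
                   rng[1L], ", ", rng[2L], "] at line ", line_no[bad[1L]],
                   " in ", path)
  chrom <- dt[[1L]]
  values <- list()
  overlap_warned <- FALSE
  for (nm in unique(chrom)) {
    sel <- which(chrom == nm)
    s <- as.integer(start[sel]); e <- as.integer(end[sel]); v <- val[sel]
    vec <- rep(NA_real_, max(e))
    o <- order(s)
    if (!overlap_warned && any(s[o][-1L] < cummax(e[o])[-length(o)])) {
      warning("overlapping bedGraph intervals in ", path,
              "; later lines take precedence", call. = FALSE)
      overlap_warned <- TRUE
    }
    pos <- sequence(e - s, from = s + 1L)       # file order => last wins
    vec[pos] <- rep(v, e - s)
    values[[nm]] <- vec
  }
  signal_track(values, kind)
}

#' Write a signal track (or interval table) as bedGraph
#'
#' @param x Either a `g4_signal_track` or a data frame with columns
#'   `chrom`, `start`, `end`, `value` (0-based half-open).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  if (inherits(x, "g4_signal_track")) {
    rows <- lapply(names(x$values), function(nm) {
      v <- x$values[[nm]]
      keep <- which(!is.na(v))
      if (!length(keep)) return(NULL)
      # merge consecutive equal-valued bases into intervals
      brk <- c(TRUE, diff(keep) != 1L | diff(v[keep]) != 0)
      grp <- cumsum(brk)
      first <- !duplicated(grp); last <- !duplicated(grp, fromLast = TRUE)
      data.frame(chrom = nm, start = keep[first] - 1L, end = keep[last],
                 value = v[keep[first]])
    })
    x <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  dt <- data.table::data.table(x$chrom, as.integer(x$start),
                               as.integer(x$end), sprintf("%.4f", x$value))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score motifs against a stability signal track
#'
#' Aggregates the per-base signal over each motif footprint (optionally
#' extended `window_3p` bases past the motif's 3' end, in motif-strand
#' orientation) into one stability score per motif: the mean raw value for
#' `mm_pct` tracks, or the mean of `ln(41.1 - x)`-transformed values for
#' `phred_quality` tracks.  Uncovered bases are skipped and the covered
#' fraction recorded; motifs with zero covered bases get `NA` scores and
#' `excluded = TRUE`.
#'
#' @param motifs A `g4_motifs` data frame.
#' @param track A [signal_track()] object.
#' @param window_3p Extra bases past the 3' end included in the aggregation
#'   span (default 0: motif footprint only).
#' @return A `g4_scored_motifs` data frame: the motif table plus `score`,
#'   `coverage`, `n_covered`, `excluded` and a `kind` attribute.
#' @examples
#' m <- find_canonical_pqs(c(chr = "AAAAAGGGTGGGTGGGTGGGAAAAA"))
#' tr <- signal_track(list(chr = rep(20, 25)), "mm_pct")
#' motif_stability_score(m, tr)$score  # 20
#' @export
motif_stability_score <- function(motifs, track, window_3p = 0L) {
  if (!inherits(track, "g4_signal_track"))
    g4_input_error("track must be a g4_signal_track")
  if (window_3p < 0L) g4_config_error("window_3p must be >= 0")
  n <- nrow(motifs)
  score <- rep(NA_real_, n); coverage <- numeric(n); n_cov <- integer(n)
  for (i in seq_len(n)) {
    v <- track$values[[motifs$chrom[i]]]
    if (is.null(v)) next
    if (motifs$strand[i] == "-") {
      a <- motifs$start[i] - window_3p; b <- motifs$end[i]
    } else {
      a <- motifs$start[i]; b <- motifs$end[i] + window_3p
    }
    a <- max(a, 0L); b <- min(b, length(v))
    if (b <= a) next
    vals <- v[(a + 1L):b]
    ok <- !is.na(vals)
    n_cov[i] <- sum(ok)
    coverage[i] <- n_cov[i] / (motifs$end[i] - motifs$start[i] + window_3p)
    if (n_cov[i] == 0L) next
    score[i] <- if (track$kind == "phred_quality")
      mean(transform_quality(vals[ok])) else mean(vals[ok])
  }
  out <- motifs
  out$score <- score
  out$coverage <- coverage
  out$n_covered <- n_cov
  out$excluded <- n_cov == 0L
  if (any(out$excluded))
    log_msg(sum(out$excluded), " motif(s) had no signal coverage and are excluded")
  attr(out, "kind") <- track$kind
  class(out) <- c("g4_scored_motifs", "g4_motifs", "data.frame")
  out
}
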