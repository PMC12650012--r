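# Motif grammar: detection and structural decomposition of potential
# G-quadruplex sequences (PQS).
#
# A PQS is parsed as four G-tracts separated by three loops:
#     G{k1} L1 G{k2} L2 G{k3} L3 G{k4},   ki >= min_g, |Li| in [loop_min, loop_max]
# Optionally one tract may carry a single bulge: a run of 1-8 non-G bases
# splitting the tract, with at least one guanine on each side.  The number of
# stacked tetrad layers (NT) is the minimum guanine count across the four
# tracts; for a bulged tract only the guanines are counted.

#' Default motif grammar parameters
#'
#' Canonical PQS grammar used throughout: G-tracts of at least three
#' guanines, loops of 1-7 nt, 5 nt of flanking sequence on each side, both
#' strands scanned.  These bounds cover every stratification used by the
#' stratified reports (the 1-6-1 loop configuration fits within a 7 nt
#' maximum loop).
#'
#' @param min_g Minimum guanines per G-tract (and hence minimum tetrad layers).
#' @param loop_min,loop_max Allowed loop lengths in nucleotides.
#' @param flank_width Width of the 5' and 3' flank reported with each motif.
#' @param both_strands Scan the reverse complement as well.
#' @param max_bulges Maximum number of bulged tracts per motif (0 or 1).
#' @param bulge_min,bulge_max Allowed bulge sizes in nucleotides.
#' @return A named list of grammar parameters.
#' @export
pqs_params <- function(min_g = 3L, loop_min = 1L, loop_max = 7L,
                       flank_width = 5L, both_strands = TRUE,
                       max_bulges = 0L, bulge_min = 1L, bulge_max = 8L) {
  p <- list(min_g = as.integer(min_g), loop_min = as.integer(loop_min),
            loop_max = as.integer(loop_max), flank_width = as.integer(flank_width),
            both_strands = isTRUE(both_strands), max_bulges = as.integer(max_bulges),
            bulge_min = as.integer(bulge_min), bulge_max = as.integer(bulge_max))
  if (p$min_g < 2L) g4_config_error("min_g must be >= 2")
  if (p$loop_min < 1L) g4_config_error("loop_min must be >= 1")
  if (p$loop_min > p$loop_max) g4_config_error("loop_min > loop_max")
  if (p$max_bulges < 0L || p$max_bulges > 1L)
    g4_config_error("max_bulges must be 0 or 1")
  if (p$bulge_max < p$bulge_min) g4_config_error("bulge_max < bulge_min")
  if (p$bulge_min < 1L) g4_config_error("bulge_min must be >= 1")
  if (p$flank_width < 0L) g4_config_error("flank_width must be >= 0")
  p
}

# --- low-level single-strand machinery -------------------------------------

# Candidate layout (numeric vector):
# [1] start (1-based), [2] end (1-based exclusive), [3] NT, [4] total loop,
# [5] n bulges, [6..25] four tracts as (start, span, g_count, bulge_offset,
# bulge_size), [26..28] loop lengths.
.CAND_LEN <- 28L

.seq_index <- function(ch) {
  L <- length(ch)
  isG <- ch == "G"
  # run length of G starting at each position (0 if not G)
  grun <- integer(L)
  if (L) {
    r <- rle(isG)
    glen <- r$lengths[r$values]
    if (length(glen))
      grun[isG] <- sequence(glen, from = glen, by = -1L)
  }
  # index of next G at or after i (L+1 if none)
  gpos <- which(isG)
  nextG <- if (L) {
    k <- findInterval(seq_len(L) - 1L, gpos) + 1L
    c(gpos, L + 1L)[pmin(k, length(gpos) + 1L)]
  } else integer(0)
  list(isG = isG, grun = grun, nextG = nextG,
       cumG = c(0L, cumsum(isG)), cumN = c(0L, cumsum(ch == "N")))
}

# All grammar parses starting exactly at position i.  Returns list of
# candidate vectors (possibly empty).
.pqs_candidates <- function(ch, i, par, idx) {
  L <- length(ch)
  min_g <- par$min_g; lmin <- par$loop_min; lmax <- par$loop_max
  grun <- idx$grun; nextG <- idx$nextG; cumN <- idx$cumN
  out <- vector("list", 16L); n_out <- 0L

  tract_options <- function(p, allow_bulge) {
    r <- grun[p]
    if (r == 0L) return(NULL)
    opts <- NULL
    if (r >= min_g)
      opts <- lapply(min_g:r, function(t) c(t, t, 0L, 0L))
    if (allow_bulge) {
      q <- p + r                      # first non-G after the run
      if (q <= L) {
        j <- nextG[q]
        if (j <= L) {
          b <- j - q                  # bulge size = gap to the next G
          if (b >= par$bulge_min && b <= par$bulge_max &&
              cumN[j] - cumN[q] == 0L) {
            r2 <- grun[j]
            for (k2 in seq_len(r2)) {
              gc <- r + k2
              if (gc >= min_g)
                opts <- c(opts, list(c(r + b + k2, gc, r, b)))
            }
          }
        }
      }
    }
    opts
  }

  rec <- function(p, tract_no, bulges, tracts, loops) {
    opts <- tract_options(p, bulges < par$max_bulges)
    for (o in opts) {
      span <- o[1L]; tr <- c(p, o[1L], o[2L], o[3L], o[4L])
      nb <- bulges + (o[4L] > 0L)
      if (tract_no == 4L) {
        tt <- c(tracts, tr)
        cand <- c(i, p + span, min(tt[seq(3L, 20L, by = 5L)]), sum(loops),
                  nb, tt, loops)
        n_out <<- n_out + 1L
        if (n_out > length(out)) length(out) <<- 2L * n_out
        out[[n_out]] <<- cand
      } else {
        after <- p + span
        for (l in lmin:lmax) {
          np <- after + l
          if (np > L) break
          if (cumN[np] - cumN[after] > 0L) break  # N terminates loops
          if (grun[np] == 0L) next
          rec(np, tract_no + 1L, nb, c(tracts, tr), c(loops, l))
        }
      }
    }
  }
  rec(i, 1L, 0L, integer(0), integer(0))
  if (n_out) out[seq_len(n_out)] else list()
}

# Deterministic choice among candidates at one start position:
# canonical before bulged, then more tetrad layers, then shorter total loop,
# then shorter span, then lexicographically smallest tract layout.
.select_candidate <- function(cands) {
  if (length(cands) == 1L) return(cands[[1L]])
  m <- do.call(rbind, cands)
  keys <- cbind(m[, 5L], -m[, 3L], m[, 4L], m[, 2L] - m[, 1L],
                m[, 6L:25L])
  ord <- do.call(order, as.data.frame(keys))
  cands[[ord[1L]]]
}

# Leftmost-greedy non-overlapping scan of one strand.  Returns list of
# selected candidate vectors in coordinate order.
.scan_strand <- function(ch, par) {
  L <- length(ch)
  idx <- .seq_index(ch)
  need <- 4L * par$min_g
  W <- 4L * par$min_g + 3L * par$loop_max +
    if (par$max_bulges > 0L) par$bulge_max else 0L
  gwin <- function(i) idx$cumG[min(i + W - 1L, L) + 1L] - idx$cumG[i]
  run_starts <- which(idx$isG & c(TRUE, !idx$isG[-L]))
  if (length(run_starts))
    run_starts <- run_starts[vapply(run_starts, gwin, 0L) >= need]
  res <- vector("list", 64L); n_res <- 0L
  pos <- 1L; si <- 1L; n_rs <- length(run_starts)
  while (pos <= L) {
    while (si <= n_rs && run_starts[si] < pos) si <- si + 1L
    next_rs <- if (si <= n_rs) run_starts[si] else L + 1L
    if (idx$isG[pos] && pos < next_rs && gwin(pos) >= need) {
      s <- pos
    } else {
      s <- next_rs
      if (s > L) break
    }
    cands <- .pqs_candidates(ch, s, par, idx)
    if (length(cands)) {
      best <- .select_candidate(cands)
      n_res <- n_res + 1L
      if (n_res > length(res)) length(res) <- 2L * n_res
      res[[n_res]] <- best
      pos <- best[2L]
    } else if (s == next_rs) {
      pos <- s + 1L                  # exhausted this run start
    } else {
      # no parse from this mid-run guanine => none from the rest of the run
      pos <- next_rs
    }
  }
  if (n_res) res[seq_len(n_res)] else list()
}

# Unified scan with canonical precedence at the locus level: canonical
# motifs are selected first (leftmost-greedy); bulged motifs are then
# selected only within the gaps between canonical motifs, so a locus matched
# by the canonical grammar is never reported as bulged.
.scan_unified <- function(ch, par) {
  if (par$max_bulges == 0L) return(.scan_strand(ch, par))
  par0 <- par; par0$max_bulges <- 0L
  canon <- .scan_strand(ch, par0)
  L <- length(ch)
  starts <- vapply(canon, `[`, 0, 1L)
  ends <- vapply(canon, `[`, 0, 2L)
  gap_a <- as.integer(c(1L, ends))
  gap_b <- as.integer(c(starts, L + 1L))
  res <- canon
  min_len <- 4L * par$min_g + 3L * par$loop_min
  for (k in seq_along(gap_a)) {
    a <- gap_a[k]; b <- gap_b[k]
    if (b - a < min_len) next
    for (cd in .scan_strand(ch[a:(b - 1L)], par)) {
      if (cd[5L] > 0) {                       # bulged only
        cd[c(1L, 2L, 6L, 11L, 16L, 21L)] <-
          cd[c(1L, 2L, 6L, 11L, 16L, 21L)] + (a - 1L)
        res[[length(res) + 1L]] <- cd
      }
    }
  }
  res[order(vapply(res, `[`, 0, 1L))]
}

.revcomp_chr <- function(ch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[ch]))
}

# Build the motif table rows for one chromosome strand scan.
.cands_to_rows <- function(cands, ch, chrom, strand, L, fw) {
  if (!length(cands)) return(NULL)
  rows <- lapply(cands, function(cd) {
    s <- cd[1L]; e <- cd[2L]              # 1-based, e exclusive
    tr <- matrix(cd[6L:25L], nrow = 4L, byrow = TRUE)
    loops <- cd[26L:28L]
    loop_seq <- character(3L)
    for (k in 1:3) {
      ls <- tr[k, 1L] + tr[k, 2L]
      loop_seq[k] <- paste(ch[ls:(ls + loops[k] - 1L)], collapse = "")
    }
    bi <- which(tr[, 5L] > 0L)
    if (length(bi)) {
      bt <- bi[1L]
      bs <- tr[bt, 1L] + tr[bt, 4L]
      bulge_seq <- paste(ch[bs:(bs + tr[bt, 5L] - 1L)], collapse = "")
      bulge_tract <- bt - 1L
      bulge_offset <- tr[bt, 4L]
      bulge_size <- tr[bt, 5L]
    } else {
      bulge_seq <- ""; bulge_tract <- NA_integer_
      bulge_offset <- NA_integer_; bulge_size <- NA_integer_
    }
    f5 <- if (fw > 0L && s > 1L)
      paste(ch[max(1L, s - fw):(s - 1L)], collapse = "") else ""
    f3 <- if (fw > 0L && e <= L)
      paste(ch[e:min(L, e + fw - 1L)], collapse = "") else ""
    # genomic 0-based half-open coordinates on the plus strand
    if (strand == "+") { g0 <- s - 1L; g1 <- e - 1L } else { g0 <- L - e + 1L; g1 <- L - s + 1L }
    data.frame(
      chrom = chrom, start = g0, end = g1, strand = strand,
      seq = paste(ch[s:(e - 1L)], collapse = ""),
      n_tetrads = cd[3L],
      tract_starts = paste(tr[, 1L] - s, collapse = ","),
      tract_spans = paste(tr[, 2L], collapse = ","),
      g_counts = paste(tr[, 3L], collapse = ","),
      loop1_len = loops[1L], loop2_len = loops[2L], loop3_len = loops[3L],
      loop1_seq = loop_seq[1L], loop2_seq = loop_seq[2L], loop3_seq = loop_seq[3L],
      total_loop_len = cd[4L],
      n_bulges = cd[5L],
      bulge_tract = bulge_tract, bulge_offset = bulge_offset,
      bulge_size = bulge_size, bulge_seq = bulge_seq,
      flank5 = f5, flank3 = f3,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.empty_motifs <- function() {
  df <- data.frame(
    chrom = character(), start = integer(), end = integer(), strand = character(),
    seq = character(), n_tetrads = integer(), tract_starts = character(),
    tract_spans = character(), g_counts = character(),
    loop1_len = integer(), loop2_len = integer(), loop3_len = integer(),
    loop1_seq = character(), loop2_seq = character(), loop3_seq = character(),
    total_loop_len = integer(), n_bulges = integer(), bulge_tract = integer(),
    bulge_offset = integer(), bulge_size = integer(), bulge_seq = character(),
    flank5 = character(), flank3 = character(), stringsAsFactors = FALSE)
  class(df) <- c("g4_motifs", "data.frame")
  df
}

.as_named_chr_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    s <- as.character(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    return(s)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  g4_input_error("sequences must be a named character vector or DNAStringSet")
}

#' Scan sequences for PQS motifs
#'
#' Detects non-overlapping PQS motifs per strand with a leftmost-greedy rule:
#' the scan proceeds 5' to 3'; at the first position where any grammar parse
#' starts, one motif is emitted and scanning resumes after it.  When several
#' parses start at the same base the scanner prefers, in order: no bulge over
#' a bulge, more tetrad layers, shorter total loop length, shorter span, and
#' finally the lexicographically smallest tract layout.  With the
#' bulge-tolerant grammar, canonical motifs are selected first and bulged
#' motifs are admitted only in the gaps between them, so a locus matched by
#' the canonical grammar is never reported as bulged.  Minus-strand motifs
#' are reported in plus-strand coordinates (0-based half-open, BED
#' convention) with the structural decomposition and flanks given on the
#' G-rich motif strand.
#'
#' @param x Named character vector of DNA sequences (or a
#'   [Biostrings::DNAStringSet]).  Alphabet A/C/G/T/N; motifs never span an N.
#' @param params Grammar parameters from [pqs_params()].
#' @return A `g4_motifs` data frame, one row per motif, with full structural
#'   decomposition (tract layout, guanine counts, loop lengths and sequences,
#'   bulge annotation, flanks).
#' @seealso [find_canonical_pqs()], [find_bulged_pqs()]
#' @export
find_pqs <- function(x, params = pqs_params()) {
  seqs <- .as_named_chr_seqs(x)
  out <- list()
  for (nm in names(seqs)) {
    ch <- strsplit(toupper(seqs[[nm]]), "", fixed = TRUE)[[1L]]
    bad <- !(ch %in% c("A", "C", "G", "T", "N"))
    if (any(bad))
      g4_input_error("invalid base '", ch[which(bad)[1L]], "' at position ",
                     which(bad)[1L], " of ", nm)
    L <- length(ch)
    rows_p <- .cands_to_rows(.scan_unified(ch, params), ch, nm, "+", L,
                             params$flank_width)
    rows_m <- NULL
    if (params$both_strands && L) {
      rc <- .revcomp_chr(ch)
      rows_m <- .cands_to_rows(.scan_unified(rc, params), rc, nm, "-", L,
                               params$flank_width)
    }
    out[[nm]] <- rbind(rows_p, rows_m)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(df)) return(.empty_motifs())
  df <- df[order(match(df$chrom, names(seqs)), df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("g4_motifs", "data.frame")
  df
}

#' Find canonical (bulge-free) PQS motifs
#'
#' @inheritParams find_pqs
#' @param min_g,loop_min,loop_max,flank_width,both_strands See [pqs_params()].
#' @return A `g4_motifs` data frame of canonical motifs.
#' @examples
#' find_canonical_pqs(c(chr = "GGGTGGGTGGGTGGG"))
#' @export
find_canonical_pqs <- function(x, min_g = 3L, loop_min = 1L, loop_max = 7L,
                               flank_width = 5L, both_strands = TRUE) {
  find_pqs(x, pqs_params(min_g, loop_min, loop_max, flank_width, both_strands,
                         max_bulges = 0L))
}

#' Find single-bulge PQS motifs
#'
#' Scans with a bulge-tolerant grammar (one tract may carry one bulge of
#' `bulge_min`-`bulge_max` non-guanine nucleotides) and returns only motifs
#' that actually carry a bulge.  Because canonical parses take precedence at
#' any locus, a sequence matched by the canonical grammar is never reported
#' as bulged there.
#'
#' @inheritParams find_canonical_pqs
#' @param bulge_min,bulge_max Allowed bulge sizes (nt).
#' @return A `g4_motifs` data frame of bulged motifs.
#' @examples
#' find_bulged_pqs(c(chr = "GGAGTGGGTGGGTGGG"))
#' @export
find_bulged_pqs <- function(x, min_g = 3L, loop_min = 1L, loop_max = 7L,
                            flank_width = 5L, both_strands = TRUE,
                            bulge_min = 1L, bulge_max = 8L) {
  m <- find_pqs(x, pqs_params(min_g, loop_min, loop_max, flank_width,
                              both_strands, max_bulges = 1L,
                              bulge_min = bulge_min, bulge_max = bulge_max))
  m <- m[m$n_bulges > 0L, , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("g4_motifs", "data.frame")
  m
}

# --- feature classifiers ----------------------------------------------------

.loop_matrix <- function(motifs) {
  if (is.data.frame(motifs))
    cbind(motifs$loop1_len, motifs$loop2_len, motifs$loop3_len)
  else if (is.numeric(motifs) && length(motifs) == 3L)
    matrix(motifs, nrow = 1L)
  else if (is.matrix(motifs) && ncol(motifs) == 3L)
    motifs
  else g4_input_error("expected a g4_motifs table, a length-3 numeric, or an n x 3 matrix")
}

#' Classify the loop-length permutation of a motif
#'
#' Orders the three loop lengths into the permutation classes used for
#' loop-order stratification: `all_equal`; three unequal lengths
#' (`x!=y!=z`) labelled positionally by rank as s (short), m (median),
#' l (long), e.g. `s-l-m`; or an equal pair with a distinct third, labelled
#' positionally with `x` for the pair and `z` for the odd loop
#' (`x-x-z`, `x-z-x`, `z-x-x`), with shape `x=y>z` when the pair is longer
#' and `x=y<z` when it is shorter.
#'
#' @param motifs A `g4_motifs` table, a length-3 numeric vector of loop
#'   lengths, or an n x 3 matrix.
#' @return A data frame with columns `shape` and `label`.
#' @examples
#' classify_permutation(c(1, 3, 2))   # shape x!=y!=z, label s-l-m
#' classify_permutation(c(2, 2, 1))   # shape x=y>z,  label x-x-z
#' @export
classify_permutation <- function(motifs) {
  lm <- .loop_matrix(motifs)
  if (any(lm < 1L)) g4_input_error("loop lengths must be >= 1")
  n <- nrow(lm)
  shape <- character(n); label <- character(n)
  for (i in seq_len(n)) {
    v <- lm[i, ]
    u <- unique(v)
    if (length(u) == 1L) {
      shape[i] <- "all_equal"; label[i] <- "x-x-x"
    } else if (length(u) == 3L) {
      shape[i] <- "x!=y!=z"
      label[i] <- paste(c("s", "m", "l")[rank(v)], collapse = "-")
    } else {
      pair_val <- u[match(TRUE, tabulate(match(v, u)) == 2L)]
      odd_val <- setdiff(u, pair_val)
      shape[i] <- if (pair_val > odd_val) "x=y>z" else "x=y<z"
      label[i] <- paste(ifelse(v == pair_val, "x", "z"), collapse = "-")
    }
  }
  data.frame(shape = shape, label = label, stringsAsFactors = FALSE)
}

#' Classify telomeric repeat motifs and their A-to-T loop variants
#'
#' A motif is wild-type telomeric (`WT`) when it consists of four canonical
#' tracts of exactly three guanines joined by three `TTA` loops, i.e. the
#' human telomeric repeat (GGGTTA)n.  Replacing the adenine of one or more
#' loops with thymine (`TTT`) while keeping the rest of the architecture
#' yields `A_to_T_variant`.  Everything else is `not_telomeric`.
#'
#' @param motifs A `g4_motifs` data frame.
#' @return Character vector: `"WT"`, `"A_to_T_variant"` or `"not_telomeric"`.
#' @export
classify_telomeric_variant <- function(motifs) {
  gc3 <- vapply(comma_split_int(motifs$g_counts),
                function(g) all(g == 3L), TRUE)
  loops <- cbind(motifs$loop1_seq, motifs$loop2_seq, motifs$loop3_seq)
  telo_arch <- gc3 & motifs$n_bulges == 0L &
    apply(loops, 1L, function(s) all(s %in% c("TTA", "TTT")))
  wt <- telo_arch & apply(loops, 1L, function(s) all(s == "TTA"))
  out <- rep("not_telomeric", nrow(motifs))
  out[telo_arch] <- "A_to_T_variant"
  out[wt] <- "WT"
  out
}

#' Match an IUPAC pattern against a motif flank
#'
#' Tests the flank bases immediately adjacent to the motif, on the motif
#' strand: a 5' pattern is right-anchored at the motif start (it must match
#' the last `nchar(pattern)` flank bases) and a 3' pattern is left-anchored
#' at the motif end.  IUPAC ambiguity codes are honoured (`N` = any base).
#'
#' @param motifs A `g4_motifs` data frame.
#' @param side `"5p"` or `"3p"`.
#' @param pattern IUPAC pattern string, e.g. `"NNNTT"` or `"NNTGA"`.
#' @return Logical vector, one element per motif; `FALSE` when the stored
#'   flank is shorter than the pattern.
#' @export
match_flank_motif <- function(motifs, side = c("5p", "3p"), pattern) {
  side <- match.arg(side)
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  codes <- Biostrings::IUPAC_CODE_MAP
  if (!all(pat %in% names(codes)))
    g4_config_error("pattern contains non-IUPAC characters: ", pattern)
  allowed <- strsplit(unname(codes[pat]), "", fixed = TRUE)
  np <- length(pat)
  flank <- if (side == "5p") motifs$flank5 else motifs$flank3
  vapply(flank, function(f) {
    nf <- nchar(f)
    if (nf < np) return(FALSE)
    fc <- strsplit(f, "", fixed = TRUE)[[1L]]
    fc <- if (side == "5p") fc[(nf - np + 1L):nf] else fc[seq_len(np)]
    all(mapply(function(b, ok) b %in% ok, fc, allowed))
  }, TRUE, USE.NAMES = FALSE)
}

#' Loop-length class of a motif
#'
#' Three-way stratification used when comparing tetrad layers: `all_1nt`
#' when every loop is a single nucleotide, `max_2nt` when the longest loop
#' is 2 nt, and `long` otherwise (longest loop >= 3 nt).
#'
#' @param motifs A `g4_motifs` table, length-3 numeric, or n x 3 matrix.
#' @return Character vector of classes.
#' @export
loop_class <- function(motifs) {
  lm <- .loop_matrix(motifs)
  mx <- apply(lm, 1L, max)
  ifelse(apply(lm, 1L, function(v) all(v == 1L)), "all_1nt",
         ifelse(mx == 2L, "max_2nt", "long"))
}

#' @export
print.g4_motifs <- function(x, ...) {
  cat(sprintf("g4_motifs: %d motif(s), %d bulged, strands %s\n",
              nrow(x), sum(x$n_bulges > 0L),
              paste(names(table(x$strand)), collapse = "/")))
  NextMethod()
  invisible(x)
}
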