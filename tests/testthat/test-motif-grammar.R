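# Scanner and structural decomposition.

test_that("canonical scanner decomposes textbook motifs", {
  m <- find_canonical_pqs(c(chr = "GGGTGGGTGGGTGGG"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_tetrads, 3L)
  expect_equal(c(m$loop1_len, m$loop2_len, m$loop3_len), c(1L, 1L, 1L))
  expect_equal(c(m$loop1_seq, m$loop2_seq, m$loop3_seq), c("T", "T", "T"))
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)

  telo <- find_canonical_pqs(c(chr = "GGGTTAGGGTTAGGGTTAGGG"))
  expect_equal(nrow(telo), 1L)
  expect_equal(telo$n_tetrads, 3L)
  expect_equal(c(telo$loop1_seq, telo$loop2_seq, telo$loop3_seq),
               rep("TTA", 3L))

  expect_equal(nrow(find_canonical_pqs(c(chr = "ACGTACGTACGT"))), 0L)
})

test_that("bulged scanner reports single bulges and defers to canonical parses", {
  m <- find_bulged_pqs(c(chr = "GGAGTGGGTGGGTGGG"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_tetrads, 3L)
  expect_equal(m$bulge_tract, 0L)
  expect_equal(m$bulge_size, 1L)
  expect_equal(m$bulge_seq, "A")
  expect_equal(c(m$loop1_len, m$loop2_len, m$loop3_len), c(1L, 1L, 1L))

  # canonical locus is never reported as bulged
  expect_equal(nrow(find_bulged_pqs(c(chr = "GGGTGGGTGGGTGGG"))), 0L)

  # multi-base bulge: unique grammar-consistent decomposition has the
  # non-guanine insert ACTA (4 nt) splitting the first tract
  m4 <- find_bulged_pqs(c(chr = "GGACTAGTGGGTGGGTGGG"))
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$bulge_tract, 0L)
  expect_equal(m4$bulge_seq, "ACTA")
  expect_equal(m4$bulge_size, 4L)
  ps <- oracle_parses(strsplit("GGACTAGTGGGTGGGTGGG", "")[[1]], 1L,
                      pqs_params(max_bulges = 1L))
  expect_equal(length(ps), 1L)      # brute force confirms uniqueness
  expect_equal(ps[[1]][5], 1)       # one bulge
  expect_equal(unname(ps[[1]][10]), 4)  # tract 1 bulge size
})

test_that("input and configuration errors are classed", {
  expect_error(find_canonical_pqs(c(chr = "GGGXGGG")),
               class = "g4strat_input_error")
  expect_error(pqs_params(loop_min = 5L, loop_max = 3L),
               class = "g4strat_config_error")
  expect_error(pqs_params(bulge_min = 4L, bulge_max = 2L),
               class = "g4strat_config_error")
  expect_error(pqs_params(min_g = 1L), class = "g4strat_config_error")
})

test_that("N bases terminate tracts and loops", {
  expect_equal(nrow(find_canonical_pqs(c(chr = "GGGTGGGNGGGTGGG"))), 0L)
  expect_equal(nrow(find_bulged_pqs(c(chr = "GGNGTGGGTGGGTGGG"))), 0L)
})

test_that("scanner equals brute-force oracle on random sequences", {
  set.seed(101)
  par0 <- pqs_params(max_bulges = 0L)
  par1 <- pqs_params(max_bulges = 1L)
  for (i in 1:25) {
    s <- random_dna(400, probs = c(0.2, 0.2, 0.35, 0.25))  # G-rich
    expect_scan_matches_oracle(s, par0)
    expect_scan_matches_oracle(s, par1)
  }
})

test_that("re-scanning a motif's own sequence reproduces its decomposition", {
  set.seed(202)
  par <- pqs_params(max_bulges = 1L, both_strands = FALSE, flank_width = 0L)
  found <- 0L
  for (i in 1:40) {
    s <- random_dna(600, probs = c(0.2, 0.2, 0.35, 0.25))
    m <- find_pqs(c(chr = s), par)
    for (j in seq_len(nrow(m))) {
      m2 <- find_pqs(c(chr = m$seq[j]), par)
      expect_equal(nrow(m2), 1L)
      cols <- c("seq", "n_tetrads", "tract_starts", "tract_spans", "g_counts",
                "loop1_len", "loop2_len", "loop3_len", "bulge_size",
                "bulge_tract", "n_bulges")
      expect_equal(m2[1, cols], m[j, cols], ignore_attr = TRUE)
      found <- found + 1L
    }
  }
  expect_gt(found, 10L)
})

test_that("scanning the reverse complement flips strands and mirrors coordinates", {
  set.seed(303)
  par <- pqs_params(max_bulges = 1L)
  for (i in 1:15) {
    s <- random_dna(500, probs = c(0.2, 0.25, 0.3, 0.25))
    L <- nchar(s)
    a <- find_pqs(c(chr = s), par)
    b <- find_pqs(c(chr = revcomp(s)), par)
    b2 <- b
    b2$start <- L - b$end
    b2$end <- L - b$start
    b2$strand <- as.character(ifelse(b$strand == "+", "-", "+"))
    b2 <- b2[order(b2$start, b2$strand), ]
    rownames(b2) <- rownames(a) <- NULL
    cols <- c("start", "end", "strand", "seq", "n_tetrads", "g_counts",
              "loop1_seq", "loop2_seq", "loop3_seq", "bulge_size", "flank5",
              "flank3")
    expect_equal(a[order(a$start, a$strand), cols], b2[, cols],
                 ignore_attr = TRUE)
  }
})

test_that("tetrad count and loop totals are conserved", {
  set.seed(404)
  par <- pqs_params(max_bulges = 1L)
  s <- paste(replicate(10, random_dna(500, probs = c(0.2, 0.2, 0.35, 0.25))),
             collapse = "")
  m <- find_pqs(c(chr = s), par)
  expect_gt(nrow(m), 0L)
  gc <- lapply(strsplit(m$g_counts, ","), as.integer)
  expect_equal(m$n_tetrads, vapply(gc, min, 0L))
  expect_equal(m$total_loop_len, m$loop1_len + m$loop2_len + m$loop3_len)
  expect_true(all(vapply(gc, min, 0L) >= 3L))
  # per-strand non-overlap
  for (str in c("+", "-")) {
    ms <- m[m$strand == str, ]
    if (nrow(ms) > 1L) expect_true(all(ms$start[-1L] >= ms$end[-nrow(ms)]))
  }
})

# --- classifiers -----------------------------------------------------------

test_that("loop permutation classes follow rank order", {
  expect_equal(classify_permutation(c(1, 3, 2)),
               data.frame(shape = "x!=y!=z", label = "s-l-m"))
  expect_equal(classify_permutation(c(2, 2, 1)),
               data.frame(shape = "x=y>z", label = "x-x-z"))
  expect_equal(classify_permutation(c(1, 1, 1)),
               data.frame(shape = "all_equal", label = "x-x-x"))
  expect_equal(classify_permutation(c(1, 2, 2)),
               data.frame(shape = "x=y>z", label = "z-x-x"))
  expect_equal(classify_permutation(c(5, 5, 7)),
               data.frame(shape = "x=y<z", label = "x-x-z"))
  expect_equal(classify_permutation(c(3, 1, 2))$label, "l-s-m")
  # label consistent with sorted lengths for all small cases
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    pc <- classify_permutation(c(a, b, c))
    lets <- strsplit(pc$label, "-", fixed = TRUE)[[1]]
    if (pc$shape == "x!=y!=z")
      expect_equal(order(c(a, b, c)), order(match(lets, c("s", "m", "l"))))
  }
})

test_that("telomeric variants are recognised", {
  wt <- find_canonical_pqs(c(chr = "GGGTTAGGGTTAGGGTTAGGG"))
  expect_equal(classify_telomeric_variant(wt), "WT")
  var <- find_canonical_pqs(c(chr = "GGGTTTGGGTTAGGGTTAGGG"))
  expect_equal(classify_telomeric_variant(var), "A_to_T_variant")
  t1 <- find_canonical_pqs(c(chr = "GGGTGGGTGGGTGGG"))
  expect_equal(classify_telomeric_variant(t1), "not_telomeric")
  # four-tetrad tracts with TTA loops are not the telomeric architecture
  g4 <- find_canonical_pqs(c(chr = "GGGGTTAGGGGTTAGGGGTTAGGGG"))
  expect_equal(classify_telomeric_variant(g4), "not_telomeric")
})

test_that("flank patterns match with IUPAC codes and anchoring", {
  m <- find_canonical_pqs(c(chr = "ACGTTGGGTGGGTGGGTGGGCATGA"))
  expect_equal(m$flank5, "ACGTT")
  expect_true(match_flank_motif(m, "5p", "NNNTT"))
  expect_false(match_flank_motif(m, "5p", "NNTGA"))
  m2 <- find_canonical_pqs(c(chr = "CATGAGGGTGGGTGGGTGGGTTAAA"))
  expect_true(match_flank_motif(m2, "5p", "NNTGA"))
  expect_false(match_flank_motif(m2, "5p", "NNNTT"))
  expect_true(match_flank_motif(m2, "3p", "TTNNN"))
  expect_false(match_flank_motif(m2, "3p", "GAANN"))
  # anchoring: 5' pattern tests the bases immediately before the motif
  expect_true(match_flank_motif(m2, "5p", "TGA"))
  expect_false(match_flank_motif(m2, "5p", "CAT"))
  expect_error(match_flank_motif(m2, "5p", "NNX"),
               class = "g4strat_config_error")
})

test_that("loop length classes are assigned by the longest loop", {
  expect_equal(loop_class(c(1, 1, 1)), "all_1nt")
  expect_equal(loop_class(c(2, 1, 2)), "max_2nt")
  expect_equal(loop_class(c(1, 6, 1)), "long")
  expect_equal(loop_class(c(1, 1, 3)), "long")
})
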