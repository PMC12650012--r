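# Grouping rules, resampling, rank-sum tests, report assembly.

# small scored table built directly (scores chosen by hand)
make_scored <- function(seqs, scores, kind = "mm_pct") {
  stopifnot(length(seqs) == length(scores))
  rows <- lapply(seq_along(seqs), function(i) {
    m <- find_pqs(c(chr = seqs[[i]]), pqs_params(max_bulges = 1L))
    m <- m[m$strand == "+", , drop = FALSE][1, , drop = FALSE]
    m
  })
  df <- do.call(rbind, rows)
  df$score <- scores
  df$coverage <- 1; df$n_covered <- df$end - df$start
  df$excluded <- FALSE
  attr(df, "kind") <- kind
  class(df) <- c("g4_scored_motifs", "g4_motifs", "data.frame")
  df
}

test_that("telomeric grouping keeps WT and variant, excludes the rest", {
  sc <- make_scored(
    c("GGGTTAGGGTTAGGGTTAGGG",   # WT
      "GGGTTTGGGTTAGGGTTAGGG",   # A-to-T variant
      "GGGTGGGTGGGTGGG"),        # canonical 1-nt
    c(5, 4, 9))
  g <- group_motifs(sc, "telomeric_AtoT")
  expect_equal(names(g), c("WT", "A_to_T"))
  expect_equal(g$WT, 5)
  expect_equal(g$A_to_T, 4)
  expect_equal(attr(g, "excluded"), 1L)
})

test_that("bulge grouping separates presence and size; canonical-only input gives empty size groups", {
  sc <- make_scored(
    c("GGGTGGGTGGGTGGG", "GGAGTGGGTGGGTGGG", "GGACTGTGGGTGGGTGGG"),
    c(10, 8, 7))
  g <- group_motifs(sc, "bulge_presence")
  expect_equal(g$no_bulge, 10)
  expect_equal(sort(g$bulge), c(7, 8))
  gs <- group_motifs(sc, "bulge_size")
  expect_equal(names(gs), as.character(1:8))
  expect_equal(gs[["1"]], 8)
  expect_equal(gs[["3"]], 7)   # bulge "ACT" splits the first tract
  expect_equal(sum(lengths(gs[c(2, 4:8)])), 0L)
  # canonical-only input: eight empty size groups
  sc2 <- make_scored("GGGTGGGTGGGTGGG", 10)
  gs2 <- group_motifs(sc2, "bulge_size")
  expect_equal(lengths(gs2), setNames(rep(0L, 8), as.character(1:8)))
})

test_that("loop composition labels pair the first and third 1-nt loops", {
  sc <- make_scored(c("GGGAGGGCCAGGGTGGG",    # loops A, CCA, T -> A-T
                      "GGGCGGGATTGGGCGGG"),   # loops C, ATT, C -> C-C
                    c(3, 4))
  g <- group_motifs(sc, "loop_composition_131")
  expect_equal(g[["A-T"]], 3)
  expect_equal(g[["C-C"]], 4)
  expect_equal(length(g), 9L)
  expect_equal(attr(g, "excluded"), 0L)
})

test_that("unknown feature ids fail with the valid list", {
  sc <- make_scored("GGGTGGGTGGGTGGG", 1)
  expect_error(group_motifs(sc, "nope"), "layers_by_loopclass",
               class = "g4strat_config_error")
})

test_that("resampled means are reproducible and collapse for constant input", {
  expect_equal(resampled_mean(c(5, 5, 5), seed = 1),
               list(mean = 5, sd = 0))
  a <- resampled_mean(rnorm(50), resample_n = 200, seed = 42)
  b <- resampled_mean(rnorm(50), resample_n = 200, seed = 42)
  # same seed, same data => identical; with_seed isolates the RNG
  set.seed(99); x <- rnorm(50)
  r1 <- resampled_mean(x, resample_n = 500, seed = 7)
  r2 <- resampled_mean(x, resample_n = 500, seed = 7)
  expect_identical(r1, r2)
  expect_equal(resampled_mean(numeric(0)), list(mean = NA_real_, sd = NA_real_))
})

test_that("resampled mean converges to the plain mean and tracks the population", {
  set.seed(11)
  x <- rnorm(10000)
  r <- resampled_mean(x, resample_n = 100000, seed = 3)
  se <- sd(x) / sqrt(100000)
  expect_lt(abs(r$mean - mean(x)), 3 * se + 1e-12)
  expect_lt(abs(r$mean - 0), 0.1)
})

test_that("exact rank-sum p equals full enumeration on small samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$mode, "exact")
  set.seed(21)
  for (it in 1:30) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    pool <- sample(1000, m + n)           # tie-free
    a <- pool[1:m]; b <- pool[(m + 1):(m + n)]
    r <- wilcoxon_rank_sum(a, b)
    e <- wilcox_enum(a, b)
    expect_equal(r$mode, "exact")
    expect_equal(r$statistic, e$statistic)
    expect_equal(r$p_value, e$p_value, tolerance = 1e-12)
  }
})

test_that("approximate rank-sum p stays close to exact at moderate size", {
  set.seed(31)
  for (it in 1:10) {
    pool <- sample(10000, 12)
    a <- pool[1:6]; b <- pool[7:12]
    pe <- wilcox_enum(a, b)$p_value
    pa <- wilcoxon_rank_sum(a, b, mode = "approx")$p_value
    expect_lt(abs(pa - pe), 0.02)
  }
})

test_that("degenerate and identical comparisons behave by convention", {
  r <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5))
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, 10)
  x <- c(1, 3, 7, 9)
  expect_gt(wilcoxon_rank_sum(x, x)$p_value, 0.99)
})

test_that("feature reports assemble group summaries and comparisons", {
  set.seed(5)
  seqs <- c(rep("GGGTTAGGGTTAGGGTTAGGG", 30), rep("GGGTTTGGGTTAGGGTTAGGG", 30))
  sc <- make_scored(seqs, c(rnorm(30, 10, 1), rnorm(30, 6, 1)))
  rep1 <- run_feature_report(sc, "telomeric_AtoT", resample_n = 500, seed = 9)
  g <- rep1$groups
  expect_equal(g$label, c("WT", "A_to_T"))
  expect_equal(g$n, c(30L, 30L))
  expect_gt(g$mean[1], g$mean[2])
  expect_equal(g$ref[2], "WT")
  expect_lt(g$p_value[2], 0.001)
  expect_equal(g$signif[2], "***")
  expect_true(is.na(g$p_value[1]))
  # determinism
  rep2 <- run_feature_report(sc, "telomeric_AtoT", resample_n = 500, seed = 9)
  expect_identical(rep1$groups, rep2$groups)
})

test_that("group assignment is order-invariant and partitions the input", {
  set.seed(6)
  seqs <- c(rep("GGGTGGGTGGGTGGG", 10), rep("GGAGTGGGTGGGTGGG", 10),
            rep("GGGTTAGGGTTAGGGTTAGGG", 5))
  sc <- make_scored(seqs, rnorm(25))
  for (f in c("bulge_presence", "total_loop_length", "layers_by_loopclass")) {
    g1 <- group_motifs(sc, f)
    perm <- sample(nrow(sc))
    sc2 <- sc[perm, ]
    attr(sc2, "kind") <- "mm_pct"
    class(sc2) <- class(sc)
    g2 <- group_motifs(sc2, f)
    expect_equal(lapply(g1, sort), lapply(g2, sort))
    expect_equal(sum(lengths(g1)) + attr(g1, "excluded"), nrow(sc))
  }
})
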