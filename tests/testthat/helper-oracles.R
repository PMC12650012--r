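# Independent brute-force oracles used to validate the scanner and the
# rank-sum test, plus small fixture helpers.  Deliberately written as plain
# nested loops over every start position, independent of the package's
# scanning machinery.

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# All grammar parses starting at position i (1-based).  Each parse is a
# numeric vector: start, end(exclusive), NT, total_loop, n_bulges,
# 4 x (tract_start, span, g_count, bulge_offset, bulge_size), 3 loop lens.
oracle_parses <- function(ch, i, par) {
  L <- length(ch)
  g_run_from <- function(p) {
    k <- 0L
    while (p + k <= L && ch[p + k] == "G") k <- k + 1L
    k
  }
  tract_opts <- function(p, allow_bulge) {
    opts <- list()
    k <- g_run_from(p)
    if (k == 0L) return(opts)
    if (k >= par$min_g)
      for (t in par$min_g:k)
        opts[[length(opts) + 1L]] <- c(t, t, 0L, 0L)
    if (allow_bulge) {
      q <- p + k
      for (b in par$bulge_min:par$bulge_max) {
        if (q + b > L) break
        if (!all(ch[q:(q + b - 1L)] %in% c("A", "C", "T"))) next
        if (ch[q + b] != "G") next
        k2m <- g_run_from(q + b)
        for (k2 in 1:k2m)
          if (k + k2 >= par$min_g)
            opts[[length(opts) + 1L]] <- c(k + b + k2, k + k2, k, b)
      }
    }
    opts
  }
  parses <- list()
  for (o1 in tract_opts(i, par$max_bulges >= 1L)) {
    p2s <- i + o1[1]
    for (l1 in par$loop_min:par$loop_max) {
      lp1 <- p2s + l1
      if (lp1 > L || any(ch[p2s:(lp1 - 1L)] == "N")) next
      for (o2 in tract_opts(lp1, par$max_bulges >= 1L && o1[4] == 0L)) {
        p3s <- lp1 + o2[1]
        for (l2 in par$loop_min:par$loop_max) {
          lp2 <- p3s + l2
          if (lp2 > L || any(ch[p3s:(lp2 - 1L)] == "N")) next
          used2 <- o1[4] > 0L || o2[4] > 0L
          for (o3 in tract_opts(lp2, par$max_bulges >= 1L && !used2)) {
            p4s <- lp2 + o3[1]
            for (l3 in par$loop_min:par$loop_max) {
              lp3 <- p4s + l3
              if (lp3 > L || any(ch[p4s:(lp3 - 1L)] == "N")) next
              used3 <- used2 || o3[4] > 0L
              for (o4 in tract_opts(lp3, par$max_bulges >= 1L && !used3)) {
                tr <- c(i, o1, lp1, o2, lp2, o3, lp3, o4)
                nb <- sum(c(o1[4], o2[4], o3[4], o4[4]) > 0L)
                parses[[length(parses) + 1L]] <- c(
                  i, lp3 + o4[1], min(o1[2], o2[2], o3[2], o4[2]),
                  l1 + l2 + l3, nb, tr, l1, l2, l3)
              }
            }
          }
        }
      }
    }
  }
  parses
}

# Leftmost-greedy selection over brute-force parses from every G position.
oracle_greedy <- function(ch, par) {
  L <- length(ch)
  sel <- list()
  pos <- 1L
  while (pos <= L) {
    gpos <- which(ch == "G")
    gpos <- gpos[gpos >= pos]
    found <- NULL
    for (s in gpos) {
      ps <- oracle_parses(ch, s, par)
      if (length(ps)) { found <- ps; break }
    }
    if (is.null(found)) break
    m <- do.call(rbind, found)
    key <- data.frame(nb = m[, 5], nt = -m[, 3], lt = m[, 4],
                      span = m[, 2] - m[, 1])
    key <- cbind(key, m[, 6:25, drop = FALSE])
    best <- m[do.call(order, key)[1], ]
    sel[[length(sel) + 1L]] <- best
    pos <- best[2]
  }
  sel
}

# Two-pass rule: canonical motifs first; bulged motifs only between them.
oracle_scan <- function(seq, par) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (par$max_bulges == 0L) return(oracle_greedy(ch, par))
  par0 <- par; par0$max_bulges <- 0L
  canon <- oracle_greedy(ch, par0)
  L <- length(ch)
  gaps_a <- c(1, vapply(canon, `[`, 0, 2))
  gaps_b <- c(vapply(canon, `[`, 0, 1), L + 1)
  out <- canon
  for (k in seq_along(gaps_a)) {
    a <- gaps_a[k]; b <- gaps_b[k]
    if (b - a < 12) next
    for (p in oracle_greedy(ch[a:(b - 1)], par)) {
      if (p[5] > 0) {
        p[c(1, 2, 6, 11, 16, 21)] <- p[c(1, 2, 6, 11, 16, 21)] + (a - 1)
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out[order(vapply(out, `[`, 0, 1))]
}

# Comparable signature of one motif row / oracle parse.
motif_sig <- function(start1, end1, tract_starts, tract_spans, g_counts,
                      loops, nb) {
  paste(start1, end1, tract_starts, tract_spans, g_counts,
        paste(loops, collapse = ","), nb, sep = "|")
}

sig_from_oracle <- function(p) {
  tr <- matrix(p[6:25], nrow = 4, byrow = TRUE)
  motif_sig(p[1], p[2],
            paste(tr[, 1] - p[1], collapse = ","),
            paste(tr[, 2], collapse = ","),
            paste(tr[, 3], collapse = ","),
            p[26:28], p[5])
}

sig_from_row <- function(m) {
  vapply(seq_len(nrow(m)), function(i) {
    motif_sig(m$start[i] + 1, m$end[i] + 1, m$tract_starts[i],
              m$tract_spans[i], m$g_counts[i],
              c(m$loop1_len[i], m$loop2_len[i], m$loop3_len[i]),
              m$n_bulges[i])
  }, "")
}

# Compare scanner output with the oracle on one sequence (both strands).
expect_scan_matches_oracle <- function(seq, par) {
  m <- find_pqs(c(chr = seq), par)
  L <- nchar(seq)
  plus <- m[m$strand == "+", , drop = FALSE]
  expect_identical(sig_from_row(plus),
                   vapply(oracle_scan(seq, par), sig_from_oracle, ""))
  if (par$both_strands) {
    minus <- m[m$strand == "-", , drop = FALSE]
    # map to motif-strand coordinates on the reverse complement
    if (nrow(minus)) {
      minus$start2 <- L - minus$end
      minus$end2 <- L - minus$start
      minus <- minus[order(minus$start2), , drop = FALSE]
      minus$start <- minus$start2; minus$end <- minus$end2
    }
    expect_identical(sig_from_row(minus),
                     vapply(oracle_scan(revcomp(seq), par), sig_from_oracle, ""))
  }
}

# Exact two-sided rank-sum p by full enumeration of group labelings.
wilcox_enum <- function(a, b) {
  pool <- c(a, b)
  m <- length(a); n <- length(b)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(utils::combn(m + n, m), 2, u_of)
  u_obs <- u_of(seq_len(m))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(statistic = u_obs, p_value = min(1, p))
}
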