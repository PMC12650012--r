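# Feature-stratified statistics: group scored motifs by a structural
# feature, summarise each group by the mean and SD of a bootstrap resample,
# and compare groups with the Wilcoxon rank-sum test following the
# comparison scheme conventional for that feature.

.FEATURE_IDS <- c("layers_by_loopclass", "bulge_presence", "bulge_size",
                  "total_loop_length", "permutation", "telomeric_AtoT",
                  "loop_composition_131", "loop_composition_161",
                  "flank5", "flank3")

#' Feature identifiers understood by the stratified reports
#' @return Character vector of valid `feature_id` values.
#' @export
feature_ids <- function() .FEATURE_IDS

.default_strat_config <- function(config = list()) {
  defaults <- list(loop_min = 1L, loop_max = 7L,
                   flank5_patterns = c("NNNTT", "NNTGA"),
                   flank3_patterns = c("GAANN", "TTNNN"))
  utils::modifyList(defaults, config)
}

#' Group scored motifs by a structural feature
#'
#' Applies the grouping rule of the requested feature and returns the score
#' vectors per group label.  Motifs that do not fall in any of the feature's
#' categories (and motifs excluded for missing signal) are dropped and
#' counted in the `excluded` attribute.  Several features are restricted to
#' the homogeneous motif families in which the corresponding trend is
#' defined: tetrad-layer comparisons use canonical motifs whose three loops
#' share one length (the d(GnT)4-style series); bulge and flank features use
#' three-layer motifs with all loops 1 nt; loop-length, permutation and
#' composition features use canonical three-layer motifs.
#'
#' @param scored A `g4_scored_motifs` data frame from
#'   [motif_stability_score()].
#' @param feature_id One of [feature_ids()].
#' @param config Optional list overriding `loop_min`, `loop_max`,
#'   `flank5_patterns`, `flank3_patterns`.
#' @return Named list of numeric score vectors (possibly empty per label),
#'   in the feature's display order, with attributes `excluded` (count) and
#'   `n_total`.
#' @export
group_motifs <- function(scored, feature_id, config = list()) {
  if (!feature_id %in% .FEATURE_IDS)
    g4_config_error("unknown feature_id '", feature_id, "'; valid: ",
                    paste(.FEATURE_IDS, collapse = ", "))
  cfg <- .default_strat_config(config)
  m <- scored
  if (!is.null(m$excluded)) m <- m[!m$excluded & !is.na(m$score), , drop = FALSE]
  n_total <- nrow(scored)
  canon <- m$n_bulges == 0L
  all1 <- m$loop1_len == 1L & m$loop2_len == 1L & m$loop3_len == 1L
  nt3 <- m$n_tetrads == 3L

  assign_groups <- function(sel, lab, labels) {
    groups <- lapply(labels, function(l) m$score[sel][lab[sel] == l])
    names(groups) <- labels
    groups
  }

  groups <- switch(feature_id,
    layers_by_loopclass = {
      uniform <- m$loop1_len == m$loop2_len & m$loop2_len == m$loop3_len
      sel <- canon & uniform
      cls <- ifelse(m$loop1_len == 1L, "1nt",
                    ifelse(m$loop1_len == 2L, "2nt", "long"))
      nts <- sort(unique(m$n_tetrads[sel]))
      labels <- unlist(lapply(c("1nt", "2nt", "long"), function(c)
        paste0("NT", nts, "|", c)))
      lab <- paste0("NT", m$n_tetrads, "|", cls)
      assign_groups(sel, lab, labels)
    },
    bulge_presence = {
      sel <- nt3 & all1
      lab <- ifelse(m$n_bulges == 0L, "no_bulge", "bulge")
      assign_groups(sel, lab, c("no_bulge", "bulge"))
    },
    bulge_size = {
      sel <- nt3 & all1 & m$n_bulges == 1L
      lab <- as.character(m$bulge_size)
      assign_groups(sel, lab, as.character(1:8))
    },
    total_loop_length = {
      sel <- canon & nt3
      lab <- as.character(m$total_loop_len)
      assign_groups(sel, lab,
                    as.character((3L * cfg$loop_min):(3L * cfg$loop_max)))
    },
    permutation = {
      pc <- classify_permutation(m)
      sel <- canon & nt3 & pc$shape != "all_equal"
      lab <- ifelse(pc$shape == "x!=y!=z", pc$label,
                    paste0(pc$shape, "|", pc$label))
      labels <- c("s-m-l", "s-l-m", "m-s-l", "m-l-s", "l-s-m", "l-m-s",
                  paste0("x=y>z|", c("x-x-z", "x-z-x", "z-x-x")),
                  paste0("x=y<z|", c("x-x-z", "x-z-x", "z-x-x")))
      assign_groups(sel, lab, labels)
    },
    telomeric_AtoT = {
      tv <- classify_telomeric_variant(m)
      sel <- tv != "not_telomeric"
      lab <- ifelse(tv == "WT", "WT", "A_to_T")
      assign_groups(sel, lab, c("WT", "A_to_T"))
    },
    loop_composition_131 = ,
    loop_composition_161 = {
      mid <- if (feature_id == "loop_composition_131") 3L else 6L
      sel <- canon & nt3 & m$loop1_len == 1L & m$loop2_len == mid &
        m$loop3_len == 1L & m$loop1_seq %in% c("A", "C", "T") &
        m$loop3_seq %in% c("A", "C", "T")
      lab <- paste0(m$loop1_seq, "-", m$loop3_seq)
      labels <- as.vector(t(outer(c("A", "C", "T"), c("A", "C", "T"), paste,
                                  sep = "-")))
      assign_groups(sel, lab, labels)
    },
    flank5 = ,
    flank3 = {
      side <- if (feature_id == "flank5") "5p" else "3p"
      pats <- if (side == "5p") cfg$flank5_patterns else cfg$flank3_patterns
      hits <- vapply(pats, function(p) match_flank_motif(m, side, p),
                     logical(nrow(m)))
      if (nrow(m) == 1L) hits <- matrix(hits, nrow = 1L)
      if (nrow(m) == 0L) hits <- matrix(logical(0), 0L, length(pats))
      sel <- nt3 & all1 & canon & rowSums(hits) == 1L
      lab <- pats[apply(hits, 1L, function(h) which(h)[1L] %||% NA_integer_)]
      lab[rowSums(hits) != 1L] <- NA
      assign_groups(sel & !is.na(lab), lab, pats)
    }
  )
  grouped <- sum(lengths(groups))
  attr(groups, "excluded") <- n_total - grouped
  attr(groups, "n_total") <- n_total
  groups
}

#' Bootstrap-resampled group mean and standard deviation
#'
#' Draws `resample_n` scores with replacement from the group and returns the
#' mean and standard deviation of the resampled set.  Reproducible for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param scores Numeric vector of group scores.
#' @param resample_n Number of resampled values (default 1000).
#' @param seed Integer seed.
#' @return List with `mean` and `sd` (both `NA` for an empty group).
#' @export
resampled_mean <- function(scores, resample_n = 1000L, seed = 1L) {
  if (!length(scores)) return(list(mean = NA_real_, sd = NA_real_))
  r <- with_seed(seed, sample(scores, resample_n, replace = TRUE))
  list(mean = mean(r), sd = stats::sd(r))
}

#' Wilcoxon rank-sum test between two score groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test.  In `auto` mode the exact
#' null distribution is used when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used.  When every value in both groups is
#' identical the test is degenerate and `p = 1` is returned by convention.
#'
#' @param a,b Numeric score vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `statistic` (Mann-Whitney U of `a`), `p_value`, and the
#'   `mode` actually used.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) g4_input_error("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    log_msg("degenerate Wilcoxon comparison (all values identical); p = 1")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                mode = "degenerate"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(mode,
    auto = (length(a) + length(b)) <= 12L && !ties,
    exact = TRUE,
    approx = FALSE)
  if (use_exact && ties)
    g4_config_error("exact mode requires tie-free data")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic),
       p_value = min(1, wt$p.value),
       mode = if (use_exact) "exact" else "approx")
}

#' Significance symbol for a p-value
#'
#' Conventional thresholds: `***` below 0.001, `**` below 0.01, `*` below
#' 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of symbols.
#' @export
significance_symbol <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

# Comparison scheme per feature: returns data.frame(label, ref) pairs.
.comparison_pairs <- function(feature_id, labels, means) {
  nonempty <- labels[!is.na(means)]
  pairs <- switch(feature_id,
    layers_by_loopclass = {
      cls <- sub("^NT[0-9]+\\|", "", nonempty)
      do.call(rbind, lapply(split(nonempty, cls), function(g) {
        g <- g[order(as.integer(sub("^NT([0-9]+)\\|.*$", "\\1", g)))]
        if (length(g) < 2L) return(NULL)
        data.frame(label = g[-1L], ref = g[1L])
      }))
    },
    bulge_presence = if (all(c("no_bulge", "bulge") %in% nonempty))
      data.frame(label = "bulge", ref = "no_bulge") else NULL,
    bulge_size = if ("1" %in% nonempty && length(nonempty) > 1L)
      data.frame(label = setdiff(nonempty, "1"), ref = "1") else NULL,
    total_loop_length = if (length(nonempty) > 1L)
      data.frame(label = nonempty[-1L], ref = nonempty[-length(nonempty)])
      else NULL,
    permutation = {
      panel <- ifelse(grepl("^x=y", nonempty),
                      sub("\\|.*$", "", nonempty), "x!=y!=z")
      do.call(rbind, lapply(split(nonempty, panel), function(g) {
        if (length(g) < 2L) return(NULL)
        best <- g[which.max(means[match(g, labels)])]
        data.frame(label = setdiff(g, best), ref = best)
      }))
    },
    telomeric_AtoT = if (all(c("WT", "A_to_T") %in% nonempty))
      data.frame(label = "A_to_T", ref = "WT") else NULL,
    loop_composition_131 = ,
    loop_composition_161 = if ("A-A" %in% nonempty && length(nonempty) > 1L)
      data.frame(label = setdiff(nonempty, "A-A"), ref = "A-A") else NULL,
    flank5 = ,
    flank3 = if (length(nonempty) == 2L)
      data.frame(label = nonempty[2L], ref = nonempty[1L]) else NULL
  )
  if (is.null(pairs)) pairs <- data.frame(label = character(), ref = character())
  rownames(pairs) <- NULL
  pairs
}

#' Run one feature-stratified report
#'
#' Groups scored motifs by `feature_id`, summarises each group by the mean
#' and SD of `resample_n` bootstrap-resampled scores, and runs the Wilcoxon
#' rank-sum comparisons conventional for the feature: bulge sizes against
#' size 1, adjacent total-loop-length groups, permutation groups against the
#' highest-mean group of their shape panel, composition cells against the
#' A-A reference, A-to-T telomeric variants against wild type, the two flank
#' groups against each other, and tetrad layers against the lowest layer
#' count within each loop-length class.  Raw (unadjusted) p-values drive the
#' significance symbols; Benjamini-Hochberg adjusted values are reported
#' alongside for transparency.
#'
#' @inheritParams group_motifs
#' @param resample_n Bootstrap resample size per group.
#' @param seed Integer seed; group `i` uses `seed + i` so reports are
#'   reproducible end to end.
#' @return A `g4_feature_report`: list with `feature_id`, `kind`, `groups`
#'   (summary data frame), `excluded`, `n_total`, `resample_n`, `seed`.
#' @export
run_feature_report <- function(scored, feature_id, config = list(),
                               resample_n = 1000L, seed = 1L) {
  groups <- group_motifs(scored, feature_id, config)
  labels <- names(groups)
  rs <- lapply(seq_along(groups), function(i)
    resampled_mean(groups[[i]], resample_n, seed + i))
  means <- vapply(rs, `[[`, 0, "mean")
  sds <- vapply(rs, `[[`, 0, "sd")
  pairs <- .comparison_pairs(feature_id, labels, means)
  stat <- pv <- rep(NA_real_, length(labels))
  ref <- rep(NA_character_, length(labels))
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$label[k], labels); j <- match(pairs$ref[k], labels)
    wt <- wilcoxon_rank_sum(groups[[i]], groups[[j]])
    stat[i] <- wt$statistic; pv[i] <- wt$p_value; ref[i] <- pairs$ref[k]
  }
  padj <- rep(NA_real_, length(labels))
  has_p <- !is.na(pv)
  padj[has_p] <- stats::p.adjust(pv[has_p], method = "BH")
  out <- list(
    feature_id = feature_id,
    kind = attr(scored, "kind") %||% NA_character_,
    groups = data.frame(
      label = labels, n = unname(lengths(groups)),
      resample_n = resample_n, mean = means, sd = sds, ref = ref,
      statistic = stat, p_value = pv, p_adj_BH = padj,
      signif = significance_symbol(pv), stringsAsFactors = FALSE),
    excluded = attr(groups, "excluded"),
    n_total = attr(groups, "n_total"),
    resample_n = resample_n, seed = seed)
  class(out) <- "g4_feature_report"
  out
}

#' @export
print.g4_feature_report <- function(x, ...) {
  cat(sprintf("g4_feature_report '%s' (track kind: %s; %d motifs, %d excluded)\n",
              x$feature_id, x$kind, x$n_total, x$excluded))
  print(x$groups, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Run a set of feature reports
#'
#' @inheritParams run_feature_report
#' @param features Character vector of feature ids (default: all).
#' @return Named list of `g4_feature_report` objects.
#' @export
run_feature_reports <- function(scored, features = feature_ids(),
                                config = list(), resample_n = 1000L,
                                seed = 1L) {
  bad <- setdiff(features, .FEATURE_IDS)
  if (length(bad))
    g4_config_error("unknown feature id(s): ", paste(bad, collapse = ", "),
                    "; valid: ", paste(.FEATURE_IDS, collapse = ", "))
  out <- lapply(seq_along(features), function(i)
    run_feature_report(scored, features[i], config, resample_n,
                       seed + 1000L * i))
  names(out) <- features
  out
}
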