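# Synthetic genome + signal generator.
#
# Generates a genome in which PQS motifs with controlled structural features
# are embedded in G-tract-suppressed background sequence, together with
# mm_pct and phred_quality signal tracks produced from an explicit latent
# thermostability model.  The generator is the ground truth for the whole
# pipeline: every trend the stratified reports are expected to recover is
# written into the latent model here (layer bonus with the three-layer/1-nt
# anomaly, per-nucleotide loop penalty, piecewise bulge penalty peaking at
# 5 nt, stabilising TGA/GAA and destabilising TT flanks, telomeric A-to-T
# destabilisation).

#' Synthetic model configuration
#'
#' All generator parameters with their defaults.  The latent stability S of
#' a motif is built additively on a melting-temperature-like scale
#' (arbitrary units commensurate with deg C):
#' `S = S0 + layer_bonus*(NT-3) - loop_penalty*Ltot - bulge_penalty[size]
#'  + anomaly_boost*[NT=3, all loops 1 nt, no bulge] + flank effects
#'  + telomeric adjustments + N(0, sigma_motif)`.
#' Signals are mapped monotonically: mismatch percentage rises with S via a
#' logistic, quality falls with S via `41.1 - exp(a*S + b)` clipped to
#' `[0, 41]`, so that the pipeline's transformed quality score is linear in
#' S wherever unclipped.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_per_cell Motifs generated per stratification cell.
#' @param background_gc GC fraction of the background sequence (G-tract
#'   suppressed: no GGG run survives outside embedded motifs).
#' @param separation Background nucleotides between consecutive inserts.
#' @param insulator Width of the A/T-only buffer wrapped around each insert
#'   (outside the designed flanks).  At 16 nt it exceeds the longest loop
#'   plus the largest bulge, so no grammar parse can bridge from background
#'   guanines (on either strand) into an embedded motif.
#' @param flank_width Designed flank width (nt) on each side of a motif core.
#' @param motifs_per_chrom Inserts per synthetic chromosome.
#' @param fraction_minus Fraction of motifs embedded on the minus strand.
#' @param genome_length Optional total genome length; padded with extra
#'   background, or a config error if shorter than the packing requires.
#' @param S0 Baseline latent stability of a canonical three-layer motif.
#' @param layer_bonus Latent gain per tetrad layer above 3.
#' @param loop_penalty Latent loss per total-loop nucleotide.
#' @param bulge_penalty Length-8 vector of penalties for bulge sizes 1-8;
#'   rises to a maximum at 5 nt then declines (internal-duplex compensation).
#' @param anomaly_boost Extra stability of the three-layer, all-1-nt-loop,
#'   bulge-free configuration (the d(G3T)4 anomaly).
#' @param flank_delta Latent shift for flank classes: `+` for 5'-...TGA and
#'   3'-GAA..., `-` for TT immediately adjacent on either side.
#' @param telo_wt_bonus,telo_at_penalty Telomeric adjustments: bonus for the
#'   (GGGTTA)n architecture, penalty once any TTA loop is mutated to TTT.
#' @param sigma_motif SD of the per-motif latent noise.
#' @param sigma_base SD of the per-base signal jitter over motif footprints.
#' @param mm_max,mm_mu,mm_tau Mismatch mapping `mm = mm_max *
#'   logistic((S - mm_mu)/mm_tau)`.
#' @param q_a,q_b Quality mapping `q = clip(41.1 - exp(q_a*S + q_b), 0, 41)`;
#'   defaults anchor q(S=28) = 40.4 and q(S=90) = 10, so the whole latent
#'   range of the default library (roughly S = 26 to 90) maps strictly
#'   inside the clip bounds and the transform stays discriminating near the
#'   41 ceiling.
#' @param background_mm,background_quality Signal level at background bases.
#' @param tm_T0,tm_slope,tm_sigma Melting-temperature simulation: `Tm = T0 -
#'   tm_slope * Ltot + N(0, tm_sigma)` with the literature default of 2 deg C
#'   lost per total-loop nucleotide.
#' @param dg0,dg_slope Free-energy simulation: `dG = dg0 + dg_slope * Ltot`
#'   plus noise scaled by `tm_sigma * dg_slope / tm_slope`; default 0.3
#'   kcal/mol lost per loop nucleotide.
#' @param min_g,loop_min,loop_max Grammar bounds the generated motifs obey.
#' @return A `g4_synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_per_cell = 200L,
                         background_gc = 0.4, separation = 50L,
                         insulator = 16L, flank_width = 5L,
                         motifs_per_chrom = 2000L,
                         fraction_minus = 0.5, genome_length = NULL,
                         S0 = 70, layer_bonus = 8, loop_penalty = 2,
                         bulge_penalty = c(1.5, 3, 4.5, 6, 7.5, 6, 4.5, 3),
                         anomaly_boost = 18, flank_delta = 3,
                         telo_wt_bonus = 2, telo_at_penalty = 3,
                         sigma_motif = 2, sigma_base = 0.5,
                         mm_max = 90, mm_mu = 70, mm_tau = 8,
                         q_a = log(31.1 / 0.7) / 62, q_b = log(0.7) - 28 * log(31.1 / 0.7) / 62,
                         background_mm = 1, background_quality = 38,
                         tm_T0 = 90, tm_slope = 2, tm_sigma = 0.5,
                         dg0 = -10, dg_slope = 0.3,
                         min_g = 3L, loop_min = 1L, loop_max = 7L) {
  cfg <- as.list(environment())
  if (cfg$n_per_cell < 1L) g4_config_error("n_per_cell must be >= 1")
  if (length(cfg$bulge_penalty) != 8L)
    g4_config_error("bulge_penalty must have 8 entries (sizes 1-8)")
  if (cfg$background_gc <= 0 || cfg$background_gc >= 1)
    g4_config_error("background_gc must be in (0, 1)")
  if (cfg$separation < 10L) g4_config_error("separation must be >= 10")
  if (cfg$insulator < cfg$loop_max + 9L)
    g4_config_error("insulator must be at least loop_max + bulge_max + 1 nt")
  if (cfg$sigma_motif < 0 || cfg$sigma_base < 0)
    g4_config_error("noise SDs must be >= 0")
  class(cfg) <- "g4_synth_config"
  cfg
}

# --- stratification cells ---------------------------------------------------

# One row per cell; loop lengths of 0 mean "drawn per motif" (loop_total).
.build_cells <- function(cfg) {
  cells <- list()
  add <- function(family, id, nt = 3L, lens = c(1L, 1L, 1L), mode = "random",
                  bulge = 0L, f5 = NA, f3 = NA, mid = NA, b1 = NA, b3 = NA,
                  total = NA) {
    cells[[length(cells) + 1L]] <<- data.frame(
      family = family, cell_id = id, n_tetrads = nt,
      l1 = lens[1L], l2 = lens[2L], l3 = lens[3L], loop_mode = mode,
      bulge_size = bulge, flank5_pattern = f5, flank3_pattern = f3,
      comp_b1 = b1, comp_b3 = b3, loop_total = total,
      stringsAsFactors = FALSE)
  }
  for (nt in 3:5) {
    add("layers", sprintf("layers_NT%d_1nt", nt), nt, c(1L, 1L, 1L))
    add("layers", sprintf("layers_NT%d_2nt", nt), nt, c(2L, 2L, 2L))
    add("layers", sprintf("layers_NT%d_long", nt), nt, c(4L, 4L, 4L))
  }
  add("bulge_ref", "bulge_none")
  for (s in 1:8) add("bulge", sprintf("bulge_%d", s), bulge = s)
  for (t in 3:21) add("loop_total", sprintf("loop_total_%02d", t),
                      lens = c(0L, 0L, 0L), mode = "split_total", total = t)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (p in perms) add("perm_unequal",
                       sprintf("perm_%d%d%d", p[1], p[2], p[3]), lens = p)
  for (p in list(c(3L, 3L, 1L), c(3L, 1L, 3L), c(1L, 3L, 3L)))
    add("perm_pair_gt", sprintf("permgt_%d%d%d", p[1], p[2], p[3]), lens = p)
  for (p in list(c(1L, 1L, 5L), c(1L, 5L, 1L), c(5L, 1L, 1L)))
    add("perm_pair_lt", sprintf("permlt_%d%d%d", p[1], p[2], p[3]), lens = p)
  add("telomeric", "telo_WT", lens = c(3L, 3L, 3L), mode = "telo_wt")
  add("telomeric", "telo_AtoT", lens = c(3L, 3L, 3L), mode = "telo_var")
  for (b1 in c("A", "C", "T")) for (b3 in c("A", "C", "T")) {
    add("comp131", sprintf("comp131_%s%s", b1, b3), lens = c(1L, 3L, 1L),
        mode = "composition", b1 = b1, b3 = b3)
    add("comp161", sprintf("comp161_%s%s", b1, b3), lens = c(1L, 6L, 1L),
        mode = "composition", b1 = b1, b3 = b3)
  }
  add("flank5", "flank5_NNNTT", f5 = "NNNTT")
  add("flank5", "flank5_NNTGA", f5 = "NNTGA")
  add("flank3", "flank3_GAANN", f3 = "GAANN")
  add("flank3", "flank3_TTNNN", f3 = "TTNNN")
  do.call(rbind, cells)
}

# --- sequence construction --------------------------------------------------

# Random loop/flank filler: A/C/T only (never extends a G-tract on the
# motif strand) and no CCC run (never fabricates a G-tract on the opposite
# strand).
.rand_act <- function(n) {
  repeat {
    s <- paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
    if (!grepl("CCC", s, fixed = TRUE)) return(s)
  }
}

# random flank that carries no modelled flank effect
.neutral_flank <- function(width, side) {
  repeat {
    f <- .rand_act(width)
    hit <- if (side == "5p")
      endsWith(f, "TT") || endsWith(f, "TGA")
    else startsWith(f, "TT") || startsWith(f, "GAA")
    if (!hit) return(f)
  }
}

.instantiate_pattern <- function(pat) {
  repeat {
    ch <- strsplit(pat, "", fixed = TRUE)[[1L]]
    ch[ch == "N"] <- sample(c("A", "C", "T"), sum(ch == "N"), replace = TRUE)
    s <- paste(ch, collapse = "")
    if (!grepl("CCC", s, fixed = TRUE)) return(s)
  }
}

# split total loop length into three parts, each within [lmin, lmax]
.split_total <- function(total, lmin, lmax) {
  repeat {
    l1 <- sample(lmin:lmax, 1L)
    l2 <- sample(lmin:lmax, 1L)
    l3 <- total - l1 - l2
    if (l3 >= lmin && l3 <= lmax) return(c(l1, l2, l3))
  }
}

# Build one motif instance from a cell definition.  Returns list with the
# core sequence, flanks (motif strand) and realised feature fields.
.build_motif <- function(cell, cfg) {
  lens <- c(cell$l1, cell$l2, cell$l3)
  if (cell$loop_mode == "split_total")
    lens <- .split_total(cell$loop_total, cfg$loop_min, cfg$loop_max)
  loops <- switch(cell$loop_mode,
    telo_wt = c("TTA", "TTA", "TTA"),
    telo_var = {
      k <- sample(1:3, 1L)
      l <- c("TTA", "TTA", "TTA")
      l[sample(1:3, k)] <- "TTT"
      l
    },
    composition = c(cell$comp_b1, .rand_act(lens[2L]), cell$comp_b3),
    vapply(lens, .rand_act, "")
  )
  lens <- nchar(loops)
  nt <- cell$n_tetrads
  tracts <- rep(strrep("G", nt), 4L)
  bulge_tract <- NA_integer_; bulge_offset <- NA_integer_
  bulge_seq <- ""
  if (cell$bulge_size > 0L) {
    bulge_tract <- sample(0:3, 1L)
    bulge_offset <- sample(seq_len(nt - 1L), 1L)
    bulge_seq <- .rand_act(cell$bulge_size)
    t <- strrep("G", nt)
    tracts[bulge_tract + 1L] <- paste0(substr(t, 1L, bulge_offset), bulge_seq,
                                       substr(t, bulge_offset + 1L, nt))
  }
  core <- paste0(tracts[1L], loops[1L], tracts[2L], loops[2L], tracts[3L],
                 loops[3L], tracts[4L])
  f5 <- if (!is.na(cell$flank5_pattern))
    .instantiate_pattern(cell$flank5_pattern)
  else .neutral_flank(cfg$flank_width, "5p")
  f3 <- if (!is.na(cell$flank3_pattern))
    .instantiate_pattern(cell$flank3_pattern)
  else .neutral_flank(cfg$flank_width, "3p")
  list(core = core, flank5 = f5, flank3 = f3, n_tetrads = nt,
       loop_lens = lens, loops = loops,
       bulge_size = if (cell$bulge_size > 0L) cell$bulge_size else NA_integer_,
       bulge_tract = bulge_tract, bulge_offset = bulge_offset,
       bulge_seq = bulge_seq)
}

# Deterministic part of the latent stability for one realised motif.
.latent_mean <- function(m, cfg) {
  ltot <- sum(m$loop_lens)
  s <- cfg$S0 + cfg$layer_bonus * (m$n_tetrads - 3L) -
    cfg$loop_penalty * ltot
  canonical <- is.na(m$bulge_size)
  if (!canonical) s <- s - cfg$bulge_penalty[m$bulge_size]
  if (canonical && m$n_tetrads == 3L && all(m$loop_lens == 1L))
    s <- s + cfg$anomaly_boost
  f5 <- m$flank5; f3 <- m$flank3
  if (endsWith(f5, "TGA")) s <- s + cfg$flank_delta
  if (endsWith(f5, "TT")) s <- s - cfg$flank_delta
  if (startsWith(f3, "GAA")) s <- s + cfg$flank_delta
  if (startsWith(f3, "TT")) s <- s - cfg$flank_delta
  if (canonical && m$n_tetrads == 3L && all(m$loops %in% c("TTA", "TTT"))) {
    s <- s + cfg$telo_wt_bonus
    if (any(m$loops == "TTT")) s <- s - cfg$telo_at_penalty
  }
  s
}

# G-tract-suppressed background: no GGG and no CCC run survives (the latter
# would be a G-tract on the minus strand).  Runs are broken with A/T, which
# cannot seed new G or C runs.
.break_runs <- function(ch, base) {
  r <- rle(ch == base)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= 3L)
  for (k in long) {
    fix <- seq(starts[k] + 2L, ends[k], by = 3L)
    ch[fix] <- sample(c("A", "T"), length(fix), replace = TRUE)
  }
  ch
}

.background_seq <- function(n, gc) {
  if (n == 0L) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
  .break_runs(.break_runs(ch, "G"), "C")
}

.REVC <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
.revcomp_str <- function(s) {
  paste(rev(.REVC[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Generate the synthetic motif library
#'
#' Embeds `n_per_cell` motifs for every stratification cell (tetrad-layer by
#' loop-class grid, bulge sizes 1-8 plus a bulge-free reference, total loop
#' lengths 3-21, the six unequal and six equal-pair loop permutations,
#' telomeric wild type and A-to-T variants, the 1-3-1 and 1-6-1 composition
#' grids, and the four flank classes) at well-separated positions in
#' G-tract-suppressed background sequence, on randomly chosen strands.  Each
#' motif receives a latent stability S from the configured thermostability
#' model.  Identical configurations (including the seed) reproduce the
#' library byte for byte.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `truth.tsv` and `manifest.json` there.
#' @return A `g4_synth_library`: list with `genome` (named character vector),
#'   `truth` (data frame, 0-based half-open core coordinates plus realised
#'   features and latent S), `config`, and `files` (if written).
#' @export
generate_library <- function(config = synth_config(), out_dir = NULL) {
  cfg <- config
  cells <- .build_cells(cfg)
  res <- with_seed(cfg$seed, {
    inst_cell <- rep(seq_len(nrow(cells)), each = cfg$n_per_cell)
    inst_cell <- sample(inst_cell)            # mix families along the genome
    n <- length(inst_cell)
    motifs <- vector("list", n)
    for (i in seq_len(n)) {
      m <- .build_motif(cells[inst_cell[i], ], cfg)
      m$cell_id <- cells$cell_id[inst_cell[i]]
      m$family <- cells$family[inst_cell[i]]
      m$latent_mean <- .latent_mean(m, cfg)
      m$latent_S <- m$latent_mean + stats::rnorm(1L, 0, cfg$sigma_motif)
      m$strand <- if (stats::runif(1L) < cfg$fraction_minus) "-" else "+"
      motifs[[i]] <- m
    }
    # required length if a fixed genome_length was requested
    ins_len <- vapply(motifs, function(m)
      nchar(m$core) + nchar(m$flank5) + nchar(m$flank3), 0) +
      2 * cfg$insulator
    n_chrom <- ceiling(n / cfg$motifs_per_chrom)
    required <- sum(ins_len) + cfg$separation * (n + n_chrom)
    if (!is.null(cfg$genome_length) && cfg$genome_length < required)
      g4_config_error("genome_length too short for the requested library; ",
                      "need at least ", required, " nt")
    extra <- if (is.null(cfg$genome_length)) 0L
             else as.integer(cfg$genome_length - required)
    genome <- character(0)
    rows <- vector("list", n)
    ci <- 0L
    for (chrom_i in seq_len(n_chrom)) {
      lo <- (chrom_i - 1L) * cfg$motifs_per_chrom + 1L
      hi <- min(chrom_i * cfg$motifs_per_chrom, n)
      parts <- character(0); off <- 0L
      for (i in lo:hi) {
        m <- motifs[[i]]
        bg <- paste(.background_seq(cfg$separation, cfg$background_gc),
                    collapse = "")
        insert <- paste0(m$flank5, m$core, m$flank3)
        if (m$strand == "-") insert <- .revcomp_str(insert)
        buf1 <- paste(sample(c("A", "T"), cfg$insulator, replace = TRUE),
                      collapse = "")
        buf2 <- paste(sample(c("A", "T"), cfg$insulator, replace = TRUE),
                      collapse = "")
        insert <- paste0(buf1, insert, buf2)
        parts <- c(parts, bg, insert)
        core_start <- off + cfg$separation + cfg$insulator + nchar(m$flank5)
        ci <- ci + 1L
        rows[[ci]] <- data.frame(
          chrom = sprintf("synth_%d", chrom_i),
          start = core_start, end = core_start + nchar(m$core),
          strand = m$strand, cell_id = m$cell_id, family = m$family,
          n_tetrads = m$n_tetrads,
          loop1_len = m$loop_lens[1L], loop2_len = m$loop_lens[2L],
          loop3_len = m$loop_lens[3L],
          loop1_seq = m$loops[1L], loop2_seq = m$loops[2L],
          loop3_seq = m$loops[3L],
          bulge_size = m$bulge_size, bulge_tract = m$bulge_tract,
          bulge_offset = m$bulge_offset, bulge_seq = m$bulge_seq,
          flank5 = m$flank5, flank3 = m$flank3,
          latent_mean = m$latent_mean, latent_S = m$latent_S,
          stringsAsFactors = FALSE)
        off <- off + cfg$separation + nchar(insert)
      }
      tail_bg <- cfg$separation + if (chrom_i == n_chrom) extra else 0L
      parts <- c(parts, paste(.background_seq(tail_bg, cfg$background_gc),
                              collapse = ""))
      genome[sprintf("synth_%d", chrom_i)] <- paste(parts, collapse = "")
    }
    list(genome = genome, truth = do.call(rbind, rows))
  })
  lib <- list(genome = res$genome, truth = res$truth, config = cfg,
              files = NULL)
  class(lib) <- "g4_synth_library"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    tsv <- file.path(out_dir, "truth.tsv")
    man <- file.path(out_dir, "manifest.json")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(res$genome), fa,
                                width = 70L)
    data.table::fwrite(res$truth, tsv, sep = "\t", quote = FALSE)
    write_manifest(man, cfg, extra = list(
      n_motifs = nrow(res$truth), n_chrom = length(res$genome)))
    lib$files <- c(fasta = fa, truth = tsv, manifest = man)
  }
  lib
}

#' @export
print.g4_synth_library <- function(x, ...) {
  cat(sprintf("g4_synth_library: %d motifs in %d chromosome(s) (%.2f Mb), seed %d\n",
              nrow(x$truth), length(x$genome),
              sum(nchar(x$genome)) / 1e6, x$config$seed))
  invisible(x)
}

#' Emit synthetic signal tracks for a generated library
#'
#' Maps each motif's latent stability S through the two monotone signal
#' mappings (logistic for mismatch percentage, `41.1 - exp(aS + b)` clipped
#' to `[0, 41]` for quality) and writes the level, plus per-base Gaussian
#' jitter, over the motif's genomic footprint.  Background positions carry
#' the constant background level.  Both tracks cover every base.
#'
#' @param lib A `g4_synth_library` from [generate_library()].
#' @param out_dir Optional directory; writes `signal_mm.bedGraph` and
#'   `signal_quality.bedGraph` there.
#' @return List with `mm` and `quality` [signal_track()] objects (and
#'   `files` if written).
#' @export
emit_tracks <- function(lib, out_dir = NULL) {
  cfg <- lib$config
  truth <- lib$truth
  chrom_len <- nchar(lib$genome)
  mm_vals <- lapply(chrom_len, function(L) rep(cfg$background_mm, L))
  q_vals <- lapply(chrom_len, function(L) rep(cfg$background_quality, L))
  names(mm_vals) <- names(q_vals) <- names(lib$genome)
  with_seed(cfg$seed + 1L, {
    for (i in seq_len(nrow(truth))) {
      S <- truth$latent_S[i]
      len <- truth$end[i] - truth$start[i]
      pos <- (truth$start[i] + 1L):truth$end[i]
      mm_level <- cfg$mm_max * stats::plogis((S - cfg$mm_mu) / cfg$mm_tau)
      q_level <- min(max(41.1 - exp(cfg$q_a * S + cfg$q_b), 0), 41)
      mm <- mm_level + stats::rnorm(len, 0, cfg$sigma_base)
      qq <- q_level + stats::rnorm(len, 0, cfg$sigma_base)
      mm_vals[[truth$chrom[i]]][pos] <- pmin(pmax(mm, 0), 100)
      q_vals[[truth$chrom[i]]][pos] <- pmin(pmax(qq, 0), 41)
    }
  })
  out <- list(mm = signal_track(mm_vals, "mm_pct"),
              quality = signal_track(q_vals, "phred_quality"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fmm <- file.path(out_dir, "signal_mm.bedGraph")
    fq <- file.path(out_dir, "signal_quality.bedGraph")
    write_bedgraph(out$mm, fmm)
    write_bedgraph(out$quality, fq)
    out$files <- c(mm = fmm, quality = fq)
  }
  out
}

#' Simulate a melting-temperature / free-energy library
#'
#' Draws motifs with total loop lengths uniform on the configured range and
#' simulates melting temperature and folding free energy as linear functions
#' of total loop length with Gaussian noise: `Tm = T0 - tm_slope*Ltot + e`
#' and `dG = dg0 + dg_slope*Ltot + e'`, with the free-energy noise scaled by
#' `dg_slope/tm_slope` so both responses carry proportionate noise.  The
#' defaults encode the empirical per-nucleotide penalties of about 2 deg C
#' and 0.3 kcal/mol, which ordinary least squares recovers from the output.
#'
#' @param config A [synth_config()] (slope, intercept and noise settings).
#' @param n Number of simulated motifs.
#' @param seed Integer seed.
#' @return Data frame with loop lengths, `total_loop_len`, `tm` and `dg`.
#' @examples
#' fit <- stats::lm(tm ~ total_loop_len, simulate_tm_library(n = 500))
#' abs(stats::coef(fit)[2])  # close to 2
#' @export
simulate_tm_library <- function(config = synth_config(), n = 1000L,
                                seed = 42L) {
  cfg <- config
  with_seed(seed, {
    total <- sample((3L * cfg$loop_min):(3L * cfg$loop_max), n, replace = TRUE)
    lens <- t(vapply(total, .split_total, integer(3L),
                     lmin = cfg$loop_min, lmax = cfg$loop_max))
    dg_sigma <- cfg$tm_sigma * cfg$dg_slope / cfg$tm_slope
    data.frame(
      loop1_len = lens[, 1L], loop2_len = lens[, 2L], loop3_len = lens[, 3L],
      total_loop_len = total,
      tm = cfg$tm_T0 - cfg$tm_slope * total + stats::rnorm(n, 0, cfg$tm_sigma),
      dg = cfg$dg0 + cfg$dg_slope * total + stats::rnorm(n, 0, dg_sigma))
  })
}
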