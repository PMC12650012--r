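# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Classed conditions so the command-line layer can map error types to exit
# codes (config error -> 2, input error -> 3) without string matching.
g4_config_error <- function(...) {
  stop(structure(
    class = c("g4strat_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

g4_input_error <- function(...) {
  stop(structure(
    class = c("g4strat_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Collapse / split integer vectors stored as comma strings in motif tables.
comma_join <- function(x) vapply(x, function(v) paste(v, collapse = ","), "")
comma_split_int <- function(s) lapply(strsplit(s, ",", fixed = TRUE), as.integer)

# Evaluate `expr` with a private RNG state: seeds the generator, restores the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message("[g4strat] ", ...)
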