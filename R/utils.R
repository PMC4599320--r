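# Internal helpers: error conditions, RNG hygiene, logging.

# Data/parse problems get a dedicated condition class so callers (and the
# command-line wrapper) can distinguish them from usage errors.
ktx_parse_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ktx_parse_error", "ktx_error")))
}

ktx_usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ktx_usage_error", "ktx_error")))
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded package internals never perturb user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Per-query seed derivation: global seed plus the query ordinal, kept inside
# 32-bit integer range. Guarantees sequential and any future concurrent
# execution agree query by query.
derive_seed <- function(seed, ordinal) {
  as.integer((as.numeric(seed) + as.numeric(ordinal)) %% .Machine$integer.max)
}

ktx_log <- function(..., logfile = NULL, verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  msg <- paste0("[kmerTax ", format(Sys.time(), "%H:%M:%S"), "] ",
                sprintf(...))
  if (is.null(logfile)) message(msg) else cat(msg, "\n", file = logfile,
                                              append = TRUE, sep = "")
  invisible(NULL)
}
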