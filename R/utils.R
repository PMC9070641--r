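# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Fixed-precision number formatting for text outputs (platform-stable).
fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

# Full-precision formatting for lossless numeric round-trips through TSV.
fmt_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17L, format = "g"))
}

assert_character_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stopf("%s contains missing or empty identifiers", what)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stopf(
      "duplicate %s: %s", what,
      paste(utils::head(dup, 5L), collapse = ", ")
    )
  }
  invisible(ids)
}
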