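# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even; reported
# percentages follow the usual clinical-paper convention of 0.5 rounding up).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of count/total rounded to one decimal place.
pct <- function(count, total) {
  round_half_up(100 * count / total, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Atomic text write: write to a sibling temp file, then rename into place.
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so cohort generation is a pure function of its arguments.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
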