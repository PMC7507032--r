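# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators do not perturb the session stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stop with a formatted message (no call in the condition).
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fail("`%s` must be a single finite number", name)
  if (strict_min && x <= min) fail("`%s` must be > %s", name, format(min))
  if (!strict_min && x < min) fail("`%s` must be >= %s", name, format(min))
  if (x > max) fail("`%s` must be <= %s", name, format(max))
  invisible(x)
}

# Rank-based AUROC (Mann-Whitney with midranks for ties); larger score
# should indicate the positive class.
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) fail("AUROC needs both classes present")
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Row-wise variance of a numeric matrix (two-pass, stable enough here).
row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}
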