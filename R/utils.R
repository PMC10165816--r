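# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a square symmetric distance representation; return a plain numeric
# matrix with zero diagonal and dimnames. Accepts dist or matrix.
as_dist_matrix <- function(d, arg = "distance matrix") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    .stopf("%s must be square", arg)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("s", seq_len(nrow(d))),
                        paste0("s", seq_len(nrow(d))))
  if (anyDuplicated(rownames(d)))
    .stopf("%s labels must be unique", arg)
  if (max(abs(d - t(d))) > 1e-12)
    .stopf("%s must be symmetric (tolerance 1e-12)", arg)
  if (any(abs(diag(d)) > 0))
    .stopf("%s must have a zero diagonal", arg)
  if (any(d < 0))
    .stopf("%s must be non-negative", arg)
  d
}

# All permutations of seq_len(n), one per row, in lexicographic order.
# Used for exhaustive permutation modes (n <= 8 or so).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Average ranks (Spearman convention).
avg_rank <- function(x) rank(x, ties.method = "average")

.pct1 <- function(x) round(100 * x, 1)
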