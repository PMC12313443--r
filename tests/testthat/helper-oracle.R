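# Independent entropy-extreme oracle: exhaustive enumeration of all
# non-negative integer tables with fixed marginals. Used to check that the
# greedy h2_min and the independence-table h2_max bracket every attainable
# two-dimensional entropy. Kept free of any package internals beyond plain
# arithmetic.

# All vectors x with 0 <= x_j <= caps_j and sum(x) = total.
enum_bounded_vectors <- function(total, caps) {
  if (length(caps) == 1L) {
    if (total <= caps) return(list(total))
    return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1])) {
    for (rest in enum_bounded_vectors(total - v, caps[-1]))
      out[[length(out) + 1L]] <- c(v, rest)
  }
  out
}

# Entropies (nats) of every non-negative integer table with the given
# marginals. Recursion over rows.
enum_table_entropies <- function(row_totals, col_totals) {
  m <- sum(row_totals)
  stopifnot(m == sum(col_totals))
  ent <- function(cells) {
    p <- cells[cells > 0] / m
    -sum(p * log(p))
  }
  rec <- function(rows, cols, acc) {
    if (length(rows) == 1L) {
      if (rows == sum(cols)) return(ent(c(acc, cols)))
      return(numeric(0))
    }
    unlist(lapply(enum_bounded_vectors(rows[1], cols), function(x)
      rec(rows[-1], cols - x, c(acc, x))))
  }
  rec(row_totals, col_totals, numeric(0))
}

# All compositions of m into k positive parts.
compositions <- function(m, k) {
  if (k == 1L) return(list(m))
  out <- list()
  for (first in seq_len(m - k + 1L)) {
    for (rest in compositions(m - first, k - 1L))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}
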