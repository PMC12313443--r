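#' Two-dimensional Shannon entropy of an interaction matrix
#'
#' For a non-negative predator x prey matrix with entries a_ij and grand total
#' m, returns -sum p_ij ln p_ij with p_ij = a_ij / m and 0 ln 0 := 0. This is
#' the "observed" entropy H2 entering the network-level specialization index.
#' Scale-invariant: multiplying the matrix by any c > 0 leaves it unchanged.
#'
#' @param mat Non-negative numeric matrix with positive grand total.
#' @return Entropy in nats.
#' @export
shannon_2d <- function(mat) {
  m <- sum(mat)
  if (!is.finite(m) || m <= 0)
    stop("shannon_2d: matrix total must be positive")
  entropy_nats(as.vector(mat))
}

check_marginals <- function(row_totals, col_totals, tol = 1e-9) {
  if (any(row_totals < 0) || any(col_totals < 0))
    stop("marginal totals must be non-negative")
  m <- sum(row_totals)
  if (abs(m - sum(col_totals)) > tol)
    stop("row and column marginal sums disagree beyond tolerance")
  if (m <= 0) stop("marginal totals must be positive")
  m
}

#' Maximum two-dimensional entropy consistent with fixed marginals
#'
#' The entropy-maximizing table with given row and column totals is the
#' independence table p_ij = (A_i/m)(A_j/m), whose entropy is the sum of the
#' two marginal Shannon entropies. This is the H2max term of the
#' specialization index (continuous formulation).
#'
#' @param row_totals,col_totals Non-negative marginal totals with equal sums.
#' @return Entropy in nats.
#' @export
h2_max <- function(row_totals, col_totals) {
  check_marginals(row_totals, col_totals)
  entropy_nats(row_totals) + entropy_nats(col_totals)
}

#' Minimum two-dimensional entropy consistent with fixed marginals
#'
#' Entropy is concave on the transportation polytope of tables with the given
#' marginals, so its minimum is attained at a vertex; vertices are exactly
#' the tables produced by saturation sequences (repeatedly allocate
#' min(remaining row, remaining column) to some cell, which exhausts a row or
#' a column). Two methods:
#'
#' * `"exact"`: memoized search over all saturation sequences — the true
#'   minimum, feasible for small grids (used automatically up to 12 cells).
#' * `"greedy"`: one deterministic sequence that always pairs the largest
#'   remaining row total with the largest remaining column total (ties broken
#'   by lowest original index). Fast and usually tight, but an upper bound on
#'   the true minimum; used automatically for production-size webs.
#'
#' @inheritParams h2_max
#' @param method `"auto"` (exact when nrow x ncol <= 12, greedy otherwise),
#'   `"exact"`, or `"greedy"`.
#' @return Entropy in nats of the most concentrated attainable table.
#' @export
h2_min <- function(row_totals, col_totals,
                   method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  m <- check_marginals(row_totals, col_totals)
  r <- as.numeric(row_totals)
  co <- as.numeric(col_totals)
  if (method == "auto")
    method <- if (length(r) * length(co) <= 12L) "exact" else "greedy"
  if (method == "exact") return(min_entropy_exact(r, co, m))
  alloc <- numeric(length(r) + length(co))
  k <- 0L
  eps <- m * 1e-12
  while (TRUE) {
    i <- which.max(r)           # which.max takes the lowest index on ties
    j <- which.max(co)
    a <- min(r[i], co[j])
    if (a <= eps) break
    k <- k + 1L
    alloc[k] <- a
    r[i] <- r[i] - a
    co[j] <- co[j] - a
  }
  entropy_nats(alloc[seq_len(k)])
}

# Exact concave minimization over the transportation polytope by memoized
# enumeration of saturation sequences. States are sorted remaining-marginal
# multisets, so permuted duplicates collapse.
min_entropy_exact <- function(r, co, m) {
  eps <- m * 1e-12
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(r, co) {
    r <- sort(r[r > eps], decreasing = TRUE)
    co <- sort(co[co > eps], decreasing = TRUE)
    if (!length(r)) return(0)
    key <- paste(c(signif(r, 12), "|", signif(co, 12)), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (i in seq_along(r)) {
      if (i > 1L && r[i] == r[i - 1L]) next
      for (j in seq_along(co)) {
        if (j > 1L && co[j] == co[j - 1L]) next
        a <- min(r[i], co[j])
        r2 <- r; co2 <- co
        r2[i] <- r2[i] - a; co2[j] <- co2[j] - a
        v <- -(a / m) * log(a / m) + rec(r2, co2)
        if (v < best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  rec(r, co)
}

# Fast internal H2' on a plain matrix; returns list(h2, h2min, h2max, h2prime,
# valid, reason) without constructing result objects. Used in the null engine
# where it runs hundreds of thousands of times.
h2_stats <- function(mat, tol = 1e-9) {
  rt <- rowSums(mat)
  ct <- colSums(mat)
  m <- sum(rt)
  if (m <= 0)
    return(list(h2 = NA_real_, h2min = NA_real_, h2max = NA_real_,
                h2prime = NA_real_, valid = FALSE, reason = "empty"))
  h2max <- entropy_nats(rt) + entropy_nats(ct)
  h2min <- h2_min(rt, ct)
  if (h2max - h2min < tol)
    return(list(h2 = entropy_nats(as.vector(mat)), h2min = h2min,
                h2max = h2max, h2prime = NA_real_, valid = FALSE,
                reason = "degenerate"))
  h2 <- entropy_nats(as.vector(mat))
  h2p <- (h2max - h2) / (h2max - h2min)
  list(h2 = h2, h2min = h2min, h2max = h2max,
       h2prime = min(1, max(0, h2p)), valid = TRUE, reason = "")
}

#' Network-level specialization H2' of an interaction web
#'
#' H2' = (H2max - H2) / (H2max - H2min), the observed two-dimensional Shannon
#' entropy standardized by the extremes attainable under the web's marginal
#' totals. It is bound between 0 (absolute generalization: every predator's
#' diet proportional to overall prey use) and 1 (absolute specialization:
#' complete diet partitioning), and is invariant to rescaling the matrix and
#' to row/column permutation.
#'
#' Webs whose grand total is zero are flagged invalid with reason `"empty"`;
#' webs whose marginals leave no entropy range (single predator species,
#' single prey target, or any case with H2max - H2min below tolerance) are
#' flagged `"degenerate"`. Invalidity is a result state, not an error, so
#' whole seasons of webs can be processed and filtered downstream.
#'
#' @param web An `interaction_web` (see [build_webs()]) or a plain
#'   non-negative matrix.
#' @return A one-row data.frame with columns H2, H2min, H2max, H2prime,
#'   valid, reason (plus the unit-key columns when `web` carries a unit).
#' @examples
#' h2_prime(diag(0.25, 4))$H2prime   # 1: perfectly specialized
#' p <- outer(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))
#' h2_prime(p)$H2prime               # 0: perfectly generalized
#' @export
h2_prime <- function(web) {
  mat <- if (inherits(web, "interaction_web")) web$matrix else as.matrix(web)
  s <- h2_stats(mat)
  res <- data.frame(H2 = s$h2, H2min = s$h2min, H2max = s$h2max,
                    H2prime = s$h2prime, valid = s$valid, reason = s$reason,
                    stringsAsFactors = FALSE)
  if (inherits(web, "interaction_web"))
    res <- cbind(web$unit, res, row.names = NULL)
  res
}

#' Specialization of every web in a list
#'
#' @param webs List of `interaction_web` objects, as from [build_webs()].
#' @return Data.frame, one row per web, with unit keys and H2 components.
#' @export
specialization_table <- function(webs) {
  do.call(rbind, lapply(webs, h2_prime))
}
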