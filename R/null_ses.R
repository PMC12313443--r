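#' Configuration of the randomization null model
#'
#' The null webs are obtained by randomly recombining individual diet data
#' points before the species-averaging step, recomputing each unit's web and
#' its specialization for every randomization. Three recombination strategies
#' are available:
#'
#' * `prey_label_shuffle` (default): within each scope stratum, each prey
#'   target's binary detection column is independently permuted across all
#'   individual records. This preserves every prey's total detection count
#'   and every individual's unit/species assignment, so it isolates exactly
#'   the predator-species-by-prey association that H2' measures.
#' * `cell_shuffle`: all cells of the individual-by-prey binary table are
#'   permuted jointly within the stratum, preserving only the grand total of
#'   detections.
#' * `within_unit_shuffle`: `prey_label_shuffle` restricted to each unit's
#'   own records.
#'
#' @param n_randomizations Number of null webs per unit (>= 1). Default 999,
#'   a desk-scale setting; 99,999 reproduces the published analysis scale.
#' @param strategy One of `"prey_label_shuffle"`, `"cell_shuffle"`,
#'   `"within_unit_shuffle"`.
#' @param scope Stratum within which diet points are recombined: `"year"`
#'   (default), `"treatment"` (year x treatment), `"global"`, or `"unit"`.
#' @param min_valid Minimum number of valid null draws required to report an
#'   SES for a unit.
#' @param seed Integer master seed; per-unit streams are derived from it by a
#'   stable hash of the unit key, so results are independent of processing
#'   order.
#' @return An object of class `null_config`.
#' @export
null_config <- function(n_randomizations = 999L,
                        strategy = c("prey_label_shuffle", "cell_shuffle",
                                     "within_unit_shuffle"),
                        scope = c("year", "treatment", "global", "unit"),
                        min_valid = 30L,
                        seed = 1L) {
  strategy <- match.arg(strategy)
  scope <- match.arg(scope)
  n_randomizations <- as.integer(n_randomizations)
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1")
  structure(list(n_randomizations = n_randomizations, strategy = strategy,
                 scope = scope, min_valid = as.integer(min_valid),
                 seed = as.integer(seed)),
            class = "null_config")
}

stratum_id <- function(records, scope) {
  switch(scope,
         year = records$year,
         treatment = paste(records$year, records$treatment, sep = ":"),
         global = rep("all", nrow(records)),
         unit = unit_id(records),
         stop("unknown scope: ", scope))
}

#' Randomly recombine diet data points
#'
#' Applies one full randomization of the detection table under the configured
#' strategy and scope (see [null_config()]). The output has identical record
#' count and unit/species structure; only the binary detection cells move.
#' Self-detection cells are re-zeroed afterwards so no randomization can
#' reintroduce an artifact the cleaning step removed.
#'
#' @param records Cleaned detection data.frame.
#' @param config A `null_config`.
#' @param design A `design_spec` (for the prey panel and self-detection map).
#' @return A shuffled detection data.frame.
#' @export
shuffle_detections <- function(records, config, design) {
  prey <- design$prey_targets
  strat <- stratum_id(records, config$scope)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    if (config$strategy == "cell_shuffle") {
      cells <- as.matrix(records[idx, prey, drop = FALSE])
      v <- as.vector(cells)
      records[idx, prey] <- matrix(v[sample.int(length(v))],
                                   nrow = length(idx))
    } else {
      # prey_label_shuffle, or within_unit_shuffle (scope forced to unit)
      groups <- if (config$strategy == "within_unit_shuffle")
        split(idx, unit_id(records[idx, , drop = FALSE])) else list(idx)
      for (g in groups)
        for (tg in prey)
          records[[tg]][g] <- records[[tg]][g][sample.int(length(g))]
    }
  }
  suppressMessages(
    remove_self_detections(records, design$self_detection_map))
}

# Precomputed per-unit context for the fast null engine.
unit_null_context <- function(records, design, config) {
  uid <- unit_id(records)
  strat <- stratum_id(records, if (config$strategy == "within_unit_shuffle")
    "unit" else config$scope)
  prey <- design$prey_targets
  D <- as.matrix(records[, prey, drop = FALSE])
  storage.mode(D) <- "double"
  self_col <- match(design$self_detection_map[records$predator_species], prey)
  list(uid = uid, strat = strat, D = D, prey = prey,
       species = records$predator_species, self_col = self_col)
}

# One unit's null H2' draws. A within-stratum independent permutation of each
# prey column, restricted to the unit's rows, is distributionally identical
# to sampling the unit's rows without replacement from the stratum column:
# that is what is drawn here, avoiding rebuilding the full table per draw.
null_draws_unit <- function(ctx, unit_rows, n_draws, strategy) {
  # canonical orderings make draws invariant to record order: unit rows are
  # processed in species order (rows within a species are exchangeable) and
  # each pool column is sorted (draws are without-replacement samples of a
  # column's value multiset, so only the multiset matters)
  unit_rows <- unit_rows[order(ctx$species[unit_rows])]
  n_u <- length(unit_rows)
  P <- ncol(ctx$D)
  sp <- factor(ctx$species[unit_rows])
  cnt <- as.vector(table(sp))
  self_cells <- {
    sc <- ctx$self_col[unit_rows]
    lev <- match(ctx$species[unit_rows], levels(sp))
    ok <- !is.na(sc)
    unique(cbind(lev[ok], sc[ok]))
  }
  pool_rows <- which(ctx$strat == ctx$strat[unit_rows[1]])
  Ds <- ctx$D[pool_rows, , drop = FALSE]
  Ds <- apply(Ds, 2L, sort)
  if (is.null(dim(Ds))) Ds <- matrix(Ds, nrow = length(pool_rows))
  N_s <- nrow(Ds)
  cellpool <- if (strategy == "cell_shuffle") sort(as.vector(Ds))
  h2p <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    U <- if (strategy == "cell_shuffle") {
      matrix(cellpool[sample.int(length(cellpool), n_u * P)], n_u, P)
    } else {
      idx <- vapply(seq_len(P), function(j) sample.int(N_s, n_u),
                    integer(n_u))
      if (n_u == 1L) idx <- matrix(idx, 1L, P)
      matrix(Ds[cbind(as.vector(idx), rep(seq_len(P), each = n_u))], n_u, P)
    }
    M <- rowsum(U, sp) / cnt
    if (nrow(self_cells)) M[self_cells] <- 0
    s <- h2_stats(M)
    h2p[d] <- if (s$valid) s$h2prime else NA_real_
  }
  h2p
}

#' Null distribution of H2' for one sampling unit
#'
#' Repeats `n_randomizations` times: recombine diet points (under the
#' configured strategy/scope), rebuild the unit's web, compute H2'. Draws
#' whose randomized web is degenerate are dropped and counted. Fully
#' reproducible from the config seed; the unit's stream is independent of any
#' other unit's.
#'
#' @param records Cleaned detection data.frame.
#' @param design A `design_spec`.
#' @param unit One-row data.frame with the unit-key columns.
#' @param config A `null_config`.
#' @return Numeric vector of valid null H2' values, with attribute
#'   `n_invalid`.
#' @export
null_distribution <- function(records, design, unit, config) {
  ctx <- unit_null_context(records, design, config)
  uid <- unit_id(as.data.frame(unit))
  unit_rows <- which(ctx$uid == uid)
  if (!length(unit_rows)) stop("no records for unit ", uid)
  draws <- withr::with_seed(
    stable_hash(config$seed, "null", uid),
    null_draws_unit(ctx, unit_rows, config$n_randomizations,
                    config$strategy))
  if (all(is.na(draws)))
    stop("all null draws degenerate for unit ", uid)
  out <- draws[!is.na(draws)]
  attr(out, "n_invalid") <- sum(is.na(draws))
  out
}

#' Cohen's-d standardized effect size against a null distribution
#'
#' ses_d = (observed - mean(null)) / sd(null), with the sample (n-1) standard
#' deviation. Positive values mean the observed web is more specialized than
#' expected under random diet recombination.
#'
#' @param observed Observed H2'.
#' @param null_draws Numeric vector of valid null H2' draws (>= 2).
#' @return One-row data.frame with observed_H2prime, null_mean, null_sd,
#'   n_null_valid, ses_d, flag (`""`, or `"sd_zero"`).
#' @export
cohens_d_ses <- function(observed, null_draws) {
  if (length(null_draws) < 2L)
    stop("need at least 2 valid null draws")
  mu <- mean(null_draws)
  sdv <- stats::sd(null_draws)
  data.frame(observed_H2prime = observed, null_mean = mu, null_sd = sdv,
             n_null_valid = length(null_draws),
             ses_d = if (sdv > 0) (observed - mu) / sdv else NA_real_,
             flag = if (sdv > 0) "" else "sd_zero",
             stringsAsFactors = FALSE)
}

#' Standardized effect size of specialization for every valid unit
#'
#' Orchestrates the whole null-model comparison: builds the observed webs,
#' computes observed H2' per unit, draws the per-unit null distribution and
#' returns one SES row per unit with a valid observed web. Units whose
#' observed web is degenerate (single captured species, no detections, ...)
#' are reported with the degeneracy reason and no SES. Per-unit RNG streams
#' are derived from the master seed by a stable hash of the unit key, so the
#' output is identical whatever the unit processing order.
#'
#' @param records Cleaned detection data.frame.
#' @param design A `design_spec`.
#' @param config A `null_config`.
#' @return Data.frame: unit keys, observed_H2prime, null_mean, null_sd,
#'   n_null_valid, n_null_invalid, ses_d, flag.
#' @export
run_ses <- function(records, design, config = null_config()) {
  if (nrow(records) == 0) {
    warning("run_ses: empty record list")
    return(data.frame(year = character(0), field = character(0),
                      treatment = character(0), plot = character(0),
                      session = integer(0), observed_H2prime = numeric(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      n_null_valid = integer(0), n_null_invalid = integer(0),
                      ses_d = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE))
  }
  webs <- build_webs(records, design)
  obs <- specialization_table(webs)
  ctx <- unit_null_context(records, design, config)
  res <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    u <- obs[i, , drop = FALSE]
    unit <- u[, unit_key_cols, drop = FALSE]
    if (!u$valid) {
      res[[i]] <- cbind(unit, data.frame(
        observed_H2prime = NA_real_, null_mean = NA_real_,
        null_sd = NA_real_, n_null_valid = 0L, n_null_invalid = 0L,
        ses_d = NA_real_, flag = u$reason, stringsAsFactors = FALSE),
        row.names = NULL)
      next
    }
    uid <- unit_id(unit)
    unit_rows <- which(ctx$uid == uid)
    draws <- withr::with_seed(
      stable_hash(config$seed, "null", uid),
      null_draws_unit(ctx, unit_rows, config$n_randomizations,
                      config$strategy))
    valid <- draws[!is.na(draws)]
    if (length(valid) < max(2L, config$min_valid)) {
      res[[i]] <- cbind(unit, data.frame(
        observed_H2prime = u$H2prime, null_mean = NA_real_,
        null_sd = NA_real_, n_null_valid = length(valid),
        n_null_invalid = sum(is.na(draws)), ses_d = NA_real_,
        flag = "too_few_valid_nulls", stringsAsFactors = FALSE),
        row.names = NULL)
      next
    }
    d <- cohens_d_ses(u$H2prime, valid)
    res[[i]] <- cbind(unit, d[, c("observed_H2prime", "null_mean", "null_sd",
                                  "n_null_valid")],
                      data.frame(n_null_invalid = sum(is.na(draws))),
                      d[, c("ses_d", "flag")], row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
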