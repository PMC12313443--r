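#' Shannon-Weaver diversity of a count vector
#'
#' H = -sum p_i ln p_i over taxa with positive counts, computed through
#' `vegan::diversity`. Natural log, so a uniform community of S taxa gives
#' ln S.
#'
#' @param counts Named non-negative numeric vector (taxon counts).
#' @return Diversity in nats.
#' @export
shannon_diversity <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts) || all(counts == 0))
    stop("shannon_diversity: needs at least one positive count")
  if (any(counts < 0)) stop("counts must be non-negative")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Substitute aphid pitfall counts with tiller counts
#'
#' Aphids are plant-dwelling, so their pitfall-trap catches under-represent
#' them; counts from the 30 collected barley tillers replace the pitfall
#' values for every aphid taxon (including replacement by 0 when the tillers
#' held none). Non-aphid taxa are untouched, and an aphid present only in the
#' tiller survey is added with its tiller count.
#'
#' @param sample List with named count vectors `pitfall` and `tillers`
#'   (see [unit_sample()]).
#' @param aphid_taxa Character vector of aphid taxon labels.
#' @return Named numeric vector of prey-community counts.
#' @export
substitute_aphid_counts <- function(sample, aphid_taxa = default_aphid_taxa()) {
  out <- sample$pitfall
  for (tx in aphid_taxa) {
    till <- if (tx %in% names(sample$tillers)) sample$tillers[[tx]] else 0
    if (tx %in% names(out)) out[[tx]] <- till
    else if (till > 0) out[tx] <- till
    else out[tx] <- 0
  }
  out
}

#' Prey-community diversity of one unit sample
#'
#' Shannon diversity restricted to the declared prey taxa, after the aphid
#' tiller substitution.
#'
#' @inheritParams substitute_aphid_counts
#' @param prey_taxa Taxa entering the prey community.
#' @return Diversity in nats, or `NA` (with a warning) when no prey taxon has
#'   a positive count.
#' @export
prey_diversity <- function(sample, prey_taxa = default_prey_taxa(),
                           aphid_taxa = default_aphid_taxa()) {
  v <- substitute_aphid_counts(sample, aphid_taxa)
  v <- v[names(v) %in% prey_taxa]
  if (!length(v) || all(v == 0)) {
    warning("prey_diversity: no positive prey counts; flagged NA")
    return(NA_real_)
  }
  shannon_diversity(v)
}

#' Predator-community diversity of one unit sample
#'
#' Shannon diversity over the declared predator taxa of the pitfall catch; no
#' substitution applies.
#'
#' @inheritParams substitute_aphid_counts
#' @param predator_taxa Taxa entering the predator community.
#' @return Diversity in nats, or `NA` (with a warning) when empty.
#' @export
predator_diversity <- function(sample, predator_taxa = default_predator_taxa()) {
  v <- sample$pitfall[names(sample$pitfall) %in% predator_taxa]
  if (!length(v) || all(v == 0)) {
    warning("predator_diversity: no positive predator counts; flagged NA")
    return(NA_real_)
  }
  shannon_diversity(v)
}

#' Per-unit diversity table
#'
#' @param cs A `community_samples` object.
#' @param prey_taxa,predator_taxa,aphid_taxa Taxon lists (defaults: the
#'   study panel).
#' @return Data.frame: unit keys, predator_H, prey_H, predator_richness,
#'   prey_richness.
#' @export
diversity_table <- function(cs, prey_taxa = default_prey_taxa(),
                            predator_taxa = default_predator_taxa(),
                            aphid_taxa = default_aphid_taxa()) {
  units <- unique(rbind(cs$pitfall[, unit_key_cols, drop = FALSE],
                        cs$tillers[, unit_key_cols, drop = FALSE]))
  rownames(units) <- NULL
  res <- lapply(seq_len(nrow(units)), function(i) {
    unit <- units[i, , drop = FALSE]
    s <- unit_sample(cs, unit)
    prey_v <- substitute_aphid_counts(s, aphid_taxa)
    prey_v <- prey_v[names(prey_v) %in% prey_taxa]
    pred_v <- s$pitfall[names(s$pitfall) %in% predator_taxa]
    cbind(unit, data.frame(
      predator_H = if (length(pred_v) && any(pred_v > 0))
        shannon_diversity(pred_v) else NA_real_,
      prey_H = if (length(prey_v) && any(prey_v > 0))
        shannon_diversity(prey_v) else NA_real_,
      predator_richness = sum(pred_v > 0),
      prey_richness = sum(prey_v > 0)), row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble the SES/diversity time series
#'
#' Joins the per-unit SES table and the per-unit diversity table on the full
#' five-part unit key and builds the per-session-by-treatment summary (mean,
#' standard error, n) that underlies the seasonal figures.
#'
#' @param ses Data.frame from [run_ses()].
#' @param diversity Data.frame from [diversity_table()].
#' @param design A `design_spec`.
#' @return List with `timeseries` (one row per unit) and `summary`
#'   (year x session x treatment means and SEs of ses_d, predator_H, prey_H).
#' @export
assemble_timeseries <- function(ses, diversity, design) {
  assert_unit_cols(ses, "ses"); assert_unit_cols(diversity, "diversity")
  sid <- unit_id(ses); did <- unit_id(diversity)
  orphans <- c(setdiff(sid, did), setdiff(did, sid))
  if (length(orphans))
    stop("SES/diversity unit mismatch: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ..." else "")
  ts <- merge(ses, diversity, by = unit_key_cols, sort = FALSE)
  ts <- ts[order(ts$year, ts$field, match(ts$treatment, design$treatments),
                 ts$plot, ts$session), , drop = FALSE]
  rownames(ts) <- NULL
  grp <- interaction(ts$year, ts$session, ts$treatment, drop = TRUE)
  summ <- do.call(rbind, lapply(split(ts, grp), function(g) {
    stat <- function(v) {
      v <- v[!is.na(v)]
      c(mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v))
    }
    s1 <- stat(g$ses_d); s2 <- stat(g$predator_H); s3 <- stat(g$prey_H)
    data.frame(year = g$year[1], session = g$session[1],
               treatment = g$treatment[1],
               ses_mean = s1[["mean"]], ses_se = s1[["se"]],
               ses_n = s1[["n"]],
               predator_H_mean = s2[["mean"]], predator_H_se = s2[["se"]],
               prey_H_mean = s3[["mean"]], prey_H_se = s3[["se"]],
               n_units = nrow(g), stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$year, match(summ$treatment, design$treatments),
                     summ$session), , drop = FALSE]
  rownames(summ) <- NULL
  list(timeseries = ts, summary = summ)
}
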