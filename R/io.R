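#' Read and validate an individual-level detection table
#'
#' One row per captured predator individual, with its sampling-unit
#' coordinates, species, and one 0/1 column per prey assay target. Every row
#' is validated against the design: labels must match exactly (case-sensitive,
#' no fuzzy matching), sessions must lie within the year's range, and
#' detection values must be 0 or 1.
#'
#' @param path CSV file with header columns `year, field, treatment, plot,
#'   session, predator_species` followed by one column per prey target.
#' @param design A `design_spec`.
#' @return A data.frame of detection records in file order.
#' @export
read_detections <- function(path, design) {
  stopifnot(inherits(design, "design_spec"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_detections(df, design)
}

#' Validate a detection table against a design
#'
#' @param df Data.frame shaped like the output of [read_detections()].
#' @inheritParams read_detections
#' @return The validated data.frame (columns coerced: session integer,
#'   detections integer, prey columns reordered to the design panel).
#' @export
validate_detections <- function(df, design) {
  need <- c(unit_key_cols, "predator_species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("detections missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(design$prey_targets, names(df))
  if (length(miss))
    stop("detections missing prey target column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, design$prey_targets))
  if (length(extra))
    stop("detections has unknown column(s): ", paste(extra, collapse = ", "))
  df$year <- as.character(df$year)
  df$session <- as.integer(df$session)
  row_err <- function(i, msg) stop("row ", i, ": ", msg, call. = FALSE)
  bad <- which(!df$year %in% design$years)
  if (length(bad))
    row_err(bad[1], paste0("unknown year '", df$year[bad[1]], "'"))
  bad <- which(!df$treatment %in% design$treatments)
  if (length(bad))
    row_err(bad[1], paste0("unknown treatment '", df$treatment[bad[1]], "'"))
  bad <- which(!df$predator_species %in% design$predator_species)
  if (length(bad))
    row_err(bad[1], paste0("unknown predator species '",
                           df$predator_species[bad[1]], "'"))
  bad <- which(!df$field %in% field_labels(design))
  if (length(bad))
    row_err(bad[1], paste0("unknown field '", df$field[bad[1]], "'"))
  bad <- which(!df$plot %in% plot_labels(design))
  if (length(bad))
    row_err(bad[1], paste0("unknown plot '", df$plot[bad[1]], "'"))
  smax <- design$sessions_per_year[df$year]
  bad <- which(is.na(df$session) | df$session < 1L | df$session > smax)
  if (length(bad))
    row_err(bad[1], paste0("session ", df$session[bad[1]],
                           " out of range for year ", df$year[bad[1]]))
  for (tg in design$prey_targets) {
    v <- df[[tg]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      row_err(bad[1], paste0("non-binary detection value '", v[bad[1]],
                             "' in column ", tg))
    df[[tg]] <- as.integer(v)
  }
  df[, c(unit_key_cols, "predator_species", design$prey_targets), drop = FALSE]
}

#' Read community count tables (wet pitfall traps and aphid tiller counts)
#'
#' Both files are long format: the five unit-key columns plus `taxon` and
#' `count`. Taxa absent from a unit are implicitly count 0; duplicated
#' (unit, taxon) rows and negative counts are errors.
#'
#' @param pitfall_path CSV of per-unit pitfall-trap counts.
#' @param tiller_path CSV of per-unit aphid counts summed over 30 collected
#'   barley tillers. May be `NULL` if no tiller survey exists.
#' @param design A `design_spec`.
#' @return An object of class `community_samples`: a list with long-format
#'   data.frames `pitfall` and `tillers`.
#' @export
read_community <- function(pitfall_path, tiller_path = NULL, design) {
  pit <- read_long_counts(pitfall_path, design, "pitfall")
  til <- if (is.null(tiller_path)) {
    empty_counts()
  } else {
    read_long_counts(tiller_path, design, "tillers")
  }
  community_samples(pit, til)
}

empty_counts <- function() {
  data.frame(year = character(0), field = character(0),
             treatment = character(0), plot = character(0),
             session = integer(0), taxon = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

read_long_counts <- function(path, design, what) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning(what, " file is empty: ", path)
    return(empty_counts())
  }
  need <- c(unit_key_cols, "taxon", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  df$year <- as.character(df$year)
  df$session <- as.integer(df$session)
  if (any(!df$year %in% design$years))
    stop(what, ": unknown year value")
  if (any(!df$treatment %in% design$treatments))
    stop(what, ": unknown treatment value")
  if (any(df$count < 0 | is.na(df$count)))
    stop(what, ": negative or missing count")
  key <- paste(unit_id(df), df$taxon)
  if (anyDuplicated(key))
    stop(what, ": duplicate (unit, taxon) rows, e.g. ", key[duplicated(key)][1])
  df$count <- as.numeric(df$count)
  df[, need, drop = FALSE]
}

#' Bundle pitfall and tiller count tables into one object
#'
#' @param pitfall,tillers Long-format data.frames with unit-key columns,
#'   `taxon` and `count`.
#' @return A `community_samples` object.
#' @export
community_samples <- function(pitfall, tillers = empty_counts()) {
  structure(list(pitfall = pitfall, tillers = tillers),
            class = "community_samples")
}

#' @export
print.community_samples <- function(x, ...) {
  cat("Community samples:", length(unique(unit_id(x$pitfall))),
      "units with pitfall counts,",
      length(unique(unit_id(x$tillers))), "with tiller counts\n")
  invisible(x)
}

#' Extract one unit's counts as named vectors
#'
#' @param cs A `community_samples` object.
#' @param unit One-row data.frame (or list) with the unit-key columns.
#' @return List with named numeric vectors `pitfall` and `tillers`.
#' @export
unit_sample <- function(cs, unit) {
  uid <- unit_id(as.data.frame(unit))
  pick <- function(df) {
    sub <- df[unit_id(df) == uid, , drop = FALSE]
    stats::setNames(sub$count, sub$taxon)
  }
  list(pitfall = pick(cs$pitfall), tillers = pick(cs$tillers))
}

#' Write a result table as CSV with stable numeric formatting
#'
#' Numeric columns are serialized with 10 significant digits so that tables
#' round-trip through the matching reader to within 1e-9 and identical runs
#' produce byte-identical files.
#'
#' @param df Data.frame (possibly zero rows, schema preserved).
#' @param path Output CSV path.
#' @export
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v)
        if (is.na(v)) "" else sprintf("%.10g", v), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' A YAML file declaring the design (years, fields, treatments, plots,
#' sessions, predator species, prey targets, self-detection map) and
#' optionally file paths and taxon lists. Any field omitted falls back to the
#' default study design, so a minimal config can override just the assay
#' panel.
#'
#' @param path YAML file.
#' @return List with elements `design` (a `design_spec`), `paths`,
#'   `prey_taxa`, `predator_taxa`, `aphid_taxa`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- default_design()
  dd <- cfg$design %||% list()
  years <- as.character(dd$years %||% d$years)
  spy <- dd$sessions_per_year %||% as.list(d$sessions_per_year)
  design <- design_spec(
    years = years,
    fields_per_year = dd$fields_per_year %||% d$fields_per_year,
    treatments = dd$treatments %||% d$treatments,
    plots_per_treatment = dd$plots_per_treatment %||% d$plots_per_treatment,
    sessions_per_year = stats::setNames(unlist(spy[years]), years),
    predator_species = dd$predator_species %||% d$predator_species,
    prey_targets = dd$prey_targets %||% d$prey_targets,
    self_detection_map = unlist(dd$self_detection_map) %||%
      d$self_detection_map)
  list(design = design,
       paths = cfg$paths %||% list(),
       prey_taxa = cfg$prey_taxa %||% default_prey_taxa(),
       predator_taxa = cfg$predator_taxa %||% default_predator_taxa(),
       aphid_taxa = cfg$aphid_taxa %||% default_aphid_taxa())
}
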