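#' Remove self-detections from a detection table
#'
#' A self-detection is a PCR positive for the consumer's own taxon assay
#' (e.g. a Poecilus gut testing positive for the Poecilus primer); these are
#' artifacts of screening predators with a panel that includes their own
#' taxon, and are removed by setting the positives to 0 before any averaging.
#' Species without an own assay target pass through untouched.
#'
#' @param records Detection data.frame (see [read_detections()]).
#' @param map Named character vector: predator species -> own prey target.
#' @return The cleaned data.frame, with attribute `n_flipped` giving the
#'   number of cells set to zero (also reported via `message()`).
#' @export
remove_self_detections <- function(records, map) {
  flipped <- 0L
  for (sp in intersect(names(map), unique(records$predator_species))) {
    tg <- map[[sp]]
    if (!tg %in% names(records))
      stop("self-detection target not a column: ", tg)
    rows <- records$predator_species == sp
    flipped <- flipped + sum(records[[tg]][rows] == 1L)
    records[[tg]][rows] <- 0L
  }
  message("remove_self_detections: ", flipped, " positive cell(s) set to 0")
  attr(records, "n_flipped") <- flipped
  records
}

new_interaction_web <- function(unit, mat, n_individuals) {
  structure(list(unit = unit, matrix = mat, n_individuals = n_individuals),
            class = "interaction_web")
}

#' @export
print.interaction_web <- function(x, ...) {
  cat("Interaction web for unit", unit_id(x$unit), "\n")
  cat(" ", nrow(x$matrix), "predator species x", ncol(x$matrix),
      "prey targets;", sum(x$n_individuals), "individuals\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Build one interaction web per sampling unit
#'
#' For every unit with at least one captured individual, the diet of each
#' predator species is averaged across all its individuals in that unit:
#' entry (s, t) is the proportion of individuals of species s in the unit
#' that tested positive for prey target t. Species captured in a unit appear
#' as rows even if all their detections are zero (they were captured and
#' screened); species with no captures are absent. The column set is always
#' the full prey panel. Records are expected to be self-detection-cleaned
#' (see [remove_self_detections()]).
#'
#' @param records Cleaned detection data.frame.
#' @param design A `design_spec`.
#' @return Named list (by unit id) of `interaction_web` objects; units with
#'   no records yield no web.
#' @export
build_webs <- function(records, design) {
  stopifnot(inherits(design, "design_spec"))
  if (nrow(records) == 0) return(list())
  uid <- unit_id(records)
  prey <- design$prey_targets
  webs <- list()
  for (u in unique(uid)) {
    sub <- records[uid == u, , drop = FALSE]
    sp <- factor(sub$predator_species,
                 levels = intersect(design$predator_species,
                                    unique(sub$predator_species)))
    det <- as.matrix(sub[, prey, drop = FALSE])
    n <- as.vector(table(sp))
    mat <- rowsum(det, sp) / n
    dimnames(mat) <- list(levels(sp), prey)
    webs[[u]] <- new_interaction_web(
      unit = sub[1, unit_key_cols, drop = FALSE],
      mat = mat,
      n_individuals = stats::setNames(n, levels(sp)))
  }
  webs
}

#' Marginal totals of an interaction web
#'
#' @param web An `interaction_web` or plain matrix.
#' @return List with `row_totals` (A_i), `col_totals` (A_j) and grand total
#'   `m`; the two marginal sums equal m to within 1e-12.
#' @export
web_marginals <- function(web) {
  mat <- if (inherits(web, "interaction_web")) web$matrix else as.matrix(web)
  list(row_totals = rowSums(mat), col_totals = colSums(mat), m = sum(mat))
}

#' Export webs as a long-format table
#'
#' @param webs List of `interaction_web` objects.
#' @return Data.frame with unit keys, predator_species, prey_target,
#'   proportion, n_individuals.
#' @export
webs_long <- function(webs) {
  out <- lapply(webs, function(w) {
    g <- expand.grid(predator_species = rownames(w$matrix),
                     prey_target = colnames(w$matrix),
                     stringsAsFactors = FALSE)
    cbind(w$unit[rep(1, nrow(g)), , drop = FALSE], g,
          proportion = as.vector(w$matrix),
          n_individuals = w$n_individuals[g$predator_species],
          row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
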