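#' Define a sampling design
#'
#' A design describes the replicated field layout of a season-wide gut-content
#' study: which years were sampled, how many fields per year, the fertilization
#' treatments applied to field halves, how many plots per treatment half, and
#' how many biweekly sampling sessions each year had. It also carries the
#' molecular assay panel: the predator species whose guts are screened, the
#' prey assay targets (one binary detection column each), and which target, if
#' any, constitutes a self-detection for each predator.
#'
#' @param years Character vector of year labels.
#' @param fields_per_year Integer, number of replicate fields per year.
#' @param treatments Character vector of distinct treatment labels, ordered.
#' @param plots_per_treatment Integer, plots within each treatment half.
#' @param sessions_per_year Named integer vector, one entry per year.
#' @param predator_species Character vector of predator taxa screened.
#' @param prey_targets Character vector of prey assay targets (columns of the
#'   detection table and of every interaction web).
#' @param self_detection_map Named character vector mapping a predator species
#'   to the prey target that is its own assay; species without an own assay
#'   are simply absent.
#'
#' @return An object of class `design_spec`.
#' @seealso [default_design()], [enumerate_units()]
#' @export
design_spec <- function(years, fields_per_year, treatments, plots_per_treatment,
                        sessions_per_year, predator_species, prey_targets,
                        self_detection_map = character(0)) {
  years <- as.character(years)
  sessions_per_year <- stats::setNames(as.integer(sessions_per_year),
                                       names(sessions_per_year))
  if (!setequal(names(sessions_per_year), years))
    stop("sessions_per_year must be named by year and cover exactly `years`")
  if (fields_per_year < 1L || plots_per_treatment < 1L ||
      any(sessions_per_year < 1L))
    stop("all design cardinalities must be >= 1")
  if (anyDuplicated(treatments))
    stop("treatment labels must be distinct")
  if (anyDuplicated(prey_targets) || anyDuplicated(predator_species))
    stop("predator and prey labels must be distinct")
  if (length(self_detection_map)) {
    bad <- setdiff(names(self_detection_map), predator_species)
    if (length(bad))
      stop("self_detection_map names unknown predator species: ",
           paste(bad, collapse = ", "))
    bad <- setdiff(self_detection_map, prey_targets)
    if (length(bad))
      stop("self_detection_map points at unknown prey targets: ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(years = years,
         fields_per_year = as.integer(fields_per_year),
         treatments = as.character(treatments),
         plots_per_treatment = as.integer(plots_per_treatment),
         sessions_per_year = sessions_per_year,
         predator_species = as.character(predator_species),
         prey_targets = as.character(prey_targets),
         self_detection_map = self_detection_map),
    class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Sampling design:", length(x$years), "year(s)\n")
  for (y in x$years)
    cat(sprintf("  %s: %d fields x %d treatments x %d plots x %d sessions = %d units\n",
                y, x$fields_per_year, length(x$treatments),
                x$plots_per_treatment, x$sessions_per_year[[y]],
                x$fields_per_year * length(x$treatments) *
                  x$plots_per_treatment * x$sessions_per_year[[y]]))
  cat(" ", length(x$predator_species), "predator species,",
      length(x$prey_targets), "prey assay targets,",
      length(x$self_detection_map), "self-detection mappings\n")
  invisible(x)
}

#' The default two-year barley study design
#'
#' Mirrors the published layout: 3 fields per year, two treatment halves
#' (manure-fertilized vs unfertilized), 4 plots of 5 x 5 m per half, and 7
#' biweekly sessions in 2020 versus 6 in 2021. The assay panel combines the
#' multi-prey assay (aphids, springtails, earthworms, slugs, the cereal leaf
#' beetle), the intraguild assay (spiders, ladybeetles) and the beetle-genus
#' assay (Bembidion, Harpalus, Poecilus, Pterostichus, Philonthus carbonarius,
#' Philonthus cognatus). Each screened beetle genus and the spiders map to
#' their own assay target for self-detection removal.
#'
#' @return A `design_spec`.
#' @export
default_design <- function() {
  beetles <- c("Bembidion", "Harpalus", "Poecilus", "Pterostichus",
               "Philonthus_carbonarius", "Philonthus_cognatus")
  prey <- c("Rhopalosiphum_padi", "Sitobion_avenae", "Metopolophium_dirhodum",
            "Collembola", "Oligochaeta", "Gastropoda", "Oulema_melanopus",
            "Araneae", "Coccinellidae", beetles)
  predators <- c(beetles, "Araneae")
  design_spec(
    years = c("2020", "2021"),
    fields_per_year = 3L,
    treatments = c("fertilized", "unfertilized"),
    plots_per_treatment = 4L,
    sessions_per_year = c("2020" = 7L, "2021" = 6L),
    predator_species = predators,
    prey_targets = prey,
    self_detection_map = stats::setNames(predators, predators))
}

#' Aphid taxa of the default assay/community panel
#' @return Character vector of aphid taxon labels.
#' @export
default_aphid_taxa <- function() {
  c("Rhopalosiphum_padi", "Sitobion_avenae", "Metopolophium_dirhodum")
}

#' Prey taxa entering the prey-community diversity calculation
#'
#' Springtails, earthworms, gastropods, the three cereal aphids and the
#' cereal leaf beetle.
#' @return Character vector of taxon labels.
#' @export
default_prey_taxa <- function() {
  c("Collembola", "Oligochaeta", "Gastropoda", default_aphid_taxa(),
    "Oulema_melanopus")
}

#' Predator taxa entering the predator-community diversity calculation
#' @return Character vector of taxon labels.
#' @export
default_predator_taxa <- function() {
  c("Bembidion", "Harpalus", "Poecilus", "Pterostichus",
    "Philonthus_carbonarius", "Philonthus_cognatus", "Araneae")
}

field_labels <- function(design) paste0("F", seq_len(design$fields_per_year))
plot_labels  <- function(design) paste0("P", seq_len(design$plots_per_treatment))

unit_key_cols <- c("year", "field", "treatment", "plot", "session")

#' Enumerate all sampling units of one year
#'
#' A sampling unit is one plot within one treatment half of one field at one
#' session: the grain at which webs, SES and diversity are computed.
#'
#' @param design A `design_spec`.
#' @param year Year label present in the design.
#' @return A data.frame with columns year, field, treatment, plot, session, in
#'   deterministic lexicographic order (field, treatment, plot, session).
#' @examples
#' nrow(enumerate_units(default_design(), "2020"))  # 168
#' @export
enumerate_units <- function(design, year) {
  stopifnot(inherits(design, "design_spec"))
  year <- as.character(year)
  if (!year %in% design$years)
    stop("unknown year: ", year)
  g <- expand.grid(session = seq_len(design$sessions_per_year[[year]]),
                   plot = plot_labels(design),
                   treatment = design$treatments,
                   field = field_labels(design),
                   stringsAsFactors = FALSE)
  out <- data.frame(year = year, field = g$field, treatment = g$treatment,
                    plot = g$plot, session = as.integer(g$session),
                    stringsAsFactors = FALSE)
  out[order(out$field, match(out$treatment, design$treatments),
            out$plot, out$session), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Unit identifier strings
#'
#' Collapses the five unit-key columns into a single `:`-separated id used for
#' joins and per-unit random seeds.
#'
#' @param units Data.frame containing the unit-key columns.
#' @return Character vector of ids.
#' @export
unit_id <- function(units) {
  paste(units$year, units$field, units$treatment, units$plot, units$session,
        sep = ":")
}
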