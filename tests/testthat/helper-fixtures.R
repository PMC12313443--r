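# Shared fixtures: small designs and hand-built detection tables.

ukc <- c("year", "field", "treatment", "plot", "session")

# A compact design with the full intraguild panel (beetle self-targets).
tiny_design <- function(sessions = 2L, fields = 1L, plots = 1L) {
  design_spec(
    years = "Y1",
    fields_per_year = fields,
    treatments = c("fertilized", "unfertilized"),
    plots_per_treatment = plots,
    sessions_per_year = c(Y1 = sessions),
    predator_species = c("Poecilus", "Harpalus", "Araneae"),
    prey_targets = c("Collembola", "Oligochaeta", "Aphid",
                     "Poecilus", "Harpalus", "Araneae"),
    self_detection_map = c(Poecilus = "Poecilus", Harpalus = "Harpalus",
                           Araneae = "Araneae"))
}

# A design with no intraguild columns: species can share one preference
# vector exactly, so there is no species-by-prey association at all.
no_association_design <- function(fields = 3L, sessions = 7L) {
  design_spec(
    years = "Y1",
    fields_per_year = fields,
    treatments = c("fertilized", "unfertilized"),
    plots_per_treatment = 4L,
    sessions_per_year = c(Y1 = sessions),
    predator_species = default_predator_taxa(),
    prey_targets = c("Rhopalosiphum_padi", "Sitobion_avenae",
                     "Metopolophium_dirhodum", "Collembola", "Oligochaeta",
                     "Gastropoda", "Oulema_melanopus"))
}

# Build a detection data.frame from a species vector and a 0/1 matrix whose
# columns are the design's prey panel.
make_detections <- function(design, species, det, year = design$years[1],
                            field = "F1", treatment = design$treatments[1],
                            plot = "P1", session = 1L) {
  det <- matrix(det, nrow = length(species),
                dimnames = list(NULL, design$prey_targets))
  cbind(data.frame(year = year, field = field, treatment = treatment,
                   plot = plot, session = as.integer(session),
                   predator_species = species, stringsAsFactors = FALSE),
        as.data.frame(det))
}

clean_quietly <- function(records, design) {
  suppressMessages(remove_self_detections(records, design$self_detection_map))
}
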