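#' dietwebs: season-wide food-web specialization from gut-content detections
#'
#' Pipeline stages: validate inputs against the sampling design
#' ([read_detections()], [read_community()]), remove self-detections
#' ([remove_self_detections()]), average individual diets into per-unit
#' interaction webs ([build_webs()]), compute network-level specialization
#' H2' ([h2_prime()]), compare against a diet-recombination null via a
#' Cohen's-d standardized effect size ([run_ses()]), compute
#' predator/prey Shannon diversity with the aphid tiller substitution
#' ([diversity_table()]), and assemble the seasonal time series
#' ([assemble_timeseries()]). A synthetic generator
#' ([simulate_dataset()]) emulates the two-year field design with a
#' controllable seasonal specialization profile.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full analysis on a dataset
#'
#' Convenience wrapper chaining self-detection removal, web building,
#' specialization, the null-model SES and the diversity report.
#'
#' @param detections Detection data.frame (raw; self-detections are removed
#'   here).
#' @param community A `community_samples` object.
#' @param design A `design_spec`.
#' @param config A `null_config`.
#' @param prey_taxa,predator_taxa,aphid_taxa Taxon lists for the diversity
#'   module.
#' @return List with `webs`, `specialization`, `ses`, `diversity`,
#'   `timeseries`, `summary`.
#' @export
run_pipeline <- function(detections, community, design,
                         config = null_config(),
                         prey_taxa = default_prey_taxa(),
                         predator_taxa = default_predator_taxa(),
                         aphid_taxa = default_aphid_taxa()) {
  cleaned <- suppressMessages(
    remove_self_detections(detections, design$self_detection_map))
  webs <- build_webs(cleaned, design)
  spec <- specialization_table(webs)
  ses <- run_ses(cleaned, design, config)
  div <- diversity_table(community, prey_taxa, predator_taxa, aphid_taxa)
  # diversity exists for every designed unit; SES only where predators were
  # caught — align on the SES units for the joined series
  div_use <- div[unit_id(div) %in% unit_id(ses), , drop = FALSE]
  ses_use <- ses[unit_id(ses) %in% unit_id(div_use), , drop = FALSE]
  asm <- assemble_timeseries(ses_use, div_use, design)
  list(webs = webs, specialization = spec, ses = ses, diversity = div,
       timeseries = asm$timeseries, summary = asm$summary)
}
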