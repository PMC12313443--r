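#' Parameters of the synthetic gut-content study generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: predator individuals are captured per species and unit with
#' Poisson-distributed effort, each species holds a session-specific diet
#' preference vector drawn from a Dirichlet distribution whose concentration
#' controls specialization, individual guts contain a Poisson number of
#' distinct prey detections sampled by preference, and community counts are
#' negative-binomial around a seasonal profile.
#'
#' The Dirichlet concentration is the specialization dial: the preference
#' vector for species s at session t is Dirichlet(kappa_t * w), where w is
#' the normalized prey availability. Small kappa concentrates each species'
#' diet on few (randomly different) prey, producing specialized webs; large
#' kappa pins every species to the availability vector, producing generalized
#' webs. The default `kappa_by_session` follows the U-shaped seasonal profile
#' (specialized early and late, generalized mid-season); for years with fewer
#' sessions the leading entries are used.
#'
#' @param design A `design_spec`.
#' @param individuals_per_species_per_unit Mean of the Poisson capture count
#'   per species and unit. Default 3, matching the order of magnitude of the
#'   field captures (roughly 3900 predators over 168 units and 7 taxa in the
#'   first study year).
#' @param kappa_by_session Positive Dirichlet concentrations, one per session
#'   (recycled/truncated to each year's session count).
#' @param base_prey_availability Named positive weights over the prey panel.
#'   Default: equal weights.
#' @param detections_per_individual Expected number of positive prey targets
#'   per predator gut. Each target is positive independently with probability
#'   min(detections_per_individual x preference, 1), i.e. a Bernoulli
#'   thinning of a Poisson feeding process, so the expected count equals this
#'   mean whenever no single preference exceeds 1/mean. Default 2.
#' @param treatment_availability_multiplier Named positive multipliers applied
#'   to detritivore prey weights per treatment; models manure increasing
#'   detritivore availability. Default: fertilized 1.5, unfertilized 1.
#' @param detritivore_taxa Prey targets treated as detritivores.
#' @param community_abundance_profile List with `pitfall_means` (named
#'   per-taxon baseline mean counts), `tiller_aphid_means` (named, aphids),
#'   `seasonal_shape` (per-session multiplier, humped by default) and
#'   `dispersion` (negative-binomial size). `NULL` for defaults.
#' @param shared_preferences If `TRUE`, every species' preference vector is
#'   the normalized availability itself (no Dirichlet draw): a community with
#'   no species-by-prey association, used for null calibration.
#' @param inject_self_detections If `TRUE`, self-detection targets can be
#'   drawn like any other prey (to exercise the cleaner); by default the
#'   generator models post-cleaning data and never emits them.
#' @param seed Integer master seed; the full dataset is a pure function of
#'   the parameter object.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(design = default_design(),
                             individuals_per_species_per_unit = 3,
                             kappa_by_session = c(0.1, 0.3, 1, 3, 1, 0.3, 0.1),
                             base_prey_availability = NULL,
                             detections_per_individual = 2,
                             treatment_availability_multiplier = NULL,
                             detritivore_taxa = c("Collembola", "Oligochaeta"),
                             community_abundance_profile = NULL,
                             shared_preferences = FALSE,
                             inject_self_detections = FALSE,
                             seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  if (any(kappa_by_session <= 0)) stop("kappa must be > 0")
  if (individuals_per_species_per_unit < 0 || detections_per_individual < 0)
    stop("means must be >= 0")
  if (is.null(base_prey_availability))
    base_prey_availability <- stats::setNames(
      rep(1, length(design$prey_targets)), design$prey_targets)
  if (!setequal(names(base_prey_availability), design$prey_targets))
    stop("base_prey_availability must be named by the full prey panel")
  if (any(base_prey_availability <= 0)) stop("availability weights must be > 0")
  if (is.null(treatment_availability_multiplier))
    treatment_availability_multiplier <- stats::setNames(
      c(1.5, rep(1, length(design$treatments) - 1L)), design$treatments)
  if (any(treatment_availability_multiplier <= 0))
    stop("treatment multipliers must be > 0")
  if (is.null(community_abundance_profile))
    community_abundance_profile <- default_community_profile(design)
  structure(
    list(design = design,
         individuals_per_species_per_unit = individuals_per_species_per_unit,
         kappa_by_session = kappa_by_session,
         base_prey_availability =
           base_prey_availability[design$prey_targets],
         detections_per_individual = detections_per_individual,
         treatment_availability_multiplier = treatment_availability_multiplier,
         detritivore_taxa = detritivore_taxa,
         community_abundance_profile = community_abundance_profile,
         shared_preferences = isTRUE(shared_preferences),
         inject_self_detections = isTRUE(inject_self_detections),
         seed = as.integer(seed)),
    class = "synthetic_params")
}

#' Default community abundance profile
#'
#' Baseline mean pitfall counts per taxon, a humped seasonal multiplier
#' (abundance low at tillering, peaking mid-season, declining at ripening)
#' and moderate negative-binomial overdispersion. Aphid tiller counts get
#' their own, larger, means since 30 tillers typically hold far more aphids
#' than a pitfall trap catches.
#'
#' @param design A `design_spec`.
#' @return List with `pitfall_means`, `tiller_aphid_means`, `seasonal_shape`,
#'   `dispersion`.
#' @export
default_community_profile <- function(design) {
  taxa <- union(default_prey_taxa(), default_predator_taxa())
  means <- stats::setNames(rep(8, length(taxa)), taxa)
  means[default_aphid_taxa()] <- 4          # aphids under-sampled by pitfalls
  list(pitfall_means = means,
       tiller_aphid_means = stats::setNames(
         c(40, 25, 10), default_aphid_taxa()),
       seasonal_shape = c(0.4, 0.7, 1.0, 1.3, 1.0, 0.7, 0.4),
       dispersion = 2)
}

kappa_at <- function(params, session) {
  k <- params$kappa_by_session
  k[((session - 1L) %% length(k)) + 1L]
}

shape_at <- function(profile, session) {
  s <- profile$seasonal_shape
  s[((session - 1L) %% length(s)) + 1L]
}

availability_weights <- function(params, treatment) {
  w <- params$base_prey_availability
  mult <- params$treatment_availability_multiplier[[treatment]]
  dets <- intersect(params$detritivore_taxa, names(w))
  w[dets] <- w[dets] * mult
  w / sum(w)
}

# Dirichlet draw via gamma normalization; guarded against total underflow at
# very small concentrations (then all mass goes to one weight-sampled target).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) {
    g <- numeric(length(alpha))
    g[sample.int(length(alpha), 1L, prob = alpha)] <- 1
    return(g)
  }
  g / s
}

#' Draw one species' diet preference vector
#'
#' Deterministic in (seed, unit, species, session): the RNG stream is seeded
#' from a stable hash of those coordinates, so repeated calls reproduce the
#' same vector regardless of call order.
#'
#' @param params A `synthetic_params`.
#' @param species Predator species label.
#' @param session Session index.
#' @param unit One-row data.frame with unit-key columns (its treatment sets
#'   the availability adjustment). `NULL` gives an unadjusted draw keyed only
#'   by (species, session).
#' @return Probability vector over the prey panel, summing to 1.
#' @export
simulate_species_preferences <- function(params, species, session, unit = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  kap <- kappa_at(params, session)
  if (kap <= 0) stop("kappa must be > 0")
  treatment <- if (is.null(unit)) params$design$treatments[1] else unit$treatment
  w <- availability_weights(params, treatment)
  if (params$shared_preferences) return(w)
  ukey <- if (is.null(unit)) "global" else unit_id(unit)
  withr::with_seed(
    stable_hash(params$seed, "pref", ukey, species, session),
    rdirichlet1(kap * w))
}

#' Simulate an individual-level detection table
#'
#' For each sampling unit and predator species, draws a Poisson number of
#' captured individuals; each individual's gut is positive for each prey
#' target independently, with probability proportional to the species'
#' unit/session preference (scaled so the expected number of positives per
#' gut is `detections_per_individual`). Self-detection targets are excluded
#' from sampling unless `inject_self_detections` is set, i.e. the default
#' output models post-cleaning data.
#'
#' @param params A `synthetic_params`.
#' @return Detection data.frame with unit keys, predator_species and one 0/1
#'   column per prey target.
#' @export
simulate_detections <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  design <- params$design
  prey <- design$prey_targets
  empty <- cbind(empty_counts()[, unit_key_cols, drop = FALSE],
                 data.frame(predator_species = character(0),
                            stringsAsFactors = FALSE),
                 stats::setNames(as.data.frame(
                   matrix(integer(0), 0, length(prey))), prey))
  if (params$individuals_per_species_per_unit == 0) return(empty)
  rows <- list()
  for (year in design$years) {
    units <- enumerate_units(design, year)
    for (u in seq_len(nrow(units))) {
      unit <- units[u, , drop = FALSE]
      for (sp in design$predator_species) {
        n <- withr::with_seed(
          stable_hash(params$seed, "ncap", unit_id(unit), sp),
          stats::rpois(1L, params$individuals_per_species_per_unit))
        if (n == 0L) next
        pref <- simulate_species_preferences(params, sp, unit$session, unit)
        avail <- rep(TRUE, length(prey))
        if (!params$inject_self_detections && sp %in%
            names(design$self_detection_map))
          avail[match(design$self_detection_map[[sp]], prey)] <- FALSE
        p <- pref[avail]
        if (sum(p) <= 0) p <- rep(1, sum(avail))
        p_gut <- pmin(params$detections_per_individual * p / sum(p), 1)
        det <- withr::with_seed(
          stable_hash(params$seed, "guts", unit_id(unit), sp),
          {
            m <- matrix(0L, n, length(prey))
            m[, avail] <- (matrix(stats::runif(n * length(p_gut)), n) <
                             rep(p_gut, each = n)) + 0L
            m
          })
        colnames(det) <- prey
        rows[[length(rows) + 1L]] <- cbind(
          unit[rep(1, n), , drop = FALSE],
          data.frame(predator_species = sp, stringsAsFactors = FALSE),
          as.data.frame(det), row.names = NULL)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate community count tables
#'
#' Per-unit taxon counts are negative-binomial around the seasonal profile
#' (baseline mean x seasonal shape, with the treatment multiplier applied to
#' detritivore taxa); aphid tiller counts are generated separately from the
#' pitfall counts with their own means.
#'
#' @param params A `synthetic_params`.
#' @return A `community_samples` object.
#' @export
simulate_community <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  design <- params$design
  prof <- params$community_abundance_profile
  pit_rows <- list(); til_rows <- list()
  rnb <- function(mu, size) {
    if (mu <= 0) return(0)
    stats::rnbinom(1L, mu = mu, size = size)
  }
  for (year in design$years) {
    units <- enumerate_units(design, year)
    for (u in seq_len(nrow(units))) {
      unit <- units[u, , drop = FALSE]
      sh <- shape_at(prof, unit$session)
      mult <- params$treatment_availability_multiplier[[unit$treatment]]
      counts <- withr::with_seed(
        stable_hash(params$seed, "pitfall", unit_id(unit)),
        vapply(names(prof$pitfall_means), function(tx) {
          mu <- prof$pitfall_means[[tx]] * sh *
            if (tx %in% params$detritivore_taxa) mult else 1
          rnb(mu, prof$dispersion)
        }, numeric(1)))
      pit_rows[[length(pit_rows) + 1L]] <- cbind(
        unit[rep(1, length(counts)), , drop = FALSE],
        data.frame(taxon = names(counts), count = unname(counts),
                   stringsAsFactors = FALSE), row.names = NULL)
      tcounts <- withr::with_seed(
        stable_hash(params$seed, "tillers", unit_id(unit)),
        vapply(names(prof$tiller_aphid_means), function(tx)
          rnb(prof$tiller_aphid_means[[tx]] * sh, prof$dispersion),
          numeric(1)))
      til_rows[[length(til_rows) + 1L]] <- cbind(
        unit[rep(1, length(tcounts)), , drop = FALSE],
        data.frame(taxon = names(tcounts), count = unname(tcounts),
                   stringsAsFactors = FALSE), row.names = NULL)
    }
  }
  pit <- do.call(rbind, pit_rows); rownames(pit) <- NULL
  til <- do.call(rbind, til_rows); rownames(til) <- NULL
  community_samples(pit, til)
}

#' Simulate a complete dataset (detections + community counts)
#'
#' @param params A `synthetic_params`.
#' @return List with `detections` (data.frame) and `community`
#'   (`community_samples`).
#' @export
simulate_dataset <- function(params) {
  list(detections = simulate_detections(params),
       community = simulate_community(params))
}
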