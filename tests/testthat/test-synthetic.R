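test_that("preference draws hit the Dirichlet concentration limits", {
  set.seed(1)
  d <- tiny_design()
  unit <- enumerate_units(d, "Y1")[1, ]
  # large concentration: preferences pin to the availability weights
  dev <- replicate(100, {
    pars <- synthetic_params(design = d, seed = sample.int(1e6, 1),
                             kappa_by_session = rep(1e6, 2))
    w <- synthetic_params(design = d, shared_preferences = TRUE,
                          kappa_by_session = rep(1e6, 2))
    max(abs(simulate_species_preferences(pars, "Poecilus", 1, unit) -
              simulate_species_preferences(w, "Poecilus", 1, unit)))
  })
  expect_lt(mean(dev), 0.01)
  # small concentration: a single target carries nearly all mass
  conc <- replicate(100, {
    pars <- synthetic_params(design = d, seed = sample.int(1e6, 1),
                             kappa_by_session = rep(0.01, 2))
    max(simulate_species_preferences(pars, "Poecilus", 1, unit))
  })
  expect_gt(mean(conc > 0.95), 0.9)
})

test_that("preference draws are deterministic in (seed, species, session, unit)", {
  d <- tiny_design()
  pars <- synthetic_params(design = d, seed = 42)
  u <- enumerate_units(d, "Y1")
  a <- simulate_species_preferences(pars, "Harpalus", 2, u[1, ])
  b <- simulate_species_preferences(pars, "Harpalus", 2, u[1, ])
  expect_identical(a, b)
  expect_equal(sum(a), 1)
  # different coordinates give different draws
  expect_false(identical(a, simulate_species_preferences(pars, "Poecilus", 2, u[1, ])))
  expect_false(identical(a, simulate_species_preferences(pars, "Harpalus", 1, u[1, ])))
  expect_error(
    synthetic_params(design = d, kappa_by_session = c(0, 1)), "kappa")
})

test_that("zero capture effort yields an empty, correctly shaped table", {
  d <- tiny_design()
  det <- simulate_detections(
    synthetic_params(design = d, individuals_per_species_per_unit = 0))
  expect_equal(nrow(det), 0L)
  expect_true(all(d$prey_targets %in% names(det)))
})

test_that("realized detections per gut match the configured mean", {
  d <- no_association_design(fields = 3L, sessions = 7L)
  # even preferences, so no single target's thinning probability caps at 1
  pars <- synthetic_params(design = d, seed = 11,
                           individuals_per_species_per_unit = 10,
                           detections_per_individual = 2,
                           shared_preferences = TRUE,
                           treatment_availability_multiplier =
                             c(fertilized = 1, unfertilized = 1))
  det <- simulate_detections(pars)
  expect_gt(nrow(det), 10000)
  pos <- rowSums(det[, d$prey_targets])
  se <- stats::sd(pos) / sqrt(length(pos))
  expect_lt(abs(mean(pos) - 2), 2 * se + 1e-12)
})

test_that("a full study-design year spans exactly its 168 designed units", {
  d <- default_design()
  pars <- synthetic_params(seed = 5)
  det <- simulate_detections(pars)
  det20 <- det[det$year == "2020", ]
  expect_equal(sort(unique(unit_id(det20))),
               sort(unit_id(enumerate_units(d, "2020"))))
  expect_equal(length(unique(unit_id(det20))), 168L)
})

test_that("the generator never emits self-detections unless asked to", {
  d <- tiny_design()
  pars <- synthetic_params(design = d, seed = 8,
                           individuals_per_species_per_unit = 20)
  det <- simulate_detections(pars)
  for (sp in names(d$self_detection_map))
    expect_equal(sum(det[det$predator_species == sp,
                         d$self_detection_map[[sp]]]), 0L)
  inj <- simulate_detections(
    synthetic_params(design = d, seed = 8,
                     individuals_per_species_per_unit = 20,
                     inject_self_detections = TRUE))
  self_pos <- sum(vapply(names(d$self_detection_map), function(sp)
    sum(inj[inj$predator_species == sp, d$self_detection_map[[sp]]]),
    numeric(1)))
  expect_gt(self_pos, 0)
})

test_that("the full synthetic dataset is a pure function of its parameters", {
  d <- tiny_design()
  pars <- synthetic_params(design = d, seed = 99)
  ds1 <- simulate_dataset(pars)
  ds2 <- simulate_dataset(pars)
  expect_identical(ds1$detections, ds2$detections)
  expect_identical(ds1$community$pitfall, ds2$community$pitfall)
  expect_identical(ds1$community$tillers, ds2$community$tillers)
  ds3 <- simulate_dataset(synthetic_params(design = d, seed = 100))
  expect_false(identical(ds1$detections, ds3$detections))
})

test_that("community counts follow the profile: uniform limit and structural zeros", {
  taxa <- paste0("t", 1:6)
  d <- design_spec("Y", 2, c("a", "b"), 2, c(Y = 2),
                   predator_species = "sp", prey_targets = c("x", "y"))
  prof <- list(pitfall_means = stats::setNames(rep(10000, 6), taxa),
               tiller_aphid_means = c(none = 0),
               seasonal_shape = c(1, 1), dispersion = 1e6)
  pars <- synthetic_params(design = d, seed = 21,
                           community_abundance_profile = prof,
                           detritivore_taxa = character(0))
  cs <- simulate_community(pars)
  H <- vapply(split(cs$pitfall, unit_id(cs$pitfall)),
              function(g) shannon_diversity(stats::setNames(g$count, g$taxon)),
              numeric(1))
  expect_true(all(abs(H - log(6)) < 0.05))
  # a zero-mean taxon never appears with a positive count
  prof$pitfall_means[["t3"]] <- 0
  cs0 <- simulate_community(
    synthetic_params(design = d, seed = 21,
                     community_abundance_profile = prof,
                     detritivore_taxa = character(0)))
  expect_true(all(cs0$pitfall$count[cs0$pitfall$taxon == "t3"] == 0))
})

test_that("smaller preference concentration yields more specialized webs", {
  d <- tiny_design(sessions = 1L, fields = 2L, plots = 2L)
  mean_h2p <- sapply(c(0.05, 0.5, 5), function(kap) {
    reps <- sapply(1:10, function(r) {
      pars <- synthetic_params(design = d, seed = 1000 * r,
                               kappa_by_session = kap,
                               individuals_per_species_per_unit = 6)
      det <- clean_quietly(simulate_detections(pars), d)
      st <- specialization_table(build_webs(det, d))
      mean(st$H2prime[st$valid])
    })
    mean(reps)
  })
  expect_true(all(diff(mean_h2p) < 0))
})
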