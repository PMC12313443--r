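test_that("prey-label shuffling conserves column totals and row structure", {
  # a panel without self-detection columns: the permutation's conservation
  # laws are exact (with self columns the post-shuffle re-zeroing may remove
  # cells that land on a species' own target)
  d <- no_association_design(fields = 2L, sessions = 2L)
  det <- simulate_detections(synthetic_params(design = d, seed = 19))
  cfg <- null_config(strategy = "prey_label_shuffle", seed = 2)
  set.seed(cfg$seed)
  sh <- shuffle_detections(det, cfg, d)
  expect_equal(colSums(sh[, d$prey_targets]), colSums(det[, d$prey_targets]))
  expect_identical(sh$predator_species, det$predator_species)
  expect_identical(unit_id(sh), unit_id(det))
  # with self columns present, cleaned totals can only shrink
  ds <- tiny_design(sessions = 2L, fields = 2L, plots = 2L)
  dets <- clean_quietly(
    simulate_detections(synthetic_params(design = ds, seed = 19)), ds)
  set.seed(2)
  shs <- shuffle_detections(dets, cfg, ds)
  expect_true(all(colSums(shs[, ds$prey_targets]) <=
                    colSums(dets[, ds$prey_targets])))
})

test_that("cell shuffling conserves the grand total of detections", {
  d <- tiny_design(sessions = 2L, fields = 2L, plots = 2L)
  det <- clean_quietly(
    simulate_detections(synthetic_params(design = d, seed = 23)), d)
  cfg <- null_config(strategy = "cell_shuffle", seed = 2)
  set.seed(cfg$seed)
  sh <- shuffle_detections(det, cfg, d)
  # self cells are re-zeroed after the shuffle, so the total can only drop
  # by the number of cells that landed on a self target
  expect_lte(sum(sh[, d$prey_targets]), sum(det[, d$prey_targets]))
  noself <- no_association_design(fields = 1L, sessions = 2L)
  det2 <- simulate_detections(synthetic_params(design = noself, seed = 23))
  set.seed(2)
  sh2 <- shuffle_detections(det2, cfg, noself)
  expect_equal(sum(sh2[, noself$prey_targets]),
               sum(det2[, noself$prey_targets]))
})

test_that("shuffling a dataset of identical diet vectors changes no web", {
  d <- no_association_design(fields = 1L, sessions = 2L)
  units <- enumerate_units(d, "Y1")
  det <- do.call(rbind, lapply(seq_len(nrow(units)), function(i)
    make_detections(d, c("Poecilus", "Harpalus"),
                    rbind(c(1, 0, 1, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0, 0)),
                    field = units$field[i], treatment = units$treatment[i],
                    plot = units$plot[i], session = units$session[i])))
  webs0 <- build_webs(det, d)
  # holds for the label-preserving strategies; cell_shuffle pools all cells
  # jointly and so can move mass between prey columns even here
  for (strat in c("prey_label_shuffle", "within_unit_shuffle")) {
    set.seed(1)
    sh <- shuffle_detections(det, null_config(strategy = strat, seed = 1), d)
    webs1 <- build_webs(sh, d)
    for (u in names(webs0))
      expect_equal(webs1[[u]]$matrix, webs0[[u]]$matrix)
  }
})

test_that("Cohen's-d SES matches its closed form and sign convention", {
  draws <- c(0.2, 0.3, 0.4, 0.5)
  r <- cohens_d_ses(mean(draws), draws)
  expect_equal(r$ses_d, 0)
  r <- cohens_d_ses(mean(draws) + 2 * sd(draws), draws)
  expect_equal(r$ses_d, 2)
  expect_equal(r$n_null_valid, 4L)
  r <- cohens_d_ses(0.5, rep(0.3, 5))
  expect_true(is.na(r$ses_d))
  expect_equal(r$flag, "sd_zero")
  expect_error(cohens_d_ses(0.5, 0.3), "at least 2")
})

test_that("null distributions are reproducible and degenerate units excluded", {
  d <- tiny_design(sessions = 1L, fields = 2L, plots = 2L)
  det <- clean_quietly(
    simulate_detections(synthetic_params(design = d, seed = 41,
                                         individuals_per_species_per_unit = 4)), d)
  unit <- det[1, ukc]
  cfg <- null_config(n_randomizations = 25L, seed = 7)
  nd1 <- null_distribution(det, d, unit, cfg)
  nd2 <- null_distribution(det, d, unit, cfg)
  expect_identical(nd1, nd2)
  expect_true(all(nd1 >= 0 & nd1 <= 1))
  # a unit holding a single captured species gives only degenerate webs
  solo <- make_detections(d, "Poecilus", matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 1),
                          field = "F2", treatment = "unfertilized")
  both <- rbind(det[det$field == "F1", ], solo)
  expect_error(
    null_distribution(both, d, solo[1, ukc],
                      null_config(n_randomizations = 10L, scope = "unit",
                                  strategy = "within_unit_shuffle", seed = 1)),
    "degenerate")
})

test_that("run_ses output is independent of unit processing order and repeatable", {
  d <- tiny_design(sessions = 2L, fields = 2L, plots = 1L)
  det <- clean_quietly(
    simulate_detections(synthetic_params(design = d, seed = 55)), d)
  cfg <- null_config(n_randomizations = 49L, min_valid = 10L, seed = 3)
  ses1 <- run_ses(det, d, cfg)
  ses2 <- run_ses(det[rev(seq_len(nrow(det))), ], d, cfg)
  a <- ses2[order(unit_id(ses2)), ]; rownames(a) <- NULL
  b <- ses1[order(unit_id(ses1)), ]; rownames(b) <- NULL
  expect_equal(a, b)
  # byte-identical CSV on repeat runs
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_table(ses1, p1)
  write_table(run_ses(det, d, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_warning(empty <- run_ses(det[0, ], d, cfg), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("null distribution covers the observed H2' on association-free data", {
  d <- no_association_design(fields = 2L, sessions = 2L)
  pars <- synthetic_params(design = d, seed = 61, shared_preferences = TRUE,
                           individuals_per_species_per_unit = 3,
                           treatment_availability_multiplier =
                             c(fertilized = 1, unfertilized = 1))
  det <- simulate_detections(pars)
  webs <- build_webs(det, d)
  obs <- specialization_table(webs)
  obs <- obs[obs$valid, ]
  cfg <- null_config(n_randomizations = 199L, seed = 9)
  inside <- vapply(seq_len(nrow(obs)), function(i) {
    nd <- null_distribution(det, d, obs[i, ukc], cfg)
    q <- stats::quantile(nd, c(0.025, 0.975))
    obs$H2prime[i] >= q[1] && obs$H2prime[i] <= q[2]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("SES grows as generative preferences concentrate", {
  # the full assay panel gives the concentration dial room to act: with few
  # targets, strongly and moderately concentrated diets collide on the same
  # prey and saturate the web at full specialization
  base <- default_design()
  d <- design_spec("Y1", 2L, base$treatments, 2L, c(Y1 = 1L),
                   predator_species = base$predator_species,
                   prey_targets = base$prey_targets,
                   self_detection_map = base$self_detection_map)
  mean_ses <- sapply(c(0.05, 0.5, 5), function(kap) {
    reps <- sapply(1:3, function(r) {
      det <- clean_quietly(simulate_detections(
        synthetic_params(design = d, seed = 71 + r, kappa_by_session = kap,
                         individuals_per_species_per_unit = 5)), d)
      ses <- run_ses(det, d, null_config(n_randomizations = 99L,
                                         min_valid = 20L, seed = 4))
      mean(ses$ses_d, na.rm = TRUE)
    })
    mean(reps)
  })
  # both concentrated settings sit far above the generalized one and above
  # zero; between the two concentrated settings SES saturates (one-hot diets
  # concentrate the null's preserved column totals too), so no strict order
  # is asserted there
  expect_gt(mean_ses[1], mean_ses[3])
  expect_gt(mean_ses[2], mean_ses[3])
  expect_gt(min(mean_ses), 0)
})
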