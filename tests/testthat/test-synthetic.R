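test_that("population and config validation reject bad inputs", {
  expect_error(population_spec("x", -1, c(CD45 = "high")), "concentration")
  expect_error(population_spec("x", 10, c(CD45 = "shiny")), "expression")
  expect_error(tiny_config(sigma_inter = -0.1), "SDs")
  expect_error(tiny_config(events_per_sample = 0), "events_per_sample")
  expect_error(tiny_config(blood_volume = 0), "volumes")
  # a population missing a gated channel is rejected
  panel <- tiny_panel()
  pops <- tiny_populations(panel)
  pops[[1]]$signature <- pops[[1]]$signature[
    names(pops[[1]]$signature) != "Ly6C"]
  expect_error(
    sim_config(list(panel = panel, hierarchy = tiny_hierarchy()),
               populations = pops),
    "Ly6C")
})

test_that("identical seed gives identical output", {
  s1 <- generate_study(tiny_config(n_animals = 2, n_timepoints = 2,
                                   events_per_sample = 500, seed = 99))
  s2 <- generate_study(tiny_config(n_animals = 2, n_timepoints = 2,
                                   events_per_sample = 500, seed = 99))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$samples[[3]]$events, s2$samples[[3]]$events)
  s3 <- generate_study(tiny_config(n_animals = 2, n_timepoints = 2,
                                   events_per_sample = 500, seed = 100))
  expect_false(identical(s1$samples[[1]]$events, s3$samples[[1]]$events))
})

test_that("event split follows the concentrations multinomially", {
  # two populations at 100 and 300 cells/uL, 4000 events: expected split
  # 1000/3000, tolerance three binomial SDs = 3 * sqrt(4000 * .25 * .75)
  panel <- tiny_panel()
  pops <- list(
    population_spec("a", 100, full_signature(panel, c(CD45 = "high"))),
    population_spec("b", 300, full_signature(panel, c(CD11b = "high"))))
  cfg <- sim_config(list(panel = panel, hierarchy = tiny_hierarchy()),
                    populations = pops, n_animals = 1, n_timepoints = 1,
                    events_per_sample = 4000, sigma_inter = 0,
                    sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 7)
  counts <- setNames(s$truth$count, s$truth$population)
  expect_equal(sum(counts), 4000)
  expect_lt(abs(counts[["a"]] - 1000), 3 * sqrt(4000 * 0.25 * 0.75))
})

test_that("event intensities reflect the signature levels", {
  cfg <- tiny_config(n_animals = 1, n_timepoints = 1,
                     events_per_sample = 4000, sigma_inter = 0,
                     sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 5)
  m <- s$events$events
  hi <- s$labels == "myeloid_high"
  lo <- s$labels == "myeloid_low"
  neg <- s$labels == "lymphocytes"   # Ly6C negative
  expect_gt(min(m[hi, "Ly6C"]), max(m[neg, "Ly6C"]))
  # negative and low share the autofluorescence location
  expect_lt(abs(median(log10(m[lo, "Ly6C"])) -
                  median(log10(m[neg, "Ly6C"]))), 0.05)
  # labels, events and truth are consistent after shuffling
  expect_equal(as.vector(table(s$labels)[s$truth$population]),
               s$truth$count)
})

test_that("acquired volume links event count and suspension concentration", {
  cfg <- tiny_config(n_animals = 1, n_timepoints = 1,
                     events_per_sample = 2000, sigma_inter = 0,
                     sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 3)
  susp <- sum(s$truth$concentration) /
    dilution_factor(cfg$blood_volume, cfg$diluent_volume)
  expect_equal(s$events$acquired_volume, 2000 / susp)
  # fixed acquired volume instead derives the event count
  cfg2 <- tiny_config(n_animals = 1, n_timepoints = 1,
                      acquired_volume = 10, sigma_inter = 0,
                      sigma_intra = 0, sigma_resid = 0)
  s2 <- generate_sample(cfg2, seed = 3)
  expect_equal(nrow(s2$events$events), round(10 * susp))
})

test_that("a single timepoint leaves only inter-animal truth variation", {
  cfg <- tiny_config(n_animals = 6, n_timepoints = 1,
                     events_per_sample = 100, sigma_inter = 0.3,
                     sigma_intra = 0, sigma_resid = 0, seed = 21)
  st <- generate_study(cfg)
  tr <- st$truth[st$truth$population == "lymphocytes", ]
  expect_equal(length(unique(tr$timepoint)), 1L)
  expect_gt(var(log10(tr$concentration)), 0)
})

test_that("per-animal mean log10 abundance has the closed-form variance", {
  # u ~ N(0, .2^2) plus the occasion mean of w ~ N(0, .1^2) over 5 draws:
  # Var(mean) = 0.2^2 + 0.1^2 / 5 (no residual term)
  set.seed(202)
  means <- as.vector(replicate(2000, rowMeans(
    simulate_log10_matrix(sigma_resid = 0))))
  expect_lt(abs(var(means) - (0.2^2 + 0.1^2 / 5)), 0.004)
})

test_that("population-to-node membership follows the level ranks", {
  cfg <- tiny_config()
  mem <- population_node_membership(cfg$hierarchy, cfg$populations,
                                    cfg$panel)
  expect_true(mem["Leukocytes", "lymphocytes"])
  expect_false(mem["Leukocytes", "debris"])
  expect_true(mem["Ly6C_high", "myeloid_high"])
  expect_false(mem["Ly6C_high", "myeloid_low"])
  expect_true(mem["Ly6C_low", "myeloid_low"])
  # the intermediate band belongs to neither the low nor the high node
  expect_false(mem["Ly6C_high", "myeloid_mid"])
  expect_false(mem["Ly6C_low", "myeloid_mid"])
  # debris has intact-range scatter (fixed threshold vs the level median)
  # but fails the CD45 leukocyte gate
  expect_true(mem["intact", "debris"])
  expect_false(mem["Leukocytes", "debris"])
})

test_that("node ground truth aggregates populations up the tree", {
  cfg <- tiny_config(n_animals = 1, n_timepoints = 1,
                     events_per_sample = 1000, sigma_inter = 0,
                     sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 11)
  gt <- node_ground_truth(s$truth, cfg)
  counts <- setNames(s$truth$count, s$truth$population)
  expect_equal(gt$count[gt$node == "Myeloid"],
               as.integer(counts[["myeloid_high"]] + counts[["myeloid_low"]] +
                            counts[["myeloid_mid"]]))
  expect_equal(gt$count[gt$node == "Leukocytes"],
               as.integer(sum(counts) - counts[["debris"]]))
  expect_equal(gt$concentration[gt$node == "Leukocytes"], 1600)
})

test_that("event tables validate their inputs", {
  m <- matrix(1, 2, 2, dimnames = list(NULL, c("FSC", "CD45")))
  expect_error(event_table(m, "s", acquired_volume = -1, blood_volume = 50),
               "acquired_volume")
  m2 <- m; m2[1, 1] <- NA
  expect_error(event_table(m2, "s", acquired_volume = 1, blood_volume = 50),
               "finite")
  expect_error(event_table(unname(m), "s", acquired_volume = 1,
                           blood_volume = 50), "channel names")
})
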