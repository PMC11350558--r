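test_that("anova_components equals brute-force deviation sums", {
  set.seed(71)
  for (dims in list(c(2, 2), c(3, 4), c(5, 5))) {
    m <- matrix(rnorm(prod(dims)), nrow = dims[1])
    got <- anova_components(m)
    want <- brute_force_ss(m)
    # brute force counts each deviation once per cell; scale to row/col sums
    expect_equal(got$SS_animal, want$SS_animal)
    expect_equal(got$SS_time, want$SS_time)
    expect_equal(got$SS_residual, want$SS_residual)
    expect_equal(got$SS_total, want$SS_total)
  }
})

test_that("anova_components matches aov on a random matrix", {
  set.seed(72)
  m <- matrix(rnorm(20, sd = 2), nrow = 4)
  got <- anova_components(m)
  df <- data.frame(y = as.vector(m),
                   animal = factor(rep(seq_len(4), 5)),
                   time = factor(rep(seq_len(5), each = 4)))
  tab <- summary(aov(y ~ animal + time, data = df))[[1]]
  expect_equal(got$SS_animal, tab["animal", "Sum Sq"], tolerance = 1e-10)
  expect_equal(got$SS_time, tab["time", "Sum Sq"], tolerance = 1e-10)
  expect_equal(got$SS_residual, tab["Residuals", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("missing animals are dropped listwise with a warning", {
  m <- matrix(rnorm(12), nrow = 4)
  m[2, 3] <- NA
  expect_warning(got <- anova_components(m), "dropped")
  expect_equal(got$n_animals, 3)
  expect_error(suppressWarnings(anova_components(rbind(m[1, ], m[2, ]))),
               "at least 2")
})

test_that("eta-squared shares are in [0,1] and sum to one", {
  set.seed(73)
  e <- eta_squared(matrix(rnorm(25), 5))
  shares <- c(e$eta_sq_inter, e$eta_sq_intra, e$eta_sq_residual)
  expect_true(all(shares >= 0 & shares <= 1))
  expect_lt(abs(sum(shares) - 1), 1e-9)
  expect_error(eta_squared(matrix(5, 3, 3)), "constant")
})

test_that("panel_mean_eta averages either naming convention", {
  decs <- list(list(eta_sq_intra = 0.2, eta_sq_inter = 0.6),
               list(eta_sq_intra = 0.4, eta_sq_inter = 0.2))
  expect_equal(panel_mean_eta(decs),
               c(mean_intra = 0.3, mean_inter = 0.4))
  df <- data.frame(eta_intra_pct = c(20, 40), eta_inter_pct = c(60, 20))
  expect_equal(panel_mean_eta(df), c(mean_intra = 30, mean_inter = 40))
  expect_error(panel_mean_eta(list()), "empty")
})

test_that("the shipped healthy-reference tables give the known panel means", {
  ref <- reference_variability()
  expect_equal(nrow(ref$eta), 42)
  expect_equal(nrow(ref$mdc), 42)
  mye <- ref$eta[ref$eta$panel == "myeloid", ]
  expect_equal(nrow(mye), 16)
  pm <- panel_mean_eta(mye)
  expect_equal(unname(pm["mean_intra"]), 35.49, tolerance = 0.005)
  expect_equal(unname(pm["mean_inter"]), 22.90, tolerance = 0.005)
  lym <- ref$eta[ref$eta$panel == "lymphoid", ]
  expect_equal(nrow(lym), 26)
  # the qualitative claim: average intra-individual share about twice the
  # inter-individual share in both peripheral panels
  pl <- panel_mean_eta(lym)
  expect_gt(pm[["mean_intra"]], pm[["mean_inter"]])
  expect_gt(pl[["mean_intra"]], pl[["mean_inter"]])
})

test_that("detectable change is d times the SD, relative to a mean", {
  v <- c(10, 12, 14, 16, 18)
  dc <- detectable_change(v, cohens_d = 0.5)
  expect_equal(dc$mdc_cells, 0.5 * sd(v))
  expect_equal(dc$mdc_relative_pct, 100 * 0.5 * sd(v) / mean(v))
  dc2 <- detectable_change(v, denominator = "leukocyte_mean",
                           leukocyte_mean = 100)
  expect_equal(dc2$mdc_relative_pct, 100 * 0.5 * sd(v) / 100)
  expect_error(detectable_change(c(1, 1, 1)), "zero")
  expect_error(detectable_change(v, cohens_d = 0), "cohens_d")
})

test_that("exact power agrees with stats::power.t.test", {
  for (n in c(5, 20, 64)) {
    expect_equal(power_two_sample_t(n, 0.5),
                 power.t.test(n = n, delta = 0.5, sd = 1,
                              type = "two.sample", strict = TRUE)$power,
                 tolerance = 1e-6)
  }
})

test_that("required_n iterates to the smallest sufficient n", {
  rn <- required_n(cohens_d = 0.5, power = 0.80, alpha = 0.05)
  expect_equal(rn$n_exact, 64L)
  expect_equal(rn$n_normal_approx, 63L)
  expect_gte(rn$achieved_power, 0.80)
  expect_lt(power_two_sample_t(rn$n_exact - 1, 0.5), 0.80)
  # cross-check with the reference implementation
  expect_equal(rn$n_exact,
               ceiling(power.t.test(delta = 0.5, sd = 1, power = 0.80,
                                    type = "two.sample")$n))
  expect_error(required_n(cohens_d = -1), "cohens_d")
  expect_error(required_n(power = 1), "power")
})

test_that("variance_tables lays out the eta and MDC summaries", {
  cfg <- tiny_config(n_animals = 4, n_timepoints = 4,
                     events_per_sample = 1500, seed = 81)
  st <- generate_study(cfg)
  q <- quantify_study(gate_study(st), st)
  vt <- variance_tables(q)
  expect_setequal(vt$eta$variable,
                  c("Leukocytes", "Myeloid", "Ly6C_high", "Ly6C_low"))
  expect_true(all(abs(vt$eta$eta_intra_pct + vt$eta$eta_inter_pct +
                        vt$eta$eta_residual_pct - 100) < 1e-9))
  expect_true(all(vt$mdc$mdc_cells > 0))
  # MDC column recomputed by hand for one variable
  v <- q$cells_per_uL[q$node == "Myeloid"]
  expect_equal(vt$mdc$mdc_cells[vt$mdc$variable == "Myeloid"], 0.5 * sd(v))
})
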