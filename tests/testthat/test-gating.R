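test_that("asinh transform matches the closed form and inverts", {
  m <- matrix(c(150, 300, 0, 1e5, 20, 50), ncol = 3,
              dimnames = list(NULL, c("CD45", "FSC", "SSC")))
  et <- event_table(m, "s", acquired_volume = 1, blood_volume = 50)
  tr <- transform_intensities(et, cofactor = 150)
  expect_equal(unname(tr$events[1, "CD45"]), asinh(1))   # ln(1 + sqrt(2))
  expect_equal(unname(tr$events[1, "CD45"]), log(1 + sqrt(2)))
  # scatter channels stay linear
  expect_equal(tr$events[, "FSC"], m[, "FSC"])
  expect_equal(tr$events[, "SSC"], m[, "SSC"])
  back <- transform_intensities(tr, cofactor = 150, inverse = TRUE)
  expect_equal(back$events, m)
  expect_error(transform_intensities(tr), "already")
  expect_error(transform_intensities(et, cofactor = 0), "cofactor")
})

test_that("valley threshold separates two well-separated modes", {
  set.seed(1)
  v <- c(rnorm(3000, 0, 0.3), rnorm(1000, 4, 0.3))
  th <- estimate_threshold(v, mode = "valley")
  expect_equal(th$method_tag, "valley")
  expect_false(th$fallback)
  expect_gt(th$thresholds, 1)
  expect_lt(th$thresholds, 3)
  # determinism
  expect_identical(th, estimate_threshold(v, mode = "valley"))
})

test_that("valley mode places two thresholds across three modes", {
  set.seed(2)
  v <- c(rnorm(5000, 0, 0.3), rnorm(500, 3, 0.3), rnorm(1500, 6, 0.3))
  th <- estimate_threshold(v, mode = "valley", n_thresholds = 2)
  expect_equal(th$method_tag, "valley")
  expect_length(th$thresholds, 2)
  expect_true(th$thresholds[1] > 1 && th$thresholds[1] < 2.5)
  expect_true(th$thresholds[2] > 3.5 && th$thresholds[2] < 5.5)
})

test_that("ripples on one cluster are not mistaken for extra modes", {
  set.seed(3)
  # heavy dominant cluster with KDE ripples plus one true positive mode
  v <- c(rnorm(20000, 0, 0.5), rnorm(300, 5, 0.3))
  th <- estimate_threshold(v, mode = "valley")
  expect_false(th$fallback)
  expect_true(th$thresholds > 2 && th$thresholds < 4.5)
})

test_that("gmm mode returns equal-posterior boundaries", {
  set.seed(4)
  v <- c(rnorm(2000, 0, 0.4), rnorm(2000, 4, 0.4))
  th <- estimate_threshold(v, mode = "gmm")
  expect_equal(th$method_tag, "gmm")
  expect_gt(th$thresholds, 1.2)
  expect_lt(th$thresholds, 2.8)
})

test_that("unimodal data fall back to the tagged quantile threshold", {
  set.seed(5)
  v <- rnorm(5000)
  th <- estimate_threshold(v, mode = "valley")
  expect_equal(th$method_tag, "quantile")
  expect_true(th$fallback)
  expect_equal(th$thresholds, quantile(v, 0.995, names = FALSE))
  # explicitly requested quantile is not flagged as a fallback
  thq <- estimate_threshold(v, mode = "quantile")
  expect_false(thq$fallback)
})

test_that("too few events is an error", {
  expect_error(estimate_threshold(rnorm(10)), "at least 50")
})

test_that("ties at the threshold go to the positive side", {
  m <- matrix(c(2, 1.999, 2.001, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("CD45", "FSC")))
  et <- event_table(m, "s", acquired_volume = 1, blood_volume = 50,
                    transformed = TRUE)
  ths <- list(CD45 = list(thresholds = 2))
  keep <- cytovar:::evaluate_conditions(
    et, list(gate_condition("CD45", "positive")), ths)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  keep_neg <- cytovar:::evaluate_conditions(
    et, list(gate_condition("CD45", "negative")), ths)
  expect_equal(keep_neg, !keep)
})

test_that("tri-level relations partition events exactly", {
  m <- matrix(c(0.5, 1.5, 2.5, 1, 2, 3), ncol = 2,
              dimnames = list(NULL, c("Ly6C", "FSC")))
  et <- event_table(m, "s", acquired_volume = 1, blood_volume = 50,
                    transformed = TRUE)
  ths <- list(Ly6C = list(thresholds = c(1, 2)))
  bands <- sapply(c("low", "intermediate", "high"), function(r)
    cytovar:::evaluate_conditions(et, list(gate_condition("Ly6C", r)), ths))
  expect_equal(rowSums(bands), c(1, 1, 1))   # each event in exactly one band
  expect_equal(unname(which(bands[, "low"])), 1L)
  expect_equal(unname(which(bands[, "intermediate"])), 2L)
  expect_equal(unname(which(bands[, "high"])), 3L)
})

test_that("gating matches a brute-force per-event oracle", {
  cfg <- tiny_config(n_animals = 1, n_timepoints = 1,
                     events_per_sample = 3000, sigma_inter = 0,
                     sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 31)
  ev <- transform_intensities(s$events)
  ths <- estimate_thresholds(ev, cfg$hierarchy)
  res <- gate_sample(ev, cfg$hierarchy, thresholds = ths,
                     keep_membership = TRUE)
  mem <- attr(res, "membership")
  m <- ev$events
  th1 <- function(ch) ths[[ch]]$thresholds[1]
  # independent vectorized reimplementation of the full condition paths
  intact <- m[, "FSC"] >= 10000
  leuk <- intact & m[, "CD45"] >= th1("CD45")
  mye <- leuk & m[, "CD11b"] >= th1("CD11b")
  hi <- mye & m[, "Ly6C"] >= ths[["Ly6C"]]$thresholds[2]
  lo <- mye & m[, "Ly6C"] < th1("Ly6C")
  expect_equal(unname(mem[, "intact"]), unname(intact))
  expect_equal(unname(mem[, "Leukocytes"]), unname(leuk))
  expect_equal(unname(mem[, "Myeloid"]), unname(mye))
  expect_equal(unname(mem[, "Ly6C_high"]), unname(hi))
  expect_equal(unname(mem[, "Ly6C_low"]), unname(lo))
  # summary columns agree with the membership matrix
  expect_equal(res$count, unname(colSums(mem)))
  expect_equal(res$fraction_of_leukocytes,
               unname(colSums(mem)) / sum(leuk))
  expect_equal(res$fraction_of_parent[res$node == "Myeloid"],
               sum(mye) / sum(leuk))
})

test_that("gate_sample transforms raw input and records metadata", {
  cfg <- tiny_config(n_animals = 1, n_timepoints = 1,
                     events_per_sample = 2000, sigma_inter = 0,
                     sigma_intra = 0, sigma_resid = 0)
  s <- generate_sample(cfg, seed = 32)
  res <- gate_sample(s$events, cfg$hierarchy)
  expect_s3_class(res, "subset_result")
  expect_equal(attr(res, "sample_id"), s$events$sample_id)
  expect_s3_class(attr(res, "thresholds"), "threshold_set")
  # channels with only fixed conditions get no estimated threshold
  expect_false("FSC" %in% names(attr(res, "thresholds")))
})

test_that("gating fails loudly on missing channels", {
  m <- matrix(1, 5, 2, dimnames = list(NULL, c("FSC", "CD45")))
  et <- event_table(m, "s", acquired_volume = 1, blood_volume = 50)
  expect_error(gate_sample(et, tiny_hierarchy()), "missing")
})

test_that("gate_study stacks per-sample results with metadata", {
  cfg <- tiny_config(n_animals = 2, n_timepoints = 2,
                     events_per_sample = 800, seed = 41)
  st <- generate_study(cfg)
  g <- gate_study(st)
  expect_equal(nrow(g), 4 * 5)   # 4 samples x 5 nodes
  expect_setequal(unique(g$animal_id), c("animal01", "animal02"))
  expect_true(all(c("sample_id", "timepoint", "node", "count") %in%
                    names(g)))
})
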