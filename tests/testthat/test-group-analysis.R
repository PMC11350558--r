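test_that("percent change handles sign, zero and undefined baselines", {
  expect_equal(as.numeric(percent_change(c(100, 50), c(150, 25))),
               c(50, -50))
  expect_warning(pc <- percent_change(c(100, 0), c(150, 10)), "undefined")
  expect_true(is.na(pc[2]))
  expect_equal(attr(pc, "undefined"), 2L)
})

test_that("pooled t test reproduces the textbook example", {
  # {1,2,3} vs {4,5,6}: pooled SD = 1, t = -3/sqrt(2/3)
  tt <- two_sample_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3))
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-3 / sqrt(2 / 3), 4))
  expect_equal(tt$p_value, 0.02131, tolerance = 1e-4)
})

test_that("pooled and Welch tests agree with stats::t.test", {
  set.seed(91)
  a <- rnorm(8, 1); b <- rnorm(12, 0, 2)
  tt <- two_sample_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic))
  expect_equal(tt$p_value, ref$p.value)
  tw <- two_sample_test(a, b, var_equal = FALSE)
  refw <- t.test(a, b)
  expect_equal(tw$statistic, unname(refw$statistic))
  expect_equal(tw$df, unname(refw$parameter))
  expect_equal(tw$p_value, refw$p.value)
})

test_that("degenerate zero-variance inputs follow the documented convention", {
  expect_equal(two_sample_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(two_sample_test(c(1, 1), c(1, 1))$statistic, 0)
  expect_equal(two_sample_test(c(2, 2), c(1, 1))$p_value, 0)
  expect_equal(two_sample_test(c(2, 2), c(1, 1))$statistic, Inf)
  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
})

test_that("block+group ANOVA agrees with aov on a balanced design", {
  set.seed(92)
  d <- expand.grid(block = factor(1:3), group = factor(c("ctl", "lps")),
                   rep = 1:2)
  d$y <- rnorm(nrow(d)) + as.numeric(d$group)
  got <- block_group_anova(d$y, d$group, d$block)
  tab <- summary(aov(y ~ block + group, data = d))[[1]]
  expect_equal(got$F_group, tab["group", "F value"], tolerance = 1e-10)
  expect_equal(got$p_group, tab["group", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(got$F_block, tab["block", "F value"], tolerance = 1e-10)
  expect_equal(got$p_block, tab["block", "Pr(>F)"], tolerance = 1e-10)
  expect_false(got$single_block)
})

test_that("block ANOVA flags degeneration and rejects empty cells", {
  set.seed(93)
  y <- rnorm(8)
  g <- rep(c("a", "b"), each = 4)
  expect_true(block_group_anova(y, g, rep("only", 8))$single_block)
  expect_error(
    block_group_anova(y, g, c(rep("b1", 4), rep("b2", 4))),
    "empty")
})

test_that("variance-ratio test matches var.test up to the tail convention", {
  set.seed(94)
  a <- rnorm(10); b <- rnorm(10, 0, 3)
  got <- variance_ratio_test(a, b)
  ref <- var.test(b, a)   # larger variance in the numerator
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_gte(got$statistic, 1)
  expect_error(variance_ratio_test(c(1, 1), c(1, 1)), "zero variance")
})

test_that("the humane endpoint rule fires on cumulative or maximal scores", {
  none <- rep(0L, 7)
  expect_false(endpoint_reached(none)$reached)
  # cumulative: strictly greater than 16
  expect_false(endpoint_reached(c(3, 3, 3, 3, 2, 1, 1))$reached)  # 16
  hit <- endpoint_reached(c(3, 3, 3, 3, 3, 1, 1))                 # 17
  expect_true(hit$reached)
  expect_match(hit$reason, "cumulative")
  # any single item at 4
  single <- endpoint_reached(c(4, 0, 0, 0, 0, 0, 0))
  expect_true(single$reached)
  expect_match(single$reason, "single item")
  expect_error(endpoint_reached(c(5, 0, 0, 0, 0, 0, 0)), "0..4")
  expect_error(endpoint_reached(rep(0, 6)), "7 item")
})

test_that("both tests hold their nominal type-I error approximately", {
  set.seed(95)
  n_sim <- 2000
  p_t <- replicate(n_sim, two_sample_test(rnorm(6), rnorm(6))$p_value)
  p_f <- replicate(n_sim,
                   variance_ratio_test(rnorm(6), rnorm(6))$p_value)
  expect_lt(abs(mean(p_t < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(p_f < 0.05) - 0.05), 0.015)
})

test_that("compare_groups runs the challenge workflow per variable", {
  cfg <- tiny_config(n_animals = 6, n_timepoints = 2,
                     events_per_sample = 1500, seed = 96)
  st <- generate_study(cfg)
  q <- quantify_study(gate_study(st), st)
  # stamp groups (3 vs 3) and blocks (pairs) onto the tidy table
  grp <- setNames(rep(c("ctl", "lps"), each = 3),
                  sprintf("animal%02d", 1:6))
  blk <- setNames(rep(c("b1", "b2", "b3"), times = 2),
                  sprintf("animal%02d", 1:6))
  q$group <- grp[q$animal_id]
  q$block <- blk[q$animal_id]
  res <- compare_groups(q, baseline = "t01", followup = "t02")
  expect_setequal(res$variable,
                  c("Leukocytes", "Myeloid", "Ly6C_high", "Ly6C_low"))
  expect_true(all(c("mean_ctl", "mean_lps", "t", "p_value", "block_p") %in%
                    names(res)))
  expect_true(all(is.finite(res$p_value)))
  # cross-check one variable against a direct computation
  d <- q[q$node == "Leukocytes", ]
  pc <- sapply(sprintf("animal%02d", 1:6), function(a) {
    b <- d$cells_per_uL[d$animal_id == a & d$timepoint == "t01"]
    f <- d$cells_per_uL[d$animal_id == a & d$timepoint == "t02"]
    100 * (f - b) / b
  })
  tt <- two_sample_test(pc[1:3], pc[4:6])
  expect_equal(res$t[res$variable == "Leukocytes"], tt$statistic)
  expect_equal(res$p_value[res$variable == "Leukocytes"], tt$p_value)
})
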