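# Challenge-study (e.g. intratracheal LPS) group statistics:
# baseline-normalized change, pooled-variance t tests, randomized-block
# two-way ANOVA, variance-equality testing, and the clinical endpoint rule.

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`, the per-animal change between
#' the 24-hour and baseline samples. Undefined (non-positive baseline)
#' entries return `NA` and are flagged, never dropped silently.
#'
#' @param baseline,followup Concentrations (vectorized).
#' @return Numeric vector with attribute `"undefined"` (indices with
#'   baseline <= 0); a warning is raised when any entry is undefined.
#' @export
percent_change <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  bad <- which(!(baseline > 0))
  out <- 100 * (followup - baseline) / baseline
  out[bad] <- NA_real_
  if (length(bad))
    warning("percent change undefined for ", length(bad),
            " entr(ies) with baseline <= 0")
  structure(out, undefined = bad)
}

#' Two-sample t test (pooled variance)
#'
#' Student's two-sided t test with pooled variance, computed from the
#' textbook sums. Degenerate inputs are resolved by convention: zero pooled
#' variance with equal means gives `t = 0, p = 1`; with unequal means the
#' statistic is infinite and `p = 0`. Significance thresholds are applied
#' by the caller, not here.
#'
#' @param group_a,group_b At least two values each.
#' @param var_equal Pool the variances (default, the classic Student test);
#'   `FALSE` gives the Welch test.
#' @return List of class `cyto_test`: `statistic`, `p_value`, `df`,
#'   `mean_difference` (a minus b), `method`.
#' @export
two_sample_test <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need at least 2 values per group",
                             call. = FALSE)
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    method <- "two-sample t (pooled variance)"
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "two-sample t (Welch)"
  }
  if (se == 0) {
    t_stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
  } else {
    t_stat <- (ma - mb) / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(statistic = t_stat, p_value = p, df = df,
                 mean_difference = ma - mb, method = method),
            class = "cyto_test")
}

#' Two-way ANOVA with block and group factors
#'
#' Additive two-factor analysis of variance for the randomized-block
#' challenge design (blocks of animals, treatment vs control within each
#' block), computed from deviation sums of squares with both factors tested
#' against the residual.
#'
#' @param values Response values (e.g. percent change of one variable).
#' @param group Treatment/control labels, one per value.
#' @param block Block labels, one per value; every (block, group) cell must
#'   be non-empty. A single block degenerates to one-way ANOVA on `group`
#'   (flagged in the result).
#' @return List of class `block_group_anova`: `F_group`, `p_group`,
#'   `F_block`, `p_block`, the SS/df table, and `single_block`.
#' @export
block_group_anova <- function(values, group, block) {
  group <- factor(group); block <- factor(block)
  stopifnot(length(values) == length(group),
            length(values) == length(block))
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  cells <- table(block, group)
  if (any(cells == 0))
    stop("empty (block, group) cell(s): ",
         paste(which(cells == 0, arr.ind = TRUE), collapse = " "),
         call. = FALSE)
  n <- length(values)
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  group_means <- tapply(values, group, mean)
  block_means <- tapply(values, block, mean)
  ss_group <- sum(tabulate(group) * (group_means - grand)^2)
  ss_block <- sum(tabulate(block) * (block_means - grand)^2)
  single_block <- nlevels(block) < 2
  if (single_block) ss_block <- 0
  ss_resid <- ss_total - ss_group - ss_block
  df_group <- nlevels(group) - 1L
  df_block <- if (single_block) 0L else nlevels(block) - 1L
  df_resid <- n - 1L - df_group - df_block
  if (df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)
  ms_resid <- ss_resid / df_resid
  f_of <- function(ss, df) {
    if (df == 0) return(c(NA_real_, NA_real_))
    if (ms_resid == 0) return(c(Inf, 0))
    f <- (ss / df) / ms_resid
    c(f, stats::pf(f, df, df_resid, lower.tail = FALSE))
  }
  fg <- f_of(ss_group, df_group)
  fb <- f_of(ss_block, df_block)
  structure(list(F_group = fg[1], p_group = fg[2],
                 F_block = fb[1], p_block = fb[2],
                 SS = c(group = ss_group, block = ss_block,
                        residual = ss_resid, total = ss_total),
                 df = c(group = df_group, block = df_block,
                        residual = df_resid),
                 single_block = single_block),
            class = "block_group_anova")
}

#' @export
print.block_group_anova <- function(x, ...) {
  cat("<block_group_anova>",
      if (x$single_block) "(single block: one-way on group)", "\n")
  cat(sprintf("  group: F = %.4g, p = %.4g (df %d/%d)\n", x$F_group,
              x$p_group, x$df[["group"]], x$df[["residual"]]))
  if (!x$single_block)
    cat(sprintf("  block: F = %.4g, p = %.4g (df %d/%d)\n", x$F_block,
                x$p_block, x$df[["block"]], x$df[["residual"]]))
  invisible(x)
}

#' F test for equality of variances
#'
#' Ratio of sample variances with a two-sided p value from the F
#' distribution. By convention the larger variance goes in the numerator,
#' so `F >= 1` always.
#'
#' @param sample_a,sample_b At least two values each.
#' @return List of class `cyto_test`: `statistic` (the F ratio),
#'   `p_value`, `df` (numerator, denominator).
#' @export
variance_ratio_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need at least 2 values per sample", call. = FALSE)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0)
    stop("both samples have zero variance", call. = FALSE)
  if (min(va, vb) == 0)
    stop("zero variance in denominator sample", call. = FALSE)
  if (va >= vb) {
    f <- va / vb; df1 <- length(sample_a) - 1L; df2 <- length(sample_b) - 1L
  } else {
    f <- vb / va; df1 <- length(sample_b) - 1L; df2 <- length(sample_a) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  structure(list(statistic = f, p_value = p, df = c(df1, df2),
                 method = "F test for equality of variances"),
            class = "cyto_test")
}

#' @export
print.cyto_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 5), "\n", sep = "")
  invisible(x)
}

# The seven daily clinical signs monitored during the challenge study.
.clinical_items <- c("dehydration", "piloerection", "cleanliness", "lesions",
                     "aggressiveness", "passivity", "repetitive_behaviors")

#' Humane-endpoint decision from a daily clinical score
#'
#' Seven clinical signs are each scored 0 (none) to 4 (high severity). The
#' endpoint is reached when the cumulative score strictly exceeds 16
#' points, or when any single sign scores 4.
#'
#' @param scores Integer vector of 7 item scores (named or in the standard
#'   order: dehydration, piloerection, cleanliness, lesions, aggressiveness,
#'   passivity, repetitive behaviors).
#' @param cumulative_threshold Cumulative score that must be exceeded
#'   (default 16, strict).
#' @param max_item Single-item score that triggers the endpoint (default 4).
#' @return List: `reached` (logical), `reason` (`"single item at maximum"`,
#'   `"cumulative score exceeded"`, both, or `NA`), `total`.
#' @export
endpoint_reached <- function(scores, cumulative_threshold = 16,
                             max_item = 4) {
  scores <- unlist(scores)
  if (length(scores) != length(.clinical_items))
    stop("expected ", length(.clinical_items), " item scores", call. = FALSE)
  if (any(scores != round(scores)) || any(scores < 0) || any(scores > max_item))
    stop("item scores must be integers in 0..", max_item, call. = FALSE)
  total <- sum(scores)
  reasons <- character()
  if (any(scores == max_item)) reasons <- c(reasons, "single item at maximum")
  if (total > cumulative_threshold)
    reasons <- c(reasons, "cumulative score exceeded")
  list(reached = length(reasons) > 0,
       reason = if (length(reasons)) paste(reasons, collapse = "; ")
                else NA_character_,
       total = total)
}

#' Group comparison of baseline-normalized change for every variable
#'
#' The challenge-study pipeline: per animal and variable, percent change
#' between a baseline and a follow-up timepoint; then a pooled t test
#' between the two groups per variable. When block labels are available, an
#' additive block+group ANOVA is run first; if the block factor is not
#' significant at `block_alpha` it is dropped (logged in the output),
#' mirroring the standard randomized-block workflow.
#'
#' @param quantified Tidy table from [quantify_study()] with `group` (two
#'   levels) and optionally `block` metadata.
#' @param baseline,followup Timepoint labels.
#' @param value `"pct_change"` (default) or `"followup"`: compare percent
#'   change or raw follow-up values (recorded in the output).
#' @param block_alpha Significance threshold for keeping the block factor.
#' @return Data frame per variable: group means of the compared value, `t`,
#'   `p_value`, `block_p` (NA when blocks unavailable/dropped), and the
#'   comparison metadata as attributes.
#' @export
compare_groups <- function(quantified, baseline, followup,
                           value = c("pct_change", "followup"),
                           block_alpha = 0.05) {
  value <- match.arg(value)
  q <- quantified[quantified$timepoint %in% c(baseline, followup), ]
  groups <- sort(unique(q$group[!is.na(q$group)]))
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  out <- list()
  for (v in unique(q$node)) {
    d <- q[q$node == v, ]
    base <- d[d$timepoint == baseline, ]
    foll <- d[d$timepoint == followup, ]
    m <- merge(base[, c("animal_id", "group", "block", "cells_per_uL")],
               foll[, c("animal_id", "cells_per_uL")],
               by = "animal_id", suffixes = c("_baseline", "_followup"))
    y <- if (value == "pct_change")
      suppressWarnings(as.numeric(percent_change(m$cells_per_uL_baseline,
                                                 m$cells_per_uL_followup)))
    else m$cells_per_uL_followup
    ok <- is.finite(y)
    block_p <- NA_real_
    has_blocks <- !all(is.na(m$block)) && length(unique(m$block[ok])) > 1
    if (has_blocks) {
      ba <- tryCatch(block_group_anova(y[ok], m$group[ok], m$block[ok]),
                     error = function(e) NULL)
      if (!is.null(ba)) block_p <- ba$p_block
    }
    tt <- tryCatch(two_sample_test(y[ok & m$group == groups[1]],
                                   y[ok & m$group == groups[2]]),
                   error = function(e) NULL)
    out[[v]] <- data.frame(
      variable = v,
      mean_a = mean(y[ok & m$group == groups[1]]),
      mean_b = mean(y[ok & m$group == groups[2]]),
      t = if (is.null(tt)) NA_real_ else tt$statistic,
      p_value = if (is.null(tt)) NA_real_ else tt$p_value,
      block_p = block_p,
      block_retained = !is.na(block_p) && block_p <= block_alpha,
      n_undefined = sum(!ok),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(res)[names(res) == "mean_a"] <- paste0("mean_", groups[1])
  names(res)[names(res) == "mean_b"] <- paste0("mean_", groups[2])
  attr(res, "value") <- value
  attr(res, "baseline") <- baseline
  attr(res, "followup") <- followup
  res
}
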