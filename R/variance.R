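# Longitudinal variance decomposition: two-factor (animal x occasion)
# sums of squares without replication, eta-squared shares, minimum
# detectable change, and sample-size computation.

#' Two-factor sums of squares for a longitudinal matrix
#'
#' Decomposes an animals-by-timepoints matrix (one variable, typically log10
#' cells/uL) into animal, timepoint and residual sums of squares, computed
#' from row and column means (repeated-measures ANOVA without replication).
#' Additivity `SS_animal + SS_time + SS_residual = SS_total` holds exactly.
#'
#' @param values Numeric matrix, animals in rows, timepoints in columns,
#'   at least 2 x 2. Rows containing missing values are dropped (listwise)
#'   with a warning.
#' @return A list of class `anova_components`: `SS_animal`, `SS_time`,
#'   `SS_residual`, `SS_total`, degrees of freedom, and the design size.
#' @export
anova_components <- function(values) {
  values <- as.matrix(values)
  incomplete <- rowSums(!is.finite(values)) > 0
  if (any(incomplete)) {
    warning(sum(incomplete), " animal row(s) with missing values dropped")
    values <- values[!incomplete, , drop = FALSE]
  }
  a <- nrow(values); b <- ncol(values)
  if (a < 2 || b < 2)
    stop("need at least 2 animals and 2 timepoints", call. = FALSE)
  grand <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  ss_animal <- b * sum((row_m - grand)^2)
  ss_time <- a * sum((col_m - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_resid <- ss_total - ss_animal - ss_time
  structure(list(SS_animal = ss_animal, SS_time = ss_time,
                 SS_residual = ss_resid, SS_total = ss_total,
                 df_animal = a - 1L, df_time = b - 1L,
                 df_residual = (a - 1L) * (b - 1L),
                 n_animals = a, n_timepoints = b),
            class = "anova_components")
}

#' @export
print.anova_components <- function(x, ...) {
  cat("<anova_components> ", x$n_animals, " animals x ", x$n_timepoints,
      " timepoints\n", sep = "")
  cat(sprintf("  SS animal   %10.4f (df %d)\n", x$SS_animal, x$df_animal))
  cat(sprintf("  SS time     %10.4f (df %d)\n", x$SS_time, x$df_time))
  cat(sprintf("  SS residual %10.4f (df %d)\n", x$SS_residual,
              x$df_residual))
  cat(sprintf("  SS total    %10.4f\n", x$SS_total))
  invisible(x)
}

#' Eta-squared variance shares
#'
#' Converts an [anova_components()] decomposition into the proportion of
#' total variance attributable to each factor: the inter-individual share
#' (animal factor), the intra-individual share (repetition/timepoint
#' factor), and the unassigned residual. The three shares sum to one.
#'
#' @param components An [anova_components()] result, or a matrix (which is
#'   decomposed first).
#' @return A list of class `variance_decomposition`: `eta_sq_inter`,
#'   `eta_sq_intra`, `eta_sq_residual`.
#' @export
eta_squared <- function(components) {
  if (is.matrix(components) || is.data.frame(components))
    components <- anova_components(components)
  if (!inherits(components, "anova_components"))
    stop("expected an anova_components object or a matrix", call. = FALSE)
  if (components$SS_total <= 0)
    stop("constant variable: total sum of squares is zero, eta-squared ",
         "undefined", call. = FALSE)
  structure(list(
    eta_sq_inter = components$SS_animal / components$SS_total,
    eta_sq_intra = components$SS_time / components$SS_total,
    eta_sq_residual = components$SS_residual / components$SS_total),
    class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> inter %.1f%%, intra %.1f%%, residual %.1f%%\n",
    100 * x$eta_sq_inter, 100 * x$eta_sq_intra, 100 * x$eta_sq_residual))
  invisible(x)
}

#' Panel-average variance shares
#'
#' Arithmetic means of the intra- and inter-individual eta-squared shares
#' across the variables of a panel.
#'
#' @param decompositions Non-empty list of [eta_squared()] results, or a
#'   data frame / matrix with columns `eta_sq_intra`/`eta_sq_inter` or
#'   `eta_intra_pct`/`eta_inter_pct` (as in [variance_tables()]; any scale,
#'   percentages are averaged as given).
#' @return Named numeric vector `c(mean_intra, mean_inter)`.
#' @export
panel_mean_eta <- function(decompositions) {
  if (is.data.frame(decompositions) || is.matrix(decompositions)) {
    df <- as.data.frame(decompositions)
    if (nrow(df) == 0) stop("empty input", call. = FALSE)
    intra <- if (!is.null(df$eta_sq_intra)) df$eta_sq_intra
             else df$eta_intra_pct
    inter <- if (!is.null(df$eta_sq_inter)) df$eta_sq_inter
             else df$eta_inter_pct
    if (is.null(intra) || is.null(inter))
      stop("no eta-share columns found", call. = FALSE)
    return(c(mean_intra = mean(intra), mean_inter = mean(inter)))
  }
  if (length(decompositions) == 0) stop("empty input", call. = FALSE)
  c(mean_intra = mean(vapply(decompositions, `[[`, 0, "eta_sq_intra")),
    mean_inter = mean(vapply(decompositions, `[[`, 0, "eta_sq_inter")))
}

#' Minimum detectable change for a variable
#'
#' The smallest change declarable meaningful at a target standardized
#' effect size: `mdc = d * SD(values)` in the input's units, also expressed
#' relative to a denominator mean (the variable's own mean by default, or a
#' supplied leukocyte mean).
#'
#' @param values At least two observations of the variable (cells/uL or
#'   log10 units; the result follows the input scale).
#' @param cohens_d Target standardized effect size (default 0.5, a medium
#'   effect).
#' @param denominator `"own_mean"` or `"leukocyte_mean"`.
#' @param leukocyte_mean Mean leukocyte concentration, required for
#'   `denominator = "leukocyte_mean"`.
#' @param power,alpha Stated design context, carried through to the result
#'   (the companion sample-size computation is [required_n()]).
#' @return A list of class `detectable_change`: `mdc_cells`,
#'   `mdc_relative_pct`, `cohens_d`, `power`, `alpha`, `denominator_mean`.
#' @export
detectable_change <- function(values, cohens_d = 0.5,
                              denominator = c("own_mean", "leukocyte_mean"),
                              leukocyte_mean = NULL,
                              power = 0.80, alpha = 0.05) {
  denominator <- match.arg(denominator)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (cohens_d <= 0) stop("cohens_d must be > 0", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation: detectable change undefined",
                   call. = FALSE)
  den <- switch(denominator,
                own_mean = mean(values),
                leukocyte_mean = {
                  if (is.null(leukocyte_mean))
                    stop("leukocyte_mean required", call. = FALSE)
                  leukocyte_mean
                })
  if (den == 0) stop("zero denominator mean", call. = FALSE)
  mdc <- cohens_d * s
  structure(list(mdc_cells = mdc, mdc_relative_pct = 100 * mdc / den,
                 cohens_d = cohens_d, power = power, alpha = alpha,
                 denominator = denominator, denominator_mean = den),
            class = "detectable_change")
}

#' @export
print.detectable_change <- function(x, ...) {
  cat(sprintf(
    "<detectable_change> %.4g (%.2f%% of %s) at d = %.2f\n",
    x$mdc_cells, x$mdc_relative_pct, x$denominator, x$cohens_d))
  invisible(x)
}

#' Power of the two-sided two-sample t test
#'
#' Exact noncentral-t power for `n` animals per group at standardized
#' effect `d` and significance level `alpha`.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Standardized mean difference (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); vectorized over `n`.
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}

#' Per-group sample size for a target power
#'
#' Smallest integer `n` per group achieving the target power for a
#' two-sided two-sample comparison at effect size `d`, found by iterating
#' the exact noncentral-t power function upward from `n = 2`. The
#' normal-approximation size `ceiling(2 (z_{1-alpha/2} + z_{power})^2 / d^2)`
#' is reported alongside.
#'
#' @param cohens_d Standardized effect size (> 0).
#' @param power Target power in (0, 1) (default 0.80).
#' @param alpha Two-sided significance level in (0, 1) (default 0.05).
#' @return List of class `required_n`: `n_exact`, `n_normal_approx`,
#'   `achieved_power`, plus the inputs.
#' @export
required_n <- function(cohens_d = 0.5, power = 0.80, alpha = 0.05) {
  if (cohens_d <= 0) stop("cohens_d must be > 0", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  n <- 2L
  while (power_two_sample_t(n, cohens_d, alpha) < power) n <- n + 1L
  n_norm <- ceiling(2 * (stats::qnorm(1 - alpha / 2) +
                           stats::qnorm(power))^2 / cohens_d^2)
  structure(list(n_exact = n, n_normal_approx = as.integer(n_norm),
                 achieved_power = power_two_sample_t(n, cohens_d, alpha),
                 cohens_d = cohens_d, power = power, alpha = alpha),
            class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  cat(sprintf(
    "<required_n> %d per group (exact t; achieves %.1f%%), %d by normal approximation\n  d = %.2f, power = %.2f, alpha = %.3f\n",
    x$n_exact, 100 * x$achieved_power, x$n_normal_approx, x$cohens_d,
    x$power, x$alpha))
  invisible(x)
}

#' Variance-share and detectable-change tables for a quantified study
#'
#' For every reported variable of a tidy concentration table
#' ([quantify_study()] output), computes the eta-squared shares on the
#' log10 scale and the minimum detectable change on the cells/uL scale,
#' laid out as the two standard summary tables (variable, intra %, inter %)
#' and (variable, MDC cells, MDC %).
#'
#' @param quantified Output of [quantify_study()].
#' @param cohens_d Effect size for the detectable-change column.
#' @param scale `"log10"` (default) or `"raw"`: analysis scale for the
#'   eta-squared decomposition.
#' @return List with data frames `eta` (`variable`, `eta_intra_pct`,
#'   `eta_inter_pct`, `eta_residual_pct`) and `mdc` (`variable`,
#'   `mdc_cells`, `mdc_relative_pct`).
#' @export
variance_tables <- function(quantified, cohens_d = 0.5,
                            scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  vars <- unique(quantified$node)
  eta_rows <- list(); mdc_rows <- list()
  for (v in vars) {
    d <- quantified[quantified$node == v, ]
    m <- tapply(if (scale == "log10") d$log10_value else d$cells_per_uL,
                list(d$animal_id, d$timepoint), mean)
    dec <- tryCatch(eta_squared(anova_components(m)), error = function(e) NULL)
    if (!is.null(dec))
      eta_rows[[v]] <- data.frame(variable = v,
                                  eta_intra_pct = 100 * dec$eta_sq_intra,
                                  eta_inter_pct = 100 * dec$eta_sq_inter,
                                  eta_residual_pct = 100 * dec$eta_sq_residual,
                                  stringsAsFactors = FALSE)
    mdc <- tryCatch(detectable_change(d$cells_per_uL, cohens_d = cohens_d),
                    error = function(e) NULL)
    if (!is.null(mdc))
      mdc_rows[[v]] <- data.frame(variable = v, mdc_cells = mdc$mdc_cells,
                                  mdc_relative_pct = mdc$mdc_relative_pct,
                                  stringsAsFactors = FALSE)
  }
  list(eta = do.call(rbind, c(eta_rows, list(make.row.names = FALSE))),
       mdc = do.call(rbind, c(mdc_rows, list(make.row.names = FALSE))))
}
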