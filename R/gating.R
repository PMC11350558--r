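# Automated hierarchical gating: asinh transform, data-driven threshold
# placement (density valley / Gaussian mixture / quantile fallback), and
# top-down execution of a gating hierarchy on an event table.

#' Transform fluorescence intensities for gating
#'
#' Maps fluorescence channels through the inverse hyperbolic sine
#' `asinh(x / cofactor)`, the standard variance-stabilizing transform for
#' cytometry intensities; scatter channels are left linear. Invertible via
#' `inverse = TRUE`.
#'
#' @param events An [event_table()].
#' @param cofactor Positive cofactor (default 150, appropriate for
#'   conventional-fluorescence instruments).
#' @param scatter_channels Channels to leave untouched; defaults to the
#'   table's `FSC`/`SSC`-named columns.
#' @param inverse Undo the transform instead.
#' @return The event table with transformed fluorescence channels.
#' @export
transform_intensities <- function(events, cofactor = 150,
                                  scatter_channels = NULL, inverse = FALSE) {
  if (!is.numeric(cofactor) || cofactor <= 0)
    stop("cofactor must be > 0", call. = FALSE)
  if (is.null(scatter_channels))
    scatter_channels <- intersect(c("FSC", "SSC"), events$channel_names)
  fluor <- setdiff(events$channel_names, scatter_channels)
  m <- events$events
  if (inverse) {
    if (!events$transformed) stop("event table is not transformed",
                                  call. = FALSE)
    m[, fluor] <- sinh(m[, fluor]) * cofactor
    events$transformed <- FALSE
  } else {
    if (events$transformed) stop("event table is already transformed",
                                 call. = FALSE)
    m[, fluor] <- asinh(m[, fluor] / cofactor)
    events$transformed <- TRUE
  }
  events$events <- m
  events
}

# Deterministic thinning used before mixture fits: evenly spaced order
# statistics preserve the distribution's shape.
thin_sorted <- function(x, n_max = 20000L) {
  x <- sort(x)
  if (length(x) <= n_max) return(x)
  x[unique(round(seq(1L, length(x), length.out = n_max)))]
}

#' Estimate gating threshold(s) for one channel
#'
#' Operationalizes manual gate placement. `"valley"` locates the
#' kernel-density minima between the largest modes (the two largest for one
#' threshold, the three largest for two); `"gmm"` fits a 2- or 3-component
#' Gaussian mixture and returns the equal-posterior boundaries between
#' ordered components; `"quantile"` is the fixed-quantile fallback used
#' when the data show no usable additional mode. All methods are
#' deterministic given identical input.
#'
#' @param values Numeric vector of intensities in gating space.
#' @param mode `"valley"`, `"gmm"` or `"quantile"`.
#' @param n_thresholds 1 (positive/negative split) or 2 (low/int/high
#'   bands).
#' @param fallback_quantile Quantile used by the fallback (default 0.995:
#'   with no positive population, the gate sits above essentially all
#'   events).
#' @param min_events Minimum number of events required (default 50).
#' @return List with `thresholds` (numeric, length 1 or 2), `method_tag`
#'   (method actually used) and `fallback` (logical).
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_threshold <- function(values, mode = c("valley", "gmm", "quantile"),
                               n_thresholds = 1,
                               fallback_quantile = 0.995, min_events = 50) {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  if (length(values) < min_events)
    stop("need at least ", min_events, " events to place a threshold",
         call. = FALSE)
  fallback <- function() {
    q <- if (n_thresholds == 1) fallback_quantile
         else c(fallback_quantile / 2, fallback_quantile)
    list(thresholds = as.numeric(stats::quantile(values, q, names = FALSE)),
         method_tag = "quantile", fallback = mode != "quantile")
  }
  if (mode == "quantile" || stats::sd(values) == 0) return(fallback())

  if (mode == "valley") {
    d <- stats::density(values, n = 1024)
    y <- d$y; x <- d$x
    # interior local maxima
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    peaks <- peaks[y[peaks] > 1e-3 * max(y)]
    # Greedy selection by height, but a candidate only counts as a new mode
    # if the density drops below half the smaller peak between it and every
    # mode already selected; otherwise it is a ripple on the same cluster.
    sel <- integer()
    for (p in peaks[order(y[peaks], decreasing = TRUE)]) {
      separated <- all(vapply(sel, function(s) {
        seg <- seq(min(p, s), max(p, s))
        min(y[seg]) < 0.5 * min(y[p], y[s])
      }, TRUE))
      if (separated) sel <- c(sel, p)
      if (length(sel) == n_thresholds + 1L) break
    }
    if (length(sel) < n_thresholds + 1L) return(fallback())
    top <- sort(sel)
    th <- vapply(seq_len(n_thresholds), function(k) {
      seg <- seq(top[k], top[k + 1L])
      lo <- min(y[seg])
      # centre of the low-density plateau between the two modes
      plateau <- seg[y[seg] <= lo + 1e-9 * max(y)]
      stats::median(x[plateau])
    }, 0)
    list(thresholds = th, method_tag = "valley", fallback = FALSE)
  } else {
    g <- n_thresholds + 1L
    fit <- tryCatch(
      mclust::Mclust(thin_sorted(values), G = g, modelNames = "V",
                     verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    mu <- fit$parameters$mean
    ord <- order(mu)
    th <- numeric(n_thresholds)
    for (k in seq_len(n_thresholds)) {
      a <- ord[k]; b <- ord[k + 1L]
      grid <- seq(mu[a], mu[b], length.out = 2000L)
      post <- component_density(grid, fit$parameters)
      # equal-posterior boundary between the two adjacent components
      cross <- which(post[, b] >= post[, a])
      if (!length(cross) || cross[1] == 1L) return(fallback())
      th[k] <- mean(grid[cross[1] - c(1L, 0L)])
    }
    if (n_thresholds == 2L && diff(th) <= 0) return(fallback())
    list(thresholds = th, method_tag = "gmm", fallback = FALSE)
  }
}

# Weighted component densities of a 1-D mclust "V" fit on a grid.
component_density <- function(grid, par) {
  pro <- par$pro
  mu <- par$mean
  sd <- sqrt(par$variance$sigmasq)
  if (length(sd) == 1L) sd <- rep(sd, length(mu))
  vapply(seq_along(mu), function(k)
    pro[k] * stats::dnorm(grid, mu[k], sd[k]), numeric(length(grid)))
}

#' Estimate a full threshold set for a hierarchy
#'
#' Places one threshold (valley between the two largest density modes) or
#' two (valleys between the three largest) on every channel the hierarchy
#' gates automatically, using the events that pass the fixed-threshold root
#' gate. Fallbacks to the quantile method are recorded per channel in the
#' result.
#'
#' @param events A transformed [event_table()] (see
#'   [transform_intensities()]).
#' @param hierarchy A [gating_hierarchy()].
#' @param min_events Passed to [estimate_threshold()].
#' @return A named list (`threshold_set`): per channel a list with
#'   `thresholds`, `method_tag`, `fallback`.
#' @export
estimate_thresholds <- function(events, hierarchy, min_events = 50) {
  stopifnot(inherits(events, "event_table"))
  root_keep <- evaluate_conditions(events, hierarchy$root$conditions,
                                   thresholds = list())
  m <- events$events[root_keep, , drop = FALSE]
  tri <- hierarchy_trilevel_channels(hierarchy)
  channels <- setdiff(hierarchy_channels(hierarchy), auto_exempt(hierarchy))
  out <- list()
  for (ch in channels) {
    if (!ch %in% colnames(m))
      stop("channel '", ch, "' used by the hierarchy is absent from the ",
           "event table", call. = FALSE)
    nt <- if (ch %in% tri) 2L else 1L
    out[[ch]] <- estimate_threshold(m[, ch], mode = "valley",
                                    n_thresholds = nt,
                                    min_events = min_events)
  }
  structure(out, class = "threshold_set")
}

# Channels whose every condition in the hierarchy is fixed (no auto
# threshold needed).
auto_exempt <- function(hierarchy) {
  nodes <- hierarchy_nodes(hierarchy)
  conds <- unlist(lapply(nodes, `[[`, "conditions"), recursive = FALSE)
  ch <- vapply(conds, `[[`, "", "channel")
  fixed <- vapply(conds, function(cc) identical(cc$threshold_source, "fixed"),
                  TRUE)
  setdiff(unique(ch[fixed]), unique(ch[!fixed]))
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>", length(x), "channels\n")
  for (ch in names(x)) {
    cat("  ", format(ch, width = 12), " ",
        paste(signif(x[[ch]]$thresholds, 4), collapse = " / "),
        "  [", x[[ch]]$method_tag,
        if (isTRUE(x[[ch]]$fallback)) ", fallback", "]\n", sep = "")
  }
  invisible(x)
}

# Evaluate a conjunction of conditions on (a subset of) the event matrix.
# Ties at a threshold go to the positive/higher side (documented convention).
evaluate_conditions <- function(events, conditions, thresholds,
                                subset = NULL) {
  m <- events$events
  keep <- rep(TRUE, nrow(m))
  if (!is.null(subset)) keep <- subset
  for (cond in conditions) {
    if (!cond$channel %in% colnames(m))
      stop("channel '", cond$channel, "' absent from the event table",
           call. = FALSE)
    v <- m[, cond$channel]
    if (identical(cond$threshold_source, "fixed")) {
      th <- as.numeric(cond$threshold)
    } else {
      ts <- thresholds[[cond$channel]]
      if (is.null(ts))
        stop("no threshold available for channel '", cond$channel, "'",
             call. = FALSE)
      th <- ts$thresholds
    }
    pass <- switch(cond$relation,
      positive = v >= th[1],
      negative = v < th[1],
      low = v < th[1],
      intermediate = if (length(th) < 2)
        stop("relation 'intermediate' on '", cond$channel,
             "' needs two thresholds", call. = FALSE)
        else v >= th[1] & v < th[2],
      high = v >= th[length(th)])
    keep <- keep & pass
  }
  keep
}

#' Gate a sample through a hierarchy
#'
#' Assigns events top-down: a node's member set is the intersection of its
#' parent's member set with all of the node's conditions. Produces
#' per-node event counts, fractions of parent, and fractions of the
#' CD45-positive leukocyte node.
#'
#' @param events An [event_table()] (raw; it is asinh-transformed
#'   internally unless already transformed).
#' @param hierarchy A [gating_hierarchy()].
#' @param thresholds `"auto"` (estimate via [estimate_thresholds()]) or a
#'   `threshold_set`.
#' @param cofactor Transform cofactor, see [transform_intensities()].
#' @param keep_membership Attach the per-event node membership matrix
#'   (logical, events x nodes) as attribute `"membership"`.
#' @return A `subset_result`: data frame with columns `node`, `parent`,
#'   `reported`, `count`, `fraction_of_parent`, `fraction_of_leukocytes`;
#'   attributes `thresholds` and `sample_id`.
#' @export
gate_sample <- function(events, hierarchy, thresholds = "auto",
                        cofactor = 150, keep_membership = FALSE) {
  stopifnot(inherits(events, "event_table"),
            inherits(hierarchy, "gating_hierarchy"))
  if (!events$transformed)
    events <- transform_intensities(events, cofactor = cofactor)
  missing <- setdiff(hierarchy_channels(hierarchy), events$channel_names)
  if (length(missing))
    stop("hierarchy channels missing from the event table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (identical(thresholds, "auto"))
    thresholds <- estimate_thresholds(events, hierarchy)

  nodes <- hierarchy_nodes(hierarchy)
  n_ev <- nrow(events$events)
  member <- matrix(FALSE, nrow = n_ev, ncol = length(nodes),
                   dimnames = list(NULL, vapply(nodes, `[[`, "", "name")))
  counts <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    parent_set <- if (is.na(n$parent)) NULL else member[, n$parent]
    member[, i] <- evaluate_conditions(events, n$conditions, thresholds,
                                       subset = parent_set)
    counts[i] <- sum(member[, i])
  }
  parent_counts <- vapply(seq_along(nodes), function(i) {
    p <- nodes[[i]]$parent
    if (is.na(p)) n_ev else counts[match(p, colnames(member))]
  }, 0)
  leuko <- hierarchy$leukocyte_node
  leuko_count <- if (!is.null(leuko)) counts[match(leuko, colnames(member))]
                 else NA_integer_
  res <- data.frame(
    node = colnames(member),
    parent = vapply(nodes, `[[`, "", "parent"),
    reported = vapply(nodes, `[[`, TRUE, "reported"),
    count = counts,
    fraction_of_parent = ifelse(parent_counts > 0, counts / parent_counts, 0),
    fraction_of_leukocytes = if (!is.na(leuko_count) && leuko_count > 0)
      counts / leuko_count else NA_real_,
    stringsAsFactors = FALSE)
  attr(res, "thresholds") <- thresholds
  attr(res, "sample_id") <- events$sample_id
  if (keep_membership) attr(res, "membership") <- member
  class(res) <- c("subset_result", "data.frame")
  res
}

#' Gate every sample of a study
#'
#' @param study A `cyto_study` from [generate_study()], or a list of
#'   [event_table()]s.
#' @param hierarchy A [gating_hierarchy()]; defaults to the study's own.
#' @param ... Passed to [gate_sample()].
#' @return Data frame of stacked [gate_sample()] results with a `sample_id`
#'   column (plus `animal_id`, `timepoint`, `group`, `block` metadata).
#' @export
gate_study <- function(study, hierarchy = NULL, ...) {
  samples <- if (inherits(study, "cyto_study")) study$samples else study
  if (is.null(hierarchy)) {
    if (!inherits(study, "cyto_study"))
      stop("supply a hierarchy when gating a plain sample list",
           call. = FALSE)
    hierarchy <- study$config$hierarchy
  }
  out <- lapply(samples, function(et) {
    r <- gate_sample(et, hierarchy, ...)
    cbind(data.frame(sample_id = et$sample_id, animal_id = et$animal_id,
                     timepoint = et$timepoint, group = et$group,
                     block = et$block, stringsAsFactors = FALSE),
          as.data.frame(r))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
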