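# Synthetic event-level cytometry with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a fixed set of mutually exclusive cell populations, per-animal
# and per-occasion log-normal variation of their whole-blood concentrations,
# multinomial event sampling, and per-channel log-normal staining
# intensities at four canonical expression levels.

.expression_levels <- c("negative", "low", "intermediate", "high")
.level_rank <- c(negative = 0L, low = 1L, intermediate = 2L, high = 3L)

#' Default staining-intensity model
#'
#' Per expression level, a log-normal intensity distribution given as
#' (location, scale) in log10 intensity units. Fluorescence and scatter
#' channels carry separate models: scatter pulses live on a higher, tighter
#' scale and are never asinh-transformed. `negative` and `low` share the
#' fluorescence autofluorescence location; they are distinguished only on
#' channels gated with two thresholds, where `low` is the bottom band.
#'
#' @return A list with elements `fluor` and `scatter`, each a named list
#'   mapping expression level to `c(location, scale)` in log10 units.
#' @export
default_intensity_model <- function() {
  list(
    fluor = list(negative     = c(location = 2.0, scale = 0.15),
                 low          = c(location = 2.0, scale = 0.15),
                 intermediate = c(location = 3.2, scale = 0.15),
                 high         = c(location = 4.2, scale = 0.15)),
    scatter = list(negative     = c(location = 2.90, scale = 0.05),
                   low          = c(location = 4.48, scale = 0.05),
                   intermediate = c(location = 4.85, scale = 0.05),
                   high         = c(location = 5.18, scale = 0.05)))
}

#' Define a synthetic cell population
#'
#' @param name Population name (for reported populations, conventionally the
#'   matching gate-node name, but any label is allowed).
#' @param concentration Baseline whole-blood concentration in cells/uL (> 0).
#' @param signature Named character vector mapping every channel the
#'   population is measured on to an expression level
#'   (`"negative"`, `"low"`, `"intermediate"`, `"high"`).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, concentration, signature) {
  if (!is.numeric(concentration) || concentration <= 0)
    stop("population concentration must be > 0", call. = FALSE)
  bad <- signature[!signature %in% .expression_levels]
  if (length(bad))
    stop("unknown expression level(s) in signature of '", name, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name),
                 concentration = as.numeric(concentration),
                 signature = signature),
            class = "population_spec")
}

# Build a full signature: every panel channel at `base` level, overridden
# where stated.
full_signature <- function(panel, overrides = character(),
                           base_fluor = "negative", base_scatter = "low") {
  channels <- c(panel$scatter_channels, panel$markers$marker)
  sig <- c(stats::setNames(rep(base_scatter, length(panel$scatter_channels)),
                           panel$scatter_channels),
           stats::setNames(rep(base_fluor, nrow(panel$markers)),
                           panel$markers$marker))
  sig[names(overrides)] <- overrides
  sig[channels]
}

#' Default synthetic populations for a built-in panel
#'
#' A mutually exclusive set of leaf populations whose signatures resolve the
#' built-in gating hierarchy, at baseline concentrations chosen to be
#' order-of-magnitude plausible for healthy adult mouse peripheral blood
#' (total leukocytes around 2,500-3,000 cells/uL). A debris/doublet "junk"
#' population outside all gates makes up about 2% of events.
#'
#' @param panel_name `"myeloid"`, `"lymphoid"` or `"intracellular"`.
#' @param panel Optional panel object (defaults to the matching built-in).
#' @return A list of [population_spec()] objects.
#' @export
default_populations <- function(panel_name = c("myeloid", "lymphoid",
                                               "intracellular"),
                                panel = NULL) {
  panel_name <- match.arg(panel_name)
  if (is.null(panel)) panel <- builtin_panel(panel_name)$panel
  hi <- function(...) stats::setNames(rep("high", length(c(...))), c(...))
  pop <- function(name, conc, ..., fsc = "low", ssc = "low") {
    over <- c(...)
    over <- c(over, FSC = fsc, SSC = ssc)
    population_spec(name, conc, full_signature(panel, over))
  }
  junk <- function(conc) {
    population_spec("junk", conc,
                    full_signature(panel, c(FSC = "negative",
                                            SSC = "negative")))
  }
  # Residual erythrocytes/platelet aggregates: intact-sized scatter but
  # CD45-negative, so the leukocyte gate has a visible negative mode.
  rbc <- function(conc) population_spec(
    "rbc_platelets", conc, full_signature(panel, c(FSC = "low", SSC = "low")))
  switch(panel_name,
    myeloid = list(
      pop("lymphoid_other", 2100, hi("CD45")),
      pop("neutrophils", 200, hi("CD45", "CD11b", "CD172a", "Ly6G"),
          c(Ly6C = "intermediate"), fsc = "high", ssc = "high"),
      pop("eosinophils", 100, hi("CD45", "CD11b", "CD172a", "Siglec-F"),
          fsc = "high", ssc = "high"),
      pop("basophils", 30, hi("CD45", "CD11b", "CD172a", "CD49b"),
          fsc = "high", ssc = "high"),
      pop("classical_monocytes", 60,
          hi("CD45", "CD11b", "CD172a", "F4/80", "CCR2"),
          c(Ly6C = "high"), fsc = "intermediate", ssc = "intermediate"),
      pop("nonclassical_monocytes", 40,
          hi("CD45", "CD11b", "CD172a", "F4/80"),
          c(Ly6C = "low"), fsc = "intermediate", ssc = "intermediate"),
      pop("m_mdsc", 50, hi("CD45", "CD11b", "CD172a", "CCR2"),
          c(Ly6C = "high"), fsc = "intermediate", ssc = "intermediate"),
      pop("pmn_mdsc", 20, hi("CD45", "CD11b", "CD172a", "Ly6G"),
          c(Ly6C = "low"), fsc = "high", ssc = "high"),
      pop("pdc_immature", 6, hi("CD45", "CD11c", "B220")),
      pop("pdc_mature", 4, hi("CD45", "CD11c", "B220", "MHC-II")),
      pop("cdc1_immature", 5, hi("CD45", "CD11c", "MHC-II"),
          fsc = "intermediate"),
      pop("cdc1_mature", 3, hi("CD45", "CD11c", "MHC-II", "CD80", "CD86"),
          fsc = "intermediate"),
      rbc(110),
      junk(54)),
    lymphoid = list(
      pop("cd4_naive", 75, hi("CD45", "CD3", "CD4", "CD62L")),
      pop("cd4_cmem", 25, hi("CD45", "CD3", "CD4", "CD44", "CD62L")),
      pop("cd4_emem", 25, hi("CD45", "CD3", "CD4", "CD44")),
      pop("cd4_acteff", 30, hi("CD45", "CD3", "CD4", "CD44", "CD25")),
      pop("th1", 4, hi("CD45", "CD3", "CD4", "CXCR3", "CD62L")),
      pop("th1_eff", 3, hi("CD45", "CD3", "CD4", "CXCR3", "CD44")),
      pop("th2", 2, hi("CD45", "CD3", "CD4", "CCR4", "CD62L")),
      pop("th2_eff", 1.5, hi("CD45", "CD3", "CD4", "CCR4", "CD44")),
      pop("th17", 2, hi("CD45", "CD3", "CD4", "CCR6", "CCR4", "CD62L")),
      pop("th17_eff", 1.5, hi("CD45", "CD3", "CD4", "CCR6", "CCR4", "CD44")),
      pop("th9", 9, hi("CD45", "CD3", "CD4", "CCR6", "CD62L")),
      pop("treg", 6, hi("CD45", "CD3", "CD4", "CD25", "TNF-RII", "CD44")),
      pop("cd8_naive", 85, hi("CD45", "CD3", "CD8", "CD62L")),
      pop("cd8_cmem", 22, hi("CD45", "CD3", "CD8", "CD44", "CD62L")),
      pop("cd8_emem", 9, hi("CD45", "CD3", "CD8", "CD44")),
      pop("cd8_acteff", 12, hi("CD45", "CD3", "CD8", "CD44", "CD25")),
      pop("nkt", 53, hi("CD45", "CD3", "NK1.1", "CD44")),
      pop("nk", 70, hi("CD45", "NK1.1")),
      pop("b_cells", 1400, hi("CD45", "CD19")),
      pop("plasma_cells", 18, hi("CD45", "CD19", "CD138")),
      pop("granulocyte_filler", 450, hi("CD45"), fsc = "high", ssc = "high"),
      pop("monocyte_filler", 150, hi("CD45"), fsc = "intermediate",
          ssc = "intermediate"),
      rbc(100),
      junk(50)),
    intracellular = list(
      pop("cd4_conv", 180, hi("CD3", "CD4")),
      pop("cd4_treg_other", 12, hi("CD3", "CD4", "FOXP3", "CD25")),
      pop("cd4_efftreg_ccr5", 8,
          hi("CD3", "CD4", "FOXP3", "CD25", "CD44", "CCR5")),
      pop("cd8_noncyto", 90, hi("CD3", "CD8")),
      pop("cd8_cyto", 25, hi("CD3", "CD8", "GranzymeB", "Perforin", "CD44")),
      pop("nkt_other", 30, hi("CD3", "NK1.1", "CD44")),
      pop("nkt_gzm", 15, hi("CD3", "NK1.1", "GranzymeB")),
      pop("nk_perf_rest", 30, hi("NK1.1", "Perforin", "GranzymeB")),
      pop("nk_act_perf", 20, hi("NK1.1", "Perforin", "CD25", "CD44")),
      pop("nk_neg", 25, hi("NK1.1")),
      pop("b_other_filler", 150, character()),
      pop("dead_cells", 30, hi("Viability")),
      junk(12)))
}

#' Simulation configuration
#'
#' Bundles everything [generate_study()] needs: the panel and hierarchy, the
#' population set, the longitudinal design, the variance components of
#' log10 abundance, the staining-intensity model, and the tube volumes.
#'
#' The abundance model for population *p* in animal *a* at occasion *t* is
#' `log10 c = log10(base) + u_a + w_t + e_at` with `u ~ N(0, sigma_inter^2)`
#' (per-animal effect, shared across that animal's occasions),
#' `w ~ N(0, sigma_intra^2)` (per-occasion effect, shared across animals at
#' that occasion) and `e ~ N(0, sigma_resid^2)` (animal-by-occasion
#' residual). All effects are drawn independently per population.
#'
#' @param panel_config A list with `panel` and `hierarchy`, e.g. from
#'   [builtin_panel()].
#' @param populations List of [population_spec()]; defaults to
#'   [default_populations()] for built-in panels.
#' @param n_animals,n_timepoints Longitudinal design (5 x 5 by default, the
#'   repeated-sampling design on days 1, 5, 8, 12 and 15).
#' @param events_per_sample Events acquired per sample (ignored when
#'   `acquired_volume` is given, in which case the event count is derived
#'   from the suspension concentration).
#' @param sigma_inter,sigma_intra,sigma_resid SDs of the log10-abundance
#'   random effects (see Details).
#' @param intensity_model See [default_intensity_model()].
#' @param blood_volume,diluent_volume Tube volumes in uL (50 uL blood into
#'   500 uL anticoagulant by default).
#' @param acquired_volume Optional fixed acquired suspension volume (uL).
#' @param seed Integer seed governing all randomness of the study.
#' @param animal_ids,timepoints Optional label vectors.
#' @return A `sim_config` object.
#' @export
sim_config <- function(panel_config,
                       populations = NULL,
                       n_animals = 5, n_timepoints = 5,
                       events_per_sample = 20000,
                       sigma_inter = 0.2, sigma_intra = 0.1,
                       sigma_resid = 0.05,
                       intensity_model = default_intensity_model(),
                       blood_volume = 50, diluent_volume = 500,
                       acquired_volume = NULL, seed = NULL,
                       animal_ids = NULL, timepoints = NULL) {
  panel <- panel_config$panel
  hierarchy <- panel_config$hierarchy
  if (is.null(populations)) {
    if (!panel$name %in% .panel_names)
      stop("no default populations for panel '", panel$name,
           "'; supply `populations`", call. = FALSE)
    populations <- default_populations(panel$name, panel = panel)
  }
  if (sigma_inter < 0 || sigma_intra < 0 || sigma_resid < 0)
    stop("variance-component SDs must be >= 0", call. = FALSE)
  if (is.null(acquired_volume) && events_per_sample < 1)
    stop("events_per_sample must be >= 1", call. = FALSE)
  if (blood_volume <= 0 || diluent_volume < 0 ||
      (!is.null(acquired_volume) && acquired_volume <= 0))
    stop("volumes must be positive", call. = FALSE)
  if (n_animals < 1 || n_timepoints < 1)
    stop("design needs at least one animal and one timepoint", call. = FALSE)
  # every channel on a population's root-to-node gating path must be covered
  channels_needed <- hierarchy_channels(hierarchy)
  for (p in populations) {
    missing <- setdiff(channels_needed, names(p$signature))
    if (length(missing))
      stop("population '", p$name, "' signature misses gated channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  total <- sum(vapply(populations, `[[`, 0, "concentration"))
  if (total <= 0) stop("total concentration must be > 0", call. = FALSE)
  structure(list(
    panel = panel, hierarchy = hierarchy, populations = populations,
    n_animals = as.integer(n_animals),
    n_timepoints = as.integer(n_timepoints),
    events_per_sample = as.integer(events_per_sample),
    sigma_inter = sigma_inter, sigma_intra = sigma_intra,
    sigma_resid = sigma_resid,
    intensity_model = intensity_model,
    blood_volume = blood_volume, diluent_volume = diluent_volume,
    acquired_volume = acquired_volume,
    seed = if (!is.null(seed)) as.integer(seed),
    animal_ids = if (is.null(animal_ids))
      sprintf("animal%02d", seq_len(n_animals)) else as.character(animal_ids),
    timepoints = if (is.null(timepoints))
      sprintf("t%02d", seq_len(n_timepoints)) else as.character(timepoints)),
    class = "sim_config")
}

# Level model for a channel: scatter or fluorescence.
channel_class <- function(channel, panel) {
  if (channel %in% panel$scatter_channels) "scatter" else "fluor"
}

# Draw intensities for one population block: matrix n x channels (linear).
draw_intensities <- function(n, signature, panel, model) {
  channels <- names(signature)
  out <- matrix(0, nrow = n, ncol = length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    par <- model[[channel_class(ch, panel)]][[signature[[ch]]]]
    out[, ch] <- 10^stats::rnorm(n, mean = par[["location"]],
                                 sd = par[["scale"]])
  }
  out
}

#' Generate one synthetic sample
#'
#' Draws realized per-population concentrations from the hierarchical
#' log-normal abundance model, splits the acquired events multinomially, and
#' draws per-event channel intensities from the population signatures.
#'
#' @param config A [sim_config()].
#' @param animal_index,occasion_index Position in the design (1-based).
#' @param animal_effects Numeric vector of per-population animal effects
#'   `u_a` (drawn once per animal); `NULL` draws a fresh one.
#' @param occasion_effects Numeric vector of per-population occasion effects
#'   `w_t` (shared across animals); `NULL` draws a fresh one.
#' @param seed Optional seed for a standalone reproducible sample.
#' @return A list with `events` (an [event_table()]), `truth` (data frame of
#'   per-population true concentration and event count), and `labels`
#'   (character vector, true population of each event row).
#' @export
generate_sample <- function(config, animal_index = 1, occasion_index = 1,
                            animal_effects = NULL, occasion_effects = NULL,
                            seed = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pops <- config$populations
  np <- length(pops)
  if (is.null(animal_effects))
    animal_effects <- stats::rnorm(np, 0, config$sigma_inter)
  if (is.null(occasion_effects))
    occasion_effects <- stats::rnorm(np, 0, config$sigma_intra)
  resid <- stats::rnorm(np, 0, config$sigma_resid)
  base <- vapply(pops, `[[`, 0, "concentration")
  conc <- 10^(log10(base) + animal_effects + occasion_effects + resid)

  dilution <- (config$blood_volume + config$diluent_volume) /
    config$blood_volume
  susp_conc <- sum(conc) / dilution        # cells per uL of suspension
  if (is.null(config$acquired_volume)) {
    n_events <- config$events_per_sample
    acquired <- n_events / susp_conc
  } else {
    acquired <- config$acquired_volume
    n_events <- max(1L, as.integer(round(acquired * susp_conc)))
  }
  counts <- as.integer(stats::rmultinom(1, n_events, conc / sum(conc)))

  blocks <- vector("list", np)
  for (i in seq_len(np)) {
    blocks[[i]] <- draw_intensities(counts[i], pops[[i]]$signature,
                                    config$panel, config$intensity_model)
  }
  events <- do.call(rbind, blocks)
  labels <- rep(vapply(pops, `[[`, "", "name"), counts)
  perm <- sample.int(nrow(events))
  events <- events[perm, , drop = FALSE]
  labels <- labels[perm]

  animal_id <- config$animal_ids[animal_index]
  timepoint <- config$timepoints[occasion_index]
  et <- event_table(events,
                    sample_id = paste(animal_id, timepoint, sep = "_"),
                    animal_id = animal_id, timepoint = timepoint,
                    acquired_volume = acquired,
                    blood_volume = config$blood_volume,
                    diluent_volume = config$diluent_volume)
  truth <- data.frame(population = vapply(pops, `[[`, "", "name"),
                      concentration = conc, count = counts,
                      stringsAsFactors = FALSE)
  list(events = et, truth = truth, labels = labels)
}

#' Generate a full longitudinal synthetic study
#'
#' Animal effects are drawn once per animal and shared across that animal's
#' timepoints; occasion effects are drawn once per timepoint and shared
#' across animals (see [sim_config()] for the abundance model).
#'
#' @param config A [sim_config()]; its `seed` governs all randomness.
#' @return A `cyto_study` object: list with `samples` (list of
#'   [event_table()]), `truth` (per sample/population true concentrations
#'   and event counts), `labels` (per-sample true event labels), `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config",
                                            call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- length(config$populations)
  A <- config$n_animals; T_ <- config$n_timepoints
  u <- matrix(stats::rnorm(A * np, 0, config$sigma_inter), nrow = A)
  w <- matrix(stats::rnorm(T_ * np, 0, config$sigma_intra), nrow = T_)
  samples <- list(); truth <- list(); labels <- list()
  k <- 0L
  for (a in seq_len(A)) {
    for (t in seq_len(T_)) {
      k <- k + 1L
      s <- generate_sample(config, animal_index = a, occasion_index = t,
                           animal_effects = u[a, ], occasion_effects = w[t, ])
      samples[[k]] <- s$events
      tr <- s$truth
      tr$sample_id <- s$events$sample_id
      tr$animal_id <- s$events$animal_id
      tr$timepoint <- s$events$timepoint
      truth[[k]] <- tr[, c("sample_id", "animal_id", "timepoint",
                           "population", "concentration", "count")]
      labels[[s$events$sample_id]] <- s$labels
    }
  }
  structure(list(samples = samples, truth = do.call(rbind, truth),
                 labels = labels, config = config),
            class = "cyto_study")
}

#' @export
print.cyto_study <- function(x, ...) {
  cat("<cyto_study> ", length(x$samples), " samples (",
      x$config$n_animals, " animals x ", x$config$n_timepoints,
      " timepoints), panel ", x$config$panel$name, "\n", sep = "")
  invisible(x)
}

#' Simulate a log10-abundance matrix without events
#'
#' Fast path for studying the variance-decomposition machinery: draws the
#' hierarchical abundance model of [sim_config()] directly on the log10
#' scale, skipping event generation.
#'
#' @param n_animals,n_timepoints Design size.
#' @param mean_log10 Grand mean of log10 concentration.
#' @param sigma_inter,sigma_intra,sigma_resid Effect SDs as in [sim_config()].
#' @return An `n_animals` x `n_timepoints` numeric matrix.
#' @export
simulate_log10_matrix <- function(n_animals = 5, n_timepoints = 5,
                                  mean_log10 = 2, sigma_inter = 0.2,
                                  sigma_intra = 0.1, sigma_resid = 0.05) {
  u <- stats::rnorm(n_animals, 0, sigma_inter)
  w <- stats::rnorm(n_timepoints, 0, sigma_intra)
  e <- matrix(stats::rnorm(n_animals * n_timepoints, 0, sigma_resid),
              nrow = n_animals)
  mean_log10 + outer(u, w, `+`) + e
}

# ---- ground truth under the gating hierarchy -----------------------------

# Does a signature satisfy one condition? Levels are ranked
# negative < low < intermediate < high; `positive` means intermediate-or-high,
# `negative`/`low` mean below the (lower) threshold, `intermediate`/`high`
# are the middle/top band of a two-threshold channel. Fixed-threshold
# conditions are evaluated against the level's median intensity.
signature_satisfies_condition <- function(signature, cond, panel, model,
                                          cofactor = 150) {
  level <- signature[[cond$channel]]
  if (is.null(level) || is.na(level))
    stop("signature misses channel ", cond$channel, call. = FALSE)
  if (identical(cond$threshold_source, "fixed")) {
    cls <- channel_class(cond$channel, panel)
    loc <- 10^model[[cls]][[level]][["location"]]
    val <- if (cls == "fluor") asinh(loc / cofactor) else loc
    th <- as.numeric(cond$threshold)
    return(switch(cond$relation,
                  positive = val >= th[1],
                  negative = val < th[1],
                  low = val < th[1],
                  intermediate = val >= th[1] && val < th[2],
                  high = val >= th[2]))
  }
  r <- .level_rank[[level]]
  switch(cond$relation,
         positive = r >= 2L,
         negative = r <= 1L,
         low = r <= 1L,
         intermediate = r == 2L,
         high = r == 3L)
}

#' Map populations to the gate nodes that contain them
#'
#' Evaluates each population's signature against the full root-to-node
#' condition path of every node in a hierarchy.
#'
#' @param hierarchy A [gating_hierarchy()].
#' @param populations List of [population_spec()].
#' @param panel The panel the hierarchy belongs to.
#' @param intensity_model,cofactor Used only for fixed-threshold conditions.
#' @return Logical matrix, nodes x populations.
#' @export
population_node_membership <- function(hierarchy, populations, panel,
                                       intensity_model =
                                         default_intensity_model(),
                                       cofactor = 150) {
  nodes <- hierarchy_nodes(hierarchy)
  out <- matrix(FALSE, nrow = length(nodes), ncol = length(populations),
                dimnames = list(vapply(nodes, `[[`, "", "name"),
                                vapply(populations, `[[`, "", "name")))
  for (i in seq_along(nodes)) {
    for (j in seq_along(populations)) {
      out[i, j] <- all(vapply(nodes[[i]]$path_conditions, function(cond)
        signature_satisfies_condition(populations[[j]]$signature, cond,
                                      panel, intensity_model, cofactor),
        TRUE))
    }
  }
  out
}

#' Ground-truth event counts and concentrations per gate node
#'
#' Aggregates a sample's (or study's) per-population ground truth up the
#' gating hierarchy: a node's true count is the summed count of every
#' population whose signature satisfies the node's full condition path.
#'
#' @param truth Data frame with columns `population`, `count`,
#'   `concentration` (and optionally `sample_id`).
#' @param config The [sim_config()] the truth was generated under.
#' @return Data frame with columns (`sample_id`,) `node`, `count`,
#'   `concentration`.
#' @export
node_ground_truth <- function(truth, config) {
  membership <- population_node_membership(config$hierarchy,
                                           config$populations, config$panel,
                                           config$intensity_model)
  agg_one <- function(df) {
    counts <- stats::setNames(df$count, df$population)
    concs <- stats::setNames(df$concentration, df$population)
    data.frame(
      node = rownames(membership),
      count = as.integer(membership %*% counts[colnames(membership)]),
      concentration = as.numeric(membership %*% concs[colnames(membership)]),
      stringsAsFactors = FALSE)
  }
  if (!is.null(truth$sample_id)) {
    parts <- lapply(split(truth, truth$sample_id), agg_one)
    out <- do.call(rbind, Map(function(id, df) {
      df$sample_id <- id
      df[, c("sample_id", "node", "count", "concentration")]
    }, names(parts), parts))
    rownames(out) <- NULL
    out
  } else {
    agg_one(truth)
  }
}
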